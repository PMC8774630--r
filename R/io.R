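#' Read a univariate sample from a text file
#'
#' Expects one numeric value per row (an optional single header line is
#' tolerated).  Integer-only content is flagged so that discrete
#' dictionaries can be enabled downstream.
#'
#' @param path file path.
#' @return list with \code{x} (numeric vector), \code{n}, and
#'   \code{discrete} (\code{TRUE} when all values are non-negative
#'   integers).
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("sample file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop(sprintf("empty sample file: %s", path))
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && length(vals) > 1) {   # header line
    lines <- lines[-1]
    lineno <- lineno[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite value at line %d of %s",
                 lineno[bad[1]], path))
  list(x = vals, n = length(vals),
       discrete = all(vals >= 0 & vals == floor(vals)))
}

#' Read a dictionary from a YAML or JSON config file
#'
#' The config specifies \code{family} (\code{gaussian} or
#' \code{poisson}), the parameter vectors (\code{mean} and \code{sd}, or
#' \code{rate}), and an optional logical \code{normalize}.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return a \code{\link{dictionary}}.
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path))
    stop(sprintf("dictionary file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$family)) stop("dictionary config must name a 'family'")
  d <- switch(cfg$family,
    gaussian = dictionary("gaussian", mean = unlist(cfg$mean),
                          sd = unlist(cfg$sd)),
    poisson = dictionary("poisson", rate = unlist(cfg$rate)),
    stop(sprintf("unsupported dictionary family '%s'", cfg$family)))
  if (isTRUE(cfg$normalize)) d <- normalize_dictionary(d) else d
}

#' Serialize a fit to JSON
#'
#' Full-precision round trip of the numeric fields of a
#' \code{\link{fit_coefficients}} result.
#'
#' @param fit a \code{csde_fit}.
#' @param path output path; when \code{NULL} the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
write_fit <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "csde_fit"))
  obj <- list(beta = fit$beta, support = fit$support,
              objective = fit$objective,
              kkt_max_violation = fit$kkt_max_violation,
              omega = fit$omega, c = fit$c, nonneg = fit$nonneg,
              n_iter = fit$n_iter, converged = fit$converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a fit back from JSON
#'
#' @param path file written by \code{\link{write_fit}}.
#' @return a \code{csde_fit}-like list (numeric fields restored exactly).
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$support <- as.integer(obj$support)
  class(obj) <- "csde_fit"
  obj
}

#' Export penalty weights as a table
#'
#' @param wt result of \code{\link{compute_weights}}.
#' @param L the sup-norm vector the weights were computed from.
#' @param path optional CSV output path.
#' @return data frame with columns \code{j}, \code{L}, \code{omega},
#'   \code{omega_tilde}.
#' @export
weights_table <- function(wt, L, path = NULL) {
  df <- data.frame(j = seq_along(wt$omega), L = rep_len(L, length(wt$omega)),
                   omega = wt$omega, omega_tilde = wt$omega_tilde)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
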