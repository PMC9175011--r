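#' Read and write tube profiles as long-format CSV
#'
#' The canonical exchange format: one row per observation with columns
#' `tube_id`, `x` (position in micrometres) and `y` (intensity). Reading
#' validates the file and reports offending row numbers for non-numeric
#' coordinates or duplicated (tube, position) pairs.
#'
#' @param path CSV file path.
#' @param data Data frame with columns `tube_id`, `x`, `y`.
#' @return `read_tubes()` returns a tibble `tube_id`, `x`, `y`;
#'   `write_tubes()` returns `path` invisibly.
#' @export
read_tubes <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("tube_id", "x", "y")
  if (!all(need %in% names(raw))) {
    abort(sprintf("%s: missing required column(s) %s", path,
                  paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric x/y at data row(s) %s", path,
                  paste(head(bad, 10), collapse = ", ")))
  }
  dup <- which(duplicated(paste(raw$tube_id, x)))
  if (length(dup)) {
    abort(sprintf("%s: duplicated (tube_id, x) pair(s) at data row(s) %s",
                  path, paste(head(dup, 10), collapse = ", ")))
  }
  tibble(tube_id = raw$tube_id, x = x, y = y)
}

#' @rdname read_tubes
#' @export
write_tubes <- function(data, path) {
  stopifnot(all(c("tube_id", "x", "y") %in% names(data)))
  readr::write_csv(data[, c("tube_id", "x", "y")], path)
  invisible(path)
}

#' Read and write tube-by-position matrices as wide CSV
#'
#' Wide layout for the preprocessing path: first column `tube_id`, remaining
#' column names are the grid positions, empty cells are missing values.
#'
#' @param path CSV file path.
#' @param mat Numeric matrix with the grid in its `"grid"` attribute or
#'   numeric column names.
#' @return `read_intensity_matrix()` returns a numeric matrix with `NA` for
#'   missing entries and the grid attached; `write_intensity_matrix()`
#'   returns `path` invisibly.
#' @export
read_intensity_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (names(raw)[1] != "tube_id") {
    abort(sprintf("%s: first column must be 'tube_id'", path))
  }
  grid <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (anyNA(grid)) abort(sprintf("%s: header must hold numeric grid positions", path))
  mat <- as.matrix(raw[, -1])
  mode(mat) <- "numeric"
  rownames(mat) <- raw$tube_id
  colnames(mat) <- names(raw)[-1]
  attr(mat, "grid") <- grid
  mat
}

#' @rdname read_intensity_matrix
#' @export
write_intensity_matrix <- function(mat, path) {
  grid <- matrix_grid(mat)
  df <- as.data.frame(mat)
  names(df) <- format(grid, trim = TRUE)
  df <- cbind(tube_id = rownames(mat), df)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Serialize a fit to JSON
#'
#' Writes every estimate, its uncertainty, the options and the reference
#' solution's metadata hash, so a fit artifact is self-describing and
#' reloadable.
#'
#' @param fit A `tube_fit` or `population_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  UseMethod("write_fit_json")
}

#' @export
write_fit_json.tube_fit <- function(fit, path) {
  payload <- list(
    type = "tube_fit",
    tube_id = fit$tube_id,
    estimates = list(lambda = fit$lambda, mu = fit$mu, nu = fit$nu,
                     knf = fit$knf, kpf = fit$kpf, sigma = fit$sigma),
    rss = fit$rss, n = fit$n,
    cov_shape = fit$cov_shape,
    on_boundary = fit$on_boundary, converged = fit$converged,
    restarts_used = fit$restarts_used,
    start = as.list(fit$start),
    constants = unclass(fit$constants),
    reference = c(fit$ref_meta, hash = fit$ref_hash))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @export
write_fit_json.population_fit <- function(fit, path) {
  payload <- list(
    type = "population_fit",
    m = fit$m, dropped = fit$dropped,
    theta0 = as.list(fit$theta0),
    rates0 = as.list(fit$rates0),
    sigma = fit$sigma,
    Sigma0 = fit$Sigma0, Sigma0_raw = fit$Sigma0_raw,
    eigenvalues_raw = fit$eigenvalues_raw,
    cov_theta0 = fit$cov_theta0,
    ci_shape = fit$ci_shape, ci_rates = fit$ci_rates,
    rho_shape = fit$rho_shape, rho_rates = fit$rho_rates,
    conf.level = fit$conf.level,
    per_tube = per_tube_estimates(fit),
    constants = unclass(fit$constants),
    reference = c(fit$ref_meta, hash = fit$ref_hash))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Reload a fit artifact written by [write_fit_json()]
#'
#' @param path JSON path.
#' @return A named list mirroring the JSON payload, with matrices restored.
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("cov_shape", "Sigma0", "Sigma0_raw", "cov_theta0")) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.matrix(out[[nm]])
  }
  out
}
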