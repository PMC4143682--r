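#' Residualize a quantitative trait on covariates
#'
#' Least-squares residuals of the trait on an intercept plus the supplied
#' covariate columns, divided by their sample standard deviation so the
#' adjusted trait has mean 0 and unit variance. This is the phenotype
#' preparation step expected by every region test in the package: blood
#' pressure is typically adjusted for age, sex, age x sex and
#' antihypertensive medication use per exam; ancestry principal components
#' from [genotype_pcs()] can be supplied the same way.
#'
#' Rows with a missing trait or any missing covariate are dropped with a
#' warning.
#'
#' @param data data.frame with `fid`, `iid`, the trait column and covariate
#'   columns (one row per person for a given exam).
#' @param trait Name of the trait column.
#' @param covariates Character vector of covariate column names (may be
#'   empty: residualization then just centers and scales). Interactions may
#'   be precomputed as literal product columns.
#' @param exam Optional exam label attached to the result.
#' @return A `trait_vector`: data.frame with `fid`, `iid`, `value`;
#'   attributes `exam` and `n_dropped`.
#' @export
residualize <- function(data, trait, covariates = character(0), exam = NA) {
  stopifnot(all(c("fid", "iid", trait, covariates) %in% names(data)))
  y <- data[[trait]]
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates) > 0) {
    X <- cbind(X, as.matrix(data[covariates]))
  }
  complete <- !is.na(y) & stats::complete.cases(X)
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    warning(n_drop, " person(s) dropped: missing trait or covariate values")
  }
  y <- y[complete]; X <- X[complete, , drop = FALSE]
  if (length(y) < ncol(X) + 2) stop("too few complete observations to residualize")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  r <- qr.resid(qrX, y)
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-12 * max(1, stats::sd(y))) {
    stop("degenerate trait: residuals have (near-)zero variance after adjustment")
  }
  out <- data.frame(fid = data$fid[complete], iid = data$iid[complete],
                    value = r / s, stringsAsFactors = FALSE)
  structure(out, class = c("trait_vector", "data.frame"),
            exam = exam, n_dropped = n_drop)
}

#' Average adjusted residuals across exams
#'
#' Per-person mean of the available per-exam residuals, re-standardized to
#' unit variance. Persons present at a subset of exams are averaged over
#' the exams they have; persons with no exam at all are dropped with a
#' warning (this can only happen if an empty trait_vector is supplied).
#'
#' @param traits List of `trait_vector` objects, one per exam.
#' @return A `trait_vector` with attribute `exam = "average"` and a
#'   `n_exams_used` column.
#' @export
average_exams <- function(traits) {
  stopifnot(length(traits) >= 1)
  all_rows <- do.call(rbind, lapply(traits, function(t) as.data.frame(t)[c("fid", "iid", "value")]))
  key <- paste(all_rows$fid, all_rows$iid, sep = ":")
  mean_by <- tapply(all_rows$value, key, mean)
  n_by <- tapply(all_rows$value, key, length)
  keys <- unique(key)
  fidiid <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  v <- as.numeric(mean_by[keys])
  v <- v - mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("degenerate averaged trait: zero variance")
  out <- data.frame(fid = fidiid[, 1], iid = fidiid[, 2], value = v / s,
                    n_exams_used = as.integer(n_by[keys]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("trait_vector", "data.frame"), exam = "average")
}

#' Write a trait vector as a tab-delimited table
#' @param trait A `trait_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait <- function(trait, path) {
  df <- as.data.frame(trait)
  df$exam <- attr(trait, "exam")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
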