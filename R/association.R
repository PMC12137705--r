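#' Partial correlation with covariate control
#'
#' Pearson correlation between the residuals of `x` and `y` after regressing
#' each on the covariate matrix `Z` (intercept always included). With no
#' covariates this reduces to the plain Pearson correlation. The two-sided
#' p-value uses a t distribution with n - 2 - k degrees of freedom, k the
#' number of covariates.
#'
#' @param x,y numeric vectors of equal length.
#' @param Z optional numeric matrix or data frame of covariates (n rows).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(Z) || NCOL(Z) == 0) {
    k <- 0L
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n)
    k <- ncol(Z)
    X <- cbind(`(Intercept)` = 1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop(sprintf("covariate matrix is rank deficient; collinear column(s): %s",
                   paste(dropped, collapse = ", ")))
    }
    rx <- stats::lm.fit(X, x)$residuals
    ry <- stats::lm.fit(X, y)$residuals
  }
  if (n <= k + 3) stop("too few observations for the requested covariates")
  # a residual that is numerically zero relative to its input means the
  # variable lies in the covariate span: the partial correlation is 0
  degen <- sum(rx^2) <= 1e-20 * max(1, sum(x^2)) ||
    sum(ry^2) <= 1e-20 * max(1, sum(y^2))
  if (degen) return(list(r = 0, p = 1, n = n, df = n - 2L - k))
  den <- sqrt(sum(rx^2) * sum(ry^2))
  r <- sum(rx * ry) / den
  r <- min(max(r, -1), 1)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, n = n, df = df)
}

# covariate matrix for one condition: age, gender, handedness and the
# condition-specific mean framewise displacement
condition_covariates <- function(participants, condition) {
  motion_col <- paste0("motion_", condition)
  needed <- c("age", "gender", "handedness", motion_col)
  missing_cols <- setdiff(needed, names(participants))
  if (length(missing_cols)) {
    stop(sprintf("participant table lacks covariate column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  Z <- as.matrix(participants[, needed])
  colnames(Z) <- c("age", "gender", "handedness", "motion")
  Z
}

#' Association between brain-average coupling and the phenotype
#'
#' Partial correlation between the phenotype score g and the brain-average
#' coupling value of every condition x measure cell, controlling for age,
#' gender, handedness and the condition-specific mean framewise
#' displacement. Significance is flagged at the Bonferroni-corrected
#' threshold across the four measures (default p < 0.0125).
#'
#' @param table a [coupling_table()].
#' @param participants data frame with columns `g`, `age`, `gender`,
#'   `handedness` and `motion_<condition>` per analyzed condition, rows
#'   aligned with the table's participant dimension.
#' @param cfg an [analysis_config()].
#' @return Data frame with one row per condition x measure: `condition`,
#'   `measure`, `r`, `p`, `n`, `significant`.
#' @export
brain_average_association <- function(table, participants,
                                      cfg = analysis_config()) {
  ba <- brain_average_by_cell(table)        # n x cond x meas
  conds <- dimnames(ba)[[2]]; measures <- dimnames(ba)[[3]]
  stopifnot(nrow(participants) == dim(ba)[1])
  out <- list()
  for (cond in conds) {
    Z <- condition_covariates(participants, cond)
    for (m in measures) {
      pc <- partial_correlation(ba[, cond, m], participants$g, Z)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, measure = m, r = pc$r, p = pc$p, n = pc$n,
        significant = pc$p < cfg$bonferroni_alpha)
    }
  }
  do.call(rbind, out)
}
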