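# Column-wise Pearson correlations between two matrices' regional profiles,
# excluding the diagonal entry of each column. Vectorized over columns.
profile_correlations <- function(P, F_, warn_constant = TRUE) {
  n <- nrow(P)
  stopifnot(identical(dim(P), dim(F_)))
  dP <- diag(P); dF <- diag(F_)
  m <- n - 1
  sx <- colSums(P) - dP
  sy <- colSums(F_) - dF
  sxx <- colSums(P^2) - dP^2
  syy <- colSums(F_^2) - dF^2
  sxy <- colSums(P * F_) - dP * dF
  covxy <- sxy - sx * sy / m
  varx <- sxx - sx^2 / m
  vary <- syy - sy^2 / m
  den <- sqrt(pmax(varx, 0) * pmax(vary, 0))
  r <- rep(0, n)
  ok <- den > .Machine$double.eps * m
  r[ok] <- covxy[ok] / den[ok]
  if (warn_constant && any(!ok)) {
    warning(sprintf("constant profile in %d region(s): coupling set to 0",
                    sum(!ok)))
  }
  pmin(pmax(r, -1), 1)
}

#' Region-specific structure-function coupling
#'
#' For each region i, the Pearson correlation between column i of a
#' similarity/communication matrix and column i of a condition-specific FC
#' matrix, computed over the N - 1 off-diagonal entries. This is the
#' coupling value r_C.
#'
#' @param pred a [predictor_matrix()].
#' @param fc a [functional_connectome()] with the same regions in the same
#'   order.
#' @return Numeric vector of N coupling values in \[-1, 1\]. Regions whose
#'   predictor profile is constant get 0 with a warning.
#' @export
regional_coupling <- function(pred, fc) {
  P <- pred$values; F_ <- fc$values
  if (!identical(dim(P), dim(F_))) stop("predictor and FC dimensions differ")
  r <- profile_correlations(P, F_)
  names(r) <- fc$region_labels
  r
}

#' Full coupling table for a cohort
#'
#' Computes r_C for every participant x condition x measure x region cell.
#' Participants missing any required condition are dropped with a message.
#'
#' @param predictors nested list: `predictors[[pid]]` is the named list of
#'   four [predictor_matrix()] objects from [all_predictors()].
#' @param fcs nested list: `fcs[[pid]][[condition]]` is a
#'   [functional_connectome()].
#' @param conditions character vector of conditions to include (default: all
#'   conditions of the first participant).
#' @return A 4-D array of class `coupling_table` with dimensions
#'   participant x condition x measure x region.
#' @export
coupling_table <- function(predictors, fcs, conditions = NULL) {
  pids <- names(predictors)
  stopifnot(length(pids) > 0, all(pids %in% names(fcs)))
  if (is.null(conditions)) conditions <- names(fcs[[pids[1]]])
  keep <- vapply(pids, function(p) all(conditions %in% names(fcs[[p]])), TRUE)
  if (any(!keep)) {
    message(sprintf("excluding %d participant(s) with missing conditions: %s",
                    sum(!keep), paste(pids[!keep], collapse = ", ")))
    pids <- pids[keep]
  }
  measures <- names(predictors[[pids[1]]])
  n_regions <- nrow(predictors[[pids[1]]][[1]]$values)
  region_labels <- fcs[[pids[1]]][[conditions[1]]]$region_labels
  tab <- array(NA_real_,
               dim = c(length(pids), length(conditions), length(measures), n_regions),
               dimnames = list(pids, conditions, measures, region_labels))
  for (p in pids) {
    for (cond in conditions) {
      F_ <- fcs[[p]][[cond]]$values
      for (m in measures) {
        tab[p, cond, m, ] <- profile_correlations(
          predictors[[p]][[m]]$values, F_, warn_constant = FALSE)
      }
    }
  }
  class(tab) <- c("coupling_table", "array")
  tab
}

#' Brain-average coupling
#'
#' Averages region-specific coupling over all regions per participant, then
#' over the requested axis: `"over_measures"` yields one value per
#' participant x condition (used for condition contrasts),
#' `"over_conditions"` one per participant x measure (used for measure
#' contrasts).
#'
#' @param table a [coupling_table()].
#' @param axis `"over_measures"` or `"over_conditions"`.
#' @return A numeric matrix (participants x conditions, or participants x
#'   measures) with attribute `axis`.
#' @export
brain_average <- function(table, axis = c("over_measures", "over_conditions")) {
  axis <- match.arg(axis)
  per_pcm <- apply(table, c(1, 2, 3), mean)   # participant x condition x measure
  out <- if (axis == "over_measures") apply(per_pcm, c(1, 2), mean)
         else apply(per_pcm, c(1, 3), mean)
  attr(out, "axis") <- axis
  out
}

#' Brain-average coupling per condition and measure
#'
#' Region-mean coupling without collapsing conditions or measures; the unit
#' of analysis for phenotype associations.
#'
#' @param table a [coupling_table()].
#' @return 3-D array participant x condition x measure.
#' @export
brain_average_by_cell <- function(table) {
  apply(table, c(1, 2, 3), mean)
}
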