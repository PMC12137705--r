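#' Repeated-measures contrast of brain-average coupling across conditions
#'
#' One-way within-participant ANOVA on a participants x conditions matrix of
#' brain-average coupling values, with Mauchly's sphericity test and a
#' Greenhouse-Geisser corrected p-value applied when sphericity is rejected
#' (Mauchly p < 0.05). Post-hoc pairwise comparisons use model-estimated
#' marginal means from a random-intercept mixed model (Tukey adjustment by
#' default, Bonferroni optionally).
#'
#' @param ba participants x conditions numeric matrix, e.g.
#'   `brain_average(table, "over_measures")`. Works identically for a
#'   participants x measures matrix.
#' @param adjust `"tukey"` or `"bonferroni"`.
#' @param pairwise compute the post-hoc pairwise contrasts (default TRUE);
#'   FALSE skips the mixed-model fit, e.g. inside simulation loops that only
#'   need the omnibus F.
#' @return List with elements `F`, `df1`, `df2`, `p` (sphericity-corrected
#'   when warranted), `p_uncorrected`, `gg_epsilon`, `mauchly_p`, and
#'   `pairwise`, a data frame of all pairwise marginal-mean contrasts.
#' @export
condition_contrast <- function(ba, adjust = c("tukey", "bonferroni"),
                               pairwise = TRUE) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(ba))
  n <- nrow(ba); k <- ncol(ba)
  if (k < 2) stop("need at least 2 conditions")
  if (n < 3) stop("need at least 3 participants for a repeated-measures contrast")
  levels_ <- colnames(ba)
  if (is.null(levels_)) levels_ <- paste0("C", seq_len(k))

  # degenerate: no within-participant variability at all
  within_var <- sum(apply(ba, 1, stats::var))
  if (within_var < .Machine$double.eps * n * k) {
    warning("no within-participant variability across conditions; F set to 0")
    pw <- data.frame(contrast = combn_labels(levels_), estimate = 0,
                     t = 0, p = 1)
    return(list(F = 0, df1 = k - 1, df2 = (n - 1) * (k - 1), p = 1,
                p_uncorrected = 1, gg_epsilon = NA_real_,
                mauchly_p = NA_real_, pairwise = pw))
  }

  fit <- stats::lm(ba ~ 1)
  idata <- data.frame(condition = factor(levels_, levels = levels_))
  av <- stats::anova(fit, idata = idata, X = ~1, M = ~condition,
                     test = "Spherical")
  row <- which(rownames(av) == "(Intercept)")[1]
  Fval <- av[row, "F"]
  df1 <- av[row, "num Df"]; df2 <- av[row, "den Df"]
  p_unc <- av[row, "Pr(>F)"]
  # Greenhouse-Geisser epsilon from the orthonormal-contrast covariance
  C <- stats::contr.helmert(k) / sqrt(2)
  C <- qr.Q(qr(C))
  E <- crossprod(C, stats::cov(ba)) %*% C
  gg_eps <- sum(diag(E))^2 / ((k - 1) * sum(E^2))
  p_gg <- if ("G-G Pr" %in% colnames(av)) av[row, "G-G Pr"] else
    stats::pf(Fval, gg_eps * df1, gg_eps * df2, lower.tail = FALSE)
  mau_p <- tryCatch(
    stats::mauchly.test(fit, idata = idata, X = ~1, M = ~condition)$p.value,
    error = function(e) NA_real_)
  use_gg <- is.finite(mau_p) && mau_p < 0.05 && k > 2
  p <- if (use_gg) p_gg else p_unc

  pw_tab <- NULL
  if (pairwise) {
    long <- data.frame(
      y = as.vector(ba),
      condition = factor(rep(levels_, each = n), levels = levels_),
      pid = factor(rep(seq_len(n), times = k)))
    mm <- suppressMessages(lme4::lmer(y ~ condition + (1 | pid), data = long))
    emm <- emmeans::emmeans(mm, "condition")
    pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = adjust))
    pw_tab <- data.frame(contrast = as.character(pw$contrast),
                         estimate = pw$estimate, t = pw$t.ratio,
                         p = pw$p.value)
  }
  list(F = Fval, df1 = df1, df2 = df2, p = p, p_uncorrected = p_unc,
       gg_epsilon = if (is.null(gg_eps)) NA_real_ else gg_eps,
       mauchly_p = mau_p, pairwise = pw_tab)
}

combn_labels <- function(levels_) {
  cc <- utils::combn(levels_, 2)
  paste(cc[1, ], "-", cc[2, ])
}

#' Best measure per region and the regional coupling pattern
#'
#' For one condition, identifies per region which measure explains the most
#' FC variance across participants (largest mean squared coupling, R^2), and
#' summarizes the winning measure's individual R^2 values as the group
#' pattern (mean) and its dispersion (SD).
#'
#' @param table a [coupling_table()].
#' @param condition condition tag present in the table.
#' @return An object of class `regional_pattern`: list with `condition`,
#'   `values` (N group-mean winning R^2), `assignment` (N winning measure
#'   tags), `dispersion` (N across-participant SDs of the winning R^2).
#' @export
best_measure_pattern <- function(table, condition) {
  stopifnot(condition %in% dimnames(table)[[2]])
  sl <- table[, condition, , , drop = FALSE]        # n x 1 x M x N
  dims <- dim(sl)
  r2 <- array(sl^2, dim = dims[c(1, 3, 4)])          # n x M x N
  measures <- dimnames(table)[[3]]
  regions <- dimnames(table)[[4]]
  mean_r2 <- apply(r2, c(2, 3), mean)                # M x N
  win <- apply(mean_r2, 2, which.max)                # ties: first (measure order)
  n_tied <- sum(apply(mean_r2, 2, function(v) sum(v == max(v)) > 1))
  if (n_tied > 0) message(sprintf("%d region(s) with tied best measure; lowest-index measure kept", n_tied))
  vals <- mean_r2[cbind(win, seq_along(win))]
  disp <- vapply(seq_along(win), function(i) stats::sd(r2[, win[i], i]), 0)
  structure(list(condition = condition,
                 values = stats::setNames(vals, regions),
                 assignment = stats::setNames(measures[win], regions),
                 dispersion = stats::setNames(disp, regions)),
            class = "regional_pattern")
}

#' Similarity of regional coupling patterns between conditions
#'
#' Pearson correlations between condition-specific group-average regional
#' R^2 vectors for all condition pairs, plus a two-sample z-test on the
#' Fisher z-transformed correlations comparing rest-task pairs against
#' task-task pairs.
#'
#' @param patterns list of [best_measure_pattern()] results, one per
#'   condition.
#' @param rest the condition tag regarded as resting state.
#' @return List with `cor_matrix` (condition x condition), `z` (test
#'   statistic; positive when task-task similarity exceeds rest-task
#'   similarity), `p` (two-sided), `mean_z_rest_task`, `mean_z_task_task`.
#' @export
pattern_similarity <- function(patterns, rest = "RES") {
  conds <- vapply(patterns, `[[`, "", "condition")
  stopifnot(length(conds) >= 3, rest %in% conds)
  V <- vapply(patterns, `[[`, patterns[[1]]$values, "values")  # N x C
  colnames(V) <- conds
  R <- stats::cor(V)
  n_regions <- nrow(V)
  iu <- which(upper.tri(R), arr.ind = TRUE)
  rvals <- R[iu]
  is_rest <- (conds[iu[, 1]] == rest) | (conds[iu[, 2]] == rest)
  degenerate <- any(abs(rvals) >= 1 - 1e-12) || !is.finite(stats::sd(rvals)) ||
    stats::sd(rvals) == 0
  if (degenerate) {
    warning("degenerate pattern similarity (identical patterns); test reported as non-significant")
    return(list(cor_matrix = R, z = 0, p = 1,
                mean_z_rest_task = NA_real_, mean_z_task_task = NA_real_))
  }
  z <- atanh(rvals)
  mz_rt <- mean(z[is_rest]); mz_tt <- mean(z[!is_rest])
  se <- sqrt((1 / (n_regions - 3)) * (1 / sum(is_rest) + 1 / sum(!is_rest)))
  zstat <- (mz_tt - mz_rt) / se
  list(cor_matrix = R, z = zstat,
       p = 2 * stats::pnorm(-abs(zstat)),
       mean_z_rest_task = mz_rt, mean_z_task_task = mz_tt)
}

#' Task-adaptation maps of regional coupling
#'
#' Quantifies how the regional coupling pattern reorganizes from its
#' intrinsic (resting) configuration: per task, the absolute regional
#' difference from rest (`task_specific_vs_rest`); the absolute difference
#' between rest and the mean over all task patterns (`task_general`); and
#' per task, the absolute difference from the mean pattern of the remaining
#' tasks (`task_specific_vs_taskgeneral`). Each per-task kind also reports
#' the task's mean adaptation as a signed percentage relative to the grand
#' mean over tasks.
#'
#' @param patterns list of [best_measure_pattern()] results including the
#'   rest condition and at least two tasks.
#' @param rest the resting-state condition tag.
#' @return Named list of `adaptation_map` objects, each with `kind`,
#'   `condition` (NA for task_general), `values` (non-negative regional
#'   vector), `summary` (mean) and `relative_pct`.
#' @export
adaptation_maps <- function(patterns, rest = "RES") {
  conds <- vapply(patterns, `[[`, "", "condition")
  stopifnot(rest %in% conds)
  tasks <- setdiff(conds, rest)
  if (length(tasks) < 2) stop("task-general adaptation needs at least 2 tasks")
  V <- vapply(patterns, `[[`, patterns[[1]]$values, "values")
  colnames(V) <- conds
  rest_v <- V[, rest]
  task_V <- V[, tasks, drop = FALSE]

  make_map <- function(kind, condition, values, rel = NA_real_) {
    structure(list(kind = kind, condition = condition, values = values,
                   summary = mean(values), relative_pct = as.numeric(rel)),
              class = "adaptation_map")
  }
  out <- list()

  ts_means <- numeric(length(tasks)); names(ts_means) <- tasks
  ts_vals <- list()
  for (t in tasks) {
    v <- abs(rest_v - task_V[, t])
    ts_vals[[t]] <- v; ts_means[t] <- mean(v)
  }
  grand <- mean(ts_means)
  for (t in tasks) {
    rel <- if (grand > 0) 100 * (ts_means[t] - grand) / grand else 0
    out[[paste0("task_specific_vs_rest.", t)]] <-
      make_map("task_specific_vs_rest", t, ts_vals[[t]], rel)
  }

  out[["task_general"]] <-
    make_map("task_general", NA_character_, abs(rest_v - rowMeans(task_V)))

  tg_means <- numeric(length(tasks)); names(tg_means) <- tasks
  tg_vals <- list()
  for (t in tasks) {
    baseline <- rowMeans(task_V[, setdiff(tasks, t), drop = FALSE])
    v <- abs(baseline - task_V[, t])
    tg_vals[[t]] <- v; tg_means[t] <- mean(v)
  }
  grand2 <- mean(tg_means)
  for (t in tasks) {
    rel <- if (grand2 > 0) 100 * (tg_means[t] - grand2) / grand2 else 0
    out[[paste0("task_specific_vs_taskgeneral.", t)]] <-
      make_map("task_specific_vs_taskgeneral", t, tg_vals[[t]], rel)
  }
  out
}
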