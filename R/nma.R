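# ---- internal machinery ----------------------------------------------------

# Flatten one condition of a coupling table to an n x (M*N) matrix whose
# column (m-1)*N + i holds region i's coupling under measure m.
flatten_condition <- function(table, condition) {
  dn <- dimnames(table)
  stopifnot(condition %in% dn[[2]])
  sl <- table[, condition, , , drop = FALSE]
  n <- dim(table)[1]; M <- dim(table)[3]; N <- dim(table)[4]
  sl <- array(sl, dim = c(n, M, N))
  flat <- aperm(sl, c(1, 3, 2))
  dim(flat) <- c(n, N * M)
  attr(flat, "N") <- N
  attr(flat, "M") <- M
  attr(flat, "measures") <- dn[[3]]
  attr(flat, "regions") <- dn[[4]]
  flat
}

# argmax / argmin per region over measures; ties broken by measure order
mask_from_rp <- function(rp, N, M) {
  rpm <- matrix(rp, N, M)
  list(positive = max.col(rpm, ties.method = "first"),
       negative = max.col(-rpm, ties.method = "first"),
       r_P = rpm)
}

feature_cols <- function(assign, N) (assign - 1L) * N + seq_len(N)

# 0/1-over-N selection matrix turning a flat coupling matrix into the two
# mask features by a single matrix product
selection_matrix <- function(positive, negative, N, M) {
  S <- matrix(0, N * M, 2)
  S[cbind(feature_cols(positive, N), 1L)] <- 1 / N
  S[cbind(feature_cols(negative, N), 2L)] <- 1 / N
  S
}

features_from_mask <- function(flat, positive, negative) {
  N <- attr(flat, "N")
  cbind(rowMeans(flat[, feature_cols(positive, N), drop = FALSE]),
        rowMeans(flat[, feature_cols(negative, N), drop = FALSE]))
}

# OLS coefficients by normal equations with a QR fallback for near-singular
# feature sets
ols_coefs <- function(A, y) {
  tryCatch(solve(crossprod(A), crossprod(A, y)),
           error = function(e) qr.solve(qr(A, LAPACK = TRUE), y))
}

fold_assignments <- function(n, K) sample(rep(seq_len(K), length.out = n))

# Pre-compute everything that does not depend on the phenotype for one fold
# split: training/test indices, an orthonormal covariate basis Q per
# condition, unit-norm residualized coupling columns (for fast partial
# correlations by a single matrix-vector product), and the train/test
# coupling submatrices used for feature extraction. Only training rows ever
# enter mask construction or coefficient fitting.
build_rep_cache <- function(inputs, folds, K) {
  nfeat <- 2L * length(inputs$flats)
  lapply(seq_len(K), function(k) {
    test <- which(folds == k)
    train <- which(folds != k)
    if (length(test) < 3 || length(train) < 3) {
      stop("cross-validation fold with fewer than 3 participants")
    }
    if (nfeat + 1L >= length(train)) {
      stop("feature count saturates the training fold; reduce conditions or folds")
    }
    per_cond <- lapply(seq_along(inputs$flats), function(ci) {
      flat <- inputs$flats[[ci]]
      Q <- qr.Q(qr(cbind(1, inputs$Zs[[ci]][train, , drop = FALSE])))
      Ftr <- flat[train, , drop = FALSE]
      Yres <- Ftr - Q %*% crossprod(Q, Ftr)
      cn <- sqrt(colSums(Yres^2))
      ok <- cn > 1e-10 * sqrt(length(train))
      Ystd <- Yres
      Ystd[, ok] <- sweep(Yres[, ok, drop = FALSE], 2, cn[ok], "/")
      Ystd[, !ok] <- 0
      Fte <- flat[test, , drop = FALSE]
      list(Q = Q, Ystd = Ystd, ok = ok, Ftr = Ftr, Fte = Fte,
           N = attr(flat, "N"), M = attr(flat, "M"))
    })
    list(train = train, test = test, per_cond = per_cond)
  })
}

# One CV repetition for phenotype vector `g` on a pre-built fold cache.
cv_rep_cached <- function(g, cache) {
  n <- length(g)
  pred <- rep(NA_real_, n)
  for (fold in cache) {
    gtr <- g[fold$train]
    Xtr <- matrix(0, length(fold$train), 0)
    Xte <- matrix(0, length(fold$test), 0)
    for (pc in fold$per_cond) {
      gr <- gtr - as.vector(pc$Q %*% crossprod(pc$Q, gtr))
      gn <- sqrt(sum(gr^2))
      rp <- if (gn > 0) as.vector(crossprod(pc$Ystd, gr)) / gn else
        numeric(ncol(pc$Ystd))
      mk <- mask_from_rp(rp, pc$N, pc$M)
      S <- selection_matrix(mk$positive, mk$negative, pc$N, pc$M)
      Xtr <- cbind(Xtr, pc$Ftr %*% S)
      Xte <- cbind(Xte, pc$Fte %*% S)
    }
    coefs <- ols_coefs(cbind(1, Xtr), gtr)
    pred[fold$test] <- as.vector(cbind(1, Xte) %*% coefs)
  }
  if (stats::sd(pred) == 0 || stats::sd(g) == 0) return(0)
  stats::cor(pred, g)
}

# Many phenotype vectors (columns of G) through the same fold caches at
# once: per fold and condition, the partial correlations for all phenotype
# columns collapse to one matrix product, and all masks' feature
# extractions to another (stacked 2-column selection matrices).
# Returns the vector of mean prediction r across caches.
run_cached_multi <- function(G, caches) {
  n <- nrow(G); P <- ncol(G)
  rsum <- numeric(P)
  for (cache in caches) {
    pred <- matrix(NA_real_, n, P)
    for (fold in cache) {
      Gtr <- G[fold$train, , drop = FALSE]
      ntr <- nrow(Gtr)
      C <- length(fold$per_cond)
      Xtr_all <- vector("list", C)
      Xte_all <- vector("list", C)
      for (ci in seq_len(C)) {
        pc <- fold$per_cond[[ci]]
        GR <- Gtr - pc$Q %*% crossprod(pc$Q, Gtr)
        gn <- sqrt(.colSums(GR^2, ntr, P))
        RP <- crossprod(pc$Ystd, GR)
        RP <- RP / rep(pmax(gn, 1e-300), each = nrow(RP))
        N <- pc$N; M <- pc$M
        byM <- matrix(aperm(array(RP, c(N, M, P)), c(1, 3, 2)), N * P, M)
        pos <- max.col(byM, ties.method = "first")
        neg <- max.col(-byM, ties.method = "first")
        i_idx <- rep.int(seq_len(N), P)
        p_idx <- rep(seq_len(P), each = N)
        Sall <- matrix(0, N * M, 2L * P)
        Sall[cbind((pos - 1L) * N + i_idx, 2L * p_idx - 1L)] <- 1 / N
        Sall[cbind((neg - 1L) * N + i_idx, 2L * p_idx)] <- 1 / N
        Xtr_all[[ci]] <- pc$Ftr %*% Sall
        Xte_all[[ci]] <- pc$Fte %*% Sall
      }
      if (C == 1L) {
        # two-feature model: solve all P normal systems in closed form
        u <- Xtr_all[[1]][, seq(1L, 2L * P, 2L), drop = FALSE]
        v <- Xtr_all[[1]][, seq(2L, 2L * P, 2L), drop = FALSE]
        ue <- Xte_all[[1]][, seq(1L, 2L * P, 2L), drop = FALSE]
        ve <- Xte_all[[1]][, seq(2L, 2L * P, 2L), drop = FALSE]
        su <- .colSums(u, ntr, P); sv <- .colSums(v, ntr, P)
        suu <- .colSums(u * u, ntr, P); svv <- .colSums(v * v, ntr, P)
        suv <- .colSums(u * v, ntr, P)
        sg <- .colSums(Gtr, ntr, P)
        sug <- .colSums(u * Gtr, ntr, P); svg <- .colSums(v * Gtr, ntr, P)
        # inverse of the symmetric 3x3 normal matrix [[n,su,sv],...] by cofactors
        A11 <- suu * svv - suv^2
        A12 <- sv * suv - su * svv
        A13 <- su * suv - sv * suu
        A22 <- ntr * svv - sv^2
        A23 <- su * sv - ntr * suv
        A33 <- ntr * suu - su^2
        det <- ntr * A11 + su * A12 + sv * A13
        bad <- !is.finite(det) | abs(det) < 1e-10 * ntr
        b0 <- (A11 * sg + A12 * sug + A13 * svg) / det
        b1 <- (A12 * sg + A22 * sug + A23 * svg) / det
        b2 <- (A13 * sg + A23 * sug + A33 * svg) / det
        for (p in which(bad)) {
          cf <- ols_coefs(cbind(1, u[, p], v[, p]), Gtr[, p])
          b0[p] <- cf[1]; b1[p] <- cf[2]; b2[p] <- cf[3]
        }
        pred[fold$test, ] <- rep(b0, each = length(fold$test)) +
          ue * rep(b1, each = length(fold$test)) +
          ve * rep(b2, each = length(fold$test))
      } else {
        for (p in seq_len(P)) {
          cols <- c(2L * p - 1L, 2L * p)
          Xtr <- do.call(cbind, lapply(Xtr_all, function(x) x[, cols]))
          Xte <- do.call(cbind, lapply(Xte_all, function(x) x[, cols]))
          coefs <- ols_coefs(cbind(1, Xtr), Gtr[, p])
          pred[fold$test, p] <- as.vector(cbind(1, Xte) %*% coefs)
        }
      }
    }
    pc_ <- pred - rep(colMeans(pred), each = n)
    gc_ <- G - rep(colMeans(G), each = n)
    den <- sqrt(.colSums(pc_^2, n, P) * .colSums(gc_^2, n, P))
    r <- .colSums(pc_ * gc_, n, P)
    r <- ifelse(den > 0, r / den, 0)
    rsum <- rsum + r
  }
  rsum / length(caches)
}

cv_single_rep <- function(g, flats, Zs, folds, K) {
  cache <- build_rep_cache(list(flats = flats, Zs = Zs), folds, K)
  cv_rep_cached(g, cache)
}

# assemble flats and covariate matrices for a model specification
model_inputs <- function(table, participants, model, condition = NULL,
                         rest = "RES") {
  conds_all <- dimnames(table)[[2]]
  conds <- if (model == "bnma") {
    stopifnot(!is.null(condition), condition %in% conds_all)
    condition
  } else {
    setdiff(conds_all, rest)
  }
  if (model == "enma" && length(conds) < 1) stop("E-NMA needs at least one task condition")
  flats <- lapply(conds, function(cc) flatten_condition(table, cc))
  Zs <- lapply(conds, function(cc) condition_covariates(participants, cc))
  list(conditions = conds, flats = flats, Zs = Zs)
}

run_repetitions <- function(g, inputs, cfg, n_reps, seed) {
  K <- cfg$n_folds
  n <- length(g)
  fold_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  vapply(seq_len(n_reps), function(r) {
    folds <- withr::with_seed(fold_seeds[r], fold_assignments(n, K))
    cv_single_rep(g, inputs$flats, inputs$Zs, folds, K)
  }, 0)
}

# caches for a fixed set of repetitions, reusable across many phenotype
# vectors (permutation tests)
build_run_caches <- function(inputs, n, cfg, n_reps, seed) {
  K <- cfg$n_folds
  fold_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  lapply(seq_len(n_reps), function(r) {
    folds <- withr::with_seed(fold_seeds[r], fold_assignments(n, K))
    build_rep_cache(inputs, folds, K)
  })
}

run_cached <- function(g, caches) {
  mean(vapply(caches, function(cache) cv_rep_cached(g, cache), 0))
}

# ---- public API ------------------------------------------------------------

#' Build a node-measure assignment (NMA) mask
#'
#' For one condition, correlates each region x measure coupling value with
#' the phenotype across the (training) participants, controlling for age,
#' gender, handedness and condition-specific motion. This yields one partial
#' correlation r_P per region and measure. The positive mask assigns each
#' region the measure with the largest r_P, the negative mask the measure
#' with the smallest (most negative) r_P; ties are broken by measure order.
#' Regions whose largest r_P is still negative (or smallest still positive)
#' are flagged in the `forced_positive` / `forced_negative` fields.
#'
#' @param table a [coupling_table()].
#' @param participants aligned participant data frame (see
#'   [brain_average_association()]).
#' @param condition condition tag.
#' @param train optional integer vector of training-row indices; the mask is
#'   built from these participants only (default: all rows).
#' @return Object of class `nma_mask`: `condition`, `positive` and
#'   `negative` (integer measure indices per region), `r_P` (N x M matrix),
#'   `measures`, flag vectors.
#' @export
build_nma_mask <- function(table, participants, condition, train = NULL) {
  flat <- flatten_condition(table, condition)
  Z <- condition_covariates(participants, condition)
  if (is.null(train)) train <- seq_len(nrow(flat))
  N <- attr(flat, "N"); M <- attr(flat, "M")
  Q <- qr.Q(qr(cbind(1, Z[train, , drop = FALSE])))
  Ytr <- flat[train, , drop = FALSE]
  Yres <- Ytr - Q %*% crossprod(Q, Ytr)
  cn <- sqrt(colSums(Yres^2))
  g <- participants$g[train]
  gr <- g - as.vector(Q %*% crossprod(Q, g))
  gn <- sqrt(sum(gr^2))
  rp <- numeric(ncol(flat))
  ok <- cn > 1e-10 * sqrt(length(train))
  if (any(!ok)) message(sprintf("%d degenerate coupling column(s); r_P set to 0", sum(!ok)))
  if (gn > 0 && any(ok)) {
    rp[ok] <- as.vector(crossprod(Yres[, ok, drop = FALSE], gr)) / (cn[ok] * gn)
  }
  mk <- mask_from_rp(rp, N, M)
  rownames(mk$r_P) <- attr(flat, "regions")
  colnames(mk$r_P) <- attr(flat, "measures")
  structure(list(condition = condition,
                 positive = mk$positive, negative = mk$negative,
                 r_P = mk$r_P, measures = attr(flat, "measures"),
                 forced_positive = mk$r_P[cbind(seq_len(N), mk$positive)] < 0,
                 forced_negative = mk$r_P[cbind(seq_len(N), mk$negative)] > 0),
            class = "nma_mask")
}

#' Extract NMA model features for each participant
#'
#' X1 is a participant's mean coupling over regions, taking for each region
#' the measure assigned by the positive mask; X2 analogously for the
#' negative mask. When applied to held-out participants, the mask must have
#' been built on disjoint training data.
#'
#' @param mask an [build_nma_mask()] result.
#' @param table a [coupling_table()].
#' @param rows optional participant row indices (default all).
#' @return Data frame with columns `X1`, `X2`.
#' @export
extract_features <- function(mask, table, rows = NULL) {
  flat <- flatten_condition(table, mask$condition)
  if (!is.null(rows)) flat_sub <- flat[rows, , drop = FALSE] else flat_sub <- flat
  attr(flat_sub, "N") <- attr(flat, "N")
  X <- features_from_mask(flat_sub, mask$positive, mask$negative)
  data.frame(X1 = X[, 1], X2 = X[, 2])
}

#' Basic NMA prediction of the phenotype from one condition
#'
#' Predicts the phenotype g from region-specific coupling of a single fMRI
#' condition via the two-feature regression y = b0 + b1 X1 + b2 X2 + e under
#' repeated k-fold cross-validation: per fold, NMA masks and regression
#' coefficients are fitted on the training folds only, then applied to the
#' test fold. Fold-concatenated predictions yield one Pearson r per
#' repetition; performance is the mean over repetitions.
#'
#' @param table a [coupling_table()].
#' @param participants aligned participant data frame with phenotype `g` and
#'   covariates.
#' @param condition condition tag.
#' @param cfg an [analysis_config()]; uses `n_folds`, `n_repetitions`,
#'   `rng_seed`.
#' @return Object of class `prediction_result` with `model`, `condition`,
#'   `r` (mean over repetitions), `R2` (square of the mean r),
#'   `R2_mean_rep` (mean per-repetition r^2), `per_repetition_r`, `p`
#'   (NA until [permutation_test()]), `seed`.
#' @export
fit_predict_bnma <- function(table, participants, condition,
                             cfg = analysis_config()) {
  inputs <- model_inputs(table, participants, "bnma", condition)
  rs <- run_repetitions(participants$g, inputs, cfg, cfg$n_repetitions,
                        cfg$rng_seed)
  new_prediction_result("bnma", condition, rs, cfg)
}

#' Expanded NMA prediction from all task conditions jointly
#'
#' Builds the two NMA features per task condition (resting state excluded)
#' and fits one regression on all 2 x n_tasks features simultaneously,
#' otherwise following the same cross-validation protocol as
#' [fit_predict_bnma()].
#'
#' @inheritParams fit_predict_bnma
#' @param rest the condition tag excluded as resting state.
#' @return A `prediction_result` with `model = "enma"`.
#' @export
fit_predict_enma <- function(table, participants, cfg = analysis_config(),
                             rest = "RES") {
  inputs <- model_inputs(table, participants, "enma", rest = rest)
  rs <- run_repetitions(participants$g, inputs, cfg, cfg$n_repetitions,
                        cfg$rng_seed)
  res <- new_prediction_result("enma", NA_character_, rs, cfg)
  res$conditions <- inputs$conditions
  res
}

new_prediction_result <- function(model, condition, rs, cfg) {
  r <- mean(rs)
  structure(list(model = model, condition = condition,
                 r = r, R2 = r^2, R2_mean_rep = mean(rs^2),
                 per_repetition_r = rs, p = NA_real_,
                 seed = cfg$rng_seed, n_folds = cfg$n_folds,
                 n_repetitions = length(rs)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  lab <- if (x$model == "bnma") sprintf("B-NMA (%s)", x$condition) else "E-NMA"
  cat(sprintf("%s: r = %.3f, R2 = %.3f (%d reps%s)\n", lab, x$r, x$R2,
              x$n_repetitions,
              if (is.na(x$p)) "" else sprintf(", permutation p = %.4g", x$p)))
  invisible(x)
}

#' Permutation test of prediction performance
#'
#' Re-runs the full cross-validated NMA pipeline with phenotype scores
#' permuted across participants (covariates stay attached to the imaging
#' data), yielding a null distribution of mean prediction r. The p-value
#' uses add-one smoothing: p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#' Permutation runs use `cfg$n_perm_repetitions` CV repetitions.
#'
#' @param result a `prediction_result` from [fit_predict_bnma()] or
#'   [fit_predict_enma()].
#' @param table,participants the data the result was fitted on.
#' @param cfg an [analysis_config()]; uses `n_permutations`,
#'   `n_perm_repetitions`, `rng_seed`.
#' @param rest resting-state tag (E-NMA only).
#' @return List with `p`, `r_obs`, `r_perm` (length `n_permutations`).
#' @export
permutation_test <- function(result, table, participants,
                             cfg = analysis_config(), rest = "RES") {
  inputs <- model_inputs(table, participants, result$model, result$condition,
                         rest = rest)
  g <- participants$g
  n <- length(g)
  seeds <- withr::with_seed(cfg$rng_seed + 1L, list(
    perms = replicate(cfg$n_permutations, sample.int(n), simplify = FALSE),
    rep_seed = sample.int(.Machine$integer.max, 1)))
  caches <- build_run_caches(inputs, n, cfg, cfg$n_perm_repetitions,
                             seeds$rep_seed)
  G <- vapply(seeds$perms, function(ix) g[ix], g)
  r_perm <- run_cached_multi(G, caches)
  p <- (1 + sum(r_perm >= result$r)) / (1 + length(r_perm))
  list(p = p, r_obs = result$r, r_perm = r_perm)
}

#' Permutation test of the performance difference between two models
#'
#' Compares |r_A - r_B| observed against the distribution of |Delta r| when
#' both models are trained on the same permuted phenotype scores.
#'
#' @param resA,resB `prediction_result` objects fitted on the same cohort.
#' @param table,participants the shared data.
#' @param cfg an [analysis_config()].
#' @param rest resting-state tag.
#' @return List with `p`, `delta_obs`, `delta_perm`.
#' @export
model_difference_test <- function(resA, resB, table, participants,
                                  cfg = analysis_config(), rest = "RES") {
  if (resA$n_folds != resB$n_folds) stop("models use different fold schemes")
  inA <- model_inputs(table, participants, resA$model, resA$condition, rest)
  inB <- model_inputs(table, participants, resB$model, resB$condition, rest)
  g <- participants$g
  n <- length(g)
  delta_obs <- abs(resA$r - resB$r)
  seeds <- withr::with_seed(cfg$rng_seed + 2L, list(
    perms = replicate(cfg$n_permutations, sample.int(n), simplify = FALSE),
    rep_seed = sample.int(.Machine$integer.max, 1)))
  cachesA <- build_run_caches(inA, n, cfg, cfg$n_perm_repetitions, seeds$rep_seed)
  cachesB <- build_run_caches(inB, n, cfg, cfg$n_perm_repetitions, seeds$rep_seed)
  G <- vapply(seeds$perms, function(ix) g[ix], g)
  delta_perm <- abs(run_cached_multi(G, cachesA) - run_cached_multi(G, cachesB))
  p <- (1 + sum(delta_perm >= delta_obs)) / (1 + length(delta_perm))
  list(p = p, delta_obs = delta_obs, delta_perm = delta_perm)
}

#' Cross-sample model generalization
#'
#' Trains NMA models on 4/5 of the main sample (five models per repetition,
#' over `n_repetitions` random splits), freezes each model's masks and
#' regression coefficients, and applies them unchanged to a replication
#' cohort. Performance is the mean Pearson r between frozen-model
#' predictions and observed phenotype over all 5 x n_repetitions models.
#' Significance is assessed by permuting the replication phenotype against
#' the frozen predictions.
#'
#' @param table,participants main-sample coupling table and participant
#'   table.
#' @param repl_table,repl_participants replication-sample data with the same
#'   measures and (for B-NMA) the required condition.
#' @param model `"bnma"` or `"enma"`.
#' @param condition condition tag (B-NMA only).
#' @param cfg an [analysis_config()].
#' @param rest resting-state tag.
#' @return List with `r` (mean over models), `per_model_r`, `p`.
#' @export
cross_sample_generalize <- function(table, participants, repl_table,
                                    repl_participants, model = "bnma",
                                    condition = NULL, cfg = analysis_config(),
                                    rest = "RES") {
  repl_conds <- dimnames(repl_table)[[2]]
  needed <- if (model == "bnma") condition else setdiff(dimnames(table)[[2]], rest)
  absent <- setdiff(needed, repl_conds)
  if (length(absent)) {
    warning(sprintf("condition(s) %s absent in replication cohort; model skipped",
                    paste(absent, collapse = ", ")))
    return(NULL)
  }
  inputs <- model_inputs(table, participants, model, condition, rest)
  repl_flats <- lapply(inputs$conditions, function(cc) flatten_condition(repl_table, cc))
  g <- participants$g
  g_repl <- repl_participants$g
  n <- length(g); K <- cfg$n_folds
  fold_seeds <- withr::with_seed(cfg$rng_seed, sample.int(.Machine$integer.max,
                                                          cfg$n_repetitions))
  preds <- list(); per_model_r <- numeric(0)
  for (r in seq_len(cfg$n_repetitions)) {
    folds <- withr::with_seed(fold_seeds[r], fold_assignments(n, K))
    for (k in seq_len(K)) {
      train <- which(folds != k)
      Xtr <- matrix(0, length(train), 0)
      Xre <- matrix(0, length(g_repl), 0)
      gtr <- g[train]
      for (ci in seq_along(inputs$flats)) {
        flat <- inputs$flats[[ci]]
        N <- attr(flat, "N"); M <- attr(flat, "M")
        Q <- qr.Q(qr(cbind(1, inputs$Zs[[ci]][train, , drop = FALSE])))
        Ytr <- flat[train, , drop = FALSE]
        Yres <- Ytr - Q %*% crossprod(Q, Ytr)
        cn <- sqrt(colSums(Yres^2))
        gr <- gtr - as.vector(Q %*% crossprod(Q, gtr))
        gn <- sqrt(sum(gr^2))
        rp <- numeric(ncol(flat))
        ok <- cn > 1e-10 * sqrt(length(train))
        if (gn > 0 && any(ok)) {
          rp[ok] <- as.vector(crossprod(Yres[, ok, drop = FALSE], gr)) / (cn[ok] * gn)
        }
        mk <- mask_from_rp(rp, N, M)
        S <- selection_matrix(mk$positive, mk$negative, N, M)
        Xtr <- cbind(Xtr, flat[train, , drop = FALSE] %*% S)
        Xre <- cbind(Xre, repl_flats[[ci]] %*% S)
      }
      coefs <- qr.solve(qr(cbind(1, Xtr), LAPACK = TRUE), gtr)
      pr <- as.vector(cbind(1, Xre) %*% coefs)
      preds[[length(preds) + 1L]] <- pr
      per_model_r <- c(per_model_r,
                       if (stats::sd(pr) == 0) 0 else stats::cor(pr, g_repl))
    }
  }
  r_mean <- mean(per_model_r)
  # permutation of the replication phenotype against frozen predictions
  P <- do.call(cbind, preds)
  Ps <- scale(P)
  Ps[, apply(P, 2, stats::sd) == 0] <- 0
  nr <- length(g_repl)
  r_perm <- withr::with_seed(cfg$rng_seed + 3L, vapply(seq_len(cfg$n_permutations),
    function(i) {
      gp <- g_repl[sample.int(nr)]
      gs <- (gp - mean(gp)) / stats::sd(gp)
      mean(crossprod(Ps, gs) / (nr - 1))
    }, 0))
  p <- (1 + sum(r_perm >= r_mean)) / (1 + length(r_perm))
  list(r = r_mean, per_model_r = per_model_r, p = p, r_perm = r_perm)
}
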