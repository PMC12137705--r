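#' Synthetic cohort generator configuration
#'
#' Defines the statistical structure of a simulated connectome cohort:
#' distance-dependent sparse structural networks with heavy-tailed
#' (log-normal) weights shared around a group template; condition-specific
#' functional networks built as noisy mixtures of region-preferred
#' similarity/communication-matrix columns with a regional coupling
#' gradient, global condition offsets (rest highest by default), a
#' rest-specific pattern component, and planted region-by-measure phenotype
#' associations; and a standardized phenotype g with weak covariate
#' confounds.
#'
#' Group-level structure (node geometry, template network, regional
#' gradient, measure preferences, rest pattern) is derived from `seed`;
#' participant-level draws use the `cohort_seed` passed to the generator
#' functions, so independent cohorts with identical group structure (e.g. a
#' replication sample) are obtained by changing only the cohort seed.
#'
#' @param n_participants cohort size.
#' @param n_regions number of brain regions N (default 60; use 358 for a
#'   full-cortex multimodal parcellation).
#' @param n_task_conditions number of task conditions besides rest
#'   (default 7, named after the standard fMRI battery when 7).
#' @param density edge density of the structural template in (0, 1].
#' @param signal_regions data frame with columns `region` (index),
#'   `measure` (tag), `sign` (+1/-1) and `effect_r` in (-1, 1): regions
#'   whose coupling under the planted measure carries a phenotype
#'   association of that strength. An optional `condition` column restricts
#'   a row's effect to one condition (NA = all conditions). Empty by
#'   default (global null).
#' @param condition_offsets named numeric vector of global coupling offsets
#'   per condition (target correlation scale). Default: rest +0.05, first
#'   task -0.05, others 0.
#' @param rest_divergence scale of the rest-specific regional pattern
#'   component separating rest from the shared task pattern (default 0.3).
#' @param noise_sd FC noise standard deviation relative to a unit-noise
#'   reference (default 1; larger values lower and blur coupling).
#' @param signal_strength amplitude of the phenotype-linked FC component in
#'   signal regions (default 0.6).
#' @param pref_mix weight of the measure-unique (orthogonalized) component
#'   in each region's preferred mixing direction (default 0.5); larger
#'   values widen the gap between the preferred measure's coupling and the
#'   other measures'.
#' @param base_coupling_range range of the target regional coupling gradient
#'   (default 0.5 to 0.85, mimicking low coupling in multimodal and high
#'   coupling in unimodal areas).
#' @param sc_perturb_sd log-normal sd of per-participant multiplicative SC
#'   weight perturbation (default 0.2).
#' @param participant_sd sd of a stable participant-level offset on the
#'   target coupling level, shared across regions and conditions (default
#'   0.02); the main source of between-participant brain-average coupling
#'   variance.
#' @param confound_strengths list of correlations between g and the
#'   covariates age, gender, handedness, motion.
#' @param region_preferences optional integer vector (1..4) fixing each
#'   region's preferred measure; default drawn from the structure seed.
#' @param seed structure seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_participants = 200L, n_regions = 60L,
                             n_task_conditions = 7L, density = 0.25,
                             signal_regions = NULL,
                             condition_offsets = NULL,
                             rest_divergence = 0.3, noise_sd = 1,
                             signal_strength = 0.6, pref_mix = 0.5,
                             base_coupling_range = c(0.5, 0.85),
                             sc_perturb_sd = 0.2, participant_sd = 0.02,
                             confound_strengths = list(age = 0.1, gender = 0.05,
                                                       handedness = 0,
                                                       motion = -0.15),
                             region_preferences = NULL,
                             seed = 1L) {
  stopifnot(density > 0, density <= 1, n_regions >= 5, n_task_conditions >= 1)
  conditions <- if (n_task_conditions == 7) {
    c("RES", "EMO", "GAM", "LAN", "MOT", "REL", "SOC", "WM")
  } else {
    c("RES", paste0("T", seq_len(n_task_conditions)))
  }
  if (is.null(condition_offsets)) {
    condition_offsets <- stats::setNames(rep(0, length(conditions)), conditions)
    condition_offsets["RES"] <- 0.05
    condition_offsets[conditions[2]] <- -0.05
  }
  if (is.null(signal_regions)) {
    signal_regions <- data.frame(region = integer(0), measure = character(0),
                                 sign = numeric(0), effect_r = numeric(0))
  }
  if (is.null(signal_regions$condition)) {
    signal_regions$condition <- rep(NA_character_, nrow(signal_regions))
  }
  stopifnot(all(abs(signal_regions$effect_r) < 1))
  if (sum(signal_regions$effect_r^2) > 1) {
    stop("planted effect_r values exceed unit phenotype variance")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_regions = as.integer(n_regions),
    n_task_conditions = as.integer(n_task_conditions),
    conditions = conditions, density = density,
    signal_regions = signal_regions, condition_offsets = condition_offsets,
    rest_divergence = rest_divergence, noise_sd = noise_sd,
    signal_strength = signal_strength, pref_mix = pref_mix,
    base_coupling_range = base_coupling_range, sc_perturb_sd = sc_perturb_sd,
    participant_sd = participant_sd,
    confound_strengths = confound_strengths,
    region_preferences = region_preferences, seed = as.integer(seed)
  ), class = "generator_config")
}

# Group-level structure shared by all cohorts drawn from one config:
# node coordinates, template adjacency + weights (distance-dependent,
# log-normal, connected via the Euclidean MST), regional coupling gradient,
# rest-pattern component, and region-preferred measures.
cohort_structure <- function(cfg) {
  withr::with_seed(cfg$seed, {
    N <- cfg$n_regions
    coords <- matrix(stats::runif(N * 3), N, 3)
    D <- as.matrix(stats::dist(coords))
    score <- exp(-D / 0.3)
    diag(score) <- 0
    p <- cfg$density * score / mean(score[upper.tri(score)])
    p <- pmin(p, 1)
    adj <- matrix(FALSE, N, N)
    up <- upper.tri(adj)
    adj[up] <- stats::runif(sum(up)) < p[up]
    adj <- adj | t(adj)
    # guarantee connectedness with the Euclidean minimum spanning tree
    gfull <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                 weighted = TRUE, diag = FALSE)
    mst <- igraph::as_adjacency_matrix(igraph::mst(gfull), sparse = FALSE) > 0
    repaired <- sum(mst & !adj) / 2
    if (repaired > 0 && cfg$density < 2 / N) {
      warning(sprintf("density too low for connectedness; %d spanning edge(s) added",
                      repaired))
    }
    adj <- adj | mst
    W <- matrix(0, N, N)
    ne <- sum(adj[up])
    wts <- stats::rlnorm(ne, meanlog = 0, sdlog = 1) * exp(-D[up & adj][seq_len(ne)])
    W[up & adj] <- wts
    W <- W + t(W)
    grad <- seq(cfg$base_coupling_range[1], cfg$base_coupling_range[2],
                length.out = N)[rank(coords[, 1], ties.method = "first")]
    rest_pattern <- stats::rnorm(N, 0, 0.1)
    prefs <- if (!is.null(cfg$region_preferences)) cfg$region_preferences else
      sample.int(4, N, replace = TRUE)
    list(coords = coords, template = W, grad = grad,
         rest_pattern = rest_pattern, prefs = prefs)
  })
}

#' Generate per-participant structural connectomes
#'
#' Each participant's SC is the group template with independent
#' multiplicative log-normal weight perturbations on every edge, preserving
#' topology (hence connectedness).
#'
#' @param cfg a [generator_config()].
#' @param cohort_seed participant-level seed.
#' @param n number of participants (default `cfg$n_participants`).
#' @return List of [structural_connectome()] objects named `S1..Sn`.
#' @export
generate_sc <- function(cfg, cohort_seed = 1L, n = cfg$n_participants) {
  st <- cohort_structure(cfg)
  N <- cfg$n_regions
  up <- upper.tri(st$template)
  edge_idx <- which(up & st$template > 0)
  withr::with_seed(cohort_seed, {
    out <- lapply(seq_len(n), function(s) {
      W <- st$template
      W[edge_idx] <- W[edge_idx] * exp(stats::rnorm(length(edge_idx), 0,
                                                    cfg$sc_perturb_sd))
      W[lower.tri(W)] <- 0
      W <- W + t(W)
      structural_connectome(W, participant_id = sprintf("S%d", s))
    })
    names(out) <- vapply(out, `[[`, "", "participant_id")
    out
  })
}

# Per-participant FC mixing basis: for each region, the standardized
# predictor columns, the preferred mixing direction (preferred column
# blended with its measure-unique orthogonal component), and the
# orthogonalized signal directions for planted regions.
fc_basis_one <- function(predictors, st, cfg) {
  N <- cfg$n_regions
  mu <- cfg$pref_mix
  Pmats <- lapply(predictors, `[[`, "values")
  H <- matrix(0, N, N)
  sig <- cfg$signal_regions
  Wsig <- if (nrow(sig)) matrix(0, N, nrow(sig)) else NULL
  measures <- names(predictors)
  for (i in seq_len(N)) {
    U <- vapply(Pmats, function(P) {
      v <- P[-i, i]
      s <- stats::sd(v)
      if (s == 0) rep(0, N - 1) else (v - mean(v)) / s
    }, numeric(N - 1))
    orth_unique <- function(m) {
      others <- U[, -m, drop = FALSE]
      qo <- qr.Q(qr(others))
      w <- U[, m] - qo %*% crossprod(qo, U[, m])
      nw <- sqrt(sum(w^2))
      if (nw < 1e-10) rep(0, N - 1) else w / nw * sqrt(N - 2)  # unit sd scale
    }
    pm <- st$prefs[i]
    w_pref <- orth_unique(pm)
    h <- (1 - mu) * U[, pm] + mu * w_pref
    h <- h / stats::sd(h)
    H[-i, i] <- h
    if (nrow(sig)) {
      for (j in which(sig$region == i)) {
        ms <- match(sig$measure[j], measures)
        Wsig[-i, j] <- orth_unique(ms)
      }
    }
  }
  list(H = H, Wsig = Wsig)
}

#' Generate condition-specific functional connectomes
#'
#' For each participant, condition and region, the FC column is a noisy
#' mixture: the region's preferred mixing direction scaled to a target
#' coupling level (regional gradient + global condition offset + a
#' rest-specific component), plus, in planted signal regions, a
#' measure-unique orthogonal component whose weight carries the
#' participant's latent deviation, plus Gaussian noise. Columns are
#' assembled into a matrix, symmetrized by averaging, and scaled to a
#' Fisher-z-like magnitude.
#'
#' @param cfg a [generator_config()].
#' @param predictors nested list participant -> measure ->
#'   [predictor_matrix()], from [all_predictors()].
#' @param deviations n x k matrix of latent signal-region deviations (one
#'   column per row of `cfg$signal_regions`); NULL for none.
#' @param cohort_seed participant-level seed (offset internally from the SC
#'   draw so SC and FC noise are independent).
#' @param basis optional precomputed list of per-participant bases from a
#'   previous call (attribute `basis` of the result), reused to avoid
#'   recomputing orthogonalizations.
#' @param conditions conditions to generate (default: all in `cfg`).
#' @return Nested list `fc[[pid]][[condition]]` of
#'   [functional_connectome()] objects, with the basis attached as attribute
#'   `basis`.
#' @export
generate_fc <- function(cfg, predictors, deviations = NULL, cohort_seed = 1L,
                        basis = NULL, conditions = cfg$conditions) {
  st <- cohort_structure(cfg)
  N <- cfg$n_regions
  pids <- names(predictors)
  sig <- cfg$signal_regions
  sig_key <- paste(sig$region, sig$measure, collapse = ";")
  basis_ok <- !is.null(basis) && length(basis) == length(pids) &&
    identical(attr(basis, "sig_key"), sig_key)
  if (!basis_ok) {
    basis <- lapply(predictors, fc_basis_one, st = st, cfg = cfg)
    attr(basis, "sig_key") <- sig_key
  }
  fc <- withr::with_seed(cohort_seed + 1000003L, {
    lapply(seq_along(pids), function(s) {
      b <- basis[[s]]
      p_offset <- stats::rnorm(1, 0, cfg$participant_sd)
      per_cond <- lapply(conditions, function(cond) {
        r_target <- st$grad + cfg$condition_offsets[[cond]] + p_offset
        if (cond == "RES") {
          r_target <- r_target + cfg$rest_divergence * st$rest_pattern
        }
        r_target <- pmin(pmax(r_target, 0.05), 0.9)
        A <- r_target / sqrt(1 - r_target^2)
        M <- sweep(b$H, 2, A, "*") +
          cfg$noise_sd * matrix(stats::rnorm(N * N), N, N)
        if (nrow(sig) && !is.null(deviations)) {
          for (j in seq_len(nrow(sig))) {
            if (!is.na(sig$condition[j]) && sig$condition[j] != cond) next
            i <- sig$region[j]
            M[, i] <- M[, i] + b$Wsig[, j] *
              (cfg$signal_strength * deviations[s, j])
          }
        }
        diag(M) <- 0
        M <- (M + t(M)) / 2
        M <- 0.3 * M / stats::sd(M)
        # symmetric and zero-diagonal by construction: build directly
        labels <- paste0("R", seq_len(N))
        dimnames(M) <- list(labels, labels)
        structure(list(participant_id = pids[s], condition = cond,
                       values = M, region_labels = labels),
                  class = "functional_connectome")
      })
      names(per_cond) <- conditions
      per_cond
    })
  })
  names(fc) <- pids
  attr(fc, "basis") <- basis
  fc
}

#' Generate the phenotype and covariate table
#'
#' The phenotype g is a weighted sum of the latent signal-region deviations
#' (weights = signed planted effect sizes) plus an independent standard
#' normal residual scaled so g has unit variance, then standardized.
#' Covariates (age, gender, handedness, condition-specific motion) are drawn
#' with the configured weak correlations to g.
#'
#' @param cfg a [generator_config()].
#' @param deviations n x k latent deviation matrix (see [generate_fc()]).
#' @param cohort_seed participant-level seed.
#' @param n cohort size.
#' @return Data frame with columns `participant_id`, `g`, `age`, `gender`,
#'   `handedness` and `motion_<condition>`.
#' @export
generate_phenotype <- function(cfg, deviations = NULL, cohort_seed = 1L,
                               n = cfg$n_participants) {
  sig <- cfg$signal_regions
  withr::with_seed(cohort_seed + 2000003L, {
    if (nrow(sig) && !is.null(deviations)) {
      ess <- sum(sig$effect_r^2)
      g0 <- as.vector(deviations %*% (sig$sign * sig$effect_r)) +
        sqrt(1 - ess) * stats::rnorm(n)
    } else {
      g0 <- stats::rnorm(n)
    }
    g <- as.vector(scale(g0))
    cs <- cfg$confound_strengths
    mix <- function(rho) rho * g + sqrt(1 - rho^2) * stats::rnorm(n)
    out <- data.frame(
      participant_id = sprintf("S%d", seq_len(n)),
      g = g,
      age = 29 + 3.5 * mix(cs$age),
      gender = as.integer(mix(cs$gender) > 0),
      handedness = pmin(pmax(65 + 30 * mix(cs$handedness), -100), 100),
      stringsAsFactors = FALSE)
    for (cond in cfg$conditions) {
      out[[paste0("motion_", cond)]] <-
        pmax(0.12 + 0.03 * mix(cs$motion) + 0.01 * stats::rnorm(n), 0.01)
    }
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [generate_sc()], [all_predictors()], latent deviations,
#' [generate_phenotype()] and [generate_fc()]. Passing a previous cohort as
#' `base` reuses its structural connectomes, predictor matrices and FC
#' mixing bases (the expensive, phenotype-independent parts) and redraws
#' only the participant-level deviations, phenotype and FC noise — useful
#' for simulation studies that need many cohorts under one group structure.
#'
#' @param cfg a [generator_config()].
#' @param cohort_seed participant-level seed.
#' @param base optional cohort from a previous call with the same `cfg`
#'   geometry.
#' @param acfg [analysis_config()] controlling predictor computation.
#' @param conditions conditions to generate (default: all in `cfg`).
#' @return List with `sc`, `predictors`, `fc`, `participants`, `truth`
#'   (latent deviations, structure, config) and `cfg`.
#' @export
generate_cohort <- function(cfg, cohort_seed = 1L, base = NULL,
                            acfg = analysis_config(),
                            conditions = cfg$conditions) {
  n <- cfg$n_participants
  if (is.null(base)) {
    sc <- generate_sc(cfg, cohort_seed, n)
    predictors <- lapply(sc, all_predictors, cfg = acfg)
    basis <- NULL
  } else {
    sc <- base$sc
    predictors <- base$predictors
    basis <- attr(base$fc, "basis")
  }
  k <- nrow(cfg$signal_regions)
  deviations <- if (k) withr::with_seed(cohort_seed + 3000017L,
    matrix(stats::rnorm(n * k), n, k)) else NULL
  participants <- generate_phenotype(cfg, deviations, cohort_seed, n)
  fc <- generate_fc(cfg, predictors, deviations, cohort_seed, basis = basis,
                    conditions = conditions)
  list(sc = sc, predictors = predictors, fc = fc, participants = participants,
       truth = list(deviations = deviations,
                    structure = cohort_structure(cfg)),
       cfg = cfg)
}

#' BOLD-like time series matching a functional connectome
#'
#' Draws multivariate normal time series whose population correlation matrix
#' equals the inverse-Fisher-transformed FC values, for integration testing
#' of the time-series-to-FC path.
#'
#' @param fc a [functional_connectome()].
#' @param n_timepoints number of samples T.
#' @param seed RNG seed.
#' @return T x N numeric matrix with region labels as column names.
#' @export
generate_timeseries <- function(fc, n_timepoints = 200L, seed = 1L) {
  R <- tanh(fc$values)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-6)
  L <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(n_timepoints * nrow(R)), n_timepoints)
    ts <- Z %*% L
  })
  colnames(ts) <- fc$region_labels
  ts
}
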