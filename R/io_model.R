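#' Structural connectome object
#'
#' A participant's weighted structural connectivity (SC) matrix, e.g. SIFT2
#' streamline-density weights between parcellated brain regions. The matrix
#' must be symmetric, non-negative, with a zero diagonal and at least three
#' regions.
#'
#' @param weights numeric N x N matrix of non-negative connection weights.
#' @param participant_id character scalar identifying the participant.
#' @param region_labels character vector of N region identifiers; defaults to
#'   existing dimnames or `"R1"..."RN"`.
#' @return An object of class `structural_connectome` with fields
#'   `participant_id`, `weights`, `region_labels`.
#' @export
structural_connectome <- function(weights, participant_id = "P1",
                                  region_labels = NULL) {
  weights <- validate_sc_matrix(weights)
  n <- nrow(weights)
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  }
  stopifnot(length(region_labels) == n)
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(participant_id = as.character(participant_id),
                 weights = weights,
                 region_labels = as.character(region_labels)),
            class = "structural_connectome")
}

#' Functional connectome object
#'
#' A participant-by-condition functional connectivity (FC) matrix of Fisher
#' z-transformed Pearson correlations between regional BOLD time courses.
#' The diagonal is stored as 0 and ignored by all downstream consumers
#' (self-correlation is undefined after the Fisher transform).
#'
#' @param values numeric N x N symmetric matrix (Fisher z scale).
#' @param participant_id character scalar.
#' @param condition character condition tag (e.g. `"RES"`, `"WM"`).
#' @param region_labels optional character vector of region identifiers.
#' @return An object of class `functional_connectome`.
#' @export
functional_connectome <- function(values, participant_id = "P1",
                                  condition = "RES", region_labels = NULL) {
  values <- validate_fc_matrix(values)
  n <- nrow(values)
  if (is.null(region_labels)) {
    region_labels <- rownames(values)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  }
  stopifnot(length(region_labels) == n)
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(participant_id = as.character(participant_id),
                 condition = as.character(condition),
                 values = values,
                 region_labels = as.character(region_labels)),
            class = "functional_connectome")
}

# Shared symmetry handling: reject asymmetry beyond `hard`, warn and
# symmetrize by averaging above `soft` (floating-point I/O noise).
enforce_symmetry <- function(m, hard = 1e-6, what = "matrix") {
  asym <- max(abs(m - t(m)))
  if (asym > hard) {
    stop(sprintf("%s is asymmetric (max |m - t(m)| = %.3g > %.1g)",
                 what, asym, hard), call. = FALSE)
  }
  if (asym > 0) m <- (m + t(m)) / 2
  m
}

validate_sc_matrix <- function(w) {
  if (!is.matrix(w) || !is.numeric(w)) stop("SC weights must be a numeric matrix")
  if (nrow(w) != ncol(w)) stop("SC matrix must be square")
  if (nrow(w) < 3) stop("SC matrix needs at least 3 regions")
  if (anyNA(w)) stop("SC matrix contains missing values")
  if (any(w < 0)) stop("SC weights must be non-negative")
  w <- enforce_symmetry(w, what = "SC matrix")
  diag(w) <- 0
  w
}

validate_fc_matrix <- function(v) {
  if (!is.matrix(v) || !is.numeric(v)) stop("FC values must be a numeric matrix")
  if (nrow(v) != ncol(v)) stop("FC matrix must be square")
  offd <- v[row(v) != col(v)]
  if (any(!is.finite(offd))) stop("FC matrix has non-finite off-diagonal entries")
  v <- enforce_symmetry(v, what = "FC matrix")
  diag(v) <- 0
  v
}

#' Read a connectome matrix from a delimited text file
#'
#' Reads a dense N x N matrix written by [write_connectome_matrix()] (CSV with
#' a header row of region labels) and validates it as a structural or
#' functional connectome.
#'
#' @param path file path to a CSV matrix.
#' @param kind `"structural"` or `"functional"`.
#' @param participant_id,condition metadata attached to the returned object
#'   (condition only used for functional matrices).
#' @return A [structural_connectome()] or [functional_connectome()].
#' @export
read_connectome_matrix <- function(path, kind = c("structural", "functional"),
                                   participant_id = "P1", condition = "RES") {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("non-numeric entries in %s", path))
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is not square (%d x %d)", path, nrow(m), ncol(m)))
  }
  labels <- colnames(m)
  rownames(m) <- labels
  if (kind == "structural") {
    structural_connectome(m, participant_id, labels)
  } else {
    functional_connectome(m, participant_id, condition, labels)
  }
}

#' Write a connectome matrix to CSV
#'
#' Values are serialized with 17 significant digits so that a
#' write-then-read round trip is bitwise lossless for doubles.
#'
#' @param x a `structural_connectome`, `functional_connectome`, or plain
#'   numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome_matrix <- function(x, path) {
  m <- if (is.matrix(x)) x else if (!is.null(x$weights)) x$weights else x$values
  fm <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  colnames(fm) <- colnames(m)
  utils::write.table(fm, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Functional connectivity from regional time series
#'
#' Computes the Fisher z-transformed Pearson correlation between every pair
#' of regional time courses. The diagonal is set to 0.
#'
#' @param ts numeric T x N matrix, one column per region, T >= 3 time points.
#' @param participant_id,condition metadata for the returned object.
#' @return A [functional_connectome()].
#' @export
fc_from_timeseries <- function(ts, participant_id = "P1", condition = "RES") {
  if (!is.matrix(ts) || nrow(ts) < 3) stop("time series must be a T x N matrix with T >= 3")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant time series for region(s): %s",
                 paste(bad, collapse = ", ")))
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  if (any(abs(r) >= 1)) {
    stop("perfectly correlated region pair: Fisher z undefined (|r| = 1)")
  }
  z <- atanh(r)
  functional_connectome(z, participant_id, condition, colnames(ts))
}

#' Average functional connectomes across runs
#'
#' Element-wise mean of several FC matrices from the same participant and
#' condition, e.g. the two phase-encoding runs (L/R and R/L) of one fMRI
#' condition.
#'
#' @param fc_list list of [functional_connectome()] objects with identical
#'   participant, condition and region labels.
#' @return A single [functional_connectome()].
#' @export
average_runs <- function(fc_list) {
  stopifnot(length(fc_list) >= 1)
  ref <- fc_list[[1]]
  for (fc in fc_list[-1]) {
    if (!identical(dim(fc$values), dim(ref$values)) ||
        !identical(fc$region_labels, ref$region_labels)) {
      stop("run FC matrices have mismatched shapes or region labels")
    }
    if (!identical(fc$participant_id, ref$participant_id) ||
        !identical(fc$condition, ref$condition)) {
      stop("runs to average must share participant and condition")
    }
  }
  avg <- Reduce(`+`, lapply(fc_list, `[[`, "values")) / length(fc_list)
  functional_connectome(avg, ref$participant_id, ref$condition, ref$region_labels)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the coupling and prediction pipeline.
#'
#' @param n_folds folds of the cross-validation scheme (default 5).
#' @param n_repetitions training-test split repetitions averaged for
#'   prediction performance (default 100).
#' @param n_permutations iterations of the non-parametric permutation tests
#'   (default 1000).
#' @param n_perm_repetitions CV repetitions used inside each permutation
#'   (default 10; set to `n_repetitions` for the full protocol).
#' @param alpha nominal significance level (default 0.05).
#' @param bonferroni_alpha Bonferroni-corrected threshold across the four
#'   coupling measures (default 0.0125 = 0.05 / 4).
#' @param rng_seed integer master seed for all resampling.
#' @param measure_set ordered measure tags; also the tie-break order.
#' @param weight_to_length `"inverse"` (L = 1/w) or `"neglog"`
#'   (L = -log(w / max(w))).
#' @param invert how "inversion" of PL and SI matrices is applied:
#'   `"negate"` (default) or `"reciprocal"`.
#' @param cos_exclude_pair drop entries i and j from the profile vectors when
#'   computing cosine similarity between regions i and j (default TRUE).
#' @param posthoc_adjust p adjustment for pairwise marginal-means contrasts:
#'   `"tukey"` (default) or `"bonferroni"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_folds = 5L, n_repetitions = 100L,
                            n_permutations = 1000L, n_perm_repetitions = 10L,
                            alpha = 0.05, bonferroni_alpha = 0.0125,
                            rng_seed = 1L,
                            measure_set = c("CoS", "PL", "G", "SI"),
                            weight_to_length = c("inverse", "neglog"),
                            invert = c("negate", "reciprocal"),
                            cos_exclude_pair = TRUE,
                            posthoc_adjust = c("tukey", "bonferroni")) {
  stopifnot(n_folds >= 2, n_repetitions >= 1, n_permutations >= 1,
            alpha > 0, alpha < 1, bonferroni_alpha > 0, bonferroni_alpha < 1)
  structure(list(
    n_folds = as.integer(n_folds),
    n_repetitions = as.integer(n_repetitions),
    n_permutations = as.integer(n_permutations),
    n_perm_repetitions = as.integer(n_perm_repetitions),
    alpha = alpha,
    bonferroni_alpha = bonferroni_alpha,
    rng_seed = as.integer(rng_seed),
    measure_set = measure_set,
    weight_to_length = match.arg(weight_to_length),
    invert = match.arg(invert),
    cos_exclude_pair = isTRUE(cos_exclude_pair),
    posthoc_adjust = match.arg(posthoc_adjust)
  ), class = "analysis_config")
}

#' Write a synthetic or real cohort to disk
#'
#' One CSV matrix per participant (SC) and per participant x condition (FC),
#' a TSV participant table, and a YAML manifest binding them together.
#'
#' @param cohort a cohort list as produced by [generate_cohort()]: fields
#'   `sc` (list of structural connectomes), `fc` (nested list
#'   participant -> condition -> functional connectome) and `participants`
#'   (data frame).
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(participants = list())
  for (sc in cohort$sc) {
    pid <- sc$participant_id
    sc_path <- file.path(dir, paste0(pid, "_sc.csv"))
    write_connectome_matrix(sc, sc_path)
    fc_entries <- list()
    for (fc in cohort$fc[[pid]]) {
      fc_path <- file.path(dir, paste0(pid, "_fc_", fc$condition, ".csv"))
      write_connectome_matrix(fc, fc_path)
      fc_entries[[fc$condition]] <- basename(fc_path)
    }
    manifest$participants[[pid]] <- list(sc = basename(sc_path), fc = fc_entries)
  }
  ppath <- file.path(dir, "participants.tsv")
  utils::write.table(cohort$participants, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$participant_table <- basename(ppath)
  mpath <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path path to a `cohort.yaml` written by [write_cohort()].
#' @return A list with `sc`, `fc` and `participants` in the same layout that
#'   [generate_cohort()] produces.
#' @export
read_cohort <- function(manifest_path) {
  dir <- dirname(manifest_path)
  manifest <- yaml::read_yaml(manifest_path)
  sc <- list(); fc <- list()
  for (pid in names(manifest$participants)) {
    entry <- manifest$participants[[pid]]
    sc[[pid]] <- read_connectome_matrix(file.path(dir, entry$sc),
                                        "structural", participant_id = pid)
    fc[[pid]] <- lapply(names(entry$fc), function(cond) {
      read_connectome_matrix(file.path(dir, entry$fc[[cond]]), "functional",
                             participant_id = pid, condition = cond)
    })
    names(fc[[pid]]) <- names(entry$fc)
  }
  participants <- utils::read.delim(file.path(dir, manifest$participant_table),
                                    check.names = FALSE)
  list(sc = sc, fc = fc, participants = participants)
}
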