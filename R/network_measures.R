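#' Predictor matrix object
#'
#' A similarity or communication matrix derived from one structural
#' connectome, tagged with its measure and whether the post-computation
#' adjustment (inversion / symmetrization) has been applied.
#'
#' @param values numeric N x N matrix.
#' @param measure one of `"CoS"`, `"PL"`, `"G"`, `"SI"`.
#' @param adjusted logical; TRUE once the measure's published adjustment has
#'   been applied.
#' @param region_labels optional character vector.
#' @return An object of class `predictor_matrix`.
#' @export
predictor_matrix <- function(values, measure, adjusted = FALSE,
                             region_labels = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (!is.null(region_labels)) dimnames(values) <- list(region_labels, region_labels)
  structure(list(measure = measure, values = values, adjusted = adjusted),
            class = "predictor_matrix")
}

#' Cosine similarity of structural connectivity profiles
#'
#' Entry (i, j) is the cosine of the angle between regions i's and j's
#' structural connectivity profiles (SC matrix columns). By default the
#' entries belonging to the pair itself (rows i and j) are excluded from both
#' profiles, so a strong direct connection cannot trivially inflate the
#' similarity of its endpoints. The diagonal is set to 1.
#'
#' @param sc a [structural_connectome()].
#' @param exclude_pair drop rows i and j from the profile vectors
#'   (default TRUE).
#' @return A [predictor_matrix()] with measure `"CoS"`; entries lie in
#'   \[0, 1\] for non-negative SC. Regions with zero strength get a zero
#'   row/column with a warning.
#' @export
cosine_similarity_matrix <- function(sc, exclude_pair = TRUE) {
  w <- sc$weights
  n <- nrow(w)
  f <- crossprod(w)                    # f[i,j] = full dot(c_i, c_j); diag = |c_i|^2
  nrm2 <- diag(f)
  if (exclude_pair) {
    # zero diagonal => removing rows i,j leaves the dot product unchanged,
    # but shrinks each norm by the mutual weight
    den_i <- nrm2[row(w)] - w^2        # |c_i|^2 without entries i (0) and j
    den_j <- nrm2[col(w)] - w^2
    den <- sqrt(pmax(den_i, 0) * pmax(den_j, 0))
  } else {
    den <- sqrt(outer(nrm2, nrm2))
  }
  cosm <- matrix(0, n, n)
  ok <- den > 0
  cosm[ok] <- f[ok] / den[ok]
  cosm <- pmin(pmax(cosm, 0), 1)
  dim(cosm) <- c(n, n)
  zero_strength <- nrm2 == 0
  if (any(zero_strength)) {
    warning(sprintf("zero-strength region(s) %s: cosine row/column set to 0",
                    paste(which(zero_strength), collapse = ", ")))
    cosm[zero_strength, ] <- 0
    cosm[, zero_strength] <- 0
  }
  diag(cosm) <- ifelse(zero_strength, 0, 1)
  cosm <- (cosm + t(cosm)) / 2
  predictor_matrix(cosm, "CoS", adjusted = TRUE, region_labels = sc$region_labels)
}

#' Map connection weights to edge lengths
#'
#' Strong connections should be short: the default rule is L = 1/w; the
#' alternative is L = -log(w / max(w)), under which the strongest edge has
#' zero length. Absent connections (w = 0) map to `Inf`.
#'
#' @param sc a [structural_connectome()].
#' @param rule `"inverse"` or `"neglog"`.
#' @return N x N numeric length matrix with `Inf` for missing edges and 0 on
#'   the diagonal.
#' @export
weight_to_length <- function(sc, rule = c("inverse", "neglog")) {
  rule <- match.arg(rule)
  w <- sc$weights
  L <- matrix(Inf, nrow(w), ncol(w))
  pos <- w > 0
  if (rule == "inverse") {
    L[pos] <- 1 / w[pos]
  } else {
    L[pos] <- -log(w[pos] / max(w))
  }
  diag(L) <- 0
  L
}

# Dijkstra from one source on an edge-length matrix, with deterministic
# lexicographic tie-breaking: among equal-length alternatives the smallest
# predecessor index is kept, and among equally distant unvisited nodes the
# smallest index is settled first. Returns distances and predecessor vector.
dijkstra_tree <- function(L, source, tol = 1e-12) {
  n <- nrow(L)
  dist <- rep(Inf, n); dist[source] <- 0
  pred <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  for (step in seq_len(n)) {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]    # which.min takes the first = smallest index
    visited[u] <- TRUE
    nd <- dist[u] + L[u, ]
    better <- !visited & nd < dist - tol
    tie <- !visited & !better & abs(nd - dist) <= tol & is.finite(nd) &
      (is.na(pred) | u < pred)
    tie[source] <- FALSE
    dist[better] <- nd[better]
    pred[better] <- u
    pred[tie] <- u
  }
  list(dist = dist, pred = pred)
}

#' Shortest path length matrix
#'
#' All-pairs shortest path distances (Dijkstra) on the weight-to-length
#' transformed structural connectome, then adjusted so that larger values
#' mean closer/easier communication: distances are negated by default
#' (`invert = "negate"`) or replaced by their reciprocal. Unreachable pairs
#' are assigned 1.5 times the largest finite distance before adjustment,
#' with a warning. Diagonal 0.
#'
#' @param sc a [structural_connectome()].
#' @param rule weight-to-length rule, see [weight_to_length()].
#' @param invert `"negate"` (default) or `"reciprocal"`.
#' @return A [predictor_matrix()] with measure `"PL"`.
#' @export
path_length_matrix <- function(sc, rule = c("inverse", "neglog"),
                               invert = c("negate", "reciprocal")) {
  rule <- match.arg(rule); invert <- match.arg(invert)
  L <- weight_to_length(sc, rule)
  D <- igraph_distances_from_lengths(L)
  offd <- D[row(D) != col(D)]
  if (any(!is.finite(offd))) {
    mx <- max(offd[is.finite(offd)], -Inf)
    if (!is.finite(mx)) mx <- 1
    warning("disconnected region pair(s): assigned 1.5 x the largest finite distance")
    D[!is.finite(D)] <- mx * 1.5
  }
  vals <- if (invert == "negate") -D else {
    out <- matrix(0, nrow(D), ncol(D))
    nz <- D > 0
    out[nz] <- 1 / D[nz]
    out
  }
  diag(vals) <- 0
  predictor_matrix(vals, "PL", adjusted = TRUE, region_labels = sc$region_labels)
}

# all-pairs Dijkstra distances via igraph on a finite-length edge list
igraph_distances_from_lengths <- function(L) {
  n <- nrow(L)
  idx <- which(is.finite(L) & upper.tri(L), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    D <- matrix(Inf, n, n); diag(D) <- 0
    return(D)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(idx))
  igraph::E(g)$weight <- L[idx]
  igraph::distances(g, algorithm = "dijkstra")
}

#' Communicability matrix
#'
#' Weighted communicability: the matrix exponential of the strength-
#' normalized weight matrix, exp(D^{-1/2} W D^{-1/2}) with
#' D = diag(node strengths). All walks of all lengths contribute, each
#' damped by the factorial of its length. No post-computation adjustment is
#' applied. Computed by symmetric eigendecomposition.
#'
#' @param sc a [structural_connectome()].
#' @return A [predictor_matrix()] with measure `"G"`.
#' @export
communicability_matrix <- function(sc) {
  w <- sc$weights
  s <- rowSums(w)
  d <- ifelse(s > 0, 1 / sqrt(s), 0)
  m <- w * outer(d, d)
  m <- (m + t(m)) / 2
  eig <- eigen(m, symmetric = TRUE)
  G <- eig$vectors %*% (exp(eig$values) * t(eig$vectors))
  G <- (G + t(G)) / 2
  predictor_matrix(G, "G", adjusted = TRUE, region_labels = sc$region_labels)
}

#' Search information matrix
#'
#' Bits of information a random walker needs to follow the shortest path
#' between two regions: raw SI(i -> j) = -log2 of the product of transition
#' probabilities p(u -> v) = w_uv / strength(u) along the shortest path from
#' i to j on the weight-to-length graph. The raw matrix is then symmetrized,
#' S = (SI(i->j) + SI(j->i)) / 2, and inverted (negated by default) so that
#' larger adjusted values mean easier communication. Unreachable pairs get
#' 1.5 times the largest finite symmetrized SI before inversion, with a
#' warning. Diagonal 0. Equal-length shortest-path ties are broken
#' deterministically (lexicographic smallest predecessor).
#'
#' @param sc a [structural_connectome()].
#' @param rule weight-to-length rule for the shortest-path graph.
#' @param invert `"negate"` (default) or `"reciprocal"`.
#' @return A [predictor_matrix()] with measure `"SI"`.
#' @export
search_information_matrix <- function(sc, rule = c("inverse", "neglog"),
                                      invert = c("negate", "reciprocal")) {
  rule <- match.arg(rule); invert <- match.arg(invert)
  w <- sc$weights
  n <- nrow(w)
  L <- weight_to_length(sc, rule)
  strength <- rowSums(w)
  logp <- matrix(-Inf, n, n)
  pos <- w > 0
  logp[pos] <- log2(w[pos]) - log2(strength[row(w)[pos]])
  raw <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tr <- dijkstra_tree(L, i)
    for (j in seq_len(n)) {
      if (j == i) { raw[i, j] <- 0; next }
      if (!is.finite(tr$dist[j])) next   # unreachable, fill later
      bits <- 0; v <- j
      while (v != i) {
        u <- tr$pred[v]
        bits <- bits - logp[u, v]
        v <- u
      }
      raw[i, j] <- bits
    }
  }
  S <- (raw + t(raw)) / 2
  offd <- S[row(S) != col(S)]
  if (anyNA(offd)) {
    mx <- max(offd, na.rm = TRUE)
    if (!is.finite(mx)) mx <- 1
    warning("disconnected region pair(s): assigned 1.5 x the largest finite search information")
    S[is.na(S)] <- mx * 1.5
  }
  vals <- if (invert == "negate") -S else {
    out <- matrix(0, n, n)
    nz <- S > 0
    out[nz] <- 1 / S[nz]
    out
  }
  diag(vals) <- 0
  predictor_matrix(vals, "SI", adjusted = TRUE, region_labels = sc$region_labels)
}

#' All four predictor matrices for one structural connectome
#'
#' Applies [cosine_similarity_matrix()], [path_length_matrix()],
#' [communicability_matrix()] and [search_information_matrix()] in the order
#' given by `cfg$measure_set`.
#'
#' @param sc a [structural_connectome()].
#' @param cfg an [analysis_config()].
#' @return Named list of four [predictor_matrix()] objects.
#' @export
all_predictors <- function(sc, cfg = analysis_config()) {
  out <- lapply(cfg$measure_set, function(m) {
    switch(m,
      CoS = cosine_similarity_matrix(sc, exclude_pair = cfg$cos_exclude_pair),
      PL  = path_length_matrix(sc, rule = cfg$weight_to_length, invert = cfg$invert),
      G   = communicability_matrix(sc),
      SI  = search_information_matrix(sc, rule = cfg$weight_to_length,
                                      invert = cfg$invert),
      stop(sprintf("unknown measure '%s'", m)))
  })
  names(out) <- cfg$measure_set
  out
}
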