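# Fixture builders and independent oracles used across test files.

# random connected weighted SC (chain backbone + random extra edges,
# continuous log-normal weights so shortest paths are unique a.s.)
rand_sc <- function(n, density = 0.4, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) W[i, i + 1] <- rlnorm(1)
    up <- which(upper.tri(W) & W == 0)
    extra <- up[runif(length(up)) < density]
    W[extra] <- rlnorm(length(extra))
    W <- W + t(W)
    structural_connectome(W, participant_id = sprintf("S%d", seed))
  })
}

# exhaustive simple-path enumeration oracle for all-pairs shortest path
# distances on an edge-length matrix (Inf = no edge); feasible for n <= 7
oracle_shortest_paths <- function(L) {
  n <- nrow(L)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  walk <- function(path, len, target) {
    u <- path[length(path)]
    if (u == target) {
      if (len < best[path[1], target]) best[path[1], target] <<- len
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (is.finite(L[u, v]) && u != v && !(v %in% path)) {
        walk(c(path, v), len + L[u, v], target)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) walk(i, 0, j)
  best
}

# independent search-information oracle: find the shortest path with igraph,
# then multiply the random-walk transition probabilities step by step
oracle_search_information <- function(sc, rule = "inverse") {
  W <- sc$weights
  n <- nrow(W)
  L <- weight_to_length(sc, rule)
  idx <- which(is.finite(L) & upper.tri(L), arr.ind = TRUE)
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  gr <- igraph::add_edges(gr, t(idx))
  igraph::E(gr)$weight <- L[idx]
  strength <- rowSums(W)
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sp <- suppressWarnings(igraph::shortest_paths(gr, from = i,
                                                  to = seq_len(n),
                                                  output = "vpath"))
    for (j in seq_len(n)) {
      if (j == i) next
      path <- as.integer(sp$vpath[[j]])
      if (length(path) < 2) { raw[i, j] <- NA; next }
      bits <- 0
      for (s in seq_len(length(path) - 1)) {
        u <- path[s]; v <- path[s + 1]
        bits <- bits - log2(W[u, v] / strength[u])
      }
      raw[i, j] <- bits
    }
  }
  S <- (raw + t(raw)) / 2
  -S
}

# truncated power-series oracle for normalized weighted communicability
oracle_communicability <- function(sc, K = 60) {
  W <- sc$weights
  s <- rowSums(W)
  d <- ifelse(s > 0, 1 / sqrt(s), 0)
  M <- W * outer(d, d)
  acc <- diag(nrow(W))
  term <- diag(nrow(W))
  for (k in seq_len(K)) {
    term <- term %*% M / k
    acc <- acc + term
  }
  acc
}

# direct per-pair evaluation of the cosine-similarity formula
oracle_cosine <- function(W, exclude_pair = TRUE) {
  n <- nrow(W)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- W[, i]; cj <- W[, j]
    if (exclude_pair) { ci <- ci[-c(i, j)]; cj <- cj[-c(i, j)] }
    den <- sqrt(sum(ci^2) * sum(cj^2))
    out[i, j] <- if (den > 0) sum(ci * cj) / den else 0
  }
  out
}

# two columns with an exact sample Pearson correlation r, plus independent
# filler columns
ts_with_cor <- function(r, T_ = 50, extra = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(T_)
    e <- rnorm(T_)
    x <- (x - mean(x)) / sd(x)
    e <- lm.fit(cbind(1, x), e)$residuals
    e <- e / sd(e)
    y <- r * x + sqrt(1 - r^2) * e
    cbind(x = x, y = y,
          matrix(rnorm(T_ * extra), T_, extra,
                 dimnames = list(NULL, paste0("z", seq_len(extra)))))
  })
}

# participant table with covariates for hand-built coupling tables
make_participants <- function(n, conditions, g = NULL, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(participant_id = sprintf("S%d", seq_len(n)),
                     g = if (is.null(g)) rnorm(n) else g,
                     age = runif(n, 22, 36),
                     gender = rbinom(n, 1, 0.5),
                     handedness = runif(n, -100, 100))
    for (cond in conditions) df[[paste0("motion_", cond)]] <- runif(n, 0.05, 0.2)
    df
  })
}

# coupling table array with the right dimnames from an n x M x N generator
make_coupling_table <- function(values, conditions, measures = c("CoS", "PL", "G", "SI")) {
  dn <- list(sprintf("S%d", seq_len(dim(values)[1])), conditions, measures,
             sprintf("R%d", dim(values)[4]))
  dn[[4]] <- sprintf("R%d", seq_len(dim(values)[4]))
  dimnames(values) <- dn
  class(values) <- c("coupling_table", "array")
  values
}
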