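test_that("cosine similarity matches the profile-formula oracle", {
  # two regions with identical profiles -> 1; orthogonal profiles -> 0
  W <- matrix(0, 5, 5)
  W[1, 3] <- W[2, 3] <- 1     # regions 1 and 2 share exactly neighbor 3
  W[4, 5] <- 2                # regions 4 and 5 connect only to each other
  W <- W + t(W)
  cs <- suppressWarnings(cosine_similarity_matrix(structural_connectome(W)))
  expect_equal(cs$values[1, 2], 1)
  expect_equal(cs$values[1, 4], 0)   # no shared neighbors

  sc <- rand_sc(4, density = 1, seed = 9)
  got <- cosine_similarity_matrix(sc)$values
  expect_equal(unname(got), oracle_cosine(sc$weights), tolerance = 1e-12)

  sc2 <- rand_sc(7, density = 0.6, seed = 10)
  full <- cosine_similarity_matrix(sc2, exclude_pair = FALSE)$values
  expect_equal(unname(full), oracle_cosine(sc2$weights, exclude_pair = FALSE),
               tolerance = 1e-12)
  expect_true(all(full >= 0 & full <= 1))
})

test_that("cosine similarity zeroes out zero-strength regions with a warning", {
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 3] <- 1; W <- W + t(W)  # node 4 isolated
  expect_warning(cs <- cosine_similarity_matrix(structural_connectome(W)),
                 "zero-strength")
  expect_equal(cs$values[4, ], rep(0, 4), ignore_attr = TRUE)
})

test_that("weight-to-length rules behave as documented", {
  W <- matrix(0, 3, 3); W[1, 2] <- 2; W[2, 3] <- 4; W <- W + t(W)
  sc <- structural_connectome(W)
  L <- weight_to_length(sc, "inverse")
  expect_equal(L[1, 2], 0.5)
  expect_equal(L[1, 3], Inf)
  L2 <- weight_to_length(sc, "neglog")
  expect_equal(L2[2, 3], 0)                 # max-weight edge has zero length
  expect_equal(L2[1, 2], -log(2 / 4))
})

test_that("shortest path lengths equal exhaustive enumeration and are negated", {
  W <- matrix(0, 3, 3); W[1, 2] <- 1; W[2, 3] <- 1; W <- W + t(W)
  pl <- path_length_matrix(structural_connectome(W))
  expect_equal(pl$values[1, 3], -2)         # chain a-b-c with lengths 1, 1
  expect_equal(pl$values[1, 2], -1)         # direct edge

  for (seed in 1:8) {
    sc <- rand_sc(7, density = 0.35, seed = seed)
    L <- weight_to_length(sc)
    want <- oracle_shortest_paths(L)
    got <- path_length_matrix(sc)$values
    expect_equal(unname(got), -want, tolerance = 1e-10)
  }
})

test_that("disconnected pairs get the sentinel distance with a warning", {
  W <- matrix(0, 5, 5); W[1, 2] <- W[2, 3] <- 1; W[4, 5] <- 1; W <- W + t(W)
  expect_warning(pl <- path_length_matrix(structural_connectome(W)),
                 "disconnected")
  expect_equal(pl$values[1, 4], -2 * 1.5)   # 1.5 x the largest finite distance
})

test_that("communicability equals the truncated power series", {
  # empty graph: exp(0) = identity
  g0 <- communicability_matrix(structural_connectome(matrix(0, 4, 4)))
  expect_equal(unname(g0$values), diag(4), tolerance = 1e-12)

  # two connected nodes: strength normalization gives off-diagonal sinh(1)
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 5
  g2 <- communicability_matrix(structural_connectome(W))
  expect_equal(g2$values[1, 2], sinh(1), tolerance = 1e-12)
  expect_equal(g2$values[1, 1], cosh(1), tolerance = 1e-12)

  sc <- rand_sc(20, density = 0.3, seed = 4)
  expect_lt(max(abs(communicability_matrix(sc)$values - oracle_communicability(sc))),
            1e-8)
})

test_that("search information matches closed forms and is symmetric-negated", {
  # star: center -> leaf costs log2(k) bits, leaf -> center 0
  k <- 4
  W <- matrix(0, k + 1, k + 1); W[1, 2:(k + 1)] <- 1; W <- W + t(W)
  si <- search_information_matrix(structural_connectome(W))
  expect_equal(si$values[1, 2], -(log2(k) + 0) / 2)
  expect_equal(si$values, t(si$values))

  # forced single step both ways: chain end pair
  W3 <- matrix(0, 3, 3); W3[1, 2] <- W3[2, 3] <- 1; W3 <- W3 + t(W3)
  si3 <- search_information_matrix(structural_connectome(W3))
  # 1->2: p = 1 (only edge); 2->1: p = 1/2; symmetrized 0.5, negated
  expect_equal(si3$values[1, 2], -0.5)

  for (seed in 1:6) {
    sc <- rand_sc(8, density = 0.4, seed = 20 + seed)
    want <- oracle_search_information(sc)
    got <- search_information_matrix(sc)$values
    diag(want) <- 0
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("all_predictors returns the four measures in order, symmetric, equivariant", {
  sc <- rand_sc(12, density = 0.4, seed = 6)
  cfg <- analysis_config()
  preds <- all_predictors(sc, cfg)
  expect_identical(names(preds), c("CoS", "PL", "G", "SI"))
  for (p in preds) expect_lt(max(abs(p$values - t(p$values))), 1e-10)

  # permutation equivariance: relabeling nodes relabels every output
  perm <- withr::with_seed(1, sample(12))
  scp <- structural_connectome(sc$weights[perm, perm])
  predsp <- all_predictors(scp, cfg)
  for (m in names(preds)) {
    expect_equal(unname(predsp[[m]]$values), unname(preds[[m]]$values[perm, perm]),
                 tolerance = 1e-9, label = m)
  }
})

test_that("adjusted PL and SI are monotone decreasing in their raw values", {
  sc <- rand_sc(9, density = 0.5, seed = 33)
  pl_neg <- path_length_matrix(sc, invert = "negate")$values
  pl_rec <- path_length_matrix(sc, invert = "reciprocal")$values
  off <- upper.tri(pl_neg)
  # both inversions order pairs identically (larger = closer)
  expect_equal(order(pl_neg[off]), order(pl_rec[off]))
  si_neg <- search_information_matrix(sc)$values
  raw <- -si_neg
  expect_equal(cor(si_neg[off], raw[off]), -1)
})
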