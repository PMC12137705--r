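# a coupling table where measure `m_idx` at every region tracks the
# phenotype linearly and the others are noise
planted_table <- function(n, N, g, m_idx = 3, conds = c("RES", "T1"),
                          noise = 0.02, seed = 1) {
  vals <- withr::with_seed(seed, array(rnorm(n * length(conds) * 4 * N, 0, noise),
                                       c(n, length(conds), 4, N)))
  sig <- 0.2 * as.vector(scale(g))
  for (cc in seq_along(conds)) for (i in seq_len(N)) {
    vals[, cc, m_idx, i] <- vals[, cc, m_idx, i] + sig
  }
  make_coupling_table(vals, conditions = conds)
}

test_that("NMA masks pick the dominant measure and flag forced assignments", {
  n <- 120; N <- 6
  parts <- make_participants(n, c("RES", "T1"), seed = 2)
  tab <- planted_table(n, N, parts$g, m_idx = 3)
  mk <- build_nma_mask(tab, parts, "T1")
  expect_true(all(mk$positive == 3))
  expect_false(any(mk$forced_positive))
  # negative mask comes from noise only here; swapping g flips the roles
  parts2 <- parts; parts2$g <- -parts$g
  mk2 <- build_nma_mask(tab, parts2, "T1")
  expect_true(all(mk2$negative == 3))
})

test_that("degenerate coupling columns get r_P = 0 and are logged", {
  n <- 40; N <- 4
  parts <- make_participants(n, "T1", seed = 3)
  vals <- withr::with_seed(4, array(rnorm(n * 4 * N, 0, 0.05), c(n, 1, 4, N)))
  vals[, 1, 2, 1] <- 0.3          # constant column: PL at region 1
  tab <- make_coupling_table(vals, conditions = "T1")
  expect_message(mk <- build_nma_mask(tab, parts, "T1"), "degenerate")
  expect_equal(mk$r_P[1, "PL"], 0)
})

test_that("feature extraction averages masked couplings and swaps with the mask", {
  n <- 10; N <- 3
  vals <- array(0.33, c(n, 1, 4, N))
  tab <- make_coupling_table(vals, conditions = "T1")
  parts <- make_participants(n, "T1", seed = 5)
  mk <- suppressMessages(build_nma_mask(tab, parts, "T1"))
  ft <- extract_features(mk, tab)
  expect_equal(ft$X1, rep(0.33, n))
  expect_equal(ft$X2, rep(0.33, n))

  # hand-built 3-region check with distinct values per measure/region
  vals2 <- withr::with_seed(6, array(runif(n * 4 * N, -0.5, 0.5), c(n, 1, 4, N)))
  tab2 <- make_coupling_table(vals2, conditions = "T1")
  mk2 <- suppressMessages(build_nma_mask(tab2, parts, "T1"))
  ft2 <- extract_features(mk2, tab2)
  want_X1 <- rowMeans(sapply(1:N, function(i) vals2[, 1, mk2$positive[i], i]))
  expect_equal(ft2$X1, want_X1, tolerance = 1e-12)
  swapped <- mk2; swapped$positive <- mk2$negative; swapped$negative <- mk2$positive
  ft3 <- extract_features(swapped, tab2)
  expect_equal(ft3$X1, ft2$X2)
  expect_equal(ft3$X2, ft2$X1)
})

test_that("B-NMA recovers a noiseless linear phenotype and is deterministic", {
  n <- 80; N <- 6
  parts <- make_participants(n, c("RES", "T1"), seed = 7)
  tab <- planted_table(n, N, parts$g, m_idx = 3, noise = 0.001)
  cfg <- analysis_config(n_repetitions = 5, rng_seed = 42)
  res <- fit_predict_bnma(tab, parts, "T1", cfg)
  expect_gt(res$r, 0.95)
  expect_equal(res$R2, res$r^2)
  expect_length(res$per_repetition_r, 5)
  # bitwise determinism under the same seed
  res2 <- fit_predict_bnma(tab, parts, "T1", cfg)
  expect_identical(res$per_repetition_r, res2$per_repetition_r)
  # different seed changes the folds
  res3 <- fit_predict_bnma(tab, parts, "T1",
                           analysis_config(n_repetitions = 5, rng_seed = 43))
  expect_false(identical(res$per_repetition_r, res3$per_repetition_r))
})

test_that("masks are leakage-free: test-fold participants cannot alter them", {
  n <- 50; N <- 5
  parts <- make_participants(n, "T1", seed = 8)
  vals <- withr::with_seed(9, array(rnorm(n * 4 * N, 0, 0.1), c(n, 1, 4, N)))
  tab <- make_coupling_table(vals, conditions = "T1")
  train <- 1:40
  mk_a <- build_nma_mask(tab, parts, "T1", train = train)
  # plant a marker participant in the held-out fold
  vals_b <- vals; vals_b[45, , , ] <- 0.99
  tab_b <- make_coupling_table(vals_b, conditions = "T1")
  parts_b <- parts; parts_b$g[45] <- 100
  mk_b <- build_nma_mask(tab_b, parts_b, "T1", train = train)
  expect_identical(mk_a$positive, mk_b$positive)
  expect_identical(mk_a$negative, mk_b$negative)
  expect_identical(mk_a$r_P, mk_b$r_P)
})

test_that("E-NMA reduces to B-NMA for a single-task cohort", {
  n <- 70; N <- 5
  parts <- make_participants(n, c("RES", "T1"), seed = 10)
  tab <- planted_table(n, N, parts$g, m_idx = 2, noise = 0.05)
  cfg <- analysis_config(n_repetitions = 4, rng_seed = 11)
  rb <- fit_predict_bnma(tab, parts, "T1", cfg)
  re <- fit_predict_enma(tab, parts, cfg, rest = "RES")
  expect_identical(re$conditions, "T1")
  expect_equal(re$per_repetition_r, rb$per_repetition_r, tolerance = 1e-12)
})

test_that("E-NMA uses 2 features per task and guards against saturation", {
  n <- 24; N <- 4
  conds <- c("RES", paste0("T", 1:9))
  parts <- make_participants(n, conds, seed = 12)
  vals <- withr::with_seed(13, array(rnorm(n * 10 * 4 * N, 0, 0.1),
                                     c(n, 10, 4, N)))
  tab <- make_coupling_table(vals, conditions = conds)
  cfg <- analysis_config(n_repetitions = 1, rng_seed = 14)
  # 9 tasks -> 18 features + intercept vs ~19 training rows: saturated
  expect_error(fit_predict_enma(tab, parts, cfg), "saturates")
})

test_that("permutation p attains its lower bound for a dominant effect", {
  n <- 80; N <- 5
  parts <- make_participants(n, c("RES", "T1"), seed = 15)
  tab <- planted_table(n, N, parts$g, m_idx = 1, noise = 0.001)
  cfg <- analysis_config(n_repetitions = 3, n_permutations = 19,
                         n_perm_repetitions = 2, rng_seed = 16)
  res <- fit_predict_bnma(tab, parts, "T1", cfg)
  pt <- permutation_test(res, tab, parts, cfg)
  expect_equal(pt$p, 1 / 20)
  expect_length(pt$r_perm, 19)
})

test_that("comparing a model with itself gives p = 1", {
  n <- 60; N <- 4
  parts <- make_participants(n, c("RES", "T1"), seed = 17)
  tab <- planted_table(n, N, parts$g, noise = 0.05)
  cfg <- analysis_config(n_repetitions = 2, n_permutations = 20,
                         n_perm_repetitions = 2, rng_seed = 18)
  res <- fit_predict_bnma(tab, parts, "T1", cfg)
  md <- model_difference_test(res, res, tab, parts, cfg)
  expect_equal(md$delta_obs, 0)
  expect_equal(md$p, 1)
  expect_true(all(md$delta_perm >= 0))
})

test_that("cross-sample transfer approaches the within-sample fit and nulls out", {
  n <- 100; N <- 6
  parts <- make_participants(n, c("RES", "T1"), seed = 19)
  tab <- planted_table(n, N, parts$g, m_idx = 3, noise = 0.02)
  cfg <- analysis_config(n_repetitions = 5, n_permutations = 50, rng_seed = 20)
  internal <- fit_predict_bnma(tab, parts, "T1", cfg)
  # self-application: replication = training cohort
  gen <- cross_sample_generalize(tab, parts, tab, parts, "bnma", "T1", cfg)
  expect_length(gen$per_model_r, 5 * 5)
  expect_gt(gen$r, internal$r - 0.1)
  expect_lt(gen$p, 0.05)
  # phenotype-rerandomized replication transfers nothing
  parts_null <- parts
  parts_null$g <- withr::with_seed(21, sample(parts$g))
  gen0 <- cross_sample_generalize(tab, parts, tab, parts_null, "bnma", "T1", cfg)
  expect_lt(abs(gen0$r), 0.15)
  # missing condition -> model skipped with a warning
  tab_small <- make_coupling_table(array(unclass(tab)[, 1, , , drop = FALSE],
                                         c(n, 1, 4, N)), conditions = "RES")
  expect_warning(gen_na <- cross_sample_generalize(tab, parts, tab_small,
                                                   parts, "bnma", "T1", cfg),
                 "absent")
  expect_null(gen_na)
})
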