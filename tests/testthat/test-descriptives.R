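test_that("condition_contrast handles the degenerate equal-condition case", {
  ba <- matrix(0.4, 20, 4, dimnames = list(NULL, c("RES", "A", "B", "C")))
  expect_warning(res <- condition_contrast(ba), "no within-participant")
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("two-condition repeated-measures F equals the squared paired t", {
  withr::with_seed(5, {
    ba <- cbind(RES = rnorm(25, 0.4, 0.05), TSK = rnorm(25, 0.37, 0.05))
  })
  res <- condition_contrast(ba, pairwise = FALSE)
  tt <- t.test(ba[, 1], ba[, 2], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p, tt$p.value, tolerance = 1e-8)
})

test_that("a planted condition offset is detected in all its pairwise contrasts", {
  withr::with_seed(6, {
    n <- 200
    base <- rnorm(n, 0.4, 0.01)
    ba <- cbind(RES = base + rnorm(n, 0.05, 0.01),
                A = base + rnorm(n, 0, 0.01),
                B = base + rnorm(n, 0, 0.01),
                C = base + rnorm(n, 0, 0.01))
  })
  res <- condition_contrast(ba)
  expect_lt(res$p, 0.001)
  res_rows <- grepl("RES", res$pairwise$contrast)
  expect_true(all(res$pairwise$p[res_rows] < 0.05))
  expect_true(all(res$pairwise$estimate[res_rows] > 0))
})

test_that("repeated-measures contrast keeps its nominal type-I error", {
  rejections <- 0
  n_sims <- 200
  for (s in seq_len(n_sims)) {
    ba <- withr::with_seed(1000 + s, matrix(rnorm(50 * 4, 0.4, 0.02), 50, 4))
    colnames(ba) <- c("RES", "A", "B", "C")
    res <- condition_contrast(ba, pairwise = FALSE)
    if (res$p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sims
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("best_measure_pattern recovers a dominant measure and breaks ties low", {
  n <- 30; N <- 8
  vals <- withr::with_seed(2, array(rnorm(n * 2 * 4 * N, 0.1, 0.02), c(n, 2, 4, N)))
  vals[, , 3, ] <- 0.9    # G dominates everywhere
  tab <- make_coupling_table(vals, conditions = c("RES", "T1"))
  bp <- best_measure_pattern(tab, "T1")
  expect_true(all(bp$assignment == "G"))
  expect_equal(unname(bp$values), rep(0.81, N), tolerance = 1e-6)
  expect_true(all(bp$values >= 0 & bp$values <= 1))

  # exact tie -> lowest-index measure wins, with a log message
  vals[, , 1, ] <- 0.9
  tab2 <- make_coupling_table(vals, conditions = c("RES", "T1"))
  expect_message(bp2 <- best_measure_pattern(tab2, "T1"), "tied")
  expect_true(all(bp2$assignment == "CoS"))

  # invariance to participant order
  perm <- withr::with_seed(3, sample(n))
  tab3 <- make_coupling_table(vals[perm, , , ], conditions = c("RES", "T1"))
  bp3 <- suppressMessages(best_measure_pattern(tab3, "T1"))
  expect_identical(bp3$assignment, bp2$assignment)
  expect_equal(bp3$values, bp2$values, tolerance = 1e-12)
})

test_that("pattern_similarity separates rest from a shared task template", {
  N <- 80
  mk <- function(cond, v) structure(list(condition = cond, values = v),
                                    class = "regional_pattern")
  withr::with_seed(7, {
    template <- runif(N, 0.2, 0.6)
    rest_shift <- rnorm(N, 0, 0.2)     # rest diverges from the task template
    pats <- c(list(mk("RES", template + rest_shift)),
              lapply(1:4, function(i) mk(paste0("T", i),
                                         template + rnorm(N, 0, 0.03))))
  })
  ps <- pattern_similarity(pats, rest = "RES")
  expect_equal(ps$cor_matrix, t(ps$cor_matrix))
  expect_equal(unname(diag(ps$cor_matrix)), rep(1, 5))
  expect_gt(ps$mean_z_task_task, ps$mean_z_rest_task)
  expect_lt(ps$p, 0.05)

  # identical patterns: degenerate, flagged non-significant
  same <- lapply(c("RES", "T1", "T2"), function(cc) mk(cc, template))
  expect_warning(ps2 <- pattern_similarity(same), "degenerate")
  expect_equal(ps2$p, 1)
})

test_that("adaptation maps follow their closed-form construction", {
  N <- 12; k <- 3; d <- 0.1
  mk <- function(cond, v) structure(list(condition = cond, values = v),
                                    class = "regional_pattern")
  rest <- withr::with_seed(8, runif(N, 0.3, 0.5))
  pats <- list(mk("RES", rest),
               mk("T1", rest + d),      # one task shifted by +d everywhere
               mk("T2", rest), mk("T3", rest))
  maps <- adaptation_maps(pats, rest = "RES")
  expect_true(all(vapply(maps, function(m) all(m$values >= 0), TRUE)))
  m1 <- maps[["task_specific_vs_rest.T1"]]
  expect_equal(m1$summary, d, tolerance = 1e-12)
  expect_equal(maps[["task_specific_vs_rest.T2"]]$summary, 0)
  # relative percentage vs the grand mean d/k
  expect_equal(m1$relative_pct, 100 * (d - d / k) / (d / k), tolerance = 1e-9)
  expect_equal(maps[["task_general"]]$summary, d / k, tolerance = 1e-12)
  # identical patterns everywhere -> all maps zero
  pats0 <- list(mk("RES", rest), mk("T1", rest), mk("T2", rest))
  maps0 <- adaptation_maps(pats0)
  expect_true(all(vapply(maps0, function(m) max(m$values), 0) == 0))
  expect_error(adaptation_maps(list(mk("RES", rest), mk("T1", rest))),
               "at least 2 tasks")
})
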