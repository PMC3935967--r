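# TM-score and selection metrics.

test_that("tm_score is 1 for identity and rigid motions, errors on mismatch", {
  nat <- tiny_native()
  expect_equal(tm_score(nat, nat), 1)
  set.seed(5)
  rot <- meftop:::random_rotation()
  moved <- meftop:::transform_model(nat, rot, c(14, -8, 3))
  expect_equal(tm_score(moved, nat), 1, tolerance = 1e-6)
  short <- structure_model(rep("A", 5), ca = cbind(3.8 * (0:4), 0, 0))
  expect_error(tm_score(short, nat), "length")
})

test_that("tm_score tracks the exhaustive-window superposition oracle", {
  # 30-residue toy with half the chain displaced far away
  set.seed(2)
  base <- cbind(cumsum(runif(30, 3.6, 3.9)), cumsum(rnorm(30, 0, 1.5)),
                cumsum(rnorm(30, 0, 1.5)))
  nat <- structure_model(rep("A", 30), ca = base)
  mod <- nat
  mod$ca[16:30, ] <- mod$ca[16:30, ] + 60
  got <- tm_score(mod, nat)
  want <- oracle_tm(mod$ca, nat$ca)
  expect_equal(got, want, tolerance = 0.01)
  expect_lt(got, 0.6)
})

test_that("top1_percent applies the strict native-likeness cutoff", {
  expect_equal(top1_percent(c(0.5, 0.3, 0.45, 0.2)), 50)
  expect_equal(top1_percent(c(0.4)), 0)        # exactly 0.4 is not native-like
  expect_equal(top1_percent(rep(0.9, 7)), 100)
})

test_that("average_rank uses true-TM ordering with averaged ties", {
  scored <- tibble::tibble(
    target_id = rep(c("a", "b"), each = 3),
    model_id = rep(c("m1", "m2", "m3"), 2),
    tm = c(0.9, 0.5, 0.1, 0.7, 0.7, 0.2))
  best <- tibble::tibble(target_id = c("a", "b"), model_id = c("m1", "m1"))
  # target b has m1 and m2 tied at the top: both get rank 1.5
  expect_equal(average_rank(scored, best), mean(c(1, 1.5)))
  worst <- tibble::tibble(target_id = c("a", "b"), model_id = c("m3", "m3"))
  expect_equal(average_rank(scored, worst), 3)
  # invariance under model relabeling
  relabeled <- scored
  relabeled$model_id <- rep(c("x9", "x2", "x5"), 2)
  best2 <- tibble::tibble(target_id = c("a", "b"), model_id = c("x9", "x9"))
  expect_equal(average_rank(relabeled, best2), mean(c(1, 1.5)))
})

test_that("per_target_cc covers perfect, inverted and degenerate predictors", {
  scored <- tibble::tibble(
    target_id = rep(c("a", "b"), each = 4),
    tm = rep(c(0.1, 0.4, 0.6, 0.9), 2))
  scored$p <- scored$tm
  expect_equal(per_target_cc(scored)$mean_cc, 1)
  expect_equal(per_target_cc(scored)$sd_cc, 0)
  scored$p <- -scored$tm
  expect_equal(per_target_cc(scored)$mean_cc, -1)
  scored$p <- 0.5
  expect_equal(per_target_cc(scored)$mean_cc, 0)
})

test_that("evaluate_selection reports per-metric summaries and strata", {
  scored <- dplyr::bind_rows(lapply(1:4, function(t) {
    tibble::tibble(target_id = paste0("t", t), model_id = paste0("m", 1:4),
                   tm = c(0.8, 0.5, 0.3, 0.1),
                   z = c(0.1, 0.2, 1.5, -1),     # z picks the 0.3 model
                   p = c(0.9, 0.6, 0.2, 0.1),    # p picks the 0.8 model
                   z_best = t)                   # strata 1..4
  }))
  ev <- evaluate_selection(scored, metrics = c("z", "p"), strata = c(3, 5))
  all_rows <- ev[ev$stratum == "all", ]
  expect_equal(all_rows$top1_pct[all_rows$metric == "z"], 0)
  expect_equal(all_rows$top1_pct[all_rows$metric == "p"], 100)
  expect_equal(all_rows$avg_rank[all_rows$metric == "p"], 1)
  expect_equal(ev$n_targets[ev$stratum == "z_best<3" & ev$metric == "z"], 2)
  # tidy/glance style accessors stay consistent
  td <- tidy(ev)
  expect_true(all(c("metric", "statistic", "value") %in% names(td)))
})
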