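# Z-score, SVR training/prediction, M-score, ranking, cost function,
# serialization.

make_training_table <- function() {
  cached("training_table", function() {
    fs <- make_fixture_set(4, decoys_per_target = 25, seed = 301)
    dplyr::bind_rows(lapply(fs, function(t)
      dplyr::mutate(extract_features(t$models, t$profile), tm = t$tm)))
  })
}

test_that("z_score standardizes with population sd and handles degeneracy", {
  expect_equal(z_score(c(10, 8, 6)), c(1.2247, 0, -1.2247), tolerance = 1e-4)
  expect_equal(z_score(c(3, 3, 3, 3)), rep(0, 4))
  expect_error(z_score(5), "at least 2")
  for (seed in 1:10) {
    set.seed(seed)
    s <- rnorm(30)
    expect_equal(mean(z_score(s)), 0)
    # invariance under positive affine transformation
    expect_equal(z_score(2.5 * s + 7), z_score(s))
  }
})

test_that("weighted SVR fits synthetic decoys and obeys the weight rule", {
  tr <- make_training_table()
  sc <- train_scorer(tr, tr$tm)
  expect_s3_class(sc, "meftop_scorer")
  r <- cor(p_score(sc, tr), tr$tm)
  expect_gt(r, 0.7)
  # replication realizes TM-proportional weights exactly at one decimal
  expect_equal(max(1L, as.integer(round(10 * 0.8))) /
                 max(1L, as.integer(round(10 * 0.4))), 2)
  # degenerate inputs rejected
  expect_error(train_scorer(tr[1:10, ], tr$tm[1:10]), "at least 20")
  expect_error(train_scorer(tr, rep(0.5, nrow(tr))), "degenerate")
})

test_that("p_score is deterministic, clipped, and matches the libsvm path", {
  tr <- make_training_table()
  sc <- train_scorer(tr, tr$tm)
  p1 <- p_score(sc, tr)
  p2 <- p_score(sc, tr)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # dual route: own kernel expansion vs e1071's predict on the same fit
  x <- as.matrix(as.data.frame(tr)[, feature_names()])
  xs <- sweep(sweep(x, 2, sc$scale_min), 2, sc$scale_span, `/`)
  reps <- pmax(1L, as.integer(round(10 * tr$tm)))
  idx <- rep(seq_len(nrow(xs)), times = reps)
  refit <- e1071::svm(x = xs[idx, , drop = FALSE], y = tr$tm[idx],
                      type = "eps-regression", kernel = "radial",
                      cost = sc$cost, gamma = sc$gamma, epsilon = sc$epsilon,
                      scale = FALSE)
  expect_equal(p_score(sc, tr, clip = FALSE),
               unname(predict(refit, xs)), tolerance = 1e-8)
})

test_that("scorer serialization round-trips bit-identically", {
  tr <- make_training_table()
  sc <- train_scorer(tr, tr$tm)
  path <- withr::local_tempfile(fileext = ".json")
  write_scorer(sc, path)
  sc2 <- read_scorer(path)
  expect_identical(p_score(sc, tr), p_score(sc2, tr))
})

test_that("m_score is the committed linear combination", {
  expect_equal(m_score(1.3, 0.7, 0), 1.3)
  expect_equal(m_score(0, 0.7, 1), 0.7)
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(m_score(0.5, p, 2)) > 0))
  expect_error(m_score(1, 0.5, -1))
})

test_that("rank_models sorts by metric with stable id tie-break", {
  tr <- make_training_table()
  one <- dplyr::filter(tr, .data$target_id == tr$target_id[1])
  sc <- train_scorer(tr, tr$tm)
  raw <- seq(nrow(one), 1)   # descending raw scores
  rk <- rank_models(one, scorer = sc, raw_scores = raw, metric = "z")
  expect_equal(rk$model_id[1], one$model_id[1])
  expect_equal(sort(rk$model_id), sort(one$model_id))   # permutation
  # m with weight 0 reproduces z ordering
  sc0 <- sc; sc0$mscore_weight <- 0
  rm0 <- rank_models(one, scorer = sc0, raw_scores = raw, metric = "m")
  expect_equal(rm0$model_id, rk$model_id)
  # constant metric: ordering falls back to model_id
  rc <- rank_models(one, scorer = sc, raw_scores = rep(1, nrow(one)),
                    metric = "z")
  expect_equal(rc$model_id, sort(one$model_id))
  expect_error(rank_models(one, scorer = sc, metric = "z"), "raw_scores")
})

test_that("cost_f composes rank, Z_svm and missed terms linearly", {
  expect_equal(cost_f(rep(1, 5), rep(2, 5), n = 1.5), 1 - 1.5 * 2)
  base <- cost_f(c(1, 2, 1), c(1, 1, 1))
  worse <- cost_f(c(1, 2, 2), c(1, 1, 1))
  expect_equal(worse - base, (1 / 3) + 1)   # rank term + one more missed
  expect_equal(cost_f(c(1, 1), c(0, 0), lambda = 3) -
                 cost_f(c(1, 2), c(0, 0), lambda = 3), -0.5 - 3)
  expect_error(cost_f(numeric(0), numeric(0)), "empty")
})

test_that("tune_scorer picks the grid point minimizing the cost function", {
  tr <- make_training_table()
  val <- tr |>
    dplyr::group_by(.data$target_id) |>
    dplyr::slice(1:12) |>
    dplyr::ungroup()
  tuned <- tune_scorer(tr, tr$tm, val, cost_grid = c(1, 10),
                       gamma_grid = 1 / 37)
  expect_equal(nrow(tuned$grid), 2)
  expect_equal(tuned$best$cost_f, min(tuned$grid$cost_f))
  expect_s3_class(tuned$scorer, "meftop_scorer")
})

test_that("select_mscore_weight maximizes Top1% on validation pools", {
  # synthetic scored table where moderate n is needed: z picks wrong model,
  # p picks the right one
  scored <- dplyr::bind_rows(lapply(1:6, function(t) {
    tibble::tibble(target_id = paste0("t", t),
                   model_id = paste0("m", 1:5),
                   tm = c(0.9, 0.35, 0.3, 0.25, 0.2),
                   z = c(-1, 2, 0.5, 0, -1.5),
                   p = c(0.8, 0.3, 0.25, 0.2, 0.15))
  }))
  n <- select_mscore_weight(scored)
  m <- m_score(scored$z, scored$p, n)
  sel <- scored |>
    dplyr::mutate(m = m) |>
    dplyr::group_by(.data$target_id) |>
    dplyr::slice_max(m, n = 1) |>
    dplyr::ungroup()
  expect_true(all(sel$tm > 0.4))
})
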