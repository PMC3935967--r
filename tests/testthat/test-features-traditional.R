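# Composition, similarity transforms, contact profiles and f_res.

test_that("composition_1d counts state fractions and normalizes", {
  comp <- composition_1d(c(rep("H", 5), rep("E", 4), "C"),
                         c(rep("e", 10)))
  expect_equal(unname(comp[1:3]), c(0.5, 0.4, 0.1))
  expect_equal(unname(comp[4:5]), c(1, 0))
  for (seed in 1:10) {
    ss <- random_ss_string(30, seed)
    rsa <- sample(c("e", "b"), 30, replace = TRUE)
    cc <- composition_1d(ss, rsa)
    expect_equal(sum(cc[1:3]), 1)
    expect_equal(sum(cc[4:5]), 1)
  }
  expect_error(composition_1d(character(0), character(0)), "empty")
})

test_that("vector_similarities match closed forms and conventions", {
  u <- c(0.5, 0.4, 0.1)
  s_id <- vector_similarities(u, u)
  expect_equal(unname(s_id[c("cosine", "gaussian")]), c(1, 1))
  s_orth <- vector_similarities(c(1, 0), c(0, 1))
  expect_equal(unname(s_orth[c("cosine", "dot")]), c(0, 0))
  s <- vector_similarities(u, c(0.4, 0.5, 0.1), gamma = 1)
  expect_equal(unname(s["gaussian"]), exp(-0.02))
  # zero vector and constant vector conventions
  expect_equal(unname(vector_similarities(c(0, 0), c(1, 2))["cosine"]), 0)
  expect_equal(unname(vector_similarities(c(1, 1), c(1, 2))["correlation"]), 0)
})

test_that("contact profiles match definitions and the brute-force oracle", {
  # single contact 10 positions away
  m <- matrix(0, 12, 12); m[1, 11] <- m[11, 1] <- 1
  p <- contact_profiles(m)
  expect_equal(p$order[1], 10)
  expect_equal(p$number[1], 1)
  expect_equal(p$order[2], 0)   # no contacts: order 0 by convention
  expect_equal(p$number, rowSums(m))
  for (seed in 1:25) {
    mod <- random_ca_model(25, seed)
    cm <- contact_map(mod, 8)
    expect_equal(contact_profiles(cm), oracle_contact_profiles(cm))
    # probability-valued maps too
    set.seed(seed)
    pm <- matrix(runif(25 * 25), 25, 25); pm <- (pm + t(pm)) / 2
    pm[abs(outer(1:25, 1:25, `-`)) < 6] <- 0
    expect_equal(contact_profiles(pm), oracle_contact_profiles(pm))
  }
})

test_that("f_res matches analytic cases and the pair-count oracle", {
  # binary C identical to N
  m <- random_ca_model(20, 1)
  nm <- contact_map(m, 8)
  expect_equal(f_res(nm, nm), 1)
  # C = 0.5 everywhere (eligible band) gives 0.5 regardless of N
  n <- 20
  half <- matrix(0.5, n, n); half[abs(outer(1:n, 1:n, `-`)) < 6] <- 0
  expect_equal(f_res(half, nm), 0.5)
  # 10-residue toy: C_1,7 = 0.8, model contact only at (1,7); 10 eligible
  # pairs at separation >= 6 give (0.8 + 9) / 10
  cm <- matrix(0, 10, 10); cm[1, 7] <- cm[7, 1] <- 0.8
  nn <- matrix(0L, 10, 10); nn[1, 7] <- nn[7, 1] <- 1L
  expect_equal(f_res(cm, nn), oracle_f_res(cm, nn))
  expect_equal(f_res(cm, nn), 0.98)
  # too short for any eligible pair
  expect_warning(v <- f_res(matrix(0, 4, 4), matrix(0L, 4, 4)), "f_res")
  expect_equal(v, 0)
  for (seed in 1:20) {
    mod <- random_ca_model(22, seed + 100)
    nm <- contact_map(mod, 12)
    set.seed(seed)
    cp <- matrix(runif(22 * 22), 22, 22); cp <- (cp + t(cp)) / 2
    cp[abs(outer(1:22, 1:22, `-`)) < 6] <- 0
    expect_equal(f_res(cp, nm), oracle_f_res(cp, nm))
  }
})

test_that("f_res degrades monotonically as model contacts are toggled away", {
  nat <- tiny_native()
  nm <- contact_map(nat, 8)
  n <- nrow(nm)
  elig <- which(upper.tri(nm) & abs(outer(1:n, 1:n, `-`)) >= 6)
  set.seed(11)
  vals <- sapply(c(0, 0.1, 0.3, 0.6, 0.9), function(rate) {
    per <- nm
    flip <- sample(elig, round(rate * length(elig)))
    per[flip] <- 1 - per[flip]
    per[lower.tri(per)] <- t(per)[lower.tri(per)]
    f_res(nm, per)
  })
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1)
})

test_that("the traditional block emits 14 + 10 bounded features", {
  prof <- tiny_profile()
  nat <- tiny_native()
  f1 <- meftop:::features_1d(prof, nat)
  f2 <- meftop:::features_2d(prof, nat)
  expect_length(f1, 14)
  expect_length(f2, 10)
  sim_like <- c(f1[c("comp_cosine", "comp_correlation", "comp_gaussian")],
                f2[!grepl("f_res", names(f2))])
  expect_true(all(sim_like >= -1 - 1e-9 & sim_like <= 1 + 1e-9))
  expect_true(all(f2[c("f_res_8", "f_res_12")] >= 0 &
                    f2[c("f_res_8", "f_res_12")] <= 1))
})
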