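# SSE segmentation, correspondence, contact strengths, and the 6 SSE features.

test_that("identify_sses applies the minimum-run rule and maximality", {
  sses <- identify_sses(strsplit("CCHHHHHCCEEEECC", "")[[1]])
  expect_equal(sses$kind, c("H", "E"))
  expect_equal(sses$start, c(3, 10))
  expect_equal(sses$end, c(7, 13))
  expect_equal(nrow(identify_sses(strsplit("HHHC", "")[[1]])), 0)
  sses2 <- identify_sses(strsplit("HHHHEEEE", "")[[1]])
  expect_equal(sses2$start, c(1, 5))
  expect_equal(sses2$end, c(4, 8))
  for (seed in 1:40) {
    ss <- random_ss_string(40, seed)
    got <- as.data.frame(identify_sses(ss))
    want <- oracle_sses(ss)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("correspond_sses matches by start difference with stated tie-break", {
  a <- identify_sses(strsplit("CCHHHHHCCEEEECC", "")[[1]])
  expect_equal(correspond_sses(a, a),
               tibble::tibble(model = 1:2, target = 1:2))
  model <- tibble::tibble(kind = "H", start = 3, end = 7, length = 5)
  target <- tibble::tibble(kind = c("H", "E"), start = c(4, 20),
                           end = c(8, 24), length = c(5, 5))
  expect_equal(correspond_sses(model, target),
               tibble::tibble(model = 1L, target = 1L))
  # tie: target SSEs starting at 8 and 12, model at 10 -> earlier wins
  m2 <- tibble::tibble(kind = "H", start = 10, end = 15, length = 6)
  t2 <- tibble::tibble(kind = c("H", "H"), start = c(8, 12), end = c(13, 17),
                       length = c(6, 6))
  expect_equal(correspond_sses(m2, t2)$target, 1L)
  expect_equal(nrow(correspond_sses(m2, t2[0, ])), 0)
})

test_that("sse_contact_strength counts model pairs and sums probabilities", {
  # two strands 4 residues each, separation >= 6, exactly 3 SCM pairs < 8.5
  scm <- rbind(cbind(0, 0, 3.3 * (0:3)),
               matrix(c(50, 50, 50), 3, 3, byrow = TRUE),   # spacer residues
               cbind(8.45, 0, c(0, 3.3, 6.6, 50)))
  m <- structure_model(rep("A", 11), ca = scm, scm = scm)
  sses <- tibble::tibble(kind = c("E", "E"), start = c(1, 8), end = c(4, 11),
                         length = c(4, 4))
  s <- sse_contact_strength(sses, model = m)
  # exactly the pairs (1,8),(2,9),(3,10) lie under 8.5 A at separation >= 6
  expect_equal(s[1, 2], 3)
  # sequence side: 4x4 pairs at probability 0.5 sum to 8
  cp <- matrix(0, 20, 20)
  cp[1:4, 11:14] <- 0.5; cp[11:14, 1:4] <- 0.5
  sses2 <- tibble::tibble(kind = c("E", "E"), start = c(1, 11), end = c(4, 14),
                          length = c(4, 4))
  expect_equal(sse_contact_strength(sses2, cprob = cp)[1, 2], 8)
  # separation band: pairs closer than 6 in sequence never count, even at
  # sub-Angstrom distance; here the only sep >= 6 pairs are 100 A away
  close_scm <- rbind(cbind(0.5 * (0:5), 0, 0), cbind(100 + 0.5 * (0:1), 0, 0))
  mc <- structure_model(rep("A", 8), ca = close_scm, scm = close_scm)
  ssc <- tibble::tibble(kind = c("E", "E"), start = c(1, 5), end = c(4, 8),
                        length = c(4, 4))
  expect_equal(sse_contact_strength(ssc, model = mc)[1, 2], 0)
})

test_that("f_sse agreement score covers identity, disjoint and plug-in cases", {
  s <- matrix(c(0, 2, 1, 0), 2, 2)
  expect_equal(f_sse(s, s), 1)
  z <- matrix(0, 2, 2)
  expect_equal(f_sse(z, s), 0)          # model contact-free vs target contacts
  expect_equal(f_sse(z, z), 1)          # both contact-free agree
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  b <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(f_sse(a, b), 0.5)        # 1 - |2-1|/max(2,1) per orientation
  expect_equal(f_sse(matrix(0, 0, 0), matrix(0, 0, 0)), 0)
})

test_that("sse pair distances: model minimum vs probability interpolation", {
  scm <- rbind(cbind(0, 0, 3.3 * (0:3)),
               matrix(60, 3, 3),
               cbind(4.8, 0, 3.3 * (0:3)))
  m <- structure_model(rep("A", 11), ca = scm, scm = scm)
  sses <- tibble::tibble(kind = c("E", "E"), start = c(1, 8), end = c(4, 11),
                         length = c(4, 4))
  expect_equal(sse_pair_distance(sses, model = m)[1, 2], 4.8)
  # sequence side: p = 1 -> ideal 3.8; p = 0 -> threshold 8
  cp1 <- matrix(0, 20, 20); cp1[1, 11] <- cp1[11, 1] <- 1
  sses2 <- tibble::tibble(kind = c("E", "E"), start = c(1, 11), end = c(4, 14),
                          length = c(4, 4))
  expect_equal(sse_pair_distance(sses2, cprob = cp1)[1, 2], 3.8)
  expect_equal(sse_pair_distance(sses2, cprob = matrix(0, 20, 20))[1, 2], 8)
})

test_that("distance similarity and length ratios follow their closed forms", {
  d <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(sse_distance_similarity(d, d), 1)
  d2 <- matrix(c(0, 9, 9, 0), 2, 2)
  expect_equal(sse_distance_similarity(d, d2), exp(-1))   # |dD| = sigma = 4
  d3 <- matrix(c(0, 1e5, 1e5, 0), 2, 2)
  expect_lt(sse_distance_similarity(d, d3), 1e-10)
  expect_equal(unname(sse_length_ratios(c(4, 8), c(4, 8))), c(1, 1))
  expect_equal(unname(sse_length_ratios(c(4, 8), c(8, 8))), c(0.75, 0.75))
  expect_equal(unname(sse_length_ratios(4, 16)), c(0.25, 0.25))
  expect_equal(unname(sse_length_ratios(numeric(0), numeric(0))), c(0, 0))
})

test_that("the SSE block emits 6 features, maximal on the zero-noise chain", {
  nat <- tiny_native()
  prof <- profile_from_structure(nat, seed = 1)   # zero noise
  fs <- meftop:::features_sse_group(prof, nat, model_threshold = 8)
  expect_length(fs, 6)
  exact <- c("f_sse", "sse_number_cosine", "sse_number_correlation",
             "sse_length_ratio_pooled", "sse_length_ratio_mean")
  expect_equal(unname(fs[exact]), rep(1, 5))
  expect_gt(fs["sse_distance_similarity"], 0.8)
})
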