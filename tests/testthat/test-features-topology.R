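# Gyration agreement, hydrophobic core, fragment potentials.

test_that("gyration features follow the power law and ratio conventions", {
  # L = 100 with defaults: R_pred = 2.2 * 100^0.38
  r_pred <- 2.2 * 100^0.38
  expect_equal(r_pred, 12.66, tolerance = 1e-3)
  # a model whose CA gyration equals R_pred maxes both features
  m <- structure_model(rep("A", 4),
                       ca = r_pred * rbind(c(1, 0, 0), c(-1, 0, 0),
                                           c(0, 1, 0), c(0, -1, 0)))
  expect_equal(unname(gyration_features(m, 100)), c(1, 1))
  # doubled radius halves the ratio
  m2 <- m; m2$ca <- 2 * m$ca
  expect_equal(unname(gyration_features(m2, 100)["rg_ratio"]), 0.5)
})

test_that("detect_hc clusters hydrophobic SCMs by single linkage", {
  # no hydrophobic residues
  none <- structure_model(rep("S", 5), ca = cbind(3.8 * (0:4), 0, 0))
  hc0 <- detect_hc(none)
  expect_equal(hc0$n_residues, 0L)
  expect_equal(hc0$radius, 0)
  # two clusters, sizes 5 and 3, far apart: the 5-cluster wins
  xyz <- rbind(cbind(3 * (0:4), 0, 0), cbind(30 + 3 * (0:2), 0, 0))
  m <- structure_model(rep("L", 8), ca = xyz, scm = xyz)
  m$ss <- rep("C", 8); m$rsa <- rep("e", 8)
  hc <- detect_hc(m)
  expect_equal(hc$n_residues, 5L)
  expect_equal(hc$members, 1:5)
  # one connected chain within linkage distance
  chain <- cbind(6 * (0:7), 0, 0)
  mc <- structure_model(rep("V", 8), ca = chain, scm = chain)
  mc$ss <- rep("C", 8)
  expect_equal(detect_hc(mc)$n_residues, 8L)
})

test_that("hc_features are min/max ratios with zero conventions", {
  prof <- tiny_profile()
  hc_empty <- list(members = integer(0), radius = 0, n_residues = 0L, n_sses = 0L)
  expect_equal(unname(hc_features(hc_empty, prof)), c(0, 0, 0))
  n_hyd <- sum(prof$sequence %in% meftop:::hydrophobic_set)
  exp_count <- 0.6 * n_hyd
  hc_half <- list(members = 1:5, radius = 2.2 * exp_count^0.38,
                  n_residues = exp_count / 2, n_sses = 0L)
  got <- hc_features(hc_half, prof, rho = 0.6, k_hc = 2.2)
  expect_equal(unname(got["hc_count_ratio"]), 0.5)
  expect_equal(unname(got["hc_radius_ratio"]), 1)
})

test_that("fragment potentials reward ideal geometry and punish distortion", {
  f <- meftop:::build_fragment("H", 12)
  m <- annotate_model(structure_model(rep("A", 12), ca = f$ca, n_xyz = f$n,
                                      c_xyz = f$c, o_xyz = f$o))
  fp <- fragment_potentials(m)
  expect_gt(fp["frag_span"], 0.95)
  expect_equal(unname(fp["frag_torsion"]), 1)
  # all-coil model: no qualifying window
  coil <- structure_model(rep("A", 10), ca = cbind(3.8 * (0:9), 0, 0))
  coil$ss <- rep("C", 10); coil$rsa <- rep("e", 10)
  expect_equal(unname(fragment_potentials(coil)), c(0, 0))
  expect_equal(unname(fragment_potentials(
    structure_model(rep("A", 4), ca = cbind(3.8 * (0:3), 0, 0)))), c(0, 0))
  # distorting one window lowers the span potential strictly
  md <- m
  md$ca[12, ] <- md$ca[12, ] + c(0, 0, 4)
  md$ss <- m$ss
  expect_lt(fragment_potentials(md)["frag_span"], fp["frag_span"])
})

test_that("the topology block emits 7 bounded rigid-motion-invariant features", {
  nat <- tiny_native()
  prof <- tiny_profile()
  ft <- meftop:::features_topology_group(prof, nat)
  expect_length(ft, 7)
  expect_true(all(ft >= 0 & ft <= 1))
  set.seed(13)
  rot <- meftop:::random_rotation()
  moved <- annotate_model(meftop:::transform_model(nat, rot, c(-6, 9, 2)))
  ft2 <- meftop:::features_topology_group(prof, moved)
  expect_equal(ft2, ft, tolerance = 1e-6)
})

test_that("topology features discriminate natives from heavy decoys", {
  nat <- helix_native()
  prof <- profile_from_structure(nat, seed = 2)
  dec <- make_decoys(nat, grades = 6, n = 20, seed = 21)
  ft_nat <- meftop:::features_topology_group(prof, nat)
  ft_dec <- sapply(dec$models, function(m)
    meftop:::features_topology_group(prof, m))
  # on average over 20 heavy decoys, each feature is no better than native
  expect_true(all(rowMeans(ft_dec) <= ft_nat + 1e-8))
})
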