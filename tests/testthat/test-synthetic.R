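test_that("OU gap relaxes monotonically to the mean when noiseless", {
  cfg <- synthetic_config(n_frames = 500, sigma_gap = 0, seed = 1,
                          k_cs1_cs2 = 0, k_cs2_cs1 = 0,
                          gap_mean_cs1 = 300)
  g <- simulate_gap(cfg)
  expect_equal(unique(g$state), "CS1")
  # starts on the mean when sigma = 0 and stays there
  expect_true(all(abs(g$gap_mev - 300) < 1e-9))

  # relaxation after a forced mean switch is monotone
  cfg2 <- synthetic_config(n_frames = 500, sigma_gap = 0, seed = 1,
                           forced_switch_time = 100,
                           gap_mean_cs1 = 300, gap_mean_cs2 = -267)
  g2 <- simulate_gap(cfg2)
  post <- g2$gap_mev[g2$time_fs >= 100]
  expect_true(all(diff(post) <= 0))
  expect_equal(post[length(post)], -267, tolerance = 0.05)
})

test_that("OU stationary variance matches sigma^2 within 5% over 1e5 steps", {
  cfg <- synthetic_config(n_frames = 1e5, seed = 2024, sigma_gap = 50,
                          tau_gap = 10, k_cs1_cs2 = 0, k_cs2_cs1 = 0)
  g <- simulate_gap(cfg)
  v <- var(g$gap_mev)
  expect_equal(v, 50^2, tolerance = 0.05)
})

test_that("gap simulation is seed-reproducible", {
  cfg <- synthetic_config(n_frames = 200, seed = 7)
  expect_identical(simulate_gap(cfg), simulate_gap(cfg))
  cfg2 <- synthetic_config(n_frames = 200, seed = 8)
  expect_false(identical(simulate_gap(cfg)$gap_mev,
                         simulate_gap(cfg2)$gap_mev))
})

test_that("two-state hole fractions follow the 2x2 ground eigenvector", {
  expect_equal(gap_to_hole_fractions(0, 40)$f124, 0.5)
  expect_equal(gap_to_hole_fractions(0, 0)$f124, 0.5)
  expect_equal(gap_to_hole_fractions(500, 1e-9)$f124, 1, tolerance = 1e-12)
  expect_equal(gap_to_hole_fractions(-500, 1e-9)$f124, 0, tolerance = 1e-12)
  # minority fraction 0.10 at |gap| = sqrt(2.56/0.36) * H = 2.666.. * H
  ratio <- sqrt(2.56 / 0.36)
  f <- gap_to_hole_fractions(ratio * 40, 40)
  expect_equal(f$f122, 0.10, tolerance = 1e-12)
  # shares always sum to 1 and stay in [0, 1]
  gaps <- seq(-500, 500, by = 37)
  fr <- gap_to_hole_fractions(gaps, 25)
  expect_true(all(abs(fr$f124 + fr$f122 - 1) < 1e-12))
  expect_true(all(fr$f124 >= 0 & fr$f124 <= 1))
  expect_error(gap_to_hole_fractions(0, -1), "H_ab")
})

test_that("generated frames conserve the +1 hole across the indoles", {
  sys <- generate_charge_series(synthetic_config(n_frames = 2000, seed = 3))
  ic <- indole_charges(sys$series)
  expect_true(all(abs(ic$q124 + ic$q122 - 1) < 1e-9))
  # dmp carries its configured share of the reduced sensitizer
  dmp <- dplyr::filter(sys$series, fragment == "dmp")
  expect_true(all(abs(dmp$charge_e + 0.45) < 1e-9))
})

test_that("back-ET runs decay the hole total instead of conserving it", {
  cfg <- synthetic_config(n_frames = 1500, seed = 9, back_et_time = 500,
                          back_et_tau = 200, k_cs1_cs2 = 0, k_cs2_cs1 = 0)
  out <- generate_charge_series(cfg)
  ic <- indole_charges(out$series)
  tot <- ic$q124 + ic$q122
  expect_true(all(abs(tot[ic$time_fs < 500] - 1) < 1e-9))
  expect_equal(tot[ic$time_fs == 1000], exp(-500 / 200), tolerance = 1e-9)
  expect_true(any(out$truth$state == "BACK_ET"))
})

test_that("frozen conformer rates pin the rotamer label", {
  sys <- generate_system(synthetic_config(n_frames = 50, n_waters = 4,
                                          seed = 4, k_in_out = 0,
                                          start_conformer = "in"))
  expect_true(all(sys$truth$conformer == "in"))
})

test_that("a single forced mean switch yields exactly one recorded onset", {
  cfg <- synthetic_config(n_frames = 2000, seed = 12,
                          forced_switch_time = 900, sigma_gap = 0)
  out <- generate_charge_series(cfg)
  expect_equal(length(out$truth$onset_fs), 1)
  expect_gt(out$truth$onset_fs, 900)
})

test_that("identical configs give identical systems; bias 0 keeps solvation symmetric", {
  cfg <- synthetic_config(n_frames = 60, n_waters = 30, seed = 21,
                          water_bias_strength = 0,
                          k_cs1_cs2 = 0, k_cs2_cs1 = 0)
  s1 <- generate_system(cfg)
  s2 <- generate_system(cfg)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)

  # with no bias, mean coordination numbers of the two indoles agree
  # within sampling error (wide cutoff, symmetric box)
  cn124 <- coordination_number(s1$trajectory, s1$topology, "W124",
                               residues = c("W124", "W122"), r_cut = 8)
  cn122 <- coordination_number(s1$trajectory, s1$topology, "W122",
                               residues = c("W124", "W122"), r_cut = 8)
  expect_equal(cn124, cn122, tolerance = 0.5)
})

test_that("water bias pulls solvation toward the cationic indole", {
  base <- list(n_frames = 150, n_waters = 40, seed = 33,
               k_cs1_cs2 = 0, k_cs2_cs1 = 0, start_state = "CS1")
  biased <- generate_system(do.call(synthetic_config,
                                    c(base, water_bias_strength = 2)))
  plain <- generate_system(do.call(synthetic_config,
                                   c(base, water_bias_strength = 0)))
  late <- 100:150
  cn_b <- coordination_number(biased$trajectory, biased$topology, "W124",
                              residues = c("W124", "W122"), r_cut = 4.5,
                              frames = late)
  cn_p <- coordination_number(plain$trajectory, plain$topology, "W124",
                              residues = c("W124", "W122"), r_cut = 4.5,
                              frames = late)
  expect_gt(cn_b, cn_p)
})

test_that("ensemble generation labels every trajectory with its truth", {
  ens <- generate_trajectory_ensemble(
    n_reactive = 2, n_unreactive = 2, n_back_et = 1,
    config = synthetic_config(n_frames = 1200, seed = 5))
  expect_length(ens, 5)
  expect_equal(vapply(ens, `[[`, "", "true_verdict"),
               c("reactive", "reactive", "unreactive", "unreactive",
                 "back_ET"))
  # reactive members hold a true onset; unreactive none
  expect_true(all(vapply(ens[1:2],
                         function(e) length(e$truth$onset_fs) > 0,
                         logical(1))))
  expect_true(all(vapply(ens[3:4],
                         function(e) length(e$truth$onset_fs) == 0,
                         logical(1))))
})

test_that("written system files round trip through the readers", {
  dir <- withr::local_tempdir()
  sys <- generate_system(synthetic_config(n_frames = 5, n_waters = 6,
                                          seed = 77))
  paths <- write_system(sys, dir)
  topo <- read_topology(paths$pdb, paths$config)
  expect_equal(topo$atoms$fragment, sys$topology$atoms$fragment)
  tr <- read_xyz_trajectory(paths$xyz, topo)
  expect_equal(n_frames(tr), 5)
  ser <- read_fragment_series(paths$series)
  expect_equal(indole_charges(ser)$q124, indole_charges(sys$series)$q124,
               tolerance = 1e-9)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$lag_fs, sys$truth$lag_fs)
})
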