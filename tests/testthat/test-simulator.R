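test_that("ground-truth generator hits the configured counts exactly", {
  tbl <- simulate_ground_truth(ground_truth_config(seed = 3))
  expect_equal(nrow(tbl), 2000L)                     # 10 x 100 + 50% background
  expect_equal(sum(tbl$true_label == 0), 1000L)
  expect_equal(sum(tbl$true_label > 0), 1000L)
  expect_equal(tabulate(tbl$true_label, 10), rep(100L, 10))
  # background density: 1000 localizations on a 9 um^2 field
  expect_equal(sum(tbl$true_label == 0) / 9, 111.1, tolerance = 1e-3)
  expect_true(all(tbl$sd_nm > 0))

  none <- simulate_ground_truth(ground_truth_config(
    background_fraction = 0, n_clusters = 2, locs_per_cluster = 10, seed = 1))
  expect_true(all(none$true_label > 0))
})

test_that("ground-truth generator is deterministic under a fixed seed", {
  a <- simulate_ground_truth(ground_truth_config(seed = 99))
  b <- simulate_ground_truth(ground_truth_config(seed = 99))
  expect_identical(a, b)
})

test_that("clustered offsets have the configured spread", {
  # without localization error the offsets are exactly N(0, cluster_sd^2)
  cfg <- ground_truth_config(n_clusters = 1, locs_per_cluster = 10000,
                             background_fraction = 0, min_center_sep_nm = 0,
                             apply_precision_error = FALSE, seed = 5)
  tbl <- simulate_ground_truth(cfg)
  off <- c(tbl$x_nm - mean(tbl$x_nm), tbl$y_nm - mean(tbl$y_nm))
  expect_equal(sd(off), 50, tolerance = 0.02)

  # with the error applied, the variance grows by E[sd^2] of the gamma law
  cfg2 <- ground_truth_config(n_clusters = 1, locs_per_cluster = 10000,
                              background_fraction = 0, min_center_sep_nm = 0,
                              seed = 5)
  tbl2 <- simulate_ground_truth(cfg2)
  off2 <- c(tbl2$x_nm - mean(tbl2$x_nm), tbl2$y_nm - mean(tbl2$y_nm))
  expected_var <- 50^2 + (5 / 0.166667^2 + (5 / 0.166667)^2) / 1  # var+mean^2
  expect_equal(sd(off2), sqrt(expected_var), tolerance = 0.03)
})

test_that("cluster center placement respects separation, margin and overlap", {
  set.seed(8)
  ctr <- smlmclust:::place_centers(25, roi(3000, 3000), min_sep = 300)
  expect_gte(min(dist(ctr)), 300)

  ctr2 <- smlmclust:::place_centers(40, roi(4000, 4000), min_sep = 0,
                                    margin = 500, disc_d = 50)
  expect_gte(min(dist(ctr2)), 50)                    # discs do not overlap
  expect_true(all(ctr2 >= 500 & ctr2 <= 3500))       # margin from every border

  expect_error(
    smlmclust:::place_centers(50, roi(1000, 1000), min_sep = 500,
                              max_attempts = 2000),
    "attempts")
})

test_that("blinking emulation matches the two-state chain statistics", {
  cfg <- blink_config(n_clusters = 2, cluster_diameter_nm = 50,
                      molecules_per_cluster_mean = 150,
                      background_molecule_density_um2 = 0,
                      roi = roi(2000, 2000), min_cluster_margin_nm = 200,
                      n_frames = 5000, seed = 21)
  tbl <- simulate_blinking(cfg)
  n_mol_detected <- length(unique(tbl$molecule_id))
  expect_true(all(tbl$frame >= 1 & tbl$frame <= 5000))

  # discrete-chain stationary on fraction (the analytic oracle)
  a <- 1 - exp(-cfg$k_on * cfg$exposure_s)
  b <- 1 - exp(-cfg$k_off * cfg$exposure_s)
  pi_on <- a / (a + b)
  n_mol <- 300  # expected molecules simulated (Poisson mean 2 x 150)
  expected_locs <- n_mol * cfg$n_frames * pi_on
  expect_equal(nrow(tbl), expected_locs, tolerance = 0.2)

  # independent per-frame Bernoulli-chain Monte Carlo at small scale
  set.seed(1)
  mc <- replicate(300, {
    on <- runif(1) < pi_on
    tot <- 0L
    for (f in 1:500) {
      tot <- tot + on
      on <- if (on) runif(1) > b else runif(1) < a
    }
    tot
  })
  cfg_short <- blink_config(n_clusters = 2, molecules_per_cluster_mean = 150,
                            background_molecule_density_um2 = 0,
                            roi = roi(2000, 2000), min_cluster_margin_nm = 200,
                            n_frames = 500, seed = 22)
  tbl_short <- simulate_blinking(cfg_short)
  expect_equal(nrow(tbl_short) / 300, mean(mc), tolerance = 0.35)

  # k_on = 0: the stationary initial state is off, so nothing is emitted
  dark <- simulate_blinking(blink_config(
    n_clusters = 2, molecules_per_cluster_mean = 20, k_on = 0,
    background_molecule_density_um2 = 0, roi = roi(2000, 2000),
    min_cluster_margin_nm = 200, n_frames = 100, seed = 4))
  expect_equal(nrow(dark), 0L)
})

test_that("blinking molecules respect cluster geometry", {
  cfg <- blink_config(n_clusters = 8, cluster_diameter_nm = 50,
                      molecules_per_cluster_mean = 30, k_on = 1, k_off = 1,
                      background_molecule_density_um2 = 0,
                      roi = roi(3000, 3000), min_cluster_margin_nm = 500,
                      n_frames = 10, seed = 13)
  tbl <- simulate_blinking(cfg)
  # cluster molecules sit within margin - radius - 3*precision of the border
  slack <- 500 - 25 - 3 * max(tbl$sd_nm)
  expect_true(all(tbl$x_nm > slack & tbl$x_nm < 3000 - slack))
  expect_true(all(tbl$y_nm > slack & tbl$y_nm < 3000 - slack))
  expect_true(all(tbl$true_label > 0))
})

test_that("grouping follows the chaining rule, hand-traced", {
  # three co-located detections at frames 1, 2, 4 with dT = 1:
  # frames 1-2 chain, frame 4 stands alone
  tbl <- localization_table(c(100, 105, 102), c(100, 96, 101),
                            c(10, 20, 10), frame = c(1L, 2L, 4L))
  g <- group_localizations(tbl, dT = 1, dX_nm = 96)
  expect_equal(nrow(g), 2L)
  expect_equal(g$frame, c(1L, 4L))
  # precision-weighted mean and combined precision of the 1-2 chain
  w <- c(1 / 100, 1 / 400)
  expect_equal(g$x_nm[1], sum(w * c(100, 105)) / sum(w))
  expect_equal(g$sd_nm[1], 1 / sqrt(sum(w)))

  # a single localization passes through unchanged
  one <- localization_table(5, 5, 3, frame = 10L)
  expect_equal(group_localizations(one, 1, 96)$x_nm, 5)

  # same-frame localizations never merge, whatever the distance
  same <- localization_table(c(0, 0), c(0, 0), c(5, 5), frame = c(3L, 3L))
  expect_equal(nrow(group_localizations(same, 5, 1e6)), 2L)

  # missing frame column is a usage error
  expect_error(group_localizations(toy_table(1:3, 1:3), 1, 96), "frame")
})

test_that("grouping is idempotent and never increases the row count", {
  # idempotence is the designed regime: localization error well below dX,
  # so a chain's merged position cannot drift into another chain's catchment
  cfg <- blink_config(n_clusters = 4, molecules_per_cluster_mean = 25,
                      background_molecule_density_um2 = 50, k_on = 0.002,
                      roi = roi(3000, 3000), min_cluster_margin_nm = 300,
                      precision_shape = 5, precision_rate = 1,  # ~5 nm error
                      n_frames = 3000, seed = 78)
  tbl <- simulate_blinking(cfg)
  g1 <- group_localizations(tbl, dT = 1, dX_nm = 96)
  expect_lte(nrow(g1), nrow(tbl))
  g2 <- group_localizations(g1, dT = 1, dX_nm = 96)
  expect_equal(g2, g1)
})
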