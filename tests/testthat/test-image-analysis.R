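test_that("pattern width is the mean horizontal-scan width", {
  mk <- function(w, nr = 40, nc = 30, jitter = 0) {
    m <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) {
      wr <- w + jitter * (r %% 2 * 2 - 1)
      c0 <- floor((nc - wr) / 2) + 1
      m[r, c0:(c0 + wr - 1)] <- TRUE
    }
    m
  }
  expect_equal(measure_pattern_width(mk(13), 1), 13)
  expect_equal(measure_pattern_width(mk(3), 1), 3)   # narrowest pattern used
  # alternating +/-1 px edge jitter averages out
  expect_lt(abs(measure_pattern_width(mk(13, jitter = 1), 1) - 13), 0.5)
  expect_equal(measure_pattern_width(mk(13), 0.5), 6.5)
  expect_error(measure_pattern_width(matrix(FALSE, 5, 5)), "empty")
})

test_that("patterned cell length is the extent along the line axis", {
  m <- matrix(FALSE, 60, 30)
  m[10:53, 9:21] <- TRUE   # 44 x 13 rectangle
  nuc <- matrix(FALSE, 60, 30); nuc[30:34, 13:17] <- TRUE
  res <- measure_cell_length(m, nuc, "patterned", 1)
  expect_false(res$rejected)
  expect_equal(res$length_um, 44)
  # translation along the line axis does not change the measurement
  m2 <- matrix(FALSE, 60, 30); m2[3:46, 9:21] <- TRUE
  expect_equal(measure_cell_length(m2, NULL, "patterned", 1)$length_um, 44)
  expect_error(measure_cell_length(matrix(FALSE, 5, 5), NULL, "patterned"),
               "empty")
})

test_that("non-patterned cell length is the Feret diameter", {
  disc <- make_disc_mask(60, 20)
  res <- measure_cell_length(disc, NULL, "nonpatterned", 1)
  expect_equal(res$length_um, 40, tolerance = 1 / 40)
  # rotation invariance: an ellipse-like bar measured at 0 and 45 degrees
  bar <- matrix(FALSE, 80, 80)
  bar[20:60, 38:42] <- TRUE
  d0 <- measure_cell_length(bar, NULL, "nonpatterned", 1)$length_um
  idx <- which(bar, arr.ind = TRUE)
  rot <- matrix(FALSE, 120, 120)
  ctr <- c(40, 40)
  ry <- round(60 + (idx[, 1] - ctr[1]) * cos(pi / 4) -
                (idx[, 2] - ctr[2]) * sin(pi / 4))
  rx <- round(60 + (idx[, 1] - ctr[1]) * sin(pi / 4) +
                (idx[, 2] - ctr[2]) * cos(pi / 4))
  rot[cbind(ry, rx)] <- TRUE
  d45 <- measure_cell_length(rot, NULL, "nonpatterned", 1)$length_um
  expect_lt(abs(d45 - d0), 1.5)
})

test_that("multinucleate cells are rejected with a reason", {
  m <- matrix(TRUE, 30, 30)
  nuc <- matrix(FALSE, 30, 30)
  nuc[5:8, 5:8] <- TRUE
  nuc[20:23, 20:23] <- TRUE
  res <- measure_cell_length(m, nuc, "patterned", 1)
  expect_true(res$rejected)
  expect_match(res$reason, "2 nucleus")
  expect_true(is.na(res$length_um))
})

test_that("axial filaments concentrate orientation mass in the axial bin", {
  img <- render_patterned_cell(44, 13, 0.5, 6, list(name = "point", angle = 0),
                               noise_sd = 4, seed = 3,
                               filament_length_frac = c(0.3, 0.7))
  od <- orientation_distribution(img$channel, img$cell_mask)
  expect_equal(sum(od$mass), 1, tolerance = 1e-9)
  expect_true(all(od$mass >= 0))
  expect_gte(od$mass[od$bin_centres == 0], 0.9)
  # a tilted point mass lands in its own bin; sharper optics (blur 0.5 px)
  # because stroke width sets the angular resolution of the line kernels
  m30 <- 0
  for (s in 1:4) {
    img2 <- render_patterned_cell(44, 30, 0.5, 6,
                                  list(name = "point", angle = 30),
                                  noise_sd = 2, seed = s,
                                  filament_length_frac = c(0.2, 0.4),
                                  blur_sigma = 0.5)
    od2 <- orientation_distribution(img2$channel, img2$cell_mask)
    m30 <- m30 + sum(od2$mass[abs(od2$bin_centres - 30) <= 5]) / 4
  }
  expect_gt(m30, 0.8)
})

test_that("a blank channel yields the empty-distribution flag", {
  img <- render_patterned_cell(44, 13, 1, 0, noise_sd = 0, seed = 1)
  od <- orientation_distribution(img$channel, img$cell_mask)
  expect_true(od$empty)
  expect_equal(sum(od$mass), 0)
})

test_that("von Mises filaments are recovered with matching circular variance", {
  # pooled over seeded images: per-image recovered variance is unbiased but
  # scatters, so the distribution-level check aggregates
  cvt_all <- cvr_all <- numeric(0)
  for (s in 1:8) {
    img <- render_patterned_cell(44, 30, 0.5, 15,
                                 list(name = "vonmises", mu = 0, kappa = 4),
                                 noise_sd = 4, seed = s,
                                 filament_length_frac = c(0.2, 0.35))
    od <- orientation_distribution(img$channel, img$cell_mask)
    fil <- img$ground_truth$filaments
    cvt_all <- c(cvt_all, circular_variance_axial(
      rep(fil$angle_deg, times = pmax(1, round(fil$length_um / 0.5)))))
    cvr_all <- c(cvr_all, circular_variance_axial(od$bin_centres, od$mass))
  }
  expect_equal(mean(cvr_all), mean(cvt_all), tolerance = 0.15)
})

test_that("uniform filament angles give a flat orientation distribution", {
  # pooled over seeds; sharp optics for the same resolution reason as the
  # tilted-angle check
  mass <- 0
  for (s in 1:10) {
    img <- render_patterned_cell(44, 30, 0.5, 12,
                                 list(name = "uniform", min = -90, max = 90),
                                 noise_sd = 4, seed = s,
                                 filament_length_frac = c(0.2, 0.35),
                                 blur_sigma = 0.5)
    od <- orientation_distribution(img$channel, img$cell_mask)
    mass <- mass + od$mass
  }
  mass <- mass / 10
  expect_lt(max(mass), 3 * mean(mass))
})

test_that("fate classification from track geometry matches ground truth", {
  rule <- mt_fate_rule()
  tr <- simulate_comet_tracks(44, 13, rule, 400,
                              list(name = "uniform", min = 0, max = 90),
                              seed = 23)
  res <- classify_contact_fates(tr, rule)
  # outside the ambiguous band the rule is deterministic: full agreement
  expect_equal(res$agreement, 1)
  ev <- res$events
  expect_equal(ev$measured_angle_deg, tr$events$angle_deg, tolerance = 1e-6)
  # ambiguous-band events are flagged, not scored
  expect_equal(res$n_ambiguous,
               sum(abs(tr$events$angle_deg) > 25 & abs(tr$events$angle_deg) < 32))
})

test_that("steep contacts survive moderate angle-measurement noise", {
  rule <- mt_fate_rule()
  tr <- simulate_comet_tracks(44, 13, rule, 2000,
                              list(name = "uniform", min = 45, max = 90),
                              seed = 29)
  set.seed(1)
  res <- classify_contact_fates(tr, rule, angle_noise_sd = 3)
  expect_gte(res$agreement, 0.99)
})

test_that("integrated intensity converts to filament counts", {
  img <- render_patterned_cell(60, 20, 1, 5, list(name = "point", angle = 0),
                               noise_sd = 0, seed = 4, force_blur = TRUE)
  cnt <- estimate_mt_count(img$channel, img$cell_mask,
                           img$ground_truth$intensity_unit,
                           mean(img$ground_truth$filaments$length_um))
  expect_equal(cnt$count, 5L)
  # a region with no filaments reports zero
  corner <- matrix(FALSE, nrow(img$channel), ncol(img$channel))
  corner[1:3, 1:3] <- TRUE
  empty <- estimate_mt_count(img$channel, corner, 100, 10)
  expect_equal(empty$count, 0L)
  expect_error(estimate_mt_count(img$channel, matrix(TRUE, 2, 2), 100, 10),
               "shape")
})

test_that("edge-band counting recovers the number of boundary filaments", {
  # filaments laid into the lateral 30% bands, as in edge-leading counts
  img <- render_patterned_cell(44, 13, 0.5, 0, noise_sd = 0, seed = 1)
  band <- edge_band_mask(img$cell_mask, 0.3)
  expect_true(all(which(band) %in% which(img$cell_mask)))
  # band must hug the lateral edges, leaving the centre clear
  cols <- which(colSums(img$cell_mask) > 0)
  centre_col <- round(mean(range(cols)))
  expect_false(any(band[, centre_col]))

  img2 <- render_patterned_cell(44, 13, 0.5, 11,
                                list(name = "point", angle = 0),
                                noise_sd = 2, seed = 9,
                                filament_length_frac = c(0.3, 0.6))
  cnt <- estimate_mt_count(img2$channel, img2$cell_mask,
                           img2$ground_truth$intensity_unit,
                           mean(img2$ground_truth$filaments$length_um) / 0.5)
  expect_lte(abs(cnt$count - 11L), 2L)
})
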