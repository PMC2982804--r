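test_that("a bare rectangular cell has exact ground-truth geometry", {
  img <- render_patterned_cell(44, 13, 1, 0, noise_sd = 0, seed = 1)
  rows <- which(rowSums(img$cell_mask) > 0)
  expect_equal(max(rows) - min(rows) + 1, 44)
  cols <- which(colSums(img$cell_mask) > 0)
  expect_equal(max(cols) - min(cols) + 1, 13)
  expect_equal(dim(img$channel), dim(img$cell_mask))
  expect_equal(dim(img$channel), dim(img$nucleus_mask))
  # the cell sits on the adhesive line
  expect_true(all(img$line_mask[img$cell_mask]))
  expect_equal(img$ground_truth$cell_length_um, 44)
  expect_equal(img$ground_truth$pattern_width_um, 13)
})

test_that("angle models produce the requested angular statistics", {
  set.seed(1)
  expect_equal(sample_angles(5, list(name = "point", angle = 12)),
               rep(12, 5))
  u <- sample_angles(2000, list(name = "uniform", min = 0, max = 90))
  expect_true(all(u >= 0 & u <= 90))
  expect_equal(mean(u), 45, tolerance = 0.1)
  v <- sample_angles(200, list(name = "vonmises", mu = 0, kappa = 4))
  expect_true(all(v >= -90 & v <= 90))
  # axial circular mean within 3 degrees of the requested axis
  circ_mean <- 0.5 * atan2(mean(sin(2 * v * pi / 180)),
                           mean(cos(2 * v * pi / 180))) * 180 / pi
  expect_lt(abs(circ_mean), 3)
  expect_error(sample_angles(5, list(name = "beta")), "unsupported")
})

test_that("rendered filaments honour the angle model and stay inside the cell", {
  img <- render_patterned_cell(60, 20, 1, 10, list(name = "point", angle = 0),
                               noise_sd = 0, seed = 3)
  fil <- img$ground_truth$filaments
  expect_equal(nrow(fil), 10)
  expect_true(all(fil$angle_deg == 0))
  rows <- range(which(rowSums(img$cell_mask) > 0))
  cols <- range(which(colSums(img$cell_mask) > 0))
  expect_true(all(fil$row0 >= rows[1] & fil$row1 <= rows[2] + 1))
  expect_true(all(pmin(fil$col0, fil$col1) >= cols[1] - 0.5 &
                    pmax(fil$col0, fil$col1) <= cols[2] + 0.5))
  # total deposited intensity matches length x unit calibration
  expect_equal(sum(img$channel),
               sum(fil$length_um) * img$ground_truth$intensity_unit,
               tolerance = 0.02)
  # impossible placements error out after the retry cap
  expect_error(
    render_patterned_cell(10, 4, 1, 1, list(name = "point", angle = 90),
                          noise_sd = 0, seed = 1,
                          filament_length_frac = c(2, 2.1)),
    "place filament")
})

test_that("rasters and tracks are identical under identical seeds", {
  a <- render_patterned_cell(44, 13, 1, 8, list(name = "vonmises", kappa = 4),
                             noise_sd = 5, seed = 11)
  b <- render_patterned_cell(44, 13, 1, 8, list(name = "vonmises", kappa = 4),
                             noise_sd = 5, seed = 11)
  expect_identical(a$channel, b$channel)
  expect_identical(a$ground_truth$filaments, b$ground_truth$filaments)
  t1 <- simulate_comet_tracks(44, 13, mt_fate_rule(), 50,
                              list(name = "uniform", min = -90, max = 90),
                              seed = 4)
  t2 <- simulate_comet_tracks(44, 13, mt_fate_rule(), 50,
                              list(name = "uniform", min = -90, max = 90),
                              seed = 4)
  expect_identical(t1$events, t2$events)
})

test_that("the fate rule validates its thresholds and classifies by angle", {
  rule <- mt_fate_rule()
  expect_equal(rule$bend_max, 25)
  expect_equal(rule$cat_min, 32)
  expect_error(mt_fate_rule(bend_max = 40, cat_min = 32))
  expect_error(mt_fate_rule(cat_min = 95))
  expect_equal(mtlength:::apply_fate_rule(rule, c(10, -10, 60, -60, 28)),
               c("bend", "bend", "catastrophe", "catastrophe", "ambiguous"))
})

test_that("comet fates follow the angle rule and tracks end or bend accordingly", {
  rule <- mt_fate_rule()
  tr <- simulate_comet_tracks(44, 13, rule, 200,
                              list(name = "uniform", min = 0, max = 90),
                              seed = 8)
  ev <- tr$events
  expect_true(all(ev$fate[abs(ev$angle_deg) <= 25] == "bend"))
  expect_true(all(ev$fate[abs(ev$angle_deg) >= 32] == "catastrophe"))
  # catastrophes end their track at the contact point
  for (k in which(ev$fate == "catastrophe")[1:10]) {
    last <- tail(tr$tracks[[k]], 1)
    expect_equal(last$x_um, ev$x_um[k])
    expect_equal(last$y_um, ev$y_um[k])
  }
  # bends continue along the boundary direction (lateral position frozen)
  k <- which(ev$fate == "bend" & ev$boundary == "lateral")[1]
  tail3 <- tail(tr$tracks[[k]], 3)
  expect_true(all(abs(diff(tail3$x_um)) < 1e-9))
  expect_true(all(diff(tail3$y_um) > 0))

  # purely axial comets never trigger catastrophe
  tr0 <- simulate_comet_tracks(44, 13, rule, 100,
                               list(name = "point", angle = 0), seed = 2)
  expect_true(all(tr0$events$fate == "bend"))
})

test_that("uniform launch angles give the exact mixed catastrophe fraction", {
  # (90 - 32)/90 + 0.5 * (32 - 25)/90 = 0.6833
  tr <- simulate_comet_tracks(44, 13, mt_fate_rule(), 4000,
                              list(name = "uniform", min = 0, max = 90),
                              seed = 17)
  expect_equal(mean(tr$events$fate == "catastrophe"), 58 / 90 + 3.5 / 90,
               tolerance = 0.035)
})

test_that("synthetic images round-trip through disk with ground truth intact", {
  img <- render_patterned_cell(44, 13, 0.5, 6, list(name = "point", angle = 0),
                               noise_sd = 4, seed = 5)
  dir <- withr::local_tempdir()
  write_synthetic_image(img, dir, "cell")
  img2 <- read_synthetic_image(dir, "cell")
  expect_identical(img2$cell_mask, img$cell_mask)
  expect_identical(img2$line_mask, img$line_mask)
  expect_identical(img2$nucleus_mask, img$nucleus_mask)
  expect_lt(max(abs(img2$channel - img$channel)), 0.01)
  expect_equal(img2$pixel_size, 0.5)
  expect_equal(img2$ground_truth$filaments$angle_deg,
               img$ground_truth$filaments$angle_deg)
})
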