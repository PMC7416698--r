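# B-scan processing: downsampling, alignment, foveola, segmentation,
# thicknesses, extrema, sample extraction.

test_that("downsample_lrps averages non-overlapping blocks exactly", {
  # 8 A-scans, blocks of 2, hand-computed block means
  m <- matrix(rep(1:8, each = 3), nrow = 3)
  sc <- toy_bscan(m, lateral = seq(0, 15, length.out = 8))
  out <- downsample_lrps(sc, target_per_15deg = 4)
  expect_equal(ncol(out$reflectivity), 4)
  expect_equal(out$reflectivity[1, ], c(1.5, 3.5, 5.5, 7.5))

  # paper-scale contract: 4091 A-scans over 15 deg -> 512
  sc2 <- toy_bscan(matrix(0, 2, 4091), lateral = seq(0, 15, length.out = 4091))
  expect_equal(length(downsample_lrps(sc2, 512)$lateral_deg), 512)

  # constant scan unchanged; over-dense target rejected
  cc <- toy_bscan(matrix(3.7, 4, 16), lateral = seq(0, 15, length.out = 16))
  expect_true(all(downsample_lrps(cc, 8)$reflectivity == 3.7))
  expect_error(downsample_lrps(cc, 512), "exceeds")
})

test_that("align_to_brm straightens a tilted scan and is idempotent", {
  ret <- retina_mid()
  sc <- render_bscan(ret, lateral_extent = 3, n_ascans = 128, noise_sd = 0,
                     brm_tilt = 20)
  expect_false(sc$aligned)
  al <- align_to_brm(sc)
  expect_true(al$aligned)
  tr <- attr(al, "truth")
  expect_true(all(abs(tr[, "rpe2_brm"]) <= 2)) # BrM at depth 0 +/- 1 step

  al2 <- align_to_brm(al)
  expect_lt(max(abs(al2$reflectivity - al$reflectivity)), 1e-9)

  expect_error(align_to_brm(toy_bscan(matrix(0, 50, 8))), "flat")
})

test_that("locate_foveola finds the pit, honours overrides, flags monotone surfaces", {
  al <- align_to_brm(scan_clean())
  expect_lt(abs(locate_foveola(al)), 0.05) # true pit at 0

  sc3 <- render_bscan(retina_mid(), lateral_extent = 3, n_ascans = 256,
                      noise_sd = 0, pit_center = 0.3)
  expect_lt(abs(locate_foveola(align_to_brm(sc3)) - 0.3), 0.05)

  expect_equal(locate_foveola(al, override = -0.1), -0.1)

  # monotone surface: a single band whose depth rises linearly
  n <- 64
  m <- matrix(0, 100, n)
  for (j in 1:n) m[10 + j, j] <- 1
  mono <- toy_bscan(m, depth = seq(-20, by = 2, length.out = 100))
  mono$aligned <- TRUE
  expect_error(locate_foveola(mono), "override")
})

test_that("segmentation recovers all six boundaries within one axial step (noiseless)", {
  al <- align_to_brm(scan_clean())
  seg <- segment_layers(al)
  tr <- attr(al, "truth")
  err <- abs(seg$boundaries - tr[, colnames(seg$boundaries)])
  expect_lt(max(err, na.rm = TRUE), 2) # +/- 1 axial step (2 um)
  expect_equal(mean(seg$flags), 0)
})

test_that("missing EZ/COST bands are flagged, not misassigned", {
  amps <- band_amplitudes(ez = 0, cost = 0)
  sc <- render_bscan(retina_mid(), lateral_extent = 3, n_ascans = 128,
                     noise_sd = 0, amplitudes = amps)
  seg <- segment_layers(align_to_brm(sc))
  expect_true(all(seg$flags[, "ez"]))
  expect_true(all(seg$flags[, "cost"]))
  tr <- attr(sc, "truth")
  expect_lt(max(abs(seg$boundaries[, "elm"] - tr[, "elm"]), na.rm = TRUE), 2)
  expect_lt(max(abs(seg$boundaries[, "opl"] - tr[, "opl"]), na.rm = TRUE), 2)
  expect_lt(max(abs(seg$boundaries[, "rpe1"] - tr[, "rpe1"]), na.rm = TRUE), 2)
})

test_that("pure-noise scans are rejected as unsegmentable", {
  set.seed(9)
  noise <- matrix(rnorm(150 * 64, 0, 0.02), 150, 64)
  sc <- toy_bscan(abs(noise), depth = seq(-20, by = 2, length.out = 150))
  sc$aligned <- TRUE
  expect_error(segment_layers(sc), "unsegmentable")
})

test_that("boundary ordering invariant holds on unflagged A-scans", {
  set.seed(11)
  co <- generate_training_cohort(seed = 301)
  idx <- which(co$gt_cos_fovea > 12)[1:3]
  for (i in idx) {
    sc <- render_bscan(ground_truth_retina(co[i, ]), lateral_extent = 3,
                       n_ascans = 96, noise_sd = 0.02, seed = i)
    seg <- segment_layers(align_to_brm(sc))
    b <- seg$boundaries
    ok <- rowSums(seg$flags) == 0
    expect_true(any(ok))
    expect_true(all(b[ok, "opl"] > b[ok, "elm"]))
    expect_true(all(b[ok, "elm"] > b[ok, "ez"]))
    expect_true(all(b[ok, "ez"] > b[ok, "cost"]))
    expect_true(all(b[ok, "cost"] > b[ok, "rpe1"]))
    expect_true(all(b[ok, "rpe1"] > b[ok, "rpe2_brm"]))
  }
})

test_that("thicknesses follow the boundary-difference definitions with flag propagation", {
  b <- matrix(c(180, 80, 55, 30, 18, 0), nrow = 1,
              dimnames = list(NULL, c("opl", "elm", "ez", "cost", "rpe1",
                                      "rpe2_brm")))
  seg <- structure(list(boundaries = b,
                        flags = matrix(FALSE, 1, 6,
                                       dimnames = dimnames(b)),
                        lateral_deg = 0), class = "layer_segmentation")
  th <- thicknesses_from_segmentation(seg)
  expect_equal(unlist(th[1, c("onl", "is_len", "cos_len", "rpe")]),
               c(onl = 100, is_len = 25, cos_len = 25, rpe = 18))

  seg$flags[1, "ez"] <- TRUE
  th2 <- thicknesses_from_segmentation(seg)
  expect_true(is.na(th2$is_len) && is.na(th2$cos_len))
  expect_false(is.na(th2$onl) || is.na(th2$rpe))

  # negative thickness flags rather than clips
  seg$flags[1, "ez"] <- FALSE
  seg$boundaries[1, "ez"] <- 90 # above ELM
  th3 <- thicknesses_from_segmentation(seg)
  expect_true(is.na(th3$is_len))
})

test_that("count_extrema matches analytic band counts", {
  depth <- seq(0, 200, by = 1)
  flat <- rep(1, length(depth))
  expect_equal(count_extrema(flat, depth, elm_depth = 150,
                             min_prominence = 0.01), 0)

  one_band <- exp(-(depth - 80)^2 / (2 * 5^2))
  expect_equal(count_extrema(one_band, depth, elm_depth = 150,
                             min_prominence = 0.01), 2)

  four <- rowSums(sapply(c(30, 60, 90, 120),
                         function(c0) exp(-(depth - c0)^2 / (2 * 4^2))))
  expect_equal(count_extrema(four, depth, elm_depth = 150,
                             min_prominence = 0.01), 8)

  expect_error(count_extrema(flat, depth, elm_depth = 1,
                             min_prominence = 0.01), "3 samples")
  expect_error(count_extrema(flat, depth, elm_depth = -5, brm_depth = 0,
                             min_prominence = 0.01), "elm_depth")
})

test_that("extract_samples: exact grid, translation invariance, band peaks in refl vec", {
  al <- align_to_brm(scan_clean())
  fov <- locate_foveola(al)
  seg <- segment_layers(al)
  s <- extract_samples(al, seg, fov, scan_id = "t")
  expect_equal(s$eccentricity, seq(-0.75, 0.75, 0.25))
  expect_equal(nrow(s), 7)

  # laterally-flat world: all 7 samples identical
  row <- cohort29()[which(cohort29()$gt_cos_fovea > 12)[1], ]
  row$gt_onl_decline <- 0; row$gt_subret_decline <- 0; row$gt_rim_inner <- 0
  flat <- render_bscan(ground_truth_retina(row), lateral_extent = 3,
                       n_ascans = 128, noise_sd = 0)
  seg_f <- segment_layers(flat)
  sf <- extract_samples(flat, seg_f, 0, scan_id = "flat")
  num <- sf[setdiff(names(sf), c("scan_id", "eccentricity"))]
  expect_true(all(apply(num, 2, function(v) max(v) - min(v)) < 1e-6))

  # reflectivity vector peaks coincide with rendered band centres
  rv <- as.numeric(s[4, grep("^refl_", names(s))])
  depths <- seq(0, 240, by = 4)
  tr <- attr(al, "truth")
  j0 <- which.min(abs(al$lateral_deg - fov))
  for (bnd in c("ez", "elm", "opl")) {
    near <- which(abs(depths - tr[j0, bnd]) <= 6)
    expect_gt(max(rv[near]), max(rv) * 0.2) # a band, not baseline
  }

  expect_error(extract_samples(al, seg, foveola = 2), "outside")
})

test_that("pipeline is equivariant to a lateral shift of the scan", {
  ret <- retina_mid()
  a <- render_bscan(ret, lateral_extent = 3, n_ascans = 256, noise_sd = 0,
                    pit_center = 0)
  b <- render_bscan(ret, lateral_extent = 3, n_ascans = 256, noise_sd = 0,
                    pit_center = 0.25)
  fa <- locate_foveola(align_to_brm(a))
  fb <- locate_foveola(align_to_brm(b))
  expect_lt(abs((fb - fa) - 0.25), 0.03)
  sa <- extract_samples(a, segment_layers(a), fa)
  sb <- extract_samples(b, segment_layers(b), fb)
  expect_equal(sa$onl, sb$onl, tolerance = 0.05)
  expect_equal(sa$cos_len, sb$cos_len, tolerance = 0.05)
})
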