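test_that("band set spans the spectrometer range with 123 linear channels", {
  bs <- band_set()
  expect_length(bs, 123)
  expect_equal(unname(as.numeric(bs)[c(1, 123)]), c(397, 1086))
  expect_true(all(diff(as.numeric(bs)) > 0))
  # quoted wavelengths resolve to in-range channels
  idx <- nearest_channel(bs, c(428, 489, 781, 932, 954, 982, 988, 994))
  expect_true(all(idx >= 1 & idx <= 123))
  expect_true(all(abs(as.numeric(bs)[idx] -
                        c(428, 489, 781, 932, 954, 982, 988, 994)) <
                    diff(as.numeric(bs))[1] / 2 + 1e-9))
})

test_that("default garden config reproduces the study inventory", {
  cfg <- default_garden_config()
  counts <- vapply(cfg$templates, function(t) t$count, integer(1))
  expect_equal(sum(counts), 168L)
  named <- vapply(cfg$templates, function(t) t$name, character(1))
  expect_equal(length(unique(named[named != "unidentified"])), 23L)
  # pure function: identical on repeat call
  expect_identical(cfg, default_garden_config())
})

test_that("species template validates its invariants", {
  bs <- band_set()
  curve <- rep(0.5, 123)
  expect_error(species_template("x", "coniferous",
                                list(type = "cone", base_radius_frac = .2),
                                height_range = c(5, 3), point_density = 10,
                                reflectance_curve = curve))
  expect_error(species_template("x", "coniferous",
                                list(type = "cone", base_radius_frac = .2),
                                height_range = c(3, 5), point_density = 10,
                                reflectance_curve = rep(2, 123)))
  expect_error(species_template("x", "coniferous",
                                list(type = "blob"),
                                height_range = c(3, 5), point_density = 10,
                                reflectance_curve = curve))
})

test_that("cone and ellipsoid crown profiles have the analytic centroids", {
  # cone: height density 3(1-h)^2 on [0,1], mean 1/4
  tpl_cone <- species_template(
    "cone", "coniferous", list(type = "cone", base_radius_frac = 0.25),
    height_range = c(6, 6), point_density = 60, # fixed height
    reflectance_curve = rep(0.5, 123))
  set.seed(11)
  tr <- sample_tree(tpl_cone)
  big <- do.call(rbind, lapply(1:40, function(i) sample_tree(tpl_cone)$points))
  hN <- big$z / 6
  expect_gt(nrow(big), 10000)
  expect_lt(mean(hN), 0.5)
  expect_equal(mean(hN), 0.25, tolerance = 0.02)
  # ellipsoid crown centred at 0.7 with 90% of density in the crown and a
  # trunk below 0.4: mean 0.9*0.7 + 0.1*0.2 = 0.65
  tpl_ell <- species_template(
    "ell", "deciduous",
    list(type = "ellipsoid", center = 0.7, half_height = 0.3,
         radius_frac = 0.2, crown_fraction = 0.9),
    height_range = c(6, 6), point_density = 60,
    reflectance_curve = rep(0.5, 123))
  set.seed(12)
  big2 <- do.call(rbind, lapply(1:40, function(i) sample_tree(tpl_ell)$points))
  hN2 <- big2$z / 6
  expect_gt(mean(hN2), 0.5)
  expect_equal(mean(hN2), 0.65, tolerance = 0.02)
  # closed-form shape knob agrees with simulation
  expect_equal(crown_fraction_above(tpl_cone, 0.5), 0.125)
  expect_equal(mean(hN > 0.5), 0.125, tolerance = 0.02)
  expect_equal(mean(hN2 > 0.5), crown_fraction_above(tpl_ell, 0.5),
               tolerance = 0.02)
})

test_that("sample_tree is deterministic under a fixed seed and floors at 20 points", {
  tpl <- species_template(
    "tiny", "coniferous", list(type = "cone", base_radius_frac = 0.2),
    height_range = c(1, 1.2), point_density = 0.5,
    reflectance_curve = rep(0.3, 123))
  set.seed(5); a <- sample_tree(tpl)
  set.seed(5); b <- sample_tree(tpl)
  expect_identical(a, b)
  expect_gte(nrow(a$points), 20)
  expect_true(all(a$points$z >= 0))
})

test_that("deciduous templates put more density above mid-height than conifers", {
  cfg <- mini_config(k_con = 3, k_dec = 3, count = 1L)
  habit <- vapply(cfg$templates, function(t) t$habit, character(1))
  above <- vapply(cfg$templates, crown_fraction_above, numeric(1), h = 0.5)
  expect_gt(min(above[habit == "deciduous"]),
            max(above[habit == "coniferous"]) + 0.3)
  # and the empirical per-tree proportions separate accordingly
  sc <- generate_scene(mini_config(k_con = 2, k_dec = 2, count = 50L,
                                   simulate_frames = FALSE), seed = 3)
  pr <- vapply(sc$specimens, function(s) {
    hN <- normalized_heights(s$points$z)
    mean(hN > 0.5)
  }, numeric(1))
  hab <- vapply(sc$specimens, function(s) s$habit, character(1))
  expect_gt(mean(pr[hab == "deciduous"]) - mean(pr[hab == "coniferous"]),
            0.3)
})

test_that("generate_scene is deterministic and serializes byte-identically", {
  cfg <- mini_config(count = 3L)
  s1 <- generate_scene(cfg, seed = 42)
  s2 <- generate_scene(cfg, seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_points_csv(s1, f1); write_points_csv(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(lapply(s1$frames, `[[`, "dn"),
                   lapply(s2$frames, `[[`, "dn"))
  s3 <- generate_scene(cfg, seed = 43)
  expect_false(identical(s1$specimens, s3$specimens))
  unlink(c(f1, f2))
})

test_that("scene with zero species is empty, not an error", {
  cfg <- mini_config(count = 0L)
  sc <- generate_scene(cfg, seed = 1)
  expect_length(sc$specimens, 0)
  expect_length(sc$frames, 0)
  expect_identical(nrow(points_table(sc)), 0L)
})

test_that("specimen timestamps are non-decreasing and frames well-formed", {
  sc <- generate_scene(mini_config(count = 4L), seed = 9)
  for (s in sc$specimens) expect_true(all(diff(s$points$t) >= 0))
  fr <- sc$frames[[3]]
  expect_equal(nrow(fr$dn), 659)
  expect_equal(ncol(fr$dn), 123)
  expect_length(fr$reference_pixels, 10)
  expect_true(all(fr$dn >= 0))
  # reference pixels illuminated in every frame
  for (f in sc$frames) expect_gt(mean(f$dn[f$reference_pixels, ]), 0)
  expect_error(simulate_frames(sc$specimens, list(t = numeric(0)),
                               sc$band_set, sc$config$sensor,
                               sc$config$noise, sc$config$templates),
               "empty trajectory")
})

test_that("illumination noise is strong: single-pixel reflectance ratio exceeds 2", {
  # lognormal sdlog 0.25 over 1,000 draws: max/min ratio far above 2
  set.seed(21)
  draws <- rlnorm(1000, 0, 0.25)
  expect_gt(max(draws) / min(draws), 2)
  # and end-to-end: normalized single-pixel reflectances of one species in
  # one channel vary by over a factor of 2 across pixels/frames
  cfg <- mini_config(k_con = 1, k_dec = 0, count = 6L,
                     illumination_sdlog = 0.5, pixel_sdlog = 0.25,
                     shaded_reference_prob = 0)
  sc <- generate_scene(cfg, seed = 8)
  vals <- unlist(lapply(sc$frames, function(f) {
    nf <- normalize_frame(f)
    v <- nf$reflectance[, 60]
    v[v > 0]
  }))
  expect_gt(length(vals), 100)
  expect_gt(max(vals) / min(vals), 2)
})

test_that("tall near trees get truncated spectral coverage", {
  bs <- band_set()
  tall <- species_template(
    "tall", "coniferous", list(type = "cone", base_radius_frac = 0.2),
    height_range = c(12, 12), point_density = 15,
    reflectance_curve = rep(0.5, 123), spectral_sd = 0)
  cfg <- garden_config(list(tall), bs,
                       layout = list(spacing = 3, n_rows = 1, row_y = 4),
                       noise = list(illumination_sdlog = 0, pixel_sdlog = 0,
                                    shaded_reference_prob = 0,
                                    shade_factor = 0.3))
  # top subtends atan((12-2)/4) = 68 deg >> half FOV of 22.2 deg
  sc <- generate_scene(cfg, seed = 2)
  fc <- fuse(points_table(sc), sc$frames, bs)
  frac <- mean(fc[[1]]$points$n_pixels > 0)
  expect_lt(frac, 1)
  expect_gt(frac, 0)   # the lower crown is still covered
})

test_that("points and frames round-trip through their CSV formats", {
  sc <- generate_scene(mini_config(count = 2L), seed = 4)
  pf <- tempfile(fileext = ".csv")
  write_points_csv(sc, pf)
  pts <- read_points_csv(pf)
  expect_equal(pts, points_table(sc), tolerance = 1e-12)
  ff <- tempfile(fileext = ".csv")
  write_frames_csv(sc$frames[1:2], ff)
  back <- read_frames_csv(ff, sensor_height = sc$config$trajectory$sensor_height)
  expect_length(back, 2)
  expect_equal(unname(back[[1]]$dn), unname(sc$frames[[1]]$dn),
               tolerance = 1e-9)
  expect_equal(back[[1]]$reference_pixels, sc$frames[[1]]$reference_pixels)
  mf <- tempfile(fileext = ".json")
  scene_manifest(sc, mf)
  man <- jsonlite::fromJSON(mf)
  expect_equal(man$seed, 4)
  expect_equal(man$n_specimens, length(sc$specimens))
  unlink(c(pf, ff, mf))
})
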