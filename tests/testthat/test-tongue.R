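test_that("filiform number density is the stated quotient", {
  expect_equal(filiform_number_density(0.3, 0.18, 0.36), 0.3 / (0.18 * 0.36))
  expect_equal(filiform_number_density(0.3, 0.18, 0.72),
               filiform_number_density(0.3, 0.18, 0.36) / 2)
  expect_lt(filiform_number_density(1e-9, 0.18, 0.36), 1e-7)
  expect_error(filiform_number_density(0, 0.18, 0.36), "domain")
  expect_error(filiform_number_density(0.3, -1, 0.36), "domain")
})

test_that("place_papillae honors the minimum distance and the seed", {
  f <- place_papillae(c(filiform = 50), c(10, 10), 0.5, seed = 1)
  expect_identical(nrow(f$papillae), 50L)
  xy <- as.matrix(f$papillae[, c("x", "y")])
  expect_gte(min(brute_nn(xy)), 0.5)
  expect_true(all(xy >= 0 & xy <= 10))

  f2 <- place_papillae(c(filiform = 50), c(10, 10), 0.5, seed = 1)
  expect_identical(f$papillae, f2$papillae)
  f3 <- place_papillae(c(filiform = 50), c(10, 10), 0.5, seed = 2)
  expect_false(identical(f$papillae, f3$papillae))

  empty <- place_papillae(c(filiform = 0), c(10, 10), 0.5)
  expect_identical(nrow(empty$papillae), 0L)

  expect_error(place_papillae(c(filiform = 200), c(2, 2), 0.5, seed = 1,
                              max_attempts = 5000), "packing")
})

test_that("papilla_height is the inverted scaled paraboloid template", {
  sp <- papilla_spec("fungiform", radius_um = 400, height_um = 390)
  expect_equal(papilla_height(0, 0, sp), 0.390)
  expect_equal(papilla_height(0.4, 0, sp), 0)
  expect_equal(papilla_height(0.4 / sqrt(2), 0, sp), 0.390 / 2)
  expect_equal(papilla_height(1, 1, sp), 0)  # outside support
})

test_that("build_mesh samples papillae by pointwise maximum", {
  f <- place_papillae(c(fungiform = 1), c(4, 4), 0.5, seed = 3)
  m <- build_mesh(f, 0.05)
  expect_equal(max(m$z), 0.390, tolerance = 0.05 * 0.390)
  expect_true(all(m$z >= 0))
  expect_lte(max(m$z), max(f$papillae$height_mm))
  # monotone refinement: halving resolution never decreases max z
  m2 <- build_mesh(f, 0.025)
  expect_gte(max(m2$z), max(m$z))

  empty <- build_mesh(place_papillae(c(filiform = 0), c(2, 2), 0.3), 0.05)
  expect_true(all(empty$z == 0))

  expect_error(build_mesh(f, 0.3), "sampling error")
})

test_that("OBJ export round-trips the height grid", {
  f <- place_papillae(c(fungiform = 2, filiform = 5), c(5, 4), 0.9,
                      seed = 4)
  m <- build_mesh(f, 0.09)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, path)
  back <- read_obj(path)
  expect_identical(nrow(back$vertices),
                   as.integer(length(m$x) * length(m$y)))
  z_back <- matrix(back$vertices$z, length(m$y), length(m$x), byrow = TRUE)
  expect_equal(z_back, m$z, tolerance = 1e-7)
  expect_identical(nrow(back$faces),
                   as.integer(2 * (length(m$x) - 1) * (length(m$y) - 1)))
  # every face references valid vertices
  expect_true(all(back$faces >= 1 & back$faces <= nrow(back$vertices)))
})

test_that("smear kernel spreads each dot over the oscillation band", {
  p <- generate_pattern("SpacedQuarter")
  p$dots <- data.frame(x = 18, y = 12, ink = "C", diameter = 1.5)
  k <- shear_kinematics(half_amplitude_mm = 5)
  m <- smear_exposure(p, k, grid_resolution = 0.25)
  mass <- tastant_load(p)$total_ug
  expect_equal(m$total_ug, mass, tolerance = 1e-9)
  prof <- colSums(m$density) * m$cell_area
  inside <- m$x > 13.1 & m$x < 22.9
  expect_true(all(prof[inside] > 0))
  expect_equal(sum(prof[m$x > 12.9 & m$x < 23.1]), mass, tolerance = 1e-9)
  expect_true(all(prof[!(m$x >= 12.9 & m$x <= 23.1)] == 0))
  # uniform within the band
  expect_lt(diff(range(prof[inside])) / mean(prof[inside]), 1e-9)
})

test_that("smearing conserves mass and is linear in load", {
  k <- shear_kinematics()
  for (d in c("Homogeneous", "SpacedQuarter", "Centered", "Layer")) {
    p <- generate_pattern(d)
    m <- smear_exposure(p, k)
    expect_equal(m$total_ug, tastant_load(p)$total_ug, tolerance = 1e-9)
  }
  p <- generate_pattern("SpacedQuarter")
  m1 <- smear_exposure(p, k, drop_mass_ug = 390)
  m2 <- smear_exposure(p, k, drop_mass_ug = 780)
  expect_equal(m2$density, 2 * m1$density, tolerance = 1e-12)
})

test_that("zero amplitude reduces the smear to the deposit map", {
  p <- generate_pattern("SpacedQuarter")
  k0 <- shear_kinematics(half_amplitude_mm = 0)
  m <- smear_exposure(p, k0, grid_resolution = 0.5)
  expect_equal(sum(m$density > 0), nrow(p$dots))
  expect_equal(m$total_ug, tastant_load(p)$total_ug, tolerance = 1e-9)
})

test_that("along-axis CV orders uniform below clustered patterns", {
  k <- shear_kinematics()
  cv <- vapply(c("Homogeneous", "SpacedQuarter", "Centered"), function(d) {
    exposure_cv(smear_exposure(generate_pattern(d), k))
  }, numeric(1))
  expect_lt(cv[["Homogeneous"]], cv[["Centered"]])
  expect_lt(cv[["SpacedQuarter"]], cv[["Centered"]])
})

test_that("region_split returns mass fractions around the boundary", {
  k <- shear_kinematics()
  hom <- smear_exposure(generate_pattern("Homogeneous"), k)
  fr <- region_split(hom)
  expect_equal(sum(fr), 1)
  expect_true(all(fr > 0.2))  # symmetric pattern spans both regions
  # posterior-edge mass: Centered cannot reach x > 30, Homogeneous can
  cen <- smear_exposure(generate_pattern("Centered"), k)
  expect_equal(unname(region_split(cen, boundary = 30)[["posterior"]]), 0)
  expect_gt(region_split(hom, boundary = 30)[["posterior"]], 0)
  # all mass on one side
  expect_equal(unname(region_split(hom, boundary = 100)[["anterior"]]), 1)
  empty <- cen
  empty$density[] <- 0
  expect_warning(fr0 <- region_split(empty), "zero total mass")
  expect_true(all(is.na(fr0)))
})

test_that("segmentation recovers synthetic papillae counts", {
  tg <- render_tongue(n_fungiform = 12, n_filiform = 80, seed = 3)
  seg <- segment_papillae(tg$image, tg$scale)
  expect_identical(unname(seg$counts), c(12L, 80L))
  expect_true(all(seg$components$kind[seg$components$equiv_radius_mm > 0.28]
                  == "fungiform"))

  blank <- matrix(0.15, 50, 50)
  blank[1, 1] <- 0.16  # avoid the uniform-image error; still no components
  expect_warning(seg0 <- segment_papillae(blank, 0.02), "no papillae")
  expect_identical(unname(seg0$counts), c(0, 0))

  # mild noise: at least 95% of components still correctly classified
  tgn <- render_tongue(n_fungiform = 10, n_filiform = 60, seed = 5,
                       noise_sd = 0.05)
  segn <- segment_papillae(tgn$image, tgn$scale)
  expect_gte(sum(segn$counts), 0.95 * 70)
  expect_equal(unname(segn$counts[["fungiform"]]), 10, tolerance = 0.1)
})
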