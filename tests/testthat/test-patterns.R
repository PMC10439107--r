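test_that("ink formulations reproduce the canonical concentrations", {
  inks <- canonical_inks()
  expect_equal(inks$A$effective_thaumatin, 9e-4)
  expect_equal(inks$B$effective_thaumatin, 1.8e-3)
  expect_equal(inks$C$effective_thaumatin, 3.6e-3)
  expect_equal(inks$D$effective_thaumatin, 0)
  for (k in inks) {
    expect_equal(sum(k$emulsion_composition), 1, tolerance = 1e-12)
    expect_equal(k$seeded_cocoa_butter_frac + k$emulsion_frac, 1)
    expect_equal(k$effective_thaumatin,
                 k$emulsion_frac * k$emulsion_composition[["thaumatin"]])
  }
})

test_that("invalid ink compositions are rejected with the offender named", {
  expect_error(ink_formulation("X", 1.2), "emulsion thaumatin")
  expect_error(ink_formulation("X", 0.009, emulsion_frac = 0.3,
                               seeded_cb_frac = 0.9), "sum to 1")
  expect_error(
    ink_formulation("X", 0.01,
                    emulsion_components = c(thaumatin = 0.01, water = 0.5,
                                            PGPR = 0.03, CCT_oil = 0.52)),
    "sum to 1")
  expect_error(
    ink_formulation("X", 0.01,
                    emulsion_components = c(thaumatin = 0.02, water = 0.43,
                                            PGPR = 0.03, CCT_oil = 0.52)),
    "thaumatin")
})

test_that("canonical designs have the canonical dot counts and inks", {
  counts <- c(Bulk = 184, Homogeneous = 184, SpacedFull = 184,
              SpacedHalf = 92, SpacedQuarter = 46, Centered = 184,
              Periphery = 184, Layer = 0)
  inks <- list(Bulk = "D", Homogeneous = "A", SpacedFull = "A",
               SpacedHalf = "B", SpacedQuarter = "C")
  for (d in names(counts)) {
    p <- generate_pattern(d)
    expect_identical(nrow(p$dots), as.integer(counts[[d]]))
    if (d %in% names(inks)) expect_true(all(p$dots$ink == inks[[d]]))
    expect_false(anyDuplicated(p$dots[, c("x", "y")]) > 0)
  }
  expect_true(generate_pattern("Bulk")$bulk_thaumatin_frac > 0)
  expect_true(!is.null(generate_pattern("Layer")$layer))
  expect_error(generate_pattern("Spiral"), "unknown design")
})

test_that("design aliases resolve", {
  expect_identical(generate_pattern("sp. quarter")$design_name,
                   "SpacedQuarter")
  expect_identical(generate_pattern("Layered")$design_name, "Layer")
})

test_that("halving: SpacedQuarter subset of SpacedHalf subset of SpacedFull", {
  key <- function(d) paste(d$dots$x, d$dots$y)
  full <- key(generate_pattern("SpacedFull"))
  half <- key(generate_pattern("SpacedHalf"))
  quarter <- key(generate_pattern("SpacedQuarter"))
  expect_true(all(half %in% full))
  expect_true(all(quarter %in% half))
  expect_identical(c(length(full), length(half), length(quarter)),
                   c(184L, 92L, 46L))
})

test_that("dots stay inside the printable region without overlap", {
  for (d in dotted_designs) {
    p <- generate_pattern(d)
    reg <- list(x = c(1, 35), y = c(1, 23))
    expect_true(all(p$dots$x >= reg$x[1] & p$dots$x <= reg$x[2]))
    expect_true(all(p$dots$y >= reg$y[1] & p$dots$y <= reg$y[2]))
    centers <- min(dot_distances(p, "center"))
    expect_gte(centers, max(p$dots$diameter) - 1e-9)
  }
})

test_that("dot_distances matches arithmetic and the brute-force oracle", {
  p <- generate_pattern("SpacedQuarter")
  p$dots <- data.frame(x = c(10, 14), y = c(10, 10), ink = "C",
                       diameter = 1.5)
  expect_equal(dot_distances(p, "edge"), c(2.5, 2.5))
  expect_equal(dot_distances(p, "center"), c(4, 4))
  p$dots <- p$dots[1, ]
  expect_identical(dot_distances(p), numeric(0))

  q <- generate_pattern("SpacedQuarter")
  oracle <- brute_nn(as.matrix(q$dots[, c("x", "y")]), diameter = 1.5)
  expect_equal(dot_distances(q, "edge"), unname(oracle))
  expect_equal(max(oracle), 2.5)
})

test_that("classify_scale assigns micro / meso / none canonically", {
  for (d in micro_designs) {
    expect_identical(generate_pattern(d)$scale_class, "micro")
  }
  expect_identical(generate_pattern("Centered")$scale_class, "meso")
  expect_identical(generate_pattern("Periphery")$scale_class, "meso")
  expect_identical(generate_pattern("Layer")$scale_class, "none")
})

test_that("meso contrasting-cluster gap exceeds 8 mm along the long axis", {
  for (d in c("Centered", "Periphery")) {
    expect_gt(cluster_gap(generate_pattern(d)), 8)
  }
  expect_true(is.na(cluster_gap(generate_pattern("Homogeneous"))))
})

test_that("tastant load is conserved across all dotted designs", {
  loads <- vapply(dotted_designs, function(d) {
    tastant_load(generate_pattern(d))$total_ug
  }, numeric(1))
  expect_equal(loads[["Homogeneous"]], 184 * 390 * 9e-4)  # 64.584 ug
  expect_true(all(abs(loads / loads[["Homogeneous"]] - 1) < 1e-9))
  # Bulk and Layer match the dotted load through bulk fraction / coat mass
  expect_equal(tastant_load(generate_pattern("Bulk"))$total_ug,
               loads[["Homogeneous"]], tolerance = 1e-12)
  expect_equal(tastant_load(generate_pattern("Layer"))$total_ug,
               loads[["Homogeneous"]], tolerance = 1e-12)
  # Bulk dot contribution is zero (ink D)
  by_ink <- tastant_load(generate_pattern("Bulk"))$by_ink
  expect_equal(unname(by_ink[["D"]]), 0)
  expect_error(tastant_load(generate_pattern("Bulk"), drop_mass_ug = 0),
               "drop_mass_ug")
})

test_that("pattern JSON and bitmap PBM round trips preserve the design", {
  p <- generate_pattern("SpacedHalf")
  f <- withr::local_tempfile(fileext = ".json")
  pattern_to_json(p, f)
  q <- pattern_from_json(f)
  expect_equal(q$dots, p$dots)
  expect_identical(q$design_name, p$design_name)
  expect_equal(tastant_load(q)$total_ug, tastant_load(p)$total_ug)

  bmp <- render_bitmap(p, 2)
  expect_identical(sum(bmp), 92L)
  fb <- withr::local_tempfile(fileext = ".pbm")
  write_pbm(bmp, fb)
  expect_identical(read_pbm(fb), bmp)
})

test_that("too-coarse bitmaps warn about merged dots", {
  expect_warning(render_bitmap(generate_pattern("Centered"), 2), "merges")
  expect_silent(render_bitmap(generate_pattern("Centered"), 0.75))
})
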