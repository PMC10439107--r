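make_panel <- function(means, n_assessors = 10, seed = 1, ...) {
  cfg <- panel_config(rownames(means), means, n_assessors = n_assessors,
                      seed = seed, ...)
  gen_ratings(cfg)
}

two_sample_means <- function(m1, m2, m3 = NULL) {
  s <- c("S1", "S2", if (!is.null(m3)) "S3")
  m <- do.call(rbind, c(list(m1, m2), if (!is.null(m3)) list(m3)))
  dimnames(m) <- list(s, c("t_start", "t_max", "t_end"))
  m
}

test_that("ANOVA decomposes sums of squares and degrees of freedom", {
  r <- make_panel(two_sample_means(c(30, 50, 20), c(35, 55, 25)), seed = 2)
  a <- two_way_anova(r)
  expect_equal(sum(a$df), nrow(r) - 1)
  expect_true(all(a$sum_sq >= 0))
  total_ss <- sum((r$intensity - mean(r$intensity))^2)
  expect_equal(sum(a$sum_sq), total_ss, tolerance = 1e-8)
  expect_setequal(a$term, c("assessor", "session", "sample", "timepoint",
                            "sample:timepoint", "Residuals"))
  expect_identical(a$role[a$term == "assessor"], "random")
  expect_identical(a$role[a$term == "sample"], "fixed")
})

test_that("ANOVA detects a strong sample effect and not a null one", {
  # identical cell means: sample effect should be null
  r0 <- make_panel(two_sample_means(c(40, 50, 30), c(40, 50, 30)), seed = 3)
  a0 <- two_way_anova(r0)
  expect_gt(a0$p[a0$term == "sample"], 0.05)
  # 3 residual sds of separation at n=14: overwhelming evidence
  r1 <- make_panel(two_sample_means(c(40, 50, 30), c(70, 80, 60)),
                   n_assessors = 14, seed = 4)
  a1 <- two_way_anova(r1)
  expect_lt(a1$p[a1$term == "sample"], 1e-3)
})

test_that("ANOVA validates the design", {
  r <- make_panel(two_sample_means(c(30, 50, 20), c(35, 55, 25)))
  expect_error(two_way_anova(r[r$sample == "S1", ]), "design error")
  bad <- r
  bad$intensity[1] <- 150
  expect_error(two_way_anova(bad), "0-100")
  expect_warning(two_way_anova(r[-1, ]), "unbalanced")
})

test_that("unbalanced Type-II ANOVA stays close to the balanced table", {
  r <- make_panel(two_sample_means(c(30, 50, 20), c(40, 60, 30)), seed = 8)
  a_bal <- two_way_anova(r)
  a_unb <- suppressWarnings(two_way_anova(r[-(1:2), ]))
  for (tm in c("sample", "timepoint")) {
    expect_equal(a_unb$F[a_unb$term == tm], a_bal$F[a_bal$term == tm],
                 tolerance = 0.15)
  }
})

test_that("Tukey comparisons flag only genuinely shifted samples", {
  # identical groups: nothing significant at the 0.01 level
  r0 <- make_panel(two_sample_means(c(40, 50, 30), c(40, 50, 30),
                                    c(40, 50, 30)), seed = 5)
  t0 <- tukey_by_timepoint(r0, "t_max")
  expect_identical(nrow(t0), 3L)
  expect_true(all(t0$p_adj > 0.01))
  # one group shifted by 5 residual sds
  r1 <- make_panel(two_sample_means(c(40, 50, 30), c(40, 50, 30),
                                    c(90, 100, 80)), seed = 6)
  t1 <- tukey_by_timepoint(r1, "t_max")
  hit <- t1$sample_1 == "S3" | t1$sample_2 == "S3"
  expect_true(all(t1$p_adj[hit] < 0.001))
  expect_true(all(t1$stars[hit] == "****"))
  # differences match group means with pair-order sign
  m <- tapply(r1$intensity[r1$timepoint == "t_max"],
              r1$sample[r1$timepoint == "t_max"], mean)
  for (i in seq_len(nrow(t1))) {
    expect_equal(t1$mean_difference[i],
                 m[[t1$sample_1[i]]] - m[[t1$sample_2[i]]],
                 tolerance = 1e-8)
  }
})

test_that("Tukey familywise error stays near nominal under the null", {
  set.seed(30)
  m <- two_sample_means(c(40, 50, 30), c(40, 50, 30), c(40, 50, 30))
  any_hit <- vapply(1:200, function(i) {
    r <- make_panel(m, seed = 4000 + i)
    any(tukey_by_timepoint(r, "t_max")$p_adj < 0.05)
  }, logical(1))
  expect_lte(mean(any_hit), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("significance stars follow the four-level figure convention", {
  expect_identical(significance_stars(c(0.6, 0.3, 0.05, 0.005, 1e-4)),
                   c("", "*", "**", "***", "****"))
})

test_that("amplification is the percent change versus the reference mean", {
  df <- expand.grid(assessor = 1:2, session = 1, sample = c("Ref", "Up",
                                                            "Down"),
                    timepoint = "t_max", stringsAsFactors = FALSE)
  df$intensity <- c(Ref = 20, Up = 80, Down = 15.2)[df$sample]
  amp <- amplification(df, "Ref", "t_max")
  expect_equal(unname(amp[["Up"]]), 300)
  expect_equal(unname(amp[["Down"]]), -24)
  same <- df
  same$intensity[same$sample == "Up"] <- 20
  expect_equal(unname(amplification(same, "Ref", "t_max")[["Up"]]), 0)
  zero <- df
  zero$intensity[zero$sample == "Ref"] <- 0
  expect_error(amplification(zero, "Ref", "t_max"), "undefined")
  expect_error(amplification(df, "Missing", "t_max"), "not present")
})

test_that("stimulus-response fit reports slope, R2 and deviations", {
  pts <- data.frame(stimulus_size = c(0.1, 0.2, 0.3, 0.4),
                    intensity = c(10, 20, 30, 40))
  f <- fit_stimulus_response(pts)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 100)
  expect_error(fit_stimulus_response(pts[1:2, ]), "3 points")

  set.seed(21)
  pts2 <- data.frame(stimulus_size = seq(0.1, 0.6, length.out = 8))
  pts2$intensity <- 10 + 60 * pts2$stimulus_size + rnorm(8, 0, 2)
  f2 <- fit_stimulus_response(pts2)
  # on-line point deviates ~0; symmetric points have opposite signs
  on_line <- f2$intercept + f2$slope * 0.3
  expect_equal(predict_deviation(f2, 0.3, on_line), 0, tolerance = 1e-8)
  up <- predict_deviation(f2, 0.3, on_line + 3 * f2$residual_sd)
  dn <- predict_deviation(f2, 0.3, on_line - 3 * f2$residual_sd)
  expect_equal(up, 3)
  expect_equal(dn, -3)

  # zero-slope data: median R2 over replicates stays near zero
  set.seed(22)
  r2 <- vapply(1:200, function(i) {
    y <- rnorm(8, 30, 5)
    fit_stimulus_response(data.frame(stimulus_size = pts2$stimulus_size,
                                     intensity = y))$r_squared
  }, numeric(1))
  expect_lt(median(r2), 0.2)
})

test_that("ratings CSV round trip preserves records", {
  r <- make_panel(two_sample_means(c(30, 50, 20), c(35, 55, 25)), seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  ratings_to_csv(r, f)
  back <- ratings_from_csv(f)
  expect_equal(back$intensity, r$intensity)
  expect_identical(nrow(back), nrow(r))
})
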