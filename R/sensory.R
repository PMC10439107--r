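#' Validate and normalize a ratings table
#'
#' @param records data.frame with columns `assessor`, `sample`, `session`,
#'   `timepoint` (levels `t_start`, `t_max`, `t_end`) and `intensity`
#'   (0-100).
#' @return The table with factor columns in canonical order.
#' @keywords internal
.check_records <- function(records) {
  need <- c("assessor", "sample", "session", "timepoint", "intensity")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("ratings table missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(records$intensity < 0 | records$intensity > 100)) {
    stop("intensity outside the 0-100 scale")
  }
  tp <- c("t_start", "t_max", "t_end")
  if (!all(records$timepoint %in% tp)) {
    stop("timepoint must be one of ", paste(tp, collapse = ", "))
  }
  records$assessor <- factor(records$assessor)
  records$sample <- factor(records$sample)
  records$session <- factor(records$session)
  records$timepoint <- factor(records$timepoint, levels = tp)
  records
}

#' Mixed two-way ANOVA of sweetness intensity
#'
#' Sample and timepoint (plus their interaction) are fixed effects;
#' assessor and session (replicate) enter as additive random blocks. All
#' terms are tested against the residual stratum. Balanced designs use
#' sequential sums of squares (orthogonal here); unbalanced data trigger a
#' warning and Type-II sums of squares.
#'
#' @param records Ratings table (see [.check_records] for the schema).
#' @param unbalance_tol Maximum relative spread of cell counts treated as
#'   balanced.
#' @return Object of class `anova_result`: data.frame with `term`, `role`
#'   (fixed/random/residual), `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(records, unbalance_tol = 1e-9) {
  d <- .check_records(records)
  for (f in c("sample", "timepoint", "assessor")) {
    if (nlevels(droplevels(d[[f]])) < 2) {
      stop("design error: factor '", f, "' needs at least 2 levels")
    }
  }
  counts <- table(d$sample, d$timepoint, d$assessor)
  balanced <- diff(range(counts)) <= unbalance_tol * max(counts)
  form <- intensity ~ assessor + session + sample * timepoint
  if (balanced) {
    fit <- stats::aov(form, data = d)
    tab <- summary(fit)[[1]]
  } else {
    warning("unbalanced design: using Type-II sums of squares")
    tab <- .type2_anova(form, d)
  }
  term <- trimws(rownames(tab))
  role <- ifelse(term == "Residuals", "residual",
                 ifelse(term %in% c("assessor", "session"), "random",
                        "fixed"))
  res <- data.frame(term = term, role = role, df = tab$Df,
                    sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
                    F = tab$`F value`, p = tab$`Pr(>F)`)
  structure(res, class = c("anova_result", "data.frame"))
}

# Type-II SS: each term's SS is the RSS increase from dropping it from the
# model containing all terms except those that contain it.
.type2_anova <- function(form, d) {
  full <- stats::lm(form, data = d)
  rss_full <- sum(stats::resid(full)^2)
  df_res <- full$df.residual
  ms_res <- rss_full / df_res
  terms_all <- attr(stats::terms(form), "term.labels")
  rows <- lapply(terms_all, function(tm) {
    containing <- terms_all[vapply(terms_all, function(o) {
      o != tm && all(strsplit(tm, ":")[[1]] %in% strsplit(o, ":")[[1]])
    }, logical(1))]
    base_terms <- setdiff(terms_all, c(tm, containing))
    f_with <- stats::reformulate(c(base_terms, tm), response = "intensity")
    f_without <- if (length(base_terms)) {
      stats::reformulate(base_terms, response = "intensity")
    } else intensity ~ 1
    m1 <- stats::lm(f_with, data = d)
    m0 <- stats::lm(f_without, data = d)
    ss <- sum(stats::resid(m0)^2) - sum(stats::resid(m1)^2)
    df <- m0$df.residual - m1$df.residual
    data.frame(Df = df, `Sum Sq` = ss, `Mean Sq` = ss / df,
               `F value` = (ss / df) / ms_res,
               `Pr(>F)` = stats::pf((ss / df) / ms_res, df, df_res,
                                    lower.tail = FALSE),
               check.names = FALSE, row.names = tm)
  })
  resid_row <- data.frame(Df = df_res, `Sum Sq` = rss_full,
                          `Mean Sq` = ms_res, `F value` = NA,
                          `Pr(>F)` = NA, check.names = FALSE,
                          row.names = "Residuals")
  rbind(do.call(rbind, rows), resid_row)
}

#' Significance stars
#'
#' Default thresholds follow the four-level figure convention:
#' p < 0.5 `*`, < 0.1 `**`, < 0.01 `***`, < 0.001 `****`.
#'
#' @param p P-values.
#' @param thresholds Named numeric vector, names = star strings, sorted
#'   loosest first.
#' @return Character vector of stars (`""` when not significant).
#' @export
significance_stars <- function(p, thresholds = c("*" = 0.5, "**" = 0.1,
                                                 "***" = 0.01,
                                                 "****" = 0.001)) {
  vapply(p, function(pp) {
    hit <- names(thresholds)[pp < thresholds]
    if (length(hit)) hit[length(hit)] else ""
  }, character(1))
}

#' Tukey post-hoc comparisons between samples at one timepoint
#'
#' All pairwise sample comparisons at the given timepoint, adjusted with
#' the studentized range (Tukey HSD) on the block-adjusted model
#' `intensity ~ assessor + session + sample`.
#'
#' @param records Ratings table.
#' @param timepoint One of `t_start`, `t_max`, `t_end`.
#' @param thresholds Star thresholds, see [significance_stars].
#' @return data.frame with `timepoint`, `sample_1`, `sample_2`,
#'   `mean_difference`, `p_adj`, `stars`; zero rows for < 2 samples.
#' @export
tukey_by_timepoint <- function(records, timepoint,
                               thresholds = c("*" = 0.5, "**" = 0.1,
                                              "***" = 0.01, "****" = 0.001)) {
  d <- .check_records(records)
  d <- droplevels(d[d$timepoint == timepoint, , drop = FALSE])
  if (nrow(d) == 0) stop("timepoint '", timepoint, "' not present")
  if (nlevels(d$sample) < 2) {
    return(data.frame(timepoint = character(0), sample_1 = character(0),
                      sample_2 = character(0), mean_difference = numeric(0),
                      p_adj = numeric(0), stars = character(0)))
  }
  form <- if (nlevels(d$session) > 1) {
    intensity ~ assessor + session + sample
  } else intensity ~ assessor + sample
  fit <- stats::aov(form, data = d)
  tk <- stats::TukeyHSD(fit, "sample")$sample
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(timepoint = timepoint,
             sample_1 = vapply(pair, `[`, "", 1),
             sample_2 = vapply(pair, `[`, "", 2),
             mean_difference = unname(tk[, "diff"]),
             p_adj = unname(tk[, "p adj"]),
             stars = significance_stars(tk[, "p adj"], thresholds))
}

#' Percent amplification of mean intensity vs a reference sample
#'
#' `100 * (mean_sample - mean_reference) / mean_reference` per sample, so
#' an amplification of 300% means the sample mean is 4x the reference mean.
#'
#' @param records Ratings table.
#' @param reference_sample Reference design name (e.g. `"Bulk"`).
#' @param timepoint Timepoint to evaluate at.
#' @return Named numeric vector of percent amplification per non-reference
#'   sample.
#' @export
amplification <- function(records, reference_sample, timepoint) {
  d <- .check_records(records)
  d <- d[d$timepoint == timepoint, , drop = FALSE]
  if (!reference_sample %in% d$sample) {
    stop("reference sample '", reference_sample, "' not present at ",
         timepoint)
  }
  m <- tapply(d$intensity, droplevels(d$sample), mean)
  ref <- m[[reference_sample]]
  if (ref == 0) stop("undefined amplification: reference mean is 0")
  out <- 100 * (m - ref) / ref
  out[setdiff(names(out), reference_sample)]
}

#' Linear stimulus-size response model
#'
#' OLS fit of mean maximum intensity on stimulus size
#' (`A_pattern * C_thaumatin`), with a pointwise 95% confidence band for
#' the mean response.
#'
#' @param points data.frame with `stimulus_size` and `intensity` (>= 3
#'   rows); an optional `sd` column is carried through.
#' @return Object of class `stimulus_response_fit`: `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `band(x)` (data.frame `fit`, `lwr`,
#'   `upr`), and the underlying `lm`.
#' @export
fit_stimulus_response <- function(points) {
  if (nrow(points) < 3) stop("fit error: need at least 3 points")
  fit <- stats::lm(intensity ~ stimulus_size, data = points)
  sm <- suppressWarnings(summary(fit))  # collinear points are legal input
  band <- function(x) {
    as.data.frame(stats::predict(fit,
                                 newdata = data.frame(stimulus_size = x),
                                 interval = "confidence", level = 0.95))
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, residual_sd = sm$sigma,
                 band = band, fit = fit),
            class = "stimulus_response_fit")
}

#' Standardized residual of a point from the stimulus-response line
#'
#' Used to flag off-line samples (e.g. the manually coated Layer design,
#' whose perceived sweetness falls below the line for its stimulus size).
#'
#' @param fit A [fit_stimulus_response] result.
#' @param stimulus_size,observed Point to evaluate.
#' @return `(observed - predicted) / residual_sd`.
#' @export
predict_deviation <- function(fit, stimulus_size, observed) {
  pred <- stats::predict(fit$fit,
                         newdata = data.frame(stimulus_size = stimulus_size))
  (observed - unname(pred)) / fit$residual_sd
}

#' Read / write ratings tables
#'
#' CSV with columns `assessor`, `sample`, `session`, `timepoint`,
#' `intensity`.
#'
#' @param records Ratings table.
#' @param path File path.
#' @export
ratings_to_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ratings_to_csv
#' @export
ratings_from_csv <- function(path) {
  .check_records(utils::read.csv(path))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed two-way ANOVA (fixed: sample, timepoint; random blocks:",
      "assessor, session)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
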