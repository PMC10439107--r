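#' Printable ink formulation
#'
#' An ink is a seeded-cocoa-butter matrix carrying a water-in-oil emulsion
#' whose aqueous phase contains the tastant (thaumatin). The effective
#' tastant concentration of the ink, `C_thaumatin`, is the product of the
#' emulsion mass fraction and the thaumatin mass fraction of the emulsion.
#'
#' @param name Ink label, e.g. `"A"`.
#' @param emulsion_thaumatin_frac Thaumatin mass fraction of the emulsion
#'   (e.g. 0.009 for 0.9 %w/w).
#' @param emulsion_frac Emulsion mass fraction of the ink (default 0.1).
#' @param emulsion_components Optional named numeric vector giving the full
#'   emulsion composition (`thaumatin`, `water`, `PGPR`, `CCT_oil`); must sum
#'   to 1 and its `thaumatin` entry must equal `emulsion_thaumatin_frac`.
#'   If `NULL` the water fraction absorbs the remainder beyond the default
#'   PGPR (0.03) and CCT oil (0.52) levels.
#' @param seeded_cb_frac Seeded cocoa butter mass fraction of the ink;
#'   defaults to `1 - emulsion_frac`.
#' @return An object of class `ink_formulation`: a list with fields `name`,
#'   `seeded_cocoa_butter_frac`, `emulsion_frac`, `emulsion_composition` and
#'   `effective_thaumatin` (mass fraction of the ink).
#' @examples
#' ink_formulation("A", 0.009)$effective_thaumatin  # 9e-4, i.e. 0.09 %w/w
#' @export
ink_formulation <- function(name, emulsion_thaumatin_frac,
                            emulsion_frac = 0.1,
                            emulsion_components = NULL,
                            seeded_cb_frac = 1 - emulsion_frac) {
  .check_frac(emulsion_thaumatin_frac, "emulsion thaumatin")
  .check_frac(emulsion_frac, "emulsion")
  .check_frac(seeded_cb_frac, "seeded cocoa butter")
  if (abs(seeded_cb_frac + emulsion_frac - 1) > 1e-9) {
    stop("ink composition error: seeded cocoa butter (", seeded_cb_frac,
         ") + emulsion (", emulsion_frac, ") fractions must sum to 1")
  }
  if (is.null(emulsion_components)) {
    pgpr <- 0.03
    cct <- 0.52
    water <- 1 - emulsion_thaumatin_frac - pgpr - cct
    emulsion_components <- c(thaumatin = emulsion_thaumatin_frac,
                             water = water, PGPR = pgpr, CCT_oil = cct)
  }
  for (comp in names(emulsion_components)) {
    .check_frac(emulsion_components[[comp]], comp)
  }
  if (abs(sum(emulsion_components) - 1) > 1e-9) {
    stop("ink composition error: emulsion components (",
         paste(names(emulsion_components), collapse = ", "),
         ") must sum to 1, got ", sum(emulsion_components))
  }
  if (abs(emulsion_components[["thaumatin"]] - emulsion_thaumatin_frac) > 1e-9) {
    stop("ink composition error: component 'thaumatin' (",
         emulsion_components[["thaumatin"]],
         ") disagrees with emulsion_thaumatin_frac (",
         emulsion_thaumatin_frac, ")")
  }
  structure(list(
    name = as.character(name),
    seeded_cocoa_butter_frac = seeded_cb_frac,
    emulsion_frac = emulsion_frac,
    emulsion_composition = emulsion_components,
    effective_thaumatin = emulsion_frac * emulsion_thaumatin_frac
  ), class = "ink_formulation")
}

.check_frac <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("ink composition error: ", what,
         " fraction must be a single value in [0, 1], got ", x)
  }
  invisible(x)
}

#' Canonical ink set A-D
#'
#' The four study inks: 90 %w/w seeded cocoa butter + 10 %w/w W/O emulsion,
#' with emulsion thaumatin at 0.9 / 1.8 / 3.6 / 0 %w/w (inks A-D), yielding
#' effective ink concentrations of 0.09, 0.18, 0.36 and 0 %w/w.
#'
#' @return Named list of [ink_formulation] objects `A`, `B`, `C`, `D`.
#' @export
canonical_inks <- function() {
  mk <- function(nm, th, water) {
    ink_formulation(nm, th, 0.1,
                    c(thaumatin = th, water = water, PGPR = 0.03,
                      CCT_oil = 0.52))
  }
  list(A = mk("A", 0.009, 0.441),
       B = mk("B", 0.018, 0.432),
       C = mk("C", 0.036, 0.414),
       D = mk("D", 0.000, 0.450))
}

#' @export
print.ink_formulation <- function(x, ...) {
  cat("<ink_formulation>", x$name, "\n",
      " seeded cocoa butter:", x$seeded_cocoa_butter_frac,
      " emulsion:", x$emulsion_frac, "\n",
      " effective thaumatin (C_thaumatin):",
      sprintf("%.4f %%w/w", 100 * x$effective_thaumatin), "\n")
  invisible(x)
}
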