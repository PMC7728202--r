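#' Comparative-Ct relative expression
#'
#' Averages each Ct triplicate (arithmetic mean of the finite values),
#' forms `dct = mean(ct_target) - mean(ct_housekeeper)`, and reports
#' `rel_expr_pct = 2^(-dct) * 100`, the target's abundance as a percentage
#' of the housekeeper. The subtraction direction is the conventional
#' target-minus-housekeeper one, so targets rarer than the housekeeper give
#' values below 100% (the opposite literal order would report low-abundance
#' targets above 100%, contradicting the magnitudes such assays produce).
#' `dct = 0` gives exactly 100%, and each additional cycle of `dct` halves
#' the relative expression.
#'
#' @param ct_target Numeric Ct replicates for the target (>= 1 finite value).
#' @param ct_housekeeper Numeric Ct replicates for the housekeeper.
#' @return List with `dct` (cycles) and `rel_expr_pct` (%).
#' @export
relative_expression <- function(ct_target, ct_housekeeper) {
  avg <- function(x, what) {
    x <- x[is.finite(x)]
    if (length(x) == 0) stop("no finite Ct value in ", what, " replicates")
    if (length(x) > 1 && diff(range(x)) > 1)
      warning("Ct replicate spread exceeds 1 cycle in ", what,
              " (replicate inconsistency)")
    mean(x)
  }
  dct <- avg(ct_target, "target") - avg(ct_housekeeper, "housekeeper")
  list(dct = dct, rel_expr_pct = 2^(-dct) * 100)
}

#' Densitometric ratio to the loading control
#'
#' @param target Band intensity of the target protein (arbitrary units).
#' @param loading Band intensity of the loading control (> 0).
#' @return `target / loading`.
#' @export
densitometry_ratio <- function(target, loading) {
  if (any(loading <= 0)) stop("loading-control intensity must be > 0")
  target / loading
}

#' Cross-sectional tongue area from two diameters
#'
#' Elliptical approximation: `area = d_lateral * d_dorsoventral * 0.25 * pi`.
#' Equal diameters reduce to a circle of that diameter.
#'
#' @param d_lateral_mm Lateral (transversal-plane) diameter (mm, > 0).
#' @param d_dorsoventral_mm Dorso-ventral (sagittal-plane) diameter (mm, > 0).
#' @return Area in mm^2.
#' @export
ellipse_area <- function(d_lateral_mm, d_dorsoventral_mm) {
  if (any(d_lateral_mm <= 0) || any(d_dorsoventral_mm <= 0))
    stop("diameters must be > 0")
  d_lateral_mm * d_dorsoventral_mm * 0.25 * pi
}

#' Organ-weight to body-weight ratio
#'
#' Heart- or lung-weight normalized to body weight, in percent. Cohort-level
#' summaries are means of the per-animal ratios, not ratios of means.
#'
#' @param organ_g Organ weight (g).
#' @param bw_g Body weight (g, > 0).
#' @return `100 * organ_g / bw_g` (%).
#' @export
organ_ratio <- function(organ_g, bw_g) {
  if (any(bw_g <= 0)) stop("body weight must be > 0")
  100 * organ_g / bw_g
}

#' Pure-volume equivalent of a PTFE dose
#'
#' Converts an injected PTFE mass to the pure volume it occupies:
#' `volume_ul = mass_mg / density_g_per_ml` (mg divided by g/ml is ul).
#' 50 mg at 2.1 g/ml gives 23.81 ul, i.e. ~24 ul of pure PTFE in a 100 ul
#' dilution.
#'
#' @param mass_mg PTFE mass (mg).
#' @param density_g_per_ml Density (g/ml, > 0). Default 2.1.
#' @return Volume in microliters.
#' @export
ptfe_dose_volume <- function(mass_mg, density_g_per_ml = 2.1) {
  if (any(density_g_per_ml <= 0)) stop("density must be > 0")
  mass_mg / density_g_per_ml
}

#' Diastolic function index E/e'
#'
#' Ratio of early mitral inflow velocity (E) to early diastolic mitral
#' annular velocity (e'); higher values indicate more severe diastolic
#' dysfunction.
#'
#' @param e_vel E velocity.
#' @param eprime_vel e' velocity (nonzero).
#' @return `e_vel / eprime_vel`.
#' @export
e_over_eprime <- function(e_vel, eprime_vel) {
  if (any(eprime_vel == 0)) stop("e' velocity must be nonzero")
  e_vel / eprime_vel
}

#' Derived morphometry fields for an animal table
#'
#' Adds `tongue_area_mm2`, `hw_bw_pct`, `lw_bw_pct`, and `e_over_eprime`
#' columns recomputed from the raw columns (`d_lateral_mm`,
#' `d_dorsoventral_mm`, `hw_g`, `lw_g`, `bw_g`, `e_vel`, `eprime_vel`);
#' columns absent from the input are skipped, and stored derived values are
#' always overwritten so raw and derived fields cannot drift apart.
#'
#' @param morph Data frame of per-animal morphometry measurements.
#' @return The data frame with derived columns filled in.
#' @export
morphometry_derive <- function(morph) {
  if (all(c("d_lateral_mm", "d_dorsoventral_mm") %in% names(morph)))
    morph$tongue_area_mm2 <- ellipse_area(morph$d_lateral_mm,
                                          morph$d_dorsoventral_mm)
  if (all(c("hw_g", "bw_g") %in% names(morph)))
    morph$hw_bw_pct <- organ_ratio(morph$hw_g, morph$bw_g)
  if (all(c("lw_g", "bw_g") %in% names(morph)))
    morph$lw_bw_pct <- organ_ratio(morph$lw_g, morph$bw_g)
  if (all(c("e_vel", "eprime_vel") %in% names(morph)))
    morph$e_over_eprime <- e_over_eprime(morph$e_vel, morph$eprime_vel)
  morph
}
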