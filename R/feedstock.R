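#' Describe a lignocellulosic feedstock
#'
#' Bundles the compositional measurements of a milled feedstock into a
#' one-row tibble. Carbohydrate is expressed on a monomer-equivalent basis
#' (g glucose/xylose/arabinose equivalent per g as-is solids, i.e. inclusive
#' of moisture), matching how quantitative saccharification results are
#' reported. No anhydro-correction (1.111/1.136) is applied anywhere in the
#' package: concentrations derived from these fractions are monomer
#' equivalents throughout.
#'
#' @param glucan_frac Glucose-equivalent mass fraction of as-is solids.
#' @param xylan_frac Xylose-equivalent mass fraction.
#' @param arabinan_frac Arabinose-equivalent mass fraction.
#' @param moisture_frac Moisture mass fraction.
#' @param ash_frac Ash mass fraction.
#' @param cod_per_gram Chemical oxygen demand, g COD per g as-is solids.
#'
#' @return A one-row tibble of class `feedstock_composition`.
#' @examples
#' # mid-season switchgrass, 0.5 mm milled
#' switchgrass <- feedstock_composition(
#'   glucan_frac = 0.306, xylan_frac = 0.229, arabinan_frac = 0.0407,
#'   moisture_frac = 0.0605, ash_frac = 0.0592, cod_per_gram = 1.22
#' )
#' feed_carbohydrate_concentration(switchgrass, solids_loading = 30)
#' @export
feedstock_composition <- function(glucan_frac, xylan_frac, arabinan_frac,
                                  moisture_frac = 0, ash_frac = 0,
                                  cod_per_gram = 1) {
  fracs <- c(
    glucan_frac = glucan_frac, xylan_frac = xylan_frac,
    arabinan_frac = arabinan_frac, moisture_frac = moisture_frac,
    ash_frac = ash_frac
  )
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop_domain("all composition fractions must lie in [0, 1]",
      "thermodigest_invalid_composition")
  }
  total <- glucan_frac + xylan_frac + arabinan_frac + ash_frac + moisture_frac
  if (total > 1 + 1e-9) {
    stop_domain(
      sprintf("composition fractions sum to %.3f; must not exceed 1", total),
      "thermodigest_invalid_composition")
  }
  if (!is.finite(cod_per_gram) || cod_per_gram <= 0) {
    stop_domain("cod_per_gram must be > 0", "thermodigest_invalid_composition")
  }
  out <- tibble(
    glucan_frac = glucan_frac, xylan_frac = xylan_frac,
    arabinan_frac = arabinan_frac, moisture_frac = moisture_frac,
    ash_frac = ash_frac, cod_per_gram = cod_per_gram
  )
  class(out) <- c("feedstock_composition", class(out))
  out
}

#' Carbohydrate concentration entering the reactor
#'
#' Total monomer-equivalent carbohydrate concentration contributed by the
#' feed, `C0 = (glucan + xylan + arabinan fractions) * solids_loading`. This
#' is the `C0` of the recalcitrant-fraction rate law (see
#' [fit_recalcitrant_first_order()]).
#'
#' @param comp A [feedstock_composition()].
#' @param solids_loading As-is solids loading of the medium, g/L.
#'
#' @return Carbohydrate concentration, g monomer equivalent / L.
#' @export
feed_carbohydrate_concentration <- function(comp, solids_loading) {
  stopifnot(inherits(comp, "feedstock_composition"))
  if (!is.numeric(solids_loading) || length(solids_loading) != 1 ||
      !is.finite(solids_loading) || solids_loading <= 0) {
    stop_domain("solids_loading must be a single positive number",
      "thermodigest_domain_error")
  }
  (comp$glucan_frac + comp$xylan_frac + comp$arabinan_frac) * solids_loading
}
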