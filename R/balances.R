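#' Mass and electron (COD) balance streams
#'
#' Daily mass flows in and out of a semi-continuous digester, used by
#' [cod_recovery()] and [mass_recovery()]. All streams are g/day (g COD/day
#' for the COD entries) and must be non-negative.
#'
#' @param feed_solids Dry feedstock added, g/day.
#' @param feed_cod COD of the feedstock added, g COD/day.
#' @param ch4_mass Methane leaving in the biogas, g/day.
#' @param co2_gas_mass CO2 leaving in the biogas, g/day.
#' @param co2_dissolved_mass CO2 leaving dissolved in withdrawn slurry,
#'   g/day (see [dissolved_co2_concentration()]).
#' @param slurry_dry_mass Freeze-dried solids in withdrawn slurry, g/day.
#' @param slurry_cod COD of withdrawn slurry, g COD/day.
#' @return A one-row tibble of class `balance_streams`.
#' @export
balance_streams <- function(feed_solids, feed_cod, ch4_mass = 0,
                            co2_gas_mass = 0, co2_dissolved_mass = 0,
                            slurry_dry_mass = 0, slurry_cod = 0) {
  vals <- c(
    feed_solids = feed_solids, feed_cod = feed_cod, ch4_mass = ch4_mass,
    co2_gas_mass = co2_gas_mass, co2_dissolved_mass = co2_dissolved_mass,
    slurry_dry_mass = slurry_dry_mass, slurry_cod = slurry_cod
  )
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_domain("all balance streams must be finite and >= 0",
      "thermodigest_domain_error")
  }
  out <- as_tibble(as.list(vals))
  class(out) <- c("balance_streams", class(out))
  out
}

# 4.00 g COD per g CH4: CH4 + 2 O2 -> CO2 + 2 H2O, 64 g O2 / 16 g CH4
COD_PER_G_CH4 <- 4.0

#' Electron (COD) balance closure
#'
#' COD of methane plus withdrawn slurry leaving the reactor, as a percentage
#' of the COD fed. Methane carries 4.0 g COD per g (oxidation
#' stoichiometry); CO2 carries none.
#'
#' @param streams A [balance_streams()] row.
#' @return Recovery, percent.
#' @export
cod_recovery <- function(streams) {
  stopifnot(inherits(streams, "balance_streams"))
  if (streams$feed_cod <= 0) {
    stop_domain("feed_cod must be > 0", "thermodigest_domain_error")
  }
  100 * (COD_PER_G_CH4 * streams$ch4_mass + streams$slurry_cod) / streams$feed_cod
}

#' Mass balance closure
#'
#' Methane, gaseous CO2, dissolved CO2 and freeze-dried slurry solids leaving
#' the reactor, as a percentage of the dry feedstock added per day.
#'
#' @param streams A [balance_streams()] row.
#' @return Recovery, percent.
#' @export
mass_recovery <- function(streams) {
  stopifnot(inherits(streams, "balance_streams"))
  if (streams$feed_solids <= 0) {
    stop_domain("feed_solids must be > 0", "thermodigest_domain_error")
  }
  100 * (streams$ch4_mass + streams$co2_gas_mass +
    streams$co2_dissolved_mass + streams$slurry_dry_mass) / streams$feed_solids
}

#' Dissolved CO2 concentration from headspace composition
#'
#' Simplified carbonate-system estimate: aqueous CO2 from Henry's law at the
#' headspace CO2 partial pressure, plus bicarbonate from the first carbonate
#' dissociation at the measured pH (carbonate itself is negligible below
#' pH ~9 and is ignored). Returns total dissolved inorganic carbon expressed
#' as g CO2 per litre of broth; multiply by the daily withdrawn volume
#' (reactor volume / RT) to get the `co2_dissolved_mass` stream.
#'
#' Defaults are for thermophilic operation at 55 degC: Henry constant
#' 0.0164 mol/(L atm) and first dissociation pKa1 = 6.30.
#'
#' @param co2_frac CO2 mole fraction of the headspace gas.
#' @param ph Broth pH.
#' @param pressure_atm Total headspace pressure, atm.
#' @param henry_mol_per_l_atm Henry's-law constant for CO2, mol/(L atm).
#' @param pka1 First carbonate dissociation pKa.
#' @return Dissolved CO2 (CO2(aq) + HCO3-, as CO2 mass), g/L.
#' @export
dissolved_co2_concentration <- function(co2_frac, ph, pressure_atm = 1,
                                        henry_mol_per_l_atm = 0.0164,
                                        pka1 = 6.30) {
  if (any(co2_frac < 0) || any(co2_frac > 1)) {
    stop_domain("co2_frac must lie in [0, 1]", "thermodigest_domain_error")
  }
  if (any(ph < 0) || any(ph > 14)) {
    stop_domain("ph must lie in [0, 14]", "thermodigest_domain_error")
  }
  co2_aq <- henry_mol_per_l_atm * co2_frac * pressure_atm # mol/L
  hco3 <- co2_aq * 10^(ph - pka1)
  44.01 * (co2_aq + hco3)
}
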