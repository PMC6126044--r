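#' Configure a semi-continuous reactor simulation
#'
#' Describes one simulated digester: feed, residence time, feeding protocol
#' and the two-pool solubilization kinetics it obeys. The feeding protocol
#' replaces `replaced_fraction` of the working volume per event,
#' `feeds_per_rt` times per residence time; the two must multiply to 1 so
#' the nominal residence time (volume / volume fed per day) equals
#' `rt_days`.
#'
#' @param rt_days Residence time, days.
#' @param k First-order rate constant of the accessible pool, 1/day.
#' @param f_r Recalcitrant fraction of entering carbohydrate.
#' @param feed_composition A [feedstock_composition()].
#' @param feed_solids Solids loading of the feed medium, g/L.
#' @param volume Working volume, L (bookkeeping only; the state is tracked
#'   per litre).
#' @param feeds_per_rt Feed events per residence time.
#' @param replaced_fraction Fraction of volume replaced per event.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise applied to measured FCS.
#' @param seed RNG seed for the measurement noise.
#' @return A list of class `reactor_config`.
#' @export
reactor_config <- function(rt_days, k, f_r,
                           feed_composition = feedstock_composition(
                             0.306, 0.229, 0.0407, 0.0605, 0.0592, 1.22),
                           feed_solids = 30, volume = 1,
                           feeds_per_rt = 10, replaced_fraction = 0.10,
                           noise_cv = 0, seed = 1) {
  problems <- character(0)
  if (!is.finite(rt_days) || rt_days <= 0) problems <- c(problems, "rt_days must be > 0")
  if (!is.finite(k) || k < 0) problems <- c(problems, "k must be >= 0")
  if (!is.finite(f_r) || f_r < 0 || f_r >= 1) problems <- c(problems, "f_r must lie in [0, 1)")
  if (!is.finite(feed_solids) || feed_solids <= 0) problems <- c(problems, "feed_solids must be > 0")
  if (!is.finite(replaced_fraction) || replaced_fraction <= 0 ||
      replaced_fraction >= 1) {
    problems <- c(problems, "replaced_fraction must lie in (0, 1)")
  }
  if (!is.finite(feeds_per_rt) || feeds_per_rt < 1 ||
      feeds_per_rt != round(feeds_per_rt)) {
    problems <- c(problems, "feeds_per_rt must be a positive integer")
  }
  if (length(problems) == 0 &&
      abs(feeds_per_rt * replaced_fraction - 1) > 1e-9) {
    problems <- c(problems,
      "feeds_per_rt * replaced_fraction must equal 1 (nominal residence-time consistency)")
  }
  if (!is.finite(noise_cv) || noise_cv < 0) problems <- c(problems, "noise_cv must be >= 0")
  if (length(problems) > 0) {
    stop_domain(paste0("invalid reactor config: ",
      paste(problems, collapse = "; ")), "thermodigest_config_error")
  }
  structure(
    list(
      rt_days = rt_days, k = k, f_r = f_r,
      feed_composition = feed_composition, feed_solids = feed_solids,
      volume = volume, feeds_per_rt = as.integer(feeds_per_rt),
      replaced_fraction = replaced_fraction, noise_cv = noise_cv,
      seed = seed,
      c0 = feed_carbohydrate_concentration(feed_composition, feed_solids)
    ),
    class = "reactor_config"
  )
}

#' Simulate a semi-continuously fed digester
#'
#' Two-pool state per litre of broth: an accessible carbohydrate pool `A`
#' that decays first-order (`dA/dt = -k A`) between feed events, and an
#' inert recalcitrant pool `R`. Each feed event removes `replaced_fraction`
#' of both pools with the withdrawn slurry and adds feed carbohydrate,
#' `C0 (1 - f_r)` to the accessible and `C0 f_r` to the recalcitrant pool
#' per litre added. The reactor starts charged with one feed's worth of
#' substrate (`A = C0 (1 - f_r)`, `R = C0 f_r`).
#'
#' Two FCS readouts are reported per interval. `fcs` is the instantaneous
#' value at sampling time (just before the feed event) — what an assay of
#' the withdrawn slurry measures — and `fcs_measured` is the same with
#' multiplicative Gaussian noise (CV `noise_cv`, truncated to `[0, 1]`).
#' `fcs_interval_mean` is the time-average of `1 - (A(t) + R)/C0` over the
#' inter-feed interval, the quantity to compare with the continuous-washout
#' closed form of [predict_steady_state_fcs()].
#'
#' @param config A [reactor_config()].
#' @param n_rts Number of residence times to simulate (>= 1).
#' @return A tibble with one row per feed interval: `event`, `time` (days,
#'   at sampling), `c_accessible`, `c_recalcitrant` (g/L, at sampling),
#'   `fcs`, `fcs_measured`, `fcs_interval_mean`, `rate` (g/L/day solubilized
#'   over the interval), `feed_in`, `removed_mass` (g per litre of working
#'   volume), `a_post`, `r_post` (pools just after feeding).
#' @export
simulate_reactor <- function(config, n_rts) {
  stopifnot(inherits(config, "reactor_config"))
  if (!is.finite(n_rts) || n_rts < 1) {
    stop_domain("n_rts must be >= 1", "thermodigest_config_error")
  }
  c0 <- config$c0
  k <- config$k
  f <- config$replaced_fraction
  dt <- config$rt_days / config$feeds_per_rt
  n_events <- as.integer(round(n_rts * config$feeds_per_rt))
  decay <- exp(-k * dt)
  # time-average of exp(-k t) over one interval
  avg_factor <- if (k > 0) (1 - decay) / (k * dt) else 1

  a <- c0 * (1 - config$f_r)
  r <- c0 * config$f_r
  a_start <- a_end <- a_mean <- r_pre <- a_post_v <- r_post_v <-
    numeric(n_events)
  for (i in seq_len(n_events)) {
    a_start[i] <- a
    a_end[i] <- a * decay
    a_mean[i] <- a * avg_factor
    r_pre[i] <- r
    a_post_v[i] <- a_end[i] * (1 - f) + f * c0 * (1 - config$f_r)
    r_post_v[i] <- r * (1 - f) + f * c0 * config$f_r
    a <- a_post_v[i]
    r <- r_post_v[i]
  }
  fcs_inst <- 1 - (a_end + r_pre) / c0
  fcs_meas <- fcs_inst
  if (config$noise_cv > 0) {
    with_seed(config$seed, {
      fcs_meas <- pmin(pmax(
        fcs_inst * (1 + rnorm(n_events, 0, config$noise_cv)), 0), 1)
    })
  }
  out <- tibble(
    event = seq_len(n_events), time = seq_len(n_events) * dt,
    c_accessible = a_end, c_recalcitrant = r_pre,
    fcs = fcs_inst, fcs_measured = fcs_meas,
    fcs_interval_mean = 1 - (a_mean + r_pre) / c0,
    rate = (a_start - a_end) / dt,
    feed_in = f * c0, removed_mass = f * (a_end + r_pre),
    a_post = a_post_v, r_post = r_post_v
  )
  attr(out, "config") <- config
  out
}

#' Steady-state summary of a reactor simulation
#'
#' Averages the last `n_cycles` full feeding cycles of a simulation (by
#' default everything after a `burnin_rts`-residence-time transient).
#' `fcs_cycle_mean` is the time-averaged FCS (for comparison with the
#' continuous closed form); `fcs_sampled_mean` averages the noisy sampled
#' measurements (what a steady-state data table reports).
#'
#' @param sim Output of [simulate_reactor()].
#' @param burnin_rts Residence times discarded as transient.
#' @return A one-row tibble: `rt_days`, `fcs_cycle_mean`,
#'   `fcs_sampled_mean`, `fcs_sampled_sd`, `n_samples`.
#' @export
steady_state_summary <- function(sim, burnin_rts = 3) {
  config <- attr(sim, "config")
  stopifnot(!is.null(config))
  keep <- sim$time > burnin_rts * config$rt_days + 1e-9
  if (!any(keep)) {
    stop_domain("simulation shorter than the burn-in period",
      "thermodigest_domain_error")
  }
  s <- sim[keep, ]
  tibble(
    rt_days = config$rt_days,
    fcs_cycle_mean = mean(s$fcs_interval_mean),
    fcs_sampled_mean = mean(s$fcs_measured),
    fcs_sampled_sd = stats::sd(s$fcs_measured),
    n_samples = nrow(s)
  )
}

#' Generate a steady-state solubilization dataset
#'
#' Runs one simulated reactor per configuration, discards a 3-residence-time
#' burn-in, and reports the per-RT mean of the sampled (noisy) FCS
#' measurements — the synthetic analogue of a steady-state data summary
#' table, ready for [steady_state_points()] and
#' [fit_recalcitrant_first_order()]. The generating parameters are attached
#' as the `truth` attribute.
#'
#' @param configs List of [reactor_config()] objects covering at least 3
#'   distinct residence times.
#' @param n_rts Residence times to simulate per reactor (must exceed
#'   `burnin_rts`).
#' @param burnin_rts Residence times discarded before averaging.
#' @return A tibble with columns `reactor_id`, `rt_days`, `fcs_total`,
#'   `fcs_sd`, `n_samples`; attribute `truth` is a list `(k, f_r, c0)`.
#' @export
generate_steady_state_dataset <- function(configs, n_rts = 5,
                                          burnin_rts = 3) {
  if (inherits(configs, "reactor_config")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1), "reactor_config")))
  rts <- vapply(configs, `[[`, numeric(1), "rt_days")
  if (dplyr::n_distinct(rts) < 3) {
    stop_domain("need configurations at >= 3 distinct residence times",
      "thermodigest_domain_error")
  }
  obs <- purrr::imap(configs, function(cfg, i) {
    s <- steady_state_summary(simulate_reactor(cfg, n_rts), burnin_rts)
    tibble(
      reactor_id = sprintf("sim%02d", i), rt_days = cfg$rt_days,
      fcs_total = s$fcs_sampled_mean, fcs_sd = s$fcs_sampled_sd,
      n_samples = s$n_samples
    )
  }) |> purrr::list_rbind()
  attr(obs, "truth") <- list(
    k = configs[[1]]$k, f_r = configs[[1]]$f_r, c0 = configs[[1]]$c0
  )
  obs
}

#' Balance streams implied by a simulated reactor
#'
#' Converts a steady-state simulation into daily [balance_streams()] under a
#' fixed, loss-free digestion stoichiometry: solubilized carbohydrate
#' (glucose equivalent, C6H12O6) is fully converted to an equimolar
#' methane/carbon-dioxide biogas (C6H12O6 -> 3 CH4 + 3 CO2, i.e. 48 g CH4
#' and 132 g CO2 per 180 g monomer), the withdrawn slurry carries all
#' unsolubilized dry matter, and slurry COD is the feed COD minus the COD
#' of the solubilized carbohydrate (192/180 g COD per g monomer). Because
#' nothing is lost, both [mass_recovery()] and [cod_recovery()] close at
#' 100% exactly; the function exists to exercise the balance accounting
#' against a conservation oracle.
#'
#' @param sim Output of [simulate_reactor()].
#' @param burnin_rts Residence times discarded as transient.
#' @return A [balance_streams()] row (g/day).
#' @export
reactor_balance_streams <- function(sim, burnin_rts = 3) {
  config <- attr(sim, "config")
  stopifnot(!is.null(config))
  s <- steady_state_summary(sim, burnin_rts)
  vol_fed_per_day <- config$volume / config$rt_days
  feed_solids_day <- config$feed_solids * vol_fed_per_day
  feed_cod_day <- feed_solids_day * config$feed_composition$cod_per_gram
  # exact steady-state mass balance: solubilized = fed - withdrawn carbohydrate
  solub_day <- config$c0 * s$fcs_sampled_mean * vol_fed_per_day
  ch4 <- solub_day * 48 / 180
  co2 <- solub_day * 132 / 180
  balance_streams(
    feed_solids = feed_solids_day,
    feed_cod = feed_cod_day,
    ch4_mass = ch4,
    co2_gas_mass = co2,
    co2_dissolved_mass = 0,
    slurry_dry_mass = feed_solids_day - solub_day,
    slurry_cod = feed_cod_day - solub_day * 192 / 180
  )
}
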