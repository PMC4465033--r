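#' Enteric methane yield of forage dry matter
#'
#' Emission rate in g CH4 per kg forage dry matter as a linear, decreasing
#' function of forage metabolisable energy: higher-quality forage ferments
#' to less methane per kg.  Concentrate emits at this rate divided by the
#' configured divisor (default 150).
#'
#' @param forage_me Forage metabolisable energy, MJ/kg DM.
#' @param config A configuration list from [run_config()].
#' @return g CH4 per kg forage DM.
#' @export
forage_ch4_rate <- function(forage_me, config = sim_defaults()) {
  mp <- config$methane
  mp$rate_at_me_min + mp$rate_slope * (forage_me - mp$me_ref)
}

#' Daily methane emission from intake
#'
#' `forage_dmi * rate + concentrate_dmi * rate / 150`: methane production
#' from concentrate is 150 times lower than from forage on a dry-matter
#' basis.  Vectorised.
#'
#' @param forage_dmi,concentrate_dmi Intakes in kg DM/day.
#' @param rate Forage emission rate (g CH4/kg DM), from
#'   [forage_ch4_rate()].
#' @param config A configuration list from [run_config()].
#' @return g CH4 per day.
#' @export
daily_methane <- function(forage_dmi, concentrate_dmi,
                          rate = forage_ch4_rate(10.5), config = sim_defaults()) {
  rate * (forage_dmi + concentrate_dmi / config$methane$concentrate_divisor)
}

#' Herd methane including the replacement-rearing uplift
#'
#' Scales the summed cow emissions by a replacement-heifer uplift
#' proportional to the herd's realised replacement rate: at the commercial
#' baseline rate (default 0.25/year) heifers contribute 27% of the herd
#' total, so the uplift factor is `(0.27/0.73) * (rate / 0.25)`.  A herd
#' that culls no cow rears no heifers and gets no uplift; scenario-driven
#' changes in culling therefore move herd methane through this term.
#'
#' @param cow_ch4_g Total methane of the milking herd over the horizon (g).
#' @param culls Number of culls over the horizon.
#' @param n_cows Herd size.
#' @param config A configuration list from [run_config()].
#' @return Total herd methane in g.
#' @export
herd_methane <- function(cow_ch4_g, culls, n_cows, config = sim_defaults()) {
  mp <- config$methane
  years <- config$timing$horizon / 365
  rate <- culls / (n_cows * years)
  uplift <- (mp$heifer_share / (1 - mp$heifer_share)) *
    (rate / mp$commercial_replacement_rate)
  cow_ch4_g * (1 + uplift)
}

## Aggregate all cow slots of a herd under one scenario into totals.
## One vectorised production pass per herd-scenario: milking-day vectors are
## assembled across every lactation segment, then milk, intake and methane
## are computed in bulk.
simulate_scenario_totals <- function(cows, herd, scenario, config,
                                     herd_eff = herd_conception_effect(herd, config)) {
  ik <- config$intake
  seg_from <- integer(0); seg_to <- integer(0)
  seg_yield <- numeric(0); seg_parity <- integer(0)
  seg_cal0 <- numeric(0); seg_cdim <- numeric(0)
  dry_days <- 0
  services <- 0L; culls <- 0L
  first_forced <- numeric(0)
  for (cw in cows) {
    slot <- simulate_cow(cw, herd, scenario, config, herd_eff)
    services <- services + slot$services
    culls <- culls + slot$culls
    for (id in slot$identities) {
      for (lc in id$lactations) {
        if (lc$milk_end >= 1) {
          seg_from <- c(seg_from, 1L)
          seg_to <- c(seg_to, as.integer(lc$milk_end))
          seg_yield <- c(seg_yield, lc$yield)
          seg_parity <- c(seg_parity, lc$parity)
          seg_cal0 <- c(seg_cal0, lc$cal0)
          seg_cdim <- c(seg_cdim,
                        if (is.na(lc$conception_dim)) Inf
                        else round(lc$conception_dim))
        }
        dry_days <- dry_days + lc$dry_days
      }
    }
  }
  if (length(seg_from)) {
    n <- seg_to - seg_from + 1L
    dims <- sequence(n, from = seg_from)
    sid <- rep.int(seq_along(n), n)
    doy <- (seg_cal0[sid] + dims) %% 365
    dp <- pmax(0, dims - seg_cdim[sid])
    dp[!is.finite(dp)] <- 0
    milk <- milk_yield(dims, seg_yield[sid], seg_parity[sid], doy, dp, config)
    dmi <- dry_matter_intake(dims, milk, config, warn = FALSE)
    milk_total <- sum(milk)
    conc_total <- sum(dmi$concentrate)
    forage_total <- sum(dmi$forage)
  } else {
    milk_total <- conc_total <- forage_total <- 0
  }
  forage_total <- forage_total + dry_days * ik$base_dmi
  anoe <- vapply(cows, function(cw) cw$anoestrus_length + 1 > herd$vwp,
                 logical(1))
  rate <- forage_ch4_rate(herd$forage_me, config)
  cow_ch4 <- daily_methane(forage_total, conc_total, rate, config)
  structure(list(
    scenario = scenario, n_cows = length(cows),
    total_milk_l = milk_total, total_services = services, culls = culls,
    forage_dmi_kg = forage_total, concentrate_dmi_kg = conc_total,
    cow_ch4_g = cow_ch4,
    total_ch4_g = herd_methane(cow_ch4, culls, length(cows), config),
    anoestrous_at_vwp_end = mean(anoe)
  ), class = "herd_outcome")
}

#' Cost difference between an intervention and baseline
#'
#' The change in non-tangible cost per cow per year: the change in milk
#' sold valued at the herd milk margin and the change in inseminations at
#' the serve cost, each per cow-year over the two-year horizon, plus the
#' change in the proportion of cows culled charged at the cull
#' (depreciation) cost.  The cull term is a change in a risk, not a flow,
#' so by default it is not annualised; set `costs$annualize_culls` to divide
#' it by the horizon years as well.  Negative values are savings.  Drug
#' costs are not included here (see `d_cost_net` in [simulate_herd()]).
#'
#' @param baseline,scenario `herd_outcome` objects for the same cow
#'   population.
#' @param herd A `herd_params` object supplying the unit costs.
#' @param config A configuration list from [run_config()].
#' @return GBP per cow per year (signed; negative = saving).
#' @export
cost_delta <- function(baseline, scenario, herd, config = sim_defaults()) {
  if (baseline$n_cows != scenario$n_cows) {
    stop("outcomes come from different cow populations", call. = FALSE)
  }
  years <- config$costs$years
  cow_years <- baseline$n_cows * years
  d_milk <- scenario$total_milk_l - baseline$total_milk_l
  d_serv <- scenario$total_services - baseline$total_services
  d_cull_prop <- (scenario$culls - baseline$culls) / baseline$n_cows
  if (config$costs$annualize_culls) d_cull_prop <- d_cull_prop / years
  (-d_milk * herd$milk_margin + d_serv * herd$serve_cost) / cow_years +
    d_cull_prop * herd$cull_cost
}

#' Methane difference per litre of milk
#'
#' Difference in herd methane intensity, `g CH4 per L`, between an
#' intervention and baseline.  Negative values are reductions.
#'
#' @param baseline,scenario `herd_outcome` objects.
#' @return g CH4 per L milk (signed).
#' @export
methane_delta_per_l <- function(baseline, scenario) {
  if (baseline$total_milk_l <= 0 || scenario$total_milk_l <= 0) {
    stop("cannot compute methane intensity with zero milk", call. = FALSE)
  }
  scenario$total_ch4_g / scenario$total_milk_l -
    baseline$total_ch4_g / baseline$total_milk_l
}

#' Simulate one herd under a set of scenarios
#'
#' Generates the herd's cow population once, replays it under the baseline
#' and each requested intervention using the shared random-number contract,
#' and returns the per-scenario outcomes together with the
#' intervention-minus-baseline deltas (cost per cow per year, gross and net
#' of drug cost; methane per litre of milk).
#'
#' @param herd A `herd_params` object.
#' @param n_cows Herd size (default 200).
#' @param scenarios Character vector of scenarios; `"baseline"` is always
#'   included.
#' @param seed Integer seed for the herd's cow population.
#' @param config A configuration list from [run_config()].
#' @return A list with elements `outcomes` (named list of `herd_outcome`)
#'   and `deltas` (data.frame, one row per intervention).
#' @examples
#' h <- herd_params()
#' r <- simulate_herd(h, n_cows = 20, scenarios = "ovsynch", seed = 1)
#' r$deltas
#' @export
simulate_herd <- function(herd, n_cows = 200,
                          scenarios = c("ovsynch", "ovsynch_p4", "double_pg"),
                          seed = 1L, config = sim_defaults()) {
  scenarios <- setdiff(scenarios, "baseline")
  cows <- assign_cow_attributes(herd, n_cows, config, seed)
  herd_eff <- herd_conception_effect(herd, config)
  outs <- list(baseline = simulate_scenario_totals(cows, herd, "baseline",
                                                   config, herd_eff))
  for (sc in scenarios) {
    outs[[sc]] <- simulate_scenario_totals(cows, herd, sc, config, herd_eff)
  }
  deltas <- NULL
  if (length(scenarios)) {
    rows <- lapply(scenarios, function(sc) {
      dc <- cost_delta(outs$baseline, outs[[sc]], herd, config)
      data.frame(scenario = sc,
                 d_cost = dc,
                 d_cost_net = dc + config$scenarios[[sc]]$drug_cost,
                 d_ch4_per_l = methane_delta_per_l(outs$baseline, outs[[sc]]))
    })
    deltas <- do.call(rbind, rows)
  }
  list(outcomes = outs, deltas = deltas)
}

#' @export
print.herd_outcome <- function(x, ...) {
  cat(sprintf("<herd_outcome: %s> %d cows, %.0f L milk, %d services, %d culls, %.1f kg CH4\n",
              x$scenario, x$n_cows, x$total_milk_l, x$total_services,
              x$culls, x$total_ch4_g / 1000))
  invisible(x)
}
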