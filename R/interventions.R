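#' Scenario specification
#'
#' Returns the constants defining one management programme: drug cost per
#' cow, the conception-multiplier distribution, and programme-specific
#' constants (progesterone resumption boost; prostaglandin oestrus efficacy
#' and maximum injections), together with the shared timing constants
#' (programmed AI window, batch interval).
#'
#' @param name One of `"baseline"`, `"ovsynch"`, `"ovsynch_p4"`,
#'   `"double_pg"`.
#' @param config A configuration list from [run_config()].
#' @return A named list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, config = sim_defaults()) {
  spec <- config$scenarios[[name]]
  if (is.null(spec)) stop("unknown scenario: ", name, call. = FALSE)
  tm <- config$timing
  structure(c(list(name = name,
                   forced_first_ai = name %in% c("ovsynch", "ovsynch_p4"),
                   first_ai_window = c(tm$forced_ai_from,
                                       tm$forced_ai_from + tm$batch_interval),
                   batch_interval = tm$batch_interval),
              spec),
            class = "scenario_spec")
}

#' All scenario names
#' @export
scenario_names <- function() c("baseline", "ovsynch", "ovsynch_p4", "double_pg")

#' Programmed first-insemination day on the herd batch calendar
#'
#' Treatments are applied in fortnightly batches anchored on herd day 0, so
#' the programmed first AI falls on the earliest batch day at or after 50
#' days in milk, i.e. between 50 and 63 DIM depending on where the calving
#' falls on the 14-day grid.
#'
#' @param calving_herd_day Herd-calendar day of the calving.
#' @param config A configuration list from [run_config()].
#' @return Days in milk of the programmed AI, in `[50, 64)`.
#' @export
batch_ai_day <- function(calving_herd_day, config = sim_defaults()) {
  tm <- config$timing
  from <- tm$forced_ai_from
  iv <- tm$batch_interval
  from + ((-(calving_herd_day + from)) %% iv)
}

#' Treatment plan for the Ovsynch programme
#'
#' Every cow receives a programmed first AI on the herd's batch calendar
#' regardless of the voluntary waiting period, with the cycle reset on the
#' treatment day and the conception risk scaled by a mode-0.8 beta
#' multiplier.  A cow still anoestrous at 64 DIM is served but cannot
#' conceive to the programmed AI.
#'
#' @param cow A `cow_attributes` object.
#' @param herd A `herd_params` object.
#' @param lact Lactation number within the identity (indexes the cow's
#'   pre-drawn scenario slots).
#' @param config A configuration list from [run_config()].
#' @param anoestrus Post-partum anoestrus length for this lactation
#'   (defaults to the cow's first-lactation draw).
#' @param calving_herd_day Herd-calendar day of this lactation's calving
#'   (defaults to the cow's initial calving day).
#' @return A list: `forced_ai_dim`, `fertile`, `infertile_at_forced_ai`,
#'   `boosted`, `multiplier`.
#' @export
apply_ovsynch <- function(cow, herd, lact = 1L, config = sim_defaults(),
                          anoestrus = cow$anoestrus_length,
                          calving_herd_day = cow$calving_doy) {
  tm <- config$timing
  f <- batch_ai_day(calving_herd_day, config)
  cutoff <- tm$forced_ai_from + tm$batch_interval   # resumed-by-64 rule
  fertile <- (anoestrus + 1) <= cutoff
  mult <- multiplier_from_u(cow$u_mult[lact, "ovsynch"],
                            config$scenarios$ovsynch$multiplier,
                            config$beta_lambda)
  list(forced_ai_dim = f, fertile = fertile,
       infertile_at_forced_ai = !fertile, boosted = FALSE, multiplier = mult)
}

#' Treatment plan for Ovsynch with supplementary progesterone
#'
#' As [apply_ovsynch()], with two differences: the conception multiplier is
#' drawn from a mode-0.96 beta on `[0.96, 1.02]`, and a multiparous cow that
#' would still be anoestrous at 64 DIM resumes cyclicity (and is fertile at
#' the programmed AI) with probability 0.05.
#'
#' @inheritParams apply_ovsynch
#' @param parity Current parity (the resumption boost applies to multiparous
#'   cows only).
#' @return As [apply_ovsynch()], with `boosted` indicating a progesterone
#'   induced resumption.
#' @export
apply_ovsynch_p4 <- function(cow, herd, lact = 1L, parity = cow$parity,
                             config = sim_defaults(),
                             anoestrus = cow$anoestrus_length,
                             calving_herd_day = cow$calving_doy) {
  tm <- config$timing
  sp <- config$scenarios$ovsynch_p4
  f <- batch_ai_day(calving_herd_day, config)
  cutoff <- tm$forced_ai_from + tm$batch_interval
  fertile <- (anoestrus + 1) <= cutoff
  boosted <- FALSE
  if (!fertile && parity >= 2 && cow$u_boost[lact] < sp$resumption_boost) {
    fertile <- TRUE
    boosted <- TRUE
  }
  mult <- multiplier_from_u(cow$u_mult[lact, "ovsynch_p4"],
                            sp$multiplier, config$beta_lambda)
  list(forced_ai_dim = f, fertile = fertile,
       infertile_at_forced_ai = !fertile, boosted = boosted, multiplier = mult)
}

#' Treatment plan for the double-prostaglandin programme
#'
#' Cows not yet inseminated by the first batch day at or after 50 DIM
#' receive a prostaglandin injection, repeated once 14 days later if no
#' insemination follows.  Each injection induces oestrus with probability
#' 0.8 provided the cow's cycles have resumed; an induced oestrus is then
#' observed and served with the herd submission risk.  The conception risk
#' of a service following the programme is scaled by a uniform multiplier on
#' `[0.9, 1.1]`.
#'
#' @inheritParams apply_ovsynch
#' @param baseline_first_service_dim DIM of the cow's first service under
#'   baseline management (`NA` if never served); determines eligibility.
#' @return A list: `eligible`, `injection_dims` (length 0--2), `multiplier`.
#' @export
apply_double_pg <- function(cow, herd, baseline_first_service_dim = NA,
                            lact = 1L, config = sim_defaults()) {
  tm <- config$timing
  sp <- config$scenarios$double_pg
  b1 <- batch_ai_day(cow$calving_doy, config)
  eligible <- is.na(baseline_first_service_dim) ||
    baseline_first_service_dim >= b1
  inj <- if (eligible) b1 + (seq_len(sp$max_injections) - 1) * tm$batch_interval
         else numeric(0)
  inj <- inj[inj <= tm$breeding_end]
  mult <- multiplier_from_u(cow$u_mult[lact, "double_pg"],
                            sp$multiplier, config$beta_lambda)
  list(eligible = eligible, injection_dims = inj, multiplier = mult)
}
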