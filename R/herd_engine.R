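#' Timing constants of the reproductive state machine
#'
#' @param config A configuration list from [run_config()].
#' @return Named list: horizon (730 d), gestation (280 d), dry-off lead
#'   (60 d), end of breeding (300 DIM), replacement lag (60 d), treatment
#'   batch interval (14 d), earliest programmed AI (50 DIM).
#' @export
timing_constants <- function(config = sim_defaults()) config$timing

#' Oestrus calendar of a cow within one lactation
#'
#' Cows are in oestrus on day 1 of each ovarian cycle: the first oestrus
#' falls on the day after post-partum anoestrus ends, and subsequent oestrus
#' events recur every cycle length until the end of the breeding window.
#'
#' @param anoestrus_length Days of post-partum anoestrus.
#' @param cycle_length Oestrous cycle length in days.
#' @param horizon Last DIM considered (default 300, end of breeding).
#' @return Numeric vector of oestrus days (DIM).
#' @examples
#' oestrus_calendar(25, 21)[1:3]   # 26, 47, 68
#' @export
oestrus_calendar <- function(anoestrus_length, cycle_length, horizon = 300) {
  first <- anoestrus_length + 1
  if (first > horizon) return(numeric(0))
  seq(first, horizon, by = cycle_length)
}

## cached 305-day sums of the Wood kernel t^b exp(-c t)
.wood_cache <- new.env(parent = emptyenv())
wood_sum <- function(b, c) {
  key <- paste(b, c)
  s <- .wood_cache[[key]]
  if (is.null(s)) {
    t <- 1:305
    s <- sum(t^b * exp(-c * t))
    .wood_cache[[key]] <- s
  }
  s
}

#' Daily milk yield
#'
#' Wood lactation curve `a * t^b * exp(-c t)` with parity-specific shape
#' (primiparous cows flatter and more persistent), the scale `a` solved so
#' that the 305-day total of a non-pregnant cow equals her 305-d yield; a
#' sinusoidal seasonal multiplier peaking in spring; and a multiplicative
#' late-gestation depression.  Vectorised over all arguments.
#'
#' @param dim Days in milk (yield is 0 for `dim < 1`).
#' @param yield_305d 305-day yield in thousand kg.
#' @param parity Parity (1 = primiparous shape, otherwise multiparous).
#' @param doy Day of year (0-based) for the seasonal term; `NA` disables it.
#' @param days_pregnant Days pregnant (0 if open).
#' @param config A configuration list from [run_config()].
#' @return Daily yield in litres.
#' @export
milk_yield <- function(dim, yield_305d, parity = 2, doy = NA,
                       days_pregnant = 0, config = sim_defaults()) {
  lc <- config$lactation
  primi <- parity == 1
  b <- ifelse(primi, lc$wood_b[["primiparous"]], lc$wood_b[["multiparous"]])
  cc <- ifelse(primi, lc$wood_c[["primiparous"]], lc$wood_c[["multiparous"]])
  s <- ifelse(primi,
              wood_sum(lc$wood_b[["primiparous"]], lc$wood_c[["primiparous"]]),
              wood_sum(lc$wood_b[["multiparous"]], lc$wood_c[["multiparous"]]))
  a <- yield_305d * 1000 / s
  y <- a * dim^b * exp(-cc * dim)
  season <- ifelse(is.na(doy), 1,
                   1 + lc$season_amplitude *
                     cos(2 * pi * ((doy %% 365) - lc$season_peak_doy) / 365))
  over <- pmax(0, days_pregnant - lc$preg_depression_onset)
  dep <- pmax(lc$preg_depression_floor, 1 - lc$preg_depression_rate * over)
  out <- y * season * dep
  out[dim < 1] <- 0
  out
}

#' Daily dry-matter intake and its forage/concentrate partition
#'
#' Total intake follows stage of lactation and milk yield: a base allowance
#' plus a per-litre increment, ramping up linearly over early lactation.
#' Concentrate is fed at a fixed fresh rate per litre above the yield that
#' forage alone supports, at 90% dry matter; forage intake is the remainder,
#' clipped at zero (with a warning) if concentrate would exceed the total.
#'
#' @param dim Days in milk.
#' @param milk_l Daily milk yield in litres (0 when dry).
#' @param config A configuration list from [run_config()].
#' @param warn Warn when concentrate exceeds the total allowance and forage
#'   is clipped to zero (high-yielding cows in very early lactation); the
#'   bulk simulation path silences this and the clipped days remain visible
#'   in the returned intakes.
#' @return List of numeric vectors `total`, `concentrate`, `forage`
#'   (kg DM/day).
#' @examples
#' dry_matter_intake(150, 30)$concentrate   # 0.36 * 20 = 7.2
#' @export
dry_matter_intake <- function(dim, milk_l, config = sim_defaults(),
                              warn = TRUE) {
  ik <- config$intake
  ramp <- pmin(1, ik$ramp_start + (1 - ik$ramp_start) * dim / ik$ramp_dim)
  total <- ramp * (ik$base_dmi + ik$dmi_per_l * milk_l)
  concentrate <- ik$conc_per_l * ik$conc_dm * pmax(0, milk_l - ik$conc_threshold_l)
  forage <- total - concentrate
  if (any(forage < 0)) {
    if (warn) {
      warning("forage intake clipped to zero on ", sum(forage < 0), " day(s)")
    }
    forage <- pmax(forage, 0)
  }
  list(total = total, concentrate = concentrate, forage = forage)
}

## ---------------------------------------------------------------------------
## Reproductive event simulation
## ---------------------------------------------------------------------------

## Natural-oestrus breeding loop shared by all scenarios.  Oestrus events at
## first_o + j*cyc; a submission draw is consumed at every eligible oestrus
## (>= min_dim); a conception draw at every service.  Stops before processing
## an oestrus at or beyond `stop_before` so a caller can splice in a
## programme and resume with identical draw indexing.
natural_breeding <- function(first_o, cyc, k, m, min_dim, end,
                             stop_before = Inf, cow, herd, pconc) {
  services <- numeric(0)
  o <- first_o
  lact_row <- attr(pconc, "lact")
  repeat {
    if (o > end) {
      return(list(status = "end", conception_dim = NA_real_, k = k, m = m,
                  services = services, resume_o = o))
    }
    if (o >= stop_before) {
      return(list(status = "stopped", conception_dim = NA_real_, k = k, m = m,
                  services = services, resume_o = o))
    }
    if (o >= min_dim) {
      k <- k + 1L
      if (k > N_EVENTS) {
        return(list(status = "end", conception_dim = NA_real_, k = k, m = m,
                    services = services, resume_o = o))
      }
      if (cow$u_subm[lact_row, k] < herd$submission_risk) {
        m <- m + 1L
        if (m > N_EVENTS) {
          return(list(status = "end", conception_dim = NA_real_, k = k, m = m,
                      services = services, resume_o = o))
        }
        services <- c(services, o)
        if (cow$u_conc[lact_row, m] < pconc(o)) {
          return(list(status = "pregnant", conception_dim = o, k = k, m = m,
                      services = services, resume_o = o))
        }
      }
    }
    o <- o + cyc
  }
}

## Simulate the breeding of one lactation under one scenario.  Returns the
## conception DIM (NA if open), the service days, and programme bookkeeping.
repro_lactation <- function(scenario, cow, herd, lact, parity, an, cyc,
                            yield, cal0, maxdim, herd_eff, config) {
  tm <- config$timing
  co <- config$conception$coefficients
  mscale <- config$conception$multiplier_scale
  end <- min(tm$breeding_end, maxdim)
  pconc <- function(dims, multiplier = 1, fertile = TRUE) {
    lp <- linear_predictor(parity, dims, yield,
                           is_summer(cal0 + dims),
                           herd_eff$offset, cow$cow_random_intercept, co)
    conception_probability(lp, multiplier * herd_eff$multiplier, fertile,
                           mscale)
  }
  attr(pconc, "lact") <- lact

  first_or_na <- function(x) if (length(x)) x[1] else NA_real_

  empty <- list(conception_dim = NA_real_, services = numeric(0),
                first_service = NA_real_, forced_ai_dim = NA_real_,
                infertile_at_forced_ai = FALSE, n_injections = 0L,
                induced_oestrus_dims = numeric(0))

  if (scenario == "baseline") {
    st <- natural_breeding(an + 1, cyc, 0L, 0L, herd$vwp, end,
                           cow = cow, herd = herd, pconc = pconc)
    return(modifyList(empty, list(conception_dim = st$conception_dim,
                                  services = st$services,
                                  first_service = first_or_na(st$services))))
  }

  if (scenario %in% c("ovsynch", "ovsynch_p4")) {
    plan <- if (scenario == "ovsynch") {
      apply_ovsynch(cow, herd, lact, config, anoestrus = an,
                    calving_herd_day = cal0)
    } else {
      apply_ovsynch_p4(cow, herd, lact, parity, config, anoestrus = an,
                       calving_herd_day = cal0)
    }
    f <- plan$forced_ai_dim
    if (f > end) return(empty)
    services <- f
    p <- pconc(f, plan$multiplier, plan$fertile)
    if (cow$u_conc[lact, 1] < p) {
      return(modifyList(empty, list(conception_dim = f, services = services,
                                    first_service = f, forced_ai_dim = f,
                                    infertile_at_forced_ai = !plan$fertile)))
    }
    ## repeats to observed oestrus; cycle reset at treatment if the cow was
    ## cyclic (or resumed), otherwise natural resumption after anoestrus
    first_o <- if (plan$fertile) f + cyc else an + 1
    st <- natural_breeding(first_o, cyc, 0L, 1L, 0, end,
                           cow = cow, herd = herd, pconc = pconc)
    return(modifyList(empty, list(conception_dim = st$conception_dim,
                                  services = c(services, st$services),
                                  first_service = f, forced_ai_dim = f,
                                  infertile_at_forced_ai = !plan$fertile)))
  }

  if (scenario == "double_pg") {
    b1 <- batch_ai_day(cal0, config)
    sspec <- config$scenarios$double_pg
    ## phase 1: baseline behaviour up to (not including) the first batch day
    ph1 <- natural_breeding(an + 1, cyc, 0L, 0L, herd$vwp, end,
                            stop_before = b1, cow = cow, herd = herd,
                            pconc = pconc)
    if (ph1$status == "pregnant" || length(ph1$services) > 0) {
      ## already inseminated before the programme: pure baseline lactation
      if (ph1$status == "stopped") {
        st <- natural_breeding(ph1$resume_o, cyc, ph1$k, ph1$m, herd$vwp, end,
                               cow = cow, herd = herd, pconc = pconc)
        return(modifyList(empty, list(
          conception_dim = st$conception_dim,
          services = c(ph1$services, st$services),
          first_service = ph1$services[1])))
      }
      return(modifyList(empty, list(conception_dim = ph1$conception_dim,
                                    services = ph1$services,
                                    first_service = ph1$services[1])))
    }
    if (ph1$status == "end" || b1 > end) {
      return(modifyList(empty, list(services = ph1$services)))
    }
    ## programme: up to two injections 14 days apart, oestrus induced with
    ## probability 0.8 in cows whose cycles have resumed
    k <- ph1$k; m <- ph1$m
    services <- numeric(0)
    mult <- multiplier_from_u(cow$u_mult[lact, "double_pg"],
                              sspec$multiplier, config$beta_lambda)
    last_reset <- NA_real_
    t_last <- NA_real_
    induced <- numeric(0)
    n_inj <- 0L
    for (inj in seq_len(sspec$max_injections)) {
      tinj <- b1 + (inj - 1) * config$timing$batch_interval
      if (tinj > end) break
      n_inj <- n_inj + 1L
      t_last <- tinj
      cyclic <- (an + 1 <= tinj) || !is.na(last_reset)
      if (cyclic && cow$u_pg[lact, inj] < sspec$oestrus_efficacy) {
        last_reset <- tinj
        induced <- c(induced, tinj)
        k <- k + 1L
        if (k > N_EVENTS) break
        if (cow$u_subm[lact, k] < herd$submission_risk) {
          m <- m + 1L
          if (m > N_EVENTS) break
          services <- c(services, tinj)
          if (cow$u_conc[lact, m] < pconc(tinj, mult)) {
            return(modifyList(empty, list(conception_dim = tinj,
                                          services = c(ph1$services, services),
                                          first_service = tinj,
                                          n_injections = n_inj,
                                          induced_oestrus_dims = induced)))
          }
          break   # inseminated: no further injections
        }
      }
    }
    ## revert to baseline behaviour
    if (!is.na(last_reset)) {
      st <- natural_breeding(last_reset + cyc, cyc, k, m, 0, end,
                             cow = cow, herd = herd, pconc = pconc)
    } else {
      ## never induced: natural calendar resumes after the last injection
      j <- max(0, ceiling((t_last - (an + 1)) / cyc + 1e-9))
      first_o <- an + 1 + j * cyc
      if (first_o <= t_last) first_o <- first_o + cyc
      st <- natural_breeding(first_o, cyc, k, m, herd$vwp, end,
                             cow = cow, herd = herd, pconc = pconc)
    }
    all_serv <- c(ph1$services, services, st$services)
    return(modifyList(empty, list(conception_dim = st$conception_dim,
                                  services = all_serv,
                                  first_service = first_or_na(all_serv),
                                  n_injections = n_inj,
                                  induced_oestrus_dims = induced)))
  }

  stop("unknown scenario: ", scenario, call. = FALSE)
}

## ---------------------------------------------------------------------------
## Identity and slot simulation
## ---------------------------------------------------------------------------

## Simulate one cow identity from its entry day until the horizon, a cull,
## or the last lactation slot.  Returns per-lactation records and totals.
sim_identity <- function(cow, herd, scenario, t_enter, herd_eff, config) {
  tm <- config$timing
  horizon_last <- tm$horizon - 1
  parity <- cow$parity
  t0 <- t_enter
  lacts <- list()
  services_total <- 0L
  culled <- FALSE
  cull_day <- NA_real_
  for (lact in seq_len(config$cow$max_lactations)) {
    maxdim <- horizon_last - t0
    if (maxdim < 1) break
    an <- if (lact == 1) cow$anoestrus_length else cow$an_redraw[lact - 1]
    cyc <- if (lact == 1) cow$cycle_length else cow$cyc_redraw[lact - 1]
    yield <- cow_yield_305d(cow, herd, parity, config)
    cal0 <- cow$calving_doy + t0
    rep <- repro_lactation(scenario, cow, herd, lact, parity, an, cyc,
                           yield, cal0, maxdim, herd_eff, config)
    services_total <- services_total + length(rep$services)
    pregnant <- !is.na(rep$conception_dim)
    d <- if (pregnant) round(rep$conception_dim) else NA_real_
    dry_from <- if (pregnant) d + tm$gestation - tm$dry_off else NA_real_
    milk_end <- if (pregnant) min(dry_from - 1, maxdim) else min(tm$breeding_end, maxdim)
    this_cull <- !pregnant && maxdim >= tm$breeding_end
    dry_days <- if (pregnant) max(0, min(d + tm$gestation - 1, maxdim) - dry_from + 1) else 0
    lacts[[lact]] <- list(t0 = t0, parity = parity, yield = yield,
                          cal0 = cal0, an = an, cyc = cyc,
                          conception_dim = rep$conception_dim,
                          services = rep$services,
                          milk_end = milk_end, dry_days = dry_days,
                          maxdim = maxdim, culled = this_cull,
                          forced_ai_dim = rep$forced_ai_dim,
                          infertile_at_forced_ai = rep$infertile_at_forced_ai,
                          n_injections = rep$n_injections,
                          induced_oestrus_dims = rep$induced_oestrus_dims)
    if (pregnant) {
      next_calving <- t0 + d + tm$gestation
      if (next_calving > horizon_last) break
      t0 <- next_calving
      parity <- parity + 1L
    } else {
      if (this_cull) {
        culled <- TRUE
        cull_day <- t0 + tm$breeding_end
      }
      break
    }
  }
  list(lactations = lacts, services = services_total,
       culled = culled, cull_day = cull_day)
}

#' Simulate one cow slot over the full horizon
#'
#' Follows a cow for the 730-day horizon under one management scenario,
#' through successive lactations and, if she is culled open at 300 days in
#' milk, through the replacement heifer (and recursively its replacement)
#' entering 60 days later.  All randomness comes from the identity's
#' pre-drawn block, so the same cow can be replayed under any scenario.
#'
#' @param cow A `cow_attributes` object from [make_cow()] or
#'   [assign_cow_attributes()].
#' @param herd A `herd_params` object.
#' @param scenario `"baseline"`, `"ovsynch"`, `"ovsynch_p4"` or
#'   `"double_pg"`.
#' @param config A configuration list from [run_config()].
#' @param herd_eff Herd-level conception effect; defaults to
#'   [herd_conception_effect()] under the configured linkage.
#' @return A list with one element per identity (`identities`), each holding
#'   per-lactation records, plus slot totals `services` and `culls`.
#' @export
simulate_cow <- function(cow, herd, scenario = "baseline",
                         config = sim_defaults(),
                         herd_eff = herd_conception_effect(herd, config)) {
  tm <- config$timing
  horizon_last <- tm$horizon - 1
  identities <- list()
  culls <- 0L
  services <- 0L
  cur <- cow
  t_enter <- 0
  repeat {
    res <- sim_identity(cur, herd, scenario, t_enter, herd_eff, config)
    res$t_enter <- t_enter
    res$cow <- cur
    identities[[length(identities) + 1L]] <- res
    services <- services + res$services
    if (!res$culled) break
    culls <- culls + 1L
    entry <- res$cull_day + tm$replacement_lag
    if (entry > horizon_last ||
        length(identities) > config$cow$max_replacements) break
    repl <- make_cow(cur$rep_seeds[1], herd, config, parity = 1L)
    repl$calving_doy <- cow$calving_doy
    cur <- repl
    t_enter <- entry
  }
  list(identities = identities, services = services, culls = culls)
}

#' Expand a simulated cow slot into a day-by-day trace
#'
#' Produces one row per day of the horizon with the days in milk, the
#' reproductive state (`anoestrus`, `cycling-open`, `pregnant`, `dry`,
#' `culled-gap`), service flags, and daily milk, intake and methane.  Mainly
#' a debugging and validation surface; the aggregate pipeline works on the
#' compact slot records.
#'
#' @param slot Result of [simulate_cow()].
#' @param herd A `herd_params` object.
#' @param config A configuration list from [run_config()].
#' @return A data.frame with `config$timing$horizon` rows.
#' @export
cow_trace <- function(slot, herd, config = sim_defaults()) {
  tm <- config$timing
  horizon <- tm$horizon
  day <- 0:(horizon - 1)
  state <- rep("culled-gap", horizon)   # days with no cow present
  dim <- rep(NA_real_, horizon)
  milk <- rep(0, horizon)
  service <- rep(FALSE, horizon)
  identity <- rep(NA_integer_, horizon)
  for (i in seq_along(slot$identities)) {
    id <- slot$identities[[i]]
    for (lc in id$lactations) {
      days <- (lc$t0):(lc$t0 + lc$maxdim)
      dims <- days - lc$t0
      st <- rep("cycling-open", length(days))
      st[dims <= lc$an] <- "anoestrus"
      if (!is.na(lc$conception_dim)) {
        d <- round(lc$conception_dim)
        st[dims > d] <- "pregnant"
        st[dims >= d + tm$gestation - tm$dry_off] <- "dry"
        keep <- dims <= min(d + tm$gestation - 1, lc$maxdim)
        st[dims > d + tm$gestation - 1] <- NA   # next lactation overwrites
      } else if (lc$culled) {
        keep <- dims <= tm$breeding_end
        st[dims > tm$breeding_end] <- NA
      } else {
        keep <- rep(TRUE, length(days))
      }
      ok <- keep & !is.na(st) & days < horizon
      state[days[ok] + 1] <- st[ok]
      dim[days[ok] + 1] <- dims[ok]
      identity[days[ok] + 1] <- i
      mdays <- dims >= 1 & dims <= lc$milk_end & days < horizon
      dp <- if (is.na(lc$conception_dim)) 0 else pmax(0, dims - round(lc$conception_dim))
      milk[days[mdays] + 1] <- milk_yield(dims[mdays], lc$yield, lc$parity,
                                          (lc$cal0 + dims[mdays]) %% 365,
                                          if (length(dp) > 1) dp[mdays] else dp,
                                          config)
      sv <- round(lc$services)
      sv <- sv[sv <= lc$maxdim]
      service[lc$t0 + sv + 1] <- TRUE
    }
  }
  dmi <- dry_matter_intake(ifelse(is.na(dim), 0, dim), milk, config,
                           warn = FALSE)
  nocow <- state == "culled-gap"
  dmi$total[nocow] <- 0; dmi$forage[nocow] <- 0; dmi$concentrate[nocow] <- 0
  ch4 <- daily_methane(dmi$forage, dmi$concentrate,
                       forage_ch4_rate(herd$forage_me, config), config)
  data.frame(day = day, identity = identity, dim = dim, state = state,
             service = service, milk_l = milk,
             forage_dmi = dmi$forage, concentrate_dmi = dmi$concentrate,
             methane_g = ch4)
}
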