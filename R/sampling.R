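#' Draw one herd's management and economic inputs
#'
#' Samples the twelve herd-level inputs independently from their uniform
#' ranges (submission risk, pregnancy risk, 305-d yield, heifer proportion,
#' calving-index cost, cull cost, serve cost, voluntary waiting period, mean
#' time to first cycle, mean cycle length, forage metabolisable energy, milk
#' margin).  Draws use the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param config A configuration list from [run_config()].
#' @return An object of class `herd_params`: a named list of scalars.
#' @examples
#' set.seed(1)
#' draw_herd_params()
#' @export
draw_herd_params <- function(config = sim_defaults()) {
  r <- config$herd_ranges
  vals <- lapply(r, function(b) stats::runif(1, b[1], b[2]))
  structure(vals, class = "herd_params")
}

#' Construct herd parameters explicitly
#'
#' Builds a `herd_params` object from named values, filling unspecified
#' inputs with the midpoints of their ranges.  Values outside the configured
#' ranges are an error.
#'
#' @param ... Named scalar inputs (e.g. `submission_risk = 0.3`).
#' @param config A configuration list from [run_config()].
#' @param check Validate ranges (default `TRUE`).
#' @return A `herd_params` object.
#' @examples
#' herd_params(submission_risk = 0.375, vwp = 50)
#' @export
herd_params <- function(..., config = sim_defaults(), check = TRUE) {
  vals <- as.list(herd_input_means(config))
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(vals))
    if (length(unknown)) {
      stop("unknown herd parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    vals[names(over)] <- over
  }
  if (check) {
    for (nm in names(vals)) {
      b <- config$herd_ranges[[nm]]
      if (vals[[nm]] < b[1] || vals[[nm]] > b[2]) {
        stop(sprintf("herd parameter '%s' = %g outside [%g, %g]",
                     nm, vals[[nm]], b[1], b[2]), call. = FALSE)
      }
    }
  }
  structure(vals, class = "herd_params")
}

#' @export
print.herd_params <- function(x, ...) {
  cat("<herd_params>\n")
  print(unlist(x))
  invisible(x)
}

## PERT shape parameters for a mode-parameterised beta on [minimum, maximum]
pert_shapes <- function(mode, minimum, maximum, lambda) {
  z <- (mode - minimum) / (maximum - minimum)
  c(shape1 = 1 + lambda * z, shape2 = 1 + lambda * (1 - z))
}

#' Sample from a mode-parameterised beta distribution
#'
#' Draws from a beta distribution specified by its mode and support, using
#' the PERT convention: with concentration `lambda` (default 4) the shapes
#' are `1 + lambda*(mode-min)/(max-min)` and `1 + lambda*(max-mode)/(max-min)`
#' on the unit interval, rescaled to `[minimum, maximum]`.  A degenerate
#' support (`minimum == maximum`) returns the common value.
#'
#' @param n Number of draws.
#' @param mode Mode of the density; must lie inside the support.
#' @param minimum,maximum Support bounds.
#' @param lambda Concentration (non-negative); larger values tighten the
#'   density around the mode.
#' @return Numeric vector of length `n` in `[minimum, maximum]`.
#' @examples
#' set.seed(1)
#' range(sample_mode_beta(1000, 0.8, 0.4, 1.7))
#' @export
sample_mode_beta <- function(n, mode, minimum, maximum, lambda = 4) {
  if (minimum > maximum) stop("minimum must not exceed maximum", call. = FALSE)
  if (mode < minimum || mode > maximum) {
    stop(sprintf("mode %g outside support [%g, %g]", mode, minimum, maximum),
         call. = FALSE)
  }
  if (minimum == maximum) return(rep(minimum, n))
  s <- pert_shapes(mode, minimum, maximum, lambda)
  minimum + (maximum - minimum) * stats::rbeta(n, s[1], s[2])
}

## quantile transform of a pre-drawn uniform through the same PERT beta,
## used when consuming a cow's keyed random-number block
qmode_beta <- function(u, mode, minimum, maximum, lambda = 4) {
  if (minimum == maximum) return(rep(minimum, length(u)))
  s <- pert_shapes(mode, minimum, maximum, lambda)
  minimum + (maximum - minimum) * stats::qbeta(u, s[1], s[2])
}

#' Draw a scenario conception-risk multiplier
#'
#' Each hormonal programme scales the conception risk of its programmed first
#' insemination by a random factor: Ovsynch uses a mode-0.8 beta on
#' `[0.4, 1.7]`, Ovsynch with progesterone a mode-0.96 beta on
#' `[0.96, 1.02]`, and the double-prostaglandin regime a uniform on
#' `[0.9, 1.1]`.
#'
#' @param scenario One of `"ovsynch"`, `"ovsynch_p4"`, `"double_pg"`.
#' @param n Number of draws.
#' @param config A configuration list from [run_config()].
#' @return Numeric vector of multipliers.
#' @export
draw_scenario_multiplier <- function(scenario, n = 1, config = sim_defaults()) {
  spec <- config$scenarios[[scenario]]
  if (is.null(spec) || is.null(spec$multiplier)) {
    stop("unknown intervention scenario: ", scenario, call. = FALSE)
  }
  multiplier_from_u(stats::runif(n), spec$multiplier, config$beta_lambda)
}

multiplier_from_u <- function(u, mspec, lambda) {
  switch(mspec$dist,
    modebeta = qmode_beta(u, mspec$mode, mspec$min, mspec$max, lambda),
    uniform  = mspec$min + (mspec$max - mspec$min) * u,
    stop("unknown multiplier distribution: ", mspec$dist, call. = FALSE)
  )
}

## ---------------------------------------------------------------------------
## Cow identities and the shared random-number contract
##
## Every cow identity (an original cow or a replacement heifer) is built from
## a single integer seed.  All random draws the identity may ever need -- in
## any scenario -- are generated once, in a fixed order, into a fixed-layout
## block.  The four scenario branches index into the same block, so shared
## draws (attributes, submission draws by (lactation, oestrus event),
## conception draws by (lactation, service number)) are identical across
## branches, and scenario-specific draws live in reserved slots that the
## baseline simply never reads.  This is what makes the four branches operate
## on exactly the same simulated cows.
## ---------------------------------------------------------------------------

N_LACT <- 4L     # lactations per identity that can start inside 730 days
N_EVENTS <- 18L  # oestrus/service events per lactation (cycle >= 18 d)

#' Build one cow identity from a seed
#'
#' Generates a cow's fixed biology (parity, individual yield multiplier,
#' post-partum anoestrus length, oestrous cycle length, conception-model
#' random intercept, calving day of year) and its full pre-drawn
#' random-number block (per-lactation redraws, submission and conception
#' uniforms, scenario multiplier/boost/prostaglandin draws, replacement
#' seeds).  Identical seeds give bit-identical cows, which is the basis of
#' the common-random-numbers contract across scenario branches.
#'
#' @param seed Integer seed for this identity.
#' @param herd A `herd_params` object.
#' @param config A configuration list from [run_config()].
#' @param parity Force a parity (used for replacement heifers, parity 1);
#'   `NULL` samples from the herd age structure.
#' @return A list of class `cow_attributes`.
#' @export
make_cow <- function(seed, herd, config = sim_defaults(), parity = NULL) {
  set.seed(seed)
  cw <- config$cow
  lam <- config$beta_lambda
  ## fixed draw order; branches must not change the number of draws
  u_par <- stats::runif(2)
  if (is.null(parity)) {
    if (u_par[1] < herd$heifer_proportion) {
      parity <- 1L
    } else {
      w <- cumsum(cw$parity_weights / sum(cw$parity_weights))
      parity <- 1L + findInterval(u_par[2], w, left.open = TRUE) + 1L
    }
  }
  sdlog <- sqrt(log(1 + cw$yield_cv^2))
  ymult <- exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
  anoestrus <- qmode_beta(stats::runif(1), herd$mean_anoestrus,
                          cw$anoestrus_bounds[1], cw$anoestrus_bounds[2], lam)
  cycle <- qmode_beta(stats::runif(1), herd$mean_cycle_length,
                      cw$cycle_bounds[1], cw$cycle_bounds[2], lam)
  cow_re <- stats::rnorm(1, 0, sqrt(config$conception$coefficients$var_cow))
  doy0 <- floor(stats::runif(1, 0, 365))

  nl <- N_LACT; ne <- N_EVENTS
  n_block <- 2 * (nl - 1) + 2 * nl * ne + 3 * nl + nl + 2 * nl + 2
  u <- stats::runif(n_block)
  i <- 0L
  take <- function(k) {
    out <- u[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  an_redraw <- qmode_beta(take(nl - 1), herd$mean_anoestrus,
                          cw$anoestrus_bounds[1], cw$anoestrus_bounds[2], lam)
  cyc_redraw <- qmode_beta(take(nl - 1), herd$mean_cycle_length,
                           cw$cycle_bounds[1], cw$cycle_bounds[2], lam)
  u_subm <- matrix(take(nl * ne), nl, ne)
  u_conc <- matrix(take(nl * ne), nl, ne)
  u_mult <- matrix(take(3 * nl), nl, 3,
                   dimnames = list(NULL, c("ovsynch", "ovsynch_p4", "double_pg")))
  u_boost <- take(nl)
  u_pg <- matrix(take(2 * nl), nl, 2)
  rep_seeds <- as.integer(floor(take(2) * 2147483646)) + 1L

  structure(list(
    seed = seed, parity = as.integer(parity), yield_mult = ymult,
    anoestrus_length = anoestrus, cycle_length = cycle,
    cow_random_intercept = cow_re, calving_doy = doy0,
    an_redraw = an_redraw, cyc_redraw = cyc_redraw,
    u_subm = u_subm, u_conc = u_conc, u_mult = u_mult,
    u_boost = u_boost, u_pg = u_pg, rep_seeds = rep_seeds
  ), class = "cow_attributes")
}

#' Generate the cow population of a herd
#'
#' Draws `n_cows` cow identities for a herd: parity 1 with probability equal
#' to the herd heifer proportion, higher parities sharing the remaining mass
#' with configurable weights; anoestrus and cycle lengths from
#' mode-parameterised betas centred on the herd means; 305-d yields as the
#' herd mean scaled by a parity factor and a lognormal individual spread.
#' Each cow receives its own sub-seed, so the population is reproducible and
#' shared verbatim across scenario branches.
#'
#' @param herd A `herd_params` object.
#' @param n_cows Number of cows.
#' @param config A configuration list from [run_config()].
#' @param seed Integer seed for the herd's population.
#' @return A list of `cow_attributes`.
#' @export
assign_cow_attributes <- function(herd, n_cows, config = sim_defaults(),
                                  seed = 1L) {
  stopifnot(n_cows >= 1)
  set.seed(seed)
  seeds <- sample.int(2147483646L, n_cows)
  lapply(seeds, make_cow, herd = herd, config = config)
}

#' 305-day yield of a cow at a given parity
#'
#' The herd 305-d mean scaled by the parity adjustment factor (capped at
#' parity 5+) and the cow's individual lognormal multiplier, in thousand kg.
#'
#' @param cow A `cow_attributes` object.
#' @param herd A `herd_params` object.
#' @param parity Current parity (defaults to the cow's).
#' @param config A configuration list from [run_config()].
#' @return Scalar yield in thousand kg.
#' @export
cow_yield_305d <- function(cow, herd, parity = cow$parity,
                           config = sim_defaults()) {
  pf <- config$cow$yield_parity_factors
  herd$yield_305d * pf[min(parity, length(pf))] * cow$yield_mult
}

## deterministic derivation of substream seeds (multiplicative LCG mix);
## keeps every derived seed in [1, 2^31 - 2]
derive_seed <- function(master_seed, key) {
  s <- (as.numeric(master_seed) %% 2147483647)
  for (k in as.numeric(key)) {
    s <- (48271 * s + k + 1) %% 2147483647
  }
  as.integer(s) + 1L
}
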