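#' Conception-model coefficients
#'
#' The fixed-effect coefficients and random-effect variances of the logistic
#' regression for the probability that an insemination results in pregnancy:
#' an intercept for a parity-1 cow at calving with zero yield, offsets for
#' parities 2 to 5+, a cubic in days in milk, a linear term in 305-d yield
#' (thousand kg), a June--September season offset, and herd- and cow-level
#' random-intercept variances on the logit scale.
#'
#' @param config A configuration list from [run_config()]; coefficients can
#'   be overridden there for sensitivity analysis.
#' @return A named list of coefficients.
#' @export
conception_coefficients <- function(config = sim_defaults()) {
  config$conception$coefficients
}

#' Is a day of year in the June--September season?
#'
#' @param doy Day of year, 0-based (0 = 1 January), non-leap calendar.
#' @return Logical vector.
#' @export
is_summer <- function(doy) {
  doy <- doy %% 365
  doy >= 151 & doy <= 272   # 1 June .. 30 September, 0-based
}

#' Linear predictor of the conception model
#'
#' Evaluates the logit of the conception probability for a service:
#' intercept + parity offset + cubic days-in-milk polynomial + yield term +
#' season offset + herd and cow random intercepts.  All arguments are
#' vectorised.
#'
#' @param parity Parity category, capped at 5 (5+).
#' @param dim Days in milk at insemination.
#' @param yield_305d 305-day milk yield in thousand kg.
#' @param summer Logical: service in June--September.
#' @param herd_re,cow_re Herd- and cow-level random intercepts (logit units).
#' @param coeffs Coefficients from [conception_coefficients()].
#' @return Logit-scale linear predictor.
#' @examples
#' linear_predictor(1, 0, 0, FALSE)   # the model intercept, -0.517
#' @export
linear_predictor <- function(parity, dim, yield_305d, summer,
                             herd_re = 0, cow_re = 0,
                             coeffs = conception_coefficients()) {
  pc <- pmin(as.integer(parity), 5L)
  coeffs$intercept + coeffs$parity[pc] +
    coeffs$dim * dim + coeffs$dim2 * dim^2 + coeffs$dim3 * dim^3 +
    coeffs$yield * yield_305d + coeffs$summer * as.numeric(summer) +
    herd_re + cow_re
}

#' Conception probability for a service
#'
#' Inverse-logit of the linear predictor, scaled by the scenario risk
#' multiplier.  On the default risk scale the product is truncated at 1; on
#' the odds scale the multiplier shifts the logit by `log(multiplier)`.
#' A service marked infertile (a cow still anoestrous at a programmed
#' insemination) has probability 0 regardless of the predictor.
#'
#' @param lp Logit-scale linear predictor from [linear_predictor()].
#' @param multiplier Scenario conception-risk multiplier (1 for baseline).
#' @param fertile Logical; `FALSE` forces probability 0.
#' @param scale `"risk"` (default) or `"odds"`.
#' @return Probability in `[0, 1]`.
#' @examples
#' conception_probability(0)                 # 0.5
#' conception_probability(-0.517)            # plogis(-0.517)
#' conception_probability(0, multiplier = 0.8)
#' @export
conception_probability <- function(lp, multiplier = 1, fertile = TRUE,
                                   scale = c("risk", "odds")) {
  scale <- match.arg(scale)
  p <- switch(scale,
    risk = pmin(1, stats::plogis(lp) * multiplier),
    odds = stats::plogis(lp + log(multiplier))
  )
  p * as.numeric(fertile)
}

#' Draw herd- and cow-level random intercepts
#'
#' Independent zero-mean normal draws with the conception model's herd and
#' cow variances.
#'
#' @param n Number of draws of each.
#' @param coeffs Coefficients from [conception_coefficients()].
#' @return List with numeric vectors `herd` and `cow`.
#' @export
draw_random_intercepts <- function(n = 1, coeffs = conception_coefficients()) {
  list(herd = stats::rnorm(n, 0, sqrt(coeffs$var_herd)),
       cow  = stats::rnorm(n, 0, sqrt(coeffs$var_cow)))
}

#' Herd-level conception effect
#'
#' The sampled herd input "pregnancy risk" ties the herd to the conception
#' model in one of two configurable ways.  Under the default
#' `"risk_multiplier"` linkage the input scales the predicted conception
#' probability of every service multiplicatively, exactly parallel to the
#' scenario factors (the herd logit offset is then 0); this is what
#' reproduces the magnitude of the reference cost models.  Under
#' `"calibrated_offset"` the herd receives a logit intercept chosen so that
#' the predicted probability at a reference service -- reference days in
#' milk, the herd's mean yield, its expected parity mix, season averaged --
#' equals the input, which honours the input's literal definition as the
#' proportion of served cows that conceive.  `herd_conception_effect()`
#' returns both pieces for the configured linkage;
#' `herd_logit_offset()` computes the calibrated offset itself.
#'
#' @param herd A `herd_params` object.
#' @param config A configuration list from [run_config()].
#' @return `herd_conception_effect()`: list with `offset` (logit) and
#'   `multiplier` (risk scale).  `herd_logit_offset()`: scalar logit offset.
#' @export
herd_conception_effect <- function(herd, config = sim_defaults()) {
  mode <- config$conception$herd_effect
  if (mode == "risk_multiplier") {
    list(offset = 0, multiplier = herd$pregnancy_risk)
  } else if (mode == "calibrated_offset") {
    list(offset = herd_logit_offset(herd, config), multiplier = 1)
  } else {
    stop("unknown conception herd_effect: ", mode, call. = FALSE)
  }
}

#' @rdname herd_conception_effect
#' @export
herd_logit_offset <- function(herd, config = sim_defaults()) {
  co <- conception_coefficients(config)
  h <- herd$heifer_proportion
  w <- c(h, (1 - h) * config$cow$parity_weights / sum(config$cow$parity_weights))
  parity_mean <- sum(w * co$parity)
  dim_ref <- config$conception$dim_ref
  summer_frac <- 122 / 365
  lp_ref <- co$intercept + parity_mean +
    co$dim * dim_ref + co$dim2 * dim_ref^2 + co$dim3 * dim_ref^3 +
    co$yield * herd$yield_305d + co$summer * summer_frac
  stats::qlogis(herd$pregnancy_risk) - lp_ref
}
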