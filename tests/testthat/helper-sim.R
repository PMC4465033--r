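# shared fixtures built in code

mean_herd <- function(...) herd_params(...)

# a herd in which every cow conceives at her first service: submission risk 1
# and an effectively certain conception probability (huge intercept on the
# odds scale, where the risk multiplier cannot truncate the probability)
certain_conception_config <- function() {
  run_config(list(conception = list(
    coefficients = list(intercept = 50),
    multiplier_scale = "odds"
  )))
}

# herd outcome stub for the delta arithmetic tests
mk_outcome <- function(n_cows = 200, milk = 0, services = 0, culls = 0,
                       ch4 = 0) {
  structure(list(scenario = "stub", n_cows = n_cows, total_milk_l = milk,
                 total_services = services, culls = culls,
                 forage_dmi_kg = 0, concentrate_dmi_kg = 0,
                 cow_ch4_g = ch4, total_ch4_g = ch4,
                 anoestrous_at_vwp_end = 0),
            class = "herd_outcome")
}

# closed-form first eligible oestrus day at or after the VWP
first_eligible_oestrus <- function(an, cyc, vwp) {
  an + 1 + cyc * max(0, ceiling((vwp - an - 1) / cyc))
}
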