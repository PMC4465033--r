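#' Default simulation configuration
#'
#' Returns the full nested list of model constants: the herd-level input
#' ranges, the beta-sampling shape, cow attribute rules, the conception-model
#' coefficients, the timing constants of the reproductive state machine, the
#' lactation-curve / intake / methane submodel parameters, the scenario
#' constants for the three hormonal programmes, and the cost accounting
#' switches.  Every constant used anywhere in the simulator lives here so
#' that a run is fully described by one object.
#'
#' @return A named nested list.
#' @seealso [run_config()] to override entries.
#' @export
sim_defaults <- function() {
  list(
    ## Uniform ranges for the twelve herd-level inputs
    herd_ranges = list(
      submission_risk    = c(0.10, 0.65),  # P(oestrus observed & served)
      pregnancy_risk     = c(0.10, 0.65),  # P(conception | service), herd level
      yield_305d         = c(3, 10),       # thousand kg / 305 d
      heifer_proportion  = c(0.05, 0.50),
      calving_index_cost = c(2, 5),        # GBP per day of calving interval
      cull_cost          = c(700, 1500),   # GBP per cull+replacement
      serve_cost         = c(0, 25),       # GBP per insemination
      vwp                = c(30, 70),      # days, voluntary waiting period
      mean_anoestrus     = c(20, 30),      # days, herd mean time to first cycle
      mean_cycle_length  = c(20.5, 22.5),  # days
      forage_me          = c(9.5, 11.5),   # MJ ME / kg DM
      milk_margin        = c(0.10, 0.20)   # GBP / L
    ),
    ## Mode-parameterised beta draws use the PERT convention
    beta_lambda = 4,
    cow = list(
      anoestrus_bounds = c(10, 80),        # days; mode = herd mean_anoestrus
      cycle_bounds     = c(18, 27),        # days; mode = herd mean_cycle_length
      ## parities 2,3,4,5+ share of the non-heifer mass
      parity_weights = c(0.30, 0.25, 0.20, 0.25),
      ## multiplicative 305-d yield adjustment for parity 1..5+
      yield_parity_factors = c(0.87, 1.00, 1.07, 1.07, 1.07),
      yield_cv = 0.15,                     # lognormal within-herd yield spread
      max_lactations = 4,                  # per identity within the horizon
      max_oestrus_events = 18,             # per lactation (cycle >= 18 d caps this)
      max_replacements = 2                 # per cow slot within the horizon
    ),
    conception = list(
      coefficients = list(
        intercept = -0.517,
        parity    = c(0, -0.0136, -0.0209, -0.081, -0.284),  # parity 1..5+
        dim       = 0.0177,
        dim2      = -0.0000994,
        dim3      = 0.000000177,
        yield     = -0.0695,     # per thousand kg 305-d yield
        summer    = -0.0861,     # June-September service
        var_herd  = 0.065,
        var_cow   = 0.135
      ),
      multiplier_scale = "risk",  # "risk": p*m truncated at 1; "odds": logit shift
      ## how the herd pregnancy-risk input enters the conception model:
      ## "risk_multiplier": scales the predicted probability, like the
      ## scenario factors; "calibrated_offset": a herd logit intercept chosen
      ## so the predicted probability at a reference service equals the input
      herd_effect = "risk_multiplier",
      dim_ref = 120               # reference DIM for the calibrated offset
    ),
    timing = list(
      horizon = 730,            # days followed per cow slot
      gestation = 280,          # days
      dry_off = 60,             # days dry before expected calving
      breeding_end = 300,       # DIM; open cows culled here
      replacement_lag = 60,     # days from cull to heifer entry
      batch_interval = 14,      # days between treatment batches
      forced_ai_from = 50       # earliest DIM for programme first AI
    ),
    lactation = list(
      ## Wood curve y(t) = a * t^b * exp(-c t); a solved per cow so the
      ## 305-day integral equals the cow's 305-d yield
      wood_b = c(primiparous = 0.15, multiparous = 0.20),
      wood_c = c(primiparous = 0.0025, multiparous = 0.0040),
      season_amplitude = 0.05,
      season_peak_doy = 120,          # spring peak
      preg_depression_onset = 150,    # days pregnant before yield depression
      preg_depression_rate = 0.004,   # per day beyond onset
      preg_depression_floor = 0.6
    ),
    intake = list(
      base_dmi = 10,          # kg DM/day at zero milk
      dmi_per_l = 0.2,        # kg DM per L milk
      ramp_start = 0.7,       # intake fraction at calving
      ramp_dim = 70,          # DIM by which intake reaches its plateau
      conc_per_l = 0.4,       # kg fresh concentrate per L above threshold
      conc_dm = 0.9,          # concentrate dry-matter fraction
      conc_threshold_l = 10   # L supported by forage alone
    ),
    methane = list(
      rate_at_me_min = 23.5,  # g CH4 / kg forage DM at ME 9.5
      rate_slope = -0.5,      # g CH4 / kg DM per MJ ME above 9.5
      me_ref = 9.5,
      concentrate_divisor = 150,
      heifer_share = 0.27,                # heifer share of herd CH4, commercial
      commercial_replacement_rate = 0.25  # per cow per year
    ),
    scenarios = list(
      baseline = list(drug_cost = 0),
      ovsynch = list(
        drug_cost = 9,
        multiplier = list(dist = "modebeta", mode = 0.8, min = 0.4, max = 1.7)
      ),
      ovsynch_p4 = list(
        drug_cost = 19,
        multiplier = list(dist = "modebeta", mode = 0.96, min = 0.96, max = 1.02),
        resumption_boost = 0.05   # absolute probability, multiparous only
      ),
      double_pg = list(
        drug_cost = 5,
        multiplier = list(dist = "uniform", min = 0.9, max = 1.1),
        oestrus_efficacy = 0.8,
        max_injections = 2
      )
    ),
    costs = list(
      include_calving_index = FALSE,  # optional Delta(calving interval) term
      years = 2,                      # horizon length for per-year scaling
      ## milk and services are annualised; the change in the culled
      ## proportion is charged once at the cull cost (set TRUE to divide the
      ## cull term by the horizon years as well)
      annualize_culls = FALSE
    )
  )
}

#' Build a run configuration
#'
#' Starts from [sim_defaults()] and applies overrides, either programmatically
#' (a nested list via `overrides`) or from a YAML file.  Any key not present
#' in the defaults is an error, never a silent no-op: a typo in a scenario
#' constant would otherwise corrupt a counterfactual comparison.
#'
#' @param overrides Nested list of values to replace, mirroring the structure
#'   of [sim_defaults()].
#' @param config_file Optional path to a YAML file with the same structure.
#' @return The merged configuration list.
#' @examples
#' cfg <- run_config(list(timing = list(horizon = 365)))
#' cfg$timing$horizon
#' @export
run_config <- function(overrides = list(), config_file = NULL) {
  cfg <- sim_defaults()
  if (!is.null(config_file)) {
    file_over <- yaml::read_yaml(config_file)
    cfg <- merge_config(cfg, file_over, path = "")
  }
  merge_config(cfg, overrides, path = "")
}

## strict recursive merge: unknown keys error with their full path
merge_config <- function(base, over, path) {
  if (length(over) == 0L) return(base)
  if (is.null(names(over)) || any(!nzchar(names(over)))) {
    stop("configuration overrides must be named at '", path, "'", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste0(path, ".", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Theoretical means and upper quartiles of the herd input distributions
#'
#' Closed-form moments of the uniform herd-input distributions, used to centre
#' regression covariates and to define the "mean to upper quartile" shifts of
#' the prediction tables.
#'
#' @param config A configuration list from [run_config()].
#' @return Named numeric vector over the twelve herd inputs.
#' @export
herd_input_means <- function(config = sim_defaults()) {
  vapply(config$herd_ranges, function(r) (r[1] + r[2]) / 2, numeric(1))
}

#' @rdname herd_input_means
#' @export
herd_input_upper_quartiles <- function(config = sim_defaults()) {
  vapply(config$herd_ranges, function(r) r[1] + 0.75 * (r[2] - r[1]), numeric(1))
}
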