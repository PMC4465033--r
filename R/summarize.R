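## ---------------------------------------------------------------------------
## Herd-level linear summarisation: centred polynomials + interactions,
## backward elimination, and mean-to-upper-quartile prediction shifts.
##
## Terms are written as products of factors joined by ":", each factor a
## covariate name optionally raised to a power, e.g.
##   "submission_risk", "submission_risk^2", "pregnancy_risk:submission_risk^2"
## All covariates are centred on their (theoretical) means *before* powers
## and products are formed, so a term evaluates to zero whenever any of its
## covariates sits at its mean.
## ---------------------------------------------------------------------------

parse_term <- function(term) {
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  out <- lapply(facs, function(f) {
    parts <- strsplit(f, "^", fixed = TRUE)[[1]]
    list(var = parts[1],
         power = if (length(parts) > 1) as.numeric(parts[2]) else 1)
  })
  out
}

eval_term <- function(term, centred) {
  facs <- parse_term(term)
  v <- 1
  for (f in facs) v <- v * centred[[f$var]]^f$power
  v
}

term_vars <- function(term) {
  vapply(parse_term(term), `[[`, character(1), "var")
}

## does `big` contain `small` in the marginality sense (every factor of
## `small` present in `big` with at least its power)?
term_contains <- function(big, small) {
  if (big == small) return(FALSE)
  fb <- parse_term(big); fs <- parse_term(small)
  pb <- vapply(fb, function(f) f$power, numeric(1))
  names(pb) <- vapply(fb, function(f) f$var, character(1))
  for (f in fs) {
    if (is.na(pb[f$var]) || pb[f$var] < f$power) return(FALSE)
  }
  TRUE
}

#' The saturated polynomial term set of the herd summarisation models
#'
#' Linear and quadratic terms in the reproductive inputs, linear terms in
#' the economic inputs, and the investigated interactions of submission and
#' pregnancy risk with each other and with the voluntary waiting period.
#'
#' @param outcome `"d_ch4_per_l"` or `"d_cost"`; the cost models also carry
#'   the cull- and serve-cost terms.
#' @return Character vector of term labels.
#' @export
saturated_terms <- function(outcome = c("d_ch4_per_l", "d_cost")) {
  outcome <- match.arg(outcome)
  base <- c("submission_risk", "submission_risk^2",
            "pregnancy_risk", "pregnancy_risk^2",
            "yield_305d", "vwp",
            "submission_risk:vwp", "submission_risk^2:vwp",
            "pregnancy_risk:vwp", "pregnancy_risk^2:vwp",
            "pregnancy_risk:submission_risk",
            "pregnancy_risk:submission_risk^2")
  if (outcome == "d_cost") {
    base <- append(base, c("cull_cost", "serve_cost"), after = 6)
  }
  base
}

#' Build a centred polynomial design matrix from herd deltas
#'
#' Centres each covariate on its mean (theoretical means of the herd input
#' distributions by default, or the empirical sample means), then forms the
#' requested powers and products.  The centring constants are recorded for
#' later prediction.
#'
#' @param deltas A data.frame with one row per herd carrying the covariate
#'   columns and the outcome.
#' @param outcome Name of the outcome column.
#' @param terms Character vector of term labels (see [saturated_terms()]).
#' @param centres Named numeric vector of centring constants; defaults to
#'   the theoretical means of the herd input distributions.
#' @param config A configuration list from [run_config()].
#' @return A list of class `herd_design`: `X` (with intercept), `y`,
#'   `terms`, `centres`.
#' @export
build_design <- function(deltas, outcome, terms,
                         centres = herd_input_means(config),
                         config = sim_defaults()) {
  if (nrow(deltas) < 2) stop("need at least 2 herds", call. = FALSE)
  if (anyDuplicated(terms)) {
    stop("duplicate terms in formula: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "),
         call. = FALSE)
  }
  vars <- unique(unlist(lapply(terms, term_vars)))
  missing_v <- setdiff(vars, names(deltas))
  if (length(missing_v)) {
    stop("covariate(s) absent from data: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  centred <- lapply(vars, function(v) deltas[[v]] - centres[[v]])
  names(centred) <- vars
  cols <- vapply(terms, eval_term, numeric(nrow(deltas)), centred = centred)
  X <- cbind(`(Intercept)` = 1, cols)
  structure(list(X = X, y = deltas[[outcome]], terms = terms,
                 centres = centres[vars], outcome = outcome),
            class = "herd_design")
}

#' Fit the herd-level linear summarisation model
#'
#' Ordinary least squares on the centred design.  With exactly one delta
#' per herd, a herd random intercept is not separately identifiable from
#' the residual, so the between-herd variance is reported as the residual
#' variance.
#'
#' @param design A `herd_design` from [build_design()].
#' @return An object of class `herd_lm`: coefficient table (estimate, SE,
#'   z, p), residual variance, n, and the proportion of the null-model
#'   variance explained.
#' @export
fit_model <- function(design) {
  X <- design$X; y <- design$y
  if (nrow(X) <= ncol(X)) stop("need more herds than terms", call. = FALSE)
  fit <- stats::lm(y ~ X - 1)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  if (anyNA(beta)) {
    stop("singular design; offending term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sm$sigma^2
  se <- stats::setNames(sm$coefficients[, "Std. Error"], colnames(X))
  z <- beta / se
  pval <- stats::setNames(sm$coefficients[, "Pr(>|t|)"], colnames(X))
  null_var <- stats::var(y)
  structure(list(
    coefficients = beta, se = se, z = z, p_value = pval,
    residual_variance = sigma2, n = n,
    var_explained = 1 - sigma2 / null_var,
    terms = design$terms, centres = design$centres,
    outcome = design$outcome
  ), class = "herd_lm")
}

#' @export
print.herd_lm <- function(x, ...) {
  cat(sprintf("<herd_lm> outcome %s, n = %d herds\n", x$outcome, x$n))
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p_value)
  print(round(tab, 4))
  cat(sprintf("residual (herd) variance %.4g; variance explained %.1f%%\n",
              x$residual_variance, 100 * x$var_explained))
  invisible(x)
}

#' Backward elimination with a Wald criterion
#'
#' Starting from a fitted saturated model, repeatedly removes the least
#' significant removable term and refits, until every removable term passes
#' the criterion.  Marginality is respected: a term is removable only while
#' no retained higher-order term (a power or interaction containing it)
#' remains; the intercept is never removed.  The default criterion drops
#' terms with Wald p > 0.05; `"z1"` instead drops terms whose effect size
#' does not exceed its standard error.
#'
#' @param model A `herd_lm` from [fit_model()].
#' @param design The `herd_design` the model was fitted to.
#' @param threshold_p Wald p-value retention threshold (default 0.05).
#' @param criterion `"wald"` (p-value) or `"z1"` (|estimate| > SE).
#' @return The pruned `herd_lm`.
#' @export
backward_eliminate <- function(model, design, threshold_p = 0.05,
                               criterion = c("wald", "z1")) {
  criterion <- match.arg(criterion)
  terms <- design$terms
  repeat {
    protected <- vapply(terms, function(t) {
      any(vapply(terms, term_contains, logical(1), small = t))
    }, logical(1))
    est <- model$coefficients[terms]
    se <- model$se[terms]
    fails <- if (criterion == "wald") {
      model$p_value[terms] > threshold_p
    } else {
      abs(est) <= se
    }
    candidates <- which(!protected & fails)
    if (!length(candidates)) break
    worst <- candidates[which.max(model$p_value[terms][candidates])]
    terms <- terms[-worst]
    if (!length(terms)) {
      design2 <- design
      design2$X <- design$X[, "(Intercept)", drop = FALSE]
      design2$terms <- character(0)
      model <- fit_model(design2)
      break
    }
    design2 <- design
    design2$X <- design$X[, c("(Intercept)", terms), drop = FALSE]
    design2$terms <- terms
    model <- fit_model(design2)
    design <- design2
  }
  model
}

#' Predicted outcome change when one input moves, others at their means
#'
#' Evaluates the fitted (or reference) model at two values of one covariate
#' with every other covariate held at its centring mean, and returns the
#' difference in the prediction.  Because all covariates are centred before
#' powers and products are formed, interaction terms vanish and only the
#' shifted covariate's own polynomial contributes.
#'
#' @param coefficients Named numeric vector of term coefficients (term
#'   labels as in [saturated_terms()]; an `(Intercept)` entry is allowed
#'   and cancels in the difference).  A `herd_lm` may be given instead.
#' @param covariate Covariate to shift.
#' @param from,to Values of the covariate (uncentred).
#' @param centres Named numeric vector of centring means.
#' @return Scalar change in the predicted outcome.
#' @examples
#' cf <- c(submission_risk = 2.4, `submission_risk^2` = -5.2)
#' ctr <- c(submission_risk = 0.375)
#' prediction_shift(cf, "submission_risk", 0.375, 0.5125, ctr)
#' @export
prediction_shift <- function(coefficients, covariate, from, to,
                             centres = herd_input_means()) {
  if (inherits(coefficients, "herd_lm")) {
    centres <- coefficients$centres
    coefficients <- coefficients$coefficients
  }
  terms <- setdiff(names(coefficients), c("(Intercept)", "herd_variance"))
  involved <- vapply(terms, function(t) covariate %in% term_vars(t), logical(1))
  if (!any(involved)) {
    stop("covariate '", covariate, "' does not appear in the model",
         call. = FALSE)
  }
  predict_at <- function(value) {
    centred <- list()
    for (v in unique(unlist(lapply(terms, term_vars)))) {
      centred[[v]] <- if (v == covariate) value - centres[[v]] else 0
    }
    sum(vapply(terms, function(t) {
      coefficients[[t]] * eval_term(t, centred)
    }, numeric(1)))
  }
  predict_at(to) - predict_at(from)
}

#' Prediction grid over two or three inputs
#'
#' Evaluates a fitted (or reference) model over a lattice of covariate
#' values with all remaining covariates at their centring means.
#'
#' @param coefficients Named coefficient vector (with optional
#'   `(Intercept)`) or a `herd_lm`.
#' @param axes Named list of numeric vectors, one per varied covariate.
#' @param centres Named numeric vector of centring means.
#' @return A data.frame: one column per axis plus `predicted`.
#' @export
prediction_grid <- function(coefficients, axes,
                            centres = herd_input_means()) {
  if (inherits(coefficients, "herd_lm")) {
    centres <- coefficients$centres
    coefficients <- coefficients$coefficients
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  terms <- setdiff(names(coefficients), c("(Intercept)", "herd_variance"))
  intercept <- if ("(Intercept)" %in% names(coefficients)) {
    coefficients[["(Intercept)"]]
  } else 0
  vars <- unique(unlist(lapply(terms, term_vars)))
  centred <- lapply(vars, function(v) {
    if (v %in% names(grid)) grid[[v]] - centres[[v]] else rep(0, nrow(grid))
  })
  names(centred) <- vars
  pred <- rep(intercept, nrow(grid))
  for (t in terms) pred <- pred + coefficients[[t]] * eval_term(t, centred)
  grid$predicted <- pred
  grid
}

#' Reference final-model coefficients
#'
#' The final herd-level model coefficients for the three programmes,
#' distributed with the package as plain-text fixtures (fitted to 10,000
#' simulated herds of 200 cows): one set for the methane intensity
#' difference (g CH4 per L milk) and one for the cost difference (GBP per
#' cow per year).  Rows with term `herd_variance` carry the between-herd
#' variance.
#'
#' @param outcome `"methane"` or `"cost"`.
#' @param scenario Optionally restrict to one programme.
#' @return A data.frame with columns `scenario`, `term`, `estimate`, `se`,
#'   or, when `scenario` is given, a named coefficient vector.
#' @export
reference_model_coefficients <- function(outcome = c("methane", "cost"),
                                         scenario = NULL) {
  outcome <- match.arg(outcome)
  path <- system.file("extdata",
                      paste0(outcome, "_model_coefficients.csv"),
                      package = "dairysynch", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (is.null(scenario)) return(tab)
  tab <- tab[tab$scenario == scenario, ]
  if (!nrow(tab)) stop("no reference model for scenario ", scenario,
                       call. = FALSE)
  stats::setNames(tab$estimate, tab$term)
}

#' Fit and prune the summarisation model for one scenario and outcome
#'
#' Convenience pipeline: build the centred saturated design from simulated
#' herd deltas, fit it, and apply backward elimination.
#'
#' @param deltas Herd-level deltas (one row per herd) from
#'   [simulate_herds()], already filtered to one scenario.
#' @param outcome `"d_ch4_per_l"` or `"d_cost"`.
#' @param centres Centring constants (default: theoretical input means).
#' @param threshold_p Wald retention threshold.
#' @param config A configuration list from [run_config()].
#' @return A pruned `herd_lm`.
#' @export
summarize_deltas <- function(deltas, outcome = c("d_ch4_per_l", "d_cost"),
                             centres = herd_input_means(config),
                             threshold_p = 0.05, config = sim_defaults()) {
  outcome <- match.arg(outcome)
  des <- build_design(deltas, outcome, saturated_terms(outcome), centres,
                      config)
  backward_eliminate(fit_model(des), des, threshold_p)
}
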