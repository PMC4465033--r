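make_synth_deltas <- function(n, coefs, centres, noise_sd, seed,
                              config = sim_defaults()) {
  set.seed(seed)
  r <- config$herd_ranges
  d <- data.frame(
    submission_risk = runif(n, r$submission_risk[1], r$submission_risk[2]),
    pregnancy_risk = runif(n, r$pregnancy_risk[1], r$pregnancy_risk[2]),
    yield_305d = runif(n, r$yield_305d[1], r$yield_305d[2]),
    vwp = runif(n, r$vwp[1], r$vwp[2]),
    cull_cost = runif(n, r$cull_cost[1], r$cull_cost[2]),
    serve_cost = runif(n, r$serve_cost[1], r$serve_cost[2])
  )
  terms <- setdiff(names(coefs), c("(Intercept)", "herd_variance"))
  d$y <- 0
  des <- build_design(d, "y", terms, centres, config)
  mu <- as.vector(des$X %*% coefs[c("(Intercept)", terms)])
  d$y <- mu + rnorm(n, 0, noise_sd)
  d
}

test_that("design columns are centred products with recorded constants", {
  ctr <- herd_input_means()
  d <- data.frame(submission_risk = c(0.375, 0.5, 0.2),
                  vwp = c(50, 60, 40), y = c(1, 2, 3))
  des <- build_design(d, "y", c("submission_risk", "submission_risk^2",
                                "submission_risk:vwp"), ctr)
  # a covariate at its mean zeroes its column, its square and its products
  expect_equal(unname(des$X[1, -1]), c(0, 0, 0))
  # hand-computed row: submission 0.5 -> 0.125; vwp 60 -> 10
  expect_equal(unname(des$X[2, -1]), c(0.125, 0.125^2, 0.125 * 10))
  expect_equal(des$centres[["submission_risk"]], 0.375)
  # intercept-only formula is a column of ones
  des0 <- build_design(d, "y", character(0), ctr)
  expect_equal(unname(des0$X[, 1]), rep(1, 3))
  expect_error(build_design(d, "y", c("vwp", "vwp"), ctr), "duplicate")
})

test_that("least squares recovers exactly, and duplication shrinks SEs only", {
  ctr <- herd_input_means()
  truth <- c(`(Intercept)` = -0.5, submission_risk = 2.4,
             `submission_risk^2` = -5.2, pregnancy_risk = 0.5)
  d <- make_synth_deltas(40, truth, ctr, noise_sd = 0, seed = 2)
  des <- build_design(d, "y", names(truth)[-1], ctr)
  # zero-noise data: the fit interpolates, so the SE machinery warns
  fit <- suppressWarnings(fit_model(des))
  expect_equal(fit$coefficients, truth, tolerance = 1e-10)

  d2 <- rbind(d, d)
  fit2 <- suppressWarnings(fit_model(build_design(d2, "y", names(truth)[-1], ctr)))
  dn <- make_synth_deltas(60, truth, ctr, noise_sd = 0.3, seed = 3)
  fitn <- fit_model(build_design(dn, "y", names(truth)[-1], ctr))
  fitn2 <- fit_model(build_design(rbind(dn, dn), "y", names(truth)[-1], ctr))
  expect_equal(fitn2$coefficients, fitn$coefficients)
  expect_true(all(fitn2$se < fitn$se))

  # a constant covariate centres to zero and is reported as singular
  dbad <- dn
  dbad$vwp <- 50
  expect_error(fit_model(build_design(dbad, "y", c("submission_risk", "vwp"),
                                      ctr)),
               "singular design.*vwp")
})

test_that("saturated fits recover the reference coefficients within 3 SEs", {
  ctr <- herd_input_means()
  ref <- reference_model_coefficients("methane", "ovsynch")
  coefs <- ref[setdiff(names(ref), "herd_variance")]
  d <- make_synth_deltas(10000, coefs, ctr, noise_sd = sqrt(0.3), seed = 11)
  terms <- setdiff(names(coefs), "(Intercept)")
  fit <- fit_model(build_design(d, "y", terms, ctr))
  for (nm in names(coefs)) {
    expect_lt(abs(fit$coefficients[[nm]] - coefs[[nm]]), 3 * fit$se[[nm]] + 1e-12)
  }
})

test_that("backward elimination prunes noise, respects marginality, and is idempotent", {
  ctr <- herd_input_means()
  truth <- c(`(Intercept)` = 1, submission_risk = 30, pregnancy_risk = -25)
  # a pure-noise covariate is eliminated in most replicates
  dropped <- vapply(1:100, function(i) {
    d <- make_synth_deltas(200, truth, ctr, noise_sd = 1, seed = 1000 + i)
    des <- build_design(d, "y", c(names(truth)[-1], "yield_305d"), ctr)
    fit <- backward_eliminate(fit_model(des), des)
    !"yield_305d" %in% names(fit$coefficients)
  }, logical(1))
  expect_gt(mean(dropped), 0.9)

  # strongly significant terms survive untouched
  d <- make_synth_deltas(500, truth, ctr, noise_sd = 0.5, seed = 5)
  des <- build_design(d, "y", names(truth)[-1], ctr)
  fit <- backward_eliminate(fit_model(des), des)
  expect_setequal(names(fit$coefficients),
                  c("(Intercept)", "submission_risk", "pregnancy_risk"))

  # a weak main effect is retained while its interaction stays in the model
  truth2 <- c(`(Intercept)` = 0, submission_risk = 0.001, vwp = 0.001,
              `submission_risk:vwp` = 8)
  d2 <- make_synth_deltas(800, truth2, ctr, noise_sd = 0.5, seed = 6)
  des2 <- build_design(d2, "y", names(truth2)[-1], ctr)
  fit2 <- backward_eliminate(fit_model(des2), des2)
  expect_true(all(c("submission_risk", "vwp", "submission_risk:vwp") %in%
                    names(fit2$coefficients)))

  # a second elimination pass changes nothing
  des3 <- des2
  des3$X <- des2$X[, c("(Intercept)", setdiff(names(fit2$coefficients),
                                              "(Intercept)")), drop = FALSE]
  des3$terms <- setdiff(names(fit2$coefficients), "(Intercept)")
  fit3 <- backward_eliminate(fit_model(des3), des3)
  expect_equal(fit3$coefficients, fit2$coefficients)
})

test_that("prediction shifts and grids agree with direct evaluation", {
  ctr <- herd_input_means()
  cf <- reference_model_coefficients("methane", "ovsynch")
  # from == to gives zero
  expect_equal(prediction_shift(cf, "vwp", 55, 55, ctr), 0)
  # shift equals the covariate's own polynomial contribution
  s <- prediction_shift(cf, "submission_risk", 0.375, 0.5125, ctr)
  expect_equal(s, 2.4 * 0.1375 - 5.2 * 0.1375^2)
  expect_error(prediction_shift(cf, "milk_margin", 0.1, 0.2, ctr),
               "does not appear")

  # the all-mean grid point is the intercept
  g <- prediction_grid(cf, list(submission_risk = 0.375,
                                pregnancy_risk = 0.375), ctr)
  expect_equal(g$predicted, cf[["(Intercept)"]])
  # a one-point grid equals intercept + shift from the mean
  g2 <- prediction_grid(cf, list(submission_risk = 0.5125), ctr)
  expect_equal(g2$predicted, cf[["(Intercept)"]] + s)
  # the fitted quadratic dictates where the section turns
  sub <- seq(0.1, 0.65, by = 0.001)
  gs <- prediction_grid(cf, list(submission_risk = sub), ctr)
  vertex <- 0.375 - 2.4 / (2 * -5.2)
  expect_lt(abs(sub[which.max(gs$predicted)] - vertex), 0.002)
})
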