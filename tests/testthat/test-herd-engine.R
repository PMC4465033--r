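test_that("oestrus calendar follows the day-1-of-cycle rule", {
  expect_equal(oestrus_calendar(25, 21)[1:3], c(26, 47, 68))
  expect_equal(oestrus_calendar(80, 18)[1], 81)
  # number of oestrus events by DIM 300 for anoestrus 25, cycle 21
  expect_length(oestrus_calendar(25, 21, 300), 14)
  expect_length(oestrus_calendar(300, 20, 300), 0)
})

test_that("lactation curve integrates to the 305-day yield and behaves with stage", {
  dims <- 1:305
  for (par in c(1, 3)) {
    y <- milk_yield(dims, 7.0, parity = par, doy = NA, days_pregnant = 0)
    expect_lt(abs(sum(y) - 7000), 1e-6)      # scale solved exactly, no season
  }
  # with seasonality the 305-day total stays within 2%
  ys <- milk_yield(dims, 7.0, parity = 2, doy = (100 + dims) %% 365)
  expect_lt(abs(sum(ys) - 7000), 140)
  # zero before calving day 1
  expect_equal(milk_yield(0, 7, 2), 0)
  # late-gestation depression is monotone
  expect_lt(milk_yield(200, 7, 2, NA, days_pregnant = 200),
            milk_yield(200, 7, 2, NA, days_pregnant = 0))
  expect_equal(milk_yield(200, 7, 2, NA, days_pregnant = 100),
               milk_yield(200, 7, 2, NA, days_pregnant = 0))
})

test_that("intake partition feeds concentrate above 10 L at 90% dry matter", {
  expect_equal(dry_matter_intake(150, 10)$concentrate, 0)
  expect_equal(dry_matter_intake(150, 30)$concentrate, 7.2)
  d0 <- dry_matter_intake(400, 0)
  expect_equal(d0$concentrate, 0)
  expect_equal(d0$forage, d0$total)
  d <- dry_matter_intake(150, 30)
  expect_equal(d$forage, d$total - d$concentrate)
  expect_true(all(dry_matter_intake(1:300, rep(25, 300))$forage >= 0))
})

test_that("a herd with no oestrus detection culls every cow open at 300 DIM", {
  h <- herd_params(submission_risk = 0, check = FALSE)
  cw <- make_cow(101, h)
  slot <- simulate_cow(cw, h, "baseline")
  expect_equal(slot$services, 0L)
  id1 <- slot$identities[[1]]
  expect_true(id1$culled)
  expect_equal(id1$cull_day, 300)
  # replacement heifer enters after the 60-day lag and starts a lactation
  expect_equal(slot$identities[[2]]$t_enter, 360)
  expect_equal(slot$identities[[2]]$cow$parity, 1L)
  # milk is zero throughout the replacement gap
  tr <- cow_trace(slot, h)
  gap <- tr$day >= 301 & tr$day <= 359
  expect_true(all(tr$state[gap] == "culled-gap"))
  expect_true(all(tr$milk_l[gap] == 0))
})

test_that("with certain submission and conception the trace follows closed-form timing", {
  cfg <- certain_conception_config()
  h <- herd_params(submission_risk = 1, vwp = 30, check = FALSE)
  cw <- make_cow(55, h, cfg)
  cw$anoestrus_length <- 25
  cw$cycle_length <- 21
  slot <- simulate_cow(cw, h, "baseline", cfg)
  l1 <- slot$identities[[1]]$lactations[[1]]
  # oestrus days 26, 47, ...: first at/after the 30-day VWP is DIM 47
  expect_equal(l1$conception_dim, 47)
  # milking ceases 60 days before the 280-day-gestation calving
  expect_equal(l1$milk_end, 47 + 280 - 60 - 1)
  expect_equal(l1$dry_days, 60)
  expect_equal(slot$identities[[1]]$lactations[[2]]$t0, 327)
})

test_that("forced-conception oracle: conception at the first eligible oestrus for all cows", {
  cfg <- certain_conception_config()
  h <- herd_params(submission_risk = 1, vwp = 55, check = FALSE)
  cows <- assign_cow_attributes(h, 150, cfg, seed = 12)
  for (cw in cows) {
    slot <- simulate_cow(cw, h, "baseline", cfg)
    l1 <- slot$identities[[1]]$lactations[[1]]
    expect_equal(l1$conception_dim,
                 first_eligible_oestrus(cw$anoestrus_length,
                                        cw$cycle_length, 55))
    expect_length(l1$services, 1L)
  }
})

test_that("traces are deterministic and states partition every day", {
  h <- mean_herd()
  cw <- make_cow(31, h)
  s1 <- simulate_cow(cw, h, "ovsynch")
  s2 <- simulate_cow(cw, h, "ovsynch")
  expect_identical(s1, s2)
  states <- c("anoestrus", "cycling-open", "pregnant", "dry", "culled-gap")
  set.seed(99)
  for (seed in c(3, 14, 159)) {
    cw <- make_cow(seed, h)
    for (sc in scenario_names()) {
      tr <- cow_trace(simulate_cow(cw, h, sc), h)
      expect_equal(nrow(tr), 730)
      expect_true(all(tr$state %in% states))
      expect_true(all(tr$milk_l[tr$state %in% c("dry", "culled-gap")] == 0))
      expect_true(all(tr$milk_l >= 0))
    }
  }
})

test_that("services and conceptions are conserved in the slot records", {
  h <- mean_herd()
  cows <- assign_cow_attributes(h, 60, seed = 4)
  for (sc in scenario_names()) {
    for (cw in cows[1:20]) {
      slot <- simulate_cow(cw, h, sc)
      n_serv <- sum(vapply(slot$identities, function(id) {
        sum(vapply(id$lactations, function(lc) length(lc$services),
                   integer(1)))
      }, integer(1)))
      expect_equal(slot$services, n_serv)
      for (id in slot$identities) {
        for (lc in id$lactations) {
          if (!is.na(lc$conception_dim)) {
            # the conception day is a recorded service day
            expect_true(any(abs(lc$services - lc$conception_dim) < 1e-9))
          }
        }
      }
    }
  }
})

test_that("calving-to-conception interval shortens as submission risk rises", {
  mean_cdim <- function(sub) {
    h <- herd_params(submission_risk = sub)
    cows <- assign_cow_attributes(h, 400, seed = 21)
    cd <- vapply(cows, function(cw) {
      l1 <- simulate_cow(cw, h, "baseline")$identities[[1]]$lactations[[1]]
      l1$conception_dim
    }, numeric(1))
    mean(cd, na.rm = TRUE)
  }
  m <- vapply(c(0.15, 0.375, 0.65), mean_cdim, numeric(1))
  expect_true(all(diff(m) < 0))
})
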