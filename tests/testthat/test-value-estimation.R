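# Minimal synthetic trajectory: a single run with prescribed provisions and
# a trivially constant state (useful for window arithmetic).
flat_trajectory <- function(cf, carbon = cf, t = seq(0, by = 5,
                                                     length.out = length(cf))) {
  tibble::tibble(
    regime_id = "r", run = 1L, t = t,
    lead_age = 10, gap_age = NA_real_, lead_share = 1,
    gap_share = 0, lead_origin = "planting", gap_origin = NA_character_,
    n_cohorts = 1L, disturbed = FALSE, fail_lead = FALSE, fail_gap = FALSE,
    cf = cf, carbon = carbon
  )
}

test_that("the window sum matches the annuity closed form", {
  expect_equal(discounted_window_sum(seq(0, 1000, 5), rep(0, 201), 0,
                                     0.015), 0)
  # a single provision at the window start is undiscounted
  expect_equal(
    discounted_window_sum(c(0, 1000), c(7.5, 0), 0, 0.015, 1000), 7.5
  )
  # constant 1 EUR/yr on an annual grid vs (1 - (1+r)^-H) / r
  t <- 0:1000
  p <- c(0, rep(1, 1000))
  s <- discounted_window_sum(t, p, 0, 0.015, 1000)
  closed <- (1 - 1.015^(-1000)) / 0.015
  expect_lt(abs(s - closed) / closed, 1e-9)
  # and it sits within 4e-7 relative of the perpetuity value 1/r
  expect_lt(abs(s - 1 / 0.015) / (1 / 0.015), 4e-7)
  expect_error(discounted_window_sum(t, p, 5, 0.015, 1000), "overshoot")
})

test_that("the fast grid implementation agrees with the generic sum", {
  set.seed(31)
  p <- rnorm(120, sd = 500)
  t <- seq(0, by = 5, length.out = 120)
  for (r in c(0.015, 0.005)) {
    fast <- standres:::window_sums_grid(p, r, m = 40)
    slow <- vapply(seq_len(120 - 40), function(i) {
      discounted_window_sum(t, p, t[i], r, 200)
    }, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("sampling truncates where the window overshoots the series", {
  tr <- flat_trajectory(rep(1, 401)) # 2000 years
  sm <- collect_value_samples(tr, horizon = 1000)
  expect_equal(nrow(sm), 2 * 201) # 201 windows per ecosystem service
  expect_equal(sort(unique(sm$t)), seq(0, 1000, 5))
  # boundary: series length equals the horizon, exactly one sample
  one <- collect_value_samples(flat_trajectory(rep(1, 201)), horizon = 1000)
  expect_equal(nrow(one), 2)
  expect_equal(unique(one$t), 0)
  expect_error(collect_value_samples(flat_trajectory(rep(1, 100))),
               "shorter")
})

test_that("value samples scale linearly in the provisions", {
  tr <- flat_trajectory(cf = sin(1:241) * 100, carbon = cos(1:241)^2)
  s1 <- collect_value_samples(tr, horizon = 1000)
  tr2 <- tr
  tr2$cf <- 3 * tr2$cf
  tr2$carbon <- 3 * tr2$carbon
  s2 <- collect_value_samples(tr2, horizon = 1000)
  expect_equal(s2$value, 3 * s1$value, tolerance = 1e-12)
})

test_that("deterministic clear-cut samples collapse to one value per state", {
  tr <- deterministic_trajectory(clearcut_regime(), series_years = 2000)
  sm <- collect_value_samples(tr, horizon = 1000)
  spread <- sm |>
    dplyr::summarise(
      d = max(value) - min(value), v = mean(abs(value)),
      .by = c(es, lead_age)
    )
  # all samples of a state agree up to the truncation error of the window
  expect_true(all(spread$d / pmax(spread$v, 1) < 1e-4))
})

test_that("aggregation groups by state without cross-contamination", {
  sm <- tibble::tibble(
    regime_id = "r", run = 1L, t = c(0, 5, 10),
    lead_age = c(10, 10, 20), gap_age = NA_real_, lead_share = 1,
    es = "financial", value = c(10, 20, 99)
  )
  vt <- aggregate_by_state(sm, min_n = 2)
  expect_equal(nrow(vt), 2)
  expect_equal(vt$mean[vt$lead_age == 10], 15)
  expect_equal(vt$n[vt$lead_age == 10], 2)
  expect_equal(vt$mean[vt$lead_age == 20], 99)
  expect_true(vt$low_n[vt$lead_age == 20])
  expect_error(aggregate_by_state(sm[0, ]), "No samples")
})

test_that("the first sample of each run is the soil expectation value", {
  tr <- deterministic_trajectory(clearcut_regime(), series_years = 2000)
  sm <- collect_value_samples(tr, horizon = 1000)
  sev <- sev_distribution(sm)
  expect_equal(nrow(sev), 2) # one per ecosystem service for the single run
  sev_f <- sev$sev[sev$es == "financial"]
  # Faustmann geometric-series oracle, computed straight from the tables
  oracle <- faustmann_sev(zero_hazard_params())
  expect_equal(sev_f, oracle, tolerance = 1e-5)
  # runs must start from bare soil
  bad <- sm
  bad$lead_age[bad$t == 0] <- 30
  expect_error(sev_distribution(bad), "bare soil")
})

test_that("stochastic SEV extraction returns one value per run", {
  reg <- dplyr::bind_rows(clearcut_regime(), gapcut_regime(0.2, 40))
  tr <- simulate_regimes(reg, n_runs = 4, seed = 5, test_params(),
                         series_years = 1000)
  sm <- collect_value_samples(tr, horizon = 1000)
  sev <- sev_distribution(sm)
  expect_equal(nrow(sev), 2 * 2 * 4)
  expect_equal(as.vector(table(sev$regime_id)), c(8L, 8L))
})
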