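test_that("the threshold is the baseline's time-occupancy mean and is linear", {
  sm <- tibble::tibble(
    regime_id = c("clearcut", "clearcut", "gap"), run = 1L, t = c(0, 5, 0),
    lead_age = 0, gap_age = NA_real_, lead_share = 1,
    es = "financial", value = c(10, 30, 999)
  )
  th <- compute_threshold(sm)
  expect_equal(th$threshold, 20) # gap samples are ignored
  sm2 <- sm
  sm2$value <- 2 * sm2$value
  expect_equal(compute_threshold(sm2)$threshold, 40)
  expect_error(compute_threshold(sm |> dplyr::filter(regime_id == "gap")),
               "baseline")
})

test_that("the sawtooth threshold equals the analytic time-average", {
  # deterministic clear-cut: the V path is periodic; its threshold must
  # match the mean of the window sums computed independently by the
  # generic discounting routine over the same sample times
  tr <- deterministic_trajectory(clearcut_regime(), series_years = 2000)
  sm <- collect_value_samples(tr, horizon = 1000)
  th <- compute_threshold(sm, baseline_id = "clearcut")
  t0s <- seq(0, 1000, 5)
  oracle_f <- mean(vapply(t0s, function(t0) {
    discounted_window_sum(tr$t, tr$cf, t0, 0.015, 1000)
  }, numeric(1)))
  expect_equal(th$threshold[th$es == "financial"], oracle_f,
               tolerance = 1e-10)
})

test_that("disturbance types partition every failure", {
  expect_equal(classify_disturbance(1, TRUE, FALSE, "planting"), 1L)
  expect_equal(classify_disturbance(2, TRUE, TRUE, "planting"), 2L)
  expect_equal(classify_disturbance(2, TRUE, FALSE, "planting"), 3L)
  expect_equal(classify_disturbance(2, TRUE, FALSE, "gap_regeneration"), 4L)
  expect_error(classify_disturbance(2, FALSE, FALSE, "planting"),
               "At least one")
  expect_error(classify_disturbance(2, FALSE, TRUE, "planting"),
               "Unclassifiable")
})

test_that("recovery times interpolate linearly between grid points", {
  expect_equal(recovery_time(c(0, 5), c(40, 60), 50)$t_recov, 2.5)
  expect_equal(recovery_time(c(0, 5), c(50, 60), 50)$t_recov, 0)
  r <- recovery_time(c(0, 5, 10, 15), c(40, 45, 48, 55), 50)
  expect_equal(r$t_recov, 10 + 5 * (50 - 48) / (55 - 48))
  expect_false(r$censored)
  cens <- recovery_time(c(0, 5, 10), c(10, 20, 30), 50)
  expect_true(cens$censored)
  expect_true(is.na(cens$t_recov))
})

# Hand-built two-regime world for the pairing rules: a "gap" regime and a
# baseline with known paths and events.
pairing_fixture <- function() {
  grid <- seq(0, 100, 5)
  path <- function(regime, es, run, v) {
    tibble::tibble(regime_id = regime, es = es, run = run, t = grid, v = v)
  }
  # baseline fails at t = 20 (type 1); gap regime fails at t = 20 (type 3)
  up <- function(start, slope) start + slope * grid
  paths <- dplyr::bind_rows(
    path("gap", "financial", 1L, up(40, 1)),
    path("base", "financial", 1L, up(40, 2))
  )
  events <- tibble::tibble(
    regime_id = c("gap", "base"), run = 1L, t = 20, type = c(3L, 1L)
  )
  thresholds <- tibble::tibble(es = "financial", threshold = 70)
  bare <- tibble::tibble(
    regime_id = c("gap", "base"), es = "financial", v_bare = c(30, 30)
  )
  list(paths = paths, events = events, thresholds = thresholds, bare = bare)
}

test_that("counterfactual pairing measures both regimes from the event step", {
  fx <- pairing_fixture()
  rec <- match_counterfactual(fx$events, fx$paths, fx$thresholds,
                              "gap", "base", fx$bare)
  expect_equal(nrow(rec), 1)
  # gap regime: type 3, path starts at t_e + 5 (v = 40 + t): the points
  # (5, 65), (10, 70) bracket the threshold -> recovery 10
  expect_equal(rec$t_recov, 10)
  # baseline: type 1, anchored at bare value 30 at the event, then from
  # t+5 (v = 40 + 2t): 40 + 2(rel t + 20) >= 70 at rel t = ... the first
  # path point v(25) = 90 >= 70, interpolated from the anchor:
  # 30 + (70-30)/(90-30)*5 = 10/3
  expect_equal(rec$t_recov_base, 5 * 40 / 60)
  expect_equal(rec$gain, 5 * 40 / 60 - 10)
})

test_that("an undisturbed counterpart contributes its (possibly zero) distance", {
  fx <- pairing_fixture()
  # drop the baseline event: baseline undisturbed at t = 20; its value
  # v(20) = 80 is already above the threshold -> recovery 0
  rec <- match_counterfactual(fx$events[1, ], fx$paths, fx$thresholds,
                              "gap", "base", fx$bare)
  expect_equal(rec$t_recov_base, 0)
  expect_true(is.na(rec$type_base))
  # a regime compared against itself gains nothing
  ev_self <- fx$events[2, ]
  rec_self <- match_counterfactual(ev_self, fx$paths, fx$thresholds,
                                   "base", "base", fx$bare)
  expect_equal(rec_self$gain, 0)
})

test_that("events past the path end are censored, not dropped silently", {
  fx <- pairing_fixture()
  ev <- fx$events
  ev$t <- 100 # at the very end of the path
  ev$type <- c(3L, 3L)
  low <- fx$paths
  low$v <- 0 # never recovers
  rec <- match_counterfactual(ev, low, fx$thresholds, "gap", "base", fx$bare)
  expect_true(all(rec$censored))
})

test_that("the trade-off metric is the SEV change per year of gain", {
  tr <- tradeoff(11000, 11936, 2.35)
  expect_equal(tr$tau, -936 / 2.35)
  expect_false(tr$dominant)
  expect_equal(tradeoff(5, 5, 5)$tau, 0) # boundary: dominant at zero cost
  expect_true(tradeoff(5, 5, 5)$dominant)
  expect_true(is.na(tradeoff(10, 5, 0)$tau))
  # identity: tau * mean gain reproduces the SEV difference exactly
  set.seed(9)
  for (i in 1:20) {
    sev_g <- rnorm(10, 10000, 500)
    sev_b <- rnorm(10, 10500, 500)
    gains <- rnorm(15, 3, 2)
    tr <- tradeoff(sev_g, sev_b, gains)
    expect_equal(tr$tau * tr$mean_gain, mean(sev_g) - mean(sev_b),
                 tolerance = 1e-12)
  }
})

test_that("a full assessment on a small simulated world is coherent", {
  reg <- dplyr::bind_rows(clearcut_regime(), gapcut_regime(0.3, 20),
                          gapcut_regime(0.3, 60))
  tr <- simulate_regimes(reg, n_runs = 12, seed = 21, test_params(),
                         series_years = 1500)
  sm <- collect_value_samples(tr, horizon = 1000)
  as <- assess_resilience(tr, sm)
  expect_s3_class(as, "standres_assessment")
  expect_setequal(unique(as$summary$regime_id),
                  setdiff(reg$id, "clearcut"))
  # tau identity at the aggregate level
  ok <- as$summary[!is.na(as$summary$tau), ]
  expect_equal(ok$tau * ok$mean_gain, ok$d_sev, tolerance = 1e-9)
  # every classified event type is within 1..4 and recovery times >= 0
  expect_true(all(as$records$type %in% c(NA, 1:4)))
  done <- as$records[!as$records$censored, ]
  expect_true(all(done$t_recov >= 0 & done$t_recov_base >= 0))
  # tidy/glance accessors
  expect_identical(tidy(as), as$summary)
  expect_equal(glance(as)$n_regimes, 2)
})
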