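# Shared fixtures: built in code, small enough for fast tests.

# Default parameter bundle, memoised per test file.
test_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- sim_params()
    p
  }
})

# Zero-hazard parameter bundle: infinite Weibull scale gives S(a) = 1 and
# hz = 0 exactly, so trajectories are fully deterministic.
zero_hazard_params <- function() {
  sim_params(survival = survival_model(alpha = Inf, beta = 1))
}

# A deterministic trajectory (no disturbance possible, y = 1 > hz always).
deterministic_trajectory <- function(regime, series_years = 2000,
                                     params = zero_hazard_params()) {
  tr <- simulate_trajectory(regime, rep(1, series_years / 5 + 1),
                            params, series_years)
  tr$regime_id <- regime$id
  tr$run <- 1L
  tr[, c("regime_id", "run", setdiff(names(tr), c("regime_id", "run")))]
}

# Independent Faustmann oracle for the zero-hazard clear-cut: present value
# of one rotation's cash flows as a geometric series, computed directly from
# the parameter tables (no simulator involved).
faustmann_sev <- function(params, r = 0.015, rotation = 85) {
  tab <- params$growth
  val <- params$valuation
  vol <- function(a) tab$standing_volume[tab$age == a]
  rem <- function(a) tab$thinning_removal[tab$age == a]
  rdbh <- function(a) tab$thinning_dbh[tab$age == a]
  dbh <- function(a) tab$mean_dbh[tab$age == a]
  thin_ages <- tab$age[tab$thinning_removal > 0 & tab$age < rotation]
  cycle <- -planting_cost("regular", 1, val) +
    sum(vapply(thin_ages, function(a) {
      net_revenue(rem(a), rdbh(a), "thinning", val) * (1 + r)^(-a)
    }, numeric(1))) +
    net_revenue(vol(rotation), dbh(rotation), "harvest", val) *
      (1 + r)^(-rotation)
  cycle / (1 - (1 + r)^(-rotation))
}
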