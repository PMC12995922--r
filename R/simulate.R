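#' Growth-modifier settings
#'
#' Bundles the coefficients of [suppression_multiplier()] and
#' [acceleration_multiplier()].
#'
#' @param c0,c1,m_min Suppression coefficients and floor.
#' @param gain,window Acceleration strength and decay window (years).
#' @return An object of class `growth_modifiers`.
#' @export
growth_modifiers <- function(c0 = 0.004, c1 = 0.006, m_min = 0.4,
                             gain = 0.5, window = 15) {
  structure(list(c0 = c0, c1 = c1, m_min = m_min, gain = gain,
                 window = window),
            class = "growth_modifiers")
}

#' Model parameter bundle
#'
#' Collects every parameter table/object the simulator needs: the growth
#' table (young ages filled automatically), the survival model and hazard
#' reduction, the growth modifiers, and the valuation/carbon parameters.
#'
#' @param growth A `growth_table`.
#' @param survival A [survival_model()].
#' @param reduction A [hazard_reduction()].
#' @param modifiers A [growth_modifiers()].
#' @param valuation A [valuation_params()].
#' @param carbon A [carbon_params()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(growth = growth_table() |> interpolate_young_ages(),
                       survival = survival_model(),
                       reduction = hazard_reduction(),
                       modifiers = growth_modifiers(),
                       valuation = valuation_params(),
                       carbon = carbon_params()) {
  if (min(growth$age) != 0) growth <- interpolate_young_ages(growth)
  structure(
    list(growth = growth, survival = survival, reduction = reduction,
         modifiers = modifiers, valuation = valuation, carbon = carbon),
    class = "sim_params"
  )
}

#' Simulate one stand trajectory
#'
#' Runs the stand-level disturbance, management and growth model for one
#' regime under one stream of uniform draws. Time advances in 5-year steps
#' from 0 to `series_years` (inclusive). Within each step, in order:
#'
#' 1. the *pre-event* stand state is recorded (this is the state under which
#'    the step's present-value sample is later filed);
#' 2. the shared uniform draw is compared against each cohort's hazard at
#'    its start-of-step age (reduced for non-leading cohorts); failed
#'    cohorts are salvage-logged at full standing volume under degraded
#'    price/cost factors and replanted immediately at doubled planting cost;
#' 3. surviving cohorts receive their scheduled management: final harvest
#'    plus replanting at rotation age, the prescribed gap cut when a single
#'    cohort passes `age_gap`, otherwise the yield table's thinning;
#' 4. cohorts grow by their modifier-adjusted gross increment and age by 5
#'    years; the step's gross increment defines the carbon provision.
#'
#' @param regime One-row regime tibble.
#' @param y Numeric vector of uniform draws, one per step
#'   (`length(y) >= series_years / 5 + 1`).
#' @param params A [sim_params()] bundle.
#' @param series_years Simulated series length in years.
#' @return A tibble with one row per step: time `t`, the pre-event state
#'   (`lead_age`, `gap_age`, `lead_share`, `lead_origin`, `gap_origin`,
#'   `n_cohorts`), disturbance flags (`disturbed`, `fail_lead`,
#'   `fail_gap`), and the step provisions `cf` (EUR/ha) and `carbon`
#'   (tC/ha).
#' @export
simulate_trajectory <- function(regime, y, params = sim_params(),
                                series_years = 2000) {
  check_regime(regime)
  step <- 5
  n_pts <- series_years / step + 1
  if (length(y) < n_pts) abort("Draw stream shorter than the series.")
  lk <- growth_lookup(params$growth)
  u <- regime$rotation_u
  if (lk$max_age < u) abort("Growth table does not reach rotation age.")
  gapcut <- regime$kind == "gapcut"
  s_gap <- regime$s_gap
  age_gap <- regime$age_gap
  hzt <- hazard_table(params$survival, max_age = u)
  hz_vec <- hzt$hz
  red <- params$reduction
  mod <- params$modifiers
  val <- params$valuation
  carb <- params$carbon

  # state: cohort 1 is leading (oldest); cohort 2 optional
  a1 <- 0; s1 <- 1; o1 <- "planting"; v1 <- 0; g1 <- 0
  a2 <- NA_real_; s2 <- 0; o2 <- NA_character_; v2 <- 0; g2 <- 0
  two <- FALSE
  t_since_gap <- Inf

  t_out <- numeric(n_pts)
  lead_age <- numeric(n_pts); gap_age <- rep(NA_real_, n_pts)
  lead_share <- numeric(n_pts); gap_share <- numeric(n_pts)
  lead_origin <- character(n_pts); gap_origin <- rep(NA_character_, n_pts)
  n_coh <- integer(n_pts)
  disturbed <- logical(n_pts); fail_lead <- logical(n_pts)
  fail_gap <- logical(n_pts)
  cf_out <- numeric(n_pts); c_out <- numeric(n_pts)

  for (i in seq_len(n_pts)) {
    t <- (i - 1) * step
    # 1. record pre-event state
    t_out[i] <- t
    lead_age[i] <- a1; lead_share[i] <- s1; lead_origin[i] <- o1
    n_coh[i] <- if (two) 2L else 1L
    if (two) { gap_age[i] <- a2; gap_share[i] <- s2; gap_origin[i] <- o2 }

    cf <- 0; carbon <- 0
    if (t == 0) cf <- cf - planting_cost("regular", 1, val)

    # 2. disturbance: shared draw vs per-cohort hazards at start-of-step age
    yi <- y[i]
    hz1 <- hz_vec[a1 / 5 + 1]
    f1 <- yi <= hz1
    f2 <- FALSE
    if (two) {
      hz2 <- reduced_hazard(hz_vec[a2 / 5 + 1], d_age = a1 - a2, size = s2,
                            reduction = red, leading = FALSE)
      f2 <- yi <= hz2
    }
    if (f1) {
      cf <- cf + net_revenue(v1, lk$dbh_at(g1), "salvage", val) -
        planting_cost("salvage", s1, val)
      a1 <- 0; o1 <- "salvage_replant"; v1 <- 0; g1 <- 0
      t_since_gap <- Inf
    }
    if (f2) {
      cf <- cf + net_revenue(v2, lk$dbh_at(g2), "salvage", val) -
        planting_cost("salvage", s2, val)
      a2 <- 0; o2 <- "salvage_replant"; v2 <- 0; g2 <- 0
    }
    disturbed[i] <- f1 || f2
    fail_lead[i] <- f1; fail_gap[i] <- two && f2

    # 3. scheduled management on surviving cohorts
    if (!f1 && a1 == u) {
      cf <- cf + net_revenue(v1, lk$dbh_at(g1), "harvest", val) -
        planting_cost("regular", s1, val)
      a1 <- 0; o1 <- "planting"; v1 <- 0; g1 <- 0
      t_since_gap <- Inf
    }
    if (two && !f2 && a2 == u) { # unreachable in practice (a2 < a1 <= u)
      cf <- cf + net_revenue(v2, lk$dbh_at(g2), "harvest", val) -
        planting_cost("regular", s2, val)
      a2 <- 0; o2 <- "planting"; v2 <- 0; g2 <- 0
    }
    if (!two && !f1 && gapcut && a1 == age_gap) {
      removed <- s_gap * v1
      cf <- cf + net_revenue(removed, lk$dbh_at(g1), "gap", val) -
        planting_cost("gap", s_gap, val)
      v1 <- v1 - removed
      s1 <- 1 - s_gap
      two <- TRUE
      a2 <- 0; s2 <- s_gap; o2 <- "gap_regeneration"; v2 <- 0; g2 <- 0
      t_since_gap <- 0
    } else {
      # thinning per yield table for cohorts not otherwise treated
      if (!f1 && a1 > 0 && a1 < u) {
        r1 <- lk$removal(a1)
        if (r1 > 0) {
          q1 <- v1 / (s1 * lk$volume(a1))
          rem <- s1 * q1 * r1
          cf <- cf + net_revenue(rem, lk$removal_dbh(a1), "thinning", val)
          v1 <- v1 - rem
        }
      }
    }
    if (two && !f2 && a2 > 0 && a2 < u) {
      r2 <- lk$removal(a2)
      if (r2 > 0) {
        q2 <- v2 / (s2 * lk$volume(a2))
        rem <- s2 * q2 * r2
        cf <- cf + net_revenue(rem, lk$removal_dbh(a2), "thinning", val)
        v2 <- v2 - rem
      }
    }

    # merge two bare (age-0) cohorts back into one
    if (two && a1 == 0 && a2 == 0) {
      s1 <- s1 + s2
      o1 <- if (o1 == "salvage_replant" && o2 == "salvage_replant")
        "salvage_replant" else "planting"
      v1 <- v1 + v2
      two <- FALSE
      a2 <- NA_real_; s2 <- 0; o2 <- NA_character_; v2 <- 0; g2 <- 0
    }
    # keep cohort 1 the older one
    if (two && a2 > a1) {
      tmp <- list(a1, s1, o1, v1, g1)
      a1 <- a2; s1 <- s2; o1 <- o2; v1 <- v2; g1 <- g2
      a2 <- tmp[[1]]; s2 <- tmp[[2]]; o2 <- tmp[[3]]; v2 <- tmp[[4]]; g2 <- tmp[[5]]
      t_since_gap <- Inf
    }

    # 4. growth over the step (every recorded point carries its full step
    # provisions, so the final window is not truncated mid-step)
    {
      m1 <- if (two && is.finite(t_since_gap)) {
        acceleration_multiplier(s_gap, t_since_gap, mod$gain, mod$window)
      } else 1
      inc1 <- s1 * m1 * lk$gross_increment(a1)
      v1 <- v1 + inc1
      g1 <- g1 + step * m1
      carbon <- carbon + inc1
      if (two) {
        # suppression concerns gap regeneration growing under the retained
        # canopy; unequal-aged neighbours otherwise grow independently
        m2 <- if (o2 == "gap_regeneration") {
          suppression_multiplier(a1 - a2, s2, mod$c0, mod$c1, mod$m_min)
        } else 1
        inc2 <- s2 * m2 * lk$gross_increment(a2)
        v2 <- v2 + inc2
        g2 <- g2 + step * m2
        carbon <- carbon + inc2
      }
      a1 <- a1 + step
      if (two) a2 <- a2 + step
      t_since_gap <- t_since_gap + step
    }
    carbon <- carbon * carb$conversion_t_m3
    cf_out[i] <- cf; c_out[i] <- carbon
  }

  tibble(
    t = t_out, lead_age = lead_age, gap_age = gap_age,
    lead_share = lead_share, gap_share = gap_share,
    lead_origin = lead_origin,
    gap_origin = gap_origin, n_cohorts = n_coh,
    disturbed = disturbed, fail_lead = fail_lead, fail_gap = fail_gap,
    cf = cf_out, carbon = c_out
  )
}

#' Simulate all regimes under common random numbers
#'
#' Simulates `n_runs` trajectories for every regime in `regimes`, re-using
#' the identical draw stream for all regimes within a run so that every
#' disturbance impulse has a direct counterfactual analog in every other
#' regime.
#'
#' @param regimes Tibble of regimes (e.g. [regime_set()]).
#' @param n_runs Number of Monte-Carlo runs per regime.
#' @param seed Master seed; streams are pure functions of `(seed, run)`.
#' @inheritParams simulate_trajectory
#' @return A tibble of per-step records with `regime_id` and `run` columns
#'   (see [simulate_trajectory()]).
#' @export
simulate_regimes <- function(regimes, n_runs, seed, params = sim_params(),
                             series_years = 2000) {
  n_pts <- series_years / 5 + 1
  ys <- draw_streams(n_runs, n_pts, seed)
  out <- vector("list", nrow(regimes) * n_runs)
  idx <- 0
  for (g in seq_len(nrow(regimes))) {
    regime <- regimes[g, ]
    for (k in seq_len(n_runs)) {
      idx <- idx + 1
      tr <- simulate_trajectory(regime, ys[, k], params, series_years)
      tr$regime_id <- regime$id
      tr$run <- k
      out[[idx]] <- tr
    }
  }
  bind_rows(out) |>
    select("regime_id", "run", dplyr::everything())
}
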