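#' Age-dependent survival model
#'
#' Survivor function S(a) giving the probability that a cohort reaches age
#' `a` undisturbed. The default functional form is a two-parameter Weibull,
#' `S(a) = exp(-(a/alpha)^beta)`; with `beta > 1` the derived hazard rate
#' increases with age, the qualitative pattern expected for storm-driven
#' mortality of even-aged Norway spruce. The shipped parameter values are
#' synthetic defaults -- site-specific survivor-curve coefficients are loaded
#' via configuration. Climate descriptors (mean warmest-month temperature,
#' warmest-quarter precipitation sum) are carried as provenance metadata
#' only; they do not enter the computation.
#'
#' @param alpha Weibull scale (years): the age at which S drops to exp(-1).
#' @param beta Weibull shape (dimensionless); > 1 for increasing hazard.
#' @param t_warm_c,p_warm_mm Climate provenance fields (deg C, mm).
#' @param step Step length in years (default 5).
#' @return An object of class `survival_model`.
#' @examples
#' m <- survival_model()
#' survival_probability(m, c(0, 50, 100))
#' @export
survival_model <- function(alpha = 200, beta = 2.75,
                           t_warm_c = NA_real_, p_warm_mm = NA_real_,
                           step = 5) {
  if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be positive.")
  structure(
    list(alpha = alpha, beta = beta,
         t_warm_c = t_warm_c, p_warm_mm = p_warm_mm, step = step),
    class = "survival_model"
  )
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf(
    "<survival_model Weibull(alpha = %g yr, beta = %g), step = %g yr>\n",
    x$alpha, x$beta, x$step
  ))
  invisible(x)
}

#' Survival probability at a given age
#'
#' @param model A [survival_model()].
#' @param age Age(s) in years, non-negative.
#' @return S(age), in `[0, 1]`, with S(0) = 1.
#' @export
survival_probability <- function(model, age) {
  if (any(age < 0)) abort("`age` must be non-negative.")
  exp(-(age / model$alpha)^model$beta)
}

#' Convert a survivor function to per-step hazard rates
#'
#' The hazard `hz(a) = 1 - S(a + step)/S(a)` is the probability that a cohort
#' surviving to age `a` fails within the next step (here: 5-year-step failure
#' probabilities).
#'
#' @param model A [survival_model()].
#' @param max_age Last age (years) of the tabulated grid.
#' @return Tibble `hazard_table` with columns `age`, `survival`, `hz`.
#' @examples
#' hazard_table(survival_model(), max_age = 85)
#' @export
hazard_table <- function(model, max_age = 200) {
  ages <- seq(0, max_age, by = model$step)
  s0 <- survival_probability(model, ages)
  s1 <- survival_probability(model, ages + model$step)
  if (any(s0 <= 0)) {
    abort("Survivor function reaches 0 inside the grid; hazard undefined.")
  }
  tibble(age = ages, survival = s0, hz = 1 - s1 / s0)
}

#' Hazard reduction for non-leading cohorts
#'
#' A cohort sheltered below taller neighbours grows less in height and is
#' therefore less wind-exposed than an even-aged cohort of the same age. The
#' reduction factor `red_hz` scales the cohort's hazard downward:
#' `hz_new = red_hz * hz` with `0 <= red_hz <= 1`. The default linear form
#' `red_hz = clamp(1 - (b0 + b1 * (1 - size)) * d_age, red_min, 1)`
#' is the simplest form with the required monotonicities: the reduction
#' strengthens with the age difference `d_age` to the leading cohort and is
#' stronger for smaller cohorts. Coefficients are configurable artifact
#' defaults, not empirical values.
#'
#' @param b0,b1 Linear coefficients (per year of age difference).
#' @param red_min Floor of the reduction factor.
#' @return An object of class `hazard_reduction`.
#' @export
hazard_reduction <- function(b0 = 0.002, b1 = 0.004, red_min = 0.3) {
  if (red_min < 0 || red_min > 1) abort("`red_min` must lie in [0, 1].")
  structure(list(b0 = b0, b1 = b1, red_min = red_min),
            class = "hazard_reduction")
}

#' Reduced hazard of a cohort
#'
#' Leading cohorts keep their unreduced hazard (gap-edge wind loading and
#' longer-term edge-tree stability gains are assumed to offset each other);
#' non-leading cohorts are scaled by the reduction factor.
#'
#' @param hz Unreduced per-step hazard(s) in `[0, 1]`.
#' @param d_age Age difference (years) to the leading cohort, >= 0.
#' @param size Area share of the cohort (the gap share for a fresh gap
#'   cohort).
#' @param reduction A [hazard_reduction()].
#' @param leading Logical; `TRUE` leaves `hz` unchanged.
#' @return Reduced hazard(s).
#' @examples
#' reduced_hazard(0.05, d_age = 50, size = 0.3)
#' @export
reduced_hazard <- function(hz, d_age, size, reduction = hazard_reduction(),
                           leading = FALSE) {
  stopifnot(all(hz >= 0 & hz <= 1), all(d_age >= 0))
  if (isTRUE(leading)) return(hz)
  red <- 1 - (reduction$b0 + reduction$b1 * (1 - size)) * d_age
  red <- pmin(1, pmax(reduction$red_min, red))
  hz * red
}

#' Shared-draw step outcome
#'
#' One uniform draw `y` per stand per step is compared against every
#' cohort's (possibly reduced) hazard: cohort `i` fails iff `y <= hz[i]`,
#' and failure is always a complete drop-out of the cohort. Sharing the draw
#' across cohorts deliberately correlates their failures: whenever hazards
#' are ordered (older/leading above younger/sheltered), failure of the less
#' exposed cohort implies failure of the more exposed one.
#'
#' @param hz Numeric vector of per-cohort hazards.
#' @param y Uniform draw in `[0, 1]` for the whole stand.
#' @return Logical vector: `TRUE` where the cohort fails.
#' @examples
#' draw_step_outcome(c(0.05, 0.01), y = 0.03) # leading fails, gap survives
#' @export
draw_step_outcome <- function(hz, y) {
  if (y < 0 || y > 1) abort("`y` must lie in [0, 1].")
  stopifnot(all(hz >= 0 & hz <= 1))
  y <= hz
}

#' Reproducible per-run draw streams
#'
#' One stream of uniform draws per simulation run (one draw per time step for
#' the whole stand). Streams are a pure function of `(seed, run)`: random
#' seeds vary between runs but are held constant across regimes within a
#' run, so all regimes experience identical disturbance impulses (common
#' random numbers), which is what makes the later event pairing
#' counterfactual.
#'
#' @param n_runs Number of runs.
#' @param n_steps Number of time steps per run.
#' @param seed Master seed (integer).
#' @return A numeric matrix with `n_steps` rows and `n_runs` columns.
#' @examples
#' identical(draw_streams(3, 10, 1), draw_streams(3, 10, 1))
#' @export
draw_streams <- function(n_runs, n_steps, seed) {
  stopifnot(n_runs >= 1, n_steps >= 1)
  sub_seeds <- run_seeds(n_runs, seed)
  vapply(sub_seeds, function(s) {
    withr_seed <- .Random.seed_exists()
    on.exit(restore_seed(withr_seed), add = TRUE)
    set.seed(s)
    runif(n_steps)
  }, numeric(n_steps))
}

# Derived per-run sub-seeds, pure in (seed, k), kept below 2^31.
run_seeds <- function(n_runs, seed) {
  (as.integer(seed) + 977L * seq_len(n_runs)) %% 2147483629L
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
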