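#' Discounted moving-window sum
#'
#' One present-value sample: the sum of provisions inside the window
#' `[t0, t0 + horizon]`, discounted to `t0` with annual compounding,
#' `sum p_t (1 + r)^-(t - t0)`. The window must fit inside the series; the
#' truncation rule (dropping windows that overshoot the series end) is the
#' caller's job.
#'
#' @param t Times (years) of the provisions.
#' @param p Provisions (EUR/ha or tC/ha) at those times.
#' @param t0 Window start (years).
#' @param r Annual discount rate.
#' @param horizon Window length in years.
#' @return A single present value.
#' @examples
#' discounted_window_sum(seq(0, 1000, 5), rep(1, 201), 0, 0.015, 1000)
#' @export
discounted_window_sum <- function(t, p, t0, r, horizon = 1000) {
  if (t0 + horizon > max(t)) {
    abort("Window overshoots the end of the series.")
  }
  inside <- t >= t0 & t <= t0 + horizon
  sum(p[inside] * (1 + r)^(-(t[inside] - t0)))
}

# O(n) window sums on the regular 5-yr grid via discounted suffix sums:
# W_i = S_i - d^(m+1) S_{i+m+1},  S_i = p_i + d S_{i+1},  d = (1+r)^-5.
window_sums_grid <- function(p, r, m, step = 5) {
  n <- length(p)
  d <- (1 + r)^(-step)
  s <- numeric(n + 1)
  for (i in n:1) s[i] <- p[i] + d * s[i + 1]
  i <- seq_len(n - m)
  s[i] - d^(m + 1) * s[i + m + 1]
}

#' Collect present-value samples along simulated series
#'
#' Rolls the 1000-year moving window along every simulated provision series
#' and emits one value sample per grid time whose window still fits inside
#' the series (the series is truncated where the window would overshoot).
#' Each sample is tagged with the pre-event stand state at the window start,
#' under which it is later aggregated. Net revenues and carbon provisions
#' are discounted separately at their own rates.
#'
#' @param trajectories Per-step records from [simulate_regimes()].
#' @param horizon Window length in years (default 1000).
#' @param r_financial,r_carbon Annual discount rates (defaults 0.015 and
#'   0.005).
#' @return A tibble of samples: `regime_id`, `run`, `t`, state columns
#'   (`lead_age`, `gap_age`, `lead_share`), `es`
#'   (`"financial"`/`"carbon"`) and `value`.
#' @export
collect_value_samples <- function(trajectories, horizon = 1000,
                                  r_financial = 0.015, r_carbon = 0.005) {
  t_end <- max(trajectories$t)
  if (t_end < horizon) abort("Series shorter than the window horizon.")
  m <- horizon / 5
  one_run <- function(df) {
    n_keep <- nrow(df) - m
    base <- df[seq_len(n_keep),
               c("t", "lead_age", "gap_age", "lead_share")]
    bind_rows(
      mutate(base, es = "financial",
             value = window_sums_grid(df$cf, r_financial, m)),
      mutate(base, es = "carbon",
             value = window_sums_grid(df$carbon, r_carbon, m))
    )
  }
  trajectories |>
    group_by(.data$regime_id, .data$run) |>
    dplyr::group_modify(~ one_run(.x)) |>
    ungroup()
}

#' Aggregate value samples per stand state
#'
#' Groups the moving-window samples by their canonical state key and
#' estimates each state's expected present value as the sample mean. States
#' visited fewer than `min_n` times are flagged (`low_n`) rather than
#' silently trusted.
#'
#' @param samples Output of [collect_value_samples()].
#' @param min_n Minimum sample count below which a state is flagged.
#' @return A `value table`: one row per (regime, es, state) with `mean`,
#'   `n`, `se`, `low_n`.
#' @export
aggregate_by_state <- function(samples, min_n = 10) {
  if (nrow(samples) == 0) abort("No samples to aggregate.")
  samples |>
    group_by(.data$regime_id, .data$es, .data$lead_age, .data$gap_age,
             .data$lead_share) |>
    summarise(
      mean = mean(.data$value),
      n = dplyr::n(),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    mutate(
      key = state_key(.data$regime_id, .data$lead_age, .data$gap_age,
                      .data$lead_share),
      low_n = .data$n < min_n
    )
}

#' Soil expectation values per run
#'
#' Every simulation starts from bare forest soil, so the first value sample
#' of each run *is* that run's soil expectation value (SEV): the discounted
#' value of the infinite management sequence started on bare ground. This
#' extracts one SEV per (regime, es, run).
#'
#' @param samples Output of [collect_value_samples()].
#' @return Tibble `regime_id`, `es`, `run`, `sev`.
#' @export
sev_distribution <- function(samples) {
  first <- samples |> filter(.data$t == 0)
  bad <- first |> filter(.data$lead_age != 0 | !is.na(.data$gap_age))
  if (nrow(bad) > 0) abort("A run does not start from bare soil.")
  first |>
    select("regime_id", "es", "run", sev = "value") |>
    arrange(.data$regime_id, .data$es, .data$run)
}
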