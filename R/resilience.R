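#' Recovery threshold of an ecosystem service
#'
#' The reference level a disturbed stand must regain: the average present
#' value under the baseline clear-cut regime, taken as the unweighted mean
#' over all sampled time steps and runs of the baseline (a time-occupancy
#' mean).
#'
#' @param samples Value samples from [collect_value_samples()].
#' @param baseline_id Regime id of the clear-cut baseline.
#' @return Tibble `es`, `threshold`.
#' @export
compute_threshold <- function(samples, baseline_id = "clearcut") {
  base <- samples |> filter(.data$regime_id == baseline_id)
  if (nrow(base) == 0) abort("No baseline samples found.")
  base |>
    group_by(.data$es) |>
    summarise(threshold = mean(.data$value), .groups = "drop")
}

#' Classify a disturbance event
#'
#' Total partition of simulated cohort failures into the four disturbance
#' types:
#'
#' 1. complete failure of a single-cohort stand with no regeneration
#'    present (before any gap cut);
#' 2. complete failure of a two-cohort stand (regeneration present but also
#'    lost);
#' 3. failure of only the older cohort of a two-cohort stand;
#' 4. failure replacing a former gap cohort that had become the leading
#'    cohort.
#'
#' Vectorised; any failure combination outside the partition (e.g. a
#' sheltered cohort failing while the leading cohort survives, impossible
#' under shared draws with age-increasing hazards) is an error.
#'
#' @param n_cohorts Number of cohorts before the disturbance (1 or 2).
#' @param fail_lead,fail_gap Logical: which cohorts failed.
#' @param lead_origin Origin of the pre-disturbance leading cohort.
#' @return Integer vector of types 1-4.
#' @examples
#' classify_disturbance(1, TRUE, FALSE, "planting") # 1
#' classify_disturbance(2, TRUE, FALSE, "gap_regeneration") # 4
#' @export
classify_disturbance <- function(n_cohorts, fail_lead, fail_gap,
                                 lead_origin) {
  if (any(!fail_lead & !fail_gap)) {
    abort("At least one cohort must have failed.")
  }
  type <- dplyr::case_when(
    n_cohorts == 1 & fail_lead ~ 1L,
    n_cohorts == 2 & fail_lead & fail_gap ~ 2L,
    n_cohorts == 2 & fail_lead & !fail_gap &
      lead_origin == "gap_regeneration" ~ 4L,
    n_cohorts == 2 & fail_lead & !fail_gap ~ 3L,
    TRUE ~ NA_integer_
  )
  if (anyNA(type)) {
    abort("Unclassifiable failure combination (partition must be total).")
  }
  type
}

#' Extract classified disturbance events from trajectories
#'
#' @param trajectories Output of [simulate_regimes()].
#' @param t_max Latest event time to keep (normally the last time the value
#'   path is defined, `series length - horizon`); `Inf` keeps all.
#' @return Tibble `regime_id`, `run`, `t`, `type`.
#' @export
disturbance_events <- function(trajectories, t_max = Inf) {
  ev <- trajectories |> filter(.data$disturbed, .data$t <= t_max)
  if (nrow(ev) == 0) {
    return(tibble(regime_id = character(), run = integer(), t = double(),
                  type = integer()))
  }
  ev |>
    mutate(type = classify_disturbance(.data$n_cohorts, .data$fail_lead,
                                       .data$fail_gap, .data$lead_origin)) |>
    select("regime_id", "run", "t", "type")
}

#' Interpolated recovery time
#'
#' First time at which a post-disturbance value path regains the threshold,
#' interpolated linearly between the two bracketing grid points. Times are
#' relative to the disturbance event. If the first supplied point is already
#' at or above the threshold the recovery time is 0; if the path never
#' crosses before it ends, the event is censored (`t_recov = NA`).
#'
#' @param t Times (years) relative to the event, increasing.
#' @param v Value path at those times.
#' @param threshold Recovery threshold.
#' @return One-row tibble `t_recov`, `censored`.
#' @examples
#' recovery_time(c(0, 5, 10, 15), c(40, 45, 48, 55), 50) # 11.43 yr
#' @export
recovery_time <- function(t, v, threshold) {
  tr <- rec_time_scan(t, v, threshold)
  tibble(t_recov = tr, censored = is.na(tr))
}

rec_time_scan <- function(t, v, threshold) {
  if (length(v) == 0) return(NA_real_)
  if (v[1] >= threshold) return(0)
  above <- which(v >= threshold)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  t[i - 1] + (t[i] - t[i - 1]) * (threshold - v[i - 1]) / (v[i] - v[i - 1])
}

#' Re-join state values onto trajectories
#'
#' Builds the estimated present-value path of every run by looking each
#' sampled stand state up in the aggregated value table.
#'
#' @param samples Value samples from [collect_value_samples()].
#' @param value_table Output of [aggregate_by_state()].
#' @return Tibble `regime_id`, `es`, `run`, `t`, `v`.
#' @export
value_paths <- function(samples, value_table) {
  samples |>
    left_join(
      value_table |> select("regime_id", "es", "lead_age", "gap_age",
                            "lead_share", v = "mean"),
      by = c("regime_id", "es", "lead_age", "gap_age", "lead_share")
    ) |>
    select("regime_id", "es", "run", "t", "v") |>
    arrange(.data$regime_id, .data$es, .data$run, .data$t)
}

# Internal: fast path store -- one value matrix (time x run) per regime/es.
path_matrices <- function(paths) {
  grid <- sort(unique(paths$t))
  runs <- sort(unique(paths$run))
  out <- list()
  for (key in unique(paste(paths$regime_id, paths$es, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- paths |> filter(.data$regime_id == parts[1], .data$es == parts[2])
    m <- matrix(NA_real_, nrow = length(grid), ncol = length(runs))
    m[cbind(match(sub$t, grid), match(sub$run, runs))] <- sub$v
    out[[key]] <- m
  }
  list(grid = grid, runs = runs, mats = out)
}

#' Pair disturbance events counterfactually across regimes
#'
#' Because all regimes of a run share one draw stream, every disturbance in
#' one regime has a direct analog in every other. For each (run, step) at
#' which either the gap-cut regime or the baseline registers a failure, this
#' measures both regimes' recovery times from that step and their
#' difference (gain = baseline - gap):
#'
#' * a regime disturbed at the step starts its recovery clock at the event;
#'   for stand-replacing events (types 1/2) the path is anchored at the
#'   event time with the regime's bare-soil value (a stand-replacing
#'   disturbance resets V to its bare-soil default), for partial events
#'   (types 3/4) at the first post-event sample;
#' * a regime undisturbed at the step contributes the (possibly zero) time
#'   its value path needs to reach the threshold from that step.
#'
#' Events whose recovery is not observed before the path ends are censored
#' and excluded from mean gains (but counted).
#'
#' @param events Classified events from [disturbance_events()].
#' @param paths Value paths from [value_paths()].
#' @param thresholds Output of [compute_threshold()].
#' @param regime_id Gap-cut regime to assess.
#' @param baseline_id Clear-cut baseline regime id.
#' @param bare_values Tibble `regime_id`, `es`, `v_bare` with each regime's
#'   bare-soil state value (mean SEV); taken from the value table.
#' @return Tibble of recovery records: `regime_id`, `es`, `run`, `t`,
#'   `type` (gap-regime event type, `NA` if only the baseline failed),
#'   `type_base`, `t_recov`, `t_recov_base`, `gain`, `censored`.
#' @export
match_counterfactual <- function(events, paths, thresholds, regime_id,
                                 baseline_id = "clearcut", bare_values) {
  runs_g <- unique(paths$run[paths$regime_id == regime_id])
  runs_b <- unique(paths$run[paths$regime_id == baseline_id])
  if (!setequal(runs_g, runs_b)) {
    abort("Regime and baseline were not simulated over the same runs; counterfactual pairing requires common random numbers.")
  }
  pm <- path_matrices(paths)
  grid <- pm$grid
  ev_g <- events |> filter(.data$regime_id == !!regime_id)
  ev_b <- events |> filter(.data$regime_id == baseline_id)
  type_of <- function(ev) {
    setNames(ev$type, paste(ev$run, ev$t))
  }
  tg <- type_of(ev_g); tb <- type_of(ev_b)
  union_ev <- dplyr::bind_rows(ev_g[c("run", "t")], ev_b[c("run", "t")]) |>
    distinct() |> arrange(.data$run, .data$t)
  out <- vector("list", length(unique(paths$es)))
  es_i <- 0
  for (es in sort(unique(paths$es))) {
    es_i <- es_i + 1
    thr <- thresholds$threshold[thresholds$es == es]
    mg <- pm$mats[[paste(regime_id, es, sep = "\r")]]
    mb <- pm$mats[[paste(baseline_id, es, sep = "\r")]]
    vb_g <- bare_values$v_bare[bare_values$regime_id == regime_id &
                                 bare_values$es == es]
    vb_b <- bare_values$v_bare[bare_values$regime_id == baseline_id &
                                 bare_values$es == es]
    n_ev <- nrow(union_ev)
    rec_g <- numeric(n_ev); rec_b <- numeric(n_ev)
    typ_g <- integer(n_ev); typ_b <- integer(n_ev)
    for (j in seq_len(n_ev)) {
      run <- union_ev$run[j]; t_e <- union_ev$t[j]
      ki <- match(run, pm$runs)
      ti <- match(t_e, grid)
      key <- paste(run, t_e)
      after <- if (ti < length(grid)) seq(ti + 1, length(grid)) else integer(0)
      one_side <- function(mat, type, v_bare) {
        if (is.na(type)) { # undisturbed at this step
          rel_t <- grid[ti:length(grid)] - t_e
          v <- mat[ti:length(grid), ki]
        } else if (type %in% c(1L, 2L)) { # stand-replacing: bare-soil anchor
          rel_t <- c(0, grid[after] - t_e)
          v <- c(v_bare, mat[after, ki])
        } else { # partial: first post-event sample
          if (length(after) == 0) return(NA_real_)
          rel_t <- grid[after] - t_e
          v <- mat[after, ki]
        }
        rec_time_scan(rel_t, v, thr)
      }
      typ_g[j] <- tg[key] %||% NA_integer_
      typ_b[j] <- tb[key] %||% NA_integer_
      rec_g[j] <- one_side(mg, typ_g[j], vb_g)
      rec_b[j] <- one_side(mb, typ_b[j], vb_b)
    }
    out[[es_i]] <- tibble(
      regime_id = regime_id, es = es,
      run = union_ev$run, t = union_ev$t,
      type = typ_g, type_base = typ_b,
      t_recov = rec_g, t_recov_base = rec_b,
      gain = rec_b - rec_g,
      censored = is.na(rec_g) | is.na(rec_b)
    )
  }
  bind_rows(out)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

#' Performance/resilience trade-off metric
#'
#' The trade-off metric divides the mean SEV difference of a gap-cut regime
#' relative to the baseline by its mean recovery-time gain:
#' `tau = mean(SEV_gap - SEV_base) / mean(gain)`, the SEV change that must
#' be accepted for one year of average recovery-time reduction. A regime is
#' *dominant* when it improves resilience at no performance cost: positive
#' mean gain with a non-negative SEV change (equivalently `tau >= 0` on the
#' resilience-improving side). With a zero mean gain the metric is
#' undefined and reported as `NA`.
#'
#' @param sev_regime,sev_baseline Numeric vectors of per-run SEVs.
#' @param gains Numeric vector of per-event recovery gains (years),
#'   censored events removed.
#' @return One-row tibble `d_sev`, `mean_gain`, `tau`, `dominant`.
#' @examples
#' tradeoff(11000, 11936, 2.35) # tau approx -398
#' @export
tradeoff <- function(sev_regime, sev_baseline, gains) {
  d_sev <- mean(sev_regime) - mean(sev_baseline)
  mean_gain <- mean(gains)
  tau <- if (isTRUE(all.equal(mean_gain, 0))) NA_real_ else d_sev / mean_gain
  tibble(
    d_sev = d_sev, mean_gain = mean_gain, tau = tau,
    dominant = !is.na(mean_gain) & mean_gain > 0 & d_sev >= 0
  )
}

#' Full resilience and trade-off assessment
#'
#' Runs the complete assessment stage: thresholds from the baseline,
#' classified disturbance events, counterfactual pairing of every gap-cut
#' regime against the baseline, per-regime mean recovery-time gains, SEV
#' distributions and trade-off metrics.
#'
#' @param trajectories Output of [simulate_regimes()] (must contain the
#'   baseline).
#' @param samples Output of [collect_value_samples()].
#' @param value_table Output of [aggregate_by_state()]; recomputed when
#'   omitted.
#' @param baseline_id Id of the clear-cut baseline regime.
#' @return An object of class `standres_assessment`: list with `summary`
#'   (per regime and es: mean gain, relative gain, SEV statistics, tau),
#'   `records` (per paired event), `thresholds`, `baseline_recovery`
#'   (per es: mean recovery time of the baseline's own events), `sev`
#'   (per-run SEVs).
#' @export
assess_resilience <- function(trajectories, samples,
                              value_table = aggregate_by_state(samples),
                              baseline_id = "clearcut") {
  thresholds <- compute_threshold(samples, baseline_id)
  t_max <- max(samples$t)
  events <- disturbance_events(trajectories, t_max = t_max)
  paths <- value_paths(samples, value_table)
  sev <- sev_distribution(samples)
  bare_values <- value_table |>
    filter(.data$lead_age == 0, is.na(.data$gap_age)) |>
    select("regime_id", "es", v_bare = "mean")

  # baseline's own average recovery time
  base_records <- match_counterfactual(
    events |> filter(.data$regime_id == baseline_id),
    paths |> filter(.data$regime_id == baseline_id),
    thresholds, baseline_id, baseline_id, bare_values
  )
  baseline_recovery <- base_records |>
    filter(!.data$censored) |>
    group_by(.data$es) |>
    summarise(mean_recovery = mean(.data$t_recov),
              n_events = dplyr::n(), .groups = "drop")

  gap_ids <- setdiff(unique(trajectories$regime_id), baseline_id)
  records <- purrr::map(gap_ids, function(g) {
    match_counterfactual(events, paths, thresholds, g, baseline_id,
                         bare_values)
  }) |> bind_rows()

  sev_means <- sev |>
    group_by(.data$regime_id, .data$es) |>
    summarise(mean_sev = mean(.data$sev), .groups = "drop")
  base_sev <- sev |> filter(.data$regime_id == baseline_id)

  summary <- purrr::map(gap_ids, function(g) {
    purrr::map(sort(unique(samples$es)), function(es) {
      rec <- records |> filter(.data$regime_id == g, .data$es == !!es)
      ok <- rec |> filter(!.data$censored)
      sev_g <- sev |> filter(.data$regime_id == g, .data$es == !!es) |>
        pull("sev")
      sev_b <- base_sev |> filter(.data$es == !!es) |> pull("sev")
      base_rec <- baseline_recovery$mean_recovery[baseline_recovery$es == es]
      if (length(base_rec) == 0) base_rec <- NA_real_
      tradeoff(sev_g, sev_b, ok$gain) |>
        mutate(
          regime_id = g, es = es,
          rel_gain = .data$mean_gain / base_rec,
          mean_sev = mean(sev_g), mean_sev_baseline = mean(sev_b),
          n_events = nrow(rec), n_censored = sum(rec$censored),
          .before = 1
        )
    }) |> bind_rows()
  }) |> bind_rows() |>
    select("regime_id", "es", "mean_gain", "rel_gain", "n_events",
           "n_censored", "mean_sev", "mean_sev_baseline", "d_sev", "tau",
           "dominant")

  structure(
    list(summary = summary, records = records, thresholds = thresholds,
         baseline_recovery = baseline_recovery, sev = sev,
         baseline_id = baseline_id),
    class = "standres_assessment"
  )
}

#' @export
print.standres_assessment <- function(x, ...) {
  cat("Stand-level resilience assessment\n")
  cat(sprintf("  baseline: %s\n", x$baseline_id))
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  threshold (%s): %.4g\n", x$thresholds$es[i],
                x$thresholds$threshold[i]))
  }
  for (i in seq_len(nrow(x$baseline_recovery))) {
    cat(sprintf("  baseline mean recovery (%s): %.2f yr over %d events\n",
                x$baseline_recovery$es[i],
                x$baseline_recovery$mean_recovery[i],
                x$baseline_recovery$n_events[i]))
  }
  cat(sprintf("  %d gap-cut regimes assessed\n",
              length(unique(x$summary$regime_id))))
  print(x$summary)
  invisible(x)
}

#' Tidy an assessment
#'
#' `tidy()` returns the per-regime summary table; `glance()` a one-row
#' overview (thresholds, baseline recovery times, best trade-offs).
#'
#' @param x A `standres_assessment`.
#' @param ... Unused.
#' @export
tidy.standres_assessment <- function(x, ...) {
  x$summary
}

#' @rdname tidy.standres_assessment
#' @export
glance.standres_assessment <- function(x, ...) {
  wide <- function(df, col, prefix = col) {
    if (nrow(df) == 0) return(list())
    setNames(as.list(df[[col]]), paste0(prefix, "_", df$es))
  }
  best <- x$summary |>
    group_by(.data$es) |>
    dplyr::slice_max(.data$tau, n = 1, with_ties = FALSE) |>
    ungroup()
  as_tibble(c(
    list(n_regimes = length(unique(x$summary$regime_id))),
    wide(x$thresholds, "threshold"),
    wide(x$baseline_recovery, "mean_recovery", "baseline_recovery"),
    wide(best, "tau", "best_tau")
  ))
}
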