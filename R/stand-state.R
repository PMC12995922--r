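#' Stand states
#'
#' A stand state is the discrete cohort composition that keys every value
#' estimate: one or two age-homogeneous cohorts, each with an age (a multiple
#' of the 5-year step), an area share, and an origin
#' (`"planting"`, `"gap_regeneration"` or `"salvage_replant"`). The older
#' cohort is the *leading* cohort; cohorts of equal age merge into one, so a
#' stand never holds more than two cohorts.
#'
#' @param ages Numeric vector (length 1 or 2) of cohort ages in years;
#'   multiples of 5. `NA` marks a harvested, not-yet-replanted area.
#' @param shares Area shares, summing to 1.
#' @param origins Character vector of cohort origins.
#' @param regime_id Label of the regime the stand is managed under.
#' @return An object of class `stand_state`: a list with fields `ages`,
#'   `shares`, `origins`, `regime_id`, cohorts ordered oldest first.
#' @examples
#' stand_state(c(40, 0), c(0.7, 0.3), c("planting", "gap_regeneration"))
#' @export
stand_state <- function(ages, shares, origins = rep("planting", length(ages)),
                        regime_id = "clearcut") {
  n <- length(ages)
  if (n < 1 || n > 2) abort("A stand holds 1 or 2 cohorts.")
  if (length(shares) != n || length(origins) != n) {
    abort("`ages`, `shares` and `origins` must have equal length.")
  }
  if (any(shares <= 0) || abs(sum(shares) - 1) > 1e-9) {
    abort("Cohort shares must be positive and sum to 1.")
  }
  if (any(!is.na(ages) & (ages < 0 | ages %% 5 != 0))) {
    abort("Cohort ages must be non-negative multiples of 5.")
  }
  # merge equal-aged cohorts (also handles two fresh replants)
  if (n == 2 && !anyNA(ages) && ages[1] == ages[2]) {
    origin <- if (all(origins == "salvage_replant")) "salvage_replant" else origins[1]
    ages <- ages[1]; shares <- sum(shares); origins <- origin
    n <- 1
  }
  if (n == 2) {
    ord <- order(ages, decreasing = TRUE, na.last = TRUE)
    ages <- ages[ord]; shares <- shares[ord]; origins <- origins[ord]
  }
  structure(
    list(ages = ages, shares = shares, origins = origins,
         regime_id = regime_id),
    class = "stand_state"
  )
}

#' @export
format.stand_state <- function(x, ...) {
  coh <- paste(
    sprintf("%s yr (%.0f%%, %s)", ifelse(is.na(x$ages), "bare", x$ages),
            100 * x$shares, x$origins),
    collapse = " + "
  )
  sprintf("<stand_state [%s] %s>", x$regime_id, coh)
}

#' @export
print.stand_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Canonical state key
#'
#' The key under which present-value samples are aggregated: regime, leading
#' age, gap-cohort age (or none) and leading share. Vectorised over its
#' arguments.
#'
#' @param regime_id,lead_age,gap_age,lead_share Key components; `gap_age` is
#'   `NA` for single-cohort stands.
#' @return Character vector of keys.
#' @export
state_key <- function(regime_id, lead_age, gap_age, lead_share) {
  sprintf(
    "%s|%s|%s|%s", regime_id, lead_age,
    ifelse(is.na(gap_age), "-", gap_age),
    formatC(round(lead_share, 6), format = "g")
  )
}

key_of_state <- function(state) {
  state_key(
    state$regime_id, state$ages[1],
    if (length(state$ages) == 2) state$ages[2] else NA_real_,
    state$shares[1]
  )
}

#' Deterministic management schedule
#'
#' Returns the management actions a regime prescribes for a stand state at
#' the current step, as a tibble of actions. The schedule is a total,
#' deterministic function of the state:
#'
#' * a **gap cut** when the stand holds exactly one cohort at age `age_gap`
#'   under a gap-cut regime (creating the regeneration cohort);
#' * a **final harvest** plus **replant** for any cohort at rotation age;
#' * otherwise a **thinning** for every established cohort (whether volume is
#'   actually removed is decided by the yield table).
#'
#' @param state A [stand_state()].
#' @param regime A one-row regime tibble (see [clearcut_regime()]).
#' @return Tibble with columns `kind`, `cohort` (index into the state, oldest
#'   first) and `s_gap` (only set for gap cuts).
#' @examples
#' scheduled_actions(stand_state(85, 1), clearcut_regime())
#' scheduled_actions(stand_state(40, 1), gapcut_regime(0.3, 40))
#' @export
scheduled_actions <- function(state, regime) {
  check_regime(regime)
  acts <- list()
  n <- length(state$ages)
  gap_cut_due <- regime$kind == "gapcut" && n == 1 &&
    !is.na(state$ages[1]) && state$ages[1] == regime$age_gap
  for (i in seq_len(n)) {
    a <- state$ages[i]
    if (is.na(a)) {
      acts[[length(acts) + 1]] <- tibble(kind = "replant", cohort = i, s_gap = NA_real_)
    } else if (a == regime$rotation_u) {
      acts[[length(acts) + 1]] <- tibble(kind = "final_harvest", cohort = i, s_gap = NA_real_)
      acts[[length(acts) + 1]] <- tibble(kind = "replant", cohort = i, s_gap = NA_real_)
    } else if (i == 1 && gap_cut_due) {
      acts[[length(acts) + 1]] <- tibble(kind = "gap_cut", cohort = i, s_gap = regime$s_gap)
    } else if (a > 0) {
      acts[[length(acts) + 1]] <- tibble(kind = "thinning", cohort = i, s_gap = NA_real_)
    }
  }
  if (length(acts) == 0) {
    return(tibble(kind = character(), cohort = integer(), s_gap = double()))
  }
  bind_rows(acts)
}

#' Apply a management action to a stand state
#'
#' Pure state transition; volumes and cash flows are handled by the
#' simulation engine. Shares are conserved by every action. A harvest or
#' salvage leaves the cohort's area bare (`age = NA`) until the paired
#' replant resets its age to 0; equal-aged cohorts merge.
#'
#' @param state A [stand_state()].
#' @param action One action row as produced by [scheduled_actions()]; for
#'   replants after salvage set `origin = "salvage_replant"` via the
#'   `origin` argument.
#' @param origin Origin recorded for a replanted cohort.
#' @return The successor [stand_state()].
#' @examples
#' s <- stand_state(40, 1)
#' a <- scheduled_actions(s, gapcut_regime(0.3, 40))
#' apply_action(s, a[1, ]) # cohorts 40 yr (70%) + 0 yr (30%)
#' @export
apply_action <- function(state, action, origin = "planting") {
  stopifnot(nrow(action) == 1)
  i <- action$cohort
  if (i < 1 || i > length(state$ages)) abort("Action refers to a missing cohort.")
  ages <- state$ages; shares <- state$shares; origins <- state$origins
  switch(action$kind,
    thinning = state,
    gap_cut = {
      if (length(ages) != 1 || is.na(ages[1])) {
        abort("A gap cut requires a single established cohort.")
      }
      s_gap <- action$s_gap
      if (is.na(s_gap) || s_gap <= 0 || s_gap >= 1) abort("Invalid `s_gap` for gap cut.")
      stand_state(
        c(ages[1], 0), c((1 - s_gap) * shares[1], s_gap * shares[1]),
        c(origins[1], "gap_regeneration"), regime_id = state$regime_id
      )
    },
    final_harvest = ,
    salvage = {
      if (is.na(ages[i])) abort("Cohort is already bare.")
      ages[i] <- NA_real_
      structure(
        list(ages = ages, shares = shares, origins = origins,
             regime_id = state$regime_id),
        class = "stand_state"
      )
    },
    replant = {
      if (!is.na(ages[i])) abort("Replant requires a bare cohort area.")
      ages[i] <- 0
      origins[i] <- origin
      stand_state(ages, shares, origins, regime_id = state$regime_id)
    },
    abort(sprintf("Unknown action kind '%s'.", action$kind))
  )
}

#' Enumerate the zero-hazard reachable state space
#'
#' Breadth-first closure of the deterministic scheduler: starting from a
#' freshly planted stand, repeatedly applies the scheduled actions and a
#' 5-year ageing step. Under a fixed regime the reachable space is finite;
#' this enumeration must match the states visited by a long undisturbed
#' simulation (a structural test of the engine).
#'
#' @param regime One-row regime tibble.
#' @param max_states Safety cap on the closure size.
#' @return Tibble of distinct states: `lead_age`, `gap_age`, `lead_share`,
#'   `key`.
#' @export
reachable_states <- function(regime, max_states = 1000) {
  check_regime(regime)
  start <- stand_state(0, 1, regime_id = regime$id)
  seen <- character()
  out <- list()
  queue <- list(start)
  while (length(queue) > 0) {
    st <- queue[[1]]; queue <- queue[-1]
    k <- key_of_state(st)
    if (k %in% seen) next
    seen <- c(seen, k)
    out[[length(out) + 1]] <- tibble(
      lead_age = st$ages[1],
      gap_age = if (length(st$ages) == 2) st$ages[2] else NA_real_,
      lead_share = st$shares[1], key = k
    )
    if (length(seen) > max_states) abort("State space exceeded `max_states`.")
    acts <- scheduled_actions(st, regime)
    nxt <- st
    for (j in seq_len(nrow(acts))) nxt <- apply_action(nxt, acts[j, ])
    nxt$ages <- nxt$ages + 5
    nxt <- stand_state(nxt$ages, nxt$shares, nxt$origins, regime_id = regime$id)
    queue[[length(queue) + 1]] <- nxt
  }
  bind_rows(out)
}
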