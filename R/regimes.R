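#' Silvicultural regimes
#'
#' A regime is a constant management rule applied to a stand over its whole
#' simulated life. Two kinds exist:
#'
#' * **clear-cut** (`clearcut_regime()`): the stand grows even-aged, is thinned
#'   per the yield table and harvested entirely at rotation age `rotation_u`,
#'   followed by immediate replanting.
#' * **gap-cut** (`gapcut_regime()`): additionally, a single prescribed gap cut
#'   at stand age `age_gap` removes a share `s_gap` of the canopy, establishing
#'   a second, younger regeneration cohort that then grows in parallel.
#'
#' Regimes are plain tibble rows so that a set of regimes is a tibble and
#' pipes through the rest of the package.
#'
#' @param s_gap Fraction of canopy removed at the gap cut, strictly in (0, 1).
#' @param age_gap Stand age (years) of the gap cut; must be a positive
#'   multiple of the step length and below `rotation_u`.
#' @param rotation_u Rotation age in years (default 85).
#' @param id Stable label; generated from the parameters when `NULL`.
#'
#' @return A one-row tibble with columns `id`, `kind`, `s_gap`, `age_gap`,
#'   `rotation_u`.
#' @examples
#' clearcut_regime()
#' gapcut_regime(0.3, 40)
#' @export
clearcut_regime <- function(rotation_u = 85, id = "clearcut") {
  tibble(
    id = id, kind = "clearcut",
    s_gap = NA_real_, age_gap = NA_real_, rotation_u = rotation_u
  )
}

#' @rdname clearcut_regime
#' @export
gapcut_regime <- function(s_gap, age_gap, rotation_u = 85, id = NULL) {
  if (!is.numeric(s_gap) || s_gap <= 0 || s_gap >= 1) {
    abort("`s_gap` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(age_gap) || age_gap <= 0 || age_gap >= rotation_u) {
    abort("`age_gap` must lie strictly between 0 and `rotation_u`.")
  }
  if (age_gap %% 5 != 0) {
    abort("`age_gap` must be a multiple of the 5-year step length.")
  }
  if (is.null(id)) {
    id <- sprintf("gap_s%03d_a%02d", round(100 * s_gap), age_gap)
  }
  tibble(
    id = id, kind = "gapcut",
    s_gap = s_gap, age_gap = age_gap, rotation_u = rotation_u
  )
}

#' Enumerate a grid of gap-cut regimes
#'
#' Builds the Cartesian product of gap sizes and gap-cut ages in a stable
#' order (sizes vary fastest within each age). The clear-cut baseline is not
#' part of the grid; append it with [clearcut_regime()] or use
#' [regime_set()].
#'
#' @param sizes Numeric vector of gap shares, each strictly in (0, 1).
#' @param ages Numeric vector of gap-cut ages (years), each below
#'   `rotation_u`.
#' @inheritParams clearcut_regime
#' @return A tibble with one row per regime and unique `id`s.
#' @examples
#' regime_grid(c(0.1, 0.15, 0.2, 0.25, 0.3), c(20, 40, 60)) # 15 regimes
#' @export
regime_grid <- function(sizes, ages, rotation_u = 85) {
  if (anyDuplicated(sizes) || anyDuplicated(ages)) {
    abort("Duplicate entries in the regime grid are not allowed.")
  }
  if (length(sizes) == 0 || length(ages) == 0) {
    return(clearcut_regime()[0, ])
  }
  grid <- tidyr::expand_grid(age_gap = sort(ages), s_gap = sort(sizes))
  purrr::pmap(grid, function(age_gap, s_gap) {
    gapcut_regime(s_gap, age_gap, rotation_u = rotation_u)
  }) |>
    bind_rows()
}

#' @description `regime_set()` returns the clear-cut baseline followed by the
#'   gap-cut grid -- the full comparison set used throughout.
#' @rdname regime_grid
#' @export
regime_set <- function(sizes = c(0.1, 0.15, 0.2, 0.25, 0.3),
                       ages = c(20, 40, 60), rotation_u = 85) {
  bind_rows(
    clearcut_regime(rotation_u = rotation_u),
    regime_grid(sizes, ages, rotation_u = rotation_u)
  )
}

# Validate one regime row (internal).
check_regime <- function(regime) {
  stopifnot(nrow(regime) == 1)
  if (regime$kind == "clearcut") {
    if (!is.na(regime$s_gap) || !is.na(regime$age_gap)) {
      abort("A clear-cut regime must leave `s_gap` and `age_gap` unset.")
    }
  } else if (regime$kind == "gapcut") {
    if (is.na(regime$s_gap) || regime$s_gap <= 0 || regime$s_gap >= 1 ||
        is.na(regime$age_gap) || regime$age_gap <= 0 ||
        regime$age_gap >= regime$rotation_u) {
      abort("Invalid gap-cut regime parameters.")
    }
  } else {
    abort(sprintf("Unknown regime kind '%s'.", regime$kind))
  }
  invisible(regime)
}
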