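#' Age-indexed growth-and-yield table
#'
#' The growth model is a yield-table abstraction: per 5-year age class it
#' carries the standing volume before thinning (m3/ha at full stocking), the
#' mean diameter at breast height (cm), the volume removed by the scheduled
#' thinning at that age (m3/ha) and the mean DBH of the removed trees.
#' Region-specific tables are loaded from CSV
#' (columns `age,standing_volume,mean_dbh,thinning_removal,thinning_dbh`);
#' `growth_table()` generates a synthetic but structurally faithful default
#' from a Chapman-Richards volume curve
#' `V(a) = v_max * (1 - exp(-k a))^p`, a linear DBH trend, and thinning
#' removals taken as a fraction of the periodic increment that declines with
#' age. Like real planning tables, the generated table starts at age 15;
#' young ages are filled by [interpolate_young_ages()].
#'
#' @param v_max Asymptotic standing volume (m3/ha).
#' @param k,p Chapman-Richards rate and shape parameters.
#' @param dbh_max Mean DBH (cm) reached at `max_age`.
#' @param max_age Last tabulated age (years), normally the rotation age.
#' @param thin_start First thinning age (years).
#' @param thin_frac_young,thin_frac_old Fraction of the periodic increment
#'   removed by thinning at `thin_start` resp. `max_age` (linear in between).
#' @param site_index Metadata: mean stand height (m) at age 50.
#' @return A `growth_table` tibble (ages from 15 up; see
#'   [interpolate_young_ages()]).
#' @examples
#' tab <- growth_table() |> interpolate_young_ages()
#' @export
growth_table <- function(v_max = 900, k = 0.025, p = 3, dbh_max = 45,
                         max_age = 85, thin_start = 20,
                         thin_frac_young = 0.4, thin_frac_old = 0.1,
                         site_index = 21.9) {
  ages <- seq(15, max_age, by = 5)
  vol_cr <- function(a) v_max * (1 - exp(-k * a))^p
  volume <- vol_cr(ages)
  dbh <- dbh_max * pmin(ages, max_age) / max_age
  incr <- vol_cr(ages) - vol_cr(ages - 5)
  frac <- ifelse(
    ages < thin_start | ages >= max_age, 0,
    thin_frac_young + (thin_frac_old - thin_frac_young) *
      (ages - thin_start) / (max_age - thin_start)
  )
  tab <- tibble(
    age = ages,
    standing_volume = volume,
    mean_dbh = dbh,
    thinning_removal = frac * incr,
    thinning_dbh = 0.8 * dbh
  )
  new_growth_table(tab, site_index = site_index)
}

new_growth_table <- function(tab, site_index = NA_real_) {
  structure(tab, class = c("growth_table", class(tibble())),
            site_index = site_index)
}

#' Read / write a growth table as CSV
#'
#' @param path CSV file with columns
#'   `age,standing_volume,mean_dbh,thinning_removal,thinning_dbh`.
#' @param site_index Site index metadata attached on read.
#' @return `read_growth_table()` returns a `growth_table`;
#'   `write_growth_table()` returns `path` invisibly.
#' @export
read_growth_table <- function(path, site_index = NA_real_) {
  tab <- as_tibble(utils::read.csv(path))
  needed <- c("age", "standing_volume", "mean_dbh",
              "thinning_removal", "thinning_dbh")
  if (!all(needed %in% names(tab))) {
    abort("Growth-table CSV is missing required columns.")
  }
  check_growth_table(new_growth_table(tab[needed], site_index = site_index))
}

#' @rdname read_growth_table
#' @param table A `growth_table`.
#' @export
write_growth_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

check_growth_table <- function(table) {
  if (any(table$standing_volume < 0) || any(table$thinning_removal < 0)) {
    abort("Volumes in a growth table must be non-negative.")
  }
  if (is.unsorted(table$age) || anyDuplicated(table$age)) {
    abort("Growth-table ages must be strictly increasing.")
  }
  if (is.unsorted(table$mean_dbh)) {
    abort("Mean DBH must be non-decreasing in age.")
  }
  table
}

#' Fill young stand ages by linear interpolation
#'
#' Planning yield tables omit volume estimates below age 15. Young ages
#' (0, 5, 10) are filled by linear interpolation between volume 0 (and DBH 0)
#' at age 0 and the tabulated age-15 row, with no thinnings, so that carbon
#' sequestration of young stands can be computed.
#'
#' @param table A `growth_table` whose first row is age 15.
#' @return The completed `growth_table` covering ages 0 to the table's
#'   maximum in 5-year steps.
#' @export
interpolate_young_ages <- function(table) {
  if (min(table$age) == 0) return(table)
  if (!(15 %in% table$age) || min(table$age) != 15) {
    abort("Interpolation requires the age-15 anchor row.")
  }
  anchor <- table[table$age == 15, ]
  young <- tibble(
    age = c(0, 5, 10),
    standing_volume = anchor$standing_volume * c(0, 5, 10) / 15,
    mean_dbh = anchor$mean_dbh * c(0, 5, 10) / 15,
    thinning_removal = 0,
    thinning_dbh = 0
  )
  new_growth_table(bind_rows(young, as_tibble(table)),
                   site_index = attr(table, "site_index"))
}

# Fast lookup closures over a completed table (internal).
growth_lookup <- function(table) {
  if (min(table$age) != 0) abort("Growth table must cover age 0; run interpolate_young_ages().")
  ages <- table$age
  if (any(diff(ages) != 5)) abort("Growth table must be on a 5-year grid.")
  v <- table$standing_volume
  d <- table$mean_dbh
  r <- table$thinning_removal
  rd <- table$thinning_dbh
  max_age <- max(ages)
  idx <- function(a) {
    if (any(a < 0 | a > max_age)) abort("Age beyond the growth table.")
    a / 5 + 1
  }
  list(
    max_age = max_age,
    volume = function(a) v[idx(a)],
    dbh_at = function(g_age) {
      # growth age may be off-grid after modifier accumulation
      g <- pmin(pmax(g_age, 0), max_age)
      i <- pmin(floor(g / 5), max_age / 5 - 1)
      f <- (g - 5 * i) / 5
      d[i + 1] * (1 - f) + d[i + 2] * f
    },
    removal = function(a) r[idx(a)],
    removal_dbh = function(a) rd[idx(a)],
    # gross growth over the step starting at age a (after that age's thinning)
    gross_increment = function(a) {
      i <- idx(a)
      v[i + 1] - (v[i] - r[i])
    }
  )
}

#' Competition modifiers for two-cohort stands
#'
#' Growth interactions between unequal-aged cohorts are represented by two
#' multipliers on the periodic volume increment:
#'
#' * `suppression_multiplier(d_age, size)` < 1 slows a gap-regeneration
#'   cohort growing below the retained canopy; suppression strengthens with the age
#'   difference `d_age` and weakens with the cohort's area share `size`
#'   (small gaps in old stands are most suppressed). Default
#'   `clamp(1 - (c0 + c1 * (1 - size)) * d_age, m_min, 1)`.
#' * `acceleration_multiplier(size, years_since_gap)` >= 1 temporarily speeds
#'   up the leading cohort after a gap cut (canopy opening improves growing
#'   conditions near gap edges); it scales with the gap share and decays
#'   linearly to 1 over `window` years. Default
#'   `1 + 0.5 * size * max(0, 1 - years_since_gap / window)`.
#'
#' Both forms are minimal shapes satisfying the required monotonicities;
#' coefficients are configurable artifact defaults.
#'
#' @param d_age Age difference (years) to the leading cohort.
#' @param size Area share of the gap/regeneration cohort.
#' @param years_since_gap Years elapsed since the gap cut.
#' @param c0,c1,m_min Suppression coefficients and floor.
#' @param gain,window Acceleration strength and decay window (years).
#' @return Multiplier(s) on the periodic increment.
#' @examples
#' suppression_multiplier(40, 0.1)
#' acceleration_multiplier(0.3, 0)
#' @export
suppression_multiplier <- function(d_age, size, c0 = 0.004, c1 = 0.006,
                                   m_min = 0.4) {
  stopifnot(all(d_age >= 0))
  pmin(1, pmax(m_min, 1 - (c0 + c1 * (1 - size)) * d_age))
}

#' @rdname suppression_multiplier
#' @export
acceleration_multiplier <- function(size, years_since_gap, gain = 0.5,
                                    window = 15) {
  1 + gain * size * pmax(0, 1 - years_since_gap / window)
}

#' Cohort standing volume
#'
#' Share-scaled, modifier-adjusted standing volume of a cohort. The stocking
#' factor `q` accumulates the history of growth modifiers (1 when all
#' modifiers were 1), so `cohort_volume()` equals `share * table volume`
#' exactly in the unmodified case.
#'
#' @param table A completed `growth_table`.
#' @param age Cohort age (years, on the 5-year grid).
#' @param share Area share of the cohort.
#' @param q Accumulated stocking factor (default 1).
#' @return Standing volume in m3 per hectare of stand.
#' @export
cohort_volume <- function(table, age, share, q = 1) {
  lk <- growth_lookup(table)
  share * q * lk$volume(age)
}

#' Per-step gross volume increment of a stand
#'
#' Mass-balance bookkeeping against the table: over the step from age `a`
#' to `a + 5` an unmodified cohort grows by
#' `V(a+5) - (V(a) - R(a))`, i.e. the tabulated volume difference plus the
#' thinning removal of the step. Modifiers multiply this gross growth.
#' Additive over cohorts.
#'
#' @param table A completed `growth_table`.
#' @param ages,shares Cohort ages and area shares.
#' @param modifiers Per-cohort increment multipliers (default 1).
#' @param q Per-cohort accumulated stocking factors (default 1).
#' @return Per-cohort gross increments (m3/ha of stand per step).
#' @export
step_increment <- function(table, ages, shares, modifiers = 1, q = 1) {
  lk <- growth_lookup(table)
  shares * rep_len(q, length(ages)) * rep_len(modifiers, length(ages)) *
    vapply(ages, lk$gross_increment, numeric(1))
}
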