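#' Timber valuation parameters
#'
#' Net revenues are `volume * (price(dbh) - cost(dbh))`, with DBH-dependent
#' price and harvest-cost functions in EUR per m3. After a disturbance,
#' salvage logging sells at a degraded price (factor 0.74 on the price
#' function) with elevated logging costs (factor 1.15 on the cost function).
#' Fixed planting costs are 2000 EUR/ha after regular harvests, doubled
#' (4000 EUR/ha) after salvage loggings, and halved (1000 EUR/ha) for gap
#' regeneration, where natural regeneration is assumed to replace planting
#' on half the area; all planting costs scale with the replanted area share.
#'
#' The default price/cost functions are synthetic stand-ins with the right
#' shape (price increasing in DBH towards the 92.47 EUR/m3 reference-
#' assortment baseline; costs falling with DBH under mechanised harvest,
#' rising again for very large motor-manually felled trees). Site-specific
#' valuation functions are plugged in via these arguments.
#'
#' @param base_price Reference-assortment price (EUR/m3).
#' @param price_fn,cost_fn Functions of DBH (cm) returning EUR/m3.
#' @param salvage_price_factor,salvage_cost_factor Salvage degradation
#'   factors (price < 1 < cost).
#' @param planting_cost_regular,planting_cost_salvage,planting_cost_gap
#'   Planting costs (EUR/ha) by context.
#' @return An object of class `valuation_params`.
#' @export
valuation_params <- function(base_price = 92.47,
                             price_fn = NULL, cost_fn = NULL,
                             salvage_price_factor = 0.74,
                             salvage_cost_factor = 1.15,
                             planting_cost_regular = 2000,
                             planting_cost_salvage = 4000,
                             planting_cost_gap = 1000) {
  if (is.null(price_fn)) {
    price_fn <- function(dbh) base_price * (0.3 + 0.7 * pmin(dbh, 45) / 45)
  }
  if (is.null(cost_fn)) {
    cost_fn <- function(dbh) {
      45 - 0.4 * pmin(dbh, 45) + 0.012 * pmax(0, dbh - 45)^2
    }
  }
  if (salvage_price_factor >= 1 || salvage_cost_factor <= 1) {
    abort("Salvage factors must satisfy price factor < 1 < cost factor.")
  }
  if (!(planting_cost_gap < planting_cost_regular &&
        planting_cost_regular < planting_cost_salvage)) {
    abort("Planting costs must be ordered gap < regular < salvage.")
  }
  structure(
    list(
      base_price = base_price, price_fn = price_fn, cost_fn = cost_fn,
      salvage_price_factor = salvage_price_factor,
      salvage_cost_factor = salvage_cost_factor,
      planting_cost_regular = planting_cost_regular,
      planting_cost_salvage = planting_cost_salvage,
      planting_cost_gap = planting_cost_gap
    ),
    class = "valuation_params"
  )
}

#' Carbon accounting parameters
#'
#' Aboveground carbon sequestration is derived from gross volume increment:
#' volume is converted to dry mass with a mean wood density and to carbon
#' with an average carbon fraction. The derived conversion factor (default
#' 410 kg/m3 x 0.5 kgC/kg = 205 kgC/m3) is validated against its factors at
#' construction.
#'
#' @param wood_density Dry wood density (kg/m3).
#' @param carbon_fraction Carbon content of dry mass (kgC/kg).
#' @return An object of class `carbon_params` with the derived
#'   `conversion_kg_m3` (kgC per m3) and `conversion_t_m3` (tC per m3).
#' @examples
#' carbon_params()$conversion_kg_m3 # 205
#' @export
carbon_params <- function(wood_density = 410, carbon_fraction = 0.5) {
  if (wood_density <= 0 || carbon_fraction <= 0 || carbon_fraction > 1) {
    abort("Invalid carbon parameters.")
  }
  conv <- wood_density * carbon_fraction
  structure(
    list(wood_density = wood_density, carbon_fraction = carbon_fraction,
         conversion_kg_m3 = conv, conversion_t_m3 = conv / 1000),
    class = "carbon_params"
  )
}

#' Net revenue of a removal
#'
#' @param volume Removed volume (m3/ha), non-negative.
#' @param dbh Mean DBH (cm) of the removed trees.
#' @param context One of `"thinning"`, `"harvest"`, `"gap"`, `"salvage"`;
#'   salvage applies the degraded price and elevated cost factors.
#' @param params A [valuation_params()].
#' @return Net revenue in EUR/ha (may be negative for small DBH).
#' @examples
#' p <- valuation_params(cost_fn = function(dbh) rep(30, length(dbh)))
#' net_revenue(100, 45, "harvest", p)
#' net_revenue(100, 45, "salvage", p)
#' @export
net_revenue <- function(volume, dbh, context, params = valuation_params()) {
  if (any(volume < 0)) abort("`volume` must be non-negative.")
  if (!all(context %in% c("thinning", "harvest", "gap", "salvage"))) {
    abort("Unknown revenue context.")
  }
  price <- params$price_fn(dbh)
  cost <- params$cost_fn(dbh)
  salv <- context == "salvage"
  price <- ifelse(salv, price * params$salvage_price_factor, price)
  cost <- ifelse(salv, cost * params$salvage_cost_factor, cost)
  volume * (price - cost)
}

#' Planting cost of a replanted area
#'
#' @param context One of `"regular"`, `"salvage"`, `"gap"`.
#' @param share Replanted area share of the stand.
#' @param params A [valuation_params()].
#' @return Cost in EUR/ha of stand (positive number).
#' @examples
#' planting_cost("gap", share = 0.3) # 300
#' @export
planting_cost <- function(context, share = 1, params = valuation_params()) {
  base <- c(
    regular = params$planting_cost_regular,
    salvage = params$planting_cost_salvage,
    gap = params$planting_cost_gap
  )[context]
  if (anyNA(base)) abort("Unknown planting context.")
  unname(base) * share
}

#' Cash flow of one simulation step
#'
#' Sums the net revenues of all removal events of the step and subtracts all
#' planting costs, per the step cash-flow identity
#' `CF_t = sum NR_thin + sum NR_harv + sum NR_gap + sum NR_salv - sum C_plant`.
#'
#' @param events Tibble with columns `kind` (`"thinning"`, `"harvest"`,
#'   `"gap"`, `"salvage"`, `"plant_regular"`, `"plant_salvage"`,
#'   `"plant_gap"`), `volume`, `dbh`, `share`.
#' @param params A [valuation_params()].
#' @return Cash flow in EUR/ha (single number).
#' @export
cash_flow_at_step <- function(events, params = valuation_params()) {
  if (nrow(events) == 0) return(0)
  cf <- 0
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k %in% c("thinning", "harvest", "gap", "salvage")) {
      cf <- cf + net_revenue(events$volume[i], events$dbh[i], k, params)
    } else if (k %in% c("plant_regular", "plant_salvage", "plant_gap")) {
      cf <- cf - planting_cost(sub("^plant_", "", k), events$share[i], params)
    } else {
      abort(sprintf("Unknown event kind '%s'.", k))
    }
  }
  cf
}

#' Carbon sequestration of one step
#'
#' @param volume_increment Gross volume increment over the step (m3/ha),
#'   non-negative.
#' @param params A [carbon_params()].
#' @return Sequestration in tC/ha.
#' @examples
#' carbon_at_step(1) # 0.205
#' @export
carbon_at_step <- function(volume_increment, params = carbon_params()) {
  if (any(volume_increment < 0)) abort("Increment must be non-negative.")
  volume_increment * params$conversion_t_m3
}
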