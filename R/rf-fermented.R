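# RFs for fermented foods.
#
# Alcoholic fermentation converts glucose to ethanol and CO2; with ~20% of
# the glucose feeding yeast growth the practical yield is 0.42 kg ethanol
# per kg glucose, i.e. 2.38 g glucose per g ethanol.  The raw-material mass
# behind 100 g of fermented product is then the glucose that became ethanol
# plus the carbohydrate still present, expressed in units of the raw
# material's carbohydrate content c:
#
#   RF = (238 * ethanol / c + 100 * residual_carb / c) / 100
#
# Acetic fermentation oxidizes ethanol to acetic acid (theoretically
# 1.304 kg acid per kg ethanol; assumed 1:1 by mass here because
# Acetobacter consumes part of the ethanol), so the same equation applies
# with acetic acid in place of ethanol.

check_ferment_input <- function(x_g, residual_carb_g, raw_carb_g, what) {
  stopifnot(is.numeric(x_g), is.numeric(residual_carb_g), is.numeric(raw_carb_g))
  if (any(x_g < 0) || any(residual_carb_g < 0)) {
    stop(what, ": nutrient masses must be non-negative")
  }
  if (any(raw_carb_g <= 0)) {
    stop(what, ": raw material has no available carbohydrate to divide by")
  }
  invisible(TRUE)
}

#' RF for an alcohol-fermented food
#'
#' Grams of raw material (per gram of product) required to supply both the
#' glucose fermented into the product's ethanol and its residual
#' carbohydrate.
#'
#' @param ethanol_g ethanol in the product, g/100 g.
#' @param residual_carb_g available carbohydrate remaining in the product,
#'   g/100 g.
#' @param raw_carb_g available carbohydrate of the raw material, g/100 g
#'   (must be > 0).
#' @param constants a [process_constants()] list.
#' @return Dimensionless RF.
#' @examples
#' # polished rice behind 100 g of sake:
#' 100 * rf_alcohol_fermented(12.8, 2.5, 83.1)  # 39.67 g
#' @export
rf_alcohol_fermented <- function(ethanol_g, residual_carb_g, raw_carb_g,
                                 constants = process_constants()) {
  check_ferment_input(ethanol_g, residual_carb_g, raw_carb_g,
                      "rf_alcohol_fermented")
  (constants$ferment_constant * ethanol_g / raw_carb_g +
     100 * residual_carb_g / raw_carb_g) / 100
}

#' RF for an acetic-acid-fermented food
#'
#' As [rf_alcohol_fermented()] but driven by the product's acetic acid,
#' under the assumption that 1 g of acetic acid traces back to 1 g of
#' ethanol (and hence 2.38 g of raw-material glucose).  Set
#' \code{acetic_per_ethanol} to
#' \code{process_constants()$acetic_per_ethanol_theoretical} (1.304) for a
#' sensitivity analysis under full stoichiometric conversion.
#'
#' @param acetic_g acetic acid in the product, g/100 g.
#' @param residual_carb_g available carbohydrate remaining in the product,
#'   g/100 g.
#' @param raw_carb_g available carbohydrate of the raw material, g/100 g.
#' @param constants a [process_constants()] list.
#' @param acetic_per_ethanol kg acetic acid produced per kg ethanol
#'   metabolized; defaults to the assumed 1.0.
#' @return Dimensionless RF.
#' @export
rf_acetic_fermented <- function(acetic_g, residual_carb_g, raw_carb_g,
                                constants = process_constants(),
                                acetic_per_ethanol = constants$acetic_per_ethanol_assumed) {
  check_ferment_input(acetic_g, residual_carb_g, raw_carb_g,
                      "rf_acetic_fermented")
  ethanol_equiv <- acetic_g / acetic_per_ethanol
  (constants$ferment_constant * ethanol_equiv / raw_carb_g +
     100 * residual_carb_g / raw_carb_g) / 100
}

#' RF components for a lactic-acid-fermented food
#'
#' Lactic items split by recipe structure: a pickle-style item (one
#' ingredient) goes through the salted-food water balance; a beverage-style
#' item (two ingredients) is solved as a 2x2 nutrient-balance system with
#' available carbohydrate and calcium as the conserved markers.
#'
#' @param spec a [recipe_spec()] with category \code{"fermented_lactic"}.
#' @param table a [composition_table()].
#' @param constants a [process_constants()] list.
#' @param pivot_tol pivot tolerance passed to the linear solver.
#' @return Data.frame of per-ingredient RFs, as [solve_mixed_rf()] returns.
#' @export
rf_lactic_fermented <- function(spec, table, constants = process_constants(),
                                pivot_tol = 1e-10) {
  stopifnot(inherits(spec, "recipe_spec"), spec$category == "fermented_lactic")
  reason <- classify_failure(spec, table)
  if (!is.null(reason)) {
    stop("rf_lactic_fermented: ", spec$composite_id,
         " is not computable (", reason, ")")
  }
  if (length(spec$ingredients) == 1L) {
    comp <- get_food(table, spec$composite_id)
    src <- get_food(table, spec$ingredients[1L])
    rf <- rf_salted(src$water_pct, comp$water_pct, comp$salt_eq_g)
    return(data.frame(ingredient_id = spec$ingredients, rf = rf,
                      method = "fermented-lactic/salted",
                      stringsAsFactors = FALSE))
  }
  lac <- recipe_spec(spec$composite_id, "mixed", spec$ingredients,
                     markers = c("avail_carb_g", "calcium_mg"))
  out <- solve_mixed_rf(lac, table, pivot_tol = pivot_tol)
  out$method <- "fermented-lactic/gauss-jordan"
  out
}
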