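# Food categories.  Categorization is an input: the assignment of each
# composite food to a processing category (and its candidate ingredients)
# reflects expert recipe knowledge and is supplied as configuration, never
# inferred from names.
CATEGORIES <- c(
  "dried", "salted",
  "pickle_rice_bran", "pickle_vinegar", "pickle_soy", "pickle_miso",
  "fermented_alcohol", "fermented_acetic", "fermented_lactic",
  "mixed_known_ratio", "mixed",
  "uncooked", "cooked"
)

# Categories whose RF comes from a closed-form equation with one principal
# ingredient (plus media for pickles).
SIMPLE_CATEGORIES <- c(
  "dried", "salted", "pickle_rice_bran", "pickle_vinegar", "pickle_soy",
  "pickle_miso", "fermented_alcohol", "fermented_acetic"
)

FAILURE_REASONS <- c(
  "INGREDIENTS_UNKNOWN", "TOO_MANY_INGREDIENTS", "COMPLICATED_PROCESSING"
)

#' Construct a recipe specification
#'
#' A recipe spec links one composite food to its processing category and
#' candidate ingredients.  For \code{mixed} foods, \code{markers} names the
#' nutrients assumed conserved through processing that give the rows of the
#' nutrient-balance linear system; at least as many markers as ingredients
#' are required (surplus candidate markers are pruned to the
#' best-conditioned square subset at solve time).  For
#' \code{mixed_known_ratio} foods, \code{known_ratios} gives grams of each
#' ingredient per 100 g of composite directly.
#'
#' Ingredient order conventions for the closed-form categories:
#' \itemize{
#'   \item \code{dried}, \code{salted}, \code{fermented_alcohol},
#'     \code{fermented_acetic}: a single ingredient, the source commodity.
#'   \item \code{pickle_rice_bran}: (vegetable, rice-bran paste).
#'   \item \code{pickle_vinegar}: (vegetable, vinegar\[, sugar\]).
#'   \item \code{pickle_soy} / \code{pickle_miso}: (vegetable, soy
#'     sauce or miso\[, sugar\]).
#'   \item \code{fermented_lactic}: one ingredient routes the item through
#'     the salted-food water balance (lactic pickles); two ingredients
#'     route it through the mixed-food solver with carbohydrate and
#'     calcium markers (lactic beverages).
#' }
#'
#' @param composite_id id of the composite food.
#' @param category one of the documented category strings.
#' @param ingredients character vector of ingredient food ids.
#' @param markers character vector of nutrient column names (mixed foods).
#' @param known_ratios numeric vector, g per 100 g composite
#'   (\code{mixed_known_ratio} only).
#' @param complicated logical; marks processing too complicated for
#'   disaggregation (the item is reported as non-computable).
#' @return A \code{recipe_spec} list.
#' @export
recipe_spec <- function(composite_id, category, ingredients = character(),
                        markers = character(), known_ratios = NULL,
                        complicated = FALSE) {
  category <- as.character(category)
  if (!category %in% CATEGORIES) {
    stop(sprintf("recipe %s: unknown category '%s'", composite_id, category))
  }
  ingredients <- as.character(ingredients)
  markers <- as.character(markers)
  if (length(markers)) {
    bad <- setdiff(markers, NUTRIENT_FIELDS)
    if (length(bad)) {
      stop(sprintf("recipe %s: unknown marker nutrient(s): %s",
                   composite_id, paste(bad, collapse = ", ")))
    }
  }
  if (category == "mixed" && length(markers) < length(ingredients)) {
    stop(sprintf(
      "recipe %s: mixed food needs at least as many markers (%d) as ingredients (%d)",
      composite_id, length(markers), length(ingredients)))
  }
  if (!is.null(known_ratios)) {
    known_ratios <- as.numeric(known_ratios)
    if (length(known_ratios) != length(ingredients)) {
      stop(sprintf("recipe %s: known_ratios count (%d) != ingredient count (%d)",
                   composite_id, length(known_ratios), length(ingredients)))
    }
    if (any(known_ratios < 0)) {
      stop(sprintf("recipe %s: known_ratios must be non-negative", composite_id))
    }
  }
  if (category == "mixed_known_ratio" && is.null(known_ratios)) {
    stop(sprintf("recipe %s: category mixed_known_ratio requires known_ratios",
                 composite_id))
  }
  structure(
    list(composite_id = as.character(composite_id), category = category,
         ingredients = ingredients, markers = markers,
         known_ratios = known_ratios, complicated = isTRUE(complicated)),
    class = "recipe_spec"
  )
}

#' @export
print.recipe_spec <- function(x, ...) {
  cat(sprintf("Recipe %s [%s]: %s\n", x$composite_id, x$category,
              paste(x$ingredients, collapse = " + ")))
  if (length(x$markers)) cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  if (!is.null(x$known_ratios)) {
    cat("  known ratios (g/100 g):", paste(x$known_ratios, collapse = ", "), "\n")
  }
  if (x$complicated) cat("  flagged: processing too complicated\n")
  invisible(x)
}

#' Load recipe specifications from a YAML config
#'
#' The config is a YAML document with a top-level \code{foods} list; each
#' entry has keys \code{composite_id}, \code{category}, and optionally
#' \code{ingredients}, \code{markers}, \code{known_ratios},
#' \code{complicated}.  Categories are parsed strictly; an unknown category
#' string is an error, as is a mixed food with fewer markers than
#' ingredients.
#'
#' @param path YAML file path.
#' @return Named list of [recipe_spec()] objects (names = composite ids).
#' @export
load_recipes <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  doc <- yaml::read_yaml(path)
  foods <- doc$foods
  if (is.null(foods)) foods <- list()
  specs <- lapply(foods, function(f) {
    if (is.null(f$composite_id)) stop("recipe entry lacks composite_id")
    recipe_spec(
      composite_id = f$composite_id,
      category = f$category,
      ingredients = if (is.null(f$ingredients)) character() else unlist(f$ingredients),
      markers = if (is.null(f$markers)) character() else unlist(f$markers),
      known_ratios = f$known_ratios,
      complicated = isTRUE(f$complicated)
    )
  })
  names(specs) <- vapply(specs, `[[`, character(1L), "composite_id")
  if (anyDuplicated(names(specs))) {
    stop("duplicate composite_id in recipe file: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "))
  }
  specs
}

#' Write recipe specifications to a YAML config
#'
#' Inverse of [load_recipes()]; used by the corpus generator.
#'
#' @param recipes list of [recipe_spec()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recipes <- function(recipes, path) {
  foods <- lapply(unname(recipes), function(s) {
    out <- list(composite_id = s$composite_id, category = s$category)
    if (length(s$ingredients)) out$ingredients <- as.list(s$ingredients)
    if (length(s$markers)) out$markers <- as.list(s$markers)
    if (!is.null(s$known_ratios)) out$known_ratios <- as.list(s$known_ratios)
    if (s$complicated) out$complicated <- TRUE
    out
  })
  yaml::write_yaml(list(foods = foods), path)
  invisible(path)
}

# nutrient values a closed-form category needs, beyond ingredient lookups
required_composite_fields <- function(category) {
  switch(category,
    dried = "water_pct",
    salted = c("water_pct", "salt_eq_g"),
    pickle_rice_bran = c("water_pct", "salt_eq_g", "thiamine_mg"),
    pickle_vinegar = c("water_pct", "salt_eq_g", "acetic_acid_g", "sucrose_g"),
    pickle_soy = c("water_pct", "salt_eq_g", "protein_g", "sucrose_g"),
    pickle_miso = c("water_pct", "salt_eq_g", "protein_g", "sucrose_g"),
    fermented_alcohol = c("ethanol_g", "avail_carb_g"),
    fermented_acetic = c("acetic_acid_g", "avail_carb_g"),
    character()
  )
}

required_ingredient_fields <- function(category) {
  switch(category,
    dried = ,
    salted = ,
    pickle_rice_bran = "water_pct",
    pickle_vinegar = c("water_pct", "sucrose_g"),
    pickle_soy = ,
    pickle_miso = c("water_pct", "sucrose_g"),
    fermented_alcohol = ,
    fermented_acetic = "avail_carb_g",
    character()
  )
}

profile_value <- function(table, food_id, field) {
  table[[field]][match(food_id, table$food_id)]
}

#' Classify why a composite food's RF cannot be computed
#'
#' Returns one of \code{"INGREDIENTS_UNKNOWN"} (an ingredient id is absent
#' from the table, or a required nutrient value is missing),
#' \code{"TOO_MANY_INGREDIENTS"} (the ingredient count exceeds the number
#' of usable independent marker nutrients), or
#' \code{"COMPLICATED_PROCESSING"} (the recipe is flagged non-disaggregable,
#' e.g. nata de coco), or \code{NULL} when the food is computable.  When
#' several reasons apply the precedence is
#' INGREDIENTS_UNKNOWN > TOO_MANY_INGREDIENTS > COMPLICATED_PROCESSING,
#' reflecting the dominant class of real non-computable items.
#'
#' @param spec a [recipe_spec()].
#' @param table a [composition_table()].
#' @return A failure-reason string or \code{NULL}.
#' @export
classify_failure <- function(spec, table) {
  if (spec$category %in% c("uncooked", "cooked")) return(NULL)
  if (spec$category == "mixed_known_ratio") {
    if (!length(spec$ingredients)) return("INGREDIENTS_UNKNOWN")
    if (!all(spec$ingredients %in% table$food_id)) return("INGREDIENTS_UNKNOWN")
    if (spec$complicated) return("COMPLICATED_PROCESSING")
    return(NULL)
  }

  ing <- spec$ingredients
  if (!length(ing) || any(!nzchar(ing)) || !all(ing %in% table$food_id)) {
    return("INGREDIENTS_UNKNOWN")
  }
  if (!spec$composite_id %in% table$food_id) return("INGREDIENTS_UNKNOWN")

  if (spec$category %in% SIMPLE_CATEGORIES ||
      (spec$category == "fermented_lactic" && length(ing) == 1L)) {
    cat_eff <- if (spec$category == "fermented_lactic") "salted" else spec$category
    comp_need <- required_composite_fields(cat_eff)
    comp_vals <- vapply(comp_need, function(f)
      profile_value(table, spec$composite_id, f), numeric(1L))
    if (anyNA(comp_vals)) return("INGREDIENTS_UNKNOWN")
    ing_need <- required_ingredient_fields(cat_eff)
    for (f in ing_need) {
      if (is.na(profile_value(table, ing[1L], f))) return("INGREDIENTS_UNKNOWN")
    }
    # fermentation needs strictly positive raw carbohydrate to divide by
    if (cat_eff %in% c("fermented_alcohol", "fermented_acetic")) {
      raw_c <- profile_value(table, ing[1L], "avail_carb_g")
      if (raw_c <= 0) return("INGREDIENTS_UNKNOWN")
    }
    if (spec$complicated) return("COMPLICATED_PROCESSING")
    return(NULL)
  }

  # mixed (and two-ingredient lactic, which is a 2x2 mixed system)
  markers <- spec$markers
  if (spec$category == "fermented_lactic") {
    markers <- c("avail_carb_g", "calcium_mg")
  }
  k <- length(ing)
  usable <- vapply(markers, function(m) {
    vals <- c(profile_value(table, spec$composite_id, m),
              vapply(ing, function(id) profile_value(table, id, m), numeric(1L)))
    !anyNA(vals)
  }, logical(1L))
  n_usable <- sum(usable)
  if (n_usable < k) {
    # a square config with holes lacks information; a surplus config whose
    # usable markers still fall short cannot separate that many ingredients
    if (length(markers) <= k) return("INGREDIENTS_UNKNOWN")
    return("TOO_MANY_INGREDIENTS")
  }
  if (spec$complicated) return("COMPLICATED_PROCESSING")
  NULL
}
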