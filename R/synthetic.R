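# Forward simulation of food processing.
#
# The generator builds composition tables whose composite foods were
# produced from known raw-primary-commodity (RPC) profiles by exact mass
# balance: water removal, salt addition, glucose-to-ethanol fermentation,
# ethanol-to-acetic-acid oxidation, and linear blending.  Because every
# step is the algebraic inverse of an RF equation, the ground-truth RF of
# each edge is known exactly and every engine is testable by parameter
# recovery.  Fermentation consumes glucose at exactly ferment_constant/100
# grams per gram of ethanol so that the RF equation (whose coefficient is
# the integer 238) inverts the simulation without rounding residue; CO2
# and biomass mass loss is tracked explicitly so the balance closes.

# internal batch state: absolute masses (g; thiamine/calcium in mg)
state_from_item <- function(item, grams) {
  g <- grams / 100
  list(mass = grams,
       w = g * item$water_pct, pr = g * item$protein_g,
       cb = g * item$avail_carb_g, su = g * item$sucrose_g,
       ac = g * item$acetic_acid_g, et = g * item$ethanol_g,
       sa = g * item$salt_eq_g, th = g * item$thiamine_mg,
       ca = g * item$calcium_mg)
}

state_to_profile <- function(st) {
  f <- 100 / st$mass
  list(water_pct = f * st$w, protein_g = f * st$pr,
       avail_carb_g = f * st$cb, sucrose_g = f * st$su,
       acetic_acid_g = f * st$ac, ethanol_g = f * st$et,
       salt_eq_g = f * st$sa, thiamine_mg = f * st$th,
       calcium_mg = f * st$ca)
}

apply_step <- function(st, step, constants) {
  type <- step$type
  if (type == "DRY") {
    tw <- step$target_water
    cur <- 100 * st$w / st$mass
    if (tw > cur + 1e-12) {
      stop(sprintf("DRY: target water %.1f%% above source water %.1f%%", tw, cur))
    }
    solids <- st$mass - st$w
    new_mass <- solids / (1 - tw / 100)
    st$w <- new_mass - solids
    st$mass <- new_mass
  } else if (type == "SALT") {
    # salt_g grams of dry NaCl per 100 g of incoming batch, then water
    # adjusted (removed or taken up in brining) to the target content
    S <- step$salt_g * st$mass / 100
    tw <- step$target_water
    if (tw >= 100) stop("SALT: target water must be < 100%")
    st$sa <- st$sa + S
    solids <- (st$mass - st$w) + S
    new_mass <- solids / (1 - tw / 100)
    st$w <- new_mass - solids
    if (st$w < 0) stop("SALT: infeasible water target")
    st$mass <- new_mass
  } else if (type == "FERMENT_ALCOHOL") {
    fr <- step$fraction
    if (fr < 0 || fr > 1) stop("FERMENT_ALCOHOL: fraction outside [0, 1]")
    glucose <- fr * st$cb
    ethanol <- glucose * 100 / constants$ferment_constant
    st$cb <- st$cb - glucose
    st$su <- st$su * (1 - fr)
    st$et <- st$et + ethanol
    st$mass <- st$mass - (glucose - ethanol)  # CO2 + biomass leave the batch
  } else if (type == "FERMENT_ACETIC") {
    fr <- step$fraction
    if (fr < 0 || fr > 1) stop("FERMENT_ACETIC: fraction outside [0, 1]")
    oxidized <- fr * st$et
    st$et <- st$et - oxidized
    # assumed 1:1 by mass, so batch mass is unchanged
    st$ac <- st$ac + oxidized * constants$acetic_per_ethanol_assumed
  } else {
    stop("unknown processing step type: ", type)
  }
  st
}

#' Generate reproducible RPC nutrient profiles
#'
#' Pseudo-random but realistic raw-commodity profiles: roughly a third
#' grain-like (low water, carbohydrate-rich — fermentation and drying
#' sources), a third vegetable-like (high water — salting and pickling
#' sources), the rest generic.  Salt, ethanol and acetic acid are zero, as
#' for raw commodities; mass closure (water + protein + carbohydrate
#' within 100 g) always holds, so every profile passes table validation.
#' The same seed yields identical output.
#'
#' @param seed integer RNG seed.
#' @param n number of profiles (>= 1).
#' @param id_prefix prefix for generated food ids.
#' @return A [composition_table()] of \code{n} RPC items.
#' @export
generate_rpc_profiles <- function(seed, n, id_prefix = "R") {
  if (n < 1) stop("generate_rpc_profiles: n must be >= 1")
  set.seed(seed)
  kind <- rep(c("grain", "vegetable", "generic"), length.out = n)
  water <- numeric(n); carb <- numeric(n); protein <- numeric(n)
  for (i in seq_len(n)) {
    if (kind[i] == "grain") {
      water[i] <- stats::runif(1, 10, 16)
      carb[i] <- stats::runif(1, 60, min(82, 93 - water[i]))
      protein[i] <- stats::runif(1, 3, min(12, 98.5 - water[i] - carb[i]))
    } else if (kind[i] == "vegetable") {
      water[i] <- stats::runif(1, 85, 94)
      carb[i] <- stats::runif(1, 1, min(6, 97 - water[i]))
      protein[i] <- stats::runif(1, 0.3, min(2.5, 98.5 - water[i] - carb[i]))
    } else {
      water[i] <- stats::runif(1, 30, 80)
      budget <- 99 - water[i]
      protein[i] <- stats::runif(1, 0, 0.4 * budget)
      carb[i] <- stats::runif(1, 0.1 * budget, budget - protein[i])
    }
  }
  sucrose <- stats::runif(n, 0, 0.5) * carb
  composition_table(data.frame(
    food_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    name = paste0("synthetic ", kind, " RPC ", seq_len(n)),
    group = sample(1:17, n, replace = TRUE),
    water_pct = water, protein_g = protein, avail_carb_g = carb,
    sucrose_g = sucrose, acetic_acid_g = 0, ethanol_g = 0, salt_eq_g = 0,
    thiamine_mg = stats::runif(n, 0.02, 1.2),
    calcium_mg = stats::runif(n, 5, 250),
    is_rpc = TRUE, stringsAsFactors = FALSE
  ))
}

#' Forward-simulate one processing chain
#'
#' Applies an ordered list of processing steps to a source food (or a
#' blend) by exact mass balance and returns the resulting composite item,
#' the matching recipe spec, and the analytically known ground-truth RFs.
#'
#' A script is a list with \code{composite_id}, \code{name} (optional),
#' and either \code{source_id} plus \code{steps} (each step a list with
#' \code{type} in \code{DRY} (target_water), \code{SALT} (salt_g,
#' target_water), \code{FERMENT_ALCOHOL} (fraction of carbohydrate
#' fermented), \code{FERMENT_ACETIC} (fraction of ethanol oxidized)), or a
#' \code{MIX} specification (\code{mix_ids}, \code{mix_weights} in grams,
#' optional \code{water_g} of added water, and \code{markers} for the
#' recipe).  The recipe category is derived from the steps.
#'
#' @param script processing script (see Details).
#' @param table a [composition_table()] resolving the source ids.
#' @param constants a [process_constants()] list.
#' @return List with \code{item} (one-row data.frame for the composite),
#'   \code{spec} (a [recipe_spec()]) and \code{truth} (data.frame
#'   \code{ingredient_id}, \code{rf_true}).
#' @export
simulate_processing <- function(script, table, constants = process_constants()) {
  cid <- script$composite_id
  nm <- if (is.null(script$name)) paste("synthetic composite", cid) else script$name
  if (!is.null(script$mix_ids)) {
    ids <- script$mix_ids
    wts <- script$mix_weights
    stopifnot(length(ids) == length(wts), all(wts > 0))
    st <- NULL
    for (i in seq_along(ids)) {
      si <- state_from_item(get_food(table, ids[i]), wts[i])
      if (is.null(st)) st <- si
      else for (f in names(st)) st[[f]] <- st[[f]] + si[[f]]
    }
    if (!is.null(script$water_g) && script$water_g > 0) {
      st$w <- st$w + script$water_g
      st$mass <- st$mass + script$water_g
    }
    truth <- data.frame(ingredient_id = ids, rf_true = wts / st$mass,
                        stringsAsFactors = FALSE)
    category <- "mixed"
    markers <- script$markers
    spec <- recipe_spec(cid, category, ids, markers = markers)
  } else {
    src <- get_food(table, script$source_id)
    st <- state_from_item(src, 100)
    types <- vapply(script$steps, `[[`, character(1L), "type")
    for (step in script$steps) st <- apply_step(st, step, constants)
    truth <- data.frame(ingredient_id = script$source_id,
                        rf_true = 100 / st$mass, stringsAsFactors = FALSE)
    category <- if ("FERMENT_ACETIC" %in% types) "fermented_acetic"
      else if ("FERMENT_ALCOHOL" %in% types) "fermented_alcohol"
      else if ("SALT" %in% types) "salted"
      else "dried"
    spec <- recipe_spec(cid, category, script$source_id)
  }
  prof <- state_to_profile(st)
  item <- data.frame(food_id = cid, name = nm,
                     group = sample(1:17, 1L),
                     water_pct = prof$water_pct, protein_g = prof$protein_g,
                     avail_carb_g = prof$avail_carb_g,
                     sucrose_g = prof$sucrose_g,
                     acetic_acid_g = prof$acetic_acid_g,
                     ethanol_g = prof$ethanol_g, salt_eq_g = prof$salt_eq_g,
                     thiamine_mg = prof$thiamine_mg,
                     calcium_mg = prof$calcium_mg,
                     is_rpc = FALSE, stringsAsFactors = FALSE)
  list(item = item, spec = spec, truth = truth)
}

# model-consistent pickle synthesis: the product's water/salt follow the
# vegetable water balance, while each marker nutrient carries only its
# designated source's contribution (thiamine from bran, acetate from
# vinegar, protein from soy/miso, sucrose from vegetable+medium+sugar) --
# exactly the assumptions the pickle RF equations make
simulate_pickle <- function(cid, type, veg_id, medium_id, sugar_id, table,
                            b, S, M, G, constants = process_constants()) {
  veg <- get_food(table, veg_id)
  a <- veg$water_pct
  V <- 100 * (100 - S - b) / (100 - a)
  if (V <= 0) stop("simulate_pickle: infeasible water/salt target")
  prof <- list(water_pct = b, salt_eq_g = S, ethanol_g = 0, acetic_acid_g = 0,
               protein_g = (V / 100) * veg$protein_g,
               sucrose_g = (V / 100) * veg$sucrose_g,
               thiamine_mg = 0, calcium_mg = (V / 100) * veg$calcium_mg)
  ingredients <- c(veg_id, medium_id)
  truth_rf <- c(V / 100, M / 100)
  if (type == "pickle_rice_bran") {
    prof$thiamine_mg <- M * constants$thiamine_rice_bran / 100
  } else if (type == "pickle_vinegar") {
    prof$acetic_acid_g <- M * constants$acetate_vinegar / 100
    prof$sucrose_g <- prof$sucrose_g + G * constants$sucrose_sugar / 100
  } else if (type == "pickle_soy") {
    prof$protein_g <- M * constants$protein_soy_sauce / 100
    prof$sucrose_g <- prof$sucrose_g + M * constants$sucrose_soy_sauce / 100 +
      G * constants$sucrose_sugar / 100
  } else if (type == "pickle_miso") {
    prof$protein_g <- M * constants$protein_miso / 100
    prof$sucrose_g <- prof$sucrose_g + G * constants$sucrose_sugar / 100
  } else stop("unknown pickle type: ", type)
  if (type != "pickle_rice_bran" && !is.null(sugar_id)) {
    ingredients <- c(ingredients, sugar_id)
    truth_rf <- c(truth_rf, G / 100)
  }
  prof$avail_carb_g <- prof$sucrose_g +
    (V / 100) * max(veg$avail_carb_g - veg$sucrose_g, 0)
  item <- data.frame(food_id = cid, name = paste("synthetic", type, cid),
                     group = 6L, water_pct = prof$water_pct,
                     protein_g = prof$protein_g,
                     avail_carb_g = prof$avail_carb_g,
                     sucrose_g = prof$sucrose_g,
                     acetic_acid_g = prof$acetic_acid_g,
                     ethanol_g = prof$ethanol_g, salt_eq_g = prof$salt_eq_g,
                     thiamine_mg = prof$thiamine_mg,
                     calcium_mg = prof$calcium_mg,
                     is_rpc = FALSE, stringsAsFactors = FALSE)
  list(item = item,
       spec = recipe_spec(cid, type, ingredients),
       truth = data.frame(ingredient_id = ingredients, rf_true = truth_rf,
                          stringsAsFactors = FALSE))
}

# standard processing-medium items (canonical composition-table profiles)
media_items <- function(constants = process_constants()) {
  composition_table(data.frame(
    food_id = c("M_BRAN", "M_VINEGAR", "M_SOY", "M_MISO", "M_SUGAR"),
    name = c("rice-bran paste", "grain vinegar", "soy sauce", "miso",
             "table sugar"),
    group = c(17L, 17L, 17L, 17L, 3L),
    water_pct = c(55, 93, 67, 45, 0.7),
    protein_g = c(10, 0.1, constants$protein_soy_sauce,
                  constants$protein_miso, 0),
    avail_carb_g = c(25, 2.4, 7.9, 21.9, constants$sucrose_sugar),
    sucrose_g = c(1, 0.2, constants$sucrose_soy_sauce,
                  constants$sucrose_miso, constants$sucrose_sugar),
    acetic_acid_g = c(0, constants$acetate_vinegar, 0, 0, 0),
    ethanol_g = 0,
    salt_eq_g = c(12, 0, 14.5, 12.4, 0),
    thiamine_mg = c(constants$thiamine_rice_bran, 0.01, 0.05, 0.03, 0),
    calcium_mg = c(30, 2, 29, 100, 1),
    is_rpc = FALSE, stringsAsFactors = FALSE
  ))
}

# choose a nonsingular marker subset for a blend (deterministic order)
pick_markers <- function(table, ids, k,
                         candidates = c("protein_g", "avail_carb_g",
                                        "sucrose_g", "calcium_mg",
                                        "thiamine_mg", "salt_eq_g")) {
  combos <- utils::combn(candidates, k, simplify = FALSE)
  for (mk in combos) {
    R <- sapply(ids, function(id)
      vapply(mk, function(m) profile_value(table, id, m), numeric(1L)))
    R <- matrix(R, nrow = k)
    if (anyNA(R)) next
    if (kappa(R, exact = TRUE) < 1e6) return(mk)
  }
  stop("pick_markers: no well-conditioned marker subset found")
}

#' Generate a full synthetic test corpus
#'
#' Builds a composition table, recipe set and ground-truth RF table
#' spanning every processing category, multi-tier chains up to the
#' requested depth, and deliberately non-computable foods (missing
#' ingredients or marker values, too many ingredients, singular systems,
#' complicated processing).  All randomness is governed by \code{seed};
#' the same seed reproduces the corpus exactly.
#'
#' @param seed integer RNG seed.
#' @param n_foods number of composite foods (>= 20).
#' @param category_mix named numeric vector of proportions over
#'   \code{dried}, \code{salted}, \code{pickle_rice_bran},
#'   \code{pickle_vinegar}, \code{pickle_soy}, \code{pickle_miso},
#'   \code{fermented_alcohol}, \code{fermented_acetic},
#'   \code{fermented_lactic}, \code{mixed}, \code{mixed_known_ratio},
#'   \code{failing}; must sum to 1.
#' @param max_tier deepest mixed-food chain to construct (default 6).
#' @param constants a [process_constants()] list.
#' @return List with \code{table} (a [composition_table()]),
#'   \code{recipes} (named list of [recipe_spec()]) and \code{truth}
#'   (data.frame \code{composite_id}, \code{ingredient_id},
#'   \code{rf_true}, \code{expect} -- \code{"ok"} or the expected failure
#'   status).
#' @export
generate_corpus <- function(seed, n_foods = 220,
                            category_mix = c(
                              dried = 0.14, salted = 0.11,
                              pickle_rice_bran = 0.05, pickle_vinegar = 0.05,
                              pickle_soy = 0.04, pickle_miso = 0.04,
                              fermented_alcohol = 0.09,
                              fermented_acetic = 0.05,
                              fermented_lactic = 0.04,
                              mixed = 0.25, mixed_known_ratio = 0.07,
                              failing = 0.07),
                            max_tier = 6L,
                            constants = process_constants()) {
  if (n_foods < 20) stop("generate_corpus: n_foods must be >= 20")
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("generate_corpus: category_mix proportions must sum to 1")
  }
  n_rpc <- max(30L, ceiling(n_foods * 0.3))
  rpcs <- generate_rpc_profiles(seed, n_rpc)
  table <- rbind(as.data.frame(rpcs), as.data.frame(media_items(constants)))
  grain_ids <- rpcs$food_id[rpcs$water_pct < 20 & rpcs$avail_carb_g > 50]
  veg_ids <- rpcs$food_id[rpcs$water_pct > 85]
  all_ids <- rpcs$food_id

  counts <- round(category_mix * n_foods)
  counts[["mixed"]] <- n_foods - sum(counts[names(counts) != "mixed"])

  recipes <- list()
  truth <- list()
  extra_items <- list()
  idx <- 0L
  next_id <- function(tag) {
    idx <<- idx + 1L
    sprintf("C%s%04d", tag, idx)
  }
  add <- function(res, expect = "ok") {
    extra_items[[length(extra_items) + 1L]] <<- res$item
    recipes[[res$spec$composite_id]] <<- res$spec
    tr <- res$truth
    tr$composite_id <- res$spec$composite_id
    tr$expect <- expect
    truth[[length(truth) + 1L]] <<- tr[c("composite_id", "ingredient_id",
                                         "rf_true", "expect")]
  }
  lookup <- function() {
    composition_table(do.call(rbind, c(list(table), extra_items)))
  }

  # --- dried ---
  for (i in seq_len(counts[["dried"]])) {
    src <- get_food(rpcs, sample(all_ids[rpcs$water_pct > 25], 1L))
    b <- stats::runif(1, 0.03, 0.7) * src$water_pct
    add(simulate_processing(list(
      composite_id = next_id("D"), source_id = src$food_id,
      steps = list(list(type = "DRY", target_water = b))), rpcs, constants))
  }
  # --- salted ---
  for (i in seq_len(counts[["salted"]])) {
    src <- get_food(rpcs, sample(all_ids[rpcs$water_pct > 40], 1L))
    S <- stats::runif(1, 2, 14)
    tw <- stats::runif(1, 0.55, 0.97) * src$water_pct
    add(simulate_processing(list(
      composite_id = next_id("S"), source_id = src$food_id,
      steps = list(list(type = "SALT", salt_g = S, target_water = tw))),
      rpcs, constants))
  }
  # --- pickles ---
  for (type in c("pickle_rice_bran", "pickle_vinegar", "pickle_soy",
                 "pickle_miso")) {
    med_id <- switch(type, pickle_rice_bran = "M_BRAN",
                     pickle_vinegar = "M_VINEGAR", pickle_soy = "M_SOY",
                     pickle_miso = "M_MISO")
    for (i in seq_len(counts[[type]])) {
      veg_id <- sample(veg_ids, 1L)
      a <- profile_value(rpcs, veg_id, "water_pct")
      S <- stats::runif(1, 1.5, 6)
      b <- stats::runif(1, 0.75, 0.95) * a
      M <- stats::runif(1, 3, 20)
      G <- if (type == "pickle_rice_bran") 0 else stats::runif(1, 0.5, 4)
      add(simulate_pickle(next_id("P"), type, veg_id, med_id,
                          if (G > 0) "M_SUGAR" else NULL,
                          lookup(), b, S, M, G, constants))
    }
  }
  # --- alcohol-fermented ---
  alc_ids <- character(0L)
  for (i in seq_len(counts[["fermented_alcohol"]])) {
    src_id <- sample(grain_ids, 1L)
    cid <- next_id("F")
    add(simulate_processing(list(
      composite_id = cid, source_id = src_id,
      steps = list(list(type = "FERMENT_ALCOHOL",
                        fraction = stats::runif(1, 0.3, 0.9)))),
      rpcs, constants))
    alc_ids <- c(alc_ids, cid)
  }
  # --- acetic-fermented (full oxidation of the ethanol) ---
  for (i in seq_len(counts[["fermented_acetic"]])) {
    src_id <- sample(grain_ids, 1L)
    add(simulate_processing(list(
      composite_id = next_id("A"), source_id = src_id,
      steps = list(
        list(type = "FERMENT_ALCOHOL", fraction = stats::runif(1, 0.4, 0.9)),
        list(type = "FERMENT_ACETIC", fraction = 1.0))),
      rpcs, constants))
  }
  # --- lactic: half pickles (salted route), half 2-ingredient beverages ---
  n_lac <- counts[["fermented_lactic"]]
  for (i in seq_len(n_lac)) {
    if (i %% 2 == 1L) {
      src <- get_food(rpcs, sample(veg_ids, 1L))
      S <- stats::runif(1, 2, 8)
      tw <- stats::runif(1, 0.8, 0.95) * src$water_pct
      res <- simulate_processing(list(
        composite_id = next_id("L"), source_id = src$food_id,
        steps = list(list(type = "SALT", salt_g = S, target_water = tw))),
        rpcs, constants)
      res$spec <- recipe_spec(res$spec$composite_id, "fermented_lactic",
                              res$spec$ingredients)
      add(res)
    } else {
      ids <- sample(all_ids, 2L)
      wts <- stats::runif(2, 10, 45)
      res <- simulate_processing(list(
        composite_id = next_id("L"), mix_ids = ids, mix_weights = wts,
        water_g = stats::runif(1, 20, 60),
        markers = c("avail_carb_g", "calcium_mg")), rpcs, constants)
      res$spec <- recipe_spec(res$spec$composite_id, "fermented_lactic", ids)
      add(res)
    }
  }
  # --- mixed with known content ratios ---
  for (i in seq_len(counts[["mixed_known_ratio"]])) {
    k <- sample(2:4, 1L)
    ids <- sample(all_ids, k)
    wts <- stats::runif(k, 5, 80 / k)
    res <- simulate_processing(list(
      composite_id = next_id("K"), mix_ids = ids, mix_weights = wts,
      water_g = stats::runif(1, 0, 30),
      markers = pick_markers(rpcs, ids, k)), rpcs, constants)
    mass <- wts[1L] / res$truth$rf_true[1L]  # total batch mass incl. water
    res$spec <- recipe_spec(res$spec$composite_id, "mixed_known_ratio", ids,
                            known_ratios = 100 * wts / mass)
    add(res)
  }
  # --- mixed (solver), tier 1 ---
  n_mixed <- counts[["mixed"]]
  n_chain <- min(max_tier, n_mixed)  # one chain food per tier 2..max_tier
  mix_pool <- c(all_ids, alc_ids)    # fermented composites give tier-2 mixes
  for (i in seq_len(n_mixed - n_chain)) {
    k <- sample(2:4, 1L)
    ids <- sample(mix_pool, k)
    wts <- stats::runif(k, 5, 85 / k)
    tab_now <- lookup()
    add(simulate_processing(list(
      composite_id = next_id("X"), mix_ids = ids, mix_weights = wts,
      water_g = stats::runif(1, 0, 25),
      markers = pick_markers(tab_now, ids, k)), tab_now, constants))
  }
  # --- a deep chain: each tier blends the previous composite with an RPC ---
  prev <- sample(all_ids, 1L)
  for (d in seq_len(n_chain)) {
    ids <- c(prev, sample(setdiff(all_ids, prev), 1L))
    wts <- stats::runif(2, 15, 45)
    tab_now <- lookup()
    cid <- next_id("X")
    add(simulate_processing(list(
      composite_id = cid, mix_ids = ids, mix_weights = wts,
      water_g = stats::runif(1, 0, 20),
      markers = pick_markers(tab_now, ids, 2L)), tab_now, constants))
    prev <- cid
  }
  # --- deliberately non-computable foods ---
  n_fail <- counts[["failing"]]
  fail_kinds <- rep(c("unknown_ingredient", "missing_marker",
                      "too_many", "singular", "complicated"),
                    length.out = n_fail)
  for (kind in fail_kinds) {
    cid <- next_id("Z")
    base <- get_food(rpcs, sample(all_ids, 1L))
    item <- base
    item$food_id <- cid
    item$name <- paste("synthetic failing food", cid)
    item$is_rpc <- FALSE
    if (kind == "unknown_ingredient") {
      spec <- recipe_spec(cid, "dried", "NO_SUCH_FOOD")
      expect <- "failed(INGREDIENTS_UNKNOWN)"
    } else if (kind == "missing_marker") {
      item$thiamine_mg <- NA_real_
      spec <- recipe_spec(cid, "pickle_rice_bran",
                          c(sample(veg_ids, 1L), "M_BRAN"))
      expect <- "failed(INGREDIENTS_UNKNOWN)"
    } else if (kind == "too_many") {
      # 3 ingredients, 4 candidate markers of which only 2 usable
      item$thiamine_mg <- NA_real_
      item$calcium_mg <- NA_real_
      spec <- recipe_spec(cid, "mixed", sample(all_ids, 3L),
                          markers = c("protein_g", "avail_carb_g",
                                      "thiamine_mg", "calcium_mg"))
      expect <- "failed(TOO_MANY_INGREDIENTS)"
    } else if (kind == "singular") {
      # two ingredients with proportional marker columns
      dup <- get_food(rpcs, sample(all_ids, 1L))
      dup2 <- dup
      dup2$food_id <- paste0(dup$food_id, "_B")
      dup2$name <- paste(dup$name, "(proportional profile)")
      for (f in setdiff(NUTRIENT_FIELDS, "water_pct")) {
        dup2[[f]] <- 0.5 * dup[[f]]  # proportional marker columns -> singular
      }
      extra_items[[length(extra_items) + 1L]] <- dup2
      spec <- recipe_spec(cid, "mixed", c(dup$food_id, dup2$food_id),
                          markers = c("protein_g", "avail_carb_g"))
      expect <- "failed(TOO_MANY_INGREDIENTS)"
    } else {
      spec <- recipe_spec(cid, "mixed", sample(all_ids, 2L),
                          markers = c("protein_g", "avail_carb_g"),
                          complicated = TRUE)
      expect <- "failed(COMPLICATED_PROCESSING)"
    }
    extra_items[[length(extra_items) + 1L]] <- item
    recipes[[cid]] <- spec
    truth[[length(truth) + 1L]] <- data.frame(
      composite_id = cid, ingredient_id = spec$ingredients,
      rf_true = NA_real_, expect = expect, stringsAsFactors = FALSE)
  }

  full_table <- composition_table(do.call(rbind, c(list(table), extra_items)))
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  list(table = full_table, recipes = recipes, truth = truth_df)
}

#' Write a generated corpus to disk
#'
#' Emits the same delimited-text table and YAML recipe formats consumed by
#' [read_composition_table()] and [load_recipes()], plus a tab-delimited
#' ground-truth file.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(table = file.path(dir, "composition_table.tsv"),
             recipes = file.path(dir, "recipes.yaml"),
             truth = file.path(dir, "truth.tsv"))
  write_composition_table(corpus$table, paths[["table"]])
  write_recipes(corpus$recipes, paths[["recipes"]])
  tr <- corpus$truth
  tr$rf_true <- ifelse(is.na(tr$rf_true), "",
                       formatC(tr$rf_true, digits = 17, format = "g"))
  utils::write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
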