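# Chaining per-step RFs across processing tiers.
#
# Every computed RF is an edge (composite -> ingredient).  A composite
# food's full disaggregation walks these edges depth-first, multiplying
# RFs, until raw primary commodities (or failed/truncated branches) are
# reached; the cumulative RF at an RPC leaf is the grams of that RPC
# behind one gram of the root food.

#' Construct an RF database
#'
#' A data.frame of RF edges with columns \code{composite_id},
#' \code{ingredient_id}, \code{rf} (grams ingredient per gram composite,
#' \code{NA} for failed edges), \code{tier} (the composite's
#' disaggregation depth, >= 1), \code{category}, \code{method} (derivation
#' tag) and \code{status} (\code{ok}, \code{infeasible}, or
#' \code{failed(REASON)}).
#'
#' @param entries data.frame with the columns above (\code{category} is
#'   optional and filled with \code{NA} when absent).
#' @return An \code{rf_database} data.frame.
#' @export
rf_database <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("composite_id", "ingredient_id", "rf", "tier", "method", "status")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    stop("rf entries lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"category" %in% names(entries)) {
    entries$category <- rep(NA_character_, nrow(entries))
  }
  entries <- entries[c("composite_id", "ingredient_id", "rf", "tier",
                       "category", "method", "status")]
  ok <- entries$status == "ok"
  if (any(ok & (is.na(entries$rf) | entries$rf < 0))) {
    stop("rf must be present and >= 0 on every ok entry")
  }
  if (any(!is.na(entries$tier) & entries$tier < 1L)) {
    stop("tier must be >= 1")
  }
  entries <- entries[order(entries$composite_id, entries$ingredient_id), ]
  rownames(entries) <- NULL
  class(entries) <- c("rf_database", "data.frame")
  entries
}

#' @export
print.rf_database <- function(x, ...) {
  n_ok <- sum(x$status == "ok")
  cat(sprintf("RF database: %d edges over %d composite foods (%d ok, %d not computable)\n",
              nrow(x), length(unique(x$composite_id)), n_ok, nrow(x) - n_ok))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... and %d more edges\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.rf_database <- function(object, ...) {
  tier_statistics(object)
}

# depth of each composite in the recipe graph: 1 for a food whose
# ingredients carry no recipe, else 1 + max over composite ingredients
recipe_tiers <- function(recipes) {
  has_recipe <- names(recipes)
  memo <- new.env(parent = emptyenv())
  depth <- function(id) {
    if (!id %in% has_recipe) return(0L)
    if (!is.null(memo[[id]])) return(memo[[id]])
    spec <- recipes[[id]]
    if (spec$category %in% c("uncooked", "cooked") || !length(spec$ingredients)) {
      memo[[id]] <- 0L
      return(0L)
    }
    d <- 1L + max(vapply(spec$ingredients, depth, integer(1L)), 0L)
    memo[[id]] <- d
    d
  }
  stats::setNames(vapply(has_recipe, depth, integer(1L)), has_recipe)
}

# detect cycles in the ingredient graph; error names the cycle
check_acyclic <- function(recipes) {
  color <- new.env(parent = emptyenv())
  path <- character(0L)
  visit <- function(id) {
    st <- color[[id]]
    if (identical(st, "done")) return(invisible())
    if (identical(st, "active")) {
      cyc <- c(path[which(path == id)[1L]:length(path)], id)
      stop("cyclic ingredient references: ", paste(cyc, collapse = " -> "))
    }
    color[[id]] <- "active"
    path <<- c(path, id)
    spec <- recipes[[id]]
    if (!is.null(spec)) {
      for (child in spec$ingredients) visit(child)
    }
    path <<- path[-length(path)]
    color[[id]] <- "done"
    invisible()
  }
  for (id in names(recipes)) visit(id)
  invisible(TRUE)
}

failed_entries <- function(spec, reason, tier) {
  ing <- spec$ingredients
  if (!length(ing)) ing <- NA_character_
  data.frame(
    composite_id = spec$composite_id, ingredient_id = ing,
    rf = NA_real_, tier = tier, category = spec$category,
    method = "none", status = paste0("failed(", reason, ")"),
    stringsAsFactors = FALSE
  )
}

compute_one <- function(spec, table, constants, pivot_tol) {
  comp <- get_food(table, spec$composite_id)
  ing <- spec$ingredients
  row <- function(ids, rfs, method, status = "ok") {
    data.frame(composite_id = spec$composite_id, ingredient_id = ids,
               rf = rfs, tier = NA_integer_, category = spec$category,
               method = method, status = status, stringsAsFactors = FALSE)
  }
  switch(spec$category,
    dried = {
      src <- get_food(table, ing[1L])
      row(ing[1L], rf_dried(src$water_pct, comp$water_pct), "dried")
    },
    salted = {
      src <- get_food(table, ing[1L])
      row(ing[1L], rf_salted(src$water_pct, comp$water_pct, comp$salt_eq_g),
          "salted")
    },
    pickle_rice_bran = {
      veg <- get_food(table, ing[1L])
      p <- rf_pickle_rice_bran(veg$water_pct, comp$water_pct, comp$salt_eq_g,
                               comp$thiamine_mg, constants)
      row(ing[1:2], c(p$rf_vegetable, p$rf_medium), "pickle-rice-bran")
    },
    pickle_vinegar = {
      veg <- get_food(table, ing[1L])
      p <- rf_pickle_vinegar(veg$water_pct, comp$water_pct, comp$salt_eq_g,
                             comp$acetic_acid_g, comp$sucrose_g,
                             veg$sucrose_g, constants)
      ids <- ing[seq_len(min(3L, length(ing)))]
      rfs <- c(p$rf_vegetable, p$rf_medium, p$rf_sugar)[seq_along(ids)]
      row(ids, rfs, "pickle-vinegar")
    },
    pickle_soy = ,
    pickle_miso = {
      veg <- get_food(table, ing[1L])
      med <- if (spec$category == "pickle_soy") "soy" else "miso"
      p <- rf_pickle_soy_miso(veg$water_pct, comp$water_pct, comp$salt_eq_g,
                              comp$protein_g, comp$sucrose_g, veg$sucrose_g,
                              medium = med, constants = constants)
      ids <- ing[seq_len(min(3L, length(ing)))]
      rfs <- c(p$rf_vegetable, p$rf_medium, p$rf_sugar)[seq_along(ids)]
      row(ids, rfs, paste0("pickle-", med))
    },
    fermented_alcohol = {
      src <- get_food(table, ing[1L])
      row(ing[1L],
          rf_alcohol_fermented(comp$ethanol_g, comp$avail_carb_g,
                               src$avail_carb_g, constants),
          "fermented-alcohol")
    },
    fermented_acetic = {
      src <- get_food(table, ing[1L])
      row(ing[1L],
          rf_acetic_fermented(comp$acetic_acid_g, comp$avail_carb_g,
                              src$avail_carb_g, constants),
          "fermented-acetic")
    },
    fermented_lactic = {
      res <- rf_lactic_fermented(spec, table, constants, pivot_tol)
      st <- if ("status" %in% names(res)) res$status else "ok"
      row(res$ingredient_id, res$rf, res$method, st)
    },
    mixed = ,
    mixed_known_ratio = {
      res <- solve_mixed_rf(spec, table, pivot_tol = pivot_tol)
      row(res$ingredient_id, res$rf, res$method, res$status)
    },
    stop("no RF dispatch for category ", spec$category)
  )
}

#' Compute all RF edges for a recipe set
#'
#' Dispatches every recipe to its category's RF engine and returns one
#' entry per (composite, ingredient) edge, in deterministic order (by
#' composite id then ingredient id).  Non-computable foods yield
#' \code{failed(REASON)} entries; infeasible water balances or negative
#' mixed-food solutions yield \code{infeasible} entries; a singular mixed
#' system is reported as \code{failed(TOO_MANY_INGREDIENTS)}.  Each edge
#' carries the composite's tier: the number of disaggregation steps from
#' the composite down to recipe-free foods (tier 1 = all ingredients are
#' RPCs or RPC derivatives without recipes).
#'
#' @param table a [composition_table()].
#' @param recipes named list of [recipe_spec()], as from [load_recipes()].
#' @param constants a [process_constants()] list.
#' @param pivot_tol pivot tolerance for the mixed-food solver.
#' @return An [rf_database()].
#' @export
compute_all_rfs <- function(table, recipes, constants = process_constants(),
                            pivot_tol = 1e-10) {
  stopifnot(inherits(table, "composition_table"))
  names(recipes) <- vapply(recipes, `[[`, character(1L), "composite_id")
  check_acyclic(recipes)
  tiers <- recipe_tiers(recipes)
  chunks <- list()
  for (spec in recipes) {
    if (spec$category %in% c("uncooked", "cooked")) next
    tier <- max(tiers[[spec$composite_id]], 1L)
    reason <- classify_failure(spec, table)
    if (!is.null(reason)) {
      chunks[[length(chunks) + 1L]] <- failed_entries(spec, reason, tier)
      next
    }
    ent <- tryCatch(
      compute_one(spec, table, constants, pivot_tol),
      ryf_singular_system = function(e) {
        failed_entries(spec, "TOO_MANY_INGREDIENTS", tier)
      },
      error = function(e) {
        data.frame(composite_id = spec$composite_id,
                   ingredient_id = spec$ingredients,
                   rf = NA_real_, tier = tier, category = spec$category,
                   method = "none", status = "infeasible",
                   stringsAsFactors = FALSE)
      }
    )
    ent$tier <- tier
    chunks[[length(chunks) + 1L]] <- ent
  }
  if (!length(chunks)) {
    return(rf_database(data.frame(
      composite_id = character(), ingredient_id = character(),
      rf = numeric(), tier = integer(), category = character(),
      method = character(), status = character(), stringsAsFactors = FALSE)))
  }
  rf_database(do.call(rbind, chunks))
}

#' Disaggregate a food into its RPC tree
#'
#' Depth-first expansion over the RF edges: each child's cumulative RF is
#' its parent's cumulative RF times the edge RF.  Expansion stops at foods
#' with no outgoing ok edges (RPC or RPC-derivative leaves), at failed or
#' infeasible edges (the branch is marked \code{failed} and truncated;
#' the rest of the tree remains usable), and at \code{max_depth} (deeper
#' composites are marked \code{truncated}).
#'
#' @param food_id root food id.
#' @param entries an [rf_database()].
#' @param max_depth maximum number of tiers to expand (default 6).
#' @param table optional [composition_table()] used to validate the id and
#'   flag RPC leaves via \code{is_rpc}.
#' @return A \code{disaggregation_node}: list with \code{food_id},
#'   \code{cumulative_rf}, \code{depth}, \code{status} (\code{ok},
#'   \code{failed} or \code{truncated}), \code{is_rpc_leaf} and
#'   \code{children}.
#' @export
disaggregate <- function(food_id, entries, max_depth = 6L, table = NULL) {
  stopifnot(max_depth >= 1L)
  known <- unique(c(entries$composite_id, entries$ingredient_id))
  if (!is.null(table)) {
    if (!food_id %in% table$food_id) stop("unknown food_id: ", food_id)
  } else if (nrow(entries) && !food_id %in% known) {
    stop("unknown food_id: ", food_id)
  }
  is_rpc <- function(id) {
    if (!is.null(table) && id %in% table$food_id) {
      return(isTRUE(table$is_rpc[match(id, table$food_id)]))
    }
    !id %in% entries$composite_id
  }
  expand <- function(id, cum, depth) {
    edges <- entries[entries$composite_id == id, , drop = FALSE]
    node <- list(food_id = id, cumulative_rf = cum, depth = depth,
                 status = "ok", is_rpc_leaf = FALSE, children = list())
    if (!nrow(edges)) {
      node$is_rpc_leaf <- is_rpc(id) || !id %in% entries$composite_id
      return(node)
    }
    if (any(edges$status != "ok")) {
      node$status <- "failed"
      return(node)
    }
    if (depth >= max_depth) {
      node$status <- "truncated"
      return(node)
    }
    node$children <- lapply(seq_len(nrow(edges)), function(i) {
      expand(edges$ingredient_id[i], cum * edges$rf[i], depth + 1L)
    })
    node
  }
  structure(expand(food_id, 1.0, 0L), class = "disaggregation_node")
}

#' @export
print.disaggregation_node <- function(x, ...) {
  walk <- function(node, indent) {
    tag <- if (node$status != "ok") paste0(" [", node$status, "]")
           else if (node$is_rpc_leaf) " (RPC)" else ""
    cat(sprintf("%s%s  cumulative RF = %.6g%s\n",
                strrep("  ", indent), node$food_id, node$cumulative_rf, tag))
    for (ch in node$children) walk(ch, indent + 1L)
  }
  walk(unclass(x), 0L)
  invisible(x)
}

# plain nested list (for structured-text export)
node_as_list <- function(node) {
  out <- list(food_id = node$food_id,
              cumulative_rf = node$cumulative_rf,
              depth = node$depth, status = node$status,
              is_rpc_leaf = node$is_rpc_leaf)
  if (length(node$children)) out$children <- lapply(node$children, node_as_list)
  out
}

#' Export a disaggregation tree as structured text
#'
#' Writes the nested tree as a YAML document.
#'
#' @param node a \code{disaggregation_node}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_disaggregation_tree <- function(node, path) {
  yaml::write_yaml(node_as_list(node), path)
  invisible(path)
}

#' Flatten a disaggregation tree into an RPC summary
#'
#' Leaf contributions are summed per leaf food (the same RPC reached along
#' several paths is aggregated): \code{cumulative_rf * 100} is the grams
#' of that RPC behind 100 g of the root food.  \code{complete} is
#' \code{"yes"} only when no branch failed or was truncated.
#'
#' @param node a \code{disaggregation_node} from [disaggregate()].
#' @return Data.frame with columns \code{food_id} (root), \code{rpc_id},
#'   \code{cumulative_rf}, \code{complete}; attribute
#'   \code{"n_incomplete_branches"} counts failed/truncated branches.
#' @export
rpc_summary <- function(node) {
  leaves <- list()
  bad <- 0L
  walk <- function(nd) {
    if (nd$status != "ok") {
      bad <<- bad + 1L
      return(invisible())
    }
    if (!length(nd$children)) {
      leaves[[length(leaves) + 1L]] <<- list(id = nd$food_id,
                                             rf = nd$cumulative_rf)
      return(invisible())
    }
    for (ch in nd$children) walk(ch)
  }
  walk(node)
  complete <- if (bad == 0L) "yes" else "no"
  if (!length(leaves)) {
    out <- data.frame(food_id = character(), rpc_id = character(),
                      cumulative_rf = numeric(), complete = character(),
                      stringsAsFactors = FALSE)
  } else {
    ids <- vapply(leaves, `[[`, character(1L), "id")
    rfs <- vapply(leaves, `[[`, numeric(1L), "rf")
    agg <- tapply(rfs, ids, sum)
    out <- data.frame(food_id = node$food_id, rpc_id = names(agg),
                      cumulative_rf = as.numeric(agg), complete = complete,
                      stringsAsFactors = FALSE)
    out <- out[order(out$rpc_id), ]
    rownames(out) <- NULL
  }
  attr(out, "n_incomplete_branches") <- bad
  out
}

#' Tier statistics for an RF database
#'
#' Counts composite foods by category, tier and status, with percentages
#' within each category (summing to 100 within rounding).  A composite's
#' status is \code{ok} when every edge is ok, otherwise the first
#' non-ok edge status.
#'
#' @param entries an [rf_database()].
#' @return A \code{tier_stats} data.frame with columns \code{category},
#'   \code{tier}, \code{status}, \code{n}, \code{pct}.
#' @export
tier_statistics <- function(entries) {
  if (!nrow(entries)) {
    out <- data.frame(category = character(), tier = integer(),
                      status = character(), n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("tier_stats", "data.frame")
    return(out)
  }
  per_comp <- do.call(rbind, lapply(split(as.data.frame(entries),
                                          entries$composite_id), function(d) {
    st <- if (all(d$status == "ok")) "ok" else d$status[d$status != "ok"][1L]
    data.frame(composite_id = d$composite_id[1L], category = d$category[1L],
               tier = d$tier[1L], status = st, stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(
    list(n = per_comp$composite_id),
    by = list(category = per_comp$category, tier = per_comp$tier,
              status = per_comp$status),
    FUN = length
  )
  cat_totals <- tapply(agg$n, agg$category, sum)
  agg$pct <- 100 * agg$n / as.numeric(cat_totals[agg$category])
  agg <- agg[order(agg$category, agg$tier, agg$status), ]
  rownames(agg) <- NULL
  class(agg) <- c("tier_stats", "data.frame")
  agg
}

#' @export
print.tier_stats <- function(x, ...) {
  cat("Composite foods by category, tier and status:\n")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}
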