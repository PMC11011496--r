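make_entries <- function(...) {
  rf_database(data.frame(..., stringsAsFactors = FALSE))
}

test_that("edges are one per (composite, ingredient) with deterministic order", {
  co <- generate_corpus(3, n_foods = 30)
  db <- compute_all_rfs(co$table, co$recipes)
  key <- paste(db$composite_id, db$ingredient_id)
  expect_false(anyDuplicated(key) > 0)
  expect_equal(order(db$composite_id, db$ingredient_id), seq_len(nrow(db)))
  # identical rerun -> identical database
  db2 <- compute_all_rfs(co$table, co$recipes)
  expect_identical(as.data.frame(db), as.data.frame(db2))
})

test_that("a failed food leaves the rest of the corpus untouched", {
  tab <- tiny_table()
  recipes <- list(
    UDON = udon_spec(),
    BAD = recipe_spec("01085", "mixed", c("01080", "GHOST"),
                      markers = c("avail_carb_g", "thiamine_mg"))
  )
  db <- compute_all_rfs(tab, recipes)
  expect_true(all(db$status[db$composite_id == "UDON"] == "ok"))
  expect_true(all(db$status[db$composite_id == "01085"] ==
                    "failed(INGREDIENTS_UNKNOWN)"))
  expect_equal(nrow(compute_all_rfs(tab, list())), 0L)
})

test_that("cyclic ingredient references are rejected with the cycle named", {
  tab <- tiny_table()
  recipes <- list(
    A1 = recipe_spec("01080", "mixed", "01085", markers = "avail_carb_g"),
    A2 = recipe_spec("01085", "mixed", "01080", markers = "avail_carb_g")
  )
  expect_error(compute_all_rfs(tab, recipes), "cyclic.*01080")
})

test_that("cumulative RFs are products of edge RFs along each path", {
  entries <- make_entries(
    composite_id = c("A", "B"), ingredient_id = c("B", "C"),
    rf = c(0.5, 2.0), tier = c(2L, 1L), category = "mixed",
    method = "mixed/gauss-jordan", status = "ok")
  tree <- disaggregate("A", entries)
  expect_equal(tree$children[[1]]$children[[1]]$cumulative_rf, 1.0)
  # independent path re-walk over a generated multi-tier corpus
  co <- generate_corpus(17, n_foods = 40)
  db <- compute_all_rfs(co$table, co$recipes)
  deep <- db$composite_id[db$tier == max(db$tier)][1]
  tr <- disaggregate(deep, db, max_depth = 10, table = co$table)
  leaves <- walk_leaf_products(tr, db)
  for (lf in leaves) expect_equal(lf$cum, lf$product, tolerance = 1e-12)
})

test_that("disaggregating a simulated chain recovers the generating RPC masses", {
  co <- generate_corpus(29, n_foods = 60)
  db <- compute_all_rfs(co$table, co$recipes)
  truth_ok <- co$truth[co$truth$expect == "ok", ]
  # cumulative truth along the chain = product of per-edge truths
  cum_truth <- function(id) {
    edges <- truth_ok[truth_ok$composite_id == id, ]
    if (!nrow(edges)) return(stats::setNames(1, id))
    out <- numeric(0)
    for (i in seq_len(nrow(edges))) {
      sub <- cum_truth(edges$ingredient_id[i]) * edges$rf_true[i]
      for (nm in names(sub)) out[nm] <- sum(out[nm], sub[nm], na.rm = TRUE)
    }
    out
  }
  deep <- db$composite_id[db$tier >= 3 & db$status == "ok"]
  expect_true(length(deep) > 0)
  for (id in unique(deep)[1:2]) {
    flat <- rpc_summary(disaggregate(id, db, max_depth = 10, table = co$table))
    want <- cum_truth(id)
    got <- stats::setNames(flat$cumulative_rf, flat$rpc_id)
    expect_equal(got[names(want)], want, tolerance = 1e-6)
  }
})

test_that("RPC inputs, failed branches and depth limits shape the tree", {
  co <- generate_corpus(31, n_foods = 30)
  db <- compute_all_rfs(co$table, co$recipes)
  rpc_id <- co$table$food_id[co$table$is_rpc][1]
  leaf <- disaggregate(rpc_id, db, table = co$table)
  expect_equal(leaf$cumulative_rf, 1.0)
  expect_true(leaf$is_rpc_leaf)
  expect_length(leaf$children, 0L)
  expect_error(disaggregate("NOPE", db, table = co$table), "unknown food_id")
  # failed composite shows as a failed node but siblings still expand
  failed_id <- unique(db$composite_id[startsWith(db$status, "failed")])[1]
  ftree <- disaggregate(failed_id, db, table = co$table)
  expect_equal(ftree$status, "failed")
  # truncation at max_depth 1
  deep_id <- db$composite_id[db$tier >= 2][1]
  ttree <- disaggregate(deep_id, db, max_depth = 1, table = co$table)
  statuses <- vapply(ttree$children, `[[`, character(1), "status")
  expect_true("truncated" %in% statuses)
  flat <- rpc_summary(ttree)
  expect_equal(unique(flat$complete), "no")
})

test_that("tier statistics count composites with percentages summing to 100", {
  entries <- make_entries(
    composite_id = c("A", "B", "C", "D", "E"),
    ingredient_id = c("r1", "r2", "r3", "r4", "A"),
    rf = 1, tier = c(1L, 1L, 1L, 1L, 2L), category = "dried",
    method = "dried", status = "ok")
  st <- tier_statistics(entries)
  expect_equal(st$pct[st$tier == 1], 80)
  expect_equal(st$pct[st$tier == 2], 20)
  expect_equal(nrow(tier_statistics(entries[0, ])), 0L)
  co <- generate_corpus(41, n_foods = 40)
  db <- compute_all_rfs(co$table, co$recipes)
  st2 <- tier_statistics(db)
  for (cat in unique(st2$category)) {
    expect_equal(sum(st2$pct[st2$category == cat]), 100, tolerance = 1e-9)
  }
})

test_that("tree export writes a readable nested document", {
  co <- generate_corpus(43, n_foods = 30)
  db <- compute_all_rfs(co$table, co$recipes)
  id <- db$composite_id[db$status == "ok"][1]
  tree <- disaggregate(id, db, table = co$table)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_disaggregation_tree(tree, path)
  doc <- yaml::read_yaml(path)
  expect_equal(doc$food_id, id)
  expect_equal(doc$cumulative_rf, 1.0)
})
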