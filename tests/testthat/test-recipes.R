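test_that("recipe YAML round-trips and parses categories strictly", {
  specs <- list(
    UDON = udon_spec(),
    MESHI = recipe_spec("MESHI", "mixed_known_ratio", "01080",
                        known_ratios = 47.6),
    NATA = recipe_spec("NATA", "mixed", c("01080", "FLOUR"),
                       markers = c("protein_g", "avail_carb_g"),
                       complicated = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_recipes(specs, path)
  back <- load_recipes(path)
  expect_named(back, names(specs))
  expect_equal(back$UDON$markers, c("avail_carb_g", "salt_eq_g"))
  expect_equal(back$MESHI$known_ratios, 47.6)
  expect_true(back$NATA$complicated)

  writeLines("foods:\n- composite_id: X\n  category: roasted\n", path)
  expect_error(load_recipes(path), "unknown category")
})

test_that("mixed recipes reject fewer markers than ingredients, naming the id", {
  expect_error(
    recipe_spec("TRIPLE", "mixed", c("A", "B", "C"),
                markers = c("protein_g", "avail_carb_g")),
    "TRIPLE.*markers"
  )
  # surplus candidate markers are allowed (pruned at solve time)
  expect_s3_class(
    recipe_spec("PAIR", "mixed", c("A", "B"),
                markers = c("protein_g", "avail_carb_g", "calcium_mg")),
    "recipe_spec"
  )
})

test_that("known_ratios must match ingredient count and be non-negative", {
  expect_error(recipe_spec("X", "mixed_known_ratio", c("A", "B"),
                           known_ratios = 60), "count")
  expect_error(recipe_spec("X", "mixed_known_ratio", c("A", "B"),
                           known_ratios = c(60, -1)), "non-negative")
})

test_that("empty recipe file loads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("foods: []", path)
  expect_length(load_recipes(path), 0L)
})

test_that("classify_failure detects missing ingredients and markers", {
  tab <- tiny_table()
  # unknown ingredient id
  sp <- recipe_spec("UDON", "mixed", c("FLOUR", "GHOST"),
                    markers = c("avail_carb_g", "salt_eq_g"))
  expect_equal(classify_failure(sp, tab), "INGREDIENTS_UNKNOWN")
  # fully specified square system is computable
  expect_null(classify_failure(udon_spec(), tab))
  # missing marker value on a square system lacks information
  tab2 <- as.data.frame(tab)
  tab2$salt_eq_g[tab2$food_id == "UDON"] <- NA
  tab2 <- composition_table(tab2)
  expect_equal(classify_failure(udon_spec(), tab2), "INGREDIENTS_UNKNOWN")
})

test_that("too many ingredients for the usable markers is its own reason", {
  tab <- as.data.frame(tiny_table())
  tab$thiamine_mg[tab$food_id == "UDON"] <- NA
  tab$calcium_mg[tab$food_id == "UDON"] <- NA
  tab <- composition_table(tab)
  # 3 ingredients, 5 candidate markers of which only 3 usable... still ok
  sp3 <- recipe_spec("UDON", "mixed", c("FLOUR", "SALT", "01080"),
                     markers = c("protein_g", "avail_carb_g", "salt_eq_g",
                                 "thiamine_mg", "calcium_mg"))
  expect_null(classify_failure(sp3, tab))
  # 4 ingredients, only 3 usable markers -> cannot be separated
  sp4 <- recipe_spec("UDON", "mixed", c("FLOUR", "SALT", "01080", "01161"),
                     markers = c("protein_g", "avail_carb_g", "salt_eq_g",
                                 "thiamine_mg", "calcium_mg"))
  expect_equal(classify_failure(sp4, tab), "TOO_MANY_INGREDIENTS")
})

test_that("failure precedence: unknown ingredients dominate the complicated flag", {
  tab <- tiny_table()
  sp <- recipe_spec("UDON", "mixed", c("FLOUR", "GHOST"),
                    markers = c("avail_carb_g", "salt_eq_g"),
                    complicated = TRUE)
  expect_equal(classify_failure(sp, tab), "INGREDIENTS_UNKNOWN")
  sp2 <- recipe_spec("UDON", "mixed", c("FLOUR", "SALT"),
                     markers = c("avail_carb_g", "salt_eq_g"),
                     complicated = TRUE)
  expect_equal(classify_failure(sp2, tab), "COMPLICATED_PROCESSING")
})

test_that("process constants validate their internal consistency", {
  pc <- process_constants()
  expect_equal(pc$ferment_constant, round(100 * pc$glucose_per_ethanol))
  expect_lt(abs(pc$glucose_per_ethanol - 1 / pc$ethanol_yield), 0.005)
  expect_error(process_constants(ferment_constant = 240), "ferment_constant")
  expect_error(process_constants(glucose_per_ethanol = 3), "1/ethanol_yield")
  expect_error(process_constants(nonsense = 1), "unknown process constant")
  pc2 <- process_constants(acetate_vinegar = 4.5)
  expect_equal(pc2$acetate_vinegar, 4.5)
})

test_that("classify-none foods compute without information errors on a corpus", {
  co <- generate_corpus(11, n_foods = 40)
  db <- compute_all_rfs(co$table, co$recipes)
  for (id in names(co$recipes)) {
    sp <- co$recipes[[id]]
    if (sp$category %in% c("uncooked", "cooked")) next
    reason <- classify_failure(sp, co$table)
    st <- db$status[db$composite_id == id]
    if (is.null(reason)) {
      expect_false(any(grepl("INGREDIENTS_UNKNOWN", st)),
                   label = paste("computable food", id))
    } else {
      expect_true(all(st == paste0("failed(", reason, ")")),
                  label = paste("failed food", id))
    }
  }
})
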