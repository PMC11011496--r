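test_that("alcohol-fermentation RF reproduces the rice-to-sake calculation", {
  expect_equal(round(100 * rf_alcohol_fermented(12.8, 2.5, 83.1), 2), 39.67)
  # unfermented material with conserved carbohydrate is a pure pass-through
  expect_equal(rf_alcohol_fermented(0, 55, 55), 1.0)
  # constant isolation: 1 g ethanol from 100 g-carb raw material
  expect_equal(rf_alcohol_fermented(1, 0, 100), 0.0238)
})

test_that("acetic-fermentation RF mirrors the alcohol equation 1:1", {
  expect_equal(rf_acetic_fermented(0, 30, 30), 1.0)
  expect_equal(rf_acetic_fermented(4.2, 1.0, 60),
               (238 * 4.2 / 60 + 100 * 1.0 / 60) / 100)
  expect_equal(rf_acetic_fermented(1, 0, 238), 0.01)
  # the acetic equation equals the alcohol equation under the 1:1
  # acetic<->ethanol mass assumption
  set.seed(3)
  for (i in 1:20) {
    d <- runif(1, 0, 10); b <- runif(1, 0, 20); cc <- runif(1, 20, 90)
    expect_equal(rf_acetic_fermented(d, b, cc),
                 rf_alcohol_fermented(d, b, cc))
  }
  # theoretical-yield alternative lowers the RF by the 1.304 factor
  pc <- process_constants()
  expect_equal(
    rf_acetic_fermented(2.6, 0, 60,
                        acetic_per_ethanol = pc$acetic_per_ethanol_theoretical),
    (238 * (2.6 / (60 / 46)) / 60) / 100)
})

test_that("fermentation RFs are linear in ethanol/acetic and residual carbohydrate", {
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 0.5, 15); b <- runif(1, 0.5, 20); cc <- runif(1, 30, 90)
    lam <- runif(1, 0.2, 3)
    f0 <- rf_alcohol_fermented(0, b, cc)
    expect_equal(rf_alcohol_fermented(lam * a, b, cc) - f0,
                 lam * (rf_alcohol_fermented(a, b, cc) - f0))
    g0 <- rf_alcohol_fermented(a, 0, cc)
    expect_equal(rf_alcohol_fermented(a, lam * b, cc) - g0,
                 lam * (rf_alcohol_fermented(a, b, cc) - g0))
    # with no ethanol the RF is the pure concentration ratio
    expect_equal(rf_alcohol_fermented(0, b, cc), b / cc)
  }
  expect_error(rf_alcohol_fermented(5, 2, 0), "no available carbohydrate")
})

test_that("stoichiometric glucose equivalents follow molar arithmetic", {
  expect_equal(glucose_equiv_ethanol(46), 90)
  expect_equal(glucose_equiv_ethanol(0), 0)
  expect_equal(glucose_equiv_ethanol(23), 45)
  expect_equal(glucose_equiv_acetate(60), 90)
  expect_equal(glucose_equiv_acetate(2), 3)
  expect_equal(glucose_equiv_acetate(0), 0)
})

test_that("simulated fermentation is inverted exactly by the RF equation", {
  tab <- generate_rpc_profiles(21, 9)
  grains <- tab[tab$avail_carb_g > 50, ]
  for (i in seq_len(nrow(grains))) {
    src <- grains[i, ]
    for (fr in c(0.2, 0.5, 0.85)) {
      res <- simulate_processing(list(
        composite_id = "F", source_id = src$food_id,
        steps = list(list(type = "FERMENT_ALCOHOL", fraction = fr))), tab)
      got <- rf_alcohol_fermented(res$item$ethanol_g, res$item$avail_carb_g,
                                  src$avail_carb_g)
      expect_equal(got, res$truth$rf_true, tolerance = 1e-6)
      # chain on full acetic oxidation: same raw material mass recovered
      res2 <- simulate_processing(list(
        composite_id = "V", source_id = src$food_id,
        steps = list(list(type = "FERMENT_ALCOHOL", fraction = fr),
                     list(type = "FERMENT_ACETIC", fraction = 1.0))), tab)
      got2 <- rf_acetic_fermented(res2$item$acetic_acid_g,
                                  res2$item$avail_carb_g, src$avail_carb_g)
      expect_equal(got2, res2$truth$rf_true, tolerance = 1e-6)
    }
  }
})

test_that("lactic foods route by recipe structure", {
  tab <- as.data.frame(tiny_table())
  # beverage-style: exact blend of two ingredients
  blend <- tab[tab$food_id == "01080", ]
  blend$food_id <- "LACB"
  for (f in ryf:::NUTRIENT_FIELDS) {
    blend[[f]] <- 0.4 * tab[[f]][tab$food_id == "01080"] +
      0.1 * tab[[f]][tab$food_id == "FLOUR"]
  }
  blend$water_pct <- blend$water_pct + 50  # made up to volume with water
  blend$is_rpc <- FALSE
  tab2 <- composition_table(rbind(tab, blend))
  sp <- recipe_spec("LACB", "fermented_lactic", c("01080", "FLOUR"))
  res <- rf_lactic_fermented(sp, tab2)
  expect_equal(sort(res$rf), c(0.1, 0.4), tolerance = 1e-9)
  # product equal to one ingredient -> weights (1, 0)
  pure <- tab[tab$food_id == "01080", ]
  pure$food_id <- "LACP"
  pure$is_rpc <- FALSE
  tab3 <- composition_table(rbind(tab, pure))
  sp2 <- recipe_spec("LACP", "fermented_lactic", c("01080", "FLOUR"))
  res2 <- rf_lactic_fermented(sp2, tab3)
  expect_equal(res2$rf[res2$ingredient_id == "01080"], 1, tolerance = 1e-9)
  expect_equal(res2$rf[res2$ingredient_id == "FLOUR"], 0, tolerance = 1e-9)
  # missing calcium -> insufficient information
  tab4 <- as.data.frame(tab2)
  tab4$calcium_mg[tab4$food_id == "LACB"] <- NA
  tab4 <- composition_table(tab4)
  expect_equal(classify_failure(sp, tab4), "INGREDIENTS_UNKNOWN")
  expect_error(rf_lactic_fermented(sp, tab4), "INGREDIENTS_UNKNOWN")
  # pickle-style single ingredient goes through the salted balance
  sp3 <- recipe_spec("01085", "fermented_lactic", "01080")
  res3 <- rf_lactic_fermented(sp3, tiny_table())
  expect_equal(res3$rf, rf_salted(14.9, 60.0, 0))
})
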