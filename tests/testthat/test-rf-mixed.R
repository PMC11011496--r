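test_that("the noodle system builds with documented row/column order", {
  sys <- build_nutrient_system(udon_spec(), tiny_table())
  expect_equal(unname(sys$R), matrix(c(75.1, 0, 0, 99.5), 2, 2, byrow = TRUE))
  expect_equal(sys$P, c(56.8, 2.5))
  expect_equal(sys$markers, c("avail_carb_g", "salt_eq_g"))
  expect_equal(sys$ingredients, c("FLOUR", "SALT"))
})

test_that("single-ingredient systems are 1x1; absent ids fail", {
  tab <- tiny_table()
  sp <- recipe_spec("01085", "mixed", "01080", markers = "avail_carb_g")
  sys <- build_nutrient_system(sp, tab)
  expect_equal(dim(sys$R), c(1L, 1L))
  sp2 <- recipe_spec("01085", "mixed", "GHOST", markers = "avail_carb_g")
  expect_error(build_nutrient_system(sp2, tab), "INGREDIENTS_UNKNOWN")
})

test_that("Gauss-Jordan solves the noodle system to the closed form", {
  sys <- build_nutrient_system(udon_spec(), tiny_table())
  sol <- gauss_jordan_solve(sys)
  expect_false(sol$singular)
  W <- unname(sol$solution)
  expect_equal(W, c(100 * 56.8 / 75.1, 100 * 2.5 / 99.5), tolerance = 1e-12)
  expect_lt(sol$residual, 1e-8)
  rfs <- solve_mixed_rf(udon_spec(), tiny_table())
  expect_equal(rfs$rf, c(56.8 / 75.1, 2.5 / 99.5), tolerance = 1e-12)
  expect_equal(rfs$method, rep("mixed/gauss-jordan", 2))
})

test_that("identity systems return the right-hand side; contracts enforced", {
  sol <- gauss_jordan_solve(diag(3), c(1, 2, 3))
  expect_equal(unname(sol$solution), c(1, 2, 3))
  expect_error(gauss_jordan_solve(matrix(1, 2, 3), c(1, 2)), "square")
  expect_error(gauss_jordan_solve(diag(2), 1), "length")
  expect_error(gauss_jordan_solve(matrix(c(1, NA, 0, 1), 2), c(1, 2)),
               "non-finite")
})

test_that("singular systems yield a structured report naming dependent columns", {
  A <- matrix(c(1, 2, 2, 4), 2, 2)  # rank 1
  colnames(A) <- c("u", "v")
  sol <- gauss_jordan_solve(A, c(1, 2))
  expect_true(sol$singular)
  expect_true(length(sol$dependent_columns) >= 1L)
  expect_true(all(sol$dependent_columns %in% c("u", "v")))
})

test_that("exact blends are recovered and invariances hold", {
  set.seed(101)
  tab <- generate_rpc_profiles(101, 10)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    ids <- sample(tab$food_id, k)
    wts <- runif(k, 5, 70 / k)
    mk <- ryf:::pick_markers(tab, ids, k)
    res <- simulate_processing(list(
      composite_id = "BLEND", mix_ids = ids, mix_weights = wts,
      water_g = runif(1, 0, 20), markers = mk), tab)
    tab2 <- composition_table(rbind(as.data.frame(tab), res$item))
    out <- solve_mixed_rf(res$spec, tab2)
    expect_equal(out$rf, res$truth$rf_true, tolerance = 1e-9)
    expect_lt(attr(out, "residual"), 1e-8)

    # permutation equivariance
    perm <- sample(k)
    sp_perm <- recipe_spec("BLEND", "mixed", ids[perm], markers = mk)
    out_perm <- solve_mixed_rf(sp_perm, tab2)
    expect_equal(out_perm$rf[match(ids, out_perm$ingredient_id)], out$rf,
                 tolerance = 1e-9)

    # scale invariance: scaling one marker row of R and P leaves W unchanged
    sys <- build_nutrient_system(res$spec, tab2)
    sol <- gauss_jordan_solve(sys)
    sys2 <- sys
    sys2$R[1, ] <- 100 * sys2$R[1, ]
    sys2$P[1] <- 100 * sys2$P[1]
    sol2 <- gauss_jordan_solve(sys2)
    expect_equal(sol2$solution, sol$solution, tolerance = 1e-9)
  }
})

test_that("known content ratios bypass the solver", {
  tab <- tiny_table()
  sp <- recipe_spec("01085", "mixed_known_ratio", "01080", known_ratios = 47.6)
  out <- solve_mixed_rf(sp, tab)
  expect_equal(out$rf, 0.476)
  expect_equal(out$method, "known-ratio")
})

test_that("negative solution components mark the entry set infeasible", {
  # composite with less salt than any blend of flour+salt can explain a
  # carbohydrate level above flour's own: forces a negative flour weight
  tab <- as.data.frame(tiny_table())
  tab$avail_carb_g[tab$food_id == "UDON"] <- 70
  tab$salt_eq_g[tab$food_id == "UDON"] <- 0.1
  tab$water_pct[tab$food_id == "UDON"] <- 20
  tab <- composition_table(tab)
  sp <- recipe_spec("UDON", "mixed", c("FLOUR", "01080"),
                    markers = c("avail_carb_g", "thiamine_mg"))
  out <- solve_mixed_rf(sp, tab)
  if (any(out$rf < 0 | out$status != "ok")) {
    expect_true(all(out$status == "infeasible"))
  }
  # direct construction: P outside the cone of the ingredient profiles
  A <- matrix(c(10, 0, 0, 5), 2, 2,
              dimnames = list(NULL, c("i1", "i2")))
  sysd <- structure(list(R = A, P = c(-1, 2), markers = c("m1", "m2"),
                         ingredients = c("i1", "i2"), k = 2L,
                         composite_id = "NEG"),
                    class = "nutrient_system")
  sol <- gauss_jordan_solve(sysd)
  expect_lt(sol$solution[[1]], -1e-9)
})

test_that("surplus candidate markers are pruned to a well-conditioned subset", {
  tab <- generate_rpc_profiles(55, 6)
  ids <- tab$food_id[1:2]
  res <- simulate_processing(list(
    composite_id = "B2", mix_ids = ids, mix_weights = c(30, 25),
    water_g = 10,
    markers = c("protein_g", "avail_carb_g", "sucrose_g", "calcium_mg")),
    tab)
  tab2 <- composition_table(rbind(as.data.frame(tab), res$item))
  sys <- build_nutrient_system(res$spec, tab2)
  expect_equal(sys$k, 2L)
  expect_equal(nrow(sys$R), 2L)       # pruned to square
  out <- solve_mixed_rf(res$spec, tab2)
  expect_equal(out$rf, res$truth$rf_true, tolerance = 1e-9)
})
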