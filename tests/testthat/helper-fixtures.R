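# In-code fixtures shared across test files.

# a tiny hand-written composition table: brown rice, cooked rice, rice
# bran style ids plus a flour/salt pair for the noodle system
tiny_table <- function() {
  composition_table(data.frame(
    food_id = c("01080", "01085", "01161", "FLOUR", "SALT", "UDON"),
    name = c("brown rice", "cooked rice", "rice bran", "wheat flour",
             "table salt", "udon noodles"),
    group = c(1L, 1L, 1L, 1L, 17L, 1L),
    water_pct = c(14.9, 60.0, 10.3, 14.0, 0.1, 33.0),
    protein_g = c(6.8, 2.5, 13.4, 8.3, 0, 2.6),
    avail_carb_g = c(78.4, 36.1, 48.8, 75.1, 0, 56.8),
    sucrose_g = c(0.8, 0.2, 3.0, 0.3, 0, 0.1),
    acetic_acid_g = 0,
    ethanol_g = 0,
    salt_eq_g = c(0, 0, 0, 0, 99.5, 2.5),
    thiamine_mg = c(0.41, 0.16, 3.12, 0.11, 0, 0.09),
    calcium_mg = c(9, 3, 35, 20, 22, 6),
    is_rpc = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
}

udon_spec <- function() {
  recipe_spec("UDON", "mixed", c("FLOUR", "SALT"),
              markers = c("avail_carb_g", "salt_eq_g"))
}

# mass-balance oracle for drying: the grams m of source (water a%) that
# leave exactly 100 g of product at water b% after removing water only
oracle_dried <- function(a, b) {
  solids <- 100 * (1 - b / 100)
  m <- solids / (1 - a / 100)
  m / 100
}

# mass-balance oracle for salting: m g source (water a%) + s g salt
# +/- water = 100 g product at water b%
oracle_salted <- function(a, b, s) {
  nonsalt_solids <- 100 - s - b      # g of source-derived solids in product
  m <- nonsalt_solids / (1 - a / 100)
  m / 100
}

# cofactor-expansion determinant: independent of base solve()/det()
cofactor_det <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(A[1, 1])
  if (n == 2L) return(A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  acc <- 0
  for (j in seq_len(n)) {
    minor <- A[-1, -j, drop = FALSE]
    acc <- acc + (-1)^(1 + j) * A[1, j] * cofactor_det(minor)
  }
  acc
}

cramer_solve <- function(A, b) {
  n <- nrow(A)
  d <- cofactor_det(A)
  vapply(seq_len(n), function(j) {
    Aj <- A
    Aj[, j] <- b
    cofactor_det(Aj) / d
  }, numeric(1L))
}

# independent re-walk of a disaggregation tree: recompute each leaf's
# cumulative RF as the explicit product of edge RFs along its path
walk_leaf_products <- function(node, entries, acc = 1) {
  if (!length(node$children)) {
    return(list(list(id = node$food_id, cum = node$cumulative_rf,
                     product = acc)))
  }
  out <- list()
  for (ch in node$children) {
    e <- entries[entries$composite_id == node$food_id &
                   entries$ingredient_id == ch$food_id, ]
    out <- c(out, walk_leaf_products(ch, entries, acc * e$rf[1L]))
  }
  out
}
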