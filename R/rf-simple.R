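# Closed-form RFs for dried, salted and pickled foods.
#
# All equations are water/salt mass balances per 100 g of product.  With a
# the source commodity's water content (%), b the product's water content
# (%) and s the added salt (g/100 g product), the grams of source needed
# per 100 g of product follow from conservation of non-water, non-salt
# solids:
#
#   RF = (100 - s - b) / (100 - a)        (s = 0 for plain drying)
#
# Pickling media (rice-bran paste, vinegar, soy sauce, miso) and added
# sugar are quantified through marker nutrients assumed to originate
# solely from the medium: thiamine, acetic acid, protein and sucrose.

# negatives within this tolerance are rounding noise and clamp to zero;
# anything larger signals recipe misconfiguration and is a hard error
NEG_TOL <- 1e-9

#' RF for a dried food
#'
#' Grams of source commodity per gram of dried product, from the water
#' contents before (\code{a_pct}) and after (\code{b_pct}) drying:
#' \code{RF = (100 - b) / (100 - a)}.  Always >= 1 since drying removes
#' mass.
#'
#' @param a_pct water content (\%) of the source commodity.
#' @param b_pct water content (\%) of the dried product.
#' @return Dimensionless RF.
#' @examples
#' rf_dried(90, 20)  # 8: dried shiitake-style concentration
#' @export
rf_dried <- function(a_pct, b_pct) {
  stopifnot(is.numeric(a_pct), is.numeric(b_pct))
  if (any(a_pct >= 100)) {
    stop("rf_dried: source water content must be < 100% (ratio undefined)")
  }
  if (any(a_pct < 0 | b_pct < 0)) stop("rf_dried: water contents must be >= 0")
  if (any(b_pct > a_pct)) {
    stop("rf_dried: product water content exceeds source (drying cannot add water)")
  }
  (100 - b_pct) / (100 - a_pct)
}

#' RF for a salted food
#'
#' Grams of source commodity per gram of salted product:
#' \code{RF = (100 - s - b) / (100 - a)} where \code{s_g} is the added
#' salt (g/100 g product, NaCl equivalent; the water content of salt is
#' taken as negligible).  Reduces to [rf_dried()] at \code{s_g = 0}.  RF
#' below 1 indicates net water uptake during brining.
#'
#' @param a_pct water content (\%) of the source commodity.
#' @param b_pct water content (\%) of the salted product.
#' @param s_g added salt, g per 100 g product.
#' @return Dimensionless RF.
#' @examples
#' rf_salted(90, 80, 5)  # 1.5
#' @export
rf_salted <- function(a_pct, b_pct, s_g) {
  stopifnot(is.numeric(a_pct), is.numeric(b_pct), is.numeric(s_g))
  if (any(a_pct >= 100)) {
    stop("rf_salted: source water content must be < 100% (ratio undefined)")
  }
  if (any(a_pct < 0 | b_pct < 0 | b_pct >= 100)) {
    stop("rf_salted: water contents must lie in [0, 100)")
  }
  if (any(s_g < 0 | s_g >= 100)) stop("rf_salted: salt must lie in [0, 100)")
  num <- 100 - s_g - b_pct
  if (any(num < 0)) {
    stop("rf_salted: salt + water exceed product mass (infeasible composition)")
  }
  num / (100 - a_pct)
}

# shared sugar mass balance: product sucrose minus sucrose contributed by
# the other ingredients, divided by sugar's own sucrose content
sugar_rf <- function(sucrose_product, contributed, constants, context) {
  implied <- sucrose_product - contributed
  if (implied < 0) {
    if (implied >= -NEG_TOL) {
      message(sprintf("%s: implied sugar %.3g within rounding tolerance, clamped to 0",
                      context, implied))
      implied <- 0
    } else {
      stop(sprintf(
        "%s: implied sugar is negative (%.6g); other ingredients already supply more sucrose than the product contains",
        context, implied))
    }
  }
  implied / constants$sucrose_sugar
}

#' RF components for vegetables pickled in salty rice-bran paste
#'
#' The vegetable RF comes from the water/salt balance; the rice-bran paste
#' RF from the product's thiamine, assumed to come entirely from the paste
#' (vegetable thiamine is negligible): \code{rf_medium = c / 3.12} with
#' 3.12 mg/100 g the thiamine content of rice-bran paste.
#'
#' @param a_pct,b_pct,s_g as in [rf_salted()].
#' @param c_thiamine thiamine of the pickled product, mg/100 g.
#' @param constants a [process_constants()] list.
#' @return List with components \code{rf_vegetable}, \code{rf_medium} and
#'   \code{medium = "rice_bran_paste"}.
#' @export
rf_pickle_rice_bran <- function(a_pct, b_pct, s_g, c_thiamine,
                                constants = process_constants()) {
  stopifnot(c_thiamine >= 0)
  list(
    rf_vegetable = rf_salted(a_pct, b_pct, s_g),
    rf_medium = c_thiamine / constants$thiamine_rice_bran,
    rf_sugar = NULL,
    medium = "rice_bran_paste"
  )
}

#' RF components for vegetables pickled in vinegar
#'
#' Vegetable RF from the water/salt balance; vinegar RF from the product's
#' acetic acid (\code{d / 4.2}, 4.2\% being the acetate content of
#' vinegar); sugar RF from the sucrose left after subtracting the
#' vegetable's own contribution, divided by sugar's 99.3\% sucrose.
#'
#' @param a_pct,b_pct,s_g as in [rf_salted()].
#' @param d_acetate acetic acid of the pickled product, g/100 g.
#' @param e_sucrose_product sucrose of the pickled product, g/100 g.
#' @param f_sucrose_veg sucrose of the raw vegetable, g/100 g.
#' @param constants a [process_constants()] list.
#' @return List with \code{rf_vegetable}, \code{rf_medium},
#'   \code{rf_sugar}, \code{medium = "vinegar"}.
#' @export
rf_pickle_vinegar <- function(a_pct, b_pct, s_g, d_acetate,
                              e_sucrose_product, f_sucrose_veg,
                              constants = process_constants()) {
  stopifnot(d_acetate >= 0, e_sucrose_product >= 0, f_sucrose_veg >= 0)
  rf_veg <- rf_salted(a_pct, b_pct, s_g)
  list(
    rf_vegetable = rf_veg,
    rf_medium = d_acetate / constants$acetate_vinegar,
    rf_sugar = sugar_rf(e_sucrose_product, rf_veg * f_sucrose_veg,
                        constants, "rf_pickle_vinegar"),
    medium = "vinegar"
  )
}

#' RF components for vegetables pickled in soy sauce or miso
#'
#' Vegetable RF from the water/salt balance (the product's salt is assumed
#' to arrive with the soy sauce/miso).  Medium RF from the product's
#' protein, assumed to come from the medium: \code{protein / 7.7} for soy
#' sauce or \code{protein / 12.5} for miso.  Sugar RF from the sucrose
#' left after subtracting both the vegetable's and the medium's
#' contributions (soy sauce carries 0.1 g sucrose per 100 g; miso none).
#'
#' @param a_pct,b_pct,s_g as in [rf_salted()].
#' @param protein_product protein of the pickled product, g/100 g.
#' @param i_sucrose_product sucrose of the pickled product, g/100 g.
#' @param j_sucrose_veg sucrose of the raw vegetable, g/100 g.
#' @param medium \code{"soy"} or \code{"miso"}.
#' @param constants a [process_constants()] list.
#' @return List with \code{rf_vegetable}, \code{rf_medium},
#'   \code{rf_sugar}, \code{medium}.
#' @export
rf_pickle_soy_miso <- function(a_pct, b_pct, s_g, protein_product,
                               i_sucrose_product, j_sucrose_veg,
                               medium = c("soy", "miso"),
                               constants = process_constants()) {
  medium <- match.arg(medium)
  stopifnot(protein_product >= 0, i_sucrose_product >= 0, j_sucrose_veg >= 0)
  rf_veg <- rf_salted(a_pct, b_pct, s_g)
  if (medium == "soy") {
    rf_med <- protein_product / constants$protein_soy_sauce
    sucrose_med <- constants$sucrose_soy_sauce
  } else {
    rf_med <- protein_product / constants$protein_miso
    sucrose_med <- constants$sucrose_miso
  }
  list(
    rf_vegetable = rf_veg,
    rf_medium = rf_med,
    rf_sugar = sugar_rf(i_sucrose_product,
                        rf_veg * j_sucrose_veg + rf_med * sucrose_med,
                        constants, paste0("rf_pickle_", medium)),
    medium = medium
  )
}
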