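#' Processing constants used by the RF equations
#'
#' Returns the set of fixed nutrient contents and stoichiometric yields that
#' parameterize the closed-form RF equations.  Each constant is the
#' composition-table value of a standard processing medium (rice-bran paste,
#' vinegar, table sugar, soy sauce, miso) or a fermentation yield, and can be
#' overridden so that a revised composition table changes data, not code.
#'
#' The defaults are:
#' \describe{
#'   \item{thiamine_rice_bran}{3.12 mg thiamine per 100 g rice-bran paste.}
#'   \item{acetate_vinegar}{4.2 g acetic acid per 100 g vinegar.}
#'   \item{sucrose_sugar}{99.3 g sucrose per 100 g table sugar.}
#'   \item{protein_soy_sauce}{7.7 g protein per 100 g soy sauce.}
#'   \item{protein_miso}{12.5 g protein per 100 g miso.}
#'   \item{sucrose_soy_sauce}{0.1 g sucrose per 100 g soy sauce.}
#'   \item{sucrose_miso}{0 g sucrose per 100 g miso.}
#'   \item{ethanol_yield}{0.42 kg ethanol per kg glucose fermented
#'     (practical yield; the remainder feeds yeast growth and CO2).}
#'   \item{glucose_per_ethanol}{2.38 g glucose consumed per g ethanol
#'     (1 / ethanol_yield, rounded as conventionally printed).}
#'   \item{ferment_constant}{238, the coefficient multiplying ethanol (or
#'     acetic acid) in the fermentation RF equations; equals
#'     round(100 * glucose_per_ethanol).}
#'   \item{acetic_per_ethanol_theoretical}{1.304 kg acetic acid per kg
#'     ethanol (molar stoichiometry, 60/46).}
#'   \item{acetic_per_ethanol_assumed}{1.0 kg acetic acid per kg ethanol,
#'     the working assumption (some ethanol feeds Acetobacter growth).}
#'   \item{trace_as_zero}{logical; whether "Tr" (trace) cells in a
#'     composition table are read as 0 rather than missing.}
#' }
#'
#' @param ... named overrides of any default, e.g.
#'   \code{process_constants(acetate_vinegar = 4.5)}.
#' @return A named list of class \code{"process_constants"}.  Internal
#'   consistency (glucose_per_ethanol vs. ethanol_yield, ferment_constant)
#'   is asserted on construction.
#' @examples
#' pc <- process_constants()
#' pc$ferment_constant            # 238
#' process_constants(acetate_vinegar = 4.5)$acetate_vinegar
#' @export
process_constants <- function(...) {
  pc <- list(
    thiamine_rice_bran            = 3.12,
    acetate_vinegar               = 4.2,
    sucrose_sugar                 = 99.3,
    protein_soy_sauce             = 7.7,
    protein_miso                  = 12.5,
    sucrose_soy_sauce             = 0.1,
    sucrose_miso                  = 0.0,
    ethanol_yield                 = 0.42,
    glucose_per_ethanol           = 2.38,
    ferment_constant              = 238,
    acetic_per_ethanol_theoretical = 60 / 46,
    acetic_per_ethanol_assumed    = 1.0,
    trace_as_zero                 = TRUE
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(pc))
    if (length(unknown)) {
      stop("unknown process constant(s): ", paste(unknown, collapse = ", "))
    }
    pc[names(overrides)] <- overrides
  }
  validate_process_constants(pc)
  structure(pc, class = "process_constants")
}

validate_process_constants <- function(pc) {
  num <- pc[setdiff(names(pc), "trace_as_zero")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1L)))) {
    stop("process constants must be finite numeric scalars")
  }
  pos <- setdiff(names(num), "sucrose_miso")
  if (any(unlist(num[pos]) <= 0)) {
    stop("process constants must be strictly positive (except sucrose_miso)")
  }
  if (abs(pc$glucose_per_ethanol - 1 / pc$ethanol_yield) > 0.005) {
    stop("glucose_per_ethanol must equal 1/ethanol_yield within 0.005")
  }
  if (pc$ferment_constant != round(100 * pc$glucose_per_ethanol)) {
    stop("ferment_constant must equal round(100 * glucose_per_ethanol)")
  }
  invisible(pc)
}

#' @export
print.process_constants <- function(x, ...) {
  cat("Processing constants for reverse-yield-factor calculation\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Glucose equivalent of ethanol (theoretical stoichiometry)
#'
#' Grams of glucose corresponding to a given mass of ethanol under the
#' theoretical fermentation stoichiometry (one glucose yields two ethanol):
#' \code{ethanol_g / 46 * 1/2 * 180 = (45/23) * ethanol_g}.  This is the
#' molar conversion; the practical, yield-adjusted factor used in the RF
#' equations is 2.38 g glucose per g ethanol.
#'
#' @param ethanol_g grams of ethanol (non-negative).
#' @return grams of glucose.
#' @examples
#' glucose_equiv_ethanol(46)  # 90
#' @export
glucose_equiv_ethanol <- function(ethanol_g) {
  stopifnot(is.numeric(ethanol_g), all(ethanol_g >= 0))
  (45 / 23) * ethanol_g
}

#' Glucose equivalent of acetic acid (theoretical stoichiometry)
#'
#' Grams of glucose corresponding to a given mass of acetic acid, tracing
#' acetic acid back through ethanol to glucose:
#' \code{acetic_g / 60 * 1/2 * 180 = 1.5 * acetic_g}.
#'
#' @param acetic_g grams of acetic acid (non-negative).
#' @return grams of glucose.
#' @examples
#' glucose_equiv_acetate(60)  # 90
#' @export
glucose_equiv_acetate <- function(acetic_g) {
  stopifnot(is.numeric(acetic_g), all(acetic_g >= 0))
  1.5 * acetic_g
}
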