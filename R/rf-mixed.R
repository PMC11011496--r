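# Nutrient-balance linear system for mixed foods.
#
# A composite made from k ingredients C_1..C_k in unknown amounts W_i
# (grams per 100 g of composite) must balance every conserved marker
# nutrient j:
#
#   sum_i (R_ji / 100) * W_i = P_j
#
# where R_ji is marker j's content per 100 g of ingredient C_i and P_j its
# content per 100 g of the composite.  With as many independent markers as
# ingredients the system is square; solving it by Gauss-Jordan elimination
# yields W, and RF_i = W_i / 100.

#' Build the nutrient-balance system for a mixed food
#'
#' Rows are ordered by \code{spec$markers}, columns by
#' \code{spec$ingredients}; entries are the table's per-100 g values.  When
#' more candidate markers than ingredients are configured, the square
#' subset minimizing the condition number of the marker matrix is selected
#' by exhaustive search (markers with missing values are dropped first).
#'
#' @param spec a [recipe_spec()] of category \code{"mixed"} (or the
#'   two-ingredient lactic case).
#' @param table a [composition_table()].
#' @return A \code{nutrient_system} list with elements \code{R} (k x k
#'   matrix, rows = markers, columns = ingredients), \code{P} (length-k
#'   target vector), \code{markers}, \code{ingredients}, \code{k}.
#' @export
build_nutrient_system <- function(spec, table) {
  stopifnot(inherits(spec, "recipe_spec"))
  reason <- classify_failure(spec, table)
  if (!is.null(reason)) {
    stop("build_nutrient_system: ", spec$composite_id,
         " is not computable (", reason, ")")
  }
  ing <- spec$ingredients
  k <- length(ing)
  markers <- spec$markers
  usable <- markers[vapply(markers, function(m) {
    vals <- c(profile_value(table, spec$composite_id, m),
              vapply(ing, function(id) profile_value(table, id, m), numeric(1L)))
    !anyNA(vals)
  }, logical(1L))]
  R_full <- matrix(0, nrow = length(usable), ncol = k,
                   dimnames = list(usable, ing))
  for (j in seq_along(usable)) {
    for (i in seq_len(k)) {
      R_full[j, i] <- profile_value(table, ing[i], usable[j])
    }
  }
  P_full <- vapply(usable, function(m)
    profile_value(table, spec$composite_id, m), numeric(1L))

  if (length(usable) > k) {
    sel <- select_markers(R_full, k)
    R_full <- R_full[sel, , drop = FALSE]
    P_full <- P_full[sel]
    usable <- usable[sel]
  }
  structure(
    list(R = R_full, P = unname(P_full), markers = usable,
         ingredients = ing, k = k, composite_id = spec$composite_id),
    class = "nutrient_system"
  )
}

# choose the k-row subset with the smallest 2-norm condition number;
# exhaustive over combinations (k <= 6 keeps this tiny)
select_markers <- function(R, k) {
  n <- nrow(R)
  combos <- utils::combn(n, k)
  best <- NULL
  best_kappa <- Inf
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    kap <- kappa(R[idx, , drop = FALSE], exact = TRUE)
    if (is.finite(kap) && kap < best_kappa) {
      best_kappa <- kap
      best <- idx
    }
  }
  if (is.null(best)) best <- combos[, 1L]
  best
}

#' @export
print.nutrient_system <- function(x, ...) {
  cat(sprintf("Nutrient-balance system for %s: %d ingredient(s)\n",
              x$composite_id, x$k))
  cat("R (marker content per 100 g of ingredient):\n")
  print(x$R)
  cat("P (marker content per 100 g of composite):\n")
  print(stats::setNames(x$P, x$markers))
  invisible(x)
}

#' Solve a square linear system by Gauss-Jordan elimination
#'
#' Reduces the augmented matrix \code{[A | b]} to reduced row-echelon form
#' with partial (row) pivoting.  Given a \code{nutrient_system}, solves
#' \code{(R/100) W = P} for \code{W}; given a plain matrix \code{A} and
#' right-hand side \code{b}, solves \code{A x = b}.  A pivot smaller than
#' \code{pivot_tol} stops elimination and returns a structured singularity
#' report naming the column(s) that could not be separated.
#'
#' @param system a \code{nutrient_system} from [build_nutrient_system()],
#'   or a square numeric matrix.
#' @param b right-hand side (ignored when \code{system} is a
#'   \code{nutrient_system}).
#' @param pivot_tol smallest acceptable absolute pivot after scaling.
#' @return A list with \code{solution} (the vector W or x),
#'   \code{residual} (max-norm residual of the solved equations),
#'   \code{singular = FALSE}; or, on a singular system, \code{singular =
#'   TRUE} with \code{dependent_columns} naming the unresolvable columns
#'   and \code{solution = NULL}.
#' @examples
#' gauss_jordan_solve(diag(2), c(3, 4))$solution  # 3 4
#' @export
gauss_jordan_solve <- function(system, b = NULL, pivot_tol = 1e-10) {
  if (inherits(system, "nutrient_system")) {
    A <- system$R / 100
    b <- system$P
    colnames(A) <- system$ingredients
  } else {
    A <- as.matrix(system)
  }
  if (nrow(A) != ncol(A)) {
    stop("gauss_jordan_solve: system must be square (got ",
         nrow(A), " x ", ncol(A), ")")
  }
  n <- nrow(A)
  if (length(b) != n) stop("gauss_jordan_solve: right-hand side length != n")
  if (!all(is.finite(A)) || !all(is.finite(b))) {
    stop("gauss_jordan_solve: non-finite entries in the system")
  }
  cn <- colnames(A)
  if (is.null(cn)) cn <- paste0("x", seq_len(n))
  aug <- cbind(unname(A), as.numeric(b))
  # scale rows to unit max so pivot_tol is meaningful across magnitudes
  scale_ref <- apply(abs(aug[, seq_len(n), drop = FALSE]), 1L, max)
  scale_ref[scale_ref == 0] <- 1
  piv_cols <- integer(0L)
  for (col in seq_len(n)) {
    rows_left <- setdiff(seq_len(n), piv_cols_rows(piv_cols))
    cand <- abs(aug[rows_left, col]) / scale_ref[rows_left]
    pr <- rows_left[which.max(cand)]
    if (max(cand) < pivot_tol) next  # column unresolvable; leave for report
    # swap into position
    pos <- length(piv_cols) + 1L
    if (pr != pos) {
      aug[c(pos, pr), ] <- aug[c(pr, pos), ]
      scale_ref[c(pos, pr)] <- scale_ref[c(pr, pos)]
    }
    piv_cols <- c(piv_cols, col)
    pos <- length(piv_cols)
    aug[pos, ] <- aug[pos, ] / aug[pos, col]
    for (r in seq_len(n)) {
      if (r != pos && aug[r, col] != 0) {
        aug[r, ] <- aug[r, ] - aug[r, col] * aug[pos, ]
      }
    }
  }
  if (length(piv_cols) < n) {
    dep <- setdiff(seq_len(n), piv_cols)
    return(list(solution = NULL, residual = NA_real_, singular = TRUE,
                dependent_columns = cn[dep]))
  }
  x <- numeric(n)
  x[piv_cols] <- aug[seq_len(n), n + 1L]
  names(x) <- cn
  residual <- max(abs(A %*% x - b))
  list(solution = x, residual = residual, singular = FALSE,
       dependent_columns = character(0L))
}

piv_cols_rows <- function(piv_cols) seq_along(piv_cols)

#' Solve a mixed food's RFs
#'
#' For a \code{mixed} recipe, builds the nutrient-balance system and
#' solves it by Gauss-Jordan elimination; \code{RF_i = W_i / 100}.  For a
#' \code{mixed_known_ratio} recipe the known grams per 100 g are used
#' directly without solving.  A singular system is reported as failure
#' reason \code{TOO_MANY_INGREDIENTS} (dependent markers cannot separate
#' the ingredients).  A solution component below \code{-1e-9} marks the
#' whole entry set \code{infeasible} (a recipe misspecification signal,
#' never silently clamped); components in \code{[-1e-9, 0)} are rounding
#' noise and clamp to zero.
#'
#' @param spec a [recipe_spec()] of category \code{"mixed"} or
#'   \code{"mixed_known_ratio"}.
#' @param table a [composition_table()].
#' @param pivot_tol pivot tolerance for [gauss_jordan_solve()].
#' @return Data.frame with columns \code{ingredient_id}, \code{rf},
#'   \code{method}, \code{status}, and attribute \code{"residual"}.
#' @export
solve_mixed_rf <- function(spec, table, pivot_tol = 1e-10) {
  stopifnot(inherits(spec, "recipe_spec"))
  if (spec$category == "mixed_known_ratio") {
    return(data.frame(
      ingredient_id = spec$ingredients,
      rf = spec$known_ratios / 100,
      method = "known-ratio",
      status = "ok",
      stringsAsFactors = FALSE
    ))
  }
  sys <- build_nutrient_system(spec, table)
  sol <- gauss_jordan_solve(sys, pivot_tol = pivot_tol)
  if (sol$singular) {
    stop(structure(
      class = c("ryf_singular_system", "error", "condition"),
      list(message = paste0(
             "solve_mixed_rf: singular system for ", spec$composite_id,
             "; dependent column(s): ",
             paste(sol$dependent_columns, collapse = ", ")),
           call = sys.call(),
           composite_id = spec$composite_id,
           dependent_columns = sol$dependent_columns)))
  }
  W <- sol$solution
  status <- "ok"
  if (any(W < -NEG_TOL)) {
    status <- "infeasible"
  } else {
    W[W < 0] <- 0
  }
  out <- data.frame(
    ingredient_id = spec$ingredients,
    rf = unname(W) / 100,
    method = "mixed/gauss-jordan",
    status = status,
    stringsAsFactors = FALSE
  )
  attr(out, "residual") <- sol$residual
  out
}
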