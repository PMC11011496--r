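# Column schema for composition tables.  Fixed and documented: these are
# exactly the nutrients that drive the RF equations (water/salt mass
# balances, thiamine/acetate/protein/sucrose pickle markers, fermentation
# ethanol/carbohydrate, and the carbohydrate/calcium pair for lactic
# beverages).
NUTRIENT_FIELDS <- c(
  "water_pct", "protein_g", "avail_carb_g", "sucrose_g", "acetic_acid_g",
  "ethanol_g", "salt_eq_g", "thiamine_mg", "calcium_mg"
)
TABLE_COLUMNS <- c("food_id", "name", "group", NUTRIENT_FIELDS, "is_rpc")

# mass-closure slack in g per 100 g
MASS_TOLERANCE <- 0.5

#' Construct a composition table
#'
#' A composition table holds one row per food item with per-100 g edible
#' portion nutrient values: \code{water_pct} (\%), \code{protein_g},
#' \code{avail_carb_g} (available carbohydrate), \code{sucrose_g},
#' \code{acetic_acid_g}, \code{ethanol_g}, \code{salt_eq_g} (NaCl
#' equivalent) in g/100 g, and \code{thiamine_mg}, \code{calcium_mg} in
#' mg/100 g, plus \code{food_id} (stable identifier, 5-digit codes in the
#' style of the Japanese standard tables are accepted), \code{name},
#' \code{group} (integer food group 1-17) and \code{is_rpc} (flags raw
#' primary commodities).  Missing values are explicit \code{NA}, never 0:
#' downstream RF calculations treat them as "insufficient information".
#'
#' @param items data.frame with (at least) the schema columns; extra
#'   columns are dropped.
#' @return A validated \code{composition_table} (a data.frame subclass).
#' @seealso [read_composition_table()]
#' @export
composition_table <- function(items) {
  stopifnot(is.data.frame(items))
  missing_cols <- setdiff(TABLE_COLUMNS, names(items))
  if (length(missing_cols)) {
    stop("composition table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  items <- items[TABLE_COLUMNS]
  items$food_id <- as.character(items$food_id)
  items$name <- as.character(items$name)
  items$group <- as.integer(items$group)
  for (f in NUTRIENT_FIELDS) items[[f]] <- as.numeric(items[[f]])
  items$is_rpc <- as.logical(items$is_rpc)
  rownames(items) <- NULL
  validate_composition_table(items)
  class(items) <- c("composition_table", "data.frame")
  items
}

validate_composition_table <- function(items) {
  if (anyDuplicated(items$food_id)) {
    dup <- unique(items$food_id[duplicated(items$food_id)])
    stop("duplicate food_id: ", paste(dup, collapse = ", "))
  }
  for (i in seq_len(nrow(items))) {
    validate_profile_row(items[i, ], row_label = items$food_id[i])
  }
  bad_grp <- !is.na(items$group) & (items$group < 1L | items$group > 17L)
  if (any(bad_grp)) {
    stop("group out of range 1-17 for food_id ",
         paste(items$food_id[bad_grp], collapse = ", "))
  }
  invisible(items)
}

validate_profile_row <- function(row, row_label) {
  w <- row$water_pct
  if (!is.na(w) && (w < 0 || w > 100)) {
    stop(sprintf("row %s: water_pct = %g outside [0, 100]", row_label, w))
  }
  for (f in setdiff(NUTRIENT_FIELDS, "water_pct")) {
    v <- row[[f]]
    if (!is.na(v) && v < 0) {
      stop(sprintf("row %s: %s = %g is negative", row_label, f, v))
    }
  }
  # proximate mass closure: water + protein + carbohydrate + ethanol can
  # never exceed 100 g in 100 g of food (fat/ash/fibre take the rest)
  parts <- c(row$water_pct, row$protein_g, row$avail_carb_g, row$ethanol_g)
  if (!anyNA(parts) && sum(parts) > 100 + MASS_TOLERANCE) {
    stop(sprintf(
      "row %s: water + protein + carbohydrate + ethanol = %.2f exceeds 100 g",
      row_label, sum(parts)))
  }
  invisible(row)
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Composition table: %d food items (%d flagged RPC)\n",
              nrow(x), sum(x$is_rpc, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Look up one food item
#'
#' @param table a [composition_table()].
#' @param food_id identifier to fetch.
#' @return One-row data.frame.  Raises an error naming the id when absent.
#' @export
get_food <- function(table, food_id) {
  idx <- match(food_id, table$food_id)
  if (is.na(idx)) stop("food_id not in composition table: ", food_id)
  table[idx, , drop = FALSE]
}

#' Read a composition table from delimited text
#'
#' Reads a UTF-8 comma- or tab-delimited file (delimiter auto-detected from
#' the header row) with one header row matching the documented schema;
#' extra columns are ignored.  Blank cells become explicit \code{NA},
#' never zero.  \code{"Tr"} (trace) cells are read as 0 when
#' \code{trace_as_zero} (the conventional reading of trace amounts) and as
#' missing otherwise.
#'
#' @param path file path.
#' @param trace_as_zero logical; how to read \code{"Tr"} cells.
#' @return A validated [composition_table()].
#' @export
read_composition_table <- function(path, trace_as_zero = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = TRUE,
                           na.strings = character(), encoding = "UTF-8",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(TABLE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("header lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  parse_num <- function(col, field) {
    col <- trimws(col)
    out <- rep(NA_real_, length(col))
    tr <- toupper(col) == "TR"
    if (any(tr)) out[tr] <- if (trace_as_zero) 0 else NA_real_
    plain <- !tr & nzchar(col)
    if (any(plain)) {
      v <- suppressWarnings(as.numeric(col[plain]))
      if (anyNA(v)) {
        bad <- which(plain)[which(is.na(v))[1L]]
        stop(sprintf("malformed value in row %d, field %s: '%s'",
                     bad, field, col[bad]))
      }
      out[plain] <- v
    }
    out
  }
  items <- data.frame(
    food_id = trimws(raw$food_id),
    name = raw$name,
    group = as.integer(parse_num(raw$group, "group")),
    stringsAsFactors = FALSE
  )
  for (f in NUTRIENT_FIELDS) items[[f]] <- parse_num(raw[[f]], f)
  isr <- toupper(trimws(raw$is_rpc))
  items$is_rpc <- isr %in% c("TRUE", "T", "1", "YES")
  composition_table(items)
}

#' Write a composition table to delimited text
#'
#' Tab-delimited, full precision (round-trips exactly through
#' [read_composition_table()]).  Missing values are written as empty cells.
#'
#' @param table a [composition_table()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_composition_table <- function(table, path) {
  out <- as.data.frame(table)
  for (f in NUTRIENT_FIELDS) {
    out[[f]] <- ifelse(is.na(out[[f]]), "",
                       formatC(out[[f]], digits = 17, format = "g"))
  }
  out$group <- ifelse(is.na(out$group), "", as.character(out$group))
  out$is_rpc <- ifelse(out$is_rpc, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an RF database to delimited text
#'
#' Flat export of computed RF entries: tab-delimited with columns
#' \code{composite_id}, \code{ingredient_id}, \code{rf} (full precision),
#' \code{rf_display} (rounded to 3 decimals), \code{tier}, \code{method},
#' \code{status}.
#'
#' @param entries an [rf_database()] or compatible data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [read_rf_database()]
#' @export
write_rf_database <- function(entries, path) {
  entries <- as.data.frame(entries)
  need <- c("composite_id", "ingredient_id", "rf", "tier", "method", "status")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    stop("rf entries lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    composite_id = entries$composite_id,
    ingredient_id = entries$ingredient_id,
    rf = ifelse(is.na(entries$rf), "",
                formatC(entries$rf, digits = 17, format = "g")),
    rf_display = ifelse(is.na(entries$rf), "",
                        formatC(round(entries$rf, 3), format = "f", digits = 3)),
    tier = ifelse(is.na(entries$tier), "", as.character(entries$tier)),
    method = entries$method,
    status = entries$status,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back an RF database written by [write_rf_database()]
#'
#' @param path file path.
#' @return An [rf_database()] data.frame (the \code{rf_display} column is
#'   dropped; \code{rf} is the full-precision value).
#' @export
read_rf_database <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character",
                           na.strings = character(),
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  rf_database(data.frame(
    composite_id = raw$composite_id,
    ingredient_id = raw$ingredient_id,
    rf = suppressWarnings(as.numeric(ifelse(nzchar(raw$rf), raw$rf, NA))),
    tier = suppressWarnings(as.integer(ifelse(nzchar(raw$tier), raw$tier, NA))),
    method = raw$method,
    status = raw$status,
    stringsAsFactors = FALSE
  ))
}
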