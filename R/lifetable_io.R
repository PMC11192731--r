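#' @name dataset_schema
#' @title Dataset schema
#' @description Column names, in order, of the published panel files: country
#'   identification, the full indicator block, populations, and the source
#'   quality code.
#' @return Character vector of the 30 column names.
#' @export
dataset_columns <- function() {
  c("country", "year", "desa_id", "country_year_id", "ISO3",
    "area_type_name", "SDG_reg_name", "WB_inc_name", "WB_reg_name",
    "le", "theil", "mld", "ge2", "variance", "stdev", "gini", "abs_gini",
    "iqr", "H_keyfitz", "life_disparity",
    "ader_25", "ader_50", "ader_75", "ader_1",
    "rder_25", "rder_50", "rder_75", "rder_1",
    "adult_pop", "total_pop", "source")
}

dataset_sexes <- c("both", "female", "male")
dataset_scopes <- c("total", "15")

# role -> candidate header names in WPP-style exports (case-insensitive)
.unwpp_aliases <- list(
  location = c("location", "country", "region"),
  year     = c("time", "year", "mid_period"),
  sex      = c("sex"),
  x        = c("agegrpstart", "age", "x", "agestart"),
  n        = c("agegrpspan", "n", "width", "agespan"),
  d        = c("dx", "d", "deaths"),
  a        = c("ax", "a"),
  l        = c("lx", "l", "survivors"),
  e        = c("ex", "e")
)

match_column <- function(role, headers, aliases = .unwpp_aliases) {
  hit <- which(tolower(headers) %in% aliases[[role]])
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Read abridged life tables from a WPP-style CSV
#'
#' Accepts the column dialects found in World Population Prospects abridged
#' life-table exports: `AgeGrpStart`/`AgeGrpSpan`-style or plain `x`/`n`
#' headers, with `dx`, `ax` and optionally `lx`, `ex`; one table is built per
#' (location, year, sex) present. The terminal open-ended interval is
#' signalled by a span of -1, an empty/NA span, or an age label ending in
#' `+`. Every table is validated on construction; non-contiguous intervals
#' raise an error naming the offending ages.
#'
#' @param path CSV file path.
#' @param sex which sex values to keep: one of `"both"`, `"female"`,
#'   `"male"`, or `"all"` (default) for everything present. Matched
#'   case-insensitively; `"total"` in the file is treated as `"both"`.
#' @return A list of [abridged_lifetable()] objects, one per
#'   (location, year, sex), each with `meta$country`, `meta$year`,
#'   `meta$sex` filled in.
#' @export
read_unwpp_csv <- function(path, sex = "all") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  headers <- names(raw)
  roles <- c("location", "year", "sex", "x", "n", "d", "a")
  idx <- vapply(c(roles, "l", "e"), match_column, integer(1), headers = headers)
  missing <- names(idx[roles])[is.na(idx[roles])]
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  build_tables_from_frame(raw, idx, sex)
}

#' Read abridged life tables from a generic CSV with a user column map
#'
#' Same contract as [read_unwpp_csv()] but with explicit column names. The
#' map is a named character vector from role to the file's column name;
#' roles `x` (interval start), `n` (width), `d` (deaths), `a` (average years
#' lived) are mandatory, `l`, `e`, `location`, `year`, `sex` optional.
#'
#' @param path CSV file path.
#' @param column_map named character vector, e.g.
#'   `c(x = "age", n = "width", d = "dx", a = "ax")`.
#' @param sex sex filter as in [read_unwpp_csv()].
#' @return A list of [abridged_lifetable()] objects.
#' @export
read_generic <- function(path, column_map, sex = "all") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mandatory <- c("x", "n", "d", "a")
  missing <- setdiff(mandatory, names(column_map))
  if (length(missing) > 0) {
    stop("column_map missing mandatory role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idx <- vapply(c("location", "year", "sex", "x", "n", "d", "a", "l", "e"),
                function(role) {
                  if (!role %in% names(column_map)) return(NA_integer_)
                  hit <- which(names(raw) == column_map[[role]])
                  if (length(hit) == 0) {
                    stop("mapped column not in file: ", column_map[[role]],
                         call. = FALSE)
                  }
                  hit[1]
                }, integer(1))
  build_tables_from_frame(raw, idx, sex)
}

build_tables_from_frame <- function(raw, idx, sex) {
  get <- function(role) if (is.na(idx[[role]])) NULL else raw[[idx[[role]]]]
  loc <- get("location"); yr <- get("year"); sx <- get("sex")
  if (is.null(loc)) loc <- rep("", nrow(raw))
  if (is.null(yr)) yr <- rep(NA, nrow(raw))
  if (is.null(sx)) sx <- rep("both", nrow(raw))
  sx <- tolower(as.character(sx))
  sx[sx %in% c("total", "both sexes")] <- "both"
  if (!identical(sex, "all")) {
    keep <- sx == tolower(sex)
    raw <- raw[keep, , drop = FALSE]
    loc <- loc[keep]; yr <- yr[keep]; sx <- sx[keep]
  }
  if (nrow(raw) == 0) stop("no rows after sex filter", call. = FALSE)

  x_raw <- raw[[idx[["x"]]]]
  x <- suppressWarnings(as.numeric(sub("[-+].*$", "", as.character(x_raw))))
  n <- suppressWarnings(as.numeric(as.character(raw[[idx[["n"]]]])))
  open <- is.na(n) | n < 0 | grepl("\\+$", as.character(x_raw))
  n[open] <- NA_real_

  key <- paste(loc, yr, sx, sep = "\r")
  lapply(split(seq_len(nrow(raw)), key), function(rows) {
    ord <- rows[order(x[rows])]
    lt <- abridged_lifetable(
      x = x[ord], n = n[ord],
      d = raw[[idx[["d"]]]][ord], a = raw[[idx[["a"]]]][ord],
      l = if (!is.na(idx[["l"]])) raw[[idx[["l"]]]][ord],
      e = if (!is.na(idx[["e"]])) raw[[idx[["e"]]]][ord],
      meta = list(country = loc[ord[1]], year = yr[ord[1]], sex = sx[ord[1]])
    )
    assert_valid(lt)
  })
}

#' Write life tables in the generic CSV dialect
#'
#' Writes `location, year, sex, x, n, d, a[, l, e]` rows, full precision,
#' one row per interval with the open-ended interval's width left empty.
#' The output round-trips through [read_generic()] (and, since the headers
#' are recognised aliases, through [read_unwpp_csv()]).
#'
#' @param tables list of [abridged_lifetable()] objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_generic <- function(tables, path) {
  if (inherits(tables, "abridged_lifetable")) tables <- list(tables)
  rows <- lapply(tables, function(lt) {
    iv <- lt$intervals
    out <- data.frame(
      location = lt$meta$country %||% "",
      year = lt$meta$year %||% NA,
      sex = lt$meta$sex %||% "both",
      x = iv$x, n = iv$n, d = iv$d, a = iv$a)
    out$l <- if (!is.null(iv$l)) iv$l else NA_real_
    out$e <- if (!is.null(iv$e)) iv$e else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$l))) out$l <- NULL
  if (all(is.na(out$e))) out$e <- NULL
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the six-file dataset panel
#'
#' Emits the panel in its published layout: one CSV per (sex, scope)
#' combination, named `{tag}_{sex}_{scope}.csv` with sex in
#' both/female/male and scope in total/15, each carrying exactly the
#' [dataset_columns()] header in order. Combinations with no records are
#' written header-only. Missing metadata is written as empty fields.
#'
#' @param records data frame of measure records as returned by
#'   [compute_measures()]: the [dataset_columns()] plus routing columns
#'   `sex` and `scope` (dropped on write).
#' @param tag file-name prefix, e.g. a vintage label.
#' @param out_dir output directory, created if needed.
#' @return Character vector of the six file paths, invisibly.
#' @export
write_dataset <- function(records, tag, out_dir = ".") {
  cols <- dataset_columns()
  if (is.null(records) || nrow(records) == 0) {
    records <- cbind(
      as.data.frame(setNames(rep(list(character(0)), length(cols)), cols)),
      sex = character(0), scope = character(0))
  }
  if (!all(c("sex", "scope") %in% names(records))) {
    stop("records must carry routing columns 'sex' and 'scope'", call. = FALSE)
  }
  bad <- !(records$sex %in% dataset_sexes) | !(records$scope %in% dataset_scopes)
  if (any(bad)) {
    stop("records with unknown sex/scope: ",
         paste(records$country_year_id[bad], collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing schema column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sx in dataset_sexes) {
    for (sc in dataset_scopes) {
      sel <- records[records$sex == sx & records$scope == sc, cols, drop = FALSE]
      if (nrow(sel) > 0) sel <- sel[order(sel$country, sel$year), , drop = FALSE]
      p <- file.path(out_dir, sprintf("%s_%s_%s.csv", tag, sx, sc))
      utils::write.csv(sel, p, row.names = FALSE, na = "", fileEncoding = "UTF-8")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
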