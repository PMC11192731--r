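#' Compute the full indicator record for one life table
#'
#' Assembles one row of the dataset schema ([dataset_columns()]) from a
#' single life table: life expectancy, the inequality battery (Theil, MLD,
#' GE(2), variance, standard deviation, Gini, absolute Gini, IQR, Keyfitz's
#' H, life disparity) and absolute/relative DER polarization on the alpha
#' grid 0.25, 0.5, 0.75, 1. With `scope = "15"` every indicator is computed
#' on the distribution of ages at death conditional on survival to 15
#' (absolute ages, renormalized masses), as in the over-15 panel files.
#' Metadata and the source quality code are passed through from
#' `table$meta`; populations default to the radix (total) and survivors to
#' age 15 (adult) when the metadata carries none.
#'
#' @param table a valid [abridged_lifetable()].
#' @param scope `"total"` or `"15"`.
#' @return One-row data frame: [dataset_columns()] plus routing columns
#'   `sex` and `scope`.
#' @export
compute_measures <- function(table, scope = c("total", "15")) {
  scope <- match.arg(scope)
  m <- table$meta
  ctx <- paste(c(m$country, m$year, m$sex), collapse = " ")
  min_age <- if (scope == "15") 15 else 0
  rec <- tryCatch({
    dist <- if (min_age > 0) condition_on_age(table, min_age)
            else to_distribution(table)
    alphas <- c(0.25, 0.5, 0.75, 1)
    ader <- vapply(alphas, der, numeric(1), dist = dist)
    rder <- vapply(alphas, rel_der, numeric(1), dist = dist)
    l15 <- survivorship(table)[which(abs(table$intervals$x - 15) < 1e-9)]
    data.frame(
      country = m$country %||% "", year = m$year %||% NA,
      desa_id = m$desa_id %||% NA,
      country_year_id = m$country_year_id %||%
        paste0(m$ISO3 %||% m$country %||% "", m$year %||% ""),
      ISO3 = m$ISO3 %||% "", area_type_name = m$area_type_name %||% "country",
      SDG_reg_name = m$SDG_reg_name %||% "",
      WB_inc_name = m$WB_inc_name %||% "",
      WB_reg_name = m$WB_reg_name %||% "",
      le = dist$mu, theil = theil(dist), mld = mld(dist), ge2 = ge2(dist),
      variance = lifespan_variance(dist), stdev = lifespan_stdev(dist),
      gini = gini(dist), abs_gini = abs_gini(dist),
      iqr = lifespan_iqr(dist), H_keyfitz = keyfitz_h(table, min_age),
      life_disparity = life_disparity(table, min_age),
      ader_25 = ader[1], ader_50 = ader[2], ader_75 = ader[3],
      ader_1 = ader[4],
      rder_25 = rder[1], rder_50 = rder[2], rder_75 = rder[3],
      rder_1 = rder[4],
      adult_pop = m$adult_pop %||% (if (length(l15) == 1) l15 else NA),
      total_pop = m$total_pop %||% table$radix,
      source = m$source %||% "",
      sex = m$sex %||% "both", scope = scope,
      stringsAsFactors = FALSE)
  }, error = function(err) {
    stop(sprintf("[%s, scope %s] %s", ctx, scope, conditionMessage(err)),
         call. = FALSE)
  })
  rec
}

#' Batch pipeline: tables in, six dataset files out
#'
#' Computes [compute_measures()] for every table and both population
#' scopes, and writes the panel with [write_dataset()]. Tables that fail
#' validation or indicator computation are logged and skipped, never
#' fatal; the run errors only if nothing was processed. Output ordering is
#' deterministic (country, then year).
#'
#' @param tables list of [abridged_lifetable()]s.
#' @param tag file-name prefix for the six output files.
#' @param out_dir output directory.
#' @param scopes which population scopes to compute; default both.
#' @return List with `paths` (six files), `records` (all emitted rows),
#'   and `log` (one row per (table, scope) attempt with its outcome).
#' @export
run_panel <- function(tables, tag, out_dir = ".",
                      scopes = c("total", "15")) {
  log <- list()
  recs <- list()
  for (i in seq_along(tables)) {
    for (sc in scopes) {
      ctx <- paste(c(tables[[i]]$meta$country, tables[[i]]$meta$year,
                     tables[[i]]$meta$sex, sc), collapse = " ")
      res <- tryCatch(compute_measures(tables[[i]], sc),
                      error = function(err) conditionMessage(err))
      if (is.character(res)) {
        log[[length(log) + 1]] <- data.frame(id = ctx, status = "failed",
                                             detail = res)
      } else {
        recs[[length(recs) + 1]] <- res
        log[[length(log) + 1]] <- data.frame(id = ctx, status = "ok",
                                             detail = "")
      }
    }
  }
  if (length(recs) == 0) stop("no tables processed successfully", call. = FALSE)
  records <- do.call(rbind, recs)
  records <- records[order(records$country, records$year), ]
  paths <- write_dataset(records, tag, out_dir)
  list(paths = paths, records = records, log = do.call(rbind, log))
}

#' Cross-check computed life expectancy against the tables' own e column
#'
#' For tables that carry a remaining-life-expectancy column, compares the
#' package's life expectancy at birth (mean of the age-at-death
#' distribution) with the table's own e at age 0, reporting the Pearson
#' correlation and the maximum absolute gap. A near-1 correlation is the
#' internal-consistency check between independently supplied e columns and
#' the deaths-based computation.
#'
#' @param tables list of at least two [abridged_lifetable()]s with `e`.
#' @return List with `correlation`, `max_abs_gap`, and the two vectors
#'   (`computed_e0`, `table_e0`).
#' @export
validate_against_table_e0 <- function(tables) {
  if (length(tables) < 2) {
    stop("need at least two tables to correlate", call. = FALSE)
  }
  has_e <- vapply(tables, function(t) !is.null(t$intervals$e), logical(1))
  if (!all(has_e)) stop("every table must carry an e column", call. = FALSE)
  computed <- vapply(tables, function(t) to_distribution(t)$mu, numeric(1))
  given <- vapply(tables, function(t) t$intervals$e[1], numeric(1))
  list(correlation = stats::cor(computed, given),
       max_abs_gap = max(abs(computed - given)),
       computed_e0 = computed, table_e0 = given)
}

#' Group-level indicator rows
#'
#' Aggregates country tables into group rows using a grouping map
#' (ISO3 -> group label) and population weights (total population for the
#' total scope, adult population for the over-15 scope; both fall back to
#' the cohort counts carried by the tables). GE-family columns come from
#' [ge_decompose()] totals — identical, by additivity, to GE of the pooled
#' distribution; life expectancy is the weighted mean; Gini, absolute
#' Gini, IQR and the DER columns are computed on the pooled distribution.
#' Life disparity and Keyfitz's H need the full person-years chain of a
#' merged table and are left empty at group level. Tables whose ISO3 is
#' not mapped are reported and skipped.
#'
#' @param tables list of [abridged_lifetable()]s with `meta$ISO3`.
#' @param grouping data frame with columns `ISO3` and `group`.
#' @param scope `"total"` or `"15"`.
#' @return Data frame of group rows in the dataset schema (plus `sex`,
#'   `scope`), with an attribute `"unmapped"` listing skipped ISO3 codes.
#' @export
aggregate_groups <- function(tables, grouping, scope = c("total", "15")) {
  scope <- match.arg(scope)
  min_age <- if (scope == "15") 15 else 0
  iso <- vapply(tables, function(t) t$meta$ISO3 %||% "", character(1))
  mapped <- iso %in% grouping$ISO3
  unmapped <- unique(iso[!mapped])
  if (length(unmapped) > 0) {
    warning("unmapped ISO3 skipped: ", paste(unmapped, collapse = ", "),
            call. = FALSE)
  }
  tables <- tables[mapped]
  iso <- iso[mapped]
  if (length(tables) == 0) stop("no mapped tables", call. = FALSE)
  groups <- grouping$group[match(iso, grouping$ISO3)]
  rows <- lapply(split(seq_along(tables), groups), function(idx) {
    tabs <- tables[idx]
    w <- vapply(tabs, function(t) {
      m <- t$meta
      if (scope == "15") {
        (m$adult_pop %||%
           survivorship(t)[which(abs(t$intervals$x - 15) < 1e-9)])
      } else {
        m$total_pop %||% t$radix
      }
    }, numeric(1))
    dists <- lapply(tabs, function(t) {
      if (min_age > 0) condition_on_age(t, min_age) else to_distribution(t)
    })
    pooled <- pool_distributions(dists, w)
    alphas <- c(0.25, 0.5, 0.75, 1)
    ader <- vapply(alphas, der, numeric(1), dist = pooled)
    rder <- vapply(alphas, rel_der, numeric(1), dist = pooled)
    data.frame(
      country = groups[idx][1], year = tabs[[1]]$meta$year %||% NA,
      desa_id = NA, country_year_id = "", ISO3 = "",
      area_type_name = "region", SDG_reg_name = "", WB_inc_name = "",
      WB_reg_name = "",
      le = pooled$mu,
      theil = ge_decompose(dists, w, 1)$total,
      mld = ge_decompose(dists, w, 0)$total,
      ge2 = ge_decompose(dists, w, 2)$total,
      variance = lifespan_variance(pooled), stdev = lifespan_stdev(pooled),
      gini = gini(pooled), abs_gini = abs_gini(pooled),
      iqr = lifespan_iqr(pooled),
      H_keyfitz = NA_real_, life_disparity = NA_real_,
      ader_25 = ader[1], ader_50 = ader[2], ader_75 = ader[3],
      ader_1 = ader[4],
      rder_25 = rder[1], rder_50 = rder[2], rder_75 = rder[3],
      rder_1 = rder[4],
      adult_pop = if (scope == "15") sum(w) else NA,
      total_pop = if (scope == "total") sum(w) else NA,
      source = "", sex = tabs[[1]]$meta$sex %||% "both", scope = scope,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}
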