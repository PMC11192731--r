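#' Abridged period life tables
#'
#' An `abridged_lifetable` holds one period life table as an ordered set of
#' age intervals for a synthetic cohort of size `radix` (conventionally
#' 100,000). Each closed interval `[x, x + n)` carries the deaths `d`
#' occurring in it and the average time `a` lived in the interval by those
#' dying in it; the terminal interval is open-ended (`n = NA`). Survivorship
#' `l` at each interval start and remaining life expectancy `e` are optional:
#' when absent they are reconstructed from `d` and `a` (see
#' [remaining_life_expectancy()]).
#'
#' @param x integer vector of interval start ages, contiguous from 0 upward.
#' @param n interval widths in years; `NA` marks the single open-ended
#'   terminal interval.
#' @param d deaths in each interval, in cohort units; must sum to `radix`.
#' @param a average years lived within the interval by those dying in it.
#' @param l optional survivors at each interval start (cohort units).
#' @param e optional remaining life expectancy at each interval start (years).
#' @param radix synthetic cohort size \eqn{\ell_0}; defaults to `sum(d)`.
#' @param meta named list of metadata (country, ISO3, year, sex, source
#'   quality code, populations, ...). Carried through unmodified.
#'
#' @return An object of class `abridged_lifetable`: a list with elements
#'   `intervals` (data frame with columns `x`, `n`, `d`, `a`, and `l`, `e`
#'   when available), `radix`, and `meta`.
#' @seealso [validate_lifetable()], [to_distribution()], [make_lifetable()]
#' @export
#' @examples
#' lt <- abridged_lifetable(
#'   x = c(0, 5), n = c(5, NA), d = c(20000, 80000), a = c(2.5, 10)
#' )
#' validate_lifetable(lt)
abridged_lifetable <- function(x, n, d, a, l = NULL, e = NULL,
                               radix = sum(d), meta = list()) {
  k <- length(x)
  stopifnot(length(n) == k, length(d) == k, length(a) == k)
  if (!is.null(l)) stopifnot(length(l) == k)
  if (!is.null(e)) stopifnot(length(e) == k)
  ord <- order(x)
  intervals <- data.frame(x = as.numeric(x)[ord], n = as.numeric(n)[ord],
                          d = as.numeric(d)[ord], a = as.numeric(a)[ord])
  if (!is.null(l)) intervals$l <- as.numeric(l)[ord]
  if (!is.null(e)) intervals$e <- as.numeric(e)[ord]
  structure(list(intervals = intervals, radix = as.numeric(radix),
                 meta = meta),
            class = "abridged_lifetable")
}

#' @export
print.abridged_lifetable <- function(x, ...) {
  m <- x$meta
  id <- paste(c(m$country, m$year, m$sex), collapse = " ")
  cat(sprintf("Abridged life table%s: %d intervals, radix %g\n",
              if (nzchar(id)) paste0(" [", id, "]") else "",
              nrow(x$intervals), x$radix))
  print(utils::head(x$intervals, 8), ...)
  if (nrow(x$intervals) > 8) cat("...\n")
  invisible(x)
}

n_intervals <- function(table) nrow(table$intervals)

is_open <- function(table) is.na(table$intervals$n)

# survivorship at interval starts, reconstructed from d when absent or
# inconsistent with cumulative deaths (d and a are the primitives)
survivorship <- function(table, tol = 1e-4) {
  iv <- table$intervals
  l_chain <- table$radix - cumsum(c(0, iv$d[-nrow(iv)]))
  if (!is.null(iv$l)) {
    if (max(abs(iv$l - l_chain)) > tol * table$radix) {
      warning("survivorship column inconsistent with cumulative deaths; ",
              "recomputed from d", call. = FALSE)
      return(l_chain)
    }
    return(iv$l)
  }
  l_chain
}

#' Validate an abridged life table
#'
#' Checks every structural invariant of the `abridged_lifetable` class and
#' returns a report of violations rather than throwing. The invariants are:
#' contiguous intervals; exactly one open-ended terminal interval; a
#' boundary at age 15 (needed for over-15 conditioning); non-negative deaths
#' summing to the radix; `0 <= a <= n` for closed intervals and `a > 0` for
#' the open one; and, when survivorship is present, `l` non-increasing and
#' consistent with cumulative deaths.
#'
#' @param table an [abridged_lifetable()].
#' @param tol relative tolerance on radix conservation and `l`/`d`
#'   consistency, as a fraction of the radix.
#' @return A data frame with columns `invariant`, `interval` (1-based index
#'   or `NA` for table-level checks), and `message`; zero rows iff the table
#'   is valid.
#' @export
validate_lifetable <- function(table, tol = 1e-6) {
  iv <- table$intervals
  k <- nrow(iv)
  bad <- list()
  note <- function(invariant, interval, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      invariant = invariant, interval = interval, message = message)
  }

  open <- which(is.na(iv$n))
  if (length(open) != 1L || open != k) {
    note("terminal_open", NA_integer_,
         sprintf("expected exactly one open-ended terminal interval, found %d (at %s)",
                 length(open), paste(open, collapse = ",")))
  }
  closed <- which(!is.na(iv$n))
  closed <- closed[closed < k]
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      if (is.na(iv$n[i])) next
      if (abs(iv$x[i] + iv$n[i] - iv$x[i + 1]) > 1e-9) {
        note("contiguity", i,
             sprintf("gap or overlap between ages %g and %g", iv$x[i] + iv$n[i],
                     iv$x[i + 1]))
      }
    }
  }
  if (!any(abs(c(iv$x, iv$x[k] + if (!is.na(iv$n[k])) iv$n[k] else 0) - 15) < 1e-9)) {
    note("boundary_15", NA_integer_, "no interval boundary at age 15")
  }
  if (any(iv$d < 0)) {
    for (i in which(iv$d < 0)) note("d_nonnegative", i,
                                    sprintf("d = %g < 0", iv$d[i]))
  }
  if (abs(sum(iv$d) - table$radix) > tol * table$radix) {
    note("radix_conservation", NA_integer_,
         sprintf("sum(d) = %g differs from radix %g", sum(iv$d), table$radix))
  }
  for (i in seq_len(k)) {
    if (is.na(iv$n[i])) {
      if (iv$d[i] > 0 && iv$a[i] <= 0) {
        note("a_open_positive", i, sprintf("open interval a = %g <= 0", iv$a[i]))
      }
    } else if (iv$a[i] < 0 || iv$a[i] > iv$n[i]) {
      note("a_within_width", i,
           sprintf("a = %g outside [0, %g]", iv$a[i], iv$n[i]))
    }
  }
  if (!is.null(iv$l)) {
    if (any(diff(iv$l) > 1e-9)) {
      for (i in which(diff(iv$l) > 1e-9)) {
        note("l_nonincreasing", i + 1L,
             sprintf("l rises from %g to %g", iv$l[i], iv$l[i + 1]))
      }
    }
    dl <- iv$l[-k] - iv$l[-1]
    off <- which(abs(dl - iv$d[-k]) > 1e-4 * table$radix)
    for (i in off) {
      note("d_l_consistency", i,
           sprintf("d = %g but l drop is %g", iv$d[i], dl[i]))
    }
  }
  if (length(bad) == 0) {
    return(data.frame(invariant = character(), interval = integer(),
                      message = character()))
  }
  do.call(rbind, bad)
}

assert_valid <- function(table) {
  rep <- validate_lifetable(table)
  if (nrow(rep) > 0) {
    stop("invalid life table: ",
         paste(sprintf("[%s] %s", rep$invariant, rep$message), collapse = "; "),
         call. = FALSE)
  }
  invisible(table)
}
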