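#' Discrete distribution of age at death
#'
#' [to_distribution()] turns an abridged life table into the grouped
#' distribution of length of life: mass \eqn{f_k = d_k/\ell_0} located at the
#' mean age at death within the interval, \eqn{c_k = x_k + a_k}. Life
#' expectancy at birth is the mean \eqn{\mu = \sum_k f_k c_k} of this
#' distribution, and every inequality and polarization indicator in the
#' package is a functional of it. [condition_on_age()] restricts the
#' distribution to deaths at or above a boundary age (age 15 separates adult
#' from infant mortality) and renormalizes; ages stay absolute, so the
#' conditional mean is the mean age at death of survivors to that age, not a
#' remaining-life expectancy.
#'
#' @param table a valid [abridged_lifetable()].
#' @return A `lifespan_dist`: list with `c` (mean ages at death, years), `f`
#'   (probability masses, summing to 1), `x` and `n` (interval start and
#'   width backing each mass point; `n` is `NA` for the open interval), `mu`
#'   (the mean, years), and `origin` (minimum age of the support: 0 for the
#'   total population, `min_age` after conditioning).
#' @export
#' @examples
#' lt <- abridged_lifetable(x = c(0, 5), n = c(5, NA),
#'                          d = c(50000, 50000), a = c(1, 55))
#' d <- to_distribution(lt)
#' d$mu  # 0.5 * 1 + 0.5 * 60
to_distribution <- function(table) {
  assert_valid(table)
  if (table$radix <= 0) stop("degenerate input: zero radix", call. = FALSE)
  iv <- table$intervals
  new_lifespan_dist(c = iv$x + iv$a, f = iv$d / table$radix,
                    x = iv$x, n = iv$n, origin = 0)
}

new_lifespan_dist <- function(c, f, x, n, origin) {
  structure(list(c = c, f = f, x = x, n = n,
                 mu = sum(f * c), origin = origin),
            class = "lifespan_dist")
}

#' @export
print.lifespan_dist <- function(x, ...) {
  cat(sprintf("Lifespan distribution: %d mass points, mu = %.3f, origin = %g\n",
              length(x$f), x$mu, x$origin))
  invisible(x)
}

#' @rdname to_distribution
#' @param min_age conditioning age in years; must coincide with an interval
#'   boundary of the table. `min_age = 0` is the identity.
#' @export
condition_on_age <- function(table, min_age = 15) {
  assert_valid(table)
  iv <- table$intervals
  if (min_age > 0 && !any(abs(iv$x - min_age) < 1e-9)) {
    below <- max(iv$x[iv$x < min_age], -Inf)
    above <- min(iv$x[iv$x > min_age], Inf)
    stop(sprintf(
      "no interval boundary at age %g (nearest boundaries: %g and %g)",
      min_age, below, above), call. = FALSE)
  }
  keep <- iv$x >= min_age - 1e-9
  mass <- sum(iv$d[keep])
  if (mass <= 0) {
    stop("degenerate input: no deaths at or above age ", min_age, call. = FALSE)
  }
  new_lifespan_dist(c = (iv$x + iv$a)[keep], f = iv$d[keep] / mass,
                    x = iv$x[keep], n = iv$n[keep], origin = min_age)
}

#' Remaining life expectancy at each interval start
#'
#' Reconstructs the life-table `e` column from deaths and average years
#' lived, via the standard person-years chain: for closed intervals
#' \eqn{L_k = n_k (l_k - d_k) + a_k d_k}, for the open terminal interval
#' \eqn{L_K = a_K d_K}; then \eqn{e_k = T_k / l_k} with
#' \eqn{T_k = \sum_{j \ge k} L_j}. Survivorship is taken from the table when
#' present and consistent, otherwise chained from the deaths. Under this
#' chain \eqn{e_0} equals the mean of the age-at-death distribution exactly.
#'
#' @param table a valid [abridged_lifetable()].
#' @return Data frame with columns `x`, `e` (reconstructed), and `e_table`
#'   (the table's own `e` column if it carried one, else `NA`), one row per
#'   interval start.
#' @export
remaining_life_expectancy <- function(table) {
  assert_valid(table)
  iv <- table$intervals
  k <- nrow(iv)
  l <- survivorship(table)
  if (any(l <= 0 & iv$d > 0)) {
    stop("inconsistent table: deaths in interval with zero survivors",
         call. = FALSE)
  }
  L <- ifelse(is.na(iv$n), iv$a * iv$d, iv$n * (l - iv$d) + iv$a * iv$d)
  T_k <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T_k / l, 0)
  data.frame(x = iv$x, e = e,
             e_table = if (!is.null(iv$e)) iv$e else NA_real_)
}
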