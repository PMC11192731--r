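#' Duclos-Esteban-Ray polarization of lifespan
#'
#' Identification-alienation polarization of the age-at-death distribution:
#' \deqn{DER(\alpha) = \sum_k \sum_j |c_k - c_j| \, f_k^{1+\alpha} f_j,}
#' where the exponent \eqn{1 + \alpha} on the first mass is the
#' identification weight and \eqn{\alpha \in [0.25, 1]} is the polarization
#' aversion parameter: the larger \eqn{\alpha}, the more the index rewards
#' concentration around poles and departs from plain inequality. At
#' \eqn{\alpha = 0} the double sum collapses to
#' \eqn{\sum\sum |c_k - c_j| f_k f_j}, i.e. exactly twice the absolute Gini
#' under these formulas; that case is exposed for testing only, the dataset
#' columns use \eqn{\alpha \in \{0.25, 0.5, 0.75, 1\}}.
#'
#' `rel_der` is the relative version, `der * mu^(alpha - 1)` with `mu` the
#' life expectancy. The masses are the probability masses \eqn{f_k =
#' d_k/\ell_0} of the grouped distribution, not per-year densities, so for
#' \eqn{\alpha > 0} the relative index is a convention rather than a
#' scale-invariant functional; the formulas are applied verbatim.
#'
#' @param dist a `lifespan_dist`.
#' @param alpha polarization aversion, non-negative real.
#' @return Years-scaled value for `der`; `rel_der` divides out the mean to
#'   the power `1 - alpha`.
#' @export
#' @examples
#' lt <- abridged_lifetable(x = c(0, 5), n = c(5, NA),
#'                          d = c(50000, 50000), a = c(1, 55))
#' der(to_distribution(lt), 1)
der <- function(dist, alpha) {
  check_dist(dist)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  as.numeric((dist$f^(1 + alpha)) %*% abs(outer(dist$c, dist$c, "-")) %*% dist$f)
}

#' @rdname der
#' @export
rel_der <- function(dist, alpha) {
  mu <- life_expectancy(dist)
  if (mu <= 0) stop("degenerate input: non-positive mean", call. = FALSE)
  der(dist, alpha) * mu^(alpha - 1)
}
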