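#' Lifespan inequality indicators
#'
#' Grouped-data inequality measures of the age-at-death distribution
#' \eqn{(c_k, f_k)}. Absolute measures (variance, standard deviation,
#' interquartile range, absolute Gini, life disparity) respond to
#' year differences; relative measures (Gini, the generalized entropy
#' family, Keyfitz's H) respond to proportional differences and are
#' invariant to rescaling every age at death by a common factor.
#'
#' @param dist a `lifespan_dist` from [to_distribution()] or
#'   [condition_on_age()].
#' @return A single numeric value; units are years for `life_expectancy`,
#'   `lifespan_stdev`, `lifespan_iqr`, `abs_gini`, years squared for
#'   `lifespan_variance`, dimensionless otherwise.
#' @name inequality
NULL

check_dist <- function(dist) {
  stopifnot(inherits(dist, "lifespan_dist"))
  if (abs(sum(dist$f) - 1) > 1e-8) {
    stop("distribution masses do not sum to 1", call. = FALSE)
  }
  invisible(dist)
}

#' @rdname inequality
#' @export
life_expectancy <- function(dist) {
  check_dist(dist)
  sum(dist$f * dist$c)
}

#' @rdname inequality
#' @export
lifespan_variance <- function(dist) {
  check_dist(dist)
  mu <- sum(dist$f * dist$c)
  sum(dist$f * (dist$c - mu)^2)
}

#' @rdname inequality
#' @export
lifespan_stdev <- function(dist) sqrt(lifespan_variance(dist))

#' Grouped quantiles and the interquartile range
#'
#' Inverts the grouped CDF assuming deaths are uniform within each closed
#' interval (linear interpolation); a quantile falling in the open-ended
#' terminal interval is returned as its mean age at death \eqn{x_K + a_K}.
#' `lifespan_iqr` is `quantile(0.75) - quantile(0.25)`.
#'
#' @inheritParams inequality
#' @param p probability in (0, 1).
#' @return Age in years.
#' @export
lifespan_quantile <- function(dist, p) {
  check_dist(dist)
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly within (0, 1)", call. = FALSE)
  }
  Fcum <- cumsum(dist$f)
  vapply(p, function(pp) {
    k <- which(Fcum >= pp - 1e-12)[1]
    if (is.na(dist$n[k])) return(dist$c[k])
    Fprev <- if (k == 1) 0 else Fcum[k - 1]
    dist$x[k] + dist$n[k] * (pp - Fprev) / dist$f[k]
  }, numeric(1))
}

#' @rdname lifespan_quantile
#' @export
lifespan_iqr <- function(dist) {
  q <- lifespan_quantile(dist, c(0.25, 0.75))
  q[2] - q[1]
}

#' Gini index of lifespan
#'
#' The grouped Gini coefficient
#' \deqn{G = \frac{1}{2\mu} \sum_k \sum_j |c_k - c_j| f_k f_j,}
#' computed as the full pairwise double sum (the number of age groups is
#' small, so the quadratic form is exact and auditable). `abs_gini` is the
#' absolute version \eqn{AG = \mu G}, in years.
#'
#' @inheritParams inequality
#' @export
gini <- function(dist) {
  check_dist(dist)
  mu <- sum(dist$f * dist$c)
  if (mu <= 0) stop("degenerate input: non-positive mean", call. = FALSE)
  pairwise_abs_mean(dist) / (2 * mu)
}

#' @rdname gini
#' @export
abs_gini <- function(dist) {
  check_dist(dist)
  pairwise_abs_mean(dist) / 2
}

pairwise_abs_mean <- function(dist) {
  # sum_k sum_j |c_k - c_j| f_k f_j over all ordered pairs
  as.numeric(dist$f %*% abs(outer(dist$c, dist$c, "-")) %*% dist$f)
}

#' Generalized entropy family
#'
#' \deqn{GE(\theta) = \frac{1}{\theta(\theta - 1)}
#'   \left( \sum_k f_k (c_k/\mu)^\theta - 1 \right), \quad \theta \ne 0, 1,}
#' with the limiting cases Theil's T at \eqn{\theta = 1},
#' \eqn{T = \sum_k f_k (c_k/\mu) \log(c_k/\mu)}, and the mean log deviation
#' at \eqn{\theta = 0}, \eqn{MLD = \sum_k f_k \log(\mu/c_k)}. Larger
#' \eqn{\theta} puts more weight on differences among the long-lived; the
#' MLD is most sensitive to infant mortality. `ge2` (\eqn{\theta = 2})
#' equals \eqn{\sigma^2 / 2\mu^2} identically.
#'
#' @inheritParams inequality
#' @param theta sensitivity parameter, any real; values at or below 1
#'   require every age at death with positive mass to be strictly positive.
#' @export
ge_index <- function(dist, theta) {
  check_dist(dist)
  mu <- sum(dist$f * dist$c)
  if (mu <= 0) stop("degenerate input: non-positive mean", call. = FALSE)
  pos <- dist$f > 0
  c_k <- dist$c[pos]
  f_k <- dist$f[pos]
  if (theta <= 1 && any(c_k <= 0)) {
    stop("ge_index with theta <= 1 needs all ages at death > 0 ",
         "(the 0-1 interval must have a > 0)", call. = FALSE)
  }
  r <- c_k / mu
  if (abs(theta - 1) < 1e-12) {
    sum(f_k * r * log(r))
  } else if (abs(theta) < 1e-12) {
    sum(f_k * log(1 / r))
  } else {
    (sum(f_k * r^theta) - 1) / (theta * (theta - 1))
  }
}

#' @rdname ge_index
#' @export
theil <- function(dist) ge_index(dist, 1)

#' @rdname ge_index
#' @export
mld <- function(dist) ge_index(dist, 0)

#' @rdname ge_index
#' @export
ge2 <- function(dist) ge_index(dist, 2)

#' Life disparity (e-dagger) and Keyfitz's entropy
#'
#' Life disparity is the average remaining life expectancy at the moment of
#' death — the life years lost to death:
#' \deqn{e^\dagger = \sum_x f_x \left[ e_x + \frac{a_x}{n}
#'   (e_{x+1} - e_x) \right],}
#' summed over age intervals, with \eqn{e_x} the remaining life expectancy
#' at the interval start (taken from the table or reconstructed by
#' [remaining_life_expectancy()]). For the open-ended terminal interval the
#' successor term \eqn{e_{K+1}} is taken as 0 and `n` as the table's modal
#' closed-interval width, giving a contribution
#' \eqn{f_K \, e_K \, (1 - a_K/n)} floored at zero; the terminal mass is
#' small for realistic tables, and this closure is documented rather than
#' silent. Keyfitz's H is the relative companion \eqn{H = e^\dagger / \mu}:
#' the elasticity of life expectancy to a proportional change in the force
#' of mortality at all ages.
#'
#' @param table a valid [abridged_lifetable()].
#' @param min_age restrict to deaths at or above this boundary age
#'   (renormalized over survivors); 0 gives the whole-population value.
#' @return Years for `life_disparity`; dimensionless for `keyfitz_h`.
#' @export
life_disparity <- function(table, min_age = 0) {
  assert_valid(table)
  iv <- table$intervals
  k <- nrow(iv)
  e <- remaining_life_expectancy(table)$e
  f <- iv$d / table$radix
  n_mode <- modal_width(iv$n)
  e_next <- c(e[-1], 0)
  n_eff <- ifelse(is.na(iv$n), n_mode, iv$n)
  contrib <- f * (e + (iv$a / n_eff) * (e_next - e))
  contrib[k] <- max(0, contrib[k])
  if (min_age > 0) {
    keep <- iv$x >= min_age - 1e-9
    mass <- sum(f[keep])
    if (mass <= 0) stop("no deaths at or above age ", min_age, call. = FALSE)
    return(sum(contrib[keep]) / mass)
  }
  sum(contrib)
}

modal_width <- function(n) {
  n <- n[!is.na(n)]
  if (length(n) == 0) return(5)
  tab <- table(n)
  as.numeric(names(tab)[which.max(tab)])
}

#' @rdname life_disparity
#' @export
keyfitz_h <- function(table, min_age = 0) {
  mu <- if (min_age > 0) condition_on_age(table, min_age)$mu
        else to_distribution(table)$mu
  if (mu <= 0) stop("degenerate input: zero life expectancy", call. = FALSE)
  life_disparity(table, min_age) / mu
}
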