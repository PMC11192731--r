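#' Siler mortality model
#'
#' Five-parameter force of mortality
#' \deqn{h(t) = a_1 e^{-b_1 t} + a_2 + a_3 e^{b_3 t},}
#' the sum of a declining infant component, a constant background hazard,
#' and an exponentially rising (Gompertz) senescent component. This is the
#' simplest hazard that reproduces the bimodal age-at-death density of real
#' populations: an infant-mortality spike falling steeply to adolescence
#' and an adult bell-shaped mode. An optional Gaussian hazard bump
#' (`bump_height` at `bump_age`, width `bump_sd`) adds excess mid-adult
#' mortality of the kind seen in HIV-era profiles; its cumulative hazard is
#' analytic, so survival stays closed-form.
#'
#' @param a1 infant hazard level (per year, > 0).
#' @param b1 infant hazard decay rate (per year, > 0).
#' @param a2 age-independent background hazard (per year, >= 0).
#' @param a3 senescent hazard level at age 0 (per year, > 0).
#' @param b3 senescent hazard growth rate (per year, > 0). The adult modal
#'   age at death is approximately \eqn{\log(b_3/a_3)/b_3}.
#' @param max_age truncation age opening the terminal interval (years);
#'   survival there must be below 5\% for the open-interval mass to be
#'   acceptable.
#' @param bump_height,bump_age,bump_sd optional Gaussian excess-hazard bump
#'   (per year, years, years); `bump_height = 0` disables it.
#' @return A list of class `siler_params`.
#' @export
siler_params <- function(a1, b1, a2, a3, b3, max_age = 100,
                         bump_height = 0, bump_age = 35, bump_sd = 8) {
  stopifnot(a1 > 0, b1 > 0, a2 >= 0, a3 > 0, b3 > 0, max_age > 15,
            bump_height >= 0, bump_sd > 0)
  structure(list(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3,
                 max_age = max_age, bump_height = bump_height,
                 bump_age = bump_age, bump_sd = bump_sd),
            class = "siler_params")
}

#' @rdname siler_params
#' @param params a `siler_params` object.
#' @param t age(s) in years.
#' @export
siler_hazard <- function(params, t) {
  with(params, a1 * exp(-b1 * t) + a2 + a3 * exp(b3 * t) +
         bump_height * exp(-(t - bump_age)^2 / (2 * bump_sd^2)))
}

#' @rdname siler_params
#' @export
siler_cumhaz <- function(params, t) {
  with(params, {
    h <- a1 / b1 * (1 - exp(-b1 * t)) + a2 * t + a3 / b3 * (exp(b3 * t) - 1)
    if (bump_height > 0) {
      h <- h + bump_height * bump_sd * sqrt(2 * pi) *
        (stats::pnorm((t - bump_age) / bump_sd) -
           stats::pnorm(-bump_age / bump_sd))
    }
    h
  })
}

#' @rdname siler_params
#' @export
siler_survival <- function(params, t) exp(-siler_cumhaz(params, t))

#' Documented Siler presets
#'
#' Three mortality regimes: `modern` (low infant mortality, adult deaths
#' concentrated around a mode near 80), `historical` (an order of magnitude
#' more infant mortality, higher background hazard, wider adult spread with
#' a mode near the late 70s), and `hiv_like` (the modern schedule plus a
#' Gaussian excess-hazard bump centred at age 35, echoing the atypical
#' mid-adult mortality of HIV-affected populations).
#'
#' @param name preset id; with no argument, the catalogue of all presets.
#' @return A `siler_params` object, or a named list of them.
#' @export
siler_preset <- function(name) {
  catalogue <- list(
    modern = siler_params(a1 = 0.03, b1 = 1.2, a2 = 4e-4,
                          a3 = 5e-5, b3 = 0.095),
    historical = siler_params(a1 = 0.25, b1 = 1.0, a2 = 8e-3,
                              a3 = 3e-4, b3 = 0.075),
    hiv_like = siler_params(a1 = 0.03, b1 = 1.2, a2 = 4e-4,
                            a3 = 5e-5, b3 = 0.095,
                            bump_height = 0.012, bump_age = 35, bump_sd = 8)
  )
  if (missing(name)) return(catalogue)
  if (!name %in% names(catalogue)) {
    stop("unknown preset: ", name, " (available: ",
         paste(names(catalogue), collapse = ", "), ")", call. = FALSE)
  }
  catalogue[[name]]
}

#' Standard abridged age layout
#'
#' Interval starts 0, 1, 5, 10, ..., `max_age`, i.e. the split first
#' five years (0-1, 1-4) followed by five-year groups and an open-ended
#' terminal interval.
#'
#' @param max_age start of the open-ended interval (multiple of 5).
#' @return Data frame with columns `x` and `n` (`NA` for the open interval).
#' @export
standard_abridged_layout <- function(max_age = 100) {
  x <- c(0, 1, seq(5, max_age, by = 5))
  n <- c(diff(x), NA)
  data.frame(x = x, n = n)
}

#' Generate an abridged life table from a Siler hazard
#'
#' Deterministic construction: survivorship at the layout boundaries is the
#' closed-form Siler survival, deaths are its differences scaled by the
#' radix, and the average years lived in each interval by those dying in it
#' come from the exact person-years integral
#' \eqn{a_k = (\int_{x_k}^{x_{k+1}} S - n_k S(x_{k+1})) / (S(x_k) -
#' S(x_{k+1}))} computed by adaptive quadrature; the open interval gets the
#' conditional mean remaining lifetime beyond its start. Remaining life
#' expectancy is chained and stored on the table.
#'
#' @param params a [siler_params()] specification.
#' @param layout abridged boundaries as from [standard_abridged_layout()];
#'   defaults to the standard layout truncated at `params$max_age`.
#' @param radix synthetic cohort size, default 100,000.
#' @param meta metadata list passed through to the table.
#' @return A valid [abridged_lifetable()] carrying `l` and `e` columns.
#' @export
make_lifetable <- function(params, layout = standard_abridged_layout(params$max_age),
                           radix = 1e5, meta = list()) {
  stopifnot(inherits(params, "siler_params"))
  k <- nrow(layout)
  if (!is.na(layout$n[k])) stop("layout must end with an open interval",
                                call. = FALSE)
  s_open <- siler_survival(params, layout$x[k])
  if (s_open >= 0.05) {
    stop(sprintf(
      "survival at age %g is %.3f >= 0.05: open-interval mass too large",
      layout$x[k], s_open), call. = FALSE)
  }
  bounds <- c(layout$x, Inf)
  S <- c(siler_survival(params, layout$x), 0)
  l <- radix * S[seq_len(k)]
  d <- radix * (S[seq_len(k)] - S[seq_len(k) + 1])
  surv <- function(t) siler_survival(params, t)
  a <- vapply(seq_len(k), function(i) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    dS <- S[i] - S[i + 1]
    if (dS <= .Machine$double.eps * 10) {
      return(if (is.finite(hi)) (hi - lo) / 2 else 1)
    }
    int <- stats::integrate(surv, lo, hi, rel.tol = 1e-10,
                            abs.tol = 1e-13)$value
    if (is.finite(hi)) {
      (int - (hi - lo) * S[i + 1]) / dS
    } else {
      int / dS  # conditional mean years lived beyond the open boundary
    }
  }, numeric(1))
  lt <- abridged_lifetable(x = layout$x, n = layout$n, d = d, a = a, l = l,
                           radix = radix, meta = meta)
  lt$intervals$e <- remaining_life_expectancy(lt)$e
  lt
}

#' Exact ages at death from the Siler model
#'
#' i.i.d. draws by inverse-transform sampling of the Siler survival
#' function: \eqn{t} solves \eqn{H(t) = -\log u} for uniform \eqn{u},
#' inverted by vectorized bisection on the (monotone) cumulative hazard.
#' Used as the individual-level Monte-Carlo oracle for the grouped
#' indicators.
#'
#' @inheritParams make_lifetable
#' @param n number of draws.
#' @param seed integer seed; draws are reproducible given the seed.
#' @return Numeric vector of `n` exact ages at death.
#' @export
micro_sample <- function(params, n, seed) {
  stopifnot(n >= 1)
  if (!missing(seed)) set.seed(seed)
  u <- stats::runif(n)
  target <- -log(u)
  lo <- rep(0, n)
  hi <- rep(params$max_age + 60, n)
  # expand upper bound until it dominates every target
  while (siler_cumhaz(params, hi[1]) < max(target)) hi <- hi * 2
  for (i in 1:64) {
    mid <- (lo + hi) / 2
    below <- siler_cumhaz(params, mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Comparative-statics scenario pairs
#'
#' Deterministic pairs of life tables illustrating how inequality and
#' polarization can move in opposite directions:
#' \describe{
#'   \item{`adult_concentration`}{both tables identical below age 65; the
#'     second concentrates adult deaths toward the modal old-age interval
#'     by a mass-preserving transfer within ages 65+. Inequality (MLD)
#'     falls while polarization rises: the old-age pole becomes more
#'     representative.}
#'   \item{`infant_stagnation`}{the second table shifts adult mortality to
#'     older ages (progress for adults) while infant deaths over ages 0-5
#'     are held fixed; deaths are renormalized to the radix. Both the
#'     spread and the distance between the infant and adult poles grow, so
#'     inequality and polarization rise together.}
#' }
#'
#' @param name `"adult_concentration"` or `"infant_stagnation"`.
#' @param seed accepted for interface uniformity; construction is
#'   deterministic and ignores it.
#' @param radix synthetic cohort size.
#' @return List of two [abridged_lifetable()]s, `before` and `after`.
#' @export
make_scenario_pair <- function(name, seed = NULL, radix = 1e5) {
  if (!name %in% c("adult_concentration", "infant_stagnation")) {
    stop("unknown preset: ", name, call. = FALSE)
  }
  if (name == "adult_concentration") {
    before <- make_lifetable(siler_preset("modern"), radix = radix,
                             meta = list(country = "scenario", sex = "both"))
    iv <- before$intervals
    block <- iv$x >= 65
    d2 <- iv$d
    # interval holding the block's death-weighted mean age: the adult mode
    cbar <- sum(iv$d[block] * (iv$x + iv$a)[block]) / sum(iv$d[block])
    mode_k <- which(block & iv$x <= cbar &
                      (is.na(iv$n) | iv$x + iv$n > cbar))
    lambda <- 0.5
    moved <- lambda * iv$d[block]
    d2[block] <- iv$d[block] - moved
    d2[mode_k] <- d2[mode_k] + sum(moved)
    after <- rebuild_from_da(iv$x, iv$n, d2, iv$a, radix,
                             meta = before$meta)
    list(before = before, after = after)
  } else {
    p1 <- siler_preset("historical")
    before <- make_lifetable(p1, radix = radix,
                             meta = list(country = "scenario", sex = "both"))
    # adult progress: senescent deaths pushed ~8 years older, background halved
    p2 <- siler_params(a1 = p1$a1, b1 = p1$b1, a2 = p1$a2 / 2,
                       a3 = p1$a3 * exp(-p1$b3 * 8), b3 = p1$b3,
                       max_age = p1$max_age)
    shifted <- make_lifetable(p2, radix = radix, meta = before$meta)
    iv1 <- before$intervals
    iv2 <- shifted$intervals
    infant <- iv1$x < 5
    d2 <- iv2$d
    a2 <- iv2$a
    d2[infant] <- iv1$d[infant]  # infant mortality stagnates
    a2[infant] <- iv1$a[infant]
    d2[!infant] <- d2[!infant] * (radix - sum(d2[infant])) / sum(iv2$d[!infant])
    after <- rebuild_from_da(iv1$x, iv1$n, d2, a2, radix, meta = before$meta)
    list(before = before, after = after)
  }
}

# rebuild a consistent table (l, e recomputed) from deaths and a-values
rebuild_from_da <- function(x, n, d, a, radix, meta = list()) {
  d <- d * radix / sum(d)
  lt <- abridged_lifetable(x = x, n = n, d = d, a = a, radix = radix,
                           meta = meta)
  lt$intervals$l <- survivorship(lt)
  lt$intervals$e <- remaining_life_expectancy(lt)$e
  lt
}

#' Life table with a purely atomic age-at-death distribution
#'
#' Builds the smallest valid abridged table whose distribution of age at
#' death is a given set of atoms — the discrete analogue of a population of
#' named individuals. Interval boundaries are placed so the layout is
#' contiguous, has a boundary at 15, and ends open; each atom's interval
#' gets the matching `a`. Handy for worked examples and exact oracles.
#'
#' @param ages strictly increasing atom locations (years, each below 105).
#' @param masses probability masses, summing to 1.
#' @param radix synthetic cohort size.
#' @return A valid [abridged_lifetable()].
#' @export
#' @examples
#' # two people: one dies at 6, one at 60
#' to_distribution(atom_table(c(6, 60), c(0.5, 0.5)))$mu
atom_table <- function(ages, masses, radix = 1e5) {
  if (length(masses) == 1) masses <- rep(masses, length(ages))
  stopifnot(length(ages) == length(masses), all(diff(ages) > 0),
            all(ages < 105), abs(sum(masses) - 1) < 1e-9)
  bounds <- sort(unique(c(0, 5, 15, floor(ages / 5) * 5, 105)))
  x <- bounds
  n <- c(diff(bounds), NA)
  d <- rep(0, length(x))
  a <- ifelse(is.na(n), 1, n / 2)
  for (i in seq_along(ages)) {
    k <- findInterval(ages[i], x)
    d[k] <- d[k] + masses[i] * radix
    a[k] <- ages[i] - x[k]
  }
  abridged_lifetable(x = x, n = n, d = d, a = a, radix = radix,
                     meta = list(country = "atoms", sex = "both"))
}

#' Bin exact ages at death into an abridged life table
#'
#' Groups a vector of individual ages at death (e.g. from
#' [micro_sample()]) into an abridged layout, with each interval's `a`
#' set to the within-interval mean age minus the interval start. The
#' resulting table's grouped indicators are the binned Monte-Carlo
#' estimates of the continuous model's indicators.
#'
#' @param ages numeric vector of exact ages at death.
#' @param layout abridged boundaries as from [standard_abridged_layout()].
#' @return An [abridged_lifetable()] with radix `length(ages)`.
#' @export
bin_sample_to_table <- function(ages, layout = standard_abridged_layout()) {
  k <- nrow(layout)
  idx <- findInterval(ages, layout$x)
  d <- tabulate(idx, nbins = k)
  a <- vapply(seq_len(k), function(i) {
    if (d[i] == 0) return(if (is.na(layout$n[i])) 1 else layout$n[i] / 2)
    mean(ages[idx == i]) - layout$x[i]
  }, numeric(1))
  abridged_lifetable(x = layout$x, n = layout$n, d = d, a = a,
                     meta = list(country = "binned", sex = "both"))
}

#' Random Siler parameter draws within documented ranges
#'
#' Samples plausible mortality regimes for property tests: infant level
#' `a1` in \[0.01, 0.25\], decay `b1` in \[0.8, 2\], background `a2` in
#' \[1e-4, 3e-3\], Gompertz slope `b3` in \[0.09, 0.13\], and an adult
#' modal age in \[68, 85\] from which the senescent level is solved as
#' \eqn{a_3 = b_3 e^{-b_3 M}}. These ranges keep survival past 100 under
#' 5\%, so every draw yields a valid standard-layout table.
#'
#' @param n_draws number of parameter sets.
#' @param seed integer seed.
#' @return List of `siler_params`.
#' @export
random_siler_params <- function(n_draws, seed) {
  if (!missing(seed)) set.seed(seed)
  lapply(seq_len(n_draws), function(i) {
    b3 <- stats::runif(1, 0.09, 0.13)
    mode_age <- stats::runif(1, 68, 85)
    siler_params(
      a1 = stats::runif(1, 0.01, 0.25),
      b1 = stats::runif(1, 0.8, 2),
      a2 = stats::runif(1, 1e-4, 3e-3),
      a3 = b3 * exp(-b3 * mode_age),
      b3 = b3)
  })
}
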