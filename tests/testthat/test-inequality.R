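test_that("variance and stdev match hand computations and the algebraic oracle", {
  expect_equal(lifespan_variance(two_atom_dist(6, 60)), 729)
  expect_equal(lifespan_stdev(two_atom_dist(6, 60)), 27)
  one <- to_distribution(atom_table(70, 1))
  expect_equal(lifespan_variance(one), 0)
  for (lt in random_tables(5, seed = 3)) {
    d <- to_distribution(lt)
    oracle <- sum(d$f * d$c^2) - sum(d$f * d$c)^2
    expect_equal(lifespan_variance(d), oracle, tolerance = 1e-10)
  }
})

test_that("grouped quantiles invert the piecewise-linear CDF", {
  # all deaths uniform over [0,10): median 5, iqr 5
  unif <- abridged_lifetable(x = c(0, 10, 15), n = c(10, 5, NA),
                             d = c(1e5, 0, 0), a = c(5, 2.5, 1))
  du <- to_distribution(unif)
  expect_equal(lifespan_quantile(du, 0.5), 5)
  expect_equal(lifespan_quantile(du, 0.25), 2.5)
  expect_equal(lifespan_iqr(du), 5)
  # iqr = width/2 whenever a single interval holds all deaths
  expect_equal(lifespan_iqr(to_distribution(
    abridged_lifetable(x = c(0, 15, 19), n = c(15, 4, NA),
                       d = c(0, 1e5, 0), a = c(7, 2, 1)))), 2)
  # four equal-mass intervals: q1 = 5, q3 = 15
  four <- abridged_lifetable(x = c(0, 5, 10, 15, 20), n = c(5, 5, 5, 5, NA),
                             d = c(25e3, 25e3, 25e3, 25e3, 0),
                             a = c(2.5, 2.5, 2.5, 2.5, 1))
  expect_equal(lifespan_quantile(to_distribution(four), 0.25), 5)
  expect_equal(lifespan_quantile(to_distribution(four), 0.75), 15)
  expect_equal(lifespan_iqr(to_distribution(four)), 10)
  expect_error(lifespan_quantile(du, 1.2), "within")
})

test_that("gini double sum matches hand values, the sorted-form oracle, and scale invariance", {
  dA <- two_atom_dist(6, 60)
  expect_equal(gini(dA), 27 / 66, tolerance = 1e-12)
  expect_equal(abs_gini(dA), 13.5, tolerance = 1e-12)
  expect_equal(gini(to_distribution(atom_table(70, 1))), 0)
  # Country A/B: rescaling every age leaves the relative index unchanged
  expect_equal(gini(two_atom_dist(7, 70)), gini(dA), tolerance = 1e-15)

  # sorted O(K log K) form as independent oracle on random tables
  for (lt in random_tables(5, seed = 21)) {
    d <- to_distribution(lt)
    ord <- order(d$c)
    cs <- d$c[ord]; fs <- d$f[ord]
    Fm <- cumsum(fs) - fs / 2
    oracle <- 2 * sum(fs * (cs - sum(fs * cs)) * Fm) / sum(fs * cs)
    expect_equal(gini(d), oracle, tolerance = 1e-10)
    expect_equal(abs_gini(d), gini(d) * life_expectancy(d), tolerance = 1e-12)
  }
})

test_that("GE family: hand values, limiting cases, and the GE(2) identity", {
  dA <- two_atom_dist(6, 60)
  expect_equal(mld(dA), 0.5 * log(33 / 6) + 0.5 * log(33 / 60),
               tolerance = 1e-12)
  one <- to_distribution(atom_table(70, 1))
  for (th in c(-1, 0, 0.5, 1, 2, 3)) expect_equal(ge_index(one, th), 0)
  for (lt in random_tables(5, seed = 13)) {
    d <- to_distribution(lt)
    expect_lt(abs(ge_index(d, 1 + 1e-6) - theil(d)), 1e-5)
    expect_lt(abs(ge_index(d, 1 - 1e-6) - theil(d)), 1e-5)
    expect_lt(abs(ge_index(d, 1e-6) - mld(d)), 1e-5)
    mu <- life_expectancy(d)
    expect_equal(ge2(d), lifespan_variance(d) / (2 * mu^2), tolerance = 1e-10)
  }
  # zero age at death with theta <= 1 is a domain error
  zero <- to_distribution(
    abridged_lifetable(x = c(0, 5, 15), n = c(5, 10, NA),
                       d = c(5e4, 0, 5e4), a = c(0, 5, 3)))
  expect_error(mld(zero), "a > 0")
})

test_that("life disparity: degenerate cases, bound, and the continuous oracle", {
  # deaths at the very start of [80,85): no remaining life at death
  lt0 <- abridged_lifetable(x = c(0, 5, 15, 80, 85), n = c(5, 10, 65, 5, NA),
                            d = c(0, 0, 0, 1e5, 0), a = c(2, 5, 30, 0, 1))
  expect_equal(life_disparity(lt0), 0)
  expect_equal(keyfitz_h(lt0), 0)

  # perfect equality: everyone dies in one interval at the same a
  eq <- atom_table(72, 1)
  a_k <- eq$intervals$a[eq$intervals$d > 0]
  expect_lte(life_disparity(eq), a_k + 1e-12)

  # continuous-model oracle: average remaining life expectancy at death
  p <- siler_preset("modern")
  e_cont <- function(t) {
    vapply(t, function(tt) {
      stats::integrate(function(u) siler_survival(p, u), tt, Inf,
                       rel.tol = 1e-9)$value / siler_survival(p, tt)
    }, numeric(1))
  }
  edag_cont <- stats::integrate(
    function(t) siler_hazard(p, t) * siler_survival(p, t) * e_cont(t),
    0, 120, rel.tol = 1e-7)$value
  edag_grouped <- life_disparity(make_lifetable(p))
  expect_lt(abs(edag_grouped - edag_cont) / edag_cont, 0.02)
})

test_that("Keyfitz H is the disparity/expectancy ratio, inside (0,1) for presets", {
  for (nm in c("modern", "historical", "hiv_like")) {
    lt <- make_lifetable(siler_preset(nm))
    mu <- to_distribution(lt)$mu
    expect_equal(keyfitz_h(lt) * mu, life_disparity(lt), tolerance = 1e-12)
    expect_gt(keyfitz_h(lt), 0)
    expect_lt(keyfitz_h(lt), 1)
  }
})

test_that("scale and translation invariance classes hold across the battery", {
  lt <- make_lifetable(siler_preset("historical"))
  d <- to_distribution(lt)
  lam <- 3
  ds <- to_distribution(scale_table(lt, lam))
  expect_equal(gini(ds), gini(d), tolerance = 1e-10)
  expect_equal(theil(ds), theil(d), tolerance = 1e-10)
  expect_equal(mld(ds), mld(d), tolerance = 1e-10)
  expect_equal(ge_index(ds, 0.5), ge_index(d, 0.5), tolerance = 1e-10)
  expect_equal(keyfitz_h(scale_table(lt, lam)), keyfitz_h(lt),
               tolerance = 1e-8)
  expect_equal(life_expectancy(ds), lam * life_expectancy(d),
               tolerance = 1e-10)
  expect_equal(abs_gini(ds), lam * abs_gini(d), tolerance = 1e-10)
  expect_equal(lifespan_stdev(ds), lam * lifespan_stdev(d), tolerance = 1e-10)
  expect_equal(lifespan_iqr(ds), lam * lifespan_iqr(d), tolerance = 1e-10)
  expect_equal(lifespan_variance(ds), lam^2 * lifespan_variance(d),
               tolerance = 1e-10)
  expect_equal(life_disparity(scale_table(lt, lam)), lam * life_disparity(lt),
               tolerance = 1e-8)

  delta <- 10
  dt <- to_distribution(shift_table(lt, delta))
  expect_equal(lifespan_variance(dt), lifespan_variance(d), tolerance = 1e-10)
  expect_equal(lifespan_stdev(dt), lifespan_stdev(d), tolerance = 1e-10)
  expect_equal(lifespan_iqr(dt), lifespan_iqr(d), tolerance = 1e-10)
  expect_equal(abs_gini(dt), abs_gini(d), tolerance = 1e-10)
})

test_that("grouped indices equal individual-level textbook formulas on expanded cohorts", {
  # small tables, integer deaths: expand to one age per individual
  set.seed(77)
  for (rep_i in 1:3) {
    ages <- sort(sample(seq(2, 92, by = 10), 5)) + stats::runif(5, 0, 3)
    masses <- as.numeric(stats::rmultinom(1, 2000, prob = stats::runif(5, 0.5, 2)))
    lt <- atom_table(ages, masses / sum(masses), radix = sum(masses))
    lt$intervals$d <- round(lt$intervals$d)
    lt$radix <- sum(lt$intervals$d)
    d <- to_distribution(lt)
    people <- rep(d$c, round(d$f * lt$radix))
    n <- length(people)
    mu <- mean(people)
    expect_equal(life_expectancy(d), mu, tolerance = 1e-12)
    expect_equal(lifespan_variance(d), mean((people - mu)^2), tolerance = 1e-10)
    gini_ind <- sum(abs(outer(people, people, "-"))) / (2 * n^2 * mu)
    expect_equal(gini(d), gini_ind, tolerance = 1e-10)
    expect_equal(theil(d), mean((people / mu) * log(people / mu)),
                 tolerance = 1e-10)
    expect_equal(mld(d), mean(log(mu / people)), tolerance = 1e-10)
    expect_equal(ge_index(d, 2), (mean((people / mu)^2) - 1) / 2,
                 tolerance = 1e-10)
  }
})

test_that("a mean-preserving spread never decreases variance, gini, or GE", {
  # atoms at 10, 20, 30; shift mass delta from the centre to both ends
  base_masses <- c(0.2, 0.6, 0.2)
  spread <- function(delta) {
    to_distribution(atom_table(c(10, 20, 30),
                               base_masses + c(delta, -2 * delta, delta)))
  }
  d0 <- spread(0)
  for (delta in c(0.05, 0.1, 0.2)) {
    d1 <- spread(delta)
    expect_equal(life_expectancy(d1), life_expectancy(d0), tolerance = 1e-12)
    expect_gte(lifespan_variance(d1), lifespan_variance(d0))
    expect_gte(gini(d1), gini(d0))
    for (th in c(0, 0.5, 1, 2)) {
      expect_gte(ge_index(d1, th), ge_index(d0, th))
    }
  }
})
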