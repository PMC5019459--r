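test_that("isotropic direction sampling is uniform on the sphere", {
  d <- sample_isotropic(2e5, seed = 601)
  expect_equal(max(abs(rowSums(d^2) - 1)), 0, tolerance = 1e-9)
  expect_lt(abs(mean(d[, 3])), 4 / sqrt(3 * 2e5)) # sd(w)=1/sqrt(3)
  # octant occupancies within binomial 4 sigma of 1/8
  oct <- table(paste0(d[, 1] > 0, d[, 2] > 0, d[, 3] > 0))
  expect_equal(length(oct), 8)
  p <- 1 / 8
  bound <- 4 * sqrt(p * (1 - p) * 2e5)
  expect_true(all(abs(oct - 2e5 * p) < bound))
})

test_that("in-organ source sampling is uniform, contained and reproducible", {
  fx <- make_fixture("one_sphere")
  pts <- sample_in_organ(fx, "Sphere", 5e4, seed = 602)
  r <- (fx$organs$volume_cm3[1] * 3 / (4 * pi))^(1 / 3)
  expect_true(all(rowSums(pts^2) <= r^2 + 1e-9))
  # mean within 4 sigma of the center; sd of a coordinate is r/sqrt(5) * ...
  sdc <- sqrt(mean(pts[, 1]^2))
  expect_lt(max(abs(colMeans(pts))), 4 * sdc / sqrt(5e4))
  # chi-square uniformity over octants at alpha = 0.01
  oct <- table(cut(atan2(pts[, 2], pts[, 1]), breaks = seq(-pi, pi, length.out = 9)))
  expect_gt(stats::chisq.test(oct)$p.value, 0.01)
  pts2 <- sample_in_organ(fx, "Sphere", 5e4, seed = 602)
  expect_identical(pts, pts2)
})

test_that("Compton sampling obeys kinematics and the Klein-Nishina mean", {
  E <- 0.5
  s <- sample_compton(E, 2e5, seed = 603)
  k <- E / 0.5109989
  expect_true(all(s$energy_out_MeV >= E / (1 + 2 * k) - 1e-12))
  expect_true(all(s$energy_out_MeV <= E + 1e-12))
  expect_true(all(abs(s$cos_theta) <= 1 + 1e-12))
  # independent quadrature of the KN density over the scattered fraction
  xmin <- 1 / (1 + 2 * k)
  g <- function(x) {
    ct <- 1 + 1 / k - 1 / (k * x)
    x + 1 / x - 1 + ct^2
  }
  num <- stats::integrate(function(x) x * g(x), xmin, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(g, xmin, 1, rel.tol = 1e-10)$value
  expect_lt(abs(mean(s$energy_out_MeV) / E - num / den), 0.005 * num / den)
  # Thomson limit: symmetric fore/aft angular distribution
  s0 <- sample_compton(0.002, 1e5, seed = 604)
  expect_lt(abs(mean(s0$cos_theta)), 0.02)
})

test_that("energy is conserved exactly and deposits never exceed the emission", {
  fx <- make_fixture("one_sphere")
  tl <- simulate_photons(fx, "Sphere", 0.3, n_histories = 5e4, seed = 605)
  g <- glance(tl)
  expect_lt(g$balance_rel_error, 1e-6)
  saf <- compute_saf(tl, fx)
  m <- fx$organs$mass_kg
  expect_true(all(saf$saf_kg <= 1 / m + 1e-12))
  # sum of absorbed fractions equals one minus the escape fraction
  af <- sum(tl$dep[rownames(tl$dep) != "(escaped)", ]) / (5e4 * 0.3)
  esc <- sum(tl$dep["(escaped)", ]) / (5e4 * 0.3)
  expect_equal(af + esc, 1, tolerance = 1e-9)
})

test_that("Woodcock tracking matches the independent ray tracer on sphere fixtures", {
  fx <- make_fixture("one_sphere")
  for (E in c(0.03, 0.3)) {
    tw <- compute_saf(simulate_photons(fx, "Sphere", E, n_histories = 1e5,
                                       seed = 606), fx)
    tr <- compute_saf(ray_trace_spheres(fx, "Sphere", E, n_histories = 1e5,
                                        seed = 607), fx)
    dv <- abs(saf_of(tw, "Sphere") - saf_of(tr, "Sphere"))
    cv <- sqrt(cv_of(tw, "Sphere")^2 + cv_of(tr, "Sphere")^2) / 100
    expect_lt(dv, 3 * cv * saf_of(tw, "Sphere"))
  }
  fx2 <- make_fixture("two_sphere")
  tw <- compute_saf(simulate_photons(fx2, "Source sphere", 0.1,
                                     n_histories = 2e5, seed = 608), fx2)
  tr <- compute_saf(ray_trace_spheres(fx2, "Source sphere", 0.1,
                                      n_histories = 2e5, seed = 609), fx2)
  for (tgt in c("Source sphere", "Target sphere")) {
    dv <- abs(saf_of(tw, tgt) - saf_of(tr, tgt))
    cv <- sqrt(cv_of(tw, tgt)^2 + cv_of(tr, tgt)^2) / 100
    expect_lt(dv, 3 * cv * saf_of(tw, tgt))
  }
})

test_that("batch CV scales as one over the square root of the history count", {
  fx <- make_fixture("two_sphere")
  cv_n <- function(n, seed) {
    s <- compute_saf(simulate_photons(fx, "Source sphere", 0.2,
                                      n_histories = n, seed = seed), fx)
    cv_of(s, "Target sphere")
  }
  # average a few seed replicates to stabilise the CV-of-CV
  r1 <- mean(sapply(1:3, function(k) cv_n(2e4, 610 + k)))
  r4 <- mean(sapply(1:3, function(k) cv_n(8e4, 620 + k)))
  expect_lt(abs(r1 / r4 / 2 - 1), 0.35)
})

test_that("sphere self absorption follows the energy-absorption physics", {
  # photoelectric dominance makes the self-AF fall steeply up to ~0.1 MeV;
  # above that it tracks the slowly varying Compton energy-absorption
  # coefficient (a shallow dip near 0.1 MeV, then nearly flat) rather than
  # decreasing monotonically
  fx <- make_fixture("one_sphere")
  Es <- c(0.03, 0.05, 0.1, 0.3, 1.0)
  af <- sapply(seq_along(Es), function(i) {
    s <- compute_saf(simulate_photons(fx, "Sphere", Es[i], n_histories = 6e4,
                                      seed = 630 + i), fx)
    saf_of(s, "Sphere")
  })
  expect_true(all(diff(af[1:3]) < 0))        # steep fall 0.03 -> 0.1
  expect_lt(af[5], af[2])                    # 1 MeV below the 50 keV value
  expect_lt(max(abs(af[3:5] / af[3] - 1)), 0.25) # plateau above 0.1 MeV
})

test_that("delta-tracking reproduces Beer-Lambert transmission through a slab", {
  tr <- slab_transmission("Soft tissue", thickness_cm = 4, energy_MeV = 0.1,
                          n = 2e5, seed = 640)
  expect_lt(abs(tr$transmission - tr$expected), 3 * tr$stderr)
})

test_that("cross absorption falls monotonically with sphere separation", {
  saf_gap <- function(gap, seed) {
    fx <- make_fixture("two_sphere", gap_cm = gap)
    s <- compute_saf(simulate_photons(fx, "Source sphere", 0.2,
                                      n_histories = 1e5, seed = seed), fx)
    saf_of(s, "Target sphere")
  }
  v <- c(saf_gap(2, 650), saf_gap(8, 651), saf_gap(20, 652))
  expect_true(all(diff(v) < 0))
})

test_that("simulation results are reproducible and inputs validated", {
  fx <- make_fixture("one_sphere")
  t1 <- simulate_photons(fx, "Sphere", 0.1, n_histories = 2e4, seed = 660)
  t2 <- simulate_photons(fx, "Sphere", 0.1, n_histories = 2e4, seed = 660)
  expect_identical(t1$dep, t2$dep)
  expect_error(simulate_photons(fx, "Nope", 0.1, 1e3, seed = 1), "unknown source")
  expect_error(simulate_photons(fx, "Sphere", 9, 1e3, seed = 1), "outside")
  expect_error(simulate_photons(fx, "Sphere", 0.1, 10, n_batches = 20, seed = 1))
})
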