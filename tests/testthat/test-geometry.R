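test_that("primitive containment follows the quadric inequalities with closed boundaries", {
  trunk <- elliptic_cylinder(18.0, 9.7, z_range = c(0, 64.7))
  expect_true(region_contains(trunk, c(0, 0, 30)))
  expect_false(region_contains(trunk, c(18.1, 0, 30)))
  expect_true(region_contains(trunk, c(18.0, 0, 30)))   # boundary is inside
  expect_false(region_contains(trunk, c(0, 0, 64.8)))   # above the clip

  sph <- ellipsoid(1, 1, 1)
  expect_true(region_contains(sph, c(1, 0, 0)))
  expect_false(region_contains(sph, c(1 + 1e-9, 0, 0)))

  legs <- cone_pair(18, 77)
  expect_true(region_contains(legs, c(9, 0, -1)))       # inside the +x leg
  expect_false(region_contains(legs, c(0, 5, -1)))      # between the legs
  expect_false(region_contains(legs, c(9, 0, 0.1)))     # above the legs

  hs <- half_space(c(0, 0, 1), 5)
  expect_true(region_contains(hs, c(100, -3, 5)))
  expect_false(region_contains(hs, c(0, 0, 5.01)))
})

test_that("analytic volumes match closed forms and flag unbounded/composite regions", {
  expect_equal(analytic_volume(ellipsoid(1, 1, 1)), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(analytic_volume(elliptic_cylinder(18, 9.7, z_range = c(0, 64.7))),
               pi * 18 * 9.7 * 64.7, tolerance = 1e-12)
  expect_equal(analytic_volume(cone_pair(18, 77)), pi * 18^2 * 77 / 6,
               tolerance = 1e-12)
  # clipped ellipsoid: hemisphere
  expect_equal(analytic_volume(ellipsoid(2, 2, 2, z_range = c(0, 2))),
               2 / 3 * pi * 8, tolerance = 1e-12)
  # affine scaling multiplies the volume by the scale product
  expect_equal(analytic_volume(region_scale(ellipsoid(1, 1, 1), c(2, 3, 4))),
               24 * 4 * pi / 3, tolerance = 1e-12)
  expect_error(analytic_volume(half_space(c(0, 0, 1), 0)), "no closed form")
  expect_error(analytic_volume(region_union(ellipsoid(1, 1, 1),
                                            ellipsoid(1, 1, 1, center = c(3, 0, 0)))),
               "no closed form")
})

test_that("Monte Carlo volume agrees with closed forms over random primitives", {
  set.seed(401)
  for (i in 1:8) {
    ax <- runif(3, 0.5, 4)
    reg <- if (i %% 2 == 0) ellipsoid(ax[1], ax[2], ax[3])
           else elliptic_cylinder(ax[1], ax[2], z_range = c(-ax[3], ax[3]))
    v <- mc_volume(reg, n = 2e5)
    expect_lt(abs(v$volume - analytic_volume(reg)), 4 * v$stderr + 1e-9)
  }
  # region equal to its own bounding box has zero estimator variance
  box <- elliptic_cylinder(1, 1, z_range = c(0, 1))
  v <- mc_volume(box, n = 1e4, bbox = rbind(c(-1, 1), c(-1, 1), c(0, 1)))
  expect_gte(v$volume, pi * 0.999) # cylinder fills pi/4 of that box
  expect_error(mc_volume(half_space(c(1, 0, 0), 0)), "unbounded")
})

test_that("mc_volume is deterministic under a fixed seed", {
  reg <- ellipsoid(2, 1, 1.5)
  v1 <- mc_volume(reg, n = 5e4, seed = 99)
  v2 <- mc_volume(reg, n = 5e4, seed = 99)
  expect_identical(v1$volume, v2$volume)
})

test_that("composite containment equals the boolean algebra of its children", {
  set.seed(402)
  a <- ellipsoid(2, 1.5, 1)
  b <- ellipsoid(1.5, 2, 1, center = c(1, 0, 0))
  pts <- cbind(runif(4000, -3, 3), runif(4000, -3, 3), runif(4000, -2, 2))
  ina <- region_contains(a, pts); inb <- region_contains(b, pts)
  expect_identical(region_contains(region_intersection(a, b), pts), ina & inb)
  expect_identical(region_contains(region_union(a, b), pts), ina | inb)
  expect_identical(region_contains(region_difference(a, b), pts), ina & !inb)
  # no point is in a difference and in its subtrahend simultaneously
  expect_false(any(region_contains(region_difference(a, b), pts) & inb))
  # nesting: (a \ b) union b == a union b
  lhs <- region_contains(region_union(region_difference(a, b), b), pts)
  expect_identical(lhs, ina | inb)
})

test_that("affine scale nodes transform containment correctly", {
  base <- ellipsoid(1, 1, 1)
  reg <- region_scale(base, scale = c(2, 1, 3), shift = c(5, 0, -1))
  expect_true(region_contains(reg, c(7, 0, -1)))   # (1,0,0) in child frame
  expect_false(region_contains(reg, c(7.1, 0, -1)))
  expect_true(region_contains(reg, c(5, 0, 2)))    # (0,0,1) in child frame
  bb <- region_bbox(reg)
  expect_equal(bb[, 1], c(3, -1, -4))
  expect_equal(bb[, 2], c(7, 1, 2))
})

test_that("regions round-trip losslessly through the list/YAML config dialect", {
  reg <- region_difference(
    region_intersection(elliptic_cylinder(16.5, 8, z_range = c(27, 43)),
                        half_space(c(1 / 35, 1 / 45, -1 / 43), -1)),
    region_scale(ellipsoid(2, 3, 4), c(0.5, 0.5, 1), c(1, 2, 3)))
  lst <- region_to_list(reg)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lst, tmp, precision = 12)
  back <- region_from_list(yaml::read_yaml(tmp))
  set.seed(403)
  pts <- cbind(runif(2000, -20, 20), runif(2000, -10, 10), runif(2000, 20, 50))
  expect_identical(region_contains(back, pts), region_contains(reg, pts))
  expect_equal(region_to_list(back), lst, tolerance = 1e-10)
})

test_that("sampled region points always fall inside the bounding box", {
  reg <- region_union(ellipsoid(1, 2, 1, center = c(2, 0, 0)),
                      cone_pair(4, 10))
  bb <- region_bbox(reg)
  set.seed(404)
  pts <- cbind(runif(5000, bb[1, 1], bb[1, 2]),
               runif(5000, bb[2, 1], bb[2, 2]),
               runif(5000, bb[3, 1], bb[3, 2]))
  inside <- region_contains(reg, pts)
  expect_gt(sum(inside), 0)
  # nothing just outside the bbox faces can be inside the region
  out <- rbind(c(bb[1, 2] + 1e-6, 0, -1), c(0, bb[2, 2] + 1e-6, -1))
  expect_false(any(region_contains(reg, out)))
})

test_that("invalid primitive parameters are rejected", {
  expect_error(ellipsoid(-1, 1, 1), "positive")
  expect_error(elliptic_cylinder(1, 1, z_range = c(2, 1)), "z_lo < z_hi")
  expect_error(half_space(c(0, 0, 0), 1), "nonzero")
  expect_error(region_scale(ellipsoid(1, 1, 1), scale = c(0, 1, 1)), "positive")
})
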