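sigmoid_slab_maps <- function(z0 = 15, dims = c(21, 21, 31)) {
  zs <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]),
              dim = dims)
  w <- density_map(c(0, 0, 0), 1, 1 / (1 + exp(-(zs - z0))))
  l <- density_map(c(0, 0, 0), 1, 1 / (1 + exp(zs - z0)))
  list(w = w, l = l)
}

cylinder_maps <- function(R = 10, dims = c(41, 41, 21)) {
  ix <- array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
              dim = dims)
  iy <- array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), dims[3]),
              dim = dims)
  r <- sqrt((ix - 20)^2 + (iy - 20)^2)
  list(w = density_map(c(0, 0, 0), 1, 1 / (1 + exp(r - R))),
       l = density_map(c(0, 0, 0), 1, 1 / (1 + exp(R - r))))
}

test_that("the equal-density surface of an analytic slab sits at the crossing", {
  m <- sigmoid_slab_maps(z0 = 15)
  surf <- extract_interface(m$w, m$l)
  expect_gt(nrow(surf$points), 100)
  expect_true(all(abs(surf$points[, 3] - 15) <= 0.5))

  # mirror-symmetric fields give a mirror-symmetric point set
  zs <- array(rep(0:30, each = 21 * 21), dim = c(21, 21, 31))
  wb <- density_map(c(0, 0, 0), 1,
                    1 / (1 + exp(-(abs(zs - 15) - 7))))
  lb <- density_map(c(0, 0, 0), 1,
                    1 / (1 + exp(abs(zs - 15) - 7)))
  s2 <- extract_interface(wb, lb)
  z_up <- sort(s2$points[s2$points[, 3] > 15, 3])
  z_dn <- sort(30 - s2$points[s2$points[, 3] < 15, 3])
  expect_equal(z_up, z_dn, tolerance = 1e-9)

  # no crossing anywhere -> error
  expect_error(extract_interface(m$w, density_map(c(0, 0, 0), 1,
                                                  m$w$values * 0.5)),
               "no interface")
})

test_that("normals of a planar sheet are the solvent-oriented z axis", {
  m <- sigmoid_slab_maps(z0 = 15)
  surf <- extract_interface(m$w, m$l)
  surf <- compute_normals(surf, m$w, m$l)
  expect_true(all(abs(sqrt(rowSums(surf$normals^2)) - 1) < 1e-9))
  # water is at high z here, so normals must point along +z
  expect_true(all(surf$normals[, 3] > 0.999))

  # exchanging the map roles flips every normal
  flipped <- compute_normals(extract_interface(m$l, m$w), m$l, m$w)
  expect_true(all(flipped$normals[, 3] < -0.999))
})

test_that("curved interfaces carry near-radial normals", {
  m <- cylinder_maps(R = 10)
  surf <- extract_interface(m$w, m$l)
  r <- sqrt((surf$points[, 1] - 20)^2 + (surf$points[, 2] - 20)^2)
  expect_true(all(abs(r - 10) <= 1))
  surf <- compute_normals(surf, m$w, m$l)
  radial <- cbind(surf$points[, 1] - 20, surf$points[, 2] - 20, 0)
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, abs(rowSums(surf$normals * radial)))) * 180 / pi
  expect_lt(mean(ang), 5)
  # solvent (water) is inside the cylinder: normals point inward
  expect_lt(mean(rowSums(surf$normals * radial)), -0.9)
})

test_that("sphere-sampled points have near-radial plane-fit normals", {
  set.seed(41)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- 20 * u
  fit <- tiltsplay:::.plane_normals_cpp(pts, 10)
  dotp <- abs(rowSums(fit$normals * u))
  expect_lt(mean(acos(pmin(1, dotp))) * 180 / pi, 5)
})

test_that("points with too few neighbours are dropped with a warning", {
  pts <- rbind(matrix(runif(60, 0, 5), ncol = 3), c(500, 500, 500))
  m <- density_map(c(0, 0, 0), 1, array(1, c(3, 3, 3)))
  expect_warning(
    out <- compute_normals(interface_surface(pts), m, m, fit_radius = 10),
    "dropped")
  expect_equal(nrow(out$points), 20)
})

test_that("nearest-point queries agree with exhaustive search", {
  set.seed(42)
  pts <- matrix(runif(9000, -25, 25), ncol = 3)
  surf <- interface_surface(pts)
  qs <- matrix(runif(3000, -30, 30), ncol = 3)
  nn <- nearest_surface_point(surf, qs)
  brute <- apply(qs, 1, function(q) which.min(colSums((t(pts) - q)^2)))
  expect_identical(nn, as.integer(brute))

  # query equal to a surface point returns that point
  expect_identical(nearest_surface_point(surf, pts[77, ]), 77L)

  # exact ties break to the lowest index
  tie <- interface_surface(rbind(c(5, 0, 0), c(9, 9, 9), c(-5, 0, 0),
                                 c(0, 5, 0), c(8, 8, 8), c(7, 7, 7),
                                 c(0, -5, 0)))
  expect_identical(nearest_surface_point(tie, c(0, 0, 0)), 1L)
  # a query equidistant from points 3 and 7 only resolves to 3
  tie2 <- interface_surface(rbind(c(40, 40, 40), c(50, 50, 50),
                                  c(-5, 0, 0), c(41, 40, 40),
                                  c(52, 50, 50), c(49, 50, 50),
                                  c(0, 5, 0)))
  expect_identical(nearest_surface_point(tie2, c(-2.5, 2.5, 0)), 3L)
})
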