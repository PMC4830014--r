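test_that("tilt sampler matches its target density and is deterministic", {
  expect_identical(sample_tilt_angles(10, 1000, seed = 81),
                   sample_tilt_angles(10, 1000, seed = 81))

  # very stiff tilt: sample mean matches quadrature of the target density
  kappa <- 1e4
  th <- sample_tilt_angles(kappa, 2e4, seed = 82)
  dens <- function(t) sin(t) * exp(-kappa * t^2 / 2)
  z <- integrate(dens, 0, pi / 2)$value
  mean_th <- integrate(function(t) t * dens(t) / z, 0, pi / 2)$value
  var_th <- integrate(function(t) (t - mean_th)^2 * dens(t) / z, 0,
                      pi / 2)$value
  expect_lt(abs(mean(th) - mean_th), 3 * sqrt(var_th / 2e4))
  expect_lt(mean(th), 0.05)

  # empirical PMF of kappa = 10 samples has quadratic coefficient 5
  th10 <- sample_tilt_angles(10, 1e5, seed = 83)
  r <- extract_tilt_modulus(th10)
  expect_lt(abs(r$value / 2 / 5 - 1), 0.05)
})

test_that("splay sampler has the harmonic variance and is deterministic", {
  expect_identical(sample_splays(10, 60, 500, seed = 84),
                   sample_splays(10, 60, 500, seed = 84))
  s <- sample_splays(10, 60, 1e5, seed = 85)
  v <- 1 / 600
  se_var <- sqrt(2 / 1e5) * v
  expect_lt(abs(var(s) - v), 3 * se_var)
  s2 <- sample_splays(20, 60, 1e5, seed = 85)
  expect_equal(var(s2), var(s) / 2, tolerance = 1e-12)
})

test_that("generators are pure functions of their spec", {
  spec <- synthetic_spec("planar", n_lipids = 16, frames = 3, seed = 86)
  g1 <- generate_planar_trajectory(spec)
  g2 <- generate_planar_trajectory(spec)
  expect_identical(g1$trajectory$frames, g2$trajectory$frames)
  expect_identical(g1$truth, g2$truth)

  spec_c <- synthetic_spec("cylindrical", n_lipids = 40, frames = 2,
                           radius = 10, seed = 87)
  c1 <- generate_cylindrical_trajectory(spec_c)
  c2 <- generate_cylindrical_trajectory(spec_c)
  expect_identical(c1$trajectory$frames, c2$trajectory$frames)
})

test_that("the calibrated planar field reproduces the requested moduli", {
  # measure the generated directors against the TRUE normal field (z axis),
  # bypassing the interface machinery: this isolates the generator contract
  spec <- synthetic_spec("planar", n_lipids = 100, frames = 400,
                         kappa_t = 12, K_c = 10, A_L = 60, seed = 88)
  gen <- generate_planar_trajectory(spec)
  traj <- gen$trajectory
  expect_lt(gen$truth$ell, spec$cutoff)  # correlation below the pair cutoff
  sys <- traj$system
  hd <- which(sys$atoms$name == "HD")
  tl <- which(sys$atoms$name == "TL")
  md <- which(sys$atoms$name == "MD")
  Lx <- traj$cell[1, 1]; Ly <- traj$cell[2, 2]
  mid1 <- traj$frames[[1]][md, ]
  pair_list <- function(idx) {
    xy <- mid1[idx, 1:2]
    ij <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
    dx <- xy[ij[, 2], 1] - xy[ij[, 1], 1]; dx <- dx - round(dx / Lx) * Lx
    dy <- xy[ij[, 2], 2] - xy[ij[, 1], 2]; dy <- dy - round(dy / Ly) * Ly
    r <- sqrt(dx^2 + dy^2); keep <- r < spec$cutoff
    list(i = idx[ij[keep, 1]], j = idx[ij[keep, 2]],
         ex = dx[keep] / r[keep], ey = dy[keep] / r[keep], h = r[keep])
  }
  up <- mid1[, 3] > 0
  pp <- list(pair_list(which(up)), pair_list(which(!up)))
  th <- numeric(0); sp <- numeric(0)
  for (f in seq_along(traj$frames)) {
    pos <- traj$frames[[f]]
    dir <- pos[hd, ] - pos[tl, ]
    dir <- dir / sqrt(rowSums(dir^2))
    th <- c(th, acos(pmin(1, abs(dir[, 3]))))
    for (p in pp)
      sp <- c(sp, ((dir[p$j, 1] - dir[p$i, 1]) * p$ex +
                     (dir[p$j, 2] - dir[p$i, 2]) * p$ey) / p$h)
  }
  rt <- extract_tilt_modulus(th)
  expect_lt(abs(rt$value / gen$truth$kappa_t - 1), 0.05)
  rs <- extract_splay_modulus(sp, gen$truth$A_L)
  expect_lt(abs(rs$value / gen$truth$K_c - 1), 0.08)
})

test_that("the zero-noise variant has vanishing tilts and splays", {
  spec <- synthetic_spec("planar", n_lipids = 16, frames = 2,
                         kappa_t = Inf, seed = 89)
  gen <- generate_planar_trajectory(spec)
  traj <- gen$trajectory
  surf <- flat_surface(z0 = 15, half = 25)
  tl <- analyze_tilts(traj, pseudo_defs(), surf)
  expect_true(all(abs(tl$LIP$theta) < 1e-9))
  sp <- analyze_splays(traj, pseudo_defs(), surf)
  expect_true(all(abs(sp[["LIP|LIP"]]$s) < 1e-12))
})

test_that("planar interface is recovered at the constructed boundary", {
  spec <- synthetic_spec("planar", n_lipids = 32, frames = 30, seed = 90)
  gen <- generate_planar_trajectory(spec)
  traj <- gen$trajectory
  grid <- density_grid(traj, "rname=SOL,LIP")
  w <- average_density(traj, "rname=SOL", grid = grid)
  l <- average_density(traj, "rname=LIP", grid = grid)
  surf <- extract_interface(w, l)
  expect_lt(mean(abs(abs(surf$points[, 3]) - gen$truth$boundary_z)), 1.5)
  # two sheets, one per leaflet
  expect_gt(sum(surf$points[, 3] > 0), 100)
  expect_gt(sum(surf$points[, 3] < 0), 100)
})

test_that("cylindrical geometry yields radial interface and normals", {
  spec <- synthetic_spec("cylindrical", n_lipids = 200, frames = 20,
                         radius = 20, seed = 91)
  gen <- generate_cylindrical_trajectory(spec)
  traj <- gen$trajectory
  expect_equal(gen$truth$A_L, spec$A_L, tolerance = 1e-9)
  grid <- density_grid(traj, "rname=SOL,LIP")
  w <- average_density(traj, "rname=SOL", grid = grid)
  l <- average_density(traj, "rname=LIP", grid = grid)
  surf <- extract_interface(w, l)
  r <- sqrt(surf$points[, 1]^2 + surf$points[, 2]^2)
  expect_lt(mean(abs(r - spec$radius)), 1.5)
  surf <- compute_normals(surf, w, l)
  radial <- cbind(surf$points[, 1], surf$points[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, abs(rowSums(surf$normals * radial)))) * 180 / pi
  expect_lt(mean(ang), 5)
  # normals point toward the water channel (inward)
  expect_lt(mean(rowSums(surf$normals * radial)), -0.9)
})

test_that("impossible calibrations are refused, not fudged", {
  # a stiff tilt field bounds how soft the splay distribution can be:
  # requesting K_c below that bound must fail loudly
  expect_error(
    generate_planar_trajectory(
      synthetic_spec("planar", n_lipids = 16, frames = 1, kappa_t = 30,
                     K_c = 5, seed = 92)),
    "below the minimum")
})
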