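test_that("director vectors are normalized tail-to-head directions", {
  expect_equal(compute_director(c(0, 0, 10), c(0, 0, 0)), c(0, 0, 1))
  expect_equal(compute_director(c(1, 0, 1), c(0, 0, 0)),
               c(1, 0, 1) / sqrt(2))
  expect_equal(compute_director(c(0, 0, 0), c(1, 0, 1)),
               -compute_director(c(1, 0, 1), c(0, 0, 0)))
  expect_error(compute_director(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("tilt angles are folded onto [0, pi/2]", {
  n <- c(0, 0, 1)
  expect_equal(compute_tilt(n, n), 0)
  expect_equal(compute_tilt(c(1, 0, 0), n), pi / 2)
  expect_equal(compute_tilt(c(1, 0, 1) / sqrt(2), n), pi / 4)
  # anti-parallel directors (other leaflet) give the same tilt
  expect_equal(compute_tilt(-c(1, 0, 1) / sqrt(2), n), pi / 4)
})

test_that("pairwise splay reproduces the finite-difference arithmetic", {
  z <- c(0, 0, 1)
  # identical fields: zero splay
  s0 <- compute_splay(z, z, z, z, c(0, 0, 0), c(5, 0, 0))
  expect_equal(s0$s, 0)
  expect_equal(s0$h, 5)

  # flat membrane, director rotated by 10 degrees: S = sin(10deg) / 5
  n2 <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  s1 <- compute_splay(z, n2, z, z, c(0, 0, 0), c(5, 0, 0))
  expect_equal(s1$s, sin(10 * pi / 180) / 5, tolerance = 1e-12)

  # exchanging the lipids leaves S unchanged on a flat membrane
  s2 <- compute_splay(n2, z, z, z, c(5, 0, 0), c(0, 0, 0))
  expect_equal(s2$s, s1$s, tolerance = 1e-12)

  # separation parallel to the normal: pair skipped
  expect_null(compute_splay(z, n2, z, z, c(0, 0, 0), c(0, 0, 5)))
  expect_error(compute_splay(z, z, z, z, c(1, 1, 1), c(1, 1, 1)),
               "coincident")
})

test_that("splay of a linear director field is its gradient, exactly", {
  alpha <- 0.02
  z <- c(0, 0, 1)
  for (h in c(2, 5, 8)) {
    x1 <- 3; x2 <- x1 + h
    n1 <- c(alpha * x1, 0, sqrt(1 - (alpha * x1)^2))
    n2 <- c(alpha * x2, 0, sqrt(1 - (alpha * x2)^2))
    s <- compute_splay(n1, n2, z, z, c(x1, 0, 0), c(x2, 0, 0))
    expect_equal(s$s, alpha, tolerance = 1e-9)
  }
})

test_that("tilt analysis honours flags, definitions and nearest normals", {
  # lipid with a director 30 degrees off the +z normal, flat surface
  xy <- matrix(c(0, 0), 1, 2)
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  traj <- membrane_frame(xy, matrix(d30, 1, 3))
  surf <- flat_surface(z0 = 15)
  tl <- analyze_tilts(traj, pseudo_defs(), surf)
  expect_equal(nrow(tl$LIP), 1)
  expect_equal(tl$LIP$theta, pi / 6, tolerance = 1e-9)

  # zero-tilt membrane: every angle is 0
  set.seed(51)
  xy8 <- cbind(runif(8, -15, 15), runif(8, -15, 15))
  traj0 <- membrane_frame(xy8, matrix(rep(c(0, 0, 1), 8), ncol = 3,
                                      byrow = TRUE))
  tl0 <- analyze_tilts(traj0, pseudo_defs(), surf)
  expect_true(all(abs(tl0$LIP$theta) < 1e-6))
  expect_equal(nrow(tl0$LIP), 8)

  # flags all FALSE: no samples at all
  traj_off <- traj0
  traj_off$system$residues$do_tilt <- FALSE
  expect_length(analyze_tilts(traj_off, pseudo_defs(), surf), 0)

  # a species absent from the definitions is reported by name
  bad_defs <- pseudo_defs()
  bad_defs$head_group <- c(OTHER = "aname=HD")
  expect_error(analyze_tilts(traj, bad_defs, surf), "LIP")
})

test_that("splay pair enumeration respects the cutoff and flags", {
  surf <- flat_surface(z0 = 15, half = 25)
  # two lipids 12 A apart: no pairs under a 10 A cutoff
  t2 <- membrane_frame(rbind(c(0, 0), c(12, 0)),
                       matrix(rep(c(0, 0, 1), 2), ncol = 3, byrow = TRUE))
  expect_length(analyze_splays(t2, pseudo_defs(), surf, cutoff = 10), 0)

  # three collinear lipids at 0, 5, 10 with cutoff 6: exactly 2 pairs
  t3 <- membrane_frame(rbind(c(0, 0), c(5, 0), c(10, 0)),
                       matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE))
  sp3 <- analyze_splays(t3, pseudo_defs(), surf, cutoff = 6)
  expect_equal(nrow(sp3[["LIP|LIP"]]), 2)

  # uniformly tilted flat system: all splays vanish
  d <- c(sin(0.3), 0, cos(0.3))
  t4 <- membrane_frame(rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5)),
                       matrix(rep(d, 4), ncol = 3, byrow = TRUE))
  sp4 <- analyze_splays(t4, pseudo_defs(), surf, cutoff = 8)
  expect_true(all(abs(sp4[["LIP|LIP"]]$s) < 1e-9))
  expect_error(analyze_splays(t4, pseudo_defs(), surf, cutoff = 0),
               "positive")
})

test_that("tilt sample counts equal frames times flagged lipids", {
  gen <- generate_planar_trajectory(
    synthetic_spec("planar", n_lipids = 16, frames = 5, seed = 12))
  surf <- flat_surface(z0 = 15, half = 25)
  tl <- analyze_tilts(gen$trajectory, pseudo_defs(), surf)
  expect_equal(nrow(tl$LIP), 5 * 32)
})

test_that("area per lipid is the in-plane cell area per leaflet lipid", {
  sys <- molecular_system(rep("MD", 128), rep("LIP", 128), 1:128,
                          rep("M", 128), mass_table = c(MD = 300))
  traj <- trajectory(sys, list(matrix(0, 128, 3)), diag(c(62, 62, 70)))
  expect_equal(analyze_area_per_lipid(traj, "LIP"), 62 * 62 / 64)

  # intensive: doubling the in-plane cell with 4x the lipids is unchanged
  sys4 <- molecular_system(rep("MD", 512), rep("LIP", 512), 1:512,
                           rep("M", 512), mass_table = c(MD = 300))
  traj4 <- trajectory(sys4, list(matrix(0, 512, 3)), diag(c(124, 124, 70)))
  expect_equal(analyze_area_per_lipid(traj4, "LIP"),
               analyze_area_per_lipid(traj, "LIP"))
  expect_error(analyze_area_per_lipid(traj, "NONE"), "no lipids")
})

test_that("leaflet partitions split a centered bilayer cleanly", {
  gen <- generate_planar_trajectory(
    synthetic_spec("planar", n_lipids = 16, frames = 2, seed = 13))
  traj <- gen$trajectory
  sys <- partition_flags(traj$system,
                         list(upper = "rname=LIP and z>0",
                              lower = "rname=LIP and z<0"),
                         positions = traj$frames[[1]])
  lip <- sys$residues$name == "LIP"
  expect_true(all(xor(sys$residues$upper[lip], sys$residues$lower[lip])))
  expect_false(any(sys$residues$upper[!lip] | sys$residues$lower[!lip]))
  expect_equal(sum(sys$residues$upper), 16)

  # analysis restricted to one leaflet via the part name
  traj$system <- sys
  surf <- flat_surface(z0 = 15, half = 25)
  tl_up <- analyze_tilts(traj, pseudo_defs(), surf, flag = "upper")
  expect_equal(nrow(tl_up$LIP), 2 * 16)

  # a part covering everything reproduces the default flag behaviour
  sys2 <- partition_flags(traj$system, list(all_m = "cname=M"))
  traj$system <- sys2
  tl_all <- analyze_tilts(traj, pseudo_defs(), surf, flag = "all_m")
  tl_def <- analyze_tilts(traj, pseudo_defs(), surf)
  expect_equal(tl_all$LIP$theta, tl_def$LIP$theta)

  # empty part: empty output downstream
  sys3 <- partition_flags(traj$system, list(nothing = "rname=ABSENT"))
  traj$system <- sys3
  expect_length(analyze_tilts(traj, pseudo_defs(), surf, flag = "nothing"),
                0)
})
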