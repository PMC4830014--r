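test_that("histograms are normalized equal-width summaries", {
  h1 <- build_histogram(rep(0.5, 200), 10)
  expect_equal(sum(h1$prob), 1)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(max(h1$prob), 1)

  set.seed(61)
  hu <- build_histogram(runif(2e5), 10, range = c(0, 1))
  se <- sqrt(0.1 * 0.9 / 2e5)
  expect_true(all(abs(hu$prob - 0.1) < 3 * se))
  expect_equal(sum(hu$prob), 1)
  expect_error(build_histogram(numeric(0), 10), "empty")
  expect_warning(build_histogram(rnorm(50), 10), "fewer than 100")
})

test_that("gaussian fits recover location and width", {
  x <- seq(-3, 3, length.out = 61)
  h <- list(mids = x, counts = rep(1, 61),
            prob = dnorm(x, 0.4, 0.8) / sum(dnorm(x, 0.4, 0.8)),
            width = x[2] - x[1])
  class(h) <- "sample_histogram"
  g <- fit_gaussian(h)
  expect_equal(g$mu, 0.4, tolerance = 0.01)
  expect_equal(g$sigma, 0.8, tolerance = 0.01)

  set.seed(62)
  hs <- build_histogram(rnorm(1e5), 100)
  gs <- fit_gaussian(hs)
  expect_true(abs(gs$mu) < 0.02)
  expect_true(gs$sigma > 0.98 && gs$sigma < 1.02)
})

test_that("tilt PMF inverts the sin-theta weighted distribution", {
  theta <- seq(0.01, pi / 2 - 0.01, length.out = 90)
  # P ~ sin(theta): PMF constant 0 after shifting
  p_sin <- sin(theta) / sum(sin(theta))
  h <- structure(list(mids = theta, counts = rep(1, 90), prob = p_sin,
                      width = theta[2] - theta[1]),
                 class = "sample_histogram")
  pmf <- tilt_pmf(h)
  expect_lt(max(abs(pmf$value)), 1e-12)

  # P ~ sin(theta) exp(-5 theta^2): PMF = 5 theta^2 + shift
  p5 <- sin(theta) * exp(-5 * theta^2)
  h5 <- structure(list(mids = theta, counts = rep(1, 90),
                       prob = p5 / sum(p5), width = theta[2] - theta[1]),
                  class = "sample_histogram")
  pmf5 <- tilt_pmf(h5)
  expect_equal(pmf5$value, 5 * pmf5$x^2 - min(5 * pmf5$x^2),
               tolerance = 1e-9)

  # normalization cancels: halving the counts leaves the PMF unchanged
  h5b <- h5; h5b$counts <- h5$counts / 2
  expect_equal(tilt_pmf(h5b)$value, pmf5$value)
})

test_that("splay PMF is the negative log-density in kT", {
  s <- seq(-0.2, 0.2, length.out = 101)
  v <- 1 / 600  # K_c A_L = 600 A^2 kT
  p <- exp(-s^2 / (2 * v))
  h <- structure(list(mids = s, counts = rep(1, 101), prob = p / sum(p),
                      width = s[2] - s[1]), class = "sample_histogram")
  pmf <- splay_pmf(h)
  fit <- lm(pmf$value ~ I(pmf$x^2))
  expect_equal(unname(coef(fit)[2]), 300, tolerance = 1e-6)
  # symmetric input, symmetric PMF
  expect_equal(pmf$value, rev(pmf$value), tolerance = 1e-12)
})

test_that("quadratic range fits recover exact polynomials", {
  x <- seq(-1, 1, length.out = 81)
  pmf <- structure(list(x = x, value = 2 + 3 * x^2, source = "splay"),
                   class = "pmf_curve")
  fits <- fit_pmf_quadratic(pmf, mu = 0, sigma = 0.4)
  expect_equal(nrow(fits), 5)
  expect_equal(fits$b, rep(3, 5), tolerance = 1e-10)
  expect_lt(tiltsplay:::pop_sd(2 * fits$b), 1e-9)

  # adding a constant changes only the intercept
  pmf2 <- pmf; pmf2$value <- pmf$value + 7
  fits2 <- fit_pmf_quadratic(pmf2, mu = 0, sigma = 0.4)
  expect_equal(fits2$b, fits$b, tolerance = 1e-10)
  expect_equal(fits2$a, fits$a + 7, tolerance = 1e-10)

  # quartic contamination: fitted b grows with the range, matching a
  # direct least-squares oracle on each window
  pmf4 <- structure(list(x = x, value = 3 * x^2 + x^4, source = "splay"),
                    class = "pmf_curve")
  fits4 <- fit_pmf_quadratic(pmf4, mu = 0, sigma = 0.4)
  expect_true(all(diff(fits4$b) > 0))
  for (i in seq_len(nrow(fits4))) {
    use <- x >= fits4$lo[i] & x <= fits4$hi[i]
    oracle <- unname(coef(lm(I(3 * x[use]^2 + x[use]^4) ~ I(x[use]^2)))[2])
    expect_equal(fits4$b[i], oracle, tolerance = 1e-12)
  }

  # a too-narrow range is skipped with a warning, wider ones still fit
  expect_warning(narrow <- fit_pmf_quadratic(pmf, mu = 0, sigma = 0.02,
                                             c_values = c(1, 2)),
                 "skipped")
  expect_equal(narrow$c, 2)
  # no usable range at all is an error
  expect_error(
    suppressWarnings(fit_pmf_quadratic(pmf, mu = 0, sigma = 1e-4)),
    "3 or more points")
})

test_that("generative tilt and splay moduli are recovered by the chain", {
  th <- sample_tilt_angles(8, 5e4, seed = 63)
  rt <- extract_tilt_modulus(th)
  expect_lt(abs(rt$value / 8 - 1), 0.05)
  expect_gt(rt$uncertainty, 0)

  sp <- sample_splays(12, 55, 5e4, seed = 64)
  rs <- extract_splay_modulus(sp, 55)
  expect_lt(abs(rs$value / 12 - 1), 0.05)

  # doubling A_L halves K_c for the same samples
  rs2 <- extract_splay_modulus(sp, 110)
  expect_equal(rs2$value, rs$value / 2, tolerance = 1e-12)
  expect_error(extract_splay_modulus(sp, -5), "positive")
  expect_error(extract_splay_modulus(rep(0.01, 1000), 60), "degenerate")
})

test_that("mixture combinations are count-weighted harmonic means", {
  expect_equal(combine_splay_moduli(c(20, 30, 60), c(1, 1, 1)), 30)
  expect_equal(combine_tilt_moduli(c(10, 20), c(5, 5)), 40 / 3)
  expect_equal(combine_splay_moduli(c(AA = 15), c(AA = 99)), 15)
  expect_equal(combine_tilt_moduli(c(A = 7), c(A = 3)), 7)

  # equal components: count weights are irrelevant
  expect_equal(combine_splay_moduli(c(9, 9, 9), c(1, 5, 100)), 9)

  # adding a species at the current combined value changes nothing
  k0 <- combine_tilt_moduli(c(10, 20), c(5, 5))
  expect_equal(combine_tilt_moduli(c(10, 20, k0), c(5, 5, 7)), k0)

  # bounded by the extreme components
  set.seed(65)
  for (i in 1:20) {
    chi <- runif(4, 5, 50); phi <- runif(4, 1, 10)
    kc <- combine_splay_moduli(chi, phi)
    expect_gte(kc, min(chi)); expect_lte(kc, max(chi))
  }
  expect_error(combine_splay_moduli(c(-1, 2), c(1, 1)), "positive")
})

test_that("the driver collapses to per-species values for one species", {
  th <- sample_tilt_angles(12, 4e4, seed = 66)
  sp <- sample_splays(10, 60, 4e4, seed = 67)
  outdir <- file.path(tempdir(), "moduli_out")
  res <- extract_tilt_and_splay_moduli(list(LIP = th),
                                       list(`LIP|LIP` = sp), 60,
                                       outdir = outdir)
  expect_equal(res$kappa_t, res$tilt$LIP$value)
  expect_equal(res$K_c, res$splay$`LIP|LIP`$value)

  # output contract: distribution, PMF, fits, figure, summary
  files <- list.files(outdir)
  for (pat in c("tilt_LIP_distribution.csv", "tilt_LIP_pmf.csv",
                "tilt_LIP_fits.csv", "splay_LIP_LIP_distribution.csv",
                "splay_LIP_LIP_pmf.csv", "moduli_summary.json",
                "moduli_summary.txt"))
    expect_true(pat %in% files, label = pat)
  expect_true(any(grepl("\\.png$", files)))
})

test_that("two-species combination is internally consistent", {
  tilts <- list(A = sample_tilt_angles(10, 3e4, seed = 68),
                B = sample_tilt_angles(20, 3e4, seed = 69))
  splays <- list(`A|A` = sample_splays(8, 60, 3e4, seed = 70),
                 `A|B` = sample_splays(12, 60, 2e4, seed = 71),
                 `B|B` = sample_splays(20, 60, 1e4, seed = 72))
  res <- extract_tilt_and_splay_moduli(tilts, splays, 60, plots = FALSE)
  chi_t <- vapply(res$tilt, `[[`, 0, "value")
  expect_equal(res$kappa_t,
               combine_tilt_moduli(chi_t, res$tilt_counts),
               tolerance = 1e-12)
  chi_s <- vapply(res$splay, `[[`, 0, "value")
  expect_equal(res$K_c,
               combine_splay_moduli(chi_s, res$splay_counts),
               tolerance = 1e-12)
  expect_equal(unname(res$splay_counts), c(3e4, 2e4, 1e4))
})
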