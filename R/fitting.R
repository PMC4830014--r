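#' Equal-width histogram of tilt or splay samples
#'
#' @param samples numeric vector of observations.
#' @param n_bins number of bins.
#' @param range optional \code{c(lo, hi)}; default spans
#'   \code{[min, max]} of the samples.
#' @return A list of class \code{"sample_histogram"} with \code{mids},
#'   \code{counts}, \code{prob} (normalized to sum 1) and \code{width}.
#' @export
build_histogram <- function(samples, n_bins, range = NULL) {
  if (length(samples) == 0) stop("cannot histogram an empty sample")
  if (length(samples) < 100)
    warning("fewer than 100 samples; distributions will be noisy")
  if (is.null(range)) range <- c(min(samples), max(samples))
  if (range[1] == range[2]) range <- range + c(-0.5, 0.5) * 1e-9
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- findInterval(samples, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                 counts = counts, prob = counts / sum(counts),
                 width = diff(breaks)[1]),
            class = "sample_histogram")
}

#' Least-squares Gaussian fit of a histogram
#'
#' Fits \eqn{A \exp(-(x-\mu)^2 / 2\sigma^2)} to the bin probabilities,
#' initialized at the histogram moments. On non-convergence the histogram
#' mean and standard deviation are returned with a warning.
#'
#' @param hist a [build_histogram()] result.
#' @return List with \code{mu}, \code{sigma}, \code{amplitude},
#'   \code{converged}.
#' @export
fit_gaussian <- function(hist) {
  use <- hist$counts > 0
  if (sum(use) < 3) stop("need at least 3 non-empty bins")
  x <- hist$mids
  p <- hist$prob
  mu0 <- weighted.mean(x, p)
  sd0 <- sqrt(max(weighted.mean((x - mu0)^2, p), 1e-12))
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(p ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                           start = list(A = max(p), mu = mu0 + 1e-3 * sd0,
                                        s = sd0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(m)
    list(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
         amplitude = unname(cf["A"]), converged = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("gaussian fit did not converge; using histogram moments")
    fit <- list(mu = mu0, sigma = sd0, amplitude = max(p),
                converged = FALSE)
  }
  fit
}

#' Tilt potential of mean force
#'
#' \eqn{\mathrm{PMF}(\theta) = -\ln(P(\theta)/\sin\theta)} in units of
#' \eqn{k_B T}, shifted so its minimum is zero. The \eqn{\sin\theta}
#' Jacobian removes the solid-angle factor of the tilt distribution. Bins
#' with zero counts (or at \eqn{\theta \le 0}) are excluded.
#'
#' @param hist tilt histogram (\eqn{\theta} in radians, bins in
#'   \code{(0, pi/2]}).
#' @param temperature temperature in K (kept for the record; the PMF is
#'   expressed in \eqn{k_B T} so it does not rescale values).
#' @return List of class \code{"pmf_curve"}: \code{x}, \code{value}
#'   (\eqn{k_B T}), \code{source}.
#' @export
tilt_pmf <- function(hist, temperature = 300) {
  use <- hist$counts > 0 & hist$mids > 0
  if (!any(use)) stop("all histogram bins are empty")
  x <- hist$mids[use]
  v <- -log(hist$prob[use] / sin(x))
  structure(list(x = x, value = v - min(v), source = "tilt",
                 temperature = temperature), class = "pmf_curve")
}

#' Splay potential of mean force
#'
#' \eqn{\mathrm{PMF}(S) = -\ln P(S)} in \eqn{k_B T}, shifted to zero
#' minimum; no Jacobian term.
#'
#' @inheritParams tilt_pmf
#' @param hist splay histogram (S in 1/Angstrom).
#' @return A \code{"pmf_curve"}.
#' @export
splay_pmf <- function(hist, temperature = 300) {
  use <- hist$counts > 0
  if (!any(use)) stop("all histogram bins are empty")
  x <- hist$mids[use]
  v <- -log(hist$prob[use])
  structure(list(x = x, value = v - min(v), source = "splay",
                 temperature = temperature), class = "pmf_curve")
}

#' Quadratic PMF fits over multiple ranges
#'
#' Unweighted least-squares fits of \eqn{a + b x^2} (or
#' \eqn{a + b (x-\mu)^2} when \code{centered}) to the PMF points with
#' abscissa in \eqn{[\mu - c\sigma, \mu + c\sigma]}, for each range
#' multiplier \code{c}. Ranges with fewer than 3 points are skipped with a
#' warning.
#'
#' @param pmf a \code{"pmf_curve"}.
#' @param mu,sigma centre and width of the fitting ranges (from
#'   [fit_gaussian()] of the distribution).
#' @param c_values range multipliers (default \code{c(1,1.25,1.5,1.75,2)}).
#' @param centered fit the quadratic around \code{mu} instead of 0 (useful
#'   for curved systems with non-zero spontaneous splay).
#' @return data.frame with one row per fitted range: \code{c}, \code{a},
#'   \code{b}, \code{n_points}, \code{lo}, \code{hi}.
#' @export
fit_pmf_quadratic <- function(pmf, mu, sigma,
                              c_values = c(1, 1.25, 1.5, 1.75, 2),
                              centered = FALSE) {
  out <- list()
  for (cc in c_values) {
    lo <- mu - cc * sigma
    hi <- mu + cc * sigma
    use <- pmf$x >= lo & pmf$x <= hi
    if (sum(use) < 3) {
      warning("fewer than 3 PMF points in range c = ", cc, "; skipped")
      next
    }
    x <- pmf$x[use]
    xx <- if (centered) (x - mu)^2 else x^2
    fit <- lm(pmf$value[use] ~ xx)
    out[[length(out) + 1]] <- data.frame(c = cc,
                                         a = unname(coef(fit)[1]),
                                         b = unname(coef(fit)[2]),
                                         n_points = sum(use),
                                         lo = lo, hi = hi)
  }
  if (length(out) == 0) stop("no fitting range contained 3 or more points")
  do.call(rbind, out)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Modulus = scale * b at the smallest c (c = 1 by convention); uncertainty =
# population sd of the moduli over all fitted ranges.
modulus_from_fits <- function(fits, scale) {
  moduli <- scale * fits$b
  i <- which.min(fits$c)
  list(value = moduli[i], uncertainty = pop_sd(moduli), fits = fits)
}

#' Tilt modulus from tilt samples
#'
#' Histogram, Gaussian fit for the range centre/width, tilt PMF, quadratic
#' fits over the five standard ranges; the modulus is \eqn{\kappa_t = 2b}
#' from the \code{c = 1} fit and the uncertainty the standard deviation of
#' the moduli over the five ranges.
#'
#' @param samples tilt angles in radians.
#' @param temperature temperature (K).
#' @param n_bins histogram bins (default 90 over \code{[0, pi/2]}, i.e.
#'   1-degree bins).
#' @param c_values fitting-range multipliers.
#' @return List with \code{value} (\eqn{\kappa_t} in \eqn{k_B T} per
#'   monolayer), \code{uncertainty}, \code{fits}, \code{mu}, \code{sigma},
#'   \code{histogram}, \code{pmf}.
#' @export
extract_tilt_modulus <- function(samples, temperature = 300, n_bins = 90,
                                 c_values = c(1, 1.25, 1.5, 1.75, 2)) {
  hist <- build_histogram(samples, n_bins, range = c(0, pi / 2))
  g <- fit_gaussian(hist)
  pmf <- tilt_pmf(hist, temperature)
  fits <- fit_pmf_quadratic(pmf, g$mu, g$sigma, c_values)
  out <- modulus_from_fits(fits, scale = 2)
  c(out, list(mu = g$mu, sigma = g$sigma, histogram = hist, pmf = pmf))
}

#' Bending rigidity from splay samples
#'
#' As [extract_tilt_modulus()] but for the splay PMF: \eqn{K_c = 2b / A_L}
#' from the \code{c = 1} fit (b carries Angstrom^2).
#'
#' @param samples splay values in 1/Angstrom.
#' @param area_per_lipid \eqn{A_L} in Angstrom^2 (> 0).
#' @param temperature temperature (K).
#' @param n_bins histogram bins (default 100 over the sample range).
#' @param c_values fitting-range multipliers.
#' @param centered fit \eqn{a + b(S-\mu)^2} instead of \eqn{a + bS^2}.
#' @return List with \code{value} (\eqn{K_c} in \eqn{k_B T} per monolayer),
#'   \code{uncertainty}, \code{fits}, \code{mu}, \code{sigma},
#'   \code{histogram}, \code{pmf}.
#' @export
extract_splay_modulus <- function(samples, area_per_lipid,
                                  temperature = 300, n_bins = 100,
                                  c_values = c(1, 1.25, 1.5, 1.75, 2),
                                  centered = FALSE) {
  if (area_per_lipid <= 0) stop("area_per_lipid must be positive")
  if (pop_sd(samples) < 1e-12)
    stop("degenerate splay sample (zero variance)")
  hist <- build_histogram(samples, n_bins)
  g <- fit_gaussian(hist)
  pmf <- splay_pmf(hist, temperature)
  fits <- fit_pmf_quadratic(pmf, g$mu, g$sigma, c_values,
                            centered = centered)
  out <- modulus_from_fits(fits, scale = 2 / area_per_lipid)
  c(out, list(mu = g$mu, sigma = g$sigma, histogram = hist, pmf = pmf))
}

#' Combine per-pair splay moduli into a monolayer bending rigidity
#'
#' Splay-count-weighted harmonic combination:
#' \deqn{1/K_c = (1/\phi_{Tot}) \sum_{ij} \phi_{ij} / \chi_{ij}}
#'
#' @param chi named numeric vector of per-species-pair splay moduli
#'   (\eqn{k_B T}).
#' @param phi named numeric vector of per-pair splay counts (same names).
#' @return Combined \eqn{K_c} in \eqn{k_B T}.
#' @export
combine_splay_moduli <- function(chi, phi) {
  stopifnot(length(chi) == length(phi))
  if (!is.null(names(chi)) && !is.null(names(phi)))
    phi <- phi[names(chi)]
  if (any(chi <= 0)) stop("all splay moduli must be positive")
  if (any(phi <= 0)) stop("all splay counts must be positive")
  sum(phi) / sum(phi / chi)
}

#' Combine per-species tilt moduli into a monolayer tilt modulus
#'
#' Lipid-count-weighted harmonic combination:
#' \deqn{1/\kappa_t = (1/N_L) \sum_i N_{Li} / \chi_i}
#'
#' @param chi named numeric vector of per-species tilt moduli (\eqn{k_B T}).
#' @param counts named numeric vector of per-species lipid counts.
#' @return Combined \eqn{\kappa_t} in \eqn{k_B T}.
#' @export
combine_tilt_moduli <- function(chi, counts) {
  stopifnot(length(chi) == length(counts))
  if (!is.null(names(chi)) && !is.null(names(counts)))
    counts <- counts[names(chi)]
  if (any(chi <= 0)) stop("all tilt moduli must be positive")
  if (any(counts <= 0)) stop("all lipid counts must be positive")
  sum(counts) / sum(counts / chi)
}

#' Extract all elastic moduli from tilt and splay samples
#'
#' Runs the full fitting chain per lipid species (tilts) and per species
#' pair (splays), then combines them into monolayer moduli with the
#' count-weighted harmonic means. Optionally writes distributions, PMFs,
#' fit tables, figures and a summary to \code{outdir}.
#'
#' @param tilts named list (by species) of tilt sample data frames (from
#'   [analyze_tilts()]) or numeric vectors of angles (radians).
#' @param splays named list (by species pair) of splay sample data frames
#'   (from [analyze_splays()]) or numeric vectors (1/Angstrom).
#' @param area_per_lipid \eqn{A_L} in Angstrom^2.
#' @param temperature temperature (K).
#' @param outdir optional output directory.
#' @param nbins_tilt,nbins_splay histogram bins.
#' @param c_values fitting-range multipliers.
#' @param centered_splay_fit centre the splay quadratic on the distribution
#'   mean (for curved systems with spontaneous splay).
#' @param plots write PNG figures of distributions and PMF fits (requires
#'   \code{outdir}).
#' @return An object of class \code{"moduli_result"}.
#' @export
extract_tilt_and_splay_moduli <- function(tilts, splays, area_per_lipid,
                                          temperature = 300, outdir = NULL,
                                          nbins_tilt = 90,
                                          nbins_splay = 100,
                                          c_values = c(1, 1.25, 1.5, 1.75, 2),
                                          centered_splay_fit = FALSE,
                                          plots = TRUE) {
  if (length(tilts) == 0 && length(splays) == 0)
    stop("no samples supplied")
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tilt_res <- list()
  tilt_counts <- numeric(0)
  for (sp in names(tilts)) {
    smp <- tilts[[sp]]
    theta <- if (is.data.frame(smp)) smp$theta else as.numeric(smp)
    tilt_res[[sp]] <- extract_tilt_modulus(theta, temperature,
                                           n_bins = nbins_tilt,
                                           c_values = c_values)
    tilt_counts[sp] <- if (is.data.frame(smp))
      length(unique(smp$lipid)) else length(theta)
    if (!is.null(outdir))
      write_fit_outputs(tilt_res[[sp]], paste0("tilt_", sp), outdir, plots)
  }
  splay_res <- list()
  splay_counts <- numeric(0)
  for (pr in names(splays)) {
    smp <- splays[[pr]]
    s <- if (is.data.frame(smp)) smp$s else as.numeric(smp)
    splay_res[[pr]] <- extract_splay_modulus(s, area_per_lipid, temperature,
                                             n_bins = nbins_splay,
                                             c_values = c_values,
                                             centered = centered_splay_fit)
    splay_counts[pr] <- length(s)
    if (!is.null(outdir))
      write_fit_outputs(splay_res[[pr]],
                        paste0("splay_", gsub("\\|", "_", pr)),
                        outdir, plots)
  }
  kappa_t <- if (length(tilt_res) > 0)
    combine_tilt_moduli(vapply(tilt_res, `[[`, 0, "value"), tilt_counts)
  else NA_real_
  k_c <- if (length(splay_res) > 0)
    combine_splay_moduli(vapply(splay_res, `[[`, 0, "value"), splay_counts)
  else NA_real_
  out <- structure(list(kappa_t = kappa_t, K_c = k_c,
                        tilt = tilt_res, splay = splay_res,
                        tilt_counts = tilt_counts,
                        splay_counts = splay_counts,
                        area_per_lipid = area_per_lipid,
                        temperature = temperature),
                   class = "moduli_result")
  if (!is.null(outdir)) {
    summary_list <- list(
      kappa_t_kT = kappa_t, K_c_kT = k_c,
      area_per_lipid_A2 = area_per_lipid, temperature_K = temperature,
      tilt = lapply(tilt_res, function(r)
        list(value = r$value, uncertainty = r$uncertainty)),
      splay = lapply(splay_res, function(r)
        list(value = r$value, uncertainty = r$uncertainty)))
    jsonlite::write_json(summary_list,
                         file.path(outdir, "moduli_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(out)),
               file.path(outdir, "moduli_summary.txt"))
  }
  out
}

#' @export
print.moduli_result <- function(x, ...) {
  cat("Membrane elastic moduli (per monolayer, units of k_B T)\n")
  cat(sprintf("  area per lipid: %.2f A^2, temperature: %.1f K\n",
              x$area_per_lipid, x$temperature))
  for (sp in names(x$tilt))
    cat(sprintf("  tilt  %-12s kappa_t = %8.3f +/- %.3f\n", sp,
                x$tilt[[sp]]$value, x$tilt[[sp]]$uncertainty))
  for (pr in names(x$splay))
    cat(sprintf("  splay %-12s chi     = %8.3f +/- %.3f\n", pr,
                x$splay[[pr]]$value, x$splay[[pr]]$uncertainty))
  if (!is.na(x$kappa_t))
    cat(sprintf("  combined monolayer tilt modulus kappa_t = %.3f k_BT\n",
                x$kappa_t))
  if (!is.na(x$K_c))
    cat(sprintf("  combined monolayer bending rigidity K_c = %.3f k_BT\n",
                x$K_c))
  invisible(x)
}

write_fit_outputs <- function(res, label, outdir, plots = TRUE) {
  dist_tab <- data.frame(x = res$histogram$mids,
                         count = res$histogram$counts,
                         prob = res$histogram$prob)
  write.csv(dist_tab, file.path(outdir, paste0(label, "_distribution.csv")),
            row.names = FALSE)
  pmf_tab <- data.frame(x = res$pmf$x, pmf_kT = res$pmf$value)
  write.csv(pmf_tab, file.path(outdir, paste0(label, "_pmf.csv")),
            row.names = FALSE)
  write.csv(res$fits, file.path(outdir, paste0(label, "_fits.csv")),
            row.names = FALSE)
  if (plots) {
    ok <- tryCatch({
      png(file.path(outdir, paste0(label, "_fit.png")),
          width = 1200, height = 500, res = 110)
      plot_moduli_fit(res, label)
      dev.off()
      TRUE
    }, error = function(e) {
      warning("could not write figure for ", label, ": ",
              conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
}

#' Plot a distribution + Gaussian fit and the PMF + quadratic fit
#'
#' Two-panel diagnostic figure: the sample distribution with the fitted
#' Gaussian, the mean and the \code{[mu - sigma, mu + sigma]} fitting range,
#' and the PMF with the \code{c = 1} quadratic fit.
#'
#' @param res result of [extract_tilt_modulus()] or
#'   [extract_splay_modulus()].
#' @param label plot title prefix.
#' @return Invisibly \code{NULL}; draws on the current device.
#' @export
plot_moduli_fit <- function(res, label = "") {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- res$histogram
  plot(h$mids, h$prob, type = "h", xlab = "value", ylab = "P",
       main = paste(label, "distribution"))
  amp <- if (!is.null(res$amplitude)) res$amplitude else max(h$prob)
  xg <- seq(min(h$mids), max(h$mids), length.out = 200)
  lines(xg, max(h$prob) * exp(-(xg - res$mu)^2 / (2 * res$sigma^2)),
        col = "darkgreen")
  abline(v = res$mu, col = "red", lty = 2)
  abline(v = res$mu + c(-1, 1) * res$sigma, col = "blue", lty = 2)
  plot(res$pmf$x, res$pmf$value, xlab = "value", ylab = "PMF (k_B T)",
       main = paste(label, "PMF"))
  f1 <- res$fits[which.min(res$fits$c), ]
  lines(xg, f1$a + f1$b * xg^2, col = "red", lty = 2)
  invisible(NULL)
}
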