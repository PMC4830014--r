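---
title: "Extracting membrane elastic moduli from lipid tilt and splay fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting membrane elastic moduli from lipid tilt and splay fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltsplay)
```

## The model

The mechanical response of a lipid monolayer to small deformations is, to
harmonic order, governed by two material constants: the tilt modulus
$\kappa_t$, which penalizes deviations of the lipid director from the local
membrane normal, and the bending rigidity $K_c$, which penalizes curvature.
Both can be read off the equilibrium fluctuations of microscopic,
per-lipid degrees of freedom observed in a molecular dynamics trajectory,
which is what this package computes. Unlike spectral analyses of membrane
undulations, the fluctuation approach works for small patches (a few
hundred lipids), for mixtures, and for curved assemblies such as the
inverted-hexagonal phase.

For a lipid tilted by a small angle $\theta$ between its director $\vec n$
(the unit vector from its tail site to its head site) and the local
interface normal $\vec N$, the equilibrium distribution is

$$P(\theta) = C \sin\theta \, \exp\!\left(-\frac{\kappa_t \theta^2}{2 k_B T}\right),$$

so the potential of mean force $-k_B T \ln(P(\theta)/\sin\theta)$ is
quadratic with curvature $\kappa_t/2$; fitting $a + b\theta^2$ gives
$\kappa_t = 2b$.

The bending rigidity comes from pairwise *splays*: for two nearby lipids at
distance-site positions $p_1$, $p_2$, the finite-difference directional
derivative

$$S_i = \frac{(n_2 - n_1)\cdot e + (N_2 - N_1)\cdot e}{h},$$

where $e$ is the unit vector from lipid 1 to lipid 2 orthogonalized
against $N_1$ and $h$ the tangential separation. Weakly correlated splays
are Gaussian,

$$P(S_i) = C \exp\!\left(-\frac{K_c A_L S_i^2}{2 k_B T}\right),$$

with $A_L$ the area per lipid, so a quadratic fit of the splay PMF gives
$A_L K_c = 2b$. For mixtures, per-species tilt moduli $\chi_i$ and
per-species-pair splay moduli $\chi^{12}_{ij}$ are combined by
count-weighted harmonic means,

$$\frac{1}{K_c} = \frac{1}{\phi_{Tot}} \sum_{ij} \frac{\phi_{ij}}{\chi^{12}_{ij}},
\qquad
\frac{1}{\kappa_t} = \frac{1}{N_L} \sum_i \frac{N_{Li}}{\chi_i}.$$

All moduli are reported per monolayer in units of $k_B T$; temperature is
carried only as metadata because the $k_B T$ scale makes the fitted values
dimensionless in energy.

## The reference shape: interface and normal field

Tilt and splay are fluctuations *around the time-averaged shape* of the
assembly, so the analysis needs a reference surface and its normal field:

1. **Periodic extension.** The system is replicated into neighbouring unit
   cells (`extend_trajectory`), the trajectory is wrapped around the centre
   of interest with residues kept whole (`wrap_trajectory`), and per-residue
   flags restrict all statistics to the lipids of the central cell. After
   this step no later stage needs to know about periodic boundaries, and
   triclinic cells are handled by the fractional-coordinate wrap.
2. **Alignment.** Planar bilayers are aligned by translating the membrane
   centre of mass to the origin. Curved assemblies are aligned per frame by
   maximizing the overlap of the solvent with a smoothed solvent density map
   of the first frame while minimizing the lipid overlap
   (`align_trajectory_on_first_frame`).
3. **Interface.** The water and lipid densities averaged over the aligned
   frames are compared on a common 1 Å grid; the interface is the set of
   grid-edge points where they are equal, found by linear interpolation of
   the density difference along grid edges (`extract_interface`).
4. **Normals.** Each interface point gets the normal of the least-squares
   plane through all surface points within 10 Å, oriented toward the
   solvent side (`compute_normals`).

Each lipid's tilt is then measured against the normal at the interface
point nearest to its headgroup centre of mass; splays take the normals
nearest to each member of the pair.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| map resolution | 4 Å | Gaussian width $s$ = resolution/2; each atom integrates to its mass, truncated at $3.5s$ |
| low-pass filter width | 4 Å | Gaussian blur applied to the alignment reference density |
| alignment grid spacing | 0.5 Å | finer than the 1 Å analysis mesh; the recovered transforms are limited by trilinear discretization of the map, and 0.5 Å keeps that bias near 0.05° |
| plane-fit radius | 10 Å | neighbourhood of the local normal estimate |
| splay cutoff | 10 Å | pairs with distance-site separation below it enter the splay statistics; about nearest neighbours at typical areas per lipid |
| tilt bins | 90 over $[0°, 90°]$ | 1° bins |
| splay bins | 100 | over the sample range |
| fitting ranges | $c \in \{1, 1.25, 1.5, 1.75, 2\}$ | windows $[\mu - c\sigma, \mu + c\sigma]$ around the Gaussian fit of the distribution |

The modulus is taken from the $c = 1$ fit; the uncertainty is the
population standard deviation of the moduli over the five ranges, which
measures the sensitivity of the harmonic approximation to the fitting
window rather than a statistical error.

## Numerical choices

* **Density constants.** The Gaussian-sum density uses
  $C = (2\pi s^2)^{-3/2}$ and $D = 1/(2s^2)$ so that maps are
  mass-normalized; the alignment optimum is unaffected by the choice of
  $C$.
* **Cutoff versus step.** The pair *cutoff* tests the full 3-D separation
  of the distance sites (which keeps tail-to-tail cross-leaflet pairs out),
  while the finite-difference denominator $h$ is the tangential component
  of the separation, consistent with $e \perp N_1$. For planar systems at
  equal distance-site heights the two coincide.
* **Sign conventions.** Normals point toward the solvent. Tilts are folded
  to $[0°, 90°]$ via $\theta = \arccos |n \cdot N|$, which makes the
  estimator leaflet-agnostic under that orientation convention. The
  normal-difference term of $S_i$ enters with a plus sign, the exact
  finite-difference form; `compute_splay(normal_sign = -1)` exposes the
  variant that differentiates $n - N$ instead. The two only differ on
  curved interfaces.
* **Splay quadratic.** Fitted as $a + bS^2$ (not centred); a centred
  variant $a + b(S-\mu)^2$ is available via `centered_splay_fit` for
  curved systems with non-zero spontaneous splay.
* **Degenerate inputs.** Pairs whose separation is parallel to the normal
  are skipped; zero-variance splay samples, empty selections and
  non-invertible cells raise errors; Gaussian fits that do not converge
  fall back to histogram moments with a warning.
* **Optimization.** Frame alignment is a derivative-free Nelder-Mead
  search over three intrinsic z-y-x Euler angles (about the frame
  centroid) and three translations, warm-started from the previous frame,
  with a deterministic second start at the identity and iterated restarts.
  The restarts matter on quasi-symmetric assemblies (a cylinder is nearly
  invariant under rotations about its axis), where a single run can stall
  in an almost-flat valley of the score.
* **Ties.** Nearest-interface-point queries are exact and break distance
  ties by the lowest point index, so results are independent of the
  spatial-binning accelerator.

## The synthetic data generators

`generate_planar_trajectory` builds a pseudo-bilayer with *known* moduli:
three-site lipids (head `HD`, mid `MD`, tail `TL`) on a jittered lattice
at the requested area per lipid, explicit solvent slabs, and directors

$$n = (t_x, t_y, \sqrt{1 - t_x^2 - t_y^2}),$$

where $(t_x, t_y)$ is a stationary Gaussian random field over the lipid
sites with covariance $C_0 \exp(-r^2 / 2\ell^2)$ under the minimum-image
metric (so pairs across the periodic boundary are statistically
consistent with the extension-based analysis). The field gives Rayleigh
tilts with per-component variance $C_0$ and Gaussian pair splays with
variance $2(C_0 - C(r))/r^2$.

The two field parameters are *solved, not tuned*: at generation time the
analytic tilt density and the analytic splay mixture density implied by
$(C_0, \ell)$ and the realized pair geometry are pushed through the same
$c = 1$ fitting convention the estimator uses (continuous least squares on
a quadrature grid — no sampling), and $C_0$ and $\ell$ are root-solved so
the implied moduli equal the requested $\kappa_t$ and $K_c$. The recorded
ground truth is therefore calibrated by construction; for the defaults
($\kappa_t = 12\,k_BT$, $K_c = 10\,k_BT$, $A_L = 60$ Å², 10 Å cutoff)
the solution is $C_0 \approx 0.083$ and $\ell \approx 5.6$ Å, a
correlation length safely below the pair cutoff. A requested combination
that the construction cannot reach (a stiff tilt field bounds the softest
achievable splay distribution) raises an error instead of silently
shifting the truth.

The head-site mass (100 amu against 300 amu mid/tail sites and 18 amu
solvent at number density 1/30 Å⁻³) is chosen so that the smeared
head-layer density peak matches half the bulk solvent density at the
default map resolution, which places the iso-density interface at the
head plane — the recorded `boundary_z`.

`generate_cylindrical_trajectory` builds an inverted-hexagonal-like water
cylinder wrapped by radially oriented lipids. With a list of known rigid
transforms it produces alignment ground truth (each frame a transformed
copy of one configuration); without it the solvent is resampled per frame
to exercise density averaging on curved geometry.

What the generators deliberately do **not** emulate: force-field dynamics,
temporal correlation between frames (fields are drawn independently per
frame), lipid diffusion, protrusions, undulations of the mean plane, and
area-per-lipid fluctuations. Passing the recovery tests therefore
demonstrates the correctness of the geometric and statistical machinery —
interface extraction, normal fields, pair bookkeeping, PMF fits,
mixture combination — not the convergence behaviour of real MD sampling,
which remains the user's responsibility (block averaging, longer
trajectories).

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run, among smaller cases: the
full planar pipeline at 200 lipids per leaflet and 500 frames (tilt
recovery within 10%, bending rigidity within 15% of the calibrated
truth, with averaged densities computed on a 20-frame stride — the
geometry is static up to director and solvent noise, so a stride changes
the interface by far less than the mesh size); direct sampler recoveries
at $2 \times 10^5$ samples (within 5%); and alignment recovery on an
8-frame cylindrical system (within 0.5° and 0.2 Å per frame).

## Worked example

```{r example, eval = FALSE}
library(tiltsplay)

# synthetic bilayer with known moduli
gen <- generate_planar_trajectory(
  synthetic_spec("planar", n_lipids = 200, frames = 500,
                 kappa_t = 12, K_c = 10, A_L = 60, seed = 1))

# periodic extension and wrapping around the membrane
ext <- extend_trajectory(gen$trajectory,
                         list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                         c(2, 2, 1))
com <- analyze_com_positions(ext, "cname=M")
ext <- translate_frames(wrap_trajectory(ext, com), -com)

# interface, normals, tilt and splay samples
defs <- lipid_definitions("LIP",
                          head_group = c(LIP = "aname=HD"),
                          tail = c(LIP = "aname=TL"),
                          distance = c(LIP = "aname=MD"),
                          solvent_names = "SOL")
res <- analyze_lipid_tilt_and_splay(ext, defs,
                                    water_expr = "cname=W and rname=SOL",
                                    lipid_expr = "cname=M and rname=LIP",
                                    density_frames = seq(1, 500, 20))

# moduli
a_l <- analyze_area_per_lipid(ext, "LIP")
extract_tilt_and_splay_moduli(res$tilts, res$splays, a_l,
                              outdir = "moduli_out")
```

## Known limitations

* The density aligner is a local optimizer: trajectories whose frames
  wander far from the reference (large drift between consecutive frames)
  can defeat the warm start. Global multi-start alignment is out of scope.
* Normals from plane fits are biased on surfaces whose curvature radius
  approaches the fit radius; with the default 10 Å fit radius the bias is
  a few degrees at a 20 Å curvature radius and grows for tighter
  geometry.
* The pivotal plane is taken where the user's distance selections put it;
  determining it from simulations is a separate procedure and not
  reproduced here.
* A single area per lipid is shared by all species of a mixture;
  per-species areas would require reweighting the splay combination and
  are not implemented.
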