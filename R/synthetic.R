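#' Generate a synthetic Bcd ensemble
#'
#' Draws per-embryo exponential-gradient parameters `(A, l)` independently
#' from lognormal distributions (guaranteeing positivity), emulating
#' embryo-to-embryo variation of the Bicoid gradient. Two presets bracket
#' the two normalization regimes of real ensembles: `"wide"` (large
#' amplitude spread, as after basic background-subtraction normalization;
#' `A_cv = 0.3`, `l_cv = 0.05`) and `"narrow"` (variance-minimizing
#' normalization; `A_cv = 0.08`, `l_cv = 0`, which by construction gives a
#' Bcd threshold-position sd of `sdlog(A)/l_mean` of about 1.2 %EL).
#'
#' @param n Number of embryos (>= 2).
#' @param preset `"narrow"`, `"wide"` or `"custom"`.
#' @param A_mean,l_mean Mean amplitude (relative units) and decay constant
#'   (1/%EL).
#' @param A_cv,l_cv Coefficients of variation (taken from the preset unless
#'   `preset = "custom"`).
#' @param seed Mandatory RNG seed.
#' @return A [bcd_ensemble()] (tag `"synthetic"`), with the generating
#'   configuration in attribute `config`.
#' @export
#' @examples
#' ens <- gen_bcd_ensemble(10, "narrow", seed = 1)
#' head(ens)
gen_bcd_ensemble <- function(n, preset = c("narrow", "wide", "custom"),
                             A_mean = 150, l_mean = 0.0665,
                             A_cv = NULL, l_cv = NULL, seed) {
  preset <- match.arg(preset)
  if (missing(seed)) .err("seed is mandatory", "gapcanal_invalid_input")
  if (n < 2L) .err("n must be >= 2", "gapcanal_invalid_input")
  defaults <- switch(preset,
                     narrow = c(A_cv = 0.08, l_cv = 0),
                     wide = c(A_cv = 0.3, l_cv = 0.05),
                     custom = c(A_cv = 0.1, l_cv = 0.02))
  if (is.null(A_cv)) A_cv <- defaults[["A_cv"]]
  if (is.null(l_cv)) l_cv <- defaults[["l_cv"]]
  draw <- function(n, mean, cv) {
    if (cv == 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  ab <- .with_seed(seed, list(A = draw(n, A_mean, A_cv),
                              l = draw(n, l_mean, l_cv)))
  ens <- bcd_ensemble(ab$A, ab$l)
  attr(ens, "config") <- list(n = n, preset = preset, A_mean = A_mean,
                              A_cv = A_cv, l_mean = l_mean, l_cv = l_cv,
                              seed = seed)
  ens
}

#' Generate synthetic raw intensity profiles
#'
#' Emulates unprocessed per-embryo gradient data: an exponential Bcd signal
#' with optional per-embryo scale and constant offset, a shared quadratic
#' staining background, and Gaussian measurement noise. The generating
#' parameters are returned for recovery tests.
#'
#' @param n Number of embryos (ignored when `ensemble` is supplied).
#' @param x Sampling positions (%EL).
#' @param background Quadratic background coefficients `(q0, q1, q2)`.
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param scale_cv Lognormal cv of per-embryo multiplicative scales.
#' @param offset_sd Sd of per-embryo constant offsets (absolute value
#'   taken, so offsets are >= 0).
#' @param ensemble Optional [bcd_ensemble()] to use as the true gradients.
#' @param seed Mandatory RNG seed.
#' @return List with `profiles` (list of data.frames `x`, `intensity`),
#'   `truth` (data.frame `embryo_id`, `A`, `l`, `scale`, `offset`),
#'   `background`.
#' @export
gen_raw_profiles <- function(n = 20L, x = seq(5, 92, by = 1),
                             background = c(20, -0.1, 0.002),
                             noise_sd = 2, scale_cv = 0, offset_sd = 0,
                             ensemble = NULL, seed) {
  if (missing(seed)) .err("seed is mandatory", "gapcanal_invalid_input")
  if (is.null(ensemble)) {
    ensemble <- gen_bcd_ensemble(n, "wide", seed = .sub_seed(seed, 1L))
  }
  n <- nrow(ensemble)
  q <- background[1] + background[2] * x + background[3] * x^2
  gen <- .with_seed(.sub_seed(seed, 2L), {
    scales <- if (scale_cv > 0) {
      sdlog <- sqrt(log(1 + scale_cv^2))
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    } else rep(1, n)
    offsets <- if (offset_sd > 0) abs(stats::rnorm(n, 0, offset_sd))
               else rep(0, n)
    profiles <- lapply(seq_len(n), function(j) {
      signal <- scales[j] * ensemble$A[j] * exp(-ensemble$l[j] * x)
      noise <- if (noise_sd > 0) stats::rnorm(length(x), 0, noise_sd)
               else 0
      data.frame(x = x, intensity = signal + q + offsets[j] + noise)
    })
    list(profiles = profiles, scales = scales, offsets = offsets)
  })
  list(profiles = gen$profiles,
       truth = data.frame(embryo_id = ensemble$embryo_id, A = ensemble$A,
                          l = ensemble$l, scale = gen$scales,
                          offset = gen$offsets),
       background = background)
}

#' Synthetic maternal Hb gradient
#'
#' A strictly decreasing logistic gradient bounded by the biological
#' initial-condition range `[0, 100]`:
#' \eqn{hb_0(x) = 100 / (1 + e^{(x - x_{1/2})/s})}, equal to 50 at the
#' midpoint.
#'
#' @param midpoint Half-maximum position (%EL).
#' @param steepness Logistic scale (%EL); smaller is steeper.
#' @return Function of x.
#' @export
#' @examples
#' hb0 <- gen_maternal_hb()
#' hb0(47)  # 50
gen_maternal_hb <- function(midpoint = 47, steepness = 5) {
  stopifnot(steepness > 0)
  function(x) 100 * stats::plogis(-(x - midpoint) / steepness)
}

#' Synthetic Cad and Tll external-input tables
#'
#' A smooth, posteriorly increasing Cad surface with a mild rise over the
#' cycle-14A time classes, and a Tll profile confined to the posterior pole
#' (exactly zero anterior of `tll_onset`, in particular throughout the
#' 37-57 %EL analysis window where Tll does not act).
#'
#' @param x Spatial grid (%EL).
#' @param cad_max,cad_mid,cad_width Cad logistic parameters.
#' @param tll_max,tll_mid,tll_width,tll_onset Tll profile parameters.
#' @return List with elements `cad` and `tll`, each an
#'   [external_input_table()].
#' @export
gen_external_inputs <- function(x = seq(35, 92, by = 1), cad_max = 150,
                                cad_mid = 60, cad_width = 8,
                                tll_max = 120, tll_mid = 85,
                                tll_width = 3, tll_onset = 70) {
  cad_space <- stats::plogis((x - cad_mid) / cad_width)
  cad_vals <- outer(cad_space, 0.55 + 0.45 * (1:8) / 8) * cad_max
  c0 <- stats::plogis((tll_onset - tll_mid) / tll_width)
  tll_space <- pmax(0, (stats::plogis((x - tll_mid) / tll_width) - c0) /
                      (1 - c0))
  tll_vals <- matrix(tll_space * tll_max, nrow = length(x), ncol = 8L)
  list(cad = external_input_table("cad", x, cad_vals),
       tll = external_input_table("tll", x, tll_vals))
}

#' Circuit parameter fixtures
#'
#' Hand-designed parameter sets with documented phase-portrait properties,
#' used throughout the test suite and examples:
#' \describe{
#'   \item{`bistable_border`}{hb and Kr mutually repressing with weak
#'     self-activation, hb activated by Bcd and Kr by Cad: across the
#'     37-57 %EL window (with the default synthetic inputs) the autonomous
#'     per-nucleus system has an hb-ON attractor (code `1000`) and a Kr-ON
#'     attractor (code `0100`) whose Hb-axis basin boundary rises to
#'     posterior and crosses the default maternal Hb gradient inside the
#'     window.}
#'   \item{`monostable`}{no gap-gap interactions (`T = 0`), hence a unique
#'     globally attracting equilibrium at every input.}
#'   \item{`decoupled`}{`T = 0` with distinct per-gene rates; equilibria
#'     factor into per-gene closed forms `R g(u)/lambda`.}
#' }
#'
#' @param preset One of `"bistable_border"`, `"monostable"`, `"decoupled"`.
#' @return A [circuit_parameters()] object.
#' @export
gen_parameter_fixture <- function(preset = c("bistable_border",
                                             "monostable", "decoupled")) {
  preset <- match.arg(preset)
  zero4 <- matrix(0, 4, 4)
  switch(preset,
    bistable_border = {
      Tm <- zero4
      Tm[1, 1] <- 0.04; Tm[1, 2] <- -0.06   # hb: self-activation, Kr repression
      Tm[2, 2] <- 0.04; Tm[2, 1] <- -0.06   # Kr: self-activation, hb repression
      circuit_parameters(
        R = c(16, 16, 0, 0), T_matrix = Tm,
        bcd_weight = c(0.3, 0.05, 0, 0),
        ext_weight = cbind(cad = c(0, 0.05, 0, 0), tll = c(0, 0, 0, 0)),
        h = c(-3.5, -3, 0, 0), lambda = c(0.08, 0.08, 0.1, 0.1),
        D = c(0.2, 0.2, 0, 0))
    },
    monostable = circuit_parameters(
      R = c(10, 10, 10, 10), T_matrix = zero4,
      bcd_weight = c(0.1, 0, 0, 0),
      ext_weight = cbind(cad = c(0, 0.05, 0, 0), tll = c(0, 0, 0, 0)),
      h = c(-1, -1, -1, -1), lambda = c(0.1, 0.1, 0.1, 0.1),
      D = c(0.1, 0.1, 0.1, 0.1)),
    decoupled = circuit_parameters(
      R = c(8, 12, 16, 20), T_matrix = zero4,
      bcd_weight = c(0.2, 0, 0, 0),
      ext_weight = cbind(cad = c(0, 0.1, 0, 0), tll = c(0, 0, 0, 0)),
      h = c(-2, -1, 0, 1), lambda = c(0.1, 0.1, 0.2, 0.2),
      D = c(0, 0, 0, 0)))
}

#' Analytically solvable toy systems
#'
#' Reduced systems inside the same circuit family, with closed-form facts
#' used as independent oracles:
#' \describe{
#'   \item{`1d_bistable`}{Only hb is active, with self-activation tuned so
#'     the fixed-point equation `R g(T v + h) = lambda v` has stable roots
#'     near 6 and 198 and an unstable root (the Hb-axis separatrix) at
#'     exactly 50: the threshold input is chosen as
#'     `h = -1/sqrt(3) - T * 50` so that `g(u(50)) = lambda * 50 / R`
#'     holds identically.}
#'   \item{`2d_saddle`}{hb and Kr symmetrically mutually repressing
#'     (`T12 = T21 = -0.05`, `h = 5`, `R = 16`, `lambda = 0.08`): the
#'     symmetric state (100, 100, 0, 0) is an exact saddle (u = 0,
#'     `g = 1/2`, `R g / lambda = 100`) with eigenvalues
#'     `-lambda ± R g'(0) |T12|` = 0.32 and -0.48 along the eigen-
#'     directions (1, -1) and (1, 1), plus the passive decay rates.}
#' }
#'
#' The returned `facts` are re-derived numerically (root bracketing of the
#' scalar fixed-point equation) rather than hard-coded, so they stay
#' consistent if a caller modifies the parameters.
#'
#' @param kind `"1d_bistable"` or `"2d_saddle"`.
#' @return List with `params` (a [circuit_parameters()]), `bcd`, `cad`
#'   (the inputs under which the facts hold, both 0), and `facts`.
#' @export
gen_toy_system <- function(kind = c("1d_bistable", "2d_saddle")) {
  kind <- match.arg(kind)
  if (kind == "1d_bistable") {
    R1 <- 16; lam1 <- 0.08; Tself <- 0.05
    h1 <- -1 / sqrt(3) - Tself * 50
    Tm <- matrix(0, 4, 4); Tm[1, 1] <- Tself
    params <- circuit_parameters(
      R = c(R1, 0, 0, 0), T_matrix = Tm, bcd_weight = rep(0, 4),
      ext_weight = rep(0, 4), h = c(h1, 0, 0, 0),
      lambda = c(lam1, 0.1, 0.1, 0.1), D = rep(0, 4))
    # all roots of the scalar fixed-point equation on [0, 1.5 R/lambda]
    fp <- function(v) R1 * regulation_g(Tself * v + h1) - lam1 * v
    grid <- seq(0, 1.5 * R1 / lam1, length.out = 4001L)
    fg <- fp(grid)
    roots <- sort(vapply(
      which(fg[-length(fg)] * fg[-1L] <= 0),
      function(i) stats::uniroot(fp, c(grid[i], grid[i + 1L]),
                                 tol = 1e-12)$root, numeric(1)))
    roots <- roots[c(TRUE, diff(roots) > 1e-6)]
    stopifnot(length(roots) == 3L)
    facts <- list(equilibria_hb = roots,
                  separatrix = roots[2L],
                  attractors_hb = roots[c(1L, 3L)])
  } else {
    R1 <- 16; lam1 <- 0.08; Tx <- -0.05; h1 <- 5
    Tm <- matrix(0, 4, 4); Tm[1, 2] <- Tx; Tm[2, 1] <- Tx
    params <- circuit_parameters(
      R = c(R1, R1, 0, 0), T_matrix = Tm, bcd_weight = rep(0, 4),
      ext_weight = rep(0, 4), h = c(h1, h1, 0, 0),
      lambda = c(lam1, lam1, 0.1, 0.1), D = rep(0, 4))
    gp0 <- regulation_g_prime(0)
    facts <- list(
      saddle = c(hb = 100, Kr = 100, gt = 0, kni = 0),
      eigenvalues = c(-lam1 - R1 * gp0 * Tx,   # 0.32, eigvec (1,-1)
                      -lam1 + R1 * gp0 * Tx,   # -0.48, eigvec (1,1)
                      -0.1, -0.1),
      unstable_direction = c(1, -1, 0, 0) / sqrt(2))
  }
  list(params = params, bcd = 0, cad = 0, facts = facts)
}
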