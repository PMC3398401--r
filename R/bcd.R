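#' Exponential Bcd gradient of one embryo
#'
#' The Bcd concentration profile of an individual embryo, approximated as
#' \eqn{v^{Bcd}(x) = A e^{-l x}} with amplitude `A` (relative units) and
#' decay constant `l` (1/%EL).
#'
#' @param A Amplitude, > 0.
#' @param l Decay constant, > 0.
#' @param embryo_id Optional identifier.
#' @return Object of class `bcd_exponential`.
#' @export
bcd_exponential <- function(A, l, embryo_id = NA_integer_) {
  if (!is.numeric(A) || !is.numeric(l) || A <= 0 || l <= 0) {
    .err("A and l must be positive", "gapcanal_invalid_input")
  }
  structure(list(A = as.numeric(A), l = as.numeric(l),
                 embryo_id = embryo_id), class = "bcd_exponential")
}

#' Evaluate a Bcd exponential at positions
#' @param profile A [bcd_exponential()].
#' @param x Positions in %EL.
#' @return Concentrations `A * exp(-l * x)`.
#' @export
eval_bcd <- function(profile, x) profile$A * exp(-profile$l * x)

#' @export
print.bcd_exponential <- function(x, ...) {
  cat(sprintf("Bcd exponential: A = %.4g, l = %.4g /%%EL (embryo %s)\n",
              x$A, x$l, as.character(x$embryo_id)))
  invisible(x)
}

#' Bcd ensemble
#'
#' A set of per-embryo exponential Bcd gradients with unique embryo ids.
#'
#' @param A,l Numeric vectors of amplitudes and decay constants.
#' @param embryo_id Unique identifiers (default 1..n).
#' @param normalization_tag `"basic"`, `"variance_minimizing"` or
#'   `"synthetic"`.
#' @return Object of class `bcd_ensemble`: a data.frame with columns
#'   `embryo_id`, `A`, `l` and the tag as an attribute.
#' @export
bcd_ensemble <- function(A, l, embryo_id = seq_along(A),
                         normalization_tag = "synthetic") {
  if (length(A) == 0L) .err("ensemble must be nonempty",
                            "gapcanal_invalid_input")
  if (anyDuplicated(embryo_id)) .err("embryo ids must be unique",
                                     "gapcanal_invalid_input")
  if (any(A <= 0) || any(l <= 0)) .err("A and l must be positive",
                                       "gapcanal_invalid_input")
  df <- data.frame(embryo_id = embryo_id, A = as.numeric(A),
                   l = as.numeric(l))
  attr(df, "normalization_tag") <- normalization_tag
  class(df) <- c("bcd_ensemble", "data.frame")
  df
}

#' Extract one member of an ensemble as a Bcd exponential
#' @param ensemble A [bcd_ensemble()].
#' @param embryo_id The id of the member.
#' @return A [bcd_exponential()].
#' @export
ensemble_member <- function(ensemble, embryo_id) {
  i <- match(embryo_id, ensemble$embryo_id)
  if (is.na(i)) .err("embryo id not in ensemble", "gapcanal_invalid_input")
  bcd_exponential(ensemble$A[i], ensemble$l[i], ensemble$embryo_id[i])
}

#' Remove a quadratic background from a raw intensity profile
#'
#' Basic normalization assumes the Bcd signal is exponential on top of a
#' quadratic background \eqn{q(x) = q_0 + q_1 x + q_2 x^2}; the corrected
#' profile is `raw - q(x)`, floored at zero. A degenerate-profile warning is
#' raised when the background exceeds the signal everywhere.
#'
#' @param raw Data frame with columns `x` (strictly increasing, %EL) and
#'   `intensity`.
#' @param background Numeric length-3 quadratic coefficients `(q0, q1, q2)`.
#' @return Data frame with columns `x`, `intensity` (corrected).
#' @export
remove_quadratic_background <- function(raw, background) {
  stopifnot(is.data.frame(raw), all(c("x", "intensity") %in% names(raw)))
  if (any(diff(raw$x) <= 0)) .err("x must be strictly increasing",
                                  "gapcanal_invalid_input")
  if (length(background) != 3L) .err("background must be (q0, q1, q2)",
                                     "gapcanal_invalid_input")
  q <- background[1] + background[2] * raw$x + background[3] * raw$x^2
  corrected <- pmax(raw$intensity - q, 0)
  if (all(corrected == 0)) {
    .warn("background exceeds signal everywhere: degenerate profile",
          "gapcanal_degenerate_profile")
  }
  data.frame(x = raw$x, intensity = corrected)
}

#' Fit an exponential gradient to a corrected profile
#'
#' Least-squares fit of \eqn{A e^{-l x}}: log-linear regression on the
#' strictly positive samples, followed by one nonlinear least-squares polish
#' on the original scale. Profiles whose log-linear fit explains less than
#' `r2_min` of the variance (or whose fitted decay is non-positive) are
#' flagged `nonexponential`, mirroring the rejection of non-exponential
#' embryos from gradient ensembles.
#'
#' @param profile Data frame with columns `x`, `intensity`.
#' @param x_range Optional `[a, b]` restriction in %EL.
#' @param r2_min Log-linear R-squared threshold for the nonexponential flag.
#' @return A [bcd_exponential()] with attributes `r_squared` (log-linear),
#'   `nonexponential` (logical) and `n_points`.
#' @export
fit_exponential <- function(profile, x_range = NULL, r2_min = 0.9) {
  x <- profile$x; y <- profile$intensity
  if (!is.null(x_range)) {
    keep <- x >= x_range[1] & x <= x_range[2]
    x <- x[keep]; y <- y[keep]
  }
  pos <- y > 0
  if (sum(pos) < 3L) {
    .err("need at least 3 strictly positive samples to fit",
         "gapcanal_unfittable")
  }
  xf <- x[pos]; yf <- y[pos]
  fit <- stats::lm(log(yf) ~ xf)
  ss_tot <- sum((log(yf) - mean(log(yf)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  l0 <- -unname(stats::coef(fit)[2L])
  A0 <- exp(unname(stats::coef(fit)[1L]))
  nonexp <- !is.finite(l0) || l0 <= 1e-8 || r2 < r2_min
  A1 <- A0; l1 <- max(l0, 1e-8)
  if (!nonexp) {
    polish <- try(minpack.lm::nlsLM(
      yf ~ A * exp(-l * xf), start = list(A = A0, l = l0),
      lower = c(A = 1e-12, l = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (!inherits(polish, "try-error")) {
      cf <- stats::coef(polish)
      A1 <- unname(cf[["A"]]); l1 <- unname(cf[["l"]])
    }
  }
  out <- bcd_exponential(A1, l1)
  attr(out, "r_squared") <- r2
  attr(out, "nonexponential") <- nonexp
  attr(out, "n_points") <- sum(pos)
  out
}

#' Variance-minimizing ensemble normalization
#'
#' Alternative normalization: chooses a per-embryo concentration scale
#' `s_j > 0` and constant background offset `b_j` so that the rescaled
#' profiles \eqn{s_j (y_j(x) - b_j)} have minimal summed across-embryo
#' variance over a common spatial grid, subject to the gauge that the grand
#' mean of the normalized ensemble equals the grand mean of the raw
#' ensemble (preventing the trivial collapse to zero). Optimization is by
#' alternating closed-form least-squares updates of each `(s_j, b_j)`
#' against the current ensemble mean profile, iterated to convergence.
#'
#' @param raws List of data frames with columns `x`, `intensity` (the raw
#'   profiles, possibly on different grids; interpolated to a common grid).
#' @param grid Optional common x grid (default: union range, 1 %EL step).
#' @param max_iter,tol Iteration controls (objective change tolerance).
#' @return List with `ensemble` (a [bcd_ensemble()] of exponential fits,
#'   tagged `variance_minimizing`), `normalized` (list of data frames),
#'   `scale`, `offset`, and `objective` (the final summed variance).
#' @export
minimize_ensemble_variance <- function(raws, grid = NULL, max_iter = 500L,
                                       tol = 1e-10) {
  if (length(raws) < 2L) .err("need at least 2 profiles",
                              "gapcanal_invalid_input")
  if (is.null(grid)) {
    lo <- max(vapply(raws, function(p) min(p$x), numeric(1)))
    hi <- min(vapply(raws, function(p) max(p$x), numeric(1)))
    if (hi <= lo) .err("profiles have no common x range",
                       "gapcanal_invalid_input")
    grid <- seq(lo, hi, by = 1)
  }
  Y <- vapply(raws, function(p) stats::approx(p$x, p$intensity,
                                              xout = grid)$y,
              numeric(length(grid)))
  Y <- matrix(Y, nrow = length(grid))
  nj <- ncol(Y)
  mu0 <- mean(Y)
  s <- rep(1, nj); b <- rep(0, nj)
  norm_mat <- function(s, b) sweep(Y, 2L, b, "-") %*% diag(s, nj)
  objective <- function(Z) sum(apply(Z, 1L, stats::var))
  Z <- norm_mat(s, b)
  obj <- objective(Z)
  best <- list(s = s, b = b, obj = obj)
  for (it in seq_len(max_iter)) {
    m <- rowMeans(Z)
    for (j in seq_len(nj)) {
      # minimize || s_j * y_j - c_j - m ||^2 over (s_j, c_j); b_j = c_j/s_j
      fitj <- stats::lm.fit(cbind(Y[, j], -1), m)
      sj <- fitj$coefficients[1L]; cj <- fitj$coefficients[2L]
      if (!is.finite(sj) || sj <= 1e-12) { sj <- s[j]; cj <- s[j] * b[j] }
      s[j] <- sj; b[j] <- cj / sj
    }
    Z <- norm_mat(s, b)
    # gauge: keep the grand mean at its raw value
    gm <- mean(Z)
    if (is.finite(gm) && abs(gm) > 1e-12) {
      s <- s * mu0 / gm
      Z <- norm_mat(s, b)
    }
    new_obj <- objective(Z)
    if (new_obj < best$obj) best <- list(s = s, b = b, obj = new_obj)
    if (abs(obj - new_obj) <= tol * max(1, obj)) { obj <- new_obj; break }
    obj <- new_obj
  }
  s <- best$s; b <- best$b; obj <- best$obj
  Z <- norm_mat(s, b)
  normalized <- lapply(seq_len(nj), function(j) {
    data.frame(x = grid, intensity = Z[, j])
  })
  fits <- lapply(normalized, function(p) {
    p$intensity <- pmax(p$intensity, 0)
    fit_exponential(p)
  })
  ens <- bcd_ensemble(A = vapply(fits, function(f) f$A, numeric(1)),
                      l = vapply(fits, function(f) f$l, numeric(1)),
                      normalization_tag = "variance_minimizing")
  list(ensemble = ens, normalized = normalized, scale = s, offset = b,
       objective = obj)
}

#' Select the median Bcd profile of an ensemble
#'
#' Returns the member whose standardized `(A, l)` pair is closest (Euclidean
#' distance) to the centroid of the standardized parameter cloud; ties are
#' broken by the smallest embryo id.
#'
#' @param ensemble A [bcd_ensemble()].
#' @return A [bcd_exponential()] (the selected member).
#' @export
select_median_profile <- function(ensemble) {
  A <- ensemble$A; l <- ensemble$l
  zs <- function(v) {
    s <- stats::sd(v)
    if (length(v) < 2L || !is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  d <- sqrt(zs(A)^2 + zs(l)^2)
  ord <- order(d, ensemble$embryo_id)
  ensemble_member(ensemble, ensemble$embryo_id[ord[1L]])
}

#' Position where a Bcd gradient crosses a threshold concentration
#'
#' For \eqn{v(x) = A e^{-l x}} and threshold `c` with `0 < c < A`, the
#' crossing is at \eqn{x = \ln(A/c)/l}.
#'
#' @param profile A [bcd_exponential()].
#' @param c Threshold concentration.
#' @return Position in %EL.
#' @export
#' @examples
#' threshold_position(bcd_exponential(200, 0.04), 200 / exp(1))  # 25
threshold_position <- function(profile, c) {
  if (c <= 0) .err("threshold must be positive", "gapcanal_invalid_input")
  if (c > profile$A) .err("threshold exceeds amplitude: no crossing",
                          "gapcanal_no_crossing")
  log(profile$A / c) / profile$l
}
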