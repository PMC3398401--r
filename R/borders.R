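#' hb border position in a shorted-model solution
#'
#' The shorted-model solution is piecewise linear in space (first-order
#' interpolation between nuclei, reflecting the absent diffusion term); the
#' border is the anteriormost downward crossing of half the window-maximal
#' Hb concentration inside the analysis window.
#'
#' @param x Nucleus positions (%EL), increasing.
#' @param hb Hb concentrations at those positions (at gastrulation time).
#' @param window Analysis window in %EL (default 37-57, the region around
#'   the posterior border of the anterior hb domain).
#' @param half_max Optional fixed crossing level; by default half of the
#'   window-maximal Hb concentration (absolute saturation varies between
#'   solutions, so a relative reference is the default; a fixed level is
#'   preferable when comparing borders across parameter sweeps).
#' @return Object of class `border_record`: list with `border_x`,
#'   `half_max`, `method = "half_max_linear"`, `flank_anterior`,
#'   `flank_posterior` (nearest lattice nuclei on either side).
#' @export
#' @examples
#' border_position_shorted(c(47, 49, 51, 53), c(200, 200, 0, 0))$border_x
border_position_shorted <- function(x, hb, window = c(37, 57),
                                    half_max = NULL) {
  keep <- x >= window[1] & x <= window[2]
  xw <- x[keep]; hw <- hb[keep]
  if (length(xw) < 2L) .err("fewer than 2 nuclei in window",
                            "gapcanal_invalid_input")
  if (xw[which.max(hw)] > xw[which.min(hw)]) {
    .err("Hb maximum lies posterior to its minimum in the window",
         "gapcanal_invalid_input")
  }
  half <- if (is.null(half_max)) max(hw) / 2 else half_max
  bx <- NA_real_
  for (i in seq_len(length(xw) - 1L)) {
    if (hw[i] >= half && hw[i + 1L] < half) {
      bx <- xw[i] + (hw[i] - half) / (hw[i] - hw[i + 1L]) *
        (xw[i + 1L] - xw[i])
      break
    }
  }
  if (is.na(bx)) .err("no downward half-max crossing in window",
                      "gapcanal_border_absent")
  structure(list(border_x = bx, half_max = half,
                 method = "half_max_linear",
                 flank_anterior = max(xw[xw <= bx]),
                 flank_posterior = min(xw[xw > bx])),
            class = "border_record")
}

#' hb border position in a full-model solution
#'
#' The full-model solution is smooth in space, so the border is defined on
#' a third-order (cubic-spline) interpolant as the local inflection point:
#' the zero of the interpolant's second derivative bracketed within
#' `bracket` %EL of the half-max crossing. When no inflection exists in the
#' bracket (e.g. exactly linear profiles) the half-max position is returned
#' with a warning.
#'
#' @param x Nucleus positions (%EL), increasing.
#' @param hb Hb concentrations.
#' @param window Analysis window (%EL).
#' @param bracket Half-width of the inflection search bracket around the
#'   half-max crossing (%EL).
#' @param half_max Optional fixed crossing level (see
#'   [border_position_shorted()]).
#' @return A `border_record`; `method` is `"inflection_cubic"` or
#'   `"half_max_fallback"`.
#' @export
border_position_full <- function(x, hb, window = c(37, 57), bracket = 3,
                                 half_max = NULL) {
  keep <- x >= window[1] & x <= window[2]
  xw <- x[keep]; hw <- hb[keep]
  if (length(xw) < 4L) {
    .err("need at least 4 nuclei in window for cubic interpolation",
         "gapcanal_invalid_input")
  }
  sf <- stats::splinefun(xw, hw, method = "natural")
  half <- if (is.null(half_max)) max(hw) / 2 else half_max
  # half-max crossing on the spline (dense scan + bisection)
  xs <- seq(xw[1L], xw[length(xw)], length.out = 2001L)
  d <- sf(xs) - half
  i <- which(d[-length(d)] >= 0 & d[-1L] < 0)[1L]
  if (is.na(i)) .err("no downward half-max crossing in window",
                     "gapcanal_border_absent")
  x_half <- stats::uniroot(function(z) sf(z) - half,
                           c(xs[i], xs[i + 1L]), tol = 1e-9)$root
  lo <- max(xw[1L], x_half - bracket); hi <- min(xw[length(xw)],
                                                 x_half + bracket)
  zs <- seq(lo, hi, length.out = 601L)
  d2 <- sf(zs, deriv = 2L)
  j <- which(d2[-length(d2)] * d2[-1L] < 0)
  if (length(j) == 0L) {
    .warn("no inflection in bracket; falling back to half-max position",
          "gapcanal_inflection_fallback")
    bx <- x_half; method <- "half_max_fallback"
  } else {
    # inflection nearest the half-max crossing
    cand <- vapply(j, function(k) {
      stats::uniroot(function(z) sf(z, deriv = 2L),
                     c(zs[k], zs[k + 1L]), tol = 1e-9)$root
    }, numeric(1))
    bx <- cand[which.min(abs(cand - x_half))]
    method <- "inflection_cubic"
  }
  structure(list(border_x = bx, half_max = half, method = method,
                 flank_anterior = max(xw[xw <= bx]),
                 flank_posterior = min(xw[xw > bx])),
            class = "border_record")
}

#' @export
print.border_record <- function(x, ...) {
  cat(sprintf("hb border at %.3f %%EL (%s; half-max %.3g)\n",
              x$border_x, x$method, x$half_max))
  invisible(x)
}

#' Mass of a spatial pattern
#'
#' Trapezoidal integral of a concentration pattern over a spatial region
#' (default 35-64 %EL), in concentration-units x %EL.
#'
#' @param profile Function of x, or a data.frame with columns `x` and a
#'   value column (second column used).
#' @param region Length-2 integration region (%EL).
#' @param dx Trapezoid resolution (%EL).
#' @return The integral (units x %EL).
#' @export
#' @examples
#' pattern_mass(function(x) rep(100, length(x)))  # 2900
pattern_mass <- function(profile, region = c(35, 64), dx = 0.1) {
  f <- if (is.function(profile)) profile else {
    stats::approxfun(profile[[1L]], profile[[2L]], rule = 2)
  }
  xs <- seq(region[1], region[2], by = dx)
  if (xs[length(xs)] < region[2]) xs <- c(xs, region[2])
  y <- f(xs)
  sum((y[-1L] + y[-length(y)]) / 2 * diff(xs))
}

#' Bcd response-curve points
#'
#' For each profile of an ensemble, pairs a characteristic hb position
#' `x_star` (either the intersection of the maternal Hb gradient with the
#' crossed basin boundary, or the model's hb border position) with that
#' embryo's own Bcd concentration at `x_star`. The resulting
#' (position, Bcd level) cloud is the model's readout response curve.
#'
#' @param ensemble A [bcd_ensemble()].
#' @param x_star Named or ordered numeric vector of positions per embryo
#'   (NA = excluded, e.g. profiles with no intersection).
#' @param mode `"intersection"` or `"border"` (annotation only).
#' @param class_tag Optional per-embryo solution class labels.
#' @return Data frame `profile_id`, `mode`, `x_star`, `bcd_at_x`,
#'   `class_tag`; excluded profiles are dropped.
#' @export
response_curve <- function(ensemble, x_star,
                           mode = c("intersection", "border"),
                           class_tag = NULL) {
  mode <- match.arg(mode)
  n <- nrow(ensemble)
  x_star <- rep_len(as.numeric(x_star), n)
  if (is.null(class_tag)) class_tag <- rep(NA_character_, n)
  keep <- !is.na(x_star)
  if (any(!keep)) {
    message(sum(!keep), " profile(s) without ", mode,
            " excluded from the response curve: ",
            paste(ensemble$embryo_id[!keep], collapse = ", "))
  }
  data.frame(profile_id = ensemble$embryo_id[keep], mode = mode,
             x_star = x_star[keep],
             bcd_at_x = ensemble$A[keep] * exp(-ensemble$l[keep] *
                                                 x_star[keep]),
             class_tag = class_tag[keep], stringsAsFactors = FALSE)
}
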