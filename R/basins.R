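#' Monte-Carlo basin partition on the biological initial-condition segment
#'
#' Estimates, at one spatial position (i.e. one `(v_Bcd, v_Cad)` input), the
#' attraction basins restricted to the segment
#' \eqn{\Omega = \{0 \le v^{Hb} \le 100,\ v^{Kr} = v^{Gt} = v^{Kni} = 0\}}:
#' `n_samples` uniform Hb draws are integrated through the nonautonomous
#' phase (mitotic gating, time-dependent Cad) and on to stabilization, each
#' endpoint is assigned to the attractor within `delta_A` of it, and the
#' sorted sample labels are condensed into disjoint intervals `(c1, c2)`
#' covering `[0, 100]`. Boundaries between opposing intervals are then
#' sharpened by bisection between the innermost opposing samples, so shared
#' interval endpoints are exact to `refine_tol` and interval lengths plus
#' gap lengths always sum to 100.
#'
#' @param bcd Fixed Bcd concentration at the position.
#' @param cad Cad input: a number (autonomous value) or a function of `t`
#'   (nonautonomous phase; its value at/after T6 is used for the autonomous
#'   tail and for attractor finding).
#' @param params A [circuit_parameters()] object.
#' @param schedule A [mitosis_schedule()], or `NULL` to integrate the
#'   autonomous flow from t = 0 (used for toy-system validation).
#' @param n_samples Number of uniform Hb draws (>= 100; 10 000 reproduces
#'   the production setting, 1 000 or fewer plus bisection suits tests).
#' @param seed Mandatory RNG seed (draws are reproducible per seed).
#' @param t_end Stabilization horizon (min).
#' @param stab_tol Stabilization test: `max|f(v)| < stab_tol`.
#' @param delta_A Attractor capture radius (concentration units).
#' @param refine Logical: sharpen boundaries by bisection.
#' @param refine_tol Bisection width target on the Hb axis.
#' @param attractors Optional precomputed labelled attractor list (from
#'   [find_equilibria()] via the internal code labelling); computed when
#'   `NULL`.
#' @param ... Passed to [find_equilibria()].
#' @return Object of class `basin_partition`: list with `intervals`
#'   (data.frame `label`, `c1`, `c2`), `gaps` (data.frame `c1`, `c2`),
#'   `attractors`, `samples` (data.frame `hb0`, `label`),
#'   `unresolved_fraction`, `n_samples`, `bcd`, `cad`, `seed`.
#' @export
sample_basin_partition <- function(bcd, cad, params, schedule,
                                   n_samples = 10000L, seed,
                                   t_end = 1000, stab_tol = 1e-6,
                                   delta_A = 1.0, refine = TRUE,
                                   refine_tol = 1e-3, attractors = NULL,
                                   ...) {
  if (n_samples < 100L) .err("n_samples must be >= 100",
                             "gapcanal_invalid_input")
  if (missing(seed)) .err("seed is mandatory", "gapcanal_invalid_input")
  cad_f <- .as_time_fun(cad, "cad")
  cad_auto <- if (is.null(schedule)) cad_f(0) else cad_f(schedule$t_T6)
  if (is.null(attractors)) {
    attractors <- .label_attractors(find_equilibria(bcd, cad_auto, params,
                                                    ...))
  }
  if (length(attractors) == 0L) {
    .err("no attractors at this input; basin partition undefined",
         "gapcanal_no_equilibria")
  }
  att_states <- vapply(attractors, function(e) e$state, numeric(4L))
  att_labels <- vapply(attractors, function(e) e$label, character(1))

  hb0 <- sort(.with_seed(seed, stats::runif(n_samples, 0, 100)))
  ends <- .flow_endpoints(rbind(hb0, 0, 0, 0), bcd, cad_f, params, schedule,
                          t_end, stab_tol)
  labels <- .assign_attractor(ends$states, att_states, att_labels, delta_A,
                              ends$stabilized)
  unresolved <- mean(is.na(labels))
  if (unresolved > 0.01) {
    .warn(sprintf("%.1f%% of samples unresolved by t_end = %g",
                  100 * unresolved, t_end), "gapcanal_unresolved_samples")
  }

  classify_one <- function(h) {
    e <- .flow_endpoints(matrix(c(h, 0, 0, 0), ncol = 1L), bcd, cad_f,
                         params, schedule, t_end, stab_tol)
    .assign_attractor(e$states, att_states, att_labels, delta_A,
                      e$stabilized)
  }

  runs <- rle(ifelse(is.na(labels), "<unresolved>", labels))
  runs$values[runs$values == "<unresolved>"] <- NA_character_
  nr <- length(runs$lengths)
  hi_idx <- cumsum(runs$lengths)
  lo_idx <- hi_idx - runs$lengths + 1L
  # boundary value between run k and run k+1
  cuts <- numeric(nr - 1L)
  if (nr > 1L) {
    for (k in seq_len(nr - 1L)) {
      a <- hb0[hi_idx[k]]; b <- hb0[lo_idx[k + 1L]]
      la <- runs$values[k]; lb <- runs$values[k + 1L]
      if (refine && !is.na(la) && !is.na(lb)) {
        while (b - a > refine_tol) {
          mid <- (a + b) / 2
          lm <- classify_one(mid)
          if (!is.na(lm) && lm == la) a <- mid
          else if (!is.na(lm) && lm == lb) b <- mid
          else break  # unresolved midpoint: stop refining this cut
        }
      }
      cuts[k] <- (a + b) / 2
    }
  }
  edges <- c(0, cuts, 100)
  iv <- data.frame(label = runs$values, c1 = edges[-length(edges)],
                   c2 = edges[-1L], stringsAsFactors = FALSE)
  gaps <- iv[is.na(iv$label), c("c1", "c2"), drop = FALSE]
  intervals <- iv[!is.na(iv$label), , drop = FALSE]
  rownames(intervals) <- NULL; rownames(gaps) <- NULL
  structure(list(intervals = intervals, gaps = gaps,
                 attractors = attractors,
                 samples = data.frame(hb0 = hb0, label = labels,
                                      stringsAsFactors = FALSE),
                 unresolved_fraction = unresolved,
                 n_samples = as.integer(n_samples),
                 bcd = bcd, cad = cad_auto, seed = seed),
            class = "basin_partition")
}

# Integrate columns of ic through the (non)autonomous flow until the
# autonomous RHS stabilizes or t_end; returns endpoint states + flags.
.flow_endpoints <- function(ic, bcd, cad_f, params, schedule, t_end,
                            stab_tol, chunk = 150) {
  K <- ncol(ic)
  cad_auto <- if (is.null(schedule)) cad_f(0) else cad_f(schedule$t_T6)
  t_now <- 0
  V <- ic
  if (!is.null(schedule)) {
    sol <- integrate_shorted_ensemble(V, bcd, cad_f, params, schedule,
                                      times = c(schedule$t0, schedule$tau))
    V <- sol$states[[2L]]
    t_now <- schedule$tau
  }
  stab <- function(V) {
    U <- .total_input_matrix(V, bcd, cad_auto, 0, params)
    dV <- params$R * regulation_g(U) - params$lambda * V
    apply(abs(dV), 2L, max) < stab_tol
  }
  done <- stab(V)
  while (!all(done) && t_now < t_end) {
    t_next <- min(t_now + chunk, t_end)
    act <- which(!done)
    sol <- integrate_shorted_ensemble(V[, act, drop = FALSE],
                                      rep_len(bcd, K)[act],
                                      rep_len(cad_auto, K)[act], params,
                                      schedule = NULL,
                                      times = c(t_now, t_next))
    V[, act] <- sol$states[[2L]]
    t_now <- t_next
    done <- stab(V)
  }
  list(states = V, stabilized = done, t_final = t_now)
}

# Assign endpoint columns to the nearest attractor within delta_A.
.assign_attractor <- function(states, att_states, att_labels, delta_A,
                              stabilized = NULL) {
  K <- ncol(states)
  out <- rep(NA_character_, K)
  for (k in seq_len(K)) {
    d <- sqrt(colSums((att_states - states[, k])^2))
    j <- which.min(d)
    if (d[j] <= delta_A) out[k] <- att_labels[j]
  }
  if (!is.null(stabilized)) out[!stabilized & is.na(out)] <- NA_character_
  out
}

#' @export
print.basin_partition <- function(x, ...) {
  cat(sprintf("Basin partition at (Bcd = %.4g, Cad = %.4g), n = %d:\n",
              x$bcd, x$cad, x$n_samples))
  print(x$intervals, row.names = FALSE)
  if (nrow(x$gaps)) {
    cat("unresolved gaps:\n"); print(x$gaps, row.names = FALSE)
  }
  invisible(x)
}

#' Spatial profile of a basin boundary
#'
#' Collects, across per-nucleus basin partitions, the shared Hb-axis
#' boundary between the basins of a given attractor pair, and interpolates
#' linearly in space so the boundary can be studied as a continuous
#' function of position. Basins with several disjoint components contribute
#' each adjacent-pair boundary separately (`component` indexes them from
#' anterior Hb upwards).
#'
#' @param partitions Named-by-position list of [sample_basin_partition()]
#'   results, or a list of `list(position =, partition =)` pairs.
#' @param positions Positions (%EL) matching `partitions` (defaults to
#'   their names).
#' @param pair Character length-2: the two attractor labels flanking the
#'   boundary (order irrelevant).
#' @param component Which boundary component to track when the pair is
#'   adjacent more than once at a position (default 1, the lowest on the
#'   Hb axis).
#' @return Object of class `basin_boundary_curve`: data.frame `x`,
#'   `hb` plus an `approxfun` interpolant in attribute `fun` and the pair
#'   in attribute `pair`. Positions not carrying the boundary are omitted;
#'   the curve spans the largest consecutive run of carrying positions.
#' @export
basin_boundary_profile <- function(partitions, pair, positions = NULL,
                                   component = 1L) {
  if (is.null(positions)) positions <- as.numeric(names(partitions))
  if (anyNA(positions)) .err("positions must be supplied or encoded as names",
                             "gapcanal_invalid_input")
  stopifnot(length(pair) == 2L)
  vals <- rep(NA_real_, length(partitions))
  for (i in seq_along(partitions)) {
    iv <- partitions[[i]]$intervals
    if (nrow(iv) < 2L) next
    found <- 0L
    for (k in seq_len(nrow(iv) - 1L)) {
      # adjacent intervals sharing an endpoint, matching the pair
      if (iv$c2[k] == iv$c1[k + 1L] &&
          setequal(c(iv$label[k], iv$label[k + 1L]), pair)) {
        found <- found + 1L
        if (found == component) { vals[i] <- iv$c2[k]; break }
      }
    }
  }
  carry <- !is.na(vals)
  if (!any(carry)) .err("boundary absent at every position",
                        "gapcanal_empty_curve")
  # largest consecutive run of carrying positions
  r <- rle(carry)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  sel <- seq(ends[best] - r$lengths[best] + 1L, ends[best])
  df <- data.frame(x = positions[sel], hb = vals[sel])
  df <- df[order(df$x), ]
  if (nrow(df) == 1L) {
    .warn("boundary present at a single position: degenerate point curve",
          "gapcanal_degenerate_curve")
    f <- function(x) ifelse(abs(x - df$x) < 1e-9, df$hb, NA_real_)
  } else {
    f <- stats::approxfun(df$x, df$hb)
  }
  structure(df, fun = f, pair = sort(pair),
            class = c("basin_boundary_curve", "data.frame"))
}

#' Intersections of the maternal Hb gradient with a basin boundary
#'
#' Locates every sign change of `hb0(x) - curve(x)` over the curve's
#' spatial support, refining each crossing by bisection. Border formation
#' corresponds to the maternal gradient crossing from one attractor's basin
#' into another's, so these intersection positions predict the hb border.
#'
#' @param hb0 Continuous maternal Hb gradient: function of x with values in
#'   `[0, 100]`.
#' @param curve A [basin_boundary_profile()] result (or any function of x
#'   plus a `range` attribute; a data.frame with `x`, `hb` also works).
#' @param grid_step Coarse scan step in %EL before bisection.
#' @param tol Bisection tolerance in %EL.
#' @return Numeric vector of crossing positions, ordered anterior to
#'   posterior (possibly empty).
#' @export
intersect_initial_hb <- function(hb0, curve, grid_step = 0.05, tol = 1e-3) {
  if (inherits(curve, "basin_boundary_curve")) {
    f <- attr(curve, "fun")
    xr <- range(curve$x)
  } else if (is.data.frame(curve)) {
    f <- stats::approxfun(curve$x, curve$hb)
    xr <- range(curve$x)
  } else {
    .err("curve must be a basin_boundary_curve or data.frame",
         "gapcanal_invalid_input")
  }
  if (xr[1] == xr[2]) return(numeric(0))
  xs <- seq(xr[1], xr[2], by = grid_step)
  if (xs[length(xs)] < xr[2]) xs <- c(xs, xr[2])
  d <- hb0(xs) - f(xs)
  out <- numeric(0)
  for (i in seq_len(length(xs) - 1L)) {
    if (d[i] == 0) { out <- c(out, xs[i]); next }
    if (d[i] * d[i + 1L] < 0) {
      a <- xs[i]; b <- xs[i + 1L]; da <- d[i]
      while (b - a > tol) {
        mid <- (a + b) / 2
        dm <- hb0(mid) - f(mid)
        if (dm == 0) { a <- mid; b <- mid; break }
        if (sign(dm) == sign(da)) { a <- mid; da <- dm } else b <- mid
      }
      out <- c(out, (a + b) / 2)
    }
  }
  if (length(xs) && d[length(xs)] == 0) out <- c(out, xs[length(xs)])
  sort(unique(out))
}

#' Intersection spread under opposite-slope versus co-varying boundaries
#'
#' Pure-geometry demonstration of the first canalization mechanism: a
#' strictly decreasing maternal Hb gradient crossed by a family of
#' vertically perturbed *increasing* boundary curves yields a strictly
#' smaller spread of intersection positions than the matched family of
#' *decreasing* boundaries of equal absolute slope.
#'
#' @param hb0_slope Slope of the linear maternal gradient (< 0).
#' @param boundary_slope Absolute boundary slope (> 0, and different from
#'   `|hb0_slope|` so the co-varying case still crosses).
#' @param offsets Vertical boundary perturbations (e.g. the ensemble's
#'   Bcd-induced shifts), in Hb units.
#' @param x_range Spatial support of the construction (%EL).
#' @param center Common crossing center `(x, Hb)` of the unperturbed
#'   configuration.
#' @return List with `opposite` and `covarying`: each a list of
#'   `intersections` and their `sd`.
#' @export
opposite_slope_spread <- function(hb0_slope = -5, boundary_slope = 2.5,
                                  offsets = seq(-10, 10, by = 2),
                                  x_range = c(37, 57),
                                  center = c(47, 50)) {
  stopifnot(hb0_slope < 0, boundary_slope > 0,
            abs(boundary_slope) != abs(hb0_slope))
  hb0 <- function(x) {
    pmin(pmax(center[2] + hb0_slope * (x - center[1]), 0), 100)
  }
  xs <- seq(x_range[1], x_range[2], length.out = 41L)
  run <- function(slope) {
    xstar <- vapply(offsets, function(dd) {
      curve <- data.frame(x = xs, hb = center[2] + slope * (xs - center[1])
                          + dd)
      hits <- intersect_initial_hb(hb0, curve)
      if (length(hits) == 0L) NA_real_ else hits[1L]
    }, numeric(1))
    list(intersections = xstar, sd = stats::sd(xstar))
  }
  list(opposite = run(boundary_slope), covarying = run(-boundary_slope))
}
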