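#' Autonomous shorted-model right-hand side
#'
#' The vector field of the per-nucleus system after the T6 freeze
#' (\eqn{\chi \equiv 1}, Cad fixed): \eqn{f(v) = R\,g(Tv + m\,v^{Bcd} +
#' E\,v^{Cad} + h) - \lambda v}.
#'
#' @param v Length-4 state.
#' @param bcd,cad Fixed input concentrations.
#' @param params A [circuit_parameters()] object.
#' @return Length-4 vector field value.
#' @export
rhs_autonomous <- function(v, bcd, cad, params) {
  u <- drop(params$T %*% v) + params$bcd_weight * bcd +
    params$ext_weight[, "cad"] * cad + params$h
  params$R * regulation_g(u) - params$lambda * v
}

#' Analytic Jacobian of the autonomous shorted model
#'
#' \eqn{J = \mathrm{diag}(R\,g'(u))\,T - \mathrm{diag}(\lambda)}.
#'
#' @inheritParams rhs_autonomous
#' @return 4x4 Jacobian matrix.
#' @export
jacobian_autonomous <- function(v, bcd, cad, params) {
  u <- drop(params$T %*% v) + params$bcd_weight * bcd +
    params$ext_weight[, "cad"] * cad + params$h
  (params$R * regulation_g_prime(u)) * params$T - diag(params$lambda)
}

#' Symbolic 0/X/1 code of a state
#'
#' Codes each gene's concentration as low (`0`, below `lo`), intermediate
#' (`X`, in `[lo, hi]`) or high (`1`, above `hi`); default thresholds 50 and
#' 150 relative units. Applied to attractors this yields the symbolic
#' attractor codes (e.g. `1000` for an hb-only state, `0100` for Kr-only).
#'
#' @param state Length-4 nonnegative state.
#' @param lo,hi Coding thresholds.
#' @return A 4-character string over `{0, X, 1}`.
#' @export
#' @examples
#' code_state(c(200, 10, 10, 10))  # "1000"
#' code_state(c(200, 10, 100, 5))  # "10X0"
code_state <- function(state, lo = 50, hi = 150) {
  if (any(state < 0)) .err("state components must be >= 0",
                           "gapcanal_invalid_input")
  paste(ifelse(state < lo, "0", ifelse(state > hi, "1", "X")),
        collapse = "")
}

#' Classify the stability of an equilibrium
#'
#' Eigenvalues of the analytic Jacobian; `attractor` when all real parts
#' are below `-eps_h`, `saddle_k` when k eigenvalues have real part above
#' `eps_h`, `nonhyperbolic` when any real part lies within `eps_h` of zero.
#'
#' @param state Equilibrium state (to tolerance).
#' @param bcd,cad Fixed inputs.
#' @param params A [circuit_parameters()] object.
#' @param eps_h Hyperbolicity tolerance on real parts.
#' @return List with `stability` (character), `eigenvalues` (complex),
#'   `n_unstable`.
#' @export
classify_stability <- function(state, bcd, cad, params, eps_h = 1e-6) {
  ev <- eigen(jacobian_autonomous(state, bcd, cad, params),
              only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (any(abs(re) <= eps_h)) {
    "nonhyperbolic"
  } else if (all(re < 0)) {
    "attractor"
  } else {
    paste0("saddle_", sum(re > 0))
  }
  list(stability = stability, eigenvalues = ev,
       n_unstable = sum(re > eps_h))
}

#' Find all equilibria of the autonomous shorted model
#'
#' Deterministic multistart Newton iteration: starting points on a regular
#' grid over `[0, search_max]` per gene plus a low-discrepancy (Halton) set,
#' with converged roots deduplicated at distance `dedup` and classified by
#' [classify_stability()].
#'
#' @param bcd,cad Fixed input concentrations.
#' @param params A [circuit_parameters()] object.
#' @param search_max Upper bound of the start box per gene (default
#'   `1.2 * max(R / lambda)`).
#' @param n_grid Regular-grid points per gene axis (default 5, i.e. 625
#'   grid starts).
#' @param n_extra Additional Halton starts (default 200).
#' @param tol Residual tolerance `max|f|` for acceptance.
#' @param dedup Merge radius for duplicate roots (concentration units).
#' @param eps_h Hyperbolicity tolerance.
#' @param max_iter Newton iteration cap per start.
#' @return List of equilibrium objects (class `equilibrium`): `state`,
#'   `stability`, `eigenvalues`, `code`, `residual`. Attractors sorted by
#'   decreasing Hb come first, then saddles.
#' @export
find_equilibria <- function(bcd, cad, params, search_max = NULL,
                            n_grid = 5L, n_extra = 200L, tol = 1e-9,
                            dedup = 0.5, eps_h = 1e-6, max_iter = 80L) {
  vmax <- max(params$R / params$lambda, 1)
  if (is.null(search_max)) search_max <- 1.2 * vmax
  axes <- seq(0, search_max, length.out = n_grid)
  starts <- as.matrix(expand.grid(axes, axes, axes, axes))
  if (n_extra > 0L) {
    starts <- rbind(starts, .halton(n_extra, 4L) * search_max)
  }
  roots <- list()
  states <- NULL
  for (k in seq_len(nrow(starts))) {
    v <- starts[k, ]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      fv <- rhs_autonomous(v, bcd, cad, params)
      if (max(abs(fv)) < tol) { ok <- TRUE; break }
      J <- jacobian_autonomous(v, bcd, cad, params)
      step <- tryCatch(solve(J, -fv), error = function(e) NULL)
      if (is.null(step)) break
      ns <- sqrt(sum(step^2))
      if (ns > search_max) step <- step * (search_max / ns)
      v <- v + step
      if (any(!is.finite(v)) || any(abs(v) > 100 * search_max)) break
    }
    if (!ok) next
    if (any(v < -1e-6)) next
    v <- pmax(v, 0)
    if (!is.null(states) &&
        any(sqrt(colSums((t(states) - v)^2)) < dedup)) next
    states <- rbind(states, v)
    cls <- classify_stability(v, bcd, cad, params, eps_h)
    roots[[length(roots) + 1L]] <- structure(
      list(state = stats::setNames(as.numeric(v), gap_genes()),
           stability = cls$stability, eigenvalues = cls$eigenvalues,
           code = code_state(pmax(v, 0)),
           residual = max(abs(rhs_autonomous(v, bcd, cad, params)))),
      class = "equilibrium")
  }
  if (length(roots) == 0L) {
    .warn("no equilibria found", "gapcanal_no_equilibria")
    return(list())
  }
  is_att <- vapply(roots, function(e) e$stability == "attractor", logical(1))
  hb <- vapply(roots, function(e) e$state[["hb"]], numeric(1))
  roots[order(!is_att, -hb)]
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium [%s] code %s: (%s); max Re(lambda) = %.3g\n",
              x$stability, x$code,
              paste(signif(x$state, 4), collapse = ", "),
              max(Re(x$eigenvalues))))
  invisible(x)
}

# Label a node's attractors by code, disambiguating duplicate codes by
# descending Hb with suffixes "", "b", "c", ...
.label_attractors <- function(eqs) {
  att <- Filter(function(e) e$stability == "attractor", eqs)
  if (length(att) == 0L) return(att)
  codes <- vapply(att, function(e) e$code, character(1))
  labels <- codes
  for (cd in unique(codes)) {
    idx <- which(codes == cd)
    if (length(idx) > 1L) {
      labels[idx] <- paste0(cd, c("", letters[2:26])[seq_along(idx)])
    }
  }
  for (i in seq_along(att)) att[[i]]$label <- labels[i]
  att
}

#' Scan the Bcd-Cad plane for attractor existence domains
#'
#' Computes the equilibrium set on a rectangular grid of fixed
#' `(v_Bcd, v_Cad)` inputs, labels attractors by nearest-state continuity
#' between neighbouring nodes (seeded by their symbolic code), and emits
#' boundary segments between nodes whose labelled attractor sets differ.
#' Each boundary is tagged `saddle-node` when the disappearing attractor's
#' leading eigenvalue is real, `Hopf` when it is a complex pair, else
#' `unclassified`.
#'
#' @param params A [circuit_parameters()] object.
#' @param bcd_range,cad_range Length-2 ranges.
#' @param resolution Grid size `c(n_bcd, n_cad)` (each >= 20 for production
#'   maps; smaller grids are permitted for toys).
#' @param match_radius Maximum state distance for label continuity.
#' @param ... Passed to [find_equilibria()] (e.g. `n_grid`, `n_extra`).
#' @return Object of class `existence_domain_map`: list with `nodes`
#'   (data.frame: bcd, cad, n_attractors, labels, codes, flagged),
#'   `equilibria` (list per node), `boundaries` (data.frame of segment
#'   midpoints with `label` and `type`), `bcd_grid`, `cad_grid`.
#' @export
scan_bcd_cad_plane <- function(params, bcd_range, cad_range,
                               resolution = c(30L, 30L),
                               match_radius = 40, ...) {
  nb <- resolution[1L]; nc <- resolution[length(resolution)]
  bcd_grid <- seq(bcd_range[1], bcd_range[2], length.out = nb)
  cad_grid <- seq(cad_range[1], cad_range[2], length.out = nc)
  eq_grid <- vector("list", nb * nc)
  att_grid <- vector("list", nb * nc)
  flagged <- logical(nb * nc)
  idx <- function(i, j) (j - 1L) * nb + i
  for (j in seq_len(nc)) {
    for (i in seq_len(nb)) {
      eqs <- find_equilibria(bcd_grid[i], cad_grid[j], params, ...)
      att <- .label_attractors(eqs)
      # continuity relabelling against already-processed neighbours
      neigh <- list()
      if (i > 1L) neigh <- c(neigh, att_grid[[idx(i - 1L, j)]])
      if (j > 1L) neigh <- c(neigh, att_grid[[idx(i, j - 1L)]])
      if (length(neigh) && length(att)) {
        for (k in seq_along(att)) {
          d <- vapply(neigh, function(e) {
            sqrt(sum((e$state - att[[k]]$state)^2))
          }, numeric(1))
          best <- which.min(d)
          if (d[best] < match_radius) {
            second <- sort(d)[2]
            if (is.finite(second) && second - d[best] < 1 &&
                neigh[[which(d == second)[1]]]$label !=
                neigh[[best]]$label) {
              flagged[idx(i, j)] <- TRUE
            }
            att[[k]]$label <- neigh[[best]]$label
          }
        }
        # duplicate labels after matching -> ambiguity flag
        if (anyDuplicated(vapply(att, function(e) e$label, character(1)))) {
          flagged[idx(i, j)] <- TRUE
        }
      }
      eq_grid[[idx(i, j)]] <- eqs
      att_grid[[idx(i, j)]] <- att
    }
  }
  labset <- function(k) {
    vapply(att_grid[[k]], function(e) e$label, character(1))
  }
  nodes <- data.frame(
    bcd = rep(bcd_grid, times = nc), cad = rep(cad_grid, each = nb),
    n_attractors = vapply(seq_len(nb * nc),
                          function(k) length(att_grid[[k]]), integer(1)),
    labels = vapply(seq_len(nb * nc),
                    function(k) paste(sort(labset(k)), collapse = ","),
                    character(1)),
    codes = vapply(seq_len(nb * nc), function(k) {
      paste(sort(vapply(att_grid[[k]], function(e) e$code, character(1))),
            collapse = ",")
    }, character(1)),
    flagged = flagged)
  # boundary segments between 4-neighbour nodes with differing label sets
  bnd <- list()
  add_boundary <- function(k1, k2) {
    l1 <- labset(k1); l2 <- labset(k2)
    for (lab in union(setdiff(l1, l2), setdiff(l2, l1))) {
      side <- if (lab %in% l1) k1 else k2
      e <- att_grid[[side]][[match(lab, labset(side))]]
      re <- Re(e$eigenvalues)
      lead <- which.max(re)
      type <- if (abs(Im(e$eigenvalues[lead])) < 1e-8) "saddle-node"
              else "Hopf"
      bnd[[length(bnd) + 1L]] <<- data.frame(
        bcd = (nodes$bcd[k1] + nodes$bcd[k2]) / 2,
        cad = (nodes$cad[k1] + nodes$cad[k2]) / 2,
        bcd1 = nodes$bcd[k1], cad1 = nodes$cad[k1],
        bcd2 = nodes$bcd[k2], cad2 = nodes$cad[k2],
        label = lab, type = type)
    }
  }
  for (j in seq_len(nc)) for (i in seq_len(nb)) {
    if (i < nb) add_boundary(idx(i, j), idx(i + 1L, j))
    if (j < nc) add_boundary(idx(i, j), idx(i, j + 1L))
  }
  boundaries <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(bcd = numeric(0), cad = numeric(0), bcd1 = numeric(0),
               cad1 = numeric(0), bcd2 = numeric(0), cad2 = numeric(0),
               label = character(0), type = character(0))
  structure(list(nodes = nodes, equilibria = eq_grid,
                 attractors = att_grid, boundaries = boundaries,
                 bcd_grid = bcd_grid, cad_grid = cad_grid),
            class = "existence_domain_map")
}

#' @export
print.existence_domain_map <- function(x, ...) {
  cat(sprintf("Existence-domain map: %d x %d nodes, %d boundary segments\n",
              length(x$bcd_grid), length(x$cad_grid), nrow(x$boundaries)))
  cat("Attractor-count table:\n")
  print(table(x$nodes$n_attractors))
  invisible(x)
}

#' Trace the 1-D unstable manifold of a saddle
#'
#' For a saddle with exactly one eigenvalue of positive real part, the two
#' branches of its unstable manifold are approximated by integrating the
#' autonomous flow forward from \eqn{S \pm \epsilon \hat w}, where
#' \eqn{\hat w} is the unit unstable eigenvector.
#'
#' @param saddle An `equilibrium` with stability `saddle_1` (or a raw state
#'   vector of such a saddle).
#' @param bcd,cad Fixed inputs.
#' @param params A [circuit_parameters()] object.
#' @param eps Seeding displacement along the eigenvector (concentration
#'   units).
#' @param t_max Integration horizon (min).
#' @param n_out Points stored per branch (time-ordered = arclength-ordered).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `manifold_trace`: list with `saddle` (state),
#'   `w` (unit unstable eigenvector), `branches` (two time-ordered point
#'   matrices, columns = genes).
#' @export
trace_unstable_manifold <- function(saddle, bcd, cad, params, eps = 0.1,
                                    t_max = 500, n_out = 200L,
                                    rtol = 1e-8, atol = 1e-8) {
  state <- if (inherits(saddle, "equilibrium")) saddle$state else saddle
  eg <- eigen(jacobian_autonomous(state, bcd, cad, params))
  re <- Re(eg$values)
  unstable <- which(re > 1e-6)
  if (length(unstable) != 1L) {
    .err(sprintf("saddle has %d unstable eigenvalues; only saddle_1 supported",
                 length(unstable)), "gapcanal_unsupported_saddle")
  }
  w <- Re(eg$vectors[, unstable])
  w <- w / sqrt(sum(w^2))
  times <- seq(0, t_max, length.out = n_out)
  f <- function(t, y) rhs_autonomous(y, bcd, cad, params)
  run <- function(y0) {
    sol <- .ode_segmented(y0, times, f, numeric(0), "lsoda", rtol, atol)
    m <- sol[, -1L, drop = FALSE]
    colnames(m) <- gap_genes()
    m
  }
  b1 <- run(pmax(state + eps * w, 0))
  b2 <- run(pmax(state - eps * w, 0))
  structure(list(saddle = state, w = w, branches = list(b1, b2),
                 bcd = bcd, cad = cad),
            class = "manifold_trace")
}

#' @export
print.manifold_trace <- function(x, ...) {
  ends <- lapply(x$branches, function(b) b[nrow(b), ])
  cat("1-D unstable manifold trace from saddle (",
      paste(signif(x$saddle, 4), collapse = ", "), ")\n", sep = "")
  for (b in ends) cat("  branch endpoint: (",
                      paste(signif(b, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
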