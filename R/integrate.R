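#' Right-hand side of the shorted (per-nucleus) model
#'
#' The diffusionless reduction of the circuit for one nucleus:
#' \deqn{dv^a/dt = R^a \chi(t) g(u^a) - \lambda^a v^a,}
#' with `u` combining gap-gap interactions, the (position-fixed) Bcd input
#' and the time-dependent Cad input. Tll does not act in the analysis region
#' and is omitted from the shorted model.
#'
#' @param state Length-4 concentration vector.
#' @param t Time in minutes.
#' @param bcd Bcd concentration: a number or a function of `t`.
#' @param cad Cad concentration: a number or a function of `t`.
#' @param params A [circuit_parameters()] object.
#' @param schedule A [mitosis_schedule()], or `NULL` for the autonomous
#'   system (\eqn{\chi \equiv 1}).
#' @param neg_tol Negativity diagnostic threshold (concentration units).
#' @return Length-4 derivative vector (concentration/min).
#' @export
rhs_shorted <- function(state, t, bcd, cad, params, schedule,
                        neg_tol = 1e-6) {
  if (length(state) != n_genes()) {
    .err("state must have length 4", "gapcanal_invalid_input")
  }
  if (any(state < -neg_tol)) {
    .err("negative concentration beyond tolerance in state",
         "gapcanal_invalid_state")
  }
  bcd_t <- .as_time_fun(bcd, "bcd")(t)
  cad_t <- .as_time_fun(cad, "cad")(t)
  ch <- if (is.null(schedule)) 1 else chi_gate(t, schedule)
  u <- drop(params$T %*% state) + params$bcd_weight * bcd_t +
    params$ext_weight[, "cad"] * cad_t + params$h
  params$R * ch * regulation_g(u) - params$lambda * state
}

#' Right-hand side of the full spatial model
#'
#' As [rhs_shorted()] per nucleus, plus the Tll input and the discrete
#' diffusion operator
#' \eqn{D^a (v_{i-1} - v_i) + D^a (v_{i+1} - v_i)}, with the corresponding
#' neighbour term dropped at the first and last nucleus (zero-flux ends).
#'
#' @param state Genes x nuclei concentration matrix.
#' @param t Time in minutes.
#' @param bcd Per-nucleus Bcd concentrations (length = number of nuclei).
#' @param cad,tll Per-nucleus external inputs: numeric vectors or functions
#'   of `t` returning such vectors.
#' @param params A [circuit_parameters()] object.
#' @param schedule A [mitosis_schedule()] (or `NULL` for \eqn{\chi \equiv 1}).
#' @param lattice The [build_lattice()] the state lives on (sets the
#'   diffusion rates through its cycle).
#' @param neg_tol Negativity diagnostic threshold.
#' @return Derivative matrix, same shape as `state`.
#' @export
rhs_full <- function(state, t, bcd, cad, tll, params, schedule, lattice,
                     neg_tol = 1e-6) {
  V <- as.matrix(state)
  M <- ncol(V)
  if (M != length(lattice$positions)) {
    .err("state width does not match lattice", "gapcanal_invalid_input")
  }
  if (any(V < -neg_tol)) {
    .err("negative concentration beyond tolerance in state",
         "gapcanal_invalid_state")
  }
  cad_t <- if (is.function(cad)) cad(t) else rep_len(cad, M)
  tll_t <- if (is.function(tll)) tll(t) else rep_len(tll, M)
  ch <- if (is.null(schedule)) 1 else chi_gate(t, schedule)
  U <- .total_input_matrix(V, bcd, cad_t, tll_t, params)
  dV <- params$R * ch * regulation_g(U) - params$lambda * V
  D <- diffusion_rates(params, lattice$cycle)
  if (any(D > 0) && M > 1L) {
    Vl <- V[, c(1L, seq_len(M - 1L)), drop = FALSE]
    Vr <- V[, c(seq_len(M)[-1L], M), drop = FALSE]
    dV <- dV + D * ((Vl - V) + (Vr - V))
  }
  dV
}

# Segmented ODE driver: integrates dy/dt = f(t, y) from min(times) to
# max(times), restarting at the supplied breakpoints (chi discontinuities,
# input freeze), and returns the solution at `times`.
.ode_segmented <- function(y0, times, f, breaks, method, rtol, atol) {
  times <- sort(unique(times))
  t0 <- times[1L]; t1 <- times[length(times)]
  edges <- sort(unique(c(t0, t1, breaks[breaks > t0 & breaks < t1])))
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  if (t0 == t1) {
    out[1L, ] <- y0
    return(cbind(time = times, out))
  }
  y <- y0
  derivs <- function(t, y, parms) list(f(t, y))
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]; b <- edges[k + 1L]
    seg_times <- sort(unique(c(a, times[times > a & times <= b], b)))
    sol <- deSolve::ode(y = y, times = seg_times, func = derivs,
                        parms = NULL, method = method, rtol = rtol,
                        atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      .err(sprintf("ODE solver failed on [%g, %g] (istate = %d)",
                   a, b, attr(sol, "istate")[1L]),
           "gapcanal_integration_failure")
    }
    keep <- seg_times %in% times
    if (any(keep)) {
      out[match(seg_times[keep], times), ] <- sol[keep, -1L, drop = FALSE]
    }
    y <- sol[nrow(sol), -1L]
  }
  if (t0 %in% times) out[1L, ] <- y0
  cbind(time = times, out)
}

#' Integrate the shorted model for one nucleus
#'
#' Adaptive (stiff-capable) integration of the per-nucleus system, restarted
#' exactly at the mitotic gating discontinuities and at the T6 input freeze.
#'
#' @param ic Length-4 initial concentrations (at the first element of
#'   `times`), each in `[0, 255]`.
#' @param bcd,cad Inputs as in [rhs_shorted()].
#' @param params A [circuit_parameters()] object.
#' @param schedule A [mitosis_schedule()], or `NULL` for autonomous flow.
#' @param times Output times (minutes), increasing; integration starts at
#'   `times[1]`.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve method (default `"lsoda"`).
#' @return Matrix with columns `time, hb, Kr, gt, kni`.
#' @export
#' @examples
#' p <- gen_parameter_fixture("decoupled")
#' sol <- integrate_shorted_nucleus(c(50, 0, 0, 0), bcd = 10, cad = 5,
#'   params = p, schedule = mitosis_schedule(), times = c(0, 30, 71.1))
integrate_shorted_nucleus <- function(ic, bcd, cad, params, schedule,
                                      times, rtol = 1e-8, atol = 1e-8,
                                      method = "lsoda") {
  if (length(ic) != n_genes() || any(ic < 0) || any(ic > 255)) {
    .err("initial condition must be 4 concentrations in [0, 255]",
         "gapcanal_invalid_input")
  }
  bcd_f <- .as_time_fun(bcd, "bcd"); cad_f <- .as_time_fun(cad, "cad")
  f <- function(t, y) {
    ch <- if (is.null(schedule)) 1 else chi_gate(t, schedule)
    u <- drop(params$T %*% y) + params$bcd_weight * bcd_f(t) +
      params$ext_weight[, "cad"] * cad_f(t) + params$h
    params$R * ch * regulation_g(u) - params$lambda * y
  }
  breaks <- if (is.null(schedule)) numeric(0) else {
    c(schedule$interphase13_end, schedule$mitosis13_end, schedule$t_T6)
  }
  sol <- .ode_segmented(as.numeric(ic), times, f, breaks, method, rtol, atol)
  colnames(sol) <- c("time", gap_genes())
  sol
}

#' Integrate an ensemble of independent shorted-model nuclei
#'
#' Vectorized integration of K independent per-nucleus systems sharing the
#' interaction parameters but with per-column Bcd/Cad inputs (as used for
#' Monte-Carlo basin sampling and multi-position sweeps). Uses an adaptive
#' explicit Runge-Kutta method, avoiding the Jacobian cost of stiff solvers
#' on the stacked system.
#'
#' @param ic Genes x K matrix of initial concentrations.
#' @param bcd Length-K Bcd concentrations (recycled scalar allowed).
#' @param cad Length-K Cad concentrations, or a function of `t` returning
#'   such a vector.
#' @param params A [circuit_parameters()] object.
#' @param schedule A [mitosis_schedule()], or `NULL` for autonomous flow.
#' @param times Output times.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve method (default `"ode45"`).
#' @return List with `times` and `states`, a list of genes x K matrices.
#' @export
integrate_shorted_ensemble <- function(ic, bcd, cad, params, schedule,
                                       times, rtol = 1e-8, atol = 1e-8,
                                       method = "ode45") {
  V0 <- as.matrix(ic)
  K <- ncol(V0)
  bcd <- rep_len(bcd, K)
  cad_f <- if (is.function(cad)) cad else local({
    cv <- rep_len(cad, K); function(t) cv
  })
  f <- function(t, y) {
    V <- matrix(y, nrow = n_genes())
    ch <- if (is.null(schedule)) 1 else chi_gate(t, schedule)
    U <- .total_input_matrix(V, bcd, cad_f(t), 0, params)
    as.vector(params$R * ch * regulation_g(U) - params$lambda * V)
  }
  breaks <- if (is.null(schedule)) numeric(0) else {
    c(schedule$interphase13_end, schedule$mitosis13_end, schedule$t_T6)
  }
  sol <- .ode_segmented(as.vector(V0), times, f, breaks, method, rtol, atol)
  states <- lapply(seq_len(nrow(sol)), function(i) {
    matrix(sol[i, -1L], nrow = n_genes(),
           dimnames = list(gap_genes(), NULL))
  })
  list(times = sol[, 1L], states = states)
}

#' Integrate the full gap gene circuit
#'
#' Runs the spatial model from the start of cleavage cycle 13: interphase 13
#' (synthesis on), mitosis 13 (synthesis gated off), the nuclear division
#' event (states copied to daughters), then cycle 14A up to the last
#' requested time. Initial conditions are the maternal Hb gradient with the
#' other three genes at zero.
#'
#' @param hb0 Maternal Hb initial gradient: a function of position (%EL) or
#'   a numeric vector over `lattice13$positions`; values in `[0, 255]`.
#' @param bcd Bcd profile: a [bcd_exponential()] object or a function of
#'   position returning concentration.
#' @param cad_table,tll_table [external_input_table()] objects (or single
#'   numbers / `NULL` for constant / absent inputs).
#' @param params A [circuit_parameters()] object.
#' @param schedule A [mitosis_schedule()].
#' @param lattice13 Cycle-13 [build_lattice()].
#' @param times Output times; the division time is handled internally.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve method for each phase (default `"lsoda"`).
#' @return Object of class `circuit_solution`: list with `times`, `states`
#'   (list of genes x nuclei matrices), `lattices` (per output time),
#'   `schedule`, `params`.
#' @export
integrate_full_circuit <- function(hb0, bcd, cad_table, tll_table, params,
                                   schedule, lattice13, times,
                                   rtol = 1e-8, atol = 1e-8,
                                   method = "lsoda") {
  if (lattice13$cycle != "13") {
    .err("lattice13 must be a cycle-13 lattice", "gapcanal_invalid_input")
  }
  pos13 <- lattice13$positions
  hb0v <- if (is.function(hb0)) hb0(pos13) else rep_len(hb0, length(pos13))
  if (any(hb0v < 0) || any(hb0v > 255)) {
    .err("maternal Hb initial gradient must lie in [0, 255]",
         "gapcanal_invalid_input")
  }
  bcd_f <- if (is.function(bcd)) bcd else function(x) eval_bcd(bcd, x)
  t_div <- schedule$mitosis13_end
  times <- sort(unique(times))
  if (times[1L] < schedule$t0) {
    .err("times must start at or after the schedule start",
         "gapcanal_invalid_input")
  }

  make_f <- function(lattice) {
    pos <- lattice$positions
    bcd_v <- bcd_f(pos)
    cad_f <- external_input_fun(cad_table, pos, schedule)
    tll_f <- external_input_fun(tll_table, pos, schedule)
    D <- diffusion_rates(params, lattice$cycle)
    M <- length(pos)
    function(t, y) {
      V <- matrix(y, nrow = n_genes())
      ch <- chi_gate(t, schedule)
      U <- .total_input_matrix(V, bcd_v, cad_f(t), tll_f(t), params)
      dV <- params$R * ch * regulation_g(U) - params$lambda * V
      if (any(D > 0) && M > 1L) {
        Vl <- V[, c(1L, seq_len(M - 1L)), drop = FALSE]
        Vr <- V[, c(seq_len(M)[-1L], M), drop = FALSE]
        dV <- dV + D * ((Vl - V) + (Vr - V))
      }
      as.vector(dV)
    }
  }

  out_times <- numeric(0)
  out_states <- list()
  out_lattices <- list()
  collect <- function(sol, lattice, keep_times) {
    for (tt in keep_times) {
      i <- match(tt, sol[, 1L])
      out_times <<- c(out_times, tt)
      out_states[[length(out_states) + 1L]] <<- matrix(
        sol[i, -1L], nrow = n_genes(),
        dimnames = list(gap_genes(), NULL))
      out_lattices[[length(out_lattices) + 1L]] <<- lattice
    }
  }

  V13 <- rbind(hb0v, 0, 0, 0)
  t13 <- times[times <= t_div]
  f13 <- make_f(lattice13)
  sol13 <- .ode_segmented(as.vector(V13), unique(c(schedule$t0, t13, t_div)),
                          f13, schedule$interphase13_end, method, rtol, atol)
  collect(sol13, lattice13, setdiff(t13, t_div))
  end13 <- matrix(sol13[nrow(sol13), -1L], nrow = n_genes())

  div <- apply_nuclear_division(end13, lattice13)
  lattice14 <- div$lattice
  # a time point exactly at the division is reported post-division
  if (t_div %in% times) collect(
    cbind(time = t_div, matrix(as.vector(div$state), nrow = 1L)),
    lattice14, t_div)

  t14 <- times[times > t_div]
  if (length(t14)) {
    f14 <- make_f(lattice14)
    sol14 <- .ode_segmented(as.vector(div$state), unique(c(t_div, t14)),
                            f14, schedule$t_T6, method, rtol, atol)
    collect(sol14, lattice14, t14)
  }

  ord <- order(out_times)
  structure(list(times = out_times[ord], states = out_states[ord],
                 lattices = out_lattices[ord], schedule = schedule,
                 params = params),
            class = "circuit_solution")
}

#' Extract the state at one time from a circuit solution
#'
#' @param sol A `circuit_solution` from [integrate_full_circuit()].
#' @param t One of the solution's output times.
#' @return List with `state` (genes x nuclei) and `lattice`.
#' @export
state_at <- function(sol, t) {
  i <- match(TRUE, abs(sol$times - t) < 1e-9)
  if (is.na(i)) .err("time not among the solution's output times",
                     "gapcanal_invalid_input")
  list(state = sol$states[[i]], lattice = sol$lattices[[i]])
}

#' @export
print.circuit_solution <- function(x, ...) {
  cat(sprintf("Gap gene circuit solution: %d time points on [%g, %g] min\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
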