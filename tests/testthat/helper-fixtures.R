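# Shared fixtures and independent oracle helpers.

fx_schedule <- function() mitosis_schedule()

fx_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_external_inputs()
    cache
  }
})

fx_params <- function(preset = "bistable_border") {
  gen_parameter_fixture(preset)
}

# Naive term-by-term total-input summation (oracle for total_input).
naive_total_input <- function(a, state, bcd, cad, tll, params) {
  u <- params$h[[a]]
  for (b in 1:4) u <- u + params$T[a, b] * state[b]
  u <- u + params$bcd_weight[[a]] * bcd
  u + params$ext_weight[a, "cad"] * cad + params$ext_weight[a, "tll"] * tll
}

# Fixed-step classical RK4 (oracle for the adaptive integrators).
rk4_integrate <- function(f, y0, t0, t1, n_steps) {
  h <- (t1 - t0) / n_steps
  y <- y0; t <- t0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Independent brute-force equilibrium enumeration for systems whose active
# dynamics live in the (gene i, gene j) plane with the other genes at their
# trivial decay equilibrium (0). Sign-change cell scan + damped Newton
# polish with a central-difference Jacobian (no reuse of package internals).
brute_force_equilibria_2d <- function(params, bcd, cad, genes = c(1L, 2L),
                                      upper = 210, n = 200L) {
  f2 <- function(v2) {
    v <- numeric(4); v[genes] <- v2
    rhs_autonomous(v, bcd, cad, params)[genes]
  }
  g1 <- seq(0, upper, length.out = n)
  F1 <- outer(g1, g1, Vectorize(function(a, b) f2(c(a, b))[1]))
  F2 <- outer(g1, g1, Vectorize(function(a, b) f2(c(a, b))[2]))
  cells <- which(
    (F1[-n, -n] * F1[-1, -n] <= 0 | F1[-n, -n] * F1[-n, -1] <= 0 |
       F1[-n, -n] * F1[-1, -1] <= 0) &
      (F2[-n, -n] * F2[-1, -n] <= 0 | F2[-n, -n] * F2[-n, -1] <= 0 |
         F2[-n, -n] * F2[-1, -1] <= 0), arr.ind = TRUE)
  roots <- NULL
  for (r in seq_len(nrow(cells))) {
    v <- c(g1[cells[r, 1]], g1[cells[r, 2]]) + upper / (2 * (n - 1))
    for (it in 1:60) {
      fv <- f2(v)
      if (max(abs(fv)) < 1e-10) break
      eps <- 1e-5
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        e <- c(0, 0); e[k] <- eps
        J[, k] <- (f2(v + e) - f2(v - e)) / (2 * eps)
      }
      dv <- tryCatch(solve(J, -fv), error = function(e) NULL)
      if (is.null(dv)) break
      if (sqrt(sum(dv^2)) > upper / 4) dv <- dv * (upper / 4) /
          sqrt(sum(dv^2))
      v <- v + dv
    }
    if (max(abs(f2(v))) < 1e-8 && all(v > -1e-6)) {
      v <- pmax(v, 0)
      if (is.null(roots) ||
          all(sqrt(colSums((t(roots) - v)^2)) > 0.5)) {
        roots <- rbind(roots, v)
      }
    }
  }
  roots[order(roots[, 1]), , drop = FALSE]
}
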