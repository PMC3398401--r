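test_that("with zero synthesis the shorted model decays exactly", {
  p <- fx_params("decoupled")
  p$R[] <- 0
  sch <- fx_schedule()
  v0 <- c(100, 80, 60, 40)
  sol <- integrate_shorted_nucleus(v0, bcd = 10, cad = 5, params = p,
                                   schedule = sch,
                                   times = c(0, 10, 40, 71.1))
  for (i in 2:4) {
    expect_equal(unname(sol[i, -1]),
                 v0 * exp(-unname(p$lambda) * sol[i, 1]), tolerance = 1e-6)
  }
})

test_that("synthesis is gated off exactly during mitosis", {
  p <- fx_params("bistable_border")
  sch <- fx_schedule()
  st <- c(50, 50, 10, 10)
  d_mit <- rhs_shorted(st, 18, bcd = 10, cad = 5, params = p,
                       schedule = sch)
  expect_equal(unname(d_mit), unname(-p$lambda * st))
  # across the whole mitosis window the solution decays in closed form
  sol <- integrate_shorted_nucleus(st, 10, 5, p, sch,
                                   times = c(sch$interphase13_end,
                                             sch$mitosis13_end))
  expect_equal(unname(sol[2, -1]),
               st * exp(-unname(p$lambda) * (sch$mitosis13_end -
                                       sch$interphase13_end)),
               tolerance = 1e-7)
})

test_that("a single constant-input gene reaches R g(u)/lambda", {
  p <- circuit_parameters(R = c(10, 0, 0, 0), T_matrix = matrix(0, 4, 4),
                          bcd_weight = c(0.5, 0, 0, 0),
                          ext_weight = rep(0, 4), h = c(-1, 0, 0, 0),
                          lambda = rep(0.05, 4), D = rep(0, 4))
  u <- 0.5 * 6 - 1
  vstar <- 10 * regulation_g(u) / 0.05
  sol <- integrate_shorted_nucleus(c(0, 0, 0, 0), bcd = 6, cad = 0,
                                   params = p, schedule = NULL,
                                   times = c(0, 400))
  expect_equal(unname(sol[2, "hb"]), vstar, tolerance = 1e-6)
})

test_that("adaptive integration matches a fine fixed-step RK4 run", {
  p <- fx_params("bistable_border")
  f <- function(t, y) rhs_autonomous(y, 8, 20, p)
  y0 <- c(60, 10, 0, 0)
  ref <- unname(rk4_integrate(f, y0, 0, 30, 6000))
  sol <- integrate_shorted_nucleus(y0, bcd = 8, cad = 20, params = p,
                                   schedule = NULL, times = c(0, 30),
                                   rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(sol[2, -1]), ref, tolerance = 1e-8)
})

test_that("full-model RHS reduces to per-nucleus dynamics", {
  p <- fx_params("bistable_border")
  sch <- fx_schedule()
  lat <- build_lattice(c(37, 57), "13")
  M <- length(lat$positions)
  # uniform state: diffusion contributes exactly zero
  V <- matrix(c(80, 40, 10, 5), nrow = 4, ncol = M)
  d_full <- rhs_full(V, 10, bcd = rep(7, M), cad = rep(15, M),
                     tll = rep(0, M), params = p, schedule = sch,
                     lattice = lat)
  d_short <- rhs_shorted(c(80, 40, 10, 5), 10, 7, 15, p, sch)
  for (i in seq_len(M)) expect_equal(unname(d_full[, i]),
                                     unname(d_short))
  # 3-nucleus toy: hand-computed discrete Laplacian with dropped ends
  lat3 <- build_lattice(c(47, 50), "13")  # 47, 49, 51
  V3 <- rbind(c(10, 40, 20), 0, 0, 0)
  p0 <- p; p0$R[] <- 0; p0$lambda[] <- 1e-9
  d3 <- rhs_full(V3, 10, rep(0, 3), rep(0, 3), rep(0, 3), p0, sch, lat3)
  D_hb <- diffusion_rates(p, "13")[["hb"]]
  expect_equal(d3[1, ], c(D_hb * (40 - 10),
                          D_hb * ((10 - 40) + (20 - 40)),
                          D_hb * (40 - 20)), tolerance = 1e-6)
})

test_that("zero-synthesis full runs decay through the division copy", {
  p <- fx_params("decoupled"); p$R[] <- 0
  sch <- fx_schedule()
  lat13 <- build_lattice(c(37, 57), "13")
  hb0 <- function(x) rep(100, length(x))
  sol <- integrate_full_circuit(hb0, function(x) rep(0, length(x)),
                                NULL, NULL, p, sch, lat13,
                                times = c(sch$mitosis13_end, sch$tau))
  st_div <- state_at(sol, sch$mitosis13_end)
  expect_equal(ncol(st_div$state), 22)
  expect_equal(unname(st_div$state[1, ]),
               rep(100 * exp(-p$lambda[[1]] * sch$mitosis13_end), 22),
               tolerance = 1e-7)
  st_tau <- state_at(sol, sch$tau)
  expect_equal(unname(st_tau$state[1, ]),
               rep(100 * exp(-p$lambda[[1]] * sch$tau), 22),
               tolerance = 1e-7)
})

test_that("full-circuit endpoints are converged in solver tolerance", {
  p <- fx_params("bistable_border")
  sch <- fx_schedule()
  ext <- fx_inputs()
  med <- bcd_exponential(150, 0.0665)
  lat13 <- build_lattice(c(37, 57), "13")
  hb0 <- gen_maternal_hb()
  run <- function(rtol) {
    s <- integrate_full_circuit(hb0, med, ext$cad, ext$tll, p, sch, lat13,
                                times = sch$tau, rtol = rtol, atol = rtol)
    state_at(s, sch$tau)$state
  }
  a <- run(1e-8); b <- run(1e-10)
  expect_equal(a, b, tolerance = 1e-5)
})

test_that("trajectories stay nonnegative and bounded", {
  p <- fx_params("bistable_border")
  sch <- fx_schedule()
  bound <- pmax(255, p$R / p$lambda) + 1e-6
  for (seed in 1:6) {
    ic <- withr::with_seed(seed, stats::runif(4, 0, 255))
    sol <- integrate_shorted_nucleus(ic, bcd = 5 * seed, cad = 10,
                                     params = p, schedule = sch,
                                     times = seq(0, 150, by = 10))
    states <- sol[, -1]
    expect_true(all(states >= -1e-6))
    expect_true(all(t(states) <= pmax(ic, p$R / p$lambda) + 1e-6))
  }
})
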