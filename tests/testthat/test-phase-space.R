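test_that("single-gene and decoupled circuits have closed-form equilibria", {
  p <- fx_params("decoupled")  # T = 0: u is state-independent
  bcd <- 10; cad <- 20
  u <- p$bcd_weight * bcd + p$ext_weight[, "cad"] * cad + p$h
  vstar <- p$R * regulation_g(u) / p$lambda
  eqs <- find_equilibria(bcd, cad, p, n_grid = 4L, n_extra = 60L)
  expect_length(eqs, 1)
  expect_equal(unname(eqs[[1]]$state), unname(vstar), tolerance = 1e-7)
  expect_identical(eqs[[1]]$stability, "attractor")
  expect_equal(Re(eqs[[1]]$eigenvalues), unname(-p$lambda),
               tolerance = 1e-9)
})

test_that("1-D toy equilibria equal the exhaustive scalar root scan", {
  toy <- gen_toy_system("1d_bistable")
  eqs <- find_equilibria(toy$bcd, toy$cad, toy$params,
                         n_grid = 5L, n_extra = 100L)
  hb <- sort(vapply(eqs, function(e) e$state[["hb"]], numeric(1)))
  # independent oracle: bracketed uniroot scan of the scalar fixed-point
  # equation R g(T v + h) - lambda v = 0
  fp <- function(v) {
    16 * regulation_g(0.05 * v + toy$params$h[["hb"]]) - 0.08 * v
  }
  grid <- seq(0, 300, length.out = 3001)
  fg <- fp(grid)
  roots <- sort(vapply(which(fg[-3001] * fg[-1] <= 0), function(i) {
    stats::uniroot(fp, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1)))
  roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  expect_length(hb, 3)
  expect_equal(hb, roots, tolerance = 1e-6)
  stab <- vapply(eqs, function(e) e$stability, character(1))
  expect_equal(sort(stab), c("attractor", "attractor", "saddle_1"))
  expect_equal(toy$facts$separatrix, 50, tolerance = 1e-9)
})

test_that("2-D toy equilibria equal brute-force grid enumeration", {
  toy <- gen_toy_system("2d_saddle")
  eqs <- find_equilibria(toy$bcd, toy$cad, toy$params,
                         n_grid = 5L, n_extra = 100L)
  found <- t(vapply(eqs, function(e) e$state[1:2], numeric(2)))
  found <- found[order(found[, 1]), , drop = FALSE]
  bf <- brute_force_equilibria_2d(toy$params, toy$bcd, toy$cad)
  expect_equal(nrow(found), nrow(bf))
  expect_equal(unname(found), unname(bf), tolerance = 1e-5)
})

test_that("stability classification matches eigen-structure and oracle", {
  toy <- gen_toy_system("2d_saddle")
  cls <- classify_stability(toy$facts$saddle, 0, 0, toy$params)
  expect_identical(cls$stability, "saddle_1")
  expect_equal(sort(Re(cls$eigenvalues)), sort(toy$facts$eigenvalues),
               tolerance = 1e-10)
  # analytic Jacobian against a central finite-difference Jacobian
  p <- fx_params("bistable_border")
  v <- c(60, 40, 10, 5)
  J <- jacobian_autonomous(v, 8, 20, p)
  Jfd <- matrix(0, 4, 4)
  for (k in 1:4) {
    e <- numeric(4); e[k] <- 1e-5
    Jfd[, k] <- (rhs_autonomous(v + e, 8, 20, p) -
                   rhs_autonomous(v - e, 8, 20, p)) / 2e-5
  }
  expect_equal(unname(J), Jfd, tolerance = 1e-5)
})

test_that("symbolic codes follow the 50/150 thresholds", {
  expect_identical(code_state(c(200, 10, 10, 10)), "1000")
  expect_identical(code_state(c(10, 200, 10, 10)), "0100")
  expect_identical(code_state(c(200, 10, 100, 5)), "10X0")
  expect_identical(code_state(c(50, 150, 49.9, 150.1)), "XX01")
  expect_error(code_state(c(-1, 0, 0, 0)), class = "gapcanal_error")
  # codes are stable under perturbations away from the thresholds
  for (seed in 1:20) {
    st <- withr::with_seed(seed, stats::runif(4, 0, 255))
    near <- pmin(abs(st - 50), abs(st - 150))
    st <- ifelse(near < 1, st + 2, st)  # keep away from thresholds
    dd <- withr::with_seed(seed + 50, stats::runif(4, -0.45, 0.45))
    expect_identical(code_state(pmax(st + dd, 0)), code_state(st))
  }
})

test_that("equilibrium sets are invariant under multistart doubling", {
  ext <- fx_inputs(); sch <- fx_schedule()
  p <- fx_params("bistable_border")
  for (x in c(41, 49, 57)) {
    bcd <- 150 * exp(-0.0665 * x)
    cad <- external_input_fun(ext$cad, x, sch)(sch$t_T6)
    e1 <- find_equilibria(bcd, cad, p, n_grid = 3L, n_extra = 60L)
    e2 <- find_equilibria(bcd, cad, p, n_grid = 6L, n_extra = 120L)
    expect_equal(length(e1), length(e2))
    expect_setequal(vapply(e1, function(e) e$code, character(1)),
                    vapply(e2, function(e) e$code, character(1)))
  }
})

test_that("plane scans localize the fold of a one-gene toy", {
  # single self-activating gene with Bcd input: fold where g'(u) R T = lambda
  R1 <- 16; lam <- 0.08; Ts <- 0.05; h1 <- -6; m <- 0.3
  Tm <- matrix(0, 4, 4); Tm[1, 1] <- Ts
  p <- circuit_parameters(R = c(R1, 0, 0, 0), T_matrix = Tm,
                          bcd_weight = c(m, 0, 0, 0),
                          ext_weight = rep(0, 4), h = c(h1, 0, 0, 0),
                          lambda = c(lam, 0.1, 0.1, 0.1), D = rep(0, 4))
  ustar <- -sqrt((R1 * Ts / (2 * lam))^(2 / 3) - 1)
  b_fold <- (ustar - Ts * R1 * regulation_g(ustar) / lam - h1) / m
  scan <- scan_bcd_cad_plane(p, bcd_range = c(0, 25), cad_range = c(0, 1),
                             resolution = c(60L, 2L), n_grid = 4L,
                             n_extra = 40L)
  cell <- diff(scan$bcd_grid[1:2])
  sn <- scan$boundaries[scan$boundaries$type == "saddle-node", ]
  expect_gt(nrow(sn), 0)
  expect_lt(min(abs(sn$bcd - b_fold)), cell)
  # attractor counts drop from 2 to 1 across the fold
  nodes1 <- scan$nodes[scan$nodes$cad == 0, ]
  expect_true(all(nodes1$n_attractors[nodes1$bcd < b_fold - cell] == 2))
  expect_true(all(nodes1$n_attractors[nodes1$bcd > b_fold + cell] == 1))
})

test_that("monostable circuits scan to a single unbounded domain", {
  p <- fx_params("monostable")
  scan <- scan_bcd_cad_plane(p, c(0, 40), c(0, 80),
                             resolution = c(6L, 6L), n_grid = 3L,
                             n_extra = 30L)
  expect_true(all(scan$nodes$n_attractors == 1))
  expect_equal(nrow(scan$boundaries), 0)
})

test_that("unstable manifolds start along the eigenvector and end at attractors", {
  toy <- gen_toy_system("2d_saddle")
  eqs <- find_equilibria(0, 0, toy$params, n_grid = 4L, n_extra = 60L)
  sad <- Filter(function(e) e$stability == "saddle_1", eqs)[[1]]
  tr <- trace_unstable_manifold(sad, 0, 0, toy$params, eps = 0.1,
                                t_max = 400)
  # eigen-direction matches the constructed (1,-1)/sqrt(2) structure
  expect_equal(abs(sum(tr$w * toy$facts$unstable_direction)), 1,
               tolerance = 1e-8)
  # early departure stays parallel to the eigen-direction
  d1 <- tr$branches[[1]][2, ] - tr$saddle
  expect_gt(abs(sum(d1 / sqrt(sum(d1^2)) * tr$w)), 0.999)
  # branches terminate at the two flanking attractors
  atts <- Filter(function(e) e$stability == "attractor", eqs)
  ends <- t(vapply(tr$branches, function(b) unname(b[nrow(b), ]),
                   numeric(4)))
  for (a in atts) {
    expect_lt(min(sqrt(rowSums((ends - rep(a$state, each = 2))^2))), 0.1)
  }
  # flow invariance: re-integrated trace points stay on the trace
  b1 <- tr$branches[[1]]
  for (i in c(20, 60, 120)) {
    nxt <- integrate_shorted_nucleus(pmin(pmax(b1[i, ], 0), 255),
                                     0, 0, toy$params, NULL,
                                     times = c(0, 4))[2, -1]
    expect_lt(min(sqrt(rowSums((b1 - rep(nxt, each = nrow(b1)))^2))),
              0.5)
  }
  # only 1-D unstable manifolds are supported
  att <- atts[[1]]
  expect_error(trace_unstable_manifold(att, 0, 0, toy$params),
               class = "gapcanal_unsupported_saddle")
})
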