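test_that("monostable circuits give a single whole-segment basin", {
  p <- fx_params("monostable")
  part <- sample_basin_partition(10, 20, p, schedule = fx_schedule(),
                                 n_samples = 100, seed = 1,
                                 n_grid = 3L, n_extra = 40L)
  expect_equal(nrow(part$intervals), 1)
  expect_equal(part$intervals$c1, 0)
  expect_equal(part$intervals$c2, 100)
  expect_equal(part$unresolved_fraction, 0)
})

test_that("the 1-D bistable toy boundary converges to the separatrix", {
  toy <- gen_toy_system("1d_bistable")
  part <- sample_basin_partition(toy$bcd, toy$cad, toy$params,
                                 schedule = NULL, n_samples = 200,
                                 seed = 7, refine = TRUE,
                                 refine_tol = 5e-4,
                                 n_grid = 4L, n_extra = 50L)
  expect_equal(nrow(part$intervals), 2)
  cut <- part$intervals$c2[1]
  expect_lt(abs(cut - toy$facts$separatrix), 1e-3)
  # unrefined Monte-Carlo boundary is within the sampling resolution
  part_mc <- sample_basin_partition(toy$bcd, toy$cad, toy$params,
                                    schedule = NULL, n_samples = 400,
                                    seed = 8, refine = FALSE,
                                    n_grid = 4L, n_extra = 50L)
  expect_lt(abs(part_mc$intervals$c2[1] - toy$facts$separatrix),
            3 * 100 / 400)
})

test_that("partitions are deterministic and measure exactly 100", {
  toy <- gen_toy_system("1d_bistable")
  p1 <- sample_basin_partition(toy$bcd, toy$cad, toy$params, NULL,
                               n_samples = 150, seed = 3,
                               n_grid = 3L, n_extra = 40L)
  p2 <- sample_basin_partition(toy$bcd, toy$cad, toy$params, NULL,
                               n_samples = 150, seed = 3,
                               n_grid = 3L, n_extra = 40L)
  expect_identical(p1$intervals, p2$intervals)
  expect_identical(p1$samples, p2$samples)
  measure <- sum(p1$intervals$c2 - p1$intervals$c1) +
    sum(p1$gaps$c2 - p1$gaps$c1)
  expect_equal(measure, 100, tolerance = 1e-12)
  # consistency: interval midpoints flow to the assigned attractor
  for (k in seq_len(nrow(p1$intervals))) {
    mid <- (p1$intervals$c1[k] + p1$intervals$c2[k]) / 2
    sol <- integrate_shorted_nucleus(c(mid, 0, 0, 0), toy$bcd, toy$cad,
                                     toy$params, NULL, times = c(0, 800))
    att <- Filter(function(e) e$label == p1$intervals$label[k],
                  p1$attractors)[[1]]
    expect_lt(sqrt(sum((sol[2, -1] - att$state)^2)), 1.0)
  }
})

test_that("basin boundary profiles interpolate linearly between nuclei", {
  fake <- function(c_cut) {
    structure(list(intervals = data.frame(
      label = c("0100", "1000"), c1 = c(0, c_cut), c2 = c(c_cut, 100))),
      class = "basin_partition")
  }
  parts <- list(`47` = fake(40), `49` = fake(60), `51` = fake(70))
  curve <- basin_boundary_profile(parts, pair = c("0100", "1000"))
  f <- attr(curve, "fun")
  expect_equal(f(48), 50)
  expect_equal(f(50), 65)
  expect_equal(f(c(47, 49, 51)), c(40, 60, 70))
  expect_error(basin_boundary_profile(parts, pair = c("0100", "0010")),
               class = "gapcanal_empty_curve")
  expect_warning(basin_boundary_profile(parts[1], pair = c("0100", "1000")),
                 class = "gapcanal_degenerate_curve")
})

test_that("gradient-boundary intersections match a dense grid scan", {
  hb0 <- function(x) 100 - 5 * (x - 37)  # 100 at 37, 0 at 57
  curve <- data.frame(x = c(37, 57), hb = c(0, 100))
  expect_equal(intersect_initial_hb(hb0, curve), 47, tolerance = 1e-3)
  # gradient everywhere above the boundary: no crossing
  expect_length(intersect_initial_hb(function(x) rep(100, length(x)),
                                     data.frame(x = c(37, 57),
                                                hb = c(0, 50))), 0)
  # wiggly boundary with three crossings versus an independent fine scan
  wig <- function(x) 50 + 30 * sin((x - 37) / 3)
  xs <- seq(37, 57, by = 0.25)
  curve3 <- data.frame(x = xs, hb = wig(xs))
  hb0b <- function(x) 120 - 3 * (x - 37)
  hits <- intersect_initial_hb(hb0b, curve3)
  fgrid <- seq(37, 57, by = 1e-3)
  d <- hb0b(fgrid) - stats::approx(xs, wig(xs), xout = fgrid)$y
  sc <- fgrid[which(d[-length(d)] * d[-1] < 0)]
  expect_equal(length(hits), length(sc))
  expect_true(all(abs(hits - sc) < 2e-3))
})

test_that("opposite-slope boundaries canalize intersection spread", {
  res <- opposite_slope_spread(hb0_slope = -5, boundary_slope = 2.5,
                               offsets = seq(-8, 8, by = 2))
  expect_true(all(!is.na(res$opposite$intersections)))
  expect_true(all(!is.na(res$covarying$intersections)))
  expect_lt(res$opposite$sd, res$covarying$sd)
  # analytic spread ratio |s0 - s_b| gives (k0-k)/(k0+k)
  expect_equal(res$opposite$sd / res$covarying$sd, (5 - 2.5) / (5 + 2.5),
               tolerance = 1e-3)
})
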