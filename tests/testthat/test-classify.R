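make_att <- function(state, label) {
  structure(list(state = state, stability = "attractor",
                 eigenvalues = rep(-0.1 + 0i, 4),
                 code = label, label = label), class = "equilibrium")
}

test_that("border mechanisms follow attractor/manifold proximity", {
  a_on <- make_att(c(197, 2, 0, 0), "1000")
  a_off <- make_att(c(2, 197, 0, 0), "0100")
  fake_manifold <- structure(list(
    saddle = c(100, 100, 0, 0), w = c(1, -1, 0, 0) / sqrt(2),
    branches = list(matrix(c(100, 100, 0, 0, 120, 80, 0, 0), nrow = 2,
                           byrow = TRUE),
                    matrix(c(100, 100, 0, 0, 80, 120, 0, 0), nrow = 2,
                           byrow = TRUE))), class = "manifold_trace")
  # both endpoints at attractors -> AA
  r <- classify_border_mechanism(c(197, 2, 0, 0), c(2, 197, 0, 0),
                                 list(a_on), list(a_off))
  expect_identical(r$mechanism, "AA")
  # an endpoint placed exactly on an attractor is "A" for any delta_A > 0
  r2 <- classify_border_mechanism(a_on$state, c(2, 197, 0, 0),
                                  list(a_on), list(a_off),
                                  delta_A = 1e-9)
  expect_identical(r2$anterior, "A")
  # posterior endpoint near the manifold, away from attractors -> AM
  r3 <- classify_border_mechanism(c(197, 2, 0, 0), c(119, 81, 0, 0),
                                  list(a_on), list(a_off),
                                  list(), list(fake_manifold))
  expect_identical(r3$mechanism, "AM")
  r4 <- classify_border_mechanism(c(119, 81, 0, 0), c(121, 79, 0, 0),
                                  list(a_on), list(a_off),
                                  list(fake_manifold),
                                  list(fake_manifold))
  expect_identical(r4$mechanism, "MM")
  # neither close -> unclassified
  r5 <- classify_border_mechanism(c(50, 50, 50, 50), c(2, 197, 0, 0),
                                  list(a_on), list(a_off))
  expect_identical(r5$mechanism, "unclassified")
})

test_that("family labels are a pure function of the transition codes", {
  # exhaustive over hb-ON/OFF code pairs
  expect_identical(family_label("1000", "0100"), "I")   # A1 -> A3 type
  expect_identical(family_label("1100", "0100"), "I")   # A2 -> A3 type
  expect_identical(family_label("1100", "1000"), "II")  # A2 -> A1 type
  expect_identical(family_label("1000", "1100"), "II")
  expect_identical(family_label("0100", "0000"), "unclassified")
  expect_identical(family_label("0100", "1000"), "unclassified")
  expect_identical(family_label("1000", "1000"), "unclassified")
  expect_identical(family_label(NA_character_, "1000"), "unclassified")
})

test_that("basin transitions identify the owning attractors", {
  part <- function(cut, lab_lo, lab_hi) {
    structure(list(intervals = data.frame(
      label = c(lab_lo, lab_hi), c1 = c(0, cut), c2 = c(cut, 100)),
      gaps = data.frame(c1 = numeric(0), c2 = numeric(0))),
      class = "basin_partition")
  }
  ant <- part(30, "0100", "1000")
  post <- part(60, "0100", "1000")
  tr <- classify_basin_transition(ant, post, 50, 40)
  expect_identical(tr$transition, "1000->0100")
  expect_identical(tr$family, "I")
  # both sides in the same basin: no transition (the exceptional case)
  tr2 <- classify_basin_transition(ant, post, 80, 80)
  expect_identical(tr2$transition, "none")
  expect_identical(tr2$family, "unclassified")
  # ON -> ON transition is Family II
  ant3 <- part(30, "0100", "1100")
  post3 <- part(60, "0100", "1000")
  expect_identical(classify_basin_transition(ant3, post3, 50, 70)$family,
                   "II")
  # value inside a gap raises an unresolved condition
  gappy <- structure(list(intervals = data.frame(
    label = "1000", c1 = 50, c2 = 100),
    gaps = data.frame(c1 = 0, c2 = 50)), class = "basin_partition")
  expect_error(classify_basin_transition(gappy, post, 20, 40),
               class = "gapcanal_unresolved")
})

test_that("solution classes follow the anterior Kr/gt pattern rules", {
  x <- seq(35, 71, by = 1)
  gt_hump <- ifelse(x >= 38 & x <= 44, 200, 10)
  kr_rise <- ifelse(x >= 46, 220, 20)
  expect_identical(classify_solution_class(x, kr_rise, gt_hump)$class,
                   "I")
  # ectopic anterior Kr, no gt hump -> II
  kr_ect <- rep(200, length(x))
  expect_identical(classify_solution_class(x, kr_ect,
                                           rep(10, length(x)))$class,
                   "II")
  # neither anterior Kr nor gt -> III
  expect_identical(classify_solution_class(x, rep(20, length(x)),
                                           rep(20, length(x)))$class,
                   "III")
})
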