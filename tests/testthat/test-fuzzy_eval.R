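test_that("scalar membership is piecewise linear with unit mass", {
  g <- grade_set()
  expect_equal(membership_scalar(2.0, g),
               c(healthy = 0, mild = 0, moderate = 1, severe = 0))
  # 1.8 is the midpoint of the 1.6 and 2.0 apexes
  expect_equal(membership_scalar(1.8, g),
               c(healthy = 0, mild = 0.5, moderate = 0.5, severe = 0))
  expect_equal(membership_scalar(1.0, g),
               c(healthy = 1, mild = 0, moderate = 0, severe = 0))
  expect_equal(membership_scalar(5.0, g),
               c(healthy = 0, mild = 0, moderate = 0, severe = 1))
  expect_error(membership_scalar(0.5, g), "outside the scale range")

  for (x in seq(1, 5, by = 0.05)) {
    mu <- membership_scalar(x, g)
    expect_equal(sum(mu), 1, tolerance = 1e-9)
    expect_lte(sum(mu > 0), 2)            # at most two adjacent grades
    if (sum(mu > 0) == 2) expect_equal(unname(diff(which(mu > 0))), 1L)
  }
})

test_that("categorical membership returns normalized configured rows", {
  g <- grade_set()
  tab <- list(yes = c(1, 0, 0, 0), unif = c(1, 1, 1, 1),
              part = c(0.6, 0.4, 0, 0), unnorm = c(3, 2, 0, 0))
  expect_equal(unname(membership_categorical("yes", tab, g)), c(1, 0, 0, 0))
  expect_equal(unname(membership_categorical("unif", tab, g)), rep(0.25, 4))
  expect_equal(unname(membership_categorical("part", tab, g)),
               c(0.6, 0.4, 0, 0))
  expect_equal(unname(membership_categorical("unnorm", tab, g)),
               c(0.6, 0.4, 0, 0))
  expect_error(membership_categorical("nope", tab, g), "unknown category")
})

test_that("set-valued weighting aggregates interval midpoints", {
  one <- data.frame(expert = 1, factor = c("A", "B"),
                    lower = c(0.2, 0.6), upper = c(0.4, 0.8))
  expect_equal(set_valued_weights(one), c(A = 0.3, B = 0.7))

  # identical experts: symmetry forces uniform weights
  same <- expand.grid(expert = 1:4, factor = c("A", "B", "C"))
  same$lower <- 0.3; same$upper <- 0.5
  expect_equal(unname(set_valued_weights(same)), rep(1 / 3, 3))

  # 5-expert fixture vs direct midpoint-average arithmetic
  set.seed(31)
  fx <- expand.grid(expert = 1:5, factor = c("F1", "F2", "F3"))
  fx$lower <- round(runif(nrow(fx), 0, 0.5), 3)
  fx$upper <- fx$lower + round(runif(nrow(fx), 0, 0.4), 3)
  mids <- tapply((fx$lower + fx$upper) / 2, fx$factor, mean)
  expect_equal(set_valued_weights(fx, n_iterations = 3),
               mids / sum(mids), tolerance = 1e-12, ignore_attr = TRUE)

  # memoryless resampling is reproducible under a seed
  w1 <- set_valued_weights(fx, resample = TRUE, seed = 9)
  w2 <- set_valued_weights(fx, resample = TRUE, seed = 9)
  expect_identical(w1, w2)
  expect_equal(sum(w1), 1, tolerance = 1e-12)

  expect_error(set_valued_weights(fx[0, ]), "empty")
  bad <- one; bad$upper[1] <- 1.2
  expect_error(set_valued_weights(bad), "<= 1")
})

test_that("composition matches the loop oracle for both operators", {
  set.seed(77)
  for (rep in 1:100) {
    R <- matrix(runif(12), 3, 4)
    R <- R / rowSums(R)
    W <- runif(3); W <- W / sum(W)
    for (op in c("weighted_average", "max_min"))
      expect_equal(unname(compose(W, R, op)), oracle_compose(W, R, op),
                   tolerance = 1e-12)
  }
})

test_that("composition reduces correctly for uniform and selector weights", {
  set.seed(3)
  R <- matrix(runif(12), 3, 4); R <- R / rowSums(R)
  expect_equal(unname(compose(rep(1 / 3, 3), R)),
               colMeans(R) / sum(colMeans(R)), tolerance = 1e-12)
  expect_equal(unname(compose(c(1, 0, 0), R)), R[1, ] / sum(R[1, ]),
               tolerance = 1e-12)
  # one-hot weights make the two operators agree
  for (i in 1:3)
    expect_equal(compose(diag(3)[i, ], R, "weighted_average"),
                 compose(diag(3)[i, ], R, "max_min"), tolerance = 1e-12)
  expect_error(compose(c(0.5, 0.5), R), "does not match")
})

test_that("two-level structure defaults to four groups of three", {
  s <- two_level_structure()
  expect_identical(names(s$groups), c("G1", "G2", "G3", "G4"))
  expect_identical(s$groups$G1, c("F1", "F5", "F9"))
  expect_identical(s$groups$G2, c("F3", "F6", "F7"))
  expect_identical(s$groups$G3, c("F2", "F4", "F8"))
  expect_identical(s$groups$G4, c("F10", "F11", "F12"))
  expect_error(two_level_structure(list(G1 = c("F1", "F2"))), "partition")
})

test_that("two-level evaluation hits the scale extremes and is monotone", {
  fm <- function(v) stats::setNames(rep(v, 9), paste0("F", 1:9))
  lo <- evaluate_two_level(fm(1), make_demographics())
  expect_identical(lo$grade, "healthy")
  expect_identical(lo$judgment_value, 1L)
  hi <- evaluate_two_level(fm(5), make_demographics("rural", "other", FALSE))
  expect_identical(hi$grade, "severe")
  expect_identical(hi$judgment_value, 2L)
  expect_equal(sum(hi$final_vector), 1, tolerance = 1e-9)
  expect_equal(rowSums(hi$group_vectors), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)

  # uniform severity shifts never move the grade toward lower severity
  dem <- make_demographics()
  grades <- vapply(seq(1, 5, by = 0.1), function(x)
    which(grade_set()$labels ==
          evaluate_two_level(fm(x), dem)$grade), integer(1))
  expect_true(all(diff(grades) >= 0))
})

test_that("the q-subset pre-filter keeps the highest-weighted groups", {
  fm <- stats::setNames(c(5, 1, 1, 1, 5, 1, 1, 1, 5), paste0("F", 1:9))
  dem <- make_demographics()
  # all weight effectively on G1 (the severe factors) when q = 1
  ev <- evaluate_two_level(fm, dem, level1_weights = c(0.7, 0.1, 0.1, 0.1),
                           q = 1)
  expect_identical(rownames(ev$group_vectors), "G1")
  expect_identical(ev$grade, "severe")
  full <- evaluate_two_level(fm, dem)
  expect_identical(nrow(full$group_vectors), 4L)
})

test_that("fuzzy judgment agrees with total-score screening at the extremes", {
  pop_lo <- gen_scl90(100, severity_mean = -3, severity_sd = 0.5, seed = 8)
  pop_hi <- gen_scl90(100, severity_mean = 3, severity_sd = 0.5, seed = 9)
  for (pop in list(pop_lo, pop_hi)) {
    sc <- score_table(pop)
    ev <- evaluate_table(sc)
    expect_identical(ev$judgment_value, sc$grade)
  }
})
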