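test_that("the unipolar sigmoid has the logistic identities", {
  expect_identical(activate(0), 0.5)
  expect_equal(activate(2), 0.8807970779778823, tolerance = 1e-15)
  x <- seq(-6, 6, by = 0.5)
  expect_equal(activate(x) + activate(-x), rep(1, length(x)),
               tolerance = 1e-12)
  expect_true(all(diff(activate(x)) > 0))
})

test_that("the forward pass matches hand and loop oracles", {
  cfg <- bp_config(n_input = 2, n_hidden = 2, n_output = 1, init_range = 0)
  st <- bp_init(cfg)
  # all-zero weights: every unit outputs f(0) = 0.5 regardless of input
  expect_equal(bp_forward(st, c(0.3, 0.9))$O, 0.5)

  # single-path hand calculation: one input, one hidden, unit weights
  st$v <- matrix(c(0, 1), 2, 1)    # bias 0, weight 1
  st$w <- matrix(c(0, 1), 2, 1)
  st$config$n_input <- 1L
  y <- 1 / (1 + exp(-0.7))
  expect_equal(bp_forward(st, 0.7)$O, 1 / (1 + exp(-y)), tolerance = 1e-15)

  set.seed(12)
  for (rep in 1:10) {
    cfg <- bp_config(n_input = 4, n_hidden = 3, n_output = 2, seed = rep)
    st <- bp_init(cfg)
    x <- runif(4)
    got <- bp_forward(st, x)
    want <- oracle_forward(st$v, st$w, x)
    expect_equal(got$y, want$y, tolerance = 1e-12)
    expect_equal(got$O, want$O, tolerance = 1e-12)
  }
  expect_error(bp_forward(st, runif(7)), "expected 4")
})

test_that("the squared-error loss behaves as defined", {
  expect_identical(bp_sse(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bp_sse(1, 0.5), 0.125)
  set.seed(2)
  d <- runif(5); O <- runif(5)
  acc <- 0
  for (k in 1:5) acc <- acc + (d[k] - O[k])^2
  expect_equal(bp_sse(d, O), acc / 2, tolerance = 1e-15)
  expect_error(bp_sse(1:2, 1:3), "differ in length")
})

test_that("analytic gradients match central finite differences", {
  set.seed(99)
  for (rep in 1:15) {
    cfg <- bp_config(n_input = sample(2:5, 1), n_hidden = sample(2:4, 1),
                     n_output = sample(1:2, 1), seed = rep)
    st <- bp_init(cfg)
    x <- runif(cfg$n_input)
    d <- runif(cfg$n_output)
    g <- bp_gradients(st, x, d)
    fd <- oracle_fd_gradients(st, x, d)
    denom <- max(abs(unlist(fd)), 1e-8)
    expect_lt(max(abs(g$gv - fd$gv), abs(g$gw - fd$gw)) / denom, 1e-6)
  }
})

test_that("a backprop step is a zero-learning-rate fixed point and descends", {
  cfg <- bp_config(n_input = 2, n_hidden = 3, seed = 4)
  st <- bp_init(cfg)
  x <- c(0.2, 0.9); d <- 1
  st0 <- bp_backprop_step(st, x, d, eta = 0)
  expect_identical(st0$v, st$v)
  expect_identical(st0$w, st$w)
  # small-step descent on a 2-sample toy set
  X <- rbind(c(0, 0), c(1, 1)); D <- c(0, 1)
  E <- function(s) bp_sse(D[1], bp_forward(s, X[1, ])$O) +
                   bp_sse(D[2], bp_forward(s, X[2, ])$O)
  before <- E(st)
  for (i in 1:2) st <- bp_backprop_step(st, X[i, ], D[i], eta = 0.05)
  expect_lt(E(st), before)
})

test_that("the adaptive learning-rate schedule follows its three branches", {
  expect_equal(adapt_learning_rate(0.1, 1.0, 0.9), 0.105)
  expect_equal(adapt_learning_rate(0.1, 1.0, 1.05), 0.07)
  expect_equal(adapt_learning_rate(0.1, 1.0, 1.02), 0.1)
  # boundary: growth exactly 4% holds the rate
  expect_equal(adapt_learning_rate(0.2, 1.0, 1.04), 0.2)
  # clamping
  expect_equal(adapt_learning_rate(0.94, 1.0, 0.5), 0.95)
  expect_equal(adapt_learning_rate(1.2e-5, 1.0, 2.0), 1e-5)
})

test_that("training is deterministic, traces valid rate ratios, and stops at fixed points", {
  # zero-init weights always output 0.5: targets of 0.5 give E = 0 at once
  X <- matrix(runif(10), 5, 2)
  D <- matrix(0.5, 5, 1)
  fit <- bp_train(bp_config(n_input = 2, init_range = 0, max_epochs = 100),
                  X, D)
  expect_identical(fit$state$epoch, 1L)
  expect_identical(fit$trace$E, 0)

  set.seed(1)
  X <- matrix(runif(40), 20, 2)
  D <- matrix(as.numeric(rowSums(X) > 1), 20, 1)
  cfg <- bp_config(n_input = 2, n_hidden = 3, max_epochs = 60, seed = 17,
                   target_error = 0)
  f1 <- bp_train(cfg, X, D)
  f2 <- bp_train(cfg, X, D)
  expect_identical(f1$trace, f2$trace)          # bit-identical under one seed
  expect_identical(f1$state$v, f2$state$v)

  ratio <- f1$trace$eta[-1] / head(f1$trace$eta, -1)
  clamped <- f1$trace$eta[-1] %in% c(cfg$eta_min, cfg$eta_max)
  ok <- vapply(seq_along(ratio), function(i)
    clamped[i] || min(abs(ratio[i] - c(1.05, 0.7, 1))) < 1e-12, logical(1))
  expect_true(all(ok))
})

test_that("the network learns XOR with four hidden units", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  D <- matrix(c(0, 1, 1, 0), ncol = 1)
  fit <- bp_train(bp_config(n_input = 2, n_hidden = 4, eta0 = 0.5,
                            target_error = 0.01, max_epochs = 20000,
                            seed = 1), X, D)
  expect_lte(tail(fit$trace$E, 1), 0.01)
  preds <- apply(X, 1, function(x) bp_forward(fit$state, x)$O)
  expect_identical(as.integer(preds > 0.5), c(0L, 1L, 1L, 0L))
})

test_that("the adaptive schedule converges no slower than a fixed rate on XOR", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  D <- matrix(c(0, 1, 1, 0), ncol = 1)
  ep_adapt <- ep_fixed <- integer(20)
  for (s in 1:20) {
    fa <- bp_train(bp_config(n_input = 2, n_hidden = 4, eta0 = 0.5,
                             target_error = 0.05, max_epochs = 5000,
                             seed = s), X, D)
    # clamping both bounds to eta0 freezes the schedule
    ff <- bp_train(bp_config(n_input = 2, n_hidden = 4, eta0 = 0.5,
                             target_error = 0.05, max_epochs = 5000,
                             seed = s, eta_min = 0.5, eta_max = 0.5), X, D)
    ep_adapt[s] <- fa$state$epoch
    ep_fixed[s] <- ff$state$epoch
  }
  expect_lte(median(ep_adapt), 1.1 * median(ep_fixed))
})

test_that("the screening judgment is learnable from the 12-factor inputs", {
  pop <- gen_scl90(400, severity_mean = 0.4, severity_sd = 1.2, seed = 11)
  sc <- score_table(pop)
  X <- bp_features(sc)
  expect_identical(ncol(X), 12L)
  expect_true(all(X >= 0 & X <= 1))
  D <- matrix(as.numeric(sc$grade == 2L), ncol = 1)
  train <- 1:300; test <- 301:400
  fit <- bp_train(bp_config(n_hidden = 8, eta0 = 0.4, target_error = 0.5,
                            max_epochs = 400, seed = 3),
                  X[train, ], D[train, , drop = FALSE])
  pred <- vapply(test, function(i) bp_predict(fit$state, X[i, ]), integer(1))
  expect_gte(mean(pred == sc$grade[test]), 0.9)
})

test_that("prediction thresholds the output with a negative-screen tie-break", {
  cfg <- bp_config(n_input = 1, n_hidden = 1, init_range = 0)
  st <- bp_init(cfg)
  # zero weights give O = 0.5 exactly: the tie goes to judgment 1
  expect_identical(bp_predict(st, 0.3), 1L)
  st$w <- matrix(c(5, 0), 2, 1)    # large positive bias: O near 1
  expect_identical(bp_predict(st, 0.3), 2L)
  st$w <- matrix(c(-5, 0), 2, 1)
  expect_identical(bp_predict(st, 0.3), 1L)
})

test_that("a trained network round-trips through JSON", {
  X <- rbind(c(0, 0), c(1, 1)); D <- matrix(c(0, 1), 2, 1)
  fit <- bp_train(bp_config(n_input = 2, n_hidden = 2, max_epochs = 5,
                            seed = 6, target_error = 0), X, D)
  path <- tempfile(fileext = ".json")
  bp_save(fit$state, path)
  back <- bp_load(path)
  expect_equal(back$v, fit$state$v, tolerance = 1e-12)
  expect_equal(back$w, fit$state$w, tolerance = 1e-12)
  expect_equal(back$eta, fit$state$eta)
  expect_equal(bp_forward(back, c(0.2, 0.7))$O,
               bp_forward(fit$state, c(0.2, 0.7))$O, tolerance = 1e-12)
})
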