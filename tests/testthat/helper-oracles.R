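# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementations they check.

# per-factor mean by explicit double loop
oracle_factor_means <- function(items, mapping) {
  out <- numeric(0)
  for (f in names(mapping$factor_items)) {
    idx <- mapping$factor_items[[f]]
    s <- 0
    for (i in idx) s <- s + items[i]
    out[f] <- s / length(idx)
  }
  out
}

# fuzzy composition by element-wise loops
oracle_compose <- function(W, R, operator) {
  B <- numeric(ncol(R))
  for (j in seq_len(ncol(R))) {
    if (operator == "weighted_average") {
      acc <- 0
      for (i in seq_len(nrow(R))) acc <- acc + W[i] * R[i, j]
      B[j] <- acc
    } else {
      acc <- -Inf
      for (i in seq_len(nrow(R))) acc <- max(acc, min(W[i], R[i, j]))
      B[j] <- acc
    }
  }
  B / sum(B)
}

# forward pass by explicit triple loop
oracle_forward <- function(v, w, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  nh <- ncol(v); no <- ncol(w)
  xb <- c(1, x)
  y <- numeric(nh)
  for (j in seq_len(nh)) {
    net <- 0
    for (i in seq_along(xb)) net <- net + v[i, j] * xb[i]
    y[j] <- sig(net)
  }
  yb <- c(1, y)
  O <- numeric(no)
  for (k in seq_len(no)) {
    net <- 0
    for (j in seq_along(yb)) net <- net + w[j, k] * yb[j]
    O[k] <- sig(net)
  }
  list(y = y, O = O)
}

# central finite-difference gradient of bp_sse(bp_forward(.)) w.r.t. both
# weight matrices
oracle_fd_gradients <- function(state, x, d, h = 1e-4) {
  loss <- function(st) bp_sse(d, bp_forward(st, x)$O)
  fd_mat <- function(name) {
    G <- state[[name]] * 0
    for (j in seq_along(G)) {
      sp <- state; sp[[name]][j] <- sp[[name]][j] + h
      sm <- state; sm[[name]][j] <- sm[[name]][j] - h
      G[j] <- (loss(sp) - loss(sm)) / (2 * h)
    }
    G
  }
  list(gv = fd_mat("v"), gw = fd_mat("w"))
}

# random valid questionnaire item vector
random_items <- function() sample(1:5, 90, replace = TRUE)

make_demographics <- function(hukou = "urban",
                              family_composition = "both_parents",
                              only_child = TRUE) {
  list(hukou = hukou, family_composition = family_composition,
       only_child = only_child)
}
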