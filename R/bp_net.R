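# Single-hidden-layer backpropagation network, written from first
# principles: unipolar logistic activation, squared-error loss
# E = 1/2 * sum (d_k - O_k)^2, delta-rule weight updates, and an
# error-feedback adaptive learning-rate schedule (grow by 1.05 when the
# epoch error falls, shrink by 0.7 when it rises by more than 4%, hold
# otherwise).  Bias terms are fixed unit inputs at index 0 of each layer.

#' Unipolar sigmoid activation
#'
#' The logistic function `1 / (1 + exp(-x))`, strictly increasing with
#' `activate(0) = 0.5`, saturating at 0 and 1.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
activate <- function(x) 1 / (1 + exp(-x))

#' Network configuration
#'
#' @param n_input Number of input units (default 12: nine SCL-90 factor
#'   means plus three demographic scores, all scaled to \[0, 1\]).
#' @param n_hidden Hidden-layer size; default 8.
#' @param n_output Output units: 1 for the binary screening judgment
#'   (default), or the number of grades for one-hot output.
#' @param init_range Half-width of the symmetric uniform weight
#'   initialisation.
#' @param eta0 Initial learning rate, in (0, 1).
#' @param target_error Expected error: training stops once the epoch error
#'   sum of squares falls to this level.
#' @param max_epochs Hard epoch cap.
#' @param eta_min,eta_max Clamp on the adaptive learning rate, guarding
#'   against runaway growth under repeated 1.05 steps.
#' @param mode `"online"` (per-sample updates, default) or `"batch"`.
#' @param seed Integer seed controlling initialisation and sample order.
#' @return Object of class `bp_config`.
#' @export
bp_config <- function(n_input = 12L, n_hidden = 8L, n_output = 1L,
                      init_range = 0.5, eta0 = 0.5, target_error = 0.01,
                      max_epochs = 1000L, eta_min = 1e-5, eta_max = 0.95,
                      mode = c("online", "batch"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_input >= 1L, n_hidden >= 1L, n_output >= 1L,
            eta0 > 0, eta0 < 1, init_range >= 0, target_error >= 0,
            max_epochs >= 1L, eta_min > 0, eta_min <= eta_max)
  structure(list(n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output),
                 init_range = init_range, eta0 = eta0,
                 target_error = target_error,
                 max_epochs = as.integer(max_epochs),
                 eta_min = eta_min, eta_max = eta_max,
                 mode = mode, seed = as.integer(seed)),
            class = "bp_config")
}

#' Initialise network weights
#'
#' Draws both weight layers uniformly from
#' `[-init_range, init_range]` under the configured seed. Row 1 of each
#' matrix holds the bias weights (fixed unit input).
#'
#' @param config A [bp_config()].
#' @return Object of class `bp_state`: list with `v` (input-to-hidden,
#'   `(n_input + 1) x n_hidden`), `w` (hidden-to-output,
#'   `(n_hidden + 1) x n_output`), current `eta`, `epoch`, and `config`.
#' @export
bp_init <- function(config) {
  set.seed(config$seed)
  r <- config$init_range
  v <- matrix(stats::runif((config$n_input + 1L) * config$n_hidden, -r, r),
              config$n_input + 1L, config$n_hidden)
  w <- matrix(stats::runif((config$n_hidden + 1L) * config$n_output, -r, r),
              config$n_hidden + 1L, config$n_output)
  structure(list(v = v, w = w, eta = config$eta0, epoch = 0L,
                 config = config),
            class = "bp_state")
}

#' Forward pass
#'
#' Hidden outputs `y_j = f(sum_i v_ij x_i)` and network outputs
#' `O_k = f(sum_j w_jk y_j)`, with `x_0 = y_0 = 1` the bias units and `f`
#' the unipolar sigmoid.
#'
#' @param state A `bp_state`.
#' @param x Input vector of length `n_input`.
#' @return List with `y` (hidden activations) and `O` (outputs).
#' @export
bp_forward <- function(state, x) {
  if (length(x) != state$config$n_input)
    stop("input has length ", length(x), "; expected ", state$config$n_input)
  y <- activate(drop(crossprod(state$v, c(1, x))))
  O <- activate(drop(crossprod(state$w, c(1, y))))
  list(y = y, O = O)
}

#' Error sum of squares
#'
#' `E = 1/2 * sum_k (d_k - O_k)^2`.
#'
#' @param d Target vector.
#' @param O Output vector of the same length.
#' @return Nonnegative scalar, zero iff `d == O`.
#' @export
bp_sse <- function(d, O) {
  if (length(d) != length(O)) stop("targets and outputs differ in length")
  0.5 * sum((d - O)^2)
}

#' Analytic error gradients
#'
#' Gradients of [bp_sse()] of the forward pass with respect to both weight
#' matrices, by backpropagation of the output error with the logistic
#' derivative `f'(net) = f(net) (1 - f(net))`.
#'
#' @param state A `bp_state`.
#' @param x Input vector.
#' @param d Target vector.
#' @return List with `gv` and `gw`, matching `state$v` and `state$w` in
#'   shape, and the forward-pass `E`.
#' @export
bp_gradients <- function(state, x, d) {
  fw <- bp_forward(state, x)
  delta_o <- (d - fw$O) * fw$O * (1 - fw$O)          # -dE/dnet_k
  delta_h <- fw$y * (1 - fw$y) *
    drop(state$w[-1L, , drop = FALSE] %*% delta_o)   # -dE/dnet_j
  list(gw = -outer(c(1, fw$y), delta_o),
       gv = -outer(c(1, x), delta_h),
       E = bp_sse(d, fw$O))
}

#' One backpropagation step
#'
#' Updates both layers by the delta rule,
#' `delta_w = -eta * dE/dw`, for a single training sample.
#'
#' @param state A `bp_state`.
#' @param x Input vector.
#' @param d Target vector.
#' @param eta Learning rate; defaults to the state's current rate.
#' @return Updated `bp_state`.
#' @export
bp_backprop_step <- function(state, x, d, eta = state$eta) {
  g <- bp_gradients(state, x, d)
  state$v <- state$v - eta * g$gv
  state$w <- state$w - eta * g$gw
  state
}

#' Error-feedback adaptive learning rate
#'
#' The schedule grows the rate by factor 1.05 when the epoch error
#' decreased, shrinks it by factor 0.7 when the error grew by more than 4%,
#' and holds it otherwise; the result is clamped to
#' `[eta_min, eta_max]`.
#'
#' @param eta Current learning rate (> 0).
#' @param E_prev,E_curr Previous and current epoch error sums of squares.
#' @param eta_min,eta_max Clamp bounds.
#' @return Updated learning rate.
#' @examples
#' adapt_learning_rate(0.1, 1.0, 0.9)   # 0.105
#' adapt_learning_rate(0.1, 1.0, 1.05)  # 0.07
#' adapt_learning_rate(0.1, 1.0, 1.02)  # 0.1
#' @export
adapt_learning_rate <- function(eta, E_prev, E_curr,
                                eta_min = 1e-5, eta_max = 0.95) {
  stopifnot(eta > 0, E_prev >= 0, E_curr >= 0)
  fac <- if (E_curr < E_prev) 1.05
         else if (E_curr > 1.04 * E_prev) 0.7
         else 1
  min(max(eta * fac, eta_min), eta_max)
}

#' Train the network
#'
#' Epoch loop over the training set. In online mode each sample (in an
#' order permuted once per epoch, reproducibly from the configured seed)
#' contributes its error to the epoch total and immediately updates the
#' weights; in batch mode gradients are accumulated and applied once per
#' epoch. After each epoch the learning rate is adapted from the change in
#' epoch error. Training stops when the epoch error reaches
#' `target_error` or after `max_epochs`.
#'
#' @param config A [bp_config()].
#' @param X Input matrix, one row per sample, `n_input` columns, values
#'   scaled to \[0, 1\].
#' @param D Target matrix (or vector for a single output), one row per
#'   sample, values in \[0, 1\].
#' @return List with the trained `state` and `trace`, a data frame with one
#'   row per epoch: `epoch`, `E` (epoch error sum of squares), `eta` (rate
#'   used during that epoch).
#' @export
bp_train <- function(config, X, D) {
  X <- as.matrix(X)
  D <- as.matrix(D)
  if (nrow(X) == 0L) stop("empty training set")
  if (nrow(D) != nrow(X)) stop("X and D must have the same number of rows")
  state <- bp_init(config)            # also seeds the sample-order RNG
  n <- nrow(X)
  E_hist <- eta_hist <- numeric(0)
  E_prev <- NA_real_
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    E <- 0
    if (config$mode == "online") {
      for (i in ord) {
        g <- bp_gradients(state, X[i, ], D[i, ])
        E <- E + g$E
        state$v <- state$v - state$eta * g$gv
        state$w <- state$w - state$eta * g$gw
      }
    } else {
      gv <- 0 * state$v; gw <- 0 * state$w
      for (i in ord) {
        g <- bp_gradients(state, X[i, ], D[i, ])
        E <- E + g$E
        gv <- gv + g$gv; gw <- gw + g$gw
      }
      state$v <- state$v - state$eta * gv
      state$w <- state$w - state$eta * gw
    }
    if (!is.finite(E))
      stop("training diverged: non-finite epoch error at epoch ", epoch,
           " (eta = ", state$eta, ")")
    E_hist <- c(E_hist, E)
    eta_hist <- c(eta_hist, state$eta)
    state$epoch <- epoch
    if (E <= config$target_error) break
    if (!is.na(E_prev))
      state$eta <- adapt_learning_rate(state$eta, E_prev, E,
                                       config$eta_min, config$eta_max)
    E_prev <- E
  }
  list(state = state,
       trace = data.frame(epoch = seq_along(E_hist), E = E_hist,
                          eta = eta_hist))
}

#' Predict the screening judgment for one input
#'
#' Binary output: judgment 2 (positive screen) when the single output
#' exceeds 0.5, judgment 1 otherwise; an output of exactly 0.5 ties toward
#' the negative screen. Multi-output (one-hot) networks take the
#' maximum-output grade and collapse it (grade 1 to judgment 1, higher
#' grades to judgment 2).
#'
#' @param state A trained `bp_state`.
#' @param x Input vector.
#' @return Integer judgment value, 1 or 2.
#' @export
bp_predict <- function(state, x) {
  O <- bp_forward(state, x)$O
  if (length(O) == 1L) {
    if (O > 0.5) 2L else 1L
  } else {
    if (which.max(O) == 1L) 1L else 2L
  }
}

#' Build the 12-column feature matrix for the network
#'
#' Maps a scored respondent table to network inputs: the nine factor means
#' rescaled from \[1, 5\] to \[0, 1\], followed by the three demographics
#' encoded as ordered risk scores in \[0, 1\] (urban 0 / rural 1;
#' both-parents 0 / single-parent 0.5 / other 1; only-child 0 / not 1).
#'
#' @param scored Data frame from [score_table()] carrying `F1`..`F9`,
#'   `hukou`, `family_composition`, `only_child`.
#' @return Numeric matrix with 12 columns, values in \[0, 1\].
#' @export
bp_features <- function(scored) {
  fm <- as.matrix(scored[paste0("F", 1:9)])
  hk <- c(urban = 0, rural = 1)[as.character(scored$hukou)]
  fc <- c(both_parents = 0, single_parent = 0.5,
          other = 1)[as.character(scored$family_composition)]
  oc <- ifelse(as.logical(scored$only_child), 0, 1)
  if (anyNA(c(hk, fc, oc))) stop("unrecognised demographic category")
  X <- cbind((fm - 1) / 4, hukou = hk, family_composition = fc,
             only_child = oc)
  rownames(X) <- NULL
  X
}

#' Serialize / restore a trained network
#'
#' Weights and configuration round-trip through a JSON document.
#'
#' @param state A `bp_state`.
#' @param path Output file path.
#' @return `bp_save` invisibly returns `path`; `bp_load` returns the
#'   restored `bp_state`.
#' @export
bp_save <- function(state, path) {
  doc <- list(config = unclass(state$config),
              v = state$v, w = state$w,
              eta = state$eta, epoch = state$epoch)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname bp_save
#' @export
bp_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(bp_config, doc$config[setdiff(names(doc$config), NULL)])
  structure(list(v = as.matrix(doc$v), w = as.matrix(doc$w),
                 eta = doc$eta, epoch = as.integer(doc$epoch),
                 config = cfg),
            class = "bp_state")
}
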