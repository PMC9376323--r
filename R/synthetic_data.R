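# Synthetic respondent populations.  A latent-distress item-response model
# stands in for a real SCL-90 cohort: each respondent draws a latent
# severity, each item a propensity base + loading * severity + noise,
# discretised to the 1..5 response scale by fixed thresholds chosen so that
# a zero-distress respondent answers mostly 1-2 (SCL-90 populations are
# floor-heavy).  Scale triples with a prescribed partial-mediation path
# structure and expert importance intervals are generated alongside.

#' Generate a synthetic SCL-90 respondent population
#'
#' Per respondent, latent distress `z ~ N(severity_mean, severity_sd^2)`;
#' per item, propensity `base + loading[factor(item)] * z + noise`, cut at
#' the fixed thresholds 0.5, 1.5, 2.5, 3.5 into responses 1..5.
#' Demographics are drawn independently of severity from
#' `demographic_probs`. Fully reproducible from `seed`.
#'
#' @param n Number of respondents.
#' @param severity_mean,severity_sd Latent distress distribution; defaults
#'   0 and 1.
#' @param factor_loadings Named vector of per-factor-set sensitivities to
#'   distress (names as in [scl90_mapping()], including `OTHER`); default 1
#'   for every set.
#' @param demographic_probs Named list of category probability vectors for
#'   `hukou`, `family_composition`, `only_child`.
#' @param base Propensity intercept; default 0 (modal response 1 at zero
#'   distress).
#' @param noise_sd Item-level noise standard deviation, default 1.
#' @param floor_all If `TRUE`, short-circuits to the scale floor (all items
#'   1) — the limit of infinitely negative severity.
#' @param mapping Factor mapping used to assign loadings to items.
#' @param seed Integer seed.
#' @return Data frame: `id`, `item_1`..`item_90`, `hukou`,
#'   `family_composition`, `only_child`.
#' @export
gen_scl90 <- function(n, severity_mean = 0, severity_sd = 1,
                      factor_loadings = NULL,
                      demographic_probs = list(
                        hukou = c(urban = 0.4, rural = 0.6),
                        family_composition = c(both_parents = 0.7,
                                               single_parent = 0.2,
                                               other = 0.1),
                        only_child = c(`TRUE` = 0.4, `FALSE` = 0.6)),
                      base = 0, noise_sd = 1, floor_all = FALSE,
                      mapping = scl90_mapping(), seed = 1L) {
  stopifnot(n >= 1L, severity_sd >= 0, noise_sd >= 0)
  for (d in names(demographic_probs)) {
    pr <- demographic_probs[[d]]
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("probabilities for ", d, " must be nonnegative and sum to 1")
  }
  set.seed(seed)
  sets <- names(mapping$factor_items)
  if (is.null(factor_loadings))
    factor_loadings <- stats::setNames(rep(1, length(sets)), sets)
  # per-item loading from the item's factor set (verbatim dialect can assign
  # an item twice; the first listed set wins)
  item_loading <- numeric(90)
  for (f in rev(sets))
    item_loading[mapping$factor_items[[f]]] <- factor_loadings[[f]]
  if (floor_all) {
    items <- matrix(1L, n, 90)
  } else {
    z <- stats::rnorm(n, severity_mean, severity_sd)
    prop <- outer(z, item_loading) + base +
      matrix(stats::rnorm(n * 90, 0, noise_sd), n, 90)
    items <- matrix(1L + findInterval(prop, c(0.5, 1.5, 2.5, 3.5)), n, 90)
  }
  colnames(items) <- paste0("item_", 1:90)
  draw <- function(pr) names(pr)[sample.int(length(pr), n, replace = TRUE,
                                            prob = pr)]
  data.frame(id = sprintf("S%04d", seq_len(n)), items,
             hukou = draw(demographic_probs$hukou),
             family_composition = draw(demographic_probs$family_composition),
             only_child = as.logical(draw(demographic_probs$only_child)),
             stringsAsFactors = FALSE)
}

#' Deterministic record with a prescribed total score
#'
#' Builds a 90-item response vector summing to `total` (responses 1..5):
#' useful for engineering respondents whose totals match published
#' screening tables.
#'
#' @param total Target total score in 90..450.
#' @return Integer vector of 90 responses summing to `total`.
#' @export
make_total_items <- function(total) {
  stopifnot(total >= 90, total <= 450, total == as.integer(total))
  excess <- total - 90L
  items <- rep(1L, 90L)
  full <- excess %/% 4L
  if (full > 0L) items[seq_len(full)] <- 5L
  rem <- excess %% 4L
  if (rem > 0L) items[full + 1L] <- 1L + rem
  items
}

#' Generate scale triples with a mediation path structure
#'
#' `x ~ N(0,1)`, `m = a x + e1`, `y = b m + c' x + e2`, with independent
#' normal residuals of standard deviation `noise_sd`. Emulates a
#' mindfulness (x) - rumination (m) - well-being (y) pathway with a
#' controllable partial-mediation structure.
#'
#' @param n Sample size.
#' @param path_a,path_b,path_c_prime Path coefficients.
#' @param noise_sd Residual standard deviation (> 0), default 1.
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `m`, `y`.
#' @export
gen_mediation <- function(n, path_a, path_b, path_c_prime,
                          noise_sd = 1, seed = 1L) {
  stopifnot(n >= 1L, noise_sd > 0)
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- path_a * x + stats::rnorm(n, 0, noise_sd)
  y <- path_b * m + path_c_prime * x + stats::rnorm(n, 0, noise_sd)
  data.frame(x = x, m = m, y = y)
}

#' Generate expert importance intervals
#'
#' Per expert and factor, an interval `[center - half_width,
#' center + half_width]` with the center drawn around a factor-importance
#' anchor; dispersion across experts shrinks as `concentration` grows
#' (`concentration = Inf` makes all experts identical). Intervals are kept
#' inside \[0, 1\].
#'
#' @param n_experts,n_factors Counts.
#' @param concentration Inverse dispersion of expert centers (> 0 or
#'   `Inf`); default 10.
#' @param anchors Optional numeric vector of factor-importance anchors in
#'   (0, 1); default uniform (all equal).
#' @param half_width Interval half-width, default 0.05.
#' @param seed Integer seed.
#' @return Data frame: `expert`, `factor`, `lower`, `upper` — the input
#'   format of [set_valued_weights()].
#' @export
gen_expert_intervals <- function(n_experts, n_factors, concentration = 10,
                                 anchors = NULL, half_width = 0.05,
                                 seed = 1L) {
  stopifnot(n_experts >= 1L, n_factors >= 1L, concentration > 0,
            half_width >= 0, half_width < 0.5)
  set.seed(seed)
  if (is.null(anchors)) anchors <- rep(0.5, n_factors)
  stopifnot(length(anchors) == n_factors, all(anchors > 0 & anchors < 1))
  sd <- if (is.infinite(concentration)) 0 else 0.5 / concentration
  grid <- expand.grid(expert = seq_len(n_experts),
                      factor = paste0("F", seq_len(n_factors)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  center <- anchors[match(grid$factor, paste0("F", seq_len(n_factors)))] +
    stats::rnorm(nrow(grid), 0, sd)
  center <- pmin(pmax(center, half_width), 1 - half_width)
  data.frame(grid, lower = center - half_width, upper = center + half_width)
}
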