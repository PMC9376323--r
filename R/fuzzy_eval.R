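# Two-level fuzzy comprehensive evaluation of well-being status.
#
# Twelve factors feed the model: the nine SCL-90 factor means plus three
# categorical demographics (household registration type, family composition,
# only-child status).  Scalar factors obtain grade memberships from a
# piecewise-linear family with breakpoints 1.6, 2.0 and 2.7 on the
# factor-mean scale; categoricals from configurable risk tables.  Group
# membership matrices are composed with weight vectors (weighted-average by
# default, max-min optionally), and the final grade is the maximum-membership
# grade with a lowest-severity tie-break.

#' Define the evaluation grade set
#'
#' Four ordered severity grades are used by default (healthy, mild,
#' moderate, severe) with membership breakpoints 1.6, 2.0 and 2.7 on the
#' factor-mean scale. The breakpoints are the apexes of the piecewise-linear
#' membership functions of grades 2..k; grade 1 has its apex at the scale
#' floor and a left shoulder, grade k a right shoulder beyond its apex.
#'
#' @param labels Ordered grade names, lowest severity first.
#' @param breakpoints Strictly increasing apex positions; must satisfy
#'   `length(labels) == length(breakpoints) + 1`.
#' @param scale_range Range of admissible scalar inputs, default `c(1, 5)`.
#' @return An object of class `grade_set`.
#' @export
grade_set <- function(labels = c("healthy", "mild", "moderate", "severe"),
                      breakpoints = c(1.6, 2.0, 2.7),
                      scale_range = c(1, 5)) {
  stopifnot(length(labels) == length(breakpoints) + 1L,
            all(diff(breakpoints) > 0),
            length(scale_range) == 2L, scale_range[1] < scale_range[2],
            breakpoints[1] > scale_range[1],
            breakpoints[length(breakpoints)] < scale_range[2])
  structure(list(labels = labels, breakpoints = breakpoints,
                 scale_range = scale_range,
                 apexes = c(scale_range[1], breakpoints)),
            class = "grade_set")
}

#' Grade membership of a scalar factor value
#'
#' Piecewise-linear membership over the grades: triangular at interior
#' grades, shoulder-shaped at the two extremes, with apexes at the scale
#' floor and at each breakpoint. At most two adjacent grades receive nonzero
#' membership, and the vector sums to exactly 1.
#'
#' @param x Scalar factor value within the grade set's scale range.
#' @param grades A [grade_set()].
#' @return Numeric membership vector, one value per grade, summing to 1.
#' @examples
#' membership_scalar(1.8, grade_set())  # split 0.5/0.5 between mild/moderate
#' @export
membership_scalar <- function(x, grades = grade_set()) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  if (x < grades$scale_range[1] || x > grades$scale_range[2])
    stop("factor value ", x, " outside the scale range [",
         grades$scale_range[1], ", ", grades$scale_range[2], "]")
  a <- grades$apexes
  k <- length(grades$labels)
  mu <- numeric(k)
  names(mu) <- grades$labels
  if (x <= a[1]) { mu[1] <- 1; return(mu) }
  if (x >= a[k]) { mu[k] <- 1; return(mu) }
  i <- findInterval(x, a)          # a[i] <= x < a[i + 1]
  t <- (x - a[i]) / (a[i + 1] - a[i])
  mu[i] <- 1 - t
  mu[i + 1] <- t
  mu
}

#' Grade membership of a categorical factor
#'
#' Looks the category up in a risk table (a named list mapping each category
#' to a membership distribution over the grades) and returns the normalized
#' distribution.
#'
#' @param value Category value (coerced to character; logicals become
#'   `"TRUE"`/`"FALSE"`).
#' @param risk_table Named list of nonnegative numeric vectors, one per
#'   category, each with one entry per grade.
#' @param grades A [grade_set()] used for validation and naming.
#' @return Numeric membership vector summing to 1.
#' @export
membership_categorical <- function(value, risk_table, grades = grade_set()) {
  key <- as.character(value)
  if (!key %in% names(risk_table))
    stop("unknown category ", sQuote(key), "; expected one of ",
         paste(sQuote(names(risk_table)), collapse = ", "))
  mu <- as.numeric(risk_table[[key]])
  if (length(mu) != length(grades$labels))
    stop("risk table entry for ", sQuote(key), " has ", length(mu),
         " values; expected ", length(grades$labels))
  if (any(mu < 0) || sum(mu) <= 0)
    stop("risk table entry for ", sQuote(key),
         " must be nonnegative with positive sum")
  mu <- mu / sum(mu)
  names(mu) <- grades$labels
  mu
}

#' Set-valued statistical weighting from expert intervals
#'
#' Aggregates expert-supplied numeric importance intervals into a normalized
#' weight vector. Each iteration is a memoryless statistical round: with
#' resampling enabled, a fresh bootstrap sample of experts is drawn each
#' round with no memory of earlier rounds; without resampling every expert
#' enters every round and the result is deterministic. A factor's weight is
#' proportional to the mean interval midpoint accumulated over rounds.
#'
#' @param intervals Data frame with columns `expert`, `factor`, `lower`,
#'   `upper`; bounds in \[0, 1\] with `lower <= upper`.
#' @param n_iterations Number of rounds, default 3.
#' @param resample Bootstrap experts each round? Default `FALSE`.
#' @param seed Optional integer seed used when `resample = TRUE`.
#' @return Named numeric weight vector summing to 1.
#' @examples
#' iv <- data.frame(expert = 1, factor = c("A", "B"),
#'                  lower = c(0.2, 0.6), upper = c(0.4, 0.8))
#' set_valued_weights(iv)  # c(A = 0.3, B = 0.7)
#' @export
set_valued_weights <- function(intervals, n_iterations = 3L,
                               resample = FALSE, seed = NULL) {
  req <- c("expert", "factor", "lower", "upper")
  if (!is.data.frame(intervals) || !all(req %in% names(intervals)))
    stop("intervals must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(intervals) == 0L) stop("empty interval set")
  with(intervals, {
    if (any(lower < 0 | upper > 1 | lower > upper))
      stop("intervals must satisfy 0 <= lower <= upper <= 1")
  })
  stopifnot(n_iterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  experts <- unique(intervals$expert)
  factors <- unique(intervals$factor)
  mid <- (intervals$lower + intervals$upper) / 2
  acc <- matrix(0, nrow = n_iterations, ncol = length(factors),
                dimnames = list(NULL, factors))
  for (it in seq_len(n_iterations)) {
    chosen <- if (resample)
      sample(experts, length(experts), replace = TRUE) else experts
    for (f in factors) {
      rows <- which(intervals$expert %in% chosen & intervals$factor == f)
      if (!length(rows)) stop("no interval for factor ", sQuote(f),
                              " among selected experts")
      if (resample) {
        # bootstrap multiplicity: each expert's midpoint counts once per draw
        cnt <- vapply(intervals$expert[rows],
                      function(e) sum(chosen == e), numeric(1))
        acc[it, f] <- sum(mid[rows] * cnt) / sum(cnt)
      } else {
        acc[it, f] <- mean(mid[rows])
      }
    }
  }
  w <- colMeans(acc)
  if (all(w == 0)) stop("degenerate all-zero weights")
  w / sum(w)
}

#' Two-level factor grouping
#'
#' The twelve factors are organised into four groups of three: G1 (bodily
#' symptoms: somatization F1, anxiety F5, psychoticism F9), G2 (outward
#' interaction: interpersonal sensitivity F3, hostility F6, phobic anxiety
#' F7), G3 (inner character and mood: obsessive-compulsive F2, depression
#' F4, paranoid ideation F8), G4 (background information: household
#' registration F10, family composition F11, only-child status F12).
#'
#' @param groups Optional named list of factor-name vectors overriding the
#'   default; must partition the 12 factors into groups of 3.
#' @return Object of class `two_level_structure`.
#' @export
two_level_structure <- function(groups = NULL) {
  if (is.null(groups))
    groups <- list(G1 = c("F1", "F5", "F9"),
                   G2 = c("F3", "F6", "F7"),
                   G3 = c("F2", "F4", "F8"),
                   G4 = c("F10", "F11", "F12"))
  all_f <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_f) || length(all_f) != 12L ||
      !all(lengths(groups) == 3L))
    stop("groups must partition 12 factors into groups of exactly 3")
  structure(list(groups = groups), class = "two_level_structure")
}

#' Default demographic risk tables
#'
#' Membership distributions over the four grades for the three categorical
#' factors. The defaults are mildly informative: rural household
#' registration, non-intact family composition and non-only-child status
#' shift a little mass toward higher severity, reflecting the reported
#' association between family background and well-being in poor student
#' cohorts. All tables are configurable.
#'
#' @return Named list (`hukou`, `family_composition`, `only_child`) of risk
#'   tables suitable for [membership_categorical()].
#' @export
default_risk_tables <- function() {
  list(
    hukou = list(urban = c(1, 0, 0, 0),
                 rural = c(0.6, 0.4, 0, 0)),
    family_composition = list(both_parents  = c(1, 0, 0, 0),
                              single_parent = c(0.5, 0.4, 0.1, 0),
                              other         = c(0.4, 0.4, 0.2, 0)),
    only_child = list(`TRUE`  = c(0.8, 0.2, 0, 0),
                      `FALSE` = c(0.7, 0.3, 0, 0))
  )
}

#' Compose a weight vector with a membership matrix
#'
#' The fuzzy composition step: `weighted_average` computes
#' `B_j = sum_i W_i R_ij` (the M(., +) operator); `max_min` computes
#' `B_j = max_i min(W_i, R_ij)`. Both results are normalized to sum 1.
#'
#' @param W Nonnegative weight vector, one entry per row of `R`.
#' @param R Membership matrix, rows = factors, columns = grades.
#' @param operator `"weighted_average"` (default) or `"max_min"`.
#' @return Normalized membership vector over the grades.
#' @export
compose <- function(W, R, operator = c("weighted_average", "max_min")) {
  operator <- match.arg(operator)
  R <- as.matrix(R)
  if (length(W) != nrow(R))
    stop("length(W) = ", length(W), " does not match nrow(R) = ", nrow(R))
  if (any(W < 0)) stop("weights must be nonnegative")
  B <- switch(operator,
    weighted_average = drop(W %*% R),
    max_min = apply(pmin(matrix(W, nrow(R), ncol(R)), R), 2L, max))
  s <- sum(B)
  if (s <= 0) stop("composition produced an all-zero vector")
  out <- B / s
  names(out) <- colnames(R)
  out
}

#' Two-level fuzzy comprehensive evaluation of one respondent
#'
#' Builds, for each factor group, a 3-row membership matrix from the
#' respondent's factor means (scalar factors) and demographics (categorical
#' factors), composes it with the group's second-level weights into a group
#' evaluation vector, stacks the group vectors into the first-level matrix,
#' composes that with the first-level weights, and defuzzifies by maximum
#' membership (ties resolved toward the lowest-severity grade). The grade is
#' collapsed to a binary judgment value: grade 1 maps to judgment 1
#' (negative screen), all higher grades to judgment 2.
#'
#' @param factor_means Named numeric vector with entries `F1`..`F9`
#'   (factor means on the 1..5 scale).
#' @param demographics List with `hukou`, `family_composition`, `only_child`.
#' @param structure A [two_level_structure()].
#' @param grades A [grade_set()].
#' @param level2_weights Optional named list of per-group weight vectors
#'   (each length 3, normalized internally); default uniform.
#' @param level1_weights Optional weight vector over the groups; default
#'   uniform.
#' @param risk_tables Risk tables for the categorical factors; default
#'   [default_risk_tables()].
#' @param operator Composition operator, see [compose()].
#' @param q Optional number of most important groups to retain (by
#'   first-level weight, ties toward earlier groups) before the final
#'   composition; default keeps all groups.
#' @return Object of class `fuzzy_evaluation`: list with `group_vectors`
#'   (matrix, one row per retained group), `final_vector`, `grade` (label),
#'   and `judgment_value` (1 or 2).
#' @export
evaluate_two_level <- function(factor_means, demographics,
                               structure = two_level_structure(),
                               grades = grade_set(),
                               level2_weights = NULL,
                               level1_weights = NULL,
                               risk_tables = default_risk_tables(),
                               operator = "weighted_average",
                               q = NULL) {
  cat_of <- c(F10 = "hukou", F11 = "family_composition", F12 = "only_child")
  memb <- function(f) {
    if (f %in% names(cat_of)) {
      field <- cat_of[[f]]
      membership_categorical(demographics[[field]], risk_tables[[field]],
                             grades)
    } else {
      if (!f %in% names(factor_means))
        stop("factor mean for ", f, " is missing")
      membership_scalar(factor_means[[f]], grades)
    }
  }
  gnames <- names(structure$groups)
  k <- length(grades$labels)
  group_vectors <- matrix(NA_real_, length(gnames), k,
                          dimnames = list(gnames, grades$labels))
  for (g in gnames) {
    fs <- structure$groups[[g]]
    R <- do.call(rbind, lapply(fs, memb))
    rownames(R) <- fs
    w2 <- level2_weights[[g]] %||% rep(1, length(fs))
    group_vectors[g, ] <- compose(w2 / sum(w2), R, operator)
  }
  w1 <- level1_weights %||% rep(1, length(gnames))
  if (length(w1) != length(gnames)) stop("level1_weights has wrong length")
  w1 <- w1 / sum(w1)
  keep <- seq_along(gnames)
  if (!is.null(q) && q < length(gnames)) {
    stopifnot(q >= 1L)
    keep <- sort(order(w1, decreasing = TRUE)[seq_len(q)])
  }
  final <- compose(w1[keep] / sum(w1[keep]),
                   group_vectors[keep, , drop = FALSE], operator)
  idx <- which.max(final)   # which.max takes the first maximum: lowest severity
  structure(list(group_vectors = group_vectors[keep, , drop = FALSE],
                 final_vector = final,
                 grade = grades$labels[idx],
                 judgment_value = if (idx == 1L) 1L else 2L),
            class = "fuzzy_evaluation")
}

#' @export
print.fuzzy_evaluation <- function(x, ...) {
  cat("Two-level fuzzy comprehensive evaluation\n")
  cat("  final memberships:",
      paste(sprintf("%s=%.3f", names(x$final_vector), x$final_vector),
            collapse = " "), "\n")
  cat("  grade:", x$grade, " judgment value:", x$judgment_value, "\n")
  invisible(x)
}

#' Evaluate a table of scored respondents
#'
#' Applies [evaluate_two_level()] to each row of a scored table (as produced
#' by [score_table()], which carries the factor means and demographic
#' columns).
#'
#' @param scored Data frame with columns `F1`..`F9`, `hukou`,
#'   `family_composition`, `only_child`.
#' @param ... Passed to [evaluate_two_level()].
#' @return Data frame with per-grade final memberships, `grade` and
#'   `judgment_value` per respondent.
#' @export
evaluate_table <- function(scored, ...) {
  rows <- lapply(seq_len(nrow(scored)), function(i) {
    fm <- unlist(scored[i, paste0("F", 1:9)])
    ev <- evaluate_two_level(fm,
      demographics = list(hukou = scored$hukou[i],
                          family_composition = scored$family_composition[i],
                          only_child = scored$only_child[i]), ...)
    c(as.list(ev$final_vector),
      list(grade = ev$grade, judgment_value = ev$judgment_value))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  cbind(id = scored$id %||% seq_len(nrow(scored)), out)
}
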