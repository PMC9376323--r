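# SCL-90 factor mapping, scoring and total-score screening.

# Published item lists for the nine symptom factors.  As printed, item 35
# appears under both F2 (obsessive-compulsive) and F9 (psychoticism), which
# is inconsistent with the stated count of 7 unassigned items; see
# scl90_mapping() for the two dialects.
.scl90_item_lists <- list(
  F1 = c(1, 4, 12, 27, 40, 42, 48, 49, 52, 53, 56, 58),
  F2 = c(3, 9, 10, 28, 35, 45, 46, 51, 55, 65),
  F3 = c(6, 21, 34, 36, 37, 41, 61, 69, 73),
  F4 = c(5, 14, 15, 20, 22, 26, 29, 30, 31, 32, 54, 71, 79),
  F5 = c(2, 17, 23, 33, 39, 57, 72, 78, 80, 86),
  F6 = c(11, 24, 63, 67, 74, 81),
  F7 = c(13, 25, 47, 50, 70, 75, 82),
  F8 = c(8, 18, 43, 68, 76, 83),
  F9 = c(7, 16, 35, 62, 77, 84, 85, 87, 88, 90)
)

.scl90_factor_labels <- c(
  F1 = "somatization", F2 = "obsessive-compulsive", F3 = "interpersonal sensitivity",
  F4 = "depression", F5 = "anxiety", F6 = "hostility", F7 = "phobic anxiety",
  F8 = "paranoid ideation", F9 = "psychoticism", OTHER = "additional items"
)

#' Build an SCL-90 item-to-factor mapping
#'
#' Partitions the 90 SCL-90 items into the nine symptom factors (F1
#' somatization ... F9 psychoticism) plus an `OTHER` set of unassigned items.
#' Two dialects are available. `"corrected"` (the default) resolves the
#' duplicated listing of item 35 under both the obsessive-compulsive and
#' psychoticism factors by substituting item 38 in F2, the unique single-item
#' substitution under which the ten sets partition `1:90` and `OTHER` has
#' exactly 7 items. `"verbatim"` keeps the published lists unaltered, so item
#' 35 belongs to two factors and `OTHER` has 8 items; the partition property
#' does not hold in that dialect.
#'
#' @param dialect `"corrected"` (default) or `"verbatim"`.
#' @param factors Optional named list of integer item vectors overriding the
#'   built-in nine factor lists (names `F1`..`F9`). Items must lie in 1..90
#'   and be unique within each factor.
#' @return An object of class `factor_mapping`: a list with elements
#'   `factor_items` (named list `F1`..`F9`, `OTHER`), `dialect`, and `labels`.
#' @examples
#' m <- scl90_mapping()
#' lengths(m$factor_items)
#' @export
scl90_mapping <- function(dialect = c("corrected", "verbatim"), factors = NULL) {
  dialect <- match.arg(dialect)
  items <- if (is.null(factors)) .scl90_item_lists else factors
  if (is.null(names(items)) || anyNA(names(items)) || any(names(items) == ""))
    stop("factor lists must be named")
  for (f in names(items)) {
    v <- items[[f]]
    if (!is.numeric(v) || any(v != as.integer(v)))
      stop("factor ", f, ": item numbers must be integers")
    if (any(v < 1L | v > 90L))
      stop("factor ", f, ": item number outside 1..90")
    if (anyDuplicated(v))
      stop("factor ", f, ": duplicate item ", v[duplicated(v)][1L])
    items[[f]] <- as.integer(v)
  }
  if (dialect == "corrected" && identical(items, lapply(.scl90_item_lists, as.integer))) {
    f2 <- items$F2
    f2[f2 == 35L] <- 38L
    items$F2 <- sort(f2)
  }
  assigned <- unlist(items, use.names = FALSE)
  items$OTHER <- setdiff(1:90, assigned)
  if (dialect == "corrected") {
    if (anyDuplicated(assigned))
      stop("corrected mapping must assign each item to at most one factor; ",
           "duplicated: ", paste(unique(assigned[duplicated(assigned)]), collapse = ", "))
    stopifnot(setequal(c(assigned, items$OTHER), 1:90))
  }
  structure(list(factor_items = items, dialect = dialect,
                 labels = .scl90_factor_labels),
            class = "factor_mapping")
}

#' Load a factor mapping from a configuration
#'
#' Accepts either a list (fields `dialect` and optionally `factors`) or a
#' path to a YAML/JSON configuration file with the same fields, and returns
#' the corresponding [scl90_mapping()].
#'
#' @param config A list, a file path, or `NULL` for the built-in default.
#' @return A `factor_mapping`.
#' @export
load_mapping <- function(config = NULL) {
  if (is.null(config)) return(scl90_mapping())
  if (is.character(config)) config <- load_config(config)
  if (!is.list(config)) stop("config must be a list or a file path")
  scl90_mapping(dialect = config$dialect %||% "corrected",
                factors = if (!is.null(config$factors))
                  lapply(config$factors, as.integer))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.factor_mapping <- function(x, ...) {
  cat("SCL-90 factor mapping (", x$dialect, " dialect)\n", sep = "")
  for (f in names(x$factor_items))
    cat(sprintf("  %-5s %-26s %2d items\n", f, x$labels[[f]],
                length(x$factor_items[[f]])))
  invisible(x)
}

#' Score one SCL-90 questionnaire record
#'
#' Computes the factor-level severity statistic (the arithmetic mean of each
#' factor's item responses) and the raw total score (the sum of all 90
#' responses, independent of the factor assignment).
#'
#' @param items Integer vector of 90 responses, each in 1..5.
#' @param mapping A `factor_mapping`, default [scl90_mapping()].
#' @return A list with `factor_means` (named numeric, one entry per factor
#'   set including `OTHER`, each in \[1, 5\]) and `total_score` (in
#'   \[90, 450\]).
#' @examples
#' score_record(rep(1L, 90))$total_score  # 90, the scale floor
#' @export
score_record <- function(items, mapping = scl90_mapping()) {
  validate_items(items)
  means <- vapply(mapping$factor_items, function(idx) mean(items[idx]),
                  numeric(1))
  list(factor_means = means, total_score = sum(items))
}

validate_items <- function(items) {
  if (length(items) != 90L)
    stop("expected exactly 90 item responses, got ", length(items))
  if (anyNA(items))
    stop("missing item response at position ",
         which(is.na(items))[1L], " (no imputation is performed)")
  if (!all(items %in% 1:5))
    stop("item responses must be integers in 1..5; offending position ",
         which(!(items %in% 1:5))[1L])
  invisible(TRUE)
}

#' Score a table of questionnaire records
#'
#' Vectorised [score_record()] over a data frame in the documented layout
#' (`id`, `item_1`..`item_90`, then any demographic columns, which are
#' carried through unchanged).
#'
#' @param records Data frame with columns `item_1`..`item_90` and optionally
#'   `id` and demographics.
#' @param mapping A `factor_mapping`.
#' @param threshold Screening cutoff passed to [screen_total()].
#' @return Data frame with one row per respondent: `id`, the ten factor
#'   means, `total_score`, `grade`, and any demographic columns.
#' @export
score_table <- function(records, mapping = scl90_mapping(), threshold = 160L) {
  item_cols <- paste0("item_", 1:90)
  if (!all(item_cols %in% names(records)))
    stop("records must contain columns item_1..item_90")
  M <- as.matrix(records[item_cols])
  apply(M, 1L, validate_items)
  means <- sapply(mapping$factor_items,
                  function(idx) rowMeans(M[, idx, drop = FALSE]))
  if (nrow(M) == 1L) means <- matrix(means, nrow = 1L,
                                     dimnames = list(NULL, names(mapping$factor_items)))
  total <- rowSums(M)
  out <- data.frame(id = records$id %||% seq_len(nrow(M)), means,
                    total_score = total,
                    grade = screen_total(total, threshold)$grade,
                    check.names = FALSE)
  extra <- setdiff(names(records), c("id", item_cols))
  if (length(extra)) out <- cbind(out, records[extra])
  out
}

#' Total-score screening
#'
#' Binary positive/negative screen on the SCL-90 total score: judgment value
#' 2 (positive screen) when the total reaches the threshold, 1 otherwise.
#' The boundary is inclusive: a total equal to the threshold screens
#' positive.
#'
#' @param total_score Numeric vector of totals (or the list returned by
#'   [score_record()]).
#' @param threshold Cutoff in 90..450; default 160.
#' @return A list with `grade` (integer vector of 1s and 2s) and
#'   `total_score`.
#' @examples
#' screen_total(115)$grade  # 1 (negative)
#' screen_total(185)$grade  # 2 (positive)
#' @export
screen_total <- function(total_score, threshold = 160L) {
  if (is.list(total_score)) total_score <- total_score$total_score
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 90, threshold <= 450)
  list(grade = ifelse(total_score >= threshold, 2L, 1L),
       total_score = total_score)
}
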