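# Delimited-text readers/writers and configuration loading shared by the
# command-line interface.

#' Read a questionnaire CSV
#'
#' Expects the documented header `id,item_1..item_90,hukou,
#' family_composition,only_child` (responses as integers, `only_child`
#' logical). Rows failing validation (an item outside 1..5, a missing
#' response) are collected into a reject report rather than aborting the
#' run; the report is attached as attribute `"rejects"` (a data frame with
#' `row` and `message`). An empty file or a malformed header is a hard
#' error, as is a file in which every row is rejected.
#'
#' @param path CSV file path.
#' @return Data frame of valid records with attribute `"rejects"`.
#' @export
read_questionnaires <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input file: ", path)
  item_cols <- paste0("item_", 1:90)
  required <- c("id", item_cols, "hukou", "family_composition", "only_child")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("malformed header; missing column(s): ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  rejects <- data.frame(row = integer(0), message = character(0))
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    msg <- tryCatch({
      vals <- as.numeric(df[i, item_cols])
      bad <- which(is.na(vals) | !(vals %in% 1:5))
      if (length(bad))
        stop("invalid response in column ", item_cols[bad[1L]])
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(msg)) ok[i] <- TRUE
    else rejects <- rbind(rejects, data.frame(row = i, message = msg))
  }
  if (!any(ok)) stop("all ", nrow(df), " rows failed validation")
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a factor-score table
#'
#' CSV output with factor means rounded to 4 decimal places and a stable
#' column order.
#'
#' @param scores Data frame from [score_table()].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  num <- vapply(scores, is.double, logical(1))
  scores[num] <- lapply(scores[num], round, digits = 4L)
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a nested results report as JSON
#'
#' Numbers are written at 6 significant digits with stable key order.
#'
#' @param results Named list (e.g. a `mediation_result` stripped of fits).
#' @param path Output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE)
  invisible(path)
}

#' Load a YAML or JSON configuration file
#'
#' The format is chosen by file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unrecognised config extension (expected .yaml/.yml/.json): ",
            path)
}
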