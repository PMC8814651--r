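#' @title Food-literacy scoring
#' @description Per-item overall scores (IOS, 0-6) and the rescaled 0-100
#'   food-literacy score.
#' @name scoring
NULL

#' Item overall score (IOS) of an answer
#'
#' Every answer option carries an IOS on a 7-point scale (0-6). For frequency
#' items the recommended portion scores the maximum 6 and any over-consumption
#' option is scored below it; for reverse-keyed items the IOS increases as the
#' unhealthy behaviour decreases.
#'
#' @param item An `iflt_item`.
#' @param answer Option label or 0-based option index.
#' @return Integer IOS in 0-6.
#' @export
item_ios <- function(item, answer) {
  option_ios(item)[resolve_answer(item, answer)]
}

#' Build a response object
#'
#' @param answers Named list or vector, names are item ids, values are option
#'   labels or 0-based indices.
#' @param respondent_id Identifier.
#' @return An object of class `iflt_response`.
#' @export
response <- function(answers, respondent_id = "r1") {
  answers <- as.list(answers)
  if (is.null(names(answers)) || any(!nzchar(names(answers))))
    stop("answers must be named by item id")
  structure(list(respondent_id = as.character(respondent_id),
                 answers = answers),
            class = "iflt_response")
}

as_response <- function(resp) {
  if (inherits(resp, "iflt_response")) return(resp)
  if (is.list(resp) || (is.vector(resp) && !is.null(names(resp))))
    return(response(resp))
  stop("cannot interpret object of class ", paste(class(resp), collapse = "/"),
       " as a response")
}

#' Overall 0-100 food-literacy score of one respondent
#'
#' The 17 item overall scores (0-6) are summed and rescaled to percent of the
#' attainable maximum (102 for the bundled instrument), so 0 means every item
#' at its minimum and 100 means every item at its maximum.
#'
#' @param inst An `iflt_instrument`.
#' @param resp An [response()] object (or a named list of answers).
#' @param missing Missing-answer policy: `"strict"` (default) errors listing
#'   the unanswered items; `"rescale"` scores the answered items against their
#'   own attainable maximum and flags the output.
#' @param exclude_situation Drop situation-choice items from both numerator
#'   and denominator (exposes the ambiguity of assigning an overall score to a
#'   forced situation choice).
#' @return A list of class `iflt_score` with `respondent_id`, `ios_sum`,
#'   `max_sum`, `score_pct`, `per_item_ios`, `rescaled` flag.
#' @export
overall_score <- function(inst, resp, missing = c("strict", "rescale"),
                          exclude_situation = FALSE) {
  missing <- match.arg(missing)
  resp <- as_response(resp)
  items <- inst$items
  if (exclude_situation)
    items <- Filter(function(it) it$format != "situation_choice", items)
  ids <- vapply(items, `[[`, character(1), "item_id")
  answered <- ids[ids %in% names(resp$answers)]
  unanswered <- setdiff(ids, answered)
  if (length(unanswered) && missing == "strict")
    stop("incomplete response '", resp$respondent_id, "': missing item(s) ",
         paste(unanswered, collapse = ", "))
  per_item <- vapply(answered, function(id)
    item_ios(items[[id]], resp$answers[[id]]), numeric(1))
  max_sum <- sum(vapply(items[answered], function(it) max(option_ios(it)),
                        numeric(1)))
  if (max_sum == 0) stop("attainable maximum IOS sum is zero")
  ios_sum <- sum(per_item)
  structure(list(respondent_id = resp$respondent_id,
                 ios_sum = ios_sum,
                 max_sum = max_sum,
                 score_pct = 100 * ios_sum / max_sum,
                 per_item_ios = per_item,
                 rescaled = length(unanswered) > 0L),
            class = "iflt_score")
}

#' @export
print.iflt_score <- function(x, ...) {
  cat(sprintf("<iflt_score> %s: IOS sum %d/%d, food literacy %.1f%%%s\n",
              x$respondent_id, as.integer(x$ios_sum), as.integer(x$max_sum),
              x$score_pct, if (x$rescaled) " (rescaled: missing items)" else ""))
  invisible(x)
}

# --- cohort (tabular) interface ----------------------------------------------

item_id_columns <- function(inst, df) {
  ids <- vapply(inst$items, `[[`, character(1), "item_id")
  miss <- setdiff(ids, names(df))
  if (length(miss))
    stop("response table is missing item column(s): ", paste(miss, collapse = ", "))
  ids
}

#' Resolve a response table to a matrix of 1-based option positions
#' @keywords internal
resolve_response_matrix <- function(inst, responses) {
  ids <- item_id_columns(inst, responses)
  n <- nrow(responses)
  idx <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    it <- inst$items[[id]]
    col <- responses[[id]]
    labs <- option_labels(it)
    if (is.numeric(col)) {
      pos <- as.integer(col) + 1L
      bad <- which(is.na(pos) | pos < 1L | pos > length(labs) | col != floor(col))
    } else {
      col <- as.character(col)
      pos <- match(col, labs)
      num <- suppressWarnings(as.numeric(col))
      useidx <- which(is.na(pos) & !is.na(num))
      pos[useidx] <- as.integer(num[useidx]) + 1L
      bad <- which(is.na(pos) | pos < 1L | pos > length(labs))
    }
    if (length(bad))
      stop("item ", id, ": unresolvable answer(s) in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    idx[, id] <- pos
  }
  idx
}

#' Score a table of respondents
#'
#' @param inst An `iflt_instrument`.
#' @param responses `data.frame` with a `respondent_id` column and one column
#'   per item id holding option labels or 0-based indices.
#' @param items Include the per-item IOS values as columns (default `TRUE`).
#' @return `data.frame` with `respondent_id`, `ios_sum`, `score_pct` and
#'   optionally one IOS column per item.
#' @export
score_responses <- function(inst, responses, items = TRUE) {
  idx <- resolve_response_matrix(inst, responses)
  ids <- colnames(idx)
  ios <- vapply(ids, function(id) option_ios(inst$items[[id]])[idx[, id]],
                numeric(nrow(idx)))
  ios <- matrix(ios, nrow = nrow(idx), dimnames = list(NULL, ids))
  max_sum <- sum(vapply(inst$items[ids], function(it) max(option_ios(it)),
                        numeric(1)))
  out <- data.frame(
    respondent_id = as.character(respondent_ids(responses)),
    ios_sum = rowSums(ios),
    score_pct = 100 * rowSums(ios) / max_sum,
    stringsAsFactors = FALSE)
  if (items) out <- cbind(out, as.data.frame(ios))
  out
}

respondent_ids <- function(df) {
  if ("respondent_id" %in% names(df)) df$respondent_id
  else sprintf("r%03d", seq_len(nrow(df)))
}

#' Read a response table from CSV
#'
#' Expects UTF-8, a header row and comma separators; columns are item ids
#' (plus `respondent_id`), values are option labels or 0-based option indices.
#'
#' @param path CSV file path.
#' @return `data.frame` of character columns.
#' @export
read_responses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", encoding = "UTF-8")
}

#' Write a response table to CSV
#' @param responses `data.frame` as produced by the simulator.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
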