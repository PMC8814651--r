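#' @title Goal prioritization algorithm
#' @description
#' Every answer option carries an item priority score (IPS, 0-5): the worse
#' the answer relative to the recommendation, the larger the IPS, with 0
#' meaning the respondent has no need to focus on the linked goal. Per goal,
#' the IPS contributions are summed (capped at 5) and added to the goal's
#' expert ranking weight (a unique value in \{0.01, ..., 0.24\} acting as the
#' default prioritization order and tie-free offset). Ranking the 24 totals
#' in descending order yields the personalized goal priority list; a
#' respondent with perfect food literacy (all IPS 0) receives the goals in
#' the default expert order.
#' @name personalization
NULL

#' Item priority scores (IPS) of an answer
#'
#' @param item An `iflt_item`.
#' @param answer Option label or 0-based option index.
#' @return Named numeric vector over the item's goal ids. Single-goal items
#'   return the option's IPS for that goal; situation items return the
#'   option's IPS for the chosen situation's goal and 0 for its siblings.
#' @export
item_ips <- function(item, answer) {
  o <- item$options[[resolve_answer(item, answer)]]
  out <- stats::setNames(numeric(length(item$goal_ids)), item$goal_ids)
  if (!is.null(o$per_goal_ips)) {
    hit <- intersect(names(o$per_goal_ips), item$goal_ids)
    out[hit] <- o$per_goal_ips[hit]
  } else {
    out[] <- o$ips
  }
  out
}

#' Per-goal priority totals for one respondent
#'
#' @param inst An `iflt_instrument`.
#' @param resp An [response()] object or named list of answers.
#' @param cap Maximum summed IPS contribution per goal (default 5), so the
#'   fractional expert weight always remains the tie-breaking component.
#' @return `data.frame` with one row per goal: `goal_id`, `ips_component`,
#'   `weight_component`, `total`.
#' @export
priority_scores <- function(inst, resp, cap = 5) {
  resp <- as_response(resp)
  ids <- vapply(inst$items, `[[`, character(1), "item_id")
  unanswered <- setdiff(ids, names(resp$answers))
  if (length(unanswered))
    stop("incomplete response '", resp$respondent_id, "': missing item(s) ",
         paste(unanswered, collapse = ", "))
  ips <- stats::setNames(numeric(nrow(inst$goals)), inst$goals$goal_id)
  for (id in ids) {
    contrib <- item_ips(inst$items[[id]], resp$answers[[id]])
    ips[names(contrib)] <- ips[names(contrib)] + contrib
  }
  ips <- pmin(ips, cap)
  data.frame(goal_id = inst$goals$goal_id,
             ips_component = unname(ips[inst$goals$goal_id]),
             weight_component = inst$goals$expert_weight,
             total = unname(ips[inst$goals$goal_id]) + inst$goals$expert_weight,
             stringsAsFactors = FALSE)
}

rank_priorities <- function(scores) {
  # defensive tie-break (unreachable with a conforming instrument):
  # larger expert weight first, then goal id ascending
  ord <- order(-scores$total, -scores$weight_component, scores$goal_id)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Personalized priority list over all 24 goals
#'
#' @inheritParams priority_scores
#' @return `data.frame` of class `iflt_priorities`, sorted by `total`
#'   descending with `rank` 1-24 assigned without gaps.
#' @examples
#' inst <- bundled_iflt()
#' perfect <- perfect_response(inst)
#' head(prioritize(inst, perfect), 3)  # default expert order: G7, G15, G17
#' @export
prioritize <- function(inst, resp, cap = 5) {
  out <- rank_priorities(priority_scores(inst, resp, cap = cap))
  resp <- as_response(resp)
  out <- cbind(respondent_id = resp$respondent_id, out,
               stringsAsFactors = FALSE)
  class(out) <- c("iflt_priorities", "data.frame")
  out
}

#' Top-k view of a priority list
#'
#' @param gpl Output of [prioritize()].
#' @param k Number of leading goals, between 1 and the number of ranked goals
#'   (default 3, the published priority-list size).
#' @return Character vector of `k` goal ids in rank order.
#' @export
top_k <- function(gpl, k = 3) {
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 1 || k > nrow(gpl))
    stop("k must be an integer between 1 and ", nrow(gpl))
  gpl$goal_id[order(gpl$rank)][seq_len(k)]
}

#' Best-possible response (maximum IOS on every item)
#' @param inst An `iflt_instrument`.
#' @return An [response()] choosing the highest-IOS option everywhere.
#' @export
perfect_response <- function(inst) {
  ans <- lapply(inst$items, function(it)
    option_labels(it)[which.max(option_ios(it))])
  response(ans, respondent_id = "perfect")
}

#' Worst-possible response (minimum IOS on every item)
#' @param inst An `iflt_instrument`.
#' @return An [response()] choosing the lowest-IOS option everywhere.
#' @export
worst_response <- function(inst) {
  ans <- lapply(inst$items, function(it)
    option_labels(it)[which.min(option_ios(it))])
  response(ans, respondent_id = "worst")
}

# --- vectorized cohort interface ---------------------------------------------

#' Priority lists for a table of respondents
#'
#' Vectorized equivalent of [prioritize()] applied row-wise; used for cohort
#' runs and the large property checks.
#'
#' @param inst An `iflt_instrument`.
#' @param responses Response table (see [score_responses()]).
#' @param cap Per-goal IPS cap, default 5.
#' @return Long `data.frame`: `respondent_id`, `rank`, `goal_id`,
#'   `ips_component`, `weight_component`, `total`.
#' @export
prioritize_responses <- function(inst, responses, cap = 5) {
  goal_ids <- inst$goals$goal_id
  ips <- ips_matrix(inst, responses, cap = cap)
  n <- nrow(ips)
  totals <- sweep(ips, 2L, inst$goals$expert_weight, `+`)
  rid <- as.character(respondent_ids(responses))
  w <- inst$goals$expert_weight
  ord <- t(apply(totals, 1L, function(tt) order(-tt, -w, goal_ids)))
  flat <- as.vector(t(ord))                       # n blocks of 24 positions
  rowi <- rep(seq_len(n), each = length(goal_ids))
  pick <- cbind(rowi, flat)
  out <- data.frame(respondent_id = rid[rowi],
                    rank = rep(seq_along(goal_ids), times = n),
                    goal_id = goal_ids[flat],
                    ips_component = ips[pick],
                    weight_component = w[flat],
                    total = totals[pick],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Priority totals matrix (fast path)
#'
#' Returns the per-respondent, per-goal priority totals (capped IPS sum plus
#' expert weight) without ranking; used by the large-scale tie checks.
#'
#' @inheritParams prioritize_responses
#' @return Numeric matrix, respondents x goals.
#' @export
priority_totals <- function(inst, responses, cap = 5) {
  sweep(ips_matrix(inst, responses, cap = cap), 2L,
        inst$goals$expert_weight, `+`)
}

# capped per-goal IPS sums for a response table (respondents x goals)
ips_matrix <- function(inst, responses, cap = 5) {
  idx <- resolve_response_matrix(inst, responses)
  goal_ids <- inst$goals$goal_id
  ips <- matrix(0, nrow(idx), length(goal_ids),
                dimnames = list(NULL, goal_ids))
  for (id in colnames(idx)) {
    it <- inst$items[[id]]
    # per-goal x per-option contribution table for this item
    contrib <- vapply(it$options, function(o) {
      row <- stats::setNames(numeric(length(it$goal_ids)), it$goal_ids)
      if (!is.null(o$per_goal_ips)) {
        hit <- intersect(names(o$per_goal_ips), it$goal_ids)
        row[hit] <- o$per_goal_ips[hit]
      } else row[] <- o$ips
      row
    }, numeric(length(it$goal_ids)))
    contrib <- matrix(contrib, ncol = length(it$options),
                      dimnames = list(it$goal_ids, NULL))
    ips[, it$goal_ids] <- ips[, it$goal_ids] + t(contrib[, idx[, id], drop = FALSE])
  }
  pmin(ips, cap)
}

#' Top-k goal assignments per respondent from a long priority table
#'
#' @param priorities Output of [prioritize_responses()].
#' @param k Number of leading goals per respondent (default 3).
#' @return `data.frame` with `respondent_id`, `rank`, `goal_id`.
#' @export
top_k_assignments <- function(priorities, k = 3) {
  if (k < 1) stop("k must be at least 1")
  out <- priorities[priorities$rank <= k,
                    c("respondent_id", "rank", "goal_id")]
  rownames(out) <- NULL
  out
}
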