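#' @title Accuracy of eating-goal assignment
#' @description Checks whether eating-domain goals assigned to a respondent's
#'   top-3 priority list correspond to actual non-compliance with the Belgian
#'   food-based dietary recommendations derived from FFQ intakes.
#' @name accuracy
NULL

#' Dietary recommendations for the five eating goals
#'
#' Thresholds use strict inequalities exactly as published, so boundary
#' intakes count as compliant: meat fails above 100 g/day, vegetables below
#' 300 g/day, fruit below 250 g/day, water below 1500 ml/day and
#' ultra-processed foods above 50 g/day.
#'
#' @return `data.frame` with `goal_id`, `intake`, `threshold`, `direction`,
#'   `unit`.
#' @export
eat_goal_recommendations <- function() {
  data.frame(
    goal_id = c("G14", "G15", "G16", "G17", "G18"),
    intake = c("meat", "vegetables", "fruit", "water", "ultra_processed"),
    threshold = c(100, 300, 250, 1500, 50),
    direction = c("fail_if_above", "fail_if_below", "fail_if_below",
                  "fail_if_below", "fail_if_above"),
    unit = c("g/day", "g/day", "g/day", "ml/day", "g/day"),
    stringsAsFactors = FALSE)
}

#' Does an intake violate the recommendation behind a goal?
#'
#' @param goal_id One of `"G14"`, `"G15"`, `"G16"`, `"G17"`, `"G18"`.
#' @param intake Named list / one-row data.frame with the intake fields in
#'   g/day (water in ml/day).
#' @return Logical: `TRUE` when the intake fails the recommendation (strict
#'   inequality).
#' @export
fails_recommendation <- function(goal_id, intake) {
  rec <- eat_goal_recommendations()
  row <- rec[rec$goal_id == goal_id, ]
  if (nrow(row) != 1L)
    stop("no dietary recommendation for goal ", goal_id)
  val <- intake[[row$intake]]
  if (is.null(val) || length(val) != 1L || is.na(val))
    stop("intake record is missing the '", row$intake, "' field required by ",
         goal_id)
  if (val < 0) stop("intake '", row$intake, "' must be non-negative")
  if (row$direction == "fail_if_above") val > row$threshold else val < row$threshold
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Accuracy percentage from counts
#'
#' `100 * n_correct / n_top3`, rounded half-up to an integer for report
#' parity; when no respondent received the goal (`n_top3 = 0`) the accuracy
#' is reported as 100 by convention and flagged as undefined.
#'
#' @param n_correct Respondents assigned the goal whose intake actually
#'   fails the recommendation.
#' @param n_top3 Respondents with the goal in their top-3 list.
#' @return List with `accuracy_pct` (integer, half-up), `accuracy_raw`
#'   (unrounded, `NA` when undefined) and `undefined_by_convention`.
#' @export
accuracy_pct <- function(n_correct, n_top3) {
  if (n_correct < 0 || n_top3 < 0 || n_correct > n_top3)
    stop("need 0 <= n_correct <= n_top3")
  if (n_top3 == 0)
    return(list(accuracy_pct = 100, accuracy_raw = NA_real_,
                undefined_by_convention = TRUE))
  raw <- 100 * n_correct / n_top3
  list(accuracy_pct = round_half_up(raw), accuracy_raw = raw,
       undefined_by_convention = FALSE)
}

intake_row <- function(intakes, rid) {
  hit <- which(intakes$respondent_id == rid)
  if (length(hit) != 1L)
    stop("missing (or duplicated) intake record for respondent '", rid, "'")
  intakes[hit, , drop = FALSE]
}

#' Assignment accuracy of one eating goal
#'
#' @param assignments `data.frame` with `respondent_id` and `goal_id`
#'   (typically [top_k_assignments()] output).
#' @param intakes `data.frame` with `respondent_id` and the intake columns
#'   (`meat`, `vegetables`, `fruit`, `water`, `ultra_processed`).
#' @param goal_id Eating goal to evaluate.
#' @return List with `goal_id`, `n_top3`, `n_correct` and the fields of
#'   [accuracy_pct()].
#' @export
goal_accuracy <- function(assignments, intakes, goal_id) {
  assigned <- unique(assignments$respondent_id[assignments$goal_id == goal_id])
  correct <- vapply(assigned, function(rid)
    fails_recommendation(goal_id, intake_row(intakes, rid)), logical(1))
  c(list(goal_id = goal_id, n_top3 = length(assigned),
         n_correct = sum(correct)),
    accuracy_pct(sum(correct), length(assigned)))
}

#' Accuracy table over the five eating goals
#'
#' @inheritParams goal_accuracy
#' @return List with `table` (one row per eating goal: `goal_id`, `n_top3`,
#'   `n_correct`, `accuracy_pct`, `undefined_by_convention`) and a `summary`
#'   row carrying the min and max accuracy.
#' @export
accuracy_table <- function(assignments, intakes) {
  rec <- eat_goal_recommendations()
  rows <- lapply(rec$goal_id, function(g) {
    a <- goal_accuracy(assignments, intakes, g)
    data.frame(goal_id = g, n_top3 = a$n_top3, n_correct = a$n_correct,
               accuracy_pct = a$accuracy_pct,
               undefined_by_convention = a$undefined_by_convention,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = c(min_accuracy = min(tab$accuracy_pct),
                   max_accuracy = max(tab$accuracy_pct)))
}

#' Energy-adjust an intake record
#'
#' Scales every food quantity by `reference / energy`, expressing intakes at
#' a common energy level. Off by default in the accuracy evaluation because
#' the published thresholds are absolute; when used, record it in the run
#' metadata.
#'
#' @param intake Named list / one-row data.frame including `energy`
#'   (kcal/day).
#' @param reference Reference energy intake in kcal/day (default 2000).
#' @return The intake with `meat`, `vegetables`, `fruit`, `water` and
#'   `ultra_processed` rescaled.
#' @export
energy_adjust <- function(intake, reference = 2000) {
  en <- intake[["energy"]]
  if (is.null(en) || length(en) != 1L || is.na(en) || en <= 0)
    stop("energy adjustment requires a positive 'energy' field")
  for (f in c("meat", "vegetables", "fruit", "water", "ultra_processed"))
    if (!is.null(intake[[f]])) intake[[f]] <- intake[[f]] * reference / en
  intake
}

#' Read an intake table from CSV
#' @param path CSV with `respondent_id` and the intake columns.
#' @return `data.frame`.
#' @export
read_intakes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
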