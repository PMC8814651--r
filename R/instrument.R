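#' @title Instrument data model for the integrated food literacy tool
#' @description
#' An instrument bundles 24 food-literacy goals (each carrying a unique
#' expert ranking weight in \{0.01, ..., 0.24\}), 17 screener items with typed
#' answer options, and the item-to-goal map. Every answer option carries two
#' scores: an item overall score (IOS, 0-6) feeding the 0-100 food-literacy
#' score, and an item priority score (IPS, 0-5) feeding the goal
#' prioritization algorithm.
#' @name instrument-model
#' @keywords internal
NULL

.iflt_domains <- c("plan", "select", "prepare", "eat", "information")
.iflt_formats <- c("likert7", "frequency", "always_never", "situation_choice")

#' Construct an answer option
#'
#' @param label Option wording (opaque text, must be unique within an item).
#' @param ios Item overall score, integer 0-6.
#' @param ips Item priority score, integer 0-5. Defaults to
#'   `max(0, 5 - ios)`, the linear-descent rule that reproduces both fully
#'   printed option sets of the bundled instrument.
#' @param per_goal_ips Optional named numeric vector (names are goal ids)
#'   giving per-goal IPS for multi-goal (situation) items; goals absent from
#'   the map receive 0.
#' @return A list of class `iflt_option`.
#' @export
answer_option <- function(label, ios, ips = max(0, 5 - ios), per_goal_ips = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  ios <- as.numeric(ios); ips <- as.numeric(ips)
  if (!is.null(per_goal_ips)) {
    per_goal_ips <- unlist(per_goal_ips)
    storage.mode(per_goal_ips) <- "double"
    if (length(per_goal_ips) > 0L && is.null(names(per_goal_ips)))
      stop("per_goal_ips must be a named vector of goal ids")
    per_goal_ips <- per_goal_ips[order(names(per_goal_ips))]
  }
  structure(list(label = label, ios = ios, ips = ips,
                 per_goal_ips = per_goal_ips),
            class = "iflt_option")
}

#' Construct a screener item
#'
#' @param item_id Identifier, e.g. `"Q1"`.
#' @param text Item wording.
#' @param format One of `"likert7"`, `"frequency"`, `"always_never"`,
#'   `"situation_choice"`.
#' @param goal_ids Character vector of goal ids the item addresses.
#' @param options List of [answer_option()] objects, in presentation order.
#' @param reverse_keyed Logical; `TRUE` for items where less of the behaviour
#'   is better (meat, snacks, overeating).
#' @param reconstructed Logical; `TRUE` when the option set is a
#'   generalization of the published scoring scheme rather than a printed
#'   option table, so it can be overridden in a config without code changes.
#' @param icvi Optional integer vector `c(relevant, total)` carrying the
#'   published expert content-validity tally for the item.
#' @return A list of class `iflt_item`.
#' @export
screener_item <- function(item_id, text, format, goal_ids, options,
                          reverse_keyed = FALSE, reconstructed = TRUE,
                          icvi = NULL) {
  stopifnot(is.character(item_id), length(item_id) == 1L,
            is.character(text), length(text) == 1L,
            is.character(goal_ids), length(goal_ids) >= 1L,
            is.list(options), length(options) >= 2L)
  if (!format %in% .iflt_formats)
    stop("unknown item format '", format, "' for item ", item_id)
  if (!all(vapply(options, inherits, logical(1), "iflt_option")))
    stop("options of item ", item_id, " must be answer_option objects")
  if (!is.null(icvi)) {
    icvi <- as.numeric(unlist(icvi))
    if (length(icvi) != 2L) stop("icvi must be c(relevant, total)")
    names(icvi) <- c("relevant", "total")
  }
  structure(list(item_id = item_id, text = text, format = format,
                 goal_ids = goal_ids,
                 reverse_keyed = isTRUE(reverse_keyed),
                 reconstructed = isTRUE(reconstructed),
                 icvi = icvi, options = options),
            class = "iflt_item")
}

#' Construct an instrument
#'
#' @param goals `data.frame` with columns `goal_id`, `label`, `domain`,
#'   `expert_weight`.
#' @param items List of [screener_item()] objects.
#' @param metadata List with at least `name` and `version`.
#' @return An object of class `iflt_instrument`.
#' @seealso [bundled_iflt()], [validate_instrument()], [load_instrument()]
#' @export
new_instrument <- function(goals, items, metadata = list(name = "instrument",
                                                         version = "0")) {
  stopifnot(is.data.frame(goals),
            all(c("goal_id", "label", "domain", "expert_weight") %in%
                  names(goals)))
  goals <- data.frame(goal_id = as.character(goals$goal_id),
                      label = as.character(goals$label),
                      domain = as.character(goals$domain),
                      expert_weight = as.numeric(goals$expert_weight),
                      stringsAsFactors = FALSE)
  rownames(goals) <- NULL
  names(items) <- vapply(items, `[[`, character(1), "item_id")
  structure(list(metadata = metadata, goals = goals, items = items),
            class = "iflt_instrument")
}

# --- option accessors (vectorized caches) -----------------------------------

option_labels <- function(item) vapply(item$options, `[[`, character(1), "label")
option_ios <- function(item) vapply(item$options, `[[`, numeric(1), "ios")
option_ips <- function(item) vapply(item$options, `[[`, numeric(1), "ips")

#' Resolve an answer to a 1-based option position
#'
#' Answers may be given as option labels or as 0-based option indices
#' (the convention of the delimited response files).
#'
#' @param item An `iflt_item`.
#' @param answer Option label (character) or 0-based index (numeric or a
#'   character that parses as a number).
#' @return 1-based integer position into `item$options`.
#' @keywords internal
resolve_answer <- function(item, answer) {
  if (length(answer) != 1L || is.na(answer))
    stop("item ", item$item_id, ": answer must be a single non-missing value")
  labs <- option_labels(item)
  if (is.character(answer)) {
    hit <- match(answer, labs)
    if (!is.na(hit)) return(hit)
    num <- suppressWarnings(as.numeric(answer))
    if (is.na(num))
      stop("item ", item$item_id, ": unknown answer option '", answer, "'")
    answer <- num
  }
  idx <- as.integer(answer)
  if (idx != answer || idx < 0L || idx >= length(labs))
    stop("item ", item$item_id, ": option index ", answer,
         " out of range 0-", length(labs) - 1L)
  idx + 1L
}

# --- validation --------------------------------------------------------------

violation <- function(field, message)
  data.frame(field = field, message = message, stringsAsFactors = FALSE)

#' Validate an instrument against the tool's structural invariants
#'
#' Checks the full invariant set: 24 goals whose expert weights are exactly
#' the set \{0.01, ..., 0.24\}, 17 items covering every goal, 7 options on
#' every scale-format item, IOS in 0-6 with an attainable maximum of 6 per
#' item, IPS in 0-5 with at least one no-need (IPS 0) option per item, and
#' referential integrity of the item-to-goal map.
#'
#' @param inst An `iflt_instrument`.
#' @return A `data.frame` with columns `field` and `message`, zero rows when
#'   the instrument is valid. Violations are returned, never raised.
#' @export
validate_instrument <- function(inst) {
  v <- violation(character(0), character(0))
  g <- inst$goals
  if (nrow(g) != 24L)
    v <- rbind(v, violation("goals", sprintf("expected 24 goals, found %d", nrow(g))))
  if (anyDuplicated(g$goal_id))
    v <- rbind(v, violation("goals.goal_id", "duplicate goal ids"))
  bad_dom <- setdiff(unique(g$domain), .iflt_domains)
  if (length(bad_dom))
    v <- rbind(v, violation("goals.domain",
                            paste("unknown domain(s):", paste(bad_dom, collapse = ", "))))
  want <- (1:24) / 100
  have <- sort(round(g$expert_weight, 10))
  if (nrow(g) == 24L && !isTRUE(all.equal(have, want, tolerance = 1e-9)))
    v <- rbind(v, violation("goals.expert_weight",
                            "expert weights must be exactly the set {0.01, ..., 0.24}"))
  if (anyDuplicated(round(g$expert_weight, 10)))
    v <- rbind(v, violation("goals.expert_weight", "expert weights must be pairwise distinct"))

  items <- inst$items
  if (length(items) != 17L)
    v <- rbind(v, violation("items", sprintf("expected 17 items, found %d", length(items))))
  if (anyDuplicated(vapply(items, `[[`, character(1), "item_id")))
    v <- rbind(v, violation("items.item_id", "duplicate item ids"))

  referenced <- character(0)
  for (it in items) {
    fid <- paste0("items.", it$item_id)
    referenced <- c(referenced, it$goal_ids)
    missing_goals <- setdiff(it$goal_ids, g$goal_id)
    if (length(missing_goals))
      v <- rbind(v, violation(paste0(fid, ".goal_ids"),
                              paste("references unknown goal(s):",
                                    paste(missing_goals, collapse = ", "))))
    n_opt <- length(it$options)
    if (it$format %in% c("likert7", "always_never", "frequency") && n_opt != 7L)
      v <- rbind(v, violation(paste0(fid, ".options"),
                              sprintf("%s items need exactly 7 options, found %d",
                                      it$format, n_opt)))
    ios <- option_ios(it); ips <- option_ips(it)
    if (any(ios != round(ios)) || any(ios < 0) || any(ios > 6))
      v <- rbind(v, violation(paste0(fid, ".options.ios"),
                              "IOS values must be integers in [0, 6]"))
    if (max(ios) != 6)
      v <- rbind(v, violation(paste0(fid, ".options.ios"),
                              "maximum attainable IOS must be 6"))
    if (any(ips != round(ips)) || any(ips < 0) || any(ips > 5))
      v <- rbind(v, violation(paste0(fid, ".options.ips"),
                              "IPS values must be integers in [0, 5]"))
    if (anyDuplicated(option_labels(it)))
      v <- rbind(v, violation(paste0(fid, ".options.label"), "duplicate option labels"))
    eff_ips <- vapply(it$options, function(o) {
      if (!is.null(o$per_goal_ips)) {
        if (length(o$per_goal_ips) == 0L) 0 else max(o$per_goal_ips)
      } else o$ips
    }, numeric(1))
    if (min(eff_ips) != 0)
      v <- rbind(v, violation(paste0(fid, ".options.ips"),
                              "at least one option must signal no need (IPS 0)"))
    for (o in it$options) {
      if (!is.null(o$per_goal_ips) && length(o$per_goal_ips) > 0L) {
        extra <- setdiff(names(o$per_goal_ips), it$goal_ids)
        if (length(extra))
          v <- rbind(v, violation(paste0(fid, ".options.per_goal_ips"),
                                  paste("maps goal(s) not linked to the item:",
                                        paste(extra, collapse = ", "))))
        if (any(o$per_goal_ips < 0) || any(o$per_goal_ips > 5) ||
            any(o$per_goal_ips != round(o$per_goal_ips)))
          v <- rbind(v, violation(paste0(fid, ".options.per_goal_ips"),
                                  "per-goal IPS values must be integers in [0, 5]"))
      }
    }
  }
  orphan <- setdiff(g$goal_id, referenced)
  if (length(orphan))
    v <- rbind(v, violation("goals", paste("goal(s) not addressed by any item:",
                                           paste(orphan, collapse = ", "))))
  v
}

# --- bundled instrument -----------------------------------------------------

likert7_options <- function() {
  labs <- c("Strongly disagree", "Disagree", "Partly disagree",
            "Not agreeing, not disagreeing", "Partly agree", "Agree",
            "Strongly agree")
  lapply(seq_along(labs), function(i) answer_option(labs[i], ios = i - 1L))
}

always_never_options <- function(reverse = FALSE) {
  labs <- c("Never", "Rarely", "Sometimes", "Regularly", "Often",
            "Almost always", "Always")
  ios <- if (reverse) 6:0 else 0:6
  lapply(seq_along(labs), function(i) answer_option(labs[i], ios = ios[i]))
}

frequency_options <- function(labels, ios = c(0:4, 6, 5)) {
  stopifnot(length(labels) == 7L)
  lapply(seq_along(labels), function(i) answer_option(labels[i], ios = ios[i]))
}

situation_options <- function(situations, goal_ids) {
  opts <- lapply(seq_along(situations), function(i)
    answer_option(situations[i], ios = 0L, ips = 5L,
                  per_goal_ips = stats::setNames(5, goal_ids[i])))
  none <- answer_option("No particular difficulties", ios = 6L, ips = 0L,
                        per_goal_ips = stats::setNames(numeric(0), character(0)))
  c(opts, list(none))
}

#' The bundled integrated food literacy tool
#'
#' Returns the canonical instrument: 24 goals with their expert ranking
#' weights, 17 screener items and the item-to-goal map. The two option sets
#' that were published in full (the healthy-food-choices agreement item Q3 and
#' the water-intake frequency item Q13) are encoded verbatim; all other option
#' sets generalize the same scheme (IOS 0-6 with the recommended answer at 6,
#' IPS = max(0, 5 - IOS)) and are flagged `reconstructed` so a user config can
#' override them. The goal weight printed as 0.8 for the food-label goal is
#' encoded as 0.08, the only value completing the stated weight set
#' \{0.01, ..., 0.24\}; the correction is recorded in the metadata.
#'
#' @return An `iflt_instrument` that passes [validate_instrument()] with zero
#'   violations.
#' @examples
#' inst <- bundled_iflt()
#' nrow(inst$goals)         # 24
#' length(inst$items)       # 17
#' @export
bundled_iflt <- function() {
  goals <- data.frame(
    goal_id = paste0("G", 1:24),
    label = c(
      "Making time to eat (together)",
      "Having access to healthy food when you have little time",
      "Having access to healthy food at home",
      "Having access to healthy food at work/school/on the road",
      "Having access to healthy food when eating out",
      "Having access to healthy food when stressed",
      "Making healthy food choices",
      "Understanding food packages and labels",
      "Variation (in selecting, preparing and eating)",
      "Being able to compose a healthy meal",
      "Being able to know and apply basic cooking skills",
      "Knowing and applying principles of food hygiene",
      "Understanding benefits of healthy eating",
      "Eating more plant-based (less animal-based)",
      "Eating enough vegetables",
      "Eating enough fruits",
      "Drinking enough and mainly water",
      "Eating less ultra-processed foods",
      "Eating consciously and not too much",
      "Eating healthy at breakfast",
      "Eating healthy at lunch",
      "Eating healthy at dinner",
      "Eating healthy when snacking",
      "Being able to find reliable information about a healthy diet"),
    domain = c("plan", rep("plan", 5), rep("select", 3), rep("prepare", 3),
               rep("eat", 11), "information"),
    expert_weight = c(0.21, 0.06, 0.16, 0.09, 0.02, 0.03, 0.24, 0.08, 0.15,
                      0.20, 0.04, 0.01, 0.14, 0.05, 0.23, 0.11, 0.22, 0.10,
                      0.13, 0.17, 0.19, 0.18, 0.12, 0.07),
    stringsAsFactors = FALSE)

  water_labels <- c("Less than 1 glass per day", "1-3 glasses per day",
                    "3-5 glasses per day", "5-7 glasses per day",
                    "7-8 glasses per day", "8-10 glasses per day",
                    "More than 10 glasses per day")
  meat_labels <- c("More than 400 g per day", "300-400 g per day",
                   "250-300 g per day", "200-250 g per day",
                   "150-200 g per day", "100-150 g per day",
                   "100 g or less per day")
  veg_labels <- c("Hardly any vegetables", "60-120 g per day",
                  "120-180 g per day", "180-240 g per day",
                  "240-300 g per day", "300-600 g per day",
                  "More than 600 g per day")
  fruit_labels <- c("Hardly any fruit", "50-100 g per day",
                    "100-150 g per day", "150-200 g per day",
                    "200-250 g per day", "250-500 g per day",
                    "More than 500 g per day")
  snack_labels <- c("More than 250 g per day", "200-250 g per day",
                    "150-200 g per day", "100-150 g per day",
                    "75-100 g per day", "50-75 g per day",
                    "50 g or less per day")

  items <- list(
    screener_item("Q1", "How often do you make time to eat?", "always_never",
                  "G1", always_never_options(), icvi = c(7, 7)),
    screener_item("Q2",
                  "In which situation do you experience the most difficulties to follow a healthy diet?",
                  "situation_choice", paste0("G", 2:6),
                  situation_options(c("When you have little time", "At home",
                                      "At work/school/on the road",
                                      "When eating out", "When stressed"),
                                    paste0("G", 2:6)),
                  icvi = c(7, 7)),
    screener_item("Q3",
                  "I can choose the right food items in order to achieve a healthy diet",
                  "likert7", "G7", likert7_options(), reconstructed = FALSE,
                  icvi = c(7, 7)),
    screener_item("Q4", "I understand what's on food packages", "likert7",
                  "G8", likert7_options(), icvi = c(6, 7)),
    screener_item("Q5", "I vary my food choices", "likert7", "G9",
                  likert7_options(), icvi = c(7, 7)),
    screener_item("Q6", "I can compose a healthy meal", "likert7", "G10",
                  likert7_options(), icvi = c(7, 7)),
    screener_item("Q7", "I can cook", "likert7", "G11", likert7_options(),
                  icvi = c(6, 7)),
    screener_item("Q8", "I can apply the principles of food hygiene",
                  "likert7", "G12", likert7_options(), icvi = c(5, 7)),
    screener_item("Q9", "What I eat influences my health", "likert7", "G13",
                  likert7_options(), icvi = c(6, 7)),
    screener_item("Q10", "How often do you eat a portion of meat?",
                  "frequency", "G14", frequency_options(meat_labels, ios = 0:6),
                  reverse_keyed = TRUE, icvi = c(7, 7)),
    screener_item("Q11", "How often do you eat a portion of vegetables?",
                  "frequency", "G15", frequency_options(veg_labels),
                  icvi = c(7, 7)),
    screener_item("Q12", "How often do you eat a portion of fruit?",
                  "frequency", "G16", frequency_options(fruit_labels),
                  icvi = c(7, 7)),
    screener_item("Q13", "How much water do you drink per day? (1 glass = 200 ml)",
                  "frequency", "G17", frequency_options(water_labels),
                  reconstructed = FALSE, icvi = c(7, 7)),
    screener_item("Q14", "How often do you eat savory and/or sweet snacks?",
                  "frequency", "G18", frequency_options(snack_labels, ios = 0:6),
                  reverse_keyed = TRUE, icvi = c(7, 7)),
    screener_item("Q15", "How often do you eat too much?", "always_never",
                  "G19", always_never_options(reverse = TRUE),
                  reverse_keyed = TRUE, icvi = c(6, 7)),
    screener_item("Q16",
                  "During which meal do you experience the most difficulties to follow a healthy diet?",
                  "situation_choice", paste0("G", 20:23),
                  situation_options(c("Breakfast", "Lunch", "Dinner", "Snacking"),
                                    paste0("G", 20:23)),
                  icvi = c(7, 7)),
    screener_item("Q17",
                  "If I have questions regarding a healthy diet, I can find reliable information on this",
                  "likert7", "G24", likert7_options(), icvi = c(5, 7)))

  new_instrument(goals, items,
                 metadata = list(
                   name = "IFLT food literacy screener",
                   version = "1.0",
                   notes = paste("Goal G8 expert weight encoded as 0.08:",
                                 "the published table prints 0.8, but the 24",
                                 "weights are stated to form the set",
                                 "{0.01, ..., 0.24} and 0.08 is the only",
                                 "missing value.")))
}

# --- serialization ----------------------------------------------------------

option_to_list <- function(o) {
  out <- list(label = o$label, ios = o$ios, ips = o$ips)
  if (!is.null(o$per_goal_ips)) out$per_goal_ips <- as.list(o$per_goal_ips)
  out
}

item_to_list <- function(it) {
  out <- list(item_id = it$item_id, text = it$text, format = it$format,
              goal_ids = as.list(it$goal_ids),
              reverse_keyed = it$reverse_keyed,
              reconstructed = it$reconstructed)
  if (!is.null(it$icvi)) out$icvi <- as.list(it$icvi)
  out$options <- lapply(it$options, option_to_list)
  out
}

#' Serialize an instrument to its JSON config form
#'
#' @param inst An `iflt_instrument`.
#' @param path File path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_instrument <- function(inst, path = NULL) {
  body <- list(
    metadata = inst$metadata,
    goals = lapply(seq_len(nrow(inst$goals)), function(i) as.list(inst$goals[i, ])),
    items = lapply(unname(inst$items), item_to_list))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop("instrument config: missing field '", field, "' in ", where)
  x[[field]]
}

#' Load an instrument from a JSON config
#'
#' The config schema mirrors [write_instrument()]: `metadata`, a `goals`
#' array (`goal_id`, `label`, `domain`, `expert_weight`) and an `items` array
#' (`item_id`, `text`, `format`, `goal_ids`, `reverse_keyed`,
#' `reconstructed`, optional `icvi`, and an `options` array with `label`,
#' `ios`, `ips` and optional `per_goal_ips`). Loading a written instrument
#' returns an object equal to the original.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @param validate Stop when [validate_instrument()] reports violations
#'   (default `TRUE`).
#' @return An `iflt_instrument`.
#' @export
load_instrument <- function(source, validate = TRUE) {
  raw <- if (length(source) == 1L && !grepl("[{\n]", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else source
  cfg <- jsonlite::fromJSON(raw, simplifyVector = FALSE)
  goals_list <- need_field(cfg, "goals", "top level")
  goals <- do.call(rbind, lapply(seq_along(goals_list), function(i) {
    gl <- goals_list[[i]]
    where <- paste0("goals[", i, "]")
    data.frame(goal_id = as.character(need_field(gl, "goal_id", where)),
               label = as.character(need_field(gl, "label", where)),
               domain = as.character(need_field(gl, "domain", where)),
               expert_weight = as.numeric(need_field(gl, "expert_weight", where)),
               stringsAsFactors = FALSE)
  }))
  items_list <- need_field(cfg, "items", "top level")
  items <- lapply(seq_along(items_list), function(i) {
    il <- items_list[[i]]
    where <- paste0("items[", i, "]")
    opts <- lapply(need_field(il, "options", where), function(ol) {
      pg <- ol$per_goal_ips
      if (!is.null(pg))
        pg <- stats::setNames(vapply(pg, as.numeric, numeric(1)), names(pg))
      answer_option(need_field(ol, "label", where),
                    ios = need_field(ol, "ios", where),
                    ips = need_field(ol, "ips", where),
                    per_goal_ips = pg)
    })
    screener_item(need_field(il, "item_id", where),
                  need_field(il, "text", where),
                  need_field(il, "format", where),
                  vapply(need_field(il, "goal_ids", where), as.character, character(1)),
                  opts,
                  reverse_keyed = isTRUE(il$reverse_keyed),
                  reconstructed = isTRUE(il$reconstructed),
                  icvi = il$icvi)
  })
  inst <- new_instrument(goals, items, metadata = cfg$metadata)
  if (validate) {
    v <- validate_instrument(inst)
    if (nrow(v) > 0L)
      stop("instrument config is invalid:\n",
           paste0("  - ", v$field, ": ", v$message, collapse = "\n"))
  }
  inst
}

#' Path of the bundled instrument config file
#' @return Path to the JSON file shipped in `inst/extdata`.
#' @export
bundled_instrument_path <- function()
  system.file("extdata", "iflt_instrument.json", package = "iflt",
              mustWork = TRUE)

#' @export
print.iflt_instrument <- function(x, ...) {
  cat(sprintf("<iflt_instrument> %s (version %s)\n",
              x$metadata$name, x$metadata$version))
  cat(sprintf("  %d goals across domains: %s\n", nrow(x$goals),
              paste(unique(x$goals$domain), collapse = ", ")))
  cat(sprintf("  %d items; max attainable IOS sum %d\n",
              length(x$items), 6L * length(x$items)))
  invisible(x)
}
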