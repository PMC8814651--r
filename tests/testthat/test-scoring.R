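test_that("published option scores are reproduced", {
  q13 <- bundled$items$Q13
  expect_equal(item_ios(q13, "8-10 glasses per day"), 6)
  expect_equal(item_ios(q13, "More than 10 glasses per day"), 5)
  expect_equal(item_ios(q13, "Less than 1 glass per day"), 0)
  q3 <- bundled$items$Q3
  expect_equal(item_ios(q3, "Strongly disagree"), 0)
  expect_equal(item_ios(q3, "Strongly agree"), 6)
  # 0-based index convention resolves to the same options
  expect_equal(item_ios(q3, 0), 0)
  expect_equal(item_ios(q3, 6), 6)
  expect_error(item_ios(q3, "Meh"), "Q3.*Meh")
  expect_error(item_ios(q3, 7), "out of range")
})

test_that("overall score spans 0-100 and rescales the IOS sum", {
  expect_equal(overall_score(bundled, perfect_response(bundled))$score_pct, 100)
  expect_equal(overall_score(bundled, worst_response(bundled))$score_pct, 0)

  sc <- overall_score(bundled, random_response <- response_from_table(
    random_responses(bundled, 1, seed = 5), 1))
  expect_equal(sc$score_pct, 100 * sc$ios_sum / 102)
  expect_equal(sum(sc$per_item_ios), sc$ios_sum)

  # a response with IOS sum 51 scores exactly 50%
  ans <- lapply(bundled$items, function(it) {
    if (it$format == "situation_choice") return(NA_character_)
    iflt:::option_labels(it)[match(3, iflt:::option_ios(it))]
  })
  ans$Q2 <- "At home"                      # IOS 0
  ans$Q16 <- "No particular difficulties"  # IOS 6
  sc51 <- overall_score(bundled, response(ans))
  expect_equal(sc51$ios_sum, 51)
  expect_equal(sc51$score_pct, 50)
})

test_that("score is monotone in any single answer upgrade", {
  tab <- random_responses(bundled, 25, seed = 11)
  set.seed(12)
  for (row in seq_len(nrow(tab))) {
    resp <- response_from_table(tab, row)
    base <- overall_score(bundled, resp)$score_pct
    it <- bundled$items[[sample(names(bundled$items), 1)]]
    ios <- iflt:::option_ios(it)
    cur <- ios[iflt:::resolve_answer(it, resp$answers[[it$item_id]])]
    better <- which(ios > cur)
    if (length(better)) {
      resp$answers[[it$item_id]] <- iflt:::option_labels(it)[sample(rep(better, 2), 1)]
      expect_gte(overall_score(bundled, resp)$score_pct, base)
    }
  }
})

test_that("score is invariant under item order and respects policies", {
  tab <- random_responses(bundled, 1, seed = 21)
  resp <- response_from_table(tab, 1)
  shuffled <- response(resp$answers[sample(names(resp$answers))],
                       respondent_id = "shuffled")
  expect_equal(overall_score(bundled, shuffled)$score_pct,
               overall_score(bundled, resp)$score_pct)

  incomplete <- resp
  incomplete$answers$Q5 <- NULL
  incomplete$answers$Q9 <- NULL
  expect_error(overall_score(bundled, incomplete), "Q5.*Q9|missing item")
  sc <- overall_score(bundled, incomplete, missing = "rescale")
  expect_true(sc$rescaled)
  expect_equal(sc$max_sum, 102 - 12)

  # situation items can be excluded with a rescaled denominator
  resp_sit <- perfect_response(bundled)
  resp_sit$answers$Q2 <- "At home"          # IOS 0 difficulty option
  resp_sit$answers$Q16 <- "Lunch"
  expect_equal(overall_score(bundled, resp_sit)$score_pct, 100 * 90 / 102)
  expect_equal(overall_score(bundled, resp_sit,
                             exclude_situation = TRUE)$score_pct, 100)
})

test_that("cohort scoring matches the single-respondent path", {
  tab <- random_responses(bundled, 20, seed = 31)
  scores <- score_responses(bundled, tab)
  expect_identical(nrow(scores), 20L)
  for (row in c(1L, 7L, 20L)) {
    sc <- overall_score(bundled, response_from_table(tab, row))
    expect_equal(scores$score_pct[row], sc$score_pct)
    expect_equal(unlist(scores[row, names(sc$per_item_ios)]),
                 sc$per_item_ios)
  }
  # label and 0-based index encodings agree
  idx_tab <- tab
  for (it in bundled$items)
    idx_tab[[it$item_id]] <- match(tab[[it$item_id]],
                                   iflt:::option_labels(it)) - 1L
  expect_equal(score_responses(bundled, idx_tab)$score_pct, scores$score_pct)
})

test_that("response tables round-trip through CSV", {
  tab <- random_responses(bundled, 8, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(tab, path)
  back <- read_responses(path)
  expect_equal(score_responses(bundled, back)$score_pct,
               score_responses(bundled, tab)$score_pct)
})
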