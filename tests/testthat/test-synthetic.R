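test_that("generation is deterministic in the seed", {
  a <- simulate_respondents(40, seed = 1, coupling = 0.7)
  b <- simulate_respondents(40, seed = 1, coupling = 0.7)
  expect_identical(a, b)
  c <- simulate_respondents(40, seed = 2, coupling = 0.7)
  expect_false(identical(a$responses, c$responses))

  r1 <- simulate_retest(a, noise_sd = 0.4, seed = 9)
  r2 <- simulate_retest(a, noise_sd = 0.4, seed = 9)
  expect_identical(r1, r2)

  e1 <- simulate_expert_ratings(7, 0.8, seed = 3)
  e2 <- simulate_expert_ratings(7, 0.8, seed = 3)
  expect_identical(e1, e2)
})

test_that("cohort components are aligned and in range", {
  co <- simulate_respondents(60, seed = 4)
  expect_identical(co$responses$respondent_id, co$intakes$respondent_id)
  expect_identical(co$responses$respondent_id, co$externals$respondent_id)
  expect_true(all(co$theta >= 0 & co$theta <= 1))
  for (f in c("meat", "vegetables", "fruit", "water", "ultra_processed",
              "energy"))
    expect_true(all(co$intakes[[f]] >= 0))
  expect_true(all(co$externals$diet_quality >= 0 &
                    co$externals$diet_quality <= 100))
  # simulated respondents always name a difficulty situation
  expect_false(any(co$responses$Q2 == "No particular difficulties"))
  expect_false(any(co$responses$Q16 == "No particular difficulties"))
  expect_error(simulate_respondents(0, seed = 1), "positive integer")
  expect_error(simulate_respondents(5, seed = 1, coupling = 2), "\\[0, 1\\]")
})

test_that("frequency answers are consistent with the simulated intakes", {
  co <- simulate_respondents(150, seed = 5, coupling = 0.5)
  map <- iflt:::.intake_params()
  for (i in seq_len(nrow(map))) {
    it <- bundled$items[[map$item_id[i]]]
    goal <- it$goal_ids
    ips <- vapply(seq_len(150), function(r)
      unname(item_ips(it, co$responses[[it$item_id]][r])[goal]), numeric(1))
    fails <- vapply(seq_len(150), function(r)
      fails_recommendation(goal, co$intakes[r, ]), logical(1))
    # a flagged need (IPS >= 1) always reflects true non-compliance
    expect_true(all(fails[ips >= 1]))
  }
})

test_that("coupling controls the trait-criterion correlation monotonically", {
  rs <- vapply(c(0, 0.5, 1), function(cp) {
    co <- simulate_respondents(400, seed = 6, coupling = cp)
    sc <- score_responses(bundled, co$responses, items = FALSE)
    cor(sc$score_pct, co$externals$diet_quality)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_lt(abs(rs[1]), 0.15)
  expect_gt(rs[3], 0.4)
})

test_that("expert rating panels have the requested relevance", {
  all_rel <- simulate_expert_ratings(7, 1, seed = 7)
  expect_true(all(all_rel >= 3))
  expect_equal(unname(expert_cvi(all_rel)$icvi), rep(1, 17))
  none <- simulate_expert_ratings(7, 0, seed = 8)
  expect_true(all(none <= 2))
  expect_equal(unname(expert_cvi(none)$icvi), rep(0, 17))
  expect_true(all(simulate_expert_ratings(5, 0.5, seed = 9) %in% 1:4))

  # binomial expectation: mean I-CVI over many replicate items ~ 6/7
  big <- simulate_expert_ratings(7, 6 / 7, seed = 10,
                                 item_ids = sprintf("I%04d", 1:1500))
  expect_equal(mean(expert_cvi(big)$icvi), 6 / 7, tolerance = 0.03 / (6 / 7))
  expect_error(simulate_expert_ratings(7, 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("retest with zero noise reproduces wave one exactly", {
  co <- simulate_respondents(50, seed = 11)
  r2 <- simulate_retest(co, noise_sd = 0, seed = 12)
  expect_identical(r2, co$responses)
  tr <- test_retest(score_responses(bundled, co$responses, items = FALSE)$score_pct,
                    score_responses(bundled, r2, items = FALSE)$score_pct)
  expect_equal(tr$pearson_r, 1)
  expect_equal(tr$icc, 1)
  expect_true(tr$reliable)
})

test_that("increasing retest noise lowers the expected coefficient", {
  co <- simulate_respondents(800, seed = 13)
  s1 <- score_responses(bundled, co$responses, items = FALSE)$score_pct
  rs <- vapply(c(0.2, 0.5, 0.9), function(ns) {
    s2 <- score_responses(bundled, simulate_retest(co, noise_sd = ns, seed = 14),
                          items = FALSE)$score_pct
    cor(s1, s2)
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("cohort files round-trip through the delimited formats", {
  co <- simulate_respondents(25, seed = 15)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_responses(paths[["responses"]])
  expect_equal(score_responses(bundled, back)$score_pct,
               score_responses(bundled, co$responses)$score_pct)
  intakes <- read_intakes(paths[["intakes"]])
  expect_equal(intakes$vegetables, co$intakes$vegetables, tolerance = 1e-8)
})
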