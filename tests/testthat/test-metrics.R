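test_that("success index formula reproduces the enumerated series value", {
  expect_equal(success_index_from_series(c(0, 0, 0, 1, 1, 2, 3, 4, 5, 6)),
               22 / 60)
  expect_equal(success_index_from_series(rep(0, 10)), 0)
  # appending a dummy round strictly increases an index below 1
  s <- c(0, 0, 1, 2, 3)
  expect_gt(success_index_from_series(s, 1), success_index_from_series(s, 0))
})

test_that("an all-wrong log scores zero under every flag combination", {
  set.seed(31)
  g <- make_outcome_log(sample(referents(), 40, replace = TRUE),
                        rep(FALSE, 40),
                        is_practice = c(rep(TRUE, 8), rep(FALSE, 32)))
  expect_true(all(established_series(g)$s == 0))
  for (ip in c(TRUE, FALSE)) for (id in c(TRUE, FALSE)) {
    expect_equal(success_index(g, ip, id)$index, 0)
  }
  expect_equal(accuracy(g), 0)
})

test_that("an all-correct balanced log reaches s = 6 after the 24th round", {
  targets <- rep(referents(), times = 4)  # each referent's 4th occurrence
  g <- make_outcome_log(c(targets, rep("banana", 6)),
                        rep(TRUE, 30))
  es <- established_series(g)
  expect_true(all(es$s[1:23] < 6))
  expect_true(all(es$s[24:30] == 6))
})

test_that("established series matches the re-scan oracle on random logs", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(10:120, 1)
    g <- random_outcome_log(n, p_correct = runif(1, 0.1, 0.95))
    expect_identical(established_series(g)$s,
                     oracle_established_series(g$rounds$target,
                                               g$rounds$correct))
  }
})

test_that("practice inclusion changes scope and histories coherently", {
  targets <- c(rep("banana", 4), rep("banana", 2))
  correct <- rep(TRUE, 6)
  g <- make_outcome_log(targets, correct,
                        is_practice = c(rep(TRUE, 4), rep(FALSE, 2)))
  # with practice: banana established from round 4 onwards
  expect_equal(established_series(g, TRUE)$s, c(0, 0, 0, 1, 1, 1))
  # without: only 2 main occurrences, never established
  expect_equal(established_series(g, FALSE)$s, c(0, 0))
})

test_that("dummy round extrapolation uses the mean of the last four rounds", {
  g <- make_outcome_log(rep(referents(), 2), rep(TRUE, 12), won = TRUE,
                        duration_s = c(rep(50, 8), rep(12, 4)))
  # total 448 s; remaining 3152 s at 12 s per round
  expect_equal(dummy_round_count(g), floor((3600 - 448) / 12))
  g2 <- make_outcome_log(rep(referents(), 2), rep(TRUE, 12), won = FALSE)
  expect_equal(dummy_round_count(g2), 0L)
  # floor: 3599 s used, 10 s rounds -> no whole extra round fits
  g3 <- make_outcome_log(rep(referents(), 2), rep(TRUE, 12), won = TRUE,
                         duration_s = c(rep(444.875, 8), rep(10, 4)))
  expect_equal(dummy_round_count(g3), 0L)
})

test_that("stability distances are per-referent successive Euclidean moves", {
  sent <- rbind(c(0, 0), c(0.5, 0.5), c(1, 1), c(0.5, 0.5), c(0, 0))
  g <- make_outcome_log(c("banana", "kiwi", "banana", "kiwi", "banana"),
                        rep(TRUE, 5), sent = sent)
  so <- stability_observations(g)
  banana <- so[so$referent == "banana", ]
  expect_equal(banana$distance, c(sqrt(2), sqrt(2)))
  expect_equal(banana$round_index, c(3L, 5L))
  kiwi <- so[so$referent == "kiwi", ]
  expect_equal(kiwi$distance, 0)
  # identical successive points give zero distance
  g2 <- make_outcome_log(c("banana", "banana"), c(TRUE, TRUE),
                         sent = rbind(c(0.3, 0.3), c(0.3, 0.3)))
  expect_equal(stability_observations(g2)$distance, 0)
  # the first occurrence of each referent yields no observation
  expect_equal(nrow(so), 3)
})

test_that("accuracy counts correct rounds in scope, timeouts as misses", {
  g <- make_outcome_log(rep("banana", 10), c(rep(TRUE, 7), rep(FALSE, 3)),
                        is_practice = c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(accuracy(g, "main_only"), 5 / 8)
  expect_equal(accuracy(g, "all"), 7 / 10)
  # a timeout (no guess) is incorrect by construction
  g$rounds$guess[10] <- NA
  expect_equal(accuracy(g, "all"), 7 / 10)
})

test_that("set-size proportions are a distribution per condition", {
  set.seed(12)
  logs <- list(random_outcome_log(50, 0.8, condition = "high",
                                  dyad_id = "h1"),
               random_outcome_log(50, 0.2, condition = "low",
                                  dyad_id = "l1"),
               make_outcome_log(sample(referents(), 30, TRUE),
                                rep(FALSE, 30), condition = "low",
                                dyad_id = "l2"))
  pr <- signal_set_proportions(logs)
  for (cond in c("high", "low")) {
    expect_equal(sum(pr$prop[pr$condition == cond]), 1)
  }
  all_wrong <- signal_set_proportions(logs[3])
  expect_equal(all_wrong$prop[all_wrong$set_size == 0], 1)
})

test_that("per-dyad summary and round table carry coherent bookkeeping", {
  cohort <- generate_cohort(c(high = 2, low = 2), seed = 5)
  pd <- per_dyad_summary(cohort)
  expect_equal(nrow(pd), 4)
  expect_true(all(pd$success_index >= 0 & pd$success_index < 1))
  expect_true(all(pd$success_index_no_dummy <= 1))
  rt <- round_table(cohort)
  expect_equal(nrow(rt), sum(vapply(cohort, function(g) nrow(g$rounds),
                                    numeric(1))))
  expect_equal(mean(rt$round_z), 0, tolerance = 1e-10)
  expect_identical(rt$presence, as.integer(rt$s > 0))
  # metric pipeline is a pure function of the log
  expect_identical(per_dyad_summary(cohort), pd)
})

test_that("a won game ends with all six established in the main-round scope", {
  g <- run_game(game_config("high"), sender_new(sender_params(sigma_motor = 0)),
                oracle_receiver(), seed = 23)
  expect_true(g$won)
  es <- established_series(g, include_practice = FALSE)
  expect_equal(es$s[nrow(es)], 6L)
})
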