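test_that("first-attempt scores rank foods by attempt time", {
  tr <- trial_log(
    list(1, "ATTEMPT", "brinjal"),
    list(2, "ATTEMPT", "bread"),
    list(3, "ATTEMPT", "cauliflower"),
    list(4, "ATTEMPT", "peanuts")
  )
  expect_equal(
    score_attempts(tr),
    c(bread = 4L, brinjal = 5L, cauliflower = 3L, peanuts = 2L)
  )

  only_bread <- trial_log(list(1, "ATTEMPT", "bread"))
  expect_equal(
    score_attempts(only_bread),
    c(bread = 5L, brinjal = 1L, cauliflower = 1L, peanuts = 1L)
  )

  expect_equal(unname(score_attempts(empty_trial())), rep(1L, 4))
})

test_that("first-choice scores rank foods by eating order", {
  tr <- trial_log(
    list(1, "ATTEMPT", "bread"),
    list(2, "ATTEMPT", "brinjal"),
    list(3, "CHOICE", "bread"),
    list(4, "CHOICE", "brinjal")
  )
  expect_equal(
    score_choices(tr),
    c(bread = 5L, brinjal = 4L, cauliflower = 1L, peanuts = 1L)
  )

  # all four eaten in attempt order: FC equals FA food by food
  tr4 <- trial_log(
    list(1, "ATTEMPT", "peanuts"), list(2, "CHOICE", "peanuts"),
    list(3, "ATTEMPT", "bread"), list(4, "CHOICE", "bread"),
    list(5, "ATTEMPT", "brinjal"), list(6, "CHOICE", "brinjal"),
    list(7, "ATTEMPT", "cauliflower"), list(8, "CHOICE", "cauliflower")
  )
  expect_equal(score_choices(tr4), score_attempts(tr4))

  expect_error(
    score_choices(trial_log(list(5, "CHOICE", "bread"))),
    "without a prior ATTEMPT"
  )
})

test_that("rejection scores count capped rejections and flag never-eaten", {
  tr <- trial_log(
    list(1, "ATTEMPT", "bread"), list(2, "CHOICE", "bread"),
    list(3, "ATTEMPT", "cauliflower"), list(4, "CHOICE", "cauliflower")
  )
  expect_equal(unname(score_rejections(tr)), rep(0L, 4))

  rej3 <- trial_log(
    list(1, "ATTEMPT", "cauliflower"),
    list(2, "REJECT", "cauliflower"),
    list(3, "REJECT", "cauliflower"),
    list(4, "REJECT", "cauliflower"),
    list(5, "CHOICE", "cauliflower")
  )
  expect_equal(score_rejections(rej3)[["cauliflower"]], 3L)

  # 11 rejections cap at 8
  specs <- c(
    list(list(1, "ATTEMPT", "peanuts")),
    lapply(1:11, function(i) list(1 + i, "REJECT", "peanuts")),
    list(list(20, "CHOICE", "peanuts"))
  )
  expect_equal(do.call(trial_log, specs) |> score_rejections() |>
                 getElement("peanuts"), 8L)

  # rejected at first attempt and never eaten: cap value 8
  ab <- trial_log(
    list(1, "ATTEMPT", "brinjal"),
    list(2, "REJECT", "brinjal")
  )
  expect_equal(score_rejections(ab)[["brinjal"]], 8L)
})

test_that("aggression scores are saturating indicators", {
  one <- trial_log(
    list(1, "ATTEMPT", "bread"),
    list(2, "CHOICE", "bread"),
    list(2, "AGGRESSION", "bread")
  )
  expect_equal(
    score_aggression(one),
    c(bread = 1L, brinjal = 0L, cauliflower = 0L, peanuts = 0L)
  )
  expect_equal(unname(score_aggression(empty_trial())), rep(0L, 4))

  two <- trial_log(
    list(1, "ATTEMPT", "brinjal"),
    list(2, "AGGRESSION", "brinjal"),
    list(3, "AGGRESSION", "brinjal")
  )
  expect_equal(score_aggression(two)[["brinjal"]], 1L)
})

test_that("delay scores anchor at 0 (none), 4 (max) and 5 (never eaten)", {
  instant <- trial_log(
    list(1, "ATTEMPT", "bread"), list(1, "CHOICE", "bread"),
    list(2, "ATTEMPT", "brinjal"), list(2, "CHOICE", "brinjal")
  )
  dl <- score_delay(instant)
  expect_equal(dl$delay_score[dl$food %in% c("bread", "brinjal")], c(0L, 0L))
  expect_equal(dl$delay_s[dl$food == "bread"], 0)

  never <- trial_log(list(3, "ATTEMPT", "bread"))
  expect_equal(score_delay(never)$delay_score[1], 5L)
  expect_true(is.na(score_delay(never)$delay_s[1]))

  # positive delays 10 s and 40 s rank as 3 and 4
  two <- trial_log(
    list(0, "ATTEMPT", "bread"), list(10, "CHOICE", "bread"),
    list(5, "ATTEMPT", "peanuts"), list(45, "CHOICE", "peanuts")
  )
  dl2 <- score_delay(two)
  expect_equal(dl2$delay_score[dl2$food == "bread"], 3L)
  expect_equal(dl2$delay_score[dl2$food == "peanuts"], 4L)
  expect_equal(dl2$delay_s[dl2$food == "peanuts"], 40)

  # unattempted foods: score 0, delay absent
  expect_equal(dl2$delay_score[dl2$food == "brinjal"], 0L)
  expect_true(is.na(dl2$delay_s[dl2$food == "brinjal"]))
})

test_that("score tables have four rows per trial and are pure", {
  ev <- simulate_trials(sim_config(n_trials = 74, seed = 21))
  s <- score_trials(ev)
  expect_equal(nrow(s), 296)
  expect_equal(as.integer(table(s$trial_id)), rep(4L, 74))
  expect_identical(s, score_trials(ev))

  # one empty trial: 4 rows of base scores
  s0 <- score_trial(empty_trial(), trial_id = "E1")
  expect_equal(nrow(s0), 4)
  expect_true(all(s0$fa == 1 & s0$fc == 1 & s0$rj == 0 & s0$ag == 0 &
                    s0$delay_score == 0))

  # duplicate trial ids across list input are rejected
  t1 <- trial_log(list(1, "ATTEMPT", "bread"), trial_id = "D1")
  expect_error(score_trials(list(t1, t1)), "duplicate trial_id")
})

test_that("score invariants hold on simulator output", {
  ev <- simulate_trials(sim_config(n_trials = 500, seed = 33))
  s <- score_trials(ev)
  expect_true(all(s$rj >= 0 & s$rj <= 8))
  expect_true(all(s$ag %in% c(0L, 1L)))
  expect_true(all(s$delay_score %in% 0:5))
  expect_true(all(s$fa[s$fc > 1] > 1))
  # FA over attempted foods is {5, ..., 5-k+1}; same for FC over eaten
  for (tr in split(s, s$trial_id)) {
    ka <- sum(tr$fa > 1)
    expect_equal(sort(tr$fa[tr$fa > 1], decreasing = TRUE),
                 seq_len(ka) * -1L + 6L)
    ke <- sum(tr$fc > 1)
    expect_equal(sort(tr$fc[tr$fc > 1], decreasing = TRUE),
                 seq_len(ke) * -1L + 6L)
    # delay score 5 exactly for approached-but-never-eaten foods
    expect_equal(tr$delay_score == 5, tr$fa > 1 & tr$fc == 1)
  }
  # when the eating sequence follows the attempt sequence (judged from
  # the raw events), the FA and FC orderings of eaten foods agree
  n_checked <- 0L
  for (tr_ev in split(ev, ev$trial_id)) {
    att <- tr_ev$food[tr_ev$event == "ATTEMPT"]
    att <- att[!duplicated(att)]
    ch <- tr_ev$food[tr_ev$event == "CHOICE"]
    if (length(ch) >= 2 && identical(ch, att[seq_along(ch)])) {
      tr <- s[s$trial_id == tr_ev$trial_id[[1]], ]
      expect_identical(tr$food[order(-tr$fa)][seq_along(ch)], ch)
      expect_identical(tr$food[order(-tr$fc)][seq_along(ch)], ch)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10)  # the pattern actually occurs in the sample
})
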