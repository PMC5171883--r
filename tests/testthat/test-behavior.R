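test_that("a clean all-hit session scores as forced by the definitions", {
  trials <- data.frame(type = rep(c("go", "nogo"), each = 5),
                       latency = c(rep(1.2, 5), rep(NA, 5)))
  log <- manual_log(trials)
  s <- score_gonogo_session(log)
  expect_equal(s$hits, 5L)
  expect_equal(s$false_alarms, 0L)
  expect_equal(s$hit_latency_mean, 1.2)
  expect_true(is.na(s$fa_latency_mean))
  expect_equal(s$correct_rejections, 5L)
  expect_equal(s$reinforcers, 10L)
  expect_equal(s$total_pokes, 5L)
  # reinforcers can exceed pokes, so the raw ratio exceeds 100
  expect_equal(s$efficiency, 200)
})

test_that("a pokeless session earns all correct rejections and an undefined efficiency", {
  trials <- data.frame(type = rep(c("go", "nogo"), 3), latency = NA_real_)
  s <- score_gonogo_session(manual_log(trials))
  expect_equal(s$hits, 0L)
  expect_equal(s$false_alarms, 0L)
  expect_equal(s$reinforcers, 3L)
  expect_equal(s$total_pokes, 0L)
  expect_true(is.na(s$efficiency))
})

test_that("pokes are classified by time-window priority", {
  # precue is 4 s: a poke 1 s before the cue is a precue response, a poke
  # 3.5 s before the cue (outside the 3-s tail) is a cue-side poke, as is
  # any poke during the intertrial interval or at the center recess
  trials <- data.frame(type = c("go", "nogo"), latency = c(2, NA))
  log <- manual_log(trials, extra_pokes = data.frame(
    t = c(3, 0.2, 15, 9),
    detail = c("cue_recess", "cue_recess", "cue_recess", "center_recess")))
  s <- score_gonogo_session(log)
  expect_equal(s$hits, 1L)
  expect_equal(s$precue_responses, 1L)   # t = 3 (cue at 4, tail 1..4)
  expect_equal(s$cue_side_pokes, 2L)     # t = 0.2 and t = 15 (ITI)
  expect_equal(s$total_pokes, 5L)        # center poke counts only here
})

test_that("training criterion needs two consecutive passing days", {
  expect_equal(evaluate_training(data.frame(hits = c(30, 30),
                                            session_minutes = c(35, 38))),
               list(passed = TRUE, day_passed = 2L))
  expect_false(evaluate_training(data.frame(hits = c(30, 30),
                                            session_minutes = c(41, 39)))$passed)
  expect_false(evaluate_training(data.frame(hits = c(30, 12, 30),
                                            session_minutes = c(39, 39, 39)))$passed)
  expect_equal(evaluate_training(data.frame(hits = c(10, 30, 31, 30),
                                            session_minutes = c(39, 39, 39, 39)))$day_passed,
               3L)
})

test_that("uncollected earned rewards exclude an animal", {
  trials <- data.frame(type = rep("go", 3), latency = 1)
  s <- score_gonogo_session(manual_log(trials))
  expect_true(apply_exclusions(list(s, s), c(3, 3))$included)
  bad <- apply_exclusions(list(s, s, s), c(3, 0, 3))
  expect_false(bad$included)
  expect_equal(bad$reason, "uncollected_reward")
  expect_equal(bad$first_violation, 2L)
  expect_error(apply_exclusions(list(s), c(1, 1)),
               class = "linedrift_alignment")
})

test_that("Y-maze scoring counts distinct-arm triplets", {
  s <- score_ymaze(c("A", "B", "C", "A", "B", "C"))
  expect_equal(s$entries, 6L)
  expect_equal(s$alternations, 4L)
  expect_equal(s$percent_alternation, 100)

  s <- score_ymaze(c("A", "B", "A", "B", "A"))
  expect_equal(s$alternations, 0L)
  expect_equal(s$percent_alternation, 0)

  expect_true(is.na(score_ymaze(c("A", "B"))$percent_alternation))
  expect_error(score_ymaze(c("A", "D")), class = "linedrift_domain")
  expect_error(score_ymaze(c("A", "A", "B")), class = "linedrift_domain")

  set.seed(81)
  for (i in 1:50) {
    n <- sample(3:64, 1)
    seq <- character(n)
    seq[1] <- sample(c("A", "B", "C"), 1)
    for (j in 2:n) seq[j] <- sample(setdiff(c("A", "B", "C"), seq[j - 1]), 1)
    s <- score_ymaze(seq)
    expect_equal(s$alternations, naive_alternations(seq))
    expect_gte(s$percent_alternation, 0)
    expect_lte(s$percent_alternation, 100)
    expect_lte(s$alternations, s$entries - 2L)
  }
})

test_that("rotarod days summarize four trials with slip replacement", {
  s <- score_rotarod(c(10, 20, 30, 40))
  expect_equal(s$mean, 25)
  expect_equal(s$max, 40)

  s <- score_rotarod(c(7, 7, 7, 7))
  expect_equal(s$mean, 7)
  expect_equal(s$max, 7)

  s <- score_rotarod(c(1, 20, 30, 40), extra = 25, slip_threshold = 5)
  expect_equal(sort(s$retained), c(20, 25, 30, 40))
  expect_equal(s$mean, 28.75)
  expect_equal(s$n_replaced, 1L)

  # a slip without a replacement is retained
  s <- score_rotarod(c(1, 20, 30, 40))
  expect_equal(s$mean, 22.75)
  expect_equal(s$n_slips, 1L)
  expect_equal(s$n_replaced, 0L)

  expect_error(score_rotarod(c(10, 20, 30)),
               class = "linedrift_insufficient_trials")
})

test_that("rotarod tables score per animal-day", {
  df <- data.frame(animal = rep(c("m1", "m2"), each = 5),
                   day = 1,
                   trial = c(1:4, 5, 1:4, 5),
                   latency = c(1, 20, 30, 40, 25, 10, 20, 30, 40, 99),
                   is_extra = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), 2))
  out <- score_rotarod_table(df)
  expect_equal(out$mean_latency[out$animal == "m1"], 28.75)
  expect_equal(out$mean_latency[out$animal == "m2"], 25)  # no slip: extra unused
})

test_that("event logs round-trip through CSV with metadata", {
  p <- behavior_params(seed = 99)
  log <- simulate_gonogo_session(p, animal_id = "m7", day = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_equal(back$meta, log$meta)
  expect_equal(back$events, log$events, tolerance = 1e-12)
  expect_equal(score_gonogo_session(back), score_gonogo_session(log))
})

test_that("event log construction rejects malformed sessions", {
  expect_error(event_log(data.frame(t = c(1, 0), kind = c("poke", "poke"),
                                    detail = "cue_recess")),
               class = "linedrift_structure")
  expect_error(event_log(data.frame(t = c(0, 1), kind = c("cue_on", "cue_on"),
                                    detail = "go")),
               class = "linedrift_structure")
  expect_error(event_log(data.frame(t = 0, kind = "jump", detail = "")),
               class = "linedrift_structure")
})

test_that("the scorer agrees with the naive event-by-event oracle", {
  set.seed(91)
  for (i in 1:40) {
    p <- behavior_params(p_hit = runif(1), p_fa = runif(1),
                         background_poke_rate = runif(1, 0, 0.2),
                         n_go = 10, n_nogo = 10,
                         seed = sample.int(1e6, 1))
    log <- simulate_gonogo_session(p)
    ours <- score_gonogo_session(log)
    ref <- naive_score_gonogo(log)
    expect_equal(ours[names(ref)], ref)
    # bookkeeping invariants
    expect_equal(ours$hits + ours$misses, ours$n_go)
    expect_equal(ours$false_alarms + ours$correct_rejections, ours$n_nogo)
    if (ours$hits) expect_lte(ours$hit_latency_mean, 5)
  }
})
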