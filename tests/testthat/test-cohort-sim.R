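test_that("curriculum spaces due dates evenly within terms", {
  cur <- make_curriculum(6, 3, 70)
  expect_equal(cur$due_time, c(35, 70, 105, 140, 175, 210))
  expect_equal(cur$term_boundaries, c(70, 140, 210))

  single <- make_curriculum(1, 1, 70)
  expect_equal(single$due_time, 70)

  big <- make_curriculum(376, 3, 70)
  expect_length(big$due_time, 376)
  expect_equal(max(big$due_time), 210)
  expect_true(all(diff(big$due_time) >= 0))
})

test_that("curriculum rejects bad arguments", {
  expect_error(make_curriculum(0, 3, 70), "positive")
  expect_error(make_curriculum(10, 0, 70), "positive")
  expect_error(make_curriculum(10, 3, -5), "positive")
  expect_error(make_curriculum(2, 3, 70), "at least")
})

test_that("archetype_spec validates probabilities and spans", {
  expect_error(archetype_spec("x", skip_prob = 1.2), "\\[0, 1\\]")
  expect_error(archetype_spec("x", offset_sd = -1), ">= 0")
  expect_error(archetype_spec("x", cram_session_span_days = 0), "> 0")
})

test_that("zero-noise early bird completes exactly offset days early", {
  cur <- make_curriculum(12, 3, 70)
  spec <- archetype_spec("early_bird", offset_days = -10, offset_sd = 0,
                         jitter_sd = 0)
  ct <- simulate_cohort(cur, list(list(spec = spec, count = 1)), seed = 1)
  expect_equal(ct$events$completion_time_days, cur$due_time - 10)
  expect_true(all(diff(ct$events$completion_time_days) > 0))
})

test_that("skip_prob = 1 yields a learner with zero rows", {
  cur <- make_curriculum(10, 2, 70)
  spec <- archetype_spec("ghost", skip_prob = 1)
  ct <- simulate_cohort(cur, list(list(spec = spec, count = 1)), seed = 1)
  expect_equal(nrow(ct$events), 0L)
  expect_named(ct$labels, "L001")
})

test_that("identical seeds give byte-identical cohorts, different seeds differ", {
  cur <- make_curriculum(40, 2, 70)
  counts <- c(early_bird = 3, crammer = 3, sporadic = 2)
  a <- simulate_cohort(cur, counts, seed = 42)
  b <- simulate_cohort(cur, counts, seed = 42)
  c <- simulate_cohort(cur, counts, seed = 43)
  expect_identical(a$events, b$events)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$events, c$events))
})

test_that("appending learners does not perturb earlier substreams", {
  cur <- make_curriculum(30, 3, 70)
  defs <- default_archetypes()
  small <- simulate_cohort(cur, list(list(spec = defs$on_time, count = 4)),
                           seed = 9)
  big <- simulate_cohort(cur, list(list(spec = defs$on_time, count = 4),
                                   list(spec = defs$crammer, count = 3)),
                         seed = 9)
  first4 <- big$events[big$events$learner_id %in% sprintf("L%03d", 1:4), ]
  rownames(first4) <- NULL
  expect_identical(small$events, first4)
})

test_that("per-archetype mean completion offsets rank early < on_time < crammer", {
  cur <- make_curriculum(90, 3, 70)
  ct <- simulate_cohort(cur, c(early_bird = 20, on_time = 20,
                               crammer = 20, low_engager = 20), seed = 7)
  per_learner <- aggregate(completion_time_days ~ learner_id, ct$events, mean)
  per_learner$arch <- ct$labels[per_learner$learner_id]
  mu <- tapply(per_learner$completion_time_days, per_learner$arch, mean)
  expect_lt(mu[["early_bird"]], mu[["on_time"]])
  expect_lt(mu[["on_time"]], mu[["crammer"]])
})

test_that("crammer trajectories contain the promised massed runs", {
  cur <- make_curriculum(90, 3, 70)
  spec <- default_archetypes()$crammer
  ct <- simulate_cohort(cur, list(list(spec = spec, count = 5)), seed = 3)
  for (lid in unique(ct$events$learner_id)) {
    times <- ct$events$completion_time_days[ct$events$learner_id == lid]
    runs <- rle(times)$lengths
    expect_gte(sum(runs >= 3), spec$cram_session_rate * cur$n_terms)
  }
})

test_that("monotone trajectories for noiseless archetypes; times nonnegative", {
  cur <- make_curriculum(50, 2, 70)
  spec <- archetype_spec("steady", offset_days = 2, offset_sd = 0,
                         jitter_sd = 0)
  ct <- simulate_cohort(cur, list(list(spec = spec, count = 3)), seed = 5)
  for (lid in unique(ct$events$learner_id)) {
    times <- ct$events$completion_time_days[ct$events$learner_id == lid]
    expect_true(all(diff(times) > 0))
  }
  noisy <- simulate_cohort(cur, c(sporadic = 5), seed = 5)
  expect_true(all(noisy$events$completion_time_days >= 0))
})

test_that("empty or malformed spec lists are rejected", {
  cur <- make_curriculum(10, 2, 70)
  expect_error(simulate_cohort(cur, list(), seed = 1), "at least one")
  expect_error(simulate_cohort(cur, list(list(spec = 1, count = 2)), seed = 1),
               "archetype_spec")
  expect_error(simulate_cohort(cur, c(nonexistent = 3), seed = 1), "unknown")
})

test_that("score_against_truth: identity, constant partition, null", {
  labels <- setNames(rep(c("a", "b", "c", "d"), each = 5),
                     sprintf("L%03d", 1:20))
  ident <- setNames(as.integer(factor(labels)), names(labels))
  s <- score_against_truth(ident, labels)
  expect_equal(s$ari, 1)
  expect_equal(s$vi, 0)

  onecluster <- setNames(rep(1L, 20), names(labels))
  expect_equal(score_against_truth(onecluster, labels)$ari, 0)

  # Monte-Carlo null: random label permutations have ARI ~ 0
  labels80 <- setNames(rep(letters[1:4], each = 20), sprintf("L%03d", 1:80))
  set.seed(1)
  aris <- replicate(100, {
    perm <- setNames(sample(as.integer(factor(labels80))), names(labels80))
    score_against_truth(perm, labels80)$ari
  })
  expect_lt(abs(mean(aris)), 0.1)

  bad <- setNames(rep(1L, 3), c("X1", "X2", "X3"))
  expect_error(score_against_truth(bad, labels), "different learner sets")
})

test_that("sample_grades respects the archetype map and bounds", {
  labels <- setNames(rep(c("early_bird", "crammer"), each = 50),
                     sprintf("L%03d", 1:100))
  g <- sample_grades(labels, seed = 2)
  expect_true(all(g$grade >= 0 & g$grade <= 100))
  mu <- tapply(g$grade, labels[g$learner_id], mean)
  expect_gt(mu[["early_bird"]], mu[["crammer"]])
  expect_error(sample_grades(setNames("zzz", "L1")), "no grade distribution")
})
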