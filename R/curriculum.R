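#' Build a fixed course curriculum
#'
#' Constructs the planned structure of an online course: `n_tasks` tasks
#' assigned evenly to `n_terms` consecutive terms, with due dates evenly
#' spaced within each term. This emulates a lock-step degree programme in
#' which the academic year is split into consecutive terms (e.g. three
#' 10-week terms) and learners are expected to progress through tasks in
#' curriculum order.
#'
#' When `n_tasks` is not a multiple of `n_terms`, the remainder tasks are
#' assigned to the earliest terms.
#'
#' @param n_tasks Total number of tasks (positive integer).
#' @param n_terms Number of consecutive terms (positive integer,
#'   `<= n_tasks`).
#' @param term_length_days Length of each term in days (positive real).
#' @return An object of class `curriculum`: a list with `n_tasks`,
#'   `due_time` (non-decreasing vector of planned completion days, one per
#'   task), `term_boundaries` (day offsets at which terms end) and
#'   `course_length_days`.
#' @examples
#' cur <- make_curriculum(n_tasks = 6, n_terms = 3, term_length_days = 70)
#' cur$due_time  # 35 70 105 140 175 210
#' @export
make_curriculum <- function(n_tasks, n_terms = 3L, term_length_days = 70) {
  if (length(n_tasks) != 1L || !is.finite(n_tasks) || n_tasks < 1 ||
      n_tasks != round(n_tasks))
    stop("`n_tasks` must be a single positive integer")
  if (length(n_terms) != 1L || !is.finite(n_terms) || n_terms < 1 ||
      n_terms != round(n_terms))
    stop("`n_terms` must be a single positive integer")
  if (length(term_length_days) != 1L || !is.finite(term_length_days) ||
      term_length_days <= 0)
    stop("`term_length_days` must be a single positive number")
  if (n_tasks < n_terms)
    stop("`n_tasks` must be at least `n_terms`")
  n_tasks <- as.integer(n_tasks)
  n_terms <- as.integer(n_terms)

  per_term <- rep(n_tasks %/% n_terms, n_terms)
  rem <- n_tasks %% n_terms
  if (rem > 0) per_term[seq_len(rem)] <- per_term[seq_len(rem)] + 1L

  due <- numeric(0)
  term_of <- integer(0)
  for (k in seq_len(n_terms)) {
    start <- (k - 1) * term_length_days
    nk <- per_term[k]
    due <- c(due, start + seq_len(nk) * (term_length_days / nk))
    term_of <- c(term_of, rep(k, nk))
  }

  structure(list(
    n_tasks = n_tasks,
    n_terms = n_terms,
    due_time = due,
    term_of_task = term_of,
    term_boundaries = seq_len(n_terms) * term_length_days,
    course_length_days = n_terms * term_length_days
  ), class = "curriculum")
}

#' @export
print.curriculum <- function(x, ...) {
  cat(sprintf("Curriculum: %d tasks over %d terms (%g days total)\n",
              x$n_tasks, x$n_terms, x$course_length_days))
  invisible(x)
}

#' Specify a behavioural archetype for the cohort simulator
#'
#' An archetype is a parametric description of one qualitative engagement
#' behaviour observed in online cohorts: systematically early or late
#' completion, task skipping, massed "cram" sessions near deadlines, and
#' sporadic out-of-order completion.
#'
#' @param name Archetype label, one of `"early_bird"`, `"on_time"`,
#'   `"low_engager"`, `"crammer"`, `"sporadic"`, or any custom string.
#' @param offset_days Systematic completion offset relative to due dates in
#'   days; negative = early.
#' @param offset_sd Standard deviation (days) of the learner's
#'   slowly-varying schedule deviation: a smooth Gaussian wander with
#'   roughly two-week correlation time (busy and free weeks), so that
#'   completion order stays near the curriculum order, as observed for
#'   non-sporadic learners.
#' @param jitter_sd Standard deviation (days) of small independent
#'   per-task timing jitter (within-day/overnight variation).
#' @param skip_prob Probability that any given task is never completed.
#' @param skip_prob_late Additional skip probability applied to tasks due
#'   after `late_onset_day` (disengagement late in the course).
#' @param late_onset_day Day after which `skip_prob_late` and
#'   `late_offset_days` apply.
#' @param late_offset_days Additional completion delay (days) for tasks
#'   due after `late_onset_day`: progressive loss of anticipation late in
#'   the course.
#' @param cram_session_rate Number of massed completion sessions per term;
#'   `0` disables cramming.
#' @param cram_session_span_days Jitter span (days) for placing a cram
#'   session relative to the latest due date it absorbs.
#' @param shuffle_prob Probability that a task takes part in out-of-order
#'   completion (local swaps or global permutation, see `shuffle_mode`).
#' @param shuffle_mode `"local"` (adjacent swaps) or `"global"` (a random
#'   subset of tasks has its completion times permuted freely).
#' @return An object of class `archetype_spec`.
#' @seealso [default_archetypes()] for the built-in parameterisations.
#' @export
archetype_spec <- function(name,
                           offset_days = 0,
                           offset_sd = 2,
                           jitter_sd = 0.25,
                           skip_prob = 0,
                           skip_prob_late = 0,
                           late_onset_day = 140,
                           late_offset_days = 0,
                           cram_session_rate = 0,
                           cram_session_span_days = 2,
                           shuffle_prob = 0,
                           shuffle_mode = c("local", "global")) {
  shuffle_mode <- match.arg(shuffle_mode)
  stopifnot(is.character(name), length(name) == 1L)
  for (p in list(skip_prob, skip_prob_late, shuffle_prob))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]")
  if (!is.finite(offset_sd) || offset_sd < 0)
    stop("`offset_sd` must be >= 0")
  if (!is.finite(jitter_sd) || jitter_sd < 0)
    stop("`jitter_sd` must be >= 0")
  if (!is.finite(cram_session_rate) || cram_session_rate < 0)
    stop("`cram_session_rate` must be >= 0")
  if (!is.finite(cram_session_span_days) || cram_session_span_days <= 0)
    stop("`cram_session_span_days` must be > 0")
  structure(list(
    name = name, offset_days = offset_days, offset_sd = offset_sd,
    jitter_sd = jitter_sd,
    skip_prob = skip_prob, skip_prob_late = skip_prob_late,
    late_onset_day = late_onset_day, late_offset_days = late_offset_days,
    cram_session_rate = cram_session_rate,
    cram_session_span_days = cram_session_span_days,
    shuffle_prob = shuffle_prob, shuffle_mode = shuffle_mode
  ), class = "archetype_spec")
}

#' Built-in behavioural archetypes
#'
#' The five default archetypes reproduce, qualitatively, behaviours
#' reported for online degree cohorts: "early birds" completing tasks with
#' a systematic 1-2 week advance, "on time" learners tracking due dates,
#' "low engagers" who lose anticipation in the later terms (completing
#' late) and skip many tasks,
#' "crammers" exhibiting massed completion plateaux and reduced completion,
#' and "sporadic" learners with noisy, out-of-order trajectories.
#'
#' @return Named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    early_bird = archetype_spec("early_bird", offset_days = -10,
                                offset_sd = 2),
    on_time = archetype_spec("on_time", offset_days = 0, offset_sd = 2),
    low_engager = archetype_spec("low_engager", offset_days = 2,
                                 offset_sd = 2, skip_prob = 0.05,
                                 skip_prob_late = 0.3,
                                 late_onset_day = 140,
                                 late_offset_days = 10),
    crammer = archetype_spec("crammer", offset_days = 3, offset_sd = 2,
                             skip_prob = 0.3, cram_session_rate = 2,
                             cram_session_span_days = 2),
    sporadic = archetype_spec("sporadic", offset_days = 5, offset_sd = 8,
                              jitter_sd = 3, skip_prob = 0.15,
                              shuffle_prob = 0.5)
  )
}
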