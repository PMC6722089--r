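#' Simulate a synthetic cohort of learners with planted archetypes
#'
#' Generates a long-format event table (one row per completed task) for a
#' cohort in which each learner follows one behavioural archetype. For
#' every learner, completion time = due time + systematic offset + Gaussian
#' noise; tasks may then be absorbed into massed cram sessions (all tasks
#' of a session share one session day), skipped (row absent), or shuffled
#' out of curriculum order. Ground-truth archetype labels are returned for
#' evaluation.
#'
#' Randomness is hierarchical: one substream per learner is derived
#' deterministically from the master `seed` and the learner's position, so
#' appending further learners to `specs` does not perturb the trajectories
#' of earlier ones. Identical `(curriculum, specs, seed)` triples produce
#' identical tables.
#'
#' @param curriculum A [make_curriculum()] object.
#' @param specs Either a list of `list(spec = archetype_spec, count = n)`
#'   entries, or a named integer vector of counts drawing on
#'   [default_archetypes()] (e.g. `c(early_bird = 20, crammer = 20)`).
#' @param seed Master integer seed fixing all randomness.
#' @return An object of class `cohort_table`: list with `events` (data.frame
#'   `learner_id`, `task_index`, `completion_time_days`), `labels` (named
#'   character vector learner_id -> archetype name), and `curriculum`.
#' @examples
#' cur <- make_curriculum(60, 3, 70)
#' ct <- simulate_cohort(cur, c(early_bird = 5, crammer = 5), seed = 1)
#' head(ct$events)
#' @export
simulate_cohort <- function(curriculum, specs, seed) {
  if (!inherits(curriculum, "curriculum"))
    stop("`curriculum` must be a curriculum object")
  specs <- normalise_specs(specs)
  if (length(specs) == 0L) stop("`specs` must contain at least one archetype")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer")
  seed <- as.integer(seed)

  rows <- vector("list", sum(vapply(specs, function(s) s$count, 1L)))
  labels <- character(0)
  idx <- 0L
  for (s in specs) {
    for (r in seq_len(s$count)) {
      idx <- idx + 1L
      lid <- sprintf("L%03d", idx)
      tab <- simulate_learner(curriculum, s$spec, learner_seed(seed, idx))
      if (nrow(tab) > 0L) tab$learner_id <- lid
      rows[[idx]] <- tab
      labels[lid] <- s$spec$name
    }
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  events <- events[, c("learner_id", "task_index", "completion_time_days")]
  structure(list(events = events, labels = labels, curriculum = curriculum),
            class = "cohort_table")
}

normalise_specs <- function(specs) {
  if (is.numeric(specs) && !is.null(names(specs))) {
    defs <- default_archetypes()
    unknown <- setdiff(names(specs), names(defs))
    if (length(unknown))
      stop("unknown archetype name(s): ", paste(unknown, collapse = ", "))
    specs <- lapply(names(specs), function(nm)
      list(spec = defs[[nm]], count = specs[[nm]]))
  }
  for (s in specs) {
    if (!inherits(s$spec, "archetype_spec"))
      stop("each spec entry needs an `archetype_spec`")
    if (!is.finite(s$count) || s$count < 1 || s$count != round(s$count))
      stop("archetype counts must be positive integers")
  }
  lapply(specs, function(s) list(spec = s$spec, count = as.integer(s$count)))
}

# Slowly-varying schedule deviation: linear interpolation of independent
# Gaussian knots placed every ~two weeks of planned time. Its slope is far
# below the task spacing, so completion order stays near curriculum order.
schedule_wander <- function(due, sd, knot_days = 14) {
  if (sd <= 0) return(rep(0, length(due)))
  knots <- seq(min(due) - knot_days, max(due) + knot_days, by = knot_days)
  vals <- stats::rnorm(length(knots), 0, sd)
  stats::approx(knots, vals, xout = due)$y
}

# Deterministic per-learner substream seed (kept < 2^31).
learner_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 48271 + idx * 16807) %% 2147483647)
}

simulate_learner <- function(curriculum, spec, lseed) {
  set.seed(lseed)
  due <- curriculum$due_time
  n <- curriculum$n_tasks
  times <- due + spec$offset_days + schedule_wander(due, spec$offset_sd) +
    if (spec$jitter_sd > 0) stats::rnorm(n, 0, spec$jitter_sd) else 0
  if (spec$late_offset_days != 0)
    times[due > spec$late_onset_day] <-
      times[due > spec$late_onset_day] + spec$late_offset_days

  # massed cram sessions: contiguous groups of a term's tasks collapse to
  # one shared session day near the group's latest due date
  if (spec$cram_session_rate > 0) {
    s_per_term <- max(1L, as.integer(round(spec$cram_session_rate)))
    for (k in seq_len(curriculum$n_terms)) {
      in_term <- which(curriculum$term_of_task == k)
      if (length(in_term) == 0L) next
      grp <- ceiling(seq_along(in_term) / (length(in_term) / s_per_term))
      grp <- pmin(grp, s_per_term)
      for (g in unique(grp)) {
        members <- in_term[grp == g]
        day <- max(due[members]) + spec$offset_days +
          stats::runif(1, -spec$cram_session_span_days / 2,
                       spec$cram_session_span_days / 2)
        times[members] <- day
      }
    }
  }

  # skipped tasks are absent rows
  p_skip <- rep(spec$skip_prob, n)
  late <- due > spec$late_onset_day
  p_skip[late] <- 1 - (1 - p_skip[late]) * (1 - spec$skip_prob_late)
  keep <- stats::runif(n) >= p_skip

  # out-of-order completion: permute completion times across task indices
  if (spec$shuffle_prob > 0) {
    if (spec$shuffle_mode == "local") {
      for (i in seq_len(n - 1L)) {
        if (stats::runif(1) < spec$shuffle_prob) {
          tmp <- times[i]
          times[i] <- times[i + 1L]
          times[i + 1L] <- tmp
        }
      }
    } else {
      sub <- which(stats::runif(n) < spec$shuffle_prob)
      if (length(sub) > 1L) times[sub] <- times[sample(sub)]
    }
  }

  times <- pmax(times, 0)
  kept <- which(keep)
  data.frame(learner_id = rep(NA_character_, length(kept)),
             task_index = kept,
             completion_time_days = times[kept],
             stringsAsFactors = FALSE)
}

#' Sample synthetic grades for a simulated cohort
#'
#' Grades are not modelled mechanistically: each archetype maps to a
#' Gaussian grade distribution (truncated to 0-100), which is sufficient to
#' exercise enrichment and classification analyses on synthetic cohorts.
#' The default map places crammers lowest and the distributed-learning
#' archetypes highest.
#'
#' @param labels Named character vector (learner_id -> archetype), e.g.
#'   `cohort$labels`.
#' @param grade_map Named list archetype -> `c(mean, sd)`.
#' @param seed Integer seed.
#' @return data.frame with `learner_id` and `grade` (0-100).
#' @export
sample_grades <- function(labels,
                          grade_map = list(
                            early_bird = c(72, 8), on_time = c(68, 8),
                            low_engager = c(62, 9), crammer = c(54, 9),
                            sporadic = c(62, 10)),
                          seed = 1L) {
  missing_map <- setdiff(unique(labels), names(grade_map))
  if (length(missing_map))
    stop("no grade distribution for archetype(s): ",
         paste(missing_map, collapse = ", "))
  set.seed(as.integer(seed))
  g <- vapply(labels, function(a) {
    pars <- grade_map[[a]]
    min(100, max(0, stats::rnorm(1, pars[1], pars[2])))
  }, 0)
  data.frame(learner_id = names(labels), grade = unname(g),
             stringsAsFactors = FALSE)
}

#' Score a computed partition against planted ground-truth labels
#'
#' @param partition Named vector of community assignments (names are
#'   learner ids), or a `partition` object from the Markov Stability scan
#'   with names attached.
#' @param labels Named vector of ground-truth labels over the same learners.
#' @return List with `ari` (adjusted Rand index, chance-corrected agreement
#'   in `[-1, 1]`) and `vi` (normalised variation of information in
#'   `[0, 1]`, 0 iff identical up to relabelling).
#' @export
score_against_truth <- function(partition, labels) {
  p <- partition_labels(partition)
  if (is.null(names(p)) || is.null(names(labels)))
    stop("both `partition` and `labels` must be named by learner id")
  if (!setequal(names(p), names(labels)))
    stop("`partition` and `labels` cover different learner sets")
  l <- labels[names(p)]
  list(ari = mclust::adjustedRandIndex(as.vector(p), as.vector(l)),
       vi = variation_of_information(as.integer(factor(p)),
                                     as.integer(factor(l))))
}

#' Convert a cohort table to per-learner event series
#'
#' Each learner becomes the vector of completion days ordered by curriculum
#' task index. Never-completed tasks are dropped by default (DTW aligns the
#' resulting unequal-length vectors natively); alternatively they can be
#' imputed at course end plus a penalty.
#'
#' @param cohort A `cohort_table` or a plain events data.frame with columns
#'   `learner_id`, `task_index`, `completion_time_days`.
#' @param missing `"drop"` (default) or `"impute"`.
#' @param impute_penalty_days Penalty added to course end for imputed tasks.
#' @param n_total_tasks Total task count; defaults to the curriculum's
#'   `n_tasks` (or the max observed task index for plain tables).
#' @return List of `event_series` objects (fields `learner_id`, `times`,
#'   `n_total_tasks`).
#' @export
as_event_series <- function(cohort, missing = c("drop", "impute"),
                            impute_penalty_days = 30,
                            n_total_tasks = NULL) {
  missing <- match.arg(missing)
  if (inherits(cohort, "cohort_table")) {
    events <- cohort$events
    if (is.null(n_total_tasks)) n_total_tasks <- cohort$curriculum$n_tasks
    course_end <- cohort$curriculum$course_length_days
  } else {
    events <- cohort
    course_end <- max(events$completion_time_days)
  }
  req <- c("learner_id", "task_index", "completion_time_days")
  if (!all(req %in% names(events)))
    stop("events table must have columns ", paste(req, collapse = ", "))
  if (is.null(n_total_tasks)) n_total_tasks <- max(events$task_index)

  split_rows <- split(events, events$learner_id)
  lapply(split_rows, function(tab) {
    tab <- tab[order(tab$task_index), ]
    times <- tab$completion_time_days
    if (missing == "impute") {
      full <- rep(course_end + impute_penalty_days, n_total_tasks)
      full[tab$task_index] <- times
      times <- full
    }
    event_series(tab$learner_id[1], times, n_total_tasks)
  })
}

#' Construct an event series for one learner
#'
#' @param learner_id Identifier string.
#' @param times Completion days ordered by curriculum task index.
#' @param n_total_tasks Total number of available tasks (`>= length(times)`).
#' @return `event_series` object.
#' @export
event_series <- function(learner_id, times, n_total_tasks = length(times)) {
  if (!all(is.finite(times))) stop("`times` must be finite")
  if (length(times) > n_total_tasks)
    stop("more completions than available tasks")
  structure(list(learner_id = as.character(learner_id),
                 times = as.numeric(times),
                 n_total_tasks = as.integer(n_total_tasks)),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("EventSeries %s: %d/%d tasks completed\n",
              x$learner_id, length(x$times), x$n_total_tasks))
  invisible(x)
}
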