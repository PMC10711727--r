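# Trial sequencing for the slow event-related session: 4 runs x 18 trials,
# each condition twice per run, variable planning delay and intertrial
# interval so that onset-to-onset spacing spans 23-31 s.

#' Trial timing constants
#'
#' Durations (seconds) used by [generate_trial_sequence()]: the jittered
#' planning delays, the fixed execution window, and the intertrial-interval
#' choices. Onset-to-onset spacing is their sum, so spacing is bounded by
#' `min(planning) + execution + min(iti)` and
#' `max(planning) + execution + max(iti)`.
#'
#' @return List with elements `planning_s` (6, 8, 10, 12), `execution_s` (7)
#'   and `iti_s` (10, 11, 12).
#' @export
trial_timing <- function() {
  list(planning_s = c(6, 8, 10, 12), execution_s = 7, iti_s = c(10, 11, 12))
}

#' Generate a pseudorandom trial sequence for one session
#'
#' Builds a 4-run, 72-trial session (each of the nine conditions exactly
#' twice per run). Condition order is pseudorandomized to minimize trial
#' order effects: by default a seeded greedy first-order counterbalancing
#' picks, at each step, the candidate condition whose transition from the
#' previous condition has been used least so far in the session (ties broken
#' at random), which keeps the condition-to-condition transition counts as
#' even as possible. Planning delays are drawn uniformly from
#' {6, 8, 10, 12} s, execution is fixed at 7 s, and the intertrial interval
#' is drawn uniformly from {10, 11, 12} s, so every onset-to-onset spacing
#' lies in [23, 31] s.
#'
#' @param design A design tibble from [build_design()].
#' @param seed Integer seed; the sequence is reproducible from it.
#' @param method `"counterbalanced"` (default, greedy transition balancing)
#'   or `"shuffle"` (plain within-run permutation).
#' @return Tibble with one row per trial: `run`, `trial_index` (1..72),
#'   `condition_id`, `planning_s`, `execution_s`, `iti_s`, `onset_s`
#'   (session-relative onset assuming back-to-back trials).
#' @export
generate_trial_sequence <- function(design, seed,
                                    method = c("counterbalanced", "shuffle")) {
  validate_design(design)
  method <- match.arg(method)
  timing <- trial_timing()
  n_cond <- nrow(design)
  n_runs <- 4L
  reps_per_run <- 2L
  n_per_run <- n_cond * reps_per_run
  withr::with_seed(seed, {
    order_all <- if (method == "shuffle") {
      unlist(lapply(seq_len(n_runs), function(r) {
        sample(rep(design$condition_id, reps_per_run))
      }))
    } else {
      transitions <- matrix(0L, n_cond, n_cond)
      seq_out <- integer(0)
      for (r in seq_len(n_runs)) {
        remaining <- stats::setNames(rep(reps_per_run, n_cond),
                                     design$condition_id)
        prev <- NA_integer_
        for (t in seq_len(n_per_run)) {
          cand <- as.integer(names(remaining)[remaining > 0])
          if (is.na(prev)) {
            pick <- cand[sample.int(length(cand), 1L)]
          } else {
            cost <- transitions[prev, cand]
            best <- cand[cost == min(cost)]
            pick <- best[sample.int(length(best), 1L)]
            transitions[prev, pick] <- transitions[prev, pick] + 1L
          }
          remaining[as.character(pick)] <- remaining[as.character(pick)] - 1L
          seq_out <- c(seq_out, pick)
          prev <- pick
        }
      }
      seq_out
    }
    planning <- sample(timing$planning_s, n_runs * n_per_run, replace = TRUE)
    iti <- sample(timing$iti_s, n_runs * n_per_run, replace = TRUE)
    out <- tibble::tibble(
      run = rep(seq_len(n_runs), each = n_per_run),
      trial_index = seq_len(n_runs * n_per_run),
      condition_id = order_all,
      planning_s = planning,
      execution_s = timing$execution_s,
      iti_s = iti
    )
    spacing <- out$planning_s + out$execution_s + out$iti_s
    out$onset_s <- cumsum(c(0, spacing[-length(spacing)]))
    out
  })
}
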