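# Model-free win-/loss-driven choice statistic.
#
# On a both-outcome trial the win and the loss co-locate over one
# stimulus, so choosing it (or avoiding it) nets zero pence and carries no
# objective guidance. The next choice therefore reveals which outcome the
# participant treats as more informative: moving toward the stimulus that
# carried both outcomes is win-driven, moving away is loss-driven.

#' Classify the follow-up choice after one trial
#'
#' A trial is eligible only if it is a both-outcome trial (win and loss on
#' the same stimulus) with a successor in the same block. The follow-up is
#' win-driven if the participant chose the both-outcome stimulus and
#' repeats that choice, or chose the other stimulus and switches (both
#' moves select the stimulus that carried the win); the complementary
#' follow-ups are loss-driven.
#'
#' @param trial_i,trial_i1 Single-row trial records; `trial_i1` must
#'   immediately follow `trial_i` within the same block.
#' @return `"win_driven"`, `"loss_driven"` or `"not_applicable"`.
#' @export
classify_followup <- function(trial_i, trial_i1) {
  same_block <- TRUE
  for (col in c("participant_id", "session_index", "block_index")) {
    if (col %in% names(trial_i) && col %in% names(trial_i1)) {
      same_block <- same_block && trial_i[[col]] == trial_i1[[col]]
    }
  }
  if (!same_block || trial_i1$trial != trial_i$trial + 1) {
    abort_param("trials must be consecutive within one block.")
  }
  if (trial_i$win_on_A != trial_i$loss_on_A) {
    return("not_applicable")
  }
  both_stim <- if (trial_i$win_on_A == 1) "A" else "B"
  chose_both <- trial_i$choice == both_stim
  stayed <- trial_i1$choice == trial_i$choice
  if (chose_both == stayed) "win_driven" else "loss_driven"
}

# Vectorized classification over one block's ordered trials: adds a
# `followup` column ("win_driven"/"loss_driven"/NA for ineligible).
classify_block_followups <- function(trials) {
  n <- nrow(trials)
  both <- trials$win_on_A == trials$loss_on_A
  has_next <- seq_len(n) < n
  eligible <- both & has_next
  both_stim <- ifelse(trials$win_on_A == 1, "A", "B")
  chose_both <- trials$choice == both_stim
  stayed <- c(trials$choice[-1] == trials$choice[-n], NA)
  followup <- ifelse(
    eligible,
    ifelse(chose_both == stayed, "win_driven", "loss_driven"),
    NA_character_
  )
  dplyr::mutate(trials, followup = followup)
}

#' Win-driven choice proportion for one block
#'
#' The proportion of eligible both-outcome trials whose follow-up choice is
#' win-driven; the loss-driven proportion is its complement. A both-outcome
#' trial in final block position has no successor and is excluded from both
#' numerator and denominator (so `eligible_n` is 40 for constraint-built
#' blocks unless a both-outcome trial falls last).
#'
#' @param trials Ordered trial tibble for one block with `win_on_A`,
#'   `loss_on_A`, `choice`.
#' @return A one-row tibble: `eligible_n`, `win_driven_n`, `p_win_driven`.
#' @export
win_driven_proportion <- function(trials) {
  cls <- classify_block_followups(trials)$followup
  eligible <- sum(!is.na(cls))
  if (eligible == 0) {
    abort_param("no eligible both-outcome trial with a successor; statistic undefined.")
  }
  wins <- sum(cls == "win_driven", na.rm = TRUE)
  tibble::tibble(
    eligible_n = eligible,
    win_driven_n = wins,
    p_win_driven = wins / eligible
  )
}

#' Win-driven proportions for every block of a trial log
#'
#' @param trial_log A trial-log tibble.
#' @return A tibble, one row per participant x session x block, with
#'   `eligible_n`, `win_driven_n`, `p_win_driven` alongside the design
#'   columns.
#' @export
#' @examples
#' log <- simulate_cohort(cohort_spec(n_participants = 2), "negative_training",
#'                        seed = 9)
#' win_driven_table(log)
win_driven_table <- function(trial_log) {
  group_cols <- intersect(
    c("study", "participant_id", "session_index", "tdcs_condition",
      "tdcs_order", "block_index", "block_type"),
    names(trial_log)
  )
  trial_log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(d, key) {
      win_driven_proportion(dplyr::arrange(d, trial))
    }) |>
    dplyr::ungroup()
}
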