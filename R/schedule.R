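# Schedule generation for the Information Bias Learning Task.
#
# A session is 5 blocks of 80 trials. On every trial an independent win and
# loss outcome each appear over one of two stimuli (A/B). The probability
# that an outcome appears over A is either volatile -- alternating between
# 0.2 and 0.8 in runs of 14-30 trials -- or stable at 0.5. Training blocks
# make exactly one valence volatile; both-volatile blocks make both
# volatile with independently drawn run boundaries.

#' Schedule design parameters
#'
#' Bundles the structural constants of the task design. The defaults are the
#' published design: 80-trial blocks, volatile runs of 14-30 trials at
#' outcome-on-A probabilities alternating between 0.2 and 0.8, stable
#' regimes at 0.5, and exactly 40 trials per block on which the win and the
#' loss co-locate over the same stimulus.
#'
#' @param n_trials Trials per block.
#' @param min_run,max_run Bounds on volatile run lengths (inclusive).
#' @param volatile_levels The two alternating outcome-on-A probabilities of
#'   a volatile trajectory.
#' @param stable_level The constant outcome-on-A probability of a stable
#'   trajectory.
#' @param target_both Required number of trials per block on which win and
#'   loss fall on the same stimulus, or `NULL` to leave unconstrained.
#' @param realization `"exact"` realizes each run at its nominal frequency
#'   exactly (positions permuted uniformly); `"bernoulli"` draws each trial
#'   independently.
#' @param max_attempts Rejection-sampling budget for hitting `target_both`.
#' @param design_retries How many times a block's run boundaries may be
#'   redrawn if no realization within `max_attempts` attains `target_both`.
#' @return A list of class `iblt_schedule_config`.
#' @export
#' @examples
#' schedule_config()
schedule_config <- function(n_trials = 80L,
                            min_run = 14L,
                            max_run = 30L,
                            volatile_levels = c(0.2, 0.8),
                            stable_level = 0.5,
                            target_both = 40L,
                            realization = c("exact", "bernoulli"),
                            max_attempts = 10000L,
                            design_retries = 100L) {
  realization <- match.arg(realization)
  if (length(volatile_levels) != 2 || any(volatile_levels <= 0) ||
      any(volatile_levels >= 1)) {
    abort_param("`volatile_levels` must be two probabilities in (0, 1).")
  }
  check_scalar_prob(stable_level, "stable_level")
  if (!is.null(target_both) && (target_both < 0 || target_both > n_trials)) {
    abort_param("`target_both` must lie in [0, n_trials] or be NULL.")
  }
  structure(
    list(
      n_trials = as.integer(n_trials),
      min_run = as.integer(min_run),
      max_run = as.integer(max_run),
      volatile_levels = sort(volatile_levels),
      stable_level = stable_level,
      target_both = if (is.null(target_both)) NULL else as.integer(target_both),
      realization = realization,
      max_attempts = as.integer(max_attempts),
      design_retries = as.integer(design_retries)
    ),
    class = "iblt_schedule_config"
  )
}

block_types <- function() {
  c("both_volatile", "train_loss_volatile", "train_win_volatile")
}

#' Partition a block into volatile run lengths
#'
#' Draws a sequence of run lengths summing to `total_trials` with every
#' length in `[min_run, max_run]`. Each length is sampled uniformly from the
#' values that leave the remainder partitionable (a dynamic feasibility
#' check), so no truncated final run can occur.
#'
#' @param total_trials Number of trials to partition.
#' @param min_run,max_run Inclusive bounds on each run length.
#' @return Integer vector of run lengths summing to `total_trials`.
#' @export
#' @examples
#' set.seed(1)
#' draw_run_lengths(80, 14, 30)
draw_run_lengths <- function(total_trials, min_run = 14L, max_run = 30L) {
  if (min_run <= 0 || max_run <= 0 || min_run > max_run) {
    abort_param("run bounds must satisfy 0 < min_run <= max_run.")
  }
  if (total_trials < min_run) {
    abort_param("`total_trials` must be at least `min_run`.")
  }
  # r trials are partitionable iff some k >= 1 has k*min <= r <= k*max
  feasible <- function(r) {
    r == 0 || ceiling(r / max_run) <= floor(r / min_run)
  }
  if (!feasible(total_trials)) {
    abort_param(sprintf(
      "%d trials cannot be partitioned into runs of %d-%d trials.",
      total_trials, min_run, max_run
    ))
  }
  lengths <- integer(0)
  remaining <- total_trials
  while (remaining > 0) {
    candidates <- seq.int(min_run, min(max_run, remaining))
    candidates <- candidates[vapply(remaining - candidates, feasible, logical(1))]
    pick <- if (length(candidates) == 1) candidates else sample(candidates, 1L)
    lengths <- c(lengths, pick)
    remaining <- remaining - pick
  }
  lengths
}

is_volatile <- function(block_type, outcome_valence) {
  switch(block_type,
    both_volatile = TRUE,
    train_loss_volatile = identical(outcome_valence, "loss"),
    train_win_volatile = identical(outcome_valence, "win"),
    abort_param(sprintf("unknown block type '%s'.", block_type))
  )
}

#' Build the probability trajectory of one outcome channel
#'
#' Returns the planned per-trial outcome-on-A probabilities for one valence
#' in one block: a single stable run at the stable level, or volatile runs
#' (lengths from [draw_run_lengths()]) whose probability alternates between
#' the two volatile levels, starting level chosen uniformly at random.
#' Realized outcome locations are left unset; see [realize_outcomes()].
#'
#' @param block_type One of `"both_volatile"`, `"train_loss_volatile"`,
#'   `"train_win_volatile"`.
#' @param outcome_valence `"win"` or `"loss"`.
#' @param config An [schedule_config()] list.
#' @return A list of class `iblt_trajectory` with elements `valence`,
#'   `volatile`, `runs` (tibble of `length`, `p_on_A`), `p_seq`, and
#'   `realized_on_A` (`NULL` until realized).
#' @export
#' @examples
#' set.seed(1)
#' make_trajectory("train_loss_volatile", "loss")$runs
make_trajectory <- function(block_type, outcome_valence,
                            config = schedule_config()) {
  if (!outcome_valence %in% c("win", "loss")) {
    abort_param("`outcome_valence` must be 'win' or 'loss'.")
  }
  volatile <- is_volatile(block_type, outcome_valence)
  if (volatile) {
    lens <- draw_run_lengths(config$n_trials, config$min_run, config$max_run)
    start_high <- runif(1) < 0.5
    levels <- config$volatile_levels[
      1L + (seq_along(lens) + start_high) %% 2L
    ]
    runs <- tibble::tibble(length = lens, p_on_A = levels)
  } else {
    runs <- tibble::tibble(length = config$n_trials, p_on_A = config$stable_level)
  }
  structure(
    list(
      valence = outcome_valence,
      volatile = volatile,
      runs = runs,
      p_seq = rep(runs$p_on_A, runs$length),
      realized_on_A = NULL
    ),
    class = "iblt_trajectory"
  )
}

#' @export
print.iblt_trajectory <- function(x, ...) {
  cat(sprintf(
    "<iblt_trajectory> %s, %s, %d trials, %d run(s)%s\n",
    x$valence, if (x$volatile) "volatile" else "stable",
    length(x$p_seq), nrow(x$runs),
    if (is.null(x$realized_on_A)) " (unrealized)" else ""
  ))
  print(x$runs, ...)
  invisible(x)
}

# Closure drawing realized outcome locations for one trajectory. "exact"
# places round(length * p) outcomes on A within each run, positions
# permuted; "bernoulli" draws each trial independently. Precomputing the
# run layout keeps each rejection attempt cheap.
run_realizer <- function(traj, mode) {
  lens <- traj$runs$length
  ks <- round(lens * traj$runs$p_on_A)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  n <- sum(lens)
  if (mode == "exact") {
    function() {
      on_A <- logical(n)
      for (j in seq_along(lens)) {
        on_A[offsets[j] + sample.int(lens[j], ks[j])] <- TRUE
      }
      on_A
    }
  } else {
    p_seq <- traj$p_seq
    function() runif(n) < p_seq
  }
}

#' Realize outcome locations for a pair of trajectories
#'
#' Fills `realized_on_A` for the win and loss trajectories. Under the
#' default exact-frequency mode every run realizes its nominal probability
#' exactly. If `target_both` is set, both realizations are redrawn
#' (rejection sampling) until the number of trials on which win and loss
#' co-locate over the same stimulus equals the target.
#'
#' @param win_traj,loss_traj `iblt_trajectory` objects of equal length.
#' @param target_both Required co-location count, or `NULL` for
#'   unconstrained realization.
#' @param config An [schedule_config()]; supplies the realization mode and
#'   the rejection budget.
#' @return A list with elements `win_traj`, `loss_traj` (realized) and
#'   `n_both` (the achieved co-location count).
#' @export
realize_outcomes <- function(win_traj, loss_traj,
                             target_both = NULL,
                             config = schedule_config()) {
  n <- length(win_traj$p_seq)
  if (n != length(loss_traj$p_seq)) {
    abort_param("win and loss trajectories must have equal length.")
  }
  if (!is.null(target_both) && target_both > n) {
    abort_param("`target_both` cannot exceed the number of trials.")
  }
  if (config$realization == "exact") {
    hit <- realize_pair_cpp(
      as.integer(win_traj$runs$length),
      as.integer(round(win_traj$runs$length * win_traj$runs$p_on_A)),
      as.integer(loss_traj$runs$length),
      as.integer(round(loss_traj$runs$length * loss_traj$runs$p_on_A)),
      if (is.null(target_both)) -1L else as.integer(target_both),
      config$max_attempts
    )
    if (length(hit) > 0) {
      win_traj$realized_on_A <- hit$win_on_A == 1L
      loss_traj$realized_on_A <- hit$loss_on_A == 1L
      return(list(win_traj = win_traj, loss_traj = loss_traj,
                  n_both = hit$n_both))
    }
  } else {
    draw_win <- run_realizer(win_traj, config$realization)
    draw_loss <- run_realizer(loss_traj, config$realization)
    for (attempt in seq_len(if (is.null(target_both)) 1L else config$max_attempts)) {
      w_on_A <- draw_win()
      l_on_A <- draw_loss()
      n_both <- sum(w_on_A == l_on_A)
      if (is.null(target_both) || n_both == target_both) {
        win_traj$realized_on_A <- w_on_A
        loss_traj$realized_on_A <- l_on_A
        return(list(win_traj = win_traj, loss_traj = loss_traj, n_both = n_both))
      }
    }
  }
  abort_generation(sprintf(
    "no realization with %d co-located trials found in %d attempts.",
    target_both, config$max_attempts
  ))
}

#' Generate one fully realized block design
#'
#' Draws win and loss probability trajectories for the block type (run
#' boundaries independent between valences), then realizes outcome
#' locations under the co-location constraint of `config`. If the rejection
#' budget is exhausted for a drawn design, the run boundaries are redrawn
#' up to `config$design_retries` times.
#'
#' @inheritParams make_trajectory
#' @return A list of class `iblt_block`: `block_type`, `n_trials`,
#'   `win_traj`, `loss_traj`, `n_both`, and `trials`, a tibble with one row
#'   per trial (`trial`, `p_win_A`, `p_loss_A`, `win_on_A`, `loss_on_A`).
#' @export
#' @examples
#' set.seed(7)
#' blk <- build_block("train_loss_volatile")
#' blk$n_both
build_block <- function(block_type, config = schedule_config()) {
  if (!block_type %in% block_types()) {
    abort_param(sprintf("unknown block type '%s'.", block_type))
  }
  last_err <- NULL
  for (retry in seq_len(max(1L, config$design_retries))) {
    win_traj <- make_trajectory(block_type, "win", config)
    loss_traj <- make_trajectory(block_type, "loss", config)
    realized <- tryCatch(
      realize_outcomes(win_traj, loss_traj, config$target_both, config),
      iblt_generation_error = function(e) e
    )
    if (!inherits(realized, "error")) {
      trials <- tibble::tibble(
        trial = seq_len(config$n_trials),
        p_win_A = realized$win_traj$p_seq,
        p_loss_A = realized$loss_traj$p_seq,
        win_on_A = as.integer(realized$win_traj$realized_on_A),
        loss_on_A = as.integer(realized$loss_traj$realized_on_A)
      )
      return(structure(
        list(
          block_type = block_type,
          n_trials = config$n_trials,
          win_traj = realized$win_traj,
          loss_traj = realized$loss_traj,
          n_both = realized$n_both,
          trials = trials
        ),
        class = "iblt_block"
      ))
    }
    last_err <- realized
  }
  abort_generation(sprintf(
    "block type '%s': %s (after %d design redraws)",
    block_type, conditionMessage(last_err), config$design_retries
  ))
}

#' @export
print.iblt_block <- function(x, ...) {
  cat(sprintf(
    "<iblt_block> %s, %d trials, %d co-located win/loss trials\n",
    x$block_type, x$n_trials, x$n_both
  ))
  invisible(x)
}

#' Generate a full five-block session schedule
#'
#' Block order is both-volatile, three training blocks, both-volatile.
#' Negative training (`study = "negative_training"`) makes the loss channel
#' volatile and the win channel stable in training blocks; positive
#' training reverses this. Each block uses a fresh stimulus pair.
#'
#' @param study `"negative_training"` or `"positive_training"`.
#' @param config An [schedule_config()].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A tibble with one row per trial (5 blocks x `n_trials`):
#'   `block_index`, `block_type`, `stimulus_pair_id`, `trial`, `p_win_A`,
#'   `p_loss_A`, `win_on_A`, `loss_on_A`.
#' @export
#' @examples
#' sched <- build_session("negative_training", seed = 11)
#' dplyr::count(sched, block_index, block_type)
build_session <- function(study, config = schedule_config(), seed = NULL) {
  if (!study %in% c("negative_training", "positive_training")) {
    abort_param("`study` must be 'negative_training' or 'positive_training'.")
  }
  training_type <- if (study == "negative_training") {
    "train_loss_volatile"
  } else {
    "train_win_volatile"
  }
  order <- c("both_volatile", rep(training_type, 3), "both_volatile")
  with_seed(seed, {
    purrr::map2_dfr(seq_along(order), order, function(i, bt) {
      blk <- build_block(bt, config)
      dplyr::mutate(blk$trials,
        block_index = i,
        block_type = bt,
        stimulus_pair_id = i,
        .before = 1
      )
    })
  })
}
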