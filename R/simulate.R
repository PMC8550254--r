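# Generative model of choice on the task: a valence-specific
# Rescorla-Wagner delta rule tracks the probability that the win and the
# loss outcome appear over stimulus A; a softmax with inverse temperature
# beta and additive bias t maps the two estimates to a choice probability.

#' Agent parameters of the valence-specific learning model
#'
#' @param alpha_win,alpha_loss Learning rates in (0, 1) for win and loss
#'   outcomes respectively.
#' @param beta Inverse decision temperature, `>= 0`; 0 yields random choice.
#' @param t_bias Additive bias inside the softmax toward stimulus A.
#' @return A list of class `iblt_params`.
#' @export
#' @examples
#' agent_params(0.3, 0.3, 8)
agent_params <- function(alpha_win, alpha_loss, beta, t_bias = 0) {
  check_scalar_prob(alpha_win, "alpha_win")
  check_scalar_prob(alpha_loss, "alpha_loss")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0) {
    abort_param("`beta` must be a single finite number >= 0.")
  }
  if (!is.numeric(t_bias) || length(t_bias) != 1 || !is.finite(t_bias)) {
    abort_param("`t_bias` must be a single finite number.")
  }
  structure(
    list(alpha_win = alpha_win, alpha_loss = alpha_loss,
         beta = beta, t_bias = t_bias),
    class = "iblt_params"
  )
}

#' @export
print.iblt_params <- function(x, ...) {
  cat(sprintf(
    "<iblt_params> alpha_win = %.3g, alpha_loss = %.3g, beta = %.3g, t = %.3g\n",
    x$alpha_win, x$alpha_loss, x$beta, x$t_bias
  ))
  invisible(x)
}

#' Rescorla-Wagner update of an outcome-probability estimate
#'
#' Moves the estimate toward the observed outcome location by a fraction
#' `alpha` of the prediction error: `r + alpha * (outcome_on_A - r)`.
#'
#' @param r Current estimate(s) in `[0, 1]`.
#' @param alpha Learning rate(s) in `[0, 1]`.
#' @param outcome_on_A 0/1: did the outcome appear over stimulus A?
#' @return Updated estimate(s), guaranteed to stay in `[0, 1]`.
#' @export
#' @examples
#' rw_update(0.5, 0.3, 1) # 0.65
rw_update <- function(r, alpha, outcome_on_A) {
  check_scalar_prob(r, "r", open = FALSE)
  check_scalar_prob(alpha, "alpha", open = FALSE)
  if (!all(outcome_on_A %in% c(0, 1))) {
    abort_param("`outcome_on_A` must be 0 or 1.")
  }
  r + alpha * (outcome_on_A - r)
}

#' Softmax choice probability for stimulus A
#'
#' `P(choice = A) = 1 / (1 + exp(-beta * (rwin + t - rloss)))`, evaluated
#' overflow-safely. Equals 0.5 when `beta = 0` or when the biased value
#' difference is zero.
#'
#' @param rwin,rloss Estimated win/loss-on-A probabilities in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @param t_bias Additive bias.
#' @return Probability of choosing A, in (0, 1).
#' @export
#' @examples
#' choice_probability(0.8, 0.2, 5) # 1 / (1 + exp(-3))
choice_probability <- function(rwin, rloss, beta, t_bias = 0) {
  check_scalar_prob(rwin, "rwin", open = FALSE)
  check_scalar_prob(rloss, "rloss", open = FALSE)
  if (any(beta < 0)) abort_param("`beta` must be >= 0.")
  plogis(beta * (rwin + t_bias - rloss))
}

# Payoff in pence: +10 if win over the chosen stimulus, -10 if loss over
# the chosen stimulus; both or neither on the chosen side nets zero.
trial_payoff <- function(chose_A, win_on_A, loss_on_A) {
  win_chosen <- ifelse(chose_A, win_on_A, 1 - win_on_A)
  loss_chosen <- ifelse(chose_A, loss_on_A, 1 - loss_on_A)
  10L * (win_chosen - loss_chosen)
}

#' Simulate an agent's choices on one realized block
#'
#' Beliefs start at 0.5 for both valences. On each trial the agent chooses
#' A with [choice_probability()] given its current beliefs, collects the
#' payoff, then updates both beliefs from the displayed outcome locations
#' (both locations are shown every trial, so learning does not depend on
#' the choice).
#'
#' @param params An [agent_params()] object.
#' @param block An `iblt_block` from [build_block()], or a tibble of
#'   realized trials with columns `trial`, `p_win_A`, `p_loss_A`,
#'   `win_on_A`, `loss_on_A`.
#' @param seed Optional seed; caller's RNG state is restored.
#' @return The trial tibble with added columns `rwin`, `rloss` (beliefs
#'   entering the trial), `choice` (`"A"`/`"B"`) and `payoff_pence`.
#' @export
#' @examples
#' set.seed(2)
#' blk <- build_block("both_volatile")
#' sim <- simulate_block(agent_params(0.3, 0.3, 8), blk)
#' table(sim$choice)
simulate_block <- function(params, block, seed = NULL) {
  stopifnot(inherits(params, "iblt_params"))
  trials <- if (inherits(block, "iblt_block")) block$trials else block
  if (is.null(trials$win_on_A) || anyNA(trials$win_on_A) ||
      is.null(trials$loss_on_A) || anyNA(trials$loss_on_A)) {
    abort_state("block has no realized outcome locations; realize it first.")
  }
  n <- nrow(trials)
  with_seed(seed, {
    rwin <- rloss <- numeric(n)
    chose_A <- logical(n)
    rw <- rl <- 0.5
    u <- runif(n)
    for (i in seq_len(n)) {
      rwin[i] <- rw
      rloss[i] <- rl
      p_A <- choice_probability(rw, rl, params$beta, params$t_bias)
      chose_A[i] <- u[i] < p_A
      rw <- rw_update(rw, params$alpha_win, trials$win_on_A[i])
      rl <- rw_update(rl, params$alpha_loss, trials$loss_on_A[i])
    }
    dplyr::mutate(trials,
      rwin = rwin,
      rloss = rloss,
      choice = ifelse(chose_A, "A", "B"),
      payoff_pence = trial_payoff(chose_A, win_on_A, loss_on_A)
    )
  })
}

#' Specification of a synthetic cohort
#'
#' Describes how per-participant model parameters are drawn and how the
#' study structure is emulated: `n_participants` agents, each completing
#' two sessions (sham/active stimulation, order counterbalanced) of five
#' blocks. Learning rates are drawn logit-normally, the inverse temperature
#' log-normally, and the bias normally; defaults give plausibly noisy but
#' learnable behaviour around alpha = 0.3, beta = 8, t = 0.
#'
#' With `volatility_adaptive = TRUE`, each agent's learning rate for
#' whichever valence is volatile in the current block is shifted up by
#' `adapt_logit` on the logit scale and the stable valence's down by the
#' same amount, emulating the volatility adaptation the task is designed to
#' train. `tdcs_alpha_logit` / `tdcs_beta_log` add offsets under active
#' stimulation (defaults zero, a null stimulation effect).
#'
#' @param n_participants Participants per study.
#' @param alpha_mean Population mean learning rate (applied on the logit
#'   scale to both valences).
#' @param alpha_sd_logit Between-participant SD of logit learning rates.
#' @param beta_meanlog,beta_sdlog Log-scale mean and SD of beta.
#' @param t_mean,t_sd Mean and SD of the bias term.
#' @param volatility_adaptive Shift learning rates by block volatility?
#' @param adapt_logit Size of the volatility shift on the logit scale.
#' @param tdcs_alpha_logit,tdcs_beta_log Additive offsets applied under
#'   active stimulation (on logit-alpha and log-beta scales).
#' @param redraw_schedule_per_session Draw a fresh realized schedule for
#'   every session (default) or share one schedule per study.
#' @return A list of class `iblt_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20L,
                        alpha_mean = 0.3,
                        alpha_sd_logit = 0.5,
                        beta_meanlog = log(8),
                        beta_sdlog = 0.4,
                        t_mean = 0,
                        t_sd = 0.05,
                        volatility_adaptive = FALSE,
                        adapt_logit = 1,
                        tdcs_alpha_logit = 0,
                        tdcs_beta_log = 0,
                        redraw_schedule_per_session = TRUE) {
  check_scalar_prob(alpha_mean, "alpha_mean")
  if (alpha_sd_logit < 0 || beta_sdlog < 0 || t_sd < 0) {
    abort_param("spread parameters must be non-negative.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      alpha_mean = alpha_mean,
      alpha_sd_logit = alpha_sd_logit,
      beta_meanlog = beta_meanlog,
      beta_sdlog = beta_sdlog,
      t_mean = t_mean,
      t_sd = t_sd,
      volatility_adaptive = volatility_adaptive,
      adapt_logit = adapt_logit,
      tdcs_alpha_logit = tdcs_alpha_logit,
      tdcs_beta_log = tdcs_beta_log,
      redraw_schedule_per_session = redraw_schedule_per_session
    ),
    class = "iblt_cohort_spec"
  )
}

# Per-block effective parameters: apply volatility-adaptive and
# stimulation offsets to an agent's baseline parameters.
effective_params <- function(base, spec, block_type, tdcs_condition) {
  la_w <- qlogis(base$alpha_win)
  la_l <- qlogis(base$alpha_loss)
  lb <- log(base$beta)
  if (spec$volatility_adaptive) {
    shift <- function(volatile) if (volatile) spec$adapt_logit else -spec$adapt_logit
    la_w <- la_w + shift(is_volatile(block_type, "win"))
    la_l <- la_l + shift(is_volatile(block_type, "loss"))
  }
  if (identical(tdcs_condition, "active")) {
    la_w <- la_w + spec$tdcs_alpha_logit
    la_l <- la_l + spec$tdcs_alpha_logit
    lb <- lb + spec$tdcs_beta_log
  }
  agent_params(plogis(la_w), plogis(la_l), exp(lb), base$t_bias)
}

draw_agent <- function(spec) {
  agent_params(
    alpha_win = plogis(rnorm(1, qlogis(spec$alpha_mean), spec$alpha_sd_logit)),
    alpha_loss = plogis(rnorm(1, qlogis(spec$alpha_mean), spec$alpha_sd_logit)),
    beta = rlnorm(1, spec$beta_meanlog, spec$beta_sdlog),
    t_bias = rnorm(1, spec$t_mean, spec$t_sd)
  )
}

#' Simulate a full synthetic cohort
#'
#' Emulates one study arm: `n_participants` agents, two sessions each with
#' counterbalanced stimulation order, a five-block session schedule per
#' session, and choices generated from the learning model. The result uses
#' the shared trial-log format, so it is interchangeable with converted
#' real data.
#'
#' @param spec A [cohort_spec()].
#' @param study `"negative_training"` or `"positive_training"`.
#' @param config An [schedule_config()].
#' @param seed Master seed; all stage randomness is derived from it via
#'   [substream_seed()], so identical seeds give identical logs.
#' @return A trial-log tibble: one row per trial with columns `study`,
#'   `participant_id`, `session_index`, `tdcs_condition`, `tdcs_order`,
#'   `block_index`, `block_type`, `trial`, `p_win_A`, `p_loss_A`,
#'   `win_on_A`, `loss_on_A`, `choice`, `payoff_pence`, `cumulative_pence`.
#' @export
#' @examples
#' log <- simulate_cohort(cohort_spec(n_participants = 2), "negative_training",
#'                        seed = 5)
#' nrow(log) # 2 participants x 2 sessions x 5 blocks x 80 trials
simulate_cohort <- function(spec, study,
                            config = schedule_config(),
                            seed = 1L) {
  stopifnot(inherits(spec, "iblt_cohort_spec"))
  if (!study %in% c("negative_training", "positive_training")) {
    abort_param("`study` must be 'negative_training' or 'positive_training'.")
  }
  shared_schedule <- NULL
  if (!spec$redraw_schedule_per_session) {
    shared_schedule <- build_session(
      study, config,
      seed = substream_seed(seed, "schedule-shared")
    )
  }
  purrr::map_dfr(seq_len(spec$n_participants), function(pid) {
    base <- with_seed(
      substream_seed(seed, paste0("agent-", pid)),
      draw_agent(spec)
    )
    order <- if (pid %% 2 == 1) "sham_first" else "active_first"
    purrr::map_dfr(1:2, function(sess) {
      tdcs <- if (order == "sham_first") {
        c("sham", "active")[sess]
      } else {
        c("active", "sham")[sess]
      }
      sched <- if (spec$redraw_schedule_per_session) {
        build_session(
          study, config,
          seed = substream_seed(seed, sprintf("schedule-p%d-s%d", pid, sess))
        )
      } else {
        shared_schedule
      }
      sim <- purrr::map_dfr(
        split(sched, sched$block_index),
        function(blk_trials) {
          bt <- blk_trials$block_type[1]
          pars <- effective_params(base, spec, bt, tdcs)
          sim_seed <- substream_seed(
            seed, sprintf("choices-p%d-s%d-b%d", pid, sess, blk_trials$block_index[1])
          )
          simulate_block(pars, blk_trials, seed = sim_seed)
        }
      )
      dplyr::mutate(sim,
        study = study,
        participant_id = pid,
        session_index = sess,
        tdcs_condition = tdcs,
        tdcs_order = order,
        cumulative_pence = 150L + cumsum(payoff_pence),
        .before = 1
      ) |>
        dplyr::select(
          study, participant_id, session_index, tdcs_condition, tdcs_order,
          block_index, block_type, trial, p_win_A, p_loss_A,
          win_on_A, loss_on_A, choice, payoff_pence, cumulative_pence
        )
    })
  })
}
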