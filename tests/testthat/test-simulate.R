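test_that("the delta rule moves estimates toward outcomes", {
  expect_equal(rw_update(0.5, 0, 1), 0.5)   # zero learning rate: identity
  expect_equal(rw_update(0.5, 1, 1), 1.0)   # full update jumps to outcome
  expect_equal(rw_update(0.5, 0.3, 1), 0.65)
  expect_equal(rw_update(0.5, 0.3, 0), 0.35)
  expect_error(rw_update(1.5, 0.3, 1), class = "iblt_parameter_error")
  expect_error(rw_update(0.5, -0.1, 1), class = "iblt_parameter_error")
  expect_error(rw_update(0.5, 0.3, 2), class = "iblt_parameter_error")
})

test_that("belief trajectories stay in [0, 1] for arbitrary outcome sequences", {
  set.seed(201)
  for (rep in 1:20) {
    alpha <- runif(1)
    outcomes <- rbinom(200, 1, runif(1))
    r <- 0.5
    path <- vapply(outcomes, function(o) r <<- rw_update(r, alpha, o),
                   numeric(1))
    expect_true(all(path >= 0 & path <= 1))
  }
})

test_that("softmax choice probability behaves at its anchors", {
  expect_equal(choice_probability(0.7, 0.7, 3), 0.5)       # symmetric values
  expect_equal(choice_probability(0.9, 0.1, 0), 0.5)       # beta = 0: random
  expect_equal(choice_probability(0.8, 0.2, 5), 1 / (1 + exp(-3)))
  # overflow-safe at extreme drive
  expect_equal(choice_probability(1, 0, 1e6), 1)
  expect_equal(choice_probability(0, 1, 1e6), 0)
  expect_error(choice_probability(0.5, 0.5, -1), class = "iblt_parameter_error")
})

test_that("a near-greedy agent locks onto a deterministic schedule", {
  # win always over A, loss always over B: rwin rises, rloss falls, so a
  # high-beta agent chooses A on every trial after the first
  blk <- toy_block_win_A(20)
  sim <- simulate_block(agent_params(0.3, 0.3, 100), blk, seed = 202)
  expect_true(all(sim$choice[-1] == "A"))
  expect_true(all(sim$payoff_pence[sim$choice == "A"] == 10))
})

test_that("payoff rules net zero on both-outcome trials", {
  trials <- manual_trials(
    win_on_A = c(1, 1, 0, 0),
    loss_on_A = c(1, 0, 1, 0),
    choice = c("A", "A", "A", "B")
  )
  sim <- simulate_block(agent_params(0.3, 0.3, 5),
                        dplyr::select(trials, -choice), seed = 203)
  both <- sim$win_on_A == sim$loss_on_A
  expect_true(all(sim$payoff_pence[both] == 0))
  # explicit cases: win on chosen only = +10; loss on chosen only = -10
  expect_equal(unname(trial_payoff(TRUE, 1, 0)), 10L)
  expect_equal(unname(trial_payoff(TRUE, 0, 1)), -10L)
  expect_equal(unname(trial_payoff(TRUE, 1, 1)), 0L)
  expect_equal(unname(trial_payoff(FALSE, 1, 1)), 0L)
})

test_that("a beta = 0 agent responds at chance", {
  set.seed(204)
  blk <- build_block("both_volatile")
  freqs <- vapply(1:30, function(i) {
    mean(simulate_block(agent_params(0.3, 0.3, 0), blk)$choice == "A")
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 0.5), 0.02)
})

test_that("an unrealized block cannot be simulated", {
  unrealized <- tibble::tibble(
    trial = 1:5, p_win_A = 0.5, p_loss_A = 0.5,
    win_on_A = NA_integer_, loss_on_A = NA_integer_
  )
  expect_error(simulate_block(agent_params(0.3, 0.3, 5), unrealized),
               class = "iblt_state_error")
})

test_that("simulated cohorts have the study's dimensions and bookkeeping", {
  log <- simulate_cohort(cohort_spec(n_participants = 4), "negative_training",
                         seed = 205)
  expect_equal(nrow(log), 4 * 2 * 5 * 80)
  expect_setequal(unique(log$tdcs_order), c("sham_first", "active_first"))
  # counterbalancing: each participant sees both conditions once
  cond <- dplyr::distinct(log, participant_id, session_index, tdcs_condition)
  expect_equal(nrow(cond), 8)
  expect_true(all(table(cond$participant_id) == 2))
  # running total tracks the 150p start amount plus payoffs within session
  one <- dplyr::filter(log, participant_id == 1, session_index == 1)
  expect_equal(one$cumulative_pence, 150 + cumsum(one$payoff_pence))
})

test_that("identical master seeds reproduce the trial log bit-identically", {
  spec <- cohort_spec(n_participants = 2)
  a <- simulate_cohort(spec, "positive_training", seed = 206)
  b <- simulate_cohort(spec, "positive_training", seed = 206)
  expect_identical(a, b)
  c <- simulate_cohort(spec, "positive_training", seed = 207)
  expect_false(identical(a$choice, c$choice))
})

test_that("win/loss and A/B relabelling is symmetric when alphas match and t = 0", {
  set.seed(208)
  blk <- build_block("both_volatile")$trials
  p <- agent_params(0.35, 0.35, 6, 0)
  a <- simulate_block(p, blk, seed = 209)

  # swapping the valence channels swaps the two belief trajectories and
  # complements the choice probability
  valence_swapped <- dplyr::mutate(blk, win_on_A = blk$loss_on_A,
                                   loss_on_A = blk$win_on_A)
  b <- simulate_block(p, valence_swapped, seed = 209)
  expect_equal(b$rwin, a$rloss)
  expect_equal(b$rloss, a$rwin)
  expect_equal(
    choice_probability(b$rwin, b$rloss, p$beta),
    1 - choice_probability(a$rwin, a$rloss, p$beta)
  )

  # relabelling the stimuli mirrors both belief trajectories and likewise
  # complements the choice probability
  stim_swapped <- dplyr::mutate(blk, win_on_A = 1L - blk$win_on_A,
                                loss_on_A = 1L - blk$loss_on_A)
  d <- simulate_block(p, stim_swapped, seed = 209)
  expect_equal(d$rwin, 1 - a$rwin)
  expect_equal(d$rloss, 1 - a$rloss)
  expect_equal(
    choice_probability(d$rwin, d$rloss, p$beta),
    1 - choice_probability(a$rwin, a$rloss, p$beta)
  )
})
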