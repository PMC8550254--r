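# Grid-based full-joint-posterior estimation of the learning model.
#
# The likelihood of a block's choices is evaluated at every node of a
# four-dimensional grid (alpha_win, alpha_loss, beta, t). With a prior
# uniform over the nodes -- i.e. uniform in the transformed space in which
# the axes are laid out -- the joint posterior is the normalized
# likelihood; parameter estimates are expectations under the marginals on
# the raw parameter scale. All normalization is done in log space.

#' Parameter grid for posterior estimation
#'
#' Learning-rate axes are uniform in logit space, the inverse-temperature
#' axis uniform in log space (matching the transformations under which the
#' parameters are analysed downstream), and the bias axis linear.
#'
#' @param n_alpha,alpha_range Points and raw-scale bounds of each
#'   learning-rate axis.
#' @param n_beta,beta_range Points and raw-scale bounds of the beta axis.
#' @param n_t,t_range Points and bounds of the bias axis.
#' @return A list of class `iblt_grid` with raw-scale axes `alpha`, `beta`,
#'   `t` (the same alpha axis is used for both valences).
#' @export
#' @examples
#' g <- parameter_grid()
#' lengths(g[c("alpha", "beta", "t")])
parameter_grid <- function(n_alpha = 30L, alpha_range = c(0.02, 0.98),
                           n_beta = 25L, beta_range = c(0.1, 30),
                           n_t = 15L, t_range = c(-0.5, 0.5)) {
  if (any(alpha_range <= 0) || any(alpha_range >= 1) ||
      alpha_range[1] >= alpha_range[2]) {
    abort_param("`alpha_range` must be increasing within (0, 1).")
  }
  if (any(beta_range <= 0) || beta_range[1] >= beta_range[2]) {
    abort_param("`beta_range` must be increasing and positive.")
  }
  structure(
    list(
      alpha = plogis(seq(qlogis(alpha_range[1]), qlogis(alpha_range[2]),
                         length.out = n_alpha)),
      beta = exp(seq(log(beta_range[1]), log(beta_range[2]),
                     length.out = n_beta)),
      t = if (n_t == 1) mean(t_range) else
        seq(t_range[1], t_range[2], length.out = n_t)
    ),
    class = "iblt_grid"
  )
}

#' @export
print.iblt_grid <- function(x, ...) {
  cat(sprintf(
    "<iblt_grid> %d alpha (logit-spaced, [%.3g, %.3g]) x %d beta (log-spaced, [%.3g, %.3g]) x %d t ([%.3g, %.3g])\n",
    length(x$alpha), min(x$alpha), max(x$alpha),
    length(x$beta), min(x$beta), max(x$beta),
    length(x$t), min(x$t), max(x$t)
  ))
  invisible(x)
}

check_fit_trials <- function(trials, omit_first) {
  needed <- c("win_on_A", "loss_on_A", "choice")
  if (!all(needed %in% names(trials))) {
    abort_param("trials must have columns win_on_A, loss_on_A, choice.")
  }
  if (nrow(trials) == 0) abort_param("empty trial list.")
  if (omit_first >= nrow(trials)) {
    abort_param("`omit_first` must be smaller than the number of trials.")
  }
  invisible(trials)
}

#' Log-likelihood of a block's choices under fixed parameters
#'
#' Beliefs are initialized at 0.5 and updated by [rw_update()] on every
#' trial from the realized outcome locations; the log-likelihood sums the
#' log choice probability of the observed choice over the scored trials
#' only (the first `omit_first` trials are updated through but not scored,
#' since estimates made while beliefs are still near their prior inflate
#' apparent learning rates).
#'
#' @param params An [agent_params()] object.
#' @param trials Ordered trial tibble with `win_on_A`, `loss_on_A`,
#'   `choice` (`"A"`/`"B"`).
#' @param omit_first Number of leading trials excluded from scoring.
#' @return The summed log-likelihood (scalar).
#' @export
block_loglik <- function(params, trials, omit_first = 10L) {
  stopifnot(inherits(params, "iblt_params"))
  check_fit_trials(trials, omit_first)
  n <- nrow(trials)
  rw <- rl <- 0.5
  ll <- 0
  for (i in seq_len(n)) {
    if (i > omit_first) {
      p_A <- choice_probability(rw, rl, params$beta, params$t_bias)
      p_obs <- if (trials$choice[i] == "A") p_A else 1 - p_A
      ll <- ll + log(p_obs)
    }
    rw <- rw_update(rw, params$alpha_win, trials$win_on_A[i])
    rl <- rw_update(rl, params$alpha_loss, trials$loss_on_A[i])
  }
  ll
}

# Log-likelihood over the full grid: (n_alpha, n_alpha, n_beta, n_t) array.
grid_loglik <- function(trials, grid, omit_first) {
  n <- nrow(trials)
  scored <- seq.int(omit_first + 1L, n)
  rwin <- belief_paths_cpp(grid$alpha, as.integer(trials$win_on_A))[, scored, drop = FALSE]
  rloss <- belief_paths_cpp(grid$alpha, as.integer(trials$loss_on_A))[, scored, drop = FALSE]
  grid_loglik_cpp(rwin, rloss, grid$beta, grid$t,
                  as.integer(trials$choice[scored] == "A"))
}

# Normalize a log-posterior array safely (max-subtraction in log space).
normalize_log_posterior <- function(logp) {
  m <- max(logp)
  if (!is.finite(m)) abort_param("posterior is degenerate (all -Inf).")
  p <- exp(logp - m)
  p / sum(p)
}

marginal_over <- function(post, axis) {
  as.numeric(apply(post, axis, sum))
}

#' Fit the learning model to one block by grid posterior
#'
#' Computes the full joint posterior of (alpha_win, alpha_loss, beta, t)
#' over the grid -- likelihood from [block_loglik()]'s rule evaluated at
#' every node, prior uniform over nodes -- then marginalises and reports
#' the expected value of each parameter on its raw scale. AIC and BIC use
#' the grid-maximum log-likelihood with `n` equal to the number of scored
#' trials.
#'
#' @param trials Ordered trial tibble for one block.
#' @param grid A [parameter_grid()].
#' @param omit_first Leading trials excluded from the likelihood.
#' @param estimate `"mean"` (default, expectation under each marginal) or
#'   `"mode"` (marginal maximizer).
#' @return An object of class `iblt_fit` with elements `estimates` (named
#'   list), `marginals` (tibble: `parameter`, `value`, `mass`), `joint`
#'   (normalized posterior array), `max_loglik`, `n_fit`, `k`, `AIC`,
#'   `BIC`, `grid`. Use [tidy()] / [glance()] to extract tables.
#' @export
#' @examples
#' set.seed(3)
#' blk <- build_block("both_volatile")
#' sim <- simulate_block(agent_params(0.4, 0.3, 10), blk)
#' fit <- fit_block_posterior(sim, parameter_grid(n_alpha = 12, n_beta = 9, n_t = 5))
#' tidy(fit)
fit_block_posterior <- function(trials, grid = parameter_grid(),
                                omit_first = 10L,
                                estimate = c("mean", "mode")) {
  estimate <- match.arg(estimate)
  check_fit_trials(trials, omit_first)
  ll <- grid_loglik(trials, grid, omit_first)
  post <- normalize_log_posterior(ll) # uniform prior over nodes
  axes <- list(alpha_win = grid$alpha, alpha_loss = grid$alpha,
               beta = grid$beta, t_bias = grid$t)
  marg <- purrr::imap(axes, function(vals, nm) {
    marginal_over(post, match(nm, names(axes)))
  })
  est <- purrr::imap(axes, function(vals, nm) {
    if (estimate == "mean") sum(marg[[nm]] * vals) else vals[which.max(marg[[nm]])]
  })
  n_fit <- nrow(trials) - omit_first
  k <- sum(lengths(axes) > 1L)
  max_ll <- max(ll)
  structure(
    list(
      estimates = est,
      marginals = purrr::imap_dfr(axes, function(vals, nm) {
        tibble::tibble(parameter = nm, value = vals, mass = marg[[nm]])
      }),
      joint = post,
      max_loglik = max_ll,
      n_fit = n_fit,
      k = k,
      AIC = 2 * k - 2 * max_ll,
      BIC = k * log(n_fit) - 2 * max_ll,
      grid = grid,
      estimate_kind = estimate
    ),
    class = "iblt_fit"
  )
}

#' @export
print.iblt_fit <- function(x, ...) {
  cat(sprintf(
    "<iblt_fit> alpha_win = %.3f, alpha_loss = %.3f, beta = %.2f, t = %.3f (posterior %s)\n",
    x$estimates$alpha_win, x$estimates$alpha_loss, x$estimates$beta,
    x$estimates$t_bias, x$estimate_kind
  ))
  cat(sprintf(
    "  max logL = %.2f over %d scored trials; k = %d; AIC = %.1f; BIC = %.1f\n",
    x$max_loglik, x$n_fit, x$k, x$AIC, x$BIC
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.iblt_fit <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$estimates),
    estimate = unlist(x$estimates, use.names = FALSE)
  )
}

#' @export
glance.iblt_fit <- function(x, ...) {
  tibble::tibble(
    maxlogL = x$max_loglik, k = x$k, n_fit = x$n_fit,
    AIC = x$AIC, BIC = x$BIC
  )
}

#' Define a model variant for comparison
#'
#' Variants restrict the full model: a single shared learning rate instead
#' of valence-specific ones, no bias term (t fixed at 0), or a fixed
#' inverse temperature instead of a free one. `k` counts the free axes.
#'
#' @param name Label used in the comparison table.
#' @param valence_specific Two learning rates (TRUE) or one shared (FALSE)?
#' @param bias Free bias term?
#' @param free_beta Free inverse temperature?
#' @param fixed_beta Value used when `free_beta = FALSE`.
#' @return A list of class `iblt_variant`.
#' @export
model_variant <- function(name, valence_specific = TRUE, bias = TRUE,
                          free_beta = TRUE, fixed_beta = 1) {
  k <- (if (valence_specific) 2L else 1L) + bias + free_beta
  if (k < 1L) abort_param("a model variant needs at least one free parameter.")
  structure(
    list(name = name, valence_specific = valence_specific, bias = bias,
         free_beta = free_beta, fixed_beta = fixed_beta, k = k),
    class = "iblt_variant"
  )
}

#' Default model-variant family
#'
#' Six nested restrictions of the full model: valence-specific or shared
#' learning rate, crossed with bias on/off under a free beta, plus the two
#' no-bias models with beta fixed.
#'
#' @param fixed_beta Inverse temperature used by the fixed-beta variants.
#' @return A list of [model_variant()] objects.
#' @export
model_variants <- function(fixed_beta = 1) {
  list(
    model_variant("two_alpha_bias"),
    model_variant("two_alpha_no_bias", bias = FALSE),
    model_variant("one_alpha_bias", valence_specific = FALSE),
    model_variant("one_alpha_no_bias", valence_specific = FALSE, bias = FALSE),
    model_variant("two_alpha_fixed_beta", bias = FALSE, free_beta = FALSE,
                  fixed_beta = fixed_beta),
    model_variant("one_alpha_fixed_beta", valence_specific = FALSE,
                  bias = FALSE, free_beta = FALSE, fixed_beta = fixed_beta)
  )
}

# Maximum grid log-likelihood of one variant on one block.
variant_max_loglik <- function(trials, variant, grid, omit_first) {
  g <- grid
  if (!variant$bias) g$t <- 0
  if (!variant$free_beta) g$beta <- variant$fixed_beta
  ll <- grid_loglik(trials, g, omit_first)
  if (!variant$valence_specific) {
    # shared alpha: restrict to the diagonal alpha_win == alpha_loss
    na <- length(g$alpha)
    d <- dim(ll)
    idx <- cbind(
      rep(seq_len(na), times = d[3] * d[4]),
      rep(seq_len(na), times = d[3] * d[4]),
      rep(rep(seq_len(d[3]), each = na), times = d[4]),
      rep(seq_len(d[4]), each = na * d[3])
    )
    ll <- ll[idx]
  }
  max(ll)
}

#' Compare model variants on one block by AIC and BIC
#'
#' Each variant's likelihood is evaluated on the (collapsed) grid -- the
#' alpha axis reused for both valences when shared, `t = 0` when the bias
#' is excluded, a single fixed beta node when beta is not free -- and
#' ranked by AIC and BIC computed from the grid-maximum log-likelihood.
#'
#' @param trials Ordered trial tibble for one block.
#' @param variants List of [model_variant()]s (default [model_variants()]).
#' @param grid A [parameter_grid()].
#' @param omit_first Leading trials excluded from the likelihood.
#' @return A tibble: `model`, `k`, `maxlogL`, `AIC`, `BIC`, `rank_AIC`,
#'   `rank_BIC`, sorted by BIC.
#' @export
compare_models <- function(trials, variants = model_variants(),
                           grid = parameter_grid(), omit_first = 10L) {
  if (length(variants) < 2) abort_param("need at least two variants.")
  check_fit_trials(trials, omit_first)
  n_fit <- nrow(trials) - omit_first
  res <- purrr::map_dfr(variants, function(v) {
    max_ll <- variant_max_loglik(trials, v, grid, omit_first)
    tibble::tibble(
      model = v$name, k = v$k, maxlogL = max_ll,
      AIC = 2 * v$k - 2 * max_ll,
      BIC = v$k * log(n_fit) - 2 * max_ll
    )
  })
  res$rank_AIC <- rank(res$AIC, ties.method = "min")
  res$rank_BIC <- rank(res$BIC, ties.method = "min")
  dplyr::arrange(res, BIC)
}

#' Fit every participant x session x block of a trial log
#'
#' Applies [fit_block_posterior()] to each block of the log and returns a
#' tidy parameter table, one row per fit. Deterministic given the input
#' and grid.
#'
#' @param trial_log A trial-log tibble (simulated or converted real data)
#'   with at least `participant_id`, `session_index`, `block_index` and the
#'   per-trial columns used by the likelihood.
#' @param grid A [parameter_grid()].
#' @param omit_first Leading trials per block excluded from the likelihood.
#' @param estimate Passed to [fit_block_posterior()].
#' @return A tibble with the grouping/design columns plus `alpha_win`,
#'   `alpha_loss`, `beta`, `t_bias`, `maxlogL`, `k`, `n_fit`, `AIC`, `BIC`.
#' @export
fit_dataset <- function(trial_log, grid = parameter_grid(),
                        omit_first = 10L, estimate = "mean") {
  group_cols <- intersect(
    c("study", "participant_id", "session_index", "tdcs_condition",
      "tdcs_order", "block_index", "block_type"),
    names(trial_log)
  )
  if (!all(c("participant_id", "block_index") %in% group_cols)) {
    abort_param("trial log needs participant_id and block_index columns.")
  }
  trial_log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_block_posterior(dplyr::arrange(d, trial), grid,
                               omit_first = omit_first, estimate = estimate)
      tibble::tibble(
        alpha_win = f$estimates$alpha_win,
        alpha_loss = f$estimates$alpha_loss,
        beta = f$estimates$beta,
        t_bias = f$estimates$t_bias,
        maxlogL = f$max_loglik, k = f$k, n_fit = f$n_fit,
        AIC = f$AIC, BIC = f$BIC
      )
    }) |>
    dplyr::ungroup()
}
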