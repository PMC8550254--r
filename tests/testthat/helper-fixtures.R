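# Shared fixtures and independent oracles, all built in code.

# A deterministic toy block: win always over A, loss always over B.
toy_block_win_A <- function(n = 20) {
  tibble::tibble(
    trial = seq_len(n),
    p_win_A = 0.8, p_loss_A = 0.2,
    win_on_A = 1L, loss_on_A = 0L
  )
}

# Hand-specifiable block of realized trials with choices.
manual_trials <- function(win_on_A, loss_on_A, choice) {
  tibble::tibble(
    trial = seq_along(win_on_A),
    p_win_A = 0.5, p_loss_A = 0.5,
    win_on_A = as.integer(win_on_A),
    loss_on_A = as.integer(loss_on_A),
    choice = choice
  )
}

# Naive brute-force grid posterior: plain products of probabilities, no
# log space, independent of the package's fitting path.
naive_grid_posterior <- function(trials, alpha_axis, beta_axis, t_axis,
                                 omit_first = 0) {
  n <- nrow(trials)
  na <- length(alpha_axis); nb <- length(beta_axis); nt <- length(t_axis)
  lik <- array(NA_real_, c(na, na, nb, nt))
  for (iw in seq_len(na)) for (il in seq_len(na)) {
    for (ib in seq_len(nb)) for (it in seq_len(nt)) {
      rw <- rl <- 0.5
      L <- 1
      for (i in seq_len(n)) {
        if (i > omit_first) {
          pA <- 1 / (1 + exp(-beta_axis[ib] * (rw + t_axis[it] - rl)))
          L <- L * if (trials$choice[i] == "A") pA else 1 - pA
        }
        rw <- rw + alpha_axis[iw] * (trials$win_on_A[i] - rw)
        rl <- rl + alpha_axis[il] * (trials$loss_on_A[i] - rl)
      }
      lik[iw, il, ib, it] <- L
    }
  }
  post <- lik / sum(lik)
  means <- c(
    alpha_win = sum(apply(post, 1, sum) * alpha_axis),
    alpha_loss = sum(apply(post, 2, sum) * alpha_axis),
    beta = sum(apply(post, 3, sum) * beta_axis),
    t_bias = sum(apply(post, 4, sum) * t_axis)
  )
  list(post = post, means = means)
}

# Count of partitions of `total` into ordered parts within [mn, mx],
# grouped by number of parts -- an enumeration oracle for run counts.
partition_part_counts <- function(total, mn, mx) {
  recurse <- function(rem, parts) {
    if (rem == 0) return(parts)
    out <- integer(0)
    for (p in mn:mx) {
      if (p <= rem) out <- c(out, recurse(rem - p, parts + 1L))
    }
    out
  }
  sort(unique(recurse(total, 0L)))
}

# Small grid that keeps test fits fast.
small_grid <- function() {
  parameter_grid(n_alpha = 12, alpha_range = c(0.05, 0.95),
                 n_beta = 9, beta_range = c(0.5, 25),
                 n_t = 5, t_range = c(-0.3, 0.3))
}
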