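test_that("parameter transforms map onto the real line and police domains", {
  expect_equal(transform_parameter(0.5, "logit"), 0)
  expect_equal(transform_parameter(1, "log"), 0)
  expect_equal(transform_parameter(0.65, "logit"), log(0.65 / 0.35))
  expect_equal(transform_parameter(c(-2, 7), "identity"), c(-2, 7))
  # monotone and invertible
  x <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(transform_parameter(x, "logit")) > 0))
  expect_equal(plogis(transform_parameter(x, "logit")), x)
  expect_error(transform_parameter(c(0.5, 1.2), "logit"),
               class = "iblt_parameter_error")
  expect_error(transform_parameter(c(2, 0), "log"),
               class = "iblt_parameter_error")
})

test_that("paired t handles regular and degenerate differences", {
  # d = (1, 2, 3, 4): mean 2.5, sd 1.290994, t = 2.5 / (1.290994/2) = 3.873
  out <- paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(out$df, 3)
  expect_equal(out$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2))
  ref <- t.test(c(2, 4, 6, 8), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p, ref$p.value)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)) # d = (1,1,1,1)
  expect_true(const$infinite_t)
  expect_equal(const$p, 0)
  expect_true(is.infinite(const$t))

  expect_error(paired_t(1:3, 1:4), class = "iblt_parameter_error")
})

test_that("a two-level within ANOVA reproduces the paired t exactly", {
  set.seed(501)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    d <- tidyr::expand_grid(participant_id = seq_len(n),
                            cond = c("a", "b"))
    d$y <- rnorm(nrow(d)) + 0.5 * (d$cond == "b") + rep(rnorm(n), each = 2)
    a <- tidy(mixed_rm_anova(d, "y", within = "cond"))
    tt <- paired_t(d$y[d$cond == "a"], d$y[d$cond == "b"])
    expect_equal(a$F, tt$t^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p, tolerance = 1e-10)
  }
})

test_that("sums of squares decompose the corrected total", {
  set.seed(502)
  d <- tidyr::expand_grid(participant_id = 1:10,
                          valence = c("win", "loss"),
                          block = c("1", "2", "3"),
                          tdcs = c("sham", "active"))
  d$order <- ifelse(d$participant_id %% 2 == 0, "af", "sf")
  d$y <- rnorm(nrow(d))
  a <- mixed_rm_anova(d, "y", within = c("valence", "block", "tdcs"),
                      between = "order")
  total <- sum((d$y - mean(d$y))^2)
  recomposed <- sum(tidy(a)$ss) + a$error_ss
  expect_lt(abs(total - recomposed) / total, 1e-8)
  expect_true(all(tidy(a)$F >= 0))
  expect_true(all(tidy(a)$ges >= 0 & tidy(a)$ges <= 1))
  # all main effects and interactions of the declared factors are present
  expect_equal(nrow(tidy(a)), 2^4 - 1)
})

test_that("constant responses give zero effects, not NaNs", {
  d <- tidyr::expand_grid(participant_id = 1:6, cond = c("a", "b"),
                          phase = c("pre", "post"))
  d$y <- 3.7
  a <- tidy(mixed_rm_anova(d, "y", within = c("cond", "phase")))
  expect_true(all(a$ss < 1e-20))
  expect_true(all(a$F == 0))
  expect_true(all(a$p == 1))
})

test_that("unbalanced or incomplete designs are refused", {
  d <- tidyr::expand_grid(participant_id = 1:6, cond = c("a", "b"))
  d$y <- rnorm(nrow(d))
  expect_error(mixed_rm_anova(d[-1, ], "y", within = "cond"),
               class = "iblt_validation_error")
  d$grp <- ifelse(d$participant_id <= 5, "g1", "g2")
  expect_error(mixed_rm_anova(d, "y", within = "cond", between = "grp"),
               class = "iblt_validation_error") # one participant in g2
  d2 <- d
  d2$grp[2] <- "g2" # participant 1 assigned to two between levels
  expect_error(mixed_rm_anova(d2, "y", within = "cond", between = "grp"),
               class = "iblt_validation_error")
})

# Reference values computed once with an independent implementation
# (pingouin 0.6.1: rm_anova / mixed_anova with effsize = "ng2") on this
# exact seeded dataset.
frozen_anova_data <- function() {
  set.seed(123)
  d <- tidyr::expand_grid(participant_id = 1:12,
                          block = c("b1", "b2", "b3"),
                          tdcs = c("sham", "active"))
  d$order <- ifelse(d$participant_id <= 6, "g1", "g2")
  d$y <- round(rnorm(nrow(d)) + 0.5 * (d$block == "b2") +
                 0.4 * (d$tdcs == "active") * (d$order == "g1"), 6)
  d
}

test_that("two-way within results agree with an independent implementation", {
  d <- frozen_anova_data()
  a <- tidy(mixed_rm_anova(d, "y", within = c("block", "tdcs")))
  blk <- a[a$effect == "block", ]
  expect_equal(blk$F, 3.614069, tolerance = 1e-4)
  expect_equal(blk$p, 0.043938, tolerance = 1e-4)
  expect_equal(blk$ges, 0.105023, tolerance = 1e-4)
  expect_equal(blk$gg_epsilon, 0.966404, tolerance = 1e-4)
  expect_equal(blk$p_gg, 0.045887, tolerance = 1e-4)
  td <- a[a$effect == "tdcs", ]
  expect_equal(td$F, 2.979359, tolerance = 1e-4)
  expect_equal(td$p, 0.112273, tolerance = 1e-4)
  expect_equal(td$ges, 0.015556, tolerance = 1e-4)
  ix <- a[a$effect == "block:tdcs", ]
  expect_equal(ix$F, 0.176709, tolerance = 1e-4)
  expect_equal(ix$ges, 0.007334, tolerance = 1e-4)
  expect_equal(ix$gg_epsilon, 0.956144, tolerance = 1e-4)
  expect_equal(ix$p_gg, 0.830070, tolerance = 1e-4)
})

test_that("mixed between/within F and p agree with an independent implementation", {
  d <- frozen_anova_data() |>
    dplyr::summarise(y = mean(y),
                     .by = c(participant_id, order, block))
  a <- tidy(mixed_rm_anova(d, "y", within = "block", between = "order"))
  expect_equal(a$F[a$effect == "order"], 1.629646, tolerance = 1e-4)
  expect_equal(a$p[a$effect == "order"], 0.230600, tolerance = 1e-4)
  expect_equal(a$F[a$effect == "block"], 3.902486, tolerance = 1e-4)
  expect_equal(a$p[a$effect == "block"], 0.037075, tolerance = 1e-4)
  expect_equal(a$F[a$effect == "order:block"], 1.877842, tolerance = 1e-4)
  expect_equal(a$p[a$effect == "order:block"], 0.178906, tolerance = 1e-4)
})
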