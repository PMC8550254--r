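# Statistical analysis layer: parameter transforms, mixed repeated-measures
# ANOVA with generalized eta-squared, and paired t-tests.
#
# The ANOVA handles the balanced fully-crossed designs used for this task
# (within factors such as outcome valence, block/time and stimulation
# condition; stimulation order between participants). The sums-of-squares
# decomposition is the classical multi-stratum one with participant as the
# blocking unit (via aov with Error strata); for balanced orthogonal
# designs all SS types coincide, so no type choice arises.

#' Transform parameter values onto the real line
#'
#' Learning rates are analysed after a logit transformation and inverse
#' temperatures after a log transformation; both are monotone and
#' invertible, so ordering is preserved.
#'
#' @param values Numeric vector.
#' @param kind `"logit"` (requires values in (0,1)), `"log"` (requires
#'   positive values) or `"identity"`.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' transform_parameter(c(0.5, 0.65), "logit")
transform_parameter <- function(values, kind = c("logit", "log", "identity")) {
  kind <- match.arg(kind)
  bad <- switch(kind,
    logit = which(!is.finite(values) | values <= 0 | values >= 1),
    log = which(!is.finite(values) | values <= 0),
    identity = integer(0)
  )
  if (length(bad) > 0) {
    abort_param(sprintf(
      "%s transform undefined for value(s) at position(s) %s.",
      kind, paste(head(bad, 5), collapse = ", ")
    ))
  }
  switch(kind,
    logit = qlogis(values),
    log = log(values),
    identity = values
  )
}

#' Paired t-test
#'
#' Classical paired t on matched vectors: `t = mean(d) / (sd(d) / sqrt(n))`
#' with `df = n - 1` and a two-sided p from the t distribution. Degenerate
#' differences are handled explicitly: all-zero differences give `t = 0`,
#' `p = 1`; zero variance around a nonzero mean gives an infinite t,
#' flagged, with `p = 0`.
#'
#' @param x,y Equal-length matched numeric vectors (`n >= 2`).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_diff`, `infinite_t`.
#' @export
#' @examples
#' paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort_param("`x` and `y` must be matched vectors of equal length >= 2.")
  }
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1, mean_diff = 0,
                            infinite_t = FALSE))
    }
    return(tibble::tibble(t = sign(m) * Inf, df = n - 1, p = 0, mean_diff = m,
                          infinite_t = TRUE))
  }
  tt <- m / (s / sqrt(n))
  tibble::tibble(
    t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1),
    mean_diff = m, infinite_t = FALSE
  )
}

# Orthonormal contrast matrix for a factor with l levels (l x (l-1)),
# columns orthogonal to the constant and to each other, unit norm.
orthonormal_contrasts <- function(l) {
  cm <- contr.helmert(l)
  sweep(cm, 2, sqrt(colSums(cm^2)), "/")
}

# Greenhouse-Geisser epsilon for a within-effect. wide: subjects x cells
# matrix of responses (cells ordered with the first within factor varying
# fastest); groups: between-group assignment per subject; C: cells x df
# contrast matrix of the effect.
gg_epsilon <- function(wide, groups, C) {
  d <- ncol(C)
  split_rows <- split(seq_len(nrow(wide)), groups)
  dof <- sum(vapply(split_rows, length, integer(1)) - 1)
  if (dof < 1) {
    return(NA_real_)
  }
  S <- Reduce(`+`, lapply(split_rows, function(rows) {
    if (length(rows) < 2) {
      return(matrix(0, ncol(wide), ncol(wide)))
    }
    (length(rows) - 1) * stats::cov(wide[rows, , drop = FALSE])
  })) / dof
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / (d * sum(M * M))
  min(1, max(1 / d, eps))
}

#' Mixed repeated-measures ANOVA
#'
#' Multi-stratum ANOVA for a balanced fully-crossed design with one or
#' more within-participant factors and optionally one or more
#' between-participant factors. Each within-factor combination defines its
#' own error stratum (participant-by-effect interaction); between effects
#' are tested against the between-participant stratum. Effect sizes are
#' generalized eta-squared (Olejnik-Algina; classical eta-squared behind
#' `effect_size = "classical"`). For within effects with more than one
#' numerator df a Greenhouse-Geisser-corrected p is reported additionally.
#'
#' Unbalanced or incomplete designs are an error: with a complete balanced
#' design all sums-of-squares types coincide, so no imputation or type
#' choice is ever made.
#'
#' @param data Long-format data frame, one row per participant x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-participant factor columns.
#' @param between Optional character vector of between-participant factor
#'   columns.
#' @param id Participant identifier column.
#' @param effect_size `"generalized"` (default) or `"classical"`.
#' @return An object of class `iblt_anova`; `tidy()` returns the effect
#'   table (`effect`, `df1`, `df2`, `ss`, `F`, `p`, `ges`, `gg_epsilon`,
#'   `p_gg`).
#' @export
#' @examples
#' d <- tidyr::expand_grid(participant_id = 1:8, valence = c("win", "loss"))
#' d$y <- rnorm(nrow(d)) + (d$valence == "loss")
#' tidy(mixed_rm_anova(d, "y", within = "valence"))
mixed_rm_anova <- function(data, dv, within, between = NULL,
                           id = "participant_id",
                           effect_size = c("generalized", "classical")) {
  effect_size <- match.arg(effect_size)
  cols <- c(id, dv, within, between)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort_param(sprintf("missing column(s): %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  d <- as.data.frame(data)[cols]
  for (f in c(id, within, between)) d[[f]] <- factor(d[[f]])
  if (!is.numeric(d[[dv]]) || anyNA(d[[dv]])) {
    abort_param("dependent variable must be numeric with no missing values.")
  }

  # balance: exactly one observation per participant x within-cell, and a
  # single between level per participant
  cell <- interaction(d[within], drop = FALSE)
  tab <- table(d[[id]], cell)
  if (any(tab != 1)) {
    abort_validation("design is unbalanced or incomplete: every participant needs exactly one observation per within-cell.")
  }
  if (!is.null(between)) {
    bcomb <- interaction(d[between], drop = FALSE)
    per_id <- tapply(bcomb, d[[id]], function(x) length(unique(x)))
    if (any(per_id != 1)) {
      abort_validation("each participant must have a single between-factor level.")
    }
    grp <- tapply(as.character(bcomb), d[[id]], `[`, 1)
    if (any(table(grp) < 2)) {
      abort_validation("need at least two participants per between-group.")
    }
  }

  fml <- as.formula(sprintf(
    "%s ~ %s + Error(%s/(%s))",
    dv,
    paste(c(between, within), collapse = " * "),
    id,
    paste(within, collapse = " * ")
  ))
  fit <- aov(fml, data = d)
  strata <- summary(fit)

  rows <- purrr::map_dfr(strata, function(stratum) {
    tb <- stratum[[1]]
    nm <- trimws(rownames(tb))
    res_i <- which(nm == "Residuals")
    if (length(res_i) == 0) {
      return(tibble::tibble())
    }
    ss_res <- tb[res_i, "Sum Sq"]
    df_res <- tb[res_i, "Df"]
    eff_i <- setdiff(seq_len(nrow(tb)), res_i)
    tibble::tibble(
      effect = nm[eff_i],
      df1 = tb[eff_i, "Df"],
      df2 = df_res,
      ss = tb[eff_i, "Sum Sq"],
      ss_error = ss_res,
      df_error = df_res
    )
  })

  total_error_ss <- sum(purrr::map_dbl(strata, function(stratum) {
    tb <- stratum[[1]]
    i <- which(trimws(rownames(tb)) == "Residuals")
    if (length(i) == 0) 0 else tb[i, "Sum Sq"]
  }))
  total_ss <- sum(rows$ss) + total_error_ss

  ms_eff <- rows$ss / rows$df1
  ms_err <- rows$ss_error / rows$df_error
  F_stat <- ifelse(rows$ss <= 1e-12 * max(total_ss, 1), 0,
                   ms_eff / ms_err)
  p_val <- ifelse(is.infinite(F_stat), 0,
                  pf(F_stat, rows$df1, rows$df2, lower.tail = FALSE))
  es <- if (effect_size == "generalized") {
    rows$ss / (rows$ss + total_error_ss)
  } else {
    rows$ss / total_ss
  }

  # Greenhouse-Geisser epsilon per within part, shared by all effects with
  # the same within factors (e.g. a between x within interaction uses its
  # within part's epsilon)
  lev <- lapply(within, function(w) levels(d[[w]]))
  names(lev) <- within
  cells <- do.call(expand.grid, c(lev, KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE))
  d$._cell <- interaction(d[within], drop = FALSE)
  cell_order <- interaction(cells, drop = FALSE)
  ids <- levels(d[[id]])
  wide <- matrix(NA_real_, length(ids), nrow(cells),
                 dimnames = list(ids, as.character(cell_order)))
  for (r in seq_len(nrow(d))) {
    wide[as.character(d[[id]][r]), as.character(d$._cell[r])] <- d[[dv]][r]
  }
  groups <- if (is.null(between)) {
    rep("all", length(ids))
  } else {
    as.character(tapply(as.character(interaction(d[between], drop = FALSE)),
                        d[[id]], `[`, 1)[ids])
  }

  eps_for_within_part <- function(wpart) {
    mats <- lapply(within, function(w) {
      l <- length(lev[[w]])
      if (w %in% wpart) orthonormal_contrasts(l) else matrix(1 / sqrt(l), l, 1)
    })
    C <- Reduce(kronecker, rev(mats))
    gg_epsilon(wide, groups, C)
  }

  parts <- strsplit(rows$effect, ":", fixed = TRUE)
  gg_eps <- p_gg <- rep(NA_real_, nrow(rows))
  for (i in seq_len(nrow(rows))) {
    wpart <- intersect(parts[[i]], within)
    if (length(wpart) == 0) next
    within_df <- prod(vapply(wpart, function(w) length(lev[[w]]) - 1L, integer(1)))
    if (within_df <= 1) next
    eps <- eps_for_within_part(wpart)
    gg_eps[i] <- eps
    if (!is.na(eps)) {
      p_gg[i] <- ifelse(
        is.infinite(F_stat[i]), 0,
        pf(F_stat[i], eps * rows$df1[i], eps * rows$df2[i], lower.tail = FALSE)
      )
    }
  }

  table <- tibble::tibble(
    effect = rows$effect,
    df1 = as.integer(rows$df1),
    df2 = as.integer(rows$df2),
    ss = rows$ss,
    F = F_stat,
    p = p_val,
    ges = es,
    gg_epsilon = gg_eps,
    p_gg = p_gg
  )
  structure(
    list(
      table = table,
      dv = dv, within = within, between = between, id = id,
      effect_size = effect_size,
      n_participants = length(ids),
      total_ss = total_ss,
      error_ss = total_error_ss,
      aov = fit
    ),
    class = "iblt_anova"
  )
}

#' @export
print.iblt_anova <- function(x, ...) {
  cat(sprintf(
    "<iblt_anova> dv = %s; within: %s%s; %d participants\n",
    x$dv, paste(x$within, collapse = ", "),
    if (is.null(x$between)) "" else
      paste0("; between: ", paste(x$between, collapse = ", ")),
    x$n_participants
  ))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.iblt_anova <- function(x, ...) {
  x$table
}

#' @export
glance.iblt_anova <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    n_effects = nrow(x$table),
    total_ss = x$total_ss,
    error_ss = x$error_ss,
    effect_size = x$effect_size
  )
}
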