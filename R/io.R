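# Trial-log IO, validation, flat key-value configs, and the end-to-end
# pipeline (simulate -> fit -> choice stats -> ANOVA -> manifest).

trial_log_cols <- function() {
  readr::cols(
    study = readr::col_character(),
    participant_id = readr::col_integer(),
    session_index = readr::col_integer(),
    tdcs_condition = readr::col_character(),
    tdcs_order = readr::col_character(),
    block_index = readr::col_integer(),
    block_type = readr::col_character(),
    trial = readr::col_integer(),
    p_win_A = readr::col_double(),
    p_loss_A = readr::col_double(),
    win_on_A = readr::col_integer(),
    loss_on_A = readr::col_integer(),
    choice = readr::col_character(),
    payoff_pence = readr::col_integer(),
    cumulative_pence = readr::col_integer()
  )
}

#' Read / write a trial log
#'
#' The shared comma-separated trial-log format (one header row, one row per
#' trial) is produced by [simulate_cohort()] and consumed by the fitting
#' and behavioural stages, so converted real data can enter the pipeline
#' the same way.
#'
#' @param path File path.
#' @return `read_trial_log()` returns a tibble.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) abort_param(sprintf("no such file: %s", path))
  readr::read_csv(path, col_types = trial_log_cols(), progress = FALSE)
}

#' @param trial_log A trial-log tibble.
#' @rdname read_trial_log
#' @export
write_trial_log <- function(trial_log, path) {
  readr::write_csv(trial_log, path, progress = FALSE)
  invisible(path)
}

#' Validate a trial log against the task's structural invariants
#'
#' Checks the schema (required columns), the payoff rule (+10p for a win
#' over the chosen stimulus, -10p for a loss, zero when win and loss
#' co-locate), block lengths, probability levels, contiguous 1-based trial
#' indices, and the running-total bookkeeping. All violations are
#' collected, not just the first.
#'
#' @param x A trial-log tibble or a path to one.
#' @param n_trials Expected trials per block.
#' @param levels Permitted outcome-on-A probability levels.
#' @return A list of class `iblt_validation`: `valid` (logical), `data`
#'   (the parsed table), `diagnostics` (tibble of `check`, `message`,
#'   `n_rows`).
#' @export
validate_trial_log <- function(x, n_trials = 80L,
                               levels = c(0.2, 0.5, 0.8)) {
  log <- if (is.character(x)) read_trial_log(x) else tibble::as_tibble(x)
  diags <- list()
  note <- function(check, message, n_rows = NA_integer_) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      check = check, message = message, n_rows = as.integer(n_rows)
    )
  }

  required <- names(trial_log_cols()$cols)
  miss <- setdiff(required, names(log))
  if (length(miss) > 0) {
    note("schema", sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    return(structure(
      list(valid = FALSE, data = log, diagnostics = dplyr::bind_rows(diags)),
      class = "iblt_validation"
    ))
  }

  chose_A <- log$choice == "A"
  expected_payoff <- trial_payoff(chose_A, log$win_on_A, log$loss_on_A)
  bad <- which(log$payoff_pence != expected_payoff)
  if (length(bad) > 0) {
    note("payoff_rule",
         sprintf("payoff_pence inconsistent with outcome locations (first at row %d)", bad[1]),
         length(bad))
  }
  both <- log$win_on_A == log$loss_on_A
  bad <- which(both & log$payoff_pence != 0)
  if (length(bad) > 0) {
    note("payoff_rule", "nonzero payoff on a both-outcome trial", length(bad))
  }
  bad <- which(!log$p_win_A %in% levels | !log$p_loss_A %in% levels)
  if (length(bad) > 0) {
    note("probability_levels",
         sprintf("probabilities outside {%s}", paste(levels, collapse = ", ")),
         length(bad))
  }
  bad <- which(!log$choice %in% c("A", "B") |
                 !log$win_on_A %in% 0:1 | !log$loss_on_A %in% 0:1)
  if (length(bad) > 0) {
    note("coding", "choice/outcome columns outside their codes", length(bad))
  }

  grouped <- split(
    log,
    interaction(log$participant_id, log$session_index, log$block_index,
                drop = TRUE)
  )
  for (g in grouped) {
    g <- g[order(g$trial), ]
    if (nrow(g) != n_trials) {
      note("block_length", sprintf(
        "participant %s session %s block %s has %d trials (expected %d)",
        g$participant_id[1], g$session_index[1], g$block_index[1],
        nrow(g), n_trials
      ), nrow(g))
    }
    if (!identical(as.integer(g$trial), seq_len(nrow(g)))) {
      note("trial_index", sprintf(
        "participant %s session %s block %s: trial indices not contiguous from 1",
        g$participant_id[1], g$session_index[1], g$block_index[1]
      ))
    }
  }
  for (s in split(log, interaction(log$participant_id, log$session_index,
                                   drop = TRUE))) {
    s <- s[order(s$block_index, s$trial), ]
    if (!identical(as.integer(s$cumulative_pence),
                   as.integer(150L + cumsum(s$payoff_pence)))) {
      note("cumulative", sprintf(
        "participant %s session %s: cumulative_pence does not track 150 + running payoff",
        s$participant_id[1], s$session_index[1]
      ))
    }
  }

  diagnostics <- if (length(diags) == 0) {
    tibble::tibble(check = character(), message = character(),
                   n_rows = integer())
  } else {
    dplyr::bind_rows(diags)
  }
  structure(
    list(valid = nrow(diagnostics) == 0, data = log, diagnostics = diagnostics),
    class = "iblt_validation"
  )
}

#' @export
print.iblt_validation <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<iblt_validation> OK: %d rows, no diagnostics\n", nrow(x$data)))
  } else {
    cat(sprintf("<iblt_validation> FAILED: %d diagnostic(s)\n",
                nrow(x$diagnostics)))
    print(as.data.frame(x$diagnostics))
  }
  invisible(x)
}

#' Pipeline run configuration
#'
#' A flat set of keys controlling an end-to-end run. Every key can be
#' stored in (and read back from) a plain `key = value` text file via
#' [write_run_config()] / [read_run_config()].
#'
#' @param study Study arm to emulate.
#' @param seed Master seed (mandatory; every stage derives a named
#'   substream from it via [substream_seed()]).
#' @param n_participants Cohort size.
#' @param volatility_adaptive Simulate volatility-adaptive agents?
#' @param n_alpha,n_beta,n_t Grid resolution for fitting.
#' @param omit_first Leading trials per block excluded from likelihoods.
#' @return A list of class `iblt_run_config`.
#' @export
run_config <- function(study = "negative_training",
                       seed = NULL,
                       n_participants = 20L,
                       volatility_adaptive = TRUE,
                       n_alpha = 30L, n_beta = 25L, n_t = 15L,
                       omit_first = 10L) {
  if (is.null(seed)) abort_param("`seed` is mandatory in a run config.")
  if (!study %in% c("negative_training", "positive_training")) {
    abort_param("`study` must be 'negative_training' or 'positive_training'.")
  }
  structure(
    list(
      study = study, seed = as.integer(seed),
      n_participants = as.integer(n_participants),
      volatility_adaptive = isTRUE(volatility_adaptive),
      n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
      n_t = as.integer(n_t), omit_first = as.integer(omit_first)
    ),
    class = "iblt_run_config"
  )
}

#' @param config An `iblt_run_config`.
#' @param path File path of the flat key-value document.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, as.character(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_param(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(
    lapply(kv, function(p) p[2]),
    vapply(kv, function(p) p[1], character(1))
  )
  cast <- function(key, f, default) if (key %in% names(vals)) f(vals[[key]]) else default
  run_config(
    study = cast("study", identity, "negative_training"),
    seed = cast("seed", as.integer, NULL),
    n_participants = cast("n_participants", as.integer, 20L),
    volatility_adaptive = cast("volatility_adaptive", \(x) tolower(x) %in% c("true", "1", "yes"), TRUE),
    n_alpha = cast("n_alpha", as.integer, 30L),
    n_beta = cast("n_beta", as.integer, 25L),
    n_t = cast("n_t", as.integer, 15L),
    omit_first = cast("omit_first", as.integer, 10L)
  )
}

# ANOVAs mirroring the primary hypothesis tests: outcome valence x block x
# stimulation (within) with stimulation order between, run separately on
# training blocks (block 2-4) and both-volatile blocks (pre/post).
pipeline_anovas <- function(param_table, choice_table) {
  long <- param_table |>
    tidyr::pivot_longer(c(alpha_win, alpha_loss),
                        names_to = "outcome_valence", names_prefix = "alpha_",
                        values_to = "alpha") |>
    dplyr::mutate(alpha_logit = transform_parameter(alpha, "logit"))

  training <- long |>
    dplyr::filter(block_type != "both_volatile") |>
    dplyr::mutate(block = block_index - 1L)
  volatile <- long |>
    dplyr::filter(block_type == "both_volatile") |>
    dplyr::mutate(time = ifelse(block_index == 1, "pre", "post"))

  res <- list(
    training_alpha = mixed_rm_anova(
      training, "alpha_logit",
      within = c("outcome_valence", "block", "tdcs_condition"),
      between = "tdcs_order"
    ),
    volatile_alpha = mixed_rm_anova(
      volatile, "alpha_logit",
      within = c("outcome_valence", "time", "tdcs_condition"),
      between = "tdcs_order"
    )
  )
  if (!is.null(choice_table)) {
    ct <- choice_table |>
      dplyr::filter(block_type != "both_volatile") |>
      dplyr::mutate(block = block_index - 1L)
    res$training_win_driven <- mixed_rm_anova(
      ct, "p_win_driven",
      within = c("block", "tdcs_condition"),
      between = "tdcs_order"
    )
  }
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit -> behavioural statistic -> ANOVA and writes
#' five artifacts to `out_dir`: `trial_log.csv`, `parameters.csv`,
#' `choice_stats.csv`, `anova_report.csv`, and `manifest.json` (config,
#' seed, package version and MD5 digests of every output, sufficient to
#' reproduce the run bit-identically).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   results (`trial_log`, `parameters`, `choice_stats`, `anovas`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "iblt_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  spec <- cohort_spec(
    n_participants = config$n_participants,
    volatility_adaptive = config$volatility_adaptive
  )
  trial_log <- simulate_cohort(spec, config$study,
                               seed = substream_seed(config$seed, "simulate"))
  check <- validate_trial_log(trial_log)
  if (!check$valid) {
    abort_validation("stage 'simulate' produced an invalid trial log.",
                     diagnostics = check$diagnostics)
  }
  grid <- parameter_grid(n_alpha = config$n_alpha, n_beta = config$n_beta,
                         n_t = config$n_t)
  params <- fit_dataset(trial_log, grid, omit_first = config$omit_first)
  choices <- win_driven_table(trial_log)
  anovas <- pipeline_anovas(params, choices)
  report <- purrr::imap_dfr(anovas, function(a, nm) {
    dplyr::mutate(tidy(a), analysis = nm, .before = 1)
  })

  paths <- list(
    trial_log = file.path(out_dir, "trial_log.csv"),
    parameters = file.path(out_dir, "parameters.csv"),
    choice_stats = file.path(out_dir, "choice_stats.csv"),
    anova_report = file.path(out_dir, "anova_report.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_trial_log(trial_log, paths$trial_log)
  readr::write_csv(params, paths$parameters, progress = FALSE)
  readr::write_csv(choices, paths$choice_stats, progress = FALSE)
  readr::write_csv(report, paths$anova_report, progress = FALSE)

  digests <- vapply(
    paths[c("trial_log", "parameters", "choice_stats", "anova_report")],
    function(p) unname(tools::md5sum(p)), character(1)
  )
  manifest <- list(
    package = "iblt",
    version = as.character(utils::packageVersion("iblt")),
    config = unclass(config),
    digests = as.list(digests)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    paths = paths,
    trial_log = trial_log,
    parameters = params,
    choice_stats = choices,
    anovas = anovas
  ))
}
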