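# I/O, configuration, pipeline orchestration and run reproducibility.

# -- Trial-level CSV ---------------------------------------------------------

#' Write trajectories to a trial-level CSV
#'
#' Schema: subject_id, timepoint, round, investment_raw, investment_bin,
#' repayment (UTF-8, header row).  Investments are grid representatives, so
#' `investment_raw` equals `investment_bin`; repayments are written rounded
#' half-up to whole coins in `repayment_display` alongside the exact value.
#'
#' @param trajs List of [game_trajectory()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    data.frame(
      subject_id = tr$subject_id,
      timepoint = tr$timepoint,
      round = tr$rounds$round,
      investment_raw = as.integer(tr$rounds$a_i),
      investment_bin = as.integer(tr$rounds$a_i),
      repayment = tr$rounds$a_t,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read trajectories from a trial-level CSV
#'
#' Validates the schema, bins raw investments via
#' [discretize_investment()], checks repayments against the legal set for
#' each binned investment, and requires complete games.  Malformed
#' subject-sessions are collected into an error report; well-formed ones are
#' returned.
#'
#' @param path CSV file with columns subject_id, timepoint, round,
#'   investment_raw, repayment (investment_bin optional; recomputed).
#' @param n_rounds Required rounds per session.
#' @return List with `trajectories` and `errors` (data frame: subject_id,
#'   timepoint, problem).
#' @export
read_trials <- function(path, n_rounds = N_ROUNDS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("subject_id", "timepoint", "round", "investment_raw", "repayment")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$subject_id, df$timepoint, sep = "\r")
  trajs <- list()
  errs <- list()
  for (kk in unique(key)) {
    sub <- df[key == kk, , drop = FALSE]
    sid <- sub$subject_id[1L]
    tp <- sub$timepoint[1L]
    problem <- NULL
    sub <- sub[order(sub$round), , drop = FALSE]
    if (nrow(sub) != n_rounds) {
      problem <- paste0("expected ", n_rounds, " rounds, found ", nrow(sub))
    } else if (!identical(as.integer(sub$round), seq_len(n_rounds))) {
      problem <- "round indices must be 1..n without gaps or duplicates"
    } else {
      tr <- tryCatch({
        bins <- discretize_investment(sub$investment_raw)
        game_trajectory(bins, sub$repayment, subject_id = sid,
                        timepoint = tp, n_rounds = n_rounds)
      }, error = function(e) conditionMessage(e))
      if (is.character(tr)) problem <- tr else {
        trajs[[length(trajs) + 1L]] <- tr
      }
    }
    if (!is.null(problem)) {
      errs[[length(errs) + 1L]] <- data.frame(
        subject_id = sid, timepoint = tp, problem = problem,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    trajectories = trajs,
    errors = if (length(errs)) do.call(rbind, errs) else
      data.frame(subject_id = character(0), timepoint = character(0),
                 problem = character(0), stringsAsFactors = FALSE)
  )
}

# -- Run configuration -------------------------------------------------------

#' Assemble a run configuration
#'
#' Either reads a YAML file or takes a named list; unspecified settings get
#' defaults.  Settings: `seed`, `n_subjects`, `grid` (`"reduced"` or
#' `"full"`), `scope`, `models` (variant names), `fairness_threshold`, and
#' any [cohort_config()] field under `cohort`.
#'
#' @param config Path to a YAML file, or a named list, or NULL for defaults.
#' @param ... Overrides applied on top.
#' @return List of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(
    seed = 1L,
    n_subjects = 30L,
    grid = "reduced",
    scope = "both_players",
    models = paste0("M", 1:5),
    fairness_threshold = 1 / 3,
    cohort = list()
  )
  over <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, config), over)
  class(cfg) <- "run_config"
  cfg
}

# -- Pipeline ----------------------------------------------------------------

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(msg)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: generate the cohort, compute behavioural trust indices, fit the
#' full model per subject-session, compare model variants, decompose age,
#' and fit the longitudinal mixed models (trust-on-age and
#' friendship-on-trust designs).  All outputs are written as CSV plus a JSON
#' run manifest and a plain-text log; a rerun with the same configuration
#' reproduces the outputs byte for byte.
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @param out_dir Output directory (created if needed).
#' @return List with the stage results, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("trustrun")) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  stage <- "generate"
  result <- tryCatch({
    t0 <- proc.time()[[3L]]
    cohort_args <- config$cohort
    cohort_args$seed <- config$seed
    cohort_args$n_subjects <- config$n_subjects
    cc <- do.call(cohort_config, cohort_args)
    syn <- generate_cohort(cc)
    write_trials(syn$trajectories, file.path(out_dir, "trials.csv"))
    utils::write.csv(syn$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(syn$cfq, file.path(out_dir, "cfq.csv"), row.names = FALSE)
    .log_line(log_path, "generate: ", length(syn$trajectories), " games in ",
              round(proc.time()[[3L]] - t0, 2), "s")

    stage <- "metrics"
    t0 <- proc.time()[[3L]]
    metrics <- do.call(rbind, lapply(syn$trajectories, trust_indices,
                                     fairness_threshold = config$fairness_threshold))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    .log_line(log_path, "metrics: ", nrow(metrics), " rows in ",
              round(proc.time()[[3L]] - t0, 2), "s")

    stage <- "fit"
    t0 <- proc.time()[[3L]]
    grid <- if (identical(config$grid, "full")) {
      parameter_grid()
    } else if (identical(config$grid, "reduced")) {
      parameter_grid(reduced = TRUE, plan = 1L, q = c(0L, 2L))
    } else {
      do.call(parameter_grid, config$grid)  # explicit level lists
    }
    specs <- lapply(config$models, model_spec)
    comparison <- compare_models(syn$trajectories, specs, grid = grid,
                                 scope = config$scope)
    utils::write.csv(comparison$fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$summary,
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    .log_line(log_path, "fit: ", nrow(comparison$fits), " fits over ",
              nrow(grid), " grid points in ",
              round(proc.time()[[3L]] - t0, 2), "s")

    stage <- "longitudinal"
    t0 <- proc.time()[[3L]]
    m1_fits <- comparison$fits[comparison$fits$model == "M1", ]
    tab <- merge(syn$cohort, metrics, by = c("subject_id", "timepoint"))
    tab <- merge(tab, m1_fits[, c("subject_id", "timepoint", "omega", "zeta")],
                 by = c("subject_id", "timepoint"))
    tab <- decompose_age(tab)
    trust_model <- fit_longitudinal_model(
      tab, outcome = "mean_trust",
      fixed = c("longitudinal_age", "cross_sectional_age", "sex"),
      interactions = list(c("longitudinal_age", "cross_sectional_age"))
    )
    utils::write.csv(trust_model$fixed,
                     file.path(out_dir, "trust_age_model.csv"),
                     row.names = FALSE)
    cfq_tab <- syn$cfq
    cfq_tab$age <- cfq_tab$age_at_wave
    cfq_tab <- decompose_age(cfq_tab)
    cfq_model <- fit_longitudinal_model(
      cfq_tab, outcome = "cfq",
      fixed = c("trust_t1", "longitudinal_age", "adversity", "sex"),
      interactions = list(c("trust_t1", "longitudinal_age"),
                          c("trust_t1", "adversity"),
                          c("longitudinal_age", "adversity"),
                          c("trust_t1", "longitudinal_age", "adversity"))
    )
    utils::write.csv(cfq_model$fixed, file.path(out_dir, "cfq_model.csv"),
                     row.names = FALSE)
    .log_line(log_path, "longitudinal: fitted in ",
              round(proc.time()[[3L]] - t0, 2), "s")

    manifest <- list(
      package = "trustmrt",
      version = as.character(utils::packageVersion("trustmrt")),
      config = unclass(config),
      files = list.files(out_dir)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(cohort = syn, metrics = metrics, comparison = comparison,
         trust_model = trust_model, cfq_model = cfq_model,
         out_dir = out_dir)
  }, error = function(e) {
    .log_line(log_path, "FAILED at stage '", stage, "': ",
              conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
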