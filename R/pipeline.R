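#' Configure the end-to-end analysis pipeline
#'
#' Validates and assembles the configuration for
#' simulate -> preprocess -> fit -> predict -> report. Unknown keys are
#' rejected; model entries must request at least two chains (split R-hat is
#' undefined otherwise). A single global seed deterministically expands into
#' per-stage sub-seeds (`seed * 7919 + stage_index * 104729, mod 2^31 - 1`).
#'
#' @param out_dir root directory for all artifacts.
#' @param sim a [sim_config()].
#' @param models named list; each element a list of [model_spec()] arguments
#'   (e.g. `list(model = "transition", variant = "age_rank")`).
#' @param curves curve requests passed to [render_report()] (optional).
#' @param seed global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            models = list(
                              transition_age_rank = list(model = "transition",
                                                         variant = "age_rank"),
                              mortality_age_rank = list(model = "mortality",
                                                        variant = "age_rank")),
                            curves = NULL, seed = 1L) {
  if (!inherits(sim, "sim_config")) stop("sim must come from sim_config()")
  if (!length(models)) stop("at least one model must be configured")
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a named list")
  for (nm in names(models)) {
    m <- models[[nm]]
    known <- names(formals(model_spec))
    bad <- setdiff(names(m), known)
    if (length(bad))
      stop("unknown keys in model '", nm, "': ", paste(bad, collapse = ", "))
    if (!is.null(m$chains) && m$chains < 2)
      stop("model '", nm, "': chains must be >= 2")
  }
  structure(list(out_dir = out_dir, sim = sim, models = models,
                 curves = curves, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + stage_index * 104729) %% (2^31 - 1))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, writing each stage's artifacts
#' under `out_dir` and hashing every file into `manifest.json`. A failing
#' stage halts the run with an error while preserving the partial outputs.
#' One structured log line is emitted at each stage boundary with row counts
#' and timing.
#'
#' @param config a [pipeline_config()], or the path to a JSON file with the
#'   same structure (`sim` and `models` given as argument lists).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `status` (`"ok"`) and the artifact
#'   `manifest` (file -> md5).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config_from_json(config)
  if (!inherits(config, "pipeline_config")) stop("config must come from pipeline_config()")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_all <- Sys.time()

  # stage 1: simulate
  t0 <- Sys.time()
  sim <- config$sim
  sim$seed <- stage_seed(config$seed, 1L)
  bundle <- simulate_population(sim)
  write_bundle(bundle, file.path(out, "sim"))
  say("[simulate] %d males, %d events, %d state records (%.1fs)",
      nrow(bundle$males), nrow(bundle$events), nrow(bundle$states),
      as.numeric(Sys.time() - t0, units = "secs"))

  # stage 2: preprocess
  t0 <- Sys.time()
  bundle2 <- read_bundle(file.path(out, "sim"))
  design <- preprocess_cohort(bundle2)
  dir.create(file.path(out, "design"), showWarnings = FALSE)
  tr_out <- design$transitions
  tr_out$origin_state <- state_code(tr_out$origin_state)
  tr_out$outcome <- state_code(tr_out$outcome)
  write.csv(tr_out, file.path(out, "design", "transitions.csv"), row.names = FALSE)
  write.csv(design$paternity, file.path(out, "design", "paternity_design.csv"),
            row.names = FALSE)
  write.csv(design$weight_change, file.path(out, "design", "weightchange_design.csv"),
            row.names = FALSE)
  write.csv(design$lrs, file.path(out, "design", "lrs_design.csv"), row.names = FALSE)
  say("[preprocess] %d transitions, %d paternity rows, %d weight changes, %d LRS rows (%.1fs)",
      nrow(design$transitions), nrow(design$paternity),
      nrow(design$weight_change), nrow(design$lrs),
      as.numeric(Sys.time() - t0, units = "secs"))

  # stage 3: fit
  fits <- list()
  scaler <- NULL
  for (i in seq_along(config$models)) {
    t0 <- Sys.time()
    nm <- names(config$models)[i]
    args <- config$models[[i]]
    args$seed <- stage_seed(config$seed, 2L + i)
    spec <- do.call(model_spec, args)
    dat <- switch(spec$model,
                  transition = design$transitions, mortality = design$transitions,
                  paternity = design$paternity, weight_change = design$weight_change,
                  lrs = design$lrs)
    fit <- if (spec$model == "weight_change") {
      do.call(fit_weight_change, c(list(design$weight_change),
                                   args[setdiff(names(args), "model")]))
    } else {
      fit_mcmc(spec, dat)
    }
    fits[[nm]] <- fit
    if (is.null(scaler) && spec$model %in% c("transition", "mortality"))
      scaler <- fit$scaler
    dir.create(file.path(out, "fits"), showWarnings = FALSE)
    write.csv(cbind(draw = seq_len(nrow(draws_matrix(fit))),
                    as.data.frame(signif(draws_matrix(fit), 8))),
              file.path(out, "fits", paste0(nm, "_draws.csv")), row.names = FALSE)
    jsonlite::write_json(
      list(model = spec$model, variant = spec$variant,
           n_obs = fit$n_obs, max_rhat = max(fit$rhat, na.rm = TRUE),
           summary = fit$summary),
      file.path(out, "fits", paste0(nm, "_summary.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    say("[fit:%s] %s/%s, %d obs, max R-hat %.3f (%.1fs)", nm, spec$model,
        spec$variant, fit$n_obs, max(fit$rhat, na.rm = TRUE),
        as.numeric(Sys.time() - t0, units = "secs"))
  }
  if (!is.null(scaler)) scaler_to_json(scaler, file.path(out, "design", "scaler.json"))

  # stages 4-5: predict + report
  t0 <- Sys.time()
  render_report(fits, transitions = design$transitions,
                out_dir = file.path(out, "report"), curves = config$curves)
  say("[report] written to %s (%.1fs)", file.path(out, "report"),
      as.numeric(Sys.time() - t0, units = "secs"))

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- substring(names(manifest), nchar(out) + 2)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"), auto_unbox = TRUE)
  say("[done] %d artifacts in %.1fs", length(manifest),
      as.numeric(Sys.time() - t_all, units = "secs"))
  invisible(list(status = "ok", manifest = manifest))
}

pipeline_config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  known <- c("out_dir", "sim", "models", "curves", "seed")
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown pipeline config keys: ", paste(bad, collapse = ", "))
  sim_args <- x$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) stop("unknown sim config keys: ", paste(bad, collapse = ", "))
  pipeline_config(out_dir = x$out_dir,
                  sim = do.call(sim_config, sim_args),
                  models = x$models %||% NULL,
                  curves = x$curves, seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
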