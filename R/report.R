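#' Write a human-readable analysis report
#'
#' Serializes parameter summaries, posterior-predictive curves and the raw
#' mortality contingency table for a set of fitted models into an output
#' directory: `params_<model>.csv` per fit, `curves/<name>.csv` per
#' requested curve, `raw_mortality.csv` and a `report.md` overview. Output
#' is deterministic given identical inputs, so re-running produces
#' byte-identical tables.
#'
#' @param fits named list of `posterior_draws` objects (at least one).
#' @param transitions transition table used for the raw mortality summary
#'   (optional).
#' @param out_dir output directory, created if needed.
#' @param curves named list of curve requests, each a list of arguments for
#'   [predict_curve()] (minus `fit`, plus `fit_name` naming an entry of
#'   `fits`). Defaults draw the standard guard-gain and guard-loss curves
#'   against group-centred weight when a transition fit is present.
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(fits, transitions = NULL, out_dir, curves = NULL) {
  if (length(fits) == 0)
    stop("no fitted models supplied: run fit_mcmc()/fit_transition() first, ",
         "then pass the fits to render_report()")
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list")
  dir.create(file.path(out_dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  written <- character()

  for (nm in names(fits)) {
    p <- file.path(out_dir, paste0("params_", nm, ".csv"))
    s <- fits[[nm]]$summary
    s[-1] <- lapply(s[-1], function(x) signif(x, 8))
    write.csv(s, p, row.names = FALSE)
    written <- c(written, p)
  }

  if (is.null(curves)) {
    curves <- list()
    tr <- which(vapply(fits, function(f) f$spec$model == "transition", logical(1)))
    if (length(tr)) {
      f1 <- names(fits)[tr[1]]
      gcw_grid <- seq(-300, 300, by = 50)
      curves$gain_guard_vs_gcw <- list(fit_name = f1, covariate = "gcw",
                                       grid = gcw_grid, origin = "subordinate",
                                       destination = "guard")
      curves$lose_guard_vs_gcw <- list(fit_name = f1, covariate = "gcw",
                                       grid = gcw_grid, origin = "guard",
                                       destination = "subordinate")
    }
  }
  for (nm in names(curves)) {
    rq <- curves[[nm]]
    fit <- fits[[rq$fit_name]]
    if (is.null(fit)) stop("curve '", nm, "' references unknown fit '", rq$fit_name, "'")
    rq$fit_name <- NULL
    cv <- do.call(predict_curve, c(list(fit = fit), rq))
    cv[] <- lapply(cv, function(x) if (is.numeric(x)) signif(x, 8) else x)
    p <- file.path(out_dir, "curves", paste0(nm, ".csv"))
    write.csv(cv, p, row.names = FALSE)
    written <- c(written, p)
  }

  if (!is.null(transitions)) {
    rm_tab <- summarize_raw_mortality(transitions)
    p <- file.path(out_dir, "raw_mortality.csv")
    write.csv(rm_tab, p, row.names = FALSE)
    written <- c(written, p)
  }

  md <- c("# Multistate reproductive life-history report", "",
          paste0("Models fitted: ", paste(names(fits), collapse = ", ")), "")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    md <- c(md, paste0("## ", nm), "",
            paste0("- model: ", f$spec$model,
                   if (f$spec$variant != "none") paste0(" (", f$spec$variant, ")")),
            paste0("- observations: ", f$n_obs),
            paste0("- draws: ", dim(f$draws)[1], " x ", dim(f$draws)[2], " chains"),
            paste0("- max R-hat: ", round(max(f$rhat, na.rm = TRUE), 4)), "")
  }
  if (!is.null(transitions)) {
    md <- c(md, "## Raw mortality by state and weight class", "",
            "See raw_mortality.csv; percent = 100 * deaths / totals.", "")
  }
  p <- file.path(out_dir, "report.md")
  writeLines(md, p)
  written <- c(written, p)
  invisible(written)
}
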