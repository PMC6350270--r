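#' Run the full ex vivo / in vivo scoring pipeline
#'
#' Executes the complete analysis on a synthetic scenario or on explant and
#' caliper tables: per-explant frequencies are summarized into per-drug
#' VitroF scores, caliper pairs are converted to volumes and scored as
#' VivoF, and the paired scores are assessed for concordance. Results are
#' returned and, when `out_dir` is given, written as CSV/JSON together with
#' a run manifest; figures are written when `plots = TRUE`.
#'
#' @param scenario A [scenario_config()] object (simulated inputs), or
#'   `NULL` when `explants` and `calipers` are supplied directly.
#' @param explants,calipers Tibbles of staining records and caliper records;
#'   ignored when `scenario` is given.
#' @param control_label Control arm label (taken from the scenario when one
#'   is given).
#' @param out_dir Optional output directory; created if missing.
#' @param seed Seed for the bootstrap and permutation streams.
#' @param n_boot,n_perm Bootstrap / permutation sizes (0 disables either).
#' @param plots Write scatter, growth-curve and bar-chart PNGs to `out_dir`.
#'   Plot files are best-effort: a missing graphics device degrades to a
#'   warning, never an error.
#' @return Invisibly, a list of class `teva_report`: `vitro` and `vivo`
#'   score tibbles, `pairs`, `concordance` (a [concordance()] object),
#'   `ranking`, `volumes`, and `manifest`.
#' @examples
#' cfg <- scenario_config(seed = 7, drug_effects = sample_drug_effects(5, seed = 7))
#' rep <- teva_run(cfg, n_boot = 100, n_perm = 200)
#' glance(rep$concordance)
#' @export
teva_run <- function(scenario = NULL, explants = NULL, calipers = NULL,
                     control_label = "vehicle", out_dir = NULL, seed = 1,
                     n_boot = 1000, n_perm = 10000, plots = FALSE) {
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "teva_scenario"))
    control_label <- scenario$control_label
    seed <- scenario$seed
    explants <- simulate_explants(scenario)
    calipers <- simulate_growth(scenario)
  }
  if (is.null(explants) || is.null(calipers)) {
    abort("Provide either `scenario` or both `explants` and `calipers`.")
  }

  vitro <- run_stage("explant_scoring",
                     vitro_scores(explants, control_label,
                                  n_boot = n_boot, seed = seed))
  volumes <- run_stage("invivo_scoring", caliper_volumes(calipers))
  vivo <- run_stage("invivo_scoring", vivo_scores(volumes, control_label))

  pairs <- dplyr::inner_join(
    dplyr::select(vitro, "drug", "vitro_f"),
    dplyr::select(vivo, "drug", "vivo_f"),
    by = "drug"
  )
  if ("patient" %in% names(explants)) {
    pairs <- dplyr::mutate(pairs, patient = explants$patient[1], .before = 1)
  }
  conc <- run_stage("concordance", concordance(pairs, n_perm = n_perm, seed = seed))
  ranking <- rank_drugs(vitro)

  manifest <- run_manifest(seed = seed, control_label = control_label,
                           n_boot = n_boot, n_perm = n_perm,
                           explants = explants, calipers = calipers)

  report <- structure(
    list(vitro = vitro, vivo = vivo, pairs = pairs, concordance = conc,
         ranking = ranking, volumes = volumes, manifest = manifest),
    class = "teva_report"
  )

  if (!is.null(out_dir)) write_report(report, out_dir, plots = plots)
  invisible(report)
}

# Re-raise stage errors with the stage name so pipeline failures are
# attributable.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' @export
print.teva_report <- function(x, ...) {
  cat("<teva_report>\n\nVitroF scores:\n")
  print(x$vitro)
  cat("\nVivoF scores:\n")
  print(x$vivo)
  cat("\n")
  print(x$concordance)
  invisible(x)
}

run_manifest <- function(seed, control_label, n_boot, n_perm,
                         explants, calipers) {
  list(
    tool = "tevascore",
    version = as.character(utils::packageVersion("tevascore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = list(control_label = control_label,
                      n_boot = n_boot, n_perm = n_perm),
    input_digests = list(
      explants = table_digest(explants),
      calipers = table_digest(calipers)
    )
  )
}

# Cheap content fingerprint of a table (dimensions + column sums + a
# polynomial hash of the serialized text); enough to tie a report to its
# inputs without a cryptographic-hash dependency.
table_digest <- function(df) {
  txt <- paste(utils::capture.output(
    utils::write.csv(as.data.frame(df), row.names = FALSE)
  ), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%dx%d-%d", nrow(df), ncol(df), h)
}

write_report <- function(report, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$vitro, file.path(out_dir, "scores_vitro.csv"))
  readr::write_csv(report$vivo, file.path(out_dir, "scores_vivo.csv"))
  readr::write_csv(report$volumes, file.path(out_dir, "volumes.csv"))
  readr::write_csv(report$ranking, file.path(out_dir, "ranking.csv"))

  conc <- report$concordance
  jsonlite::write_json(
    list(pairs = conc$pairs, n = conc$n, r = conc$r, slope = conc$slope,
         intercept = conc$intercept, spearman_rho = conc$spearman_rho,
         p_perm = conc$p_perm, n_perm = conc$n_perm, top_drug = conc$top_drug),
    file.path(out_dir, "concordance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (plots) {
    save_plot <- function(p, file) {
      tryCatch(
        suppressMessages(ggplot2::ggsave(file.path(out_dir, file), p,
                                         width = 6, height = 4, dpi = 150)),
        error = function(e) warn(sprintf("Could not write %s: %s",
                                         file, conditionMessage(e)))
      )
    }
    save_plot(autoplot(report$concordance), "concordance.png")
    save_plot(plot_growth_curves(report$volumes), "growth_curves.png")
    save_plot(plot_vitro_scores(report$vitro), "vitro_scores.png")
  }
  invisible(out_dir)
}
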