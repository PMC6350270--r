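#' Summarize a marker's object frequencies per group
#'
#' Computes each explant's positive-object frequency
#' (`positive_count / tumor_area_mm2`, pcs/mm^2), averages frequencies
#' within each group, and normalizes group means so the control group sits
#' at 100 (the "normalized value with respect to control" convention used
#' on grouped bar charts).
#'
#' Zero control means are marker-specific: a zero control Ki67 mean leaves
#' the anti-proliferative term undefined and is an error; a zero control
#' TUNEL mean (apoptosis can genuinely be absent in the vehicle arm) is
#' floored at 1 pcs/mm^2 and the summary flagged `floored`.
#'
#' @param records Tibble of explant staining records with columns `group`,
#'   `marker`, `positive_count`, `tumor_area_mm2` (see
#'   [simulate_explants()] / [read_explant_table()]).
#' @param marker `"Ki67"` or `"TUNEL"`.
#' @param control_label Label of the control group.
#' @return A tibble with one row per group: `group`, `marker`, `n_explants`,
#'   `mean_frequency` (pcs/mm^2), `normalized_value` (control = 100),
#'   `floored` (logical).
#' @examples
#' rec <- tibble::tibble(
#'   group = c("vehicle", "vehicle", "drugA", "drugA"),
#'   marker = "Ki67",
#'   positive_count = c(30, 50, 10, 30),
#'   tumor_area_mm2 = 1
#' )
#' summarize_marker(rec, "Ki67", control_label = "vehicle")
#' @export
summarize_marker <- function(records, marker, control_label = "vehicle") {
  marker <- match.arg(marker, c("Ki67", "TUNEL"))
  check_columns(records, c("group", "marker", "positive_count", "tumor_area_mm2"),
                "`records`")
  rec <- dplyr::filter(records, .data$marker == !!marker)
  if (nrow(rec) == 0) abort(sprintf("No %s records found.", marker))
  if (any(rec$tumor_area_mm2 <= 0)) abort("All `tumor_area_mm2` must be positive.")
  if (any(rec$positive_count < 0)) abort("All `positive_count` must be non-negative.")
  if (!control_label %in% rec$group) {
    abort(sprintf("Control group '%s' has no %s records.", control_label, marker))
  }

  summ <- rec |>
    dplyr::mutate(frequency = .data$positive_count / .data$tumor_area_mm2) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_explants = dplyr::n(),
                     mean_frequency = mean(.data$frequency), .groups = "drop")

  ct_mean <- summ$mean_frequency[summ$group == control_label]
  floored <- FALSE
  if (ct_mean == 0) {
    if (marker == "Ki67") {
      abort("Control Ki67 mean frequency is zero; normalization undefined.")
    }
    ct_mean <- 1  # floor at 1 pcs/mm^2, flagged
    floored <- TRUE
  }

  summ |>
    dplyr::mutate(
      marker = marker,
      normalized_value = 100 * .data$mean_frequency / ct_mean,
      floored = floored,
      .after = "group"
    ) |>
    dplyr::arrange(.data$group != control_label, .data$group)
}

#' Ex vivo drug-response score (VitroF)
#'
#' The TEVA score combines the anti-proliferative and cytotoxic arms of a
#' 24 h explant assay with equal weight:
#' \deqn{VitroF = 0.5 \cdot CtKi67 / TrKi67 + 0.5 \cdot TrTUNEL / CtTUNEL}
#' where Ct/Tr are control/treatment marker values normalized so the
#' control equals 100. A no-effect drug scores 1; stronger effects score
#' higher. The treated Ki67 value is floored at 1 (1% of control), capping
#' the proliferation term at 50, since the ratio is undefined at complete
#' cytostasis.
#'
#' @param ct_ki67,tr_ki67 Control and treated normalized Ki67 values.
#' @param ct_tunel,tr_tunel Control and treated normalized TUNEL values.
#' @return Numeric score(s); vectorized over the inputs.
#' @examples
#' vitro_score(100, 100, 100, 100) # no effect -> 1
#' vitro_score(100, 50, 100, 200)  # halved proliferation, doubled apoptosis -> 2
#' @export
vitro_score <- function(ct_ki67, tr_ki67, ct_tunel, tr_tunel) {
  if (any(ct_ki67 <= 0) || any(ct_tunel <= 0)) {
    abort("Control normalized values must be positive.")
  }
  if (any(tr_tunel < 0)) abort("`tr_tunel` must be non-negative.")
  if (any(tr_ki67 <= 0)) {
    warn("`tr_ki67` <= 0 floored at 1 (proliferation term capped at 50x).")
  }
  tr_ki67 <- pmax(tr_ki67, 1)
  0.5 * ct_ki67 / tr_ki67 + 0.5 * tr_tunel / ct_tunel
}

#' Per-drug VitroF scores from explant staining records
#'
#' Summarizes Ki67 and TUNEL object frequencies per group (control fixed at
#' 100; see [summarize_marker()]) and applies [vitro_score()] to every drug.
#' A bootstrap percentile interval over explants (resampled within each
#' group x marker) quantifies replicate uncertainty; the point score itself
#' is unchanged.
#'
#' @inheritParams summarize_marker
#' @param n_boot Bootstrap resamples for the interval (0 skips it).
#' @param conf_level Interval coverage.
#' @param seed Seed for the bootstrap stream.
#' @return A tibble with one row per drug: `drug`, `ct_ki67`, `tr_ki67`,
#'   `ct_tunel`, `tr_tunel`, `vitro_f`, `vitro_f_lo`, `vitro_f_hi`,
#'   `floored`.
#' @examples
#' cfg <- scenario_config(seed = 1, drug_effects = drug_effect("d", 0.5, 2, 0.5))
#' vitro_scores(simulate_explants(cfg), control_label = "vehicle", n_boot = 100)
#' @export
vitro_scores <- function(records, control_label = "vehicle",
                         n_boot = 1000, conf_level = 0.95, seed = 1) {
  ki67 <- summarize_marker(records, "Ki67", control_label)
  tunel <- summarize_marker(records, "TUNEL", control_label)
  drugs <- setdiff(union(ki67$group, tunel$group), control_label)
  if (length(drugs) == 0) abort("No treatment groups found in `records`.")
  missing_k <- setdiff(drugs, ki67$group)
  missing_t <- setdiff(drugs, tunel$group)
  if (length(missing_k) || length(missing_t)) {
    abort(sprintf("Groups missing a marker: %s.",
                  paste(union(missing_k, missing_t), collapse = ", ")))
  }

  norm_of <- function(summ, grp) summ$normalized_value[summ$group == grp]
  scores <- purrr::map_dfr(drugs, function(d) {
    tibble(
      drug = d,
      ct_ki67 = 100, tr_ki67 = norm_of(ki67, d),
      ct_tunel = 100, tr_tunel = norm_of(tunel, d),
      floored = any(ki67$floored) || any(tunel$floored)
    )
  }) |>
    dplyr::mutate(vitro_f = vitro_score(.data$ct_ki67, .data$tr_ki67,
                                        .data$ct_tunel, .data$tr_tunel),
                  .before = "floored")

  if (n_boot > 0) {
    ci <- bootstrap_vitro_ci(records, drugs, control_label, n_boot,
                             conf_level, seed)
    scores <- dplyr::left_join(scores, ci, by = "drug")
  } else {
    scores$vitro_f_lo <- NA_real_
    scores$vitro_f_hi <- NA_real_
  }
  dplyr::relocate(scores, "vitro_f_lo", "vitro_f_hi", .after = "vitro_f")
}

# Percentile bootstrap over explants, resampling within group x marker.
bootstrap_vitro_ci <- function(records, drugs, control_label, n_boot,
                               conf_level, seed) {
  rec <- records |>
    dplyr::filter(.data$group %in% c(drugs, control_label)) |>
    dplyr::mutate(frequency = .data$positive_count / .data$tumor_area_mm2)
  cells <- split(rec$frequency, interaction(rec$group, rec$marker, drop = TRUE))
  alpha <- (1 - conf_level) / 2

  with_seed(stream_seed(seed, "vitro_bootstrap"), {
    draws <- replicate(n_boot, {
      means <- vapply(cells, function(f) mean(sample(f, replace = TRUE)),
                      numeric(1))
      ct_k <- means[paste(control_label, "Ki67", sep = ".")]
      ct_t <- means[paste(control_label, "TUNEL", sep = ".")]
      vapply(drugs, function(d) {
        tr_k <- 100 * means[paste(d, "Ki67", sep = ".")] / max(ct_k, 1e-12)
        tr_t <- 100 * means[paste(d, "TUNEL", sep = ".")] / max(ct_t, 1)
        suppressWarnings(vitro_score(100, tr_k, 100, tr_t))
      }, numeric(1))
    })
    draws <- matrix(draws, nrow = length(drugs))
    tibble(
      drug = drugs,
      vitro_f_lo = apply(draws, 1, stats::quantile, probs = alpha, names = FALSE),
      vitro_f_hi = apply(draws, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
    )
  })
}
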