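#' Caliper tumor volume
#'
#' Volume of a subcutaneous tumor from two orthogonal caliper diameters,
#' using the modified-ellipsoid formula \eqn{V = L \cdot W^2 \cdot \pi/6}
#' with `W` the smaller and `L` the larger of the two measurements. The
#' result does not depend on the order in which the diameters are supplied.
#'
#' @param d1_mm,d2_mm Orthogonal tumor diameters, mm; vectorized.
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 8) # 335.1 mm^3
#' @export
tumor_volume <- function(d1_mm, d2_mm) {
  if (any(!is.finite(d1_mm)) || any(!is.finite(d2_mm)) ||
      any(d1_mm <= 0) || any(d2_mm <= 0)) {
    abort("Diameters must be positive finite numbers.")
  }
  l <- pmax(d1_mm, d2_mm)
  w <- pmin(d1_mm, d2_mm)
  l * w^2 * pi / 6
}

#' Convert caliper records to per-mouse volume series
#'
#' Applies [tumor_volume()] to every caliper pair and validates the series:
#' days must be strictly increasing within each mouse (duplicates are an
#' error) and at least `min_days` measurements are required for downstream
#' scoring, which needs the penultimate and last days.
#'
#' @param calipers Tibble with columns `patient`, `group`, `mouse_id`,
#'   `day`, `d1_mm`, `d2_mm` (see [simulate_growth()] /
#'   [read_caliper_table()]).
#' @param min_days Minimum measurements per mouse.
#' @return A tibble with one row per mouse x day: `patient`, `group`,
#'   `mouse_id`, `day`, `volume_mm3`, ordered by mouse and day.
#' @export
caliper_volumes <- function(calipers, min_days = 3) {
  check_columns(calipers, c("patient", "group", "mouse_id", "day",
                            "d1_mm", "d2_mm"), "`calipers`")
  dup <- calipers |>
    dplyr::count(.data$mouse_id, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate measurement for mouse '%s' on day %s.",
                  dup$mouse_id[1], format(dup$day[1])))
  }
  short <- calipers |>
    dplyr::count(.data$mouse_id) |>
    dplyr::filter(.data$n < min_days)
  if (nrow(short) > 0) {
    abort(sprintf("Mouse '%s' has fewer than %d measurements.",
                  short$mouse_id[1], min_days))
  }
  calipers |>
    dplyr::mutate(volume_mm3 = tumor_volume(.data$d1_mm, .data$d2_mm)) |>
    dplyr::select("patient", "group", "mouse_id", "day", "volume_mm3") |>
    dplyr::arrange(.data$mouse_id, .data$day)
}

#' Balanced group allocation of tumor-bearing mice
#'
#' Implements randomization under the two standard restrictions for PDX
#' efficacy studies: group means and SDs of baseline tumor volume should be
#' similar, and extreme volumes are excluded up front. Mice are sorted by
#' volume, `exclusion_fraction/2` is trimmed from each extreme, and the
#' remainder is dealt to groups in serpentine (snake) order
#' (1..k, k..1, 1..k, ...), which balances both means and spreads.
#' Ties in volume are broken by mouse id, so the allocation is
#' deterministic.
#'
#' @param baselines Tibble with columns `mouse_id` and `volume_mm3`
#'   (baseline volumes at randomization).
#' @param n_groups Number of treatment arms (including the control).
#' @param exclusion_fraction Fraction of mice to exclude, split evenly
#'   between the smallest and largest volumes (rounded per side).
#' @param group_labels Optional labels for the arms; defaults to
#'   `"group1"..."groupk"`.
#' @param min_per_group Minimum group size after exclusion.
#' @return An object of class `teva_allocation`: a list with `assignments`
#'   (tibble `mouse_id`, `volume_mm3`, `group`), `excluded` (tibble), and
#'   `group_summary` (tibble `group`, `n`, `mean_mm3`, `sd_mm3`).
#' @examples
#' base <- tibble::tibble(mouse_id = sprintf("m%02d", 1:12),
#'                        volume_mm3 = c(50, rep(100, 10), 400))
#' allocate_groups(base, n_groups = 2, exclusion_fraction = 2 / 12)
#' @export
allocate_groups <- function(baselines, n_groups, exclusion_fraction = 0,
                            group_labels = NULL, min_per_group = 3) {
  check_columns(baselines, c("mouse_id", "volume_mm3"), "`baselines`")
  check_scalar_number(n_groups, "n_groups", 1)
  check_scalar_number(exclusion_fraction, "exclusion_fraction", 0, 1)
  if (anyDuplicated(baselines$mouse_id)) abort("Duplicate `mouse_id` in baselines.")
  if (any(baselines$volume_mm3 <= 0)) abort("Baseline volumes must be positive.")
  if (is.null(group_labels)) group_labels <- sprintf("group%d", seq_len(n_groups))
  if (length(group_labels) != n_groups) {
    abort("`group_labels` must have length `n_groups`.")
  }

  n <- nrow(baselines)
  sorted <- dplyr::arrange(baselines, .data$volume_mm3, .data$mouse_id)
  n_side <- round(exclusion_fraction * n / 2)
  keep_idx <- if (n_side > 0) seq(n_side + 1, n - n_side) else seq_len(n)
  if (length(keep_idx) < min_per_group * n_groups) {
    abort(sprintf(
      "Only %d mice remain after exclusion; %d groups of >= %d are infeasible.",
      length(keep_idx), n_groups, min_per_group
    ))
  }
  excluded <- sorted[setdiff(seq_len(n), keep_idx), ]
  kept <- sorted[keep_idx, ]

  assignment <- serpentine_order(nrow(kept), n_groups)
  kept$group <- group_labels[assignment]

  summary <- kept |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mm3 = mean(.data$volume_mm3),
                     sd_mm3 = stats::sd(.data$volume_mm3), .groups = "drop")

  structure(
    list(
      assignments = dplyr::arrange(kept, .data$group, .data$mouse_id),
      excluded = dplyr::select(excluded, "mouse_id", "volume_mm3"),
      group_summary = summary
    ),
    class = "teva_allocation"
  )
}

# Group index (1..k) for the i-th mouse in sorted order under snake dealing:
# 1..k then k..1, repeating.
serpentine_order <- function(n, k) {
  pattern <- c(seq_len(k), rev(seq_len(k)))
  rep_len(pattern, n)
}

#' @export
print.teva_allocation <- function(x, ...) {
  cat("<teva_allocation>\n")
  cat(sprintf("  %d mice assigned to %d groups; %d excluded\n",
              nrow(x$assignments), nrow(x$group_summary), nrow(x$excluded)))
  print(x$group_summary)
  invisible(x)
}

#' In vivo drug-response score (VivoF)
#'
#' Combines the control-normalized treatment volumes at the penultimate and
#' last shared measurement days with equal weight:
#' \deqn{VivoF = 0.5 \cdot CTV / TTV_{2nd last} + 0.5 \cdot CTV / TTV_{last}}
#' with the control arm normalized to 100 at each day. A treatment arm that
#' tracks the control scores 1; slower growth scores higher.
#'
#' @param ttv_penultimate,ttv_last Normalized treatment volumes (control =
#'   100) at the penultimate and last shared days.
#' @param ctv Control normalization constant (100).
#' @return Numeric score(s); vectorized.
#' @examples
#' vivo_score_value(50, 25) # 0.5*2 + 0.5*4 = 3
#' @export
vivo_score_value <- function(ttv_penultimate, ttv_last, ctv = 100) {
  if (any(ctv <= 0)) abort("`ctv` must be positive.")
  if (any(ttv_penultimate <= 0) || any(ttv_last <= 0)) {
    warn("Non-positive normalized treatment volume floored at 1 (term capped at 100x).")
  }
  ttv_penultimate <- pmax(ttv_penultimate, 1)
  ttv_last <- pmax(ttv_last, 1)
  0.5 * ctv / ttv_penultimate + 0.5 * ctv / ttv_last
}

#' Per-drug VivoF scores from volume series
#'
#' For each drug arm, finds the measurement days shared with the control
#' arm, takes the arithmetic group mean of volumes at the penultimate and
#' last shared days, normalizes each mean to the control mean on the same
#' day (control = 100), and applies [vivo_score_value()]. Mice missing one
#' of the scored days are dropped from that day's mean with a warning.
#'
#' @param volumes Tibble of per-mouse volumes as returned by
#'   [caliper_volumes()].
#' @param control_label Label of the vehicle arm.
#' @return A tibble with one row per drug: `drug`, `day_penultimate`,
#'   `day_last`, `ttv_penultimate`, `ttv_last`, `vivo_f`, `n_mice`.
#' @export
vivo_scores <- function(volumes, control_label = "vehicle") {
  check_columns(volumes, c("group", "mouse_id", "day", "volume_mm3"), "`volumes`")
  if (!control_label %in% volumes$group) {
    abort(sprintf("Control group '%s' not found in `volumes`.", control_label))
  }
  ctrl <- dplyr::filter(volumes, .data$group == control_label)
  drugs <- setdiff(unique(volumes$group), control_label)
  if (length(drugs) == 0) abort("No treatment groups found in `volumes`.")

  purrr::map_dfr(drugs, function(d) {
    trt <- dplyr::filter(volumes, .data$group == d)
    shared <- sort(intersect(unique(ctrl$day), unique(trt$day)))
    if (length(shared) < 2) {
      abort(sprintf("Fewer than 2 shared measurement days for drug '%s'.", d))
    }
    days <- utils::tail(shared, 2)

    mean_at <- function(df, day, arm) {
      mice_all <- unique(df$mouse_id)
      at <- df[df$day == day, ]
      missing <- setdiff(mice_all, at$mouse_id)
      if (length(missing) > 0) {
        warn(sprintf("%s arm: %d mouse/mice missing day %s dropped from that day's mean.",
                     arm, length(missing), format(day)))
      }
      mean(at$volume_mm3)
    }
    ctv_pen <- mean_at(ctrl, days[1], control_label)
    ctv_last <- mean_at(ctrl, days[2], control_label)
    ttv_pen <- 100 * mean_at(trt, days[1], d) / ctv_pen
    ttv_last <- 100 * mean_at(trt, days[2], d) / ctv_last

    tibble(
      drug = d,
      day_penultimate = days[1], day_last = days[2],
      ttv_penultimate = ttv_pen, ttv_last = ttv_last,
      vivo_f = vivo_score_value(ttv_pen, ttv_last),
      n_mice = dplyr::n_distinct(trt$mouse_id)
    )
  })
}
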