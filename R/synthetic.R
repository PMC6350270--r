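#' Define a drug effect for a synthetic explant/xenograft scenario
#'
#' A drug effect parameterizes how a treatment shifts the three observables
#' the pipeline scores: the Ki67-positive object density (proliferation),
#' the TUNEL-positive object density (apoptosis), and the in vivo tumor
#' growth rate.
#'
#' @param drug Drug label.
#' @param prolif_multiplier Treated Ki67 density divided by control Ki67
#'   density; must be positive. Values below 1 are anti-proliferative.
#' @param apoptosis_multiplier Treated TUNEL density divided by control
#'   TUNEL density; must be positive. Values above 1 are cytotoxic.
#' @param growth_inhibition Fractional reduction of the in vivo exponential
#'   growth rate, in \[0, 1\]; 0 leaves growth untouched, 1 halts it.
#'
#' @return A one-row tibble with columns `drug`, `prolif_multiplier`,
#'   `apoptosis_multiplier`, `growth_inhibition`. Rows from several calls
#'   can be bound together and passed to [scenario_config()].
#' @examples
#' dplyr::bind_rows(
#'   drug_effect("cetuximab", 0.4, 1.8, 0.6),
#'   drug_effect("olaparib", 0.9, 1.1, 0.1)
#' )
#' @export
drug_effect <- function(drug, prolif_multiplier, apoptosis_multiplier,
                        growth_inhibition) {
  stopifnot(is.character(drug) || is.factor(drug), length(drug) == 1L)
  check_scalar_number(prolif_multiplier, "prolif_multiplier", 0, strict_lower = TRUE)
  check_scalar_number(apoptosis_multiplier, "apoptosis_multiplier", 0, strict_lower = TRUE)
  check_scalar_number(growth_inhibition, "growth_inhibition", 0, 1)
  tibble(
    drug = as.character(drug),
    prolif_multiplier = prolif_multiplier,
    apoptosis_multiplier = apoptosis_multiplier,
    growth_inhibition = growth_inhibition
  )
}

#' Sample drug effects driven by (or free of) a shared latent potency
#'
#' Generates a panel of synthetic drug effects. In the concordant regime
#' each drug has one latent potency that drives its anti-proliferative,
#' cytotoxic and growth-inhibitory effects together (with multiplicative
#' noise); ex vivo and in vivo responses are then correlated by
#' construction. In the independent regime the three effect components are
#' drawn from unrelated potencies, so ex vivo and in vivo responses share
#' no signal and the expected score correlation is zero.
#'
#' @param n_drugs Number of drugs.
#' @param seed Integer seed.
#' @param concordant If `TRUE` (default) one latent potency per drug drives
#'   all three components; if `FALSE` the ex vivo and in vivo components are
#'   driven by independent potencies.
#' @param potency_range Range of the latent potency, uniform on this
#'   interval. Potency p maps to Ki67 multiplier exp(-p), TUNEL multiplier
#'   exp(p), and growth inhibition 1 - exp(-p).
#' @param effect_sd Standard deviation of the lognormal perturbation applied
#'   to the potency separately for each component (the "biology is not one
#'   number" decoupling). Kept small by default: the dominant stochasticity
#'   in a simulated study should come from measurement (counts, calipers),
#'   not from the latent effects themselves.
#' @return A tibble of drug effects as accepted by [scenario_config()].
#' @export
sample_drug_effects <- function(n_drugs, seed, concordant = TRUE,
                                potency_range = c(0.2, 1.5),
                                effect_sd = 0.05) {
  stopifnot(n_drugs >= 1, length(potency_range) == 2L,
            potency_range[1] > 0, diff(potency_range) >= 0)
  with_seed(stream_seed(seed, "drug_effects"), {
    potency <- stats::runif(n_drugs, potency_range[1], potency_range[2])
    perturb <- function(p) p * exp(stats::rnorm(n_drugs, 0, effect_sd))
    p_vitro_ki67 <- perturb(potency)
    p_vitro_tunel <- perturb(potency)
    p_vivo <- if (concordant) {
      perturb(potency)
    } else {
      perturb(stats::runif(n_drugs, potency_range[1], potency_range[2]))
    }
    tibble(
      drug = sprintf("drug%02d", seq_len(n_drugs)),
      prolif_multiplier = exp(-p_vitro_ki67),
      apoptosis_multiplier = exp(p_vitro_tunel),
      growth_inhibition = pmin(1, 1 - exp(-p_vivo))
    )
  })
}

#' Configure a synthetic explant + xenograft experiment
#'
#' Bundles every parameter of a simulated ex vivo / in vivo drug study:
#' group sizes, baseline marker densities, count and caliper noise, the
#' exponential tumor growth model, and the per-drug effects. The defaults
#' describe a study of the size and noise level typical for a head-and-neck
#' PDX screen: explants assayed after 24 h of drug exposure, xenografts
#' randomized at roughly 100 mm^3 and measured every 3 days for two weeks.
#'
#' @param seed Master integer seed; all random streams derive from it.
#' @param drug_effects Tibble of drug effects (see [drug_effect()]). The
#'   control arm is added automatically under `control_label` with the
#'   identity effect (multipliers 1, inhibition 0).
#' @param patient Patient/PDX label attached to every record.
#' @param control_label Group label of the vehicle/DMSO control arm.
#' @param n_explants_per_group Explants stained per group and marker (>= 2).
#' @param n_mice_per_group Mice per in vivo arm (>= 3).
#' @param baseline_ki67_density,baseline_tunel_density Control-arm positive
#'   object densities, pcs/mm^2.
#' @param explant_area_mean Mean annotated tumor area per section, mm^2.
#' @param explant_area_cv Coefficient of variation of the annotated area
#'   (gamma-distributed areas); 0 fixes the area at its mean.
#' @param count_dispersion Negative-binomial overdispersion of positive
#'   object counts; 0 gives Poisson counts.
#' @param baseline_growth_rate Control exponential growth rate, per day.
#' @param initial_volume Tumor volume at randomization (day 0), mm^3.
#' @param initial_volume_cv Coefficient of variation of per-mouse baseline
#'   volumes (lognormal); 0 fixes all baselines at `initial_volume`.
#' @param measurement_days Strictly increasing caliper days (>= 3 days).
#' @param caliper_cv Multiplicative (lognormal) noise CV on each measured
#'   diameter; 0 gives noise-free calipers.
#' @param aspect_ratio Latent length-to-width ratio of the tumor (>= 1);
#'   1 gives sphere-equivalent equal diameters.
#' @param deterministic If `TRUE`, every sampling step is replaced by its
#'   expected value: counts equal density x area exactly (and may be
#'   fractional), areas and baseline volumes sit at their means, calipers
#'   are noise-free. Used for closed-form recovery checks and calibration.
#'
#' @return An object of class `teva_scenario` (a validated list).
#' @examples
#' cfg <- scenario_config(
#'   seed = 1,
#'   drug_effects = drug_effect("cetuximab", 0.4, 1.8, 0.6)
#' )
#' @export
scenario_config <- function(seed,
                            drug_effects,
                            patient = "PT1",
                            control_label = "vehicle",
                            n_explants_per_group = 4,
                            n_mice_per_group = 6,
                            baseline_ki67_density = 400,
                            baseline_tunel_density = 50,
                            explant_area_mean = 1.5,
                            explant_area_cv = 0.2,
                            count_dispersion = 0,
                            baseline_growth_rate = 0.08,
                            initial_volume = 100,
                            initial_volume_cv = 0.1,
                            measurement_days = c(1, 4, 7, 10, 13),
                            caliper_cv = 0.05,
                            aspect_ratio = 1,
                            deterministic = FALSE) {
  check_scalar_number(seed, "seed")
  check_columns(drug_effects, c("drug", "prolif_multiplier",
                                "apoptosis_multiplier", "growth_inhibition"),
                "`drug_effects`")
  if (nrow(drug_effects) < 1) abort("`drug_effects` needs at least one drug.")
  if (anyDuplicated(drug_effects$drug)) abort("Duplicate drug labels in `drug_effects`.")
  if (control_label %in% drug_effects$drug) {
    abort("`control_label` must not collide with a drug label.")
  }
  with(drug_effects, {
    if (any(prolif_multiplier <= 0) || any(apoptosis_multiplier <= 0)) {
      abort("Effect multipliers must be positive.")
    }
    if (any(growth_inhibition < 0 | growth_inhibition > 1)) {
      abort("`growth_inhibition` must lie in [0, 1].")
    }
  })
  check_scalar_number(n_explants_per_group, "n_explants_per_group", 2)
  check_scalar_number(n_mice_per_group, "n_mice_per_group", 3)
  check_scalar_number(baseline_ki67_density, "baseline_ki67_density", 0, strict_lower = TRUE)
  check_scalar_number(baseline_tunel_density, "baseline_tunel_density", 0, strict_lower = TRUE)
  check_scalar_number(explant_area_mean, "explant_area_mean", 0, strict_lower = TRUE)
  check_scalar_number(explant_area_cv, "explant_area_cv", 0)
  check_scalar_number(count_dispersion, "count_dispersion", 0)
  check_scalar_number(baseline_growth_rate, "baseline_growth_rate", 0, strict_lower = TRUE)
  check_scalar_number(initial_volume, "initial_volume", 0, strict_lower = TRUE)
  check_scalar_number(initial_volume_cv, "initial_volume_cv", 0)
  check_scalar_number(caliper_cv, "caliper_cv", 0)
  check_scalar_number(aspect_ratio, "aspect_ratio", 1)
  if (length(measurement_days) < 3 || any(diff(measurement_days) <= 0)) {
    abort("`measurement_days` must be strictly increasing with length >= 3.")
  }
  if (any(measurement_days < 0)) abort("`measurement_days` must be non-negative.")

  structure(
    list(
      seed = as.integer(seed), patient = patient,
      control_label = control_label,
      drug_effects = as_tibble(drug_effects),
      n_explants_per_group = as.integer(n_explants_per_group),
      n_mice_per_group = as.integer(n_mice_per_group),
      baseline_ki67_density = baseline_ki67_density,
      baseline_tunel_density = baseline_tunel_density,
      explant_area_mean = explant_area_mean,
      explant_area_cv = explant_area_cv,
      count_dispersion = count_dispersion,
      baseline_growth_rate = baseline_growth_rate,
      initial_volume = initial_volume,
      initial_volume_cv = initial_volume_cv,
      measurement_days = as.numeric(measurement_days),
      caliper_cv = caliper_cv,
      aspect_ratio = aspect_ratio,
      deterministic = isTRUE(deterministic)
    ),
    class = "teva_scenario"
  )
}

#' @export
print.teva_scenario <- function(x, ...) {
  cat("<teva_scenario>\n")
  cat(sprintf("  patient: %s  seed: %d  %s\n", x$patient, x$seed,
              if (x$deterministic) "(deterministic)" else ""))
  cat(sprintf("  groups: %s + %d drugs | %d explants/group, %d mice/group\n",
              x$control_label, nrow(x$drug_effects),
              x$n_explants_per_group, x$n_mice_per_group))
  cat(sprintf("  days: %s | r = %.3g/day, V0 = %.3g mm^3\n",
              paste(x$measurement_days, collapse = ", "),
              x$baseline_growth_rate, x$initial_volume))
  invisible(x)
}

# All group labels in arm order: control first, then drugs.
scenario_groups <- function(config) {
  c(config$control_label, config$drug_effects$drug)
}

# Per-group expected marker densities (pcs/mm^2).
scenario_densities <- function(config) {
  eff <- dplyr::bind_rows(
    tibble(drug = config$control_label, prolif_multiplier = 1,
           apoptosis_multiplier = 1, growth_inhibition = 0),
    config$drug_effects
  )
  tibble(
    group = rep(eff$drug, times = 2),
    marker = rep(c("Ki67", "TUNEL"), each = nrow(eff)),
    density = c(config$baseline_ki67_density * eff$prolif_multiplier,
                config$baseline_tunel_density * eff$apoptosis_multiplier)
  )
}

#' Simulate per-explant IHC staining records
#'
#' Draws one positive-object count and one annotated tumor area per explant,
#' group and marker. Annotated areas are gamma-distributed around
#' `explant_area_mean`; counts are Poisson (or negative binomial when
#' `count_dispersion > 0`) with mean density x area, where the group density
#' is the baseline density scaled by the drug's multiplier. Deterministic
#' given the scenario seed.
#'
#' @param config A [scenario_config()] object.
#' @return A tibble with one row per explant x marker: `patient`, `group`,
#'   `explant_id`, `marker`, `positive_count`, `tumor_area_mm2`.
#' @examples
#' cfg <- scenario_config(seed = 1, drug_effects = drug_effect("d", 0.5, 2, 0.5))
#' simulate_explants(cfg)
#' @export
simulate_explants <- function(config) {
  stopifnot(inherits(config, "teva_scenario"))
  dens <- scenario_densities(config)
  n <- config$n_explants_per_group
  grid <- tidyr::crossing(dens, replicate_idx = seq_len(n))

  with_seed(stream_seed(config$seed, "explants"), {
    m <- nrow(grid)
    area <- if (config$deterministic || config$explant_area_cv == 0) {
      rep(config$explant_area_mean, m)
    } else {
      shape <- 1 / config$explant_area_cv^2
      stats::rgamma(m, shape = shape, scale = config$explant_area_mean / shape)
    }
    mu <- grid$density * area
    count <- if (config$deterministic) {
      mu
    } else if (config$count_dispersion > 0) {
      stats::rnbinom(m, mu = mu, size = 1 / config$count_dispersion)
    } else {
      stats::rpois(m, mu)
    }
    tibble(
      patient = config$patient,
      group = grid$group,
      explant_id = sprintf("%s_e%02d", grid$group, grid$replicate_idx),
      marker = grid$marker,
      positive_count = count,
      tumor_area_mm2 = area
    )
  })
}

# Decompose a latent volume into (d1, d2) honoring V = L * W^2 * pi/6 with
# L = aspect * W. aspect = 1 gives the sphere-equivalent diameter.
volume_to_diameters <- function(volume, aspect = 1) {
  w <- (6 * volume / (pi * aspect))^(1 / 3)
  list(d1 = aspect * w, d2 = w)
}

#' Simulate caliper growth series for a xenograft efficacy study
#'
#' Each mouse's latent tumor volume follows
#' V(t) = V0 * exp(r * (1 - g) * t), with r the control growth rate and g
#' the drug's growth inhibition. At each measurement day the latent volume
#' is decomposed into two orthogonal diameters consistent with the caliper
#' volume formula L * W^2 * pi/6 (sphere-equivalent unless
#' `aspect_ratio > 1`), then each diameter is perturbed with multiplicative
#' lognormal noise of CV `caliper_cv`. Deterministic given the scenario seed.
#'
#' @param config A [scenario_config()] object.
#' @return A tibble with one row per mouse x day: `patient`, `group`,
#'   `mouse_id`, `day`, `d1_mm`, `d2_mm`.
#' @examples
#' cfg <- scenario_config(seed = 1, drug_effects = drug_effect("d", 0.5, 2, 0.5))
#' simulate_growth(cfg)
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "teva_scenario"))
  if (length(config$measurement_days) == 0) abort("Empty `measurement_days`.")
  groups <- scenario_groups(config)
  inhib <- c(0, config$drug_effects$growth_inhibition)
  n_mice <- config$n_mice_per_group

  with_seed(stream_seed(config$seed, "growth"), {
    purrr::map2_dfr(groups, inhib, function(grp, g) {
      v0 <- if (config$deterministic || config$initial_volume_cv == 0) {
        rep(config$initial_volume, n_mice)
      } else {
        sdlog <- sqrt(log(1 + config$initial_volume_cv^2))
        config$initial_volume * exp(stats::rnorm(n_mice, -sdlog^2 / 2, sdlog))
      }
      purrr::map_dfr(seq_len(n_mice), function(i) {
        vol <- v0[i] * exp(config$baseline_growth_rate * (1 - g) *
                             config$measurement_days)
        dia <- volume_to_diameters(vol, config$aspect_ratio)
        k <- length(vol)
        noise <- function() {
          if (config$deterministic || config$caliper_cv == 0) return(rep(1, k))
          sdlog <- sqrt(log(1 + config$caliper_cv^2))
          exp(stats::rnorm(k, -sdlog^2 / 2, sdlog))
        }
        tibble(
          patient = config$patient, group = grp,
          mouse_id = sprintf("%s_m%02d", grp, i),
          day = config$measurement_days,
          d1_mm = dia$d1 * noise(),
          d2_mm = dia$d2 * noise()
        )
      })
    })
  })
}

#' Render a synthetic DAB-like IHC tile with ground-truth nuclei
#'
#' Produces a grayscale intensity tile emulating DAB-positive nuclei inside
#' an annotated tumor mask: the true nucleus count is Poisson with mean
#' density x mask area, nuclei are non-overlapping disks placed uniformly
#' (fully inside the tile), background intensity sits below the detection
#' threshold and nuclei above it. The returned ground truth supports exact
#' recovery tests of the quantification step.
#'
#' @param density Expected positive objects per mm^2 (>= 0).
#' @param tile_side_mm Tile side length, mm.
#' @param pixel_size_um Pixel edge, micrometers.
#' @param seed Integer seed (ignored when `centers` is given).
#' @param nucleus_radius_um Nucleus disk radius, micrometers; must
#'   rasterize to >= 2 px.
#' @param background,foreground Intensities of non-stained and stained
#'   pixels (0-1 scale).
#' @param centers Optional 2-column matrix of pixel-center coordinates
#'   (row, col) for debug placement; overrides random placement.
#' @param max_tries Placement attempts per nucleus before failing.
#' @return A list with `image` (numeric matrix), `mask` (logical matrix,
#'   all `TRUE` for the full-tile annotation), `true_count`, and
#'   `pixel_size_um`.
#' @examples
#' tile <- render_ihc_tile(density = 50, tile_side_mm = 0.5,
#'                         pixel_size_um = 2, seed = 1)
#' tile$true_count
#' @export
render_ihc_tile <- function(density, tile_side_mm = 1, pixel_size_um = 2,
                            seed = 1, nucleus_radius_um = 5,
                            background = 0.15, foreground = 0.85,
                            centers = NULL, max_tries = 10000) {
  check_scalar_number(density, "density", 0)
  check_scalar_number(tile_side_mm, "tile_side_mm", 0, strict_lower = TRUE)
  check_scalar_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  n_px <- max(1L, round(tile_side_mm * 1000 / pixel_size_um))
  r_px <- nucleus_radius_um / pixel_size_um
  if (is.null(centers) && r_px < 2) {
    abort("Nucleus radius must rasterize to at least 2 px; decrease `pixel_size_um`.")
  }
  mask <- matrix(TRUE, n_px, n_px)
  image <- matrix(background, n_px, n_px)
  area_mm2 <- n_px^2 * (pixel_size_um / 1000)^2

  if (is.null(centers)) {
    with_seed(stream_seed(seed, "ihc_tile"), {
      true_count <- stats::rpois(1, density * area_mm2)
      centers <- matrix(numeric(0), 0, 2)
      tries <- 0
      while (nrow(centers) < true_count) {
        tries <- tries + 1
        if (tries > max_tries) {
          abort(sprintf(
            "Could not place %d non-overlapping nuclei in the tile after %d tries.",
            true_count, max_tries
          ))
        }
        cand <- stats::runif(2, min = r_px + 1, max = n_px - r_px)
        # 2 px margin beyond touching keeps rasterized disks from becoming
        # 8-adjacent, so each nucleus is one resolvable component
        if (nrow(centers) == 0 ||
            all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
                  (2 * r_px + 2)^2)) {
          centers <- rbind(centers, cand)
        }
      }
      centers
    }) -> centers
  } else {
    centers <- as.matrix(centers)
    if (ncol(centers) != 2) abort("`centers` must have two columns (row, col).")
  }
  true_count <- nrow(centers)

  for (i in seq_len(true_count)) {
    rows <- max(1, floor(centers[i, 1] - r_px)):min(n_px, ceiling(centers[i, 1] + r_px))
    cols <- max(1, floor(centers[i, 2] - r_px)):min(n_px, ceiling(centers[i, 2] + r_px))
    dist2 <- outer((rows - centers[i, 1])^2, (cols - centers[i, 2])^2, "+")
    image[rows, cols][dist2 <= r_px^2] <- foreground
  }

  list(image = image, mask = mask, true_count = true_count,
       pixel_size_um = pixel_size_um)
}
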