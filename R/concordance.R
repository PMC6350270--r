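#' Ex vivo / in vivo score concordance
#'
#' Pairs per-drug VitroF and VivoF scores and quantifies their agreement:
#' Pearson correlation, the least-squares regression line of VivoF on
#' VitroF, and Spearman's rank correlation. The correlation and line are
#' computed from first principles (sums of products); a seeded permutation
#' test (shuffling VivoF against VitroF) supplies a p-value for the Pearson
#' correlation, reported as a labeled extra alongside the headline r.
#'
#' @param pairs Tibble with columns `drug`, `vitro_f`, `vivo_f` (and
#'   optionally `patient`); one row per score pair. At least 3 pairs with
#'   nonzero variance on both axes are required.
#' @param n_perm Permutation count for the p-value (0 skips the test).
#' @param seed Seed for the permutation stream.
#' @return An object of class `teva_concordance`: a list with `pairs`, `n`,
#'   `r` (Pearson), `slope`, `intercept`, `spearman_rho`, `p_perm`,
#'   `n_perm`, and `top_drug` (the drug maximizing VitroF).
#' @examples
#' pairs <- tibble::tibble(drug = c("a", "b", "c", "d"),
#'                         vitro_f = c(2.1, 1.4, 1.1, 0.9),
#'                         vivo_f = c(2.4, 1.2, 1.3, 1.0))
#' concordance(pairs, n_perm = 200)
#' @export
concordance <- function(pairs, n_perm = 10000, seed = 1) {
  check_columns(pairs, c("drug", "vitro_f", "vivo_f"), "`pairs`")
  x <- pairs$vitro_f
  y <- pairs$vivo_f
  n <- length(x)
  if (n < 3) abort("Concordance requires at least 3 score pairs.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Scores must be finite.")
  if (stats::var(x) == 0) abort("Zero variance in VitroF; correlation undefined.")
  if (stats::var(y) == 0) abort("Zero variance in VivoF; correlation undefined.")

  r <- pearson_r(x, y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rho <- pearson_r(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average"))

  p_perm <- NA_real_
  if (n_perm > 0) {
    p_perm <- with_seed(stream_seed(seed, "permutation"), {
      r_perm <- replicate(n_perm, pearson_r(x, sample(y)))
      (1 + sum(abs(r_perm) >= abs(r) - 1e-12)) / (n_perm + 1)
    })
  }

  structure(
    list(
      pairs = as_tibble(pairs), n = n, r = r,
      slope = slope, intercept = intercept, spearman_rho = rho,
      p_perm = p_perm, n_perm = n_perm,
      top_drug = rank_drugs_by(pairs$drug, x)$drug[1]
    ),
    class = "teva_concordance"
  )
}

# Pearson correlation via sums of products (the independent route the
# tests cross-check against stats::cor()).
pearson_r <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

#' @export
print.teva_concordance <- function(x, ...) {
  cat("<teva_concordance>\n")
  cat(sprintf("  n = %d pairs | Pearson r = %.3f | Spearman rho = %.3f\n",
              x$n, x$r, x$spearman_rho))
  cat(sprintf("  vivoF = %.3f + %.3f * vitroF", x$intercept, x$slope))
  if (!is.na(x$p_perm)) {
    cat(sprintf(" | permutation p = %.4g (%d shuffles)", x$p_perm, x$n_perm))
  }
  cat(sprintf("\n  top drug by VitroF: %s\n", x$top_drug))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the regression line of a concordance fit
#'
#' @param x A [concordance()] result.
#' @param ... Unused.
#' @return A tibble with one row per regression term (`(Intercept)`,
#'   `vitro_f`) and its `estimate`.
#' @export
tidy.teva_concordance <- function(x, ...) {
  tibble(term = c("(Intercept)", "vitro_f"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of a concordance fit
#'
#' @param x A [concordance()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `r`, `spearman_rho`, `slope`, `intercept`,
#'   `p_perm`, `top_drug`.
#' @export
glance.teva_concordance <- function(x, ...) {
  tibble(n = x$n, r = x$r, spearman_rho = x$spearman_rho,
         slope = x$slope, intercept = x$intercept,
         p_perm = x$p_perm, top_drug = x$top_drug)
}

#' Rank drugs by ex vivo score
#'
#' Orders drugs by descending VitroF for prioritization; ties are broken
#' alphabetically and flagged.
#'
#' @param scores Tibble with columns `drug` and `vitro_f` (e.g. from
#'   [vitro_scores()]).
#' @return A tibble `rank`, `drug`, `vitro_f`, `tied`.
#' @examples
#' rank_drugs(tibble::tibble(drug = c("b", "a", "c"),
#'                           vitro_f = c(1.5, 1.5, 2)))
#' @export
rank_drugs <- function(scores) {
  check_columns(scores, c("drug", "vitro_f"), "`scores`")
  if (nrow(scores) < 1) abort("At least one score is required.")
  rank_drugs_by(scores$drug, scores$vitro_f)
}

rank_drugs_by <- function(drug, vitro_f) {
  ord <- order(-vitro_f, drug)
  out <- tibble(
    rank = seq_along(ord),
    drug = drug[ord],
    vitro_f = vitro_f[ord]
  )
  out$tied <- duplicated(out$vitro_f) | duplicated(out$vitro_f, fromLast = TRUE)
  out
}
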