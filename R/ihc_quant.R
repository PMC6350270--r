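#' @name ihc_quant
#' @title Positive-object quantification on annotated IHC images
#' @description
#' Emulates the two standard digital-pathology readouts on an annotated
#' image: the positive-object frequency (objects per mm^2 of annotated
#' tumor area, used for Ki67 and TUNEL) and the relative stained area
#' (percent of annotated pixels above threshold, used for phospho-marker
#' panels). Objects are 8-connected components of supra-threshold pixels
#' inside the annotation mask, subject to a minimum size filter.
NULL

check_image_mask <- function(image, mask) {
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix.")
  if (!identical(dim(image), dim(mask))) {
    abort(sprintf("`image` (%dx%d) and `mask` (%dx%d) have mismatched shapes.",
                  nrow(image), ncol(image), nrow(mask), ncol(mask)))
  }
  if (!any(mask)) abort("`mask` has no annotated pixels; frequency is undefined.")
  invisible(TRUE)
}

# Label 8-connected components of a logical matrix by iterative minimum-label
# propagation: every foreground pixel starts with its own index; each sweep
# takes the minimum label over the pixel and its 8 neighbours; convergence is
# reached within the pixel diameter of the largest component. Returns an
# integer matrix with consecutive labels (0 = background).
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_along(lab)[fg]  # unique index per foreground pixel

  shift_min <- function(lab, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    src <- lab[rs - dr, cs - dc, drop = FALSE]
    src[src == 0L] <- Inf
    out[rs, cs] <- src
    out
  }

  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  repeat {
    best <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(offsets))) {
      best <- pmin(best, shift_min(lab, offsets$dr[k], offsets$dc[k]))
    }
    cur <- ifelse(fg, lab, Inf)
    new_lab <- pmin(cur, best)
    new_lab[!fg] <- Inf
    new_int <- matrix(0L, nr, nc)
    new_int[fg] <- as.integer(new_lab[fg])
    if (identical(new_int, lab)) break
    lab <- new_int
  }
  # relabel to consecutive integers
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Count positive objects inside an annotated tumor area
#'
#' Thresholds the image, restricts to the annotation mask, labels
#' 8-connected components, discards components smaller than
#' `min_object_px`, and reports the count together with the annotated area
#' and the positive-object frequency (pcs/mm^2). The stained-area fraction
#' over the same mask is included for convenience.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical annotation matrix of the same shape, with at least
#'   one `TRUE` pixel.
#' @param threshold Intensity at or above which a pixel counts as stained.
#' @param min_object_px Minimum component size, pixels.
#' @param pixel_size_um Pixel edge, micrometers.
#' @return A one-row tibble: `n_objects`, `annotated_area_mm2`,
#'   `object_frequency` (pcs/mm^2), `stained_area_fraction` (percent).
#' @examples
#' tile <- render_ihc_tile(40, tile_side_mm = 0.5, pixel_size_um = 2, seed = 2)
#' count_positive_objects(tile$image, tile$mask, pixel_size_um = 2)
#' @export
count_positive_objects <- function(image, mask, threshold = 0.5,
                                   min_object_px = 4, pixel_size_um = 2) {
  check_image_mask(image, mask)
  check_scalar_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_scalar_number(min_object_px, "min_object_px", 1)

  fg <- (image >= threshold) & mask
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  n_objects <- sum(sizes >= min_object_px)
  annotated_area_mm2 <- sum(mask) * (pixel_size_um / 1000)^2
  tibble(
    n_objects = as.integer(n_objects),
    annotated_area_mm2 = annotated_area_mm2,
    object_frequency = n_objects / annotated_area_mm2,
    stained_area_fraction = 100 * sum(fg) / sum(mask)
  )
}

#' Relative stained area within an annotation
#'
#' Percent of annotated pixels at or above the staining threshold; the
#' readout used for diffuse (non-nuclear) markers.
#'
#' @inheritParams count_positive_objects
#' @return A single percentage in \[0, 100\].
#' @export
stained_area_fraction <- function(image, mask, threshold = 0.5) {
  check_image_mask(image, mask)
  100 * sum((image >= threshold) & mask) / sum(mask)
}
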