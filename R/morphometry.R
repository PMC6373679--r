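#' Histology raster with physical scale and analysis region
#'
#' Container for an RGB tissue raster. The analysis region is the part of the
#' slide selected for morphometry, chosen to avoid interstitial components;
#' all area fractions and counts are taken relative to it.
#'
#' @param pixels Numeric array `height x width x 3`, channel values in
#'   \[0, 1\] (as returned by [png::readPNG()]).
#' @param microns_per_pixel Physical pixel size, um/px, > 0.
#' @param region_mask Logical matrix of the analysed region, same height and
#'   width as `pixels`; defaults to the whole raster.
#' @return An object of class `"tissue_image"`.
#' @export
tissue_image <- function(pixels, microns_per_pixel, region_mask = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] < 3) {
    stop_schema("'pixels' must be a height x width x 3 RGB array")
  }
  if (!is_scalar_number(microns_per_pixel) || microns_per_pixel <= 0) {
    stop_domain("'microns_per_pixel' must be a single positive number")
  }
  d <- dim(pixels)[1:2]
  if (is.null(region_mask)) {
    region_mask <- matrix(TRUE, d[1], d[2])
  }
  if (!is.logical(region_mask) || !identical(dim(region_mask), d)) {
    stop_schema("'region_mask' must be a logical matrix matching the raster size")
  }
  structure(list(pixels = pixels[, , 1:3, drop = FALSE],
                 microns_per_pixel = microns_per_pixel,
                 region_mask = region_mask),
            class = "tissue_image")
}

#' @export
print.tissue_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Tissue image %d x %d px at %g um/px (region: %d px, %.4g um^2)\n",
              d[1], d[2], x$microns_per_pixel, sum(x$region_mask),
              sum(x$region_mask) * x$microns_per_pixel^2))
  invisible(x)
}

#' Segmentation thresholds and filtering parameters
#'
#' Colour classification works in HSV space. Eosin-stained cytoplasm is pink
#' (hue near 0/1 on the circular scale); hematoxylin-stained nuclei are
#' blue-purple. Pixels inside the analysis region whose hue falls in the
#' cytoplasm band are cytoplasm; the nuclei area is the region minus the
#' cytoplasm, mirroring how the areas are measured by subtraction on real
#' slides. The nuclei mask is cleaned by a 1-px-radius morphological opening
#' before components are counted.
#'
#' @param cytoplasm_hue_lo,cytoplasm_hue_hi Circular hue band \[lo, 1\] U
#'   \[0, hi\] classified as eosin/cytoplasm. Defaults cover pink through red.
#' @param min_saturation Pixels below this saturation (and bright) are
#'   treated as background/interstitium and assigned to neither class
#'   (they still count as region area if inside the region mask).
#' @param min_nucleus_area_um2 Connected components smaller than this are
#'   discarded when counting nuclei, um^2.
#' @param opening_radius_px Radius of the opening applied to the nuclei mask
#'   (0 disables it).
#' @return A list of class `"segmentation_config"`.
#' @export
segmentation_config <- function(cytoplasm_hue_lo = 0.85,
                                cytoplasm_hue_hi = 0.10,
                                min_saturation = 0.08,
                                min_nucleus_area_um2 = 4,
                                opening_radius_px = 1) {
  stopifnot(cytoplasm_hue_lo > 0.5, cytoplasm_hue_lo <= 1,
            cytoplasm_hue_hi >= 0, cytoplasm_hue_hi < 0.5,
            min_saturation >= 0, min_nucleus_area_um2 >= 0,
            opening_radius_px %in% c(0, 1))
  structure(list(cytoplasm_hue_lo = cytoplasm_hue_lo,
                 cytoplasm_hue_hi = cytoplasm_hue_hi,
                 min_saturation = min_saturation,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 opening_radius_px = opening_radius_px),
            class = "segmentation_config")
}

#' Segmentation masks for nuclei and cytoplasm
#'
#' Wraps (or validates) a pair of disjoint logical masks. Use this directly
#' to bypass colour segmentation when ground-truth or externally produced
#' masks are available.
#'
#' @param nuclei_mask,cytoplasm_mask Disjoint logical matrices of equal size.
#' @param nuclei_count Number of nucleus components after filtering; computed
#'   by [segment_by_color()] / [count_nuclei()], optional here.
#' @return An object of class `"segmentation_masks"`.
#' @export
segmentation_masks <- function(nuclei_mask, cytoplasm_mask,
                               nuclei_count = NA_integer_) {
  if (!is.logical(nuclei_mask) || !is.logical(cytoplasm_mask) ||
      !identical(dim(nuclei_mask), dim(cytoplasm_mask))) {
    stop_schema("masks must be logical matrices of identical size")
  }
  if (any(nuclei_mask & cytoplasm_mask)) {
    stop_domain("nuclei and cytoplasm masks must be disjoint")
  }
  structure(list(nuclei_mask = nuclei_mask, cytoplasm_mask = cytoplasm_mask,
                 nuclei_count = as.integer(nuclei_count)),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("Segmentation masks: %d nuclei px, %d cytoplasm px, %s nuclei\n",
              sum(x$nuclei_mask), sum(x$cytoplasm_mask),
              if (is.na(x$nuclei_count)) "uncounted" else x$nuclei_count))
  invisible(x)
}

#' Classify nuclei vs cytoplasm by colour tone
#'
#' Pixels inside the analysis region are classified by HSV hue: the eosin
#' (pink) band is cytoplasm and the nuclei area is obtained by subtracting
#' the cytoplasm from the region. Unsaturated bright pixels are treated as
#' neither. The nuclei mask is opened (1 px) and its 8-connected components
#' of at least `config$min_nucleus_area_um2` are counted.
#'
#' @param image A [tissue_image()].
#' @param config A [segmentation_config()].
#' @return A [segmentation_masks()] with `nuclei_count` filled in.
#' @export
segment_by_color <- function(image, config = segmentation_config()) {
  if (!inherits(image, "tissue_image")) {
    stop_schema("'image' must be a tissue_image")
  }
  region <- image$region_mask
  if (!any(region)) stop_domain("the analysis region is empty")
  px <- image$pixels
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  h <- matrix(hsv[1, ], nrow(region), ncol(region))
  s <- matrix(hsv[2, ], nrow(region), ncol(region))
  v <- matrix(hsv[3, ], nrow(region), ncol(region))

  background <- s < config$min_saturation & v > 0.8
  is_pink <- (h >= config$cytoplasm_hue_lo | h <= config$cytoplasm_hue_hi)
  cytoplasm <- region & !background & is_pink
  nuclei <- region & !background & !cytoplasm
  if (any(region) && (!any(nuclei) || !any(cytoplasm))) {
    warning("all classified pixels fall in a single class", call. = FALSE)
  }
  masks <- segmentation_masks(nuclei, cytoplasm)
  # the opening cleans speckle before counting but never alters the areas:
  # the N/C ratio stays a pure colour-subtraction measurement
  counting_mask <- if (config$opening_radius_px > 0) mask_open(nuclei) else nuclei
  masks$nuclei_count <- count_nuclei(
    segmentation_masks(counting_mask, cytoplasm),
    config$min_nucleus_area_um2, image$microns_per_pixel)
  masks
}

# --- binary-mask morphology and labeling ------------------------------------
# 8-connected component labeling is required (EBImage's bwlabel is
# 4-connected), so these primitives are implemented on plain logical
# matrices with vectorized shifts.

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Opening with the 4-neighbour cross (radius-1 disc): erosion then dilation.
mask_open <- function(m) {
  er <- m &
    shift_mat(m, 1, 0) & shift_mat(m, -1, 0) &
    shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
  er |
    shift_mat(er, 1, 0) | shift_mat(er, -1, 0) |
    shift_mat(er, 0, 1) | shift_mat(er, 0, -1)
}

# 8-connected labeling by iterated minimum-label propagation. Converges in
# O(component diameter) sweeps; nuclei are small so this is cheap.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- .Machine$integer.max
  repeat {
    l <- lab
    l[!mask] <- big
    m <- l
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- pmin(m, shift_mat(l, dr, dc, fill = big))
    }
    m[!mask] <- 0L
    if (identical(m, lab)) break
    lab <- m
  }
  # compact labels to 1..n
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Count nuclei as 8-connected components
#'
#' Components with area below `min_area_um2` are discarded; components
#' touching the raster border count once like any other (total region area
#' is divided by total nuclei count downstream, with no edge correction).
#'
#' @param masks A [segmentation_masks()].
#' @param min_area_um2 Minimum component area retained, um^2.
#' @param microns_per_pixel Pixel size used to convert the area threshold.
#' @return Integer count (0 is valid).
#' @export
count_nuclei <- function(masks, min_area_um2 = 4, microns_per_pixel = 1) {
  if (!inherits(masks, "segmentation_masks")) {
    stop_schema("'masks' must be a segmentation_masks object")
  }
  lab <- label_components(masks$nuclei_mask)
  if (max(lab) == 0L) return(0L)
  areas_px <- tabulate(lab[lab > 0])
  min_px <- min_area_um2 / microns_per_pixel^2
  sum(areas_px >= min_px)
}

#' Morphometric indices of a segmented region
#'
#' The N/C ratio `xnc` is the fraction of the analysis region covered by
#' nuclei (an area fraction, which by the Delesse principle estimates the
#' nuclear volume fraction). The cell-size index `xcs` is the region area
#' divided by the number of nuclei it contains, um^2 per cell.
#'
#' @param masks A [segmentation_masks()] with `nuclei_count` set (as
#'   returned by [segment_by_color()]), or pass `nuclei_count` explicitly.
#' @param image The [tissue_image()] the masks refer to (provides the region
#'   and the um/px scale).
#' @param nuclei_count Override for the nucleus count.
#' @return An object of class `"morphometric_indices"`: `xnc` (unitless, in
#'   (0, 1\]), `xcs` (um^2), `nuclei_count`, and areas used.
#' @examples
#' region <- matrix(TRUE, 100, 100)
#' nuc <- matrix(FALSE, 100, 100); nuc[1:30, 1:100] <- TRUE
#' img <- tissue_image(array(1, c(100, 100, 3)), 1, region)
#' m <- segmentation_masks(nuc, region & !nuc, nuclei_count = 10)
#' compute_indices(m, img) # xnc 0.3, xcs 1000
#' @export
compute_indices <- function(masks, image, nuclei_count = masks$nuclei_count) {
  if (!inherits(masks, "segmentation_masks")) {
    stop_schema("'masks' must be a segmentation_masks object")
  }
  if (!inherits(image, "tissue_image")) {
    stop_schema("'image' must be a tissue_image")
  }
  if (is.na(nuclei_count) || nuclei_count < 1) {
    stop_domain("the cell-size index is undefined with zero nuclei")
  }
  region_px <- sum(image$region_mask)
  nuclei_px <- sum(masks$nuclei_mask & image$region_mask)
  mpp <- image$microns_per_pixel
  structure(
    list(xnc = nuclei_px / region_px,
         xcs = region_px * mpp^2 / nuclei_count,
         nuclei_count = as.integer(nuclei_count),
         region_area_um2 = region_px * mpp^2,
         nuclei_area_um2 = nuclei_px * mpp^2),
    class = "morphometric_indices")
}

#' @export
print.morphometric_indices <- function(x, ...) {
  cat("Morphometric indices\n")
  cat(sprintf("  N/C ratio (Xnc):      %.4f\n", x$xnc))
  cat(sprintf("  cell-size index (Xcs): %.4g um^2 (%d nuclei in %.4g um^2)\n",
              x$xcs, x$nuclei_count, x$region_area_um2))
  invisible(x)
}

#' Estimate the in-vivo cell diameter from the cell-size index
#'
#' A histological section cuts each cell at a random height, so observed
#' profiles are smaller than the equatorial cross-section. Treating cells as
#' spheres of radius \eqn{R}, the mean profile radius over random sections is
#' \eqn{(\pi/4) R}. The default convention takes \eqn{\sqrt{X_{cs}/\pi}} as
#' that mean profile radius and inverts the correction:
#' \eqn{R = (4/\pi)\sqrt{X_{cs}/\pi}}, returning the diameter \eqn{2R}. The
#' alternative `"profile-area"` convention instead equates \eqn{X_{cs}} with
#' the mean profile area \eqn{(2/3)\pi R^2}, giving
#' \eqn{R = \sqrt{3 X_{cs}/(2\pi)}}.
#'
#' @param xcs Cell-size index, um^2, > 0.
#' @param convention Stereological convention, `"profile-radius"` (default)
#'   or `"profile-area"`.
#' @return Estimated cell diameter, um.
#' @examples
#' estimate_cell_diameter(108) # 14.9 um
#' @export
estimate_cell_diameter <- function(xcs,
                                   convention = c("profile-radius",
                                                  "profile-area")) {
  convention <- match.arg(convention)
  if (!is.numeric(xcs) || any(!is.finite(xcs)) || any(xcs <= 0)) {
    stop_domain("'xcs' must be positive")
  }
  r <- switch(convention,
              "profile-radius" = (4 / pi) * sqrt(xcs / pi),
              "profile-area" = sqrt(3 * xcs / (2 * pi)))
  2 * r
}

#' Estimate the nucleus diameter from the cell diameter and the N/C ratio
#'
#' The measured N/C area fraction estimates the nuclear volume fraction
#' (Delesse principle); the cube root converts the volume ratio to a linear
#' ratio: `nucleus_diameter = cell_diameter * xnc^(1/3)`.
#'
#' @param cell_diameter Cell diameter, um, > 0.
#' @param xnc N/C ratio in (0, 1].
#' @return Estimated nucleus diameter, um (never exceeds `cell_diameter`).
#' @examples
#' estimate_nucleus_diameter(18.5, 0.347) # 13.0 um
#' @export
estimate_nucleus_diameter <- function(cell_diameter, xnc) {
  if (!is.numeric(cell_diameter) || any(!is.finite(cell_diameter)) ||
      any(cell_diameter <= 0)) {
    stop_domain("'cell_diameter' must be positive")
  }
  if (!is.numeric(xnc) || any(!is.finite(xnc)) || any(xnc <= 0) || any(xnc > 1)) {
    stop_domain("'xnc' must be in (0, 1]")
  }
  cell_diameter * xnc^(1 / 3)
}

#' Full morphometry of one image
#'
#' Convenience wrapper: segment (unless masks are supplied), count, compute
#' indices and the diameter chain.
#'
#' @param image A [tissue_image()].
#' @param config A [segmentation_config()].
#' @param masks Optional [segmentation_masks()] to bypass colour
#'   segmentation (e.g. ground truth); counted here if uncounted.
#' @return A one-row data frame: `xnc`, `xcs_um2`, `cell_diameter_um`,
#'   `nucleus_diameter_um`, `nuclei_count`.
#' @export
morphometry_from_image <- function(image, config = segmentation_config(),
                                   masks = NULL) {
  if (is.null(masks)) {
    masks <- segment_by_color(image, config)
  } else if (is.na(masks$nuclei_count)) {
    masks$nuclei_count <- count_nuclei(masks, config$min_nucleus_area_um2,
                                       image$microns_per_pixel)
  }
  idx <- compute_indices(masks, image)
  cd <- estimate_cell_diameter(idx$xcs)
  data.frame(xnc = idx$xnc, xcs_um2 = idx$xcs,
             cell_diameter_um = cd,
             nucleus_diameter_um = estimate_nucleus_diameter(cd, idx$xnc),
             nuclei_count = idx$nuclei_count)
}
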