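#' Simulate a paired colony-survival experiment
#'
#' Generates a beam-only control curve and a beam-plus-boron curve with a
#' known boron-neutron D0, so the extraction chain can be validated against
#' ground truth. Expected survival at fluence \eqn{\varphi} is
#' \eqn{\exp(-k\varphi)} with \eqn{k = k_{beam}} for the control and
#' \eqn{k = k_{beam} + k_B} with boron, where the boron slope is chosen so
#' the configured D0 holds in closed form:
#' \eqn{k_B = kerma \times ppm / D_0}. Colony counts are Poisson with mean
#' `n_plated * plating_efficiency * SF` (the standard noise model for
#' colony-forming-unit counts; no over-dispersion).
#'
#' @param k_beam Log-survival slope of the beam-only control, per n/cm^2.
#' @param d0_true True boron-neutron D0, Gy.
#' @param boron_ppm Tumour 10B concentration, ppm.
#' @param fluences Design fluences, n/cm^2.
#' @param n_plated Cells plated per dish.
#' @param plating_efficiency Fraction of unirradiated cells forming colonies.
#' @param drug Carrier label attached to the boron curve.
#' @param noise If `FALSE`, curves carry the exact expected surviving
#'   fractions (no sampling).
#' @param seed Optional RNG seed; identical seed and configuration give
#'   bit-identical output.
#' @param kerma Dose-conversion coefficient, see [boron_kerma_coefficient].
#' @return An object of class `"survival_simulation"`: `beam` and `boron`
#'   ([survival_curve()]s) and `truth` (k_beam, k_boron, k_total, phi0_true,
#'   d0_true, boron_ppm).
#' @examples
#' sim <- simulate_survival_experiment(noise = FALSE)
#' extract_boron_component(sim$beam, sim$boron)$d0 # 0.35 exactly
#' @export
simulate_survival_experiment <- function(k_beam = 1e-12,
                                         d0_true = 0.35,
                                         boron_ppm = 25,
                                         fluences = c(0, 5e10, 1e11, 1.5e11, 2e11),
                                         n_plated = 1e5,
                                         plating_efficiency = 0.6,
                                         drug = c("BPA", "BSH"),
                                         noise = TRUE,
                                         seed = NULL,
                                         kerma = boron_kerma_coefficient) {
  drug <- match.arg(drug)
  if (!is_scalar_number(d0_true) || d0_true <= 0) {
    stop_domain("'d0_true' must be a single positive number")
  }
  if (!is_scalar_number(boron_ppm) || boron_ppm <= 0) {
    stop_domain("'boron_ppm' must be a single positive number")
  }
  if (!is.null(seed)) set.seed(seed)
  k_boron <- kerma * boron_ppm / d0_true
  k_total <- k_beam + k_boron
  sf_beam <- exp(-k_beam * fluences)
  sf_total <- exp(-k_total * fluences)

  if (noise) {
    mu_beam <- n_plated * plating_efficiency * sf_beam
    mu_total <- n_plated * plating_efficiency * sf_total
    if (any(c(mu_beam, mu_total) < 1)) {
      warning("expected colony count < 1 at some design point; log-survival is unstable there",
              call. = FALSE)
    }
    beam <- survival_curve(fluences,
                           colonies = stats::rpois(length(fluences), mu_beam),
                           plated = rep(n_plated, length(fluences)),
                           plating_efficiency = plating_efficiency)
    boron <- survival_curve(fluences,
                            colonies = stats::rpois(length(fluences), mu_total),
                            plated = rep(n_plated, length(fluences)),
                            plating_efficiency = plating_efficiency,
                            condition = "beam_plus_boron", drug = drug,
                            boron_ppm = boron_ppm)
  } else {
    beam <- survival_curve(fluences, sf_beam)
    boron <- survival_curve(fluences, sf_total,
                            condition = "beam_plus_boron", drug = drug,
                            boron_ppm = boron_ppm)
  }
  structure(
    list(beam = beam, boron = boron,
         truth = list(k_beam = k_beam, k_boron = k_boron, k_total = k_total,
                      phi0_true = 1 / k_boron, d0_true = d0_true,
                      boron_ppm = boron_ppm, kerma = kerma,
                      n_plated = n_plated,
                      plating_efficiency = plating_efficiency)),
    class = "survival_simulation")
}

#' @export
print.survival_simulation <- function(x, ...) {
  cat(sprintf("Simulated survival experiment: true D0 = %g Gy at %g ppm (phi0 = %.4g n/cm^2)\n",
              x$truth$d0_true, x$truth$boron_ppm, x$truth$phi0_true))
  invisible(x)
}

# Random sequential placement of non-overlapping discs (d = 2) or spheres
# (d = 3) with centres kept inside the domain. Errors when the requested
# density cannot be packed within the retry budget.
pack_hard_bodies <- function(n, radii, lo, hi, dim, gap = 0,
                             max_attempts_each = 5000L) {
  centres <- matrix(NA_real_, n, dim)
  for (i in seq_len(n)) {
    if (any(hi - radii[i] < lo + radii[i])) {
      stop_domain("domain too small for the requested cell radius")
    }
    placed <- FALSE
    for (a in seq_len(max_attempts_each)) {
      p <- stats::runif(dim, lo + radii[i], hi - radii[i])
      if (i == 1) { placed <- TRUE }
      else {
        prev <- centres[seq_len(i - 1), , drop = FALSE]
        d2 <- rowSums((prev - matrix(p, i - 1, dim, byrow = TRUE))^2)
        placed <- all(d2 >= (radii[seq_len(i - 1)] + radii[i] + gap)^2)
      }
      if (placed) { centres[i, ] <- p; break }
    }
    if (!placed) {
      stop_domain(sprintf(
        "could not place cell %d of %d without overlap; lower the density (fewer or smaller cells, or a larger domain)",
        i, n))
    }
  }
  centres
}

sample_radii <- function(n, mean_radius, cv) {
  if (cv <= 0) return(rep(mean_radius, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean_radius / shape)
}

#' Render a synthetic H&E-like tissue section with ground truth
#'
#' Places non-overlapping circular cell profiles with concentric nuclei
#' whose area fraction matches `target_xnc` (nucleus radius
#' \eqn{r\sqrt{X_{nc}}}), then rasterizes them: eosin-pink cytoplasm,
#' hematoxylin-purple nuclei, near-white background, with seeded colour
#' jitter. The analysis region is the union of the cell profiles
#' (interstitium excluded, as on a real slide). Exact per-pixel masks and
#' achieved indices are returned as ground truth. The render is the section
#' itself: no 3D sectioning effects are modelled here (see
#' [simulate_sectioned_tissue()] for those).
#'
#' @param n_cells Number of cell profiles to place.
#' @param mean_cell_radius Mean profile radius, um.
#' @param radius_cv Coefficient of variation of the radii.
#' @param target_xnc Target nuclear area fraction, in (0, 1).
#' @param microns_per_pixel Raster scale, um/px.
#' @param image_size Raster side, px (square image).
#' @param seed Optional RNG seed; same seed, same raster.
#' @param colour_jitter Half-width of the per-cell uniform colour jitter.
#' @return An object of class `"synthetic_tissue"`: `image`
#'   ([tissue_image()]), `masks` (ground-truth [segmentation_masks()] with
#'   the planted count), and `truth` (achieved `xnc`, `xcs`, centres,
#'   radii).
#' @export
generate_tissue_image <- function(n_cells = 120,
                                  mean_cell_radius = 7.5,
                                  radius_cv = 0.15,
                                  target_xnc = 0.5,
                                  microns_per_pixel = 0.5,
                                  image_size = 512,
                                  seed = NULL,
                                  colour_jitter = 0.04) {
  if (!is_scalar_number(target_xnc) || target_xnc <= 0 || target_xnc >= 1) {
    stop_domain("'target_xnc' must be in (0, 1)")
  }
  if (n_cells < 1) stop_domain("'n_cells' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  side_um <- image_size * microns_per_pixel
  radii <- sample_radii(n_cells, mean_cell_radius, radius_cv)
  centres <- pack_hard_bodies(n_cells, radii, 0, side_um, dim = 2,
                              gap = microns_per_pixel)
  r_nuc <- radii * sqrt(target_xnc)

  region <- matrix(FALSE, image_size, image_size)
  nuclei <- matrix(FALSE, image_size, image_size)
  cell_id <- matrix(0L, image_size, image_size)
  px_coord <- (seq_len(image_size) - 0.5) * microns_per_pixel
  for (i in seq_len(n_cells)) {
    cx <- centres[i, 1]; cy <- centres[i, 2]; r <- radii[i]
    rows <- which(px_coord >= cy - r & px_coord <= cy + r)
    cols <- which(px_coord >= cx - r & px_coord <= cx + r)
    if (!length(rows) || !length(cols)) next
    d2 <- outer((px_coord[rows] - cy)^2, (px_coord[cols] - cx)^2, `+`)
    inside <- d2 <= r^2
    region[rows, cols] <- region[rows, cols] | inside
    cell_id[rows, cols][inside] <- i
    nuclei[rows, cols] <- nuclei[rows, cols] | (d2 <= r_nuc[i]^2)
  }
  cytoplasm <- region & !nuclei

  base_nucleus <- c(0.38, 0.22, 0.58)
  base_cytoplasm <- c(0.93, 0.62, 0.72)
  base_background <- c(0.97, 0.96, 0.97)
  jit <- matrix(stats::runif(3 * n_cells, -colour_jitter, colour_jitter),
                n_cells, 3)
  px <- array(0, c(image_size, image_size, 3))
  for (ch in 1:3) {
    plane <- matrix(base_background[ch], image_size, image_size)
    idx <- which(cytoplasm)
    plane[idx] <- base_cytoplasm[ch] + jit[cell_id[idx], ch]
    idx <- which(nuclei)
    plane[idx] <- base_nucleus[ch] + jit[cell_id[idx], ch]
    px[, , ch] <- pmin(pmax(plane, 0), 1)
  }

  img <- tissue_image(px, microns_per_pixel, region_mask = region)
  masks <- segmentation_masks(nuclei, cytoplasm, nuclei_count = n_cells)
  achieved_xnc <- sum(nuclei) / sum(region)
  structure(
    list(image = img, masks = masks,
         truth = list(n_cells = n_cells, target_xnc = target_xnc,
                      achieved_xnc = achieved_xnc,
                      xcs = sum(region) * microns_per_pixel^2 / n_cells,
                      centres = centres, radii = radii,
                      nucleus_radii = r_nuc)),
    class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("Synthetic tissue: %d cells, achieved Xnc %.3f (target %.3f), Xcs %.4g um^2\n",
              x$truth$n_cells, x$truth$achieved_xnc, x$truth$target_xnc,
              x$truth$xcs))
  invisible(x)
}

#' Monte-Carlo statistics of random sphere sections
#'
#' Samples section offsets z uniform on \[0, R\] (sections conditioned on
#' hitting the sphere) and returns profile statistics. Closed forms for
#' comparison: mean profile radius \eqn{E\sqrt{R^2-z^2} = \pi R/4}, mean
#' profile area \eqn{E[\pi(R^2-z^2)] = (2/3)\pi R^2}. This is the
#' independent oracle behind the stereological diameter convention of
#' [estimate_cell_diameter()].
#'
#' @param radius Sphere radius, um, > 0.
#' @param n Number of sections, >= 1.
#' @param seed Optional RNG seed.
#' @return A list of class `"section_profile_stats"`: `mean_profile_radius`,
#'   `se_profile_radius`, `mean_profile_area`, `se_profile_area`, `n`,
#'   `radius`.
#' @export
simulate_random_sections <- function(radius, n, seed = NULL) {
  if (!is_scalar_number(radius) || radius <= 0) {
    stop_domain("'radius' must be a single positive number")
  }
  if (!is_scalar_number(n) || n < 1) stop_domain("'n' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  z <- stats::runif(n, 0, radius)
  pr <- sqrt(radius^2 - z^2)
  pa <- pi * (radius^2 - z^2)
  structure(
    list(mean_profile_radius = mean(pr),
         se_profile_radius = stats::sd(pr) / sqrt(n),
         mean_profile_area = mean(pa),
         se_profile_area = stats::sd(pa) / sqrt(n),
         n = as.integer(n), radius = radius),
    class = "section_profile_stats")
}

#' @export
print.section_profile_stats <- function(x, ...) {
  cat(sprintf("Random sections of a sphere (R = %g, n = %d)\n", x$radius, x$n))
  cat(sprintf("  mean profile radius: %.6g (SE %.3g; pi*R/4 = %.6g)\n",
              x$mean_profile_radius, x$se_profile_radius, pi * x$radius / 4))
  cat(sprintf("  mean profile area:   %.6g (SE %.3g; 2*pi*R^2/3 = %.6g)\n",
              x$mean_profile_area, x$se_profile_area,
              2 * pi * x$radius^2 / 3))
  invisible(x)
}

#' Section a packed 3D tissue and compare observed indices with truth
#'
#' Packs spheres (cells) with concentric nuclear spheres of radius
#' \eqn{r \cdot X_{nc}^{1/3}} in a cubic box, cuts it with random horizontal
#' planes, and measures on each section what slide morphometry would
#' measure: the analysed region is the union of cell profiles, nuclei are
#' counted only when the plane actually cuts the nucleus. Because a plane
#' can cut a cell while missing its nucleus — and does so more often the
#' smaller the N/C ratio — the observed cell-size index (region area per
#' counted nucleus) overestimates the true mean cell cross-section per cell,
#' and the overestimation grows as the N/C ratio falls.
#'
#' @param n_cells Number of spheres packed, >= 1.
#' @param mean_cell_radius Mean sphere radius, um.
#' @param radius_cv Coefficient of variation of the radii.
#' @param xnc_true True nuclear volume fraction, in (0, 1].
#' @param box_size Box side, um.
#' @param n_sections Number of random section planes.
#' @param seed Optional RNG seed. The packing and plane offsets depend only
#'   on the seed and the geometry parameters, so two runs differing only in
#'   `xnc_true` share identical cells and planes (paired comparison).
#' @return An object of class `"sectioning_simulation"`: `sections` (a data
#'   frame with per-section `n_cells_cut`, `n_nuclei_cut`,
#'   `region_area_um2`, `observed_xnc`, `observed_xcs`, `true_xcs`) and
#'   `truth`. `observed_xcs`/`true_xcs` are `NA` for sections cutting no
#'   nucleus / no cell. Use [overestimation_ratio()] to summarise.
#' @export
simulate_sectioned_tissue <- function(n_cells = 120,
                                      mean_cell_radius = 7.5,
                                      radius_cv = 0.1,
                                      xnc_true = 0.5,
                                      box_size = 120,
                                      n_sections = 100,
                                      seed = NULL) {
  if (!is_scalar_number(n_cells) || n_cells < 1) {
    stop_domain("an empty box cannot be sectioned: 'n_cells' must be >= 1")
  }
  if (!is_scalar_number(xnc_true) || xnc_true <= 0 || xnc_true > 1) {
    stop_domain("'xnc_true' must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  radii <- sample_radii(n_cells, mean_cell_radius, radius_cv)
  centres <- pack_hard_bodies(n_cells, radii, 0, box_size, dim = 3)
  planes <- stats::runif(n_sections, 0, box_size)
  r_nuc <- radii * xnc_true^(1 / 3)

  sections <- lapply(planes, function(z0) {
    dz <- centres[, 3] - z0
    cut_cell <- abs(dz) < radii
    n_cut <- sum(cut_cell)
    cell_area <- sum(pi * (radii[cut_cell]^2 - dz[cut_cell]^2))
    cut_nuc <- abs(dz) < r_nuc
    n_nuc <- sum(cut_nuc)
    nuc_area <- sum(pi * (r_nuc[cut_nuc]^2 - dz[cut_nuc]^2))
    data.frame(
      z = z0, n_cells_cut = n_cut, n_nuclei_cut = n_nuc,
      region_area_um2 = cell_area,
      observed_xnc = if (n_cut > 0) nuc_area / cell_area else NA_real_,
      observed_xcs = if (n_nuc > 0) cell_area / n_nuc else NA_real_,
      true_xcs = if (n_cut > 0) cell_area / n_cut else NA_real_)
  })
  structure(
    list(sections = do.call(rbind, sections),
         truth = list(n_cells = n_cells, xnc_true = xnc_true,
                      radii = radii, centres = centres,
                      mean_equatorial_area = mean(pi * radii^2))),
    class = "sectioning_simulation")
}

#' Mean cell-size-index overestimation of a sectioning simulation
#'
#' Ratio of the observed cell-size index to the true mean cell cross-section
#' per cell, averaged over sections that cut at least one nucleus. A value
#' above 1 means slide morphometry overestimates cell size.
#'
#' @param sim A [simulate_sectioned_tissue()] result.
#' @return A list: `mean_ratio`, `fraction_overestimated` (share of usable
#'   sections with observed > true), `n_sections_used`.
#' @export
overestimation_ratio <- function(sim) {
  if (!inherits(sim, "sectioning_simulation")) {
    stop_schema("'sim' must be a sectioning_simulation")
  }
  s <- sim$sections
  ok <- !is.na(s$observed_xcs) & !is.na(s$true_xcs)
  list(mean_ratio = mean(s$observed_xcs[ok] / s$true_xcs[ok]),
       fraction_overestimated = mean(s$observed_xcs[ok] > s$true_xcs[ok]),
       n_sections_used = sum(ok))
}

#' @export
print.sectioning_simulation <- function(x, ...) {
  r <- overestimation_ratio(x)
  cat(sprintf("Sectioned 3D tissue: %d cells, true Xnc %.2f, %d sections\n",
              x$truth$n_cells, x$truth$xnc_true, nrow(x$sections)))
  cat(sprintf("  mean Xcs overestimation ratio: %.3f (observed > true in %.0f%% of sections)\n",
              r$mean_ratio, 100 * r$fraction_overestimated))
  invisible(x)
}
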