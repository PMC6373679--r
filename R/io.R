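#' Load survival curves from CSV
#'
#' Expects a UTF-8 CSV with a header and columns `condition`
#' (`beam_only`/`beam_plus_boron`), `drug` (`none`/`BPA`/`BSH`),
#' `boron_ppm`, `fluence_n_per_cm2`, and either `surviving_fraction` or the
#' pair `colonies`,`plated`. One curve is built per distinct
#' (condition, drug, boron_ppm) combination. In the counts variant the
#' plating efficiency is taken from the zero-fluence beam-only row unless a
#' `plating_efficiency` column is present. Validation failures report the
#' offending data row.
#'
#' @param path CSV file path.
#' @return A list of [survival_curve()] objects.
#' @export
load_survival_csv <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "drug", "boron_ppm", "fluence_n_per_cm2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  has_sf <- "surviving_fraction" %in% names(df)
  has_counts <- all(c("colonies", "plated") %in% names(df))
  if (!has_sf && !has_counts) {
    stop_schema("need either a 'surviving_fraction' column or 'colonies' and 'plated'")
  }

  # rows are reported as file rows (the header is row 1)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop_schema(sprintf("row %d: non-numeric value '%s' in column '%s'",
                          bad[1] + 1, df[[col]][bad[1]], col))
    }
    v
  }
  fluence <- num("fluence_n_per_cm2")
  ppm <- num("boron_ppm")
  if (has_sf) {
    sf <- num("surviving_fraction")
    bad <- which(!is.na(sf) & (sf <= 0 | sf > 1))
    if (length(bad)) {
      stop_schema(sprintf("row %d: surviving_fraction %g is outside (0, 1]",
                          bad[1] + 1, sf[bad[1]]))
    }
  } else {
    colonies <- num("colonies")
    plated <- num("plated")
    pe_col <- if ("plating_efficiency" %in% names(df)) num("plating_efficiency")
  }

  key <- paste(df$condition, df$drug, ppm, sep = "\r")
  curves <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                   function(rows) {
    cond <- df$condition[rows[1]]
    drug <- df$drug[rows[1]]
    if (!cond %in% c("beam_only", "beam_plus_boron")) {
      stop_schema(sprintf("row %d: unknown condition '%s'", rows[1] + 1, cond))
    }
    if (!drug %in% c("none", "BPA", "BSH")) {
      stop_schema(sprintf("row %d: unknown drug '%s'", rows[1] + 1, drug))
    }
    if (has_sf) {
      survival_curve(fluence[rows], surviving_fraction = sf[rows],
                     condition = cond, drug = drug,
                     boron_ppm = ppm[rows[1]])
    } else {
      pe <- if (!is.null(pe_col)) pe_col[rows[1]] else {
        ctrl <- which(df$condition == "beam_only" & fluence == 0)
        if (!length(ctrl)) {
          stop_schema("cannot derive plating efficiency: no zero-fluence beam-only row")
        }
        colonies[ctrl[1]] / plated[ctrl[1]]
      }
      survival_curve(fluence[rows], colonies = colonies[rows],
                     plated = plated[rows], plating_efficiency = pe,
                     condition = cond, drug = drug,
                     boron_ppm = ppm[rows[1]])
    }
  })
  unname(curves)
}

#' Write survival curves to CSV
#'
#' Writes in the `surviving_fraction` schema of [load_survival_csv()], with
#' full (17 significant digit) precision so a written file re-loads to
#' curves numerically equal to the originals.
#'
#' @param curves A list of [survival_curve()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(curves, path) {
  if (inherits(curves, "survival_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(condition = cv$condition, drug = cv$drug,
               boron_ppm = sprintf("%.17g", cv$boron_ppm),
               fluence_n_per_cm2 = sprintf("%.17g", cv$fluence),
               surviving_fraction = sprintf("%.17g", cv$surviving_fraction))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged tumour reference tables
#'
#' Published reference measurements for five experimental tumour lines (EL4
#' leukemia, B16-BL6 melanoma, SAS/neo and SAS/mp53 oral squamous carcinoma,
#' SCCVII squamous carcinoma):
#' * `"d0_morphometry"` — boron-neutron D0 (Gy) under BPA and BSH together
#'   with the slide-derived N/C ratio `xnc` and cell-size index `xcs`
#'   (um^2). This is the table the default prediction models are fitted to.
#'   The B16-BL6 N/C ratio is stored as 0.3.
#' * `"total_dose_d0"` — D0 of the total dose (Gy) for beam-only, BPA and
#'   BSH conditions.
#' * `"diameters_in_vitro"` — estimated in-vivo (slide) and measured
#'   in-vitro cell and nucleus diameters (um).
#'
#' @param which Which table to load.
#' @return A data frame.
#' @export
tumor_reference_data <- function(which = c("d0_morphometry", "total_dose_d0",
                                           "diameters_in_vitro")) {
  which <- match.arg(which)
  file <- switch(which,
                 d0_morphometry = "tumor_d0_morphometry.csv",
                 total_dose_d0 = "tumor_total_dose_d0.csv",
                 diameters_in_vitro = "tumor_diameters_in_vitro.csv")
  path <- system.file("extdata", file, package = "abebnct", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Save a fitted D0 model as a JSON model card
#'
#' @param model A [fit_power_law()] or [fit_linear()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_card <- function(model, path) {
  card <- if (inherits(model, "power_law_fit")) {
    list(form = "power",
         coefficients = list(a = model$a, b = model$b),
         r_squared = model$r_squared,
         r_squared_scale = model$r_squared_scale,
         n = model$n, exclusions = I(character()))
  } else if (inherits(model, "linear_d0_fit")) {
    list(form = "linear",
         coefficients = list(slope = model$slope, intercept = model$intercept),
         r_squared = model$r_squared, r_squared_scale = "y",
         n = model$n, exclusions = I(model$exclusions))
  } else {
    stop_schema("'model' must be a power_law_fit or linear_d0_fit")
  }
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON model card back into a fitted-model object
#'
#' @param path Path written by [write_model_card()].
#' @return A `"power_law_fit"` or `"linear_d0_fit"` usable with
#'   [predict_d0()].
#' @export
read_model_card <- function(path) {
  if (!file.exists(path)) {
    stop_schema(sprintf("model card not found: %s", path))
  }
  card <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(card$form) ||
      !card$form %in% c("power", "linear")) {
    stop_schema("model card must have form 'power' or 'linear'")
  }
  if (card$form == "power") {
    structure(list(a = card$coefficients$a, b = card$coefficients$b,
                   r_squared = card$r_squared,
                   r_squared_scale = card$r_squared_scale %||% "ln-ln",
                   n = card$n, x = NULL, y = NULL),
              class = "power_law_fit")
  } else {
    structure(list(slope = card$coefficients$slope,
                   intercept = card$coefficients$intercept,
                   r_squared = card$r_squared, n = card$n,
                   exclusions = as.character(card$exclusions %||% character()),
                   x = NULL, y = NULL),
              class = "linear_d0_fit")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tissue image (and optional mask sidecar) from disk
#'
#' @param path RGB PNG path.
#' @param microns_per_pixel Raster scale, um/px.
#' @param mask_path Optional single-channel PNG sidecar encoding
#'   0 = background, 1 = cytoplasm, 2 = nuclei (stored as intensity/255).
#' @return A list: `image` ([tissue_image()]; the region is the whole
#'   raster, or the non-background part of the sidecar when given) and
#'   `masks` ([segmentation_masks()] or `NULL`).
#' @export
read_tissue_png <- function(path, microns_per_pixel, mask_path = NULL) {
  if (!file.exists(path)) stop_schema(sprintf("image not found: %s", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) {
    stop_schema("expected an RGB image, got a single-channel raster")
  }
  masks <- NULL
  region <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) {
      stop_schema(sprintf("mask sidecar not found: %s", mask_path))
    }
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    codes <- round(m * 255)
    region <- codes > 0
    masks <- segmentation_masks(codes == 2, codes == 1)
  }
  img <- tissue_image(px, microns_per_pixel, region_mask = region)
  list(image = img, masks = masks)
}

#' Write a tissue image (and mask sidecar) as PNG
#'
#' @param tissue A [tissue_image()] or [generate_tissue_image()] result.
#' @param path Output PNG path.
#' @param mask_path Optional path for the 0/1/2-coded mask sidecar (written
#'   only for objects that carry masks).
#' @return `path`, invisibly.
#' @export
write_tissue_png <- function(tissue, path, mask_path = NULL) {
  img <- if (inherits(tissue, "synthetic_tissue")) tissue$image else tissue
  if (!inherits(img, "tissue_image")) {
    stop_schema("'tissue' must be a tissue_image or synthetic_tissue")
  }
  png::writePNG(img$pixels, path)
  if (!is.null(mask_path)) {
    masks <- if (inherits(tissue, "synthetic_tissue")) tissue$masks else NULL
    if (is.null(masks)) stop_schema("no masks available to write")
    codes <- matrix(0, nrow(img$region_mask), ncol(img$region_mask))
    codes[masks$cytoplasm_mask] <- 1
    codes[masks$nuclei_mask] <- 2
    png::writePNG(codes / 255, mask_path)
  }
  invisible(path)
}

# Flat record of a boron-component extraction, for JSON reports.
boron_component_record <- function(bc) {
  list(phi0_n_per_cm2 = bc$phi0,
       d0_gy = bc$d0,
       boron_ppm = bc$boron_ppm,
       kerma_coefficient = bc$kerma_coefficient,
       drug = bc$drug,
       slope_beam = bc$fit_beam$slope_k,
       slope_total = bc$fit_boron$slope_k,
       r_squared_beam = bc$fit_beam$r_squared,
       r_squared_total = bc$fit_boron$r_squared)
}
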