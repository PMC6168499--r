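# ---- spheroid segmentation and image-derived health readouts ----
#
# Two readouts per spheroid: the shape factor S_F = P^2 / (4 pi A)
# (1 for a circle, rising with boundary roughness/disaggregation) and the
# viable fraction V_F = Area_FDA / Area_BF_before_drug. Perimeters come from
# a sub-pixel contour (marching squares at the 0.5 level of the smoothed
# mask); pixel-edge counting would overestimate P by up to ~27% and destroy
# the S_F ~ 1 circle baseline.

#' Segmentation parameters
#'
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold used when
#'   `threshold = "fixed"`.
#' @param min_area Minimum object area (um^2) for a detection.
#' @param fill_holes Fill interior holes of the mask.
#' @param smoothing Gaussian pre-smoothing sigma (px), also used when
#'   extracting the sub-pixel contour.
#' @param polarity `"dark"` for objects darker than background
#'   (brightfield), `"bright"` for fluorescence channels.
#' @param min_contrast Minimum separation between object and background
#'   mean intensities; Otsu always returns a split, so thresholds that
#'   merely bisect background noise are rejected as non-detections.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold = c("otsu", "fixed"),
                                fixed_threshold = 0.5, min_area = 400,
                                fill_holes = TRUE, smoothing = 1.5,
                                polarity = c("dark", "bright"),
                                min_contrast = 0.1) {
  threshold <- match.arg(threshold)
  polarity <- match.arg(polarity)
  if (min_area < 0) stop("min_area must be >= 0")
  structure(list(threshold = threshold, fixed_threshold = fixed_threshold,
                 min_area = min_area, fill_holes = fill_holes,
                 smoothing = smoothing, polarity = polarity,
                 min_contrast = min_contrast),
            class = "segmentation_params")
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
}

#' Sub-pixel contour of a binary mask
#'
#' Smooths the mask with a Gaussian and extracts the 0.5-level isoline
#' (marching squares with linear interpolation), giving a sub-pixel boundary
#' whose shoelace perimeter/area are unbiased enough for shape-factor work.
#'
#' @param mask Logical or 0/1 matrix.
#' @param pixel_scale Pixel size (um/px).
#' @param smooth_sigma Gaussian sigma (px) applied to the mask before
#'   contouring.
#' @return An n x 2 matrix of contour coordinates (um), or `NULL` when no
#'   closed contour exists.
#' @export
mask_contour <- function(mask, pixel_scale = 1, smooth_sigma = 1.5) {
  m <- gaussian_smooth(mask * 1.0, smooth_sigma)
  nr <- nrow(m); nc <- ncol(m)
  cl <- grDevices::contourLines(x = seq_len(nr) * pixel_scale,
                                y = seq_len(nc) * pixel_scale,
                                z = m, levels = 0.5)
  if (!length(cl)) return(NULL)
  # keep the longest closed isoline (the object boundary)
  len <- vapply(cl, function(g) length(g$x), integer(1))
  g <- cl[[which.max(len)]]
  cbind(x = g$x, y = g$y)
}

#' Segment a spheroid in a single-well crop
#'
#' Global threshold (Otsu by default) -> hole filling -> largest connected
#' component -> sub-pixel contour. Returns a `no_detection` flag when no
#' object reaches `min_area`, and a `multi_object` flag when more than one
#' does (the largest is kept).
#'
#' @param img Numeric intensity matrix in \[0, 1\].
#' @param params A [segmentation_params()].
#' @param pixel_scale Pixel size (um/px).
#' @return A list: `mask` (logical matrix), `contour` (n x 2, um),
#'   `area_um2`, `perimeter_um` (both from the sub-pixel polygon),
#'   `flags` (character vector).
#' @export
segment_spheroid <- function(img, params = segmentation_params(),
                             pixel_scale = 1) {
  stopifnot(is.matrix(img))
  work <- gaussian_smooth(img, params$smoothing)
  thr <- if (params$threshold == "otsu") {
    EBImage::otsu(EBImage::Image(pmin(pmax(work, 0), 1)))
  } else params$fixed_threshold
  mask <- if (params$polarity == "dark") work < thr else work > thr
  none <- list(mask = matrix(FALSE, nrow(img), ncol(img)), contour = NULL,
               area_um2 = NA_real_, perimeter_um = NA_real_,
               flags = "no_detection")
  if (!any(mask) || all(mask)) return(none)
  if (abs(mean(work[mask]) - mean(work[!mask])) < params$min_contrast) {
    return(none)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (params$fill_holes) lab <- EBImage::fillHull(lab)
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  min_px <- params$min_area / pixel_scale^2
  big <- which(sizes >= min_px)
  if (!length(big)) return(none)
  flags <- character(0)
  if (length(big) > 1) flags <- "multi_object"
  keep <- big[which.max(sizes[big])]
  mask <- lab == keep
  contour <- mask_contour(mask, pixel_scale, params$smoothing)
  if (is.null(contour) || nrow(contour) < 8) {
    return(utils::modifyList(none, list(mask = mask)))
  }
  list(mask = mask, contour = contour,
       area_um2 = polygon_area(contour),
       perimeter_um = polygon_perimeter(contour),
       flags = flags)
}

#' Shape factor
#'
#' `S_F = P^2 / (4 pi A)`: 1 for a perfect circle (isoperimetric minimum),
#' increasing as the boundary roughens or the spheroid disaggregates.
#' Accepts a closed contour (n x 2 matrix, >= 8 vertices), a logical mask
#' (contoured sub-pixel first), or a [segment_spheroid()] result.
#'
#' @param x Contour matrix, logical mask, or segmentation result.
#' @param pixel_scale Pixel size (um/px), used when `x` is a mask.
#' @return The dimensionless shape factor.
#' @export
#' @examples
#' shape_factor(spheroid_contour(50, 0))     # ~1
#' shape_factor(spheroid_contour(50, 0.2))   # > 1
shape_factor <- function(x, pixel_scale = 1) {
  if (is.list(x) && !is.null(x$contour)) x <- x$contour
  if (is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))) {
    x <- mask_contour(x, pixel_scale)
  }
  if (is.null(x) || !is.matrix(x) || ncol(x) != 2 || nrow(x) < 8) {
    stop("shape_factor needs a closed contour with >= 8 vertices")
  }
  A <- polygon_area(x)
  if (A <= 0) stop("degenerate contour: zero enclosed area")
  polygon_perimeter(x)^2 / (4 * pi * A)
}

#' Viable fraction
#'
#' `V_F = Area_FDA / Area_BF_PtD`: the FDA-stained (viable) area at
#' end-point over the brightfield spheroid area on the last day prior to
#' drug incubation. `V_F >= 1` marks a spheroid that grew or was unaffected;
#' `V_F < 1` a detrimental drug effect. The classification is attached as
#' attribute `"status"`.
#'
#' @param area_fda End-point FDA-positive area (um^2).
#' @param baseline_area Pre-drug brightfield area (um^2); must be > 0.
#' @return Numeric viable fraction(s) with a `"status"` attribute
#'   (`"grown/unaffected"` or `"detrimental/unhealthy"`).
#' @export
viable_fraction <- function(area_fda, baseline_area) {
  if (any(!is.finite(baseline_area)) || any(baseline_area <= 0)) {
    stop("viable fraction undefined without a positive pre-drug baseline area")
  }
  if (any(area_fda < 0)) stop("area_fda must be >= 0")
  vf <- area_fda / baseline_area
  attr(vf, "status") <- ifelse(vf >= 1, "grown/unaffected",
                               "detrimental/unhealthy")
  vf
}

#' Measure a spheroid image time course
#'
#' Segments every brightfield crop of an image set, computes per-well,
#' per-day area, perimeter, equivalent diameter and shape factor, fixes the
#' viability baseline as the brightfield area on the last imaged day before
#' `drug_day`, and computes the viable fraction wherever an FDA frame
#' exists. Missing well/day combinations are tolerated.
#'
#' @param imgset A [render_experiment()] result (or [read_image_set()]
#'   output).
#' @param params A [segmentation_params()] for the brightfield channel.
#' @param drug_day Drug-application day; defaults to the set's metadata.
#' @return A tibble with one row per well per imaged day: `well_row`,
#'   `well_col`, `day`, `area_um2`, `perimeter_um`, `eq_diam_um`,
#'   `shape_factor`, `fda_area_um2`, `baseline_area_um2`,
#'   `viable_fraction`, `flags`.
#' @export
measure_timecourse <- function(imgset, params = segmentation_params(),
                               drug_day = NULL) {
  if (is.null(drug_day)) drug_day <- imgset$drug_day
  if (is.null(drug_day)) stop("drug_day must be given")
  ps <- imgset$pixel_scale
  fparams <- segmentation_params(
    threshold = params$threshold, fixed_threshold = params$fixed_threshold,
    min_area = params$min_area, fill_holes = params$fill_holes,
    smoothing = params$smoothing, polarity = "bright")
  rows <- lapply(seq_len(nrow(imgset$manifest)), function(i) {
    m <- imgset$manifest[i, ]
    crop <- imgset$images[[m$key]]
    seg <- segment_spheroid(crop$brightfield, params, ps)
    fda_area <- NA_real_
    if (!is.null(crop$fda)) {
      fseg <- segment_spheroid(crop$fda, fparams, ps)
      fda_area <- if ("no_detection" %in% fseg$flags) 0 else fseg$area_um2
    }
    tibble::tibble(
      well_row = m$well_row, well_col = m$well_col, day = m$day,
      area_um2 = seg$area_um2, perimeter_um = seg$perimeter_um,
      eq_diam_um = if (is.na(seg$area_um2)) NA_real_ else
        2 * sqrt(seg$area_um2 / pi),
      shape_factor = if (is.na(seg$area_um2)) NA_real_ else
        seg$perimeter_um^2 / (4 * pi * seg$area_um2),
      fda_area_um2 = fda_area,
      flags = paste(seg$flags, collapse = ";"))
  })
  tab <- do.call(rbind, rows)
  # baseline: last imaged brightfield area before the drug day, per well
  base_days <- unique(tab$day[tab$day < drug_day])
  if (!length(base_days)) {
    stop("no imaged day precedes drug_day: viability baseline undefined")
  }
  bday <- max(base_days)
  base <- tab[tab$day == bday, c("well_row", "well_col", "area_um2")]
  names(base)[3] <- "baseline_area_um2"
  tab <- merge(tab, base, by = c("well_row", "well_col"), all.x = TRUE,
               sort = FALSE)
  tab$viable_fraction <- ifelse(
    !is.na(tab$fda_area_um2) & !is.na(tab$baseline_area_um2) &
      tab$baseline_area_um2 > 0,
    tab$fda_area_um2 / tab$baseline_area_um2, NA_real_)
  tab <- tab[order(tab$well_row, tab$well_col, tab$day), ]
  tibble::as_tibble(tab)
}

#' Exclude edge columns from an analysis table
#'
#' Wells in the first and last `k` columns of the array see residual
#' within-row concentration variation (fringe effects) and are excluded
#' from analysis.
#'
#' @param table A measurement table with a `well_col` column.
#' @param layout The [generate_layout()] the table refers to.
#' @param k Number of columns dropped at each end (default 3).
#' @return The filtered table.
#' @export
exclude_edge_columns <- function(table, layout, k = 3) {
  if (k < 0) stop("k must be >= 0")
  if (2 * k >= layout$n_cols) {
    stop("edge exclusion would remove every column (2k >= n_cols)")
  }
  table[table$well_col > k & table$well_col <= layout$n_cols - k, ]
}

#' Read an image set written by [write_image_set()]
#'
#' @param dir Directory containing `manifest.csv` and per-channel TIFFs.
#' @param drug_day Drug day (read from `ground_truth.json` when present).
#' @param pixel_scale Pixel size (um/px); read from the JSON sidecar when
#'   present.
#' @return A list compatible with [measure_timecourse()].
#' @export
read_image_set <- function(dir, drug_day = NULL, pixel_scale = NULL) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  gt_file <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_file)) {
    meta <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    if (is.null(drug_day)) drug_day <- meta$drug_day
    if (is.null(pixel_scale)) pixel_scale <- meta$pixel_scale
  }
  if (is.null(pixel_scale)) pixel_scale <- 1
  images <- list()
  keys <- unique(sprintf("r%dc%d_d%d", man$well_row, man$well_col, man$day))
  manifest <- NULL
  for (key in keys) {
    sel <- man[sprintf("r%dc%d_d%d", man$well_row, man$well_col, man$day) == key, ]
    crop <- list()
    for (j in seq_len(nrow(sel))) {
      crop[[sel$channel[j]]] <- tiff::readTIFF(file.path(dir, sel$file[j]))
    }
    images[[key]] <- crop
    manifest <- rbind(manifest, tibble::tibble(
      well_row = sel$well_row[1], well_col = sel$well_col[1],
      day = sel$day[1], key = key, has_endpoint = "fda" %in% sel$channel,
      under_resolved = FALSE))
  }
  list(images = images, manifest = manifest, pixel_scale = pixel_scale,
       drug_day = drug_day)
}
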