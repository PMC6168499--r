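# ---- ground-truthed synthetic spheroid experiments ----
#
# Emulates the experimental readouts of the gradient device: an 8 x 30 array
# of 150 um wells seeded with spheroids whose diameters decrease from both
# channel ends, and whose drug response (disaggregation or shrinkage) follows
# a known Hill curve, rendered as brightfield plus end-point FDA/PI channels.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Device layout
#'
#' Geometry of the micro-well array and the central channel that hosts it.
#' Row 1 is the drug-source side; columns run along the channel axis. The
#' default is the 240-well array (8 rows x 30 columns of 150 um square
#' wells); the 5-row / 250 um variant used for larger spheroids is obtained
#' with `generate_layout(n_rows = 5, well_size = 250, well_pitch = 255)`.
#'
#' @param n_rows,n_cols Array dimensions.
#' @param well_size Square well side (um).
#' @param well_depth Well depth (um).
#' @param well_pitch Centre-to-centre well spacing (um); defaults to
#'   `well_size + 5`.
#' @param margin_y Gap between the outer well edges and the channel side
#'   walls where the connecting-channel arrays open (um).
#' @param margin_x Gap between the array and the channel ends (um).
#' @param channel_depth Depth of the flow layer above the wells (um).
#' @return An object of class `device_layout`.
#' @export
#' @examples
#' generate_layout()            # 240-well default
#' generate_layout(n_rows = 5, well_size = 250, well_pitch = 255)
generate_layout <- function(n_rows = 8, n_cols = 30, well_size = 150,
                            well_depth = 180, well_pitch = well_size + 5,
                            margin_y = 180, margin_x = 180,
                            channel_depth = 20) {
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1")
  if (well_size <= 0 || well_pitch < well_size) {
    stop("need well_size > 0 and well_pitch >= well_size")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         well_size = well_size, well_depth = well_depth,
         well_pitch = well_pitch, margin_y = margin_y, margin_x = margin_x,
         channel_depth = channel_depth,
         channel_width = n_rows * well_pitch + 2 * margin_y,
         channel_length = n_cols * well_pitch + 2 * margin_x),
    class = "device_layout")
}

#' @export
print.device_layout <- function(x, ...) {
  cat(sprintf(
    "device layout: %d x %d wells of %g um (pitch %g um); channel %g x %g um\n",
    x$n_rows, x$n_cols, x$well_size, x$well_pitch,
    x$channel_length, x$channel_width))
  invisible(x)
}

#' Well centre coordinates
#'
#' @param layout A [generate_layout()].
#' @return A tibble with `row`, `col`, `x`, `y` (um; y measured from the
#'   drug-side channel wall).
#' @export
well_centers <- function(layout) {
  g <- expand.grid(row = seq_len(layout$n_rows), col = seq_len(layout$n_cols))
  tibble::tibble(
    row = g$row, col = g$col,
    x = layout$margin_x + (g$col - 0.5) * layout$well_pitch,
    y = layout$margin_y + (g$row - 0.5) * layout$well_pitch)
}

#' Sample seeding-induced spheroid diameters
#'
#' Hydrostatic seeding loads fewer cells into wells further from the two
#' channel inlets, so expected spheroid diameter decreases from both column
#' ends towards the array middle. Diameters are drawn per well as
#' `Normal(mu(col), sd)` with `mu(col) = mid_mean + (end_mean - mid_mean) *
#' xi^2`, `xi` the column position scaled to \[-1, 1\], truncated to
#' `[min_diameter, 0.9 * well_size]`. Defaults put >90% of diameters in the
#' 50-100 um band.
#'
#' @param layout A [generate_layout()].
#' @param seed Integer seed (draws are reproducible and do not disturb the
#'   global RNG stream).
#' @param size_params List overriding any of `end_mean`, `mid_mean`, `sd`,
#'   `min_diameter` (um).
#' @return A tibble `row`, `col`, `diameter_um`.
#' @export
sample_seeding_sizes <- function(layout, seed,
                                 size_params = list()) {
  p <- utils::modifyList(
    list(end_mean = 84, mid_mean = 64, sd = 7, min_diameter = 30),
    size_params)
  max_d <- 0.9 * layout$well_size
  if (p$end_mean >= max_d || p$mid_mean >= max_d) {
    stop("size parameters imply spheroids larger than the wells")
  }
  wells <- well_centers(layout)
  xi <- if (layout$n_cols > 1) {
    (wells$col - (layout$n_cols + 1) / 2) / ((layout$n_cols - 1) / 2)
  } else rep(0, nrow(wells))
  mu <- p$mid_mean + (p$end_mean - p$mid_mean) * xi^2
  d <- with_seed(seed, stats::rnorm(nrow(wells), mu, p$sd))
  d <- pmin(pmax(d, p$min_diameter), max_d)
  tibble::tibble(row = wells$row, col = wells$col, diameter_um = d)
}

# Random boundary-perturbation modes for one spheroid: cosine/sine
# coefficients for angular wavenumbers 2..(n_modes+1), 1/k amplitude decay,
# normalised so max |f(theta)| = 1.
radial_modes <- function(n_modes, seed) {
  k <- seq(2, length.out = n_modes)
  co <- with_seed(seed, {
    cbind(stats::rnorm(n_modes) / k, stats::rnorm(n_modes) / k)
  })
  th <- seq(0, 2 * pi, length.out = 2048)
  f <- as.vector(cos(outer(th, k)) %*% co[, 1] + sin(outer(th, k)) %*% co[, 2])
  co / max(abs(f))
}

radial_eval <- function(theta, radius, amplitude, modes) {
  k <- seq(2, length.out = nrow(modes))
  f <- as.vector(cos(outer(theta, k)) %*% modes[, 1] +
                 sin(outer(theta, k)) %*% modes[, 2])
  radius * (1 + amplitude * f)
}

#' Ground-truth spheroid contour
#'
#' Star-convex perturbed-circle contour
#' `r(theta) = radius * (1 + amplitude * f(theta))` with `f` a seeded sum of
#' low-order Fourier modes normalised to unit peak amplitude. The returned
#' polygon is the exact geometric ground truth for shape-factor oracles
#' (area and perimeter computable via [polygon_area()] /
#' [polygon_perimeter()]).
#'
#' @param radius Mean radius (um).
#' @param roughness_amplitude Peak fractional radial perturbation (>= 0,
#'   < 1).
#' @param n_modes Number of Fourier modes.
#' @param seed Integer seed selecting the mode coefficients.
#' @param n_vertices Number of polygon vertices.
#' @return An `n_vertices` x 2 matrix of (x, y) coordinates (um), closed
#'   implicitly (last vertex connects to first).
#' @export
#' @examples
#' xy <- spheroid_contour(50, 0.1, seed = 1)
#' polygon_area(xy) / (pi * 50^2)
spheroid_contour <- function(radius, roughness_amplitude, n_modes = 6,
                             seed = 1, n_vertices = 720) {
  if (radius <= 0) stop("radius must be > 0")
  if (roughness_amplitude < 0) stop("roughness_amplitude must be >= 0")
  if (roughness_amplitude >= 1) {
    stop("roughness amplitude too large: contour radius would reach zero")
  }
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- if (roughness_amplitude > 0) {
    radial_eval(theta, radius, roughness_amplitude, radial_modes(n_modes, seed))
  } else rep(radius, n_vertices)
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Polygon area (shoelace formula)
#' @param xy An n x 2 matrix of vertices (closed implicitly).
#' @return Area in squared input units.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Polygon perimeter
#' @inheritParams polygon_area
#' @return Perimeter in input units.
#' @export
polygon_perimeter <- function(xy) {
  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

#' Hill effect model
#'
#' Fractional effect `e = c^h / (c^h + EC50^h)` at concentration `c`.
#'
#' @param conc Concentration (uM).
#' @param ec50 Half-maximal concentration (uM).
#' @param hill Hill slope.
#' @return Effect in \[0, 1\].
#' @export
hill_effect <- function(conc, ec50, hill) {
  ifelse(conc <= 0, 0, conc^hill / (conc^hill + ec50^hill))
}

#' Assemble a ground-truth synthetic experiment
#'
#' Fixes everything the renderer needs: per-well seeded diameters and row
#' doses, the true Hill dose-response, the effect mode, and the temporal
#' ramp. Effects ramp linearly over `ramp_days` after the drug day
#' (disaggregation builds for ~3 days after treatment). In
#' `"disaggregation"` mode the effect raises the boundary-roughness
#' amplitude and kills a matching fraction of the spheroid; in
#' `"shrinkage"` mode the spheroid shrinks with an intact smooth contour.
#'
#' @param layout A [generate_layout()].
#' @param seed Integer seed for all stochastic choices.
#' @param ec50 True EC50 (uM).
#' @param hill True Hill slope.
#' @param mode `"disaggregation"` (cisplatin-like) or `"shrinkage"`
#'   (docetaxel-like).
#' @param row_doses Per-row concentrations (uM), row 1 first; defaults to a
#'   linear 8-point gradient from 206.5 down to 42.2 uM (interpolated for
#'   other row counts).
#' @param drug_day Day of drug application (baseline imaging is the last
#'   day before this).
#' @param ramp_days Days over which the drug effect develops.
#' @param size_params Passed to [sample_seeding_sizes()].
#' @param ec50_cv Log-normal coefficient of variation of the per-well EC50
#'   (biological spheroid-to-spheroid heterogeneity).
#' @param size_sensitivity Log-EC50 shift per 50 um of baseline diameter
#'   below 70 um: positive values make larger spheroids more drug-sensitive
#'   (the size dependence observed for cisplatin).
#' @param base_roughness Healthy-contour roughness amplitude.
#' @param max_roughness Added roughness at full disaggregation effect.
#' @param max_shrinkage Fractional radius loss at full shrinkage effect.
#' @param growth_per_day Fractional daily radius growth of healthy tissue.
#' @return An object of class `ground_truth` with a per-well tibble
#'   (`row`, `col`, `diameter_um`, `dose_uM`, `contour_seed`) and the global
#'   parameters.
#' @export
ground_truth <- function(layout, seed = 1, ec50 = 100, hill = 3,
                         mode = c("disaggregation", "shrinkage"),
                         row_doses = NULL, drug_day = 5, ramp_days = 3,
                         size_params = list(), ec50_cv = 0.2,
                         size_sensitivity = 0.4, base_roughness = 0.03,
                         max_roughness = 0.32, max_shrinkage = 0.45,
                         growth_per_day = 0.01) {
  mode <- match.arg(mode)
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (is.null(row_doses)) {
    row_doses <- seq(206.5, 42.2, length.out = layout$n_rows)
  }
  if (length(row_doses) != layout$n_rows) {
    stop("row_doses must have one value per layout row")
  }
  sizes <- sample_seeding_sizes(layout, seed = seed, size_params = size_params)
  wells <- tibble::tibble(
    sizes,
    dose_uM = row_doses[sizes$row],
    ec50_uM = ec50 * exp(
      with_seed(seed + 2L,
                stats::rnorm(nrow(sizes), 0, sqrt(log(1 + ec50_cv^2)))) +
        size_sensitivity * (70 - sizes$diameter_um) / 50),
    contour_seed = with_seed(seed + 1L,
                             sample.int(2^30, nrow(sizes))))
  structure(
    list(wells = wells, ec50 = ec50, hill = hill, mode = mode,
         row_doses = row_doses, drug_day = drug_day, ramp_days = ramp_days,
         base_roughness = base_roughness, max_roughness = max_roughness,
         max_shrinkage = max_shrinkage, growth_per_day = growth_per_day,
         seed = seed),
    class = "ground_truth")
}

# Per-well geometric state on a given day.
well_state <- function(gt, well, day) {
  ramp <- min(1, max(0, (day - gt$drug_day) / gt$ramp_days))
  e <- hill_effect(well$dose_uM, well$ec50_uM, gt$hill) * ramp
  r0 <- well$diameter_um / 2
  grow <- (1 + gt$growth_per_day)^day
  if (gt$mode == "disaggregation") {
    list(radius = r0 * grow,
         amplitude = gt$base_roughness + gt$max_roughness * e,
         viable = 1 - 0.95 * e)
  } else {
    list(radius = r0 * grow * (1 - gt$max_shrinkage * e),
         amplitude = gt$base_roughness,
         viable = 1 - 0.2 * e)
  }
}

#' True per-well state table
#'
#' Ground-truth radius, roughness amplitude and viable fraction per well and
#' day, plus the exact polygon shape factor of the true contour -- the
#' oracle against which image-derived measurements are judged.
#'
#' @param gt A [ground_truth()].
#' @param days Days to tabulate.
#' @return A tibble with one row per well per day.
#' @export
ground_truth_table <- function(gt, days) {
  out <- lapply(days, function(d) {
    st <- lapply(seq_len(nrow(gt$wells)), function(i) {
      w <- gt$wells[i, ]
      s <- well_state(gt, w, d)
      xy <- spheroid_contour(s$radius, s$amplitude, seed = w$contour_seed)
      tibble::tibble(
        row = w$row, col = w$col, day = d, dose_uM = w$dose_uM,
        radius_um = s$radius, amplitude = s$amplitude,
        viable_frac = s$viable,
        area_um2 = polygon_area(xy),
        shape_factor = polygon_perimeter(xy)^2 / (4 * pi * polygon_area(xy)))
    })
    do.call(rbind, st)
  })
  do.call(rbind, out)
}

#' Render a single synthetic well crop
#'
#' Low-level renderer behind [render_experiment()], exposed for oracle-style
#' validation: a spheroid of known radius, boundary roughness and viable
#' fraction is drawn with additive Gaussian noise, so image-derived
#' measurements can be compared against exact geometric ground truth.
#'
#' @param radius Spheroid mean radius (um).
#' @param amplitude Boundary-roughness amplitude (see [spheroid_contour()]).
#' @param viable True viable fraction (sets the FDA-positive core).
#' @param contour_seed Seed selecting the boundary perturbation modes.
#' @param crop_px Crop side length (px).
#' @param pixel_scale Pixel size (um/px).
#' @param noise_sd Additive Gaussian noise sd.
#' @param endpoint If `TRUE`, also render FDA and PI channels.
#' @param rng_seed Seed for the rendering noise.
#' @param n_modes Number of boundary perturbation modes.
#' @return List with `brightfield` and, for end-points, `fda`/`pi`
#'   matrices.
#' @export
render_crop <- function(radius, amplitude, viable, contour_seed, crop_px,
                        pixel_scale, noise_sd, endpoint, rng_seed,
                        n_modes = 6) {
  cx <- (crop_px + 1) / 2
  px <- (seq_len(crop_px) - cx) * pixel_scale
  X <- matrix(px, crop_px, crop_px, byrow = TRUE)
  Y <- matrix(px, crop_px, crop_px)
  rr <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  rb <- if (amplitude > 0) {
    modes <- radial_modes(n_modes, contour_seed)
    matrix(radial_eval(as.vector(th), radius, amplitude, modes),
           crop_px, crop_px)
  } else matrix(radius, crop_px, crop_px)
  mask <- rr <= rb
  with_seed(rng_seed, {
    bf <- 0.85 - 0.45 * mask +
      matrix(stats::rnorm(crop_px^2, 0, noise_sd), crop_px)
    out <- list(brightfield = bf)
    if (endpoint) {
      core <- rr <= rb * sqrt(max(viable, 0))
      out$fda <- 0.05 + 0.75 * core +
        matrix(stats::rnorm(crop_px^2, 0, noise_sd), crop_px)
      out$pi <- 0.05 + 0.75 * (mask & !core) +
        matrix(stats::rnorm(crop_px^2, 0, noise_sd), crop_px)
    }
    out
  })
}

#' Render a synthetic image set
#'
#' Renders per-well image crops for the requested days: brightfield on every
#' day, plus FDA (viable area) and PI (dead rim) channels on the final day
#' only, matching the end-point-only use of viability dyes. Images are
#' numeric matrices in \[0, 1\] with additive Gaussian noise; spheroids are
#' dark objects on a bright background in brightfield and bright on dark in
#' the fluorescence channels.
#'
#' @param layout A [generate_layout()].
#' @param gt A [ground_truth()].
#' @param days Imaging days (must include at least one day before
#'   `gt$drug_day` to serve as the viability baseline).
#' @param pixel_scale Pixel size (um/px).
#' @param seed Integer seed for rendering noise.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param wells Optional subset of wells (tibble with `row`, `col`) to
#'   render; defaults to all.
#' @return An object of class `synthetic_image_set`: `images` (named list
#'   `r<row>c<col>_d<day>` of per-channel matrices), a `manifest` tibble,
#'   `pixel_scale`, and rendering metadata. Wells whose spheroid resolves to
#'   fewer than 10 px diameter are flagged in the manifest.
#' @export
render_experiment <- function(layout, gt, days, pixel_scale = 1, seed = 1,
                              noise_sd = 0.03, wells = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  days <- sort(unique(days))
  final_day <- max(days)
  crop_px <- round(layout$well_size / pixel_scale)
  wtab <- gt$wells
  if (!is.null(wells)) {
    keep <- paste(wtab$row, wtab$col) %in% paste(wells$row, wells$col)
    wtab <- wtab[keep, ]
  }
  images <- list()
  manifest <- vector("list", nrow(wtab) * length(days))
  mi <- 0L
  rng <- with_seed(seed, sample.int(2^30, nrow(wtab) * length(days)))
  for (i in seq_len(nrow(wtab))) {
    w <- wtab[i, ]
    for (d in days) {
      mi <- mi + 1L
      s <- well_state(gt, w, d)
      key <- sprintf("r%dc%d_d%d", w$row, w$col, d)
      images[[key]] <- render_crop(
        s$radius, s$amplitude, s$viable, w$contour_seed, crop_px,
        pixel_scale, noise_sd, endpoint = (d == final_day),
        rng_seed = rng[mi])
      manifest[[mi]] <- tibble::tibble(
        well_row = w$row, well_col = w$col, day = d, key = key,
        has_endpoint = d == final_day,
        under_resolved = 2 * s$radius / pixel_scale < 10)
    }
  }
  structure(
    list(images = images, manifest = do.call(rbind, manifest),
         pixel_scale = pixel_scale, layout = layout, ground_truth = gt,
         days = days, drug_day = gt$drug_day, noise_sd = noise_sd,
         seed = seed),
    class = "synthetic_image_set")
}

#' @export
print.synthetic_image_set <- function(x, ...) {
  cat(sprintf(
    "synthetic image set: %d wells x %d days (%g um/px), drug day %d\n",
    length(unique(paste(x$manifest$well_row, x$manifest$well_col))),
    length(x$days), x$pixel_scale, x$drug_day))
  invisible(x)
}

#' Write a synthetic image set to disk
#'
#' Per-channel TIFFs plus a CSV manifest (`well_row`, `well_col`, `day`,
#' `channel`, `file`) and a JSON sidecar with the ground-truth parameters.
#'
#' @param imgset A [render_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest file path.
#' @export
write_image_set <- function(imgset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(imgset$manifest))) {
    m <- imgset$manifest[i, ]
    crop <- imgset$images[[m$key]]
    for (ch in names(crop)) {
      file <- file.path(dir, paste0(m$key, "_", ch, ".tif"))
      tiff::writeTIFF(pmin(pmax(crop[[ch]], 0), 1), file)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        well_row = m$well_row, well_col = m$well_col, day = m$day,
        channel = ch, file = basename(file))
    }
  }
  manifest_file <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_file, row.names = FALSE)
  gt <- imgset$ground_truth
  jsonlite::write_json(
    list(seed = gt$seed, ec50 = gt$ec50, hill = gt$hill, mode = gt$mode,
         drug_day = gt$drug_day, row_doses = gt$row_doses,
         pixel_scale = imgset$pixel_scale),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest_file)
}
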