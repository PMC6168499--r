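# ---- compound concentration-gradient simulation over the well array ----
#
# Depth-averaged digital twin of the central channel: the network model
# supplies the (decaying) volumetric flow; drug and medium enter through the
# connecting-channel arrays along the two long sides of the channel, meet
# over the well array and leave through the central reservoirs at both ends.
# The resulting 2D advection-diffusion problem is solved on a cell-centred
# finite-volume grid.

#' Compound properties
#'
#' @param name Compound name.
#' @param molecular_weight Molecular weight (g/mol).
#' @param diffusion_coefficient Optional explicit diffusion coefficient
#'   (m^2/s); overrides the MW-based estimate.
#' @param source_concentration Concentration loaded into the drug-side
#'   reservoirs (umol/L).
#' @return An object of class `compound`.
#' @export
#' @examples
#' compound("cisplatin", 300.05, source_concentration = 250)
compound <- function(name, molecular_weight, diffusion_coefficient = NULL,
                     source_concentration = 100) {
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  if (!is.null(diffusion_coefficient) && diffusion_coefficient <= 0) {
    stop("diffusion_coefficient, if given, must be > 0")
  }
  if (source_concentration < 0) stop("source_concentration must be >= 0")
  D <- if (is.null(diffusion_coefficient)) {
    estimate_diffusion_coefficient(molecular_weight)
  } else diffusion_coefficient
  structure(
    list(name = name, molecular_weight = molecular_weight,
         diffusion_coefficient = D,
         source_concentration = source_concentration),
    class = "compound")
}

#' Estimate a diffusion coefficient from molecular weight
#'
#' Stokes-Einstein-style power law `D = a * MW^(-1/3)` with
#' `a = 5.2e-10` chosen so the screened compound panel (cisplatin 300,
#' enzalutamide 464, calcein 623, docetaxel 808 g/mol) falls inside
#' 0.2-0.8 x 10^-10 m^2/s, the range used for the device's transport
#' simulations. An explicit `override` is returned unchanged.
#'
#' @param molecular_weight Molecular weight (g/mol), within \[100, 2000\].
#' @param override Optional known diffusion coefficient (m^2/s).
#' @return Diffusion coefficient (m^2/s).
#' @export
#' @examples
#' estimate_diffusion_coefficient(623)  # calcein
estimate_diffusion_coefficient <- function(molecular_weight, override = NULL) {
  if (!is.null(override)) {
    if (override <= 0) stop("override diffusion coefficient must be > 0")
    return(override)
  }
  if (molecular_weight < 100 || molecular_weight > 2000) {
    stop("molecular weight outside supported range [100, 2000] g/mol; ",
         "supply an explicit diffusion coefficient instead")
  }
  5.2e-10 * molecular_weight^(-1 / 3)
}

#' Explicit 2D advection-diffusion solver (cell-centred finite volume)
#'
#' Conservative flux-form solver used by [solve_gradient()] and directly
#' testable against closed-form transport solutions. Advection uses the
#' hybrid scheme: central face interpolation where the cell Peclet number
#' `|u| dx / D <= 2`, first-order upwinding beyond. Time stepping is explicit
#' with a CFL safety factor of 0.4 applied to the combined
#' diffusive/advective limit; the effective step is reported in the result.
#'
#' @param c_init Initial concentration matrix (`ny` x `nx`), cell-centred.
#' @param dx,dy Cell sizes (m).
#' @param D Diffusion coefficient (m^2/s).
#' @param u_face Matrix (`ny` x `nx+1`) of x-velocities at vertical faces
#'   (m/s), for unit velocity scale.
#' @param v_face Matrix (`ny+1` x `nx`) of y-velocities at horizontal faces.
#' @param scale_fun Function of time returning the velocity scale factor
#'   multiplying `u_face`/`v_face` (default constant 1).
#' @param duration Simulated time (s).
#' @param save_times Times at which to store frames (always includes 0 and
#'   `duration`).
#' @param bc Boundary conditions: list with entries `x0`, `x1`, `y0`, `y1`,
#'   each `list(type = "dirichlet", value = )`, `list(type = "closed")`, or
#'   `list(type = "outflow")`.
#' @param steady_tol If non-`NULL`, stop early once the maximum concentration
#'   change per unit time falls below `steady_tol` (concentration units per
#'   second).
#' @return List with `times`, `frames` (list of matrices), `dt` (effective
#'   step), `x`, `y` (cell-centre coordinates, m).
#' @export
advection_diffusion_2d <- function(c_init, dx, dy, D, u_face = NULL,
                                   v_face = NULL, scale_fun = NULL,
                                   duration, save_times = NULL,
                                   bc = list(x0 = list(type = "closed"),
                                             x1 = list(type = "closed"),
                                             y0 = list(type = "closed"),
                                             y1 = list(type = "closed")),
                                   steady_tol = NULL) {
  ny <- nrow(c_init); nx <- ncol(c_init)
  if (is.null(u_face)) u_face <- matrix(0, ny, nx + 1)
  if (is.null(v_face)) v_face <- matrix(0, ny + 1, nx)
  if (is.null(scale_fun)) scale_fun <- function(t) 1
  stopifnot(nrow(u_face) == ny, ncol(u_face) == nx + 1,
            nrow(v_face) == ny + 1, ncol(v_face) == nx)

  smax <- max(abs(scale_fun(seq(0, duration, length.out = 257))), 1e-300)
  umax <- max(abs(u_face)) * smax
  vmax <- max(abs(v_face)) * smax
  rate <- 2 * D * (1 / dx^2 + 1 / dy^2) + umax / dx + vmax / dy
  dt <- 0.4 / rate
  n_steps <- max(1L, ceiling(duration / dt))
  dt <- duration / n_steps

  if (is.null(save_times)) save_times <- c(0, duration)
  save_times <- sort(unique(pmin(pmax(save_times, 0), duration)))
  save_steps <- unique(round(save_times / dt))
  save_steps[save_steps > n_steps] <- n_steps

  # Precompute hybrid weights are velocity-scale dependent only through the
  # sign/magnitude of the faces; the scale is a scalar so the cell Peclet
  # pattern only changes when |scale| crosses thresholds -- recompute cheaply
  # per step from the scaled faces.
  cmat <- c_init
  frames <- vector("list", length(save_steps) + 1L)
  times <- numeric(0)
  out_t <- numeric(0)
  ki <- 1L
  if (0 %in% save_steps) {
    frames[[ki]] <- cmat; out_t <- c(out_t, 0); ki <- ki + 1L
  }

  ix_l <- seq_len(nx); ix_r <- ix_l + 1L   # face indices per cell
  iy_b <- seq_len(ny); iy_t <- iy_b + 1L

  for (s in seq_len(n_steps)) {
    t_mid <- (s - 0.5) * dt
    sc <- scale_fun(t_mid)
    uf <- u_face * sc
    vf <- v_face * sc

    # --- x-direction face fluxes: F[ny, nx+1]
    cl <- cmat[, c(1L, ix_l), drop = FALSE]   # left cell of each face (clamped)
    cr <- cmat[, c(ix_l, nx), drop = FALSE]   # right cell of each face
    grad <- (cr - cl) / dx
    grad[, c(1L, nx + 1L)] <- 0
    pe <- abs(uf) * dx / D
    cf <- ifelse(pe <= 2, 0.5 * (cl + cr), ifelse(uf >= 0, cl, cr))
    Fx <- uf * cf - D * grad
    Fx[, 1L] <- boundary_flux(bc$x0, uf[, 1L], cmat[, 1L], dx, D, lower = TRUE)
    Fx[, nx + 1L] <- boundary_flux(bc$x1, uf[, nx + 1L], cmat[, nx], dx, D,
                                   lower = FALSE)

    # --- y-direction face fluxes: F[ny+1, nx]
    cb <- cmat[c(1L, iy_b), , drop = FALSE]
    ct <- cmat[c(iy_b, ny), , drop = FALSE]
    grad <- (ct - cb) / dy
    grad[c(1L, ny + 1L), ] <- 0
    pe <- abs(vf) * dy / D
    cfy <- ifelse(pe <= 2, 0.5 * (cb + ct), ifelse(vf >= 0, cb, ct))
    Fy <- vf * cfy - D * grad
    Fy[1L, ] <- boundary_flux(bc$y0, vf[1L, ], cmat[1L, ], dy, D, lower = TRUE)
    Fy[ny + 1L, ] <- boundary_flux(bc$y1, vf[ny + 1L, ], cmat[ny, ], dy, D,
                                   lower = FALSE)

    dc <- -dt * ((Fx[, ix_r, drop = FALSE] - Fx[, ix_l, drop = FALSE]) / dx +
                 (Fy[iy_t, , drop = FALSE] - Fy[iy_b, , drop = FALSE]) / dy)
    cmat <- cmat + dc

    if (s %in% save_steps) {
      frames[[ki]] <- cmat; out_t <- c(out_t, s * dt); ki <- ki + 1L
    }
    if (!is.null(steady_tol) && max(abs(dc)) / dt < steady_tol) {
      frames[[ki]] <- cmat; out_t <- c(out_t, s * dt); ki <- ki + 1L
      break
    }
  }
  frames <- frames[seq_len(ki - 1L)]
  list(times = out_t, frames = frames, dt = dt,
       x = (seq_len(nx) - 0.5) * dx, y = (seq_len(ny) - 0.5) * dy)
}

# Flux through a boundary face. `lower = TRUE` for the x0/y0 face where the
# outward normal points in -x/-y; fluxes are returned in +axis orientation so
# the interior update can difference them uniformly.
boundary_flux <- function(spec, vel, c_edge, h, D, lower) {
  type <- spec$type
  if (type == "closed") return(rep(0, length(c_edge)))
  if (type == "outflow") return(vel * c_edge)
  if (type == "dirichlet") {
    b <- spec$value
    # face value pinned at b; diffusive flux from ghost-cell linear profile
    return(vel * b - D * 2 * (c_edge - b) / h * (if (lower) 1 else -1))
  }
  stop("unknown boundary type: ", type)
}

#' Simulate the compound concentration field over the well array
#'
#' Runs the depth-averaged advection-diffusion model of the central channel.
#' The drug-side long wall is held at the source concentration and the
#' medium-side wall at `c_medium` (the connecting-channel arrays continuously
#' replenish both rails); the short ends are outflow boundaries into the
#' central reservoirs. The transverse velocity enters uniformly along both
#' sides and stagnates at the channel midline,
#' `v(y) = v_s(t) (1 - 2y/W)`, while the axial velocity grows linearly
#' towards the two outlets, `u(x) = (2 v_s/W)(x - L/2)`; the pair is exactly
#' divergence-free and `v_s(t) = Q(t) / (2 L h_c)` is scaled to the central
#' flow of the network simulation.
#'
#' @param layout A [generate_layout()] device layout.
#' @param flow A `pressure_trace` from [simulate_network()], or a constant
#'   flow rate (m^3/s) given as a single number.
#' @param compound A [compound()].
#' @param duration Simulated time (s).
#' @param grid_spacing Transverse (gradient-axis) cell size (um).
#' @param grid_spacing_x Axial cell size (um).
#' @param save_every Interval between stored frames (s).
#' @param c_medium Concentration at the medium-side rail (umol/L).
#' @return An object of class `concentration_field`: `times`, `frames`,
#'   cell-centre coordinates `x`, `y` (um), the layout, compound, and the
#'   effective time step.
#' @export
solve_gradient <- function(layout, flow, compound, duration,
                           grid_spacing = 20, grid_spacing_x = 50,
                           save_every = 900, c_medium = 0) {
  stopifnot(inherits(layout, "device_layout"), inherits(compound, "compound"))
  W <- layout$channel_width * 1e-6
  L <- layout$channel_length * 1e-6
  h_c <- layout$channel_depth * 1e-6
  dy <- grid_spacing * 1e-6
  dx <- grid_spacing_x * 1e-6
  if (grid_spacing_x > layout$well_size / 3) {
    stop("grid_spacing_x must resolve the well pitch (>= 3 nodes per well)")
  }
  ny <- max(4L, round(W / dy)); dy <- W / ny
  nx <- max(4L, round(L / dx)); dx <- L / nx

  if (inherits(flow, "pressure_trace")) {
    if (max(flow$times) < duration) {
      stop("flow trace does not cover the requested duration")
    }
    Qfun <- stats::approxfun(flow$times, flow$Q_central, rule = 2)
  } else if (is.numeric(flow) && length(flow) == 1) {
    Qfun <- function(t) rep(flow, length(t))
  } else stop("flow must be a pressure_trace or a single flow rate")
  v_s <- function(t) Qfun(t) / (2 * L * h_c)

  x_face <- (0:nx) * dx
  y_face <- (0:ny) * dy
  u_face <- matrix(rep(2 / W * (x_face - L / 2), each = ny), ny, nx + 1)
  v_face <- matrix(rep(1 - 2 * y_face / W, times = nx), ny + 1, nx)

  c0 <- compound$source_concentration
  sol <- advection_diffusion_2d(
    c_init = matrix(0, ny, nx), dx = dx, dy = dy,
    D = compound$diffusion_coefficient,
    u_face = u_face, v_face = v_face, scale_fun = v_s,
    duration = duration,
    save_times = seq(0, duration, by = save_every),
    bc = list(x0 = list(type = "outflow"), x1 = list(type = "outflow"),
              y0 = list(type = "dirichlet", value = c0),
              y1 = list(type = "dirichlet", value = c_medium)))
  structure(
    list(times = sol$times, frames = sol$frames,
         x = sol$x * 1e6, y = sol$y * 1e6, dt = sol$dt,
         layout = layout, compound = compound),
    class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "concentration field: %s, %d frames over %.2f h, grid %d x %d (dt = %.2f s)\n",
    x$compound$name, length(x$times), max(x$times) / 3600,
    nrow(x$frames[[1]]), ncol(x$frames[[1]]), x$dt))
  invisible(x)
}

#' Per-row concentration summary
#'
#' Averages the simulated field over each well footprint, excludes the edge
#' columns, and summarises per array row (row 1 = drug side): mean
#' concentration over retained wells and within-row relative spread
#' `(max - min) / mean` of the per-well means.
#'
#' @param field A `concentration_field` from [solve_gradient()].
#' @param t Time (s) at which to summarise; the nearest stored frame is used.
#' @param exclude_edge_columns Number of columns dropped at each end of the
#'   array (default 3).
#' @return A tibble with columns `row`, `mean_uM`, `spread_frac`, `n_wells`,
#'   `time_s`.
#' @export
row_concentrations <- function(field, t, exclude_edge_columns = 3) {
  stopifnot(inherits(field, "concentration_field"))
  if (t < min(field$times) - 1e-9 || t > max(field$times) + 1e-9) {
    stop("t outside the stored time range of the field")
  }
  layout <- field$layout
  k <- exclude_edge_columns
  cols <- seq_len(layout$n_cols)
  keep_cols <- cols[cols > k & cols <= layout$n_cols - k]
  if (length(keep_cols) < 1) stop("edge-column exclusion leaves no wells per row")
  frame <- field$frames[[which.min(abs(field$times - t))]]
  centers <- well_centers(layout)
  half <- layout$well_size / 2
  # cell weights = fractional overlap of each cell with the well footprint,
  # so well means are insensitive to how the grid happens to align
  overlap <- function(cell_centers, lo, hi) {
    d <- diff(cell_centers[1:2])
    pmax(0, pmin(cell_centers + d / 2, hi) - pmax(cell_centers - d / 2, lo)) / d
  }
  out <- lapply(seq_len(layout$n_rows), function(r) {
    means <- vapply(keep_cols, function(cc) {
      wc <- centers[centers$row == r & centers$col == cc, ]
      wx <- overlap(field$x, wc$x - half, wc$x + half)
      wy <- overlap(field$y, wc$y - half, wc$y + half)
      as.numeric(t(wy) %*% frame %*% wx) / (sum(wy) * sum(wx))
    }, numeric(1))
    m <- mean(means)
    tibble::tibble(row = r, mean_uM = m,
                   spread_frac = if (m > 0) (max(means) - min(means)) / m else 0,
                   n_wells = length(keep_cols),
                   time_s = field$times[which.min(abs(field$times - t))])
  })
  do.call(rbind, out)
}

#' Row-profile time series
#'
#' [row_concentrations()] evaluated at every stored frame.
#'
#' @inheritParams row_concentrations
#' @return A tibble with one row per array row per stored time.
#' @export
row_concentration_series <- function(field, exclude_edge_columns = 3) {
  do.call(rbind, lapply(field$times, function(t) {
    row_concentrations(field, t, exclude_edge_columns)
  }))
}

#' Gradient stability metrics
#'
#' Operationalises gradient stability: after an establishment window
#' (default 1 h), the gradient counts as stable while (i) the row means stay
#' monotonically ordered (row 1 highest) and (ii) every row mean remains
#' within `drift_tolerance` of its value at the establishment snapshot.
#'
#' @param profiles A tibble from [row_concentration_series()] (columns
#'   `time_s`, `row`, `mean_uM`).
#' @param establishment_time Establishment window (s), default 3600.
#' @param drift_tolerance Maximum tolerated fractional per-row drift.
#' @return A list with `t_stable` (s of stability after establishment),
#'   `drift_24h` (max fractional row drift from establishment to
#'   establishment + 24 h; `NA` if the series is shorter), and `row_drift`
#'   (tibble of per-row drift at the last covered time).
#' @export
stability_metrics <- function(profiles, establishment_time = 3600,
                              drift_tolerance = 0.10) {
  times <- sort(unique(profiles$time_s))
  if (max(times) < establishment_time) {
    stop("profile series shorter than the establishment window")
  }
  t0 <- times[which.min(abs(times - establishment_time))]
  wide <- profile_matrix(profiles)   # rows x times
  ref <- wide[, as.character(t0)]
  after <- times[times >= t0]
  ok <- vapply(as.character(after), function(tc) {
    v <- wide[, tc]
    all(diff(v) < 0) && all(abs(v - ref) / ref <= drift_tolerance)
  }, logical(1))
  first_bad <- which(!ok)[1]
  t_stable <- if (is.na(first_bad)) max(times) - t0 else after[first_bad] - t0
  t24 <- t0 + 24 * 3600
  half_frame <- stats::median(diff(times)) / 2
  drift_24h <- if (min(abs(times - t24)) <= half_frame + 1e-6 * t24) {
    tk <- times[which.min(abs(times - t24))]
    max(abs(wide[, as.character(tk)] - ref) / ref)
  } else NA_real_
  tlast <- as.character(max(times))
  list(t_stable = t_stable, drift_24h = drift_24h,
       row_drift = tibble::tibble(
         row = seq_len(nrow(wide)),
         drift = (wide[, tlast] - ref) / ref))
}

profile_matrix <- function(profiles) {
  times <- sort(unique(profiles$time_s))
  rows <- sort(unique(profiles$row))
  m <- matrix(NA_real_, length(rows), length(times),
              dimnames = list(rows, times))
  m[cbind(match(profiles$row, rows), match(profiles$time_s, times))] <-
    profiles$mean_uM
  m
}

#' Export a concentration field as CSV + TIFF
#'
#' Writes the per-row profile series to `<prefix>_rows.csv` and the stored
#' frames as a multi-frame 32-bit TIFF `<prefix>_field.tif` (values scaled to
#' the source concentration).
#'
#' @param field A `concentration_field`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file names.
#' @export
export_concentration_field <- function(field, prefix) {
  rows <- row_concentration_series(field)
  csv <- paste0(prefix, "_rows.csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  tif <- paste0(prefix, "_field.tif")
  c0 <- max(field$compound$source_concentration, 1e-12)
  imgs <- lapply(field$frames, function(f) pmin(pmax(f / c0, 0), 1))
  if (requireNamespace("tiff", quietly = TRUE)) {
    tiff::writeTIFF(imgs, tif, bits.per.sample = 32L)
  } else tif <- NA_character_
  invisible(c(csv, tif))
}
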