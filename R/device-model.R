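# ---- hydraulic equivalent-circuit model of the gradient device ----
#
# Open reservoirs behave as capacitors (C = A / (rho g)), microchannels as
# resistors (Hagen-Poiseuille for rectangular ducts), so the whole device is
# an RC network driven by fluid-height differences. Pressures are hydrostatic,
# P = rho g h, and flows obey dP = R Q.

#' Rectangular microchannel segment
#'
#' Geometry of one channel of the fluidic network. Dimensions are in
#' micrometres. By convention `height` is the smaller of the two cross-section
#' dimensions; arguments are swapped on construction if supplied the other way
#' round.
#'
#' @param width Channel width (um).
#' @param height Channel depth (um).
#' @param length Channel length (um).
#' @param label Optional label used in network summaries.
#' @param n_parallel Number of identical channels lumped into this segment
#'   (e.g. the array of connecting microchannels on one side of the device);
#'   the segment resistance is divided by `n_parallel`.
#' @return An object of class `channel_segment`.
#' @export
#' @examples
#' channel_segment(width = 100, height = 7, length = 2000)
channel_segment <- function(width, height, length, label = "", n_parallel = 1) {
  dims <- c(width = width, height = height, length = length)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("invalid channel geometry: all dimensions must be finite and > 0")
  }
  if (n_parallel < 1) stop("n_parallel must be >= 1")
  if (height > width) {
    tmp <- width; width <- height; height <- tmp
  }
  structure(
    list(width = width, height = height, length = length,
         label = label, n_parallel = n_parallel),
    class = "channel_segment"
  )
}

#' @export
print.channel_segment <- function(x, ...) {
  cat(sprintf("channel segment%s: %g x %g um cross-section, %g um long (x%d)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$width, x$height, x$length, x$n_parallel))
  invisible(x)
}

#' Hydraulic resistance of a rectangular channel
#'
#' Laminar-flow resistance of a rectangular duct, from the exact Fourier
#' series solution for pressure-driven (Poiseuille) flow,
#' \deqn{R = \frac{12 \mu L}{w h^3} \left[1 - \sum_{n\,odd}
#'   \frac{192 h}{\pi^5 w n^5} \tanh\!\left(\frac{n \pi w}{2 h}\right)\right]^{-1},}
#' truncated after `n_terms` odd terms (the series converges like \eqn{n^{-5}};
#' 25 terms leave a truncation error far below 1e-10). For the device's
#' shallow channels (h << w) this approaches the familiar lubrication limit
#' \eqn{12 \mu L / (w h^3 (1 - 0.63 h/w))}.
#'
#' @param segment A [channel_segment()].
#' @param viscosity Dynamic viscosity in Pa s (default 0.7e-3, culture medium
#'   at 37 C).
#' @param n_terms Number of odd series terms retained.
#' @return Resistance in Pa s m^-3.
#' @export
#' @examples
#' seg <- channel_segment(width = 100, height = 7, length = 2000)
#' channel_resistance(seg)
channel_resistance <- function(segment, viscosity = 0.7e-3, n_terms = 25) {
  stopifnot(inherits(segment, "channel_segment"))
  if (viscosity <= 0) stop("viscosity must be > 0")
  w <- segment$width * 1e-6
  h <- segment$height * 1e-6
  L <- segment$length * 1e-6
  n <- seq(1, by = 2, length.out = n_terms)
  series <- sum(tanh(n * pi * w / (2 * h)) / n^5)
  f <- 1 - (192 * h / (pi^5 * w)) * series
  R <- 12 * viscosity * L / (w * h^3 * f)
  R / segment$n_parallel
}

#' Open-well reservoir
#'
#' @param diameter Well diameter (mm).
#' @param initial_height Initial fluid height (mm).
#' @param overflow_height Height of the overflow port (mm), or `NA` for a
#'   reservoir without an overflow port.
#' @param role One of `"side_source"` (drug side), `"side_medium"`,
#'   `"central"`.
#' @param label Reservoir label.
#' @return An object of class `reservoir`.
#' @export
reservoir <- function(diameter, initial_height, overflow_height = NA,
                      role = c("side_source", "side_medium", "central"),
                      label = "") {
  role <- match.arg(role)
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be > 0")
  if (!is.finite(initial_height) || initial_height < 0) {
    stop("initial_height must be >= 0")
  }
  if (!is.na(overflow_height) && overflow_height <= 0) {
    stop("overflow_height, if present, must be > 0")
  }
  structure(
    list(diameter = diameter, initial_height = initial_height,
         overflow_height = overflow_height, role = role, label = label),
    class = "reservoir"
  )
}

#' Hydraulic capacitance of an open reservoir
#'
#' In the electrical analogy an open well stores volume per unit pressure:
#' `C = A / (rho * g)` with `A` the cross-sectional area.
#'
#' @param reservoir A [reservoir()].
#' @param rho Fluid density (kg m^-3).
#' @param g Gravitational acceleration (m s^-2).
#' @return Capacitance in m^3 Pa^-1.
#' @export
#' @examples
#' reservoir_capacitance(reservoir(4, 0.4, role = "central"))
reservoir_capacitance <- function(reservoir, rho = 1000, g = 9.81) {
  stopifnot(inherits(reservoir, "reservoir"))
  A <- pi * (reservoir$diameter * 1e-3 / 2)^2
  A / (rho * g)
}

reservoir_area_m2 <- function(r) pi * (r$diameter * 1e-3 / 2)^2

#' Fluidic network of the gradient device
#'
#' Assembles reservoirs and channel segments into a hydraulic network.
#' Connectivity is given per segment as `from`/`to` node names; nodes that are
#' not reservoir labels are treated as internal junctions (zero storage) whose
#' pressures are solved from Kirchhoff's current law.
#'
#' @param reservoirs Named list of [reservoir()] objects (names are node
#'   labels).
#' @param segments List of [channel_segment()] objects.
#' @param connections Data frame with columns `from`, `to`, one row per
#'   segment, naming the nodes each segment joins.
#' @param rho Fluid density (kg m^-3).
#' @param g Gravitational acceleration (m s^-2).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return An object of class `fluidic_network` with precomputed segment
#'   resistances, reservoir capacitances, and the total side-to-central
#'   resistance `R_T`.
#' @export
fluidic_network <- function(reservoirs, segments, connections,
                            rho = 1000, g = 9.81, viscosity = 0.7e-3) {
  stopifnot(is.list(reservoirs), length(names(reservoirs)) == length(reservoirs))
  if (nrow(connections) != length(segments)) {
    stop("connections must have one row per segment")
  }
  R <- vapply(segments, channel_resistance, numeric(1), viscosity = viscosity)
  res_nodes <- names(reservoirs)
  all_nodes <- unique(c(connections$from, connections$to))
  junctions <- setdiff(all_nodes, res_nodes)
  if (!all(res_nodes %in% all_nodes)) {
    stop("network is not well-posed: some reservoirs are unconnected")
  }
  net <- structure(
    list(reservoirs = reservoirs, segments = segments,
         connections = connections, resistances = R,
         junctions = junctions, rho = rho, g = g, viscosity = viscosity),
    class = "fluidic_network"
  )
  net$R_T <- total_resistance(net)
  net
}

#' @export
print.fluidic_network <- function(x, ...) {
  cat(sprintf("fluidic network: %d reservoirs, %d segments, R_T = %.3g Pa s m^-3\n",
              length(x$reservoirs), length(x$segments), x$R_T))
  invisible(x)
}

# Effective resistance between the (joined) side reservoirs and the (joined)
# central reservoirs: push unit flow from side rail to central rail and read
# the pressure drop.
#' Total side-to-central hydraulic resistance
#'
#' Effective resistance `R_T` of the channel network between all side
#' reservoirs (tied together) and all central reservoirs (tied together);
#' the quantity entering the pressure decay time constant `R_T * 4 C_S`.
#'
#' @param network A [fluidic_network()].
#' @return Resistance in Pa s m^-3.
#' @export
total_resistance <- function(network) {
  res <- network$reservoirs
  side <- names(res)[vapply(res, function(r) r$role != "central", logical(1))]
  central <- names(res)[vapply(res, function(r) r$role == "central", logical(1))]
  if (!length(side) || !length(central)) stop("need side and central reservoirs")
  # Collapse side nodes into one super-node "S*", central into "C*".
  relabel <- function(n) ifelse(n %in% side, "S*", ifelse(n %in% central, "C*", n))
  conn <- network$connections
  from <- relabel(conn$from); to <- relabel(conn$to)
  nodes <- unique(c(from, to))
  gmat <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  gcond <- 1 / network$resistances
  for (i in seq_along(gcond)) {
    a <- from[i]; b <- to[i]
    if (a == b) next
    gmat[a, b] <- gmat[a, b] + gcond[i]
    gmat[b, a] <- gmat[b, a] + gcond[i]
  }
  diag(gmat) <- 0
  lap <- diag(rowSums(gmat)) - gmat
  # Solve lap %*% p = I with p("C*") = 0, unit current injected at "S*".
  keep <- setdiff(nodes, "C*")
  rhs <- as.numeric(keep == "S*")
  p <- solve(lap[keep, keep, drop = FALSE], rhs)
  unname(p["S*"])
}

#' Hydrostatic pressures with overflow ports (closed form)
#'
#' Closed-form side and central reservoir pressures when the central
#' reservoirs carry overflow ports that clamp their fluid height at the
#' initial value `h_C_in`:
#' \deqn{P(C_S) = \rho g \left(h_{S,in} - (h_{S,in} - h_{C,in})
#'   (1 - e^{-t/(R_T 4 C_S)})\right), \quad P(C_C) = \rho g\, h_{C,in}.}
#'
#' @param t Time (s), scalar or vector; must be >= 0.
#' @param h_S_in,h_C_in Initial side / central fluid heights (m),
#'   `h_S_in >= h_C_in >= 0`.
#' @param R_T Total network resistance (Pa s m^-3).
#' @param C_S Capacitance of one side reservoir (m^3 Pa^-1).
#' @param rho,g Fluid density and gravity.
#' @return A list with elements `P_CS`, `P_CC` (Pa, same length as `t`).
#' @export
pressure_overflow <- function(t, h_S_in, h_C_in, R_T, C_S,
                              rho = 1000, g = 9.81) {
  check_pressure_args(t, h_S_in, h_C_in)
  tau <- R_T * 4 * C_S
  P_CS <- rho * g * (h_S_in - (h_S_in - h_C_in) * (1 - exp(-t / tau)))
  P_CC <- rep(rho * g * h_C_in, length(t))
  list(P_CS = P_CS, P_CC = P_CC)
}

#' Hydrostatic pressures without overflow ports (closed form)
#'
#' Without overflow ports the central level rises as the side level falls and
#' the two converge to a common equilibrium:
#' \deqn{P(C_S) = \rho g\left(h_{S,in} - \frac{h_{S,in}-h_{C,in}}{1 + 2A_S/A_C}
#'   (1 - e^{-t(1+2A_S/A_C)/(R_T 4C_S)})\right)}
#' \deqn{P(C_C) = \rho g\left(h_{C,in} + \frac{2A_S}{2A_S+A_C}
#'   (h_{S,in}-h_{C,in}) (1 - e^{-t(1+2A_S/A_C)/(R_T 4C_S)})\right)}
#' Both converge to the volume-weighted mean height
#' \eqn{(2A_S h_{S,in} + A_C h_{C,in})/(2A_S + A_C)}.
#'
#' @inheritParams pressure_overflow
#' @param A_S,A_C Cross-sectional areas of one side / one central reservoir
#'   (m^2).
#' @return A list with elements `P_CS`, `P_CC` (Pa).
#' @export
pressure_no_overflow <- function(t, h_S_in, h_C_in, R_T, C_S, A_S, A_C,
                                 rho = 1000, g = 9.81) {
  check_pressure_args(t, h_S_in, h_C_in)
  if (A_S <= 0 || A_C <= 0) stop("reservoir areas must be > 0")
  ratio <- 1 + 2 * A_S / A_C
  tau <- R_T * 4 * C_S
  decay <- 1 - exp(-t * ratio / tau)
  dh <- h_S_in - h_C_in
  P_CS <- rho * g * (h_S_in - dh / ratio * decay)
  P_CC <- rho * g * (h_C_in + 2 * A_S / (2 * A_S + A_C) * dh * decay)
  list(P_CS = P_CS, P_CC = P_CC)
}

check_pressure_args <- function(t, h_S_in, h_C_in) {
  if (any(t < 0)) stop("time must be >= 0")
  if (h_C_in < 0 || h_S_in < h_C_in) {
    stop("need h_S_in >= h_C_in >= 0")
  }
  invisible(TRUE)
}

#' Simulate the fluidic network over time
#'
#' Explicit integration (Heun's method) of the per-reservoir volume balance,
#' with overflow ports modelled as a hard clamp: a reservoir's fluid height
#' cannot exceed its `overflow_height`; any excess volume within a step is
#' routed to `overflow_discharged`. Junction pressures are solved from
#' Kirchhoff's current law at every stage.
#'
#' @param network A [fluidic_network()].
#' @param duration Simulated time (s).
#' @param step Integration step (s). Steps are refined automatically if a
#'   reservoir volume would go negative within a step.
#' @param save_every Interval between saved samples (s).
#' @return A list with components `pressure` (class `pressure_trace`: `times`,
#'   `P_CS`, `P_CC`, `dP`, `Q_central`) and `state` (class `reservoir_state`:
#'   `times`, per-reservoir volumes in uL, cumulative `overflow_discharged`
#'   in uL).
#' @export
simulate_network <- function(network, duration, step = 1, save_every = 60) {
  stopifnot(inherits(network, "fluidic_network"))
  res <- network$reservoirs
  res_names <- names(res)
  rho_g <- network$rho * network$g
  areas <- vapply(res, reservoir_area_m2, numeric(1))
  ovf_h <- vapply(res, function(r) r$overflow_height, numeric(1)) * 1e-3
  heights <- vapply(res, function(r) r$initial_height, numeric(1)) * 1e-3
  vols <- heights * areas

  conn <- network$connections
  gcond <- 1 / network$resistances
  junctions <- network$junctions
  central <- res_names[vapply(res, function(r) r$role == "central", logical(1))]
  side <- setdiff(res_names, central)

  # Precompute junction Laplacian structure.
  nj <- length(junctions)
  flows_into <- function(vols) {
    h <- vols / areas
    p_res <- rho_g * h
    names(p_res) <- res_names
    if (nj > 0) {
      lap <- matrix(0, nj, nj, dimnames = list(junctions, junctions))
      rhs <- stats::setNames(numeric(nj), junctions)
      for (i in seq_len(nrow(conn))) {
        a <- conn$from[i]; b <- conn$to[i]; gi <- gcond[i]
        aj <- a %in% junctions; bj <- b %in% junctions
        if (aj) lap[a, a] <- lap[a, a] + gi
        if (bj) lap[b, b] <- lap[b, b] + gi
        if (aj && bj) {
          lap[a, b] <- lap[a, b] - gi; lap[b, a] <- lap[b, a] - gi
        } else if (aj && !bj) rhs[a] <- rhs[a] + gi * p_res[b]
        else if (bj && !aj) rhs[b] <- rhs[b] + gi * p_res[a]
      }
      p_junc <- solve(lap, rhs)
      p_all <- c(p_res, stats::setNames(as.numeric(p_junc), junctions))
    } else p_all <- p_res
    dV <- stats::setNames(numeric(length(res_names)), res_names)
    for (i in seq_len(nrow(conn))) {
      q <- gcond[i] * (p_all[conn$from[i]] - p_all[conn$to[i]])
      if (conn$to[i] %in% res_names) dV[conn$to[i]] <- dV[conn$to[i]] + q
      if (conn$from[i] %in% res_names) dV[conn$from[i]] <- dV[conn$from[i]] - q
    }
    dV
  }

  clamp <- function(vols, discharged) {
    over <- !is.na(ovf_h) & vols > ovf_h * areas
    if (any(over)) {
      excess <- vols[over] - ovf_h[over] * areas[over]
      discharged[over] <- discharged[over] + excess
      vols[over] <- ovf_h[over] * areas[over]
    }
    list(vols = vols, discharged = discharged)
  }

  discharged <- stats::setNames(numeric(length(res_names)), res_names)
  cl <- clamp(vols, discharged); vols <- cl$vols; discharged <- cl$discharged

  n_steps <- ceiling(duration / step)
  save_stride <- max(1L, round(save_every / step))
  n_save <- floor(n_steps / save_stride) + 1L
  times <- numeric(n_save)
  vol_trace <- matrix(NA_real_, n_save, length(res_names),
                      dimnames = list(NULL, res_names))
  ovf_trace <- matrix(NA_real_, n_save, length(res_names),
                      dimnames = list(NULL, res_names))
  P_CS <- P_CC <- Q_c <- numeric(n_save)

  record <- function(k, t) {
    times[k] <<- t
    vol_trace[k, ] <<- vols * 1e9            # m^3 -> uL
    ovf_trace[k, ] <<- discharged * 1e9
    h <- vols / areas
    P_CS[k] <<- mean(rho_g * h[side])
    P_CC[k] <<- mean(rho_g * h[central])
    Q_c[k] <<- (P_CS[k] - P_CC[k]) / network$R_T
  }
  record(1L, 0)

  t <- 0; k <- 1L
  for (s in seq_len(n_steps)) {
    dt <- min(step, duration - t)
    advance <- function(v, d, dt) {
      k1 <- flows_into(v)
      v1 <- v + dt * k1
      if (any(v1 < 0)) return(NULL)
      c1 <- clamp(v1, d)
      k2 <- flows_into(c1$vols)
      v2 <- v + dt * (k1 + k2) / 2
      if (any(v2 < 0)) return(NULL)
      clamp(v2, d)
    }
    out <- advance(vols, discharged, dt)
    if (is.null(out)) {
      # refine: take 10 sub-steps; if still failing, raise
      sub <- dt / 10
      for (j in 1:10) {
        out <- advance(vols, discharged, sub)
        if (is.null(out)) {
          stop(sprintf(
            "integration unstable at t = %.1f s: reservoir volume went negative; reduce `step`",
            t))
        }
        vols <- out$vols; discharged <- out$discharged
      }
    } else {
      vols <- out$vols; discharged <- out$discharged
    }
    t <- t + dt
    if (s %% save_stride == 0L) {
      k <- k + 1L
      record(k, t)
    }
  }
  if (k < n_save) {
    times <- times[1:k]; vol_trace <- vol_trace[1:k, , drop = FALSE]
    ovf_trace <- ovf_trace[1:k, , drop = FALSE]
    P_CS <- P_CS[1:k]; P_CC <- P_CC[1:k]; Q_c <- Q_c[1:k]
  }

  pressure <- structure(
    list(times = times, P_CS = P_CS, P_CC = P_CC,
         dP = P_CS - P_CC, Q_central = Q_c),
    class = "pressure_trace")
  state <- structure(
    list(times = times, volumes_uL = vol_trace,
         overflow_discharged_uL = ovf_trace),
    class = "reservoir_state")
  list(pressure = pressure, state = state)
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("pressure trace: %d samples over %.2f h, dP %.3g -> %.3g Pa\n",
              length(x$times), max(x$times) / 3600,
              x$dP[1], x$dP[length(x$dP)]))
  invisible(x)
}

#' Export a network simulation as a tidy table
#'
#' @param sim Result of [simulate_network()].
#' @param network The [fluidic_network()] that produced it (for reservoir
#'   cross-sections).
#' @return A tibble with columns `time_s`, `reservoir`, `volume_uL`,
#'   `pressure_Pa` (hydrostatic, from the fluid height), `dP_Pa`, `Q_m3s`.
#' @export
pressure_trace_table <- function(sim, network) {
  st <- sim$state; pr <- sim$pressure
  res_names <- colnames(st$volumes_uL)
  areas <- vapply(network$reservoirs[res_names], reservoir_area_m2,
                  numeric(1))
  rho_g <- network$rho * network$g
  out <- do.call(rbind, lapply(seq_along(res_names), function(i) {
    data.frame(time_s = st$times, reservoir = res_names[i],
               volume_uL = st$volumes_uL[, i],
               pressure_Pa = rho_g * st$volumes_uL[, i] * 1e-9 / areas[i],
               dP_Pa = pr$dP, Q_m3s = pr$Q_central)
  }))
  tibble::as_tibble(out)
}

#' Reservoir volume quality-control check
#'
#' An experiment is discarded when any reservoir's measured end-point volume
#' deviates from the model-expected volume by strictly more than `tolerance`
#' (default 10%); deviation exactly at the tolerance is accepted. A zero
#' expected volume with a nonzero measurement is indeterminate and treated as
#' a discard.
#'
#' @param measured,expected Named numeric vectors of volumes (uL) with
#'   matching reservoir names (order-insensitive).
#' @param tolerance Maximum tolerated fractional deviation.
#' @return A list with `verdict` (`"accept"` or `"discard"`) and `deviations`
#'   (named fractional deviations; `NA` where indeterminate).
#' @export
#' @examples
#' qc_volume_check(c(W1 = 55, W2 = 61), c(W1 = 60, W2 = 60))
qc_volume_check <- function(measured, expected, tolerance = 0.10) {
  if (is.null(names(measured)) || is.null(names(expected)) ||
      !setequal(names(measured), names(expected))) {
    stop("measured and expected must be named vectors over the same reservoirs")
  }
  expected <- expected[names(measured)]
  dev <- abs(measured - expected) / expected
  indet <- expected == 0 & measured != 0
  dev[expected == 0 & measured == 0] <- 0
  dev[indet] <- NA_real_
  discard <- any(indet) || any(dev > tolerance, na.rm = TRUE)
  list(verdict = if (discard) "discard" else "accept", deviations = dev)
}
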