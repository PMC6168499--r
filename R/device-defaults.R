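# ---- default gradient-device network ----

#' Default gradient-generating device network
#'
#' The standard six-reservoir device: two drug-side reservoirs (W1, W2) and
#' two medium-side reservoirs (W5, W6), each pair feeding a 35 um-deep side
#' channel that connects to the central channel through an array of
#' high-resistance 7 um-deep microchannels; the central channel drains into
#' two overflow-ported central reservoirs (W3, W4) whose ports clamp the
#' central fluid height, holding `P(C_C)` constant while the side levels
#' decay slowly towards it. Channel lengths, well fill volumes and the
#' overflow height are not dictated by the device concept; the defaults
#' here are chosen so the network sustains the slowly-decaying
#' microlitre-per-hour cross-flow that the gradient relies on (see the
#' package vignette for the sizing argument).
#'
#' @param layout A [generate_layout()]; the central-channel dimensions are
#'   taken from it.
#' @param side_volume_uL Drug/medium volume pipetted into each side
#'   reservoir.
#' @param side_diameter,central_diameter Reservoir punch diameters (mm).
#' @param overflow_height Central overflow-port height (mm); central
#'   reservoirs start filled to the port.
#' @param overflow If `FALSE`, build the same device without overflow ports
#'   (central levels free to rise).
#' @param side_channel [channel_segment()] of each side-channel half
#'   (reservoir to mid-channel junction).
#' @param connecting [channel_segment()] lumping one side's
#'   connecting-channel array.
#' @param viscosity Medium viscosity (Pa s).
#' @return A [fluidic_network()].
#' @export
#' @examples
#' net <- default_gradient_device()
#' net$R_T
default_gradient_device <- function(layout = generate_layout(),
                                    side_volume_uL = 60,
                                    side_diameter = 8,
                                    central_diameter = 4,
                                    overflow_height = 0.15,
                                    overflow = TRUE,
                                    side_channel = channel_segment(
                                      500, 35, 10000, "side channel half"),
                                    connecting = channel_segment(
                                      10, 7, 2000, "connecting array",
                                      n_parallel = 60),
                                    viscosity = 0.7e-3) {
  A_S <- pi * (side_diameter * 1e-3 / 2)^2
  h_S <- side_volume_uL * 1e-9 / A_S * 1e3    # mm
  res <- list(
    W1 = reservoir(side_diameter, h_S, role = "side_source", label = "W1"),
    W2 = reservoir(side_diameter, h_S, role = "side_source", label = "W2"),
    W5 = reservoir(side_diameter, h_S, role = "side_medium", label = "W5"),
    W6 = reservoir(side_diameter, h_S, role = "side_medium", label = "W6"),
    W3 = reservoir(central_diameter, overflow_height,
                   overflow_height = if (overflow) overflow_height else NA,
                   role = "central", label = "W3"),
    W4 = reservoir(central_diameter, overflow_height,
                   overflow_height = if (overflow) overflow_height else NA,
                   role = "central", label = "W4"))
  central_half <- channel_segment(layout$channel_width,
                                  layout$channel_depth,
                                  layout$channel_length / 2,
                                  "central channel half")
  segments <- list(side_channel, side_channel,     # W1-A, W2-A
                   side_channel, side_channel,     # W5-B, W6-B
                   connecting, connecting,         # A-CC, B-CC
                   central_half, central_half)     # CC-W3, CC-W4
  connections <- data.frame(
    from = c("W1", "W2", "W5", "W6", "A", "B", "CC", "CC"),
    to   = c("A",  "A",  "B",  "B",  "CC", "CC", "W3", "W4"),
    stringsAsFactors = FALSE)
  fluidic_network(res, segments, connections, viscosity = viscosity)
}

#' Simulate the default gradient protocol
#'
#' Convenience wrapper: builds the default network, integrates it, and runs
#' the concentration-gradient solver for the given compound.
#'
#' @param compound A [compound()].
#' @param duration Simulated time (s).
#' @param layout Device layout.
#' @param network Optional pre-built [fluidic_network()].
#' @param ... Passed to [solve_gradient()].
#' @return A `concentration_field`.
#' @export
simulate_gradient_experiment <- function(compound, duration,
                                         layout = generate_layout(),
                                         network = NULL, ...) {
  if (is.null(network)) network <- default_gradient_device(layout)
  sim <- simulate_network(network, duration, step = 5, save_every = 300)
  solve_gradient(layout, sim$pressure, compound, duration, ...)
}
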