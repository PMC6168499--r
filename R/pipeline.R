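# ---- configuration-driven end-to-end pipeline ----
#
# simulate (network + gradient) -> synthesize images -> analyze -> fit ->
# report. Every stage writes its artifacts into the run directory and the
# report records seeds and effective numerical parameters so a run can be
# audited and reproduced.

#' Default run configuration
#'
#' @return A nested list with sections `device`, `compound`, `experiment`,
#'   `analysis`, and a `seed`; see the vignette for field meanings. The
#'   defaults describe a cisplatin-like disaggregation screen on the
#'   240-well array with a 12 h drug incubation after a 1 h gradient
#'   establishment window.
#' @export
default_run_config <- function() {
  list(
    device = list(n_rows = 8, n_cols = 30, well_size = 150,
                  well_pitch = 155, side_volume_uL = 60,
                  overflow_height_mm = 0.15),
    compound = list(name = "cisplatin", molecular_weight = 300.05,
                    diffusion_coefficient = NULL,
                    source_concentration_uM = 250),
    experiment = list(days = c(4, 8), drug_day = 5, incubation_hours = 12,
                      establishment_hours = 1, mode = "disaggregation",
                      true_ec50_uM = 100, true_hill = 3,
                      second_application = FALSE,
                      simulate_gradient = TRUE, row_doses_uM = NULL),
    analysis = list(exclude_edge_columns = 3, min_area_um2 = 400,
                    smoothing_px = 1.5,
                    size_groups = list(list(label = "Group 1", lower = 0,
                                            upper = 75),
                                       list(label = "Group 2", lower = 76,
                                            upper = 150))),
    gradient = list(grid_spacing_um = 20, grid_spacing_x_um = 50),
    seed = 1)
}

#' Read a run configuration from YAML
#'
#' Unknown fields are rejected; missing fields fall back to
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (is.list(base[[sec]])) {
      badf <- setdiff(names(user[[sec]]), names(base[[sec]]))
      if (length(badf)) {
        stop(sprintf("unknown field(s) in config section '%s': %s", sec,
                     paste(badf, collapse = ", ")))
      }
      base[[sec]] <- utils::modifyList(base[[sec]], user[[sec]],
                                       keep.null = TRUE)
    } else base[[sec]] <- user[[sec]]
  }
  base
}

config_layout <- function(cfg) {
  generate_layout(n_rows = cfg$device$n_rows, n_cols = cfg$device$n_cols,
                  well_size = cfg$device$well_size,
                  well_pitch = cfg$device$well_pitch)
}

config_compound <- function(cfg, double = FALSE) {
  c0 <- cfg$compound$source_concentration_uM * (if (double) 2 else 1)
  compound(cfg$compound$name, cfg$compound$molecular_weight,
           diffusion_coefficient = cfg$compound$diffusion_coefficient,
           source_concentration = c0)
}

#' Run the full synthetic screening pipeline
#'
#' Executes device flow simulation, gradient simulation (or a user-supplied
#' row-dose profile), synthetic image generation, image analysis,
#' concentration-response fitting and reporting. All stochastic stages are
#' seeded from `config$seed`; identical config + seed reproduce identical
#' outputs.
#'
#' @param config A configuration list ([default_run_config()] /
#'   [read_run_config()]).
#' @param outdir Run directory; created if missing. `NULL` skips all file
#'   output.
#' @return An object of class `run_report` (also written to
#'   `report.json` in `outdir`).
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  cfg <- config
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  layout <- config_layout(cfg)
  report <- list(seed = cfg$seed, config = cfg,
                 package_version = as.character(utils::packageVersion("gradspheroid")))

  # -- stage 1: device flow -------------------------------------------------
  network <- default_gradient_device(
    layout, side_volume_uL = cfg$device$side_volume_uL,
    overflow_height = cfg$device$overflow_height_mm)
  est_s <- cfg$experiment$establishment_hours * 3600
  inc_s <- cfg$experiment$incubation_hours * 3600
  grad_s <- est_s + inc_s
  flow <- simulate_network(network, grad_s, step = 5, save_every = 300)
  report$device <- list(
    R_T = network$R_T,
    tau_h = network$R_T * 4 * reservoir_capacitance(network$reservoirs$W1) / 3600,
    dP0_Pa = flow$pressure$dP[1],
    Q0_m3s = flow$pressure$Q_central[1])
  report$expected_volumes_uL <- flow$state$volumes_uL[nrow(flow$state$volumes_uL), ]

  # -- stage 2: gradient ----------------------------------------------------
  incubations <- list(list(start_h = 0, establishment_h = est_s / 3600,
                           duration_h = grad_s / 3600, doubled = FALSE))
  if (isTRUE(cfg$experiment$simulate_gradient)) {
    cmp <- config_compound(cfg)
    field <- solve_gradient(layout, flow$pressure, cmp, grad_s,
                            grid_spacing = cfg$gradient$grid_spacing_um,
                            grid_spacing_x = cfg$gradient$grid_spacing_x_um)
    series <- row_concentration_series(
      field, exclude_edge_columns = cfg$analysis$exclude_edge_columns)
    # dose seen during incubation: time-average of the row means over the
    # incubation window
    win <- series[series$time_s >= est_s, ]
    doses <- vapply(sort(unique(win$row)),
                    function(r) mean(win$mean_uM[win$row == r]), numeric(1))
    stab <- stability_metrics(series, establishment_time = est_s)
    report$gradient <- list(
      effective_dt_s = field$dt,
      row_doses_uM = doses,
      t_stable_h = stab$t_stable / 3600,
      drift_24h = stab$drift_24h,
      max_within_row_spread = max(series$spread_frac[series$time_s >= est_s]))
    if (!is.null(outdir)) {
      utils::write.csv(series, file.path(outdir, "row_profile.csv"),
                       row.names = FALSE)
    }
  } else {
    doses <- cfg$experiment$row_doses_uM
    if (is.null(doses)) doses <- seq(206.5, 42.2, length.out = layout$n_rows)
    report$gradient <- list(row_doses_uM = doses, simulated = FALSE)
  }
  if (isTRUE(cfg$experiment$second_application)) {
    doses <- 2 * doses
    incubations[[2]] <- list(start_h = incubations[[1]]$duration_h,
                             establishment_h = est_s / 3600,
                             duration_h = grad_s / 3600, doubled = TRUE)
  }
  report$incubations <- incubations

  # -- stage 3: synthetic experiment ---------------------------------------
  gt <- ground_truth(layout, seed = cfg$seed,
                     ec50 = cfg$experiment$true_ec50_uM,
                     hill = cfg$experiment$true_hill,
                     mode = cfg$experiment$mode, row_doses = doses,
                     drug_day = cfg$experiment$drug_day)
  imgs <- render_experiment(layout, gt, days = cfg$experiment$days,
                            seed = cfg$seed + 1L)

  # -- stage 4: image analysis ---------------------------------------------
  params <- segmentation_params(min_area = cfg$analysis$min_area_um2,
                                smoothing = cfg$analysis$smoothing_px)
  meas <- measure_timecourse(imgs, params)
  meas <- exclude_edge_columns(meas, layout,
                               k = cfg$analysis$exclude_edge_columns)
  meas <- assign_row_doses(meas, doses)
  if (!is.null(outdir)) {
    utils::write.csv(meas, file.path(outdir, "measurements.csv"),
                     row.names = FALSE)
  }

  # -- stage 5: concentration-response -------------------------------------
  final_day <- max(cfg$experiment$days)
  endpoint <- meas[meas$day == final_day, ]
  curves <- list()
  fits <- list()
  for (readout in c("viable_fraction", "shape_factor")) {
    pts <- aggregate_rows(endpoint, readout)
    curves[[readout]] <- pts
    fit <- fit_concentration_response(pts)
    fits[[readout]] <- list(ec50_uM = fit$ec50, hill = fit$hill,
                            top = fit$top, bottom = fit$bottom,
                            converged = fit$converged, n_points = fit$n_points)
  }
  groups <- lapply(cfg$analysis$size_groups,
                   function(g) size_group(g$label, g$lower, g$upper))
  by_size <- group_by_size(endpoint, groups)
  group_fits <- lapply(by_size, function(tab) {
    if (nrow(tab) < 8) return(list(converged = FALSE, n = nrow(tab)))
    f <- fit_concentration_response(aggregate_rows(tab, "viable_fraction"))
    list(ec50_uM = f$ec50, converged = f$converged, n = nrow(tab))
  })
  corr <- correlate_sf_vf(endpoint)
  report$dose_response <- list(
    n_points = nrow(curves$viable_fraction), fits = fits,
    size_group_fits = group_fits,
    correlation = list(r_sf_vf = corr$r, n = corr$n))
  report$ground_truth <- list(ec50_uM = gt$ec50, hill = gt$hill,
                              mode = gt$mode)

  out <- structure(c(report, list(curves = curves)), class = "run_report")
  if (!is.null(outdir)) {
    utils::write.csv(do.call(rbind, curves), file.path(outdir, "curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    plot_run_report(out, file.path(outdir, "curves.png"))
  }
  out
}

#' Run one synthetic screen and recover its dose-response
#'
#' Convenience wrapper used for parameter-recovery studies: generates a
#' ground-truthed synthetic experiment, renders baseline and end-point
#' images for the analysis-retained wells, measures them, and fits the
#' 8-point viable-fraction concentration-response curve.
#'
#' @param seed Integer seed.
#' @param ec50,hill,mode Ground-truth response parameters.
#' @param layout Device layout.
#' @param row_doses Per-row doses (uM); default near-linear 206.5-42.2.
#' @param exclude_k Edge columns excluded per side.
#' @param days Imaging days (baseline and end-point).
#' @param drug_day Drug-application day.
#' @return A list: `fit` (the [fit_concentration_response()] result),
#'   `correlation` (S_F-V_F Pearson), `measurements` (end-point table),
#'   `true_ec50`.
#' @export
run_synthetic_screen <- function(seed = 1, ec50 = 100, hill = 3,
                                 mode = "disaggregation",
                                 layout = generate_layout(),
                                 row_doses = NULL, exclude_k = 3,
                                 days = c(4, 8), drug_day = 5) {
  gt <- ground_truth(layout, seed = seed, ec50 = ec50, hill = hill,
                     mode = mode, row_doses = row_doses,
                     drug_day = drug_day)
  keep <- well_centers(layout)
  keep <- keep[keep$col > exclude_k & keep$col <= layout$n_cols - exclude_k, ]
  imgs <- render_experiment(layout, gt, days = days, seed = seed,
                            wells = keep)
  meas <- measure_timecourse(imgs, drug_day = drug_day)
  meas <- assign_row_doses(meas, gt$row_doses)
  endpoint <- meas[meas$day == max(days), ]
  fit <- fit_concentration_response(
    aggregate_rows(endpoint, "viable_fraction"))
  list(fit = fit, correlation = correlate_sf_vf(endpoint),
       measurements = endpoint, true_ec50 = ec50)
}

#' @export
print.run_report <- function(x, ...) {
  cat("gradient-screen run report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$gradient$t_stable_h)) {
    cat(sprintf("  gradient: %d row doses, stable %.1f h after establishment\n",
                length(x$gradient$row_doses_uM), x$gradient$t_stable_h))
  }
  f <- x$dose_response$fits
  for (r in names(f)) {
    if (isTRUE(f[[r]]$converged)) {
      cat(sprintf("  %s: EC50 = %.1f uM (hill %.2f)\n", r, f[[r]]$ec50_uM,
                  f[[r]]$hill))
    } else cat(sprintf("  %s: no EC50 (flat response)\n", r))
  }
  cat(sprintf("  S_F-V_F Pearson r = %.3f (n = %d)\n",
              x$dose_response$correlation$r_sf_vf,
              x$dose_response$correlation$n))
  invisible(x)
}

plot_run_report <- function(report, file) {
  grDevices::png(file, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (readout in names(report$curves)) {
    pts <- report$curves[[readout]]
    graphics::plot(pts$conc_uM, pts$mean, log = "x", pch = 19,
                   xlab = "concentration (uM)", ylab = readout,
                   main = readout)
    graphics::arrows(pts$conc_uM, pts$mean - pts$sem, pts$conc_uM,
                     pts$mean + pts$sem, angle = 90, code = 3,
                     length = 0.03)
  }
  invisible(file)
}
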