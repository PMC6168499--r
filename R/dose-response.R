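# ---- concentration-response analysis ----
#
# Each array row sees one concentration, so a device yields an 8-point
# concentration-response curve per readout: each point is the mean (+/- SEM)
# of all retained spheroids in the row. Curves are fitted with a 4-parameter
# logistic on log-concentration; EC50 is the concentration at half-maximal
# response.

#' Spheroid size group
#'
#' @param label Group label.
#' @param lower,upper Inclusive baseline equivalent-diameter bounds (um).
#' @return An object of class `size_group`.
#' @export
#' @examples
#' size_group("Group 1", 0, 75); size_group("Group 2", 76, 150)
size_group <- function(label, lower, upper) {
  if (lower > upper) stop("size-group bounds must be ordered")
  structure(list(label = label, lower = lower, upper = upper),
            class = "size_group")
}

#' Default size groups
#'
#' Group 1 = 0-75 um, Group 2 = 76-150 um baseline diameter.
#' @return List of two [size_group()]s.
#' @export
default_size_groups <- function() {
  list(size_group("Group 1", 0, 75), size_group("Group 2", 76, 150))
}

#' Annotate measurements with per-row doses
#'
#' @param table Measurement table with `well_row`.
#' @param profile Either a tibble from [row_concentrations()] (columns
#'   `row`, `mean_uM`) or a numeric vector of per-row concentrations
#'   (row 1 first).
#' @return `table` with a `dose_uM` column.
#' @export
assign_row_doses <- function(table, profile) {
  doses <- if (is.numeric(profile)) profile
           else profile$mean_uM[order(profile$row)]
  n_rows <- max(table$well_row)
  if (length(doses) != n_rows) {
    stop(sprintf("profile has %d rows but the table spans %d array rows",
                 length(doses), n_rows))
  }
  table$dose_uM <- doses[table$well_row]
  table
}

#' Partition spheroids into size groups
#'
#' Membership by baseline equivalent diameter; bounds are inclusive at both
#' ends (a 75 um spheroid is Group 1 under the defaults, a 76 um one
#' Group 2). Spheroids outside every group are dropped.
#'
#' @param table Measurement table with `baseline_area_um2` (or
#'   `eq_diam_um` for single-day tables).
#' @param groups List of [size_group()]s; must not overlap.
#' @return Named list of tables, one per group.
#' @export
group_by_size <- function(table, groups = default_size_groups()) {
  bounds <- t(vapply(groups, function(g) c(g$lower, g$upper), numeric(2)))
  o <- order(bounds[, 1])
  if (length(groups) > 1 &&
      any(bounds[o, 1][-1] <= bounds[o, 2][-length(groups)] &
          bounds[o, 1][-1] >= bounds[o, 1][-length(groups)])) {
    stop("size groups overlap")
  }
  diam <- if ("baseline_area_um2" %in% names(table)) {
    2 * sqrt(table$baseline_area_um2 / pi)
  } else if ("eq_diam_um" %in% names(table)) {
    table$eq_diam_um
  } else stop("table lacks baseline diameters")
  out <- lapply(groups, function(g) table[!is.na(diam) & diam >= g$lower &
                                            diam <= g$upper, ])
  names(out) <- vapply(groups, function(g) g$label, character(1))
  out
}

#' Aggregate spheroid readouts into concentration-response points
#'
#' One point per array row: mean, SEM (`sd/sqrt(n)`, `NA` for n = 1) and n
#' over retained spheroids. Rows left empty after filtering are omitted
#' with a warning.
#'
#' @param table Dose-annotated measurement table (see [assign_row_doses()]).
#' @param readout Column to aggregate: `"shape_factor"` or
#'   `"viable_fraction"` (any numeric column works).
#' @return A tibble `row`, `conc_uM`, `readout`, `mean`, `sem`, `n`.
#' @export
aggregate_rows <- function(table, readout = "viable_fraction") {
  if (!readout %in% names(table)) stop("unknown readout column: ", readout)
  if (is.null(table$dose_uM)) stop("assign row doses first")
  rows <- sort(unique(table$well_row))
  pts <- lapply(rows, function(r) {
    v <- table[[readout]][table$well_row == r]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    tibble::tibble(
      row = r, conc_uM = table$dose_uM[table$well_row == r][1],
      readout = readout, mean = mean(v),
      sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  })
  empty <- vapply(pts, is.null, logical(1))
  if (any(empty)) {
    warning(sprintf("rows %s empty after filtering; points omitted",
                    paste(rows[empty], collapse = ", ")))
  }
  do.call(rbind, pts[!empty])
}

# 4PL on log10 concentration: y = bottom + (top - bottom) /
#   (1 + 10^(hill * (log10(ec50) - log10(c)))).
fourpl <- function(lc, bottom, top, lec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lc)))
}

#' Fit a 4-parameter logistic concentration-response curve
#'
#' Levenberg-Marquardt fit of top, bottom, EC50 and Hill slope on
#' log-concentration, initialised from data quantiles, with EC50 bounded to
#' \[min dose / 10, max dose x 10\]. A flat-response guard refuses an EC50
#' when the dynamic range of the means is below twice the pooled SEM.
#'
#' @param points A tibble from [aggregate_rows()] (needs `conc_uM`, `mean`;
#'   `sem` used for the flat guard when present).
#' @return An object of class `dose_response_fit`: `ec50`, `hill`, `top`,
#'   `bottom`, `converged`, `n_points`, `residual_se`, and the fitted model.
#' @export
fit_concentration_response <- function(points) {
  pts <- points[!is.na(points$mean) & points$conc_uM > 0, ]
  if (nrow(pts) < 4 || length(unique(pts$conc_uM)) < 4) {
    stop("need >= 4 points with distinct positive concentrations")
  }
  out <- structure(
    list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
         bottom = NA_real_, converged = FALSE, n_points = nrow(pts),
         residual_se = NA_real_, model = NULL),
    class = "dose_response_fit")
  rng <- diff(range(pts$mean))
  pooled_sem <- if (all(is.na(pts$sem))) 0 else
    sqrt(mean(pts$sem[!is.na(pts$sem)]^2))
  if (rng < 2 * pooled_sem || rng == 0) {
    return(out)  # flat response: no resolvable EC50
  }
  lc <- log10(pts$conc_uM)
  trend <- stats::coef(stats::lm(pts$mean ~ lc))[2]
  start <- list(bottom = min(pts$mean), top = max(pts$mean),
                lec50 = mean(range(lc)), hill = if (trend >= 0) 1 else -1)
  lower <- c(bottom = -Inf, top = -Inf, lec50 = min(lc) - 1, hill = -20)
  upper <- c(bottom = Inf, top = Inf, lec50 = max(lc) + 1, hill = 20)
  fit <- try(minpack.lm::nlsLM(
    mean ~ fourpl(lc, bottom, top, lec50, hill),
    data = data.frame(mean = pts$mean, lc = lc),
    start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(out)
  cf <- stats::coef(fit)
  if (cf[["lec50"]] <= lower[["lec50"]] + 1e-6 ||
      cf[["lec50"]] >= upper[["lec50"]] - 1e-6) {
    return(out)  # EC50 pinned at the search bound: outside the tested range
  }
  out$ec50 <- 10^cf[["lec50"]]
  out$hill <- cf[["hill"]]
  out$top <- cf[["top"]]
  out$bottom <- cf[["bottom"]]
  out$residual_se <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- TRUE
  out$model <- fit
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "4PL fit (%d points): EC50 = %.4g uM, hill = %.3g, top = %.3g, bottom = %.3g\n",
      x$n_points, x$ec50, x$hill, x$top, x$bottom))
  } else {
    cat(sprintf("4PL fit (%d points): not converged (flat or degenerate response)\n",
                x$n_points))
  }
  invisible(x)
}

#' Correlate shape factor with viable fraction
#'
#' Pearson product-moment correlation between paired end-point S_F and V_F
#' values. Spheroid disaggregation couples falling viability to a rising
#' shape factor (strong negative r); pure shrinkage with intact contours
#' leaves S_F flat and the correlation near zero.
#'
#' @param sf,vf Paired numeric vectors (or a measurement table given as
#'   `sf` with `shape_factor`/`viable_fraction` columns).
#' @return A list `r`, `n`, `p_value`.
#' @export
correlate_sf_vf <- function(sf, vf = NULL) {
  if (is.data.frame(sf)) {
    vf <- sf$viable_fraction; sf <- sf$shape_factor
  }
  ok <- !is.na(sf) & !is.na(vf)
  sf <- sf[ok]; vf <- vf[ok]
  if (length(sf) < 3) stop("need >= 3 complete (S_F, V_F) pairs")
  if (stats::sd(sf) == 0 || stats::sd(vf) == 0) {
    warning("zero variance in S_F or V_F: correlation undefined")
    return(list(r = NA_real_, n = length(sf), p_value = NA_real_))
  }
  ct <- stats::cor.test(sf, vf, method = "pearson")
  list(r = unname(ct$estimate), n = length(sf), p_value = ct$p.value)
}
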