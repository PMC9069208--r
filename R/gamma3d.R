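#' Parameters for 3-D gamma analysis
#'
#' Defaults follow a 3%/1.5 mm local-normalization criterion with a 5%
#' low-dose cutoff: voxels whose reference dose falls below
#' `low_dose_cutoff * max(reference)` are excluded from the gamma map and
#' the passing rate.
#'
#' @param dose_criterion dose-difference criterion as a fraction (0.03 =
#'   3%).
#' @param dta distance-to-agreement criterion in mm.
#' @param normalization `"local"` (reference dose at the evaluated
#'   reference point) or `"global"` (maximum reference dose).
#' @param low_dose_cutoff fraction of the maximum reference dose below
#'   which points are excluded.
#' @param search_radius_factor search sphere radius as a multiple of
#'   `dta`.
#' @param interpolation_step sub-voxel search lattice step in mm
#'   (default `dta / 10`).
#' @return A list of class `gamma_params`.
#' @export
gamma_params <- function(dose_criterion = 0.03, dta = 1.5,
                         normalization = c("local", "global"),
                         low_dose_cutoff = 0.05,
                         search_radius_factor = 3,
                         interpolation_step = dta / 10) {
  normalization <- match.arg(normalization)
  stopifnot(dose_criterion > 0, dta > 0, low_dose_cutoff >= 0,
            low_dose_cutoff < 1, search_radius_factor > 0,
            interpolation_step > 0)
  structure(list(dose_criterion = dose_criterion, dta = dta,
                 normalization = normalization,
                 low_dose_cutoff = low_dose_cutoff,
                 search_radius_factor = search_radius_factor,
                 interpolation_step = interpolation_step),
            class = "gamma_params")
}

#' 3-D gamma-index map between reference and evaluated dose grids
#'
#' For every reference voxel above the low-dose cutoff the gamma index
#' `gamma(r) = min over r_e of sqrt(|r_e - r|^2 / dta^2 +
#' (D_e(r_e) - D_r(r))^2 / (criterion * D_norm)^2)` is minimized over
#' evaluated-dose positions on a trilinearly interpolated sub-voxel
#' lattice within the search sphere. The grids need not share spacing but
#' must overlap spatially. A point passes when `gamma <= 1` (the boundary
#' counts as a pass).
#'
#' @param reference reference DOSE_GY [ct_volume()] (sets the output
#'   grid, the cutoff and the normalization).
#' @param evaluated evaluated DOSE_GY [ct_volume()].
#' @param params a [gamma_params()].
#' @return An object of class `gamma_result`: `gamma` (array on the
#'   reference grid, `NA` below cutoff), `passing_rate` (%),
#'   `n_evaluated`, `params`.
#' @export
gamma_map <- function(reference, evaluated, params = gamma_params()) {
  stopifnot(inherits(reference, "ct_volume"),
            inherits(evaluated, "ct_volume"),
            inherits(params, "gamma_params"))
  for (v in list(reference, evaluated))
    if (v$semantic != "DOSE_GY")
      stop("expected DOSE_GY volumes, got semantic ", v$semantic)
  rmax <- max(reference$values)
  if (!(rmax > 0)) stop("reference dose maximum must be positive")
  # spatial overlap check on voxel-center bounding boxes
  for (a in 1:3) {
    r_rng <- range(axis_coords(reference)[[a]])
    e_rng <- range(axis_coords(evaluated)[[a]])
    if (r_rng[1] > e_rng[2] || r_rng[2] < e_rng[1])
      stop("reference and evaluated grids do not overlap on axis ", a)
  }
  cutoff_abs <- params$low_dose_cutoff * rmax
  if (!any(reference$values >= cutoff_abs))
    stop("all reference points fall below the low-dose cutoff")
  g <- gamma_engine_cpp(
    as.vector(reference$values), dim(reference$values),
    reference$spacing, reference$origin,
    as.vector(evaluated$values), dim(evaluated$values),
    evaluated$spacing, evaluated$origin,
    params$dose_criterion, params$dta,
    params$normalization == "local", cutoff_abs, rmax,
    params$interpolation_step,
    params$search_radius_factor * params$dta)
  gamma <- array(g, dim = dim(reference$values))
  n_eval <- sum(!is.na(gamma))
  structure(list(gamma = gamma, spacing = reference$spacing,
                 origin = reference$origin,
                 passing_rate = 100 * sum(gamma <= 1, na.rm = TRUE) /
                   n_eval,
                 n_evaluated = n_eval, params = params),
            class = "gamma_result")
}

#' Gamma passing rate in percent
#'
#' `100 * #(gamma <= 1) / n_evaluated` over the points above the low-dose
#' cutoff; `gamma = 1` exactly counts as passing.
#'
#' @param result a [gamma_map()] result.
#' @return Passing rate in percent.
#' @export
passing_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  100 * sum(result$gamma <= 1, na.rm = TRUE) / result$n_evaluated
}

#' @export
print.gamma_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<gamma_result> %.1f%%/%.1f mm (%s): passing rate %.1f%% over %d points\n",
    100 * p$dose_criterion, p$dta, p$normalization, x$passing_rate,
    x$n_evaluated))
  cat("  gamma: median ",
      format(stats::median(x$gamma, na.rm = TRUE), digits = 3), ", max ",
      format(max(x$gamma, na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}
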