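#' Per-insert ROI means from a predicted volume
#'
#' Extracts, for every assigned bore of a phantom, the mean and SD of the
#' volume over a circular region of interest covering a fraction of the
#' insert's cross-sectional diameter (default ~70%), excluding slices near
#' both axial ends of the insert. The shrunken ROI avoids partial-volume /
#' gradient contamination at the insert-body boundary.
#'
#' @param vol a [ct_volume()] on the phantom grid.
#' @param phantom a [rasterize()]d phantom.
#' @param diameter_fraction fraction of the insert diameter covered by the
#'   ROI, in (0, 1].
#' @param end_exclusion_mm axial exclusion at each end of the insert (mm).
#' @return data.frame with one row per insert: `bore`, `material`, `mean`,
#'   `sd`, `n_voxels`.
#' @export
extract_roi_means <- function(vol, phantom, diameter_fraction = 0.70,
                              end_exclusion_mm = 10) {
  stopifnot(inherits(vol, "ct_volume"), inherits(phantom, "phantom"),
            diameter_fraction > 0, diameter_fraction <= 1,
            end_exclusion_mm >= 0)
  check_same_grid(vol, phantom$labels)
  geom <- phantom$geometry
  ax <- axis_coords(vol)
  inserts <- phantom$truth[!is.na(phantom$truth$bore), , drop = FALSE]
  out <- lapply(seq_len(nrow(inserts)), function(i) {
    k <- inserts$bore[i]
    b <- geom$bores[k, ]
    r_roi <- diameter_fraction * b$radius * 10        # mm
    half_z <- b$depth * 10 / 2 - end_exclusion_mm
    if (half_z <= 0)
      stop("insert '", inserts$material[i],
           "': end exclusion removes the whole insert")
    in_r <- outer((ax[[1]] - b$x * 10)^2, (ax[[2]] - b$y * 10)^2,
                  "+") <= r_roi^2
    in_z <- abs(ax[[3]]) <= half_z
    vals <- vol$values[outer(in_r, in_z, "&")]
    if (!length(vals))
      stop("insert '", inserts$material[i], "': empty ROI")
    data.frame(bore = k, material = inserts$material[i],
               mean = mean(vals), sd = stats::sd(vals),
               n_voxels = length(vals))
  })
  do.call(rbind, out)
}

#' Relative SPR residual in percent
#'
#' `(spr_pre - spr_ref) / spr_ref * 100`, signed.
#'
#' @param spr_pre predicted values.
#' @param spr_ref reference values (non-zero).
#' @return Signed percent residuals.
#' @export
relative_residual <- function(spr_pre, spr_ref) {
  if (any(spr_ref == 0)) stop("zero reference SPR")
  (spr_pre - spr_ref) / spr_ref * 100
}

#' Accuracy summary of predicted vs reference SPR values
#'
#' Computes the per-insert relative residuals and the five summary
#' statistics used to report SPR prediction accuracy: the mean overall
#' relative residual (mean of absolute residuals, %), the RMSE on the SPR
#' scale, Pearson's correlation coefficient r, and the slope `alpha` and
#' intercept `delta` of the ordinary least-squares regression
#' `spr_pre = alpha * spr_ref + delta`.
#'
#' @param spr_pre predicted SPR values, one per insert.
#' @param spr_ref reference SPR values.
#' @param names optional insert names.
#' @return An object of class `residual_report`: `per_insert` data.frame
#'   and fields `mean_overall_residual_pct`, `rmse`, `pearson_r`, `alpha`,
#'   `delta`, `n`. With fewer than 2 inserts, r/alpha/delta are `NA`.
#' @export
summarize_residuals <- function(spr_pre, spr_ref,
                                names = seq_along(spr_pre)) {
  stopifnot(length(spr_pre) == length(spr_ref))
  res <- relative_residual(spr_pre, spr_ref)
  n <- length(res)
  if (n >= 2 && stats::sd(spr_ref) > 0) {
    r <- if (stats::sd(spr_pre) > 0) stats::cor(spr_ref, spr_pre)
         else NA_real_
    fit <- stats::lm(spr_pre ~ spr_ref)
    alpha <- stats::coef(fit)[[2]]; delta <- stats::coef(fit)[[1]]
  } else {
    r <- alpha <- delta <- NA_real_  # undefined without reference spread
  }
  structure(list(
    per_insert = data.frame(name = names, spr_pre = spr_pre,
                            spr_ref = spr_ref, residual_pct = res),
    mean_overall_residual_pct = mean(abs(res)),
    rmse = sqrt(mean((spr_pre - spr_ref)^2)),
    pearson_r = r, alpha = alpha, delta = delta, n = n),
    class = "residual_report")
}

#' @export
print.residual_report <- function(x, digits = 4, ...) {
  cat("SPR accuracy report (n = ", x$n, " inserts)\n", sep = "")
  print(x$per_insert, digits = digits, row.names = FALSE)
  cat(sprintf("  mean overall relative residual: %.3f %%\n",
              x$mean_overall_residual_pct))
  cat(sprintf("  RMSE:  %.4f\n", x$rmse))
  cat(sprintf("  r:     %.4f\n  alpha: %.3f\n  delta: %.3f\n",
              x$pearson_r, x$alpha, x$delta))
  invisible(x)
}

#' @export
summary.residual_report <- function(object, ...) {
  data.frame(mean_overall_residual_pct = object$mean_overall_residual_pct,
             rmse = object$rmse, r = object$pearson_r,
             alpha = object$alpha, delta = object$delta, n = object$n)
}

# trilinear interpolation of a ct_volume at world points (n x 3 matrix);
# points outside the grid return NA
interp_trilinear <- function(vol, pts) {
  d <- dim(vol$values)
  t1 <- (pts[, 1] - vol$origin[1]) / vol$spacing[1]
  t2 <- (pts[, 2] - vol$origin[2]) / vol$spacing[2]
  t3 <- (pts[, 3] - vol$origin[3]) / vol$spacing[3]
  out <- rep(NA_real_, nrow(pts))
  ok <- t1 >= 0 & t1 <= d[1] - 1 & t2 >= 0 & t2 <= d[2] - 1 &
        t3 >= 0 & t3 <= d[3] - 1
  if (!any(ok)) return(out)
  i <- pmin(floor(t1[ok]), d[1] - 2); fx <- t1[ok] - i
  j <- pmin(floor(t2[ok]), d[2] - 2); fy <- t2[ok] - j
  k <- pmin(floor(t3[ok]), d[3] - 2); fz <- t3[ok] - k
  v <- vol$values
  idx <- function(di, dj, dk)
    v[cbind(i + di + 1, j + dj + 1, k + dk + 1)]
  out[ok] <-
    idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    idx(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    idx(1, 1, 0) * fx * fy * (1 - fz) +
    idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    idx(1, 0, 1) * fx * (1 - fy) * fz +
    idx(0, 1, 1) * (1 - fx) * fy * fz +
    idx(1, 1, 1) * fx * fy * fz
  out
}

#' Water-equivalent path length along a ray
#'
#' Samples an SPR volume by trilinear interpolation along a straight ray
#' and accumulates the water-equivalent path length
#' `WEPL(depth) = integral of SPR` by the trapezoidal rule.
#'
#' @param vol an SPR [ct_volume()].
#' @param entry world coordinate (mm) where the ray enters.
#' @param direction ray direction (normalized internally).
#' @param step sampling step in mm (should not exceed the voxel spacing).
#' @param max_depth maximum depth to trace (mm); default traces until the
#'   ray leaves the volume.
#' @return An object of class `wepl_profile`: data.frame `depth_mm`,
#'   `wepl_mm` (cumulative, non-decreasing for non-negative SPR).
#' @export
wepl_profile <- function(vol, entry, direction, step = 0.1,
                         max_depth = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$semantic != "SPR")
    stop("expected an SPR volume, got semantic ", vol$semantic)
  dirn <- direction / sqrt(sum(direction^2))
  d <- dim(vol$values)
  extent <- sqrt(sum(((d - 1) * vol$spacing)^2))
  if (is.null(max_depth)) max_depth <- extent
  t <- seq(0, max_depth, by = step)
  pts <- cbind(entry[1] + t * dirn[1], entry[2] + t * dirn[2],
               entry[3] + t * dirn[3])
  spr <- interp_trilinear(vol, pts)
  inside <- !is.na(spr)
  if (!any(inside)) stop("ray does not intersect the volume")
  # trace up to the last contiguous in-volume sample from the entry side
  first <- which(inside)[1]
  run <- which(!inside & seq_along(inside) > first)
  last <- if (length(run)) run[1] - 1 else length(t)
  t <- t[first:last]; spr <- spr[first:last]
  wepl <- c(0, cumsum((spr[-1] + spr[-length(spr)]) / 2 * diff(t)))
  structure(list(profile = data.frame(depth_mm = t - t[1],
                                      wepl_mm = wepl),
                 entry = entry, direction = dirn, step = step),
            class = "wepl_profile")
}

#' @export
print.wepl_profile <- function(x, ...) {
  p <- x$profile
  cat("<wepl_profile> depth 0..", format(max(p$depth_mm)), " mm, WEPL ",
      format(max(p$wepl_mm), digits = 6), " mm (step ", x$step, " mm)\n",
      sep = "")
  invisible(x)
}

# depth at which the cumulative WEPL crosses `target` (linear inverse
# interpolation)
wepl_crossing_depth <- function(report, target) {
  p <- report$profile
  if (max(p$wepl_mm) < target)
    stop("WEPL target ", target, " mm not reached (max ",
         format(max(p$wepl_mm), digits = 6), " mm)")
  i <- which(p$wepl_mm >= target)[1]
  if (i == 1) return(p$depth_mm[1])
  w0 <- p$wepl_mm[i - 1]; w1 <- p$wepl_mm[i]
  p$depth_mm[i - 1] + (target - w0) / (w1 - w0) *
    (p$depth_mm[i] - p$depth_mm[i - 1])
}

#' Distal range shift between two WEPL profiles
#'
#' Difference of the depths at which two cumulative WEPL profiles cross a
#' common water-equivalent target: `depth_b - depth_a` in mm. Positive
#' values mean profile `b` reaches the target deeper (predicts a longer
#' range) than `a`.
#'
#' @param report_a,report_b [wepl_profile()] objects.
#' @param wepl_target water-equivalent depth target (mm).
#' @return Shift in mm.
#' @export
distal_shift <- function(report_a, report_b, wepl_target) {
  wepl_crossing_depth(report_b, wepl_target) -
    wepl_crossing_depth(report_a, wepl_target)
}
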