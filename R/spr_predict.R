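#' Piecewise log-linear mapping from effective atomic number to I-value
#'
#' The DLCT route needs a mean excitation energy at every voxel, but the
#' scanner only delivers an effective atomic number (EAN). The mapping
#' models `ln I` as a continuous piecewise-linear function of EAN,
#' calibrated on reference human tissues: soft tissues and bone-like
#' tissues fall on clearly different loci, so by default one segment covers
#' each side of a configurable EAN boundary (8.0). Outside the calibrated
#' range the mapping is clamped to its boundary values.
#'
#' @param db a [load_material_tables()] database.
#' @param tissues material names used for calibration; default all
#'   `reference_human_tissue` entries.
#' @param boundaries interior EAN breakpoints between segments.
#' @param anchor_water shift the segment containing the water EAN so the
#'   mapping returns exactly `constants$I_water` there (default TRUE).
#' @param constants a [physics_constants()] object (EAN exponent and the
#'   water I-value used for anchoring).
#' @return An object of class `ivalue_mapping` with a `segments`
#'   data.frame (`z_lo`, `z_hi`, `slope`, `intercept` for `ln I`),
#'   `clamp_range`, per-tissue fit table and the ln-I RMS residual.
#' @export
fit_ivalue_mapping <- function(db,
                               tissues = materials_in_category(
                                 db, "reference_human_tissue"),
                               boundaries = 8.0, anchor_water = TRUE,
                               constants = physics_constants()) {
  props <- material_properties_table(db, tissues, constants)
  z <- props$z_eff; lnI <- log(props$i_value)
  edges <- c(-Inf, sort(boundaries), Inf)
  nseg <- length(edges) - 1
  seg_of <- findInterval(z, edges)
  counts <- tabulate(seg_of, nseg)
  if (any(counts < 2))
    stop("segment(s) ", paste(which(counts < 2), collapse = ", "),
         " have fewer than 2 calibration tissues")

  slope <- intercept <- numeric(nseg)
  f1 <- stats::lm(lnI ~ z, subset = seg_of == 1)
  slope[1] <- stats::coef(f1)[[2]]; intercept[1] <- stats::coef(f1)[[1]]
  if (anchor_water) {
    zw <- effective_atomic_number("water", db, constants$zeff_exponent)
    wseg <- findInterval(zw, edges)
    if (wseg == 1)
      intercept[1] <- intercept[1] +
        (log(constants$I_water) - (intercept[1] + slope[1] * zw))
  }
  # later segments: slope refit with the intercept pinned for continuity
  if (nseg > 1) for (s in 2:nseg) {
    zb <- edges[s]
    y0 <- intercept[s - 1] + slope[s - 1] * zb
    sel <- seg_of == s
    slope[s] <- sum((lnI[sel] - y0) * (z[sel] - zb)) / sum((z[sel] - zb)^2)
    intercept[s] <- y0 - slope[s] * zb
  }

  seg <- data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
                    slope = slope, intercept = intercept)
  m <- structure(list(segments = seg,
                      clamp_range = range(z),
                      anchor_water = anchor_water),
                 class = "ivalue_mapping")
  fitted <- predict_ivalue(z, m)
  m$fit <- data.frame(name = props$name, z_eff = z, i_value = props$i_value,
                      i_fitted = fitted)
  m$lnI_rms <- sqrt(mean((log(fitted) - lnI)^2))
  m
}

#' Exactly interpolating I-value mapping
#'
#' Builds an [fit_ivalue_mapping()]-compatible mapping that passes exactly
#' through a set of (EAN, I) points, one log-linear segment per adjacent
#' pair. Used for self-consistent closed-loop experiments where the mapping
#' must reproduce each calibration material's I-value exactly.
#'
#' @param z_eff numeric vector of effective atomic numbers (distinct).
#' @param i_value matching mean excitation energies (eV).
#' @return An `ivalue_mapping`.
#' @export
exact_ivalue_mapping <- function(z_eff, i_value) {
  stopifnot(length(z_eff) == length(i_value), length(z_eff) >= 2,
            all(i_value > 0))
  o <- order(z_eff)
  z <- z_eff[o]; lnI <- log(i_value[o])
  if (any(diff(z) < 1e-9))
    stop("EAN values must be distinct for exact interpolation")
  slope <- diff(lnI) / diff(z)
  intercept <- lnI[-length(lnI)] - slope * z[-length(z)]
  seg <- data.frame(z_lo = c(-Inf, z[-c(1, length(z))]),
                    z_hi = c(z[-c(1, length(z))], Inf),
                    slope = slope, intercept = intercept)
  structure(list(segments = seg, clamp_range = range(z),
                 anchor_water = FALSE,
                 fit = data.frame(z_eff = z, i_value = exp(lnI))),
            class = "ivalue_mapping")
}

#' Predict I-values from effective atomic numbers
#'
#' Evaluates an [fit_ivalue_mapping()] (vectorized). EAN values outside the
#' mapping's calibrated range are clamped to the nearest boundary.
#'
#' @param z_eff numeric vector/array of effective atomic numbers.
#' @param mapping an `ivalue_mapping`.
#' @return I-values in eV, same shape as `z_eff`.
#' @export
predict_ivalue <- function(z_eff, mapping) {
  stopifnot(inherits(mapping, "ivalue_mapping"))
  z <- pmin(pmax(z_eff, mapping$clamp_range[1]), mapping$clamp_range[2])
  seg <- mapping$segments
  idx <- findInterval(z, c(seg$z_lo[1], seg$z_hi))
  idx[idx < 1] <- 1L; idx[idx > nrow(seg)] <- nrow(seg)
  out <- exp(seg$intercept[idx] + seg$slope[idx] * z)
  if (!is.null(dim(z_eff))) dim(out) <- dim(z_eff)
  out
}

#' @export
predict.ivalue_mapping <- function(object, z_eff, ...)
  predict_ivalue(z_eff, object)

#' @export
print.ivalue_mapping <- function(x, ...) {
  cat("<ivalue_mapping> ", nrow(x$segments), " segment(s), EAN range [",
      format(x$clamp_range[1], digits = 4), ", ",
      format(x$clamp_range[2], digits = 4), "]",
      if (isTRUE(x$anchor_water)) ", water-anchored", "\n", sep = "")
  if (!is.null(x$lnI_rms))
    cat("  ln-I fit RMS: ", format(x$lnI_rms, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Serialize calibration objects to JSON
#'
#' Writes an [fit_ivalue_mapping()] or [fit_deedz()] object to a small
#' versioned JSON file, and reads it back. Fit diagnostics (per-tissue
#' tables, RMS) are not serialized; the reloaded object is
#' evaluation-equivalent.
#'
#' @param x an `ivalue_mapping` or `deedz_fit`.
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed object (read).
#' @export
write_calibration <- function(x, path) {
  if (inherits(x, "ivalue_mapping")) {
    payload <- list(schema = "sprct/ivalue_mapping/1",
                    segments = x$segments, clamp_range = x$clamp_range,
                    anchor_water = isTRUE(x$anchor_water))
  } else if (inherits(x, "deedz_fit")) {
    payload <- list(schema = "sprct/deedz_fit/1", e = x$e, m = x$m,
                    z_eff_w = x$z_eff_w)
  } else {
    stop("cannot serialize objects of class ", class(x)[1])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$schema, "sprct/ivalue_mapping/1")) {
    seg <- as.data.frame(p$segments)
    # JSON has no Infinity literal: open ends round-trip as NA
    seg$z_lo[is.na(seg$z_lo)] <- -Inf
    seg$z_hi[is.na(seg$z_hi)] <- Inf
    structure(list(segments = seg, clamp_range = p$clamp_range,
                   anchor_water = p$anchor_water),
              class = "ivalue_mapping")
  } else if (identical(p$schema, "sprct/deedz_fit/1")) {
    structure(list(e = p$e, m = p$m, z_eff_w = p$z_eff_w),
              class = "deedz_fit")
  } else {
    stop("unrecognized calibration schema in '", path, "'")
  }
}

#' Voxelwise SPR prediction from DLCT channel volumes
#'
#' The DLCT route: at every voxel, the EAN is converted to a mean
#' excitation energy through `mapping` and combined with the relative
#' electron density in the Bethe stopping-power ratio ([bethe_spr()]).
#' Voxels with ED below `air_threshold` are set to `air_spr` to avoid
#' log-domain blow-ups in near-vacuum.
#'
#' @param ed ED [ct_volume()].
#' @param ean EAN [ct_volume()] on the same grid.
#' @param mapping an [fit_ivalue_mapping()].
#' @param constants a [physics_constants()] object.
#' @param air_threshold ED below which a voxel is treated as air.
#' @param air_spr SPR assigned to air voxels.
#' @return An SPR [ct_volume()].
#' @export
predict_spr_volume <- function(ed, ean, mapping,
                               constants = physics_constants(),
                               air_threshold = 0.05, air_spr = 0.001) {
  stopifnot(inherits(ed, "ct_volume"), inherits(ean, "ct_volume"))
  if (ed$semantic != "ED" || ean$semantic != "EAN")
    stop("expected semantics ED and EAN, got ", ed$semantic, " and ",
         ean$semantic)
  check_same_grid(ed, ean)
  iv <- predict_ivalue(ean$values, mapping)
  spr <- bethe_spr(pmax(ed$values, 0), iv, constants)
  spr[ed$values < air_threshold] <- air_spr
  ct_volume(spr, ed$spacing, ed$origin, "SPR")
}

#' Fit the DEEDZ mass-density coefficients
#'
#' The dual-energy mass-density model expresses the ratio of mass density
#' to relative electron density as a quadratic in
#' `x = (Z_eff / Z_eff_w)^m - 1`:
#' `rho = rho_e * (1 + e0 + e1 * x + e2 * x^2)`.
#' The coefficients `(e0, e1, e2)` are obtained by least squares of
#' `rho / rho_e - 1` on `(1, x, x^2)` over a reference tissue set spanning
#' soft tissue and bone; the exponent `m` defaults to 3.3.
#'
#' @param db a [load_material_tables()] database.
#' @param tissues calibration material names.
#' @param m power-law exponent of the EAN ratio.
#' @param constants a [physics_constants()] object (EAN exponent, used to
#'   compute tissue EANs and the water EAN).
#' @param props optional pre-computed calibration table with columns
#'   `name`, `z_eff`, `rho_e`, `rho`; bypasses the composition lookup
#'   (useful for synthetic calibration sets).
#' @return An object of class `deedz_fit` with `e` (length-3 coefficients),
#'   `m`, `z_eff_w` and the per-tissue fit table.
#' @export
fit_deedz <- function(db,
                      tissues = materials_in_category(
                        db, "reference_human_tissue"),
                      m = 3.3, constants = physics_constants(),
                      props = NULL) {
  stopifnot(m > 0)
  if (is.null(props)) {
    if (length(tissues) < 3)
      stop("need at least 3 calibration tissues")
    props <- material_properties_table(db, tissues, constants)
  }
  if (nrow(props) < 3)
    stop("need at least 3 calibration tissues")
  z_eff_w <- effective_atomic_number("water", db, constants$zeff_exponent)
  x <- (props$z_eff / z_eff_w)^m - 1
  y <- props$rho / props$rho_e - 1
  X <- cbind(1, x, x^2)
  if (qr(X)$rank < 3) stop("rank-deficient design: tissues do not span ",
                           "enough EAN range for a quadratic fit")
  e <- as.numeric(qr.solve(X, y))
  structure(list(e = e, m = m, z_eff_w = z_eff_w,
                 fit = data.frame(name = props$name, z_eff = props$z_eff,
                                  rho = props$rho, rho_e = props$rho_e,
                                  rho_fitted = as.numeric(
                                    props$rho_e * (1 + X %*% e)))),
            class = "deedz_fit")
}

#' @export
print.deedz_fit <- function(x, ...) {
  cat("<deedz_fit> e = (", paste(format(x$e, digits = 4), collapse = ", "),
      "), m = ", x$m, ", Z_eff_w = ", format(x$z_eff_w, digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Voxelwise mass density from DLCT channel volumes
#'
#' Evaluates the dual-energy mass-density model
#' `rho = rho_e * (1 + sum_n e_n * x^n)`, `x = (Z_eff/Z_eff_w)^m - 1`
#' (with the convention `x^0 = 1`), at every voxel.
#'
#' @param ed ED [ct_volume()].
#' @param ean EAN [ct_volume()] on the same grid.
#' @param coeffs a [fit_deedz()] object.
#' @return A MASS_DENSITY [ct_volume()] in g/cm3.
#' @export
mass_density_volume <- function(ed, ean, coeffs) {
  stopifnot(inherits(coeffs, "deedz_fit"))
  if (ed$semantic != "ED" || ean$semantic != "EAN")
    stop("expected semantics ED and EAN, got ", ed$semantic, " and ",
         ean$semantic)
  check_same_grid(ed, ean)
  x <- (pmax(ean$values, 0) / coeffs$z_eff_w)^coeffs$m - 1
  rho <- ed$values * (1 + coeffs$e[1] + coeffs$e[2] * x +
                        coeffs$e[3] * x^2)
  ct_volume(rho, ed$spacing, ed$origin, "MASS_DENSITY")
}
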