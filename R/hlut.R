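#' Two-parameter stoichiometric attenuation model
#'
#' Parametrizes the relative photon attenuation of a mixture at a given
#' scanner spectrum as
#' `u = rho_e * (k1 * Zt^3.62 + k2 * Zh^1.86 + 1) / (same for water)`,
#' where `Zt` and `Zh` are electron-fraction power means of the atomic
#' numbers with the photoelectric (3.62) and coherent-scatter (1.86)
#' exponents, and `CTN = 1000 * (u - 1)` in Hounsfield units. `k1` and
#' `k2` are spectrum-dependent weights.
#'
#' @param k1 photoelectric weight (>= 0).
#' @param k2 coherent/Rayleigh weight (>= 0).
#' @param db a [load_material_tables()] database (for the water term).
#' @param exponents power-mean exponents `(p_pe, p_coh)`.
#' @return An object of class `attenuation_fit`.
#' @export
attenuation_fit <- function(k1, k2, db, exponents = c(3.62, 1.86)) {
  stopifnot(k1 >= 0, k2 >= 0, all(exponents > 0))
  w <- get_material(db, "water")
  zt_w <- zbar(w, db, exponents[1])
  zh_w <- zbar(w, db, exponents[2])
  water_norm <- k1 * zt_w^exponents[1] + k2 * zh_w^exponents[2] + 1
  structure(list(k1 = k1, k2 = k2, exponents = exponents,
                 water_norm = water_norm),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat("<attenuation_fit> k1 = ", format(x$k1, digits = 6), ", k2 = ",
      format(x$k2, digits = 6), " (exponents ", x$exponents[1], "/",
      x$exponents[2], ")\n", sep = "")
  invisible(x)
}

# electron-fraction power mean of Z with exponent p
zbar <- function(comp, db, p) {
  ew <- electron_weights(comp, db)
  (sum(ew$lambda * ew$Z^p) / sum(ew$lambda))^(1 / p)
}

#' Theoretical CT number of a material
#'
#' Forward model of the SECT scanner: evaluates the two-parameter
#' stoichiometric attenuation of a composition relative to water and
#' converts it to Hounsfield units. Water returns exactly 0 HU and a
#' material of zero electron density exactly -1000 HU.
#'
#' @param comp a `material` or material name.
#' @param fit an [attenuation_fit()].
#' @param db a [load_material_tables()] database.
#' @return CT number in HU.
#' @export
theoretical_ctn <- function(comp, fit, db) {
  stopifnot(inherits(fit, "attenuation_fit"))
  comp <- as_material(comp, db)
  rho_e <- electron_density(comp, db)
  zt <- zbar(comp, db, fit$exponents[1])
  zh <- zbar(comp, db, fit$exponents[2])
  u <- rho_e * (fit$k1 * zt^fit$exponents[1] +
                fit$k2 * zh^fit$exponents[2] + 1) / fit$water_norm
  1000 * (u - 1)
}

#' Fit the attenuation weights from a CT calibration scan
#'
#' Estimates `(k1, k2)` from measured CT numbers of materials with known
#' composition by least squares on relative attenuation,
#' `sum((u_model - u_meas)^2)`. The normalization by the water term makes
#' the model nonlinear in `(k1, k2)`; an exact linearized solve (clearing
#' the water denominator) provides the start, refined by Nelder-Mead on
#' the true objective. Negative solutions are clipped to zero with a
#' warning.
#'
#' @param comps list of `material` objects (or material names).
#' @param ctn measured CT numbers in HU, one per material.
#' @param db a [load_material_tables()] database.
#' @param exponents power-mean exponents.
#' @return An [attenuation_fit()] with an added `residual_hu` field.
#' @export
fit_attenuation <- function(comps, ctn, db, exponents = c(3.62, 1.86)) {
  stopifnot(length(comps) == length(ctn), length(ctn) >= 2)
  comps <- lapply(comps, as_material, db = db)
  u <- 1 + ctn / 1000
  rho_e <- vapply(comps, electron_density, 0, db = db)
  zt <- vapply(comps, zbar, 0, db = db, p = exponents[1])^exponents[1]
  zh <- vapply(comps, zbar, 0, db = db, p = exponents[2])^exponents[2]
  w <- get_material(db, "water")
  zt_w <- zbar(w, db, exponents[1])^exponents[1]
  zh_w <- zbar(w, db, exponents[2])^exponents[2]

  # u * (k1 zt_w + k2 zh_w + 1) = rho_e (k1 zt + k2 zh + 1)  -- linear in k
  A <- cbind(rho_e * zt - u * zt_w, rho_e * zh - u * zh_w)
  b <- u - rho_e
  if (qr(A)$rank < 2)
    stop("degenerate calibration design: need materials with distinct ",
         "effective atomic numbers (include a bone-like material)")
  k0 <- as.numeric(qr.solve(A, b))

  obj <- function(k) {
    k <- pmax(k, 0)
    wn <- k[1] * zt_w + k[2] * zh_w + 1
    sum((rho_e * (k[1] * zt + k[2] * zh + 1) / wn - u)^2)
  }
  opt <- stats::optim(pmax(k0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  k <- opt$par
  if (any(k < 0)) {
    warning("negative attenuation weight(s) clipped to 0")
    k <- pmax(k, 0)
  }
  fit <- attenuation_fit(k[1], k[2], db, exponents)
  fit$residual_hu <- sqrt(opt$value / length(u)) * 1000
  fit
}

default_hlut_segments <- function() {
  data.frame(label = c("air", "lung", "soft", "bone"),
             lo = c(-Inf, -950, -120, 100),
             hi = c(-950, -120, 100, Inf))
}

#' Build a Hounsfield look-up table from reference tissues
#'
#' The SECT route's calibration: each reference tissue is placed at its
#' theoretical CT number ([theoretical_ctn()]) and its Bethe SPR (with
#' Bragg-additivity I-value, keeping this path independent of the DLCT
#' EAN-to-I mapping), and a continuous piecewise-linear curve is fitted
#' over configurable CTN segments (default air / lung / soft tissue /
#' bone) by least squares on a hat-function basis. An air node at
#' (-1000, 0.001) is always included.
#'
#' @param fit an [attenuation_fit()].
#' @param db a [load_material_tables()] database.
#' @param tissues reference material names spanning lung to cortical bone.
#' @param segments data.frame with columns `label`, `lo`, `hi` in HU.
#' @param constants a [physics_constants()] object.
#' @return An object of class `hlut`: `nodes` (data.frame `ctn`, `spr`),
#'   `tissue_fit` (per-tissue CTN, true and fitted SPR, residual %), and
#'   `spr_at_0hu`.
#' @export
build_hlut <- function(fit, db,
                       tissues = materials_in_category(
                         db, "reference_human_tissue"),
                       segments = default_hlut_segments(),
                       constants = physics_constants()) {
  props <- material_properties_table(db, tissues, constants)
  ctn <- vapply(tissues, function(nm) theoretical_ctn(nm, fit, db), 0)
  spr <- props$spr
  knots <- sort(unique(c(segments$lo[is.finite(segments$lo)],
                         segments$hi[is.finite(segments$hi)])))
  node_ctn <- sort(unique(c(-1000, knots, max(c(ctn, knots)) + 1)))

  # continuous piecewise-linear least squares via hat basis at the nodes;
  # the air anchor (-1000 HU -> 0.001) enters as a heavily weighted point
  x <- c(ctn, -1000); y <- c(spr, 0.001); wt <- c(rep(1, length(ctn)), 1e6)
  repeat {
    B <- sapply(seq_along(node_ctn), function(j) hat_basis(x, node_ctn, j))
    unsupported <- colSums(B != 0) == 0
    if (!any(unsupported)) break
    if (all(unsupported))
      stop("empty HLUT segment range: no calibration tissue in any segment")
    warning("dropping HLUT node(s) at ",
            paste(node_ctn[unsupported], collapse = ", "),
            " HU: no calibration tissue in range")
    node_ctn <- node_ctn[!unsupported]
  }
  W <- sqrt(wt)
  coefs <- as.numeric(qr.solve(W * B, W * y))
  nodes <- data.frame(ctn = node_ctn, spr = coefs)

  h <- structure(list(nodes = nodes, segments = segments,
                      fit = fit), class = "hlut")
  fitted <- evaluate_hlut(ctn, h)
  h$tissue_fit <- data.frame(name = props$name, ctn = ctn, spr_true = spr,
                             spr_fitted = fitted,
                             residual_pct = (fitted - spr) / spr * 100)
  h$spr_at_0hu <- evaluate_hlut(0, h)
  h$fit_rms_pct <- sqrt(mean(h$tissue_fit$residual_pct^2))
  if (any(diff(nodes$spr) < -1e-9))
    warning("HLUT nodes are not monotone non-decreasing in SPR")
  h
}

hat_basis <- function(x, knots, j) {
  n <- length(knots)
  lo <- if (j > 1) knots[j - 1] else -Inf
  mid <- knots[j]
  hi <- if (j < n) knots[j + 1] else Inf
  out <- numeric(length(x))
  l <- x >= lo & x <= mid
  r <- x > mid & x <= hi
  if (is.finite(lo)) out[l] <- (x[l] - lo) / (mid - lo) else out[l] <- 1
  if (is.finite(hi)) out[r] <- (hi - x[r]) / (hi - mid) else out[r] <- 1
  out
}

evaluate_hlut <- function(ctn, hlut) {
  nd <- hlut$nodes
  stats::approx(nd$ctn, nd$spr, xout = ctn, rule = 2)$y
}

#' @export
predict.hlut <- function(object, ctn, ...) evaluate_hlut(ctn, object)

#' @export
print.hlut <- function(x, ...) {
  cat("<hlut> ", nrow(x$nodes), " nodes over [",
      min(x$nodes$ctn), ", ", max(x$nodes$ctn), "] HU; SPR at 0 HU = ",
      format(x$spr_at_0hu, digits = 5), "\n  per-tissue fit RMS: ",
      format(x$fit_rms_pct, digits = 3), " %\n", sep = "")
  invisible(x)
}

#' Convert a CT-number volume to SPR through an HLUT
#'
#' Voxelwise continuous piecewise-linear evaluation with flat extrapolation
#' beyond the end nodes.
#'
#' @param hu an HU [ct_volume()].
#' @param hlut a [build_hlut()] object.
#' @return An SPR [ct_volume()].
#' @export
convert_ctn_volume <- function(hu, hlut) {
  stopifnot(inherits(hu, "ct_volume"), inherits(hlut, "hlut"))
  if (hu$semantic != "HU")
    stop("expected an HU volume, got semantic ", hu$semantic)
  spr <- evaluate_hlut(as.vector(hu$values), hlut)
  ct_volume(array(spr, dim = dim(hu$values)), hu$spacing, hu$origin, "SPR")
}

#' Export / import an HLUT as CSV plus JSON metadata
#'
#' The CSV carries the two-column (HU, SPR) node table; a JSON sidecar
#' stores the attenuation-fit parameters.
#'
#' @param hlut a [build_hlut()] object.
#' @param path CSV output path.
#' @return `path` (write) or an `hlut` (read; evaluation-only, no tissue
#'   fit table).
#' @export
write_hlut <- function(hlut, path) {
  utils::write.csv(hlut$nodes, path, row.names = FALSE)
  jsonlite::write_json(list(k1 = hlut$fit$k1, k2 = hlut$fit$k2,
                            exponents = hlut$fit$exponents,
                            spr_at_0hu = hlut$spr_at_0hu),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_hlut
#' @export
read_hlut <- function(path) {
  nodes <- utils::read.csv(path)
  stopifnot(all(c("ctn", "spr") %in% names(nodes)))
  if (any(diff(nodes$ctn) <= 0)) stop("HLUT nodes must be strictly ",
                                      "increasing in CTN")
  meta <- paste0(path, ".json")
  h <- structure(list(nodes = nodes), class = "hlut")
  if (file.exists(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    h$spr_at_0hu <- m$spr_at_0hu
  }
  h$spr_at_0hu <- h$spr_at_0hu %||% evaluate_hlut(0, h)
  h
}

#' Construct a CT-number-degenerate material pair
#'
#' Demonstrates the central limitation of the SECT route: two materials
#' with different (electron density, EAN) combinations but identical
#' theoretical CT numbers. The second composition's bulk density is tuned
#' so its CTN matches the first material's exactly; a single-energy scan
#' cannot tell them apart, while their true SPRs differ.
#'
#' @param fit an [attenuation_fit()].
#' @param db a [load_material_tables()] database.
#' @param comp_a first material (kept as-is).
#' @param comp_b second material; its density is rescaled.
#' @return List with `a`, `b` (materials, equal CTN) and `ctn`.
#' @export
make_ctn_degenerate_pair <- function(fit, db, comp_a = "muscle",
                                     comp_b = "inner_bone") {
  a <- as_material(comp_a, db); b <- as_material(comp_b, db)
  ctn_a <- theoretical_ctn(a, fit, db)
  u_a <- 1 + ctn_a / 1000
  # CTN is linear in rho (via rho_e at fixed composition): solve for rho_b
  u_b1 <- 1 + theoretical_ctn(b, fit, db) / 1000
  b$rho <- b$rho * u_a / u_b1
  b$name <- paste0(b$name, "_ctn_matched")
  stopifnot(abs(theoretical_ctn(b, fit, db) - ctn_a) < 1e-6)
  list(a = a, b = b, ctn = ctn_a)
}
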