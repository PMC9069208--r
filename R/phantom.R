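#' Cylindrical phantom geometry
#'
#' Describes a cylindrical phantom body with cylindrical bores holding
#' insert materials. All lengths are in cm; the phantom axis is z and the
#' body is centered at the world origin.
#'
#' @param name geometry identifier.
#' @param body_radius body cylinder radius (cm).
#' @param body_height body cylinder height (cm).
#' @param bores data.frame with columns `y`, `x` (bore axis position, cm),
#'   `radius` (cm), `depth` (cm, centered axially).
#' @param insert_assignment character vector of material names, one per bore
#'   (NA for an empty bore).
#' @param body_material material name of the body (default PMMA).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(name, body_radius, body_height, bores,
                             insert_assignment = rep(NA_character_,
                                                     nrow(bores)),
                             body_material = "pmma") {
  stopifnot(body_radius > 0, body_height > 0,
            all(c("y", "x", "radius", "depth") %in% names(bores)))
  if (length(insert_assignment) != nrow(bores))
    stop("insert_assignment must have one entry per bore")
  r_c <- sqrt(bores$y^2 + bores$x^2)
  if (any(r_c + bores$radius > body_radius + 1e-9))
    stop("bore(s) ", paste(which(r_c + bores$radius > body_radius),
                           collapse = ", "), " extend outside the body")
  if (any(bores$depth > body_height + 1e-9))
    stop("bore depth exceeds body height")
  if (nrow(bores) > 1) {
    dd <- as.matrix(stats::dist(cbind(bores$y, bores$x)))
    rr <- outer(bores$radius, bores$radius, "+")
    diag(dd) <- Inf
    if (any(dd < rr - 1e-9)) stop("bores overlap")
  }
  structure(list(name = name, body_radius = body_radius,
                 body_height = body_height, body_material = body_material,
                 bores = bores, insert_assignment = insert_assignment),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry> ", x$name, ": radius ", x$body_radius,
      " cm, height ", x$body_height, " cm, ", nrow(x$bores), " bore(s) [",
      x$body_material, " body]\n", sep = "")
  invisible(x)
}

# one central bore + 8 on a ring at 60% body radius; bone-like materials are
# interleaved with soft surrogates so no two bone inserts are adjacent
nine_bore_layout <- function(body_radius, bore_radius = 1.4, depth = 7) {
  ring <- 0.6 * body_radius
  ang <- (0:7) * pi / 4
  data.frame(y = c(0, ring * sin(ang)), x = c(0, ring * cos(ang)),
             radius = bore_radius, depth = depth)
}

#' Built-in phantom geometries
#'
#' The four cylindrical PMMA phantoms used throughout the package: two
#' one-bore long cylinders, LCT (radius 5 cm) and LC (radius 8 cm), both of
#' height 46 cm, and two nine-bore short cylinders of height 10 cm, SC
#' (radius 8 cm) and SCB (radius 16 cm). Inserts are cylinders of radius
#' 1.4 cm and depth 7 cm. Default insert assignments use the packaged
#' tissue surrogates, with bone-like inserts placed non-adjacent.
#'
#' @return Named list of [phantom_geometry()] objects (`LCT`, `LC`, `SC`,
#'   `SCB`).
#' @export
builtin_geometries <- function() {
  one <- data.frame(y = 0, x = 0, radius = 1.4, depth = 7)
  ring9 <- c("true_water", "adipose", "inner_bone", "muscle", "cb2_30",
             "brain", "cortical_bone", "liver", "breast")
  list(
    LCT = phantom_geometry("LCT", 5, 46, one, "solid_water"),
    LC  = phantom_geometry("LC", 8, 46, one, "solid_water"),
    SC  = phantom_geometry("SC", 8, 10, nine_bore_layout(8), ring9),
    SCB = phantom_geometry("SCB", 16, 10, nine_bore_layout(16), ring9)
  )
}

#' Voxelize a phantom geometry
#'
#' Labels every voxel air / body / insert-k by center-point membership and
#' computes the ground-truth radiological properties of each label from its
#' material composition. Label 0 is air, 1 the body, and `1 + k` the insert
#' in bore k.
#'
#' @param geom a [phantom_geometry()].
#' @param spacing voxel spacing (dx, dy, dz) in mm; default matches a
#'   typical planning-CT grid.
#' @param db a [load_material_tables()] database.
#' @param constants a [physics_constants()] object.
#' @param margin_mm air margin around the body (mm).
#' @return An object of class `phantom` with elements `labels` (a LABEL
#'   [ct_volume()]), `truth` (data.frame: `label`, `material`, `bore`,
#'   `rho_e`, `z_eff`, `i_value`, `spr`, `rho`, `category`), `geometry`,
#'   and `db`.
#' @export
rasterize <- function(geom, spacing = c(0.977, 0.977, 1),
                      db = load_material_tables(),
                      constants = physics_constants(), margin_mm = 5) {
  stopifnot(inherits(geom, "phantom_geometry"), all(spacing > 0))
  assign <- geom$insert_assignment
  if (any(is.na(assign)) || any(assign == "")) {
    warning("unassigned bore(s) ",
            paste(which(is.na(assign) | assign == ""), collapse = ", "),
            " filled with body material")
  }
  R <- geom$body_radius * 10; H <- geom$body_height * 10  # cm -> mm
  n <- ceiling((c(2 * R, 2 * R, H) + 2 * margin_mm) / spacing)
  origin <- -(n - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(n[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]

  # 2-D cross-section labels, then extruded with per-label axial extents
  r2 <- outer(xs^2, ys^2, "+")
  slice <- ifelse(r2 <= R^2, 1L, 0L)
  for (k in seq_len(nrow(geom$bores))) {
    b <- geom$bores[k, ]
    d2 <- outer((xs - b$x * 10)^2, (ys - b$y * 10)^2, "+")
    slice[d2 <= (b$radius * 10)^2] <- 1L + k
  }
  labels <- array(0L, dim = n)
  in_body_z <- abs(zs) <= H / 2
  for (iz in seq_len(n[3])) {
    if (!in_body_z[iz]) next
    lab <- slice
    for (k in seq_len(nrow(geom$bores))) {
      depth <- geom$bores$depth[k] * 10
      if (abs(zs[iz]) > depth / 2) lab[lab == 1L + k] <- 1L
    }
    labels[, , iz] <- lab
  }

  mat_names <- c("air", geom$body_material,
                 ifelse(is.na(assign) | assign == "",
                        geom$body_material, assign))
  truth <- material_properties_table(db, mat_names, constants)
  truth <- cbind(label = 0:(length(mat_names) - 1),
                 material = truth$name,
                 bore = c(NA, NA, seq_len(nrow(geom$bores))),
                 truth[, c("rho_e", "z_eff", "i_value", "spr", "rho")],
                 category = vapply(mat_names, function(nm)
                   get_material(db, nm)$category, ""))
  rownames(truth) <- NULL
  structure(list(labels = ct_volume(labels, spacing, origin, "LABEL"),
                 truth = truth, geometry = geom, db = db,
                 constants = constants),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$geometry$name, ", ",
      paste(dim(x$labels$values), collapse = " x "), " voxels\n", sep = "")
  print(x$truth[, c("label", "material", "rho_e", "z_eff", "i_value",
                    "spr")], digits = 4)
  invisible(x)
}

#' Per-channel Gaussian noise model
#'
#' @param sigma_hu,sigma_ed,sigma_ean standard deviations for the HU, ED and
#'   EAN channels (all >= 0).
#' @param seed RNG seed; the same seed reproduces identical volumes.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma_hu = 0, sigma_ed = 0, sigma_ean = 0,
                        seed = NULL) {
  if (any(c(sigma_hu, sigma_ed, sigma_ean) < 0))
    stop("noise standard deviations must be non-negative")
  structure(list(sigma_hu = sigma_hu, sigma_ed = sigma_ed,
                 sigma_ean = sigma_ean, seed = seed),
            class = "noise_model")
}

label_lookup <- function(phantom, column) {
  lut <- phantom$truth[[column]][match(as.vector(phantom$labels$values),
                                       phantom$truth$label)]
  array(lut, dim = dim(phantom$labels$values))
}

add_noise <- function(values, sd) {
  if (sd == 0) return(values)
  values + array(stats::rnorm(length(values), 0, sd), dim = dim(values))
}

#' Render noisy DLCT channel volumes from a phantom
#'
#' Produces the relative electron-density (ED) and effective-atomic-number
#' (EAN) volumes a dual-layer scanner would deliver: piecewise-constant at
#' the ground-truth values of each label plus independent Gaussian noise.
#'
#' @param phantom a [rasterize()]d phantom.
#' @param noise a [noise_model()].
#' @return List with `ed` and `ean` [ct_volume()]s.
#' @export
render_dlct <- function(phantom, noise = noise_model()) {
  stopifnot(inherits(phantom, "phantom"), inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  sp <- phantom$labels$spacing; or <- phantom$labels$origin
  ed <- add_noise(label_lookup(phantom, "rho_e"), noise$sigma_ed)
  ean <- add_noise(label_lookup(phantom, "z_eff"), noise$sigma_ean)
  list(ed = ct_volume(ed, sp, or, "ED"),
       ean = ct_volume(ean, sp, or, "EAN"))
}

#' Render a noisy SECT CT-number volume from a phantom
#'
#' Produces the Hounsfield-unit volume a single-energy scanner would
#' deliver, using the two-parameter stoichiometric forward model
#' ([theoretical_ctn()]) for each label's composition plus Gaussian noise.
#' Water maps to ~0 HU and air to ~-1000 HU by construction.
#'
#' @param phantom a [rasterize()]d phantom.
#' @param fit an [attenuation_fit()] describing the scanner spectrum.
#' @param noise a [noise_model()].
#' @param quantize round voxel values to integer HU.
#' @return An HU [ct_volume()].
#' @export
render_sect <- function(phantom, fit, noise = noise_model(),
                        quantize = FALSE) {
  stopifnot(inherits(phantom, "phantom"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  ctn <- vapply(phantom$truth$material, function(nm)
    theoretical_ctn(nm, fit, phantom$db), 0)
  lut <- ctn[match(as.vector(phantom$labels$values), phantom$truth$label)]
  hu <- add_noise(array(lut, dim = dim(phantom$labels$values)),
                  noise$sigma_hu)
  if (quantize) hu <- round(hu)
  ct_volume(hu, phantom$labels$spacing, phantom$labels$origin, "HU")
}

#' Paired analytic dose grids for gamma testing
#'
#' Builds a smooth reference dose field and an evaluated field that is the
#' same analytic field translated by `shift` and multiplied by `scale`
#' (both evaluated exactly, not by resampling). Two shapes are available:
#' `"edge"`, a sigmoid distal fall-off along z extruded in 3-D, and
#' `"blob"`, an isotropic 3-D Gaussian.
#'
#' @param dims grid size (nx, ny, nz).
#' @param spacing voxel spacing in mm.
#' @param shift translation of the evaluated field (mm, length 3).
#' @param scale multiplicative dose scaling of the evaluated field.
#' @param shape `"edge"` or `"blob"`.
#' @param d0 plateau / peak dose (Gy).
#' @param edge_z0 sigmoid mid-edge position (mm; default grid center).
#' @param edge_width sigmoid width parameter (mm).
#' @param blob_sigma Gaussian sigma (mm).
#' @param noise_sd additive Gaussian noise on the evaluated field (Gy).
#' @param seed RNG seed for the noise.
#' @return List with `reference` and `evaluated` DOSE_GY [ct_volume()]s.
#' @export
make_dose_pair <- function(dims = c(32, 32, 64), spacing = c(1, 1, 1),
                           shift = c(0, 0, 0), scale = 1,
                           shape = c("edge", "blob"), d0 = 1,
                           edge_z0 = NULL, edge_width = 3,
                           blob_sigma = 10, noise_sd = 0, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(all(is.finite(shift)), scale > 0)
  origin <- -(dims - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  if (is.null(edge_z0)) edge_z0 <- 0
  field <- function(x, y, z) {
    if (shape == "edge") d0 / (1 + exp((z - edge_z0) / edge_width))
    else d0 * exp(-(x^2 + y^2 + z^2) / (2 * blob_sigma^2))
  }
  grid3 <- function(f) {
    X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    f(X, Y, Z)
  }
  ref <- grid3(field)
  ev <- scale * grid3(function(x, y, z)
    field(x - shift[1], y - shift[2], z - shift[3]))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ev <- add_noise(ev, noise_sd)
  }
  list(reference = ct_volume(ref, spacing, origin, "DOSE_GY"),
       evaluated = ct_volume(ev, spacing, origin, "DOSE_GY"))
}
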