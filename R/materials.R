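#' Load element and material composition tables
#'
#' Reads the elemental data table (atomic number, atomic mass, mean excitation
#' energy) and a material composition table (bulk density plus elemental mass
#' fractions in long form) into a material database used by every physics
#' routine in the package. With no arguments the packaged defaults are loaded:
#' water, air, PMMA, thirteen tissue-surrogate inserts, eight implant
#' materials and a set of reference human tissues for calibration.
#'
#' The material CSV schema is long form with header
#' `name,category,rho_g_cm3,element,fraction`, one row per element of each
#' material; `category` is one of `tissue_surrogate`,
#' `reference_human_tissue`, `implant`, `phantom_body`, `water`, `air`.
#' The element CSV schema is `symbol,Z,A_g_mol,I_eV`. Lines starting with `#`
#' are comments.
#'
#' @param materials_path path to a material composition CSV; `NULL` for the
#'   packaged table.
#' @param elements_path path to an element CSV; `NULL` for the packaged table.
#' @return An object of class `material_db`: a list with `elements`
#'   (data.frame) and `materials` (named list of `material` objects with
#'   fields `name`, `category`, `rho`, `fractions`).
#' @examples
#' db <- load_material_tables()
#' names(db$materials)[1:5]
#' @export
load_material_tables <- function(materials_path = NULL, elements_path = NULL) {
  if (is.null(elements_path))
    elements_path <- system.file("extdata", "elements.csv", package = "sprct")
  if (is.null(materials_path))
    materials_path <- system.file("extdata", "materials.csv", package = "sprct")

  el <- utils::read.csv(elements_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("symbol", "Z", "A_g_mol", "I_eV")
  if (!all(need %in% names(el)))
    stop("element table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(el$symbol))
    stop("duplicate element symbols in element table")
  if (any(el$Z < 1) || any(el$A_g_mol <= 0) || any(el$I_eV <= 0))
    stop("element table contains non-physical Z, A or I values")

  mt <- utils::read.csv(materials_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("name", "category", "rho_g_cm3", "element", "fraction")
  if (!all(need %in% names(mt)))
    stop("material table must have columns: ", paste(need, collapse = ", "))

  mats <- lapply(split(mt, factor(mt$name, levels = unique(mt$name))),
                 function(d) {
    rows <- match(d$name, mt$name)  # first row index, for error reporting
    m <- list(name = d$name[[1]], category = d$category[[1]],
              rho = d$rho_g_cm3[[1]],
              fractions = stats::setNames(d$fraction, d$element))
    class(m) <- "material"
    validate_material(m, el, row = rows[[1]])
    m
  })
  db <- list(elements = el, materials = mats)
  class(db) <- "material_db"
  db
}

validate_material <- function(m, elements, row = NA) {
  where <- if (is.na(row)) m$name else paste0(m$name, " (first row ", row, ")")
  missing <- setdiff(names(m$fractions), elements$symbol)
  if (length(missing))
    stop("material '", where, "': unknown element symbol(s): ",
         paste(missing, collapse = ", "))
  s <- sum(m$fractions)
  if (abs(s - 1) > 1e-6)
    stop("material '", where, "': mass fractions sum to ", format(s),
         ", not 1")
  if (m$category != "air" && m$rho <= 0)
    stop("material '", where, "': non-positive density")
  if (any(m$fractions < 0))
    stop("material '", where, "': negative mass fraction")
  invisible(m)
}

#' Construct a material composition in code
#'
#' @param name material identifier.
#' @param fractions named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-6).
#' @param rho bulk mass density in g/cm3.
#' @param category material category string.
#' @param db optional `material_db` used to validate element symbols.
#' @return A `material` object.
#' @export
material <- function(name, fractions, rho,
                     category = "tissue_surrogate", db = NULL) {
  m <- list(name = name, category = category, rho = rho,
            fractions = fractions)
  class(m) <- "material"
  if (!is.null(db)) validate_material(m, db$elements)
  m
}

#' @export
print.material_db <- function(x, ...) {
  cat("<material_db> ", length(x$materials), " materials, ",
      nrow(x$elements), " elements\n", sep = "")
  tab <- table(vapply(x$materials, `[[`, "", "category"))
  for (k in names(tab)) cat("  ", k, ": ", tab[[k]], "\n", sep = "")
  invisible(x)
}

#' @export
print.material <- function(x, ...) {
  cat("<material> ", x$name, " [", x$category, "], rho = ", x$rho,
      " g/cm3\n  ", paste(names(x$fractions),
                          sprintf("%.4f", x$fractions), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

get_material <- function(db, name) {
  m <- db$materials[[name]]
  if (is.null(m)) stop("unknown material '", name, "'")
  m
}

#' Physics constants for stopping-power calculations
#'
#' Bundles the constants entering the Bethe stopping-power ratio: electron
#' rest energy, the water mean excitation energy convention (78.73 eV),
#' the fixed evaluation energy of 100 MeV per nucleon, the nucleon rest
#' energy used for the relativistic beta (proton rest energy by default),
#' and the power-law exponent of the effective-atomic-number definition.
#'
#' @param me_c2 electron rest energy in eV.
#' @param I_water water mean excitation energy in eV.
#' @param T_per_u kinetic energy per nucleon in MeV.
#' @param m_nucleon_c2 nucleon rest energy in MeV.
#' @param zeff_exponent exponent of the effective-atomic-number power law.
#' @return A list of class `physics_constants`.
#' @export
physics_constants <- function(me_c2 = 510998.95, I_water = 78.73,
                              T_per_u = 100, m_nucleon_c2 = 938.272,
                              zeff_exponent = 3.3) {
  stopifnot(me_c2 > 0, I_water > 0, T_per_u > 0, m_nucleon_c2 > 0,
            zeff_exponent > 0)
  structure(list(me_c2 = me_c2, I_water = I_water, T_per_u = T_per_u,
                 m_nucleon_c2 = m_nucleon_c2,
                 zeff_exponent = zeff_exponent),
            class = "physics_constants")
}

# electron-fraction weights lambda_i = w_i Z_i / A_i for a composition
electron_weights <- function(comp, db) {
  idx <- match(names(comp$fractions), db$elements$symbol)
  if (anyNA(idx)) {
    bad <- names(comp$fractions)[is.na(idx)]
    stop("material '", comp$name, "': unknown element symbol(s): ",
         paste(bad, collapse = ", "))
  }
  Z <- db$elements$Z[idx]
  A <- db$elements$A_g_mol[idx]
  list(lambda = comp$fractions * Z / A, Z = Z,
       I = db$elements$I_eV[idx])
}

#' Relative electron density of a material
#'
#' Electrons per unit volume relative to water:
#' `rho_e = rho * sum(w_i Z_i / A_i) / (rho_w * sum(w_i Z_i / A_i)_water)`.
#'
#' @param comp a `material` (or material name present in `db`).
#' @param db a `material_db` (supplies the element table and the water
#'   composition used for normalization).
#' @return Dimensionless relative electron density (water = 1).
#' @export
electron_density <- function(comp, db) {
  comp <- as_material(comp, db)
  w <- get_material(db, "water")
  num <- comp$rho * sum(electron_weights(comp, db)$lambda)
  den <- w$rho * sum(electron_weights(w, db)$lambda)
  num / den
}

as_material <- function(comp, db) {
  if (is.character(comp)) get_material(db, comp) else comp
}

#' Effective atomic number of a material
#'
#' Power-law mean `Z_eff = (sum(lambda_i Z_i^p) / sum(lambda_i))^(1/p)` with
#' electron-fraction weights `lambda_i = w_i Z_i / A_i`. A single-element
#' material returns its Z exactly for any exponent.
#'
#' @inheritParams electron_density
#' @param exponent power-law exponent `p` (> 0); 3.3 by default, matching the
#'   exponent of the mass-density model.
#' @return Dimensionless effective atomic number.
#' @export
effective_atomic_number <- function(comp, db, exponent = 3.3) {
  stopifnot(exponent > 0)
  comp <- as_material(comp, db)
  if (!length(comp$fractions)) stop("empty composition")
  ew <- electron_weights(comp, db)
  (sum(ew$lambda * ew$Z^exponent) / sum(ew$lambda))^(1 / exponent)
}

#' Mean excitation energy by Bragg additivity
#'
#' `ln I = sum(lambda_i ln I_i) / sum(lambda_i)` over the constituent
#' elements, with electron-fraction weights. Used for reference-tissue and
#' insert ground truth; note this differs from the 78.73 eV water convention
#' (Bragg additivity on elemental I-values gives ~69 eV for water).
#'
#' @inheritParams electron_density
#' @return Mean excitation energy in eV.
#' @export
i_value_bragg <- function(comp, db) {
  comp <- as_material(comp, db)
  if (!length(comp$fractions)) stop("empty composition")
  ew <- electron_weights(comp, db)
  if (any(!is.finite(ew$I)) || any(ew$I <= 0))
    stop("material '", comp$name, "': missing or non-positive elemental I")
  exp(sum(ew$lambda * log(ew$I)) / sum(ew$lambda))
}

#' Relativistic beta squared at a kinetic energy per nucleon
#'
#' `beta^2 = 1 - (m c^2 / (T + m c^2))^2`.
#'
#' @param T_per_u kinetic energy per nucleon in MeV (> 0).
#' @param m_nucleon_c2 nucleon rest energy in MeV.
#' @return Dimensionless beta squared, strictly in (0, 1).
#' @export
beta_squared <- function(T_per_u, m_nucleon_c2 = 938.272) {
  if (any(T_per_u <= 0)) stop("kinetic energy must be positive")
  1 - (m_nucleon_c2 / (T_per_u + m_nucleon_c2))^2
}

# stopping number ln(2 me c^2 beta^2 / (1 - beta^2)) - ln I - beta^2
stopping_number <- function(i_value, beta2, me_c2) {
  log(2 * me_c2 * beta2 / (1 - beta2)) - log(i_value) - beta2
}

#' Stopping-power ratio from the Bethe equation
#'
#' Ratio of the material's to water's Bethe stopping number, scaled by the
#' relative electron density and with higher-order correction terms (shell,
#' density effect, Barkas) neglected:
#' `SPR = rho_e * L(I) / L(I_w)` with
#' `L(I) = ln(2 me c^2 beta^2 / (1 - beta^2)) - ln I - beta^2`.
#'
#' @param rho_e relative electron density (vectorized).
#' @param i_value mean excitation energy in eV (vectorized).
#' @param constants a [physics_constants()] object (fixes the evaluation
#'   energy, water I-value and nucleon mass).
#' @return Stopping-power ratio, dimensionless; exactly `rho_e` when
#'   `i_value` equals the water I-value.
#' @export
bethe_spr <- function(rho_e, i_value, constants = physics_constants()) {
  if (any(rho_e < 0, na.rm = TRUE)) stop("negative electron density")
  if (any(i_value <= 0, na.rm = TRUE)) stop("non-positive I-value")
  b2 <- beta_squared(constants$T_per_u, constants$m_nucleon_c2)
  Lw <- stopping_number(constants$I_water, b2, constants$me_c2)
  L <- stopping_number(i_value, b2, constants$me_c2)
  if (Lw <= 0 || any(L <= 0, na.rm = TRUE))
    stop("non-positive stopping number: I-value too large for this energy")
  rho_e * L / Lw
}

#' All radiological properties of a material
#'
#' Convenience wrapper computing relative electron density, effective atomic
#' number, Bragg-additivity I-value, Bethe SPR and bulk density in one call.
#'
#' @inheritParams electron_density
#' @param constants a [physics_constants()] object.
#' @return A one-row data.frame with columns `name`, `rho_e`, `z_eff`,
#'   `i_value`, `spr`, `rho`.
#' @export
material_properties <- function(comp, db, constants = physics_constants()) {
  comp <- as_material(comp, db)
  rho_e <- electron_density(comp, db)
  z <- effective_atomic_number(comp, db, constants$zeff_exponent)
  iv <- i_value_bragg(comp, db)
  data.frame(name = comp$name, rho_e = rho_e, z_eff = z, i_value = iv,
             spr = bethe_spr(rho_e, iv, constants), rho = comp$rho,
             stringsAsFactors = FALSE)
}

# properties for a set of material names -> data.frame
material_properties_table <- function(db, names,
                                      constants = physics_constants()) {
  do.call(rbind, lapply(names, function(n)
    material_properties(n, db, constants)))
}

# names of materials in a category
materials_in_category <- function(db, category) {
  nm <- vapply(db$materials, `[[`, "", "name")
  cat_ <- vapply(db$materials, `[[`, "", "category")
  unname(nm[cat_ %in% category])
}
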