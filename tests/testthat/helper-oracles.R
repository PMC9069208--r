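# shared fixtures and independent oracles used across the suite

db_fx <- load_material_tables()
fit_fx <- default_attenuation_fit(db_fx)

# independent trilinear interpolation (plain R, written against the textbook
# formula; deliberately separate from the package internals)
oracle_interp <- function(values, spacing, origin, p) {
  d <- dim(values)
  t <- (p - origin) / spacing
  if (any(t < 0) || any(t > d - 1)) return(NA_real_)
  i0 <- pmin(floor(t), d - 2)
  f <- t - i0
  acc <- 0
  for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
    w <- (if (ci) f[1] else 1 - f[1]) *
         (if (cj) f[2] else 1 - f[2]) *
         (if (ck) f[3] else 1 - f[3])
    acc <- acc + w * values[i0[1] + ci + 1, i0[2] + cj + 1, i0[3] + ck + 1]
  }
  acc
}

# exhaustive gamma search over the full interpolated candidate lattice
oracle_gamma <- function(reference, evaluated, params) {
  rmax <- max(reference$values)
  cutoff <- params$low_dose_cutoff * rmax
  step <- params$interpolation_step
  radius <- params$search_radius_factor * params$dta
  ns <- ceiling(radius / step)
  offs <- as.matrix(expand.grid(dx = (-ns:ns) * step,
                                dy = (-ns:ns) * step,
                                dz = (-ns:ns) * step))
  d2 <- rowSums(offs^2)
  keep <- d2 <= radius^2 + 1e-12
  offs <- offs[keep, , drop = FALSE]; d2 <- d2[keep]
  d <- dim(reference$values)
  g <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    dr <- reference$values[i, j, k]
    if (!(dr >= cutoff)) next
    p0 <- reference$origin + (c(i, j, k) - 1) * reference$spacing
    denom <- params$dose_criterion *
      (if (params$normalization == "local") dr else rmax)
    best <- Inf
    for (q in seq_len(nrow(offs))) {
      de <- oracle_interp(evaluated$values, evaluated$spacing,
                          evaluated$origin, p0 + offs[q, ])
      if (is.na(de)) next
      g2 <- d2[q] / params$dta^2 + ((de - dr) / denom)^2
      if (g2 < best) best <- g2
    }
    if (is.finite(best)) g[i, j, k] <- sqrt(best)
  }
  g
}

# smooth positive random dose field: superposition of a few Gaussian blobs
rand_dose_field <- function(dims = c(5, 5, 5), spacing = c(2, 2, 2),
                            n_blobs = 3) {
  origin <- -(dims - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  vals <- array(0.02, dims)
  for (b in seq_len(n_blobs)) {
    c0 <- stats::runif(3, -3, 3); s <- stats::runif(1, 3, 8)
    amp <- stats::runif(1, 0.4, 1)
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1])) {
        p <- c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
        vals[i, j, k] <- vals[i, j, k] +
          amp * exp(-sum((p - c0)^2) / (2 * s^2))
      }
  }
  ct_volume(vals, spacing, origin, "DOSE_GY")
}

# small single-bore phantom used by several suites (cheap to rasterize)
small_phantom <- function(insert = "true_water", spacing = c(2, 2, 2),
                          body_radius = 3, body_height = 10) {
  geom <- phantom_geometry("mini", body_radius, body_height,
                          data.frame(y = 0, x = 0, radius = 1.4, depth = 7),
                          insert)
  rasterize(geom, spacing = spacing, db = db_fx)
}
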