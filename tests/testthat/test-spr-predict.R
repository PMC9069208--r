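test_that("two-point segments interpolate exactly; flat I gives zero slope", {
  db2 <- db_fx
  db2$materials$pure_si <- material("pure_si", c(Si = 1), 2.33,
                                    "reference_human_tissue")
  db2$materials$pure_p <- material("pure_p", c(P = 1), 1.82,
                                   "reference_human_tissue")
  m <- fit_ivalue_mapping(db2, tissues = c("pure_si", "pure_p"),
                          boundaries = numeric(0), anchor_water = FALSE)
  # Si and P share I = 173 eV: exact interpolation through both points
  # means zero slope and intercept ln(173)
  expect_equal(m$segments$slope[1], 0, tolerance = 1e-12)
  expect_equal(exp(m$segments$intercept[1]), 173, tolerance = 1e-9)
  expect_equal(predict_ivalue(c(14, 15), m), c(173, 173),
               tolerance = 1e-9)

  m2 <- fit_ivalue_mapping(db_fx, tissues = c("ref_adipose", "ref_muscle"),
                           boundaries = numeric(0), anchor_water = FALSE)
  for (nm in c("ref_adipose", "ref_muscle"))
    expect_equal(predict_ivalue(effective_atomic_number(nm, db_fx, 3.3), m2),
                 i_value_bragg(nm, db_fx), tolerance = 1e-9)
  expect_error(fit_ivalue_mapping(db_fx, tissues = c("ref_adipose",
                                                     "ref_muscle")),
               "fewer than 2")
})

test_that("default mapping recovers tissue I-values within 15 percent", {
  m <- fit_ivalue_mapping(db_fx, anchor_water = FALSE)
  rel <- abs(m$fit$i_fitted - m$fit$i_value) / m$fit$i_value
  expect_lt(max(rel), 0.15)
})

test_that("mapping is continuous, clamped, and water-anchored", {
  m <- fit_ivalue_mapping(db_fx)  # anchor ON by default
  zw <- effective_atomic_number("water", db_fx, 3.3)
  expect_equal(predict_ivalue(zw, m), 78.73, tolerance = 1e-10)
  # continuity across the interior boundary at z_eff = 8
  eps <- 1e-9
  expect_equal(predict_ivalue(8 - eps, m), predict_ivalue(8 + eps, m),
               tolerance = 1e-7)
  # clamping outside the calibrated range
  expect_equal(predict_ivalue(m$clamp_range[1] - 2, m),
               predict_ivalue(m$clamp_range[1], m), tolerance = 1e-12)
  expect_equal(predict_ivalue(m$clamp_range[2] + 5, m),
               predict_ivalue(m$clamp_range[2], m), tolerance = 1e-12)
})

test_that("exact mapping passes through its points and rejects ties", {
  z <- c(6.2, 7.4, 9.1, 13.6); iv <- c(64, 69, 74, 96)
  m <- exact_ivalue_mapping(z, iv)
  expect_equal(predict_ivalue(z, m), iv, tolerance = 1e-10)
  expect_error(exact_ivalue_mapping(c(7, 7), c(60, 70)), "distinct")
})

test_that("SPR volume: water identity, ED linearity, grid checks,
           EAN monotonicity", {
  m <- fit_ivalue_mapping(db_fx)
  zw <- effective_atomic_number("water", db_fx, 3.3)
  ed <- ct_volume(array(1, c(4, 4, 4)), c(1, 1, 1), semantic = "ED")
  ean <- ct_volume(array(zw, c(4, 4, 4)), c(1, 1, 1), semantic = "EAN")
  spr <- predict_spr_volume(ed, ean, m)
  expect_identical(spr$semantic, "SPR")
  expect_equal(as.vector(spr$values), rep(1, 64), tolerance = 1e-9)

  ed2 <- ed; ed2$values <- ed$values * 2
  spr2 <- predict_spr_volume(ed2, ean, m)
  expect_equal(spr2$values, 2 * spr$values, tolerance = 1e-12)

  ed_bad <- ct_volume(array(1, c(4, 4, 5)), c(1, 1, 1), semantic = "ED")
  expect_error(predict_spr_volume(ed_bad, ean, m), "grids do not match")
  expect_error(predict_spr_volume(ean, ean, m), "expected semantics")

  # soft-tissue segment: higher EAN -> higher I -> lower SPR at fixed ED
  zs <- seq(6.3, 7.9, length.out = 7)
  sprs <- bethe_spr(1, predict_ivalue(zs, m))
  expect_true(all(diff(sprs) < 0))

  # air voxels get the configured air SPR
  ed3 <- ed; ed3$values[1, 1, 1] <- 0.0011
  spr3 <- predict_spr_volume(ed3, ean, m)
  expect_equal(spr3$values[1, 1, 1], 0.001)
})

test_that("zero-noise phantom round trip recovers ground truth to 1e-6", {
  ph <- rasterize(builtin_geometries()$SC, spacing = c(2, 2, 2),
                  db = db_fx)
  dl <- render_dlct(ph)
  truth <- ph$truth[ph$truth$label >= 1, ]  # body + inserts
  m <- exact_ivalue_mapping(truth$z_eff, truth$i_value)
  spr <- predict_spr_volume(dl$ed, dl$ean, m)
  roi <- extract_roi_means(spr, ph)
  ref <- ph$truth$spr[match(roi$material, ph$truth$material)]
  expect_equal(roi$mean, ref, tolerance = 1e-9)
  expect_true(all(roi$sd < 1e-12))
})

test_that("DEEDZ fit: exact inverse problem, null signal, water behavior", {
  # synthetic calibration set generated from known coefficients
  e_true <- c(0.012, 0.025, 0.004)
  zw <- effective_atomic_number("water", db_fx, 3.3)
  z <- seq(6.0, 13.8, length.out = 12)
  x <- (z / zw)^3.3 - 1
  rho_e <- seq(0.9, 1.8, length.out = 12)
  rho <- rho_e * (1 + e_true[1] + e_true[2] * x + e_true[3] * x^2)
  f <- fit_deedz(props = data.frame(name = paste0("s", 1:12),
                                    z_eff = z, rho_e = rho_e, rho = rho),
                 m = 3.3, db = db_fx)
  expect_equal(f$e, e_true, tolerance = 1e-8)

  # rho = rho_e exactly -> all coefficients vanish
  f0 <- fit_deedz(props = data.frame(name = paste0("n", 1:12),
                                     z_eff = z, rho_e = rho_e,
                                     rho = rho_e),
                  m = 3.3, db = db_fx)
  expect_equal(f0$e, c(0, 0, 0), tolerance = 1e-10)

  # packaged tissue fit: |e0| small (water-like tissues have rho ~ rho_e)
  fp <- fit_deedz(db_fx)
  expect_lt(abs(fp$e[1]), 0.05)
  expect_error(fit_deedz(db_fx, tissues = c("ref_water", "ref_muscle")),
               "at least 3")
})

test_that("mass-density volume: identity coefficients and exact recovery", {
  zw <- effective_atomic_number("water", db_fx, 3.3)
  ed <- ct_volume(array(runif(64, 0.9, 1.6), c(4, 4, 4)), c(1, 1, 1),
                  semantic = "ED")
  ean <- ct_volume(array(runif(64, 6, 13), c(4, 4, 4)), c(1, 1, 1),
                   semantic = "EAN")
  ident <- structure(list(e = c(0, 0, 0), m = 3.3, z_eff_w = zw),
                     class = "deedz_fit")
  rho <- mass_density_volume(ed, ean, ident)
  expect_identical(rho$semantic, "MASS_DENSITY")
  expect_equal(rho$values, ed$values, tolerance = 1e-12)

  # volumes generated from known coefficients are recovered voxelwise
  e_true <- c(0.012, 0.025, 0.004)
  x <- (ean$values / zw)^3.3 - 1
  rho_true <- ed$values * (1 + e_true[1] + e_true[2] * x +
                             e_true[3] * x^2)
  gen <- structure(list(e = e_true, m = 3.3, z_eff_w = zw),
                   class = "deedz_fit")
  expect_equal(mass_density_volume(ed, ean, gen)$values, rho_true,
               tolerance = 1e-12)
})

test_that("calibration objects round-trip through JSON", {
  m <- fit_ivalue_mapping(db_fx)
  p1 <- tempfile(fileext = ".json")
  write_calibration(m, p1)
  m2 <- read_calibration(p1)
  zs <- seq(6, 14, by = 0.25)
  expect_equal(predict_ivalue(zs, m2), predict_ivalue(zs, m),
               tolerance = 1e-12)

  f <- fit_deedz(db_fx)
  p2 <- tempfile(fileext = ".json")
  write_calibration(f, p2)
  f2 <- read_calibration(p2)
  expect_equal(f2$e, f$e, tolerance = 1e-12)
  expect_equal(f2$z_eff_w, f$z_eff_w, tolerance = 1e-12)
  p3 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), p3)
  expect_error(read_calibration(p3), "schema")
})
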