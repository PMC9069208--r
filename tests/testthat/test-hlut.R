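test_that("forward CT-number model: water, air, Compton limit", {
  expect_equal(theoretical_ctn("water", fit_fx, db_fx), 0,
               tolerance = 1e-10)
  expect_equal(theoretical_ctn("air", fit_fx, db_fx), -1000,
               tolerance = 1.5)
  # k1 = k2 = 0 collapses to the pure Compton closed form
  f0 <- attenuation_fit(0, 0, db_fx)
  for (nm in c("muscle", "cortical_bone", "adipose")) {
    expect_equal(theoretical_ctn(nm, f0, db_fx),
                 1000 * (electron_density(nm, db_fx) - 1),
                 tolerance = 1e-9)
  }
})

test_that("attenuation fit recovers generating weights exactly", {
  surr <- materials_in_category(db_fx, "tissue_surrogate")
  ctn <- vapply(surr, function(n) theoretical_ctn(n, fit_fx, db_fx), 0)
  f <- fit_attenuation(as.list(surr), ctn, db_fx)
  expect_equal(f$k1, fit_fx$k1, tolerance = 1e-8)
  expect_equal(f$k2, fit_fx$k2, tolerance = 1e-8)
  # water-only calibration is degenerate
  expect_error(fit_attenuation(list("water", "true_water"), c(0, 0),
                               db_fx), "degenerate")
})

test_that("noisy calibration: k1 recovered within 10%, model CTNs stable", {
  surr <- materials_in_category(db_fx, "tissue_surrogate")
  ctn0 <- vapply(surr, function(n) theoretical_ctn(n, fit_fx, db_fx), 0)
  set.seed(301)
  res <- replicate(40, {
    f <- suppressWarnings(
      fit_attenuation(as.list(surr), ctn0 + stats::rnorm(13, 0, 5),
                      db_fx))
    refit <- vapply(surr, function(n) theoretical_ctn(n, f, db_fx), 0)
    c(k1_rel = abs(f$k1 - fit_fx$k1) / fit_fx$k1,
      ctn_rms = sqrt(mean((refit - ctn0)^2)))
  })
  expect_lt(stats::median(res["k1_rel", ]), 0.10)
  # the refitted forward model stays within the noise floor in HU terms
  expect_lt(stats::median(res["ctn_rms", ]), 5)
})

test_that("HLUT: monotone nodes, self-evaluation, CSV round trip", {
  h <- build_hlut(fit_fx, db_fx)
  expect_true(all(diff(h$nodes$ctn) > 0))
  expect_true(all(diff(h$nodes$spr) > -1e-9))
  expect_true(all(h$nodes$spr >= 0))
  # evaluating at each reference tissue's CTN reproduces the stored
  # fit residuals
  ev <- predict(h, h$tissue_fit$ctn)
  expect_equal((ev - h$tissue_fit$spr_true) / h$tissue_fit$spr_true * 100,
               h$tissue_fit$residual_pct, tolerance = 1e-10)

  path <- tempfile(fileext = ".csv")
  write_hlut(h, path)
  h2 <- read_hlut(path)
  expect_equal(h2$nodes$ctn, h$nodes$ctn)
  expect_equal(predict(h2, c(-500, -80, 0, 40, 700)),
               predict(h, c(-500, -80, 0, 40, 700)), tolerance = 1e-9)
})

test_that("tissues on a line within each segment are interpolated exactly", {
  # craft materials whose (CTN, SPR) points are collinear per segment by
  # scaling water's density: CTN and SPR are then both linear in rho
  db2 <- db_fx
  for (s in c(0.95, 1.0, 1.05)) {
    nm <- sprintf("wl_%d", round(s * 100))
    m <- db_fx$materials$water
    m$name <- nm; m$rho <- s; m$category <- "reference_human_tissue"
    db2$materials[[nm]] <- m
  }
  h <- build_hlut(fit_fx, db2, tissues = c("wl_95", "wl_100", "wl_105"),
                  segments = data.frame(label = c("air", "soft"),
                                        lo = c(-Inf, -120),
                                        hi = c(-120, Inf)))
  expect_lt(max(abs(h$tissue_fit$residual_pct)), 1e-8)
})

test_that("CTN volume conversion: water anchor, clamping, semantics", {
  # hand-built water-anchored HLUT through (0 HU, SPR 1)
  h <- structure(list(nodes = data.frame(
    ctn = c(-1000, -120, 0, 100, 1500),
    spr = c(0.001, 0.88, 1.0, 1.07, 1.71))), class = "hlut")
  vol0 <- ct_volume(array(0, c(3, 3, 3)), c(1, 1, 1), semantic = "HU")
  spr <- convert_ctn_volume(vol0, h)
  expect_identical(spr$semantic, "SPR")
  expect_equal(as.vector(spr$values), rep(1, 27), tolerance = 1e-12)
  # flat extrapolation below the first and above the last node
  vlo <- ct_volume(array(-4000, c(2, 2, 2)), c(1, 1, 1), semantic = "HU")
  expect_equal(unique(as.vector(convert_ctn_volume(vlo, h)$values)),
               0.001)
  vhi <- ct_volume(array(9000, c(2, 2, 2)), c(1, 1, 1), semantic = "HU")
  expect_equal(unique(as.vector(convert_ctn_volume(vhi, h)$values)), 1.71)
  expect_error(convert_ctn_volume(
    ct_volume(array(1, c(2, 2, 2)), c(1, 1, 1), semantic = "ED"), h),
    "HU")
})

test_that("closed-loop SECT residuals equal the HLUT fit residuals", {
  ph <- rasterize(builtin_geometries()$SC, spacing = c(2, 2, 2),
                  db = db_fx)
  hu <- render_sect(ph, fit_fx)
  ins <- ph$truth$material[!is.na(ph$truth$bore)]
  h <- suppressWarnings(build_hlut(fit_fx, db_fx, tissues = ins))
  roi <- extract_roi_means(convert_ctn_volume(hu, h), ph)
  truth <- ph$truth$spr[match(roi$material, ph$truth$material)]
  got <- (roi$mean - truth) / truth * 100
  stored <- h$tissue_fit$residual_pct[match(roi$material,
                                            h$tissue_fit$name)]
  expect_equal(got, stored, tolerance = 1e-8)
})

test_that("a CTN-degenerate pair defeats SECT but not DLCT", {
  pair <- make_ctn_degenerate_pair(fit_fx, db_fx)
  expect_equal(theoretical_ctn(pair$a, fit_fx, db_fx),
               theoretical_ctn(pair$b, fit_fx, db_fx), tolerance = 1e-6)
  pa <- material_properties(pair$a, db_fx)
  pb <- material_properties(pair$b, db_fx)
  # the two materials genuinely differ in the DLCT observables
  expect_gt(abs(pa$z_eff - pb$z_eff), 1)
  h <- build_hlut(fit_fx, db_fx)
  sect_a <- predict(h, pair$ctn); sect_b <- predict(h, pair$ctn)
  m <- fit_ivalue_mapping(db_fx, anchor_water = FALSE)
  dlct_a <- bethe_spr(pa$rho_e, predict_ivalue(pa$z_eff, m))
  dlct_b <- bethe_spr(pb$rho_e, predict_ivalue(pb$z_eff, m))
  expect_gt(abs(dlct_a - dlct_b), 10 * abs(sect_a - sect_b))
  # and the DLCT route tracks both true SPRs closely
  expect_lt(abs(dlct_a - pa$spr) / pa$spr, 0.02)
  expect_lt(abs(dlct_b - pb$spr) / pb$spr, 0.02)
})
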