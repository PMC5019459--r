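test_that("body frames reproduce the printed total heights exactly", {
  expect_equal(build_body(body_frame("TRM"))$total_height_cm, 168.7)
  expect_equal(build_body(body_frame("TRW"))$total_height_cm, 156.2)
  expect_equal(build_body(body_frame("ORNL"))$total_height_cm, 178.6)
  expect_error(body_frame("XXX"), "unknown")
  expect_error(body_frame(list(A_H = -1, B_H = 1, C_H = 1, A_T = 1, B_T = 1,
                               C_T = 1, C_L = 1)), "positive")
})

test_that("body segments are disjoint and stack to the full height", {
  body <- build_body(body_frame("TRM"))
  set.seed(501)
  pts <- cbind(runif(5000, -20, 20), runif(5000, -10, 10), runif(5000, -80, 95))
  inh <- region_contains(body$head, pts)
  int <- region_contains(body$trunk, pts)
  inl <- region_contains(body$legs, pts)
  expect_equal(sum(inh & int) + sum(int & inl) + sum(inh & inl), 0)
})

test_that("assembled phantoms carry the sex-specific organ sets", {
  trm <- test_phantom("TRM"); trw <- test_phantom("TRW"); ornl <- test_phantom("ORNL")
  expect_true("Testes" %in% trm$organs$organ)
  expect_false(any(c("Uterus", "Ovaries", "Breasts") %in% trm$organs$organ))
  expect_true(all(c("Uterus", "Ovaries", "Breasts") %in% trw$organs$organ))
  expect_false("Testes" %in% trw$organs$organ)
  expect_true(all(c("Testes", "Uterus", "Ovaries") %in% ornl$organs$organ))
  expect_error(assemble_phantom("Nope"), "unknown")
})

test_that("organ masses are the product of reference volume and density", {
  trm <- test_phantom("TRM")
  mt <- organ_mass_table(trm)
  expect_equal(mt$mass_kg, mt$volume_cm3 * mt$density_g_cm3 / 1000)
  expect_equal(mt$mass_kg[mt$organ == "Kidneys"], 0.33075)
  expect_equal(mt$mass_kg[mt$organ == "Liver"], 1.4045)
  expect_equal(mt$volume_cm3[mt$organ == "Stomach wall"], 74.2)
  trw <- test_phantom("TRW")
  expect_equal(organ_mass_table(trw)$volume_cm3[
    organ_mass_table(trw)$organ == "Ovaries"], 11.2)
  # gall bladder differs from the baseline adult phantom by more than +50%
  ornl <- test_phantom("ORNL")
  gb <- function(p) organ_mass_table(p)$mass_kg[organ_mass_table(p)$organ == "Gall bladder"]
  expect_gt(gb(trm) / gb(ornl) - 1, 0.5)
})

test_that("calibrated organ volumes match their targets", {
  # constructive: the stored volume is the target by calibration
  for (nm in c("TRM", "TRW", "ORNL")) {
    ph <- test_phantom(nm)
    tg <- organ_volume_targets(nm)
    got <- ph$organs$volume_cm3[match(tg$organ, ph$organs$organ)]
    expect_equal(got, tg$volume_cm3, tolerance = 2e-3)
  }
  # independent Monte Carlo verification on a representative subset
  trm <- test_phantom("TRM")
  for (org in c("Pancreas", "Spleen", "Kidneys", "Lungs")) {
    v <- mc_volume(trm$regions[[org]], n = 4e5, seed = 515)
    tgt <- trm$organs$volume_cm3[match(org, trm$organs$organ)]
    expect_lt(abs(v$volume - tgt), 4 * v$stderr + 0.004 * tgt)
  }
})

test_that("lateral calibration preserves the x:y semi-axis ratio and is idempotent", {
  tpl <- list(parts = list(list(anchor = c(0, 0, 10), shape = ellipsoid(3, 1.5, 2))))
  cal <- scale_and_calibrate(tpl, z_ratio = 0.9, target_volume = 20)
  # closed form for an ellipsoid: s = sqrt(V / (4/3 pi a b c r))
  s_expect <- sqrt(20 / (4 / 3 * pi * 3 * 1.5 * 2 * 0.9))
  expect_equal(cal$s, s_expect, tolerance = 1e-9)
  v <- mc_volume(cal$region, n = 2e5, seed = 2)
  expect_lt(abs(v$volume - 20), 4 * v$stderr)
  # identity: z_ratio 1 and target equal to the baseline volume leave s = 1
  v0 <- 4 / 3 * pi * 3 * 1.5 * 2
  cal1 <- scale_and_calibrate(tpl, 1, v0)
  expect_equal(cal1$s, 1, tolerance = 1e-9)
  # idempotence: recalibrating a calibrated organ moves s by < 1e-3
  tpl2 <- list(parts = list(list(anchor = c(0, 0, 9), shape = cal$region)))
  cal2 <- scale_and_calibrate(tpl2, 1, 20)
  expect_lt(abs(cal2$s - 1), 1e-3)
})

test_that("every organ lies inside the body envelope and classification is exclusive", {
  for (nm in c("TRM", "TRW")) {
    ph <- test_phantom(nm)
    chk <- validate_phantom(ph, n = 4000, seed = 52)
    expect_true(all(chk$pass), info = nm)
  }
})

test_that("point classification respects precedence and returns single labels", {
  trm <- test_phantom("TRM")
  pts <- sample_in_organ(trm, "Liver", 2000, seed = 53)
  lab <- classify_points(trm, pts)
  expect_true(all(lab %in% c(trm$organs$organ, "Residual tissue")))
  expect_gt(mean(lab == "Liver"), 0.98)
  # a point far outside is vacuum
  expect_true(is.na(classify_points(trm, c(100, 100, 100))))
  # wall sampling never lands in the content
  pts <- sample_in_organ(trm, "Stomach wall", 1500, seed = 54)
  expect_false(any(classify_points(trm, pts) == "Stomach content"))
})

test_that("phantom serialization writes a lossless organ config", {
  trm <- test_phantom("TRM")
  tmp <- tempfile(fileext = ".yaml")
  write_phantom_config(trm, tmp)
  cfg <- yaml::read_yaml(tmp)
  expect_equal(length(cfg$regions), nrow(trm$organs))
  liver <- region_from_list(cfg$regions$Liver)
  pts <- sample_in_organ(trm, "Liver", 500, seed = 55)
  expect_true(all(region_contains(liver, pts)))
})
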