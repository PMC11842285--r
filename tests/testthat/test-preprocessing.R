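test_that("the S/N filter masks values at or below the threshold, strictly", {
  x <- matrix(c(100, 200, 300), 1, 3)
  s <- matrix(c(9, 10, 1000), 1, 3)
  fe <- toy_table(intensity = cbind(x, 400), snr = cbind(s, 11))
  out <- filterSNR(fe, 10)
  expect_true(is.na(intensities(out)[1, 1]))   # snr 9 -> masked
  expect_true(is.na(intensities(out)[1, 2]))   # snr 10 -> masked (> is strict)
  expect_equal(intensities(out)[1, 3], 300)    # snr 1000 untouched
  expect_equal(intensities(out)[1, 4], 400)    # snr 11 kept
  # table with uniformly high S/N is unchanged
  hi <- toy_table()
  expect_equal(intensities(filterSNR(hi, 10)), intensities(hi))
})

test_that("IDMS ratios divide unlabeled by labeled areas and flag invalids", {
  intensity <- matrix(c(1000, NA, 500), 1, 3)
  labeled <- matrix(c(2000, 1500, NA), 1, 3)
  snr <- matrix(100, 1, 3); snr[is.na(intensity)] <- NA
  fe <- FootprintExperiment(intensity, snr,
    data.frame(role = "standard", injection_order = 1:3, batch = "B1",
               class_label = NA, bio_rep = 1, tech_rep = 1:3, dilution = 1),
    labeled = labeled)
  out <- idmsRatio(fe)
  r <- SummarizedExperiment::assay(out, "ratio")
  ok <- SummarizedExperiment::assay(out, "ratio_valid")
  expect_equal(r[1, 1], 0.5)
  expect_true(is.na(r[1, 2]) && ok[1, 2])   # unlabeled missing -> NA, valid
  expect_true(is.na(r[1, 3]) && !ok[1, 3])  # labeled missing -> invalid
  expect_error(idmsRatio(toy_table()), "labeled")
})

test_that("calibration fits recover the response line", {
  plate <- generateCalibrationPlate(slope = 0.1, intercept = 0, noise_sd = 0)
  curve <- fitCalibration(plate)
  expect_equal(curve@slope, 0.1)
  expect_equal(curve@intercept, 0, tolerance = 1e-12)
  expect_equal(curve@r_squared, 1)
  expect_equal(curve@range, c(0.01, 16))

  # noisy line: slope within 3 standard errors of truth
  plate_n <- generateCalibrationPlate(slope = 0.1, intercept = 0.01,
                                      noise_sd = 0.05, seed = 12)
  curve_n <- fitCalibration(plate_n)
  se <- summary(lm(ratio ~ concentration, plate_n))$coefficients[2, 2]
  expect_lt(abs(curve_n@slope - 0.1), 3 * se)

  expect_error(fitCalibration(data.frame(concentration = c(1, 2),
                                         ratio = c(0.1, 0.2))),
               "3 distinct")
  expect_error(fitCalibration(data.frame(concentration = c(1, 1, 1),
                                         ratio = c(0.1, 0.2, 0.3))),
               "3 distinct")
})

test_that("quantification inverts the curve and applies the dilution", {
  curve <- fitCalibration(data.frame(concentration = c(1, 5, 10),
                                     ratio = c(0.1, 0.5, 1.0)))
  out <- quantifyConcentrations(0.5, curve, dilution = 2)
  expect_equal(out$concentration, 10)
  expect_false(out$out_of_range)
  # ratio above the calibrated top is flagged but still returned
  top <- quantifyConcentrations(1.5, curve)
  expect_equal(top$concentration, 15)
  expect_true(top$out_of_range)
  # ratio equal to the intercept maps to 0 uM
  expect_equal(quantifyConcentrations(curve@intercept, curve)$concentration,
               0)
  zero <- new("CalibrationCurve", slope = 0, intercept = 0, r_squared = 1,
              range = c(1, 10), n_standards = 3L, feature_id = "f")
  expect_error(quantifyConcentrations(0.5, zero), "slope")
})

test_that("constant QC signal yields an identity correction", {
  x <- matrix(c(100, 50, 100, 70, 100, 60, 100), 1, 7)
  fe <- qc_table(x, qc_cols = c(1, 3, 5, 7))
  m <- fitDriftModel(fe)
  info <- driftInfo(m)
  expect_true(all(info$correctable))
  expect_equal(info$reference, 100)
  out <- applyDriftCorrection(fe, m)
  expect_equal(intensities(out), intensities(fe))
})

test_that("noiseless linear drift is corrected to machine precision", {
  orders <- 1:13
  qc_cols <- c(1, 4, 7, 10, 13)
  drift <- 100 + (orders - 1) / 12 * 100          # 100 -> 200 across run
  x <- rbind(drift, 5 * drift)
  rownames(x) <- c("f1", "f2")
  fe <- qc_table(x, qc_cols = qc_cols, orders = orders)
  m <- fitDriftModel(fe)
  # spline reproduces the line at QC positions
  for (key in names(m@fits)) {
    ft <- m@fits[[key]]
    base <- if (grepl("f1", key)) 1 else 5
    expect_equal(ft$spline(qc_cols), base * drift[qc_cols],
                 tolerance = 1e-6)
  }
  out <- applyDriftCorrection(fe, m)
  rsd <- qcRSD(out)
  expect_lt(max(rsd), 1e-6)
  # all corrected samples sit at the reference level too
  expect_equal(unname(intensities(out)[1, ]),
               rep(driftInfo(m)$reference[1], 13), tolerance = 1e-6)
})

test_that("correction improves QC precision under noisy sinusoidal drift", {
  spec <- SimulationSpec(n_features = 40, n_classes = 2, sigma = 0.1,
                         drift = "sinusoidal", drift_amplitude = 0.2,
                         qc_every_k = 6, seed = 101)
  fe <- generateRun(spec)
  m <- fitDriftModel(fe)
  out <- applyDriftCorrection(fe, m)
  raw_rsd <- qcRSD(fe)
  cor_rsd <- qcRSD(out)
  expect_gte(mean(cor_rsd < raw_rsd), 0.95)
  # LOO-CV picked spans that actually help on the median feature
  expect_lt(median(cor_rsd), median(raw_rsd))
})

test_that("drift correction is idempotent", {
  spec <- SimulationSpec(n_features = 10, n_classes = 2, sigma = 0.05,
                         drift = "linear", drift_amplitude = 0.3,
                         qc_every_k = 5, seed = 55)
  fe <- generateRun(spec)
  once <- applyDriftCorrection(fe, fitDriftModel(fe))
  m2 <- fitDriftModel(once)
  twice <- applyDriftCorrection(once, m2)
  # refit correction factors are ~1: second pass changes values marginally
  rel <- abs(intensities(twice) / intensities(once) - 1)
  expect_lt(max(rel, na.rm = TRUE), 0.05)
})

test_that("features with too few QCs pass through with a warning", {
  x <- matrix(c(100, 50, 110, 70, 120), 1, 5)
  fe <- qc_table(x, qc_cols = c(1, 3, 5))   # only 3 QCs
  expect_warning(m <- fitDriftModel(fe), "uncorrectable")
  expect_false(driftInfo(m)$correctable)
  out <- applyDriftCorrection(fe, m)
  expect_equal(intensities(out), intensities(fe))
})

test_that("correction preserves sample order at equal injection positions", {
  # identical QC drift in two batches; samples at the same position keep
  # their relative order after correction
  orders <- 1:9
  qc_cols <- c(1, 3, 5, 7, 9)
  drift <- 100 * (1 + 0.1 * orders)
  mk <- function(batch, samp_scale) {
    x <- matrix(drift, 1, 9)
    x[1, -qc_cols] <- samp_scale * drift[-qc_cols]
    qc_table(x, qc_cols = qc_cols, orders = orders, batch = batch)
  }
  fe1 <- mk("B1", 0.5)
  fe2 <- mk("B2", 0.8)
  cmb <- BiocGenerics::cbind(fe1, fe2)
  fe <- as(cmb, "FootprintExperiment")
  m <- fitDriftModel(fe)
  out <- applyDriftCorrection(fe, m)
  pos <- injectionOrder(fe)[!isQC(fe)]
  b <- analyticalBatch(fe)[!isQC(fe)]
  raw <- intensities(fe)[1, !isQC(fe)]
  corr <- intensities(out)[1, !isQC(fe)]
  for (p in unique(pos)) {
    at_p <- pos == p
    expect_equal(order(raw[at_p]), order(corr[at_p]))
  }
})

test_that("thresholding drops exactly the features failing the QC rules", {
  n_qc <- 10
  qc_cols <- seq_len(n_qc)
  # f_rsd: RSD > 20%; f_miss: 40% missing; f_good: tight and complete
  f_rsd <- c(100, 100, 100, 100, 150, 150, 150, 150, 100, 150) * 2
  f_miss <- c(100, 101, 99, 100, 102, 98, NA, NA, NA, NA)
  f_good <- c(100, 101, 99, 100, 102, 98, 100, 101, 99, 100)
  x <- rbind(f_rsd = f_rsd, f_miss = f_miss, f_good = f_good)
  x <- cbind(x, matrix(100, 3, 2))   # two trailing samples
  fe <- qc_table(x, qc_cols = qc_cols, orders = seq_len(ncol(x)))
  th <- thresholdFeatures(fe)
  rep <- th$report
  expect_equal(rep$reason[rep$feature_id == "f_rsd"], "rsd")
  expect_equal(rep$reason[rep$feature_id == "f_miss"], "missing")
  expect_true(rep$kept[rep$feature_id == "f_good"])
  expect_equal(rownames(th$table), "f_good")
  # the report partitions the features, and kept <=> both rules pass
  expect_setequal(rep$feature_id, rownames(fe))
  expect_equal(rep$kept, rep$reason == "")
  expect_equal(rep$kept,
               rep$qc_rsd < 0.20 & rep$qc_missing < 0.30 & rep$n_qc_obs >= 4)
})

test_that("features with under 4 QC observations are dropped at thresholding", {
  x <- rbind(f_few = c(100, NA, 99, NA, NA, NA, NA, NA, 101, 100, 100),
             f_ok = c(rep(100, 8), NA, 100, 100))
  fe <- qc_table(x, qc_cols = 1:9)
  th <- thresholdFeatures(fe)
  expect_equal(th$report$reason[1], "too_few_qc")
  expect_false(th$report$kept[1])
  expect_true(th$report$kept[2])
})

test_that("imputation applies half-minimum for MNAR and class means for MAR", {
  # classes: A A A | B B B (samples); f_mar misses one A cell (MAR),
  # f_mnar misses the whole B class (MNAR)
  x <- rbind(f_mar = c(10, 14, NA, 30, 31, 32),
             f_mnar = c(4, 6, 5, NA, NA, NA),
             f_full = c(1, 2, 3, 4, 5, 6))
  snr <- matrix(100, 3, 6); snr[is.na(x)] <- NA
  fe <- FootprintExperiment(x, snr,
    data.frame(role = "sample", injection_order = 1:6, batch = "B1",
               class_label = rep(c("A", "B"), each = 3), bio_rep = 1,
               tech_rep = 1:6, dilution = 1))
  out <- imputeMissing(fe)
  xi <- intensities(out)
  expect_equal(xi["f_mar", 3], 12)          # mean of within-class {10, 14}
  expect_equal(unname(xi["f_mnar", 4:6]), rep(2, 3))  # half of min {4,5,6}/2
  # observed entries bit-identical, nothing missing afterwards
  expect_identical(xi[!is.na(x)], x[!is.na(x)])
  expect_false(anyNA(xi))
  log <- S4Vectors::metadata(out)$imputation
  expect_setequal(log$mechanism[log$feature_id == "f_mnar"], "mnar")
  expect_setequal(log$mechanism[log$feature_id == "f_mar"], "mar")
  # table without missing cells is returned unchanged
  full <- toy_table()
  expect_identical(intensities(imputeMissing(full)), intensities(full))
})

test_that("imputation refuses features with no observed values", {
  x <- rbind(f1 = c(NA, NA, NA, NA), f2 = c(1, 2, 3, 4))
  snr <- matrix(100, 2, 4); snr[is.na(x)] <- NA
  fe <- FootprintExperiment(x, snr,
    data.frame(role = "sample", injection_order = 1:4, batch = "B1",
               class_label = rep(c("A", "B"), 2), bio_rep = 1,
               tech_rep = 1:4, dilution = 1))
  expect_error(imputeMissing(fe), "zero observed")
})

test_that("correction factors converge to the true drift with QC density", {
  mad_at_density <- function(k) {
    spec <- SimulationSpec(n_features = 15, n_classes = 2, sigma = 0.05,
                           drift = "sinusoidal", drift_amplitude = 0.25,
                           qc_every_k = k, seed = 33)
    fe <- generateRun(spec)
    g <- S4Vectors::metadata(fe)$true_drift
    m <- fitDriftModel(fe)
    io <- injectionOrder(fe)
    errs <- vapply(names(m@fits), function(key) {
      ft <- m@fits[[key]]
      if (!isTRUE(ft$correctable)) return(NA_real_)
      est <- ft$reference / ft$spline(io)          # estimated factor
      tru <- median(g(ft$qc_orders)) / g(io)       # true factor
      mean(abs(est - tru))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  expect_lt(mad_at_density(4), mad_at_density(12))
})
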