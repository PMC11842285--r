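#' @importFrom stats loess loess.control predict splinefun median sd lm coef
NULL

#' Mask low signal-to-noise measurements
#'
#' Measurements whose signal-to-noise value does not exceed the threshold
#' are set to missing. The comparison is strict (`snr > threshold` is kept),
#' so with the default threshold of 10 a measurement at exactly S/N = 10 is
#' removed.
#'
#' @param fe a [FootprintExperiment-class].
#' @param threshold signal-to-noise cut (default 10).
#' @return the table with sub-threshold intensities set to `NA`.
#' @export
filterSNR <- function(fe, threshold = 10) {
  x <- intensities(fe)
  s <- snrValues(fe)
  mask <- !is.na(x) & !(s > threshold)
  x[mask] <- NA_real_
  s[mask] <- NA_real_
  assays(fe)$intensity <- x
  assays(fe)$snr <- s
  fe
}

#' @importFrom SummarizedExperiment assays<- assays
NULL

#' Isotope-dilution area ratios
#'
#' Normalizes unlabeled analyte areas by the areas of the uniformly
#' 13C15N-labelled internal standard, yielding the 12C14N/13C15N ratio per
#' measurement. Measurements with an observed unlabeled area but a missing
#' or zero labelled area cannot be ratio-normalized; they are flagged
#' invalid (assay `ratio_valid` FALSE) and their ratio is `NA`. A missing
#' unlabeled area gives a missing ratio, not 0.
#'
#' @param fe a [FootprintExperiment-class] with a `labeled` assay.
#' @return `fe` with added assays `ratio` and `ratio_valid`.
#' @export
idmsRatio <- function(fe) {
  lab <- labeledAreas(fe)
  if (is.null(lab)) stop("no 'labeled' assay: IDMS ratios need labelled areas")
  x <- intensities(fe)
  invalid <- !is.na(x) & (is.na(lab) | lab == 0)
  ratio <- x / lab
  ratio[invalid] <- NA_real_
  assays(fe)$ratio <- ratio
  assays(fe)$ratio_valid <- !invalid
  fe
}

# ---------------------------------------------------------------------------

#' Linear IDMS calibration curve
#'
#' Ordinary-least-squares regression of the 12C14N/13C15N area ratio on the
#' known standard concentration, with its validity range.
#'
#' @aliases CalibrationCurve-class
#' @export
setClass("CalibrationCurve", representation(
  slope = "numeric", intercept = "numeric", r_squared = "numeric",
  range = "numeric", n_standards = "integer", feature_id = "character"))

setValidity("CalibrationCurve", function(object) {
  if (object@range[1] >= object@range[2]) return("range lower >= upper")
  if (object@n_standards < 3) return("fit needs >= 3 standards")
  TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s]: ratio = %.6g * conc %+.6g, R2 = %.4f, range [%g, %g] uM (n = %d)\n",
    object@feature_id, object@slope, object@intercept, object@r_squared,
    object@range[1], object@range[2], object@n_standards))
})

#' Fit an IDMS calibration curve
#'
#' @param standards data.frame with columns `concentration` (uM) and
#'   `ratio` (unlabeled/labelled area ratio); rows with missing ratios are
#'   dropped.
#' @param feature_id identifier recorded on the curve.
#' @return a [CalibrationCurve-class]; the calibrated range is the span of
#'   the standard concentrations. At least 3 distinct concentrations are
#'   required.
#' @export
fitCalibration <- function(standards, feature_id = "analyte") {
  stopifnot(all(c("concentration", "ratio") %in% colnames(standards)))
  ok <- stats::complete.cases(standards[c("concentration", "ratio")])
  standards <- standards[ok, ]
  if (length(unique(standards$concentration)) < 3)
    stop("calibration needs >= 3 distinct standard concentrations")
  fit <- lm(ratio ~ concentration, data = standards)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new("CalibrationCurve", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), r_squared = r2,
      range = range(standards$concentration),
      n_standards = nrow(standards), feature_id = feature_id)
}

#' Quantify sample concentrations from a calibration curve
#'
#' Inverts the calibration line and corrects for the sample dilution:
#' `conc = dilution * (ratio - intercept) / slope`. Back-calculated
#' (pre-dilution) ratios outside the calibrated concentration range are
#' returned but flagged out-of-range.
#'
#' @param ratios numeric vector of measured area ratios (`NA` allowed).
#' @param curve a [CalibrationCurve-class].
#' @param dilution per-sample dilution factor(s) (> 0), recycled.
#' @return data.frame with `ratio`, `dilution`, `concentration` (uM) and
#'   logical `out_of_range`.
#' @export
quantifyConcentrations <- function(ratios, curve, dilution = 1) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (curve@slope == 0) stop("calibration slope is zero")
  dilution <- rep_len(dilution, length(ratios))
  if (any(dilution <= 0)) stop("dilution must be > 0")
  conc_at_instrument <- (ratios - curve@intercept) / curve@slope
  data.frame(ratio = ratios, dilution = dilution,
             concentration = dilution * conc_at_instrument,
             out_of_range = !is.na(ratios) &
               (conc_at_instrument < curve@range[1] |
                conc_at_instrument > curve@range[2]))
}

# ---------------------------------------------------------------------------

#' Per-feature QC-anchored signal-drift model
#'
#' For each feature and analytical batch, a locally weighted linear (LOESS,
#' degree 1) smoother is fitted to the pooled-QC intensities against
#' injection order; the smoothing span is chosen from a fixed candidate
#' grid by leave-one-out cross-validation, and a natural cubic spline
#' through the smoother's fitted QC values provides the correction function
#' over the whole injection-order range. The reference level is the median
#' of the fitted QC values.
#'
#' @aliases DriftModel-class
#' @export
setClass("DriftModel", representation(fits = "list", info = "data.frame",
                                      spans = "numeric"))

setMethod("show", "DriftModel", function(object) {
  cat(sprintf("DriftModel: %d feature-batch fit(s), %d uncorrectable\n",
              nrow(object@info), sum(!object@info$correctable)))
  if (nrow(object@info))
    cat(sprintf("span grid {%s}; chosen spans: %s\n",
                paste(object@spans, collapse = ", "),
                paste(names(table(object@info$span)), collapse = ", ")))
})

#' @describeIn fitDriftModel per-fit summary table (feature, batch, span,
#'   reference level, LOO-CV error, correctable flag).
#' @param model a `DriftModel`.
#' @export
driftInfo <- function(model) model@info

.looCvError <- function(x, y, span) {
  err <- 0
  for (i in seq_along(x)) {
    fit <- tryCatch(
      suppressWarnings(loess(y[-i] ~ x[-i], span = span, degree = 1,
                             control = loess.control(surface = "direct"),
                             family = "gaussian")),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pred <- tryCatch(suppressWarnings(predict(fit, x[i])),
                     error = function(e) NA_real_)
    if (is.na(pred)) return(Inf)
    err <- err + (y[i] - pred)^2
  }
  err
}

#' Fit QC-anchored drift models
#'
#' @param fe a [FootprintExperiment-class] containing pooled-QC injections.
#' @param spans candidate LOESS span grid searched by leave-one-out
#'   cross-validation.
#' @return a [DriftModel-class]. Features with fewer than 4 observed QC
#'   values in a batch are marked uncorrectable (and a warning is raised);
#'   [applyDriftCorrection()] passes them through unchanged.
#' @export
fitDriftModel <- function(fe, spans = seq(0.3, 0.9, by = 0.1)) {
  qc <- isQC(fe)
  if (!any(qc)) stop("no QC injections in table")
  batches <- unique(analyticalBatch(fe))
  io <- injectionOrder(fe)
  x_all <- intensities(fe)
  fits <- list()
  rows <- list()
  n_uncorrectable <- 0
  for (b in batches) {
    in_b <- analyticalBatch(fe) == b
    for (f in rownames(fe)) {
      y <- x_all[f, qc & in_b]
      t_qc <- io[qc & in_b]
      keep <- !is.na(y)
      y <- y[keep]; t_qc <- t_qc[keep]
      o <- order(t_qc); y <- y[o]; t_qc <- t_qc[o]
      key <- paste(f, b, sep = "\r")
      if (length(y) < 4) {
        n_uncorrectable <- n_uncorrectable + 1
        fits[[key]] <- list(correctable = FALSE)
        rows[[key]] <- data.frame(feature_id = f, batch = b,
                                  span = NA_real_, reference = NA_real_,
                                  cv_error = NA_real_, correctable = FALSE)
        next
      }
      if (max(y) == min(y)) {
        # constant QC signal: correction function is the constant itself
        ref <- y[1]
        fits[[key]] <- list(correctable = TRUE, span = NA_real_,
                            spline = local({v <- ref; function(t)
                              rep(v, length(t))}),
                            reference = ref, qc_orders = t_qc, fitted = y)
        rows[[key]] <- data.frame(feature_id = f, batch = b, span = NA_real_,
                                  reference = ref, cv_error = 0,
                                  correctable = TRUE)
        next
      }
      # local windows need >= 4 points: with fewer, the tricube weight of
      # the farthest point is 0 and a degree-1 fit interpolates the QC
      # noise exactly instead of smoothing it
      eligible <- spans[spans * length(y) >= 4]
      if (!length(eligible)) eligible <- 1
      cv <- vapply(eligible, function(sp) .looCvError(t_qc, y, sp),
                   numeric(1))
      if (all(!is.finite(cv))) {
        n_uncorrectable <- n_uncorrectable + 1
        fits[[key]] <- list(correctable = FALSE)
        rows[[key]] <- data.frame(feature_id = f, batch = b,
                                  span = NA_real_, reference = NA_real_,
                                  cv_error = NA_real_, correctable = FALSE)
        next
      }
      span <- eligible[which.min(cv)]
      sm <- suppressWarnings(
        loess(y ~ t_qc, span = span, degree = 1,
              control = loess.control(surface = "direct"),
              family = "gaussian"))
      fitted_qc <- suppressWarnings(predict(sm, t_qc))
      spl <- splinefun(t_qc, fitted_qc, method = "natural")
      ref <- median(fitted_qc)
      fits[[key]] <- list(correctable = TRUE, span = span, spline = spl,
                          reference = ref, qc_orders = t_qc,
                          fitted = fitted_qc)
      rows[[key]] <- data.frame(feature_id = f, batch = b, span = span,
                                reference = ref, cv_error = min(cv),
                                correctable = TRUE)
    }
  }
  if (n_uncorrectable > 0)
    warning(n_uncorrectable,
            " feature-batch combination(s) with < 4 QC values are uncorrectable")
  new("DriftModel", fits = fits,
      info = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      spans = spans)
}

#' Apply a drift correction to a measurement table
#'
#' Each observed intensity is rescaled by `reference / spline(order)` for
#' its feature and batch, anchoring all injections to the model's reference
#' QC level. Missing values stay missing. If the correction function is
#' non-positive anywhere the feature is needed, that feature-batch is marked
#' uncorrectable and passed through unchanged (with a warning).
#'
#' @param fe a [FootprintExperiment-class].
#' @param model a [DriftModel-class] fitted on the same batches.
#' @return the corrected table; `metadata(fe)$uncorrected` keeps a copy of
#'   the input intensity matrix.
#' @export
applyDriftCorrection <- function(fe, model) {
  stopifnot(is(model, "DriftModel"))
  x <- intensities(fe)
  raw <- x
  io <- injectionOrder(fe)
  bad <- character()
  for (b in unique(analyticalBatch(fe))) {
    in_b <- analyticalBatch(fe) == b
    for (f in rownames(fe)) {
      ft <- model@fits[[paste(f, b, sep = "\r")]]
      if (is.null(ft) || !isTRUE(ft$correctable)) next
      pred <- ft$spline(io[in_b])
      if (any(pred <= 0)) {
        bad <- c(bad, sprintf("%s/%s", f, b))
        next
      }
      x[f, in_b] <- x[f, in_b] * ft$reference / pred
    }
  }
  if (length(bad))
    warning("non-positive correction function; passed through unchanged: ",
            paste(bad, collapse = ", "))
  assays(fe)$intensity <- x
  metadata(fe)$uncorrected <- raw
  fe
}

#' QC relative standard deviation per feature
#'
#' RSD = sd/mean of the observed QC intensities (missing excluded).
#'
#' @param fe a [FootprintExperiment-class].
#' @return named numeric vector (NA where < 2 QC observations).
#' @export
qcRSD <- function(fe) {
  xq <- intensities(fe)[, isQC(fe), drop = FALSE]
  apply(xq, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / mean(v)
  })
}

#' Threshold features on QC precision and completeness
#'
#' A feature is kept for statistical analysis only if its pooled-QC
#' relative standard deviation is below `rsd_threshold` and its fraction of
#' missing QC measurements is below `missing_threshold` (defaults: RSD
#' < 20%, missing < 30%). Features with fewer than 4 observed QC values can
#' be neither corrected nor assessed and are dropped with reason
#' `"too_few_qc"`.
#'
#' @param fe a [FootprintExperiment-class] (drift-corrected).
#' @param rsd_threshold maximum QC RSD (fraction).
#' @param missing_threshold maximum QC missing fraction.
#' @return list with `table` (kept features only) and `report`, a
#'   data.frame with `feature_id`, `qc_rsd`, `qc_missing`, `n_qc_obs`,
#'   `kept`, `reason` (`""`, `"rsd"`, `"missing"`, `"rsd;missing"` or
#'   `"too_few_qc"`); kept and dropped features partition the input.
#' @export
thresholdFeatures <- function(fe, rsd_threshold = 0.20,
                              missing_threshold = 0.30) {
  if (!any(isQC(fe))) stop("no QC injections in table")
  xq <- intensities(fe)[, isQC(fe), drop = FALSE]
  n_obs <- rowSums(!is.na(xq))
  missing_frac <- rowMeans(is.na(xq))
  rsd <- qcRSD(fe)
  reason <- character(nrow(fe))
  reason[rsd >= rsd_threshold & !is.na(rsd)] <- "rsd"
  miss_bad <- missing_frac >= missing_threshold
  reason[miss_bad] <- ifelse(reason[miss_bad] == "", "missing",
                             "rsd;missing")
  few <- n_obs < 4
  reason[few] <- "too_few_qc"
  kept <- reason == ""
  report <- data.frame(feature_id = rownames(fe), qc_rsd = rsd,
                       qc_missing = missing_frac, n_qc_obs = n_obs,
                       kept = kept, reason = reason, row.names = NULL)
  list(table = fe[kept, ], report = report)
}

#' Impute missing values, distinguishing MAR from MNAR
#'
#' Operates per feature and sample class on the study samples (QCs,
#' standards and blanks are untouched). A missing cell is treated as
#' missing-not-at-random (left-censored) if (a) its class has no observed
#' value for that feature, or (b) the class's observed minimum for the
#' feature lies within a factor 2 of the feature's global observed minimum
#' while the feature's missingness rate exceeds twice the table-wide rate;
#' such cells are imputed with half of the feature's global observed
#' minimum. All other (missing-at-random) cells receive the within-class
#' mean of observed values. Observed entries are never changed and the
#' returned table has no missing sample cells.
#'
#' @param fe a [FootprintExperiment-class] with thresholded features.
#' @return `fe` imputed, with a per-cell log in
#'   `metadata(fe)$imputation` (`feature_id`, `sample_id`, `mechanism`,
#'   `imputed_value`).
#' @export
imputeMissing <- function(fe) {
  x <- intensities(fe)
  s <- snrValues(fe)
  is_sample <- sampleRoles(fe) == "sample"
  xs <- x[, is_sample, drop = FALSE]
  cls <- classLabels(fe)[is_sample]
  none_observed <- rowSums(!is.na(xs)) == 0
  if (any(none_observed))
    stop("feature(s) with zero observed sample values (should have been ",
         "thresholded): ",
         paste(rownames(fe)[none_observed], collapse = ", "))
  table_missing_rate <- mean(is.na(xs))
  log <- list()
  for (f in seq_len(nrow(xs))) {
    v <- xs[f, ]
    if (!anyNA(v)) next
    global_min <- min(v, na.rm = TRUE)
    feat_missing_rate <- mean(is.na(v))
    for (cl in unique(cls)) {
      in_cl <- cls == cl
      obs <- v[in_cl & !is.na(v)]
      nas <- which(in_cl & is.na(v))
      if (!length(nas)) next
      mnar <- length(obs) == 0 ||
        (min(obs) <= 2 * global_min &&
         feat_missing_rate > 2 * table_missing_rate)
      val <- if (mnar) global_min / 2 else mean(obs)
      v[nas] <- val
      log[[length(log) + 1]] <- data.frame(
        feature_id = rownames(xs)[f],
        sample_id = colnames(xs)[nas],
        mechanism = if (mnar) "mnar" else "mar",
        imputed_value = val)
    }
    xs[f, ] <- v
  }
  x[, is_sample] <- xs
  imputed_mask <- is.na(s) & !is.na(x)
  s[imputed_mask] <- Inf   # imputed values carry no instrument S/N
  assays(fe)$intensity <- x
  assays(fe)$snr <- s
  metadata(fe)$imputation <- if (length(log)) do.call(rbind, log)
    else data.frame(feature_id = character(), sample_id = character(),
                    mechanism = character(), imputed_value = numeric())
  fe
}

#' Run the full footprint preprocessing chain
#'
#' S/N filtering, QC-anchored drift correction, feature thresholding and
#' MAR/MNAR imputation, in that order, using a [PipelineConfig()].
#'
#' @param fe a raw [FootprintExperiment-class].
#' @param config a [PipelineConfig()].
#' @return list with `table` (preprocessed), `report` (feature QC report)
#'   and `drift_model`.
#' @export
preprocessFootprint <- function(fe, config = PipelineConfig()) {
  fe <- filterSNR(fe, config@snr_threshold)
  model <- fitDriftModel(fe)
  fe <- applyDriftCorrection(fe, model)
  th <- thresholdFeatures(fe, config@qc_rsd_threshold,
                          config@qc_missing_threshold)
  list(table = imputeMissing(th$table), report = th$report,
       drift_model = model)
}
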