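#' Molar masses of the study analytes
#'
#' Built-in g/mol table for l-histidine, glycine, l-alanine, l-valine and
#' d-glucose, used by [molarYield()]; any analyte can be overridden by
#' passing an explicit molar mass.
#'
#' @param analyte analyte short name (`His`, `Gly`, `Ala`, `Val`, `Glc`).
#' @return molar mass in g/mol.
#' @export
molarMass <- function(analyte) {
  tab <- c(His = 155.15, Gly = 75.07, Ala = 89.09, Val = 117.15,
           Glc = 180.16)
  if (!analyte %in% names(tab)) stop("unknown analyte: ", analyte)
  unname(tab[analyte])
}

#' Validated cultivation time series
#'
#' @param time time points in hours, strictly increasing.
#' @param backscatter,cdw biomass signal (a.u. or g/L), optional.
#' @param substrate substrate concentration in g/L, optional.
#' @param condition condition label.
#' @return a data.frame of the supplied columns with class
#'   `CultivationSeries`.
#' @export
CultivationSeries <- function(time, backscatter = NULL, cdw = NULL,
                              substrate = NULL, condition = NA_character_) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  df <- data.frame(time = time)
  for (nm in c("backscatter", "cdw", "substrate")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (any(v < 0, na.rm = TRUE)) stop(nm, " must be >= 0")
      df[[nm]] <- v
    }
  }
  attr(df, "condition") <- condition
  class(df) <- c("CultivationSeries", "data.frame")
  df
}

#' Specific growth rate from an exponential signal
#'
#' The specific growth rate mu (1/h) is the least-squares slope of
#' `ln(signal)` against time. The fitting window is either user-supplied
#' (a time interval) or, with `window = "auto"`, the sliding window of at
#' least `min_points` consecutive points maximizing the regression R2.
#' Invariant to multiplicative rescaling of the signal.
#'
#' @param time time points in hours.
#' @param signal biomass proxy (backscatter, CDW, OD); must be positive
#'   inside the window.
#' @param window `NULL` (all points), a `c(t_min, t_max)` interval, or
#'   `"auto"`.
#' @param min_points minimum window size for `"auto"` (>= 3).
#' @return list with `mu` (1/h), `r_squared`, `window` (time interval
#'   used) and `n` points.
#' @export
growthRate <- function(time, signal, window = NULL, min_points = 3) {
  stopifnot(length(time) == length(signal))
  if (identical(window, "auto")) {
    best <- NULL
    for (i in seq_len(length(time) - min_points + 1))
      for (j in seq(i + min_points - 1, length(time))) {
        res <- tryCatch(
          growthRate(time[i:j], signal[i:j]), error = function(e) NULL)
        if (!is.null(res) &&
            (is.null(best) || res$r_squared > best$r_squared))
          best <- res
      }
    if (is.null(best)) stop("no valid window found")
    return(best)
  }
  keep <- if (is.null(window)) rep(TRUE, length(time))
          else time >= window[1] & time <= window[2]
  t_w <- time[keep]; s_w <- signal[keep]
  if (length(t_w) < 3) stop("need >= 3 points in window")
  if (any(s_w <= 0)) stop("non-positive signal in window")
  fit <- stats::lm(log(s_w) ~ t_w)
  list(mu = unname(stats::coef(fit)[2]),
       r_squared = if (stats::var(log(s_w)) == 0) 1
                   else suppressWarnings(summary(fit)$r.squared),
       window = range(t_w), n = length(t_w))
}

#' Molar product yield
#'
#' Moles of product formed per mole of substrate consumed. Product is given
#' in mM (as quantified by IDMS) or in g/L with its molar mass; substrate
#' in g/L (with molar mass) or mM.
#'
#' @param product product formed, in `product_unit`.
#' @param substrate_consumed substrate consumed (> 0), in `substrate_unit`.
#' @param product_unit `"mM"` or `"g_per_L"`.
#' @param substrate_unit `"g_per_L"` or `"mM"`.
#' @param product_mw,substrate_mw molar masses (g/mol), required for g/L
#'   inputs; see [molarMass()].
#' @return yield in mol/mol.
#' @export
molarYield <- function(product, substrate_consumed,
                       product_unit = c("mM", "g_per_L"),
                       substrate_unit = c("g_per_L", "mM"),
                       product_mw = NULL, substrate_mw = NULL) {
  product_unit <- match.arg(product_unit)
  substrate_unit <- match.arg(substrate_unit)
  if (substrate_consumed <= 0) stop("substrate consumed must be > 0")
  if (product < 0) stop("product must be >= 0")
  prod_mmol <- switch(product_unit,
    mM = product,
    g_per_L = {
      if (is.null(product_mw)) stop("product_mw required for g/L input")
      1000 * product / product_mw
    })
  sub_mmol <- switch(substrate_unit,
    mM = substrate_consumed,
    g_per_L = {
      if (is.null(substrate_mw)) stop("substrate_mw required for g/L input")
      1000 * substrate_consumed / substrate_mw
    })
  prod_mmol / sub_mmol
}

#' Fold change against a reference
#'
#' @param value observed value (e.g. optimized titer).
#' @param reference reference value (> 0).
#' @return `value / reference`.
#' @export
foldChange <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be > 0")
  value / reference
}
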