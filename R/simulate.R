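#' Specification of a synthetic measurement run
#'
#' Describes the statistical structure of a simulated flow-injection
#' footprint run: class-structured multiplicative metabolite effects on
#' lognormal baselines, biological-by-technical replicate nesting, pooled-QC
#' injections interleaved deterministically every `qc_every_k`-th position
#' (starting at position 1), a smooth multiplicative injection-order drift,
#' uniform missingness (MAR) and left-censoring below a limit of detection
#' (MNAR). Defaults mirror the study design: 3 biological x 4 technical
#' replicates per class, ~10% lognormal measurement RSD, QC every 6
#' injections.
#'
#' @param n_features number of metabolite features.
#' @param n_classes number of sample classes (conditions / time points).
#' @param n_biological,n_technical replicate structure per class.
#' @param qc_every_k pooled-QC injection interval (>= 1).
#' @param baseline_mean per-feature baseline intensity; scalar recycled, or
#'   `NULL` to draw log-uniform baselines in `10^[4, 6]`.
#' @param sigma lognormal sdlog of multiplicative measurement noise
#'   (RSD is approximately `sigma` for small values).
#' @param class_effects features x classes matrix of multiplicative effects
#'   (default all 1).
#' @param drift drift family applied to all intensities as a function of
#'   injection position: `"none"`, `"linear"` (rising by `drift_amplitude`
#'   across the run) or `"sinusoidal"` (one period, amplitude
#'   `drift_amplitude`).
#' @param drift_amplitude drift amplitude as a fraction of baseline (>= 0).
#' @param mar_rate probability that any measurement is missing at random.
#' @param lod per-feature limit of detection; observed values strictly below
#'   it are censored (`NA`). Scalar recycled; `NA` disables censoring.
#' @param noise_floor_frac per-feature noise floor as a fraction of the
#'   baseline; emitted `snr = intensity / noise_floor`.
#' @param seed integer RNG seed.
#' @return a `SimulationSpec` object.
#' @export
SimulationSpec <- function(n_features = 50, n_classes = 2,
                           n_biological = 3, n_technical = 4,
                           qc_every_k = 6, baseline_mean = NULL,
                           sigma = 0.1, class_effects = NULL,
                           drift = c("none", "linear", "sinusoidal"),
                           drift_amplitude = 0, mar_rate = 0,
                           lod = NA_real_, noise_floor_frac = 0.001,
                           seed = 1L) {
  drift <- match.arg(drift)
  new("SimulationSpec", n_features = as.integer(n_features),
      n_classes = as.integer(n_classes),
      n_biological = as.integer(n_biological),
      n_technical = as.integer(n_technical),
      qc_every_k = as.integer(qc_every_k),
      baseline_mean = if (is.null(baseline_mean)) numeric(0)
                      else as.numeric(baseline_mean),
      sigma = sigma,
      class_effects = if (is.null(class_effects)) matrix(numeric(0), 0, 0)
                      else as.matrix(class_effects),
      drift = drift, drift_amplitude = drift_amplitude,
      mar_rate = mar_rate, lod = as.numeric(lod),
      noise_floor_frac = noise_floor_frac, seed = as.integer(seed))
}

#' @rdname SimulationSpec
#' @aliases SimulationSpec-class
#' @export
setClass("SimulationSpec", representation(
  n_features = "integer", n_classes = "integer", n_biological = "integer",
  n_technical = "integer", qc_every_k = "integer", baseline_mean = "numeric",
  sigma = "numeric", class_effects = "matrix", drift = "character",
  drift_amplitude = "numeric", mar_rate = "numeric", lod = "numeric",
  noise_floor_frac = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@n_features < 1) msg <- c(msg, "n_features must be >= 1")
  n_samp <- object@n_classes * object@n_biological * object@n_technical
  if (n_samp < 1) msg <- c(msg, "spec yields zero samples")
  if (object@qc_every_k < 1) msg <- c(msg, "qc_every_k must be >= 1")
  if (object@drift_amplitude < 0) msg <- c(msg, "drift_amplitude must be >= 0")
  if (object@mar_rate < 0 || object@mar_rate > 1)
    msg <- c(msg, "mar_rate must be in [0,1]")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

.driftFun <- function(family, amplitude, n_pos) {
  switch(family,
    none = function(t) rep(1, length(t)),
    linear = function(t) 1 + amplitude * (t - 1) / max(n_pos - 1, 1),
    sinusoidal = function(t) 1 + amplitude * sin(2 * pi * (t - 1) / n_pos))
}

#' Generate a synthetic measurement run
#'
#' Produces a [FootprintExperiment-class] following a [SimulationSpec()]:
#' sample intensities are `baseline x class effect x drift(t) x
#' exp(N(0, sigma^2))`; QC injections are draws around the pooled mean of
#' all class means; every injection gets a unique order; `snr` is the
#' intensity divided by the feature's noise floor; MAR missingness removes
#' cells uniformly at random and values below the feature's limit of
#' detection are censored. Identical seeds give identical tables.
#'
#' @param spec a [SimulationSpec()].
#' @return a validated [FootprintExperiment-class] with true-signal
#'   bookkeeping in `metadata()` (`true_drift`, `class_means`).
#' @export
generateRun <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  set.seed(spec@seed)
  p <- spec@n_features
  K <- spec@n_classes
  n_samp <- K * spec@n_biological * spec@n_technical
  baseline <- if (length(spec@baseline_mean))
    rep_len(spec@baseline_mean, p) else 10 ^ runif(p, 4, 6)
  eff <- if (length(spec@class_effects))
    spec@class_effects else matrix(1, p, K)
  stopifnot(nrow(eff) == p, ncol(eff) == K)
  class_means <- baseline * eff                     # p x K
  qc_mean <- rowMeans(class_means)                  # pooled mean of class means

  # injection layout: QC at every position congruent to 1 mod k, samples on
  # the remaining positions (seeded random run order), plus one trailing QC
  # so QCs bracket the whole run
  k <- spec@qc_every_k
  if (k < 2) stop("qc_every_k must be >= 2 to leave room for samples")
  n_blocks <- ceiling(n_samp / (k - 1))
  pos <- seq_len(n_blocks * k + 1)
  is_qc_pos <- (pos - 1) %% k == 0
  samp_pos <- pos[!is_qc_pos][seq_len(n_samp)]
  n_pos <- samp_pos[n_samp] + (k - (samp_pos[n_samp] - 1) %% k)
  qc_pos <- pos[is_qc_pos & pos <= n_pos]

  classes <- rep(LETTERS[seq_len(K)],
                 each = spec@n_biological * spec@n_technical)
  bio <- rep(rep(seq_len(spec@n_biological), each = spec@n_technical), K)
  tech <- rep(seq_len(spec@n_technical), K * spec@n_biological)
  ord <- sample.int(n_samp)
  samp_pos_assigned <- samp_pos[order(ord)]

  g <- .driftFun(spec@drift, spec@drift_amplitude, n_pos)
  noise_floor <- baseline * spec@noise_floor_frac

  n_col <- n_samp + length(qc_pos)
  intensity <- matrix(NA_real_, p, n_col)
  all_pos <- integer(n_col)
  roles <- character(n_col)
  cls <- rep(NA_character_, n_col)
  bio_all <- tech_all <- rep(NA_integer_, n_col)
  ids <- character(n_col)

  noise <- function(n) if (spec@sigma > 0)
    exp(stats::rnorm(n, 0, spec@sigma)) else rep(1, n)

  j <- 0
  for (q in seq_along(qc_pos)) {
    j <- j + 1
    intensity[, j] <- qc_mean * g(qc_pos[q]) * noise(p)
    all_pos[j] <- qc_pos[q]; roles[j] <- "qc"
    bio_all[j] <- 1L; tech_all[j] <- q
    ids[j] <- sprintf("QC%02d", q)
  }
  for (i in seq_len(n_samp)) {
    j <- j + 1
    ci <- match(classes[i], LETTERS)
    intensity[, j] <- class_means[, ci] * g(samp_pos_assigned[i]) * noise(p)
    all_pos[j] <- samp_pos_assigned[i]; roles[j] <- "sample"
    cls[j] <- classes[i]; bio_all[j] <- bio[i]; tech_all[j] <- tech[i]
    ids[j] <- sprintf("%s_b%d_t%d", classes[i], bio[i], tech[i])
  }

  # MAR then MNAR (left-censoring at the LOD)
  if (spec@mar_rate > 0) {
    drop <- matrix(stats::runif(p * n_col) < spec@mar_rate, p, n_col)
    intensity[drop] <- NA_real_
  }
  lod <- rep_len(spec@lod, p)
  cens <- !is.na(lod) & !is.na(intensity) & intensity < lod
  intensity[cens] <- NA_real_

  snr <- intensity / noise_floor
  dimnames(intensity) <- list(sprintf("f%03d", seq_len(p)), ids)

  o <- order(all_pos)
  sm <- data.frame(role = roles, injection_order = all_pos, batch = "B1",
                   class_label = cls, bio_rep = bio_all, tech_rep = tech_all,
                   dilution = 1)[o, ]
  fe <- FootprintExperiment(intensity[, o, drop = FALSE],
                            snr[, o, drop = FALSE], sm)
  metadata(fe)$true_drift <- g
  metadata(fe)$class_means <- class_means
  metadata(fe)$seed <- spec@seed
  fe
}

#' Default IDMS calibration dilution series
#'
#' The 12-concentration layout used for the flow-injection methods: a
#' linear series 16, 14, 12, 10, 8, 6, 4, 2, 1 uM followed by a logarithmic
#' series 0.5, 0.25, 0.01 uM.
#'
#' @return numeric vector of concentrations (uM), descending.
#' @export
defaultCalibrationSeries <- function()
  c(16, 14, 12, 10, 8, 6, 4, 2, 1, 0.5, 0.25, 0.01)

#' Generate a synthetic calibration plate
#'
#' Emits unlabeled/labeled peak-area pairs whose area ratio follows
#' `slope * concentration + intercept` plus Gaussian noise, emulating an
#' isotope-dilution calibration series.
#'
#' @param concentrations standard concentrations in uM (positive); defaults
#'   to [defaultCalibrationSeries()].
#' @param slope,intercept true response line (ratio per uM, ratio).
#' @param noise_sd Gaussian noise on the ratio.
#' @param labeled_area constant internal-standard area.
#' @param seed RNG seed.
#' @return data.frame with `concentration`, `area`, `labeled_area`, `ratio`.
#' @export
generateCalibrationPlate <- function(concentrations = defaultCalibrationSeries(),
                                     slope = 0.1, intercept = 0,
                                     noise_sd = 0, labeled_area = 1e5,
                                     seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  set.seed(seed)
  ratio <- slope * concentrations + intercept +
    stats::rnorm(length(concentrations), 0, noise_sd)
  data.frame(concentration = concentrations,
             area = ratio * labeled_area,
             labeled_area = labeled_area, ratio = ratio)
}

#' Generate a toy pathway fixture
#'
#' Builds weakly connected directed compound graphs small enough for
#' hand-checkable centralities: each pathway gets a random directed spanning
#' path through its members plus extra random edges at the given density
#' (`density = 0` yields edgeless pathways).
#'
#' @param n_pathways number of pathways.
#' @param n_compounds compounds per pathway (>= 3).
#' @param density probability of each extra directed edge, in `[0, 1]`.
#' @param seed RNG seed.
#' @return a [PathwaySet-class] whose background is the union of members.
#' @export
generatePathwayFixture <- function(n_pathways = 3, n_compounds = 6,
                                   density = 0.2, seed = 1L) {
  if (n_compounds < 3) stop("n_compounds must be >= 3")
  set.seed(seed)
  total <- n_pathways * n_compounds
  cpds <- sprintf("C%05d", seq_len(ceiling(total * 0.8)))
  pws <- lapply(seq_len(n_pathways), function(i) {
    nodes <- sample(cpds, n_compounds)
    edges <- list()
    if (density > 0) {
      ordn <- sample(nodes)
      edges <- lapply(seq_len(n_compounds - 1),
                      function(j) c(ordn[j], ordn[j + 1]))
      for (a in nodes) for (b in nodes)
        if (a != b && stats::runif(1) < density)
          edges <- c(edges, list(c(a, b)))
      edges <- unique(edges)
    }
    list(id = sprintf("pw%02d", i), name = sprintf("toy pathway %d", i),
         nodes = nodes, edges = edges)
  })
  PathwaySet(pws)
}

#' Three-compound path-graph fixture
#'
#' The minimal directed pathway A -> B -> C, where B carries all betweenness
#' centrality.
#'
#' @return a [PathwaySet-class] with one 3-node pathway.
#' @export
pathGraphFixture <- function() {
  PathwaySet(list(list(id = "pw_path3", name = "linear path A>B>C",
                       nodes = c("A", "B", "C"),
                       edges = list(c("A", "B"), c("B", "C")))))
}
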