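#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
NULL

.SAMPLE_ROLES <- c("qc", "sample", "standard", "blank")

.REQUIRED_COLDATA <- c("role", "injection_order", "batch", "class_label",
                       "bio_rep", "tech_rep", "dilution")

#' Container for flow-injection MS footprint measurements
#'
#' `FootprintExperiment` extends [SummarizedExperiment] to hold a
#' features-by-samples intensity matrix together with the per-measurement
#' metadata that footprint preprocessing relies on. The `intensity` assay
#' carries non-negative peak areas (missing values are `NA`, never 0); the
#' `snr` assay carries per-measurement signal-to-noise values and must be
#' non-missing wherever an intensity is observed. An optional `labeled`
#' assay holds the areas of the uniformly 13C15N-labelled internal standard
#' for isotope-dilution quantification.
#'
#' Column (sample) metadata must provide: `role` (one of `qc`, `sample`,
#' `standard`, `blank`), `injection_order` (positive integer, unique within
#' an analytical `batch`), `batch`, `class_label` (may be `NA` for QCs and
#' blanks), `bio_rep`, `tech_rep` and `dilution` (> 0).
#'
#' @aliases FootprintExperiment-class
#' @export
setClass("FootprintExperiment", contains = "SummarizedExperiment")

setValidity("FootprintExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("intensity", "snr") %in% an))
    return("assays must include 'intensity' and 'snr'")
  x <- assay(object, "intensity")
  s <- assay(object, "snr")
  neg <- which(!is.na(x) & x < 0)
  if (length(neg))
    msg <- c(msg, sprintf("negative intensities at %d cell(s), first at [%s]",
                          length(neg), paste(arrayInd(neg[1], dim(x)),
                                             collapse = ",")))
  nosnr <- which(!is.na(x) & is.na(s))
  if (length(nosnr))
    msg <- c(msg, sprintf("snr missing for %d observed intensity cell(s)",
                          length(nosnr)))
  cd <- colData(object)
  missing_cols <- setdiff(.REQUIRED_COLDATA, colnames(cd))
  if (length(missing_cols))
    return(paste0("colData lacks: ", paste(missing_cols, collapse = ", ")))
  if (!all(cd$role %in% .SAMPLE_ROLES))
    msg <- c(msg, sprintf("role must be one of {%s}",
                          paste(.SAMPLE_ROLES, collapse = ", ")))
  io <- cd$injection_order
  if (any(is.na(io)) || any(io < 1) || any(io != round(io)))
    msg <- c(msg, "injection_order must be positive integers")
  for (b in unique(cd$batch)) {
    iob <- io[cd$batch == b]
    if (anyDuplicated(iob))
      msg <- c(msg, sprintf(
        "injection_order not unique within batch '%s' (order %s)", b,
        paste(unique(iob[duplicated(iob)]), collapse = ",")))
  }
  if (any(is.na(cd$dilution)) || any(cd$dilution <= 0))
    msg <- c(msg, "dilution must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FootprintExperiment
#'
#' @param intensity numeric matrix, features x samples; `NA` marks a missing
#'   measurement, values must be >= 0.
#' @param snr matrix of signal-to-noise values aligned with `intensity`.
#' @param sample_meta data.frame with one row per sample and columns
#'   `role`, `injection_order`, `batch`, `class_label`, `bio_rep`,
#'   `tech_rep`, `dilution`.
#' @param feature_meta optional data.frame with one row per feature
#'   (e.g. `metabolite`, `compound_id`, `has_labeled_standard`).
#' @param labeled optional matrix of labelled internal-standard areas.
#' @return a validated [FootprintExperiment-class] object.
#' @examples
#' fe <- FootprintExperiment(
#'   intensity = matrix(c(1, 2, 3, 4), 2,
#'                      dimnames = list(c("f1", "f2"), c("s1", "s2"))),
#'   snr = matrix(100, 2, 2),
#'   sample_meta = data.frame(role = "sample", injection_order = 1:2,
#'                            batch = "B1", class_label = "A",
#'                            bio_rep = 1, tech_rep = 1:2, dilution = 1))
#' @export
FootprintExperiment <- function(intensity, snr, sample_meta,
                                feature_meta = NULL, labeled = NULL) {
  intensity <- as.matrix(intensity)
  snr <- as.matrix(snr)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("f", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("s", seq_len(ncol(intensity)))
  dimnames(snr) <- dimnames(intensity)
  alist <- list(intensity = intensity, snr = snr)
  if (!is.null(labeled)) {
    labeled <- as.matrix(labeled)
    dimnames(labeled) <- dimnames(intensity)
    alist$labeled <- labeled
  }
  sample_meta <- as.data.frame(sample_meta)
  if (nrow(sample_meta) == 1L && ncol(intensity) > 1L)
    sample_meta <- sample_meta[rep(1L, ncol(intensity)), , drop = FALSE]
  if (!"class_label" %in% colnames(sample_meta))
    sample_meta$class_label <- NA_character_
  rownames(sample_meta) <- colnames(intensity)
  if (is.null(feature_meta))
    feature_meta <- data.frame(metabolite = rownames(intensity))
  rownames(feature_meta) <- rownames(intensity)
  se <- SummarizedExperiment(
    assays = alist,
    colData = DataFrame(sample_meta),
    rowData = DataFrame(feature_meta))
  new("FootprintExperiment", se)
}

#' @describeIn FootprintExperiment intensity matrix accessor.
#' @param object,x a `FootprintExperiment`.
#' @export
intensities <- function(x) assay(x, "intensity")

#' @describeIn FootprintExperiment signal-to-noise matrix accessor.
#' @export
snrValues <- function(x) assay(x, "snr")

#' @describeIn FootprintExperiment labelled internal-standard areas (or NULL).
#' @export
labeledAreas <- function(x)
  if ("labeled" %in% assayNames(x)) assay(x, "labeled") else NULL

#' @describeIn FootprintExperiment sample role vector.
#' @export
sampleRoles <- function(x) as.character(colData(x)$role)

#' @describeIn FootprintExperiment logical mask of pooled-QC injections.
#' @export
isQC <- function(x) sampleRoles(x) == "qc"

#' @describeIn FootprintExperiment injection-order vector.
#' @export
injectionOrder <- function(x) as.integer(colData(x)$injection_order)

#' @describeIn FootprintExperiment class-label vector (NA where undefined).
#' @export
classLabels <- function(x) as.character(colData(x)$class_label)

#' @describeIn FootprintExperiment analytical-batch vector.
#' @export
analyticalBatch <- function(x) as.character(colData(x)$batch)

setMethod("show", "FootprintExperiment", function(object) {
  callNextMethod()
  cat(sprintf("roles: %s\n",
              paste(sprintf("%s(%d)", names(table(sampleRoles(object))),
                            table(sampleRoles(object))), collapse = " ")))
  cat(sprintf("missing intensity cells: %d / %d\n",
              sum(is.na(intensities(object))),
              length(intensities(object))))
})

# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the thresholds and tuning constants used across preprocessing and
#' modelling. Defaults follow the study conventions: signal-to-noise filter
#' at > 10, QC relative standard deviation < 20%, QC missingness < 30%,
#' significance level 0.05, stratified double 7-fold cross-validation,
#' component selection at a 5% relative Q2 gain, 100 bootstrap resamples and
#' a VIP threshold of 1.
#'
#' @param snr_threshold signal-to-noise cut; measurements with snr <= this
#'   are masked.
#' @param qc_rsd_threshold maximum QC relative standard deviation (fraction).
#' @param qc_missing_threshold maximum QC missing fraction.
#' @param alpha significance level.
#' @param n_folds folds for (double) cross-validation.
#' @param q2_rel_increase relative Q2 gain under which no further component
#'   is added.
#' @param n_bootstrap bootstrap resamples for CI estimation.
#' @param vip_threshold VIP selection threshold.
#' @param rng_seed integer seed used by all randomized operations.
#' @return a `PipelineConfig` object.
#' @export
PipelineConfig <- function(snr_threshold = 10, qc_rsd_threshold = 0.20,
                           qc_missing_threshold = 0.30, alpha = 0.05,
                           n_folds = 7, q2_rel_increase = 0.05,
                           n_bootstrap = 100, vip_threshold = 1.0,
                           rng_seed = 1L) {
  new("PipelineConfig", snr_threshold = snr_threshold,
      qc_rsd_threshold = qc_rsd_threshold,
      qc_missing_threshold = qc_missing_threshold, alpha = alpha,
      n_folds = as.integer(n_folds), q2_rel_increase = q2_rel_increase,
      n_bootstrap = as.integer(n_bootstrap), vip_threshold = vip_threshold,
      rng_seed = as.integer(rng_seed))
}

#' @rdname PipelineConfig
#' @aliases PipelineConfig-class
#' @export
setClass("PipelineConfig", representation(
  snr_threshold = "numeric", qc_rsd_threshold = "numeric",
  qc_missing_threshold = "numeric", alpha = "numeric",
  n_folds = "integer", q2_rel_increase = "numeric",
  n_bootstrap = "integer", vip_threshold = "numeric", rng_seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@qc_rsd_threshold <= 0) msg <- c(msg, "qc_rsd_threshold must be > 0")
  if (object@qc_missing_threshold < 0 || object@qc_missing_threshold > 1)
    msg <- c(msg, "qc_missing_threshold must be in [0,1]")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (object@n_folds < 2) msg <- c(msg, "n_folds must be >= 2")
  if (object@n_bootstrap < 1) msg <- c(msg, "n_bootstrap must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-21s %s\n", s, format(slot(object, s))))
})

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file with any subset of the [PipelineConfig()] fields.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(PipelineConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(PipelineConfig, cfg)
}

# ---------------------------------------------------------------------------

#' Set of directed compound-graph pathways
#'
#' Each pathway is a named directed graph over compound identifiers
#' (KEGG-style C-numbers or any exact identifier strings); `background` is
#' the universe of compounds used by over-representation analysis. Every
#' edge endpoint must be a pathway member and every member must be in the
#' background.
#'
#' @aliases PathwaySet-class
#' @export
setClass("PathwaySet", representation(pathways = "list",
                                      background = "character"))

setValidity("PathwaySet", function(object) {
  msg <- character()
  for (pw in object@pathways) {
    if (!all(c("id", "name", "nodes") %in% names(pw)))
      return("each pathway needs id, name, nodes")
    ep <- unique(unlist(pw$edges))
    bad <- setdiff(ep, pw$nodes)
    if (length(bad))
      msg <- c(msg, sprintf("pathway '%s': edge endpoint(s) %s not in members",
                            pw$id, paste(bad, collapse = ", ")))
    out <- setdiff(pw$nodes, object@background)
    if (length(out))
      msg <- c(msg, sprintf("pathway '%s': member(s) %s not in background",
                            pw$id, paste(out, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwaySet
#'
#' @param pathways list of lists with elements `id`, `name`, `nodes`
#'   (character) and `edges` (list of length-2 character vectors, directed
#'   from -> to; may be empty).
#' @param background character vector of all assayable compounds; defaults
#'   to the union of all pathway member sets.
#' @return a validated [PathwaySet-class].
#' @export
PathwaySet <- function(pathways, background = NULL) {
  pathways <- lapply(pathways, function(pw) {
    pw$nodes <- as.character(pw$nodes)
    pw$edges <- lapply(pw$edges, as.character)
    pw
  })
  if (is.null(background))
    background <- sort(unique(unlist(lapply(pathways, `[[`, "nodes"))))
  new("PathwaySet", pathways = pathways,
      background = as.character(background))
}

setMethod("show", "PathwaySet", function(object) {
  cat(sprintf("PathwaySet: %d pathway(s), background of %d compound(s)\n",
              length(object@pathways), length(object@background)))
  for (pw in object@pathways)
    cat(sprintf("  %s '%s': %d nodes, %d edges\n", pw$id, pw$name,
                length(pw$nodes), length(pw$edges)))
})

#' @describeIn PathwaySet number of pathways.
#' @param x a `PathwaySet`.
#' @export
setMethod("length", "PathwaySet", function(x) length(x@pathways))

#' @describeIn PathwaySet list of pathway entries.
#' @export
pathwayList <- function(x) x@pathways

#' @describeIn PathwaySet background compound identifiers.
#' @export
pathwayBackground <- function(x) x@background
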