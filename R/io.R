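#' @importFrom utils read.csv write.csv read.delim write.table
NULL

.LONG_COLS <- c("sample_id", "feature_id", "area", "labeled_area", "snr",
                "role", "injection_order", "batch", "class", "bio_rep",
                "tech_rep", "dilution")

.WIDE_META <- c("sample_id", "role", "injection_order", "batch", "class",
                "bio_rep", "tech_rep", "dilution")

#' Read a peak table into a FootprintExperiment
#'
#' The canonical dialect is long format: one row per sample-by-feature
#' measurement with columns `sample_id, feature_id, area, labeled_area, snr,
#' role, injection_order, batch, class, bio_rep, tech_rep, dilution`
#' (`labeled_area` may be absent for semi-targeted data). Missing
#' measurements are empty cells, never 0. The wide dialect is a convenience
#' reader: sample metadata columns followed by one intensity column per
#' feature; since wide tables carry no per-measurement signal-to-noise, snr
#' is set to `Inf` (every observed value passes any S/N filter).
#'
#' @param path CSV (or TSV, detected by extension) file path.
#' @param dialect `"long"` (canonical) or `"wide"`.
#' @return a validated [FootprintExperiment-class]; duplicate
#'   (sample, feature) pairs, negative intensities or missing mandatory
#'   metadata raise an error naming the offending rows.
#' @export
readMeasurementTable <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, na.strings = c("", "NA"),
                 check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "long") .fromLong(df) else .fromWide(df)
}

.fromLong <- function(df) {
  need <- setdiff(.LONG_COLS, c("labeled_area", "class"))
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("long table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"class" %in% colnames(df)) df$class <- NA_character_
  key <- paste(df$sample_id, df$feature_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    stop(sprintf("duplicate (sample, feature) pair(s) at row(s) %s",
                 paste(utils::head(d, 5), collapse = ", ")))
  }
  bad <- which(!is.na(df$area) & df$area < 0)
  if (length(bad))
    stop(sprintf("negative intensities at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  meta_cols <- c("role", "injection_order", "batch", "bio_rep", "tech_rep",
                 "dilution")
  badm <- which(!stats::complete.cases(df[meta_cols]))
  if (length(badm))
    stop(sprintf("missing mandatory metadata at row(s) %s",
                 paste(utils::head(badm, 5), collapse = ", ")))
  samples <- unique(df$sample_id)
  features <- unique(df$feature_id)
  si <- match(df$sample_id, samples)
  fi <- match(df$feature_id, features)
  mk <- function(col) {
    m <- matrix(NA_real_, length(features), length(samples),
                dimnames = list(features, samples))
    m[cbind(fi, si)] <- df[[col]]
    m
  }
  intensity <- mk("area")
  snr <- mk("snr")
  labeled <- if ("labeled_area" %in% colnames(df) &&
                 any(!is.na(df$labeled_area))) mk("labeled_area") else NULL
  first <- !duplicated(df$sample_id)
  sm <- data.frame(role = df$role[first],
                   injection_order = as.integer(df$injection_order[first]),
                   batch = as.character(df$batch[first]),
                   class_label = as.character(df$class[first]),
                   bio_rep = as.integer(df$bio_rep[first]),
                   tech_rep = as.integer(df$tech_rep[first]),
                   dilution = as.numeric(df$dilution[first]))
  # per-sample metadata must be constant across that sample's rows
  for (cn in c("role", "injection_order", "batch", "dilution")) {
    n_per <- tapply(df[[cn]], df$sample_id, function(v) length(unique(v)))
    if (any(n_per > 1))
      stop("inconsistent per-sample metadata in column '", cn, "' for: ",
           paste(names(n_per)[n_per > 1], collapse = ", "))
  }
  FootprintExperiment(intensity, snr, sm, labeled = labeled)
}

.fromWide <- function(df) {
  miss <- setdiff(setdiff(.WIDE_META, "class"), colnames(df))
  if (length(miss))
    stop("wide table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"class" %in% colnames(df)) df$class <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in wide table")
  fcols <- setdiff(colnames(df), c(.WIDE_META, "class"))
  if (!length(fcols)) stop("wide table has no feature columns")
  intensity <- t(as.matrix(df[fcols]))
  colnames(intensity) <- df$sample_id
  snr <- ifelse(is.na(intensity), NA_real_, Inf)
  sm <- data.frame(role = df$role, injection_order = df$injection_order,
                   batch = df$batch, class_label = df$class,
                   bio_rep = df$bio_rep, tech_rep = df$tech_rep,
                   dilution = df$dilution)
  FootprintExperiment(intensity, snr, sm)
}

#' Write a pipeline result to disk
#'
#' Every result type is written with a deterministic column order so that a
#' read-back equals the written object. A `FootprintExperiment` is written
#' as a long-format CSV (missing measurements become empty cells); result
#' data frames (QC reports, univariate tables, enrichment tables,
#' selections) are written as TSV; an empty result yields a header-only
#' file.
#'
#' @param obj a `FootprintExperiment` or a result `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
setGeneric("writeResults", function(obj, path) standardGeneric("writeResults"))

#' @rdname writeResults
#' @export
setMethod("writeResults", "FootprintExperiment", function(obj, path) {
  cd <- colData(obj)
  x <- intensities(obj)
  s <- snrValues(obj)
  lab <- labeledAreas(obj)
  grid <- expand.grid(feature_id = rownames(obj), sample_id = colnames(obj),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  si <- match(grid$sample_id, colnames(obj))
  df <- data.frame(
    sample_id = grid$sample_id, feature_id = grid$feature_id,
    area = as.vector(x), labeled_area = if (is.null(lab)) NA_real_
                                        else as.vector(lab),
    snr = as.vector(s), role = cd$role[si],
    injection_order = cd$injection_order[si], batch = cd$batch[si],
    class = cd$class_label[si], bio_rep = cd$bio_rep[si],
    tech_rep = cd$tech_rep[si], dilution = cd$dilution[si])
  df <- df[order(match(df$sample_id, colnames(obj)),
                 match(df$feature_id, rownames(obj))), .LONG_COLS]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
})

#' @rdname writeResults
#' @export
setMethod("writeResults", "data.frame", function(obj, path) {
  write.table(obj, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
})

#' Load a pathway set from a JSON graph file
#'
#' The file holds `{"pathways": [{"id", "name", "nodes", "edges"}, ...],
#' "background": [...]}` with `edges` a list of `[from, to]` compound pairs.
#' If `background` is omitted it defaults to the union of all pathway
#' member sets.
#'
#' @param path JSON file path.
#' @return a validated [PathwaySet-class].
#' @export
loadPathways <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$pathways)) stop("no 'pathways' element in ", path)
  pws <- lapply(j$pathways, function(pw)
    list(id = pw$id, name = pw$name,
         nodes = unlist(pw$nodes),
         edges = lapply(pw$edges, unlist)))
  bg <- if (is.null(j$background)) NULL else unlist(j$background)
  PathwaySet(pws, background = bg)
}

#' Write a pathway set as JSON
#'
#' @param ps a [PathwaySet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePathways <- function(ps, path) {
  j <- list(pathways = lapply(ps@pathways, function(pw)
    list(id = pw$id, name = pw$name, nodes = as.list(pw$nodes),
         edges = lapply(pw$edges, as.list))),
    background = as.list(ps@background))
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
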