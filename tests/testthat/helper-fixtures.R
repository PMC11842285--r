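# small in-code fixtures shared across test files

toy_table <- function(n_features = 3, n_samples = 4, classes = c("A", "B"),
                      intensity = NULL, snr = NULL) {
  if (is.null(intensity))
    intensity <- matrix(seq_len(n_features * n_samples) * 10,
                        n_features, n_samples)
  if (is.null(snr)) snr <- matrix(100, nrow(intensity), ncol(intensity))
  snr[is.na(intensity)] <- NA
  FootprintExperiment(
    intensity, snr,
    data.frame(role = "sample",
               injection_order = seq_len(ncol(intensity)),
               batch = "B1",
               class_label = rep_len(classes, ncol(intensity)),
               bio_rep = 1, tech_rep = seq_len(ncol(intensity)),
               dilution = 1))
}

# table with explicit QC columns at given injection orders
qc_table <- function(intensity, qc_cols, orders = seq_len(ncol(intensity)),
                     batch = "B1", snr = NULL) {
  if (is.null(snr)) { snr <- intensity * 0 + 100; snr[is.na(intensity)] <- NA }
  role <- rep("sample", ncol(intensity))
  role[qc_cols] <- "qc"
  cls <- rep(c("A", "B"), length.out = ncol(intensity))
  cls[qc_cols] <- NA
  FootprintExperiment(
    intensity, snr,
    data.frame(role = role, injection_order = orders, batch = batch,
               class_label = cls, bio_rep = 1,
               tech_rep = seq_len(ncol(intensity)), dilution = 1))
}

# two well-separated classes with planted discriminating features
separable_xy <- function(n_per_class = 14, p = 20, n_informative = 4,
                         effect = 4, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p, 10, sd), n, p,
              dimnames = list(NULL, sprintf("x%02d", seq_len(p))))
  y <- rep(c("A", "B"), each = n_per_class)
  X[y == "B", seq_len(n_informative)] <-
    X[y == "B", seq_len(n_informative)] + effect
  list(X = X, y = y)
}
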