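# Preprocessing: primary-arrival truncation of the multistatic record, the
# 64 x 144 waveform-matrix reshape, binary labeling, and stratified splitting.
# No per-sample normalization is applied anywhere: all samples share the same
# excitation and material conventions, so amplitudes are already on a common
# scale and carry scattering-strength information.

#' Detect the primary arrival of a record
#'
#' Global onset: the earliest sample index at which any off-diagonal channel's
#' absolute value exceeds `frac` times that channel's absolute maximum.  One
#' onset per record keeps the channels aligned.
#'
#' @param rec A [multistatic_record()].
#' @param frac Threshold fraction (default 0.1).
#' @return Integer onset index (1-based).
#' @export
detect_primary_arrival <- function(rec, frac = 0.1) {
  d <- dim(rec$S)
  Sm <- abs(matrix(rec$S, d[1] * d[2], d[3]))
  off <- which(outer(seq_len(d[1]), seq_len(d[2]), "!="))
  Sm <- Sm[off, , drop = FALSE]
  peaks <- apply(Sm, 1, max)
  if (all(peaks == 0)) stop("cannot detect an arrival on an identically zero record")
  keep <- peaks > 0
  hits <- Sm[keep, , drop = FALSE] > frac * peaks[keep]
  if (frac <= 0) hits <- Sm[keep, , drop = FALSE] > 0
  idx <- apply(hits, 1, function(z) which(z)[1])
  min(idx, na.rm = TRUE)
}

#' Truncate a record after the onset
#'
#' Keeps `L` samples from `onset` per channel, zero-padding at the tail when
#' the record ends early; the diagonal stays zero.
#'
#' @param rec A [multistatic_record()].
#' @param onset 1-based onset index (>= 1).
#' @param L Retained length (default 64).
#' @return Array `(n_antennas, n_antennas, L)`.
#' @export
truncate_record <- function(rec, onset, L = 64L) {
  if (onset < 1) stop("onset must be >= 1")
  d <- dim(rec$S)
  out <- array(0, c(d[1], d[2], L))
  keep <- min(L, max(0, d[3] - onset + 1))
  if (keep > 0)
    out[, , seq_len(keep)] <- rec$S[, , onset + seq_len(keep) - 1]
  out
}

#' Reshape a truncated tensor to the waveform matrix
#'
#' Flattens the transmitter-receiver channels transmitter-major: column
#' `c = n_rx * (i - 1) + j` holds the time series of channel `(i, j)`; rows
#' are time.  For the default 12-antenna, 64-sample configuration the result
#' is 64 x 144.
#'
#' @param trunc Array `(n_tx, n_rx, L)` from [truncate_record()].
#' @return Matrix `L x (n_tx * n_rx)`.
#' @export
reshape_waveform <- function(trunc) {
  d <- dim(trunc)
  if (length(d) != 3) stop("expected a (tx, rx, time) array")
  # aperm to (time, rx, tx) then flatten so that rx varies fastest within tx
  m <- matrix(aperm(trunc, c(3, 2, 1)), d[3], d[1] * d[2])
  colnames(m) <- NULL
  m
}

#' Invert the waveform-matrix reshape
#'
#' @param m Matrix `L x (n_tx * n_rx)`.
#' @param n_tx,n_rx Channel counts.
#' @return Array `(n_tx, n_rx, L)`.
#' @export
unshape_waveform <- function(m, n_tx = 12L, n_rx = 12L) {
  aperm(array(m, c(nrow(m), n_rx, n_tx)), c(3, 2, 1))
}

#' Binarize the three-class label
#'
#' Normal (0 lesions) maps to class 0; single and double hemorrhage (1 or 2
#' lesions) map uniformly to the abnormal class 1.
#'
#' @param label3 Integer vector with values in `{0, 1, 2}`.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_labels <- function(label3) {
  if (any(!label3 %in% 0:2)) stop("label3 values must be in {0, 1, 2}")
  as.integer(label3 != 0)
}

#' One paired multimodal sample
#'
#' @param image A [confocal_image()].
#' @param wave_matrix Waveform matrix from [reshape_waveform()].
#' @param label3 Original class (0/1/2).
#' @param sample_id Identifier.
#' @param seed Generating seed.
#' @return Object of class `sample_record` (with `label2 = binarize_labels(label3)`).
#' @export
sample_record <- function(image, wave_matrix, label3, sample_id, seed = NA_integer_) {
  structure(list(image = image, wave_matrix = wave_matrix,
                 label3 = as.integer(label3),
                 label2 = binarize_labels(label3),
                 sample_id = sample_id, seed = seed),
            class = "sample_record")
}

#' Stratified train / validation / test split
#'
#' Per class (stratified on the original three labels): the test set takes
#' `round(0.2 n_c)` samples (round half up), the remainder trains, and
#' `round(0.1 train_c)` of the training samples move to validation.  For the
#' default composition 2000/2000/808 this yields per-class test counts
#' 400/400/162 (962 in total).
#'
#' @param labels3 Integer vector of three-class labels, one per sample.
#' @param seed Split seed.
#' @param test_frac,val_frac Split ratios (defaults 0.2 and 0.1).
#' @return Object of class `split_spec` with disjoint `train_ids`, `val_ids`,
#'   `test_ids` (1-based indices into `labels3`) and the seed/ratios.
#' @export
split_dataset <- function(labels3, seed = 1L, test_frac = 0.2, val_frac = 0.1) {
  classes <- sort(unique(labels3))
  if (any(table(labels3) < 3)) stop("every class needs at least 3 samples")
  train <- integer(0); val <- integer(0); test <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      ids <- which(labels3 == cl)
      ids <- ids[sample.int(length(ids))]
      n_test <- round_half_up(test_frac * length(ids))
      test <- c(test, ids[seq_len(n_test)])
      rest <- ids[-seq_len(n_test)]
      n_val <- round_half_up(val_frac * length(rest))
      val <- c(val, rest[seq_len(n_val)])
      train <- c(train, rest[-seq_len(n_val)])
    }
  })
  structure(list(train_ids = sort(train), val_ids = sort(val),
                 test_ids = sort(test), seed = seed,
                 ratios = c(test = test_frac, val = val_frac)),
            class = "split_spec")
}

#' Full record-to-sample preprocessing
#'
#' Applies arrival detection, truncation and reshaping to one record and pairs
#' it with its confocal image.
#'
#' @param rec A [multistatic_record()].
#' @param image The paired [confocal_image()].
#' @param label3 Original class label.
#' @param sample_id Identifier.
#' @param frac Arrival threshold fraction.
#' @param L Truncation length.
#' @param seed Generating seed to record.
#' @return A [sample_record()].
#' @export
preprocess_record <- function(rec, image, label3, sample_id, frac = 0.1,
                              L = 64L, seed = NA_integer_) {
  onset <- detect_primary_arrival(rec, frac)
  wave <- reshape_waveform(truncate_record(rec, onset, L))
  sample_record(image, wave, label3, sample_id, seed)
}
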