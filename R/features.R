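#' Extract the per-sample fragmentomic feature vector
#'
#' Runs the per-sample stages on one `FragmentSet` and returns a named
#' numeric vector: `jagged_index`, global `fragment_score`, `mito_pct`,
#' per-bin coverage percentages (`cov_<bin>`) and per-bin fragment scores
#' (`fs_<bin>`), plus `entropy_bits` and `gquad_pct` when a reference is
#' supplied.
#'
#' @param fragset a `FragmentSet`.
#' @param bins `GenomeBins` for the binned stages.
#' @param reference optional reference (FASTA path, `FaFile`,
#'   `DNAStringSet`) enabling the sequence-based features.
#' @param threshold short/long length cut (bp).
#' @param min_len,max_len histogram window (bp).
#' @param peak_params [peak_detect_params()] for the jaggedness stage.
#' @param k end-motif length.
#' @return named numeric vector.
#' @export
extract_sample_features <- function(fragset, bins, reference = NULL,
                                    threshold = 100L, min_len = 20L,
                                    max_len = 400L,
                                    peak_params = peak_detect_params(),
                                    k = 4L) {
  hist <- build_size_histogram(fragset, min_len, max_len)
  bt <- assign_to_bins(fragset, bins, threshold)
  out <- c(jagged_index = jagged_index(hist, peak_params),
           fragment_score = fragment_score(fragset, threshold),
           mito_pct = tryCatch(mitochondrial_fraction(fragset),
                               error = function(e) NA_real_))
  cov <- stats::setNames(bt$coverage_pct, paste0("cov_", bt$bin_id))
  fs <- stats::setNames(bt$frag_score, paste0("fs_", bt$bin_id))
  out <- c(out, cov, fs)
  if (!is.null(reference)) {
    prof <- extract_end_motifs(fragset, reference, k)
    out <- c(out, entropy_bits = prof$entropy_bits,
             gquad_pct = as.numeric(gquad_prevalence(fragset, reference)))
  }
  out
}

#' Assemble a cohort feature matrix from FragmentSets
#'
#' @param fragsets named list of `FragmentSet`s (names become sample ids).
#' @param ... passed to [extract_sample_features()].
#' @inheritParams extract_sample_features
#' @return numeric matrix, samples x features.
#' @export
build_feature_matrix <- function(fragsets, bins, reference = NULL, ...) {
  stopifnot(length(fragsets) >= 1)
  rows <- lapply(fragsets, extract_sample_features, bins = bins,
                 reference = reference, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(fragsets)
  m
}
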