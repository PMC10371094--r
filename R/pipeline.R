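#' Read and validate a pipeline configuration
#'
#' YAML with a `samples` list (each entry `id`, `fragments` path, `group`),
#' a `chrom_sizes` path, optional `reference`, `annotation` (category BED),
#' `peaks` (narrowPeak) and `taxa` paths, a `params` block (`bin_size`,
#' `threshold`, `k`, `lookahead`, `delta`, `q`, `n_components`, `min_len`,
#' `max_len`), an `out_dir` and a `seed`.
#'
#' @param path YAML file, or an equivalent named list.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$samples) || length(cfg$samples) == 0L)
    stop("config: at least one sample is required")
  if (is.null(cfg$chrom_sizes)) stop("config: chrom_sizes is required")
  for (s in cfg$samples) {
    if (is.null(s$id) || is.null(s$fragments))
      stop("config: every sample needs id and fragments")
    if (!file.exists(s$fragments))
      stop("config: fragment file not found: ", s$fragments)
  }
  for (f in c("chrom_sizes", "reference", "annotation", "peaks", "taxa")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config: ", f, " file not found: ", cfg[[f]])
  }
  defaults <- list(bin_size = 1e6, threshold = 100L, k = 4L,
                   lookahead = 1L, delta = 1e-4, q = 0.05,
                   n_components = 20L, min_len = 20L, max_len = 400L)
  cfg$params <- utils::modifyList(defaults,
                                  as.list(cfg$params %||% list()))
  if (is.null(cfg$out_dir)) cfg$out_dir <- "cffrag_out"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the fragmentomics pipeline end to end
#'
#' Fragment loading, size histogram + jaggedness, binning + fragment
#' scores + mitochondrial fraction, end motifs + G-quadruplex scan (when a
#' reference is configured), peak and annotation profiles (when peak /
#' annotation inputs are configured), microbiome summaries (when a taxa
#' table is configured), then the cohort feature matrix, the two-group
#' feature scan and PCA integration (when two groups with at least two
#' samples each are present). Optional stages missing their inputs are
#' skipped with a warning; a failing mandatory stage aborts with the stage
#' name and leaves a `FAILED` marker in the output directory.
#'
#' @param config path to a YAML config or a list (see
#'   [read_pipeline_config()]).
#' @return list with `features`, `scan`, `pca`, `outputs` (paths written),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  con <- file(logfile, "w")
  on.exit(close(con), add = TRUE)
  set.seed(cfg$seed)
  outputs <- character()
  emit <- function(path) { outputs[[length(outputs) + 1L]] <<- path; path }
  fail <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "--",
                     conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  pipeline_log(con, "cffrag pipeline; seed=", cfg$seed,
               "; params: ", paste(names(p), unlist(p), sep = "=",
                                   collapse = " "))

  chrom_sizes <- tryCatch(read_chrom_sizes(cfg$chrom_sizes),
                          error = function(e) fail("chrom_sizes", e))
  bins <- tryCatch(make_bins(chrom_sizes, p$bin_size),
                   error = function(e) fail("binning", e))
  reference <- cfg$reference
  if (is.null(reference))
    pipeline_log(con, "no reference configured: end-motif and G-quad ",
                 "stages skipped")

  fragsets <- list(); groups <- character()
  for (s in cfg$samples) {
    fs <- tryCatch(load_fragments(s$fragments, chrom_sizes,
                                  sample_id = s$id,
                                  filters = frag_filters(
                                    min_len = p$min_len,
                                    max_len = p$max_len)),
                   error = function(e) fail(paste0("load:", s$id), e))
    fragsets[[s$id]] <- fs
    groups[s$id] <- s$group %||% NA_character_
    hist <- build_size_histogram(fs, p$min_len, p$max_len)
    emit(write_histogram_tsv(hist, file.path(
      cfg$out_dir, paste0(s$id, ".histogram.tsv"))))
    emit(write_bin_table(assign_to_bins(fs, bins, p$threshold), file.path(
      cfg$out_dir, paste0(s$id, ".bins.tsv"))))
    pipeline_log(con, "sample ", s$id, ": ", n_fragments(fs),
                 " fragments loaded")
  }

  features <- tryCatch(
    build_feature_matrix(fragsets, bins, reference = reference,
                         threshold = p$threshold, min_len = p$min_len,
                         max_len = p$max_len,
                         peak_params = peak_detect_params(p$lookahead,
                                                          p$delta),
                         k = p$k),
    error = function(e) fail("features", e))

  if (!is.null(cfg$peaks)) {
    pk <- tryCatch(read_narrowpeak(cfg$peaks),
                   error = function(e) fail("peaks", e))
    ppr <- vapply(fragsets, function(fs) as.numeric(peaks_per_read(pk, fs)),
                  numeric(1))
    features <- cbind(features, peaks_per_read = ppr)
    if (!is.null(cfg$annotation)) {
      ann <- read_annotation_bed(cfg$annotation)
      oe <- categorize_peaks(pk, ann, chrom_sizes)
      emit(local({
        f <- file.path(cfg$out_dir, "peak_categories.tsv")
        data.table::fwrite(oe, f, sep = "\t"); f
      }))
    }
  } else {
    pipeline_log(con, "no peaks configured: peak stage skipped")
  }

  if (!is.null(cfg$taxa)) {
    taxa <- tryCatch(read_taxa_table(cfg$taxa),
                     error = function(e) fail("microbiome", e))
    ids <- intersect(rownames(features), taxa_sample_cols(taxa))
    if (length(ids) == nrow(features)) {
      ad <- alpha_diversity(taxa)[rownames(features)]
      features <- cbind(features, alpha_diversity = ad)
    } else {
      warning("taxa table does not cover all samples; diversity skipped")
    }
  } else {
    pipeline_log(con, "no taxa table configured: microbiome stage skipped")
  }

  featfile <- file.path(cfg$out_dir, "features.tsv")
  data.table::fwrite(data.table::data.table(
    sample = rownames(features), group = groups[rownames(features)],
    features), featfile, sep = "\t")
  emit(featfile)

  scan <- NULL; pca <- NULL
  gf <- factor(groups[rownames(features)])
  if (nlevels(gf) == 2L && all(table(gf) >= 2L)) {
    scan <- tryCatch(feature_scan(features, gf, p$q),
                     error = function(e) fail("scan", e))
    emit(local({
      f <- file.path(cfg$out_dir, "scan.tsv")
      data.table::fwrite(scan, f, sep = "\t"); f
    }))
    pca <- tryCatch(pca_integrate(features, p$n_components),
                    error = function(e) fail("pca", e))
    emit(local({
      f <- file.path(cfg$out_dir, "pca_scores.tsv")
      data.table::fwrite(data.table::data.table(
        sample = rownames(pca$scores), group = as.character(gf),
        pca$scores), f, sep = "\t"); f
    }))
    emit(local({
      f <- file.path(cfg$out_dir, "pca_variance.tsv")
      data.table::fwrite(data.table::data.table(
        component = seq_along(pca$var_explained),
        var_explained_pct = pca$var_explained), f, sep = "\t"); f
    }))
  } else {
    pipeline_log(con, "fewer than two groups of >= 2 samples: scan/PCA ",
                 "skipped")
  }

  manifest <- file.path(cfg$out_dir, "manifest.tsv")
  writeLines(c("path", unlist(outputs)), manifest)
  pipeline_log(con, "pipeline complete: ", length(outputs),
               " outputs in ", cfg$out_dir)
  invisible(list(features = features, scan = scan, pca = pca,
                 outputs = unlist(outputs)))
}
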