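#' Read ENCODE narrowPeak (BED6+4) peak calls
#'
#' @param path narrowPeak file.
#' @return a `data.table` of class `PeakCalls` with 0-based half-open
#'   `start`/`end`, the opaque score fields, and a resolved `summit`
#'   position (`start + summit_offset`, or the interval midpoint when the
#'   offset is -1/absent).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "summit_offset")
  pk <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(pk) < 3L) stop("narrowPeak needs at least chrom/start/end")
  data.table::setnames(pk, seq_len(min(ncol(pk), 10L)),
                       cols[seq_len(min(ncol(pk), 10L))])
  if (!"summit_offset" %in% names(pk)) pk[, summit_offset := -1L]
  bad <- pk$end <= pk$start |
    (pk$summit_offset >= 0 & pk$summit_offset >= pk$end - pk$start)
  if (any(bad)) stop(sum(bad), " malformed peak record(s)")
  pk[, summit := ifelse(summit_offset >= 0, start + summit_offset,
                        floor((start + end) / 2))]
  data.table::setattr(pk, "class", c("PeakCalls", class(pk)))
  pk
}

#' Read a category-labelled element annotation BED
#'
#' BED with the category label (promoter, 5utr, exon, intron, ...) in the
#' 4th column; optional columns 5 (score) and 6 (strand).
#'
#' @param path BED file.
#' @return a `data.table` with `chrom`, `start`, `end`, `category`,
#'   optionally `strand`.
#' @export
read_annotation_bed <- function(path) {
  if (!file.exists(path)) stop("annotation BED not found: ", path)
  ann <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(ann) < 4L) stop("annotation BED needs a 4th (category) column")
  data.table::setnames(ann, 1:4, c("chrom", "start", "end", "category"))
  if (ncol(ann) >= 6L) data.table::setnames(ann, 6L, "strand")
  if (any(ann$end <= ann$start)) stop("annotation interval with end <= start")
  ann
}

#' Peaks-per-read ratio
#'
#' Number of called peaks divided by the number of fragments; attribute
#' `per_million` carries the same ratio scaled to peaks per million
#' fragments.
#'
#' @param peaks `PeakCalls` (or anything with one row per peak).
#' @param fragset a `FragmentSet`.
#' @export
peaks_per_read <- function(peaks, fragset) {
  n_frag <- n_fragments(fragset)
  if (n_frag == 0L) stop("fragment set is empty")
  r <- nrow(peaks) / n_frag
  structure(r, per_million = r * 1e6)
}

# Resolve annotation categories by precedence into disjoint GRanges:
# each base belongs to the highest-precedence category covering it.
resolve_categories <- function(annotation, precedence) {
  extra <- setdiff(unique(annotation$category), precedence)
  precedence <- c(setdiff(precedence, "intergenic"), extra)
  claimed <- GenomicRanges::GRanges()
  out <- list()
  for (cat in precedence) {
    a <- annotation[annotation$category == cat, ]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      a$chrom, IRanges::IRanges(a$start + 1, a$end)))
    gr <- GenomicRanges::setdiff(gr, claimed)
    claimed <- GenomicRanges::reduce(c(claimed, gr))
    out[[cat]] <- gr
  }
  out
}

#' Assign peaks to genomic-element categories and compute
#' observed/expected enrichment
#'
#' Each peak is assigned one category by the element overlapping its summit
#' position, resolving overlaps with the precedence order (default promoter
#' > 5utr > exon > intron; summits covered by no element are intergenic).
#' Expected shares are each category's fraction of the genome; the
#' intergenic fraction is the uncovered remainder.
#'
#' @param peaks `PeakCalls` from [read_narrowpeak()].
#' @param annotation annotation table from [read_annotation_bed()].
#' @param chrom_sizes named vector from [read_chrom_sizes()]; defines the
#'   genome size used for expected shares.
#' @param precedence category precedence, highest first; categories present
#'   in the annotation but not listed are inserted before `intergenic`.
#' @return a `data.table` with per-category `n_peaks`, `obs_share`,
#'   `genome_frac` and `obs_exp` (observed / expected; `NaN` for a
#'   zero-width category).
#' @export
categorize_peaks <- function(peaks, annotation, chrom_sizes,
                             precedence = c("promoter", "5utr", "exon",
                                            "intron", "intergenic")) {
  stopifnot(nrow(peaks) > 0)
  resolved <- resolve_categories(annotation, precedence)
  genome_size <- sum(chrom_sizes)

  summit_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$summit + 1, peaks$summit + 1))
  assigned <- rep("intergenic", nrow(peaks))
  unclaimed <- rep(TRUE, nrow(peaks))
  fracs <- c()
  for (cat in names(resolved)) {
    hit <- IRanges::overlapsAny(summit_gr, resolved[[cat]])
    assigned[unclaimed & hit] <- cat
    unclaimed <- unclaimed & !hit
    fracs[cat] <- sum(GenomicRanges::width(resolved[[cat]])) / genome_size
  }
  fracs["intergenic"] <- 1 - sum(fracs)

  cats <- c(names(resolved), "intergenic")
  n <- table(factor(assigned, levels = cats))
  out <- data.table::data.table(
    category = cats,
    n_peaks = as.integer(n),
    obs_share = as.numeric(n) / nrow(peaks),
    genome_frac = as.numeric(fracs[cats]))
  out[, obs_exp := ifelse(genome_frac > 0, obs_share / genome_frac, NaN)]
  out
}

#' Relative fragment coverage around element centers
#'
#' Per-base fragment coverage accumulated over windows centred on each
#' element's midpoint (orientation flipped for minus-strand elements),
#' averaged across elements and divided by the window-wide mean, so a flat
#' profile equals 1.0 and the curve always has mean 1.
#'
#' @param fragset a `FragmentSet`.
#' @param elements table with `chrom`, `start`, `end` and optional `strand`
#'   (e.g. one category of an annotation BED).
#' @param chrom_sizes named vector from [read_chrom_sizes()].
#' @param window half-width in bp (default 2000); the profile spans
#'   `[-window, +window]`.
#' @return a `data.table` with `offset` (bp from element center) and
#'   `relative_coverage`; attribute `n_elements` used.
#' @export
relative_coverage_profile <- function(fragset, elements, chrom_sizes,
                                      window = 2000L) {
  if (is.null(elements) || nrow(elements) == 0L)
    stop("no elements supplied")
  window <- as.integer(window)
  frg <- fragset$fragments
  frg <- frg[frg$chrom %in% names(chrom_sizes)]
  gr <- GenomicRanges::GRanges(
    frg$chrom, IRanges::IRanges(frg$start + 1, frg$end),
    seqlengths = chrom_sizes[unique(c(frg$chrom, elements$chrom))])
  cov <- GenomicRanges::coverage(gr)

  centers <- floor((elements$start + elements$end) / 2)
  width <- 2L * window + 1L
  acc <- numeric(width)
  n_used <- 0L
  for (i in seq_len(nrow(elements))) {
    ch <- elements$chrom[i]
    if (!ch %in% names(cov)) next
    lo <- centers[i] - window      # 0-based positions
    hi <- centers[i] + window
    if (lo < 0 || hi >= chrom_sizes[[ch]]) next  # window leaves the contig
    v <- as.numeric(cov[[ch]][(lo + 1):(hi + 1)])
    if (!is.null(elements$strand) && identical(elements$strand[i], "-"))
      v <- rev(v)
    acc <- acc + v
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable elements (windows leave the contigs?)")
  prof <- acc / n_used
  m <- mean(prof)
  if (m == 0) stop("no fragment coverage in any element window")
  out <- data.table::data.table(offset = -window:window,
                                relative_coverage = prof / m)
  data.table::setattr(out, "n_elements", n_used)
  out
}
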