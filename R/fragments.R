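#' @import data.table
#' @importFrom methods is
NULL

#' Fragment filter configuration
#'
#' Filters applied when loading aligned cfDNA fragments. Thresholds follow
#' common low-coverage cfDNA practice and are fully configurable: mapping
#' quality at least 20, fragment length inside 20-400 bp (the window that
#' contains both the sub-100 bp cfDNA population and the mononucleosomal
#' ~167 bp component), and chromosomes restricted to the primary assembly
#' (autosomes, chrX/chrY, chrM).
#'
#' @param min_mapq minimum mapping quality kept (records without a mapq,
#'   e.g. TSV input lacking the column, are kept).
#' @param min_len,max_len inclusive fragment-length window in bp.
#' @param chroms character vector of chromosomes to keep, or `NULL` to keep
#'   every chromosome present in the `chrom.sizes` table.
#' @return a list of class `frag_filters`.
#' @export
frag_filters <- function(min_mapq = 20L, min_len = 20L, max_len = 400L,
                         chroms = NULL) {
  stopifnot(min_mapq >= 0, min_len > 0, max_len >= min_len)
  structure(list(min_mapq = as.integer(min_mapq),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 chroms = chroms),
            class = "frag_filters")
}

#' Read a two-column chrom.sizes table
#'
#' @param path path to a TSV with columns chromosome name and length (bp).
#' @return named integer vector of chromosome lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  cs <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  if (nrow(cs) == 0L) stop("empty chrom.sizes: ", path)
  if (anyDuplicated(cs$chrom)) stop("duplicated chromosome in chrom.sizes")
  sizes <- as.numeric(cs$size)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome sizes must be positive numbers")
  stats::setNames(sizes, cs$chrom)
}

# Genomic compartment of a chromosome name (chr-prefix optional).
compartment_of <- function(chrom) {
  bare <- sub("^chr", "", chrom)
  out <- rep("unplaced", length(chrom))
  out[grepl("^[0-9]+$", bare)] <- "autosomal"
  out[bare %in% c("X", "Y")] <- "sexchrom"
  out[bare %in% c("M", "MT")] <- "mitochondrial"
  out
}

new_fragment_set <- function(sample_id, fragments, rejects = integer()) {
  frg <- data.table::as.data.table(fragments)
  counts <- c(autosomal = 0L, sexchrom = 0L, mitochondrial = 0L,
              unplaced = 0L)
  if (nrow(frg)) {
    tab <- table(factor(compartment_of(frg$chrom), levels = names(counts)))
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(sample_id = sample_id, fragments = frg,
                 counts_by_compartment = counts,
                 n_rejected = rejects),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat("FragmentSet '", x$sample_id, "': ", nrow(x$fragments),
      " fragments\n", sep = "")
  cc <- x$counts_by_compartment
  cat("  compartments:", paste(names(cc), cc, sep = "=", collapse = " "),
      "\n")
  if (length(x$n_rejected) && sum(x$n_rejected) > 0)
    cat("  rejected:", paste(names(x$n_rejected), x$n_rejected, sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Number of fragments in a FragmentSet
#' @param fragset a `FragmentSet`.
#' @export
n_fragments <- function(fragset) nrow(fragset$fragments)

# Apply filters + coordinate validation to a raw fragment table. Returns the
# retained table plus a named tally of rejected records.
filter_fragment_table <- function(frg, chrom_sizes, filters) {
  frg <- data.table::as.data.table(frg)
  rejects <- c(bad_interval = 0L, unknown_chrom = 0L, out_of_bounds = 0L,
               low_mapq = 0L, length_out_of_range = 0L,
               excluded_chrom = 0L)
  if (nrow(frg) == 0L) {
    frg[, length := integer()]
    return(list(fragments = frg, rejects = rejects))
  }
  frg[, start := as.numeric(start)][, end := as.numeric(end)]

  bad <- !is.finite(frg$start) | !is.finite(frg$end) | frg$end <= frg$start |
    frg$start < 0
  rejects["bad_interval"] <- sum(bad)
  frg <- frg[!bad]

  known <- frg$chrom %in% names(chrom_sizes)
  rejects["unknown_chrom"] <- sum(!known)
  frg <- frg[known]

  oob <- frg$end > chrom_sizes[frg$chrom]
  rejects["out_of_bounds"] <- sum(oob)
  frg <- frg[!oob]

  if (!is.null(filters$chroms)) {
    keep <- frg$chrom %in% filters$chroms
    rejects["excluded_chrom"] <- sum(!keep)
    frg <- frg[keep]
  }

  if ("mapq" %in% names(frg)) {
    lowq <- !is.na(frg$mapq) & frg$mapq < filters$min_mapq
    rejects["low_mapq"] <- sum(lowq)
    frg <- frg[!lowq]
  }

  frg[, length := as.integer(end - start)]
  lenout <- frg$length < filters$min_len | frg$length > filters$max_len
  rejects["length_out_of_range"] <- sum(lenout)
  frg <- frg[!lenout]

  chrom_order <- factor(frg$chrom, levels = names(chrom_sizes))
  frg <- frg[order(chrom_order, frg$start, frg$end)]
  list(fragments = frg, rejects = rejects)
}

#' Load aligned cfDNA fragments
#'
#' Reads fragments from a coordinate-sorted BAM (properly paired reads or
#' merged single-end reads) or from a plain fragment TSV with header
#' `chrom start end strand [mapq] [sequence]`, validates coordinates
#' against a chrom.sizes table, applies the filters and returns a
#' `FragmentSet` with per-compartment counts (autosomal, sex chromosome,
#' mitochondrial, unplaced) and a tally of rejected records.
#'
#' Coordinates are 0-based half-open throughout; BAM 1-based positions are
#' converted on ingest. For properly paired reads the fragment is the
#' reference span of the pair (leftmost start to rightmost end); for
#' single-end (pre-merged) reads it is the aligned reference span.
#' Duplicate removal is assumed done upstream.
#'
#' @param path input file.
#' @param chrom_sizes named vector from [read_chrom_sizes()].
#' @param format `"auto"` (by extension), `"tsv"` or `"bam"`.
#' @param filters a [frag_filters()] object.
#' @param sample_id sample label; defaults to the file base name.
#' @return a `FragmentSet`.
#' @export
load_fragments <- function(path, chrom_sizes, format = c("auto", "tsv", "bam"),
                           filters = frag_filters(), sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bam", "sam")) "bam" else "tsv"
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.(tsv|txt|bam|sam)(\\.gz)?$", "",
                     basename(path), ignore.case = TRUE)
  frg <- switch(format,
                tsv = read_fragment_tsv(path),
                bam = read_fragment_bam(path))
  res <- filter_fragment_table(frg, chrom_sizes, filters)
  new_fragment_set(sample_id, res$fragments, res$rejects)
}

read_fragment_tsv <- function(path) {
  frg <- data.table::fread(path, header = TRUE, sep = "\t")
  if (nrow(frg) == 0L && ncol(frg) == 0L)
    frg <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), strand = character())
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(frg)))
    stop("fragment TSV must have columns chrom, start, end")
  if (!"strand" %in% names(frg)) frg[, strand := "."]
  keep <- intersect(c("chrom", "start", "end", "strand", "mapq", "sequence"),
                    names(frg))
  frg[, ..keep]
}

read_fragment_bam <- function(path) {
  # SAM input is converted on the fly so text fixtures work everywhere.
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = TRUE)
    path <- bam
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  flag1 <- Rsamtools::scanBamFlag(isPaired = TRUE)
  n_paired <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(flag = flag1))$records
  if (n_paired > 0) {
    prs <- GenomicAlignments::readGAlignmentPairs(
      path, param = Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isProperPair = TRUE),
        what = "mapq"))
    gr <- GenomicRanges::granges(prs)  # pair reference span, first-read strand
    mapq <- pmin(S4Vectors::mcols(GenomicAlignments::first(prs))$mapq,
                 S4Vectors::mcols(GenomicAlignments::last(prs))$mapq)
  } else {
    aln <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
        what = "mapq"))
    gr <- GenomicRanges::granges(aln)
    mapq <- S4Vectors::mcols(aln)$mapq
  }
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    mapq = as.integer(mapq))
}

#' Write a FragmentSet to TSV
#'
#' @param fragset a `FragmentSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(fragset, path) {
  cols <- intersect(c("chrom", "start", "end", "strand", "mapq", "sequence"),
                    names(fragset$fragments))
  out <- fragset$fragments[, ..cols]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Fragment-length histogram in percent of reads
#'
#' 1-bp-resolution histogram of fragment lengths over `[min_len, max_len]`,
#' expressed as percent of the fragments inside that window, the substrate
#' of the jagged peak-valley index and of fragment-length plots (x axis:
#' fragment length; y axis: % reads).
#'
#' @param fragset a `FragmentSet` or an integer vector of fragment lengths.
#' @param min_len,max_len histogram window in bp.
#' @return a `data.table` of class `SizeHistogram` with columns `length`
#'   and `percent_reads` (summing to 100).
#' @export
build_size_histogram <- function(fragset, min_len = 20L, max_len = 400L) {
  lens <- if (inherits(fragset, "FragmentSet"))
    fragset$fragments$length else as.integer(fragset)
  if (length(lens) == 0L) stop("no fragments: cannot build a size histogram")
  stopifnot(max_len > min_len)
  inr <- lens[lens >= min_len & lens <= max_len]
  if (length(inr) == 0L)
    stop("no fragments inside [", min_len, ", ", max_len, "]")
  grid <- min_len:max_len
  counts <- tabulate(inr - min_len + 1L, nbins = length(grid))
  hist <- data.table::data.table(length = grid,
                                 percent_reads = 100 * counts / length(inr))
  data.table::setattr(hist, "class",
                      c("SizeHistogram", class(hist)))
  hist
}

#' Write / read a size histogram TSV (`length  percent_reads`)
#' @param hist a `SizeHistogram`.
#' @param path file path.
#' @return `path` (write) or a `SizeHistogram` (read).
#' @export
write_histogram_tsv <- function(hist, path) {
  data.table::fwrite(hist, path, sep = "\t")
  invisible(path)
}

#' @rdname write_histogram_tsv
#' @export
read_histogram_tsv <- function(path) {
  hist <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("length", "percent_reads") %in% names(hist)))
  data.table::setattr(hist, "class", c("SizeHistogram", class(hist)))
  hist
}
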