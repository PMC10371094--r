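#' @importFrom Biostrings readDNAStringSet DNAStringSet reverseComplement
#'   mkAllStrings
NULL

# Normalise a reference accessor: a FASTA path becomes an indexed FaFile;
# a DNAStringSet passes through. Both support ranged extraction below.
ref_accessor <- function(reference) {
  if (is(reference, "DNAStringSet") || is(reference, "FaFile"))
    return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    if (!file.exists(reference)) stop("reference FASTA not found: ", reference)
    fai <- paste0(reference, ".fai")
    if (!file.exists(fai)) Rsamtools::indexFa(reference)
    return(Rsamtools::FaFile(reference))
  }
  stop("reference must be a FASTA path, FaFile or DNAStringSet")
}

# Extract reference sequence for 0-based half-open intervals, as an
# uppercase character vector. Intervals must already be inside the contig.
get_ref_seqs <- function(ref, chrom, start, end) {
  if (is(ref, "FaFile")) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    return(toupper(as.character(Biostrings::getSeq(ref, gr))))
  }
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::extractAt(ref[[ch]],
                               IRanges::IRanges(start[i] + 1, end[i]))
    out[i] <- as.character(v)
  }
  toupper(out)
}

# Contig lengths of a reference accessor, named.
ref_seqlengths <- function(ref) {
  if (is(ref, "FaFile")) {
    info <- Rsamtools::seqinfo(ref)
    GenomeInfoDb::seqlengths(info)
  } else {
    stats::setNames(Biostrings::width(ref), names(ref))
  }
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fragment end-motif profile
#'
#' Profile of the k-mer (default 4-mer) motifs at fragment 5' ends, read
#' from the reference genome: each fragment contributes the k reference
#' bases at its left end (forward-strand 5' end) and the reverse complement
#' of the k bases at its right end (the 5' end of the complementary
#' strand). Motifs containing non-ACGT characters (reference Ns) are
#' discarded and tallied; fragments shorter than k or extending outside the
#' reference are skipped and tallied.
#'
#' @param fragset a `FragmentSet`.
#' @param reference FASTA path, `FaFile` or `DNAStringSet` covering the
#'   fragment intervals.
#' @param k motif length (default 4, giving the 256-motif vocabulary).
#' @return a `MotifProfile`: list with `counts` (named integer over the
#'   full 4^k vocabulary), `freqs` (normalised to sum 1), `entropy_bits`,
#'   `n_discarded`, `n_skipped`, `k`.
#' @export
extract_end_motifs <- function(fragset, reference, k = 4L) {
  ref <- ref_accessor(reference)
  frg <- fragset$fragments
  k <- as.integer(k)
  stopifnot(k >= 1L)

  lens <- ref_seqlengths(ref)
  usable <- frg$chrom %in% names(lens)
  frg <- frg[usable]
  inside <- rep(FALSE, nrow(frg))
  if (nrow(frg))
    inside <- frg$end <= lens[frg$chrom] & frg$start >= 0
  long_enough <- frg$length >= k
  keep <- inside & long_enough
  n_skipped <- sum(!usable) + sum(!keep)
  frg <- frg[keep]

  motifs <- character(0)
  if (nrow(frg)) {
    left <- get_ref_seqs(ref, frg$chrom, frg$start, frg$start + k)
    right <- revcomp_chr(get_ref_seqs(ref, frg$chrom, frg$end - k, frg$end))
    motifs <- c(left, right)
  }
  vocab <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  valid <- motifs %in% vocab
  counts <- table(factor(motifs[valid], levels = vocab))
  counts <- stats::setNames(as.integer(counts), vocab)
  new_motif_profile(counts, n_discarded = sum(!valid), n_skipped = n_skipped)
}

new_motif_profile <- function(counts, n_discarded = 0L, n_skipped = 0L) {
  total <- sum(counts)
  freqs <- if (total > 0) counts / total else counts * NA_real_
  prof <- structure(list(counts = counts, freqs = freqs,
                         entropy_bits = NA_real_,
                         n_discarded = n_discarded, n_skipped = n_skipped,
                         k = as.integer(round(log(length(counts), 4)))),
                    class = "MotifProfile")
  if (total > 0) prof$entropy_bits <- shannon_entropy(prof)
  prof
}

#' Build a MotifProfile from raw motif counts
#' @param counts named integer vector over the full `{A,C,G,T}^k` vocabulary
#'   (or a vector whose names are a subset of it; missing motifs count 0).
#' @param k motif length.
#' @return a `MotifProfile`.
#' @export
motif_profile <- function(counts, k = 4L) {
  vocab <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), as.integer(k))
  full <- stats::setNames(integer(length(vocab)), vocab)
  if (is.null(names(counts)) && length(counts) == length(vocab))
    names(counts) <- vocab
  if (!all(names(counts) %in% vocab))
    stop("counts contain motifs outside the {A,C,G,T}^k vocabulary")
  full[names(counts)] <- as.integer(counts)
  new_motif_profile(full)
}

#' @export
print.MotifProfile <- function(x, ...) {
  cat("MotifProfile: ", length(x$counts), " motifs (k=", x$k, "), ",
      sum(x$counts), " ends counted, entropy ",
      format(x$entropy_bits, digits = 4), " bits\n", sep = "")
  invisible(x)
}

#' Shannon entropy of a motif profile
#'
#' `H = -sum f log2 f` over motifs with positive frequency, in bits;
#' bounded by `[0, 2k]` for k-mers (8 bits for the 256-motif 4-mer
#' vocabulary).
#'
#' @param profile a `MotifProfile`, or a numeric vector of counts or
#'   frequencies.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(profile) {
  f <- if (inherits(profile, "MotifProfile")) profile$freqs else
    as.numeric(profile)
  if (all(f == 0) || anyNA(f)) stop("profile has no counted motifs")
  f <- f / sum(f)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' G-quadruplex scan parameters
#'
#' The default pattern is the canonical sequence definition: four runs of
#' at least three Gs separated by loops of 1-7 bases,
#' `G{3,}(N{1,7}G{3,}){3}`, scanned on both strands.
#'
#' @param min_run minimum G-run length (>= 2).
#' @param max_loop maximum loop length (>= 1).
#' @param n_runs number of G runs (>= 4).
#' @param scan_both_strands also scan the reverse complement.
#' @export
gquad_params <- function(min_run = 3L, max_loop = 7L, n_runs = 4L,
                         scan_both_strands = TRUE) {
  stopifnot(min_run >= 2, max_loop >= 1, n_runs >= 4)
  structure(list(min_run = as.integer(min_run),
                 max_loop = as.integer(max_loop),
                 n_runs = as.integer(n_runs),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "GQuadParams")
}

gquad_regex <- function(params) {
  sprintf("G{%d,}([ACGT]{1,%d}G{%d,}){%d}",
          params$min_run, params$max_loop, params$min_run,
          params$n_runs - 1L)
}

#' G-quadruplex prevalence among fragments
#'
#' Percent of fragments whose sequence contains at least one G-quadruplex
#' motif match (on either strand when `scan_both_strands`). Sequences are
#' taken from the `sequence` column when present, otherwise read from the
#' reference.
#'
#' @param fragset a `FragmentSet`.
#' @param reference FASTA path, `FaFile` or `DNAStringSet`; may be `NULL`
#'   when fragments carry sequences.
#' @param params a [gquad_params()] object.
#' @return percentage of scanned fragments with a match; attribute
#'   `n_scanned` carries the denominator.
#' @export
gquad_prevalence <- function(fragset, reference = NULL,
                             params = gquad_params()) {
  frg <- fragset$fragments
  if ("sequence" %in% names(frg) && !is.null(frg$sequence) &&
      !all(is.na(frg$sequence))) {
    seqs <- toupper(frg$sequence[!is.na(frg$sequence)])
  } else {
    if (is.null(reference))
      stop("fragments carry no sequence; a reference is required")
    ref <- ref_accessor(reference)
    lens <- ref_seqlengths(ref)
    ok <- frg$chrom %in% names(lens)
    frg <- frg[ok]
    frg <- frg[frg$end <= lens[frg$chrom]]
    if (nrow(frg) == 0L) return(structure(NaN, n_scanned = 0L))
    seqs <- get_ref_seqs(ref, frg$chrom, frg$start, frg$end)
  }
  if (length(seqs) == 0L) return(structure(NaN, n_scanned = 0L))
  pat <- gquad_regex(params)
  hit <- grepl(pat, seqs, perl = TRUE)
  if (params$scan_both_strands)
    hit <- hit | grepl(pat, revcomp_chr(seqs), perl = TRUE)
  structure(100 * mean(hit), n_scanned = length(seqs))
}

#' Write a motif profile TSV (`motif count freq`)
#' @param profile a `MotifProfile`.
#' @param path output path.
#' @export
write_motif_profile <- function(profile, path) {
  data.table::fwrite(
    data.table::data.table(motif = names(profile$counts),
                           count = profile$counts,
                           freq = profile$freqs),
    path, sep = "\t")
  invisible(path)
}
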