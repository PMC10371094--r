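#' Autosome names present in a chrom.sizes table
#' @param chrom_sizes named vector from [read_chrom_sizes()].
#' @return character vector in table order.
#' @export
autosome_names <- function(chrom_sizes) {
  names(chrom_sizes)[compartment_of(names(chrom_sizes)) == "autosomal"]
}

#' Tile chromosomes into fixed-size bins
#'
#' Contiguous 0-based half-open bins from position 0; the last bin of each
#' chromosome is truncated at the chromosome end, so a chromosome of length
#' L yields `ceiling(L / bin_size)` bins. With the bundled GRCh38
#' chrom.sizes and the default 1-Mb bin size, chr1-22 tile into 2887 bins.
#'
#' @param chrom_sizes named vector from [read_chrom_sizes()].
#' @param bin_size bin width in bp (default 1e6).
#' @param chroms chromosomes to tile; default all autosomes in the table.
#' @return a `data.table` of class `GenomeBins` with columns `chrom`,
#'   `start`, `end`, `bin_id`; attribute `bin_size`.
#' @export
make_bins <- function(chrom_sizes, bin_size = 1e6,
                      chroms = autosome_names(chrom_sizes)) {
  stopifnot(length(chrom_sizes) > 0, bin_size > 0)
  if (length(chroms) == 0L)
    stop("no chromosomes to tile (no autosomes in chrom.sizes?)")
  missing <- setdiff(chroms, names(chrom_sizes))
  if (length(missing))
    stop("chromosome(s) not in chrom.sizes: ", paste(missing, collapse = ", "))
  pieces <- lapply(chroms, function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + bin_size, len))
  })
  bins <- data.table::rbindlist(pieces)
  bins[, bin_id := sprintf("%s:%s-%s", chrom, as.integer64maybe(start),
                           as.integer64maybe(end))]
  data.table::setattr(bins, "bin_size", bin_size)
  data.table::setattr(bins, "class", c("GenomeBins", class(bins)))
  bins
}

# sprintf("%d") needs integers; genome coordinates fit in doubles but not
# 32-bit ints, so format through non-scientific character instead.
as.integer64maybe <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

#' Count fragments per genome bin
#'
#' Each fragment is assigned to exactly one bin by its midpoint
#' `floor((start + end) / 2)` and classified as short (`length <
#' threshold`) or long (`length >= threshold`). Fragments on chromosomes
#' outside the bin set are skipped and tallied in attribute `n_skipped`.
#'
#' @param fragset a `FragmentSet`.
#' @param bins a `GenomeBins` from [make_bins()].
#' @param threshold short/long fragment-length cut in bp (default 100;
#'   length exactly 100 counts as long).
#' @return a `data.table` of class `BinTable` with per-bin `n_short`,
#'   `n_long`, `n_total`, `coverage_pct` (percent of counted fragments,
#'   summing to 100) and `frag_score` (`n_short / n_long`, `NaN` where no
#'   long fragments).
#' @export
assign_to_bins <- function(fragset, bins, threshold = 100L) {
  frg <- fragset$fragments
  bin_size <- attr(bins, "bin_size")
  out <- data.table::as.data.table(bins)[, .(chrom, start, end, bin_id)]
  out[, `:=`(n_short = 0L, n_long = 0L)]

  in_bins <- frg$chrom %in% unique(bins$chrom)
  n_skipped <- sum(!in_bins)
  frg <- frg[in_bins]
  if (nrow(frg)) {
    mid <- floor((frg$start + frg$end) / 2)
    key <- sprintf("%s:%s", frg$chrom,
                   format(floor(mid / bin_size), scientific = FALSE,
                          trim = TRUE))
    binkey <- sprintf("%s:%s", out$chrom,
                      format(floor(out$start / bin_size),
                             scientific = FALSE, trim = TRUE))
    idx <- match(key, binkey)
    short <- frg$length < threshold
    cnt_s <- tabulate(idx[short], nbins = nrow(out))
    cnt_l <- tabulate(idx[!short], nbins = nrow(out))
    out[, `:=`(n_short = cnt_s, n_long = cnt_l)]
  }
  out[, n_total := n_short + n_long]
  tot <- sum(out$n_total)
  out[, coverage_pct := if (tot > 0) 100 * n_total / tot else NA_real_]
  out[, frag_score := ifelse(n_long > 0, n_short / n_long, NaN)]
  data.table::setattr(out, "threshold", as.integer(threshold))
  data.table::setattr(out, "n_skipped", n_skipped)
  data.table::setattr(out, "class", c("BinTable", class(out)))
  out
}

#' Global short/long fragmentomic score
#'
#' Ratio of fragments shorter than `threshold` (default 100 bp) to those at
#' least `threshold` long. Lower scores indicate a shift toward longer
#' (e.g. mononucleosomal) fragments.
#'
#' @param x a `FragmentSet`, an integer vector of lengths, or a `BinTable`
#'   (per-bin scores are then returned as stored).
#' @param threshold length cut in bp.
#' @return numeric scalar (global) or numeric vector (per bin, `NaN` where
#'   a bin has no long fragments).
#' @export
fragment_score <- function(x, threshold = 100L) {
  if (inherits(x, "BinTable")) return(x$frag_score)
  lens <- if (inherits(x, "FragmentSet")) x$fragments$length else
    as.numeric(x)
  n_long <- sum(lens >= threshold)
  if (n_long == 0L) return(NaN)
  sum(lens < threshold) / n_long
}

#' Mitochondrial read fraction
#'
#' Percent of human-mapped fragments on the mitochondrial genome:
#' `100 * n_chrM / (n_chrM + n_nuclear)` with nuclear = autosomes + sex
#' chromosomes.
#'
#' @param fragset a `FragmentSet` with compartment counts populated.
#' @return percentage in `[0, 100]`.
#' @export
mitochondrial_fraction <- function(fragset) {
  cc <- fragset$counts_by_compartment
  human <- cc[["mitochondrial"]] + cc[["autosomal"]] + cc[["sexchrom"]]
  if (human == 0L) stop("no human-mapped fragments")
  100 * cc[["mitochondrial"]] / human
}

#' Write a bin table (`chrom start end bin_id n_short n_long coverage_pct
#' frag_score`)
#' @param bintab a `BinTable`.
#' @param path output path.
#' @export
write_bin_table <- function(bintab, path) {
  data.table::fwrite(
    bintab[, .(chrom, start, end, bin_id, n_short, n_long, coverage_pct,
               frag_score)],
    path, sep = "\t")
  invisible(path)
}
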