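# Shared fixtures and independent oracles, all built in code at test time.

toy_sizes <- c(chr1 = 2.5e6, chr2 = 1e6, chrM = 16569)

write_toy_chrom_sizes <- function(sizes = toy_sizes,
                                  path = tempfile(fileext = ".chrom.sizes")) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  path
}

write_fragment_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

as_hist <- function(lengths, percent) {
  h <- data.table::data.table(length = lengths, percent_reads = percent)
  data.table::setattr(h, "class", c("SizeHistogram", class(h)))
  h
}

# Brute-force neighbour-comparison extremum oracle: an interior point is a
# peak when strictly greater than both neighbours, a valley when strictly
# smaller than both.
neighbor_extrema <- function(y, x = seq_along(y)) {
  n <- length(y)
  i <- 2:(n - 1)
  peaks <- i[y[i] > y[i - 1] & y[i] > y[i + 1]]
  valleys <- i[y[i] < y[i - 1] & y[i] < y[i + 1]]
  list(peak_x = x[peaks], valley_x = x[valleys])
}

# Independent step-by-step two-stage step-up procedure (oracle for bky_fdr):
# literal transcription of the published algorithm using a naive step-up.
oracle_bky <- function(p, q = 0.05) {
  m <- length(p)
  stepup <- function(p, level) {
    o <- order(p)
    rej <- logical(m)
    k <- 0
    for (i in seq_len(m)) if (p[o[i]] <= i * level / m) k <- i
    if (k > 0) rej[o[1:k]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  s1 <- stepup(p, q1)
  r1 <- sum(s1)
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  stepup(p, q1 * m / (m - r1))
}

# Exhaustive pair-counting AUC oracle (ties count half).
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Minimal paired-end SAM fixture: returns list(path, n_expected_fragments,
# fragment spans) for hand-verified loading.  Coordinates 1-based SAM.
write_sam_fixture <- function(path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:2500000",
           "@SQ\tSN:chrM\tLN:16569")
  rec <- function(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen) {
    paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
          "*", "*", sep = "\t")
  }
  # three proper pairs (fragments 100, 60 and 167 bp) + one low-mapq pair
  body <- c(
    rec("p1", 99, "chr1", 1001, 60, "50M", "=", 1051, 100),
    rec("p1", 147, "chr1", 1051, 60, "50M", "=", 1001, -100),
    rec("p2", 99, "chr1", 5001, 60, "40M", "=", 5021, 60),
    rec("p2", 147, "chr1", 5021, 60, "40M", "=", 5001, -60),
    rec("p4", 99, "chr1", 9001, 5, "50M", "=", 9051, 100),
    rec("p4", 147, "chr1", 9051, 5, "50M", "=", 9001, -100),
    rec("p3", 99, "chrM", 101, 60, "80M", "=", 188, 167),
    rec("p3", 147, "chrM", 188, 60, "80M", "=", 101, -167))
  writeLines(c(hdr, body), path)
  list(path = path,
       spans = data.frame(chrom = c("chr1", "chr1", "chrM"),
                          start = c(1000, 5000, 100),
                          end = c(1100, 5060, 267)))
}

# Small deterministic fragment set on the toy genome.
toy_fragset <- function(n = 2000, seed = 11, mito = 0.05) {
  set.seed(seed)
  tcs <- toy_sizes
  bins <- make_bins(tcs, bin_size = 1e6)
  simulate_fragments(sample_params(n_fragments = n, mito_fraction = mito),
                     bins, tcs, seed = seed)
}
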