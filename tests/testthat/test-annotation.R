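write_narrowpeak_fixture <- function(df, path = tempfile(fileext = ".narrowPeak")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

test_that("narrowPeak parsing resolves summits", {
  pk <- read_narrowpeak(write_narrowpeak_fixture(data.frame(
    chrom = "chrA", start = c(100, 500), end = c(200, 700),
    name = c("p1", "p2"), score = 0, strand = ".",
    signalValue = 5, pValue = 2, qValue = 1,
    summit_offset = c(30, -1))))
  expect_equal(pk$summit, c(130, 600))
  expect_error(read_narrowpeak(write_narrowpeak_fixture(data.frame(
    chrom = "chrA", start = 100, end = 200, name = "x", score = 0,
    strand = ".", sv = 1, p = 1, q = 1, summit_offset = 150))),
    "malformed")
})

test_that("peaks-per-read is the direct ratio", {
  fs <- toy_fragset(n = 3500)
  pk <- data.table::data.table(chrom = rep("chrA", 7), start = 1:7 * 1000,
                               end = 1:7 * 1000 + 200)
  r <- peaks_per_read(pk, fs)
  expect_equal(as.numeric(r), 7 / 3500)
  expect_equal(attr(r, "per_million"), 7 / 3500 * 1e6)
  expect_equal(as.numeric(peaks_per_read(pk[0], fs)), 0)
  empty <- structure(list(sample_id = "e",
                          fragments = fs$fragments[0],
                          counts_by_compartment = c(autosomal = 0L,
                                                    sexchrom = 0L,
                                                    mitochondrial = 0L,
                                                    unplaced = 0L)),
                     class = "FragmentSet")
  expect_error(peaks_per_read(pk, empty), "empty")
})

test_that("category observed/expected follows the toy hand arithmetic", {
  # 1 Mb toy genome: promoter 100 kb, intron 900 kb
  cs <- c(chrA = 1e6)
  ann <- data.table::data.table(
    chrom = "chrA", start = c(0, 1e5), end = c(1e5, 1e6),
    category = c("promoter", "intron"))
  # 8 promoter-summit + 2 intron-summit peaks
  pk <- data.table::data.table(
    chrom = "chrA",
    start = c(seq(1000, 80000, length.out = 8), 2e5, 5e5),
    end = c(seq(1000, 80000, length.out = 8), 2e5, 5e5) + 500,
    name = ".", score = 0, strand = ".", sv = 0, p = 0, q = 0,
    summit_offset = 10)
  pk[, summit := start + summit_offset]
  oe <- categorize_peaks(pk, ann, cs)
  expect_equal(oe$obs_exp[oe$category == "promoter"], 0.8 / 0.1)
  expect_equal(oe$obs_exp[oe$category == "intron"], 0.2 / 0.9)
  expect_equal(sum(oe$n_peaks), nrow(pk))

  # all peaks in a 10%-of-genome category
  ann2 <- ann[category == "promoter"]
  oe2 <- categorize_peaks(pk[1:8], ann2, cs)
  expect_equal(oe2$obs_exp[oe2$category == "promoter"], 10)
  # genome fractions sum to 1 with intergenic as remainder
  expect_equal(sum(oe2$genome_frac), 1)
})

test_that("summit precedence resolves overlapping annotations", {
  cs <- c(chrA = 1e6)
  ann <- data.table::data.table(
    chrom = "chrA", start = c(0, 0), end = c(5e4, 1e5),
    category = c("promoter", "exon"))
  pk <- data.table::data.table(chrom = "chrA", start = c(1e4, 7e4),
                               end = c(1e4, 7e4) + 100, name = ".",
                               score = 0, strand = ".", sv = 0, p = 0,
                               q = 0, summit_offset = 0)
  pk[, summit := start]
  oe <- categorize_peaks(pk, ann, cs)
  expect_equal(oe$n_peaks[oe$category == "promoter"], 1L)
  expect_equal(oe$n_peaks[oe$category == "exon"], 1L)
  # exon genome share excludes the promoter-claimed bases
  expect_equal(oe$genome_frac[oe$category == "exon"], 5e4 / 1e6)
})

test_that("uniformly placed peaks give share-weighted O/E near 1", {
  set.seed(71)
  cs <- c(chrA = 1e6)
  ann <- data.table::data.table(
    chrom = "chrA", start = c(0, 2e5, 6e5), end = c(2e5, 6e5, 9e5),
    category = c("promoter", "exon", "intron"))
  oes <- replicate(40, {
    s <- sample(0:(1e6 - 200), 150)
    pk <- data.table::data.table(chrom = "chrA", start = s, end = s + 200,
                                 name = ".", score = 0, strand = ".",
                                 sv = 0, p = 0, q = 0, summit_offset = 100)
    pk[, summit := start + 100]
    oe <- categorize_peaks(pk, ann, cs)
    sum(oe$obs_exp * oe$genome_frac, na.rm = TRUE)
  })
  expect_equal(mean(oes), 1, tolerance = 0.02)
})

test_that("relative coverage profiles are normalised to mean 1", {
  cs <- c(chrA = 1e5)
  # uniform tiling coverage -> flat curve at 1
  frg <- data.table::data.table(
    chrom = "chrA", start = seq(0, 99900, by = 100),
    end = seq(0, 99900, by = 100) + 100, strand = "+", length = 100L)
  fs <- structure(list(sample_id = "u", fragments = frg,
                       counts_by_compartment = c(autosomal = nrow(frg),
                                                 sexchrom = 0L,
                                                 mitochondrial = 0L,
                                                 unplaced = 0L)),
                  class = "FragmentSet")
  el <- data.table::data.table(chrom = "chrA", start = 4e4, end = 4e4 + 100)
  prof <- relative_coverage_profile(fs, el, cs, window = 500)
  expect_equal(prof$relative_coverage, rep(1, 1001), tolerance = 1e-9)

  # coverage only in the central 100 bp
  center <- 4e4 + 50
  frg2 <- data.table::data.table(chrom = "chrA",
                                 start = rep(center - 50, 20),
                                 end = rep(center + 50, 20),
                                 strand = "+", length = 100L)
  fs2 <- structure(list(sample_id = "c", fragments = frg2,
                        counts_by_compartment = c(autosomal = 20L,
                                                  sexchrom = 0L,
                                                  mitochondrial = 0L,
                                                  unplaced = 0L)),
                   class = "FragmentSet")
  prof2 <- relative_coverage_profile(fs2, el, cs, window = 500)
  expect_equal(mean(prof2$relative_coverage), 1, tolerance = 1e-9)
  expect_equal(prof2$relative_coverage[prof2$offset == 400], 0)
  expect_gt(prof2$relative_coverage[prof2$offset == 0], 1)
  # piecewise arithmetic: central value = 1001 / 100
  expect_equal(prof2$relative_coverage[prof2$offset == 0], 1001 / 100)

  expect_error(relative_coverage_profile(fs, el[0], cs), "no elements")
})

test_that("a planted central depletion is recovered as a dip", {
  set.seed(73)
  tcs <- c(chrA = 5e5)
  bins <- make_bins(tcs, bin_size = 1e6, chroms = "chrA")
  centers <- seq(5e4, 4.5e5, by = 5e4)
  dips <- vapply(1:6, function(s) {
    fs <- simulate_fragments(sample_params(n_fragments = 30000,
                                           mito_fraction = 0),
                             bins, tcs, seed = 200 + s)
    # remove fragments whose midpoint falls within 300 bp of a center
    mid <- (fs$fragments$start + fs$fragments$end) / 2
    near <- vapply(mid, function(m) any(abs(m - centers) < 300), logical(1))
    fs$fragments <- fs$fragments[!near]
    el <- data.table::data.table(chrom = "chrA", start = centers - 50,
                                 end = centers + 50)
    prof <- relative_coverage_profile(fs, el, tcs, window = 1000)
    ctr <- mean(prof$relative_coverage[abs(prof$offset) <= 100])
    flank <- mean(prof$relative_coverage[abs(prof$offset) > 700])
    ctr < flank
  }, logical(1))
  expect_true(all(dips))
})
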