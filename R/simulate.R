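#' Synthetic-sample parameters
#'
#' Parameters of one simulated salivary-cfDNA sample. The fragment-length
#' model is a two-component mixture: a sub-100-bp population centred at
#' `short_mode` whose density is modulated by a 10-bp periodic comb of
#' amplitude `comb_amplitude` (truncated cosine, negative part clipped,
#' renormalised), plus a `mono_weight` proportion of a mononucleosomal
#' Normal(167, 15) component, all truncated to `[20, 400]` bp at 1-bp
#' resolution. Fragments are placed on genome bins with a multinomial
#' weighted by `telomere_bias` on each chromosome's terminal bins, a
#' `mito_fraction` proportion is placed on the mitochondrial contig, and an
#' optional `motif_bias` snaps a fraction of left fragment ends onto
#' reference positions carrying favoured 4-mers.
#'
#' @param n_fragments fragments per sample.
#' @param short_mode,short_spread mode and s.d. (bp) of the short component.
#' @param mono_weight proportion of the ~167 bp component, in `[0, 1]`.
#' @param comb_amplitude 10-bp comb amplitude `a` in `[0, 1]`.
#' @param mito_fraction proportion of fragments on the mitochondrial contig.
#' @param telomere_bias multiplicative placement weight of each
#'   chromosome's first and last bin (1 = no bias).
#' @param motif_bias `NULL`, or `list(motifs = <4-mers>, weight = <prob>)`:
#'   each nuclear fragment's left end is snapped, with probability
#'   `weight`, onto a reference occurrence of one of the favoured motifs
#'   (requires a reference at simulation time).
#' @param taxa_composition optional named probability vector over taxa for
#'   the paired microbial community.
#' @return list of class `SampleParams`.
#' @export
sample_params <- function(n_fragments = 50000L, short_mode = 60,
                          short_spread = 12, mono_weight = 0.05,
                          comb_amplitude = 0.5, mito_fraction = 0.03,
                          telomere_bias = 1, motif_bias = NULL,
                          taxa_composition = NULL) {
  stopifnot(n_fragments > 0, short_mode > 0, short_spread > 0,
            mono_weight >= 0, mono_weight <= 1,
            comb_amplitude >= 0, comb_amplitude <= 1,
            mito_fraction >= 0, mito_fraction <= 1,
            telomere_bias > 0)
  if (!is.null(taxa_composition))
    stopifnot(abs(sum(taxa_composition) - 1) < 1e-8)
  if (!is.null(motif_bias))
    stopifnot(is.list(motif_bias), !is.null(motif_bias$motifs),
              motif_bias$weight >= 0, motif_bias$weight <= 1)
  structure(list(n_fragments = as.integer(n_fragments),
                 short_mode = short_mode, short_spread = short_spread,
                 mono_weight = mono_weight,
                 comb_amplitude = comb_amplitude,
                 mito_fraction = mito_fraction,
                 telomere_bias = telomere_bias,
                 motif_bias = motif_bias,
                 taxa_composition = taxa_composition),
            class = "SampleParams")
}

#' Fragment-length probability mass function of the simulator
#'
#' Analytic pmf of the mixture described in [sample_params()], on the
#' integer grid `min_len:max_len`. Exposed so tests can compare sampled
#' masses against closed-form expectations.
#'
#' @param params a `SampleParams`.
#' @param min_len,max_len grid bounds (bp).
#' @return numeric vector over `min_len:max_len`, summing to 1.
#' @export
length_pmf <- function(params, min_len = 20L, max_len = 400L) {
  grid <- min_len:max_len
  short <- stats::dnorm(grid, params$short_mode, params$short_spread)
  comb <- pmax(0, 1 + params$comb_amplitude * cos(2 * pi * grid / 10))
  short <- short * comb
  short <- short / sum(short)
  mono <- stats::dnorm(grid, 167, 15)
  mono <- mono / sum(mono)
  pmf <- (1 - params$mono_weight) * short + params$mono_weight * mono
  pmf / sum(pmf)
}

#' Generate a toy reference genome
#'
#' Random-composition contigs (default GC 0.45) used by the simulator when
#' end-motif or G-quadruplex features are wanted without a real genome.
#' Clearly synthetic: not modelled on any assembly.
#'
#' @param chrom_sizes named vector of contig lengths (bp).
#' @param gc GC content of the random bases.
#' @param seed optional RNG seed.
#' @return a `DNAStringSet`.
#' @export
simulate_reference <- function(chrom_sizes = toy_chrom_sizes(), gc = 0.45,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_sizes, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_sizes)))
}

#' Toy genome sizes used by the simulator
#'
#' Two autosomal contigs plus a mitochondrial contig of the human chrM
#' length; small enough that a whole cohort simulates in seconds.
#' @export
toy_chrom_sizes <- function() {
  c(chr1 = 3e6, chr2 = 2e6, chrM = 16569)
}

# 0-based start positions (per chromosome) whose reference 4-mer is one of
# the favoured motifs.
motif_start_positions <- function(reference, motifs) {
  ref <- ref_accessor(reference)
  stopifnot(is(ref, "DNAStringSet"))
  out <- list()
  for (ch in names(ref)) {
    hits <- unlist(lapply(motifs, function(m) {
      IRanges::start(Biostrings::matchPattern(m, ref[[ch]]))
    }))
    out[[ch]] <- sort(hits) - 1L
  }
  out
}

#' Simulate one sample's fragments
#'
#' Draws fragment lengths from the analytic mixture pmf ([length_pmf()]),
#' places a `mito_fraction` binomial share on the mitochondrial contig
#' (uniform position) and the rest on the supplied genome bins via a
#' telomere-weighted multinomial with uniform position within the bin
#' (starts clamped so fragments stay inside the contig). Deterministic
#' given `seed`.
#'
#' @param params a `SampleParams`.
#' @param bins `GenomeBins` over the nuclear contigs (from [make_bins()]).
#' @param chrom_sizes named contig lengths; must include the binned contigs
#'   and, when `mito_fraction > 0`, a mitochondrial contig (chrM/MT).
#' @param reference optional reference (needed only for `motif_bias`).
#' @param sample_id sample label.
#' @param seed optional RNG seed.
#' @return a `FragmentSet`.
#' @export
simulate_fragments <- function(params, bins, chrom_sizes,
                               reference = NULL, sample_id = "sim",
                               seed = NULL) {
  stopifnot(inherits(params, "SampleParams"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_fragments
  pmf <- length_pmf(params)
  grid <- 20:400
  lens <- sample(grid, n, replace = TRUE, prob = pmf)

  mito_chrom <- names(chrom_sizes)[
    compartment_of(names(chrom_sizes)) == "mitochondrial"]
  n_mito <- if (params$mito_fraction > 0 && length(mito_chrom)) {
    stats::rbinom(1, n, params$mito_fraction)
  } else 0L

  # nuclear placement: telomere-weighted multinomial over bins
  bw <- as.numeric(bins$end - bins$start)
  terminal <- logical(nrow(bins))
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    terminal[c(i[1L], i[length(i)])] <- TRUE
  }
  w <- bw * ifelse(terminal, params$telomere_bias, 1)
  n_nuc <- n - n_mito
  bin_idx <- sample.int(nrow(bins), n_nuc, replace = TRUE, prob = w)
  start <- floor(bins$start[bin_idx] +
                   stats::runif(n_nuc) * (bins$end[bin_idx] -
                                            bins$start[bin_idx]))
  chrom <- bins$chrom[bin_idx]
  len_nuc <- lens[seq_len(n_nuc)]
  start <- pmin(start, chrom_sizes[chrom] - len_nuc)  # keep inside contig
  start <- pmax(start, 0)

  if (!is.null(params$motif_bias) && params$motif_bias$weight > 0) {
    if (is.null(reference))
      stop("motif_bias requires a reference")
    pos <- motif_start_positions(reference, params$motif_bias$motifs)
    snap <- stats::runif(n_nuc) < params$motif_bias$weight
    for (ch in unique(chrom)) {
      cand <- pos[[ch]]
      cand <- cand[cand + 400 < chrom_sizes[[ch]]]
      i <- which(snap & chrom == ch)
      if (length(i) && length(cand))
        start[i] <- cand[sample.int(length(cand), length(i),
                                    replace = TRUE)]
    }
  }

  frg <- data.table::data.table(chrom = chrom, start = start,
                                end = start + len_nuc,
                                strand = sample(c("+", "-"), n_nuc,
                                                replace = TRUE))
  if (n_mito > 0L) {
    mlen <- lens[(n_nuc + 1L):n]
    msz <- chrom_sizes[[mito_chrom[1L]]]
    mlen <- pmin(mlen, msz)
    mstart <- floor(stats::runif(n_mito) * (msz - mlen))
    frg <- rbind(frg, data.table::data.table(
      chrom = mito_chrom[1L], start = mstart, end = mstart + mlen,
      strand = sample(c("+", "-"), n_mito, replace = TRUE)))
  }
  res <- filter_fragment_table(frg, chrom_sizes,
                               frag_filters(min_mapq = 0L))
  new_fragment_set(sample_id, res$fragments, res$rejects)
}

#' Default two-group cohort templates
#'
#' Planted group differences mirroring the direction of the salivary-cfDNA
#' case/control contrasts this package is designed to detect: the
#' "noncancer" template has a strong 10-bp comb (a = 0.8), almost no
#' mononucleosomal component (5 percent), low mitochondrial fraction
#' (2 percent), telomeric placement enrichment, mild end-motif bias and an
#' even oral-genus community; the "cancer" template has a weak comb
#' (a = 0.1), a prominent ~167 bp component (30 percent), a higher
#' mitochondrial fraction (8 percent), no telomeric enrichment, stronger
#' end-motif concentration (lower entropy) and a skewed, lower-diversity
#' community.
#'
#' @param n_fragments fragments per sample used by both templates.
#' @return named list of two `SampleParams`.
#' @export
cohort_templates <- function(n_fragments = 50000L) {
  motifs <- c("CCCA", "CCAG", "CCTG", "CCCT")
  list(
    noncancer = sample_params(
      n_fragments = n_fragments, comb_amplitude = 0.8, mono_weight = 0.05,
      mito_fraction = 0.02, telomere_bias = 2,
      motif_bias = list(motifs = motifs, weight = 0.1),
      taxa_composition = default_taxa_composition("even")),
    cancer = sample_params(
      n_fragments = n_fragments, comb_amplitude = 0.1, mono_weight = 0.30,
      mito_fraction = 0.08, telomere_bias = 1,
      motif_bias = list(motifs = motifs, weight = 0.4),
      taxa_composition = default_taxa_composition("skewed")))
}

# A small synthetic oral-like taxonomy (genus level with full lineages).
default_taxa_lineages <- function() {
  c(Streptococcus = "Bacteria;Bacillota;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus",
    Veillonella = "Bacteria;Bacillota;Negativicutes;Veillonellales;Veillonellaceae;Veillonella",
    Lactobacillus = "Bacteria;Bacillota;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus",
    Haemophilus = "Bacteria;Pseudomonadota;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Haemophilus",
    Neisseria = "Bacteria;Pseudomonadota;Betaproteobacteria;Neisseriales;Neisseriaceae;Neisseria",
    Prevotella = "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
    Porphyromonas = "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Porphyromonadaceae;Porphyromonas",
    Capnocytophaga = "Bacteria;Bacteroidota;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Capnocytophaga",
    Fusobacterium = "Bacteria;Fusobacteriota;Fusobacteriia;Fusobacteriales;Fusobacteriaceae;Fusobacterium",
    Leptotrichia = "Bacteria;Fusobacteriota;Fusobacteriia;Fusobacteriales;Leptotrichiaceae;Leptotrichia",
    Rothia = "Bacteria;Actinomycetota;Actinomycetes;Micrococcales;Micrococcaceae;Rothia",
    Actinomyces = "Bacteria;Actinomycetota;Actinomycetes;Actinomycetales;Actinomycetaceae;Actinomyces")
}

#' Default group taxa compositions ("even" and "skewed")
#' @param kind `"even"` (higher diversity) or `"skewed"` (dominated by a
#'   few genera, lower diversity).
#' @return named probability vector over the built-in genera.
#' @export
default_taxa_composition <- function(kind = c("even", "skewed")) {
  kind <- match.arg(kind)
  taxa <- names(default_taxa_lineages())
  if (kind == "even") {
    w <- c(22, 12, 3, 10, 9, 10, 6, 5, 8, 5, 6, 4)
  } else {
    w <- c(45, 18, 12, 4, 3, 5, 2, 1, 4, 2, 2, 2)
  }
  stats::setNames(w / sum(w), taxa)
}

#' Simulate a taxa abundance table
#'
#' Dirichlet-multinomial counts per sample: with `overdispersion = 0` each
#' sample is a plain multinomial draw of `depth` reads from `composition`;
#' with `overdispersion = s > 0` the per-sample composition is first drawn
#' from `Dirichlet(composition / s)`.
#'
#' @param n_samples number of samples.
#' @param composition named probability vector over taxa (names must be
#'   genera of the built-in taxonomy, or arbitrary labels -- lineages then
#'   fall back to `Bacteria;...;<label>`).
#' @param depth microbial reads per sample.
#' @param overdispersion Dirichlet overdispersion `s >= 0`.
#' @param seed optional RNG seed.
#' @param sample_ids optional sample names.
#' @return a `TaxaTable` (genus-rank rows).
#' @export
simulate_taxa <- function(n_samples, composition =
                            default_taxa_composition("even"),
                          depth = 1e5, overdispersion = 0.02, seed = NULL,
                          sample_ids = NULL) {
  stopifnot(n_samples >= 1, depth > 0, overdispersion >= 0,
            abs(sum(composition) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n_samples))
  k <- length(composition)
  counts <- matrix(0L, nrow = k, ncol = n_samples,
                   dimnames = list(names(composition), sample_ids))
  for (j in seq_len(n_samples)) {
    p <- if (overdispersion > 0) {
      g <- stats::rgamma(k, shape = composition / overdispersion)
      if (sum(g) == 0) composition else g / sum(g)
    } else composition
    counts[, j] <- stats::rmultinom(1, size = depth, prob = p)
  }
  lin <- default_taxa_lineages()
  lineage <- ifelse(names(composition) %in% names(lin),
                    lin[names(composition)],
                    paste0("Bacteria;unclassified;unclassified;",
                           "unclassified;unclassified;",
                           names(composition)))
  out <- data.table::data.table(taxon_id = names(composition),
                                lineage = lineage, rank = "genus")
  out <- cbind(out, data.table::as.data.table(counts))
  data.table::setattr(out, "class", c("TaxaTable", class(out)))
  out
}

# lognormal jitter of a sample's continuous parameters around a template
jitter_params <- function(template, sd = 0.1) {
  j <- function(v, lo = 0, hi = Inf)
    min(max(v * exp(stats::rnorm(1, 0, sd)), lo), hi)
  sample_params(
    n_fragments = template$n_fragments,
    short_mode = j(template$short_mode),
    short_spread = j(template$short_spread),
    mono_weight = j(template$mono_weight, 0, 1),
    comb_amplitude = j(template$comb_amplitude, 0, 1),
    mito_fraction = j(template$mito_fraction, 0, 1),
    telomere_bias = j(template$telomere_bias),
    motif_bias = template$motif_bias,
    taxa_composition = template$taxa_composition)
}

#' Simulate a two-group cohort and extract its feature matrix
#'
#' Draws `n_per_group` samples per template (per-sample lognormal jitter of
#' the continuous parameters, s.d. `jitter_sd` on the log scale), runs the
#' full per-sample feature extraction ([extract_sample_features()]) and
#' returns the cohort feature matrix with group labels, the taxa table, and
#' the planted truth. With `out_dir` set, per-sample fragment TSVs, the
#' taxa TSV, the feature matrix TSV and a `truth.json` are written.
#' Deterministic given `seed`.
#'
#' @param n_per_group samples per group (>= 2).
#' @param templates named list of two `SampleParams` (see
#'   [cohort_templates()]).
#' @param seed RNG seed.
#' @param chrom_sizes contig lengths used for simulation (default
#'   [toy_chrom_sizes()]).
#' @param reference `NULL` (skip sequence-based features), `"toy"`
#'   (generate a toy reference) or a `DNAStringSet`/FASTA path.
#' @param taxa_depth microbial reads per sample (0 skips taxa simulation).
#' @param jitter_sd per-sample parameter jitter on the log scale.
#' @param out_dir optional output directory.
#' @param keep_fragsets keep the per-sample `FragmentSet`s in the result.
#' @return list of class `sim_cohort`: `features` (samples x features
#'   matrix), `groups` (factor), `taxa` (`TaxaTable` or `NULL`),
#'   `truth` (planted parameters), `bins`, `chrom_sizes`, optionally
#'   `fragsets`.
#' @export
simulate_cohort <- function(n_per_group = 10L,
                            templates = cohort_templates(),
                            seed = 1L,
                            chrom_sizes = toy_chrom_sizes(),
                            reference = NULL,
                            taxa_depth = 1e5,
                            jitter_sd = 0.1,
                            out_dir = NULL,
                            keep_fragsets = FALSE) {
  stopifnot(n_per_group >= 2, length(templates) == 2L,
            !is.null(names(templates)))
  set.seed(seed)
  if (identical(reference, "toy"))
    reference <- simulate_reference(chrom_sizes)
  if (is.null(reference))  # sequence-based planting needs a reference
    templates <- lapply(templates, function(t) { t$motif_bias <- NULL; t })
  bins <- make_bins(chrom_sizes, bin_size = 1e6)

  groups <- factor(rep(names(templates), each = n_per_group),
                   levels = names(templates))
  ids <- sprintf("%s_%02d", groups, rep(seq_len(n_per_group), times = 2))
  feats <- list(); fragsets <- list(); truth <- list()
  for (i in seq_along(ids)) {
    prm <- jitter_params(templates[[as.character(groups[i])]], jitter_sd)
    fs <- simulate_fragments(prm, bins, chrom_sizes,
                             reference = reference, sample_id = ids[i])
    feats[[ids[i]]] <- extract_sample_features(fs, bins,
                                               reference = reference)
    truth[[ids[i]]] <- prm[c("short_mode", "short_spread", "mono_weight",
                             "comb_amplitude", "mito_fraction",
                             "telomere_bias")]
    if (keep_fragsets) fragsets[[ids[i]]] <- fs
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fragments_tsv(fs, file.path(out_dir,
                                        paste0(ids[i], ".fragments.tsv")))
    }
  }
  features <- do.call(rbind, feats)
  rownames(features) <- ids

  taxa <- NULL
  if (taxa_depth > 0) {
    tabs <- lapply(seq_along(templates), function(g) {
      comp <- templates[[g]]$taxa_composition
      if (is.null(comp)) comp <- default_taxa_composition("even")
      simulate_taxa(n_per_group, comp, depth = taxa_depth,
                    sample_ids = ids[groups == names(templates)[g]])
    })
    taxa <- tabs[[1L]]
    smp2 <- taxa_sample_cols(tabs[[2L]])
    taxa <- cbind(taxa, tabs[[2L]][, ..smp2])
    data.table::setattr(taxa, "class",
                        unique(c("TaxaTable", class(taxa))))
  }

  if (!is.null(taxa)) {
    ad <- alpha_diversity(taxa)
    rab <- t(relative_abundance(taxa))
    colnames(rab) <- paste0("rab_", colnames(rab))
    features <- cbind(features,
                      alpha_diversity = ad[rownames(features)],
                      rab[rownames(features), , drop = FALSE])
  }

  out <- structure(list(features = features, groups = groups, taxa = taxa,
                        truth = truth, bins = bins,
                        chrom_sizes = chrom_sizes,
                        templates = templates, seed = seed),
                   class = "sim_cohort")
  if (keep_fragsets) out$fragsets <- fragsets
  if (!is.null(out_dir)) {
    data.table::fwrite(
      data.table::data.table(sample = ids, group = as.character(groups),
                             features),
      file.path(out_dir, "features.tsv"), sep = "\t")
    if (!is.null(taxa)) write_taxa_table(taxa,
                                         file.path(out_dir, "taxa.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$features), "samples (",
      paste(levels(x$groups), table(x$groups), sep = "=", collapse = ", "),
      "),", ncol(x$features), "features\n")
  invisible(x)
}
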