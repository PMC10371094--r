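test_that("identical seeds give byte-identical cohort outputs", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  co1 <- simulate_cohort(n_per_group = 2,
                         templates = cohort_templates(n_fragments = 2000),
                         seed = 17, taxa_depth = 5000, out_dir = d1)
  co2 <- simulate_cohort(n_per_group = 2,
                         templates = cohort_templates(n_fragments = 2000),
                         seed = 17, taxa_depth = 5000, out_dir = d2)
  expect_identical(co1$features, co2$features)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  co3 <- simulate_cohort(n_per_group = 2,
                         templates = cohort_templates(n_fragments = 2000),
                         seed = 18, taxa_depth = 5000)
  expect_false(identical(co1$features, co3$features))
})

test_that("sampled length mass matches the analytic mixture pmf", {
  prm <- sample_params(n_fragments = 50000, mono_weight = 0.3,
                       mito_fraction = 0)
  pmf <- length_pmf(prm)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  grid <- 20:400
  mass <- sum(pmf[grid >= 150 & grid <= 185])
  tcs <- toy_chrom_sizes()
  fs <- simulate_fragments(prm, make_bins(tcs), tcs, seed = 5)
  obs <- mean(fs$fragments$length >= 150 & fs$fragments$length <= 185)
  se <- sqrt(mass * (1 - mass) / 50000)
  expect_lt(abs(obs - mass), 3 * se)
})

test_that("comb amplitude controls 10-bp periodicity of the histogram", {
  tcs <- toy_chrom_sizes()
  bins <- make_bins(tcs)
  # lag autocorrelation of the envelope-detrended histogram (11-point
  # moving average removes the smooth short-fragment envelope)
  autocor10 <- function(a, seed) {
    fs <- simulate_fragments(sample_params(n_fragments = 40000,
                                           comb_amplitude = a,
                                           mono_weight = 0,
                                           mito_fraction = 0),
                             bins, tcs, seed = seed)
    y <- build_size_histogram(fs, 30, 100)$percent_reads
    r <- y - as.numeric(stats::filter(y, rep(1 / 11, 11)))
    r <- r[!is.na(r)]
    ac <- function(lag) cor(r[1:(length(r) - lag)], r[(lag + 1):length(r)])
    c(lag10 = ac(10), off = mean(c(ac(9), ac(11))))
  }
  # no comb: lag-10 autocorrelation indistinguishable from lag 9/11
  flat <- autocor10(0, 301)
  expect_lt(abs(flat["lag10"] - flat["off"]), 0.2)
  expect_lt(flat["lag10"], 0.35)
  # strong comb: a dominant period-10 signal
  comb <- autocor10(0.8, 302)
  expect_gt(comb["lag10"], 0.6)
  expect_gt(comb["lag10"] - comb["off"], 0.05)
})

test_that("taxa simulation approaches multinomial behaviour without
           overdispersion and the uniform large-depth diversity limit", {
  comp <- default_taxa_composition("even")
  tt <- simulate_taxa(40, comp, depth = 2000, overdispersion = 0, seed = 83)
  m <- taxa_counts(tt)
  # chi-square check of per-taxon variance against multinomial expectation
  ratio <- vapply(seq_along(comp), function(i) {
    v_exp <- 2000 * comp[i] * (1 - comp[i])
    var(m[i, ]) / v_exp
  }, numeric(1))
  expect_lt(mean(ratio), 2)
  expect_gt(mean(ratio), 0.5)

  k <- 8
  unif <- setNames(rep(1 / k, k), paste0("t", 1:k))
  tt2 <- simulate_taxa(5, unif, depth = 2e5, overdispersion = 0, seed = 89)
  ad <- alpha_diversity(tt2)
  expect_equal(unname(ad), rep(log(k), 5), tolerance = 0.005)

  expect_error(simulate_taxa(3, unif, depth = 0), "depth")
})

test_that("a planted genus difference is detected by the feature scan", {
  set.seed(97)
  comp1 <- default_taxa_composition("even")
  comp2 <- comp1
  comp2["Fusobacterium"] <- comp2["Fusobacterium"] * 3
  comp2 <- comp2 / sum(comp2)
  hits <- vapply(1:10, function(s) {
    t1 <- simulate_taxa(10, comp1, depth = 1e5, overdispersion = 0.02,
                        seed = 1000 + s, sample_ids = sprintf("a%02d", 1:10))
    t2 <- simulate_taxa(10, comp2, depth = 1e5, overdispersion = 0.02,
                        seed = 2000 + s, sample_ids = sprintf("b%02d", 1:10))
    m <- cbind(relative_abundance(t1), relative_abundance(t2))
    s <- feature_scan(t(m), rep(c("a", "b"), each = 10))
    isTRUE(s$rejected[s$feature == "Fusobacterium"])
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("null cohorts keep the scan near its nominal FDR", {
  set.seed(101)
  tmpl <- cohort_templates(n_fragments = 4000)
  tmpl$cancer <- tmpl$noncancer   # identical templates: no real effect
  fr <- vapply(1:6, function(s) {
    co <- simulate_cohort(n_per_group = 5, templates = tmpl,
                          seed = 3000 + s, taxa_depth = 2e4)
    sc <- feature_scan(co$features, co$groups)
    r <- mean(sc$rejected, na.rm = TRUE)
    if (is.nan(r)) 0 else r
  }, numeric(1))
  expect_lte(mean(fr), 0.1)
})

test_that("planted motif bias lowers end-motif entropy", {
  tcs <- toy_chrom_sizes()
  bins <- make_bins(tcs)
  ref <- simulate_reference(tcs, seed = 103)
  ent <- function(weight, seed) {
    prm <- sample_params(n_fragments = 10000, mito_fraction = 0,
                         motif_bias = list(
                           motifs = c("CCCA", "CCAG", "CCTG", "CCCT"),
                           weight = weight))
    fs <- simulate_fragments(prm, bins, tcs, reference = ref, seed = seed)
    extract_end_motifs(fs, ref)$entropy_bits
  }
  lo <- vapply(1:4, function(s) ent(0.4, 400 + s), numeric(1))
  hi <- vapply(1:4, function(s) ent(0.05, 500 + s), numeric(1))
  expect_lt(mean(lo), mean(hi))
  expect_true(all(lo < min(hi)))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sample_params(n_fragments = 0))
  expect_error(sample_params(mono_weight = 1.4))
  expect_error(sample_params(comb_amplitude = -0.1))
  expect_error(simulate_cohort(n_per_group = 1), "n_per_group")
})
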