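test_that("compare_loads reproduces the exact separated-sample p-value", {
  res <- compare_loads(c(1000, 1150, 1192), c(3600, 3700, 3750, 3814))
  expect_equal(res$p_one_sided, 1 / 35)
  expect_equal(res$mean_multiplexed, 1114)
  expect_equal(res$mean_sequential, 3716)
  expect_equal(res$fold, 3716 / 1114)
  # tie convention: identical singletons carry no evidence
  expect_equal(compare_loads(5, 5)$p_one_sided, 1)
  expect_error(compare_loads(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals 1/choose(n, n_a) under complete separation", {
  for (n_a in 1:6) {
    for (n_b in 1:6) {
      a <- seq_len(n_a)               # smaller group
      b <- 100 + seq_len(n_b)         # fully separated larger group
      res <- compare_loads(a, b)
      expect_equal(res$p_one_sided, 1 / choose(n_a + n_b, n_b),
                   label = sprintf("n=%d vs %d", n_a, n_b))
    }
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(19)
  for (i in 1:25) {
    a <- sample(1000, sample(3:8, 1))
    b <- sample(1000, sample(3:8, 1))
    if (length(intersect(a, b)) > 0) next
    res <- compare_loads(a, b)
    ref <- suppressWarnings(stats::wilcox.test(b, a,
                                               alternative = "greater",
                                               exact = TRUE))
    expect_equal(res$p_one_sided, unname(ref$p.value))
  }
  # large samples switch to the tie-corrected normal approximation
  set.seed(20)
  a <- rpois(30, 100); b <- rpois(30, 120)
  res <- compare_loads(a, b)
  expect_identical(res$method, "tie-corrected normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(b, a, alternative = "greater",
                                             exact = FALSE, correct = TRUE))
  expect_equal(res$p_one_sided, unname(ref$p.value), tolerance = 1e-8)
})

test_that("profile construction normalizes purine-reference mutations", {
  m1 <- data.frame(chrom = "1", pos = 1, ref = "C", alt = "T",
                   context = "ACA")
  p1 <- build_profile96(m1)
  expect_equal(sum(p1), 1L)
  expect_equal(unname(p1[["A[C>T]A"]]), 1L)
  # purine strand: G>A at TGT is the same class
  m2 <- data.frame(chrom = "1", pos = 1, ref = "G", alt = "A",
                   context = "TGT")
  p2 <- build_profile96(m2)
  expect_identical(as.integer(p1), as.integer(p2))
  # conservation at scale, and malformed contexts are collected
  sigs <- gen_signatures(3, 2)
  ms <- gen_mutation_set(5, 1000, c(0.5, 0.5), sigs)
  expect_equal(sum(build_profile96(ms$mutations)), 1000L)
  bad <- rbind(m1, data.frame(chrom = "1", pos = 2, ref = "C", alt = "T",
                              context = "AGA"))
  pb <- build_profile96(bad)
  expect_equal(sum(pb), 1L)
  expect_length(attr(pb, "errors"), 1L)
})

test_that("signature refitting is exact on noiseless mixtures", {
  sigs <- gen_signatures(41, 2)
  # pure column
  prof <- 500 * sigs[, 1]
  fit <- refit_signatures(prof, sigs)
  expect_equal(unname(fit$exposures), c(500, 0), tolerance = 1e-6)
  # noiseless 0.6/0.4 mixture of 10,000 mutations
  prof2 <- 10000 * (0.6 * sigs[, 1] + 0.4 * sigs[, 2])
  fit2 <- refit_signatures(prof2, sigs)
  expect_equal(unname(fit2$proportions), c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(fit2$cosine, 1, tolerance = 1e-9)
  # zero profile
  fit0 <- refit_signatures(rep(0, 96), sigs)
  expect_equal(unname(fit0$exposures), c(0, 0))
  expect_true(is.na(fit0$cosine))
  expect_error(refit_signatures(rep(1, 96), sigs * 2), "sum to 1")
})

test_that("sampled mixtures are recovered within sampling error", {
  sigs <- gen_signatures(41, 2)
  ms <- gen_mutation_set(101, 10000, c(0.6, 0.4), sigs)
  fit <- refit_signatures(build_profile96(ms$mutations), sigs)
  expect_lt(max(abs(fit$proportions - c(0.6, 0.4)) / c(0.6, 0.4)), 0.05)
})

test_that("APOBEC-like classification follows the TpC rule with normalization", {
  expect_true(classify_apobec_like("C", "T", "TCA"))
  expect_false(classify_apobec_like("C", "T", "ACG"))
  expect_true(classify_apobec_like("G", "A", "TGA"))  # revcomp of TCA
  expect_true(classify_apobec_like("C", "G", "TCT"))
  expect_false(classify_apobec_like("T", "C", "TTA"))
})

test_that("gene-body depletion matches closed-form and enumeration oracles", {
  genes <- interval_set(data.frame(chrom = "chr1", start = 1, end = 400),
                        total_genome_length = 1000)
  mk <- function(n_in, n_out) {
    data.frame(chrom = "chr1",
               pos = c(seq_len(n_in), 400 + seq_len(n_out)))
  }
  r <- gene_body_depletion(mk(40, 60), genes)
  expect_equal(r$observed, 40)
  expect_equal(r$expected, 40)
  expect_equal(r$log2_score, 0)
  expect_equal(r$p_binomial, 1)
  r2 <- gene_body_depletion(mk(20, 80), genes)
  expect_equal(r2$log2_score, -1)
  # exact two-sided binomial by full enumeration over 0..100
  d_obs <- dbinom(20, 100, 0.4)
  p_enum <- sum(dbinom(0:100, 100, 0.4)[dbinom(0:100, 100, 0.4) <=
                                          d_obs * (1 + 1e-7)])
  expect_equal(r2$p_binomial, p_enum, tolerance = 1e-9)
  none <- data.frame(chrom = character(0), pos = integer(0))
  expect_error(gene_body_depletion(none, genes), "empty mutation set")
})

test_that("depletion score is near zero under uniform placement", {
  gm <- gen_genome_model()
  ms <- gen_mutation_set(7, 100000, c(1, 0), gen_signatures(7, 2), gm)
  r <- gene_body_depletion(ms$mutations, gm)
  expect_lt(abs(r$log2_score), 0.05)
})

test_that("depletion comparison uses Fisher's exact test with degenerate guard", {
  expect_equal(compare_depletion(c(`in` = 5, out = 5),
                                 c(`in` = 5, out = 5))$p, 1)
  r <- compare_depletion(c(`in` = 10, out = 90), c(`in` = 40, out = 60))
  # enumeration oracle: sum of hypergeometric probs <= observed
  probs <- dhyper(0:50, 50, 150, 100)
  p_enum <- sum(probs[probs <= probs[11] * (1 + 1e-7)])
  expect_equal(r$p, p_enum, tolerance = 1e-9)
  ext <- compare_depletion(c(`in` = 0, out = 10), c(`in` = 10, out = 0))
  expect_equal(ext$p, min(ext$p, 1))  # smallest achievable for the margins
  expect_equal(ext$p, dhyper(0, 10, 10, 10) * 2, tolerance = 1e-9)
  deg <- compare_depletion(c(`in` = 0, out = 0), c(`in` = 3, out = 4))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("rainfall distances and kataegis calls behave on planted data", {
  # widely spaced mutations: no calls
  wide <- data.frame(chrom = "chr1", pos = seq(1e5, 9e5, by = 1e5))
  rf <- rainfall(wide)
  expect_equal(nrow(rf$kataegis), 0L)
  expect_true(is.na(rf$distances$dist_to_prev[1]))
  expect_equal(rf$distances$dist_to_prev[-1], rep(1e5, 8))
  # planted run of 6 mutations spaced 500 bp inside a uniform background
  planted <- data.frame(chrom = "chr1",
                        pos = c(seq(1e5, 9e5, by = 1e5),
                                seq(432000, 434500, by = 500)))
  k <- rainfall(planted)$kataegis
  expect_equal(nrow(k), 1L)
  expect_equal(k$start, 432000)
  expect_equal(k$end, 434500)
  expect_equal(k$n_mutations, 6L)
  # run of 5 is below the default threshold
  short <- data.frame(chrom = "chr1",
                      pos = c(seq(1e5, 9e5, by = 1e5),
                              seq(432000, 434000, by = 500)))
  expect_equal(nrow(rainfall(short)$kataegis), 0L)
  # single mutation on a chromosome: NA distance, no calls
  single <- data.frame(chrom = c("chr1", "chr2"), pos = c(100, 200))
  rf2 <- rainfall(single)
  expect_true(all(is.na(rf2$distances$dist_to_prev)))
})

test_that("off-target search matches the naive oracle on random genomes", {
  set.seed(55)
  rb <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                 replace = TRUE), collapse = "")
  for (i in 1:20) {
    genome <- c(chrA = rb(600), chrB = rb(400))
    spacer <- substring(genome[[1]], 100, 119)
    mm <- sample(0:4, 1)
    got <- find_offtarget_sites(spacer, genome, mm)
    keys <- sort(paste(got$chrom, got$strand, got$start, got$mismatches,
                       sep = "|"))
    expect_identical(keys, oracle_offtargets(spacer, genome, mm, "NGG"))
  }
})

test_that("off-target edge cases: exact hit, too many mismatches, flank clipping", {
  spacer <- "ACGTACGTACGTACGTACGT"
  g <- c(chr1 = paste0(spacer, "AGG"))
  s <- find_offtarget_sites(spacer, g)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mismatches, 0L)
  expect_equal(s$flank_start, 1L)  # clipped at sequence bounds
  expect_equal(s$flank_end, 23L)
  # 5 substitutions exceed a 4-mismatch budget
  mutated <- spacer
  for (p in c(1, 5, 9, 13, 17)) {
    substr(mutated, p, p) <- chartr("ACGT", "CATG",
                                    substring(mutated, p, p))
  }
  g2 <- c(chr1 = paste0(mutated, "AGG"))
  expect_equal(nrow(find_offtarget_sites(spacer, g2, 4)), 0L)
})

test_that("mutation intersection classifies spacer, flank and boundary positions", {
  sites <- data.frame(chrom = "chr1", strand = "+", start = 1000,
                      end = 1019, matched = "x", mismatches = 0,
                      flank_start = 800, flank_end = 1219)
  muts <- data.frame(chrom = "chr1", pos = c(1005, 1169, 1219, 1220, 999))
  hits <- intersect_offtargets(muts, sites)
  expect_equal(hits$region[hits$pos == 1005], "in_spacer")
  expect_equal(hits$region[hits$pos == 1169], "in_flank")
  expect_equal(hits$region[hits$pos == 1219], "in_flank")  # closed boundary
  expect_false(1220 %in% hits$pos)
  expect_equal(hits$region[hits$pos == 999], "in_flank")
})
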