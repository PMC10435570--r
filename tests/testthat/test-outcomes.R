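test_that("classify_consequence distinguishes silent, missense and nonsense", {
  expect_identical(classify_consequence("CAG", "TAG"), "nonsense")
  expect_identical(classify_consequence("GCA", "GCG"), "silent")
  expect_identical(classify_consequence("TCT", "TTT"), "missense")  # S>F
  # stop-to-stop is not nonsense
  expect_identical(classify_consequence("TAA", "TGA"), "silent")
  expect_error(classify_consequence("CA", "TAG"), "length 3")
})

test_that("outcome count is exactly 2^k and alleles re-translate correctly", {
  set.seed(23)
  reg <- default_registry()
  checked <- 0L
  for (i in 1:60) {
    tx <- random_tx(15)
    pos <- sample(nchar(tx$cds), 1)
    ref <- substring(tx$cds, pos, pos)
    alt <- switch(ref, C = "T", G = "A", A = "G", T = "C")
    guides <- find_guides(coding_change(pos, ref, alt), tx, reg)
    if (length(guides) == 0L) next
    g <- guides[[sample(length(guides), 1)]]
    outs <- enumerate_outcomes(g, tx)
    expect_length(outs, 2^length(g$substrate_offsets))
    expect_equal(sum(vapply(outs, function(o) o$is_headline, TRUE)), 1L)
    for (o in outs) {
      # allele differs from reference exactly at the edited CDS positions
      ref_v <- strsplit(tx$cds, "")[[1]]
      alt_v <- strsplit(o$allele, "")[[1]]
      diff_pos <- which(ref_v != alt_v)
      # oracle: re-derive edited CDS positions from strand geometry
      full <- paste0(tx$up_flank, tx$cds, tx$down_flank)
      strand_pos <- g$protospacer_start + o$edited_offsets - 1L
      full_pos <- if (g$strand == "sense") strand_pos else
        nchar(full) - strand_pos + 1L
      cds_pos <- full_pos - nchar(tx$up_flank)
      cds_pos <- sort(cds_pos[cds_pos >= 1 & cds_pos <= nchar(tx$cds)])
      expect_identical(diff_pos, as.integer(cds_pos))
      # consequences agree with independent re-translation
      for (r in seq_len(nrow(o$consequences))) {
        cons <- o$consequences[r, ]
        aa_b <- ORACLE_CODON_TABLE[[cons$codon_before]]
        aa_a <- ORACLE_CODON_TABLE[[cons$codon_after]]
        expected_class <- if (aa_b == aa_a) "silent" else
          if (aa_a == "*" && aa_b != "*") "nonsense" else "missense"
        expect_identical(cons$class, expected_class)
      }
      expect_identical(oracle_translate(o$allele),
                       translate_cds(o$allele))
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)
})

test_that("zero and single substrate guides enumerate trivially", {
  # ABE guide over a window with exactly one A
  spec <- default_registry()[["SpCas9-ABE"]]
  seqv <- rep("C", 60)
  seqv[35] <- "A"                      # window pos 6 for start 30
  seqv[50:52] <- c("C", "G", "G")      # PAM at 50 (start 30 + 20)
  tx <- transcript("Z", paste(seqv, collapse = ""))
  g <- find_guides(coding_change(35, "A", "G"), tx, list(spec))[[1]]
  outs <- enumerate_outcomes(g, tx)
  expect_length(outs, 2L)
  # zero-substrate cross-candidate: exactly the identity outcome
  g0 <- g
  g0$substrate_offsets <- integer(0)
  outs0 <- enumerate_outcomes(g0, tx)
  expect_length(outs0, 1L)
  expect_true(outs0[[1]]$is_headline)
  expect_identical(outs0[[1]]$allele, tx$cds)
})

test_that("rare CBE variants are labeled and appended only on request", {
  gt <- gen_transcript(31, 40, list(plant_spec("CAA", 12, "SaKKH-CBE")))
  tx <- gt$transcript
  cc <- coding_change(gt$truth$cds_pos[1], gt$truth$ref[1], gt$truth$alt[1])
  g <- find_guides(cc, tx, default_registry()["SaKKH-CBE"])[[1]]
  k <- length(g$substrate_offsets)
  plain <- enumerate_outcomes(g, tx)
  rare <- enumerate_outcomes(g, tx, include_rare_cbe = TRUE)
  expect_length(plain, 2^k)
  expect_length(rare, 2^k + 2L * k)
  extra <- rare[(2^k + 1L):length(rare)]
  expect_true(all(vapply(extra, function(o) o$rare, TRUE)))
  expect_true(all(grepl("^C>[AG]@", vapply(extra, function(o) o$rare_alt,
                                           ""))))
})

test_that("stop-convertible codons are exactly CAA, CAG, CGA, TGG implying Q/R/W", {
  conv <- stop_convertible_codons()
  expect_setequal(names(conv), c("CAA", "CAG", "CGA", "TGG"))
  # implied residue set
  expect_setequal(unname(vapply(names(conv), function(c.)
    ORACLE_CODON_TABLE[[c.]], "")), c("Q", "R", "W"))
  # strategies: Q/R codons sense, W antisense
  expect_identical(unique(conv$CAA$strategy), "sense_C>T")
  expect_identical(unique(conv$CAG$strategy), "sense_C>T")
  expect_identical(unique(conv$CGA$strategy), "sense_C>T")
  expect_identical(unique(conv$TGG$strategy), "antisense_C>T")
  # TGG reaches TGA, TAG and TAA via antisense C>T subsets
  expect_setequal(conv$TGG$stop_codon, c("TGA", "TAG", "TAA"))
  # independent closure check: simulate every codon and every C>T subset
  for (codon in names(ORACLE_CODON_TABLE)) {
    if (codon %in% c("TAA", "TAG", "TGA")) next
    reachable <- FALSE
    cv <- strsplit(codon, "")[[1]]
    for (mask in 1:7) {
      sel <- which(bitwAnd(mask, c(1L, 2L, 4L)) != 0L)
      s1 <- cv; s1[sel][s1[sel] == "C"] <- "T"
      s2 <- cv; s2[sel][s2[sel] == "G"] <- "A"
      for (s in list(s1, s2)) {
        if (!identical(s, cv) &&
            paste(s, collapse = "") %in% c("TAA", "TAG", "TGA")) {
          reachable <- TRUE
        }
      }
    }
    expect_identical(codon %in% names(conv), reachable, label = codon)
  }
})

test_that("crispr_stop_scan matches a brute-force codon-by-codon oracle", {
  reg <- default_registry()
  set.seed(77)
  for (i in 1:12) {
    tx <- random_tx(20)
    sites <- crispr_stop_scan(tx, reg)
    got <- vapply(sites, function(s) s$codon_index, 1L)
    # oracle: a codon is a site iff convertible and some stop-producing
    # C>T subset has a brute-force guide
    want <- integer(0)
    conv <- stop_convertible_codons()
    for (ci in seq_len(n_codons(tx))) {
      codon <- codon_at(tx, ci)
      strat <- conv[[codon]]
      if (is.null(strat)) next
      any_guide <- FALSE
      for (r in seq_len(nrow(strat))) {
        cp <- as.integer(strsplit(strat$codon_positions[r], ",")[[1]])
        cds_pos <- codon_positions(tx, ci)[cp]
        refs <- substring(tx$cds, cds_pos, cds_pos)
        alts <- rep(if (strat$strategy[r] == "sense_C>T") "T" else "A",
                    length(cp))
        cbes <- Filter(function(e) e$chemistry == "CBE", reg)
        if (length(oracle_guide_keys(cds_pos, refs, alts, tx, cbes)) > 0L) {
          any_guide <- TRUE
        }
      }
      if (any_guide) want <- c(want, ci)
    }
    expect_identical(got, want)
    # every reported guide really creates the stop
    for (s in sites) {
      expect_true(all(vapply(s$guides, function(g) {
        outs <- enumerate_outcomes(g, tx)
        any(vapply(outs, function(o)
          any(o$consequences$class == "nonsense" &
                o$consequences$codon_index == s$codon_index), TRUE))
      }, TRUE)))
    }
  }
})

test_that("stop scan on a CDS without editable cytosines is empty", {
  tx <- transcript("AT", paste(rep("ATA", 12), collapse = ""))
  expect_length(crispr_stop_scan(tx), 0)
  expect_error(crispr_stop_scan(tx, default_registry()["SpCas9-ABE"]),
               "no CBE editors")
})

test_that("planted convertible codons are found with expected guides and flags", {
  gt <- gen_transcript(1, 50, list(plant_spec("CAA", 10, "SpCas9-CBE")))
  sites <- crispr_stop_scan(gt$transcript)
  idx <- vapply(sites, function(s) s$codon_index, 1L)
  expect_true(10L %in% idx)
  # extended-only placement carries the extended-position flags
  gt3 <- gen_transcript(8, 40, list(
    plant_spec("CAA", 10, "SpCas9-CBE", window_offset = 3)))
  s_core <- crispr_stop_scan(gt3$transcript,
                             default_registry()["SpCas9-CBE"])
  s_ext <- crispr_stop_scan(gt3$transcript,
                            default_registry()["SpCas9-CBE"],
                            allow_extended = TRUE)
  core_idx <- vapply(s_core, function(s) s$codon_index, 1L)
  expect_false(10L %in% core_idx)
  site10 <- Filter(function(s) s$codon_index == 10L, s_ext)
  expect_length(site10, 1L)
  at3 <- Filter(function(g) 3L %in% g$target_offsets, site10[[1]]$guides)
  expect_true(length(at3) >= 1L)
  expect_true(all(vapply(at3, function(g)
    all(c("LOW_POSITION", "OUTSIDE_CORE_WINDOW") %in% g$flags), TRUE)))
})

test_that("stop report TSV has one row per site-guide-outcome", {
  gt <- gen_transcript(1, 50, list(plant_spec("CAA", 10, "SpCas9-CBE")))
  sites <- crispr_stop_scan(gt$transcript)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_stop_report_tsv(sites, gt$transcript, tmp)
  df <- read.delim(tmp, comment.char = "#")
  n_expected <- sum(vapply(sites, function(s) {
    sum(vapply(s$guides, function(g)
      2^length(g$substrate_offsets), 1))
  }, 1))
  expect_equal(nrow(df), n_expected)
  expect_true(all(c("gene", "codon_index", "spacer", "editor",
                    "consequences") %in% names(df)))
})
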