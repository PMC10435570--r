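# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's internal helpers: complementing, codon lookup, PAM
# expansion and placement search are re-implemented from first principles.

# hard-coded standard genetic code, written out independently
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_complement <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

oracle_revcomp <- function(seq) {
  paste(rev(unname(oracle_complement(strsplit(seq, "")[[1]]))),
        collapse = "")
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_pam_match <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  length(s) == length(p) &&
    all(vapply(seq_along(s), function(i) s[i] %in% ORACLE_IUPAC[[p[i]]],
               TRUE))
}

# naive sliding-window placement oracle
oracle_protospacers <- function(strand_seq, spacer_len, pam) {
  n <- nchar(strand_seq)
  total <- spacer_len + nchar(pam)
  out <- integer(0)
  for (s in seq_len(max(0L, n - total + 1L))) {
    pam_seq <- substring(strand_seq, s + spacer_len, s + total - 1L)
    if (oracle_pam_match(pam_seq, pam)) out <- c(out, s)
  }
  out
}

# brute-force guide search for sense-strand substitutions; returns a
# canonical key per valid (editor, strand, start) placement
oracle_guide_keys <- function(positions, refs, alts, tx, editors,
                              allow_extended = FALSE) {
  full <- paste0(tx$up_flank, tx$cds, tx$down_flank)
  keys <- character(0)
  for (ed in editors) {
    win <- if (allow_extended) ed$extended_window else ed$window
    sub_base <- if (ed$chemistry == "CBE") "C" else "A"
    ed_base <- if (ed$chemistry == "CBE") "T" else "G"
    for (strand in c("sense", "antisense")) {
      strand_seq <- if (strand == "sense") full else oracle_revcomp(full)
      spos <- vapply(positions, function(p) {
        fp <- nchar(tx$up_flank) + p
        if (strand == "sense") fp else nchar(full) - fp + 1L
      }, 1L)
      sref <- if (strand == "sense") refs else
        unname(oracle_complement(refs))
      salt <- if (strand == "sense") alts else
        unname(oracle_complement(alts))
      if (!all(sref == sub_base) || !all(salt == ed_base)) next
      n <- nchar(strand_seq)
      for (s in seq_len(max(0L, n - ed$spacer_len - nchar(ed$pam) + 1L))) {
        offs <- spos - s + 1L
        if (any(offs < win[1] | offs > win[2])) next
        pam_seq <- substring(strand_seq, s + ed$spacer_len,
                             s + ed$spacer_len + nchar(ed$pam) - 1L)
        if (!oracle_pam_match(pam_seq, ed$pam)) next
        keys <- c(keys, paste(ed$name, strand, s, sep = "|"))
      }
    }
  }
  sort(keys)
}

guide_keys <- function(guides) {
  sort(vapply(guides, function(g) {
    paste(g$editor, g$strand, g$protospacer_start, sep = "|")
  }, ""))
}

# random transcript with flanks, uniform base composition
random_tx <- function(n_codons, flank = 25L, gene_id = "RND") {
  rb <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  transcript(gene_id, rb(3L * n_codons), up_flank = rb(flank),
             down_flank = rb(flank))
}

# independent re-translation of an outcome allele
oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  paste(vapply(seq_len(n), function(i) {
    ORACLE_CODON_TABLE[[substring(cds, 3L * i - 2L, 3L * i)]]
  }, ""), collapse = "")
}

# naive off-target oracle: slide over both strands, count mismatches, and
# require an adjacent PAM
oracle_offtargets <- function(spacer, genome, max_mm, pam) {
  sl <- nchar(spacer); pl <- nchar(pam)
  sp <- strsplit(spacer, "")[[1]]
  keys <- character(0)
  for (ch in names(genome)) {
    seq_p <- genome[[ch]]
    L <- nchar(seq_p)
    for (strand in c("+", "-")) {
      s_seq <- if (strand == "+") seq_p else oracle_revcomp(seq_p)
      for (s in seq_len(max(0L, L - sl - pl + 1L))) {
        w <- strsplit(substring(s_seq, s, s + sl - 1L), "")[[1]]
        mm <- sum(w != sp)
        if (mm > max_mm) next
        if (!oracle_pam_match(substring(s_seq, s + sl, s + sl + pl - 1L),
                              pam)) next
        start <- if (strand == "+") s else L - (s + sl - 1L) + 1L
        keys <- c(keys, paste(ch, strand, start, mm, sep = "|"))
      }
    }
  }
  sort(keys)
}
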