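# Sequence, codon, coordinate and variant-notation data model shared by all
# design and audit stages. CDS coordinates are 1-based; codon i covers CDS
# positions frame_offset + (3i-2 .. 3i).

#' Validate a nucleotide sequence
#'
#' Normalizes to uppercase and rejects any character outside \{A,C,G,T\}.
#' Ambiguity codes (including N) are deliberately rejected: editing-window
#' logic is undefined on ambiguous bases. IUPAC patterns are a separate
#' concept handled by [match_pam()].
#'
#' @param x A single character string (possibly empty).
#' @return The validated, uppercased sequence string.
#' @export
nuc_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) > 0L && grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A sequence string over \{A,C,G,T\}.
#' @return The 5'->3' reverse complement. Applying twice returns the input.
#' @examples
#' reverse_complement("GGT") # "ACC"
#' @export
reverse_complement <- function(seq) {
  seq <- nuc_seq(seq)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding sequence slice
#'
#' Standard genetic code; stop codons are rendered `*`.
#'
#' @param cds_slice Sequence whose length is divisible by 3.
#' @return Amino-acid string (one-letter code).
#' @export
translate_cds <- function(cds_slice) {
  cds_slice <- nuc_seq(cds_slice)
  if (nchar(cds_slice) %% 3L != 0L) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  if (nchar(cds_slice) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(cds_slice),
                                     no.init.codon = TRUE))
}

#' Construct a transcript model
#'
#' A gene's CDS plus optional flanking context. `frame_offset` allows partial
#' CDS fragments so short planted contexts can be analyzed in frame: codon 1
#' starts at CDS position `frame_offset + 1`.
#'
#' @param gene_id Gene symbol or identifier.
#' @param cds Coding sequence (sense strand).
#' @param role One of "oncogene", "tsg", "other".
#' @param up_flank,down_flank Optional genomic context flanking the CDS.
#' @param frame_offset Integer 0-2; bases to skip before the first full codon.
#' @return An object of class `transcript`.
#' @export
transcript <- function(gene_id, cds, role = c("other", "oncogene", "tsg"),
                       up_flank = "", down_flank = "", frame_offset = 0L) {
  role <- match.arg(role)
  cds <- nuc_seq(cds)
  up_flank <- nuc_seq(up_flank)
  down_flank <- nuc_seq(down_flank)
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0L || frame_offset > 2L) {
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  }
  if ((nchar(cds) - frame_offset) %% 3L != 0L) {
    stop("(length(cds) - frame_offset) must be a whole number of codons",
         call. = FALSE)
  }
  structure(
    list(gene_id = as.character(gene_id), role = role, cds = cds,
         up_flank = up_flank, down_flank = down_flank,
         frame_offset = frame_offset),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s [%s]: %d nt CDS (+%d/+%d nt flanks), %d codons\n",
              x$gene_id, x$role, nchar(x$cds), nchar(x$up_flank),
              nchar(x$down_flank), n_codons(x)))
  invisible(x)
}

#' Number of complete codons in the analyzed frame
#' @param tx A [transcript()].
#' @export
n_codons <- function(tx) {
  (nchar(tx$cds) - tx$frame_offset) %/% 3L
}

#' Codon sequence at a residue index
#' @param tx A [transcript()].
#' @param i 1-based codon (residue) index.
#' @return The codon triplet as a string.
#' @export
codon_at <- function(tx, i) {
  i <- as.integer(i)
  if (any(i < 1L) || any(i > n_codons(tx))) {
    stop("codon index out of range", call. = FALSE)
  }
  start <- tx$frame_offset + 3L * i - 2L
  substring(tx$cds, start, start + 2L)
}

#' CDS positions covered by a codon
#' @inheritParams codon_at
#' @return Integer vector of the three 1-based CDS positions.
#' @export
codon_positions <- function(tx, i) {
  start <- tx$frame_offset + 3L * as.integer(i) - 2L
  start:(start + 2L)
}

#' Construct a coding (nucleotide-level) change
#'
#' @param position 1-based CDS coordinate.
#' @param ref,alt Single reference/alternate bases; `ref != alt`.
#' @return An object of class `coding_change`.
#' @export
coding_change <- function(position, ref, alt) {
  position <- as.integer(position)
  ref <- nuc_seq(ref); alt <- nuc_seq(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("ref and alt must be single bases", call. = FALSE)
  }
  if (position < 1L) stop("position must be >= 1", call. = FALSE)
  if (ref == alt) stop("ref and alt must differ", call. = FALSE)
  structure(list(position = position, ref = ref, alt = alt),
            class = "coding_change")
}

#' @export
format.coding_change <- function(x, ...) {
  sprintf("c.%d%s>%s", x$position, x$ref, x$alt)
}

#' @export
print.coding_change <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Parse an HGVS-like coding change (c.96C>T)
#'
#' Supports the substitution subset `c.<pos><ref>><alt>`, with optional
#' whitespace around `>`. The reference base is validated against the
#' supplied transcript.
#'
#' @param text The change string, e.g. `"c.96C>T"`.
#' @param tx A [transcript()] to validate against.
#' @return A [coding_change()].
#' @export
parse_coding_change <- function(text, tx) {
  m <- regmatches(text,
                  regexec("^\\s*c\\.(\\d+)\\s*([ACGTacgt])\\s*>\\s*([ACGTacgt])\\s*$",
                          text))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse coding change: '", text,
         "' (expected e.g. c.96C>T)", call. = FALSE)
  }
  pos <- as.integer(m[2]); ref <- toupper(m[3]); alt <- toupper(m[4])
  if (ref == alt) {
    stop("cannot parse coding change: ref equals alt in '", text, "'",
         call. = FALSE)
  }
  if (pos > nchar(tx$cds)) {
    stop("position ", pos, " beyond CDS of ", tx$gene_id,
         " (", nchar(tx$cds), " nt)", call. = FALSE)
  }
  have <- substring(tx$cds, pos, pos)
  if (have != ref) {
    stop("reference mismatch at c.", pos, " of ", tx$gene_id,
         ": CDS has ", have, ", change states ", ref, call. = FALSE)
  }
  coding_change(pos, ref, alt)
}

#' Construct a protein-level change
#'
#' @param residue 1-based codon index.
#' @param ref_aa One-letter reference amino acid.
#' @param alt_aa One-letter alternate amino acid, or `"*"` for a stop.
#' @return An object of class `protein_change`.
#' @export
protein_change <- function(residue, ref_aa, alt_aa) {
  residue <- as.integer(residue)
  ref_aa <- toupper(ref_aa); alt_aa <- toupper(alt_aa)
  aas <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  if (!(ref_aa %in% aas) || !(alt_aa %in% aas)) {
    stop("invalid amino-acid code", call. = FALSE)
  }
  if (ref_aa == alt_aa) stop("ref_aa and alt_aa must differ", call. = FALSE)
  structure(list(residue = residue, ref_aa = ref_aa, alt_aa = alt_aa),
            class = "protein_change")
}

#' @export
format.protein_change <- function(x, ...) {
  sprintf("p.%s%d%s", x$ref_aa, x$residue, x$alt_aa)
}

#' @export
print.protein_change <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Parse a protein change such as p.S45P or p.Q1406*
#'
#' @param text The change string; the `p.` prefix is optional.
#' @param tx Optional [transcript()]; when supplied, the reference amino
#'   acid is validated against the translated codon.
#' @return A [protein_change()].
#' @export
parse_protein_change <- function(text, tx = NULL) {
  m <- regmatches(text,
                  regexec("^\\s*(?:p\\.)?([A-Za-z])(\\d+)([A-Za-z*])\\s*$",
                          text))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse protein change: '", text,
         "' (expected e.g. p.S45P or p.Q1406*)", call. = FALSE)
  }
  pc <- protein_change(as.integer(m[3]), m[2], m[4])
  if (!is.null(tx)) validate_protein_change(pc, tx)
  pc
}

validate_protein_change <- function(pc, tx) {
  if (pc$residue < 1L || pc$residue > n_codons(tx)) {
    stop("residue ", pc$residue, " out of range for ", tx$gene_id,
         " (", n_codons(tx), " codons)", call. = FALSE)
  }
  have <- translate_cds(codon_at(tx, pc$residue))
  if (have != pc$ref_aa) {
    stop("reference mismatch at residue ", pc$residue, " of ", tx$gene_id,
         ": codon encodes ", have, ", change states ", pc$ref_aa,
         call. = FALSE)
  }
  invisible(pc)
}

# Classify a single sense-strand substitution by base-editor chemistry as
# seen from the protospacer strand that could install it.
substitution_chemistry <- function(ref, alt) {
  key <- paste0(ref, alt)
  switch(key,
         "CT" = "C>T sense",
         "GA" = "C>T antisense",
         "AG" = "A>G sense",
         "TC" = "A>G antisense",
         "other")
}

#' Nucleotide substitution options for a protein-level change
#'
#' Enumerates every set of within-codon substitutions converting the
#' reference codon into any codon encoding the target amino acid. Each
#' substitution is annotated with the strand-specific base-editor chemistry
#' able to install it (`"C>T sense"`, `"C>T antisense"` i.e. G>A on the
#' sense strand, `"A>G sense"`, `"A>G antisense"` i.e. T>C sense, or
#' `"other"` for transversions neither CBE nor ABE can produce).
#'
#' Options are ordered by edit count (minimal first), then alphabetically by
#' target codon, so `options[[1]]` is a minimal-edit route.
#'
#' @param pc A [protein_change()].
#' @param tx The [transcript()] providing the reference codon.
#' @return A list of options; each option is a data.frame with columns
#'   `codon_pos` (1-3), `cds_pos`, `ref`, `alt`, `chemistry`, and attributes
#'   `target_codon` and `n_edits`.
#' @export
protein_to_nucleotide_options <- function(pc, tx) {
  validate_protein_change(pc, tx)
  ref_codon <- codon_at(tx, pc$residue)
  cds_pos <- codon_positions(tx, pc$residue)
  alt_codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == pc$alt_aa]
  opts <- list()
  for (codon in sort(alt_codons)) {
    diff <- which(strsplit(ref_codon, "")[[1]] != strsplit(codon, "")[[1]])
    if (length(diff) == 0L) next
    ref_b <- substring(ref_codon, diff, diff)
    alt_b <- substring(codon, diff, diff)
    df <- data.frame(codon_pos = diff, cds_pos = cds_pos[diff],
                     ref = ref_b, alt = alt_b,
                     chemistry = vapply(seq_along(diff), function(j) {
                       substitution_chemistry(ref_b[j], alt_b[j])
                     }, character(1)),
                     stringsAsFactors = FALSE)
    attr(df, "target_codon") <- codon
    attr(df, "n_edits") <- length(diff)
    opts[[length(opts) + 1L]] <- df
  }
  ord <- order(vapply(opts, attr, 1L, "n_edits"),
               vapply(opts, attr, "", "target_codon"))
  opts[ord]
}

# Standard genetic code as a named vector codon -> one-letter AA ('*' stop).
# Derived once from Biostrings at load; an independent hard-coded table
# lives in the test suite as the oracle.
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Read transcripts from a FASTA file
#'
#' Record ids are parsed as `gene_id|role|frame_offset`; `role` defaults to
#' `"other"` and `frame_offset` to 0 when omitted. Sequences are uppercased
#' and validated strictly (no ambiguity codes). A record may carry flank
#' annotations in the description as `up=<seq> down=<seq>`.
#'
#' @param path Path to a FASTA file of CDS (sense-strand) sequences.
#' @return A named list of [transcript()] objects keyed by `gene_id`.
#' @export
read_transcripts_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(ss)) {
    header <- names(ss)[i]
    fields <- strsplit(sub("\\s.*$", "", header), "|", fixed = TRUE)[[1]]
    gene_id <- fields[1]
    role <- if (length(fields) >= 2L && nzchar(fields[2])) fields[2] else "other"
    fo <- if (length(fields) >= 3L && nzchar(fields[3])) as.integer(fields[3]) else 0L
    desc <- sub("^\\S+\\s*", "", header)
    up <- ""; down <- ""
    mu <- regmatches(desc, regexec("up=([ACGTacgt]+)", desc))[[1]]
    md <- regmatches(desc, regexec("down=([ACGTacgt]+)", desc))[[1]]
    if (length(mu) == 2L) up <- mu[2]
    if (length(md) == 2L) down <- md[2]
    out[[gene_id]] <- transcript(gene_id, as.character(ss[[i]]), role = role,
                                 up_flank = up, down_flank = down,
                                 frame_offset = fo)
  }
  out
}

#' Write transcripts to a FASTA file
#'
#' Inverse of [read_transcripts_fasta()]: headers carry
#' `gene_id|role|frame_offset` plus `up=`/`down=` flank annotations.
#'
#' @param transcripts Named list of [transcript()] objects.
#' @param path Output path.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    hdr <- sprintf(">%s|%s|%d", tx$gene_id, tx$role, tx$frame_offset)
    if (nzchar(tx$up_flank)) hdr <- paste0(hdr, " up=", tx$up_flank)
    if (nzchar(tx$down_flank)) hdr <- paste0(hdr, " down=", tx$down_flank)
    lines <- c(lines, hdr, tx$cds)
  }
  writeLines(lines, path)
  invisible(path)
}
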