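# Editor registry, PAM matching, protospacer enumeration and guide-candidate
# search. Window positions are 1-based from the 5' (PAM-distal) end of the
# protospacer; the deaminase substrate is the protospacer strand (the strand
# identical to the spacer), since the R-loop displaces that strand
# single-stranded. Hence a sense-strand C>T needs a sense protospacer with a
# downstream PAM, and a sense G>A needs an antisense protospacer.

#' Construct a base-editor specification
#'
#' @param name Unique editor name, e.g. `"SpCas9-CBE"`.
#' @param homolog Cas9 species family, `"Sp"` or `"Sa"` (determines the
#'   sgRNA backbone and therefore multiplex compatibility).
#' @param chemistry `"CBE"` (C->T via a uracil intermediate) or `"ABE"`
#'   (A->G via an inosine intermediate).
#' @param pam IUPAC PAM pattern immediately 3' of the protospacer.
#' @param spacer_len Spacer length in nt.
#' @param window Core editing window `[lo, hi]`, 1-based from the
#'   protospacer 5' end.
#' @param extended_window Opt-in wider window containing `window`;
#'   edits placed here outside the core window are flagged.
#' @return An object of class `editor_spec`.
#' @export
editor_spec <- function(name, homolog = c("Sp", "Sa"),
                        chemistry = c("CBE", "ABE"), pam,
                        spacer_len = 20L, window = c(4L, 8L),
                        extended_window = c(3L, 9L)) {
  homolog <- match.arg(homolog)
  chemistry <- match.arg(chemistry)
  spacer_len <- as.integer(spacer_len)
  window <- as.integer(window); extended_window <- as.integer(extended_window)
  pam <- toupper(pam)
  if (grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                   collapse = "")), pam)) {
    stop("PAM pattern contains non-IUPAC letters: ", pam, call. = FALSE)
  }
  if (length(window) != 2L || window[1] < 1L || window[1] > window[2] ||
      window[2] > spacer_len) {
    stop("invalid editing window", call. = FALSE)
  }
  if (extended_window[1] > window[1] || extended_window[2] < window[2] ||
      extended_window[1] < 1L || extended_window[2] > spacer_len) {
    stop("extended_window must contain window and fit the spacer",
         call. = FALSE)
  }
  structure(list(name = name, homolog = homolog, chemistry = chemistry,
                 pam = pam, spacer_len = spacer_len, window = window,
                 extended_window = extended_window),
            class = "editor_spec")
}

#' @export
print.editor_spec <- function(x, ...) {
  cat(sprintf("<editor_spec> %s: %s-%s, PAM %s, %d-nt spacer, window [%d,%d] (ext [%d,%d])\n",
              x$name, x$homolog, x$chemistry, x$pam, x$spacer_len,
              x$window[1], x$window[2],
              x$extended_window[1], x$extended_window[2]))
  invisible(x)
}

#' Default base-editor registry
#'
#' SpCas9 (NGG), SpCas9-NG (NG, plus a convenience NGT entry matching its
#' use on KRAS G12), SpRY (NAN), SaCas9 (NNGRRT) and SaKKH (NNNRRT), each in
#' CBE and ABE chemistry. Sp-family spacers are 20 nt, Sa-family 21 nt; all
#' entries use the canonical editing window [4,8] with extended window [3,9].
#'
#' @return A named list of [editor_spec()] objects.
#' @export
default_registry <- function() {
  specs <- list(
    list("SpCas9",     "Sp", "NGG",    20L),
    list("SpCas9-NG",  "Sp", "NG",     20L),
    list("SpCas9-NGT", "Sp", "NGT",    20L),
    list("SpRY",       "Sp", "NAN",    20L),
    list("SaCas9",     "Sa", "NNGRRT", 21L),
    list("SaKKH",      "Sa", "NNNRRT", 21L)
  )
  out <- list()
  for (s in specs) {
    for (chem in c("CBE", "ABE")) {
      nm <- paste0(s[[1]], "-", chem)
      out[[nm]] <- editor_spec(nm, homolog = s[[2]], chemistry = chem,
                               pam = s[[3]], spacer_len = s[[4]])
    }
  }
  out
}

#' Match a sequence against an IUPAC PAM pattern
#'
#' @param seq Concrete sequence over \{A,C,G,T\}.
#' @param pattern IUPAC pattern of the same length.
#' @return `TRUE` iff every base is in the IUPAC class of the corresponding
#'   pattern letter.
#' @export
match_pam <- function(seq, pattern) {
  seq <- nuc_seq(seq)
  pattern <- toupper(pattern)
  if (nchar(seq) != nchar(pattern)) {
    stop("sequence and pattern lengths differ", call. = FALSE)
  }
  map <- Biostrings::IUPAC_CODE_MAP
  pat <- strsplit(pattern, "")[[1]]
  if (!all(pat %in% names(map))) {
    stop("non-IUPAC letter in pattern: ", pattern, call. = FALSE)
  }
  sq <- strsplit(seq, "")[[1]]
  all(vapply(seq_along(pat), function(i) {
    grepl(sq[i], map[[pat[i]]], fixed = TRUE)
  }, logical(1)))
}

# Compile an IUPAC pattern into a regex character-class string.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% names(map))) {
    stop("non-IUPAC letter in pattern: ", pattern, call. = FALSE)
  }
  paste0(vapply(pat, function(p) paste0("[", map[[p]], "]"), character(1)),
         collapse = "")
}

#' Enumerate protospacer placements on one strand
#'
#' Reports every 1-based start position where `spacer_len` bases are
#' followed immediately 3' by a PAM match, in ascending order.
#'
#' @param strand_seq The strand sequence, 5'->3'.
#' @param editor An [editor_spec()].
#' @return Integer vector of start positions (possibly empty).
#' @export
enumerate_protospacers <- function(strand_seq, editor) {
  strand_seq <- nuc_seq(strand_seq)
  total <- editor$spacer_len + nchar(editor$pam)
  n <- nchar(strand_seq)
  if (n < total) return(integer(0))
  pam_re <- iupac_regex(editor$pam)
  # PAM occurrence starts (allow overlaps via lookahead)
  hits <- gregexpr(paste0("(?=", pam_re, ")"), strand_seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  starts <- as.integer(hits) - editor$spacer_len
  sort(starts[starts >= 1L & (starts + total - 1L) <= n])
}

# --- transcript/full-context coordinate helpers -----------------------------

full_context <- function(tx) paste0(tx$up_flank, tx$cds, tx$down_flank)

# map a 1-based CDS position to position in the full sense context
cds_to_full <- function(tx, pos) nchar(tx$up_flank) + as.integer(pos)

# map a full sense-context position to the antisense strand coordinate
full_to_antisense <- function(tx, pos) {
  nchar(full_context(tx)) - as.integer(pos) + 1L
}

substrate_base <- function(chemistry) if (chemistry == "CBE") "C" else "A"
edited_base <- function(chemistry) if (chemistry == "CBE") "T" else "G"

#' Construct a guide candidate record
#'
#' Usually produced by [find_guides()]; exported for fixture construction.
#'
#' @param editor Editor name.
#' @param spec The [editor_spec()] used.
#' @param gene_id Target gene.
#' @param spacer Protospacer-strand spacer sequence 5'->3'.
#' @param strand `"sense"` or `"antisense"` relative to the transcript.
#' @param protospacer_start 1-based 5' position of the spacer in the stated
#'   strand's coordinate system (the full CDS+flank context).
#' @param pam_seq Concrete PAM bases 3' of the protospacer.
#' @param target_offsets Window positions carrying required substitutions.
#' @param substrate_offsets All applied-window positions holding a
#'   chemistry-substrate base on the protospacer strand.
#' @param flags Character vector of efficiency-flag labels.
#' @param window_used The window interval the candidate was matched under.
#' @return An object of class `guide_candidate`.
#' @export
guide_candidate <- function(editor, spec, gene_id, spacer, strand,
                            protospacer_start, pam_seq, target_offsets,
                            substrate_offsets, flags = character(0),
                            window_used = spec$window) {
  structure(list(editor = editor, spec = spec, gene_id = gene_id,
                 spacer = spacer, strand = strand,
                 protospacer_start = as.integer(protospacer_start),
                 pam_seq = pam_seq,
                 target_offsets = sort(as.integer(target_offsets)),
                 substrate_offsets = sort(as.integer(substrate_offsets)),
                 flags = flags, window_used = as.integer(window_used)),
            class = "guide_candidate")
}

#' @export
print.guide_candidate <- function(x, ...) {
  cat(sprintf("<guide> %s %s %s@%d spacer %s PAM %s targets [%s] flags [%s]\n",
              x$gene_id, x$editor, x$strand, x$protospacer_start, x$spacer,
              x$pam_seq, paste(x$target_offsets, collapse = ","),
              paste(x$flags, collapse = ",")))
  invisible(x)
}

#' Efficiency flags for a guide candidate
#'
#' Encodes two empirical liabilities of base-editing efficiency: target
#' positions 3, 4 or 8 of the protospacer edit less efficiently
#' (`LOW_POSITION`), and a target cytosine inside an ACG trinucleotide on
#' the protospacer strand hampers editing (`BAD_CONTEXT`). Targets placed
#' outside the core window (extended-window designs) additionally carry
#' `OUTSIDE_CORE_WINDOW`.
#'
#' @param candidate A [guide_candidate()].
#' @param tx The [transcript()] the candidate was designed on.
#' @return Character vector drawn from
#'   \{`LOW_POSITION`, `BAD_CONTEXT`, `OUTSIDE_CORE_WINDOW`\}.
#' @export
efficiency_flags <- function(candidate, tx) {
  flags <- character(0)
  off <- candidate$target_offsets
  if (any(off %in% c(3L, 4L, 8L))) flags <- c(flags, "LOW_POSITION")
  strand_seq <- if (candidate$strand == "sense") full_context(tx) else
    reverse_complement(full_context(tx))
  pos <- candidate$protospacer_start + off - 1L
  tri <- substring(strand_seq, pos - 1L, pos + 1L)
  if (any(nchar(tri) == 3L & tri == "ACG")) flags <- c(flags, "BAD_CONTEXT")
  core <- candidate$spec$window
  if (any(off < core[1] | off > core[2])) {
    flags <- c(flags, "OUTSIDE_CORE_WINDOW")
  }
  flags
}

# Internal worker: find guides for a set of sense-strand substitutions given
# as parallel vectors of CDS positions / ref / alt.
find_guides_subst <- function(positions, refs, alts, tx, editors,
                              allow_extended = FALSE) {
  stopifnot(length(positions) == length(refs), length(refs) == length(alts))
  # verify refs against the CDS
  have <- substring(tx$cds, positions, positions)
  if (!all(have == refs)) {
    stop("reference mismatch at CDS position(s) ",
         paste(positions[have != refs], collapse = ","), call. = FALSE)
  }
  chems <- vapply(seq_along(refs), function(i) {
    substitution_chemistry(refs[i], alts[i])
  }, character(1))
  if (length(unique(chems)) != 1L || unique(chems) == "other") {
    return(list())  # no single-strand single-chemistry route
  }
  chem <- unique(chems)
  chemistry <- if (startsWith(chem, "C>T")) "CBE" else "ABE"
  strand <- if (endsWith(chem, "sense") && !endsWith(chem, "antisense"))
    "sense" else "antisense"

  full <- full_context(tx)
  strand_seq <- if (strand == "sense") full else reverse_complement(full)
  pos_full <- cds_to_full(tx, positions)
  pos_strand <- if (strand == "sense") pos_full else
    full_to_antisense(tx, pos_full)
  n <- nchar(strand_seq)

  out <- list()
  for (ed in editors) {
    if (ed$chemistry != chemistry) next
    win <- if (allow_extended) ed$extended_window else ed$window
    # protospacer starts s with all targets inside the window
    s_lo <- max(max(pos_strand) - win[2] + 1L, 1L)
    s_hi <- min(pos_strand) - win[1] + 1L
    if (s_hi < s_lo) next
    pam_len <- nchar(ed$pam)
    for (s in s_lo:s_hi) {
      if (s + ed$spacer_len + pam_len - 1L > n) next
      pam_seq <- substring(strand_seq, s + ed$spacer_len,
                           s + ed$spacer_len + pam_len - 1L)
      if (!match_pam(pam_seq, ed$pam)) next
      spacer <- substring(strand_seq, s, s + ed$spacer_len - 1L)
      offs <- win[1]:win[2]
      bases <- substring(strand_seq, s + offs - 1L, s + offs - 1L)
      subs <- offs[bases == substrate_base(chemistry)]
      cand <- guide_candidate(ed$name, ed, tx$gene_id, spacer, strand, s,
                              pam_seq, target_offsets = pos_strand - s + 1L,
                              substrate_offsets = subs, window_used = win)
      cand$flags <- efficiency_flags(cand, tx)
      out[[length(out) + 1L]] <- cand
    }
  }
  ord <- order(vapply(out, function(g) g$editor, ""),
               vapply(out, function(g) g$strand, ""),
               vapply(out, function(g) g$protospacer_start, 1L))
  out[ord]
}

#' Find guide candidates installing a desired edit
#'
#' A candidate is returned iff (a) all required substitutions lie on one
#' strand and share one chemistry (C->T for CBE or A->G for ABE, both read
#' on the protospacer strand), (b) all required substitution positions fall
#' in the editing window (the extended window when `allow_extended`), and
#' (c) the editor's PAM matches immediately 3' of the protospacer.
#' Protein-level edits are expanded through
#' [protein_to_nucleotide_options()] and return candidates per option.
#' Edits achievable by no registered editor yield an empty list.
#'
#' @param edit A [coding_change()], [protein_change()], or a string parsed
#'   as either (`"c.96C>T"` / `"p.S45P"`).
#' @param tx The target [transcript()].
#' @param editors List of [editor_spec()]; defaults to [default_registry()].
#' @param allow_extended Permit extended-window target placement (flagged
#'   `OUTSIDE_CORE_WINDOW`).
#' @return A list of [guide_candidate()] objects, deterministically ordered.
#'   For protein edits each candidate carries an `option` attribute-like
#'   field recording the substitution set used.
#' @export
find_guides <- function(edit, tx, editors = default_registry(),
                        allow_extended = FALSE) {
  if (is.character(edit)) {
    edit <- if (grepl("^\\s*c\\.", edit)) parse_coding_change(edit, tx) else
      parse_protein_change(edit, tx)
  }
  if (inherits(edit, "coding_change")) {
    return(find_guides_subst(edit$position, edit$ref, edit$alt, tx, editors,
                             allow_extended))
  }
  if (!inherits(edit, "protein_change")) {
    stop("edit must be a coding_change or protein_change", call. = FALSE)
  }
  opts <- protein_to_nucleotide_options(edit, tx)
  out <- list()
  for (opt in opts) {
    if (any(opt$chemistry == "other")) next
    cands <- find_guides_subst(opt$cds_pos, opt$ref, opt$alt, tx, editors,
                               allow_extended)
    for (g in cands) {
      g$option <- opt
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

#' Tabulate guide candidates
#'
#' @param guides A list of [guide_candidate()] objects.
#' @return A data.frame with one row per candidate.
#' @export
guides_as_data_frame <- function(guides) {
  if (length(guides) == 0L) {
    return(data.frame(gene = character(0), editor = character(0),
                      strand = character(0), protospacer_start = integer(0),
                      spacer = character(0), pam = character(0),
                      target_offsets = character(0),
                      substrate_offsets = character(0),
                      flags = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    gene = vapply(guides, function(g) g$gene_id, ""),
    editor = vapply(guides, function(g) g$editor, ""),
    strand = vapply(guides, function(g) g$strand, ""),
    protospacer_start = vapply(guides, function(g) g$protospacer_start, 1L),
    spacer = vapply(guides, function(g) g$spacer, ""),
    pam = vapply(guides, function(g) g$pam_seq, ""),
    target_offsets = vapply(guides, function(g)
      paste(g$target_offsets, collapse = ","), ""),
    substrate_offsets = vapply(guides, function(g)
      paste(g$substrate_offsets, collapse = ","), ""),
    flags = vapply(guides, function(g) paste(g$flags, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}
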