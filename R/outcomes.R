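# Bystander outcome enumeration, protein-consequence annotation, and
# CRISPR-stop scanning. Every subset of substrate bases in the editing
# window is a possible allele; the headline outcome (all substrates edited)
# reflects the full-window co-edits typically observed in edited clones.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Classify the protein consequence of a codon change
#'
#' `silent` iff both codons encode the same amino acid; `nonsense` iff the
#' new codon is a stop and the old one is not; otherwise `missense`.
#'
#' @param codon_before,codon_after Codon triplets.
#' @return One of `"silent"`, `"missense"`, `"nonsense"`.
#' @export
classify_consequence <- function(codon_before, codon_after) {
  codon_before <- nuc_seq(codon_before)
  codon_after <- nuc_seq(codon_after)
  if (nchar(codon_before) != 3L || nchar(codon_after) != 3L) {
    stop("codons must have length 3", call. = FALSE)
  }
  aa_b <- GENETIC_CODE_TABLE[[codon_before]]
  aa_a <- GENETIC_CODE_TABLE[[codon_after]]
  if (aa_b == aa_a) return("silent")
  if (aa_a == "*" && aa_b != "*") return("nonsense")
  "missense"
}

# consequences of an allele relative to the reference CDS, restricted to
# codons overlapping the edited CDS positions
allele_consequences <- function(tx, allele, edited_cds_pos) {
  if (length(edited_cds_pos) == 0L) {
    return(data.frame(codon_index = integer(0), codon_before = character(0),
                      codon_after = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- sort(unique((edited_cds_pos - tx$frame_offset + 2L) %/% 3L))
  idx <- idx[idx >= 1L & idx <= n_codons(tx)]
  rows <- lapply(idx, function(i) {
    p <- codon_positions(tx, i)
    before <- substring(tx$cds, p[1], p[3])
    after <- substring(allele, p[1], p[3])
    data.frame(codon_index = i, codon_before = before, codon_after = after,
               class = if (before == after) "silent" else
                 classify_consequence(before, after),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# apply edits at strand offsets of a candidate; returns the sense-strand CDS
# allele. `alt_by_offset`: named character vector offset -> replacement base
# on the protospacer strand.
apply_strand_edits <- function(candidate, tx, alt_by_offset) {
  full <- full_context(tx)
  cds_start <- nchar(tx$up_flank) + 1L
  cds_end <- nchar(tx$up_flank) + nchar(tx$cds)
  allele_full <- strsplit(full, "")[[1]]
  edited_cds <- integer(0)
  for (off_chr in names(alt_by_offset)) {
    off <- as.integer(off_chr)
    strand_pos <- candidate$protospacer_start + off - 1L
    full_pos <- if (candidate$strand == "sense") strand_pos else
      nchar(full) - strand_pos + 1L
    base <- alt_by_offset[[off_chr]]
    sense_base <- if (candidate$strand == "sense") base else
      chartr("ACGT", "TGCA", base)
    allele_full[full_pos] <- sense_base
    if (full_pos >= cds_start && full_pos <= cds_end) {
      edited_cds <- c(edited_cds, full_pos - cds_start + 1L)
    }
  }
  list(allele = paste(allele_full[cds_start:cds_end], collapse = ""),
       edited_cds_pos = sort(edited_cds))
}

#' Enumerate bystander edit outcomes for a guide
#'
#' Returns one outcome per subset of the candidate's substrate offsets
#' (2^k alleles, including the identity), applying the editor chemistry on
#' the protospacer strand and mapping back to the transcript sense strand.
#' The headline outcome is the full-substrate subset. When
#' `include_rare_cbe` is set and the chemistry is CBE, single-substrate
#' C>A and C>G variants of the headline outcome are appended and labeled
#' rare; these reflect occasional non-canonical CBE resolution and are
#' never counted towards targetability.
#'
#' @param candidate A [guide_candidate()].
#' @param tx The [transcript()] the candidate was designed on.
#' @param include_rare_cbe Also enumerate rare C>A / C>G headline variants.
#' @return A list of `edit_outcome` objects with fields `edited_offsets`,
#'   `allele` (sense CDS after edits), `consequences` (data.frame),
#'   `is_headline`, `rare`, `rare_alt`.
#' @export
enumerate_outcomes <- function(candidate, tx, include_rare_cbe = FALSE) {
  subs <- candidate$substrate_offsets
  k <- length(subs)
  if (k > 12L) {
    stop("more than 12 substrate bases in window; restrict the window ",
         "before enumerating outcomes", call. = FALSE)
  }
  chem <- candidate$spec$chemistry
  to <- edited_base(chem)
  outcomes <- list()
  for (mask in 0:(2^k - 1L)) {
    chosen <- subs[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    alt <- stats::setNames(rep(to, length(chosen)), as.character(chosen))
    ap <- apply_strand_edits(candidate, tx, alt)
    outcomes[[length(outcomes) + 1L]] <- structure(
      list(edited_offsets = chosen, allele = ap$allele,
           consequences = allele_consequences(tx, ap$allele,
                                              ap$edited_cds_pos),
           is_headline = length(chosen) == k, rare = FALSE, rare_alt = NA),
      class = "edit_outcome")
  }
  if (include_rare_cbe && chem == "CBE" && k > 0L) {
    for (o in subs) {
      for (rare_to in c("A", "G")) {
        alt <- stats::setNames(rep("T", k), as.character(subs))
        alt[[as.character(o)]] <- rare_to
        ap <- apply_strand_edits(candidate, tx, alt)
        outcomes[[length(outcomes) + 1L]] <- structure(
          list(edited_offsets = subs, allele = ap$allele,
               consequences = allele_consequences(tx, ap$allele,
                                                  ap$edited_cds_pos),
               is_headline = FALSE, rare = TRUE,
               rare_alt = sprintf("C>%s@%d", rare_to, o)),
          class = "edit_outcome")
      }
    }
  }
  outcomes
}

#' @export
print.edit_outcome <- function(x, ...) {
  lab <- if (x$is_headline) " (headline)" else if (isTRUE(x$rare))
    paste0(" (rare ", x$rare_alt, ")") else ""
  cons <- if (nrow(x$consequences) == 0L) "no coding change" else
    paste(sprintf("%s%d%s[%s]", x$consequences$codon_before,
                  x$consequences$codon_index, x$consequences$codon_after,
                  x$consequences$class), collapse = ", ")
  cat(sprintf("<outcome> offsets [%s]%s: %s\n",
              paste(x$edited_offsets, collapse = ","), lab, cons))
  invisible(x)
}

#' Codons convertible to a stop by C>T editing
#'
#' Computed by brute force over all 64 codons and all subsets of C->T edits
#' on either strand (antisense C->T appearing as G->A on the codon). Only
#' non-stop codons reaching a stop are reported. The result is
#' \{CAA, CAG, CGA: sense; TGG: antisense\}, i.e. the Gln/Arg/Trp residues
#' accessible to CRISPR-stop.
#'
#' @return Named list codon -> data.frame of strategies with columns
#'   `strategy` (`sense_C>T` / `antisense_C>T`), `codon_positions`
#'   (comma-separated edited positions 1-3) and `stop_codon`.
#' @export
stop_convertible_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE),
                  1L, paste, collapse = "")
  out <- list()
  for (codon in sort(codons)) {
    if (codon %in% STOP_CODONS) next
    strategies <- list()
    cv <- strsplit(codon, "")[[1]]
    # sense strategy: C -> T at any subset of C positions
    c_pos <- which(cv == "C")
    for (sub in edit_subsets(c_pos)) {
      new <- cv; new[sub] <- "T"
      nc <- paste(new, collapse = "")
      if (nc %in% STOP_CODONS) {
        strategies[[length(strategies) + 1L]] <- data.frame(
          strategy = "sense_C>T",
          codon_positions = paste(sub, collapse = ","),
          stop_codon = nc, stringsAsFactors = FALSE)
      }
    }
    # antisense strategy: G -> A (C>T on the opposite strand)
    g_pos <- which(cv == "G")
    for (sub in edit_subsets(g_pos)) {
      new <- cv; new[sub] <- "A"
      nc <- paste(new, collapse = "")
      if (nc %in% STOP_CODONS) {
        strategies[[length(strategies) + 1L]] <- data.frame(
          strategy = "antisense_C>T",
          codon_positions = paste(sub, collapse = ","),
          stop_codon = nc, stringsAsFactors = FALSE)
      }
    }
    if (length(strategies) > 0L) out[[codon]] <- do.call(rbind, strategies)
  }
  out
}

# non-empty subsets of a position vector
edit_subsets <- function(pos) {
  k <- length(pos)
  if (k == 0L) return(list())
  out <- list()
  for (mask in 1:(2^k - 1L)) {
    out[[mask]] <- pos[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
  }
  out
}

#' Scan a CDS for CRISPR-stop sites
#'
#' For every codon occurrence convertible to a stop by C>T editing, searches
#' the supplied CBE editors for guides placing the required edits in the
#' editing window with a matching PAM. One site is reported per codon with
#' at least one valid guide; with `report_unguided`, convertible codons
#' lacking any PAM-supported guide are reported with an empty guide list.
#'
#' @param tx A [transcript()].
#' @param editors Editor list; only CBE-chemistry entries are used.
#' @param allow_extended Permit extended-window designs (flagged).
#' @param report_unguided Also report convertible codons without guides.
#' @return A list of `stop_site` objects with fields `codon_index`, `codon`,
#'   `strategies` (data.frame as in [stop_convertible_codons()]), `guides`.
#' @export
crispr_stop_scan <- function(tx, editors = default_registry(),
                             allow_extended = FALSE,
                             report_unguided = FALSE) {
  cbes <- Filter(function(e) e$chemistry == "CBE", editors)
  if (length(cbes) == 0L) {
    stop("no CBE editors supplied; CRISPR-stop requires C>T chemistry",
         call. = FALSE)
  }
  conv <- stop_convertible_codons()
  sites <- list()
  for (i in seq_len(n_codons(tx))) {
    codon <- codon_at(tx, i)
    strat <- conv[[codon]]
    if (is.null(strat)) next
    guides <- list()
    pos <- codon_positions(tx, i)
    for (r in seq_len(nrow(strat))) {
      cp <- as.integer(strsplit(strat$codon_positions[r], ",")[[1]])
      cds_pos <- pos[cp]
      refs <- substring(tx$cds, cds_pos, cds_pos)
      alts <- if (strat$strategy[r] == "sense_C>T") rep("T", length(cp)) else
        rep("A", length(cp))
      cands <- find_guides_subst(cds_pos, refs, alts, tx, cbes,
                                 allow_extended)
      for (g in cands) {
        g$stop_strategy <- strat$strategy[r]
        g$stop_codon <- strat$stop_codon[r]
        guides[[length(guides) + 1L]] <- g
      }
    }
    if (length(guides) > 0L || report_unguided) {
      sites[[length(sites) + 1L]] <- structure(
        list(codon_index = i, codon = codon,
             residue = GENETIC_CODE_TABLE[[codon]],
             strategies = strat, guides = guides),
        class = "stop_site")
    }
  }
  sites
}

#' @export
print.stop_site <- function(x, ...) {
  cat(sprintf("<stop_site> codon %d (%s, %s): %d strateg%s, %d guide(s)\n",
              x$codon_index, x$codon, x$residue, nrow(x$strategies),
              if (nrow(x$strategies) == 1L) "y" else "ies",
              length(x$guides)))
  invisible(x)
}

#' Write a (site, guide, outcome) TSV report
#'
#' One row per combination of stop/design site, guide and enumerated
#' outcome, with a '#'-prefixed metadata header.
#'
#' @param sites List of `stop_site` objects from [crispr_stop_scan()].
#' @param tx The scanned [transcript()].
#' @param path Output TSV path.
#' @param include_rare_cbe Forwarded to [enumerate_outcomes()].
#' @return The output path, invisibly.
#' @export
write_stop_report_tsv <- function(sites, tx, path,
                                  include_rare_cbe = FALSE) {
  rows <- list()
  for (s in sites) {
    if (length(s$guides) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = tx$gene_id, codon_index = s$codon_index, codon = s$codon,
        residue = s$residue, spacer = NA, pam = NA, editor = NA,
        strand = NA, offsets = NA, consequences = NA, flags = NA,
        stringsAsFactors = FALSE)
      next
    }
    for (g in s$guides) {
      outs <- enumerate_outcomes(g, tx, include_rare_cbe)
      for (o in outs) {
        cons <- if (nrow(o$consequences) == 0L) "none" else
          paste(sprintf("%s%d%s:%s", o$consequences$codon_before,
                        o$consequences$codon_index,
                        o$consequences$codon_after, o$consequences$class),
                collapse = ";")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = tx$gene_id, codon_index = s$codon_index, codon = s$codon,
          residue = s$residue, spacer = g$spacer, pam = g$pam_seq,
          editor = g$editor, strand = g$strand,
          offsets = paste(o$edited_offsets, collapse = ","),
          consequences = cons, flags = paste(g$flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene = character(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bemux stop-scan report: gene=%s codons=%d",
                     tx$gene_id, n_codons(tx)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
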