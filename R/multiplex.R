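# Multi-edit panel assembly, cross-editor sgRNA interference auditing, and
# functional selection-strategy annotation. Interference is the same-homolog
# cross-loading mechanism: an sgRNA designed for a CBE built on one Cas9
# backbone is equally loaded by an ABE on the same backbone (and vice
# versa), so opposite-chemistry substrates in its window can be edited
# unintentionally. Mixing Cas9 homologs (Sp vs Sa) avoids this because the
# sgRNA backbones are mutually incompatible.

#' Assemble a panel of multiplexed edits
#'
#' @param entries List of entries, each a list with fields `edit` (the
#'   requested change, any form accepted by [find_guides()]), `tx` (the
#'   [transcript()]), `guide` (the chosen [guide_candidate()]) and `editor`
#'   (the [editor_spec()] delivering it).
#' @param delivered_editors List of all [editor_spec()] objects co-delivered
#'   in the experiment; must contain every entry's editor.
#' @return An object of class `panel`.
#' @export
panel <- function(entries, delivered_editors) {
  nm <- vapply(delivered_editors, function(e) e$name, "")
  for (en in entries) {
    if (!(en$editor$name %in% nm)) {
      stop("entry editor ", en$editor$name,
           " not among delivered editors", call. = FALSE)
    }
  }
  structure(list(entries = entries,
                 delivered_editors = delivered_editors),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %d entries, %d delivered editors\n",
              length(x$entries), length(x$delivered_editors)))
  for (en in x$entries) {
    cat(sprintf("  %s %s via %s\n", en$tx$gene_id,
                if (is.character(en$edit)) en$edit else format(en$edit),
                en$editor$name))
  }
  invisible(x)
}

#' Audit cross-editor sgRNA interference in a panel
#'
#' For each entry and each delivered editor sharing the entry's sgRNA
#' backbone (same Cas9 homolog) but of opposite chemistry, enumerates the
#' cross-chemistry outcomes at the entry's protospacer. Severity is
#' `"coding"` if any non-identity cross outcome is missense or nonsense,
#' `"silent_only"` if all non-identity outcomes are silent (or fall outside
#' the CDS), and `"none"` if the window holds no cross-chemistry substrate.
#'
#' @param pan A [panel()].
#' @return List of `interference_finding` objects with fields `entry`,
#'   `cross_editor`, `cross_outcomes`, `severity`. Entries whose window
#'   holds no opposite-chemistry substrate still yield a `"none"` finding
#'   record only when a same-homolog opposite-chemistry editor is delivered.
#' @export
check_interference <- function(pan) {
  findings <- list()
  for (i in seq_along(pan$entries)) {
    en <- pan$entries[[i]]
    g <- en$guide
    for (ce in pan$delivered_editors) {
      if (ce$name == en$editor$name) next
      if (ce$homolog != en$editor$homolog) next
      if (ce$chemistry == en$editor$chemistry) next
      cross <- cross_candidate(g, ce)
      outs <- enumerate_outcomes(cross, en$tx)
      non_id <- Filter(function(o) length(o$edited_offsets) > 0L, outs)
      severity <- if (length(non_id) == 0L) "none" else {
        classes <- unlist(lapply(non_id, function(o) o$consequences$class))
        if (any(classes %in% c("missense", "nonsense"))) "coding"
        else "silent_only"
      }
      findings[[length(findings) + 1L]] <- structure(
        list(entry = i, cross_editor = ce$name, cross_outcomes = outs,
             severity = severity),
        class = "interference_finding")
    }
  }
  findings
}

# re-type a candidate under a cross-loading editor: same placement and
# spacer, substrate offsets recomputed for the cross chemistry
cross_candidate <- function(g, cross_editor) {
  win <- g$window_used
  offs <- win[1]:win[2]
  bases <- substring(g$spacer, offs, offs)
  subs <- offs[bases == substrate_base(cross_editor$chemistry)]
  g2 <- g
  g2$editor <- cross_editor$name
  g2$spec <- cross_editor
  g2$target_offsets <- integer(0)
  g2$substrate_offsets <- subs
  g2
}

#' @export
print.interference_finding <- function(x, ...) {
  cat(sprintf("<interference> entry %d x %s: severity %s\n",
              x$entry, x$cross_editor, x$severity))
  invisible(x)
}

#' Greedily assign Cas9 homologs/editors to a set of edits
#'
#' Deterministic greedy assignment: edits are canonically sorted (by gene,
#' then formatted edit), then each receives the candidate guide minimizing
#' the number of coding-severity interference findings against the panel so
#' far, tie-broken by fewer efficiency flags, then by editor name and
#' lexicographic spacer. Splitting chemistries across homologs (e.g.
#' Sa-CBE with Sp-ABE) emerges whenever same-homolog pairing would create
#' coding cross-edits.
#'
#' @param edits List of entries, each a list with `edit` and `tx` (plus an
#'   optional `preferred_editor` name restricting candidates).
#' @param editors Registry of [editor_spec()] objects.
#' @param allow_extended Forwarded to [find_guides()].
#' @return A [panel()] whose delivered editors are those actually used.
#' @export
assign_homologs <- function(edits, editors = default_registry(),
                            allow_extended = FALSE) {
  fmt <- vapply(edits, function(e) {
    paste(e$tx$gene_id,
          if (is.character(e$edit)) e$edit else format(e$edit))
  }, "")
  edits <- edits[order(fmt)]
  entries <- list()
  delivered <- list()
  for (e in edits) {
    eds <- editors
    if (!is.null(e$preferred_editor)) {
      eds <- Filter(function(x) x$name == e$preferred_editor, eds)
    }
    cands <- find_guides(e$edit, e$tx, eds, allow_extended)
    if (length(cands) == 0L) {
      stop("unsatisfiable edit: no guide candidate for ", e$tx$gene_id, " ",
           if (is.character(e$edit)) e$edit else format(e$edit),
           call. = FALSE)
    }
    ed_of <- function(g) editors[[g$editor]]
    scores <- vapply(cands, function(g) {
      trial_entries <- c(entries, list(list(edit = e$edit, tx = e$tx,
                                            guide = g, editor = ed_of(g))))
      trial_delivered <- unique_editors(c(delivered, list(ed_of(g))))
      f <- check_interference(panel(trial_entries, trial_delivered))
      sum(vapply(f, function(x) x$severity == "coding", TRUE))
    }, 1L)
    ord <- order(scores,
                 vapply(cands, function(g) length(g$flags), 1L),
                 vapply(cands, function(g) g$editor, ""),
                 vapply(cands, function(g) g$spacer, ""))
    best <- cands[[ord[1]]]
    entries[[length(entries) + 1L]] <- list(edit = e$edit, tx = e$tx,
                                            guide = best,
                                            editor = ed_of(best))
    delivered <- unique_editors(c(delivered, list(ed_of(best))))
  }
  panel(entries, delivered)
}

unique_editors <- function(eds) {
  nm <- vapply(eds, function(e) e$name, "")
  eds[!duplicated(nm)]
}

#' Default functional selection table
#'
#' Gene-to-intervention mapping for functional selection of edited
#' organoids: APC loss selected by withdrawal of Wnt activators, TP53 loss
#' by Nutlin-3, PIK3CA activation by MEK inhibition, CTNNB1 activation by
#' withdrawal of the Wnt activators CHIR/R-spondin1 plus Nutlin-3 context.
#' Fully user-overridable.
#'
#' @return Named character vector gene -> intervention description.
#' @export
default_selection_table <- function() {
  c(APC = "removal of Wnt-Surrogate and Rspo1-conditioned medium",
    TP53 = "addition of Nutlin-3",
    PIK3CA = "addition of Meki",
    CTNNB1 = "removal of the Wnt activators Chir and R-spondin1")
}

#' Annotate a panel with its functional selection plan
#'
#' Genes absent from the table fall back to antibiotic/transfection
#' selection (stable integration of a hygromycin cassette).
#'
#' @param pan A [panel()].
#' @param selection_table Named character vector gene -> intervention.
#' @return data.frame with columns `gene`, `edit`, `editor`, `selection`.
#' @export
annotate_selection <- function(pan, selection_table = default_selection_table()) {
  rows <- lapply(pan$entries, function(en) {
    gene <- en$tx$gene_id
    sel <- if (gene %in% names(selection_table)) selection_table[[gene]] else
      "antibiotic/transfection selection"
    data.frame(gene = gene,
               edit = if (is.character(en$edit)) en$edit else format(en$edit),
               editor = en$editor$name, selection = sel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
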