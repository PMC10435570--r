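# Targetability aggregation over a COSMIC-like variant catalog: for each
# pathogenic variant, does at least one base editor have a suitable sgRNA
# (chemistry + window + PAM) to install it? Aggregated per role (oncogene /
# tumor suppressor) at the variant and the gene level.

#' Read a COSMIC-like variant catalog
#'
#' Thin column-mapping layer over a TSV with columns `gene`, `role`
#' (oncogene/tsg), `coding_change` (HGVS-like, e.g. `c.96C>T`) and
#' `pathogenic` (0/1). Lines starting with '#' are ignored. Which release
#' or pathogenicity tier defines "pathogenic" is left to the user.
#'
#' @param path TSV path.
#' @return data.frame with those four columns (`pathogenic` as logical).
#' @export
read_catalog_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "role", "coding_change", "pathogenic")
  if (!all(need %in% names(df))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$pathogenic <- as.logical(as.integer(df$pathogenic))
  df
}

#' Write a variant catalog TSV
#' @param catalog data.frame as returned by [read_catalog_tsv()].
#' @param path Output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  catalog$pathogenic <- as.integer(catalog$pathogenic)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bemux variant catalog: gene role coding_change pathogenic",
             con)
  utils::write.table(catalog, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-editor targetability of a single variant
#'
#' An editor can target a variant iff [find_guides()] returns at least one
#' candidate under the strict core window (no extended positions);
#' bystander substrates do not disqualify a guide.
#'
#' @param coding_change_text HGVS-like change string (e.g. `"c.96C>T"`).
#' @param tx The gene's [transcript()].
#' @param editors Registry of [editor_spec()] objects.
#' @param allow_extended Count extended-window designs as targetable
#'   (off by default; reported separately when used).
#' @return Named logical vector, one element per editor.
#' @export
variant_targetable <- function(coding_change_text, tx,
                               editors = default_registry(),
                               allow_extended = FALSE) {
  cc <- parse_coding_change(coding_change_text, tx)
  vapply(editors, function(ed) {
    length(find_guides(cc, tx, list(ed), allow_extended)) > 0L
  }, logical(1))
}

#' Aggregate targetability over a variant catalog
#'
#' Applies the pathogenic filter first; a variant counts as targetable iff
#' targetable by at least one editor, and a gene counts iff at least one of
#' its pathogenic variants is targetable. Fractions are reported to 4
#' decimals. Variants whose gene lacks a transcript are skipped with a
#' warning record in the report.
#'
#' @param catalog data.frame from [read_catalog_tsv()].
#' @param transcripts Named list of [transcript()] objects.
#' @param editors Registry of [editor_spec()] objects.
#' @param allow_extended Forwarded to [variant_targetable()].
#' @return An object of class `targetability_report`: a list with `by_role`
#'   (data.frame of counts/fractions per role), `by_editor` (per-editor
#'   targetable variant counts), `per_variant` (row-level booleans),
#'   `skipped` (skip records), `empty` flag.
#' @export
scan_catalog <- function(catalog, transcripts,
                         editors = default_registry(),
                         allow_extended = FALSE) {
  cat_p <- catalog[catalog$pathogenic, , drop = FALSE]
  skipped <- list()
  per_variant <- list()
  editor_names <- vapply(editors, function(e) e$name, "")
  for (r in seq_len(nrow(cat_p))) {
    gene <- cat_p$gene[r]
    tx <- transcripts[[gene]]
    if (is.null(tx)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        gene = gene, coding_change = cat_p$coding_change[r],
        reason = "missing transcript", stringsAsFactors = FALSE)
      next
    }
    tm <- variant_targetable(cat_p$coding_change[r], tx, editors,
                             allow_extended)
    per_variant[[length(per_variant) + 1L]] <- cbind(
      data.frame(gene = gene, role = cat_p$role[r],
                 coding_change = cat_p$coding_change[r],
                 targetable = any(tm), stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(tm, editor_names))))
  }
  pv <- if (length(per_variant) > 0L) do.call(rbind, per_variant) else NULL
  empty <- is.null(pv)
  roles <- c("oncogene", "tsg")
  by_role <- do.call(rbind, lapply(roles, function(role) {
    sub <- if (empty) NULL else pv[pv$role == role, , drop = FALSE]
    n_var <- if (is.null(sub)) 0L else nrow(sub)
    n_tar <- if (is.null(sub)) 0L else sum(sub$targetable)
    genes <- if (is.null(sub)) character(0) else unique(sub$gene)
    genes_t <- if (is.null(sub)) character(0) else
      unique(sub$gene[sub$targetable])
    data.frame(role = role,
               n_pathogenic_variants = n_var,
               n_targetable_variants = n_tar,
               variant_fraction = if (n_var == 0L) 0 else
                 round(n_tar / n_var, 4L),
               n_genes = length(genes),
               n_genes_with_any_targetable = length(genes_t),
               gene_fraction = if (length(genes) == 0L) 0 else
                 round(length(genes_t) / length(genes), 4L),
               stringsAsFactors = FALSE)
  }))
  by_editor <- if (empty) {
    stats::setNames(rep(0L, length(editor_names)), editor_names)
  } else {
    vapply(editor_names, function(nm) sum(pv[[nm]]), 1L)
  }
  structure(list(by_role = by_role, by_editor = by_editor,
                 per_variant = pv,
                 skipped = if (length(skipped) > 0L)
                   do.call(rbind, skipped) else NULL,
                 empty = empty),
            class = "targetability_report")
}

#' @export
print.targetability_report <- function(x, ...) {
  cat("<targetability_report>\n")
  print(x$by_role, row.names = FALSE)
  if (x$empty) cat("  (empty catalog: fractions reported as 0)\n")
  if (!is.null(x$skipped)) {
    cat(sprintf("  %d variant(s) skipped (missing transcript)\n",
                nrow(x$skipped)))
  }
  invisible(x)
}

#' Write a targetability report (TSV + JSON summary)
#'
#' @param report A `targetability_report` from [scan_catalog()].
#' @param tsv_path Row-level TSV output path (per-variant booleans).
#' @param json_path JSON summary output path (role-level aggregation).
#' @export
write_targetability_report <- function(report, tsv_path, json_path) {
  con <- file(tsv_path, "w")
  writeLines("# bemux targetability report (per pathogenic variant)", con)
  df <- if (is.null(report$per_variant))
    data.frame(gene = character(0)) else report$per_variant
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(by_role = report$by_role,
         by_editor = as.list(report$by_editor),
         empty_catalog = report$empty),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
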