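# Seeded generators producing inputs with known ground truth for every
# pipeline stage: transcripts with planted editable codons and PAM
# placements, variant catalogs with a known targetable fraction, mutation
# sets drawn from known signature mixtures over a gene-body/intergenic
# interval model, and clone mutation-load samples for two groups. Each
# generator draws from its own named random stream derived from the single
# seed, so adding a generator never shifts existing outputs, and each
# self-verifies its ground truth against the production operations before
# returning.

# derive a sub-seed (< 2^31) for a named stream
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

random_bases <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# instantiate an IUPAC pattern with concrete random bases
instantiate_pam <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(toupper(pattern), "")[[1]], function(p) {
    choices <- strsplit(map[[p]], "")[[1]]
    sample(choices, 1L)
  }, character(1)), collapse = "")
}

#' Specify a planted editable codon
#'
#' @param codon Codon triplet to plant (e.g. `"CAA"`).
#' @param codon_index 1-based codon index in the generated CDS.
#' @param pam_for Name of the registry editor the plant must satisfy.
#' @param strand `"sense"` or `"antisense"`: the protospacer strand on
#'   which the codon's editable base is placed.
#' @param window_offset Window position (from the protospacer 5' end) of
#'   the codon's editable base.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(codon, codon_index, pam_for = "SpCas9-CBE",
                       strand = c("sense", "antisense"),
                       window_offset = 6L) {
  strand <- match.arg(strand)
  structure(list(codon = nuc_seq(codon), codon_index = as.integer(codon_index),
                 pam_for = pam_for, strand = strand,
                 window_offset = as.integer(window_offset)),
            class = "plant_spec")
}

#' Generate a transcript with planted editable codons
#'
#' Builds an `n_codons` CDS of filler codons (biased against G to keep the
#' sequence PAM-poor for NGG-family editors), overwrites the planted
#' codons, and writes a concrete PAM so each plant's editable base sits at
#' the requested window offset of a valid protospacer for the requested
#' editor. The generator asserts each plant is recovered by [find_guides()]
#' before returning; residual incidental sites elsewhere are permitted.
#'
#' The editable base of a plant is the first chemistry-substrate base of
#' the codon on the requested protospacer strand (C for CBE, A for ABE).
#'
#' @param seed Integer seed (named stream "transcript").
#' @param n_codons CDS length in codons.
#' @param plants List of [plant_spec()] objects, mutually non-overlapping.
#' @param gene_id,role Forwarded to [transcript()].
#' @param editors Registry used for plant placement and self-verification.
#' @return List with `transcript` and `truth` (per-plant data.frame of
#'   codon index, edit, editor, strand, expected window offset).
#' @export
gen_transcript <- function(seed, n_codons, plants = list(),
                           gene_id = "SYNTH1", role = "other",
                           editors = default_registry()) {
  set.seed(derive_seed(seed, "transcript"))
  idx <- vapply(plants, function(p) p$codon_index, 1L)
  if (anyDuplicated(idx)) stop("plants overlap", call. = FALSE)
  if (length(idx) > 0L && max(idx) > n_codons) {
    stop("plant codon_index beyond n_codons", call. = FALSE)
  }
  # PAM-poor filler: G down-weighted to limit incidental NGG sites
  filler_prob <- c(A = 0.35, C = 0.2, G = 0.1, T = 0.35)
  cds <- vapply(seq_len(n_codons), function(i) random_bases(3L, filler_prob),
                character(1))
  for (p in plants) cds[p$codon_index] <- p$codon
  cds <- paste(cds, collapse = "")
  up <- random_bases(30L, filler_prob)
  down <- random_bases(30L, filler_prob)

  truth_rows <- list()
  for (p in plants) {
    ed <- editors[[p$pam_for]]
    if (is.null(ed)) stop("unknown editor in plant: ", p$pam_for,
                          call. = FALSE)
    sub <- substrate_base(ed$chemistry)
    cpos <- (p$codon_index * 3L - 2L):(p$codon_index * 3L)
    codon_sense <- strsplit(p$codon, "")[[1]]
    strand_codon <- if (p$strand == "sense") codon_sense else
      rev(chartr("ACGT", "TGCA", codon_sense))
    hit <- which(strand_codon == sub)
    if (length(hit) == 0L) {
      stop("plant codon ", p$codon, " has no ", sub, " substrate on the ",
           p$strand, " strand", call. = FALSE)
    }
    edit_in_codon <- hit[1]
    # position of the editable base in full sense coordinates
    sense_pos_in_codon <- if (p$strand == "sense") edit_in_codon else
      4L - edit_in_codon
    full <- paste0(up, cds, down)
    full_pos <- nchar(up) + cpos[1] - 1L + sense_pos_in_codon
    strand_pos <- if (p$strand == "sense") full_pos else
      nchar(full) - full_pos + 1L
    proto_start <- strand_pos - p$window_offset + 1L
    pam_start <- proto_start + ed$spacer_len
    if (proto_start < 1L || pam_start + nchar(ed$pam) - 1L > nchar(full)) {
      stop("plant at codon ", p$codon_index,
           " does not fit the context; increase n_codons or flanks",
           call. = FALSE)
    }
    pam_concrete <- instantiate_pam(ed$pam)
    # write the PAM on the protospacer strand, mapped to sense coordinates
    full_chars <- strsplit(full, "")[[1]]
    for (j in seq_len(nchar(ed$pam))) {
      sp <- pam_start + j - 1L
      fp <- if (p$strand == "sense") sp else nchar(full) - sp + 1L
      b <- substring(pam_concrete, j, j)
      full_chars[fp] <- if (p$strand == "sense") b else
        chartr("ACGT", "TGCA", b)
    }
    full <- paste(full_chars, collapse = "")
    up <- substring(full, 1L, nchar(up))
    cds <- substring(full, nchar(up) + 1L, nchar(up) + nchar(cds))
    down <- substring(full, nchar(up) + nchar(cds) + 1L, nchar(full))
    # the plant's designed edit, in sense CDS coordinates
    cds_pos <- cpos[1] - 1L + sense_pos_in_codon
    ref <- substring(cds, cds_pos, cds_pos)
    alt <- if (p$strand == "sense") edited_base(ed$chemistry) else
      chartr("ACGT", "TGCA", edited_base(ed$chemistry))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      codon_index = p$codon_index, cds_pos = cds_pos, ref = ref, alt = alt,
      editor = p$pam_for, strand = p$strand,
      window_offset = p$window_offset, stringsAsFactors = FALSE)
  }
  # PAM writes may have clobbered a planted codon written earlier; re-write
  # plants and fail if a PAM then breaks (plants too close together)
  for (p in plants) {
    cpos <- (p$codon_index * 3L - 2L)
    if (substring(cds, cpos, cpos + 2L) != p$codon) {
      stop("unsatisfiable plant layout: PAM of one plant overlaps codon ",
           "of another", call. = FALSE)
    }
  }
  tx <- transcript(gene_id, cds, role = role, up_flank = up,
                   down_flank = down, frame_offset = 0L)
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame()
  # self-verification: every plant recoverable by the production search
  for (r in seq_len(nrow(truth))) {
    cc <- coding_change(truth$cds_pos[r], truth$ref[r], truth$alt[r])
    gg <- find_guides(cc, tx, editors[truth$editor[r]],
                      allow_extended = TRUE)
    found <- any(vapply(gg, function(g) {
      g$strand == truth$strand[r] &&
        truth$window_offset[r] %in% g$target_offsets
    }, logical(1)))
    if (!found) {
      stop("unsatisfiable plant: codon ", truth$codon_index[r],
           " not recovered by find_guides (a later plant's PAM likely ",
           "overlaps this plant's protospacer or PAM; space plants apart)",
           call. = FALSE)
    }
  }
  list(transcript = tx, truth = truth)
}

#' Generate a variant catalog with a known targetable fraction
#'
#' Plants PAM-adjacent transition variants (sense C>T at window offset 5 of
#' a valid SpCas9 protospacer) for the targetable fraction, and transversion
#' variants (C>G, untargetable by any transition chemistry regardless of
#' PAM placement) for the remainder. The targetable count is
#' `round(frac_targetable * n_variants)`; the realized per-variant truth is
#' recorded and self-verified against [variant_targetable()].
#'
#' @param seed Integer seed (named stream "catalog").
#' @param n_genes Number of genes (transcripts) to distribute variants over.
#' @param n_variants Total number of pathogenic variants.
#' @param frac_targetable Fraction in `[0, 1]` of variants to make
#'   targetable.
#' @param editors Registry used for planting and verification.
#' @return List with `catalog` (data.frame), `transcripts` (named list) and
#'   `truth` (data.frame with per-variant `targetable`).
#' @export
gen_catalog <- function(seed, n_genes, n_variants, frac_targetable,
                        editors = default_registry()) {
  if (frac_targetable < 0 || frac_targetable > 1) {
    stop("frac_targetable must be in [0, 1]", call. = FALSE)
  }
  set.seed(derive_seed(seed, "catalog"))
  n_target <- as.integer(round(frac_targetable * n_variants))
  roles <- sample(c("oncogene", "tsg"), n_genes, replace = TRUE)
  gene_ids <- sprintf("SGENE%02d", seq_len(n_genes))
  # one variant slot per variant; round-robin genes; codon slots spaced out
  gene_of <- rep(gene_ids, length.out = n_variants)
  slot_of <- as.integer((seq_len(n_variants) - 1L) %/% n_genes)
  transcripts <- list()
  rows <- list(); truth <- list()
  for (gi in seq_len(n_genes)) {
    vidx <- which(gene_of == gene_ids[gi])
    n_codons <- 10L + 8L * length(vidx)
    plants <- list()
    for (k in seq_along(vidx)) {
      v <- vidx[k]
      if (v <= n_target) {
        plants[[length(plants) + 1L]] <- plant_spec(
          "CAA", codon_index = 5L + 8L * (k - 1L),
          pam_for = "SpCas9-CBE", strand = "sense", window_offset = 5L)
      }
    }
    gt <- gen_transcript(seed + gi, n_codons, plants,
                         gene_id = gene_ids[gi], role = roles[gi],
                         editors = editors)
    transcripts[[gene_ids[gi]]] <- gt$transcript
    plant_row <- 0L
    for (k in seq_along(vidx)) {
      v <- vidx[k]
      if (v <= n_target) {
        plant_row <- plant_row + 1L
        tr <- gt$truth[plant_row, ]
        change <- sprintf("c.%d%s>%s", tr$cds_pos, tr$ref, tr$alt)
        targetable <- TRUE
      } else {
        # transversion at a codon slot: untargetable by CBE/ABE chemistry
        ci <- 5L + 8L * (k - 1L)
        pos <- 3L * ci - 2L
        ref <- substring(gt$transcript$cds, pos, pos)
        alt <- setdiff(c("A", "C", "G", "T"),
                       c(ref, switch(ref, A = "G", G = "A", C = "T",
                                     T = "C")))[1]
        change <- sprintf("c.%d%s>%s", pos, ref, alt)
        targetable <- FALSE
      }
      rows[[v]] <- data.frame(gene = gene_ids[gi], role = roles[gi],
                              coding_change = change, pathogenic = TRUE,
                              stringsAsFactors = FALSE)
      truth[[v]] <- data.frame(gene = gene_ids[gi], coding_change = change,
                               targetable = targetable,
                               stringsAsFactors = FALSE)
    }
  }
  catalog <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  # self-verification against the production operation
  for (r in seq_len(nrow(truth))) {
    tm <- variant_targetable(truth$coding_change[r],
                             transcripts[[truth$gene[r]]], editors)
    if (any(tm) != truth$targetable[r]) {
      stop("generator self-check failed for ", truth$gene[r], " ",
           truth$coding_change[r], call. = FALSE)
    }
  }
  list(catalog = catalog, transcripts = transcripts, truth = truth)
}

#' Generate a genome interval model
#'
#' A toy single-chromosome genome of the given length with regularly
#' spaced gene bodies covering the requested fraction.
#'
#' @param genome_length Total genome length (bp).
#' @param gene_fraction Fraction covered by gene bodies.
#' @param n_genes Number of gene intervals.
#' @return An [interval_set()].
#' @export
gen_genome_model <- function(genome_length = 1e6, gene_fraction = 0.4,
                             n_genes = 20L) {
  gene_len <- floor(genome_length * gene_fraction / n_genes)
  gap <- floor((genome_length - n_genes * gene_len) / n_genes)
  starts <- (seq_len(n_genes) - 1L) * (gene_len + gap) + gap %/% 2L + 1L
  interval_set(data.frame(chrom = "chr1", start = starts,
                          end = starts + gene_len - 1L),
               total_genome_length = genome_length)
}

#' Generate a mutation set from a known signature mixture
#'
#' Samples 96-channel classes from the mixture `sigs %*% exposures`, places
#' mutations uniformly over the genome model (gene-body positions
#' down-weighted by `gene_depletion_factor`), and reports the ground-truth
#' exposures and depletion factor. Contexts are emitted on the pyrimidine
#' strand or its reverse complement with equal probability.
#'
#' @param seed Integer seed (named stream "mutations").
#' @param n Number of mutations.
#' @param exposures Mixture proportions (sum to 1), one per signature.
#' @param sigs 96 x k signature matrix (columns sum to 1).
#' @param genome_model An [interval_set()] gene-body model.
#' @param gene_depletion_factor Relative rate of mutations inside gene
#'   bodies (1 = uniform; 0.5 = planted log2 depletion score of -1).
#' @return List with `mutations` (data.frame chrom/pos/ref/alt/context) and
#'   `truth` (exposures, depletion factor).
#' @export
gen_mutation_set <- function(seed, n, exposures, sigs,
                             genome_model = gen_genome_model(),
                             gene_depletion_factor = 1) {
  if (abs(sum(exposures) - 1) > 1e-9) {
    stop("exposures must sum to 1", call. = FALSE)
  }
  set.seed(derive_seed(seed, "mutations"))
  classes <- profile96_classes()
  if (n == 0L) {
    return(list(mutations = data.frame(chrom = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0),
                                       context = character(0)),
                truth = list(exposures = exposures,
                             gene_depletion_factor = gene_depletion_factor)))
  }
  mix <- as.numeric(as.matrix(sigs) %*% exposures)
  drawn <- sample(classes, n, replace = TRUE, prob = mix)
  ref <- substring(drawn, 3L, 3L)
  alt <- substring(drawn, 5L, 5L)
  context <- paste0(substring(drawn, 1L, 1L), ref, substring(drawn, 7L, 7L))
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- vapply(context[flip], reverse_complement, character(1))
  # place each mutation in a gene body with probability
  # gene_depletion_factor * gene_fraction (so observed/expected equals the
  # depletion factor in expectation), uniformly within the chosen stratum
  L <- genome_model$total_genome_length
  iv <- genome_model$intervals
  widths <- iv$end - iv$start + 1
  gene_len <- sum(widths)
  frac <- gene_len / L
  p_in <- gene_depletion_factor * frac
  stopifnot(p_in <= 1)
  in_gene <- stats::runif(n) < p_in
  pos <- integer(n)
  if (any(in_gene)) {
    k <- sample.int(nrow(iv), sum(in_gene), replace = TRUE,
                    prob = widths)
    pos[in_gene] <- iv$start[k] +
      floor(stats::runif(sum(in_gene)) * widths[k])
  }
  if (any(!in_gene)) {
    # complement intervals of the single-chromosome model
    gaps_start <- c(1, iv$end + 1)
    gaps_end <- c(iv$start - 1, L)
    ok <- gaps_end >= gaps_start
    gaps_start <- gaps_start[ok]; gaps_end <- gaps_end[ok]
    gw <- gaps_end - gaps_start + 1
    k <- sample.int(length(gw), sum(!in_gene), replace = TRUE, prob = gw)
    pos[!in_gene] <- gaps_start[k] + floor(stats::runif(sum(!in_gene)) * gw[k])
  }
  list(mutations = data.frame(chrom = "chr1", pos = pos, ref = ref,
                              alt = alt, context = context,
                              stringsAsFactors = FALSE),
       truth = list(exposures = exposures,
                    gene_depletion_factor = gene_depletion_factor))
}

#' Generate synthetic signature matrices
#'
#' Peaked, non-collinear synthetic 96-channel signatures (each column sums
#' to 1), labeled SYN1..SYNk. These are synthetic stand-ins with the same
#' shape contract as COSMIC SBS matrices, not reproductions of them.
#'
#' @param seed Integer seed (named stream "signatures").
#' @param k Number of signatures.
#' @return A 96 x k matrix with rownames [profile96_classes()].
#' @export
gen_signatures <- function(seed, k = 2L) {
  set.seed(derive_seed(seed, "signatures"))
  m <- matrix(stats::rgamma(96L * k, shape = 0.3), nrow = 96L)
  # make each signature peak on its own disjoint block of channels
  block <- split(seq_len(96L), rep(seq_len(k), length.out = 96L))
  for (j in seq_len(k)) m[block[[j]], j] <- m[block[[j]], j] + 2
  m <- sweep(m, 2L, colSums(m), "/")
  rownames(m) <- profile96_classes()
  colnames(m) <- paste0("SYN", seq_len(k))
  m
}

#' Generate clone mutation-load samples for two editing strategies
#'
#' Log-normal draws around the group means with coefficient of variation
#' `cv`. With a small `cv` and well-separated means the groups are
#' completely separated with high probability, pinning the exact one-sided
#' Mann-Whitney p at `1 / choose(n_multiplex + n_sequential, n_multiplex)`.
#'
#' @param seed Integer seed (named stream "loads").
#' @param n_multiplex,n_sequential Group sizes (both >= 1).
#' @param mean_m,mean_s Group means (mutation counts).
#' @param cv Coefficient of variation of the log-normal draws.
#' @return List with `multiplexed`, `sequential` (numeric vectors) and
#'   `truth` (the draws and parameters).
#' @export
gen_clone_loads <- function(seed, n_multiplex = 3L, n_sequential = 4L,
                            mean_m = 1114, mean_s = 3716, cv = 0.05) {
  if (n_multiplex < 1L || n_sequential < 1L) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  if (mean_m <= 0 || mean_s <= 0) stop("means must be > 0", call. = FALSE)
  set.seed(derive_seed(seed, "loads"))
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(n, mean) {
    round(stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog))
  }
  m <- draw(n_multiplex, mean_m)
  s <- draw(n_sequential, mean_s)
  list(multiplexed = m, sequential = s,
       truth = list(multiplexed = m, sequential = s, mean_m = mean_m,
                    mean_s = mean_s, cv = cv))
}
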