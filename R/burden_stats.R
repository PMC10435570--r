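# Whole-genome safety statistics for base-editor burden auditing: exact
# Mann-Whitney comparison of clone mutation loads, 96-channel spectrum
# construction and signature refitting, gene-body depletion tests, rainfall
# inter-mutation distances with kataegis calling, and a mismatch-tolerant
# off-target site search with flank intersection. Exact (enumeration-based)
# tests are used at desk scale so small-n results are reproducible to the
# printed digit.

# --- Mann-Whitney -----------------------------------------------------------

# U statistic (#pairs a > b + half-ties), alternative: a stochastically
# larger than b
mw_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Compare clone mutation loads between two editing strategies
#'
#' One-sided Mann-Whitney U test of whether the `sequential` group carries
#' a larger mutation load than the `multiplexed` group. For group sizes up
#' to 8 the p-value is exact, computed by full enumeration of all
#' assignments of the pooled observations to groups (this handles ties
#' exactly); above that a tie-corrected normal approximation with
#' continuity correction is used. With completely separated groups of sizes
#' n1 and n2 the exact p equals 1 / choose(n1+n2, n1) (e.g. 1/35 = 0.02857
#' for 3 vs 4).
#'
#' @param multiplexed,sequential Non-empty numeric vectors of per-clone
#'   mutation counts.
#' @return List with `mean_multiplexed`, `mean_sequential`, `fold`
#'   (sequential over multiplexed mean ratio), `U`, `p_one_sided`, `method`.
#' @export
compare_loads <- function(multiplexed, sequential) {
  if (length(multiplexed) == 0L || length(sequential) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_m <- length(multiplexed); n_s <- length(sequential)
  u_obs <- mw_u(sequential, multiplexed)
  if (max(n_m, n_s) <= 8L) {
    pooled <- c(sequential, multiplexed)
    idx <- utils::combn(n_s + n_m, n_s)
    u_perm <- apply(idx, 2L, function(sel) {
      mw_u(pooled[sel], pooled[-sel])
    })
    p <- mean(u_perm >= u_obs - 1e-9)
    method <- "exact permutation"
  } else {
    pooled <- c(sequential, multiplexed)
    n <- n_s + n_m
    mu <- n_s * n_m / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_s * n_m / 12 * ((n + 1) - tie_term)
    z <- (u_obs - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "tie-corrected normal approximation"
  }
  list(mean_multiplexed = mean(multiplexed),
       mean_sequential = mean(sequential),
       fold = mean(sequential) / mean(multiplexed),
       U = u_obs, p_one_sided = p, method = method)
}

# --- 96-channel spectrum ----------------------------------------------------

#' Canonical 96 single-base-substitution classes
#'
#' Six pyrimidine substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) by
#' sixteen flanking contexts, lexicographic, in the standard
#' `X[R>A]Y` notation.
#'
#' @return Character vector of length 96.
#' @export
profile96_classes <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (b5 in bases) for (b3 in bases) {
      out <- c(out, sprintf("%s[%s]%s", b5, s, b3))
    }
  }
  out
}

# normalize a (ref, alt, context) triple to the pyrimidine strand
normalize_substitution <- function(ref, alt, context) {
  stopifnot(nchar(context) == 3L)
  if (substring(context, 2L, 2L) != ref) {
    stop("context middle base does not match ref", call. = FALSE)
  }
  if (ref %in% c("G", "A")) {
    list(ref = chartr("ACGT", "TGCA", ref),
         alt = chartr("ACGT", "TGCA", alt),
         context = reverse_complement(context))
  } else {
    list(ref = ref, alt = alt, context = context)
  }
}

#' Build a 96-channel mutational profile
#'
#' Purine-reference mutations are mapped to the reverse-complement
#' pyrimidine class; the counts sum to the number of contributing SNVs.
#' Records with malformed contexts are collected into an `errors` attribute
#' rather than silently dropped without trace.
#'
#' @param mutations data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `context` (3-mer centered on the mutated base).
#' @return Named integer vector of length 96 (class `profile96`), in
#'   [profile96_classes()] order, with attribute `errors`.
#' @export
build_profile96 <- function(mutations) {
  classes <- profile96_classes()
  counts <- stats::setNames(rep(0L, 96L), classes)
  errors <- list()
  for (i in seq_len(nrow(mutations))) {
    ok <- tryCatch({
      nz <- normalize_substitution(mutations$ref[i], mutations$alt[i],
                                   mutations$context[i])
      key <- sprintf("%s[%s>%s]%s", substring(nz$context, 1L, 1L), nz$ref,
                     nz$alt, substring(nz$context, 3L, 3L))
      counts[key] <- counts[key] + 1L
      TRUE
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- list(row = i,
                                             message = conditionMessage(e))
      FALSE
    })
  }
  structure(counts, errors = errors, class = c("profile96", class(counts)))
}

#' Refit known mutational signatures to a profile
#'
#' Non-negative least squares: exposures >= 0 minimizing the squared
#' reconstruction error between the observed 96-channel profile and the
#' signature mixture. On a noiseless full-rank mixture the recovery is
#' exact. Reported with the cosine similarity between the profile and its
#' reconstruction; a zero profile yields zero exposures with the cosine
#' flagged as undefined (`NA`).
#'
#' @param profile Numeric vector of length 96 (a [build_profile96()]
#'   result).
#' @param sigs 96 x k non-negative matrix of signatures; each column sums
#'   to 1 (checked to 1e-9 tolerance). Column names label the signatures
#'   (e.g. SBS1, SBS2, SBS5, SBS13, SBS18).
#' @return List with `exposures` (named, mutation counts attributed),
#'   `proportions`, `cosine`, `residual_norm`.
#' @export
refit_signatures <- function(profile, sigs) {
  sigs <- as.matrix(sigs)
  if (nrow(sigs) != 96L || ncol(sigs) < 1L) {
    stop("signature matrix must be 96 x k with k >= 1", call. = FALSE)
  }
  if (any(sigs < 0)) stop("signatures must be non-negative", call. = FALSE)
  csum <- colSums(sigs)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("each signature column must sum to 1", call. = FALSE)
  }
  p <- as.numeric(profile)
  if (length(p) != 96L) stop("profile must have length 96", call. = FALSE)
  labels <- colnames(sigs)
  if (is.null(labels)) labels <- paste0("S", seq_len(ncol(sigs)))
  if (sum(p) == 0) {
    return(list(exposures = stats::setNames(rep(0, ncol(sigs)), labels),
                proportions = stats::setNames(rep(0, ncol(sigs)), labels),
                cosine = NA_real_, residual_norm = 0))
  }
  fit <- pracma::lsqnonneg(sigs, p)
  expo <- stats::setNames(fit$x, labels)
  recon <- as.numeric(sigs %*% fit$x)
  cosine <- sum(p * recon) / (sqrt(sum(p^2)) * sqrt(sum(recon^2)))
  list(exposures = expo,
       proportions = expo / sum(expo),
       cosine = cosine,
       residual_norm = sqrt(sum((p - recon)^2)))
}

#' Classify a mutation as APOBEC-like (SBS2-like)
#'
#' Deterministic per-mutation proxy for APOBEC attribution: true iff the
#' pyrimidine-normalized substitution is C>T or C>G with a 5' T (TpC
#' context). Vectorized over rows.
#'
#' @param ref,alt,context Vectors of reference base, alternate base and
#'   centered 3-mer context.
#' @return Logical vector.
#' @export
classify_apobec_like <- function(ref, alt, context) {
  vapply(seq_along(ref), function(i) {
    nz <- normalize_substitution(ref[i], alt[i], context[i])
    nz$ref == "C" && nz$alt %in% c("T", "G") &&
      substring(nz$context, 1L, 1L) == "T"
  }, logical(1))
}

# --- interval model and depletion ------------------------------------------

#' Construct an interval set (gene-body model)
#'
#' Intervals are 1-based closed and normalized: sorted and merged where
#' overlapping or adjacent, per chromosome.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based closed).
#' @param total_genome_length Total length of the genome model.
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(intervals, total_genome_length) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end < intervals$start)) {
    stop("interval end before start", call. = FALSE)
  }
  norm <- do.call(rbind, lapply(split(intervals, intervals$chrom),
                                function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
    data.frame(chrom = df$chrom[1], start = IRanges::start(ir),
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  rownames(norm) <- NULL
  structure(list(intervals = norm,
                 total_genome_length = as.numeric(total_genome_length)),
            class = "interval_set")
}

#' Total length covered by an interval set
#' @param is_ An [interval_set()].
#' @export
interval_length <- function(is_) {
  sum(is_$intervals$end - is_$intervals$start + 1)
}

# logical: is each (chrom,pos) inside the interval set?
positions_in_intervals <- function(chrom, pos, is_) {
  out <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- is_$intervals[is_$intervals$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ir <- IRanges::IRanges(sub$start, sub$end)
    q <- IRanges::IRanges(pos[sel], pos[sel])
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' Gene-body depletion of mutations
#'
#' Compares the observed number of mutations inside gene bodies with the
#' expectation proportional to their total length, summarized as a log2
#' observed/expected score and an exact two-sided binomial p-value
#' (minimum-likelihood method, as in [stats::binom.test()]).
#'
#' @param mutations data.frame with `chrom` and `pos` columns (non-empty).
#' @param genes An [interval_set()] of gene bodies.
#' @param pseudocount Added to observed and expected before the log2 ratio
#'   to guard against log(0); 0 by default (score is `-Inf` when no
#'   mutation falls in a gene body).
#' @return List with `observed`, `expected`, `log2_score`, `p_binomial`,
#'   `n_mutations`, `gene_fraction`.
#' @export
gene_body_depletion <- function(mutations, genes, pseudocount = 0) {
  n <- nrow(mutations)
  if (is.null(n) || n == 0L) stop("empty mutation set", call. = FALSE)
  if (genes$total_genome_length <= 0) {
    stop("total_genome_length must be positive", call. = FALSE)
  }
  frac <- interval_length(genes) / genes$total_genome_length
  obs <- sum(positions_in_intervals(mutations$chrom, mutations$pos, genes))
  stopifnot(obs <= n)
  expd <- n * frac
  log2_score <- log2((obs + pseudocount) / (expd + pseudocount))
  p <- stats::binom.test(obs, n, frac)$p.value
  list(observed = obs, expected = expd, log2_score = log2_score,
       p_binomial = p, n_mutations = n, gene_fraction = frac)
}

#' Compare gene-body depletion between two mutation classes
#'
#' Two-sided Fisher exact test on the 2x2 table of in/out-of-gene counts
#' for two mutation classes (e.g. SBS2-like vs all other mutations). A
#' table with a zero margin is reported as p = 1 with a flag.
#'
#' @param class_a,class_b Lists/vectors with elements `in` and `out`
#'   (non-negative counts).
#' @return List with `p`, `odds_ratio`, `table`, `degenerate`.
#' @export
compare_depletion <- function(class_a, class_b) {
  tab <- matrix(c(class_a[["in"]], class_a[["out"]],
                  class_b[["in"]], class_b[["out"]]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("class_a", "class_b"),
                                c("in_gene", "out_gene")))
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, odds_ratio = NA_real_, table = tab,
                degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab,
       degenerate = FALSE)
}

# --- rainfall / kataegis ----------------------------------------------------

#' Rainfall distances and kataegis calls
#'
#' Per chromosome, sorts mutations by position and computes the distance of
#' each mutation to the previous one. A kataegis call is a maximal run of
#' at least `min_mutations` mutations in which every consecutive distance
#' is at most `max_distance` bp.
#'
#' @param mutations data.frame with `chrom` and `pos`.
#' @param min_mutations Minimum run length (mutations) for a call.
#' @param max_distance Maximum inter-mutation distance inside a run (bp).
#' @return List with `distances` (data.frame chrom/pos/dist_to_prev; NA for
#'   the first mutation on a chromosome) and `kataegis` (data.frame
#'   chrom/start/end/n_mutations; zero rows when none).
#' @export
rainfall <- function(mutations, min_mutations = 6L, max_distance = 1000L) {
  dist_rows <- list()
  calls <- list()
  for (ch in unique(mutations$chrom)) {
    pos <- sort(mutations$pos[mutations$chrom == ch])
    d <- c(NA_real_, diff(pos))
    dist_rows[[length(dist_rows) + 1L]] <-
      data.frame(chrom = ch, pos = pos, dist_to_prev = d,
                 stringsAsFactors = FALSE)
    if (length(pos) < 2L) next
    close_ <- diff(pos) <= max_distance
    r <- rle(close_)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      n_mut <- r$lengths[j] + 1L  # k distances span k+1 mutations
      if (n_mut >= min_mutations) {
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch, start = pos[idx_start[j]], end = pos[idx_end[j] + 1L],
          n_mutations = n_mut, stringsAsFactors = FALSE)
      }
    }
  }
  list(distances = do.call(rbind, dist_rows),
       kataegis = if (length(calls) > 0L) do.call(rbind, calls) else
         data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), n_mutations = integer(0)))
}

# --- off-target search ------------------------------------------------------

#' Mismatch-tolerant off-target site search
#'
#' Scans both strands of every chromosome for spacer-length windows with at
#' most `max_mismatches` mismatches to the spacer AND an adjacent PAM
#' match. Each site carries a flank interval of `flank` bp on each side
#' (closed, clipped to sequence bounds), the region of interest used for
#' variant intersection.
#'
#' @param spacer Spacer sequence, 5'->3'.
#' @param genome Named character vector of chromosome sequences.
#' @param max_mismatches Maximum mismatches in the spacer match (PAM must
#'   match exactly by IUPAC class).
#' @param pam IUPAC PAM pattern.
#' @param flank Flank size in bp on each side of the protospacer region.
#' @return data.frame with columns `chrom`, `strand` (+/-), `start`, `end`
#'   (plus-strand protospacer span), `matched` (plus-strand sequence of the
#'   span), `mismatches`, `flank_start`, `flank_end`.
#' @export
find_offtarget_sites <- function(spacer, genome, max_mismatches = 4L,
                                 pam = "NGG", flank = 200L) {
  spacer <- nuc_seq(spacer)
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0", call. = FALSE)
  sl <- nchar(spacer); pl <- nchar(pam)
  rows <- list()
  pat <- Biostrings::DNAString(spacer)
  for (ch in names(genome)) {
    chrom_seq <- nuc_seq(genome[[ch]])
    L <- nchar(chrom_seq)
    for (strand in c("+", "-")) {
      subj_chr <- if (strand == "+") chrom_seq else
        reverse_complement(chrom_seq)
      subj <- Biostrings::DNAString(subj_chr)
      hits <- Biostrings::matchPattern(pat, subj,
                                       max.mismatch = max_mismatches)
      for (k in seq_along(hits)) {
        s <- Biostrings::start(hits)[k]
        if (s + sl + pl - 1L > L) next
        pam_seq <- substring(subj_chr, s + sl, s + sl + pl - 1L)
        if (!match_pam(pam_seq, pam)) next
        window <- substring(subj_chr, s, s + sl - 1L)
        mm <- sum(strsplit(window, "")[[1]] != strsplit(spacer, "")[[1]])
        if (mm > max_mismatches) next
        if (strand == "+") {
          start <- s; end <- s + sl - 1L
        } else {
          end <- L - s + 1L; start <- L - (s + sl - 1L) + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, strand = strand, start = start, end = end,
          matched = substring(chrom_seq, start, end), mismatches = mm,
          flank_start = max(1L, start - as.integer(flank)),
          flank_end = min(L, end + as.integer(flank)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      matched = character(0), mismatches = integer(0),
                      flank_start = integer(0), flank_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

#' Intersect mutations with off-target regions of interest
#'
#' A mutation overlaps a site if its position falls inside the protospacer
#' span (`in_spacer`) or within the flank interval (`in_flank`); positions
#' beyond the flank are not reported.
#'
#' @param mutations data.frame with `chrom` and `pos`.
#' @param sites data.frame from [find_offtarget_sites()].
#' @return data.frame of overlapping (mutation, site) pairs with columns of
#'   the mutation, the site index, and `region`
#'   (`"in_spacer"`/`"in_flank"`).
#' @export
intersect_offtargets <- function(mutations, sites) {
  rows <- list()
  for (i in seq_len(nrow(mutations))) {
    ch <- mutations$chrom[i]; p <- mutations$pos[i]
    hit <- which(sites$chrom == ch & p >= sites$flank_start &
                   p <= sites$flank_end)
    for (j in hit) {
      region <- if (p >= sites$start[j] && p <= sites$end[j]) "in_spacer"
      else "in_flank"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = p, site = j, region = region,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      site = integer(0), region = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
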