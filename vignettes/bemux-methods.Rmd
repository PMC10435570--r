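---
title: "bemux: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bemux: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bemux)
```

# The editing model

`bemux` models a base editor as five parameters: the Cas9 homolog (Sp or
Sa, which determines the sgRNA backbone and hence multiplex
compatibility), the deaminase chemistry (CBE: C→T; ABE: A→G), an IUPAC PAM
pattern, the spacer length, and a closed editing-window interval counted
1-based from the protospacer's 5' (PAM-distal) end.

Two conventions drive everything else:

1. **Edited-strand convention.** The deaminase substrate is the
   protospacer strand — the strand identical to the spacer — because the
   R-loop displaces that strand single-stranded. A sense-strand C>T
   therefore requires a sense protospacer with a downstream PAM, while a
   sense G>A is installed by a CBE on an *antisense* protospacer. The
   four designable substitution chemistries are thus C>T sense,
   C>T antisense (= sense G>A), A>G sense and A>G antisense (= sense T>C);
   all other substitutions (transversions) are not reachable by either
   chemistry and `find_guides()` returns no candidates for them.
2. **Coordinates.** CDS coordinates are 1-based; codon *i* covers
   positions `frame_offset + (3i-2 .. 3i)`, matching the `c.` notation
   used for coding changes. Partial CDS fragments are supported through
   `frame_offset` so short planted contexts can be analyzed in frame.
   Sequences containing ambiguity codes are rejected at parse time —
   editing-window logic is undefined on an ambiguous base (IUPAC letters
   are legal only inside PAM patterns).

A guide candidate for an edit must satisfy three conditions: all required
substitutions lie on one strand and share one chemistry; all required
positions fall in the editing window; and the PAM matches immediately 3'
of the protospacer. Protein-level requests (`p.S45P`, `p.Q1406*`) are
expanded into every within-codon substitution set reaching any codon of
the target residue, each annotated with its chemistry; a multi-substitution
option must fit inside a single guide's window (this is exactly how a
single NGT-PAM guide can install either the one-edit G12S or the two-edit
G12N variant of a GGT glycine codon).

## Registry defaults

| editor | PAM | spacer | window |
|---|---|---|---|
| SpCas9 | NGG | 20 nt | [4, 8] |
| SpCas9-NG | NG | 20 nt | [4, 8] |
| SpCas9-NGT | NGT | 20 nt | [4, 8] |
| SpRY | NAN | 20 nt | [4, 8] |
| SaCas9 | NNGRRT | 21 nt | [4, 8] |
| SaKKH | NNNRRT | 21 nt | [4, 8] |

each in CBE and ABE chemistry. Choices worth explaining:

- **Core window [4, 8]** (5 positions, inclusive). Descriptions of the
  window as "roughly four nucleotides" between positions 4 and 8 are
  ambiguous; we use the inclusive closed interval. An **extended window
  [3, 9]** is available behind `allow_extended = TRUE`; designs using it
  always carry the `OUTSIDE_CORE_WINDOW` flag.
- **Spacer lengths** 20 nt (Sp family) and 21 nt (Sa family) follow
  common usage; both are ordinary `editor_spec` fields, not constants.
- **SpCas9-NGT** is a convenience entry for the NGT sub-pattern of
  SpCas9-NG used in KRAS codon-12 designs; `NG` and `NGT` PAMs have
  different lengths, and PAM length is a field.
- **SpRY** is registered with the narrow `NAN` motif; published SpRY
  characterizations are broader (essentially NRN > NYN), and users who
  want that behavior can register their own pattern.

## Efficiency flags

Candidates are annotated, never filtered: `LOW_POSITION` when a target
sits at protospacer position 3, 4 or 8 (empirically weaker editing);
`BAD_CONTEXT` when a target cytosine lies inside an `ACG` trinucleotide on
the protospacer strand; `OUTSIDE_CORE_WINDOW` for extended-window
placement. The flags mirror the practical failure mode in which two
guides against the same arginine hotspot both edit poorly because their
substrate C sits at position 3 or 8 inside `ACG` — the remedy being a
near-PAMless editor (SpRY) rather than a better flagging scheme.

# Outcome enumeration

Every subset of the chemistry-substrate bases in the applied window is a
possible allele: `enumerate_outcomes()` returns all 2^k of them (k ≤ 12,
guarded), maps edits back to the sense strand, and classifies each changed
codon as silent, missense or nonsense (nonsense requires the *new* codon
to be a stop and the old one not — a stop-to-stop change is not counted).
The **headline outcome** is the full-substrate subset, reflecting the
observation that edited clones typically carry the complete window
converted (silent co-edits at wobble positions are the common case).

Rare non-canonical CBE resolutions (C>A, C>G at one substrate of the
headline allele) can be appended with `include_rare_cbe = TRUE`. They are
always labeled `rare`, never counted in targetability, and applied
uniformly across substrates since no per-offset preference is established.
Indel risk with Sa-family CBEs is a known liability but is not enumerated
as alleles.

`stop_convertible_codons()` recomputes, by brute force over all 64 codons
and all C>T edit subsets on both strands, the codon set convertible into a
stop: CAA, CAG, CGA (sense) and TGG (antisense) — i.e. Gln, Arg and Trp.
The test suite asserts this closure against an independent hard-coded
codon table.

# Multiplex interference

When a CBE and an ABE built on the *same* Cas9 homolog are co-delivered,
every sgRNA is loaded by both: the audit re-types each entry's guide under
the opposite chemistry and enumerates what the unintended editor can do in
that window. Severity is `none` (no opposite-chemistry substrate in the
window), `silent_only`, or `coding`. Only same-backbone cross-loading is
modeled; genomic cross-targeting of one guide at another locus is the
off-target scanner's job.

`assign_homologs()` is a deterministic greedy assignment (edits are
canonically sorted first, so the result is invariant under input
permutation): each edit takes the candidate minimizing coding-severity
findings against the panel so far, tie-broken by fewer efficiency flags,
then editor name, then spacer. Splitting chemistries across homologs
(Sa-CBE + Sp-ABE) emerges from the cost function rather than being
hard-coded. The default selection table maps APC → Wnt-activator
withdrawal, TP53 → Nutlin-3, PIK3CA → MEK inhibition, CTNNB1 →
CHIR/R-spondin withdrawal; genes without a functional handle (e.g. SMAD4)
fall back to antibiotic/transfection selection.

# Catalog targetability

`scan_catalog()` filters to pathogenic rows, tests each variant with every
registry editor under the **strict core window** (extended placements are
not counted as targetable; they can be tallied separately), and aggregates
per role: variant fraction and gene fraction (a gene counts if any of its
pathogenic variants is targetable). Bystander substrates never disqualify
a guide. Variants are genomic-agnostic — context comes from the supplied
CDS + flanks, not a genome build — which keeps the scan desk-scale. Which
catalog release or pathogenicity tier defines "pathogenic" is left to the
user's column mapping.

# Burden statistics

- **Load comparison.** One-sided Mann–Whitney U (alternative: sequential
  loads exceed multiplexed). For group sizes ≤ 8 the p-value is exact by
  full enumeration of all `choose(n1+n2, n1)` group assignments, which
  handles ties exactly (two identical singletons give p = 1); larger
  groups use the tie-corrected normal approximation with continuity
  correction. Base R's `wilcox.test` cannot compute an exact p in the
  presence of ties, so the enumeration is implemented here and
  `wilcox.test` serves as an independent cross-check on tie-free cases in
  the tests. Complete separation at 3 vs 4 gives p = 1/35 ≈ 0.02857.
- **Spectra and refitting.** 96-channel profiles use the canonical
  pyrimidine-strand classes; refitting is non-negative least squares
  (`pracma::lsqnonneg`), exact on noiseless full-rank mixtures, reported
  with the reconstruction cosine similarity.
- **APOBEC-like proxy.** A mutation is "SBS2-like" iff its normalized
  substitution is C>T or C>G in a TpC context. This is a deterministic
  per-mutation stand-in for probabilistic signature attribution — a
  documented divergence, chosen because per-mutation attribution rules
  are otherwise underdetermined.
- **Gene-body depletion.** Expected in-gene count is length-proportional;
  the score is log2(observed/expected) (optional pseudocount guards the
  degenerate zero), tested with the exact two-sided binomial
  (minimum-likelihood method, i.e. `binom.test`). Class comparisons use
  the two-sided Fisher exact test; a zero-margin table returns p = 1 with
  a `degenerate` flag.
- **Rainfall / kataegis.** Distances to the previous mutation per
  chromosome; a call is a maximal run of ≥ 6 mutations with every
  consecutive distance ≤ 1000 bp. Both thresholds are configurable; the
  defaults follow common convention since no canonical values exist.
- **Off-target search.** Both strands of each chromosome are scanned for
  spacer-length windows with ≤ 4 mismatches plus an adjacent PAM match
  (`Biostrings::matchPattern` under the hood, verified against a naive
  sliding-window oracle in the tests). No bulges/gaps are modeled. Each
  site carries a ±200 bp closed flank; `intersect_offtargets()`
  classifies overlapping mutations as `in_spacer` or `in_flank`. A
  mutation exactly 200 bp away is inside the flank; 201 bp is out.
- **Intervals** are 1-based closed internally; BED-like input files are
  0-based half-open and converted at the reader boundary.

# Synthetic data: what it emulates, and what it does not

The generators replace restricted study data (patient WGS, proprietary
catalog releases) with seeded constructions whose ground truth is known
and **self-verified against the production operations before returning**:

- `gen_transcript()` plants editable codons with concrete PAMs at chosen
  window offsets inside G-depleted filler (to keep incidental NGG-family
  sites rare); each plant must be recovered by `find_guides()` or
  generation fails. Incidental sites are permitted and are covered by the
  brute-force oracles in the tests. Plants whose PAM would overwrite
  another plant raise a generation error.
- `gen_catalog()` builds a catalog with a planted targetable fraction:
  targetable variants are PAM-adjacent sense C>T plants at window
  position 5; untargetable ones are transversions, which no transition
  chemistry can install regardless of PAM placement — making the planted
  truth robust rather than probabilistic. The count is
  `round(frac * n_variants)`.
- `gen_mutation_set()` samples 96-channel classes from a known signature
  mixture and places mutations so that the in-gene probability is
  `depletion_factor x gene_fraction`, making the expected log2
  depletion score equal `log2(depletion_factor)` exactly.
- `gen_clone_loads()` draws log-normal loads (default means 1114 and
  3716, CV 0.05, sizes 3 and 4) — at this CV the groups are essentially
  always completely separated, pinning the exact Mann–Whitney p at 1/35.
- `gen_signatures()` produces peaked, non-collinear synthetic signatures
  labeled `SYN*`. They share only the shape contract (96 rows, columns
  sum to 1) with real SBS matrices and are not reproductions of them.

Each generator draws from its own named random stream derived from the
single seed, so adding a generator never shifts existing outputs.

What passing tests on these data do **not** show: recovery performance on
real human genomes (no replication timing, expression or chromatin
covariates of mutation rate; single-chromosome interval model), real
editing efficiencies (the flags are annotations, not a trained activity
model), or the published catalog fractions (which depend on a specific
external catalog release and are deliberately not reproduced).

# Problem sizes and numerical choices

The test suite and the acceptance script use deliberately desk-scale
problems: 50-instance oracle-equivalence sweeps on ~60–80 nt transcripts,
10,000 sampled mutations for signature recovery (5% relative-error
criterion, dominated by multinomial sampling noise), 50,000 for the
depletion score (±0.1 on log2), exhaustive 2^5 window-pattern sweeps for
the interference audit, and exact tests throughout (permutation,
binomial, hypergeometric) so small-sample p-values are reproducible to
the printed digit rather than approximation-dependent. NNLS needs no
tolerance tuning at these sizes; ties in the Mann–Whitney statistic use
the mid-rank (0.5 per tied pair) convention.

# Known limitations

- No learned on-target activity scoring, chromatin accessibility, or
  NMD-escape/splice-disruption prediction.
- Indels are a risk annotation, not enumerated alleles.
- Off-target search is mismatch-only (no bulges) and single-PAM per run.
- The SpRY PAM default is intentionally narrow (see registry notes).
- The interference model assumes complete cross-loading within a homolog
  and none across homologs; partial backbone promiscuity is not modeled.
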