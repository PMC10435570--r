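# bemux — base-editor multiplex guide design and safety auditing

`bemux` is an R package for designing and auditing one-step multiplexed
base-editing experiments of the kind used to build complex tumor models in
organoids. It is aimed at genome engineers who need to answer, *before*
touching cells:

- Which base editor / sgRNA combinations can install a desired point
  mutation (given as `c.96C>T` or `p.S45P`)?
- What bystander alleles can each guide produce, and are the co-edits
  silent or coding?
- Where can a tumor suppressor be inactivated by CRISPR-stop?
- When several editors are co-delivered, will sgRNAs designed for a CBE be
  hijacked by an ABE on the same Cas9 backbone (and vice versa)?
- What fraction of a pathogenic variant catalog is targetable at all?
- Do whole-genome mutation calls from edited clones show excess burden,
  APOBEC-signature activity, gene-body effects, kataegis, or mutations
  near predicted off-target sites?

## The model in brief

A base editor is a nickase-Cas9 fused to a deaminase: a **CBE** converts
C→T via a uracil intermediate, an **ABE** converts A→G via inosine. The
deaminase acts on the single-stranded protospacer strand displaced in the
R-loop, and only within an editing window at positions **4–8** from the
protospacer's 5' (PAM-distal) end. Placement is constrained by the PAM of
the Cas9 variant: SpCas9 `NGG`, SpCas9-NG `NG` (or the `NGT` form used on
*KRAS* G12), SpRY `NAN`, SaCas9 `NNGRRT`, SaKKH `NNNRRT`.

A sense-strand C>T therefore needs a sense protospacer with a downstream
PAM; a sense G>A needs an antisense protospacer. Every substrate base in
the window is a potential bystander: `bemux` enumerates all 2^k edit
subsets and classifies each changed codon as silent / missense / nonsense.
Brute force over the codon table shows exactly four codons are C>T
convertible into stops — CAA, CAG, CGA (sense) and TGG (antisense) — the
Gln/Arg/Trp residues exploited by CRISPR-stop.

For safety auditing, clone mutation loads are compared with an **exact
one-sided Mann–Whitney test** (full permutation enumeration for groups of
up to 8, so 3-vs-4 fully separated groups give p = 1/35 ≈ 0.02857);
96-channel mutational spectra are refit against signature matrices by
non-negative least squares; gene-body depletion uses exact binomial and
Fisher tests; rainfall plots feed a kataegis caller (≥6 mutations, each
≤1 kb apart); and a mismatch-tolerant scan (≤4 mismatches + `NGG` PAM,
±200 bp flanks) finds candidate off-target regions to intersect with
variant calls.

## Worked example

Scan a synthetic tumor-suppressor transcript (with a planted CAA codon)
for CRISPR-stop sites, inspect a guide and its outcomes:

```r
library(bemux)
gt <- gen_transcript(seed = 1, n_codons = 50,
                     plants = list(plant_spec("CAA", 10, "SpCas9-CBE")),
                     gene_id = "TP53like", role = "tsg")
sites <- crispr_stop_scan(gt$transcript)
for (s in sites) print(s)
#> <stop_site> codon 10 (CAA, Q): 1 strategy, 6 guide(s)
#> <stop_site> codon 30 (CAA, Q): 1 strategy, 1 guide(s)

print(sites[[1]]$guides[[1]])
#> <guide> TP53like SaCas9-CBE sense@52 spacer ACTAGACAATTCTAATTTATT PAM CGGAAT targets [7] flags []

for (o in enumerate_outcomes(sites[[1]]$guides[[1]], gt$transcript)) print(o)
#> <outcome> offsets []: no coding change
#> <outcome> offsets [7] (headline): CAA10TAA[nonsense]
```

The scan found the planted Gln codon (plus an incidental one at codon 30);
the shown guide places the target C at window position 7 with no
efficiency liabilities, and its only non-identity outcome converts CAA→TAA
(Q10\*), a nonsense edit with no bystanders.

Comparing mutation loads of 3 multiplexed vs 4 sequentially edited clones:

```r
compare_loads(c(1000, 1150, 1192), c(3600, 3700, 3750, 3814))
#> $mean_multiplexed  1114
#> $mean_sequential   3716
#> $fold              3.34
#> $p_one_sided       0.02857  (exact permutation)
```

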