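---
title: "Discovering convergent IgE clonal families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering convergent IgE clonal families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonverge)
```

## The problem

Allergen-specific IgE is rare in blood, but single-cell sorting of B cells
from allergic donors yields paired heavy/light antibody sequences together
with each cell's transcriptome. Two questions drive the analysis this
package implements. First, do unrelated individuals converge on the same
antibody solution — *public* clonal families whose members, drawn from
different subjects, share a heavy-chain rearrangement and a near-identical
CDR3? Second, where on the allergen do those convergent antibodies bind —
in the peanut-allergy setting, a tandem `DPYSPS` repeat on the flexible
loop unique to the 2S-albumin Ara h 2?

`clonverge` provides the full desk-side pipeline: input/output for the
standard exchange formats, quality control, clonal family construction
with convergence annotation, sequence metrics, cell-state classification,
and linear epitope mapping — plus a simulator that generates repertoires
with known ground truth so every stage can be verified without access to
patient data.

## Quality control

A cell enters the analysis only if it has **at least 500 expressed genes**
and **a single productive heavy/light pair** in which both chains satisfy:

* V segment length strictly greater than **250 nt**;
* no stop codon in the variable-region translation up to the junction end
  (constant-region trailers appended by some assemblers are deliberately
  ignored — they are often template-switch artifacts);
* no ambiguous nucleotides (`N`);
* an in-frame CDR3 whose translation matches the reported amino-acid
  CDR3 (this, together with the stop-free translation, operationalizes
  "correct reading frame");
* a constant-region call resolving to exactly one isotype after splitting
  multi-calls on commas;
* a productive rearrangement flag.

Cells with two or more passing chains of the same class are rejected as
multiplets. Every rejection carries the complete set of reason codes, and
`pair_cells()` returns a per-cell report whose tallies are exact — on
simulated data they equal the planted defect counts cell for cell. Both
thresholds are configuration values (`qc_config()`), defaulting to the
500-gene and 250-nt criteria above.

## Clonal families and convergence

Cells are grouped by heavy-chain **V gene, J gene and CDR3 length**
(allele suffixes after `*` are stripped; multi-gene calls take the first
listed gene, since allele-level calls are assembler-noisy). Within a
group, cells join the same clonal family when their CDR3 identity is
**70% or higher**. Identity is position-wise (Hamming; equal lengths are
guaranteed by the grouping), computed on the amino-acid CDR3 by default —
the residue-level logos are the natural readout, and amino-acid identity
is the conservative choice; nucleotide mode is available via `on = "nt"`.

The default linkage is **single** (connected components of the
at-threshold graph), the standard clonotyping realization of "assigned on
the basis of ≥70% identity"; complete linkage is available for
sensitivity analysis. A boundary note: a pair at exactly 70% identity
merges, a pair at 69% does not, and the implementation guards the
comparison with a 1e-9 tolerance so rational identities such as 7/10 are
never lost to floating-point representation.

Family ids are deterministic and order-independent: cells are sorted by
subject then cell id before clustering, and families are numbered by
decreasing size with lexicographic tie-breaks. A family is **convergent**
iff its members come from at least two subjects. `annotate_convergence()`
also emits a per-family persistence table (subject × contributing blood
draws) supporting longitudinal claims about clonal persistence.

Light chains play no role in family assignment — clustering is on the
heavy chain only — but light-chain information is retained on every
paired cell for diagnostics and VL metrics.

## Sequence metrics

* **Edit distances** are unit-cost Levenshtein distances over amino-acid
  sequences, by default the full variable region (clustermap-style
  summaries of within- and between-family heterogeneity can reach tens of
  residues even within one family); `region = "cdr3"` restricts to the
  CDR3. Clustermap ordering uses average-linkage hierarchical clustering
  with label-sorted deterministic tie-breaking.
* **Somatic hypermutation** is the nucleotide mismatch fraction between
  the observed V segment and its position-aligned germline, the field's
  IMGT-style percent mutation; positions with `N` in either string are
  excluded from both numerator and denominator, and a missing germline
  yields a missing estimate, never zero.
* **Logo position-frequency matrices** align CDR3s of unequal length with
  a `center_gap` policy: the first ⌈L/2⌉ residues anchor left, the last
  ⌊L/2⌋ anchor right, and gaps are inserted centrally. Junctions are most
  conserved at their ends and most diverse in the middle, so central gaps
  distort least. This policy is a documented package choice for cross-
  family comparisons; with equal-length input it is a no-op and all
  policies agree. Columns, gap symbol included, always sum to one.

## Cell state

The plasmablast/memory partition is anchored on two markers: the
plasmablast transcription factor **PRDM1** and the naive/memory marker
**MS4A1** (CD20). The default `marker_rule` calls a cell a plasmablast
iff `log2(cpm(PRDM1)+1) > log2(cpm(MS4A1)+1)` (pseudocount 1 throughout;
cells with both markers zero are `unassigned`). The rule is
scale-invariant by construction. The confirmatory `pca_kmeans` route runs
PCA (gene-mean centred, unscaled — the common practice for log-normalized
counts) on the 500 highest-variance genes and k-means with k = 2 on the
first two components under a fixed, caller-supplied seed; the cluster
with higher mean PRDM1 is labelled plasmablast. The marker rule is the
default because the published partition is explicitly anchored on these
two genes; the PCA route is reported with per-cell margins so
discrepancies between the methods are visible rather than hidden.

## Epitope mapping

`tile_protein()` emulates a linear peptide array: k-mers (default 15)
offset by 1 along the protein, so a length-L protein yields L−14 tiles.
`scan_motif()` finds exact motif occurrences, overlapping ones included —
the target here is an exact hexapeptide repeat, so degenerate/PSSM motifs
are out of scope. `map_array_signal()` projects per-tile signals onto
residues by **maximum** over covering tiles (a single strongly bound
peptide suffices to localize an epitope; the threshold for calling
epitope intervals defaults to half the profile maximum and treats signals
as arbitrary non-negative units). `align_global()` is a Needleman–Wunsch
global aligner with the fully stated scoring (+1 match, −1 mismatch, −2
linear gap) and a deterministic tie-break (diagonal, then gap in the
second sequence, then gap in the first); it reports intervals of the
first sequence aligned entirely to gaps in the second — exactly the
signature of a loop present in one homolog and absent from the other.
A simple linear gap penalty is used rather than an affine one: unique-
loop detection is robust to the scheme, and a fully specified scheme is
reproducible. No implicit signal-peptide trimming is performed; isoform
numbering follows the input FASTA as given.

## The simulator

`simulate_repertoire()` generates everything the pipeline consumes, with
complete ground truth. Its defaults are the study conditions the package
is verified under:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` × `cells_per_subject` | 8 × 150 | cohort shape |
| `n_public_families` | 3 | convergent families planted across 2–5 subjects |
| `n_private_families` | 40 | single-subject families |
| `shm_rate_per_site` | 0.02 | per-nt V-region mutation over 300 nt toy V segments |
| `cdr3_intra_family_mutation_rate` | 0.05 | per-codon CDR3 substitution (capped at 0.1 to keep expected intra-family identity ≥ 0.8) |
| `defect_rates` | 5/5/5/5/3/2 % | stop codon, ambiguous nt, short V, low gene count, multiplet, ambiguous constant region |
| `isotype_mix` | IgE 0.85, IgG 0.10, IgM 0.05 | IgE-enriched discovery setting |
| `plasmablast_fraction` | 0.6 | plasmablast-biased state mix |
| `marker_fold_change` | 8 | PRDM1/MS4A1 asymmetry between states |
| `nb_dispersion` | 4 | negative-binomial size for counts |

Design notes, in the package's own words:

* **Toy germline segments are bundled synthetic constants** (10 V of
  300 nt and 4 J per locus, generated once from a fixed internal seed),
  not real human genes: the pipeline must be testable with zero
  downloads, and nothing in the method depends on true germline content.
* **CDR3 mutations are substitution-only**, so family members share
  their clone key by construction — matching the grouping assumption the
  clustering imposes. Every planted substitution changes the base and is
  re-drawn if it would create a stop codon, so the realized V-region
  mismatch count is exactly binomial at the configured rate; that is
  what makes the SHM calibration checks sharp.
* **At most one labelled defect is planted per cell** (one multinomial
  draw at the configured rates). This keeps the audit exact: each
  rejected cell traces to one planted cause, and QC tallies can be
  compared to planted counts cell by cell.
* **Expression counts** are negative-binomial with lognormal per-gene
  baselines. Besides the two markers, a 100-gene state-dependent program
  (4-fold, half up in plasmablasts, half up in memory) separates the
  states — real plasmablasts differ from memory cells across a broad
  transcriptional program, and without one a PCA on 500 genes could not
  plausibly recover the partition. Marker means are 120 vs 120/8 at the
  default fold change; with dispersion 4 the marker rule's per-cell
  error rate is below 1%, which is what a clean published partition
  looks like.
* One RNG stream per run, fully determined by `seed`; runs are
  byte-identical under a repeated seed, and the caller's RNG state is
  never disturbed.

What the simulator does **not** emulate: human germline allele usage,
SHM hotspot (WRC) targeting, selection pressure, indels in CDR3 (indel
escape appears only as labelled defect classes), doublets beyond the
two-chain rule, or ambient-RNA contamination. Passing tests on simulated
data therefore demonstrate the correctness of the algorithms under the
stated generative model, not robustness to every artifact of real
droplet or plate data.

## Problem sizes and verification

The verification suite exercises the default 1,200-cell cohort for
family recovery and the QC audit, a 200-cell cohort for SHM calibration
(3-binomial-SE band around the planted 2%), and a 300-cell cohort for
state recovery; brute-force oracles (recursive edit distance, naive
motif scanning, transitive-closure components, an independent global
aligner) back the core primitives on hundreds of randomized cases.
These sizes give stable statistics at interactive runtimes and are the
sizes reported by `scripts/acceptance.R`.

## Known limitations

* Clonal families are flat partitions; no lineage trees or germline
  inference (partis/IgPhyML territory).
* Convergence is a subject-count statement; the package does not model
  the probability of convergence under a null repertoire.
* The V-length criterion uses the upstream-reported V segment length;
  assemblers that report full-contig lengths instead should be mapped at
  the I/O layer (the `minimal` dialect requires the column explicitly).
* `pca_kmeans` is a two-cluster model by design; repertoires with more
  than two expression states need a dedicated tool (Seurat, scran).
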