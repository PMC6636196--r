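---
title: "Mining and classifying MHC class I genes: models and methods"
author: "mhciscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and classifying MHC class I genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mhciscan` characterizes the major histocompatibility complex (MHC) class I
gene repertoire of a genome assembly: it finds candidate loci by translated
homology search, curates them into gene models classified as putatively
functional genes (PFGs) or pseudogenes, localizes the canonical MHC class I
region through its six framework marker genes and assigns every locus to
the alpha, kappa or beta duplication block (or the extended class I
interval, or "outside"), calls lineage-specific in-frame insertions in the
alpha-1 peptide-binding domain, screens aligned loci for recombination, and
summarizes relationships as a bootstrap-supported NeighborNet split
network. A synthetic-genome simulator with a machine-readable truth set
makes every stage testable end to end.

# The synthetic study conditions

The simulator is not a toy fixture but the package's definition of the
conditions under which the method is validated. `sim_config()` plants, by
default, 26 class I loci across three scaffolds: scaffold 1 carries the
seven framework markers in their conserved order (HIST1H2AA, MOG, RNF39,
TRIM26, ABCF1, TCF19, MICB/BAT1) with genes inside the extended class I,
alpha, kappa and beta intervals; the other scaffolds carry outside-region
genes, including one mosaic recombinant. Loci are generated from a common
ancestral six-exon coding sequence (default exon lengths 72, 270, 276, 276,
117 and 150 nt, the last exon including the terminal stop codon; introns
fixed at 200 nt) under per-site Jukes-Cantor substitution at half the
configured pairwise paralog divergence (default 0.10/site pairwise).
Functional loci keep a valid open reading frame by construction
(substitutions that would create a stop, or destroy the start or terminal
stop, are reverted); pseudogenes receive exactly one lesion (premature
stop, 1-nt frameshift, lost start, or lost stop, cycled); partial genes
keep their first three to five exons and are flanked by an N-run, as
happens at assembly gaps. All loci of the focal lineage carry the shared
3- or 5-codon alpha-1 insertion allele at a fixed anchor, mirroring a
lineage in which the insertion is fixed.

Residues of simulated proteins are drawn uniformly over the twenty amino
acids and then assigned a synonymous codon uniformly. Drawing codons
uniformly instead would enrich both the planted proteins and the
translation of random intergenic DNA for leucine, serine and arginine, so
that BLOSUM62 scores of unrelated sequence would drift around zero rather
than being clearly negative; the per-amino-acid scheme keeps the score
statistics of unrelated sequence comparable to real proteins. The
simulator does not model splice signals, repeats, sequencing error beyond
N-runs, or realistic intron length variation; passing the recovery tests
therefore demonstrates the correctness of the decision logic and the
coordinate bookkeeping, not robustness to every artifact of real
assemblies.

# Translated search

The search is a self-contained seed-and-extend engine. Each scaffold is
translated in six frames; exact 4-mer amino-acid seeds are extended along
the diagonal without gaps under an x-drop rule (default 20 matrix units),
and each surviving segment is re-scored by a banded affine-gap local
alignment (BLOSUM62, gap open 11, extend 1) in a window padded by 25
residues — deliberately less than an intron's width in frame units so that
segments do not bridge introns. E-values follow Karlin-Altschul statistics
with published ungapped BLOSUM62 constants (lambda 0.3176, K 0.134).

Two details matter for gene-model quality. First, reported segment
coordinates are those of the ungapped core trimmed to its outermost run of
three consecutive exact residue matches: random (e.g. intronic)
translation essentially never contains such a run, so score random-walk
overshoot past exon boundaries is removed, while the gapped window score
is still reported for statistics. Second, individual exon segments are
retained at a looser E-value (1e-3) and the strict cutoff (1e-10) is
applied to the merged locus — the analog of BLAST's sum statistics for
linked segments, without which short leader exons of diverged loci would
be lost and their gene models would spuriously fail the start-codon rule.

Loci are formed by merging same-scaffold, same-strand segments within
1 kb (introns are far smaller, intergenic spacing far larger), and loci
spanning fewer than 400 nt are discarded; the length rule is strict, a
span of exactly 400 survives.

# Gene models and the PFG/pseudogene rules

For each locus a candidate coding sequence is spliced from the exon
clusters of its segments. Cluster boundaries are polished in three ways,
all reference-guided: terminal clusters are extended along the anchor
segment's diagonal to reference position 1 and to the reference end plus a
stop codon when the shortfall is at most 12 codons; internal junctions
reclaim stub codons that continue the reference in frame with at least 60%
identity (a premature stop inside an otherwise matching stub is reclaimed
too, so it can be counted); and junctions with three or more reference
residues still unexplained are tested for a hidden frameshift by asking
whether the missing residues reappear in a 1-2 nt shifted frame adjacent
to an in-frame anchor (three missing residues must all match, longer runs
need at least four matches, and the shifted reading must beat the best
in-frame reading by 0.2). These rules recover lesions that fall so close
to an exon boundary that the shifted or interrupted remainder is too short
to seed its own alignment segment — the blind spot of every
homology-extraction pipeline.

The spliced sequence is realigned to the best-matching reference protein
by a frameshift-aware codon dynamic program (free end gaps; frameshift
penalty 30; whole-codon indel penalty 12) that reports explicit 1-2 nt
frameshift events and internal stop codons with positions. Domains
(leader, alpha-1, alpha-2, alpha-3, intercellular, cytoplasmic) are called
present when at least 80% of their reference columns are aligned.

Classification follows fixed rules. An intact model (all six domains) is a
PFG iff it starts with ATG, ends with a stop codon, and has no frameshifts
and no premature stops; indels in multiples of three nucleotides never
pseudogenize. A partial model is a PFG iff its present exons are clean and
an N-run of at least 10 bases lies within 500 bp of the locus — the
assembly-gap excuse; otherwise it is a pseudogene. Identity confirmation
against the reference panel is computed on nucleotides (free-end-gap
alignment; matches over aligned columns, at least 60% of the locus
covered) with a strict > 0.90 rule. Nucleotide rather than protein
identity is used because genuine class I paralogs at the default study
divergence sit near 0.95 nucleotide but only ~0.89 protein identity; a
protein threshold of 0.90 would reject true loci wholesale, while the
nucleotide scale preserves the intent of confirming hits against known
class I sequences.

# Region mapping

Markers are located with the same search engine (best locus per marker per
scaffold; a marker on several scaffolds is flagged ambiguous and blocks
depending on it refuse to form). Blocks are the open intervals between
their bounding markers — alpha: MOG-RNF39, kappa: TRIM26-ABCF1, beta:
TCF19-MICB/BAT1, extended class I: HIST1H2AA-MOG — defined only when both
markers share a scaffold, and orientation-invariant. MICB/BAT1 is one
composite marker satisfied by either protein. Genes are assigned to the
unique block containing their midpoint; genes on marker-free scaffolds or
between blocks are "outside". The midpoint rule is a convention for edge
cases (a gene straddling a block edge); the extended-interval anchor pair
is likewise a convention, as no cross-species definition exists. Within a
defined block, gaps between consecutive anchored features larger than
1 Mbp are reported as splits.

# Alpha-1 insertion calling

The alpha-1 peptide of each model is the translation of the locus
nucleotides spanning the codons aligned to the reference alpha-1 columns,
inserted codons included. Focal peptides are aligned with the reference
set in one multiple alignment (MAFFT, inputs sorted by name for order
invariance); columns where every reference has a gap, in maximal runs away
from the first and last five columns, are insertion candidates; a block is
lineage-specific when at least 90% of focal sequences have residues in it,
and one call per locus reports that locus's own residue count — so 3- and
5-residue alleles sharing an anchor are reported per locus. The 90%
requirement tolerates one poor gene model without losing the
lineage-specificity claim.

# Recombination screen

Screening runs on the exon 2-5 region projected into reference
coordinates (the codon alignment already provides column homology).
Sequences below 50% mean pairwise identity are removed first. Two
statistics are computed per candidate against its parent pair (parents
preselected as the candidate's nearest neighbours; all pairs among the top
three are tested and the best MaxChi p-value is Bonferroni-adjusted):
MaxChi slides a 40-variable-site window and tests the two halves with a
2x2 chi-square, assessing the maximum by permuting variable-site order
(seeded; at least 100 permutations); the window distance scan looks for a
single switch of the nearer parent across window runs of at least three,
with at least 80% of informative windows consistent. A sequence is a
consensus recombinant only when both statistics flag it — the
all-methods-agree analog of multi-method consensus screening — and
consensus recombinants are excluded from network building. Triplet
statistics cannot tell a mosaic from its parents: the parents of a strong
recombinant are often reciprocally flagged and will then also be excluded;
this is conservative for network building and is left as documented
behavior. Recombination and gene conversion are not distinguished, which
is appropriate for segments well under 1 kb.

# Split network

Distances are Jukes-Cantor with pairwise deletion; a pair at or beyond
p = 0.75 is either an error or, for bootstrap replicates, capped just
below saturation and flagged. The circular ordering follows the
agglomerative NeighborNet scheme: cluster pairs chosen by a
neighbor-joining-type criterion, junction nodes by the corresponding
node-level criterion, chains reduced three-nodes-to-two with 2/3-1/3
distance updates, and reductions expanded in reverse; ties break
lexicographically so the ordering is deterministic and label-invariant.
Weights for all splits compatible with the ordering are fit by
non-negative least squares (Lawson-Hanson); on an additive tree metric the
fit is exact, recovering the tree's splits and branch lengths and giving
non-tree splits zero weight, which is the package's primary correctness
check for the whole chain. Splits below 1e-8 are pruned. Bootstrap support
resamples alignment columns (the standard reading, since resampling
distances has no column-level justification); support is the percentage of
replicate networks containing the same bipartition, with supports above 70
flagged strong. The default run uses 100 replicates to keep the
desk-scale scenario fast; the conventional 1,000 replicates are a
parameter away (`bootstrap_B`).

# Problem sizes and reproducibility

The default validation scenario uses 26 loci in a ~240 kb three-scaffold
assembly, 200 clonal replicates for type-I calibration, 25 mosaics for
power, five 8-taxon trees for network exactness and 100-200 bootstrap
replicates — sizes chosen so the full validation runs in minutes on one
CPU while leaving each statistical check adequately powered. A single
global seed fans out to per-stage seeds by hashing the stage name
(`derive_seed()`), so toggling one stage never perturbs another's stream,
and identical configurations give identical outputs.

# Known limitations

Lesions in the one or two codons immediately at an exon boundary can
still evade both segment recovery and junction rescue, so a planted
pseudogene is occasionally read as functional; the recovery criterion is
therefore set at 95%, not 100%, of loci. The search engine has no
composition-based score adjustment or low-complexity masking. The
similarity confirmation depends on the reference panel supplied; with a
sparse panel the >0.90 rule is conservative. The recombination consensus
inherits the parent/recombinant ambiguity discussed above. None of the
stages model splice-site sequence, so exon boundaries are accurate only to
within a few codons — sufficient for classification and repertoire
accounting, not for annotation-grade gene structures.
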