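---
title: "Methods: group-differential polymorphism discovery and seed-specific candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-differential polymorphism discovery and seed-specific candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Seed size/weight in chickpea is a polygenic agronomic trait. One route to
candidate genes is to resequence cultivars at the two ends of the phenotype —
here two small-seeded (Himchana 1, Pusa 362) and two large-seeded (JGK 3,
PG 0515) cultivars — and ask which DNA polymorphisms *consistently separate
the two groups*, which genes they hit, and which of those genes are
specifically expressed during seed development and differentially expressed
between a small- and a large-seeded cultivar at the stages that matter
(late embryogenesis S3, mid-maturation S5). `seedvar` implements that
discovery-to-candidates funnel as a tested package, together with a
synthetic-data generator that plants a known truth at every stage so the
whole pipeline can be validated by set equality rather than by eyeballing.

## Variant model and site filters

Variants are consumed as one record per cultivar per site (VCF v4.2 with
`DP` and `AF` INFO fields) and classified from the minimal allele
representation (shared suffix, then prefix, stripped):

* **SNP** — single-base substitution;
* **MNP** — two or more consecutive substituted bases, no length change;
* **InDel** — pure length change (one allele a prefix/suffix extension of
  the other);
* **complex** — substitution mixed with length change in one record.

A call is confident when read depth is at least 10 and the alternate-allele
fraction is at least 0.9. Genotypes are treated as homozygous single-allele
calls: chickpea is highly selfing and the 0.9 fraction cutoff effectively
removes heterozygous sites, so one allele per cultivar per site is the
natural model. Multi-allelic records are rejected rather than decomposed —
the group logic below needs an unambiguous allele per cultivar, and MNPs and
complex variants are kept atomic throughout.

**Density filter.** A polymorphism is discarded if it lies in any 10-bp
window containing three or more polymorphisms. The implementation removes a
variant iff it belongs to a run of three start positions spanning at most
9 bp, which is equivalent to the sliding-window definition; the test suite
checks this against an exhaustive scan of every window alignment. The filter
is applied to the merged per-chromosome call set (all classes jointly)
*before* the group comparison; whether the original analysis merged per
cultivar or globally is not decidable from the description, and merging is
the stricter, order-independent choice.

**Group-differential variants.** A site differentiates the groups iff (i)
all four cultivars have a confident call — a passing variant call, or a
reference call backed by a per-site coverage track of depth ≥ 10 (a cultivar
with no call and no adequate coverage is a no-call, and a cultivar whose
only record *failed* the filters is a no-call, never silently reference);
(ii) both small cultivars agree; (iii) both large cultivars agree; (iv) the
group alleles differ. Sites where the two groups carry two different
non-reference alleles still differentiate the groups and are emitted. The
one-to-one (`pairwise_differential()`) sets use the same machinery; the
group set is provably contained in each small-versus-large pairwise set and
the tests assert it.

## Annotation

**Regions.** Each variant's reference span is labelled exon, intron,
promoter or intergenic with precedence exon > intron > promoter >
intergenic, the promoter being the 2 kb immediately upstream of the
transcription start, strand-aware. The TSS (not the CDS start) anchors the
promoter because "upstream" is a transcript-level notion. A variant inside
one gene and upstream of another gets the genic label; residual ties are
broken by nearest TSS, then gene id, so the partition is total and
deterministic.

**Consequences.** For genic variants the reference CDS is built in
transcript orientation, the substituted allele is spliced in, and the two
CDS strings are compared. The substituted allele is the one that differs
from the reference — the large-group allele when both differ; substituting a
group allele equal to the reference would vacuously report "synonymous".
The severity ladder is:

1. `splice_site` — the span intersects the first/last 2 bp of an intron
   (2 bp because the canonical GT/AG dinucleotides define the junction; the
   width is a parameter);
2. `start_loss` — any change to the initiator ATG;
3. `frameshift` — net CDS length change not divisible by 3;
4. `stop_gain` — a new in-frame stop before the native stop;
5. `non_synonymous`, `synonymous` — by comparing the translated proteins up
   to the first stop.

The frameshift test precedes the stop check deliberately: a frameshifted
tail almost always contains some downstream stop, but "premature stop" is
only meaningful in-frame, so a 1–2 bp indel is a frameshift even when the
shifted sequence happens to terminate early. In-frame InDels that do not
introduce a stop are classed non-synonymous — the three-way CDS
classification has no separate in-frame class. Exonic positions outside the
CDS (UTRs) are `non_coding`. MNP and complex consequences are computed by
whole-CDS re-substitution, never by per-base decomposition.

The unit tests validate the ladder against an independent oracle that edits
the *genome*, shifts all downstream coordinates, re-extracts and
re-translates the CDS — a different computational route that must agree on
1,000+ random variants over random gene models on both strands, and under
reverse-complementation of the entire genome.

**Summaries.** Transitions are A↔G and C↔T; everything else is a
transversion. InDel length is the absolute allele-length difference, an
insertion when the substituted allele is longer. Window densities tile each
chromosome from position 0 in 100-kb windows, keep the last partial tile
with a length-normalized frequency, and must conserve chromosome totals.
Highly polymorphic genes are those whose per-kb exonic (or intronic)
polymorphism density lies strictly above the third quartile of the
distribution over genes with at least one such polymorphism; Q3 uses linear
interpolation between order statistics (`quantile(type = 7)`), the common
boxplot default, and is tested against a hand-rolled quantile.

## Seed-specificity and the DE gate

The tissue-specificity index over a profile $x$ of $N$ tissues is

$$\tau = \frac{\sum_{i=1}^{N} (1 - \hat{x}_i)}{N - 1},
\qquad \hat{x}_i = \frac{x_i}{\max_j x_j},$$

computed after a `log2(x + 1)` transform by default. τ is 0 for a uniform
profile and 1 for single-tissue expression; concentrating mass onto the peak
never decreases it. The source index formula is cited rather than restated
in the original description, so the transform is a switchable parameter and
both behaviours are tested (with the transform disabled τ is exactly
scale-invariant). The 29 columns — seven seed stages S1–S7 from each of two
cultivars plus 15 vegetative/floral tissues — enter separately; averaging
the two cultivars' seed columns first would be an alternative reading, but
using all columns is the more conservative choice and matches how the panel
is described.

A gene is **seed-specific** when its expression peak (argmax over the 29
columns) is a seed stage and τ strictly exceeds 0.6 (τ = 0.600 fails,
0.601 passes). Patterns are otherwise `not_expressed` (all tissues below
1 FPKM), `non_seed` (expressed somewhere, below the floor in every seed
stage) or `ubiquitous`.

The **DE gate** passes when |log2 fold change| ≥ 1 (fold change of at least
two) and q ≤ 0.05, with direction from the sign; the S3/S5 criterion is an
inclusive *or* over the two stages with direction "higher in large".
q-values are inputs — the upstream DE caller's model is not re-derived. When
only replicate FPKMs are available, `de_from_replicates()` provides a
clearly-labelled stand-in (means with pseudocount 1, per-gene t statistics,
Benjamini–Hochberg) used only in synthetic tests.

## Candidates and QTLs

A **candidate gene** is seed-specific, harbors a promoter polymorphism
and/or a non-synonymous or large-effect change among the group-differential
variants, and passes the S3/S5 DE gate. The three marginal lists are
reported separately since one gene can carry several evidence types.
"Located within a QTL" means full containment of the gene span in the
interval (0-based half-open); that is the literal reading of "within", and
an any-overlap mode is available behind a flag because interval tools
default to overlap. Functional categories come from a user-supplied
gene-to-category table — the package does not infer them.
`genotype_concordance()` compares base calls over a complete site × cultivar
grid between two platforms and reports the exact match fraction (e.g.
179 matches over 48 SNPs × 4 cultivars = 192 cells gives 93.2%).

## The synthetic generator

`simulate_dataset()` emulates the study inputs at desk scale. Defaults: two
2-Mb chromosomes, 200 multi-exon genes, ~5,000 planted group-differentiating
variants (3,800 SNP / 250 MNP / 600 InDel / 350 complex), 300 confounders,
4% low-depth exclusions, 20 three-SNP density clusters, 40 seed-specific
genes, 8 QTLs. These sizes keep the full pipeline under a few minutes on one
CPU while leaving every downstream statistic non-trivial; they do not mimic
the real genome's eight chromosomes or its variant density.

Construction guarantees, rather than post-hoc checks, make the planted
labels true by geometry:

* genes are placed with ≥ 2 kb clear upstream, so promoter labels are
  unambiguous; CDSs start ATG, end with a single stop, and introns are
  GT..AG with planted splice variants confined to the terminal 2 bp;
* effect-labelled variants are built from the codon table (e.g. a stop-gain
  picks a codon one substitution away from TAA/TAG/TGA in transcript
  orientation; minus-strand alleles are reverse-complemented);
* planted variants are kept ≥ 13 bp apart except the deliberate density
  clusters (three SNPs spanning ≤ 9 bp), so the density filter removes
  exactly the clusters;
* confounders include variants shared by all four cultivars, within-group
  polymorphic sites, and calls that fail the alternate-fraction filter;
* seed-specific profiles peak at 40–300 FPKM in one seed column against a
  ≤ 1.2 FPKM background, which puts τ near 0.85; every planted profile is
  verified to classify as intended at generation time and redrawn if noise
  breaks it;
* SNP substitutions draw transitions with probability 0.63, echoing the
  transition excess universally observed in resequencing data; insertion
  lengths span 1–20 nt and deletions 1–10 nt with ~70% single-base events.

Determinism: the config seed fixes every stage (each stage derives its own
sub-seed), and the emitted FASTA/GFF3/VCF/BED/TSV files are byte-identical
across runs — the test suite compares checksums.

What the generator does **not** emulate: linkage disequilibrium and
demography, read-level sequencing error (no FASTQ/BAM), mapping artefacts,
heterozygosity, alternative splicing (one transcript per gene), genuine
Cuffdiff statistics (q-values are planted), and GO/KOG annotation. Passing
the planted-truth suites therefore demonstrates that the pipeline's logic is
exact under its stated model, not that the thresholds are optimal for real
resequencing data.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; GFF3/VCF conversion
happens once at the I/O boundary and a cross-convention test pins VCF
POS=100 to BED `[99,100)`. Ties in the τ argmax go to the first tissue in
panel order. `tau_index()` refuses all-zero profiles (the pattern classifier
handles them as `not_expressed` first). The quartile rule needs at least
four genes, concordance at least one comparison, and the density filter
sorted input — each failure is a typed error, not a silent answer. Problem
sizes in the tests: the shared unit fixture uses one 300-kb chromosome with
25 genes and ~200 planted variants; the end-to-end suite runs the full
default scale (2 × 2 Mb, 200 genes, ~5,000 variants) once and shares it
across assertions.

## Known limitations

Region assignment uses a single canonical transcript per gene; overlapping
genes are resolved by precedence and nearest-TSS rather than reported
multiply. The consequence caller assumes variants are contained in single
gene features (a variant spanning an exon–intron junction beyond the splice
window falls back to a length-rule classification). Reference-allele
confidence requires a coverage track; without one, sites missing a call in
any cultivar are conservatively dropped.
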