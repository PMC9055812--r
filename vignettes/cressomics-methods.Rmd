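---
title: "Methods and design of cressomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of cressomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cressomics)
```

cressomics implements the downstream analytics that turn raw genomic
resources for field pennycress — small-RNA alignments, bisulphite calls,
expression counts, assembly contigs, resequencing genotypes — into the
summaries a genome paper reports: consensus sRNA loci, curated MIRNA
hairpins, methylation landscapes, a tissue-specificity atlas, assembly QC
and population-genetic descriptors. This vignette explains each procedure,
its assumptions, the parameters that matter, and the design choices made
where the underlying methods literature leaves the details open.

## Synthetic data as the testbed

Real inputs for these pipelines are tens of gigabytes of alignments. The
package therefore ships seeded generators (`sim_config()` and the `gen_*`
family) that emulate every input type at desk scale with recorded planted
truth, so each downstream stage can be validated by recovery rather than
by fixture files.

The default configuration defines the study conditions used throughout
the test suite and the acceptance script:

* a 4-Mbp genome (2 scaffolds of 2 Mbp) with gene density highest toward
  scaffold ends and TE density highest in the centre, mimicking the
  telomere/pericentromere geometry of a real chromosome at 1/30 scale;
* four tissues (rosette, root, inflorescence, pollen) with three
  replicate sRNA libraries each, 1 million mapped reads per library;
* 200 planted sRNA loci, 100–300 bp, roughly 90% in the heterochromatic
  23–24-nt class, with abundances log-uniform between 8 and 50 RPM —
  comfortably above the 2-RPM cluster floor, because the recovery tests
  measure pipeline fidelity for loci that should be found, not detection
  limits;
* 2000 scattered background singleton reads per library. The background
  level of genuine sRNA data is not well characterized, so this is a free
  parameter; singletons at this library size are 1 RPM, below the cluster
  threshold, which is what "sub-threshold noise" has to mean for the
  noise-only control to be meaningful.

All randomness flows from one integer seed through a fixed RNG stream per
generator, so adding draws to one generator never shifts another, and the
same configuration is byte-identical across runs. What the generators do
*not* emulate: sequence content (no FASTQ, no alignment ambiguity),
bisulphite conversion chemistry, mapping bias, or biological correlation
between data types. Passing recovery tests therefore demonstrate
correctness of the downstream logic, not robustness to upstream
artefacts.

## Consensus sRNA locus annotation

Each library is clustered de novo: reads whose gaps are ≤ 75 nt merge
into islands (`discover_clusters()`), and islands below 2 RPM are
discarded. The 75-nt pad matches the default of the standard sRNA
clustering tool; the 2-RPM floor is the conventional minimum expression
threshold. RPM uses total mapped 20–24-nt reads per library as the
denominator.

`consensus_loci()` then applies, per tissue, a per-base multi-intersection:
only intervals covered by clusters from at least 3 libraries survive
(with three replicates per tissue this demands support in every
replicate). Surviving loci 25 nt apart are padded together — interpreted
with merge-distance semantics, i.e. a gap of exactly 25 nt merges and 26
does not, matching the `-d` behaviour of the merge utility this step
emulates. Loci whose expression stays below 0.5 RPM in all of a tissue's
libraries are removed; a locus's per-library expression is the summed RPM
of that library's clusters overlapping it. Finally, per-tissue loci are
unioned across tissues, keeping the contributing tissue labels. The
implementation rides on run-length coverage vectors; the test suite holds
it against a literal per-base voting oracle on 50-kbp instances.

Whether "at least three libraries" should count within a tissue or across
all libraries is ambiguous in the original procedure; the package counts
within tissue (the intersection step runs per tissue) and exposes
`min_libraries` for the other reading.

`classify_locus()` calls a locus 23–24 nt (or 20–22 nt) when ≥ 80% of its
copy-weighted read mass falls in that length band, with an explicit
`mixed` class otherwise — the dominance cutoff is this package's choice,
as no published threshold exists. Complexity is distinct read positions
divided by total copies (1 = maximally diverse, 1/n = one read stack),
and 5′-nucleotide frequencies are copy-weighted.

### Phasing statistic

No standard closed-form test exists for phasiRNA detection, so
`phase_score()` defines one: among register-length reads, the score is
the largest fraction of 5′ ends sharing one register offset; the p-value
is the binomial tail of that best offset under a uniform null,
Bonferroni-corrected by the register (21 or 24). A locus is phased when
p < 0.05 and score ≥ 0.5. The Bonferroni correction makes the test
conservative — simulated type-I error is essentially zero at the default
read depths — while planted loci with 10% off-register noise are detected
with power above 99%. Loci with fewer than 10 register-length reads are
reported unphased with a reason code rather than raising an error,
because sparse loci are routine in genome-wide scans.

## MIRNA hairpin curation

`evaluate_candidate()` applies the standard plant MIRNA annotation rules:
hairpin ≤ 300 nt; mature 20–24 nt; ≥ 75% of copy-weighted reads in the
miRNA/miRNA* duplex; ≤ 5 mismatched bases, of which ≤ 3 nucleotides in
asymmetric bulges; no internal loops; 2-nt 3′ overhangs on both duplex
ends; and a single stem across the mature–star span. Definitions the rule
list leaves implicit are fixed as: a *mismatch* is a 1:1 unpaired
opposition, an *asymmetric bulge* counts unpaired nucleotides on exactly
one strand, and an *internal loop* is a ≥2:≥2 opposition — since
mismatches and bulges are explicitly tolerated, "no internal loops" can
only refer to the larger symmetric openings. The star arm is inferred
from the pairing table with the canonical 2-nt 3′ offset and never needs
to be sequenced; duplex read membership allows ±2 nt of end slack, common
curation practice. Secondary structure is an input (any folder, or the
generator); no folding engine is implemented. When a hairpin terminus
truncates one duplex end the overhang rule still applies to both ends by
default (`both_overhangs = FALSE` relaxes it).

When the proposed mature interval spans the terminal loop there is no
duplex; the candidate fails `single_stem` and the duplex-dependent
criteria are reported as `NA` measures that do not independently fail —
this keeps the generator's single-fault fixtures diagnostic: each
engineered defect trips exactly one criterion.

## Feature context

Density tracks count features into tiling windows by midpoint (a feature
straddling a boundary is counted once, no double counting). The
gene-density partition labels windows strictly above the mean as
enriched; the procedure's own description quotes both a mean and a
median, uses the mean, and so does the package — both are reported. Locus
→ annotation assignment uses a fixed precedence (exon, intron, TE,
intergenic) with ≥1-bp overlap; nearest-feature distances are 0 for
overlaps and gap lengths otherwise. TE containment requires a gene's
full span inside a single TE interval, with a MuLE-intersecting subset
flagged.

Ancestral-karyotype block painting (`assign_ancestral_blocks()`) was a
manual, synteny-tool-driven step in the original workflow; here it is an
exact dynamic programme: segments must carry ≥ `min_run` labelled genes
with a majority label at ≥ 80% of labelled genes, unlabelled genes never
break runs, and among admissible segmentations the one covering the most
labelled genes wins. The smoothing parameters are this module's own. The
DP is quadratic per scaffold, adequate for gene orders in the tens of
thousands.

## Methylation summaries

Cytosines below 3× coverage are removed first. Global levels are reported
two ways, because the published 70/47/33% CG/CHG/CHH figures do not state
their definition: the coverage-weighted level (Σ methylated / Σ total)
and the fraction of sites with per-site level ≥ 0.5; the package asserts
the CG > CHG > CHH ordering on both, never the absolute percentages.
Window tracks use 200-kbp tiles, with missing contexts reported as `NA`,
not zero. Symmetric CG/CHG sites are kept per strand (the input dialect
is per-strand); collapsing is left to upstream callers.

Metaprofiles cut 2-kb flanks into fixed 25-bp bins (80 per side) and
rescale feature bodies into 40 proportional bins; minus-strand features
are reversed so the axis is 5′→3′. Bodies shorter than the bin count
still contribute proportionally (a count of such features is attached as
an attribute). On generator output the TE-body profile exceeds the
gene-body profile in all three contexts, and gene bodies sit at the
unmethylated floor — by construction, since the generator plants a
species that lost gene-body methylation.

## Expression atlas

Counts are TMM-normalized. The factors come from edgeR's implementation
of the trimmed mean of M-values (30% log-ratio trim, 5% intensity trim,
reference sample by upper quartile); one numerical choice is layered on
top: factors are computed from *relative* library sizes at a canonical
one-million-read scale (rounded to integers), which makes the factors —
and hence the normalized matrix and every τ value — exactly invariant
under a global rescaling of library sizes. Without this, the precision
weights inside TMM depend weakly on absolute depth and a rescaled run
can flip the reference sample.

Tau is computed on per-tissue means of normalized counts after a
`log2(x + 1)` transform (the widely used τ implementation transforms;
`log_transform = FALSE` switches it off): τ = Σ(1 − x̂)/(n − 1), where x̂
scales each gene by its maximum tissue value. Genes with zero maximum
are reported missing. Low-coverage sample groups are excluded by
configuration, not by hard-coded tissue names. Classes are [0, 0.2) low,
[0.2, 0.8) intermediate, [0.8, 1.0] high — left-closed, top bin closed.
The quantile-normalization step of one published τ implementation is not
replicated; the transform chain here is documented and switchable, which
is the reproducible subset.

In the generator, "single-tissue" genes are expressed in exactly one
tissue (zero elsewhere) and "uniform" genes carry stable
housekeeping-level abundance (baseline ~200 counts); these definitions
make the planted classes sharp: recovered τ is exactly 1 for
single-tissue plants and stays below 0.1 for uniform plants at the
default dispersion of 0.05.

## Assembly QC

`kmer_genome_size()` splits the error spike from the coverage peak at the
first local minimum of the histogram (an explicit cutoff overrides this
when the valley is ambiguous), then applies genome size = total retained
k-mers / peak depth, floored. The single-copy fraction is the retained
mass within [peak/2, 3·peak/2] — a pragmatic window definition, since the
quantity is conventionally reported without a formula.

`depth_modes()` reports local maxima of a length-weighted kernel density
of contig depths. Two guards keep it honest on degenerate input: modes
closer than a tenth of the depth range to a taller mode are treated as
smoothing ripples, and a valley that is not clearly lower than the
smaller of the two top modes (below half its density) demotes the result
to unimodal with zero duplicated mass.

`purge_duplicates()` is the greedy duplicate purge: contigs sorted by
ascending depth (ties: longer first, then id) are removed until the
retained length enters the target budget, defined as the estimated
genome size plus 2% — the tolerance operationalizes "an approximation of
the estimated genome size". Contigs carrying a single-status BUSCO are
never removed; the walk skips them and takes the next unprotected contig.
If protected length alone exceeds the budget, the walk stops, keeps all
protected contigs, and flags the overflow. Depth is the per-contig mean;
a per-window variant would need windowed input the purge step does not
consume here.

## Population-genetic summaries

The variant summary applies the QD ≥ 2000 hard filter (only where a QD
value is present), tabulates SNP/insertion/deletion counts and one-decimal
percentages (half-even rounding), and breaks exonic records down by
effect label — effect classification itself is consumed, never computed.
A multiplicity column lets tallied tables stand in for full record lists.

r² is the squared Pearson correlation of genotype dosages (composite LD)
over pairwise-complete samples, for marker pairs within a 40-marker
sliding window. For the inbred, selfing accessions this resource targets,
dosage-based r² is nearly equivalent to haplotype r². The decay curve is
a LOESS fit (span 0.3, quadratic) evaluated on a fixed grid, with the
threshold crossing found by linear interpolation; a curve that never
reaches the threshold reports its minimum instead.

The genotype generator plants binary Markov haplotypes at allele
frequency 1/2 whose correlation decays as exp(−d/scale); two haplotypes
sum to a dosage, so E[r²] ≈ exp(−2d/s) + (1 − exp(−2d/s))/n with n
samples. `ld_recover_scale()` inverts exactly this model at the crossing
point, after restricting pairs to the decay region (≤ 15 kb by default)
so the flat far-distance baseline does not dominate the local fit — with
40 samples and 2000 markers the planted 2-kb scale is recovered within a
few percent.

## Problem sizes and limitations

The shipped test suite and the acceptance script run the full synthetic
study (4-Mbp genome, 12 sRNA libraries, 33 expression samples, 150k
methylation sites, 2000 markers × 40 samples, 10 000 phasing null
simulations) in well under a minute of CPU; these sizes were chosen so
that recovery statistics are stable across seeds while iteration stays
fast. Known limitations: the phasing test is deliberately conservative
(Bonferroni) and will under-call marginal loci; the consensus pipeline's
per-library expression of a locus is the sum of overlapping cluster RPMs,
which can overstate expression when a locus fuses several clusters; block
painting assumes block labels are mostly locally homogeneous and has no
notion of inversions; and none of the generators model upstream artefacts
(mapping bias, bisulphite non-conversion, index hopping), so recovery
results bound logic errors, not end-to-end accuracy on real data.
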