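---
title: "Methods: classifying CpG-disrupting SNPs and testing methylation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying CpG-disrupting SNPs and testing methylation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesnp)
```

## The problem

DNA methylation in vertebrate genomes is laid down almost exclusively at CpG
dinucleotides. A single-base substitution that removes a CpG deletes a
potential methylation target; one that forms a new CpG creates one. Such
variants — methylation-relevant SNPs, or meSNPs — are a plausible mechanistic
link between genotype and the methylation differences observed between
phenotype groups. `mesnp` provides the full desk half of that analysis:
classify variants by their effect on CpG sites, relate them to CpG islands
and to differentially methylated regions, and nominate candidates whose
allele frequencies track the methylation phenotype. Wet-lab steps (library
construction, alignment, peak calling, DMR statistics, consequence
prediction) are consumed as standard files, never recomputed.

## The classifier

A substitution at position $p$ can only affect CpG dinucleotides that contain
$p$, so the trinucleotide window $(l, c, r)$ centred on the variant is
sufficient: the left slot $(l, c)$ is a CpG only when $l = C, c = G$, and the
right slot $(c, r)$ only when $c = C, r = G$. Since no base is both C and G,
each allele can occupy at most one slot. Writing $R$ and $A$ for the slots
occupied by the reference and alternate allele:

* $R = \emptyset, A \neq \emptyset$ — **create** (the alternate is the
  methylation-site-creating, MSC, allele);
* $R \neq \emptyset, A = \emptyset$ — **destroy** (the reference is the MSC
  allele);
* both non-empty — **displace** (necessarily different slots, e.g. CGG →
  CCG);
* both empty — **none**.

Classification is on the forward strand only. Because CG is its own reverse
complement, classifying the reverse-complemented context with complemented
alleles gives the same class, so no information is lost; the test suite
asserts this on 10,000 random cases, alongside exact agreement with an
independent oracle that diffs the full-sequence CpG start sets of the
reference and mutated sequences.

An unknown flank (`N`) is never coerced: both resolutions of each `N` are
enumerated and the class is reported only when it does not depend on the
unknown base; otherwise the variant is `unclassifiable`. A flank that does
not exist (variant at position 1 or the chromosome end) is different — that
slot simply cannot hold a CpG, and the variant is classified from the
remaining slot.

## CpG islands

Islands are spans with length ≥ 200 bp (relaxed) or ≥ 500 bp (strict), G+C
content ≥ 50%, and observed/expected CpG ratio ≥ 0.60, where
$\mathrm{obs/exp} = n_{CpG} \cdot L / (n_C \cdot n_G)$ (the classical
Gardiner-Garden/Frommer form), defined as 0 when $n_C$ or $n_G$ is 0.
`detect_cgi()` slides a fixed 200-bp window one base at a time, unions
qualifying windows, filters merged runs by the minimum length and re-checks
every merged interval against all three criteria, dropping any that fail the
re-check. This is the simplest deterministic scheme whose output provably
satisfies the printed criteria; it does not attempt to reproduce any
particular annotation pipeline's islands bit-for-bit, and published island
coordinates can be supplied via `read_intervals()` instead. Note that a
uniform random sequence has obs/exp near 1, so GC content is the binding
criterion on random backgrounds.

## Enrichment

The expected number of meSNPs inside a feature set on a chromosome is
$E = n \cdot \mathrm{feature\ bp} / \mathrm{chromosome\ bp}$ — uniform random
placement, deliberately ignoring nucleotide composition. Features are merged
(unioned) per chromosome before length summation so overlapping intervals are
not double-counted. Observed versus expected is tested with a two-cell
Pearson goodness-of-fit on 1 df,
$X^2 = (O-E)^2/E + (O-E)^2/(T-E)$, significance at $\alpha = 0.01$. The
two-cell table is the minimal structure consistent with comparing one
observed count against one expectation; no continuity correction is applied
by default because intended counts are in the thousands (a flag enables
Yates' correction for small counts). The genome-wide "average fold" is the
unweighted mean of per-chromosome folds; a pooled genome-wide ratio can be
computed from the returned table if preferred, since both observed and
expected are reported per chromosome.

## Group-specific regions and concordance

Per-sample methylation peak sets (e.g. from an enrichment assay such as
MIRA-Seq) are combined with a presence/absence rule: a region is specific to
a group when it is covered by peaks in at least 3 of that group's samples
(configurable) and by no peak of the other group. "Absent in the other
group" is read as zero overlapping bases in every other-group sample — one
shared base pair disqualifies the whole candidate region, which also makes
the rule antisymmetric. The emitted region is the bp-level intersection of
the supporting peaks (the run of bases with support ≥ the threshold); this
is the conservative choice — a union of supporting peaks is recoverable from
the inputs but is not what the rule emits.

Within these regions, for each classified meSNP with genotypes, per-group
alternate-allele frequencies are computed over non-missing genotypes only
(each called diploid sample contributes two alleles to the denominator).
Candidates must have ≥ 3 called samples per group and an absolute
between-group frequency difference ≥ 0.5. A candidate is *compatible* with
the methylation signal when its MSC allele is at strictly higher frequency
in the hypermethylated group (equivalently the MSD allele in the
hypomethylated group); ties carry no signal and are incompatible, and
`displace` variants — where both alleles support a CpG — are indeterminate
and reported in a separate appendix section.

Two genotype-combinatorics accessors exist because the numbers are easy to
get wrong: 4 states over 4 samples give $4^4 = 256$ vectors, and exact
enumeration gives 189 vectors with ≥ 3 non-missing calls
($3^4 + 4 \cdot 3^3$); `genotype_states_min_called()` always reports the
enumerated value.

## Coordinate conventions

VCF positions are 1-based; BED intervals are 0-based half-open. All
conversion happens at the I/O boundary (`read_intervals()` /
`write_intervals()`, via rtracklayer); in memory everything is a 1-based
closed `GRanges`, the Bioconductor convention. A SNP at 1-based position $p$
is inside BED interval $[s, e)$ iff $s \le p - 1 < e$; the suite probes
both boundaries. Multi-allelic VCF records are split into one record per
alternate allele, each classified independently; INDEL and symbolic alleles
are dropped with a count. Soft-masked genome bases are uppercased — repeat
masking carries no information for CpG status.

## The synthetic-data generator

`make_fixture()` emulates the shape of the intended study: a
multi-chromosome genome (default 2 × 50 kb) with planted CpG islands, SNPs
of every class at known positions, and two phenotype groups of 4 diploid
samples with per-sample peak sets. Defaults: background GC 0.30 (low enough
that no spurious islands arise at these genome sizes, see above), two
islands per chromosome of 400 and 600 bp (one recoverable only under
relaxed criteria, one under both), 10/10/5/5 planted
create/destroy/displace/none SNPs, and 3 compatible + 2 incompatible
concordance meSNPs in 300-bp group-specific regions supported by exactly 3
of 4 samples. Planting edits the genome *before* the FASTA is emitted, so
the reference is always self-consistent with the truth tables, and class is
forced by template trinucleotides (outer bases cannot change the class).
Planned allele frequencies at concordance loci are realized by exact dose
allocation rather than sampling, so truth labels are guaranteed;
`simulate_genotypes()` provides the sampling behaviour (frequencies correct
in expectation) where distributional realism matters more than exactness.
One integer seed drives everything; each generator stage derives a fixed
offset of it, and identical seed plus spec yields byte-identical files.

What the fixtures do *not* emulate: read-level noise, peak-caller
uncertainty, linkage between nearby variants, and composition-dependent SNP
density. Passing the recovery tests therefore demonstrates correctness of
the bookkeeping and statistics, not robustness to upstream noise — that
robustness lives in the upstream callers this package deliberately consumes
rather than reimplements.

## Problem sizes and numerical choices

The test-suite and acceptance runs use 10,000 random classifier cases, 1,000
null replicates of 1,000 uniformly placed meSNPs for chi-square calibration,
a planted 2.5-fold enrichment at $n = 5000$, and the default fixture above —
sizes at which every stochastic check has comfortable margins (e.g. the
planted-fold estimate has a standard error ≈ 0.06 against a ±0.15
acceptance band). Ties in consequence binning are broken by a severity rank
following the conventional most-severe-first ordering, overridable via a
user mapping since category membership is a reporting convention, not part
of the method. Degenerate enrichment inputs (expected count 0 or ≥ total)
are flagged untestable rather than producing an infinite or zero fold.

## Known limitations

* The island scanner is a generic criteria-satisfying detector; island
  boundaries can differ from any specific published annotation by up to one
  window length at each edge.
* The uniform-placement null ignores composition by design; a GC-matched
  background would be stricter but is explicitly out of scope.
* Compatibility is a per-variant direction check, not a statistical test; it
  inherits the small-n limits of 4-vs-4 designs.
* Consequence terms are consumed, not computed; gene models are never
  parsed.
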