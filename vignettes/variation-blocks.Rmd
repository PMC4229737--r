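---
title: "Variation blocks: detecting and comparing recombination blocks in bred crop genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variation blocks: detecting and comparing recombination blocks in bred crop genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Modern crop cultivars descend from a small number of founder lines through
repeated crossing and selection. Each meiosis shuffles the parental
chromosomes at a handful of crossover points, so after a few generations a
cultivar genome is a mosaic of large ancestral segments. Against a single
reference genome, the segments fall into two visibly different states:
stretches that descend from the same ancestral haplotype as the reference
are almost devoid of homozygous SNVs, while stretches introgressed from a
different ancestor carry them at hundreds per 100 kb. The boundaries
between the two states mark historical recombination events.

`vblock` operationalises this observation as a three-stage pipeline:

1. **Block detection per sample.** Homozygous SNVs (heterozygous calls and
   indels removed, optionally masked by the variant calls of a resequenced
   reference individual, which can only be artefacts) are counted in
   consecutive 10-kb bins. Bins with at least 4 SNVs are *dense* (dRB),
   the rest *sparse* (sRB). A two-pass smoothing turns bins into blocks:
   dense runs separated by a sparse gap shorter than 90 kb are joined into
   one dense variation block (dVB), and any dense block still shorter than
   30 kb is dissolved into the surrounding sparse block (sVB).
2. **A shared comparison frame.** The dVB/sVB boundaries of all samples are
   pooled per chromosome, near-duplicates within one bin (10 kb) are
   collapsed to their median, and the resulting *recombination sites* cut
   every chromosome into variation blocks (VBs) — the common units at
   which all genomes are compared.
3. **Typing.** Two samples carry the *same type* at a VB when their
   variant-level sequence identity is at least 99.8% **and** the
   concordance of their SNV sets is at least 0.80. Types are the
   single-linkage components of this pairwise relation; they proxy
   identity by descent from a common parental haplotype.

On top of the frame and the type assignment the package computes
parental-origin maps of descendants, the fraction of one group's blocks
recurring in another group, a *diversity score* (distinct VB types per VB
site, accumulated as genomes are added to a panel), and block-representing
indel markers for rapid trait mapping.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `bin_size` | 10,000 | bp | resolution of the SNV density profile; also bounds boundary precision |
| `dense_snv_threshold` | 4 | SNVs/bin | dRB/sRB split; at typical cultivar densities dense bins carry tens of SNVs, so the call is far from the threshold on both sides |
| `dvb_gap_merge` | 90,000 | bp | sparse gaps below this are absorbed when dense runs are joined |
| `svb_gap_merge` | 30,000 | bp | dense blocks below this are dissolved (equivalently, sparse runs closer than this merge) |
| `identity_threshold` | 0.998 | fraction | minimum variant-level identity for same-type |
| `concordance_threshold` | 0.80 | fraction | minimum SNV-set Jaccard for same-type |
| `boundary_dedup_tolerance` | 10,000 | bp | span of a boundary cluster collapsed to one site; one bin, the intrinsic resolution |
| `min_marker_indel_length` | 5 | bp | indel markers must be longer than four bases to score reliably on gels |

All parameters live in a single `vb_params()` object and can be overridden
from a YAML file (`read_vb_params()`), including through the command-line
front end in `inst/cli/vblock.R`.

## Design choices where the procedure was open

Several details of the published procedure are stated in one sentence or
not at all; the package fixes one defensible reading each and keeps it
consistent everywhere:

* **Merge rule.** The 90/30-kb figures are read as *gap* distances, with
  the dense-join pass applied before the small-dense dissolve pass. A
  dense block spanning an entire chromosome is exempt from the dissolve: a
  fully dense chromosome should not flip to sparse on account of a length
  rule meant for islands. Chromosome-terminal blocks may be shorter than
  the minima, since an edge has no second neighbour to merge across. The
  merge is verified against an independent brute-force per-bin relabelling
  oracle on hundreds of random instances.
* **Identity from variant calls.** Per-base alignment identity would
  require the consensus sequences, which are upstream of this tool.
  Identity is computed as `1 - D/L` where `D` counts positions carried by
  only one sample plus positions where both carry different alternate
  alleles, each once, and `L` is the VB length in bp.
* **Concordance as Jaccard.** The SNV-set concordance is the Jaccard index
  of (position, alt) pairs; two empty sets are fully concordant, so pairs
  of reference-like sparse blocks type together without a special case.
* **Single linkage.** The same-type relation is not transitive at the
  margins; its equivalence closure (connected components) matches the
  intended "descends from one parental haplotype" reading and is
  deterministic, with components numbered by the first sample they
  contain.
* **All instances are typed**, dense and sparse alike; the density label
  is carried on each instance for downstream filtering.
* **Marker screen.** Pass 1 associates one marker per VB genome-wide by
  Pearson correlation between 0/1 genotype codes and a binary phenotype;
  pass 2 re-screens one marker per block within ±1 Mb (a 2-Mb target
  region) of the best hit; pass 3 uses every marker inside the best block
  and brackets the locus by the nearest flanking markers that show
  recombinants. LOD is reported through the standard single-marker
  approximation `n/2 · log10(1/(1-r²))` (infinite for perfect
  cosegregation); heterozygous genotype calls should be coded missing, as
  recombinant inbred lines (RILs) at F4 and beyond are near-homozygous.
* **Genetic distance.** Observed recombination fractions convert to map
  distances with the Kosambi function `25·ln((1+2r)/(1-2r))`, defined for
  `0 ≤ r < 0.5`.

## The simulator

Real resequencing data for this problem is hundreds of gigabytes of reads;
the package instead ships a generative model of exactly the structure the
method assumes, so every stage can be scored against known truth.

* **Founders** are mosaics over a shared per-chromosome segment grid
  (segment lengths uniform on 0.1–3 Mb). Each segment offers one shared
  *reference-like* haplotype (sparse; SNV density 0.05/kb) and a pool of
  `n_haplotypes = 3` divergent haplotypes (dense; 3.8 SNVs/kb). A founder
  picks the sparse state with probability `1 - dense_fraction`
  (`dense_fraction = 0.4`). Haplotype variant sets are drawn once, so two
  founders sharing a haplotype are exactly identical over that segment —
  the identity-by-descent structure the typing thresholds exploit. The
  sparse state is modelled as a *single* shared haplotype because sparse
  blocks are, by definition, the ancestral state shared with the
  reference; a cultivar panel does not segregate multiple "reference-like"
  haplotypes. The dense pool size 3 reflects the narrow pedigree of a
  breeding programme. The dense density 3.8/kb is back-calculated from
  published genome-wide SNV totals and dense-fraction ranges; indels ride
  along at 0.2 per SNV (the published indel:SNV count ratio) with lengths
  uniform on 1–15 bp, so that marker selection has realistic material.
* **Crosses** place a fixed number of crossovers with per-bp weight 6.6 in
  regions where the parents carry identical haplotypes and 1 elsewhere —
  the published sparse/dense recombination contrast — and copy parental
  variants segment-wise. Truth tracks record crossovers, parental origin
  and the inherited haplotype mosaic.
* **RIL populations** accumulate a Poisson(1) number of crossovers per
  chromosome per meiosis over `generations` meioses and toggle parental
  origin; genotypes are read off the true origin at marker positions and
  the phenotype is fully penetrant for the designated parent's allele at a
  causal block. Crossovers form a uniform Poisson process without
  interference, so the simulator's own closed form for the recombination
  fraction between two points is Haldane's; the Kosambi function remains
  the conversion applied to *observed* fractions, as in practice.
* **Depth-dependent dropout** is modelled at the variant level: each SNV
  survives calling at a reduced sequencing depth independently with a
  retention probability (published sensitivities: 1.00 at ≥10-fold, 0.79
  at 6-fold, 0.73 at 5-fold). Read-level resampling, alignment and calling
  are deliberately out of scope.

What the simulator does **not** emulate: sequencing error and false
positive calls beyond the noise-mask mechanism, SNV hotspots within
segments, heterochromatin-dependent block-length distributions,
heterozygosity decay across selfing generations (only origin bookkeeping
is maintained), and structural variation. Passing tests therefore show
that the pipeline recovers the block structure *its model assumes*, at
realistic densities and scales — not that variant calling on real reads is
accurate.

## Numerical conventions and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; VCF positions are
  converted on read, BED is written natively (four columns, deterministic
  byte-identical output for identical input).
* The last bin of a chromosome may be short and keeps its raw count — no
  density rescaling; this affects less than one bin per chromosome.
* Boundary clusters are replaced by their median, rounded; an even cluster
  takes the mean of its middle members.
* An instance-density tie (a VB split exactly 50/50 by a sample boundary)
  takes the label of the block containing the interval start.
* Equidistant candidate markers tie-break to the lower coordinate.
* Multi-allelic VCF genotypes keep the first called alternate allele;
  same-position collisions keep the first record and are reported.
* Empty SNV sets: two empty instances are concordant (1.0); an empty
  marker panel or a zero-variance genotype column is reported as NA rather
  than an error; empty truth sets give NA sensitivity.
* A chromosome entirely dense keeps its dVB even below the 30-kb dissolve
  length (see above).

## Scale of the shipped experiments

The test suite and the acceptance script run the pipeline end to end on
simulated genomes of 20–50 Mb (4–10 chromosomes of 5 Mb), populations of
around 100 RILs, and 10–20 replicate seeds per experiment. These sizes
give stable averages for every reported quantity while keeping a full run
in the minutes range; the method itself is linear in genome size and has
been applied to full crop genomes at 1-Gb scale.

## Known limitations

* Identity is variant-based; two genomes differing only by variants the
  upstream caller missed will look more similar than they are. The
  depth-robustness experiment quantifies exactly this effect.
* A crossover joining two *different dense* haplotypes leaves no density
  boundary, so the resulting chimeric block cannot be split by any
  density-based method and types with neither parent. This is the dominant
  contributor to the small unassigned fraction in descendant typing, and
  matches the ~1–2% unexplained regions reported for real pedigrees.
* Boundary precision is limited to one bin (10 kb) by construction.
* The diversity score uses a frame fixed from the full sample pool before
  any prefix scoring; this makes the curve monotone and its endpoint
  order-invariant, but means the score of a sample subset depends on the
  panel it was framed in.
* Typing against genomes absent from the frame, phasing, imputation and
  LD-based analyses are out of scope.
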