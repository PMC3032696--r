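---
title: "Methods: simulating and analysing ampliconic Y-chromosome gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ampliconic Y-chromosome gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ygenefam)
```

# The system being modelled

Mammalian Y chromosomes carry ampliconic regions: long, internally
repetitive segments built of near-identical repeat units that house
multi-copy, testis-expressed gene families. `ygenefam` models a bovine-style
system in which an ancestral two-gene block (a "B-like" gene and an
adjacent "A-like" gene) transposed onto the Y and then amplified. The
package provides, as one pipeline:

1. a generative simulator for the family, its ampliconic layout, per-locus
   expression and short paired-end reads;
2. coding assessment of each amplified copy (indels, frameshifts,
   premature stops) and an active/pseudogene call;
3. locus-specific expression quantification from 2 x 36 bp read pairs over
   near-identical references;
4. codon-level synonymous divergence (Ks), neighbor-joining phylogenetics
   with bootstrap support, and Ks-calibrated duplication dating;
5. dot-plot detection of direct/inverted repeat arms and overlap-based
   contig assembly.

# The generative model

## Birth process and molecular evolution

Gene-family growth follows the birth-and-death view of multigene family
evolution. Duplication is a pure-birth (Yule) process on *blocks*: every
extant block duplicates at `duplication_rate` per My, and the B-like and
A-like genes of a block duplicate together. Death is not modelled as locus
loss; instead copies degenerate in place, which is what the downstream
classifiers measure. Along every lineage, sequences accrue:

* substitutions under JC69 at `substitution_rate` per site per My
  (`mutate_jc()` draws each site from the exact JC transition kernel, so
  composing intervals is exact);
* indels at `indel_rate` per locus per My, with signed sizes drawn
  uniformly from `indel_sizes`.

Defaults (chosen once, as a realistic desk-scale operating point):

| parameter | default | why |
|---|---|---|
| `total_time` | 19.6 My | the cattle/sheep calibration split |
| `substitution_rate` | 0.004 /site/My | implies interspecies Ks about 2 x 19.6 x 0.004 = 0.157, the observed order for this system |
| `duplication_rate` | 0.12 /block/My | expected 2e^(lambda T) = 21 blocks; large enough to exercise every stage, small enough for fast tests |
| `indel_rate` | 0.08 /locus/My | a mixed active/pseudogene population at desk scale |
| `indel_sizes` | +/-1, 2, 3, 6, 8, 13 | includes the documented +13 insertion and -8 deletion sizes plus small in-frame and frameshifting sizes |

The ancestral block is generated by `ancestral_block()`: each gene has two
exons, a GT-AG intron confined to the 5'-UTR ending 71 bp upstream of the
start codon, and the CDS in exon 2 (543 aa for the B-like gene, 538 aa for
the A-like gene). The simulated intron is 500 bp. Real introns in such
families run 9-31 kb; intron length does not enter any downstream
statistic, so the short intron only saves runtime.

A locus is active *in truth* iff it carries no frameshifting CDS indel and
its truth CDS translates without a premature stop. Note a consequence of
the fully neutral clock: over 19.6 My at 0.004/site/My essentially every
deep lineage acquires a nonsense substitution, so old copies are almost
always truth-pseudogenes. Real active copies persist through purifying
selection and recent birth, which this generator deliberately does not
model; analyses that need intact coding sequences (the Ks/dating stage)
therefore select full-length-CDS loci rather than truth-active ones.

## Expression and reads

`assign_expression()` draws B-like levels log-uniformly on `[1, max_fold]`
(default 60-fold) and A-like levels log-uniformly rescaled so the A-family
mean is `family_a_scale` (default 1/6) of the B-family mean.
`simulate_read_pairs()` samples fragments with probability proportional to
level x transcript length, insert length uniform on 200-300 bp, reads
2 x 36 bp in inward FR orientation, substitution-only sequencing errors at
`error_rate` (default 1e-3), constant quality strings. Qualities are
carried but never used: the quantification logic is mismatch-count based.

## Amplicon layout

`layout_amplicon()` concatenates oriented copies of repeat units with
i.i.d. random spacers (uniform over ACGT, avoiding spurious repeats).
Same-orientation copies are direct repeats by construction,
opposite-orientation copies inverted repeats, giving exact truth for the
repeat-detection tests.

# Coding assessment

`assess_coding()` aligns the transcript's CDS region to the reference CDS
with a global-in-reference / local-in-transcript pairwise alignment
(match +1, mismatch -1, gap open -5, gap extend -1). Indels are read off
the gapped alignment with 1-based reference coordinates; when equivalent
gap placements exist the aligner's leftmost convention fixes the
coordinate, so an indel flanked by a repeated base may be reported one
base left or right of where it was engineered. Any indel of size not
divisible by 3 sets the frameshift flag. Translation then proceeds from
the reference start through the (possibly shifted) frame to the first
stop; `premature_stop_start` is the 1-based CDS position of the stop
codon's *first* base, so the encoded peptide is
`(premature_stop_start - 1) / 3` aa. This convention exactly reproduces
the documented deletion arithmetic (stop at nt 1273 after an 8 bp
deletion -> 424 aa). The corresponding insertion-type arithmetic reported
alongside it (stop at nt 1293 -> 431 aa) is internally inconsistent under
any single convention ((1293 - 1)/3 is not an integer), so the deletion
convention is adopted and the insertion case is validated against direct
translation instead of a fixed constant.

Structural types label the lesion: `A-like` (no indel, full-length
peptide), `B-like` (insertion-driven frameshift), `C-like`
(deletion-driven frameshift), `other`.

`classify_locus()` calls a copy active iff its predicted peptide reaches
`max(min_aa, ceiling(min_fraction * reference_aa))`, defaults 200 aa and
0.40. Reported boundaries for such families are inconsistent (222 aa
copies called active in one family, 262 aa called pseudo in the other), so
the thresholds are explicit configuration. A consequence tested directly:
the length-based call and the frameshift-based truth disagree for
*late* frameshifts (a frameshift at aa 400 still leaves a long peptide);
agreement is therefore asserted one-sidedly (every truth-active locus is
called active; every called pseudogene is a truth pseudogene when the
substitution rate is zero) and the full confusion table is reported by
`analysis/02_annotate.R`.

# Expression quantification

`collapse_identical()` groups byte-identical transcripts into unique
references carrying a copy number, mirroring clustering at 100% identity
and coverage. `align_read_pairs()` searches both strands of every
reference allowing at most 2 substitutions per 36 bp mate (pigeonhole
12-mer seeding, exactly equivalent to a full scan — a property the tests
enforce against an independent oracle). Concordant placements (same
reference, inward FR, insert within 200-300 bp) are enumerated and a pair
is counted *unique* iff all of its minimum-total-mismatch concordant
placements lie on a single reference. Read pairs shared by two or more
references are discarded; multiple placements within one reference do not
disqualify. This pair-level best-hit rule is the one semantics consistent
with both the unique-site normalization below and practical short-read
aligners; the stricter "no secondary hits anywhere" reading leaves a few
percent of pairs and destroys level recovery on realistic families (the
package's tests measure recovery at Spearman >= 0.9 under the pair-level
rule).

Unique pairs are tallied per reference into the three mismatch
categories: A (both mates within the allowance), B (at least one exact
mate), C (both exact). With error-free reads the three coincide — a
property the tests assert.

`count_unique_sites()` enumerates every admissible pair placement (all
starts x all inserts in 200-300 bp) and counts those carrying at least one
36-mer that occurs, exactly and on either strand, in no other reference.
Normalization is then

    normalized = raw / copy_number * avg_length / length * 1 / unique_sites

with `avg_length` the mean length of unique references within the same
family, and the value flagged undefined when `unique_sites = 0`. Each
category is normalized separately.

# Divergence, trees and dating

`ng_pair()` implements codon-based synonymous/nonsynonymous counting:
per-codon synonymous site fractions from the standard genetic code
averaged between the two sequences; multi-substitution codons averaged
over all minimal pathways with pathways through stop codons excluded
(equal pathway weighting; if every pathway is blocked the unrestricted
average is used); changes into stop codons count as nonsynonymous. Codons
containing a gap, `N`, or a stop in either row are removed pair-by-pair
(pairwise deletion). Proportions are corrected with Jukes-Cantor,
`d = -(3/4) ln(1 - 4p/3)`, undefined at `p >= 3/4` and reported as `NA`
rather than an error. An exhaustive pathway-enumeration oracle in the test
suite checks `S`, `N`, `Sd`, `Nd` exactly on random codon pairs.

`nj_tree()` is a from-scratch Saitou-Nei implementation returning an
`ape::phylo`; ties in the Q matrix break on the smallest index pair and
negative branch estimates are clamped to zero (counted in an attribute).
On additive matrices it reproduces the generating topology and branch
lengths exactly, which the tests verify on random trees alongside an
`ape::nj` topology cross-check. Distances for tree building are
JC-corrected dS values; the original analysis used a tool-specific
composite-likelihood distance, and the substitution is deliberate — dS is
fully specified by the Ks machinery already present.

`bootstrap_support()` resamples codon columns (not nucleotides, to
preserve codon structure), rebuilds the Ks matrix and NJ tree per
replicate, and reports for each internal bipartition of the full-data tree
the percentage of usable replicates containing it; replicates with
undefined distances are skipped and counted. Split identity uses canonical
bipartition keys (complement taken against the alphabetically first
taxon), avoiding any rooting convention.

`estimate_duplication_age()` is the calibrated ratio
`max_intrafamily_ks / interspecies_ks_mean * t_split` (default
`t_split = 19.6` Mya). The dating *experiment* (acceptance suite and
`analysis/04_evolve.R`) computes the intrafamily matrix on the
concatenated CDS of both block members: blocks duplicate as a unit, so the
concatenation measures the same event with roughly twice the synonymous
sites. This matters because "max pairwise Ks" is an extreme-value
statistic: with a single 543 aa gene its sampling noise inflates the
estimate by roughly 20-25% on families of tens of loci, while the
block-level version recovers the oldest duplication within the tested 20%
band. The single-gene behaviour is an inherent limitation of this
extreme-value statistic, not of the implementation.

# Repeat structure and assembly

`dotplot_matches()` lists all exact w-mer matches (default w = 10) in
forward and reverse-complement orientation. `detect_arm_pairs()` chains
off-diagonal forward matches along diagonals into direct-repeat candidates
and reverse-complement matches along anti-diagonals into inverted-repeat
candidates, merging runs with internal gaps up to `max_gap` (default
500 bp; at 1% arm divergence the expected spacing of broken words is far
below this) and discarding candidates shorter than `min_arm` or with
overlapping arms. Planted arms are recovered to within a few bases — word
runs can extend past a junction by chance (probability 1/4 per extra
base), so boundary assertions carry a small tolerance. `arm_identity()`
aligns arms globally (IR arms reverse-complemented first) and reports
matches over aligned columns *excluding gap columns*, the "without
considering gaps" convention; 6 substitutions in 1000 bp give exactly
99.40%, and a pure insertion leaves identity at 100%.

`assemble_overlaps()` detects suffix-prefix overlaps between all ordered
sequence pairs in all four orientation combinations, anchored on an exact
64-mer end seed (at the >= 99.85% identities involved an intact 64-mer
exists with overwhelming probability), verifies gapless identity over the
implied overlap, keeps edges meeting the length/identity thresholds
(defaults 30 kb / 99.99%, relaxed 20 kb / 99.85%), and merges unambiguous
chains of the oriented overlap digraph into contigs; branching nodes split
chains. Exact tilings reassemble byte-identically, including tiles
presented reverse-complemented.

# Problem sizes and numerical choices

The shipped tests and drivers run at desk scale, chosen as the package's
own operating point: families of ~20-60 loci (the birth process is
conditioned to at least 20 loci where a stated condition requires it, by
advancing a sub-seed deterministically — a size condition, never an
outcome condition), 10,000-20,000 read pairs, 100-200 bootstrap
replicates in drivers (the configuration default is 1000), 5 kb planted
repeat arms, and a 1.2 Mb nine-tile assembly. All stochastic stages are
driven by explicit seeds through one RNG discipline (`withr::with_seed`),
so a fixed seed and configuration give byte-identical tabular outputs.

# Known limitations

* No purifying selection: active fractions in deep simulated families are
  far below those of real, selected families (see above).
* The aligner models substitutions only; indel sequencing errors and
  quality-aware alignment are out of scope, matching the mismatch-count
  contract.
* Interspersed repeat content (LINE/SINE-style) is not simulated, so
  dot-plots of simulated contigs are cleaner than real ampliconic
  sequence.
* Codon alignments are taken from indel-free CDS sets; building gapped
  codon alignments from diverged, indel-bearing sequences is explicitly
  not provided.
* `unique_sites` counts exact-kmer-private placements; under extreme
  mosaic reference sets a pair can be concordant-unique on a reference
  with no private kmers, so the no-leakage property is guaranteed only
  for collinear families like those simulated here.
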