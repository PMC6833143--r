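---
title: "Scrubbing long noisy reads with overlap pileup images"
author: "PileupScrub authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scrubbing long noisy reads with overlap pileup images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PileupScrub)
```

## The problem

Single-molecule long reads (Oxford Nanopore and similar) carry per-read
error rates of roughly 5--40%, and the errors are not spread evenly:
they cluster into low-quality "junk" stretches, and library artifacts can
join two unrelated loci into one chimeric read. Removing (*scrubbing*)
these internal low-quality segments -- as opposed to *trimming*, which only
touches read ends -- improves downstream error correction and assembly.

The scrubbing problem is reference-free at application time: with no
truth available, the only evidence about a read segment's accuracy is
(a) its base quality scores and (b) how well other reads support it.
PileupScrub operationalizes "support" with minimizer-based all-vs-all
read overlapping, encodes the evidence as an image per read, and trains a
small convolutional network to regress each fixed-width image segment to
its *percent identity* -- the fraction of read bases in the segment that
are correct. Segments predicted below a cutoff (default 0.8) are removed,
the read is split there, and fragments shorter than a minimum length
(default 500 bases) are discarded.

## Minimizer sketching and overlapping

A *(w,k)-minimizer* is the minimum-order k-mer among `w` consecutive
k-mers. If two reads share an identical stretch of `w + k - 1` bases they
are guaranteed to share the minimizer selected inside it, so shared
minimizers are a compressed proxy for sequence agreement. Defaults are
`(w, k) = (5, 15)`, with `(7, 17)` supported as a sparser variant.

Design choices worth stating explicitly:

* **Order key.** K-mers are ranked by an invertible 64-bit mixing hash
  (splitmix64 finalizer, truncated to 53 bits so a key fits exactly in a
  double) of the canonical 2-bit encoding -- the smaller of the forward
  and reverse-complement codes. A hash order avoids the poly-A bias of
  plain alphabetical order; canonical k-mers make overlap detection
  strand-agnostic at extraction time.
* **Ties.** All tied occurrences in a window are selected. This keeps the
  window-sharing guarantee exact (homopolymers select every position).
* **Ambiguity.** K-mers containing a non-ACGT base are ineligible and
  simply drop out of their windows.
* **Brute-force oracle.** `bruteForceMinimizers()` enumerates every
  window explicitly and shares nothing with the production path but the
  order key; the test suite asserts exact equivalence across hundreds of
  random sequences and parameter settings.

Overlapping indexes every occurrence by hash and, per read pair and
relative orientation, keeps the longest co-linear chain: strictly
increasing reference minimizer index, query positions strictly monotone
(increasing on `+`, decreasing on `-`), and base gaps on both reads
capped at `maxGap` (default 500). This is a gap-limited longest
increasing subsequence, chosen over production-grade scored chaining
because the downstream encoder only needs matched minimizer positions and
an LIS is exactly testable against subset enumeration. Pairs with fewer
than `minShared = 4` chained matches are suppressed; minimizers occurring
in more than 200 reads are skipped as a repeat guard. A standard PAF
file from an external overlapper can substitute for the built-in
overlapper; matched minimizer positions are then recovered by
intersecting sketches inside the reported intervals.

A consequence of "longest chain only" is that a read whose middle is junk
keeps matching-read support on just one side of it (the chain cannot
bridge a gap larger than `maxGap`); the unsupported half appears black in
the image even though its sequence may be fine. At the coverages used
here other piled reads cover that half, so the encoder still sees
support; the limitation matters mainly at very low coverage.

## The pileup image

One image per read. Columns are the reference read's minimizers in
order; row 1 is the reference read itself and rows 2..24 are matching
reads (`depth = 24` including the reference; when the pile is larger, 23
matching reads are sampled uniformly without replacement under a seed,
after sorting by shared-minimizer count so truncated piles favor
informative reads). Per pixel:

* **red** -- 255 where the matching read's chain contains the column's
  minimizer, 70 elsewhere inside the read's matched span;
* **green** -- twice the average Phred+33 quality *character* value over
  the pixel's base interval, clamped to [66, 254] (`'!'` = ASCII 33 is
  the floor: 66);
* **blue** -- the distance in bases to the next minimizer, capped at 255;
  disagreement between a matching read's blue value and the reference
  row's signals an indel.

Pixels outside a matching read's matched span, and rows with no matching
read, are black `(0,0,0)`. For columns inside the span whose minimizer
the matching read lacks, the read's corresponding base interval is
inferred by linear interpolation between the flanking matched
minimizers; that choice keeps the indel signal in the blue channel
without doing any base-level alignment. The stated green upper bound of
254 would correspond to quality characters up to ASCII 127, one past the
printable `'~'` = 126; we clamp at 254.

Images are cut into segments of `segmentLength = 48` columns (the
`(36, 36)` depth/length variant is also supported); the final partial
window is right-padded with black columns. Segment base ranges come from
the column coordinates, with the first segment extended back to base 0
and the last to the read end so that one read's segments exactly
partition `[0, read length)` -- the property the scrubber needs to slice
reads losslessly.

## Labels

At training time each segment is labeled with its percent identity:
matched read bases divided by read bases in the segment's range.
Clipped, inserted, mismatched and unaligned bases count only in the
denominator; deletions from the reference consume no read bases and do
not enter it. Labels can come from:

* SAM alignments (`readSamAlignments()` + `labelSegments()`): extended
  CIGAR (`=`/`X`) is used directly; ambiguous `M` is resolved through the
  MD tag when present and otherwise counted as match with a warning.
  One primary alignment per read is kept (most aligned bases;
  secondary/supplementary records are ignored), so the far side of a
  chimeric junction is labeled 0 -- exactly the signal the scrubber
  should learn. Unmapped reads are labeled 0 everywhere.
* PAF with `cg:Z:` tags (`readPafAlignments()`), converted to the same
  record shape.
* The simulator's truth track (`truthLabels()`), which needs no mapper.

Because match counts are additive, a read's whole-read identity equals
the length-weighted mean of its segment identities exactly; the test
suite asserts this to numerical precision, and also that alignment-based
labels equal mask-based truth labels on simulated data (the simulator
emits its own exact SAM via `truthToSam()`).

## The regressor

The fidelity architecture (`vgg16_adapted`) follows the classic
13-convolution / 3-dense VGG16 stack of 3x3 filters, modified to emit a
single value: the final dense unit passes through a sigmoid, since
identities are proportions in [0, 1]. A 24-pixel depth axis cannot
survive five 2x2 poolings, so after the third block pooling acts along
the length axis only -- the canonical schedule is otherwise preserved.
Weights are Glorot-uniform initialized from a seed; training minimizes
mean squared error with Adam. The published recipe (learning rate 1e-4,
five epochs, batch 64) is the package default.

The `small` variant (conv 8/16/32 with 2x2 pooling, one 64-unit hidden
dense layer, same bounded head) exists so the full pipeline trains in
minutes on one CPU core. All of the network -- forward, backward, Adam,
init, shuffling -- is implemented in single-threaded compiled code with
its own RNG, so training and prediction are bit-reproducible given the
seed, and a saved model reloads with bit-identical predictions.

**Step size at desk scale.** The published learning rate belongs to a
setting with ~25,000 reads (hundreds of thousands of Adam updates over
five epochs). The package's end-to-end experiment below trains on about
8,500 segments, i.e. ~2,700 updates at batch 16 -- over an order of
magnitude fewer. At 1e-4 the five-epoch budget then stalls in the
regression-to-the-mean regime: rank correlation is respectable but the
low-identity tail never drops below the scrub cutoff, so nothing is
scrubbed (training the same model longer confirms the encoding carries
the signal: specificity climbs above 0.5). The small-variant CPU recipe
therefore scales the step size to the update budget -- learning rate
1e-3, batch 16, five epochs -- roughly conserving learning rate times
update count. Model defaults are unchanged; the recipe applies to the
desk-scale experiment and is what `test-acceptance.R` uses.

Training splits train/validation by *reference read*, never by segment:
segments of one read share rows and errors, and a segment-level split
would leak.

## The simulator

The synthetic-data generator emulates the platform's error structure so
the whole pipeline can be trained and evaluated hermetically:

* genomes are uniform random ACGT of configurable lengths;
* read lengths are log-normal (median ~2 kb, matching the ~2.6 kb
  average of the motivating datasets);
* each read draws a baseline error rate from a log-normal around the
  configured mean (default 0.15, spread `readErrorSdLog = 0.35`, clamped
  to [0.02, 0.45]) -- reads of this class span roughly 5--40% error, and
  a per-read spread is what makes identity a continuum worth regressing;
* errors are 40% substitutions and 60% single-base indels (split evenly
  between insertions and deletions), reflecting the platform's
  indel-dominant spectrum;
* with probability 0.3 a read carries one junk segment of 100--1000
  bases at 30--50% error;
* with probability 0.05 a read is a chimera of two independently drawn
  loci (either strand, possibly different genomes);
* per-base Phred qualities are normal around `-10 log10(local error
  rate)` with sd 3, truncated to [0, 40] -- informative but imperfect,
  which is precisely the regime where overlap evidence should help.

The truth track records source intervals, junk intervals, a per-base
error mask (substituted and inserted bases), and the exact per-chunk
extended CIGAR, enabling three independent label routes that the tests
cross-check. Deliberate non-realisms: genomes are repeat-free and
uncorrelated, indels are single-base (real Nanopore indels can be
large), junk is a single contiguous region, and quality-score noise is
Gaussian. Passing the end-to-end test therefore demonstrates that the
pipeline learns and removes clustered low-quality sequence under a
faithful error *structure*; it does not certify performance on any real
flowcell or basecaller, for which a model should be trained on reads of
that technology with alignment-derived labels.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; strands are `+`/`-`.
* Reads shorter than `w + k - 1` bases have no minimizer window, hence
  no columns and no segments; the scrubber passes such reads through
  unmodified (with a warning at the FASTQ level).
* Interpolated base intervals that collapse to zero width are widened to
  a single base; interpolation is rounded to integer coordinates and
  clamped to the read.
* Pooling uses floor division; architectures whose spatial axes would
  collapse below one pixel are refused at build time with both shapes in
  the message.
* Zero-variance inputs leave correlation metrics `NA` rather than
  failing.
* Scrub fragment ids are `<read_id>:<n>`, numbered left-to-right over
  emitted fragments; a read with nothing removed keeps its id.

## Problem sizes used by the test suite

Unit tests run on sequences of a few hundred bases and networks of
8x16 pixels. The end-to-end experiment simulates one 50 kb genome at
30x (~700 reads, ~10,000 segments), trains the small variant for five
epochs on 80% of reads, and evaluates on the held-out 20%: it requires
Spearman >= 0.5 between predicted and true identity, sensitivity >= 0.8
at the 0.8 cutoff, and that scrubbing strictly raises the mean truth
identity of retained bases over the raw reads. The whole suite completes
in well under half an hour on one CPU core.

## Limitations

* The overlapper reports one chain per read pair; split support around
  long junk regions is recovered only through other piled reads.
* Chimeric junctions and large indel regions are scrubbed identically;
  discriminating them (splitting only true chimeras) would need labels
  that distinguish the two.
* The simulator's junk/chimera machinery provides the *structure* of
  platform noise, not any specific chemistry; models intended for real
  data must be retrained per technology and basecaller.
* `vgg16_adapted` is faithful but heavy for CPU-only training; the
  `small` variant is the practical default at package scale.
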