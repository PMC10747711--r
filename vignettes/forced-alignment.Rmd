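---
title: "Text-independent forced alignment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Text-independent forced alignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonalign)
```

## The problem

Clinical assessment of speech sound disorders needs phone-level time
alignments of what a speaker *actually said*, which routinely deviates
from the dictionary form ("ca" for "cat"). Text-dependent forced
aligners are therefore unusable: they require the target transcript and
will silently correct the speaker. `phonalign` implements a
text-independent aligner that fuses two independent, imperfect frontend
signals — a CTC phoneme recognizer's per-frame labels, which know *what*
was said but only weakly *when*, and an unsupervised segmenter's
boundaries, which know *when* something changed but not *what* — into a
labelled segmentation.

## The model

**Timed tokens.** A recognizer emitting `T` frame labels over `s`
seconds gives token `i` (0-based) the impulse time
`t_i = (2i + 1)·s/(2T)`: the frames are spread uniformly and each token
sits at its frame centre. Timestamping happens *before* special-token
filtering, so surviving phones keep their positions. These times are
deliberately treated as weak evidence; nothing downstream assumes they
are accurate beyond ordering.

**Class regions.** Between successive filtered impulses at `t1 < t2`
the class boundary is `(1 − β)·t1 + β·t2`. The first region is extended
to 0 and the last to `s`, so the regions exactly partition
`[0, s)` — every instant of the utterance belongs to exactly one
candidate phone. β compensates recognizers whose impulses
systematically lead (β < 0.5) or lag (β > 0.5) the phone they
detect; β = 0.5 is the nearest-neighbour midpoint and the default. β is
a single global setting per run; we considered per-phone biases out of
scope (they would need per-phone calibration data the tool's users
rarely have).

**Maximum contribution.** Each unlabelled segment receives the label
with the greatest summed region overlap inside it, accumulated per
label rather than per region so a phone split across two regions still
competes as one candidate. Intervals are half-open; a shared endpoint
contributes zero. Ties are broken toward the label whose contribution
starts earliest in the segment: the natural alternative (container
iteration order) is an accident of implementation, while the temporal
rule is deterministic in any language. Because the regions partition
the timeline, per-segment overlaps always sum to the segment length and
a zero-overlap segment cannot occur.

**Cleaning.** Recognizer overfitting yields runs of equal-label
segments. A duplicate pair is *permissible* only if the CTC-collapsed
token string contains that label twice in a row — which happens exactly
when the two impulses were pad-separated, as in a genuine repeated
phone. *Hard* cleaning merges every non-permissible adjacent duplicate
anywhere, iterating to a fixed point (the published pseudocode of this
strategy neither terminates nor advances its cursor as printed; our
loop advances when no merge occurs and steps back one position after a
merge, the minimal repair consistent with the prose). *Soft* cleaning
is a single left-to-right pass synchronised with the transition list:
merge a duplicate that is not the expected transition and move to the
next transition, advance the transition on a realised pair, otherwise
advance the segment cursor — hence only the first duplicate pair of a
run is amalgamated per pass. A `fixed_point` option repeats the pass
until stable, but the single pass is the default since the strategy is
defined as a local clean. Hard cleaning is the package default: in the
published ablation it gives the best label accuracy, and our synthetic
duplicate-corruption experiments reproduce that direction.

**Voice activity filtering (off by default).** The published
description fixes the VAD parameters (nFFT 2048, 25 ms window, 10 ms
hop, threshold 0.5) but not the algorithm, so the package implements a
documented baseline: framewise RMS energy with frame `i` covering
`[i·hop, i·hop + window)`, normalised to `[0, 1]` by the utterance
maximum. We chose max-normalisation over min–max because a uniformly
voiced utterance should score 1 everywhere rather than being stretched
to full range; the two coincide whenever the utterance contains
silence. The probability sequence is thresholded and converted to
rising/falling edge pairs (a run opens at its first speech frame's
start time and closes at the first non-speech frame's start time, or at
the end of audio); any boundary not inside a speech region is deleted,
so segments wholly inside silence vanish. Whether points or whole
intervals should be deleted is an interpretation; the point rule
reproduces the intended picture and is idempotent. Any external VAD can
be substituted by passing its probability vector to
`probabilities_to_regions()`. Filtering is off by default because the
ablation selected hard cleaning *without* VAD as the final
configuration.

## Evaluation protocols

The *midpoint* protocol counts a hit when a truth segment's midpoint
falls inside a prediction and the labels agree; `hits/n_truth` and
`hits/n_pred` are combined by the harmonic mean `2/(1/a + 1/b)`
(defined as 0 when either argument is 0). As in the reference
pseudocode, one truth segment may match several predictions and vice
versa; we reproduce that multi-match behaviour exactly and expose a
greedy one-to-one variant behind `one_to_one = TRUE` for comparison.
Matched pairs contribute absolute onset/offset errors, summarised as
fractions strictly below 20/40/60 ms. The *onset* protocol matches
predicted onsets to truth onsets within ±20 ms; multiplicity is not
specified in the source description, so we use greedy nearest-first
one-to-one matching, the standard for boundary F1. Per-phoneme error
rates are reported as the fraction of a phone's truth segments with no
label-correct midpoint match — counting distinct matched truth segments
keeps the rate in `[0, 1]`, which a raw hit count cannot guarantee
under multi-matching.

## The synthetic generator

`generate_ground_truth()` draws phone labels uniformly from the
61-phone ARPABET inventory (silence `h#` reserved for optional
100 ms edge padding) with durations uniform on 0.06–0.18 s, quantised
to the 16 kHz sample grid. The band is a deliberately mid-range phone
duration model: with recognizer impulses at frame centres (50
frames/s, the typical self-supervised frontend stride) it guarantees
each phone's own class region strictly dominates neighbour intrusions,
so the zero-corruption pipeline recovers ground truth *exactly* for
every seed — the parameter-recovery baseline is then a sharp test, not
a statistical one. Real speech contains shorter phones (closures,
flaps) for which this guarantee does not hold; passing the recovery
baseline therefore shows internal consistency of the pipeline, not
field accuracy on real audio.

`emulate_recognizer()` renders each phone as one labelled frame near
its centre among pads, with Gaussian impulse jitter (default sd 10 ms),
substitutions (default 0.1) and *overfitting duplicates* (default
0.1): a duplicated phone fires on two consecutive frames, so CTC
collapse merges the pair — the duplicate is not a permissible
transition and is exactly what cleaning removes — whereas genuine
ground-truth repeats are rendered pad-separated and survive collapse as
permissible pairs. An earlier design that emitted duplicates
pad-separated was rejected: such duplicates become permissible
transitions that cleaning must preserve, making the duplicate rate
inert. Since an overfitted phone only manifests as two *segments* when
the segmenter also splits there, the duplicate split times are fed to
`emulate_segmenter()` as extra boundaries; the segmenter otherwise
jitters true boundaries (default sd 20 ms, a typical unsupervised
segmenter error), drops them (default 0.05) and inserts spurious ones
(default 0.1 per segment). What the generator does *not* model:
acoustic confusability structure (substitutions are uniform), duration
correlations between neighbouring phones, and recognizer
deletions/insertions beyond the duplicate mechanism.

## Numerical choices and degenerate inputs

Sample indices are 0-based with half-open `[begin, end)` intervals
(the TIMIT convention), making contiguity exactly testable. PHN
sample-rate repair multiplies indices by the rate ratio and rounds
half-away-from-zero — the source only says "multiply the ratio", and a
fixed rounding rule is needed for reproducibility; a composed
16→44.1→16 kHz round trip moves any index by at most 2 samples.
Empty or placeholder annotation files (".jpg"/"xxx", from picture-naming
prompts in dysarthric corpora) are rejected as unusable rather than
parsed. Equal impulse times are rejected rather than tie-broken — the
timestamping rule cannot produce them. Writing an empty PHN file is
refused. Region partitions assert coverage to 1e-12. The `h#`-padded
utterance edges mean leading/trailing silence is aligned like any
phone, which is how TIMIT annotates it. The Unicode codepoint map
(phones to emoji-range codepoints, a tokenizer workaround in some CTC
stacks) is carried as inventory metadata only; all APIs speak ARPABET.

## Problem sizes

The test-suite property checks use 1000 random labelling instances
against a 0.1 ms grid-counting oracle (instance times drawn from a 2 ms
lattice so grid counts are exact rather than approximate), 200 random
instances each for partition/cleaning/evaluation properties, a
50-utterance zero-corruption recovery corpus, 50 seeds for the
cleaning-efficacy direction, and a 40-utterance corpus for the 9-point
bias sweep; the whole suite runs in about half a minute on one core.

## Known limitations

* The aligner can never recover a phone the recognizer missed entirely,
  nor split a segment the segmenter did not propose; it only transfers
  and cleans labels.
* The energy VAD is a baseline; noisy recordings need a model-based
  VAD plugged in through the probability interface.
* Timing accuracy is bounded by the frontend frame stride; impulse
  times carry no sub-frame information.
* The evaluation reproduces the reference multi-match midpoint
  semantics, which can count one truth segment several times; compare
  with `one_to_one = TRUE` when that matters.
```{r example}
gt <- generate_ground_truth(8, seed = 42, silence_pad = 0.1)
bundle <- synthesize_bundle(gt, corruption_config(), seed = 42)
report <- midpoint_evaluate(gt$phones, align(bundle))
report
tolerance_table(report)
```
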