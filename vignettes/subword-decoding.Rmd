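---
title: "Decoding evoked responses with compositional subword embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding evoked responses with compositional subword embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In morphologically rich, agglutinative languages most word forms are rare:
even very large corpora contain too few occurrences of a given inflected
form to estimate a reliable distributional vector for its surface form. If
complex words are processed compositionally — a stem plus one or more
affixes, concatenated — then a word vector can instead be *composed* as the
sum of the embedding vectors of its subword segments, and that composed
vector can stand in for the surface vector in a brain-decoding analysis.

`morphodecode` implements this analysis for item-averaged evoked MEG (or
similar) data: a linear decoder maps windowed sensor features to the
semantic space, held-out word pairs are scored with the 2-vs-2 test, and —
critically — two different permutation nulls separate decoding that is
driven by the *content* of the segment vectors from decoding that merely
rides on the *pattern of shared segments* across words.

## The decoding model

Let $X$ be the $n \times p$ matrix of windowed sensor features ($n$ words;
$p$ = sensors × samples per window, features flattened sensor-major) and
$Y$ the $n \times D$ matrix of word vectors. For each 100-ms window
(50-ms step, starting at the epoch onset so that pre-stimulus windows act
as an internal control) we fit a ridge regression $f: X \to Y$:

* columns of $X$ and $Y$ are z-transformed using the training rows of the
  fold only (a `global_zscore` flag reproduces the alternative convention
  of standardizing once over all rows, for comparison);
* the penalty $\alpha$ is selected independently for every target
  dimension from a grid of exactly 100 log-spaced values between
  $10^{-5}$ and $10^5$;
* selection uses the exact SVD leave-one-out shortcut by default
  (`cv = "loo"`, the same computation the common `RidgeCV` implementation
  performs), with an explicit leave-two-out enumeration available as
  `cv = "l2o"`.

Evaluation is the leave-two-out **2-vs-2 test**: for every unordered word
pair, a fresh decoder is trained on the remaining $n-2$ words, the two
held-out words are projected into the semantic space, and the pair counts
as correct when the matched sum of cosine distances
$d(p_1,a_1)+d(p_2,a_2)$ is strictly smaller than the crossed sum
$d(p_1,a_2)+d(p_2,a_1)$. Exact ties score 0.5, so the accuracy remains an
unbiased mean under degenerate predictors. Window accuracy is the mean
over pairs; chance is 0.5.

## The two permutation nulls

**Word-label permutation** is the standard chance estimate: the assignment
between brain-response rows and word-vector rows is shuffled uniformly,
the full evaluation is re-run, and the significance threshold is the 95th
percentile of the null accuracies (linear-interpolation quantile by
default; a nearest-rank option exists because the convention is not
forced).

**Segment-label permutation** is the decisive test for compositional
claims. When word vectors are sums of segment vectors, words sharing a
segment share a vector term, so they align in the composed space *whatever
the segment vectors contain*. That alignment alone can support decoding.
The null therefore shuffles the bijection between segment labels and
segment vectors — over the segment types of the words under study — and
recomposes all word vectors before re-running the evaluation. The
word-by-segment occurrence pattern is identical in every permutation; only
the identity of the vectors is scrambled. If the segment-label threshold
sits far above the word-label threshold, decoding can succeed from shared
structure alone; if an observed accuracy beats the segment-label
threshold, the segment vectors themselves carry decodable information.

Both nulls reuse, by default, the per-fold alphas selected in the observed
run. This is not an approximation of the refit: under either permutation
only the target side of every fold changes, so the cached per-fold SVD and
standardization of $X$ are exactly what a full retrain would compute.
`retune_alphas = TRUE` re-tunes inside every permutation (slow, and in our
checks within ±0.1 of the fast mode per permutation). Bijections are
uniform over all permutations — the identity is allowed, matching a
"randomly selected vector from the set" reading; derangements are not
forced. The p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_\text{perm})$. Per-window accuracies are compared against per-window
thresholds without multiple-testing correction across windows; this
mirrors the common practice for this analysis and is a deliberate,
documented limitation.

## Segmentation schemes

Four schemes are built in: `whole` (no segmentation), `ngram` (contiguous,
non-overlapping, left-to-right chunks of *k* characters, final chunk
possibly shorter — not the overlapping FastText convention), `random`
(each word split into $n$ segments at interior positions drawn uniformly
without replacement, $n$ uniform on $\{2,\dots,\lfloor l/2\rfloor\}$;
words of length ≤ 3 are left whole since the draw set is empty, and
lengths 4–5 force $n = 2$; the segmentation is cached per word type so
repeated tokens segment identically), and `lexicon` (external
morphological segmentations, e.g. linguistic analyses or Morfessor
output, consumed as TSV). All string lengths are Unicode code-point
counts, which matters for alphabets with multibyte letters (ä, ö).

`compare_segmentations()` classifies a statistical segmentation against a
linguistic reference into five categories (identical / unsegmented /
incomplete / incorrect-stem / incorrect-suffix). The boundary-set rules —
"incomplete" means every statistical boundary is a reference boundary but
not all reference boundaries are present, and an incorrect segmentation is
a *stem* error when the first offending boundary lies at or before the end
of the first reference segment — are our formalization of category names
that are usually reported only as counts; alternative formalizations could
shift words between the two "incorrect" categories.

## Segment vectors

Segment embeddings follow the skip-gram contract: dimension $D$ (default
300), symmetric context window (default 7), and a minimum corpus frequency
(default 50) below which a segment gets no vector. Because no R embedding
package is available as a dependency, the package ships a minimal,
deterministic skip-gram negative-sampling trainer (compiled inner loop,
fixed — not dynamically shrunk — context window, negative = 5, linear
learning-rate decay). It is meant for toy corpora and for exercising the
pipeline end to end; at real-corpus scale one would import vectors in the
word2vec text format via `read_vectors()` instead. Hyperparameters beyond
dim/window/min-count are exposed in `embedding_config()` because no single
convention is forced.

Word vectors are sums of segment vectors with multiplicity, never
normalized before summation (the cosine metric used in evaluation absorbs
global scale). Segments missing from the store are skipped and recorded in
a coverage report; a word with no covered segment is flagged `NA` and must
be excluded from decoding — it cannot be represented, which is exactly the
out-of-vocabulary failure mode the composition approach is designed to
alleviate.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` creates the full study: an artificial multimorphemic
lexicon (words = stem + 1–2 suffixes from a closed set, so suffixes are
shared by many words while stems are rare), structured segment vectors
(stem vectors scatter around cluster centroids; suffix vectors occupy a
disjoint subspace with smaller norm), an optional toy corpus for embedding
training (cluster-specific filler contexts; an `exclude_targets` mode
emits sentences that never contain a stimulus surface form), and simulated
epochs in which each word's response is a random linear sensor projection
of its composed word vector, gated by a raised-cosine envelope supported
on the 350–500 ms effect window, plus Gaussian noise. SNR is defined as
signal RMS over the effect window divided by noise RMS; an AR(1) flag adds
temporally correlated noise for robustness checks, but white noise is the
default null because the decoding contract is agnostic to noise color.

Two generator design choices deserve emphasis. First, stems and suffixes
draw on disjoint letter inventories. In natural agglutinative text, words
sharing several characters are on average more likely to share a suffix;
with a single shared alphabet and random strings, accidental
stem–character collisions dilute that relation badly at a 40-word scale,
and the shared-structure artifact that the segment-label permutation test
is designed to expose becomes unreliable to demonstrate. Separating the
inventories (mirroring the disjoint vector subspaces) restores the regime
the argument concerns. Second, the envelope is zero outside the effect
window, so pre-stimulus windows are signal-free by construction and serve
as a built-in negative control.

What the generator does *not* emulate: realistic forward models (no head
geometry or source dipoles), colored sensor noise by default,
participant-level variability (the data model is the item average), or the
statistical texture of real corpora. Passing tests on synthetic data
therefore show that the machinery is correct and that the dissociation
logic behaves as designed — not that any particular real dataset will
decode.

## Problem sizes and numerical choices

The package's reference desk-scale conditions, used by the test suite and
the acceptance script, are: 40 words (20 stems × 2 suffixes), $D = 20$,
6 sensors at 100 Hz (a 100-ms window holds 60 features), epoch −200 to
800 ms (19 windows), SNR 5, 100 permutations per null over 500 subsampled
pairs (of 780), with the test window chosen as the effect-window slice
centered nearest 400 ms. The type-I calibration uses 200 independent
SNR-0 replicates of a reduced configuration (12 words, $D = 6$,
4 sensors, 100 permutations each). These sizes were chosen once as the
smallest configuration in which all the qualitative contrasts are clearly
resolved.

Numerical details: ridge solutions come from a thin SVD with singular
values below $10^{-12}$ of the maximum truncated; constant feature or
target columns get unit scale with a warning; the per-fold alphas always
lie on the declared grid; cosine distance is undefined (an error) for
zero vectors rather than silently coerced; and every random operation
takes an explicit seed, so identical configurations reproduce results
bit for bit.

## A worked example

```{r, eval = FALSE}
library(morphodecode)

cfg <- synthetic_config(n_stems = 20, n_suffixes = 2, dim = 20,
                        n_sensors = 6, sfreq = 100, snr = 5,
                        semantic_clusters = 4, seed = 101)
ds <- generate_dataset(cfg)

spec <- window_spec(100, 50)
idx <- effect_window_indices(ds$epochs, spec, cfg$effect_window)

result <- run_two_vs_two(ds$epochs, ds$word_vectors, spec,
                         max_pairs = 500, seed = 202)
accuracy_timecourse(result)

wl <- word_label_null(ds$epochs, ds$word_vectors, window = idx$effect[2],
                      spec = spec, n_perm = 100, seed = 202,
                      max_pairs = 500)
sl <- segment_label_null(ds$epochs, ds$lexicon, ds$store,
                         window = idx$effect[2], spec = spec,
                         n_perm = 100, seed = 202, words = ds$words,
                         max_pairs = 500)
wl; sl
```

The morphological run beats both thresholds inside the effect window and
sits inside the null band before stimulus onset. Replacing the true store
with a label-permuted one (`permute_segment_store()`) collapses the
observed accuracy into the segment-label null band, and composing from
1-character segments raises the segment-label threshold well above the
word-label threshold — the package's reproduction of the headline
dissociation.

## Known limitations

* The internal skip-gram trainer is single-threaded and toy-scale by
  design; import pretrained vectors for real corpora.
* Epoch serialization is a plain-text TSV, deliberately portable and
  diff-able but not suited to very large sensor arrays.
* Whether alpha should be tuned once per window or inside every fold is
  not settled by convention; the default tunes per fold (no leakage), and
  permutation runs inherit the observed run's per-fold alphas unless
  `retune_alphas = TRUE`.
* No multiple-testing correction is applied across windows.
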