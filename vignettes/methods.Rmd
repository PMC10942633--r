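---
title: "Models and methods in tcrpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tcrpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcrpred)
```

This vignette documents the models implemented in `tcrpred`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical conventions the package fixes where the field leaves a choice
open, and what the synthetic benchmarks do and do not demonstrate.

## The prediction problem

A paired-chain TCR is represented by its six CDR loop sequences plus the
candidate peptide. The package answers a binary question — does this TCR
bind this peptide? — with a score in (0, 1), and evaluates it per peptide,
because both the data volume and the attainable accuracy differ by orders
of magnitude between well-studied and rare epitopes. MHC alleles are
carried as metadata only: with few distinct alleles per peptide in typical
curated data there is no signal to learn from them, so no model consumes
them.

## Data curation

**Nomenclature.** CDR3 junctions are normalised to the IMGT convention
(leading cysteine, trailing phenylalanine or tryptophan) by
`fix_cdr3_nomenclature()`, which prepends `C` and appends `F` only when
missing; the interior is never edited and the operation is idempotent.

**Redundancy reduction** (`two_step_reduction()`). Pairwise TCR similarity
is the mean of the CDR3α and CDR3β kernel similarities, so it lives on
[0, 1] and the 0.95 threshold is directly interpretable (a sum on [0, 2]
would make that cut meaningless). Step 1 runs the greedy Hobohm-1 scan
within each peptide in input order — the protocol does not prescribe a
within-peptide ordering, and input order keeps the result reproducible
without inventing a priority. Peptides with fewer than 30 unique TCRs
*after* this step are dropped; the minimum counts survivors, not raw
input. Step 2 rescans across peptides ordered by ascending survivor count
(ties broken lexicographically), so when near-duplicates span peptides the
rarer peptide keeps its copy.

**Partitioning and negatives.** Positives are split into five
cross-validation partitions of near-equal size by a seeded permutation.
Swapped negatives relabel binders of distant peptides (Levenshtein
distance ≥ 4 by default; the IMMREP-style mode uses ≥ 3, matching how that
benchmark states its constraint) as non-binders, drawn only within the
same partition to avoid leakage. Donors are sampled uniformly without
replacement from the pooled eligible TCRs per (peptide, partition) rather
than per positive observation — the protocol fixes only the achieved
ratio, and pooled sampling makes the fallback exact: when the pool is
smaller than five donors per positive, the entire pool is used once, which
is why the most abundant peptide in the bundled reference summary ends at
a 1:4.647 rather than 1:5 ratio. A TCR may serve as a negative for several
peptides, never twice for the same one.

## Sequence representations

The CNNs consume BLOSUM50 embeddings: residue rows are the BLOSUM50
column divided by 5, right-padded to per-feature maxima (12, 7, 8, 22, 6,
7, 23) with rows of twenty −1 values. The maxima are frozen constants of
the model contract — recomputing them per dataset would silently change
input shapes between training and prediction — and an over-length sequence
is an error, never a truncation.

The kernel baseline uses BLOSUM62. The k-mer kernel sums, over k-mer
lengths `kmin = 1` to `kmax = 30` and every k-mer pair, the product of
per-position base similarities; k-mers longer than a sequence contribute
nothing, so `kmax` is effectively `min(30, length)`. The citation chain
behind the kernel does not print the base similarity, so the package fixes
a documented convention: `b(x,y) = 2^(0.1139 · BLOSUM62(x,y))`, normalised
per pair as `b(x,y)/sqrt(b(x,x) b(y,y))` — strictly positive and
multiplicative, which a product kernel requires — with the whole kernel
normalised as `K(a,b)/sqrt(K(a,a) K(b,b))` so self-similarity is exactly 1.
The base matrix is a replaceable argument of `kernel_params()`; every test
of this module checks self-consistency and agreement with a brute-force
enumeration oracle, not absolute values, so an alternative transform can
be swapped without invalidating the contract. A related open reading —
whether "mean kernel similarity over k-mers of size 1–30" averages per-k
similarities instead of summing raw kernels before normalisation — is
covered by the same hook; the package documents and uses the summed form.

The database aggregation of the nearest-binder score is the maximum over
positives (exposed as `max`/`mean`): the ensemble uses "similarity to known
binders" as a per-TCR penalty, and the maximum is the only aggregation
under which a TCR identical to a known binder is guaranteed a score of 1.

## CNN architectures and training

Three variants share one convolutional pattern: per input feature, 1-D
convolutions of sizes 1, 3, 5, 7, 9; global max pooling per filter with
the activation applied to the pooled value; concatenation; dropout; and a
sigmoid dense head ending in a single sigmoid output unit.

| variant | features | filters | pooling act. | dropout | dense |
|---|---|---|---|---|---|
| `pan21` | 7 | 16 | sigmoid | 0 | 32 |
| `pan22` | 7 | 16 | ReLU | 0.6 | 64 |
| `pep22` | 6 (no peptide) | 16 | ReLU | 0.6 | 64 |
| `pretrained` | 7 + 6 | 32 + 16 | ReLU | 0.6 per block | 64 + 64 → 32 |

The two-block model concatenates the two 64-unit block outputs (width 128)
before the shared 32-unit layer; the source description says only that
both blocks connect to the second dense layer, and concatenation is the
minimal-assumption junction that preserves both signals. Convolutions use
same-padding along the length axis — with feature maxima as small as 6,
valid padding would forbid width-9 kernels — and the padding value is the
encoding's −1 pad vector, so windows beyond a sequence see exactly what
genuine padding rows contain and appending padding never changes the
pooled output (a tested invariant).

Because no deep-learning framework is a dependency, the forward and
backward passes, Adam, dropout and early stopping are implemented directly
on base-R matrix operations; gradients are verified against central finite
differences in the test suite, and weights use Glorot-uniform
initialisation under a recorded seed.

Training follows nested 5×4 cross-validation: per outer test partition,
four models (three training partitions, one validation), test scores
averaged over the four. Defaults: Adam at learning rate 0.001, weighted
binary cross-entropy, batch 64 (peptide-specific batches grow from 64
until the final batch holds ≥ 32 observations; smaller datasets train as a
single batch), early stopping on validation AUC 0.1 with patience 100
(pan, pre-training rounds) or 200 (peptide-specific), and pan-mode sample
weights `log2(N_total/N_peptide)/c` with `c = 3.8`. `N_peptide` counts all
observations labelled with the peptide in the training split — negatives
carry a peptide label and enter the same loss, and the weighting exists to
balance peptides, not classes. The non-pretrained epoch cap defaults to
1000 (patience governs in practice); pre-training rounds cap at 200.
Every stochastic step (partitioning, sampling, initialisation, shuffling,
dropout) draws from seeds derived from one master seed, so runs reproduce
exactly.

The two-block model trains in two rounds: pan-specific with the peptide
block frozen, then per peptide with the pan block frozen; the shared head
stays trainable throughout. Low-data fine-tuning
(`finetune_pan_block()`) starts from a round-1 model whose training data
excluded the new peptide, removes base swapped negatives donated by the
new peptide's TCRs, trains the pan block for exactly 30 epochs with
weights 1 (new peptide) and 0.1 (rest), then runs the peptide round with
batch 32 and the combined stopping metric `AUC0.1 − 0.1·loss`, which
balances ranking quality against calibration when validation sets are
tiny.

## Denoising

Validation scores from the peptide-specific cross-validation give each
record four scores from models that never trained on its partition. A
positive is flagged when it scores below the n-th percentile of the
negatives' scores — same peptide, same model — under **all four** models;
a negative symmetrically against the (100−n)-th percentile of the
positives. Two conventions are fixed and pinned by oracle tests:
percentiles interpolate linearly between order statistics
(`stats::quantile` type 7), and the reference scores are those of the same
model (test fold × validation partition), not pooled across partitions —
the same scope for both rules. The "(1−n)th percentile" phrasing of the
negative rule is read as (100−n) on the 0–100 scale, by symmetry.

## Evaluation conventions

AUC uses the midrank convention. AUC 0.1 is the area under the
piecewise-linear ROC restricted to FPR ≤ 0.1, McClish-standardised so
chance is 0.5 and perfection 1.0: reported partial-AUC working points such
as usability cuts at 0.65 only make sense on a chance-0.5 scale, which the
raw area (chance 0.05) cannot produce. The raw area remains available via
`standardized = FALSE`. Aggregates are the unweighted mean over peptides
and the mean weighted by positive counts. Bootstrap comparison resamples
records with replacement 10,000 times, with one shared index stream for
both models, and reports the fraction of resamples where the first model
is strictly better — a one-sided quantity, with no two-sided correction
added because none is defined for it. Percentile ranks count controls
strictly above the query score, so ties lower (improve) the rank. The rank
test counts a TCR as correctly identified only when the true pairing is
the unique best score; its excluded-peptide list is a caller-supplied
argument, not a hard-coded rule.

## The synthetic generator

`simulate_repertoire()` emulates what the models need from real
repertoires: per-peptide CDR3β sequence motifs (5 residues at a fixed
offset, wildcards allowed) over i.i.d. uniform background residues,
peptides pairwise Levenshtein ≥ 4, configurable label noise (positives
secretly built from another peptide's motif) and near-duplicates
(identical CDR3 loops, one substitution in a CDR1/2 loop, placing each
duplicate at summed CDR3 similarity 1 — a single CDR3 substitution lands
just *below* the 0.95 threshold at typical lengths, so duplication leaves
the CDR3s intact by design). The uniform background is the simplest null
the kernel cannot accidentally exploit; an option plants paired α/β motifs.

What the generator does **not** emulate: real V/J-gene usage and CDR3
length distributions, shared public clonotypes across peptides, assay
noise structure, or the extreme per-peptide imbalance of curated data.
Passing benchmarks on this data therefore demonstrates that the pipeline
machinery is correct and that the models can extract a planted sequence
signal — not that real-data accuracies transfer.

## Desk-scale benchmark sizes

The bundled benchmarks and the reproduction script run at sizes chosen to
keep a full run in minutes on one CPU while leaving the learning problems
non-trivial: a separable 2-peptide benchmark with 60 binders per peptide
(100 at the `desk` scale of `make_benchmark_suite()`), swapped negatives
at the default ratio (which saturates at 1:1 for two peptides), epoch caps
of 30–60 with patience 10–20 in place of the full patience-200 protocol,
a 3-peptide leave-most-out sweep over 5–100 subsampled positives
(interpreted as totals across partitions), and a denoising run with 10%
planted flips on 100 binders per peptide. On the separable benchmark the
peptide-specific CNN reaches AUC ≈ 0.99 and the kernel baseline ≈ 0.9.
The α = 10 ensemble does not reduce partial AUC while the CNN has headroom
left; once the CNN is trained to near-saturation on this easy signal the
rescaling can cost a little partial AUC instead — its benefit is a
low-FPR correction for imperfect models, not a free improvement. The
low-data sweep
saturates near AUC 1.0 from roughly five positives upward because the
planted motif is far cleaner than real data. Denoising recovery sits near
the 50% recall mark with essentially no clean records flagged — the
all-four-models quantifier is deliberately conservative.

## Known limitations

* The base similarity inside the k-mer kernel is a documented convention,
  not a published constant; absolute kernel values are therefore not
  comparable across implementations, though rankings are robust.
* The hand-rolled CNN stack is single-threaded BLAS code: adequate for
  desk-scale repertoires (thousands of records), not for hundred-thousand
  record training runs.
* Percentile-rank calibration needs a sizeable negative-control set per
  peptide; with few controls the rank is a coarse step function.
* The pan-specific weighting constant `c = 3.8` was calibrated for a
  ~26-peptide, strongly imbalanced dataset; for panels with very few
  peptides the weights collapse towards zero and peptide-specific
  training is the better tool (the package warns in the degenerate case).
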