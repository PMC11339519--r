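---
title: "Training ontology-grounded concept embeddings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training ontology-grounded concept embeddings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures implemented by
`ontolord`, the assumptions behind them, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open. Nothing here reports an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The pipeline

The package trains a text encoder in three phases, followed by an optional
cross-lingual phase. Throughout, an *encoder* is anything that maps a
character vector to unit-norm embedding rows; similarity is always the
cosine (equivalently, the dot product of normalized vectors) — one
similarity for training and for every evaluation.

### Phase 1 — contrastive learning on (name, positive) pairs

The training corpus pairs each concept name with each of the concept's
positives: human definitions, generated definitions read from an
AGCT-style table (treated identically — both are textual knowledge about
the concept), and short template verbalizations of knowledge-graph
relations ("x is a concept that may treat y"). A batch holds `B` pairs
with pairwise-**distinct** concepts; the sampler enforces this so that no
in-batch negative is secretly a positive (a false negative). The
symmetrized InfoNCE loss over the `B x B` cosine matrix is minimized by
plain SGD.

Assumptions: concept identity is the unit of supervision (any name of a
concept may be attracted to any of its positives), and a batch of distinct
concepts provides unbiased negatives. The loss needs `B >= 2`; a
single-pair batch is degenerate (softmax over one logit, loss exactly 0).

An optional *STS adaptation* brackets the contrastive epochs: full-batch
gradient steps on `(cosine(e(s1), e(s2)) - gold/5)^2` over a user-supplied
STS file. The two sub-phases run strictly in sequence (adaptation,
contrastive epochs, adaptation); no batch-level interleaving is done.

**Temperature.** The default is `tau = 0.2`, deliberately larger than the
0.05 customary for deep contrastive encoders. The InfoNCE gradient fades
once the positive logit leads the negatives by a few multiples of `tau`,
so the achieved name–definition alignment scales with it. With the shallow
reference encoder, `tau = 0.05` saturates with same-concept cosines around
0.75, which is enough to separate concepts but leaves the name and
definition embeddings of one concept far apart — and the self-distillation
phase regresses onto their *average*, so loose alignment there poisons the
targets. `tau = 0.2` drives same-concept alignment to ~0.95 on the default
fixture. The parameter is exposed and fixed (not learned).

### Phase 2 — self-distillation

The contrastive model ("teacher") embeds, per concept, its preferred name
and one definition (generated first, else human — the generated
definitions were written to be self-contained descriptions, which is what
the embedding should summarize); the elementwise average is the concept's
full-dimension embedding. PCA (centered, unscaled; `stats::prcomp`)
reduces these to `d` dimensions. A **fresh** base encoder (the "student",
same initialization as the teacher's starting point, never contrastively
trained) plus a linear projection head are trained jointly with MSE so
that every textual variant of a concept — each name *and* each definition
— predicts the same `d`-dimensional target. After training the head is
discarded: the product is the student's own full-dimension embedding.

Three numerical choices matter here, all of which were settled by
implementation experience with the shallow student:

* **Unit-norm targets.** Projected targets are rescaled to unit norm by
  default (`make_distillation_targets(normalize = TRUE)`). The student
  emits unit vectors and the head is near-isometric (below), so unit
  targets make a zero-residual fit attainable. With raw targets the
  student must leave part of its unit norm in the head's null space, and
  that unconstrained component contaminates the student's pairwise
  geometry. The option can be disabled for a raw-MSE fit.
* **Isometric head initialization.** `new_projection_head()` draws a
  random *partial isometry* (QR of a seeded Gaussian): an
  angle-preserving map. A head that preserves angles transfers the target
  geometry into the student's embedding space instead of absorbing it.
* **Slow head.** The head trains at `learning_rate / 100` by default. A
  head trained at the full rate drifts away from isometry early (its
  singular values spread far from 1) and then warps every angle the
  student learns. The head remains trainable — a frozen head is the
  `head_learning_rate = 0` special case.

The PCA sign convention (largest-magnitude coordinate of each component
made positive) makes transforms reproducible across runs; ties in
`which.max` cannot occur for continuous data.

**Why distillation at all?** Contrastive training reorganizes the encoder
aggressively: it helps concept linking but distorts graded, general-domain
similarity (the anisotropy problem). Regressing a fresh model onto fixed
low-dimensional targets is a gentler acquisition route: the acceptance
suite checks, over five head seeds, that the student's general-STS loss is
on average strictly smaller than the contrastive model's, while the
student still reproduces the teacher's concept geometry (pairwise-name
similarity Spearman at or above 0.9). The margin of the directional check
is modest at desk scale — the two drops are of the same order — which
mirrors its nature: a preference between two training routes to the same
knowledge, not a night-and-day contrast.

### Phase 3 — uniform soup

Students differ only through their head seeds; `soup_average()` takes the
uniform elementwise mean of their named parameter arrays (shape- and
architecture-checked; arrays under a `head.` prefix are excluded — heads
are seed-specific and already discarded). Uniform averaging only; no
greedy member selection. Normalization-statistics arrays of pluggable
encoders, if present, are averaged like any other parameter.

A desk-scale caveat the tests document: with a one-layer student, each
head seed realizes the target geometry in a differently rotated subspace,
so souping preserves linking behavior but can blunt the students' STS
gains. Deep students with strongly anchored features are expected to soup
more gracefully; the phase is kept faithful to its definition rather than
tuned around this.

### Cross-lingual distillation

`mine_parallel_pairs()` scores every source/target name combination with a
pluggable encoder and keeps mutual-best matches above a cosine threshold
(default 0.8), each side used at most once, ties to the first index.
`train_crosslingual_distillation()` then minimizes
`MSE(student(s) - teacher(s)) + MSE(student(t) - teacher(s))` with the
teacher frozen — the student learns to give a text and its translation the
teacher's embedding of the source text. The multilingual student uses a
larger hash space (default 8192) to host two alphabets, and a small weight
initialization (`init_sd = 0.01`): unlike the base encoder, whose random
init *is* its useful surface-similarity prior, this student's init is
noise to be overwritten, and a large init dominates the embedding of any
n-gram the parallel corpus did not cover (e.g. inside perturbed mentions).

## The reference encoder

`make_reference_encoder()` hashes character n-grams (orders 2–4 by
default, with per-order boundary padding so every non-empty text has
features) into `H` count buckets via an exact-in-doubles polynomial
rolling hash, applies a trainable linear map to `D` dimensions, and
L2-normalizes. Gradients flow through the normalization
(`g_z = (g_e - (g_e . e) e) / |z|`); zero-norm pre-activations are left at
zero rather than divided. It is not a language model: it has no word
order beyond n-gram width, no syntax, no pretrained knowledge. It is the
smallest trainable encoder on which all four phases, their failure modes
(false negatives, anisotropy, geometry loss, cross-lingual drift) and
their evaluations are faithfully exercisable on one CPU. Pretrained
transformers slot in behind `make_callable_encoder()` but are never
required.

Defaults used by the pipeline and the acceptance runs: `D = 96`,
`H = 4096` (`8192` for the multilingual student), `d = 48`, batch size 32,
`tau = 0.2`, 40 contrastive epochs of SGD at rate 0.2, 1600 full-batch
distillation steps at rate 2 with momentum 0.95, 400 cross-lingual steps
with the same optimizer. Capacity was set to the smallest round values at
which retrieval on the default fixture is not feature-collision-limited;
the hash space trades memory for collision rate, and collisions are also
the mechanism by which training one vocabulary disturbs another (the
desk-scale analogue of shared-parameter interference in a transformer).

## The synthetic study conditions

`generate_synthetic_ontology()` builds 5 topics x 10 concepts x 3 names by
default. The preferred name of a concept is a two-token core that also
appears in its definitions; the other names are **alias synonyms** —
concept-specific token pairs sharing no surface material with the core,
lightly perturbed at `noise_rate = 0.08` per character (swap / delete /
duplicate). This mirrors real synonymy ("myocardial infarction" vs "heart
attack"): the dictionary lists the canonical name, informal mentions
derive from aliases, and nothing ties them together except the ontology.
Consequently an untrained or random encoder links mentions at chance, and
any linking success must be learned through the shared definitions — the
chance-level and oracle bounds in the test suite pin both ends of the
scale (a latent-structure oracle encoder attains NEL 1.0 and STS Pearson
at or above 0.95; a random-embedding baseline stays within 0.05 of
chance).

Benchmarks derive from the same latent structure: gold similarity is 5 for
same-concept pairs, 2.5 for same-topic, 0 otherwise, plus uniform jitter
of half-width 0.5 clipped to [0, 5] — so even a perfect model cannot reach
r = 1, and thresholds account for that. The STS sentence pool is half
**general-domain**: sentences about topics and concepts that never occur
in the training graph, emulating the general-purpose half of a clinical
STS suite. This is what makes "contrastive training hurts the general
task" measurable: training reshapes hash buckets that general sentences
also use. The parallel corpus pairs every name and definition with its
deterministic cipher translation (a seeded letter bijection, space fixed);
the held-out split is drawn from definition pairs, whose tokens recur
across training pairs, so held-out performance measures compositional
generalization — held-out *alias* pairs would be unanswerable in
principle, since aliases share no n-grams with anything.

What the generator does **not** emulate: real clinical language (word
frequencies, abbreviations, negation), hierarchical relation semantics,
ambiguous mentions (every mention has exactly one gold concept),
morphology-bearing translation (ciphers preserve n-gram structure
exactly), and annotator disagreement beyond uniform jitter. Passing these
tests therefore demonstrates that the algorithms do what they claim on
data with the assumed structure — not that any particular score would be
attained on clinical corpora.

## Degenerate inputs and tie-breaking

Empty texts are input errors naming the offending index; empty corpora
and empty mining results are legal; a zero-epoch phase is an exact no-op.
Correlations with a zero-variance series raise an undefined-correlation
error rather than returning NA. NEL scores a multi-name concept at its
best name and breaks score ties by dictionary row order; Spearman ties
get average ranks (`stats::cor`). Batch sampling requires at least `B`
distinct concepts and fails loudly otherwise. All randomness (generator,
sampler, initializations) flows through named seeds; every training
function restores the caller's RNG state, and `run_pipeline()` records
its seeds in the manifest, so reruns reproduce checkpoints
bit-identically.

## Problem sizes

The default test and acceptance runs use the 50-concept fixture (150
names, 100 mentions, 150 STS pairs, 250 parallel pairs per language),
five distillation seeds for the forgetting comparison, three for the
soup, and a 12-concept fixture for the two full pipeline reruns of the
determinism check. These sizes keep every phase's behavior measurably
above its chance floor and below its oracle ceiling while a complete
suite run stays in the minutes range on a single CPU core; all of them
scale up through `synth_config()` without code changes.

## Known limitations

* The reference encoder's capacity bounds what the phases can show;
  results quantify algorithmic behavior, not state-of-the-art quality.
* The soup rotation caveat above.
* PCA is fit in memory on all concepts (`fit_pca` errors when `d` exceeds
  the bank size); real-scale users should subsample the bank before
  fitting.
* The STS adaptation uses plain cosine regression to gold/5; no
  calibration layer is learned, matching correlation-based reporting.
* `verbalize_relation()` lower-cases names inside templates; casing that
  is semantically load-bearing (abbreviations) is preserved everywhere
  else but not in relation verbalizations.
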