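---
title: "Normalizing entity mentions to ontology concepts by projecting word embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing entity mentions to ontology concepts by projecting word embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontonorm)
```

## The problem

Entity normalization (entity linking) maps a textual mention — "soil
samples", "human gut flora" — to an identifier in a reference vocabulary,
here an ontology of concepts connected by is-a relations, such as an
ontology of microorganism habitats. Treated as classification, the task is
hostile to standard supervised learning: thousands of classes, a handful of
annotated examples per class, and many classes with no examples at all.

`ontonorm` implements a projection-based approach. Two vector spaces are
built independently:

* the **term space** (semantic space of the corpus): distributional word
  embeddings, composed into one vector per (possibly multiword) mention;
* the **concept space** (semantic space of the ontology): one vector per
  concept, derived from its position in the is-a hierarchy.

A linear map from the term space into the concept space is then learned
from (term, concept) pairs, with the objective of making each projected
term point in the direction of its concept's vector. Prediction is cosine
nearest neighbour in the concept space. Because every concept has a vector
whether or not it has training examples, the method can predict classes it
has never seen annotated, and because concept vectors encode ancestry,
errors tend to land near the reference concept rather than anywhere in the
ontology. In the fully unsupervised setting the training pairs are simply
(concept label, concept) — associations intrinsic to the ontology.

## Concept spaces

### Decay-weighted ancestry

The base representation gives each concept a vector with one dimension per
concept of the ontology. For concept $c$ and ancestor $a$ the entry is

$$v_c[a] = w^{d(c,a)},$$

where $d(c,a)$ is the number of is-a edges on the shortest directed path
from $c$ to $a$ (0 for $c$ itself, 1 for a direct parent; with multiple
inheritance the minimum over paths, so each ancestor receives its maximal
weight), and $w \in [0,1]$ is the decay factor. Entries for non-ancestors
are 0, and $0^0 = 1$ by convention, so:

* $w = 1$ is the binary **ancestry** representation — 1 on the concept and
  every ancestor;
* $w = 0$ is the **one-hot** representation — 1 on the concept alone;
* intermediate $w$ interpolates, down-weighting distant ancestors.

The ancestry representation preserves the hierarchy (ancestor sets, and
hence the ontology structure, are reconstructible from the $w = 1$ matrix)
but gives a root shared by everything the same weight as a direct parent,
which encourages over-general predictions. The decay factor is the dial
that trades generalization against specificity; `sweep_decay()` measures
the trade-off on a grid, by default $w = 0, 0.1, \ldots, 1$.

### Graph-walk embeddings

`build_node2vec_sso()` provides low-dimensional concept vectors for
ontologies too large for the per-concept-dimension representation: biased
second-order random walks over the is-a graph treated as undirected
(return parameter `p`, in-out parameter `q`; non-is-a relations such as
`sameAs` can be included behind a flag), fed to a skip-gram objective with
negative sampling. Defaults (dimension 64, walk length 10, 20 walks per
node, $p = q = 1$, window 5) are conventional settings, not tuned claims.
A single worker and a fixed seed make the output reproducible; an isolated
concept still receives a (near-initialization) vector rather than an error.

### Dimensionality reduction

`reduce_dimensions()` offers `pca` (centered principal components), `svd`
(uncentered truncated SVD) and `mds` (classical metric scaling of
Euclidean row distances via `cmdscale`, which is deterministic, so the
seed recorded in the metadata is inert). At full rank the SVD variant is an
orthogonal change of basis and leaves all pairwise cosines — hence all
predictions and scores — unchanged; that identity is used as a correctness
check. t-SNE is refused with an explicit error: it targets 2–3 output
dimensions for visualisation and does not scale to the dimensionalities a
concept space needs.

## Term space

Word embeddings are trained by a compiled single-threaded word2vec-style
trainer (skip-gram or CBOW, negative sampling, linearly decayed learning
rate, reduced dynamic window). The `subword` mode follows the character
n-gram approach: a word's input representation is the mean of its own
vector and its hashed 3–6-gram vectors (word-boundary markers included,
hashed into 32,768 buckets), so a word never seen in training still
composes a finite vector from its n-grams. Under `skipgram`/`cbow` an
unseen word is an explicit out-of-vocabulary signal (`NULL`), never a
silent guess: the two policies delimit what the method can and cannot
predict, and the no-vector path is carried through prediction
(`status = "no_vector"`) and scoring (counts 0) rather than dropped.

Multiword mentions are composed as the unweighted mean of their available
token vectors — the mean keeps magnitudes comparable across term lengths —
with a coverage fraction reporting how many tokens had vectors. A mention
with zero coverage is excluded from training and explicitly unpredictable
at test time.

## The projection

`fit_projection()` learns $M$ (and bias $b$) such that $M x + b$ points
toward the concept row $y$ for each training pair. Two losses:

* **`least_squares`** (default): closed-form multivariate least squares of
  the concept rows on the term vectors, via an SVD pseudo-inverse
  (minimum-norm solution; singular values below $10^{-10}$ of the largest
  are treated as zero, which handles rank deficiency and fewer pairs than
  dimensions). Targets are unit-normalized by default so that the surrogate
  optimizes the direction of the fit, aligning it with the cosine
  objective. Deterministic, no tuning.
* **`cosine`**: the training objective itself — mean cosine between
  projected terms and concept rows — maximized directly. The optimizer is
  warm-started from the least-squares solution and refined with a fixed
  budget of Adam steps (300 by default), keeping the best iterate; the
  final mean cosine is recorded in the training metadata. Starting from
  the closed-form surrogate makes the procedure deterministic and
  guarantees the refinement never ends below its initialization.

The bias is included by default (it costs nothing and absorbs uncentered
embeddings). Because an affine map is not scale-equivariant, prediction
rescales every query to the mean norm of the training inputs before
projecting: rankings are then invariant to positive rescaling of the query
while the bias still acts at the magnitude it was fitted for. Cosine ties
in the ranking are broken by lexicographic concept identifier, making
predictions fully deterministic.

## Evaluation

Two metrics, both means over mentions:

* the **semantic score** uses the Wang et al. DAG similarity: concept $A$
  assigns S-values over its reflexive ancestor closure $T_A$ —
  $S_A(A) = 1$ and $S_A(t) = f \cdot \max_{t'} S_A(t')$ over children $t'$
  of $t$ inside the closure, with contribution factor $f \in (0,1)$ — and
  $\mathrm{sim}(A,B) = \sum_{t \in T_A \cap T_B} (S_A(t) + S_B(t)) \big/
  (SV(A) + SV(B))$ with $SV(A)=\sum_{t \in T_A} S_A(t)$. It is symmetric,
  lies in $(0,1]$ on a rooted DAG, and equals 1 exactly on identity, so
  near-misses in the hierarchy earn partial credit;
* the **strict score** counts only exact matches, and is therefore never
  above the semantic score.

The contribution factor defaults to 0.65 — the conventional choice for
this family of measures — and is recorded in every report so runs remain
comparable. When a mention carries several reference concepts, the top-1
prediction is scored against the best-matching reference (the most
permissive deterministic rule; the strict measure then rewards hitting any
reference). Mentions without a vector score 0 on both measures instead of
being dropped, which would silently inflate the scores.

`random_assignment_baseline()` estimates by Monte-Carlo (1,000 draws by
default) the semantic score of assigning concepts uniformly at random —
the floor any trained pipeline must clear, and a non-trivial floor, since
even random concepts share ancestors with the reference.

## The synthetic benchmark

All tests run without external data. `generate_ontology()` builds a random
is-a DAG (single root; each later concept draws 1–`max_parents` parents
among earlier concepts, so acyclicity holds by construction).
`generate_lexicon_corpus()` gives each concept a small lexicon of
pseudo-words — headed by the concept's label, so label-based unsupervised
training pairs are distributionally grounded — and writes sentences whose
tokens come from the concept's lexicon or, with probability `mixing`
(default 0.3), from a direct parent's. This plants the method's central
premise, distributional similarity mirroring ontological proximity, into
the corpus by construction. Annotated mentions (default 200, 30% held
out) use 1–2 lexicon words as surface; 10% of held-out mentions get a
token never seen in the corpus (a corpus word plus a suffix), exercising
the out-of-vocabulary path with genuine subword overlap.

The default study conditions are 50 concepts, 20-dimensional embeddings,
and 200 mentions — small enough to run everywhere in seconds, large
enough that scores separate cleanly from the random baseline.

What the generator does **not** emulate: real biomedical morphology and
typography, sense ambiguity (each pseudo-word belongs to one concept),
discontinuous mentions, and corpus scale. Passing the synthetic benchmark
shows the machinery is correct and that the method works when its premise
holds; it does not certify performance on real corpora, where the premise
holds only approximately.

`generate_planted_instance()` serves a different purpose: it plants a
known well-conditioned linear map $G$ (orthonormal rows from a QR
decomposition) from the concept space into the term space, emits
$x_c = G y_c + \varepsilon$ with a second independently-noised copy as
held-out queries, and returns $G$ for recovery checks. The recovery
experiment uses the one-hot concept space: its rows are mutually
orthogonal, so exact zero-noise recovery is a theorem rather than a
coincidence of geometry, and any failure indicates a defect in the fit.
(Against strongly correlated ancestry rows, rank-limited regression
provably cannot reproduce the targets exactly, and near-collinear rows tie
under cosine; correlated targets are exercised by the end-to-end
benchmark instead.)

## Numerical choices and degenerate inputs

* concept order, and hence vector dimension order, is lexicographic by
  identifier, fixed at ontology construction — matrices are reproducible
  across runs;
* $0^0 = 1$ in the decay construction, forced by the one-hot limit;
* pseudo-inverse cutoff $10^{-10}$ relative to the largest singular value;
* all-zero term vectors are rejected from training with a warning count,
  and produce `no_vector` predictions at test time;
* cosine ties in rankings break lexicographically; equal-similarity
  concepts are therefore ordered but a tie at similarity 1 between
  distinct concepts (possible only in a reduced space) resolves to the
  smaller identifier;
* every stochastic component (generators, embedding trainer, walks) is a
  pure function of its seed, single-threaded, and reproduces bitwise.

## Limitations

* The linear projection cannot separate mentions whose term vectors
  coincide (identical token multisets) but whose references differ.
* Skip-gram/CBOW modes cannot predict for fully out-of-vocabulary
  mentions; the subword mode can, at the cost of noisier vectors for rare
  n-grams.
* The decay representation keeps one dimension per concept; for ontologies
  far beyond ~10^4 concepts use the graph-walk space or a reduced space.
* Classical MDS here reduces Euclidean row distances; it is not the
  iterative stress-minimizing variant.
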