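---
title: "Methods: graph retrieval-augmented diagnosis and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph retrieval-augmented diagnosis and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorag)
```

## The problem

Many rare genetic syndromes present with recognizable facial phenotypes —
a wide nasal bridge, proptosis, posteriorly rotated ears — that clinicians
use as diagnostic clues. Large language models answer such diagnostic
questions unreliably: they hallucinate associations and their answers
drift across repeated queries and decoding temperatures. Retrieval-
augmented generation (RAG) over a curated knowledge graph addresses both
failure modes by injecting verifiable phenotype–gene–disease facts into
the prompt.

`phenorag` implements that pipeline end to end: a typed property graph of
facial phenotypes, genotypes, variations, diseases, patients and articles;
two retrievers over it; a graph-embedding selection harness; builders for
diagnostic benchmarks; and an evaluation suite for accuracy, consistency,
keypoint coverage and temperature sensitivity. A seeded synthetic-data
generator and a seeded mock language model make every experiment runnable
offline and bit-reproducible.

## The graph model

Persisted graphs contain six node kinds (`Article`, `Disease`,
`Genotype`, `Variation`, `FacePhenotype`, `Sample`) and seven relation
kinds, constrained by a schema policy of allowed
(source kind, relation, target kind) triples:

| relation | triple |
|---|---|
| Affect | Genotype → FacePhenotype |
| Cause | Variation → Disease |
| Exist | Sample → Article |
| Has_Phenotype | Disease → FacePhenotype |
| Have | Variation → Genotype |
| Mention_FP | Sample → FacePhenotype |
| Mention_Var | Sample → Variation |

Two schema readings were genuinely open. First, the reference statistics
describe `Mention_Var` with the same wording as `Cause`
(variation–disease), yet its count (1239) tracks the Variation node count
(1242) rather than anything disease-shaped, and the variation–disease
association is already carried by `Cause`; we therefore fix `Mention_Var`
as Sample → Variation and keep the policy configurable through
`schema_policy()`. Second, diagram-style exports of such graphs sometimes
label relations `From`, `Exhibit`, `with_FP`, `with_Var`; an alias map
accepts those spellings on input and normalizes them to the table above.

Graphs are directed as in the schema, but retrieval treats edges as
traversable in both directions, since a clue is as informative read
forward as backward. A seventh node kind, `Query`, is transient: it can
exist only inside a retrieval operation and is rejected by the
constructor for persisted graphs.

## The two retrievers

**Cypher route.** A language model is prompted with a schema description
and asked to translate the question into a pattern query.
`query_graph()` executes a deliberate minimal subset of the Cypher
language — `MATCH` with one or two relationship hops, label and
property-equality constraints, `WHERE` with `=`/`CONTAINS`, `RETURN` of
node properties, `LIMIT` — and is verified against an exhaustive
pattern-enumeration oracle in the test suite. Data-modifying clauses in
model output are stripped and flagged; output without a parseable query
raises a typed error, and the configured fallback (`empty_context` by
default, `vector` as the recommended production mode) decides what the
pipeline does next. The empty-context default deliberately reproduces the
degradation observed when a model cannot write valid Cypher: retrieval
returns nothing and the model falls back to its unaided prior.

**Vector route.** The question is linked to graph nodes by a greedy
longest-match lexicon matcher over canonical names and synonyms
(case-insensitive, whitespace-collapsed, non-overlapping spans), with a
fuzzy pass (normalized edit similarity, threshold 0.85) for
identifier-like tokens; a plugin recognizer can replace the matcher where
a trained entity-recognition model is available. The matched query is
inserted as a transient `Query` node wired to its matches, the augmented
graph is embedded, and the `k` nodes most cosine-similar to the query
node — plus their neighbors within `expansion_depth` undirected hops —
form the context subgraph, which is serialized one edge per line as
`[source] -(relation)-> [target]` in a fixed lexicographic order.

Two retrieval parameters are stated nowhere in the source material and
are therefore package defaults: `k = 5` and `expansion_depth = 1`
("their neighbors" read as one hop); both are configurable. The ordering
question — rank first, then expand — follows the retriever's description.
Context is unlimited by default, with an optional character budget that
drops whole trailing triplet lines.

A property of the Laplacian-reconstruction embedding worth knowing:
because the outer product of the embedding approximates `L = D − A`,
*adjacent* nodes have negative inner products, while nodes with similar
neighborhoods (a disease and a query listing that disease's phenotypes)
land close together. The retriever therefore surfaces the disease whose
phenotype profile matches the question directly in the top-k, and the
matched entities themselves enter through the one-hop expansion. The test
suite checks the ranking against a brute-force cosine oracle rather than
against intuitions about which node "should" rank first.

## The embedding family and the selection harness

Seven algorithms sit behind `embed_graph()`:

* **GLEE** — eigenvectors of the combinatorial Laplacian taken from the
  large end of the spectrum, scaled by the square root of their
  eigenvalues so `S Sᵀ ≈ L` (exact at full dimension; reconstruction
  error is non-increasing in `d`).
* **SocioDim** — leading eigenvectors of the modularity matrix
  `B = A − d dᵀ / 2m`.
* **NetMF** — truncated SVD of the log-clipped shifted PMI matrix implied
  by length-`window` random walks.
* **RandNE** — iterated seeded orthogonal random projection through
  powers of the adjacency operator with geometric weights.
* **DeepWalk / Node2Vec / Walklets** — skip-gram with negative sampling
  trained on seeded uniform, (p, q)-biased, or skip-subsampled walks; the
  trainer is a single-threaded C++ routine with its own deterministic
  PRNG, so runs are bit-reproducible (a faster non-deterministic mode is
  deliberately not provided).

No hyperparameters were published for the embedding comparison, so the
defaults are the community-standard ones: `d = 128`, 10 walks of length
80, window 5, 5 negative samples for walk methods; `d = 32` for spectral
methods; Node2Vec `p = q = 1`; Walklets scales 1–4 with the dimension
split evenly. Disconnected graphs are embedded whole (the eigensolver
handles multiplicity) with a message reporting the component count.

`node_classification_eval()` reruns the embedding-selection experiment:
embed the full graph, split nodes stratified by kind (test fraction 0.2),
train a classifier (random-forest by default, pluggable) to predict the
node kind, and report micro/macro/weighted F1. The published F1 table is
treated as an external reference point, not a test target, because the
split ratio, dimension and classifier settings behind it are unknown.

## The mock language model

`mock_model_spec()` defines a model rich enough to reproduce the
qualitative RAG phenomena offline:

* **Context path** — candidate diseases are read out of the context block
  (vocabulary matches plus entities in a disease position of a triplet);
  each is scored by its *evidence lines*, triplets linking it to an
  entity that itself appears in the question, with raw mention counts
  breaking ties. The best-supported candidate is answered with
  probability `context_fidelity`.
* **Unaided path** — with probability `base_accuracy` the model consults
  its "pretrained knowledge" (a disease → phenotype map, typically
  extracted from the graph) by nearest-neighbor phenotype overlap, ties
  random; otherwise it guesses a distractor. Overlapping diseases
  therefore degrade unaided accuracy, which is how the benchmark's
  ambiguity dial reaches the model.
* **Temperature** — the answer flips to a random distractor with
  probability `perturbation_rate(T)` (linear, `0.3·T`, by default;
  `perturbation_rate(0) = 0` always).

One modelling decision deserves emphasis. A flip applied uniformly to
every answer would make the standard deviation of accuracy across a
temperature grid *scale with the accuracy level*, so the augmented
model — being more accurate — would show more temperature variability
than the unaided one, inverting the phenomenon the harness exists to
study. Retrieval anchors decoding: when the answer is read off retrieved
context, sampling temperature has little room to act. The mock therefore
exempts context-taken answers from the flip while `context_anchor = TRUE`
(the default); setting it to `FALSE` restores the uniform flip.

All randomness derives from the per-call seed, and at `T = 0` a
completion is a pure function of the prompt — the property underlying
every reproducibility test in the suite.

## Benchmarks and grading

`render_stem()` fills the fixed case template ("There is a
{age}-year-old {gender} {ethnicity} patient with a mutation in {gene},
namely, {variant} and with facial phenotypes of {…}. What disease might
this patient have?"), ages always printed with one decimal. Selective
questions draw three distinct distractors without replacement from the
configured pool (excluding the truth) and a seeded shuffle assigns labels
A–D; option order is fixed per question, not per repeat. Non-selective
questions are the bare stem.

Grading normalizes responses (case-fold, strip punctuation, collapse
whitespace). Selective answers may arrive as a bare label, the option
text, a disease name, or a registered short-form alias (the
parenthesized abbreviation in an option string); naming two different
option diseases is ambiguous and graded `INVALID`. `INVALID` counts as
wrong for accuracy, as a distinct value for consistency, and an entirely
invalid (model, method) cell is reported missing — zero-scoring of
partially invalid cells is the default, matching how an uncooperative
model's near-zero rows are averaged.

The aggregate metrics mirror the published tables: accuracy is the mean
over five repeated queries (percent, 2 decimals); consistency is the
modal-answer share among the five; coverage is the fraction of reference
keypoints present in the response; the temperature profile is the sample
standard deviation (n − 1; population estimator opt-in, since the
published choice is unstated) of accuracy over the grid
`T = 0, 0.2, …, 1.0` with single queries per point; and the RAG sigma
reduction averages `1 − sigma_RAG / sigma_vanilla` over the two
retrievers. Averages are computed on 2-decimal-rounded columns and deltas
on the rounded averages — the printed-arithmetic convention, which the
acceptance suite reproduces figure by figure. Per-row published
reductions were evidently computed from unrounded sigmas, so recomputing
them from printed sigmas agrees only to print-rounding slack; the mean of
the printed reductions is the exactly reproducible quantity.

## The synthetic world

`generate_kg()` emulates the curated graph's composition; its default
node counts are the reference ones (509 articles, 225 diseases, 397
genotypes, 1242 variations, 2623 facial phenotypes, 1147 samples).
Disease–phenotype assignment uses a *confuser-pair* design: diseases are
paired and each pair shares exactly `phenotype_overlap` of its phenotype
set, with the remainder disjoint within the pair — a deliberate
reproduction of clinically overlapping syndromes, rather than uniform
random sharing which dilutes ambiguity. Variations link to a genotype
and a disease; genotypes affect the phenotypes of the diseases their
variations cause; samples mention phenotypes and variations and exist in
articles. Every generated graph passes schema validation by
construction, and with zero overlap and zero noise a nearest-neighbor
diagnosis by phenotype-set overlap is perfect, giving the evaluation
harness a benchmark whose ceiling is known.

Case records sample a disease with a causal variant, that variant's
genotype, a phenotype subset of configurable size
(`case_phenotype_subset`), Poisson-distributed spurious phenotypes
(`noise_rate`), and demographics from small fixed vocabularies. Names
are synthetic (`DIS-0042`, `PHEN-0001`) — the generator emulates the
*statistical structure* of curated data, not its vocabulary, real HPO
synonymy, literature provenance, or variant nomenclature beyond a
plausible coding-change pattern. Passing tests on this world demonstrate
that the pipeline's machinery behaves as specified, not that any
particular language model diagnoses real patients well.

## Experiment sizes and numerical choices

The end-to-end suites run a 200-question selective benchmark over a
~140-node world (20 diseases at overlap 0.5, full phenotype reporting),
five repeats at `T = 0.1` for diagnosis/consistency and one query per
grid point for the temperature sweep — sizes chosen so that the binomial
significance checks have real power while a complete run stays
desk-scale. Retrieval contexts are computed once per (model, method,
question) and reused across repeats and temperatures, which is exact
because retrieval is deterministic.

Other numerical choices: cosine similarity is computed on raw vectors
with zero-norm vectors scoring 0 (never an error); ranking ties break by
ascending node id; serialized contexts order lines lexicographically;
table output sorts rows in the C locale so repeated writes are
byte-identical; seeds for sub-processes are derived from the master seed
and a path of string labels through a 31-bit polynomial hash, keeping
every derived seed a valid R integer.

## Known limitations

* The Cypher interpreter is a minimal subset by design; no `OPTIONAL
  MATCH`, aggregation, or multi-pattern queries. An adapter to a live
  graph database can replace it, but nothing in the package requires one.
* The semantic-similarity metric defaults to lexical token-F1; a
  transformer-based scorer is a plugin port, never bundled.
* The entity linker is a lexicon matcher; it inherits the graph's name
  and synonym coverage and will miss paraphrases a trained recognizer
  would catch.
* The mock model is a simulation device for harness validation, not a
  model of any specific commercial system; published per-model accuracy
  figures depend on proprietary APIs and human grading and are outside
  what this package can or tries to reproduce.
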