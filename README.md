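# phenorag

Knowledge-graph retrieval-augmented generation (RAG) for
phenotype-driven rare-disease diagnosis, with a fully offline evaluation
harness.

Many rare genetic syndromes have recognizable facial phenotypes — a wide
nasal bridge, proptosis, posteriorly rotated ears — that clinicians use
as diagnostic clues. Language models answer diagnostic questions about
such syndromes unreliably: they hallucinate phenotype–gene–disease
associations and their answers drift across repeated queries and
decoding temperatures. Grounding the model in a curated knowledge graph
mitigates both problems. `phenorag` is for researchers who want to build
that pipeline, measure those effects, and audit every step: it provides
the typed graph, both retrieval routes, the embedding selection harness,
the diagnostic benchmark builders, and the evaluation statistics, plus a
seeded synthetic world and mock language model so the whole study runs
without any external service.

## What is inside

* **Typed property graph** (`knowledge_graph`, `load_graph`,
  `write_graph`, `validate_schema`, `graph_stats`, `export_cypher`):
  six node kinds (Article, Disease, Genotype, Variation, FacePhenotype,
  Sample) and seven relation kinds under a configurable schema policy,
  persisted as TSV, exportable as Cypher `CREATE` statements.
* **Seven graph embeddings behind one interface** (`embed_graph`):
  spectral Laplacian (GLEE: `S Sᵀ ≈ L = D − A`), modularity eigenvectors
  (SocioDim), shifted-PMI factorization (NetMF), iterated random
  projection (RandNE), and skip-gram over seeded random walks (DeepWalk,
  Node2Vec, Walklets; single-threaded C++ trainer, bit-reproducible).
  `node_classification_eval` reruns the embedding-selection experiment:
  predict the node kind from the embedding, report micro/macro/weighted
  F1.
* **Two retrievers** (`cypher_retrieve`, `vector_retrieve`): an
  LLM-generated Cypher query executed by a verified minimal interpreter
  (`query_graph`), and an embedding retriever that links question
  entities (`link_entities`), inserts the query as a transient node,
  ranks by cosine similarity (top *k* = 5), and expands one hop. Contexts
  serialize as `[entity] -(relation)-> [entity]` triplet lines.
* **Benchmark builders** (`render_stem`, `build_question`,
  `build_qa_items`): selective (4 options, 3 seeded distractors) and
  non-selective diagnostic questions from case records; domain-QA items
  with graph-derived reference keypoints; JSON-lines round trips.
* **Evaluation** (`extract_and_grade`, `accuracy`, `consistency`,
  `coverage`, `semantic_score`, `temperature_sigma`,
  `rag_sigma_reduction`, `summarize_records`): accuracy averaged over
  five repeats; consistency = modal-answer share of five responses
  (3 of 5 identical → 60%); coverage = fraction of reference keypoints
  mentioned (4 of 23 → 17.39%); sample-SD of accuracy over the
  temperature grid `T = 0, 0.2, …, 1.0` and the average sigma reduction
  achieved by the two RAG routes.
* **Synthetic world + mock model** (`generate_kg`, `generate_cases`,
  `mock_model`): schema-valid graphs with a confuser-pair phenotype
  overlap dial, case records with controllable reporting and noise, and
  a seeded mock LLM with context-grounded answering, imperfect
  pretrained knowledge and temperature perturbation.

## Worked example

Build a small synthetic world, retrieve context for a case, and compare
an unaided mock model against its vector-RAG counterpart:

```r
library(phenorag)

cfg <- synth_config(
  node_counts = c(Article = 5, Disease = 20, Genotype = 12,
                  Variation = 30, FacePhenotype = 60, Sample = 15),
  phenotypes_per_disease = c(4, 6), phenotype_overlap = 0.5,
  cases_per_disease = c(2, 2), seed = 11)
kg <- generate_kg(cfg)
kg
#> <phenorag knowledge graph> 142 nodes, 371 edges

cases <- generate_cases(kg, cfg)
cat(render_stem(cases[[1]]))
#> There is a 33.5-year-old male Japanese patient with a mutation in
#> GEN-0004, namely, c. 254G > A and with facial phenotypes of PHEN-0040,
#> PHEN-0006, PHEN-0047, PHEN-0031. What disease might this patient have?

ctx <- vector_retrieve(kg, render_stem(cases[[1]]),
  retriever_config(embedding = embedding_config("GLEE", dim = 16, seed = 3)))
cat(ctx$triplet_text)
#> [DIS-0001] -(Has_Phenotype)-> [PHEN-0006]
#> [DIS-0001] -(Has_Phenotype)-> [PHEN-0031]
#> [DIS-0001] -(Has_Phenotype)-> [PHEN-0039]
#> ...

pool <- kg$nodes$name[kg$nodes$kind == "Disease"]
questions <- lapply(seq_along(cases), function(i)
  build_question(cases[[i]], "selective", pool, seed = i,
                 id = sprintf("q%03d", i)))
spec <- mock_model_spec(knowledge = mock_knowledge_from_kg(kg),
                        context_fidelity = 0.95, base_accuracy = 0.5,
                        distractor_pool = pool)
run <- run_config(kg = kg, questions = questions,
                  models = list(mock = mock_model(spec)),
                  methods = c("vanilla", "vector_rag"), R = 5, seed = 42,
                  retriever = retriever_config(
                    embedding = embedding_config("GLEE", dim = 16, seed = 3)))
out <- run_experiment(run, "consistency")
out$summary$by_cell
#>   model     method accuracy consistency
#> 1  mock    vanilla     56.5        60.0
#> 2  mock vector_rag     98.5        98.5
```

The unaided model gets 56.5% of repeated queries right and repeats its
modal answer 60% of the time; with retrieved graph context the same mock
reaches 98.5% on both — the accuracy and consistency gains the harness
exists to measure. A temperature sweep (`run_experiment(run,
"temperature")`) additionally reports the per-method sigma of accuracy
across `T = 0 … 1` and the average sigma reduction under RAG.

A thin CLI wraps the same functions for shell use:

```sh
exec/phenorag synth --out world/ --seed 1 --diseases 20 --overlap 0.5
exec/phenorag stats --nodes world/nodes.tsv --edges world/edges.tsv
exec/phenorag retrieve --nodes world/nodes.tsv --edges world/edges.tsv \
    --query "patient with PHEN-0031" --k 5
```

## Documentation

The methods vignette (`vignettes/phenorag-methods.Rmd`) documents the
graph schema and its open readings, both retrieval routes, the embedding
algorithms and their defaults, the mock model's design (including why
context-grounded answers are exempt from temperature perturbation), the
grading rules, the synthetic world's confuser-pair construction, and
known limitations.
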