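test_that("entity linking finds the case entities in the worked stem", {
  kg <- chd7_graph()
  stem <- render_stem(chd7_case())
  m <- link_entities(stem, kg)
  hit_names <- node_name_of(kg, m$node_id)
  expect_true(all(c("CHD7", "c. 2443-2 A > G", "Wide nasal bridge",
                    "Proptosis") %in% hit_names))
  expect_true(all(m$score[m$method %in% c("exact", "synonym")] == 1))
})

test_that("linking is greedy longest-match with non-overlapping spans", {
  nodes <- data.frame(id = c("p1", "p2"), kind = "FacePhenotype",
                      name = c("Wide nasal bridge", "Nasal bridge"),
                      stringsAsFactors = FALSE)
  kg <- knowledge_graph(nodes)
  m <- link_entities("patient with Wide nasal bridge", kg)
  expect_equal(m$node_id, "p1")  # only the longer span matches
  # the shorter name still matches when alone
  m2 <- link_entities("abnormal nasal bridge", kg)
  expect_equal(m2$node_id, "p2")
})

test_that("linking falls back to fuzzy matching for identifier-like tokens", {
  kg <- chd7_graph()
  m <- link_entities("patient with a CHD77 mutation", kg,
                     retriever_config(fuzzy_threshold = 0.7))
  fz <- m[m$method == "fuzzy", ]
  expect_equal(node_name_of(kg, fz$node_id), "CHD7")
  expect_true(all(fz$score >= 0.7 & fz$score < 1))
})

test_that("synonyms link to their canonical node at score 1", {
  kg <- chd7_graph()
  m <- link_entities("child with Broad nasal bridge", kg)
  expect_true("p1" %in% m$node_id)
  expect_equal(m$method[m$node_id == "p1"], "synonym")
})

test_that("empty queries produce no matches", {
  expect_equal(nrow(link_entities("", chd7_graph())), 0)
  expect_equal(nrow(link_entities("   ", chd7_graph())), 0)
})

test_that("query-node insertion is non-destructive and deduplicated", {
  kg <- chd7_graph()
  before <- graph_stats(kg)
  m <- data.frame(surface = c("chd7", "chd7", "proptosis"),
                  node_id = c("g1", "g1", "p6"), score = 1,
                  method = "exact", stringsAsFactors = FALSE)
  aug <- insert_query_node(kg, m, "some question")
  # duplicate matches to one node yield a single edge; degree = 2
  qe <- aug$graph$edges[aug$graph$edges$source == aug$query_id, ]
  expect_equal(nrow(qe), 2)
  expect_setequal(qe$target, c("g1", "p6"))
  expect_true(all(qe$relation == "Mention_Query"))
  # original untouched
  expect_equal(graph_stats(kg), before)
  # empty matches: isolated query node, logged
  expect_message(aug2 <- insert_query_node(kg, m[0, ], "q"),
                 "isolated query node")
  expect_equal(sum(aug2$graph$edges$relation == "Mention_Query"), 0)
})

test_that("persisted graphs refuse transient query nodes", {
  kg <- chd7_graph()
  m <- link_entities("CHD7", kg)
  aug <- insert_query_node(kg, m, "q")
  expect_error(knowledge_graph(aug$graph$nodes, aug$graph$edges),
               class = "phenorag_schema_error")
})

vr_config <- function(k = 5, depth = 1)
  retriever_config(k = k, expansion_depth = depth,
                   embedding = embedding_config("GLEE", dim = 8, seed = 5))

test_that("vector retrieval saturates to the whole graph at large k and covers the star hub", {
  kg <- chd7_graph()
  ctx <- suppressMessages(vector_retrieve(kg, render_stem(chd7_case()),
                                          vr_config(k = 50, depth = 2)))
  expect_equal(sort(ctx$subgraph$nodes$id), sort(kg$nodes$id))
  expect_equal(nrow(ctx$subgraph$edges), nrow(kg$edges))

  # star graph, query matching the hub: the depth-0 node set must equal
  # the brute-force cosine ranking on the augmented graph, and one hop of
  # expansion pulls in the hub (the query's matched entity)
  nodes <- data.frame(id = c("g1", paste0("p", 1:6)),
                      kind = c("Genotype", rep("FacePhenotype", 6)),
                      name = c("HUBGENE1", paste0("Leaf phenotype ", 1:6)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = "g1", relation = "Affect",
                      target = paste0("p", 1:6), stringsAsFactors = FALSE)
  star <- knowledge_graph(nodes, edges)
  cfg <- vr_config(k = 2, depth = 0)
  ctx2 <- suppressMessages(vector_retrieve(star, "variants of HUBGENE1",
                                           cfg))
  aug <- suppressMessages(insert_query_node(
    star, link_entities("variants of HUBGENE1", star, cfg), "q"))
  emb <- suppressMessages(embed_graph(aug$graph, cfg$embedding))
  qi <- match(aug$query_id, emb$node_order)
  sims <- vapply(seq_along(emb$node_order), function(j) {
    a <- emb$vectors[qi, ]; b <- emb$vectors[j, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }, numeric(1))
  keep <- setdiff(seq_along(emb$node_order), qi)
  want <- head(emb$node_order[keep[order(-sims[keep],
                                         emb$node_order[keep])]], 2)
  expect_setequal(ctx2$subgraph$nodes$id, want)
  ctx3 <- suppressMessages(vector_retrieve(star, "variants of HUBGENE1",
                                           vr_config(k = 2, depth = 1)))
  expect_true("g1" %in% ctx3$subgraph$nodes$id)
})

test_that("vector retrieval is deterministic and never leaks the query node", {
  kg <- chd7_graph()
  q <- render_stem(chd7_case())
  c1 <- suppressMessages(vector_retrieve(kg, q, vr_config()))
  c2 <- suppressMessages(vector_retrieve(kg, q, vr_config()))
  expect_identical(c1$triplet_text, c2$triplet_text)
  expect_false(any(c1$subgraph$nodes$kind == "Query"))
  expect_false(any(c1$subgraph$edges$relation == "Mention_Query"))
  expect_true(all(c1$subgraph$nodes$id %in% kg$nodes$id))
})

test_that("retrieved node set grows monotonically with k before expansion", {
  w <- small_world(seed = 21, overlap = 0.3, cases_per_disease = 1)
  q <- render_stem(w$cases[[1]])
  prev <- character()
  for (k in 1:6) {
    ctx <- suppressMessages(vector_retrieve(w$kg, q, vr_config(k = k,
                                                               depth = 0)))
    ids <- ctx$subgraph$nodes$id
    expect_true(all(prev %in% ids), info = paste("k =", k))
    prev <- ids
  }
})

test_that("context serialization follows the triplet format deterministically", {
  kg <- chd7_graph()
  one <- phenorag:::induced_subgraph(kg, c("d1", "p6"))
  expect_equal(serialize_context(one),
               "[CHARGE syndrome] -(Has_Phenotype)-> [Proptosis]")
  empty <- phenorag:::induced_subgraph(kg, character())
  expect_equal(serialize_context(empty), "NO CONTEXT RETRIEVED")
  # line count equals edge count on any subgraph
  for (ids in list(c("d1", "p1", "p2", "g1"), kg$nodes$id)) {
    sub <- phenorag:::induced_subgraph(kg, ids)
    expect_equal(length(strsplit(serialize_context(sub), "\n")[[1]]),
                 nrow(sub$edges))
  }
})

test_that("the Cypher subset matches a brute-force pattern enumeration", {
  kg <- chd7_graph()
  res <- query_graph(kg,
    "MATCH (g:Genotype {name: 'CHD7'})-[:Affect]->(p:FacePhenotype) RETURN p.name")
  want <- oracle_match(kg,
    specs = list(list(label = "Genotype", props = c(name = "CHD7")),
                 list(label = "FacePhenotype", props = character())),
    rels = list(list(rel = "Affect", dir = "forward")),
    ret = list(list(var_idx = 2, prop = "name")))
  expect_equal(res$rows[[1]], want[[1]])
  expect_equal(nrow(res$rows), 6)

  # no instances -> empty rows
  res2 <- query_graph(kg,
    "MATCH (g:Genotype {name: 'NOPE'})-[:Affect]->(p:FacePhenotype) RETURN p.name")
  expect_equal(nrow(res2$rows), 0)
})

test_that("two-hop patterns equal the oracle on random graphs", {
  for (seed in c(5, 23)) {
    kg <- random_valid_graph(n_per_kind = 4, p_edge = 0.5, seed = seed)
    res <- query_graph(kg,
      "MATCH (v:Variation)-[:Have]->(g:Genotype)-[:Affect]->(p:FacePhenotype) RETURN v.name, p.name")
    want <- oracle_match(kg,
      specs = list(list(label = "Variation", props = character()),
                   list(label = "Genotype", props = character()),
                   list(label = "FacePhenotype", props = character())),
      rels = list(list(rel = "Have", dir = "forward"),
                  list(rel = "Affect", dir = "forward")),
      ret = list(list(var_idx = 1, prop = "name"),
                 list(var_idx = 3, prop = "name")))
    expect_equal(unname(as.list(res$rows)), unname(as.list(want)),
                 info = paste("seed", seed))
  }
})

test_that("WHERE equality and CONTAINS, backward arrows, and LIMIT behave", {
  kg <- chd7_graph()
  res <- query_graph(kg,
    "MATCH (p:FacePhenotype)<-[:Has_Phenotype]-(d:Disease) WHERE d.name CONTAINS 'CHARGE' RETURN p.name LIMIT 3")
  expect_equal(nrow(res$rows), 3)
  expect_true(all(res$rows[[1]] %in% chd7_case()$phenotypes))

  res2 <- query_graph(kg,
    "MATCH (d:Disease) WHERE d.omim = '214800' RETURN d.name")
  expect_equal(res2$rows[[1]], "CHARGE syndrome")
})

test_that("queries outside the subset raise a named unsupported error", {
  kg <- chd7_graph()
  expect_error(query_graph(kg, "MATCH (a)-[:X]->(b)-[:Y]->(c)-[:Z]->(d) RETURN a.name"),
               class = "phenorag_unsupported_query")
  expect_error(query_graph(kg, "MATCH (d:Disease) RETURN d.name ORDER BY d.name"),
               regexp = "RETURN item|unsupported")
  expect_error(query_graph(kg, "FOREACH x IN y"),
               class = "phenorag_unsupported_query")
})

test_that("Cypher generation returns valid queries, strips mutations, flags prose", {
  pol <- schema_policy()
  ok <- scripted_model("MATCH (d:Disease) RETURN d.name")
  g1 <- generate_cypher(ok, pol, "which diseases exist?")
  expect_equal(g1$query, "MATCH (d:Disease) RETURN d.name")
  expect_length(g1$flags, 0)

  mut <- scripted_model("MATCH (d:Disease) RETURN d.name\nDELETE d")
  g2 <- generate_cypher(mut, pol, "q")
  expect_match(g2$flags, "DELETE")
  expect_false(grepl("DELETE", g2$query))

  prose <- scripted_model("I cannot write Cypher, sorry.")
  expect_error(generate_cypher(prose, pol, "q"),
               class = "phenorag_cypher_generation_error")
})

test_that("Cypher retrieval falls back per configuration on generation failure", {
  kg <- chd7_graph()
  prose <- scripted_model("no query here")
  ctx <- cypher_retrieve(kg, "q", prose,
                         retriever_config(fallback = "empty_context"))
  expect_equal(ctx$triplet_text, "NO CONTEXT RETRIEVED")
  expect_match(paste(ctx$diagnostics, collapse = " "), "fallback")

  ctx2 <- suppressMessages(cypher_retrieve(
    kg, "patient with Proptosis", prose,
    retriever_config(fallback = "vector",
                     embedding = embedding_config("GLEE", dim = 6,
                                                  seed = 2))))
  expect_equal(ctx2$retriever, "vector")
  expect_gt(nrow(ctx2$subgraph$nodes), 0)

  expect_error(cypher_retrieve(kg, "q", prose,
                               retriever_config(fallback = "none")),
               class = "phenorag_cypher_generation_error")
})

test_that("end-to-end retrieval context is byte-stable for identical inputs", {
  w <- small_world(seed = 31, overlap = 0.4, cases_per_disease = 1)
  q <- render_stem(w$cases[[3]])
  cfg <- vr_config(k = 5, depth = 1)
  a <- suppressMessages(vector_retrieve(w$kg, q, cfg))
  b <- suppressMessages(vector_retrieve(w$kg, q, cfg))
  expect_identical(a$triplet_text, b$triplet_text)
  expect_identical(a$matches, b$matches)
})
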