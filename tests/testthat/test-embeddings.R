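# tiny graphs for spectral checks, built directly from node/edge frames
path_graph <- function(n) {
  nodes <- data.frame(id = paste0("p", seq_len(n)), kind = "FacePhenotype",
                      name = paste0("P", seq_len(n)),
                      stringsAsFactors = FALSE)
  # FacePhenotype has no self-relations in the default policy; use a
  # permissive schema for these abstract spectral fixtures
  pol <- schema_policy(data.frame(source_kind = "FacePhenotype",
                                  relation = "Affect",
                                  target_kind = "FacePhenotype",
                                  stringsAsFactors = FALSE))
  edges <- if (n > 1)
    data.frame(source = paste0("p", 1:(n - 1)), relation = "Affect",
               target = paste0("p", 2:n), stringsAsFactors = FALSE)
  else NULL
  knowledge_graph(nodes, edges, pol)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- data.frame(id = paste0("p", seq_len(n)), kind = "FacePhenotype",
                      name = paste0("P", seq_len(n)),
                      stringsAsFactors = FALSE)
  pol <- schema_policy(data.frame(source_kind = "FacePhenotype",
                                  relation = "Affect",
                                  target_kind = "FacePhenotype",
                                  stringsAsFactors = FALSE))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  edges <- if (nrow(keep))
    data.frame(source = paste0("p", keep[, 1]), relation = "Affect",
               target = paste0("p", keep[, 2]), stringsAsFactors = FALSE)
  else NULL
  knowledge_graph(nodes, edges, pol)
}

laplacian_of <- function(kg) {
  A <- phenorag:::adjacency_matrix(kg)
  diag(rowSums(A)) - A
}

test_that("spectral Laplacian embedding of the 2-node complete graph is (+1, -1) up to sign", {
  kg <- path_graph(2)  # the 2-path is the 2-node complete graph
  e <- suppressMessages(embed_graph(kg, embedding_config("GLEE", dim = 1)))
  v <- as.numeric(e$vectors)
  expect_equal(abs(v), c(1, 1), tolerance = 1e-10)
  expect_equal(v[1], -v[2], tolerance = 1e-10)
})

test_that("full-dimension Laplacian embedding reconstructs L exactly", {
  for (kg in list(path_graph(3), random_graph(8, 0.5, seed = 4))) {
    n <- nrow(kg$nodes)
    e <- suppressMessages(embed_graph(kg, embedding_config("GLEE", dim = n)))
    S <- e$vectors
    expect_lt(max(abs(S %*% t(S) - laplacian_of(kg))), 1e-8)
  }
})

test_that("Laplacian reconstruction error is non-increasing in dimension", {
  for (seed in c(1, 6)) {
    kg <- random_graph(10, 0.4, seed = seed)
    L <- laplacian_of(kg)
    errs <- vapply(1:10, function(d) {
      S <- suppressMessages(embed_graph(kg, embedding_config("GLEE",
                                                             dim = d)))$vectors
      norm(S %*% t(S) - L, "F")
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-8), info = paste("seed", seed))
  }
})

test_that("every algorithm is deterministic for a fixed seed and finite", {
  kg <- suppressMessages(generate_kg(synth_config(
    node_counts = c(Article = 3, Disease = 5, Genotype = 4, Variation = 8,
                    FacePhenotype = 15, Sample = 6), seed = 2)))
  for (alg in c("GLEE", "SocioDim", "NetMF", "RandNE", "DeepWalk",
                "Node2Vec", "Walklets")) {
    cfg <- embedding_config(alg, dim = 8, seed = 42, num_walks = 3,
                            walk_length = 10, epochs = 1)
    e1 <- suppressMessages(embed_graph(kg, cfg))
    e2 <- suppressMessages(embed_graph(kg, cfg))
    expect_identical(e1$vectors, e2$vectors, info = alg)
    expect_true(all(is.finite(e1$vectors)), info = alg)
    expect_equal(dim(e1$vectors), c(nrow(kg$nodes), 8), info = alg)
  }
})

test_that("spectral embeddings are relabeling-invariant up to sign and row order", {
  for (seed in c(3, 8, 12)) {
    kg <- random_graph(12, 0.45, seed = seed)
    # choose a dimension bounded by a clear spectral gap so the top
    # eigenspace is stable under relabeling
    lam <- eigen(laplacian_of(kg), symmetric = TRUE, only.values = TRUE)$values
    gaps <- abs(diff(lam[1:8]))
    d <- which.max(gaps > 1e-6)
    perm <- sample(nrow(kg$nodes))
    kg2 <- knowledge_graph(kg$nodes[perm, ], kg$edges, kg$schema)
    e1 <- suppressMessages(embed_graph(kg, embedding_config("GLEE", dim = d)))
    e2 <- suppressMessages(embed_graph(kg2, embedding_config("GLEE", dim = d)))
    V1 <- e1$vectors[kg2$nodes$id, , drop = FALSE]  # align row order
    V2 <- e2$vectors
    for (j in seq_len(d)) {
      agree <- min(max(abs(V1[, j] - V2[, j])), max(abs(V1[, j] + V2[, j])))
      expect_lt(agree, 1e-6)
    }
  }
})

test_that("spectral dimension above the node count is a parameter error", {
  kg <- path_graph(3)
  expect_error(embed_graph(kg, embedding_config("GLEE", dim = 4)),
               class = "phenorag_parameter_error")
})

test_that("cosine_topk matches an exhaustive brute-force ranking", {
  brute_topk <- function(V, ids, qi, k) {
    cs <- function(a, b) {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    }
    sims <- vapply(seq_len(nrow(V)), function(j) cs(V[qi, ], V[j, ]),
                   numeric(1))
    keep <- setdiff(seq_len(nrow(V)), qi)
    ord <- keep[order(-sims[keep], ids[keep])]
    head(data.frame(id = ids[ord], similarity = sims[ord],
                    stringsAsFactors = FALSE), k)
  }
  for (seed in 1:5) {
    set.seed(seed)
    V <- matrix(rnorm(50), 10, 5)
    V[3, ] <- 0  # zero vector must score 0, not crash
    ids <- sprintf("n%02d", 1:10)
    emb <- structure(list(node_order = ids, kinds = rep("Disease", 10),
                          vectors = V,
                          config = embedding_config("GLEE", dim = 5)),
                     class = "phenorag_embedding")
    got <- cosine_topk(emb, ids[1], 3)
    want <- brute_topk(V, ids, 1, 3)
    expect_equal(got$id, want$id, info = paste("seed", seed))
    expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
  }
})

test_that("cosine similarity boundaries: duplicate vector ranks first at 1, orthogonal scores 0", {
  V <- rbind(c(1, 0), c(1, 0), c(0, 1))
  emb <- structure(list(node_order = c("q", "dup", "orth"),
                        kinds = rep("Disease", 3), vectors = V,
                        config = embedding_config("GLEE", dim = 2)),
                   class = "phenorag_embedding")
  got <- cosine_topk(emb, "q", 2)
  expect_equal(got$id[1], "dup")
  expect_equal(got$similarity[1], 1)
  expect_equal(got$similarity[got$id == "orth"], 0)
})

test_that("embedding matrices persist to TSV + JSON sidecar and reload", {
  kg <- path_graph(5)
  e <- suppressMessages(embed_graph(kg, embedding_config("GLEE", dim = 3,
                                                         seed = 9)))
  f <- tempfile(fileext = ".tsv")
  write_embeddings(e, f)
  e2 <- read_embeddings(f)
  expect_equal(e2$node_order, e$node_order)
  expect_equal(unname(e2$vectors), unname(e$vectors), tolerance = 1e-12)
  expect_equal(e2$config$algorithm, "GLEE")
})

test_that("classification harness scores an oracle learner at F1 = 1 and a constant learner at its closed form", {
  kg <- suppressMessages(generate_kg(synth_config(
    node_counts = c(Article = 0, Disease = 10, Genotype = 0, Variation = 0,
                    FacePhenotype = 10, Sample = 0), seed = 5)))
  oracle <- function(x, y) {
    kinds <- kg$nodes$kind
    names(kinds) <- kg$nodes$id
    function(newx) unname(kinds[rownames(newx)])
  }
  rep1 <- suppressMessages(node_classification_eval(
    kg, embedding_config("GLEE", dim = 4), test_fraction = 0.5,
    split_seed = 2, classifier = oracle))
  expect_equal(rep1$micro_f1, 1)
  expect_equal(rep1$macro_f1, 1)
  expect_equal(rep1$weighted_f1, 1)

  # constant predictor on a balanced two-kind graph: micro F1 = accuracy
  # = 0.5 at a 50/50 split
  constant <- function(x, y) function(newx) rep("Disease", nrow(newx))
  rep2 <- suppressMessages(node_classification_eval(
    kg, embedding_config("GLEE", dim = 4), test_fraction = 0.5,
    split_seed = 2, classifier = constant))
  expect_equal(rep2$micro_f1, 0.5)
})

test_that("single-kind graphs and singleton kinds are rejected with guidance", {
  kg1 <- suppressMessages(generate_kg(synth_config(
    node_counts = c(Article = 0, Disease = 6, Genotype = 0, Variation = 0,
                    FacePhenotype = 0, Sample = 0), seed = 1)))
  expect_error(node_classification_eval(kg1), class = "phenorag_input_error")

  nodes <- data.frame(id = c("d1", "d2", "a1"),
                      kind = c("Disease", "Disease", "Article"),
                      name = c("D1", "D2", "A1"), stringsAsFactors = FALSE)
  kg2 <- knowledge_graph(nodes)
  expect_error(node_classification_eval(kg2),
               class = "phenorag_stratification_error")
})

test_that("disconnected single-kind cliques separate cleanly under the spectral embedding", {
  skip_if_not_installed("randomForest")
  # unequal clique sizes keep the per-block Laplacian eigenvalues
  # distinct across blocks, so the top eigenspace respects the blocks
  kinds <- c("Disease", "FacePhenotype", "Genotype")
  sizes <- c(6, 8, 10)
  nodes <- do.call(rbind, lapply(seq_along(kinds), function(i)
    data.frame(id = sprintf("k%d_%02d", i, seq_len(sizes[i])),
               kind = kinds[i],
               name = paste0(kinds[i], seq_len(sizes[i])),
               stringsAsFactors = FALSE)))
  pol <- schema_policy(data.frame(
    source_kind = kinds, relation = "Affect", target_kind = kinds,
    stringsAsFactors = FALSE))
  edges <- do.call(rbind, lapply(seq_along(kinds), function(i) {
    ids <- sprintf("k%d_%02d", i, seq_len(sizes[i]))
    grid <- expand.grid(source = ids, target = ids,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$source < grid$target, ]
    data.frame(source = grid$source, relation = "Affect",
               target = grid$target, stringsAsFactors = FALSE)
  }))
  kg <- knowledge_graph(nodes, edges, pol)
  rep <- suppressMessages(node_classification_eval(
    kg, embedding_config("GLEE", dim = 21, seed = 3),
    test_fraction = 0.25, split_seed = 7))
  expect_gte(rep$macro_f1, 0.95)
})
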