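#' @title Graph embeddings and the node-classification selection harness
#' @description
#' Seven embedding algorithms behind one interface.  Four are spectral or
#' matrix-factorization methods requiring no sampling (GLEE, SocioDim,
#' NetMF, RandNE) and three are random-walk skip-gram methods sharing a
#' seeded walk generator (DeepWalk, Node2Vec, Walklets).  Edges are treated
#' as undirected and unweighted for embedding purposes.
#' @name embeddings
NULL

EMBED_ALGORITHMS <- c("GLEE", "SocioDim", "NetMF", "RandNE",
                      "DeepWalk", "Node2Vec", "Walklets")

#' Embedding configuration
#'
#' Defaults: spectral/factorization methods use `dim = 32`; walk methods
#' `dim = 128` with 10 walks of length 80 per node, window 5 and 5 negative
#' samples; Node2Vec return/in-out biases `p = q = 1`; Walklets skip scales
#' `powers = 1:4` with the dimension split evenly across scales.
#'
#' @param algorithm One of `"GLEE"`, `"SocioDim"`, `"NetMF"`, `"RandNE"`,
#'   `"DeepWalk"`, `"Node2Vec"`, `"Walklets"`.
#' @param dim Embedding dimension (must not exceed the node count for
#'   spectral methods).
#' @param seed Integer seed governing all sampling.
#' @param num_walks,walk_length,window,negative,epochs,alpha Walk and
#'   skip-gram training parameters.
#' @param p,q Node2Vec bias parameters (> 0).
#' @param powers Walklets skip scales.
#' @param steps RandNE adjacency power iterations.
#' @param weights RandNE per-order weights (length `steps + 1`).
#' @return A `phenorag_embed_config` list.
#' @export
embedding_config <- function(algorithm = "GLEE", dim = NULL, seed = 1L,
                             num_walks = 10L, walk_length = 80L,
                             window = 5L, negative = 5L, epochs = 2L,
                             alpha = 0.025, p = 1, q = 1, powers = 1:4,
                             steps = 3L,
                             weights = c(1, 0.1, 0.01, 0.001)) {
  algorithm <- match.arg(algorithm, EMBED_ALGORITHMS)
  if (is.null(dim))
    dim <- if (algorithm %in% c("DeepWalk", "Node2Vec", "Walklets")) 128L
           else 32L
  stopifnot(dim >= 1, p > 0, q > 0, num_walks >= 1, walk_length >= 2,
            window >= 1, negative >= 0, epochs >= 1)
  structure(list(algorithm = algorithm, dim = as.integer(dim),
                 seed = as.integer(seed), num_walks = as.integer(num_walks),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 negative = as.integer(negative),
                 epochs = as.integer(epochs), alpha = alpha, p = p, q = q,
                 powers = as.integer(powers), steps = as.integer(steps),
                 weights = weights),
            class = "phenorag_embed_config")
}

# symmetric 0/1 adjacency matrix in the node order of kg$nodes$id
adjacency_matrix <- function(kg) {
  ids <- kg$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(kg$edges)) {
    i <- match(kg$edges$source, ids)
    j <- match(kg$edges$target, ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  diag(A) <- 0
  A
}

count_components <- function(kg) {
  adj <- adjacency_list(kg)
  ids <- kg$nodes$id
  seen <- setNames(rep(FALSE, length(ids)), ids)
  ncomp <- 0L
  for (s in ids) {
    if (seen[[s]]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[[s]] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  ncomp
}

#' Embed a knowledge graph
#'
#' Deterministic for a fixed seed.  GLEE takes eigenvectors from the large
#' end of the combinatorial Laplacian's spectrum, scaled so the outer
#' product of the embedding approximates `L = D - A`; SocioDim takes
#' leading eigenvectors of the modularity matrix; NetMF factorizes the
#' shifted positive PMI matrix implied by length-`window` random walks;
#' RandNE iterates a seeded orthogonal random projection through powers of
#' the adjacency operator.  DeepWalk, Node2Vec and Walklets train skip-gram
#' with negative sampling on seeded walks.
#'
#' @param kg A non-empty `phenorag_kg`.
#' @param config An [embedding_config()].
#' @return A `phenorag_embedding` with fields `node_order`, `kinds`,
#'   `vectors` (nodes x dim matrix) and `config`.
#' @export
embed_graph <- function(kg, config = embedding_config()) {
  n <- nrow(kg$nodes)
  if (n == 0) pr_abort("cannot embed an empty graph", "phenorag_input_error")
  spectral <- config$algorithm %in% c("GLEE", "SocioDim", "NetMF", "RandNE")
  if (spectral && config$dim > n)
    pr_abort(sprintf("dim %d exceeds node count %d for %s",
                     config$dim, n, config$algorithm),
             "phenorag_parameter_error")
  ncomp <- count_components(kg)
  if (ncomp > 1)
    message(sprintf("graph has %d connected components; embedding proceeds on the full graph", ncomp))
  vec <- with_seed(config$seed, switch(config$algorithm,
    GLEE = embed_glee(kg, config),
    SocioDim = embed_sociodim(kg, config),
    NetMF = embed_netmf(kg, config),
    RandNE = embed_randne(kg, config),
    DeepWalk = embed_walk_sgns(kg, config, kind = "deepwalk"),
    Node2Vec = embed_walk_sgns(kg, config, kind = "node2vec"),
    Walklets = embed_walklets(kg, config)))
  stopifnot(all(is.finite(vec)))
  rownames(vec) <- kg$nodes$id
  structure(list(node_order = kg$nodes$id, kinds = kg$nodes$kind,
                 vectors = vec, config = config),
            class = "phenorag_embedding")
}

embed_glee <- function(kg, config) {
  A <- adjacency_matrix(kg)
  L <- diag(rowSums(A)) - A
  es <- eigen(L, symmetric = TRUE)  # eigenvalues in decreasing order
  d <- config$dim
  lam <- pmax(es$values[seq_len(d)], 0)
  es$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam), d, d)
}

embed_sociodim <- function(kg, config) {
  A <- adjacency_matrix(kg)
  deg <- rowSums(A)
  m2 <- sum(deg)
  B <- if (m2 > 0) A - outer(deg, deg) / m2 else A
  es <- eigen(B, symmetric = TRUE)
  es$vectors[, seq_len(config$dim), drop = FALSE]
}

embed_netmf <- function(kg, config) {
  A <- adjacency_matrix(kg)
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / deg, 0)
  P <- A * dinv  # row-stochastic transition matrix (zero rows stay zero)
  Tw <- config$window
  S <- matrix(0, nrow(A), ncol(A))
  Pr <- diag(nrow(A))
  for (r in seq_len(Tw)) {
    Pr <- Pr %*% P
    S <- S + Pr
  }
  vol <- sum(deg)
  b <- max(config$negative, 1)
  M <- (vol / (b * Tw)) * S %*% diag(dinv)
  Mlog <- log(pmax(M, 1))
  sv <- svd(Mlog)
  d <- config$dim
  sv$u[, seq_len(d), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(d)]), d, d)
}

embed_randne <- function(kg, config) {
  A <- adjacency_matrix(kg)
  n <- nrow(A)
  R <- matrix(stats::rnorm(n * config$dim), n, config$dim)
  U <- qr.Q(qr(R))
  if (ncol(U) < config$dim)  # n < dim: pad (projection cannot be orthogonal)
    U <- cbind(U, R[, seq_len(config$dim - ncol(U)), drop = FALSE])
  out <- config$weights[1] * U
  Ui <- U
  for (i in seq_len(config$steps)) {
    Ui <- A %*% Ui
    w <- if (i + 1 <= length(config$weights)) config$weights[i + 1] else 0
    out <- out + w * Ui
  }
  out
}

# seeded uniform (DeepWalk) or p,q-biased (Node2Vec) random walks;
# returns list of integer vectors of 0-based node indices
generate_walks <- function(kg, config, kind = "deepwalk") {
  ids <- kg$nodes$id
  adj <- adjacency_list(kg)
  idx <- setNames(seq_along(ids), ids)
  walks <- vector("list", config$num_walks * length(ids))
  wi <- 0L
  for (rep_i in seq_len(config$num_walks)) {
    for (start in sample(ids)) {
      walk <- integer(config$walk_length)
      walk[1] <- idx[[start]]
      prev <- NA_character_
      cur <- start
      len <- 1L
      while (len < config$walk_length) {
        nb <- adj[[cur]]
        if (!length(nb)) break
        nxt <- if (kind == "node2vec" && !is.na(prev)) {
          w <- ifelse(nb == prev, 1 / config$p,
                      ifelse(nb %in% adj[[prev]], 1, 1 / config$q))
          nb[sample.int(length(nb), 1, prob = w)]
        } else nb[sample.int(length(nb), 1)]
        len <- len + 1L
        walk[len] <- idx[[nxt]]
        prev <- cur
        cur <- nxt
      }
      wi <- wi + 1L
      walks[[wi]] <- walk[seq_len(len)] - 1L
    }
  }
  walks[seq_len(wi)]
}

neg_sampling_cdf <- function(walks, n) {
  freq <- tabulate(unlist(walks) + 1L, nbins = n)
  w <- (freq + 1)^0.75  # smoothed unigram distribution
  cumsum(w / sum(w))
}

embed_walk_sgns <- function(kg, config, kind) {
  walks <- generate_walks(kg, config, kind)
  n <- nrow(kg$nodes)
  train_sgns_cpp(walks, n, config$dim, config$window, config$negative,
                 config$epochs, config$alpha, neg_sampling_cdf(walks, n),
                 derive_seed(config$seed, "sgns", kind))
}

embed_walklets <- function(kg, config) {
  walks <- generate_walks(kg, config, "deepwalk")
  n <- nrow(kg$nodes)
  npow <- length(config$powers)
  dsub <- max(1L, config$dim %/% npow)
  blocks <- lapply(config$powers, function(k) {
    sub <- unlist(lapply(walks, function(w) {
      lapply(seq_len(min(k, length(w))), function(o)
        w[seq(o, length(w), by = k)])
    }), recursive = FALSE)
    sub <- Filter(function(x) length(x) >= 2, sub)
    if (!length(sub)) return(matrix(0, n, dsub))
    train_sgns_cpp(sub, n, dsub, 1L, config$negative, config$epochs,
                   config$alpha, neg_sampling_cdf(sub, n),
                   derive_seed(config$seed, "walklets", k))
  })
  do.call(cbind, blocks)
}

#' Top-k nodes by cosine similarity to a query node
#'
#' Similarities use the raw vectors; a zero-norm vector scores 0.  The
#' query node itself is excluded; ties break by ascending node id.
#'
#' @param embedding A `phenorag_embedding`.
#' @param query_id Node id present in the embedding.
#' @param k Number of hits (>= 1).
#' @param candidate_filter Optional character vector of node kinds to
#'   restrict candidates to.
#' @return Data frame with columns `id`, `similarity`, sorted descending.
#' @export
cosine_topk <- function(embedding, query_id, k, candidate_filter = NULL) {
  stopifnot(k >= 1)
  i <- match(query_id, embedding$node_order)
  if (is.na(i))
    pr_abort(paste0("query id not embedded: ", query_id),
             "phenorag_input_error")
  V <- embedding$vectors
  qv <- V[i, ]
  qn <- sqrt(sum(qv^2))
  norms <- sqrt(rowSums(V^2))
  sims <- if (qn == 0) rep(0, nrow(V)) else {
    s <- as.numeric(V %*% qv) / (norms * qn)
    s[norms == 0] <- 0
    s
  }
  keep <- seq_len(nrow(V)) != i
  if (!is.null(candidate_filter))
    keep <- keep & embedding$kinds %in% candidate_filter
  ids <- embedding$node_order[keep]
  sims <- sims[keep]
  ord <- order(-sims, ids, method = "radix")
  top <- head(ord, k)
  data.frame(id = ids[top], similarity = sims[top],
             stringsAsFactors = FALSE)
}

#' Persist and reload an embedding matrix
#'
#' The matrix goes to TSV (node id + one column per dimension) and the
#' configuration to a JSON sidecar `<path>.json`.
#'
#' @param embedding A `phenorag_embedding`.
#' @param path TSV output path.
#' @export
write_embeddings <- function(embedding, path) {
  df <- data.frame(id = embedding$node_order, kind = embedding$kinds,
                   embedding$vectors, stringsAsFactors = FALSE)
  names(df) <- c("id", "kind", paste0("d", seq_len(ncol(embedding$vectors))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(unclass(embedding$config),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cfgl <- jsonlite::fromJSON(paste0(path, ".json"))
  cfg <- do.call(embedding_config,
                 cfgl[intersect(names(cfgl),
                                names(formals(embedding_config)))])
  V <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(V) <- df$id
  structure(list(node_order = df$id, kinds = df$kind, vectors = V,
                 config = cfg),
            class = "phenorag_embedding")
}

f1_scores <- function(truth, pred) {
  classes <- sort(unique(truth))
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(pred == cl & truth == cl)
    fp[cl] <- sum(pred == cl & truth != cl)
    fn[cl] <- sum(pred != cl & truth == cl)
  }
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  micro <- if (sum(tp + fp + fn) > 0)
    2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn)) else 0
  list(micro_f1 = micro, macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support) / sum(support))
}

#' Default node-kind classifier (random-forest ensemble)
#'
#' @param ntree Number of trees.
#' @return A learner: `function(x, y)` returning a prediction function.
#' @export
random_forest_learner <- function(ntree = 200L) {
  function(x, y) {
    if (!requireNamespace("randomForest", quietly = TRUE))
      pr_abort("randomForest not installed; supply a classifier",
               "phenorag_config_error")
    fit <- randomForest::randomForest(x, factor(y), ntree = ntree)
    function(newx) as.character(predict(fit, newx))
  }
}

#' Node-classification harness for embedding selection
#'
#' Embeds the full graph, splits nodes stratified by kind, trains the
#' learner on train-split embeddings with the node kind as label and
#' reports micro/macro/weighted F1 on the test split.  Used to pick the
#' embedding algorithm that best preserves graph structure.
#'
#' @param kg A `phenorag_kg` with >= 2 node kinds, each with >= 2 nodes.
#' @param config An [embedding_config()].
#' @param test_fraction Test split fraction in (0, 1).
#' @param split_seed Seed for the stratified split (and the learner).
#' @param classifier A learner `function(x, y) -> function(newx)`.
#' @return List with `micro_f1`, `macro_f1`, `weighted_f1`, `split_seed`,
#'   `test_fraction`, `algorithm`.
#' @export
node_classification_eval <- function(kg, config = embedding_config(),
                                     test_fraction = 0.2, split_seed = 1L,
                                     classifier = random_forest_learner()) {
  kinds <- kg$nodes$kind
  tab <- table(kinds)
  if (length(tab) < 2)
    pr_abort("need at least two node kinds", "phenorag_input_error")
  if (any(tab < 2))
    pr_abort(paste0("node kind(s) with a single node cannot be stratified: ",
                    paste(names(tab)[tab < 2], collapse = ", "),
                    "; add nodes or drop the kind"),
             "phenorag_stratification_error")
  emb <- embed_graph(kg, config)
  with_seed(derive_seed(split_seed, "split"), {
    test_idx <- unlist(lapply(names(tab), function(kl) {
      idx <- which(kinds == kl)
      sample(idx, max(1L, round(test_fraction * length(idx))))
    }))
    train_idx <- setdiff(seq_along(kinds), test_idx)
    model <- classifier(emb$vectors[train_idx, , drop = FALSE],
                        kinds[train_idx])
    pred <- model(emb$vectors[test_idx, , drop = FALSE])
    c(f1_scores(kinds[test_idx], pred),
      list(split_seed = split_seed, test_fraction = test_fraction,
           algorithm = config$algorithm))
  })
}
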