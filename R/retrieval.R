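#' @title Graph retrievers
#' @description
#' Two retrieval routes over the knowledge graph.  The Cypher route has a
#' language model translate the question into a pattern query executed by a
#' deliberate minimal Cypher subset.  The vector route links question
#' entities to graph nodes, inserts the query as a transient node wired to
#' its matches, embeds the augmented graph, and takes the top-K
#' cosine-similar nodes plus their neighbors as the context subgraph.
#' @name retrieval
NULL

#' Retriever configuration
#'
#' @param k Number of top-similarity nodes kept by the vector retriever.
#' @param expansion_depth Undirected neighbor hops (0, 1 or 2) around each
#'   hit; the default 1 reads "their neighbors" as one hop.
#' @param embedding An [embedding_config()] for the augmented graph.
#' @param fuzzy_threshold Normalized similarity in (0, 1] below which fuzzy
#'   entity matches are discarded.
#' @param fallback What the Cypher route does when query generation or
#'   execution fails: `"none"` (error), `"empty_context"`, or `"vector"`.
#' @param char_budget Optional maximum context length in characters
#'   (`Inf` = unlimited); truncation drops whole trailing triplet lines.
#' @return A `phenorag_retriever_config` list.
#' @export
retriever_config <- function(k = 5L, expansion_depth = 1L,
                             embedding = embedding_config("GLEE"),
                             fuzzy_threshold = 0.85,
                             fallback = c("empty_context", "none", "vector"),
                             char_budget = Inf) {
  fallback <- match.arg(fallback)
  stopifnot(k >= 1, expansion_depth %in% 0:2,
            fuzzy_threshold > 0, fuzzy_threshold <= 1)
  structure(list(k = as.integer(k),
                 expansion_depth = as.integer(expansion_depth),
                 embedding = embedding, fuzzy_threshold = fuzzy_threshold,
                 fallback = fallback, char_budget = char_budget),
            class = "phenorag_retriever_config")
}

# lexicon rows: key (normalized), node_id, exactness
build_lexicon <- function(kg) {
  n <- kg$nodes
  syn_n <- lengths(n$synonyms)
  data.frame(
    key = c(norm_name(n$name), norm_name(unlist(n$synonyms))),
    node_id = c(n$id, rep(n$id, syn_n)),
    method = c(rep("exact", nrow(n)), rep("synonym", sum(syn_n))),
    stringsAsFactors = FALSE)
}

#' Link question text to graph nodes
#'
#' Greedy longest-match over canonical names and synonyms
#' (case-insensitive, whitespace-collapsed, non-overlapping spans), then
#' fuzzy matching of remaining capitalized or identifier-like tokens above
#' `fuzzy_threshold`.  A plugin recognizer, `function(query, kg)` returning
#' a compatible data frame, may replace the default entirely.
#'
#' @param query Question text.
#' @param kg A `phenorag_kg`.
#' @param config A [retriever_config()].
#' @param recognizer Optional plugin replacing the lexicon matcher.
#' @return Data frame with columns `surface`, `node_id`, `score`,
#'   `method`.
#' @export
link_entities <- function(query, kg, config = retriever_config(),
                          recognizer = NULL) {
  empty <- data.frame(surface = character(), node_id = character(),
                      score = numeric(), method = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(recognizer)) return(recognizer(query, kg))
  if (!nzchar(norm_space(query)) || nrow(kg$nodes) == 0) return(empty)
  qn <- norm_name(query)
  lex <- build_lexicon(kg)
  lex <- lex[nzchar(lex$key), , drop = FALSE]
  lex <- lex[c_order(-nchar(lex$key), lex$key, lex$node_id), , drop = FALSE]
  lex <- lex[!duplicated(lex$key), , drop = FALSE]
  covered <- rep(FALSE, nchar(qn))
  out <- list()
  for (r in seq_len(nrow(lex))) {
    key <- lex$key[r]
    hits <- gregexpr(key, qn, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in hits) {
      span <- h:(h + nchar(key) - 1L)
      # word boundaries and no overlap with an earlier (longer) match
      before_ok <- h == 1 || grepl("[^a-z0-9]", substr(qn, h - 1, h - 1))
      after <- h + nchar(key)
      after_ok <- after > nchar(qn) ||
        grepl("[^a-z0-9]", substr(qn, after, after))
      if (before_ok && after_ok && !any(covered[span])) {
        covered[span] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          surface = substr(qn, h, h + nchar(key) - 1L),
          node_id = lex$node_id[r], score = 1,
          method = lex$method[r], stringsAsFactors = FALSE)
      }
    }
  }
  # fuzzy pass over identifier-like tokens not already covered
  toks <- regmatches(query, gregexpr("[A-Za-z][A-Za-z0-9._-]*", query))[[1]]
  cand <- unique(toks[grepl("^[A-Z]", toks) | grepl("[0-9]", toks)])
  cand <- cand[!(norm_name(cand) %in%
                   unlist(lapply(out, `[[`, "surface")))]
  cand <- cand[nchar(cand) >= 3]
  if (length(cand) && nrow(lex)) {
    for (tok in cand) {
      tn <- norm_name(tok)
      if (grepl(tn, qn, fixed = TRUE)) {
        pos <- regexpr(tn, qn, fixed = TRUE)[1]
        if (any(covered[pos:(pos + nchar(tn) - 1)])) next
      }
      d <- adist(tn, lex$key)
      sim <- 1 - d / pmax(nchar(tn), nchar(lex$key))
      best <- which.max(sim)
      if (sim[best] >= config$fuzzy_threshold && sim[best] < 1) {
        out[[length(out) + 1L]] <- data.frame(
          surface = tok, node_id = lex$node_id[best],
          score = unname(sim[best]), method = "fuzzy",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$surface, res$node_id)), , drop = FALSE]
}

QUERY_NODE_ID <- "__query__"

#' Insert a transient query node
#'
#' Returns a copy of the graph with one `Query` node and one
#' `Mention_Query` edge per distinct matched node; the original graph is
#' untouched.  With no matches the query node is isolated (logged via a
#' message) and downstream code falls back per the retriever config.
#'
#' @param kg A `phenorag_kg`.
#' @param matches Data frame from [link_entities()].
#' @param query_text Stored as the query node's name.
#' @return List with `graph` (augmented copy) and `query_id`.
#' @export
insert_query_node <- function(kg, matches, query_text = "query") {
  ids <- unique(matches$node_id)
  if (length(setdiff(ids, kg$nodes$id)))
    pr_abort("matched id(s) absent from graph", "phenorag_input_error")
  if (!length(ids))
    message("query matched no entities; inserting isolated query node")
  qnode <- data.frame(id = QUERY_NODE_ID, kind = "Query",
                      name = if (nzchar(query_text)) query_text else "query",
                      synonyms = I(list(character())),
                      properties = I(list(character())),
                      stringsAsFactors = FALSE)
  nodes <- rbind(kg$nodes, qnode)
  edges <- kg$edges
  if (length(ids))
    edges <- rbind(edges, data.frame(source = QUERY_NODE_ID,
                                     relation = "Mention_Query",
                                     target = ids, stringsAsFactors = FALSE))
  list(graph = knowledge_graph(nodes, edges, kg$schema, allow_query = TRUE),
       query_id = QUERY_NODE_ID)
}

expand_hops <- function(kg, ids, depth) {
  adj <- adjacency_list(kg)
  frontier <- ids
  seen <- ids
  for (h in seq_len(depth)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  seen
}

#' Serialize a subgraph to triplet text
#'
#' One line per edge, `[source name] -(relation)-> [target name]`, ordered
#' lexicographically by source name, relation, target name.  An empty
#' subgraph yields the sentinel line `NO CONTEXT RETRIEVED`.
#'
#' @param subgraph A `phenorag_kg`.
#' @return A single string.
#' @export
serialize_context <- function(subgraph) {
  if (!nrow(subgraph$edges)) return("NO CONTEXT RETRIEVED")
  sn <- node_name_of(subgraph, subgraph$edges$source)
  tn <- node_name_of(subgraph, subgraph$edges$target)
  rel <- subgraph$edges$relation
  ord <- c_order(sn, rel, tn)
  paste(sprintf("[%s] -(%s)-> [%s]", sn[ord], rel[ord], tn[ord]),
        collapse = "\n")
}

new_context <- function(subgraph, matches, retriever, query, diagnostics,
                        char_budget = Inf) {
  txt <- serialize_context(subgraph)
  if (is.finite(char_budget) && nchar(txt) > char_budget) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    keep <- cumsum(nchar(lines) + 1) <= char_budget
    txt <- if (any(keep)) paste(lines[keep], collapse = "\n")
           else "NO CONTEXT RETRIEVED"
    diagnostics <- c(diagnostics,
                     sprintf("context truncated to %d chars", char_budget))
  }
  structure(list(subgraph = subgraph, triplet_text = txt,
                 matches = matches, retriever = retriever, query = query,
                 diagnostics = diagnostics),
            class = "phenorag_context")
}

#' Vector retrieval: query-node insertion + embedding + top-K + expansion
#'
#' Links entities, inserts the transient query node, embeds the augmented
#' graph, ranks all non-query nodes by cosine similarity to the query
#' node, expands each of the top `k` hits by `expansion_depth` undirected
#' hops, and returns the induced subgraph of the original graph (the query
#' node never appears in the context).
#'
#' @param kg A non-empty `phenorag_kg`.
#' @param query Question text.
#' @param config A [retriever_config()].
#' @return A `phenorag_context`.
#' @export
vector_retrieve <- function(kg, query, config = retriever_config()) {
  if (nrow(kg$nodes) == 0)
    pr_abort("cannot retrieve from an empty graph", "phenorag_input_error")
  matches <- link_entities(query, kg, config)
  diag <- sprintf("%d entity match(es)", nrow(matches))
  if (nrow(matches) == 0 && config$fallback == "empty_context") {
    return(new_context(induced_subgraph(kg, character()), matches,
                       "vector", query,
                       c(diag, "no matches: empty context fallback")))
  }
  aug <- suppressMessages(insert_query_node(kg, matches, query))
  emb <- suppressMessages(embed_graph(aug$graph, config$embedding))
  hits <- cosine_topk(emb, aug$query_id, config$k,
                      candidate_filter = setdiff(node_kinds(), "Query"))
  keep <- expand_hops(kg, hits$id, config$expansion_depth)
  sub <- induced_subgraph(kg, keep)
  new_context(sub, matches, "vector", query,
              c(diag, sprintf("top-%d hits expanded by %d hop(s) to %d nodes",
                              config$k, config$expansion_depth,
                              length(keep))),
              config$char_budget)
}

## ---- Cypher subset ---------------------------------------------------------

strip_quotes <- function(x) {
  x <- sub("^\\s*['\"]", "", x)
  sub("['\"]\\s*$", "", x)
}

parse_props_clause <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  s <- sub("^\\{", "", sub("\\}$", "", trimws(s)))
  if (!nzchar(trimws(s))) return(character())
  parts <- strsplit(s, ",(?=(?:[^'\"]*['\"][^'\"]*['\"])*[^'\"]*$)",
                    perl = TRUE)[[1]]
  kv <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$",
                               p))[[1]]
    if (length(m) != 3)
      pr_abort(paste0("cannot parse property: ", p),
               "phenorag_unsupported_query")
    c(m[2], gsub('\\\\"', '"', strip_quotes(m[3])))
  })
  setNames(vapply(kv, `[`, character(1), 2),
           vapply(kv, `[`, character(1), 1))
}

NODE_PAT <- "\\(\\s*([A-Za-z_][A-Za-z0-9_]*)?\\s*(?::([A-Za-z_][A-Za-z0-9_]*))?\\s*(\\{[^}]*\\})?\\s*\\)"

parse_match_pattern <- function(pat) {
  rel_pat <- paste0("(<-|-)\\[:([A-Za-z_][A-Za-z0-9_]*)\\](->|-)")
  nodes <- list(); rels <- list()
  rest <- trimws(pat)
  m <- regexec(paste0("^", NODE_PAT), rest)[[1]]
  if (m[1] == -1)
    pr_abort("MATCH pattern must start with a node",
             "phenorag_unsupported_query")
  take <- function(m, rest) {
    g <- regmatches(rest, list(m))[[1]]
    list(groups = g, rest = trimws(substr(rest, attr(m, "match.length")[1] + 1,
                                          nchar(rest))))
  }
  t1 <- take(m, rest)
  nodes[[1]] <- t1$groups
  rest <- t1$rest
  while (nzchar(rest)) {
    mr <- regexec(paste0("^", rel_pat, "\\s*", NODE_PAT), rest)[[1]]
    if (mr[1] == -1)
      pr_abort(paste0("unsupported pattern tail: ", rest),
               "phenorag_unsupported_query")
    g <- regmatches(rest, list(mr))[[1]]
    dir <- if (g[2] == "<-") "backward" else "forward"
    if (dir == "backward" && g[4] != "-")
      pr_abort("bidirectional arrows are not supported",
               "phenorag_unsupported_query")
    if (dir == "forward" && g[4] != "->")
      pr_abort("undirected relationships are not supported",
               "phenorag_unsupported_query")
    rels[[length(rels) + 1L]] <- list(relation = g[3], direction = dir)
    nodes[[length(nodes) + 1L]] <- c("", g[5], g[6], g[7])
    rest <- trimws(substr(rest, attr(mr, "match.length")[1] + 1,
                          nchar(rest)))
  }
  if (length(rels) > 2)
    pr_abort("patterns with more than 2 relationship hops are unsupported",
             "phenorag_unsupported_query")
  vars <- lapply(seq_along(nodes), function(i) {
    g <- nodes[[i]]
    list(var = if (nzchar(g[2])) g[2] else paste0(".anon", i),
         label = if (nzchar(g[3])) g[3] else NA_character_,
         props = parse_props_clause(g[4]))
  })
  list(vars = vars, rels = rels)
}

node_prop <- function(kg, idx, prop) {
  switch(prop,
         id = kg$nodes$id[idx],
         name = kg$nodes$name[idx],
         kind = kg$nodes$kind[idx],
         vapply(kg$nodes$properties[idx], function(p) {
           if (prop %in% names(p)) unname(p[[prop]]) else NA_character_
         }, character(1)))
}

candidate_idx <- function(kg, spec) {
  idx <- seq_len(nrow(kg$nodes))
  if (!is.na(spec$label)) idx <- idx[kg$nodes$kind[idx] == spec$label]
  for (k in names(spec$props))
    idx <- idx[!is.na(node_prop(kg, idx, k)) &
                 node_prop(kg, idx, k) == spec$props[[k]]]
  idx
}

parse_where <- function(clause) {
  if (is.na(clause) || !nzchar(trimws(clause))) return(list())
  conds <- strsplit(clause, "\\s+AND\\s+", perl = TRUE)[[1]]
  lapply(conds, function(cn) {
    m <- regmatches(cn, regexec(
      "^\\s*([A-Za-z_][A-Za-z0-9_]*)\\.([A-Za-z_][A-Za-z0-9_]*)\\s+(CONTAINS|=)\\s+(.+?)\\s*$",
      cn))[[1]]
    if (length(m) != 5) {
      m2 <- regmatches(cn, regexec(
        "^\\s*([A-Za-z_][A-Za-z0-9_]*)\\.([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+?)\\s*$",
        cn))[[1]]
      if (length(m2) != 4)
        pr_abort(paste0("unsupported WHERE condition: ", cn),
                 "phenorag_unsupported_query")
      m <- c(m2[1], m2[2], m2[3], "=", m2[4])
    }
    list(var = m[2], prop = m[3], op = m[4], value = strip_quotes(m[5]))
  })
}

#' Execute a Cypher-subset query or data-definition statement
#'
#' The read subset is `MATCH` with one to two relationship hops, node
#' labels and property-equality constraints, `WHERE` with `=` or
#' `CONTAINS` on properties, `RETURN` of node properties, and an optional
#' `LIMIT`.  Rows equal the set produced by exhaustive subgraph-pattern
#' enumeration, ordered lexicographically.  Data-definition mode accepts
#' the `CREATE` statements emitted by [export_cypher()] (one per line) and
#' returns the extended graph in `$graph`.  Anything outside the subset
#' raises an `phenorag_unsupported_query` error naming the clause.
#'
#' @param kg A `phenorag_kg`.
#' @param cypher Query text (DDL mode may hold several statements,
#'   one per line).
#' @return For queries: list with `rows` (data frame) and `subgraph`.  For
#'   DDL: list with `graph`.
#' @export
query_graph <- function(kg, cypher) {
  stmts <- trimws(strsplit(cypher, "\n", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  if (!length(stmts)) return(list(graph = kg))
  if (any(grepl("^(CREATE|MATCH\\s*\\(a\\s*\\{id)", stmts[1])) &&
      !grepl("RETURN", cypher, ignore.case = TRUE))
    return(apply_ddl(kg, stmts))
  if (length(stmts) != 1)
    pr_abort("multiple read statements are unsupported",
             "phenorag_unsupported_query")
  run_match(kg, stmts[[1]])
}

apply_ddl <- function(kg, stmts) {
  nodes <- kg$nodes
  edges <- kg$edges
  for (s in stmts) {
    mn <- regexec(paste0("^CREATE\\s*\\(\\s*:([A-Za-z_][A-Za-z0-9_]*)\\s*",
                         "(\\{.*\\})\\s*\\)\\s*$"), s)[[1]]
    if (mn[1] != -1) {
      g <- regmatches(s, list(mn))[[1]]
      props <- parse_props_clause(g[3])
      syn <- if ("synonyms" %in% names(props) && nzchar(props[["synonyms"]]))
        strsplit(props[["synonyms"]], "|", fixed = TRUE)[[1]]
      else character()
      extra <- props[setdiff(names(props), c("id", "name", "synonyms"))]
      nodes <- rbind(nodes, data.frame(
        id = props[["id"]] %||% paste0("n", nrow(nodes) + 1),
        kind = g[2], name = props[["name"]],
        synonyms = I(list(syn)), properties = I(list(extra)),
        stringsAsFactors = FALSE))
      next
    }
    me <- regexec(paste0(
      "^MATCH\\s*\\(a\\s*\\{id:\\s*(\"[^\"]*\"|'[^']*')\\}\\)\\s*,\\s*",
      "\\(b\\s*\\{id:\\s*(\"[^\"]*\"|'[^']*')\\}\\)\\s*",
      "CREATE\\s*\\(a\\)-\\[:([A-Za-z_][A-Za-z0-9_]*)\\]->\\(b\\)\\s*$"),
      s)[[1]]
    if (me[1] != -1) {
      g <- regmatches(s, list(me))[[1]]
      edges <- rbind(edges, data.frame(source = strip_quotes(g[2]),
                                       relation = g[4],
                                       target = strip_quotes(g[3]),
                                       stringsAsFactors = FALSE))
      next
    }
    pr_abort(paste0("unsupported data-definition statement: ", s),
             "phenorag_unsupported_query")
  }
  list(graph = knowledge_graph(nodes, edges, kg$schema))
}

run_match <- function(kg, stmt) {
  m <- regmatches(stmt, regexec(paste0(
    "^MATCH\\s+(.*?)\\s*(?:WHERE\\s+(.*?)\\s*)?RETURN\\s+(.*?)",
    "\\s*(?:LIMIT\\s+([0-9]+)\\s*)?$"), stmt, ignore.case = TRUE,
    perl = TRUE))[[1]]
  if (length(m) == 0 || m[1] == "")
    pr_abort(paste0("unsupported statement (need MATCH ... RETURN ...): ",
                    stmt), "phenorag_unsupported_query")
  pat <- parse_match_pattern(m[2])
  wh <- parse_where(m[3])
  ret_items <- trimws(strsplit(m[4], ",", fixed = TRUE)[[1]])
  lim <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_

  vars <- vapply(pat$vars, `[[`, character(1), "var")
  cand <- lapply(pat$vars, function(v) candidate_idx(kg, v))
  # progressive join over hops
  bind <- data.frame(v1 = cand[[1]])
  names(bind) <- vars[1]
  if (length(pat$rels)) {
    for (h in seq_along(pat$rels)) {
      r <- pat$rels[[h]]
      e <- kg$edges[kg$edges$relation == r$relation, , drop = FALSE]
      si <- match(e$source, kg$nodes$id)
      ti <- match(e$target, kg$nodes$id)
      step <- if (r$direction == "forward")
        data.frame(from = si, to = ti) else data.frame(from = ti, to = si)
      step <- step[step$to %in% cand[[h + 1]], , drop = FALSE]
      names(step) <- c(vars[h], vars[h + 1])
      bind <- merge(bind, step, by = vars[h])
      if (!nrow(bind)) break
    }
  }
  if (nrow(bind)) {
    # distinct variables must bind distinct nodes within a row
    if (ncol(bind) > 1) {
      ok <- apply(bind, 1, function(r) !anyDuplicated(r))
      bind <- bind[ok, , drop = FALSE]
    }
    for (cond in wh) {
      if (!(cond$var %in% names(bind)))
        pr_abort(paste0("WHERE references unknown variable: ", cond$var),
                 "phenorag_unsupported_query")
      vals <- node_prop(kg, bind[[cond$var]], cond$prop)
      keep <- if (cond$op == "=") !is.na(vals) & vals == cond$value
      else !is.na(vals) & grepl(cond$value, vals, fixed = TRUE)
      bind <- bind[keep, , drop = FALSE]
    }
  }
  rows <- as.data.frame(lapply(ret_items, function(it) {
    mi <- regmatches(it, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\.([A-Za-z_][A-Za-z0-9_]*)$", it))[[1]]
    if (length(mi) != 3)
      pr_abort(paste0("unsupported RETURN item: ", it),
               "phenorag_unsupported_query")
    if (!(mi[2] %in% names(bind)))
      pr_abort(paste0("RETURN references unknown variable: ", mi[2]),
               "phenorag_unsupported_query")
    node_prop(kg, bind[[mi[2]]], mi[3])
  }), stringsAsFactors = FALSE)
  names(rows) <- ret_items
  if (nrow(rows)) {
    rows <- unique(rows)
    rows <- rows[do.call(c_order, unname(as.list(rows))), , drop = FALSE]
    rownames(rows) <- NULL
    if (!is.na(lim)) rows <- head(rows, lim)
  }
  matched_ids <- unique(kg$nodes$id[unlist(bind)])
  list(rows = rows, subgraph = induced_subgraph(kg, matched_ids))
}

#' Generate a Cypher query through a language model
#'
#' The prompt injects a schema description derived from the policy.  The
#' model's output is returned verbatim alongside a sanitization report:
#' data-modifying clauses are stripped and flagged; output without a
#' parseable `MATCH ... RETURN` raises `phenorag_cypher_generation_error`
#' (callers apply the configured fallback).
#'
#' @param llm A language-model port (see [mock_model()]).
#' @param schema A [schema_policy()].
#' @param question Question text.
#' @param settings [generation_settings()].
#' @return List with `query` (sanitized), `raw`, `flags`.
#' @export
generate_cypher <- function(llm, schema, question,
                            settings = generation_settings()) {
  schema_desc <- paste(
    sprintf("(:%s)-[:%s]->(:%s)", schema$source_kind, schema$relation,
            schema$target_kind), collapse = "\n")
  prompt <- paste0(
    "Translate the question into a single Cypher MATCH query.\n",
    "Graph schema (allowed patterns):\n", schema_desc, "\n",
    "Nodes carry a `name` property. Reply with the query only.\n",
    "Question: ", question, "\n")
  raw <- llm$complete(prompt, settings)
  flags <- character()
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  bad <- grepl("\\b(DELETE|DETACH|REMOVE|SET|MERGE|DROP|CREATE)\\b", lines,
               ignore.case = TRUE)
  if (any(bad)) {
    flags <- paste0("stripped data-modifying clause: ",
                    trimws(lines[bad]))
    lines <- lines[!bad]
  }
  query <- trimws(paste(lines, collapse = "\n"))
  if (!grepl("MATCH", query, ignore.case = TRUE) ||
      !grepl("RETURN", query, ignore.case = TRUE))
    pr_abort("model output contains no MATCH ... RETURN query",
             "phenorag_cypher_generation_error")
  list(query = query, raw = raw, flags = flags)
}

#' Cypher retrieval route
#'
#' Generates a query via the model, executes it against the graph, and
#' serializes the matched subgraph as context.  Generation or execution
#' failure triggers the configured fallback (`empty_context` mirrors the
#' degradation seen when a model cannot write Cypher; `vector` delegates
#' to [vector_retrieve()]).
#'
#' @inheritParams generate_cypher
#' @param kg A `phenorag_kg`.
#' @param config A [retriever_config()].
#' @return A `phenorag_context`.
#' @export
cypher_retrieve <- function(kg, question, llm,
                            config = retriever_config(),
                            settings = generation_settings()) {
  res <- tryCatch({
    gen <- generate_cypher(llm, kg$schema, question, settings)
    out <- query_graph(kg, gen$query)
    new_context(out$subgraph,
                data.frame(surface = character(), node_id = character(),
                           score = numeric(), method = character(),
                           stringsAsFactors = FALSE),
                "cypher", question,
                c(paste0("cypher: ", gen$query), gen$flags),
                config$char_budget)
  }, phenorag_cypher_generation_error = function(e) e,
     phenorag_unsupported_query = function(e) e)
  if (inherits(res, "error")) {
    if (config$fallback == "vector")
      return(vector_retrieve(kg, question, config))
    if (config$fallback == "empty_context")
      return(new_context(induced_subgraph(kg, character()),
                         data.frame(surface = character(),
                                    node_id = character(),
                                    score = numeric(),
                                    method = character(),
                                    stringsAsFactors = FALSE),
                         "cypher", question,
                         paste0("fallback after failure: ",
                                conditionMessage(res))))
    stop(res)
  }
  res
}
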