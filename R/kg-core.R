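#' @title Typed phenotype-gene-disease knowledge graph
#' @description
#' The knowledge graph is a directed, typed property graph with six
#' persistable node kinds (Article, Disease, Genotype, Variation,
#' FacePhenotype, Sample) and seven relation kinds.  A seventh node kind,
#' `Query`, is transient: the vector retriever inserts it while ranking and
#' it never appears in persisted graphs.
#' @name kg_core
NULL

NODE_KINDS <- c("Article", "Disease", "Genotype", "Variation",
                "FacePhenotype", "Sample", "Query")

RELATION_KINDS <- c("Affect", "Cause", "Exist", "Has_Phenotype", "Have",
                    "Mention_FP", "Mention_Var", "Mention_Query")

# alternative relation spellings seen in diagram-style exports
RELATION_ALIASES <- c(From = "Exist", Exhibit = "Has_Phenotype",
                      with_FP = "Mention_FP", with_Var = "Mention_Var")

#' Node kinds and relation kinds of the graph schema
#'
#' @return Character vector of recognised labels.
#' @export
node_kinds <- function() NODE_KINDS

#' @rdname node_kinds
#' @export
relation_kinds <- function() RELATION_KINDS

#' Schema policy: the allowed (source kind, relation, target kind) triples
#'
#' The default policy encodes the seven persisted relation types:
#' Genotype-Affect->FacePhenotype, Variation-Cause->Disease,
#' Sample-Exist->Article, Disease-Has_Phenotype->FacePhenotype,
#' Variation-Have->Genotype, Sample-Mention_FP->FacePhenotype and
#' Sample-Mention_Var->Variation.  Mention_Var endpoints are
#' Sample -> Variation: its count sits next to the Variation node count and
#' the variation-disease link is already carried by Cause.  The policy is a
#' plain data frame so alternative readings can be supplied.
#'
#' @param allowed Optional data frame with columns `source_kind`,
#'   `relation`, `target_kind` replacing the default triples.
#' @return A `phenorag_schema` data frame.
#' @export
schema_policy <- function(allowed = NULL) {
  if (is.null(allowed)) {
    allowed <- data.frame(
      source_kind = c("Genotype", "Variation", "Sample", "Disease",
                      "Variation", "Sample", "Sample"),
      relation    = c("Affect", "Cause", "Exist", "Has_Phenotype",
                      "Have", "Mention_FP", "Mention_Var"),
      target_kind = c("FacePhenotype", "Disease", "Article",
                      "FacePhenotype", "Genotype", "FacePhenotype",
                      "Variation"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("source_kind", "relation", "target_kind") %in%
                  names(allowed)))
  if (nrow(allowed) == 0)
    pr_abort("schema policy must allow at least one triple",
             "phenorag_schema_error")
  bad <- setdiff(allowed$relation, RELATION_KINDS)
  if (length(bad))
    pr_abort(paste0("unknown relation kind(s): ", paste(bad, collapse = ", ")),
             "phenorag_schema_error")
  structure(allowed, class = c("phenorag_schema", "data.frame"))
}

empty_nodes <- function() {
  data.frame(id = character(), kind = character(), name = character(),
             synonyms = I(list()), properties = I(list()),
             stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(source = character(), relation = character(),
             target = character(), stringsAsFactors = FALSE)
}

#' Construct a validated knowledge graph
#'
#' @param nodes Data frame with columns `id`, `kind`, `name` and optional
#'   list-columns `synonyms` (character vectors) and `properties` (named
#'   character vectors).
#' @param edges Data frame with columns `source`, `relation`, `target`.
#' @param schema A [schema_policy()].
#' @param allow_query Permit transient `Query` nodes and `Mention_Query`
#'   edges (used internally by the vector retriever, never when persisting).
#' @return A `phenorag_kg` object.
#' @export
knowledge_graph <- function(nodes = empty_nodes(), edges = empty_edges(),
                            schema = schema_policy(), allow_query = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) && !all(c("id", "kind", "name") %in% names(nodes)))
    pr_abort("nodes need columns id, kind, name", "phenorag_input_error")
  if (is.null(nodes$synonyms)) nodes$synonyms <- I(rep(list(character()),
                                                       nrow(nodes)))
  if (is.null(nodes$properties)) nodes$properties <- I(rep(list(character()),
                                                           nrow(nodes)))
  if (anyDuplicated(nodes$id))
    pr_abort(paste0("duplicate node id(s): ",
                    paste(unique(nodes$id[duplicated(nodes$id)]),
                          collapse = ", ")),
             "phenorag_integrity_error")
  kinds_ok <- if (allow_query) NODE_KINDS else setdiff(NODE_KINDS, "Query")
  bad <- setdiff(nodes$kind, kinds_ok)
  if (length(bad))
    pr_abort(paste0("unknown or non-persistable node kind(s): ",
                    paste(bad, collapse = ", ")),
             "phenorag_schema_error")
  if (nrow(nodes) && any(!nzchar(nodes$name)))
    pr_abort("node names must be non-empty", "phenorag_input_error")
  # drop synonym duplicates after normalization
  nodes$synonyms <- I(lapply(nodes$synonyms, function(s) {
    s <- as.character(s)
    s[!duplicated(norm_name(s))]
  }))

  if (nrow(edges)) {
    if (!all(c("source", "relation", "target") %in% names(edges)))
      pr_abort("edges need columns source, relation, target",
               "phenorag_input_error")
    edges$relation <- ifelse(edges$relation %in% names(RELATION_ALIASES),
                             RELATION_ALIASES[edges$relation],
                             edges$relation)
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing))
      pr_abort(paste0("edge endpoint(s) not in node set: ",
                      paste(head(missing, 5), collapse = ", ")),
               "phenorag_integrity_error")
    key <- paste(edges$source, edges$relation, edges$target, sep = "\r")
    if (anyDuplicated(key))
      pr_abort("duplicate (source, relation, target) edges",
               "phenorag_integrity_error")
  }

  kg <- structure(list(nodes = nodes, edges = edges, schema = schema),
                  class = "phenorag_kg")
  viol <- validate_schema(kg, allow_query = allow_query)
  if (length(viol))
    pr_abort(paste0("schema violation: ", viol[[1]]), "phenorag_schema_error")
  kg
}

#' @export
print.phenorag_kg <- function(x, ...) {
  st <- graph_stats(x)
  cat("<phenorag knowledge graph> ", st$node_total, " nodes, ",
      st$edge_total, " edges\n", sep = "")
  invisible(x)
}

node_kind_of <- function(kg, ids) {
  kg$nodes$kind[match(ids, kg$nodes$id)]
}

node_name_of <- function(kg, ids) {
  kg$nodes$name[match(ids, kg$nodes$id)]
}

#' Check every edge against the schema policy
#'
#' Violations are returned as data, one message per offending edge; an empty
#' list means the graph is schema-conformant.
#'
#' @param kg A `phenorag_kg`.
#' @param allow_query Also accept Query/Mention_Query plumbing.
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_schema <- function(kg, allow_query = FALSE) {
  if (!nrow(kg$edges)) return(character())
  allowed <- paste(kg$schema$source_kind, kg$schema$relation,
                   kg$schema$target_kind, sep = "\r")
  if (allow_query) {
    qk <- expand.grid(s = "Query", r = "Mention_Query",
                      t = setdiff(NODE_KINDS, "Query"))
    allowed <- c(allowed, paste(qk$s, qk$r, qk$t, sep = "\r"))
  }
  sk <- node_kind_of(kg, kg$edges$source)
  tk <- node_kind_of(kg, kg$edges$target)
  key <- paste(sk, kg$edges$relation, tk, sep = "\r")
  bad <- which(!(key %in% allowed))
  vapply(bad, function(i) {
    sprintf("edge %s -(%s)-> %s: (%s, %s, %s) not allowed by schema",
            kg$edges$source[i], kg$edges$relation[i], kg$edges$target[i],
            sk[i], kg$edges$relation[i], tk[i])
  }, character(1))
}

#' Node and edge counts by kind
#'
#' @param kg A `phenorag_kg`.
#' @return List with `node_counts`, `edge_counts`, `node_total`,
#'   `edge_total`.
#' @export
graph_stats <- function(kg) {
  nk <- setdiff(NODE_KINDS, "Query")
  node_counts <- vapply(nk, function(k) sum(kg$nodes$kind == k), integer(1))
  rk <- setdiff(RELATION_KINDS, "Mention_Query")
  edge_counts <- vapply(rk, function(r) sum(kg$edges$relation == r),
                        integer(1))
  list(node_counts = node_counts, edge_counts = edge_counts,
       node_total = nrow(kg$nodes), edge_total = nrow(kg$edges))
}

serialize_props <- function(p) {
  if (!length(p)) return("")
  paste(paste0(names(p), "=", unname(p)), collapse = ";")
}

parse_props <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE),
                   invert = TRUE)
  out <- vapply(kv, function(x) if (length(x) == 2) x[2] else "",
                character(1))
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Read a knowledge graph from node and edge tables
#'
#' Tables are UTF-8 TSV with a header row.  The node table has columns
#' `id`, `kind`, `name`, optional `synonyms` (pipe-delimited) and optional
#' `properties` (semicolon-separated `key=value` pairs).  The edge table
#' has columns `source`, `relation`, `target`.
#'
#' @param node_table,edge_table File paths.
#' @param schema A [schema_policy()].
#' @return A validated `phenorag_kg`.
#' @export
load_graph <- function(node_table, edge_table, schema = schema_policy()) {
  for (p in c(node_table, edge_table))
    if (!file.exists(p))
      pr_abort(paste0("file not found: ", p), "phenorag_input_error")
  rd <- function(p) read.delim(p, sep = "\t", quote = "", comment.char = "",
                               stringsAsFactors = FALSE,
                               colClasses = "character",
                               fileEncoding = "UTF-8")
  nt <- rd(node_table)
  et <- rd(edge_table)
  nodes <- if (nrow(nt) == 0) empty_nodes() else {
    if (!all(c("id", "kind", "name") %in% names(nt)))
      pr_abort("node table needs columns id, kind, name",
               "phenorag_input_error")
    syn <- if ("synonyms" %in% names(nt)) {
      lapply(nt$synonyms, function(s)
        if (is.na(s) || !nzchar(s)) character()
        else strsplit(s, "|", fixed = TRUE)[[1]])
    } else rep(list(character()), nrow(nt))
    props <- if ("properties" %in% names(nt)) {
      lapply(nt$properties, parse_props)
    } else rep(list(character()), nrow(nt))
    data.frame(id = nt$id, kind = nt$kind, name = nt$name,
               synonyms = I(syn), properties = I(props),
               stringsAsFactors = FALSE)
  }
  edges <- if (nrow(et) == 0) empty_edges() else {
    if (!all(c("source", "relation", "target") %in% names(et)))
      pr_abort("edge table needs columns source, relation, target",
               "phenorag_input_error")
    et[, c("source", "relation", "target")]
  }
  knowledge_graph(nodes, edges, schema)
}

#' Write a knowledge graph to node and edge tables
#'
#' Rows are sorted (nodes by id; edges by source, relation, target) so two
#' writes of the same graph are byte-identical.
#'
#' @param kg A `phenorag_kg`.
#' @param node_table,edge_table Output file paths.
#' @export
write_graph <- function(kg, node_table, edge_table) {
  n <- kg$nodes[c_order(kg$nodes$id), , drop = FALSE]
  out_n <- data.frame(
    id = n$id, kind = n$kind, name = n$name,
    synonyms = vapply(n$synonyms, paste, character(1), collapse = "|"),
    properties = vapply(n$properties, serialize_props, character(1)),
    stringsAsFactors = FALSE
  )
  e <- kg$edges[c_order(kg$edges$source, kg$edges$relation, kg$edges$target),
                , drop = FALSE]
  wr <- function(df, p) {
    con <- tryCatch(file(p, open = "wb"), error = function(e)
      pr_abort(paste0("cannot write: ", p), "phenorag_io_error"))
    on.exit(close(con))
    writeLines(c(paste(names(df), collapse = "\t"),
                 if (nrow(df)) do.call(paste, c(unname(df), sep = "\t"))),
               con, useBytes = TRUE)
  }
  wr(out_n, node_table)
  wr(e, edge_table)
  invisible(NULL)
}

cypher_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a graph as CREATE statements
#'
#' Emits one statement per node and per relationship in the property-graph
#' query dialect understood by [query_graph()]'s data-definition mode, so
#' replaying the text reconstructs an equal graph.
#'
#' @param kg A `phenorag_kg`.
#' @return A single string, one statement per line (empty for the empty
#'   graph).
#' @export
export_cypher <- function(kg) {
  n <- kg$nodes[c_order(kg$nodes$id), , drop = FALSE]
  node_stmt <- vapply(seq_len(nrow(n)), function(i) {
    props <- c(id = n$id[i], name = n$name[i])
    if (length(n$synonyms[[i]]))
      props <- c(props, synonyms = paste(n$synonyms[[i]], collapse = "|"))
    props <- c(props, n$properties[[i]])
    sprintf("CREATE (:%s {%s})", n$kind[i],
            paste(paste0(names(props), ": ", cypher_quote(props)),
                  collapse = ", "))
  }, character(1))
  e <- kg$edges[c_order(kg$edges$source, kg$edges$relation, kg$edges$target),
                , drop = FALSE]
  edge_stmt <- vapply(seq_len(nrow(e)), function(i) {
    sprintf("MATCH (a {id: %s}), (b {id: %s}) CREATE (a)-[:%s]->(b)",
            cypher_quote(e$source[i]), cypher_quote(e$target[i]),
            e$relation[i])
  }, character(1))
  paste(c(node_stmt, edge_stmt), collapse = "\n")
}

# induced subgraph on a set of node ids (edges with both endpoints kept)
induced_subgraph <- function(kg, ids) {
  ids <- unique(ids)
  nodes <- kg$nodes[kg$nodes$id %in% ids, , drop = FALSE]
  keep <- kg$edges$source %in% ids & kg$edges$target %in% ids
  edges <- kg$edges[keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, schema = kg$schema),
            class = "phenorag_kg")
}

# undirected adjacency list keyed by node id
adjacency_list <- function(kg) {
  adj <- split(c(kg$edges$target, kg$edges$source),
               c(kg$edges$source, kg$edges$target))
  ids <- kg$nodes$id
  out <- rep(list(character()), length(ids))
  names(out) <- ids
  out[names(adj)] <- lapply(adj, unique)
  out
}

graphs_equal <- function(a, b) {
  na <- a$nodes[c_order(a$nodes$id), ]
  nb <- b$nodes[c_order(b$nodes$id), ]
  if (!identical(na$id, nb$id) || !identical(na$kind, nb$kind) ||
      !identical(na$name, nb$name))
    return(FALSE)
  syn_eq <- all(mapply(function(x, y) identical(as.character(x),
                                                as.character(y)),
                       na$synonyms, nb$synonyms))
  prop_eq <- all(mapply(function(x, y) {
    x <- unlist(x); y <- unlist(y)
    length(x) == length(y) && setequal(names(x), names(y)) &&
      all(x[names(x)] == y[names(x)])
  }, na$properties, nb$properties))
  ka <- sort(paste(a$edges$source, a$edges$relation, a$edges$target))
  kb <- sort(paste(b$edges$source, b$edges$relation, b$edges$target))
  syn_eq && prop_eq && identical(ka, kb)
}
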