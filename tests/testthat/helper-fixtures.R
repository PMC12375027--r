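# fixture builders shared across test files; everything is generated in
# code so the suite needs no data files

# the worked six-phenotype CHD7 case
chd7_case <- function() {
  case_record(age_years = 5, gender = "female", ethnicity = "Turkish",
              gene = "CHD7", variant = "c. 2443-2 A > G",
              phenotypes = c("Wide nasal bridge", "Posteriorly rotated ears",
                             "Thin upper lip vermilion",
                             "Chorioretinal coloboma", "Protruding ear",
                             "Proptosis"),
              diagnosis = "CHARGE syndrome", source = "10.1016/test")
}

# hand-built graph around the CHD7 case: 1 disease, 1 genotype, 1
# variation, 6 phenotypes, 1 sample, 1 article
chd7_graph <- function() {
  ph_names <- chd7_case()$phenotypes
  nodes <- data.frame(
    id = c("d1", "g1", "v1", paste0("p", 1:6), "s1", "a1"),
    kind = c("Disease", "Genotype", "Variation", rep("FacePhenotype", 6),
             "Sample", "Article"),
    name = c("CHARGE syndrome", "CHD7", "c. 2443-2 A > G", ph_names,
             "patient 1", "article 1"),
    stringsAsFactors = FALSE)
  nodes$synonyms <- I(c(list(character()), list(character()),
                        list(character()), list("Broad nasal bridge"),
                        rep(list(character()), 5), list(character()),
                        list(character())))
  nodes$properties <- I(c(list(c(omim = "214800")),
                          rep(list(character()), 10)))
  edges <- rbind(
    data.frame(source = "d1", relation = "Has_Phenotype",
               target = paste0("p", 1:6), stringsAsFactors = FALSE),
    data.frame(source = "g1", relation = "Affect",
               target = paste0("p", 1:6), stringsAsFactors = FALSE),
    data.frame(source = "v1", relation = c("Cause", "Have"),
               target = c("d1", "g1"), stringsAsFactors = FALSE),
    data.frame(source = "s1", relation = c("Exist", "Mention_Var",
                                           "Mention_FP"),
               target = c("a1", "v1", "p1"), stringsAsFactors = FALSE))
  knowledge_graph(nodes, edges)
}

# random schema-valid graph built edge-by-edge from the allowed triples
random_valid_graph <- function(n_per_kind = 4, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  kinds <- setdiff(node_kinds(), "Query")
  nodes <- data.frame(
    id = paste0("n", seq_len(n_per_kind * length(kinds))),
    kind = rep(kinds, each = n_per_kind),
    stringsAsFactors = FALSE)
  nodes$name <- paste(nodes$kind, nodes$id)
  pol <- schema_policy()
  edges <- do.call(rbind, lapply(seq_len(nrow(pol)), function(r) {
    src <- nodes$id[nodes$kind == pol$source_kind[r]]
    tgt <- nodes$id[nodes$kind == pol$target_kind[r]]
    grid <- expand.grid(source = src, target = tgt,
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < p_edge, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    data.frame(source = grid$source, relation = pol$relation[r],
               target = grid$target, stringsAsFactors = FALSE)
  }))
  knowledge_graph(nodes, if (is.null(edges)) NULL else edges)
}

# small synthetic world reused by end-to-end tests
small_world <- function(seed = 11, overlap = 0.5, cases_per_disease = 10) {
  cfg <- synth_config(
    node_counts = c(Article = 5, Disease = 20, Genotype = 12,
                    Variation = 30, FacePhenotype = 60, Sample = 15),
    phenotypes_per_disease = c(4, 6), phenotype_overlap = overlap,
    cases_per_disease = c(cases_per_disease, cases_per_disease),
    case_phenotype_subset = 1, noise_rate = 0, seed = seed)
  kg <- generate_kg(cfg)
  cases <- generate_cases(kg, cfg)
  list(cfg = cfg, kg = kg, cases = cases)
}

# independent exhaustive pattern-match oracle: enumerate every node tuple
# and keep those satisfying labels, property constraints, hops and WHERE;
# intentionally brute force, no shared code with query_graph
oracle_match <- function(kg, specs, rels, where = list(), ret) {
  n <- nrow(kg$nodes)
  prop_of <- function(i, prop) {
    switch(prop, id = kg$nodes$id[i], name = kg$nodes$name[i],
           kind = kg$nodes$kind[i], {
             p <- kg$nodes$properties[[i]]
             if (prop %in% names(p)) unname(p[[prop]]) else NA_character_
           })
  }
  node_ok <- function(i, spec) {
    if (!is.null(spec$label) && kg$nodes$kind[i] != spec$label)
      return(FALSE)
    for (k in names(spec$props)) {
      v <- prop_of(i, k)
      if (is.na(v) || v != spec$props[[k]]) return(FALSE)
    }
    TRUE
  }
  edge_ok <- function(i, j, rel, dir) {
    e <- kg$edges
    if (dir == "forward")
      any(e$source == kg$nodes$id[i] & e$relation == rel &
            e$target == kg$nodes$id[j])
    else
      any(e$source == kg$nodes$id[j] & e$relation == rel &
            e$target == kg$nodes$id[i])
  }
  k <- length(specs)
  tuples <- do.call(expand.grid, rep(list(seq_len(n)), k))
  rows <- list()
  for (t in seq_len(nrow(tuples))) {
    tp <- as.integer(tuples[t, ])
    if (k > 1 && anyDuplicated(tp)) next
    ok <- all(vapply(seq_len(k), function(i) node_ok(tp[i], specs[[i]]),
                     logical(1)))
    if (ok && length(rels))
      ok <- all(vapply(seq_along(rels), function(h)
        edge_ok(tp[h], tp[h + 1], rels[[h]]$rel, rels[[h]]$dir),
        logical(1)))
    if (ok)
      for (w in where) {
        v <- prop_of(tp[w$var_idx], w$prop)
        ok <- ok && !is.na(v) &&
          if (w$op == "=") v == w$value else grepl(w$value, v, fixed = TRUE)
      }
    if (ok)
      rows[[length(rows) + 1L]] <- vapply(ret, function(r)
        prop_of(tp[r$var_idx], r$prop), character(1))
  }
  if (!length(rows))
    return(as.data.frame(matrix(character(), ncol = length(ret))))
  df <- unique(as.data.frame(do.call(rbind, rows),
                             stringsAsFactors = FALSE))
  df <- df[do.call(order, c(unname(as.list(df)), method = "radix")), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
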