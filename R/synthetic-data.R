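#' @title Synthetic knowledge graphs and case records
#' @description
#' Generates schema-valid graphs whose type composition mirrors a curated
#' facial-phenotype knowledge graph, plus patient case records drawn from
#' the generated disease-phenotype associations.  Diagnostic ambiguity is
#' controlled by a confuser-pair design: diseases are paired and each pair
#' shares a configurable fraction of phenotypes, emulating clinically
#' overlapping syndromes.
#' @name synthetic_data
NULL

#' Configuration for the synthetic generator
#'
#' Default node counts reproduce the composition of the reference curated
#' graph: 509 articles, 225 diseases, 397 genotypes, 1242 variations, 2623
#' facial phenotypes and 1147 patient samples (6143 nodes).
#'
#' @param node_counts Named integer vector over the six persistable kinds.
#' @param phenotypes_per_disease Integer range `c(lo, hi)` of phenotypes
#'   wired to each disease.
#' @param phenotype_overlap Fraction in `[0, 1]` of a disease's phenotypes
#'   shared with its designated confuser disease.
#' @param variants_per_gene Integer range of variations per genotype.
#' @param cases_per_disease Integer range of case records per disease.
#' @param case_phenotype_subset Fraction in `(0, 1]` of a disease's
#'   phenotypes included in each case.
#' @param noise_rate Expected number of spurious phenotypes per case.
#' @param seed Integer seed; the whole generation is a pure function of the
#'   configuration.
#' @return A `phenorag_synth_config` list.
#' @export
synth_config <- function(node_counts = c(Article = 509L, Disease = 225L,
                                         Genotype = 397L, Variation = 1242L,
                                         FacePhenotype = 2623L,
                                         Sample = 1147L),
                         phenotypes_per_disease = c(5L, 12L),
                         phenotype_overlap = 0,
                         variants_per_gene = c(1L, 4L),
                         cases_per_disease = c(1L, 3L),
                         case_phenotype_subset = 0.8,
                         noise_rate = 0,
                         seed = 1L) {
  stopifnot(all(node_counts >= 0),
            phenotypes_per_disease[1] <= phenotypes_per_disease[2],
            phenotype_overlap >= 0, phenotype_overlap <= 1,
            variants_per_gene[1] <= variants_per_gene[2],
            cases_per_disease[1] <= cases_per_disease[2],
            case_phenotype_subset > 0, case_phenotype_subset <= 1,
            noise_rate >= 0, noise_rate <= 1e6)
  kinds <- setdiff(node_kinds(), "Query")
  counts <- setNames(integer(length(kinds)), kinds)
  counts[names(node_counts)] <- as.integer(node_counts)
  structure(list(node_counts = counts,
                 phenotypes_per_disease = as.integer(phenotypes_per_disease),
                 phenotype_overlap = phenotype_overlap,
                 variants_per_gene = as.integer(variants_per_gene),
                 cases_per_disease = as.integer(cases_per_disease),
                 case_phenotype_subset = case_phenotype_subset,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "phenorag_synth_config")
}

synth_ids <- function(kind, n) {
  prefix <- c(Article = "ART", Disease = "DIS", Genotype = "GEN",
              Variation = "VAR", FacePhenotype = "PHEN", Sample = "SAM")[kind]
  if (n == 0) return(character())
  sprintf("%s-%04d", prefix, seq_len(n))
}

synth_names <- function(kind, n) {
  ids <- synth_ids(kind, n)
  if (kind == "Variation") {
    # plausible coding-change notation, unique per variation
    sprintf("c. %d%s > %s", 100L + 7L * seq_len(n),
            c("A", "C", "G", "T")[1 + (seq_len(n) %% 4)],
            c("G", "T", "A", "C")[1 + (seq_len(n) %% 4)])
  } else ids
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a schema-valid synthetic knowledge graph
#'
#' Diseases get `Has_Phenotype` edges with the configured confuser-pair
#' overlap; variations get `Have` (genotype) and `Cause` (disease) edges;
#' genotypes get `Affect` edges to the phenotypes of the diseases their
#' variations cause; samples get `Exist` (article), `Mention_FP` and
#' `Mention_Var` edges.
#'
#' @param config A [synth_config()].
#' @return A validated `phenorag_kg`.
#' @export
generate_kg <- function(config) {
  nc <- config$node_counts
  with_seed(config$seed, {
    kinds <- names(nc)
    nodes <- do.call(rbind, lapply(kinds, function(k) {
      n <- nc[[k]]
      if (n == 0) return(NULL)
      data.frame(id = synth_ids(k, n), kind = k, name = synth_names(k, n),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(nodes)) nodes <- empty_nodes()
    nodes$synonyms <- I(rep(list(character()), nrow(nodes)))
    nodes$properties <- I(rep(list(character()), nrow(nodes)))
    # every second phenotype gets a synonym so lexicon matching is testable
    ph <- which(nodes$kind == "FacePhenotype")
    if (length(ph)) {
      even <- ph[seq_along(ph) %% 2 == 0]
      nodes$synonyms[even] <- lapply(nodes$id[even],
                                     function(i) paste0("syn ", i))
    }

    dis <- nodes$id[nodes$kind == "Disease"]
    phen <- nodes$id[nodes$kind == "FacePhenotype"]
    gen <- nodes$id[nodes$kind == "Genotype"]
    var <- nodes$id[nodes$kind == "Variation"]
    sam <- nodes$id[nodes$kind == "Sample"]
    art <- nodes$id[nodes$kind == "Article"]

    edges <- list()

    # Disease -Has_Phenotype-> FacePhenotype with confuser-pair overlap
    dis_phen <- list()
    if (length(dis) && length(phen)) {
      sizes <- rint(length(dis), config$phenotypes_per_disease)
      sizes <- pmin(sizes, length(phen))
      for (i in seq_along(dis)) {
        partner <- if (i %% 2 == 0) i - 1L else i + 1L
        shared <- character()
        prev <- character()
        if (partner >= 1 && partner <= length(dis) && partner < i) {
          prev <- dis_phen[[dis[partner]]]
          if (config$phenotype_overlap > 0) {
            n_shared <- min(floor(config$phenotype_overlap * sizes[i]),
                            length(prev))
            if (n_shared < 1 && config$phenotype_overlap * sizes[i] >= 1)
              pr_abort("overlap demands more phenotypes than exist",
                       "phenorag_generation_error")
            shared <- sample(prev, n_shared)
          }
        }
        # the rest of the pair's phenotypes stay disjoint so the designed
        # overlap fraction is exact; tight vocabularies truncate the draw
        pool <- setdiff(phen, c(shared, prev))
        own <- sample(pool, min(max(sizes[i] - length(shared), 0),
                                length(pool)))
        dis_phen[[dis[i]]] <- c(shared, own)
      }
      edges$hp <- data.frame(
        source = rep(dis, lengths(dis_phen[dis])),
        relation = "Has_Phenotype",
        target = unlist(dis_phen[dis], use.names = FALSE),
        stringsAsFactors = FALSE)
    }

    # Variation -Have-> Genotype and -Cause-> Disease
    var_gene <- character(); var_dis <- character()
    if (length(var) && length(gen)) {
      var_gene <- setNames(sample(gen, length(var), replace = TRUE), var)
      edges$have <- data.frame(source = var, relation = "Have",
                               target = unname(var_gene),
                               stringsAsFactors = FALSE)
    }
    if (length(var) && length(dis)) {
      # guarantee every disease has at least one causal variant when possible
      base <- if (length(var) >= length(dis))
        c(dis, sample(dis, length(var) - length(dis), replace = TRUE))
      else sample(dis, length(var))
      var_dis <- setNames(sample(base), var)
      edges$cause <- data.frame(source = var, relation = "Cause",
                                target = unname(var_dis),
                                stringsAsFactors = FALSE)
    }

    # Genotype -Affect-> FacePhenotype of the diseases its variants cause
    if (length(var) && length(gen) && length(dis) && length(phen)) {
      aff <- unique(do.call(rbind, lapply(var, function(v) {
        d <- var_dis[[v]]
        ph_d <- dis_phen[[d]] %||% character()
        if (!length(ph_d)) return(NULL)
        data.frame(source = var_gene[[v]], relation = "Affect",
                   target = ph_d, stringsAsFactors = FALSE)
      })))
      edges$affect <- aff
    }

    # Sample -Exist-> Article, -Mention_FP-> phenotypes, -Mention_Var-> var
    if (length(sam) && length(art)) {
      edges$exist <- data.frame(source = sam, relation = "Exist",
                                target = sample(art, length(sam),
                                                replace = TRUE),
                                stringsAsFactors = FALSE)
    }
    if (length(sam) && length(var)) {
      sam_var <- setNames(sample(var, length(sam), replace = TRUE), sam)
      edges$mvar <- unique(data.frame(source = sam, relation = "Mention_Var",
                                      target = unname(sam_var),
                                      stringsAsFactors = FALSE))
      if (length(dis) && length(phen)) {
        mfp <- do.call(rbind, lapply(sam, function(s) {
          d <- var_dis[[sam_var[[s]]]]
          ph_d <- dis_phen[[d]] %||% character()
          if (!length(ph_d)) return(NULL)
          k <- max(1L, ceiling(0.6 * length(ph_d)))
          data.frame(source = s, relation = "Mention_FP",
                     target = sample(ph_d, k), stringsAsFactors = FALSE)
        }))
        edges$mfp <- mfp
      }
    }

    edges <- do.call(rbind, edges)
    if (is.null(edges)) edges <- empty_edges()
    edges <- unique(edges)
    rownames(edges) <- NULL
    knowledge_graph(nodes, edges)
  })
}

#' Generate case records from a knowledge graph
#'
#' Each case samples a disease with at least one causal variant, one of its
#' variants and that variant's genotype, a phenotype subset of configurable
#' size plus Poisson-distributed spurious phenotypes, and demographics from
#' small fixed vocabularies.  The diagnosis is recorded as ground truth.
#'
#' @param kg A `phenorag_kg` (typically from [generate_kg()]).
#' @param config A [synth_config()].
#' @return List of `phenorag_case` records (see [case_record()]).
#' @export
generate_cases <- function(kg, config) {
  e <- kg$edges
  dis <- kg$nodes$id[kg$nodes$kind == "Disease"]
  cause <- e[e$relation == "Cause", ]
  have <- e[e$relation == "Have", ]
  hp <- e[e$relation == "Has_Phenotype", ]
  phen_all <- kg$nodes$id[kg$nodes$kind == "FacePhenotype"]
  if (!nrow(cause))
    pr_abort("graph has no disease with a causal variant",
             "phenorag_generation_error")
  genders <- c("female", "male")
  ethnicities <- c("Turkish", "Chinese", "German", "Brazilian", "Japanese",
                   "Nigerian", "Finnish", "Indian")
  with_seed(derive_seed(config$seed, "cases"), {
    cases <- list()
    for (d in dis) {
      vars_d <- cause$source[cause$target == d]
      if (!length(vars_d)) next  # disease without variant: skipped
      ph_d <- hp$target[hp$source == d]
      if (!length(ph_d)) next
      n_cases <- rint(1, config$cases_per_disease)
      for (j in seq_len(n_cases)) {
        v <- if (length(vars_d) == 1) vars_d else sample(vars_d, 1)
        g <- have$target[have$source == v][1]
        k <- ceiling(config$case_phenotype_subset * length(ph_d))
        ph_case <- if (length(ph_d) == 1) ph_d else sample(ph_d, k)
        n_noise <- stats::rpois(1, config$noise_rate)
        noise_pool <- setdiff(phen_all, ph_d)
        if (n_noise > 0 && length(noise_pool))
          ph_case <- c(ph_case, sample(noise_pool,
                                       min(n_noise, length(noise_pool))))
        cases[[length(cases) + 1L]] <- case_record(
          age_years = round(stats::runif(1, 0.5, 40), 1),
          gender = sample(genders, 1),
          ethnicity = sample(ethnicities, 1),
          gene = node_name_of(kg, g),
          variant = node_name_of(kg, v),
          phenotypes = node_name_of(kg, ph_case),
          diagnosis = node_name_of(kg, d),
          source = sprintf("synthetic:%s-case%d", d, j))
      }
    }
    cases
  })
}
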