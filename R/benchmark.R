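#' @title Diagnostic benchmark construction
#' @description
#' Turns patient case records into selective (four-option multiple choice)
#' or non-selective (free answer) diagnostic questions, and builds
#' domain-knowledge QA items whose reference keypoints come from graph
#' queries.
#' @name benchmark
NULL

#' A patient case record
#'
#' @param age_years Non-negative age in years (printed with one decimal).
#' @param gender,ethnicity Free strings; masked values such as `"*****"`
#'   are preserved verbatim.
#' @param gene Gene symbol.
#' @param variant Variant notation, e.g. `"c. 2443-2 A > G"`.
#' @param phenotypes Non-empty character vector of facial phenotype names.
#' @param diagnosis Ground-truth disease name.
#' @param source Provenance identifier (DOI or synthetic id).
#' @return A `phenorag_case` list.
#' @export
case_record <- function(age_years, gender, ethnicity, gene, variant,
                        phenotypes, diagnosis, source = "") {
  if (!length(phenotypes))
    pr_abort("case needs at least one phenotype", "phenorag_input_error")
  if (!nzchar(diagnosis))
    pr_abort("case needs a diagnosis", "phenorag_input_error")
  structure(list(age_years = as.numeric(age_years),
                 gender = as.character(gender),
                 ethnicity = as.character(ethnicity),
                 gene = as.character(gene),
                 variant = as.character(variant),
                 phenotypes = as.character(phenotypes),
                 diagnosis = as.character(diagnosis),
                 source = as.character(source)),
            class = "phenorag_case")
}

#' Render the fixed diagnostic question stem for a case
#'
#' Ages always print one decimal place (an integer age renders as
#' `"5.0"`); phenotypes are comma-joined in the given order.
#'
#' @param case A [case_record()].
#' @return The stem text.
#' @export
render_stem <- function(case) {
  sprintf(paste0("There is a %.1f-year-old %s %s patient with a mutation ",
                 "in %s, namely, %s and with facial phenotypes of %s. ",
                 "What disease might this patient have?"),
          case$age_years, case$gender, case$ethnicity, case$gene,
          case$variant, paste(case$phenotypes, collapse = ", "))
}

#' Build a selective or non-selective diagnostic question
#'
#' Selective questions draw three distinct distractors without replacement
#' from `distractor_pool` excluding the true diagnosis, then a seeded
#' shuffle assigns labels A-D; the correct answer appears exactly once.
#'
#' @param case A [case_record()].
#' @param mode `"selective"` or `"non_selective"`.
#' @param distractor_pool Character vector of candidate distractor
#'   diseases (needed for selective mode; at least 3 after excluding the
#'   diagnosis).
#' @param seed Integer seed making the question reproducible.
#' @param id Question identifier.
#' @return A `phenorag_question` list with fields `id`, `stem`, `mode`,
#'   `options` (data frame label/disease, empty for non-selective),
#'   `answer`, `answer_label`, `case`.
#' @export
build_question <- function(case, mode = c("selective", "non_selective"),
                           distractor_pool = character(), seed = 1L,
                           id = NULL) {
  mode <- match.arg(mode)
  options <- data.frame(label = character(), disease = character(),
                        stringsAsFactors = FALSE)
  answer_label <- ""
  if (mode == "selective") {
    pool <- setdiff(unique(distractor_pool), case$diagnosis)
    if (length(pool) < 3)
      pr_abort("distractor pool must hold >= 3 diseases besides the answer",
               "phenorag_benchmark_error")
    with_seed(derive_seed(seed, "question", case$diagnosis, case$variant), {
      distractors <- sample(pool, 3)
      opts <- sample(c(case$diagnosis, distractors))
      options <- data.frame(label = c("A", "B", "C", "D"), disease = opts,
                            stringsAsFactors = FALSE)
      answer_label <- options$label[options$disease == case$diagnosis]
    })
  }
  structure(list(id = id %||% paste0("q-", derive_seed(seed, case$source,
                                                       case$diagnosis)),
                 stem = render_stem(case), mode = mode, options = options,
                 answer = case$diagnosis, answer_label = answer_label,
                 case = case),
            class = "phenorag_question")
}

case_to_list <- function(case) unclass(case)

list_to_case <- function(x, line = NA) {
  need <- c("age_years", "gender", "ethnicity", "gene", "variant",
            "phenotypes", "diagnosis")
  miss <- setdiff(need, names(x))
  if (length(miss))
    pr_abort(sprintf("case row %s: missing field(s) %s", line,
                     paste(miss, collapse = ", ")),
             "phenorag_input_error")
  case_record(x$age_years, x$gender, x$ethnicity, x$gene, x$variant,
              unlist(x$phenotypes), x$diagnosis, x$source %||% "")
}

#' Read and write case records as JSON-lines
#'
#' One JSON object per line with the [case_record()] fields; `phenotypes`
#' is an array.  Round-trip stable, masked fields preserved verbatim.
#'
#' @param path File path.
#' @return `load_cases()`: list of `phenorag_case`.
#' @export
load_cases <- function(path) {
  if (!file.exists(path))
    pr_abort(paste0("file not found: ", path), "phenorag_input_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e)
                    pr_abort(sprintf("case row %d: malformed JSON", i),
                             "phenorag_input_error"))
    list_to_case(x, line = i)
  })
}

#' @rdname load_cases
#' @param cases List of `phenorag_case` records.
#' @export
write_cases <- function(cases, path) {
  lines <- vapply(cases, function(cs)
    jsonlite::toJSON(case_to_list(cs), auto_unbox = TRUE), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' Read and write diagnostic benchmarks as JSON-lines
#'
#' @param questions List of `phenorag_question`.
#' @param path File path.
#' @export
write_benchmark <- function(questions, path) {
  lines <- vapply(questions, function(q) {
    jsonlite::toJSON(list(id = q$id, stem = q$stem, mode = q$mode,
                          options = q$options, answer = q$answer,
                          answer_label = q$answer_label,
                          case = case_to_list(q$case)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' @rdname write_benchmark
#' @export
load_benchmark <- function(path) {
  if (!file.exists(path))
    pr_abort(paste0("file not found: ", path), "phenorag_input_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    x <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    opts <- if (length(x$options))
      as.data.frame(x$options, stringsAsFactors = FALSE)
    else data.frame(label = character(), disease = character(),
                    stringsAsFactors = FALSE)
    structure(list(id = x$id, stem = x$stem, mode = x$mode, options = opts,
                   answer = x$answer, answer_label = x$answer_label %||% "",
                   case = list_to_case(x$case, line = i)),
              class = "phenorag_question")
  })
}

#' Build domain-knowledge QA items from the graph
#'
#' Reference keypoints are read off the graph: for
#' `phenotype_disease`, the facial phenotypes of a disease; for
#' `phenotype_gene`, the phenotypes a genotype affects; for `disease_gene`,
#' the genotypes whose variations cause a disease; for
#' `phenotype_synonym`, the stored synonyms of a phenotype.
#'
#' @param kg A `phenorag_kg`.
#' @param task One of `"phenotype_disease"`, `"phenotype_gene"`,
#'   `"disease_gene"`, `"phenotype_synonym"`.
#' @param n Maximum number of items.
#' @return List of `phenorag_qa_item` (fields `task`, `question`,
#'   `reference_keypoints`).
#' @export
build_qa_items <- function(kg, task = c("phenotype_disease",
                                        "phenotype_gene", "disease_gene",
                                        "phenotype_synonym"), n = 25L) {
  task <- match.arg(task)
  e <- kg$edges
  mk <- function(question, keypoints) {
    keypoints <- keypoints[!duplicated(norm_name(keypoints))]
    if (!length(keypoints)) return(NULL)
    structure(list(task = task, question = question,
                   reference_keypoints = keypoints),
              class = "phenorag_qa_item")
  }
  items <- switch(task,
    phenotype_disease = {
      dis <- unique(e$source[e$relation == "Has_Phenotype"])
      lapply(dis, function(d) {
        kp <- node_name_of(kg, e$target[e$relation == "Has_Phenotype" &
                                          e$source == d])
        mk(sprintf("What facial phenotypes are associated with %s?",
                   node_name_of(kg, d)), kp)
      })
    },
    phenotype_gene = {
      gen <- unique(e$source[e$relation == "Affect"])
      lapply(gen, function(g) {
        kp <- node_name_of(kg, e$target[e$relation == "Affect" &
                                          e$source == g])
        mk(sprintf("What facial phenotypes are associated with gene %s?",
                   node_name_of(kg, g)), kp)
      })
    },
    disease_gene = {
      dis <- unique(e$target[e$relation == "Cause"])
      lapply(dis, function(d) {
        vars <- e$source[e$relation == "Cause" & e$target == d]
        genes <- e$target[e$relation == "Have" & e$source %in% vars]
        mk(sprintf("Mutations in which genes cause %s?",
                   node_name_of(kg, d)), unique(node_name_of(kg, genes)))
      })
    },
    phenotype_synonym = {
      ph <- kg$nodes[kg$nodes$kind == "FacePhenotype", , drop = FALSE]
      lapply(seq_len(nrow(ph)), function(i) {
        if (!length(ph$synonyms[[i]])) return(NULL)
        mk(sprintf("What are synonyms of the facial phenotype %s?",
                   ph$name[i]), ph$synonyms[[i]])
      })
    })
  items <- Filter(Negate(is.null), items)
  head(items, n)
}
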