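#' @title Experiment orchestration
#' @description
#' Runs the four evaluation experiments — domain-knowledge QA, diagnostic
#' tests, consistency, and the temperature sweep — for every (model,
#' method) pair, producing graded records and aggregate tables.  Contexts
#' are retrieved once per (model, method, question) and reused across
#' repeats and temperature points, since retrieval is deterministic.
#' @name cli_reporting
NULL

#' Run configuration
#'
#' @param kg A `phenorag_kg`.
#' @param questions List of `phenorag_question` (diagnostic experiments).
#' @param qa_items List of `phenorag_qa_item` (domain QA).
#' @param models Named list of language-model ports.
#' @param methods Subset of `c("vanilla", "cypher_rag", "vector_rag")`.
#' @param R Repeats per question for diagnostic/consistency runs.
#' @param fixed_temperature Temperature for QA, diagnostic and consistency
#'   runs (default 0.1).
#' @param temperature_grid Grid for the temperature sweep (default
#'   `seq(0, 1, 0.2)`), each point queried once per question.
#' @param retriever A [retriever_config()].
#' @param seed Master seed; every query seed is derived from it.
#' @return A `phenorag_run_config` list.
#' @export
run_config <- function(kg, questions = list(), qa_items = list(),
                       models = list(),
                       methods = c("vanilla", "cypher_rag", "vector_rag"),
                       R = 5L, fixed_temperature = 0.1,
                       temperature_grid = seq(0, 1, by = 0.2),
                       retriever = retriever_config(), seed = 1L) {
  stopifnot(R >= 1, length(temperature_grid) >= 1,
            all(temperature_grid >= 0 & temperature_grid <= 1))
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(kg = kg, questions = questions, qa_items = qa_items,
                 models = models, methods = methods, R = as.integer(R),
                 fixed_temperature = fixed_temperature,
                 temperature_grid = sort(temperature_grid),
                 retriever = retriever, seed = as.integer(seed)),
            class = "phenorag_run_config")
}

get_context <- function(config, model, method, query_text, cache) {
  if (method == "vanilla") return(NULL)
  key <- paste(model$identity, method, query_text, sep = "\r")
  if (!is.null(cache[[key]])) return(cache[[key]])
  ctx <- if (method == "vector_rag") {
    vector_retrieve(config$kg, query_text, config$retriever)
  } else {
    cypher_retrieve(config$kg, query_text, model, config$retriever,
                    generation_settings(0, seed = derive_seed(
                      config$seed, "cypher", model$identity, query_text)))
  }
  cache[[key]] <- ctx
  ctx
}

ask <- function(config, model, method, question, ctx, temperature, rep_i) {
  prompt <- build_prompt(question, ctx,
                         if (method == "vanilla") "vanilla" else "rag")
  settings <- generation_settings(
    temperature,
    seed = derive_seed(config$seed, model$identity, method, question$id,
                       rep_i, format(temperature)))
  resp <- tryCatch(model$complete(prompt, settings), error = function(e) {
    message(sprintf("model %s failed on %s: %s", model$identity,
                    question$id, conditionMessage(e)))
    ""
  })
  eval_record(model$identity, method, question$id, rep_i, temperature,
              resp, question)
}

#' Run an evaluation experiment
#'
#' `diagnostic` and `consistency` use `R` repeats per question at the
#' fixed temperature (they share a record layout; consistency adds the
#' modal-answer column in its summary).  `temperature` queries each
#' question once per grid point and reports per-temperature accuracy, the
#' sigma across the grid, and the per-model RAG sigma reduction.
#' `domain_qa` grades coverage and semantic similarity against reference
#' keypoints.  Model failures yield an INVALID record, never a crashed
#' run.
#'
#' @param config A [run_config()].
#' @param experiment One of `"domain_qa"`, `"diagnostic"`,
#'   `"consistency"`, `"temperature"`.
#' @return List with `records` (data frame) and experiment-specific
#'   aggregates.
#' @export
run_experiment <- function(config,
                           experiment = c("diagnostic", "consistency",
                                          "temperature", "domain_qa")) {
  experiment <- match.arg(experiment)
  cache <- new.env(parent = emptyenv())
  if (experiment == "domain_qa") return(run_domain_qa(config, cache))

  grid <- if (experiment == "temperature") config$temperature_grid
          else config$fixed_temperature
  reps <- if (experiment == "temperature") 1L else config$R
  rows <- list()
  for (mname in names(config$models)) {
    model <- config$models[[mname]]
    for (method in config$methods) {
      for (q in config$questions) {
        ctx <- get_context(config, model, method, q$stem, cache)
        for (temp in grid) {
          for (r in seq_len(reps)) {
            rows[[length(rows) + 1L]] <-
              ask(config, model, method, q, ctx, temp, r)
          }
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  out <- list(records = records)
  if (experiment == "temperature") {
    cells <- unique(records[c("model", "method")])
    profs <- lapply(seq_len(nrow(cells)), function(i) {
      sub <- records[records$model == cells$model[i] &
                       records$method == cells$method[i], ]
      acc_by_T <- vapply(config$temperature_grid, function(tt)
        accuracy(sub[sub$temperature == tt, ]), numeric(1))
      list(model = cells$model[i], method = cells$method[i],
           grid = config$temperature_grid, accuracy_by_T = acc_by_T,
           sigma = temperature_sigma(acc_by_T))
    })
    out$profiles <- profs
    sig <- function(mo, me) {
      s <- Filter(function(p) p$model == mo && p$method == me, profs)
      if (length(s)) s[[1]]$sigma else NA_real_
    }
    out$sigma_reduction <- vapply(unique(cells$model), function(mo)
      rag_sigma_reduction(sig(mo, "vanilla"), sig(mo, "cypher_rag"),
                          sig(mo, "vector_rag")), numeric(1))
    out$summary <- summarize_records(records, R = NA)
  } else {
    out$summary <- summarize_records(records,
                                     R = if (experiment == "consistency")
                                       config$R else NA)
  }
  out
}

qa_prompt <- function(item, context = NULL) {
  parts <- "You are an expert in rare genetic diseases and facial phenotypes."
  if (!is.null(context))
    parts <- c(parts, "[CONTEXT]", context$triplet_text, "[/CONTEXT]")
  c(parts, "[QUESTION]", item$question, "[/QUESTION]",
    "Answer concisely with the requested terms.") |>
    paste(collapse = "\n")
}

run_domain_qa <- function(config, cache) {
  rows <- list()
  for (mname in names(config$models)) {
    model <- config$models[[mname]]
    for (method in config$methods) {
      for (i in seq_along(config$qa_items)) {
        item <- config$qa_items[[i]]
        ctx <- get_context(config, model, method, item$question, cache)
        prompt <- qa_prompt(item, ctx)
        settings <- generation_settings(
          config$fixed_temperature,
          seed = derive_seed(config$seed, mname, method, i))
        resp <- tryCatch(model$complete(prompt, settings),
                         error = function(e) "")
        ref <- paste(item$reference_keypoints, collapse = ", ")
        rows[[length(rows) + 1L]] <- data.frame(
          model = mname, method = method, task = item$task, item = i,
          response = resp,
          coverage = coverage(resp, as.list(item$reference_keypoints)),
          semantic = semantic_score(resp, ref),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  agg <- aggregate(cbind(coverage, semantic) ~ model + method,
                   data = records, FUN = mean)
  agg$coverage <- round2(100 * agg$coverage)
  agg$semantic <- round(agg$semantic, 4)
  list(records = records, summary = agg)
}

#' Persist and reload run records as JSON-lines
#'
#' @param records Data frame of records.
#' @param path File path.
#' @export
write_records <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i)
    jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                     digits = NA),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}
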