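#' @title Grading and aggregate metrics
#' @description
#' Grades free-text responses against diagnostic questions and computes
#' the reported statistics: accuracy averaged over repeated queries,
#' answer consistency (modal-answer share over five repeats), reference
#' keypoint coverage, semantic similarity through a pluggable scorer,
#' the standard deviation of accuracy across a temperature grid, and the
#' average variability reduction achieved by retrieval augmentation.
#' @name evaluation
NULL

# registered alias: the parenthesized short form in an option string,
# e.g. "Floating-Harbor syndrome (FLHS)" -> alias "FLHS"
option_aliases <- function(disease) {
  m <- regmatches(disease, gregexpr("\\(([^)]+)\\)", disease))[[1]]
  alias <- gsub("[()]", "", m)
  base <- trimws(gsub("\\([^)]*\\)", "", disease))
  unique(c(disease, base, alias))
}

# normalized terms contain only [a-z0-9 ], so a fixed word-boundary wrap
# is safe without further escaping
mentions <- function(response_norm, term) {
  grepl(paste0("(^| )", norm_text(term), "( |$)"), response_norm)
}

#' Extract and grade a model response
#'
#' Normalization case-folds, strips punctuation and collapses whitespace.
#' Selective questions accept a bare option label, the option text, or the
#' disease name (or its parenthesized short form), all mapped to the
#' chosen option; naming two different option diseases is ambiguous and
#' graded `INVALID`.  Non-selective questions are correct iff the
#' normalized truth (or a registered alias) occurs in the response.
#'
#' @param response Raw response text.
#' @param question A `phenorag_question`.
#' @return List with `extracted_answer` (normalized disease, option label,
#'   or `"INVALID"`) and `correct` (logical).
#' @export
extract_and_grade <- function(response, question) {
  rn <- norm_text(response)
  invalid <- list(extracted_answer = "INVALID", correct = FALSE)
  if (!nzchar(rn)) return(invalid)
  if (question$mode == "selective") {
    opt <- question$options
    hit_name <- vapply(opt$disease, function(d)
      any(vapply(option_aliases(d), function(a) mentions(rn, a),
                 logical(1))), logical(1))
    hit_label <- vapply(tolower(opt$label), function(l)
      grepl(paste0("(^|[^a-z0-9])", l, "([^a-z0-9]|$)"), rn), logical(1))
    # a bare label alone is decisive even if option text repeats diseases
    hits <- which(hit_name | hit_label)
    if (length(hits) == 1) {
      label <- opt$label[hits]
      return(list(extracted_answer = label,
                  correct = label == question$answer_label))
    }
    if (length(hits) > 1 && sum(hit_label) == 1 && sum(hit_name) <= 1) {
      label <- opt$label[which(hit_label)]
      return(list(extracted_answer = label,
                  correct = label == question$answer_label))
    }
    return(invalid)
  }
  found <- any(vapply(option_aliases(question$answer), function(a)
    mentions(rn, a), logical(1)))
  if (found)
    list(extracted_answer = norm_text(question$answer), correct = TRUE)
  else invalid
}

#' Assemble one graded evaluation record
#'
#' @param model,method,question_id,repeat_index,temperature Record keys
#'   (`method` is one of `vanilla`, `cypher_rag`, `vector_rag`).
#' @param raw_response Response text.
#' @param question The `phenorag_question` it answers.
#' @return One-row data frame.
#' @export
eval_record <- function(model, method, question_id, repeat_index,
                        temperature, raw_response, question) {
  g <- extract_and_grade(raw_response, question)
  data.frame(model = model, method = method, question_id = question_id,
             repeat_index = repeat_index, temperature = temperature,
             raw_response = raw_response,
             extracted_answer = g$extracted_answer, correct = g$correct,
             stringsAsFactors = FALSE)
}

#' Accuracy of a record group, percent
#'
#' Mean over repeats of the per-repeat accuracy, times 100, to 2 decimals.
#' Invalid answers score as wrong.  An empty group is not computable and
#' reports `NA`.
#'
#' @param records Data frame of graded records.
#' @param model,method Optional filters.
#' @return Percent accuracy (2 decimals) or `NA`.
#' @export
accuracy <- function(records, model = NULL, method = NULL) {
  if (!is.null(model)) records <- records[records$model == model, ]
  if (!is.null(method)) records <- records[records$method == method, ]
  if (!nrow(records)) return(NA_real_)
  round2(100 * mean(records$correct))
}

#' Consistency of repeated answers to one question, percent
#'
#' The share of the modal extracted answer among the `R` repeats.
#' `INVALID` counts as a distinct answer value; a group that is entirely
#' `INVALID` is not computable and reports `NA`.
#'
#' @param answers Character vector of extracted answers for one question.
#' @param R Expected repeat count (default 5).
#' @return Percent in `[100/R, 100]`, or `NA`.
#' @export
consistency <- function(answers, R = 5L) {
  if (length(answers) != R)
    pr_abort(sprintf("expected %d answers, got %d", R, length(answers)),
             "phenorag_input_error")
  if (all(answers == "INVALID")) return(NA_real_)
  round2(100 * max(table(answers)) / R)
}

#' Keypoint coverage of a response
#'
#' Fraction of reference keypoints found in the normalized response
#' (exact or synonym occurrence).
#'
#' @param response Response text.
#' @param reference_keypoints Non-empty list; each element a character
#'   vector whose first entry is the canonical term and the rest synonyms.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(response, reference_keypoints) {
  if (!length(reference_keypoints))
    pr_abort("reference keypoints must be non-empty",
             "phenorag_input_error")
  rn <- norm_text(response)
  found <- vapply(reference_keypoints, function(kp)
    any(vapply(as.character(kp), function(a) mentions(rn, a), logical(1))),
    logical(1))
  sum(found) / length(found)
}

#' Semantic similarity through a pluggable scorer
#'
#' The default lexical scorer is token-level F1 overlap after
#' normalization (identical texts score 1, disjoint token sets 0).  Model
#' scorers (e.g. transformer-based) can be registered under a name and
#' selected per call.
#'
#' @param candidate,reference Texts to compare.
#' @param scorer Scorer name, `"token_f1"` by default.
#' @param scorers Named list of scorer functions
#'   `function(candidate, reference) -> [0, 1]`.
#' @return Real in `[0, 1]`.
#' @export
semantic_score <- function(candidate, reference, scorer = "token_f1",
                           scorers = list(token_f1 = token_f1_score)) {
  if (!scorer %in% names(scorers))
    pr_abort(paste0("no scorer registered under: ", scorer),
             "phenorag_config_error")
  scorers[[scorer]](candidate, reference)
}

#' @rdname semantic_score
#' @export
token_f1_score <- function(candidate, reference) {
  ct <- strsplit(norm_text(candidate), " ", fixed = TRUE)[[1]]
  rt <- strsplit(norm_text(reference), " ", fixed = TRUE)[[1]]
  ct <- ct[nzchar(ct)]; rt <- rt[nzchar(rt)]
  if (!length(ct) || !length(rt)) return(as.numeric(identical(ct, rt)))
  # multiset overlap
  common <- sum(pmin(table(ct)[intersect(names(table(ct)),
                                         names(table(rt)))],
                     table(rt)[intersect(names(table(ct)),
                                         names(table(rt)))]))
  if (common == 0) return(0)
  prec <- common / length(ct)
  rec <- common / length(rt)
  2 * prec * rec / (prec + rec)
}

#' Standard deviation of accuracy across a temperature grid
#'
#' Sample standard deviation (denominator `n - 1`) by default, on the
#' percent scale, to 2 decimals; the population estimator is opt-in.
#'
#' @param accuracy_by_T Numeric vector of per-temperature accuracies
#'   (percent), one per grid point, at least 2.
#' @param estimator `"sample"` (n-1) or `"population"` (n).
#' @return Sigma, 2 decimals.
#' @export
temperature_sigma <- function(accuracy_by_T,
                              estimator = c("sample", "population")) {
  estimator <- match.arg(estimator)
  stopifnot(length(accuracy_by_T) >= 2)
  s <- stats::sd(accuracy_by_T)
  if (estimator == "population")
    s <- s * sqrt((length(accuracy_by_T) - 1) / length(accuracy_by_T))
  round2(s)
}

#' Average variability reduction under retrieval augmentation, percent
#'
#' `100 * mean(1 - sigma_cypher / sigma_vanilla,
#' 1 - sigma_vector / sigma_vanilla)`, to 2 decimals.  Undefined (NA) when
#' the vanilla sigma is 0.
#'
#' @param sigma_vanilla,sigma_cypher,sigma_vector Sigmas on any common
#'   scale.
#' @return Percent reduction (2 decimals) or `NA`.
#' @export
rag_sigma_reduction <- function(sigma_vanilla, sigma_cypher, sigma_vector) {
  if (is.na(sigma_vanilla) || sigma_vanilla == 0) return(NA_real_)
  round2(100 * mean(c(1 - sigma_cypher / sigma_vanilla,
                      1 - sigma_vector / sigma_vanilla)))
}

#' Per-method averages and deltas from a per-model accuracy table
#'
#' Averages are the arithmetic mean of each method column rounded to 2
#' decimals; deltas are differences of the rounded averages (the printed
#' arithmetic convention).
#'
#' @param table Data frame with a `model` column and one numeric column
#'   per method (e.g. `vanilla`, `cypher_rag`, `vector_rag`); `NA` cells
#'   mark uncomputable model rows and are excluded from that column's
#'   average.
#' @return List with `averages` (named, 2 decimals) and `deltas` (each
#'   RAG method minus vanilla, plus `vector_minus_cypher` when both
#'   present).
#' @export
method_averages <- function(table) {
  methods <- setdiff(names(table), "model")
  averages <- vapply(methods, function(m)
    round2(mean(table[[m]], na.rm = TRUE)), numeric(1))
  deltas <- list()
  if ("vanilla" %in% methods)
    for (m in setdiff(methods, "vanilla"))
      deltas[[paste0(m, "_minus_vanilla")]] <-
        round2(averages[[m]] - averages[["vanilla"]])
  if (all(c("cypher_rag", "vector_rag") %in% methods))
    deltas[["vector_minus_cypher"]] <-
      round2(averages[["vector_rag"]] - averages[["cypher_rag"]])
  list(averages = averages, deltas = deltas)
}

#' Aggregate graded records into a metrics table
#'
#' One row per (model, method) with accuracy and mean consistency, plus
#' per-method averages over models and deltas against vanilla, mirroring
#' the published table layout.  A model row whose records are entirely
#' invalid is reported missing and excluded from averages.
#'
#' @param records Graded records (from [eval_record()] /
#'   [run_experiment()]).
#' @param R Repeats per question used for consistency (default 5; pass
#'   `NA` to skip the consistency column).
#' @return List with `by_cell` (data frame), `accuracy_table`,
#'   `averages`, `deltas`.
#' @export
summarize_records <- function(records, R = 5L) {
  cells <- unique(records[c("model", "method")])
  canon <- c("vanilla", "cypher_rag", "vector_rag")
  cells <- cells[order(cells$model,
                       match(cells$method, canon, nomatch = 99L),
                       cells$method, method = "radix"), , drop = FALSE]
  rownames(cells) <- NULL
  cells$accuracy <- mapply(function(mo, me) {
    sub <- records[records$model == mo & records$method == me, ]
    if (all(sub$extracted_answer == "INVALID")) NA_real_
    else accuracy(sub)
  }, cells$model, cells$method)
  if (!is.na(R)) {
    cells$consistency <- mapply(function(mo, me) {
      sub <- records[records$model == mo & records$method == me, ]
      qs <- split(sub$extracted_answer, sub$question_id)
      qs <- qs[lengths(qs) == R]
      if (!length(qs)) return(NA_real_)
      vals <- vapply(qs, consistency, numeric(1), R = R)
      if (all(is.na(vals))) NA_real_ else round2(mean(vals, na.rm = TRUE))
    }, cells$model, cells$method)
  }
  acc <- stats::reshape(cells[c("model", "method", "accuracy")],
                        idvar = "model", timevar = "method",
                        direction = "wide")
  names(acc) <- sub("^accuracy\\.", "", names(acc))
  ma <- method_averages(acc)
  list(by_cell = cells, accuracy_table = acc,
       averages = ma$averages, deltas = ma$deltas)
}

#' Write a metrics table as TSV
#'
#' @param summary Output of [summarize_records()].
#' @param path Output file.
#' @export
write_metrics <- function(summary, path) {
  tab <- summary$accuracy_table
  avg <- c(model = "Average",
           lapply(summary$averages[setdiff(names(tab), "model")],
                  identity))
  tab <- rbind(tab, as.data.frame(avg, stringsAsFactors = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(NULL)
}
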