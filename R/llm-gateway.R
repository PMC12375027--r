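#' @title Language-model gateway and seeded mock model
#' @description
#' The language-model dependency sits behind a minimal port: an object
#' with an `identity` string and a `complete(prompt, settings)` function.
#' A seeded mock model implements the port richly enough to simulate the
#' retrieval-augmentation phenomena offline: context-grounded answering,
#' an imperfect unaided "pretrained knowledge", and temperature-driven
#' answer perturbation.  Live API adapters can implement the same port but
#' are never required.
#' @name llm_gateway
NULL

#' Decoding settings
#'
#' @param temperature Real in `[0, 1]` (the evaluated range).
#' @param seed Integer; for `temperature = 0` and a fixed seed,
#'   completion is a pure function of the prompt.
#' @param max_length Maximum response length in characters.
#' @return A `phenorag_gen_settings` list.
#' @export
generation_settings <- function(temperature = 0.1, seed = 1L,
                                max_length = 2000L) {
  stopifnot(temperature >= 0, temperature <= 1, max_length >= 1)
  structure(list(temperature = temperature, seed = as.integer(seed),
                 max_length = as.integer(max_length)),
            class = "phenorag_gen_settings")
}

#' Build a deterministic prompt from a question and optional context
#'
#' The `vanilla` template omits the context block entirely; the `rag`
#' template embeds the serialized triplet text verbatim.  Selective
#' questions list exactly the four labeled options.
#'
#' @param question A `phenorag_question`.
#' @param context Optional `phenorag_context` (required by the `rag`
#'   template).
#' @param template `"vanilla"` or `"rag"`.
#' @return Prompt text.
#' @export
build_prompt <- function(question, context = NULL,
                         template = c("vanilla", "rag")) {
  template <- match.arg(template)
  parts <- "You are an expert in rare genetic diseases and facial phenotypes."
  if (template == "rag") {
    if (is.null(context))
      pr_abort("rag template requires a retrieval context",
               "phenorag_template_error")
    parts <- c(parts, "[CONTEXT]", context$triplet_text, "[/CONTEXT]")
  }
  parts <- c(parts, "[QUESTION]", question$stem, "[/QUESTION]")
  if (question$mode == "selective") {
    parts <- c(parts, "[OPTIONS]",
               sprintf("%s. %s", question$options$label,
                       question$options$disease),
               "[/OPTIONS]",
               "Answer with the letter and name of the correct option.")
  } else {
    parts <- c(parts, "Answer with the name of the disease.")
  }
  paste(parts, collapse = "\n")
}

# split a gateway prompt back into its blocks (the mock model's parser)
parse_prompt <- function(prompt) {
  block <- function(tag) {
    m <- regmatches(prompt, regexec(
      paste0("\\[", tag, "\\]\n(.*?)\n\\[/", tag, "\\]"), prompt))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  opts <- block("OPTIONS")
  options <- if (!is.na(opts)) {
    lines <- strsplit(opts, "\n", fixed = TRUE)[[1]]
    mm <- regmatches(lines, regexec("^([A-D])\\. (.*)$", lines))
    data.frame(label = vapply(mm, `[`, character(1), 2),
               disease = vapply(mm, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  } else NULL
  list(context = block("CONTEXT"), question = block("QUESTION"),
       options = options)
}

#' Mock model specification
#'
#' @param knowledge Named list mapping disease name to its phenotype-name
#'   set: the mock's "pretrained knowledge".  Unaided answers run a
#'   nearest-neighbor lookup over it (ties and recall failures produce
#'   errors, so overlapping diseases degrade unaided accuracy).  An empty
#'   knowledge map makes unaided answers pure guesses.
#' @param context_fidelity Probability of answering from the context block
#'   when it names a candidate disease.
#' @param base_accuracy Probability that an unaided answer consults the
#'   knowledge map (rather than guessing a distractor).
#' @param distractor_pool Character vector of disease names used for
#'   guesses and perturbations.
#' @param perturbation_rate Monotone map from temperature to answer-flip
#'   probability with `perturbation_rate(0) = 0`; default linear,
#'   `0.3 * T`.
#' @param context_anchor If `TRUE` (default) answers taken from retrieved
#'   context are not perturbed by temperature: retrieval anchors decoding,
#'   so stochasticity acts on the unanchored prior only.
#' @param cypher_skill Probability that a Cypher-generation request yields
#'   a valid query rather than prose (models differ sharply here).
#' @return A `phenorag_mock_spec` list.
#' @export
mock_model_spec <- function(knowledge = list(), context_fidelity = 0.95,
                            base_accuracy = 0.5,
                            distractor_pool = character(),
                            perturbation_rate = function(T) 0.3 * T,
                            context_anchor = TRUE, cypher_skill = 1) {
  stopifnot(context_fidelity >= 0, context_fidelity <= 1,
            base_accuracy >= 0, base_accuracy <= 1,
            cypher_skill >= 0, cypher_skill <= 1,
            abs(perturbation_rate(0)) < 1e-12)
  structure(list(knowledge = knowledge,
                 context_fidelity = context_fidelity,
                 base_accuracy = base_accuracy,
                 distractor_pool = distractor_pool,
                 perturbation_rate = perturbation_rate,
                 context_anchor = context_anchor,
                 cypher_skill = cypher_skill),
            class = "phenorag_mock_spec")
}

#' Extract a mock knowledge map from a knowledge graph
#'
#' @param kg A `phenorag_kg`.
#' @return Named list: disease name -> character vector of phenotype
#'   names.
#' @export
mock_knowledge_from_kg <- function(kg) {
  e <- kg$edges[kg$edges$relation == "Has_Phenotype", , drop = FALSE]
  if (!nrow(e)) return(list())
  sp <- split(node_name_of(kg, e$target), node_name_of(kg, e$source))
  lapply(sp, unique)
}

mock_disease_vocab <- function(spec, options) {
  unique(c(names(spec$knowledge), spec$distractor_pool,
           if (!is.null(options)) options$disease))
}

# diseases named in the context, scored by evidence lines; candidates are
# vocabulary entries plus entities sitting in a disease position of a
# triplet (Has_Phenotype source, Cause target).  A line only counts as
# evidence when the entity linked to the candidate is itself mentioned in
# the question, which is how a careful reader weighs retrieved triplets;
# the raw mention count breaks ties.
context_candidates <- function(context, vocab, question = NA_character_) {
  if (is.na(context) || !nzchar(context) ||
      identical(context, "NO CONTEXT RETRIEVED")) return(NULL)
  lines <- strsplit(context, "\n", fixed = TRUE)[[1]]
  src <- sub("^\\[(.*?)\\] .*$", "\\1", lines)
  tgt <- sub("^.*> \\[(.*)\\]$", "\\1", lines)
  structural <- c(src[grepl("-\\(Has_Phenotype\\)->", lines)],
                  tgt[grepl("-\\(Cause\\)->", lines)])
  cand <- unique(c(vocab, structural))
  raw <- vapply(cand, function(d)
    sum(src == d | tgt == d | grepl(d, lines, fixed = TRUE)), numeric(1))
  evidence <- vapply(cand, function(d) {
    if (is.na(question)) return(0)
    other <- ifelse(src == d, tgt, ifelse(tgt == d, src, NA_character_))
    sum(!is.na(other) &
          vapply(other, function(o)
            !is.na(o) && grepl(o, question, fixed = TRUE), logical(1)))
  }, numeric(1))
  score <- if (is.na(question)) raw else evidence + raw / 1e3
  score <- score[raw > 0 & score > 0]
  if (!length(score)) NULL else score
}

# nearest-neighbor diagnosis over the knowledge map; ties broken at random
knowledge_lookup <- function(spec, question_text) {
  if (!length(spec$knowledge)) return(NA_character_)
  scores <- vapply(spec$knowledge, function(ph)
    sum(vapply(ph, function(p) grepl(p, question_text, fixed = TRUE),
               logical(1))), numeric(1))
  if (max(scores) == 0) return(NA_character_)
  best <- names(scores)[scores == max(scores)]
  if (length(best) == 1) best else sample(best, 1)
}

# open-ended domain question: list terms from context when available,
# otherwise recall a seeded fraction of the relevant knowledge entry
mock_qa_answer <- function(spec, p) {
  if (!is.na(p$context) && nzchar(p$context) &&
      !identical(p$context, "NO CONTEXT RETRIEVED") &&
      stats::runif(1) < spec$context_fidelity) {
    ents <- regmatches(p$context,
                       gregexpr("\\[([^]]+)\\]", p$context))[[1]]
    ents <- unique(gsub("[][]", "", ents))
    return(paste(ents, collapse = ", "))
  }
  q <- p$question %||% ""
  known <- names(spec$knowledge)[vapply(names(spec$knowledge), function(d)
    grepl(d, q, fixed = TRUE), logical(1))]
  if (length(known)) {
    ph <- spec$knowledge[[known[1]]]
    keep <- ph[stats::runif(length(ph)) < spec$base_accuracy]
    if (length(keep)) return(paste(keep, collapse = ", "))
  }
  "I am not certain."
}

pick_distractor <- function(pool, exclude) {
  pool <- setdiff(pool, exclude)
  if (!length(pool)) return(exclude[1])
  if (length(pool) == 1) pool else sample(pool, 1)
}

# query strategy mirrors a capable generator: prefer the most specific
# entity in the question (named disease for association questions, the
# variant for case stems), fall back to a single-phenotype lookup
mock_generate_cypher <- function(spec, prompt) {
  if (stats::runif(1) >= spec$cypher_skill)
    return("I am sorry, I cannot write that query.")
  q <- sub(".*Question: ", "", prompt)
  dis <- names(spec$knowledge)[vapply(names(spec$knowledge), function(d)
    grepl(d, q, fixed = TRUE), logical(1))]
  if (length(dis))
    return(sprintf(
      "MATCH (d:Disease {name: \"%s\"})-[:Has_Phenotype]->(p:FacePhenotype) RETURN p.name",
      dis[1]))
  var <- regmatches(q, regexec("namely, (.*?) and with", q))[[1]]
  if (length(var) == 2)
    return(sprintf(
      "MATCH (v:Variation {name: \"%s\"})-[:Cause]->(d:Disease) RETURN d.name",
      var[2]))
  phen <- unlist(spec$knowledge, use.names = FALSE)
  hit <- phen[vapply(phen, function(p) grepl(p, q, fixed = TRUE),
                     logical(1))]
  if (!length(hit))
    return("MATCH (d:Disease) RETURN d.name LIMIT 5")
  sprintf(
    "MATCH (d:Disease)-[:Has_Phenotype]->(p:FacePhenotype {name: \"%s\"}) RETURN d.name",
    hit[1])
}

#' Complete a prompt with the mock model
#'
#' Behavior: if the context block names candidate diseases, the
#' best-supported one is answered with probability `context_fidelity`
#' (ties seeded-random); otherwise the unaided path consults the knowledge
#' map with probability `base_accuracy` and guesses a distractor
#' otherwise; finally the answer flips to a random distractor with
#' probability `perturbation_rate(temperature)` (context-taken answers are
#' exempt while `context_anchor` is set).  All randomness derives from
#' `settings$seed`.
#'
#' @param spec A [mock_model_spec()].
#' @param prompt Prompt text from [build_prompt()] (or a Cypher-generation
#'   request).
#' @param settings A [generation_settings()].
#' @return Response text.
#' @export
mock_complete <- function(spec, prompt, settings = generation_settings()) {
  with_seed(derive_seed(settings$seed, substr(prompt, 1, 512)), {
    if (startsWith(prompt, "Translate the question into a single Cypher"))
      return(mock_generate_cypher(spec, prompt))
    p <- parse_prompt(prompt)
    diagnostic <- !is.na(p$question) &&
      grepl("What disease might this patient have", p$question, fixed = TRUE)
    if (!diagnostic)
      return(substr(mock_qa_answer(spec, p), 1, settings$max_length))
    vocab <- mock_disease_vocab(spec, p$options)
    answer <- NA_character_
    from_context <- FALSE
    cand <- context_candidates(p$context, vocab, p$question)
    if (!is.null(cand) && stats::runif(1) < spec$context_fidelity) {
      best <- names(cand)[cand == max(cand)]
      answer <- if (length(best) == 1) best else sample(best, 1)
      from_context <- TRUE
    }
    if (is.na(answer)) {
      guess_pool <- if (!is.null(p$options)) p$options$disease
                    else spec$distractor_pool
      if (stats::runif(1) < spec$base_accuracy)
        answer <- knowledge_lookup(spec, p$question %||% prompt)
      if (is.na(answer))
        answer <- pick_distractor(guess_pool, character())
    }
    flip_p <- spec$perturbation_rate(settings$temperature)
    anchored <- from_context && spec$context_anchor
    if (!anchored && flip_p > 0 && stats::runif(1) < flip_p) {
      pool <- if (!is.null(p$options)) p$options$disease
              else spec$distractor_pool
      answer <- pick_distractor(pool, answer)
    }
    substr(answer, 1, settings$max_length)
  })
}

#' Wrap a mock specification as a language-model port
#'
#' @param spec A [mock_model_spec()].
#' @param name Model identity string.
#' @return A port: list with `identity` and `complete(prompt, settings)`.
#' @export
mock_model <- function(spec, name = "mock") {
  structure(list(identity = name,
                 complete = function(prompt,
                                     settings = generation_settings())
                   mock_complete(spec, prompt, settings)),
            class = "phenorag_llm")
}

#' A port that replays scripted responses (testing aid)
#'
#' @param responses Character vector replayed in order (recycled).
#' @param name Model identity string.
#' @return A language-model port.
#' @export
scripted_model <- function(responses, name = "scripted") {
  i <- 0L
  structure(list(identity = name,
                 complete = function(prompt,
                                     settings = generation_settings()) {
                   i <<- i %% length(responses) + 1L
                   responses[[i]]
                 }),
            class = "phenorag_llm")
}
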