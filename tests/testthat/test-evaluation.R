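# the worked selective question: a three-disease pool forces exactly the
# published option set alongside the true diagnosis
sel_question <- function() {
  build_question(chd7_case(), "selective",
                 c("Floating-Harbor syndrome (FLHS)",
                   "Noonan syndrome-like disorder with loose anagen hair 2 (NSLH2)",
                   "Tricho-rhino-phalangeal syndrome,TYPE I(TRPS1)"),
                 seed = 8)
}

test_that("grading accepts names, labels, option text and short-form aliases", {
  qn <- build_question(chd7_case(), "non_selective")
  expect_true(extract_and_grade("CHARGE syndrome", qn)$correct)
  expect_true(extract_and_grade(
    "The patient most likely has CHARGE syndrome.", qn)$correct)
  expect_false(extract_and_grade("Noonan syndrome", qn)$correct)
  expect_equal(extract_and_grade("Noonan syndrome", qn)$extracted_answer,
               "INVALID")

  qs <- sel_question()
  # bare label, case-insensitive
  lab <- qs$answer_label
  g1 <- extract_and_grade(tolower(lab), qs)
  expect_equal(g1$extracted_answer, lab)
  expect_true(g1$correct)
  # full option text
  g2 <- extract_and_grade("CHARGE syndrome", qs)
  expect_true(g2$correct)
  # parenthesized short form of a distractor maps to that option
  g3 <- extract_and_grade("It is FLHS", qs)
  expect_false(g3$correct)
  expect_equal(
    qs$options$disease[qs$options$label == g3$extracted_answer],
    "Floating-Harbor syndrome (FLHS)")
})

test_that("responses naming two option diseases are INVALID by the ambiguity rule", {
  qs <- sel_question()
  multi <- c("Either CHARGE syndrome or Floating-Harbor syndrome",
             "CHARGE syndrome, though FLHS is possible",
             "A B")
  for (resp in multi) {
    g <- extract_and_grade(resp, qs)
    expect_equal(g$extracted_answer, "INVALID", info = resp)
    expect_false(g$correct)
  }
  expect_equal(extract_and_grade("", qs)$extracted_answer, "INVALID")
})

test_that("accuracy averages per-repeat correctness to two decimals", {
  qn <- build_question(chd7_case(), "non_selective")
  recs <- do.call(rbind, lapply(1:5, function(r)
    eval_record("m", "vanilla", "q1", r, 0.1,
                if (r <= 3) "CHARGE syndrome" else "Noonan", qn)))
  expect_equal(accuracy(recs), 60)
  expect_equal(accuracy(recs[0, ]), NA_real_)
  # published per-model column averages to 74.98
  vals <- c(67.60, 90.40, 90.20, 85.20, 63.60, 75.60, 54.40, 72.80)
  expect_equal(phenorag:::round2(mean(vals)), 74.98)
})

test_that("consistency is the modal-answer share with INVALID as its own value", {
  expect_equal(consistency(c("a", "a", "a", "b", "c")), 60)
  expect_equal(consistency(rep("a", 5)), 100)
  expect_equal(consistency(c("a", "b", "c", "d", "e")), 20)
  expect_equal(consistency(c("INVALID", "INVALID", "INVALID", "a", "b")), 60)
  expect_true(is.na(consistency(rep("INVALID", 5))))
  expect_error(consistency(c("a", "b")), class = "phenorag_input_error")
})

test_that("coverage counts keypoints found, including synonym hits, and is monotone", {
  kps <- as.list(paste0("phenotype term ", 1:23))
  resp <- paste(unlist(kps[1:4]), collapse = "; ")
  expect_equal(coverage(resp, kps), 4 / 23)
  expect_equal(coverage(paste(unlist(kps), collapse = ", "), kps), 1)
  expect_equal(coverage("nothing relevant", kps), 0)
  # synonym listed with the keypoint counts as found
  kps2 <- list(c("Proptosis", "Exophthalmos"), "Ptosis")
  expect_equal(coverage("shows exophthalmos", kps2), 0.5)
  # monotone: mentioning one more keypoint never lowers coverage
  base <- coverage(resp, kps)
  expect_gte(coverage(paste(resp, unlist(kps[5])), kps), base)
})

test_that("the lexical semantic scorer follows token F1 arithmetic", {
  expect_equal(semantic_score("wide nasal bridge", "wide nasal bridge"), 1)
  expect_equal(semantic_score("proptosis", "micrognathia ptosis"), 0)
  # candidate holding half the reference tokens and nothing else:
  # precision 1, recall 0.5 -> F1 = 2/3
  expect_equal(semantic_score("alpha", "alpha beta"), 2 / 3,
               tolerance = 1e-12)
  expect_error(semantic_score("a", "b", scorer = "bert"),
               class = "phenorag_config_error")
})

test_that("temperature sigma uses the sample estimator on the percent scale", {
  expect_equal(temperature_sigma(rep(90, 6)), 0)
  expect_equal(temperature_sigma(c(90, 90, 90, 90, 90, 96)), 2.45)
  a <- 81.4; b <- 77.8
  expect_equal(temperature_sigma(c(a, b)),
               phenorag:::round2(abs(a - b) / sqrt(2)))
  expect_equal(temperature_sigma(c(90, 90, 90, 90, 90, 96),
                                 estimator = "population"),
               phenorag:::round2(sqrt(30 / 6)))
})

test_that("sigma reduction recovers analytic ground truth and degenerate cases", {
  expect_equal(rag_sigma_reduction(2, 2, 2), 0)
  expect_equal(rag_sigma_reduction(2, 0, 0), 100)
  expect_equal(rag_sigma_reduction(2, 1, 1.5), 37.5)
  expect_true(is.na(rag_sigma_reduction(0, 1, 1)))
})

test_that("method averages and deltas reproduce the published arithmetic", {
  pub_sel <- data.frame(
    model = c("GPT-3.5-turbo", "GPT-4-turbo", "GPT-4o", "Claude-3-opus",
              "Claude-3-sonnet", "Claude-3-haiku", "Gemini-pro",
              "LLaMA-70b"),
    vanilla = c(67.60, 90.40, 90.20, 85.20, 63.60, 75.60, 54.40, 72.80),
    cypher_rag = c(92.40, 97.00, 95.40, 94.40, 91.20, 90.60, 47.60, 94.40),
    vector_rag = c(90.60, 95.00, 95.00, 94.00, 92.20, 91.00, 92.40, 93.20))
  ma <- method_averages(pub_sel)
  expect_equal(unname(ma$averages[c("vanilla", "cypher_rag",
                                    "vector_rag")]),
               c(74.98, 87.88, 92.93))
  expect_equal(ma$deltas$cypher_rag_minus_vanilla, 12.90)
  expect_equal(ma$deltas$vector_rag_minus_vanilla, 17.95)
})

test_that("summarize_records aggregates cells, flags all-INVALID rows, and is order-invariant", {
  qn <- build_question(chd7_case(), "non_selective", id = "q1")
  q2 <- build_question(case_record(2, "male", "German", "G", "c.1A>G",
                                   "Ptosis", "Noonan syndrome"),
                       "non_selective", id = "q2")
  mk <- function(model, method, q, answers)
    do.call(rbind, lapply(seq_along(answers), function(r)
      eval_record(model, method, q$id, r, 0.1, answers[r], q)))
  recs <- rbind(
    mk("m1", "vanilla", qn, c("CHARGE syndrome", "x", "x", "x", "x")),
    mk("m1", "vanilla", q2, c(rep("Noonan syndrome", 4), "x")),
    mk("m1", "vector_rag", qn, rep("CHARGE syndrome", 5)),
    mk("m1", "vector_rag", q2, rep("Noonan syndrome", 5)),
    mk("m2", "vanilla", qn, rep("zzz", 5)),
    mk("m2", "vanilla", q2, rep("zzz", 5)))
  s <- summarize_records(recs, R = 5)
  cell <- function(mo, me, col)
    s$by_cell[s$by_cell$model == mo & s$by_cell$method == me, col]
  expect_equal(cell("m1", "vanilla", "accuracy"), 50)
  expect_equal(cell("m1", "vector_rag", "accuracy"), 100)
  expect_equal(cell("m1", "vector_rag", "consistency"), 100)
  # all responses ungradable: cell reported missing
  expect_true(is.na(cell("m2", "vanilla", "accuracy")))
  # permutation invariance
  s2 <- summarize_records(recs[sample(nrow(recs)), ], R = 5)
  expect_equal(s$averages, s2$averages)
  expect_equal(cell("m1", "vanilla", "consistency"),
               phenorag:::round2(mean(c(80, 80))))
})
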