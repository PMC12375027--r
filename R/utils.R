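#' @useDynLib phenorag, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict sd aggregate
#' @importFrom utils read.delim write.table head adist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

pr_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phenorag_error", "error")))
}

#' @keywords internal
norm_space <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# canonical match key: case-folded, whitespace-collapsed
norm_name <- function(x) tolower(norm_space(x))

# text normalization for grading: case-fold, strip punctuation, collapse ws
norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  norm_space(x)
}

# half-up rounding to 2 decimals, matching printed-table arithmetic
round2 <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

# locale-independent ordering used for byte-stable output
c_order <- function(...) order(..., method = "radix")

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a reproducible child seed from a base seed and string parts
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}
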