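# Fixed-effect term bookkeeping shared by the rating simulator and the
# model-averaging machinery. Terms are strings like "perspective:valence";
# components are always kept in canonical factor order.

#' All fixed-effect terms of a factorial global model
#'
#' Returns the main effects and every interaction of the given factors,
#' ordered by interaction order (mains, then 2-way, 3-way, ...), each term's
#' components in the order of `factors`. Four factors give 15 terms.
#'
#' @param factors Character vector of predictor names.
#' @return Character vector of term names.
#' @export
model_terms <- function(factors = c("perspective", "valence", "fixation", "covariate")) {
  k <- length(factors)
  out <- character(0)
  for (ord in seq_len(k)) {
    combs <- utils::combn(factors, ord, simplify = FALSE)
    out <- c(out, vapply(combs, paste, character(1), collapse = ":"))
  }
  out
}

term_order <- function(terms) {
  lengths(strsplit(terms, ":", fixed = TRUE))
}

# every lower-order term implied by a term's components (marginality)
lower_order_terms <- function(term) {
  comp <- strsplit(term, ":", fixed = TRUE)[[1]]
  k <- length(comp)
  if (k == 1) return(character(0))
  out <- character(0)
  for (ord in seq_len(k - 1)) {
    combs <- utils::combn(comp, ord, simplify = FALSE)
    out <- c(out, vapply(combs, paste, character(1), collapse = ":"))
  }
  out
}

# design matrix (with intercept) for coded numeric predictor columns
term_design_matrix <- function(data, terms) {
  n <- nrow(data)
  X <- matrix(1, n, length(terms) + 1,
    dimnames = list(NULL, c("(Intercept)", terms))
  )
  for (t in terms) {
    comp <- strsplit(t, ":", fixed = TRUE)[[1]]
    X[, t] <- Reduce(`*`, lapply(comp, function(f) data[[f]]))
  }
  X
}

z_score <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# effect coding: reference level -0.5, other +0.5
effect_code <- function(x, levels) {
  stopifnot(all(x %in% levels), length(levels) == 2)
  ifelse(x == levels[1], -0.5, 0.5)
}
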