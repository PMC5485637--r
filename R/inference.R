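#' Assemble the trial-level modelling table
#'
#' Joins AOI fixation metrics, interpretation ratings and participant
#' measures into one row per QC-retained trial, with predictors coded for
#' modelling: the two factors effect-coded (-0.5 / +0.5: perspective
#' other/self, valence negative/positive), and the continuous predictors
#' (fixation time, and social anxiety or age) z-scored across the retained
#' trials. Ratings stay on the 0-100 visual-analogue scale.
#'
#' @param metrics Tibble with `participant_id`, `trial_id`,
#'   `total_aoi_fixation_ms`, `perspective`, `statement_valence`.
#' @param ratings Tibble with `participant_id`, `trial_id`, `rating`.
#' @param participants Tibble with `participant_id` and `sasa_total` and/or
#'   `age`.
#' @param which Individual-difference covariate: `"anxiety"` or `"age"`.
#' @return Tibble with columns `rating`, `perspective`, `valence`,
#'   `fixation`, `covariate` (all predictors numeric, coded as above),
#'   `subject_id`, `scene_id`.
#' @export
build_model_table <- function(metrics, ratings, participants,
                              which = c("anxiety", "age")) {
  which <- match.arg(which)
  cov_col <- if (which == "anxiety") "sasa_total" else "age"
  if (!cov_col %in% names(participants)) {
    stop("participants table lacks column ", cov_col)
  }
  tab <- dplyr::inner_join(metrics, ratings, by = c("participant_id", "trial_id"))
  if (nrow(tab) < nrow(metrics)) {
    miss <- dplyr::anti_join(metrics, ratings, by = c("participant_id", "trial_id"))
    stop(
      "no rating for ", nrow(miss), " trial(s), e.g. ",
      miss$participant_id[1], "/", miss$trial_id[1]
    )
  }
  unmatched <- setdiff(tab$participant_id, participants$participant_id)
  if (length(unmatched) > 0) {
    stop("participants missing from questionnaire table: ",
         paste(unmatched, collapse = ", "))
  }
  tab <- dplyr::inner_join(
    tab, participants[, c("participant_id", cov_col)],
    by = "participant_id"
  )
  tibble::tibble(
    rating = tab$rating,
    perspective = effect_code(tab$perspective, c("other", "self")),
    valence = effect_code(tab$statement_valence, c("negative", "positive")),
    fixation = z_score(tab$total_aoi_fixation_ms),
    covariate = z_score(tab[[cov_col]]),
    subject_id = as.character(tab$participant_id),
    scene_id = as.character(tab$scene_id)
  )
}

#' Fit one candidate linear mixed model
#'
#' Fits `rating ~ <terms> + (1 | subject_id) + (1 | scene_id)` by maximum
#' likelihood (not REML, so that AIC is comparable across fixed-effect
#' structures). The parameter count `k` is the fixed-effect count plus the
#' two random-intercept variances and the residual variance.
#'
#' @param records Output of [build_model_table()].
#' @param term_set Character vector of fixed-effect terms (may be empty for
#'   the intercept-only model); must be marginality-closed.
#' @return List of class `candidate_model`: `terms`, `log_lik`, `k`, `aic`,
#'   `estimates` (named), `se` (named), `converged`.
#' @export
fit_lmm <- function(records, term_set = character(0)) {
  if (length(unique(records$subject_id)) < 2 || length(unique(records$scene_id)) < 2) {
    stop("need at least 2 subjects and 2 scenes for crossed random intercepts")
  }
  for (t in term_set) {
    missing_lower <- setdiff(lower_order_terms(t), term_set)
    if (length(missing_lower) > 0) {
      stop("term set is not marginality-closed: ", t, " lacks ",
           paste(missing_lower, collapse = ", "))
    }
  }
  fixed <- if (length(term_set) == 0) "1" else paste(c("1", term_set), collapse = " + ")
  fml <- stats::as.formula(
    paste0("rating ~ ", fixed, " + (1 | subject_id) + (1 | scene_id)")
  )
  msgs <- character(0)
  # calc.derivs = FALSE skips the finite-difference Hessian check, which
  # dominates fit time in 167-candidate sweeps; optimizer failures still
  # surface through warnings and optinfo
  fit <- withCallingHandlers(
    lme4::lmer(
      fml, data = records, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE)
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- names(est)
  # singular (boundary) fits are valid ML optima, e.g. a variance estimated
  # at zero; only genuine optimizer failure marks a candidate non-converged
  all_msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  trouble <- grepl("converge|Hessian|unable", all_msgs, ignore.case = TRUE) &
    !grepl("singular", all_msgs, ignore.case = TRUE)
  structure(
    list(
      terms = term_set,
      log_lik = as.numeric(ll),
      k = k,
      aic = -2 * as.numeric(ll) + 2 * k,
      estimates = est,
      se = se,
      converged = !any(trouble),
      messages = all_msgs
    ),
    class = "candidate_model"
  )
}

#' Enumerate all marginality-closed candidate term sets
#'
#' All subsets of the global model's terms in which every interaction is
#' accompanied by all its lower-order terms, including the empty
#' (intercept-only) set. A 4-factor global model (15 terms) yields 167
#' candidates. Ordering is deterministic: candidates are grown by scanning
#' terms in increasing interaction order.
#'
#' @param factors Character vector of the global model's factors.
#' @return List of character vectors (term sets).
#' @export
enumerate_candidates <- function(factors = c("perspective", "valence", "fixation", "covariate")) {
  terms <- model_terms(factors)
  sets <- list(character(0))
  for (t in terms) {
    lower <- lower_order_terms(t)
    extended <- Filter(function(s) all(lower %in% s), sets)
    sets <- c(sets, lapply(extended, function(s) c(s, t)))
  }
  sets
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`. Invariant to adding a constant to all AICs.
#'
#' @param aics Numeric vector of AIC values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) == 0 || all(!is.finite(aics))) {
    stop("akaike_weights needs at least one finite AIC")
  }
  delta <- aics - min(aics, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[!is.finite(aics)] <- 0
  w / sum(w)
}

#' Full model averaging over a candidate set
#'
#' Averages each coefficient over all candidate models with the model
#' Akaike weights, substituting 0 in models that omit the term ("full"
#' averaging). The unconditional standard error combines within-model
#' sampling variance and between-model spread:
#' `SE_bar = sum_i w_i * sqrt(SE_i^2 + (theta_i - theta_bar)^2)`.
#' Confidence intervals are `theta_bar +/- 1.96 * SE_bar`; p-values come
#' from the normal approximation `z = theta_bar / SE_bar`. A term is
#' flagged significant iff its interval excludes zero.
#'
#' @param candidates List of `candidate_model` objects (see [fit_lmm()]).
#' @param weights Numeric weights aligned with `candidates` (summing to 1).
#' @param conditional If `TRUE`, average each term only over the models
#'   that contain it (conditional averaging) instead of substituting zeros.
#' @return Object of class `model_averaging_result` with elements
#'   `coefficients` (tibble: term, estimate, se, ci_low, ci_high, p,
#'   significant, weight_sum), `candidates` (summary tibble) and `weights`.
#' @export
model_average <- function(candidates, weights, conditional = FALSE) {
  if (length(candidates) != length(weights)) {
    stop("candidates and weights must have the same length")
  }
  all_terms <- unique(unlist(c(
    list("(Intercept)"), lapply(candidates, function(m) m$terms)
  )))
  coef_rows <- lapply(all_terms, function(term) {
    theta <- vapply(candidates, function(m) {
      if (term %in% names(m$estimates)) m$estimates[[term]] else 0
    }, numeric(1))
    se_i <- vapply(candidates, function(m) {
      if (term %in% names(m$se)) m$se[[term]] else 0
    }, numeric(1))
    has <- vapply(candidates, function(m) term %in% names(m$estimates), logical(1))
    if (conditional && term != "(Intercept)") {
      wc <- weights * has
      if (sum(wc) == 0) wc <- has * 0
      wc <- wc / sum(wc)
      theta_bar <- sum(wc * theta)
      se_bar <- sum(wc * sqrt(se_i^2 + (theta - theta_bar)^2))
    } else {
      theta_bar <- sum(weights * theta)
      se_bar <- sum(weights * sqrt(se_i^2 + (theta - theta_bar)^2))
    }
    z <- theta_bar / se_bar
    tibble::tibble(
      term = term,
      estimate = theta_bar,
      se = se_bar,
      ci_low = theta_bar - 1.96 * se_bar,
      ci_high = theta_bar + 1.96 * se_bar,
      p = 2 * stats::pnorm(-abs(z)),
      significant = (theta_bar - 1.96 * se_bar) > 0 | (theta_bar + 1.96 * se_bar) < 0,
      weight_sum = sum(weights[has])
    )
  })
  cand_tab <- tibble::tibble(
    terms = vapply(candidates, function(m) paste(m$terms, collapse = " + "), character(1)),
    k = vapply(candidates, function(m) m$k, numeric(1)),
    log_lik = vapply(candidates, function(m) m$log_lik, numeric(1)),
    aic = vapply(candidates, function(m) m$aic, numeric(1)),
    weight = weights
  )
  structure(
    list(
      coefficients = dplyr::bind_rows(coef_rows),
      candidates = cand_tab,
      weights = weights
    ),
    class = "model_averaging_result"
  )
}

#' Information-theoretic analysis of interpretation ratings
#'
#' The full analysis for one covariate: enumerates all marginality-closed
#' subsets of the 4-factor global model (perspective, statement valence,
#' AOI fixation time, and social anxiety or age), fits each candidate by
#' maximum likelihood with crossed subject and scene random intercepts,
#' computes Akaike weights, and returns full model-averaged coefficients
#' with 95% confidence intervals: a 16-row table (intercept plus 15 terms).
#' Candidates that fail to converge are dropped from the set with a warning.
#'
#' @param records Output of [build_model_table()].
#' @param which Covariate label used for the pretty term names:
#'   `"anxiety"` or `"age"`.
#' @param conditional Passed to [model_average()].
#' @return A `model_averaging_result`; its `coefficients` tibble carries a
#'   human-readable `label` column.
#' @export
run_analysis <- function(records, which = c("anxiety", "age"),
                         conditional = FALSE) {
  which <- match.arg(which)
  sets <- enumerate_candidates()
  fits <- lapply(sets, function(s) fit_lmm(records, s))
  ok <- vapply(fits, function(m) m$converged, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " candidate model(s) failed to converge and were dropped")
    fits <- fits[ok]
  }
  w <- akaike_weights(vapply(fits, function(m) m$aic, numeric(1)))
  res <- model_average(fits, w, conditional = conditional)
  # order rows as intercept, mains, then interactions by order, and label
  canonical <- c("(Intercept)", model_terms())
  res$coefficients <- res$coefficients[
    order(match(res$coefficients$term, canonical)),
  ]
  cov_label <- if (which == "anxiety") "Social anxiety" else "Age"
  labels <- c(
    "(Intercept)" = "(Intercept)",
    perspective = "Perspective",
    valence = "Statement valence",
    fixation = "Fixation time",
    covariate = cov_label
  )
  res$coefficients$label <- vapply(res$coefficients$term, function(t) {
    comp <- strsplit(t, ":", fixed = TRUE)[[1]]
    paste(ifelse(comp %in% names(labels), labels[comp], comp), collapse = " * ")
  }, character(1))
  res$which <- which
  res
}

#' @export
print.model_averaging_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Model-averaged coefficients over %d candidate models\n",
    nrow(x$candidates)
  ))
  tab <- x$coefficients
  out <- data.frame(
    `Fixed effect` = if ("label" %in% names(tab)) tab$label else tab$term,
    Estimate = round(tab$estimate, digits),
    `95% CI` = sprintf("[%.*f, %.*f]", digits, tab$ci_low, digits, tab$ci_high),
    `p-value` = signif(tab$p, 2),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  invisible(x)
}
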