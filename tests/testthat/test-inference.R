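test_that("the modelling table is coded as documented", {
  h <- make_records(6, 21)
  rec <- h$records
  expect_equal(nrow(rec), nrow(h$design))
  expect_true(all(rec$perspective %in% c(-0.5, 0.5)))
  expect_true(all(rec$valence %in% c(-0.5, 0.5)))
  expect_equal(mean(rec$fixation), 0, tolerance = 1e-9)
  expect_equal(sd(rec$fixation), 1, tolerance = 1e-9)
  expect_equal(mean(rec$covariate), 0, tolerance = 1e-9)
  expect_equal(sd(rec$covariate), 1, tolerance = 1e-9)
  expect_true(all(rec$rating >= 0 & rec$rating <= 100))
})

test_that("the modelling table reports unmatched identifiers", {
  h <- make_records(4, 22)
  broken <- h$ratings[-3, ]
  expect_error(
    build_model_table(h$metrics, broken, h$participants, "anxiety"),
    "no rating"
  )
  p2 <- h$participants[-1, ]
  expect_error(
    build_model_table(h$metrics, h$ratings, p2, "anxiety"),
    "missing from questionnaire"
  )
})

test_that("swapping factor level coding flips the corresponding coefficient", {
  h <- make_records(8, 23)
  rec <- h$records
  m1 <- fit_lmm(rec, c("perspective", "valence"))
  rec2 <- rec
  rec2$valence <- -rec2$valence
  m2 <- fit_lmm(rec2, c("perspective", "valence"))
  expect_equal(m2$estimates[["valence"]], -m1$estimates[["valence"]], tolerance = 1e-6)
  expect_equal(m2$estimates[["perspective"]], m1$estimates[["perspective"]], tolerance = 1e-6)
})

test_that("ML mixed fits collapse to OLS when the random variances are truly zero", {
  tm <- truth_model(
    c("(Intercept)" = 50, valence = -4, fixation = 2),
    sigma_subject = 0, sigma_scene = 0, sigma_resid = 10
  )
  h <- make_records(10, 31, truth = tm)
  rec <- h$records
  terms <- c("perspective", "valence", "fixation")
  mm <- fit_lmm(rec, terms)
  ols <- lm(rating ~ perspective + valence + fixation, data = rec)
  for (t in c("(Intercept)", terms)) {
    expect_equal(mm$estimates[[t]], unname(coef(ols)[t]), tolerance = 1e-3)
  }
  # AIC is definitional
  expect_equal(mm$aic, -2 * mm$log_lik + 2 * mm$k, tolerance = 1e-12)
})

test_that("an intercept-only fit on constant ratings recovers the constant", {
  h <- make_records(4, 33)
  rec <- h$records
  rec$rating <- 50
  m <- suppressWarnings(fit_lmm(rec, character(0)))
  expect_equal(m$estimates[["(Intercept)"]], 50, tolerance = 1e-6)
})

test_that("fit_lmm rejects marginality-violating term sets", {
  h <- make_records(4, 34)
  expect_error(
    fit_lmm(h$records, c("perspective:valence", "perspective")),
    "marginality"
  )
})

test_that("candidate enumeration respects marginality and is exhaustive", {
  two <- enumerate_candidates(c("A", "B"))
  expect_equal(length(two), 5)
  canon <- function(sets) {
    sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1)))
  }
  expect_equal(
    canon(two),
    canon(list(character(0), "A", "B", c("A", "B"), c("A", "B", "A:B")))
  )
  # brute-force oracle: filter the full power set for 3 factors
  terms3 <- model_terms(c("A", "B", "C"))
  power <- unlist(
    lapply(0:7, function(k) utils::combn(terms3, k, simplify = FALSE)),
    recursive = FALSE
  )
  ok <- Filter(function(s) {
    all(vapply(s, function(t) {
      comp <- strsplit(t, ":", fixed = TRUE)[[1]]
      if (length(comp) == 1) return(TRUE)
      lower <- unlist(lapply(seq_len(length(comp) - 1), function(o) {
        vapply(utils::combn(comp, o, simplify = FALSE), paste, character(1), collapse = ":")
      }))
      all(lower %in% s)
    }, logical(1)))
  }, power)
  three <- enumerate_candidates(c("A", "B", "C"))
  expect_equal(canon(three), canon(ok))
  # 4 factors: deterministic, all marginality-closed
  four <- enumerate_candidates()
  expect_equal(length(four), 167)
  expect_identical(canon(four), canon(enumerate_candidates()))
})

test_that("Akaike weights match the closed form and its invariances", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))), tolerance = 1e-9)
  expect_equal(w[1], 0.731, tolerance = 1e-3)
  expect_equal(w[2], 0.269, tolerance = 1e-3)
  ws <- akaike_weights(c(311.2, 308.4, 315.9, 309.0))
  expect_equal(sum(ws), 1, tolerance = 1e-12)
  expect_true(all(ws >= 0))
  expect_equal(akaike_weights(c(311.2, 308.4, 315.9, 309.0) + 57), ws, tolerance = 1e-12)
  expect_error(akaike_weights(c(Inf, Inf)), "finite")
})

test_that("full model averaging matches an independent arithmetic oracle", {
  mk <- function(terms, est, se, aic) {
    structure(
      list(
        terms = terms, log_lik = NA_real_, k = length(est) + 3, aic = aic,
        estimates = est, se = se, converged = TRUE
      ),
      class = "candidate_model"
    )
  }
  m1 <- mk(
    c("A", "B"),
    c("(Intercept)" = 50.2, A = 3.1, B = -2.0),
    c("(Intercept)" = 1.1, A = 0.9, B = 0.7), aic = 400.0
  )
  m2 <- mk(
    "A",
    c("(Intercept)" = 49.8, A = 3.6),
    c("(Intercept)" = 1.2, A = 1.0), aic = 401.5
  )
  m3 <- mk(
    character(0),
    c("(Intercept)" = 50.9),
    c("(Intercept)" = 1.4), aic = 404.0
  )
  w <- akaike_weights(c(400.0, 401.5, 404.0))
  res <- model_average(list(m1, m2, m3), w)

  # spreadsheet-style recomputation, term by term
  d <- c(0, 1.5, 4)
  wo <- exp(-d / 2) / sum(exp(-d / 2))
  thA <- c(3.1, 3.6, 0)
  seA <- c(0.9, 1.0, 0)
  thA_bar <- sum(wo * thA)
  seA_bar <- sum(wo * sqrt(seA^2 + (thA - thA_bar)^2))
  rowA <- res$coefficients[res$coefficients$term == "A", ]
  expect_equal(rowA$estimate, thA_bar, tolerance = 1e-9)
  expect_equal(rowA$se, seA_bar, tolerance = 1e-9)
  expect_equal(rowA$ci_low, thA_bar - 1.96 * seA_bar, tolerance = 1e-9)
  expect_equal(rowA$ci_high, thA_bar + 1.96 * seA_bar, tolerance = 1e-9)
  expect_equal(rowA$p, 2 * pnorm(-abs(thA_bar / seA_bar)), tolerance = 1e-9)
  expect_equal(rowA$weight_sum, wo[1] + wo[2], tolerance = 1e-9)

  thB <- c(-2.0, 0, 0)
  thB_bar <- sum(wo * thB)
  rowB <- res$coefficients[res$coefficients$term == "B", ]
  expect_equal(rowB$estimate, thB_bar, tolerance = 1e-9)
  expect_equal(
    rowB$se, sum(wo * sqrt(c(0.7, 0, 0)^2 + (thB - thB_bar)^2)),
    tolerance = 1e-9
  )

  # convexity: averaged magnitude never exceeds the largest candidate magnitude
  for (i in seq_len(nrow(res$coefficients))) {
    term <- res$coefficients$term[i]
    cand_mag <- vapply(list(m1, m2, m3), function(m) {
      if (term %in% names(m$estimates)) abs(m$estimates[[term]]) else 0
    }, numeric(1))
    expect_lte(abs(res$coefficients$estimate[i]), max(cand_mag) + 1e-12)
  }
})

test_that("degenerate averages reduce to the single supported model", {
  mk <- function(est, se, aic) {
    structure(
      list(
        terms = setdiff(names(est), "(Intercept)"), log_lik = NA_real_,
        k = length(est) + 3, aic = aic, estimates = est, se = se, converged = TRUE
      ),
      class = "candidate_model"
    )
  }
  m1 <- mk(c("(Intercept)" = 48, A = 2.5), c("(Intercept)" = 1, A = 0.8), 100)
  res1 <- model_average(list(m1), 1)
  expect_equal(res1$coefficients$estimate, c(48, 2.5))
  expect_equal(res1$coefficients$ci_low, c(48 - 1.96, 2.5 - 1.96 * 0.8))
  m2 <- mk(c("(Intercept)" = 51, A = -1), c("(Intercept)" = 1, A = 0.5), 130)
  res2 <- model_average(list(m1, m2), c(1, 0))
  expect_equal(
    res2$coefficients$estimate[res2$coefficients$term == "A"], 2.5,
    tolerance = 1e-12
  )
  expect_error(model_average(list(m1, m2), 1), "same length")
})

test_that("the full analysis emits a 16-row table with unit weight mass", {
  h <- make_records(10, 41)
  res <- suppressWarnings(run_analysis(h$records, "anxiety"))
  expect_equal(nrow(res$coefficients), 16)
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)
  expect_equal(res$coefficients$term[1], "(Intercept)")
  expect_equal(nrow(res$candidates), sum(res$weights > -1)) # one row per candidate
  expect_true(all(c("Perspective", "Statement valence", "Fixation time",
                    "Social anxiety") %in% res$coefficients$label))
  # age variant relabels the covariate
  res_age <- suppressWarnings(run_analysis(make_records(10, 41, which = "age")$records, "age"))
  expect_true("Age" %in% res_age$coefficients$label)
})
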