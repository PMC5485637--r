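#' Generate a counterbalanced trial design
#'
#' Each participant sees each of the 72 scenes exactly once, in 6 blocks of
#' 12 trials, with scene order permuted per participant. Scenes are
#' partitioned (per seed) into four groups of 18 and rotated through the
#' perspective x valence cells across participants, so each scene appears
#' in the self condition for half of the participants (plus/minus one when
#' the participant count is odd) and condition cells stay balanced at
#' 18 trials each.
#'
#' @param n_participants Number of participants (at least 2, for
#'   counterbalancing).
#' @param seed Integer seed; fully determines the output.
#' @param n_scenes,n_blocks Scene and block counts (defaults 72 and 6).
#' @return Tibble with one row per trial: `participant_id`, `scene_id`,
#'   `block`, `trial_index_in_block`, `perspective`, `statement_valence`,
#'   `protagonist_side`, `trial_id`.
#' @export
generate_design <- function(n_participants, seed, n_scenes = 72, n_blocks = 6) {
  if (n_participants < 2) {
    stop("counterbalancing requires at least 2 participants")
  }
  stopifnot(n_scenes %% (2 * n_blocks) == 0, n_scenes %% 4 == 0)
  withr::with_seed(seed, {
    group_of <- rep(1:4, each = n_scenes / 4)[sample.int(n_scenes)]
    cells <- data.frame(
      perspective = c("self", "other", "self", "other"),
      statement_valence = c("positive", "positive", "negative", "negative")
    )
    per_block <- n_scenes / n_blocks
    rows <- lapply(seq_len(n_participants), function(p) {
      shift <- (p - 1) %% 4
      cell_idx <- (group_of - 1 + shift) %% 4 + 1
      order <- sample.int(n_scenes)
      tibble::tibble(
        participant_id = sprintf("P%03d", p),
        scene_id = order,
        block = rep(seq_len(n_blocks), each = per_block),
        trial_index_in_block = rep(seq_len(per_block), n_blocks),
        perspective = cells$perspective[cell_idx[order]],
        statement_valence = cells$statement_valence[cell_idx[order]],
        protagonist_side = sample(c("left", "right"), n_scenes, replace = TRUE),
        trial_id = sprintf("P%03d_T%02d", p, seq_len(n_scenes))
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate participant questionnaire responses and age
#'
#' Generates, per participant: 22 SAS-A item responses (18 scored
#' statements driven by a participant-level social-anxiety factor plus item
#' noise, and 4 filler items), PDS responses (four development items on the
#' 1-4 scale, loosely increasing with age, plus menarche), and age in
#' years, uniform over 14-19.75 by default. SAS-A item parameters are set
#' so that total scores in a large sample centre near 46.9 with a standard
#' deviation near 10.6, matching community samples of adolescent females.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param age_range Age range in years.
#' @return List with `participants` (tibble: `participant_id`, `age`,
#'   `sasa_total`, `sasa_cutoff_status`, `pds_category`, `menarche`),
#'   `sasa_items` (n x 22 matrix) and `pds_items` (n x 4 matrix).
#' @export
simulate_participants <- function(n, seed, age_range = c(14, 19.75)) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    z <- stats::rnorm(n)
    scored <- matrix(
      pmin(5, pmax(1, round(
        2.585 + 0.59 * rep(z, each = 18) + 0.9 * stats::rnorm(18 * n)
      ))),
      nrow = n, ncol = 18, byrow = TRUE
    )
    filler <- matrix(sample(1:5, 4 * n, replace = TRUE), nrow = n)
    filler_pos <- c(5, 10, 16, 22)
    sasa <- matrix(NA_real_, n, 22)
    sasa[, filler_pos] <- filler
    sasa[, setdiff(1:22, filler_pos)] <- scored
    sasa_scores <- score_sas_a(sasa, filler_items = filler_pos)

    pgrow <- (age - age_range[1]) / diff(age_range)
    pds_items <- matrix(
      pmin(4, pmax(1, round(
        1.8 + 1.8 * rep(pgrow, 4) + 0.7 * stats::rnorm(4 * n)
      ))),
      nrow = n, ncol = 4
    )
    menarche <- stats::runif(n) < 0.95
    pds_cat <- score_pds(pds_items, menarche)

    list(
      participants = tibble::tibble(
        participant_id = sprintf("P%03d", seq_len(n)),
        age = age,
        sasa_total = sasa_scores$total,
        sasa_cutoff_status = sasa_scores$cutoff_status,
        pds_category = pds_cat,
        menarche = menarche
      ),
      sasa_items = sasa,
      pds_items = pds_items
    )
  })
}

#' Ground-truth rating model
#'
#' The generative mirror of the fitted mixed model: fixed-effect
#' coefficients on the 0-100 rating scale over effect-coded factors and
#' z-scored continuous predictors, plus Gaussian random intercepts for
#' subject and scene and a Gaussian residual.
#'
#' @param beta Named numeric vector of coefficients; names must be
#'   `"(Intercept)"` or terms from [model_terms()].
#' @param sigma_subject,sigma_scene,sigma_resid Standard deviations
#'   (rating units) of the subject intercepts, scene intercepts, and
#'   residual; must be non-negative.
#' @return List of class `truth_model`.
#' @export
truth_model <- function(beta, sigma_subject, sigma_scene, sigma_resid) {
  allowed <- c("(Intercept)", model_terms())
  bad <- setdiff(names(beta), allowed)
  if (length(bad) > 0) {
    stop("unknown terms in beta: ", paste(bad, collapse = ", "))
  }
  stopifnot(sigma_subject >= 0, sigma_scene >= 0, sigma_resid >= 0)
  structure(
    list(
      beta = beta, sigma_subject = sigma_subject,
      sigma_scene = sigma_scene, sigma_resid = sigma_resid
    ),
    class = "truth_model"
  )
}

#' Default truth model for the parameter-recovery harness
#'
#' Coefficients at the magnitude typical of interpretation-bias studies on
#' the 0-100 scale: intercept near 50, main effects of a few units,
#' valence interactions around plus/minus 4-5, higher-order terms zero.
#' Random-effect standard deviations of 6 (subject), 4 (scene) and 18
#' (residual) give mild clustering typical of trial-level VAS ratings.
#'
#' @return A [truth_model()].
#' @export
default_truth_model <- function() {
  truth_model(
    beta = c(
      "(Intercept)" = 50,
      perspective = -1.5,
      valence = -3,
      fixation = 2,
      covariate = 3,
      "perspective:valence" = 4,
      "perspective:fixation" = 2.5,
      "valence:fixation" = -5,
      "valence:covariate" = -4.5
    ),
    sigma_subject = 6, sigma_scene = 4, sigma_resid = 18
  )
}

#' Simulate interpretation ratings from a known mixed model
#'
#' Ratings are generated as `X beta + b_subject + b_scene + e`, truncated
#' to the 0-100 scale, where `X` uses exactly the coding of
#' [build_model_table()]: factors effect-coded -0.5/+0.5 and continuous
#' predictors z-scored across the supplied trials.
#'
#' @param design Design tibble from [generate_design()] (or any table with
#'   `participant_id`, `trial_id`, `scene_id`, `perspective`,
#'   `statement_valence`).
#' @param fixation_time Per-trial fixation time (ms), aligned with
#'   `design` rows.
#' @param covariate Per-trial covariate values (e.g. each participant's
#'   social anxiety score or age), aligned with `design` rows.
#' @param truth A [truth_model()].
#' @param seed Integer seed.
#' @return Tibble: `participant_id`, `trial_id`, `rating`.
#' @export
simulate_ratings <- function(design, fixation_time, covariate, truth, seed) {
  stopifnot(
    inherits(truth, "truth_model"),
    length(fixation_time) == nrow(design),
    length(covariate) == nrow(design)
  )
  coded <- data.frame(
    perspective = effect_code(design$perspective, c("other", "self")),
    valence = effect_code(design$statement_valence, c("negative", "positive")),
    fixation = z_score(fixation_time),
    covariate = z_score(covariate)
  )
  X <- term_design_matrix(coded, model_terms())
  beta_full <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta_full[names(truth$beta)] <- truth$beta
  mu <- as.numeric(X %*% beta_full)
  withr::with_seed(seed, {
    subjects <- unique(design$participant_id)
    scenes <- unique(design$scene_id)
    b_subj <- stats::setNames(stats::rnorm(length(subjects), 0, truth$sigma_subject), subjects)
    b_scene <- stats::setNames(stats::rnorm(length(scenes), 0, truth$sigma_scene), as.character(scenes))
    e <- stats::rnorm(nrow(design), 0, truth$sigma_resid)
    rating <- mu + b_subj[design$participant_id] +
      b_scene[as.character(design$scene_id)] + e
    tibble::tibble(
      participant_id = design$participant_id,
      trial_id = design$trial_id,
      rating = pmin(100, pmax(0, as.numeric(rating)))
    )
  })
}
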