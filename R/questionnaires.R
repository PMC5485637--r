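#' Score the Social Anxiety Scale for Adolescents (SAS-A)
#'
#' The SAS-A has 22 items on a 1-5 scale: 18 statements about social
#' anxiety plus 4 filler items that are not scored. The total score is the
#' sum of the 18 scored items (range 18-90). Published clinical cut-offs
#' lie in the band 50-54; the output annotates each score as below, within,
#' or above that band. Filler positions vary between printed versions of
#' the instrument and are configurable.
#'
#' @param items A numeric vector of 22 responses, or an n x 22 matrix /
#'   data frame (one row per participant).
#' @param filler_items Positions of the 4 unscored filler items.
#' @param cutoff_band Clinical cut-off band `c(lo, hi)`.
#' @return Tibble with `total` and `cutoff_status` (factor:
#'   `below_cutoff`, `within_cutoff_band`, `above_cutoff`).
#' @export
score_sas_a <- function(items, filler_items = c(5, 10, 16, 22),
                        cutoff_band = c(50, 54)) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  if (ncol(m) != 22) stop("SAS-A requires exactly 22 item responses, got ", ncol(m))
  if (length(filler_items) != 4) stop("SAS-A has exactly 4 filler items")
  if (anyNA(m) || any(m < 1 | m > 5) || any(m != round(m))) {
    stop("SAS-A item responses must be integers in 1..5")
  }
  total <- rowSums(m[, -filler_items, drop = FALSE])
  status <- cut(
    total,
    breaks = c(-Inf, cutoff_band[1] - 1e-9, cutoff_band[2], Inf),
    labels = c("below_cutoff", "within_cutoff_band", "above_cutoff")
  )
  tibble::tibble(total = total, cutoff_status = status)
}

#' Score the Pubertal Development Scale (PDS)
#'
#' The category score is the mean of five items: four development questions
#' on a four-point scale (1 = "not yet begun" ... 4 = "seems completed")
#' and menarche as the fifth item, coded 4 ("yes") or 1 ("no").
#'
#' @param items Numeric: either the 4 development items (with `menarche`
#'   supplied separately) or all 5 items with menarche already coded 1/4.
#'   A matrix/data frame scores one participant per row.
#' @param menarche Logical (or `NULL` when `items` already has 5 columns).
#' @return Numeric vector of category scores in `[1, 4]`.
#' @export
score_pds <- function(items, menarche = NULL) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  if (!is.null(menarche)) {
    if (ncol(m) != 4) stop("with menarche supplied, items must have 4 columns")
    if (length(menarche) != nrow(m) || !is.logical(menarche)) {
      stop("menarche must be a logical vector, one value per participant")
    }
    m <- cbind(m, ifelse(menarche, 4, 1))
  }
  if (ncol(m) != 5) stop("PDS requires 5 items (or 4 plus menarche)")
  if (anyNA(m) || any(!m %in% 1:4)) {
    stop("PDS item scores must be in {1, 2, 3, 4}")
  }
  as.numeric(rowSums(m) / 5)
}
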