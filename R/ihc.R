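ihc_levels <- c("not_detected", "low", "medium", "high")
ihc_level_values <- c(not_detected = 0, low = 0.33, medium = 0.66, high = 1)

#' Numeric value of an ordinal IHC staining level
#'
#' Maps the four qualitative staining descriptors used by pathology atlases to
#' fixed numeric values: not detected = 0, low = 0.33, medium = 0.66,
#' high = 1.
#'
#' @param level Character vector of staining levels.
#' @return Numeric vector of the corresponding values.
#' @examples
#' level_value(c("not_detected", "medium", "high"))
#' @export
level_value <- function(level) {
  bad <- setdiff(unique(level[!is.na(level)]), ihc_levels)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Unknown IHC staining level(s): ", paste(bad, collapse = ", "),
      ". Expected one of: ", paste(ihc_levels, collapse = ", "), "."
    ))
  }
  unname(ihc_level_values[level])
}

#' Weighted average of an IHC staining tally
#'
#' Converts a tally of tumor samples scored at each ordinal staining level
#' into a single score in `[0, 1]`:
#' `(1*n_high + 0.66*n_medium + 0.33*n_low + 0*n_not_detected) / total`.
#'
#' @param n_not_detected,n_low,n_medium,n_high Non-negative integer vectors of
#'   sample counts per level (recycled to a common length).
#' @return Numeric vector of weighted averages; an all-zero tally is an error.
#' @examples
#' ihc_weighted_average(1, 1, 1, 1) # 0.4975
#' @export
ihc_weighted_average <- function(n_not_detected, n_low, n_medium, n_high) {
  tot <- n_not_detected + n_low + n_medium + n_high
  if (any(c(n_not_detected, n_low, n_medium, n_high) < 0)) {
    rlang::abort("IHC tallies must be non-negative.")
  }
  if (any(tot < 1)) {
    rlang::abort("IHC weighted average is undefined for a tally with zero samples.")
  }
  (1 * n_high + 0.66 * n_medium + 0.33 * n_low) / tot
}

#' Score IHC tallies and call protein-level overexpression
#'
#' For each (gene, cancer) record, computes the tumor-sample weighted average
#' staining score ([ihc_weighted_average()]) and compares it with the single
#' assigned normal-tissue level: the subunit is called overexpressed when the
#' weighted average is *strictly* greater than the numeric normal value
#' (equality is not overexpression).
#'
#' Records with no stained samples (all four tallies zero, or tally columns
#' missing/NA) represent subunits without usable IHC data; they are emitted
#' with `overexpressed = FALSE` and `reason = "no_data"` so downstream
#' integration can distinguish absence of evidence from negative evidence.
#' An optional `antibody_id` column is carried through untouched.
#'
#' @param tally Tibble with columns `gene`, `cancer`, `n_not_detected`,
#'   `n_low`, `n_medium`, `n_high`, `normal_level` (one of the four level
#'   descriptors), optionally `antibody_id`.
#' @return A tibble with columns `gene`, `cancer`, `weighted_average`,
#'   `normal_value`, `overexpressed`, `reason`
#'   (`"overexpressed"`, `"not_overexpressed"` or `"no_data"`), plus
#'   `antibody_id` if supplied.
#' @examples
#' tally <- tibble::tibble(gene = "ITGA6", cancer = "PAAD",
#'   n_not_detected = 0, n_low = 1, n_medium = 2, n_high = 7,
#'   normal_level = "low")
#' score_ihc(tally)
#' @export
score_ihc <- function(tally) {
  needed <- c("gene", "cancer", "n_not_detected", "n_low", "n_medium",
              "n_high", "normal_level")
  missing <- setdiff(needed, names(tally))
  if (length(missing) > 0) {
    rlang::abort(paste0("IHC tally is missing column(s): ", paste(missing, collapse = ", ")))
  }
  cnt <- tally[c("n_not_detected", "n_low", "n_medium", "n_high")]
  cnt[is.na(cnt)] <- 0
  if (any(as.matrix(cnt) < 0)) rlang::abort("IHC tallies must be non-negative.")
  total <- rowSums(cnt)
  has_data <- total >= 1 & !is.na(tally$normal_level)

  out <- tibble::tibble(
    gene = tally$gene,
    cancer = tally$cancer,
    weighted_average = NA_real_,
    normal_value = level_value(tally$normal_level),
    overexpressed = FALSE,
    reason = "no_data"
  )
  if (any(has_data)) {
    wa <- ihc_weighted_average(
      cnt$n_not_detected[has_data], cnt$n_low[has_data],
      cnt$n_medium[has_data], cnt$n_high[has_data]
    )
    out$weighted_average[has_data] <- wa
    over <- wa > out$normal_value[has_data]
    out$overexpressed[has_data] <- over
    out$reason[has_data] <- ifelse(over, "overexpressed", "not_overexpressed")
  }
  if ("antibody_id" %in% names(tally)) out$antibody_id <- tally$antibody_id
  out
}
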