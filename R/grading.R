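#' Map Gleason scores to ISUP grade groups
#'
#' Converts a Gleason primary/secondary pattern pair into the 5-level ISUP
#' grade group (GG) scale used for prostate biopsies: 3+3 is GG1, 3+4 GG2,
#' 4+3 GG3, 4+4/3+5/5+3 GG4 and 4+5/5+4/5+5 GG5. Only modern patterns
#' 3, 4 and 5 are accepted; obsolete patterns 1-2 are rejected rather than
#' clamped.
#'
#' @param primary,secondary Integer vectors of Gleason patterns, each in
#'   \{3, 4, 5\}. Recycled to a common length.
#' @return An integer vector of ISUP grade groups in 1-5.
#' @examples
#' isup_from_gleason(3, 4) # GG2
#' isup_from_gleason(c(3, 4, 5), c(3, 3, 4))
#' @export
isup_from_gleason <- function(primary, secondary) {
  n <- max(length(primary), length(secondary))
  primary <- rep_len(primary, n)
  secondary <- rep_len(secondary, n)
  ok <- function(p) is.numeric(p) && all(!is.na(p)) && all(p %in% c(3, 4, 5))
  if (!ok(primary) || !ok(secondary)) {
    abort_pk("invalid_pattern", "Gleason patterns must be 3, 4 or 5.")
  }
  s <- primary + secondary
  gg <- integer(n)
  gg[s == 6L] <- 1L
  gg[primary == 3L & secondary == 4L] <- 2L
  gg[primary == 4L & secondary == 3L] <- 3L
  gg[s == 8L & primary != secondary] <- 4L # 3+5 and 5+3
  gg[s == 8L & primary == secondary] <- 4L # 4+4
  gg[s >= 9L] <- 5L
  gg
}

#' Binarize grades into benign versus cancer
#'
#' Collapses the 6-level grade scale (0 = benign, 1-5 = ISUP GG1-GG5) into
#' the detection outcome: any grade of 1 or above is cancer-containing.
#'
#' @param grade Integer vector of grade labels in 0-5; `NA` allowed and
#'   propagated.
#' @return A character vector with values `"benign"` and `"cancer"`.
#' @examples
#' binarize_grade(c(0, 1, 5, NA))
#' @export
binarize_grade <- function(grade) {
  check_grades(grade, "grade", allow_na = TRUE)
  out <- ifelse(grade >= 1L, "cancer", "benign")
  out[is.na(grade)] <- NA_character_
  out
}
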