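# Degrading relative-abundance profiles to presence/absence at a detection
# threshold, and sweeping thresholds.

#' Degrade a relative-abundance profile to presence/absence
#'
#' Entries become 1 when the abundance is strictly positive and at least the
#' threshold, else 0. Thresholds are expressed in percent at the interface
#' (the field's convention) and converted to fractions internally. At
#' `threshold_percent = 0` this is the support indicator: 1 marks presence of
#' the taxon regardless of its relative abundance. Values equal to a positive
#' threshold count as present: only values below the threshold are forced to
#' zero. Idempotent in effect: binarizing an already binary table at
#' threshold 0 returns it unchanged.
#'
#' @param profile A [profile_table()].
#' @param threshold_percent Detection threshold in percent (>= 0).
#' @return A binary [profile_table()] with the same samples and taxa.
#' @export
binarize <- function(profile, threshold_percent = 0) {
  assert_scalar_number(threshold_percent, "threshold_percent", min = 0)
  t_frac <- threshold_percent / 100
  m <- profile_matrix(profile)
  b <- (m > 0 & m >= t_frac) * 1
  res <- dplyr::bind_cols(
    tibble::tibble(sample_id = profile$sample_id),
    tibble::as_tibble(b)
  )
  as_profile(res, rank = profile_rank(profile), binary = TRUE)
}

#' Sweep binarization thresholds
#'
#' Applies [binarize()] at each threshold of the sweep. The default sweep is
#' `{0, 0.0001, 0.001, 0.01, 0.1}` percent: the support indicator plus four
#' detection-limit probes. Per-sample presence counts are non-increasing in
#' the threshold.
#'
#' @param profile A non-binary [profile_table()].
#' @param thresholds_percent Strictly increasing nonnegative thresholds in
#'   percent.
#' @return A named list of binary profile tables, one per threshold, names
#'   formatted from the threshold values.
#' @export
threshold_sweep <- function(profile,
                            thresholds_percent = c(0, 1e-4, 1e-3, 1e-2, 0.1)) {
  if (!is.numeric(thresholds_percent) || !length(thresholds_percent) ||
      any(thresholds_percent < 0) ||
      is.unsorted(thresholds_percent, strictly = TRUE)) {
    stop_input("`thresholds_percent` must be nonnegative and strictly increasing.")
  }
  out <- lapply(thresholds_percent, function(t) binarize(profile, t))
  names(out) <- format(thresholds_percent, trim = TRUE, scientific = FALSE)
  out
}
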