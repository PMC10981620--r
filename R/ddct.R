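#' Relative quantitation by the 2^-ddCt method
#'
#' Standard qPCR relative quantitation: per group, delta-Ct is the mean of
#' target minus reference cycle thresholds; delta-delta-Ct is the treatment
#' minus control difference; the fold change is `2^-ddCt`. Per-sample fold
#' changes (each treatment sample against the control mean delta-Ct) are
#' returned alongside the group summary.
#'
#' @param ct_records `data.frame` with columns `sample_id`, `group`
#'   (`"treatment"` or `"control"`), `ct_target`, `ct_reference`; Ct values
#'   must be finite and positive.
#' @return List with `fold_change`, `ddct`, `dct_treatment`,
#'   `dct_control`, and `per_sample` (`data.frame` of treatment-sample fold
#'   changes).
#' @export
relative_quantity <- function(ct_records) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  stopifnot(is.data.frame(ct_records), all(need %in% colnames(ct_records)))
  if (!all(ct_records$group %in% c("treatment", "control"))) {
    stop("group must be 'treatment' or 'control'", call. = FALSE)
  }
  ct <- ct_records[, c("ct_target", "ct_reference")]
  if (any(!is.finite(as.matrix(ct))) || any(as.matrix(ct) <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  trt <- ct_records[ct_records$group == "treatment", , drop = FALSE]
  ctl <- ct_records[ct_records$group == "control", , drop = FALSE]
  if (nrow(trt) == 0L || nrow(ctl) == 0L) {
    stop("both treatment and control groups must be non-empty",
         call. = FALSE)
  }
  dct_t <- mean(trt$ct_target - trt$ct_reference)
  dct_c <- mean(ctl$ct_target - ctl$ct_reference)
  ddct <- dct_t - dct_c
  per_sample <- data.frame(
    sample_id = trt$sample_id,
    fold_change = 2^-((trt$ct_target - trt$ct_reference) - dct_c),
    stringsAsFactors = FALSE)
  list(fold_change = 2^-ddct, ddct = ddct,
       dct_treatment = dct_t, dct_control = dct_c,
       per_sample = per_sample)
}
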