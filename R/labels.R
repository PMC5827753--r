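#' Performance level from the NASA-TLX performance score
#'
#' The NASA-TLX performance index PS is scored on the 0--20 tick scale
#' with low values meaning good performance, so the performance level is
#' its reversal, PL = 20 - PS.
#'
#' @param ps numeric performance score(s) in \[0, 20\].
#' @param scale_max top of the TLX tick scale (default 20).
#' @return numeric performance level(s).
#' @examples
#' performance_level(8)    # 12
#' @export
performance_level <- function(ps, scale_max = 20) {
  if (any(!is.finite(ps) | ps < 0 | ps > scale_max)) {
    abort(sprintf("performance score outside the 0-%g scale", scale_max))
  }
  scale_max - ps
}

#' Binary trust label from the performance level
#'
#' A recording is labelled `"trustworthy"` when PL strictly exceeds 11 and
#' `"concerning"` otherwise (PL = 11 is concerning).
#'
#' @param pl numeric performance level(s).
#' @param threshold decision threshold (default 11, strict inequality).
#' @return factor with levels `concerning`, `trustworthy`.
#' @examples
#' trust_label(c(12, 11, 0))
#' @export
trust_label <- function(pl, threshold = 11) {
  factor(ifelse(pl > threshold, "trustworthy", "concerning"),
         levels = c("concerning", "trustworthy"))
}

#' Label a table of NASA-TLX assessments
#'
#' Adds `PL` (performance level) and `label` (trust label) columns to a
#' table of TLX scores. The mental-demand column doubles as the task
#' complexity covariate in the complexity-classification experiment.
#'
#' @param data data frame with at least a performance-score column.
#' @param ps_col name of the performance-score column (default
#'   `"performance_score"`).
#' @param scale_max,threshold passed to [performance_level()] and
#'   [trust_label()].
#' @return the input as a tibble with `PL` and `label` appended.
#' @export
label_performance <- function(data, ps_col = "performance_score",
                              scale_max = 20, threshold = 11) {
  if (!ps_col %in% names(data)) {
    abort(paste0("column not found: ", ps_col))
  }
  out <- as_tibble(data)
  out$PL <- performance_level(out[[ps_col]], scale_max = scale_max)
  out$label <- trust_label(out$PL, threshold = threshold)
  out
}
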