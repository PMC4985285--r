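#' Knockdown percentage from cytometry events
#'
#' Gates events on the transfection marker (mCherry at or above the
#' threshold = transfected) and reports 100 x median(GFP | transfected) /
#' median(GFP | untransfected) — the median-fluorescence ratio used to
#' quantify intrabody-mediated protein knockdown. Medians use the midpoint
#' convention for even counts.
#'
#' @param events data.frame with numeric `gfp` and `mcherry` columns.
#' @param mcherry_threshold Gate on the mCherry channel.
#' @return List with `percentage`, `n_transfected`, `n_untransfected`,
#'   `median_transfected`, `median_untransfected`.
#' @examples
#' ev <- data.frame(gfp = c(30, 30, 100, 100), mcherry = c(10, 10, 1, 1))
#' knockdown_percentage(ev, mcherry_threshold = 5)$percentage
#' @export
knockdown_percentage <- function(events, mcherry_threshold) {
  stopifnot(all(c("gfp", "mcherry") %in% names(events)),
            all(events$gfp >= 0), all(events$mcherry >= 0))
  transfected <- events$mcherry >= mcherry_threshold
  n_t <- sum(transfected)
  n_u <- sum(!transfected)
  if (n_t == 0L) stop("no events in the transfected gate")
  if (n_u == 0L) stop("no events in the untransfected gate")
  m_t <- median(events$gfp[transfected])
  m_u <- median(events$gfp[!transfected])
  list(percentage = 100 * m_t / m_u, n_transfected = n_t,
       n_untransfected = n_u, median_transfected = m_t,
       median_untransfected = m_u)
}

#' Normalize a percentage to a non-relevant control
#'
#' @param value Measured percentage.
#' @param control_value Percentage of the non-relevant control.
#' @return 100 * value / control_value.
#' @export
normalize_to_control <- function(value, control_value) {
  stopifnot(control_value > 0)
  100 * value / control_value
}

#' Differential positivity call on a signal pair
#'
#' A clone is called positive for side `a` when its signal clears the floor
#' and exceeds the other side by at least the ratio threshold (and
#' symmetrically for `b`); otherwise negative. This is the rule behind
#' calling clones with a differential ELISA signal in favor of one antigen
#' state.
#'
#' @param signal_a,signal_b Non-negative signals.
#' @param ratio_threshold Minimum fold difference (default 2).
#' @param floor Minimum absolute signal for a positive call.
#' @param eps Guard against division by zero.
#' @return `"positive_a"`, `"positive_b"` or `"negative"`.
#' @export
differential_call <- function(signal_a, signal_b, ratio_threshold = 2,
                              floor = 0.1, eps = 1e-12) {
  stopifnot(signal_a >= 0, signal_b >= 0, ratio_threshold > 0)
  if (signal_a >= floor && signal_a / max(signal_b, eps) >= ratio_threshold)
    return("positive_a")
  if (signal_b >= floor && signal_b / max(signal_a, eps) >= ratio_threshold)
    return("positive_b")
  "negative"
}
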