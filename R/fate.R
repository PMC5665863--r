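#' Eya/Cas co-expression state classification
#'
#' At late stages the two markers become mutually exclusive: main body
#' cells are Eya-high Cas-low, polar and stalk cells Eya-low Cas-high.
#' Earlier, precursors are low for both and delayed-differentiation
#' phenotypes show double-positive cells. A cell is "high" for a marker
#' iff its normalized value is at or above the marker's threshold.
#'
#' @param eya_norm,cas_norm normalized marker values (>= 0)
#' @param thresholds length-2 numeric `c(t_eya, t_cas)` in (0, 1)
#' @return factor with levels `precursor_low_low`, `main_body_high_low`,
#'   `polar_stalk_low_high`, `double_positive_high_high`
#' @export
classify_fate <- function(eya_norm, cas_norm, thresholds = c(0.5, 0.5)) {
  if (any(eya_norm < 0) || any(cas_norm < 0)) stopf("inputs must be >= 0")
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stopf("thresholds must lie in (0, 1) on the normalized scale")
  eh <- eya_norm >= thresholds[1]
  ch <- cas_norm >= thresholds[2]
  lv <- c("precursor_low_low", "main_body_high_low",
          "polar_stalk_low_high", "double_positive_high_high")
  state <- ifelse(eh & ch, lv[4], ifelse(eh, lv[2], ifelse(ch, lv[3], lv[1])))
  factor(state, levels = lv)
}

#' Data-driven fate thresholds from a bimodal marker distribution
#'
#' At stage 4 each marker is bimodal (off vs on); the threshold is placed
#' at the density minimum between the two main modes of a kernel density
#' estimate. If a marker's distribution is unimodal the threshold falls
#' back to 0.5 with a warning.
#'
#' @param eya_norm,cas_norm normalized marker values from late-stage cells
#'   (>= 50 cells)
#' @param bw kernel bandwidth passed to [stats::density()]
#' @return named numeric `c(t_eya, t_cas)`
#' @export
auto_thresholds <- function(eya_norm, cas_norm, bw = "SJ") {
  if (length(eya_norm) < 50 || length(cas_norm) < 50)
    stopf("need at least 50 cells with both markers normalized")
  one <- function(x, label) {
    d <- tryCatch(stats::density(x, bw = bw), error = function(e)
      stats::density(x))
    y <- d$y
    is_max <- which(y > c(-Inf, utils::head(y, -1)) &
                    y >= c(utils::tail(y, -1), -Inf))
    # candidate modes need at least 10% of the peak density
    is_max <- is_max[y[is_max] >= 0.1 * max(y)]
    unimodal <- length(is_max) < 2
    if (!unimodal) {
      two <- sort(is_max[order(-y[is_max])][1:2])
      valley <- two[1] + which.min(y[two[1]:two[2]]) - 1L
      # a shallow dip between wiggles of one mode is not bimodality
      unimodal <- y[valley] > 0.75 * min(y[two])
    }
    if (unimodal) {
      warnf("%s distribution looks unimodal; falling back to threshold 0.5", label)
      return(0.5)
    }
    d$x[valley]
  }
  c(t_eya = one(eya_norm, "Eya"), t_cas = one(cas_norm, "Cas"))
}
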