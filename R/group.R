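#' Group-level inference from single-subject contrast estimates
#'
#' Combines per-subject contrast estimates into per-channel group effects
#' by one of two routes:
#' \describe{
#'   \item{`hierarchical`}{two-level GLS: the between-subject variance is
#'     estimated per channel by a one-step non-negative method of moments
#'     (`max(0, var(b) - mean(v))` with `b` the subject estimates and `v`
#'     their first-level variances), subjects are weighted by
#'     `1 / (v_i + tau^2)`, and a t-statistic on the weighted mean is
#'     formed with `n_subjects - 1` degrees of freedom.}
#'   \item{`summary`}{the summary-statistic shortcut: a one-sample t-test
#'     on the per-subject estimates, ignoring first-level variances.}
#' }
#' With equal first-level variances (and a non-degenerate moment
#' estimate) the hierarchical route reduces to the summary t-test.
#'
#' @param estimates numeric matrix of contrast estimates, subjects x
#'   channels (a vector is treated as a single channel).
#' @param variances matrix of first-level contrast variances, same shape
#'   (required for `method = "hierarchical"`; all > 0).
#' @param method `"hierarchical"` or `"summary"`.
#' @param bonferroni add channel-count-corrected p-values.
#' @return data.frame with one row per channel: `channel`, `effect`,
#'   `se`, `stat`, `p`, `tau2` (hierarchical only), and optionally
#'   `p_bonferroni`. p-values are two-sided.
#' @export
group_inference <- function(estimates, variances = NULL,
                            method = c("hierarchical", "summary"),
                            bonferroni = FALSE) {
  method <- match.arg(method)
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1)
  n_sub <- nrow(estimates)
  if (n_sub < 3) stop("group inference requires at least 3 subjects")
  if (method == "hierarchical") {
    if (is.null(variances)) stop("hierarchical inference needs first-level variances")
    if (is.vector(variances)) variances <- matrix(variances, ncol = 1)
    if (!all(dim(variances) == dim(estimates)))
      stop("`variances` must match the shape of `estimates`")
    if (any(variances <= 0)) stop("first-level variances must be positive")
  }
  chans <- colnames(estimates)
  if (is.null(chans)) chans <- paste0("ch", seq_len(ncol(estimates)))
  rows <- lapply(seq_len(ncol(estimates)), function(j) {
    b <- estimates[, j]
    if (method == "summary") {
      tt <- stats::t.test(b)
      data.frame(channel = chans[j], effect = mean(b),
                 se = unname(tt$stderr), stat = unname(tt$statistic),
                 p = tt$p.value, tau2 = NA_real_)
    } else {
      v <- variances[, j]
      tau2 <- max(0, stats::var(b) - mean(v))
      w <- 1 / (v + tau2)
      eff <- sum(w * b) / sum(w)
      se <- sqrt(1 / sum(w))
      tt <- eff / se
      data.frame(channel = chans[j], effect = eff, se = se, stat = tt,
                 p = 2 * stats::pt(-abs(tt), n_sub - 1), tau2 = tau2)
    }
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}
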