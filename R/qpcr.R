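#' Per-probe qPCR log2 fold changes
#'
#' Averages the replicate relative expressions per condition and takes
#' `log2(mean RW / mean DS)` for every (probe, genotype).
#'
#' @param qpcr Data frame with columns `probe_id`, `genotype`,
#'   `treatment` (`DS`/`RW`), `replicate`, `relative_expression` (> 0).
#' @return Data frame `probe_id`, `genotype`, `log2fc`.
#' @export
qpcr_log2fc <- function(qpcr) {
  need <- c("probe_id", "genotype", "treatment", "relative_expression")
  stopifnot(all(need %in% names(qpcr)))
  if (any(qpcr$relative_expression <= 0))
    stop("relative expressions must be positive")
  agg <- stats::aggregate(relative_expression ~ probe_id + genotype + treatment,
                          data = qpcr, FUN = mean)
  ds <- agg[agg$treatment == "DS", ]
  rw <- agg[agg$treatment == "RW", ]
  key <- function(d) paste(d$probe_id, d$genotype)
  m <- match(key(ds), key(rw))
  if (any(is.na(m))) stop("each probe/genotype needs both DS and RW values")
  out <- data.frame(probe_id = ds$probe_id, genotype = ds$genotype,
                    log2fc = log2(rw$relative_expression[m] /
                                    ds$relative_expression),
                    stringsAsFactors = FALSE)
  out <- out[stable_order(out$probe_id, out$genotype), ]
  rownames(out) <- NULL
  out
}

#' RNA-seq / qPCR concordance regression
#'
#' Ordinary least squares of the RNA-seq log2 fold changes (response) on
#' the qPCR log2 fold changes (predictor), matching the orientation of a
#' platform-validation scatter plot; reports the slope, intercept and
#' squared Pearson correlation.
#'
#' @param rnaseq_lfc,qpcr_lfc Matched numeric vectors (n >= 3); the qPCR
#'   vector must not be constant.
#' @return List `n_points`, `slope`, `intercept`, `r2`.
#' @export
#' @examples
#' concordance(c(-1.8, -1.2, 0.1, 1.1, 1.9), c(-2, -1, 0, 1, 2))
concordance <- function(rnaseq_lfc, qpcr_lfc) {
  if (length(rnaseq_lfc) != length(qpcr_lfc))
    stop("fold-change vectors must be matched")
  ok <- is.finite(rnaseq_lfc) & is.finite(qpcr_lfc)
  x <- qpcr_lfc[ok]; y <- rnaseq_lfc[ok]
  if (length(x) < 3) stop("concordance requires at least 3 points")
  if (stats::var(x) == 0) stop("qPCR fold changes are constant; fit degenerate")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(n_points = length(x),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r^2)
}
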