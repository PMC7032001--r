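#' Hypergeometric over-representation test per annotation term
#'
#' For each term with `K` annotated genes in the population (`N` genes),
#' of which `k` fall in the study set (`n` genes), computes the
#' upper-tail hypergeometric probability `P(X >= k)` and BH-corrects
#' across the terms of the map. The "rich factor" `k/K` — the share of a
#' term's genes that are in the study set — is reported per term.
#'
#' @param study Character vector of study (e.g. DE or co-expressed
#'   target) gene ids; must be a subset of `population`.
#' @param population Character vector of universe gene ids.
#' @param term_map Data frame with columns `feature_id`, `term_id`
#'   (one namespace, e.g. GO or KEGG).
#' @return Data frame `term_id`, `k`, `K`, `n`, `N`, `rich_factor`, `p`,
#'   `p_corrected`, `method`, sorted by `p`.
#' @export
#' @examples
#' pop <- sprintf("g%02d", 1:20)
#' tm <- data.frame(feature_id = pop[1:5], term_id = "T1")
#' hypergeom_enrich(pop[c(1:4, 6:9)], pop, tm)
hypergeom_enrich <- function(study, population, term_map) {
  tab <- enrich_table(study, population, term_map)
  tab$p <- stats::phyper(tab$k - 1, tab$K, tab$N - tab$K, tab$n,
                         lower.tail = FALSE)
  finish_enrich(tab, "hypergeometric")
}

enrich_table <- function(study, population, term_map) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    stop("study set must be a subset of the population")
  tm <- term_map[term_map$feature_id %in% population, , drop = FALSE]
  terms <- sort(unique(tm$term_id))
  N <- length(population); n <- length(study)
  K <- vapply(terms, function(t)
    length(unique(tm$feature_id[tm$term_id == t])), integer(1))
  k <- vapply(terms, function(t)
    length(intersect(study, tm$feature_id[tm$term_id == t])), integer(1))
  data.frame(term_id = terms, k = k, K = K, n = n, N = N,
             rich_factor = ifelse(K > 0, k / K, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

finish_enrich <- function(tab, method) {
  tab$p_corrected <- bh_adjust(tab$p)
  tab$method <- method
  tab <- tab[stable_order(tab$p, tab$term_id), ]
  rownames(tab) <- NULL
  tab
}

#' Monotone gene-length weights for length-bias correction
#'
#' Longer genes accumulate more fragments and are easier to call DE; the
#' correction estimates `P(DE | length)` as a monotone nondecreasing step
#' function (binned proportions followed by a pooled-adjacent-violators
#' fit via [stats::isoreg]) and returns it per gene, normalized to mean
#' 1 over the population. With a single bin, or when the study flags are
#' all equal, the weights are identically 1.
#'
#' @param lengths Positive gene lengths (bp), one per population gene.
#' @param de_flags Logical vector marking study-set membership.
#' @param n_bins Number of quantile bins of length (default 20).
#' @return Numeric weights, mean exactly 1.
#' @export
length_weights <- function(lengths, de_flags, n_bins = 20) {
  stopifnot(length(lengths) == length(de_flags), n_bins >= 1)
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  de_flags <- as.logical(de_flags)
  if (all(de_flags) || !any(de_flags) || n_bins == 1)
    return(rep(1, length(lengths)))
  breaks <- unique(stats::quantile(lengths, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(rep(1, length(lengths)))
  bin <- cut(lengths, breaks, include.lowest = TRUE, labels = FALSE)
  bin_len <- tapply(lengths, bin, mean)
  bin_prob <- tapply(de_flags, bin, mean)
  o <- order(bin_len)
  fit <- stats::isoreg(bin_len[o], bin_prob[o])
  fitted <- fit$yf[order(o)]
  w <- fitted[match(bin, sort(unique(bin)))]
  w <- pmax(w, 1e-6)       # keep odds finite for empty low-length bins
  w / mean(w)
}

#' Wallenius noncentral hypergeometric pmf
#'
#' Probability of drawing `k` "success" items when `n` items are drawn
#' sequentially without replacement from an urn of `N` items, `K` of
#' them successes, each success having sampling weight `w` relative to
#' 1 for a failure. Computed exactly by dynamic programming over the
#' draw sequence (state = draws made, successes so far), which follows
#' directly from the distribution's sequential definition and is exact
#' for any urn size. `w = 1` reduces to the central hypergeometric.
#'
#' @param N,K,n Urn size, success count, number of draws.
#' @param w Positive odds of a success item.
#' @return Numeric vector of probabilities for `k = 0, ..., min(n, K)`
#'   (named by `k`); sums to 1.
#' @export
#' @examples
#' wallenius_pmf(10, 4, 3, w = 2)
wallenius_pmf <- function(N, K, n, w) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N, is.finite(w), w > 0)
  kmax <- min(n, K)
  f <- c(1, rep(0, kmax))              # f[k+1] = P(k successes after t draws)
  if (n > 0) {
    for (t in 0:(n - 1)) {
      ks <- 0:min(t, kmax)
      succ_left <- K - ks
      fail_left <- (N - K) - (t - ks)
      denom <- w * succ_left + fail_left
      p_succ <- ifelse(denom > 0, w * succ_left / denom, 0)
      nf <- rep(0, kmax + 1)
      nf[ks + 1] <- f[ks + 1] * (1 - p_succ)
      up <- which(p_succ > 0)          # ks < kmax whenever p_succ > 0
      nf[ks[up] + 2] <- nf[ks[up] + 2] + f[ks[up] + 1] * p_succ[up]
      f <- nf
    }
  }
  names(f) <- 0:kmax
  f
}

#' Upper-tail Wallenius probability
#'
#' `P(X >= k)` under [wallenius_pmf()].
#'
#' @inheritParams wallenius_pmf
#' @param k Observed success count.
#' @return Upper-tail probability.
#' @export
wallenius_tail <- function(k, N, K, n, w) {
  pmf <- wallenius_pmf(N, K, n, w)
  if (k <= 0) return(1)
  sum(pmf[as.integer(names(pmf)) >= k])
}

#' Length-bias-corrected over-representation test (Wallenius)
#'
#' Like [hypergeom_enrich()] but models the sampling bias encoded in
#' per-gene `weights` (typically from [length_weights()]): each term's
#' odds parameter is the mean weight of its genes divided by the mean
#' weight of the remaining population, and the upper-tail p-value is
#' computed under the Wallenius noncentral hypergeometric distribution.
#' Unit weights reproduce the central hypergeometric test.
#'
#' @inheritParams hypergeom_enrich
#' @param weights Positive per-gene weights, named by gene id or in
#'   `population` order.
#' @return Data frame as in [hypergeom_enrich()] with
#'   `method = "wallenius"`.
#' @export
wallenius_enrich <- function(study, population, term_map, weights) {
  population <- unique(population)
  if (!is.null(names(weights))) weights <- weights[population]
  if (length(weights) != length(population) || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop("weights must be positive and finite, one per population gene")
  tab <- enrich_table(study, population, term_map)
  tm <- term_map[term_map$feature_id %in% population, , drop = FALSE]
  tab$p <- vapply(seq_len(nrow(tab)), function(i) {
    members <- unique(tm$feature_id[tm$term_id == tab$term_id[i]])
    inside <- population %in% members
    w_in <- mean(weights[inside])
    w_out <- if (all(inside)) w_in else mean(weights[!inside])
    odds <- w_in / w_out
    if (!is.finite(odds) || odds <= 0) stop("non-finite odds for term ",
                                            tab$term_id[i])
    wallenius_tail(tab$k[i], tab$N[i], tab$K[i], tab$n[i], odds)
  }, numeric(1))
  finish_enrich(tab, "wallenius")
}

#' Term over-representation with selectable method
#'
#' Dispatches to [hypergeom_enrich()] or, when `method = "wallenius"`,
#' fits [length_weights()] from `lengths` and study membership and runs
#' [wallenius_enrich()].
#'
#' @inheritParams hypergeom_enrich
#' @param method `"hypergeometric"` (default) or `"wallenius"`.
#' @param lengths Gene lengths named by id (required for Wallenius).
#' @param n_bins Bins for [length_weights()].
#' @return Enrichment data frame.
#' @export
enrich_terms <- function(study, population, term_map,
                         method = c("hypergeometric", "wallenius"),
                         lengths = NULL, n_bins = 20) {
  method <- match.arg(method)
  if (method == "hypergeometric")
    return(hypergeom_enrich(study, population, term_map))
  if (is.null(lengths)) stop("'lengths' required for the Wallenius method")
  population <- unique(population)
  len <- lengths[population]
  if (any(is.na(len))) stop("lengths missing for some population genes")
  w <- length_weights(len, population %in% study, n_bins = n_bins)
  names(w) <- population
  wallenius_enrich(study, population, term_map, w)
}
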