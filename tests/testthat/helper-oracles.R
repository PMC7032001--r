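# Independent brute-force oracles used to check the package's formulas.
# These deliberately avoid the code paths they verify.

# FPKM from its definition, one cell at a time
bf_fpkm <- function(counts, lengths, lib_sizes) {
  out <- matrix(NA_real_, nrow(counts), ncol(counts))
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      out[i, j] <- counts[i, j] * 1e9 /
        (as.numeric(lengths[i]) * as.numeric(lib_sizes[j]))
  dimnames(out) <- dimnames(counts)
  out
}

# product-moment correlation from sums
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# BH from the literal step-up definition: q_i is the smallest
# t * m / rank(t) over all observed thresholds t >= p_i
bf_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) t * m / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# upper-tail hypergeometric via binomial coefficients
bf_hyper_tail <- function(k, N, K, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# closed-form least squares on centered data
bf_ols <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = sum(xc * yc)^2 / (sum(xc^2) * sum(yc^2)))
}

# Wallenius pmf by exhaustive recursion over ordered draw sequences:
# every draw picks a remaining item with probability proportional to
# its weight (w for a success, 1 for a failure)
bf_wallenius_pmf <- function(N, K, n, w) {
  pmf <- numeric(min(n, K) + 1)
  recurse <- function(succ_left, fail_left, draws_left, k, prob) {
    if (draws_left == 0) {
      pmf[k + 1] <<- pmf[k + 1] + prob
      return(invisible())
    }
    tot <- w * succ_left + fail_left
    if (succ_left > 0)
      recurse(succ_left - 1, fail_left, draws_left - 1, k + 1,
              prob * w * succ_left / tot)
    if (fail_left > 0)
      recurse(succ_left, fail_left - 1, draws_left - 1, k,
              prob * fail_left / tot)
  }
  recurse(K, N - K, n, 0, 1)
  names(pmf) <- 0:min(n, K)
  pmf
}

# interval gap by naive case analysis
bf_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) return(s2 - e1)
  if (e2 < s1) return(s1 - e2)
  0
}

# all planted (lncRNA, mRNA) same-module pairs for one genotype
planted_module_pairs <- function(truth, genotype) {
  tr <- truth[truth$genotype == genotype & truth$module_id != "", ]
  mods <- split(tr, tr$module_id)
  do.call(rbind, lapply(mods, function(m) {
    expand.grid(lncrna_id = m$feature_id[m$biotype == "lncRNA"],
                mrna_id = m$feature_id[m$biotype == "mRNA"],
                stringsAsFactors = FALSE)
  }))
}

# all between-module (lncRNA, mRNA) pairs for one genotype
cross_module_pairs <- function(truth, genotype) {
  tr <- truth[truth$genotype == genotype & truth$module_id != "", ]
  lnc <- tr[tr$biotype == "lncRNA", ]
  mrna <- tr[tr$biotype == "mRNA", ]
  out <- expand.grid(lncrna_id = lnc$feature_id, mrna_id = mrna$feature_id,
                     stringsAsFactors = FALSE)
  out$same <- lnc$module_id[match(out$lncrna_id, lnc$feature_id)] ==
    mrna$module_id[match(out$mrna_id, mrna$feature_id)]
  out[!out$same, c("lncrna_id", "mrna_id")]
}

pair_key <- function(d) paste(d$lncrna_id, d$mrna_id)

# a small study shared by several test files (computed once per run)
test_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study(simulate_config(
        n_mrna = 600, n_lncrna = 100, n_modules = 2, module_size = c(4, 10),
        n_go_terms = 15, n_kegg_terms = 8, seed = 42))
    cache
  }
})

de_by_biotype <- function(study, genotype, ...) {
  lengths <- stats::setNames(study$annotation$length,
                             study$annotation$feature_id)
  de <- call_de(study$counts, study$design, genotype, lengths, ...)
  is_lnc <- stats::setNames(study$annotation$biotype == "lncRNA",
                            study$annotation$feature_id)
  list(all = de, lnc = de[is_lnc[de$feature_id], ],
       mrna = de[!is_lnc[de$feature_id], ],
       fpkm = compute_fpkm(study$counts, lengths))
}
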