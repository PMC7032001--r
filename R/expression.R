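#' Fragments per kilobase per million mapped fragments (FPKM)
#'
#' `fpkm[i, j] = counts[i, j] * 1e9 / (lengths[i] * library_sizes[j])`.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param lengths Positive integer vector of exonic lengths (bp), one per
#'   feature (recycled from a named vector by rowname match when named).
#' @param library_sizes Positive totals of mapped fragments per sample;
#'   defaults to the column sums of `counts`.
#' @return Numeric matrix of FPKM values with the dimnames of `counts`.
#' @export
#' @examples
#' m <- matrix(c(0L, 200L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_fpkm(m, lengths = c(1000, 2000), library_sizes = 2e6)
compute_fpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("'lengths' must supply one length per feature")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("feature lengths must be positive")
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0))
    stop("'library_sizes' must be positive, one per sample")
  fpkm <- sweep(counts / lengths, 2, library_sizes, "/") * 1e9
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Mean expression per (genotype, treatment) condition
#'
#' Arithmetic mean of the replicate columns for every design cell.
#'
#' @param expr Numeric matrix, features x samples (FPKM).
#' @param design Sample design with columns `sample_id`, `genotype`,
#'   `treatment`.
#' @return Matrix, features x conditions, condition columns named
#'   `"<genotype>.<treatment>"`.
#' @export
condition_means <- function(expr, design) {
  check_design(design, colnames(expr))
  cells <- unique(design[, c("genotype", "treatment")])
  out <- vapply(seq_len(nrow(cells)), function(i) {
    s <- design$sample_id[design$genotype == cells$genotype[i] &
                            design$treatment == cells$treatment[i]]
    if (length(s) == 0) stop("empty design cell: ",
                             cells$genotype[i], "/", cells$treatment[i])
    rowMeans(expr[, s, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr), ncol = nrow(cells))
  colnames(out) <- paste(cells$genotype, cells$treatment, sep = ".")
  rownames(out) <- rownames(expr)
  out
}

check_design <- function(design, sample_ids = NULL) {
  need <- c("sample_id", "genotype", "treatment")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  if (!is.null(sample_ids) && !all(design$sample_id %in% sample_ids))
    stop("design samples missing from the expression matrix")
  invisible(design)
}

#' Moderated log2 expression ratio
#'
#' `log2((a + epsilon) / (b + epsilon))`, the RW-over-DS fold change.
#' With `epsilon = 0` a zero denominator yields a signed infinity and a
#' 0/0 ratio is defined as 0 (degenerate, both conditions silent).
#'
#' @param mean_rw,mean_ds Non-negative condition means (vectorized).
#' @param epsilon Non-negative pseudo-expression added to both means.
#' @return Numeric vector of log2 ratios.
#' @export
#' @examples
#' log2_ratio(8, 2, epsilon = 0)    # 2
#' log2_ratio(8, 2, epsilon = 0.1)  # log2(8.1/2.1)
log2_ratio <- function(mean_rw, mean_ds, epsilon = 0.1) {
  stopifnot(epsilon >= 0)
  if (any(mean_rw < 0 | mean_ds < 0, na.rm = TRUE))
    stop("condition means must be >= 0")
  r <- log2((mean_rw + epsilon) / (mean_ds + epsilon))
  r[mean_rw == 0 & mean_ds == 0] <- 0
  r
}

#' Negative-binomial Wald test for a two-group count contrast
#'
#' Tests, per feature, whether the expression rate differs between the DS
#' and RW replicate groups. Counts are normalized by relative library
#' size; the statistic is the difference of the log rate means divided by
#' its delta-method standard error, with the NB variance
#' \eqn{\mu + \phi\mu^2} estimated per group by method of moments (the
#' group sample variance of the normalized counts, floored at the Poisson
#' variance when it degenerates to zero). Reference distribution is
#' Student t with `n1 + n2 - 2` degrees of freedom, which keeps the test
#' close to nominal size with as few as three replicates per group.
#'
#' @param counts_ds,counts_rw Integer matrices (features x replicates) or
#'   vectors (one feature) of fragment counts per group.
#' @param sizes_ds,sizes_rw Library sizes for the columns of each group.
#' @return Data frame with columns `p` and `degenerate` (`TRUE` where the
#'   feature is all-zero in both groups; such features get `p = 1`).
#' @export
#' @examples
#' nb_test(c(10, 12, 11), c(100, 110, 105),
#'         sizes_ds = rep(1e6, 3), sizes_rw = rep(1e6, 3))
nb_test <- function(counts_ds, counts_rw, sizes_ds, sizes_rw) {
  if (is.null(dim(counts_ds))) counts_ds <- matrix(counts_ds, nrow = 1)
  if (is.null(dim(counts_rw))) counts_rw <- matrix(counts_rw, nrow = 1)
  n1 <- ncol(counts_ds); n2 <- ncol(counts_rw)
  if (n1 < 2 || n2 < 2) stop("at least 2 replicates per group required")
  stopifnot(length(sizes_ds) == n1, length(sizes_rw) == n2,
            all(sizes_ds > 0), all(sizes_rw > 0))
  s_all <- c(sizes_ds, sizes_rw) / mean(c(sizes_ds, sizes_rw))
  y1 <- sweep(counts_ds, 2, s_all[seq_len(n1)], "/")
  y2 <- sweep(counts_rw, 2, s_all[n1 + seq_len(n2)], "/")
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  degenerate <- m1 == 0 & m2 == 0
  # continuity shift when one group is all-zero, so the log contrast exists
  shift <- !degenerate & (m1 == 0 | m2 == 0)
  if (any(shift)) {
    y1[shift, ] <- y1[shift, , drop = FALSE] + 0.5
    y2[shift, ] <- y2[shift, , drop = FALSE] + 0.5
    m1[shift] <- rowMeans(y1[shift, , drop = FALSE])
    m2[shift] <- rowMeans(y2[shift, , drop = FALSE])
  }
  v1 <- apply(y1, 1, stats::var); v2 <- apply(y2, 1, stats::var)
  v1 <- ifelse(v1 == 0, m1, v1)   # Poisson floor for degenerate variances
  v2 <- ifelse(v2 == 0, m2, v2)
  se <- sqrt(v1 / (n1 * m1^2) + v2 / (n2 * m2^2))
  z <- (log(m2) - log(m1)) / se
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)
  p[degenerate | m1 == m2] <- 1
  data.frame(p = pmin(p, 1), degenerate = degenerate)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to
#' the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  p <- pvals[ok]
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  qq <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[ok][o] <- qq
  q
}

#' Call differential expression for one genotype (RW versus DS)
#'
#' Applies the expression filter, the NB Wald test, BH correction, and
#' the joint threshold `q <= q_max` and `|log2 ratio| >= lfc_min`. The
#' tested universe is every feature with nonzero mean FPKM in at least
#' one condition of the genotype; excluded features are reported
#' `not_de` with `degenerate = TRUE`.
#'
#' @param counts Integer count matrix, features x samples.
#' @param design Sample design (see [generate_study()]).
#' @param genotype Genotype label to contrast.
#' @param lengths Feature lengths in bp (for FPKM).
#' @param q_max,lfc_min Call thresholds (defaults `0.05` and `1`).
#' @param epsilon Pseudo-expression for [log2_ratio()].
#' @return Data frame of per-feature records: `feature_id`, `genotype`,
#'   `mean_DS`, `mean_RW`, `log2_ratio`, `p`, `q`, `call` (one of `up`,
#'   `down`, `not_de`) and `degenerate`.
#' @export
call_de <- function(counts, design, genotype, lengths,
                    q_max = 0.05, lfc_min = 1, epsilon = 0.1) {
  check_design(design, colnames(counts))
  if (!genotype %in% design$genotype)
    stop("unknown genotype: ", genotype)
  d <- design[design$genotype == genotype, ]
  s_ds <- d$sample_id[d$treatment == "DS"]
  s_rw <- d$sample_id[d$treatment == "RW"]
  if (length(s_ds) < 2 || length(s_rw) < 2)
    stop("need >= 2 replicates per treatment for genotype ", genotype)
  lib <- d$library_size %||% colSums(counts)[d$sample_id]
  names(lib) <- d$sample_id
  fpkm <- compute_fpkm(counts[, d$sample_id, drop = FALSE], lengths,
                       library_sizes = lib[d$sample_id])
  mean_ds <- rowMeans(fpkm[, s_ds, drop = FALSE])
  mean_rw <- rowMeans(fpkm[, s_rw, drop = FALSE])
  lfc <- log2_ratio(mean_rw, mean_ds, epsilon)

  tested <- mean_ds > 0 | mean_rw > 0
  res <- data.frame(feature_id = rownames(counts), genotype = genotype,
                    mean_DS = mean_ds, mean_RW = mean_rw, log2_ratio = lfc,
                    p = NA_real_, q = NA_real_, call = "not_de",
                    degenerate = !tested, stringsAsFactors = FALSE)
  if (any(tested)) {
    tst <- nb_test(counts[tested, s_ds, drop = FALSE],
                   counts[tested, s_rw, drop = FALSE],
                   sizes_ds = lib[s_ds], sizes_rw = lib[s_rw])
    res$p[tested] <- tst$p
    res$q[tested] <- bh_adjust(tst$p)
    up <- tested & res$q <= q_max & res$log2_ratio >= lfc_min
    dn <- tested & res$q <= q_max & res$log2_ratio <= -lfc_min
    res$call[which(up)] <- "up"
    res$call[which(dn)] <- "down"
  }
  rownames(res) <- NULL
  res
}

#' Compare differential-expression calls between two genotypes
#'
#' Partitions the union of the two DE sets into `A_only`, `B_only`,
#' `shared_up`, `shared_down`, `up_A_down_B` and `down_A_up_B`. The four
#' shared/converse classes are disjoint and their union is the DE
#' intersection, so class sizes reconstruct |A| and |B| exactly.
#'
#' @param de_a,de_b DE tables from [call_de()] over the same feature
#'   universe.
#' @return List with `classes` (named list of feature-id vectors) and
#'   `counts` (named integer vector, including `A_total`, `B_total`,
#'   `shared_total`).
#' @export
compare_genotypes <- function(de_a, de_b) {
  if (!setequal(de_a$feature_id, de_b$feature_id))
    stop("the two DE tables must cover the same feature universe")
  a <- de_a[de_a$call != "not_de", c("feature_id", "call")]
  b <- de_b[de_b$call != "not_de", c("feature_id", "call")]
  shared <- intersect(a$feature_id, b$feature_id)
  ca <- a$call[match(shared, a$feature_id)]
  cb <- b$call[match(shared, b$feature_id)]
  classes <- list(
    A_only       = sort(setdiff(a$feature_id, b$feature_id)),
    B_only       = sort(setdiff(b$feature_id, a$feature_id)),
    shared_up    = sort(shared[ca == "up" & cb == "up"]),
    shared_down  = sort(shared[ca == "down" & cb == "down"]),
    up_A_down_B  = sort(shared[ca == "up" & cb == "down"]),
    down_A_up_B  = sort(shared[ca == "down" & cb == "up"]))
  counts <- vapply(classes, length, integer(1))
  counts <- c(counts, A_total = nrow(a), B_total = nrow(b),
              shared_total = length(shared))
  list(classes = classes, counts = counts)
}
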