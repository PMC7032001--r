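#' Configuration for a synthetic two-genotype drought/re-watering study
#'
#' Builds and validates the parameter set for [generate_study()]. The
#' defaults emulate a bulk RNA-seq experiment with two contrasting
#' genotypes (`tolerant`, `sensitive`), two treatments (drought stress
#' `DS`, re-watering `RW`) and three biological replicates per cell —
#' twelve libraries in all — with negative-binomial counts, planted
#' differential expression, and planted co-regulated lncRNA-mRNA modules.
#'
#' Counts for feature \eqn{i} in sample \eqn{j} are drawn
#' \eqn{NB(\mu_{ij}, \phi)} with \eqn{Var = \mu + \phi\mu^2}. The mean is
#' assembled on the FPKM scale: a base expression level
#' \eqn{10^{U(\code{base_mean_log_range})}} FPKM, converted to expected
#' fragments via feature length and library size, then modulated by
#' \eqn{2^{\beta \cdot RW_j + \epsilon_{ij}}} where \eqn{\beta} is the
#' planted re-watering effect (zero for non-DE features) and
#' \eqn{\epsilon} is log-normal replicate noise. Members of a planted
#' module share, within each genotype, a single latent per-sample profile
#' (sd `module_latent_sd` in log2 units, centred within each treatment
#' group so it perturbs replicate covariance but not the planted
#' contrast); this is what makes their expression profiles correlate.
#'
#' @param n_mrna,n_lncrna Number of protein-coding / lncRNA features.
#' @param n_chromosomes Number of chromosomes features are placed on.
#' @param n_reps Biological replicates per (genotype, treatment) cell.
#' @param frac_de Fraction of features planted as differentially
#'   expressed per genotype (module members come on top of this).
#' @param lfc_range Range (log2 units) of planted |effect| for ordinary
#'   DE features; the minimum must be >= 1 so planted effects clear the
#'   |log2 ratio| >= 1 call threshold by construction.
#' @param dispersion Negative-binomial dispersion \eqn{\phi} (0 gives
#'   Poisson counts).
#' @param base_mean_log_range Range of log10 base expression (FPKM scale).
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Integer pair `c(n_lnc, n_mrna)` per module.
#' @param module_lfc_range Range (log2) of the shared |effect| of module
#'   members; strong by default, emulating tightly co-regulated
#'   drought-marker genes.
#' @param module_latent_sd Sd (log2) of the shared latent profile.
#' @param sample_noise_sd Sd (log2) of independent per-feature replicate
#'   noise for non-module features.
#' @param noise_sd Sd (log2) of qPCR measurement noise.
#' @param library_size_range Range of intended library sizes (fragments).
#' @param cis_max_gap Maximum genomic gap (bp) between a module lncRNA
#'   and its planted partner mRNA.
#' @param n_go_terms,n_kegg_terms Number of random annotation terms per
#'   namespace (one extra KEGG term, the planted "pathway", holds all
#'   module mRNAs).
#' @param n_qpcr_probes Number of lncRNAs profiled by synthetic qPCR.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulate_config(n_mrna = 200, n_lncrna = 40, seed = 1)
simulate_config <- function(n_mrna = 5000, n_lncrna = 500,
                            n_chromosomes = 10, n_reps = 3,
                            frac_de = 0.15, lfc_range = c(1.5, 3),
                            dispersion = 0.01,
                            base_mean_log_range = c(1, 2.5),
                            n_modules = 3, module_size = c(5, 20),
                            module_lfc_range = c(4.5, 5.5),
                            module_latent_sd = 0.8,
                            sample_noise_sd = 0.25,
                            noise_sd = 0.25,
                            library_size_range = c(15e6, 25e6),
                            cis_max_gap = 5e4,
                            n_go_terms = 50, n_kegg_terms = 20,
                            n_qpcr_probes = 9,
                            seed = 1) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_chromosomes = as.integer(n_chromosomes),
              n_reps = as.integer(n_reps),
              frac_de = frac_de, lfc_range = as.numeric(lfc_range),
              dispersion = dispersion,
              base_mean_log_range = as.numeric(base_mean_log_range),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_lfc_range = as.numeric(module_lfc_range),
              module_latent_sd = module_latent_sd,
              sample_noise_sd = sample_noise_sd,
              noise_sd = noise_sd,
              library_size_range = as.numeric(library_size_range),
              cis_max_gap = cis_max_gap,
              n_go_terms = as.integer(n_go_terms),
              n_kegg_terms = as.integer(n_kegg_terms),
              n_qpcr_probes = as.integer(n_qpcr_probes),
              seed = as.integer(seed))
  counts <- c("n_mrna", "n_lncrna", "n_chromosomes", "n_reps")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("'", f, "' must be a single count >= 1")
  if (!(cfg$frac_de >= 0 && cfg$frac_de < 1))
    stop("'frac_de' must lie in [0, 1)")
  if (length(cfg$lfc_range) != 2L || cfg$lfc_range[1] < 1 ||
      diff(cfg$lfc_range) < 0)
    stop("'lfc_range' must be an increasing pair with minimum >= 1")
  if (cfg$dispersion < 0) stop("'dispersion' must be >= 0")
  if (length(cfg$module_size) != 2L || any(cfg$module_size < 1L))
    stop("'module_size' must be a pair of counts (n_lnc, n_mrna)")
  if (cfg$n_modules > 0 &&
      (cfg$n_modules * cfg$module_size[1] > cfg$n_lncrna ||
       cfg$n_modules * cfg$module_size[2] > cfg$n_mrna))
    stop("planted module sizes exceed the number of available features")
  if (cfg$module_latent_sd < 0 || cfg$sample_noise_sd < 0 || cfg$noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (any(cfg$library_size_range <= 0) || diff(cfg$library_size_range) < 0)
    stop("'library_size_range' must be a positive increasing pair")
  structure(cfg, class = "sim_config")
}

GENOTYPES  <- c("tolerant", "sensitive")
TREATMENTS <- c("DS", "RW")
TF_FAMILIES <- c("MYB", "bHLH", "WRKY", "NFY", "ERF", "NAC", "bZIP", "HSF")

#' Generate a complete synthetic drought/re-watering study
#'
#' Draws counts, sample design, genomic annotation, GO/KEGG term maps, a
#' transcription-factor table, a qPCR table and the ground-truth table
#' for one synthetic study under `config`. See [simulate_config()] for
#' the generative model. Module lncRNAs are relocated next to one of
#' their partner mRNAs (gap <= `cis_max_gap`) so cis co-location has
#' planted positives, and all module mRNAs are annotated to one planted
#' KEGG "pathway" term.
#'
#' @param config A `sim_config` from [simulate_config()].
#' @return A list of class `lnc_study` with elements `counts` (integer
#'   matrix, features x samples), `design`, `annotation`, `go_map`,
#'   `kegg_map`, `tf_table`, `qpcr`, `truth`, `pathway_term`, `config`.
#'   `design$library_size` equals `colSums(counts)`.
#' @export
#' @examples
#' study <- generate_study(simulate_config(n_mrna = 200, n_lncrna = 40,
#'                                         n_modules = 1, seed = 7))
#' dim(study$counts)
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n_feat <- cfg$n_mrna + cfg$n_lncrna
  feature_id <- c(sprintf("GENE%05d", seq_len(cfg$n_mrna)),
                  sprintf("LNC%04d", seq_len(cfg$n_lncrna)))
  biotype <- rep(c("mRNA", "lncRNA"), c(cfg$n_mrna, cfg$n_lncrna))
  length_bp <- ifelse(biotype == "mRNA",
                      sample(500:5000, n_feat, replace = TRUE),
                      sample(200:2000, n_feat, replace = TRUE))
  base_fpkm <- 10 ^ stats::runif(n_feat, cfg$base_mean_log_range[1],
                                 cfg$base_mean_log_range[2])
  strand <- sample(c("+", "-"), n_feat, replace = TRUE)

  ## --- planted modules -------------------------------------------------
  module_id <- rep(NA_integer_, n_feat)
  idx_lnc  <- which(biotype == "lncRNA")
  idx_mrna <- which(biotype == "mRNA")
  if (cfg$n_modules > 0) {
    pick_lnc  <- sample(idx_lnc,  cfg$n_modules * cfg$module_size[1])
    pick_mrna <- sample(idx_mrna, cfg$n_modules * cfg$module_size[2])
    module_id[pick_lnc]  <- rep(seq_len(cfg$n_modules), each = cfg$module_size[1])
    module_id[pick_mrna] <- rep(seq_len(cfg$n_modules), each = cfg$module_size[2])
  }
  # alternate module directions so both up- and down-modules exist
  module_dir <- if (cfg$n_modules > 0)
    rep_len(c(1, -1), cfg$n_modules) else integer(0)

  ## --- planted DE effects per genotype ---------------------------------
  lfc <- matrix(0, n_feat, 2, dimnames = list(feature_id, GENOTYPES))
  for (g in 1:2) {
    if (cfg$n_modules > 0) {
      beta_mod <- stats::runif(cfg$n_modules, cfg$module_lfc_range[1],
                               cfg$module_lfc_range[2]) * module_dir
      in_mod <- !is.na(module_id)
      lfc[in_mod, g] <- beta_mod[module_id[in_mod]]
    }
    free <- which(is.na(module_id))
    n_de <- round(cfg$frac_de * n_feat)
    n_de <- min(n_de, length(free))
    de_idx <- sample(free, n_de)
    lfc[de_idx, g] <- stats::runif(n_de, cfg$lfc_range[1], cfg$lfc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)
  }

  ## --- sample design ----------------------------------------------------
  design <- expand.grid(replicate = seq_len(cfg$n_reps),
                        treatment = TREATMENTS, genotype = GENOTYPES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "replicate")]
  design$sample_id <- sprintf("%s_%s_%d", design$treatment, design$genotype,
                              design$replicate)
  n_samp <- nrow(design)
  lib_intended <- round(stats::runif(n_samp, cfg$library_size_range[1],
                                     cfg$library_size_range[2]))

  ## --- per-sample log2 modulation --------------------------------------
  is_rw <- as.numeric(design$treatment == "RW")
  geno_col <- match(design$genotype, GENOTYPES)
  log2mod <- matrix(0, n_feat, n_samp)
  # independent replicate noise for non-module features
  if (cfg$sample_noise_sd > 0) {
    free <- which(is.na(module_id))
    log2mod[free, ] <- stats::rnorm(length(free) * n_samp, 0,
                                    cfg$sample_noise_sd)
  }
  # Shared latent per module x genotype. Modules are distinct co-expression
  # programmes, so their latent profiles are built mutually orthogonal
  # (randomly rotated Helmert contrasts within each treatment group) with
  # exact per-group spread module_latent_sd: the planted module strength,
  # and the separation between modules, are then properties of the config
  # rather than of the random draw. With r replicates, 2(r - 1) orthogonal
  # programmes exist per genotype; further modules start a fresh rotation.
  if (cfg$n_modules > 0 && cfg$module_latent_sd > 0 && cfg$n_reps >= 2) {
    for (g in 1:2) {
      js <- which(geno_col == g)
      pats <- module_latent_patterns(cfg$n_modules, cfg$n_reps,
                                     cfg$module_latent_sd)
      # pats columns are ordered DS block then RW block, matching the
      # design layout within one genotype
      for (m in seq_len(cfg$n_modules)) {
        members <- which(!is.na(module_id) & module_id == m)
        log2mod[members, js] <- rep(pats[, m], each = length(members))
      }
    }
  }
  # planted treatment effect
  for (j in seq_len(n_samp))
    log2mod[, j] <- log2mod[, j] + lfc[, geno_col[j]] * is_rw[j]

  ## --- counts -----------------------------------------------------------
  mu <- (base_fpkm * length_bp / 1e3) %o% (lib_intended / 1e6) * 2 ^ log2mod
  counts <- if (cfg$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
           n_feat, n_samp)
  } else {
    matrix(stats::rpois(length(mu), mu), n_feat, n_samp)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(feature_id, design$sample_id)
  design$library_size <- as.integer(colSums(counts))
  design <- design[, c("sample_id", "genotype", "treatment", "replicate",
                       "library_size")]

  ## --- genomic placement ------------------------------------------------
  chrom <- sprintf("chr%02d", sample.int(cfg$n_chromosomes, n_feat,
                                         replace = TRUE))
  start <- integer(n_feat)
  for (ch in unique(chrom)) {
    on_ch <- which(chrom == ch)
    gaps <- round(stats::runif(length(on_ch), 2e3, 2e4))
    start[on_ch] <- cumsum(gaps + c(0L, length_bp[on_ch][-length(on_ch)]))
  }
  end <- start + length_bp - 1L
  # relocate module lncRNAs next to one of their partner mRNAs
  if (cfg$n_modules > 0) {
    for (m in seq_len(cfg$n_modules)) {
      m_lnc  <- which(!is.na(module_id) & module_id == m & biotype == "lncRNA")
      m_mrna <- which(!is.na(module_id) & module_id == m & biotype == "mRNA")
      partners <- sample(m_mrna, length(m_lnc), replace = TRUE)
      gap <- round(stats::runif(length(m_lnc), 500, cfg$cis_max_gap))
      chrom[m_lnc] <- chrom[partners]
      start[m_lnc] <- end[partners] + gap
      end[m_lnc]   <- start[m_lnc] + length_bp[m_lnc] - 1L
    }
  }
  annotation <- data.frame(feature_id = feature_id, chrom = chrom,
                           start = as.integer(start), end = as.integer(end),
                           strand = strand, biotype = biotype,
                           length = as.integer(length_bp),
                           stringsAsFactors = FALSE)

  ## --- term maps --------------------------------------------------------
  random_terms <- function(prefix, n_terms, ids) {
    if (n_terms == 0L)
      return(data.frame(feature_id = character(), term_id = character()))
    out <- lapply(seq_len(n_terms), function(t) {
      size <- sample(10:80, 1)
      data.frame(feature_id = sample(ids, min(size, length(ids))),
                 term_id = sprintf("%s%05d", prefix, t),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  mrna_ids <- feature_id[idx_mrna]
  go_map <- random_terms("GO:", cfg$n_go_terms, mrna_ids)
  kegg_map <- random_terms("ko", cfg$n_kegg_terms, mrna_ids)
  pathway_term <- "ko90001"   # planted pathway: all module mRNAs + extras
  mod_mrna_ids <- feature_id[!is.na(module_id) & biotype == "mRNA"]
  extra <- sample(setdiff(mrna_ids, mod_mrna_ids),
                  min(40L, cfg$n_mrna - length(mod_mrna_ids)))
  kegg_map <- rbind(kegg_map,
                    data.frame(feature_id = c(mod_mrna_ids, extra),
                               term_id = pathway_term,
                               stringsAsFactors = FALSE))
  go_map <- go_map[stable_order(go_map$term_id, go_map$feature_id), ]
  kegg_map <- kegg_map[stable_order(kegg_map$term_id, kegg_map$feature_id), ]
  rownames(go_map) <- rownames(kegg_map) <- NULL

  ## --- TF table ---------------------------------------------------------
  n_tf <- max(1L, round(0.08 * cfg$n_mrna))
  tf_ids <- sort(sample(mrna_ids, n_tf))
  tf_table <- data.frame(feature_id = tf_ids,
                         family = sample(TF_FAMILIES, n_tf, replace = TRUE),
                         stringsAsFactors = FALSE)

  ## --- truth table ------------------------------------------------------
  truth <- do.call(rbind, lapply(1:2, function(g)
    data.frame(feature_id = feature_id, genotype = GENOTYPES[g],
               biotype = biotype, true_log2fc = lfc[, g],
               is_de = lfc[, g] != 0,
               module_id = ifelse(is.na(module_id), "",
                                  sprintf("module%02d", module_id)),
               stringsAsFactors = FALSE)))
  truth$tf_family <- tf_table$family[match(truth$feature_id,
                                           tf_table$feature_id)]
  truth$tf_family[is.na(truth$tf_family)] <- ""
  rownames(truth) <- NULL

  ## --- qPCR -------------------------------------------------------------
  de_both <- feature_id[biotype == "lncRNA" & lfc[, 1] != 0 & lfc[, 2] != 0]
  probes <- if (length(de_both) > 0)
    sort(sample(de_both, min(cfg$n_qpcr_probes, length(de_both))))
  else character(0)
  qpcr <- generate_qpcr(truth, probes, noise_sd = cfg$noise_sd,
                        seed = (cfg$seed + 77L) %% .Machine$integer.max,
                        n_reps = cfg$n_reps)

  structure(list(counts = counts, design = design, annotation = annotation,
                 go_map = go_map, kegg_map = kegg_map, tf_table = tf_table,
                 qpcr = qpcr, truth = truth, pathway_term = pathway_term,
                 config = cfg),
            class = "lnc_study")
}

# Mutually orthogonal per-sample latent profiles for planted modules.
# Returns a (2 * n_reps) x n_modules matrix; each column is centred within
# each treatment block with sample sd exactly `sd` per block, and columns
# within one block of 2 * (n_reps - 1) modules are pairwise orthogonal.
module_latent_patterns <- function(n_modules, n_reps, sd) {
  ndf <- n_reps - 1L
  basis <- function() {
    h <- stats::contr.helmert(n_reps)
    h <- sweep(h, 2, apply(h, 2, stats::sd), "/")   # columns: sample sd 1
    rot <- qr.Q(qr(matrix(stats::rnorm(ndf * ndf), ndf)))
    h %*% rot
  }
  per_block <- 2L * ndf
  out <- matrix(0, 2L * n_reps, n_modules)
  b_ds <- b_rw <- NULL
  for (m in seq_len(n_modules)) {
    pos <- (m - 1L) %% per_block
    if (pos == 0L) {               # fresh rotations for each module block
      b_ds <- basis()
      b_rw <- basis()
    }
    i <- pos %% ndf + 1L
    s <- if (pos < ndf) 1 else -1
    out[, m] <- c(b_ds[, i], s * b_rw[, i]) * sd
  }
  out
}

#' Generate a synthetic qPCR relative-expression table
#'
#' For each probe and genotype the qPCR-side log2 fold change is the true
#' planted effect plus `Normal(0, noise_sd)` measurement error. The table
#' is laid out as replicate-level relative expressions (DS replicates at
#' 1, RW replicates at `2^lfc`), the format a wet-lab relative-expression
#' sheet would take.
#'
#' @param truth Truth table from [generate_study()].
#' @param probe_ids Feature ids to profile; must appear in `truth`.
#' @param noise_sd Sd (log2) of qPCR noise; 0 reproduces the true effects
#'   exactly.
#' @param seed Integer seed.
#' @param n_reps Technical replicates per condition.
#' @return Data frame with columns `probe_id`, `genotype`, `treatment`,
#'   `replicate`, `relative_expression`.
#' @export
generate_qpcr <- function(truth, probe_ids, noise_sd, seed, n_reps = 3) {
  missing_ids <- setdiff(probe_ids, truth$feature_id)
  if (length(missing_ids) > 0)
    stop("unknown probe id(s): ", paste(missing_ids, collapse = ", "))
  if (length(probe_ids) == 0)
    return(data.frame(probe_id = character(), genotype = character(),
                      treatment = character(), replicate = integer(),
                      relative_expression = numeric()))
  with_seed(seed, {
    rows <- lapply(GENOTYPES, function(g) {
      tr <- truth[truth$genotype == g, ]
      true_lfc <- tr$true_log2fc[match(probe_ids, tr$feature_id)]
      lfc <- true_lfc + stats::rnorm(length(probe_ids), 0, noise_sd)
      do.call(rbind, lapply(seq_along(probe_ids), function(i)
        data.frame(probe_id = probe_ids[i], genotype = g,
                   treatment = rep(TREATMENTS, each = n_reps),
                   replicate = rep(seq_len(n_reps), 2),
                   relative_expression = rep(c(1, 2 ^ lfc[i]), each = n_reps),
                   stringsAsFactors = FALSE)))
    })
    do.call(rbind, rows)
  })
}

#' Write a synthetic study to disk as plain-text files
#'
#' Writes `counts.tsv`, `design.tsv`, `annotation.gff3`, `go_map.tsv`,
#' `kegg_map.tsv`, `tf_table.tsv`, `qpcr.tsv` and `truth.tsv` (all UTF-8,
#' tab-delimited with a header; GFF3 per its own spec).
#'
#' @param study An `lnc_study` from [generate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "lnc_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- data.frame(feature_id = rownames(study$counts),
                          study$counts, check.names = FALSE)
  write_tsv(counts_df, file.path(dir, "counts.tsv"))
  write_tsv(study$design, file.path(dir, "design.tsv"))
  write_gff3(study$annotation, file.path(dir, "annotation.gff3"))
  write_tsv(study$go_map, file.path(dir, "go_map.tsv"))
  write_tsv(study$kegg_map, file.path(dir, "kegg_map.tsv"))
  write_tsv(study$tf_table, file.path(dir, "tf_table.tsv"))
  write_tsv(study$qpcr, file.path(dir, "qpcr.tsv"))
  write_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @return An `lnc_study` list (without `config`; `pathway_term` absent).
#' @export
read_study <- function(dir) {
  counts_df <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$feature_id
  storage.mode(counts) <- "integer"
  ann <- read_gff3(file.path(dir, "annotation.gff3"))
  structure(list(counts = counts,
                 design = read_tsv(file.path(dir, "design.tsv")),
                 annotation = ann,
                 go_map = read_tsv(file.path(dir, "go_map.tsv")),
                 kegg_map = read_tsv(file.path(dir, "kegg_map.tsv")),
                 tf_table = read_tsv(file.path(dir, "tf_table.tsv")),
                 qpcr = read_tsv(file.path(dir, "qpcr.tsv")),
                 truth = read_tsv(file.path(dir, "truth.tsv"))),
            class = "lnc_study")
}

#' @export
print.lnc_study <- function(x, ...) {
  cat("Synthetic lncRNA/mRNA study\n")
  cat(sprintf("  features: %d (%d mRNA, %d lncRNA)\n", nrow(x$counts),
              sum(x$annotation$biotype == "mRNA"),
              sum(x$annotation$biotype == "lncRNA")))
  cat(sprintf("  samples:  %d (%s x %s, %d replicates)\n", ncol(x$counts),
              paste(unique(x$design$genotype), collapse = "/"),
              paste(unique(x$design$treatment), collapse = "/"),
              max(x$design$replicate)))
  invisible(x)
}
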