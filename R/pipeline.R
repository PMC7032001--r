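#' Assemble a pipeline configuration
#'
#' Exactly one of `sim` (a [simulate_config()] object — the study is
#' generated in memory) or `input_dir` (a directory of files as written
#' by [write_study()]) must be supplied. Threshold defaults are the
#' analysis' standard operating point: `q <= 0.05` with
#' `|log2 ratio| >= 1` for DE calls, `|PCC| >= 0.95` with raw `p < 0.05`
#' for network edges, corrected `p < 0.05` for enrichment.
#'
#' @param sim Optional `sim_config`.
#' @param input_dir Optional directory of study input files.
#' @param out_dir Optional output directory; when `NULL` nothing is
#'   written and the report is only returned.
#' @param q_max,lfc_min,epsilon DE thresholds (see [call_de()]).
#' @param r_min,p_max Network thresholds (see [build_network()]).
#' @param window Cis co-location window in bp.
#' @param enrichment_method `"hypergeometric"` or `"wallenius"`.
#' @param n_bins Length-weight bins for the Wallenius method.
#' @param alpha_enrich Corrected-p cutoff counted as significant.
#' @param seed Optional integer overriding the simulation seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, out_dir = NULL,
                            q_max = 0.05, lfc_min = 1, epsilon = 0.1,
                            r_min = 0.95, p_max = 0.05, window = 1e5,
                            enrichment_method = c("hypergeometric",
                                                  "wallenius"),
                            n_bins = 20, alpha_enrich = 0.05, seed = NULL) {
  if (is.null(sim) == is.null(input_dir))
    stop("supply exactly one of 'sim' or 'input_dir'")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  stopifnot(q_max > 0, q_max <= 1, lfc_min >= 0, epsilon >= 0,
            r_min >= 0, r_min <= 1, p_max > 0, p_max <= 1, window >= 0)
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 q_max = q_max, lfc_min = lfc_min, epsilon = epsilon,
                 r_min = r_min, p_max = p_max, window = window,
                 enrichment_method = match.arg(enrichment_method),
                 n_bins = n_bins, alpha_enrich = alpha_enrich,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a study bundle against the pipeline's input contract
#'
#' Checks id cross-references between counts, design, annotation, term
#' maps, TF and qPCR tables, plus duplicates and dtype violations.
#' Violations are returned, not raised; an empty frame means the bundle
#' is valid.
#'
#' @param study An `lnc_study` (from [generate_study()] or
#'   [read_study()]).
#' @return Data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when fully consistent.
#' @export
validate_inputs <- function(study) {
  probs <- list()
  add <- function(level, msg)
    probs[[length(probs) + 1L]] <<- data.frame(level = level, message = msg,
                                               stringsAsFactors = FALSE)
  cn <- colnames(study$counts)
  if (anyDuplicated(rownames(study$counts)))
    add("error", "duplicate feature ids in counts")
  if (anyDuplicated(cn)) add("error", "duplicate sample ids in counts")
  if (anyDuplicated(study$design$sample_id))
    add("error", "duplicate sample ids in design")
  miss <- setdiff(cn, study$design$sample_id)
  if (length(miss) > 0)
    add("error", paste("samples in counts absent from design:",
                       paste(miss, collapse = ", ")))
  extra <- setdiff(study$design$sample_id, cn)
  if (length(extra) > 0)
    add("error", paste("design samples absent from counts:",
                       paste(extra, collapse = ", ")))
  if (any(study$counts < 0) || any(study$counts != round(study$counts)))
    add("error", "counts must be non-negative integers")
  cells <- table(study$design$genotype, study$design$treatment)
  if (any(cells < 2))
    add("error", "every (genotype, treatment) cell needs >= 2 replicates")
  if (!is.null(study$design$library_size) &&
      any(study$design$library_size <= 0))
    add("error", "library sizes must be positive")
  ann_missing <- setdiff(study$annotation$feature_id, rownames(study$counts))
  if (length(ann_missing) > 0)
    add("warning", paste("annotated features absent from counts:",
                         paste(utils::head(ann_missing, 5), collapse = ", ")))
  cnt_missing <- setdiff(rownames(study$counts), study$annotation$feature_id)
  if (length(cnt_missing) > 0)
    add("error", paste("counted features lack annotation:",
                       paste(utils::head(cnt_missing, 5), collapse = ", ")))
  for (nm in c("go_map", "kegg_map")) {
    tm <- study[[nm]]
    unknown <- setdiff(tm$feature_id, study$annotation$feature_id)
    if (length(unknown) > 0)
      add("warning", paste(nm, "references unknown features:",
                           paste(utils::head(unknown, 5), collapse = ", ")))
  }
  unknown_tf <- setdiff(study$tf_table$feature_id,
                        study$annotation$feature_id)
  if (length(unknown_tf) > 0)
    add("warning", "tf_table references unknown features")
  if (nrow(study$qpcr) > 0) {
    if (any(study$qpcr$relative_expression <= 0))
      add("error", "qPCR relative expressions must be positive")
    if (!all(study$qpcr$treatment %in% c("DS", "RW")))
      add("error", "qPCR treatments must be DS or RW")
  }
  if (length(probs) == 0)
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, probs)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one study: FPKM, per-genotype DE calls,
#' co-expression networks with topology summaries and pathway
#' subnetwork, genotype comparison, cis co-location, GO/KEGG enrichment
#' of the co-expressed targets, TF classification, and RNA-seq/qPCR
#' concordance. When `cfg$out_dir` is set, per-stage tables and a
#' `report.json` are written there; the same seed always produces
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The report, a nested list of all headline counts and
#'   statistics, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  study <- if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    if (!is.null(cfg$seed)) sim$seed <- cfg$seed
    generate_study(sim)
  } else {
    read_study(cfg$input_dir)
  }
  issues <- validate_inputs(study)
  if (any(issues$level == "error"))
    stop("input validation failed:\n  ",
         paste(issues$message[issues$level == "error"], collapse = "\n  "))

  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) if (!is.null(out)) write_tsv(x, file.path(out, name))

  ann <- study$annotation
  lengths <- stats::setNames(ann$length, ann$feature_id)
  lib <- stats::setNames(study$design$library_size, study$design$sample_id)
  fpkm <- compute_fpkm(study$counts, lengths,
                       library_sizes = lib[colnames(study$counts)])
  is_lnc <- stats::setNames(ann$biotype == "lncRNA", ann$feature_id)
  genotypes <- unique(study$design$genotype)
  stopifnot(length(genotypes) == 2)

  de <- list(); nets <- list(); geno_report <- list()
  for (g in genotypes) {
    deg_all <- call_de(study$counts, study$design, g, lengths,
                       q_max = cfg$q_max, lfc_min = cfg$lfc_min,
                       epsilon = cfg$epsilon)
    emit(deg_all, sprintf("de_%s.tsv", g))
    de_lnc  <- deg_all[is_lnc[deg_all$feature_id], ]
    de_mrna <- deg_all[!is_lnc[deg_all$feature_id], ]
    de[[g]] <- list(all = deg_all, lnc = de_lnc, mrna = de_mrna)

    net <- build_network(de_lnc, de_mrna, fpkm, study$design, g,
                         r_min = cfg$r_min, p_max = cfg$p_max)
    nets[[g]] <- net
    emit(net$edges, sprintf("edges_%s.tsv", g))
    if (!is.null(out)) {
      export_network(net, "sif", file.path(out, sprintf("network_%s.sif", g)))
      export_network(net, "graphml",
                     file.path(out, sprintf("network_%s.graphml", g)))
    }

    # enrichment universe: mRNAs expressed in >= 1 sample of the genotype
    g_samples <- study$design$sample_id[study$design$genotype == g]
    expressed <- rownames(fpkm)[rowSums(fpkm[, g_samples, drop = FALSE]) > 0]
    population <- intersect(expressed, ann$feature_id[ann$biotype == "mRNA"])
    targets <- intersect(net$mrna, population)
    enr <- lapply(list(GO = study$go_map, KEGG = study$kegg_map),
                  function(tm) {
      if (length(targets) == 0 || nrow(tm) == 0) return(NULL)
      enrich_terms(targets, population, tm,
                   method = cfg$enrichment_method,
                   lengths = lengths, n_bins = cfg$n_bins)
    })
    if (!is.null(enr$GO)) emit(enr$GO, sprintf("enrichment_go_%s.tsv", g))
    if (!is.null(enr$KEGG)) emit(enr$KEGG, sprintf("enrichment_kegg_%s.tsv", g))

    # pathway subnetwork: most enriched KEGG term touching the network
    sub_rep <- list(term_id = NA_character_, n_pairs = 0L,
                    n_lncrna = 0L, n_mrna = 0L)
    if (!is.null(enr$KEGG) && nrow(enr$KEGG) > 0) {
      hit <- enr$KEGG$term_id[enr$KEGG$k > 0]
      if (length(hit) > 0) {
        term <- hit[1]                      # rows are sorted by p
        sub <- subnetwork_by_term(net, study$kegg_map, term)
        sub_rep <- list(term_id = term, n_pairs = nrow(sub$edges),
                        n_lncrna = length(sub$lncrna),
                        n_mrna = length(sub$mrna))
      }
    }

    tfp <- tf_lncrna_pairs(net, study$tf_table)
    summ <- degree_summary(net)
    count_calls <- function(d) list(up = sum(d$call == "up"),
                                    down = sum(d$call == "down"),
                                    total_de = sum(d$call != "not_de"))
    geno_report[[g]] <- list(
      de = list(mrna = count_calls(de_mrna), lncrna = count_calls(de_lnc),
                tested = sum(!deg_all$degenerate)),
      network = summ,
      pathway_subnetwork = sub_rep,
      enrichment = list(
        go_significant = if (is.null(enr$GO)) 0L else
          sum(enr$GO$p_corrected < cfg$alpha_enrich),
        kegg_significant = if (is.null(enr$KEGG)) 0L else
          sum(enr$KEGG$p_corrected < cfg$alpha_enrich),
        top_go = if (is.null(enr$GO) || nrow(enr$GO) == 0) NA_character_
                 else enr$GO$term_id[1],
        top_kegg = if (is.null(enr$KEGG) || nrow(enr$KEGG) == 0)
                   NA_character_ else enr$KEGG$term_id[1]),
      tf_pairs = list(n_edges = nrow(tfp$edges), n_tf = tfp$n_tf,
                      n_family = tfp$n_family, n_lncrna = tfp$n_lncrna))
  }

  gA <- genotypes[1]; gB <- genotypes[2]
  cmp_lnc  <- compare_genotypes(de[[gA]]$lnc,  de[[gB]]$lnc)
  cmp_mrna <- compare_genotypes(de[[gA]]$mrna, de[[gB]]$mrna)
  tf_cls <- classify_tf_expression(de[[gA]]$mrna, de[[gB]]$mrna,
                                   study$tf_table)
  emit(tf_cls$records, "tf_classes.tsv")

  # cis co-location for lncRNAs DE in either genotype
  de_lnc_ids <- sort(union(de[[gA]]$lnc$feature_id[de[[gA]]$lnc$call != "not_de"],
                           de[[gB]]$lnc$feature_id[de[[gB]]$lnc$call != "not_de"]))
  cis <- cis_pairs(ann[ann$biotype == "mRNA" |
                         ann$feature_id %in% de_lnc_ids, ],
                   window = cfg$window)
  emit(cis, "cis_pairs.tsv")

  # qPCR concordance, pooling genotypes as in a validation scatter
  qp_rep <- list(n_points = 0L, slope = NA_real_, intercept = NA_real_,
                 r2 = NA_real_)
  if (nrow(study$qpcr) > 0) {
    qlfc <- qpcr_log2fc(study$qpcr)
    rna <- mapply(function(id, g)
      de[[g]]$all$log2_ratio[match(id, de[[g]]$all$feature_id)],
      qlfc$probe_id, qlfc$genotype)
    qp_rep <- concordance(rna, qlfc$log2fc)
  }

  report <- list(
    parameters = cfg[c("q_max", "lfc_min", "epsilon", "r_min", "p_max",
                       "window", "enrichment_method", "alpha_enrich")],
    n_features = nrow(study$counts),
    n_samples = ncol(study$counts),
    genotypes = geno_report,
    comparison = list(lncrna = as.list(cmp_lnc$counts),
                      mrna = as.list(cmp_mrna$counts)),
    tf_classes = as.list(tf_cls$class_counts),
    cis = list(n_pairs = nrow(cis),
               n_lncrna_with_partner = length(unique(cis$lncrna_id))),
    qpcr = qp_rep)
  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    return(invisible(report))
  }
  report
}
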