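#' Two-sided p-value for a Pearson correlation
#'
#' Student-t test on `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom; `|r| = 1` gives `p = 0`.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s).
#' @export
#' @examples
#' correlation_pvalue(0.95, 6)
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("correlation test requires n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  dm <- dim(r)
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  dim(p) <- dm
  p
}

#' Build the bipartite lncRNA-mRNA co-expression network for one genotype
#'
#' Scores every (DE lncRNA, DE mRNA) pair by the Pearson correlation of
#' their per-replicate FPKM profiles across the genotype's samples (DS
#' and RW replicates pooled) and keeps pairs with `|r| >= r_min` and
#' `p < p_max`. Nodes are the differentially expressed features incident
#' to at least one retained edge, so the result is bipartite by
#' construction. Constant (zero-variance) profiles are excluded from
#' pairing with a warning.
#'
#' @param de_lnc,de_mrna DE tables from [call_de()] restricted to
#'   lncRNAs / mRNAs (rows with `call != "not_de"` are used).
#' @param fpkm FPKM matrix covering all DE features.
#' @param design Sample design.
#' @param genotype Genotype whose samples are correlated.
#' @param r_min Minimum |Pearson r| for an edge (default 0.95).
#' @param p_max Maximum raw correlation p-value (default 0.05; edge
#'   p-values are deliberately not multiplicity-corrected).
#' @return Object of class `coexp_network`: list with `edges` (data frame
#'   `lncrna_id`, `mrna_id`, `r`, `p`, `trend`), `lncrna`, `mrna` (node
#'   id vectors), `genotype`, `n_samples`.
#' @export
build_network <- function(de_lnc, de_mrna, fpkm, design, genotype,
                          r_min = 0.95, p_max = 0.05) {
  check_design(design, colnames(fpkm))
  samples <- design$sample_id[design$genotype == genotype]
  if (length(samples) < 3)
    stop("need >= 3 samples in genotype ", genotype, " for correlation")
  lnc_ids  <- de_lnc$feature_id[de_lnc$call != "not_de"]
  mrna_ids <- de_mrna$feature_id[de_mrna$call != "not_de"]
  empty <- function() new_network(empty_edges(), genotype, length(samples))
  if (length(lnc_ids) == 0 || length(mrna_ids) == 0) return(empty())
  missing_ids <- setdiff(c(lnc_ids, mrna_ids), rownames(fpkm))
  if (length(missing_ids) > 0)
    stop("DE features missing from the expression matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))

  X <- t(fpkm[lnc_ids, samples, drop = FALSE])
  Y <- t(fpkm[mrna_ids, samples, drop = FALSE])
  const_x <- apply(X, 2, function(v) stats::var(v) == 0)
  const_y <- apply(Y, 2, function(v) stats::var(v) == 0)
  if (any(const_x) || any(const_y))
    warning(sum(const_x) + sum(const_y),
            " constant expression profile(s) excluded from pairing")
  X <- X[, !const_x, drop = FALSE]
  Y <- Y[, !const_y, drop = FALSE]
  if (ncol(X) == 0 || ncol(Y) == 0) return(empty())

  R <- stats::cor(X, Y)
  P <- correlation_pvalue(R, n = length(samples))
  keep <- which(abs(R) >= r_min & P < p_max, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty())
  edges <- data.frame(lncrna_id = colnames(X)[keep[, 1]],
                      mrna_id = colnames(Y)[keep[, 2]],
                      r = R[keep], p = P[keep], stringsAsFactors = FALSE)
  edges$trend <- classify_trend(
    de_lnc$call[match(edges$lncrna_id, de_lnc$feature_id)],
    de_mrna$call[match(edges$mrna_id, de_mrna$feature_id)])
  edges <- edges[stable_order(edges$lncrna_id, edges$mrna_id), ]
  rownames(edges) <- NULL
  new_network(edges, genotype, length(samples))
}

empty_edges <- function() {
  data.frame(lncrna_id = character(), mrna_id = character(),
             r = numeric(), p = numeric(), trend = character(),
             stringsAsFactors = FALSE)
}

new_network <- function(edges, genotype, n_samples) {
  structure(list(edges = edges,
                 lncrna = sort(unique(edges$lncrna_id)),
                 mrna = sort(unique(edges$mrna_id)),
                 genotype = genotype, n_samples = n_samples),
            class = "coexp_network")
}

#' @export
print.coexp_network <- function(x, ...) {
  cat(sprintf("lncRNA-mRNA co-expression network (%s): %d lncRNAs, %d mRNAs, %d edges\n",
              x$genotype, length(x$lncrna), length(x$mrna), nrow(x$edges)))
  invisible(x)
}

#' Expression-trend class of a co-expression pair
#'
#' `same` when both endpoints are called in the same direction (both up
#' or both down after re-watering), `opposite` otherwise. Endpoints must
#' carry an `up` or `down` call.
#'
#' @param call_lnc,call_mrna DE calls of the two endpoints (vectorized).
#' @return Character vector of `"same"` / `"opposite"`.
#' @export
classify_trend <- function(call_lnc, call_mrna) {
  ok <- call_lnc %in% c("up", "down") & call_mrna %in% c("up", "down")
  if (!all(ok))
    stop("trend is defined only for endpoints called up or down")
  ifelse(call_lnc == call_mrna, "same", "opposite")
}

#' Topology summary of a co-expression network
#'
#' Node and edge counts, per-side degree ranges, trend counts, and the
#' hub (maximum-degree node over both sides, ties broken
#' lexicographically).
#'
#' @param net A `coexp_network`.
#' @return List with `n_lncrna`, `n_mrna`, `n_nodes`, `n_edges`,
#'   `lncrna_degree_min/max`, `mrna_degree_min/max`, `n_same_trend`,
#'   `n_opposite_trend`, `hub` (`NA` for an empty network) and
#'   `hub_degree`.
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  e <- net$edges
  if (nrow(e) == 0)
    return(list(n_lncrna = 0L, n_mrna = 0L, n_nodes = 0L, n_edges = 0L,
                lncrna_degree_min = 0L, lncrna_degree_max = 0L,
                mrna_degree_min = 0L, mrna_degree_max = 0L,
                n_same_trend = 0L, n_opposite_trend = 0L,
                hub = NA_character_, hub_degree = 0L))
  dl <- table(e$lncrna_id)
  dm <- table(e$mrna_id)
  deg <- c(dl, dm)
  hub <- sort(names(deg)[deg == max(deg)])[1]
  list(n_lncrna = length(dl), n_mrna = length(dm),
       n_nodes = length(dl) + length(dm), n_edges = nrow(e),
       lncrna_degree_min = as.integer(min(dl)),
       lncrna_degree_max = as.integer(max(dl)),
       mrna_degree_min = as.integer(min(dm)),
       mrna_degree_max = as.integer(max(dm)),
       n_same_trend = sum(e$trend == "same"),
       n_opposite_trend = sum(e$trend == "opposite"),
       hub = hub, hub_degree = as.integer(max(deg)))
}

#' Extract the subnetwork annotated to one functional term
#'
#' Keeps the edges whose mRNA endpoint is annotated to `term_id`;
#' lncRNA nodes are retained only while incident to a kept edge.
#'
#' @param net A `coexp_network`.
#' @param term_map Data frame with columns `feature_id`, `term_id`.
#' @param term_id Term to extract; must exist in `term_map`.
#' @return A `coexp_network` restricted to the term.
#' @export
subnetwork_by_term <- function(net, term_map, term_id) {
  stopifnot(inherits(net, "coexp_network"))
  if (!term_id %in% term_map$term_id)
    stop("unknown term: ", term_id)
  members <- term_map$feature_id[term_map$term_id == term_id]
  edges <- net$edges[net$edges$mrna_id %in% members, , drop = FALSE]
  rownames(edges) <- NULL
  new_network(edges, net$genotype, net$n_samples)
}

#' Export a network as SIF or GraphML text
#'
#' SIF lines have the form `"<lncrna> coexp <mrna>"`. GraphML carries a
#' `type` node attribute (`lncRNA`/`mRNA`) and `r`, `p`, `trend` edge
#' attributes, and is well-formed XML readable by standard graph tools.
#'
#' @param net A `coexp_network`.
#' @param format `"sif"` or `"graphml"`.
#' @param path Optional file to write to.
#' @return Character vector of output lines, invisibly when `path` is
#'   given.
#' @export
export_network <- function(net, format = c("sif", "graphml"), path = NULL) {
  stopifnot(inherits(net, "coexp_network"))
  format <- match.arg(format)
  lines <- if (format == "sif") {
    sprintf("%s\tcoexp\t%s", net$edges$lncrna_id, net$edges$mrna_id)
  } else {
    graphml_lines(net)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# vectorized GraphML serializer; xml2 parses/validates it in the tests
graphml_lines <- function(net) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  e <- net$edges
  node_lines <- function(ids, type)
    sprintf('    <node id="%s"><data key="type">%s</data></node>',
            esc(ids), type)
  edge_lines <- if (nrow(e) == 0) character(0) else
    sprintf(paste0('    <edge source="%s" target="%s">',
                   '<data key="r">%s</data><data key="p">%s</data>',
                   '<data key="trend">%s</data></edge>'),
            esc(e$lncrna_id), esc(e$mrna_id),
            format(e$r, digits = 15, trim = TRUE),
            format(e$p, digits = 15, trim = TRUE), esc(e$trend))
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="r" for="edge" attr.name="r" attr.type="double"/>',
    '  <key id="p" for="edge" attr.name="p" attr.type="double"/>',
    '  <key id="trend" for="edge" attr.name="trend" attr.type="string"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">',
            esc(net$genotype %||% "G")),
    node_lines(net$lncrna, "lncRNA"),
    node_lines(net$mrna, "mRNA"),
    edge_lines,
    '  </graph>',
    '</graphml>')
}
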