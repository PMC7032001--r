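#' Read mRNA/lncRNA loci from a GFF3 file
#'
#' Parses the file with `rtracklayer::import` and keeps one locus per
#' record of type `mRNA` or `lncRNA` (GFF3 column 3); all other feature
#' types are ignored. Coordinates stay 1-based inclusive, the GFF3
#' convention.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `length`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("mRNA", "lncRNA"), , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(feature_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), biotype = character(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- data.frame(feature_id = as.character(df$ID),
                    chrom = as.character(df$seqnames),
                    start = as.integer(df$start), end = as.integer(df$end),
                    strand = as.character(df$strand),
                    biotype = as.character(df$type),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "."
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

#' Write an annotation table as GFF3
#'
#' One line per feature, type `mRNA`/`lncRNA` in column 3 and `ID=` in
#' the attribute column; round-trips through [read_gff3()].
#'
#' @param annotation Data frame as returned by [read_gff3()] or found in
#'   an `lnc_study`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(all(c("feature_id", "chrom", "start", "end", "strand",
                  "biotype") %in% names(annotation)))
  if (any(annotation$start > annotation$end))
    stop("invalid locus: start > end")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tlncoexp\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$chrom, annotation$biotype,
                     annotation$start, annotation$end,
                     annotation$strand, annotation$feature_id), con)
  invisible(path)
}

#' Genes cis co-located with a lncRNA
#'
#' Returns the protein-coding loci on the same chromosome whose interval
#' gap to the lncRNA is at most `window` bp. Overlapping intervals have
#' distance 0; for disjoint intervals the distance is the difference
#' between the nearer start and the farther end (so `[4000,4500]` vs
#' `[5000,6000]` is 500 bp apart). The search is strand-agnostic.
#'
#' @param lnc_id Feature id of the lncRNA.
#' @param annotation Locus table (see [read_gff3()]).
#' @param window Maximum gap in bp (default 100 kb).
#' @return Data frame `gene_id`, `distance`, sorted by distance then id.
#' @export
co_located <- function(lnc_id, annotation, window = 1e5) {
  stopifnot(window >= 0)
  i <- match(lnc_id, annotation$feature_id)
  if (is.na(i)) stop("unknown feature: ", lnc_id)
  genes <- annotation[annotation$biotype == "mRNA" &
                        annotation$chrom == annotation$chrom[i], ,
                      drop = FALSE]
  d <- interval_gap(annotation$start[i], annotation$end[i],
                    genes$start, genes$end)
  keep <- d <= window
  out <- data.frame(gene_id = genes$feature_id[keep],
                    distance = d[keep], stringsAsFactors = FALSE)
  out <- out[stable_order(out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# gap between [s1,e1] and vectors [s2,e2]; 0 when the intervals overlap
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' All cis lncRNA-gene pairs within a window
#'
#' Applies [co_located()] to every lncRNA in the annotation.
#'
#' @inheritParams co_located
#' @return Data frame `lncrna_id`, `gene_id`, `distance_bp`.
#' @export
cis_pairs <- function(annotation, window = 1e5) {
  lncs <- annotation$feature_id[annotation$biotype == "lncRNA"]
  out <- lapply(lncs, function(id) {
    hits <- co_located(id, annotation, window)
    if (nrow(hits) == 0) return(NULL)
    data.frame(lncrna_id = id, gene_id = hits$gene_id,
               distance_bp = hits$distance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lncrna_id = character(), gene_id = character(),
                      distance_bp = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
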