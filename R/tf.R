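#' Classify transcription-factor expression across two genotypes
#'
#' Every TF that is differentially expressed in at least one genotype is
#' assigned exactly one class: `A_specific` / `B_specific` (DE in one
#' genotype only), `shared_same` (DE in both, same direction) or
#' `converse` (DE in both, opposite directions). TFs DE in neither
#' genotype are excluded. The classes partition the DE-TF universe.
#'
#' @param de_a,de_b DE tables from [call_de()] for the two genotypes.
#' @param tf_table Data frame with columns `feature_id`, `family`.
#' @return List with `records` (data frame `feature_id`, `family`,
#'   `class`), `class_counts` (named integer vector) and
#'   `family_counts` (table of family x class).
#' @export
classify_tf_expression <- function(de_a, de_b, tf_table) {
  stopifnot(all(c("feature_id", "family") %in% names(tf_table)))
  call_of <- function(de) {
    de <- de[de$call != "not_de", ]
    stats::setNames(de$call, de$feature_id)
  }
  ca <- call_of(de_a); cb <- call_of(de_b)
  tfs <- tf_table$feature_id
  in_a <- tfs %in% names(ca); in_b <- tfs %in% names(cb)
  keep <- in_a | in_b
  cls <- character(sum(keep))
  t_in_a <- in_a[keep]; t_in_b <- in_b[keep]; t_id <- tfs[keep]
  cls[t_in_a & !t_in_b] <- "A_specific"
  cls[!t_in_a & t_in_b] <- "B_specific"
  both <- t_in_a & t_in_b
  cls[both] <- ifelse(ca[t_id[both]] == cb[t_id[both]],
                      "shared_same", "converse")
  records <- data.frame(feature_id = t_id,
                        family = tf_table$family[keep],
                        class = cls, stringsAsFactors = FALSE)
  records <- records[stable_order(records$class, records$family,
                                  records$feature_id), ]
  rownames(records) <- NULL
  lv <- c("A_specific", "B_specific", "shared_same", "converse")
  class_counts <- table(factor(records$class, levels = lv))
  list(records = records,
       class_counts = stats::setNames(as.integer(class_counts), lv),
       family_counts = table(records$family,
                             factor(records$class, levels = lv)))
}

#' Co-expression edges whose mRNA endpoint is a transcription factor
#'
#' Restricts a network's edge set to TF mRNAs and reports the distinct
#' TF, family and lncRNA counts involved.
#'
#' @param net A `coexp_network`.
#' @param tf_table Data frame with columns `feature_id`, `family`.
#' @return List with `edges` (edge data frame plus a `family` column),
#'   `n_tf`, `n_family`, `n_lncrna`.
#' @export
tf_lncrna_pairs <- function(net, tf_table) {
  stopifnot(inherits(net, "coexp_network"))
  e <- net$edges[net$edges$mrna_id %in% tf_table$feature_id, , drop = FALSE]
  e$family <- tf_table$family[match(e$mrna_id, tf_table$feature_id)]
  rownames(e) <- NULL
  list(edges = e,
       n_tf = length(unique(e$mrna_id)),
       n_family = length(unique(e$family)),
       n_lncrna = length(unique(e$lncrna_id)))
}
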