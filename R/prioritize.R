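#' Call bona fide lignin-pathway candidate genes
#'
#' A gene is called bona fide when it is significantly higher in all three
#' lignin-contrast comparisons (stem vs leaf, root vs leaf, inner vs outer
#' stem tissue): every log2 ratio at least `min_lfc` and every Mann-Whitney
#' p-value below `alpha`. Co-clustering with the other bona fide genes and
#' MBSIIG promoter presence are reported as corroborating evidence but never
#' gate the call; a hypolignified-tissue expression pattern (high stem/leaf
#' but flat IT/OT) is thereby excluded.
#'
#' @param diffcalls `calls` data.frame from [condition_ratios()]; must
#'   contain the three comparisons.
#' @param clusters Named integer vector of cluster labels per gene (e.g.
#'   `labels` from [kmedians_cluster()]), or NULL.
#' @param motif_table `presence` data.frame from [motif_presence_table()],
#'   or NULL.
#' @param comparisons Character vector of the three required
#'   `condition_vs_control` keys.
#' @param min_lfc Minimum log2 fold change gate (default 1, i.e. 2-fold).
#' @param alpha Significance gate (default 0.01).
#' @return data.frame of `CandidateCall`s: per gene the three log2 ratios
#'   and p-values, `bona_fide`, `cluster`, `in_modal_cluster`,
#'   `mbsiig_present`, `evidence`.
#' @export
call_candidates <- function(diffcalls, clusters = NULL, motif_table = NULL,
                            comparisons = c("stem_vs_leaf", "root_vs_leaf",
                                            "IT_vs_OT"),
                            min_lfc = 1.0, alpha = 0.01) {
  key <- paste(diffcalls$condition, diffcalls$control, sep = "_vs_")
  missing_cmp <- setdiff(comparisons, unique(key))
  if (length(missing_cmp) > 0) {
    stop("comparison '", missing_cmp[1], "' missing from differential calls")
  }
  dc <- diffcalls[key %in% comparisons, , drop = FALSE]
  dc$cmp <- paste(dc$condition, dc$control, sep = "_vs_")
  genes <- unique(dc$assay)
  rows <- lapply(genes, function(g) {
    d <- dc[dc$assay == g, , drop = FALSE]
    lfc <- setNames(d$log2_ratio[match(comparisons, d$cmp)], comparisons)
    pv <- setNames(d$p_value[match(comparisons, d$cmp)], comparisons)
    testable <- all(!is.na(lfc)) && all(!is.na(pv))
    bona <- testable && all(lfc >= min_lfc) && all(pv < alpha)
    out <- data.frame(gene_id = g, t(lfc), t(setNames(pv, paste0("p_", comparisons))),
                      bona_fide = bona, stringsAsFactors = FALSE)
    names(out)[2:4] <- paste0("log2fc_", comparisons)
    out
  })
  calls <- do.call(rbind, rows)
  calls$cluster <- if (!is.null(clusters)) {
    unname(clusters[calls$gene_id])
  } else NA_integer_
  bf_clusters <- calls$cluster[calls$bona_fide & !is.na(calls$cluster)]
  modal <- if (length(bf_clusters) > 0) {
    as.integer(names(sort(table(bf_clusters), decreasing = TRUE))[1])
  } else NA_integer_
  calls$in_modal_cluster <- !is.na(calls$cluster) & !is.na(modal) &
    calls$cluster == modal
  calls$mbsiig_present <- if (!is.null(motif_table) &&
                              "MBSIIG" %in% names(motif_table)) {
    motif_table$MBSIIG[match(calls$gene_id, motif_table$gene_id)]
  } else NA
  calls$evidence <- apply(calls, 1, function(r) {
    e <- c(if (isTRUE(as.logical(r[["bona_fide"]]))) "expression",
           if (isTRUE(as.logical(r[["in_modal_cluster"]]))) "coexpression",
           if (isTRUE(as.logical(r[["mbsiig_present"]]))) "MBSIIG")
    paste(e, collapse = "+")
  })
  rownames(calls) <- NULL
  calls
}
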