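#' Three-way intersection of method hit sets
#'
#' The consensus ("key genera") are those flagged by all three screening
#' methods: Spearman correlation, the two-part MWAS, and high-vs-low
#' differential abundance.
#'
#' @param spearman,mwas,diff character vectors of genus IDs.
#' @return character vector, the three-way intersection (order of the
#'   `spearman` argument).
#' @examples
#' intersect_hits(c("a", "b", "c"), c("b", "c", "d"), c("c", "e"))  # "c"
#' @export
intersect_hits <- function(spearman, mwas, diff) {
  intersect(intersect(spearman, mwas), diff)
}

#' Tally consensus genera by phylum
#'
#' @param consensus character vector of genus IDs.
#' @param taxonomy either a named character vector (genus -> phylum) or a
#'   data.frame with `genus` and `phylum` columns. Genera without a taxonomy
#'   entry are tallied under `"Unclassified"`.
#' @return named integer vector of phylum counts (decreasing, ties by name).
#' @examples
#' phylum_tally(c("g1", "g2"), c(g1 = "Firmicutes", g2 = "Bacteroidetes"))
#' @export
phylum_tally <- function(consensus, taxonomy) {
  if (is.data.frame(taxonomy)) {
    taxonomy <- stats::setNames(as.character(taxonomy$phylum),
                                taxonomy$genus)
  }
  if (length(consensus) == 0L) return(stats::setNames(integer(0),
                                                      character(0)))
  ph <- unname(taxonomy[consensus])
  ph[is.na(ph) | ph == ""] <- "Unclassified"
  tab <- table(ph)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' Build the consensus report from the three screening results
#'
#' Extracts each method's hit set using the conventional rules — Spearman:
#' classification not `"none"` (p < 0.01 and |rho| > 0.20); MWAS:
#' Bonferroni-significant; differential abundance: group t-test p below its
#' threshold — intersects them, and tallies consensus genera by phylum.
#'
#' @param spearman_res result of [correlation_screen()].
#' @param mwas_res result of [mwas_screen()].
#' @param diff_res result of [group_comparison()] on genus columns.
#' @param taxonomy genus -> phylum map (vector or data.frame), or `NULL` to
#'   skip the tally.
#' @param target phenotype label.
#' @return a `consensus_report`: list with `target`, the three hit sets,
#'   `consensus`, `phylum_counts`, and `membership` (genus x method logical
#'   matrix over the union of hits, for upset-style plots).
#' @export
consensus_report <- function(spearman_res, mwas_res, diff_res,
                             taxonomy = NULL, target = "NDFD") {
  sp_hits <- spearman_res$feature[spearman_res$classification != "none"]
  mw_hits <- mwas_res$feature[mwas_res$significant]
  df_hits <- diff_res$feature[diff_res$significant]
  consensus <- intersect_hits(sp_hits, mw_hits, df_hits)
  universe <- sort(unique(c(sp_hits, mw_hits, df_hits)))
  membership <- cbind(spearman = universe %in% sp_hits,
                      mwas = universe %in% mw_hits,
                      differential = universe %in% df_hits)
  rownames(membership) <- universe
  structure(list(target = target, spearman_hits = sp_hits,
                 mwas_hits = mw_hits, diff_hits = df_hits,
                 consensus = consensus,
                 phylum_counts = if (is.null(taxonomy)) NULL
                                 else phylum_tally(consensus, taxonomy),
                 membership = membership),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("consensus_report [%s]: %d spearman, %d mwas, %d differential",
              x$target, length(x$spearman_hits), length(x$mwas_hits),
              length(x$diff_hits)),
      sprintf("-> %d consensus genera\n", length(x$consensus)))
  if (length(x$consensus)) {
    cat("  ", paste(x$consensus, collapse = ", "), "\n")
  }
  if (!is.null(x$phylum_counts) && length(x$phylum_counts)) {
    cat("  phyla:", paste(names(x$phylum_counts), x$phylum_counts,
                          sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}
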