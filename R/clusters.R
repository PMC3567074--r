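# Motif-cluster architecture: single-linkage grouping of same-motif hits and
# their placement relative to the regulated intron's splice acceptor.

#' Call motif clusters from a hit table
#'
#' Single-linkage grouping of same-motif hits: consecutive hits (by start)
#' whose inter-hit gap (next start minus previous end) is at most `max_gap`
#' join one cluster. When a gene model is supplied, each cluster is annotated
#' with its feature context and, for clusters inside the regulated intron,
#' the gap between the cluster's 3' end and the splice acceptor.
#'
#' @param hits A motif-hit table.
#' @param max_gap Maximum inter-hit gap in nt (default 150, reflecting the
#'   conserved TRA/TRA2 inter-site spacing).
#' @param gene Optional `gene_model` for context annotation.
#' @return data.frame with one row per cluster: `motif_name`, `n_sites`,
#'   `start`, `end` (span, 0-based half-open), `context`, `gap_to_acceptor`
#'   (`NA` outside the regulated intron). The hit-to-cluster assignment is
#'   attached as attribute `"assignment"` (integer vector parallel to the
#'   row order of the cluster-sorted hits, carried in attribute `"hits"`).
#' @export
call_clusters <- function(hits, max_gap = 150L, gene = NULL) {
  empty <- data.frame(motif_name = character(0), n_sites = integer(0),
                      start = integer(0), end = integer(0),
                      context = character(0), gap_to_acceptor = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$motif_name, hits$start), , drop = FALSE]
  assignment <- integer(nrow(hits))
  rows <- list()
  cid <- 0L
  for (nm in unique(hits$motif_name)) {
    idx <- which(hits$motif_name == nm)
    gap_new <- c(Inf, hits$start[idx][-1L] - hits$end[idx][-length(idx)])
    grp <- cumsum(gap_new > max_gap)
    for (g in unique(grp)) {
      cid <- cid + 1L
      members <- idx[grp == g]
      assignment[members] <- cid
      span <- c(min(hits$start[members]), max(hits$end[members]))
      ctx <- NA_character_; gap_acc <- NA_integer_
      if (!is.null(gene)) {
        ctx <- feature_context(gene, span[1], span[2])
        fi <- gene_feature(gene, "female_intron_1")
        if (nrow(fi) == 1L && span[1] >= fi$start && span[2] <= fi$end)
          gap_acc <- fi$end - span[2]
      }
      rows[[cid]] <- data.frame(motif_name = nm, n_sites = length(members),
                                start = span[1], end = span[2],
                                context = ctx, gap_to_acceptor = gap_acc,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- assignment
  attr(out, "hits") <- hits
  out
}
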