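# End-to-end orchestration: annotate one gene, compare two or more genes,
# and write machine-readable reports.

#' Annotate a single gene
#'
#' Runs the full single-gene pipeline: motif scanning over the built-in (or
#' supplied) library with feature context, motif-cluster calling, splice-site
#' extraction and scoring, and isoform construction with in-frame stop
#' detection.
#'
#' @param gene A `gene_model`.
#' @param library Motif library (default [motif_library()]).
#' @param max_gap Cluster-calling gap (default 150).
#' @param donor_consensus,u1_5prime Passed to [score_splice_sites()].
#' @return An object of class `gene_report` with elements `gene_id`,
#'   `features`, `hits`, `clusters`, `splice`, `isoforms` (summary
#'   data.frame) and `isoform_objects`.
#' @export
annotate_gene <- function(gene, library = motif_library(), max_gap = 150L,
                          donor_consensus = "AG/GTAAGT",
                          u1_5prime = U1_5PRIME_DEFAULT) {
  validate_gene_model(gene)
  hits <- scan_gene(gene, library)
  clusters <- call_clusters(hits, max_gap = max_gap, gene = gene)
  splice <- score_splice_sites(gene, donor_consensus = donor_consensus,
                               u1_5prime = u1_5prime)
  iso <- build_isoforms(gene)
  iso_df <- do.call(rbind, lapply(iso, function(x) data.frame(
    sex = x$sex, spliced_length = nchar(x$spliced_seq),
    donor_used = x$donor_used,
    n_inframe_stops = length(x$stop_positions_in_frame),
    premature_stop = has_premature_stop(x), stringsAsFactors = FALSE)))
  rownames(iso_df) <- NULL
  structure(list(gene_id = gene$gene_id, features = gene$features,
                 hits = hits, clusters = clusters, splice = splice,
                 isoforms = iso_df, isoform_objects = iso),
            class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf("<gene_report> %s: %d motif hits, %d clusters\n", x$gene_id,
              nrow(x$hits), nrow(x$clusters)))
  print(x$clusters, row.names = FALSE)
  cat("splice sites:\n")
  print(x$splice[, c("kind", "sex", "word", "consensus_matches", "u1_pairs")],
        row.names = FALSE)
  invisible(x)
}

# region sequence used for pairwise comparison
.region_seq <- function(gene, region) {
  switch(region,
    intron1 = feature_seq(gene, "female_intron_1"),
    cds = build_isoforms(gene)$female$spliced_seq,
    protein = translate_cds(build_isoforms(gene)$female$spliced_seq),
    gene = gene$sequence,
    .val_err(sprintf("unknown region '%s'", region)))
}

#' Compare two or more genes pairwise
#'
#' For every unordered pair, computes global-alignment identity (and, for
#' proteins, similarity) of the requested region, the dot matrix, conserved
#' blocks and insertion calls of the regulated intron, and each gene's
#' TRA/TRA2 cluster architecture.
#'
#' @param genes Named list of `gene_model`s (length >= 2).
#' @param region Region for the identity statistic: `"intron1"` (default),
#'   `"cds"`, `"protein"` or `"gene"`.
#' @param window,min_matches Dot-matrix parameters (defaults 8 and 7).
#' @param min_block_len,min_block_identity Conserved-block parameters.
#' @param min_insertion_len Minimum insertion call length (default 100).
#' @return An object of class `comparison_report`: `identity` (symmetric
#'   matrix, percent), `pairs` (per-pair list with `alignment`, `dot_matrix`,
#'   `blocks`, `insertions`), `architecture` (per-gene cluster table).
#' @export
compare_genes <- function(genes, region = "intron1", window = 8L,
                          min_matches = 7L, min_block_len = 30L,
                          min_block_identity = 0.8,
                          min_insertion_len = 100L) {
  if (length(genes) < 2L) .val_err("need at least two genes to compare")
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, `[[`, "", "gene_id")
  ids <- names(genes)
  idm <- matrix(100, length(genes), length(genes),
                dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    mode <- if (region == "protein") "protein" else "dna"
    a <- .region_seq(genes[[i]], region)
    b <- .region_seq(genes[[j]], region)
    cmp <- global_align(a, b, mode = mode, seq_ids = c(ids[i], ids[j]))
    ia <- feature_seq(genes[[i]], "female_intron_1")
    ib <- feature_seq(genes[[j]], "female_intron_1")
    icmp <- if (region == "intron1") cmp else
      global_align(ia, ib, seq_ids = c(ids[i], ids[j]))
    pairs[[paste(ids[i], ids[j], sep = "|")]] <- list(
      alignment = cmp,
      dot_matrix = dot_matrix(ia, ib, window, min_matches),
      blocks = conserved_blocks(icmp, min_block_len, min_block_identity),
      insertions = find_insertions(icmp, min_insertion_len))
    idm[i, j] <- idm[j, i] <- cmp$pct_identity
  }
  arch <- do.call(rbind, lapply(ids, function(id) {
    rep <- call_clusters(
      scan_iupac(genes[[id]]$sequence, motif_library()$tra_tra2_core),
      gene = genes[[id]])
    if (nrow(rep)) rep$gene_id <- id
    rep
  }))
  structure(list(identity = idm, pairs = pairs, architecture = arch,
                 region = region), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d genes, region '%s'\n",
              nrow(x$identity), x$region))
  print(round(x$identity, 1))
  invisible(x)
}

#' Write a report directory
#'
#' Writes deterministic TSV/BED/JSON outputs (re-running with the same
#' inputs reproduces them byte-identically): the hit table with BED6, the
#' cluster, splice and isoform tables for gene reports; identity matrix,
#' per-pair block/insertion tables and sparse dot matrices for comparison
#' reports; plus a JSON manifest of what was written.
#'
#' @param report A `gene_report` or `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }
  written <- character(0)
  if (inherits(report, "gene_report")) {
    written <- c(written, tsv(report$features, "features.tsv"),
                 tsv(report$hits, "hits.tsv"),
                 tsv(report$clusters, "clusters.tsv"),
                 tsv(report$splice, "splice_sites.tsv"),
                 tsv(report$isoforms, "isoforms.tsv"))
    export_hits_bed(report$hits, file.path(dir, "hits.bed"),
                    seqname = report$gene_id)
    written <- c(written, "hits.bed")
  } else if (inherits(report, "comparison_report")) {
    idm <- as.data.frame(report$identity)
    idm <- cbind(gene_id = rownames(idm), idm)
    written <- c(written, tsv(idm, "identity_matrix.tsv"))
    if (!is.null(report$architecture))
      written <- c(written, tsv(report$architecture, "architecture.tsv"))
    for (nm in names(report$pairs)) {
      p <- report$pairs[[nm]]
      safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
      written <- c(written,
                   tsv(p$blocks, paste0(safe, ".blocks.tsv")),
                   tsv(p$insertions, paste0(safe, ".insertions.tsv")),
                   tsv(p$dot_matrix$points, paste0(safe, ".dotmatrix.tsv")))
    }
  } else .val_err("write_report needs a gene_report or comparison_report")
  jsonlite::write_json(list(report_class = class(report)[1], files = written),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
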