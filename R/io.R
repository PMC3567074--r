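# Reading and writing gene models: FASTA + (TSV | GFF3) annotation, BED export.
#
# The TSV annotation dialect has columns gene_id, role, start, end, rank with
# 0-based half-open coordinates; GFF3 uses the standard 1-based inclusive
# coordinates (type column = feature role, attributes gene_id and rank).

.annot_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
}

#' Load a gene model from FASTA plus annotation
#'
#' @param fasta_path FASTA file with the genomic sequence.
#' @param annotation_path Feature annotation, either the package TSV dialect
#'   (0-based half-open; columns `gene_id`, `role`, `start`, `end`, `rank`) or
#'   GFF3 (1-based inclusive).
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @param species_tag Optional species label.
#' @param sex_specific Passed to [validate_gene_model()].
#' @return A validated `gene_model`. Minus-strand GFF3 genes are
#'   reverse-complemented at load so the model is on the transcribed strand.
#' @export
load_gene <- function(fasta_path, annotation_path, format = "auto",
                      species_tag = "", sex_specific = TRUE) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  if (length(fa) < 1L) .val_err("FASTA contains no records")
  ids <- sub("\\s.*$", "", names(fa))
  format <- .annot_format(annotation_path, format)
  if (format == "tsv") {
    ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
    need <- c("gene_id", "role", "start", "end")
    if (!all(need %in% names(ann)))
      .val_err("TSV annotation must have columns gene_id, role, start, end[, rank]")
    if (is.null(ann$rank)) ann$rank <- NA_integer_
    gene_id <- ann$gene_id[1]
    feats <- feature_table(ann$role, ann$start, ann$end, ann$rank)
    minus <- FALSE
  } else {
    gr <- rtracklayer::import(annotation_path, format = "gff3")
    if (length(gr) == 0L) .val_err("GFF3 annotation contains no features")
    md <- S4Vectors::mcols(gr)
    gene_id <- if (!is.null(md$gene_id)) as.character(md$gene_id[1]) else
      as.character(GenomicRanges::seqnames(gr)[1])
    rank <- if (!is.null(md$rank)) suppressWarnings(as.integer(md$rank)) else
      rep(NA_integer_, length(gr))
    feats <- feature_table(as.character(md$type),
                           GenomicRanges::start(gr) - 1L,
                           GenomicRanges::end(gr), rank)
    minus <- any(as.character(GenomicRanges::strand(gr)) == "-")
  }
  hit <- match(gene_id, ids)
  if (is.na(hit))
    .val_err(sprintf("FASTA record id '%s' not found for gene_id '%s'",
                     paste(ids, collapse = ","), gene_id))
  seq <- as.character(fa[[hit]])
  if (minus) {
    n <- nchar(seq)
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    new_start <- n - feats$end
    feats$end <- n - feats$start
    feats$start <- new_start
    feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  }
  gene_model(gene_id, seq, feats, species_tag = species_tag,
             sex_specific = sex_specific)
}

#' Write a gene model to FASTA plus annotation
#'
#' Inverse of [load_gene()]; coordinates round-trip bit-exactly through either
#' annotation format.
#'
#' @param gene A `gene_model`.
#' @param fasta_path,annotation_path Output paths.
#' @param format `"auto"`, `"tsv"` or `"gff3"`.
#' @return Invisibly, the annotation path.
#' @export
write_gene <- function(gene, fasta_path, annotation_path, format = "auto") {
  x <- Biostrings::DNAStringSet(gene$sequence)
  names(x) <- gene$gene_id
  Biostrings::writeXStringSet(x, fasta_path)
  format <- .annot_format(annotation_path, format)
  f <- gene$features
  if (format == "tsv") {
    out <- data.frame(gene_id = gene$gene_id, role = f$role,
                      start = f$start, end = f$end, rank = f$rank)
    write.table(out, annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = gene$gene_id,
      ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
      strand = "+", type = f$role, source = "traScan",
      gene_id = gene$gene_id, rank = f$rank)
    rtracklayer::export(gr, annotation_path, format = "gff3")
  }
  invisible(annotation_path)
}

#' Export gene features as BED6
#'
#' @param gene A `gene_model`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
export_features_bed <- function(gene, path) {
  f <- gene$features
  gr <- GenomicRanges::GRanges(
    seqnames = gene$gene_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = "+")
  gr$name <- ifelse(is.na(f$rank), f$role, paste0(f$role, "_", f$rank))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export motif hits as BED6 with extra columns
#'
#' Writes a BED6 file of the hit intervals plus a companion TSV carrying the
#' non-BED columns (mismatches, probability, feature context).
#'
#' @param hits A motif-hit table from [scan_iupac()] and friends.
#' @param path Output BED path; the companion TSV is `path` with a `.tsv`
#'   extension appended.
#' @param seqname Sequence name for the BED records.
#' @return Invisibly, `path`.
#' @export
export_hits_bed <- function(hits, path, seqname = "seq") {
  if (nrow(hits)) {
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
      strand = "+")
    gr$name <- hits$motif_name
    gr$score <- hits$mismatches
    rtracklayer::export(gr, path, format = "BED")
  } else {
    file.create(path)
  }
  write.table(hits, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
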