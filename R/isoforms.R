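# Male and female transcript isoforms of a sex-specifically spliced gene.
#
# The two isoforms differ only in the splice donor used to join intron 1's
# acceptor: females splice from the end of exon 1, males from the downstream
# donor at the 3' end of the male exon, so the male mRNA retains exon 1
# extended through the 5' part of the intron and the male exon.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# 0-based spliced offsets of in-frame stop codons (frame anchored at offset 0)
.frame_stops <- function(spliced) {
  n <- nchar(spliced)
  if (n < 3L) return(integer(0))
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(spliced, starts, starts + 2L)
  starts[codons %in% .STOP_CODONS] - 1L
}

#' Build the female and male transcript isoforms
#'
#' @param gene A `gene_model` with ranked exons, a `male_exon` and a
#'   `female_intron_1`.
#' @return A list with elements `female` and `male`, each of class
#'   `transcript_isoform` with fields `sex`, `exon_chain` (feature rows),
#'   `spliced_seq`, `donor_used` (genomic offset of the donor junction) and
#'   `stop_positions_in_frame` (0-based spliced offsets of in-frame stop
#'   codons, frame anchored at the first spliced base).
#' @export
build_isoforms <- function(gene) {
  validate_gene_model(gene, sex_specific = TRUE)
  ex <- gene_feature(gene, "exon")
  if (nrow(ex) < 2L) .val_err("need at least exons 1 and 2 to build isoforms")
  me <- gene_feature(gene, "male_exon")
  fi <- gene_feature(gene, "female_intron_1")
  if (me$end <= fi$start)
    .val_err("male donor must be downstream of the female donor")
  exon_seqs <- vapply(seq_len(nrow(ex)),
                      function(i) .subseq0(gene$sequence, ex$start[i], ex$end[i]),
                      "")
  female <- structure(list(
    sex = "female", exon_chain = ex,
    spliced_seq = paste(exon_seqs, collapse = ""),
    donor_used = fi$start), class = "transcript_isoform")
  # male: exon 1 extended through the intron 5' segment and male exon,
  # spliced at the male donor to exon 2 onwards
  ext1 <- .subseq0(gene$sequence, ex$start[1L], me$end)
  male_chain <- rbind(ex[1L, , drop = FALSE], me, ex[-1L, , drop = FALSE])
  male <- structure(list(
    sex = "male", exon_chain = male_chain,
    spliced_seq = paste(c(ext1, exon_seqs[-1L]), collapse = ""),
    donor_used = me$end), class = "transcript_isoform")
  female$stop_positions_in_frame <- .frame_stops(female$spliced_seq)
  male$stop_positions_in_frame <- .frame_stops(male$spliced_seq)
  list(female = female, male = male)
}

#' @export
print.transcript_isoform <- function(x, ...) {
  cat(sprintf("<transcript_isoform> %s: %d nt spliced, donor at %d, %d in-frame stop(s)\n",
              x$sex, nchar(x$spliced_seq), x$donor_used,
              length(x$stop_positions_in_frame)))
  invisible(x)
}

#' Does an isoform carry a premature in-frame stop?
#'
#' A stop codon in the final complete codon terminates the ORF normally and
#' does not count as premature.
#'
#' @param isoform A `transcript_isoform`.
#' @return Logical.
#' @export
has_premature_stop <- function(isoform) {
  n <- nchar(isoform$spliced_seq)
  last_codon_start <- (n %/% 3L - 1L) * 3L
  any(isoform$stop_positions_in_frame < last_codon_start)
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons render as `*`, codons containing `N`
#' as `X`. A trailing partial codon is dropped with a warning.
#'
#' @param cds DNA string, length at least 3.
#' @return Protein string.
#' @examples
#' translate_cds("ATGTAA")  # "M*"
#' @export
translate_cds <- function(cds) {
  cds <- .normalize_dna(cds, "CDS")
  n <- nchar(cds)
  if (n < 3L) .val_err("CDS must be at least one codon long")
  if (n %% 3L != 0L) {
    warning(sprintf("dropping trailing partial codon (%d nt)", n %% 3L))
    n <- n - n %% 3L
    cds <- substr(cds, 1L, n)
  }
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
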