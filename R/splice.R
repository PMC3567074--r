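# Splice-site extraction and scoring: consensus match counting at the
# donor/acceptor junctions and the predicted hybrid with the 5' end of U1
# snRNA (a proxy for intrinsic donor strength).

# canonical metazoan U1 snRNA 5' terminus, written 5'->3'
U1_5PRIME_DEFAULT <- "ACUUACCUGG"

.splice_site <- function(kind, sex, junction, exonic, intronic) {
  canonical <- if (kind == "donor") startsWith(intronic, "GT") else
    endsWith(intronic, "AG")
  structure(list(kind = kind, sex = sex, junction_offset = junction,
                 exonic_flank = exonic, intronic_flank = intronic,
                 canonical = canonical),
            class = "splice_site")
}

#' @export
print.splice_site <- function(x, ...) {
  word <- if (x$kind == "donor") paste0(x$exonic_flank, "/", x$intronic_flank)
          else paste0(x$intronic_flank, "/", x$exonic_flank)
  cat(sprintf("<splice_site> %s (%s) at %d: %s%s\n", x$kind, x$sex,
              x$junction_offset, word,
              if (x$canonical) "" else " [non-canonical]"))
  invisible(x)
}

# window on the sequence, N-padded beyond the ends
.padded_window <- function(seq, start, end) {
  n <- nchar(seq)
  left <- max(0L, -start); right <- max(0L, end - n)
  core <- .subseq0(seq, max(0L, start), min(n, end))
  paste0(strrep("N", left), core, strrep("N", right))
}

#' Extract the sex-specific splice sites of a gene
#'
#' Returns the female donor (exon 1 / intron 1 junction), the male donor
#' (male exon / intron junction) and the shared acceptor (intron 1 / exon 2
#' junction), each with exonic and intronic flanking windows (donor window
#' -3..+6, acceptor window -14..+2 by default, N-padded at sequence edges).
#' Non-GT donors / non-AG acceptors are flagged `canonical = FALSE`, not
#' rejected.
#'
#' @param gene A `gene_model` with `female_intron_1` and `male_exon`.
#' @param donor_exonic,donor_intronic Donor window sizes (default 3 and 6).
#' @param acceptor_intronic,acceptor_exonic Acceptor window sizes (default 14
#'   and 2).
#' @return Named list of `splice_site`s: `female_donor`, `male_donor`,
#'   `acceptor`.
#' @export
extract_splice_sites <- function(gene, donor_exonic = 3L, donor_intronic = 6L,
                                 acceptor_intronic = 14L,
                                 acceptor_exonic = 2L) {
  fi <- gene_feature(gene, "female_intron_1")
  me <- gene_feature(gene, "male_exon")
  if (nrow(fi) != 1L || nrow(me) != 1L)
    .val_err("gene must have one female_intron_1 and one male_exon")
  s <- gene$sequence
  donor <- function(j, sex) .splice_site(
    "donor", sex, j,
    .padded_window(s, j - donor_exonic, j),
    .padded_window(s, j, j + donor_intronic))
  acc_j <- fi$end
  acceptor <- .splice_site(
    "acceptor", "na", acc_j,
    .padded_window(s, acc_j, acc_j + acceptor_exonic),
    .padded_window(s, acc_j - acceptor_intronic, acc_j))
  list(female_donor = donor(fi$start, "female"),
       male_donor = donor(me$end, "male"),
       acceptor = acceptor)
}

#' Count matches of a splice site to a junction-aligned consensus
#'
#' The consensus uses split notation anchored at the junction, e.g. the
#' donor consensus `"AG/GTAAGT"` (2 exonic + 6 intronic positions). The
#' corresponding site word is assembled from the site's flanks and compared
#' positionwise with [match_count()] (the consensus may be degenerate).
#'
#' @param site A `splice_site`.
#' @param consensus Split-notation IUPAC consensus.
#' @return List with `consensus_matches` and `window_len`.
#' @export
consensus_match <- function(site, consensus = "AG/GTAAGT") {
  parts <- strsplit(consensus, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    .val_err("consensus must use split notation, e.g. 'AG/GTAAGT'")
  # junction-anchored assembly: the upstream side is right-aligned (left
  # N-padded if the window is shorter than the consensus), the downstream
  # side left-aligned (right N-padded)
  left_take <- function(x, k) {   # last k characters, left-padded
    got <- substr(x, max(1L, nchar(x) - k + 1L), nchar(x))
    paste0(strrep("N", k - nchar(got)), got)
  }
  right_take <- function(x, k) {  # first k characters, right-padded
    got <- substr(x, 1L, k)
    paste0(got, strrep("N", k - nchar(got)))
  }
  if (site$kind == "donor") {
    word <- paste0(left_take(site$exonic_flank, nchar(parts[1])),
                   right_take(site$intronic_flank, nchar(parts[2])))
  } else {
    word <- paste0(left_take(site$intronic_flank, nchar(parts[1])),
                   right_take(site$exonic_flank, nchar(parts[2])))
  }
  ref <- paste0(parts[1], parts[2])
  list(consensus_matches = match_count(word, ref), window_len = nchar(ref),
       word = word)
}

#' Predicted hybrid of a donor window with the U1 snRNA 5' end
#'
#' Counts base pairs formed between the donor window (exonic + intronic
#' flank, 9 nt by default) and the 5' end of U1 snRNA in the fixed
#' antiparallel register in which the first `w` bases of the U1 5' end pair
#' with the `w`-base donor window (donor position `i` against U1 position
#' `w - i + 1`). Watson-Crick pairs (G:C, A:U/T) make up `u1_pairs`; G:U
#' wobble pairs are counted separately and not included by default.
#'
#' @param donor A donor `splice_site` (or a bare DNA window string).
#' @param u1_5prime U1 snRNA 5' end, written 5'->3' (RNA or DNA alphabet).
#' @return List with `u1_pairs` (Watson-Crick), `gu_pairs` (wobble),
#'   `window_len`.
#' @export
u1_hybrid <- function(donor, u1_5prime = U1_5PRIME_DEFAULT) {
  window <- if (inherits(donor, "splice_site"))
    paste0(donor$exonic_flank, donor$intronic_flank) else donor
  window <- .normalize_dna(window, "donor window")
  w <- nchar(window)
  if (w < 3L) .val_err("donor window shorter than 3 nt")
  u1 <- .normalize_dna(u1_5prime, "U1 5' end")
  if (nchar(u1) < w) .val_err("u1_5prime shorter than the donor window")
  d <- strsplit(window, "", fixed = TRUE)[[1]]
  u <- rev(strsplit(substr(u1, 1L, w), "", fixed = TRUE)[[1]])
  wc <- (d == "A" & u == "T") | (d == "T" & u == "A") |
        (d == "G" & u == "C") | (d == "C" & u == "G")
  gu <- (d == "G" & u == "T") | (d == "T" & u == "G")
  list(u1_pairs = sum(wc), gu_pairs = sum(gu), window_len = w)
}

#' Score all sex-specific splice sites of a gene
#'
#' @param gene A `gene_model`.
#' @param donor_consensus Split-notation donor consensus (default the
#'   Drosophila `"AG/GTAAGT"`).
#' @param acceptor_consensus Split-notation acceptor consensus.
#' @param u1_5prime U1 5' end for donor hybrid scoring.
#' @return A data.frame with one row per site: kind, sex, junction offset,
#'   junction word, consensus matches / window length, U1 Watson-Crick and
#'   wobble pairs (donors only) and the canonical flag.
#' @export
score_splice_sites <- function(gene, donor_consensus = "AG/GTAAGT",
                               acceptor_consensus = "TTTTTTTTTTTNCAG/G",
                               u1_5prime = U1_5PRIME_DEFAULT) {
  sites <- extract_splice_sites(gene)
  rows <- lapply(sites, function(s) {
    cm <- consensus_match(s, if (s$kind == "donor") donor_consensus else
      acceptor_consensus)
    hy <- if (s$kind == "donor") u1_hybrid(s, u1_5prime) else
      list(u1_pairs = NA_integer_, gu_pairs = NA_integer_)
    data.frame(kind = s$kind, sex = s$sex,
               junction_offset = s$junction_offset, word = cm$word,
               consensus_matches = cm$consensus_matches,
               window_len = cm$window_len, u1_pairs = hy$u1_pairs,
               gu_pairs = hy$gu_pairs, canonical = s$canonical,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
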