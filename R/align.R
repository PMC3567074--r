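# Pairwise global alignment and alignment-derived conservation statistics:
# percent identity/similarity, conserved blocks and insertion calls.
#
# Alignment itself is Needleman-Wunsch with affine gaps via
# Biostrings::pairwiseAlignment; identity uses total alignment columns
# (internal gaps included) as the denominator, which is what makes very low
# intron identities reachable when indels accumulate.

# Clustal "strong group" conservative amino-acid sets, used for % similarity
.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY*X", "")[[1]]

.group_index <- local({
  idx <- lapply(.STRONG_GROUPS, function(g) strsplit(g, "")[[1]])
  m <- matrix(FALSE, 26, 26, dimnames = list(LETTERS, LETTERS))
  for (g in idx) for (a in g) for (b in g) m[a, b] <- TRUE
  m
})

#' Global pairwise alignment with conservation statistics
#'
#' Needleman-Wunsch global alignment with affine gap penalties. DNA defaults
#' are EMBOSS-like (match +5 / mismatch -4, gap open 10 / extend 0.5);
#' protein mode uses BLOSUM62 and additionally reports percent similarity
#' (identical plus Clustal strong-group conservative substitutions). Percent
#' identity is matches / total alignment columns x 100.
#'
#' @param a,b Sequences (DNA or protein strings).
#' @param mode `"dna"` or `"protein"`.
#' @param seq_ids Length-2 character vector of labels.
#' @param match,mismatch DNA scores.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param submat Protein substitution matrix name (default `"BLOSUM62"`).
#' @return An object of class `pair_comparison`: `seq_ids`, `mode`,
#'   `aligned` (named character pair with `-` gaps), `score`,
#'   `alignment_length`, `matches`, `pct_identity`, `pct_similarity`
#'   (protein mode, else `NA`).
#' @export
global_align <- function(a, b, mode = c("dna", "protein"),
                         seq_ids = c("a", "b"), match = 5, mismatch = -4,
                         gap_open = 10, gap_extend = 0.5,
                         submat = "BLOSUM62") {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) .val_err("sequences must be non-empty")
  # canonical pair ordering: ties among co-optimal alignments are broken
  # differently for the pattern and subject roles, so identity is made
  # symmetric by always aligning the lexicographically smaller sequence
  # as the pattern and swapping the result back
  swapped <- a > b
  if (swapped) {
    tmp <- a; a <- b; b <- tmp
    seq_ids <- rev(seq_ids)
  }
  if (mode == "dna") {
    a <- .normalize_dna(a, "sequence a"); b <- .normalize_dna(b, "sequence b")
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                   mismatch = mismatch,
                                                   baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  } else {
    a <- toupper(a); b <- toupper(b)
    bad <- regmatches(paste0(a, b), regexpr("[^ACDEFGHIKLMNPQRSTVWYX*]",
                                            paste0(a, b)))
    if (length(bad) && nzchar(bad))
      .val_err(sprintf("invalid residue '%s' in protein sequence", bad))
    a2 <- gsub("*", "X", a, fixed = TRUE); b2 <- gsub("*", "X", b, fixed = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a2), Biostrings::AAString(b2), type = "global",
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend)
  }
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  if (swapped) {
    tmp <- al_a; al_a <- al_b; al_b <- tmp
    seq_ids <- rev(seq_ids)
  }
  ca <- strsplit(al_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1]]
  len <- length(ca)
  ident <- ca == cb & ca != "-"
  matches <- sum(ident)
  pct_sim <- NA_real_
  if (mode == "protein") {
    both <- ca != "-" & cb != "-" & ca %in% LETTERS & cb %in% LETTERS
    cons <- both & .group_index[cbind(
      match(ca, LETTERS, nomatch = 1L), match(cb, LETTERS, nomatch = 1L))]
    pct_sim <- (matches + sum(cons & !ident)) / len * 100
  }
  structure(list(seq_ids = seq_ids, mode = mode,
                 aligned = c(a = al_a, b = al_b),
                 score = Biostrings::score(pa), alignment_length = len,
                 matches = matches, pct_identity = matches / len * 100,
                 pct_similarity = pct_sim),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair_comparison> %s vs %s (%s): %d columns, %.1f%% identity",
              x$seq_ids[1], x$seq_ids[2], x$mode, x$alignment_length,
              x$pct_identity))
  if (!is.na(x$pct_similarity))
    cat(sprintf(", %.1f%% similarity", x$pct_similarity))
  cat("\n")
  invisible(x)
}

# alignment column -> 0-based host offset of the residue at/preceding it
.host_coords <- function(aligned_chars) cumsum(aligned_chars != "-")

#' Call insertions from a pairwise alignment
#'
#' Maximal gap runs of at least `min_len` columns in either aligned sequence;
#' a gap run in one sequence is an insertion hosted by the other. Offsets are
#' 0-based positions in the host sequence where the inserted material starts.
#'
#' @param cmp A `pair_comparison`.
#' @param min_len Minimum insertion length (default 30).
#' @param merge_within Merge same-host gap runs whose host-coordinate gap is
#'   at most this many nt (default 10; long insertions of low-complexity or
#'   random sequence often align as several gap runs broken by a few spurious
#'   matched columns). Merged calls span the full host interval.
#' @return data.frame with columns `offset`, `length`, `which_seq` (the
#'   sequence carrying the inserted material: `"a"` or `"b"`).
#' @export
find_insertions <- function(cmp, min_len = 30L, merge_within = 10L) {
  ca <- strsplit(cmp$aligned[["a"]], "", fixed = TRUE)[[1]]
  cb <- strsplit(cmp$aligned[["b"]], "", fixed = TRUE)[[1]]
  one <- function(gapped, host_chars, which_host) {
    r <- rle(gapped == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)  # all runs; length filter applied after merging
    if (!length(keep))
      return(data.frame(offset = integer(0), length = integer(0),
                        which_seq = character(0)))
    host_pos <- .host_coords(host_chars)
    data.frame(offset = host_pos[starts[keep]] - 1L,
               length = r$lengths[keep], which_seq = which_host,
               stringsAsFactors = FALSE)
  }
  merge_runs <- function(df) {
    if (nrow(df) < 2L) return(df)
    df <- df[order(df$offset), , drop = FALSE]
    grp <- cumsum(c(1L, df$offset[-1L] -
                      (df$offset[-nrow(df)] + df$length[-nrow(df)]) >
                      merge_within))
    do.call(rbind, lapply(split(df, grp), function(d)
      data.frame(offset = d$offset[1L],
                 length = max(d$offset + d$length) - d$offset[1L],
                 which_seq = d$which_seq[1L], stringsAsFactors = FALSE)))
  }
  out <- rbind(merge_runs(one(ca, cb, "b")), merge_runs(one(cb, ca, "a")))
  out <- out[out$length >= min_len, , drop = FALSE]
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call conserved blocks from a pairwise alignment
#'
#' Deterministic greedy block calling: every alignment window of
#' `min_block_len` columns with identity at least `min_block_identity` seeds
#' a block; overlapping covered regions are merged, block ends are trimmed to
#' matching (gap-free) columns, and merged blocks are kept if they still
#' satisfy both thresholds.
#'
#' @param cmp A `pair_comparison`.
#' @param min_block_len Minimum block length in alignment columns
#'   (default 30).
#' @param min_block_identity Identity threshold within a block (default 0.8,
#'   as a fraction).
#' @return data.frame with columns `start_a`, `end_a`, `start_b`, `end_b`
#'   (0-based half-open host coordinates), `length` (columns),
#'   `block_identity` (fraction). Blocks are non-overlapping and ordered.
#' @export
conserved_blocks <- function(cmp, min_block_len = 30L,
                             min_block_identity = 0.8) {
  ca <- strsplit(cmp$aligned[["a"]], "", fixed = TRUE)[[1]]
  cb <- strsplit(cmp$aligned[["b"]], "", fixed = TRUE)[[1]]
  eq <- as.integer(ca == cb & ca != "-")
  L <- length(eq)
  w <- as.integer(min_block_len)
  empty <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      length = integer(0), block_identity = numeric(0))
  if (L < w) return(empty)
  cs <- cumsum(c(0L, eq))
  wsum <- cs[(w + 1L):(L + 1L)] - cs[1:(L - w + 1L)]
  seeds <- which(wsum >= min_block_identity * w)
  if (!length(seeds)) return(empty)
  cover <- logical(L)
  for (s in seeds) cover[s:(s + w - 1L)] <- TRUE
  r <- rle(cover)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  pos_a <- .host_coords(ca); pos_b <- .host_coords(cb)
  rows <- lapply(segs, function(k) {
    s <- starts[k]; e <- ends[k]
    while (s <= e && eq[s] == 0L) s <- s + 1L   # gap-free matching ends
    while (e >= s && eq[e] == 0L) e <- e - 1L
    len <- e - s + 1L
    if (len < w) return(NULL)
    bid <- mean(eq[s:e])
    if (bid < min_block_identity) return(NULL)
    data.frame(start_a = pos_a[s] - 1L, end_a = pos_a[e],
               start_b = pos_b[s] - 1L, end_b = pos_b[e],
               length = len, block_identity = bid)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Write blocks or insertions as TSV
#'
#' @param x data.frame from [conserved_blocks()] or [find_insertions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
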