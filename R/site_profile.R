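# Binding-site profiles: aligned fixed-width windows, their PFM, per-column
# information content and a derived degenerate consensus -- the machinery
# behind a count-based sequence logo.

#' Extract fixed-width windows around motif hits
#'
#' Cuts equal-length windows from a sequence so that every hit's motif start
#' lands on the same window column, the registration needed before profiling
#' a set of sites (default 26-nt windows).
#'
#' @param hits A hit table (rows with `start`).
#' @param seq The sequence the hits were found on.
#' @param width Window width (default 26).
#' @param anchor 0-based column at which the motif start is placed within the
#'   window (default `6`).
#' @return An object of class `site_window_set`: a character vector of
#'   windows with attribute `anchor`. Hits too close to the sequence ends to
#'   yield a full window are dropped with a warning; zero extractable windows
#'   is an error.
#' @export
extract_windows <- function(hits, seq, width = 26L, anchor = 6L) {
  seq <- .normalize_dna(seq)
  width <- as.integer(width); anchor <- as.integer(anchor)
  if (!nrow(hits)) .val_err("no hits supplied")
  ws <- hits$start - anchor
  ok <- ws >= 0L & (ws + width) <= nchar(seq)
  if (any(!ok))
    warning(sprintf("dropped %d hit(s) too close to the sequence ends",
                    sum(!ok)))
  if (!any(ok)) .val_err("no extractable windows")
  w <- substring(seq, ws[ok] + 1L, ws[ok] + width)
  structure(w, anchor = anchor, class = "site_window_set")
}

#' Read / write aligned site windows as FASTA
#'
#' @param windows A `site_window_set` or character vector of equal-length
#'   windows.
#' @param path FASTA path.
#' @param anchor Anchor column recorded when reading (default 0).
#' @return `write_windows_fasta` invisibly returns `path`;
#'   `read_windows_fasta` returns a `site_window_set`.
#' @export
write_windows_fasta <- function(windows, path) {
  x <- Biostrings::DNAStringSet(as.character(windows))
  names(x) <- sprintf("window_%03d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_windows_fasta
#' @export
read_windows_fasta <- function(path, anchor = 0L) {
  w <- as.character(Biostrings::readDNAStringSet(path))
  structure(unname(w), anchor = as.integer(anchor), class = "site_window_set")
}

#' Build a position frequency matrix from aligned windows
#'
#' Exact per-column base counts; `N` bases are excluded from the column
#' totals (so columns of an N-containing set sum to fewer than the window
#' count).
#'
#' @param windows A `site_window_set` or character vector (>= 1 window, equal
#'   lengths; >= 2 for a meaningful profile).
#' @return An object of class `site_profile` with fields `pfm` (4 x L
#'   counts), `n_windows`, `anchor`.
#' @export
build_pfm <- function(windows) {
  w <- toupper(as.character(windows))
  if (!length(w)) .val_err("no windows")
  lens <- unique(nchar(w))
  if (length(lens) != 1L) .val_err("windows must all have the same length")
  L <- lens
  mat <- matrix(unlist(strsplit(w, "", fixed = TRUE), use.names = FALSE),
                nrow = length(w), byrow = TRUE)
  pfm <- vapply(seq_len(L), function(j)
    c(A = sum(mat[, j] == "A"), C = sum(mat[, j] == "C"),
      G = sum(mat[, j] == "G"), T = sum(mat[, j] == "T")),
    numeric(4))
  structure(list(pfm = pfm, n_windows = length(w),
                 anchor = attr(windows, "anchor") %||% 0L),
            class = "site_profile")
}

#' Per-column information content
#'
#' `IC_j = 2 + sum_b p_bj log2 p_bj` bits against a uniform background, with
#' `0 * log 0 = 0` and no pseudocounts; column probabilities come from the
#' N-excluded counts. Values lie in `[0, 2]`.
#'
#' @param profile A `site_profile` (or bare 4 x L count matrix).
#' @return Numeric vector of per-column bits.
#' @export
information_content <- function(profile) {
  pfm <- if (inherits(profile, "site_profile")) profile$pfm else profile
  cs <- colSums(pfm)
  vapply(seq_len(ncol(pfm)), function(j) {
    if (cs[j] == 0) return(0)
    p <- pfm[, j] / cs[j]
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
}

#' Derive a degenerate consensus and high-information core span
#'
#' Per column, the consensus code is the smallest IUPAC code covering all
#' bases at frequency at least `fraction_threshold`; the core span is the
#' longest contiguous run of columns with information content at least
#' `ic_threshold` (first such run on ties).
#'
#' @param profile A `site_profile`.
#' @param ic_threshold Bits, in `[0, 2]` (default 0.5).
#' @param fraction_threshold Base frequency cutoff (default 0.25).
#' @return List with `consensus_iupac`, `core_span` (1-based inclusive column
#'   range, `c(NA, NA)` if no column reaches threshold), `column_ic`.
#' @export
derive_consensus <- function(profile, ic_threshold = 0.5,
                             fraction_threshold = 0.25) {
  if (ic_threshold < 0 || ic_threshold > 2)
    .val_err("ic_threshold must lie in [0, 2]")
  pfm <- profile$pfm
  cs <- colSums(pfm)
  cons <- vapply(seq_len(ncol(pfm)), function(j) {
    if (cs[j] == 0) return("N")
    keep <- rownames(pfm)[pfm[, j] / cs[j] >= fraction_threshold]
    if (!length(keep)) keep <- rownames(pfm)[pfm[, j] > 0]  # none dominant
    .set_to_iupac(keep)
  }, "")
  ic <- information_content(profile)
  above <- ic >= ic_threshold
  span <- c(NA_integer_, NA_integer_)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    span <- c(starts[best], ends[best])
  }
  list(consensus_iupac = paste(cons, collapse = ""), core_span = span,
       column_ic = ic)
}

#' Logo matrix of a profile
#'
#' Column base heights `p * IC` (the count-based logo representation);
#' plotting is left to the caller.
#'
#' @param profile A `site_profile`.
#' @return 4 x L numeric matrix of letter heights in bits.
#' @export
logo_matrix <- function(profile) {
  pfm <- profile$pfm
  cs <- colSums(pfm)
  cs[cs == 0] <- 1
  p <- sweep(pfm, 2L, cs, "/")
  sweep(p, 2L, information_content(profile), "*")
}

#' Full site profile in one call
#'
#' Convenience wrapper: PFM, information content, consensus and core span
#' from a window set.
#'
#' @inheritParams build_pfm
#' @inheritParams derive_consensus
#' @return A `site_profile` with `column_ic`, `consensus_iupac`, `core_span`
#'   filled in.
#' @export
site_profile <- function(windows, ic_threshold = 0.5,
                         fraction_threshold = 0.25) {
  prof <- build_pfm(windows)
  d <- derive_consensus(prof, ic_threshold, fraction_threshold)
  prof$column_ic <- d$column_ic
  prof$consensus_iupac <- d$consensus_iupac
  prof$core_span <- d$core_span
  prof
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile> %d windows x %d columns\n", x$n_windows,
              ncol(x$pfm)))
  if (!is.null(x$consensus_iupac)) {
    cat("consensus:", x$consensus_iupac, "\n")
    if (!anyNA(x$core_span))
      cat(sprintf("core span: columns %d-%d (%d columns)\n", x$core_span[1],
                  x$core_span[2], diff(x$core_span) + 1L))
  }
  invisible(x)
}

#' Write a profile (or logo matrix) as TSV
#'
#' @param x A `site_profile` or matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(x, path) {
  m <- if (inherits(x, "site_profile")) x$pfm else x
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
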