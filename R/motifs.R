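# Motif definitions and scanning: degenerate IUPAC consensi and position
# frequency matrices, with regex-style expansion, k-mer fragmenting and
# per-hit PFM probability.

#' Define a motif
#'
#' A motif is either a degenerate IUPAC consensus or a position frequency
#' matrix (PFM; 4 x L counts, rows A,C,G,T with equal column sums).
#'
#' @param name Motif name.
#' @param iupac Degenerate IUPAC string, or `NULL`.
#' @param pfm Numeric 4 x L matrix of nonnegative counts, or `NULL`. Exactly
#'   one of `iupac`/`pfm` must be given.
#' @param max_mismatch Default mismatch allowance when scanning (0 = exact
#'   degenerate match, the default).
#' @param fragment_k Default fragment length for [fragment_scan()], or `NULL`.
#' @return An object of class `motif_def`.
#' @export
motif_def <- function(name, iupac = NULL, pfm = NULL, max_mismatch = 0L,
                      fragment_k = NULL) {
  if (is.null(iupac) == is.null(pfm))
    .val_err("exactly one of iupac or pfm must be supplied")
  if (!is.null(iupac)) {
    parse_iupac(iupac)  # validates
    iupac <- toupper(gsub("U", "T", iupac, fixed = TRUE))
    len <- nchar(iupac)
  } else {
    pfm <- as.matrix(pfm)
    if (nrow(pfm) != 4L) .val_err("PFM must have 4 rows (A,C,G,T)")
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0)) .val_err("PFM counts must be nonnegative")
    cs <- colSums(pfm)
    if (length(unique(cs)) != 1L)
      .val_err("PFM columns must all sum to the same site count")
    len <- ncol(pfm)
  }
  structure(list(name = as.character(name),
                 kind = if (is.null(pfm)) "iupac" else "pfm",
                 iupac = iupac, pfm = pfm,
                 max_mismatch = as.integer(max_mismatch),
                 fragment_k = if (is.null(fragment_k)) NULL else
                   as.integer(fragment_k),
                 length = as.integer(len)),
            class = "motif_def")
}

#' @export
print.motif_def <- function(x, ...) {
  cat(sprintf("<motif_def> %s [%s, %d nt]%s\n", x$name, x$kind, x$length,
              if (x$kind == "iupac") paste0(": ", x$iupac) else ""))
  invisible(x)
}

#' Build a PFM motif from aligned site instances
#'
#' @param name Motif name.
#' @param sites Character vector of equal-length concrete DNA sites.
#' @param ... Passed to [motif_def()].
#' @return A PFM `motif_def`.
#' @export
motif_from_sites <- function(name, sites, ...) {
  prof <- build_pfm(sites)
  motif_def(name, pfm = prof$pfm, ...)
}

#' The built-in splicing-regulator motif library
#'
#' Degenerate DNA renderings of the binding-site consensi used throughout the
#' package: the 13-nt TRA/TRA2 core (dsxRE repeat), its TAC(C/T)A 3' flank and
#' the 18/19-nt extended site (core + 0-1 spacer + flank), the RBP1 type A
#' site, a polyU/T-rich run (one mismatch allowed), the Nasonia-type
#' (U/G)GAAGAU(U/A) element and the UNR-associated AUGAAUUU element. The
#' TRA2-ISS silencer consensus is deliberately not built in: supply it via the
#' motif config if you have one.
#'
#' @return Named list of `motif_def` objects.
#' @export
motif_library <- function() {
  defs <- list(
    motif_def("tra_tra2_core", iupac = "WMWWCAATCAACA"),
    motif_def("tacca_flank", iupac = "TACYA"),
    motif_def("tra_tra2_ext18", iupac = "WMWWCAATCAACATACYA"),
    motif_def("tra_tra2_ext19", iupac = "WMWWCAATCAACANTACYA"),
    motif_def("rbp1_type_a", iupac = "DCADCTTA"),
    motif_def("t_rich", iupac = "TTTTT", max_mismatch = 1L),
    motif_def("nasonia_like", iupac = "KGAAGATW", fragment_k = 8L),
    motif_def("unr_like", iupac = "ATGAATTT", fragment_k = 8L)
  )
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Read / write a motif library config
#'
#' Libraries serialize losslessly to a YAML schema: one entry per motif with
#' fields `kind`, `iupac` or `pfm` (counts by row A,C,G,T), `max_mismatch`,
#' `fragment_k`.
#'
#' @param path Config path.
#' @param library Named list of `motif_def`s.
#' @return `read_motif_library` returns the named list; `write_motif_library`
#'   invisibly returns `path`.
#' @export
write_motif_library <- function(library, path) {
  enc <- lapply(library, function(m) {
    e <- list(kind = m$kind, max_mismatch = m$max_mismatch)
    if (!is.null(m$fragment_k)) e$fragment_k <- m$fragment_k
    if (m$kind == "iupac") e$iupac <- m$iupac
    else e$pfm <- lapply(seq_len(4), function(i) unname(m$pfm[i, ]))
    e
  })
  yaml::write_yaml(enc, path)
  invisible(path)
}

#' @rdname write_motif_library
#' @export
read_motif_library <- function(path) {
  enc <- yaml::read_yaml(path)
  out <- lapply(names(enc), function(nm) {
    e <- enc[[nm]]
    pfm <- if (!is.null(e$pfm)) do.call(rbind, e$pfm) else NULL
    motif_def(nm, iupac = e$iupac, pfm = pfm,
              max_mismatch = e$max_mismatch %||% 0L,
              fragment_k = e$fragment_k)
  })
  setNames(out, names(enc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_hits <- function() {
  data.frame(motif_name = character(0), start = integer(0), end = integer(0),
             matched_word = character(0), mismatches = integer(0),
             probability = numeric(0), feature_context = character(0),
             stringsAsFactors = FALSE)
}

.hits_df <- function(motif_name, start, len, seq, mismatches,
                     probability = NA_real_) {
  data.frame(motif_name = motif_name, start = start, end = start + len,
             matched_word = substring(seq, start + 1L, start + len),
             mismatches = as.integer(mismatches),
             probability = probability,
             feature_context = NA_character_, stringsAsFactors = FALSE)
}

#' Scan a sequence with a degenerate IUPAC motif
#'
#' Slides the motif over every window of the sequence and reports all windows
#' (including overlapping ones) whose mismatch count -- positions whose base
#' falls outside the motif's allowed set, with `N` in the sequence always a
#' mismatch -- is at most `max_mismatch`.
#'
#' @param seq DNA string.
#' @param motif An IUPAC `motif_def` (or a bare IUPAC string).
#' @param max_mismatch Mismatch allowance; defaults to the motif's own.
#' @return A hit table (`data.frame`): `motif_name`, `start`, `end` (0-based
#'   half-open), `matched_word`, `mismatches`, `probability` (`NA` here),
#'   `feature_context` (`NA` until annotated), sorted by `start`.
#' @export
scan_iupac <- function(seq, motif, max_mismatch = NULL) {
  if (is.character(motif)) motif <- motif_def(motif, iupac = motif)
  if (motif$kind != "iupac") .val_err("scan_iupac requires an IUPAC motif")
  mm <- if (is.null(max_mismatch)) motif$max_mismatch else
    as.integer(max_mismatch)
  seq <- .normalize_dna(seq)
  L <- motif$length
  nw <- nchar(seq) - L + 1L
  if (nw < 1L) return(.empty_hits())
  allowed <- .iupac_allowed(motif$iupac)
  s <- .encode_dna(seq)
  mis <- integer(nw)
  for (j in seq_len(L))
    mis <- mis + !allowed[s[j:(j + nw - 1L)], j]
  keep <- which(mis <= mm)
  if (!length(keep)) return(.empty_hits())
  .hits_df(motif$name, keep - 1L, L, seq, mis[keep])
}

#' Scan a sequence with a PFM motif
#'
#' Follows the liberal regex-expansion policy: the PFM is collapsed to a
#' per-column set of bases with nonzero count, every window matching that
#' degenerate pattern is reported, and each hit is assigned the probability of
#' its exact word under the column-independent PFM model (product over columns
#' of the observed base's count / column total).
#'
#' @param seq DNA string.
#' @param motif A PFM `motif_def`.
#' @return A hit table as in [scan_iupac()], with `probability` in (0, 1].
#' @export
scan_pfm <- function(seq, motif) {
  if (motif$kind != "pfm") .val_err("scan_pfm requires a PFM motif")
  cs <- colSums(motif$pfm)
  if (any(cs == 0)) .val_err("PFM has an all-zero column")
  seq <- .normalize_dna(seq)
  L <- motif$length
  nw <- nchar(seq) - L + 1L
  if (nw < 1L) return(.empty_hits())
  p <- sweep(motif$pfm, 2L, cs, "/")
  lp <- rbind(log(p), N = -Inf)   # row 5: N in sequence never matches
  lp[lp == -Inf] <- -Inf
  s <- .encode_dna(seq)
  acc <- numeric(nw)
  for (j in seq_len(L))
    acc <- acc + lp[cbind(s[j:(j + nw - 1L)], j)]
  keep <- which(is.finite(acc))
  if (!length(keep)) return(.empty_hits())
  .hits_df(motif$name, keep - 1L, L, seq, 0L, probability = exp(acc[keep]))
}

#' Scan with overlapping k-mer fragments of a motif
#'
#' Re-implements the fragment-search policy for long degenerate motifs: the
#' motif is broken into all overlapping substrings of length `k` and each
#' fragment is scanned independently. Hits carry the 1-based fragment index
#' and the fragment pattern.
#'
#' @param seq DNA string.
#' @param motif An IUPAC `motif_def`.
#' @param k Fragment length (defaults to the motif's `fragment_k`); `k` below
#'   4 triggers a warning (spurious-hit regime) but still runs.
#' @return A hit table with extra columns `fragment` and `fragment_pattern`,
#'   sorted by `(start, fragment)`.
#' @export
fragment_scan <- function(seq, motif, k = NULL) {
  if (is.character(motif)) motif <- motif_def(motif, iupac = motif)
  if (motif$kind != "iupac") .val_err("fragment_scan requires an IUPAC motif")
  k <- as.integer(k %||% motif$fragment_k %||%
                    .val_err("no fragment length given"))
  if (k > motif$length) .val_err("fragment length k exceeds motif length")
  if (k < 4L) warning("fragment length < 4 will match near-randomly")
  nfrag <- motif$length - k + 1L
  out <- lapply(seq_len(nfrag), function(f) {
    frag <- substr(motif$iupac, f, f + k - 1L)
    h <- scan_iupac(seq, motif_def(motif$name, iupac = frag,
                                   max_mismatch = motif$max_mismatch))
    if (nrow(h)) { h$fragment <- f; h$fragment_pattern <- frag }
    h
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (!length(out)) {
    e <- .empty_hits(); e$fragment <- integer(0); e$fragment_pattern <- character(0)
    return(e)
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$fragment), , drop = FALSE]
}

#' Scan a gene with a motif library
#'
#' Runs every library motif over the gene sequence (sense strand only, as all
#' the elements modeled here act on the pre-mRNA) and annotates each hit with
#' its enclosing feature role.
#'
#' @param gene A `gene_model`.
#' @param library Named list of `motif_def`s (default [motif_library()]).
#' @param max_mismatch Optional global mismatch override.
#' @return Combined hit table sorted by `(start, motif_name)`.
#' @export
scan_gene <- function(gene, library = motif_library(), max_mismatch = NULL) {
  hits <- lapply(library, function(m) {
    if (m$kind == "iupac") scan_iupac(gene$sequence, m, max_mismatch)
    else scan_pfm(gene$sequence, m)
  })
  hits <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_hits())
  hits <- hits[order(hits$start, hits$motif_name), , drop = FALSE]
  hits$feature_context <- vapply(seq_len(nrow(hits)), function(i)
    feature_context(gene, hits$start[i], hits$end[i]), "")
  rownames(hits) <- NULL
  hits
}
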