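# Pustell-style dot matrix: all window pairs between two sequences whose
# identity meets a stringency threshold. Diagonal runs reveal conserved
# blocks; vertical/horizontal breaks in the main diagonal reveal indels.

#' Compute a dot matrix between two sequences
#'
#' A point `(i, j)` (0-based window anchors) is present iff
#' `a[i, i+window)` and `b[j, j+window)` agree at `min_matches` or more
#' positions. `N` never matches. The sweep is organized per diagonal with
#' running window sums, so sequences of a few kilobases are fine.
#'
#' @param a,b DNA strings.
#' @param window Window length (default 8).
#' @param min_matches Stringency; must be `<= window` (default 7).
#' @return An object of class `dot_matrix`: `points` (data.frame `i`, `j`),
#'   `len_a`, `len_b`, `window`, `min_matches`.
#' @export
dot_matrix <- function(a, b, window = 8L, min_matches = 7L) {
  a <- .normalize_dna(a, "sequence a"); b <- .normalize_dna(b, "sequence b")
  window <- as.integer(window); min_matches <- as.integer(min_matches)
  if (min_matches > window) .val_err("min_matches must not exceed window")
  n <- nchar(a); m <- nchar(b)
  if (window > min(n, m)) .val_err("window longer than a sequence")
  A <- .encode_dna(a)
  B <- .encode_dna(b)
  B[B == 5L] <- 6L  # N in either sequence never matches
  pts <- vector("list", n + m)
  k <- 0L
  for (d in (1L - n):(m - 1L)) {
    i1 <- max(1L, 1L - d); i2 <- min(n, m - d)
    len <- i2 - i1 + 1L
    if (len < window) next
    eq <- A[i1:i2] == B[(i1:i2) + d]
    cs <- cumsum(c(0L, eq))
    wsum <- cs[(window + 1L):(len + 1L)] - cs[1:(len - window + 1L)]
    hit <- which(wsum >= min_matches)
    if (length(hit)) {
      i0 <- i1 + hit - 1L
      k <- k + 1L
      pts[[k]] <- cbind(i = i0 - 1L, j = i0 + d - 1L)
    }
  }
  pts <- if (k) as.data.frame(do.call(rbind, pts[seq_len(k)])) else
    data.frame(i = integer(0), j = integer(0))
  pts <- pts[order(pts$i, pts$j), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, len_a = n, len_b = m, window = window,
                 min_matches = min_matches), class = "dot_matrix")
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat(sprintf("<dot_matrix> %d x %d nt, window %d, stringency %d/%d: %d points\n",
              x$len_a, x$len_b, x$window, x$min_matches, x$window,
              nrow(x$points)))
  invisible(x)
}

#' Does the dot matrix contain the full main diagonal?
#'
#' @param dm A `dot_matrix` (typically of a self-comparison).
#' @return Logical.
#' @export
has_main_diagonal <- function(dm) {
  need <- 0:(min(dm$len_a, dm$len_b) - dm$window)
  diag_pts <- dm$points$i[dm$points$i == dm$points$j]
  all(need %in% diag_pts)
}

#' Write a dot matrix as sparse TSV
#'
#' @param dm A `dot_matrix`.
#' @param path Output path (columns `i`, `j`, 0-based anchors).
#' @return Invisibly, `path`.
#' @export
write_dot_matrix <- function(dm, path) {
  write.table(dm$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
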