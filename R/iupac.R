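# IUPAC degenerate nucleotide codes and low-level sequence encoding.

# The 15 standard degenerate DNA codes. U is accepted as an input alias for T
# (motifs in the splicing literature are often quoted as RNA) but is not itself
# a distinct code.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# reverse map: sorted base set -> smallest covering code
.IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.val_err <- function(msg, class = "traScan_validation_error") {
  stop(errorCondition(msg, class = c(class, "traScan_error")))
}

# uppercase, U -> T; error on anything outside A,C,G,T,N
.normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  if (length(bad) && nzchar(bad))
    .val_err(sprintf("invalid character '%s' in %s (allowed: A,C,G,T,N,U)", bad, what))
  x
}

# integer encoding A=1 C=2 G=3 T=4 N=5 (assumes normalized input)
.encode_dna <- function(x) {
  unname(.BASE_CODE[strsplit(x, "", fixed = TRUE)[[1]]])
}

.decode_dna <- function(code) paste(names(.BASE_CODE)[code], collapse = "")

# 0-based half-open substring
.subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

#' Parse a degenerate IUPAC pattern into per-position allowed-base sets
#'
#' @param pattern A non-empty character string of IUPAC nucleotide codes
#'   (the 15 standard codes; `U` is accepted as an alias for `T`).
#' @return A list with one element per pattern position, each a character
#'   vector of allowed bases (`N` expands to all four). The list has the same
#'   length as the pattern.
#' @examples
#' parse_iupac("DCADCTTA")[[1]]  # "A" "G" "T"
#' @export
parse_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    .val_err("pattern must be a single non-empty string")
  chars <- strsplit(toupper(gsub("U", "T", pattern, fixed = TRUE)), "",
                    fixed = TRUE)[[1]]
  ok <- chars %in% names(IUPAC_SETS)
  if (!all(ok))
    .val_err(sprintf("invalid IUPAC code '%s' at position %d",
                     chars[!ok][1], which(!ok)[1]))
  lapply(chars, function(ch) IUPAC_SETS[[ch]])
}

# 5 x L logical matrix: allowed[base_code, position]; an N in the *sequence*
# (row 5) never matches any motif position.
.iupac_allowed <- function(pattern) {
  sets <- parse_iupac(pattern)
  L <- length(sets)
  m <- matrix(FALSE, nrow = 5L, ncol = L)
  for (j in seq_len(L)) m[.BASE_CODE[sets[[j]]], j] <- TRUE
  m[5L, ] <- FALSE
  m
}

# smallest IUPAC code covering a set of concrete bases
.set_to_iupac <- function(bases) {
  if (!length(bases)) return("N")
  .IUPAC_FROM_SET[[paste(sort(unique(bases)), collapse = "")]]
}

#' Count positions of a word matching a (possibly degenerate) reference
#'
#' Positionwise comparison of a concrete DNA word `a` against a reference `b`
#' that may contain degenerate IUPAC codes, as used for "n/m match" statements
#' about candidate binding sites. An `N` in `a` matches nothing.
#'
#' @param a Concrete DNA string (A,C,G,T,N).
#' @param b Reference string, possibly degenerate IUPAC.
#' @return Integer count of positions where `a`'s base is within `b`'s
#'   allowed set.
#' @examples
#' match_count("TGAAGATT", "KGAAGATW")  # 8
#' @export
match_count <- function(a, b) {
  a <- .normalize_dna(a, "word")
  if (nchar(a) != nchar(b))
    .val_err("match_count requires equal-length strings")
  if (!nzchar(a)) return(0L)
  allowed <- .iupac_allowed(b)
  s <- .encode_dna(a)
  sum(allowed[cbind(s, seq_along(s))])
}
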