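# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (per-window loops, full DP tables) that
# share no code with the package internals.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

# naive all-windows degenerate scanner; N in the sequence never matches
oracle_scan <- function(seq, pattern, max_mismatch = 0L) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc); n <- length(sc)
  out <- list()
  if (n >= L) for (i in 1:(n - L + 1L)) {
    mm <- 0L
    for (j in 1:L)
      if (!(sc[i + j - 1L] %in% ORACLE_IUPAC[[pc[j]]])) mm <- mm + 1L
    if (mm <= max_mismatch)
      out[[length(out) + 1L]] <- c(start = i - 1L, mismatches = mm)
  }
  if (!length(out)) return(data.frame(start = integer(0),
                                      mismatches = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# all-pairs window checker for the dot matrix
oracle_dot_matrix <- function(a, b, window, min_matches) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  ac[ac == "N"] <- "!"; bc[bc == "N"] <- "?"
  pts <- list()
  for (i in 0:(length(ac) - window)) for (j in 0:(length(bc) - window)) {
    if (sum(ac[(i + 1):(i + window)] == bc[(j + 1):(j + window)]) >=
        min_matches)
      pts[[length(pts) + 1L]] <- c(i = i, j = j)
  }
  if (!length(pts)) return(data.frame(i = integer(0), j = integer(0)))
  as.data.frame(do.call(rbind, pts))
}

# Gotoh affine-gap global alignment, optimal score only
# (gap of length L costs gap_open + L * gap_extend)
oracle_gotoh_score <- function(a, b, match = 5, mismatch = -4,
                               gap_open = 10, gap_extend = 0.5) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (ac[i - 1] == bc[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                   X[i - 1, j] - gap_extend,
                   Y[i - 1, j] - gap_open - gap_extend)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                   Y[i, j - 1] - gap_extend,
                   X[i, j - 1] - gap_open - gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# toy sex-specific gene used across tests: exon1 carries an ATG-anchored
# frame, the male exon an in-frame TAA, the female CDS no stop at all
make_toy_gene <- function() {
  # exon1 0-21, intron 21-81 (male exon 30-60 inside), exon2 81-102
  exon1 <- "ATGGCTGCAGCTGCAGCATTG"                  # 21 nt, 7 codons
  # male transcript frame: 21 + r; male exon starts at intron offset 9
  intron_pre <- "GTAATTTTC"                         # 9 nt
  male_exon <- "CATTAACATCAACATAACATCAACATCAAG"     # 30 nt, TAA in frame
  intron_post <- paste0("GTAAGT", strrep("T", 9), "CAG")  # 18 nt... pad below
  intron_post <- paste0("GTAAGT", strrep("CT", 6), "CAG") # 21 nt
  exon2 <- "GTGAAGGTTCGCAGCTGCAGC"                  # 21 nt
  seq <- paste0(exon1, intron_pre, male_exon, intron_post, exon2)
  feats <- feature_table(
    role = c("exon", "female_intron_1", "male_exon", "exon"),
    start = c(0L, 21L, 30L, 81L),
    end = c(21L, 81L, 60L, 102L),
    rank = c(1L, NA, NA, 2L))
  gene_model("toy", seq, feats, species_tag = "toy")
}
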