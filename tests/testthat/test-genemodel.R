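test_that("TSV load builds a validated gene model and errors on bad input", {
  dir <- withr::local_tempdir()
  set.seed(11)
  seq <- rand_seq(60)
  fa <- file.path(dir, "toy.fasta")
  writeLines(c(">toy60", seq), fa)
  ann <- file.path(dir, "toy.tsv")
  df <- data.frame(gene_id = "toy60",
                   role = c("exon", "female_intron_1", "male_exon", "exon"),
                   start = c(0, 20, 25, 50), end = c(20, 50, 40, 60),
                   rank = c(1, NA, NA, 2))
  write.table(df, ann, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- load_gene(fa, ann)
  expect_s3_class(g, "gene_model")
  expect_equal(nrow(g$features), 4L)
  expect_equal(g$sequence, seq)

  # male exon running past the sequence end
  df_bad <- df; df_bad$end[3] <- 70
  write.table(df_bad, ann, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_gene(fa, ann), class = "traScan_validation_error")

  # duplicated male exon
  df_dup <- rbind(df, data.frame(gene_id = "toy60", role = "male_exon",
                                 start = 42, end = 48, rank = NA))
  write.table(df_dup, ann, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_gene(fa, ann), class = "traScan_validation_error")
})

test_that("GFF3 (1-based inclusive) and TSV loads agree; round-trips are exact", {
  dir <- withr::local_tempdir()
  set.seed(12)
  seq <- rand_seq(60)
  fa <- file.path(dir, "toy.fasta")
  writeLines(c(">toy60", seq), fa)
  tsv <- file.path(dir, "toy.tsv")
  write.table(data.frame(gene_id = "toy60",
                         role = c("exon", "female_intron_1", "male_exon", "exon"),
                         start = c(0, 20, 25, 50), end = c(20, 50, 40, 60),
                         rank = c(1, NA, NA, 2)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  # hand-written GFF3 for the same features: start+1, end unchanged
  gff <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3",
    "toy60\ttest\texon\t1\t20\t.\t+\t.\tID=e1;gene_id=toy60;rank=1",
    "toy60\ttest\tfemale_intron_1\t21\t50\t.\t+\t.\tID=i1;gene_id=toy60",
    "toy60\ttest\tmale_exon\t26\t40\t.\t+\t.\tID=me;gene_id=toy60",
    "toy60\ttest\texon\t51\t60\t.\t+\t.\tID=e2;gene_id=toy60;rank=2"), gff)
  g_tsv <- load_gene(fa, tsv)
  g_gff <- load_gene(fa, gff)
  expect_equal(g_gff$features[c("role", "start", "end", "rank")],
               g_tsv$features[c("role", "start", "end", "rank")])

  # write/load round trip, both formats
  for (fmt in c("tsv", "gff3")) {
    fa2 <- file.path(dir, paste0("rt.", fmt, ".fasta"))
    an2 <- file.path(dir, paste0("rt.", fmt, ".", fmt))
    write_gene(g_tsv, fa2, an2)
    g2 <- load_gene(fa2, an2)
    expect_identical(g2$sequence, g_tsv$sequence)
    expect_equal(g2$features[c("role", "start", "end", "rank")],
                 g_tsv$features[c("role", "start", "end", "rank")])
  }
})

test_that("isoform construction splices the documented architecture", {
  g <- make_toy_gene()
  iso <- build_isoforms(g)
  # female = exons only; male = exon 1 extended through the male donor
  expect_identical(iso$female$spliced_seq,
                   paste0(substr(g$sequence, 1, 21),
                          substr(g$sequence, 82, 102)))
  expect_identical(iso$male$spliced_seq,
                   paste0(substr(g$sequence, 1, 60),
                          substr(g$sequence, 82, 102)))
  expect_gt(iso$male$donor_used, iso$female$donor_used)
  # exon 1 is a shared prefix of both isoforms
  expect_identical(substr(iso$male$spliced_seq, 1, 21),
                   substr(iso$female$spliced_seq, 1, 21))
  # planted TAA is in frame in the male isoform only
  expect_true(length(iso$male$stop_positions_in_frame) >= 1)
  expect_length(iso$female$stop_positions_in_frame, 0)
  expect_false(has_premature_stop(iso$female))
  expect_true(has_premature_stop(iso$male))

  # degenerate male exon (zero length) is a model error
  f_bad <- g$features
  f_bad$end[f_bad$role == "male_exon"] <- f_bad$start[f_bad$role == "male_exon"]
  expect_error(gene_model("bad", g$sequence, f_bad),
               class = "traScan_validation_error")
})

test_that("feature geometry is additive over the spanned region", {
  sim <- generate_gene(synth_config(seed = 5))
  g <- sim$gene
  ex <- gene_feature(g, "exon")
  fi <- gene_feature(g, "female_intron_1")
  intr <- gene_feature(g, "intron")
  total <- sum(ex$end - ex$start) + (fi$end - fi$start) +
    sum(intr$end - intr$start)
  expect_equal(total, nchar(g$sequence))
})

test_that("translation follows the standard code with stop and edge handling", {
  expect_identical(translate_cds("ATGTAA"), "M*")
  expect_identical(translate_cds("ATGGGTGAA"), "MGE")
  expect_warning(p <- translate_cds("ATGGG"), "partial codon")
  expect_identical(p, "M")
  expect_identical(translate_cds("ATGNNNTGA"), "MX*")
  expect_error(translate_cds("ATGQQQ"), class = "traScan_validation_error")
})

test_that("BED export writes one interval per feature", {
  g <- make_toy_gene()
  bed <- withr::local_tempfile(fileext = ".bed")
  export_features_bed(g, bed)
  lines <- readLines(bed)
  expect_length(lines, nrow(g$features))
  f1 <- strsplit(lines[1], "\t")[[1]]
  expect_identical(f1[2], "0")   # BED is 0-based half-open
})
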