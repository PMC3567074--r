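test_that("generation is deterministic and self-validating", {
  cfg <- synth_config(seed = 13)
  a <- generate_gene(cfg)
  b <- generate_gene(cfg)
  expect_identical(a$gene$sequence, b$gene$sequence)
  expect_identical(a$gene$features, b$gene$features)
  expect_identical(a$truth$motifs, b$truth$motifs)
  expect_true(validate_gene_model(a$gene))
})

test_that("all planted TRA/TRA2 sites are recovered exactly at generation", {
  for (n_sites in c(4L, 5L)) {
    sim <- generate_gene(synth_config(seed = 6, n_intron_sites = n_sites))
    hits <- scan_iupac(sim$gene$sequence, motif_library()$tra_tra2_core)
    truth <- sim$truth$motifs
    cores <- truth[grepl("^intron_site_[0-9]+$|^male_exon_site$", truth$name), ]
    expect_equal(nrow(cores), n_sites + 1L)
    expect_true(all(cores$start %in% hits$start))   # 100% recall
    expect_equal(nrow(hits), n_sites + 1L)          # and no spurious hits here
  }
})

test_that("the planted regulatory architecture is where the ground truth says", {
  sim <- generate_gene(synth_config(seed = 10))
  g <- sim$gene
  tr <- sim$truth
  m <- tr$motifs
  get <- function(nm) m[m$name == nm, ]
  # RBP1 type A site ends 100 bp upstream of the acceptor, half-site follows
  rb <- get("rbp1_type_a")
  expect_equal(tr$acceptor - rb$end, 100L)
  expect_identical(substr(g$sequence, rb$start + 1, rb$end),
                   regmatches(substr(g$sequence, rb$start + 1, rb$end),
                              regexpr("[AGT]CA[AGT]CTTA",
                                      substr(g$sequence, rb$start + 1, rb$end))))
  hs <- get("rbp1_half_site")
  expect_equal(hs$start, rb$end)
  # conserved elements flank the most 5' intronic site
  s1 <- get("intron_site_1")
  expect_lt(get("unr_like")$end, s1$start)
  expect_gt(get("nasonia_like")$start, s1$end)
  # male exon in-frame stop and site near its 3' end
  me <- gene_feature(g, "male_exon")
  ms <- get("male_exon_site")
  expect_true(ms$start > me$start && ms$end <= me$end - 25)
})

test_that("isoforms of the generated gene encode the sex difference", {
  sim <- generate_gene(synth_config(seed = 3))
  iso <- build_isoforms(sim$gene)
  expect_true(has_premature_stop(iso$male))
  expect_false(has_premature_stop(iso$female))
  prot <- translate_cds(iso$female$spliced_seq)
  expect_true(endsWith(prot, "*"))
  expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
})

test_that("zero divergence yields an identical ortholog", {
  cfg <- synth_config(seed = 19, divergence = 0, indel_rate = 0)
  sim <- generate_gene(cfg)
  div <- diverge_gene(sim, cfg)
  expect_identical(div$gene$sequence, sim$gene$sequence)
  expect_equal(global_align(feature_seq(sim$gene, "female_intron_1"),
                            feature_seq(div$gene, "female_intron_1"))$pct_identity,
               100)
})

test_that("perfectly conserved motifs survive heavy background divergence", {
  cfg <- synth_config(seed = 23, divergence = 0.3,
                      motif_conservation_factor = 0)
  sim <- generate_gene(cfg)
  div <- diverge_gene(sim, cfg)
  hits <- scan_iupac(div$gene$sequence, motif_library()$tra_tra2_core)
  cores <- div$truth$motifs[grepl("^intron_site_[0-9]+$|^male_exon_site$",
                                  div$truth$motifs$name), ]
  recall <- mean(cores$start %in% hits$start)
  expect_equal(recall, 1)
  # lifted coordinates still carry the planted words
  for (r in seq_len(nrow(cores)))
    expect_equal(nrow(scan_iupac(substr(div$gene$sequence,
                                        cores$start[r] + 1, cores$end[r]),
                                 motif_library()$tra_tra2_core)), 1L)
})

test_that("substitution-only divergence recovers the configured identity", {
  set.seed(47)
  x <- rand_seq(10000, gc = 0.35)
  for (d in c(0.1, 0.2)) {
    y <- mutate_sequence(x, sub_prob = d)$sequence
    id <- global_align(x, y)$pct_identity
    # 99% binomial interval around 100 * (1 - d), n = 10000
    half <- 2.576 * sqrt(d * (1 - d) / 10000) * 100
    expect_true(abs(id - 100 * (1 - d)) <= half + 1e-9)
  }
})

test_that("indel bookkeeping lifts coordinates through the edit trace", {
  set.seed(53)
  x <- rand_seq(2000)
  protected <- rep(FALSE, 2000)
  protected[501:520] <- TRUE
  mut <- mutate_sequence(x, sub_prob = 0, indel_rate = 0.01,
                         indel_forbidden = protected)
  # the protected interval survives untouched at its lifted position
  lifted <- mut$lift[501]
  expect_identical(substr(mut$sequence, lifted + 1, lifted + 20),
                   substr(x, 501, 520))
  expect_equal(nchar(mut$sequence), mut$new_length)
})

test_that("the emitted gene pair round-trips through FASTA + TSV + JSON", {
  dir <- withr::local_tempdir()
  sim <- generate_gene(synth_config(seed = 29))
  write_synth_gene(sim, dir)
  id <- sim$gene$gene_id
  g2 <- load_gene(file.path(dir, paste0(id, ".fasta")),
                  file.path(dir, paste0(id, ".tsv")))
  expect_identical(g2$sequence, sim$gene$sequence)
  truth <- jsonlite::read_json(file.path(dir, paste0(id, ".truth.json")),
                               simplifyVector = TRUE)
  expect_equal(truth$female_donor, sim$truth$female_donor)
})

test_that("infeasible packing is rejected with a clear error", {
  expect_error(generate_gene(synth_config(seed = 1, intron1_len = 700)),
               class = "traScan_validation_error")
})
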