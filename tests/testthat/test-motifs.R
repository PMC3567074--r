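test_that("IUPAC parsing expands codes positionwise and names bad positions", {
  p <- parse_iupac("DCADCTTA")
  expect_equal(p[[1]], c("A", "G", "T"))
  expect_equal(p[[2]], "C")
  expect_equal(parse_iupac("WMWW"),
               list(c("A", "T"), c("A", "C"), c("A", "T"), c("A", "T")))
  expect_error(parse_iupac("DCAXCTTA"), "position 4")
  expect_equal(parse_iupac("UU"), list("T", "T"))  # RNA alias
})

test_that("degenerate scanning reports planted, overlapping and mismatched hits", {
  h <- scan_iupac("GGTACCAGG", motif_def("flank", iupac = "TACYA"))
  expect_equal(h$start, 2L)
  expect_equal(h$matched_word, "TACCA")

  core <- motif_library()$tra_tra2_core
  h2 <- scan_iupac("ACAACAATCAACA", core)
  expect_equal(h2$start, 0L)
  expect_equal(h2$mismatches, 0L)

  # two overlapping core matches, offset 7 (the smallest feasible overlap)
  pair <- "ACAACAATCAACAATCAACA"
  h3 <- scan_iupac(pair, core)
  expect_equal(h3$start, c(0L, 7L))
  orc <- oracle_scan(pair, core$iupac)
  expect_equal(h3$start, orc$start)

  # motif longer than the sequence is an empty result, not an error
  expect_equal(nrow(scan_iupac("ACGT", core)), 0L)

  # N in the sequence counts as a mismatch
  hN <- scan_iupac("ACANCAATCAACA", core, max_mismatch = 1)
  expect_equal(hN$mismatches, 1L)
  expect_equal(nrow(scan_iupac("ACANCAATCAACA", core, max_mismatch = 0)), 0L)
})

test_that("degenerate scanning equals the brute-force oracle with overlap and mismatches", {
  set.seed(42)
  motifs <- c("WMWWCAATCAACA", "DCADCTTA", "TACYA", "KGAAGATW", "TTTTT")
  for (rep in 1:30) {
    seq <- rand_seq(sample(50:200, 1), gc = runif(1, 0.25, 0.6))
    for (m in motifs) for (mm in 0:1) {
      got <- scan_iupac(seq, motif_def(m, iupac = m), max_mismatch = mm)
      want <- oracle_scan(seq, m, mm)
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("mismatch allowance is monotone: hits at m are a subset of hits at m+1", {
  set.seed(7)
  core <- motif_library()$tra_tra2_core
  for (rep in 1:10) {
    seq <- rand_seq(300, gc = 0.35)
    h0 <- scan_iupac(seq, core, max_mismatch = 0)$start
    h1 <- scan_iupac(seq, core, max_mismatch = 1)$start
    h2 <- scan_iupac(seq, core, max_mismatch = 2)$start
    expect_true(all(h0 %in% h1))
    expect_true(all(h1 %in% h2))
  }
})

test_that("PFM scanning assigns exact product probabilities", {
  m <- motif_from_sites("ac", c("AC", "AC"))
  h <- scan_pfm("GACG", m)
  expect_equal(h$start, 1L)
  expect_equal(h$probability, 1.0)

  m2 <- motif_from_sites("ac_gc", c("AC", "GC"))
  h2 <- scan_pfm("AC", m2)
  expect_equal(h2$probability, 0.5)

  # single-site PFM degenerates to exact string search with probability 1
  m3 <- motif_from_sites("one", "ACGT")
  h3 <- scan_pfm("TTACGTTTACGT", m3)
  expect_equal(h3$start, c(2L, 8L))
  expect_equal(h3$probability, c(1, 1))

  expect_error(scan_pfm("ACGT", motif_def("z", pfm = matrix(0, 4, 2))),
               class = "traScan_validation_error")
})

test_that("PFM hit probabilities match exhaustive window enumeration", {
  set.seed(99)
  sites <- vapply(1:6, function(i) rand_seq(8), "")
  m <- motif_from_sites("rand8", sites)
  seq <- rand_seq(1000, gc = 0.45)
  got <- scan_pfm(seq, m)
  # oracle: evaluate every window against the PFM directly
  p <- sweep(m$pfm, 2, colSums(m$pfm), "/")
  exp_hits <- list()
  for (i in 0:(nchar(seq) - 8)) {
    w <- strsplit(substr(seq, i + 1, i + 8), "")[[1]]
    pr <- prod(p[cbind(match(w, c("A", "C", "G", "T")), 1:8)])
    if (pr > 0) exp_hits[[length(exp_hits) + 1]] <- c(i, pr)
  }
  exp_hits <- do.call(rbind, exp_hits)
  if (is.null(exp_hits)) {
    expect_equal(nrow(got), 0L)
  } else {
    expect_equal(got$start, as.integer(exp_hits[, 1]))
    expect_equal(got$probability, exp_hits[, 2])
  }
  # every probability is bounded by the per-column maximum product
  expect_true(all(got$probability <= prod(apply(p, 2, max)) + 1e-12))
})

test_that("fragment scanning searches every overlapping k-mer of the motif", {
  seq <- paste0("GGG", "ATGAATTT", "GGGGG")
  h <- fragment_scan(seq, motif_def("unr", iupac = "ATGAATTT"), k = 8)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)
  expect_equal(h$fragment, 1L)

  # 9-mer motif: only its first 8-mer fragment is present
  h2 <- fragment_scan(seq, motif_def("unr9", iupac = "ATGAATTTA"), k = 8)
  expect_equal(h2$fragment, 1L)
  expect_equal(h2$start, 3L)

  # k = motif length reduces to plain degenerate scanning
  core <- motif_library()$tra_tra2_core
  seq2 <- rand_seq(500, gc = 0.3)
  h3 <- fragment_scan(seq2, core, k = core$length)
  expect_equal(h3$start, scan_iupac(seq2, core)$start)

  expect_warning(fragment_scan("ACGTACGT", motif_def("s", iupac = "ACGT"),
                               k = 3), "near-randomly")
})

test_that("positionwise match counting handles degenerate references", {
  expect_equal(match_count("AATTT", "AATTA"), 4L)
  expect_equal(match_count("TGAAGATT", "KGAAGATW"), 8L)
  expect_equal(match_count("", ""), 0L)
  expect_equal(match_count("NNNN", "ACGT"), 0L)  # N never matches
  set.seed(3)
  for (rep in 1:20) {  # positionwise oracle
    a <- rand_seq(12); b <- "NRYSWKMBDHVNACGT"
    b <- paste(sample(strsplit(b, "")[[1]], 12), collapse = "")
    want <- sum(mapply(function(x, y) x %in% ORACLE_IUPAC[[y]],
                       strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
    expect_equal(match_count(a, b), want)
  }
})

test_that("motif libraries serialize losslessly through the YAML config", {
  lib <- motif_library()
  lib$custom_pfm <- motif_from_sites("custom_pfm", c("ACGTA", "ACGTT", "AGGTA"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_motif_library(lib, path)
  lib2 <- read_motif_library(path)
  expect_equal(names(lib2), names(lib))
  for (nm in names(lib)) {
    expect_equal(lib2[[nm]]$kind, lib[[nm]]$kind)
    expect_equal(lib2[[nm]]$iupac, lib[[nm]]$iupac)
    expect_equal(lib2[[nm]]$max_mismatch, lib[[nm]]$max_mismatch)
    if (lib[[nm]]$kind == "pfm")
      expect_equal(unname(lib2[[nm]]$pfm), unname(lib[[nm]]$pfm))
  }
})

test_that("gene scanning annotates hits with their feature context", {
  sim <- generate_gene(synth_config(seed = 2))
  hits <- scan_gene(sim$gene, motif_library()["tra_tra2_core"])
  expect_true(all(hits$feature_context %in%
                    c("male_exon", "female_intron_1")))
  expect_equal(sum(hits$feature_context == "male_exon"), 1L)
})
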