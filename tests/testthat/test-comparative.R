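test_that("global alignment identity matches hand-checked small cases", {
  expect_equal(global_align("ACGT", "ACGT")$pct_identity, 100)
  expect_equal(global_align("ACGT", "AGGT")$pct_identity, 75)
  # one gap: 3 matches over 4 alignment columns
  expect_equal(global_align("AAAA", "AAA")$pct_identity, 75)
  expect_error(global_align("", "ACGT"), class = "traScan_validation_error")
  expect_error(global_align("ACQT", "ACGT"), class = "traScan_validation_error")
})

test_that("alignment scores are optimal against an affine-gap DP oracle", {
  set.seed(17)
  for (rep in 1:25) {
    a <- rand_seq(sample(3:9, 1)); b <- rand_seq(sample(3:9, 1))
    got <- global_align(a, b)$score
    want <- oracle_gotoh_score(a, b)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("identity is symmetric", {
  set.seed(23)
  for (rep in 1:10) {
    a <- rand_seq(80); b <- rand_seq(70)
    expect_equal(global_align(a, b)$pct_identity,
                 global_align(b, a)$pct_identity)
  }
})

test_that("protein similarity bounds identity and uses conservative groups", {
  cmp <- global_align("MSRSKD", "MTRSRE", mode = "protein")
  expect_true(cmp$pct_identity <= cmp$pct_similarity)
  expect_true(cmp$pct_similarity <= 100)
  # S/T and D/E are strong-group pairs, K/R too: similarity counts them
  expect_gt(cmp$pct_similarity, cmp$pct_identity)
})

test_that("dot matrix equals the all-pairs window checker and shows structure", {
  set.seed(29)
  a <- rand_seq(200)
  dm_self <- dot_matrix(a, a, window = 8, min_matches = 8)
  expect_true(has_main_diagonal(dm_self))

  # equality with the brute-force checker on small inputs
  for (rep in 1:3) {
    x <- rand_seq(120, gc = 0.4); y <- rand_seq(100, gc = 0.4)
    got <- dot_matrix(x, y, window = 6, min_matches = 5)$points
    want <- oracle_dot_matrix(x, y, 6, 5)
    want <- want[order(want$i, want$j), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }

  # an insertion shifts the matched diagonal
  ins <- paste0(substr(a, 1, 100), rand_seq(50), substr(a, 101, 200))
  dm <- dot_matrix(a, ins, window = 10, min_matches = 10)
  d_off <- dm$points$j - dm$points$i
  expect_true(any(d_off == 0 & dm$points$i < 90))
  expect_true(any(d_off == 50 & dm$points$i > 110))
  expect_error(dot_matrix(a, a, window = 8, min_matches = 9),
               class = "traScan_validation_error")
})

test_that("unrelated sequences give near-empty dot matrices at full stringency", {
  set.seed(37)
  counts <- vapply(1:5, function(i) {
    nrow(dot_matrix(rand_seq(200), rand_seq(200), 10, 10)$points)
  }, numeric(1))
  # expected points ~ 191^2 / 4^10 ~ 0.03 per pair
  expect_true(mean(counts) < 1)
})

test_that("insertion calls recover a planted gap with host coordinates", {
  set.seed(41)
  x <- rand_seq(400)
  a <- paste0(substr(x, 1, 100), substr(x, 221, 400))  # 120 nt removed
  cmp <- global_align(a, x, seq_ids = c("short", "long"))
  calls <- find_insertions(cmp, min_len = 100)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$which_seq, "b")
  expect_equal(calls$length, 120L)
  expect_true(abs(calls$offset - 100) <= 5)
  expect_equal(nrow(find_insertions(cmp, min_len = 200)), 0L)
})

test_that("conserved blocks span identical sequences and vanish in noise", {
  set.seed(43)
  a <- rand_seq(300)
  cmp <- global_align(a, a)
  bl <- conserved_blocks(cmp, min_block_len = 30, min_block_identity = 0.9)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$start_a, 0L)
  expect_equal(bl$end_a, 300L)
  expect_equal(bl$block_identity, 1)

  # ~60% identical pair at a 90% threshold: no blocks
  empty <- vapply(1:5, function(i) {
    x <- rand_seq(500)
    y <- mutate_sequence(x, sub_prob = 0.4)$sequence
    nrow(conserved_blocks(global_align(x, y), 30, 0.9))
  }, numeric(1))
  expect_true(all(empty == 0))
})

test_that("cluster calling groups hits by single linkage with gap ceiling", {
  hits <- data.frame(motif_name = "m", start = c(100L, 160L, 230L, 300L),
                     end = c(113L, 173L, 243L, 313L))
  cl <- call_clusters(hits, max_gap = 150)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_sites, 4L)
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 313L)

  hits2 <- data.frame(motif_name = "m", start = c(100L, 400L),
                      end = c(113L, 413L))
  cl2 <- call_clusters(hits2, max_gap = 150)
  expect_equal(cl2$n_sites, c(1L, 1L))
})

test_that("the generated gene carries one intronic cluster plus a male-exon singleton", {
  for (seed in c(1, 9)) {
    sim <- generate_gene(synth_config(seed = seed))
    hits <- scan_gene(sim$gene, motif_library()["tra_tra2_core"])
    cl <- call_clusters(hits, max_gap = 150, gene = sim$gene)
    intronic <- cl[cl$context == "female_intron_1", ]
    mex <- cl[cl$context == "male_exon", ]
    expect_equal(nrow(intronic), 1L)
    expect_true(intronic$n_sites %in% 4:5)
    expect_equal(nrow(mex), 1L)
    expect_equal(mex$n_sites, 1L)
    expect_false(is.na(intronic$gap_to_acceptor))
    # cores end 250 nt before the acceptor, plus the 5-6 nt flank when planted
    expect_true(intronic$gap_to_acceptor >= 250L &&
                  intronic$gap_to_acceptor <= 256L)
  }
})
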