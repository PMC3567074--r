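# Synthetic tra-like genes with planted regulatory architecture, and a
# substitution+indel divergence process that conserves the planted elements.
#
# The generator emulates the blowfly tra architecture: four coding exons, one
# male-specific exon inside a large regulated first intron, the invariant
# female donor context TG/GTAATTTT, a consensus-matching male donor AG/GTAAGT,
# the invariant acceptor-adjacent exon start GTGAAGGTTC, one exonic TRA/TRA2
# site near the male exon's 3' end, a 3'-clustered run of intronic TRA/TRA2
# sites with 40-120 nt spacing (most followed by the TACC/TA flank), the
# conserved UNR-like and Nasonia-like elements flanking the most 5' site, an
# RBP1 type A site + TRA/TRA2 half-site ~100 bp upstream of the acceptor,
# T-rich runs, and in-frame stop codons in the male exon.

TRA_CORE_SETS <- list(c("A", "T"), c("A", "C"), c("A", "T"), c("A", "T"),
                      "C", "A", "A", "T", "C", "A", "A", "C", "A")

#' Configuration for the synthetic tra-like gene generator
#'
#' Defaults reproduce a scaled-down blowfly-like architecture: AT-rich
#' background (GC 0.35), a 2.5 kb regulated intron whose male exon ends 311 nt
#' downstream of the female donor, four intronic TRA/TRA2 sites clustered
#' toward the intron 3' end, and an ortholog divergence of 0.2 substitutions
#' per site with tenfold conservation inside planted motifs.
#'
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param exon_lengths Lengths of the four coding exons (sum must be a
#'   multiple of 3; exon 1 a multiple of 3 keeps the planted junction codons
#'   stop-free by construction).
#' @param male_exon_len,male_exon_offset Male exon length and its offset from
#'   the intron start.
#' @param intron1_len Regulated intron length.
#' @param intron_lengths Lengths of the two short downstream introns.
#' @param n_intron_sites Number of intronic TRA/TRA2 sites (4 or 5; with 5,
#'   the most 5' "site" is a pair of overlapping core matches at offset 7).
#' @param flank_prob Probability that an intronic site is followed by the
#'   TAC(C/T)A flank (0-1 nt spacer drawn at random).
#' @param rbp1_offset_from_acceptor Distance from the RBP1 site's 3' end to
#'   the splice acceptor (default 100).
#' @param gc_content Background GC fraction.
#' @param divergence Ortholog per-site substitution probability `d`.
#' @param indel_rate Per-site indel initiation probability.
#' @param mean_indel_len Mean geometric indel length.
#' @param motif_conservation_factor Multiplier on `d` inside planted motifs
#'   (0 = perfectly conserved).
#' @param insertion_len Optional structural-variant insertion (nt) placed
#'   between the TRA/TRA2 cluster and the acceptor in the ortholog
#'   (0 = none; ~1100 mimics the large intron insertion seen in one species).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, exon_lengths = c(198L, 150L, 162L, 246L),
                         male_exon_len = 231L, male_exon_offset = 80L,
                         intron1_len = 2500L, intron_lengths = c(72L, 69L),
                         n_intron_sites = 4L, flank_prob = 0.75,
                         rbp1_offset_from_acceptor = 100L,
                         gc_content = 0.35, divergence = 0.2,
                         indel_rate = 0.005, mean_indel_len = 3,
                         motif_conservation_factor = 0.1,
                         insertion_len = 0L) {
  cfg <- list(seed = as.integer(seed), exon_lengths = as.integer(exon_lengths),
              male_exon_len = as.integer(male_exon_len),
              male_exon_offset = as.integer(male_exon_offset),
              intron1_len = as.integer(intron1_len),
              intron_lengths = as.integer(intron_lengths),
              n_intron_sites = as.integer(n_intron_sites),
              flank_prob = flank_prob,
              rbp1_offset_from_acceptor = as.integer(rbp1_offset_from_acceptor),
              gc_content = gc_content, divergence = divergence,
              indel_rate = indel_rate, mean_indel_len = mean_indel_len,
              motif_conservation_factor = motif_conservation_factor,
              insertion_len = as.integer(insertion_len))
  if (length(cfg$exon_lengths) < 2L || any(cfg$exon_lengths <= 0L))
    .val_err("exon_lengths must be positive")
  if (sum(cfg$exon_lengths) %% 3L != 0L)
    .val_err("total exon length must be a multiple of 3")
  if (cfg$male_exon_len <= 60L) .val_err("male exon too short to host motifs")
  if (!cfg$n_intron_sites %in% c(4L, 5L))
    .val_err("n_intron_sites must be 4 or 5")
  probs <- c(cfg$flank_prob, cfg$gc_content, cfg$divergence,
             cfg$motif_conservation_factor)
  if (any(probs < 0) || any(probs > 1) || cfg$divergence >= 1)
    .val_err("probabilities must lie in [0, 1] (divergence < 1)")
  structure(cfg, class = "synth_config")
}

.rand_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# concrete realization of the degenerate TRA/TRA2 core
.realize_core <- function() {
  paste(vapply(TRA_CORE_SETS, function(s)
    if (length(s) == 1L) s else sample(s, 1L), ""), collapse = "")
}

# 20-nt word matching the core at offsets 0 and 7 (smallest feasible overlap)
.overlapping_core_pair <- function() {
  pre <- c(sample(c("A", "T"), 1), sample(c("A", "C"), 1),
           sample(c("A", "T"), 1), sample(c("A", "T"), 1), "C", "A", "A")
  paste(c(pre, "T", "C", "A", "A", "C", "A",
          "A", "T", "C", "A", "A", "C", "A"), collapse = "")
}

.tacca_flank <- function() paste0("TAC", sample(c("C", "T"), 1L), "A")

# overwrite `piece` into `chars` (a char vector) at 0-based offset
.plant <- function(chars, offset, piece) {
  p <- strsplit(piece, "", fixed = TRUE)[[1]]
  chars[(offset + 1L):(offset + length(p))] <- p
  chars
}

#' Generate a synthetic tra-like gene with ground truth
#'
#' Emits an iid background sequence at the configured GC content and plants
#' the full regulatory architecture (see [synth_config()]). Identical
#' configurations produce bit-identical output.
#'
#' @param cfg A `synth_config`.
#' @return A list with `gene` (a validated `gene_model`) and `truth`, where
#'   `truth$motifs` is a data.frame of planted-element coordinates (0-based
#'   half-open, genomic) and `truth` also records `female_donor`,
#'   `male_donor`, `acceptor` junction offsets and the configuration.
#' @export
generate_gene <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, .generate_gene_impl(cfg))
}

.generate_gene_impl <- function(cfg) {
  gc <- cfg$gc_content
  e1 <- cfg$exon_lengths[1L]
  cds_len <- sum(cfg$exon_lengths)
  I <- cfg$intron1_len
  off <- cfg$male_exon_offset
  mex <- cfg$male_exon_len

  ## female CDS: background, then start/terminal codons and the invariant
  ## junction sequences; internal in-frame stops repaired afterwards
  cds <- strsplit(.rand_dna(cds_len, gc), "", fixed = TRUE)[[1]]
  cds <- .plant(cds, 0L, "ATG")
  cds <- .plant(cds, e1 - 2L, "TG")             # female donor exonic context
  cds <- .plant(cds, e1, "GTGAAGGTTC")          # invariant exon 2 start
  cds <- .plant(cds, cds_len - 3L, "TAA")       # terminal stop
  fixed_pos <- c(1:3, (e1 - 1L):(e1 + 10L), (cds_len - 2L):cds_len)
  repeat {
    starts <- seq(1L, cds_len - 5L, by = 3L)    # internal codons only
    codons <- vapply(starts, function(s)
      paste(cds[s:(s + 2L)], collapse = ""), "")
    bad <- starts[codons %in% .STOP_CODONS]
    bad <- bad[!(bad %in% fixed_pos | (bad + 2L) %in% fixed_pos)]
    if (!length(bad)) break
    for (s in bad)                               # mutate wobble position
      cds[s + 2L] <- if (cds[s + 1L] == "A") sample(c("C", "T"), 1L) else "T"
  }
  exon_seq <- character(length(cfg$exon_lengths))
  pos <- 0L
  for (i in seq_along(cfg$exon_lengths)) {
    exon_seq[i] <- paste(cds[(pos + 1L):(pos + cfg$exon_lengths[i])],
                         collapse = "")
    pos <- pos + cfg$exon_lengths[i]
  }

  ## regulated intron with planted elements (coordinates relative to intron)
  intron <- strsplit(.rand_dna(I, gc), "", fixed = TRUE)[[1]]
  plan <- list()
  add <- function(name, offset, piece) {
    plan[[length(plan) + 1L]] <<- list(name = name, offset = as.integer(offset),
                                       piece = piece)
  }
  add("female_donor_site", 0L, "GTAATTTT")
  add("t_rich_male_exon", off + 40L, "TTTTTT")
  # in-frame stop in the male exon (frame anchored at the male transcript)
  stop_rel <- off + 15L
  stop_rel <- stop_rel + (3L - (e1 + stop_rel) %% 3L) %% 3L
  add("male_exon_stop", stop_rel, "TAA")
  add("male_exon_site", off + mex - 45L, .realize_core())
  add("male_exon_flank", off + mex - 32L, .tacca_flank())
  add("male_donor_site", off + mex - 2L, paste0("AGGTAAGT"))
  add("t_rich_intron", off + mex + 40L, "TTTTTT")

  # TRA/TRA2 cluster placed so its last site ends 250 nt before the acceptor
  n_sites <- cfg$n_intron_sites
  overlap5 <- n_sites == 5L
  n_units <- if (overlap5) n_sites - 1L else n_sites  # planted words
  widths <- integer(n_units)
  flanks <- character(n_units)
  spacers <- integer(n_units)
  words <- character(n_units)
  for (k in seq_len(n_units)) {
    words[k] <- if (overlap5 && k == 1L) .overlapping_core_pair() else
      .realize_core()
    has_flank <- runif(1L) < cfg$flank_prob
    flanks[k] <- if (has_flank) .tacca_flank() else ""
    spacers[k] <- if (has_flank) sample(0:1, 1L) else 0L
    widths[k] <- nchar(words[k]) + spacers[k] + nchar(flanks[k])
  }
  gaps <- sample(40:120, n_units - 1L, replace = TRUE)
  cluster_end <- I - 250L
  starts_rel <- cluster_end - rev(cumsum(rev(widths + c(gaps, 0L))))[1L] +
    cumsum(c(0L, widths[-n_units] + gaps))
  site_id <- 0L
  for (k in seq_len(n_units)) {
    site_id <- site_id + 1L
    if (overlap5 && k == 1L) {
      add("intron_site_pair", starts_rel[k], words[k])  # expanded below
      site_id <- site_id + 1L
    } else {
      add(sprintf("intron_site_%d", site_id), starts_rel[k], words[k])
    }
    if (nzchar(flanks[k]))
      add(sprintf("intron_site_%d_flank", site_id),
          starts_rel[k] + nchar(words[k]) + spacers[k], flanks[k])
  }
  add("unr_like", starts_rel[1L] - 30L, "ATGAATTT")
  add("nasonia_like", starts_rel[1L] + widths[1L] + 15L, "TGAAGATT")
  rbp1 <- paste0(sample(c("A", "G", "T"), 1L), "CA",
                 sample(c("A", "G", "T"), 1L), "CTTA")
  add("rbp1_type_a", I - cfg$rbp1_offset_from_acceptor - 8L, rbp1)
  add("rbp1_half_site", I - cfg$rbp1_offset_from_acceptor, "TCAACATACCA")
  add("acceptor_site", I - 14L, "TCTTTTTTTTTCAG")

  # feasibility: planted pieces must fit and not collide (overlap pair aside)
  ends <- vapply(plan, function(p) p$offset + nchar(p$piece), 1L)
  offs <- vapply(plan, function(p) p$offset, 1L)
  ord <- order(offs)
  if (any(offs < 0L) || any(ends > I) ||
      any(offs[ord][-1L] < ends[ord][-length(ord)]) ||
      starts_rel[1L] - 40L <= off + mex + 46L)
    .val_err("infeasible packing: planted elements collide; enlarge the intron")
  for (p in plan) intron <- .plant(intron, p$offset, p$piece)
  intron_seq <- paste(intron, collapse = "")

  ## short downstream introns
  mk_intron <- function(n) {
    x <- strsplit(.rand_dna(n, gc), "", fixed = TRUE)[[1]]
    x <- .plant(x, 0L, "GTAAGT")
    x <- .plant(x, n - 6L, "TTTCAG")
    paste(x, collapse = "")
  }
  i2 <- mk_intron(cfg$intron_lengths[1L])
  i3 <- mk_intron(cfg$intron_lengths[2L])

  ## assemble genome and features
  segs <- c(exon_seq[1L], intron_seq, exon_seq[2L], i2, exon_seq[3L], i3,
            exon_seq[4L])
  seq <- paste(segs, collapse = "")
  seg_start <- cumsum(c(0L, nchar(segs)))
  feats <- feature_table(
    role = c("exon", "female_intron_1", "male_exon", "exon", "intron",
             "exon", "intron", "exon"),
    start = c(seg_start[1L], seg_start[2L], seg_start[2L] + off, seg_start[3L],
              seg_start[4L], seg_start[5L], seg_start[6L], seg_start[7L]),
    end = c(seg_start[2L], seg_start[3L], seg_start[2L] + off + mex,
            seg_start[4L], seg_start[5L], seg_start[6L], seg_start[7L],
            seg_start[8L]),
    rank = c(1L, NA, NA, 2L, 2L, 3L, 3L, 4L))
  gene <- gene_model(sprintf("synth_tra_seed%d", cfg$seed), seq, feats,
                     species_tag = "synthetic")

  g0 <- seg_start[2L]  # intron genomic start
  motifs <- do.call(rbind, lapply(plan, function(p) {
    if (p$name == "intron_site_pair")  # two overlapping core matches
      return(data.frame(name = c("intron_site_1", "intron_site_2"),
                        start = g0 + p$offset + c(0L, 7L),
                        end = g0 + p$offset + c(13L, 20L),
                        stringsAsFactors = FALSE))
    data.frame(name = p$name, start = g0 + p$offset,
               end = g0 + p$offset + nchar(p$piece), stringsAsFactors = FALSE)
  }))
  # the invariant donor/acceptor-adjacent exon sequences are planted too
  motifs <- rbind(motifs,
    data.frame(name = c("female_donor_exonic", "acceptor_exon_start"),
               start = c(g0 - 2L, g0 + I), end = c(g0, g0 + I + 10L)))
  motifs <- motifs[order(motifs$start), , drop = FALSE]
  rownames(motifs) <- NULL
  truth <- list(motifs = motifs, female_donor = g0,
                male_donor = g0 + off + mex, acceptor = g0 + I,
                config = cfg)
  list(gene = gene, truth = truth)
}

#' Mutate a sequence by substitutions and indels
#'
#' Jukes-Cantor-like substitution (uniform choice among the three other
#' bases) at a per-position probability, plus geometric-length insertions and
#' deletions initiated at `indel_rate` per position outside forbidden
#' regions. Deletions truncate at forbidden positions.
#'
#' @param seq DNA string.
#' @param sub_prob Scalar or per-position substitution probability.
#' @param indel_rate Per-position indel initiation probability.
#' @param mean_indel_len Mean geometric indel length.
#' @param indel_forbidden Logical vector marking positions where indels may
#'   neither start nor delete (default none).
#' @param gc_content GC fraction of inserted material.
#' @return List with `sequence`, `lift` (for each old 0-based position, its
#'   new 0-based offset; deleted positions map to the deletion point),
#'   `new_length`, `kept`, `n_sub`, and `indels` (data.frame `old_pos`,
#'   `length`, `type`).
#' @export
mutate_sequence <- function(seq, sub_prob, indel_rate = 0,
                            mean_indel_len = 3, indel_forbidden = NULL,
                            gc_content = 0.5) {
  seq <- .normalize_dna(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  sub_prob <- rep_len(sub_prob, n)
  if (is.null(indel_forbidden)) indel_forbidden <- logical(n)
  do_sub <- runif(n) < sub_prob
  idx <- which(do_sub)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(ch[idx], bases, nomatch = sample.int(4L, 1L))
    ch[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  keep <- rep(TRUE, n)
  ins <- character(n)
  indels <- list()
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate & !indel_forbidden)
    for (e in ev) {
      len <- rgeom(1L, 1 / mean_indel_len) + 1L
      if (runif(1L) < 0.5) {
        ins[e] <- .rand_dna(len, gc_content)
        indels[[length(indels) + 1L]] <-
          data.frame(old_pos = e - 1L, length = len, type = "insertion")
      } else {
        j <- e
        while (j <= n && j < e + len && !indel_forbidden[j]) {
          keep[j] <- FALSE
          j <- j + 1L
        }
        if (j > e)
          indels[[length(indels) + 1L]] <-
            data.frame(old_pos = e - 1L, length = j - e, type = "deletion")
      }
    }
  }
  contrib <- as.integer(keep) + nchar(ins)
  lift <- cumsum(c(0L, contrib))[seq_len(n)]
  parts <- character(2L * n)
  parts[2L * seq_len(n) - 1L] <- ifelse(keep, ch, "")
  parts[2L * seq_len(n)] <- ins
  list(sequence = paste(parts, collapse = ""), lift = lift,
       new_length = sum(contrib), kept = keep, n_sub = length(idx),
       indels = if (length(indels)) do.call(rbind, indels) else
         data.frame(old_pos = integer(0), length = integer(0),
                    type = character(0)))
}

#' Derive a diverged ortholog of a synthetic gene
#'
#' Applies [mutate_sequence()] with per-position substitution probability
#' `d * motif_conservation_factor` inside planted elements and `d` elsewhere;
#' indels are forbidden inside planted elements and within 10 nt of every
#' feature boundary (splice junctions are invariant in the system modeled).
#' Planted-element and feature coordinates are lifted through the indels.
#' With `insertion_len > 0` a structural insertion of background sequence is
#' additionally placed 150 nt upstream of the acceptor, between the TRA/TRA2
#' cluster and the acceptor.
#'
#' @param sim A list with `gene` and `truth` from [generate_gene()].
#' @param cfg Optional `synth_config` overriding the one in `truth` (its
#'   `seed` is used for this divergence draw).
#' @return A list with `gene` (the ortholog `gene_model`), `truth` (lifted
#'   coordinates) and `trace` (substitution and indel record).
#' @export
diverge_gene <- function(sim, cfg = NULL) {
  cfg <- cfg %||% sim$truth$config
  withr::with_seed(cfg$seed + 10000L, .diverge_impl(sim, cfg))
}

.diverge_impl <- function(sim, cfg) {
  gene <- sim$gene
  truth <- sim$truth
  n <- nchar(gene$sequence)
  protected <- logical(n)
  for (r in seq_len(nrow(truth$motifs)))
    protected[(truth$motifs$start[r] + 1L):truth$motifs$end[r]] <- TRUE
  guard <- logical(n)
  for (b in unique(c(gene$features$start, gene$features$end))) {
    lo <- max(1L, b - 9L); hi <- min(n, b + 10L)
    guard[lo:hi] <- TRUE
  }
  sub_prob <- ifelse(protected, cfg$divergence * cfg$motif_conservation_factor,
                     cfg$divergence)
  mut <- mutate_sequence(gene$sequence, sub_prob,
                         indel_rate = cfg$indel_rate,
                         mean_indel_len = cfg$mean_indel_len,
                         indel_forbidden = protected | guard,
                         gc_content = cfg$gc_content)
  liftpt <- function(p) ifelse(p >= n, mut$new_length,
                               mut$lift[pmin(p, n - 1L) + 1L])
  new_seq <- mut$sequence
  shift_at <- Inf; shift_by <- 0L
  if (cfg$insertion_len > 0L) {
    ins_old <- truth$acceptor - 150L
    q <- liftpt(ins_old)
    insert <- .rand_dna(cfg$insertion_len, cfg$gc_content)
    new_seq <- paste0(substr(new_seq, 1L, q), insert,
                      substr(new_seq, q + 1L, nchar(new_seq)))
    shift_at <- q; shift_by <- cfg$insertion_len
  }
  lift2 <- function(p) {
    x <- liftpt(p)
    x + ifelse(x >= shift_at, shift_by, 0L)
  }
  f <- gene$features
  feats <- feature_table(f$role, lift2(f$start), lift2(f$end), f$rank)
  ortho <- gene_model(paste0(gene$gene_id, "_ortholog"), new_seq, feats,
                      species_tag = paste0(gene$species_tag, "_ortholog"))
  m <- truth$motifs
  m$start <- lift2(m$start); m$end <- lift2(m$end)
  truth2 <- list(motifs = m, female_donor = lift2(truth$female_donor),
                 male_donor = lift2(truth$male_donor),
                 acceptor = lift2(truth$acceptor), config = cfg)
  list(gene = ortho, truth = truth2,
       trace = list(n_sub = mut$n_sub, indels = mut$indels,
                    structural_insertion = if (shift_by > 0L)
                      c(at = shift_at, length = shift_by) else NULL))
}

#' Write a synthetic gene with its ground truth
#'
#' Emits FASTA + TSV annotation (via [write_gene()]) and a ground-truth JSON.
#'
#' @param sim Output of [generate_gene()] or [diverge_gene()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synth_gene <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$gene$gene_id
  write_gene(sim$gene, file.path(dir, paste0(id, ".fasta")),
             file.path(dir, paste0(id, ".tsv")))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, paste0(id, ".truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Detectable planted islands of a synthetic gene
#'
#' Merges planted-element intervals lying within `merge_gap` nt of each other
#' (a core and its flank, or the RBP1 site and its half-site, form one
#' physically contiguous conserved island) and keeps islands of at least
#' `min_len` nt -- the elements long enough to be recoverable as conserved
#' blocks of that minimum length.
#'
#' @param truth Ground truth from [generate_gene()] / [diverge_gene()].
#' @param min_len Minimum island length (default 12).
#' @param merge_gap Maximum gap merged into one island (default 2).
#' @return data.frame with `start`, `end` (0-based half-open, genomic).
#' @export
planted_islands <- function(truth, min_len = 12L, merge_gap = 2L) {
  m <- truth$motifs[order(truth$motifs$start), , drop = FALSE]
  grp <- cumsum(c(1L, m$start[-1L] - m$end[-nrow(m)] > merge_gap))
  isl <- do.call(rbind, lapply(split(m, grp), function(d)
    data.frame(start = min(d$start), end = max(d$end))))
  isl <- isl[isl$end - isl$start >= min_len, , drop = FALSE]
  rownames(isl) <- NULL
  isl
}

#' Coverage Jaccard of conserved blocks against planted islands
#'
#' Aligns the regulated introns of a synthetic gene and its ortholog, calls
#' conserved blocks at motif scale and returns the Jaccard index between the
#' intron positions covered by blocks and those covered by detectable
#' planted islands (see [planted_islands()]), in the original gene's
#' coordinates.
#'
#' @param sim Output of [generate_gene()].
#' @param div Output of [diverge_gene()] for the same gene.
#' @param min_block_len,min_block_identity Block-calling parameters at the
#'   planted-element scale (defaults 12 and 0.95).
#' @return Jaccard index in `[0, 1]`.
#' @export
block_motif_jaccard <- function(sim, div, min_block_len = 12L,
                                min_block_identity = 0.95) {
  fi <- gene_feature(sim$gene, "female_intron_1")
  n <- fi$end - fi$start
  cmp <- global_align(feature_seq(sim$gene, "female_intron_1"),
                      feature_seq(div$gene, "female_intron_1"))
  bl <- conserved_blocks(cmp, min_block_len, min_block_identity)
  cov_b <- logical(n)
  if (nrow(bl)) for (r in seq_len(nrow(bl)))
    cov_b[(bl$start_a[r] + 1L):bl$end_a[r]] <- TRUE
  isl <- planted_islands(sim$truth, min_len = min_block_len)
  isl$start <- pmax(0L, isl$start - fi$start)
  isl$end <- pmin(n, isl$end - fi$start)
  isl <- isl[isl$end > isl$start, , drop = FALSE]
  cov_m <- logical(n)
  if (nrow(isl)) for (r in seq_len(nrow(isl)))
    cov_m[(isl$start[r] + 1L):isl$end[r]] <- TRUE
  sum(cov_b & cov_m) / sum(cov_b | cov_m)
}
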