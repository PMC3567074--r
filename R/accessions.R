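# Working from raw genomic sequence: re-deriving the sex-specific splice
# architecture from its invariant junction contexts, fetching the deposited
# blowfly tra accessions, and the accession-based validation battery.
#
# Exact exon/intron coordinates are not published for these genes, so the
# architecture is inferred from the invariant sequence contexts themselves:
# the female donor TG/GTAATTTT, a consensus male donor AG/GTAAGT downstream,
# and the acceptor followed by the invariant exon sequence GTGAAGGTTC.

#' Infer the sex-specific splice architecture from raw sequence
#'
#' Locates the female donor (first `TGGTAATTTT`), the male donor (first
#' `AGGTAAGT` downstream of it, taken as far downstream as possible before
#' the acceptor) and the acceptor (last `AG` preceding a downstream
#' `GTGAAGGTTC`), and builds a minimal gene model: a 60-nt pseudo-exon on
#' each side of the regulated intron and the male exon spanning from the
#' female donor junction to the male donor. In these genes the male exon
#' begins immediately at the female donor junction.
#'
#' @param seq Genomic DNA string.
#' @param gene_id,species_tag Labels for the resulting model.
#' @param flank Pseudo-exon length (default 60).
#' @return A `gene_model`, or an error if the invariant contexts are absent.
#' @export
infer_tra_architecture <- function(seq, gene_id = "tra", species_tag = "",
                                   flank = 60L) {
  seq <- .normalize_dna(seq)
  fd <- regexpr("TGGTAATTTT", seq, fixed = TRUE)[1]
  if (fd < 0) .val_err("female donor context TG/GTAATTTT not found")
  intron_start <- fd + 1L  # 0-based: junction after the TG
  acc <- regexpr("AGGTGAAGGTTC", substr(seq, fd, nchar(seq)),
                 fixed = TRUE)[1]
  if (acc < 0) .val_err("acceptor context AG/GTGAAGGTTC not found")
  intron_end <- (fd - 1L) + acc + 1L  # 0-based offset of first exon 2 base
  intr <- .subseq0(seq, intron_start, intron_end)
  md <- gregexpr("AGGTAAGT", intr, fixed = TRUE)[[1]]
  if (md[1] < 0) .val_err("male donor context AG/GTAAGT not found in intron")
  male_end <- intron_start + md[1] + 1L  # first donor; junction after the AG
  feats <- feature_table(
    role = c("exon", "female_intron_1", "male_exon", "exon"),
    start = c(max(0L, intron_start - flank), intron_start, intron_start,
              intron_end),
    end = c(intron_start, intron_end, male_end,
            min(nchar(seq), intron_end + flank)),
    rank = c(1L, NA, NA, 2L))
  gene_model(gene_id, seq, feats, species_tag = species_tag)
}

#' Fetch the deposited blowfly tra accessions
#'
#' Downloads the three deposited transformer gene sequences (JX315618,
#' JX315619, JX315620) from NCBI as FASTA. Requires network access; nothing
#' else in the package does.
#'
#' @param dest_dir Download directory.
#' @param accessions Named character vector of accessions.
#' @return Named vector of FASTA paths.
#' @export
fetch_tra_accessions <- function(dest_dir,
                                 accessions = c(Chtra = "JX315618",
                                                Cmtra = "JX315619",
                                                Lstra = "JX315620")) {
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
  paths <- vapply(names(accessions), function(nm) {
    path <- file.path(dest_dir, paste0(nm, ".fasta"))
    url <- sprintf("%s?db=nuccore&id=%s&rettype=fasta&retmode=text",
                   base, accessions[[nm]])
    download.file(url, path, quiet = TRUE)
    path
  }, "")
  paths
}

#' Accession-based validation battery
#'
#' Runs the comparative checks on the three deposited blowfly tra genes
#' (supplied as FASTA paths, e.g. from [fetch_tra_accessions()]): intronic
#' TRA/TRA2 site counts (4 in the Cochliomyia genes, 5 with overlap counting
#' in L. sericata), the male-exon singleton site, the invariant female donor
#' and acceptor-adjacent exon sequences, the RBP1 site ~100 bp upstream of
#' the acceptor, male-exon and intron identities, the large Cmtra intron
#' insertion, and the 18-19 column high-information core of the extended
#' TRA/TRA2 site profile.
#'
#' @param fasta_paths Named character vector (`Chtra`, `Cmtra`, `Lstra`) of
#'   FASTA paths.
#' @return data.frame with columns `check`, `value`, `expected`, `pass`.
#' @export
validate_accessions <- function(fasta_paths) {
  need <- c("Chtra", "Cmtra", "Lstra")
  if (!all(need %in% names(fasta_paths)))
    .val_err("fasta_paths must be named Chtra, Cmtra, Lstra")
  genes <- lapply(fasta_paths[need], function(p) {
    fa <- Biostrings::readDNAStringSet(p)
    infer_tra_architecture(as.character(fa[[1]]),
                           gene_id = sub("\\s.*", "", names(fa)[1]))
  })
  names(genes) <- need
  core <- motif_library()$tra_tra2_core
  res <- list()
  chk <- function(check, value, expected, pass)
    res[[length(res) + 1L]] <<- data.frame(check = check, value = value,
                                           expected = expected, pass = pass,
                                           stringsAsFactors = FALSE)
  for (nm in need) {
    g <- genes[[nm]]
    hits <- scan_iupac(g$sequence, core)
    hits$feature_context <- vapply(seq_len(nrow(hits)), function(i)
      feature_context(g, hits$start[i], hits$end[i]), "")
    fi <- gene_feature(g, "female_intron_1")
    me <- gene_feature(g, "male_exon")
    in_intron <- sum(hits$start >= me$end & hits$end <= fi$end)
    exp_n <- if (nm == "Lstra") 5L else 4L
    chk(paste0(nm, "_intron_site_count"), in_intron, exp_n,
        in_intron == exp_n)
    in_mex <- sum(hits$start >= me$start & hits$end <= me$end)
    chk(paste0(nm, "_male_exon_site"), in_mex, 1L, in_mex >= 1L)
    sites <- extract_splice_sites(g)
    fw <- paste0(substr(sites$female_donor$exonic_flank, 2, 3),
                 substr(sites$female_donor$intronic_flank, 1, 8))
    chk(paste0(nm, "_female_donor"), fw, "TGGTAATTTT", fw == "TGGTAATTTT")
    ex2 <- .subseq0(g$sequence, fi$end, fi$end + 10L)
    chk(paste0(nm, "_acceptor_exon_start"), ex2, "GTGAAGGTTC",
        ex2 == "GTGAAGGTTC")
    rb <- scan_iupac(feature_seq(g, "female_intron_1"),
                     motif_library()$rbp1_type_a)
    d <- if (nrow(rb)) min(abs((fi$end - fi$start) - rb$end)) else NA
    chk(paste0(nm, "_rbp1_offset"), d, "100 +/- 40",
        !is.na(d) && abs(d - 100) <= 40)
  }
  mex_seq <- lapply(genes, feature_seq, feature = "male_exon")
  id_mex <- global_align(mex_seq$Chtra, mex_seq$Cmtra)$pct_identity
  chk("ChCm_male_exon_identity", round(id_mex, 1), "85 +/- 3",
      abs(id_mex - 85) <= 3)
  intr <- lapply(genes, feature_seq, feature = "female_intron_1")
  cml <- global_align(intr$Cmtra, intr$Lstra)
  chk("CmLs_intron_identity", round(cml$pct_identity, 1), "28 +/- 5",
      abs(cml$pct_identity - 28) <= 5)
  chcm <- global_align(intr$Chtra, intr$Cmtra)
  ins <- find_insertions(chcm, min_len = 500L)
  big <- ins[ins$which_seq == "b", , drop = FALSE]  # Cmtra hosts it
  len <- if (nrow(big)) max(big$length) else 0L
  chk("Cmtra_insertion_len", len, "1100 +/- 20%",
      len >= 880 && len <= 1320)
  wins <- unlist(lapply(genes, function(g) {
    h <- scan_iupac(g$sequence, core)
    tryCatch(as.character(extract_windows(h, g$sequence, width = 26L,
                                          anchor = 4L)),
             error = function(e) character(0))
  }))
  prof <- site_profile(wins)
  width <- diff(prof$core_span) + 1L
  chk("extended_site_ic_core_width", width, "18-19",
      !anyNA(prof$core_span) && width %in% 18:19)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
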