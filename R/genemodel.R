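# Gene models: a sequence plus typed features in one coordinate frame.

FEATURE_ROLES <- c("exon", "male_exon", "female_intron_1", "intron",
                   "utr5", "utr3")

#' Construct a feature table
#'
#' @param role Character vector of feature roles; one of `exon`, `male_exon`,
#'   `female_intron_1`, `intron`, `utr5`, `utr3`.
#' @param start,end Integer vectors of 0-based half-open genomic offsets.
#' @param rank Integer rank (exon order); `NA` where not applicable.
#' @return A `data.frame` with columns `role`, `start`, `end`, `rank`.
#' @export
feature_table <- function(role, start, end, rank = NA_integer_) {
  df <- data.frame(role = as.character(role), start = as.integer(start),
                   end = as.integer(end), rank = as.integer(rank),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Construct and validate a gene model
#'
#' A gene model bundles a genomic sequence with typed features (exons, the
#' male-specific exon, the regulated female first intron) in a single 0-based
#' half-open coordinate frame on the sense strand.
#'
#' @param gene_id Gene identifier (matches the FASTA record id on I/O).
#' @param sequence DNA string; `U` is normalized to `T`, `N` is allowed.
#' @param features A feature table (see [feature_table()]).
#' @param species_tag Free-text species label.
#' @param sex_specific If `TRUE` (default) the model must contain exactly one
#'   `male_exon` and one `female_intron_1` containing it.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, sequence, features, species_tag = "",
                       sex_specific = TRUE) {
  sequence <- .normalize_dna(sequence, sprintf("sequence of '%s'", gene_id))
  g <- structure(
    list(gene_id = as.character(gene_id), sequence = sequence,
         features = features, species_tag = as.character(species_tag)),
    class = "gene_model")
  validate_gene_model(g, sex_specific = sex_specific)
  g
}

#' Validate gene-model invariants
#'
#' Checks feature bounds, exon ordering/ranks and, when `sex_specific`, the
#' male-exon / regulated-intron architecture (exactly one `male_exon`, lying
#' within the single `female_intron_1` and ending strictly before the splice
#' acceptor).
#'
#' @param gene A `gene_model`.
#' @param sex_specific Require the sex-specific architecture.
#' @return Invisibly `TRUE`; signals a condition of class
#'   `traScan_validation_error` otherwise.
#' @export
validate_gene_model <- function(gene, sex_specific = TRUE) {
  f <- gene$features
  n <- nchar(gene$sequence)
  need <- c("role", "start", "end", "rank")
  if (!all(need %in% names(f)))
    .val_err("features must have columns role, start, end, rank")
  if (!all(f$role %in% FEATURE_ROLES))
    .val_err(sprintf("unknown feature role '%s'",
                     setdiff(f$role, FEATURE_ROLES)[1]))
  if (any(f$start >= f$end))
    .val_err("every feature must satisfy start < end")
  if (any(f$start < 0L) || any(f$end > n))
    .val_err(sprintf("feature out of bounds for sequence of length %d", n))
  ex <- f[f$role == "exon", , drop = FALSE]
  if (nrow(ex)) {
    if (anyNA(ex$rank) || anyDuplicated(ex$rank))
      .val_err("exon ranks must be unique and non-missing")
    ex <- ex[order(ex$rank), , drop = FALSE]
    if (is.unsorted(ex$start, strictly = TRUE))
      .val_err("exon coordinates must increase with rank")
    if (any(ex$start[-1L] < ex$end[-nrow(ex)]))
      .val_err("exons must be non-overlapping")
  }
  if (sex_specific) {
    me <- f[f$role == "male_exon", , drop = FALSE]
    if (nrow(me) != 1L)
      .val_err(sprintf("expected exactly one male_exon, found %d", nrow(me)))
    fi <- f[f$role == "female_intron_1", , drop = FALSE]
    if (nrow(fi) != 1L)
      .val_err(sprintf("expected exactly one female_intron_1, found %d",
                       nrow(fi)))
    if (me$start < fi$start || me$end >= fi$end)
      .val_err("male_exon must lie within female_intron_1 and end strictly before the acceptor")
  }
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s%s: %d nt, %d features\n", x$gene_id,
              if (nzchar(x$species_tag)) paste0(" (", x$species_tag, ")") else "",
              nchar(x$sequence), nrow(x$features)))
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Extract features of one role
#'
#' @param gene A `gene_model`.
#' @param role A feature role.
#' @return The matching feature rows, exons ordered by rank.
#' @export
gene_feature <- function(gene, role) {
  f <- gene$features[gene$features$role == role, , drop = FALSE]
  if (role == "exon") f <- f[order(f$rank), , drop = FALSE]
  f
}

#' Sequence of one feature
#'
#' @param gene A `gene_model`.
#' @param feature A single feature row (or a role name, for unique roles).
#' @return DNA string of the feature.
#' @export
feature_seq <- function(gene, feature) {
  if (is.character(feature)) feature <- gene_feature(gene, feature)
  if (nrow(feature) != 1L) .val_err("feature_seq needs exactly one feature")
  .subseq0(gene$sequence, feature$start, feature$end)
}

#' Feature context of an interval
#'
#' Role of the feature enclosing `[start, end)`, with the most specific role
#' winning where features nest (`male_exon` lies inside `female_intron_1`).
#'
#' @param gene A `gene_model`.
#' @param start,end 0-based half-open interval.
#' @return A role string, or `"intergenic"`.
#' @export
feature_context <- function(gene, start, end = start + 1L) {
  f <- gene$features
  enclosing <- f$start <= start & f$end >= end
  if (!any(enclosing)) return("intergenic")
  roles <- f$role[enclosing]
  for (r in c("male_exon", "exon", "utr5", "utr3", "female_intron_1", "intron"))
    if (r %in% roles) return(r)
  "intergenic"
}
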