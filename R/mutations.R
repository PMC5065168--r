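.mutation_cols <- c("sample", "gene", "cdna_change", "protein_change",
                    "mutation_type", "vaf_pct", "cosmic_id")

#' Read / write targeted-sequencing mutation tables
#'
#' Tab-delimited tables shaped like a published amplicon-sequencing summary:
#' columns `sample`, `gene`, `cdna_change`, `protein_change`,
#' `mutation_type` (missense, nonsense, frameshift, synonymous, intronic or
#' SNP), `vaf_pct` (variant allele frequency in percent) and `cosmic_id`
#' (optional catalogue id, NA when absent). HGVS-like change strings are
#' treated as opaque labels.
#'
#' @param path File path.
#' @param records Mutation data frame.
#' @return `load_mutation_table()` the validated data frame;
#'   `write_mutation_table()` the path, invisibly.
#' @export
load_mutation_table <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  missing_cols <- setdiff(.mutation_cols, names(df))
  if (length(missing_cols))
    stop("mutation table ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[.mutation_cols]
  df$vaf_pct <- suppressWarnings(as.numeric(df$vaf_pct))
  bad <- which(is.na(df$vaf_pct) | df$vaf_pct < 0 | df$vaf_pct > 100)
  if (length(bad))
    stop("VAF outside [0, 100] in mutation table row(s): ",
         paste(bad, collapse = ", "))
  df$mutation_type <- tolower(df$mutation_type)
  df
}

#' @rdname load_mutation_table
#' @export
write_mutation_table <- function(records, path) {
  write.table(records[.mutation_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Apply variant scoring exclusions
#'
#' Drops records that are not scored as somatic candidate mutations:
#' intronic variants, records typed as SNPs, and records whose identifier
#' (`snp_id` column when present, otherwise `cosmic_id`) appears in the
#' supplied known-polymorphism list. Filtering is idempotent.
#'
#' @param records Mutation data frame.
#' @param known_snp_ids Character vector of identifiers of known
#'   polymorphisms.
#' @return Filtered data frame.
#' @export
filter_scored_variants <- function(records, known_snp_ids = character()) {
  if (nrow(records) == 0) return(records)
  type <- tolower(records$mutation_type)
  ids <- if ("snp_id" %in% names(records)) records$snp_id
         else records$cosmic_id
  drop <- type %in% c("intronic", "snp") |
    (!is.na(ids) & ids %in% known_snp_ids)
  records[!drop, , drop = FALSE]
}

#' Classify mutation zygosity from variant allele frequency
#'
#' A mutation with VAF at or above `hom_vaf_threshold` (default 80%,
#' inclusive) is classed `homozygous_or_hemizygous`; below, `heterozygous`.
#' VAF alone cannot distinguish a truly homozygous mutation from a
#' hemizygous one on the single allele remaining after deletion - the two
#' are deliberately one class, and the deletion context is resolved by
#' [biallelic_status()].
#'
#' @param records Mutation data frame (uses `vaf_pct`).
#' @param hom_vaf_threshold VAF percent boundary, inclusive.
#' @return `records` with an added `zygosity` column.
#' @export
classify_zygosity <- function(records, hom_vaf_threshold = 80) {
  if (any(records$vaf_pct < 0 | records$vaf_pct > 100))
    stop("VAF outside [0, 100]")
  records$zygosity <- ifelse(records$vaf_pct >= hom_vaf_threshold,
                             "homozygous_or_hemizygous", "heterozygous")
  records
}

#' Biallelic status of a gene in one patient
#'
#' Combines deletion calls with retained mutations:
#' `deletion_plus_mutation` when a somatic loss call overlaps the gene and
#' the patient carries at least one retained mutation in it (both alleles
#' hit); `deletion_only`, `mutation_only` and `wild_type` by elimination.
#'
#' @param patient Patient/sample id.
#' @param gene Gene symbol; must be present in `genes`.
#' @param loss_calls Somatic loss calls for this patient (data frame with
#'   chrom, start, end, direction).
#' @param mutations Retained mutation records for this patient (data frame
#'   with sample, gene).
#' @param genes Gene annotation data frame (chrom, start, end, gene).
#' @return Data frame row: patient, gene, category, n_deletions,
#'   n_mutations.
#' @export
biallelic_status <- function(patient, gene, loss_calls, mutations, genes) {
  gi <- genes[genes$gene == gene, , drop = FALSE]
  if (nrow(gi) == 0) stop("unknown gene: ", gene)
  has_del <- FALSE
  if (!is.null(loss_calls) && nrow(loss_calls)) {
    losses <- loss_calls[loss_calls$direction == "loss", , drop = FALSE]
    if (nrow(losses)) {
      hits <- .find_overlaps(gi[1, ], losses)
      has_del <- length(hits) > 0
    }
  }
  n_mut <- if (is.null(mutations) || nrow(mutations) == 0) 0L
           else sum(mutations$sample == patient & mutations$gene == gene)
  category <- if (has_del && n_mut > 0) "deletion_plus_mutation"
              else if (has_del) "deletion_only"
              else if (n_mut > 0) "mutation_only"
              else "wild_type"
  data.frame(patient = patient, gene = gene, category = category,
             n_deletions = as.integer(has_del), n_mutations = n_mut,
             stringsAsFactors = FALSE)
}

#' Minimal deleted region across patients
#'
#' The genomic intersection of overlapping deletions at a locus: the
#' largest interval contained in every supporting deletion. Disjoint inputs
#' yield an "absent" result, never a zero-length interval.
#'
#' @param deletions Data frame of deletions on one chromosome (chrom,
#'   start, end, 0-based half-open).
#' @param label Optional gene/locus label.
#' @return Object of class `mdr`: list with label, chrom, absent, and when
#'   present start, end, size_bp, size_kb, n_supporting.
#' @export
minimal_deleted_region <- function(deletions, label = NULL) {
  if (is.null(deletions) || nrow(deletions) == 0)
    stop("at least one deletion is required")
  chrom <- unique(deletions$chrom)
  if (length(chrom) != 1)
    stop("deletions must all lie on one chromosome")
  start <- max(deletions$start)
  end <- min(deletions$end)
  if (start >= end) {
    res <- list(label = label, chrom = chrom, absent = TRUE,
                n_supporting = nrow(deletions))
  } else {
    res <- list(label = label, chrom = chrom, absent = FALSE,
                start = start, end = end,
                size_bp = end - start, size_kb = (end - start) / 1e3,
                n_supporting = nrow(deletions))
  }
  class(res) <- "mdr"
  res
}

#' @export
print.mdr <- function(x, ...) {
  lbl <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  if (x$absent) {
    cat("Minimal deleted region", lbl, ": absent (disjoint deletions, n = ",
        x$n_supporting, ")\n", sep = "")
  } else {
    cat(sprintf("Minimal deleted region%s: %s:%d-%d (%.1f kb, n = %d)\n",
                lbl, x$chrom, x$start, x$end, x$size_kb, x$n_supporting))
  }
  invisible(x)
}
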