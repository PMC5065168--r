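#' Read / write probe-level log2-ratio tables
#'
#' Tab-delimited with header `chrom  pos  log2ratio`; positions are 1-based.
#'
#' @param path File path.
#' @param probes Data frame with columns chrom, pos, log2ratio.
#' @return `read_probe_table()` the data frame; `write_probe_table()` the
#'   path, invisibly.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("probe table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "log2ratio")
  if (!all(need %in% names(df)))
    stop("probe table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_probe_table
#' @export
write_probe_table <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write SEG-format segment tables
#'
#' Columns `sample  chrom  start  end  n_probes  seg_mean`; coordinates are
#' 0-based half-open.
#'
#' @param path File path.
#' @param segments Segment data frame (column `mean_log2` is written as
#'   `seg_mean`).
#' @return `read_seg()` a data frame with column `mean_log2`; `write_seg()`
#'   the path, invisibly.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "n_probes", "seg_mean")
  if (!all(need %in% names(df)))
    stop("SEG file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  names(df)[names(df) == "seg_mean"] <- "mean_log2"
  df
}

#' @rdname read_seg
#' @export
write_seg <- function(segments, path) {
  out <- segments
  if (!"sample" %in% names(out)) out$sample <- NA_character_
  out <- out[c("sample", "chrom", "start", "end", "n_probes", "mean_log2")]
  names(out)[names(out) == "mean_log2"] <- "seg_mean"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write interval annotation as BED
#'
#' Thin wrappers over rtracklayer's BED support. Data frames use the
#' package-internal convention (0-based half-open `start`/`end`, a `name`
#' column when present).
#'
#' @param path BED file path.
#' @param intervals Data frame with chrom, start, end and optionally name.
#' @return `read_bed_intervals()` a data frame; `write_bed_intervals()` the
#'   path, invisibly.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED ", path, ": ",
                                          conditionMessage(e)))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- nm
  df
}

#' @rdname read_bed_intervals
#' @export
write_bed_intervals <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  if ("name" %in% names(intervals)) names(gr) <- intervals$name
  else if ("gene" %in% names(intervals)) names(gr) <- intervals$gene
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write karyotype tables
#'
#' Tab-delimited with header `patient  iscn  n_metaphases`.
#'
#' @param path File path.
#' @param karyotypes Data frame with those columns.
#' @return `read_karyotype_table()` the data frame;
#'   `write_karyotype_table()` the path, invisibly.
#' @export
read_karyotype_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("patient", "iscn", "n_metaphases")
  if (!all(need %in% names(df)))
    stop("karyotype table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df$iscn[is.na(df$iscn)] <- ""
  df
}

#' @rdname read_karyotype_table
#' @export
write_karyotype_table <- function(karyotypes, path) {
  write.table(karyotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GRanges view of 0-based half-open interval data frames.
.intervals_gr <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  GenomicRanges::GRanges(
    factor(df$chrom, levels = seqlevels),
    IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# findOverlaps between two interval data frames on a shared seqlevel set
.find_overlaps <- function(a, b) {
  lev <- union(unique(a$chrom), unique(b$chrom))
  GenomicRanges::findOverlaps(.intervals_gr(a, lev), .intervals_gr(b, lev))
}
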