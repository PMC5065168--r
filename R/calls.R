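#' Call copy-number aberrations from a segmented profile
#'
#' Maps each segment to a copy state by the calling thresholds (mean at or
#' below `loss_threshold`: one copy; at or above `gain_threshold`: three
#' copies; otherwise normal) and emits one call per maximal run of adjacent
#' same-direction segments - adjacent called segments merge only when no
#' normal segment lies between them. Normal segments produce no call.
#'
#' @param segments Segment data frame from [segment_profile()] (an optional
#'   `sample` column is carried through).
#' @param config A [calling_config()].
#' @return Data frame of calls: sample (if present), chrom, start, end
#'   (0-based half-open), n_probes, mean_log2 (probe-weighted), direction
#'   ("loss"/"gain"), copy_state (1 or 3), size_bp, cryptic, germline_cnv
#'   (initialized FALSE), followup (initialized FALSE).
#' @export
call_cnas <- function(segments, config = calling_config()) {
  stopifnot(inherits(config, "calling_config"))
  empty <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_probes = integer(), mean_log2 = numeric(),
                      direction = character(), copy_state = integer(),
                      size_bp = numeric(), cryptic = logical(),
                      germline_cnv = logical(), followup = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0) return(empty)
  has_sample <- "sample" %in% names(segments)
  key <- if (has_sample) paste(segments$sample, segments$chrom)
         else segments$chrom
  out <- list()
  for (k in unique(key)) {
    seg <- segments[key == k, , drop = FALSE]
    states <- assign_states(seg, config)
    run <- rle(states)
    stop_i <- cumsum(run$lengths)
    start_i <- stop_i - run$lengths + 1L
    for (r in seq_along(run$values)) {
      st <- run$values[r]
      if (st == 2L) next
      i <- start_i[r]; j <- stop_i[r]
      np <- sum(seg$n_probes[i:j])
      out[[length(out) + 1L]] <- data.frame(
        sample = if (has_sample) seg$sample[i] else NA_character_,
        chrom = seg$chrom[i],
        start = seg$start[i],
        end = seg$end[j],
        n_probes = np,
        mean_log2 = sum(seg$mean_log2[i:j] * seg$n_probes[i:j]) / np,
        direction = if (st == 1L) "loss" else "gain",
        copy_state = st,
        size_bp = seg$end[j] - seg$start[i],
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else empty[0, 1:9]
  calls$cryptic <- classify_cryptic(calls, config)
  calls$germline_cnv <- logical(nrow(calls))
  calls$followup <- logical(nrow(calls))
  if (!has_sample) calls$sample <- NULL
  rownames(calls) <- NULL
  calls
}

#' Flag germline copy-number variants by reciprocal overlap
#'
#' A call whose reciprocal overlap with any catalogued germline-CNV region
#' reaches `cnv_overlap_fraction` (the overlap must cover that fraction of
#' the call *and* of the region) is flagged `germline_cnv` and thereby
#' excluded from downstream somatic counts. The operation only sets flags,
#' so it is idempotent; use [retained_calls()] for the somatic subset.
#'
#' @param calls Call data frame from [call_cnas()].
#' @param cnv_regions Data frame with chrom, start, end (0-based half-open),
#'   e.g. from [read_bed_intervals()]; may be empty or NULL.
#' @param config A [calling_config()].
#' @return `calls` with the `germline_cnv` flag set.
#' @export
filter_germline_cnv <- function(calls, cnv_regions,
                                config = calling_config()) {
  stopifnot(inherits(config, "calling_config"))
  calls$germline_cnv <- logical(nrow(calls))
  if (nrow(calls) == 0 || is.null(cnv_regions) || nrow(cnv_regions) == 0)
    return(calls)
  if (any(cnv_regions$end <= cnv_regions$start))
    stop("malformed CNV region: end <= start")
  hits <- .find_overlaps(calls, cnv_regions)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(calls$end[qi], cnv_regions$end[si]) -
      pmax(calls$start[qi], cnv_regions$start[si])
    recip <- ov / (calls$end[qi] - calls$start[qi]) >=
      config$cnv_overlap_fraction &
      ov / (cnv_regions$end[si] - cnv_regions$start[si]) >=
      config$cnv_overlap_fraction
    calls$germline_cnv[unique(qi[recip])] <- TRUE
  }
  calls
}

#' Somatic (non-germline) subset of a call table
#'
#' @param calls Call data frame.
#' @return Rows not flagged `germline_cnv`.
#' @export
retained_calls <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  calls[!calls$germline_cnv, , drop = FALSE]
}

#' Classify calls as cryptic (below the cytogenetic detection limit)
#'
#' A CNA is cryptic when its size is at most `cryptic_max` (inclusive;
#' default 5 Mb), i.e. too small to be seen on banded metaphases.
#'
#' @param calls Call data frame (uses `size_bp`), or a numeric vector of
#'   sizes in bp.
#' @param config A [calling_config()].
#' @return Logical vector.
#' @export
classify_cryptic <- function(calls, config = calling_config()) {
  sizes <- if (is.data.frame(calls)) calls$size_bp else calls
  sizes <= config$cryptic_max
}

#' Flag deletions for targeted-sequencing follow-up
#'
#' A call is selected when it is a loss, strictly larger than
#' `followup_min` (default 100 kb), and overlaps (>= 1 bp) a gene of the
#' sequencing panel - the rule used to pick regions whose remaining allele
#' is screened for mutations.
#'
#' @param calls Call data frame.
#' @param panel_genes Data frame of panel-gene intervals (chrom, start, end,
#'   0-based half-open).
#' @param config A [calling_config()].
#' @return `calls` with the `followup` flag set.
#' @export
select_for_sequencing <- function(calls, panel_genes,
                                  config = calling_config()) {
  calls$followup <- logical(nrow(calls))
  if (nrow(calls) == 0 || is.null(panel_genes) || nrow(panel_genes) == 0)
    return(calls)
  hits <- .find_overlaps(calls, panel_genes)
  overlaps_gene <- seq_len(nrow(calls)) %in% S4Vectors::queryHits(hits)
  calls$followup <- calls$direction == "loss" &
    calls$size_bp > config$followup_min &
    overlaps_gene
  calls
}
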