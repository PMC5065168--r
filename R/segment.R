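#' Segment a probe-level log2-ratio profile
#'
#' Partitions each chromosome's ordered probes into contiguous segments by
#' exact penalized least-squares changepoint detection: the partition
#' minimizes the residual sum of squares around per-segment means plus
#' `segmentation_penalty` per segment, subject to every segment holding at
#' least `min_probes` probes. The optimum is found by an exhaustive dynamic
#' program (compiled), so results are deterministic and reproducible.
#'
#' Chromosomes with fewer than `min_probes` probes are skipped with a
#' warning. Probes must be sorted by position within each chromosome.
#'
#' @param probes Data frame with columns chrom, pos (1-based), log2ratio.
#' @param config A [calling_config()].
#' @return Data frame of segments: chrom, start, end (0-based half-open,
#'   spanning the member probe positions), n_probes, mean_log2. Chromosome
#'   blocks appear in input order.
#' @export
segment_profile <- function(probes, config = calling_config()) {
  stopifnot(inherits(config, "calling_config"))
  need <- c("chrom", "pos", "log2ratio")
  if (!all(need %in% names(probes)))
    stop("`probes` must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(probes$log2ratio)))
    stop("non-finite log2 ratios in input")
  chroms <- unique(probes$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    chrom <- chroms[k]
    idx <- probes$chrom == chrom
    pos <- probes$pos[idx]
    x <- probes$log2ratio[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("probes not sorted by position on ", chrom)
    if (length(x) < config$min_probes) {
      warning("skipping ", chrom, ": fewer than ", config$min_probes,
              " probes")
      next
    }
    ends <- .dp_changepoints(x, config$segmentation_penalty,
                             config$min_probes)
    starts <- c(1L, head(ends, -1L) + 1L)
    out[[k]] <- data.frame(
      chrom = chrom,
      start = pos[starts] - 1,
      end = pos[ends],
      n_probes = ends - starts + 1L,
      mean_log2 = vapply(seq_along(ends), function(i)
        mean(x[starts[i]:ends[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      mean_log2 = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
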