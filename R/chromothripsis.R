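#' Assign copy states to segments
#'
#' Maps each segment mean to a copy state by the calling thresholds: 1
#' (deletion) at or below `loss_threshold`, 3 (gain) at or above
#' `gain_threshold`, 2 (normal) otherwise. Order is preserved; an empty
#' input yields an empty sequence.
#'
#' @param segments Segment data frame (uses `mean_log2`), or a numeric
#'   vector of segment means.
#' @param config A [calling_config()].
#' @return Integer vector of states in \{1, 2, 3\}.
#' @export
assign_states <- function(segments, config = calling_config()) {
  means <- if (is.data.frame(segments)) segments$mean_log2 else segments
  if (length(means) == 0) return(integer(0))
  ifelse(means <= config$loss_threshold, 1L,
         ifelse(means >= config$gain_threshold, 3L, 2L))
}

#' Count copy-state switches along a chromosome
#'
#' The number of adjacent unequal pairs after run-length encoding of the
#' state sequence: a profile of k alternating segments has k - 1 switches.
#' Constant and empty sequences have 0 switches.
#'
#' @param states Integer vector of per-segment copy states, in chromosome
#'   order.
#' @return Non-negative integer.
#' @export
count_state_switches <- function(states) {
  if (length(states) == 0) return(0L)
  length(rle(as.vector(states))$values) - 1L
}

#' Evaluate the chromothripsis criterion on a state sequence
#'
#' A single chromosome is chromothriptic when its segmental copy states
#' switch at least `min_switches` times while oscillating among at most
#' `max_states` distinct states. This low-level form accepts any integer
#' state sequence; [detect_chromothripsis()] derives states from segment
#' means via the calling thresholds.
#'
#' @param states Integer vector of per-segment copy states.
#' @param config A [chromothripsis_config()].
#' @return List with n_state_switches, n_distinct_states, positive, states.
#' @export
chromothripsis_call <- function(states, config = chromothripsis_config()) {
  stopifnot(inherits(config, "chromothripsis_config"))
  n_sw <- count_state_switches(states)
  n_states <- length(unique(states))
  list(n_state_switches = n_sw,
       n_distinct_states = n_states,
       positive = n_sw >= config$min_switches &&
         n_states <= config$max_states,
       states = as.integer(states))
}

#' Detect chromothripsis per chromosome
#'
#' Applies the oscillation criterion chromosome by chromosome to a
#' segmented profile: a positive call requires at least `min_switches`
#' changes of segmental copy state with at most `max_states` distinct
#' states, evaluated on each single chromosome only (switches never pool
#' across chromosomes).
#'
#' @param segments Segment data frame for one patient (all chromosomes).
#' @param config A [chromothripsis_config()].
#' @param calling A [calling_config()] supplying the state thresholds.
#' @param sample Optional sample id recorded in the output.
#' @return Data frame with one row per chromosome: sample, chrom,
#'   n_state_switches, n_distinct_states, positive, states
#'   (comma-collapsed sequence).
#' @export
detect_chromothripsis <- function(segments,
                                  config = chromothripsis_config(),
                                  calling = calling_config(),
                                  sample = NA_character_) {
  chroms <- unique(segments$chrom)
  rows <- lapply(chroms, function(chrom) {
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    cl <- chromothripsis_call(assign_states(seg, calling), config)
    data.frame(sample = sample, chrom = chrom,
               n_state_switches = cl$n_state_switches,
               n_distinct_states = cl$n_distinct_states,
               positive = cl$positive,
               states = paste(cl$states, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(), chrom = character(),
                      n_state_switches = integer(),
                      n_distinct_states = integer(), positive = logical(),
                      states = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes commonly affected across chromothripsis-positive patients
#'
#' On a chromothriptic chromosome, a gene is "commonly affected" when in
#' every positive patient it overlaps (>= 1 bp) at least one non-normal
#' segment. The reported direction is "amplified" when every patient's
#' overlapping aberrant segments are gains, "deleted" when all are losses,
#' and "mixed" otherwise.
#'
#' @param patient_segments Named list (one element per positive patient) of
#'   segment data frames restricted to the called chromosome.
#' @param genes Gene annotation data frame (chrom, start, end, gene) with
#'   entries on that chromosome.
#' @param calling A [calling_config()].
#' @return Data frame: gene, chrom, start, end, n_patients_affected,
#'   shared, direction ("amplified"/"deleted"/"mixed"; NA when not shared).
#' @export
shared_affected_genes <- function(patient_segments, genes,
                                  calling = calling_config()) {
  stopifnot(length(patient_segments) >= 1)
  chrom <- unique(unlist(lapply(patient_segments, function(s) s$chrom)))
  if (length(chrom) != 1)
    stop("patient segments must all come from one chromosome")
  genes <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(genes) == 0)
    stop("no gene annotation for chromosome ", chrom)
  gene_gr <- .intervals_gr(genes)
  per_patient <- lapply(patient_segments, function(seg) {
    states <- assign_states(seg, calling)
    aberrant <- seg[states != 2L, , drop = FALSE]
    st <- states[states != 2L]
    touched <- rep(FALSE, nrow(genes))
    dir_gain <- rep(FALSE, nrow(genes))
    dir_loss <- rep(FALSE, nrow(genes))
    if (nrow(aberrant)) {
      hits <- GenomicRanges::findOverlaps(gene_gr, .intervals_gr(aberrant))
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      touched[unique(qi)] <- TRUE
      dir_gain[unique(qi[st[si] == 3L])] <- TRUE
      dir_loss[unique(qi[st[si] == 1L])] <- TRUE
    }
    list(touched = touched, gain = dir_gain, loss = dir_loss)
  })
  touched_all <- Reduce(`&`, lapply(per_patient, `[[`, "touched"))
  n_affected <- Reduce(`+`, lapply(per_patient, function(p)
    as.integer(p$touched)))
  all_gain <- Reduce(`&`, lapply(per_patient, function(p)
    p$gain & !p$loss))
  all_loss <- Reduce(`&`, lapply(per_patient, function(p)
    p$loss & !p$gain))
  direction <- ifelse(!touched_all, NA_character_,
                      ifelse(all_gain, "amplified",
                             ifelse(all_loss, "deleted", "mixed")))
  data.frame(gene = genes$gene, chrom = chrom,
             start = genes$start, end = genes$end,
             n_patients_affected = n_affected,
             shared = touched_all, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}
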