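#' Default per-patient frequencies of implanted aberration classes
#'
#' Cohort-level fractions of patients carrying each recurrent aberration
#' class. They reproduce the frequency profile reported for large MDS/CMML
#' cohorts: roughly a quarter of patients carry at least one copy-number
#' abnormality, del(5q) is the most frequent large lesion, and cryptic
#' deletions cluster at the recurrently mutated panel genes (TET2, TP53,
#' RUNX1, DNMT3A, BCOR).
#'
#' Class name grammar understood by the generator:
#' \itemize{
#'   \item \code{del(<chrom><arm>)} - arm-level deletion, e.g. \code{del(5q)};
#'   \item \code{+<chrom>} - whole-chromosome trisomy, e.g. \code{+8};
#'   \item \code{dup(<chrom><arm>)} - arm-level gain, e.g. \code{dup(1q)};
#'   \item \code{-Y} - loss of chromosome Y (implanted in males only);
#'   \item \code{cryptic:<gene>} - small deletion centred on a panel gene;
#'   \item \code{t(...)} - balanced translocation (karyotype only, no
#'     copy-number footprint).
#' }
#'
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
default_event_frequencies <- function() {
  c("del(5q)"        = 0.083,
    "del(20q)"       = 0.043,
    "+8"             = 0.033,
    "-Y"             = 0.033,
    "del(7q)"        = 0.030,
    "dup(1q)"        = 0.017,
    "del(17p)"       = 0.013,
    "del(11q)"       = 0.013,
    "cryptic:TET2"   = 0.023,
    "cryptic:TP53"   = 0.020,
    "cryptic:RUNX1"  = 0.017,
    "cryptic:DNMT3A" = 0.007,
    "cryptic:BCOR"   = 0.007,
    "t(3;3)"         = 0.003)
}

#' Simulation configuration for synthetic aCGH cohorts
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate the study conditions of a 301-patient MDS/CMML aCGH cohort
#' profiled on a ~135,000-probe whole-genome tiling design: probe-level
#' Gaussian noise on log2 ratios, recurrent aberration classes at the
#' frequencies of [default_event_frequencies()], chromothripsis confined to
#' chromosome 13 in roughly 1.2% of patients with 11-18 copy-number
#' switches, binomial sampling of variant reads, and metaphase-adequacy
#' structure (non-informative karyotypes in ~13% of patients).
#'
#' @param n_patients Number of patients to simulate.
#' @param probe_count Total probes genome-wide (default 135000; scale down
#'   for small experiments, keeping at least 2 per chromosome).
#' @param noise_sd Probe-level Gaussian noise standard deviation, log2 units.
#' @param chromothripsis_prevalence Fraction of patients with an implanted
#'   chromothriptic chromosome.
#' @param event_frequency_table Named fractions of patients carrying each
#'   aberration class; see [default_event_frequencies()] for the grammar.
#' @param read_depth Sequencing depth used for binomial VAF sampling.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param chrom_lengths Named chromosome lengths in bp (synthetic genome by
#'   default; a real assembly's lengths may be substituted).
#' @param male_fraction Fraction of male patients.
#' @param non_informative_rate Fraction of patients whose karyotyping fails
#'   (no metaphases).
#' @param cc_visible_min Minimum event size (bp) rendered in the ISCN
#'   karyotype string; smaller events are invisible to banded metaphases.
#' @param chromothripsis_chromosome Chromosome receiving implanted
#'   chromothripsis.
#' @param chromothripsis_switches Integer range (length-2) of implanted
#'   state-switch counts.
#' @param chromothripsis_min_run Minimum probes per implanted chromothripsis
#'   segment.
#' @param germline_cnv_rate Fraction of patients carrying a germline CNV
#'   deletion at a catalogued polymorphic region.
#' @param mutation_given_cryptic_del Probability that a cryptic-deletion
#'   carrier also has a point mutation in the remaining allele of the gene.
#' @param background_mutation_rate Per-patient probability of an unrelated
#'   heterozygous panel-gene mutation.
#' @param exact_counts If TRUE each class gets exactly round(n * fraction)
#'   carriers (stratified cohort construction); if FALSE carriers are drawn
#'   per patient (binomial).
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       probe_count = 135000L,
                       noise_sd = 0.1,
                       chromothripsis_prevalence = 0.012,
                       event_frequency_table = default_event_frequencies(),
                       read_depth = 500L,
                       seed = 1L,
                       chrom_lengths = default_chrom_lengths(),
                       male_fraction = 0.635,
                       non_informative_rate = 0.133,
                       cc_visible_min = 10e6,
                       chromothripsis_chromosome = "chr13",
                       chromothripsis_switches = c(11L, 18L),
                       chromothripsis_min_run = 20L,
                       germline_cnv_rate = 0.2,
                       mutation_given_cryptic_del = 0.5,
                       background_mutation_rate = 0.05,
                       exact_counts = FALSE) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1)
  fracs <- c(chromothripsis_prevalence, event_frequency_table,
             male_fraction, non_informative_rate, germline_cnv_rate,
             mutation_given_cryptic_del, background_mutation_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must lie in [0, 1]")
  if (any(chrom_lengths <= 0))
    stop("zero-length chromosome in `chrom_lengths`")
  if (probe_count < 2L * length(chrom_lengths))
    stop("`probe_count` must be at least 2 per chromosome")
  if (read_depth < 1L) stop("`read_depth` must be >= 1")
  stopifnot(length(chromothripsis_switches) == 2L,
            chromothripsis_switches[1] >= 1L,
            chromothripsis_switches[2] >= chromothripsis_switches[1])
  cfg <- list(n_patients = as.integer(n_patients),
              probe_count = as.integer(probe_count),
              noise_sd = noise_sd,
              chromothripsis_prevalence = chromothripsis_prevalence,
              event_frequency_table = event_frequency_table,
              read_depth = as.integer(read_depth),
              seed = as.integer(seed),
              chrom_lengths = chrom_lengths,
              male_fraction = male_fraction,
              non_informative_rate = non_informative_rate,
              cc_visible_min = cc_visible_min,
              chromothripsis_chromosome = chromothripsis_chromosome,
              chromothripsis_switches = as.integer(chromothripsis_switches),
              chromothripsis_min_run = as.integer(chromothripsis_min_run),
              germline_cnv_rate = germline_cnv_rate,
              mutation_given_cryptic_del = mutation_given_cryptic_del,
              background_mutation_rate = background_mutation_rate,
              exact_counts = isTRUE(exact_counts))
  class(cfg) <- "sim_config"
  cfg
}

#' CNA calling configuration
#'
#' Thresholds and size rules used by segmentation and calling. The calling
#' thresholds sit midway between the noiseless log2 levels of a normal
#' segment (0) and a single-copy change (-1 for one copy, +0.585 for three):
#' a segment mean at or below `loss_threshold` is a one-copy loss, at or
#' above `gain_threshold` a three-copy gain. `cryptic_max` is the inclusive
#' size bound below which a CNA is invisible to banded-metaphase
#' cytogenetics (5 Mb); `followup_min` is the strict lower size bound for
#' flagging panel-gene deletions for targeted sequencing (100 kb).
#'
#' @param loss_threshold Log2-ratio at or below which a segment is a loss.
#' @param gain_threshold Log2-ratio at or above which a segment is a gain.
#' @param min_probes Minimum probes per segment (and per analyzable
#'   chromosome).
#' @param segmentation_penalty Penalty added per changepoint in the penalized
#'   residual-sum-of-squares objective (log2^2 units).
#' @param cnv_overlap_fraction Reciprocal-overlap fraction at or above which
#'   a call is flagged as a germline CNV.
#' @param cryptic_max Inclusive maximum size (bp) of a cryptic CNA.
#' @param followup_min Strict minimum size (bp) of a deletion selected for
#'   sequencing follow-up.
#'
#' @return Object of class `calling_config`.
#' @export
calling_config <- function(loss_threshold = -0.25,
                           gain_threshold = 0.25,
                           min_probes = 5L,
                           segmentation_penalty = 0.4,
                           cnv_overlap_fraction = 0.5,
                           cryptic_max = 5e6,
                           followup_min = 1e5) {
  if (!(loss_threshold < 0 && gain_threshold > 0))
    stop("need loss_threshold < 0 < gain_threshold")
  if (segmentation_penalty <= 0) stop("`segmentation_penalty` must be > 0")
  if (cnv_overlap_fraction <= 0 || cnv_overlap_fraction > 1)
    stop("`cnv_overlap_fraction` must lie in (0, 1]")
  stopifnot(min_probes >= 1L, cryptic_max > 0, followup_min >= 0)
  cfg <- list(loss_threshold = loss_threshold,
              gain_threshold = gain_threshold,
              min_probes = as.integer(min_probes),
              segmentation_penalty = segmentation_penalty,
              cnv_overlap_fraction = cnv_overlap_fraction,
              cryptic_max = cryptic_max,
              followup_min = followup_min)
  class(cfg) <- "calling_config"
  cfg
}

#' Chromothripsis detection configuration
#'
#' A chromosome is called chromothriptic when its segmented copy-number
#' profile shows at least `min_switches` changes of segmental copy state
#' (default 10) oscillating among at most `max_states` distinct copy states
#' (default 3: deletion, normal, gain), evaluated per single chromosome.
#'
#' @param min_switches Minimum state switches for a positive call.
#' @param max_states Maximum distinct copy states allowed (2 or 3).
#' @return Object of class `chromothripsis_config`.
#' @export
chromothripsis_config <- function(min_switches = 10L, max_states = 3L) {
  stopifnot(min_switches >= 1L)
  if (!max_states %in% c(2L, 3L))
    stop("`max_states` must be 2 or 3")
  cfg <- list(min_switches = as.integer(min_switches),
              max_states = as.integer(max_states))
  class(cfg) <- "chromothripsis_config"
  cfg
}
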