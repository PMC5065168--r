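# Shared fixtures, built in code at test time.

# Small full genome (24 chromosomes) with a modest probe count.
small_config <- function(n_patients = 6, probe_count = 2400, ...) {
  sim_config(n_patients = n_patients, probe_count = probe_count, ...)
}

small_model <- function(probe_count = 2400, seed = 1) {
  build_genome_model(small_config(probe_count = probe_count, seed = seed))
}

# One-chromosome probe table with given per-probe log2 values.
probe_frame <- function(values, chrom = "chr1", spacing = 1000) {
  data.frame(chrom = chrom, pos = seq_along(values) * spacing,
             log2ratio = values, stringsAsFactors = FALSE)
}

# Segment table from explicit means (one chromosome, unit-width segments).
segment_frame <- function(means, chrom = "chr1", n_probes = 10,
                          seg_span = 1e6) {
  k <- length(means)
  data.frame(chrom = chrom,
             start = (seq_len(k) - 1) * seg_span,
             end = seq_len(k) * seg_span,
             n_probes = n_probes,
             mean_log2 = means,
             stringsAsFactors = FALSE)
}

# A loss/gain call row with sensible defaults.
call_row <- function(chrom = "chr1", start = 0, end = 1e6,
                     direction = "loss", sample = "P001",
                     config = calling_config()) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             n_probes = 10L,
             mean_log2 = if (direction == "loss") -1 else log2(3 / 2),
             direction = direction,
             copy_state = if (direction == "loss") 1L else 3L,
             size_bp = end - start,
             cryptic = (end - start) <= config$cryptic_max,
             germline_cnv = FALSE, followup = FALSE,
             stringsAsFactors = FALSE)
}

published_mutation_table <- function() {
  load_mutation_table(system.file("extdata", "mds_cohort_mutations.tsv",
                                  package = "karyoshatter"))
}
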