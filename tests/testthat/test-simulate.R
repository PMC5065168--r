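test_that("noise-free profiles equal log2(state/2) exactly", {
  model <- small_model()
  # no events: everything at log2(2/2) = 0
  p0 <- simulate_patient_profile(model, NULL, noise_sd = 0)
  expect_true(all(p0$probes$log2ratio == 0))
  expect_true(all(p0$truth$switch_counts == 0L))

  ev <- data.frame(chrom = c("chr3", "chr6"),
                   start = c(20e6, 30e6), end = c(80e6, 90e6),
                   state = c(1L, 3L))
  p <- simulate_patient_profile(model, ev, noise_sd = 0)
  loss_probes <- p$probes$chrom == "chr3" & p$probes$pos > 20e6 &
    p$probes$pos <= 80e6
  gain_probes <- p$probes$chrom == "chr6" & p$probes$pos > 30e6 &
    p$probes$pos <= 90e6
  expect_true(all(p$probes$log2ratio[loss_probes] == -1))
  expect_true(all(p$probes$log2ratio[gain_probes] == log2(3 / 2)))
  expect_true(all(p$probes$log2ratio[!loss_probes & !gain_probes] == 0))
  expect_equal(unname(p$truth$switch_counts[c("chr3", "chr6")]), c(2L, 2L))
})

test_that("profile simulation validates events and covers every implant", {
  model <- small_model()
  overlapping <- data.frame(chrom = "chr1", start = c(0, 5e6),
                            end = c(10e6, 15e6), state = c(1L, 3L))
  expect_error(simulate_patient_profile(model, overlapping, noise_sd = 0),
               "overlapping")
  # an event between two probes covers none and must be refused
  pos <- model$probes$chr1
  gap <- data.frame(chrom = "chr1", start = pos[1], end = pos[2] - 1,
                    state = 1L)
  expect_error(simulate_patient_profile(model, gap, noise_sd = 0),
               "covers no probe")
  # truth events are snapped to the covered probes
  ev <- data.frame(chrom = "chr2", start = 20e6, end = 60e6, state = 1L)
  p <- simulate_patient_profile(model, ev, noise_sd = 0)
  pos2 <- model$probes$chr2
  covered <- pos2[pos2 > 20e6 & pos2 <= 60e6]
  expect_equal(p$truth$events$start, covered[1] - 1)
  expect_equal(p$truth$events$end, covered[length(covered)])
})

test_that("female patients carry no Y probes and -Y stays male-only", {
  model <- small_model()
  pf <- simulate_patient_profile(model, NULL, noise_sd = 0, sex = "female")
  expect_false("chrY" %in% pf$probes$chrom)
  pm <- simulate_patient_profile(model, NULL, noise_sd = 0, sex = "male")
  expect_true("chrY" %in% pm$probes$chrom)
})

test_that("chromothripsis simulation yields the requested oscillation", {
  model <- small_model(probe_count = 12000)
  # the worked pattern: 18 alternating changes -> 19 segments
  ev <- simulate_chromothripsis_chromosome(model, "chr13", 18, seed = 4,
                                           min_run_probes = 10)
  expect_equal(nrow(ev), 19L)
  expect_true(all(ev$state[-1] != ev$state[-nrow(ev)]))
  expect_equal(oracle_switch_count(ev$state), 18L)

  ev1 <- simulate_chromothripsis_chromosome(model, "chr13", 1, seed = 4,
                                            min_run_probes = 10)
  expect_equal(nrow(ev1), 2L)
  expect_true(ev1$state[1] != ev1$state[2])

  # recounting the probe-level states reproduces the implanted switches
  for (k in c(3, 9, 14)) {
    evk <- simulate_chromothripsis_chromosome(model, "chr13", k,
                                              seed = 40 + k,
                                              min_run_probes = 10)
    states <- oracle_probe_states(model$probes$chr13, evk)
    expect_equal(oracle_switch_count(states), k)
  }
  expect_error(
    simulate_chromothripsis_chromosome(model, "chr13", 10000,
                                       min_run_probes = 10),
    "cannot fit")
  expect_error(
    simulate_chromothripsis_chromosome(model, "chr13", 5,
                                       allowed_states = c(1L)),
    "2 states")
})

test_that("binomial VAF sampling is centred on the true VAF", {
  tv <- data.frame(sample = "S1", gene = "TP53", true_vaf = 50,
                   mutation_type = "missense")
  big_depth <- 200000L
  obs <- simulate_variant_table(tv, big_depth, seed = 9)$vaf_pct
  sd3 <- 3 * 100 * sqrt(0.25 / big_depth)
  expect_lt(abs(obs - 50), sd3 + 0.05)  # one-decimal rounding slack

  # a clonal homozygous variant is always observed at 100%
  tv100 <- data.frame(sample = "S1", gene = "TP53", true_vaf = 100,
                      mutation_type = "nonsense")
  expect_equal(simulate_variant_table(tv100, 10L, seed = 1)$vaf_pct, 100)
  expect_error(simulate_variant_table(
    data.frame(sample = "S", gene = "G", true_vaf = 0,
               mutation_type = "missense"), 10L), "\\(0, 100\\]")

  # table shape and determinism
  t1 <- simulate_variant_table(tv, 500L, seed = 7)
  t2 <- simulate_variant_table(tv, 500L, seed = 7)
  expect_identical(t1, t2)
  expect_named(t1, c("sample", "gene", "cdna_change", "protein_change",
                     "mutation_type", "vaf_pct", "cosmic_id"))
})

test_that("cohorts honour configured prevalences and are reproducible", {
  # an all-quiet configuration produces an all-normal cohort
  quiet <- sim_config(n_patients = 6, probe_count = 1200, noise_sd = 0,
                      chromothripsis_prevalence = 0,
                      event_frequency_table = c("del(5q)" = 0),
                      germline_cnv_rate = 0,
                      background_mutation_rate = 0, seed = 2)
  d <- withr::local_tempdir()
  coh <- simulate_cohort(quiet, file.path(d, "quiet"))
  for (t in coh$truth) {
    expect_equal(sum(t$switch_counts), 0L)
    expect_false(t$chromothripsis)
    expect_true(is.null(t$events) || nrow(t$events) == 0)
  }

  # fixed seed: implanted chromothripsis count reproduces exactly
  cfg <- sim_config(n_patients = 12, probe_count = 6000, noise_sd = 0.1,
                    chromothripsis_prevalence = 0.5,
                    chromothripsis_min_run = 8, seed = 21)
  c1 <- simulate_cohort(cfg, file.path(d, "a"))
  c2 <- simulate_cohort(cfg, file.path(d, "b"))
  n_ct <- function(coh) sum(vapply(coh$truth, `[[`, logical(1),
                                   "chromothripsis"))
  expect_identical(n_ct(c1), n_ct(c2))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$mutations, c2$mutations)
  # byte-identical files
  f <- "probes/P001.tsv"
  expect_identical(readLines(file.path(d, "a", f)),
                   readLines(file.path(d, "b", f)))

  # exclusive class fractions that cannot coexist are rejected
  expect_error(simulate_cohort(
    sim_config(n_patients = 4, probe_count = 1200,
               event_frequency_table = c("cryptic:TET2" = 0.6,
                                         "cryptic:TP53" = 0.6)),
    file.path(d, "bad")), "inconsistent frequencies")
})

test_that("class carrier counts track configured fractions (binomial)", {
  freq <- c("del(5q)" = 0.35, "+8" = 0.15, "cryptic:TET2" = 0.10)
  cfg <- sim_config(n_patients = 301, probe_count = 2400, noise_sd = 0,
                    chromothripsis_prevalence = 0,
                    event_frequency_table = freq,
                    germline_cnv_rate = 0, background_mutation_rate = 0,
                    seed = 8)
  d <- withr::local_tempdir()
  coh <- simulate_cohort(cfg, d)
  classes <- unlist(lapply(coh$truth, function(t)
    if (!is.null(t$events) && nrow(t$events))
      unique(t$events$class) else character(0)))
  n <- cfg$n_patients
  for (class in names(freq)) {
    p <- freq[[class]]
    expect_lt(abs(sum(classes == class) - n * p),
              3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("cohort truth switch counts agree with an independent re-scan", {
  cfg <- sim_config(n_patients = 8, probe_count = 6000, noise_sd = 0.1,
                    chromothripsis_prevalence = 0.4,
                    chromothripsis_min_run = 8, seed = 33)
  d <- withr::local_tempdir()
  coh <- simulate_cohort(cfg, d)
  for (t in coh$truth) {
    ev <- t$events
    if (is.null(ev) || nrow(ev) == 0) next
    for (chrom in unique(ev$chrom)) {
      pos <- coh$model$probes[[chrom]]
      states <- oracle_probe_states(pos, ev[ev$chrom == chrom, ])
      expect_equal(unname(t$switch_counts[chrom]),
                   oracle_switch_count(states))
    }
  }
  # karyotype strings parse and only encode CC-visible somatic events
  for (i in seq_len(nrow(coh$karyotypes))) {
    rec <- parse_iscn(coh$karyotypes$iscn[i])
    tr <- coh$truth[[coh$karyotypes$patient[i]]]
    expect_identical(rec$status, tr$karyotype_status)
    if (rec$status == "non_informative")
      expect_identical(coh$karyotypes$n_metaphases[i], 0L)
  }
})
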