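test_that("CC abnormalities match array calls by direction and overlap", {
  model <- small_model()
  # del(5q) with a same-arm loss call: detected
  rec <- parse_iscn("46,XX,del(5)(q13q33)[20]", patient = "P1")
  qiv <- arm_interval(model, "chr5", "q")
  loss5q <- call_row(chrom = "chr5", start = qiv[1] + 1e6,
                     end = qiv[2] - 1e6)
  res <- match_cc_to_acgh(rec, loss5q, model)
  expect_equal(unname(res$counts["detected"]), 1L)
  # +8 with no chromosome-8 gain: missed
  rec8 <- parse_iscn("47,XY,+8[20]")
  res8 <- match_cc_to_acgh(rec8, loss5q, model)
  expect_equal(unname(res8$counts["missed"]), 1L)
  # a same-position call of the wrong direction does not count
  gain5q <- call_row(chrom = "chr5", start = qiv[1] + 1e6,
                     end = qiv[2] - 1e6, direction = "gain")
  expect_equal(unname(match_cc_to_acgh(rec, gain5q,
                                       model)$counts["missed"]), 1L)
  # balanced translocations are expected to be invisible to the array
  rect <- parse_iscn("46,XY,t(3;3)(q21;q26)[20]")
  rest <- match_cc_to_acgh(rect, loss5q, model)
  expect_equal(unname(rest$counts["expected_undetectable"]), 1L)
  # -Y against a Y-loss call
  recy <- parse_iscn("45,X,-Y[20]")
  lossy <- call_row(chrom = "chrY", start = 0, end = 50e6)
  expect_equal(unname(match_cc_to_acgh(recy, lossy,
                                       model)$counts["detected"]), 1L)
  # unknown chromosome in the karyotype is an error
  tiny <- structure(list(chromosomes = "chr1", lengths = c(chr1 = 1e8),
                         centromeres = c(chr1 = 4e7)),
                    class = "genome_model")
  expect_error(match_cc_to_acgh(rec, loss5q, tiny),
               "absent from genome model")
})

test_that("concordance categories always partition the CC abnormalities", {
  model <- small_model()
  set.seed(91)
  kinds <- c("del(5)(q13q33)", "del(7)(q22q36)", "+8", "-Y",
             "t(3;3)(q21;q26)", "dup(1)(q11q31)")
  for (i in 1:15) {
    tokens <- sample(kinds, sample(1:4, 1))
    iscn <- paste0(paste(c(46, "XY", tokens), collapse = ","), "[20]")
    rec <- parse_iscn(iscn)
    calls <- if (runif(1) < 0.5) call_row(chrom = "chr5",
                                          start = 120e6, end = 150e6)
             else call_row(chrom = "chr5", start = 120e6,
                           end = 150e6)[0, ]
    res <- match_cc_to_acgh(rec, calls, model)
    expect_equal(sum(res$counts), sum(rec$abnormalities$counted))
    expect_equal(nrow(res$per_abnormality),
                 sum(rec$abnormalities$counted))
  }
})

test_that("cohort summaries aggregate fractions and complexity correctly", {
  model <- small_model()
  karyotypes <- data.frame(
    patient = c("P1", "P2", "P3", "P4"),
    iscn = c("46,XY[25]", "46,XX,del(5)(q13q33)[20]", "", "46,XY[12]"),
    n_metaphases = c(25L, 20L, 0L, 12L))
  qiv <- arm_interval(model, "chr5", "q")
  calls <- rbind(call_row(chrom = "chr5", start = qiv[1] + 1e6,
                          end = qiv[2] - 1e6, sample = "P2"),
                 call_row(chrom = "chr4", start = 100e6, end = 101e6,
                          sample = "P3"))
  s <- summarize_cohort(karyotypes, calls, model)
  expect_equal(s$n_patients, 4L)
  expect_equal(unname(s$subgroup_counts),
               c(2L, 1L, 1L))
  expect_equal(s$frac_cna_overall, 0.5)
  expect_equal(unname(s$frac_cna_by_cc),
               c(0, 1, 1))
  expect_equal(s$loss_fraction, 1)       # every call is a loss
  expect_equal(s$n_complex_acgh, 0L)
  expect_equal(s$n_complex_cc, 0L)
  # per-class labels via arm overlap
  classes <- aberration_class(calls, model)
  expect_equal(classes[1], "del(5q)")
  expect_error(summarize_cohort(karyotypes[0, ], calls, model),
               "empty cohort")
})

test_that("association tests match exact enumeration and refuse degeneracy", {
  # identical group distributions: balanced 2x2, p = 1
  outcome <- rep(c("yes", "no"), each = 10)
  group <- rep(c("a", "b"), times = 10)
  res <- association_tests(outcome, group)
  expect_equal(res$p_value, 1)

  # a perfectly separated 2x2 table vs hypergeometric enumeration
  out2 <- c(rep("yes", 10), rep("no", 10))
  grp2 <- c(rep("a", 10), rep("b", 10))
  res2 <- association_tests(out2, grp2)
  tab <- table(factor(out2), factor(grp2))
  expect_equal(res2$p_value, oracle_fisher_2x2(tab), tolerance = 1e-8)

  # continuous outcome goes through the rank-sum route
  res3 <- association_tests(c(1, 2, 3, 10, 11, 12),
                            c("a", "a", "a", "b", "b", "b"))
  expect_match(res3$method, "Wilcoxon")
  expect_lt(res3$p_value, 0.1)

  expect_error(association_tests(1:5, rep("a", 5)), "degenerate")
  expect_error(association_tests(rep("yes", 6), rep(c("a", "b"), 3)),
               "degenerate")
})

test_that("noise-free cohorts reach full concordance minus balanced events", {
  cfg <- sim_config(n_patients = 14, probe_count = 6000, noise_sd = 0,
                    chromothripsis_prevalence = 0,
                    event_frequency_table = c("del(5q)" = 0.4,
                                              "+8" = 0.3, "-Y" = 0.3,
                                              "t(3;3)" = 0.2),
                    germline_cnv_rate = 0, non_informative_rate = 0,
                    seed = 61)
  d <- withr::local_tempdir()
  coh <- simulate_cohort(cfg, d)
  res <- run_pipeline(d, file.path(d, "out"))
  counts <- table(res$concordance$status)
  expect_equal(sum(res$concordance$status == "missed"), 0L)
  n_balanced <- sum(res$concordance$kind == "translocation")
  expect_equal(unname(counts["expected_undetectable"]), n_balanced)
  expect_gt(sum(res$concordance$status == "detected"), 0L)
})
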