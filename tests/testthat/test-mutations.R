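test_that("the published mutation table loads with validated VAFs", {
  tab <- published_mutation_table()
  expect_equal(nrow(tab), 12L)
  row <- tab[tab$sample == "#072", ]
  expect_equal(row$gene, "TP53")
  expect_equal(row$cdna_change, "c.395A>G")
  expect_equal(row$protein_change, "p.Lys132Arg")
  expect_equal(row$mutation_type, "missense")
  expect_equal(row$vaf_pct, 92.5)

  d <- withr::local_tempdir()
  empty <- file.path(d, "empty.tsv")
  writeLines(paste(c("sample", "gene", "cdna_change", "protein_change",
                     "mutation_type", "vaf_pct", "cosmic_id"),
                   collapse = "\t"), empty)
  expect_equal(nrow(load_mutation_table(empty)), 0L)

  bad <- file.path(d, "bad.tsv")
  out <- tab[1:3, ]
  out$vaf_pct[2] <- 101
  write_mutation_table(out, bad)
  expect_error(load_mutation_table(bad), "row\\(s\\): 2")
  expect_error(load_mutation_table(file.path(d, "none.tsv")), "not found")
  trunc <- file.path(d, "trunc.tsv")
  writeLines("sample\tgene", trunc)
  expect_error(load_mutation_table(trunc), "missing columns")
})

test_that("scoring exclusions drop intronic variants and known SNPs", {
  tab <- rbind(published_mutation_table(),
               data.frame(sample = "#900", gene = "TET2",
                          cdna_change = "c.100+5G>A", protein_change = NA,
                          mutation_type = "intronic", vaf_pct = 48,
                          cosmic_id = NA),
               data.frame(sample = "#901", gene = "TP53",
                          cdna_change = "c.215C>G", protein_change = "p.Pro72Arg",
                          mutation_type = "snp", vaf_pct = 51,
                          cosmic_id = "rs1042522"),
               data.frame(sample = "#902", gene = "RUNX1",
                          cdna_change = "c.167T>C", protein_change = "p.Leu56Ser",
                          mutation_type = "missense", vaf_pct = 47,
                          cosmic_id = "rs111527738"))
  kept <- filter_scored_variants(tab, known_snp_ids = "rs111527738")
  expect_equal(nrow(kept), 12L)
  expect_false(any(kept$sample %in% c("#900", "#901", "#902")))
  # missense exonic records without a listed id are retained; idempotent
  expect_identical(filter_scored_variants(kept,
                                          known_snp_ids = "rs111527738"),
                   kept)
})

test_that("zygosity follows the VAF threshold, inclusive at the boundary", {
  tab <- published_mutation_table()
  z <- classify_zygosity(tab, hom_vaf_threshold = 80)
  expect_equal(z$zygosity[z$vaf_pct == 93.5], "homozygous_or_hemizygous")
  expect_equal(z$zygosity[z$vaf_pct == 46.5], "heterozygous")
  at <- classify_zygosity(data.frame(vaf_pct = 80), 80)
  expect_equal(at$zygosity, "homozygous_or_hemizygous")
  # raising the threshold never converts heterozygous -> homozygous
  for (th in c(60, 70, 80, 90, 99)) {
    lo <- classify_zygosity(tab, th)
    hi <- classify_zygosity(tab, th + 1)
    flipped <- lo$zygosity == "heterozygous" &
      hi$zygosity == "homozygous_or_hemizygous"
    expect_false(any(flipped))
  }
})

test_that("zygosity recovery from binomial sampling at depth 500", {
  set.seed(101)
  true_vafs <- sample(c(seq(5, 60, by = 5), seq(90, 100, by = 2.5)),
                      2000, replace = TRUE)
  tv <- data.frame(sample = sprintf("S%04d", 1:2000), gene = "TP53",
                   true_vaf = true_vafs, mutation_type = "missense")
  obs <- simulate_variant_table(tv, 500L)
  z <- classify_zygosity(obs, 80)
  truth <- ifelse(true_vafs >= 80, "homozygous_or_hemizygous",
                  "heterozygous")
  expect_lt(mean(z$zygosity != truth), 0.01)
})

test_that("mutation tables round-trip through disk exactly", {
  tab <- published_mutation_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(tab, path)
  expect_identical(load_mutation_table(path), tab)
})

test_that("biallelic status combines deletions with retained mutations", {
  genes <- data.frame(chrom = c("chr2", "chr4", "chr17"),
                      start = c(25e6, 105e6, 7.5e6),
                      end = c(25.1e6, 105.2e6, 7.6e6),
                      gene = c("DNMT3A", "TET2", "TP53"))
  muts <- classify_zygosity(data.frame(
    sample = "#132", gene = "DNMT3A", cdna_change = "c.1961G>A",
    protein_change = "p.Gly654Asp", mutation_type = "missense",
    vaf_pct = 73.5, cosmic_id = NA))
  del_dnmt3a <- call_row(chrom = "chr2", start = 24.9e6, end = 25.4e6,
                         sample = "#132")
  hit <- biallelic_status("#132", "DNMT3A", del_dnmt3a, muts, genes)
  expect_equal(hit$category, "deletion_plus_mutation")

  del_tet2 <- call_row(chrom = "chr4", start = 104e6, end = 106e6,
                       sample = "#201")
  expect_equal(biallelic_status("#201", "TET2", del_tet2, muts,
                                genes)$category, "deletion_only")
  expect_equal(biallelic_status("#132", "TP53", NULL, muts,
                                genes)$category, "wild_type")
  expect_equal(biallelic_status("#132", "DNMT3A", NULL, muts,
                                genes)$category, "mutation_only")
  # a deletion elsewhere on the chromosome does not hit the gene
  far <- call_row(chrom = "chr2", start = 90e6, end = 95e6,
                  sample = "#132")
  expect_equal(biallelic_status("#132", "DNMT3A", far, muts,
                                genes)$category, "mutation_only")
  expect_error(biallelic_status("#132", "NOPE", NULL, muts, genes),
               "unknown gene")
})

test_that("minimal deleted regions are exact interval intersections", {
  one <- data.frame(chrom = "chr4", start = 100, end = 500)
  m1 <- minimal_deleted_region(one, label = "TET2")
  expect_false(m1$absent)
  expect_equal(c(m1$start, m1$end), c(100, 500))
  expect_equal(m1$n_supporting, 1L)

  two <- rbind(one, data.frame(chrom = "chr4", start = 300, end = 900))
  m2 <- minimal_deleted_region(two)
  expect_equal(c(m2$start, m2$end), c(300, 500))
  expect_equal(m2$size_bp, 200)

  disjoint <- data.frame(chrom = "chr4", start = c(0, 200),
                         end = c(100, 300))
  m3 <- minimal_deleted_region(disjoint)
  expect_true(m3$absent)
  expect_null(m3$size_bp)

  expect_error(minimal_deleted_region(one[0, ]), "at least one")
  expect_error(minimal_deleted_region(
    data.frame(chrom = c("chr1", "chr2"), start = 0, end = 10)),
    "one chromosome")
})

test_that("an MDR is contained in every supporting deletion", {
  set.seed(55)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    starts <- sample(0:50, k, replace = TRUE) * 1e4
    ends <- starts + sample(5:40, k, replace = TRUE) * 1e4
    dels <- data.frame(chrom = "chr7", start = starts, end = ends)
    m <- minimal_deleted_region(dels)
    if (!m$absent) {
      expect_true(all(m$start >= dels$start & m$end <= dels$end))
      # adding a deletion never widens the region
      extra <- rbind(dels, data.frame(chrom = "chr7", start = 1e5,
                                      end = 6e5))
      m2 <- minimal_deleted_region(extra)
      if (!m2$absent) {
        expect_gte(m2$start, m$start)
        expect_lte(m2$end, m$end)
      }
    }
  }
})
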