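.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Orchestrates every stage end-to-end on a directory laid out as written
#' by [simulate_cohort()] (real data in the same formats works the same
#' way): per-patient probe tables are segmented and CNAs called; germline
#' CNVs are flagged by reciprocal overlap with the catalogue BED and
#' excluded from somatic counts; chromothripsis is evaluated per
#' chromosome and shared affected genes reported for chromosomes positive
#' in at least one patient; the mutation table is filtered, zygosity
#' classified, biallelic status resolved against panel-gene deletions and
#' minimal deleted regions intersected across patients; karyotypes are
#' parsed and matched against the array calls; and a cohort summary with
#' association tests is assembled. All outputs are plain text
#' (SEG/TSV/JSON) and bit-stable given identical inputs; the configuration
#' used is stored alongside them.
#'
#' @param input_dir Cohort directory (probes/, karyotypes.tsv,
#'   mutations.tsv, genes.bed, panel_genes.bed, cnv_regions.bed,
#'   genome.json).
#' @param out_dir Output directory (created).
#' @param calling A [calling_config()].
#' @param chromo A [chromothripsis_config()].
#' @param hom_vaf_threshold VAF percent bound for
#'   homozygous-or-hemizygous classification.
#' @param known_snp_ids Identifiers of known polymorphisms to exclude.
#' @param verbose Emit per-stage record counts via [message()].
#' @return Invisibly, a list with segments, calls, chromothripsis,
#'   shared_genes, mutations (classified), biallelic, mdr, concordance,
#'   summary, patients.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         calling = calling_config(),
                         chromo = chromothripsis_config(),
                         hom_vaf_threshold = 80,
                         known_snp_ids = character(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  path <- function(...) file.path(input_dir, ...)
  for (f in c("karyotypes.tsv", "mutations.tsv", "genes.bed",
              "panel_genes.bed", "genome.json"))
    if (!file.exists(path(f))) stop("missing input file: ", path(f))
  model <- .with_stage("load_inputs", read_genome_model(path("genome.json")))
  genes <- .with_stage("load_inputs", {
    g <- read_bed_intervals(path("genes.bed")); names(g)[4] <- "gene"; g
  })
  panel <- .with_stage("load_inputs", {
    g <- read_bed_intervals(path("panel_genes.bed"))
    names(g)[4] <- "gene"; g
  })
  cnv_regions <- if (file.exists(path("cnv_regions.bed")))
    read_bed_intervals(path("cnv_regions.bed")) else NULL
  karyotypes <- read_karyotype_table(path("karyotypes.tsv"))
  patients_tab <- if (file.exists(path("patients.tsv")))
    read.delim(path("patients.tsv"), stringsAsFactors = FALSE) else NULL
  ids <- karyotypes$patient
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # segmentation + calling, per patient
  seg_list <- list(); call_list <- list()
  for (id in ids) {
    pf <- path("probes", paste0(id, ".tsv"))
    if (!file.exists(pf))
      stop("stage segmentation: probe file not found for patient ", id,
           ": ", pf, call. = FALSE)
    probes <- .with_stage("segmentation", read_probe_table(pf))
    seg <- .with_stage("segmentation", segment_profile(probes, calling))
    seg$sample <- id
    seg_list[[id]] <- seg
    calls <- .with_stage("cna_calling", {
      x <- call_cnas(seg, calling)
      x <- filter_germline_cnv(x, cnv_regions, calling)
      select_for_sequencing(x, panel, calling)
    })
    call_list[[id]] <- calls
  }
  segments <- do.call(rbind, seg_list); rownames(segments) <- NULL
  calls <- do.call(rbind, call_list); rownames(calls) <- NULL
  somatic <- retained_calls(calls)
  say("cna_calling: ", nrow(calls), " calls, ", nrow(somatic),
      " somatic after CNV filtering")

  # chromothripsis
  ct <- .with_stage("chromothripsis", {
    rows <- lapply(ids, function(id)
      detect_chromothripsis(seg_list[[id]], chromo, calling, sample = id))
    do.call(rbind, rows)
  })
  pos <- ct[ct$positive, , drop = FALSE]
  shared <- list()
  for (chrom in unique(pos$chrom)) {
    pats <- pos$sample[pos$chrom == chrom]
    seg_by_pat <- lapply(pats, function(id) {
      s <- seg_list[[id]]
      s[s$chrom == chrom, , drop = FALSE]
    })
    names(seg_by_pat) <- pats
    sg <- .with_stage("chromothripsis",
                      shared_affected_genes(seg_by_pat, genes, calling))
    shared[[chrom]] <- list(chromosome = chrom, patients = pats,
                            n_shared = sum(sg$shared),
                            genes = sg[sg$shared, , drop = FALSE])
  }
  say("chromothripsis: ", nrow(pos), " positive chromosome(s)")

  # mutation integration
  mut <- .with_stage("mutation_integration", {
    m <- load_mutation_table(path("mutations.tsv"))
    m <- filter_scored_variants(m, known_snp_ids)
    classify_zygosity(m, hom_vaf_threshold)
  })
  biallelic <- .with_stage("mutation_integration", {
    rows <- list()
    for (id in ids) {
      pc <- somatic[somatic$sample == id & somatic$direction == "loss", ,
                    drop = FALSE]
      for (g in unique(panel$gene)) {
        row <- biallelic_status(id, g, pc, mut, panel)
        if (row$category != "wild_type")
          rows[[length(rows) + 1L]] <- row
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(patient = character(), gene = character(),
                    category = character(), n_deletions = integer(),
                    n_mutations = integer())
  })
  mdr <- .with_stage("mutation_integration", {
    out <- list()
    for (g in unique(panel$gene)) {
      gi <- panel[panel$gene == g, ][1, ]
      losses <- somatic[somatic$direction == "loss" &
                          somatic$chrom == gi$chrom &
                          somatic$start < gi$end &
                          somatic$end > gi$start, , drop = FALSE]
      if (nrow(losses) == 0) next
      out[[g]] <- minimal_deleted_region(losses, label = g)
    }
    out
  })
  say("mutation_integration: ", nrow(mut), " scored variants, ",
      nrow(biallelic), " non-wild-type gene states, ",
      length(mdr), " minimal deleted regions")

  # cytogenetic concordance
  concordance <- .with_stage("concordance", {
    rows <- list()
    for (i in seq_len(nrow(karyotypes))) {
      rec <- parse_iscn(karyotypes$iscn[i], patient = karyotypes$patient[i])
      m <- match_cc_to_acgh(
        rec, somatic[somatic$sample == rec$patient, , drop = FALSE], model)
      if (nrow(m$per_abnormality))
        rows[[length(rows) + 1L]] <- cbind(patient = rec$patient,
                                           m$per_abnormality)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(patient = character(), token = character(),
                    kind = character(), status = character())
  })
  summary <- .with_stage("summary",
                         summarize_cohort(karyotypes, somatic, model, panel))
  assoc <- NULL
  if (!is.null(patients_tab) &&
      all(c("age", "risk_group") %in% names(patients_tab))) {
    ord <- match(ids, patients_tab$patient)
    abnormal <- summary$patients$abnormal_acgh
    assoc <- .with_stage("summary", list(
      risk_vs_acgh = if (length(unique(patients_tab$risk_group[ord])) > 1)
        association_tests(abnormal, patients_tab$risk_group[ord]) else NULL,
      age_vs_acgh = if (length(unique(abnormal)) > 1)
        association_tests(patients_tab$age[ord], abnormal) else NULL))
  }

  # reports
  reports <- lapply(ids, function(id)
    render_patient_report(id, ct, somatic, mut, biallelic))
  names(reports) <- ids

  # outputs
  write_seg(segments, file.path(out_dir, "segments.seg"))
  write.table(calls, file.path(out_dir, "cna_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ct, file.path(out_dir, "chromothripsis_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(shared,
                       file.path(out_dir, "chromothripsis_shared_genes.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(mut, file.path(out_dir, "zygosity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write.table(biallelic, file.path(out_dir, "biallelic_status.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(mdr, unclass),
                       file.path(out_dir, "mdr.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(concordance, file.path(out_dir, "concordance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_patients = summary$n_patients,
         subgroup_counts = as.list(summary$subgroup_counts),
         frac_cna_overall = summary$frac_cna_overall,
         frac_cna_by_cc = as.list(summary$frac_cna_by_cc),
         frac_cna_by_adequacy = as.list(summary$frac_cna_by_adequacy),
         n_calls = summary$n_calls,
         loss_fraction = summary$loss_fraction,
         gain_fraction = summary$gain_fraction,
         class_frequencies = as.list(summary$class_frequencies),
         n_complex_cc = summary$n_complex_cc,
         n_complex_acgh = summary$n_complex_acgh,
         concordance_totals = as.list(table(concordance$status)),
         associations = lapply(Filter(Negate(is.null), assoc), function(a)
           list(method = a$method, p_value = a$p_value))),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(reports, file.path(out_dir, "patient_reports.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("karyoshatter")),
         input_dir = input_dir,
         calling = unclass(calling), chromothripsis = unclass(chromo),
         hom_vaf_threshold = hom_vaf_threshold,
         known_snp_ids = known_snp_ids),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(segments = segments, calls = calls,
                 chromothripsis = ct, shared_genes = shared,
                 mutations = mut, biallelic = biallelic, mdr = mdr,
                 concordance = concordance, summary = summary,
                 associations = assoc, patients = summary$patients,
                 reports = reports))
}

#' Render a per-patient report
#'
#' Assembles the quantities a per-patient array report presents:
#' per-chromosome copy-state switch counts, chromothripsis-positive
#' chromosomes, somatic CNAs with 1-based inclusive coordinates, mutation
#' zygosity and biallelic gene status. Patients with no somatic findings
#' are reported as a normal array profile.
#'
#' @param patient Patient id.
#' @param chromothripsis Chromothripsis call table (all patients).
#' @param somatic Somatic call table (all patients).
#' @param mutations Classified mutation table.
#' @param biallelic Biallelic status table.
#' @return List (JSON-ready).
#' @export
render_patient_report <- function(patient, chromothripsis, somatic,
                                  mutations, biallelic) {
  ct <- chromothripsis[chromothripsis$sample == patient, , drop = FALSE]
  calls <- somatic[somatic$sample == patient, , drop = FALSE]
  mut <- mutations[mutations$sample == patient, , drop = FALSE]
  bi <- biallelic[biallelic$patient == patient, , drop = FALSE]
  cna_rows <- if (nrow(calls)) lapply(seq_len(nrow(calls)), function(i)
    list(chrom = calls$chrom[i],
         start_1based = calls$start[i] + 1,
         end_1based = calls$end[i],
         direction = calls$direction[i],
         copy_state = calls$copy_state[i],
         size_bp = calls$size_bp[i],
         cryptic = calls$cryptic[i],
         followup = calls$followup[i])) else list()
  list(patient = patient,
       profile = if (nrow(calls) == 0 && !any(ct$positive))
         "normal aCGH profile" else "abnormal aCGH profile",
       switch_counts = stats::setNames(as.list(ct$n_state_switches),
                                       ct$chrom),
       chromothripsis_chromosomes = ct$chrom[ct$positive],
       cnas = cna_rows,
       mutations = if (nrow(mut)) lapply(seq_len(nrow(mut)), function(i)
         list(gene = mut$gene[i], vaf_pct = mut$vaf_pct[i],
              zygosity = mut$zygosity[i])) else list(),
       biallelic = if (nrow(bi)) lapply(seq_len(nrow(bi)), function(i)
         list(gene = bi$gene[i], category = bi$category[i])) else list())
}
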