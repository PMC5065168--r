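#' Simulate one patient's probe-level aCGH profile
#'
#' Implants copy-number events on a diploid baseline and measures every
#' probe as `log2(copy_state / 2)` plus i.i.d. Gaussian noise: one copy
#' gives -1, two copies 0, three copies log2(3/2). Female patients carry no
#' Y probes. The returned truth snaps each event to the probes it covers
#' (the finest interval any array analysis can recover) and records the
#' per-chromosome state-switch count by run-length encoding of the
#' probe-state sequence.
#'
#' @param model A `genome_model`.
#' @param events Data frame of non-overlapping events: chrom, start, end
#'   (0-based half-open), state (1, 2 or 3); optional class / germline
#'   columns are carried into the truth.
#' @param noise_sd Gaussian noise SD in log2 units.
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used (as in [simulate_cohort()]).
#' @param sex "male" or "female".
#' @return List: `probes` (chrom, pos, log2ratio) and `truth` (list with
#'   probe-aligned `events` and named `switch_counts`).
#' @export
simulate_patient_profile <- function(model, events, noise_sd = 0.1,
                                     seed = NULL, sex = "male") {
  stopifnot(inherits(model, "genome_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events))
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), state = integer())
  if (nrow(events)) {
    if (!all(events$state %in% 1:3))
      stop("event states must be 1, 2 or 3")
    for (chrom in unique(events$chrom)) {
      ev <- events[events$chrom == chrom, , drop = FALSE]
      ev <- ev[order(ev$start), , drop = FALSE]
      if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)]))
        stop("overlapping events on ", chrom)
    }
  }
  chroms <- model$chromosomes
  if (identical(sex, "female")) chroms <- setdiff(chroms, "chrY")
  truth_rows <- list()
  probe_list <- vector("list", length(chroms))
  switch_counts <- integer(length(chroms))
  names(switch_counts) <- chroms
  for (k in seq_along(chroms)) {
    chrom <- chroms[k]
    pos <- model$probes[[chrom]]
    states <- rep(2L, length(pos))
    ev <- events[events$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      covered <- which(pos > ev$start[i] & pos <= ev$end[i])
      if (length(covered) == 0)
        stop("event ", chrom, ":", ev$start[i], "-", ev$end[i],
             " covers no probe")
      states[covered] <- ev$state[i]
      tr <- ev[i, , drop = FALSE]
      tr$start <- pos[covered[1]] - 1
      tr$end <- pos[covered[length(covered)]]
      truth_rows[[length(truth_rows) + 1L]] <- tr
    }
    switch_counts[k] <- count_state_switches(states)
    lr <- log2(states / 2)
    if (noise_sd > 0) lr <- lr + rnorm(length(pos), 0, noise_sd)
    probe_list[[k]] <- data.frame(chrom = chrom, pos = pos,
                                  log2ratio = lr,
                                  stringsAsFactors = FALSE)
  }
  truth_events <- if (length(truth_rows)) do.call(rbind, truth_rows)
                  else events[0, , drop = FALSE]
  rownames(truth_events) <- NULL
  list(probes = do.call(rbind, probe_list),
       truth = list(events = truth_events, switch_counts = switch_counts,
                    sex = sex))
}

#' Simulate a chromothriptic chromosome
#'
#' Partitions a chromosome's probes into `n_switches + 1` contiguous
#' segments (each spanning at least `min_run_probes` probes) and assigns
#' copy states from `allowed_states` such that adjacent segments always
#' differ - the oscillating pattern characteristic of chromothripsis. By
#' construction the run-length-encoded switch count equals `n_switches`
#' exactly.
#'
#' @param model A `genome_model`.
#' @param chromosome Chromosome to shatter.
#' @param n_switches Number of copy-state switches (>= 1).
#' @param allowed_states Subset of c(1, 2, 3).
#' @param seed Optional seed (NULL: current RNG stream).
#' @param min_run_probes Minimum probes per segment.
#' @return Data frame of contiguous events (chrom, start, end, state)
#'   covering the chromosome; normal-state (2) segments included.
#' @export
simulate_chromothripsis_chromosome <- function(model, chromosome,
                                               n_switches,
                                               allowed_states = c(1L, 2L, 3L),
                                               seed = NULL,
                                               min_run_probes = 20L) {
  stopifnot(inherits(model, "genome_model"), n_switches >= 1)
  if (!all(allowed_states %in% 1:3) || length(allowed_states) < 2)
    stop("`allowed_states` must be >= 2 states from {1, 2, 3}")
  if (!is.null(seed)) set.seed(seed)
  pos <- model$probes[[chromosome]]
  if (is.null(pos)) stop("chromosome not in genome model: ", chromosome)
  n_seg <- n_switches + 1L
  if (n_seg * min_run_probes > length(pos))
    stop("chromosome ", chromosome, " has ", length(pos),
         " probes; cannot fit ", n_seg, " segments of >= ",
         min_run_probes, " probes")
  extra <- length(pos) - n_seg * min_run_probes
  add <- if (extra > 0) tabulate(sample.int(n_seg, extra, replace = TRUE),
                                 n_seg) else integer(n_seg)
  runs <- min_run_probes + add
  stops <- cumsum(runs)
  starts <- stops - runs + 1L
  states <- integer(n_seg)
  states[1] <- sample(allowed_states, 1L)
  for (i in seq_len(n_seg - 1L))
    states[i + 1L] <- sample(rep(setdiff(allowed_states, states[i]), 2L), 1L)
  data.frame(chrom = chromosome,
             start = pos[starts] - 1,
             end = pos[stops],
             state = states,
             stringsAsFactors = FALSE)
}

#' Simulate an observed mutation table by binomial read sampling
#'
#' For each true variant, the observed VAF is `100 * Binomial(depth,
#' true_vaf / 100) / depth` (rounded to one decimal), emitted in the shape
#' of a published targeted-sequencing summary table with synthetic
#' HGVS-like labels.
#'
#' @param truth_variants Data frame: sample, gene, true_vaf (percent in
#'   (0, 100]), mutation_type; optional zygosity carried through is NOT
#'   emitted (it lives in the cohort truth).
#' @param read_depth Binomial depth (>= 1).
#' @param seed Optional seed (NULL: current RNG stream).
#' @return Mutation data frame with the standard columns (see
#'   [load_mutation_table()]).
#' @export
simulate_variant_table <- function(truth_variants, read_depth,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(read_depth >= 1)
  n <- nrow(truth_variants)
  empty <- data.frame(sample = character(), gene = character(),
                      cdna_change = character(), protein_change = character(),
                      mutation_type = character(), vaf_pct = numeric(),
                      cosmic_id = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  if (any(truth_variants$true_vaf <= 0 | truth_variants$true_vaf > 100))
    stop("true VAF must lie in (0, 100]")
  reads <- rbinom(n, read_depth, truth_variants$true_vaf / 100)
  obs <- round(100 * reads / read_depth, 1)
  idx <- seq_len(n)
  protein <- vapply(idx, function(i) {
    switch(truth_variants$mutation_type[i],
           nonsense = sprintf("p.Gln%d*", 100 + i),
           frameshift = sprintf("p.Leu%dfs*12", 100 + i),
           sprintf("p.Ala%dThr", 100 + i))
  }, character(1))
  data.frame(sample = truth_variants$sample,
             gene = truth_variants$gene,
             cdna_change = sprintf("c.%dA>G", 300 + 3 * idx),
             protein_change = protein,
             mutation_type = truth_variants$mutation_type,
             vaf_pct = obs,
             cosmic_id = NA_character_,
             stringsAsFactors = FALSE)
}

# ---- cohort assembly ---------------------------------------------------

# interval + state for a named large-aberration class, or NULL for
# karyotype-only classes (balanced translocations)
.class_event <- function(class, model) {
  arm_ev <- function(chrom, arm, state) {
    iv <- arm_interval(model, chrom, arm)
    span <- iv[2] - iv[1]
    # inset from the arm boundaries so breakpoints are interstitial
    data.frame(chrom = chrom, start = round(iv[1] + 0.03 * span),
               end = round(iv[2] - 0.03 * span), state = state,
               stringsAsFactors = FALSE)
  }
  whole_ev <- function(chrom, state)
    data.frame(chrom = chrom, start = 0, end = model$lengths[[chrom]],
               state = state, stringsAsFactors = FALSE)
  m <- regmatches(class, regexec("^del\\(([0-9XY]+)([pq])\\)$", class))[[1]]
  if (length(m)) return(arm_ev(paste0("chr", m[2]), m[3], 1L))
  m <- regmatches(class, regexec("^dup\\(([0-9XY]+)([pq])\\)$", class))[[1]]
  if (length(m)) return(arm_ev(paste0("chr", m[2]), m[3], 3L))
  m <- regmatches(class, regexec("^\\+([0-9XY]+)$", class))[[1]]
  if (length(m)) return(whole_ev(paste0("chr", m[2]), 3L))
  if (class == "-Y") return(whole_ev("chrY", 1L))
  if (grepl("^t\\(", class)) return(NULL)
  m <- regmatches(class, regexec("^cryptic:(\\S+)$", class))[[1]]
  if (length(m)) return(.cryptic_event(m[2], model))
  stop("unrecognized aberration class: ", class)
}

# small deletion centred on a panel gene, spanning 7-12 consecutive probes
# and at least 150 kb (so it qualifies for sequencing follow-up)
.cryptic_event <- function(gene, model) {
  gi <- model$genes[model$genes$gene == gene, , drop = FALSE]
  if (nrow(gi) == 0) stop("unknown gene for cryptic event: ", gene)
  chrom <- gi$chrom[1]
  pos <- model$probes[[chrom]]
  mid <- (gi$start[1] + gi$end[1]) / 2
  i0 <- which.min(abs(pos - mid))
  k <- sample(7:12, 1L)
  repeat {
    i1 <- max(1L, i0 - k %/% 2L)
    i2 <- min(length(pos), i1 + k - 1L)
    if (pos[i2] - pos[i1] >= 1.5e5 || i2 - i1 + 1L >= length(pos)) break
    k <- k + 1L
  }
  data.frame(chrom = chrom, start = pos[i1] - 1, end = pos[i2],
             state = 1L, stringsAsFactors = FALSE)
}

# carriers per class: binomial per patient, or exactly round(n * p)
.draw_carriers <- function(n, p, exact, eligible = seq_len(n)) {
  if (exact) {
    k <- min(round(p * n), length(eligible))
    if (k == 0) return(integer(0))
    sort(eligible[sample.int(length(eligible), k)])
  } else {
    eligible[runif(length(eligible)) < p]
  }
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Generates, deterministically from `config$seed`, a cohort with the
#' statistical structure the downstream analysis assumes: per-patient
#' probe-level log2-ratio tables; recurrent large and cryptic aberrations
#' at the configured class frequencies; chromothriptic chromosomes with a
#' controlled number of state switches; germline-CNV carriers at
#' catalogued regions; ISCN karyotype strings that encode only events
#' large enough to be visible on banded metaphases (non-informative
#' patients emit no metaphases); and a mutation table drawn by binomial
#' read sampling (chromothripsis patients carry TP53 mutations; a fraction
#' of cryptic-deletion carriers bear a high-VAF mutation on the remaining
#' allele). The complete implant truth is stored alongside.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created). Files written: one probe
#'   table per patient under `probes/`, `patients.tsv`, `karyotypes.tsv`,
#'   `mutations.tsv`, `genes.bed`, `panel_genes.bed`, `cnv_regions.bed`,
#'   `genome.json`, `truth.json`, `sim_config.json`.
#' @return Invisibly, a list with `model`, `truth` (per patient),
#'   `patients`, `karyotypes`, `mutations` and `dir`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  freq <- config$event_frequency_table
  excl <- freq[grepl("^cryptic:", names(freq))]
  if (sum(excl) > 1)
    stop("inconsistent frequencies: exclusive cryptic classes sum to > 1")
  set.seed(config$seed)
  model <- build_genome_model(config)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  age <- pmin(93, pmax(11, round(rnorm(n, 77, 10))))

  ct_carriers <- .draw_carriers(n, config$chromothripsis_prevalence,
                                config$exact_counts)
  class_carriers <- lapply(names(freq), function(class) {
    eligible <- if (class == "-Y") which(sex == "male") else seq_len(n)
    p <- if (class == "-Y") freq[[class]] * n / max(1, length(eligible))
         else freq[[class]]
    .draw_carriers(n, min(1, p), config$exact_counts, eligible)
  })
  names(class_carriers) <- names(freq)
  cnv_carriers <- .draw_carriers(n, config$germline_cnv_rate,
                                 config$exact_counts)

  truth <- vector("list", n)
  names(truth) <- ids
  karyo_rows <- vector("list", n)
  variant_rows <- list()
  probes_dir <- file.path(out_dir, "probes")
  dir.create(probes_dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(n)) {
    events <- list()
    classes <- character()
    kar_tokens <- character()
    has_ct <- i %in% ct_carriers
    if (has_ct) {
      sw_range <- seq(config$chromothripsis_switches[1],
                      config$chromothripsis_switches[2])
      nsw <- sw_range[sample.int(length(sw_range), 1L)]
      ct_ev <- simulate_chromothripsis_chromosome(
        model, config$chromothripsis_chromosome, nsw,
        min_run_probes = config$chromothripsis_min_run)
      ct_ev$class <- "chromothripsis"
      ct_ev$germline <- FALSE
      events[[length(events) + 1L]] <- ct_ev
    }
    for (class in names(freq)) {
      if (!(i %in% class_carriers[[class]])) next
      ev <- .class_event(class, model)
      if (is.null(ev)) {                       # balanced translocation
        classes <- c(classes, class)
        kar_tokens <- c(kar_tokens, paste0(class, "(q21;q26)"))
        next
      }
      if (has_ct && ev$chrom[1] == config$chromothripsis_chromosome) next
      prior <- if (length(events)) do.call(rbind, lapply(events, function(e)
        e[c("chrom", "start", "end")])) else NULL
      clash <- !is.null(prior) &&
        any(prior$chrom == ev$chrom & prior$start < ev$end &
              prior$end > ev$start)
      if (clash) next
      ev$class <- class
      ev$germline <- FALSE
      events[[length(events) + 1L]] <- ev
      classes <- c(classes, class)
    }
    if (i %in% cnv_carriers && !is.null(model$cnv_regions)) {
      reg <- model$cnv_regions[sample.int(nrow(model$cnv_regions), 1L), ]
      pos <- model$probes[[reg$chrom]]
      ev <- data.frame(chrom = reg$chrom,
                       start = pos[reg$probe_from] - 1,
                       end = pos[reg$probe_to],
                       state = 1L, class = "germline_cnv",
                       germline = TRUE, stringsAsFactors = FALSE)
      prior <- if (length(events)) do.call(rbind, lapply(events, function(e)
        e[c("chrom", "start", "end")])) else NULL
      clash <- !is.null(prior) &&
        any(prior$chrom == ev$chrom & prior$start < ev$end &
              prior$end > ev$start)
      if (!clash) events[[length(events) + 1L]] <- ev
    }
    events_df <- if (length(events)) do.call(rbind, events) else NULL
    prof <- simulate_patient_profile(model, events_df,
                                     noise_sd = config$noise_sd,
                                     sex = sex[i])
    write_probe_table(prof$probes,
                      file.path(probes_dir, paste0(ids[i], ".tsv")))
    tev <- prof$truth$events
    somatic <- if (is.null(tev) || nrow(tev) == 0) tev
               else tev[!tev$germline & tev$state != 2L, , drop = FALSE]

    # karyotype: only CC-visible somatic events make it into the ISCN string
    non_informative <- runif(1) < config$non_informative_rate
    if (!is.null(somatic) && nrow(somatic)) {
      for (j in seq_len(nrow(somatic))) {
        span <- somatic$end[j] - somatic$start[j]
        chrom <- somatic$chrom[j]
        whole <- span >= 0.9 * model$lengths[[chrom]]
        if (!whole && span < config$cc_visible_min) next
        num <- sub("^chr", "", chrom)
        tok <- if (whole && somatic$state[j] == 3L) paste0("+", num)
          else if (whole && chrom == "chrY") "-Y"
          else if (whole) paste0("-", num)
          else {
            cent <- model$centromeres[[chrom]]
            midp <- (somatic$start[j] + somatic$end[j]) / 2
            arm <- if (midp < cent) "p" else "q"
            paste0(if (somatic$state[j] == 1L) "del(" else "dup(",
                   num, ")(", arm, "11", arm, "31)")
          }
        kar_tokens <- c(kar_tokens, tok)
      }
    }
    kar_tokens <- unique(kar_tokens)
    if (non_informative) {
      iscn <- ""
      n_meta <- 0L
    } else {
      band <- sample(c("ge20", "m11_19", "le10"), 1L,
                     prob = c(164, 38, 14) / 216)
      n_meta <- switch(band, ge20 = sample(20:30, 1L),
                       m11_19 = sample(11:19, 1L),
                       le10 = sample(2:10, 1L))
      sex_tok <- if (sex[i] == "male") "XY" else "XX"
      if (length(kar_tokens)) {
        kinds_tri <- sum(grepl("^\\+[0-9XY]+$", kar_tokens))
        kinds_mono <- sum(grepl("^-[0-9XY]+$", kar_tokens))
        modal <- 46L + kinds_tri - kinds_mono
        clone_sex <- if ("-Y" %in% kar_tokens) "X" else sex_tok
        iscn <- paste0(paste(c(modal, clone_sex, kar_tokens),
                             collapse = ","), "[", n_meta, "]")
      } else {
        iscn <- paste0("46,", sex_tok, "[", n_meta, "]")
      }
    }
    karyo_rows[[i]] <- data.frame(patient = ids[i], iscn = iscn,
                                  n_metaphases = n_meta,
                                  stringsAsFactors = FALSE)

    # variant truth
    pvars <- list()
    if (has_ct) {
      if (runif(1) < 1 / 3) {
        pvars[[length(pvars) + 1L]] <- data.frame(
          sample = ids[i], gene = "TP53",
          true_vaf = c(46.5, 43.5),
          mutation_type = c("nonsense", "missense"),
          zygosity = "heterozygous", stringsAsFactors = FALSE)
      } else {
        pvars[[length(pvars) + 1L]] <- data.frame(
          sample = ids[i], gene = "TP53", true_vaf = 93.5,
          mutation_type = sample(c("nonsense", "missense"), 1L),
          zygosity = "homozygous_or_hemizygous", stringsAsFactors = FALSE)
      }
    }
    for (class in classes[grepl("^cryptic:", classes)]) {
      if (runif(1) < config$mutation_given_cryptic_del) {
        pvars[[length(pvars) + 1L]] <- data.frame(
          sample = ids[i], gene = sub("^cryptic:", "", class),
          true_vaf = 90,
          mutation_type = sample(c("missense", "nonsense", "frameshift"), 1L),
          zygosity = "homozygous_or_hemizygous", stringsAsFactors = FALSE)
      }
    }
    if (runif(1) < config$background_mutation_rate) {
      pvars[[length(pvars) + 1L]] <- data.frame(
        sample = ids[i], gene = sample(model$panel_genes, 1L),
        true_vaf = 45, mutation_type = "missense",
        zygosity = "heterozygous", stringsAsFactors = FALSE)
    }
    pvars <- if (length(pvars)) do.call(rbind, pvars) else NULL
    if (!is.null(pvars)) variant_rows[[length(variant_rows) + 1L]] <- pvars

    any_somatic <- !is.null(somatic) && nrow(somatic) > 0
    truth[[i]] <- list(
      patient = ids[i], sex = sex[i], age = age[i],
      events = tev,
      switch_counts = prof$truth$switch_counts,
      chromothripsis = has_ct,
      chromothripsis_chromosome =
        if (has_ct) config$chromothripsis_chromosome else NA_character_,
      chromothripsis_switches =
        if (has_ct) unname(prof$truth$switch_counts[
          config$chromothripsis_chromosome]) else 0L,
      variants = pvars,
      karyotype_status = if (n_meta == 0L) "non_informative"
                         else if (length(kar_tokens)) "abnormal"
                         else "normal",
      any_somatic_event = any_somatic)
  }

  risk <- ifelse(runif(n) < ifelse(vapply(truth, `[[`, logical(1),
                                          "any_somatic_event"),
                                   0.5, 0.15), "high", "low")
  patients <- data.frame(patient = ids, sex = sex, age = age,
                         risk_group = risk, stringsAsFactors = FALSE)
  for (i in seq_len(n)) truth[[i]]$risk_group <- risk[i]

  karyotypes <- do.call(rbind, karyo_rows)
  variants <- if (length(variant_rows)) do.call(rbind, variant_rows)
              else data.frame(sample = character(), gene = character(),
                              true_vaf = numeric(),
                              mutation_type = character(),
                              zygosity = character())
  mutations <- simulate_variant_table(variants, config$read_depth)

  write.table(patients, file.path(out_dir, "patients.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_karyotype_table(karyotypes, file.path(out_dir, "karyotypes.tsv"))
  write_mutation_table(mutations, file.path(out_dir, "mutations.tsv"))
  write_bed_intervals(model$genes, file.path(out_dir, "genes.bed"))
  write_bed_intervals(
    model$genes[model$genes$gene %in% model$panel_genes, ],
    file.path(out_dir, "panel_genes.bed"))
  if (!is.null(model$cnv_regions))
    write_bed_intervals(model$cnv_regions,
                        file.path(out_dir, "cnv_regions.bed"))
  write_genome_model(model, file.path(out_dir, "genome.json"))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_out <- config
  cfg_out$chrom_lengths <- as.list(cfg_out$chrom_lengths)
  cfg_out$event_frequency_table <- as.list(cfg_out$event_frequency_table)
  jsonlite::write_json(unclass(cfg_out),
                       file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, truth = truth, patients = patients,
                 karyotypes = karyotypes, mutations = mutations,
                 dir = out_dir))
}
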