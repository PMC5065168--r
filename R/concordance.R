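#' Match conventional-cytogenetics abnormalities to array calls
#'
#' Every counted CC abnormality of a patient is mapped to a genomic
#' interval via the genome model (arm-level for `del(5q)`-style tokens,
#' whole-chromosome for monosomies/trisomies and -Y) and compared with the
#' patient's somatic array calls: an unbalanced abnormality with at least
#' 1 bp of same-direction call overlap is `detected`, one without is
#' `missed`, and copy-neutral or unmappable abnormalities (balanced
#' translocations, unsupported "other" tokens) are `expected_undetectable`.
#' The three categories always sum to the number of counted abnormalities.
#'
#' @param record A `karyotype_record`.
#' @param calls Somatic call data frame for the same patient (may be
#'   empty).
#' @param model A `genome_model` (only lengths and centromeres are used).
#' @return List with `per_abnormality` (token, kind, status) and `counts`
#'   (named integer vector detected/missed/expected_undetectable).
#' @export
match_cc_to_acgh <- function(record, calls, model) {
  stopifnot(inherits(record, "karyotype_record"),
            inherits(model, "genome_model"))
  abn <- record$abnormalities
  abn <- abn[abn$counted, , drop = FALSE]
  status <- character(nrow(abn))
  for (i in seq_len(nrow(abn))) {
    kind <- abn$kind[i]
    if (kind %in% c("translocation", "other")) {
      status[i] <- "expected_undetectable"
      next
    }
    chrom <- abn$chrom[i]
    if (!chrom %in% names(model$lengths))
      stop("abnormality on chromosome absent from genome model: ", chrom)
    interval <- switch(kind,
      del = arm_interval(model, chrom, abn$arm[i]),
      gain = arm_interval(model, chrom, abn$arm[i]),
      monosomy = c(0, model$lengths[[chrom]]),
      loss_Y = c(0, model$lengths[[chrom]]),
      trisomy = c(0, model$lengths[[chrom]]),
      stop("unhandled abnormality kind: ", kind))
    direction <- if (kind %in% c("del", "monosomy", "loss_Y")) "loss"
                 else "gain"
    hit <- FALSE
    if (!is.null(calls) && nrow(calls)) {
      cand <- calls[calls$chrom == chrom & calls$direction == direction, ,
                    drop = FALSE]
      hit <- any(cand$start < interval[2] & cand$end > interval[1])
    }
    status[i] <- if (hit) "detected" else "missed"
  }
  counts <- c(detected = sum(status == "detected"),
              missed = sum(status == "missed"),
              expected_undetectable = sum(status == "expected_undetectable"))
  list(per_abnormality = data.frame(token = abn$token, kind = abn$kind,
                                    status = status,
                                    stringsAsFactors = FALSE),
       counts = counts)
}

#' Assign a recurrent-aberration class label to a call
#'
#' Labels somatic calls with the arm-overlap classes used in cohort
#' frequency summaries: whole-chromosome calls (>= 90% of the chromosome)
#' become `+8` / `-Y`-style labels; cryptic calls overlapping a panel gene
#' become `del(TET2)` / `gain(TET2)`; other calls get arm labels such as
#' `del(5q)` or `dup(1q)` from the arm holding most of the call.
#'
#' @param calls Call data frame.
#' @param model A `genome_model`.
#' @param panel_genes Optional panel-gene annotation (chrom, start, end,
#'   gene).
#' @return Character vector of class labels.
#' @export
aberration_class <- function(calls, model, panel_genes = NULL) {
  if (nrow(calls) == 0) return(character(0))
  labels <- character(nrow(calls))
  panel_hit <- rep(NA_character_, nrow(calls))
  if (!is.null(panel_genes) && nrow(panel_genes)) {
    hits <- .find_overlaps(calls, panel_genes)
    panel_hit[S4Vectors::queryHits(hits)] <-
      panel_genes$gene[S4Vectors::subjectHits(hits)]
  }
  for (i in seq_len(nrow(calls))) {
    chrom <- calls$chrom[i]
    L <- model$lengths[[chrom]]
    num <- sub("^chr", "", chrom)
    cover <- (calls$end[i] - calls$start[i]) / L
    if (cover >= 0.9) {
      labels[i] <- if (calls$direction[i] == "gain") paste0("+", num)
                   else paste0("-", num)
    } else if (isTRUE(calls$cryptic[i]) && !is.na(panel_hit[i])) {
      labels[i] <- paste0(if (calls$direction[i] == "loss") "del(" else
        "gain(", panel_hit[i], ")")
    } else {
      cent <- model$centromeres[[chrom]]
      p_ov <- max(0, min(calls$end[i], cent) - calls$start[i])
      q_ov <- max(0, calls$end[i] - max(calls$start[i], cent))
      arm <- if (p_ov >= q_ov) "p" else "q"
      labels[i] <- paste0(if (calls$direction[i] == "loss") "del(" else
        "dup(", num, arm, ")")
    }
  }
  labels
}

#' Cohort-level summary of array findings against cytogenetics
#'
#' Computes the headline cohort quantities: the fraction of patients with
#' at least one somatic CNA overall and within each cytogenetic subgroup
#' (normal / abnormal / non-informative karyotype, plus metaphase-adequacy
#' bands within the normal group), the loss/gain split of all somatic
#' calls, per-aberration-class frequencies among CNA-positive patients,
#' and complex-karyotype counts under both definitions (CC >= 3
#' abnormalities; array >= 5 CNAs).
#'
#' @param karyotypes Karyotype table (patient, iscn, n_metaphases) or a
#'   list of `karyotype_record`s.
#' @param calls Somatic call data frame for the cohort (`sample` column).
#' @param model A `genome_model`.
#' @param panel_genes Optional panel-gene annotation for class labels.
#' @return List of class `cohort_summary`.
#' @export
summarize_cohort <- function(karyotypes, calls, model, panel_genes = NULL) {
  records <- if (is.data.frame(karyotypes)) {
    if (nrow(karyotypes) == 0) stop("empty cohort")
    lapply(seq_len(nrow(karyotypes)), function(i)
      parse_iscn(karyotypes$iscn[i], patient = karyotypes$patient[i]))
  } else {
    if (length(karyotypes) == 0) stop("empty cohort")
    karyotypes
  }
  patients <- vapply(records, `[[`, character(1), "patient")
  status <- vapply(records, `[[`, character(1), "status")
  n_meta <- vapply(records, `[[`, integer(1), "n_metaphases")
  n_cna <- vapply(patients, function(p)
    sum(calls$sample == p), integer(1))
  has_cna <- n_cna > 0
  frac_by <- function(mask) if (any(mask)) mean(has_cna[mask]) else NA_real_
  normal_adeq <- adequacy_category(n_meta)
  subgroup_counts <- c(normal = sum(status == "normal"),
                       abnormal = sum(status == "abnormal"),
                       non_informative = sum(status == "non_informative"))
  classes <- aberration_class(calls, model, panel_genes)
  class_freq <- if (any(has_cna))
    sort(table(classes[!duplicated(paste(calls$sample, classes))]) /
           sum(has_cna), decreasing = TRUE)
  else table(character(0))
  complex_cc <- vapply(records, function(r)
    isTRUE(classify_complex_cc(r)), logical(1))
  res <- list(
    n_patients = length(patients),
    patients = data.frame(patient = patients, cc_status = status,
                          n_metaphases = n_meta,
                          adequacy = normal_adeq, n_cna = n_cna,
                          abnormal_acgh = has_cna,
                          complex_cc = complex_cc,
                          complex_acgh = classify_complex_acgh(n_cna),
                          stringsAsFactors = FALSE),
    subgroup_counts = subgroup_counts,
    frac_cna_overall = mean(has_cna),
    frac_cna_by_cc = c(
      normal = frac_by(status == "normal"),
      abnormal = frac_by(status == "abnormal"),
      non_informative = frac_by(status == "non_informative")),
    frac_cna_by_adequacy = c(
      ge20 = frac_by(status == "normal" & normal_adeq == "ge20"),
      m11_19 = frac_by(status == "normal" & normal_adeq == "m11_19"),
      le10 = frac_by(status == "normal" & normal_adeq == "le10")),
    n_calls = nrow(calls),
    loss_fraction = if (nrow(calls)) mean(calls$direction == "loss")
                    else NA_real_,
    gain_fraction = if (nrow(calls)) mean(calls$direction == "gain")
                    else NA_real_,
    class_frequencies = class_freq,
    n_complex_cc = sum(complex_cc),
    n_complex_acgh = sum(classify_complex_acgh(n_cna)))
  class(res) <- "cohort_summary"
  res
}

#' Association tests between patient groupings and findings
#'
#' Categorical outcomes are tested with Fisher's exact test on the
#' contingency table; numeric outcomes with the two-sided Wilcoxon
#' rank-sum test (two groups) or Kruskal-Wallis (more). Degenerate inputs
#' (a single group, or a constant categorical outcome) are an error - no
#' p-value is fabricated.
#'
#' @param outcome Numeric vector, or vector coercible to factor.
#' @param group Grouping vector (>= 2 non-empty groups).
#' @return List: method, statistic (NA for Fisher), p_value, and the
#'   contingency table for categorical outcomes.
#' @export
association_tests <- function(outcome, group) {
  stopifnot(length(outcome) == length(group))
  keep <- !is.na(outcome) & !is.na(group)
  outcome <- outcome[keep]; group <- factor(group[keep])
  if (nlevels(droplevels(group)) < 2)
    stop("degenerate grouping: need at least 2 non-empty groups")
  group <- droplevels(group)
  if (is.numeric(outcome)) {
    if (nlevels(group) == 2) {
      ht <- wilcox.test(outcome ~ group, exact = FALSE)
    } else {
      ht <- kruskal.test(outcome ~ group)
    }
    list(method = ht$method, statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    tab <- table(factor(outcome), group)
    if (nrow(tab) < 2)
      stop("degenerate table: outcome has a single level")
    ht <- fisher.test(tab)
    list(method = ht$method, statistic = NA_real_, p_value = ht$p.value,
         table = tab)
  }
}
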