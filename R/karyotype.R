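#' Parse a simplified ISCN karyotype string
#'
#' Supports the subset of ISCN nomenclature needed for copy-number
#' concordance: clones separated by "/", each clone
#' `count,sex,abn1,abn2,...[n]` with the metaphase count in brackets.
#' Recognized abnormality tokens: `del(5)(q13q33)` (arm-level deletion),
#' `dup(1)(q11q31)` (arm-level gain), `+8` (trisomy), `-7` (monosomy), `-Y`
#' (Y loss) and `t(...)(...)` (balanced translocation, copy-neutral).
#' Well-formed but unsupported rearrangement tokens (e.g. `inv(3)(q21q26)`)
#' parse to kind "other" with a warning; structurally malformed input (a
#' clone without a `[n]` cell count, an unrecognizable token) is an error
#' naming the offending text.
#'
#' An abnormality is counted as a clonal CC abnormality when it is seen in
#' at least 2 metaphases (`counted`); sub-threshold clones stay annotated.
#' Metaphases are summed across clones. An empty string means karyotyping
#' failed (non-informative, 0 metaphases).
#'
#' @param iscn Karyotype string.
#' @param patient Optional patient id stored in the record.
#' @return Object of class `karyotype_record`: list with patient, iscn,
#'   n_metaphases, sex (sex-chromosome token of the first clone), status
#'   ("normal", "abnormal" or "non_informative") and `abnormalities`, a
#'   data.frame (token, kind, chrom, arm, clone_size, counted).
#' @export
parse_iscn <- function(iscn, patient = NA_character_) {
  abn_empty <- data.frame(token = character(), kind = character(),
                          chrom = character(), arm = character(),
                          clone_size = integer(), counted = logical(),
                          stringsAsFactors = FALSE)
  iscn <- trimws(iscn)
  if (is.na(iscn) || nchar(iscn) == 0) {
    rec <- list(patient = patient, iscn = "", n_metaphases = 0L,
                sex = NA_character_, status = "non_informative",
                abnormalities = abn_empty)
    class(rec) <- "karyotype_record"
    return(rec)
  }
  clones <- strsplit(iscn, "/", fixed = TRUE)[[1]]
  total_m <- 0L
  sex <- NA_character_
  abn_rows <- list()
  for (clone in clones) {
    m <- regmatches(clone, regexec("^(.*)\\[([0-9]+)\\]$", clone))[[1]]
    if (length(m) != 3)
      stop("clone without metaphase count [n]: '", clone, "'")
    count <- as.integer(m[3])
    total_m <- total_m + count
    tokens <- strsplit(m[2], ",", fixed = TRUE)[[1]]
    if (length(tokens) < 2)
      stop("clone must start with 'count,sex': '", clone, "'")
    if (!grepl("^[0-9]+$", trimws(tokens[1])))
      stop("invalid modal chromosome count: '", tokens[1], "'")
    sex_tok <- trimws(tokens[2])
    if (!grepl("^[XY]+$", sex_tok))
      stop("invalid sex chromosome token: '", sex_tok, "'")
    # constitutional sex = longest sex-chromosome token across clones
    # (a -Y clone shows "X" while the normal clone shows "XY")
    if (is.na(sex) || nchar(sex_tok) > nchar(sex)) sex <- sex_tok
    for (tok in trimws(tokens[-(1:2)])) {
      if (nchar(tok) == 0) next
      abn_rows[[length(abn_rows) + 1L]] <-
        cbind(.parse_abn_token(tok), clone_size = count)
    }
  }
  abn <- if (length(abn_rows)) do.call(rbind, abn_rows) else abn_empty[0, 1:5]
  if (nrow(abn)) {
    # same token seen in several clones: one abnormality, metaphases summed
    agg <- stats::aggregate(clone_size ~ token, data = abn, FUN = sum)
    abn <- merge(unique(abn[c("token", "kind", "chrom", "arm")]), agg,
                 by = "token", sort = FALSE)
    abn$counted <- abn$clone_size >= 2L
  } else {
    abn <- abn_empty
  }
  status <- if (total_m == 0L) "non_informative"
            else if (any(abn$counted)) "abnormal" else "normal"
  rec <- list(patient = patient, iscn = iscn, n_metaphases = total_m,
              sex = sex, status = status, abnormalities = abn)
  class(rec) <- "karyotype_record"
  rec
}

.parse_abn_token <- function(tok) {
  row <- function(kind, chrom = NA_character_, arm = NA_character_)
    data.frame(token = tok, kind = kind, chrom = chrom, arm = arm,
               stringsAsFactors = FALSE)
  m <- regmatches(tok, regexec(
    "^(del|dup)\\(([0-9]+|X|Y)\\)\\(([pq])[0-9.]*([pq]?)[0-9.]*\\)$", tok))[[1]]
  if (length(m)) {
    kind <- if (m[2] == "del") "del" else "gain"
    return(row(kind, paste0("chr", m[3]), m[4]))
  }
  if (tok == "-Y") return(row("loss_Y", "chrY"))
  m <- regmatches(tok, regexec("^-([0-9]+|X)$", tok))[[1]]
  if (length(m)) return(row("monosomy", paste0("chr", m[2])))
  m <- regmatches(tok, regexec("^\\+([0-9]+|X|Y)$", tok))[[1]]
  if (length(m)) return(row("trisomy", paste0("chr", m[2])))
  if (grepl("^t\\([0-9XY;]+\\)(\\([pq0-9.;]+\\))?$", tok))
    return(row("translocation"))
  if (grepl("^[a-z]{2,5}\\([0-9XY;]+\\)(\\([pq0-9.;]+\\))?$", tok)) {
    warning("unsupported ISCN token '", tok, "'; recorded as kind 'other'")
    return(row("other"))
  }
  stop("unparseable ISCN token: '", tok, "'")
}

#' Render a karyotype record back to ISCN text
#'
#' Abnormalities are grouped by clone size (largest first) into one clone
#' each; metaphases not carrying any abnormality form a trailing normal
#' clone. Re-parsing the rendered text reproduces the record (idempotent on
#' the supported grammar).
#'
#' @param record A `karyotype_record`.
#' @return ISCN string ("" for non-informative records).
#' @export
format_iscn <- function(record) {
  stopifnot(inherits(record, "karyotype_record"))
  if (record$status == "non_informative" && record$n_metaphases == 0L)
    return("")
  sex <- if (is.na(record$sex)) "XX" else record$sex
  abn <- record$abnormalities
  clone_txt <- function(tokens, n) {
    kinds <- abn$kind[match(tokens, abn$token)]
    modal <- 46L + sum(kinds == "trisomy") -
      sum(kinds %in% c("monosomy", "loss_Y"))
    sex_tok <- if (any(kinds == "loss_Y")) sub("Y", "", sex) else sex
    paste0(paste(c(modal, sex_tok, tokens), collapse = ","), "[", n, "]")
  }
  if (nrow(abn) == 0)
    return(paste0("46,", sex, "[", record$n_metaphases, "]"))
  clones <- character()
  used <- 0L
  for (cs in sort(unique(abn$clone_size), decreasing = TRUE)) {
    tokens <- abn$token[abn$clone_size == cs]
    clones <- c(clones, clone_txt(tokens, cs))
    used <- used + cs
  }
  rest <- record$n_metaphases - used
  if (rest > 0)
    clones <- c(clones, paste0("46,", sex, "[", rest, "]"))
  paste(clones, collapse = "/")
}

#' @export
print.karyotype_record <- function(x, ...) {
  cat("Karyotype", if (!is.na(x$patient)) paste0("(", x$patient, ")"),
      ":", if (nchar(x$iscn)) x$iscn else "<non-informative>", "\n")
  cat("  status:", x$status, "| metaphases:", x$n_metaphases,
      "| abnormalities:", nrow(x$abnormalities), "\n")
  invisible(x)
}

#' Metaphase adequacy category
#'
#' Cytogenetic quality banding by the number of good-quality metaphases:
#' `ge20` (>= 20, a karyotype can be considered confidently normal),
#' `m11_19`, `le10`, and `non_informative` for 0 metaphases (absence of
#' mitosis).
#'
#' @param n_metaphases Non-negative integer vector.
#' @return Character vector of categories.
#' @export
adequacy_category <- function(n_metaphases) {
  if (any(n_metaphases < 0)) stop("metaphase counts must be >= 0")
  ifelse(n_metaphases == 0, "non_informative",
         ifelse(n_metaphases <= 10, "le10",
                ifelse(n_metaphases <= 19, "m11_19", "ge20")))
}

#' Complex karyotype by conventional cytogenetics
#'
#' Complex = at least 3 clonal abnormalities. Non-informative karyotypes
#' are not evaluable and return NA.
#'
#' @param record A `karyotype_record`.
#' @return TRUE/FALSE, or NA for non-informative records.
#' @export
classify_complex_cc <- function(record) {
  stopifnot(inherits(record, "karyotype_record"))
  if (record$status == "non_informative") return(NA)
  sum(record$abnormalities$counted) >= 3L
}

#' Complex karyotype by array profile
#'
#' Complex = at least 5 retained (non-germline) copy-number changes.
#'
#' @param n_cnas Integer vector of retained CNA counts.
#' @return Logical vector.
#' @export
classify_complex_acgh <- function(n_cnas) {
  n_cnas >= 5L
}
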