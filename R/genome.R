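#' Synthetic chromosome lengths
#'
#' A fully synthetic diploid genome: 22 autosomes with linearly decreasing
#' lengths (250 Mb down to 61 Mb), a 150 Mb X and a 60 Mb Y. No coordinate
#' corresponds to a real assembly; real chromosome lengths can be passed to
#' [sim_config()] instead.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
default_chrom_lengths <- function() {
  auto <- paste0("chr", 1:22)
  len <- (250 - 9 * (0:21)) * 1e6
  c(stats::setNames(len, auto), chrX = 150e6, chrY = 60e6)
}

# Arm boundary (p|q) placed at a fixed fraction of each chromosome.
.centromere_fraction <- 0.4

#' Build the genome model used by the simulator and the concordance matcher
#'
#' Allocates probes to chromosomes proportionally to length (largest-
#' remainder rounding, so counts sum exactly to `probe_count`), spaces them
#' evenly along each chromosome, places the arm boundary at a fixed fraction
#' of each chromosome, and lays out a synthetic gene annotation: the five
#' sequencing-panel genes (DNMT3A, TET2, TP53, RUNX1, BCOR), further
#' MDS-associated loci, and a dense strip of genes on chromosome 13 used by
#' the shared-gene analysis of chromothriptic chromosomes. Germline-CNV
#' catalogue regions are probe-aligned spans on each autosome.
#'
#' @param config A [sim_config()].
#' @return Object of class `genome_model`: list with `chromosomes`,
#'   `lengths`, `centromeres`, `probes` (named list of 1-based positions,
#'   strictly increasing), `genes` (data.frame chrom/start/end/gene,
#'   0-based half-open), `panel_genes`, `cnv_regions` (data.frame).
#' @export
build_genome_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lengths <- config$chrom_lengths
  if (any(lengths <= 0)) stop("zero-length chromosome")
  chroms <- names(lengths)
  counts <- .allocate_proportional(config$probe_count, lengths)
  probes <- lapply(seq_along(chroms), function(i) {
    k <- counts[i]
    L <- lengths[i]
    pos <- unique(round(seq_len(k) * (L / (k + 1))))
    pos[pos >= 1]
  })
  names(probes) <- chroms
  bad <- vapply(seq_along(probes), function(i)
    length(probes[[i]]) != counts[i] || is.unsorted(probes[[i]], strictly = TRUE),
    logical(1))
  if (any(bad))
    stop("could not place distinct probe positions on: ",
         paste(chroms[bad], collapse = ", "))
  genes <- .default_gene_table(lengths)
  if (any(genes$end > lengths[genes$chrom]))
    stop("gene outside chromosome bounds")
  model <- list(chromosomes = chroms,
                lengths = lengths,
                centromeres = round(.centromere_fraction * lengths),
                probes = probes,
                genes = genes,
                panel_genes = c("DNMT3A", "TET2", "TP53", "RUNX1", "BCOR"),
                cnv_regions = NULL)
  model$cnv_regions <- .default_cnv_regions(model)
  class(model) <- "genome_model"
  model
}

# Largest-remainder apportionment of `total` probes across weights.
.allocate_proportional <- function(total, weights) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Synthetic gene annotation; fractions of chromosome length, 100 kb genes.
.default_gene_table <- function(lengths) {
  gene_width <- 1e5
  place <- function(chrom, frac, gene) {
    start <- round(frac * lengths[[chrom]])
    data.frame(chrom = chrom, start = start, end = start + gene_width,
               gene = gene, stringsAsFactors = FALSE)
  }
  spots <- data.frame(
    chrom = c("chr2", "chr4", "chr5", "chr7", "chr17", "chr21", "chr21",
              "chrX"),
    frac = c(0.10, 0.55, 0.80, 0.55, 0.05, 0.60, 0.90, 0.15),
    gene = c("DNMT3A", "TET2", "SPARC", "CUX1", "TP53", "RUNX1", "U2AF1",
             "BCOR"),
    stringsAsFactors = FALSE)
  # chromosome 13: named cancer genes plus filler loci along the q arm
  if ("chr13" %in% names(lengths)) {
    spots <- rbind(spots, data.frame(
      chrom = "chr13", frac = seq(0.42, 0.95, length.out = 45),
      gene = c("XPO4", "FLT3", "FLT1", "BRCA2", "RB1",
               sprintf("C13G%03d", 6:45)),
      stringsAsFactors = FALSE))
  }
  spots <- spots[spots$chrom %in% names(lengths), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(spots)), function(i)
    place(spots$chrom[i], spots$frac[i], spots$gene[i])))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Probe-aligned germline-CNV catalogue: one region per autosome spanning 9
# consecutive probes, padded by half the local probe spacing, so a carrier's
# deletion call reciprocally overlaps its region at any probe density.
.default_cnv_regions <- function(model) {
  auto <- grep("^chr[0-9]+$", model$chromosomes, value = TRUE)
  rows <- lapply(auto, function(chrom) {
    pos <- model$probes[[chrom]]
    n <- length(pos)
    if (n < 12) return(NULL)
    i <- max(2L, floor(0.88 * n))
    j <- min(n - 1L, i + 8L)
    pad <- round((pos[2] - pos[1]) / 2)
    data.frame(chrom = chrom,
               start = max(0, pos[i] - 1 - pad),
               end = min(model$lengths[[chrom]], pos[j] + pad),
               name = paste0("CNV_", chrom),
               probe_from = i, probe_to = j,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arm interval of a chromosome
#'
#' @param model A `genome_model`.
#' @param chrom Chromosome name.
#' @param arm "p" or "q".
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
arm_interval <- function(model, chrom, arm) {
  if (!chrom %in% names(model$lengths))
    stop("chromosome not in genome model: ", chrom)
  cent <- model$centromeres[[chrom]]
  if (arm == "p") c(0, cent)
  else if (arm == "q") c(cent, model$lengths[[chrom]])
  else stop("arm must be 'p' or 'q'")
}

#' Serialize / read the genome model coordinate frame
#'
#' Writes chromosome lengths and arm boundaries as JSON (probe positions
#' live in the probe tables, gene annotation in BED; neither is duplicated
#' here). `read_genome_model()` returns a `genome_model` usable by the
#' concordance matcher; its `probes`, `genes` and `cnv_regions` slots are
#' NULL unless supplied separately.
#'
#' @param model A `genome_model`.
#' @param path Output/input JSON path.
#' @return `write_genome_model()` the path, invisibly;
#'   `read_genome_model()` a `genome_model`.
#' @export
write_genome_model <- function(model, path) {
  payload <- list(chromosomes = model$chromosomes,
                  lengths = as.list(model$lengths),
                  centromeres = as.list(model$centromeres))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome_model
#' @export
read_genome_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(chromosomes = payload$chromosomes,
                lengths = unlist(payload$lengths),
                centromeres = unlist(payload$centromeres),
                probes = NULL, genes = NULL,
                panel_genes = NULL, cnv_regions = NULL)
  class(model) <- "genome_model"
  model
}
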