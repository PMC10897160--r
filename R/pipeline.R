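## Per-cell QC metrics, sample filters and end-to-end orchestration.

#' Circular spike-in enrichment
#'
#' Reads on the circular spike-in contig divided by reads on all
#' spike-in contigs. Quantifies how completely linear DNA was removed
#' before amplification.
#'
#' @param reads_circular_spike,reads_all_spike read counts.
#' @return fraction in \[0, 1\].
#' @export
spikein_enrichment <- function(reads_circular_spike, reads_all_spike) {
  if (reads_all_spike == 0) stop("no spike-in reads detected")
  stopifnot(reads_all_spike >= reads_circular_spike)
  reads_circular_spike / reads_all_spike
}

#' Circle-read enrichment
#'
#' Fraction of primary non-duplicate reads whose midpoint falls inside
#' any CPR.
#'
#' @param aln alignment data.frame.
#' @param cprs CPR GRanges.
#' @return fraction in \[0, 1\].
#' @export
circle_read_enrichment <- function(aln, cprs) {
  reads <- aln_granges(aln)
  if (length(reads) == 0) stop("zero reads")
  if (length(cprs) == 0) return(0)
  mean(overlapsAny(midpoints(reads), cprs, ignore.strand = TRUE))
}

#' Cell-level QC filter
#'
#' Applies the per-sample thresholds: mapping rate, circular spike-in
#' enrichment, minimum number of CPRs and minimum mappability proxy
#' (fraction of primary reads above mapping quality 20). The default
#' combination rule fails a cell on any violated criterion; `rule =
#' "all"` fails only when every criterion is violated.
#'
#' @param profile list with qc fields `mapping_rate`,
#'   `spikein_circular_fraction`, `n_cprs`, `mappability`.
#' @param min_mapping_rate,min_spike_circ,min_cprs,min_mappability
#'   thresholds (defaults 0.90, 0.80, 100, 0.70).
#' @param rule "any" (default) or "all".
#' @return list with `pass` (logical) and `reasons` (character of
#'   violated criteria; empty when passing).
#' @export
cell_filter <- function(profile, min_mapping_rate = 0.90,
                        min_spike_circ = 0.80, min_cprs = 100L,
                        min_mappability = 0.70,
                        rule = c("any", "all")) {
  rule <- match.arg(rule)
  qc <- profile$qc %||% profile
  viol <- character()
  if (qc$mapping_rate < min_mapping_rate) {
    viol <- c(viol, sprintf("mapping_rate %.3f < %.2f",
                            qc$mapping_rate, min_mapping_rate))
  }
  if (qc$spikein_circular_fraction < min_spike_circ) {
    viol <- c(viol, sprintf("spikein_circular_fraction %.3f < %.2f",
                            qc$spikein_circular_fraction, min_spike_circ))
  }
  if (qc$n_cprs < min_cprs) {
    viol <- c(viol, sprintf("n_cprs %d < %d", qc$n_cprs, min_cprs))
  }
  if (qc$mappability < min_mappability) {
    viol <- c(viol, sprintf("mappability %.3f < %.2f",
                            qc$mappability, min_mappability))
  }
  n_criteria <- 4L
  pass <- if (rule == "any") length(viol) == 0 else length(viol) < n_criteria
  list(pass = pass, reasons = viol)
}

#' Process one cell end to end
#'
#' Reads and deduplicates the alignments, computes QC metrics, calls
#' CPRs on the nuclear contigs and detected regions on the
#' mitochondrial contig, extracts chimeric reads, clusters junctions
#' and classifies CPR structure.
#'
#' @param path SAM/BAM file of one cell.
#' @param seqinfo Seqinfo of the active genome.
#' @param params [cpr_params()] list; `exclude_contigs` must list the
#'   mitochondrial and spike-in contigs and `mito_contig` must be set.
#' @param spike_contigs character of (circular, linear) spike-in contig
#'   names, or NULL when the assay has no spike-ins.
#' @param cell_id cell identifier (defaults to the file name).
#' @param keep_aln keep the deduplicated alignment table and read
#'   GRanges on the profile (needed for pseudo-bulk and topics).
#' @return `ecc_cell_profile` list: cell_id, cprs, junctions,
#'   mito_regions, reads, qc, pass_qc, qc_reasons.
#' @export
run_cell <- function(path, seqinfo, params = cpr_params(),
                     spike_contigs = NULL, cell_id = NULL,
                     keep_aln = TRUE) {
  cell_id <- cell_id %||% sub("\\.(sam|bam)$", "", basename(path))
  aln <- tryCatch(read_alignments(path),
                  error = function(e) stop("alignment_io: ", conditionMessage(e)))
  if (nrow(aln) == 0) stop("alignment_io: empty alignment file ", path)
  n_total <- sum(!aln$is_secondary & !aln$is_supplementary)
  aln <- deduplicate(aln)
  profile_from_alignments(aln, seqinfo, params, spike_contigs, cell_id,
                          n_total_reads = n_total, keep_aln = keep_aln)
}

# QC + detection from an in-memory (deduplicated) alignment table
profile_from_alignments <- function(aln, seqinfo, params,
                                    spike_contigs = NULL, cell_id,
                                    n_total_reads = NULL,
                                    keep_aln = TRUE) {
  prim <- !aln$is_secondary & !aln$is_supplementary & aln$is_mapped
  map_rate <- mapping_rate(aln, n_total_reads)
  mappability <- sum(prim & aln$mapq > 20L) / max(1L, sum(prim))
  spike_frac <- NA_real_
  if (!is.null(spike_contigs)) {
    n_circ <- sum(prim & aln$chrom == spike_contigs[1])
    n_all <- sum(prim & aln$chrom %in% spike_contigs)
    spike_frac <- if (n_all > 0) spikein_enrichment(n_circ, n_all) else 0
  }
  cprs <- tryCatch(detect_cprs(aln, seqinfo, params),
                   error = function(e) stop("cpr_detect: ",
                                            conditionMessage(e)))
  mito_regions <- GRanges()
  if (!is.na(params$mito_contig) &&
      params$mito_contig %in% names(seqlengths(seqinfo))) {
    cov_mt <- compute_coverage(aln[aln$chrom == params$mito_contig, ,
                                   drop = FALSE],
                               seqinfo, params$bin_size)
    mito_regions <- call_peaks(cov_mt, params$min_cov,
                               enrichment_factor = 0,
                               contigs = params$mito_contig)
    mito_regions <- merge_regions(mito_regions, params$merge_gap)
  }
  chim <- extract_chimeric(aln, params$min_mapq, params$insert_threshold)
  raw_jx <- extract_junction_endpoints(chim$split)
  junctions <- cluster_junctions(raw_jx, cprs,
                                 window = 500L, min_support = 2L)
  cprs <- attach_structure(cprs, junctions)
  qc <- list(
    mapping_rate = map_rate,
    spikein_circular_fraction = spike_frac,
    circle_read_enrichment = if (length(cprs)) {
      circle_read_enrichment(aln, cprs)
    } else 0,
    total_reads = n_total_reads %||% sum(prim),
    n_cprs = length(cprs),
    mappability = mappability
  )
  filt <- if (is.na(spike_frac)) {
    qc2 <- qc; qc2$spikein_circular_fraction <- 1
    cell_filter(list(qc = qc2))
  } else cell_filter(list(qc = qc))
  structure(list(cell_id = cell_id, cprs = cprs, junctions = junctions,
                 mito_regions = mito_regions,
                 reads = if (keep_aln) aln_granges(aln, seqinfo) else NULL,
                 aln = if (keep_aln) aln else NULL,
                 qc = qc, pass_qc = filt$pass, qc_reasons = filt$reasons),
            class = "ecc_cell_profile")
}

#' Process a whole population
#'
#' Runs every cell, applies the QC filter, builds the pseudo-bulk CPR
#' set from passing cells, classifies it, and optionally fits the topic
#' model. QC-failing cells are excluded from classification and topics
#' but reported in the summary.
#'
#' @param paths character vector of per-cell SAM/BAM files (or a
#'   directory containing them).
#' @param seqinfo Seqinfo of the active genome.
#' @param params [cpr_params()] list (see [run_cell()]).
#' @param spike_contigs spike-in contig names (circular first), or NULL.
#' @param fit_topics fit an LDA model on the passing cells.
#' @param n_topics topic number (single value) used when `fit_topics`.
#' @param seed integer seed (topics).
#' @param out_dir optional directory for TSV/BED/JSON outputs.
#' @return list with `profiles`, `pseudo_cprs`, `classification`,
#'   `bin_matrix`, `topic_model`, `summary`.
#' @export
run_population <- function(paths, seqinfo, params = cpr_params(),
                           spike_contigs = NULL, fit_topics = FALSE,
                           n_topics = 3L, seed = 1L, out_dir = NULL) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(sam|bam)$",
                        full.names = TRUE)
  }
  if (length(paths) == 0) stop("no alignment files found")
  profiles <- lapply(paths, run_cell, seqinfo = seqinfo, params = params,
                     spike_contigs = spike_contigs)
  names(profiles) <- vapply(profiles, `[[`, "", "cell_id")
  pass <- vapply(profiles, `[[`, logical(1), "pass_qc")
  if (!any(pass)) {
    reasons <- lapply(profiles, `[[`, "qc_reasons")
    stop("every cell fails QC: ",
         paste(names(profiles), vapply(reasons, paste, "", collapse = "; "),
               sep = ": ", collapse = " | "))
  }
  passing <- profiles[pass]
  pseudo <- build_pseudobulk(lapply(passing, `[[`, "aln"), seqinfo, params)
  classification <- classify_population(
    pseudo,
    cell_cprs = lapply(passing, `[[`, "cprs"),
    cell_mito = lapply(passing, `[[`, "mito_regions"),
    mito_contig = params$mito_contig, seqinfo = seqinfo)
  bin_matrix <- NULL; topic_model <- NULL
  if (fit_topics) {
    bin_matrix <- build_bin_matrix(
      lapply(passing, `[[`, "reads"),
      lapply(passing, `[[`, "cprs"),
      seqinfo,
      contigs = setdiff(names(seqlengths(seqinfo)),
                        params$exclude_contigs))
    topic_model <- fit_lda(bin_matrix, n_topics, seed = seed)
  }
  summary <- list(
    n_cells = length(profiles),
    n_pass = sum(pass),
    qc = lapply(profiles, function(p) c(p$qc, pass = p$pass_qc,
                                        reasons = list(p$qc_reasons))),
    label_counts = as.list(table(classification$label))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_classification(classification,
                         file.path(out_dir, "classification.tsv"),
                         file.path(out_dir, "pseudo_cprs.bed"))
    for (p in passing) {
      write_cprs(p$cprs,
                 file.path(out_dir, paste0(p$cell_id, ".cprs.bed")),
                 file.path(out_dir, paste0(p$cell_id, ".cprs.tsv")))
      write_bedpe(p$junctions,
                  file.path(out_dir, paste0(p$cell_id, ".junctions.bedpe")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(topic_model)) {
      write_topic_model(topic_model, file.path(out_dir, "topics"),
                        bin_matrix)
    }
  }
  list(profiles = profiles, pseudo_cprs = pseudo,
       classification = classification, bin_matrix = bin_matrix,
       topic_model = topic_model, summary = summary)
}
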