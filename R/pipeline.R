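# Orchestration: subsampling, saturation curves, report tables, and the
# end-to-end synthetic-study pipeline.

#' Nested read-pair subsampling
#'
#' Draws subsets of read pairs without replacement such that every smaller
#' subset is contained in every larger one (so detection curves are
#' monotone by construction, not just in expectation). Pairs are kept
#' together by sampling pair indices.
#'
#' @param n_pairs Total number of read pairs available.
#' @param depths Integer vector of subset sizes (pairs).
#' @param seed Integer seed for the subsampling permutation.
#' @return A list (one element per depth, in the given order) of sorted
#'   pair-index vectors.
#' @export
subsample_reads <- function(n_pairs, depths, seed) {
  depths <- as.integer(depths)
  if (any(depths > n_pairs)) {
    stop("requested depth exceeds the ", n_pairs, " available pairs")
  }
  if (any(depths < 0L)) stop("depths must be non-negative")
  set.seed(as.integer(seed))
  perm <- sample.int(n_pairs)
  lapply(depths, function(d) sort(perm[seq_len(d)]))
}

#' Gene-detection saturation curve
#'
#' For each nested read subset, a gene counts as detected iff at least
#' `min_reads` of the subset's reads map to one of its transcripts.
#'
#' @param subsets List of pair-index vectors from [subsample_reads()].
#' @param placements Read placements from [map_reads()] of the full read
#'   set.
#' @param pair_of_read Integer vector giving, for each read index used in
#'   `placements`, its pair index.
#' @param transcript_to_gene Named character vector mapping transcript ids
#'   to gene ids.
#' @param total_genes Denominator for the detected fraction.
#' @param min_reads Minimum mapped reads for detection (default 1).
#' @return Data.frame of saturation points: `n_pairs`, `n_genes_detected`,
#'   `fraction_detected`, sorted by `n_pairs`.
#' @export
detection_curve <- function(subsets, placements, pair_of_read,
                            transcript_to_gene, total_genes,
                            min_reads = 1L) {
  gene <- transcript_to_gene[placements$transcript_id]
  pair <- pair_of_read[placements$read]
  pts <- lapply(subsets, function(idx) {
    sel <- pair %in% idx
    tab <- table(gene[sel])
    n_det <- sum(tab >= min_reads)
    data.frame(n_pairs = length(idx), n_genes_detected = n_det,
               fraction_detected = n_det / total_genes)
  })
  out <- do.call(rbind, pts)
  out[order(out$n_pairs), , drop = FALSE]
}

#' Labeled counts with rounded percentages
#'
#' @param counts Named integer vector.
#' @param denominator Positive denominator for the percentages.
#' @param decimals Decimal places; rounding is half-away-from-zero (so
#'   93.05 at 1 decimal prints 93.1), matching how report tables are
#'   conventionally rounded rather than R's banker's rounding.
#' @return Data.frame with `label`, `count`, `percent`.
#' @export
percentage_table <- function(counts, denominator, decimals = 1L) {
  if (denominator < 1) stop("denominator must be >= 1")
  pct <- 100 * counts / denominator
  f <- 10^decimals
  pct <- sign(pct) * floor(abs(pct) * f + 0.5) / f
  data.frame(label = names(counts), count = as.integer(counts),
             percent = unname(pct), stringsAsFactors = FALSE)
}

default_pipeline_stages <- c("simulate", "trim", "merge", "map", "psv",
                             "orf", "motifs", "saturate")

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> trim -> merge -> map -> PSV/duplication ->
#' ORF/full-length -> motifs -> saturation and writes all report tables
#' plus a run manifest into `out_dir`. The run is fully deterministic
#' given the configuration (identical config implies byte-identical
#' outputs).
#'
#' @param cfg A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run; later stages stop with
#'   an informative error if a stage they depend on was disabled.
#' @param saturation_depths Fractions of the full pair count used for the
#'   saturation curve.
#' @return Invisibly, a list with the in-memory results (`sim`, `truth`,
#'   `placements`, `calls`, `dup`, `anns`, `motifs`, `saturation`) and
#'   `out_dir`.
#' @export
run_full_pipeline <- function(cfg, out_dir,
                              stages = default_pipeline_stages,
                              saturation_depths = c(0.05, 0.1, 0.25, 0.5,
                                                    0.75, 1)) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(stage, dep) {
    if (!dep %in% stages) {
      stop("stage '", stage, "' requires disabled stage '", dep, "'")
    }
  }
  res <- list(out_dir = out_dir)
  tsv <- function(df, file) {
    write.table(df, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # manifest first: full config, seed, package version
  manifest <- c(sprintf("dhtrans_version\t%s",
                        as.character(packageVersion("dhtrans"))),
                sprintf("stages\t%s", paste(stages, collapse = ",")),
                vapply(names(unclass(cfg)), function(k) {
                  sprintf("%s\t%s", k,
                          paste(format(cfg[[k]], trim = TRUE),
                                collapse = ","))
                }, character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))

  if ("simulate" %in% stages) {
    proteome <- generate_proteome(cfg)
    sim <- generate_transcriptome(cfg, proteome)
    reads <- simulate_reads(cfg, sim$transcripts, sim$truth)
    res$sim <- sim
    res$truth <- sim$truth
    res$proteome <- proteome
    res$reads <- reads
    write_fasta(sim$transcripts, file.path(out_dir, "transcripts.fa"))
    write_fastq(reads$read1, file.path(out_dir, "reads_1.fq"))
    write_fastq(reads$read2, file.path(out_dir, "reads_2.fq"))
    truth_out <- sim$truth
    tsv(truth_out, "truth_genes.tsv")
    message("simulate: ", length(sim$transcripts), " transcripts, ",
            length(reads$read1), " read pairs")
  }

  if ("trim" %in% stages) {
    need("trim", "simulate")
    t1 <- trim_reads(res$reads$read1)
    t2 <- trim_reads(res$reads$read2)
    message("trim: discarded ", attr(t1, "n_discarded"), " + ",
            attr(t2, "n_discarded"), " reads")
    res$trimmed <- list(read1 = t1, read2 = t2)
  }

  if ("merge" %in% stages) {
    need("merge", "simulate")
    contigs <- deduplicate_contigs(res$sim$transcripts, min_len = 200L)
    res$contigs <- contigs
    st <- assembly_stats(contigs)
    res$assembly_stats <- st
    tsv(as.data.frame(st), "assembly_stats.tsv")
    message("merge: ", length(contigs), " non-redundant contigs, N50 ",
            st$n50)
  }

  if ("map" %in% stages) {
    need("map", "trim")
    need("map", "merge")
    all_reads <- c(as.character(res$trimmed$read1),
                   as.character(res$trimmed$read2))
    names(all_reads) <- c(names(res$trimmed$read1),
                          names(res$trimmed$read2))
    placements <- map_reads(all_reads, res$contigs)
    res$all_reads <- all_reads
    res$placements <- placements
    message("map: ", nrow(placements), " placements for ",
            length(all_reads), " reads")
  }

  if ("psv" %in% stages) {
    need("psv", "map")
    pile <- build_pileup(res$placements, res$contigs, res$all_reads)
    calls <- call_psvs(pile)
    t2g <- setNames(res$truth$gene_id, res$truth$gene_id)
    dup <- summarize_duplicates(calls, t2g)
    res$pileup <- pile
    res$calls <- calls
    res$dup <- dup
    write_psv_table(calls, file.path(out_dir, "psv_calls.tsv"))
    tsv(dup$genes, "duplication_summary.tsv")
    tsv(dup$histogram, "psv_histogram.tsv")
    message("psv: ", nrow(calls), " calls, ", nrow(dup$genes),
            " putative duplicated genes")
  }

  if ("orf" %in% stages) {
    need("orf", "merge")
    anns <- annotate_orfs(res$contigs, res$proteome)
    res$anns <- anns
    out_anns <- as.data.frame(anns)
    out_anns$protein <- NULL
    tsv(out_anns, "orf_annotations.tsv")
    tsv(attr(anns, "summary"), "completeness_summary.tsv")
    prots <- attr(anns, "summary")
    message("orf: ", sum(anns$completeness == "FULL_LENGTH"),
            " full-length of ", nrow(anns))
  }

  if ("motifs" %in% stages) {
    need("motifs", "orf")
    fl <- res$anns[res$anns$completeness == "FULL_LENGTH", , drop = FALSE]
    kozak_w <- extract_context(res$contigs, fl, "START")
    kozak <- build_pfm(kozak_w, upstream = 4L)
    stop_w <- extract_context(res$contigs, fl, "STOP")
    stop_pfm <- build_pfm(stop_w, upstream = 6L)
    usage <- stop_codon_usage(fl, res$contigs)
    polya <- select_polya_transcripts(res$contigs)
    hex <- pas_hexamer_scan(res$contigs, polya)
    pas_rep <- pas_mixture_report(hex)
    res$motifs <- list(kozak = kozak, stop_context = stop_pfm,
                       stop_usage = usage, polya = polya, hexamers = hex,
                       pas_report = pas_rep)
    write_pfm(kozak, file.path(out_dir, "kozak_pfm.tsv"))
    write_pfm(stop_pfm, file.path(out_dir, "stop_context_pfm.tsv"))
    tsv(usage, "stop_usage.tsv")
    tsv(hex$table, "pas_hexamers.tsv")
    tsv(pas_rep, "pas_report.tsv")
    message("motifs: Kozak consensus ",
            consensus_from_pfm(kozak, rna = TRUE), "; ",
            nrow(polya), " polyA transcripts")
  }

  if ("saturate" %in% stages) {
    need("saturate", "map")
    n_pairs <- length(res$trimmed$read1)
    depths <- unique(pmax(1L, round(saturation_depths * n_pairs)))
    subsets <- subsample_reads(n_pairs, depths, seed = cfg$seed + 4L)
    # read index -> pair index: read1 block then read2 block, but
    # placements index into the trimmed+concatenated read vector
    n1 <- length(res$trimmed$read1)
    pair_of_read <- c(match(names(res$trimmed$read1),
                            names(res$reads$read1)),
                      match(names(res$trimmed$read2),
                            names(res$reads$read2)))
    # pairs surviving trimming keep their original index; renumber to the
    # trimmed pair universe used for subsampling
    pair_of_read <- match(pair_of_read, sort(unique(pair_of_read)))
    t2g <- setNames(res$truth$gene_id, res$truth$gene_id)
    curve <- detection_curve(subsets, res$placements, pair_of_read,
                             t2g, total_genes = nrow(res$truth))
    res$saturation <- curve
    tsv(curve, "saturation.tsv")
    message("saturate: ", nrow(curve), " depth points, max fraction ",
            sprintf("%.3f", max(curve$fraction_detected)))
  }

  invisible(res)
}
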