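# Multi-assembly merging, assembly statistics, and benchmark assessment.

#' Merge assemblies into a non-redundant contig set
#'
#' Pools one or more contig sets, removes contigs shorter than `min_len`,
#' sorts by length descending (ties broken by lexicographic id), and drops
#' every contig that is an exact substring -- on either strand -- of an
#' already-retained contig. Exact containment (rather than
#' identity-threshold clustering) is deterministic and sufficient for
#' merging overlapping assemblies of the same haploid source.
#'
#' @param assemblies A `DNAStringSet` or a list of them.
#' @param min_len Minimum contig length to retain (default 200).
#' @return A non-redundant `DNAStringSet`, longest first. The number of
#'   contigs removed by containment is attached as
#'   `attr(, "n_contained")`.
#' @export
deduplicate_contigs <- function(assemblies, min_len = 200L) {
  if (is(assemblies, "XStringSet")) assemblies <- list(assemblies)
  stopifnot(length(assemblies) >= 1L)
  pool <- do.call(c, lapply(assemblies, function(a) {
    setNames(as.character(a), names(a))
  }))
  names(pool) <- make.unique(names(pool), sep = "#")
  pool <- pool[nchar(pool) >= min_len]
  ord <- order(-nchar(pool), names(pool))
  pool <- pool[ord]
  rc <- as.character(reverseComplement(DNAStringSet(pool)))
  retained <- character(0)
  retained_ids <- character(0)
  n_contained <- 0L
  for (i in seq_along(pool)) {
    contained <- length(retained) > 0L &&
      (any(grepl(pool[i], retained, fixed = TRUE)) ||
         any(grepl(rc[i], retained, fixed = TRUE)))
    if (contained) {
      n_contained <- n_contained + 1L
    } else {
      retained <- c(retained, pool[i])
      retained_ids <- c(retained_ids, names(pool)[i])
    }
  }
  out <- DNAStringSet(setNames(retained, retained_ids))
  attr(out, "n_contained") <- n_contained
  out
}

#' Assembly length statistics
#'
#' Computes contig counts, mean length, total bases and N50 after applying
#' the minimum-length filter. N50 is the largest length L such that contigs
#' of length >= L contain at least half of all assembled bases (descending
#' cumulative sum).
#'
#' @param contigs A `DNAStringSet` (or numeric vector of lengths).
#' @param min_len Minimum contig length (default 200); shorter contigs are
#'   dropped before any statistic is computed.
#' @return An object of class `assembly_stats`: list with `n_contigs`,
#'   `n_ge_1kb`, `n_ge_n50`, `mean_len`, `n50`, `total_bases`, `min_len`.
#' @export
assembly_stats <- function(contigs, min_len = 200L) {
  lens <- if (is.numeric(contigs)) as.integer(contigs) else width(contigs)
  lens <- lens[lens >= min_len]
  if (length(lens) == 0L) stop("no contigs of length >= ", min_len)
  sl <- sort(lens, decreasing = TRUE)
  total <- sum(as.numeric(sl))
  n50 <- sl[which(cumsum(as.numeric(sl)) >= total / 2)[1]]
  structure(list(n_contigs = length(sl),
                 n_ge_1kb = sum(sl >= 1000L),
                 n_ge_n50 = sum(sl >= n50),
                 mean_len = mean(sl),
                 n50 = n50,
                 total_bases = total,
                 min_len = as.integer(min_len)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Assembly statistics (contigs >= %d bp)\n", x$min_len))
  cat(sprintf("  contigs: %d  (>= 1 kb: %d, >= N50: %d)\n",
              x$n_contigs, x$n_ge_1kb, x$n_ge_n50))
  cat(sprintf("  mean length: %.1f bp   N50: %d bp   total: %.0f bp\n",
              x$mean_len, x$n50, x$total_bases))
  invisible(x)
}

#' @export
#' @method as.data.frame assembly_stats
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(n_contigs = x$n_contigs, n_ge_1kb = x$n_ge_1kb,
             n_ge_n50 = x$n_ge_n50, mean_len = round(x$mean_len, 1),
             n50 = x$n50, total_bases = x$total_bases)
}

#' Best local nucleotide alignment between two sequences
#'
#' Smith-Waterman local alignment (via
#' [Biostrings::pairwiseAlignment()]) under match = +1, mismatch = -2,
#' gap = -3 per gapped position, searching both strands of the query.
#'
#' @param query,subject `DNAString`s, `DNAStringSet`s of length 1, or
#'   character scalars.
#' @return A list with `score`, `identity` (percent, matches / alignment
#'   columns x 100), `aligned_len` (alignment columns), `q_start`, `q_end`
#'   (forward strand of the query), `s_start`, `s_end`, `strand`
#'   (`"+"`/`"-"`), and the underlying `PairwiseAlignments` object as
#'   `alignment`.
#' @export
local_align_nt <- function(query, subject) {
  q <- as(query, "DNAString")
  s <- as(subject, "DNAString")
  if (length(q) == 0L || length(s) == 0L) stop("empty sequence")
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                      baseOnly = FALSE)
  aln_f <- pairwiseAlignment(q, s, type = "local", substitutionMatrix = mat,
                             gapOpening = 0, gapExtension = 3)
  aln_r <- pairwiseAlignment(reverseComplement(q), s, type = "local",
                             substitutionMatrix = mat,
                             gapOpening = 0, gapExtension = 3)
  minus <- score(aln_r) > score(aln_f)
  aln <- if (minus) aln_r else aln_f
  cols <- nchar(as.character(pattern(aln)))
  qs <- start(pattern(aln)); qe <- end(pattern(aln))
  if (minus) {
    L <- length(q)
    tmp <- qs
    qs <- L - qe + 1L
    qe <- L - tmp + 1L
  }
  list(score = score(aln),
       identity = 100 * nmatch(aln) / cols,
       aligned_len = cols,
       q_start = qs, q_end = qe,
       s_start = start(subject(aln)), s_end = end(subject(aln)),
       strand = if (minus) "-" else "+",
       alignment = aln)
}

# subject-coordinate positions of indel columns of a local alignment
.indel_positions_on_subject <- function(aln) {
  p <- strsplit(as.character(pattern(aln)), "")[[1]]
  s <- strsplit(as.character(subject(aln)), "")[[1]]
  spos <- start(subject(aln)) - 1L + cumsum(s != "-")
  spos[s == "-"] <- NA  # insertion in query: between subject positions
  idx <- which(p == "-" | s == "-")
  if (length(idx) == 0L) return(integer(0))
  # an insertion column inherits the preceding subject position
  pos <- spos[idx]
  for (i in which(is.na(pos))) {
    prior <- spos[seq_len(idx[i])]
    pos[i] <- if (all(is.na(prior))) start(subject(aln)) else
      max(prior, na.rm = TRUE)
  }
  pos
}

#' Assess an assembly against a benchmark full-length cDNA set
#'
#' Classifies each benchmark cDNA by how well any contig reconstructs it:
#' `COMPLETE` if a contig aligns at >= `min_identity` percent identity over
#' >= `min_len` columns and the alignment covers the cDNA's entire ORF with
#' no indel columns inside the ORF; `PARTIAL` if a qualifying alignment
#' exists but the ORF is not fully and cleanly covered; `POOR` if no
#' qualifying alignment exists.
#'
#' @param contigs `DNAStringSet` of assembled contigs.
#' @param benchmark_cdnas `DNAStringSet` of benchmark full-length cDNAs.
#' @param benchmark_orfs Data.frame with `id`, `orf_start`, `orf_end`
#'   (1-based inclusive ORF interval on each cDNA).
#' @param min_identity,min_len Qualifying-alignment thresholds (defaults
#'   90 percent over 100 columns).
#' @return An object of class `benchmark_assessment`: list with
#'   `per_cdna` (data.frame `id`, `class`, `matched_contig`) and `summary`
#'   (data.frame `class`, `count`, `percent` to 1 decimal).
#' @export
assess_against_benchmark <- function(contigs, benchmark_cdnas,
                                     benchmark_orfs,
                                     min_identity = 90, min_len = 100L) {
  stopifnot(all(c("id", "orf_start", "orf_end") %in% names(benchmark_orfs)))
  cand <- kmer_candidates(benchmark_cdnas, contigs)
  classes <- character(length(benchmark_cdnas))
  matched <- rep(NA_character_, length(benchmark_cdnas))
  for (i in seq_along(benchmark_cdnas)) {
    orf <- benchmark_orfs[benchmark_orfs$id == names(benchmark_cdnas)[i], ]
    if (nrow(orf) != 1L) {
      stop("benchmark ORF coordinates missing for ",
           names(benchmark_cdnas)[i])
    }
    cls <- "POOR"
    for (j in cand[[i]]) {
      al <- local_align_nt(contigs[[j]], benchmark_cdnas[[i]])
      if (al$identity < min_identity || al$aligned_len < min_len) next
      if (cls == "POOR") {
        cls <- "PARTIAL"
        matched[i] <- names(contigs)[j]
      }
      covers <- al$s_start <= orf$orf_start && al$s_end >= orf$orf_end
      if (covers) {
        ind <- .indel_positions_on_subject(al$alignment)
        if (!any(ind >= orf$orf_start & ind <= orf$orf_end)) {
          cls <- "COMPLETE"
          matched[i] <- names(contigs)[j]
          break
        }
      }
    }
    classes[i] <- cls
  }
  per_cdna <- data.frame(id = names(benchmark_cdnas), class = classes,
                         matched_contig = matched, stringsAsFactors = FALSE)
  counts <- table(factor(classes, levels = c("COMPLETE", "PARTIAL", "POOR")))
  summary <- percentage_table(setNames(as.integer(counts), names(counts)),
                              denominator = length(benchmark_cdnas),
                              decimals = 1L)
  structure(list(per_cdna = per_cdna, summary = summary),
            class = "benchmark_assessment")
}

#' @export
print.benchmark_assessment <- function(x, ...) {
  cat("Benchmark full-length cDNA assessment\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
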