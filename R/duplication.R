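# PSV/MSV-based duplicate-gene detection under the doubled-haploid null.
#
# In a doubled haploid there are no allelic variants, so any well-supported
# "SNP" in the pileup of reads mapped back to an assembled transcript marks
# a paralogous sequence variant between collapsed duplicate gene copies.

#' Map reads to transcripts at high identity
#'
#' Seed-and-extend, ungapped, end-to-end mapping of each read to its
#' best-matching transcript position on either strand. Placements below
#' `min_identity` are rejected; a read tied between several transcripts is
#' reported on all of them (cross-mapping between collapsed paralogs is
#' precisely the signal source for PSV detection).
#'
#' @param reads A `DNAStringSet`/`QualityScaledDNAStringSet` or character
#'   vector of reads.
#' @param transcripts A named `DNAStringSet` of reference transcripts.
#' @param min_identity Minimum identity `(aligned_len - mismatches) /
#'   aligned_len` for an accepted placement (default 0.99).
#' @param seed_len Exact k-mer seed length (default 21). Reads shorter than
#'   the seed are unmappable.
#' @return A data.frame of placements: `read_id`, `transcript_id`, `start`
#'   (1-based on the transcript), `strand` (`"+"`/`"-"`), `n_mismatches`,
#'   `aligned_len`.
#' @export
map_reads <- function(reads, transcripts, min_identity = 0.99,
                      seed_len = 21L) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  r_chr <- as.character(reads)
  t_chr <- as.character(transcripts)
  res <- .map_reads_cpp(unname(r_chr), unname(t_chr), as.integer(seed_len),
                        min_identity)
  read_names <- names(reads)
  if (is.null(read_names)) read_names <- as.character(seq_along(r_chr))
  data.frame(
    read_id = read_names[res$read],
    transcript_id = names(transcripts)[res$transcript],
    start = res$start,
    strand = ifelse(res$strand > 0, "+", "-"),
    n_mismatches = res$n_mismatches,
    aligned_len = res$aligned_len,
    read = res$read, transcript = res$transcript,
    stringsAsFactors = FALSE
  )
}

#' Build a per-position base pileup from read placements
#'
#' Accumulates base counts per covered transcript position. Minus-strand
#' placements contribute the reverse complement of the read, i.e. the
#' transcript-forward base. Positions with zero depth are omitted.
#'
#' @param placements Data.frame from [map_reads()] (the integer `read` and
#'   `transcript` index columns are used).
#' @param transcripts The `DNAStringSet` passed to [map_reads()].
#' @param reads The reads passed to [map_reads()].
#' @return A data.frame with `transcript_id`, `pos` (1-based), `A`, `C`,
#'   `G`, `T` counts and `depth`.
#' @export
build_pileup <- function(placements, transcripts, reads) {
  if (nrow(placements) == 0L) {
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), depth = integer(0)))
  }
  res <- .build_pileup_cpp(placements$read, placements$transcript,
                           placements$start,
                           ifelse(placements$strand == "+", 1L, -1L),
                           unname(as.character(reads)),
                           unname(as.character(transcripts)))
  out <- data.frame(transcript_id = names(transcripts)[res$transcript],
                    pos = res$pos, A = res$A, C = res$C, G = res$G,
                    T = res$T, stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out
}

#' Call PSVs/MSVs from a pileup
#'
#' A position is called iff its depth is at least `min_depth`, the count of
#' the second-most-frequent base is at least `min_minor`, and the minor
#' allele frequency (second count / depth) is at least `min_maf`. Under the
#' doubled-haploid premise every such call is a paralogous sequence variant
#' (or multisite variant), not an allelic SNP.
#'
#' @param pileup Data.frame from [build_pileup()].
#' @param min_depth Minimum read depth (default 4).
#' @param min_minor Minimum minor-allele read count (default 2).
#' @param min_maf Minimum minor allele frequency (default 0.10).
#' @return A data.frame of calls: `transcript_id`, `pos`, `major_allele`,
#'   `minor_allele`, `depth`, `minor_count`, `maf`. Ties for the major
#'   allele are broken in base order A < C < G < T.
#' @export
call_psvs <- function(pileup, min_depth = 4L, min_minor = 2L,
                      min_maf = 0.10) {
  empty <- data.frame(transcript_id = character(0), pos = integer(0),
                      major_allele = character(0), minor_allele = character(0),
                      depth = integer(0), minor_count = integer(0),
                      maf = numeric(0))
  if (nrow(pileup) == 0L) return(empty)
  cm <- as.matrix(pileup[, c("A", "C", "G", "T")])
  # order within each row: ties broken by base order (A<C<G<T) because
  # max.col(ties.method = "first") scans columns left to right
  major_i <- max.col(cm, ties.method = "first")
  major_n <- cm[cbind(seq_len(nrow(cm)), major_i)]
  cm2 <- cm
  cm2[cbind(seq_len(nrow(cm)), major_i)] <- -1L
  minor_i <- max.col(cm2, ties.method = "first")
  minor_n <- cm[cbind(seq_len(nrow(cm)), minor_i)]
  depth <- pileup$depth
  keep <- depth >= min_depth & minor_n >= min_minor &
    minor_n / depth >= min_maf
  if (!any(keep)) return(empty)
  bases <- c("A", "C", "G", "T")
  data.frame(transcript_id = pileup$transcript_id[keep],
             pos = pileup$pos[keep],
             major_allele = bases[major_i[keep]],
             minor_allele = bases[minor_i[keep]],
             depth = depth[keep],
             minor_count = minor_n[keep],
             maf = minor_n[keep] / depth[keep],
             stringsAsFactors = FALSE)
}

#' Summarize PSV calls into putative duplicated genes
#'
#' Pools calls per gene over all of a gene's transcripts (distinct
#' `(transcript, pos)` sites counted once) and flags genes with at least
#' one PSV as putative duplicates.
#'
#' @param calls Data.frame from [call_psvs()].
#' @param transcript_to_gene Named character vector mapping transcript ids
#'   to gene ids (for real data, the transcript's unique best protein hit;
#'   for synthetic data, the truth).
#' @return An object of class `duplication_summary`: list with `genes`
#'   (data.frame `gene_id`, `n_psv`, `is_putative_duplicate`), `histogram`
#'   (data.frame `n_psv`, `n_genes` over flagged genes), `n_calls`,
#'   `n_transcripts_with_calls`.
#' @export
summarize_duplicates <- function(calls, transcript_to_gene) {
  calls <- unique(calls[, c("transcript_id", "pos")])
  gene <- transcript_to_gene[calls$transcript_id]
  if (anyNA(gene)) {
    orphan <- unique(calls$transcript_id[is.na(gene)])
    warning(length(orphan), " transcript(s) with calls but no gene ",
            "mapping excluded: ", paste(head(orphan, 5), collapse = ", "))
    calls <- calls[!is.na(gene), , drop = FALSE]
    gene <- gene[!is.na(gene)]
  }
  if (nrow(calls) == 0L) {
    genes <- data.frame(gene_id = character(0), n_psv = integer(0),
                        is_putative_duplicate = logical(0))
    hist <- data.frame(n_psv = integer(0), n_genes = integer(0))
  } else {
    tab <- table(gene)
    genes <- data.frame(gene_id = names(tab), n_psv = as.integer(tab),
                        is_putative_duplicate = TRUE,
                        stringsAsFactors = FALSE)
    genes <- genes[order(genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL
    ht <- table(genes$n_psv)
    hist <- data.frame(n_psv = as.integer(names(ht)),
                       n_genes = as.integer(ht))
  }
  structure(list(genes = genes, histogram = hist,
                 n_calls = nrow(calls),
                 n_transcripts_with_calls =
                   length(unique(calls$transcript_id))),
            class = "duplication_summary")
}

#' @export
print.duplication_summary <- function(x, ...) {
  cat("PSV/MSV duplication summary\n")
  cat(sprintf("  %d PSV/MSV sites on %d transcript(s), %d putative ",
              x$n_calls, x$n_transcripts_with_calls, nrow(x$genes)))
  cat("duplicated gene(s)\n")
  if (nrow(x$histogram)) {
    cat("  PSVs-per-gene histogram:\n")
    print(x$histogram, row.names = FALSE)
  }
  invisible(x)
}

#' Count genomic contigs hit by PSV-bearing transcripts
#'
#' Each transcript is aligned (via [local_align_nt()]) to candidate genome
#' contigs sharing at least one exact k-mer; contigs reached at >= 90%
#' identity over at least `min_len` aligned columns count as hits.
#' Duplicated genes are expected to hit more than one genomic contig.
#'
#' @param transcripts `DNAStringSet` of PSV-bearing transcripts.
#' @param genome_contigs `DNAStringSet` of genomic contigs.
#' @param min_len Minimum aligned length for a hit (default 100).
#' @param min_identity Minimum percent identity (default 90).
#' @param seed_len Candidate-prefilter k-mer length (default 21); contig
#'   pairs sharing no exact k-mer on either strand are not aligned.
#' @return A data.frame with `transcript_id`, `n_contigs_hit`, and `class`
#'   in `{"multi-hit", "single-hit", "no-hit"}`.
#' @export
evaluate_genome_hits <- function(transcripts, genome_contigs,
                                 min_len = 100L, min_identity = 90,
                                 seed_len = 21L) {
  cand <- kmer_candidates(transcripts, genome_contigs, k = seed_len)
  n_hit <- integer(length(transcripts))
  names(n_hit) <- names(transcripts)
  for (i in seq_along(transcripts)) {
    subj <- cand[[i]]
    for (j in subj) {
      al <- local_align_nt(transcripts[[i]], genome_contigs[[j]])
      if (al$identity >= min_identity && al$aligned_len >= min_len) {
        n_hit[i] <- n_hit[i] + 1L
      }
    }
  }
  data.frame(transcript_id = names(transcripts),
             n_contigs_hit = unname(n_hit),
             class = ifelse(n_hit > 1L, "multi-hit",
                            ifelse(n_hit == 1L, "single-hit", "no-hit")),
             stringsAsFactors = FALSE)
}

# indices of subjects sharing >= 1 exact k-mer (either strand) per query;
# low-complexity seeds (long homopolymer runs, e.g. around polyA tails)
# would link unrelated sequences and are excluded
kmer_candidates <- function(queries, subjects, k = 21L, stride = 5L) {
  q_chr <- as.character(queries)
  s_chr <- as.character(subjects)
  s_rc <- as.character(reverseComplement(DNAStringSet(s_chr)))
  low_complexity <- function(km) {
    grepl("A{12,}|C{12,}|G{12,}|T{12,}", km)
  }
  q_kmers <- lapply(q_chr, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    km <- unique(substring(s, starts, starts + k - 1L))
    km[!low_complexity(km)]
  })
  all_q <- unique(unlist(q_kmers, use.names = FALSE))
  hit_any <- function(subj_seq) {
    # which query k-mers occur in this subject
    L <- nchar(subj_seq)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    intersect(unique(substring(subj_seq, starts, starts + k - 1L)), all_q)
  }
  subj_kmers <- lapply(seq_along(s_chr), function(j) {
    union(hit_any(s_chr[j]), hit_any(s_rc[j]))
  })
  lapply(seq_along(q_chr), function(i) {
    qi <- q_kmers[[i]]
    which(vapply(subj_kmers, function(sk) any(qi %in% sk), logical(1)))
  })
}

#' Write PSV calls as a VCF-like tab-separated table
#'
#' @param calls Data.frame from [call_psvs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psv_table <- function(calls, path) {
  out <- calls
  out$maf <- sprintf("%.4f", out$maf)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
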