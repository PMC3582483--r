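# UTR sequence-context analyses: Kozak window, stop-codon context and
# usage, polyA-tail selection, and polyadenylation-signal hexamer
# discovery.
#
# Motifs are handled as DNA internally; reports use the RNA alphabet (U)
# to match the conventions of the motif literature.

IUPAC_FROM_SET <- c(A = "A", C = "C", G = "G", T = "T",
                    AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                    GT = "K", ACG = "V", ACT = "H", AGT = "D", CGT = "B",
                    ACGT = "N")

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' Extract fixed-width sequence windows around start or stop codons
#'
#' For `anchor = "START"` the default window spans positions -4..+4 (8
#' bases, the start `ATG` at +1..+3); for `anchor = "STOP"` it spans
#' -6..+12 (18 bases, the stop codon at +1..+3). There is no position 0:
#' +1 is the first base of the anchor codon, -1 the base before it.
#' Transcripts whose window would run off either end are skipped and
#' counted.
#'
#' @param transcripts Named `DNAStringSet`.
#' @param anns ORF annotations ([annotate_orfs()]); only `FULL_LENGTH`
#'   rows are accepted.
#' @param anchor `"START"` or `"STOP"`.
#' @param upstream,downstream Bases before the anchor codon and after its
#'   first base; defaults give the -4..+4 and -6..+12 windows.
#' @param rna Report windows in the RNA alphabet (default `FALSE`).
#' @return Named character vector of windows; skipped-transcript count in
#'   `attr(, "n_skipped")`.
#' @export
extract_context <- function(transcripts, anns,
                            anchor = c("START", "STOP"),
                            upstream = NULL, downstream = NULL,
                            rna = FALSE) {
  anchor <- match.arg(anchor)
  if (any(anns$completeness != "FULL_LENGTH")) {
    stop("extract_context() requires FULL_LENGTH annotations only")
  }
  if (is.null(upstream)) upstream <- if (anchor == "START") 4L else 6L
  if (is.null(downstream)) downstream <- if (anchor == "START") 4L else 12L

  out <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(anns))) {
    id <- anns$transcript_id[i]
    s <- as.character(transcripts[[id]])
    L <- nchar(s)
    if (!is.na(anns$strand[i]) && anns$strand[i] == "-") {
      s <- as.character(reverseComplement(DNAString(s)))
      cs <- L - anns$cds_end[i] + 1L
      ce <- L - anns$cds_start[i] + 1L
    } else {
      cs <- anns$cds_start[i]
      ce <- anns$cds_end[i]
    }
    a <- if (anchor == "START") cs else ce - 2L  # first base of anchor codon
    from <- a - upstream
    to <- a + downstream - 1L
    if (from < 1L || to > L) {
      n_skipped <- n_skipped + 1L
      next
    }
    out <- c(out, setNames(substr(s, from, to), id))
  }
  if (rna) out[] <- dna_to_rna(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build a position frequency matrix
#'
#' Per-position base counts, frequencies, and information content
#' (2 minus the base-2 Shannon entropy of the column; no small-sample
#' correction) over a set of equal-length gap-free windows.
#'
#' @param windows Character vector of equal-length DNA (or RNA) windows.
#' @param positions Optional integer position labels (e.g. `-4..-1, 1..4`);
#'   defaults to signed labels centred so that the first downstream
#'   position is +1 with no position 0.
#' @param upstream Number of upstream positions used to derive default
#'   labels when `positions` is `NULL` (default half the window).
#' @return An object of class `pfm`: list with `counts` and `freqs`
#'   (4 x width matrices, rows A/C/G/U in the internal DNA encoding
#'   A/C/G/T), `info_bits`, `positions`, `n_sequences`.
#' @export
build_pfm <- function(windows, positions = NULL, upstream = NULL) {
  if (length(windows) == 0L) stop("no windows supplied")
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("windows differ in length")
  dna <- chartr("Uu", "Tt", windows)
  mat <- matrix(unlist(strsplit(toupper(dna), ""), use.names = FALSE),
                nrow = length(windows), byrow = TRUE)
  counts <- apply(mat, 2, function(col) {
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L)
  })
  rownames(counts) <- DNA_BASES
  freqs <- sweep(counts, 2, colSums(counts), "/")
  info <- apply(freqs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  if (is.null(positions)) {
    if (is.null(upstream)) upstream <- w %/% 2L
    positions <- c(seq(-upstream, -1L), seq_len(w - upstream))
  }
  stopifnot(length(positions) == w)
  colnames(counts) <- colnames(freqs) <- names(info) <- positions
  structure(list(counts = counts, freqs = freqs, info_bits = info,
                 positions = as.integer(positions),
                 n_sequences = length(windows)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d sequences x %d positions\n",
              x$n_sequences, length(x$positions)))
  cat("  consensus:", dna_to_rna(consensus_from_pfm(x)), "(RNA)\n")
  cat(sprintf("  information content: %.2f-%.2f bits\n",
              min(x$info_bits), max(x$info_bits)))
  invisible(x)
}

#' Consensus sequence from a position frequency matrix
#'
#' Per-position argmax base; ties are rendered as IUPAC ambiguity codes.
#'
#' @param pfm A [build_pfm()] object.
#' @param rna Return in the RNA alphabet (default `FALSE`).
#' @return A character scalar.
#' @export
consensus_from_pfm <- function(pfm, rna = FALSE) {
  cons <- apply(pfm$counts, 2, function(cc) {
    top <- DNA_BASES[cc == max(cc)]
    IUPAC_FROM_SET[[paste(top, collapse = "")]]
  })
  out <- paste(cons, collapse = "")
  if (rna) dna_to_rna(out) else out
}

#' Export a PFM as a tab-separated table
#'
#' Rows are signed positions; columns are per-base counts and frequencies
#' (RNA alphabet) plus information content.
#'
#' @param pfm A [build_pfm()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = pfm$positions,
                   t(pfm$counts),
                   round(t(pfm$freqs), 4),
                   info_bits = round(pfm$info_bits, 4))
  names(df) <- c("position", paste0("n_", c("A", "C", "G", "U")),
                 paste0("f_", c("A", "C", "G", "U")), "info_bits")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stop codon usage
#'
#' Relative usage of the three stop codons among full-length annotations.
#'
#' @param anns ORF annotations; only `FULL_LENGTH` rows are used.
#' @param transcripts Named `DNAStringSet` the annotations refer to.
#' @return Data.frame with `stop_codon` (RNA alphabet: UGA/UAA/UAG),
#'   `count`, and `percent` (1 decimal).
#' @export
stop_codon_usage <- function(anns, transcripts) {
  fl <- anns[anns$completeness == "FULL_LENGTH", , drop = FALSE]
  if (nrow(fl) == 0L) stop("no FULL_LENGTH annotations")
  stops <- vapply(seq_len(nrow(fl)), function(i) {
    s <- as.character(transcripts[[fl$transcript_id[i]]])
    if (!is.na(fl$strand[i]) && fl$strand[i] == "-") {
      s <- as.character(reverseComplement(DNAString(s)))
      L <- nchar(s)
      ce <- L - fl$cds_start[i] + 1L
    } else {
      ce <- fl$cds_end[i]
    }
    substr(s, ce - 2L, ce)
  }, character(1))
  counts <- table(factor(stops, levels = c("TGA", "TAA", "TAG")))
  out <- percentage_table(setNames(as.integer(counts), names(counts)),
                          denominator = nrow(fl), decimals = 1L)
  names(out)[1] <- "stop_codon"
  out$stop_codon <- dna_to_rna(out$stop_codon)
  out
}

#' Select polyA-tailed transcripts
#'
#' A transcript qualifies iff its terminal run of `A` has length at least
#' `min_a`; internal A-runs are irrelevant.
#'
#' @param transcripts Named `DNAStringSet`.
#' @param min_a Minimum terminal adenosine count (default 7).
#' @return Data.frame with `transcript_id`, `polya_start` (1-based first
#'   position of the terminal run), `polya_len`.
#' @export
select_polya_transcripts <- function(transcripts, min_a = 7L) {
  s <- as.character(transcripts)
  run <- nchar(s) - nchar(sub("A+$", "", s))
  keep <- run >= min_a
  data.frame(transcript_id = names(transcripts)[keep],
             polya_start = (nchar(s) - run + 1L)[keep],
             polya_len = run[keep],
             stringsAsFactors = FALSE)
}

#' Polyadenylation-signal hexamer scan
#'
#' Counts every overlapping N-free hexamer in the `window_len` bases
#' immediately upstream of each transcript's polyA run (exhaustive
#' fixed-length enumeration, equivalent to exact pattern discovery at
#' L = W = 6), classifies hexamers against the canonical signal, and
#' assigns each transcript its highest-priority hexamer present:
#' canonical AAUAAA first, then AUUAAA, then the other single-base
#' variants (most frequent first, ties alphabetical), then none.
#'
#' @param transcripts Named `DNAStringSet`.
#' @param polya Data.frame from [select_polya_transcripts()].
#' @param window_len Upstream window length in bp (default 35; shorter if
#'   the transcript is too short).
#' @return An object of class `hexamer_table`: list with `table`
#'   (data.frame `hexamer` (RNA), `window_count`, `transcript_count`,
#'   `class` in CANONICAL/SINGLE_BASE_VARIANT/OTHER), `assigned`
#'   (data.frame `transcript_id`, `assigned_pas` (RNA or `"none"`)),
#'   `n_windows`, `n_transcripts`.
#' @export
pas_hexamer_scan <- function(transcripts, polya, window_len = 35L) {
  canon <- "AATAAA"
  n_tx <- nrow(polya)
  win_counts <- list()
  tx_hex <- vector("list", n_tx)
  n_windows <- 0L
  for (i in seq_len(n_tx)) {
    s <- as.character(transcripts[[polya$transcript_id[i]]])
    to <- polya$polya_start[i] - 1L
    from <- max(1L, to - window_len + 1L)
    win <- substr(s, from, to)
    W <- nchar(win)
    if (W < 6L) {
      tx_hex[[i]] <- character(0)
      next
    }
    starts <- seq_len(W - 5L)
    hex <- substring(win, starts, starts + 5L)
    hex <- hex[!grepl("N", hex, fixed = TRUE)]
    n_windows <- n_windows + length(hex)
    win_counts[[i]] <- hex
    tx_hex[[i]] <- unique(hex)
  }
  all_hex <- unlist(win_counts, use.names = FALSE)
  wc <- table(all_hex)
  tc <- table(unlist(tx_hex, use.names = FALSE))
  hexamers <- sort(unique(c(names(wc), names(tc))))
  hamming1 <- function(h) {
    sum(strsplit(h, "")[[1]] != strsplit(canon, "")[[1]]) == 1L
  }
  cls <- vapply(hexamers, function(h) {
    if (h == canon) "CANONICAL"
    else if (nchar(h) == 6L && hamming1(h)) "SINGLE_BASE_VARIANT"
    else "OTHER"
  }, character(1))
  tab <- data.frame(hexamer = dna_to_rna(hexamers),
                    window_count = as.integer(wc[hexamers]),
                    transcript_count = as.integer(tc[hexamers]),
                    class = unname(cls),
                    stringsAsFactors = FALSE)
  tab$window_count[is.na(tab$window_count)] <- 0L
  tab$transcript_count[is.na(tab$transcript_count)] <- 0L
  tab <- tab[order(-tab$transcript_count, tab$hexamer), , drop = FALSE]
  rownames(tab) <- NULL

  # per-transcript assignment by fixed priority
  sbv <- hexamers[cls == "SINGLE_BASE_VARIANT" & hexamers != "ATTAAA"]
  sbv <- sbv[order(-as.integer(tc[sbv]), sbv)]
  priority <- c(canon, "ATTAAA", sbv)
  assigned <- vapply(tx_hex, function(hx) {
    hit <- priority[priority %in% hx]
    if (length(hit)) dna_to_rna(hit[1]) else "none"
  }, character(1))
  structure(list(table = tab,
                 assigned = data.frame(
                   transcript_id = polya$transcript_id,
                   assigned_pas = assigned,
                   stringsAsFactors = FALSE),
                 n_windows = n_windows,
                 n_transcripts = n_tx),
            class = "hexamer_table")
}

#' @export
print.hexamer_table <- function(x, ...) {
  cat(sprintf("PAS hexamer scan: %d transcripts, %d hexamer windows\n",
              x$n_transcripts, x$n_windows))
  print(head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Polyadenylation-signal mixture report
#'
#' Partitions the selected transcripts by their assigned PAS and reports
#' counts with integer percentages of the selected-transcript denominator.
#'
#' @param hex A [pas_hexamer_scan()] result.
#' @return Data.frame with `assigned_pas`, `count`, `percent` (integer
#'   percentages; raw counts are retained so no information is lost to
#'   rounding).
#' @export
pas_mixture_report <- function(hex) {
  counts <- table(hex$assigned$assigned_pas)
  counts <- counts[order(-as.integer(counts), names(counts))]
  out <- percentage_table(setNames(as.integer(counts), names(counts)),
                          denominator = hex$n_transcripts, decimals = 0L)
  names(out)[1] <- "assigned_pas"
  out
}
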