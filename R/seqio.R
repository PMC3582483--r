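# Sequence I/O and read cleaning.
#
# Sequences are carried as Biostrings objects throughout the package:
# DNAStringSet for contigs/transcripts, QualityScaledDNAStringSet
# (Phred+33 / PhredQuality) for reads, AAStringSet for proteins.

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] (or
#' [Biostrings::readAAStringSet()]) that splits the identifier from the
#' description and enforces identifier uniqueness.
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return A `DNAStringSet` (or `AAStringSet`) named by the identifier (the
#'   header token before the first whitespace). Any remaining description is
#'   kept in `metadata(x)$description`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- if (type == "DNA") readDNAStringSet(path) else readAAStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  desc <- sub("^\\S+\\s*", "", full)
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier in ", path, ": ",
         ids[anyDuplicated(ids)])
  }
  names(x) <- ids
  S4Vectors::metadata(x)$description <- setNames(desc, ids)
  x
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- DNAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all sequences must be named before writing FASTA")
  }
  writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A `QualityScaledDNAStringSet` with `PhredQuality` (Phred+33)
#'   qualities.
#' @details Only Sanger/Illumina 1.8+ (Phred+33) encoding is supported;
#'   records whose quality string length differs from the sequence length
#'   cause an error. Paired files are read as two calls; mates correspond by
#'   record order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # validate the 4-line record structure on a streaming pass; the binary
  # parser below silently pads short quality strings otherwise
  n_lines <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    chunk <- readLines(con, n = 65536L)  # multiple of 4
    if (length(chunk) == 0L) break
    if (length(chunk) %% 4L != 0L) {
      stop("truncated FASTQ record at end of ", path)
    }
    i <- seq(1L, length(chunk), by = 4L)
    if (any(!startsWith(chunk[i], "@")) ||
        any(!startsWith(chunk[i + 2L], "+"))) {
      stop("malformed FASTQ record in ", path, " near line ",
           n_lines + i[which(!startsWith(chunk[i], "@"))[1]])
    }
    bad <- which(nchar(chunk[i + 1L]) != nchar(chunk[i + 3L]))
    if (length(bad)) {
      stop("FASTQ record with sequence/quality length mismatch in ",
           path, " near line ", n_lines + i[bad[1]])
    }
    n_lines <- n_lines + length(chunk)
  }
  x <- suppressWarnings(
    readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  if (length(x) != n_lines %/% 4L) {
    stop("truncated or malformed FASTQ record in ", path)
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param x A `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(is(x, "QualityScaledDNAStringSet"))
  writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param x A `QualityScaledDNAStringSet` or `PhredQuality`/`BStringSet` of
#'   quality strings.
#' @return An `IntegerList` of per-base Phred scores.
#' @export
phred_scores <- function(x) {
  if (is(x, "QualityScaledDNAStringSet")) x <- quality(x)
  if (!is(x, "PhredQuality")) x <- PhredQuality(as(x, "BStringSet"))
  as(x, "IntegerList")
}

#' Clean short reads
#'
#' Applies the standard read-cleaning rules for this pipeline: optional
#' literal adaptor clipping, removal of terminal runs of `N` from both ends,
#' then discarding of reads whose post-trim mean Phred quality is below
#' `min_avg_q` or whose post-trim length is below `min_len`.
#'
#' @param reads A `QualityScaledDNAStringSet` (Phred+33).
#' @param min_avg_q Minimum whole-read mean quality after trimming
#'   (default 20).
#' @param min_len Minimum read length after trimming in bp (default 15).
#' @param adaptor Optional literal adaptor string; if supplied, one leading
#'   and/or trailing exact occurrence is clipped (with everything outward of
#'   it) before `N` trimming. No default: adaptor sequences are
#'   platform/library specific and must be user supplied.
#' @return The retained, trimmed `QualityScaledDNAStringSet`. The number of
#'   discarded reads is attached as `attr(, "n_discarded")`.
#' @details The quality rule is applied as the mean over the trimmed read
#'   (not per-base). Trimming is idempotent: applying the function to its
#'   own output changes nothing.
#' @export
trim_reads <- function(reads, min_avg_q = 20L, min_len = 15L, adaptor = NULL) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  n0 <- length(reads)
  if (n0 == 0L) {
    attr(reads, "n_discarded") <- 0L
    return(reads)
  }
  s <- as.character(reads)
  q <- as.character(quality(reads))

  if (!is.null(adaptor) && nzchar(adaptor)) {
    # clip a terminal exact adaptor occurrence and anything outward of it
    pre <- startsWith(s, adaptor)
    suf <- endsWith(s, adaptor)
    al <- nchar(adaptor)
    from <- ifelse(pre, al + 1L, 1L)
    to <- nchar(s) - ifelse(suf & nchar(s) >= from + al - 1L, al, 0L)
    keepable <- to >= from
    s <- ifelse(keepable, substr(s, from, to), "")
    q <- ifelse(keepable, substr(q, from, to), "")
  }

  # terminal N runs, both ends
  lead <- nchar(s) - nchar(sub("^N+", "", s))
  trail <- nchar(s) - nchar(sub("N+$", "", s))
  trail[nchar(s) == lead] <- 0L  # all-N read: already emptied by lead trim
  from <- lead + 1L
  to <- nchar(s) - trail
  ok <- to >= from
  s[ok] <- substr(s[ok], from[ok], to[ok])
  q[ok] <- substr(q[ok], from[ok], to[ok])
  s[!ok] <- ""
  q[!ok] <- ""

  len <- nchar(s)
  qual_int <- as(PhredQuality(BStringSet(q)), "IntegerList")
  mean_q <- sum(qual_int) / pmax(len, 1L)
  keep <- len >= min_len & mean_q >= min_avg_q
  out <- QualityScaledDNAStringSet(DNAStringSet(s[keep]),
                                   PhredQuality(BStringSet(q[keep])))
  names(out) <- names(reads)[keep]
  attr(out, "n_discarded") <- n0 - sum(keep)
  out
}

hit_table_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore", "frame")

#' Read a tabular homology-hit file
#'
#' Reads a tab-separated hit table in BLAST `outfmt 6` column order
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), optionally extended with a 13th `frame` column for
#' translated searches. Coordinates are 1-based inclusive.
#'
#' @param path Path to the table (no header).
#' @return A data.frame with columns named as above; a missing `frame`
#'   column is filled with `+1` with a warning.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("hits table not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!ncol(df) %in% c(12L, 13L)) {
    stop("hit table must have 12 or 13 tab-separated columns, found ",
         ncol(df))
  }
  if (ncol(df) == 12L) {
    warning("hit table lacks a frame column; assuming frame +1")
    df$frame <- "1"
  }
  names(df) <- hit_table_cols
  num_cols <- setdiff(hit_table_cols, c("qseqid", "sseqid"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(sub("^\\+", "", df[[cc]])))
    bad <- which(is.na(v) & !(df[[cc]] %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value in column '", cc, "' of ", path,
           " at row ", bad[1L])
    }
    df[[cc]] <- v
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "frame")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  validate_hits(df)
  df
}

#' Write a homology-hit table
#'
#' @param hits Data.frame as returned by [read_hits_table()] or
#'   [translated_search()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  validate_hits(hits)
  out <- hits[, hit_table_cols]
  out$frame <- sprintf("%+d", out$frame)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_hits <- function(hits) {
  stopifnot(all(hit_table_cols %in% names(hits)))
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$frame == 0L | abs(hits$frame) > 3L)) {
    stop("frame must be in {-3,-2,-1,+1,+2,+3}")
  }
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("percent identity outside [0, 100]")
  }
  if (any(hits$qstart > hits$qend)) {
    stop("qstart > qend: query coordinates must be forward-strand ordered")
  }
  invisible(hits)
}
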