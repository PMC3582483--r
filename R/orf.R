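# Homology-guided and ab initio ORF prediction, full-length classification,
# and UTR extraction.

STOP_CODONS <- c("TAA", "TAG", "TGA")
COMPLETENESS_LEVELS <- c("FULL_LENGTH", "PARTIAL_5P", "PARTIAL_3P",
                         "INCORRECT_ORF", "NO_ORF")

.translate_chr <- function(dna) {
  if (nchar(dna) < 3L) return("")
  dna <- substr(dna, 1L, 3L * (nchar(dna) %/% 3L))
  # the fuzzy-codon path rebuilds its genetic-code table on every call;
  # only take it when an ambiguous base is actually present
  fuzzy <- grepl("[^ACGT]", dna)
  as.character(Biostrings::translate(
    DNAString(dna), if.fuzzy.codon = if (fuzzy) "X" else "error"))
}

#' Six-frame translation
#'
#' @param seq A `DNAString` or character scalar over `{A,C,G,T,N}`.
#' @return A named character vector of the six translated frames
#'   (`"+1","+2","+3","-1","-2","-3"`); stops are rendered `*`, codons
#'   containing `N` as `X`, and trailing partial codons are dropped.
#' @export
six_frame_translate <- function(seq) {
  s <- as.character(as(seq, "DNAString"))
  rc <- as.character(reverseComplement(DNAString(s)))
  out <- character(6)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (f in 1:3) {
    out[f] <- .translate_chr(substr(s, f, nchar(s)))
    out[f + 3L] <- .translate_chr(substr(rc, f, nchar(rc)))
  }
  out
}

# protein k-mer index: list(kmers = unique k-mers, prot = IntegerList of
# protein indices per k-mer)
.protein_kmer_index <- function(proteins, k = 6L) {
  p_chr <- as.character(proteins)
  km <- lapply(seq_along(p_chr), function(i) {
    L <- nchar(p_chr[i])
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    unique(substring(p_chr[i], starts, starts + k - 1L))
  })
  all_km <- unlist(km, use.names = FALSE)
  prot_of <- rep(seq_along(p_chr), lengths(km))
  uk <- unique(all_km)
  list(kmers = uk, prot = unname(split(prot_of, match(all_km, uk))))
}

.frame_to_nt <- function(frame, p1, p2, L) {
  off <- abs(frame) - 1L
  nt1 <- off + 3L * (p1 - 1L) + 1L
  nt2 <- off + 3L * p2
  if (frame > 0L) c(nt1, nt2) else c(L - nt2 + 1L, L - nt1 + 1L)
}

#' Translated homology search
#'
#' Finds, for each transcript, the best local protein alignment between any
#' of its six translated frames and a reference protein set
#' (BLOSUM62, affine gaps open 11 / extend 1). Candidate proteins are
#' pre-selected by shared exact amino-acid `seed_aa`-mers; an unrelated
#' random protein shares none and can in practice not reach the score
#' floor. Hits scoring below `score_floor` are dropped.
#'
#' @param transcripts Named `DNAStringSet` (or character vector).
#' @param proteins Named `AAStringSet` of reference proteins.
#' @param score_floor Minimum raw alignment score (default 50).
#' @param seed_aa Amino-acid seed length for candidate pre-selection
#'   (default 6).
#' @param min_seed_hits Minimum number of distinct shared seeds before a
#'   frame/protein pair is aligned (default 2: chance co-occurrence of two
#'   distinct 6-mers between unrelated sequences is vanishingly rare,
#'   while even a short stretch of genuine homology shares many).
#' @param max_candidates At most this many candidate proteins (by
#'   descending shared-seed count) are aligned per frame (default 20).
#' @return A hit table (one best row per transcript with a hit) in
#'   `outfmt 6` + `frame` layout: `qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore frame`. Query
#'   coordinates are forward-strand nucleotides (1-based inclusive);
#'   subject coordinates are residues. Ties are broken by lower subject id.
#' @export
translated_search <- function(transcripts, proteins, score_floor = 50,
                              seed_aa = 6L, min_seed_hits = 2L,
                              max_candidates = 20L) {
  if (length(proteins) == 0L) stop("empty protein set")
  if (is.character(transcripts)) transcripts <- DNAStringSet(transcripts)
  if (is.null(names(transcripts))) {
    names(transcripts) <- as.character(seq_along(transcripts))
  }
  idx <- .protein_kmer_index(proteins, k = seed_aa)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  p_aa <- as.character(proteins)
  rows <- vector("list", length(transcripts))
  for (ti in seq_along(transcripts)) {
    L <- width(transcripts)[ti]
    frames <- six_frame_translate(transcripts[[ti]])
    frame_num <- c(1L, 2L, 3L, -1L, -2L, -3L)
    best <- NULL
    for (fi in seq_along(frames)) {
      pep <- frames[fi]
      if (nchar(pep) < seed_aa) next
      starts <- seq_len(nchar(pep) - seed_aa + 1L)
      qk <- unique(substring(pep, starts, starts + seed_aa - 1L))
      hit_k <- match(qk, idx$kmers)
      hits <- unlist(idx$prot[hit_k[!is.na(hit_k)]], use.names = FALSE)
      if (length(hits) == 0L) next
      tab <- sort(table(hits), decreasing = TRUE)
      tab <- tab[tab >= min_seed_hits]
      cands <- as.integer(names(head(tab, max_candidates)))
      for (pi in cands) {
        aln <- pairwiseAlignment(AAString(pep), AAString(p_aa[pi]),
                                 type = "local", substitutionMatrix = B62,
                                 gapOpening = 11, gapExtension = 1)
        sc <- score(aln)
        if (sc < score_floor) next
        better <- is.null(best) || sc > best$score ||
          (sc == best$score &&
             names(proteins)[pi] < names(proteins)[best$pi])
        if (better) {
          best <- list(score = sc, pi = pi, aln = aln,
                       frame = frame_num[fi])
        }
      }
    }
    if (is.null(best)) next
    aln <- best$aln
    pat <- as.character(pattern(aln))
    sub <- as.character(subject(aln))
    cols <- nchar(pat)
    gaps <- sum(strsplit(pat, "")[[1]] == "-") +
      sum(strsplit(sub, "")[[1]] == "-")
    nm <- nmatch(aln)
    qnt <- .frame_to_nt(best$frame, start(pattern(aln)), end(pattern(aln)),
                        L)
    gap_runs <- function(x) {
      m <- gregexpr("-+", x)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }
    gapopens <- gap_runs(pat) + gap_runs(sub)
    rows[[ti]] <- data.frame(
      qseqid = names(transcripts)[ti],
      sseqid = names(proteins)[best$pi],
      pident = 100 * nm / cols,
      length = cols,
      mismatch = cols - gaps - nm,
      gapopen = gapopens,
      qstart = qnt[1], qend = qnt[2],
      sstart = start(subject(aln)), send = end(subject(aln)),
      evalue = NA_real_,
      bitscore = best$score,
      frame = best$frame,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  out
}

#' Homology-guided ORF prediction
#'
#' Working in the hit's frame and strand: the CDS start is the in-frame
#' `ATG` at, or nearest upstream of, the aligned region with no intervening
#' in-frame stop; failing that, the first in-frame `ATG` inside the aligned
#' region; failing that the alignment start with `has_start = FALSE`. The
#' CDS end is the first in-frame stop at or downstream of the aligned
#' region (included in the CDS interval); if none exists before the
#' transcript end, the last complete codon with `has_stop = FALSE`.
#'
#' @param transcript A `DNAString`/character scalar.
#' @param hit One row of a hit table from [translated_search()] referring
#'   to this transcript.
#' @return A one-row data.frame (an ORF annotation): `transcript_id`,
#'   `strand`, `cds_start`, `cds_end` (1-based inclusive on the forward
#'   strand, stop codon included when present), `has_start`, `has_stop`,
#'   `protein` (translated CDS without the terminator), `orf_ratio` (`NA`
#'   until [compute_orf_ratio()]), `completeness` (`NA` until
#'   [classify_completeness()]), `source`, plus the alignment bookkeeping
#'   fields `subject_id`, `s_start`, `s_end`, `start_offset_res` (residues
#'   between alignment start and chosen start; negative = upstream).
#' @export
predict_orf_guided <- function(transcript, hit) {
  s_fwd <- as.character(as(transcript, "DNAString"))
  L <- nchar(s_fwd)
  f <- hit$frame
  s <- if (f > 0L) s_fwd else
    as.character(reverseComplement(DNAString(s_fwd)))
  if (f > 0L) {
    a1 <- hit$qstart; a2 <- hit$qend
  } else {
    a1 <- L - hit$qend + 1L; a2 <- L - hit$qstart + 1L
  }
  off <- abs(f) - 1L
  if ((a1 - 1L - off) %% 3L != 0L) {
    stop("hit frame inconsistent with its query coordinates")
  }
  codon_at <- function(p) substr(s, p, p + 2L)

  # start: at, then nearest upstream, stopping at the first in-frame stop
  has_start <- FALSE
  cds_start_o <- a1
  p <- a1
  repeat {
    cod <- codon_at(p)
    if (p != a1 && cod %in% STOP_CODONS) break
    if (cod == "ATG") {
      has_start <- TRUE
      cds_start_o <- p
      break
    }
    if (p - 3L < 1L) break
    p <- p - 3L
  }
  if (!has_start) {
    # first in-frame ATG inside the aligned region
    p <- a1
    while (p + 2L <= a2) {
      if (codon_at(p) == "ATG") {
        has_start <- TRUE
        cds_start_o <- p
        break
      }
      p <- p + 3L
    }
  }

  # end: first in-frame stop from the codon containing the alignment end
  has_stop <- FALSE
  k0 <- (a2 - a1) %/% 3L
  p <- a1 + 3L * k0
  cds_end_o <- NA_integer_
  while (p + 2L <= L) {
    if (codon_at(p) %in% STOP_CODONS) {
      has_stop <- TRUE
      cds_end_o <- p + 2L
      break
    }
    p <- p + 3L
  }
  if (!has_stop) {
    cds_end_o <- cds_start_o + 3L * ((L - cds_start_o + 1L) %/% 3L) - 1L
  }

  cds_o <- substr(s, cds_start_o, cds_end_o)
  prot_part <- if (has_stop) substr(cds_o, 1L, nchar(cds_o) - 3L) else cds_o
  protein <- .translate_chr(prot_part)

  if (f > 0L) {
    cds_start <- cds_start_o; cds_end <- cds_end_o
  } else {
    cds_start <- L - cds_end_o + 1L; cds_end <- L - cds_start_o + 1L
  }
  data.frame(
    transcript_id = hit$qseqid,
    strand = if (f > 0L) "+" else "-",
    cds_start = cds_start, cds_end = cds_end,
    has_start = has_start, has_stop = has_stop,
    protein = protein,
    orf_ratio = NA_real_,
    completeness = NA_character_,
    source = "GUIDED",
    subject_id = hit$sseqid,
    s_start = hit$sstart, s_end = hit$send,
    start_offset_res = as.integer((cds_start_o - a1) / 3L),
    stringsAsFactors = FALSE
  )
}

#' Ab initio ORF prediction
#'
#' Finds the longest complete `ATG`-to-stop ORF over all six frames. Ties
#' are broken in favour of the plus strand, then the lowest forward-strand
#' start coordinate. Returns a `NO_ORF` annotation if the longest ORF
#' encodes fewer than `min_aa` amino acids.
#'
#' @param transcript A `DNAString`/character scalar.
#' @param min_aa Minimum protein length in residues (default 30).
#' @param id Transcript id recorded in the annotation.
#' @return A one-row ORF-annotation data.frame (see
#'   [predict_orf_guided()]) with `source = "AB_INITIO"`; when no
#'   qualifying ORF exists, `completeness` is `"NO_ORF"` and the
#'   coordinates are `NA`.
#' @export
predict_orf_ab_initio <- function(transcript, min_aa = 30L, id = "query") {
  s_fwd <- as.character(as(transcript, "DNAString"))
  L <- nchar(s_fwd)
  rc <- as.character(reverseComplement(DNAString(s_fwd)))
  best <- NULL
  for (fi in 1:6) {
    strand <- if (fi <= 3L) "+" else "-"
    off <- (fi - 1L) %% 3L
    s <- if (strand == "+") s_fwd else rc
    n_codon <- (nchar(s) - off) %/% 3L
    if (n_codon < 2L) next
    starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg <- cumsum(c(FALSE, head(is_stop, -1L)))  # segment between stops
    for (j in which(is_stop)) {
      in_seg <- which(is_atg & seg == seg[j] & seq_along(codons) < j)
      if (length(in_seg) == 0L) next
      a <- in_seg[1L]
      aa_len <- j - a
      # oriented coordinates of ATG..stop inclusive
      o1 <- starts[a]; o2 <- starts[j] + 2L
      if (strand == "+") {
        c1 <- o1; c2 <- o2
      } else {
        c1 <- L - o2 + 1L; c2 <- L - o1 + 1L
      }
      better <- is.null(best) || aa_len > best$aa_len ||
        (aa_len == best$aa_len &&
           (strand == "+" & best$strand == "-")) ||
        (aa_len == best$aa_len && strand == best$strand && c1 < best$c1)
      if (better) {
        best <- list(aa_len = aa_len, strand = strand, c1 = c1, c2 = c2,
                     o1 = o1, o2 = o2, s = s)
      }
    }
  }
  if (is.null(best) || best$aa_len < min_aa) {
    return(data.frame(transcript_id = id, strand = NA_character_,
                      cds_start = NA_integer_, cds_end = NA_integer_,
                      has_start = FALSE, has_stop = FALSE,
                      protein = NA_character_, orf_ratio = NA_real_,
                      completeness = "NO_ORF", source = "AB_INITIO",
                      subject_id = NA_character_, s_start = NA_integer_,
                      s_end = NA_integer_, start_offset_res = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  prot <- .translate_chr(substr(best$s, best$o1, best$o2 - 3L))
  data.frame(
    transcript_id = id, strand = best$strand,
    cds_start = best$c1, cds_end = best$c2,
    has_start = TRUE, has_stop = TRUE,
    protein = prot, orf_ratio = NA_real_,
    completeness = NA_character_, source = "AB_INITIO",
    subject_id = NA_character_, s_start = NA_integer_,
    s_end = NA_integer_, start_offset_res = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' ORF length ratio
#'
#' Predicted protein length divided by the reference protein length. A
#' ratio of at least 0.9 marks a full-length candidate; 1.0 or more marks a
#' complete-or-longer CDS.
#'
#' @param ann A one-row ORF annotation.
#' @param ref_protein_len Length of the matched reference protein in
#'   residues (must be >= 1).
#' @return The annotation with `orf_ratio` filled in.
#' @export
compute_orf_ratio <- function(ann, ref_protein_len) {
  if (is.na(ref_protein_len) || ref_protein_len < 1) {
    stop("reference protein length must be >= 1")
  }
  ann$orf_ratio <- nchar(ann$protein) / ref_protein_len
  ann
}

#' Classify transcript completeness
#'
#' A guided annotation is `FULL_LENGTH` iff it has both a start and a stop
#' codon and the chosen start maps within `tol` residues of the reference
#' protein's first residue while the alignment reaches within `tol`
#' residues of its last. A missing or displaced 5' end gives `PARTIAL_5P`,
#' a missing stop (or an alignment stopping short of the protein end)
#' `PARTIAL_3P`. `INCORRECT_ORF` marks internal stops in the claimed CDS
#' and start choices that contradict the alignment span: a start implying
#' a position more than `tol` residues upstream of the protein's first
#' residue (a chance upstream ATG), or -- when the alignment shows the
#' protein's start region is present on the transcript (`sstart <= tol`)
#' -- a start buried more than `tol` residues inside the aligned region
#' (no usable ATG near the homologous start, e.g. a corrupted start
#' codon). When instead the alignment itself begins well into the
#' reference protein, the transcript genuinely lacks 5' sequence and is
#' `PARTIAL_5P`.
#'
#' @param ann A one-row guided ORF annotation.
#' @param hit The hit row used for the prediction.
#' @param ref_protein_len Reference protein length in residues.
#' @param tol Agreement tolerance in residues (default 10).
#' @return The annotation with `completeness` set.
#' @export
classify_completeness <- function(ann, hit, ref_protein_len, tol = 10L) {
  stopifnot(ann$source == "GUIDED")
  implied_start <- hit$sstart + ann$start_offset_res
  cls <- NULL
  if (grepl("*", ann$protein, fixed = TRUE)) {
    cls <- "INCORRECT_ORF"
  } else if (ann$has_start && implied_start < 1L - tol) {
    # chance ATG far upstream of where the protein begins
    cls <- "INCORRECT_ORF"
  } else if (ann$has_start && ann$start_offset_res > tol &&
             hit$sstart <= tol) {
    # the alignment shows the protein start region is present on the
    # transcript, yet no usable ATG exists near it (e.g. a corrupted start
    # codon); a start buried deep inside the homology contradicts the span
    cls <- "INCORRECT_ORF"
  } else {
    ok5 <- ann$has_start && abs(implied_start - 1L) <= tol
    ok3 <- ann$has_stop && (ref_protein_len - hit$send) <= tol
    cls <- if (ok5 && ok3) "FULL_LENGTH"
    else if (!ok5) "PARTIAL_5P"
    else "PARTIAL_3P"
  }
  ann$completeness <- cls
  ann
}

#' Extract UTR sequences around an annotated CDS
#'
#' @param transcript A `DNAString`/character scalar.
#' @param ann A one-row ORF annotation with forward-strand coordinates.
#' @return A list with `utr5` and `utr3` character scalars, reported in
#'   mRNA sense (minus-strand ORFs are reverse-complemented first); the
#'   polyA tail, if present, remains part of `utr3`.
#' @export
extract_utrs <- function(transcript, ann) {
  s <- as.character(as(transcript, "DNAString"))
  L <- nchar(s)
  if (is.na(ann$cds_start) || ann$cds_start < 1L || ann$cds_end > L) {
    stop("CDS coordinates out of transcript bounds")
  }
  if (!is.na(ann$strand) && ann$strand == "-") {
    s <- as.character(reverseComplement(DNAString(s)))
    cs <- L - ann$cds_end + 1L
    ce <- L - ann$cds_start + 1L
  } else {
    cs <- ann$cds_start
    ce <- ann$cds_end
  }
  list(utr5 = substr(s, 1L, cs - 1L), utr3 = substr(s, ce + 1L, L))
}

#' Annotate ORFs across a transcript set
#'
#' Runs the translated homology search (unless a precomputed hit table is
#' supplied), guided prediction plus completeness classification and ORF
#' ratio for transcripts with a hit, and ab initio prediction for the
#' rest.
#'
#' @param transcripts Named `DNAStringSet`.
#' @param proteins Named `AAStringSet` of reference proteins.
#' @param hits Optional precomputed hit table (best hit per transcript) in
#'   the layout of [translated_search()].
#' @param min_aa Ab initio minimum ORF length in residues (default 30).
#' @param score_floor,seed_aa Passed to [translated_search()].
#' @param tol Completeness tolerance in residues (default 10).
#' @return An object of class `orf_annotations`: the per-transcript
#'   annotation data.frame, with the classification summary as
#'   `attr(, "summary")`.
#' @export
annotate_orfs <- function(transcripts, proteins, hits = NULL,
                          min_aa = 30L, score_floor = 50, seed_aa = 6L,
                          tol = 10L) {
  if (is.null(hits)) {
    hits <- translated_search(transcripts, proteins,
                              score_floor = score_floor, seed_aa = seed_aa)
  }
  ref_len <- setNames(nchar(as.character(proteins)), names(proteins))
  rows <- vector("list", length(transcripts))
  for (i in seq_along(transcripts)) {
    id <- names(transcripts)[i]
    h <- if (nrow(hits)) hits[hits$qseqid == id, , drop = FALSE] else hits
    if (!is.null(nrow(h)) && nrow(h) >= 1L) {
      h <- h[1L, , drop = FALSE]
      ann <- predict_orf_guided(transcripts[[i]], h)
      ann <- classify_completeness(ann, h, ref_len[[h$sseqid]], tol = tol)
      ann <- compute_orf_ratio(ann, ref_len[[h$sseqid]])
    } else {
      ann <- predict_orf_ab_initio(transcripts[[i]], min_aa = min_aa,
                                   id = id)
    }
    rows[[i]] <- ann
  }
  out <- do.call(rbind, rows)
  cls <- table(factor(out$completeness, levels = COMPLETENESS_LEVELS))
  attr(out, "summary") <- data.frame(class = names(cls),
                                     count = as.integer(cls))
  class(out) <- c("orf_annotations", "data.frame")
  out
}
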