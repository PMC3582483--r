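# Truth-tracked synthetic doubled-haploid transcriptome and read simulator.
#
# The generator emulates the statistical structure the downstream stages
# assume: a fully homozygous transcriptome in which a fraction of genes are
# collapsed duplicated pairs at low divergence, transcripts composed of
# 5'UTR + CDS + stop + 3'UTR + polyA, a weighted start-codon (Kozak)
# context, a stop-codon usage mixture, and a polyadenylation-signal hexamer
# mixture planted 10-30 nt upstream of the polyA run.

DNA_BASES <- c("A", "C", "G", "T")

# codon table derived from the standard nuclear genetic code, cached
.codon_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      aa <- setdiff(unique(gc_tab), "*")
      by_aa <- split(names(gc_tab), gc_tab)[aa]
      n_syn <- lengths(by_aa)
      mat <- matrix(NA_character_, nrow = length(aa), ncol = max(n_syn),
                    dimnames = list(aa, NULL))
      for (a in aa) mat[a, seq_len(n_syn[[a]])] <- by_aa[[a]]
      cache <<- list(aa = aa, by_aa = by_aa, n_syn = n_syn, mat = mat)
    }
    cache
  }
})

#' Default polyadenylation-signal hexamer mixture
#'
#' The canonical hexamer at 0.61, its most common variant AUUAAA at 0.21,
#' and the remaining 0.18 spread uniformly over the other 17 single-base
#' variants of the canonical signal (DNA alphabet).
#'
#' @return Named numeric vector of hexamer probabilities summing to 1.
#' @export
default_pas_mixture <- function() {
  canon <- "AATAAA"
  vars <- character(0)
  cb <- strsplit(canon, "")[[1]]
  for (i in seq_len(6)) {
    for (b in setdiff(DNA_BASES, cb[i])) {
      v <- cb
      v[i] <- b
      vars <- c(vars, paste(v, collapse = ""))
    }
  }
  vars <- setdiff(vars, "ATTAAA")
  p <- c(0.61, 0.21, rep(0.18 / length(vars), length(vars)))
  setNames(p, c(canon, "ATTAAA", vars))
}

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic doubled-haploid
#' transcriptome generator. Defaults encode the study conditions the
#' pipeline is designed for: 20% of genes duplicated at 0.5% copy
#' divergence, CDS lengths of 50-600 codons, a Kozak-like start context
#' centred on `AAACATGG`, stop-codon usage of 48.5/32.5/19% for
#' TGA/TAA/TAG, a PAS mixture dominated by AATAAA (61%) and ATTAAA (21%),
#' and 100-bp paired-end reads from 350-bp fragments at 30-fold coverage.
#'
#' @param n_genes Number of genes to simulate.
#' @param seed Integer seed; mandatory, all generator stages derive their
#'   RNG state from it.
#' @param dup_fraction Fraction of genes carrying a collapsed duplicate
#'   copy.
#' @param psv_rate Per-base divergence between duplicate copies; values
#'   above 0.01 draw a warning because single 100-bp reads then often span
#'   two or more PSVs and fail the 99%-identity mapping filter, which
#'   lowers detection sensitivity.
#' @param cds_len_dist Integer range (min, max) of protein lengths in
#'   codons; the stop codon is appended in addition.
#' @param utr5_len_dist,utr3_len_dist Integer ranges (min, max) of UTR
#'   lengths in bp; the 3'UTR length excludes the polyA tail.
#' @param kozak_consensus 8-mer consensus for positions -4..+4 around the
#'   start codon (positions +1..+3 must be `ATG`).
#' @param kozak_strength Probability mass on the consensus base at each
#'   free Kozak position (the remainder split evenly); 1 plants the
#'   consensus as a point mass.
#' @param stop_usage Named probabilities over the stop codons TGA/TAA/TAG.
#' @param pas_mixture Named hexamer probability vector (DNA alphabet); see
#'   [default_pas_mixture()].
#' @param polya_len PolyA tail length in nt (>= 7 so tailed transcripts are
#'   recoverable by the polyA selector).
#' @param read_len Read length in bp.
#' @param mean_depth Mean fold-coverage per gene (both copies pooled).
#' @param seq_error_rate Per-base sequencing error rate.
#' @param insert_len Fragment (insert) size in bp.
#' @param abundance_skew Fraction of a duplicated gene's coverage assigned
#'   to copy A (0.5 = equal paralog expression; values away from 0.5
#'   exercise the minor-allele-frequency filter).
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_genes = 100L,
                       seed,
                       dup_fraction = 0.2,
                       psv_rate = 0.005,
                       cds_len_dist = c(50L, 600L),
                       utr5_len_dist = c(20L, 500L),
                       utr3_len_dist = c(100L, 2000L),
                       kozak_consensus = "AAACATGG",
                       kozak_strength = 0.55,
                       stop_usage = c(TGA = 0.485, TAA = 0.325, TAG = 0.19),
                       pas_mixture = default_pas_mixture(),
                       polya_len = 20L,
                       read_len = 100L,
                       mean_depth = 30,
                       seq_error_rate = 0.001,
                       insert_len = 350L,
                       abundance_skew = 0.5) {
  if (missing(seed)) stop("sim_config(): 'seed' is mandatory")
  cfg <- list(n_genes = as.integer(n_genes), seed = as.integer(seed),
              dup_fraction = dup_fraction, psv_rate = psv_rate,
              cds_len_dist = as.integer(cds_len_dist),
              utr5_len_dist = as.integer(utr5_len_dist),
              utr3_len_dist = as.integer(utr3_len_dist),
              kozak_consensus = toupper(kozak_consensus),
              kozak_strength = kozak_strength,
              stop_usage = stop_usage, pas_mixture = pas_mixture,
              polya_len = as.integer(polya_len),
              read_len = as.integer(read_len), mean_depth = mean_depth,
              seq_error_rate = seq_error_rate,
              insert_len = as.integer(insert_len),
              abundance_skew = abundance_skew)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L,
            cfg$dup_fraction >= 0, cfg$dup_fraction <= 1,
            cfg$psv_rate >= 0,
            length(cfg$cds_len_dist) == 2L,
            cfg$cds_len_dist[1] >= 2L,
            diff(cfg$cds_len_dist) >= 0,
            cfg$utr5_len_dist[1] >= 4L,   # Kozak window needs 4 nt of 5'UTR
            cfg$utr3_len_dist[1] >= 45L,  # room for PAS placement
            cfg$polya_len >= 7L,
            cfg$read_len >= 21L,
            cfg$insert_len >= cfg$read_len,
            cfg$seq_error_rate >= 0, cfg$seq_error_rate < 0.1,
            cfg$abundance_skew > 0, cfg$abundance_skew < 1)
  if (cfg$psv_rate > 0.05) {
    stop("psv_rate above 0.05 is not supported")
  }
  if (cfg$psv_rate > 0.01) {
    warning("psv_rate above 0.01: reads will often span several PSVs and ",
            "fail the 99%-identity mapping filter, reducing sensitivity")
  }
  if (nchar(cfg$kozak_consensus) != 8L ||
      substr(cfg$kozak_consensus, 5L, 7L) != "ATG") {
    stop("kozak_consensus must be an 8-mer with ATG at positions 5-7")
  }
  if (cfg$kozak_strength <= 0 || cfg$kozak_strength > 1) {
    stop("kozak_strength must be in (0, 1]")
  }
  if (!setequal(names(cfg$stop_usage), c("TGA", "TAA", "TAG")) ||
      abs(sum(cfg$stop_usage) - 1) > 1e-9) {
    stop("stop_usage must be named TGA/TAA/TAG and sum to 1")
  }
  if (is.null(names(cfg$pas_mixture)) ||
      any(nchar(names(cfg$pas_mixture)) != 6L) ||
      abs(sum(cfg$pas_mixture) - 1) > 1e-9) {
    stop("pas_mixture must be a named hexamer vector summing to 1")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic doubled-haploid transcriptome configuration\n")
  cat(sprintf("  genes: %d (duplicated fraction %.2f, copy divergence %.4f)\n",
              x$n_genes, x$dup_fraction, x$psv_rate))
  cat(sprintf("  CDS %d-%d codons; 5'UTR %d-%d bp; 3'UTR %d-%d bp; polyA %d\n",
              x$cds_len_dist[1], x$cds_len_dist[2],
              x$utr5_len_dist[1], x$utr5_len_dist[2],
              x$utr3_len_dist[1], x$utr3_len_dist[2], x$polya_len))
  cat(sprintf("  reads: %d bp paired, insert %d bp, depth %gx, error %g\n",
              x$read_len, x$insert_len, x$mean_depth, x$seq_error_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# uniform integer draw over [a, b] that is safe when a == b (unlike
# sample(a:b, ...), which would sample 1:a)
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

# one long random-DNA string cut into pieces of the requested lengths
rand_dna <- function(lens) {
  if (length(lens) == 0L) return(character(0))
  total <- sum(lens)
  s <- paste(sample(DNA_BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(lens)
  substring(s, ends - lens + 1L, ends)
}

# 4 x 8 Kozak position-probability matrix from consensus + strength
kozak_profile <- function(cfg) {
  cons <- strsplit(cfg$kozak_consensus, "")[[1]]
  prof <- matrix((1 - cfg$kozak_strength) / 3, nrow = 4, ncol = 8,
                 dimnames = list(DNA_BASES, NULL))
  for (j in 1:8) prof[cons[j], j] <- cfg$kozak_strength
  prof[, 5:7] <- 0
  prof["A", 5] <- 1; prof["T", 6] <- 1; prof["G", 7] <- 1
  prof
}

#' Generate a synthetic proteome
#'
#' Draws `n_genes` random proteins with lengths uniform over
#' `cds_len_dist` (codons). Every protein starts with methionine; the
#' second residue is drawn compatible with the Kozak +4 base profile (it
#' must own a codon starting with the drawn base) so that the start-codon
#' context can later be planted on the transcript; all remaining residues
#' are i.i.d. uniform over the 20 amino acids.
#'
#' @param cfg A [sim_config()].
#' @return An `AAStringSet` named `g0001 ...`.
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ct <- .codon_cache()
  n <- cfg$n_genes
  lens <- sample_range(cfg$cds_len_dist, n)
  prof4 <- kozak_profile(cfg)[, 8]
  first_base <- substr(ct$mat[ct$aa, 1], 1, 1)  # not exhaustive; see below
  # amino acids owning >= 1 codon starting with each base
  aa_by_first <- lapply(DNA_BASES, function(b) {
    ct$aa[vapply(ct$by_aa, function(cc) any(startsWith(cc, b)), logical(1))]
  })
  names(aa_by_first) <- DNA_BASES
  b4 <- sample(DNA_BASES, n, replace = TRUE, prob = prof4)
  res2 <- vapply(b4, function(b) sample(aa_by_first[[b]], 1L), character(1))
  body_lens <- lens - 2L
  total <- sum(body_lens)
  body_all <- paste(sample(ct$aa, total, replace = TRUE), collapse = "")
  ends <- cumsum(body_lens)
  bodies <- substring(body_all, ends - body_lens + 1L, ends)
  prots <- paste0("M", res2, bodies)
  AAStringSet(setNames(prots, sprintf("g%04d", seq_len(n))))
}

# uniformly-random synonymous reverse translation of one protein
reverse_translate <- function(protein, kozak_b4 = NULL) {
  ct <- .codon_cache()
  res <- strsplit(protein, "")[[1]]
  idx <- match(res, ct$aa)
  if (anyNA(idx)) {
    stop("protein contains a residue with no codon: ",
         res[which(is.na(idx))[1]])
  }
  pick <- floor(runif(length(idx)) * ct$n_syn[idx]) + 1L
  codons <- ct$mat[cbind(idx, pick)]
  if (!is.null(kozak_b4) && length(res) >= 2L) {
    # re-draw the second codon among synonyms starting with the Kozak +4 base
    syn2 <- ct$by_aa[[res[2]]]
    syn2b <- syn2[startsWith(syn2, kozak_b4)]
    if (length(syn2b)) codons[2] <- sample(syn2b, 1L)
  }
  paste(codons, collapse = "")
}

#' Generate a truth-tracked doubled-haploid transcriptome
#'
#' Builds one representative transcript per gene
#' (5'UTR + CDS + stop + 3'UTR + polyA) by reverse-translating the given
#' proteome with uniformly random synonymous codons, planting the Kozak
#' -4..+4 context, a stop codon drawn from the configured usage mixture,
#' and a PAS hexamer whose 3' end lies 10-29 nt upstream of the polyA run
#' (hence entirely within the 35-bp scan window). For duplicated genes a
#' second copy diverged at `psv_rate` is created, but only copy A enters
#' the transcript set, emulating assembly collapse of recent duplicates;
#' both copies are retained for read simulation and as synthetic "genome"
#' records.
#'
#' @param cfg A [sim_config()].
#' @param proteome `AAStringSet` from [generate_proteome()].
#' @return A list with elements
#'   \describe{
#'     \item{transcripts}{`DNAStringSet`, one representative (copy A) per
#'       gene.}
#'     \item{truth}{data.frame with one row per gene: `gene_id`,
#'       `is_duplicated`, `cds_start`, `cds_end` (1-based inclusive, stop
#'       codon included), `stop_codon`, `pas_hexamer`, `polya_start`,
#'       `n_psv`, `psv_positions` (comma-separated 1-based positions on the
#'       representative transcript), `protein`. The diverged copies are
#'       attached as `attr(truth, "copies")`, a `DNAStringSet` named
#'       `<gene>|A` / `<gene>|B`.}
#'   }
#' @export
generate_transcriptome <- function(cfg, proteome) {
  stopifnot(inherits(cfg, "sim_config"), length(proteome) == cfg$n_genes)
  set.seed(cfg$seed + 2L)
  n <- cfg$n_genes
  ids <- names(proteome)
  prof <- kozak_profile(cfg)

  utr5_len <- sample_range(cfg$utr5_len_dist, n)
  utr3_len <- sample_range(cfg$utr3_len_dist, n)
  stop_codons <- sample(names(cfg$stop_usage), n, TRUE, prob = cfg$stop_usage)
  pas <- sample(names(cfg$pas_mixture), n, TRUE, prob = cfg$pas_mixture)
  pas_gap <- sample_range(c(10L, 29L), n)  # hexamer end -> polyA start distance
  n_dup <- round(cfg$dup_fraction * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  is_dup <- seq_len(n) %in% dup_idx

  utr5 <- rand_dna(utr5_len)
  utr3_front <- rand_dna(pmax(utr3_len - 6L - pas_gap, 0L))
  utr3_gap <- rand_dna(pas_gap)
  # last base before the polyA tail must not be A, so the observed terminal
  # A-run equals the planted tail
  substr(utr3_gap, pas_gap, pas_gap) <-
    sample(c("C", "G", "T"), n, replace = TRUE)
  polya <- strrep("A", cfg$polya_len)

  free_pos <- c(1:4, 8)
  kozak_cols <- matrix("", nrow = n, ncol = 5L)
  for (j in seq_along(free_pos)) {
    kozak_cols[, j] <- sample(DNA_BASES, n, TRUE,
                              prob = prof[, free_pos[j]])
  }
  # overwrite the last 4 bases of the 5'UTR with the drawn -4..-1 context
  for (j in 1:4) {
    substr(utr5, utr5_len - 4L + j, utr5_len - 4L + j) <- kozak_cols[, j]
  }

  prot_chr <- as.character(proteome)
  cds <- vapply(seq_len(n), function(i) {
    reverse_translate(prot_chr[i], kozak_b4 = kozak_cols[i, 5]) },
    character(1))

  tx <- paste0(utr5, cds, stop_codons, utr3_front, pas, utr3_gap, polya)
  tx_len <- nchar(tx)
  cds_start <- utr5_len + 1L
  cds_end <- utr5_len + nchar(cds) + 3L
  polya_start <- tx_len - cfg$polya_len + 1L

  # diverged copy B for duplicated genes: substitutions at psv_rate over the
  # non-polyA body (a PSV inside the homopolymer tail would be unmappable)
  copy_b <- rep(NA_character_, n)
  psv_pos <- vector("list", n)
  for (i in dup_idx) {
    body_len <- polya_start[i] - 1L
    k <- rbinom(1L, body_len, cfg$psv_rate)
    if (k == 0L) k <- 1L  # a duplicate with zero PSVs is invisible by design
    pos <- sort(sample.int(body_len, k))
    b <- tx[i]
    for (p in pos) {
      cur <- substr(b, p, p)
      substr(b, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
    copy_b[i] <- b
    psv_pos[[i]] <- pos
  }

  truth <- data.frame(
    gene_id = ids,
    is_duplicated = is_dup,
    cds_start = cds_start,
    cds_end = cds_end,
    stop_codon = stop_codons,
    pas_hexamer = names(cfg$pas_mixture)[match(pas, names(cfg$pas_mixture))],
    polya_start = polya_start,
    n_psv = vapply(psv_pos, length, integer(1)),
    psv_positions = vapply(psv_pos, function(p) paste(p, collapse = ","),
                           character(1)),
    protein = prot_chr,
    stringsAsFactors = FALSE
  )

  copies <- setNames(tx, paste0(ids, "|A"))
  if (any(is_dup)) {
    copies <- c(copies, setNames(copy_b[is_dup], paste0(ids[is_dup], "|B")))
  }
  attr(truth, "copies") <- DNAStringSet(copies)
  list(transcripts = DNAStringSet(setNames(tx, ids)), truth = truth)
}

# introduce k[i] uniform substitution errors into string i
.add_errors <- function(reads, n_err) {
  idx <- which(n_err > 0L)
  for (i in idx) {
    w <- nchar(reads[i])
    pos <- sample.int(w, min(n_err[i], w))
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  reads
}

#' Simulate paired-end reads from the synthetic transcriptome
#'
#' Draws fragments uniformly along each gene's copies (both copies for
#' duplicated genes, copy A only otherwise) to an expected total coverage
#' of `mean_depth`, sequencing `read_len` bases from each fragment end
#' (mate 2 reverse-complemented), with i.i.d. substitution errors at
#' `seq_error_rate` and constant Phred quality 35.
#'
#' @param cfg A [sim_config()].
#' @param transcripts Representative transcripts from
#'   [generate_transcriptome()] (used for fragment-length bookkeeping).
#' @param truth Truth table from [generate_transcriptome()] (supplies the
#'   diverged copies).
#' @return A list with `read1` and `read2`
#'   (`QualityScaledDNAStringSet`s, synchronized order) and `origin`, a
#'   data.frame with one row per pair: `pair_id`, `gene_id`, `copy`,
#'   `frag_start`, `frag_end` (1-based on the copy sequence).
#' @export
simulate_reads <- function(cfg, transcripts, truth) {
  stopifnot(inherits(cfg, "sim_config"), length(transcripts) > 0L)
  set.seed(cfg$seed + 3L)
  copies <- attr(truth, "copies")
  if (is.null(copies)) {
    copies <- transcripts
    names(copies) <- paste0(names(transcripts), "|A")
  }
  cp_seq <- as.character(copies)
  cp_gene <- sub("\\|[AB]$", "", names(copies))
  cp_copy <- sub("^.*\\|", "", names(copies))
  lens <- nchar(cp_seq)
  gene_dup <- truth$is_duplicated[match(cp_gene, truth$gene_id)]
  share <- ifelse(gene_dup,
                  ifelse(cp_copy == "A", cfg$abundance_skew,
                         1 - cfg$abundance_skew),
                  1)
  lambda <- cfg$mean_depth * lens / (2 * cfg$read_len) * share
  n_pairs <- rpois(length(lambda), lambda)

  r1 <- r2 <- vector("list", length(cp_seq))
  origin <- vector("list", length(cp_seq))
  truncated <- 0L
  for (i in seq_along(cp_seq)) {
    np <- n_pairs[i]
    if (np == 0L) next
    len <- lens[i]
    frag <- min(cfg$insert_len, len)
    if (frag < cfg$insert_len) truncated <- truncated + 1L
    rl <- min(cfg$read_len, frag)
    starts <- sample.int(len - frag + 1L, np, replace = TRUE)
    ends <- starts + frag - 1L
    r1[[i]] <- substring(cp_seq[i], starts, starts + rl - 1L)
    r2[[i]] <- substring(cp_seq[i], ends - rl + 1L, ends)
    origin[[i]] <- data.frame(gene_id = cp_gene[i], copy = cp_copy[i],
                              frag_start = starts, frag_end = ends,
                              stringsAsFactors = FALSE)
  }
  if (truncated > 0L) {
    message(truncated,
            " template(s) shorter than the insert length; fragment ",
            "length truncated to the template length")
  }
  r1 <- unlist(r1, use.names = FALSE)
  r2 <- unlist(r2, use.names = FALSE)
  origin <- do.call(rbind, origin)
  if (is.null(r1)) stop("no reads simulated; increase mean_depth")
  origin$pair_id <- sprintf("%s|%s|p%06d", origin$gene_id, origin$copy,
                            seq_along(r1))
  r2 <- as.character(reverseComplement(DNAStringSet(r2)))
  r1 <- .add_errors(r1, rbinom(length(r1), nchar(r1), cfg$seq_error_rate))
  r2 <- .add_errors(r2, rbinom(length(r2), nchar(r2), cfg$seq_error_rate))

  qual1 <- BStringSet(strrep("D", nchar(r1)))  # 'D' = Phred 35
  qual2 <- BStringSet(strrep("D", nchar(r2)))
  read1 <- QualityScaledDNAStringSet(DNAStringSet(r1), PhredQuality(qual1))
  read2 <- QualityScaledDNAStringSet(DNAStringSet(r2), PhredQuality(qual2))
  names(read1) <- paste0(origin$pair_id, "/1")
  names(read2) <- paste0(origin$pair_id, "/2")
  list(read1 = read1, read2 = read2, origin = origin)
}

#' Truth-derived ORF annotations
#'
#' Converts the generator's truth table into the annotation layout
#' produced by [annotate_orfs()], with every gene `FULL_LENGTH` on the
#' plus strand. This lets the UTR/motif stages be exercised directly
#' against planted truth, independently of the ORF-prediction stage.
#'
#' @param truth Truth table from [generate_transcriptome()].
#' @return A data.frame usable wherever ORF annotations are expected.
#' @export
truth_annotations <- function(truth) {
  data.frame(transcript_id = truth$gene_id,
             strand = "+",
             cds_start = truth$cds_start,
             cds_end = truth$cds_end,
             has_start = TRUE, has_stop = TRUE,
             protein = truth$protein,
             orf_ratio = 1,
             completeness = "FULL_LENGTH",
             source = "TRUTH",
             subject_id = truth$gene_id,
             s_start = 1L,
             s_end = nchar(truth$protein),
             start_offset_res = 0L,
             stringsAsFactors = FALSE)
}
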