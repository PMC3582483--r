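# Independent oracles and small fixture builders used across the suite.

suppressPackageStartupMessages(library(Biostrings))

# exhaustive N50: the largest candidate length L (taken from the multiset)
# such that contigs of length >= L hold at least half of all bases
n50_oracle <- function(lens) {
  total <- sum(as.numeric(lens))
  ok <- vapply(sort(unique(lens), decreasing = TRUE), function(L) {
    sum(as.numeric(lens[lens >= L])) >= total / 2
  }, logical(1))
  sort(unique(lens), decreasing = TRUE)[which(ok)[1]]
}

# full Smith-Waterman DP (match +1, mismatch -2, -3 per gapped position):
# returns the best local score; deliberately plain nested loops
sw_local_score_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (a[i] == b[j]) 1 else -2
      H[i + 1, j + 1] <- max(0, sub, H[i, j + 1] - 3, H[i + 1, j] - 3)
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# brute-force hexamer counting by position-wise character comparison
hexamer_counts_oracle <- function(window) {
  counts <- new.env()
  W <- nchar(window)
  if (W >= 6L) {
    for (p in seq_len(W - 5L)) {
      h <- substr(window, p, p + 5L)
      if (grepl("N", h, fixed = TRUE)) next
      counts[[h]] <- (if (is.null(counts[[h]])) 0L else counts[[h]]) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer(0) else out[order(names(out))]
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# QualityScaledDNAStringSet from character sequences + quality strings
qss <- function(seqs, quals, ids = NULL) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
  names(x) <- if (is.null(ids)) paste0("r", seq_along(seqs)) else ids
  x
}

# planted PSV sites of a truth table as "gene pos" keys
truth_psv_keys <- function(truth) {
  unlist(mapply(function(g, p) {
    if (nzchar(p)) paste(g, strsplit(p, ",")[[1]]) else character(0)
  }, truth$gene_id, truth$psv_positions, USE.NAMES = FALSE))
}

# one shared small simulation reused by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 40L, seed = 101L, mean_depth = 25)
      pro <- generate_proteome(cfg)
      sim <- generate_transcriptome(cfg, pro)
      reads <- simulate_reads(cfg, sim$transcripts, sim$truth)
      cache <<- list(cfg = cfg, proteome = pro, transcripts = sim$transcripts,
                     truth = sim$truth, reads = reads)
    }
    cache
  }
})
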