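# Kozak and stop-codon context windows, PFMs, polyA selection, PAS scan.

test_that("context windows slice -4..+4 and -6..+12 correctly", {
  utr5 <- paste0(random_dna(20), "CAAAC")
  cds <- paste0("ATGG", random_dna(32), "AAA")
  utr3 <- paste0("GCTAGCTAGCTA", random_dna(30), strrep("A", 10))
  txs <- paste0(utr5, cds, "TAA", utr3)
  ann <- data.frame(transcript_id = "t", strand = "+",
                    cds_start = 26L, cds_end = nchar(utr5) + nchar(cds) + 3L,
                    completeness = "FULL_LENGTH")
  tx <- DNAStringSet(setNames(txs, "t"))
  start_w <- extract_context(tx, ann, "START")
  expect_equal(start_w[[1]], "AAACATGG")
  stop_w <- extract_context(tx, ann, "STOP")
  expect_equal(stop_w[[1]],
               paste0(substr(cds, nchar(cds) - 5L, nchar(cds)), "TAA",
                      "GCTAGCTAG"))
  expect_equal(nchar(stop_w[[1]]), 18L)

  # 5'UTR shorter than the upstream window: transcript skipped and counted
  ann2 <- ann
  ann2$cds_start <- 3L
  short <- DNAStringSet(setNames(substr(txs, 24, nchar(txs)), "t"))
  w2 <- extract_context(short, ann2, "START")
  expect_length(w2, 0L)
  expect_equal(attr(w2, "n_skipped"), 1L)

  ann_bad <- ann
  ann_bad$completeness <- "PARTIAL_5P"
  expect_error(extract_context(tx, ann_bad, "START"), "FULL_LENGTH")
})

test_that("position frequency matrices count, normalize and score", {
  w <- c("AAACATGG", "AAACATGG", "CAACATGG")
  pfm <- build_pfm(w, upstream = 4L)
  expect_equal(unname(pfm$freqs["A", 1]), 2 / 3)
  expect_equal(unname(pfm$freqs["C", 1]), 1 / 3)
  expect_equal(consensus_from_pfm(pfm), "AAACATGG")
  expect_equal(colnames(pfm$counts), as.character(c(-4:-1, 1:4)))
  # column sums to one; information content within [0, 2]
  expect_true(all(abs(colSums(pfm$freqs) - 1) < 1e-9))
  expect_true(all(pfm$info_bits >= 0 & pfm$info_bits <= 2))
  # all-A column carries 2 bits, uniform column 0 bits
  expect_equal(unname(pfm$info_bits[2]), 2)
  u <- build_pfm(c("A", "C", "G", "T"), positions = 1L)
  expect_equal(unname(u$info_bits), 0)

  # duplicated window leaves frequencies unchanged
  pfm2 <- build_pfm(c(w, w), upstream = 4L)
  expect_equal(pfm2$freqs, pfm$freqs)

  # ties render as IUPAC codes
  r <- build_pfm(c("AG", "GA"), positions = 1:2)
  expect_equal(consensus_from_pfm(r), "RR")

  expect_error(build_pfm(character(0)), "no windows")
  expect_error(build_pfm(c("AA", "AAA")), "length")
})

test_that("stop codon usage is tabulated over full-length transcripts", {
  mk <- function(stop) paste0(random_dna(10), "ATGAAA", stop,
                              random_dna(10))
  txs <- c(vapply(rep("TGA", 2), mk, character(1)), mk("TAA"), mk("TAG"))
  tx <- DNAStringSet(setNames(txs, paste0("t", 1:4)))
  anns <- data.frame(transcript_id = names(tx), strand = "+",
                     cds_start = 11L, cds_end = 19L,
                     completeness = "FULL_LENGTH")
  su <- stop_codon_usage(anns, tx)
  expect_equal(su$percent[su$stop_codon == "UGA"], 50.0)
  expect_equal(su$percent[su$stop_codon == "UAA"], 25.0)
  expect_equal(su$percent[su$stop_codon == "UAG"], 25.0)
  expect_error(stop_codon_usage(anns[0, ], tx), "FULL_LENGTH")
})

test_that("polyA selection uses the exact terminal run", {
  tx <- DNAStringSet(c(
    yes = paste0(random_dna(50), "GCT", strrep("A", 7)),
    no = paste0(random_dna(50), "GCT", strrep("A", 6)),
    internal = paste0(strrep("A", 30), "GCT", strrep("A", 7))))
  sel <- select_polya_transcripts(tx)
  expect_setequal(sel$transcript_id, c("yes", "internal"))
  expect_equal(sel$polya_start[sel$transcript_id == "yes"],
               width(tx)[match("yes", names(tx))] - 6L)
  expect_equal(sel$polya_len[sel$transcript_id == "internal"], 7L)
})

test_that("hexamer windows enumerate exactly and match the oracle", {
  # 6-nt window has a single hexamer; 7-nt window has two
  tx <- DNAStringSet(c(a = paste0(random_dna(20), "CAATAAAC", "G",
                                  strrep("A", 8))))
  polya <- select_polya_transcripts(tx)
  hx <- pas_hexamer_scan(tx, polya, window_len = 7L)
  win <- substr(as.character(tx), polya$polya_start - 7L,
                polya$polya_start - 1L)
  expect_equal(hx$n_windows, 2L)

  set.seed(40)
  for (i in 1:300) {
    w <- random_dna(sample(6:40, 1))
    tx1 <- DNAStringSet(setNames(paste0("GGG", w, "C", strrep("A", 9)),
                                 "t"))
    p1 <- select_polya_transcripts(tx1)
    h1 <- pas_hexamer_scan(tx1, p1, window_len = nchar(w) + 1L)
    got <- setNames(h1$table$window_count, chartr("U", "T",
                                                  h1$table$hexamer))
    got <- got[order(names(got))]
    oracle <- hexamer_counts_oracle(paste0(w, "C"))
    expect_identical(as.integer(got), as.integer(oracle))
    expect_identical(names(got), names(oracle))
    expect_equal(h1$n_windows, max(nchar(w) + 1L - 5L, 0L))
  }
})

test_that("PAS classification and per-transcript assignment follow priority", {
  tx <- DNAStringSet(c(
    canon = paste0(random_dna(30), "AATAAA", random_dna(15), "C",
                   strrep("A", 10)),
    both = paste0(random_dna(24), "ATTAAA", "AATAAA", random_dna(10), "C",
                  strrep("A", 10)),
    variant = paste0(random_dna(30), "TATAAA", random_dna(15), "C",
                     strrep("A", 10)),
    none = paste0(strrep("GC", 30), "C", strrep("A", 10))))
  polya <- select_polya_transcripts(tx)
  hx <- pas_hexamer_scan(tx, polya)
  tab <- hx$table
  expect_equal(tab$class[tab$hexamer == "AAUAAA"], "CANONICAL")
  expect_equal(tab$class[tab$hexamer == "AUUAAA"], "SINGLE_BASE_VARIANT")
  expect_equal(tab$class[tab$hexamer == "UAUAAA"], "SINGLE_BASE_VARIANT")
  a <- setNames(hx$assigned$assigned_pas, hx$assigned$transcript_id)
  expect_equal(unname(a["canon"]), "AAUAAA")
  expect_equal(unname(a["both"]), "AAUAAA")  # canonical outranks AUUAAA
  expect_equal(unname(a["variant"]), "UAUAAA")
  expect_equal(unname(a["none"]), "none")

  rep <- pas_mixture_report(hx)
  expect_equal(sum(rep$count), 4L)
  expect_lte(abs(sum(rep$percent) - 100), 2)
})

test_that("planted motif mixtures are recovered from a simulation", {
  cfg <- sim_config(n_genes = 600L, seed = 41L, kozak_strength = 1)
  sim <- generate_transcriptome(cfg, generate_proteome(cfg))
  anns <- truth_annotations(sim$truth)

  kz <- build_pfm(extract_context(sim$transcripts, anns, "START"),
                  upstream = 4L)
  expect_equal(consensus_from_pfm(kz), cfg$kozak_consensus)

  su <- stop_codon_usage(anns, sim$transcripts)
  for (cod in c("TGA", "TAA", "TAG")) {
    p <- cfg$stop_usage[[cod]]
    se <- sqrt(p * (1 - p) / 600)
    obs <- su$percent[su$stop_codon == chartr("T", "U", cod)] / 100
    expect_lt(abs(obs - p), 3 * se + 1e-3)
  }

  polya <- select_polya_transcripts(sim$transcripts)
  expect_equal(nrow(polya), 600L)
  rep <- pas_mixture_report(pas_hexamer_scan(sim$transcripts, polya))
  canon <- rep$count[rep$assigned_pas == "AAUAAA"] / 600
  se_c <- sqrt(0.61 * 0.39 / 600)
  # chance canonical hexamers in the window inflate the planted 0.61 a bit
  expect_lt(abs(canon - 0.61), 3 * se_c + 0.02)
})
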