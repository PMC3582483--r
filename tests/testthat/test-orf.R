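# Translation, translated search, ORF prediction and classification.

test_that("six-frame translation handles frames, strands and Ns", {
  fr <- six_frame_translate("ATGAAATAG")
  expect_equal(unname(fr["+1"]), "MK*")
  fr_rc <- six_frame_translate(revcomp_chr("ATGAAATAG"))
  expect_equal(unname(fr_rc["-1"]), "MK*")
  fr2 <- six_frame_translate("AATGAAATAG")
  expect_equal(unname(fr2["+2"]), "MK*")
  frN <- six_frame_translate("ATGANATAG")
  expect_equal(unname(frN["+1"]), "MX*")
})

test_that("translated search finds exact homologs with coordinates", {
  set.seed(30)
  s <- small_sim()
  tx <- s$transcripts[1:10]
  hits <- translated_search(tx, s$proteome)
  expect_equal(nrow(hits), 10L)
  expect_equal(hits$qseqid, hits$sseqid)  # genes are named alike
  expect_equal(hits$pident, rep(100, 10))
  expect_equal(hits$sstart, rep(1L, 10))
  expect_equal(hits$send, nchar(s$truth$protein[1:10]))
  # the CDS frame follows from where the 5'UTR ends
  expect_equal(hits$frame, ((s$truth$cds_start[1:10] - 1L) %% 3L) + 1L)
  expect_equal(hits$qstart, s$truth$cds_start[1:10])

  # reverse-complemented transcript: same subject, negated frame
  rc <- DNAStringSet(setNames(revcomp_chr(as.character(tx[[1]])), "rc1"))
  h_rc <- translated_search(rc, s$proteome)
  expect_equal(h_rc$sseqid, hits$sseqid[1])
  expect_lt(h_rc$frame, 0L)
  expect_equal(h_rc$qstart, width(tx)[1] - hits$qend[1] + 1L)

  # unrelated random sequences stay below the score floor
  rnd <- DNAStringSet(setNames(vapply(rep(300, 20), random_dna,
                                      character(1)),
                               sprintf("rnd%02d", 1:20)))
  expect_equal(nrow(translated_search(rnd, s$proteome)), 0L)
})

test_that("guided prediction recovers planted CDS coordinates", {
  s <- small_sim()
  tx <- s$transcripts[1:15]
  hits <- translated_search(tx, s$proteome)
  for (i in 1:15) {
    ann <- predict_orf_guided(tx[[i]], hits[i, ])
    expect_equal(ann$cds_start, s$truth$cds_start[i])
    expect_equal(ann$cds_end, s$truth$cds_end[i])
    expect_true(ann$has_start && ann$has_stop)
    expect_equal(ann$protein, s$truth$protein[i])
  }
})

test_that("constructed truncations classify as the matching partial class", {
  s <- small_sim()
  tr <- s$truth
  tx <- as.character(s$transcripts)
  n <- 12

  t5 <- substring(tx[1:n], tr$cds_start[1:n] + 60L)
  names(t5) <- paste0("t5_", names(tx)[1:n])
  a5 <- annotate_orfs(DNAStringSet(t5), s$proteome)
  expect_true(mean(a5$completeness == "PARTIAL_5P") >= 0.95)

  t3 <- substring(tx[1:n], 1L, tr$cds_end[1:n] - 33L)
  names(t3) <- paste0("t3_", names(tx)[1:n])
  a3 <- annotate_orfs(DNAStringSet(t3), s$proteome)
  expect_true(mean(a3$completeness == "PARTIAL_3P") >= 0.95)
  expect_true(all(!a3$has_stop[a3$completeness == "PARTIAL_3P"]))
})

test_that("a corrupted start codon with deep internal ATG is INCORRECT_ORF", {
  # protein engineered so the only internal Met sits 20 residues in:
  # destroying the start codon forces a start choice that contradicts an
  # alignment still spanning the protein's first residue
  set.seed(31)
  aa_pool <- setdiff(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]], "M")
  prot <- paste0("M", paste(sample(aa_pool, 19, TRUE), collapse = ""),
                 "M", paste(sample(aa_pool, 60, TRUE), collapse = ""))
  proteins <- AAStringSet(c(ref = prot))
  ct <- Biostrings::GENETIC_CODE
  cds <- paste(vapply(strsplit(prot, "")[[1]], function(a) {
    names(ct)[ct == a][1]
  }, character(1)), collapse = "")
  utr5 <- paste0(random_dna(40), "CC")   # no upstream in-frame ATG
  utr5 <- gsub("ATG", "CTG", utr5, fixed = TRUE)
  txs <- paste0(utr5, cds, "TAA", random_dna(60))
  broken <- txs
  substr(broken, nchar(utr5) + 1L, nchar(utr5) + 1L) <- "C"
  anns <- annotate_orfs(DNAStringSet(c(intact = txs, broken = broken)),
                        proteins)
  expect_equal(anns$completeness[anns$transcript_id == "intact"],
               "FULL_LENGTH")
  expect_equal(anns$completeness[anns$transcript_id == "broken"],
               "INCORRECT_ORF")
})

test_that("ab initio prediction picks the longest qualifying ORF", {
  expect_equal(predict_orf_ab_initio("CCATGAAATAACC")$completeness,
               "NO_ORF")
  ann <- predict_orf_ab_initio("CCATGAAATAACC", min_aa = 2L)
  expect_equal(ann$cds_start, 3L)
  expect_equal(ann$cds_end, 11L)
  expect_equal(ann$protein, "MK")

  expect_equal(predict_orf_ab_initio(strrep("C", 200))$completeness,
               "NO_ORF")

  # a longer minus-strand ORF beats a shorter plus-strand one
  set.seed(32)
  plus_orf <- paste0("ATG", paste(rep("GCT", 34), collapse = ""), "TAA")
  minus_orf <- revcomp_chr(
    paste0("ATG", paste(rep("GAA", 39), collapse = ""), "TAG"))
  txs <- paste0("CC", plus_orf, "CC", minus_orf, "CC")
  ann2 <- predict_orf_ab_initio(txs, min_aa = 30L)
  expect_equal(ann2$strand, "-")
  expect_equal(nchar(ann2$protein), 40L)
})

test_that("guided and ab initio agree when the planted CDS is longest", {
  s <- small_sim()
  anns <- annotate_orfs(s$transcripts[1:10], s$proteome)
  for (i in 1:10) {
    ab <- predict_orf_ab_initio(s$transcripts[[i]],
                                id = names(s$transcripts)[i])
    if (!is.na(ab$cds_start) &&
        ab$cds_start == s$truth$cds_start[i]) {
      expect_equal(ab$cds_end, anns$cds_end[i])
      expect_equal(ab$protein, anns$protein[i])
    }
  }
})

test_that("orf ratio is predicted over reference length", {
  ann <- data.frame(protein = strrep("K", 90))
  expect_equal(compute_orf_ratio(ann, 100)$orf_ratio, 0.9)
  expect_equal(compute_orf_ratio(ann, 90)$orf_ratio, 1.0)
  ann$protein <- strrep("K", 120)
  expect_equal(compute_orf_ratio(ann, 100)$orf_ratio, 1.2)
  expect_error(compute_orf_ratio(ann, 0), ">= 1")
})

test_that("UTR extraction partitions the transcript", {
  ann <- data.frame(transcript_id = "t", strand = "+",
                    cds_start = 101L, cds_end = 700L)
  txs <- random_dna(1000)
  u <- extract_utrs(txs, ann)
  expect_equal(nchar(u$utr5), 100L)
  expect_equal(nchar(u$utr3), 300L)
  expect_equal(paste0(u$utr5, substr(txs, 101, 700), u$utr3), txs)

  whole <- data.frame(strand = "+", cds_start = 1L, cds_end = 300L)
  u2 <- extract_utrs(random_dna(300), whole)
  expect_equal(nchar(u2$utr5), 0L)
  expect_equal(nchar(u2$utr3), 0L)

  bad <- data.frame(strand = "+", cds_start = 10L, cds_end = 400L)
  expect_error(extract_utrs(random_dna(300), bad), "bounds")

  # minus-strand coordinates are reported in mRNA sense
  fwd <- random_dna(500)
  ann_m <- data.frame(strand = "-", cds_start = 101L, cds_end = 400L)
  um <- extract_utrs(fwd, ann_m)
  expect_equal(nchar(um$utr5), 100L)
  expect_equal(nchar(um$utr3), 100L)
  expect_equal(um$utr5, substr(revcomp_chr(fwd), 1, 100))
})

test_that("full-length annotations translate cleanly end to end", {
  s <- small_sim()
  anns <- annotate_orfs(s$transcripts, s$proteome)
  fl <- anns[anns$completeness == "FULL_LENGTH", ]
  expect_gt(nrow(fl), 35)
  expect_false(any(grepl("*", fl$protein, fixed = TRUE)))
  expect_true(all((fl$cds_end - fl$cds_start + 1L) %% 3L == 0L))
  expect_true(all(fl$orf_ratio == 1))
})
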