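# High-identity mapping, pileups, PSV calling, duplicate summarization.

test_that("mapper accepts reads at the identity boundary and not below", {
  set.seed(20)
  tx <- DNAStringSet(c(t1 = random_dna(1200)))
  r <- unname(substr(as.character(tx), 301, 400))
  mutate <- function(x, pos) {
    for (p in pos) {
      substr(x, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(x, p, p))[1]
    }
    x
  }
  reads <- c(exact = r, one = mutate(r, 50), two = mutate(r, c(30, 60)))
  pl <- map_reads(reads, tx)
  expect_setequal(pl$read_id, c("exact", "one"))
  expect_equal(pl$n_mismatches[pl$read_id == "exact"], 0L)
  expect_equal(pl$n_mismatches[pl$read_id == "one"], 1L)
  expect_equal(pl$start[pl$read_id == "exact"], 301L)

  # reverse-complement read maps at the same place on the minus strand
  pl_rc <- map_reads(c(rc = revcomp_chr(r)), tx)
  expect_equal(pl_rc$start, 301L)
  expect_equal(pl_rc$strand, "-")

  expect_error(map_reads(reads, DNAStringSet()), "empty")
})

test_that("ties between collapsed paralog transcripts map to both", {
  set.seed(21)
  a <- random_dna(500)
  tx <- DNAStringSet(c(copyA = a, copyB = a))
  pl <- map_reads(c(r = substr(a, 101, 200)), tx)
  expect_setequal(pl$transcript_id, c("copyA", "copyB"))
})

test_that("pileup accumulates transcript-forward bases from both strands", {
  tx <- DNAStringSet(c(t = "ACGTACGTACGTACGTACGTACGTA"))
  reads <- c(p = substr(as.character(tx), 1, 24),
             m = revcomp_chr(substr(as.character(tx), 1, 24)))
  pl <- map_reads(reads, tx, seed_len = 10L)
  pile <- build_pileup(pl, tx, reads)
  expect_equal(nrow(pile), 24L)
  expect_true(all(pile$depth == 2L))
  expect_equal(pile$A[pile$pos == 1L], 2L)
  expect_equal(pile$C[pile$pos == 2L], 2L)

  empty <- build_pileup(pl[0, ], tx, reads)
  expect_equal(nrow(empty), 0L)
})

test_that("psv calling applies the depth, minor-count and MAF thresholds", {
  pile <- data.frame(transcript_id = "t", pos = 1:3,
                     A = c(8L, 19L, 2L), C = c(0L, 1L, 0L),
                     G = c(2L, 0L, 1L), T = c(0L, 0L, 0L))
  pile$depth <- pile$A + pile$C + pile$G + pile$T
  calls <- call_psvs(pile)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 1L)
  expect_equal(calls$major_allele, "A")
  expect_equal(calls$minor_allele, "G")
  expect_equal(calls$maf, 0.2)

  # tie for the major allele resolves in base order A < C < G < T
  tie <- data.frame(transcript_id = "t", pos = 1L,
                    A = 5L, C = 0L, G = 5L, T = 0L, depth = 10L)
  ct <- call_psvs(tie)
  expect_equal(ct$major_allele, "A")
  expect_equal(ct$minor_allele, "G")
})

test_that("doubled-haploid null yields exactly zero calls without errors", {
  cfg <- sim_config(n_genes = 25L, seed = 22L, dup_fraction = 0,
                    seq_error_rate = 0, mean_depth = 20)
  sim <- generate_transcriptome(cfg, generate_proteome(cfg))
  rd <- simulate_reads(cfg, sim$transcripts, sim$truth)
  reads <- c(as.character(rd$read1), as.character(rd$read2))
  pl <- map_reads(reads, sim$transcripts)
  calls <- call_psvs(build_pileup(pl, sim$transcripts, reads))
  expect_equal(nrow(calls), 0L)
})

test_that("calls at planted sites have balanced allele frequencies", {
  s <- small_sim()
  reads <- c(as.character(s$reads$read1), as.character(s$reads$read2))
  pl <- map_reads(reads, s$transcripts)
  calls <- call_psvs(build_pileup(pl, s$transcripts, reads))
  # every emitted call satisfies its own thresholds
  expect_true(all(calls$depth >= 4L))
  expect_true(all(calls$minor_count >= 2L))
  expect_true(all(calls$maf >= 0.10))
  expect_true(all(calls$major_allele != calls$minor_allele))
  # at equal paralog abundance the allele ratio at isolated PSV sites sits
  # near 50% (sites with another PSV within a read length lose copy-B
  # coverage to the identity filter, so they are excluded here)
  iso <- unlist(mapply(function(g, p) {
    if (!nzchar(p)) return(character(0))
    pos <- as.integer(strsplit(p, ",")[[1]])
    gap_ok <- vapply(seq_along(pos), function(i) {
      others <- pos[-i]
      length(others) == 0L || min(abs(others - pos[i])) > 150L
    }, logical(1))
    paste(g, pos[gap_ok])
  }, s$truth$gene_id, s$truth$psv_positions, USE.NAMES = FALSE))
  tp <- calls[paste(calls$transcript_id, calls$pos) %in% iso &
                calls$depth >= 20L, ]
  expect_gt(nrow(tp), 10L)
  expect_lt(abs(mean(tp$maf) - 0.5), 0.1)
})

test_that("site sensitivity degrades once reads span multiple PSVs", {
  site_sens <- function(rate) {
    cfg <- suppressWarnings(
      sim_config(n_genes = 60L, seed = 23L, dup_fraction = 1,
                 psv_rate = rate, mean_depth = 25))
    sim <- generate_transcriptome(cfg, generate_proteome(cfg))
    rd <- simulate_reads(cfg, sim$transcripts, sim$truth)
    reads <- c(as.character(rd$read1), as.character(rd$read2))
    pl <- map_reads(reads, sim$transcripts)
    calls <- call_psvs(build_pileup(pl, sim$transcripts, reads))
    keys <- truth_psv_keys(sim$truth)
    mean(keys %in% paste(calls$transcript_id, calls$pos))
  }
  s <- vapply(c(0.002, 0.005, 0.02), site_sens, numeric(1))
  expect_lt(s[3], s[2])
  expect_lt(s[3], s[1])
})

test_that("gene summaries pool distinct sites and build the histogram", {
  calls <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2", "t3"),
    pos = c(10L, 20L, 5L, 5L, 7L))
  t2g <- c(t1 = "gA", t2 = "gA", t3 = "gB")
  ds <- summarize_duplicates(calls, t2g)
  expect_equal(ds$genes$n_psv[ds$genes$gene_id == "gA"], 3L)
  expect_equal(ds$genes$n_psv[ds$genes$gene_id == "gB"], 1L)
  expect_true(all(ds$genes$is_putative_duplicate))
  expect_equal(sum(ds$histogram$n_genes), nrow(ds$genes))

  empty <- summarize_duplicates(calls[0, ], t2g)
  expect_equal(nrow(empty$genes), 0L)

  expect_warning(summarize_duplicates(
    data.frame(transcript_id = "tX", pos = 1L), t2g), "no gene")
})

test_that("genome-contig hits separate duplicated from unique genes", {
  cfg <- sim_config(n_genes = 12L, seed = 24L, dup_fraction = 0.5)
  sim <- generate_transcriptome(cfg, generate_proteome(cfg))
  tr <- sim$truth
  genome <- attr(tr, "copies")
  pick <- c(tr$gene_id[tr$is_duplicated][1:2],
            tr$gene_id[!tr$is_duplicated][1:2])
  res <- evaluate_genome_hits(sim$transcripts[pick], genome)
  expect_equal(res$class[1:2], c("multi-hit", "multi-hit"))
  expect_equal(res$class[3:4], c("single-hit", "single-hit"))

  foreign <- DNAStringSet(c(zz = random_dna(800)))
  res2 <- evaluate_genome_hits(foreign, genome)
  expect_equal(res2$class, "no-hit")
})
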