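test_that("local alignment scores match published BLOSUM62 entries", {
  a <- smith_waterman_protein("MKT", "MKT")
  expect_equal(a$score, 15)  # M/M 5 + K/K 5 + T/T 5
  expect_equal(a$query_span, c(0L, 3L))
  expect_equal(a$subject_span, c(0L, 3L))
  empty <- smith_waterman_protein("", "MKT")
  expect_equal(empty$score, 0)
  expect_equal(empty$query_span, c(0L, 0L))
})

test_that("alignment score is symmetric and self-score is the diagonal sum", {
  set.seed(5)
  mat <- blosum62()
  for (k in 1:10) {
    a <- random_protein(sample(3:12, 1))
    b <- random_protein(sample(3:12, 1))
    expect_equal(smith_waterman_protein(a, b)$score,
                 smith_waterman_protein(b, a)$score)
    expect_equal(smith_waterman_protein(a, a)$score,
                 sum(diag(mat)[strsplit(a, "")[[1]]]))
  }
})

test_that("scores equal exhaustive enumeration over local alignments", {
  set.seed(13)
  mat <- blosum62()
  for (k in 1:40) {
    a <- random_protein(sample(1:8, 1))
    b <- random_protein(sample(1:8, 1))
    expect_equal(smith_waterman_protein(a, b)$score, sw_enum(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("scores agree with an independent aligner on longer proteins", {
  skip_if_not_installed("Biostrings")
  set.seed(17)
  for (k in 1:10) {
    a <- random_protein(30)
    b <- random_protein(30)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(smith_waterman_protein(a, b)$score, ref)
  }
})

test_that("unknown residues fall back to the X wildcard row", {
  x <- smith_waterman_protein("MJT", "MJT")  # J not in BLOSUM62
  expect_true(x$score > 0)
  mat <- blosum62()[1:20, 1:20]              # no X row
  expect_error(smith_waterman_protein("MJT", "MKT", matrix = mat), "wildcard")
})

make_planted_contig <- function(n_aa = 20, lf = 30, rf = 30, seed = 1) {
  set.seed(seed)
  cds <- gcapr:::random_cds(n_aa)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  contig <- paste0(gcapr:::random_dna(lf), cds, gcapr:::random_dna(rf))
  list(cds = cds, prot = prot, contig = contig, lf = lf, rf = rf)
}

test_that("call_target back-projects the exon and measures flanks", {
  p <- make_planted_contig()
  tc <- call_target("L1", p$prot, c(c1 = p$contig))
  expect_equal(tc$exon_span, c(30L, 90L))
  expect_equal(tc$exon_seq, p$cds)
  expect_equal(tc$left_flank_len, 30L)
  expect_equal(tc$right_flank_len, 30L)
  expect_null(call_target("L1", p$prot, c(c1 = p$contig), min_score = 1e6))
})

test_that("reverse-complement contigs give identical exon output", {
  for (seed in 1:5) {
    p <- make_planted_contig(n_aa = 25, lf = 17, rf = 41, seed = seed)
    fwd <- call_target("L1", p$prot, c(c1 = p$contig))
    rev <- call_target("L1", p$prot, c(c1 = gcapr:::revcomp(p$contig)))
    expect_true(rev$frame < 0)
    expect_equal(rev$exon_seq, fwd$exon_seq)
    expect_equal(rev$exon_span, fwd$exon_span)
  }
})

test_that("mutated fixtures still recover the planted contig and span", {
  cfg <- sim_config(seed = 23, n_loci = 15, n_taxa = 4,
                    groups = c("G1", "G2"), exon_len = c(120, 360),
                    flank_len = c(80, 20), missingness = 0)
  sim <- simulate_capture(cfg)
  n_checked <- 0
  for (k in seq_len(nrow(sim$contigs))) {
    row <- sim$contigs[k, ]
    truth <- sim$truth$spans[k, ]
    prot <- sim$ref$protein[sim$ref$locus_id == row$locus_id]
    tc <- call_target(row$locus_id, prot,
                      setNames(row$sequence, row$contig_id))
    expect_equal(tc$contig_id, row$contig_id)
    expect_equal(tc$exon_span, c(truth$exon_start, truth$exon_end),
                 info = paste("contig", k))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("tied best scores break deterministically with a warning", {
  p <- make_planted_contig()
  contigs <- c(b_long = paste0(p$contig, "AAAA"), a_short = p$contig)
  expect_warning(tc <- call_target("L1", p$prot, contigs), "tie")
  expect_equal(tc$contig_id, "b_long")  # longer contig wins
})

test_that("split_outputs keeps id sets aligned and length arithmetic exact", {
  p1 <- make_planted_contig(seed = 2)
  p2 <- make_planted_contig(n_aa = 30, lf = 10, rf = 50, seed = 3)
  calls <- list(call_target("LA", p1$prot, c(c1 = p1$contig)),
                call_target("LB", p2$prot, c(c1 = p2$contig)),
                NULL)
  out <- split_outputs(calls)
  expect_equal(out$exon$locus_id, out$flanked$locus_id)
  expect_equal(nchar(out$flanked$sequence) - nchar(out$exon$sequence),
               c(60L, 60L))
  empty <- split_outputs(list())
  expect_equal(nrow(empty$exon), 0L)
  expect_equal(nrow(empty$flanked), 0L)
})
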