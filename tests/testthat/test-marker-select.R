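test_that("merging projects unions taxa and keeps the longer duplicate", {
  p1 <- data.frame(locus_id = c("L1", "L2", "L1"),
                   taxon = c("tA", "tA", "tB"),
                   sequence = c("ACGTACGT", "ACGT", "ACGTAC"),
                   stringsAsFactors = FALSE)
  p2 <- data.frame(locus_id = c("L1", "L2"),
                   taxon = c("tC", "tA"),
                   sequence = c("ACGT", "ACGTACGTACGT"),
                   stringsAsFactors = FALSE)
  m <- suppressMessages(merge_projects(list(p1, p2)))
  expect_setequal(colnames(m$cells), c("tA", "tB", "tC"))
  expect_setequal(rownames(m$cells), c("L1", "L2"))
  expect_equal(m$cells["L2", "tA"], "ACGTACGTACGT")  # 12 nt beats 4 nt
  expect_equal(m$cells["L1", "tA"], "ACGTACGT")      # single-project cell intact

  # equal-length conflicting duplicate: first project wins, with a warning
  p3 <- data.frame(locus_id = "L1", taxon = "tA", sequence = "TTTTTTTT",
                   stringsAsFactors = FALSE)
  expect_warning(m2 <- suppressMessages(merge_projects(list(p1, p3))),
                 "conflicting")
  expect_equal(m2$cells["L1", "tA"], "ACGTACGT")
})

test_that("taxon filter enforces strictly-greater-than semantics", {
  # 3001 loci: tA captures all 3001, tB exactly 3000, tC 2999
  loci <- sprintf("L%04d", 1:3001)
  df <- rbind(
    data.frame(locus_id = loci, taxon = "tA", sequence = "A"),
    data.frame(locus_id = loci[1:3000], taxon = "tB", sequence = "A"),
    data.frame(locus_id = loci[1:2999], taxon = "tC", sequence = "A"))
  m <- capture_matrix(df)
  kept <- filter_taxa(m, min_loci = 3000L)
  expect_equal(colnames(kept$cells), "tA")  # tB at exactly 3,000 is dropped
  expect_error(filter_taxa(m, min_loci = 3001L), "cutoff")
})

test_that("threshold zero keeps every taxon and drops empty loci", {
  set.seed(3)
  r <- random_capture_matrix(20, 6, 3)
  m <- capture_matrix(r$df, r$group_of)
  f <- filter_taxa(m, 0L)
  expect_setequal(colnames(f$cells), unique(r$df$taxon))
})

test_that("taxon filter matches brute-force row counting on random matrices", {
  set.seed(19)
  for (k in 1:20) {
    r <- random_capture_matrix(sample(5:30, 1), sample(2:8, 1), 3,
                               p_present = runif(1, 0.3, 0.9))
    m <- capture_matrix(r$df, r$group_of)
    thr <- sample(0:10, 1)
    want <- filter_taxa_oracle(r$present[rownames(m$cells),
                                         colnames(m$cells), drop = FALSE], thr)
    if (length(want$taxa) == 0L) {
      expect_error(filter_taxa(m, thr))
    } else {
      got <- filter_taxa(m, thr)
      expect_setequal(colnames(got$cells), want$taxa)
      expect_setequal(rownames(got$cells), want$loci)
    }
  }
})

test_that("decisiveness keeps exactly the all-groups-present loci", {
  taxa <- sprintf("t%d", 1:8)
  group_of <- setNames(paste0("G", rep(1:4, each = 2)), taxa)
  df <- expand.grid(locus_id = c("full", "gap"), taxon = taxa,
                    stringsAsFactors = FALSE)
  df$sequence <- "ACGT"
  df <- df[!(df$locus_id == "gap" & df$taxon %in% c("t1", "t2")), ]  # G1 empty
  m <- capture_matrix(df, group_of)
  expect_equal(decisive_loci(m, paste0("G", 1:4)), "full")
  expect_error(decisive_loci(m, c("G1", "G9")), "G9")
})

test_that("decisiveness equals brute-force group coverage on random matrices", {
  set.seed(29)
  for (k in 1:40) {
    r <- random_capture_matrix(sample(5:40, 1), sample(4:10, 1),
                               sample(2:4, 1), p_present = runif(1, 0.2, 0.9))
    m <- capture_matrix(r$df, r$group_of)
    avail <- unique(r$group_of[colnames(m$cells)])
    req <- sample(avail, sample(seq_along(avail), 1))
    want <- decisive_oracle(r$present[rownames(m$cells), colnames(m$cells),
                                      drop = FALSE],
                            r$group_of, req)
    expect_setequal(decisive_loci(m, req), want)
  }
})

test_that("adding a sequence never shrinks the decisive set", {
  set.seed(37)
  for (k in 1:10) {
    r <- random_capture_matrix(15, 6, 3, p_present = 0.5)
    m <- capture_matrix(r$df, r$group_of)
    req <- unique(r$group_of)
    before <- decisive_loci(m, req)
    # fill one absent cell
    absent <- which(is.na(m$cells), arr.ind = TRUE)
    if (nrow(absent) == 0L) next
    pick <- absent[sample(nrow(absent), 1), ]
    m$cells[pick[1], pick[2]] <- "ACGT"
    after <- decisive_loci(m, req)
    expect_true(all(before %in% after))
  }
})

test_that("planted decisive loci flow through filter and selection exactly", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = 100 + seed, n_loci = 20, n_taxa = 8,
                      missingness = 0.15, n_decisive = 8,
                      flank_len = c(30, 5), exon_len = c(102, 240))
    sim <- simulate_capture(cfg)
    m <- capture_matrix(sim$contigs[, c("locus_id", "taxon", "sequence")],
                        sim$group_of)
    m <- filter_taxa(m, 2L)
    expect_setequal(decisive_loci(m, default_groups()), sim$truth$decisive)
  }
})
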