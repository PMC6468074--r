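test_that("p-distance excludes gaps and missing data", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)     # 3 comparable, 0 mismatches
  expect_equal(p_distance("ANGT", "ACGA"), 1 / 3) # N site dropped
  expect_true(is.na(p_distance("----", "ACGT")))
})

test_that("basic stats summarise length, GC and mean p-dist", {
  aln <- c(t1 = "ACGTAC", t2 = "ACGTAC", t3 = "ACG-AC")
  bs <- basic_stats(aln)
  expect_equal(bs$mean_length, (6 + 6 + 5) / 3)
  expect_equal(bs$gc, 9 / 17)
  expect_equal(bs$mean_pdist, 0)
  aln2 <- c(t1 = "AAAA", t2 = "TTTT")
  expect_equal(basic_stats(aln2)$mean_pdist, 1)
  expect_warning(basic_stats(c(t1 = "A-", t2 = "-A", t3 = "AA")),
                 "no comparable")
})

tree4 <- ape::read.tree(text = "((t1,t2),(t3,t4));")

test_that("Fitch site lengths on hand-worked four-taxon cases", {
  expect_equal(fitch_site_length(c(t1 = "A", t2 = "A", t3 = "A", t4 = "A"),
                                 tree4), 0L)
  expect_equal(fitch_site_length(c(t1 = "A", t2 = "A", t3 = "C", t4 = "C"),
                                 tree4), 1L)
  expect_equal(fitch_site_length(c(t1 = "A", t2 = "C", t3 = "A", t4 = "C"),
                                 tree4), 2L)
  # missing data contributes no changes
  expect_equal(fitch_site_length(c(t1 = "A", t2 = "N", t3 = "C", t4 = "-"),
                                 tree4), 1L)
  expect_error(fitch_site_length(c(x1 = "A", x2 = "C", x3 = "A", x4 = "C"),
                                 tree4), "disagree")
})

test_that("Fitch equals exhaustive labeling enumeration on random trees", {
  set.seed(83)
  for (k in 1:30) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    states <- setNames(sample(c("A", "C", "G", "T", "N", "-"), n, TRUE),
                       tr$tip.label)
    expect_equal(fitch_site_length(states, tr), fitch_enum(states, tr),
                 info = paste(states, collapse = ""))
  }
})

test_that("Fitch matches an independent parsimony engine", {
  skip_if_not_installed("phangorn")
  set.seed(89)
  for (k in 1:5) {
    n <- 6
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    aln <- evolve_jc(tr, 40, rate = 0.6, seed = 90 + k)
    m <- do.call(rbind, strsplit(aln, ""))
    rownames(m) <- names(aln)
    dat <- phangorn::phyDat(m)
    ours <- sum(vapply(seq_len(ncol(m)), function(j) {
      fitch_site_length(setNames(m[, j], rownames(m)), tr)
    }, integer(1)))
    expect_equal(ours, phangorn::parsimony(tr, dat, method = "fitch"))
  }
})

test_that("CI and RI on the hand-worked single-site cases", {
  aln <- c(t1 = "A", t2 = "C", t3 = "A", t4 = "C")
  pr <- ci_ri(aln, tree4)
  expect_equal(pr$S, 2L); expect_equal(pr$M, 1L); expect_equal(pr$G, 2L)
  expect_equal(pr$CI, 0.5)
  expect_equal(pr$RI, 0.0)
  tree4b <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  pr2 <- ci_ri(aln, tree4b)
  expect_equal(pr2$CI, 1.0)
  expect_equal(pr2$RI, 1.0)
})

test_that("homoplasy-free alignments give CI = 1", {
  # one clean synapomorphy plus autapomorphies and constant sites
  aln <- c(t1 = "AAGCA", t2 = "AAGCA", t3 = "ACGTA", t4 = "ACGTT")
  pr <- ci_ri(aln, tree4)
  expect_equal(pr$CI, 1.0)
  expect_error(ci_ri(c(t1 = "AA", t2 = "AA", t3 = "AA", t4 = "AA"), tree4),
               "invariant")
})

test_that("per-site bounds M <= S <= G always hold", {
  set.seed(97)
  for (k in 1:10) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    aln <- evolve_jc(tr, 30, rate = 1.5, seed = 200 + k)
    pr <- tryCatch(ci_ri(aln, tr), error = function(e) NULL)
    if (is.null(pr)) next
    expect_true(all(pr$M_i <= pr$S_i))
    expect_true(all(pr$S_i <= pr$G_i))
    expect_true(pr$CI > 0 && pr$CI <= 1)
    if (!is.na(pr$RI)) expect_true(pr$RI >= 0 && pr$RI <= 1)
  }
})

test_that("informative-only mode drops uninformative sites from the sums", {
  # site 1: informative with homoplasy; site 2: autapomorphy (uninformative)
  aln <- c(t1 = "AA", t2 = "CA", t3 = "AA", t4 = "CT")
  all_sites <- ci_ri(aln, tree4)
  inf_only <- ci_ri(aln, tree4, informative_only = TRUE)
  expect_equal(inf_only$S, 2L)            # the A/C site alone
  expect_equal(all_sites$S, 3L)
  expect_equal(inf_only$CI, 0.5)
})

test_that("marker_stats assembles a per-locus table", {
  set.seed(101)
  tr <- ape::rtree(5, tip.label = paste0("t", 1:5))
  alns <- list(
    loc1 = evolve_jc(tr, 60, rate = 0.3, seed = 1),
    loc2 = evolve_jc(tr, 90, rate = 0.8, seed = 2))
  st <- marker_stats(alns, tr)
  expect_equal(st$locus_id, c("loc1", "loc2"))
  expect_true(all(st$mean_length == c(60, 90)))
  expect_true(all(st$gc > 0 & st$gc < 1))
  expect_true(all(is.na(st$ci) | (st$ci > 0 & st$ci <= 1)))
})
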