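test_that("uniform depth yields no anomalies; a 200x plateau is exact", {
  expect_equal(nrow(detect_anomalies(rep(10L, 500))), 0L)

  d <- rep(10L, 500); d[201:250] <- 2000L          # 200x background
  spans <- detect_anomalies(d)
  expect_equal(unname(spans), matrix(c(200L, 250L), ncol = 2))

  d99 <- rep(10L, 500); d99[201:250] <- 990L       # 99x: below the cutoff
  expect_equal(nrow(detect_anomalies(d99)), 0L)

  d100 <- rep(10L, 500); d100[201:250] <- 1000L    # exactly 100x: inclusive
  expect_equal(nrow(detect_anomalies(d100)), 1L)
})

test_that("anomaly detection is invariant to scaling all depths", {
  set.seed(47)
  for (k in 1:5) {
    d <- rpois(400, 20) + 1L
    s <- sample(50:300, 1); len <- sample(20:60, 1)
    d[s:(s + len)] <- d[s:(s + len)] * 500L
    expect_equal(detect_anomalies(d), detect_anomalies(d * 3L))
  }
})

test_that("plateaus wider than the flank window are still fully flagged", {
  d <- rep(10L, 800); d[301:500] <- 5000L          # 200 bp > 100 bp window
  spans <- detect_anomalies(d, flank_window = 100L)
  expect_equal(unname(spans), matrix(c(300L, 500L), ncol = 2))
})

test_that("masking lowercases anomalies and segments by the 120-nt floor", {
  m <- mask_and_segment(strrep("A", 400), matrix(c(100L, 150L), ncol = 2),
                        locus_id = "L1")
  # [0,100) is 100 nt < 120 -> dropped; [150,400) = 250 nt kept
  expect_equal(unname(m$segments), matrix(c(150L, 400L), ncol = 2))
  expect_equal(substr(m$sequence, 101, 150), strrep("a", 50))

  expect_message(none <- mask_and_segment(strrep("A", 100),
                                          NULL, locus_id = "L2"),
                 "discarded")
  expect_null(none)

  m3 <- mask_and_segment(strrep("A", 300), NULL)
  expect_equal(unname(m3$segments), matrix(c(0L, 300L), ncol = 2))

  # overlapping anomaly spans merge silently
  m4 <- mask_and_segment(strrep("A", 400),
                         matrix(c(100L, 140L, 130L, 150L), ncol = 2, byrow = TRUE))
  expect_equal(unname(masked_spans(m4$sequence)),
               matrix(c(100L, 150L), ncol = 2))
})

test_that("re-masking an already-masked locus is idempotent", {
  m <- mask_and_segment(strrep("A", 400), matrix(c(100L, 150L), ncol = 2))
  m2 <- mask_and_segment(m$sequence, NULL)
  expect_equal(m2$sequence, m$sequence)
  expect_equal(m2$segments, m$segments)
})

test_that("2x tiling lays baits at 60-nt steps with exact interior coverage", {
  m <- mask_and_segment(strrep("A", 240), NULL)
  b <- tile_baits(m)
  expect_equal(b$offset, c(0L, 60L, 120L))
  expect_true(all(nchar(b$sequence) == 120L))
  cov <- integer(240)
  for (k in seq_len(nrow(b))) {
    cov[(b$offset[k] + 1):(b$offset[k] + 120)] <- cov[(b$offset[k] + 1):(b$offset[k] + 120)] + 1L
  }
  expect_true(all(cov >= 1L))
  expect_true(all(cov[61:180] == 2L))  # >= 60 nt from both ends: exactly 2x

  one <- tile_baits(mask_and_segment(strrep("A", 120), NULL))
  expect_equal(nrow(one), 1L)
  expect_equal(one$pad_len, 0L)
})

test_that("legacy short loci get one bait padded with 3' Ts", {
  m <- mask_and_segment(strrep("A", 100), NULL, min_len = 100L)
  b <- tile_baits(m, allow_short = TRUE)
  expect_equal(nrow(b), 1L)
  expect_equal(b$pad_len, 20L)
  expect_equal(b$sequence, paste0(strrep("A", 100), strrep("T", 20)))
  # below the 100-nt legacy floor: skipped with a warning
  m2 <- mask_and_segment(strrep("A", 90), NULL, min_len = 80L)
  expect_warning(b2 <- tile_baits(m2, allow_short = TRUE), "skipped")
  expect_equal(nrow(b2), 0L)
})

test_that("baits never contain masked source characters and cover all segments", {
  set.seed(53)
  for (k in 1:10) {
    L <- sample(150:800, 1)
    seq <- gcapr:::random_dna(L)
    n_an <- sample(0:2, 1)
    an <- if (n_an) {
      t(vapply(seq_len(n_an), function(i) {
        s <- sample(0:(L - 30), 1); c(s, s + sample(10:30, 1))
      }, integer(2)))
    } else NULL
    m <- mask_and_segment(seq, an)
    if (is.null(m)) next
    b <- tile_baits(m)
    expect_false(any(grepl("[a-z]", b$sequence)))
    for (si in seq_len(nrow(m$segments))) {
      s0 <- m$segments[si, 1]; s1 <- m$segments[si, 2]
      cov <- integer(s1 - s0)
      bi <- b[b$segment == si, , drop = FALSE]
      for (j in seq_len(nrow(bi))) {
        idx <- (bi$offset[j] + 1):(bi$offset[j] + 120)
        cov[idx] <- cov[idx] + 1L
      }
      expect_true(all(cov >= 1L))
      # interior coverage is exactly 2x on the regular grid; the
      # right-aligned final bait can add one extra layer locally
      interior <- cov[seq_along(cov) > 60 & seq_along(cov) <= length(cov) - 60]
      if (length(interior)) {
        expect_true(all(interior >= 2L & interior <= 3L))
        if ((length(cov) - 120L) %% 60L == 0L) expect_true(all(interior == 2L))
      }
    }
  }
})

test_that("refine_loci discards, masks and reports consistently", {
  loci <- data.frame(
    locus_id = c("keep", "discard"),
    sequence = c(strrep("A", 400), strrep("G", 150)),
    stringsAsFactors = FALSE)
  depths <- list(
    keep = { d <- rep(20L, 400); d[101:150] <- 4000L; d },
    discard = { d <- rep(20L, 150); d[41:130] <- 4000L; d })
  out <- suppressMessages(refine_loci(loci, depths))
  expect_equal(out$report$status, c("kept", "discarded"))
  expect_equal(out$masked$locus_id, "keep")
  expect_true(all(out$baits$locus_id == "keep"))
  expect_equal(out$report$masked_bp, c(50L, 90L))
})
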