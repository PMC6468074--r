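## A posteriori bait refinement.  Pilot-capture read depth exposes
## low-complexity regions that escaped a priori repeat masking: they soak
## up reads at orders of magnitude above their surroundings.  These are
## soft-masked (lowercased), loci too short without them are discarded,
## longer loci are split into unmasked segments, and 120-nt baits are
## re-tiled over the segments at 2x coverage.

#' Detect read-depth anomalies in one depth profile
#'
#' A position is anomalous when its depth reaches \code{ratio} times the
#' local background.  The background is the smaller of the median depths
#' of the two flanking windows of \code{flank_window} positions (a
#' position must stand \code{ratio}-fold above its quieter neighbourhood),
#' computed over positions not already flagged as anomalous -- so a wide
#' plateau cannot inflate its own background, and flagging grows inward
#' from the plateau edges until a fixed point.  A side with no unflagged
#' positions is ignored; the background is floored at 1 to avoid division
#' by zero.
#'
#' @param depths integer vector of per-position read depths (1-based).
#' @param ratio fold-change threshold (inclusive, \code{>= ratio x
#'   background} flags); default 100.
#' @param flank_window flanking window size per side, in bp.
#' @return integer matrix with columns \code{start}, \code{end}: 0-based
#'   half-open spans of the maximal anomalous runs (zero rows if none).
#' @export
detect_anomalies <- function(depths, ratio = 100, flank_window = 100L) {
  stopifnot(length(depths) >= 1L, all(depths >= 0), ratio > 1)
  if (flank_window < 1L) stop("flank_window must be >= 1")
  L <- length(depths)
  anom <- rep(FALSE, L)
  repeat {
    bg <- local_background(depths, anom, flank_window)
    new <- anom | (depths >= ratio * pmax(1, bg))
    if (identical(new, anom)) break
    anom <- new
  }
  runs_to_spans(anom)
}

# min of the per-side medians over the nearest `w` unflagged depths on
# each side of each position (the position itself excluded); a side with
# no unflagged data is ignored, and Inf is returned when neither side has
# any, so an isolated position is never called anomalous against nothing.
local_background <- function(depths, excl, w) {
  L <- length(depths)
  keep <- which(!excl)
  bg <- numeric(L)
  for (i in seq_len(L)) {
    left <- keep[keep < i]
    if (length(left) > w) left <- left[(length(left) - w + 1L):length(left)]
    right <- keep[keep > i]
    if (length(right) > w) right <- right[1:w]
    lm <- if (length(left)) median(depths[left]) else Inf
    rm <- if (length(right)) median(depths[right]) else Inf
    bg[i] <- min(lm, rm)
  }
  bg
}

runs_to_spans <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  matrix(c(starts[keep], ends[keep]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' Soft-mask anomalous spans and segment a locus for bait design
#'
#' Anomalous spans are lowercased (overlapping spans merge silently).
#' Segments are the maximal unmasked (uppercase) runs of at least
#' \code{min_len} nt; pre-existing lowercase in the input counts as
#' masked.  A locus with no eligible segment is discarded
#' (\code{NULL} is returned, with a message).
#'
#' @param sequence the locus DNA string (may already carry soft-masking).
#' @param anomalies matrix of 0-based half-open spans from
#'   [detect_anomalies()] (or any list/matrix of spans).
#' @param min_len minimum segment length, default 120 (one bait).
#' @param locus_id optional id carried through to baits.
#' @return an object of class \code{masked_locus}: list with
#'   \code{locus_id}, \code{sequence} (masked), and \code{segments}
#'   (integer matrix of 0-based half-open unmasked spans, each
#'   \code{>= min_len}); or \code{NULL} when the locus is discarded.
#' @export
mask_and_segment <- function(sequence, anomalies, min_len = 120L,
                             locus_id = NA_character_) {
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  L <- nchar(sequence)
  if (is.list(anomalies)) {
    anomalies <- do.call(rbind, lapply(anomalies, function(s) matrix(s, ncol = 2L)))
  }
  if (is.null(anomalies)) anomalies <- matrix(integer(), ncol = 2L)
  ch <- strsplit(sequence, "")[[1]]
  masked <- ch %in% letters  # pre-existing soft-masking
  if (nrow(anomalies)) {
    if (any(anomalies[, 1] < 0L) || any(anomalies[, 2] > L)) {
      stop("anomaly span outside sequence bounds")
    }
    for (k in seq_len(nrow(anomalies))) {
      if (anomalies[k, 2] > anomalies[k, 1]) {
        idx <- (anomalies[k, 1] + 1L):anomalies[k, 2]
        masked[idx] <- TRUE
      }
    }
  }
  ch[masked] <- tolower(ch[masked])
  ch[!masked] <- toupper(ch[!masked])
  spans <- runs_to_spans(!masked)
  spans <- spans[spans[, 2] - spans[, 1] >= min_len, , drop = FALSE]
  if (nrow(spans) == 0L) {
    message("locus ", locus_id, " discarded: no unmasked segment >= ",
            min_len, " nt")
    return(NULL)
  }
  structure(list(locus_id = locus_id,
                 sequence = paste(ch, collapse = ""),
                 segments = spans),
            class = "masked_locus")
}

#' Tile baits over the unmasked segments of a locus
#'
#' Baits of \code{bait_len} nt are laid down every \code{bait_len /
#' tiling} nt (60 nt at the default 2x tiling), so interior positions are
#' covered exactly \code{tiling} times; the final bait is right-aligned to
#' the segment end when a regular offset would overrun.  Baits never
#' contain masked (lowercase) source characters.  In legacy mode
#' (\code{allow_short = TRUE}) a whole segment of \code{min_short} to
#' \code{bait_len - 1} nt yields a single bait padded at the 3' end with
#' \code{T}s up to \code{bait_len} -- thymine pairs with fewer hydrogen
#' bonds than G/C, so T-padding adds the least spurious hybridization
#' energy.
#'
#' @param m a \code{masked_locus} from [mask_and_segment()].
#' @param bait_len bait length in nt (default 120).
#' @param tiling tiling factor (default 2); must divide \code{bait_len}.
#' @param allow_short emit a single T-padded bait for segments shorter
#'   than \code{bait_len} but at least \code{min_short} nt.
#' @param min_short shortest segment eligible for a padded bait (default
#'   100, the floor used for short-target designs).
#' @return data frame of class \code{bait_set}: one row per bait with
#'   \code{locus_id}, \code{segment} (1-based index), \code{offset}
#'   (0-based within the segment), \code{sequence} (exactly
#'   \code{bait_len} nt) and \code{pad_len}.
#' @export
tile_baits <- function(m, bait_len = 120L, tiling = 2L,
                       allow_short = FALSE, min_short = 100L) {
  stopifnot(inherits(m, "masked_locus"), bait_len >= 1L, tiling >= 1L)
  if (bait_len %% tiling != 0L) stop("tiling must divide bait_len")
  step <- bait_len %/% tiling
  out <- list()
  for (si in seq_len(nrow(m$segments))) {
    s0 <- m$segments[si, 1]
    s1 <- m$segments[si, 2]
    L <- s1 - s0
    if (L >= bait_len) {
      offs <- seq(0L, L - bait_len, by = step)
      if (offs[length(offs)] != L - bait_len) offs <- c(offs, L - bait_len)
      seqs <- substring(m$sequence, s0 + offs + 1L, s0 + offs + bait_len)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = m$locus_id, segment = si, offset = offs,
        sequence = seqs, pad_len = 0L, stringsAsFactors = FALSE)
    } else if (allow_short && L >= min_short) {
      seqs <- paste0(substr(m$sequence, s0 + 1L, s1),
                     strrep("T", bait_len - L))
      out[[length(out) + 1L]] <- data.frame(
        locus_id = m$locus_id, segment = si, offset = 0L,
        sequence = seqs, pad_len = bait_len - L, stringsAsFactors = FALSE)
    } else if (allow_short) {
      warning("segment ", si, " of locus ", m$locus_id, " shorter than ",
              min_short, " nt; skipped")
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(), segment = integer(), offset = integer(),
               sequence = character(), pad_len = integer(),
               stringsAsFactors = FALSE)
  class(res) <- c("bait_set", class(res))
  res
}

#' Refine a set of loci from depth profiles: mask, discard/split, re-tile
#'
#' Runs [detect_anomalies()], [mask_and_segment()] and [tile_baits()] over
#' a locus table.  Depth profiles from multiple samples should be combined
#' beforehand with [combine_depths()].
#'
#' @param loci data frame with columns \code{locus_id}, \code{sequence}.
#' @param depths named list of depth vectors (names = locus ids); loci
#'   without a profile are treated as anomaly-free.
#' @param ratio,flank_window passed to [detect_anomalies()].
#' @param bait_len,tiling,allow_short,min_short passed to [tile_baits()].
#' @param min_len minimum unmasked segment length (defaults to
#'   \code{bait_len}, or \code{min_short} when \code{allow_short}).
#' @return list with \code{masked} (data frame of retained, soft-masked
#'   loci), \code{baits} (a \code{bait_set}) and \code{report} (per-locus
#'   status, masked bp, segment and bait counts).
#' @export
refine_loci <- function(loci, depths, ratio = 100, flank_window = 100L,
                        bait_len = 120L, tiling = 2L,
                        allow_short = FALSE, min_short = 100L,
                        min_len = if (allow_short) min_short else bait_len) {
  stopifnot(is.data.frame(loci),
            all(c("locus_id", "sequence") %in% names(loci)))
  masked <- list(); baits <- list(); rep_rows <- list()
  for (i in seq_len(nrow(loci))) {
    id <- loci$locus_id[i]
    seq <- loci$sequence[i]
    an <- if (!is.null(depths[[id]])) {
      d <- depths[[id]]
      if (length(d) < nchar(seq)) d <- c(d, integer(nchar(seq) - length(d)))
      detect_anomalies(d[seq_len(nchar(seq))], ratio, flank_window)
    } else matrix(integer(), ncol = 2L)
    m <- mask_and_segment(seq, an, min_len = min_len, locus_id = id)
    masked_bp <- sum(an[, 2] - an[, 1])
    if (is.null(m)) {
      rep_rows[[i]] <- data.frame(locus_id = id, status = "discarded",
                                  masked_bp = masked_bp, n_segments = 0L,
                                  n_baits = 0L, stringsAsFactors = FALSE)
      next
    }
    b <- tile_baits(m, bait_len, tiling, allow_short, min_short)
    masked[[length(masked) + 1L]] <- data.frame(
      locus_id = id, sequence = m$sequence, stringsAsFactors = FALSE)
    baits[[length(baits) + 1L]] <- b
    rep_rows[[i]] <- data.frame(locus_id = id, status = "kept",
                                masked_bp = masked_bp,
                                n_segments = nrow(m$segments),
                                n_baits = nrow(b), stringsAsFactors = FALSE)
  }
  list(masked = if (length(masked)) do.call(rbind, masked) else
         data.frame(locus_id = character(), sequence = character()),
       baits = if (length(baits)) do.call(rbind, baits) else
         tile_baits(structure(list(locus_id = NA, sequence = "A",
                                   segments = matrix(integer(), ncol = 2L)),
                              class = "masked_locus")),
       report = do.call(rbind, rep_rows))
}
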