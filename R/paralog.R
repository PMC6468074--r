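## Paralog screening: a captured sequence whose best genome hit falls
## outside its annotated target region is flagged as a putative paralog
## and excluded from downstream marker selection.

#' Best hit among tabular alignment hits for one query
#'
#' Maximal bitscore; ties broken by lower evalue, then longer alignment,
#' then lexicographically smaller subject id.
#'
#' @param hits data frame of hits for a single query, as returned by
#'   [read_hits_table()].
#' @return a one-row data frame, or \code{NULL} for an empty input.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (length(unique(hits$qseqid)) > 1L) {
    stop("best_hit() expects hits for a single query")
  }
  o <- order(-hits$bitscore, hits$evalue, -hits$length, hits$sseqid)
  hits[o[1], , drop = FALSE]
}

#' Screen captured sequences for putative paralogs
#'
#' For each query, the best hit (see [best_hit()]) is compared with the
#' annotated target region of its locus: the verdict is \code{ortholog}
#' when the strand-normalized hit interval overlaps the annotation on the
#' same chromosome by at least \code{min_overlap_bp}, \code{paralog}
#' otherwise, and \code{no_hit} when the query has no hits at all.  Strand
#' is ignored for the overlap test.  Query ids may encode a taxon as
#' \code{locus_id|taxon}; the locus part keys into the annotation table.
#'
#' @param hits data frame of hits for any number of queries.
#' @param targets annotation data frame from [read_target_table()].
#' @param min_overlap_bp minimum overlap (bp) to count as in-target.
#' @param queries optional character vector of all query ids (so queries
#'   with zero hits receive a \code{no_hit} verdict); defaults to the
#'   queries present in \code{hits}.
#' @param drop_no_hit if \code{TRUE}, \code{no_hit} queries join the
#'   excluded set; by default they are retained with a warning since only
#'   wrong-location hits diagnose paralogy.
#' @return data frame with one row per query: \code{query_id},
#'   \code{locus_id}, \code{taxon}, \code{status}, \code{excluded}, and the
#'   best-hit subject/coordinates (NA for \code{no_hit}).
#' @export
screen_paralogs <- function(hits, targets, min_overlap_bp = 1L,
                            queries = NULL, drop_no_hit = FALSE) {
  stopifnot(min_overlap_bp >= 1L)
  if (!all(c("s_lo", "s_hi") %in% names(hits))) {
    hits$s_lo <- pmin(hits$sstart, hits$send)
    hits$s_hi <- pmax(hits$sstart, hits$send)
  }
  if (is.null(queries)) queries <- unique(hits$qseqid)
  parts <- strsplit(queries, "|", fixed = TRUE)
  locus <- vapply(parts, `[`, character(1), 1L)
  taxon <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                  character(1))

  missing <- setdiff(unique(locus), targets$locus_id)
  if (length(missing)) {
    stop("no target annotation for locus/loci: ", paste(missing, collapse = ", "))
  }

  n <- length(queries)
  status <- character(n)
  sseqid <- rep(NA_character_, n)
  s_lo <- s_hi <- rep(NA_integer_, n)
  bitscore <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    bh <- best_hit(hits[hits$qseqid == queries[k], , drop = FALSE])
    if (is.null(bh)) {
      status[k] <- "no_hit"
      next
    }
    ann <- targets[targets$locus_id == locus[k], , drop = FALSE][1, ]
    ov <- if (bh$sseqid == ann$chrom) {
      min(bh$s_hi, ann$end) - max(bh$s_lo, ann$start) + 1L
    } else 0L
    status[k] <- if (ov >= min_overlap_bp) "ortholog" else "paralog"
    sseqid[k] <- bh$sseqid
    s_lo[k] <- bh$s_lo
    s_hi[k] <- bh$s_hi
    bitscore[k] <- bh$bitscore
  }
  if (any(status == "no_hit") && !drop_no_hit) {
    warning(sum(status == "no_hit"), " query(ies) had no hits; retained ",
            "(use drop_no_hit = TRUE to exclude them)")
  }
  data.frame(query_id = queries, locus_id = locus, taxon = taxon,
             status = status,
             excluded = status == "paralog" | (drop_no_hit & status == "no_hit"),
             sseqid = sseqid, s_lo = s_lo, s_hi = s_hi, bitscore = bitscore,
             stringsAsFactors = FALSE, row.names = NULL)
}
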