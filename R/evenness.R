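## Coverage evenness.  RC50: sort loci by read coverage in descending
## order; RC50 is the number of top loci that consume half of all mapped
## read data.  A higher RC50 means the reads are spread more evenly over
## the loci (a perfectly even capture has RC50 = ceiling(n/2)); a low RC50
## means a few runaway loci ate most of the sequencing.

#' Per-locus read coverage
#'
#' Coverage is the total length of captured reads mapped to a locus
#' divided by the locus length.
#'
#' @param locus_len locus length(s) in nt, \code{> 0}.
#' @param mapped_read_bases total mapped read bases, \code{>= 0}.  When
#'   the same mapping produced a per-position depth profile, this equals
#'   the sum of the profile, so coverage equals mean depth.
#' @return numeric coverage value(s).
#' @export
locus_coverage <- function(locus_len, mapped_read_bases) {
  if (any(locus_len <= 0)) stop("locus_len must be > 0")
  if (any(mapped_read_bases < 0)) stop("mapped_read_bases must be >= 0")
  mapped_read_bases / locus_len
}

#' Assemble a coverage table
#'
#' @param locus_id,locus_len,mapped_read_bases parallel vectors.
#' @param mapped_reads optional read counts (for \code{unit = "reads"} in
#'   [rc50()]).
#' @return data frame with a computed \code{coverage} column.
#' @export
coverage_table <- function(locus_id, locus_len, mapped_read_bases,
                           mapped_reads = NULL) {
  out <- data.frame(locus_id = locus_id, locus_len = locus_len,
                    mapped_read_bases = mapped_read_bases,
                    coverage = locus_coverage(locus_len, mapped_read_bases),
                    stringsAsFactors = FALSE)
  if (!is.null(mapped_reads)) out$mapped_reads <- mapped_reads
  out
}

#' RC50 coverage-evenness statistic
#'
#' Loci are sorted by coverage in descending order (ties by mapped mass
#' descending, then locus id); RC50 is the smallest k such that the top k
#' loci account for at least half of the total mapped read data.  The
#' accumulated quantity is mapped bases by default (consistent with the
#' coverage definition); set \code{unit = "reads"} to accumulate read
#' counts from a \code{mapped_reads} column instead.
#'
#' @param tab a [coverage_table()].
#' @param unit \code{"bases"} (default) or \code{"reads"}.
#' @return integer RC50, in \code{[1, nrow(tab)]}.
#' @export
rc50 <- function(tab, unit = c("bases", "reads")) {
  unit <- match.arg(unit)
  if (nrow(tab) == 0L) stop("empty coverage table")
  w <- if (unit == "bases") tab$mapped_read_bases else {
    if (is.null(tab$mapped_reads)) stop("no mapped_reads column for unit = 'reads'")
    tab$mapped_reads
  }
  total <- sum(w)
  if (total <= 0) stop("total mapped data is zero")
  o <- order(-tab$coverage, -w, tab$locus_id)
  unname(which(cumsum(w[o]) >= 0.5 * total)[1])
}

#' Sorted cumulative coverage curve
#'
#' The curve behind RC50: loci ranked by coverage against the cumulative
#' fraction of mapped data they consume.
#'
#' @inheritParams rc50
#' @return data frame with \code{rank}, \code{locus_id}, \code{coverage},
#'   \code{cum_fraction}.
#' @export
rc50_curve <- function(tab, unit = c("bases", "reads")) {
  unit <- match.arg(unit)
  w <- if (unit == "bases") tab$mapped_read_bases else tab$mapped_reads
  o <- order(-tab$coverage, -w, tab$locus_id)
  data.frame(rank = seq_along(o),
             locus_id = tab$locus_id[o],
             coverage = tab$coverage[o],
             cum_fraction = cumsum(w[o]) / sum(w),
             stringsAsFactors = FALSE)
}
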