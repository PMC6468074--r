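## Readers and writers for the external formats the pipeline consumes.
##
## Coordinate conventions: depth tables are 1-based (samtools depth dialect),
## tabular hits and target annotations are 1-based inclusive (BLAST dialect),
## and everything held internally -- exon spans, masked spans, bait offsets --
## is 0-based half-open.  The readers below are the only place the shift
## between the two conventions happens.

#' Read a (possibly soft-masked) FASTA file of captured loci
#'
#' Parses one record per FASTA entry.  Headers are expected in the form
#' \code{locus_id|taxon}; a bare \code{locus_id} (no \code{|}) is accepted,
#' in which case the taxon is \code{NA}.  Locus ids follow the dot-separated
#' \code{reference_species.chrom.start.end} scheme (e.g.
#' \code{"Danio_rerio.20.4037479.4035425"}) but any non-empty token is
#' allowed.  Character case is preserved: lowercase bases mark soft-masked
#' (e.g. read-depth anomalous) regions.
#'
#' @param path path to a FASTA file.
#' @return a data frame with columns \code{locus_id}, \code{taxon}
#'   (\code{NA} when not encoded in the header) and \code{sequence}.
#'   An empty file yields a zero-row data frame with a warning.
#' @seealso [write_fasta()], [masked_spans()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    warning("no FASTA records in ", path)
    return(data.frame(locus_id = character(), taxon = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- strip_ws(vapply(recs, function(r) as.character(r[1]), character(1)))
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(vapply(parts, function(p) {
    length(p) < 1L || length(p) > 2L || !nzchar(p[[1]])
  }, logical(1)))
  if (length(bad)) {
    stop("malformed FASTA header(s) at record(s) ",
         paste(bad, collapse = ", "), " in ", path)
  }
  data.frame(
    locus_id = vapply(parts, `[`, character(1), 1L),
    taxon    = vapply(parts, function(p) if (length(p) == 2L) p[2L] else NA_character_,
                      character(1)),
    sequence = unname(seqs),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# seqinr returns the sequence string untouched when forceDNAtolower = FALSE;
# this is only a sanity hook that strips stray whitespace.
strip_ws <- function(x) gsub("[[:space:]]", "", x)

#' Write locus sequences to FASTA, preserving soft-masking
#'
#' The inverse of [read_fasta()]: headers are \code{locus_id|taxon}, or bare
#' \code{locus_id} when \code{taxon} is \code{NA}/absent.  Case (and hence
#' soft-masking) is written exactly as stored.
#'
#' @param x data frame with columns \code{locus_id}, \code{sequence} and
#'   optionally \code{taxon}.
#' @param path output path.
#' @param width line width for the sequence block.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), all(c("locus_id", "sequence") %in% names(x)))
  taxon <- if ("taxon" %in% names(x)) x$taxon else rep(NA_character_, nrow(x))
  nm <- ifelse(is.na(taxon), x$locus_id, paste0(x$locus_id, "|", taxon))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", nm[i]), con)
    s <- x$sequence[i]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Soft-masked spans of a sequence
#'
#' @param sequence a DNA string with lowercase marking masked regions.
#' @return integer matrix with columns \code{start}, \code{end}: 0-based
#'   half-open spans of the lowercase runs (zero rows if none).
#' @export
masked_spans <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  m <- gregexpr("[a-z]+", sequence)[[1]]
  if (m[1] == -1L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = as.integer(m) - 1L,
        end   = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Read a samtools-depth style table into per-locus depth profiles
#'
#' Expects a headerless 3-column TSV: \code{locus_id}, \code{pos} (1-based)
#' and \code{depth}.  Positions absent from the table are imputed as depth 0
#' (samtools omits zero-depth rows unless run with \code{-a}), up to the
#' maximum observed position or the supplied locus length.
#'
#' @param path path to the TSV.
#' @param lengths optional named integer vector of locus lengths; profiles
#'   are padded with zeros to these lengths.
#' @return named list of integer depth vectors, one per locus, indexed by
#'   1-based position.  An empty file yields an empty list.
#' @export
read_depth_table <- function(path, lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(list())
  tab <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 3L) stop("expected 3 columns (locus, pos, depth), got ", ncol(tab))
  pos <- suppressWarnings(as.integer(tab[[2]]))
  dep <- suppressWarnings(as.integer(tab[[3]]))
  bad <- which(is.na(pos) | is.na(dep) | dep < 0L | pos < 1L)
  if (length(bad)) stop("non-integer or negative pos/depth at row ", bad[1])
  out <- lapply(split(seq_len(nrow(tab)), tab[[1]]), function(idx) {
    id <- tab[[1]][idx[1]]
    L <- max(pos[idx])
    if (!is.null(lengths) && !is.na(lengths[id])) L <- max(L, lengths[[id]])
    d <- integer(L)
    d[pos[idx]] <- dep[idx]
    d
  })
  out[unique(tab[[1]])]
}

#' Combine depth profiles across samples
#'
#' Profiles for the same locus from different samples are combined
#' position-wise; shorter profiles are zero-padded.  The default
#' \code{"max"} masks a region that is anomalous in any sample.
#'
#' @param profiles list of named depth-profile lists (one per sample), as
#'   returned by [read_depth_table()].
#' @param method \code{"max"} or \code{"mean"}.
#' @return a single named list of depth vectors.
#' @export
combine_depths <- function(profiles, method = c("max", "mean")) {
  method <- match.arg(method)
  loci <- unique(unlist(lapply(profiles, names)))
  out <- lapply(loci, function(id) {
    vs <- lapply(profiles, function(p) p[[id]])
    vs <- vs[!vapply(vs, is.null, logical(1))]
    L <- max(vapply(vs, length, integer(1)))
    mat <- vapply(vs, function(v) c(v, integer(L - length(v))), numeric(L))
    mat <- matrix(mat, nrow = L)
    if (method == "max") as.integer(apply(mat, 1L, max))
    else as.numeric(rowMeans(mat))
  })
  names(out) <- loci
  out
}

#' Read a 12-column tabular alignment-hit file (BLAST outfmt 6 dialect)
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore.  A subject start greater than the subject
#' end encodes a minus-strand hit; both the original coordinates and a
#' strand-normalized interval (\code{s_lo <= s_hi}, 1-based inclusive) are
#' returned.
#'
#' @param path path to the TSV.
#' @return data frame of hits with added columns \code{strand},
#'   \code{s_lo}, \code{s_hi}.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = 12, dimnames = list(NULL, cols)))
    out$strand <- character(); out$s_lo <- integer(); out$s_hi <- integer()
    return(out)
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) stop("expected 12 columns (outfmt 6), got ", ncol(tab))
  names(tab) <- cols
  tab$bitscore <- as.numeric(tab$bitscore)
  if (any(tab$bitscore < 0, na.rm = TRUE)) stop("negative bitscore")
  tab$strand <- ifelse(tab$sstart <= tab$send, "+", "-")
  tab$s_lo <- pmin(tab$sstart, tab$send)
  tab$s_hi <- pmax(tab$sstart, tab$send)
  tab
}

#' Read a target-region annotation table
#'
#' A 5-column TSV giving each marker's true location in its reference
#' genome: \code{locus_id}, \code{genome_id}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive, \code{start <= end}).
#'
#' @param path path to the TSV.
#' @return data frame of annotations.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 5L) stop("expected 5 columns, got ", ncol(tab))
  names(tab) <- c("locus_id", "genome_id", "chrom", "start", "end")
  if (any(tab$start > tab$end)) stop("annotation with start > end")
  tab
}

#' Write a target-region annotation table
#' @param x data frame as returned by [read_target_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_target_table <- function(x, path) {
  write.table(x[, c("locus_id", "genome_id", "chrom", "start", "end")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
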