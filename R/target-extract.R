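## Target identification: translate assembled contigs in all six frames,
## align them to the bait protein by local (Smith-Waterman) alignment under
## an affine gap model, and delineate the exon (the bait-covered region)
## from the flanking sequence.

#' The BLOSUM62 substitution matrix
#'
#' Convenience accessor for the BLOSUM62 matrix shipped with Biostrings,
#' the default scoring matrix for the translated alignment step.
#'
#' @return numeric substitution matrix with amino-acid row/column names
#'   (including the X wildcard and the * stop rows).
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under an affine gap model (Gotoh's algorithm):
#' a gap of length L costs \code{gap_open + gap_extend * L}.  Residues not
#' present in the scoring matrix are scored through its \code{X} wildcard
#' row when available, otherwise an error is raised.  The empty alignment
#' (score 0) is allowed, so the score is never negative.
#'
#' @param a,b protein sequences (single strings over the 20 amino acids
#'   plus \code{X} and \code{*}).
#' @param matrix substitution matrix; default [blosum62()].
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return an object of class \code{protein_alignment}: a list with
#'   \code{score}, \code{query_span} and \code{subject_span} (0-based
#'   half-open spans of the aligned region in \code{a} and \code{b}), and
#'   \code{query_aln}/\code{subject_aln}, the gapped aligned strings.
#' @examples
#' smith_waterman_protein("MKT", "MKT")$score  # 15 under BLOSUM62
#' @export
smith_waterman_protein <- function(a, b, matrix = blosum62(),
                                   gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    return(structure(list(score = 0, query_span = c(0L, 0L),
                          subject_span = c(0L, 0L),
                          query_aln = "", subject_aln = ""),
                     class = "protein_alignment"))
  }
  ai <- encode_protein(a, matrix)
  bi <- encode_protein(b, matrix)
  r <- sw_align_cpp(ai, bi, matrix, gap_open, gap_extend)
  achr <- strsplit(a, "")[[1]]
  bchr <- strsplit(b, "")[[1]]
  qaln <- ifelse(is.na(r$q_aln), "-", achr[r$q_aln + 1L])
  saln <- ifelse(is.na(r$s_aln), "-", bchr[r$s_aln + 1L])
  structure(list(score = r$score,
                 query_span = c(r$q_start, r$q_end),
                 subject_span = c(r$s_start, r$s_end),
                 query_aln = paste(qaln, collapse = ""),
                 subject_aln = paste(saln, collapse = "")),
            class = "protein_alignment")
}

# map residues to 0-based matrix indices; unknowns fall back to X
encode_protein <- function(x, matrix) {
  rn <- rownames(matrix)
  ch <- strsplit(toupper(x), "")[[1]]
  idx <- match(ch, rn)
  if (anyNA(idx)) {
    if (!"X" %in% rn) {
      stop("residue(s) ", paste(unique(ch[is.na(idx)]), collapse = ","),
           " not in scoring matrix and no X wildcard row available")
    }
    idx[is.na(idx)] <- match("X", rn)
  }
  idx - 1L
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Local protein alignment, score", x$score, "\n")
  cat("  query  [", x$query_span[1], ",", x$query_span[2], ") ",
      x$query_aln, "\n", sep = "")
  cat("  sbjct  [", x$subject_span[1], ",", x$subject_span[2], ") ",
      x$subject_aln, "\n", sep = "")
  invisible(x)
}

# standard codon table, stops and ambiguous codons mapped to the X
# wildcard so they score neutrally in the local alignment
codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(as.vector(outer(b, b, paste0)), b,
                            function(x, y) paste0(x, y)))
  codons <- sort(codons)
  tab <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd)))
  }, character(1))
  tab[tab == "*"] <- "X"
  tab
})

#' Translate a DNA string (frame +1)
#'
#' Trailing partial codons are dropped; stop codons and codons containing
#' ambiguous bases become the \code{X} wildcard.
#'
#' @param sequence DNA string (case-insensitive).
#' @return amino-acid string.
#' @export
translate_dna <- function(sequence) {
  s <- toupper(sequence)
  L <- (nchar(s) %/% 3L) * 3L
  if (L == 0L) return("")
  starts <- seq(1L, L, by = 3L)
  aa <- codon_table[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a contig in all six reading frames
#'
#' Stop codons are rewritten as the \code{X} wildcard so a contig carrying
#' an in-frame stop (assembly artefact, UTR overhang) can still anchor a
#' local alignment; frameshifted contigs match only up to their best single
#' frame.
#'
#' @param sequence DNA string (case-insensitive; \code{N} allowed).
#' @return data frame with columns \code{frame} (+1,+2,+3,-1,-2,-3) and
#'   \code{protein}.
#' @export
translate_frames <- function(sequence) {
  s <- toupper(sequence)
  r <- revcomp(s)
  data.frame(frame = c(1L, 2L, 3L, -1L, -2L, -3L),
             protein = c(translate_dna(s), translate_dna(substring(s, 2L)),
                         translate_dna(substring(s, 3L)),
                         translate_dna(r), translate_dna(substring(r, 2L)),
                         translate_dna(substring(r, 3L))),
             stringsAsFactors = FALSE)
}

#' Identify the target exon for one locus among assembled contigs
#'
#' Every contig is translated in all six frames and aligned locally to the
#' bait protein; the highest-scoring contig x frame combination wins.  The
#' exon span is the nucleotide back-projection of the bait-covered aligned
#' region onto the contig, reported in forward-strand coordinates after
#' orientation (minus-frame hits are reverse-complemented first); the rest
#' of the contig on either side is flanking sequence.  Partial codons at
#' the alignment ends are kept: bait coverage, not codon structure, defines
#' the exon boundary.
#'
#' Ties in best score across contigs are broken deterministically (longer
#' contig, then lexicographically smaller contig id) with a warning; within
#' a contig the first frame in the order +1,+2,+3,-1,-2,-3 wins.
#'
#' @param locus_id locus identifier carried into the call.
#' @param bait_protein amino-acid sequence of the original bait/reference
#'   exon.
#' @param contigs named character vector (\code{contig_id -> sequence}) or
#'   a data frame with columns \code{contig_id}, \code{sequence}.
#' @param min_score minimum alignment score (matrix units) to accept a
#'   call; below it \code{NULL} is returned.
#' @param matrix,gap_open,gap_extend passed to [smith_waterman_protein()].
#' @return an object of class \code{target_call} (list with
#'   \code{locus_id}, \code{contig_id}, \code{frame}, \code{score},
#'   \code{sequence} -- the oriented contig --, \code{exon_span} 0-based
#'   half-open, \code{exon_seq}, \code{left_flank_len},
#'   \code{right_flank_len}), or \code{NULL} when no contig reaches
#'   \code{min_score}.
#' @export
call_target <- function(locus_id, bait_protein, contigs, min_score = 40,
                        matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  if (is.data.frame(contigs)) {
    contigs <- setNames(contigs$sequence, contigs$contig_id)
  }
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)))

  best <- NULL
  for (cid in names(contigs)) {
    tf <- translate_frames(contigs[[cid]])
    for (k in seq_len(nrow(tf))) {
      if (!nzchar(tf$protein[k])) next
      aln <- smith_waterman_protein(bait_protein, tf$protein[k],
                                    matrix, gap_open, gap_extend)
      cand <- list(contig_id = cid, frame = tf$frame[k], aln = aln,
                   len = nchar(contigs[[cid]]))
      if (!is.null(best) && aln$score == best$aln$score &&
          cid != best$contig_id && aln$score > 0) {
        warning("tie in best score for locus ", locus_id, " between contigs ",
                best$contig_id, " and ", cid, "; broken deterministically")
      }
      if (is.null(best) || better_call(cand, best)) best <- cand
    }
  }
  if (is.null(best) || best$aln$score < min_score) return(NULL)

  seq <- contigs[[best$contig_id]]
  if (best$frame < 0L) seq <- revcomp(seq)
  off <- abs(best$frame) - 1L
  ss <- best$aln$subject_span
  exon_start <- off + 3L * ss[1]
  exon_end <- off + 3L * ss[2]
  structure(list(locus_id = locus_id,
                 contig_id = best$contig_id,
                 frame = best$frame,
                 score = best$aln$score,
                 sequence = seq,
                 exon_span = c(exon_start, exon_end),
                 exon_seq = substr(seq, exon_start + 1L, exon_end),
                 left_flank_len = exon_start,
                 right_flank_len = nchar(seq) - exon_end),
            class = "target_call")
}

# strict preference order: score desc, contig length desc, contig id asc,
# frame order as generated
better_call <- function(cand, best) {
  if (cand$aln$score != best$aln$score) return(cand$aln$score > best$aln$score)
  if (cand$contig_id == best$contig_id) return(FALSE)
  if (cand$len != best$len) return(cand$len > best$len)
  cand$contig_id < best$contig_id
}

revcomp <- function(x) {
  ch <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]])
  paste(ch, collapse = "")
}

#' @export
print.target_call <- function(x, ...) {
  cat("Target call ", x$locus_id, ": contig ", x$contig_id,
      ", frame ", x$frame, ", score ", x$score, "\n",
      "  exon [", x$exon_span[1], ",", x$exon_span[2], ") with flanks ",
      x$left_flank_len, "/", x$right_flank_len, " nt\n", sep = "")
  invisible(x)
}

#' Split target calls into exon-only and exon-plus-flank sequence sets
#'
#' @param calls list of \code{target_call} objects (NULLs are dropped).
#' @return list with two data frames, \code{exon} and \code{flanked}, with
#'   identical \code{locus_id} sets and order; ready for [write_fasta()].
#' @export
split_outputs <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  if (length(calls) == 0L) {
    empty <- data.frame(locus_id = character(), sequence = character(),
                        stringsAsFactors = FALSE)
    return(list(exon = empty, flanked = empty))
  }
  for (cl in calls) {
    if (cl$exon_span[1] < 0L || cl$exon_span[2] > nchar(cl$sequence)) {
      stop("exon span outside contig bounds for locus ", cl$locus_id)
    }
  }
  list(
    exon = data.frame(
      locus_id = vapply(calls, `[[`, character(1), "locus_id"),
      sequence = vapply(calls, `[[`, character(1), "exon_seq"),
      stringsAsFactors = FALSE),
    flanked = data.frame(
      locus_id = vapply(calls, `[[`, character(1), "locus_id"),
      sequence = vapply(calls, `[[`, character(1), "sequence"),
      stringsAsFactors = FALSE)
  )
}
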