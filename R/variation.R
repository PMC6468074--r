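## Flanking-region variability, majority-rule consensus references, and
## one-best-SNP genotype export.  Flanks are captured by hitchhiking and
## are typically more variable than the targeted coding sequence, which
## makes them attractive for shallow-divergence work -- once the short,
## indel-ridden and unalignable ones are filtered out.

#' Classify flanking sequences for retention
#'
#' Each flank is assigned exactly one primary status, tested in order:
#' \code{too_short} when the ungapped length is below \code{min_len} nt;
#' \code{long_indel} when the aligned sequence carries a gap run longer
#' than \code{max_gap_run}; \code{unalignable} when the p-distance to the
#' per-locus/side majority consensus exceeds \code{max_pdist}; otherwise
#' \code{pass}.  Alignment-based rules only apply within groups
#' (locus, side) whose sequences share one aligned length; raw-length
#' groups get the length rule only.  Sequences are never modified.
#'
#' @param flanks data frame with columns \code{locus_id}, \code{taxon},
#'   \code{side} (\code{"left"}/\code{"right"}), \code{sequence}.
#' @param min_len minimum ungapped length (default 20 nt).
#' @param max_gap_run longest tolerated gap run (default 30 nt).
#' @param max_pdist maximum p-distance to the consensus (default 0.6).
#' @return the input with an added \code{status} column.
#' @export
filter_flanks <- function(flanks, min_len = 20L, max_gap_run = 30L,
                          max_pdist = 0.6) {
  stopifnot(is.data.frame(flanks),
            all(c("locus_id", "taxon", "side", "sequence") %in% names(flanks)))
  ungapped <- nchar(gsub("-", "", flanks$sequence))
  status <- rep("pass", nrow(flanks))
  status[ungapped < min_len] <- "too_short"

  grp <- paste(flanks$locus_id, flanks$side, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g & status != "too_short")
    if (length(idx) == 0L) next
    if (length(unique(nchar(flanks$sequence[idx]))) != 1L) next  # unaligned
    gaprun <- vapply(flanks$sequence[idx], function(s) {
      m <- gregexpr("-+", s)[[1]]
      if (m[1] == -1L) 0L else max(attr(m, "match.length"))
    }, integer(1))
    status[idx[gaprun > max_gap_run]] <- "long_indel"
    idx2 <- idx[status[idx] == "pass"]
    if (length(idx2) >= 2L) {
      cons <- majority_consensus(setNames(flanks$sequence[idx2],
                                          flanks$taxon[idx2]),
                                 drop_gap_majority = FALSE)
      pd <- vapply(flanks$sequence[idx2],
                   function(s) p_distance(s, cons), numeric(1))
      status[idx2[!is.na(pd) & pd > max_pdist]] <- "unalignable"
    }
  }
  flanks$status <- status
  flanks
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent called base wins; ties among bases are
#' encoded as the IUPAC ambiguity code of the tied set; columns where gaps
#' hold a strict majority are omitted from the consensus; columns with no
#' called base at all become \code{N}.
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @param drop_gap_majority omit gap-majority columns (default
#'   \code{TRUE}; set \code{FALSE} to keep the consensus aligned to the
#'   input, with \code{-} in those columns).
#' @return consensus DNA string.
#' @export
majority_consensus <- function(aln, drop_gap_majority = TRUE) {
  stopifnot(length(aln) >= 1L)
  if (length(unique(nchar(aln))) != 1L) stop("rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- nrow(m)
  out <- apply(m, 2L, function(col) {
    gaps <- sum(col == "-")
    if (gaps > n / 2) return(if (drop_gap_majority) "" else "-")
    base <- col[col %in% c("A", "C", "G", "T")]
    if (length(base) == 0L) return("N")
    tab <- table(base)
    winners <- sort(names(tab)[tab == max(tab)])
    iupac_code(winners)
  })
  paste(out, collapse = "")
}

IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

iupac_code <- function(bases) unname(IUPAC[paste(sort(unique(bases)), collapse = "")])

#' Flank and coding variability summary
#'
#' Summarises ungapped flank lengths, all pairwise flank p-distances, and
#' SNP densities per kb for the flank and coding partitions.  A SNP is an
#' alignment column with at least two distinct called bases; the surveyed
#' denominator is the number of columns with at least two called bases
#' (approximately the reference length actually screened), so density =
#' 1000 x SNPs / surveyed bp.
#'
#' @param flank_alns named list of flank alignments (named character
#'   vectors per locus).
#' @param coding_alns optional named list of coding alignments.
#' @return list with \code{flank_lengths} (data frame), \code{flank_pdist}
#'   (data frame of pairwise distances), \code{flank_per_kb},
#'   \code{coding_per_kb} (NA when not computable), and the underlying
#'   \code{flank_snps}/\code{coding_snps} counts and surveyed totals.
#' @export
flank_variability <- function(flank_alns, coding_alns = NULL) {
  lengths <- do.call(rbind, lapply(names(flank_alns), function(id) {
    a <- flank_alns[[id]]
    data.frame(locus_id = id, taxon = names(a),
               length = nchar(gsub("[-?]", "", a)),
               stringsAsFactors = FALSE)
  }))
  pd <- do.call(rbind, lapply(names(flank_alns), function(id) {
    a <- flank_alns[[id]]
    if (length(a) < 2L) return(NULL)
    cbind(locus_id = id, pdist_pairs(a))
  }))
  fl <- snp_density(flank_alns)
  cd <- if (is.null(coding_alns)) list(n_snps = NA_integer_,
                                       surveyed_bp = NA_integer_,
                                       per_kb = NA_real_)
        else snp_density(coding_alns)
  list(flank_lengths = lengths, flank_pdist = pd,
       flank_snps = fl$n_snps, flank_surveyed_bp = fl$surveyed_bp,
       flank_per_kb = fl$per_kb,
       coding_snps = cd$n_snps, coding_surveyed_bp = cd$surveyed_bp,
       coding_per_kb = cd$per_kb)
}

#' SNP count and density over a set of alignments
#'
#' @param alns named list of alignments (named character vectors).
#' @return list with \code{n_snps}, \code{surveyed_bp} and \code{per_kb}
#'   (\code{NA} when nothing was surveyed).
#' @export
snp_density <- function(alns) {
  n_snps <- 0L
  surveyed <- 0L
  for (aln in alns) {
    if (length(aln) < 2L) next
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    for (j in seq_len(ncol(m))) {
      base <- m[, j][m[, j] %in% c("A", "C", "G", "T")]
      if (length(base) >= 2L) {
        surveyed <- surveyed + 1L
        if (length(unique(base)) >= 2L) n_snps <- n_snps + 1L
      }
    }
  }
  list(n_snps = n_snps, surveyed_bp = surveyed,
       per_kb = if (surveyed > 0L) 1000 * n_snps / surveyed else NA_real_)
}

#' One-best-SNP genotype matrix from a VCF
#'
#' Drops indels and multi-allelic records, then keeps a single SNP per
#' locus -- the one with the highest QUAL, ties broken by lowest
#' missingness and then smallest position -- so downstream analyses such
#' as PCA see at most one (approximately unlinked) variant per locus.
#' Genotypes are coded as alternate-allele dosage 0/1/2, \code{NA} for
#' missing calls.  The locus id is taken from CHROM.
#'
#' @param vcf path to a VCF 4.x file, or a \code{vcfR} object.
#' @return list with \code{genotypes} (integer matrix, samples x loci) and
#'   \code{snps} (data frame of the kept SNP per locus: \code{locus_id},
#'   \code{pos}, \code{qual}).
#' @export
select_best_snp <- function(vcf) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  n_multi <- sum(grepl(",", fix$ALT))
  if (n_multi) message(n_multi, " multi-allelic record(s) dropped")
  if (!any(keep)) {
    return(list(genotypes = matrix(integer(), nrow = ncol(gt), ncol = 0L,
                                   dimnames = list(colnames(gt), NULL)),
                snps = data.frame(locus_id = character(), pos = integer(),
                                  qual = numeric())))
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  pos <- as.integer(fix$POS)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- -Inf
  # records x samples dosage matrix
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) dosage[, j] <- gt_dosage(gt[, j])
  missing_n <- rowSums(is.na(dosage))

  sel <- integer(0)
  for (id in unique(fix$CHROM)) {
    idx <- which(fix$CHROM == id)
    o <- order(-qual[idx], missing_n[idx], pos[idx])
    sel <- c(sel, idx[o[1]])
  }
  geno <- t(dosage[sel, , drop = FALSE])
  colnames(geno) <- fix$CHROM[sel]
  rownames(geno) <- colnames(gt)
  list(genotypes = geno,
       snps = data.frame(locus_id = fix$CHROM[sel], pos = pos[sel],
                         qual = qual[sel], stringsAsFactors = FALSE,
                         row.names = NULL))
}

# "0/1", "0|1", "./.", "1" -> alternate-allele count or NA
gt_dosage <- function(g) {
  vapply(g, function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".") || length(al) == 0L) return(NA_integer_)
    sum(al != "0")
  }, integer(1), USE.NAMES = FALSE)
}
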