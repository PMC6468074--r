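## Marker summary statistics on aligned loci: ungapped length, GC content,
## pairwise p-distance, and Fitch-parsimony consistency (CI) and retention
## (RI) indices on a reference tree.
##
## An alignment is represented as a named character vector of equal-length
## gapped DNA strings over {A,C,G,T,N,-}; names are taxon labels.

aln_matrix <- function(aln) {
  stopifnot(length(aln) >= 2L, !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L) stop("rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

MISSING_CHARS <- c("-", "N", "?")

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of mismatches among comparable sites; a site is comparable
#' when neither row carries a gap, \code{N} or \code{?}.  \code{NA} when
#' no site is comparable.
#'
#' @param a,b equal-length gapped DNA strings.
#' @return p-distance in \code{[0, 1]}, or \code{NA}.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(x) == length(y))
  ok <- !(x %in% MISSING_CHARS | y %in% MISSING_CHARS)
  if (!any(ok)) return(NA_real_)
  mean(x[ok] != y[ok])
}

#' All pairwise p-distances of an alignment
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @return data frame with \code{taxon_a}, \code{taxon_b}, \code{pdist}
#'   for each of the \code{choose(n, 2)} pairs.
#' @export
pdist_pairs <- function(aln) {
  n <- length(aln)
  stopifnot(n >= 2L)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(taxon_a = names(aln)[idx[, 1]],
             taxon_b = names(aln)[idx[, 2]],
             pdist = mapply(function(i, j) p_distance(aln[[i]], aln[[j]]),
                            idx[, 1], idx[, 2]),
             stringsAsFactors = FALSE)
}

#' Basic marker statistics of one aligned locus
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @return list with \code{mean_length} (mean ungapped, non-missing length
#'   in nt), \code{gc} (G+C fraction of called bases) and
#'   \code{mean_pdist} (mean pairwise p-distance; pairs with no comparable
#'   site are excluded with a warning).
#' @export
basic_stats <- function(aln) {
  m <- aln_matrix(aln)
  called <- !(m %in% MISSING_CHARS)
  dim(called) <- dim(m)
  pd <- pdist_pairs(aln)$pdist
  if (anyNA(pd)) {
    warning(sum(is.na(pd)), " pair(s) with no comparable sites excluded")
    pd <- pd[!is.na(pd)]
  }
  list(mean_length = mean(rowSums(called)),
       gc = sum(m %in% c("G", "C")) / sum(called),
       mean_pdist = if (length(pd)) mean(pd) else NA_real_)
}

## ---- Fitch parsimony ------------------------------------------------------

# bitmask encoding of nucleotide state sets; missing data gets the full
# set, so it can match any neighbour at no cost
state_mask <- function(x) {
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L,
            N = 15L, `-` = 15L, `?` = 15L)
  m <- code[toupper(x)]
  if (anyNA(m)) stop("unknown state(s): ", paste(unique(x[is.na(m)]), collapse = ","))
  unname(m)
}

# returns a rooted, binary version of `tree` with tips unchanged; the
# parsimony length is invariant to how the basal multifurcation is resolved
as_binary_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) tree <- ape::multi2di(tree)
  tree
}

#' Fitch parsimony length of one site on a tree
#'
#' Counts the minimum number of state changes needed to explain the site
#' on the tree (Fitch's small-parsimony algorithm).  Gaps, \code{N} and
#' \code{?} are treated as missing: the leaf receives the full state set
#' and contributes no changes.  The count does not depend on the rooting.
#'
#' @param states named character vector of states (\code{A,C,G,T} plus
#'   missing codes), names matching the tree's tip labels.
#' @param tree an \code{ape} \code{phylo} tree whose tips are exactly
#'   \code{names(states)}.
#' @return integer number of steps.
#' @export
fitch_site_length <- function(states, tree) {
  po <- fitch_postorder(tree)
  if (!setequal(po$tips, names(states))) {
    stop("tree tips and state names disagree")
  }
  fitch_steps_mask(state_mask(states[po$tips]), po)
}

# resolve/root the tree once and cache its postorder edge list
fitch_postorder <- function(tree) {
  tr <- as_binary_rooted(tree)
  list(edge = ape::reorder.phylo(tr, "postorder")$edge,
       ntip = length(tr$tip.label), nnode = tr$Nnode,
       tips = tr$tip.label)
}

# core Fitch pass; `m` is the tip masks in po$tips order
fitch_steps_mask <- function(m, po) {
  edge <- po$edge
  mask <- integer(po$ntip + po$nnode)
  mask[seq_len(po$ntip)] <- m
  steps <- 0L
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    if (mask[p] == 0L) {
      mask[p] <- mask[ch]
    } else {
      inter <- bitwAnd(mask[p], mask[ch])
      if (inter == 0L) {
        mask[p] <- bitwOr(mask[p], mask[ch])
        steps <- steps + 1L
      } else {
        mask[p] <- inter
      }
    }
  }
  steps
}

#' Consistency and retention indices of an alignment on a tree
#'
#' Per site i, S_i is the observed Fitch parsimony length, M_i the minimum
#' conceivable length (number of distinct observed states minus one) and
#' G_i the maximum (non-missing taxa minus the count of the most frequent
#' state).  Then CI = sum(M)/sum(S) measures how free of homoplasy the
#' alignment is on the tree (1 = none), and RI = (sum(G)-sum(S)) /
#' (sum(G)-sum(M)) measures how much potential homoplasy is avoided.
#' Constant and all-missing sites contribute zeros to every sum.
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @param tree \code{phylo} tree over the alignment's taxa.
#' @param informative_only drop parsimony-uninformative sites (sites where
#'   fewer than two states occur in two or more taxa) from the sums,
#'   mirroring the corresponding option of classic parsimony software.
#' @return object of class \code{parsimony_scores}: list with per-site
#'   vectors \code{S_i}, \code{M_i}, \code{G_i}, totals \code{S}, \code{M},
#'   \code{G}, and \code{CI}, \code{RI} (\code{RI} is \code{NA} when
#'   \code{G == M}).  An alignment with \code{S == 0} (invariant on the
#'   tree) is an error since CI is undefined.
#' @export
ci_ri <- function(aln, tree, informative_only = FALSE) {
  m <- aln_matrix(aln)
  po <- fitch_postorder(tree)
  if (!setequal(po$tips, rownames(m))) stop("tree tips and taxa disagree")
  m <- m[po$tips, , drop = FALSE]
  nsite <- ncol(m)
  S <- M <- G <- integer(nsite)
  keep <- rep(TRUE, nsite)
  for (j in seq_len(nsite)) {
    col <- m[, j]
    obs <- col[!(col %in% MISSING_CHARS)]
    tabs <- table(obs)
    if (length(tabs) >= 1L) {
      M[j] <- length(tabs) - 1L
      G[j] <- length(obs) - max(tabs)
    }
    if (informative_only && sum(tabs >= 2L) < 2L) keep[j] <- FALSE
    if (M[j] > 0L) S[j] <- fitch_steps_mask(state_mask(col), po)
  }
  Ssum <- sum(S[keep]); Msum <- sum(M[keep]); Gsum <- sum(G[keep])
  if (Ssum == 0L) stop("alignment invariant on tree: CI undefined")
  structure(list(S_i = S, M_i = M, G_i = G,
                 S = Ssum, M = Msum, G = Gsum,
                 CI = Msum / Ssum,
                 RI = if (Gsum == Msum) NA_real_ else (Gsum - Ssum) / (Gsum - Msum)),
            class = "parsimony_scores")
}

#' @export
print.parsimony_scores <- function(x, ...) {
  cat("Parsimony: S =", x$S, " M =", x$M, " G =", x$G,
      "\n  CI =", round(x$CI, 4), " RI =",
      if (is.na(x$RI)) "NA" else round(x$RI, 4), "\n")
  invisible(x)
}

#' Per-locus marker statistics table
#'
#' Convenience wrapper producing one row per locus: mean ungapped length,
#' GC, mean p-distance, CI and RI (the latter two \code{NA} for loci
#' invariant on the tree).
#'
#' @param alns named list of alignments (named character vectors).
#' @param tree optional \code{phylo} tree; when \code{NULL}, CI/RI are
#'   skipped.  Loci with taxa absent from the tree are subset to the
#'   shared taxa (those with fewer than 2 shared taxa are skipped).
#' @return data frame with columns \code{locus_id}, \code{n_taxa},
#'   \code{mean_length}, \code{gc}, \code{mean_pdist}, \code{ci}, \code{ri}.
#' @export
marker_stats <- function(alns, tree = NULL) {
  rows <- lapply(names(alns), function(id) {
    aln <- alns[[id]]
    bs <- basic_stats(aln)
    ci <- ri <- NA_real_
    if (!is.null(tree)) {
      shared <- intersect(names(aln), tree$tip.label)
      if (length(shared) >= 3L) {
        sub <- ape::keep.tip(tree, shared)
        pr <- tryCatch(ci_ri(aln[shared], sub), error = function(e) NULL)
        if (!is.null(pr)) { ci <- pr$CI; ri <- pr$RI }
      }
    }
    data.frame(locus_id = id, n_taxa = length(aln),
               mean_length = bs$mean_length, gc = bs$gc,
               mean_pdist = bs$mean_pdist, ci = ci, ri = ri,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
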