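# Independent brute-force oracles.  Each is written straight from the
# mathematical definition of the quantity and shares no code with the
# implementation it checks.

# Exhaustive local alignment: enumerate every set of order-preserving
# aligned residue pairs; unpaired residues between consecutive pairs are
# gapped, a gap of length L costing gap_open + gap_extend * L.  The
# optimum over all local alignments is attained on such pair sets (an
# optimal local alignment never starts or ends with a gap when penalties
# are positive).
sw_enum <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) return(0)
  best <- 0
  gapcost <- function(L) if (L > 0L) gap_open + gap_extend * L else 0
  recurse <- function(i, j, sc) {
    if (sc > best) best <<- sc
    if (i >= n || j >= m) return(invisible())
    for (ii in (i + 1L):n) {
      for (jj in (j + 1L):m) {
        recurse(ii, jj,
                sc - gapcost(ii - i - 1L) - gapcost(jj - j - 1L) +
                  mat[A[ii], B[jj]])
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) recurse(i, j, mat[A[i], B[j]])
  max(0, best)
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

# RC50 by explicit sort and running total
rc50_oracle <- function(tab) {
  o <- order(-tab$coverage, -tab$mapped_read_bases, tab$locus_id)
  w <- tab$mapped_read_bases[o]
  total <- sum(w)
  acc <- 0
  for (k in seq_along(w)) {
    acc <- acc + w[k]
    if (acc >= total / 2) return(k)
  }
  length(w)
}

# Fitch length by exhaustive enumeration of all internal (and missing-tip)
# state assignments; steps = edges whose endpoints differ.
fitch_enum <- function(states, tree) {
  tr <- tree
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) tr <- ape::multi2di(tr)
  ntip <- length(tr$tip.label)
  N <- ntip + tr$Nnode
  bases <- c("A", "C", "G", "T")
  s <- toupper(states[tr$tip.label])
  cand <- vector("list", N)
  for (i in seq_len(ntip)) {
    cand[[i]] <- if (s[i] %in% bases) s[i] else bases
  }
  for (i in (ntip + 1L):N) cand[[i]] <- bases
  grid <- as.matrix(do.call(expand.grid, c(cand, list(stringsAsFactors = FALSE))))
  e <- tr$edge
  steps <- integer(nrow(grid))
  for (k in seq_len(nrow(e))) {
    steps <- steps + (grid[, e[k, 1]] != grid[, e[k, 2]])
  }
  min(steps)
}

# Same enumeration, factored for sweeping many tip patterns over one tree:
# returns a function(tip-state character vector in tip.label order) -> steps.
fitch_enum_tree <- function(tree) {
  tr <- tree
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) tr <- ape::multi2di(tr)
  ntip <- length(tr$tip.label)
  bases <- c("A", "C", "G", "T")
  ig <- as.matrix(do.call(expand.grid,
                          c(rep(list(bases), tr$Nnode),
                            list(stringsAsFactors = FALSE))))
  e <- tr$edge
  function(tipstates) {
    full <- cbind(matrix(rep(tipstates, each = nrow(ig)), nrow = nrow(ig)), ig)
    steps <- integer(nrow(ig))
    for (k in seq_len(nrow(e))) {
      steps <- steps + (full[, e[k, 1]] != full[, e[k, 2]])
    }
    min(steps)
  }
}

# Vectorized version of the same enumeration for sweeping every site
# pattern over one tree: pats is a (patterns x tips) character matrix in
# tip.label order; returns the minimum steps per pattern.
fitch_oracle_all_patterns <- function(tree, pats) {
  tr <- tree
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) tr <- ape::multi2di(tr)
  ntip <- length(tr$tip.label)
  bases <- c("A", "C", "G", "T")
  ig <- as.matrix(do.call(expand.grid,
                          c(rep(list(bases), tr$Nnode),
                            list(stringsAsFactors = FALSE))))
  nP <- nrow(pats); nA <- nrow(ig)
  total <- matrix(0L, nP, nA)
  for (k in seq_len(nrow(tr$edge))) {
    u <- tr$edge[k, 1]; v <- tr$edge[k, 2]
    if (v > ntip) {                       # internal-internal edge
      d <- as.integer(ig[, u - ntip] != ig[, v - ntip])
      total <- total + matrix(d, nP, nA, byrow = TRUE)
    } else {                              # tip-internal edge
      total <- total + outer(pats[, v], ig[, u - ntip], "!=")
    }
  }
  as.integer(apply(total, 1L, min))
}

# all-groups-present decisiveness on a presence matrix, by direct loops
decisive_oracle <- function(present, group_of, required, min_per_group = 1L) {
  keep <- character(0)
  for (locus in rownames(present)) {
    ok <- TRUE
    for (g in required) {
      cnt <- 0L
      for (taxon in colnames(present)) {
        if (group_of[[taxon]] == g && present[locus, taxon]) cnt <- cnt + 1L
      }
      if (cnt < min_per_group) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, locus)
  }
  keep
}

# strict > taxon filter by direct counting
filter_taxa_oracle <- function(present, min_loci) {
  keep <- colnames(present)[colSums(present) > min_loci]
  pres <- present[, keep, drop = FALSE]
  list(taxa = keep, loci = rownames(pres)[rowSums(pres) > 0L])
}

# random capture matrix over made-up groups
random_capture_matrix <- function(n_loci, n_taxa, n_groups, p_present = 0.6) {
  loci <- sprintf("L%03d", seq_len(n_loci))
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  groups <- sprintf("G%d", seq_len(n_groups))
  group_of <- setNames(sample(groups, n_taxa, replace = TRUE), taxa)
  present <- matrix(runif(n_loci * n_taxa) < p_present,
                    nrow = n_loci, dimnames = list(loci, taxa))
  df <- data.frame(locus_id = rep(loci, n_taxa),
                   taxon = rep(taxa, each = n_loci),
                   sequence = "ACGT", stringsAsFactors = FALSE)[as.vector(present), ]
  list(present = present, group_of = group_of, groups = groups, df = df)
}
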