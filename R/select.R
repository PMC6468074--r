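## Marker selection: merge capture results from multiple projects into a
## loci x taxa matrix, drop poorly captured taxa, and keep only loci that
## are phylogenetically decisive -- i.e. sampled in every clade group whose
## relationships the analysis addresses.

#' Build a capture matrix from a long table of sequences
#'
#' @param x data frame with columns \code{locus_id}, \code{taxon},
#'   \code{sequence} (one row per captured locus/taxon cell).
#' @param group_of optional named character vector mapping taxon to a
#'   clade-group label; required before decisiveness filtering.
#' @return an object of class \code{capture_matrix}: a list with
#'   \code{cells} (character matrix, loci x taxa, \code{NA} = not
#'   captured) and \code{group_of}.
#' @export
capture_matrix <- function(x, group_of = NULL) {
  stopifnot(is.data.frame(x),
            all(c("locus_id", "taxon", "sequence") %in% names(x)))
  if (any(!nzchar(x$sequence))) stop("empty sequence in capture table")
  loci <- unique(x$locus_id)
  taxa <- unique(x$taxon)
  cells <- matrix(NA_character_, nrow = length(loci), ncol = length(taxa),
                  dimnames = list(loci, taxa))
  cells[cbind(match(x$locus_id, loci), match(x$taxon, taxa))] <- x$sequence
  if (!is.null(group_of)) {
    miss <- setdiff(taxa, names(group_of))
    if (length(miss)) stop("no group label for taxa: ", paste(miss, collapse = ", "))
    group_of <- group_of[taxa]
  }
  structure(list(cells = cells, group_of = group_of),
            class = "capture_matrix")
}

#' @export
print.capture_matrix <- function(x, ...) {
  cat("Capture matrix:", nrow(x$cells), "loci x", ncol(x$cells), "taxa;",
      sum(!is.na(x$cells)), "cells filled\n")
  if (!is.null(x$group_of)) {
    cat("Groups:", paste(sort(unique(x$group_of)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Merge capture results from several projects
#'
#' Takes the union of loci and taxa across projects.  When the same
#' locus/taxon cell is sequenced in more than one project the longer
#' sequence wins (logged); on an exact length tie with differing sequence
#' the earlier project in list order wins, with a warning.
#'
#' @param projects list (optionally named) of data frames with columns
#'   \code{locus_id}, \code{taxon}, \code{sequence}.
#' @param group_of optional taxon-to-group map, stored on the result.
#' @return a [capture_matrix()].
#' @export
merge_projects <- function(projects, group_of = NULL) {
  stopifnot(length(projects) >= 1L)
  all <- do.call(rbind, lapply(seq_along(projects), function(i) {
    p <- projects[[i]]
    p$.project <- i
    p[, c("locus_id", "taxon", "sequence", ".project")]
  }))
  key <- paste(all$locus_id, all$taxon, sep = "\r")
  # longest wins, then earliest project
  o <- order(key, -nchar(all$sequence), all$.project)
  all <- all[o, ]
  dup <- duplicated(key[o])
  if (any(dup)) {
    first <- all[!dup, ]
    clash <- key[o][dup]
    eq <- vapply(which(dup), function(i) {
      j <- match(key[o][i], key[o][!dup])
      nchar(all$sequence[i]) == nchar(first$sequence[j]) &&
        all$sequence[i] != first$sequence[j]
    }, logical(1))
    if (any(eq)) {
      warning("equal-length conflicting duplicates for ",
              sum(eq), " cell(s); kept first project's sequence")
    }
    message("merge: ", sum(dup), " duplicate cell(s) resolved (longest wins)")
  }
  capture_matrix(all[!duplicated(key[o]), c("locus_id", "taxon", "sequence")],
                 group_of = group_of)
}

#' Drop poorly captured taxa from a capture matrix
#'
#' Keeps taxa whose captured-locus count is strictly greater than
#' \code{min_loci} (a taxon at exactly the threshold is dropped); loci left
#' with no taxa are removed.
#'
#' @param m a [capture_matrix()].
#' @param min_loci the locus-count threshold (default 3000, the whole-
#'   pipeline operating point for genome-scale capture sets).
#' @return the filtered \code{capture_matrix}.
#' @export
filter_taxa <- function(m, min_loci = 3000L) {
  stopifnot(inherits(m, "capture_matrix"), min_loci >= 0L)
  counts <- colSums(!is.na(m$cells))
  keep <- counts > min_loci
  if (!any(keep)) stop("all taxa fall at or below the ", min_loci, "-locus cutoff")
  cells <- m$cells[, keep, drop = FALSE]
  cells <- cells[rowSums(!is.na(cells)) > 0L, , drop = FALSE]
  structure(list(cells = cells,
                 group_of = if (is.null(m$group_of)) NULL else
                   m$group_of[colnames(cells)]),
            class = "capture_matrix")
}

#' Select phylogenetically decisive loci
#'
#' A locus is decisive when, for every required clade group, at least
#' \code{min_taxa_per_group} taxa belonging to that group have a sequence
#' at the locus; such loci jointly constrain the relationships among all
#' the groups of interest.
#'
#' @param m a [capture_matrix()] whose taxa all carry group labels.
#' @param required_groups character vector of clade-group labels that must
#'   each be represented.
#' @param min_taxa_per_group minimum representatives per group (default 1).
#' @return character vector of decisive locus ids (possibly empty).
#' @export
decisive_loci <- function(m, required_groups, min_taxa_per_group = 1L) {
  stopifnot(inherits(m, "capture_matrix"), length(required_groups) >= 1L)
  if (is.null(m$group_of) || anyNA(m$group_of)) {
    stop("every taxon needs a group label before decisiveness filtering")
  }
  unknown <- setdiff(required_groups, unique(m$group_of))
  if (length(unknown)) {
    stop("required group(s) not present among taxa: ",
         paste(unknown, collapse = ", "))
  }
  present <- !is.na(m$cells)
  ok <- rep(TRUE, nrow(present))
  for (g in required_groups) {
    in_g <- m$group_of[colnames(present)] == g
    ok <- ok & rowSums(present[, in_g, drop = FALSE]) >= min_taxa_per_group
  }
  rownames(present)[ok]
}
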