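## Seeded synthetic-data generators for every input the pipeline consumes:
## reference exons and per-taxon contigs, read-depth profiles with planted
## high-depth plateaus, hit/annotation tables with planted paralogs, and
## aligned loci with distinct coding and flank mutation rates.  Each
## generator sets the RNG seed from its config, so a fixed seed gives
## byte-identical output.

#' Default clade-group labels used by the generators
#'
#' Eight major ray-finned fish clades typically required for a decisive
#' marker set.
#' @return character vector of length 8.
#' @export
default_groups <- function() {
  c("Acipenseriformes", "Lepisosteiformes", "Elopomorpha",
    "Osteoglossomorpha", "Otomorpha", "Gobiaria", "Ovalentaria",
    "Eupercaria")
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic capture study: exons of
#' 100-600 nt (coding markers in this size class average a few hundred
#' nt), flanks centred around 800 nt, per-site mutation rates of 0.035
#' (coding) and 0.050 (flank) reflecting the typical excess variability
#' of flanking sequence, 10% missingness, and occasional low-complexity
#' regions that pile up reads at 200x background.
#'
#' @param seed integer RNG seed.
#' @param n_loci,n_taxa problem size.
#' @param groups clade-group labels; taxa are assigned round-robin.
#' @param exon_len length-2 vector, uniform exon length range in nt
#'   (rounded to whole codons).
#' @param flank_len length-2 vector: mean and sd of the (truncated
#'   normal) per-side flank length.
#' @param coding_rate,flank_rate per-site substitution probabilities.
#' @param missingness probability a locus/taxon cell is not captured.
#' @param n_decisive if set, exactly this many loci are planted as
#'   phylogenetically decisive and the rest are forced non-decisive.
#' @param paralog_fraction fraction of loci planted with an off-target
#'   best hit in [simulate_paralogs()].
#' @param anomaly list(prob, len, fold): probability a locus carries a
#'   read-depth plateau, its length (bp) and its fold over background.
#' @param depth_mean Poisson mean of the background read depth.
#' @param revcomp_prob probability a contig is planted in reverse
#'   orientation.
#' @param protect_ends codons at each exon end shielded from mutation so
#'   planted exon boundaries stay identifiable in the truth table.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_loci = 50L, n_taxa = 16L,
                       groups = default_groups(),
                       exon_len = c(100L, 600L),
                       flank_len = c(800, 200),
                       coding_rate = 0.035, flank_rate = 0.050,
                       missingness = 0.10, n_decisive = NULL,
                       paralog_fraction = 0,
                       anomaly = list(prob = 0.1, len = 50L, fold = 200),
                       depth_mean = 50, revcomp_prob = 0.25,
                       protect_ends = 1L) {
  stopifnot(n_loci >= 1L, n_taxa >= 1L, length(groups) >= 1L,
            coding_rate >= 0, coding_rate <= 1,
            flank_rate >= 0, flank_rate <= 1,
            missingness >= 0, missingness <= 1,
            paralog_fraction >= 0, paralog_fraction <= 1,
            exon_len[1] >= 3L, exon_len[2] >= exon_len[1])
  if (!is.null(n_decisive)) stopifnot(n_decisive >= 0L, n_decisive <= n_loci)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 n_taxa = as.integer(n_taxa), groups = groups,
                 exon_len = exon_len, flank_len = flank_len,
                 coding_rate = coding_rate, flank_rate = flank_rate,
                 missingness = missingness, n_decisive = n_decisive,
                 paralog_fraction = paralog_fraction, anomaly = anomaly,
                 depth_mean = depth_mean, revcomp_prob = revcomp_prob,
                 protect_ends = as.integer(protect_ends)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# the 61 sense codons
sense_codons <- function() {
  all <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Point-mutate a DNA sequence
#'
#' Each site is substituted independently with probability \code{rate};
#' a substituted base changes to one of the three other bases uniformly.
#'
#' @param sequence DNA string.
#' @param rate per-site substitution probability.
#' @param protect_nt leave this many nt untouched at each end.
#' @return mutated DNA string.
#' @export
mutate_dna <- function(sequence, rate, protect_nt = 0L) {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  if (L == 0L || rate <= 0) return(sequence)
  eligible <- seq_len(L)
  if (protect_nt > 0L && L > 2L * protect_nt) {
    eligible <- (protect_nt + 1L):(L - protect_nt)
  }
  hit <- eligible[runif(length(eligible)) < rate]
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a capture experiment: reference exons, contigs, truth tables
#'
#' Generates a reference exon (whole sense codons, so its translation is
#' stop-free) per locus, a presence/absence pattern over taxa, and one
#' contig per present cell built as left flank + mutated exon + right
#' flank, optionally reverse-complemented.  When \code{cfg$n_decisive} is
#' set, exactly that many loci are planted decisive (every clade group
#' represented) and each remaining locus is stripped of one whole group.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{ref} (data frame: \code{locus_id},
#'   \code{exon_seq}, \code{protein}), \code{contigs} (data frame:
#'   \code{locus_id}, \code{taxon}, \code{contig_id}, \code{sequence}),
#'   \code{group_of} (named vector), and \code{truth} (list with
#'   \code{presence} logical matrix, \code{decisive} locus ids, and
#'   \code{spans}: planted exon span per contig in oriented forward
#'   coordinates, plus \code{strand}).
#' @export
simulate_capture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$n_decisive) && cfg$n_taxa < length(cfg$groups)) {
    stop("need at least one taxon per group to plant decisive loci")
  }
  set.seed(cfg$seed)
  taxa <- sprintf("taxon%02d", seq_len(cfg$n_taxa))
  group_of <- setNames(rep(cfg$groups, length.out = cfg$n_taxa), taxa)

  n_aa <- round(runif(cfg$n_loci, cfg$exon_len[1], cfg$exon_len[2]) / 3)
  starts <- sample.int(5e7, cfg$n_loci)
  loci <- sprintf("Simref.%d.%d.%d", sample.int(25, cfg$n_loci, replace = TRUE),
                  starts, starts + 3L * n_aa - 1L)
  exons <- vapply(n_aa, random_cds, character(1))
  prots <- vapply(exons, function(e) {
    as.character(Biostrings::translate(Biostrings::DNAString(e)))
  }, character(1), USE.NAMES = FALSE)

  presence <- matrix(runif(cfg$n_loci * cfg$n_taxa) >= cfg$missingness,
                     nrow = cfg$n_loci, ncol = cfg$n_taxa,
                     dimnames = list(loci, taxa))
  decisive <- character(0)
  if (!is.null(cfg$n_decisive)) {
    dec_idx <- sort(sample.int(cfg$n_loci, cfg$n_decisive))
    decisive <- loci[dec_idx]
    for (i in seq_len(cfg$n_loci)) {
      if (i %in% dec_idx) {
        for (g in cfg$groups) {          # guarantee one representative
          members <- which(group_of == g)
          if (!any(presence[i, members])) {
            presence[i, members[sample.int(length(members), 1L)]] <- TRUE
          }
        }
      } else {                           # knock out one whole group
        g <- sample(cfg$groups, 1L)
        presence[i, group_of == g] <- FALSE
      }
    }
  }

  rows <- list()
  spans <- list()
  for (i in seq_len(cfg$n_loci)) {
    for (t in which(presence[i, ])) {
      lf <- max(0L, round(rnorm(1, cfg$flank_len[1], cfg$flank_len[2])))
      rf <- max(0L, round(rnorm(1, cfg$flank_len[1], cfg$flank_len[2])))
      exon <- mutate_dna(exons[i], cfg$coding_rate,
                         protect_nt = 3L * cfg$protect_ends)
      fwd <- paste0(if (lf) random_dna(lf) else "", exon,
                    if (rf) random_dna(rf) else "")
      strand <- if (runif(1) < cfg$revcomp_prob) "-" else "+"
      contig <- if (strand == "-") revcomp(fwd) else fwd
      cid <- paste0(loci[i], "_", taxa[t], "_c1")
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci[i], taxon = taxa[t], contig_id = cid,
        sequence = contig, stringsAsFactors = FALSE)
      spans[[length(spans) + 1L]] <- data.frame(
        locus_id = loci[i], taxon = taxa[t], contig_id = cid,
        exon_start = lf, exon_end = lf + nchar(exons[i]),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  list(ref = data.frame(locus_id = loci, exon_seq = exons, protein = prots,
                        stringsAsFactors = FALSE),
       contigs = do.call(rbind, rows),
       group_of = group_of,
       truth = list(presence = presence, decisive = decisive,
                    spans = do.call(rbind, spans)))
}

#' Simulate per-position read-depth profiles with planted plateaus
#'
#' Background depth is Poisson around \code{cfg$depth_mean}; with
#' probability \code{cfg$anomaly$prob} a locus receives a plateau of
#' \code{cfg$anomaly$len} bp at \code{cfg$anomaly$fold} times the
#' background mean (itself Poisson), emulating low-complexity regions
#' that soak up reads.
#'
#' @param cfg a [sim_config()].
#' @param locus_lens named integer vector of locus lengths.
#' @return list with \code{depths} (named list of integer vectors) and
#'   \code{truth} (data frame of planted spans, 0-based half-open:
#'   \code{locus_id}, \code{start}, \code{end}; zero rows if none).
#' @export
simulate_depth <- function(cfg, locus_lens) {
  stopifnot(inherits(cfg, "sim_config"), all(locus_lens > 0))
  set.seed(cfg$seed)
  truth <- list()
  depths <- lapply(names(locus_lens), function(id) {
    L <- locus_lens[[id]]
    d <- rpois(L, cfg$depth_mean)
    if (runif(1) < cfg$anomaly$prob && L > cfg$anomaly$len + 20L) {
      s <- sample.int(L - cfg$anomaly$len - 10L, 1L) + 5L  # 0-based start
      idx <- (s + 1L):(s + cfg$anomaly$len)
      d[idx] <- rpois(length(idx), cfg$anomaly$fold * cfg$depth_mean)
      truth[[length(truth) + 1L]] <<- data.frame(
        locus_id = id, start = s, end = s + cfg$anomaly$len,
        stringsAsFactors = FALSE)
    }
    d
  })
  names(depths) <- names(locus_lens)
  list(depths = depths,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(locus_id = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE))
}

#' Simulate a target-annotation table and hit table with planted paralogs
#'
#' Every locus gets an annotated target interval and an in-target hit; a
#' planted fraction of loci additionally get an off-target best hit (on a
#' different chromosome, outscoring the in-target one), emulating a
#' diverged duplicate that assembles better than the true copy.
#'
#' @param cfg a [sim_config()]; \code{cfg$paralog_fraction} controls the
#'   planted fraction (rounded to a whole count).
#' @return list with \code{targets} (annotation data frame),
#'   \code{hits} (outfmt-6-style data frame as from [read_hits_table()])
#'   and \code{truth} (data frame \code{locus_id}, \code{status}).
#' @export
simulate_paralogs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_loci
  len <- round(runif(n, cfg$exon_len[1], cfg$exon_len[2]))
  chrom <- sample.int(25, n, replace = TRUE)
  start <- sample.int(5e7, n)
  loci <- sprintf("Simref.%d.%d.%d", chrom, start, start + len - 1L)
  targets <- data.frame(locus_id = loci, genome_id = "Simref",
                        chrom = as.character(chrom), start = start,
                        end = start + len - 1L, stringsAsFactors = FALSE)
  n_par <- round(cfg$paralog_fraction * n)
  par_idx <- if (n_par > 0L) sort(sample.int(n, n_par)) else integer(0)

  mk_hit <- function(q, s, lo, hi, bits) {
    data.frame(qseqid = q, sseqid = s, pident = round(runif(1, 85, 100), 2),
               length = hi - lo + 1L, mismatch = 0L, gapopen = 0L,
               qstart = 1L, qend = hi - lo + 1L,
               sstart = lo, send = hi, evalue = 10^-runif(1, 20, 80),
               bitscore = bits, stringsAsFactors = FALSE)
  }
  hits <- list()
  for (i in seq_len(n)) {
    in_bits <- runif(1, 150, 250)
    hits[[length(hits) + 1L]] <- mk_hit(loci[i], as.character(chrom[i]),
                                        start[i], start[i] + len[i] - 1L,
                                        in_bits)
    if (i %in% par_idx) {
      other <- sample(setdiff(1:25, chrom[i]), 1L)
      s2 <- sample.int(5e7, 1L)
      hits[[length(hits) + 1L]] <- mk_hit(loci[i], as.character(other),
                                          s2, s2 + len[i] - 1L,
                                          in_bits + runif(1, 20, 60))
    }
  }
  list(targets = targets,
       hits = do.call(rbind, hits),
       truth = data.frame(locus_id = loci,
                          status = ifelse(seq_len(n) %in% par_idx,
                                          "paralog", "ortholog"),
                          stringsAsFactors = FALSE))
}

#' Simulate coding and flank alignments with distinct mutation rates
#'
#' Per locus, an ancestral coding and flank sequence are drawn and each
#' taxon receives an independently mutated copy (coding at
#' \code{cfg$coding_rate}, flank at \code{cfg$flank_rate}); no indels, so
#' the copies are trivially aligned.
#'
#' @param cfg a [sim_config()].
#' @param flank_each_side flank length per side in nt (default 200, kept
#'   modest so alignment sets stay small).
#' @return list with \code{coding} and \code{flank}: named lists of
#'   alignments (named character vectors over the taxa).
#' @export
simulate_alignments <- function(cfg, flank_each_side = 200L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  taxa <- sprintf("taxon%02d", seq_len(cfg$n_taxa))
  coding <- list(); flank <- list()
  for (i in seq_len(cfg$n_loci)) {
    id <- sprintf("simlocus%03d", i)
    n_aa <- round(runif(1, cfg$exon_len[1], cfg$exon_len[2]) / 3)
    anc_c <- random_cds(n_aa)
    anc_f <- random_dna(2L * flank_each_side)
    coding[[id]] <- setNames(
      vapply(taxa, function(t) mutate_dna(anc_c, cfg$coding_rate), character(1)),
      taxa)
    flank[[id]] <- setNames(
      vapply(taxa, function(t) mutate_dna(anc_f, cfg$flank_rate), character(1)),
      taxa)
  }
  list(coding = coding, flank = flank)
}

#' Evolve a sequence alignment along a tree under Jukes-Cantor
#'
#' The root sequence is uniform random; along each branch every site
#' substitutes with probability \code{3/4 (1 - exp(-4/3 rate b))} for
#' branch length \code{b}, to one of the other three bases uniformly.
#' Useful for building alignments with known homoplasy structure for
#' parsimony-score tests.
#'
#' @param tree \code{phylo} tree with branch lengths.
#' @param n_sites number of sites.
#' @param rate substitutions per site per unit branch length.
#' @param seed optional RNG seed.
#' @return named character vector of tip sequences.
#' @export
evolve_jc <- function(tree, n_sites, rate = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tr$Nnode)
  seqs[[root]] <- sample(BASES, n_sites, replace = TRUE)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    pch <- 0.75 * (1 - exp(-4 / 3 * rate * tr$edge.length[k]))
    s <- seqs[[p]]
    hit <- which(runif(n_sites) < pch)
    for (i in hit) s[i] <- sample(setdiff(BASES, s[i]), 1L)
    seqs[[ch]] <- s
  }
  setNames(vapply(seqs[seq_len(ntip)], paste, character(1), collapse = ""),
           tr$tip.label)
}
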