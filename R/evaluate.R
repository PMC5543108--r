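#' Assembly contiguity statistics
#'
#' N50 is the smallest length L such that scaffolds of length at least L sum
#' to at least half of the total assembly length.
#'
#' @param lengths Numeric vector of scaffold lengths (bp), non-empty.
#' @return A list: \code{n_scaffolds}, \code{total_bp}, \code{n50},
#'   \code{max_len}, \code{min_len}, \code{n_over_1mb},
#'   \code{frac_in_over_1mb}.
#' @export
assemblyStats <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  n50 <- s[which(cumsum(s) >= total / 2)[1]]
  big <- s[s > 1e6]
  list(n_scaffolds = length(s),
       total_bp = total,
       n50 = n50,
       max_len = max(s),
       min_len = min(s),
       n_over_1mb = length(big),
       frac_in_over_1mb = sum(big) / total)
}

#' Truth-based misjoin accounting
#'
#' Scores every scaffold-internal adjacency against simulator ground truth: an
#' adjacency is a misjoin iff its two seeds lie on different truth
#' chromosomes, disagree in relative order/orientation, or sit at a truth
#' distance differing from the claimed \code{gap_after + seed_len} by more
#' than \code{tolerance}. Orientation errors (the two placements implying
#' opposite genome directions) are also reported separately.
#'
#' @param scaffolds A \linkS4class{ScaffoldSet}.
#' @param truth A \linkS4class{SimTruth} (or its seed placements data.frame).
#' @param tolerance Distance tolerance in bp; defaults to the simplification
#'   span tolerance \code{max(50, 0.2 * claimed span)}.
#' @return A list: \code{misjoins}, \code{orientation_errors},
#'   \code{seeds_recovered_frac} (fraction of truth seeds placed in multi-seed
#'   scaffolds), and \code{per_scaffold} breakdown.
#' @export
misjoinReport <- function(scaffolds, truth, tolerance = NULL) {
  stopifnot(methods::is(scaffolds, "ScaffoldSet"))
  pl_truth <- if (methods::is(truth, "SimTruth")) truth@seed_placements else truth
  L <- seedLength(scaffolds)
  tr <- pl_truth
  rownames(tr) <- tr$seed_id
  per <- list()
  total_mis <- 0L
  total_orient <- 0L
  for (sid in names(scaffoldPlacements(scaffolds))) {
    pl <- scaffoldPlacements(scaffolds)[[sid]]
    mis <- 0L; orient_err <- 0L
    if (nrow(pl) > 1L) {
      if (!all(pl$seed_id %in% rownames(tr)))
        stop("scaffold seed absent from truth placements")
      for (j in seq_len(nrow(pl) - 1L)) {
        a <- tr[pl$seed_id[j], ]; b <- tr[pl$seed_id[j + 1L], ]
        g <- pl$gap_after[j]
        bad <- FALSE
        if (a$chrom != b$chrom) {
          bad <- TRUE
        } else {
          da <- if (pl$orient[j] == a$strand) 1L else -1L
          db <- if (pl$orient[j + 1L] == b$strand) 1L else -1L
          if (da != db) {
            bad <- TRUE
            orient_err <- orient_err + 1L
          } else {
            truth_gap <- if (da == 1L) b$start - (a$start + L)
                         else a$start - (b$start + L)
            tol <- if (is.null(tolerance)) max(50, 0.2 * abs(g + L)) else
              tolerance
            if (abs(truth_gap - g) > tol) bad <- TRUE
          }
        }
        if (bad) mis <- mis + 1L
      }
    }
    per[[sid]] <- data.frame(scaffold_id = sid, n_seeds = nrow(pl),
                             misjoins = mis, orientation_errors = orient_err,
                             stringsAsFactors = FALSE)
    total_mis <- total_mis + mis
    total_orient <- total_orient + orient_err
  }
  multi <- unlist(lapply(scaffoldPlacements(scaffolds),
                         function(p) if (nrow(p) > 1L) p$seed_id),
                  use.names = FALSE)
  list(misjoins = total_mis,
       orientation_errors = total_orient,
       seeds_recovered_frac = length(unique(multi)) / nrow(tr),
       per_scaffold = do.call(rbind, unname(per)))
}

#' Compare k-mer spectra between sequence sets
#'
#' Canonical k-mer frequency vectors per input set and pairwise Pearson
#' correlation of their log10(count + 1) values — a light-weight sequence
#' composition similarity measure between assemblies.
#'
#' @param fastas Named list of \code{DNAStringSet} objects (or character
#'   vectors of sequences, or FASTA file paths).
#' @param k K-mer length, at most 8 (dense-vector bound; default 6).
#' @return A list: \code{k}, \code{counts} (matrix, canonical k-mers x sets)
#'   and \code{r} (Pearson correlation matrix).
#' @export
spectrumCompare <- function(fastas, k = 6L) {
  stopifnot(k >= 1L, k <= 8L, length(fastas) >= 1L)
  as_set <- function(x) {
    if (methods::is(x, "DNAStringSet")) x
    else if (is.character(x) && length(x) == 1L && file.exists(x))
      Biostrings::readDNAStringSet(x)
    else Biostrings::DNAStringSet(x)
  }
  sets <- lapply(fastas, as_set)
  if (is.null(names(sets)))
    names(sets) <- paste0("set", seq_along(sets))
  counts <- vapply(sets, function(s) {
    colSums(Biostrings::oligonucleotideFrequency(s, width = k))
  }, numeric(4^k))
  kmers <- rownames(counts)
  canon <- canonical_kmers(kmers)
  cc <- rowsum(counts, canon)
  lg <- log10(cc + 1)
  r <- stats::cor(lg)
  list(k = as.integer(k), counts = cc, r = r)
}

#' Summarize orthologue-completeness counts
#'
#' Post-processes externally produced universal-orthologue counts (complete /
#' fragmented out of a catalogue total) into the conventional percentages
#' (one decimal, half-up); missing is the remainder.
#'
#' @param total Catalogue size (number of genes searched).
#' @param complete Genes recovered complete.
#' @param fragmented Genes recovered fragmented.
#' @return A list: \code{total_genes}, \code{complete}, \code{fragmented},
#'   \code{missing}, \code{pct_complete}, \code{pct_fragmented},
#'   \code{pct_missing}.
#' @export
completenessSummary <- function(total, complete, fragmented) {
  stopifnot(total > 0, complete >= 0, fragmented >= 0,
            complete + fragmented <= total)
  missing <- total - complete - fragmented
  list(total_genes = total,
       complete = complete,
       fragmented = fragmented,
       missing = missing,
       pct_complete = round_half_up(100 * complete / total, 1),
       pct_fragmented = round_half_up(100 * fragmented / total, 1),
       pct_missing = round_half_up(100 * missing / total, 1))
}
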