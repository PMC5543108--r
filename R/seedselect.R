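#' Merge a read pair by exact terminal overlap
#'
#' Overlaps the 3' end of the forward read with the reverse complement of the
#' reverse read at the longest exact-match terminal overlap of at least
#' \code{min_overlap} nt, producing a single merged fragment. Pairs with no
#' qualifying overlap, or containing characters outside \{A,C,G,T,N\}, yield
#' \code{NULL}. Merging is exact-match by default; a mismatch-tolerant mode
#' accepts up to \code{max_mismatch_frac} mismatching positions in the overlap.
#'
#' @param seq1,seq2 Character scalars: the forward and reverse read of the pair
#'   (reverse read in sequencing orientation, i.e. it is reverse-complemented
#'   internally before overlap detection).
#' @param min_overlap Minimum terminal overlap in nt (default 15).
#' @param max_mismatch_frac Maximum fraction of mismatching positions tolerated
#'   inside the overlap (default 0 = exact matching).
#' @return A list with \code{seq} (merged fragment) and \code{overlap_len}, or
#'   \code{NULL} when the pair cannot be merged. The merged length always
#'   equals \code{nchar(seq1) + nchar(seq2) - overlap_len}.
#' @examples
#' mergePair("AAAACCCC", as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAString("CCCCGGGG"))),
#'   min_overlap = 4)
#' @export
mergePair <- function(seq1, seq2, min_overlap = 15L, max_mismatch_frac = 0) {
  stopifnot(min_overlap >= 1L)
  if (!nzchar(seq1) || !nzchar(seq2)) return(NULL)
  if (!is_dna(seq1) || !is_dna(seq2)) return(NULL)
  r2 <- revcomp_chr(seq2)
  n1 <- nchar(seq1); n2 <- nchar(r2)
  for (ov in seq(min(n1, n2), min_overlap)) {
    tail1 <- substring(seq1, n1 - ov + 1L, n1)
    head2 <- substring(r2, 1L, ov)
    if (max_mismatch_frac <= 0) {
      ok <- tail1 == head2
    } else {
      mm <- sum(strsplit(tail1, "")[[1]] != strsplit(head2, "")[[1]])
      ok <- mm <= max_mismatch_frac * ov
    }
    if (ok) {
      merged <- paste0(seq1, substring(r2, ov + 1L, n2))
      return(list(seq = merged, overlap_len = as.integer(ov)))
    }
  }
  NULL
}

#' Count canonical k-mers across fragments
#'
#' Streams the fragment collection in chunks, counting every k-mer window in
#' canonical form (lexicographic minimum of the k-mer and its reverse
#' complement). Windows containing N are skipped. Only the aggregated table is
#' held in memory; if the table grows beyond \code{max_table_entries} distinct
#' k-mers, per-chunk partial counts are spilled to disk and merged
#' partition-wise by k-mer prefix, bounding peak memory.
#'
#' @param fragments Character vector of DNA fragments.
#' @param k K-mer length (default 25).
#' @param chunk_size Fragments per streaming chunk.
#' @param max_table_entries Distinct-k-mer threshold above which the
#'   disk-backed merge is used.
#' @return A \linkS4class{KmerTable}.
#' @export
countKmers <- function(fragments, k = 25L, chunk_size = 10000L,
                       max_table_entries = 5e6) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  if (length(fragments) && all(nchar(fragments) < k))
    warning("k exceeds every fragment length; k-mer table is empty")
  chunks <- split(fragments,
                  ceiling(seq_along(fragments) / max(1L, chunk_size)))
  tab <- data.table::data.table(kmer = character(0), count = integer(0))
  spill_dir <- NULL
  for (ch in chunks) {
    wins <- unlist(lapply(ch, kmer_windows, k = k), use.names = FALSE)
    if (!length(wins)) next
    part <- data.table::data.table(kmer = canonical_kmers(wins))
    part <- part[, list(count = .N), by = "kmer"]
    tab <- data.table::rbindlist(list(tab, part))
    tab <- tab[, list(count = sum(count)), by = "kmer"]
    if (nrow(tab) > max_table_entries) {
      if (is.null(spill_dir)) {
        spill_dir <- tempfile("kmerspill")
        dir.create(spill_dir)
      }
      f <- tempfile("part", tmpdir = spill_dir, fileext = ".tsv")
      data.table::fwrite(tab, f, sep = "\t")
      tab <- data.table::data.table(kmer = character(0), count = integer(0))
    }
  }
  if (!is.null(spill_dir)) {
    f <- tempfile("part", tmpdir = spill_dir, fileext = ".tsv")
    data.table::fwrite(tab, f, sep = "\t")
    # merge spilled partials one nucleotide-prefix partition at a time
    files <- list.files(spill_dir, full.names = TRUE)
    merged <- lapply(c("A", "C", "G", "T"), function(pre) {
      pieces <- lapply(files, function(fn) {
        d <- data.table::fread(fn, colClasses = list(character = "kmer"))
        d[startsWith(d$kmer, pre)]
      })
      p <- data.table::rbindlist(pieces)
      if (nrow(p)) p[, list(count = sum(count)), by = "kmer"] else p
    })
    tab <- data.table::rbindlist(merged)
    unlink(spill_dir, recursive = TRUE)
  }
  data.table::setorder(tab, kmer)
  methods::new("KmerTable", k = k, counts = tab[])
}

#' Filter fragments whose k-mers are all sufficiently rare
#'
#' Retains exactly the fragments in which every k-mer window has abundance at
#' most \code{max_count} in the supplied table (the bound is inclusive: a
#' k-mer occurring exactly \code{max_count} times does not disqualify its
#' fragment). Fragments shorter than k, or containing N, are excluded from
#' candidacy.
#'
#' @param fragments Character vector of DNA fragments.
#' @param table A \linkS4class{KmerTable} built over the same (or a superset)
#'   collection.
#' @param max_count Maximum tolerated k-mer abundance (default 25).
#' @return The retained subset of \code{fragments}.
#' @export
filterUnique <- function(fragments, table, max_count = 25L) {
  stopifnot(methods::is(table, "KmerTable"))
  k <- table@k
  ct <- table@counts
  bad <- ct$kmer[ct$count > max_count]
  keep <- vapply(fragments, function(f) {
    if (nchar(f) < k || grepl("N", f, fixed = TRUE)) return(FALSE)
    wins <- canonical_kmers(kmer_windows(f, k))
    !any(data.table::`%chin%`(wins, bad))
  }, logical(1), USE.NAMES = FALSE)
  fragments[keep]
}

#' Select seed fragments by exact length
#'
#' Keeps fragments of exactly \code{seed_len} nt and assigns stable sequential
#' identifiers \code{seed_1, seed_2, ...} in input order.
#'
#' @param fragments Character vector of candidate fragments.
#' @param seed_len Required seed length in nt (270 or 285 in typical use).
#' @return A \linkS4class{SeedSet}.
#' @export
selectByLength <- function(fragments, seed_len) {
  stopifnot(seed_len > 0)
  sel <- fragments[nchar(fragments) == seed_len]
  if (!length(sel))
    stop("no fragments of length ", seed_len,
         " nt; consider a different seed_len")
  seeds <- Biostrings::DNAStringSet(sel)
  names(seeds) <- paste0("seed_", seq_along(sel))
  methods::new("SeedSet", seeds = seeds, seedLen = as.integer(seed_len))
}

#' Analytic seed-density statistics
#'
#' For a seed set of \code{n_seeds} seeds of \code{seed_len} nt on a genome of
#' \code{genome_size} bp, computes the seed fold-coverage, mean seed spacing
#' and mean inter-seed gap, and the minimum and typical long-read lengths able
#' to link two seeds. The minimum assumes two seeds overlapping by at most
#' \code{max_overlap_frac} of one seed length
#' (\code{ceil(2*seed_len - max_overlap_frac*seed_len)}); the typical length
#' is one mean spacing plus one seed length, rounded half-up.
#'
#' @param n_seeds Number of seeds.
#' @param seed_len Seed length (nt).
#' @param genome_size Genome size (bp).
#' @param max_overlap_frac Maximum tolerated seed overlap as a fraction of
#'   seed length (default 0.10).
#' @return A list with \code{n_seeds}, \code{seed_len}, \code{genome_size},
#'   \code{fold_coverage}, \code{mean_spacing}, \code{mean_gap},
#'   \code{min_link_len}, \code{typical_link_len}. Coverages are unrounded;
#'   \code{mean_gap}, \code{min_link_len} and \code{typical_link_len} are
#'   integers per the conventions above.
#' @examples
#' seedStats(873058, 285, 860e6, 0.10)$min_link_len  # 542
#' @export
seedStats <- function(n_seeds, seed_len, genome_size, max_overlap_frac = 0.10) {
  stopifnot(n_seeds > 0, seed_len > 0, genome_size > 0,
            max_overlap_frac >= 0, max_overlap_frac < 1)
  spacing <- genome_size / n_seeds
  list(
    n_seeds = n_seeds,
    seed_len = seed_len,
    genome_size = genome_size,
    fold_coverage = n_seeds * seed_len / genome_size,
    mean_spacing = spacing,
    mean_gap = round_half_up(spacing - seed_len),
    min_link_len = ceiling(2 * seed_len - max_overlap_frac * seed_len),
    typical_link_len = round_half_up(spacing + seed_len)
  )
}

#' Genomic occurrence implied by a k-mer abundance cap
#'
#' Translates an abundance cap applied to k-mer counts in read data into the
#' maximum genomic copy number it tolerates: the cap divided by the read-data
#' coverage of the genome, where coverage = merged data volume / genome size,
#' rounded to the nearest integer.
#'
#' @param max_count The k-mer abundance cap.
#' @param data_bp Total read data volume in bp.
#' @param merged_fraction Fraction of the data volume in merged fragments.
#' @param genome_size Genome size in bp.
#' @return The implied maximum fold occurrence (numeric).
#' @examples
#' occurrenceCapEstimate(25, 11.9e9, 0.2916, 860e6)  # 6.25
#' @export
occurrenceCapEstimate <- function(max_count, data_bp, merged_fraction,
                                  genome_size) {
  stopifnot(max_count > 0, data_bp > 0, merged_fraction > 0, genome_size > 0)
  cov <- round_half_up(data_bp * merged_fraction / genome_size)
  if (cov == 0)
    stop("merged data volume rounds to zero-fold genome coverage")
  max_count / cov
}

#' Select seeds from paired short reads
#'
#' End-to-end seed selection: merge pairs by terminal overlap, count canonical
#' k-mers in the merged fragments, drop fragments containing any k-mer more
#' abundant than \code{max_count}, and keep fragments of exactly
#' \code{seed_len} nt.
#'
#' @param r1,r2 Character vectors of forward/reverse read sequences (equal
#'   length), or \code{r2 = NULL} with \code{r1} already-merged fragments.
#' @param k K-mer length (default 25).
#' @param max_count K-mer abundance cap (default 25).
#' @param seed_len Seed length to select (default 285).
#' @param min_overlap Minimum pair overlap in nt (default 15).
#' @return A list with the \code{SeedSet} (\code{seeds}), the merged fragments
#'   (\code{fragments}), the \code{KmerTable} (\code{table}) and the merged
#'   fraction of pairs (\code{merged_fraction}).
#' @export
selectSeeds <- function(r1, r2 = NULL, k = 25L, max_count = 25L,
                        seed_len = 285L, min_overlap = 15L) {
  if (is.null(r2)) {
    frags <- r1
    merged_fraction <- NA_real_
  } else {
    stopifnot(length(r1) == length(r2))
    merged <- mapply(function(a, b) mergePair(a, b, min_overlap),
                     r1, r2, SIMPLIFY = FALSE)
    frags <- vapply(merged[!vapply(merged, is.null, logical(1))],
                    `[[`, character(1), "seq")
    merged_fraction <- length(frags) / length(r1)
  }
  tab <- countKmers(frags, k = k)
  kept <- filterUnique(frags, tab, max_count = max_count)
  list(seeds = selectByLength(kept, seed_len),
       fragments = frags, table = tab, merged_fraction = merged_fraction)
}
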