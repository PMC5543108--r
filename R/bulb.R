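# Supporting-read evidence for each adjacency of a scaffold, recomputed from
# the read chains: a read supports placement i -> i+1 if it carries hits on
# both seeds with consistent orientation (parallel or antiparallel to the
# scaffold). All within-read hit pairs qualify, not only consecutive ones —
# the read-space distance between the two seed-alignment ends is the same
# physical gap either way, and long-range joined adjacencies may only be
# supported across intervening hits. Returns, per adjacency, a data.frame of
# read_id, observed gap, and the donor patch coordinates on the read.
adjacency_support <- function(pl, chains) {
  h <- chainHits(chains)
  h <- h[order(h$read_id, h$read_start), , drop = FALSE]
  n <- nrow(pl)
  if (n < 2L) return(list())
  by_read <- split(seq_len(nrow(h)), h$read_id)
  pair_key <- function(a, oa, b, ob) paste(a, oa, b, ob, sep = "\t")
  ii <- integer(0); jj <- integer(0)
  for (rows in by_read) {
    m <- length(rows)
    if (m < 2L) next
    pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    ii <- c(ii, rows[pr[, 1]])
    jj <- c(jj, rows[pr[, 2]])
  }
  seen <- pair_key(h$seed_id[ii], h$strand[ii], h$seed_id[jj], h$strand[jj])
  mir <- pair_key(h$seed_id[jj], flip_orient(h$strand[jj]),
                  h$seed_id[ii], flip_orient(h$strand[ii]))
  support <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    want <- pair_key(pl$seed_id[j], pl$orient[j],
                     pl$seed_id[j + 1L], pl$orient[j + 1L])
    fwd <- which(seen == want)  # read traverses the pair in scaffold order
    rev <- which(mir == want)   # read traverses antiparallel
    rows <- list()
    if (length(fwd))
      rows$fwd <- data.frame(read_id = h$read_id[ii[fwd]],
                             gap = h$read_start[jj[fwd]] - h$read_end[ii[fwd]],
                             patch_start = h$read_end[ii[fwd]],
                             patch_end = h$read_start[jj[fwd]],
                             antiparallel = FALSE, stringsAsFactors = FALSE)
    if (length(rev))
      rows$rev <- data.frame(read_id = h$read_id[ii[rev]],
                             gap = h$read_start[jj[rev]] - h$read_end[ii[rev]],
                             patch_start = h$read_end[ii[rev]],
                             patch_end = h$read_start[jj[rev]],
                             antiparallel = TRUE, stringsAsFactors = FALSE)
    support[[j]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(0), gap = numeric(0),
                 patch_start = integer(0), patch_end = integer(0),
                 antiparallel = logical(0), stringsAsFactors = FALSE)
    rownames(support[[j]]) <- NULL
  }
  support
}

#' Lay out uncorrected scaffold sequence
#'
#' Attaches sequence to scaffold models: seed sequences (reverse-complemented
#' per placement orientation) joined by read-derived patches. For each
#' positive gap, the patch is excised from the supporting read whose observed
#' gap is closest to the link's mean gap (ties broken by lexicographically
#' smallest read id), between the read's two seed-alignment ends, and
#' reverse-complemented when the donor read runs antiparallel to the scaffold.
#' For negative gaps the downstream seed is trimmed by the overlap and no
#' patch is inserted. Per-base provenance is tracked as runs attributing every
#' scaffold base to a seed or a donor read.
#'
#' @param scaffolds A \linkS4class{ScaffoldSet}.
#' @param seeds The \linkS4class{SeedSet} (must cover every placed seed).
#' @param reads Named character vector (or \code{DNAStringSet}) of the long
#'   reads.
#' @param chains The \linkS4class{ReadChainSet} supporting the scaffolds.
#' @return A list: \code{sequences} (named \code{DNAStringSet}) and
#'   \code{provenance} (data.frame scaffold_id, start, end, source; 0-based
#'   half-open scaffold coordinates).
#' @export
fillGaps <- function(scaffolds, seeds, reads, chains) {
  stopifnot(methods::is(scaffolds, "ScaffoldSet"),
            methods::is(seeds, "SeedSet"))
  if (methods::is(reads, "DNAStringSet")) {
    rn <- names(reads)
    reads <- as.character(reads)
    names(reads) <- rn
  }
  L <- seedLength(seeds)
  sseq <- as.character(seedSequences(seeds))
  out_seqs <- character(0)
  prov <- list()
  for (sid in names(scaffoldPlacements(scaffolds))) {
    pl <- scaffoldPlacements(scaffolds)[[sid]]
    sup <- adjacency_support(pl, chains)
    parts <- character(0)
    runs <- list()
    pos <- 0L
    trim_next <- 0L
    for (j in seq_len(nrow(pl))) {
      s <- sseq[[pl$seed_id[j]]]
      if (is.null(s)) stop("seed missing from SeedSet: ", pl$seed_id[j])
      if (pl$orient[j] == "-") s <- revcomp_chr(s)
      if (trim_next > 0L) s <- substring(s, trim_next + 1L)
      parts <- c(parts, s)
      runs[[length(runs) + 1L]] <-
        data.frame(scaffold_id = sid, start = pos, end = pos + nchar(s),
                   source = pl$seed_id[j], stringsAsFactors = FALSE)
      pos <- pos + nchar(s)
      trim_next <- 0L
      if (j < nrow(pl)) {
        g <- pl$gap_after[j]
        if (g < 0) {
          trim_next <- as.integer(-g)
        } else if (g > 0) {
          d <- sup[[j]]
          d <- d[d$gap > 0, , drop = FALSE]
          if (!nrow(d))
            stop("no supporting read available for gap after ",
                 pl$seed_id[j], " in ", sid)
          mean_gap <- mean(sup[[j]]$gap)
          d <- d[order(abs(d$gap - mean_gap), d$read_id), , drop = FALSE]
          donor <- d[1L, ]
          if (!donor$read_id %in% names(reads))
            stop("supporting read not found in read store: ", donor$read_id)
          rseq <- reads[[donor$read_id]]
          patch <- substring(rseq, donor$patch_start + 1L, donor$patch_end)
          if (donor$antiparallel) patch <- revcomp_chr(patch)
          parts <- c(parts, patch)
          runs[[length(runs) + 1L]] <-
            data.frame(scaffold_id = sid, start = pos,
                       end = pos + nchar(patch),
                       source = donor$read_id, stringsAsFactors = FALSE)
          pos <- pos + nchar(patch)
        }
      }
    }
    out_seqs[[sid]] <- paste(parts, collapse = "")
    prov[[sid]] <- do.call(rbind, runs)
  }
  sequences <- Biostrings::DNAStringSet(out_seqs)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  list(sequences = sequences, provenance = provenance)
}

#' Per-scaffold read bundles for each scaffold's retained links
#'
#' A read belongs to a scaffold's bundle iff it supports at least one adjacency
#' of that scaffold; bundles contain no duplicates. A read supporting links in
#' two scaffolds appears in both bundles.
#'
#' @param scaffolds A \linkS4class{ScaffoldSet}.
#' @param chains The supporting \linkS4class{ReadChainSet}.
#' @return Named list: per scaffold, the character vector of read ids.
#' @export
scaffoldBundles <- function(scaffolds, chains) {
  lapply(scaffoldPlacements(scaffolds), function(pl) {
    sup <- adjacency_support(pl, chains)
    sort(unique(unlist(lapply(sup, function(d) d$read_id),
                       use.names = FALSE)))
  })
}

#' Export uncorrected scaffolds and read bundles
#'
#' In \code{"per-scaffold"} mode, writes for every scaffold a pair of FASTA
#' files, \code{<id>.scaffold.fa} (the uncorrected sequence) and
#' \code{<id>.bundle.fa} (all long reads supporting its links), ready for
#' external consensus polishing. In \code{"combined"} mode, writes a single
#' \code{scaffolds.fa} with all scaffold sequences. FASTA is wrapped at 80
#' columns.
#'
#' @param scaffolds A \linkS4class{ScaffoldSet}.
#' @param chains The supporting \linkS4class{ReadChainSet}.
#' @param reads Named character vector or \code{DNAStringSet} of long reads.
#' @param sequences The filled sequences from \code{\link{fillGaps}} (a named
#'   \code{DNAStringSet}).
#' @param dir Output directory (created if needed).
#' @param mode "per-scaffold" or "combined".
#' @return Character vector of the files written, invisibly.
#' @export
exportBundles <- function(scaffolds, chains, reads, sequences, dir,
                          mode = c("per-scaffold", "combined")) {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (methods::is(reads, "DNAStringSet")) {
    rn <- names(reads)
    reads <- as.character(reads)
    names(reads) <- rn
  }
  written <- character(0)
  if (mode == "combined") {
    f <- file.path(dir, "scaffolds.fa")
    Biostrings::writeXStringSet(sequences, f, width = 80L)
    written <- f
  } else {
    bundles <- scaffoldBundles(scaffolds, chains)
    for (sid in names(scaffoldPlacements(scaffolds))) {
      fs <- file.path(dir, paste0(sid, ".scaffold.fa"))
      Biostrings::writeXStringSet(sequences[sid], fs, width = 80L)
      fb <- file.path(dir, paste0(sid, ".bundle.fa"))
      b <- bundles[[sid]]
      missing <- setdiff(b, names(reads))
      if (length(missing))
        stop("bundle reads missing from read store: ",
             paste(missing, collapse = ", "))
      bs <- Biostrings::DNAStringSet(reads[b])
      Biostrings::writeXStringSet(bs, fb, width = 80L)
      written <- c(written, fs, fb)
    }
  }
  invisible(written)
}

#' Write per-base provenance as BED
#'
#' Scaffold-relative provenance runs (0-based half-open) from
#' \code{\link{fillGaps}}, as a 4-column BED.
#'
#' @param provenance The provenance data.frame from \code{\link{fillGaps}}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeProvenanceBed <- function(provenance, file) {
  utils::write.table(provenance[, c("scaffold_id", "start", "end", "source")],
                     file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
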