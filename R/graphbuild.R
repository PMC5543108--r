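#' Read long-read-to-seed alignments from SAM/BAM into per-read chains
#'
#' Consumes alignments of long reads (queries) against seed sequences
#' (references), applying the standard filters: unmapped, secondary and
#' supplementary records are dropped; records with seed coverage below
#' \code{min_seed_cov} or mapping quality below \code{min_mapq} are dropped;
#' if a read hits the same seed more than once only the best hit (highest seed
#' coverage, then mapq) is kept. Hits are reported in 0-based half-open
#' coordinates on the original read (reverse-strand records are mapped back
#' through the flip) and sorted by position along each read.
#'
#' The seeds-as-reference dialect is required: every \code{@SQ} length in the
#' header must equal the seed length (and, when \code{seeds} is given, every
#' reference name must be a seed id). Input with reads as references is
#' rejected.
#'
#' @param file Path to a SAM or BAM file with a header.
#' @param seeds A \linkS4class{SeedSet}, or \code{NULL} to derive the seed
#'   length from the header.
#' @param seed_len Seed length in nt; required if \code{seeds} is \code{NULL}.
#' @param min_seed_cov Minimum aligned fraction of the seed (default 0.8).
#' @param min_mapq Minimum mapping quality (default 1).
#' @return A \linkS4class{ReadChainSet}.
#' @export
readSeedAlignments <- function(file, seeds = NULL, seed_len = NULL,
                               min_seed_cov = 0.8, min_mapq = 1L) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  is_bam <- grepl("\\.bam$", file, ignore.case = TRUE)
  bam <- if (is_bam) file else {
    dest <- tempfile(fileext = "")
    tryCatch(Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                              indexDestination = FALSE),
             error = function(e) stop("cannot parse SAM (missing header?): ",
                                      conditionMessage(e)))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!length(hdr)) stop("SAM/BAM header has no @SQ reference entries")
  if (is.null(seed_len)) {
    if (!is.null(seeds)) seed_len <- seedLength(seeds)
    else seed_len <- as.integer(unique(hdr))
  }
  if (length(unique(hdr)) != 1L || unique(hdr) != seed_len)
    stop("reference sequences are not uniform-length seeds of ", seed_len,
         " nt; input must use seeds as references (reads-as-reference SAM ",
         "is not supported)")
  if (!is.null(seeds) && !all(names(hdr) %in% names(seedSequences(seeds))))
    stop("SAM references are not all known seed ids")

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(rec$qname))
    return(methods::new("ReadChainSet",
                        hits = empty_chain_df()))
  flag <- rec$flag
  keep <- bitwAnd(flag, 0x4L) == 0L &      # mapped
          bitwAnd(flag, 0x100L) == 0L &    # primary
          bitwAnd(flag, 0x800L) == 0L      # non-supplementary
  cig <- rec$cigar[keep]
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  clip_left <- mapply(function(o, l) {
    i <- which(!o %in% c("H", "S"))
    if (!length(i)) sum(l) else sum(l[seq_len(i[1] - 1L)])
  }, ops, lens)
  clip_right <- mapply(function(o, l) {
    i <- which(!o %in% c("H", "S"))
    if (!length(i)) 0L else sum(l[seq(i[length(i)] + 1L, length.out = length(l) - i[length(i)])])
  }, ops, lens)
  qalen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  ralen <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  hard <- mapply(function(o, l) sum(l[o == "H"]), ops, lens)
  read_len <- nchar(as.character(rec$seq[keep])) + hard
  rev <- bitwAnd(flag[keep], 0x10L) != 0L
  read_start <- ifelse(rev, read_len - clip_left - qalen, clip_left)
  read_end <- read_start + qalen
  hits <- data.frame(
    read_id = rec$qname[keep],
    read_len = as.integer(read_len),
    seed_id = as.character(rec$rname[keep]),
    read_start = as.integer(read_start),
    read_end = as.integer(read_end),
    strand = ifelse(rev, "-", "+"),
    seed_cov = ralen / seed_len,
    mapq = rec$mapq[keep],
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$seed_id)) stop("record with unknown reference name")
  hits <- hits[hits$seed_cov >= min_seed_cov & hits$mapq >= min_mapq, ,
               drop = FALSE]
  # best hit per (read, seed): highest coverage, then mapq, then leftmost
  o <- order(hits$read_id, hits$seed_id, -hits$seed_cov, -hits$mapq,
             hits$read_start)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("read_id", "seed_id")]), , drop = FALSE]
  hits <- hits[order(hits$read_id, hits$read_start), , drop = FALSE]
  rownames(hits) <- NULL
  methods::new("ReadChainSet", hits = hits)
}

empty_chain_df <- function() {
  data.frame(read_id = character(0), read_len = integer(0),
             seed_id = character(0), read_start = integer(0),
             read_end = integer(0), strand = character(0),
             seed_cov = numeric(0), mapq = integer(0),
             stringsAsFactors = FALSE)
}

# Directed-link key strings, used for canonical ordering and mirror pairing.
link_key <- function(from, from_o, to, to_o) {
  paste(from, from_o, to, to_o, sep = "\t")
}

mirror_key <- function(from, from_o, to, to_o) {
  link_key(to, flip_orient(to_o), from, flip_orient(from_o))
}

# TRUE for rows that are the canonical representative of their mirror pair
# (key <= mirror key; a self-mirror link counts once and is always canonical).
is_canonical_link <- function(links) {
  k <- link_key(links$from, links$from_o, links$to, links$to_o)
  m <- mirror_key(links$from, links$from_o, links$to, links$to_o)
  k <= m
}

empty_link_df <- function(reason = FALSE) {
  d <- data.frame(from = character(0), from_o = character(0),
                  to = character(0), to_o = character(0),
                  evidence = integer(0), stringsAsFactors = FALSE)
  d$gap_obs <- list()
  d$reads <- list()
  if (reason) d$reason <- character(0)
  d
}

#' Build the bidirected seed graph from read chains
#'
#' For every pair of consecutive seed hits along a read, records a link between
#' the correspondingly oriented seeds with the apparent gap (start of the
#' second hit minus end of the first, on the read; negative when the seeds
#' overlap on the read). Pairs overlapping by more than
#' \code{max_overlap_frac} of a seed length are skipped and counted. Every link
#' is stored with its reverse-complement mirror; gap observations and
#' supporting read ids accumulate across reads and evidence counts supporting
#' reads. The construction is order-independent: links and their observations
#' are canonically sorted.
#'
#' @param chains A \linkS4class{ReadChainSet}.
#' @param seed_len Seed length in nt.
#' @param max_overlap_frac Maximum tolerated seed overlap on the read, as a
#'   fraction of seed length (default 0.10).
#' @return A \linkS4class{SeedGraph}.
#' @export
buildSeedGraph <- function(chains, seed_len, max_overlap_frac = 0.10) {
  stopifnot(methods::is(chains, "ReadChainSet"))
  h <- chainHits(chains)
  seed_len <- as.integer(seed_len)
  if (!nrow(h)) {
    return(methods::new("SeedGraph", links = empty_link_df(),
                        removed = empty_link_df(reason = TRUE),
                        seedLen = seed_len, skipped = 0L))
  }
  h <- h[order(h$read_id, h$read_start), , drop = FALSE]
  same_read <- h$read_id[-nrow(h)] == h$read_id[-1L]
  i <- which(same_read)
  if (!length(i)) {
    return(methods::new("SeedGraph", links = empty_link_df(),
                        removed = empty_link_df(reason = TRUE),
                        seedLen = seed_len, skipped = 0L))
  }
  gap <- h$read_start[i + 1L] - h$read_end[i]
  ok <- gap >= -max_overlap_frac * seed_len
  skipped <- sum(!ok)
  i <- i[ok]; gap <- gap[ok]
  if (!length(i)) {
    return(methods::new("SeedGraph", links = empty_link_df(),
                        removed = empty_link_df(reason = TRUE),
                        seedLen = seed_len, skipped = as.integer(skipped)))
  }
  fwd <- data.frame(from = h$seed_id[i], from_o = h$strand[i],
                    to = h$seed_id[i + 1L], to_o = h$strand[i + 1L],
                    gap = gap, read = h$read_id[i],
                    stringsAsFactors = FALSE)
  rev <- data.frame(from = fwd$to, from_o = flip_orient(fwd$to_o),
                    to = fwd$from, to_o = flip_orient(fwd$from_o),
                    gap = fwd$gap, read = fwd$read,
                    stringsAsFactors = FALSE)
  obs <- rbind(fwd, rev)
  obs <- obs[order(obs$from, obs$from_o, obs$to, obs$to_o, obs$read, obs$gap), ,
             drop = FALSE]
  key <- link_key(obs$from, obs$from_o, obs$to, obs$to_o)
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  links <- data.frame(from = obs$from[first], from_o = obs$from_o[first],
                      to = obs$to[first], to_o = obs$to_o[first],
                      evidence = as.integer(tabulate(grp)),
                      stringsAsFactors = FALSE)
  links$gap_obs <- split(obs$gap, grp)
  links$reads <- split(obs$read, grp)
  rownames(links) <- NULL
  methods::new("SeedGraph", links = links,
               removed = empty_link_df(reason = TRUE),
               seedLen = seed_len, skipped = as.integer(skipped))
}

#' Evidence and distance distributions of a seed graph
#'
#' Summarizes the graph's links (each bidirected link counted once) as a
#' histogram of link evidence and a histogram of mean link distance (gap mean
#' rounded half-up to the nearest bp), for inspection or TSV export.
#'
#' @param graph A \linkS4class{SeedGraph}.
#' @return A list of two data.frames: \code{evidence} (\code{evidence},
#'   \code{n}) and \code{distance} (\code{distance}, \code{n}).
#' @export
graphReport <- function(graph) {
  stopifnot(methods::is(graph, "SeedGraph"))
  l <- graphLinks(graph)
  l <- l[is_canonical_link(l), , drop = FALSE]
  if (!nrow(l)) {
    return(list(
      evidence = data.frame(evidence = integer(0), n = integer(0)),
      distance = data.frame(distance = numeric(0), n = integer(0))))
  }
  ev <- table(l$evidence)
  md <- round_half_up(vapply(l$gap_obs, mean, numeric(1)))
  dt <- table(md)
  list(
    evidence = data.frame(evidence = as.integer(names(ev)),
                          n = as.integer(ev)),
    distance = data.frame(distance = as.numeric(names(dt)),
                          n = as.integer(dt))
  )
}
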