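#' @import methods
NULL

#' SeedSet: a sparse seed reference
#'
#' Fixed-length, genome-unique short sequences used as nodes of the seed graph
#' and as the sparse alignment reference for long reads. Seeds are stored as a
#' named \link[Biostrings]{DNAStringSet}; all sequences have length
#' \code{seedLen} and unique identifiers.
#'
#' @slot seeds A \code{DNAStringSet}, names are seed identifiers.
#' @slot seedLen Integer seed length in nt (typically 270 or 285).
#' @export
setClass("SeedSet", representation(seeds = "ANY", seedLen = "integer"))

setValidity("SeedSet", function(object) {
  s <- object@seeds
  if (!methods::is(s, "DNAStringSet"))
    return("'seeds' must be a DNAStringSet")
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      return("seed identifiers must be present and unique")
    if (!all(Biostrings::width(s) == object@seedLen))
      return("all seed sequences must have length 'seedLen'")
  }
  TRUE
})

#' KmerTable: canonical k-mer abundance table
#'
#' Counts of canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) over a fragment collection. Windows containing N are
#' skipped.
#'
#' @slot k Integer k-mer length.
#' @slot counts A \code{data.table} with columns \code{kmer} (character,
#'   canonical) and \code{count} (integer).
#' @export
setClass("KmerTable", representation(k = "integer", counts = "ANY"))

setValidity("KmerTable", function(object) {
  ct <- object@counts
  if (!is.data.frame(ct) || !all(c("kmer", "count") %in% names(ct)))
    return("'counts' must have columns kmer and count")
  if (nrow(ct) && !all(nchar(ct$kmer) == object@k))
    return("all k-mers must have length k")
  if (nrow(ct) && any(ct$count < 0))
    return("counts must be non-negative")
  TRUE
})

#' ReadChainSet: per-read chains of seed alignments
#'
#' Filtered long-read-to-seed alignments, grouped by read and sorted by
#' position on the read. One row per retained hit.
#'
#' @slot hits A \code{data.frame} with columns \code{read_id}, \code{read_len},
#'   \code{seed_id}, \code{read_start}, \code{read_end} (0-based half-open read
#'   coordinates), \code{strand} ("+" or "-", orientation of the seed relative
#'   to the read), \code{seed_cov} (fraction of the seed aligned), \code{mapq}.
#'   Rows are ordered by \code{read_id} then \code{read_start}.
#' @export
setClass("ReadChainSet", representation(hits = "data.frame"))

.chain_cols <- c("read_id", "read_len", "seed_id", "read_start", "read_end",
                 "strand", "seed_cov", "mapq")

setValidity("ReadChainSet", function(object) {
  h <- object@hits
  if (!all(.chain_cols %in% names(h)))
    return(paste("hits must have columns:", paste(.chain_cols, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$read_start >= h$read_end))
      return("read_start must be < read_end")
    if (!all(h$strand %in% c("+", "-")))
      return("strand must be '+' or '-'")
  }
  TRUE
})

#' SeedGraph: bidirected graph over oriented seeds
#'
#' Nodes are oriented seeds; a link between oriented seeds records that the two
#' seeds co-align adjacently to at least one long read, with the apparent
#' inter-seed gap (signed; negative = overlap) and the supporting read ids.
#' Every link is stored together with its reverse-complement mirror: link
#' (A,o1)->(B,o2) exists iff (B,!o2)->(A,!o1) exists with identical gap
#' observations. Removed links are retained for audit with their reason.
#'
#' @slot links A \code{data.frame} with columns \code{from}, \code{from_o},
#'   \code{to}, \code{to_o}, \code{evidence}, and list-columns \code{gap_obs}
#'   (signed bp per supporting read) and \code{reads} (read ids).
#' @slot removed Same shape as \code{links} plus a \code{reason} column.
#' @slot seedLen Integer seed length (nt), used for span arithmetic.
#' @slot skipped Integer count of adjacent hit pairs rejected by the overlap
#'   cap during construction.
#' @export
setClass("SeedGraph", representation(links = "data.frame",
                                     removed = "data.frame",
                                     seedLen = "integer",
                                     skipped = "integer"))

.link_cols <- c("from", "from_o", "to", "to_o", "evidence")

setValidity("SeedGraph", function(object) {
  for (nm in c("links", "removed")) {
    l <- methods::slot(object, nm)
    if (!all(.link_cols %in% names(l)))
      return(paste(nm, "must have columns:", paste(.link_cols, collapse = ", ")))
    if (!all(c("gap_obs", "reads") %in% names(l)))
      return(paste(nm, "must have list-columns gap_obs and reads"))
  }
  if (nrow(object@removed) && !"reason" %in% names(object@removed))
    return("removed links must carry a reason")
  l <- object@links
  if (nrow(l)) {
    ev_ok <- vapply(seq_len(nrow(l)), function(i) {
      length(l$gap_obs[[i]]) == l$evidence[i] &&
        length(l$reads[[i]]) == l$evidence[i]
    }, logical(1))
    if (!all(ev_ok))
      return("evidence must equal length(gap_obs) and length(reads)")
  }
  TRUE
})

#' ScaffoldSet: ordered, oriented seed placements
#'
#' Linear scaffold models: each scaffold is an ordered list of oriented seed
#' placements with the mean inter-seed gap after each seed (possibly negative,
#' never beyond a full seed overlap). No seed appears in more than one
#' scaffold.
#'
#' @slot scaffolds Named list; each element is a \code{data.frame} with columns
#'   \code{seed_id}, \code{orient} ("+"/"-") and \code{gap_after} (signed bp;
#'   \code{NA} for the last placement).
#' @slot seedLen Integer seed length (nt).
#' @export
setClass("ScaffoldSet", representation(scaffolds = "list", seedLen = "integer"))

setValidity("ScaffoldSet", function(object) {
  ids <- unlist(lapply(object@scaffolds, function(s) s$seed_id), use.names = FALSE)
  if (anyDuplicated(ids))
    return("a seed may appear in at most one scaffold")
  for (s in object@scaffolds) {
    if (!all(c("seed_id", "orient", "gap_after") %in% names(s)))
      return("placements need seed_id, orient, gap_after")
    g <- s$gap_after[-nrow(s)]
    if (length(g) && any(is.na(g)))
      return("only the last placement may have NA gap_after")
    if (any(!is.na(s$gap_after) & s$gap_after < -object@seedLen))
      return("gap_after must be >= -seedLen")
  }
  TRUE
})

#' SimTruth: ground truth from the simulator
#'
#' Seed placements on the simulated genome, read origins, and the true seed
#' alignment intervals on each read, kept consistent with the emitted FASTA /
#' FASTQ / SAM byte for byte.
#'
#' @slot seed_placements \code{data.frame}: \code{seed_id}, \code{chrom},
#'   \code{start} (0-based), \code{strand}.
#' @slot read_origins \code{data.frame}: \code{read_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{n_edits}, \code{chimeric}.
#' @slot read_seed_hits \code{data.frame}: true per-read seed alignment
#'   intervals in read coordinates (same columns as ReadChainSet hits).
#' @export
setClass("SimTruth", representation(seed_placements = "data.frame",
                                    read_origins = "data.frame",
                                    read_seed_hits = "data.frame"))

## ---- show methods ----

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet with", length(object@seeds), "seeds of length",
      object@seedLen, "nt\n")
})

setMethod("show", "KmerTable", function(object) {
  cat("KmerTable: ", nrow(object@counts), " canonical ", object@k,
      "-mers, total count ", sum(as.numeric(object@counts$count)), "\n", sep = "")
})

setMethod("show", "ReadChainSet", function(object) {
  h <- object@hits
  cat("ReadChainSet:", length(unique(h$read_id)), "reads,",
      nrow(h), "seed hits\n")
})

setMethod("show", "SeedGraph", function(object) {
  cat("SeedGraph:", nLinks(object), "bidirected links over",
      length(unique(c(object@links$from, object@links$to))), "seeds;",
      nrow(object@removed) / 2L, "removed;",
      object@skipped, "hit pairs skipped\n")
})

setMethod("show", "ScaffoldSet", function(object) {
  n <- vapply(object@scaffolds, nrow, integer(1))
  cat("ScaffoldSet:", length(n), "scaffolds covering", sum(n), "seeds",
      if (length(n)) paste0("(largest ", max(n), " seeds)") else "", "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@seed_placements), "seed placements,",
      nrow(object@read_origins), "reads,",
      nrow(object@read_seed_hits), "true seed hits\n")
})

## ---- accessors ----

#' @rdname SeedSet-class
#' @param object,x A \code{SeedSet}.
#' @export
setGeneric("seedSequences", function(object) standardGeneric("seedSequences"))

#' @rdname SeedSet-class
#' @export
setMethod("seedSequences", "SeedSet", function(object) object@seeds)

#' Seed length accessor
#' @param object A SeedSet, SeedGraph or ScaffoldSet.
#' @return Integer seed length in nt.
#' @export
setGeneric("seedLength", function(object) standardGeneric("seedLength"))

#' @rdname seedLength
#' @export
setMethod("seedLength", "SeedSet", function(object) object@seedLen)

#' @rdname seedLength
#' @export
setMethod("seedLength", "SeedGraph", function(object) object@seedLen)

#' @rdname seedLength
#' @export
setMethod("seedLength", "ScaffoldSet", function(object) object@seedLen)

#' @rdname SeedSet-class
#' @export
setMethod("length", "SeedSet", function(x) length(x@seeds))

#' Graph link accessors
#'
#' \code{graphLinks} returns the retained directed link table (each bidirected
#' link appears as a mirror pair); \code{removedLinks} the audit table of
#' removed links with reasons; \code{nLinks} the number of bidirected links
#' counted once.
#'
#' @param object A \code{SeedGraph}.
#' @export
setGeneric("graphLinks", function(object) standardGeneric("graphLinks"))

#' @rdname graphLinks
#' @export
setMethod("graphLinks", "SeedGraph", function(object) object@links)

#' @rdname graphLinks
#' @export
setGeneric("removedLinks", function(object) standardGeneric("removedLinks"))

#' @rdname graphLinks
#' @export
setMethod("removedLinks", "SeedGraph", function(object) object@removed)

#' @rdname graphLinks
#' @export
setGeneric("nLinks", function(object) standardGeneric("nLinks"))

#' @rdname graphLinks
#' @export
setMethod("nLinks", "SeedGraph", function(object) nrow(object@links) %/% 2L)

#' Scaffold accessors
#'
#' @param object A \code{ScaffoldSet}.
#' @return \code{scaffoldPlacements}: named list of placement data.frames;
#'   \code{scaffoldLengths}: named integer vector of estimated lengths
#'   (sum of seed lengths plus signed gaps).
#' @export
setGeneric("scaffoldPlacements", function(object) standardGeneric("scaffoldPlacements"))

#' @rdname scaffoldPlacements
#' @export
setMethod("scaffoldPlacements", "ScaffoldSet", function(object) object@scaffolds)

#' @rdname scaffoldPlacements
#' @export
setGeneric("scaffoldLengths", function(object) standardGeneric("scaffoldLengths"))

#' @rdname scaffoldPlacements
#' @export
setMethod("scaffoldLengths", "ScaffoldSet", function(object) {
  vapply(object@scaffolds, function(s) {
    nrow(s) * object@seedLen + sum(s$gap_after[-nrow(s)])
  }, numeric(1))
})

#' Read chain accessor
#' @param object A \code{ReadChainSet}.
#' @export
setGeneric("chainHits", function(object) standardGeneric("chainHits"))

#' @rdname chainHits
#' @export
setMethod("chainHits", "ReadChainSet", function(object) object@hits)
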