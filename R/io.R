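#' Write a seed graph as GFA1
#'
#' S-lines carry the seeds (sequence if a \code{SeedSet} is supplied, \code{*}
#' otherwise with an \code{LN} tag); L-lines carry each bidirected link once,
#' with the overlap CIGAR encoding negative gaps (\code{<n>M}; \code{0M} for
#' non-overlapping links) and tags \code{gp:i:} (mean gap, rounded half-up)
#' and \code{ev:i:} (evidence). The per-observation gap lists are summarized,
#' not serialized: a graph read back from GFA carries the mean gap replicated
#' per unit of evidence.
#'
#' @param graph A \linkS4class{SeedGraph}.
#' @param file Output path.
#' @param seeds Optional \linkS4class{SeedSet} to embed sequences.
#' @return The path, invisibly.
#' @export
writeGFA <- function(graph, file, seeds = NULL) {
  stopifnot(methods::is(graph, "SeedGraph"))
  l <- graphLinks(graph)
  node_ids <- sort(unique(c(l$from, l$to)))
  sseq <- if (!is.null(seeds)) as.character(seedSequences(seeds)) else NULL
  s_lines <- vapply(node_ids, function(id) {
    if (!is.null(sseq) && !is.na(sseq[id]))
      paste("S", id, sseq[[id]], sep = "\t")
    else paste("S", id, "*", paste0("LN:i:", graph@seedLen), sep = "\t")
  }, character(1))
  lc <- l[is_canonical_link(l), , drop = FALSE]
  l_lines <- character(nrow(lc))
  if (nrow(lc)) {
    gp <- round_half_up(vapply(lc$gap_obs, mean, numeric(1)))
    ov <- ifelse(gp < 0, paste0(-gp, "M"), "0M")
    l_lines <- paste("L", lc$from, lc$from_o, lc$to, lc$to_o, ov,
                     paste0("gp:i:", gp), paste0("ev:i:", lc$evidence),
                     sep = "\t")
  }
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), file)
  invisible(file)
}

#' Read a GFA1 seed graph written by \code{\link{writeGFA}}
#'
#' Reconstructs a \linkS4class{SeedGraph} from S- and L-lines. Gap
#' observations are the serialized mean replicated per unit of evidence
#' (GFA stores the summary, not the observation list); supporting read ids are
#' not recoverable and are filled with placeholders.
#'
#' @param file GFA path.
#' @param seed_len Seed length; derived from \code{LN} tags or sequence
#'   lengths when \code{NULL}.
#' @return A \linkS4class{SeedGraph}.
#' @export
readGFA <- function(file, seed_len = NULL) {
  lines <- readLines(file)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(parts, `[`, character(1), 1L)
  if (is.null(seed_len)) {
    s <- parts[types == "S"]
    lens <- vapply(s, function(p) {
      if (p[3] != "*") nchar(p[3])
      else {
        ln <- grep("^LN:i:", p, value = TRUE)
        if (length(ln)) as.integer(sub("^LN:i:", "", ln[1])) else NA_integer_
      }
    }, numeric(1))
    seed_len <- as.integer(unique(lens[!is.na(lens)]))
    if (length(seed_len) != 1L)
      stop("cannot derive a unique seed length from GFA S-lines")
  }
  lp <- parts[types == "L"]
  if (!length(lp)) {
    return(methods::new("SeedGraph", links = empty_link_df(),
                        removed = empty_link_df(reason = TRUE),
                        seedLen = as.integer(seed_len), skipped = 0L))
  }
  tagval <- function(p, tag) {
    v <- grep(paste0("^", tag, ":i:"), p, value = TRUE)
    if (length(v)) as.integer(sub(paste0("^", tag, ":i:"), "", v[1]))
    else NA_integer_
  }
  fwd <- data.frame(
    from = vapply(lp, `[`, character(1), 2L),
    from_o = vapply(lp, `[`, character(1), 3L),
    to = vapply(lp, `[`, character(1), 4L),
    to_o = vapply(lp, `[`, character(1), 5L),
    gp = vapply(lp, tagval, numeric(1), "gp"),
    ev = vapply(lp, tagval, numeric(1), "ev"),
    stringsAsFactors = FALSE)
  fwd$ev[is.na(fwd$ev)] <- 1L
  rev <- data.frame(from = fwd$to, from_o = flip_orient(fwd$to_o),
                    to = fwd$from, to_o = flip_orient(fwd$from_o),
                    gp = fwd$gp, ev = fwd$ev, stringsAsFactors = FALSE)
  both <- rbind(fwd, rev)
  both <- both[!duplicated(link_key(both$from, both$from_o, both$to,
                                    both$to_o)), , drop = FALSE]
  both <- both[order(both$from, both$from_o, both$to, both$to_o), ,
               drop = FALSE]
  links <- data.frame(from = both$from, from_o = both$from_o, to = both$to,
                      to_o = both$to_o, evidence = as.integer(both$ev),
                      stringsAsFactors = FALSE)
  links$gap_obs <- lapply(seq_len(nrow(both)),
                          function(i) rep(both$gp[i], both$ev[i]))
  links$reads <- lapply(seq_len(nrow(both)),
                        function(i) paste0("gfa_read_", i, "_",
                                           seq_len(both$ev[i])))
  rownames(links) <- NULL
  methods::new("SeedGraph", links = links,
               removed = empty_link_df(reason = TRUE),
               seedLen = as.integer(seed_len), skipped = 0L)
}

#' Write scaffold models as AGP v2.1 with a signed-gap sidecar
#'
#' Component (W) lines place the seeds by id; gap lines between them use the
#' \code{scaffold} gap type with \code{paired-ends;map} linkage evidence.
#' Positive gaps become N gap lines of that size. AGP cannot express component
#' overlap, so negative gaps are encoded as 1-bp U gap lines; the true signed
#' gaps (every adjacency) are written to the sidecar \code{<file>.gaps.tsv},
#' from which \code{\link{readScaffoldsAGP}} restores them exactly.
#'
#' @param scaffolds A \linkS4class{ScaffoldSet}.
#' @param file Output AGP path.
#' @return The path, invisibly.
#' @export
writeScaffoldsAGP <- function(scaffolds, file) {
  stopifnot(methods::is(scaffolds, "ScaffoldSet"))
  L <- seedLength(scaffolds)
  rows <- list()
  gaps <- list()
  for (sid in names(scaffoldPlacements(scaffolds))) {
    pl <- scaffoldPlacements(scaffolds)[[sid]]
    pos <- 0L
    part <- 0L
    for (j in seq_len(nrow(pl))) {
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = sid, object_beg = pos + 1L, object_end = pos + L,
        part_number = part, component_type = "W",
        comp = pl$seed_id[j], comp_beg = 1L, comp_end = L,
        orientation = pl$orient[j], stringsAsFactors = FALSE)
      pos <- pos + L
      if (j < nrow(pl)) {
        g <- pl$gap_after[j]
        part <- part + 1L
        glen <- if (g > 0) as.integer(g) else 1L
        gtype <- if (g > 0) "N" else "U"
        rows[[length(rows) + 1L]] <- data.frame(
          object = sid, object_beg = pos + 1L, object_end = pos + glen,
          part_number = part, component_type = gtype,
          comp = as.character(glen), comp_beg = "scaffold", comp_end = "yes",
          orientation = "paired-ends;map", stringsAsFactors = FALSE)
        pos <- pos + glen
        gaps[[length(gaps) + 1L]] <- data.frame(
          object = sid, after_part = part - 1L, gap = g,
          stringsAsFactors = FALSE)
      }
    }
  }
  con <- file(file, "w")
  writeLines("##agp-version\t2.1", con)
  tab <- do.call(rbind, rows)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  sidecar <- paste0(file, ".gaps.tsv")
  gt <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(object = character(0), after_part = integer(0),
               gap = numeric(0))
  utils::write.table(gt, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read scaffold models from AGP (+ sidecar) written by
#' \code{\link{writeScaffoldsAGP}}
#'
#' @param file AGP path; \code{<file>.gaps.tsv} is consulted for signed gaps
#'   when present (otherwise N gap sizes are used and U gaps read as 1).
#' @param seed_len Seed length; derived from the first component line when
#'   \code{NULL}.
#' @return A \linkS4class{ScaffoldSet}.
#' @export
readScaffoldsAGP <- function(file, seed_len = NULL) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  comp <- parts[vapply(parts, `[`, character(1), 5L) == "W"]
  gapl <- parts[vapply(parts, `[`, character(1), 5L) %in% c("N", "U")]
  if (is.null(seed_len))
    seed_len <- as.integer(comp[[1]][8]) - as.integer(comp[[1]][7]) + 1L
  sidecar <- paste0(file, ".gaps.tsv")
  side <- if (file.exists(sidecar))
    utils::read.table(sidecar, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  d <- data.frame(
    object = vapply(comp, `[`, character(1), 1L),
    part = as.integer(vapply(comp, `[`, character(1), 4L)),
    seed_id = vapply(comp, `[`, character(1), 6L),
    orient = vapply(comp, `[`, character(1), 9L),
    stringsAsFactors = FALSE)
  gd <- data.frame(
    object = vapply(gapl, `[`, character(1), 1L),
    part = as.integer(vapply(gapl, `[`, character(1), 4L)),
    size = as.integer(vapply(gapl, `[`, character(1), 6L)),
    stringsAsFactors = FALSE)
  placements <- lapply(split(d, d$object), function(s) {
    s <- s[order(s$part), , drop = FALSE]
    g <- rep(NA_real_, nrow(s))
    if (nrow(s) > 1L) {
      for (j in seq_len(nrow(s) - 1L)) {
        if (!is.null(side)) {
          m <- side[side$object == s$object[1] &
                      side$after_part == s$part[j], "gap"]
          g[j] <- if (length(m)) m[1] else NA_real_
        }
        if (is.na(g[j])) {
          m <- gd[gd$object == s$object[1] & gd$part == s$part[j] + 1L, "size"]
          g[j] <- if (length(m)) m[1] else 0
        }
      }
    }
    data.frame(seed_id = s$seed_id, orient = s$orient, gap_after = g,
               stringsAsFactors = FALSE)
  })
  methods::new("ScaffoldSet", scaffolds = placements,
               seedLen = as.integer(seed_len))
}

#' Write the link-removal audit as TSV
#'
#' One row per removed directed link: endpoints, orientations, evidence, mean
#' gap and removal reason.
#'
#' @param graph A simplified \linkS4class{SeedGraph}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeRemovalAudit <- function(graph, file) {
  r <- removedLinks(graph)
  d <- data.frame(from = r$from, from_o = r$from_o, to = r$to, to_o = r$to_o,
                  evidence = r$evidence,
                  mean_gap = if (nrow(r))
                    round_half_up(vapply(r$gap_obs, mean, numeric(1)))
                  else numeric(0),
                  reason = r$reason, stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a k-mer table as two-column TSV
#' @param table A \linkS4class{KmerTable}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeKmerTable <- function(table, file) {
  stopifnot(methods::is(table, "KmerTable"))
  data.table::fwrite(table@counts, file, sep = "\t")
  invisible(file)
}

#' Write a statistics list as JSON
#' @param stats A named list (e.g. from \code{\link{seedStats}} or
#'   \code{\link{assemblyStats}}).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeStatsJson <- function(stats, file) {
  jsonlite::write_json(stats, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read paired FASTQ/FASTA short reads
#'
#' Convenience reader for seed selection input: two files (R1/R2) or a single
#' pre-merged FASTA/FASTQ.
#'
#' @param r1 Path to the forward (or merged) file.
#' @param r2 Optional path to the reverse file.
#' @return A list of character vectors \code{r1} and (optionally) \code{r2}.
#' @export
readShortReads <- function(r1, r2 = NULL) {
  rd <- function(f) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", f, ignore.case = TRUE))
      as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
    else as.character(Biostrings::readDNAStringSet(f))
  }
  out <- list(r1 = rd(r1))
  if (!is.null(r2)) out$r2 <- rd(r2)
  out
}
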