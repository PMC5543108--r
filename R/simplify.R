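#' Configuration for graph simplification and scaffold layout
#'
#' Thresholds governing the simplification of the seed graph. Span tolerance
#' bounds how closely an intermediate seed path must fit under a spanning link
#' for the spanning link to be deemed redundant: the tolerance is
#' \code{max(span_tolerance_abs, span_tolerance_frac * spanning gap)}, sized to
#' nanopore indel noise. \code{max_lookahead} bounds the number of intermediate
#' seeds considered (and the terminal-region depth for long-range joins).
#' \code{min_evidence_ratio} is the margin by which one link must outvote every
#' rival before a branching node is resolved in its favour rather than severed
#' as repetitive. \code{min_join_evidence} is the minimum number of reads
#' required to join two scaffolds long-range.
#'
#' @param span_tolerance_frac Fractional span tolerance (default 0.2).
#' @param span_tolerance_abs Absolute span tolerance in bp (default 50).
#' @param max_lookahead Maximum intermediate seeds under a spanning link
#'   (default 3).
#' @param max_branch Maximum tolerated branching before severing (default 2).
#' @param min_join_evidence Minimum reads supporting a long-range join
#'   (default 2).
#' @param min_evidence_ratio Evidence ratio for branch arbitration
#'   (default 3.0).
#' @param gap_consensus "mean" (default) or "median" gap consensus.
#' @param keep_singletons Emit single-seed scaffolds (default FALSE).
#' @return A list of class \code{simplify_config}.
#' @export
simplifyConfig <- function(span_tolerance_frac = 0.2,
                           span_tolerance_abs = 50,
                           max_lookahead = 3L,
                           max_branch = 2L,
                           min_join_evidence = 2L,
                           min_evidence_ratio = 3.0,
                           gap_consensus = c("mean", "median"),
                           keep_singletons = FALSE) {
  gap_consensus <- match.arg(gap_consensus)
  cfg <- list(span_tolerance_frac = span_tolerance_frac,
              span_tolerance_abs = span_tolerance_abs,
              max_lookahead = as.integer(max_lookahead),
              max_branch = as.integer(max_branch),
              min_join_evidence = as.integer(min_join_evidence),
              min_evidence_ratio = min_evidence_ratio,
              gap_consensus = gap_consensus,
              keep_singletons = keep_singletons)
  stopifnot(all(vapply(cfg[1:6], function(x) x > 0, logical(1))))
  class(cfg) <- "simplify_config"
  cfg
}

link_gap_consensus <- function(gaps, how = "mean") {
  if (how == "median") stats::median(gaps) else mean(gaps)
}

# Move the directed links with the given keys (mirrors added automatically)
# from the retained set to the removed audit table.
move_links <- function(graph, keys, reason) {
  if (!length(keys)) return(graph)
  l <- graph@links
  all_keys <- unique(c(keys, {
    i <- match(keys, link_key(l$from, l$from_o, l$to, l$to_o))
    i <- i[!is.na(i)]
    mirror_key(l$from[i], l$from_o[i], l$to[i], l$to_o[i])
  }))
  idx <- link_key(l$from, l$from_o, l$to, l$to_o) %in% all_keys
  gone <- l[idx, , drop = FALSE]
  if (nrow(gone)) gone$reason <- reason
  graph@removed <- rbind(graph@removed, gone)
  graph@links <- l[!idx, , drop = FALSE]
  rownames(graph@links) <- NULL
  rownames(graph@removed) <- NULL
  graph
}

# Out-link adjacency: list mapping oriented-node key "seed\to" to the integer
# row indices of its out-links.
out_index <- function(links) {
  if (!nrow(links)) return(list())
  nk <- paste(links$from, links$from_o, sep = "\t")
  split(seq_len(nrow(links)), nk)
}

node_key <- function(seed, orient) paste(seed, orient, sep = "\t")

#' Remove spanning links explained by an intermediate seed path
#'
#' At every oriented seed with more than one outgoing link, looks for a direct
#' link A->C coexisting with a path A->B1->...->Bk->C (k up to
#' \code{max_lookahead} intermediate seeds). If the intermediate seeds fit
#' under the direct link — the direct link's mean gap agrees with the path's
#' total span (sum of path gaps plus intermediate seed lengths) within the span
#' tolerance — the direct link is redundant (it arose from reads missing the
#' intermediate alignments) and is moved to the removal audit with reason
#' \code{"spanned"}, together with its mirror. Sweeps iterate to a fixpoint
#' (each sweep evaluates against the state left by the previous one), bounded
#' at \code{max_sweeps}.
#'
#' @param graph A \linkS4class{SeedGraph} (reverse-complement symmetric).
#' @param cfg A \code{\link{simplifyConfig}}.
#' @param max_sweeps Sweep bound (default 10).
#' @return The simplified \code{SeedGraph}.
#' @export
resolveSpans <- function(graph, cfg = simplifyConfig(), max_sweeps = 10L) {
  stopifnot(methods::is(graph, "SeedGraph"))
  L <- graph@seedLen
  for (sweep in seq_len(max_sweeps)) {
    l <- graph@links
    if (!nrow(l)) break
    idx <- out_index(l)
    mean_gap <- vapply(l$gap_obs, link_gap_consensus, numeric(1),
                       how = cfg$gap_consensus)
    to_key <- node_key(l$to, l$to_o)
    drop_keys <- character(0)
    multi <- names(idx)[lengths(idx) > 1L]
    for (nk in multi) {
      rows <- idx[[nk]]
      for (r in rows) {
        target <- to_key[r]
        g_direct <- mean_gap[r]
        tol <- max(cfg$span_tolerance_abs, cfg$span_tolerance_frac * g_direct)
        # DFS over out-links for a path with 1..max_lookahead intermediates
        found <- span_path_exists(r, nk, target, g_direct, tol, idx, l,
                                  mean_gap, to_key, L, cfg$max_lookahead)
        if (found)
          drop_keys <- c(drop_keys,
                         link_key(l$from[r], l$from_o[r], l$to[r], l$to_o[r]))
      }
    }
    if (!length(drop_keys)) break
    graph <- move_links(graph, unique(drop_keys), "spanned")
  }
  graph
}

# TRUE if a simple path from node `start_key` to oriented node `target`,
# avoiding the direct link row `direct_row`, with 1..lookahead intermediates,
# has total span within tol of g_direct. Depth-first with cumulative span.
span_path_exists <- function(direct_row, start_key, target, g_direct, tol,
                             idx, links, mean_gap, to_key, seed_len,
                             lookahead) {
  # stack entries: (current node key, seeds visited, depth, span so far)
  recurse <- function(nkey, span, depth, visited) {
    rows <- idx[[nkey]]
    if (is.null(rows)) return(FALSE)
    for (r in rows) {
      if (r == direct_row) next
      tk <- to_key[r]
      if (tk == target) {
        if (depth >= 1L && abs(g_direct - (span + mean_gap[r])) <= tol)
          return(TRUE)
        next
      }
      if (depth >= lookahead) next
      seed <- links$to[r]
      if (seed %in% visited) next
      if (recurse(tk, span + mean_gap[r] + seed_len, depth + 1L,
                  c(visited, seed)))
        return(TRUE)
    }
    FALSE
  }
  start_seed <- strsplit(start_key, "\t", fixed = TRUE)[[1]][1]
  tgt_seed <- strsplit(target, "\t", fixed = TRUE)[[1]][1]
  recurse(start_key, 0, 0L, c(start_seed, tgt_seed))
}

#' Sever ambiguous links at residual branching seeds
#'
#' After span resolution, an oriented seed that still has several outgoing
#' links is either resolvable by evidence or repetitive. If one competing link
#' is supported by at least \code{min_evidence_ratio} times the evidence of
#' every rival, the rivals are removed (reason \code{"outvoted"}); otherwise
#' the seed likely represents repetitive content and all links on that side
#' are severed (reason \code{"repeat"}). Mirrors are removed in lockstep.
#' Decisions for all nodes are taken against the state at entry and applied
#' together, making the operation order-independent.
#'
#' @param graph A \linkS4class{SeedGraph}, ideally after
#'   \code{\link{resolveSpans}}.
#' @param cfg A \code{\link{simplifyConfig}}.
#' @return The severed \code{SeedGraph}; every oriented seed is left with at
#'   most one outgoing (and, by symmetry, one incoming) link.
#' @export
severRepeats <- function(graph, cfg = simplifyConfig()) {
  stopifnot(methods::is(graph, "SeedGraph"))
  l <- graph@links
  if (!nrow(l)) return(graph)
  idx <- out_index(l)
  outvoted <- character(0)
  repeats <- character(0)
  for (nk in names(idx)[lengths(idx) > 1L]) {
    rows <- idx[[nk]]
    ev <- l$evidence[rows]
    o <- order(-ev)
    e1 <- ev[o[1]]; e2 <- ev[o[2]]
    keys <- link_key(l$from[rows], l$from_o[rows], l$to[rows], l$to_o[rows])
    if (e1 > e2 && e1 >= cfg$min_evidence_ratio * e2) {
      outvoted <- c(outvoted, keys[o[-1]])
    } else {
      repeats <- c(repeats, keys)
    }
  }
  # a link severed as repeat anywhere is recorded as repeat even if outvoted
  # at its other endpoint
  outvoted <- setdiff(outvoted, repeats)
  graph <- move_links(graph, unique(repeats), "repeat")
  graph <- move_links(graph, unique(outvoted), "outvoted")
  graph
}

flip_placements <- function(pl) {
  n <- nrow(pl)
  data.frame(seed_id = rev(pl$seed_id),
             orient = flip_orient(rev(pl$orient)),
             gap_after = c(rev(pl$gap_after[-n]), NA_real_),
             stringsAsFactors = FALSE)
}

# Canonical orientation (lexicographically smaller terminal seed first),
# canonical order, sequential ids.
finalize_scaffolds <- function(placements, seed_len) {
  placements <- lapply(placements, function(pl) {
    if (nrow(pl) > 1L && pl$seed_id[nrow(pl)] < pl$seed_id[1L])
      flip_placements(pl) else pl
  })
  first <- vapply(placements, function(pl) pl$seed_id[1L], character(1))
  placements <- placements[order(first)]
  names(placements) <- paste0("scaffold_", seq_along(placements))
  methods::new("ScaffoldSet", scaffolds = placements,
               seedLen = as.integer(seed_len))
}

#' Extract linear scaffolds from a simplified seed graph
#'
#' Requires every oriented seed to have at most one outgoing and one incoming
#' link (as guaranteed after \code{\link{severRepeats}}); maximal simple chains
#' then become scaffolds. Each bidirected chain is emitted exactly once, in
#' canonical orientation (lexicographically smaller terminal seed id first);
#' the gap after each placement is the consensus (mean, rounded half-up) of
#' the link's gap observations. Circular components are linearized by breaking
#' the lowest-evidence link (smallest canonical key on ties; the broken link
#' is recorded with reason \code{"circular"}). Seeds without retained links
#' become single-seed scaffolds only if \code{cfg$keep_singletons} is set and
#' the seed universe is supplied.
#'
#' @param graph A simplified \linkS4class{SeedGraph}.
#' @param cfg A \code{\link{simplifyConfig}}.
#' @param all_seeds Optional character vector of all seed ids, used for
#'   singleton emission.
#' @return A \linkS4class{ScaffoldSet}.
#' @export
extractPaths <- function(graph, cfg = simplifyConfig(), all_seeds = NULL) {
  stopifnot(methods::is(graph, "SeedGraph"))
  l <- graph@links
  L <- graph@seedLen
  if (nrow(l)) {
    idx <- out_index(l)
    if (any(lengths(idx) > 1L))
      stop("graph still has branching seeds; run severRepeats first")
  }
  placements <- list()
  used <- character(0)
  if (nrow(l)) {
    succ_row <- vapply(out_index(l), `[`, integer(1), 1L)
    has_out <- names(succ_row)
    gap_cons <- vapply(l$gap_obs, link_gap_consensus, numeric(1),
                       how = cfg$gap_consensus)
    has_in <- unique(node_key(l$to, l$to_o))
    walk <- function(start) {
      path_rows <- integer(0)
      cur <- start
      repeat {
        r <- succ_row[[cur]]
        if (is.null(r) || is.na(r)) break
        path_rows <- c(path_rows, r)
        cur <- node_key(l$to[r], l$to_o[r])
        if (cur == start) break  # circular guard
        if (!cur %in% has_out) break
      }
      path_rows
    }
    starts <- setdiff(has_out, has_in)
    emitted_rows <- logical(nrow(l))
    for (s in sort(starts)) {
      rows <- walk(s)
      if (!length(rows)) next
      seeds <- c(l$from[rows[1]], l$to[rows])
      orients <- c(l$from_o[rows[1]], l$to_o[rows])
      if (seeds[length(seeds)] < seeds[1]) next  # mirror walk emits it
      pl <- data.frame(seed_id = seeds, orient = orients,
                       gap_after = c(round_half_up(gap_cons[rows]), NA_real_),
                       stringsAsFactors = FALSE)
      placements[[length(placements) + 1L]] <- pl
      emitted_rows[rows] <- TRUE
      used <- c(used, seeds)
    }
    # circular leftovers: nodes with out-links never visited in either
    # direction of any linear walk
    leftover <- which(!emitted_rows)
    if (length(leftover)) {
      mirror_of <- match(mirror_key(l$from, l$from_o, l$to, l$to_o),
                         link_key(l$from, l$from_o, l$to, l$to_o))
      covered <- emitted_rows | emitted_rows[mirror_of]
      while (any(!covered)) {
        # deterministically pick the weakest link of some cycle
        cand <- which(!covered)
        keys <- link_key(l$from[cand], l$from_o[cand], l$to[cand], l$to_o[cand])
        pick <- cand[order(l$evidence[cand], keys)][1]
        # collect the cycle through this link
        start <- node_key(l$to[pick], l$to_o[pick])
        rows <- integer(0)
        cur <- start
        repeat {
          r <- succ_row[[cur]]
          rows <- c(rows, r)
          cur <- node_key(l$to[r], l$to_o[r])
          if (cur == start) break
        }
        cyc_rows <- setdiff(rows, pick)
        seeds <- c(l$from[cyc_rows[1]], l$to[cyc_rows])
        orients <- c(l$from_o[cyc_rows[1]], l$to_o[cyc_rows])
        pl <- data.frame(seed_id = seeds, orient = orients,
                         gap_after = c(round_half_up(gap_cons[cyc_rows]),
                                       NA_real_),
                         stringsAsFactors = FALSE)
        if (seeds[length(seeds)] < seeds[1]) pl <- flip_placements(pl)
        placements[[length(placements) + 1L]] <- pl
        used <- c(used, seeds)
        touched <- c(rows, pick, mirror_of[c(rows, pick)])
        covered[touched] <- TRUE
        broken <- link_key(l$from[pick], l$from_o[pick], l$to[pick],
                           l$to_o[pick])
        graph <- move_links(graph, broken, "circular")
      }
    }
  }
  if (isTRUE(cfg$keep_singletons) && !is.null(all_seeds)) {
    for (s in sort(setdiff(all_seeds, used))) {
      placements[[length(placements) + 1L]] <-
        data.frame(seed_id = s, orient = "+", gap_after = NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  finalize_scaffolds(placements, L)
}

# Per-scaffold layout table: seed_id, orient, index, offset (bp from scaffold
# start to the seed's left edge), plus total length.
scaffold_layout <- function(pl, seed_len) {
  n <- nrow(pl)
  gaps <- pl$gap_after
  gaps[n] <- 0
  off <- cumsum(c(0, (seed_len + gaps)[-n]))
  list(offsets = off, total = off[n] + seed_len)
}

#' Join scaffolds by unambiguous long-distance co-alignments
#'
#' Scaffolds that share no direct seed adjacency can still be linked by reads
#' that co-align to seeds near the ends of both. A candidate join connects a
#' terminal region (the outermost \code{max_lookahead} seeds) of one scaffold
#' end to a terminal region of another when at least \code{min_join_evidence}
#' reads co-align across them with consistent orientation and implied
#' inter-scaffold gap (all observations within the span tolerance of their
#' median). A join is applied only when neither scaffold end participates in
#' more than one surviving candidate; applied joins merge the scaffold models
#' with the mean implied gap (rounded half-up) between the boundary seeds.
#'
#' @param scaffolds A \linkS4class{ScaffoldSet} from \code{\link{extractPaths}}.
#' @param chains The \linkS4class{ReadChainSet} used to build the graph (it
#'   retains the non-adjacent co-alignments).
#' @param cfg A \code{\link{simplifyConfig}}.
#' @return A merged \linkS4class{ScaffoldSet}.
#' @export
joinLongRange <- function(scaffolds, chains, cfg = simplifyConfig()) {
  stopifnot(methods::is(scaffolds, "ScaffoldSet"),
            methods::is(chains, "ReadChainSet"))
  L <- scaffolds@seedLen
  pls <- scaffolds@scaffolds
  if (length(pls) < 2L) return(scaffolds)
  # seed -> (scaffold, index); per-scaffold offsets
  seed2scaf <- list()
  layouts <- lapply(pls, scaffold_layout, seed_len = L)
  for (sid in names(pls)) {
    pl <- pls[[sid]]
    for (i in seq_len(nrow(pl)))
      seed2scaf[[pl$seed_id[i]]] <- list(scaf = sid, i = i)
  }
  h <- chainHits(chains)
  h <- h[order(h$read_id, h$read_start), , drop = FALSE]
  obs <- list()  # per candidate key: data.frame(read, gap)
  by_read <- split(seq_len(nrow(h)), h$read_id)
  for (rows in by_read) {
    if (length(rows) < 2L) next
    info <- lapply(rows, function(r) {
      m <- seed2scaf[[h$seed_id[r]]]
      if (is.null(m)) return(NULL)
      pl <- pls[[m$scaf]]
      n <- nrow(pl)
      d <- if (h$strand[r] == pl$orient[m$i]) 1L else -1L
      list(scaf = m$scaf, i = m$i, n = n, d = d, row = r)
    })
    for (a in seq_along(rows)) {
      ia <- info[[a]]
      if (is.null(ia)) next
      # read exits ia's scaffold at end R (d=+1) or L (d=-1)
      exit_end <- if (ia$d == 1L) "R" else "L"
      near_exit <- if (ia$d == 1L) ia$n - ia$i < cfg$max_lookahead
                   else ia$i - 1L < cfg$max_lookahead
      if (!near_exit) next
      for (b in seq_along(rows)) {
        if (b <= a) next
        ib <- info[[b]]
        if (is.null(ib) || ib$scaf == ia$scaf) next
        entry_end <- if (ib$d == 1L) "L" else "R"
        near_entry <- if (ib$d == 1L) ib$i - 1L < cfg$max_lookahead
                      else ib$n - ib$i < cfg$max_lookahead
        if (!near_entry) next
        ra <- ia$row; rb <- ib$row
        g_read <- h$read_start[rb] - h$read_end[ra]
        offa <- layouts[[ia$scaf]]$offsets[ia$i]
        offb <- layouts[[ib$scaf]]$offsets[ib$i]
        rem_a <- if (exit_end == "R") layouts[[ia$scaf]]$total - (offa + L)
                 else offa
        rem_b <- if (entry_end == "L") offb
                 else layouts[[ib$scaf]]$total - (offb + L)
        g <- g_read - rem_a - rem_b
        t1 <- paste(ia$scaf, exit_end, sep = ":")
        t2 <- paste(ib$scaf, entry_end, sep = ":")
        key <- if (t1 <= t2) paste(t1, t2, sep = "|") else
          paste(t2, t1, sep = "|")
        obs[[key]] <- rbind(obs[[key]],
                            data.frame(read = h$read_id[ra], gap = g,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (!length(obs)) return(scaffolds)
  # one observation per read per candidate; evidence and consistency filters
  cands <- list()
  for (key in sort(names(obs))) {
    d <- obs[[key]]
    agg <- tapply(d$gap, d$read, mean)
    g <- as.numeric(agg)
    if (length(g) < cfg$min_join_evidence) next
    med <- stats::median(g)
    tol <- max(cfg$span_tolerance_abs, cfg$span_tolerance_frac * abs(med))
    if (any(abs(g - med) > tol)) next
    cands[[key]] <- list(terminals = strsplit(key, "|", fixed = TRUE)[[1]],
                         gap = round_half_up(mean(g)),
                         evidence = length(g))
  }
  if (!length(cands)) return(scaffolds)
  # unambiguity: drop candidates sharing a terminal
  terms <- unlist(lapply(cands, `[[`, "terminals"))
  shared <- names(table(terms))[table(terms) > 1L]
  cands <- Filter(function(cc) !any(cc$terminals %in% shared), cands)
  if (!length(cands)) return(scaffolds)
  # merge; containers track which original ends are exposed
  containers <- lapply(names(pls), function(sid) {
    list(pl = pls[[sid]], left = paste(sid, "L", sep = ":"),
         right = paste(sid, "R", sep = ":"))
  })
  names(containers) <- names(pls)
  end2cont <- new.env()
  for (cn in names(containers)) {
    assign(containers[[cn]]$left, cn, envir = end2cont)
    assign(containers[[cn]]$right, cn, envir = end2cont)
  }
  flip_container <- function(cc) {
    list(pl = flip_placements(cc$pl), left = cc$right, right = cc$left)
  }
  for (key in sort(names(cands))) {
    cc <- cands[[key]]
    t1 <- cc$terminals[1]; t2 <- cc$terminals[2]
    c1n <- get0(t1, envir = end2cont); c2n <- get0(t2, envir = end2cont)
    if (is.null(c1n) || is.null(c2n) || c1n == c2n) next  # cycle guard
    c1 <- containers[[c1n]]; c2 <- containers[[c2n]]
    if (c1$left == t1) c1 <- flip_container(c1)
    if (c2$right == t2) c2 <- flip_container(c2)
    pl1 <- c1$pl; pl2 <- c2$pl
    pl1$gap_after[nrow(pl1)] <- cc$gap
    merged <- list(pl = rbind(pl1, pl2), left = c1$left, right = c2$right)
    containers[[c1n]] <- merged
    containers[[c2n]] <- NULL
    rm(list = c(t1, t2), envir = end2cont)
    for (endlab in c(merged$left, merged$right))
      assign(endlab, c1n, envir = end2cont)
  }
  finalize_scaffolds(lapply(containers, `[[`, "pl"), L)
}

#' Local subgraph around a scaffold or seed
#'
#' Returns the induced subgraph (retained and removed links, the latter
#' flagged with their recorded removal reason) within a given number of links
#' of a scaffold's seeds or of a single seed, for inspection or export to
#' graph visualization tools.
#'
#' @param graph A \linkS4class{SeedGraph} (typically the initial graph, which
#'   carries the removal audit after simplification).
#' @param id A scaffold id (when \code{scaffolds} is supplied) or a seed id.
#' @param radius Number of links to expand (default 10).
#' @param scaffolds Optional \linkS4class{ScaffoldSet} for scaffold-id lookup.
#' @return A data.frame of directed links with columns of the link table plus
#'   \code{removed} (logical) and \code{reason}.
#' @export
neighborhood <- function(graph, id, radius = 10L, scaffolds = NULL) {
  stopifnot(methods::is(graph, "SeedGraph"), radius >= 0L)
  ret <- graph@links
  rem <- graph@removed
  ret$removed <- rep(FALSE, nrow(ret))
  ret$reason <- rep(NA_character_, nrow(ret))
  rem$removed <- rep(TRUE, nrow(rem))
  cols <- c(.link_cols, "gap_obs", "reads", "reason", "removed")
  all_l <- rbind(ret[, cols, drop = FALSE], rem[, cols, drop = FALSE])
  start <- if (!is.null(scaffolds) && id %in% names(scaffolds@scaffolds)) {
    scaffolds@scaffolds[[id]]$seed_id
  } else id
  known <- unique(c(all_l$from, all_l$to))
  if (!any(start %in% known))
    stop("unknown scaffold or seed id: ", id)
  frontier <- intersect(start, known)
  seen <- frontier
  for (r in seq_len(radius)) {
    nb <- c(all_l$to[all_l$from %in% frontier],
            all_l$from[all_l$to %in% frontier])
    frontier <- setdiff(unique(nb), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  sub <- all_l[all_l$from %in% seen & all_l$to %in% seen, , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Run the full scaffolding stage
#'
#' Convenience wrapper chaining \code{\link{resolveSpans}},
#' \code{\link{severRepeats}}, \code{\link{extractPaths}} and
#' \code{\link{joinLongRange}}, with seed conservation accounting: every seed
#' ends up scaffolded, singleton, or isolated by repeat severing.
#'
#' @param graph The initial \linkS4class{SeedGraph}.
#' @param chains The \linkS4class{ReadChainSet} behind the graph.
#' @param cfg A \code{\link{simplifyConfig}}.
#' @param all_seeds Optional character vector of all seed ids (for counts and
#'   singleton emission).
#' @return A list: \code{graph} (simplified, with removal audit),
#'   \code{scaffolds} (final \code{ScaffoldSet}), and \code{counts} (named
#'   integer vector: scaffolded, singleton, severed_isolated).
#' @export
runScaffolding <- function(graph, chains, cfg = simplifyConfig(),
                           all_seeds = NULL) {
  g1 <- resolveSpans(graph, cfg)
  g2 <- severRepeats(g1, cfg)
  sc <- extractPaths(g2, cfg, all_seeds = all_seeds)
  sc <- joinLongRange(sc, chains, cfg)
  in_scaf <- unlist(lapply(sc@scaffolds, function(p) p$seed_id),
                    use.names = FALSE)
  multi <- unlist(lapply(sc@scaffolds,
                         function(p) if (nrow(p) > 1L) p$seed_id),
                  use.names = FALSE)
  universe <- if (is.null(all_seeds))
    unique(c(graph@links$from, graph@links$to,
             graph@removed$from, graph@removed$to)) else all_seeds
  severed <- unique(c(g2@removed$from[g2@removed$reason == "repeat"],
                      g2@removed$to[g2@removed$reason == "repeat"]))
  # scaffolded = seeds in multi-seed scaffolds; of the rest, those touched by
  # repeat severing vs plain singletons
  rest <- setdiff(universe, multi)
  counts <- c(scaffolded = length(unique(multi)),
              singleton = length(setdiff(rest, severed)),
              severed_isolated = length(intersect(rest, severed)))
  list(graph = g2, scaffolds = sc, counts = counts)
}
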