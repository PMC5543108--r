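#' Simulation configuration
#'
#' Study conditions for the synthetic genome / read generator. Defaults
#' describe the desk-scale regime used throughout the package's tests: a 1 Mbp
#' single-chromosome random genome at GC 0.5, seeds of 285 nt at a mean
#' spacing of 700 bp, and 15-fold coverage in log-normal reads of mean 8 kbp.
#' Chemistry presets set per-base alignment identity (R7.3 2D ~0.75, R9 1D
#' ~0.89, R9 2D ~0.94; R9.4 1D is treated like R9 1D) with stated
#' mismatch:insertion:deletion splits; \code{"perfect"} emits exact substrings.
#'
#' @param genome_len Total genome length in bp.
#' @param n_chromosomes Number of chromosomes (equal sizes).
#' @param gc GC content, fraction.
#' @param repeat_frac Fraction of the genome occupied by implanted repeat
#'   copies (0 disables).
#' @param repeat_unit_len Repeat unit length in bp.
#' @param seed_len Seed length in nt.
#' @param seed_spacing_mean Mean seed spacing in bp.
#' @param coverage Read fold-coverage of the genome.
#' @param read_len_mean,read_len_sd Log-normal read length mean and sd in bp.
#' @param chemistry One of "perfect", "r73-2d", "r9-1d", "r9-2d", "r94-1d".
#' @param chimera_rate Fraction of reads that are two joined unrelated
#'   fragments.
#' @param missed_hit_rate Fraction of true seed alignments randomly omitted
#'   from the truth SAM (models missed alignments of a noisy aligner).
#' @param homopolymer_bias Double the deletion rate inside homopolymers of
#'   length >= 4 (default TRUE), approximating nanopore homopolymer loss.
#' @param rng_seed Integer seed; the generator is fully deterministic given it
#'   (one derived substream per stage).
#' @return A list of class \code{sim_config}.
#' @export
simConfig <- function(genome_len = 1e6, n_chromosomes = 1L, gc = 0.5,
                      repeat_frac = 0, repeat_unit_len = 500L,
                      seed_len = 285L, seed_spacing_mean = 700,
                      coverage = 15, read_len_mean = 8000,
                      read_len_sd = 4000,
                      chemistry = c("perfect", "r73-2d", "r9-1d", "r9-2d",
                                    "r94-1d"),
                      chimera_rate = 0, missed_hit_rate = 0,
                      homopolymer_bias = TRUE, rng_seed = 42L) {
  chemistry <- match.arg(chemistry)
  stopifnot(gc >= 0, gc <= 1, repeat_frac >= 0, repeat_frac <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            missed_hit_rate >= 0, missed_hit_rate <= 1,
            genome_len > 0, seed_len > 0, seed_spacing_mean > 0,
            coverage > 0, read_len_mean > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Chemistry error presets
#'
#' Per-chemistry alignment identity and mismatch:insertion:deletion split.
#' Identity is defined as matches over alignment columns; the per-base edit
#' rate is solved from it so that the expected identity of simulated reads
#' equals the preset.
#'
#' @param chemistry Preset name.
#' @return List with \code{identity} and \code{ratio} (named fractions
#'   summing to 1).
#' @export
chemistryPreset <- function(chemistry) {
  switch(chemistry,
    "perfect" = list(identity = 1.0, ratio = c(mm = 0,    ins = 0,    del = 0)),
    "r73-2d"  = list(identity = 0.75, ratio = c(mm = 0.40, ins = 0.30, del = 0.30)),
    "r9-1d"   = list(identity = 0.89, ratio = c(mm = 0.35, ins = 0.30, del = 0.35)),
    "r9-2d"   = list(identity = 0.94, ratio = c(mm = 0.35, ins = 0.30, del = 0.35)),
    "r94-1d"  = list(identity = 0.89, ratio = c(mm = 0.35, ins = 0.30, del = 0.35)),
    stop("unknown chemistry: ", chemistry))
}

# per-base edit rate e solving identity = (1 - e*(rm+rd)) / (1 + e*ri)
edit_rate <- function(preset) {
  id <- preset$identity
  if (id >= 1) return(0)
  r <- preset$ratio
  (1 - id) / (r[["mm"]] + r[["del"]] + id * r[["ins"]])
}

stage_seed <- function(cfg, stage) {
  (as.integer(cfg$rng_seed) + stage * 10007L) %% .Machine$integer.max
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a random genome
#'
#' I.i.d. bases at the target GC content, split over equal-size chromosomes.
#' When \code{repeat_frac > 0}, a single random repeat unit is implanted in
#' enough copies (at random non-overlapping positions) to occupy the requested
#' fraction of the genome. Deterministic under \code{rng_seed}.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return A named \link[Biostrings]{DNAStringSet} (chr1, chr2, ...).
#' @export
simulateGenome <- function(cfg) {
  set.seed(stage_seed(cfg, 1L))
  n_chr <- as.integer(cfg$n_chromosomes)
  chr_len <- floor(cfg$genome_len / n_chr)
  if (cfg$repeat_frac > 0 &&
      cfg$repeat_frac * cfg$genome_len < cfg$repeat_unit_len)
    stop("repeat_frac * genome_len smaller than one repeat unit")
  chrs <- vapply(seq_len(n_chr), function(i) random_dna(chr_len, cfg$gc),
                 character(1))
  if (cfg$repeat_frac > 0) {
    unit <- random_dna(cfg$repeat_unit_len, cfg$gc)
    n_copies <- max(2L, floor(cfg$repeat_frac * cfg$genome_len /
                                cfg$repeat_unit_len))
    per_chr <- tabulate(sample(n_chr, n_copies, replace = TRUE), n_chr)
    for (i in seq_len(n_chr)) {
      if (!per_chr[i]) next
      # non-overlapping implant positions
      max_start <- chr_len - cfg$repeat_unit_len
      pos <- sort(sample(max_start, per_chr[i]))
      keep <- c(TRUE, diff(pos) >= cfg$repeat_unit_len)
      pos <- pos[keep]
      s <- chrs[i]
      for (p in pos)
        substring(s, p + 1L, p + cfg$repeat_unit_len) <- unit
      chrs[i] <- s
    }
  }
  g <- Biostrings::DNAStringSet(chrs)
  names(g) <- paste0("chr", seq_len(n_chr))
  g
}

#' Sample genome-unique seeds from a simulated genome
#'
#' Seed start positions are drawn uniformly from loci whose every 25-mer is
#' unique in the genome (canonical counting, both strands), targeting a mean
#' spacing of \code{seed_spacing_mean}; overlapping picks are rejected. Half
#' of the seeds are stored reverse-complemented (strand "-") so that
#' orientation handling is exercised downstream.
#'
#' @param genome A \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @param cfg A \code{\link{simConfig}}.
#' @return A list: \code{seeds} (a \linkS4class{SeedSet}) and
#'   \code{placements} (data.frame seed_id, chrom, start, strand).
#' @export
sampleSeeds <- function(genome, cfg) {
  set.seed(stage_seed(cfg, 2L))
  k <- 25L
  L <- as.integer(cfg$seed_len)
  chrs <- as.character(genome)
  # canonical k-mer multiplicity over the whole genome
  wins <- lapply(chrs, kmer_windows, k = k)
  all_canon <- canonical_kmers(unlist(wins, use.names = FALSE))
  tab <- data.table::data.table(kmer = all_canon)
  tab <- tab[, list(count = .N), by = "kmer"]
  multi_kmers <- tab$kmer[tab$count > 1L]
  placements <- list()
  for (ci in seq_along(chrs)) {
    w <- canonical_kmers(wins[[ci]])
    dup <- w %chin% multi_kmers
    # locus p (0-based) eligible iff windows p+1 .. p+L-k+1 all unique
    cd <- cumsum(as.integer(dup))
    n_loci <- nchar(chrs[ci]) - L + 1L
    if (n_loci < 1L) next
    lo <- seq_len(n_loci)
    hi <- lo + (L - k)
    elig <- which((cd[hi] - c(0, cd)[lo]) == 0L)  # 1-based starts
    n_target <- max(1L, round(nchar(chrs[ci]) / cfg$seed_spacing_mean))
    if (length(elig) < n_target)
      stop("insufficient unique loci for requested seed density; ",
           "lower the density or the repeat fraction")
    cand <- sample(elig, min(length(elig), 3L * n_target))
    taken <- integer(0)
    for (p in cand) {
      if (length(taken) >= n_target) break
      if (length(taken) &&
          any(abs(taken - p) < L)) next
      taken <- c(taken, p)
    }
    if (length(taken) < n_target / 2)
      stop("insufficient non-overlapping unique loci; lower the seed density")
    taken <- sort(taken)
    placements[[ci]] <- data.frame(
      chrom = names(genome)[ci], start = taken - 1L,
      stringsAsFactors = FALSE)
  }
  pl <- do.call(rbind, placements)
  pl$seed_id <- paste0("seed_", seq_len(nrow(pl)))
  pl$strand <- sample(c("+", "-"), nrow(pl), replace = TRUE)
  seqs <- character(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    s <- substring(chrs[[match(pl$chrom[i], names(genome))]],
                   pl$start[i] + 1L, pl$start[i] + L)
    seqs[i] <- if (pl$strand[i] == "-") revcomp_chr(s) else s
  }
  seeds <- Biostrings::DNAStringSet(seqs)
  names(seeds) <- pl$seed_id
  list(seeds = methods::new("SeedSet", seeds = seeds, seedLen = L),
       placements = pl[, c("seed_id", "chrom", "start", "strand")])
}

# Apply the chemistry error model to one fragment (character, read
# orientation). Returns the mutated sequence, the cumulative output-offset
# vector (cumout[i+1] = read bases emitted for fragment positions <= i), the
# per-position deletion/insertion vectors, and identity bookkeeping.
mutate_fragment <- function(frag, preset, homopolymer_bias) {
  n <- nchar(frag)
  bases <- strsplit(frag, "")[[1]]
  e <- edit_rate(preset)
  if (e == 0) {
    return(list(seq = frag, cumout = 0:n, del = logical(n),
                ins = integer(n), matches = n, columns = n, edits = 0L))
  }
  r <- preset$ratio
  p_del <- rep(e * r[["del"]], n)
  if (homopolymer_bias && n >= 4L) {
    rl <- rle(bases)
    hp <- rep(rl$lengths >= 4L, rl$lengths)
    p_del[hp] <- pmin(1, 2 * p_del[hp])
  }
  del <- stats::runif(n) < p_del
  mm <- !del & (stats::runif(n) < e * r[["mm"]])
  ins <- as.integer(stats::runif(n) < e * r[["ins"]])
  out <- bases
  if (any(mm)) {
    alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    out[mm] <- alt[cbind(match(out[mm], rownames(alt)),
                         sample.int(3L, sum(mm), replace = TRUE))]
  }
  pieces <- out
  pieces[del] <- ""
  if (any(ins > 0)) {
    ii <- which(ins > 0)
    pieces[ii] <- paste0(pieces[ii],
                         sample(c("A", "C", "G", "T"), length(ii),
                                replace = TRUE))
  }
  contrib <- as.integer(!del) + ins
  list(seq = paste(pieces, collapse = ""),
       cumout = c(0L, cumsum(contrib)),
       del = del, ins = ins,
       matches = sum(!del & !mm),
       columns = n + sum(ins),
       edits = sum(mm) + sum(del) + sum(ins))
}

# CIGAR for the seed interval [a, b) (0-based fragment coordinates) given the
# mutation record; returns list(cigar ops in fragment order, read_start,
# read_end) with trailing insertions excluded from the alignment.
seed_interval_aln <- function(mut, a, b) {
  rs <- mut$cumout[a + 1L]
  re <- mut$cumout[b + 1L] - if (length(mut$ins)) mut$ins[b] else 0L
  idx <- seq(a + 1L, b)
  ops <- character(0)
  if (length(mut$del)) {
    per <- ifelse(mut$del[idx], "D", "M")
    insv <- mut$ins[idx]
    insv[length(insv)] <- 0L  # trailing insertions stay outside
    ops <- unlist(mapply(function(o, k) c(o, rep("I", k)), per, insv,
                         SIMPLIFY = FALSE), use.names = FALSE)
  } else {
    ops <- rep("M", b - a)
  }
  list(ops = ops, read_start = rs, read_end = re)
}

rle_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate nanopore-like reads with ground truth
#'
#' Samples reads of log-normal length uniformly over the genome (uniform
#' strand), applies the chemistry error model (i.i.d. per-base edits at the
#' rate implied by the preset identity, split per the preset
#' mismatch:insertion:deletion ratio, with optional extra deletions inside
#' homopolymers), optionally joins a fraction of read pairs into chimeras, and
#' records the ground truth: read origins and, for every seed fully contained
#' in a read's genomic footprint, the true edit-adjusted alignment interval on
#' the read. A fraction \code{missed_hit_rate} of truth alignments is randomly
#' dropped to emulate aligner misses.
#'
#' @param genome A \code{DNAStringSet}.
#' @param seed_placements The placements data.frame from
#'   \code{\link{sampleSeeds}}.
#' @param cfg A \code{\link{simConfig}}.
#' @return A list: \code{reads} (named character vector), \code{truth} (a
#'   \linkS4class{SimTruth}), and \code{identity} (per-read achieved alignment
#'   identity).
#' @export
simulateReads <- function(genome, seed_placements, cfg) {
  set.seed(stage_seed(cfg, 3L))
  preset <- chemistryPreset(cfg$chemistry)
  L <- as.integer(cfg$seed_len)
  chrs <- as.character(genome)
  chr_len <- nchar(chrs)
  n_reads <- max(1L, round(cfg$coverage * cfg$genome_len / cfg$read_len_mean))
  sdlog <- sqrt(log(1 + (cfg$read_len_sd / cfg$read_len_mean)^2))
  mulog <- log(cfg$read_len_mean) - sdlog^2 / 2
  pl <- seed_placements
  pl_by_chr <- split(pl, pl$chrom)
  reads <- character(n_reads)
  origins <- vector("list", n_reads)
  hits <- vector("list", n_reads)
  identity <- numeric(n_reads)
  chimeric <- stats::runif(n_reads) < cfg$chimera_rate
  sample_fragment <- function(len) {
    ci <- sample.int(length(chrs), 1L, prob = chr_len)
    len <- min(len, chr_len[ci])
    s <- sample.int(chr_len[ci] - len + 1L, 1L) - 1L
    list(ci = ci, start = s, end = s + len,
         strand = sample(c("+", "-"), 1L))
  }
  frag_truth <- function(fr, mut, read_id, read_offset, read_len) {
    p <- pl_by_chr[[names(genome)[fr$ci]]]
    if (is.null(p)) return(NULL)
    inside <- p$start >= fr$start & (p$start + L) <= fr$end
    if (!any(inside)) return(NULL)
    p <- p[inside, , drop = FALSE]
    recs <- lapply(seq_len(nrow(p)), function(j) {
      a <- if (fr$strand == "+") p$start[j] - fr$start
           else fr$end - (p$start[j] + L)
      aln <- seed_interval_aln(mut, a, a + L)
      rel <- if ((fr$strand == p$strand[j])) "+" else "-"
      data.frame(read_id = read_id, read_len = read_len,
                 seed_id = p$seed_id[j],
                 read_start = aln$read_start + read_offset,
                 read_end = aln$read_end + read_offset,
                 strand = rel,
                 seed_cov = 1.0, mapq = 60L,
                 cigar_ops = I(list(aln$ops)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  }
  for (i in seq_len(n_reads)) {
    len <- max(200L, round(stats::rlnorm(1, mulog, sdlog)))
    read_id <- sprintf("read_%05d", i)
    parts <- if (chimeric[i]) {
      list(sample_fragment(max(200L, len %/% 2L)),
           sample_fragment(max(200L, len %/% 2L)))
    } else list(sample_fragment(len))
    seqs <- character(length(parts))
    offset <- 0L
    rec_list <- list()
    m_tot <- 0L; c_tot <- 0L; e_tot <- 0L
    for (pi in seq_along(parts)) {
      fr <- parts[[pi]]
      s <- substring(chrs[fr$ci], fr$start + 1L, fr$end)
      if (fr$strand == "-") s <- revcomp_chr(s)
      mut <- mutate_fragment(s, preset, cfg$homopolymer_bias)
      seqs[pi] <- mut$seq
      rec_list[[pi]] <- frag_truth(fr, mut, read_id, offset, NA_integer_)
      offset <- offset + nchar(mut$seq)
      m_tot <- m_tot + mut$matches; c_tot <- c_tot + mut$columns
      e_tot <- e_tot + mut$edits
    }
    reads[i] <- paste(seqs, collapse = "")
    rl <- nchar(reads[i])
    rr <- do.call(rbind, rec_list)
    if (!is.null(rr)) rr$read_len <- rl
    hits[[i]] <- rr
    fr1 <- parts[[1]]
    origins[[i]] <- data.frame(
      read_id = read_id, chrom = names(genome)[fr1$ci],
      start = fr1$start, end = fr1$end, strand = fr1$strand,
      n_edits = e_tot, chimeric = chimeric[i], stringsAsFactors = FALSE)
    identity[i] <- if (c_tot) m_tot / c_tot else 1
  }
  names(reads) <- sprintf("read_%05d", seq_len(n_reads))
  hit_df <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hit_df)) hit_df <- cbind(empty_chain_df(),
                                       data.frame(cigar_ops = I(list())))
  if (cfg$missed_hit_rate > 0 && nrow(hit_df)) {
    keep <- stats::runif(nrow(hit_df)) >= cfg$missed_hit_rate
    hit_df <- hit_df[keep, , drop = FALSE]
  }
  rownames(hit_df) <- NULL
  truth <- methods::new("SimTruth",
                        seed_placements = seed_placements,
                        read_origins = do.call(rbind, origins),
                        read_seed_hits = hit_df)
  list(reads = reads, truth = truth, identity = identity)
}

#' Write the simulator's truth alignments as SAM
#'
#' Emits one record per true (read, contained seed) alignment, with seeds as
#' references: header \code{@SQ} lines for every seed, detailed M/I/D CIGARs
#' reflecting the introduced edits, soft clips for the flanking read sequence,
#' and flag 16 with reverse-complemented SEQ where the seed lies on the
#' opposite strand of the read. The output is accepted unchanged by
#' \code{\link{readSeedAlignments}}.
#'
#' @param sim Result of \code{\link{simulateReads}}.
#' @param seeds The \linkS4class{SeedSet}.
#' @param file Output SAM path.
#' @return The file path, invisibly.
#' @export
writeTruthSam <- function(sim, seeds, file) {
  L <- seedLength(seeds)
  hd <- c("@HD\tVN:1.6\tSO:unknown",
          paste0("@SQ\tSN:", names(seedSequences(seeds)), "\tLN:", L))
  h <- sim$truth@read_seed_hits
  lines <- character(nrow(h))
  if (nrow(h)) {
    need_rc <- unique(h$read_id[h$strand == "-"])
    rc_reads <- revcomp_chr(sim$reads[need_rc])
    names(rc_reads) <- need_rc
    for (i in seq_len(nrow(h))) {
      rid <- h$read_id[i]
      seq <- sim$reads[[rid]]
      ops <- h$cigar_ops[[i]]
      rs <- h$read_start[i]; re <- h$read_end[i]
      rl <- h$read_len[i]
      if (h$strand[i] == "+") {
        cig <- paste0(if (rs) paste0(rs, "S") else "",
                      rle_cigar(ops),
                      if (rl - re) paste0(rl - re, "S") else "")
        flag <- 0L
        out_seq <- seq
      } else {
        cig <- paste0(if (rl - re) paste0(rl - re, "S") else "",
                      rle_cigar(rev(ops)),
                      if (rs) paste0(rs, "S") else "")
        flag <- 16L
        out_seq <- rc_reads[[rid]]
      }
      lines[i] <- paste(rid, flag, h$seed_id[i], 1L, h$mapq[i], cig,
                        "*", 0L, 0L, out_seq, "*", sep = "\t")
    }
  }
  writeLines(c(hd, lines), file)
  invisible(file)
}

#' Simulate a complete dataset
#'
#' Runs \code{\link{simulateGenome}}, \code{\link{sampleSeeds}} and
#' \code{\link{simulateReads}}, optionally writing genome FASTA, seeds FASTA,
#' reads FASTQ, truth SAM and truth tables (TSV) to a directory.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param dir Output directory, or \code{NULL} for in-memory only.
#' @return A list: \code{genome}, \code{seeds} (SeedSet), \code{truth}
#'   (SimTruth), \code{reads} (named character), \code{identity}, and, when
#'   \code{dir} is given, \code{files} (named paths).
#' @export
simulateDataset <- function(cfg = simConfig(), dir = NULL) {
  genome <- simulateGenome(cfg)
  ss <- sampleSeeds(genome, cfg)
  sim <- simulateReads(genome, ss$placements, cfg)
  out <- list(genome = genome, seeds = ss$seeds, truth = sim$truth,
              reads = sim$reads, identity = sim$identity)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(genome = file.path(dir, "genome.fa"),
               seeds = file.path(dir, "seeds.fa"),
               reads = file.path(dir, "reads.fq"),
               sam = file.path(dir, "truth.sam"),
               placements = file.path(dir, "seed_placements.tsv"),
               origins = file.path(dir, "read_origins.tsv"))
    Biostrings::writeXStringSet(genome, files["genome"], width = 80L)
    Biostrings::writeXStringSet(seedSequences(ss$seeds), files["seeds"],
                                width = 80L)
    writeFastq(sim$reads, files["reads"])
    writeTruthSam(sim, ss$seeds, files["sam"])
    utils::write.table(sim$truth@seed_placements, files["placements"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth@read_origins, files["origins"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- files
  }
  out
}

writeFastq <- function(reads, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(reads)) {
    writeLines(c(paste0("@", nm), reads[[nm]], "+",
                 strrep("I", nchar(reads[[nm]]))), con)
  }
  invisible(file)
}
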