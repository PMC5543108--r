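sam_header <- function(seed_ids, seed_len = 285L) {
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", seed_ids, "\tLN:", seed_len))
}

sam_rec <- function(qname, flag, rname, cigar, seq, mapq = 60L) {
  paste(qname, flag, rname, 1L, mapq, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}

test_that("SAM consumption filters and maps to read coordinates", {
  # read of 1000 nt with two seed hits (285M each) at read offsets 100 and 500
  L <- 285L
  rd <- random_seq(1000)
  lines <- c(sam_header(c("seed_1", "seed_2"), L),
             sam_rec("r1", 0L, "seed_1", "100S285M615S", rd),
             sam_rec("r1", 0L, "seed_2", "500S285M215S", rd),
             # secondary record: excluded
             sam_rec("r1", 256L, "seed_1", "200S285M515S", rd),
             # low mapq: excluded at default min_mapq 1
             sam_rec("r1", 0L, "seed_2", "10S285M705S", rd, mapq = 0L))
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  ch <- readSeedAlignments(f, seed_len = L)
  h <- chainHits(ch)
  expect_equal(nrow(h), 2L)
  expect_equal(h$seed_id, c("seed_1", "seed_2"))
  expect_equal(h$read_start, c(100L, 500L))
  expect_equal(h$read_end, c(385L, 785L))
  expect_equal(h$strand, c("+", "+"))
  expect_equal(h$seed_cov, c(1, 1))
})

test_that("reverse-strand records map back to original read coordinates", {
  L <- 285L
  rd <- random_seq(600)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  # seed aligns reverse: in SEQ (revcomp'd read) the match sits at offset 50;
  # on the original read that is [600-50-285, 600-50) = [265, 315+235... )
  lines <- c(sam_header("seed_1", L),
             sam_rec("r1", 16L, "seed_1", "50S285M265S", rc))
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  h <- chainHits(readSeedAlignments(f, seed_len = L))
  expect_equal(h$strand, "-")
  expect_equal(h$read_start, 600L - 50L - 285L)
  expect_equal(h$read_end, 600L - 50L)
})

test_that("seed coverage filter uses reference-space CIGAR width", {
  L <- 285L
  rd <- random_seq(600)
  lines <- c(sam_header("seed_1", L),
             sam_rec("r1", 0L, "seed_1", "100S150M350S", rd))  # 150/285 < 0.8
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  expect_equal(nrow(chainHits(readSeedAlignments(f, seed_len = L))), 0L)
  expect_equal(nrow(chainHits(readSeedAlignments(f, seed_len = L,
                                                 min_seed_cov = 0.5))), 1L)
})

test_that("reads-as-reference input is rejected", {
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:read_1\tLN:8000", "@SQ\tSN:read_2\tLN:5432")
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  expect_error(readSeedAlignments(f, seed_len = 285),
               "seeds as references")
})

test_that("truth SAM chains reproduce the simulator's per-read seed lists", {
  cfg <- simConfig(genome_len = 120000, coverage = 5, read_len_mean = 6000,
                   read_len_sd = 2500, chemistry = "r9-1d", rng_seed = 31L)
  d <- simulateDataset(cfg, dir = tempfile("sim"))
  ch <- readSeedAlignments(d$files[["sam"]], seeds = d$seeds)
  got <- chainHits(ch)
  want <- d$truth@read_seed_hits
  want <- want[order(want$read_id, want$read_start), , drop = FALSE]
  expect_equal(got$read_id, want$read_id)
  expect_equal(got$seed_id, want$seed_id)
  expect_equal(got$read_start, want$read_start)
  expect_equal(got$read_end, want$read_end)
  expect_equal(got$strand, want$strand)
})

test_that("adjacent hits become links with apparent gap and mirror", {
  L <- 285L
  ch <- make_chains(data.frame(
    read_id = "r1", seed_id = c("S1", "S2"),
    read_start = c(100L, 500L), read_end = c(385L, 785L),
    strand = "+", stringsAsFactors = FALSE))
  g <- buildSeedGraph(ch, seed_len = L)
  l <- graphLinks(g)
  expect_equal(nrow(l), 2L)  # link + mirror
  fwd <- l[l$from == "S1", ]
  expect_equal(fwd$to, "S2")
  expect_equal(fwd$gap_obs[[1]], 115L)
  expect_equal(fwd$evidence, 1L)
  mir <- l[l$from == "S2", ]
  expect_equal(mir$from_o, "-")
  expect_equal(mir$to_o, "-")
  expect_equal(mir$gap_obs[[1]], 115L)
})

test_that("the overlap cap admits shallow overlaps and skips deep ones", {
  L <- 285L
  # gap -25: |25| <= 28.5 -> link
  ch1 <- make_chains(data.frame(
    read_id = "r1", seed_id = c("S1", "S2"),
    read_start = c(100L, 360L), read_end = c(385L, 645L),
    strand = "+", stringsAsFactors = FALSE))
  g1 <- buildSeedGraph(ch1, seed_len = L, max_overlap_frac = 0.10)
  expect_equal(nLinks(g1), 1L)
  expect_equal(graphLinks(g1)$gap_obs[[1]], -25L)
  # gap -85 exceeds the cap -> skipped and counted
  ch2 <- make_chains(data.frame(
    read_id = "r1", seed_id = c("S1", "S2"),
    read_start = c(100L, 300L), read_end = c(385L, 585L),
    strand = "+", stringsAsFactors = FALSE))
  g2 <- buildSeedGraph(ch2, seed_len = L, max_overlap_frac = 0.10)
  expect_equal(nLinks(g2), 0L)
  expect_equal(g2@skipped, 1L)
})

test_that("graph construction is order-independent and evidence-conserving", {
  set.seed(21)
  walks <- lapply(1:20, function(i) {
    seeds <- paste0("S", sort(sample(1:8, sample(3:6, 1))))
    chain_along(sprintf("r%02d", i), seeds,
                gaps = sample(50:400, length(seeds) - 1L))
  })
  g1 <- graph_from_walks(walks)
  g2 <- graph_from_walks(rev(walks))
  expect_identical(graphLinks(g1), graphLinks(g2))
  expect_rc_symmetric(g1)
  # sum of evidence over bidirected links = number of retained adjacent pairs
  l <- graphLinks(g1)
  canon <- l[tulip:::is_canonical_link(l), , drop = FALSE]
  n_pairs <- sum(vapply(walks, nrow, integer(1)) - 1L)
  expect_equal(sum(canon$evidence), n_pairs)
})

test_that("error-free simulated links carry exactly the true genomic gap", {
  fx <- perfect_sim_1mb()
  l <- graphLinks(fx$g)
  pl <- fx$d$truth@seed_placements
  starts <- stats::setNames(pl$start, pl$seed_id)
  ok <- vapply(seq_len(nrow(l)), function(i) {
    true_gap <- abs(starts[[l$to[i]]] - starts[[l$from[i]]]) -
      seedLength(fx$g)
    all(l$gap_obs[[i]] == true_gap)
  }, logical(1))
  expect_true(all(ok))
})

test_that("graph report histograms count links once and match expectation", {
  # hand graph: links with evidence 1, 1, 3
  walks <- list(
    chain_along("r1", c("A", "B"), 100),
    chain_along("r2", c("B", "C"), 200),
    chain_along("r3", c("C", "D"), 300),
    chain_along("r4", c("C", "D"), 300),
    chain_along("r5", c("C", "D"), 300))
  rep1 <- graphReport(graph_from_walks(walks))
  expect_equal(rep1$evidence,
               data.frame(evidence = c(1L, 3L), n = c(2L, 1L)))
  # empty graph
  rep0 <- graphReport(buildSeedGraph(make_chains(
    data.frame(read_id = character(0), seed_id = character(0),
               read_start = integer(0), read_end = integer(0),
               strand = character(0))), 285))
  expect_equal(nrow(rep0$evidence), 0L)

  # simulated 15x: modal evidence near the span-coverage expectation
  fx <- perfect_sim_1mb()
  rep <- graphReport(fx$g)
  mode_ev <- rep$evidence$evidence[which.max(rep$evidence$n)]
  lens <- with(fx$d$truth@read_origins, end - start)
  span <- 2 * 285 + 700  # two seeds plus a typical gap
  lambda <- sum(pmax(0, lens - span)) / 1e6
  expect_gt(mode_ev, lambda / 2)
  expect_lt(mode_ev, lambda * 2)
})
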