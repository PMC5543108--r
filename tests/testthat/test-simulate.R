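test_that("genome simulation hits the target GC and is deterministic", {
  cfg <- simConfig(genome_len = 1e6, gc = 0.5, rng_seed = 5L)
  g1 <- simulateGenome(cfg)
  f <- Biostrings::letterFrequency(g1[[1]], c("GC"), as.prob = TRUE)
  expect_lt(abs(f[[1]] - 0.5), 0.01)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  # at GC 0.4 the deviation tracks the target, not 0.5
  g3 <- simulateGenome(simConfig(genome_len = 2e5, gc = 0.4, rng_seed = 5L))
  f3 <- Biostrings::letterFrequency(g3[[1]], c("GC"), as.prob = TRUE)
  expect_lt(abs(f3[[1]] - 0.4), 0.01)
})

test_that("a repeat-free 100 kbp genome has (almost) all 25-mers unique", {
  cfg <- simConfig(genome_len = 1e5, repeat_frac = 0, rng_seed = 6L)
  g <- simulateGenome(cfg)
  tab <- countKmers(as.character(g), k = 25)
  expect_equal(max(tab@counts$count), 1L)
})

test_that("seed sampling density, uniqueness and sequence fidelity hold", {
  fx <- perfect_sim_1mb()
  pl <- fx$d$truth@seed_placements
  n_expect <- 1e6 / 700
  expect_lt(abs(nrow(pl) - n_expect) / n_expect, 0.10)
  # no overlapping picks
  o <- pl[order(pl$chrom, pl$start), ]
  expect_true(all(diff(o$start) >= 285))
  # stored seed sequences match genome substrings (reverse-complemented on -)
  gen <- as.character(fx$d$genome[[1]])
  set.seed(1)
  idx <- sample(nrow(pl), 50)
  for (i in idx) {
    sub <- substring(gen, pl$start[i] + 1, pl$start[i] + 285)
    want <- if (pl$strand[i] == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
      else sub
    expect_equal(as.character(seedSequences(fx$d$seeds)[[pl$seed_id[i]]]),
                 want)
  }
})

test_that("repeat implants are avoided by seed sampling", {
  cfg <- simConfig(genome_len = 2e5, repeat_frac = 0.1,
                   repeat_unit_len = 800L, seed_spacing_mean = 1500,
                   rng_seed = 13L)
  g <- simulateGenome(cfg)
  ss <- sampleSeeds(g, cfg)
  # every seed's 25-mers are unique, so no seed can sit inside a repeat copy;
  # verify each seed occurs exactly once in the genome
  gen <- as.character(g[[1]])
  set.seed(2)
  for (i in sample(nrow(ss$placements), 20)) {
    p <- ss$placements[i, ]
    s <- substring(gen, p$start + 1, p$start + 285)
    expect_equal(length(gregexpr(s, gen, fixed = TRUE)[[1]]), 1L)
  }
})

test_that("perfect chemistry emits exact genome substrings", {
  cfg <- simConfig(genome_len = 50000, coverage = 3, read_len_mean = 3000,
                   read_len_sd = 1000, chemistry = "perfect", rng_seed = 17L)
  g <- simulateGenome(cfg)
  ss <- sampleSeeds(g, cfg)
  sim <- simulateReads(g, ss$placements, cfg)
  gen <- as.character(g[[1]])
  for (rid in names(sim$reads)) {
    s <- sim$reads[[rid]]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_true(grepl(s, gen, fixed = TRUE) || grepl(rc, gen, fixed = TRUE))
  }
  expect_true(all(sim$identity == 1))
})

test_that("the r9-1d preset achieves its nominal identity", {
  # 1000 reads of ~2 kbp
  cfg <- simConfig(genome_len = 2e5, coverage = 10, read_len_mean = 2000,
                   read_len_sd = 600, chemistry = "r9-1d", rng_seed = 19L)
  g <- simulateGenome(cfg)
  ss <- sampleSeeds(g, cfg)
  sim <- simulateReads(g, ss$placements, cfg)
  expect_gte(length(sim$identity), 1000L)
  expect_lt(abs(mean(sim$identity) - 0.89), 0.01)
})

test_that("truth coordinates on perfect reads equal genomic offset arithmetic", {
  cfg <- simConfig(genome_len = 50000, coverage = 4, read_len_mean = 4000,
                   read_len_sd = 1500, chemistry = "perfect", rng_seed = 23L)
  g <- simulateGenome(cfg)
  ss <- sampleSeeds(g, cfg)
  sim <- simulateReads(g, ss$placements, cfg)
  h <- sim$truth@read_seed_hits
  ro <- sim$truth@read_origins
  rownames(ro) <- ro$read_id
  pl <- ss$placements
  rownames(pl) <- pl$seed_id
  for (i in seq_len(nrow(h))) {
    r <- ro[h$read_id[i], ]
    p <- pl[h$seed_id[i], ]
    a <- if (r$strand == "+") p$start - r$start else r$end - (p$start + 285L)
    expect_equal(h$read_start[i], a)
    expect_equal(h$read_end[i], a + 285L)
  }
})

test_that("the dataset writer is deterministic and self-consistent", {
  cfg <- simConfig(genome_len = 40000, coverage = 3, read_len_mean = 3000,
                   chemistry = "r9-1d", rng_seed = 29L)
  d1 <- simulateDataset(cfg, dir = tempfile("det1"))
  d2 <- simulateDataset(cfg, dir = tempfile("det2"))
  for (f in c("genome", "seeds", "reads", "sam"))
    expect_identical(readLines(d1$files[[f]]), readLines(d2$files[[f]]))
  # emitted FASTQ matches the in-memory reads byte for byte
  fq <- readLines(d1$files[["reads"]])
  expect_identical(fq[seq(2, length(fq), by = 4)], unname(d1$reads))
})

test_that("chimeric reads are flagged and join two unrelated fragments", {
  cfg <- simConfig(genome_len = 100000, coverage = 5, read_len_mean = 4000,
                   read_len_sd = 1000, chemistry = "perfect",
                   chimera_rate = 0.5, rng_seed = 37L)
  g <- simulateGenome(cfg)
  ss <- sampleSeeds(g, cfg)
  sim <- simulateReads(g, ss$placements, cfg)
  ro <- sim$truth@read_origins
  expect_gt(mean(ro$chimeric), 0.3)
  gen <- as.character(g[[1]])
  chim <- names(sim$reads)[ro$chimeric]
  # a chimera is (almost surely) not a contiguous genome substring
  not_sub <- vapply(chim, function(rid) {
    s <- sim$reads[[rid]]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    !grepl(s, gen, fixed = TRUE) && !grepl(rc, gen, fixed = TRUE)
  }, logical(1))
  expect_true(all(not_sub))
})

test_that("missed-hit thinning removes about the requested record fraction", {
  base <- simConfig(genome_len = 200000, coverage = 8, read_len_mean = 5000,
                    read_len_sd = 1500, chemistry = "perfect", rng_seed = 41L)
  thin <- base; thin$missed_hit_rate <- 0.15
  g <- simulateGenome(base)
  ss <- sampleSeeds(g, base)
  full <- simulateReads(g, ss$placements, base)
  part <- simulateReads(g, ss$placements, thin)
  frac <- 1 - nrow(part$truth@read_seed_hits) /
    nrow(full$truth@read_seed_hits)
  expect_lt(abs(frac - 0.15), 0.03)
})
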