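test_that("naive rearrangements are internally consistent", {
  set.seed(2)
  cfg <- simConfig()
  cat <- germlineCatalog()
  for (i in 1:20) {
    r <- sampleNaiveRearrangement(cfg, cat)
    len_aa <- nchar(r$junction_aa)
    expect_gte(len_aa, cfg@junctionLenRange[1])
    expect_lte(len_aa, cfg@junctionLenRange[2])
    expect_equal(nchar(r$junction), 3 * len_aa)
    expect_identical(substr(r$junction_aa, 1, 1), "C")
    expect_identical(substr(r$junction_aa, len_aa, len_aa), "W")
    expect_identical(r$cdr3_aa, substr(r$junction_aa, 2, len_aa - 1))
    expect_identical(r$sequence_alignment, r$germline_alignment)
    expect_true(geneName(r$v_call) %in% cat$v$gene)
  }
  set.seed(77); a <- sampleNaiveRearrangement(cfg, cat)
  set.seed(77); b <- sampleNaiveRearrangement(cfg, cat)
  expect_identical(a, b)
})

test_that("V gene draw follows the configured usage weights", {
  set.seed(4)
  cat <- germlineCatalog()
  cfg <- simConfig()
  draws <- replicate(4000, sampleNaiveRearrangement(cfg, cat)$v_call)
  obs <- table(factor(geneName(draws), levels = cat$v$gene))
  expected_p <- cat$v$weight / sum(cat$v$weight)
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
  expect_gt(chi$p.value, 1e-4)
})

test_that("lineage expansion follows the substitution model", {
  set.seed(6)
  cfg0 <- simConfig(shmSubRate = 0, trunkSubRate = 0)
  anc <- sampleNaiveRearrangement(cfg0)
  copies <- expandLineage(anc, 5, cfg0)
  expect_equal(nrow(copies), 5)
  expect_true(all(copies$sequence_alignment == anc$sequence_alignment))

  # star topology: mean per-member mutation count ~ Binomial(L, r)
  r <- 0.02
  cfgr <- simConfig(shmSubRate = r, trunkSubRate = 0)
  anc2 <- sampleNaiveRearrangement(cfgr)
  L <- nchar(anc2$sequence_alignment)
  members <- expandLineage(anc2, 400, cfgr)
  counts <- vapply(seq_len(400), function(i)
    nrow(deriveMutations(members$sequence_alignment[i],
                         members$germline_alignment[i])), numeric(1))
  se <- sqrt(L * r * (1 - r) / 400)
  expect_lt(abs(mean(counts) - L * r), 3 * se + 0.05)
})

test_that("trunk mutations are shared by all members; branch mutations are not", {
  set.seed(9)
  cfg <- simConfig(shmSubRate = 0.01, trunkSubRate = 0.05)
  anc <- sampleNaiveRearrangement(cfg)
  members <- expandLineage(anc, 6, cfg)
  muts <- lapply(seq_len(6), function(i)
    deriveMutations(members$sequence_alignment[i],
                    members$germline_alignment[i]))
  shared <- sharedMutationCount(muts[[1]], muts[[2]])
  expect_gt(shared, 0)  # the founder trunk guarantees sharing
  # two-level topology: clade mates share more than the trunk alone
  cfg2 <- simConfig(shmSubRate = 0.02, trunkSubRate = 0,
                    topology = "two_level")
  anc2 <- sampleNaiveRearrangement(cfg2)
  members2 <- expandLineage(anc2, 16, cfg2)
  muts2 <- lapply(seq_len(16), function(i)
    deriveMutations(members2$sequence_alignment[i],
                    members2$germline_alignment[i]))
  k <- max(2L, round(sqrt(16)))  # clade assignment is round-robin
  same_clade <- sharedMutationCount(muts2[[1]], muts2[[1 + k]])
  expect_gt(same_clade, 0)
})

test_that("repertoires are deterministic, donor-closed and singleton-dominated", {
  cfg <- simConfig(nLineages = 120, nDonors = 3, seed = 14)
  sim1 <- simulateRepertoire(cfg)
  sim2 <- simulateRepertoire(cfg)
  expect_identical(sim1, sim2)
  expect_identical(sim1$records$sequence_id, sim1$truth$sequence_id)
  # no true lineage spans donors, by construction
  spans <- tapply(sim1$truth$donor_id, sim1$truth$true_lineage_id,
                  function(x) length(unique(x)))
  expect_true(all(spans == 1))
  # singleton fraction of lineages in the 80-90% band across seeds
  singleton_frac <- vapply(1:20, function(s) {
    sizes <- table(simulateRepertoire(
      simConfig(nLineages = 50, seed = 100 + s))$truth$true_lineage_id)
    mean(sizes == 1)
  }, numeric(1))
  expect_gt(mean(singleton_frac), 0.80)
  expect_lt(mean(singleton_frac), 0.90)
})

test_that("read simulation is faithful at zero error and unit copies", {
  set.seed(21)
  cfg <- simConfig(nLineages = 20, seqErrorRate = 0, ampMeanlog = 0,
                   ampSigma = 0, uaidLength = 6)
  sim <- simulateRepertoire(cfg)
  rl <- simulateReads(sim$records, cfg)
  expect_equal(length(rl$reads), nrow(sim$records))
  seqs <- as.character(rl$reads)
  expect_identical(unname(substring(seqs, 7)),
                   gsub("-", "", sim$records$sequence_alignment))
  expect_identical(unname(substr(seqs, 1, 6)), rl$truth$uaid)
})

test_that("sequencing errors appear at the configured rate", {
  set.seed(22)
  e <- 0.01
  cfg <- simConfig(nLineages = 30, seqErrorRate = e, ampMeanlog = 1.2,
                   ampSigma = 0.5, uaidLength = 8)
  sim <- simulateRepertoire(cfg)
  rl <- simulateReads(sim$records, cfg)
  truthSeq <- stats::setNames(
    paste0(rl$truth$uaid, gsub("-", "", sim$records$sequence_alignment[
      match(rl$truth$sequence_id, sim$records$sequence_id)])),
    rl$truth$read_id)
  obs <- vapply(names(truthSeq), function(id) {
    a <- strsplit(as.character(rl$reads[[id]]), "")[[1]]
    b <- strsplit(truthSeq[[id]], "")[[1]]
    mean(a != b)
  }, numeric(1))
  n_bases <- sum(nchar(truthSeq))
  se <- sqrt(e * (1 - e) / n_bases)
  expect_lt(abs(mean(obs) - e), 4 * se)
})

test_that("heavy-tailed amplification produces very large barcode bins", {
  set.seed(23)
  cfg <- simConfig(nLineages = 900, shmSubRate = 0, trunkSubRate = 0,
                   seqErrorRate = 0, ampMeanlog = 1.5, ampSigma = 2.5,
                   uaidLength = 12,
                   junctionLenRange = c(5, 8))
  sim <- simulateRepertoire(cfg)
  rl <- simulateReads(sim$records, cfg)
  sizes <- table(rl$truth$uaid)
  expect_gt(max(sizes), 1000)
  expect_equal(sum(sizes), length(rl$reads))
})

test_that("unique-labeling probability matches the birthday product", {
  expect_equal(uniqueLabelingProbability(1, 20), 1)
  expect_equal(uniqueLabelingProbability(2, 1), 0.75)  # 1 - 1/4
  # small-case oracle: direct product
  for (n in c(2, 5, 17)) {
    direct <- prod(1 - (0:(n - 1)) / 4^6)
    expect_equal(uniqueLabelingProbability(n, 6), direct)
  }
  expect_equal(uniqueLabelingProbability(4^3 + 1, 3), 0)
  # exponential approximation agrees to >= 6 decimals at study scale
  expect_lt(abs(uniqueLabelingProbability(250000, 20) -
                uniqueLabelingProbability(250000, 20, "approx")),
            1e-6)
})
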