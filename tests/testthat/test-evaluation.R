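test_that("clonality fraction counts sequences in multi-member lineages", {
  expect_equal(clonalityFraction(makePartition(list(c("a", "b"), "c"))),
               2 / 3)
  expect_equal(clonalityFraction(makePartition(list("a", "b", "c"))), 0)
  expect_equal(clonalityFraction(makePartition(list(c("a", "b", "c")))), 1)
  expect_error(clonalityFraction(makePartition(list())), "empty")
})

test_that("clonality rises with sampling depth toward a plateau", {
  set.seed(61)
  sim <- simulateRepertoire(simConfig(nLineages = 1200, seed = 61))
  n <- nrow(sim$records)
  depths <- c(250, 500, 1000, round(n))
  truth <- stats::setNames(sim$truth$true_lineage_id,
                           sim$truth$sequence_id)
  # true-partition clonality of subsamples isolates the sampling effect
  clon <- vapply(depths, function(k) {
    mean(vapply(1:8, function(r) {
      ids <- sample(sim$records$sequence_id, k)
      clonalityFraction(makePartition(split(ids, truth[ids])))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(clon) > 0))
  # increments shrink as the curve approaches its plateau
  expect_lt(clon[4] - clon[3], clon[2] - clon[1])
})

test_that("cross-donor contamination follows the modal-donor rule", {
  part <- makePartition(list(c("s1", "s2", "s3"), "s4"))
  donors <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  expect_equal(crossDonorContamination(part, donors), 1 / 4)
  # strict rule: all members of any mixed lineage are incorrect
  expect_equal(crossDonorContamination(part, donors, rule = "strict"),
               3 / 4)
  # single-donor lineages are never contaminated
  pure <- makePartition(list(c("s1", "s2"), c("s3", "s4")))
  donorsP <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  expect_equal(crossDonorContamination(pure, donorsP), 0)
  expect_equal(crossDonorContamination(pure, donorsP, "strict"), 0)
  # modal ties break to the lexicographically smallest donor
  tied <- makePartition(list(c("s1", "s3")))
  expect_equal(crossDonorContamination(tied, donors), 1 / 2)
})

test_that("LOOCV pools omit one donor and are seeded", {
  sets <- lapply(1:8, function(d) {
    df <- makeRecords(makeRecord(paste0("d", d, "_1")),
                      makeRecord(paste0("d", d, "_2")),
                      makeRecord(paste0("d", d, "_3")))
    df$donor_id <- paste0("D", d)
    df
  })
  names(sets) <- paste0("D", 1:8)
  pools <- loocvPools(sets, nPerDonor = 2, seed = 10)
  expect_length(pools, 8)
  for (d in names(pools)) {
    expect_equal(nrow(pools[[d]]), 14)  # 7 donors x 2
    expect_false(d %in% pools[[d]]$donor_id)
  }
  pools2 <- loocvPools(sets, nPerDonor = 2, seed = 10)
  expect_identical(pools, pools2)
  expect_error(loocvPools(sets, nPerDonor = 5), "fewer than")
  expect_error(loocvPools(sets[1], nPerDonor = 1), "at least 2")
})

test_that("short-HCDR3 enrichment is computed per assignment-correctness group", {
  recs <- makeRecords(
    makeRecord("s1", cdr3 = strrep("A", 8)),   # short
    makeRecord("s2", cdr3 = strrep("A", 8)),   # short
    makeRecord("s3", cdr3 = strrep("G", 20)),  # long
    makeRecord("s4", cdr3 = strrep("G", 20)))
  part <- makePartition(list(c("s1", "s2"), c("s3", "s4")))
  donors <- c(s1 = "A", s2 = "B", s3 = "A", s4 = "A")
  enr <- shortHcdr3Enrichment(recs, part, donors)
  expect_equal(enr$nIncorrect, 1)     # s2: donor B in an A-modal lineage
  expect_equal(enr$fracShortIncorrect, 1)
  expect_equal(enr$fracShortCorrect, 1 / 3)
  # no incorrect sequences: the ratio is undefined, never 0 or 1
  allcorrect <- shortHcdr3Enrichment(
    recs, part, c(s1 = "A", s2 = "A", s3 = "A", s4 = "A"))
  expect_true(is.na(allcorrect$fracShortIncorrect))
})

test_that("germline usage counts lineages once at the lineage level", {
  recs <- do.call(rbind, c(
    lapply(1:100, function(i) makeRecord(paste0("v3_", i),
                                         v = "IGHV3-23*01")),
    list(makeRecord("v1_1", v = "IGHV1-2*01"))))
  part <- makePartition(list(paste0("v3_", 1:100), "v1_1"))
  seq_usage <- germlineUsage(recs, level = "sequence")
  lin_usage <- germlineUsage(recs, part, level = "lineage")
  vseq <- seq_usage[seq_usage$class == "v_family", ]
  vlin <- lin_usage[lin_usage$class == "v_family", ]
  expect_equal(vlin$freq[vlin$gene == "IGHV3"], 0.5)
  expect_equal(vlin$freq[vlin$gene == "IGHV1"], 0.5)
  expect_equal(vseq$freq[vseq$gene == "IGHV3"], 100 / 101)
  # frequencies sum to 1 within every gene class
  for (u in list(seq_usage, lin_usage))
    expect_equal(as.numeric(tapply(u$freq, u$class, sum)),
                 rep(1, length(unique(u$class))))
})

test_that("sequence- and lineage-level usage agree when gene draw is size-independent", {
  set.seed(91)
  sim <- simulateRepertoire(simConfig(nLineages = 600, seed = 91))
  part <- makePartition(split(sim$truth$sequence_id,
                              sim$truth$true_lineage_id))
  s <- germlineUsage(sim$records, level = "sequence")
  l <- germlineUsage(sim$records, part, level = "lineage")
  sv <- s[s$class == "v_family", ]
  lv <- l[l$class == "v_family", ]
  common <- intersect(sv$gene, lv$gene)
  diffs <- abs(sv$freq[match(common, sv$gene)] -
               lv$freq[match(common, lv$gene)])
  # sampling bound: ~4 SE of a frequency estimated from ~600 lineages
  expect_lt(max(diffs), 4 * sqrt(0.25 / 600))
})

test_that("pairwise precision/recall follow pair counting", {
  truth <- c(a = "T1", b = "T1", c = "T1")
  perfect <- makePartition(list(c("a", "b", "c")))
  pr <- pairwisePrecisionRecall(perfect, truth)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  split_part <- makePartition(list(c("a", "b"), "c"))
  pr2 <- pairwisePrecisionRecall(split_part, truth)
  expect_equal(pr2$precision, 1)
  expect_equal(pr2$recall, 1 / 3)
  singletons <- makePartition(list("a", "b", "c"))
  pr3 <- pairwisePrecisionRecall(singletons, truth)
  expect_true(is.na(pr3$precision))  # 0/0 reported as undefined
  expect_equal(pr3$recall, 0)
})

test_that("lineage graphs collapse identical sequences and honor nearest-neighbor ties", {
  same <- do.call(rbind, lapply(1:3, function(i)
    makeRecord(paste0("s", i), cdr3 = "CAAAAW")))
  g1 <- buildLineageGraph(same, collapseOn = "cdr3_aa")
  expect_equal(nrow(graphNodes(g1)), 1)
  expect_equal(graphNodes(g1)$weight, 3)
  expect_equal(nrow(graphEdges(g1)), 0)

  two <- makeRecords(makeRecord("a", cdr3 = "CAAAAW"),
                     makeRecord("b", cdr3 = "CAAATW"))
  g2 <- buildLineageGraph(two, collapseOn = "cdr3_aa")
  expect_equal(nrow(graphEdges(g2)), 1)

  # center equidistant to two flanks: one edge per tied nearest neighbor
  tri <- makeRecords(makeRecord("c", cdr3 = "CAAAAW"),
                     makeRecord("l", cdr3 = "CAAATW"),
                     makeRecord("r", cdr3 = "CATAAW"))
  g3 <- buildLineageGraph(tri, collapseOn = "cdr3_aa")
  expect_equal(nrow(graphEdges(g3)), 2)
  center <- graphNodes(g3)$node_id[graphNodes(g3)$sequence == "CAAAAW"]
  expect_true(all(apply(graphEdges(g3)[, c("from", "to")], 1,
                        function(e) center %in% e)))
  # node weights sum to the lineage size
  expect_equal(sum(graphNodes(g3)$weight), 3)
})

test_that("graph export writes GraphML and edge lists", {
  two <- makeRecords(makeRecord("a", cdr3 = "CAAAAW"),
                     makeRecord("b", cdr3 = "CAAATW"))
  g <- buildLineageGraph(two, collapseOn = "cdr3_aa")
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeLineageGraph(g, gml)
  expect_true(file.exists(gml))
  expect_match(paste(readLines(gml, warn = FALSE), collapse = ""),
               "graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLineageGraph(g, tsv, format = "edgelist")
  expect_equal(nrow(utils::read.delim(tsv)), 1)
})

test_that("the evaluation report bundles valid summaries", {
  set.seed(41)
  sim <- simulateRepertoire(simConfig(nLineages = 60, nDonors = 2,
                                      seed = 41))
  part <- assignLineages(sim$records)
  donors <- stats::setNames(sim$truth$donor_id, sim$truth$sequence_id)
  truth <- stats::setNames(sim$truth$true_lineage_id,
                           sim$truth$sequence_id)
  rep <- evaluationReport(sim$records, part, donors = donors,
                          truth = truth)
  expect_true(rep$clonality_fraction >= 0 && rep$clonality_fraction <= 1)
  expect_true(rep$contamination_fraction >= 0 &&
              rep$contamination_fraction <= 1)
  expect_true(rep$pairwise_precision >= 0 && rep$pairwise_precision <= 1)
  expect_true(rep$pairwise_recall >= 0 && rep$pairwise_recall <= 1)
  expect_equal(sum(rep$size_histogram$n_lineages * rep$size_histogram$size),
               rep$n_sequences)
  expect_equal(nrow(rep$feature_table), rep$n_lineages)
})
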