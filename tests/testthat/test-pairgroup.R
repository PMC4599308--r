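# classOf map used throughout: H* homodimer, M* monomer.
classMap <- function(ids) {
  stats::setNames(ifelse(startsWith(ids, "H"), "homodimer", "monomer"),
                  ids)
}

test_that("hit ranking collapses multi-HSP pairs and sorts deterministically", {
  hits <- data.frame(
    query_id = "H0",
    subject_id = c("S1", "S1", "S3", "S2", "H0"),
    percent_identity = 50,
    hsp_length = c(100L, 40L, 80L, 80L, 200L),
    evalue = c(1e-50, 1e-10, 1e-20, 1e-20, 0),
    bitscore = c(200, 50, 90, 110, 500),
    stringsAsFactors = FALSE)
  r <- rankedHits(hits, "H0")
  expect_equal(r$subject_id, c("S1", "S2", "S3"))   # self-hit dropped
  expect_equal(r$hsp_length[r$subject_id == "S1"], 100L)  # first HSP kept
  # equal e-values: bitscore descending decides
  expect_lt(which(r$subject_id == "S2"), which(r$subject_id == "S3"))
})

test_that("first-cross builds both subgroups at the minimum-five boundary", {
  ids <- c("H0", paste0("H", 1:4), paste0("M", 0:5))
  hits <- rbind(
    makeHits("H0", c(paste0("H", 1:4), paste0("M", 0:5))),
    makeHits("M0", c(paste0("M", 1:4), paste0("H", 0:4), "M5")))
  g <- buildPairGroup("H0", hits, classMap(ids))
  expect_s4_class(g, "PairGroup")
  expect_setequal(interactingIds(g), c("H0", paste0("H", 1:4)))
  expect_setequal(noninteractingIds(g), paste0("M", 0:4))
  expect_equal(anchorMonomerId(g), "M0")
  expect_equal(hspLength(g), 100L)
  # every H member sits strictly above the anchor in the query ranking
  r <- rankedHits(hits, "H0")
  anchorRank <- which(r$subject_id == "M0")
  expect_true(all(match(setdiff(interactingIds(g), "H0"),
                        r$subject_id) < anchorRank))
})

test_that("too-small subgroups and monomer-first queries give no group", {
  ids <- c("H0", "H1", paste0("M", 0:5))
  # first hit is a monomer: H = {query} only
  hits <- rbind(makeHits("H0", c(paste0("M", 0:5), "H1")),
                makeHits("M0", c(paste0("M", 1:5), "H0", "H1")))
  expect_null(buildPairGroup("H0", hits, classMap(ids)))
  expect_error(buildPairGroup("M0", hits, classMap(ids)),
               "not a homodimer")
})

test_that("fixed e-value scheme drops hits weaker than the cutoff", {
  ids <- c("H0", paste0("H", 1:6), paste0("M", 0:6))
  hits <- rbind(
    makeHits("H0", c(paste0("H", 1:6), paste0("M", 0:6)),
             evalues = rep(1e-5, 13)),
    makeHits("M0", c(paste0("M", 1:6), paste0("H", 0:6)),
             evalues = rep(1e-5, 13)))
  expect_null(buildPairGroup("H0", hits, classMap(ids),
                             scheme = "fixed_evalue",
                             fixedEvalue = 1e-10))
  # with a permissive cutoff the same hits qualify
  g <- buildPairGroup("H0", hits, classMap(ids),
                      scheme = "fixed_evalue", fixedEvalue = 1e-3)
  expect_s4_class(g, "PairGroup")
  expect_setequal(interactingIds(g), c("H0", paste0("H", 1:6)))
})

test_that("mixed scheme with zero pollution is exactly first-cross", {
  set.seed(5)
  for (i in 1:25) {
    nH <- sample(5:12, 1); nM <- sample(5:12, 1)
    ids <- c(paste0("H", seq_len(nH) - 1L), paste0("M", seq_len(nM) - 1L))
    others <- sample(setdiff(ids, "H0"))        # random interleaving
    hits <- rbind(
      makeHits("H0", others),
      makeHits(grep("^M", others, value = TRUE)[1L],
               sample(setdiff(ids, grep("^M", others, value = TRUE)[1L]))))
    fc <- buildPairGroup("H0", hits, classMap(ids), minSubgroup = 2L)
    mx <- buildPairGroup("H0", hits, classMap(ids), scheme = "mixed20",
                         mixFraction = 0, minSubgroup = 2L)
    if (is.null(fc)) {
      expect_null(mx)
    } else {
      expect_setequal(interactingIds(mx), interactingIds(fc))
      expect_setequal(noninteractingIds(mx), noninteractingIds(fc))
    }
  }
})

test_that("mixed scheme pollutes subgroups within the stated bound", {
  ids <- c("H0", paste0("H", 1:9), paste0("M", 0:9))
  ranked <- c("H1", "H2", "H3", "M0", "H4", "H5", "H6", "M1",
              "H7", "M2", "M3", "M4", "M5")
  hits <- rbind(makeHits("H0", ranked),
                makeHits("M0", c("M1", "M2", "H8", "M3", "M4",
                                 "H0", "H2", "M5")))
  g <- buildPairGroup("H0", hits, classMap(ids), scheme = "mixed20",
                      mixFraction = 0.2, minSubgroup = 2L)
  cls <- classMap(ids)
  fracM <- mean(cls[interactingIds(g)] == "monomer")
  fracH <- mean(cls[noninteractingIds(g)] == "homodimer")
  expect_lte(fracM, 0.2)
  expect_lte(fracH, 0.2)
  expect_gt(fracM, 0)   # pollution actually happened on both sides
  expect_gt(fracH, 0)
  # pollution reaches past the pure first-cross prefix
  fc <- buildPairGroup("H0", hits, classMap(ids), minSubgroup = 2L)
  expect_gt(length(interactingIds(g)), length(interactingIds(fc)))
})

test_that("lower-of-two is a strict subset selection of first-cross", {
  set.seed(9)
  for (i in 1:15) {
    nH <- sample(6:12, 1); nM <- sample(6:12, 1)
    ids <- c(paste0("H", seq_len(nH) - 1L), paste0("M", seq_len(nM) - 1L))
    others <- sample(setdiff(ids, "H0"))
    anchor <- grep("^M", others, value = TRUE)[1L]
    hits <- rbind(makeHits("H0", others),
                  makeHits(anchor, sample(setdiff(ids, anchor))))
    fc <- buildPairGroup("H0", hits, classMap(ids), minSubgroup = 2L)
    lo <- buildPairGroup("H0", hits, classMap(ids),
                         scheme = "lower_of_two", minSubgroup = 2L)
    if (!is.null(lo)) {
      expect_true(all(interactingIds(lo) %in% interactingIds(fc)))
      expect_true(all(noninteractingIds(lo) %in% noninteractingIds(fc)))
    }
  }
})

test_that("HSP and query-length filters are inclusive and monotone", {
  sim <- simulatePairGroup(simSpec(seed = 3, nColumns = 60L))
  classOf <- stats::setNames(sim$truth$true_class, sim$truth$seq_id)
  g <- buildPairGroup("H001", sim$hits, classOf)   # hsp = 60
  recs <- makeRecords(
    stats::setNames(gsub("-", "", alignedRows(sim$alignment)),
                    names(alignedRows(sim$alignment))),
    sim$truth$true_class)

  expect_length(filterPairGroups(list(g), recs, minHsp = 61L), 0L)
  expect_length(filterPairGroups(list(g), recs, minHsp = 60L), 1L)
  expect_length(filterPairGroups(list(g), recs), 1L)
  expect_length(filterPairGroups(list(g), recs, minQueryLen = 61L), 0L)
  expect_length(filterPairGroups(list(g), recs, minQueryLen = 60L), 1L)

  # raising either threshold never adds groups
  n1 <- length(filterPairGroups(list(g), recs, minHsp = 10L))
  n2 <- length(filterPairGroups(list(g), recs, minHsp = 100L))
  expect_gte(n1, n2)
})

test_that("groups with identical membership collapse to one", {
  sim <- simulatePairGroup(simSpec(seed = 4))
  classOf <- stats::setNames(sim$truth$true_class, sim$truth$seq_id)
  g <- buildPairGroup("H001", sim$hits, classOf)
  expect_length(uniquePairGroups(list(g, g)), 1L)
})
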