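# Shared fixture builders and independent oracles used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

writeFastaFile <- function(headers, seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), f)
  f
}

# A labelled sequence set without touching the FASTA reader.
makeRecords <- function(seqs, classes) {
  x <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(x)$interactionClass <- classes
  x
}

# Small hand-built alignment: query row first.
toyAlignment <- function() {
  AlignedGroup(
    c(Q = "MKAVL", H2 = "MKAVL", H3 = "MRAVL",
      M1 = "MKGIL", M2 = "MKGIL"),
    c("homodimer", "homodimer", "homodimer", "monomer", "monomer"),
    "Q")
}

toyAnnotations <- function(n = 5L,
                           classes = c("interface", "interface",
                                       "surface", "buried", "surface")) {
  asa <- ifelse(classes == "buried", 0, 50)
  bsa <- ifelse(classes == "interface", 10, 0)
  annotateResidueClasses(data.frame(
    residue_index = seq_len(n), amino_acid = rep("A", n),
    asa = asa[seq_len(n)], bsa = bsa[seq_len(n)],
    stringsAsFactors = FALSE))
}

# Random composition over the 20 amino acids with a given support size.
randomProfile <- function(support = sample(2:6, 1L)) {
  idx <- sample(seq_along(AA), support)
  w <- stats::runif(support)
  p <- stats::setNames(numeric(20L), AA)
  p[idx] <- w / sum(w)
  p
}

# Term-by-term evaluation of the harmony formula, written independently
# of shScore: explicit loop over residues, explicit 0*log0 handling.
shTermwise <- function(pH, pM) {
  acc <- 0
  for (x in seq_along(pH)) {
    s <- pH[x] + pM[x]
    if (pH[x] > 0) acc <- acc - 0.5 * pH[x] * log(pH[x] / s, base = 2)
    if (pM[x] > 0) acc <- acc - 0.5 * pM[x] * log(pM[x] / s, base = 2)
  }
  unname(acc)
}

# Exhaustive AUC oracle: count positive-negative pairs scoring the
# positive higher (1), tied (1/2) or lower (0), on predictor -sh.
aucPairCount <- function(sh, isPos) {
  pos <- -sh[isPos]
  neg <- -sh[!isPos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Trapezoidal area under the ROC obtained by sweeping the SH threshold.
aucTrapezoid <- function(sh, isPos) {
  ths <- sort(unique(sh))
  tpr <- vapply(ths, function(t) mean(sh[isPos] <= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(sh[!isPos] <= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Hamming identity over equal-length gap-free strings: identical
# positions / length, in percent.  Used where the global alignment is
# trivially the residue-by-residue correspondence.
hammingIdentity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# Straight-line re-statement of greedy longest-first clustering over a
# user-supplied identity function.
greedyClusterOracle <- function(seqs, ids, threshold, identityFun) {
  ord <- order(-nchar(seqs), ids)
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      if (identityFun(seqs[i], seqs[r]) >= threshold) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, i)
  }
  sort(ids[reps])
}

# Hit table in the 6 parsed columns for a set of ranked subjects.
makeHits <- function(queryId, subjects, classesIgnored = NULL,
                     evalues = NULL, hsp = 100L) {
  k <- length(subjects)
  if (is.null(evalues)) evalues <- 10^(seq(-60, -5, length.out = k))
  data.frame(query_id = queryId, subject_id = subjects,
             percent_identity = 50, hsp_length = hsp,
             evalue = evalues, bitscore = seq(300, 100, length.out = k),
             stringsAsFactors = FALSE)
}
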