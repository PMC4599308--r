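#' Specify a synthetic pair group
#'
#' Builds a \linkS4class{SimSpec}.  Defaults mirror the make-up of a
#' typical observed pair group: 25 interacting and 14 non-interacting
#' members, and a residue budget split into roughly 12 % interface,
#' 48 % other surface and 40 % buried positions, matching the
#' proportions seen in the worked structural examples.  When the
#' column sets are not given they are sampled (disjointly, covering
#' all columns) from the spec's own seed, so a spec is fully
#' determined by its arguments.
#'
#' @param nH,nM subgroup sizes, each at least 5.
#' @param nColumns alignment length (default 120).
#' @param interfaceColumns,surfaceColumns,buriedColumns optional
#'   disjoint 1-based index sets covering \code{1:nColumns}.
#' @param specificity probability an interface column is generated
#'   with disjoint group alphabets (default 0.6).
#' @param conservationBuried dominant-residue probability at buried
#'   columns (default 0.95).
#' @param substitutionRate probability a residue is redrawn from its
#'   column pool (default 0.1).
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimSpec}.
#' @export
simSpec <- function(nH = 25L, nM = 14L, nColumns = 120L,
                    interfaceColumns = NULL, surfaceColumns = NULL,
                    buriedColumns = NULL, specificity = 0.6,
                    conservationBuried = 0.95, substitutionRate = 0.1,
                    seed = 1L) {
  nColumns <- as.integer(nColumns)
  if (is.null(interfaceColumns) && is.null(surfaceColumns) &&
      is.null(buriedColumns)) {
    nInt <- max(1L, round(0.12 * nColumns))
    nSur <- max(1L, round(0.48 * nColumns))
    parts <- withSeed(seed, {
      idx <- sample.int(nColumns)
      list(interface = idx[seq_len(nInt)],
           surface = idx[nInt + seq_len(min(nSur, nColumns - nInt))],
           buried = idx[-seq_len(min(nInt + nSur, nColumns))])
    })
    interfaceColumns <- parts$interface
    surfaceColumns <- parts$surface
    buriedColumns <- parts$buried
  }
  new("SimSpec", nH = as.integer(nH), nM = as.integer(nM),
      nColumns = nColumns,
      interfaceColumns = as.integer(sort(interfaceColumns)),
      surfaceColumns = as.integer(sort(surfaceColumns)),
      buriedColumns = as.integer(sort(buriedColumns)),
      specificity = specificity,
      conservationBuried = conservationBuried,
      substitutionRate = substitutionRate, seed = as.integer(seed))
}

drawColumn <- function(n, pool, weights = NULL) {
  if (length(pool) == 1L) rep(pool, n)
  else sample(pool, n, replace = TRUE, prob = weights)
}

#' Simulate one pair group with planted interface specificity
#'
#' Generates a gapless alignment of \code{nH} interacting and
#' \code{nM} non-interacting rows, column by column:
#' \itemize{
#'   \item buried columns: one dominant residue shared by both groups,
#'     used with probability \code{conservationBuried} (high
#'     conservation, low entropy — the hydrophobic-core pattern);
#'   \item surface columns: both groups draw from a shared, moderately
#'     diverse residue pool;
#'   \item interface columns: with probability \code{specificity} the
#'     two groups draw from disjoint residue alphabets (planted
#'     specificity, SH towards 0); otherwise the column behaves like a
#'     surface column.
#' }
#' Annotations assign ASA/BSA consistently with the planted classes,
#' and ranked hits are generated so that the first-cross rule recovers
#' exactly the simulated membership (tight homodimer hits above the
#' anchor monomer for the query; tight monomer hits above the first
#' homodimer for the anchor).  Everything is deterministic given the
#' spec's seed.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @return list with \code{alignment} (\linkS4class{AlignedGroup}),
#'   \code{annotations} (classified data.frame), \code{hits}
#'   (BLAST-tabular-shaped data.frame), \code{truth} (data.frame of
#'   seq_id, true_class, assigned_class, subgroup), and \code{spec}.
#' @export
simulatePairGroup <- function(spec) {
  stopifnot(methods::is(spec, "SimSpec"))
  methods::validObject(spec)
  withSeed(spec@seed, simulateEngine(spec))
}

simulateEngine <- function(spec) {
  nH <- spec@nH; nM <- spec@nM; nc <- spec@nColumns
  n <- nH + nM
  ids <- c(sprintf("H%03d", seq_len(nH)), sprintf("M%03d", seq_len(nM)))
  trueClass <- rep(c("homodimer", "monomer"), c(nH, nM))
  isH <- trueClass == "homodimer"

  m <- matrix("", nrow = n, ncol = nc, dimnames = list(ids, NULL))
  colType <- character(nc)
  colType[spec@interfaceColumns] <- "interface"
  colType[spec@surfaceColumns] <- "surface"
  colType[spec@buriedColumns] <- "buried"

  asa <- bsa <- numeric(nc)
  for (j in seq_len(nc)) {
    type <- colType[j]
    if (type == "buried") {
      # conserved core: one dominant residue with occasional
      # conservative substitutions drawn from a small pool shared by
      # both groups, so buried columns are low-entropy and high-overlap
      dom <- sample(AA20, 1L)
      minor <- sample(setdiff(AA20, dom), 2L)
      keep <- stats::runif(n) < spec@conservationBuried
      col <- rep(dom, n)
      if (any(!keep))
        col[!keep] <- sample(minor, sum(!keep), replace = TRUE)
      poolH <- poolM <- c(dom, minor)
      asa[j] <- 0; bsa[j] <- 0
    } else {
      specific <- type == "interface" && stats::runif(1L) < spec@specificity
      if (specific) {
        letters <- sample(AA20, 6L)
        poolH <- letters[1:3]
        poolM <- letters[4:6]
      } else {
        poolH <- poolM <- sample(AA20, 5L)
      }
      col <- character(n)
      col[isH] <- drawColumn(nH, poolH)
      col[!isH] <- drawColumn(nM, poolM)
      asa[j] <- round(stats::runif(1L, 15, 120), 1)
      bsa[j] <- if (type == "interface")
        round(stats::runif(1L, 2, min(40, asa[j])), 1) else 0
    }
    # within-pool churn: resample a fraction of rows from their own pool
    redraw <- stats::runif(n) < spec@substitutionRate
    if (any(redraw & isH)) col[redraw & isH] <-
        drawColumn(sum(redraw & isH), poolH)
    if (any(redraw & !isH)) col[redraw & !isH] <-
        drawColumn(sum(redraw & !isH), poolM)
    m[, j] <- col
  }

  rows <- setNames(apply(m, 1L, paste, collapse = ""), ids)
  queryId <- ids[1L]
  alignment <- AlignedGroup(rows, trueClass, queryId)

  annotations <- annotateResidueClasses(data.frame(
    residue_index = seq_len(nc),
    amino_acid = m[queryId, ],
    asa = asa, bsa = bsa, stringsAsFactors = FALSE))

  hits <- simulateHits(ids[isH], ids[!isH], nc)

  truth <- data.frame(seq_id = ids, true_class = trueClass,
                      assigned_class = trueClass,
                      subgroup = ifelse(isH, "H", "M"),
                      stringsAsFactors = FALSE)
  list(alignment = alignment, annotations = annotations, hits = hits,
       truth = truth, spec = spec)
}

# Ranked hits such that first-cross reconstructs the membership: the
# query sees all other H members at tiny e-values, then the anchor
# monomer, then the remaining monomers; the anchor sees all other M
# members, then the query, then the remaining homodimers.
simulateHits <- function(hIds, mIds, hspLen) {
  query <- hIds[1L]
  anchor <- mIds[1L]
  hitRows <- function(q, subjects) {
    k <- length(subjects)
    if (!k) return(NULL)
    data.frame(query_id = q, subject_id = subjects,
               percent_identity = round(seq(95, 40,
                                            length.out = max(k, 2L))[seq_len(k)], 1),
               hsp_length = hspLen, mismatches = 0L, gap_opens = 0L,
               qstart = 1L, qend = hspLen, sstart = 1L, send = hspLen,
               evalue = 10^(seq(-150, -5,
                               length.out = max(k, 2L))[seq_len(k)]),
               bitscore = round(500 - 5 * seq_len(k), 1),
               stringsAsFactors = FALSE)
  }
  rbind(hitRows(query, c(hIds[-1L], anchor, mIds[-1L])),
        hitRows(anchor, c(mIds[-1L], query, hIds[-1L])))
}

#' Simulate a pair group with polluted subgroup labels
#'
#' Generates the same pair group as [simulatePairGroup()] and then
#' swaps up to \code{mixFraction} of each subgroup's members with the
#' other class: the assigned scoring groups then contain members whose
#' true class differs, emulating relaxed e-value thresholds that mix
#' the classes.  The truth table records both labels.
#'
#' @param spec a \linkS4class{SimSpec}.
#' @param mixFraction fraction in [0, 0.5] of each subgroup to pollute.
#' @return as [simulatePairGroup()]; \code{alignment} carries the
#'   assigned classes.
#' @export
simulateMixedLabels <- function(spec, mixFraction) {
  if (mixFraction < 0 || mixFraction > 0.5)
    stop("mixFraction must be in [0, 0.5]")
  sim <- simulatePairGroup(spec)
  k <- min(floor(mixFraction * spec@nH), floor(mixFraction * spec@nM))
  if (k == 0L) return(sim)
  truth <- sim$truth
  swap <- withSeed(spec@seed + 1L, {
    hSwap <- sample(which(truth$true_class == "homodimer" &
                            truth$seq_id != queryId(sim$alignment)), k)
    mSwap <- sample(which(truth$true_class == "monomer"), k)
    list(h = hSwap, m = mSwap)
  })
  truth$assigned_class[swap$h] <- "monomer"
  truth$assigned_class[swap$m] <- "homodimer"
  truth$subgroup <- ifelse(truth$assigned_class == "homodimer", "H", "M")
  sim$truth <- truth
  sim$alignment <- AlignedGroup(alignedRows(sim$alignment),
                                truth$assigned_class,
                                queryId(sim$alignment))
  sim
}

#' Write a simulated pair group as pipeline input files
#'
#' Materialises one simulated pair group in the on-disk layout the
#' pipeline consumes: \code{homodimers.fasta} / \code{monomers.fasta}
#' (by *assigned* class), \code{hits.tsv} (BLAST tabular),
#' \code{alignments/<query>.afa}, \code{annotations/<query>.tsv} and
#' \code{truth.json}.
#'
#' @param sim result of [simulatePairGroup()] or
#'   [simulateMixedLabels()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  rows <- alignedRows(sim$alignment)
  cls <- setNames(sim$truth$assigned_class, sim$truth$seq_id)[names(rows)]
  degapped <- gsub("[-.]", "", rows)
  for (cl in c("homodimer", "monomer")) {
    f <- file.path(dir, paste0(if (cl == "homodimer") "homodimers"
                               else "monomers", ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(degapped[cls == cl]), f)
  }
  utils::write.table(sim$hits, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  q <- queryId(sim$alignment)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(rows),
                              file.path(dir, "alignments",
                                        paste0(q, ".afa")))
  ann <- sim$annotations
  utils::write.table(
    ann[, c("residue_index", "amino_acid", "asa", "bsa")],
    file.path(dir, "annotations", paste0(q, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
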