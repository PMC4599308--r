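#' Amino-acid composition of one alignment column per subgroup
#'
#' Counts residues at a column separately for the interacting (H) and
#' non-interacting (M) rows and normalises to frequencies over the 20
#' canonical amino acids.  Gap characters and \code{X} carry no
#' compositional information and are excluded; a subgroup with no
#' countable residue at the column gets an all-zero vector and is
#' flagged empty.
#'
#' @param group an \linkS4class{AlignedGroup}.
#' @param column 1-based column index.
#' @return list with \code{column_index}, \code{freq_H}, \code{freq_M}
#'   (named 20-vectors), \code{n_ungapped_H}, \code{n_ungapped_M},
#'   \code{empty_H}, \code{empty_M}.
#' @export
columnProfile <- function(group, column) {
  if (column < 1L || column > nColumns(group))
    stop("column ", column, " out of range 1..", nColumns(group))
  m <- alignmentMatrix(group)
  cls <- rowClasses(group)
  list(column_index = as.integer(column),
       freq_H = columnFreq(m[cls == "homodimer", column]),
       freq_M = columnFreq(m[cls == "monomer", column]),
       n_ungapped_H = sum(m[cls == "homodimer", column] %in% AA20),
       n_ungapped_M = sum(m[cls == "monomer", column] %in% AA20),
       empty_H = !any(m[cls == "homodimer", column] %in% AA20),
       empty_M = !any(m[cls == "monomer", column] %in% AA20))
}

columnFreq <- function(letters) {
  counts <- table(factor(letters[letters %in% AA20], levels = AA20))
  n <- sum(counts)
  f <- setNames(numeric(20L), AA20)
  if (n > 0L) f[] <- as.numeric(counts) / n
  f
}

alignmentMatrix <- function(group) {
  rows <- alignedRows(group)
  matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(rows), byrow = TRUE, dimnames = list(names(rows)))
}

#' Shannon entropy of an amino-acid frequency vector
#'
#' \eqn{S = -\sum_x p_x \log_2 p_x} over the 20 amino-acid types, with
#' \eqn{0 \log 0 := 0}.  Low entropy means high conservation; the
#' maximum \eqn{\log_2 20 \approx 4.32} bits is reached at the uniform
#' composition.
#'
#' @param freq numeric vector of frequencies summing to 1.
#' @return entropy in bits.
#' @examples
#' shannonEntropy(c(1, rep(0, 19)))          # 0, fully conserved
#' shannonEntropy(c(0.5, 0.5, rep(0, 18)))   # 1 bit
#' @export
shannonEntropy <- function(freq) {
  if (abs(sum(freq) - 1) > 1e-6)
    stop("frequency vector must sum to 1 (got ", sum(freq), ")")
  if (any(freq < 0)) stop("frequencies must be non-negative")
  p <- freq[freq > 0]
  -sum(p * log2(p))
}

#' Sequence Harmony: compositional overlap between two groups
#'
#' For column compositions \eqn{p^H} and \eqn{p^M} of the interacting
#' and non-interacting subgroups,
#' \deqn{SH = -\tfrac12 \sum_x p^H_x \log_2 \frac{p^H_x}{p^H_x + p^M_x}
#'        -\tfrac12 \sum_x p^M_x \log_2 \frac{p^M_x}{p^H_x + p^M_x},}
#' with \eqn{0\log 0 := 0} and terms with \eqn{p^H_x + p^M_x = 0}
#' contributing nothing.  SH = 0 when no residue type co-occurs in the
#' two groups (complete specificity) and SH = 1 when the compositions
#' are identical (complete overlap).  Base-2 logarithms make the
#' identical-composition case exactly 1.  The result is clamped to
#' [0, 1] within 1e-9 to absorb rounding.
#'
#' @param freqH,freqM frequency vectors over the same residue alphabet,
#'   each summing to 1.
#' @return SH score in [0, 1].
#' @examples
#' a <- c(A = 1, V = 0); v <- c(A = 0, V = 1)
#' shScore(a, v)                 # 0: disjoint support
#' shScore(a, a)                 # 1: identical composition
#' @export
shScore <- function(freqH, freqM) {
  if (length(freqH) != length(freqM))
    stop("frequency vectors must have equal length")
  for (v in list(freqH, freqM)) {
    if (abs(sum(v) - 1) > 1e-6)
      stop("frequency vector must sum to 1 (got ", sum(v), ")")
    if (any(v < 0)) stop("frequencies must be non-negative")
  }
  tot <- freqH + freqM
  hTerm <- ifelse(freqH > 0, freqH * log2(freqH / tot), 0)
  mTerm <- ifelse(freqM > 0, freqM * log2(freqM / tot), 0)
  sh <- -0.5 * sum(hTerm) - 0.5 * sum(mTerm)
  if (sh < -1e-9 || sh > 1 + 1e-9)
    stop("SH outside [0,1] beyond numerical tolerance: ", sh)
  abs(min(max(sh, 0), 1))  # abs() folds IEEE -0 to 0
}

#' Score every column of a pair-group alignment
#'
#' Computes, for each alignment column, the per-subgroup composition,
#' Shannon entropies and the Sequence Harmony score, and maps columns
#' to residue positions of the query by counting its non-gap
#' characters left to right (1-based).  Columns where either subgroup
#' has no countable residue get \code{NA} scores and are excluded from
#' prediction and evaluation downstream.
#'
#' @param group an \linkS4class{AlignedGroup}.
#' @return data.frame with one row per column: \code{column_index}
#'   (0-based, matching the on-disk score table convention),
#'   \code{query_residue_index} (1-based, \code{NA} at query gaps),
#'   \code{query_aa}, \code{n_H}, \code{n_M}, \code{entropy_H},
#'   \code{entropy_M}, \code{sh}.
#' @export
scoreGroup <- function(group) {
  m <- alignmentMatrix(group)
  cls <- rowClasses(group)
  if (!any(cls == "homodimer") || !any(cls == "monomer"))
    stop("both subgroups must be non-empty")
  mH <- m[cls == "homodimer", , drop = FALSE]
  mM <- m[cls == "monomer", , drop = FALSE]
  nc <- ncol(m)

  countsH <- apply(mH, 2L, function(col)
    table(factor(col[col %in% AA20], levels = AA20)))
  countsM <- apply(mM, 2L, function(col)
    table(factor(col[col %in% AA20], levels = AA20)))
  nH <- colSums(countsH)
  nM <- colSums(countsM)

  entH <- entM <- sh <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    if (nH[j] > 0L) entH[j] <- shannonEntropy(countsH[, j] / nH[j])
    if (nM[j] > 0L) entM[j] <- shannonEntropy(countsM[, j] / nM[j])
    if (nH[j] > 0L && nM[j] > 0L)
      sh[j] <- shScore(countsH[, j] / nH[j], countsM[, j] / nM[j])
  }

  qrow <- m[queryId(group), ]
  isRes <- !(qrow %in% GAP_CHARS)
  qidx <- rep(NA_integer_, nc)
  qidx[isRes] <- seq_len(sum(isRes))

  data.frame(column_index = seq_len(nc) - 1L,
             query_residue_index = qidx,
             query_aa = qrow,
             n_H = as.integer(nH), n_M = as.integer(nM),
             entropy_H = entH, entropy_M = entM, sh = sh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean entropy and SH per structural position class
#'
#' Joins scored columns to classified residue annotations via the
#' query residue index and averages the interacting-subgroup entropy
#' and the SH score within each position class.  Columns without a
#' matching annotated residue, and columns without a defined SH, are
#' dropped.
#'
#' @param scores score table from [scoreGroup()].
#' @param annotations classified annotations (see
#'   [annotateResidueClasses()]).
#' @return data.frame with columns \code{position_class}, \code{n},
#'   \code{mean_entropy_H}, \code{mean_sh}; classes with no matched
#'   column are absent.  Returns a zero-row frame (empty join) when
#'   nothing matches.
#' @export
meanScoresByClass <- function(scores, annotations) {
  if (is.null(annotations$position_class))
    stop("annotations must be classified first; see annotateResidueClasses()")
  j <- merge(scores[!is.na(scores$query_residue_index) &
                      !is.na(scores$sh), ],
             annotations[, c("residue_index", "position_class")],
             by.x = "query_residue_index", by.y = "residue_index")
  if (!nrow(j))
    return(data.frame(position_class = character(), n = integer(),
                      mean_entropy_H = numeric(), mean_sh = numeric(),
                      stringsAsFactors = FALSE))
  agg <- do.call(rbind, lapply(split(j, droplevels(j$position_class)),
    function(d) data.frame(position_class = as.character(d$position_class[1L]),
                           n = nrow(d),
                           mean_entropy_H = mean(d$entropy_H),
                           mean_sh = mean(d$sh),
                           stringsAsFactors = FALSE)))
  row.names(agg) <- NULL
  agg
}
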