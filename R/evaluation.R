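#' Two-state interface prediction at an SH cutoff
#'
#' Residues whose column scores at or below the cutoff are predicted
#' to be interface.  The default cutoff of 0.2 is the recommended
#' operating point of the Sequence Harmony score for selecting
#' specificity-bearing positions.
#'
#' @param scores score table from [scoreGroup()].
#' @param cutoff inclusive SH threshold (default 0.2).
#' @return sorted integer vector of predicted query residue indices.
#' @export
predictInterface <- function(scores, cutoff = 0.2) {
  ok <- !is.na(scores$sh) & !is.na(scores$query_residue_index) &
    scores$sh <= cutoff
  sort(unique(scores$query_residue_index[ok]))
}

#' Confusion counts of an interface prediction
#'
#' Positives are annotated interface residues; negatives are surface
#' plus buried residues (\code{universe = "all_classified"}) or surface
#' residues only (\code{universe = "surface_only"}, for contrasting
#' interface against the rest of the protein surface).  Counts are
#' taken over residues that are both annotated and, when
#' \code{scoredResidues} is supplied, scored.
#'
#' @param predicted integer vector of predicted residue indices; must
#'   be a subset of the annotated residues.
#' @param annotations classified annotation table.
#' @param universe which residues count as negatives.
#' @param scoredResidues optional integer vector of residue indices
#'   that received a defined SH score; residues outside it are excluded
#'   from the evaluation entirely.
#' @return named integer vector \code{c(tp, fp, tn, fn)}.
#' @export
confusionCounts <- function(predicted, annotations,
                            universe = c("all_classified", "surface_only"),
                            scoredResidues = NULL) {
  universe <- match.arg(universe)
  if (is.null(annotations$position_class))
    stop("annotations must be classified first; see annotateResidueClasses()")
  ann <- annotations
  if (!is.null(scoredResidues))
    ann <- ann[ann$residue_index %in% scoredResidues, , drop = FALSE]
  if (universe == "surface_only")
    ann <- ann[ann$position_class != "buried", , drop = FALSE]
  outside <- setdiff(predicted, annotations$residue_index)
  if (length(outside))
    stop("predicted residue(s) outside the annotated set: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  predicted <- intersect(predicted, ann$residue_index)
  pos <- ann$residue_index[ann$position_class == "interface"]
  neg <- setdiff(ann$residue_index, pos)
  c(tp = length(intersect(predicted, pos)),
    fp = length(intersect(predicted, neg)),
    tn = length(setdiff(neg, predicted)),
    fn = length(setdiff(pos, predicted)))
}

#' Recall, false positive rate and precision from confusion counts
#'
#' Recall (true positive rate, coverage) = TP/(TP+FN); FPR =
#' FP/(TN+FP); precision (positive predictive value) = TP/(TP+FP).
#' A metric whose denominator is zero is \code{NA}.
#'
#' @param counts named vector with elements \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @return named numeric vector \code{c(recall, fpr, precision)}.
#' @examples
#' predictionMetrics(c(tp = 21, fp = 64, tn = 167, fn = 10))
#' @export
predictionMetrics <- function(counts) {
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts)))
    stop("counts must contain tp, fp, tn, fn")
  if (any(counts[need] < 0)) stop("counts must be non-negative")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  c(recall = ratio(tp, tp + fn),
    fpr = ratio(fp, tn + fp),
    precision = ratio(tp, tp + fp))
}

# Rank-sum (Mann-Whitney) AUC with midranks for ties: the probability
# that a random positive outranks a random negative, counting ties 1/2.
aucRankSum <- function(score, isPositive) {
  nPos <- sum(isPositive)
  nNeg <- sum(!isPositive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[isPositive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Threshold-free ROC AUC of the SH signal
#'
#' Treats lower SH as more interface-like (predictor score is
#' \code{-sh}) and computes the area under the ROC curve by the
#' rank-sum (Mann-Whitney) formulation with midranks for ties, which
#' equals the trapezoidal area under the ROC obtained by sweeping the
#' SH threshold.
#'
#' @inheritParams confusionCounts
#' @param scores score table from [scoreGroup()].
#' @return AUC in [0, 1], or \code{NA} when the evaluated residues do
#'   not contain both a positive and a negative.
#' @export
rocAuc <- function(scores, annotations,
                   universe = c("all_classified", "surface_only")) {
  universe <- match.arg(universe)
  if (is.null(annotations$position_class))
    stop("annotations must be classified first; see annotateResidueClasses()")
  j <- merge(scores[!is.na(scores$query_residue_index) &
                      !is.na(scores$sh), ],
             annotations[, c("residue_index", "position_class")],
             by.x = "query_residue_index", by.y = "residue_index")
  if (universe == "surface_only")
    j <- j[j$position_class != "buried", , drop = FALSE]
  aucRankSum(-j$sh, j$position_class == "interface")
}

#' Evaluate one scored pair group against its annotations
#'
#' Applies the two-state predictor at \code{cutoff}, counts the
#' confusion against the structural classes and computes the rank-sum
#' AUC, all over residues that are both annotated and scored.
#'
#' @inheritParams rocAuc
#' @param cutoff inclusive SH threshold for the two-state predictor.
#' @param groupId identifier stored in the report.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateGroup <- function(scores, annotations, cutoff = 0.2,
                          universe = c("all_classified", "surface_only"),
                          groupId = "group") {
  universe <- match.arg(universe)
  annotations <- if (is.null(annotations$position_class))
    annotateResidueClasses(annotations) else annotations
  scored <- scores$query_residue_index[!is.na(scores$sh) &
                                         !is.na(scores$query_residue_index)]
  predicted <- predictInterface(scores, cutoff)
  predicted <- intersect(predicted, annotations$residue_index)
  k <- confusionCounts(predicted, annotations, universe,
                       scoredResidues = scored)
  m <- predictionMetrics(k)
  new("EvalReport", groupId = as.character(groupId),
      counts = vapply(k, as.integer, integer(1)),
      recall = m[["recall"]], fpr = m[["fpr"]],
      precision = m[["precision"]],
      auc = rocAuc(scores, annotations, universe),
      nEvaluated = as.integer(sum(k)))
}

#' Aggregate evaluation across pair groups
#'
#' Averages AUC over groups where it is defined (undefined ones are
#' excluded and counted) and pools the per-group class means of
#' entropy and SH into grand means per position class.
#'
#' @param reports list of \linkS4class{EvalReport}.
#' @param classMeans optional list of per-group class-mean tables from
#'   [meanScoresByClass()].
#' @return list with \code{n_groups}, \code{mean_auc},
#'   \code{n_undefined_auc}, \code{mean_recall}, \code{mean_fpr},
#'   \code{mean_precision}, and (when \code{classMeans} is given)
#'   \code{class_means}, a data.frame of per-class grand means across
#'   groups.
#' @export
aggregateReports <- function(reports, classMeans = NULL) {
  if (!length(reports)) stop("at least one report is required")
  aucs <- vapply(reports, function(r) r@auc, numeric(1))
  out <- list(
    n_groups = length(reports),
    mean_auc = if (any(!is.na(aucs))) mean(aucs, na.rm = TRUE) else NA_real_,
    n_undefined_auc = sum(is.na(aucs)),
    mean_recall = mean(vapply(reports, function(r) r@recall, numeric(1)),
                       na.rm = TRUE),
    mean_fpr = mean(vapply(reports, function(r) r@fpr, numeric(1)),
                    na.rm = TRUE),
    mean_precision = mean(vapply(reports, function(r) r@precision,
                                 numeric(1)), na.rm = TRUE))
  if (!is.null(classMeans)) {
    all <- do.call(rbind, classMeans)
    if (!is.null(all) && nrow(all)) {
      cm <- do.call(rbind, lapply(split(all, all$position_class),
        function(d) data.frame(position_class = d$position_class[1L],
                               n_groups = nrow(d),
                               mean_entropy_H = mean(d$mean_entropy_H),
                               mean_sh = mean(d$mean_sh),
                               stringsAsFactors = FALSE)))
      row.names(cm) <- NULL
      out$class_means <- cm
    }
  }
  out
}

#' Two-sided Student's t-test between per-group class means
#'
#' Classical pooled-variance two-sample t-test, used to compare e.g.
#' the per-group mean SH of interface positions against that of other
#' surface positions across pair groups.  Degenerate inputs with zero
#' pooled variance return p = 1 when the means agree and p = 0 when
#' they differ (perfect separation).  Welch's unequal-variance test is
#' available via \code{welch = TRUE}.
#'
#' @param valuesA,valuesB numeric vectors, each of length >= 2.
#' @param welch use Welch's correction instead of pooling.
#' @return list with \code{statistic} (t) and \code{p.value}.
#' @export
classDifferenceTest <- function(valuesA, valuesB, welch = FALSE) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each sample needs at least two values")
  pooledVar <- (sum((valuesA - mean(valuesA))^2) +
                  sum((valuesB - mean(valuesB))^2)) /
    (length(valuesA) + length(valuesB) - 2L)
  if (pooledVar == 0) {
    if (mean(valuesA) == mean(valuesB))
      return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(valuesA) - mean(valuesB)) * Inf,
                p.value = 0))
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = !welch,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}
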