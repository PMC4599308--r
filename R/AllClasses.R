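#' Class labels for interaction status
#'
#' The two sequence classes the method contrasts: \code{"homodimer"}
#' (interacting) and \code{"monomer"} (non-interacting).
#'
#' @keywords internal
#' @noRd
INTERACTION_CLASSES <- c("homodimer", "monomer")

PAIRGROUP_SCHEMES <- c("first_cross", "lower_of_two", "fixed_evalue",
                       "mixed20")

#' AlignedGroup: a class-labelled multiple sequence alignment
#'
#' Holds one pair-group alignment: gapped amino-acid rows (an
#' \linkS4class{AAStringSet}), the interaction class of each row, and
#' the identifier of the query homodimer whose structure supplies the
#' residue labels used in evaluation.
#'
#' @slot rows \code{AAStringSet} of gapped sequences, all the same
#'   width; names are the sequence identifiers.
#' @slot rowClass character vector parallel to \code{rows}, each
#'   \code{"homodimer"} or \code{"monomer"}.  For polluted (mixed)
#'   groups this is the *assigned* scoring group, which may differ from
#'   a member's true class.
#' @slot queryId identifier of the structure-annotated query sequence;
#'   must be among the row names.
#'
#' @seealso [readAlignedFasta()], [scoreGroup()]
#' @export
setClass("AlignedGroup",
  representation(rows = "AAStringSet",
                 rowClass = "character",
                 queryId = "character"))

setValidity("AlignedGroup", function(object) {
  msg <- character()
  n <- length(object@rows)
  if (n == 0L)
    msg <- c(msg, "alignment has no rows")
  if (length(object@rowClass) != n)
    msg <- c(msg, "rowClass length differs from number of rows")
  if (n > 0L && length(unique(Biostrings::width(object@rows))) != 1L)
    msg <- c(msg, "ragged alignment: rows have unequal gapped lengths")
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
    msg <- c(msg, "rows must have unique names")
  if (!all(object@rowClass %in% INTERACTION_CLASSES))
    msg <- c(msg, "rowClass entries must be 'homodimer' or 'monomer'")
  if (length(object@queryId) != 1L || !nzchar(object@queryId))
    msg <- c(msg, "queryId must be a single non-empty string")
  else if (n > 0L && !(object@queryId %in% names(object@rows)))
    msg <- c(msg, sprintf("query '%s' is not among the alignment rows",
                          object@queryId))
  if (n > 0L && !all(INTERACTION_CLASSES %in% object@rowClass))
    msg <- c(msg, "each interaction class needs at least one row")
  if (length(msg)) msg else TRUE
})

#' Construct an AlignedGroup
#'
#' @param rows named \code{AAStringSet} (or named character vector) of
#'   gapped rows.
#' @param rowClass character vector of interaction classes
#'   (\code{"homodimer"}/\code{"monomer"}), one per row.
#' @param queryId identifier of the structure-annotated query row.
#' @return An \linkS4class{AlignedGroup}.
#' @examples
#' AlignedGroup(c(q = "MK-V", h = "MKAV", m = "LKAV"),
#'              c("homodimer", "homodimer", "monomer"), "q")
#' @export
AlignedGroup <- function(rows, rowClass, queryId) {
  if (!methods::is(rows, "AAStringSet"))
    rows <- Biostrings::AAStringSet(rows)
  new("AlignedGroup", rows = rows,
      rowClass = unname(as.character(rowClass)),
      queryId = as.character(queryId))
}

#' @describeIn AlignedGroup-class number of alignment columns.
#' @param x,object an \code{AlignedGroup}.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname AlignedGroup-class
#' @export
setMethod("nColumns", "AlignedGroup",
          function(x) if (length(x@rows)) Biostrings::width(x@rows)[1L]
                      else 0L)

#' @describeIn AlignedGroup-class gapped rows as a named character vector.
#' @export
setGeneric("alignedRows", function(x) standardGeneric("alignedRows"))

#' @rdname AlignedGroup-class
#' @export
setMethod("alignedRows", "AlignedGroup",
          function(x) setNames(as.character(x@rows), names(x@rows)))

#' @describeIn AlignedGroup-class per-row interaction classes, named by
#'   sequence id.
#' @export
setGeneric("rowClasses", function(x) standardGeneric("rowClasses"))

#' @rdname AlignedGroup-class
#' @export
setMethod("rowClasses", "AlignedGroup",
          function(x) setNames(x@rowClass, names(x@rows)))

#' @describeIn AlignedGroup-class identifier of the annotated query row.
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))

#' @rdname AlignedGroup-class
#' @export
setMethod("queryId", "AlignedGroup", function(x) x@queryId)

setMethod("show", "AlignedGroup", function(object) {
  cls <- rowClasses(object)
  cat(sprintf(
    "AlignedGroup: %d rows x %d columns (H=%d homodimer, M=%d monomer), query '%s'\n",
    length(object@rows), nColumns(object),
    sum(cls == "homodimer"), sum(cls == "monomer"), object@queryId))
})

#' PairGroup: one interacting + one non-interacting subgroup
#'
#' The product of subgroup construction from ranked homology hits: the
#' query homodimer together with its interacting subgroup H, the
#' anchoring first monomer hit with its non-interacting subgroup M, and
#' the provenance of the selection (scheme and effective e-value cuts).
#'
#' @slot queryId the homodimer query.
#' @slot interactingIds members assigned to the interacting subgroup H
#'   (includes the query).
#' @slot noninteractingIds members assigned to the non-interacting
#'   subgroup M (includes the anchor monomer).
#' @slot anchorMonomerId the query's first monomer hit.
#' @slot hspLenQueryToAnchor HSP length (aa) of the query-to-anchor hit.
#' @slot evalueCutH,evalueCutM effective e-value cut of each subgroup.
#' @slot scheme one of \code{"first_cross"}, \code{"lower_of_two"},
#'   \code{"fixed_evalue"}, \code{"mixed20"}.
#'
#' @seealso [buildPairGroup()]
#' @export
setClass("PairGroup",
  representation(queryId = "character",
                 interactingIds = "character",
                 noninteractingIds = "character",
                 anchorMonomerId = "character",
                 hspLenQueryToAnchor = "integer",
                 evalueCutH = "numeric",
                 evalueCutM = "numeric",
                 scheme = "character"))

setValidity("PairGroup", function(object) {
  msg <- character()
  if (!(object@queryId %in% object@interactingIds))
    msg <- c(msg, "query must belong to the interacting subgroup")
  if (!(object@anchorMonomerId %in% object@noninteractingIds))
    msg <- c(msg, "anchor monomer must belong to the non-interacting subgroup")
  if (length(intersect(object@interactingIds, object@noninteractingIds)))
    msg <- c(msg, "subgroups must be disjoint")
  if (anyDuplicated(object@interactingIds) ||
      anyDuplicated(object@noninteractingIds))
    msg <- c(msg, "subgroup members must be unique")
  if (!(object@scheme %in% PAIRGROUP_SCHEMES))
    msg <- c(msg, sprintf("unknown scheme '%s'", object@scheme))
  if (object@hspLenQueryToAnchor < 1L)
    msg <- c(msg, "HSP length must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn PairGroup-class interacting subgroup member ids.
#' @param x,object a \code{PairGroup}.
#' @export
setGeneric("interactingIds", function(x) standardGeneric("interactingIds"))

#' @rdname PairGroup-class
#' @export
setMethod("interactingIds", "PairGroup", function(x) x@interactingIds)

#' @describeIn PairGroup-class non-interacting subgroup member ids.
#' @export
setGeneric("noninteractingIds",
           function(x) standardGeneric("noninteractingIds"))

#' @rdname PairGroup-class
#' @export
setMethod("noninteractingIds", "PairGroup", function(x) x@noninteractingIds)

#' @describeIn PairGroup-class the query's first monomer hit.
#' @export
setGeneric("anchorMonomerId", function(x) standardGeneric("anchorMonomerId"))

#' @rdname PairGroup-class
#' @export
setMethod("anchorMonomerId", "PairGroup", function(x) x@anchorMonomerId)

#' @describeIn PairGroup-class HSP length between query and anchor.
#' @export
setGeneric("hspLength", function(x) standardGeneric("hspLength"))

#' @rdname PairGroup-class
#' @export
setMethod("hspLength", "PairGroup", function(x) x@hspLenQueryToAnchor)

#' @rdname PairGroup-class
#' @export
setMethod("queryId", "PairGroup", function(x) x@queryId)

setMethod("show", "PairGroup", function(object) {
  cat(sprintf(
    "PairGroup '%s' (%s): |H| = %d, |M| = %d, anchor '%s', HSP %d aa\n",
    object@queryId, object@scheme, length(object@interactingIds),
    length(object@noninteractingIds), object@anchorMonomerId,
    object@hspLenQueryToAnchor))
  cat(sprintf("  e-value cuts: H < %g, M < %g\n",
              object@evalueCutH, object@evalueCutM))
})

#' EvalReport: prediction performance for one pair group
#'
#' Confusion counts of the two-state predictor (SH at a cutoff) plus
#' threshold-free ROC AUC, for the residues of one query that are both
#' structure-annotated and scored.
#'
#' @slot groupId identifier (usually the query id).
#' @slot counts named integer vector \code{c(tp, fp, tn, fn)}.
#' @slot recall,fpr,precision fractions; \code{NA} when the
#'   denominator is zero.
#' @slot auc rank-sum ROC AUC; \code{NA} when either class is absent.
#' @slot nEvaluated number of residues entering the evaluation.
#'
#' @seealso [evaluateGroup()], [predictionMetrics()]
#' @export
setClass("EvalReport",
  representation(groupId = "character",
                 counts = "integer",
                 recall = "numeric",
                 fpr = "numeric",
                 precision = "numeric",
                 auc = "numeric",
                 nEvaluated = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!identical(names(object@counts), c("tp", "fp", "tn", "fn")))
    msg <- c(msg, "counts must be named tp, fp, tn, fn")
  else if (any(object@counts < 0L))
    msg <- c(msg, "confusion counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn EvalReport-class confusion counts as a named integer
#'   vector.
#' @param x,object an \code{EvalReport}.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(x) x@counts)

#' @describeIn EvalReport-class recall, FPR, precision and AUC as a
#'   named numeric vector.
#' @export
setGeneric("performance", function(x) standardGeneric("performance"))

#' @rdname EvalReport-class
#' @export
setMethod("performance", "EvalReport", function(x)
  c(recall = x@recall, fpr = x@fpr, precision = x@precision, auc = x@auc))

setMethod("show", "EvalReport", function(object) {
  k <- object@counts
  cat(sprintf("EvalReport '%s': %d residues evaluated\n",
              object@groupId, object@nEvaluated))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              k[["tp"]], k[["fp"]], k[["tn"]], k[["fn"]]))
  cat(sprintf("  recall %.3f  FPR %.3f  precision %.3f  AUC %.3f\n",
              object@recall, object@fpr, object@precision, object@auc))
})

#' SimSpec: parameters of one synthetic pair group
#'
#' Describes the synthetic study conditions: subgroup sizes, the
#' partition of columns into interface/surface/buried, the planted
#' specificity at interface columns, conservation at buried columns,
#' the within-pool substitution rate and the seed.
#'
#' @slot nH,nM subgroup sizes (each at least 5, mirroring the minimum
#'   subgroup size of the grouping rule).
#' @slot nColumns alignment length.
#' @slot interfaceColumns,surfaceColumns,buriedColumns disjoint 1-based
#'   column index sets covering all columns.
#' @slot specificity probability in [0,1] that an interface column is
#'   generated with disjoint group alphabets.
#' @slot conservationBuried per-row probability of the dominant residue
#'   at buried columns.
#' @slot substitutionRate probability a residue is redrawn from its
#'   column pool.
#' @slot seed integer RNG seed; same seed, same outputs.
#'
#' @seealso [simSpec()], [simulatePairGroup()]
#' @export
setClass("SimSpec",
  representation(nH = "integer", nM = "integer", nColumns = "integer",
                 interfaceColumns = "integer", surfaceColumns = "integer",
                 buriedColumns = "integer", specificity = "numeric",
                 conservationBuried = "numeric",
                 substitutionRate = "numeric", seed = "integer"))

setValidity("SimSpec", function(object) {
  msg <- character()
  if (object@nH < 5L || object@nM < 5L)
    msg <- c(msg, "both subgroups need at least 5 members")
  if (object@nColumns < 1L)
    msg <- c(msg, "nColumns must be >= 1")
  cols <- c(object@interfaceColumns, object@surfaceColumns,
            object@buriedColumns)
  if (anyDuplicated(cols))
    msg <- c(msg, "column classes must be disjoint")
  if (!setequal(cols, seq_len(object@nColumns)))
    msg <- c(msg, "column classes must cover all columns exactly")
  for (s in c("specificity", "conservationBuried", "substitutionRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0,1]", s))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: H=%d, M=%d, %d columns (%d interface / %d surface / %d buried)\n",
    object@nH, object@nM, object@nColumns,
    length(object@interfaceColumns), length(object@surfaceColumns),
    length(object@buriedColumns)))
  cat(sprintf(
    "  specificity %.2f, buried conservation %.2f, substitution %.2f, seed %d\n",
    object@specificity, object@conservationBuried,
    object@substitutionRate, object@seed))
})
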