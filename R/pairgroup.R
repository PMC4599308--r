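#' Rank the hits of one query
#'
#' Collapses multiple HSPs per query-subject pair to the first tabular
#' line (BLAST reports the best HSP first), drops the self-hit, and
#' sorts deterministically: ascending e-value, ties broken by
#' descending bitscore then ascending subject id.
#'
#' @param hits data.frame from [readBlastTabular()].
#' @param queryId the query whose hits to rank.
#' @return the ranked hit data.frame for the query.
#' @export
rankedHits <- function(hits, queryId) {
  h <- hits[hits$query_id == queryId & hits$subject_id != queryId, ,
            drop = FALSE]
  h <- h[!duplicated(h$subject_id), , drop = FALSE]
  h[order(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
}

# Longest prefix of the ranked classes such that, together with the
# query itself (own class), the fraction of other-class members stays
# <= mixFraction.  mixFraction 0 recovers the pure first-cross prefix.
mixedPrefixLength <- function(classes, ownClass, mixFraction) {
  nOther <- 0L
  best <- 0L
  for (k in seq_along(classes)) {
    if (classes[k] != ownClass) nOther <- nOther + 1L
    if (nOther <= mixFraction * (k + 1L)) best <- k
  }
  best
}

#' Build one interacting/non-interacting pair group
#'
#' Implements the first-cross rule: for a homodimer query, the
#' interacting subgroup H is the query plus every homodimer hit ranked
#' strictly above the query's first monomer hit (the anchor).  The
#' anchor is then taken as query of the non-interacting side:
#' M is the anchor plus every monomer hit ranked strictly above the
#' anchor's first homodimer hit.  Both subgroups must reach
#' \code{minSubgroup} members, otherwise \code{NULL} is returned.
#'
#' Threshold variants, used for robustness analysis of the e-value
#' cut:
#' \describe{
#'   \item{\code{lower_of_two}}{both subgroups additionally truncated
#'     at the lower of the two first-cross e-value cuts (a stricter
#'     selection; tests missing data).}
#'   \item{\code{fixed_evalue}}{both subgroups cut at a fixed e-value
#'     (default \code{1e-10}) instead of the first-cross e-values;
#'     tests the case where interaction annotation of the database is
#'     incomplete.}
#'   \item{\code{mixed20}}{thresholds relaxed past the first cross
#'     until up to \code{mixFraction} (default 0.20) of the opposite
#'     class is mixed into each subgroup; mixed-in members are
#'     *assigned* to the subgroup while keeping their true interaction
#'     class, which pollutes the scoring groups.}
#' }
#'
#' @param queryId a homodimer sequence id.
#' @param hits all-against-all hit table from [readBlastTabular()].
#' @param classOf named character vector mapping ids to
#'   \code{"homodimer"}/\code{"monomer"}.
#' @param scheme subgroup selection scheme.
#' @param fixedEvalue e-value cut for scheme \code{fixed_evalue}.
#' @param mixFraction pollution fraction for scheme \code{mixed20}.
#' @param minSubgroup minimum members per subgroup (default 5).
#' @return A \linkS4class{PairGroup}, or \code{NULL} when either
#'   subgroup is too small or the query has no monomer hit.
#' @export
buildPairGroup <- function(queryId, hits, classOf,
                           scheme = c("first_cross", "lower_of_two",
                                      "fixed_evalue", "mixed20"),
                           fixedEvalue = 1e-10, mixFraction = 0.20,
                           minSubgroup = 5L) {
  scheme <- match.arg(scheme)
  if (is.na(classOf[queryId]) || classOf[queryId] != "homodimer")
    stop("query '", queryId, "' is not a homodimer")

  qh <- rankedHits(hits, queryId)
  qcls <- unname(classOf[qh$subject_id])
  if (anyNA(qcls))
    stop("hit subject(s) without interaction class for query ", queryId)

  firstM <- match("monomer", qcls)
  if (is.na(firstM)) return(NULL)
  anchor <- qh$subject_id[firstM]
  evalueCutH <- qh$evalue[firstM]
  hspAnchor <- qh$hsp_length[firstM]

  ah <- rankedHits(hits, anchor)
  acls <- unname(classOf[ah$subject_id])
  if (anyNA(acls))
    stop("hit subject(s) without interaction class for anchor ", anchor)
  firstH <- match("homodimer", acls)
  evalueCutM <- if (is.na(firstH)) Inf else ah$evalue[firstH]

  if (scheme %in% c("first_cross", "lower_of_two")) {
    H <- qh$subject_id[seq_len(firstM - 1L)][
      qcls[seq_len(firstM - 1L)] == "homodimer"]
    mTop <- if (is.na(firstH)) seq_len(nrow(ah)) else seq_len(firstH - 1L)
    M <- ah$subject_id[mTop][acls[mTop] == "monomer"]
    if (scheme == "lower_of_two") {
      ecut <- min(evalueCutH, evalueCutM)
      H <- H[qh$evalue[match(H, qh$subject_id)] < ecut]
      M <- M[ah$evalue[match(M, ah$subject_id)] < ecut]
      evalueCutH <- evalueCutM <- ecut
    }
  } else if (scheme == "fixed_evalue") {
    H <- qh$subject_id[qcls == "homodimer" & qh$evalue <= fixedEvalue]
    M <- ah$subject_id[acls == "monomer" & ah$evalue <= fixedEvalue]
    evalueCutH <- evalueCutM <- fixedEvalue
  } else { # mixed20
    if (mixFraction < 0 || mixFraction > 0.5)
      stop("mixFraction must be in [0, 0.5]")
    kH <- mixedPrefixLength(qcls, "homodimer", mixFraction)
    H <- qh$subject_id[seq_len(kH)]
    evalueCutH <- if (kH) qh$evalue[kH] else 0
    kM <- mixedPrefixLength(acls, "monomer", mixFraction)
    M <- ah$subject_id[seq_len(kM)]
    evalueCutM <- if (kM) ah$evalue[kM] else 0
  }

  # the anchor stays on the non-interacting side and the query on the
  # interacting side even when a relaxed threshold reaches them
  H <- unique(c(queryId, setdiff(H, anchor)))
  M <- unique(c(anchor, setdiff(M, H)))
  if (length(H) < minSubgroup || length(M) < minSubgroup) return(NULL)

  new("PairGroup", queryId = queryId, interactingIds = H,
      noninteractingIds = M, anchorMonomerId = anchor,
      hspLenQueryToAnchor = as.integer(hspAnchor),
      evalueCutH = as.numeric(evalueCutH),
      evalueCutM = as.numeric(evalueCutM), scheme = scheme)
}

#' Filter pair groups on HSP length and query length
#'
#' Keeps groups whose query-to-anchor HSP is at least \code{minHsp}
#' amino acids and whose query sequence is at least \code{minQueryLen}
#' long.  Longer HSPs reflect stronger evidence of a homologous
#' relation between the interacting and non-interacting sides, and are
#' where the specificity signal is strongest.
#'
#' @param groups list of \linkS4class{PairGroup}.
#' @param records class-labelled \code{AAStringSet} holding at least
#'   every query sequence.
#' @param minHsp inclusive minimum HSP length (aa).
#' @param minQueryLen inclusive minimum query length (aa).
#' @return the surviving groups.
#' @export
filterPairGroups <- function(groups, records, minHsp = 0L,
                             minQueryLen = 0L) {
  if (minHsp < 0L || minQueryLen < 0L)
    stop("minHsp and minQueryLen must be >= 0")
  keep <- vapply(groups, function(g) {
    qlen <- Biostrings::width(records)[match(queryId(g), names(records))]
    if (is.na(qlen)) stop("no sequence record for query ", queryId(g))
    hspLength(g) >= minHsp && qlen >= minQueryLen
  }, logical(1))
  groups[keep]
}

#' Collapse pair groups with identical member sets
#'
#' Every homodimer may seed its own pair group, so distinct queries can
#' produce the same membership; this keeps the first of each.
#'
#' @param groups list of \linkS4class{PairGroup}.
#' @return deduplicated list.
#' @export
uniquePairGroups <- function(groups) {
  key <- vapply(groups, function(g)
    paste(paste(sort(interactingIds(g)), collapse = ","),
          paste(sort(noninteractingIds(g)), collapse = ","), sep = "|"),
    character(1))
  groups[!duplicated(key)]
}
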