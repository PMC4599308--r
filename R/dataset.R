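#' Classify residues into interface, surface or buried
#'
#' Position classes follow the accessible/buried surface area rule:
#' interface when \code{asa > 0 & bsa > 0} (area is lost on
#' association), surface when \code{asa > 0 & bsa == 0}, buried when
#' both are zero.  \code{asa == 0 & bsa > 0} is physically impossible
#' (a residue cannot bury more area than it exposes) and raises an
#' error.
#'
#' @param asa,bsa non-negative numeric vectors (A^2), recycled to a
#'   common length.
#' @return factor with levels \code{interface}, \code{surface},
#'   \code{buried}.
#' @examples
#' classifyResidues(c(12.5, 40, 0), c(3.1, 0, 0))
#' @export
classifyResidues <- function(asa, bsa) {
  if (any(asa < 0) || any(bsa < 0))
    stop("ASA and BSA must be non-negative")
  bad <- asa == 0 & bsa > 0
  if (any(bad))
    stop("invalid annotation: ASA = 0 with BSA > 0 at ",
         sum(bad), " residue(s)")
  cls <- ifelse(asa > 0 & bsa > 0, "interface",
                ifelse(asa > 0, "surface", "buried"))
  factor(cls, levels = c("interface", "surface", "buried"))
}

#' @describeIn classifyResidues add a \code{position_class} column to an
#'   annotation table from [readResidueAnnotations()].
#' @param annotations annotation data.frame with \code{asa} and
#'   \code{bsa} columns.
#' @export
annotateResidueClasses <- function(annotations) {
  annotations$position_class <-
    classifyResidues(annotations$asa, annotations$bsa)
  annotations
}

#' Keep sequences of at least a minimum length
#'
#' @param records class-labelled \code{AAStringSet} from
#'   [readSequenceFasta()].
#' @param minLen inclusive minimum length in amino acids (default 50).
#' @return the surviving records, order preserved.
#' @export
filterMinLength <- function(records, minLen = 50L) {
  if (minLen < 1L) stop("minLen must be >= 1")
  records[Biostrings::width(records) >= minLen]
}

#' Drop exact duplicate sequences within each interaction class
#'
#' Identity of the residue string is judged per class: an identical
#' sequence occurring once among the homodimers and once among the
#' monomers is kept in both, since the uniqueness requirement applies
#' within each group.  The first occurrence is retained.
#'
#' @param records class-labelled \code{AAStringSet}.
#' @return deduplicated records, order preserved.
#' @export
dedupeIdentical <- function(records) {
  if (!length(records)) return(records)
  key <- paste(S4Vectors::mcols(records)$interactionClass,
               as.character(records), sep = "\r")
  records[!duplicated(key)]
}

#' Pairwise percent identity, identities over the shorter sequence
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62, gap opening 10
#' and extension 0.5; identity is 100 x identical aligned positions /
#' length of the shorter sequence (the convention greedy incremental
#' clustering tools use).
#'
#' @param a,b amino-acid strings.
#' @return percent identity in [0, 100].
#' @export
percentIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID3")
}

#' Greedy identity clustering, longest sequence first
#'
#' Reduces redundancy the way greedy incremental clustering does: sort
#' by length descending (ties by id ascending); each sequence joins the
#' first existing cluster whose representative it matches at
#' \code{>= maxPctId} percent identity, otherwise it founds a new
#' cluster.  Representatives (the longest member of each cluster) are
#' returned, so of any set of mutually similar sequences only the
#' longest survives.  At threshold 100 this reduces to exact-duplicate
#' removal.
#'
#' @param records class-labelled \code{AAStringSet}; clustering is done
#'   over all records together.
#' @param maxPctId identity threshold in (0, 100].
#' @return the representatives, in input order.
#' @export
identityCluster <- function(records, maxPctId) {
  if (!length(records)) stop("records must be non-empty")
  if (maxPctId <= 0) stop("maxPctId must be positive")
  ord <- order(-Biostrings::width(records), names(records))
  repIdx <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in repIdx) {
      if (percentIdentity(as.character(records[[i]]),
                          as.character(records[[r]])) >= maxPctId) {
        hit <- TRUE
        break
      }
    }
    if (!hit) repIdx <- c(repIdx, i)
  }
  records[sort(repIdx)]
}

#' Identity threshold presets
#'
#' The ten maximum-identity presets used to build filtered dataset
#' variants, from 40 to 100 percent.
#'
#' @return integer vector of thresholds.
#' @export
identityPresets <- function() {
  c(40L, 50L, 60L, 70L, 80L, 90L, 95L, 98L, 99L, 100L)
}

#' Import a precomputed clustering in CD-HIT .clstr format
#'
#' Allows an externally computed clustering to stand in for
#' [identityCluster()]: parses the \code{.clstr} listing and returns
#' the representative ids (lines flagged with \code{*}).
#'
#' @param path .clstr file.
#' @return character vector of representative sequence ids.
#' @export
readCdhitClusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  repLines <- grep("\\*\\s*$", lines, value = TRUE)
  ids <- sub("^.*>", "", sub("\\.\\.\\..*$", "", repLines))
  ids <- trimws(ids)
  if (!length(ids) && any(grepl("^>Cluster", lines)))
    stop("no representatives (lines ending in '*') found in ", path)
  ids
}
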