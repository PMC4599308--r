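#' Read class-labelled protein sequences from FASTA
#'
#' Reads one FASTA file of unaligned protein sequences and labels every
#' record with an interaction class.  The header token before the first
#' whitespace becomes the sequence id; sequences are uppercased and
#' restricted to the 20 canonical amino acids plus \code{X}.
#'
#' @param path FASTA file.
#' @param classLabel \code{"homodimer"} (interacting) or
#'   \code{"monomer"} (non-interacting).
#' @return An \code{AAStringSet}, in file order, with
#'   \code{mcols(x)$interactionClass} set.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">A", "MKV", ">B desc", "MMKVL"), f)
#' seqs <- readSequenceFasta(f, "homodimer")
#' names(seqs)
#' @export
readSequenceFasta <- function(path,
                              classLabel = c("homodimer", "monomer")) {
  classLabel <- match.arg(classLabel)
  checkFastaShape(path)
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  if (length(seqs)) {
    if (any(!nzchar(names(seqs))))
      stop("empty sequence id in ", path)
    dup <- names(seqs)[duplicated(names(seqs))]
    if (length(dup))
      stop("duplicate sequence id(s) in ", path, ": ",
           paste(unique(dup), collapse = ", "))
    if (any(Biostrings::width(seqs) == 0L))
      stop("zero-length sequence in ", path)
    checkAlphabet(seqs, allowGap = FALSE, context = path)
  }
  S4Vectors::mcols(seqs)$interactionClass <- rep(classLabel, length(seqs))
  seqs
}

# Cheap structural checks with line numbers, ahead of the real parser.
checkFastaShape <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) return(invisible(NULL))
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header",
                 first, path))
  invisible(NULL)
}

checkAlphabet <- function(seqs, allowGap, context) {
  ok <- c(AA20, "X", if (allowGap) GAP_CHARS)
  seen <- unique(unlist(strsplit(as.character(seqs), "", fixed = TRUE)))
  bad <- setdiff(seen, ok)
  if (length(bad))
    stop("disallowed residue letter(s) in ", context, ": ",
         paste(bad, collapse = ", "),
         " (only the 20 canonical amino acids and X are accepted)")
  invisible(NULL)
}

#' Read ranked homology hits in BLAST tabular format
#'
#' Parses the standard 12-column tab-separated hit format (outfmt 6):
#' query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, e-value, bitscore.  The alignment
#' length column is taken as the HSP length.
#'
#' @param path tab-separated hits file without header.
#' @return A data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{hsp_length}, \code{evalue},
#'   \code{bitscore}, rows in file order.
#' @export
readBlastTabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      hsp_length = integer(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 12L)) {
    bad <- which(nfld != 12L)[1L]
    stop(sprintf(
      "line %d of %s has %d columns; 12-column BLAST tabular expected",
      bad, path, nfld[bad]))
  }
  m <- do.call(rbind, parts)
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     percent_identity = as.numeric(m[, 3L]),
                     hsp_length = as.integer(m[, 4L]),
                     evalue = as.numeric(m[, 11L]),
                     bitscore = as.numeric(m[, 12L]),
                     stringsAsFactors = FALSE)
  if (anyNA(hits$percent_identity) || anyNA(hits$evalue) ||
      anyNA(hits$bitscore) || anyNA(hits$hsp_length))
    stop("non-numeric field in numeric column of ", path)
  if (any(hits$hsp_length < 1L))
    stop("HSP length must be >= 1 in ", path)
  if (any(hits$evalue < 0))
    stop("negative e-value in ", path)
  hits
}

#' Read a class-labelled alignment from aligned FASTA
#'
#' @param path aligned FASTA (gap character \code{-}).
#' @param classOf named character vector mapping every row id to
#'   \code{"homodimer"} or \code{"monomer"}.
#' @param queryId id of the structure-annotated query row; must be
#'   present in the alignment.
#' @return An \linkS4class{AlignedGroup}.
#' @export
readAlignedFasta <- function(path, classOf, queryId) {
  checkFastaShape(path)
  rows <- Biostrings::readAAStringSet(path)
  names(rows) <- sub("\\s.*$", "", names(rows))
  rows <- Biostrings::AAStringSet(toupper(as.character(rows)))
  if (!length(rows)) stop("alignment file ", path, " has no rows")
  if (length(unique(Biostrings::width(rows))) != 1L)
    stop("ragged alignment in ", path, ": unequal row lengths")
  checkAlphabet(rows, allowGap = TRUE, context = path)
  unknown <- setdiff(names(rows), names(classOf))
  if (length(unknown))
    stop("no interaction class for sequence(s): ",
         paste(unknown, collapse = ", "))
  if (!(queryId %in% names(rows)))
    stop("query '", queryId, "' missing from alignment ", path)
  AlignedGroup(rows, classOf[names(rows)], queryId)
}

#' Read per-residue ASA/BSA annotations
#'
#' Reads the tab-separated per-residue annotation table of the query
#' homodimer: \code{residue_index}, \code{amino_acid}, \code{asa}
#' (accessible surface area before association, A^2), \code{bsa}
#' (surface area buried upon interface formation, A^2).  Indices are
#' 1-based and strictly increasing; unresolved residues may simply be
#' absent.  The position class is left unset; see
#' [annotateResidueClasses()].
#'
#' @param path annotation TSV with the exact header
#'   \code{residue_index amino_acid asa bsa}.
#' @return data.frame in residue order.
#' @export
readResidueAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("residue_index", "amino_acid", "asa", "bsa")
  if (!identical(names(ann)[seq_along(need)], need))
    stop("annotation header must be: ", paste(need, collapse = "\t"))
  if (nrow(ann)) {
    if (anyNA(ann$residue_index) || any(ann$residue_index < 1L))
      stop("residue_index must be positive integers in ", path)
    if (any(diff(ann$residue_index) <= 0L))
      stop("residue_index must be strictly increasing in ", path)
    if (anyNA(ann$asa) || anyNA(ann$bsa) ||
        any(ann$asa < 0) || any(ann$bsa < 0))
      stop("ASA and BSA must be non-negative in ", path)
  }
  ann$residue_index <- as.integer(ann$residue_index)
  ann
}

#' Write / read a per-column score table
#'
#' The score table is written as TSV with a fixed column order
#' (\code{column_index}, \code{query_residue_index}, \code{query_aa},
#' \code{n_H}, \code{n_M}, \code{entropy_H}, \code{entropy_M},
#' \code{sh}) and floats at 6 significant digits, so a read-back
#' reproduces the values to that precision.
#'
#' @param scores data.frame as returned by [scoreGroup()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @seealso [readScoresTsv()]
#' @export
writeScoresTsv <- function(scores, path) {
  cols <- c("column_index", "query_residue_index", "query_aa",
            "n_H", "n_M", "entropy_H", "entropy_M", "sh")
  missing <- setdiff(cols, names(scores))
  if (length(missing))
    stop("score table lacks column(s): ", paste(missing, collapse = ", "))
  out <- scores[, cols, drop = FALSE]
  for (num in c("entropy_H", "entropy_M", "sh"))
    out[[num]] <- formatC(out[[num]], digits = 6L, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeScoresTsv
#' @export
readScoresTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  scores <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = c(query_aa = "character"))
  scores$column_index <- as.integer(scores$column_index)
  scores$query_residue_index <- as.integer(scores$query_residue_index)
  scores
}

#' Write an evaluation report as JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsJson <- function(report, path) {
  stopifnot(methods::is(report, "EvalReport"))
  k <- confusion(report)
  obj <- list(group_id = report@groupId,
              counts = as.list(k),
              recall = report@recall, fpr = report@fpr,
              precision = report@precision, auc = report@auc,
              n_evaluated = report@nEvaluated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
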