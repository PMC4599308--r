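#' Configure a pipeline run
#'
#' Collects and validates every knob of the end-to-end run.  The
#' configuration is serialised verbatim into the run manifest so a run
#' can be reproduced from its output directory alone.
#'
#' @param homodimerFasta,monomerFasta FASTA files of the interacting
#'   and non-interacting sequence sets.
#' @param hitsTsv all-against-all BLAST tabular hit file.
#' @param alignmentsDir directory of per-group aligned FASTA files
#'   named \code{<queryId>.afa} (alignments are produced externally,
#'   e.g. by MUSCLE with default parameters; alignment is an import
#'   boundary of this pipeline).
#' @param annotationsDir directory of per-query annotation TSVs named
#'   \code{<queryId>.tsv}.
#' @param outDir output directory.
#' @param minLen minimum sequence length (aa).
#' @param identityThreshold maximum percent identity preset, one of
#'   [identityPresets()], or \code{NA} to skip identity clustering.
#' @param minHsp,minQueryLen pair-group filters (aa).
#' @param scheme subgroup selection scheme; see [buildPairGroup()].
#' @param fixedEvalue,mixFraction scheme parameters.
#' @param minSubgroup minimum subgroup size.
#' @param shCutoff two-state prediction cutoff.
#' @param universe evaluation universe; see [confusionCounts()].
#' @param uniqueGroups collapse pair groups with identical membership.
#' @param seed integer seed recorded in the manifest.
#' @return a validated configuration list of class
#'   \code{"shRunConfig"}.
#' @export
runConfig <- function(homodimerFasta, monomerFasta, hitsTsv,
                      alignmentsDir, annotationsDir, outDir,
                      minLen = 50L, identityThreshold = NA_integer_,
                      minHsp = 0L, minQueryLen = 0L,
                      scheme = "first_cross", fixedEvalue = 1e-10,
                      mixFraction = 0.20, minSubgroup = 5L,
                      shCutoff = 0.2, universe = "all_classified",
                      uniqueGroups = FALSE, seed = 1L) {
  scheme <- match.arg(scheme, PAIRGROUP_SCHEMES)
  universe <- match.arg(universe, c("all_classified", "surface_only"))
  if (!is.na(identityThreshold) &&
      !(identityThreshold %in% identityPresets()))
    stop("identityThreshold must be one of ",
         paste(identityPresets(), collapse = ", "), " or NA")
  if (shCutoff < 0 || shCutoff > 1) stop("shCutoff must be in [0, 1]")
  cfg <- list(homodimer_fasta = homodimerFasta,
              monomer_fasta = monomerFasta, hits_tsv = hitsTsv,
              alignments_dir = alignmentsDir,
              annotations_dir = annotationsDir, out_dir = outDir,
              min_len = as.integer(minLen),
              identity_threshold = as.integer(identityThreshold),
              min_hsp = as.integer(minHsp),
              min_query_len = as.integer(minQueryLen), scheme = scheme,
              fixed_evalue = fixedEvalue, mix_fraction = mixFraction,
              min_subgroup = as.integer(minSubgroup),
              sh_cutoff = shCutoff, universe = universe,
              unique_groups = isTRUE(uniqueGroups),
              seed = as.integer(seed))
  class(cfg) <- "shRunConfig"
  cfg
}

pipelineLog <- function(con, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  writeLines(line, con)
  message(line)
}

#' Run the full interface-prediction pipeline
#'
#' Executes filter, pair-group construction, alignment import, SH
#' scoring, evaluation and aggregation over file-based inputs, writing
#' per-group score tables (\code{scores/<query>.tsv}) and metric JSONs
#' (\code{metrics/<query>.json}), an aggregate \code{summary.json}, a
#' plain-text \code{run.log} with per-stage counts, and
#' \code{manifest.json} (configuration, input checksums, package
#' version).  Re-running the same configuration on the same inputs
#' reproduces all numeric outputs.
#'
#' Queries without an alignment file, without annotations, or whose
#' subgroups stay below the minimum are skipped with a logged reason.
#'
#' @param config configuration from [runConfig()].
#' @return invisibly, a list with \code{groups} (the
#'   \linkS4class{PairGroup}s evaluated), \code{reports}, and
#'   \code{summary}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "shRunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "scores"), showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "metrics"), showWarnings = FALSE)
  logCon <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logCon), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  seqs <- stage("read_sequences", {
    h <- readSequenceFasta(config$homodimer_fasta, "homodimer")
    m <- readSequenceFasta(config$monomer_fasta, "monomer")
    both <- c(h, m)
    dup <- intersect(names(h), names(m))
    if (length(dup))
      stop("id(s) present in both classes: ", paste(dup, collapse = ", "))
    both
  })
  pipelineLog(logCon, "read %d sequences (%d homodimer, %d monomer)",
              length(seqs),
              sum(S4Vectors::mcols(seqs)$interactionClass == "homodimer"),
              sum(S4Vectors::mcols(seqs)$interactionClass == "monomer"))

  seqs <- stage("filter", {
    s <- dedupeIdentical(filterMinLength(seqs, config$min_len))
    if (!is.na(config$identity_threshold) && length(s))
      s <- identityCluster(s, config$identity_threshold)
    s
  })
  pipelineLog(logCon, "after filtering: %d sequences", length(seqs))

  classOf <- setNames(S4Vectors::mcols(seqs)$interactionClass,
                      names(seqs))
  hits <- stage("read_hits", readBlastTabular(config$hits_tsv))
  hits <- hits[hits$query_id %in% names(seqs) &
                 hits$subject_id %in% names(seqs), , drop = FALSE]
  pipelineLog(logCon, "hit table: %d usable rows", nrow(hits))

  queries <- names(seqs)[classOf == "homodimer"]
  groups <- stage("build_groups", {
    g <- lapply(queries, function(q)
      buildPairGroup(q, hits, classOf, scheme = config$scheme,
                     fixedEvalue = config$fixed_evalue,
                     mixFraction = config$mix_fraction,
                     minSubgroup = config$min_subgroup))
    g <- g[!vapply(g, is.null, logical(1))]
    if (config$unique_groups) g <- uniquePairGroups(g)
    filterPairGroups(g, seqs, config$min_hsp, config$min_query_len)
  })
  pipelineLog(logCon, "pair groups after construction and filters: %d",
              length(groups))

  reports <- list()
  classMeans <- list()
  for (g in groups) {
    q <- queryId(g)
    afa <- file.path(config$alignments_dir, paste0(q, ".afa"))
    annFile <- file.path(config$annotations_dir, paste0(q, ".tsv"))
    if (!file.exists(afa)) {
      pipelineLog(logCon, "skip %s: no alignment file", q)
      next
    }
    if (!file.exists(annFile)) {
      pipelineLog(logCon, "skip %s: no annotation file", q)
      next
    }
    members <- c(interactingIds(g), noninteractingIds(g))
    memberClass <- setNames(rep(c("homodimer", "monomer"),
                                c(length(interactingIds(g)),
                                  length(noninteractingIds(g)))), members)
    aligned <- stage(paste0("score:", q),
                     readAlignedFasta(afa, memberClass, q))
    scores <- stage(paste0("score:", q), scoreGroup(aligned))
    ann <- stage(paste0("evaluate:", q),
                 annotateResidueClasses(readResidueAnnotations(annFile)))
    writeScoresTsv(scores, file.path(config$out_dir, "scores",
                                     paste0(q, ".tsv")))
    rep <- stage(paste0("evaluate:", q),
                 evaluateGroup(scores, ann, cutoff = config$sh_cutoff,
                               universe = config$universe, groupId = q))
    writeMetricsJson(rep, file.path(config$out_dir, "metrics",
                                    paste0(q, ".json")))
    reports[[q]] <- rep
    classMeans[[q]] <- meanScoresByClass(scores, ann)
    pipelineLog(logCon,
                "group %s: %d residues evaluated, AUC %.3f", q,
                rep@nEvaluated, rep@auc)
  }

  summary <- if (length(reports))
    aggregateReports(reports, classMeans)
  else list(n_groups = 0L, mean_auc = NA_real_, n_undefined_auc = 0L)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, dataframe = "rows")

  inputs <- c(config$homodimer_fasta, config$monomer_fasta,
              config$hits_tsv)
  manifest <- list(config = unclass(config),
                   input_md5 = as.list(tools::md5sum(inputs)),
                   package_version =
                     as.character(utils::packageVersion("SeqHarmony")))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  pipelineLog(logCon, "done: %d group(s) evaluated", length(reports))
  invisible(list(groups = groups, reports = reports, summary = summary))
}
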