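## Orchestration: run every record through the ordered stages, collapse
## duplicates, optionally embed 3D, and emit the output file set.

#' Standardize a single record
#'
#' Stages, in order: parse, valence remediation, ambiguous-structure filter,
#' fragment split / salt-solvent strip / mixture rule, composition filter,
#' mesomer/tautomer rules, neutralization, stereo flattening, hydrogen
#' virtualization, ring mode, coordinate sanitization, size/shape filter,
#' identifier generation. The first failing stage short-circuits with its
#' reason tag; nothing raises out of this function.
#'
#' @param record a ChemicalRecord.
#' @param config a StdConfig.
#' @param library a RuleLibrary.
#' @param blocklist a loaded blocklist data frame.
#' @return a QsarReadyResult, or a ProcessingOutcome when the record is
#'   discarded
#' @export
standardizeRecord <- function(record, config = stdConfig(),
                              library = defaultRuleLibrary(),
                              blocklist = defaultBlocklist()) {
  fail <- function(reason, stage, log) {
    new("ProcessingOutcome", identifier = record@identifier, reason = reason,
        stage = stage, originalInput = record@rawInput, log = log)
  }
  log <- character(0)
  if (record@parseStatus == "failed" || is.null(record@graph))
    return(fail("failed_parsing", "parse", record@parseMessages))
  g <- record@graph
  original_smiles <- canonicalSmiles(g)

  cv <- correctValence(g)
  if (!cv$ok) return(fail("failed_parsing", "valence", c(log, cv$messages)))
  g <- cv$graph; log <- c(log, cv$log)

  if (detectAmbiguous(g, record@rawInput))
    return(fail("ambiguous_structure", "ambiguous_filter",
                c(log, "query atom / R-group / wildcard attachment present")))

  sr <- stripAndRebalance(g, blocklist)
  log <- c(log, sr$log, sr$chargeOps)
  if (sr$status != "ok") return(fail(sr$status, "fragments", log))
  g <- sr$parent

  comp <- classifyComposition(g)
  if (comp != "organic") return(fail(comp, "composition", log))

  tt <- standardizeMesomersTautomers(g, library)
  g <- tt$graph; log <- c(log, tt$log)

  nn <- neutralize(g, library)
  g <- nn$graph; log <- c(log, nn$log)

  fs <- flattenStereo(g)
  g <- fs$graph
  if (fs$payload$tetrahedral + fs$payload$doubleBond > 0)
    log <- c(log, sprintf("flattened stereo: %d centre(s), %d double bond(s)",
                          fs$payload$tetrahedral, fs$payload$doubleBond))

  g <- virtualizeHydrogens(g)
  g <- tryCatch(setRingMode(g, config@ringMode), error = function(e) e)
  if (inherits(g, "error"))
    return(fail("failed_parsing", "ring_mode", c(log, conditionMessage(g))))
  g <- fixCrossedDoubleBonds(g)
  g <- sanitizeCoordinates(g)

  sz <- sizeShapeCheck(g, config@sizeFilter)
  if (sz != "pass") return(fail(sz, "size_shape", log))

  ids <- tryCatch(computeInchi(g), error = function(e) e)
  if (inherits(ids, "error"))
    return(fail("failed_parsing", "inchi", c(log, conditionMessage(ids))))
  smi <- canonicalSmiles(g)
  if (!nzchar(smi))
    return(fail("failed_parsing", "smiles", c(log, "canonical SMILES failed")))

  new("QsarReadyResult", identifier = record@identifier, graph = g,
      smiles = smi, inchi = ids$inchi, inchikey = ids$inchikey,
      saltSolvent = sr$stripped$smiles, saltId = sr$stripped$salt_id,
      originalSmiles = original_smiles, log = log, stereoPayload = fs$payload)
}

#' Collapse duplicate structures by InChI
#'
#' Keeps the first occurrence (input order); later records with an identical
#' standard InChI become outcomes tagged "duplicate", recording the kept
#' identifier. Identity operation when `dedup` is FALSE.
#'
#' @param results list of QsarReadyResult.
#' @param dedup whether deduplication was requested.
#' @return list(unique = list of QsarReadyResult, duplicates = list of
#'   ProcessingOutcome)
#' @export
deduplicate <- function(results, dedup = TRUE) {
  if (!dedup || !length(results))
    return(list(unique = results, duplicates = list()))
  seen <- character(0)
  keeper <- character(0)
  unique_r <- list(); dups <- list()
  for (r in results) {
    hit <- match(r@inchi, seen)
    if (is.na(hit)) {
      seen <- c(seen, r@inchi)
      keeper <- c(keeper, r@identifier)
      unique_r[[length(unique_r) + 1L]] <- r
    } else {
      dups[[length(dups) + 1L]] <- new("ProcessingOutcome",
        identifier = r@identifier, reason = "duplicate", stage = "deduplicate",
        originalInput = r@originalSmiles,
        log = sprintf("duplicate of %s (identical InChI)", keeper[hit]))
    }
  }
  list(unique = unique_r, duplicates = dups)
}

#' Embed an optimized 3D conformation
#'
#' Adds explicit hydrogens, builds one 3D starting geometry from a
#' deterministic 2D layout plus a seeded out-of-plane perturbation, and
#' optimizes it with the MMFF94 force field (UFF fallback). The same input
#' and seed give bit-identical coordinates across runs. When a stereo
#' payload from [flattenStereo()] is compatible with the standardized
#' skeleton, the stereo-bearing SMILES is used so defined configurations
#' survive into 3D.
#'
#' @param graph standardized single-fragment MolGraph.
#' @param payload optional stereo payload from [flattenStereo()].
#' @param seed embedding seed (default 42, the workflow's fixed seed).
#' @return list(graph = MolGraph with 3D coordinates and explicit hydrogens,
#'   energyBefore =, energyAfter =, forcefield =), or NULL when embedding
#'   failed (callers fall back to 2D)
#' @export
embed3d <- function(graph, payload = NULL, seed = 42L) {
  smi <- canonicalSmiles(graph, mode = "aromatic")
  if (!is.null(payload) && !is.null(payload$smiles) && !is.na(payload$smiles) &&
      !grepl(".", payload$smiles, fixed = TRUE)) {
    key_std <- molBlockToInchiKey(writeMolBlock(graph))
    key_pay <- smilesToInchiKey(payload$smiles)
    if (nzchar(key_std) && substr(key_std, 1, 14) == substr(key_pay, 1, 14))
      smi <- payload$smiles
  }
  emb <- obEmbed3d(smi, seed = seed)
  if (is.null(emb)) return(NULL)
  g3 <- tryCatch(parseMolBlock(emb$minimized, foldH = FALSE),
                 error = function(e) NULL)
  if (is.null(g3) || !all(is.finite(c(g3@atoms$x, g3@atoms$y, g3@atoms$z))))
    return(NULL)
  g3@dim <- 3L
  g3@ringMode <- graph@ringMode
  list(graph = g3, energyBefore = emb$energyBefore,
       energyAfter = emb$energyAfter, forcefield = emb$forcefield)
}

#' Run the full standardization workflow
#'
#' Reads the input, processes every record through [standardizeRecord()],
#' optionally collapses duplicates and embeds 3D coordinates, and writes the
#' five output artifacts into the output directory, named from the input
#' stem: `<stem>_QSAR-ready.sdf`, `<stem>_QSAR-ready_smi.smi`,
#' `<stem>_Summary_file.csv`, `<stem>_DiscardedStructures.csv`,
#' `<stem>_StrippedSalts.csv`.
#'
#' @param config a StdConfig with at least `input` set.
#' @return (invisibly) a run report: list(files=, results=, outcomes=,
#'   counts=, table=)
#' @export
runPipeline <- function(config) {
  if (!nzchar(config@input) || !file.exists(config@input))
    stop("input file not found: ", config@input)
  library <- if (nzchar(config@rulesPath)) loadRuleFile(config@rulesPath)
             else defaultRuleLibrary()
  if (length(config@disabledRules))
    library <- setRuleEnabled(library, config@disabledRules, FALSE)
  blocklist <- if (nzchar(config@blocklistPath)) loadBlocklist(config@blocklistPath)
               else defaultBlocklist()
  fmt <- if (config@format == "auto") NULL else config@format
  records <- readStructures(config@input, format = fmt,
    smilesColumn = if (is.na(config@smilesColumn)) NULL else config@smilesColumn,
    idColumn = if (is.na(config@idColumn)) NULL else config@idColumn)

  results <- list(); outcomes <- list()
  for (rec in records) {
    out <- standardizeRecord(rec, config, library, blocklist)
    if (is(out, "QsarReadyResult")) results[[length(results) + 1L]] <- out
    else outcomes[[length(outcomes) + 1L]] <- out
  }
  dd <- deduplicate(results, config@dedup)
  results <- dd$unique
  outcomes <- c(outcomes, dd$duplicates)

  dim_out <- "2D"
  if (config@make3d) {
    for (k in seq_along(results)) {
      e3 <- embed3d(results[[k]]@graph, results[[k]]@stereoPayload)
      if (is.null(e3)) {
        results[[k]]@log <- c(results[[k]]@log,
                              "3D embedding failed; 2D coordinates kept")
      } else {
        results[[k]]@graph <- e3$graph
        results[[k]]@log <- c(results[[k]]@log, sprintf(
          "3D embedded (%s): %.3f -> %.3f kcal/mol", e3$forcefield,
          e3$energyBefore, e3$energyAfter))
      }
    }
    if (all(vapply(results, function(r) r@graph@dim == 3L, logical(1))))
      dim_out <- "3D"
  }

  stem <- tools::file_path_sans_ext(basename(config@input))
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    sdf = file.path(config@outputDir, paste0(stem, "_QSAR-ready.sdf")),
    smi = file.path(config@outputDir, paste0(stem, "_QSAR-ready_smi.smi")),
    summary = file.path(config@outputDir, paste0(stem, "_Summary_file.csv")),
    discarded = file.path(config@outputDir, paste0(stem, "_DiscardedStructures.csv")),
    salts = file.path(config@outputDir, paste0(stem, "_StrippedSalts.csv")))
  writeSdf(results, files[["sdf"]], dimension = dim_out)
  writeSmiles(results, files[["smi"]])
  writeSummary(results, files[["summary"]])
  writeDiscarded(outcomes, files[["discarded"]])
  writeSaltMap(results, files[["salts"]])

  counts <- table(factor(vapply(outcomes, reasonTag, character(1)),
                         levels = REASON_TAGS))
  report <- list(
    files = files,
    results = results,
    outcomes = outcomes,
    counts = c(input = length(records), passed = length(results),
               discarded = length(outcomes)),
    reasons = counts,
    table = data.frame(
      ID = c(vapply(results, identifier, character(1)),
             vapply(outcomes, identifier, character(1))),
      status = c(rep("pass", length(results)), rep("discarded", length(outcomes))),
      reason = c(rep("", length(results)),
                 vapply(outcomes, reasonTag, character(1))),
      stringsAsFactors = FALSE))
  invisible(report)
}
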