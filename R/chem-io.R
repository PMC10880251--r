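## Input readers (SMILES / CSV / MOL / SDF) and the five output artifacts.

#' ChemicalRecord class
#'
#' One input entry: identifier, verbatim raw text, source format, the parsed
#' graph (when parsing succeeded) and parse status/messages. SDF data fields
#' are retained in `meta`.
#' @exportClass ChemicalRecord
setClass("ChemicalRecord", representation(
  identifier = "character", rawInput = "character", sourceFormat = "character",
  graph = "ANY", parseStatus = "character", parseMessages = "character",
  meta = "list"
))

setValidity("ChemicalRecord", function(object) {
  if (!nzchar(object@identifier)) return("identifier must be non-empty")
  if (!object@sourceFormat %in% c("smi", "csv", "mol", "sdf"))
    return("unknown source format")
  if (!object@parseStatus %in% c("ok", "warning", "failed"))
    return("unknown parse status")
  TRUE
})

setMethod("show", "ChemicalRecord", function(object) {
  cat(sprintf("ChemicalRecord %s [%s, %s]\n", object@identifier,
              object@sourceFormat, object@parseStatus))
})

#' @describeIn identifier identifier of a ChemicalRecord
#' @export
setMethod("identifier", "ChemicalRecord", function(x) x@identifier)

#' QsarReadyResult class
#'
#' A standardized, model-ready structure: the graph, its canonical SMILES,
#' standard InChI/InChIKey, the stripped salt/solvent annotation and the
#' original input SMILES.
#' @exportClass QsarReadyResult
setClass("QsarReadyResult", representation(
  identifier = "character", graph = "ANY", smiles = "character",
  inchi = "character", inchikey = "character", saltSolvent = "character",
  saltId = "character", originalSmiles = "character", log = "character",
  stereoPayload = "list"
))

setValidity("QsarReadyResult", function(object) {
  if (!grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", object@inchikey))
    return("malformed InChIKey")
  TRUE
})

setMethod("show", "QsarReadyResult", function(object) {
  cat(sprintf("QsarReadyResult %s: %s\n  %s / %s\n", object@identifier,
              object@smiles, object@inchi, object@inchikey))
})

#' @describeIn identifier identifier of a QsarReadyResult
#' @export
setMethod("identifier", "QsarReadyResult", function(x) x@identifier)

#' Canonical QSAR-ready SMILES of a result
#' @param x a QsarReadyResult
#' @export
qsarSmiles <- function(x) x@smiles

#' Standard InChI / InChIKey of a result
#' @param x a QsarReadyResult
#' @export
resultInchi <- function(x) x@inchi

#' @rdname resultInchi
#' @export
resultInchiKey <- function(x) x@inchikey

#' ProcessingOutcome class
#'
#' The fate of a record that did not pass standardization: a single reason
#' from the controlled vocabulary, the stage that raised it, and a log.
#' @exportClass ProcessingOutcome
setClass("ProcessingOutcome", representation(
  identifier = "character", reason = "character", stage = "character",
  originalInput = "character", log = "character"
))

setValidity("ProcessingOutcome", function(object) {
  if (!object@reason %in% REASON_TAGS)
    return(paste0("reason must be one of: ", paste(REASON_TAGS, collapse = ", ")))
  TRUE
})

setMethod("show", "ProcessingOutcome", function(object) {
  cat(sprintf("ProcessingOutcome %s: %s (at %s)\n", object@identifier,
              object@reason, object@stage))
})

#' @describeIn identifier identifier of a ProcessingOutcome
#' @export
setMethod("identifier", "ProcessingOutcome", function(x) x@identifier)

#' Discard reason of a ProcessingOutcome
#' @param x a ProcessingOutcome
#' @export
reasonTag <- function(x) x@reason

## ------------------------------------------------------------------ input --

#' Detect the format of a structure file
#'
#' Decides by file extension first (.smi/.csv/.mol/.sdf), then by content
#' sniffing: a "$$$$" record separator means SDF, an "M  END" line means MOL.
#' Unknown formats are returned, never raised.
#'
#' @param path an existing, readable file.
#' @return one of "smi", "csv", "mol", "sdf", "unknown"
#' @export
detectFormat <- function(path) {
  if (!file.exists(path)) stop("cannot read input file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "csv", "mol", "sdf")) return(ext)
  head <- tryCatch(readLines(path, n = 500L, warn = FALSE),
                   error = function(e) stop("cannot read input file: ", path))
  if (any(startsWith(head, "$$$$"))) return("sdf")
  if (any(startsWith(head, "M  END"))) return("mol")
  "unknown"
}

#' Read chemical structures into ChemicalRecords
#'
#' One record per input entry, in file order. Entries that fail parsing are
#' kept with `parseStatus == "failed"` so they can be reported; nothing is
#' silently dropped. Identifiers are taken from the input (.smi second token,
#' the chosen CSV column, the MOL/SDF title line) or synthesized as
#' "ROW_<n>"; collisions are disambiguated with a "_<k>" suffix.
#'
#' @param path input file.
#' @param format one of "smi", "csv", "mol", "sdf"; autodetected when NULL.
#' @param smilesColumn,idColumn CSV column names (smilesColumn is required
#'   for CSV input).
#' @return list of ChemicalRecord objects
#' @export
readStructures <- function(path, format = NULL, smilesColumn = NULL,
                           idColumn = NULL) {
  if (is.null(format)) format <- detectFormat(path)
  if (!format %in% c("smi", "csv", "mol", "sdf"))
    stop("cannot determine the structure format of ", path)
  entries <- switch(format,
    smi = .read_smi(path),
    csv = .read_csv(path, smilesColumn, idColumn),
    mol = .read_mol(path),
    sdf = .read_sdf(path))
  ids <- .dedup_ids(vapply(entries, `[[`, "", "id"))
  records <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    parsed <- parseStructure(e$raw, format)
    records[[k]] <- new("ChemicalRecord",
      identifier = ids[k], rawInput = e$raw, sourceFormat = format,
      graph = parsed$graph, parseStatus = parsed$status,
      parseMessages = parsed$messages,
      meta = if (is.null(e$meta)) list() else e$meta)
  }
  records
}

.dedup_ids <- function(ids) {
  seen <- character(0)
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    if (!nzchar(id)) id <- paste0("ROW_", k)
    if (id %in% seen) {
      n <- 2L
      while (paste0(id, "_", n) %in% seen) n <- n + 1L
      id <- paste0(id, "_", n)
    }
    seen <- c(seen, id)
    out[k] <- id
  }
  out
}

.read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(k) {
    parts <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    list(raw = lines[k],
         id = if (length(parts) >= 2) paste(parts[-1], collapse = " ") else "")
  })
}

.read_csv <- function(path, smilesColumn, idColumn) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (is.null(smilesColumn) || !smilesColumn %in% names(tab))
    stop("CSV input needs a SMILES column; available columns: ",
         paste(names(tab), collapse = ", "))
  if (!is.null(idColumn) && !idColumn %in% names(tab))
    stop("identifier column '", idColumn, "' not found; available columns: ",
         paste(names(tab), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(k) {
    list(raw = tab[[smilesColumn]][k],
         id = if (!is.null(idColumn)) tab[[idColumn]][k] else "")
  })
}

.read_mol <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  title <- strsplit(txt, "\n", fixed = TRUE)[[1]][1]
  list(list(raw = txt, id = trimws(title)))
}

.read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- which(startsWith(lines, "$$$$"))
  if (!length(breaks)) return(.read_mol(path))
  start <- 1L
  entries <- list()
  for (b in breaks) {
    chunk <- lines[start:(b - 1L)]
    start <- b + 1L
    if (!any(nzchar(trimws(chunk)))) next
    mend <- which(startsWith(chunk, "M  END"))
    molpart <- if (length(mend)) chunk[seq_len(mend[1])] else chunk
    meta <- .parse_sdf_fields(if (length(mend)) chunk[-seq_len(mend[1])]
                              else character(0))
    entries[[length(entries) + 1L]] <- list(
      raw = paste(molpart, collapse = "\n"), id = trimws(chunk[1]), meta = meta)
  }
  entries
}

.parse_sdf_fields <- function(lines) {
  meta <- list()
  tag <- NULL; buf <- character(0)
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (!is.null(tag)) meta[[tag]] <- paste(buf, collapse = "\n")
      m <- regmatches(ln, regexec("<([^>]*)>", ln))[[1]]
      tag <- if (length(m) >= 2) m[2] else NULL
      buf <- character(0)
    } else if (!is.null(tag)) {
      if (nzchar(trimws(ln))) buf <- c(buf, ln)
      else { meta[[tag]] <- paste(buf, collapse = "\n"); tag <- NULL; buf <- character(0) }
    }
  }
  if (!is.null(tag)) meta[[tag]] <- paste(buf, collapse = "\n")
  meta
}

## ----------------------------------------------------------------- output --

#' Write standardized structures as an SDF (V2000) file
#'
#' One record per result, terminated by "$$$$"; the identifier is stored both
#' as the molecule name line and as an "ID" data field. Output is
#' deterministic (byte-identical across runs).
#'
#' @param results list of QsarReadyResult.
#' @param path output file.
#' @param dimension "2D" or "3D"; 3D requires every result to carry 3D
#'   coordinates.
#' @export
writeSdf <- function(results, path, dimension = c("2D", "3D")) {
  dimension <- match.arg(dimension)
  out <- character(0)
  for (r in results) {
    if (dimension == "3D" && r@graph@dim != 3L)
      stop("3D output requested but record ", r@identifier,
           " has no 3D coordinates")
    out <- c(out, writeMolBlock(r@graph, title = r@identifier),
             "> <ID>", r@identifier, "", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write the QSAR-ready SMILES file
#'
#' One line per result: canonical SMILES, a tab, and the identifier; input
#' order is preserved.
#' @param results list of QsarReadyResult.
#' @param path output file.
#' @export
writeSmiles <- function(results, path) {
  writeLines(vapply(results, function(r) paste0(r@smiles, "\t", r@identifier),
                    character(1)), path)
  invisible(path)
}

#' Write the summary CSV of processed QSAR-ready structures
#'
#' Columns: ID, Original_SMILES, Canonical_QSARr, InChI, InChIKey,
#' Salt_Solvent, Salt_Solvent_ID; one row per successfully standardized
#' record. The header is written even when there are no rows.
#' @param results list of QsarReadyResult.
#' @param path output file.
#' @export
writeSummary <- function(results, path) {
  df <- data.frame(
    ID = vapply(results, function(r) r@identifier, character(1)),
    Original_SMILES = vapply(results, function(r) r@originalSmiles, character(1)),
    Canonical_QSARr = vapply(results, function(r) r@smiles, character(1)),
    InChI = vapply(results, function(r) r@inchi, character(1)),
    InChIKey = vapply(results, function(r) r@inchikey, character(1)),
    Salt_Solvent = vapply(results, function(r)
      paste(r@saltSolvent, collapse = "; "), character(1)),
    Salt_Solvent_ID = vapply(results, function(r)
      paste(r@saltId[nzchar(r@saltId)], collapse = "; "), character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the discarded-structures CSV
#'
#' Columns ID, Original_Structure, Reason; the reason comes from the
#' controlled vocabulary (`REASON_TAGS`). When deduplication was requested,
#' duplicates appear here too.
#' @param outcomes list of ProcessingOutcome.
#' @param path output file.
#' @export
writeDiscarded <- function(outcomes, path) {
  df <- data.frame(
    ID = vapply(outcomes, function(o) o@identifier, character(1)),
    Original_Structure = vapply(outcomes, function(o)
      gsub("[\r\n].*$", "", o@originalInput), character(1)),
    Reason = vapply(outcomes, function(o) o@reason, character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the stripped salt/solvent map CSV
#'
#' Columns ID, Salt_Solvent_SMILES, Salt_Solvent_ID; one row per stripped
#' fragment, only for records that actually had fragments stripped.
#' @param results list of QsarReadyResult.
#' @param path output file.
#' @export
writeSaltMap <- function(results, path) {
  rows <- list()
  for (r in results) {
    for (k in seq_along(r@saltSolvent)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ID = r@identifier, Salt_Solvent_SMILES = r@saltSolvent[k],
        Salt_Solvent_ID = r@saltId[k], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ID = character(0), Salt_Solvent_SMILES = character(0),
               Salt_Solvent_ID = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
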