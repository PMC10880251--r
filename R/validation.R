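## Structure validation: parsing, valence remediation and the composition /
## ambiguity / size-shape filters that decide whether a structure can ever be
## QSAR-ready.

#' Controlled vocabulary of discard reasons
#' @export
REASON_TAGS <- c("failed_parsing", "mixture", "inorganic", "organometallic",
                 "ambiguous_structure", "size", "nano_shape", "duplicate")

#' Parse a raw structure into a MolGraph
#'
#' SMILES input goes through the Open Babel reader; MOL/SDF text is first
#' normalized by Open Babel (validating the connection table and kekulizing
#' order-4 aromatic bonds) and then read by the package's V2000 parser.
#' Failures never raise: they are returned as a structured value so that
#' failed records survive to be reported.
#'
#' @param raw SMILES string or MOL block.
#' @param format "smi", "csv" (SMILES in a cell), "mol" or "sdf".
#' @return list(graph = MolGraph or NULL, status = "ok"|"failed",
#'   messages = character())
#' @export
parseStructure <- function(raw, format = "smi") {
  msgs <- character(0)
  raw <- if (is.null(raw)) "" else raw
  if (!nzchar(trimws(raw)))
    return(list(graph = NULL, status = "failed", messages = "empty input"))
  if (format %in% c("smi", "csv")) {
    smi <- trimws(strsplit(trimws(raw), "[ \t]+")[[1]][1])
    if (.smiles_has_unclosed_ring(smi))
      return(list(graph = NULL, status = "failed",
                  messages = "SMILES parse failed: unmatched ring closure"))
    mb <- smilesToMolBlock(smi)
    if (!nzchar(mb))
      return(list(graph = NULL, status = "failed",
                  messages = "SMILES parse failed"))
    stereo <- smilesToCanonical(smi)
  } else {
    mb <- normalizeMolBlock(raw)
    if (!nzchar(mb))
      return(list(graph = NULL, status = "failed",
                  messages = "MOL block rejected by reader"))
    stereo <- molBlockToSmiles(mb)
  }
  g <- tryCatch(parseMolBlock(mb), error = function(e) conditionMessage(e))
  if (is.character(g))
    return(list(graph = NULL, status = "failed", messages = g))
  if (grepl("[@/\\\\]", stereo)) g@stereoSmiles <- stereo
  list(graph = g, status = "ok", messages = msgs)
}

## ring-closure digits outside brackets must pair up
.smiles_has_unclosed_ring <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  depth <- 0L
  open <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") depth <- depth + 1L
    else if (ch == "]") depth <- depth - 1L
    else if (depth == 0L && grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      if (d %in% open) open <- setdiff(open, d) else open <- c(open, d)
    } else if (depth == 0L && ch == "%") {
      d <- suppressWarnings(as.integer(paste0(chars[i + 1], chars[i + 2])))
      if (!is.na(d)) {
        if (d %in% open) open <- setdiff(open, d) else open <- c(open, d)
        i <- i + 2L
      }
    }
    i <- i + 1L
  }
  length(open) > 0L
}

## Hard-coded remediation rules applied before any library transform: convert
## hypervalent neutral drawings (pentavalent nitro/N-oxide/azide/diazo,
## tetravalent isocyanide N) to their charge-separated equivalents without
## touching heavy-atom connectivity.
.VALENCE_SMIRKS <- c(
  "VAL-NITRO"  = "[#7v5X3+0:1](=[OX1:2])=[OX1:3]>>[#7+:1](=[O:2])[O-:3]",
  "VAL-AZOXY"  = "[#7v5X3+0:1](=[OX1:2])=[#7X2:3]>>[#7+:1]([O-:2])=[#7:3]",
  "VAL-NOX"    = "[#7v5+0:1]=[OX1+0:2]>>[#7+:1][O-:2]",
  "VAL-AZIDE"  = "[#7X2+0:1]=[#7v5X2+0:2]#[#7X1+0:3]>>[#7:1]=[#7+:2]=[#7-:3]",
  "VAL-DIAZO"  = "[#6X3+0:1]=[#7v5X2+0:2]#[#7X1:3]>>[#6:1]=[#7+:2]=[#7-:3]",
  "VAL-ISONITRILE" = "[#7X2+0v4:1]#[#6X1+0:2]>>[#7+:1]#[#6-:2]"
)

#' Check and remediate valence errors
#'
#' Applies the ordered valence remediation table (hypervalent N drawings to
#' charge-separated forms), then converts any remaining neutral
#' tetra-coordinated nitrogen to the ammonium/iminium cation, and finally
#' scans every atom against the legal valence set for its element and charge.
#' An atom whose explicit bond orders exceed every legal valence (e.g. a
#' five-coordinate carbon) is irreparable.
#'
#' @param graph a parsed MolGraph.
#' @return list(ok = TRUE, graph =, log =) or
#'   list(ok = FALSE, reason = "failed_parsing", messages =)
#' @export
correctValence <- function(graph) {
  log <- character(0)
  for (id in names(.VALENCE_SMIRKS)) {
    res <- applyRule(graph, list(rule_id = id, smirks = .VALENCE_SMIRKS[[id]]))
    if (res$applications > 0) {
      log <- c(log, sprintf("%s remedied %d site(s)", id, res$applications))
    }
    graph <- res$graph
  }
  ## neutral N with four sigma connections is an ammonium drawn uncharged
  bs <- .bond_order_sums(graph)
  a <- graph@atoms
  fix <- which(a$elem == "N" & a$charge == 0L & (bs + a$hcount) == 4L &
                 bs <= 4L)
  if (length(fix)) {
    a$charge[fix] <- 1L
    graph@atoms <- a
    log <- c(log, sprintf("assigned +1 to tetravalent neutral N at atom(s) %s",
                          paste(fix, collapse = ",")))
  }
  ## legality scan
  bs <- .bond_order_sums(graph)
  a <- graph@atoms
  for (i in seq_len(nrow(a))) {
    av <- allowedValences(a$elem[i], a$charge[i])
    if (is.null(av)) next
    if (bs[i] > max(av)) {
      return(list(ok = FALSE, reason = "failed_parsing",
                  messages = sprintf(
                    "irreparable valence: %s atom %d has bond order sum %d",
                    a$elem[i], i, bs[i])))
    }
    if (!((bs[i] + a$hcount[i]) %in% av))
      a$hcount[i] <- max(0L, min(av[av >= bs[i]]) - bs[i])
  }
  graph@atoms <- a
  list(ok = TRUE, graph = graph, log = log)
}

#' Classify a fragment as organic, inorganic or organometallic
#'
#' Organic means at least one carbon atom and no covalent carbon-metal bond;
#' a carbon-metal bond makes the fragment organometallic; no carbon at all is
#' inorganic. The metal set is every element outside {H, B, C, N, O, Si, P,
#' S, Se, halogens, noble gases}.
#'
#' @param graph a MolGraph (single or multi fragment; the classification is
#'   applied to whatever is passed).
#' @return "organic", "inorganic" or "organometallic"
#' @export
classifyComposition <- function(graph) {
  a <- graph@atoms
  if (!any(a$elem == "C")) return("inorganic")
  b <- graph@bonds
  if (nrow(b)) {
    metal <- isMetal(a$elem)
    cm <- (a$elem[b$a1] == "C" & metal[b$a2]) |
          (a$elem[b$a2] == "C" & metal[b$a1])
    if (any(cm)) return("organometallic")
  }
  "organic"
}

#' Detect Markush / ambiguous structures
#'
#' True when the molecular graph contains query atoms (MDL "A", "Q", "L",
#' "R", "R#") or wildcard attachment points ("*"), or when the raw input
#' carries a SMILES wildcard atom.
#'
#' @param graph a MolGraph or NULL.
#' @param raw the raw input text (optional).
#' @export
detectAmbiguous <- function(graph = NULL, raw = NULL) {
  if (!is.null(graph) && any(graph@atoms$elem %in% .QUERY_ATOMS)) return(TRUE)
  if (!is.null(raw) && grepl("*", raw, fixed = TRUE) &&
      !grepl("M  END", raw, fixed = TRUE)) return(TRUE)
  FALSE
}

#' SizeShapeLimits class
#'
#' Bounds for the optional size/shape filter: molecular weight, heavy-atom
#' count, and the nano-shape criterion (bonds per heavy atom above
#' `nanoRatioMax` flags cage-like structures). Filtering only happens when
#' `enabled`.
#' @exportClass SizeShapeLimits
setClass("SizeShapeLimits", representation(
  enabled = "logical", mwMin = "numeric", mwMax = "numeric",
  heavyMin = "numeric", heavyMax = "numeric", nanoRatioMax = "numeric"
))

setValidity("SizeShapeLimits", function(object) {
  chk <- function(lo, hi, what) {
    if (!is.na(lo) && !is.na(hi) && lo > hi) paste0(what, " min > max") else TRUE
  }
  r1 <- chk(object@mwMin, object@mwMax, "mw")
  if (!isTRUE(r1)) return(r1)
  chk(object@heavyMin, object@heavyMax, "heavy atom")
})

#' Construct size/shape limits
#'
#' @param enabled activate the filter (off by default: filtering is opt-in).
#' @param mwMin,mwMax molecular weight bounds in daltons (NA = unbounded).
#' @param heavyMin,heavyMax heavy-atom count bounds.
#' @param nanoRatioMax maximum bonds / heavy atoms ratio (default 1.3,
#'   separating cage-like structures from ordinary polycyclics).
#' @return a SizeShapeLimits object
#' @export
sizeLimits <- function(enabled = FALSE, mwMin = NA_real_, mwMax = NA_real_,
                       heavyMin = 2, heavyMax = NA_real_, nanoRatioMax = 1.3) {
  new("SizeShapeLimits", enabled = enabled, mwMin = as.numeric(mwMin),
      mwMax = as.numeric(mwMax), heavyMin = as.numeric(heavyMin),
      heavyMax = as.numeric(heavyMax), nanoRatioMax = as.numeric(nanoRatioMax))
}

setMethod("show", "SizeShapeLimits", function(object) {
  cat(sprintf(
    "SizeShapeLimits: %s, MW [%s, %s], heavy [%s, %s], nano ratio <= %s\n",
    if (object@enabled) "enabled" else "disabled",
    object@mwMin, object@mwMax, object@heavyMin, object@heavyMax,
    object@nanoRatioMax))
})

#' Apply the size/shape filter
#'
#' @param graph a single-fragment standardized MolGraph.
#' @param limits a SizeShapeLimits object.
#' @return "pass", "size" or "nano_shape"
#' @export
sizeShapeCheck <- function(graph, limits = sizeLimits()) {
  if (!limits@enabled) return("pass")
  heavy <- heavyAtomCount(graph)
  mw <- molWeight(graph)
  if (!is.na(limits@heavyMin) && heavy < limits@heavyMin) return("size")
  if (!is.na(limits@heavyMax) && heavy > limits@heavyMax) return("size")
  if (!is.na(limits@mwMin) && mw < limits@mwMin) return("size")
  if (!is.na(limits@mwMax) && mw > limits@mwMax) return("size")
  if (!is.na(limits@nanoRatioMax) && heavy > 0 &&
      heavyBondCount(graph) / heavy > limits@nanoRatioMax) return("nano_shape")
  "pass"
}
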