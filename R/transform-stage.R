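## Non-library standardization stages: neutralization, stereo flattening,
## ring mode, crossed double bonds, coordinate sanitization.

#' Neutralize charged structures when possible
#'
#' Two mechanisms, both best-effort ("when possible"): first the enabled
#' neutralization-family rules of the library are applied in order (each one
#' guarded so the magnitude of the net charge never increases); then
#' zwitterions are neutralized by paired proton transfer (a protonatable
#' anion and a deprotonatable cation exchange a proton), and any residual net
#' charge is brought toward zero at charged heteroatoms. Charge-separated
#' units (an anion bonded to a cation: nitro, N-oxides, azides) and cations
#' without hydrogens (quaternary N) are permanent and stay.
#'
#' @param graph single-fragment MolGraph.
#' @param library a RuleLibrary supplying neutralization rules.
#' @return list(graph=, log=)
#' @export
neutralize <- function(graph, library = defaultRuleLibrary()) {
  res <- .run_rule_families(graph, library, "neutralization",
                            allowChargeDecrease = TRUE)
  graph <- res$graph
  log <- res$log
  ## paired proton transfer for zwitterions
  repeat {
    a <- graph@atoms
    prot <- .protected_atoms(graph, a)
    anion <- which(a$charge < 0L & !prot & a$elem %in% c("O", "S", "Se", "N", "C"))
    cation <- which(a$charge > 0L & !prot & a$hcount >= 1L &
                      a$elem %in% c("N", "O", "S", "P"))
    if (!length(anion) || !length(cation)) break
    i <- anion[1]; j <- cation[1]
    a$charge[i] <- a$charge[i] + 1L; a$hcount[i] <- a$hcount[i] + 1L
    a$charge[j] <- a$charge[j] - 1L; a$hcount[j] <- a$hcount[j] - 1L
    graph@atoms <- a
    log <- c(log, sprintf("zwitterion proton transfer: atom %d to atom %d", j, i))
  }
  reb <- rebalanceCharge(graph)
  list(graph = reb$graph, log = c(log, reb$log))
}

#' Flatten stereochemistry
#'
#' Removes stereo descriptors from the working structure and returns them as
#' a payload for optional reinstatement before 3D embedding. The payload
#' counts the defined tetrahedral centres and double-bond configurations
#' (taken from the /t and /b layers of the stereo-bearing InChI) and carries
#' the stereo canonical SMILES captured at parse time.
#'
#' @param graph a MolGraph.
#' @return list(graph = flattened graph, payload = list(tetrahedral=,
#'   doubleBond=, smiles=))
#' @export
flattenStereo <- function(graph) {
  payload <- list(tetrahedral = 0L, doubleBond = 0L, smiles = NA_character_)
  s <- graph@stereoSmiles
  if (!is.na(s) && nzchar(s)) {
    inchi <- smilesToInchi(s)
    payload$tetrahedral <- .count_layer(inchi, "t")
    payload$doubleBond <- .count_layer(inchi, "b")
    payload$smiles <- s
  }
  graph@stereoSmiles <- NA_character_
  list(graph = graph, payload = payload)
}

.count_layer <- function(inchi, layer) {
  m <- regmatches(inchi, regexec(paste0("/", layer, "([^/]+)"), inchi))[[1]]
  if (length(m) < 2) return(0L)
  length(strsplit(m[2], ",", fixed = TRUE)[[1]])
}

#' Switch ring representation between aromatic and Kekule
#'
#' Aromatic mode flags every ring satisfying Huckel's 4n+2 rule; Kekule mode
#' clears aromatic flags and keeps the alternating bond orders. Both modes
#' describe the same molecule and yield identical InChI; the mode controls
#' the canonical SMILES style and the SDF bond-order convention.
#'
#' @param graph a MolGraph.
#' @param mode "aromatic" or "kekule".
#' @return the graph with flags and ring mode set; an unkekulizable aromatic
#'   system (upstream corruption) raises an error
#' @export
setRingMode <- function(graph, mode = c("aromatic", "kekule")) {
  mode <- match.arg(mode)
  graph <- perceiveAromaticity(graph)
  if (mode == "kekule") {
    graph@atoms$arom <- FALSE
    if (nrow(graph@bonds)) graph@bonds$arom <- FALSE
  }
  graph@ringMode <- mode
  if (nrow(graph@atoms) && !nzchar(canonicalSmiles(graph)))
    stop("ring processing failed: structure cannot be written as ", mode)
  graph
}

#' Mark ambiguous double bonds as crossed
#'
#' After stereo flattening, every stereogenic-capable double bond has an
#' undefined configuration; such bonds get the crossed-bond display flag for
#' SDF output. A double bond is treated as stereogenic-capable when it is
#' acyclic, non-aromatic, between C/N atoms that each carry at least one
#' other heavy substituent.
#'
#' @param graph a MolGraph.
#' @return the graph with crossed flags set
#' @export
fixCrossedDoubleBonds <- function(graph) {
  b <- graph@bonds
  if (!nrow(b)) return(graph)
  ri <- .ring_info(graph)
  deg <- integer(nrow(graph@atoms))
  hv <- !(graph@atoms$elem %in% c("H", "D", "T"))
  for (k in seq_len(nrow(b))) {
    if (hv[b$a2[k]]) deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    if (hv[b$a1[k]]) deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  for (k in seq_len(nrow(b))) {
    b$crossed[k] <- b$order[k] == 2L && !b$arom[k] && !ri$bondInRing[k] &&
      all(graph@atoms$elem[c(b$a1[k], b$a2[k])] %in% c("C", "N")) &&
      deg[b$a1[k]] >= 2L && deg[b$a2[k]] >= 2L
  }
  graph@bonds <- b
  graph
}

#' Sanitize atomic coordinates
#'
#' When 2D coordinates are absent, degenerate (all zero) or overlapping
#' (closer than `tol`), a fresh 2D layout is generated; valid coordinates
#' pass through untouched.
#'
#' @param graph a MolGraph.
#' @param tol minimum allowed inter-atom distance.
#' @return the graph with usable 2D (or original 3D) coordinates
#' @export
sanitizeCoordinates <- function(graph, tol = 1e-4) {
  a <- graph@atoms
  if (!nrow(a)) return(graph)
  degenerate <- graph@dim == 0L || all(a$x == 0 & a$y == 0 & a$z == 0)
  if (!degenerate && nrow(a) > 1) {
    d <- stats::dist(cbind(a$x, a$y, a$z))
    if (min(d) < tol) degenerate <- TRUE
  }
  if (!degenerate) return(graph)
  mb <- obConvert("MOL", "MOL", writeMolBlock(graph), gen2d = TRUE)
  if (!nzchar(mb)) return(graph)         # layout failure: keep as-is
  g2 <- tryCatch(parseMolBlock(mb, foldH = FALSE), error = function(e) NULL)
  if (is.null(g2) || nrow(g2@atoms) != nrow(a)) return(graph)
  graph@atoms$x <- g2@atoms$x
  graph@atoms$y <- g2@atoms$y
  graph@atoms$z <- 0
  graph@dim <- 2L
  graph
}
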