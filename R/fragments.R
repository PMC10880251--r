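## Multi-fragment handling: salt/solvent stripping against the blocklist,
## charge rebalancing of the parent, and the mixture rule.

#' Load a salt/solvent blocklist
#'
#' The blocklist is an editable CSV (salt_id, smiles, class, name). At load
#' time every entry is compiled to the skeleton (first) block of its standard
#' InChIKey, which makes matching insensitive to the charge state: acetate
#' and acetic acid, or chloride and hydrogen chloride, hit the same entry.
#'
#' @param path blocklist CSV; defaults to the list shipped with the package
#'   (about sixty common counterions, salt formers and solvents).
#' @return data.frame with columns salt_id, smiles, class, name, key
#' @export
loadBlocklist <- function(path = defaultBlocklistPath()) {
  if (!file.exists(path)) stop("blocklist file not found: ", path)
  bl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("salt_id", "smiles", "class", "name")
  if (!all(need %in% names(bl)))
    stop("blocklist must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(bl$salt_id)) stop("duplicate salt_id in blocklist")
  key <- vapply(bl$smiles, function(s) {
    k <- smilesToInchiKey(s)
    if (nzchar(k)) substr(k, 1, 14) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(key)) stop("blocklist entries failed InChIKey compilation: ",
                       paste(bl$salt_id[is.na(key)], collapse = ", "))
  bl$key <- key
  bl
}

#' Path of the blocklist shipped with the package
#' @export
defaultBlocklistPath <- function() {
  system.file("extdata", "salt_solvent_blocklist.csv", package = "qsarstd")
}

#' The default blocklist (cached)
#' @export
defaultBlocklist <- function() {
  if (is.null(.pkg_cache$blocklist))
    .pkg_cache$blocklist <- loadBlocklist()
  .pkg_cache$blocklist
}

#' Look a fragment up in the blocklist
#'
#' Matching is by the skeleton block of the fragment's standard InChIKey
#' (charge-state-insensitive).
#' @param fragment single-fragment MolGraph.
#' @param blocklist a loaded blocklist data frame.
#' @return the salt_id of the first matching entry, or NA
#' @export
lookupBlocklist <- function(fragment, blocklist = defaultBlocklist()) {
  key <- molBlockToInchiKey(writeMolBlock(fragment))
  if (!nzchar(key)) return(NA_character_)
  hit <- match(substr(key, 1, 14), blocklist$key)
  if (is.na(hit)) NA_character_ else blocklist$salt_id[hit]
}

#' The mixture rule
#'
#' A substance passes if at most one organic fragment remains after salt and
#' solvent stripping; two or more distinct organic fragments make a mixture,
#' which does not pass standardization.
#' @param fragments list of MolGraphs remaining after stripping.
#' @return "pass" or "mixture"
#' @export
mixtureDecision <- function(fragments) {
  n_org <- sum(vapply(fragments, function(f) classifyComposition(f) != "inorganic",
                      logical(1)))
  if (n_org > 1) "mixture" else "pass"
}

#' Strip salts/solvents and rebalance the parent's charge
#'
#' Single-fragment substances pass through untouched (a lone ethanol is a
#' structure, not a solvent to be stripped). For multi-fragment substances,
#' every blocklisted fragment is removed; identical copies of the remaining
#' organic fragment are collapsed onto one parent; non-blocklisted leftover
#' inorganic fragments are stripped like counterions (with an empty salt_id)
#' so heavy atoms are conserved. The parent's net charge is then brought as
#' close to zero as protonation/deprotonation at charged heteroatoms allows;
#' permanent charges (e.g. quaternary N) stay.
#'
#' @param graph valence-corrected MolGraph (any number of fragments).
#' @param blocklist a loaded blocklist data frame.
#' @return list(status = "ok" | "mixture" | "inorganic", parent = MolGraph,
#'   stripped = data.frame(smiles, salt_id), chargeOps = character(), log =)
#' @export
stripAndRebalance <- function(graph, blocklist = defaultBlocklist()) {
  empty_strip <- data.frame(smiles = character(0), salt_id = character(0),
                            stringsAsFactors = FALSE)
  frags <- splitFragments(graph)
  if (!length(frags))
    return(list(status = "inorganic", parent = NULL, stripped = empty_strip,
                chargeOps = character(0), log = "no atoms"))
  if (length(frags) == 1L)
    return(list(status = "ok", parent = frags[[1]], stripped = empty_strip,
                chargeOps = character(0), log = character(0)))

  log <- character(0)
  ids <- vapply(frags, function(f) lookupBlocklist(f, blocklist), character(1))
  smis <- vapply(frags, function(f) canonicalSmiles(f), character(1))
  organic_all <- vapply(frags, function(f) any(f@atoms$elem == "C"), logical(1))
  ## Inorganic blocklist entries (metal cations, halides, water) always
  ## strip. Organic entries only yield when the record has a real parent:
  ## a counterion/salt-class entry (acetate, tosylate, TFA) strips whenever
  ## any other organic fragment is present, while a solvent-class entry
  ## (ethanol, DMSO) strips only next to a strictly larger organic fragment.
  ## So sodium acetate keeps acetate as parent, butylammonium tosylate keeps
  ## the amine, a drug-ethanol solvate loses the ethanol, and an
  ## ethanol/ethylamine pair stays a mixture instead of losing the ethanol.
  if (any(organic_all & !is.na(ids))) {
    hv <- vapply(frags, heavyAtomCount, integer(1))
    cls <- blocklist$class[match(ids, blocklist$salt_id)]
    for (k in which(organic_all & !is.na(ids))) {
      others <- organic_all & seq_along(frags) != k
      strip_ok <- if (identical(cls[k], "solvent"))
        any(others & hv > hv[k]) else any(others)
      if (!strip_ok) {
        log <- c(log, sprintf("kept blocklisted organic fragment %s (no suitable parent)",
                              smis[k]))
        ids[k] <- NA_character_
      }
    }
    ## safety: never let stripping consume every organic fragment
    if (!any(organic_all & is.na(ids))) {
      k <- which(organic_all)[1]
      log <- c(log, sprintf("kept blocklisted organic fragment %s as parent", smis[k]))
      ids[k] <- NA_character_
    }
  }
  keep <- which(is.na(ids))
  stripped <- data.frame(smiles = smis[!is.na(ids)],
                         salt_id = ids[!is.na(ids)], stringsAsFactors = FALSE)
  if (length(stripped$smiles))
    log <- c(log, sprintf("stripped blocklisted fragment %s (%s)",
                          stripped$smiles, stripped$salt_id))

  ## collapse identical copies of a remaining fragment onto one parent
  if (length(keep) > 1L) {
    dup <- duplicated(smis[keep])
    if (any(dup)) {
      extra <- keep[dup]
      stripped <- rbind(stripped, data.frame(
        smiles = smis[extra], salt_id = "", stringsAsFactors = FALSE))
      log <- c(log, sprintf("collapsed duplicate fragment %s", smis[extra]))
      keep <- keep[!dup]
    }
  }
  if (!length(keep))
    return(list(status = "inorganic", parent = NULL, stripped = stripped,
                chargeOps = character(0),
                log = c(log, "nothing but salts/solvents remained")))

  organic <- vapply(frags[keep], function(f) any(f@atoms$elem == "C"), logical(1))
  if (sum(organic) >= 2L)
    return(list(status = "mixture", parent = NULL, stripped = stripped,
                chargeOps = character(0),
                log = c(log, "two or more distinct organic fragments remain")))
  if (sum(organic) == 1L && any(!organic)) {
    ## leftover inorganic fragments alongside one organic parent: stripped
    ## like counterions, with no blocklist id
    extra <- keep[!organic]
    stripped <- rbind(stripped, data.frame(
      smiles = smis[extra], salt_id = "", stringsAsFactors = FALSE))
    log <- c(log, sprintf("stripped non-blocklisted inorganic fragment %s",
                          smis[extra]))
    keep <- keep[organic]
  }
  parent <- frags[[keep[1]]]
  reb <- rebalanceCharge(parent)
  list(status = "ok", parent = reb$graph, stripped = stripped,
       chargeOps = reb$log, log = log)
}

## Bring the net formal charge as close to zero as possible by protonating
## anionic heteroatoms / deprotonating cationic ones. Atoms participating in
## an adjacent +/- pair (nitro, N-oxide, azide interiors) are protected, as
## are cations without hydrogens (quaternary N).
#' @keywords internal
rebalanceCharge <- function(graph) {
  log <- character(0)
  a <- graph@atoms
  repeat {
    net <- sum(a$charge)
    if (net == 0L) break
    prot <- .protected_atoms(graph, a)
    if (net < 0L) {
      i <- which(a$charge < 0L & !prot &
                   a$elem %in% c("O", "S", "Se", "N", "C"))[1]
      if (is.na(i)) break
      a$charge[i] <- a$charge[i] + 1L
      a$hcount[i] <- a$hcount[i] + 1L
      log <- c(log, sprintf("protonated %s at atom %d", a$elem[i], i))
    } else {
      i <- which(a$charge > 0L & !prot & a$hcount >= 1L &
                   a$elem %in% c("N", "O", "S", "P"))[1]
      if (is.na(i)) break
      a$charge[i] <- a$charge[i] - 1L
      a$hcount[i] <- a$hcount[i] - 1L
      log <- c(log, sprintf("deprotonated %s at atom %d", a$elem[i], i))
    }
  }
  graph@atoms <- a
  list(graph = graph, log = log)
}

.protected_atoms <- function(graph, a = graph@atoms) {
  prot <- logical(nrow(a))
  b <- graph@bonds
  for (k in seq_len(nrow(b))) {
    c1 <- a$charge[b$a1[k]]; c2 <- a$charge[b$a2[k]]
    if (c1 * c2 < 0) prot[c(b$a1[k], b$a2[k])] <- TRUE
  }
  prot
}
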