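## Thin interface to Open Babel: all format interconversion, canonicalization,
## InChI generation, 2D layout and 3D embedding go through here. Everything
## chemical-semantic (valence, rules, filters) lives elsewhere in the package.

.ob_no_options <- function() data.frame(names = character(0), args = character(0))

#' Convert between chemical formats via Open Babel (in process)
#'
#' @param from,to Open Babel format codes (e.g. "SMI", "MOL", "CAN", "INCHI",
#'   "INCHIKEY").
#' @param src input text (a SMILES line or a MOL/SDF block).
#' @param gen2d generate 2D coordinates during conversion.
#' @param gen3d generate 3D coordinates (deterministic builder, no conformer
#'   search).
#' @return the converted text, or "" when Open Babel rejected the input.
#' @keywords internal
obConvert <- function(from, to, src, gen2d = FALSE, gen3d = FALSE) {
  if (!nzchar(src)) return("")
  if (!endsWith(src, "\n")) src <- paste0(src, "\n")
  opts <- .ob_no_options()
  if (gen2d) opts <- data.frame(names = "gen2D", args = "")
  if (gen3d) opts <- data.frame(names = "gen3D", args = "fastest")
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, src, options = opts),
    error = function(e) ""
  )
  if (is.null(out) || is.na(out)) "" else out
}

## The in-process string bridge can (rarely) append stray bytes after the
## payload. All post-processing of Open Babel text output is therefore
## byte-safe, and results failing strict validation are recomputed through
## the obabel command line (a separate process with clean buffers).
.ob_first_field <- function(x) {
  if (!length(x) || is.na(x) || !nzchar(x)) return("")
  r <- charToRaw(x)
  stop_at <- which(r %in% as.raw(c(0x09L, 0x0aL, 0x0dL, 0x20L)))
  end <- if (length(stop_at)) stop_at[1] - 1L else length(r)
  if (end < 1L) return("")
  out <- rawToChar(r[seq_len(end)])
  ## stray non-ASCII bytes mean a corrupted buffer: reject, callers fall
  ## back to the command-line converter
  if (any(r[seq_len(end)] > as.raw(0x7e)) || !validUTF8(out)) return("")
  out
}

## ']' first and '-' last: POSIX bracket expressions take backslash literally
.SMILES_RE <- "^[][A-Za-z0-9@+\\\\/%=#$:().~*-]+$"

## Strip the "\t<title>" tail and trailing newline from a SMILES-family output.
.ob_clean_smiles <- function(x) {
  x <- .ob_first_field(x)
  if (grepl(.SMILES_RE, x, useBytes = TRUE)) x else ""
}

#' @keywords internal
smilesToMolBlock <- function(smiles, gen2d = FALSE) {
  obConvert("SMI", "MOL", smiles, gen2d = gen2d)
}

#' @keywords internal
molBlockToSmiles <- function(molblock, canonical = TRUE) {
  fmt <- if (canonical) "CAN" else "SMI"
  x <- .ob_clean_smiles(obConvert("MOL", fmt, molblock))
  if (!nzchar(x) && grepl("M  END", molblock, fixed = TRUE))
    x <- .ob_clean_smiles(.ob_cli("obabel", c("-imol", paste0("-o", tolower(fmt))),
                                  molblock))
  x
}

#' @keywords internal
smilesToCanonical <- function(smiles) {
  .ob_clean_smiles(obConvert("SMI", "CAN", smiles))
}

#' @keywords internal
smilesToInchiKey <- function(smiles) {
  key_ok <- function(x) grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x, useBytes = TRUE)
  x <- .ob_first_field(obConvert("SMI", "INCHIKEY", smiles))
  if (!key_ok(x))
    x <- .ob_first_field(.ob_cli("obabel", c(paste0("-:", smiles), "-oinchikey")))
  if (key_ok(x)) x else ""
}

.ob_clean_inchi <- function(x) {
  x <- .ob_first_field(x)
  if (grepl("^InChI=1S/[A-Za-z0-9/.,;*?+()-]+$", x, useBytes = TRUE)) x else ""
}

#' @keywords internal
molBlockToInchi <- function(molblock) {
  x <- .ob_clean_inchi(obConvert("MOL", "INCHI", molblock))
  if (!nzchar(x))
    x <- .ob_clean_inchi(.ob_cli("obabel", c("-imol", "-oinchi"), molblock))
  x
}

#' @keywords internal
molBlockToInchiKey <- function(molblock) {
  key_ok <- function(x) grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x, useBytes = TRUE)
  x <- .ob_first_field(obConvert("MOL", "INCHIKEY", molblock))
  if (!key_ok(x))
    x <- .ob_first_field(.ob_cli("obabel", c("-imol", "-oinchikey"), molblock))
  if (key_ok(x)) x else ""
}

#' @keywords internal
smilesToInchi <- function(smiles) {
  x <- .ob_clean_inchi(obConvert("SMI", "INCHI", smiles))
  if (!nzchar(x))
    x <- .ob_clean_inchi(.ob_cli("obabel", c(paste0("-:", smiles), "-oinchi")))
  x
}

## Normalize user-supplied MOL/SDF text through Open Babel. Validates the
## connection table and kekulizes any aromatic (order 4) bonds, so the
## in-package V2000 reader only ever sees orders 1-3.
#' @keywords internal
normalizeMolBlock <- function(moltext) {
  obConvert("MOL", "MOL", moltext)
}

## --- command-line Open Babel (features not reachable through ChemmineOB) ---

.ob_cli <- function(exe, args, stdin_text = NULL) {
  infile <- NULL
  if (!is.null(stdin_text)) {
    infile <- tempfile(fileext = ".mol")
    writeLines(stdin_text, infile)
    on.exit(unlink(infile), add = TRUE)
    ## obabel takes the input file before options, obminimize/obenergy after
    args <- if (identical(exe, "obabel")) c(infile, args) else c(args, infile)
  }
  out <- suppressWarnings(system2(exe, shQuote(args), stdout = TRUE,
                                  stderr = FALSE))
  paste(out, collapse = "\n")
}

#' Kekule canonical SMILES (obabel output option -xk, not exposed in process)
#' @keywords internal
molBlockToKekuleSmiles <- function(molblock) {
  .ob_clean_smiles(.ob_cli("obabel", c("-imol", "-ocan", "-xk"), molblock))
}

#' Deterministic 3D embedding
#'
#' Open Babel's own 3D builders are time-seeded and not reproducible, so the
#' package uses a fully deterministic route instead: a deterministic 2D
#' layout with explicit hydrogens, a seeded out-of-plane perturbation drawn
#' from R's RNG (this is where the embedding seed enters), and a
#' deterministic force-field minimization (obminimize, steepest descent).
#' The same SMILES and seed therefore give bit-identical coordinates across
#' runs and machines with the same Open Babel build.
#'
#' @param smiles single SMILES string (hydrogens are added before layout).
#' @param seed RNG seed for the out-of-plane perturbation.
#' @param forcefield "MMFF94", with automatic fallback to "UFF" when MMFF94
#'   has no parameters for the molecule.
#' @return list(start=jittered starting MOL block, minimized=minimized MOL
#'   block, energyBefore=, energyAfter=, forcefield=) or NULL on failure.
#' @keywords internal
obEmbed3d <- function(smiles, seed = 42L, forcefield = "MMFF94") {
  flat <- .ob_cli("obabel", c(paste0("-:", smiles), "-omol", "--gen2D", "-h"))
  if (!grepl("M  END", flat, fixed = TRUE)) return(NULL)
  g <- tryCatch(parseMolBlock(flat, foldH = FALSE), error = function(e) NULL)
  if (is.null(g) || !nrow(g@atoms)) return(NULL)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  g@atoms$z <- stats::runif(nrow(g@atoms), -0.6, 0.6)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  g@dim <- 3L
  start <- writeMolBlock(g)
  e0 <- .ob_energy(start, forcefield)
  minimized <- .ob_cli("obminimize", c("-ff", forcefield, "-o", "mol"),
                       stdin_text = start)
  if (!grepl("M  END", minimized, fixed = TRUE)) return(NULL)
  e1 <- .ob_energy(minimized, forcefield)
  if (is.na(e0) || is.na(e1)) {
    if (identical(forcefield, "MMFF94"))
      return(obEmbed3d(smiles, seed = seed, forcefield = "UFF"))
    return(NULL)
  }
  list(start = start, minimized = minimized,
       energyBefore = e0, energyAfter = e1, forcefield = forcefield)
}

.ob_energy <- function(molblock, forcefield) {
  infile <- tempfile(fileext = ".mol")
  writeLines(molblock, infile)
  on.exit(unlink(infile))
  out <- suppressWarnings(system2("obenergy", c("-ff", forcefield, infile),
                                  stdout = TRUE, stderr = TRUE))
  line <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (!length(line)) return(NA_real_)
  as.numeric(sub("^TOTAL ENERGY =\\s*([-0-9.eE+]+).*$", "\\1", line[1]))
}
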