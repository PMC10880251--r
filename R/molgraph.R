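## MolGraph: the package's molecular graph container.
##
## Atoms carry element, formal charge, isotope (0 = natural), implicit H count
## and coordinates; bonds carry Kekule order (1/2/3), an aromaticity flag set
## by Huckel perception, and the crossed (unknown cis/trans) display flag used
## in SDF output. Explicit hydrogens are folded into implicit counts at parse
## time except for isotopic hydrogens (D/T), which remain explicit atoms.

#' MolGraph class
#'
#' A minimal molecular graph: a data frame of atoms (`elem`, `charge`,
#' `isotope`, `hcount`, `arom`, `x`, `y`, `z`) and a data frame of bonds
#' (`a1`, `a2`, `order`, `arom`, `crossed`). Atom indices are 1-based.
#'
#' @slot atoms data.frame of atoms.
#' @slot bonds data.frame of bonds.
#' @slot dim 0 (no coordinates), 2 or 3.
#' @slot ringMode "aromatic" or "kekule"; controls canonical SMILES style.
#' @slot stereoSmiles canonical SMILES with stereo descriptors captured at
#'   parse time (NA once flattened).
#' @exportClass MolGraph
setClass("MolGraph", representation(
  atoms = "data.frame",
  bonds = "data.frame",
  dim = "integer",
  ringMode = "character",
  stereoSmiles = "character"
))

.empty_atoms <- function() {
  data.frame(elem = character(0), charge = integer(0), isotope = integer(0),
             hcount = integer(0), arom = logical(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             stringsAsFactors = FALSE)
}

.empty_bonds <- function() {
  data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
             arom = logical(0), crossed = logical(0), stringsAsFactors = FALSE)
}

setValidity("MolGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  need_a <- c("elem", "charge", "isotope", "hcount", "arom", "x", "y", "z")
  need_b <- c("a1", "a2", "order", "arom", "crossed")
  if (!all(need_a %in% names(a))) return("atoms is missing required columns")
  if (!all(need_b %in% names(b))) return("bonds is missing required columns")
  if (nrow(b)) {
    if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a)))
      return("bond references an atom index out of range")
    if (any(b$a1 == b$a2)) return("self-bond")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) return("duplicate bond")
    if (!all(b$order %in% 1:3)) return("bond order outside 1..3")
  }
  TRUE
})

#' Construct a MolGraph
#' @param atoms,bonds atom and bond data frames (see class docs).
#' @param dim coordinate dimensionality (0, 2 or 3).
#' @param ringMode "aromatic" or "kekule".
#' @param stereoSmiles stereo-bearing canonical SMILES or NA.
#' @return a MolGraph object
#' @export
MolGraph <- function(atoms = .empty_atoms(), bonds = .empty_bonds(),
                     dim = 0L, ringMode = "aromatic",
                     stereoSmiles = NA_character_) {
  new("MolGraph", atoms = atoms, bonds = bonds, dim = as.integer(dim),
      ringMode = ringMode, stereoSmiles = stereoSmiles)
}

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph: %d atoms (%d heavy), %d bonds, net charge %+d, %s\n",
              nrow(object@atoms), heavyAtomCount(object),
              nrow(object@bonds), netCharge(object), object@ringMode))
})

## ---------------------------------------------------------------- elements --

## Standard atomic weights for common elements (sufficient for the size
## filter; unknown elements fall back to 0 and are caught upstream by the
## composition filter anyway).
.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, T = 3.016, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085,
  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Ti = 47.867,
  Cr = 51.996, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904,
  Sr = 87.62, Mo = 95.95, Pd = 106.42, Ag = 107.868, Cd = 112.414,
  Sn = 118.71, Sb = 121.76, Te = 127.60, I = 126.904, Cs = 132.905,
  Ba = 137.327, Pt = 195.084, Au = 196.967, Hg = 200.592, Pb = 207.2,
  Bi = 208.980, Li = 6.94, Be = 9.012
)

.ATOMIC_NUMBER <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
  Kr = 36, Ag = 47, Sn = 50, Sb = 51, Te = 52, I = 53, Xe = 54, Pt = 78,
  Au = 79, Hg = 80, Pb = 82, Bi = 83
)

## Non-metals per the composition filter: H, B, C, N, O, Si, P, S, Se,
## halogens and noble gases. Everything else counts as a metal.
.NONMETALS <- c("H", "D", "T", "B", "C", "N", "O", "Si", "P", "S", "Se",
                "F", "Cl", "Br", "I", "At",
                "He", "Ne", "Ar", "Kr", "Xe", "Rn")

## MDL query-atom symbols that mark a Markush/ambiguous structure.
.QUERY_ATOMS <- c("*", "A", "Q", "R", "R#", "L", "LP", "Du", "X")

isMetal <- function(elem) {
  !(elem %in% .NONMETALS) & !(elem %in% .QUERY_ATOMS)
}

#' Allowed total valences for an element at a given formal charge
#'
#' Returns the legal valence set used both for implicit hydrogen filling and
#' for the post-remediation legality scan; NULL means "no model" (metals,
#' query atoms): any valence is tolerated and no hydrogens are implied.
#' @keywords internal
allowedValences <- function(elem, charge = 0L) {
  base <- switch(elem,
    H = 1L, D = 1L, T = 1L,
    B = 3L, C = 4L, Si = 4L, Ge = 4L, Sn = 4L,
    N = 3L, P = c(3L, 5L), As = c(3L, 5L),
    O = 2L, S = c(2L, 4L, 6L), Se = c(2L, 4L, 6L), Te = c(2L, 4L, 6L),
    F = 1L, Cl = c(1L, 3L, 5L, 7L), Br = c(1L, 3L, 5L, 7L),
    I = c(1L, 3L, 5L, 7L),
    NULL)
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  shift <- switch(elem,
    H = , D = , T = -abs(charge),
    B = if (charge < 0) -charge else -charge,
    C = , Si = , Ge = , Sn = -abs(charge),
    N = , P = , As = charge,
    O = , S = , Se = , Te = charge,
    F = , Cl = , Br = , I = charge,
    0L)
  v <- base + shift
  v <- v[v >= 0L]
  if (!length(v)) 0L else v
}

## Smallest legal valence that accommodates an existing bond-order sum; NA if
## even the largest legal valence is exceeded.
.target_valence <- function(elem, charge, bondsum) {
  av <- allowedValences(elem, charge)
  if (is.null(av)) return(bondsum)      # no model: no implicit H
  ok <- av[av >= bondsum]
  if (!length(ok)) return(NA_integer_)
  min(ok)
}

## ------------------------------------------------------------- accessors ---

#' Number of heavy (non-hydrogen) atoms
#' @param graph a MolGraph
#' @export
heavyAtomCount <- function(graph) {
  sum(!(graph@atoms$elem %in% c("H", "D", "T")))
}

#' Net formal charge
#' @param graph a MolGraph
#' @export
netCharge <- function(graph) as.integer(sum(graph@atoms$charge))

#' Number of bonds between heavy atoms
#' @param graph a MolGraph
#' @export
heavyBondCount <- function(graph) {
  if (!nrow(graph@bonds)) return(0L)
  hv <- !(graph@atoms$elem %in% c("H", "D", "T"))
  sum(hv[graph@bonds$a1] & hv[graph@bonds$a2])
}

#' Molecular weight (implicit hydrogens included)
#' @param graph a MolGraph
#' @export
molWeight <- function(graph) {
  a <- graph@atoms
  if (!nrow(a)) return(0)
  m <- unname(.ATOMIC_MASS[a$elem])
  m[is.na(m)] <- 0
  iso <- a$isotope > 0
  m[iso] <- a$isotope[iso]      # nominal mass for labelled atoms
  sum(m) + sum(a$hcount) * .ATOMIC_MASS[["H"]]
}

## Total bond order incident to each atom.
.bond_order_sums <- function(graph) {
  s <- numeric(nrow(graph@atoms))
  b <- graph@bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
      s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
    }
  }
  as.integer(s)
}

## Heavy-atom adjacency as a list of integer vectors.
.neighbors <- function(graph) {
  n <- nrow(graph@atoms)
  nb <- vector("list", n)
  b <- graph@bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- c(nb[[b$a1[k]]], b$a2[k])
    nb[[b$a2[k]]] <- c(nb[[b$a2[k]]], b$a1[k])
  }
  nb
}

## ---------------------------------------------------------------- parsing ---

#' Parse a (normalized) V2000 MOL block into a MolGraph
#'
#' Expects Kekule bond orders 1-3 (route user input through Open Babel first,
#' which kekulizes order-4 aromatic bonds). Reads M CHG / M ISO property
#' lines, folds non-isotopic explicit hydrogens into implicit counts when
#' `foldH` and fills the remaining implicit hydrogen counts from the valence
#' model.
#'
#' @param text a MOL block.
#' @param foldH fold explicit hydrogens into implicit counts.
#' @return a MolGraph; stops with an error on a malformed block.
#' @export
parseMolBlock <- function(text, foldH = TRUE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("MOL block too short")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0)
    stop("malformed counts line")
  if (length(lines) < 4 + natoms + nbonds) stop("truncated MOL block")

  atoms <- .empty_atoms()
  if (natoms > 0) {
    al <- lines[5:(4 + natoms)]
    x <- as.numeric(substr(al, 1, 10))
    y <- as.numeric(substr(al, 11, 20))
    z <- as.numeric(substr(al, 21, 30))
    elem <- trimws(substr(al, 32, 34))
    if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(elem)))
      stop("malformed atom block")
    ## old-style charge column (superseded by M CHG when present)
    cc <- suppressWarnings(as.integer(substr(al, 37, 39)))
    cc[is.na(cc)] <- 0L
    charge <- integer(natoms)
    charge[cc %in% 1:3] <- (4L - cc[cc %in% 1:3])
    charge[cc %in% 5:7] <- -(cc[cc %in% 5:7] - 4L)
    atoms <- data.frame(elem = elem, charge = charge, isotope = 0L,
                        hcount = 0L, arom = FALSE, x = x, y = y, z = z,
                        stringsAsFactors = FALSE)
  }

  bonds <- .empty_bonds()
  if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    a1 <- as.integer(substr(bl, 1, 3))
    a2 <- as.integer(substr(bl, 4, 6))
    ord <- as.integer(substr(bl, 7, 9))
    st <- suppressWarnings(as.integer(substr(bl, 10, 12)))
    st[is.na(st)] <- 0L
    if (any(is.na(a1) | is.na(a2) | is.na(ord))) stop("malformed bond block")
    if (any(ord > 3L | ord < 1L))
      stop("unsupported bond order (normalize aromatic bonds first)")
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord, arom = FALSE,
                        crossed = st == 3L, stringsAsFactors = FALSE)
  }

  ## property block: M CHG resets all old-style charges, M ISO sets isotopes
  prop <- lines[-seq_len(4 + natoms + nbonds)]
  chg_lines <- grep("^M  CHG", prop, value = TRUE)
  if (length(chg_lines)) atoms$charge <- 0L
  for (pl in chg_lines) {
    v <- .parse_m_pairs(pl)
    atoms$charge[v$idx] <- v$val
  }
  for (pl in grep("^M  ISO", prop, value = TRUE)) {
    v <- .parse_m_pairs(pl)
    atoms$isotope[v$idx] <- v$val
  }

  dim <- if (natoms == 0 || all(atoms$x == 0 & atoms$y == 0 & atoms$z == 0)) 0L
         else if (all(atoms$z == 0)) 2L else 3L
  g <- MolGraph(atoms, bonds, dim = dim)
  if (foldH) g <- virtualizeHydrogens(g)
  fillImplicitH(g)
}

.parse_m_pairs <- function(line) {
  n <- as.integer(substr(line, 7, 9))
  idx <- integer(n); val <- integer(n)
  for (i in seq_len(n)) {
    off <- 10 + (i - 1) * 8
    idx[i] <- as.integer(substr(line, off, off + 3))
    val[i] <- as.integer(substr(line, off + 4, off + 7))
  }
  list(idx = idx, val = val)
}

#' Fill implicit hydrogen counts from the valence model
#'
#' For each atom with a valence model, the implicit H count is raised to reach
#' the smallest legal valence that accommodates the explicit bond-order sum;
#' atoms without a model (metals, query atoms) get no implicit hydrogens.
#' Already-assigned implicit hydrogens are kept when larger.
#' @param graph a MolGraph
#' @export
fillImplicitH <- function(graph) {
  a <- graph@atoms
  if (!nrow(a)) return(graph)
  bs <- .bond_order_sums(graph)
  for (i in seq_len(nrow(a))) {
    tv <- .target_valence(a$elem[i], a$charge[i], bs[i])
    a$hcount[i] <- if (is.na(tv)) 0L else max(0L, tv - bs[i])
  }
  graph@atoms <- a
  graph
}

#' Fold explicit hydrogens into implicit counts
#'
#' Non-stereogenic explicit hydrogens become implicit; isotopic hydrogens
#' (D/T, M ISO > 1) stay explicit, as do charged hydrogens and H bonded to H.
#' @param graph a MolGraph
#' @return the graph with explicit H atoms removed
#' @export
virtualizeHydrogens <- function(graph) {
  a <- graph@atoms; b <- graph@bonds
  if (!nrow(a)) return(graph)
  nb <- .neighbors(graph)
  deg <- lengths(nb)
  fold <- which(a$elem == "H" & a$isotope == 0L & a$charge == 0L & deg == 1L)
  fold <- fold[vapply(fold, function(i) {
    j <- nb[[i]][1]
    a$elem[j] != "H" && b$order[b$a1 %in% c(i, j) & b$a2 %in% c(i, j)][1] == 1L
  }, logical(1))]
  if (!length(fold)) return(graph)
  for (i in fold) {
    j <- nb[[i]][1]
    a$hcount[j] <- a$hcount[j] + 1L
  }
  keep <- setdiff(seq_len(nrow(a)), fold)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  b <- b[!(b$a1 %in% fold | b$a2 %in% fold), , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  rownames(b) <- NULL
  graph@atoms <- a[keep, , drop = FALSE]
  rownames(graph@atoms) <- NULL
  graph@bonds <- b
  graph
}

## ---------------------------------------------------------------- writing ---

#' Write a MolGraph as a V2000 MOL block
#'
#' Deterministic output (fixed program line, no timestamp). Crossed double
#' bonds are written with stereo code 3; charges and isotopes as M CHG/M ISO.
#'
#' @param graph a MolGraph
#' @param title molecule name line
#' @return a single string containing the MOL block (no trailing "$$$$")
#' @export
writeMolBlock <- function(graph, title = "") {
  a <- graph@atoms; b <- graph@bonds
  dimtag <- if (graph@dim == 3L) "3D" else "2D"
  out <- c(title, sprintf("  qsarstd          %s", dimtag), "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  if (nrow(a)) {
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, a$elem))
  }
  if (nrow(b)) {
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", b$a1, b$a2, b$order,
                          ifelse(b$crossed, 3L, 0L)))
  }
  chg <- which(a$charge != 0L)
  for (grp in .chunk8(chg)) {
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                         paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                collapse = "")))
  }
  iso <- which(a$isotope != 0L)
  for (grp in .chunk8(iso)) {
    out <- c(out, paste0("M  ISO", sprintf("%3d", length(grp)),
                         paste0(sprintf("%4d%4d", grp, a$isotope[grp]),
                                collapse = "")))
  }
  paste(c(out, "M  END", ""), collapse = "\n")
}

.chunk8 <- function(idx) {
  if (!length(idx)) return(list())
  split(idx, ceiling(seq_along(idx) / 8))
}

## ---------------------------------------------------- fragments and rings ---

#' Extract the induced subgraph on a set of atoms
#' @keywords internal
subGraph <- function(graph, atomIdx) {
  atomIdx <- sort(atomIdx)
  remap <- integer(nrow(graph@atoms)); remap[atomIdx] <- seq_along(atomIdx)
  b <- graph@bonds
  b <- b[b$a1 %in% atomIdx & b$a2 %in% atomIdx, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  rownames(b) <- NULL
  a <- graph@atoms[atomIdx, , drop = FALSE]
  rownames(a) <- NULL
  MolGraph(a, b, dim = graph@dim, ringMode = graph@ringMode)
}

#' Split a molecular graph into connected fragments
#'
#' Fragments are returned in descending heavy-atom count; ties are broken by
#' lexicographic order of canonical SMILES so the result does not depend on
#' input atom numbering.
#' @param graph a MolGraph
#' @return list of single-fragment MolGraphs
#' @export
splitFragments <- function(graph) {
  n <- nrow(graph@atoms)
  if (n == 0) return(list())
  comp <- .components(graph)
  frags <- lapply(seq_len(max(comp)), function(k) {
    subGraph(graph, which(comp == k))
  })
  if (length(frags) == 1) return(frags)
  hv <- vapply(frags, heavyAtomCount, integer(1))
  smi <- vapply(frags, function(f) canonicalSmiles(f), character(1))
  frags[order(-hv, smi)]
}

## connected components without igraph overhead for tiny graphs
.components <- function(graph) {
  n <- nrow(graph@atoms)
  comp <- integer(n)
  nb <- .neighbors(graph)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

## Ring bonds = edges that are not bridges; small rings enumerated as the
## shortest cycle through each ring bond (adequate for aromaticity perception
## of 5-7 membered rings).
.ring_info <- function(graph) {
  b <- graph@bonds
  n <- nrow(graph@atoms)
  if (!nrow(b) || n < 3) {
    return(list(bondInRing = logical(nrow(b)), atomInRing = logical(n),
                rings = list()))
  }
  ig <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  br <- igraph::bridges(ig)
  bondInRing <- !(seq_len(nrow(b)) %in% as.integer(br))
  atomInRing <- logical(n)
  atomInRing[c(b$a1[bondInRing], b$a2[bondInRing])] <- TRUE
  rings <- list()
  seen <- character(0)
  for (k in which(bondInRing)) {
    ig2 <- igraph::delete_edges(ig, k)
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = b$a1[k],
                                                  to = b$a2[k]))$vpath[[1]]
    ring <- as.integer(sp)
    if (length(ring) < 3 || length(ring) > 7) next
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- ring
  }
  list(bondInRing = bondInRing, atomInRing = atomInRing, rings = rings)
}

#' Perceive aromaticity by Huckel's rule
#'
#' Flags atoms and bonds of rings whose pi-electron count satisfies 4n+2.
#' Contributions: an atom in an endocyclic double bond contributes 1; an atom
#' with an exocyclic double bond contributes 0; a heteroatom (N, O, S, Se)
#' with only single bonds contributes its lone pair (2); a carbanion 2, a
#' carbocation 0; any other saturated carbon disqualifies the ring.
#' Kekule bond orders are left untouched; only flags change.
#' @param graph a MolGraph
#' @return the graph with `arom` flags set
#' @export
perceiveAromaticity <- function(graph) {
  a <- graph@atoms; b <- graph@bonds
  a$arom <- FALSE
  if (nrow(b)) b$arom <- FALSE
  ri <- .ring_info(graph)
  bs <- .bond_order_sums(graph)
  bond_key <- if (nrow(b)) paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2)) else character(0)
  for (ring in ri$rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    pi_e <- 0
    ok <- TRUE
    for (v in ring) {
      el <- a$elem[v]
      if (!(el %in% c("C", "N", "O", "S", "Se", "P"))) { ok <- FALSE; break }
      in_ring_dbl <- any(b$order >= 2L &
        ((b$a1 == v & b$a2 %in% ring) | (b$a2 == v & b$a1 %in% ring)))
      exo_dbl <- any(b$order >= 2L &
        ((b$a1 == v & !(b$a2 %in% ring)) | (b$a2 == v & !(b$a1 %in% ring))))
      if (in_ring_dbl) {
        pi_e <- pi_e + 1
      } else if (exo_dbl) {
        pi_e <- pi_e + 0
      } else if (el %in% c("N", "O", "S", "Se", "P")) {
        pi_e <- pi_e + 2
      } else if (el == "C" && a$charge[v] < 0) {
        pi_e <- pi_e + 2
      } else if (el == "C" && a$charge[v] > 0) {
        pi_e <- pi_e + 0
      } else {
        ok <- FALSE; break     # saturated neutral carbon: no p orbital
      }
    }
    if (!ok || pi_e %% 4 != 2) next
    a$arom[ring] <- TRUE
    m <- length(ring)
    for (i in seq_len(m)) {
      u <- ring[i]; v <- ring[if (i == m) 1 else i + 1]
      b$arom[bond_key == paste(min(u, v), max(u, v))] <- TRUE
    }
  }
  graph@atoms <- a; graph@bonds <- b
  graph
}

## ------------------------------------------------------- identifiers etc. --

#' Canonical SMILES of a MolGraph
#'
#' Uses the Open Babel canonicalizer; honours the graph's ring mode
#' ("aromatic" writes aromatic SMILES, "kekule" alternating bond orders).
#' @param graph a MolGraph
#' @param mode override the graph's ring mode
#' @return a SMILES string ("" if canonicalization failed)
#' @export
canonicalSmiles <- function(graph, mode = NULL) {
  if (!nrow(graph@atoms)) return("")
  mode <- if (is.null(mode)) graph@ringMode else mode
  mb <- writeMolBlock(graph)
  if (identical(mode, "kekule")) molBlockToKekuleSmiles(mb)
  else molBlockToSmiles(mb)
}

#' Standard InChI and InChIKey of a MolGraph
#' @param graph a standardized single-fragment MolGraph
#' @return list(inchi=, inchikey=); stops if generation fails
#' @export
computeInchi <- function(graph) {
  if (!nrow(graph@atoms)) stop("cannot compute InChI of an empty graph")
  mb <- writeMolBlock(graph)
  inchi <- molBlockToInchi(mb)
  key <- molBlockToInchiKey(mb)
  if (!nzchar(inchi) || !nzchar(key)) stop("InChI generation failed")
  list(inchi = inchi, inchikey = key)
}
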