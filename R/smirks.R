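## Reaction-format (SMIRKS-style) rule expressions.
##
## A rule is "pattern>>product". The pattern side is a SMARTS subset: bracket
## atoms with element / #n / aromatic-lowercase primitives, charge, H<n>,
## X<n> (connections incl. implicit H), D<n> (explicit degree), v<n> (total
## bond order), R / R0 (ring membership), a / A, '!' negation, ',' OR and
## implicit AND; bonds - = # : ~ and the default single-or-aromatic bond;
## branches with parentheses. Ring-closure digits and multi-component
## patterns are deliberately out of the rule language: the shipped rules move
## protons, charges and bond orders only, never connectivity.
##
## Product atoms must all be mapped and bracketed; they prescribe the new
## formal charge (absent = 0) and optionally an explicit H count (otherwise
## implicit hydrogens are refilled from the valence model). Product bonds
## prescribe new Kekule orders; the product must connect the same mapped
## atom pairs as the pattern (connectivity preservation is enforced at parse
## time).

.TWO_LETTER <- c("Cl", "Br", "Si", "Se", "Na", "Li", "Mg", "Ca", "Fe", "Zn",
                 "Cu", "Mn", "Sn", "Pb", "Ag", "Au", "Hg", "As", "Te", "Al",
                 "Ba", "Sr", "Cs", "Ni", "Pt", "Pd", "Cd", "Co", "Cr", "Ti")
.AROM_LOWER <- c("c", "n", "o", "s", "p")

.Z_TO_SYMBOL <- local({
  z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
         Cl = 17, As = 33, Se = 34, Br = 35, Te = 52, I = 53)
  stats::setNames(names(z), as.character(z))
})

.prim <- function(kind, value = NA, neg = FALSE) {
  list(kind = kind, value = value, neg = neg)
}

## Parse the inside of a bracket atom (map already stripped).
## Returns a list of OR alternatives, each a list of primitives (AND).
.parse_atom_expr <- function(s, where) {
  alts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (!length(alts) || any(!nzchar(alts)))
    stop("empty atom expression in ", where)
  lapply(alts, function(alt) {
    prims <- list()
    i <- 1L; n <- nchar(alt)
    neg <- FALSE
    while (i <= n) {
      ch <- substr(alt, i, i)
      nxt <- if (i < n) substr(alt, i + 1, i + 1) else ""
      if (ch %in% c("&", ";")) { i <- i + 1L; next }
      if (ch == "!") { neg <- TRUE; i <- i + 1L; next }
      if (ch == "*") {
        prims[[length(prims) + 1L]] <- .prim("wild", neg = neg)
        i <- i + 1L
      } else if (ch == "#") {
        num <- .take_digits(alt, i + 1L)
        if (!nzchar(num$txt)) stop("'#' without atomic number in ", where)
        sym <- .Z_TO_SYMBOL[num$txt]
        if (is.na(sym)) stop("unsupported atomic number #", num$txt, " in ", where)
        prims[[length(prims) + 1L]] <- .prim("elem", list(sym = unname(sym), arom = NA), neg)
        i <- num$nxt
      } else if (ch == "H") {
        num <- .take_digits(alt, i + 1L)
        cnt <- if (nzchar(num$txt)) as.integer(num$txt) else 1L
        prims[[length(prims) + 1L]] <- .prim("H", cnt, neg)
        i <- num$nxt
      } else if (ch %in% c("X", "D", "v", "R")) {
        num <- .take_digits(alt, i + 1L)
        if (ch == "R") {
          flag <- !nzchar(num$txt) || as.integer(num$txt) > 0L
          prims[[length(prims) + 1L]] <- .prim("ring", flag, neg)
        } else {
          if (!nzchar(num$txt)) stop("'", ch, "' needs a count in ", where)
          prims[[length(prims) + 1L]] <- .prim(ch, as.integer(num$txt), neg)
        }
        i <- num$nxt
      } else if (ch %in% c("+", "-")) {
        sign <- if (ch == "+") 1L else -1L
        j <- i + 1L; reps <- 1L
        while (j <= n && substr(alt, j, j) == ch) { reps <- reps + 1L; j <- j + 1L }
        num <- .take_digits(alt, j)
        q <- if (nzchar(num$txt)) as.integer(num$txt) else reps
        prims[[length(prims) + 1L]] <- .prim("charge", sign * q, neg)
        i <- num$nxt
      } else if (ch == "A" && !(paste0(ch, nxt) %in% .TWO_LETTER)) {
        prims[[length(prims) + 1L]] <- .prim("aliphatic", neg = neg)
        i <- i + 1L
      } else if (ch == "a") {
        prims[[length(prims) + 1L]] <- .prim("aromatic", neg = neg)
        i <- i + 1L
      } else if (grepl("^[A-Z]$", ch)) {
        sym <- if (paste0(ch, nxt) %in% .TWO_LETTER) paste0(ch, nxt) else ch
        prims[[length(prims) + 1L]] <- .prim("elem", list(sym = sym, arom = FALSE), neg)
        i <- i + nchar(sym)
      } else if (grepl("^[a-z]$", ch)) {
        sym <- if (ch == "s" && nxt == "e") "se" else ch
        if (!(sym %in% c(.AROM_LOWER, "se")))
          stop("unknown aromatic symbol '", sym, "' in ", where)
        up <- if (sym == "se") "Se" else toupper(sym)
        prims[[length(prims) + 1L]] <- .prim("elem", list(sym = up, arom = TRUE), neg)
        i <- i + nchar(sym)
      } else {
        stop("unparseable atom primitive '", ch, "' in ", where)
      }
      neg <- FALSE
    }
    if (!length(prims)) stop("empty atom alternative in ", where)
    prims
  })
}

.take_digits <- function(s, i) {
  n <- nchar(s); j <- i
  while (j <= n && grepl("^[0-9]$", substr(s, j, j))) j <- j + 1L
  list(txt = substr(s, i, j - 1L), nxt = j)
}

#' Parse one side of a rule expression into a pattern graph
#' @return list(atoms = list(spec, map), bonds = data.frame(i, j, type))
#' @keywords internal
parsePattern <- function(s, where = s) {
  atoms <- list()
  bonds <- data.frame(i = integer(0), j = integer(0), type = character(0),
                      stringsAsFactors = FALSE)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- "?"
  i <- 1L; n <- nchar(s)
  add_atom <- function(spec, map) {
    atoms[[length(atoms) + 1L]] <<- list(spec = spec, map = map)
    k <- length(atoms)
    if (!is.na(prev)) {
      bonds[nrow(bonds) + 1L, ] <<- list(prev, k, pending)
    }
    prev <<- k
    pending <<- "?"
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    nxt <- if (i < n) substr(s, i + 1, i + 1) else ""
    if (ch == "[") {
      close <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close < 0) stop("unbalanced '[' in ", where)
      inner <- substr(s, i + 1L, i + close - 2L)
      map <- NA_integer_
      mm <- regmatches(inner, regexec("^(.*):([0-9]+)$", inner))[[1]]
      if (length(mm)) { inner <- mm[2]; map <- as.integer(mm[3]) }
      add_atom(.parse_atom_expr(inner, where), map)
      i <- i + close
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in ", where)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending <- "-"; i <- i + 1L
    } else if (grepl("^[0-9%]$", ch)) {
      stop("ring-closure digits are not supported in rule expressions: ", where)
    } else if (ch == ".") {
      stop("multi-component rule expressions are not supported: ", where)
    } else if (ch == "*") {
      add_atom(list(list(.prim("wild"))), NA_integer_); i <- i + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- if (paste0(ch, nxt) %in% c("Cl", "Br")) paste0(ch, nxt) else ch
      add_atom(list(list(.prim("elem", list(sym = sym, arom = FALSE)))),
               NA_integer_)
      i <- i + nchar(sym)
    } else if (ch %in% .AROM_LOWER) {
      add_atom(list(list(.prim("elem",
                               list(sym = toupper(ch), arom = TRUE)))),
               NA_integer_)
      i <- i + 1L
    } else {
      stop("unparseable character '", ch, "' in ", where)
    }
  }
  if (length(stack)) stop("unbalanced '(' in ", where)
  if (!length(atoms)) stop("empty pattern: ", where)
  list(atoms = atoms, bonds = bonds)
}

## ------------------------------------------------------------- matching ----

#' Per-atom properties consulted by pattern primitives
#' @keywords internal
atomProps <- function(graph) {
  a <- graph@atoms
  n <- nrow(a)
  deg <- integer(n); hnb <- integer(n)
  b <- graph@bonds
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
    if (a$elem[b$a2[k]] %in% c("H", "D", "T")) hnb[b$a1[k]] <- hnb[b$a1[k]] + 1L
    if (a$elem[b$a1[k]] %in% c("H", "D", "T")) hnb[b$a2[k]] <- hnb[b$a2[k]] + 1L
  }
  bs <- .bond_order_sums(graph)
  ri <- .ring_info(graph)
  list(elem = a$elem, charge = a$charge, arom = a$arom,
       totalH = a$hcount + hnb, X = deg + a$hcount, D = deg,
       v = bs + a$hcount, inRing = ri$atomInRing)
}

.prim_ok <- function(p, i, props) {
  val <- switch(p$kind,
    wild = TRUE,
    elem = {
      e <- props$elem[i] == p$value$sym
      if (e && !is.na(p$value$arom)) e <- props$arom[i] == p$value$arom
      e
    },
    aromatic = props$arom[i],
    aliphatic = !props$arom[i],
    H = props$totalH[i] == p$value,
    X = props$X[i] == p$value,
    D = props$D[i] == p$value,
    v = props$v[i] == p$value,
    ring = props$inRing[i] == p$value,
    charge = props$charge[i] == p$value,
    stop("unknown primitive kind ", p$kind))
  if (p$neg) !val else val
}

.atom_ok <- function(spec, i, props) {
  for (alt in spec) {
    ok <- TRUE
    for (p in alt) if (!.prim_ok(p, i, props)) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

.bond_ok <- function(type, order, arom) {
  switch(type,
    "-" = order == 1L && !arom,
    "=" = order == 2L,
    "#" = order == 3L,
    ":" = arom,
    "~" = TRUE,
    "?" = order == 1L || arom,
    FALSE)
}

#' Find all embeddings of a pattern in a molecular graph
#'
#' @param graph a MolGraph with aromaticity perceived.
#' @param pattern result of [parsePattern()].
#' @param props precomputed [atomProps()] (recomputed when NULL).
#' @return list of integer vectors mapping pattern atoms to graph atoms
#' @keywords internal
matchPattern <- function(graph, pattern, props = NULL) {
  np <- length(pattern$atoms)
  ng <- nrow(graph@atoms)
  if (np == 0 || ng == 0 || np > ng) return(list())
  if (is.null(props)) props <- atomProps(graph)

  ## adjacency with bond attributes
  nb <- vector("list", ng)
  b <- graph@bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- rbind(nb[[b$a1[k]]], c(b$a2[k], b$order[k], b$arom[k]))
    nb[[b$a2[k]]] <- rbind(nb[[b$a2[k]]], c(b$a1[k], b$order[k], b$arom[k]))
  }
  bond_lookup <- new.env(hash = TRUE)
  for (k in seq_len(nrow(b))) {
    assign(paste(min(b$a1[k], b$a2[k]), max(b$a1[k], b$a2[k])),
           c(b$order[k], b$arom[k]), envir = bond_lookup)
  }
  pb <- pattern$bonds
  ## for each pattern atom (after the first) the anchor bond to an earlier atom
  anchors <- lapply(seq_len(np), function(k) {
    rows <- which(pb$j == k & pb$i < k)
    if (length(rows)) rows[1] else NA_integer_
  })

  results <- list()
  assign_vec <- integer(np)
  recurse <- function(k) {
    if (k > np) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible())
    }
    anc <- anchors[[k]]
    cands <- if (is.na(anc)) seq_len(ng)
             else {
               m <- nb[[assign_vec[pb$i[anc]]]]
               if (is.null(m)) integer(0) else m[, 1]
             }
    for (t in cands) {
      if (t %in% assign_vec[seq_len(k - 1L)]) next
      if (!.atom_ok(pattern$atoms[[k]]$spec, t, props)) next
      ok <- TRUE
      for (r in which(pb$j == k | pb$i == k)) {
        other <- if (pb$i[r] == k) pb$j[r] else pb$i[r]
        if (other >= k) next
        bo <- get0(paste(min(t, assign_vec[other]), max(t, assign_vec[other])),
                   envir = bond_lookup)
        if (is.null(bo) || !.bond_ok(pb$type[r], bo[1], as.logical(bo[2]))) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[k] <<- t
      recurse(k + 1L)
      assign_vec[k] <<- 0L
    }
    invisible()
  }
  recurse(1L)
  results
}
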