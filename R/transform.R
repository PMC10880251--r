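## The transformation-rule engine: parse "pattern>>product" rules, apply one
## rule to fixed point, and run the ordered rule library.

#' Parse a reaction-format rule expression
#'
#' @param smirks a "pattern>>product" expression in the package's rule
#'   language (see `parsePattern`).
#' @return an object of class "smirks": pattern, product-side edit recipe.
#' @keywords internal
parseSmirks <- function(smirks) {
  sides <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("rule expression must contain one '>>': ", smirks)
  pat <- parsePattern(sides[1], smirks)
  prod <- parsePattern(sides[2], smirks)

  pmap <- vapply(pat$atoms, function(x) x$map, integer(1))
  qmap <- vapply(prod$atoms, function(x) x$map, integer(1))
  if (anyNA(qmap)) stop("all product atoms must be mapped: ", smirks)
  if (anyDuplicated(qmap[!is.na(qmap)]) || anyDuplicated(pmap[!is.na(pmap)]))
    stop("duplicate atom map: ", smirks)
  if (!all(qmap %in% pmap))
    stop("product atom map absent from pattern: ", smirks)

  ## edit recipe per product atom: target charge, explicit H (NA = refill)
  edits <- lapply(seq_along(prod$atoms), function(k) {
    spec <- prod$atoms[[k]]$spec
    if (length(spec) != 1)
      stop("product atoms cannot use OR expressions: ", smirks)
    charge <- 0L; hset <- NA_integer_; elem <- NA_character_
    for (p in spec[[1]]) {
      if (p$neg) stop("product atoms cannot use negation: ", smirks)
      if (p$kind == "charge") charge <- as.integer(p$value)
      else if (p$kind == "H") hset <- as.integer(p$value)
      else if (p$kind == "elem") elem <- p$value$sym
      else if (p$kind != "wild")
        stop("product atoms may carry only element/charge/H: ", smirks)
    }
    list(map = qmap[k], charge = charge, hset = hset, elem = elem)
  })

  ## product bonds keyed by map pair; must mirror the pattern's mapped bonds
  pair_key <- function(m1, m2) paste(min(m1, m2), max(m1, m2))
  prod_bonds <- list()
  for (r in seq_len(nrow(prod$bonds))) {
    m1 <- qmap[prod$bonds$i[r]]; m2 <- qmap[prod$bonds$j[r]]
    type <- prod$bonds$type[r]
    order <- switch(type, "-" = 1L, "?" = 1L, "=" = 2L, "#" = 3L,
                    stop("unsupported product bond '", type, "': ", smirks))
    prod_bonds[[pair_key(m1, m2)]] <- order
  }
  pat_pairs <- character(0)
  for (r in seq_len(nrow(pat$bonds))) {
    m1 <- pmap[pat$bonds$i[r]]; m2 <- pmap[pat$bonds$j[r]]
    if (!is.na(m1) && !is.na(m2)) pat_pairs <- c(pat_pairs, pair_key(m1, m2))
  }
  if (!setequal(names(prod_bonds), pat_pairs))
    stop("rules must not create or delete bonds (mapped connectivity must ",
         "match across '>>'): ", smirks)

  structure(list(pattern = pat, pmap = pmap, edits = edits,
                 prodBonds = prod_bonds, smirks = smirks),
            class = "smirks")
}

## Apply one parsed rule at one embedding. Returns the edited graph or NULL
## when the edit is chemically invalid (rolled back).
.apply_at <- function(graph, parsed, m, allowDecrease = FALSE) {
  a <- graph@atoms; b <- graph@bonds
  old_net <- sum(a$charge)
  target_of_map <- function(map) m[which(parsed$pmap == map)[1]]

  refill <- integer(0)
  for (e in parsed$edits) {
    t <- target_of_map(e$map)
    if (!is.na(e$elem) && a$elem[t] != e$elem) return(NULL)
    a$charge[t] <- e$charge
    if (is.na(e$hset)) refill <- c(refill, t) else a$hcount[t] <- e$hset
  }
  for (key in names(parsed$prodBonds)) {
    maps <- as.integer(strsplit(key, " ")[[1]])
    t1 <- target_of_map(maps[1]); t2 <- target_of_map(maps[2])
    row <- which((b$a1 == t1 & b$a2 == t2) | (b$a1 == t2 & b$a2 == t1))
    if (length(row) != 1) return(NULL)
    b$order[row] <- parsed$prodBonds[[key]]
    b$crossed[row] <- FALSE
  }
  g2 <- graph; g2@atoms <- a; g2@bonds <- b
  bs <- .bond_order_sums(g2)
  edited <- unique(c(refill, vapply(parsed$edits,
                                    function(e) target_of_map(e$map), integer(1))))
  for (t in edited) {
    tv <- .target_valence(a$elem[t], a$charge[t], bs[t])
    if (is.na(tv)) return(NULL)                       # over-valent result
    if (t %in% refill) a$hcount[t] <- max(0L, tv - bs[t])
    av <- allowedValences(a$elem[t], a$charge[t])
    if (!is.null(av) && !((bs[t] + a$hcount[t]) %in% av)) return(NULL)
  }
  g2@atoms <- a
  new_net <- sum(a$charge)
  ## tautomer/mesomer rules preserve net charge exactly; neutralization rules
  ## may reduce its magnitude but never push the molecule past neutral
  if (allowDecrease) {
    if (abs(new_net) > abs(old_net)) return(NULL)
  } else if (new_net != old_net) return(NULL)
  g2
}

#' Apply a transformation rule to fixed point
#'
#' All embeddings of the pattern are transformed, the graph is re-matched and
#' the rule re-applied until no match remains or the pass cap is reached (the
#' cap guards against oscillating rule pairs and is logged as a warning).
#' Edits that would produce an illegal valence are rolled back for that site.
#'
#' @param graph a MolGraph (single fragment, valence-corrected).
#' @param rule one row of a rule library (list with `rule_id`, `smirks`) or a
#'   bare SMIRKS string.
#' @param maxPasses iteration cap.
#' @param props precomputed [atomProps()] for `graph` (with aromaticity
#'   already perceived); recomputed when NULL.
#' @param allowChargeDecrease permit the edit to reduce the magnitude of the
#'   net formal charge (neutralization rules); tautomer/mesomer rules must
#'   preserve it exactly.
#' @return list(graph=, applications=, log=, props=) where `props` matches the
#'   returned graph
#' @export
applyRule <- function(graph, rule, maxPasses = 10L, props = NULL,
                      allowChargeDecrease = FALSE) {
  if (is.character(rule)) rule <- list(rule_id = rule, smirks = rule)
  parsed <- if (!is.null(rule$parsed)) rule$parsed else parseSmirks(rule$smirks)
  log <- character(0)
  napp <- 0L
  rejected <- character(0)
  if (is.null(props)) {
    graph <- perceiveAromaticity(graph)
    props <- atomProps(graph)
  }
  for (pass in seq_len(maxPasses)) {
    matches <- matchPattern(graph, parsed$pattern, props)
    if (!length(matches))
      return(list(graph = graph, applications = napp, log = log, props = props))
    used <- integer(0)
    applied <- FALSE
    seen_sites <- character(0)
    for (m in matches) {
      site <- paste(sort(m), collapse = "-")
      if (site %in% seen_sites || site %in% rejected) next
      seen_sites <- c(seen_sites, site)
      if (any(m %in% used)) next
      g2 <- .apply_at(graph, parsed, m, allowDecrease = allowChargeDecrease)
      if (is.null(g2)) {
        rejected <- c(rejected, site)
        log <- c(log, sprintf("rule %s rolled back at atoms %s (invalid valence)",
                              rule$rule_id, site))
        next
      }
      graph <- g2
      used <- c(used, m)
      napp <- napp + 1L
      applied <- TRUE
    }
    if (applied) {
      graph <- perceiveAromaticity(graph)
      props <- atomProps(graph)
    } else {
      return(list(graph = graph, applications = napp, log = log, props = props))
    }
  }
  if (length(matchPattern(graph, parsed$pattern, props))) {
    log <- c(log, sprintf("rule %s hit the %d-pass iteration cap",
                          rule$rule_id, maxPasses))
  }
  list(graph = graph, applications = napp, log = log, props = props)
}

## ------------------------------------------------------------ rule library --

#' RuleLibrary class
#'
#' The ordered, individually toggleable library of reaction-format
#' standardization rules. Rules are kept sorted by `order_index`; library
#' order is authoritative because some transformations do not commute.
#'
#' @slot rules data.frame with columns rule_id, order_index, enabled, family,
#'   smirks, name.
#' @slot parsed list of parsed rule expressions, parallel to `rules`.
#' @slot source path the library was loaded from.
#' @slot version version string.
#' @exportClass RuleLibrary
setClass("RuleLibrary", representation(
  rules = "data.frame", parsed = "list", source = "character",
  version = "character"
))

setValidity("RuleLibrary", function(object) {
  r <- object@rules
  need <- c("rule_id", "order_index", "enabled", "family", "smirks", "name")
  if (!all(need %in% names(r))) return("rules is missing required columns")
  if (anyDuplicated(r$order_index)) return("duplicate order_index")
  if (anyDuplicated(r$rule_id)) return("duplicate rule_id")
  if (is.unsorted(r$order_index)) return("rules must be sorted by order_index")
  if (length(object@parsed) != nrow(r)) return("parsed/rules length mismatch")
  TRUE
})

setMethod("show", "RuleLibrary", function(object) {
  r <- object@rules
  cat(sprintf("RuleLibrary: %d rules (%d enabled) [%s]\n",
              nrow(r), sum(r$enabled), object@source))
  print(table(r$family))
})

#' Number of rules in a library
#' @param library a RuleLibrary
#' @param enabledOnly count only enabled rules
#' @export
ruleCount <- function(library, enabledOnly = FALSE) {
  if (enabledOnly) sum(library@rules$enabled) else nrow(library@rules)
}

#' Load a transformation rule file
#'
#' One rule per line, tab-separated: `rule_id  order_index  enabled  family
#' smirks  name`. Lines starting with '#' and blank lines are skipped.
#' Malformed lines and unparseable rule expressions are reported with their
#' line number / rule id; duplicate order indices are an error.
#'
#' @param path rule file; defaults to the library shipped with the package.
#' @return a RuleLibrary
#' @export
loadRuleFile <- function(path = defaultRulePath()) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  rows <- list()
  for (ln in keep) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop("malformed rule line ", ln, " (expected 6 tab-separated fields)")
    oi <- suppressWarnings(as.integer(f[2]))
    en <- f[3] %in% c("1", "true", "TRUE", "yes")
    if (is.na(oi)) stop("bad order_index on line ", ln)
    if (!f[4] %in% c("mesomer", "tautomer", "neutralization", "other"))
      stop("unknown rule family '", f[4], "' on line ", ln)
    rows[[length(rows) + 1L]] <- data.frame(
      rule_id = f[1], order_index = oi, enabled = en, family = f[4],
      smirks = f[5], name = f[6], stringsAsFactors = FALSE)
  }
  rules <- do.call(rbind, rows)
  if (is.null(rules)) rules <- data.frame(
    rule_id = character(0), order_index = integer(0), enabled = logical(0),
    family = character(0), smirks = character(0), name = character(0))
  if (anyDuplicated(rules$order_index))
    stop("duplicate order_index in rule file: ",
         paste(rules$order_index[duplicated(rules$order_index)], collapse = ", "))
  rules <- rules[order(rules$order_index), , drop = FALSE]
  rownames(rules) <- NULL
  parsed <- vector("list", nrow(rules))
  for (k in seq_len(nrow(rules))) {
    parsed[[k]] <- tryCatch(parseSmirks(rules$smirks[k]), error = function(e) {
      stop("cannot parse rule ", rules$rule_id[k], ": ", conditionMessage(e))
    })
  }
  new("RuleLibrary", rules = rules, parsed = parsed,
      source = path, version = "1.0")
}

#' Path of the transformation rule library shipped with the package
#' @export
defaultRulePath <- function() {
  system.file("extdata", "qsar_transform_rules.tsv", package = "qsarstd")
}

.pkg_cache <- new.env(parent = emptyenv())

#' The default rule library (cached)
#' @export
defaultRuleLibrary <- function() {
  if (is.null(.pkg_cache$rules)) .pkg_cache$rules <- loadRuleFile()
  .pkg_cache$rules
}

#' Enable or disable rules by id
#' @param library a RuleLibrary
#' @param ids rule ids to change
#' @param enabled new state
#' @export
setRuleEnabled <- function(library, ids, enabled = TRUE) {
  hit <- library@rules$rule_id %in% ids
  if (!all(ids %in% library@rules$rule_id))
    stop("unknown rule id(s): ",
         paste(setdiff(ids, library@rules$rule_id), collapse = ", "))
  library@rules$enabled[hit] <- enabled
  library
}

#' Standardize mesomers and tautomers
#'
#' Applies the enabled rules of families "mesomer" and "tautomer" once
#' through the library, in order_index order, each to fixed point. Library
#' order is authoritative: the stage makes exactly one ordered sweep, with no
#' global fixed-point iteration across rules.
#'
#' @param graph single-fragment, valence-corrected MolGraph.
#' @param library a RuleLibrary (default: shipped library).
#' @return list(graph=, log=) where log records every rule application count
#' @export
standardizeMesomersTautomers <- function(graph, library = defaultRuleLibrary()) {
  .run_rule_families(graph, library, c("mesomer", "tautomer"),
                     allowChargeDecrease = FALSE)
}

.run_rule_families <- function(graph, library, families, allowChargeDecrease) {
  r <- library@rules
  idx <- which(r$enabled & r$family %in% families)
  log <- character(0)
  graph <- perceiveAromaticity(graph)
  props <- atomProps(graph)
  for (k in idx) {
    res <- applyRule(graph, c(as.list(r[k, ]), list(parsed = library@parsed[[k]])),
                     props = props, allowChargeDecrease = allowChargeDecrease)
    graph <- res$graph
    props <- res$props
    if (res$applications > 0)
      log <- c(log, sprintf("%s applied %d time(s)", r$rule_id[k],
                            res$applications))
    log <- c(log, res$log)
  }
  list(graph = graph, log = log)
}
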