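# Parsing of the BNGL-subset model dialect and the flat-text geometry format,
# plus trajectory (XYZ) and observable (TSV) writers.
#
# Supported model constructs: molecule types with components and ~states,
# seed species with counts, unidirectional (->) and reversible (<->) reaction
# rules of the binding / breaking / modifying kinds, bond labels !n, the
# bound-wildcard !+ and the anything-wildcard !?, observables (Molecules =
# per-embedding counting, Species = per-molecule-graph counting), and a
# non-standard `insertions` block for scheduled molecule additions.
# Exchange rules (creation/annihilation of molecules) are rejected.

strip_comment <- function(line) sub("#.*$", "", line)

# ---- species / pattern string parsing --------------------------------------

# Parse one molecule term "Name(b!1,p~U,c)" -> node record.
parse_node <- function(str, where = "") {
  m <- regmatches(str, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\((.*)\\))?$", str))[[1]]
  if (length(m) == 0 || m[2] == "")
    stop(sprintf("%smalformed molecule term '%s'", where, str), call. = FALSE)
  name <- m[2]
  comps <- list()
  body <- m[4]
  if (!is.na(body) && nzchar(body)) {
    for (tok in strsplit(body, ",", fixed = TRUE)[[1]]) {
      tok <- trimws(tok)
      cm <- regmatches(tok, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)(~[A-Za-z0-9_]+)?(!(\\+|\\?|[0-9]+))?$", tok))[[1]]
      if (length(cm) == 0 || cm[2] == "")
        stop(sprintf("%smalformed component '%s' in '%s'", where, tok, str),
             call. = FALSE)
      state <- if (nzchar(cm[3])) substring(cm[3], 2) else NA_character_
      bond <- "none"; label <- NA_integer_
      if (nzchar(cm[5])) {
        if (cm[5] == "+") bond <- "any"
        else if (cm[5] == "?") bond <- "wild"
        else { bond <- "edge"; label <- as.integer(cm[5]) }
      }
      comps[[length(comps) + 1L]] <- list(name = cm[2], state = state,
                                          bond = bond, label = label)
    }
  }
  list(species = name, comps = comps)
}

#' Parse a species or pattern string into a molecule graph
#'
#' `"A(b!1).S(a!1,c~P)"` becomes a graph with `nodes` (species + component
#' records) and `edges` (a matrix of node/component-slot pairs derived from
#' the bond labels).
#'
#' @param str species/pattern string.
#' @param where error-message prefix.
#' @return an `srb_graph`.
#' @export
parse_graph <- function(str, where = "") {
  terms <- strsplit(str, ".", fixed = TRUE)[[1]]
  nodes <- lapply(terms, parse_node, where = where)
  ends <- list()
  for (i in seq_along(nodes)) {
    for (s in seq_along(nodes[[i]]$comps)) {
      lb <- nodes[[i]]$comps[[s]]$label
      if (!is.na(lb)) {
        key <- as.character(lb)
        ends[[key]] <- rbind(if (key %in% names(ends)) ends[[key]], c(i, s))
      }
    }
  }
  edges <- matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("ni", "si", "nj", "sj")))
  for (key in names(ends)) {
    e <- ends[[key]]
    if (nrow(e) != 2)
      stop(sprintf("%sbond label !%s used %d time(s), need exactly 2 in '%s'",
                   where, key, nrow(e), str), call. = FALSE)
    edges <- rbind(edges, c(e[1, ], e[2, ]))
  }
  structure(list(nodes = nodes, edges = edges), class = "srb_graph")
}

graph_connected <- function(g) {
  n <- length(g$nodes)
  if (n <= 1) return(TRUE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      a <- g$edges[r, 1]; b <- g$edges[r, 3]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# Serialize a molecule graph back to its string form, assigning bond labels.
graph_to_str <- function(g) {
  lab <- matrix(NA_integer_, nrow = length(g$nodes),
                ncol = max(1L, max(vapply(g$nodes, function(n) length(n$comps), 1L))))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      lab[g$edges[r, 1], g$edges[r, 2]] <- r
      lab[g$edges[r, 3], g$edges[r, 4]] <- r
    }
  }
  terms <- vapply(seq_along(g$nodes), function(i) {
    nd <- g$nodes[[i]]
    cs <- vapply(seq_along(nd$comps), function(s) {
      cp <- nd$comps[[s]]
      out <- cp$name
      if (!is.na(cp$state)) out <- paste0(out, "~", cp$state)
      if (cp$bond == "any") out <- paste0(out, "!+")
      else if (cp$bond == "wild") out <- paste0(out, "!?")
      else if (cp$bond == "edge") out <- paste0(out, "!", lab[i, s])
      out
    }, "")
    if (length(cs)) paste0(nd$species, "(", paste(cs, collapse = ","), ")")
    else paste0(nd$species, "()")
  }, "")
  paste(terms, collapse = ".")
}

# ---- model file -------------------------------------------------------------

#' Parse a model file in the BNGL-subset dialect
#'
#' @param text model text (single string or character vector of lines), or a
#'   file path to read.
#' @return an object of class `srb_model` with elements `molecule_types`,
#'   `seeds`, `rules` (reversible rules already expanded into two
#'   unidirectional rules), `observables` and `insertions`.
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  types <- list(); seeds <- list(); rules <- list(); obs <- list(); ins <- list()
  block <- NULL
  for (ln in seq_along(lines)) {
    raw <- trimws(strip_comment(lines[ln]))
    if (!nzchar(raw)) next
    where <- sprintf("line %d: ", ln)
    low <- tolower(raw)
    if (grepl("^begin ", low)) {
      block <- sub("^begin\\s+", "", low)
      next
    }
    if (grepl("^end ", low)) { block <- NULL; next }
    if (is.null(block))
      stop(sprintf("%sstatement outside of any block: '%s'", where, raw),
           call. = FALSE)
    toks <- strsplit(raw, "\\s+")[[1]]
    if (block == "molecule types") {
      # in the types block, states are declared as name~s1~s2...
      tm <- regmatches(toks[1], regexec("^([A-Za-z_][A-Za-z0-9_]*)\\((.*)\\)$|^([A-Za-z_][A-Za-z0-9_]*)$", toks[1]))[[1]]
      body <- if (length(tm) >= 3) tm[3] else ""
      comps <- list()
      if (!is.na(body) && nzchar(body)) {
        for (tok in strsplit(body, ",", fixed = TRUE)[[1]]) {
          parts <- strsplit(trimws(tok), "~", fixed = TRUE)[[1]]
          comps[[length(comps) + 1L]] <-
            list(name = parts[1], states = if (length(parts) > 1) parts[-1] else character(0))
        }
      }
      nm <- if (!is.na(tm[2]) && nzchar(tm[2])) tm[2] else tm[4]
      if (nm %in% names(types))
        stop(sprintf("%sduplicate molecule type '%s'", where, nm), call. = FALSE)
      types[[nm]] <- list(name = nm, comps = comps)
    } else if (block == "seed species") {
      if (length(toks) != 2)
        stop(sprintf("%sseed species needs '<species> <count>'", where), call. = FALSE)
      g <- parse_graph(toks[1], where)
      if (!graph_connected(g))
        stop(sprintf("%sseed species must be connected: '%s'", where, toks[1]),
             call. = FALSE)
      cnt <- suppressWarnings(as.numeric(toks[2]))
      if (is.na(cnt) || cnt < 0 || cnt != round(cnt))
        stop(sprintf("%sbad seed count '%s'", where, toks[2]), call. = FALSE)
      seeds[[length(seeds) + 1L]] <- list(graph = g, count = as.integer(cnt),
                                          text = toks[1])
    } else if (block == "reaction rules") {
      rules <- c(rules, parse_rule_line(toks, where))
    } else if (block == "observables") {
      if (length(toks) != 3)
        stop(sprintf("%sobservable needs '<Molecules|Species> <name> <pattern>'", where),
             call. = FALSE)
      mode <- switch(tolower(toks[1]),
                     molecules = "per_embedding",
                     species = "per_molecule_graph",
                     stop(sprintf("%sunknown observable type '%s'", where, toks[1]),
                          call. = FALSE))
      g <- parse_graph(toks[3], where)
      if (!graph_connected(g))
        stop(sprintf("%sobservable pattern must be connected", where), call. = FALSE)
      obs[[length(obs) + 1L]] <- list(name = toks[2], graph = g, mode = mode,
                                      text = toks[3])
    } else if (block == "insertions") {
      if (length(toks) != 3)
        stop(sprintf("%sinsertion needs '<time> <species> <count>'", where),
             call. = FALSE)
      g <- parse_graph(toks[2], where)
      ins[[length(ins) + 1L]] <- list(time = as.numeric(toks[1]), graph = g,
                                      count = as.integer(toks[3]), text = toks[2])
    } else {
      stop(sprintf("%sunknown block '%s'", where, block), call. = FALSE)
    }
  }
  model <- structure(list(molecule_types = types, seeds = seeds, rules = rules,
                          observables = obs, insertions = ins),
                     class = "srb_model")
  validate_model(model)
  model
}

# Parse one reaction-rule line (already tokenized); returns a list of one or
# two unidirectional rule records.
parse_rule_line <- function(toks, where) {
  arrow <- which(toks %in% c("->", "<->"))
  if (length(arrow) != 1)
    stop(sprintf("%srule needs exactly one '->' or '<->'", where), call. = FALSE)
  rev <- toks[arrow] == "<->"
  lhs_toks <- toks[seq_len(arrow - 1)]
  rest <- toks[(arrow + 1):length(toks)]
  # products end where the rate expressions begin: rates are numeric
  isnum <- suppressWarnings(!is.na(as.numeric(gsub(",", "", rest))))
  nrate <- if (rev) 2L else 1L
  if (sum(isnum) < nrate || !all(isnum[(length(rest) - nrate + 1):length(rest)]))
    stop(sprintf("%scould not read %d rate constant(s) at end of rule", where, nrate),
         call. = FALSE)
  rates <- as.numeric(gsub(",", "", rest[(length(rest) - nrate + 1):length(rest)]))
  rhs_toks <- rest[seq_len(length(rest) - nrate)]
  split_side <- function(tk) {
    tk <- tk[tk != "+"]
    lapply(tk, parse_graph, where = where)
  }
  lhs <- split_side(lhs_toks)
  rhs <- split_side(rhs_toks)
  for (g in c(lhs, rhs)) if (!graph_connected(g))
    stop(sprintf("%seach reactant/product pattern must be connected", where),
         call. = FALSE)
  fwd <- analyze_rule(lhs, rhs, rates[1], where,
                      text = paste(toks, collapse = " "))
  if (!rev) return(list(fwd))
  bwd <- analyze_rule(rhs, lhs, rates[2], where,
                      text = paste(toks, collapse = " "))
  list(fwd, bwd)
}

flat_nodes <- function(side) {
  out <- list()
  for (p in seq_along(side)) for (n in seq_along(side[[p]]$nodes))
    out[[length(out) + 1L]] <- c(side[[p]]$nodes[[n]], list(p = p, n = n))
  out
}

flat_edges <- function(side) {
  off <- cumsum(c(0, vapply(side, function(g) length(g$nodes), 1L)))
  out <- matrix(integer(0), ncol = 4)
  for (p in seq_along(side)) {
    e <- side[[p]]$edges
    if (nrow(e)) {
      e[, 1] <- e[, 1] + off[p]; e[, 3] <- e[, 3] + off[p]
      out <- rbind(out, e)
    }
  }
  out
}

edge_keys <- function(e) {
  if (!nrow(e)) return(character(0))
  a <- paste0(e[, 1], ".", e[, 2]); b <- paste0(e[, 3], ".", e[, 4])
  paste(pmin(a, b), pmax(a, b))
}

# Classify a unidirectional rule as binding / breaking / modifying by
# comparing reactant and product graphs (positional node correspondence).
analyze_rule <- function(lhs, rhs, rate, where, text) {
  ln <- flat_nodes(lhs); rn <- flat_nodes(rhs)
  if (length(ln) != length(rn) ||
      !identical(vapply(ln, `[[`, "", "species"), vapply(rn, `[[`, "", "species")))
    stop(sprintf(
      "%sunsupported rule type: reactant and product molecules differ (exchange rules that create or delete molecules are not supported)",
      where), call. = FALSE)
  for (i in seq_along(ln)) {
    a <- vapply(ln[[i]]$comps, `[[`, "", "name")
    b <- vapply(rn[[i]]$comps, `[[`, "", "name")
    if (!identical(a, b))
      stop(sprintf("%smolecule %d lists different components on the two sides", where, i),
           call. = FALSE)
  }
  le <- flat_edges(lhs); re <- flat_edges(rhs)
  lk <- edge_keys(le); rk <- edge_keys(re)
  added <- setdiff(rk, lk); removed <- setdiff(lk, rk)
  state_changes <- list()
  for (i in seq_along(ln)) for (s in seq_along(ln[[i]]$comps)) {
    sl <- ln[[i]]$comps[[s]]$state; sr <- rn[[i]]$comps[[s]]$state
    if (!identical(sl, sr)) {
      if (is.na(sl) || is.na(sr))
        stop(sprintf("%sstate wildcard changed on one side only", where), call. = FALSE)
      state_changes[[length(state_changes) + 1L]] <- c(i, s)
    }
  }
  nchg <- (length(added) > 0) + (length(removed) > 0) + (length(state_changes) > 0)
  if (nchg != 1)
    stop(sprintf("%srule must make exactly one change (one bond formed, one bond deleted, or one state modified)", where),
         call. = FALSE)
  mk <- function(type, ...) {
    structure(list(type = type, rate = rate, text = text, ...),
              class = "srb_rule")
  }
  if (length(added) == 1L && length(removed) == 0L) {
    ek <- strsplit(added, " ")[[1]]
    pa <- as.integer(strsplit(ek[1], ".", fixed = TRUE)[[1]])
    pb <- as.integer(strsplit(ek[2], ".", fixed = TRUE)[[1]])
    na <- ln[[pa[1]]]; nb <- ln[[pb[1]]]
    if (na$p == nb$p)
      stop(sprintf("%sbinding within a single connected reactant pattern is not supported", where),
           call. = FALSE)
    if (length(lhs) != 2)
      stop(sprintf("%sbinding rule needs exactly two reactant patterns", where),
           call. = FALSE)
    for (nd in list(list(na, pa[2]), list(nb, pb[2]))) {
      if (nd[[1]]$comps[[nd[[2]]]]$bond != "none")
        stop(sprintf("%sbinding rule's acted components must be unbound on the reactant side", where),
             call. = FALSE)
    }
    ord <- if (na$p == 1) list(a = na, sa = pa[2], b = nb, sb = pb[2])
           else list(a = nb, sa = pb[2], b = na, sb = pa[2])
    g1 <- reorder_graph(lhs[[1]], ord$a$n)
    g2 <- reorder_graph(lhs[[2]], ord$b$n)
    mk("binding", arity = 2L, lhs = list(g1, g2),
       acted = c(ord$sa, ord$sb))
  } else if (length(removed) == 1L) {
    if (length(lhs) != 1)
      stop(sprintf("%sbreaking rule needs one connected reactant pattern", where),
           call. = FALSE)
    ek <- strsplit(removed, " ")[[1]]
    pa <- as.integer(strsplit(ek[1], ".", fixed = TRUE)[[1]])
    g <- reorder_graph(lhs[[1]], ln[[pa[1]]]$n)
    mk("breaking", arity = 1L, lhs = list(g), acted = pa[2])
  } else {
    chg <- state_changes[[1]]
    if (length(state_changes) != 1)
      stop(sprintf("%smodifying rule must change exactly one component state", where),
           call. = FALSE)
    node <- ln[[chg[1]]]
    new_state <- rn[[chg[1]]]$comps[[chg[2]]]$state
    if (length(lhs) == 1L) {
      g <- reorder_graph(lhs[[1]], node$n)
      mk("modifying", arity = 1L, lhs = list(g), acted = chg[2],
         new_state = new_state)
    } else if (length(lhs) == 2L) {
      # bimolecular (contact-catalyzed) modification: modified pattern first
      other <- if (node$p == 1) 2L else 1L
      g1 <- reorder_graph(lhs[[node$p]], node$n)
      g2 <- reorder_graph(lhs[[other]], 1L)
      mk("modifying", arity = 2L, lhs = list(g1, g2),
         acted = c(chg[2], 1L), new_state = new_state)
    } else {
      stop(sprintf("%smodifying rule needs one or two reactant patterns", where),
           call. = FALSE)
    }
  }
}

# Permute a graph's nodes so that node `first` comes first.
reorder_graph <- function(g, first) {
  n <- length(g$nodes)
  perm <- c(first, setdiff(seq_len(n), first))
  inv <- match(seq_len(n), perm)
  nodes <- g$nodes[perm]
  edges <- g$edges
  if (nrow(edges)) {
    edges[, 1] <- inv[edges[, 1]]
    edges[, 3] <- inv[edges[, 3]]
  }
  structure(list(nodes = nodes, edges = edges), class = "srb_graph")
}

# Cross-validate all references of a model against its molecule types.
validate_model <- function(model) {
  types <- model$molecule_types
  check_graph <- function(g, what, need_full = FALSE) {
    for (nd in g$nodes) {
      ty <- types[[nd$species]]
      if (is.null(ty))
        stop(sprintf("%s references undeclared species '%s'", what, nd$species),
             call. = FALSE)
      declared <- vapply(ty$comps, `[[`, "", "name")
      used <- vapply(nd$comps, `[[`, "", "name")
      for (nm in unique(used)) {
        if (sum(used == nm) > sum(declared == nm))
          stop(sprintf("%s uses component '%s' of '%s' more often than declared",
                       what, nm, nd$species), call. = FALSE)
      }
      for (cp in nd$comps) {
        if (!is.na(cp$state)) {
          ok <- any(vapply(ty$comps, function(d)
            d$name == cp$name && cp$state %in% d$states, TRUE))
          if (!ok)
            stop(sprintf("%s uses unknown state '%s' for component '%s' of '%s'",
                         what, cp$state, cp$name, nd$species), call. = FALSE)
        }
      }
      if (need_full) {
        if (length(nd$comps) != length(ty$comps))
          stop(sprintf("%s must list all components of '%s' (fully specified form)",
                       what, nd$species), call. = FALSE)
        for (s in seq_along(nd$comps)) {
          dstates <- ty$comps[[match(nd$comps[[s]]$name, declared)]]$states
          if (length(dstates) && is.na(nd$comps[[s]]$state))
            stop(sprintf("%s leaves stateful component '%s' of '%s' without a state",
                         what, nd$comps[[s]]$name, nd$species), call. = FALSE)
        }
      }
    }
  }
  for (i in seq_along(model$seeds))
    check_graph(model$seeds[[i]]$graph, sprintf("seed species %d", i), need_full = TRUE)
  for (i in seq_along(model$rules))
    for (g in model$rules[[i]]$lhs)
      check_graph(g, sprintf("rule %d ('%s')", i, model$rules[[i]]$text))
  for (i in seq_along(model$observables))
    check_graph(model$observables[[i]]$graph,
                sprintf("observable '%s'", model$observables[[i]]$name))
  for (i in seq_along(model$insertions))
    check_graph(model$insertions[[i]]$graph, sprintf("insertion %d", i),
                need_full = TRUE)
  invisible(model)
}

#' Serialize a parsed model back to its text form
#'
#' `parse_model(write_model(m))` reproduces `m` up to formatting; reversible
#' rules are written as the two expanded unidirectional rules.
#'
#' @param model an `srb_model`.
#' @return a single string of model text.
#' @export
write_model <- function(model) {
  out <- c("begin molecule types")
  for (ty in model$molecule_types) {
    cs <- vapply(ty$comps, function(cp)
      paste(c(cp$name, cp$states), collapse = "~"), "")
    out <- c(out, paste0("  ", ty$name, "(", paste(cs, collapse = ","), ")"))
  }
  out <- c(out, "end molecule types", "begin seed species")
  for (sd in model$seeds)
    out <- c(out, paste0("  ", graph_to_str(sd$graph), " ", sd$count))
  out <- c(out, "end seed species", "begin reaction rules")
  for (r in model$rules) out <- c(out, paste0("  ", rule_to_str(r)))
  out <- c(out, "end reaction rules", "begin observables")
  for (ob in model$observables) {
    kind <- if (ob$mode == "per_embedding") "Molecules" else "Species"
    out <- c(out, paste0("  ", kind, " ", ob$name, " ", graph_to_str(ob$graph)))
  }
  out <- c(out, "end observables")
  if (length(model$insertions)) {
    out <- c(out, "begin insertions")
    for (iv in model$insertions)
      out <- c(out, paste0("  ", iv$time, " ", graph_to_str(iv$graph), " ", iv$count))
    out <- c(out, "end insertions")
  }
  paste(out, collapse = "\n")
}

# Reconstruct a rule's textual form from its analyzed record.
rule_to_str <- function(r) {
  lhs <- vapply(r$lhs, graph_to_str, "")
  if (r$type == "binding") {
    g1 <- r$lhs[[1]]; g2 <- r$lhs[[2]]
    n1 <- length(g1$nodes)
    # product: merge the two graphs and add the new bond
    nodes <- c(g1$nodes, g2$nodes)
    nodes[[1]]$comps[[r$acted[1]]]$bond <- "edge"
    nodes[[n1 + 1L]]$comps[[r$acted[2]]]$bond <- "edge"
    edges <- g1$edges
    e2 <- g2$edges
    if (nrow(e2)) { e2[, 1] <- e2[, 1] + n1; e2[, 3] <- e2[, 3] + n1 }
    edges <- rbind(edges, e2, c(1L, r$acted[1], n1 + 1L, r$acted[2]))
    prod <- graph_to_str(structure(list(nodes = nodes, edges = edges),
                                   class = "srb_graph"))
    paste(lhs[1], "+", lhs[2], "->", prod, r$rate)
  } else if (r$type == "breaking") {
    g <- r$lhs[[1]]
    er <- which(
      (g$edges[, 1] == 1L & g$edges[, 2] == r$acted) |
      (g$edges[, 3] == 1L & g$edges[, 4] == r$acted))[1]
    a <- g$edges[er, 1:2]; b <- g$edges[er, 3:4]
    g2 <- g
    g2$edges <- g$edges[-er, , drop = FALSE]
    g2$nodes[[a[1]]]$comps[[a[2]]]$bond <- "none"
    g2$nodes[[b[1]]]$comps[[b[2]]]$bond <- "none"
    comp <- split_components(g2)
    rhs <- paste(vapply(comp, graph_to_str, ""), collapse = " + ")
    paste(graph_to_str(g), "->", rhs, r$rate)
  } else {
    g <- r$lhs[[1]]
    gp <- g
    gp$nodes[[1]]$comps[[r$acted[1]]]$state <- r$new_state
    if (r$arity == 1L) {
      paste(graph_to_str(g), "->", graph_to_str(gp), r$rate)
    } else {
      o <- graph_to_str(r$lhs[[2]])
      paste(graph_to_str(g), "+", o, "->", graph_to_str(gp), "+", o, r$rate)
    }
  }
}

# Split a possibly disconnected graph into its connected components.
split_components <- function(g) {
  n <- length(g$nodes)
  comp <- rep(0L, n); cc <- 0L
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(g$edges)) for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1]; b <- g$edges[r, 3]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (s in seq_len(n)) {
    if (comp[s]) next
    cc <- cc + 1L; queue <- s; comp[s] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- cc; queue <- c(queue, w) }
    }
  }
  lapply(seq_len(cc), function(k) {
    idx <- which(comp == k)
    map <- match(seq_len(n), idx)
    e <- g$edges
    if (nrow(e)) {
      keep <- comp[e[, 1]] == k
      e <- e[keep, , drop = FALSE]
      if (nrow(e)) { e[, 1] <- map[e[, 1]]; e[, 3] <- map[e[, 3]] }
    }
    structure(list(nodes = g$nodes[idx], edges = e), class = "srb_graph")
  })
}

# ---- geometry file ----------------------------------------------------------

#' Parse a geometry file
#'
#' Flat-text format, one declaration per line (angles in degrees on input,
#' stored in radians):
#' ```
#' species   <name> <mass> <radius> <diffusion>
#' component <species> <comp-name> <length> <theta> <phi>
#' tolerance <species> <t_dist> <t_ang>
#' angtol    <species> <comp-name> <t_ang>   # per-component override
#' rigid <species> [<species> ...]     # seeded complexes of these move rigidly
#' fixed <species> [<species> ...]     # these never move
#' ```
#' `component` lines are matched to the model's component declarations in
#' order of appearance per species.
#'
#' @param text geometry text or file path.
#' @param model optionally, an `srb_model` to cross-check against.
#' @return an object of class `srb_geometry`.
#' @export
parse_geometry <- function(text, model = NULL) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  species <- list(); rigid <- character(0); fixed <- character(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(strip_comment(lines[ln]))
    if (!nzchar(raw)) next
    where <- sprintf("geometry line %d: ", ln)
    toks <- strsplit(raw, "\\s+")[[1]]
    kw <- tolower(toks[1])
    if (kw == "species") {
      if (length(toks) != 5) stop(sprintf("%sspecies needs 4 fields", where), call. = FALSE)
      v <- as.numeric(toks[3:5])
      if (any(is.na(v)) || v[1] <= 0 || v[2] <= 0 || v[3] < 0)
        stop(sprintf("%sneed mass > 0, radius > 0, diffusion >= 0", where), call. = FALSE)
      species[[toks[2]]] <- list(name = toks[2], mass = v[1], radius = v[2],
                                 D = v[3], comps = list(),
                                 t_dist = NA_real_, t_ang = NA_real_)
    } else if (kw == "component") {
      if (length(toks) != 6) stop(sprintf("%scomponent needs 5 fields", where), call. = FALSE)
      sp <- species[[toks[2]]]
      if (is.null(sp)) stop(sprintf("%scomponent before species '%s'", where, toks[2]),
                            call. = FALSE)
      v <- as.numeric(toks[4:6])
      th <- v[2] * pi / 180; ph <- v[3] * pi / 180
      if (is.na(v[1]) || v[1] < 0)
        stop(sprintf("%scomponent length must be >= 0", where), call. = FALSE)
      if (th < 0 || th > pi + 1e-9)
        stop(sprintf("%stheta must lie in [0, 180] degrees", where), call. = FALSE)
      sp$comps[[length(sp$comps) + 1L]] <-
        list(name = toks[3], d = v[1], theta = th, phi = ph %% (2 * pi),
             t_ang = NA_real_)
      species[[toks[2]]] <- sp
    } else if (kw == "tolerance") {
      if (length(toks) != 4) stop(sprintf("%stolerance needs 3 fields", where), call. = FALSE)
      sp <- species[[toks[2]]]
      if (is.null(sp)) stop(sprintf("%stolerance before species '%s'", where, toks[2]),
                            call. = FALSE)
      sp$t_dist <- as.numeric(toks[3])
      sp$t_ang <- as.numeric(toks[4]) * pi / 180
      if (sp$t_dist < 0 || sp$t_ang < 0)
        stop(sprintf("%stolerances must be >= 0", where), call. = FALSE)
      species[[toks[2]]] <- sp
    } else if (kw == "angtol") {
      if (length(toks) != 4) stop(sprintf("%sangtol needs 3 fields", where), call. = FALSE)
      sp <- species[[toks[2]]]
      if (is.null(sp)) stop(sprintf("%sangtol before species '%s'", where, toks[2]),
                            call. = FALSE)
      hit <- which(vapply(sp$comps, function(c) c$name, "") == toks[3])
      if (!length(hit))
        stop(sprintf("%sangtol references unknown component '%s' of '%s'",
                     where, toks[3], toks[2]), call. = FALSE)
      for (h in hit) sp$comps[[h]]$t_ang <- as.numeric(toks[4]) * pi / 180
      species[[toks[2]]] <- sp
    } else if (kw == "rigid") {
      rigid <- union(rigid, toks[-1])
    } else if (kw == "fixed") {
      fixed <- union(fixed, toks[-1])
    } else {
      stop(sprintf("%sunknown keyword '%s'", where, toks[1]), call. = FALSE)
    }
  }
  geo <- structure(list(species = species, rigid = rigid, fixed = fixed),
                   class = "srb_geometry")
  if (!is.null(model)) validate_geometry(geo, model)
  geo
}

# Cross-check geometry entries against a model's molecule types.
validate_geometry <- function(geo, model) {
  for (ty in model$molecule_types) {
    sp <- geo$species[[ty$name]]
    if (is.null(sp))
      stop(sprintf("geometry: missing species entry for '%s'", ty$name), call. = FALSE)
    want <- vapply(ty$comps, `[[`, "", "name")
    have <- vapply(sp$comps, function(c) c$name, "")
    if (!identical(want, have))
      stop(sprintf("geometry: components of '%s' (%s) do not match the model (%s)",
                   ty$name, paste(have, collapse = ","), paste(want, collapse = ",")),
           call. = FALSE)
  }
  for (nm in c(geo$rigid, geo$fixed))
    if (!nm %in% names(model$molecule_types))
      stop(sprintf("geometry: rigid/fixed references undeclared species '%s'", nm),
           call. = FALSE)
  invisible(geo)
}

# ---- trajectory / observable output ----------------------------------------

#' Write a trajectory in XYZ format
#'
#' One block per frame: an atom count line, a comment line carrying the frame
#' time (`t=<time>`), then one `<species> x y z` record per elementary
#' molecule.
#'
#' @param frames list of frames; each frame is `list(time=, species=<chr>,
#'   pos=<n x 3 matrix>)`.
#' @param path output file.
#' @export
write_trajectory <- function(frames, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot open '%s': %s", path,
                                                   conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$pos)), con)
    writeLines(sprintf("t=%.10g", fr$time), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", fr$species,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_trajectory()]
#' @param path file path.
#' @return list of frames (`time`, `species`, `pos`).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    tm <- as.numeric(sub("^t=", "", lines[i + 1L]))
    rec <- strsplit(lines[(i + 2L):(i + 1L + n)], " ", fixed = TRUE)
    species <- vapply(rec, `[[`, "", 1)
    pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(time = tm, species = species, pos = pos)
    i <- i + 2L + n
  }
  frames
}

#' Write observable time series as tab-separated values
#'
#' @param series data.frame with a `time` column and one column per
#'   observable.
#' @param path output file.
#' @param header_lines optional provenance comment lines (prefixed `#`).
#' @export
write_observables <- function(series, path, header_lines = character(0)) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot open '%s': %s", path,
                                                   conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  writeLines(paste(colnames(series), collapse = "\t"), con)
  if (nrow(series))
    writeLines(do.call(paste, c(unname(as.list(series)), sep = "\t")), con)
  invisible(path)
}
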