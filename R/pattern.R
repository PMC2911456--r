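# Reactant patterns: compilation, anchored subgraph matching, pattern-index
# caching and incremental reindexing after reactions.
#
# A reactant pattern is a connected molecule graph in which components may be
# omitted (no constraint), carry a required state, and carry a bond-status
# requirement: unbound, bound-to-anything (!+), wildcard (!?), or bound to a
# specific pattern node (a pattern edge). Matching is a backtracking subgraph
# search anchored at a molecule (the pattern's first node), with species and
# bond-driven pruning. Automorphic images of symmetric patterns are collapsed
# so each unordered embedding is reported once.

#' Compile a parsed pattern graph into a matchable reactant pattern
#'
#' Resolves species and component references against the species tables of a
#' compiled system and precomputes the traversal order used by the matcher.
#'
#' @param graph an `srb_graph` (see [parse_graph()]).
#' @param species_tab,spindex the `species` list and `spindex` of an
#'   `srb_system`.
#' @return an `srb_pattern`.
#' @export
compile_pattern <- function(graph, species_tab, spindex) {
  n <- length(graph$nodes)
  sp <- integer(n)
  cons <- vector("list", n)
  partner <- vector("list", n)
  cands <- vector("list", n)
  for (v in seq_len(n)) {
    nd <- graph$nodes[[v]]
    sid <- spindex[[nd$species]]
    if (is.null(sid))
      stop(sprintf("pattern references unknown species '%s'", nd$species),
           call. = FALSE)
    sp[v] <- sid
    cons[[v]] <- nd$comps
    partner[[v]] <- vector("list", length(nd$comps))
    declared <- species_tab[[sid]]$comps$name
    cands[[v]] <- lapply(nd$comps, function(cp) which(declared == cp$name))
  }
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      e <- graph$edges[r, ]
      partner[[e[1]]][[e[2]]] <- c(e[3], e[4])
      partner[[e[3]]][[e[4]]] <- c(e[1], e[2])
    }
  }
  # BFS order over pattern edges from node 1
  order <- 1L
  via <- list(NULL)
  seen <- rep(FALSE, n); seen[1] <- TRUE
  qi <- 1L
  while (qi <= length(order)) {
    v <- order[qi]
    for (s in seq_along(partner[[v]])) {
      pw <- partner[[v]][[s]]
      if (!is.null(pw) && !seen[pw[1]]) {
        seen[pw[1]] <- TRUE
        order <- c(order, pw[1])
        via <- c(via, list(c(v, s, pw[2])))
      }
    }
    qi <- qi + 1L
  }
  if (!all(seen))
    stop("pattern must be connected", call. = FALSE)
  p <- list(n = n, species = sp, cons = cons, partner = partner,
            cands = cands, order = order, via = via,
            edges = graph$edges, graph = graph,
            diameter = pattern_graph_diameter(n, graph$edges))
  p$sym <- anchor_multiplicity(p)
  structure(p, class = "srb_pattern")
}

# Number of pattern nodes automorphic to node 1 (rooted-signature test).
# For a symmetric pattern every unordered embedding is seen from `sym`
# anchors, so summed anchored counts overcount occurrences by this factor.
anchor_multiplicity <- function(p) {
  sig <- function(v, depth, from_slot) {
    base <- vapply(seq_along(p$cons[[v]]), function(s) {
      cp <- p$cons[[v]][[s]]
      paste0(cp$name, "~", cp$state, "!", cp$bond)
    }, "")
    own <- paste0(p$species[v], "{", paste(sort(base), collapse = ","), "}")
    if (depth == 0L) return(own)
    nb <- character(0)
    for (s in seq_along(p$partner[[v]])) {
      pw <- p$partner[[v]][[s]]
      if (is.null(pw)) next
      nb <- c(nb, paste0(p$cons[[v]][[s]]$name, ">",
                         p$cons[[pw[1]]][[pw[2]]]$name, ">",
                         sig(pw[1], depth - 1L, pw[2])))
    }
    paste0(own, "[", paste(sort(nb), collapse = "|"), "]")
  }
  ref <- sig(1L, p$n, 0L)
  sum(vapply(seq_len(p$n), function(v) identical(sig(v, p$n, 0L), ref), TRUE))
}

pattern_graph_diameter <- function(n, edges) {
  if (n <= 1) return(0L)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 3]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dmax <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    dmax <- max(dmax, max(dist))
  }
  dmax
}

#' Graph diameter of a reactant pattern
#'
#' The longest shortest path (in bonds) between any two pattern nodes. The
#' maximum over all patterns of a rule set, `d_max`, bounds how far cached
#' pattern indices must be recomputed after a reaction.
#'
#' @param pattern a compiled pattern (`srb_pattern`).
#' @return non-negative integer.
#' @export
pattern_diameter <- function(pattern) pattern$diameter

#' Maximum pattern diameter over a compiled system's rules
#' @param sys compiled system.
#' @return integer `d_max`.
#' @export
max_rule_diameter <- function(sys) sys$d_max

# State label of component c of molecule i ("" when stateless).
mol_state_str <- function(rx, sys, i, c) {
  ss <- sys$species[[rx$species[i]]]$comp_states[[c]]
  if (!length(ss)) "" else ss[rx$state[i, c]]
}

#' Match a reactant pattern anchored at a molecule
#'
#' Enumerates every embedding of `pattern` into the reactor's molecule graphs
#' that maps the pattern's first node to `anchor`. Components omitted from a
#' pattern node impose no constraint; components listed several times under
#' one (duplicate) name are assigned to distinct same-named molecule
#' components, tried in declaration order. Automorphic images are collapsed:
#' each unordered embedding appears once.
#'
#' @param rx reactor.
#' @param sys compiled system.
#' @param pattern `srb_pattern`.
#' @param anchor molecule index.
#' @return list of embeddings, each `list(mols = <int per node>, comps =
#'   <list per node of molecule-component indices per constraint>)`.
#' @export
match_pattern <- function(rx, sys, pattern, anchor) {
  p <- pattern
  mols <- integer(p$n)
  comps <- vector("list", p$n)
  out <- list()

  node_ok_assign <- function(v, cand, k) {
    # try all injective assignments of node v's constraints to components of
    # molecule cand; on success, recurse to pattern node k+1
    ncons <- length(p$cons[[v]])
    used <- integer(0)
    assign_slot <- function(s) {
      if (s > ncons) { descend(k + 1L); return(invisible(NULL)) }
      cp <- p$cons[[v]][[s]]
      for (cc in p$cands[[v]][[s]]) {
        if (cc %in% used) next
        if (!is.na(cp$state) && mol_state_str(rx, sys, cand, cc) != cp$state) next
        bt <- rx$bond_to[cand, cc]
        if (cp$bond == "none" && bt != 0L) next
        if (cp$bond == "any" && bt == 0L) next
        if (cp$bond == "edge") {
          if (bt == 0L) next
          pw <- p$partner[[v]][[s]]
          if (mols[pw[1]] != 0L) {
            if (bt != mols[pw[1]]) next
            pc <- comps[[pw[1]]][pw[2]]
            if (!is.na(pc) && rx$bond_comp[cand, cc] != pc) next
          } else {
            if (rx$species[bt] != p$species[pw[1]]) next
          }
        }
        used <<- c(used, cc)
        comps[[v]][s] <<- cc
        assign_slot(s + 1L)
        used <<- used[-length(used)]
        comps[[v]][s] <<- NA_integer_
      }
    }
    comps[[v]] <<- rep(NA_integer_, ncons)
    mols[v] <<- cand
    assign_slot(1L)
    mols[v] <<- 0L
    comps[v] <<- list(NULL)
  }

  descend <- function(k) {
    if (k > p$n) {
      out[[length(out) + 1L]] <<- list(mols = mols, comps = comps)
      return(invisible(NULL))
    }
    v <- p$order[k]
    if (k == 1L) {
      cand <- anchor
    } else {
      vv <- p$via[[k]]
      pm <- mols[vv[1]]
      pc <- comps[[vv[1]]][vv[2]]
      cand <- rx$bond_to[pm, pc]
      if (cand == 0L) return(invisible(NULL))
    }
    if (cand %in% mols) return(invisible(NULL))
    if (rx$species[cand] != p$species[v]) return(invisible(NULL))
    node_ok_assign(v, cand, k)
  }

  if (anchor < 1L || anchor > rx$n) stop("match_pattern: no such molecule")
  descend(1L)
  # collapse automorphic images (only possible when several embeddings exist)
  if (length(out) > 1L) {
    keys <- vapply(out, function(e) embedding_key(p, e$mols, e$comps, rx), "")
    out <- out[!duplicated(keys)]
  }
  out
}

# Canonical key of an embedding, invariant under pattern automorphisms.
embedding_key <- function(p, mols, comps, rx) {
  ntok <- vapply(seq_len(p$n), function(v) {
    sig <- vapply(seq_along(p$cons[[v]]), function(s) {
      cp <- p$cons[[v]][[s]]
      paste0(comps[[v]][s], ":", cp$name, "~", cp$state, "!", cp$bond)
    }, "")
    paste0(mols[v], "[", paste(sort(sig), collapse = ","), "]")
  }, "")
  etok <- if (nrow(p$edges)) {
    vapply(seq_len(nrow(p$edges)), function(r) {
      e <- p$edges[r, ]
      a <- paste0(mols[e[1]], ".", comps[[e[1]]][e[2]])
      b <- paste0(mols[e[3]], ".", comps[[e[3]]][e[4]])
      paste(min(a, b), max(a, b))
    }, "")
  } else character(0)
  paste(paste(sort(ntok), collapse = ";"), paste(sort(etok), collapse = ";"))
}

#' Pattern indices of one molecule
#'
#' Returns, for each enumerated rule pattern, the number of embeddings
#' anchored at `molecule`; the cached `rx$P` row equals this at all times
#' outside a reaction-execution transaction.
#'
#' @param rx reactor; @param sys compiled system; @param molecule index.
#' @return integer vector over `sys$patterns`.
#' @export
assign_pattern_indices <- function(rx, sys, molecule) {
  vapply(sys$patterns, function(p) {
    if (p$species[1] != rx$species[molecule]) 0L
    else length(match_pattern(rx, sys, p, molecule))
  }, 1L)
}

# Molecules within graph distance d of the given set (bond-graph BFS).
bond_ball <- function(rx, from, d) {
  seen <- from
  frontier <- from
  depth <- 0L
  while (depth < d && length(frontier)) {
    nxt <- integer(0)
    for (m in frontier) {
      nb <- rx$bond_to[m, ]
      nb <- nb[nb > 0L]
      nxt <- c(nxt, nb[!(nb %in% seen)])
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }
  seen
}

#' Recompute cached pattern indices around modified molecules
#'
#' After a reaction transaction has changed bonds or states of `modified`,
#' it suffices to re-match molecules within graph distance `d_max` of them;
#' afterwards every cached row equals a from-scratch rematch.
#'
#' @param rx reactor; @param sys compiled system.
#' @param modified integer vector of molecule indices.
#' @param d_max recompute radius (defaults to the system's `d_max`).
#' @export
reindex_after_reaction <- function(rx, sys, modified, d_max = sys$d_max) {
  ball <- bond_ball(rx, unique(modified), d_max)
  for (m in ball) rx$P[m, ] <- assign_pattern_indices(rx, sys, m)
  rx$prop_dirty <- TRUE
  invisible(ball)
}

#' Number of distinct modification-state combinations of a species
#'
#' Product over components of `max(1, number of allowed states)`.
#'
#' @param species either a molecule-type record of a parsed model or a
#'   compiled species entry.
#' @return a double (counts can exceed integer range).
#' @export
count_species_states <- function(species) {
  ns <- if (!is.null(species$comp_states))
    vapply(species$comp_states, length, 1L)
  else vapply(species$comps, function(cp) length(cp$states), 1L)
  prod(pmax(1, ns))
}

#' Count occurrences of a pattern in the reactor
#'
#' `per_embedding` counts distinct embeddings over all anchors (automorphic
#' images of symmetric patterns count once); `per_molecule_graph` counts the
#' complexes that contain at least one embedding.
#'
#' @param rx reactor; @param sys compiled system.
#' @param pattern `srb_pattern`.
#' @param mode `"per_embedding"` or `"per_molecule_graph"`.
#' @return integer count.
#' @export
count_pattern_occurrences <- function(rx, sys, pattern,
                                      mode = c("per_embedding", "per_molecule_graph")) {
  mode <- match.arg(mode)
  keys <- character(0)
  reps <- integer(0)
  anchors <- which(rx$alive & rx$species == pattern$species[1])
  for (i in anchors) {
    for (e in match_pattern(rx, sys, pattern, i)) {
      k <- embedding_key(pattern, e$mols, e$comps, rx)
      if (!(k %in% keys)) {
        keys <- c(keys, k)
        reps <- c(reps, e$mols[1])
      }
    }
  }
  if (mode == "per_embedding") return(length(keys))
  if (!length(reps)) return(0L)
  comp <- rx_complex_ids(rx)
  length(unique(comp[reps]))
}
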