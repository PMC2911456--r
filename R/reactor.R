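# The reactor: mutable simulation state held in an environment. Arrays are
# molecule-indexed; components are columns (up to the largest component count
# over all species; unused columns stay zero). Bonds are stored symmetrically:
# bond_to[i, c] / bond_comp[i, c] give the partner molecule and its component.

#' Create an empty reactor for a compiled system
#' @param sys compiled system (see [compile_system()]).
#' @return an environment of class `srb_reactor`.
#' @export
new_reactor <- function(sys) {
  rx <- new.env(parent = emptyenv())
  mc <- sys$max_comps
  np <- length(sys$patterns)
  rx$n <- 0L
  rx$species <- integer(0)
  rx$alive <- logical(0)
  rx$pos <- matrix(numeric(0), 0, 3)
  rx$vel <- matrix(numeric(0), 0, 3)
  rx$force <- matrix(numeric(0), 0, 3)
  rx$state <- matrix(integer(0), 0, mc)
  rx$bond_to <- matrix(integer(0), 0, mc)
  rx$bond_comp <- matrix(integer(0), 0, mc)
  rx$refract <- numeric(0)
  rx$rigid <- integer(0)
  rx$frozen <- logical(0)
  rx$P <- matrix(integer(0), 0, np)
  rx$time <- 0
  rx$next_rigid <- 0L
  rx$geom_dirty <- TRUE
  rx$prop_dirty <- TRUE
  rx$bonds <- matrix(integer(0), 0, 2)
  rx$bond_d0 <- numeric(0)
  rx$angles <- matrix(integer(0), 0, 3)
  rx$angle_a0 <- numeric(0)
  rx$diag <- new.env(parent = emptyenv())
  for (k in c("candidates", "fired", "rej_dist_ang", "rej_refractory", "stale",
              "mono_events"))
    assign(k, 0L, envir = rx$diag)
  class(rx) <- "srb_reactor"
  rx
}

# Map the listed component slots of a fully specified node to declared
# component indices (duplicate names assigned in declaration order).
seed_slot_map <- function(node, species) {
  declared <- species$comps$name
  used <- logical(length(declared))
  vapply(node$comps, function(cp) {
    k <- which(declared == cp$name & !used)[1]
    if (is.na(k)) stop("component mapping failed for seed node", call. = FALSE)
    used[k] <<- TRUE
    k
  }, 1L)
}

#' Instantiate a fully specified molecule graph in the reactor
#'
#' Adds the graph's molecules at the given member coordinates (nnode x 3),
#' creates its bonds, draws thermal velocities and updates the pattern-index
#' cache. Returns the new molecule indices.
#'
#' @param rx reactor; @param sys compiled system.
#' @param graph an `srb_graph` in fully specified form.
#' @param coords member coordinates, nnode x 3.
#' @param rigid move the members as one rigid body.
#' @param frozen override the species' fixed flags.
#' @param temperature for the initial velocities.
#' @return integer molecule indices.
#' @export
rx_add_graph <- function(rx, sys, graph, coords, rigid = FALSE, frozen = NULL,
                         temperature = sys$config$temperature) {
  nn <- length(graph$nodes)
  stopifnot(nrow(coords) == nn)
  mc <- sys$max_comps
  ids <- rx$n + seq_len(nn)
  slotmaps <- vector("list", nn)
  sp <- integer(nn)
  st <- matrix(0L, nn, mc)
  for (v in seq_len(nn)) {
    nd <- graph$nodes[[v]]
    sid <- sys$spindex[[nd$species]]
    sp[v] <- sid
    spp <- sys$species[[sid]]
    slotmaps[[v]] <- seed_slot_map(nd, spp)
    for (s in seq_along(nd$comps)) {
      c <- slotmaps[[v]][s]
      states <- spp$comp_states[[c]]
      if (length(states)) {
        idx <- match(nd$comps[[s]]$state, states)
        if (is.na(idx))
          stop(sprintf("seed state '%s' not allowed for %s.%s",
                       nd$comps[[s]]$state, nd$species, nd$comps[[s]]$name),
               call. = FALSE)
        st[v, c] <- idx
      }
    }
  }
  frz <- if (is.null(frozen))
    vapply(sp, function(s) sys$species[[s]]$fixed, TRUE) else rep(frozen, nn)
  grp <- 0L
  if (rigid && nn > 1L) {
    rx$next_rigid <- rx$next_rigid + 1L
    grp <- rx$next_rigid
  }
  vel <- t(vapply(sp, function(s)
    if (temperature > 0) rnorm(3, 0, sqrt(temperature / sys$species[[s]]$mass))
    else c(0, 0, 0), numeric(3)))
  frz_any <- any(frz)
  if (frz_any) vel[frz, ] <- 0
  rx$species <- c(rx$species, sp)
  rx$alive <- c(rx$alive, rep(TRUE, nn))
  rx$pos <- rbind(rx$pos, coords)
  rx$vel <- rbind(rx$vel, vel)
  rx$force <- rbind(rx$force, matrix(0, nn, 3))
  rx$state <- rbind(rx$state, st)
  rx$bond_to <- rbind(rx$bond_to, matrix(0L, nn, mc))
  rx$bond_comp <- rbind(rx$bond_comp, matrix(0L, nn, mc))
  rx$refract <- c(rx$refract, rep(-Inf, nn))
  rx$rigid <- c(rx$rigid, rep(grp, nn))
  rx$frozen <- c(rx$frozen, frz)
  rx$P <- rbind(rx$P, matrix(0L, nn, ncol(rx$P)))
  rx$n <- rx$n + nn
  # intra-graph bonds
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      e <- graph$edges[r, ]
      rx_bind(rx, ids[e[1]], slotmaps[[e[1]]][e[2]],
              ids[e[3]], slotmaps[[e[3]]][e[4]])
    }
  }
  for (m in ids) rx$P[m, ] <- assign_pattern_indices(rx, sys, m)
  rx$geom_dirty <- TRUE
  rx$prop_dirty <- TRUE
  ids
}

#' Create a bond between two molecule components
#' @param rx reactor; @param i,ci molecule/component; @param j,cj partner.
#' @export
rx_bind <- function(rx, i, ci, j, cj) {
  if (rx$bond_to[i, ci] != 0L || rx$bond_to[j, cj] != 0L)
    stop("rx_bind: component already bound", call. = FALSE)
  if (i == j) stop("rx_bind: cannot bond a molecule to itself", call. = FALSE)
  rx$bond_to[i, ci] <- j; rx$bond_comp[i, ci] <- cj
  rx$bond_to[j, cj] <- i; rx$bond_comp[j, cj] <- ci
  rx$geom_dirty <- TRUE
  invisible(rx)
}

#' Delete the bond at a molecule component (and its mirror entry)
#' @param rx reactor; @param i,ci molecule/component.
#' @return the former partner `(molecule, component)`, invisibly.
#' @export
rx_unbind <- function(rx, i, ci) {
  j <- rx$bond_to[i, ci]
  if (j == 0L) stop("rx_unbind: component not bound", call. = FALSE)
  cj <- rx$bond_comp[i, ci]
  rx$bond_to[i, ci] <- 0L; rx$bond_comp[i, ci] <- 0L
  rx$bond_to[j, cj] <- 0L; rx$bond_comp[j, cj] <- 0L
  rx$geom_dirty <- TRUE
  invisible(c(j, cj))
}

#' Set the modification state of a molecule component
#' @param rx reactor; @param sys compiled system; @param i,ci
#'   molecule/component; @param state state label or index.
#' @export
rx_set_state <- function(rx, sys, i, ci, state) {
  states <- sys$species[[rx$species[i]]]$comp_states[[ci]]
  idx <- if (is.character(state)) match(state, states) else state
  if (is.na(idx) || idx < 1L || idx > length(states))
    stop("rx_set_state: unknown state", call. = FALSE)
  rx$state[i, ci] <- as.integer(idx)
  invisible(rx)
}

# Rebuild the bond / angle term arrays consumed by the force kernels.
# Bonds internal to one rigid group are omitted; an angle term is omitted
# only when all three molecules share a rigid group.
rx_rebuild_bonded <- function(rx, sys) {
  fl <- sys$flat
  bt <- build_bonded_cpp(rx$bond_to, rx$bond_comp, rx$species,
                         fl$comp_d, fl$ncomp, fl$alpha, rx$rigid)
  rx$bonds <- bt$bonds
  rx$bond_d0 <- bt$bond_d0
  rx$angles <- bt$angles
  rx$angle_a0 <- bt$angle_a0
  rx$geom_dirty <- FALSE
  invisible(rx)
}

#' Complex (connected-component) id per molecule
#' @param rx reactor.
#' @return integer vector over molecules.
#' @export
rx_complex_ids <- function(rx) {
  n <- rx$n
  comp <- integer(n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cc <- cc + 1L
    queue <- s; comp[s] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- rx$bond_to[v, ]
      for (w in nb[nb > 0L]) if (!comp[w]) { comp[w] <- cc; queue <- c(queue, w) }
    }
  }
  comp
}

#' Audit reactor invariants
#'
#' Checks bond symmetry (if component c of i records partner (j, c'), then
#' component c' of j records (i, c)) and, optionally, that every cached
#' pattern-index row equals a from-scratch rematch.
#'
#' @param rx reactor; @param sys compiled system.
#' @param check_patterns also verify the pattern-index cache.
#' @return `TRUE` invisibly; stops on violation.
#' @export
rx_audit <- function(rx, sys, check_patterns = FALSE) {
  for (i in seq_len(rx$n)) {
    for (c in which(rx$bond_to[i, ] > 0L)) {
      j <- rx$bond_to[i, c]; cj <- rx$bond_comp[i, c]
      if (rx$bond_to[j, cj] != i || rx$bond_comp[j, cj] != c)
        stop(sprintf("bond symmetry violated at molecule %d component %d", i, c))
    }
  }
  if (check_patterns) {
    for (i in seq_len(rx$n)) {
      want <- assign_pattern_indices(rx, sys, i)
      if (!identical(unname(rx$P[i, ]), unname(want)))
        stop(sprintf("pattern-index cache stale at molecule %d", i))
    }
  }
  invisible(TRUE)
}
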