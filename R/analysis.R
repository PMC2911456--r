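# Post-processing: mean-squared displacement, complex-structure analyzers
# for the packaged fixtures (protofilaments, seam/helicity, ring census,
# tile-grid extraction and scoring), transport summaries, and the physical
# time-step worked example. All analyzers are pure functions of reactor
# state or trajectories.

#' Mean-squared displacement versus lag time
#'
#' Ensemble- and time-averaged MSD computed from trajectory frames; periodic
#' trajectories are unwrapped via minimum-image displacements between
#' consecutive frames (valid while per-frame motion stays below half a box
#' length). For a freely diffusing species the long-time MSD is `6 D t`.
#'
#' @param frames trajectory (list of frames as produced by
#'   [run_simulation()] or [read_trajectory()]).
#' @param species optional species name filter.
#' @param box,periodic boundary description for unwrapping (omit for
#'   non-periodic data).
#' @param max_lags number of lag values to evaluate.
#' @return data.frame with `lag` (time) and `msd`.
#' @export
msd_curve <- function(frames, species = NULL, box = NULL, periodic = NULL,
                      max_lags = 40L) {
  stopifnot(length(frames) >= 2L)
  n0 <- nrow(frames[[1]]$pos)
  keep <- if (is.null(species)) seq_len(n0)
          else which(frames[[1]]$species %in% species)
  tt <- vapply(frames, `[[`, 1, "time")
  nt <- length(frames)
  X <- array(NA_real_, c(length(keep), 3, nt))
  X[, , 1] <- frames[[1]]$pos[keep, , drop = FALSE]
  for (t in 2:nt) {
    d <- frames[[t]]$pos[keep, , drop = FALSE] -
         frames[[t - 1]]$pos[keep, , drop = FALSE]
    if (!is.null(box)) {
      for (k in 1:3) if (periodic[k])
        d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    X[, , t] <- X[, , t - 1] + d
  }
  lags <- unique(round(seq(1L, nt - 1L, length.out = min(max_lags, nt - 1L))))
  msd <- vapply(lags, function(L) {
    d <- X[, , (1L + L):nt, drop = FALSE] - X[, , 1L:(nt - L), drop = FALSE]
    mean(apply(d^2, c(1, 3), sum))
  }, 1)
  data.frame(lag = tt[lags + 1L] - tt[1L], msd = msd)
}

# Longitudinal chains of a filament lattice: starting from each nucleating
# cap, follow the plus-end bond and then the alternating intra-dimer /
# longitudinal bonds upward. `up_comp` names the upward component per
# species.
protofilaments <- function(rx, sys, cap_species = "CAP",
                           up_comp = c(CAP = "plus", TA = "t", TB = "u"),
                           down_comp = c(TA = "d", TB = "b")) {
  spname <- vapply(sys$species, `[[`, "", "name")
  caps <- which(spname[rx$species] == cap_species)
  if (!length(caps))
    stop("protofilaments: no nucleating ring present", call. = FALSE)
  chains <- lapply(caps, function(cp) {
    chain <- integer(0)
    m <- cp
    repeat {
      sp <- sys$species[[rx$species[m]]]
      up <- up_comp[[sp$name]]
      if (is.null(up) || is.na(up)) break
      ci <- which(sp$comps$name == up)[1]
      nxt <- rx$bond_to[m, ci]
      if (nxt == 0L) break
      chain <- c(chain, nxt)
      m <- nxt
    }
    chain
  })
  chains
}

#' Number of protofilaments
#'
#' Counts the maximal longitudinal bond chains emanating from the nucleating
#' capping ring (a chain may have length zero when its cap has not yet
#' nucleated).
#'
#' @param rx reactor (or an `srb_result`); @param sys compiled system
#'   (taken from the result if omitted).
#' @param cap_species species name of the ring members.
#' @return integer count.
#' @export
protofilament_count <- function(rx, sys = NULL, cap_species = "CAP") {
  if (inherits(rx, "srb_result")) { sys <- rx$sys; rx <- rx$reactor }
  length(protofilaments(rx, sys, cap_species))
}

#' Protofilament lengths in dimers
#' @inheritParams protofilament_count
#' @param alpha_species species counted per dimer layer.
#' @return integer vector, one entry per chain.
#' @export
protofilament_lengths <- function(rx, sys = NULL, cap_species = "CAP",
                                  alpha_species = "TA") {
  if (inherits(rx, "srb_result")) { sys <- rx$sys; rx <- rx$reactor }
  spname <- vapply(sys$species, `[[`, "", "name")
  ch <- protofilaments(rx, sys, cap_species)
  vapply(ch, function(c) sum(spname[rx$species[c]] == alpha_species), 1L)
}

#' Seam detection and lattice helicity
#'
#' Scans the lateral bonds of the tubulin lattice. The seam is the column
#' where alpha-tubulins bind beta-tubulins laterally. The helical rise is
#' measured positionally: every lateral bond advances one azimuthal step
#' around the tube axis; its axial offset per unit azimuth, averaged over
#' all in-layer lateral bonds and extrapolated to a full turn, gives the
#' rise in subunit layers per turn (3 for the 13_3 lattice). The signed
#' azimuthal step makes the estimate independent of which of the two
#' same-contact site pairings realized the bond. Bonds whose axial offset
#' exceeds `0.6 * monomer_height` (off-layer contacts) are excluded and
#' counted separately.
#'
#' @param rx reactor or `srb_result`; @param sys compiled system.
#' @param alpha_species,beta_species tubulin species names.
#' @param lat_right,lat_left lateral component names.
#' @param monomer_height axial subunit spacing (ideal longitudinal bond
#'   length).
#' @param n_pf protofilament count for the circuit.
#' @param cap_species when given, only lateral bonds inside the complex
#'   containing this nucleating species are measured (the tube itself, not
#'   solution oligomers).
#' @return list with `seam` (logical; `NA` when no lateral bonds exist yet),
#'   `rise_per_turn` (subunit layers; `NA` if indeterminate) and `n_lateral`.
#' @export
seam_and_helicity <- function(rx, sys = NULL, alpha_species = "TA",
                              beta_species = "TB", lat_right = "lr",
                              lat_left = "ll", monomer_height = 1.0,
                              n_pf = 13L, cap_species = "CAP") {
  if (inherits(rx, "srb_result")) { sys <- rx$sys; rx <- rx$reactor }
  spname <- vapply(sys$species, `[[`, "", "name")
  box <- sys$config$box; per <- sys$config$periodic
  dz <- numeric(0); seam_bond <- logical(0)
  tub <- which(spname[rx$species] %in% c(alpha_species, beta_species))
  axis_xy <- c(mean(rx$pos[tub, 1]), mean(rx$pos[tub, 2]))
  if (!is.null(cap_species) && any(spname[rx$species] == cap_species)) {
    comp <- rx_complex_ids(rx)
    caps <- which(spname[rx$species] == cap_species)
    tube_ids <- unique(comp[caps])
    tub <- tub[comp[tub] %in% tube_ids]
    axis_xy <- c(mean(rx$pos[caps, 1]), mean(rx$pos[caps, 2]))
  }
  dpsi <- numeric(0)
  bond_m <- integer(0); bond_p <- integer(0)
  for (m in tub) {
    sp <- sys$species[[rx$species[m]]]
    ci <- which(sp$comps$name == lat_right)
    for (c in ci) {
      p <- rx$bond_to[m, c]
      if (p == 0L) next
      psp <- sys$species[[rx$species[p]]]
      if (psp$comps$name[rx$bond_comp[m, c]] != lat_left) next
      d <- rx$pos[p, 3] - rx$pos[m, 3]
      if (per[3]) d <- d - box[3] * round(d / box[3])
      a1 <- atan2(rx$pos[m, 2] - axis_xy[2], rx$pos[m, 1] - axis_xy[1])
      a2 <- atan2(rx$pos[p, 2] - axis_xy[2], rx$pos[p, 1] - axis_xy[1])
      dp <- a2 - a1
      dp <- atan2(sin(dp), cos(dp))   # wrap to (-pi, pi]
      dz <- c(dz, d)
      dpsi <- c(dpsi, dp)
      bond_m <- c(bond_m, m); bond_p <- c(bond_p, p)
      seam_bond <- c(seam_bond, spname[rx$species[m]] != spname[rx$species[p]])
    }
  }
  if (!length(dz))
    return(list(seam = NA, rise_per_turn = NA_real_, n_lateral = 0L,
                n_offlayer = 0L))
  # single lateral steps advance about one azimuthal spacing within one
  # subunit layer; wider or same-azimuth contacts are lattice defects
  # (e.g. bridges over the seam gap) and are excluded
  step0 <- 2 * pi / n_pf
  inlayer <- abs(dz) <= 0.6 * monomer_height &
    abs(dpsi) >= 0.5 * step0 & abs(dpsi) <= 1.5 * step0
  # rise per turn: follow single lateral steps once around the tube (net
  # azimuth 2*pi, passing through the seam); the walk ends above its start
  # by the accumulated axial offset
  rise <- NA_real_
  if (any(inlayer)) {
    mm <- bond_m[inlayer]; pp <- bond_p[inlayer]
    ddz <- dz[inlayer]; ddp <- dpsi[inlayer]
    # orient every step in the +psi direction
    flip <- ddp < 0
    tmp <- mm[flip]; mm[flip] <- pp[flip]; pp[flip] <- tmp
    ddz[flip] <- -ddz[flip]; ddp[flip] <- -ddp[flip]
    rises <- numeric(0)
    starts <- unique(mm)
    for (s in starts) {
      found <- NA_real_
      walk <- function(node, psum, zsum, depth) {
        if (!is.na(found)) return(invisible(NULL))
        if (psum >= 2 * pi - 0.5 * step0) {
          found <<- zsum
          return(invisible(NULL))
        }
        if (depth >= ceiling(1.5 * n_pf)) return(invisible(NULL))
        for (e in which(mm == node)) {
          walk(pp[e], psum + ddp[e], zsum + ddz[e], depth + 1L)
          if (!is.na(found)) return(invisible(NULL))
        }
      }
      walk(s, 0, 0, 0L)
      if (!is.na(found)) rises <- c(rises, found / monomer_height)
    }
    if (length(rises)) rise <- mean(rises)
  }
  list(seam = any(seam_bond),
       rise_per_turn = rise,
       n_lateral = sum(inlayer),
       n_offlayer = sum(!inlayer))
}

#' Census of minimal cycles in the monomer-bond graph
#'
#' Contracts rigid groups (multi-EM monomers) to single nodes, connects
#' nodes sharing at least one bond, and counts minimal cycles: cycles in
#' which every pair of members is no closer in the full graph than along the
#' cycle. For assembling shells these are the pentagons/hexagons/heptagons of
#' the curved lattice.
#'
#' @param x a reactor, an `srb_result`, or an igraph object (the monomer
#'   graph directly).
#' @param max_size largest cycle size counted.
#' @return named integer vector: count per cycle size.
#' @export
ring_census <- function(x, max_size = 8L) {
  g <- if (inherits(x, "igraph")) {
    x
  } else {
    if (inherits(x, "srb_result")) x <- x$reactor
    monomer_graph(x)
  }
  census_minimal_cycles(g, max_size)
}

# Monomer graph of a reactor: rigid groups become nodes; molecules outside
# any rigid group are their own node.
monomer_graph <- function(rx) {
  grp <- rx$rigid
  node <- ifelse(grp > 0L, grp, max(grp, 0L) + seq_along(grp))
  node <- match(node, unique(node))
  edges <- matrix(integer(0), 0, 2)
  for (m in seq_len(rx$n)) {
    for (c in which(rx$bond_to[m, ] > 0L)) {
      p <- rx$bond_to[m, c]
      if (p > m && node[p] != node[m])
        edges <- rbind(edges, c(node[m], node[p]))
    }
  }
  g <- igraph::make_empty_graph(n = max(node), directed = FALSE)
  if (nrow(edges)) {
    edges <- unique(t(apply(edges, 1, sort)))
    g <- igraph::add_edges(g, t(edges))
  }
  g
}

# Count minimal cycles (geodesic cycles) up to max_size.
census_minimal_cycles <- function(g, max_size = 8L) {
  n <- igraph::vcount(g)
  out <- integer(0)
  if (n == 0L) return(out)
  dmat <- igraph::distances(g)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  found <- character(0)
  sizes <- integer(0)
  # DFS over paths starting at the cycle's smallest vertex
  for (v in seq_len(n)) {
    path <- v
    dfs <- function() {
      cur <- path[length(path)]
      for (w in adj[[cur]]) {
        if (w == v && length(path) >= 3L) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% found)) {
            cyc <- path
            if (is_minimal_cycle(cyc, dmat)) {
              found <<- c(found, key)
              sizes <<- c(sizes, length(cyc))
            } else {
              found <<- c(found, key)
            }
          }
        } else if (w > v && !(w %in% path) && length(path) < max_size) {
          path <<- c(path, w)
          dfs()
          path <<- path[-length(path)]
        }
      }
    }
    dfs()
  }
  if (!length(sizes)) return(setNames(integer(0), character(0)))
  tab <- table(sizes)
  setNames(as.integer(tab), names(tab))
}

is_minimal_cycle <- function(cyc, dmat) {
  k <- length(cyc)
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    dc <- min(b - a, k - (b - a))
    if (dmat[cyc[a], cyc[b]] < dc) return(FALSE)
  }
  TRUE
}

#' Closure flags of assembled complexes
#'
#' A complex is closed when every member elementary molecule has its full
#' neighbor complement, i.e. every component is bound.
#'
#' @param rx reactor or `srb_result`; @param sys compiled system.
#' @return logical vector, one flag per complex (in complex-id order).
#' @export
complex_closure <- function(rx, sys = NULL) {
  if (inherits(rx, "srb_result")) { sys <- rx$sys; rx <- rx$reactor }
  comp <- rx_complex_ids(rx)
  ncomp <- vapply(sys$species, function(s) nrow(s$comps), 1L)
  full <- vapply(seq_len(rx$n), function(m) {
    nc <- ncomp[rx$species[m]]
    nc == 0L || all(rx$bond_to[m, seq_len(nc)] > 0L)
  }, TRUE)
  vapply(seq_len(max(comp)), function(k) all(full[comp == k]), TRUE)
}

#' Reference pattern of the XOR tile automaton
#'
#' Iterates `c[r][i] = c[r-1][i-1] XOR c[r-1][i+1]` upward from a seed row
#' (out-of-range neighbors read as 0). For a single-1 seed this is the
#' Pascal-triangle-mod-2 (Sierpinski) pattern.
#'
#' @param seed_row 0/1 vector.
#' @param n_rows rows to generate above the seed.
#' @return integer matrix of `n_rows + 1` rows (seed first).
#' @export
sierpinski_reference <- function(seed_row, n_rows) {
  w <- length(seed_row)
  out <- matrix(0L, n_rows + 1L, w)
  out[1, ] <- as.integer(seed_row)
  if (n_rows >= 1L) for (r in 2:(n_rows + 1L)) {
    left <- c(0L, out[r - 1L, -w])
    right <- c(out[r - 1L, -1L], 0L)
    out[r, ] <- bitwXor(left, right)
  }
  out
}

#' Extract the assembled tile grid and score it against the XOR automaton
#'
#' Snaps each tile attached to the nucleating row onto the lattice defined by
#' the row spacing (rows of tiles sit at half-column offsets; positions are
#' indexed on a half-spacing grid so the automaton neighbors are `i-1` and
#' `i+1`). The reference pattern is generated from the seed row; mismatches
#' are assembly errors, which are expected events, not failures. Tiles not
#' connected to the nucleating structure are ignored and counted.
#'
#' @param result `srb_result` from a Sierpinski fixture run.
#' @param lattice the fixture's `lattice` element (spacings and seed values).
#' @param tile_species named values of the tile species (1 = output one).
#' @return list with `grid` (data.frame: row, col, value, expected),
#'   `mismatches`, `n_attached`, `n_detached`.
#' @export
sierpinski_score <- function(result, lattice,
                             tile_species = c(T00 = 0, T01 = 1, T10 = 1, T11 = 0)) {
  rx <- result$reactor; sys <- result$sys
  spname <- vapply(sys$species, `[[`, "", "name")
  names_at <- spname[rx$species]
  comp <- rx_complex_ids(rx)
  nuc_comp <- unique(comp[names_at %in% c("N0", "N1")])
  tiles <- which(names_at %in% names(tile_species))
  attached <- tiles[comp[tiles] %in% nuc_comp]
  detached <- setdiff(tiles, attached)
  w <- length(lattice$seed_values)
  # reference over the half-spacing grid: seed values sit at even indices
  wide <- 2L * w - 1L
  seed_wide <- integer(wide)
  seed_wide[seq(1L, wide, by = 2L)] <- as.integer(lattice$seed_values)
  nrows_max <- 12L
  ref <- sierpinski_reference(seed_wide, nrows_max)
  grid <- data.frame(row = integer(0), col = integer(0),
                     value = integer(0), expected = integer(0))
  mism <- 0L
  for (m in attached) {
    r <- as.integer(round((rx$pos[m, 3] - lattice$z0) / lattice$sz))
    i <- as.integer(round((rx$pos[m, 1] - lattice$x0) / (lattice$sx / 2))) + 1L
    if (r < 1L || r > nrows_max || i < 1L || i > wide) next
    val <- as.integer(tile_species[[names_at[m]]])
    exp_val <- ref[r + 1L, i]
    grid <- rbind(grid, data.frame(row = r, col = i, value = val,
                                   expected = exp_val))
    if (val != exp_val) mism <- mism + 1L
  }
  list(grid = grid, mismatches = mism,
       n_attached = length(attached), n_detached = length(detached))
}

#' Axial transport summary of a cargo species
#'
#' Mean and maximum axial position and axial mean-squared displacement of a
#' species over time; compare a walker run against a motor-free control to
#' see transport faster than diffusion.
#'
#' @param frames trajectory frames.
#' @param species species name(s) to track.
#' @param axis axis index (3 = z).
#' @return data.frame with `time`, `mean_pos`, `max_pos`, `axial_msd`.
#' @export
transport_front <- function(frames, species, axis = 3L) {
  sel <- which(frames[[1]]$species %in% species)
  if (!length(sel)) {
    sel0 <- lapply(frames, function(fr) which(fr$species %in% species))
    first <- which(vapply(sel0, length, 1L) > 0L)[1]
    if (is.na(first)) stop("transport_front: species not present")
    frames <- frames[first:length(frames)]
    sel <- which(frames[[1]]$species %in% species)
  }
  x0 <- frames[[1]]$pos[sel, axis]
  do.call(rbind, lapply(frames, function(fr) {
    x <- fr$pos[sel, axis]
    data.frame(time = fr$time, mean_pos = mean(x), max_pos = max(x),
               axial_msd = mean((x - x0)^2))
  }))
}

#' Physical time-step worked example (Stokes-Einstein)
#'
#' The one place the package uses SI units: for a particle of the given
#' diameter in a solvent, the diffusion coefficient follows Stokes-Einstein,
#' `D = k_B T / (3 pi eta d)`; the time step is chosen so the mean expected
#' translation `sqrt(6 D dt)` is a set fraction of the particle diameter,
#' and the total simulated time is `n_steps * dt`.
#'
#' @param diameter particle diameter (m).
#' @param temperature absolute temperature (K).
#' @param viscosity solvent viscosity (Pa s).
#' @param fraction target mean translation per step as a fraction of the
#'   diameter.
#' @param n_steps number of steps.
#' @param dt optionally override the derived time step (s).
#' @return list with `D` (m^2/s), `dt` (s), `total_time` (s).
#' @export
timestep_worked_example <- function(diameter = 5.5e-9, temperature = 298,
                                    viscosity = 1e-3, fraction = 0.1,
                                    n_steps = 3e6, dt = NULL) {
  kB <- 1.380649e-23
  D <- kB * temperature / (3 * pi * viscosity * diameter)
  if (is.null(dt)) dt <- (fraction * diameter)^2 / (6 * D)
  list(D = D, dt = dt, total_time = n_steps * dt)
}

#' Complex-size report of a reactor
#'
#' @param rx reactor or `srb_result`.
#' @return data.frame with one row per complex: `id`, `size`; sizes sum to
#'   the total molecule count.
#' @export
structure_report <- function(rx) {
  if (inherits(rx, "srb_result")) rx <- rx$reactor
  comp <- rx_complex_ids(rx)
  tab <- table(comp)
  data.frame(id = as.integer(names(tab)), size = as.integer(tab))
}
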