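# Orchestration: initial placement, the per-step cycle (forces -> Langevin
# integration -> monomolecular Gillespie -> bimolecular detection/firing ->
# scheduled insertions -> sampling), and scheduled molecule additions.

# Rotation matrix mapping unit vector a onto unit vector b (minimal rotation).
rotation_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(diag(3))
  a <- a / na; b <- b / nb
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - d) / s^2)
}

# Uniformly random rotation matrix (quaternion method).
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Member coordinates for a seed graph built from the component geometry:
# nodes are placed by BFS over the graph's bonds, each new molecule at the
# ideal bond length along the parent's component vector, its own frame chosen
# as the minimal rotation aligning its reacting component back at the parent.
template_coords <- function(graph, sys) {
  nn <- length(graph$nodes)
  coords <- matrix(0, nn, 3)
  frames <- vector("list", nn)
  sids <- vapply(graph$nodes, function(nd) sys$spindex[[nd$species]], 1L)
  slotmaps <- lapply(seq_len(nn), function(v)
    seed_slot_map(graph$nodes[[v]], sys$species[[sids[v]]]))
  adj <- lapply(seq_len(nn), function(i) list())
  if (nrow(graph$edges)) for (r in seq_len(nrow(graph$edges))) {
    e <- graph$edges[r, ]
    adj[[e[1]]][[length(adj[[e[1]]]) + 1L]] <- c(e[3], e[2], e[4])
    adj[[e[3]]][[length(adj[[e[3]]]) + 1L]] <- c(e[1], e[4], e[2])
  }
  placed <- rep(FALSE, nn)
  frames[[1]] <- diag(3)
  placed[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (lnk in adj[[v]]) {
      w <- lnk[1]
      if (placed[w]) next
      cv <- slotmaps[[v]][lnk[2]]
      cw <- slotmaps[[w]][lnk[3]]
      spv <- sys$species[[sids[v]]]; spw <- sys$species[[sids[w]]]
      uv <- spv$cvec[, cv]
      duv <- sqrt(sum(uv^2))
      dir <- if (duv > 1e-12) as.numeric(frames[[v]] %*% (uv / duv))
             else c(0, 0, 1)
      d0 <- ideal_bond_length(spv$comps$d[cv], spw$comps$d[cw])
      coords[w, ] <- coords[v, ] + dir * max(d0, 1e-6)
      uw <- spw$cvec[, cw]
      nw <- sqrt(sum(uw^2))
      frames[[w]] <- if (nw > 1e-12) rotation_between(uw / nw, -dir) else diag(3)
      placed[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  coords
}

# TRUE when candidate member coordinates overlap existing molecules
# (center distance below the fraction `slack` of the radii sum).
overlaps_existing <- function(rx, sys, coords, radii, slack = 0.9) {
  if (rx$n == 0L) return(FALSE)
  box <- sys$config$box; per <- sys$config$periodic
  exr <- vapply(sys$species, `[[`, 1, "radius")[rx$species]
  for (m in seq_len(nrow(coords))) {
    d <- sweep(rx$pos, 2, coords[m, ])
    for (k in 1:3) if (per[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    dist <- sqrt(rowSums(d^2))
    if (any(dist < slack * (exr + radii[m]))) return(TRUE)
  }
  FALSE
}

# Place `count` copies of a seed graph by rejection sampling (uniform random
# position and orientation, no overlap with existing molecules).
place_copies <- function(rx, sys, graph, count, max_tries = 500L) {
  if (count < 1L) return(invisible(integer(0)))
  tpl <- NULL
  gkey <- graph_to_str(graph)
  for (st in sys$config$seed_templates) {
    if (identical(graph_to_str(parse_graph(st$species)), gkey)) {
      tpl <- as.matrix(st$coords)
      break
    }
  }
  if (is.null(tpl)) tpl <- template_coords(graph, sys)
  tpl <- sweep(tpl, 2, colMeans(tpl))
  sids <- vapply(graph$nodes, function(nd) sys$spindex[[nd$species]], 1L)
  radii <- vapply(sys$species, `[[`, 1, "radius")[sids]
  rigid <- all(vapply(sids, function(s) sys$species[[s]]$rigid, TRUE)) &&
    length(sids) > 1L
  box <- sys$config$box
  ids <- integer(0)
  for (copy in seq_len(count)) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      qm <- random_rotation()
      center <- runif(3) * box
      coords <- tpl %*% t(qm)
      coords <- sweep(coords, 2, center, `+`)
      if (!overlaps_existing(rx, sys, coords, radii)) {
        ids <- c(ids, rx_add_graph(rx, sys, graph, coords, rigid = rigid))
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("placement failed after %d tries (packing fraction too high?)",
                   max_tries), call. = FALSE)
  }
  invisible(ids)
}

#' Initial placement of seed species and configured structures
#'
#' Explicitly configured structures (nucleating rings, rows, ...) are placed
#' at their given member coordinates first; seed species are then placed
#' uniformly at random without overlap (rejection sampling against the
#' radii), multi-molecule seeds with a random orientation.
#'
#' @param rx empty reactor; @param sys compiled system.
#' @export
place_initial <- function(rx, sys) {
  for (st in sys$config$structures) {
    g <- parse_graph(st$species)
    rx_add_graph(rx, sys, g, as.matrix(st$coords))
  }
  for (sd in sys$model$seeds)
    place_copies(rx, sys, sd$graph, sd$count)
  invisible(rx)
}

#' Insert molecules during a run
#'
#' Adds `count` copies of a fully specified species graph with non-overlapping
#' random placement. Deletion of molecules is not supported (and not
#' offered); the total elementary-molecule count only changes here.
#'
#' @param rx reactor; @param sys compiled system.
#' @param species species graph (an `srb_graph` or a species string).
#' @param count copies to add.
#' @export
scheduled_insert <- function(rx, sys, species, count) {
  g <- if (is.character(species)) parse_graph(species) else species
  place_copies(rx, sys, g, count)
  invisible(rx)
}

# One observable sample row (time + one count per observable).
obs_row <- function(rx, sys) {
  counts <- vapply(sys$observables, function(ob)
    as.numeric(count_pattern_occurrences(rx, sys, ob$pattern, ob$mode)), 1)
  names(counts) <- vapply(sys$observables, `[[`, "", "name")
  c(time = rx$time, counts)
}

take_frame <- function(rx, sys) {
  list(time = rx$time,
       species = vapply(sys$species, `[[`, "", "name")[rx$species],
       pos = rx$pos[seq_len(rx$n), , drop = FALSE])
}

#' Run a simulation
#'
#' Executes `n_steps` iterations of: force computation and Langevin
#' velocity-Verlet integration, monomolecular Gillespie events, bimolecular
#' candidate detection and firing, scheduled insertions due this step, and
#' observable/trajectory sampling. Fully reproducible given the seed.
#'
#' @param model `srb_model` (or path to a model file).
#' @param geometry `srb_geometry` (or path).
#' @param config `srb_config` (or path to a YAML config).
#' @param seed RNG seed; defaults to `config$seed`; `NULL` leaves the RNG
#'   state alone.
#' @param quiet suppress progress output.
#' @return `srb_result`: list with `observables` (data.frame), `trajectory`
#'   (list of frames or `NULL`), `reactor`, `sys`, `diagnostics`.
#' @export
run_simulation <- function(model, geometry, config, seed = NULL, quiet = TRUE) {
  if (is.character(model)) model <- parse_model(model)
  if (is.character(geometry)) geometry <- parse_geometry(geometry, model)
  if (is.character(config)) config <- read_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  sys <- compile_system(model, geometry, config)
  rx <- new_reactor(sys)
  # insertions at t = 0 are equivalent to seeding
  ins <- sys$model$insertions
  ins_step <- vapply(ins, function(iv) max(0L, as.integer(ceiling(iv$time / config$dt))), 1L)
  place_initial(rx, sys)
  for (k in which(ins_step == 0L))
    scheduled_insert(rx, sys, ins[[k]]$graph, ins[[k]]$count)

  spname <- vapply(sys$species, `[[`, "", "name")
  spmass <- vapply(sys$species, `[[`, 1, "mass")
  spdamp <- vapply(sys$species, `[[`, 1, "damp")
  sprad <- vapply(sys$species, `[[`, 1, "radius")

  obs <- list(obs_row(rx, sys))
  frames <- if (config$traj_period > 0L) list(take_frame(rx, sys)) else NULL
  nst <- config$n_steps
  for (step in seq_len(nst)) {
    if (rx$geom_dirty) rx_rebuild_bonded(rx, sys)
    res <- md_step_cpp(rx$pos, rx$vel, rx$force,
                       spmass[rx$species], spdamp[rx$species],
                       rx$frozen, rx$rigid,
                       rx$bonds, rx$bond_d0, config$K_d,
                       rx$angles, rx$angle_a0, config$K_alpha,
                       sprad[rx$species], config$A_rep,
                       config$box, config$periodic,
                       config$dt, config$temperature, 1L)
    if (!res$ok)
      stop(sprintf("non-finite state at step %d; aborting", step), call. = FALSE)
    rx$pos <- res$pos; rx$vel <- res$vel; rx$force <- res$force
    rx$time <- step * config$dt
    step_reactions(rx, sys, config$dt)
    for (k in which(ins_step == step))
      scheduled_insert(rx, sys, ins[[k]]$graph, ins[[k]]$count)
    if (step %% config$obs_period == 0L)
      obs[[length(obs) + 1L]] <- obs_row(rx, sys)
    if (config$traj_period > 0L && step %% config$traj_period == 0L)
      frames[[length(frames) + 1L]] <- take_frame(rx, sys)
    if (!quiet && step %% 1000L == 0L)
      message(sprintf("step %d / %d (t = %.3f, n = %d)", step, nst, rx$time, rx$n))
  }
  observables <- as.data.frame(do.call(rbind, obs))
  structure(list(observables = observables, trajectory = frames,
                 reactor = rx, sys = sys,
                 diagnostics = as.list(rx$diag),
                 seed = seed),
            class = "srb_result")
}

#' @export
print.srb_result <- function(x, ...) {
  cat(sprintf("srbdyn simulation: %d molecules, t = %.4g, %d observable samples\n",
              x$reactor$n, x$reactor$time, nrow(x$observables)))
  d <- x$diagnostics
  cat(sprintf("  reactions fired: %d (mono %d); candidates %d, rejected dist/ang %d, refractory %d, stale %d\n",
              d$fired, d$mono_events, d$candidates, d$rej_dist_ang,
              d$rej_refractory, d$stale))
  invisible(x)
}
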