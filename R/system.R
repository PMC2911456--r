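# Compile a parsed model + geometry + config into the tables the engine uses:
# species records (with component vectors, ideal-angle tables, friction),
# the enumerated reactant patterns of all rules, compiled rules, observables
# and the reindexing radius d_max.

#' Simulation configuration
#'
#' All quantities are in reduced units (Boltzmann constant and characteristic
#' mass/length/energy equal to one) unless noted.
#'
#' @param box reactor dimensions, 3 lengths.
#' @param boundary per-axis boundary: `"p"` (periodic) or `"r"` (reflecting).
#' @param dt time step.
#' @param n_steps number of steps.
#' @param temperature thermostat temperature (energy, k_B = 1).
#' @param K_d bond spring constant (energy/length^2).
#' @param K_alpha angle spring constant (energy/radian^2).
#' @param A_rep soft-sphere repulsion height (energy).
#' @param sigma bimolecular candidate distance threshold (length); must be at
#'   least the largest ideal bond length plus distance tolerance of any
#'   bimolecular rule.
#' @param t_dist default distance tolerance (length); species may override.
#' @param t_ang default angular tolerance in degrees; species may override.
#' @param refractory_time no-new-binding period after a bond deletion;
#'   default `10 * dt`.
#' @param seed RNG seed recorded into outputs (the actual seeding is done by
#'   [run_simulation()]).
#' @param obs_period observable sampling period in steps.
#' @param traj_period trajectory sampling period in steps (0 = off).
#' @param structures explicitly placed initial structures: list of
#'   `list(species = <species string>, coords = <n x 3 matrix>)`; used for
#'   nucleating structures whose member coordinates matter.
#' @param seed_templates optional member-coordinate templates for
#'   multi-molecule seed species, list of `list(species = <species string>,
#'   coords = <n x 3 matrix>)`; copies are placed at random positions and
#'   orientations but with this internal geometry (rigid-body monomers).
#' @return a config list of class `srb_config`.
#' @export
sim_config <- function(box = c(10, 10, 10), boundary = c("p", "p", "p"),
                       dt = 0.005, n_steps = 1000L, temperature = 1,
                       K_d = 50, K_alpha = 10, A_rep = 5,
                       sigma = 1.5, t_dist = 0.3, t_ang = 35,
                       refractory_time = NULL, seed = NULL,
                       obs_period = 100L, traj_period = 0L,
                       structures = list(), seed_templates = list()) {
  stopifnot(dt > 0, all(box > 0), length(box) == 3, length(boundary) == 3)
  structure(list(
    box = as.numeric(box),
    boundary = boundary,
    periodic = boundary == "p",
    dt = dt, n_steps = as.integer(n_steps), temperature = temperature,
    K_d = K_d, K_alpha = K_alpha, A_rep = A_rep, sigma = sigma,
    t_dist = t_dist, t_ang = t_ang,
    refractory_time = if (is.null(refractory_time)) 10 * dt else refractory_time,
    seed = seed, obs_period = as.integer(obs_period),
    traj_period = as.integer(traj_period), structures = structures,
    seed_templates = seed_templates),
    class = "srb_config")
}

#' Read a simulation config from YAML
#' @param path YAML file.
#' @return `srb_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  unpack <- function(xs) lapply(xs, function(s)
    list(species = s$species, coords = do.call(rbind, s$coords)))
  args <- y[setdiff(names(y), c("structures", "seed_templates"))]
  do.call(sim_config, c(args, list(structures = unpack(y$structures),
                                   seed_templates = unpack(y$seed_templates))))
}

#' Write a simulation config to YAML
#' @param config `srb_config`; @param path output file.
#' @export
write_config <- function(config, path) {
  y <- unclass(config)
  y$periodic <- NULL
  pack <- function(xs) lapply(xs, function(s)
    list(species = s$species,
         coords = lapply(seq_len(nrow(s$coords)), function(i) as.numeric(s$coords[i, ]))))
  y$structures <- pack(config$structures)
  y$seed_templates <- pack(config$seed_templates)
  if (!length(y$structures)) y$structures <- NULL
  if (!length(y$seed_templates)) y$seed_templates <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Default geometry for a model
#'
#' Convenience generator used by tests and quick experiments: every species
#' gets unit mass, radius 0.5, diffusion 1; components get length 0.5 with
#' theta/phi spread evenly over the sphere.
#'
#' @param model `srb_model`.
#' @return `srb_geometry`.
#' @export
auto_geometry <- function(model) {
  lines <- character(0)
  for (ty in model$molecule_types) {
    lines <- c(lines, sprintf("species %s 1.0 0.5 1.0", ty$name))
    nc <- length(ty$comps)
    for (k in seq_len(nc)) {
      th <- 180 * k / (nc + 1)
      ph <- (137.5 * k) %% 360
      lines <- c(lines, sprintf("component %s %s 0.5 %.3f %.3f",
                                ty$name, ty$comps[[k]]$name, th, ph))
    }
  }
  parse_geometry(paste(lines, collapse = "\n"), model)
}

#' Compile model, geometry and config into a simulation system
#'
#' Builds the species tables (component vectors, ideal-angle tables,
#' per-species friction from the declared diffusion coefficient), enumerates
#' all reactant patterns of the rules (each elementary molecule will cache
#' the indices of patterns it anchors), compiles the rules and observables,
#' and computes the reindexing radius `d_max`.
#'
#' @param model `srb_model`; @param geometry `srb_geometry`;
#' @param config `srb_config`.
#' @return an `srb_system` list.
#' @export
compile_system <- function(model, geometry, config = sim_config()) {
  validate_geometry(geometry, model)
  t_ang_default <- config$t_ang * pi / 180
  species <- list()
  spindex <- list()
  for (k in seq_along(model$molecule_types)) {
    ty <- model$molecule_types[[k]]
    ge <- geometry$species[[ty$name]]
    nc <- length(ty$comps)
    comps <- data.frame(
      name = vapply(ge$comps, `[[`, "", "name"),
      d = vapply(ge$comps, `[[`, 1, "d"),
      theta = vapply(ge$comps, `[[`, 1, "theta"),
      phi = vapply(ge$comps, `[[`, 1, "phi"),
      t_ang = vapply(ge$comps, function(c)
        if (is.null(c$t_ang)) NA_real_ else c$t_ang, 1),
      stringsAsFactors = FALSE)
    if (nc == 0L)
      comps <- data.frame(name = character(0), d = numeric(0),
                          theta = numeric(0), phi = numeric(0),
                          t_ang = numeric(0))
    cvec <- if (nc) vapply(seq_len(nc), function(c)
      component_vector(comps$d[c], comps$theta[c], comps$phi[c]), numeric(3))
      else matrix(numeric(0), 3, 0)
    sp <- list(
      id = k, name = ty$name, mass = ge$mass, radius = ge$radius, D = ge$D,
      damp = if (config$temperature > 0) ge$mass * ge$D / config$temperature
             else ge$mass * ge$D,
      comps = comps,
      comp_states = lapply(ty$comps, `[[`, "states"),
      cvec = cvec,
      t_dist = if (is.na(ge$t_dist)) config$t_dist else ge$t_dist,
      t_ang = if (is.na(ge$t_ang)) t_ang_default else ge$t_ang,
      fixed = ty$name %in% geometry$fixed,
      rigid = ty$name %in% geometry$rigid)
    sp$alpha <- ideal_angle_table(sp)
    species[[k]] <- sp
    spindex[[ty$name]] <- k
  }
  # enumerate rule patterns (shared patterns get one index)
  patterns <- list()
  pkeys <- character(0)
  get_pid <- function(graph) {
    key <- graph_to_str(graph)
    hit <- match(key, pkeys)
    if (!is.na(hit)) return(hit)
    cp <- compile_pattern(graph, species, spindex)
    cp$id <- length(patterns) + 1L
    patterns[[cp$id]] <<- cp
    pkeys <<- c(pkeys, key)
    cp$id
  }
  rules <- list()
  for (r in model$rules) {
    pids <- vapply(r$lhs, get_pid, 1L)
    rec <- list(
      type = r$type, arity = length(r$lhs), rate = r$rate, pids = pids,
      acted = r$acted, new_state = r$new_state, text = r$text)
    if (rec$arity == 2L) {
      # acted-component candidates per side (for the geometric pre-gate)
      rec$acands <- lapply(1:2, function(side)
        patterns[[pids[side]]]$cands[[1]][[r$acted[side]]])
      # distance window of the acted pair: used to pre-gate candidate pairs
      reach <- vapply(1:2, function(side) {
        p <- patterns[[pids[side]]]
        sp <- species[[p$species[1]]]
        range(sp$comps$d[p$cands[[1]][[r$acted[side]]]])
      }, numeric(2))
      tmax <- max(vapply(1:2, function(side)
        species[[patterns[[pids[side]]]$species[1]]]$t_dist, 1))
      rec$dwin <- c(max(0, sum(reach[1, ]) - tmax), sum(reach[2, ]) + tmax)
    }
    rules[[length(rules) + 1L]] <- rec
  }
  obs <- lapply(model$observables, function(ob)
    list(name = ob$name, mode = ob$mode,
         pattern = compile_pattern(ob$graph, species, spindex)))
  d_max <- if (length(patterns))
    max(vapply(patterns, pattern_diameter, 1L)) else 0L
  max_comps <- max(1L, vapply(species, function(s) nrow(s$comps), 1L))
  # per-rule constraint tables for the batched C++ bimolecular step
  # (usable when both reactant patterns are single-node)
  side_info <- function(p, acted_slot) {
    cons <- p$cons[[1]]; cands <- p$cands[[1]]
    sp <- species[[p$species[1]]]
    ncons <- length(cons)
    cands_f <- vector("list", ncons); sreq <- vector("list", ncons)
    bond_req <- integer(ncons)
    for (s in seq_len(ncons)) {
      cp <- cons[[s]]
      keep <- integer(0); req <- integer(0)
      for (cc in cands[[s]]) {
        if (is.na(cp$state)) { keep <- c(keep, cc); req <- c(req, 0L) }
        else {
          idx <- match(cp$state, sp$comp_states[[cc]])
          if (!is.na(idx)) { keep <- c(keep, cc); req <- c(req, idx) }
        }
      }
      cands_f[[s]] <- as.integer(keep); sreq[[s]] <- as.integer(req)
      bond_req[s] <- switch(cp$bond, none = 0L, any = 1L, wild = 2L, 3L)
    }
    list(ncons = ncons, acted = as.integer(acted_slot), cands = cands_f,
         state_req = sreq, bond_req = bond_req)
  }
  cinfo <- vector("list", length(rules))
  rule_simple <- logical(length(rules))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (r$arity == 2L && patterns[[r$pids[1]]]$n == 1L &&
        patterns[[r$pids[2]]]$n == 1L) {
      rule_simple[k] <- TRUE
      cinfo[[k]] <- list(side1 = side_info(patterns[[r$pids[1]]], r$acted[1]),
                         side2 = side_info(patterns[[r$pids[2]]], r$acted[2]))
    } else {
      cinfo[[k]] <- list()
    }
  }
  # flat per-species tables consumed by the C++ kernels
  nsp <- length(species)
  comp_d <- matrix(0, nsp, max_comps)
  t_ang_comp <- matrix(0, nsp, max_comps)
  ncomp <- integer(nsp)
  for (k in seq_len(nsp)) {
    ncomp[k] <- nrow(species[[k]]$comps)
    if (ncomp[k]) {
      comp_d[k, seq_len(ncomp[k])] <- species[[k]]$comps$d
      ta <- species[[k]]$comps$t_ang
      ta[is.na(ta)] <- species[[k]]$t_ang
      t_ang_comp[k, seq_len(ncomp[k])] <- ta
    }
  }
  flat <- list(
    comp_d = comp_d, ncomp = ncomp, t_ang_comp = t_ang_comp,
    t_dist = vapply(species, `[[`, 1, "t_dist"),
    t_ang = vapply(species, `[[`, 1, "t_ang"),
    alpha = lapply(species, function(s)
      if (nrow(s$comps)) s$alpha else matrix(NA_real_, 1, 1)))
  sys <- structure(list(
    model = model, geometry = geometry, config = config,
    species = species, spindex = spindex,
    patterns = patterns, rules = rules, observables = obs,
    mono_rules = which(vapply(rules, function(r) r$arity == 1L, TRUE)),
    bi_rules = which(vapply(rules, function(r) r$arity == 2L, TRUE)),
    cinfo = cinfo, rule_simple = rule_simple,
    is_binding = vapply(rules, function(r) r$type == "binding", TRUE),
    d_max = d_max, max_comps = max_comps, flat = flat),
    class = "srb_system")
  validate_system(sys)
  sys
}

# Startup checks: sigma must cover every bimolecular rule's reach, geometry
# agrees with the model, tolerances sane.
validate_system <- function(sys) {
  cfg <- sys$config
  for (r in sys$rules) {
    if (r$arity != 2L) next
    reach <- 0
    for (side in 1:2) {
      p <- sys$patterns[[r$pids[side]]]
      sp <- sys$species[[p$species[1]]]
      cand <- p$cands[[1]][[r$acted[side]]]
      reach <- reach + max(sp$comps$d[cand])
    }
    tmax <- max(vapply(1:2, function(side)
      sys$species[[sys$patterns[[r$pids[side]]]$species[1]]]$t_dist, 1))
    if (cfg$sigma < reach + tmax)
      stop(sprintf(
        "sigma = %.3g is smaller than ideal bond length + t_dist = %.3g for rule '%s'; compatible pairs would be invisible to the detector",
        cfg$sigma, reach + tmax, r$text), call. = FALSE)
  }
  invisible(sys)
}

#' Candidate pairs within a radius
#'
#' Cell-list neighbor search returning exactly the unordered pairs with
#' separation at most `radius` under the active boundary conditions.
#'
#' @param positions n x 3 matrix.
#' @param radius query radius.
#' @param box 3 lengths; @param periodic logical 3-vector.
#' @return list with integer vectors `i`, `j` and numeric `dist`.
#' @export
neighbor_pairs <- function(positions, radius, box, periodic = c(TRUE, TRUE, TRUE)) {
  pairs_within_cpp(positions, as.numeric(box), as.logical(periodic), radius)
}
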