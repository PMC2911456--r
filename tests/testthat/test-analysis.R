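# Trajectory and structure analyzers, plus the physical time-step example.

# Compiled microtubule system with an empty reactor for hand-built lattices.
mt_env <- function() {
  fx <- fixture_microtubule(n_dimers = 0L)
  model <- parse_model(fx$model)
  geo <- parse_geometry(fx$geometry, model)
  cfg <- fx$config
  cfg$structures <- list()
  sys <- compile_system(model, geo, cfg)
  list(sys = sys, rx = new_reactor(sys))
}

# Add one cap at a position; returns its index.
add_cap <- function(rx, sys, xyz) {
  rx_add_graph(rx, sys, parse_graph("CAP(next,prev,plus)"),
               matrix(xyz, 1, 3), frozen = TRUE)
}

add_dimer <- function(rx, sys, xyz) {
  rx_add_graph(rx, sys, parse_graph("TA(d,t!1,ll,lr).TB(b!1,u,ll,lr,mot)"),
               rbind(xyz, xyz + c(0, 0, 1)))
}

comp_idx <- function(sys, species, comp) {
  sp <- sys$species[[sys$spindex[[species]]]]
  which(sp$comps$name == comp)[1]
}

# Hand-built lattice: n_pf columns, `layers` dimer layers, rise per lateral
# step in subunit heights (0 for an unstaggered test lattice, 3/n_pf for the
# helical one). Returns the reactor.
build_lattice <- function(env, n_pf, layers, rise) {
  sys <- env$sys; rx <- env$rx
  R <- 2; z0 <- 2
  caps <- integer(n_pf)
  tops <- vector("list", n_pf)
  for (k in seq_len(n_pf)) {
    psi <- 2 * pi * (k - 1) / n_pf
    zk <- z0 + rise * (k - 1)
    caps[k] <- add_cap(rx, sys, c(5 + R * cos(psi), 5 + R * sin(psi), zk))
    col <- integer(0)
    for (l in seq_len(layers)) {
      ids <- add_dimer(rx, sys, c(5 + R * cos(psi), 5 + R * sin(psi),
                                  zk + 1 + (l - 1) * 2))
      col <- c(col, ids)
    }
    tops[[k]] <- col
    # longitudinal bonds
    if (layers >= 1) {
      rx_bind(rx, caps[k], comp_idx(sys, "CAP", "plus"),
              col[1], comp_idx(sys, "TA", "d"))
      if (layers >= 2) for (l in 2:layers)
        rx_bind(rx, col[2 * (l - 1)], comp_idx(sys, "TB", "u"),
                col[2 * l - 1], comp_idx(sys, "TA", "d"))
    }
  }
  # lateral bonds between same-layer alphas and betas of adjacent columns;
  # the wrap column pair carries the alpha-beta (seam) contacts iff the
  # accumulated rise is a half-integer number of dimers
  for (k in seq_len(n_pf)) {
    k2 <- if (k == n_pf) 1L else k + 1L
    for (l in seq_len(layers)) {
      a1 <- tops[[k]][2 * l - 1]; b1 <- tops[[k]][2 * l]
      if (k < n_pf) {
        a2 <- tops[[k2]][2 * l - 1]; b2 <- tops[[k2]][2 * l]
        rx_bind(rx, a1, comp_idx(sys, "TA", "lr"), a2, comp_idx(sys, "TA", "ll"))
        rx_bind(rx, b1, comp_idx(sys, "TB", "lr"), b2, comp_idx(sys, "TB", "ll"))
      } else if (rise > 0) {
        # seam: alpha meets the beta 1.5 dimers up (if present)
        if (l < layers) {
          b2 <- tops[[k2]][2 * l + 2]
          rx_bind(rx, a1, comp_idx(sys, "TA", "lr"), b2, comp_idx(sys, "TB", "ll"))
        }
      } else {
        a2 <- tops[[k2]][2 * l - 1]; b2 <- tops[[k2]][2 * l]
        rx_bind(rx, a1, comp_idx(sys, "TA", "lr"), a2, comp_idx(sys, "TA", "ll"))
        rx_bind(rx, b1, comp_idx(sys, "TB", "lr"), b2, comp_idx(sys, "TB", "ll"))
      }
    }
  }
  rx
}

test_that("protofilament counting follows the capping ring", {
  env <- mt_env()
  expect_error(protofilament_count(env$rx, env$sys), "ring")
  # bare ring: chains of length zero still count
  for (k in 1:13) add_cap(env$rx, env$sys, c(k, 0, 0))
  expect_equal(protofilament_count(env$rx, env$sys), 13L)
  expect_equal(protofilament_lengths(env$rx, env$sys), rep(0L, 13))
  # hand-built 3-protofilament toy lattice
  env3 <- mt_env()
  build_lattice(env3, 3L, 2L, 0)
  expect_equal(protofilament_count(env3$rx, env3$sys), 3L)
  expect_equal(protofilament_lengths(env3$rx, env3$sys), rep(2L, 3))
})

test_that("seam and helicity: 13_0 lattice has no seam, 13_3 has one with rise 3", {
  env0 <- mt_env()
  build_lattice(env0, 13L, 2L, 0)
  sh0 <- seam_and_helicity(env0$rx, env0$sys)
  expect_false(sh0$seam)
  expect_equal(sh0$rise_per_turn, 0, tolerance = 1e-9)
  env3 <- mt_env()
  build_lattice(env3, 13L, 4L, 3 / 13)
  sh3 <- seam_and_helicity(env3$rx, env3$sys)
  expect_true(sh3$seam)
  expect_equal(sh3$rise_per_turn, 3, tolerance = 0.35)
  # empty lattice: indeterminate, not a crash
  enve <- mt_env()
  for (k in 1:13) add_cap(enve$rx, enve$sys, c(k, 0, 0))
  she <- seam_and_helicity(enve$rx, enve$sys)
  expect_true(is.na(she$seam))
  expect_true(is.na(she$rise_per_turn))
})

test_that("ring census counts minimal cycles (pentamer ring, soccer ball)", {
  ring5 <- igraph::make_ring(5)
  expect_equal(ring_census(ring5), c("5" = 5L) * 0L + c("5" = 1L))
  # truncated icosahedron ("soccer ball"): 12 pentagons and 20 hexagons.
  # Build it geometrically: one vertex per directed icosahedron edge, placed
  # a third of the way along; each vertex then has exactly 3 nearest
  # neighbors at equal minimal distance.
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  d <- as.matrix(dist(ico))
  edge_len <- min(d[d > 0])
  pts <- NULL
  for (v in 1:12) for (u in 1:12) {
    if (v != u && abs(d[v, u] - edge_len) < 1e-9)
      pts <- rbind(pts, ico[v, ] + (ico[u, ] - ico[v, ]) / 3)
  }
  expect_equal(nrow(pts), 60L)
  pd <- as.matrix(dist(pts))
  cut <- min(pd[pd > 0]) + 1e-6   # all soccer-ball edges share one length here
  adj <- which(pd > 0 & pd < cut, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], ]
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  expect_true(all(igraph::degree(g) == 3))
  census <- ring_census(g, max_size = 7L)
  expect_equal(census[["5"]], 12L)
  expect_equal(census[["6"]], 20L)
})

test_that("closure flags require every component bound", {
  sys <- make_system("
begin molecule types
  A(x,y)
end molecule types
")
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys, parse_graph("A(x!1,y!2).A(x!2,y!1)"), matrix(0, 2, 3))
  rx_add_graph(rx, sys, parse_graph("A(x!1,y).A(x,y!1)"), matrix(5, 2, 3))
  cl <- complex_closure(rx, sys)
  expect_equal(cl, c(TRUE, FALSE))
})

test_that("the XOR reference generator reproduces Pascal's triangle mod 2", {
  expect_equal(sierpinski_reference(c(0, 0, 0, 0), 3),
               matrix(0L, 4, 4))
  w <- 21
  seed <- integer(w); center <- 11L; seed[center] <- 1L
  n_rows <- 9L
  ref <- sierpinski_reference(seed, n_rows)
  for (r in 0:n_rows) for (i in seq_len(w)) {
    off <- i - center
    want <- if ((r + off) %% 2 == 0 && abs(off) <= r)
      pascal_mod2(r, (off + r) / 2) else 0L
    expect_equal(ref[r + 1L, i], want,
                 info = sprintf("row %d col %d", r, i))
  }
})

test_that("tile grids are extracted, scored, and detached tiles are counted", {
  fx <- fixture_sierpinski(seed_values = c(0, 0, 1, 0, 0), n_rows = 3L,
                           counts = c(T00 = 0L, T01 = 0L, T10 = 0L, T11 = 0L))
  model <- parse_model(fx$model)
  geo <- parse_geometry(fx$geometry, model)
  cfg <- fx$config
  cfg$n_steps <- 0L
  set.seed(3)
  res <- run_simulation(model, geo, cfg, seed = 3)
  rx <- res$reactor; sys <- res$sys
  lat <- fx$lattice
  # hand-place the correct first row: tiles above (2,3) and (3,4): 0^1=1 twice
  nuc <- which(vapply(sys$species, `[[`, "", "name")[rx$species] %in% c("N0", "N1"))
  place_tile <- function(species, cell_left, row) {
    x <- lat$x0 + (cell_left - 1) * lat$sx + lat$sx / 2
    z <- lat$z0 + row * lat$sz
    ids <- rx_add_graph(rx, sys, parse_graph(full_species_string(sys, species)),
                        matrix(c(x, 2.5, z), 1, 3))
    ids
  }
  dl <- function(sp) comp_idx(sys, sp, grep("^dl", sys$species[[sys$spindex[[sp]]]]$comps$name, value = TRUE))
  t1 <- place_tile("T01", 2L, 1L)   # inputs (0, 1) -> output 1
  t2 <- place_tile("T10", 3L, 1L)   # inputs (1, 0) -> output 1
  # bond each tile's down-left site to the lower-left cell's up site
  spT01 <- sys$species[[sys$spindex[["T01"]]]]
  rx_bind(rx, t1, which(spT01$comps$name == "dl0")[1], nuc[2],
          which(sys$species[[rx$species[nuc[2]]]]$comps$name == "u0")[1])
  spT10 <- sys$species[[sys$spindex[["T10"]]]]
  rx_bind(rx, t2, which(spT10$comps$name == "dl1")[1], nuc[3],
          which(sys$species[[rx$species[nuc[3]]]]$comps$name == "u1")[1])
  # one detached tile far away
  rx_add_graph(rx, sys, parse_graph(full_species_string(sys, "T00")),
               matrix(c(1, 1, 4), 1, 3))
  sc <- sierpinski_score(list(reactor = rx, sys = sys), lat)
  expect_equal(sc$n_attached, 2L)
  expect_equal(sc$n_detached, 1L)
  expect_equal(sc$mismatches, 0L)
  expect_equal(sort(sc$grid$value), sort(sc$grid$expected))
  # a wrong tile at a correct position is a mismatch, not an error:
  # the row-2 site between the two 1-tiles expects 1 XOR 1 = 0
  t3 <- place_tile("T10", 2.5, 2L)
  rx_bind(rx, t3, which(sys$species[[sys$spindex[["T10"]]]]$comps$name == "dl1")[1],
          t1, which(sys$species[[sys$spindex[["T01"]]]]$comps$name == "u1")[1])
  sc2 <- sierpinski_score(list(reactor = rx, sys = sys), lat)
  expect_equal(sc2$n_attached, 3L)
  expect_equal(sc2$mismatches, 1L)
})

test_that("MSD analysis: frozen structures sit still, rigid members share a curve", {
  fx <- fixture_spheres(n_monomers = 6L)
  res <- run_fixture(fx, seed = 4, n_steps = 600, traj_period = 30L,
                     obs_period = 300L)
  frames <- res$trajectory
  # members of one rigid body diffuse together: per monomer, the outer-
  # triangle centroid and the inner-triangle centroid trace one curve
  rx <- res$reactor
  spn <- vapply(res$sys$species, `[[`, "", "name")[rx$species]
  cent_frames <- lapply(frames, function(fr) {
    pos <- NULL; lab <- character(0)
    for (g in seq_len(max(rx$rigid))) {
      mo <- which(rx$rigid == g & spn == "O")
      mi <- which(rx$rigid == g & spn == "I")
      # unwrap members around the first member before averaging
      unwrap <- function(idx) {
        ref <- fr$pos[idx[1], ]
        d <- sweep(fr$pos[idx, , drop = FALSE], 2, ref)
        d <- d - rep(fx$config$box, each = length(idx)) * round(
          d / rep(fx$config$box, each = length(idx)))
        ref + colMeans(d)
      }
      pos <- rbind(pos, unwrap(mo), unwrap(mi))
      lab <- c(lab, "cO", "cI")
    }
    list(time = fr$time, species = lab, pos = pos)
  })
  msd_o <- msd_curve(cent_frames, species = "cO", box = fx$config$box,
                     periodic = rep(TRUE, 3))
  msd_i <- msd_curve(cent_frames, species = "cI", box = fx$config$box,
                     periodic = rep(TRUE, 3))
  k <- nrow(msd_o)
  # small ensemble: allow generous statistical slack
  expect_equal(msd_o$msd[k], msd_i$msd[k], tolerance = 0.35)
  expect_gt(msd_o$msd[k], msd_o$msd[2])
  # frozen nucleating row of the sierpinski fixture stays put
  fx2 <- fixture_sierpinski()
  res2 <- run_fixture(fx2, seed = 5, n_steps = 200, traj_period = 20L)
  msd_n <- msd_curve(res2$trajectory, species = c("N0", "N1"),
                     box = fx2$config$box, periodic = rep(FALSE, 3))
  expect_lt(max(msd_n$msd), 1e-12)
})

test_that("transport summary tracks axial positions", {
  frames <- lapply(0:5, function(t)
    list(time = t, species = c("CRG", "CRG", "KIN"),
         pos = rbind(c(1, 1, 1 + t), c(1, 2, 3 + t), c(0, 0, 0))))
  tf <- transport_front(frames, "CRG")
  expect_equal(nrow(tf), 6L)
  expect_equal(tf$mean_pos, 2 + 0:5)
  expect_equal(tf$max_pos, 3 + 0:5)
  # stationary cargo: zero displacement
  still <- lapply(0:3, function(t)
    list(time = t, species = "CRG", pos = matrix(c(2, 2, 2), 1, 3)))
  tfs <- transport_front(still, "CRG")
  expect_true(all(tfs$axial_msd == 0))
})

test_that("the physical time-step example follows Stokes-Einstein", {
  ex <- timestep_worked_example()
  # hemoglobin-sized particle in water: D around 8e-11 m^2/s
  expect_equal(ex$D, 1.380649e-23 * 298 / (3 * pi * 1e-3 * 5.5e-9),
               tolerance = 1e-12)
  expect_gt(ex$D, 5e-11); expect_lt(ex$D, 1.2e-10)
  # the derived step is of the stated half-nanosecond order
  expect_gt(ex$dt, 0.2e-9); expect_lt(ex$dt, 1.5e-9)
  # and 3e6 steps of 0.5 ns simulate 1.5 ms
  ex2 <- timestep_worked_example(n_steps = 3e6, dt = 0.5e-9)
  expect_equal(ex2$total_time, 1.5e-3)
  # doubling the translation fraction quadruples the step
  exf <- timestep_worked_example(fraction = 0.2)
  expect_equal(exf$dt / ex$dt, 4, tolerance = 1e-9)
})

test_that("structure reports partition the reactor", {
  sys <- make_system("
begin molecule types
  A(x,y)
end molecule types
")
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys, parse_graph("A(x!1,y).A(x,y!1)"), matrix(0, 2, 3))
  rx_add_graph(rx, sys, parse_graph("A(x,y)"), matrix(4, 1, 3))
  rep <- structure_report(rx)
  expect_equal(sum(rep$size), rx$n)
  expect_setequal(rep$size, c(2L, 1L))
})
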