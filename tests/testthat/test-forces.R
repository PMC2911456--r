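# Force terms, neighbor search, Langevin integration and rigid bodies.

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- rep(0, length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 1)
}

test_that("bond term matches the harmonic form and its numerical gradient", {
  expect_equal(bond_energy_force(2.8, 2.8, 10)$energy, 0)
  expect_equal(bond_energy_force(2.8, 2.8, 10)$force, 0)
  r <- bond_energy_force(3.0, 2.8, 10)
  expect_equal(r$energy, 10 * 0.2^2, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:20) {
    d <- runif(1, 0.5, 4); d0 <- runif(1, 0.5, 4); K <- runif(1, 1, 50)
    g <- fd_grad(function(x) bond_energy_force(x, d0, K)$energy, d)
    expect_equal(bond_energy_force(d, d0, K)$force, -g, tolerance = 1e-5)
  }
})

test_that("angle term forces equal the negative numerical gradient", {
  set.seed(5)
  for (k in 1:20) {
    xi <- rnorm(3); xj <- rnorm(3); xk <- rnorm(3)
    a0 <- runif(1, 0.3, pi - 0.3); K <- runif(1, 1, 30)
    r <- angle_energy_forces(xi, xj, xk, a0, K)
    # forces sum to zero
    expect_equal(r$f_i + r$f_j + r$f_k, c(0, 0, 0), tolerance = 1e-10)
    # net torque about the vertex vanishes
    tq <- function(rr, ff) c(rr[2] * ff[3] - rr[3] * ff[2],
                             rr[3] * ff[1] - rr[1] * ff[3],
                             rr[1] * ff[2] - rr[2] * ff[1])
    expect_equal(tq(xi - xj, r$f_i) + tq(xk - xj, r$f_k), c(0, 0, 0),
                 tolerance = 1e-9)
    e_of <- function(x) angle_energy_forces(x[1:3], x[4:6], x[7:9], a0, K)$energy
    g <- fd_grad(e_of, c(xi, xj, xk))
    expect_equal(c(r$f_i, r$f_j, r$f_k), -g, tolerance = 1e-5)
  }
  # rest angle gives zero energy and forces
  r0 <- angle_energy_forces(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), pi / 2, 12)
  expect_equal(r0$energy, 0, tolerance = 1e-12)
  expect_equal(r0$f_i, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a center with n neighbors implies n(n-1)/2 angle terms", {
  sys <- make_system("
begin molecule types
  H(c,c,c,c)
  T(h)
end molecule types
")
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys, parse_graph("H(c,c,c,c)"), matrix(0, 1, 3))
  for (k in 1:4) {
    rx_add_graph(rx, sys, parse_graph("T(h)"),
                 matrix(c(2 * cos(k), 2 * sin(k), 0.1 * k), 1, 3))
    rx_bind(rx, 1, k, 1 + k, 1)
  }
  srbdyn:::rx_rebuild_bonded(rx, sys)
  expect_equal(nrow(rx$angles), 6L)
  expect_equal(nrow(rx$bonds), 4L)
})

test_that("soft repulsion has the documented cutoff shape", {
  expect_equal(soft_repulsion(1.0, 1.0, 5)$energy, 0)
  expect_equal(soft_repulsion(0, 1.0, 5)$energy, 10)
  expect_equal(soft_repulsion(0.5, 1.0, 5)$energy, 5)
  expect_equal(soft_repulsion(1.7, 1.0, 5)$force, 0)
  set.seed(8)
  for (k in 1:10) {
    r <- runif(1, 0.05, 0.95)
    g <- fd_grad(function(x) soft_repulsion(x, 1.0, 5)$energy, r)
    expect_equal(soft_repulsion(r, 1.0, 5)$force, -g, tolerance = 1e-5)
  }
})

test_that("compiled forces equal the analytic terms on a random configuration", {
  set.seed(12)
  n <- 6
  pos <- matrix(runif(3 * n, 10, 20), n, 3)
  bonds <- rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L))
  bond_d0 <- c(1.2, 0.8, 2.0)
  angles <- rbind(c(1L, 2L, 3L))
  angle_a0 <- 1.9
  radius <- rep(1.2, n)
  box <- c(100, 100, 100); per <- rep(TRUE, 3)
  got <- srbdyn:::compute_forces_cpp(pos, bonds, bond_d0, 7, angles, angle_a0,
                                     11, radius, 3, box, per, integer(n))
  f_want <- matrix(0, n, 3)
  e_want <- 0
  for (b in 1:3) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    dv <- pos[j, ] - pos[i, ]
    d <- sqrt(sum(dv^2))
    bf <- bond_energy_force(d, bond_d0[b], 7)
    e_want <- e_want + bf$energy
    f_want[j, ] <- f_want[j, ] + bf$force * dv / d
    f_want[i, ] <- f_want[i, ] - bf$force * dv / d
  }
  af <- angle_energy_forces(pos[1, ], pos[2, ], pos[3, ], angle_a0, 11)
  e_want <- e_want + af$energy
  f_want[1, ] <- f_want[1, ] + af$f_i
  f_want[2, ] <- f_want[2, ] + af$f_j
  f_want[3, ] <- f_want[3, ] + af$f_k
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- pos[j, ] - pos[i, ]
    d <- sqrt(sum(dv^2))
    sr <- soft_repulsion(d, 2.4, 3)
    e_want <- e_want + sr$energy
    f_want[j, ] <- f_want[j, ] + sr$force * dv / d
    f_want[i, ] <- f_want[i, ] - sr$force * dv / d
  }
  expect_equal(got$energy, e_want, tolerance = 1e-10)
  expect_equal(got$force, f_want, tolerance = 1e-10)
})

test_that("neighbor search equals the all-pairs oracle, including wraparound", {
  # wraparound pair across a periodic face
  pos <- rbind(c(0.3, 5, 5), c(9.8, 5, 5))
  pr <- neighbor_pairs(pos, 1.0, c(10, 10, 10))
  expect_equal(length(pr$i), 1L)
  expect_equal(pr$dist, 0.5, tolerance = 1e-12)
  # same points without periodicity: no pair
  pr2 <- neighbor_pairs(pos, 1.0, c(10, 10, 10), periodic = rep(FALSE, 3))
  expect_equal(length(pr2$i), 0L)
  # two particles just inside the radius
  pos3 <- rbind(c(1, 1, 1), c(1.9, 1, 1))
  expect_equal(length(neighbor_pairs(pos3, 1.0, c(30, 30, 30))$i), 1L)
  # random cloud vs brute force
  set.seed(21)
  n <- 400
  box <- c(12, 9, 15)
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  for (cutoff in c(1.0, 2.5)) {
    pr <- neighbor_pairs(pos, cutoff, box)
    got <- sort(paste(pmin(pr$i, pr$j), pmax(pr$i, pr$j)))
    want <- character(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- pos[j, ] - pos[i, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) want <- c(want, paste(i, j))
    }
    expect_identical(got, sort(want))
  }
})

test_that("without friction and noise the integrator conserves energy", {
  # bonded triangle with angle terms, deterministic Verlet for 1e4 steps
  pos <- rbind(c(10, 10, 10), c(11.3, 10, 10), c(10.6, 11.1, 10))
  vel <- matrix(0.05, 3, 3)
  bonds <- rbind(c(1L, 2L), c(2L, 3L))
  st <- list(pos = pos, vel = vel)
  box <- c(50, 50, 50)
  e_tot <- function(st, e_pot) {
    e_pot + sum(0.5 * rowSums(st$vel^2))
  }
  st <- langevin_step(st, mass = 1, damp = Inf, dt = 0.002, temperature = 0,
                      box = box, bonds = bonds, bond_d0 = c(1.0, 1.2),
                      K_d = 20, angles = rbind(c(1L, 2L, 3L)),
                      angle_a0 = 1.5, K_alpha = 8, n_steps = 1L)
  e0 <- e_tot(st, st$energy)
  st <- langevin_step(st, mass = 1, damp = Inf, dt = 0.002, temperature = 0,
                      box = box, bonds = bonds, bond_d0 = c(1.0, 1.2),
                      K_d = 20, angles = rbind(c(1L, 2L, 3L)),
                      angle_a0 = 1.5, K_alpha = 8, n_steps = 10000L)
  e1 <- e_tot(st, st$energy)
  expect_lt(abs(e1 - e0) / abs(e0), 0.01)
})

test_that("zero forces and zero temperature damp motion to rest", {
  st <- list(pos = matrix(25, 4, 3), vel = matrix(2, 4, 3))
  st$pos <- st$pos + matrix(rnorm(12), 4, 3) * 3
  st <- langevin_step(st, mass = 1, damp = 0.5, dt = 0.01, temperature = 0,
                      box = c(100, 100, 100), n_steps = 2000L)
  expect_lt(max(abs(st$vel)), 1e-6)
})

test_that("rigid groups move as rigid bodies", {
  # isolated rigid hexamer at T = 0 stays put
  set.seed(31)
  tpl <- matrix(rnorm(18), 6, 3) + 25
  st <- list(pos = tpl, vel = matrix(0, 6, 3))
  st1 <- langevin_step(st, mass = 1, damp = 1, dt = 0.005, temperature = 0,
                       box = c(50, 50, 50), rigid = rep(1L, 6), n_steps = 200L)
  expect_equal(st1$pos, tpl, tolerance = 1e-12)
  # with thermal noise, intra-group distances stay fixed over 1e4 steps
  st2 <- langevin_step(st, mass = 1, damp = 1, dt = 0.005, temperature = 1,
                       box = c(50, 50, 50), rigid = rep(1L, 6),
                       n_steps = 10000L)
  d0 <- as.matrix(dist(tpl))
  d1 <- as.matrix(dist(st2$pos))
  expect_lt(max(abs(d1 - d0)), 1e-8)
  # two bonded rigid bodies relax toward the ideal bond length at T = 0
  tplA <- matrix(c(20, 20, 20, 21, 20, 20), 2, 3, byrow = TRUE)
  tplB <- tplA + rep(c(4, 0, 0), each = 2)
  st3 <- list(pos = rbind(tplA, tplB), vel = matrix(0, 4, 3))
  bonds <- rbind(c(2L, 3L))
  for (it in 1:40) {
    st3 <- langevin_step(st3, mass = 1, damp = 1, dt = 0.005, temperature = 0,
                         box = c(50, 50, 50), bonds = bonds, bond_d0 = 1.5,
                         K_d = 20, rigid = c(1L, 1L, 2L, 2L), n_steps = 100L)
  }
  gap <- sqrt(sum((st3$pos[3, ] - st3$pos[2, ])^2))
  expect_equal(gap, 1.5, tolerance = 0.05)
  # internal geometry of both bodies unchanged
  expect_equal(sqrt(sum((st3$pos[2, ] - st3$pos[1, ])^2)), 1, tolerance = 1e-8)
})

test_that("free diffusion reproduces the declared diffusion coefficient", {
  # quick Einstein-relation check (the tighter 5% version runs in the
  # acceptance suite): D = k_B T damp / m
  set.seed(41)
  n <- 300
  st <- list(pos = matrix(runif(3 * n, 0, 200), n, 3),
             vel = matrix(rnorm(3 * n), n, 3))
  x0 <- st$pos
  dt <- 0.01
  st <- langevin_step(st, mass = 1, damp = 1, dt = dt, temperature = 1,
                      box = c(200, 200, 200), n_steps = 1500L)
  d <- st$pos - x0
  d <- d - 200 * round(d / 200)           # minimum-image displacement
  msd <- mean(rowSums(d^2))
  expect_equal(msd / (6 * 1500 * dt), 1.0, tolerance = 0.12)
})
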