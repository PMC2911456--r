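# Reaction detection/execution, the fragmented Gillespie algorithm, the
# refractory mechanism and rate conversion.

test_that("firing probability is the exponential law", {
  expect_equal(fire_probability(0, 0.1), 0)
  expect_equal(fire_probability(log(2) / 0.1, 0.1), 0.5)
  expect_equal(fire_probability(1e9, 0.1), 1)
  expect_error(fire_probability(-1, 0.1))
})

test_that("macroscopic rate conversion is inverse in the reactive volume", {
  expect_equal(convert_macroscopic_rate(3, 2), 1.5)
  expect_equal(convert_macroscopic_rate(3, 4), 0.75)
  expect_equal(convert_macroscopic_rate(0, 2), 0)
  expect_error(convert_macroscopic_rate(1, 0), "zero tolerance|positive")
})

bind_sys <- function(refractory = 0.05) {
  make_system("
begin molecule types
  A(b,p~U~P)
  S(a)
end molecule types
begin reaction rules
  A(b) + S(a) -> A(b!1).S(a!1) 10
  A(b!1).S(a!1) -> A(b) + S(a) 1
  A(p~U) + A(p~U) -> A(p~P) + A(p~U) 5
end reaction rules
", "
species A 1.0 0.4 1.0
component A b 0.5 90 0
component A p 0.5 90 180
tolerance A 0.3 180
species S 1.0 0.4 1.0
component S a 0.5 90 0
tolerance S 0.3 180
", sim_config(box = c(40, 40, 40), sigma = 1.4, refractory_time = refractory))
}

test_that("a free pair at ideal distance yields exactly one binding candidate", {
  sys <- bind_sys()
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys, parse_graph("A(b,p~P)"), matrix(c(20, 20, 20), 1, 3))
  rx_add_graph(rx, sys, parse_graph("S(a)"), matrix(c(21, 20, 20), 1, 3))
  cand <- bimolecular_candidates(rx, sys)
  expect_equal(nrow(cand), 1L)
  expect_equal(sys$rules[[cand$rule[1]]]$type, "binding")
  # refractory molecules produce no binding candidates
  rx$refract[1] <- rx$time + 1
  expect_equal(nrow(bimolecular_candidates(rx, sys)), 0L)
})

test_that("intra-complex subgraph pairs become bimolecular candidates", {
  # two A bound to one scaffold-like S cannot bind each other, but their
  # phosphorylation rule applies within the complex
  sys <- make_system("
begin molecule types
  A(b,p~U~P)
  S(a,a)
end molecule types
begin reaction rules
  A(p~U) + A(p~U) -> A(p~P) + A(p~U) 5
end reaction rules
", "
species A 1.0 0.4 1.0
component A b 0.5 90 0
component A p 0.5 90 180
tolerance A 0.5 180
species S 1.0 0.6 1.0
component S a 0.8 45 0
component S a 0.8 45 180
tolerance S 0.5 180
", sim_config(box = c(40, 40, 40), sigma = 1.6))
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys,
               parse_graph("A(b!1,p~U).S(a!1,a!2).A(b!2,p~U)"),
               rbind(c(19.9, 20, 20), c(21.2, 20, 20), c(20.6, 21, 20)))
  cand <- bimolecular_candidates(rx, sys)
  expect_gte(nrow(cand), 1L)
  expect_true(all(cand$i != cand$j))
})

test_that("executing rules keeps caches, bonds and refractory state coherent", {
  sys <- bind_sys(refractory = 0.5)
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys, parse_graph("A(b,p~U)"), matrix(c(20, 20, 20), 1, 3))
  rx_add_graph(rx, sys, parse_graph("S(a)"), matrix(c(21, 20, 20), 1, 3))
  cand <- bimolecular_candidates(rx, sys)
  execute_rule(rx, sys, list(rule = cand$rule[1], mols = c(cand$i[1], cand$j[1]),
                             comps = c(cand$ci[1], cand$cj[1])))
  expect_equal(rx$bond_to[1, 1], 2L)
  rx_audit(rx, sys, check_patterns = TRUE)
  # now break it: both partners become refractory and cannot rebind
  brk <- which(vapply(sys$rules, function(r) r$type == "breaking", TRUE))
  execute_rule(rx, sys, list(rule = brk, mols = 1L, comps = 1L))
  expect_equal(rx$bond_to[1, 1], 0L)
  expect_gt(rx$refract[1], rx$time)
  expect_gt(rx$refract[2], rx$time)
  expect_equal(nrow(bimolecular_candidates(rx, sys)), 0L)
  rx_audit(rx, sys, check_patterns = TRUE)
  # once the clock passes, the candidate reappears
  rx$time <- rx$time + 1
  expect_equal(nrow(bimolecular_candidates(rx, sys)), 1L)
})

test_that("random event sequences preserve bond symmetry and cache truth", {
  set.seed(33)
  sys <- bind_sys()
  rx <- new_reactor(sys)
  for (k in 1:6) {
    rx_add_graph(rx, sys, parse_graph("A(b,p~U)"),
                 matrix(c(18 + k, 20, 20), 1, 3))
    rx_add_graph(rx, sys, parse_graph("S(a)"),
                 matrix(c(18 + k, 21, 20), 1, 3))
  }
  for (ev in 1:100) {
    cand <- bimolecular_candidates(rx, sys)
    bonded <- which(rx$bond_to[, 1] > 0L & rx$species == 1L)
    if (nrow(cand) && (runif(1) < 0.6 || !length(bonded))) {
      k <- sample(nrow(cand), 1)
      execute_rule(rx, sys, list(rule = cand$rule[k],
                                 mols = c(cand$i[k], cand$j[k]),
                                 comps = c(cand$ci[k], cand$cj[k])))
    } else if (length(bonded)) {
      brk <- which(vapply(sys$rules, function(r) r$type == "breaking", TRUE))
      execute_rule(rx, sys, list(rule = brk,
                                 mols = bonded[sample(length(bonded), 1)],
                                 comps = 1L))
    }
    rx$time <- rx$time + 0.01
  }
  expect_true(rx_audit(rx, sys, check_patterns = TRUE))
  # total molecule count conserved through all events
  expect_equal(rx$n, 12L)
})

test_that("zero total propensity yields no monomolecular events", {
  sys <- bind_sys()
  rx <- new_reactor(sys)
  rx_add_graph(rx, sys, parse_graph("A(b,p~U)"), matrix(c(20, 20, 20), 1, 3))
  fired0 <- rx$diag$mono_events
  gillespie_monomolecular(rx, sys, 1)   # no bonds: breaking cannot apply
  expect_equal(rx$diag$mono_events, fired0)
})

test_that("monomolecular decay follows the analytic exponential", {
  # A(p~P) -> A(p~U) at rate k: survival of the P population is exp(-k t)
  sys <- make_system("
begin molecule types
  A(p~U~P)
end molecule types
begin reaction rules
  A(p~P) -> A(p~U) 2.0
end reaction rules
")
  set.seed(9)
  n0 <- 600
  rx <- new_reactor(sys)
  for (k in seq_len(n0))
    rx_add_graph(rx, sys, parse_graph("A(p~P)"), matrix(runif(3, 0, 9), 1, 3))
  dt <- 0.05
  left <- numeric(0)
  for (step in 1:20) {
    gillespie_monomolecular(rx, sys, dt)
    rx$time <- step * dt
    left <- c(left, sum(rx$state[, 1] == 2L))
  }
  expected <- n0 * exp(-2.0 * (1:20) * dt)
  # binomial sampling noise: compare on the log scale with generous slack
  expect_lt(max(abs(left - expected) / sqrt(expected + 1)), 4.5)
})

test_that("refractory time suppresses immediate rebinding monotonically", {
  rebind_fraction <- function(refractory, seed) {
    sys <- bind_sys(refractory)
    set.seed(seed)
    rx <- new_reactor(sys)
    rx_add_graph(rx, sys, parse_graph("A(b,p~P)"), matrix(c(20, 20, 20), 1, 3))
    rx_add_graph(rx, sys, parse_graph("S(a)"), matrix(c(21, 20, 20), 1, 3))
    rx_bind(rx, 1, 1, 2, 1)
    reindex_after_reaction(rx, sys, c(1L, 2L))
    srbdyn:::rx_rebuild_bonded(rx, sys)
    # break the bond, then watch 10 steps for rebinding
    rebinds <- 0L; trials <- 40L
    for (t in seq_len(trials)) {
      brk <- which(vapply(sys$rules, function(r) r$type == "breaking", TRUE))
      execute_rule(rx, sys, list(rule = brk, mols = 1L, comps = 1L))
      for (s in 1:10) {
        rx$time <- rx$time + 0.005
        srbdyn:::step_reactions(rx, sys, 0.005)
        if (rx$bond_to[1, 1] > 0L) break
      }
      if (rx$bond_to[1, 1] > 0L) {
        rebinds <- rebinds + 1L
      } else {
        rx_bind(rx, 1, 1, 2, 1)   # re-arm
        reindex_after_reaction(rx, sys, c(1L, 2L))
      }
      rx$refract[] <- -Inf
    }
    rebinds / trials
  }
  f_none <- rebind_fraction(0, 5)
  f_long <- rebind_fraction(0.2, 5)   # longer than the 10-step window
  expect_gt(f_none, f_long)
  expect_equal(f_long, 0)
})
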