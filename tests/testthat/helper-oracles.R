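# Independent oracles and random-case generators shared across tests.
# The brute-force matcher below enumerates every injective node map and
# component assignment directly from the arrays; it shares no code with the
# package's backtracking matcher.

# -- tiny model/system builders ----------------------------------------------

make_system <- function(model_text, geometry_text = NULL, config = NULL) {
  model <- parse_model(model_text)
  geometry <- if (is.null(geometry_text)) auto_geometry(model)
              else parse_geometry(geometry_text, model)
  if (is.null(config)) config <- sim_config()
  compile_system(model, geometry, config)
}

# Reactor with molecules placed on a loose grid (no dynamics involved).
make_reactor <- function(sys, species_counts) {
  rx <- new_reactor(sys)
  k <- 0L
  for (nm in names(species_counts)) {
    for (i in seq_len(species_counts[[nm]])) {
      g <- parse_graph(full_species_string(sys, nm))
      k <- k + 1L
      rx_add_graph(rx, sys, g, matrix(c(3 * k, 0, 0), 1, 3))
    }
  }
  rx
}

# Fully specified single-molecule species string (first state everywhere).
full_species_string <- function(sys, name) {
  sp <- sys$species[[sys$spindex[[name]]]]
  cs <- vapply(seq_len(nrow(sp$comps)), function(c) {
    st <- sp$comp_states[[c]]
    if (length(st)) paste0(sp$comps$name[c], "~", st[1]) else sp$comps$name[c]
  }, "")
  paste0(name, "(", paste(cs, collapse = ","), ")")
}

# -- brute-force subgraph matcher (oracle) ------------------------------------

# All embeddings of `pattern` (srb_pattern) anchored at `anchor`, by
# exhaustive enumeration over molecule tuples and component assignments.
# Returns the count of distinct unordered embeddings (canonicalized the same
# way as the package: by the realized molecule/component assignment).
oracle_match_count <- function(rx, sys, pattern, anchor) {
  p <- pattern
  n <- p$n
  mols_all <- seq_len(rx$n)
  found <- character(0)
  # enumerate injective molecule tuples with node1 = anchor
  tuples <- list(anchor)
  if (n > 1) {
    for (v in 2:n) {
      new <- list()
      for (tp in tuples) {
        for (m in setdiff(mols_all, tp)) new[[length(new) + 1L]] <- c(tp, m)
      }
      tuples <- new
    }
  }
  oracle_match_run(rx, sys, p, tuples, function(key) {
    if (!(key %in% found)) found <<- c(found, key)
  })
  length(found)
}

# Distinct embedding keys over all anchors (global dedupe).
oracle_global_keys <- function(rx, sys, pattern) {
  p <- pattern
  found <- character(0)
  for (anchor in which(rx$species == p$species[1])) {
    n <- p$n
    tuples <- list(anchor)
    if (n > 1) {
      for (v in 2:n) {
        new <- list()
        for (tp in tuples)
          for (m in setdiff(seq_len(rx$n), tp)) new[[length(new) + 1L]] <- c(tp, m)
        tuples <- new
      }
    }
    oracle_match_run(rx, sys, p, tuples, function(key) {
      if (!(key %in% found)) found <<- c(found, key)
    })
  }
  found
}

oracle_match_run <- function(rx, sys, p, tuples, on_found) {
  n <- p$n
  for (tp in tuples) {
    if (any(rx$species[tp] != p$species)) next
    # enumerate injective component assignments per node
    asg_per_node <- lapply(seq_len(n), function(v) {
      slots <- p$cands[[v]]
      if (!length(slots)) return(list(integer(0)))
      out <- list()
      enum <- function(s, acc) {
        if (s > length(slots)) { out[[length(out) + 1L]] <<- acc; return(invisible(NULL)) }
        for (cc in slots[[s]]) if (!(cc %in% acc)) enum(s + 1L, c(acc, cc))
      }
      enum(1L, integer(0))
      out
    })
    # cross product over nodes of assignments, checked lazily
    rec <- function(v, acc) {
      if (v > n) {
        if (oracle_check(rx, sys, p, tp, acc))
          on_found(oracle_key(rx, p, tp, acc))
        return(invisible(NULL))
      }
      for (a in asg_per_node[[v]]) rec(v + 1L, c(acc, list(a)))
    }
    rec(1L, list())
  }
  invisible(NULL)
}

oracle_check <- function(rx, sys, p, mols, asg) {
  for (v in seq_len(p$n)) {
    m <- mols[v]
    for (s in seq_along(p$cons[[v]])) {
      cp <- p$cons[[v]][[s]]
      cc <- asg[[v]][s]
      states <- sys$species[[rx$species[m]]]$comp_states[[cc]]
      cur <- if (length(states)) states[rx$state[m, cc]] else ""
      if (!is.na(cp$state) && cur != cp$state) return(FALSE)
      bt <- rx$bond_to[m, cc]
      if (cp$bond == "none" && bt != 0L) return(FALSE)
      if (cp$bond == "any" && bt == 0L) return(FALSE)
      if (cp$bond == "edge") {
        pw <- p$partner[[v]][[s]]
        if (bt != mols[pw[1]]) return(FALSE)
        if (rx$bond_comp[m, cc] != asg[[pw[1]]][pw[2]]) return(FALSE)
      }
    }
  }
  TRUE
}

oracle_key <- function(rx, p, mols, asg) {
  ntok <- vapply(seq_len(p$n), function(v) {
    sig <- vapply(seq_along(p$cons[[v]]), function(s) {
      cp <- p$cons[[v]][[s]]
      paste0(asg[[v]][s], ":", cp$name, "~", cp$state, "!", cp$bond)
    }, "")
    paste0(mols[v], "[", paste(sort(sig), collapse = ","), "]")
  }, "")
  etok <- if (nrow(p$edges)) {
    vapply(seq_len(nrow(p$edges)), function(r) {
      e <- p$edges[r, ]
      a <- paste0(mols[e[1]], ".", asg[[e[1]]][e[2]])
      b <- paste0(mols[e[3]], ".", asg[[e[3]]][e[4]])
      paste(min(a, b), max(a, b))
    }, "")
  } else character(0)
  paste(paste(sort(ntok), collapse = ";"), paste(sort(etok), collapse = ";"))
}

# -- random reactors / patterns ----------------------------------------------

# A model with 3 species carrying states and duplicate component names.
random_test_system <- function() {
  make_system("
begin molecule types
  X(a,a,p~U~P)
  Y(b,c~On~Off)
  Z(d,e)
end molecule types
begin seed species
  X(a,a,p~U) 1
end seed species
begin reaction rules
  X(p~U) -> X(p~P) 1.0
end reaction rules
begin observables
end observables
")
}

# Random reactor over the test system: random molecules, bonds and states.
random_reactor <- function(sys, n = 8L, p_bond = 0.5) {
  rx <- new_reactor(sys)
  nm <- c("X", "Y", "Z")
  for (i in seq_len(n)) {
    g <- parse_graph(full_species_string(sys, sample(nm, 1)))
    rx_add_graph(rx, sys, g, matrix(runif(3, 0, 50), 1, 3))
  }
  # random states
  for (m in seq_len(rx$n)) {
    sp <- sys$species[[rx$species[m]]]
    for (c in seq_len(nrow(sp$comps))) {
      st <- sp$comp_states[[c]]
      if (length(st)) rx$state[m, c] <- sample(length(st), 1)
    }
  }
  # random bonds between free components
  tries <- rpois(1, n * p_bond) + 1L
  for (t in seq_len(tries)) {
    free <- which(rx$bond_to == 0L, arr.ind = TRUE)
    free <- free[free[, 2] <= vapply(free[, 1], function(m)
      nrow(sys$species[[rx$species[m]]]$comps), 1L), , drop = FALSE]
    if (nrow(free) < 2) break
    pick <- sample(nrow(free), 2)
    a <- free[pick[1], ]; b <- free[pick[2], ]
    if (a[1] == b[1]) next
    rx_bind(rx, a[1], a[2], b[1], b[2])
  }
  for (m in seq_len(rx$n)) rx$P[m, ] <- assign_pattern_indices(rx, sys, m)
  rx
}

# Random small pattern over the test system's species, built from a species
# string so it goes through the standard compiler.
random_pattern <- function(sys) {
  specs <- list(
    "X(a)", "X(a!+,p~P)", "X(p~U)", "Y(b)", "Y(c~On)", "Z(d,e)",
    "X(a!1).Y(b!1)", "X(a!1,a!2).Y(b!1).Y(b!2)", "Z(d!1).X(a!1)",
    "Y(b!1).Y(b!1)", "X(a!1).X(a!1)", "Z(e!1).Y(b!1,c~Off)")
  g <- parse_graph(specs[[sample(length(specs), 1)]])
  compile_pattern(g, sys$species, sys$spindex)
}

# Lucas' theorem: C(n, k) is odd iff k AND (n - k) has no carries.
pascal_mod2 <- function(n, k) {
  if (k < 0 || k > n) return(0L)
  if (bitwAnd(k, n - k) == 0L) 1L else 0L
}

# Direct (unfragmented) SSA for a one-reaction decay system: n0 molecules,
# rate k each; returns all event times.
direct_ssa_decay <- function(n0, k, t_end = Inf) {
  t <- 0; n <- n0; out <- numeric(0)
  while (n > 0) {
    t <- t + rexp(1, k * n)
    if (t > t_end) break
    out <- c(out, t)
    n <- n - 1
  }
  out
}

# Well-mixed SSA for reversible dimerization A + B <-> AB with microscopic
# association propensity kon_eff * nA * nB and dissociation koff per dimer;
# returns the time-averaged dimer count over [t_burn, t_end].
ssa_dimer_mean <- function(nA0, kon_eff, koff, t_end, t_burn = 0) {
  nA <- nA0; nAB <- 0L; t <- 0
  acc <- 0; tprev <- t_burn
  while (t < t_end) {
    a1 <- kon_eff * nA * nA
    a2 <- koff * nAB
    atot <- a1 + a2
    if (atot <= 0) break
    tau <- rexp(1, atot)
    tnew <- t + tau
    if (t >= t_burn) acc <- acc + nAB * (min(tnew, t_end) - max(t, t_burn))
    else if (tnew > t_burn) acc <- acc + nAB * (min(tnew, t_end) - t_burn)
    t <- tnew
    if (t > t_end) break
    if (runif(1) < a1 / atot) { nA <- nA - 1L; nAB <- nAB + 1L }
    else { nA <- nA + 1L; nAB <- nAB - 1L }
  }
  acc / (t_end - t_burn)
}
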