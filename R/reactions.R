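# Reaction detection and execution. Per time step: monomolecular events are
# drawn by a fragmented Gillespie algorithm on the occurrence counts of the
# monomolecular reactant patterns; bimolecular candidates are neighbor pairs
# within the threshold sigma whose cached pattern indices admit a rule, gated
# by geometric compatibility and (for binding) the refractory test, and fired
# with the exponential per-pair probability 1 - exp(-k dt). Movement within
# the step is not considered for reaction evaluation.

#' Probability that a microscopic pairwise reaction fires within one step
#'
#' While two partners sit in each other's reactive volumes they react like a
#' two-molecule well-mixed system with per-pair rate `k_2mic`; over a step of
#' length `dt` the firing probability is exponentially distributed.
#'
#' @param k_2mic microscopic per-pair rate (1/time), `>= 0`.
#' @param dt time step, `> 0`.
#' @return `1 - exp(-k_2mic * dt)`.
#' @export
fire_probability <- function(k_2mic, dt) {
  stopifnot(all(k_2mic >= 0), dt > 0)
  1 - exp(-k_2mic * dt)
}

#' Convert a macroscopic bimolecular rate to the microscopic per-pair rate
#'
#' The contract: in a dilute, well-mixed reactor of volume V, pairs spend a
#' fraction `reactive_volume / V` of their time within tolerance, so firing
#' with per-pair rate `k_macro / reactive_volume` reproduces mass-action
#' kinetics with macroscopic rate `k_macro` (particle-per-volume units).
#' Estimate `reactive_volume` with [reactive_volume()].
#'
#' @param k_macro macroscopic rate (volume/time).
#' @param reactive_volume volume of the compatibility region (length^3).
#' @return microscopic rate `k_2mic` (1/time).
#' @export
convert_macroscopic_rate <- function(k_macro, reactive_volume) {
  stopifnot(k_macro >= 0)
  if (reactive_volume <= 0)
    stop("convert_macroscopic_rate: reactive volume must be positive (no reaction possible with zero tolerance volume)",
         call. = FALSE)
  k_macro / reactive_volume
}

# ---- bimolecular ------------------------------------------------------------

#' Bimolecular rule candidates among neighbor pairs
#'
#' For every unordered pair within `sigma`, lists each rule whose two
#' reactant patterns are anchored at the two molecules (both role
#' assignments; including two disjoint subgraphs of one complex), that passes
#' the refractory test for binding rules and [check_geometric_compatibility()]
#' on the acted components. Embedding pairs must be molecule-disjoint.
#'
#' @param rx reactor; @param sys compiled system.
#' @param pairs optional precomputed neighbor list (as from
#'   [neighbor_pairs()]); found with radius `sigma` if missing.
#' @return data.frame with columns `i`, `j`, `rule`, `ci`, `cj` (molecule
#'   component indices of the acted components).
#' @export
bimolecular_candidates <- function(rx, sys, pairs = NULL) {
  pre <- candidate_prefilter(rx, sys, pairs)
  keep <- logical(nrow(pre))
  ci <- integer(nrow(pre)); cj <- integer(nrow(pre))
  for (k in seq_len(nrow(pre))) {
    res <- resolve_candidate(rx, sys, pre$rule[k], pre$i[k], pre$j[k])
    if (!is.null(res)) { keep[k] <- TRUE; ci[k] <- res[1]; cj[k] <- res[2] }
  }
  out <- pre[keep, , drop = FALSE]
  out$ci <- ci[keep]; out$cj <- cj[keep]
  rownames(out) <- NULL
  out
}

# Cheap vectorized pre-filter: pairs within sigma whose distance lies in the
# rule's reach window and whose cached pattern indices anchor the rule's two
# patterns (both role assignments). Embeddings and geometry are resolved
# lazily at firing time.
candidate_prefilter <- function(rx, sys, pairs = NULL) {
  cfg <- sys$config
  empty <- data.frame(i = integer(0), j = integer(0), rule = integer(0))
  if (rx$n < 2L) return(empty)
  if (is.null(pairs))
    pairs <- neighbor_pairs(rx$pos, cfg$sigma, cfg$box, cfg$periodic)
  if (!length(pairs$i)) return(empty)
  out_i <- integer(0); out_j <- integer(0); out_r <- integer(0)
  for (ridx in sys$bi_rules) {
    r <- sys$rules[[ridx]]
    if (r$rate <= 0) next
    p1 <- r$pids[1]; p2 <- r$pids[2]
    indist <- pairs$dist >= r$dwin[1] & pairs$dist <= r$dwin[2]
    orient <- list(cbind(pairs$i, pairs$j), cbind(pairs$j, pairs$i))
    # a symmetric binding rule forms the same bond under either role
    # assignment: evaluate the pair once (unordered embeddings count once)
    if (p1 == p2 && r$type == "binding") orient <- orient[1]
    for (o in orient) {
      hit <- which(indist &
                   rx$P[cbind(o[, 1], rep(p1, nrow(o)))] > 0L &
                   rx$P[cbind(o[, 2], rep(p2, nrow(o)))] > 0L)
      if (length(hit)) {
        out_i <- c(out_i, o[hit, 1]); out_j <- c(out_j, o[hit, 2])
        out_r <- c(out_r, rep(ridx, length(hit)))
      }
    }
  }
  data.frame(i = out_i, j = out_j, rule = out_r)
}

# Acted-component options of a single-node pattern anchored at molecule m:
# lightweight enumeration of injective constraint assignments (no embedding
# bookkeeping). Returns the distinct molecule-component indices the acted
# slot can take.
single_node_acted <- function(rx, sys, p, m, slot) {
  cons <- p$cons[[1]]
  cands <- p$cands[[1]]
  nc <- length(cons)
  slot_ok <- function(s, cc) {
    cp <- cons[[s]]
    if (!is.na(cp$state) && mol_state_str(rx, sys, m, cc) != cp$state)
      return(FALSE)
    bt <- rx$bond_to[m, cc]
    if (cp$bond == "none" && bt != 0L) return(FALSE)
    if (cp$bond == "any" && bt == 0L) return(FALSE)
    TRUE
  }
  if (nc == 1L) {
    cc <- cands[[1]]
    return(cc[vapply(cc, function(c) slot_ok(1L, c), TRUE)])
  }
  # enumerate acted options: fix the acted slot first, then check that the
  # remaining constraints still have an injective assignment
  acted_opts <- integer(0)
  for (cc in cands[[slot]]) {
    if (!slot_ok(slot, cc)) next
    others <- setdiff(seq_len(nc), slot)
    ok <- length(others) == 0L || complete_rest(rx, sys, cons, cands, m,
                                                others, cc, slot_ok)
    if (ok) acted_opts <- c(acted_opts, cc)
  }
  unique(acted_opts)
}

complete_rest <- function(rx, sys, cons, cands, m, others, used1, slot_ok) {
  rec <- function(idx, used) {
    if (idx > length(others)) return(TRUE)
    s <- others[idx]
    for (cc in cands[[s]]) {
      if (cc %in% used || !slot_ok(s, cc)) next
      if (rec(idx + 1L, c(used, cc))) return(TRUE)
    }
    FALSE
  }
  rec(1L, used1)
}

# Pick a random geometrically compatible, molecule-disjoint embedding combo
# for rule `ridx` with pattern 1 anchored at `a` and pattern 2 at `b`.
# Returns c(ci, cj) or NULL; updates the rejection diagnostics.
resolve_candidate <- function(rx, sys, ridx, a, b, cache = NULL,
                              consumed = NULL) {
  r <- sys$rules[[ridx]]
  if (r$type == "binding" &&
      (rx$refract[a] > rx$time || rx$refract[b] > rx$time)) {
    rx$diag$rej_refractory <- rx$diag$rej_refractory + 1L
    return(NULL)
  }
  # cheap geometric pre-gate over the acted components' name candidates
  # (a superset of any embedding's assignment): if no combination is
  # compatible, skip the embedding search entirely
  pre_ok <- FALSE
  for (ci in r$acands[[1]]) {
    for (cj in r$acands[[2]])
      if (check_geometric_compatibility(rx, sys, a, b, ci, cj)) {
        pre_ok <- TRUE
        break
      }
    if (pre_ok) break
  }
  if (!pre_ok) {
    rx$diag$rej_dist_ang <- rx$diag$rej_dist_ang + 1L
    return(NULL)
  }
  p1 <- sys$patterns[[r$pids[1]]]
  p2 <- sys$patterns[[r$pids[2]]]
  side_opts <- function(p, m, slot) {
    if (p$n == 1L) {
      # single-node options depend only on molecule m's own state; within a
      # step they stay valid until m reacts (and is then consumed), so they
      # may be cached per (molecule, pattern, slot)
      key <- if (is.null(cache)) NULL else paste0(m, ".", p$id, ".", slot)
      if (!is.null(key) && !is.null(cc <- get0(key, envir = cache, inherits = FALSE))) {
        if (!length(cc)) return(NULL)
        return(lapply(cc, function(c) list(mols = m, acted = c)))
      }
      cc <- single_node_acted(rx, sys, p, m, slot)
      if (!is.null(key)) cache[[key]] <- cc
      if (!length(cc)) return(NULL)
      lapply(cc, function(c) list(mols = m, acted = c))
    } else {
      # multi-node embeddings may be cached too; an entry is reused only
      # while none of its member molecules has reacted this step
      key <- if (is.null(cache) || is.null(consumed)) NULL
             else paste0(m, ".", p$id)
      if (!is.null(key) && !is.null(hit <- get0(key, envir = cache, inherits = FALSE))) {
        if (!length(hit)) return(NULL)
        if (all(!vapply(hit, function(x) any(consumed[x$mols]), TRUE))) {
          out <- lapply(hit, function(x) list(mols = x$mols,
                                              acted = x$c1[slot]))
          return(out)
        }
      }
      e <- match_pattern(rx, sys, p, m)
      if (!is.null(key))
        cache[[key]] <- lapply(e, function(x) list(mols = x$mols,
                                                   c1 = x$comps[[1]]))
      if (!length(e)) return(NULL)
      lapply(e, function(x) list(mols = x$mols, acted = x$comps[[1]][slot]))
    }
  }
  e1 <- side_opts(p1, a, r$acted[1])
  if (is.null(e1)) return(NULL)
  e2 <- side_opts(p2, b, r$acted[2])
  if (is.null(e2)) return(NULL)
  combos <- list()
  for (x in e1) for (y in e2) {
    if (length(intersect(x$mols, y$mols))) next
    combos[[length(combos) + 1L]] <- c(x$acted, y$acted)
  }
  if (!length(combos)) return(NULL)
  combos <- unique(combos)
  ok <- logical(length(combos))
  for (k in seq_along(combos)) {
    cc <- combos[[k]]
    ok[k] <- check_geometric_compatibility(rx, sys, a, b, cc[1], cc[2])
  }
  if (!any(ok)) {
    rx$diag$rej_dist_ang <- rx$diag$rej_dist_ang + 1L
    return(NULL)
  }
  good <- which(ok)
  combos[[good[sample.int(length(good), 1L)]]]
}

# ---- execution --------------------------------------------------------------

#' Execute one rule instance (a reaction transaction)
#'
#' Applies the graph transformation — one bond formed, one bond deleted (both
#' endpoint molecules become refractory), or one state change — then
#' recomputes cached pattern indices within `d_max` of the touched molecules.
#' The transaction is atomic: no observable intermediate state.
#'
#' @param rx reactor; @param sys compiled system.
#' @param instance list with `rule` (index into `sys$rules`), `mols`
#'   (molecule index per reactant pattern) and `comps` (acted molecule
#'   component index per reactant pattern).
#' @return invisibly, the molecule indices whose caches were updated.
#' @export
execute_rule <- function(rx, sys, instance) {
  r <- sys$rules[[instance$rule]]
  if (r$type == "binding") {
    i <- instance$mols[1]; j <- instance$mols[2]
    rx_bind(rx, i, instance$comps[1], j, instance$comps[2])
    modified <- c(i, j)
  } else if (r$type == "breaking") {
    i <- instance$mols[1]
    part <- rx_unbind(rx, i, instance$comps[1])
    rx$refract[c(i, part[1])] <- rx$time + sys$config$refractory_time
    modified <- c(i, part[1])
  } else {
    i <- instance$mols[1]
    rx_set_state(rx, sys, i, instance$comps[1], r$new_state)
    modified <- i
  }
  rx$diag$fired <- rx$diag$fired + 1L
  invisible(reindex_after_reaction(rx, sys, modified))
}

# ---- monomolecular (fragmented Gillespie) -----------------------------------

# Occurrence counts of the monomolecular rules' reactant patterns, from the
# cached anchored pattern indices: summed anchored embedding counts divided
# by the pattern's anchor multiplicity (symmetric patterns are seen from
# several anchors but each unordered embedding counts once).
mono_counts <- function(rx, sys) {
  mono <- sys$mono_rules
  if (!length(mono) || rx$n == 0L)
    return(list(rules = mono, counts = numeric(length(mono))))
  cs <- colSums(rx$P)
  counts <- vapply(mono, function(ridx) {
    pid <- sys$rules[[ridx]]$pids[1]
    cs[pid] / sys$patterns[[pid]]$sym
  }, 1)
  list(rules = mono, counts = counts)
}

#' Run the fragmented Gillespie algorithm for one spatial time step
#'
#' Operating on the occurrence counts of the monomolecular reactant patterns,
#' samples exponential waiting times with total propensity
#' `sum(k_r * count_r)`; while the next event time falls inside the step, an
#' arbitrary (uniformly random) molecule anchoring the chosen rule's pattern
#' is selected and modified, propensities are updated, and sampling resumes.
#' Fragmenting the algorithm across spatial steps is exact because the
#' process is memoryless.
#'
#' @param rx reactor; @param sys compiled system.
#' @param dt length of the spatial step.
#' @param consumed logical per-molecule flag; molecules already consumed this
#'   step are skipped and firing marks participants consumed.
#' @return updated `consumed` vector (invisibly returns via value).
#' @export
gillespie_monomolecular <- function(rx, sys, dt, consumed = rep(FALSE, rx$n)) {
  mc <- mono_counts(rx, sys)
  if (!length(mc$rules)) return(consumed)
  elapsed <- 0
  repeat {
    rates <- vapply(mc$rules, function(ridx) sys$rules[[ridx]]$rate, 1)
    a <- rates * mc$counts
    atot <- sum(a)
    if (atot <= 0) break
    tau <- rexp(1, atot)
    elapsed <- elapsed + tau
    if (elapsed > dt) break
    ridx <- mc$rules[sample.int(length(mc$rules), 1L, prob = a / atot)]
    r <- sys$rules[[ridx]]
    p <- sys$patterns[[r$pids[1]]]
    w <- which(rx$P[, r$pids[1]] > 0L & !consumed)
    if (!length(w)) break
    m <- if (length(w) == 1L) w else
      sample(w, 1L, prob = rx$P[w, r$pids[1]])
    emb <- match_pattern(rx, sys, p, m)
    if (!length(emb)) { rx$diag$stale <- rx$diag$stale + 1L; next }
    e <- emb[[sample.int(length(emb), 1L)]]
    execute_rule(rx, sys, list(rule = ridx, mols = m,
                               comps = e$comps[[1]][r$acted[1]]))
    consumed[e$mols] <- TRUE
    rx$diag$mono_events <- rx$diag$mono_events + 1L
    if (isTRUE(rx$record_mono))
      rx$diag$mono_times <- c(rx$diag$mono_times, rx$time + elapsed)
    mc <- mono_counts(rx, sys)
  }
  consumed
}

# ---- per-step reaction phase ------------------------------------------------

# Full reaction phase for the interval [t, t+dt): monomolecular events first,
# then bimolecular candidates in randomized order, each Bernoulli-sampled
# with its rule's exponential firing probability; the first success consumes
# its participants (no molecule reacts twice within one dt).
step_reactions <- function(rx, sys, dt) {
  consumed <- gillespie_monomolecular(rx, sys, dt)
  if (!length(sys$bi_rules) || rx$n < 2L) return(invisible(NULL))
  cand <- candidate_prefilter(rx, sys)
  if (!nrow(cand)) return(invisible(NULL))
  rx$diag$candidates <- rx$diag$candidates + nrow(cand)
  rates <- vapply(sys$rules, `[[`, 1, "rate")
  simple <- sys$rule_simple[cand$rule]
  # candidates of rules with single-node reactant patterns run through the
  # batched C++ phase; the rest through the R resolver. Both groups are
  # internally shuffled; group order is randomized to avoid systematic bias
  # when candidates of the two kinds compete for the same molecules.
  phases <- if (runif(1) < 0.5) list(TRUE, FALSE) else list(FALSE, TRUE)
  for (want_simple in phases) {
    sub <- cand[simple == want_simple, , drop = FALSE]
    if (!nrow(sub)) next
    if (want_simple) {
      fl <- sys$flat
      fires <- bi_step_cpp(sub$i, sub$j, sub$rule,
                           fire_probability(rates[sub$rule], dt),
                           sys$cinfo, sys$is_binding,
                           rx$pos, rx$bond_to, rx$state, rx$species,
                           fl$comp_d, fl$ncomp, fl$t_dist, fl$t_ang_comp, fl$alpha,
                           sys$config$box, sys$config$periodic,
                           rx$refract, rx$time, consumed)
      rx$diag$rej_refractory <- rx$diag$rej_refractory + fires$rej_refractory
      rx$diag$stale <- rx$diag$stale + fires$stale
      for (k in seq_along(fires$i)) {
        execute_rule(rx, sys, list(rule = fires$rule[k],
                                   mols = c(fires$i[k], fires$j[k]),
                                   comps = c(fires$ci[k], fires$cj[k])))
        consumed[c(fires$i[k], fires$j[k])] <- TRUE
      }
    } else {
      # Bernoulli trial first (it is independent of the deterministic
      # compatibility test, so the order does not change the firing law),
      # then embedding + geometry resolution only for drawn candidates
      ord <- sample.int(nrow(sub))
      pfire <- fire_probability(rates[sub$rule], dt)
      draws <- runif(nrow(sub))
      acache <- new.env(hash = TRUE, parent = emptyenv())
      for (k in ord) {
        if (draws[k] >= pfire[k]) next
        i <- sub$i[k]; j <- sub$j[k]
        if (consumed[i] || consumed[j]) {
          rx$diag$stale <- rx$diag$stale + 1L
          next
        }
        res <- resolve_candidate(rx, sys, sub$rule[k], i, j, cache = acache,
                                 consumed = consumed)
        if (is.null(res)) next
        execute_rule(rx, sys, list(rule = sub$rule[k], mols = c(i, j),
                                   comps = res))
        consumed[c(i, j)] <- TRUE
      }
    }
  }
  invisible(NULL)
}
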