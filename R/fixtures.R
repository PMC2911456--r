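# Generators for the four packaged example systems. Each builder returns
# model text (BNGL subset), geometry text, and an srb_config, constructed
# programmatically so every test and example runs without external files.
# Geometries are reconstructions from the systems' qualitative descriptions;
# they are validated by emergent-structure analyses (protofilament count,
# seam, ring census, tile pattern), not by byte comparison to any original.

deg <- function(rad) rad * 180 / pi

fixture_paste <- function(lines) paste(lines, collapse = "\n")

#' Scaffold-protein fixture
#'
#' Particles A phosphorylate each other on contact and lose the modification
#' over time; larger scaffold spheres S bind up to four A (all four binding
#' components face one pole) with rate `k_s`. Unphosphorylated A stick to the
#' scaffold while phosphorylated A dissociate quickly. The angular tolerance
#' is 180 degrees (binding accepted from any direction) and the angular force
#' term is off by default so bound A diffuse freely over the scaffold
#' surface.
#'
#' @param k_s scaffold binding rate (`0` = scaffold disabled, the "wo-Scf"
#'   variant).
#' @param n_a,n_s particle counts.
#' @param n_steps steps to simulate.
#' @param angular_forces turn the angular force term on.
#' @return list with `model`, `geometry` (text) and `config`.
#' @export
fixture_scaffold <- function(k_s = 50, n_a = 48, n_s = 8, n_steps = 6000L,
                             angular_forces = FALSE) {
  model <- fixture_paste(c(
    "begin molecule types",
    "  A(s,p~U~P)",
    "  S(a,a,a,a)",
    "end molecule types",
    "begin seed species",
    sprintf("  A(s,p~U) %d", n_a),
    sprintf("  S(a,a,a,a) %d", n_s),
    "end seed species",
    "begin reaction rules",
    "  A(p~U) + A(p~U) -> A(p~P) + A(p~U) 20",
    "  A(p~P) -> A(p~U) 0.5",
    sprintf("  A(s) + S(a) -> A(s!1).S(a!1) %g", k_s),
    "  A(s!1,p~P).S(a!1) -> A(s,p~P) + S(a) 2",
    "  A(s!1,p~U).S(a!1) -> A(s,p~U) + S(a) 0.05",
    "end reaction rules",
    "begin observables",
    "  Molecules Ap A(p~P)",
    "  Molecules Abound A(s!+)",
    "end observables"))
  geometry <- fixture_paste(c(
    "species A 1.0 0.5 1.0",
    "component A s 0.5 90 0",
    "component A p 0.5 90 180",
    "tolerance A 0.5 180",
    "species S 4.0 1.5 0.25",
    "component S a 1.5 35 0",
    "component S a 1.5 35 90",
    "component S a 1.5 35 180",
    "component S a 1.5 35 270",
    "tolerance S 0.5 180"))
  config <- sim_config(
    box = c(15, 15, 15), boundary = c("p", "p", "p"),
    dt = 0.005, n_steps = n_steps, temperature = 1,
    K_d = 20, K_alpha = if (angular_forces) 10 else 0, A_rep = 5,
    sigma = 2.6, t_dist = 0.5, t_ang = 180, obs_period = 50L)
  list(name = "scaffold", model = model, geometry = geometry, config = config)
}

# Microtubule lattice constants: 13 protofilaments, 3-start monomer helix
# (rise of 3 subunit layers per lateral turn), subunit spacing 1.
mt_lattice <- function(n_pf = 13L, rise_per_turn = 3) {
  rise <- rise_per_turn / n_pf             # axial rise per lateral step
  chord <- sqrt(1 - rise^2)                # horizontal lateral spacing
  list(n_pf = n_pf, rise = rise, chord = chord,
       radius = (chord / 2) / sin(pi / n_pf),
       theta_lr = acos(rise),              # lateral-right component polar angle
       phi_ll = pi - 2 * pi / n_pf)        # interior angle of the n_pf-gon
}

#' Microtubule growth / active-transport fixture
#'
#' Alpha/beta-tubulin heterodimers assemble onto a fixed nucleating
#' structure into a tube of 13 protofilaments with the 13_3 lattice
#' (3 subunit layers of rise per lateral turn), producing a seam where
#' alpha-tubulins bind beta-tubulins laterally. The nucleating structure is
#' the 13-membered capping ring plus one pre-wired dimer layer (a helical
#' collar, open at the wrap) that presents the lattice register the way a
#' templating ring complex does; the seam and all further layers assemble
#' from solution. The rule set comprises 27 rules: 13 for polymerization
#' including the seam, 4 for the processive stepping of kinesin motor
#' dimers, and 10 controlling cargo and lattice binding/release by the
#' motors. With `phase2 = TRUE`, motor dimers and cargo particles are
#' inserted in a second phase. Motor directionality is geometric: the
#' motor-binding site on beta-tubulin tilts toward the minus end, so only
#' the next plus-ward lattice site is angularly compatible for the free head
#' of a bound motor pair.
#'
#' @param n_dimers tubulin dimers seeded in solution.
#' @param n_steps steps to simulate.
#' @param phase2 insert motors and cargo mid-run.
#' @param n_motors,n_cargo phase-2 insertion counts.
#' @param phase2_time insertion time.
#' @return list with `model`, `geometry` (text), `config` and the `lattice`
#'   constants.
#' @export
fixture_microtubule <- function(n_dimers = 150L, n_steps = 10000L,
                                phase2 = FALSE, n_motors = 12L, n_cargo = 12L,
                                phase2_time = NULL) {
  lat <- mt_lattice()
  box <- c(8, 8, 12)
  z0 <- 1.4
  dt <- 0.0045
  insertions <- character(0)
  if (phase2) {
    t2 <- if (is.null(phase2_time)) round(0.6 * n_steps) * dt else phase2_time
    insertions <- c(
      "begin insertions",
      sprintf("  %g KIN(m,h!1,cg).KIN(m,h!1,cg) %d", t2, n_motors),
      sprintf("  %g CRG(g) %d", t2, n_cargo),
      "end insertions")
  }
  model <- fixture_paste(c(
    "begin molecule types",
    "  CAP(next,prev,plus)",
    "  TA(d,t,ll,lr)",
    "  TB(b,u,ll,lr,mot)",
    "  KIN(m,h,cg)",
    "  CRG(g)",
    "end molecule types",
    "begin seed species",
    sprintf("  TA(d,t!1,ll,lr).TB(b!1,u,ll,lr,mot) %d", n_dimers),
    "end seed species",
    "begin reaction rules",
    # -- polymerization (13 rules, including the seam). Elongation is
    # template-nucleated (the free dimer adds onto a lattice-attached
    # column top) and lateral bonds only zip between lattice-attached
    # subunits, so the register presented by the nucleating collar
    # propagates instead of being scrambled by solution oligomers
    "  CAP(plus) + TA(d) -> CAP(plus!1).TA(d!1) 1000",
    "  TB(b!1,u).TA(t!1,d!+) + TA(d) -> TB(b!1,u!2).TA(t!1,d!+).TA(d!2) 1000",
    "  TA(d!+,lr) + TA(d!+,ll) -> TA(d!+,lr!1).TA(d!+,ll!1) 600",
    "  TB(b!1,lr).TA(t!1,d!+) + TB(b!2,ll).TA(t!2,d!+) -> TB(b!1,lr!3).TA(t!1,d!+).TB(b!2,ll!3).TA(t!2,d!+) 600",
    "  TA(d!+,lr) + TB(b!1,ll).TA(t!1,d!+) -> TA(d!+,lr!2).TB(b!1,ll!2).TA(t!1,d!+) 600",
    "  TB(b!1,lr).TA(t!1,d!+) + TA(d!+,ll) -> TB(b!1,lr!2).TA(t!1,d!+).TA(d!+,ll!2) 600",
    "  CAP(plus!1).TA(d!1) -> CAP(plus) + TA(d) 0.005",
    "  TB(u!1).TA(d!1,ll,lr) -> TB(u) + TA(d,ll,lr) 0.1",
    "  TA(lr!1).TA(ll!1) -> TA(lr) + TA(ll) 0.02",
    "  TB(lr!1).TB(ll!1) -> TB(lr) + TB(ll) 0.02",
    "  TA(lr!1).TB(ll!1) -> TA(lr) + TB(ll) 0.02",
    "  TB(lr!1).TA(ll!1) -> TB(lr) + TA(ll) 0.02",
    "  TA(t) + TB(b) -> TA(t!1).TB(b!1) 50",
    # -- kinesin stepping (4 rules)
    "  KIN(m) + TB(mot) -> KIN(m!1).TB(mot!1) 5",
    "  KIN(m,h!1).KIN(h!1,m!+) + TB(mot) -> KIN(m!2,h!1).KIN(h!1,m!+).TB(mot!2) 100",
    "  KIN(m!1,h!2).KIN(h!2,m!+).TB(mot!1) -> KIN(m,h!2).KIN(h!2,m!+) + TB(mot) 20",
    "  KIN(m!1).TB(mot!1) -> KIN(m) + TB(mot) 0.2",
    # -- cargo / lattice control by the motors (10 rules)
    "  KIN(cg) + CRG(g) -> KIN(cg!1).CRG(g!1) 20",
    "  KIN(cg!1).CRG(g!1) -> KIN(cg) + CRG(g) 0.1",
    "  KIN(cg!1,m!2).TB(mot!2,u).CRG(g!1) -> KIN(cg,m!2).TB(mot!2,u) + CRG(g) 5",
    "  KIN(cg!+,m) + TB(mot) -> KIN(cg!+,m!1).TB(mot!1) 5",
    "  KIN(cg!+,m!1).TB(mot!1) -> KIN(cg!+,m) + TB(mot) 0.2",
    "  CRG(g) + KIN(cg,m!+) -> CRG(g!1).KIN(cg!1,m!+) 20",
    "  KIN(h) + KIN(h) -> KIN(h!1).KIN(h!1) 1",
    "  KIN(h!1,m).KIN(h!1,m) -> KIN(h,m) + KIN(h,m) 0.5",
    "  KIN(m!1,h).TB(mot!1) -> KIN(m,h) + TB(mot) 2",
    "  CRG(g!1).KIN(cg!1,m) -> CRG(g) + KIN(cg,m) 0.5",
    "end reaction rules",
    "begin observables",
    "  Molecules polymerized TA(d!+)",
    "  Molecules lateral TA(lr!+)",
    "  Molecules motors_on KIN(m!+)",
    "  Molecules cargo_loaded CRG(g!+)",
    "end observables",
    insertions))
  th_lr <- deg(lat$theta_lr); th_ll <- 180 - th_lr
  ph_ll <- deg(lat$phi_ll)
  ph_mot <- (0 + ph_ll) / 2 + 180
  lat_comp <- function(sp) c(
    sprintf("component %s ll 0.5 %.6f %.6f", sp, th_ll, ph_ll),
    sprintf("component %s lr 0.5 %.6f 0", sp, th_lr))
  # lateral sites keep the tight tolerance that discriminates the helical
  # register (the wrong-register contact deviates by 2*(90 - theta_lr) =
  # 26.6 degrees); longitudinal sites get a looser per-component tolerance
  # since attachment geometry is straightened by the angle forces anyway
  geometry <- fixture_paste(c(
    "species CAP 1.0 0.5 0.0",
    sprintf("component CAP next 0.5 %.6f 0", th_lr),
    sprintf("component CAP prev 0.5 %.6f %.6f", th_ll, ph_ll),
    "component CAP plus 0.5 0 0",
    "tolerance CAP 0.45 45",
    "species TA 1.0 0.5 1.5",
    "component TA d 0.5 180 0",
    "component TA t 0.5 0 0",
    lat_comp("TA"),
    "tolerance TA 0.45 18",
    "angtol TA d 30",
    "angtol TA t 30",
    "species TB 1.0 0.5 1.5",
    "component TB b 0.5 180 0",
    "component TB u 0.5 0 0",
    lat_comp("TB"),
    sprintf("component TB mot 0.5 120 %.6f", ph_mot),
    "tolerance TB 0.45 18",
    "angtol TB u 30",
    "angtol TB b 30",
    "angtol TB mot 35",
    "species KIN 1.0 0.4 1.5",
    "component KIN m 0.5 90 0",
    "component KIN h 0.35 90 180",
    "component KIN cg 0.4 0 0",
    "tolerance KIN 0.35 60",
    "species CRG 2.0 0.6 0.5",
    "component CRG g 0.5 0 0",
    "tolerance CRG 0.35 60",
    "fixed CAP"))
  # nucleating structure: the 13-membered capping ring plus one pre-wired
  # dimer layer (a helical collar; lateral bonds open at the wrap so the
  # seam itself forms during assembly)
  n_pf <- lat$n_pf
  cap_terms <- vapply(seq_len(n_pf), function(k) {
    nx <- if (k < n_pf) sprintf("next!%d", k) else "next"
    pv <- if (k > 1) sprintf("prev!%d", k - 1L) else "prev"
    sprintf("CAP(%s,%s,plus!%d)", nx, pv, 12L + k)
  }, "")
  dimer_terms <- vapply(seq_len(n_pf), function(k) {
    alr <- if (k < n_pf) sprintf("lr!%d", 100L + k) else "lr"
    all_ <- if (k > 1) sprintf("ll!%d", 100L + k - 1L) else "ll"
    blr <- if (k < n_pf) sprintf("lr!%d", 200L + k) else "lr"
    bll <- if (k > 1) sprintf("ll!%d", 200L + k - 1L) else "ll"
    sprintf("TA(d!%d,t!%d,%s,%s).TB(b!%d,u,%s,%s,mot)",
            12L + k, 300L + k, all_, alr, 300L + k, bll, blr)
  }, "")
  psi <- 2 * pi * (seq_len(n_pf) - 1L) / n_pf
  ring_xy <- cbind(box[1] / 2 + lat$radius * cos(psi),
                   box[2] / 2 + lat$radius * sin(psi))
  zk <- z0 + lat$rise * (seq_len(n_pf) - 1L)
  coords <- matrix(0, 3L * n_pf, 3)
  for (k in seq_len(n_pf)) {
    coords[k, ] <- c(ring_xy[k, ], zk[k])                      # CAP k
    coords[n_pf + 2L * k - 1L, ] <- c(ring_xy[k, ], zk[k] + 1) # TA k
    coords[n_pf + 2L * k, ] <- c(ring_xy[k, ], zk[k] + 2)      # TB k
  }
  structure_str <- paste(c(cap_terms, dimer_terms), collapse = ".")
  config <- sim_config(
    box = box, boundary = c("p", "p", "r"),
    dt = dt, n_steps = n_steps, temperature = 1,
    K_d = 150, K_alpha = 100, A_rep = 5,
    sigma = 1.5, t_dist = 0.45, t_ang = 25, obs_period = 200L,
    structures = list(list(species = structure_str, coords = coords)))
  list(name = "microtubule", model = model, geometry = geometry,
       config = config, lattice = lat)
}

#' Spheric self-assembly fixture
#'
#' Rigid monomers of six elementary molecules — a triangle of "outer" type O
#' above a triangle of "inner" type I — assemble into closed, roughly
#' spherical shells. Inter-monomer bonds form only between components of the
#' same type; outer components have length 1.4 and inner components 1.0, and
#' the resulting outer/inner bond-length mismatch (2.8 vs 2.0) curves the
#' growing sheet. Eight rules organized in pairs (outer/inner) with four rate
#' parameters describe free-monomer coupling, addition of a monomer to a
#' formed complex, and two dissociation behaviours.
#'
#' @param n_monomers monomer count.
#' @param n_steps steps to simulate.
#' @param k_on1,k_on2,k_off1,k_off2 the four rate parameters (free coupling,
#'   addition to complex, slow dissociation, fast dissociation of half-made
#'   contacts).
#' @return list with `model`, `geometry` (text) and `config`.
#' @export
fixture_spheres <- function(n_monomers = 40L, n_steps = 4000L,
                            k_on1 = 5, k_on2 = 50, k_off1 = 0.1, k_off2 = 2) {
  monomer <- paste0(
    "O(x,c!1).I(y,a!4,b!6,c!1).",
    "O(x,c!2).I(y,a!5,b!4,c!2).",
    "O(x,c!3).I(y,a!6,b!5,c!3)")
  model <- fixture_paste(c(
    "begin molecule types",
    "  O(x,c)",
    "  I(y,a,b,c)",
    "end molecule types",
    "begin seed species",
    sprintf("  %s %d", monomer, n_monomers),
    "end seed species",
    "begin reaction rules",
    sprintf("  O(x) + O(x) -> O(x!1).O(x!1) %g", k_on1),
    sprintf("  I(y) + I(y) -> I(y!1).I(y!1) %g", k_on1),
    sprintf("  I(y!+,c!1).O(c!1,x) + O(x) -> I(y!+,c!1).O(c!1,x!2).O(x!2) %g", k_on2),
    sprintf("  O(x!+,c!1).I(c!1,y) + I(y) -> O(x!+,c!1).I(c!1,y!2).I(y!2) %g", k_on2),
    sprintf("  O(x!1).O(x!1) -> O(x) + O(x) %g", k_off1),
    sprintf("  I(y!1).I(y!1) -> I(y) + I(y) %g", k_off1),
    sprintf("  I(y,c!1).O(c!1,x!2).O(x!2) -> I(y,c!1).O(c!1,x) + O(x) %g", k_off2),
    sprintf("  O(x,c!1).I(c!1,y!2).I(y!2) -> O(x,c!1).I(c!1,y) + I(y) %g", k_off2),
    "end reaction rules",
    "begin observables",
    "  Molecules outer_bonds O(x!+)",
    "  Molecules inner_bonds I(y!+)",
    "end observables"))
  # monomer template: inner triangle (circumradius 0.75, z = 0), outer
  # triangle (circumradius 1.05, z = 0.7); polar component coordinates are
  # derived from the same construction so ideal angles match the template
  rho_i <- 0.75; rho_o <- 1.05; dz <- 0.7
  s_i <- rho_i * sqrt(3)
  dvec <- c(rho_o - rho_i, dz)
  c_len <- sqrt(sum(dvec^2)) / 2
  th_c <- deg(atan2(dvec[1], dvec[2]))     # I's c: up and slightly outward
  psi <- c(90, 210, 330) * pi / 180
  tpl <- matrix(0, 6, 3)
  for (k in 1:3) {
    tpl[2 * k - 1, ] <- c(rho_o * cos(psi[k]), rho_o * sin(psi[k]), dz)  # O_k
    tpl[2 * k, ] <- c(rho_i * cos(psi[k]), rho_i * sin(psi[k]), 0)       # I_k
  }
  geometry <- fixture_paste(c(
    "species O 1.0 0.5 1.0",
    "component O x 1.4 90 90",
    sprintf("component O c %.6f %.6f 270", c_len, 180 - th_c),
    "tolerance O 0.4 60",
    "species I 1.0 0.5 1.0",
    "component I y 1.0 90 90",
    sprintf("component I a %.6f 90 240", s_i / 2),
    sprintf("component I b %.6f 90 300", s_i / 2),
    sprintf("component I c %.6f %.6f 90", c_len, th_c),
    "tolerance I 0.4 60",
    "rigid O I"))
  config <- sim_config(
    box = c(16, 16, 16), boundary = c("p", "p", "p"),
    dt = 0.005, n_steps = n_steps, temperature = 1,
    K_d = 40, K_alpha = 10, A_rep = 5,
    sigma = 3.3, t_dist = 0.4, t_ang = 60, obs_period = 100L,
    seed_templates = list(list(species = monomer, coords = tpl)))
  list(name = "spheres", model = model, geometry = geometry, config = config)
}

#' DNA-tile Sierpinski-triangle fixture
#'
#' Four tile species encode the XOR truth table (inputs on two downward
#' binding sites, the output exposed on two upward sites); the two '0'-output
#' tiles are distinct species (one docks onto two '0' sites, the other onto
#' two '1' sites). Tiles attach on top of a fixed one-dimensional nucleating
#' row; because only one bond can form per reaction step, attachment happens
#' in two steps, and a tile whose second input finds no matching neighbor
#' dissociates again quickly.
#'
#' @param seed_values 0/1 vector along the nucleating row.
#' @param n_rows rows the box leaves room for.
#' @param counts tile counts, named `T00`, `T01`, `T10`, `T11`.
#' @param n_steps steps to simulate.
#' @param k_on attachment rate; @param k_off dissociation rate of
#'   single-bonded tiles.
#' @return list with `model`, `geometry` (text), `config`, and the lattice
#'   constants used by the grid extractor.
#' @export
fixture_sierpinski <- function(seed_values = c(0, 0, 0, 0, 1, 0, 0, 0, 0),
                               n_rows = 4L,
                               counts = c(T00 = 24L, T01 = 10L, T10 = 10L, T11 = 6L),
                               n_steps = 6000L, k_on = 100, k_off = 20) {
  sx <- 1.2; sz <- 0.9
  blen <- sqrt((sx / 2)^2 + sz^2)
  d <- blen / 2
  th_up <- deg(atan2(sx / 2, sz))
  tiles <- list(T00 = c(0, 0), T01 = c(0, 1), T10 = c(1, 0), T11 = c(1, 1))
  out_of <- function(v) if (sum(v) == 1L) 1L else 0L
  tile_sig <- function(nm) {
    v <- tiles[[nm]]
    sprintf("%s(dl%d,dr%d,u%d,u%d)", nm, v[1], v[2], out_of(v), out_of(v))
  }
  types <- c(vapply(names(tiles), tile_sig, ""),
             "N0(u0,u0)", "N1(u1,u1)")
  lowers <- list("0" = c("N0", "T00", "T11"), "1" = c("N1", "T01", "T10"))
  uppers <- list(dl = list("0" = c("T00", "T01"), "1" = c("T10", "T11")),
                 dr = list("0" = c("T00", "T10"), "1" = c("T01", "T11")))
  # one attach rule and one single-bond dissociation rule per (lower species,
  # upper tile, down-site) combination of matching value
  rules <- character(0)
  for (v in c("0", "1")) for (site in c("dl", "dr")) {
    dsite <- paste0(site, v)
    other <- setdiff(c("dl", "dr"), site)
    for (U in uppers[[site]][[v]]) {
      ov <- tiles[[U]][if (other == "dl") 1L else 2L]
      osite <- paste0(other, ov)
      for (L in lowers[[v]]) {
        rules <- c(rules,
          sprintf("  %s(u%s) + %s(%s) -> %s(u%s!1).%s(%s!1) %g",
                  L, v, U, dsite, L, v, U, dsite, k_on),
          sprintf("  %s(%s!1,%s).%s(u%s!1) -> %s(%s,%s) + %s(u%s) %g",
                  U, dsite, osite, L, v, U, dsite, osite, L, v, k_off))
      }
    }
  }
  model <- fixture_paste(c(
    "begin molecule types",
    paste0("  ", types),
    "end molecule types",
    "begin seed species",
    vapply(names(tiles), function(nm) {
      v <- tiles[[nm]]
      sprintf("  %s(dl%d,dr%d,u%d,u%d) %d", nm, v[1], v[2],
              out_of(v), out_of(v), counts[[nm]])
    }, ""),
    "end seed species",
    "begin reaction rules",
    rules,
    "end reaction rules",
    "begin observables",
    "  Molecules ones_attached T01(dl0!+)",
    "  Molecules bonds_row1 N0(u0!+)",
    "end observables"))
  geo_tile <- function(nm, dl, dr, uv) c(
    sprintf("species %s 1.0 0.5 1.0", nm),
    sprintf("component %s dl%d %.6f %.6f 180", nm, dl, d, 180 - th_up),
    sprintf("component %s dr%d %.6f %.6f 0", nm, dr, d, 180 - th_up),
    sprintf("component %s u%d %.6f %.6f 180", nm, uv, d, th_up),
    sprintf("component %s u%d %.6f %.6f 0", nm, uv, d, th_up),
    sprintf("tolerance %s 0.3 40", nm))
  geometry <- fixture_paste(c(
    unlist(lapply(names(tiles), function(nm) {
      v <- tiles[[nm]]
      geo_tile(nm, v[1], v[2], out_of(v))
    })),
    "species N0 1.0 0.5 0.0",
    sprintf("component N0 u0 %.6f %.6f 180", d, th_up),
    sprintf("component N0 u0 %.6f %.6f 0", d, th_up),
    "tolerance N0 0.3 40",
    "species N1 1.0 0.5 0.0",
    sprintf("component N1 u1 %.6f %.6f 180", d, th_up),
    sprintf("component N1 u1 %.6f %.6f 0", d, th_up),
    "tolerance N1 0.3 40",
    "fixed N0 N1"))
  w <- length(seed_values)
  x0 <- 2; z0 <- 1; y0 <- 2.5
  box <- c((w - 1) * sx + 4, 5, n_rows * sz + 4)
  structures <- lapply(seq_len(w), function(i) {
    nm <- if (seed_values[i] == 1) "N1" else "N0"
    list(species = sprintf("%s(u%d,u%d)", nm, seed_values[i], seed_values[i]),
         coords = matrix(c(x0 + (i - 1) * sx, y0, z0), 1, 3))
  })
  config <- sim_config(
    box = box, boundary = c("r", "r", "r"),
    dt = 0.005, n_steps = n_steps, temperature = 1,
    K_d = 40, K_alpha = 10, A_rep = 5,
    sigma = 1.4, t_dist = 0.3, t_ang = 40, obs_period = 100L,
    structures = structures)
  list(name = "sierpinski", model = model, geometry = geometry,
       config = config,
       lattice = list(sx = sx, sz = sz, x0 = x0, z0 = z0,
                      seed_values = seed_values))
}

#' Build a fixture by name
#' @param name one of `"scaffold"`, `"microtubule"`, `"spheres"`,
#'   `"sierpinski"`.
#' @param ... passed to the specific builder.
#' @return the builder's result.
#' @export
build_fixture <- function(name = c("scaffold", "microtubule", "spheres",
                                   "sierpinski"), ...) {
  name <- match.arg(name)
  switch(name,
         scaffold = fixture_scaffold(...),
         microtubule = fixture_microtubule(...),
         spheres = fixture_spheres(...),
         sierpinski = fixture_sierpinski(...))
}

#' Write a fixture's input files to a directory
#'
#' Writes `<name>.bngl`, `<name>.geo` and `<name>.yaml`.
#'
#' @param fixture a builder result; @param dir output directory.
#' @return the three paths, invisibly.
#' @export
fixture_write <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(fixture$name, c(".bngl", ".geo", ".yaml")))
  writeLines(fixture$model, paths[1])
  writeLines(fixture$geometry, paths[2])
  write_config(fixture$config, paths[3])
  invisible(paths)
}

#' Run a fixture
#' @param fixture a builder result; @param seed RNG seed; @param ... override
#'   config fields (e.g. `n_steps`).
#' @return `srb_result`.
#' @export
run_fixture <- function(fixture, seed = 1L, ...) {
  cfg <- fixture$config
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (!is.null(dots$n_steps)) cfg$n_steps <- as.integer(dots$n_steps)
  model <- parse_model(fixture$model)
  geometry <- parse_geometry(fixture$geometry, model)
  run_simulation(model, geometry, cfg, seed = seed)
}
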