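# ---------------------------------------------------------------------------
# Biochemical model description, kept separate from geometry: species,
# volume systems (reactions + diffusion rules), surface systems (surface
# reactions, surface diffusion, channel-state sets). Geometry components
# reference systems by id; the association is resolved when the solver is
# built, so one model can be reused with many meshes and vice versa.
#
# Rate-constant units follow the molar convention: s^-1 for order 1,
# M^-1 s^-1 for order 2, M s^-1 for order 0. The engine converts them to
# stochastic per-element rates using the element volume.
# ---------------------------------------------------------------------------

#' Volume reaction rule
#'
#' @param id Rule id.
#' @param reactants,products Named numeric vectors of stoichiometries
#'   (names are species ids); may be empty.
#' @param kcst Rate constant: M s^-1 (order 0), s^-1 (order 1),
#'   M^-1 s^-1 (order 2). Total reactant order must be at most 2.
#' @return A `reaction` rule.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(), kcst) {
  .check_stoich(reactants, "reactants")
  .check_stoich(products, "products")
  order <- sum(reactants)
  if (order > 2) stop("reaction '", id, "': order > 2 not supported")
  if (!is.finite(kcst) || kcst < 0) stop("reaction '", id, "': kcst must be >= 0")
  structure(list(id = id, reactants = reactants, products = products,
                 kcst = kcst, order = order), class = "reaction")
}

.check_stoich <- function(x, what) {
  if (is.null(x) || !length(x)) return(invisible(numeric()))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named vector (species = stoichiometry)")
  if (any(x < 1) || any(x != round(x)))
    stop(what, " stoichiometries must be positive integers")
  invisible(x)
}

#' Volume diffusion rule
#' @param id Rule id.
#' @param species Species id.
#' @param D Diffusion coefficient, m^2/s (>= 0).
#' @return A `diffusion_rule`.
#' @export
diffusion_rule <- function(id, species, D) {
  if (!is.finite(D) || D < 0) stop("diffusion rule '", id, "': D must be >= 0")
  structure(list(id = id, species = species, D = D), class = "diffusion_rule")
}

#' Surface reaction rule
#'
#' Reactants and products are tagged by location: `surface` (on the patch
#' triangle), `inner` (volume of the compartment behind the triangle), or
#' `outer` (volume on the other side). At least one surface participant is
#' required and the total reactant order must be at most 2.
#'
#' @param id Rule id.
#' @param reactants,products Named lists with optional elements `surface`,
#'   `inner`, `outer`, each a named stoichiometry vector.
#' @param kcst Rate constant (same convention as [reaction()]).
#' @return A `surface_reaction` rule.
#' @export
surface_reaction <- function(id, reactants = list(), products = list(), kcst) {
  norm <- function(x) {
    x <- x[c("surface", "inner", "outer")]
    names(x) <- c("surface", "inner", "outer")
    x <- lapply(x, function(v) if (is.null(v)) numeric() else v)
    lapply(x, .check_stoich, what = "surface reaction stoichiometry")
    x
  }
  reactants <- norm(reactants); products <- norm(products)
  order <- sum(unlist(reactants))
  if (order > 2) stop("surface reaction '", id, "': order > 2 not supported")
  n_surf <- length(reactants$surface) + length(products$surface)
  if (n_surf == 0)
    stop("surface reaction '", id, "' needs at least one surface participant")
  if (!is.finite(kcst) || kcst < 0)
    stop("surface reaction '", id, "': kcst must be >= 0")
  structure(list(id = id, reactants = reactants, products = products,
                 kcst = kcst, order = order), class = "surface_reaction")
}

#' Surface diffusion rule (lateral diffusion on a patch)
#' @inheritParams diffusion_rule
#' @return A `surface_diffusion_rule`.
#' @export
surface_diffusion_rule <- function(id, species, D) {
  r <- diffusion_rule(id, species, D)
  class(r) <- "surface_diffusion_rule"
  r
}

#' Channel state set
#'
#' Declares that a group of surface species are the conformational states of
#' one membrane channel; transitions between states are expressed as surface
#' reactions among them. Channel copy number is conserved by any such
#' transition.
#'
#' @param id Set id.
#' @param states Character vector of distinct state species ids.
#' @param initial The initial state (one of `states`).
#' @return A `channel_state_set`.
#' @export
channel_state_set <- function(id, states, initial = states[1]) {
  if (anyDuplicated(states)) stop("channel states must be distinct")
  if (!initial %in% states) stop("initial state not among states")
  structure(list(id = id, states = states, initial = initial),
            class = "channel_state_set")
}

#' Volume system: a named group of reaction and diffusion rules
#' @param id System id (referenced from compartments).
#' @param reactions List of [reaction()] rules.
#' @param diffusion List of [diffusion_rule()]s.
#' @return A `volume_system`.
#' @export
volume_system <- function(id, reactions = list(), diffusion = list()) {
  structure(list(id = id, reactions = reactions, diffusion = diffusion),
            class = "volume_system")
}

#' Surface system: a named group of surface rules
#' @param id System id (referenced from patches).
#' @param reactions List of [surface_reaction()] rules.
#' @param diffusion List of [surface_diffusion_rule()]s.
#' @param channels List of [channel_state_set()]s.
#' @return A `surface_system`.
#' @export
surface_system <- function(id, reactions = list(), diffusion = list(),
                           channels = list()) {
  structure(list(id = id, reactions = reactions, diffusion = diffusion,
                 channels = channels), class = "surface_system")
}

#' Build and validate a biochemical model
#'
#' Checks that all ids are unique, that every rule references declared
#' species, and freezes the declarations into an immutable model object.
#'
#' @param species Character vector of species ids.
#' @param volume_systems List of [volume_system()]s.
#' @param surface_systems List of [surface_system()]s.
#' @return A `bio_model`.
#' @export
build_model <- function(species, volume_systems = list(),
                        surface_systems = list()) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicate species id")
  check_sp <- function(ids, where) {
    bad <- setdiff(ids, species)
    if (length(bad))
      stop("undeclared species in ", where, ": ", paste(bad, collapse = ", "))
  }
  vs <- list(); ss <- list()
  all_rule_ids <- character()
  for (v in volume_systems) {
    stopifnot(inherits(v, "volume_system"))
    if (v$id %in% names(vs)) stop("duplicate volume system id: ", v$id)
    for (r in v$reactions) {
      check_sp(names(r$reactants), paste0("reaction '", r$id, "'"))
      check_sp(names(r$products), paste0("reaction '", r$id, "'"))
      if (r$id %in% all_rule_ids) stop("duplicate rule id: ", r$id)
      all_rule_ids <- c(all_rule_ids, r$id)
    }
    for (d in v$diffusion) check_sp(d$species,
                                    paste0("diffusion rule '", d$id, "'"))
    vs[[v$id]] <- v
  }
  for (s in surface_systems) {
    stopifnot(inherits(s, "surface_system"))
    if (s$id %in% names(ss)) stop("duplicate surface system id: ", s$id)
    for (r in s$reactions) {
      for (loc in c("surface", "inner", "outer")) {
        check_sp(names(r$reactants[[loc]]),
                 paste0("surface reaction '", r$id, "'"))
        check_sp(names(r$products[[loc]]),
                 paste0("surface reaction '", r$id, "'"))
      }
      if (r$id %in% all_rule_ids) stop("duplicate rule id: ", r$id)
      all_rule_ids <- c(all_rule_ids, r$id)
    }
    for (d in s$diffusion) check_sp(d$species,
                                    paste0("surface diffusion '", d$id, "'"))
    for (ch in s$channels) check_sp(ch$states,
                                    paste0("channel set '", ch$id, "'"))
    ss[[s$id]] <- s
  }
  structure(list(species = species, volume_systems = vs,
                 surface_systems = ss), class = "bio_model")
}

#' @export
print.bio_model <- function(x, ...) {
  cat(sprintf("<bio_model> %d species, %d volume systems, %d surface systems\n",
              length(x$species), length(x$volume_systems),
              length(x$surface_systems)))
  invisible(x)
}

#' IP3 receptor demonstration model
#'
#' State topology of the IP3 receptor channel on the ER membrane: the native
#' receptor `R` binds cytosolic IP3 to `R_IP3`, which binds cytosolic Ca to
#' the open state `R_open`; alternatively `R` is inactivated by binding Ca
#' directly, through four sequentially Ca-bound states `R_Ca1` .. `R_Ca4`.
#' Open receptors release Ca from the ER (inner volume) to the cytosol
#' (outer volume). Inactivated states do not bind IP3. No kinetic constants
#' are bundled: every transition rate must be supplied.
#'
#' @param rate_table Named numeric vector supplying every constant:
#'   `kf_R_IP3`, `kb_R_IP3` (R + IP3 binding, M^-1 s^-1 / s^-1);
#'   `kf_RIP3_Ca`, `kb_RIP3_Ca` (opening); `kf_Ca1`..`kf_Ca4` and
#'   `kb_Ca1`..`kb_Ca4` (sequential Ca inactivation); `k_flux`
#'   (open-channel Ca release, M^-1 s^-1, applied to ER-side Ca);
#'   `D_Ca`, `D_IP3` (cytosolic diffusion, m^2/s).
#' @param vsys_cyt,vsys_er,ssys_memb System ids used in the model (match
#'   them to the compartment/patch associations of your mesh).
#' @return A `bio_model` with 7 channel states.
#' @export
ip3r_demo_model <- function(rate_table,
                            vsys_cyt = "cyt_vsys", vsys_er = "er_vsys",
                            ssys_memb = "memb_ssys") {
  need <- c("kf_R_IP3", "kb_R_IP3", "kf_RIP3_Ca", "kb_RIP3_Ca",
            paste0("kf_Ca", 1:4), paste0("kb_Ca", 1:4),
            "k_flux", "D_Ca", "D_IP3")
  missing <- setdiff(need, names(rate_table))
  if (length(missing))
    stop("rate_table is missing: ", paste(missing, collapse = ", "))
  k <- as.list(rate_table[need])

  states <- c("R", "R_IP3", "R_open", paste0("R_Ca", 1:4))
  sr <- function(id, from, to, kcst, vol_reactant = NULL,
                 vol_product = NULL) {
    surface_reaction(id,
      reactants = c(list(surface = stats::setNames(1, from)),
                    if (!is.null(vol_reactant))
                      list(outer = stats::setNames(1, vol_reactant))),
      products = c(list(surface = stats::setNames(1, to)),
                   if (!is.null(vol_product))
                     list(outer = stats::setNames(1, vol_product))),
      kcst = kcst)
  }
  reactions <- list(
    sr("R_bind_IP3",   "R",      "R_IP3",  k$kf_R_IP3, vol_reactant = "IP3"),
    sr("R_unbind_IP3", "R_IP3",  "R",      k$kb_R_IP3, vol_product = "IP3"),
    sr("RIP3_bind_Ca", "R_IP3",  "R_open", k$kf_RIP3_Ca, vol_reactant = "Ca"),
    sr("Ropen_unbind_Ca", "R_open", "R_IP3", k$kb_RIP3_Ca,
       vol_product = "Ca"))
  chain <- c("R", paste0("R_Ca", 1:4))
  for (i in 1:4) {
    reactions[[length(reactions) + 1L]] <-
      sr(paste0("inact_bind_Ca", i), chain[i], chain[i + 1L],
         k[[paste0("kf_Ca", i)]], vol_reactant = "Ca")
    reactions[[length(reactions) + 1L]] <-
      sr(paste0("inact_unbind_Ca", i), chain[i + 1L], chain[i],
         k[[paste0("kb_Ca", i)]], vol_product = "Ca")
  }
  # open-channel Ca release: ER (inner) Ca moved to cytosol (outer),
  # catalyzed by the open state
  reactions[[length(reactions) + 1L]] <- surface_reaction(
    "open_Ca_flux",
    reactants = list(surface = c(R_open = 1), inner = c(Ca = 1)),
    products = list(surface = c(R_open = 1), outer = c(Ca = 1)),
    kcst = k$k_flux)

  build_model(
    species = c("Ca", "IP3", states),
    volume_systems = list(
      volume_system(vsys_cyt, diffusion = list(
        diffusion_rule("diff_Ca_cyt", "Ca", k$D_Ca),
        diffusion_rule("diff_IP3_cyt", "IP3", k$D_IP3))),
      volume_system(vsys_er, diffusion = list(
        diffusion_rule("diff_Ca_er", "Ca", k$D_Ca)))),
    surface_systems = list(
      surface_system(ssys_memb, reactions = reactions,
                     channels = list(
                       channel_state_set("IP3R", states, initial = "R")))))
}
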