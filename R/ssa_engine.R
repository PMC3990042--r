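# ---------------------------------------------------------------------------
# Spatial SSA solver: Gillespie's direct method extended with
# inter-tetrahedron diffusion and surface reactions on patch triangles.
#
# Geometry + model are compiled into a flat table of event channels
# (see src/solver.cpp); the inter-tet hop rate for a molecule in tet i with
# face-neighbor j is d_ij = D * A_ij / (V_i * h_ij), the two-point
# finite-volume discretization of Fick's law (A_ij shared-face area). By
# default h_ij is the barycenter distance projected onto the face normal:
# on meshes whose cell connections are not face-orthogonal (e.g. Kuhn
# subdivisions) the plain Euclidean distance under-transports by ~10% in
# effective diffusivity. The formula is isolated in .diffusion_rate_factor
# / build_solver for substitution.
# ---------------------------------------------------------------------------

#' Avogadro constant (mol^-1)
#' @export
N_AVOGADRO <- 6.02214076e23

# stochastic rate prefactor for a volume (or volume-participating surface)
# reaction of the given order in an element of volume v_m3
.stoch_cfac <- function(kcst, order, v_m3) {
  v_l <- v_m3 * 1e3   # litres
  switch(as.character(order),
         "0" = kcst * N_AVOGADRO * v_l,
         "1" = kcst,
         "2" = kcst / (N_AVOGADRO * v_l),
         stop("unsupported reaction order: ", order))
}

#' Propensity of a volume reaction
#'
#' Mass-action propensity (events/s) of one reaction rule in a single
#' well-mixed element: order 0 `k NA V`; order 1 `k n`; order 2
#' `k/(NA V) nA nB` (hetero) or `k/(NA V) n (n-1)` (homo), with `V` the
#' element volume in litres and `k` in molar units.
#'
#' @param rule A [reaction()].
#' @param counts Named vector of molecule counts (names = species ids).
#' @param volume Element volume in m^3 (> 0).
#' @return Propensity in events/s.
#' @export
reaction_propensity <- function(rule, counts, volume) {
  if (volume <= 0) stop("volume must be positive")
  a <- .stoch_cfac(rule$kcst, rule$order, volume)
  for (sp in names(rule$reactants)) {
    n <- if (sp %in% names(counts)) counts[[sp]] else 0
    m <- rule$reactants[[sp]]
    for (q in seq_len(m) - 1) a <- a * (n - q)
  }
  max(a, 0)
}

# per-molecule hop rate i -> j; lface = local face of i shared with j
.diffusion_rate_factor <- function(mesh, D, i, lface,
                                   diffusion_h = "projected") {
  fv <- mesh$tets[i, .LOCAL_FACES[lface, ]]
  A <- .tri_areas(mesh$vertices, matrix(fv, ncol = 3L))
  j <- mesh$tet_neighbors[i, lface]
  dvec <- mesh$tet_barycenters[j, ] - mesh$tet_barycenters[i, ]
  if (diffusion_h == "euclidean") {
    h <- sqrt(sum(dvec^2))
  } else {
    aa <- mesh$vertices[fv[1], ]
    u <- mesh$vertices[fv[2], ] - aa
    v <- mesh$vertices[fv[3], ] - aa
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    h <- abs(sum(dvec * n)) / sqrt(sum(n^2))
  }
  D * A / (mesh$tet_volumes[i] * h)
}

#' Propensity of one diffusion channel
#'
#' Rate (events/s) of molecules hopping from tet `i` to its face-neighbor
#' `j`: `n_i * D * A_ij / (V_i * h_ij)`, with `h_ij` the barycenter
#' distance projected onto the shared-face normal (default) or the plain
#' Euclidean barycenter distance.
#'
#' @param mesh A `tetmesh`.
#' @param D Diffusion coefficient (m^2/s).
#' @param i,j Internal ids of two face-adjacent tets.
#' @param n_i Molecule count in tet `i`.
#' @param diffusion_h `"projected"` (default) or `"euclidean"`.
#' @return Propensity in events/s.
#' @export
diffusion_propensity <- function(mesh, D, i, j, n_i,
                                 diffusion_h = c("projected", "euclidean")) {
  diffusion_h <- match.arg(diffusion_h)
  lface <- which(mesh$tet_neighbors[i, ] == j)
  if (!length(lface)) stop("tets ", i, " and ", j, " are not face-adjacent")
  .diffusion_rate_factor(mesh, D, i, lface, diffusion_h) * n_i
}

# ---- solver construction --------------------------------------------------

# entity id (0-based) for element-global index (tet 1..ntet, tri ntet+1..)
.ent0 <- function(elem_global, spec_idx, nspec) {
  (elem_global - 1L) * nspec + (spec_idx - 1L)
}

.resolve_spec <- function(state_or_species, id) {
  i <- match(id, state_or_species)
  if (anyNA(i)) stop("unknown species: ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Build the spatial stochastic solver
#'
#' Instantiates every event channel implied by the model-geometry
#' association: one reaction channel per (tet, volume reaction), one
#' diffusion channel per (tet, same-compartment face neighbor, diffusion
#' rule), one surface-reaction channel per (patch triangle, surface
#' reaction), and one surface-diffusion channel per (patch triangle,
#' edge-adjacent patch triangle, rule). All counts start at zero.
#'
#' @param model A `bio_model`.
#' @param mesh A `tetmesh` whose compartments/patches reference systems of
#'   `model`.
#' @param seed Integer seed of the simulation's random stream.
#' @param diffusion_h Distance used in the inter-tet hop rate:
#'   `"projected"` (barycenter distance projected on the face normal; the
#'   consistent two-point flux on non-orthogonal meshes, default) or
#'   `"euclidean"`.
#' @return A `sim_state` (reference semantics: stepping functions modify it
#'   in place).
#' @export
build_solver <- function(model, mesh, seed = 1L,
                         diffusion_h = c("projected", "euclidean")) {
  diffusion_h <- match.arg(diffusion_h)
  stopifnot(inherits(model, "bio_model"), inherits(mesh, "tetmesh"))
  species <- model$species
  nspec <- length(species)
  ntet <- nrow(mesh$tets); ntri <- nrow(mesh$tris)

  cf <- list(); rentl <- list(); rstol <- list(); rnl <- list()
  dentl <- list(); ddell <- list(); dnl <- list(); kindl <- list()
  locl <- list()
  push <- function(kind, cfac, rent, rsto, rn, dent, ddel, dn, loc) {
    k <- length(cf) + 1L
    cf[[k]] <<- cfac; rentl[[k]] <<- rent; rstol[[k]] <<- rsto
    rnl[[k]] <<- rn; dentl[[k]] <<- dent; ddell[[k]] <<- ddel
    dnl[[k]] <<- dn; kindl[[k]] <<- rep(kind, length(cfac))
    locl[[k]] <<- as.integer(loc)
  }

  for (comp in mesh$compartments) {
    tets <- comp$tet_indices
    vols <- mesh$tet_volumes[tets]
    for (vsid in comp$volume_system_ids) {
      vsys <- model$volume_systems[[vsid]]
      if (is.null(vsys))
        stop("compartment '", comp$name, "' references unknown volume system '",
             vsid, "'")
      for (r in vsys$reactions) {
        m <- length(tets)
        net <- .net_stoich(r$reactants, r$products)
        rsp <- .resolve_spec(species, names(r$reactants))
        nsp <- .resolve_spec(species, names(net))
        nr <- length(rsp); nd <- length(nsp)
        push("reaction",
             cfac = vapply(vols, function(v)
               .stoch_cfac(r$kcst, r$order, v), 0.0),
             rent = .ent0(rep(tets, each = nr), rep(rsp, m), nspec),
             rsto = rep(as.integer(r$reactants), m),
             rn = rep(nr, m),
             dent = .ent0(rep(tets, each = nd), rep(nsp, m), nspec),
             ddel = rep(as.integer(net), m),
             dn = rep(nd, m),
             loc = tets)
      }
      diff_rules <- vsys$diffusion
      if (length(diff_rules)) {
        in_comp <- logical(ntet); in_comp[tets] <- TRUE
        # all directed adjacent pairs inside the compartment
        src <- rep(tets, times = 4L)
        lf <- rep(1:4, each = length(tets))
        dst <- mesh$tet_neighbors[cbind(src, lf)]
        ok <- !is.na(dst) & in_comp[ifelse(is.na(dst), 1L, dst)]
        src <- src[ok]; lf <- lf[ok]; dst <- dst[ok]
        fv <- cbind(mesh$tets[cbind(src, .LOCAL_FACES[lf, 1])],
                    mesh$tets[cbind(src, .LOCAL_FACES[lf, 2])],
                    mesh$tets[cbind(src, .LOCAL_FACES[lf, 3])])
        A <- .tri_areas(mesh$vertices, fv)
        dvec <- mesh$tet_barycenters[dst, , drop = FALSE] -
          mesh$tet_barycenters[src, , drop = FALSE]
        if (diffusion_h == "euclidean") {
          h <- sqrt(rowSums(dvec^2))
        } else {
          # barycenter distance projected on the face normal (two-point
          # flux with non-orthogonality correction)
          aa <- mesh$vertices[fv[, 1], , drop = FALSE]
          e1 <- mesh$vertices[fv[, 2], , drop = FALSE] - aa
          e2 <- mesh$vertices[fv[, 3], , drop = FALSE] - aa
          nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
          ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
          nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
          nn <- sqrt(nx^2 + ny^2 + nz^2)
          h <- abs(dvec[, 1] * nx + dvec[, 2] * ny + dvec[, 3] * nz) / nn
        }
        for (d in diff_rules) {
          si <- .resolve_spec(species, d$species)
          m <- length(src)
          push("diffusion",
               cfac = d$D * A / (mesh$tet_volumes[src] * h),
               rent = .ent0(src, rep(si, m), nspec),
               rsto = rep(1L, m),
               rn = rep(1L, m),
               dent = as.vector(rbind(.ent0(src, rep(si, m), nspec),
                                      .ent0(dst, rep(si, m), nspec))),
               ddel = rep(c(-1L, 1L), m),
               dn = rep(2L, m),
               loc = src)
        }
      }
    }
  }

  for (patch in mesh$patches) {
    tris <- patch$tri_indices
    inner_tet <- patch$inner_tet
    outer_tet <- patch$outer_tet
    for (ssid in patch$surface_system_ids) {
      ssys <- model$surface_systems[[ssid]]
      if (is.null(ssys))
        stop("patch '", patch$name, "' references unknown surface system '",
             ssid, "'")
      for (r in ssys$reactions) {
        uses_outer <- length(r$reactants$outer) || length(r$products$outer)
        if (uses_outer && anyNA(outer_tet))
          stop("surface reaction '", r$id,
               "' references the outer volume but patch '", patch$name,
               "' has no outer compartment")
        m <- length(tris)
        glob <- list(surface = ntet + tris, inner = inner_tet,
                     outer = outer_tet)
        # reactant slots
        rsp <- integer(0); rst <- integer(0); rel <- NULL
        for (loc in c("surface", "inner", "outer")) {
          st <- r$reactants[[loc]]
          if (!length(st)) next
          ids <- .resolve_spec(species, names(st))
          for (q in seq_along(ids)) {
            rsp <- c(rsp, ids[q]); rst <- c(rst, as.integer(st[q]))
            rel <- cbind(rel, glob[[loc]])
          }
        }
        # net deltas per (location, species)
        dsp <- integer(0); ddl <- integer(0); del <- NULL
        for (loc in c("surface", "inner", "outer")) {
          net <- .net_stoich(r$reactants[[loc]], r$products[[loc]])
          if (!length(net)) next
          ids <- .resolve_spec(species, names(net))
          for (q in seq_along(ids)) {
            dsp <- c(dsp, ids[q]); ddl <- c(ddl, as.integer(net[q]))
            del <- cbind(del, glob[[loc]])
          }
        }
        # volume used for the unit conversion: first volume participant's
        # tet, else the inner tet
        vloc <- c(if (length(r$reactants$inner)) "inner",
                  if (length(r$reactants$outer)) "outer", "inner")[1]
        vref <- glob[[vloc]]
        cvol <- mesh$tet_volumes[vref]
        nr <- length(rsp); nd <- length(dsp)
        push("surface_reaction",
             cfac = vapply(cvol, function(v)
               .stoch_cfac(r$kcst, r$order, v), 0.0),
             rent = if (nr) .ent0(as.vector(t(rel)),
                                  rep(rsp, m), nspec) else integer(0),
             rsto = rep(rst, m),
             rn = rep(nr, m),
             dent = if (nd) .ent0(as.vector(t(del)),
                                  rep(dsp, m), nspec) else integer(0),
             ddel = rep(ddl, m),
             dn = rep(nd, m),
             loc = ntet + tris)
      }
      if (length(ssys$diffusion)) {
        adj <- .patch_tri_adjacency(mesh, tris)
        for (d in ssys$diffusion) {
          si <- .resolve_spec(species, d$species)
          m <- nrow(adj)
          if (!m) next
          push("surface_diffusion",
               cfac = d$D * adj$edge_len /
                 (mesh$tri_areas[adj$from] * adj$dist),
               rent = .ent0(ntet + adj$from, rep(si, m), nspec),
               rsto = rep(1L, m),
               rn = rep(1L, m),
               dent = as.vector(rbind(
                 .ent0(ntet + adj$from, rep(si, m), nspec),
                 .ent0(ntet + adj$to, rep(si, m), nspec))),
               ddel = rep(c(-1L, 1L), m),
               dn = rep(2L, m),
               loc = ntet + adj$from)
        }
      }
    }
  }

  cfac <- unlist(cf, use.names = FALSE) %||% numeric(0)
  rn <- as.integer(unlist(rnl, use.names = FALSE) %||% integer(0))
  dn <- as.integer(unlist(dnl, use.names = FALSE) %||% integer(0))
  rptr <- c(0L, cumsum(rn))
  dptr <- c(0L, cumsum(dn))
  ptr <- solver_new(
    n_entities = (ntet + ntri) * nspec,
    cfac = as.numeric(cfac),
    rptr = rptr,
    rent = as.integer(unlist(rentl, use.names = FALSE) %||% integer(0)),
    rsto = as.integer(unlist(rstol, use.names = FALSE) %||% integer(0)),
    dptr = dptr,
    dent = as.integer(unlist(dentl, use.names = FALSE) %||% integer(0)),
    ddel = as.integer(unlist(ddell, use.names = FALSE) %||% integer(0)),
    group = as.integer(unlist(locl, use.names = FALSE) %||% integer(0)) - 1L,
    seed = as.numeric(seed))

  structure(list(ptr = ptr, model = model, mesh = mesh,
                 species = species, nspec = nspec,
                 ntet = ntet, ntri = ntri,
                 channel_kind = unlist(kindl, use.names = FALSE) %||%
                   character(0),
                 seed = as.integer(seed)),
            class = "sim_state")
}

.net_stoich <- function(reactants, products) {
  sp <- union(names(reactants), names(products))
  net <- stats::setNames(numeric(length(sp)), sp)
  if (length(reactants)) net[names(reactants)] <-
    net[names(reactants)] - reactants
  if (length(products)) net[names(products)] <-
    net[names(products)] + products
  net[net != 0]
}

# edge adjacency between patch triangles: data.frame(from, to, edge_len, dist)
.patch_tri_adjacency <- function(mesh, tris) {
  tv <- mesh$tris[tris, , drop = FALSE]
  m <- nrow(tv)
  e1 <- cbind(tv[, 1], tv[, 2]); e2 <- cbind(tv[, 2], tv[, 3])
  e3 <- cbind(tv[, 1], tv[, 3])
  ed <- rbind(e1, e2, e3)
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  owner <- rep(tris, times = 3L)
  dt <- data.table(a = ed[, 1], b = ed[, 2], tri = owner)
  dt <- dt[, if (.N == 2L) list(t1 = tri[1L], t2 = tri[2L]),
           by = c("a", "b")]
  if (!nrow(dt))
    return(data.frame(from = integer(0), to = integer(0),
                      edge_len = numeric(0), dist = numeric(0)))
  elen <- sqrt(rowSums((mesh$vertices[dt$a, , drop = FALSE] -
                        mesh$vertices[dt$b, , drop = FALSE])^2))
  dd <- sqrt(rowSums((mesh$tri_barycenters[dt$t1, , drop = FALSE] -
                      mesh$tri_barycenters[dt$t2, , drop = FALSE])^2))
  data.frame(from = c(dt$t1, dt$t2), to = c(dt$t2, dt$t1),
             edge_len = c(elen, elen), dist = c(dd, dd))
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %.6g s, %d channels, a0 = %.6g /s\n",
              solver_time(x$ptr), length(x$channel_kind), solver_a0(x$ptr)))
  invisible(x)
}

# ---- state manipulation and queries ---------------------------------------

#' Reset a solver to time zero with a new seed
#' @param state A `sim_state`.
#' @param seed New RNG seed.
#' @return The state, invisibly (modified in place).
#' @export
reset_state <- function(state, seed) {
  solver_reset(state$ptr, as.numeric(seed))
  invisible(state)
}

#' Set the molecule count of one element
#' @param state A `sim_state`.
#' @param element Internal tet id (or tri id with `kind = "tri"`).
#' @param species Species id.
#' @param n New count (>= 0).
#' @param kind `"tet"` or `"tri"`.
#' @return The state, invisibly.
#' @export
set_count <- function(state, element, species, n, kind = c("tet", "tri")) {
  kind <- match.arg(kind)
  glob <- if (kind == "tet") element else state$ntet + element
  si <- .resolve_spec(state$species, species)
  solver_set_counts(state$ptr, .ent0(glob, si, state$nspec), n)
  invisible(state)
}

#' Inject molecules into a tetrahedral ROI
#'
#' Distributes `N` molecules over the ROI's tets multinomially with
#' probabilities proportional to tet volumes, then refreshes the affected
#' propensities.
#'
#' @param state A `sim_state`.
#' @param roi ROI name (on the state's mesh) or an ROI record.
#' @param species Species id.
#' @param N Number of molecules (>= 0).
#' @return The state, invisibly.
#' @export
inject_into_roi <- function(state, roi, species, N) {
  if (is.character(roi)) roi <- get_roi(state$mesh, roi)
  if (roi$element_class != "tetrahedron")
    stop("injection requires a tetrahedral ROI")
  if (!length(roi$indices)) stop("injection into empty ROI")
  if (N < 0) stop("N must be >= 0")
  si <- .resolve_spec(state$species, species)
  ents <- .ent0(roi$indices, si, state$nspec)
  solver_inject_multinomial(state$ptr, ents,
                            state$mesh$tet_volumes[roi$indices],
                            as.integer(N))
  invisible(state)
}

#' Distribute molecules over a patch's triangles
#'
#' Places `N` copies of a surface species multinomially over the patch
#' triangles with probabilities proportional to triangle areas (used e.g.
#' to seed channel copies on a membrane).
#'
#' @param state A `sim_state`.
#' @param patch Patch name.
#' @param species Surface species id.
#' @param N Number of copies (>= 0).
#' @return The state, invisibly.
#' @export
inject_onto_patch <- function(state, patch, species, N) {
  p <- state$mesh$patches[[patch]]
  if (is.null(p)) stop("no patch named '", patch, "'")
  si <- .resolve_spec(state$species, species)
  ents <- .ent0(state$ntet + p$tri_indices, si, state$nspec)
  solver_inject_multinomial(state$ptr, ents,
                            state$mesh$tri_areas[p$tri_indices],
                            as.integer(N))
  invisible(state)
}

# resolve a scope to list(kind = "tet"/"tri", elems = internal ids)
.resolve_scope <- function(state, scope) {
  mesh <- state$mesh
  if (is.character(scope) && length(scope) == 1L) {
    if (scope %in% names(mesh$compartments))
      return(list(kind = "tet",
                  elems = mesh$compartments[[scope]]$tet_indices))
    if (scope %in% names(mesh$patches))
      return(list(kind = "tri", elems = mesh$patches[[scope]]$tri_indices))
    if (scope %in% names(mesh$rois)) {
      roi <- mesh$rois[[scope]]
      return(list(kind = if (roi$element_class == "tetrahedron") "tet"
                  else "tri",
                  elems = roi$indices))
    }
    stop("unknown scope: '", scope, "'")
  }
  if (is.list(scope) && !is.null(scope$kind)) return(scope)
  stop("scope must be a compartment/patch/ROI name or scope_tet()/scope_tri()")
}

#' Single-element scopes for count/concentration queries
#' @param id Internal element id(s).
#' @return A scope usable in [sim_count()] / [sim_conc()].
#' @export
scope_tet <- function(id) list(kind = "tet", elems = as.integer(id))

#' @rdname scope_tet
#' @export
scope_tri <- function(id) list(kind = "tri", elems = as.integer(id))

#' Total molecule count in a scope
#'
#' @param state A `sim_state`.
#' @param scope Compartment, patch or ROI name, or [scope_tet()]/
#'   [scope_tri()].
#' @param species Species id(s); default all species.
#' @return Named vector of counts per species.
#' @export
sim_count <- function(state, scope, species = NULL) {
  sc <- .resolve_scope(state, scope)
  if (is.null(species)) species <- state$species
  si <- .resolve_spec(state$species, species)
  cts <- solver_counts(state$ptr)
  glob <- if (sc$kind == "tet") sc$elems else state$ntet + sc$elems
  out <- vapply(si, function(s) sum(cts[.ent0(glob, s, state$nspec) + 1L]),
                0.0)
  stats::setNames(out, species)
}

#' Per-element molecule counts in a scope
#' @inheritParams sim_count
#' @param species One species id.
#' @return Numeric vector of counts, one per scope element.
#' @export
element_counts <- function(state, scope, species) {
  sc <- .resolve_scope(state, scope)
  si <- .resolve_spec(state$species, species)
  cts <- solver_counts(state$ptr)
  glob <- if (sc$kind == "tet") sc$elems else state$ntet + sc$elems
  cts[.ent0(glob, si, state$nspec) + 1L]
}

#' Concentration in a volume scope
#'
#' `count / (NA * V)` converted to molar (mol/L); the scope must resolve to
#' tetrahedra.
#'
#' @inheritParams sim_count
#' @return Named vector of molar concentrations per species.
#' @export
sim_conc <- function(state, scope, species = NULL) {
  sc <- .resolve_scope(state, scope)
  if (sc$kind != "tet") stop("concentration requires a volume (tet) scope")
  v_l <- sum(state$mesh$tet_volumes[sc$elems]) * 1e3
  sim_count(state, sc, species) / (N_AVOGADRO * v_l)
}

#' Current simulation time (s)
#' @param state A `sim_state`.
#' @export
sim_time <- function(state) solver_time(state$ptr)

# ---- advancing ------------------------------------------------------------

#' Execute a single SSA event
#' @param state A `sim_state`.
#' @return The state, invisibly; `sim_time()` is unchanged if no channel
#'   was active.
#' @export
step <- function(state) {
  solver_step(state$ptr)
  invisible(state)
}

#' Advance the simulation to an absolute time
#'
#' Executes events with the direct method until the next event would pass
#' `t_end`; the state time is then set to exactly `t_end`. With zero total
#' propensity the call returns immediately with `sim_time(state) == t_end`.
#'
#' @param state A `sim_state`.
#' @param t_end Absolute end time (s).
#' @return The state, invisibly.
#' @export
run_until <- function(state, t_end) {
  solver_run(state$ptr, t_end)
  invisible(state)
}

.checkpoint_times <- function(t0, t_end, dt_update) {
  if (dt_update <= 0) stop("dt_update must be positive")
  k <- floor(t_end / dt_update + 1e-9)
  times <- dt_update * seq(0L, k)
  times[times >= t0 - 1e-15]
}

#' Run with synchronized checkpoints
#'
#' Advances the state, invoking `callback(state, time)` at every multiple of
#' `dt_update` in `[sim_time(state), t_end]`. Callbacks observe the state
#' strictly before the first event whose occurrence time exceeds the
#' checkpoint.
#'
#' @param state A `sim_state`.
#' @param t_end End time (s).
#' @param dt_update Checkpoint interval (s).
#' @param callback Function `(state, time)`; its return values are
#'   collected.
#' @return List with `times` and `values` (one callback result per
#'   checkpoint), invisibly.
#' @export
run_with_checkpoints <- function(state, t_end, dt_update, callback) {
  times <- .checkpoint_times(sim_time(state), t_end, dt_update)
  values <- vector("list", length(times))
  for (i in seq_along(times)) {
    run_until(state, times[i])
    values[[i]] <- callback(state, times[i])
  }
  invisible(list(times = times, values = values))
}

#' Synchronized execution of multiple simulations
#'
#' Each simulation advances independently but is recorded at identical
#' checkpoint times, so the records of all simulations align by checkpoint
#' index (the shared end time / update interval of a simulation control).
#'
#' @param sims List of `sim_state`s.
#' @param t_end Shared end time (s).
#' @param dt_update Shared update interval (s).
#' @param recorder Function `(state, time)` returning a (named) numeric
#'   vector.
#' @return List with `times` and `records`: one matrix per simulation
#'   (rows = checkpoints).
#' @export
sync_run <- function(sims, t_end, dt_update, recorder) {
  stopifnot(length(sims) >= 1L)
  times <- .checkpoint_times(min(vapply(sims, sim_time, 0.0)), t_end,
                             dt_update)
  records <- lapply(sims, function(s) {
    rows <- lapply(seq_along(times), function(i) {
      run_until(s, times[i])
      recorder(s, times[i])
    })
    do.call(rbind, rows)
  })
  list(times = times, records = records)
}

#' Channel propensities of the solver
#'
#' With `rebuild = TRUE` the full table is recomputed from counts and
#' geometry (independently of the incremental updates maintained during
#' stepping), which is useful for consistency checking.
#'
#' @param state A `sim_state`.
#' @param rebuild Recompute from scratch instead of returning the
#'   incrementally maintained table.
#' @return Numeric vector of propensities (events/s) per channel.
#' @export
propensities <- function(state, rebuild = FALSE) {
  solver_propensities(state$ptr, rebuild)
}

#' Total propensity (events/s)
#' @param state A `sim_state`.
#' @export
total_propensity <- function(state) solver_a0(state$ptr)
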