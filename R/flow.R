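# One-dimensional Poiseuille network haemodynamics.
#
# Steady laminar Newtonian flow on the segment graph: each perfused segment
# is a resistor with conductance G = pi r^4 / (8 mu L), node pressures solve
# the Kirchhoff conservation system, and wall shear stress follows the
# Hagen-Poiseuille closed form tau = 4 mu |Q| / (pi r^3).

#' Boundary conditions for the network flow solve
#'
#' @param inlets integer node ids held at `inlet_pressure`.
#' @param outlets integer node ids held at `outlet_pressure`.
#' @param inlet_pressure,outlet_pressure pressures in Pa;
#'   `inlet_pressure > outlet_pressure` is required.
#' @param viscosity dynamic viscosity mu in Pa s (default 3.5e-3, a Newtonian
#'   whole-blood value; only the ordinal structure of the shear field matters
#'   downstream, so no haematocrit-dependent correction is applied).
#' @return A list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlets, outlets, inlet_pressure = 60,
                                outlet_pressure = 0, viscosity = 3.5e-3) {
  if (length(inlets) < 1 || length(outlets) < 1) {
    stop_input("need at least one inlet and one outlet node")
  }
  if (!(inlet_pressure > outlet_pressure)) {
    stop_input("inlet pressure must exceed outlet pressure")
  }
  if (viscosity <= 0) stop_input("viscosity must be > 0")
  structure(list(inlets = as.integer(inlets), outlets = as.integer(outlets),
                 inlet_pressure = inlet_pressure,
                 outlet_pressure = outlet_pressure,
                 viscosity = viscosity),
            class = "boundary_conditions")
}

#' Default boundary conditions for a network
#'
#' Uses the generator's recorded inlet/outlet nodes when present; otherwise
#' infers them as degree-1 nodes whose only incident segment is an artery
#' (inlet) or vein (outlet).
#'
#' @param net a [vessel_network()].
#' @inheritParams boundary_conditions
#' @return A [boundary_conditions()] object.
#' @export
default_bc <- function(net, inlet_pressure = 60, outlet_pressure = 0,
                       viscosity = 3.5e-3) {
  inl <- net$meta$inlets; outl <- net$meta$outlets
  if (is.null(inl) || is.null(outl)) {
    deg <- node_degrees(net)
    tips <- as.integer(names(deg)[deg == 1])
    kind <- vapply(tips, function(nd) {
      s <- net$segments[net$segments$a == nd | net$segments$b == nd, ]
      s$region[1]
    }, character(1))
    inl <- tips[kind == "artery"]
    outl <- tips[kind == "vein"]
  }
  boundary_conditions(inl, outl, inlet_pressure, outlet_pressure, viscosity)
}

#' Solve steady Poiseuille flow on a vessel network
#'
#' Segments with `lumen_fraction < lumen_cutoff` are excluded from the
#' conductance matrix (non-perfused). Blind-ended side branches (trees hanging
#' off the perfused core that contain no boundary node) carry exactly zero
#' flow and are pruned before the linear solve. Connected components without
#' any boundary node are held at the outlet pressure with zero flow, with a
#' warning.
#'
#' @param net a [vessel_network()].
#' @param bc a [boundary_conditions()]; default [default_bc()].
#' @param lumen_cutoff perfusion threshold on `lumen_fraction` (default 0.5).
#' @return A `flow_solution`: list with `node_pressure` (data.frame `node`,
#'   `P` in Pa), `segments` (data.frame `segment_id`, `Q` um^3/s signed
#'   a -> b, `v` um/s, `tau` (NA until [wall_shear()]), `perfused`), and
#'   `viscosity`.
#' @export
solve_flow <- function(net, bc = default_bc(net), lumen_cutoff = 0.5) {
  segs <- net$segments
  included <- segs$lumen_fraction >= lumen_cutoff
  if (any(included & segs$mean_radius <= 0)) {
    stop_input("zero radius on a lumenized (included) segment")
  }
  node_ids <- net$nodes$id
  boundary <- unique(c(bc$inlets, bc$outlets))
  if (!all(boundary %in% node_ids)) stop_input("boundary node id not in network")

  # iteratively prune blind-ended (tip) branches: degree-1 non-boundary nodes
  act <- which(included)
  repeat {
    if (!length(act)) break
    deg <- table(factor(c(segs$a[act], segs$b[act]), levels = node_ids))
    tips <- as.integer(names(deg)[deg == 1])
    tips <- setdiff(tips, boundary)
    drop <- act[segs$a[act] %in% tips | segs$b[act] %in% tips]
    if (!length(drop)) break
    act <- setdiff(act, drop)
  }

  Q <- rep(0, nrow(segs)); P <- rep(bc$outlet_pressure, length(node_ids))
  names(P) <- node_ids
  solved_any <- FALSE
  if (length(act)) {
    G <- pi * segs$mean_radius[act]^4 / (8 * bc$viscosity * segs$length[act])
    ia <- match(segs$a[act], node_ids); ib <- match(segs$b[act], node_ids)
    used_nodes <- sort(unique(c(ia, ib)))
    # connected components over active segments
    g <- igraph::graph_from_edgelist(cbind(match(ia, used_nodes),
                                           match(ib, used_nodes)),
                                     directed = FALSE)
    comp <- igraph::components(g)$membership
    comp_of_node <- setNames(comp, used_nodes)
    bnd_idx <- match(boundary, node_ids)
    bnd_present <- bnd_idx[bnd_idx %in% used_nodes]
    comps_with_bnd <- unique(comp_of_node[as.character(bnd_present)])
    has_io_path <- FALSE
    for (cmp in comps_with_bnd) {
      nd <- as.integer(names(comp_of_node)[comp_of_node == cmp])
      if (any(match(bc$inlets, node_ids) %in% nd) &&
          any(match(bc$outlets, node_ids) %in% nd)) has_io_path <- TRUE
    }
    if (!has_io_path) {
      stop_unsolvable("no inlet-to-outlet path among perfused segments")
    }
    orphan <- setdiff(unique(comp), comps_with_bnd)
    if (length(orphan)) {
      warning("component(s) without boundary node held at outlet pressure with Q = 0")
    }
    solve_nodes <- used_nodes[comp_of_node[as.character(used_nodes)] %in% comps_with_bnd]
    dir_idx <- match(c(match(bc$inlets, node_ids), match(bc$outlets, node_ids)),
                     solve_nodes)
    dirichlet <- solve_nodes[dir_idx[!is.na(dir_idx)]]
    dir_val <- setNames(rep(c(bc$inlet_pressure, bc$outlet_pressure),
                            c(length(bc$inlets), length(bc$outlets))),
                        c(match(bc$inlets, node_ids), match(bc$outlets, node_ids)))
    unknown <- setdiff(solve_nodes, dirichlet)
    pos <- rep(NA_integer_, length(node_ids))
    pos[unknown] <- seq_along(unknown)
    Pfull <- rep(NA_real_, length(node_ids))
    Pfull[dirichlet] <- dir_val[as.character(dirichlet)]
    keep <- ia %in% solve_nodes  # segment lies in a boundary component
    if (length(unknown)) {
      pa <- pos[ia]; pb <- pos[ib]
      ka <- keep & !is.na(pa); kb <- keep & !is.na(pb)
      both <- ka & kb
      trip_i <- c(pa[ka], pb[kb], pa[both], pb[both])
      trip_j <- c(pa[ka], pb[kb], pb[both], pa[both])
      trip_x <- c(G[ka], G[kb], -G[both], -G[both])
      rhs <- numeric(length(unknown))
      add_rhs <- function(idx, val) {
        if (length(idx)) {
          t <- tapply(val, idx, sum)
          rhs[as.integer(names(t))] <<- rhs[as.integer(names(t))] + as.numeric(t)
        }
      }
      sa <- ka & !kb  # a unknown, b Dirichlet
      sb <- kb & !ka
      add_rhs(pa[sa], G[sa] * Pfull[ib[sa]])
      add_rhs(pb[sb], G[sb] * Pfull[ia[sb]])
      L <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                dims = c(length(unknown), length(unknown)))
      Pfull[unknown] <- as.numeric(Matrix::solve(L, rhs))
    }
    # orphan components: outlet pressure
    Pfull[is.na(Pfull)] <- bc$outlet_pressure
    P[] <- Pfull
    Q[act[keep]] <- G[keep] * (P[ia[keep]] - P[ib[keep]])
    solved_any <- TRUE
  } else {
    stop_unsolvable("no perfused segments to solve")
  }
  v <- ifelse(segs$mean_radius > 0, Q / (pi * segs$mean_radius^2), 0)
  perfused <- logical(nrow(segs)); perfused[act] <- TRUE
  structure(list(
    node_pressure = data.frame(node = node_ids, P = unname(P)),
    segments = data.frame(segment_id = segs$id, Q = Q, v = v,
                          tau = NA_real_, perfused = perfused),
    viscosity = bc$viscosity),
    class = "flow_solution")
}

#' Wall shear stress and oriented flow directions
#'
#' Adds per-segment wall shear stress `tau = 4 mu |Q| / (pi r^3)` (Pa) and
#' per-vertex oriented unit flow-direction vectors (polyline tangents flipped
#' where `Q < 0`). Segments with `Q = 0` get `tau = 0` and flagged
#' (all-`NA`) directions.
#'
#' @param net the [vessel_network()] that was solved.
#' @param flow the [solve_flow()] result.
#' @return The `flow_solution` with `tau` filled and a `flow_dir` list (one
#'   n x 2 matrix per segment, `NA` where undefined).
#' @export
wall_shear <- function(net, flow) {
  segs <- net$segments
  stopifnot(nrow(segs) == nrow(flow$segments))
  r <- segs$mean_radius
  Q <- flow$segments$Q
  flow$segments$tau <- ifelse(r > 0, 4 * flow$viscosity * abs(Q) / (pi * r^3), 0)
  flow$flow_dir <- lapply(seq_len(nrow(segs)), function(i) {
    tg <- polyline_tangents(net$geometry[[i]])
    if (Q[i] == 0) {
      tg[] <- NA_real_
    } else if (Q[i] < 0) {
      tg <- -tg
    }
    tg
  })
  flow
}

#' Convenience wrapper: solve flow and wall shear in one call
#'
#' @inheritParams solve_flow
#' @return A `flow_solution` with shear and flow directions filled.
#' @export
solve_haemodynamics <- function(net, bc = default_bc(net), lumen_cutoff = 0.5) {
  wall_shear(net, solve_flow(net, bc, lumen_cutoff))
}

#' Classify segments into low- and high-shear groups
#'
#' Labels perfused segments strictly below the `low_q` quantile of the wall
#' shear stress distribution as `"low"`, the rest `"high"` (ties therefore
#' fall into `"high"`; with all-equal `tau` every segment is `"high"`).
#'
#' @param net a [vessel_network()].
#' @param flow a [wall_shear()] solution.
#' @param low_q quantile cut (default 0.25).
#' @return data.frame `segment_id`, `tau`, `label` over perfused segments.
#' @export
classify_flow <- function(net, flow, low_q = 0.25) {
  fs <- flow$segments[flow$segments$perfused, ]
  if (nrow(fs) < 4) stop_input("classification refused: fewer than 4 perfused segments")
  if (any(is.na(fs$tau))) stop_precondition("wall shear not computed; run wall_shear()")
  thr <- quantile(fs$tau, low_q, names = FALSE)
  data.frame(segment_id = fs$segment_id, tau = fs$tau,
             label = ifelse(fs$tau < thr, "low", "high"))
}
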