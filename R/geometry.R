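#' @importFrom stats setNames rnorm
NULL

.region_names <- c("R1", "R2", "R3", "R4", "R5", "R6",
                   "R7", "R8", "R9", "R10")

new_surface_mesh <- function(vertices, faces, region = NULL, pv = NULL,
                             landmarks = NULL) {
  storage.mode(faces) <- "integer"
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n))
    stop("faces index nodes outside the mesh", call. = FALSE)
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3]))
    stop("degenerate face with repeated vertices", call. = FALSE)
  m <- structure(list(
    vertices = vertices, faces = faces,
    region = if (is.null(region)) integer(n) else as.integer(region),
    pv = if (is.null(pv)) integer(n) else as.integer(pv),
    landmarks = landmarks), class = "surface_mesh")
  m$area <- node_areas(m)
  m$boundary <- boundary_nodes(m)
  m
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# barycentric lumping: one third of each incident triangle
node_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  n <- nrow(mesh$vertices)
  as.numeric(tapply(rep(ta / 3, 3), factor(as.vector(mesh$faces),
                                           levels = seq_len(n)), sum,
                    default = 0))
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

boundary_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  e[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

boundary_nodes <- function(mesh) {
  b <- logical(nrow(mesh$vertices))
  be <- boundary_edges(mesh)
  b[unique(as.vector(be))] <- TRUE
  b
}

#' Mesh topology summary
#'
#' Vertex, edge, face counts, Euler characteristic and the number of
#' boundary loops (orifices).
#'
#' @param mesh a `surface_mesh`.
#' @return list with `V`, `E`, `F`, `chi`, `boundary_loops`.
#' @export
mesh_topology <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  be <- boundary_edges(mesh)
  loops <- 0L
  if (nrow(be) > 0) loops <- length(.boundary_loops(be))
  list(V = nrow(mesh$vertices), E = nrow(e), F = nrow(mesh$faces),
       chi = nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces),
       boundary_loops = loops)
}

#' Minimum interior angle over all triangles (degrees)
#' @param mesh a `surface_mesh`.
#' @export
mesh_min_angle <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ang <- function(p, q, r) {
    u <- v[q, , drop = FALSE] - v[p, , drop = FALSE]
    w <- v[r, , drop = FALSE] - v[p, , drop = FALSE]
    cosang <- rowSums(u * w) /
      sqrt(rowSums(u * u) * rowSums(w * w))
    acos(pmin(1, pmax(-1, cosang)))
  }
  a1 <- ang(f[, 1], f[, 2], f[, 3])
  a2 <- ang(f[, 2], f[, 3], f[, 1])
  a3 <- ang(f[, 3], f[, 1], f[, 2])
  min(c(a1, a2, a3)) * 180 / pi
}

#' Planar triangulated sheet
#'
#' Right-triangulated rectangular sheet in the z = 0 plane, `nx` by `ny`
#' nodes spaced `dx` mm apart. Used for conduction-velocity calibration and
#' solver verification.
#'
#' @param nx,ny node counts (>= 2).
#' @param dx node spacing (mm).
#' @return a `surface_mesh` with all nodes unlabeled.
#' @export
make_sheet <- function(nx, ny, dx = 0.25) {
  stopifnot(nx >= 2, ny >= 2, dx > 0)
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  f <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
             cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  new_surface_mesh(v, f)
}

#' One-dimensional cable (degenerate two-row sheet)
#' @param n node count along the cable.
#' @param dx node spacing (mm).
#' @export
make_cable <- function(n, dx = 0.25) make_sheet(n, 2, dx)

# icosphere: subdivided icosahedron, unit radius
.icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    ek <- new.env(parent = emptyenv())
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- ek[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1]] <<- matrix(p, 1)
      nv <<- nv + 1L
      ek[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Parameters of the synthetic left-atrial surface
#'
#' The generator emulates a CT-derived left atrium: a triangulated ellipsoid
#' shell with four pulmonary-vein ostia (extruded as short tubes), an open
#' mitral annulus, an appendage protrusion, and seeded random surface
#' jitter. Defaults size the anteroposterior extent to ~48 mm, matching the
#' mean LA dimension of persistent-AF patients.
#'
#' @param semi_axes ellipsoid semi-axes (mm), c(posterior-anterior,
#'   left-right, superior-inferior) before deformation.
#' @param pv_radius pulmonary-vein ostium radius (mm).
#' @param pv_length pulmonary-vein tube length (mm).
#' @param mitral_radius mitral annulus radius (mm).
#' @param appendage_amp appendage bump amplitude (mm).
#' @param subdivisions icosphere subdivision level (4 gives ~2500 base
#'   nodes, ~2 mm edges at the default scale).
#' @param jitter random surface jitter amplitude (mm).
#' @param seed integer seed fixing the mesh bit-for-bit.
#' @return a `synthetic_la_params` list.
#' @export
synthetic_la_params <- function(semi_axes = c(38, 31, 24), pv_radius = 6.5,
                                pv_length = 8, mitral_radius = 15,
                                appendage_amp = 9, subdivisions = 4,
                                jitter = 1.0, quality_repair = FALSE,
                                seed = 1) {
  stopifnot(all(semi_axes > 0), pv_radius > 0, pv_length > 0,
            mitral_radius > 0, appendage_amp > 0, jitter >= 0)
  structure(list(semi_axes = semi_axes, pv_radius = pv_radius,
                 pv_length = pv_length, mitral_radius = mitral_radius,
                 appendage_amp = appendage_amp, subdivisions = subdivisions,
                 jitter = jitter, quality_repair = isTRUE(quality_repair),
                 seed = as.integer(seed)),
            class = "synthetic_la_params")
}

# orifice directions on the unit sphere (x: posterior, y: left, z: superior)
.la_dirs <- function() {
  norm1 <- function(x) x / sqrt(sum(x^2))
  list(
    lspv = norm1(c(0.60, 0.62, 0.50)),   # left superior PV  -> R7
    lipv = norm1(c(0.74, 0.62, -0.26)),  # left inferior PV  -> R8
    rspv = norm1(c(0.60, -0.62, 0.50)),  # right superior PV -> R9
    ripv = norm1(c(0.74, -0.62, -0.26)), # right inferior PV -> R10
    mitral = norm1(c(-0.38, -0.18, -0.90)),
    appendage = norm1(c(-0.52, 0.76, 0.39)),
    septum = norm1(c(-0.25, -0.95, 0.18)),
    anterior = norm1(c(-0.97, 0.18, 0.18)),
    posterior = norm1(c(0.95, 0.05, 0.30)),
    post_inferior = norm1(c(0.80, 0.10, -0.59)))
}

#' Synthetic left-atrium-like surface mesh
#'
#' Generates a closed, orientable LA-like triangulated surface with exactly
#' five boundary loops (four pulmonary-vein ostia and the mitral annulus)
#' and an appendage protrusion, deterministic per seed. Pulmonary-vein tube
#' nodes are pre-tagged with their region (R7-R10); six landmark nodes for
#' the R1-R6 wall sections are stored for [partition_regions()].
#'
#' @param params a [synthetic_la_params()] object.
#' @return a `surface_mesh`.
#' @export
make_synthetic_la <- function(params = synthetic_la_params()) {
  stopifnot(inherits(params, "synthetic_la_params"))
  dirs <- .la_dirs()
  ico <- .icosphere(params$subdivisions)
  u <- ico$vertices          # unit sphere positions
  f <- ico$faces
  ax <- params$semi_axes
  # local surface radius along a unit direction
  rad_at <- function(d) 1 / sqrt(sum((d / ax)^2))

  # cut holes: drop faces whose vertices all lie inside an orifice cap
  hole_specs <- list(
    list(dir = dirs$lspv, r = params$pv_radius, pv = 7L),
    list(dir = dirs$lipv, r = params$pv_radius, pv = 8L),
    list(dir = dirs$rspv, r = params$pv_radius, pv = 9L),
    list(dir = dirs$ripv, r = params$pv_radius, pv = 10L),
    list(dir = dirs$mitral, r = params$mitral_radius, pv = 0L))
  inside_any <- matrix(FALSE, nrow(u), length(hole_specs))
  for (k in seq_along(hole_specs)) {
    hs <- hole_specs[[k]]
    theta <- hs$r / rad_at(hs$dir)
    inside_any[, k] <- (u %*% hs$dir)[, 1] > cos(theta)
  }
  drop_face <- rep(FALSE, nrow(f))
  for (k in seq_along(hole_specs))
    drop_face <- drop_face | (inside_any[f[, 1], k] & inside_any[f[, 2], k] &
                                inside_any[f[, 3], k])
  f <- f[!drop_face, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  remap <- integer(nrow(u)); remap[keep] <- seq_along(keep)
  u <- u[keep, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)

  # scale to ellipsoid
  v <- sweep(u, 2, ax, `*`)
  pv_tag <- integer(nrow(v))

  # appendage bump: radial displacement with smooth falloff
  app_ang <- acos(pmin(1, pmax(-1, (u %*% dirs$appendage)[, 1])))
  wapp <- exp(-(app_ang / 0.35)^2)
  v <- v + (wapp * params$appendage_amp) * u

  # seeded surface jitter (deterministic; restores the caller's RNG state):
  # mostly tangential, so it scrambles the triangulation (the source of the
  # mesh-borne conduction heterogeneity that patient anatomies provide)
  # without inflating the surface area
  if (params$jitter > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(params$seed)
    v <- v + params$jitter * matrix(rnorm(3 * nrow(v)), ncol = 3)
    v <- .tangential_smooth(v, f, iters = 3)
    v <- .relax_inverted(v, f)
  }

  mesh <- new_surface_mesh(v, f, pv = pv_tag)

  # extrude PV tubes from the four PV boundary loops; loops are walked along
  # directed boundary half-edges so the extruded quads inherit a consistent
  # orientation from the surface
  loops <- .boundary_loops_directed(f)
  for (k in 1:4) {
    hs <- hole_specs[[k]]
    # loop whose mean direction is closest to this PV
    best <- which.max(vapply(loops, function(nd) {
      un <- v[nd, , drop = FALSE]
      mean((un / sqrt(rowSums(un^2))) %*% hs$dir)
    }, 0))
    ring <- loops[[best]]
    nr <- max(2L, ceiling(params$pv_length / 2))
    step_len <- params$pv_length / nr
    prev <- ring
    base_pts <- v[ring, , drop = FALSE]
    for (rr in seq_len(nr)) {
      # rings keep the (jittered) ostium shape: the rough PV-LA junction is
      # part of the reentry substrate; slivers are repaired afterwards
      newpts <- sweep(base_pts, 2, hs$dir * (rr * step_len), `+`)
      idx <- nrow(v) + seq_len(nrow(newpts))
      v <- rbind(v, newpts)
      pv_tag <- c(pv_tag, rep(hs$pv, nrow(newpts)))
      nn <- length(ring)
      for (q in seq_len(nn)) {
        q2 <- if (q == nn) 1L else q + 1L
        f <- rbind(f, c(prev[q2], prev[q], idx[q2]),
                   c(prev[q], idx[q], idx[q2]))
      }
      prev <- idx
    }
    pv_tag[ring] <- hs$pv   # ostium ring itself belongs to the vein
  }
  # repair any sliver triangles (mostly in the extruded tubes)
  if (params$quality_repair) v <- .fix_small_angles(v, f)
  mesh <- new_surface_mesh(v, f, pv = pv_tag)

  # orientation / gross self-intersection check on the shell proper (tube
  # side walls have normals orthogonal to the radial direction)
  shell <- pv_tag[f[, 1]] == 0 & pv_tag[f[, 2]] == 0 & pv_tag[f[, 3]] == 0
  ctr <- colMeans(v[pv_tag == 0, , drop = FALSE])
  fa <- v[f[shell, 2], ] - v[f[shell, 1], ]
  fb <- v[f[shell, 3], ] - v[f[shell, 1], ]
  nrm <- cbind(fa[, 2] * fb[, 3] - fa[, 3] * fb[, 2],
               fa[, 3] * fb[, 1] - fa[, 1] * fb[, 3],
               fa[, 1] * fb[, 2] - fa[, 2] * fb[, 1])
  cen <- (v[f[shell, 1], ] + v[f[shell, 2], ] + v[f[shell, 3], ]) / 3
  outward <- rowSums(nrm * sweep(cen, 2, ctr)) > 0
  if (mean(outward) < 0.99)
    stop("synthetic LA generation failed (inverted faces); reduce jitter",
         call. = FALSE)

  # landmarks for the six wall sections
  lm_dirs <- list(R1 = dirs$septum, R2 = dirs$anterior, R3 = dirs$appendage,
                  R4 = dirs$mitral, R5 = dirs$post_inferior,
                  R6 = dirs$posterior)
  un <- v / sqrt(rowSums(v^2))
  lm <- vapply(lm_dirs, function(d) {
    score <- un %*% d
    score[mesh$pv > 0] <- -Inf
    score[mesh$boundary & mesh$pv == 0] <- score[mesh$boundary & mesh$pv == 0] - 0.05
    which.max(score)
  }, 0L)
  mesh$landmarks <- lm
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tangential Laplacian smoothing: equalizes triangle sizes (bounding the
# lumped-mass spread that would otherwise throttle the diffusion CFL step)
# while leaving the radial surface roughness in place.
.tangential_smooth <- function(v, f, iters = 3, lambda = 0.6) {
  nbr <- split(c(f[, 2], f[, 3], f[, 1], f[, 3], f[, 1], f[, 2]),
               c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 2], f[, 3]))
  ids <- as.integer(names(nbr))
  for (it in seq_len(iters)) {
    un <- v / sqrt(rowSums(v^2))   # radial direction ~ surface normal here
    cent <- t(vapply(nbr, function(nb)
      colMeans(v[nb, , drop = FALSE]), numeric(3)))
    delta <- cent - v[ids, , drop = FALSE]
    rad <- rowSums(delta * un[ids, , drop = FALSE])
    delta <- delta - rad * un[ids, , drop = FALSE]
    v[ids, ] <- v[ids, , drop = FALSE] + lambda * delta
  }
  v
}

# targeted smoothing of vertices in triangles with interior angles below
# ~15 degrees (the quality floor for a well-behaved cotangent operator)
.fix_small_angles <- function(v, f, min_deg = 15.2, iters = 60,
                              fixed = integer(0)) {
  nbr <- split(c(f[, 2], f[, 3], f[, 1], f[, 3], f[, 1], f[, 2]),
               c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 2], f[, 3]))
  cos_lim <- cos(min_deg * pi / 180)
  for (it in seq_len(iters)) {
    bad_face <- rep(FALSE, nrow(f))
    for (perm in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))) {
      u <- v[f[, perm[2]], ] - v[f[, perm[1]], ]
      w <- v[f[, perm[3]], ] - v[f[, perm[1]], ]
      ca <- rowSums(u * w) / sqrt(rowSums(u * u) * rowSums(w * w))
      bad_face <- bad_face | ca > cos_lim
    }
    if (!any(bad_face)) break
    move <- setdiff(unique(as.vector(f[bad_face, , drop = FALSE])), fixed)
    for (vid in move) {
      nb <- nbr[[as.character(vid)]]
      v[vid, ] <- 0.5 * v[vid, ] + 0.5 * colMeans(v[nb, , drop = FALSE])
    }
  }
  v
}

# Laplacian smoothing restricted to vertices of inward-flipped faces, so
# strong surface jitter cannot invert the local orientation
.relax_inverted <- function(v, f) {
  ctr <- colMeans(v)
  nbr <- split(c(f[, 2], f[, 3], f[, 1], f[, 3], f[, 1], f[, 2]),
               c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 2], f[, 3]))
  for (iter in 1:30) {
    fa <- v[f[, 2], ] - v[f[, 1], ]
    fb <- v[f[, 3], ] - v[f[, 1], ]
    nrm <- cbind(fa[, 2] * fb[, 3] - fa[, 3] * fb[, 2],
                 fa[, 3] * fb[, 1] - fa[, 1] * fb[, 3],
                 fa[, 1] * fb[, 2] - fa[, 2] * fb[, 1])
    cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
    bad <- which(rowSums(nrm * sweep(cen, 2, ctr)) <= 0)
    if (!length(bad)) break
    for (vid in unique(as.vector(f[bad, , drop = FALSE]))) {
      nb <- nbr[[as.character(vid)]]
      v[vid, ] <- 0.4 * v[vid, ] + 0.6 * colMeans(v[nb, , drop = FALSE])
    }
  }
  v
}

# ordered boundary loops walked along directed boundary half-edges, so the
# returned node order is consistent with the surface orientation
.boundary_loops_directed <- function(faces) {
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  bd <- he[!(key %in% rkey), , drop = FALSE]
  if (nrow(bd) == 0) return(list())
  nxt <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(bd))) nxt[[as.character(bd[r, 1])]] <- bd[r, 2]
  unvisited <- unique(bd[, 1])
  loops <- list()
  while (length(unvisited)) {
    start <- unvisited[1]
    ring <- start
    cur <- nxt[[as.character(start)]]
    while (!is.null(cur) && cur != start) {
      ring <- c(ring, cur)
      cur <- nxt[[as.character(cur)]]
    }
    loops[[length(loops) + 1]] <- ring
    unvisited <- setdiff(unvisited, ring)
  }
  loops
}

# split boundary edges into ordered closed loops (list of node-id vectors)
.boundary_loops <- function(be) {
  adj <- new.env(parent = emptyenv())
  addn <- function(a, b) {
    k <- as.character(a)
    adj[[k]] <- c(adj[[k]], b)
  }
  for (r in seq_len(nrow(be))) {
    addn(be[r, 1], be[r, 2]); addn(be[r, 2], be[r, 1])
  }
  unvisited <- unique(as.vector(be))
  loops <- list()
  while (length(unvisited)) {
    start <- unvisited[1]
    ring <- start
    prev <- -1L
    cur <- start
    repeat {
      nb <- adj[[as.character(cur)]]
      nxt <- nb[nb != prev][1]
      if (is.na(nxt) || nxt == start) break
      ring <- c(ring, nxt)
      prev <- cur
      cur <- nxt
    }
    loops[[length(loops) + 1]] <- ring
    unvisited <- setdiff(unvisited, ring)
  }
  loops
}

#' Partition an LA mesh into the ten anatomical sections
#'
#' Pulmonary-vein tube nodes keep their generator tags (R7-R10); every other
#' node is assigned to the geodesically nearest of six landmark nodes
#' (R1 septum, R2 anterior wall, R3 appendage, R4 peri-mitral, R5 posterior
#' inferior wall, R6 posterior wall). Geodesic distances are shortest paths
#' on the edge graph weighted by edge length.
#'
#' @param mesh a `surface_mesh` with PV tags (from [make_synthetic_la()]).
#' @param landmarks named integer vector of six node ids (R1-R6); defaults
#'   to the generator-placed landmarks.
#' @return the mesh with `region` filled for every node.
#' @export
partition_regions <- function(mesh, landmarks = mesh$landmarks) {
  if (is.null(landmarks) || length(landmarks) != 6)
    stop("six landmark nodes (R1-R6) are required", call. = FALSE)
  e <- unique(mesh_edges(mesh))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  d <- igraph::distances(g, v = as.integer(landmarks), weights = w)
  region <- apply(d, 2, which.min)
  region[mesh$pv > 0] <- mesh$pv[mesh$pv > 0]
  mesh$region <- as.integer(region)
  counts <- tabulate(mesh$region, 10)
  if (any(counts == 0))
    stop("partition failure: empty region ",
         paste(.region_names[counts == 0], collapse = ", "), call. = FALSE)
  mesh$landmarks <- landmarks
  mesh
}

#' Total surface area and per-region areas (mm^2)
#' @param mesh a `surface_mesh`.
#' @return list with `total` and `by_region` (length 10, NA-safe).
#' @export
mesh_region_areas <- function(mesh) {
  by_region <- vapply(1:10, function(r) sum(mesh$area[mesh$region == r]), 0)
  list(total = sum(mesh$area), by_region = setNames(by_region, .region_names))
}

#' @export
print.surface_mesh <- function(x, ...) {
  topo <- mesh_topology(x)
  cat("<surface_mesh>", topo$V, "nodes,", topo$F, "triangles,",
      format(sum(x$area), digits = 6), "mm^2,",
      topo$boundary_loops, "boundary loops,",
      sum(x$region > 0), "labeled nodes\n")
  invisible(x)
}
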