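# Grid-probe cavity detection. A hydrogen-sized probe rolls over a 3D
# grid (0.5 angstrom default) around the protein: grid points are
# classified occupied / vacant / surface, buried vacancies are clustered
# into cavities, and each cavity is scored for druggability from size,
# burial and lining pharmacophores.

# 26-connectivity offsets (grid units)
OFFSETS26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

RES_HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP", "PRO", "GLY")
RES_DONOR <- c("SER", "THR", "TYR", "ASN", "GLN", "LYS", "ARG", "TRP", "HIS")
RES_ACCEPTOR <- c("ASP", "GLU", "ASN", "GLN", "SER", "THR", "TYR", "HIS")
RES_CHARGED <- c("ASP", "GLU", "LYS", "ARG", "HIS")

#' Build the labeled probe grid around a structure
#'
#' A point is occupied iff it lies within (vdW radius + probe radius) of
#' any heavy atom; vacant otherwise; vacant points 26-adjacent to an
#' occupied point are relabeled surface.
#'
#' @param structure a structure3d
#' @param spacing grid spacing in angstrom (default 0.5)
#' @param probe probe radius in angstrom (default 1.0, hydrogen-sized)
#' @param margin bounding-box margin beyond the atoms (default 4)
#' @param max_points grid-size budget (default 8e6 points)
#' @return object of class `cavity_grid`: list(origin, spacing, dims,
#'   labels) with labels 0 = vacant, 1 = occupied, 2 = surface
#' @export
build_grid <- function(structure, spacing = 0.5, probe = 1.0,
                       margin = 4.0, max_points = 8e6) {
  if (spacing <= 0) abort2("grid spacing must be positive", "cavigrow_domain_error")
  a <- structure$atoms
  if (!nrow(a)) abort2("empty structure", "cavigrow_domain_error")
  xyz <- coords(structure)
  pad <- max(a$vdw) + probe + margin
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  npts <- prod(as.numeric(dims))
  if (npts > max_points)
    abort2(sprintf(
      "grid would need %.0f points (budget %.0f); use a coarser spacing",
      npts, max_points), "cavigrow_budget_error")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  occ <- logical(npts)
  r <- a$vdw + probe
  for (k in seq_len(nrow(a))) {
    ctr <- (xyz[k, ] - lo) / spacing        # grid-unit center
    rg <- r[k] / spacing
    ix <- max(0, floor(ctr[1] - rg)):min(nx - 1, ceiling(ctr[1] + rg))
    iy <- max(0, floor(ctr[2] - rg)):min(ny - 1, ceiling(ctr[2] + rg))
    iz <- max(0, floor(ctr[3] - rg)):min(nz - 1, ceiling(ctr[3] + rg))
    dx2 <- (ix - ctr[1])^2; dy2 <- (iy - ctr[2])^2; dz2 <- (iz - ctr[3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rg^2
    if (!any(within)) next
    sub <- which(within, arr.ind = TRUE)
    idx <- (ix[sub[, 1]]) + nx * ((iy[sub[, 2]]) + ny * (iz[sub[, 3]])) + 1L
    occ[idx] <- TRUE
  }
  labels <- integer(npts)
  labels[occ] <- 1L
  # surface: vacant points 26-adjacent to occupied
  arr <- array(occ, dim = dims)
  near_occ <- array(FALSE, dim = dims)
  for (o in seq_len(nrow(OFFSETS26))) {
    dx <- OFFSETS26[o, 1]; dy <- OFFSETS26[o, 2]; dz <- OFFSETS26[o, 3]
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    zs <- max(1, 1 + dz):min(nz, nz + dz)
    near_occ[xs - dx, ys - dy, zs - dz] <-
      near_occ[xs - dx, ys - dy, zs - dz] | arr[xs, ys, zs]
  }
  surf <- as.vector(near_occ) & !occ
  labels[surf] <- 2L
  structure(list(origin = lo, spacing = spacing, dims = dims, labels = labels),
            class = "cavity_grid")
}

#' @export
print.cavity_grid <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 3L)
  cat(sprintf(
    "<cavity_grid: %dx%dx%d @ %.2f A; vacant %d, occupied %d, surface %d>\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, tab[1], tab[2], tab[3]))
  invisible(x)
}

# 0-based (ix,iy,iz) subscripts for linear indices
grid_subs <- function(grid, idx) {
  i0 <- idx - 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]
  ix <- i0 %% nx
  iy <- (i0 %/% nx) %% ny
  iz <- i0 %/% (nx * ny)
  cbind(ix, iy, iz)
}

# cartesian coordinates of grid points
grid_points_xyz <- function(grid, idx) {
  s <- grid_subs(grid, idx)
  sweep(s * grid$spacing, 2, grid$origin, "+")
}

#' Per-point burial by 26-direction ray casting
#'
#' Fraction of the 26 lattice directions along which an occupied point is
#' hit within `max_ray` angstrom.
#'
#' @param grid a cavity_grid
#' @param idx linear indices of query points
#' @param max_ray ray length in angstrom (default 12)
#' @return numeric burial fraction per query point
#' @export
point_burial <- function(grid, idx, max_ray = 12) {
  occ <- grid$labels == 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  subs <- grid_subs(grid, idx)
  nq <- length(idx)
  hits <- numeric(nq)
  for (o in seq_len(nrow(OFFSETS26))) {
    off <- OFFSETS26[o, ]
    step_len <- sqrt(sum(off^2)) * grid$spacing
    nsteps <- floor(max_ray / step_len)
    hit <- logical(nq); oob <- logical(nq)
    ix <- subs[, 1]; iy <- subs[, 2]; iz <- subs[, 3]
    for (s in seq_len(nsteps)) {
      ix <- ix + off[1]; iy <- iy + off[2]; iz <- iz + off[3]
      oob <- oob | ix < 0L | ix >= nx | iy < 0L | iy >= ny | iz < 0L | iz >= nz
      alive <- !hit & !oob
      if (!any(alive)) break
      lin <- ix[alive] + nx * (iy[alive] + ny * iz[alive]) + 1L
      hit[alive] <- occ[lin]
    }
    hits <- hits + hit
  }
  hits / nrow(OFFSETS26)
}

# connected components (26-conn) over a logical mask on the grid
grid_components <- function(grid, mask_idx) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  inset <- integer(prod(grid$dims))      # 0 = not candidate, else comp id
  inset[mask_idx] <- -1L
  comp <- 0L
  out <- vector("list", 0)
  for (seed in mask_idx) {
    if (inset[seed] != -1L) next
    comp <- comp + 1L
    members <- integer(0)
    frontier <- seed
    inset[seed] <- comp
    while (length(frontier)) {
      members <- c(members, frontier)
      subs <- grid_subs(grid, frontier)
      nbrs <- integer(0)
      for (o in seq_len(nrow(OFFSETS26))) {
        ix <- subs[, 1] + OFFSETS26[o, 1]
        iy <- subs[, 2] + OFFSETS26[o, 2]
        iz <- subs[, 3] + OFFSETS26[o, 3]
        ok <- ix >= 0L & ix < nx & iy >= 0L & iy < ny & iz >= 0L & iz < nz
        if (!any(ok)) next
        lin <- ix[ok] + nx * (iy[ok] + ny * iz[ok]) + 1L
        nbrs <- c(nbrs, lin[inset[lin] == -1L])
      }
      nbrs <- unique(nbrs)
      inset[nbrs] <- comp
      frontier <- nbrs
    }
    out[[comp]] <- members
  }
  out
}

#' Detect surface cavities
#'
#' Buried non-occupied grid points (per-point burial >= `burial_min`) are
#' clustered by 26-connectivity; components above `min_volume` become
#' cavities, ranked by druggability score (descending). Lining residues
#' are all residues with an atom within `lining_distance` of a cavity
#' point.
#'
#' @param grid a cavity_grid from [build_grid]
#' @param structure the structure3d the grid was built from
#' @param min_volume minimum cavity volume in cubic angstrom (default 50)
#' @param burial_min per-point and per-cavity burial threshold (default 0.5)
#' @param lining_distance residue lining cutoff in angstrom (default 4)
#' @param membrane optional c(zmin, zmax) slab bounds for EC/IC/TM naming
#' @return list of `cavity` objects (possibly empty), each with fields
#'   points, xyz, centroid, lining_residues, volume, burial_fraction,
#'   druggability_score, location_tag, name
#' @export
detect_cavities <- function(grid, structure, min_volume = 50,
                            burial_min = 0.5, lining_distance = 4.0,
                            membrane = NULL) {
  # candidates: non-occupied points inside the tight atom bounding box
  xyz_a <- coords(structure)
  lo <- apply(xyz_a, 2, min) - 1.0
  hi <- apply(xyz_a, 2, max) + 1.0
  all_idx <- which(grid$labels != 1L)
  pts <- grid_points_xyz(grid, all_idx)
  inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  cand <- all_idx[inside]
  if (!length(cand)) return(list())
  burial <- point_burial(grid, cand)
  buried <- cand[burial >= burial_min]
  if (!length(buried)) return(list())
  comps <- grid_components(grid, buried)
  min_pts <- ceiling(min_volume / grid$spacing^3)
  comps <- Filter(function(m) length(m) >= min_pts, comps)
  if (!length(comps)) return(list())

  cavities <- lapply(comps, function(members) {
    cxyz <- grid_points_xyz(grid, members)
    centroid <- colMeans(cxyz)
    # cavity burial: centroid-nearest point plus a deterministic sample
    d2c <- rowSums(sweep(cxyz, 2, centroid)^2)
    probe_pts <- members[order(d2c)][unique(round(seq(1, length(members),
                                                      length.out = min(26, length(members)))))]
    bf <- mean(point_burial(grid, probe_pts))
    lining <- lining_residues(structure, cxyz, lining_distance)
    vol <- length(members) * grid$spacing^3
    score <- druggability(volume = vol, burial_fraction = bf,
                          lining = lining)
    tag <- if (is.null(membrane)) "NA" else {
      mz <- centroid[3]
      if (mz > membrane[2]) "EC" else if (mz < membrane[1]) "IC" else "TM"
    }
    structure(list(points = members, xyz = cxyz, centroid = centroid,
                   lining_residues = lining, volume = vol,
                   burial_fraction = bf, druggability_score = score,
                   location_tag = tag, name = NA_character_),
              class = "cavity")
  })
  cavities <- cavities[order(vapply(cavities, `[[`, numeric(1),
                                    "druggability_score"),
                             decreasing = TRUE)]
  # names: tag + per-tag ordinal in score order
  tags <- vapply(cavities, `[[`, character(1), "location_tag")
  for (tg in unique(tags)) {
    w <- which(tags == tg)
    for (r in seq_along(w)) cavities[[w[r]]]$name <- paste0(tg, r)
  }
  cavities
}

#' @export
print.cavity <- function(x, ...) {
  cat(sprintf(
    "<cavity %s: %.0f A^3, burial %.2f, druggability %.2f, %d lining residues>\n",
    x$name, x$volume, x$burial_fraction, x$druggability_score,
    nrow(x$lining_residues)))
  invisible(x)
}

#' Lining residues of a point cloud
#' @keywords internal
lining_residues <- function(structure, cavity_xyz, lining_distance = 4.0) {
  a <- structure$atoms
  xyz <- coords(structure)
  near <- logical(nrow(a))
  # block over atoms to bound memory
  d2max <- lining_distance^2
  for (start in seq(1, nrow(xyz), by = 256)) {
    end <- min(start + 255, nrow(xyz))
    blk <- xyz[start:end, , drop = FALSE]
    # min squared distance from each atom in block to any cavity point
    for (k in seq_len(nrow(blk))) {
      d2 <- (cavity_xyz[, 1] - blk[k, 1])^2 +
        (cavity_xyz[, 2] - blk[k, 2])^2 +
        (cavity_xyz[, 3] - blk[k, 3])^2
      if (min(d2) <= d2max) near[start + k - 1L] <- TRUE
    }
  }
  res <- unique(a[near, c("chain", "resno", "resname")])
  rownames(res) <- NULL
  res
}

#' Druggability score of a cavity
#'
#' score = 0.25 * size + 0.30 * burial + 0.30 * hydrophobic lining
#' fraction + 0.15 * pharmacophore diversity, clamped to [0, 1].
#' size = min(volume / 500, 1); diversity = Shannon entropy of the
#' {donor, acceptor, hydrophobe, charged} lining classes / log 4.
#' Monotone non-decreasing in burial with the other terms fixed.
#'
#' @param volume cavity volume (cubic angstrom)
#' @param burial_fraction burial in [0, 1]
#' @param lining data.frame(chain, resno, resname) of lining residues
#' @return score in [0, 1]
#' @export
druggability <- function(volume, burial_fraction, lining) {
  size_term <- min(volume / 500, 1)
  rn <- if (NROW(lining)) lining$resname else character(0)
  counts <- c(donor = sum(rn %in% RES_DONOR),
              acceptor = sum(rn %in% RES_ACCEPTOR),
              hydrophobe = sum(rn %in% RES_HYDROPHOBIC),
              charged = sum(rn %in% RES_CHARGED))
  hydrophobic_frac <- if (length(rn)) mean(rn %in% RES_HYDROPHOBIC) else 0
  diversity <- if (sum(counts) > 0) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p)) / log(4)
  } else 0
  s <- 0.25 * size_term + 0.30 * burial_fraction +
    0.30 * hydrophobic_frac + 0.15 * diversity
  max(0, min(1, s))
}

#' Select a cavity by critical residues (or by druggability)
#'
#' Returns the cavity with the largest lining overlap with
#' `critical_residues`; ties broken by higher druggability then lower
#' ordinal. With an empty critical set, returns the top-druggability
#' cavity.
#'
#' @param cavities list of cavity objects
#' @param critical_residues optional data.frame(chain, resno) or integer
#'   vector of residue numbers
#' @return a cavity
#' @export
select_cavity <- function(cavities, critical_residues = NULL) {
  if (!length(cavities)) abort2("no cavities to select from", "cavigrow_domain_error")
  scores <- vapply(cavities, `[[`, numeric(1), "druggability_score")
  if (is.null(critical_residues) || NROW(critical_residues) == 0L) {
    return(cavities[[which.max(scores)]])
  }
  crit_keys <- if (is.data.frame(critical_residues)) {
    paste(critical_residues$chain, critical_residues$resno)
  } else NULL
  overlap <- vapply(cavities, function(cv) {
    lr <- cv$lining_residues
    if (!NROW(lr)) return(0L)
    if (is.null(crit_keys)) {
      sum(unique(lr$resno) %in% critical_residues)
    } else {
      sum(unique(paste(lr$chain, lr$resno)) %in% crit_keys)
    }
  }, integer(1))
  if (all(overlap == 0L)) {
    best <- order(scores, decreasing = TRUE)[seq_len(min(3, length(cavities)))]
    abort2(paste0(
      "no cavity overlaps any critical residue; best candidates: ",
      paste(vapply(cavities[best], `[[`, character(1), "name"), collapse = ", ")),
      "cavigrow_selection_error")
  }
  ord <- order(-overlap, -scores, seq_along(cavities))
  cavities[[ord[1]]]
}

#' Write a cavity descriptor as JSON (handoff to downstream stages)
#' @param cavity a cavity
#' @param grid the grid it came from
#' @param path output path
#' @export
write_cavity_json <- function(cavity, grid, path) {
  obj <- list(
    name = cavity$name,
    origin = grid$origin, spacing = grid$spacing, dims = grid$dims,
    points = cavity$points,
    volume = cavity$volume,
    burial_fraction = cavity$burial_fraction,
    druggability_score = cavity$druggability_score,
    lining_residues = cavity$lining_residues)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-cavity summary table
#' @param cavities list of cavity objects
#' @return data.frame (name, volume, burial, score, n_lining, location)
#' @export
cavity_table <- function(cavities) {
  data.frame(
    name = vapply(cavities, `[[`, character(1), "name"),
    volume = vapply(cavities, `[[`, numeric(1), "volume"),
    burial = vapply(cavities, `[[`, numeric(1), "burial_fraction"),
    druggability = vapply(cavities, `[[`, numeric(1), "druggability_score"),
    n_lining = vapply(cavities, function(cv) NROW(cv$lining_residues), integer(1)),
    location = vapply(cavities, `[[`, character(1), "location_tag"),
    stringsAsFactors = FALSE)
}
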