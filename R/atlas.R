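# Voxel atlas: region lookup, hierarchy queries, hemisphere assignment,
# region sampling, border distances, toy-atlas builder and raster I/O.

# ---- hierarchy helpers -------------------------------------------------

hierRootId <- function(h) h$id[is.na(h$parent_id)]

# ids of node and all its ancestors, node first.
hierAncestors <- function(h, id) {
  out <- integer(0)
  cur <- id
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- h$parent_id[match(cur, h$id)]
  }
  out
}

# ids of node and all descendants.
hierDescendants <- function(h, id) {
  out <- id
  frontier <- id
  while (length(frontier)) {
    frontier <- h$id[h$parent_id %in% frontier & !is.na(h$parent_id)]
    out <- c(out, frontier)
  }
  out
}

acronymToId <- function(atlas, acronym) {
  h <- atlas@hierarchy
  id <- h$id[match(acronym, h$acronym)]
  if (any(is.na(id))) stop("unknown region acronym: ",
                           paste(acronym[is.na(id)], collapse = ", "))
  id
}

# Lift a vector of leaf region ids to the requested hierarchy depth.
liftIds <- function(atlas, ids, level) {
  if (identical(level, "leaf")) return(ids)
  h <- atlas@hierarchy
  uids <- unique(ids[!is.na(ids)])
  lifted <- vapply(uids, function(id) {
    anc <- hierAncestors(h, id)
    depths <- h$depth[match(anc, h$id)]
    ok <- which(depths <= level)
    if (!length(ok)) anc[length(anc)] else anc[ok[1L]]
  }, 0L)
  lifted[match(ids, uids)]
}

# ---- coordinate mapping ------------------------------------------------

# World xyz (n x 3) -> 0-based voxel indices (n x 3); half-open ownership.
worldToVoxel <- function(atlas, xyz) {
  xyz <- rbind(xyz)
  floor(sweep(xyz, 2L, atlas@origin) / atlas@voxelSize)
}

voxelCenter <- function(atlas, ijk) {
  ijk <- rbind(ijk)
  sweep((ijk + 0.5) * atlas@voxelSize, 2L, atlas@origin, "+")
}

# Annotation value at 0-based voxel indices; NA when out of bounds.
annotationAt <- function(atlas, ijk) {
  ijk <- rbind(ijk)
  d <- dim(atlas@annotation)
  inb <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
    ijk[, 3] >= 0 & ijk[, 3] < d[3]
  out <- rep(NA_integer_, nrow(ijk))
  if (any(inb)) {
    lin <- 1L + ijk[inb, 1] + d[1] * (ijk[inb, 2] + d[2] * ijk[inb, 3])
    out[inb] <- atlas@annotation[lin]
  }
  out
}

#' Region at a world position
#'
#' Maps a point (or matrix of points, one per row) to the annotated region,
#' lifted to the requested hierarchy level by an ancestor walk. Points outside
#' the raster or in unannotated (0) voxels give \code{NA}.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param xyz 3-vector or n x 3 matrix of world coordinates (micrometres).
#' @param level hierarchy depth (root = 0) or \code{"leaf"} for the raw
#'   annotation.
#' @param what return \code{"acronym"} (default) or \code{"id"}.
#' @return character (or integer) vector of regions, \code{NA} outside.
#' @export
regionAt <- function(atlas, xyz, level = "leaf", what = c("acronym", "id")) {
  what <- match.arg(what)
  ids <- annotationAt(atlas, worldToVoxel(atlas, xyz))
  ids[!is.na(ids) & ids == 0L] <- NA_integer_
  ids <- liftIds(atlas, ids, level)
  if (what == "id") return(ids)
  h <- atlas@hierarchy
  h$acronym[match(ids, h$id)]
}

#' Hemisphere of a world position
#'
#' Sign of the coordinate along the midline axis relative to the midline;
#' points exactly on the midline are "right" (tie-break).
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param xyz 3-vector or n x 3 matrix, must be inside the raster.
#' @return character vector, "left" or "right".
#' @export
hemisphereOf <- function(atlas, xyz) {
  xyz <- rbind(xyz)
  ijk <- worldToVoxel(atlas, xyz)
  d <- dim(atlas@annotation)
  if (any(ijk < 0 | sweep(ijk, 2L, d, ">="))) {
    stop("point outside the atlas raster")
  }
  unname(ifelse(xyz[, atlas@midlineAxis] >= atlas@midline, "right", "left"))
}

#' Sample uniform points inside a region
#'
#' Uniform over the voxels of the region subtree (descendants included), then
#' uniform within each voxel cube; reproducible per seed.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param region region acronym.
#' @param n number of points.
#' @param hemisphere optional "left"/"right" restriction.
#' @param seed optional integer seed.
#' @return n x 3 matrix of world coordinates.
#' @export
samplePointInRegion <- function(atlas, region, n = 1L, hemisphere = NULL, seed = NULL) {
  vox <- regionVoxels(atlas, region, hemisphere)
  if (!nrow(vox)) stop("region '", region, "' has no voxels",
                       if (!is.null(hemisphere)) paste0(" in the ", hemisphere,
                                                        " hemisphere") else "")
  withSeed(seed, {
    pick <- vox[sample.int(nrow(vox), n, replace = TRUE), , drop = FALSE]
    offs <- matrix(stats::runif(3L * n), ncol = 3L)
    sweep((pick + offs) * atlas@voxelSize, 2L, atlas@origin, "+")
  })
}

# 0-based voxel indices (n x 3) of a region subtree, optionally one hemisphere.
regionVoxels <- function(atlas, region, hemisphere = NULL) {
  ids <- hierDescendants(atlas@hierarchy, acronymToId(atlas, region))
  lin <- which(atlas@annotation %in% ids)
  ijk <- arrayInd(lin, dim(atlas@annotation)) - 1L
  if (!is.null(hemisphere)) {
    centers <- voxelCenter(atlas, ijk)
    keep <- (centers[, atlas@midlineAxis] >= atlas@midline) == (hemisphere == "right")
    ijk <- ijk[keep, , drop = FALSE]
  }
  ijk
}

#' Minimum border distance between two regions
#'
#' Boundary voxels are region voxels with a 6-neighbour outside the region
#' (raster edges count as boundary). The distance is the minimum Euclidean
#' distance between boundary-voxel centers minus one voxel edge, floored at
#' zero, so adjacent or overlapping regions score 0 and regions separated by
#' k empty voxels along an axis score k * voxelSize.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param regionA,regionB region acronyms.
#' @return distance in micrometres.
#' @export
borderDistance <- function(atlas, regionA, regionB) {
  ba <- boundaryVoxels(atlas, regionA)
  bb <- boundaryVoxels(atlas, regionB)
  if (!nrow(ba)) stop("region '", regionA, "' has no voxels")
  if (!nrow(bb)) stop("region '", regionB, "' has no voxels")
  ca <- voxelCenter(atlas, ba)
  cb <- voxelCenter(atlas, bb)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  max(0, sqrt(max(0, min(d2))) - atlas@voxelSize)
}

boundaryVoxels <- function(atlas, region) {
  ids <- hierDescendants(atlas@hierarchy, acronymToId(atlas, region))
  mask <- array(atlas@annotation %in% ids, dim(atlas@annotation))
  ijk <- arrayInd(which(mask), dim(mask))
  if (!nrow(ijk)) return(ijk)
  d <- dim(mask)
  isBoundary <- rep(FALSE, nrow(ijk))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[, ax] <- nb[, ax] + s
      edge <- nb[, ax] < 1L | nb[, ax] > d[ax]
      inside <- !edge
      nbVal <- rep(FALSE, nrow(ijk))
      if (any(inside)) {
        lin <- nb[inside, 1] + d[1] * (nb[inside, 2] - 1L + d[2] * (nb[inside, 3] - 1L))
        nbVal[inside] <- mask[lin]
      }
      isBoundary <- isBoundary | edge | !nbVal
    }
  }
  ijk[isBoundary, , drop = FALSE] - 1L
}

#' Region centroid (world coordinates)
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param region acronym.
#' @param hemisphere optional hemisphere restriction.
#' @return 3-vector, micrometres.
#' @export
regionCentroid <- function(atlas, region, hemisphere = NULL) {
  vox <- regionVoxels(atlas, region, hemisphere)
  if (!nrow(vox)) stop("region '", region, "' has no voxels")
  colMeans(voxelCenter(atlas, vox))
}

# ---- toy atlas builder -------------------------------------------------

#' Build a toy atlas from an axis-aligned box specification
#'
#' Regions are listed as boxes of 1-based voxel-index ranges in the lower
#' hemisphere along \code{mirror_axis}; the builder mirrors them so the two
#' hemispheres are mirror-symmetric (same region ids on both sides, as in
#' Allen-style annotations). Grouping regions (no box) only structure the
#' hierarchy. An optional background region fills the remaining volume so the
#' brain is connected, and fiber corridors (straight cylinders between region
#' centroids) are marked in the fiber mask and annotated with their own
#' region id where they cross background.
#'
#' @param spec a list with elements \code{dims} (3 voxel counts; the extent
#'   along \code{mirror_axis} must be even), \code{voxel_size} (micrometres),
#'   \code{origin} (default c(0,0,0)), \code{mirror_axis} (default 1),
#'   \code{background} (acronym or NULL), \code{regions} (list of
#'   \code{list(acronym, parent, box)} where \code{box} is a 3 x 2 matrix of
#'   1-based inclusive index ranges; omit \code{box} for grouping nodes) and
#'   \code{fibers} (list of \code{list(from, to, radius)} in voxels).
#' @return a \linkS4class{BrainAtlas}.
#' @export
buildToyAtlas <- function(spec) {
  dims <- as.integer(spec$dims)
  vs <- spec$voxel_size
  origin <- if (is.null(spec$origin)) c(0, 0, 0) else spec$origin
  axis <- if (is.null(spec$mirror_axis)) 1L else as.integer(spec$mirror_axis)
  if (dims[axis] %% 2L != 0L) stop("extent along mirror_axis must be even")
  half <- dims[axis] %/% 2L

  regions <- spec$regions
  acronyms <- vapply(regions, `[[`, "", "acronym")
  if (anyDuplicated(acronyms)) stop("duplicate region acronyms in toy-atlas spec")

  # hierarchy: root = id 1; regions ids 2..; background and fibers appended
  h <- data.frame(id = 1L, acronym = "root", parent_id = NA_integer_)
  nextId <- 2L
  for (r in regions) {
    h <- rbind(h, data.frame(id = nextId, acronym = r$acronym, parent_id = NA_integer_))
    nextId <- nextId + 1L
  }
  for (i in seq_along(regions)) {
    p <- regions[[i]]$parent
    pid <- if (is.null(p) || identical(p, "root")) 1L else {
      j <- match(p, acronyms)
      if (is.na(j)) stop("unknown parent region: ", p)
      h$id[1L + j]
    }
    h$parent_id[1L + i] <- pid
  }
  bgId <- NA_integer_
  if (!is.null(spec$background)) {
    bgId <- nextId; nextId <- nextId + 1L
    h <- rbind(h, data.frame(id = bgId, acronym = spec$background, parent_id = 1L))
  }
  fibId <- NA_integer_
  if (length(spec$fibers)) {
    fibId <- nextId; nextId <- nextId + 1L
    h <- rbind(h, data.frame(id = fibId, acronym = "fib", parent_id = 1L))
  }
  h$depth <- vapply(h$id, function(id) length(hierAncestors(h, id)) - 1L, 0L)

  ann <- array(0L, dims)
  if (!is.na(bgId)) ann[] <- bgId
  fib <- array(FALSE, dims)

  # paint leaf boxes (lower hemisphere), then mirror
  mirrorIndex <- function(i) dims[axis] + 1L - i
  boxVoxels <- function(box) {
    box <- rbind(box)
    as.matrix(expand.grid(box[1, 1]:box[1, 2], box[2, 1]:box[2, 2],
                          box[3, 1]:box[3, 2]))
  }
  painted <- array(FALSE, dims)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (is.null(r$box)) next
    box <- r$box
    if (any(box[axis, ] > half)) stop("region box for '", r$acronym,
                                      "' crosses the midline; give boxes in the lower hemisphere")
    vox <- boxVoxels(box)
    lin <- vox[, 1] + dims[1] * (vox[, 2] - 1L + dims[2] * (vox[, 3] - 1L))
    if (any(painted[lin])) stop("overlapping region boxes at '", r$acronym, "'")
    painted[lin] <- TRUE
    id <- h$id[match(r$acronym, h$acronym)]
    ann[lin] <- id
    voxM <- vox; voxM[, axis] <- mirrorIndex(voxM[, axis])
    linM <- voxM[, 1] + dims[1] * (voxM[, 2] - 1L + dims[2] * (voxM[, 3] - 1L))
    ann[linM] <- id
  }

  atlasSoFar <- new("BrainAtlas", annotation = ann, voxelSize = vs, origin = origin,
                    hierarchy = h, fiberMask = fib, midlineAxis = axis,
                    midline = origin[axis] + half * vs)

  # fiber corridors between lower-hemisphere region centroids; the corridor
  # voxel set is computed once and mirrored by index so the two hemispheres
  # stay exactly symmetric at voxel granularity
  if (length(spec$fibers)) {
    paint <- function(v) {
      lin <- 1L + v[, 1] + dims[1] * (v[, 2] + dims[2] * v[, 3])
      # white-matter corridors live between regions: voxels inside a named
      # region stay gray matter (corridors stop at the border)
      bgOnly <- ann[lin] %in% c(if (is.na(bgId)) 0L else bgId, fibId)
      fib[lin[bgOnly]] <<- TRUE
      ann[lin[bgOnly]] <<- fibId
    }
    for (f in spec$fibers) {
      radius <- if (is.null(f$radius)) 1L else f$radius
      a <- regionCentroid(atlasSoFar, f$from, hemisphere = "left")
      b <- regionCentroid(atlasSoFar, f$to, hemisphere = "left")
      nStep <- max(2L, ceiling(vecNorm(b - a) / (vs / 2)))
      ts <- seq(0, 1, length.out = nStep)
      pts <- cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]),
                   a[3] + ts * (b[3] - a[3]))
      ijk <- unique(worldToVoxel(atlasSoFar, pts))
      rad <- seq(-radius, radius)
      offs <- as.matrix(expand.grid(rad, rad, rad))
      offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        v <- sweep(ijk, 2L, offs[o, ], "+")
        keep <- v[, 1] >= 0 & v[, 1] < dims[1] & v[, 2] >= 0 & v[, 2] < dims[2] &
          v[, 3] >= 0 & v[, 3] < dims[3]
        v <- v[keep, , drop = FALSE]
        paint(v)
        vM <- v
        vM[, axis] <- dims[axis] - 1L - vM[, axis]
        paint(vM)
      }
    }
  }

  new("BrainAtlas", annotation = ann, voxelSize = vs, origin = origin,
      hierarchy = h, fiberMask = fib, midlineAxis = axis,
      midline = origin[axis] + half * vs)
}

# ---- atlas I/O (raw int32 raster + JSON header, Allen-style hierarchy) --

#' Write / read a BrainAtlas to a directory
#'
#' Rasters are stored as little-endian raw binaries (annotation as int32,
#' fiber mask as uint8) beside a JSON header with dims, voxel size, origin
#' and midline; the hierarchy is an Allen-structure-graph-style nested JSON.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param dir directory (created if needed).
#' @return \code{dir} (write) or the atlas (read), invisibly for write.
#' @export
writeBrainAtlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(dims = dim(atlas@annotation), voxel_size = atlas@voxelSize,
              origin = atlas@origin, midline_axis = atlas@midlineAxis,
              midline = atlas@midline)
  jsonlite::write_json(hdr, file.path(dir, "header.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "annotation.raw"), "wb")
  writeBin(as.integer(atlas@annotation), con, size = 4L, endian = "little")
  close(con)
  con <- file(file.path(dir, "fiber_mask.raw"), "wb")
  writeBin(as.integer(atlas@fiberMask), con, size = 1L, endian = "little")
  close(con)
  jsonlite::write_json(hierarchyToAllenJSON(atlas@hierarchy),
                       file.path(dir, "hierarchy.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeBrainAtlas
#' @export
readBrainAtlas <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  dims <- as.integer(hdr$dims)
  n <- prod(dims)
  con <- file(file.path(dir, "annotation.raw"), "rb")
  ann <- array(readBin(con, "integer", n, size = 4L, endian = "little"), dims)
  close(con)
  con <- file(file.path(dir, "fiber_mask.raw"), "rb")
  fib <- array(readBin(con, "integer", n, size = 1L, signed = FALSE,
                       endian = "little") > 0L, dims)
  close(con)
  h <- allenJSONToHierarchy(jsonlite::read_json(file.path(dir, "hierarchy.json")))
  new("BrainAtlas", annotation = ann, voxelSize = hdr$voxel_size,
      origin = as.numeric(hdr$origin), hierarchy = h, fiberMask = fib,
      midlineAxis = as.integer(hdr$midline_axis), midline = hdr$midline)
}

hierarchyToAllenJSON <- function(h) {
  build <- function(id) {
    kids <- h$id[!is.na(h$parent_id) & h$parent_id == id]
    list(id = id, acronym = h$acronym[match(id, h$id)],
         children = lapply(kids, build))
  }
  build(hierRootId(h))
}

allenJSONToHierarchy <- function(node) {
  rows <- list()
  walk <- function(nd, parent, depth) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.integer(nd$id), acronym = nd$acronym,
      parent_id = if (is.null(parent)) NA_integer_ else as.integer(parent),
      depth = depth)
    for (ch in nd$children) walk(ch, nd$id, depth + 1L)
  }
  walk(node, NULL, 0L)
  do.call(rbind, rows)
}
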