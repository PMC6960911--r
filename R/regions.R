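#' @include AllClasses.R utils.R
NULL

emptyRegionSet <- function(dim) {
  new("RegionSet",
      labelMap = matrix(0L, dim[1L], dim[2L]),
      regions = data.frame(id = integer(), area = integer(),
                           centroidRow = numeric(), centroidCol = numeric(),
                           rowMin = integer(), rowMax = integer(),
                           colMin = integer(), colMax = integer()))
}

#' Label 8-connected foreground regions
#'
#' Connected-component labelling of a boolean mask under 8-connectivity
#' (diagonal neighbours join). Labels are contiguous `1..N`, ordered by the
#' first (column-major) pixel of each component, so the labelling is a pure
#' function of the mask. The region table records area, centroid and bounding
#' box per component (1-based row/col coordinates).
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return a [RegionSet-class]; an empty mask yields `N = 0`, `A = 0`.
#' @export
labelRegions <- function(mask) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)                      # column-major linear indices
  if (length(fg) == 0L) return(emptyRegionSet(c(h, w)))
  compact <- integer(h * w)
  compact[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  cl <- ((fg - 1L) %/% h) + 1L
  edges <- list()
  neigh <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= h & cl + dc >= 1L & cl + dc <= w
    src <- fg[ok]
    dst <- src + dr + dc * h
    keep <- mask[dst]
    cbind(compact[src[keep]], compact[dst[keep]])
  }
  edges <- rbind(neigh(1L, 0L), neigh(0L, 1L), neigh(1L, 1L), neigh(-1L, 1L))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel so that component ids increase with their first pixel
  firstPix <- vapply(split(seq_along(fg), memb), min, integer(1))
  ord <- order(firstPix)
  relab <- integer(length(ord)); relab[as.integer(names(firstPix))[ord]] <- seq_along(ord)
  lab <- relab[memb]
  labelMap <- matrix(0L, h, w)
  labelMap[fg] <- lab
  regions <- data.frame(
    id = seq_len(max(lab)),
    area = as.integer(tabulate(lab)),
    centroidRow = as.numeric(tapply(r, lab, mean)),
    centroidCol = as.numeric(tapply(cl, lab, mean)),
    rowMin = as.integer(tapply(r, lab, min)),
    rowMax = as.integer(tapply(r, lab, max)),
    colMin = as.integer(tapply(cl, lab, min)),
    colMax = as.integer(tapply(cl, lab, max)))
  new("RegionSet", labelMap = labelMap, regions = regions)
}

#' Subset a RegionSet, relabelling contiguously
#'
#' @param rs a [RegionSet-class].
#' @param ids region ids to keep.
#' @return a [RegionSet-class] with labels `1..length(ids)` preserving the
#'   original id order.
#' @export
subsetRegions <- function(rs, ids) {
  stopifnot(is(rs, "RegionSet"))
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) == 0L) return(emptyRegionSet(dim(rs@labelMap)))
  old <- rs@labelMap
  relab <- integer(regionCount(rs))
  relab[ids] <- seq_along(ids)
  lm <- matrix(0L, nrow(old), ncol(old))
  keep <- old > 0L & old %in% ids
  lm[keep] <- relab[old[keep]]
  tab <- rs@regions[rs@regions$id %in% ids, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("RegionSet", labelMap = lm, regions = tab)
}

# Drop components smaller than `minFrac` of the image area.
filterSmallRegions <- function(rs, minFrac) {
  minArea <- minFrac * length(rs@labelMap)
  subsetRegions(rs, rs@regions$id[rs@regions$area >= minArea])
}

#' Maximum inner rectangle of a region
#'
#' The largest-area axis-aligned rectangle entirely inside a region's pixel
#' set, found with the dynamic-programming histogram-stack method (ties go to
#' the candidate encountered first scanning top-to-bottom, left-to-right).
#' Texture descriptors are computed on this rectangle at segmentation time, so
#' that ragged region boundaries do not leak background texture.
#'
#' @param rs a [RegionSet-class].
#' @param id region id.
#' @return named integer vector `(rowMin, colMin, rowMax, colMax)`.
#' @export
maxInnerRectangle <- function(rs, id) {
  stopifnot(is(rs, "RegionSet"))
  row <- rs@regions[rs@regions$id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("empty or unknown region id ", id)
  sub <- rs@labelMap[row$rowMin:row$rowMax, row$colMin:row$colMax, drop = FALSE] == id
  h <- nrow(sub); w <- ncol(sub)
  heights <- integer(w)
  best <- c(area = 0L, r1 = 0L, c1 = 0L, r2 = 0L, c2 = 0L)
  for (i in seq_len(h)) {
    heights <- ifelse(sub[i, ], heights + 1L, 0L)
    # largest rectangle in histogram `heights` ending at row i
    stackPos <- integer(w + 1L); stackH <- integer(w + 1L); top <- 0L
    for (j in seq_len(w + 1L)) {
      hj <- if (j <= w) heights[j] else 0L
      start <- j
      while (top > 0L && stackH[top] > hj) {
        area <- stackH[top] * (j - stackPos[top])
        if (area > best["area"]) {
          best <- c(area = area,
                    r1 = i - stackH[top] + 1L, c1 = stackPos[top],
                    r2 = i, c2 = j - 1L)
        }
        start <- stackPos[top]
        top <- top - 1L
      }
      if (top == 0L || stackH[top] < hj) {
        top <- top + 1L
        stackPos[top] <- start
        stackH[top] <- hj
      }
    }
  }
  if (best["area"] == 0L) stop("region ", id, " is empty")
  c(rowMin = as.integer(best["r1"] + row$rowMin - 1L),
    colMin = as.integer(best["c1"] + row$colMin - 1L),
    rowMax = as.integer(best["r2"] + row$rowMin - 1L),
    colMax = as.integer(best["c2"] + row$colMin - 1L))
}

# Fill each 8-connected component of `mask` with its convex hull, iterating
# until stable (overlapping hulls merge, and the merged component is then
# hulled again), so every final component is convex. Returns a logical matrix.
convexHullFill <- function(mask) {
  for (iter in 1:10) {
    out <- convexHullFillOnce(mask)
    if (identical(out, mask)) return(out)
    mask <- out
  }
  mask
}

convexHullFillOnce <- function(mask) {
  rs <- labelRegions(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (regionCount(rs) == 0L) return(out)
  lm <- rs@labelMap
  for (i in seq_len(regionCount(rs))) {
    pts <- which(lm == i, arr.ind = TRUE)
    if (nrow(pts) <= 2L) { out[pts] <- TRUE; next }
    hull <- grDevices::chull(pts[, 2L], pts[, 1L])   # (x = col, y = row)
    hx <- pts[hull, 2L]; hy <- pts[hull, 1L]
    # force clockwise orientation (in x right / y down screen coordinates)
    signedArea <- sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)
    if (signedArea > 0) { hx <- rev(hx); hy <- rev(hy) }
    reg <- rs@regions[i, ]
    rr <- reg$rowMin:reg$rowMax; cc <- reg$colMin:reg$colMax
    gy <- matrix(rr, length(rr), length(cc))
    gx <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    nh <- length(hull)
    inside <- matrix(TRUE, length(rr), length(cc))
    # chull returns vertices clockwise in (x, y): interior has cross <= 0
    for (k in seq_len(nh)) {
      k2 <- if (k == nh) 1L else k + 1L
      cross <- (hx[k2] - hx[k]) * (gy - hy[k]) - (hy[k2] - hy[k]) * (gx - hx[k])
      inside <- inside & cross <= 1e-9
    }
    sub <- out[rr, cc, drop = FALSE]
    out[rr, cc] <- sub | inside
  }
  out
}
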