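# Low-level 3D grid helpers shared by segmentation and texture code.
# Masks are logical 3D arrays; levels are integer arrays with NA outside the
# region of interest. All neighbourhood logic is 26-connected unless stated.

#' The 13 unique direction offsets of the 26-neighbourhood
#'
#' Opposite offsets are redundant for symmetric matrices (co-occurrence,
#' runs), so one representative per axis is kept.
#'
#' @return integer matrix, 13 rows, columns (dx, dy, dz)
#' @keywords internal
offsets13 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(off, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(off[keep, , drop = FALSE])
}

#' All 26 neighbour offsets
#' @keywords internal
offsets26 <- function() {
  off <- offsets13()
  rbind(off, -off)
}

#' The 6 face-neighbour offsets
#' @keywords internal
offsets6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

#' The 18 face+edge neighbour offsets
#' @keywords internal
offsets18 <- function() {
  off <- offsets26()
  off[rowSums(abs(off)) <= 2, , drop = FALSE]
}

#' Shift a 3D array by an integer offset, filling exposed entries
#'
#' `out[i,j,k] = a[i - d1, j - d2, k - d3]` where defined, `fill` elsewhere.
#' @keywords internal
shift3d <- function(a, d, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(n - d[ax]) + d[ax]
      src[[ax]] <- seq_len(n - d[ax])
    } else {
      dst[[ax]] <- seq_len(n + d[ax])
      src[[ax]] <- seq_len(n + d[ax]) - d[ax]
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation with the 26-neighbourhood structuring element
#' @keywords internal
dilate26 <- function(mask, iter = 1L) {
  m <- mask
  off <- offsets26()
  for (it in seq_len(iter)) {
    acc <- m
    for (r in seq_len(nrow(off))) {
      acc <- acc | shift3d(m, off[r, ], fill = FALSE)
    }
    m <- acc
  }
  m
}

#' Label 26-connected components of a 3D logical mask
#'
#' Builds the adjacency graph over in-mask voxels (13 unique shifts) and
#' labels with igraph. Suited to the lesion-scale masks this package
#' manipulates.
#'
#' @return integer array, 0 outside the mask, component id (1..n) inside
#' @keywords internal
label_components26 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  if (length(idx) == 1) {
    lab[idx] <- 1L
    return(lab)
  }
  pos <- arrayInd(idx, dm)
  id_of <- array(0L, dm)
  id_of[idx] <- seq_along(idx)
  off <- offsets13()
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    d <- off[r, ]
    nb <- pos + matrix(d, nrow(pos), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    nb_id <- id_of[nb_lin]
    src <- which(ok)[nb_id > 0]
    if (length(src) == 0) next
    edges[[r]] <- rbind(src, nb_id[nb_id > 0])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && ncol(em) > 0) g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Grow the 26-connected component of `inside` that contains `seed`
#'
#' Iterative dilate-and-intersect flood fill; terminates because the region
#' is monotone nondecreasing and bounded by `inside`.
#' @keywords internal
flood26 <- function(inside, seed_lin) {
  m <- array(FALSE, dim(inside))
  m[seed_lin] <- TRUE
  repeat {
    grown <- dilate26(m) & inside
    if (sum(grown) == sum(m)) return(m)
    m <- grown
  }
}

#' Separable convolution with clamp-to-edge padding along one axis
#' @keywords internal
conv1d_axis <- function(a, kernel, axis) {
  n <- dim(a)[axis]
  rad <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (t in seq_along(kernel)) {
    d <- t - rad - 1L
    idx <- pmin(pmax(seq_len(n) - d, 1L), n)
    out <- out + kernel[t] * switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE]
    )
  }
  out
}

#' Anisotropic 3D Gaussian smoothing (separable, sigma in voxels per axis)
#' @keywords internal
gauss_smooth3d <- function(a, sigma_vox) {
  out <- a
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-rad, rad))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- conv1d_axis(out, k, ax)
  }
  out
}

#' Bounding box of a mask with margin, clipped to the grid
#' @keywords internal
mask_bbox <- function(mask, margin = 0L) {
  stopifnot(any(mask))
  dm <- dim(mask)
  pos <- arrayInd(which(mask), dm)
  lo <- pmax(apply(pos, 2, min) - margin, 1L)
  hi <- pmin(apply(pos, 2, max) + margin, dm)
  list(lo = lo, hi = hi)
}
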