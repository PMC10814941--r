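#' Ultrasound ROI masks and shape descriptors
#'
#' A lesion region of interest on a high-frequency ultrasound image is a
#' binary mask with pixel-spacing metadata. Two independent annotators
#' outline each lesion; analysis runs on the consensus (intersection) region.
#' Thirteen shape and size descriptors are emitted in physical units (mm /
#' mm2), so anisotropic pixel spacing is handled by working in mm
#' coordinates.
#'
#' @name us
NULL

#' Construct a binary ROI mask
#'
#' @param mask Logical or 0/1 matrix; `TRUE`/1 is lesion.
#' @param spacing_mm Length-2 numeric: (row spacing, column spacing) in mm.
#' @return A `roi_mask` object (logical matrix with a `spacing_mm`
#'   attribute).
#' @export
roi_mask <- function(mask, spacing_mm = c(0.1, 0.1)) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) {
    rlang::abort("mask has no foreground pixels",
                 class = "dermofuse_invalid_mask")
  }
  if (length(spacing_mm) != 2L || any(spacing_mm <= 0)) {
    rlang::abort("spacing_mm must be two positive numbers",
                 class = "dermofuse_invalid_mask")
  }
  structure(mask, spacing_mm = as.numeric(spacing_mm),
            class = c("roi_mask", "matrix"))
}

# 8-connected component labelling (flood fill). EBImage::bwlabel is
# 4-connected, which would split diagonal necks the annotators consider one
# lesion.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack[1L] <- start
    top <- 1L
    lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1L && rr <= nr && ccc >= 1L && ccc <= nc) {
          q <- (ccc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  lab
}

largest_component <- function(mask) {
  # fast path: 4-connected labels (EBImage), then merge labels that touch
  # diagonally to get 8-connectivity
  lab4 <- EBImage::bwlabel(mask * 1L)
  n4 <- max(lab4)
  if (n4 == 0L) return(mask & FALSE)
  if (n4 == 1L) return(mask)
  parent <- seq_len(n4)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  merge_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    for (k in which(keep)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab4); nc <- ncol(lab4)
  merge_pairs(as.integer(lab4[-1, -1]), as.integer(lab4[-nr, -nc]))  # \ diagonal
  merge_pairs(as.integer(lab4[-1, -nc]), as.integer(lab4[-nr, -1]))  # / diagonal
  root <- vapply(seq_len(n4), find, integer(1))
  lab8 <- matrix(0L, nr, nc)
  lab8[lab4 > 0L] <- root[lab4[lab4 > 0L]]
  sizes <- tabulate(lab8[lab8 > 0L])
  lab8 == which.max(sizes)
}

#' Two-annotator consensus ROI
#'
#' Pixelwise intersection of the two annotators' masks, reduced to its
#' largest 8-connected component.
#'
#' @param mask_a,mask_b [roi_mask()] objects on the same grid and spacing.
#' @return The consensus `roi_mask`.
#' @export
consensus_roi <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      !isTRUE(all.equal(attr(mask_a, "spacing_mm"), attr(mask_b, "spacing_mm")))) {
    rlang::abort("annotator masks must share grid size and pixel spacing",
                 class = "dermofuse_invalid_mask")
  }
  inter <- unclass(mask_a) & unclass(mask_b)
  if (!any(inter)) {
    rlang::abort("annotator ROIs do not intersect: no consensus region",
                 class = "dermofuse_no_consensus")
  }
  roi_mask(largest_component(inter), attr(mask_a, "spacing_mm"))
}

# Moore-neighbor boundary tracing (clockwise in image coordinates); returns
# an ordered (row, col) matrix of boundary pixels of a single 8-connected
# component. Stops when the (start pixel -> second pixel) transition repeats.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  start <- which(mask)[1]                 # column-major: leftmost column first
  sr <- ((start - 1L) %% nr) + 1L
  sc <- ((start - 1L) %/% nr) + 1L
  if (sum(mask) == 1L) return(matrix(c(sr, sc), ncol = 2))
  # clockwise Moore neighborhood starting from "west"
  moves <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                 c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  cap <- sum(mask) * 4L + 8L
  path <- matrix(NA_integer_, cap, 2L)
  path[1, ] <- c(sr, sc)
  np <- 1L
  scan_from <- 1L  # the west neighbor of the start pixel is background
  r <- sr; c <- sc
  second <- NULL
  repeat {
    d_found <- NA_integer_
    for (k in 0:7) {
      d <- ((scan_from - 1L + k) %% 8L) + 1L
      rr <- r + moves[d, 1L]; cc <- c + moves[d, 2L]
      if (inside(rr, cc)) { d_found <- d; break }
    }
    if (is.na(d_found)) return(path[seq_len(np), , drop = FALSE])
    rr <- r + moves[d_found, 1L]; cc <- c + moves[d_found, 2L]
    if (!is.null(second) && r == sr && c == sc &&
        rr == second[1] && cc == second[2]) {
      # the start pixel was re-appended on re-entry; keep one copy only
      if (np > 1L && path[np, 1L] == sr && path[np, 2L] == sc) np <- np - 1L
      return(path[seq_len(np), , drop = FALSE])
    }
    if (is.null(second)) second <- c(rr, cc)
    np <- np + 1L
    if (np > cap) return(path[seq_len(np - 1L), , drop = FALSE])
    path[np, ] <- c(rr, cc)
    # resume the clockwise scan one step past the direction that points back
    # to the pixel we came from
    scan_from <- ((d_found + 4L) %% 8L) + 1L
    r <- rr; c <- cc
  }
}

# convex-region pixel count: pixels of the bounding box whose centers lie
# inside (or on) the convex hull of the foreground pixel centers
convex_pixel_count <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)          # (row, col)
  if (nrow(pts) <= 2L) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])   # x = col, y = row
  hull <- pts[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh <= 2L) return(nrow(pts))
  rows <- min(pts[, 1]):max(pts[, 1])
  cols <- min(pts[, 2]):max(pts[, 2])
  grid <- expand.grid(row = rows, col = cols)
  inside <- rep(TRUE, nrow(grid))
  for (k in seq_len(nh)) {
    a <- hull[k, ]; b <- hull[(k %% nh) + 1L, ]
    # chull returns clockwise order in (x, y); with y = row pointing down this
    # is counterclockwise, so interior points have nonnegative cross product
    cr <- (b[2] - a[2]) * (grid$row - a[1]) - (b[1] - a[1]) * (grid$col - a[2])
    inside <- inside & (cr <= 1e-9)
  }
  sum(inside)
}

#' Shape descriptors of a consensus lesion ROI
#'
#' Thirteen geometric descriptors, emitted in physical units:
#' \describe{
#'   \item{Area}{foreground pixel count x pixel area (mm2).}
#'   \item{Perimeter}{sum of Euclidean distances between consecutive boundary
#'     pixels of the 8-connected boundary chain, with per-axis mm scaling.}
#'   \item{Circularity}{4 pi Area / Perimeter^2 (1 for a circle).}
#'   \item{EquivDiameter}{diameter of the circle with the same area,
#'     sqrt(4 Area / pi) (mm).}
#'   \item{Tortuosity}{Perimeter / Area (1/mm).}
#'   \item{Eccentricity, MajorAxisLength, MinorAxisLength, Orientation}{from
#'     the ellipse with the same normalized second central moments as the
#'     region (computed in mm coordinates); eccentricity is the ratio of the
#'     distance between the foci to the major axis; orientation is the angle
#'     between the major axis and the horizontal image axis,
#'     counterclockwise-positive, in (-90, 90] degrees.}
#'   \item{FilledArea}{area after hole filling (mm2).}
#'   \item{MaxFeretDiameter, MaxFeretAngle}{maximum pairwise distance between
#'     boundary pixels (mm) and the angle of that pair to the horizontal
#'     axis, in (-90, 90] degrees.}
#'   \item{Solidity}{Area / convex-hull area.}
#' }
#'
#' @param roi A consensus [roi_mask()] (single 8-connected component).
#' @return A one-row tibble with the 13 named descriptor columns.
#' @export
shape_features <- function(roi) {
  sp <- attr(roi, "spacing_mm")
  sy <- sp[1]; sx <- sp[2]
  mask <- unclass(roi)
  px_area <- sy * sx
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  area <- n * px_area

  # boundary chain and perimeter
  bd <- trace_boundary(mask)
  if (nrow(bd) > 1L) {
    closed <- rbind(bd, bd[1, ])
    steps <- diff(closed)
    perim <- sum(sqrt((steps[, 1] * sy)^2 + (steps[, 2] * sx)^2))
  } else {
    perim <- 0
  }

  # moment-of-inertia ellipse in mm coordinates; y axis points up so the
  # orientation is counterclockwise-positive on the displayed image
  x <- pts[, 2] * sx
  y <- -pts[, 1] * sy
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (l1 <= 0) 0 else sqrt(1 - l2 / l1)
  orient <- if (common == 0) 0 else 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  orient <- wrap_half_circle(orient)

  filled <- sum(EBImage::fillHull(mask * 1L) > 0) * px_area

  # maximum Feret diameter over convex-hull vertices of the boundary chain
  bx <- bd[, 2] * sx
  by <- -bd[, 1] * sy
  if (nrow(bd) > 2L) {
    h <- grDevices::chull(bx, by)
    hx <- bx[h]; hy <- by[h]
  } else {
    hx <- bx; hy <- by
  }
  dmat <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  imax <- arrayInd(which.max(dmat), dim(dmat))
  feret <- sqrt(dmat[imax])
  fangle <- if (feret == 0) 0 else
    atan2(hy[imax[2]] - hy[imax[1]], hx[imax[2]] - hx[imax[1]]) * 180 / pi
  fangle <- wrap_half_circle(fangle)

  solidity <- n / convex_pixel_count(mask)

  tibble::tibble(
    Area = area,
    Perimeter = perim,
    Circularity = if (perim > 0) 4 * pi * area / perim^2 else NA_real_,
    EquivDiameter = sqrt(4 * area / pi),
    Tortuosity = perim / area,
    Eccentricity = ecc,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Orientation = orient,
    FilledArea = filled,
    MaxFeretDiameter = feret,
    Solidity = solidity,
    MaxFeretAngle = fangle)
}

# map an angle in degrees to (-90, 90]
wrap_half_circle <- function(a) {
  a <- ((a + 90) %% 180) - 90
  if (a <= -90) a + 180 else if (a > 90) a - 180 else if (a == -90) 90 else a
}
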