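#' Membrane-ridge binarization by directional local thresholding
#'
#' A pixel is a cell-contour pixel (CCP) when, in at least one of the
#' four principal directions (horizontal, vertical, two diagonals), its
#' intensity is at least `ratio_f` times the intensity of BOTH flanking
#' pixels at distance `offset_d` - a ridge test selecting the bright
#' membrane against both the dark exterior and the dimmer cytoplasm.
#' Only the largest 8-connected component is kept.
#'
#' @param image numeric matrix (grayscale intensities).
#' @param offset_d flank distance in pixels (>= 2).
#' @param ratio_f intensity ratio (>= 1).
#' @return logical matrix (the CCP mask).
#' @export
binarize_local_threshold <- function(image, offset_d = 4, ratio_f = 1.3) {
  stopifnot(is.matrix(image), offset_d >= 2, ratio_f >= 1)
  nr <- nrow(image)
  nc <- ncol(image)
  shift <- function(dy, dx) {
    out <- matrix(Inf, nr, nc) # missing flank counts against ridge-ness
    ys <- seq_len(nr) + dy
    xs <- seq_len(nc) + dx
    oky <- ys >= 1 & ys <= nr
    okx <- xs >= 1 & xs <= nc
    out[oky, okx] <- image[ys[oky], xs[okx]]
    out
  }
  mask <- matrix(FALSE, nr, nc)
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- shift(d[1] * offset_d, d[2] * offset_d)
    b <- shift(-d[1] * offset_d, -d[2] * offset_d)
    mask <- mask | (image >= ratio_f * a & image >= ratio_f * b)
  }
  if (!any(mask)) stop("no membrane detected: empty CCP mask")
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0])
  mask & (lab == which.max(sizes))
}

# Flood-fill connected-component labelling (4- or 8-connectivity).
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dy <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dx <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dy <- c(-1, 1, 0, 0)
    dx <- c(0, 0, -1, 1)
  }
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue
      queue <- integer(0)
      py <- (p - 1L) %% nr + 1L
      px <- (p - 1L) %/% nr + 1L
      for (k in seq_along(dy)) {
        qy <- py + dy[k]
        qx <- px + dx[k]
        ok <- qy >= 1 & qy <= nr & qx >= 1 & qx <= nc
        q <- (qx[ok] - 1L) * nr + qy[ok]
        q <- q[mask[q] & lab[q] == 0L]
        if (length(q)) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Trace the inner boundary of the CCP annulus (BP1)
#'
#' Identifies the enclosed cytoplasmic region (the complement component
#' not touching the image border) and walks the CCP pixels facing it
#' with Moore boundary following, returning a closed ordered cycle.
#'
#' @param ccp_mask logical matrix from [binarize_local_threshold()].
#' @return integer matrix (k x 2) of 0-based (row, col) pixel centres,
#'   ordered along the boundary, first pixel not repeated at the end.
#' @export
trace_bp1 <- function(ccp_mask) {
  nr <- nrow(ccp_mask)
  nc <- ncol(ccp_mask)
  lab <- label_components(ccp_mask, 8)
  if (max(lab) != 1) stop("segmentation failure: CCP mask is not a single component")
  comp <- label_components(!ccp_mask, 4)
  border_ids <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
  border_ids <- border_ids[border_ids > 0]
  hole_ids <- setdiff(seq_len(max(comp)), border_ids)
  if (length(hole_ids) == 0) stop("segmentation failure: no enclosed cytoplasmic region")
  if (length(hole_ids) > 1) {
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    hole_ids <- hole_ids[sizes[hole_ids] > 2] # ignore speck holes
    if (length(hole_ids) != 1) stop("segmentation failure: multiple enclosed holes")
  }
  hole <- comp == hole_ids
  # start: a mask pixel 4-adjacent to the hole, with its hole neighbour as
  # the Moore backtrack
  idx <- which(hole)
  py <- (idx - 1L) %% nr + 1L
  px <- (idx - 1L) %/% nr + 1L
  start <- NULL
  for (k in seq_along(idx)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      y <- py[k] + d[1]
      x <- px[k] + d[2]
      if (y >= 1 && y <= nr && x >= 1 && x <= nc && ccp_mask[y, x]) {
        start <- c(y, x)
        back <- c(py[k], px[k])
        break
      }
    }
    if (!is.null(start)) break
  }
  moore_trace(ccp_mask, start, back)
}

# Moore-neighbour tracing with Jacob's stopping criterion. Returns 0-based
# (row, col) cycle.
moore_trace <- function(mask, start, back) {
  nbr <- matrix(
    c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
    ncol = 2, byrow = TRUE
  ) # clockwise ring starting north
  nr <- nrow(mask)
  nc <- ncol(mask)
  pos_of <- function(cur, p) {
    d <- c(p[1] - cur[1], p[2] - cur[2])
    which(nbr[, 1] == d[1] & nbr[, 2] == d[2])
  }
  cur <- start
  prev <- back
  out <- matrix(start, 1, 2)
  second <- NULL
  for (iter in seq_len(8L * sum(mask) + 16L)) {
    k0 <- pos_of(cur, prev)
    nxt <- NULL
    for (j in 1:8) {
      k <- (k0 - 1L + j - 1L) %% 8L + 1L
      y <- cur[1] + nbr[k, 1]
      x <- cur[2] + nbr[k, 2]
      if (y >= 1 && y <= nr && x >= 1 && x <= nc && mask[y, x]) {
        nxt <- c(y, x)
        kprev <- (k - 1L - 1L) %% 8L + 1L
        prev <- c(cur[1] + nbr[kprev, 1], cur[2] + nbr[kprev, 2])
        break
      }
    }
    if (is.null(nxt)) stop("open curve: boundary following failed")
    # stop when about to repeat the initial (start -> second) transition
    if (!is.null(second) && all(cur == start) && all(nxt == second)) break
    if (is.null(second)) second <- nxt
    out <- rbind(out, nxt)
    cur <- nxt
  }
  # the cycle closed by re-entering start: drop the duplicate final row
  if (nrow(out) > 1 && all(out[nrow(out), ] == start)) out <- out[-nrow(out), , drop = FALSE]
  unname(out) - 1L
}

#' Curvature-adaptive subsampling of the boundary (BP2)
#'
#' Walks the BP1 cycle; with Line1 the line through the two previously
#' accepted points, the next point is the first whose perpendicular
#' distance from Line1 exceeds `min_line_dist` pixels, so flat runs are
#' sampled sparsely and curved runs densely. Where the interior angle at
#' an accepted point between its incoming and outgoing chords falls
#' below pi/2 (an acute hairpin, e.g. inside the furrow), the midpoint
#' pixel of the skipped boundary run is inserted.
#'
#' @param bp1 integer matrix (k x 2) from [trace_bp1()].
#' @param min_line_dist acceptance distance in pixels (default 2).
#' @return integer matrix (j x 2), ordered and closed (first != last);
#'   attribute "inserted" flags inserted hairpin points.
#' @export
subsample_bp2 <- function(bp1, min_line_dist = 2) {
  k <- nrow(bp1)
  stopifnot(k >= 8)
  pt <- function(i) bp1[(i - 1L) %% k + 1L, ]
  acc <- 1L # indices into bp1
  # second point: first at euclidean distance > min_line_dist from start
  i <- 2L
  while (sqrt(sum((pt(i) - pt(1L))^2)) <= min_line_dist && i < k) i <- i + 1L
  acc <- c(acc, i)
  inserted <- c(FALSE, FALSE)
  repeat {
    a <- pt(acc[length(acc) - 1L])
    b <- pt(acc[length(acc)])
    u <- b - a
    un <- sqrt(sum(u^2))
    j <- acc[length(acc)] + 1L
    found <- FALSE
    while (j <= acc[length(acc)] + k) {
      p <- pt(j)
      dist <- abs(u[1] * (p[2] - a[2]) - u[2] * (p[1] - a[1])) / un
      if (dist > min_line_dist) {
        found <- TRUE
        break
      }
      j <- j + 1L
    }
    if (!found || j - k >= acc[2]) break
    # hairpin check at b: interior angle between (a - b) and (p - b)
    p <- pt(j)
    v1 <- a - b
    v2 <- p - b
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
      (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
    if (is.finite(ang) && ang < pi / 2 && j - acc[length(acc)] >= 2L) {
      h <- acc[length(acc)] + (j - acc[length(acc)]) %/% 2L
      acc <- c(acc, h)
      inserted <- c(inserted, TRUE)
    }
    if (j > k) break # wrapped past the start
    acc <- c(acc, j)
    inserted <- c(inserted, FALSE)
  }
  keep <- acc <= k
  acc <- acc[keep]
  inserted <- inserted[keep]
  if (length(acc) < 5) stop("degenerate contour: fewer than 5 BP2 points")
  out <- bp1[acc, , drop = FALSE]
  attr(out, "inserted") <- inserted
  out
}

#' Discrete curvature from circumcircle normals
#'
#' For each BP2 point the normal is the line through the point and the
#' centre of the circumcircle of its neighbour triple. For each arc
#' (i, i+1) the normals of its endpoints cross at a point X and the arc
#' curvature is the reciprocal of the mean distance from X to the two
#' endpoints (exactly 1/R on a circle). The sign is negative when X lies
#' outside the cell polygon (concave arc, as inside the furrow). A
#' collinear triple has an infinite circumradius and contributes zero
#' curvature.
#'
#' @param bp2 numeric matrix (j x 2) of ordered boundary points (pixel
#'   or physical coordinates), closed cycle (first != last).
#' @param scale physical units per pixel (1 to stay in pixel units).
#' @return list with `C_m` (per-arc curvature, units 1/(pixel*scale)),
#'   `arc_mid` (arc midpoints), `normals` (per-point unit normal
#'   directions), `centers` (per-point circumcentres, NA when collinear).
#' @export
curvature_from_normals <- function(bp2, scale = 1) {
  p <- as.matrix(bp2)
  j <- nrow(p)
  stopifnot(j >= 5, scale > 0)
  centroid <- colMeans(p)
  centers <- matrix(NA_real_, j, 2)
  normals <- matrix(NA_real_, j, 2)
  for (i in seq_len(j)) {
    a <- p[(i - 2L) %% j + 1L, ]
    b <- p[i, ]
    cc <- p[i %% j + 1L, ]
    ctr <- circumcenter(a, b, cc)
    if (any(!is.finite(ctr))) {
      # collinear: normal is the perpendicular of the chord, towards centroid
      ch <- cc - a
      nv <- c(-ch[2], ch[1])
      nv <- nv / sqrt(sum(nv^2))
      if (sum(nv * (centroid - b)) < 0) nv <- -nv
      normals[i, ] <- nv
    } else {
      centers[i, ] <- ctr
      nv <- ctr - b
      normals[i, ] <- nv / sqrt(sum(nv^2))
    }
  }
  C_m <- numeric(j)
  arc_mid <- matrix(0, j, 2)
  for (i in seq_len(j)) {
    i2 <- i %% j + 1L
    arc_mid[i, ] <- (p[i, ] + p[i2, ]) / 2
    X <- line_intersection(p[i, ], normals[i, ], p[i2, ], normals[i2, ])
    if (any(!is.finite(X))) {
      C_m[i] <- 0
      next
    }
    d <- (sqrt(sum((X - p[i, ])^2)) + sqrt(sum((X - p[i2, ])^2))) / 2
    if (d == 0) {
      C_m[i] <- 0
      next
    }
    sgn <- if (point_in_polygon(X, p)) 1 else -1
    C_m[i] <- sgn / (d * scale)
  }
  list(C_m = C_m, arc_mid = arc_mid, normals = normals, centers = centers)
}

circumcenter <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12 * max(1, sum(abs(c - a)))^2) {
    return(c(NA_real_, NA_real_))
  }
  ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
    (sum(c^2)) * (a[2] - b[2])) / d
  uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
    (sum(c^2)) * (b[1] - a[1])) / d
  c(ux, uy)
}

line_intersection <- function(p1, d1, p2, d2) {
  det <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(det) < 1e-12) {
    return(c(NA_real_, NA_real_))
  }
  t <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / det
  p1 + t * d1
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  x <- pt[1]
  y <- pt[2]
  inside <- FALSE
  jj <- n
  for (ii in seq_len(n)) {
    xi <- poly[ii, 1]; yi <- poly[ii, 2]
    xj <- poly[jj, 1]; yj <- poly[jj, 2]
    if ((yi > y) != (yj > y) &&
      x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    jj <- ii
  }
  inside
}

#' Quantify one cell image (or BP2 set) into quadrant half-contours
#'
#' The rotational axis is the principal second-moment axis of the BP2
#' point set through its centroid; the equatorial plane is perpendicular
#' to it at the interior minimum of the radius envelope within the
#' central 50 percent of the axis span (midpoint fallback when there is
#' no interior minimum). The contour cycle is split into four quadrants
#' by the axis and the equatorial plane; each is re-parameterized pole to
#' equator, converted to model units, and summarized on a uniform s grid
#' with r, z, curvatures (C_m from circumcircle normals, kernel-smoothed
#' along s; C_p from the reconstructed meridian), plus per-quadrant
#' solids-of-revolution volume and area (full-cell equivalents) and the
#' furrow radius. C_p values at s < 0.2 carry large uncertainty (the
#' parallel radius is tiny near the pole) and are flagged, not dropped.
#'
#' @param x grayscale image matrix, or a BP2 point matrix (j x 2).
#' @param scale_um_per_px physical scale (micrometres per pixel).
#' @param offset_d,ratio_f binarization parameters (image input only).
#' @param m nodes of the per-quadrant s grid.
#' @param cm_bandwidth Gaussian kernel bandwidth (in s units) for
#'   smoothing the discrete C_m estimates.
#' @param units model unit system, see [model_units()].
#' @return list of 4 quadrant records (fields `s`, `r`, `z`, `C_m`,
#'   `C_p`, `cp_flag_pole`, `furrow_radius`, `volume`, `area`,
#'   `contour`); attributes "axis", "equator_method" record the choices.
#' @export
quantify_cell <- function(x, scale_um_per_px, offset_d = 4, ratio_f = 1.3,
                          m = 100, cm_bandwidth = 0.08,
                          refine_subpixel = TRUE, units = model_units()) {
  from_image <- !(is.matrix(x) && ncol(x) == 2)
  if (from_image) {
    mask <- binarize_local_threshold(x, offset_d, ratio_f)
    bp2 <- subsample_bp2(trace_bp1(mask))
  } else {
    bp2 <- x
  }
  bp2 <- as.matrix(bp2) * 1.0
  # the walk's seed can leave a near-duplicate point pair whose tiny
  # chord destabilizes the circumcircle normals; prune points much
  # closer to their predecessor than the typical spacing
  if (nrow(bp2) > 8) {
    ch <- sqrt(rowSums((bp2 - bp2[c(nrow(bp2), 1:(nrow(bp2) - 1)), ])^2))
    keep <- ch >= 0.25 * stats::median(ch)
    keep[1] <- TRUE
    if (sum(keep) >= 5) bp2 <- bp2[keep, , drop = FALSE]
  }
  if (from_image && refine_subpixel) bp2 <- refine_ridge_subpixel(x, bp2)
  cvn <- curvature_from_normals(bp2, scale = 1)
  px_to_unit <- scale_um_per_px / units$unit_length_um
  pts <- bp2 * px_to_unit
  cm_unit <- cvn$C_m / px_to_unit # 1/px -> model curvature units
  # arclength weights: BP2 points are unevenly spaced, and unweighted
  # moments would shift the centroid (hence the axis) towards densely
  # sampled stretches
  np <- nrow(pts)
  seg <- sqrt(rowSums((pts - pts[c(2:np, 1), ])^2))
  wt_arc <- (seg + seg[c(np, 1:(np - 1))]) / 2
  cw <- stats::cov.wt(pts, wt = wt_arc / sum(wt_arc))
  ctr <- cw$center
  ev <- eigen(cw$cov, symmetric = TRUE)
  axis_v <- ev$vectors[, 1]
  a <- (pts[, 1] - ctr[1]) * axis_v[1] + (pts[, 2] - ctr[2]) * axis_v[2]
  b <- -(pts[, 1] - ctr[1]) * axis_v[2] + (pts[, 2] - ctr[2]) * axis_v[1]

  eq <- locate_equator(a, b)
  runs <- split_quadrants(a, b, eq$a_eq)
  out <- lapply(runs, function(idx) {
    build_quadrant(a, b, idx, cm_unit, eq$a_eq,
      m = m, cm_bandwidth = cm_bandwidth
    )
  })
  attr(out, "axis") <- axis_v
  attr(out, "equator_method") <- eq$method
  out
}

# subpixel ridge centering: shift each boundary point along its local
# normal to the intensity-weighted centroid of the membrane profile.
# A second pass recomputes the normals from the refined points, which
# removes the radial bias left by integer-pixel normals.
refine_ridge_subpixel <- function(img, bp2, halfwidth = 3, step = 0.25,
                                  passes = 2) {
  out <- bp2
  offs <- seq(-halfwidth, halfwidth, by = step)
  for (p in seq_len(passes)) {
    nrm <- curvature_from_normals(out, scale = 1)$normals
    for (i in seq_len(nrow(out))) {
      py <- out[i, 1] + 1 + offs * nrm[i, 1] # 0-based -> 1-based
      px <- out[i, 2] + 1 + offs * nrm[i, 2]
      w <- bilinear_sample(img, py, px)
      w <- w - min(w)
      if (sum(w) <= 0) next
      shift <- sum(w * offs) / sum(w)
      out[i, ] <- out[i, ] + shift * nrm[i, ]
    }
  }
  out
}

bilinear_sample <- function(img, y, x) {
  nr <- nrow(img)
  nc <- ncol(img)
  y <- pmin(pmax(y, 1), nr - 1e-9)
  x <- pmin(pmax(x, 1), nc - 1e-9)
  y0 <- pmin(floor(y), nr - 1)
  x0 <- pmin(floor(x), nc - 1)
  fy <- y - y0
  fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

locate_equator <- function(a, b) {
  rng <- range(a)
  span <- diff(rng)
  nb <- 41
  brks <- seq(rng[1], rng[2], length.out = nb + 1)
  mid <- (brks[-1] + brks[-(nb + 1)]) / 2
  env <- vapply(seq_len(nb), function(i) {
    sel <- a >= brks[i] & a <= brks[i + 1]
    if (!any(sel)) NA_real_ else max(abs(b[sel]))
  }, numeric(1))
  ok <- which(!is.na(env))
  env_s <- stats::supsmu(mid[ok], env[ok])$y
  central <- which(mid[ok] > rng[1] + 0.25 * span & mid[ok] < rng[2] - 0.25 * span)
  if (length(central) >= 3) {
    loc <- central[which.min(env_s[central])]
    depth <- 0.005 * max(env_s) # require a real dip, not jitter
    interior <- loc > min(central) && loc < max(central) &&
      env_s[loc] < env_s[min(central)] - depth &&
      env_s[loc] < env_s[max(central)] - depth
    if (interior) {
      return(list(a_eq = mid[ok][loc], method = "interior_r_minimum"))
    }
  }
  list(a_eq = mean(rng), method = "axis_midpoint")
}

split_quadrants <- function(a, b, a_eq) {
  n <- length(a)
  lab <- ifelse(a < a_eq, 0L, 1L) * 2L + ifelse(b >= 0, 0L, 1L) + 1L
  idx_runs <- split(seq_len(n), cumsum(c(1, diff(lab) != 0)))
  if (length(idx_runs) > 1 &&
    lab[idx_runs[[1]][1]] == lab[rev(idx_runs[[length(idx_runs)]])[1]]) {
    idx_runs[[1]] <- c(idx_runs[[length(idx_runs)]], idx_runs[[1]])
    idx_runs[[length(idx_runs)]] <- NULL
  }
  lens <- vapply(idx_runs, length, integer(1))
  idx_runs <- idx_runs[lens >= 5]
  if (length(idx_runs) < 4) stop("quadrant split failed: fragmented contour")
  unname(idx_runs[order(lens[lens >= 5], decreasing = TRUE)][1:4])
}

# Build one pole-to-equator half-contour from a quadrant run of the
# cycle. The run's cyclic neighbours are used to interpolate exact
# anchor points where the boundary crosses the rotation axis (b = 0,
# the pole, r = 0 there) and the equatorial plane (a = a_eq), so the
# reconstructed meridian spans the full pole-to-equator range even
# though the sampled points stop short of it.
build_quadrant <- function(a, b, idx, cm_unit, a_eq, m, cm_bandwidth) {
  n <- length(a)
  cyc <- function(i) (i - 1L) %% n + 1L
  side <- function(i) a[i] < a_eq
  # anchor on the local circumcircular arc through (second inside point,
  # inside point, outside neighbour): exact on circular boundaries, far
  # more accurate than linear interpolation over wide BP2 chords
  cross_point <- function(i_in2, i_in, i_out) {
    p2 <- c(a[i_in2], b[i_in2])
    p1 <- c(a[i_in], b[i_in])
    p0 <- c(a[i_out], b[i_out])
    lin <- function(frac) p1 + frac * (p0 - p1)
    ctr <- circumcenter(p2, p1, p0)
    type <- NULL
    if (sign(b[i_in]) != sign(b[i_out])) {
      frac_lin <- abs(p1[2]) / (abs(p1[2]) + abs(p0[2]))
      pt <- lin(frac_lin)
      pt[2] <- 0
      type <- "pole"
      if (all(is.finite(ctr))) {
        R2 <- sum((p1 - ctr)^2)
        disc <- R2 - ctr[2]^2
        if (disc >= 0) {
          roots <- ctr[1] + c(-1, 1) * sqrt(disc)
          pt <- c(roots[which.min(abs(roots - pt[1]))], 0)
        }
      }
    } else if (side(i_in) != side(i_out)) {
      frac_lin <- abs(p1[1] - a_eq) / abs(p1[1] - p0[1])
      pt <- lin(frac_lin)
      pt[1] <- a_eq
      type <- "equator"
      if (all(is.finite(ctr))) {
        R2 <- sum((p1 - ctr)^2)
        disc <- R2 - (a_eq - ctr[1])^2
        if (disc >= 0) {
          roots <- ctr[2] + c(-1, 1) * sqrt(disc)
          pt <- c(a_eq, roots[which.min(abs(roots - pt[2]))])
        }
      }
    } else {
      return(NULL)
    }
    list(pt = pt, type = type)
  }
  head_anchor <- cross_point(
    idx[min(2L, length(idx))], idx[1], cyc(idx[1] - 1L)
  )
  tail_anchor <- cross_point(
    idx[max(1L, length(idx) - 1L)], idx[length(idx)],
    cyc(idx[length(idx)] + 1L)
  )

  aq <- a[idx]
  bq <- b[idx]
  arc_orig <- rep(TRUE, length(idx)) # marks original (non-anchor) points
  if (!is.null(head_anchor)) {
    aq <- c(head_anchor$pt[1], aq)
    bq <- c(head_anchor$pt[2], bq)
    arc_orig <- c(FALSE, arc_orig)
  }
  if (!is.null(tail_anchor)) {
    aq <- c(aq, tail_anchor$pt[1])
    bq <- c(bq, tail_anchor$pt[2])
    arc_orig <- c(arc_orig, FALSE)
  }
  # orient pole first: prefer the anchored pole end, else the end
  # farther from the equatorial plane
  pole_first <- if (!is.null(head_anchor) && head_anchor$type == "pole") {
    TRUE
  } else if (!is.null(tail_anchor) && tail_anchor$type == "pole") {
    FALSE
  } else {
    abs(aq[1] - a_eq) >= abs(aq[length(aq)] - a_eq)
  }
  if (!pole_first) {
    aq <- rev(aq)
    bq <- rev(bq)
    arc_orig <- rev(arc_orig)
    idx <- rev(idx)
  }
  r <- abs(bq)
  zax <- abs(aq - a_eq)
  z <- zax - zax[1] # pole at 0, decreasing towards the equator
  npt <- length(r)
  t_raw <- c(0, cumsum(sqrt(diff(r)^2 + diff(z)^2)))
  # arclength-parameterized smoothing splines of the measured meridian,
  # with the pole/equator anchors pinned by weight; reporting r and z
  # from the data avoids the drift a tangent-angle re-integration of
  # noisy points would accumulate
  wts <- rep(1, npt)
  wts[!arc_orig] <- 200
  dfr <- max(4, min(12, npt - 2))
  tg <- seq(0, t_raw[npt], length.out = m)
  r_s <- stats::predict(stats::smooth.spline(t_raw, r, w = wts, df = dfr), tg)$y
  z_s <- stats::predict(stats::smooth.spline(t_raw, z, w = wts, df = dfr), tg)$y
  if (!is.null(head_anchor) && head_anchor$type == "pole") r_s[1] <- 0
  r_s <- pmax(r_s, 0)
  z_s <- z_s - z_s[1]
  ct <- contour_from_rz(r_s, z_s, m = m)
  cv <- curvatures_of(ct)
  theta_s <- c(0, atan2(-diff(z_s), diff(r_s)))
  C_p_s <- sin(theta_s) / pmax(r_s, 1e-9)
  C_p_s[1] <- cv$C_m[1]

  # map normal-based arc curvatures onto the quadrant's s grid: arcs sit
  # between consecutive original cycle points
  t_poly <- c(0, cumsum(sqrt(diff(r)^2 + diff(z)^2)))
  s_poly <- t_poly / t_poly[length(t_poly)]
  orig_pos <- which(arc_orig)
  arc_ids <- integer(0)
  s_arc <- numeric(0)
  for (k in seq_len(length(orig_pos) - 1)) {
    i1 <- idx[k]
    i2 <- idx[k + 1]
    aid <- if (cyc(i1 + 1L) == i2) i1 else i2
    arc_ids <- c(arc_ids, aid)
    s_arc <- c(s_arc, (s_poly[orig_pos[k]] + s_poly[orig_pos[k + 1]]) / 2)
  }
  sg <- seq(0, 1, length.out = m)
  if (length(arc_ids) >= 2) {
    cmq <- cm_unit[arc_ids]
    # short arcs give unstable circumcircle estimates: despike with a
    # running median, weight arcs by chord length, and clip residual
    # outliers about the quadrant median
    if (length(cmq) >= 5) cmq <- stats::runmed(cmq, 3, endrule = "median")
    chord <- t_poly[orig_pos[-1]] - t_poly[orig_pos[-length(orig_pos)]]
    med <- stats::median(cmq)
    mad <- stats::mad(cmq, constant = 1.4826)
    cmq <- pmin(pmax(cmq, med - 2.5 * mad - 1e-12), med + 2.5 * mad + 1e-12)
    w <- outer(sg, s_arc, function(x, y) exp(-(x - y)^2 / (2 * cm_bandwidth^2)))
    w <- sweep(w, 2, chord, `*`)
    cm_s <- as.numeric(w %*% cmq) / pmax(rowSums(w), 1e-12)
  } else {
    cm_s <- cv$C_m
  }
  rm2 <- (r_s[-1] + r_s[-m])^2 / 4
  V_spl <- 2 * pi * sum(rm2 * (-diff(z_s)))
  A_spl <- 4 * pi * (sum(r_s) - (r_s[1] + r_s[m]) / 2) * (tg[2] - tg[1])
  list(
    s = sg, r = r_s, z = z_s, C_m = cm_s, C_p = C_p_s,
    cp_flag_pole = sg < 0.2,
    furrow_radius = r_s[m],
    volume = V_spl, area = A_spl,
    contour = ct
  )
}

#' Read a grayscale image (TIFF or PNG) as a matrix
#' @param path file path ending in .tif/.tiff/.png.
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
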