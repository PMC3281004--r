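#' Bin-averaged shape observation
#'
#' Aggregate of quadrant half-contours falling in one furrow-radius bin:
#' per-s mean and SD of the meridian coordinates and curvatures on a
#' common uniform s grid, plus mean volume, area and furrow radius.
#' Coordinates follow the model convention: pole at the origin, z
#' decreasing towards the equator, all in model length units.
#'
#' @param bin_label furrow-radius interval label, e.g. "0.6-0.5".
#' @param s common s grid.
#' @param r_mean,r_sd,z_mean,z_sd per-s statistics of the meridian.
#' @param Cm_mean,Cm_sd,Cp_mean,Cp_sd per-s curvature statistics.
#' @param volume,area mean volume and area (length-unit integrals).
#' @param furrow_radius mean furrow radius (length units).
#' @param n_samples number of quadrants aggregated.
#' @return object of class `shape_observation`.
#' @export
shape_observation <- function(bin_label, s, r_mean, r_sd, z_mean, z_sd,
                              Cm_mean, Cm_sd, Cp_mean, Cp_sd,
                              volume, area, furrow_radius, n_samples) {
  stopifnot(
    n_samples >= 1, length(s) >= 8,
    all(r_sd >= 0), all(z_sd >= 0), volume > 0, area > 0
  )
  structure(
    list(
      bin_label = bin_label, s = s,
      r_mean = r_mean, r_sd = r_sd, z_mean = z_mean, z_sd = z_sd,
      Cm_mean = Cm_mean, Cm_sd = Cm_sd, Cp_mean = Cp_mean, Cp_sd = Cp_sd,
      volume = volume, area = area, furrow_radius = furrow_radius,
      n_samples = n_samples
    ),
    class = "shape_observation"
  )
}

#' @export
print.shape_observation <- function(x, ...) {
  cat(sprintf(
    "shape_observation [%s]: n = %d, furrow radius = %.3f, V = %.3f, A = %.3f\n",
    x$bin_label, x$n_samples, x$furrow_radius, x$volume, x$area
  ))
  invisible(x)
}

#' Convert a contour into a single-sample observation
#'
#' Useful for fitting one known shape (e.g. a solved equilibrium) with
#' the inverse estimator; SDs are zero.
#'
#' @param contour an `axisym_contour`.
#' @param bin_label optional label.
#' @param m s-grid size.
#' @export
observation_from_contour <- function(contour, bin_label = "single", m = 50) {
  ct <- resample_to_s_grid(contour, m)
  cv <- curvatures_of(ct)
  z0 <- ct$z - ct$z[1]
  shape_observation(
    bin_label, ct$s, ct$r, rep(0, m), z0, rep(0, m),
    cv$C_m, rep(0, m), cv$C_p, rep(0, m),
    enclosed_volume(ct), surface_area(ct), ct$r[m], 1L
  )
}

#' Group quadrant half-contours into furrow-radius bins and average
#'
#' Each quadrant (a list with fields `s`, `r`, `z`, `C_m`, `C_p`,
#' `furrow_radius`, `volume`, `area`) is resampled onto a common uniform
#' s grid; quadrants are grouped into 0.1-unit furrow-radius bins and
#' per-s means and SDs computed. Empty bins yield no observation.
#'
#' @param cells list of quadrant records.
#' @param bin_edges descending vector of bin edges (default 0.9 ... 0.0).
#' @param m size of the common s grid.
#' @return list of `shape_observation`, ordered by descending bin.
#' @export
bin_and_average <- function(cells, bin_edges = seq(0.9, 0, by = -0.1), m = 50) {
  stopifnot(length(cells) >= 1, !is.unsorted(rev(bin_edges)))
  s_grid <- seq(0, 1, length.out = m)
  fr <- vapply(cells, function(q) q$furrow_radius, numeric(1))
  out <- list()
  for (i in seq_len(length(bin_edges) - 1)) {
    hi <- bin_edges[i]
    lo <- bin_edges[i + 1]
    sel <- which(fr <= hi & fr > lo)
    if (length(sel) == 0) next
    lab <- sprintf("%.1f-%.1f", hi, lo)
    res <- lapply(cells[sel], resample_quadrant, s_grid = s_grid)
    stat <- function(field) {
      mat <- vapply(res, `[[`, numeric(m), field)
      dim(mat) <- c(m, length(res))
      list(mean = rowMeans(mat), sd = apply(mat, 1, stats::sd))
    }
    r <- stat("r"); z <- stat("z"); cm <- stat("C_m"); cp <- stat("C_p")
    if (length(sel) == 1) {
      r$sd <- z$sd <- cm$sd <- cp$sd <- rep(0, m)
    }
    out[[lab]] <- shape_observation(
      lab, s_grid, r$mean, r$sd, z$mean, z$sd,
      cm$mean, cm$sd, cp$mean, cp$sd,
      mean(vapply(cells[sel], `[[`, numeric(1), "volume")),
      mean(vapply(cells[sel], `[[`, numeric(1), "area")),
      mean(fr[sel]), length(sel)
    )
  }
  out
}

resample_quadrant <- function(q, s_grid) {
  rs <- function(y) stats::approx(q$s, y, xout = s_grid, rule = 2)$y
  list(
    r = rs(q$r), z = rs(q$z - q$z[1]),
    C_m = rs(q$C_m), C_p = rs(q$C_p)
  )
}

#' Write / read observations as CSV
#'
#' Long format: one row per (bin, s) with mean/SD columns, plus the
#' per-bin scalars repeated (volume, area, furrow_radius, n_samples).
#'
#' @param observations list of `shape_observation`.
#' @param path file path.
#' @export
write_observations_csv <- function(observations, path) {
  rows <- lapply(observations, function(o) {
    data.frame(
      bin_label = o$bin_label, s = o$s,
      r_mean = o$r_mean, r_sd = o$r_sd,
      z_mean = o$z_mean, z_sd = o$z_sd,
      Cm_mean = o$Cm_mean, Cm_sd = o$Cm_sd,
      Cp_mean = o$Cp_mean, Cp_sd = o$Cp_sd,
      volume = o$volume, area = o$area,
      furrow_radius = o$furrow_radius, n_samples = o$n_samples
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$bin_label), function(d) {
    d <- d[order(d$s), ]
    shape_observation(
      d$bin_label[1], d$s, d$r_mean, d$r_sd, d$z_mean, d$z_sd,
      d$Cm_mean, d$Cm_sd, d$Cp_mean, d$Cp_sd,
      d$volume[1], d$area[1], d$furrow_radius[1], d$n_samples[1]
    )
  })
}
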