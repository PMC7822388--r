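# Synthetic phantoms.
#
# Both generators render region labels on a supersampled grid and
# block-average down, so edge pixels carry partial-volume fractions
# (anti-aliased edges give smooth profiles).  `hard_edges = TRUE` renders at
# the target resolution with hard membership, for oracle tests.

#' Phantom container: two co-registered basis-fraction maps
#'
#' @param f,g numeric matrices of identical shape: fraction maps of basis
#'   materials 1 and 2.
#' @param pixel_size physical pixel size, cm.
#' @param basis the [basis_pair()] the fractions refer to.
#' @param mu_ref optional reference attenuation map rendered directly from
#'   material assignments (same grid), kept for consistency checks.
#' @return Object of class `phantom`.
#' @export
phantom <- function(f, g, pixel_size, basis, mu_ref = NULL) {
  f <- as.matrix(f); g <- as.matrix(g)
  if (!identical(dim(f), dim(g)))
    stop("f and g maps must have identical shape", call. = FALSE)
  structure(list(f = f, g = g, pixel_size = pixel_size, basis = basis,
                 mu_ref = mu_ref),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d x %d, pixel %.4g cm, basis %s/%s; f in [%.3g, %.3g], g in [%.3g, %.3g]\n",
    nrow(x$f), ncol(x$f), x$pixel_size, x$basis$names[1], x$basis$names[2],
    min(x$f), max(x$f), min(x$g), max(x$g)))
  invisible(x)
}

#' Compose attenuation and (scaled) phase maps from fraction maps
#'
#' Renders `mu = mu1 f + mu2 g` and `delta = delta1 f + delta2 g` (deltas in
#' the rescaled convention stored in the basis).
#'
#' @param ph a [phantom()] or a list with `f`, `g`.
#' @param basis basis pair; defaults to the phantom's own.
#' @return list with matrices `mu` and `delta`.
#' @export
compose_maps <- function(ph, basis = ph$basis) {
  list(mu = basis$mu1 * ph$f + basis$mu2 * ph$g,
       delta = basis$delta1 * ph$f + basis$delta2 * ph$g)
}

#' Solve fraction maps from attenuation and phase maps
#'
#' Pixelwise inverse of [compose_maps()]: solves the 2x2 system
#' `[mu1 mu2; delta1 delta2] (f, g)^T = (mu, delta)^T` for every pixel.
#'
#' @param mu,delta co-registered maps (delta in the scaled convention of
#'   `basis`).
#' @param basis a [basis_pair()].
#' @return list with matrices `f` and `g`.
#' @export
solve_fraction_maps <- function(mu, delta, basis) {
  .solve_basis(basis, as.matrix(mu), as.matrix(delta))
}

# fine-grid coordinate vectors for a supersampled render
.fine_coords <- function(n_px, pixel_size, ss) {
  nf <- n_px * ss
  ((seq_len(nf) - (nf + 1) / 2) * pixel_size / ss)
}

.block_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  n <- nrow(m) / ss
  # average ss x ss blocks
  m <- matrix(colMeans(matrix(m, nrow = ss)), nrow = n) # collapse rows
  t(matrix(colMeans(matrix(t(m), nrow = ss)), nrow = n))
}

#' Default water-like inserts of the head phantom
#'
#' Centers (cm), radii (cm) and relative water densities of the low-contrast
#' circular objects added to the two-material head.  The densities span
#' 0.95-1.10 relative water density; positions and values are an
#' approximation of the published figure, not a reproduction, and are fully
#' parameterisable.
#' @return data frame with columns `x`, `y`, `r`, `density`.
#' @export
forbild_inserts <- function() {
  data.frame(
    x = c(0.00, -0.20, 0.20, -0.11, 0.11, 0.00),
    y = c(0.18, 0.05, 0.05, -0.14, -0.14, -0.02),
    r = c(0.060, 0.055, 0.055, 0.050, 0.050, 0.045),
    density = c(1.10, 1.05, 0.95, 1.02, 0.98, 1.01))
}

#' Head phantom with bone shell, water interior and water-like inserts
#'
#' A 9.8 mm x 7.8 mm elliptical head: an outer bone shell (basis-1 fraction
#' 1), a water interior (basis-2 fraction 1) and low-contrast water-like
#' circular inserts encoded as basis-2 densities near 1.  Background outside
#' the head is 0 in both maps.
#'
#' @param n_px image side in pixels (>= 64).
#' @param inserts data frame as returned by [forbild_inserts()]; use
#'   `inserts = NULL` or a zero-row frame for the plain two-material head.
#'   Overlapping inserts draw in order, last wins (with a warning).
#' @param pixel_size cm; default covers a 10.24 mm field of view.
#' @param shell_thickness bone shell thickness, cm.
#' @param basis decomposition basis; default bone/water at 20 keV.
#' @param hard_edges if `TRUE`, hard pixel membership (no partial-volume
#'   anti-aliasing); used by oracle tests.
#' @param supersample anti-aliasing factor (ignored when `hard_edges`).
#' @return A [phantom()]; `f` holds the bone fraction, `g` the water
#'   fraction, and `mu_ref` the attenuation map rendered directly from
#'   material assignments.
#' @export
make_forbild_like <- function(n_px = 512L, inserts = forbild_inserts(),
                              pixel_size = 1.024 / n_px,
                              shell_thickness = 0.06,
                              basis = make_basis("bone", "water", 20),
                              hard_edges = FALSE, supersample = 4L) {
  if (n_px < 64L) stop("n_px must be >= 64", call. = FALSE)
  a <- 0.49; b <- 0.39                     # outer semi-axes, cm
  ai <- a - shell_thickness; bi <- b - shell_thickness
  if (is.null(inserts)) inserts <- forbild_inserts()[0, ]
  if (nrow(inserts) > 0) {
    # inserts must lie inside the water interior
    lim <- sqrt((inserts$x / (ai - inserts$r))^2 +
                  (inserts$y / (bi - inserts$r))^2)
    if (any(inserts$r >= pmin(ai, bi)) || any(lim > 1))
      stop("inserts must lie inside the interior ellipse", call. = FALSE)
    if (nrow(inserts) > 1) {
      dd <- as.matrix(dist(inserts[, c("x", "y")]))
      rr <- outer(inserts$r, inserts$r, "+")
      diag(dd) <- Inf
      if (any(dd < rr))
        warning("overlapping inserts: drawn in order, last wins",
                call. = FALSE)
    }
  }
  ss <- if (hard_edges) 1L else as.integer(supersample)
  xs <- .fine_coords(n_px, pixel_size, ss)
  nf <- length(xs)
  X <- matrix(xs, nf, nf); Y <- matrix(xs, nf, nf, byrow = TRUE)
  in_outer <- (X / a)^2 + (Y / b)^2 <= 1
  in_inner <- (X / ai)^2 + (Y / bi)^2 <= 1
  ff <- ifelse(in_outer & !in_inner, 1, 0)
  gg <- ifelse(in_inner, 1, 0)
  for (k in seq_len(nrow(inserts))) {
    m <- (X - inserts$x[k])^2 + (Y - inserts$y[k])^2 <= inserts$r[k]^2
    gg[m] <- inserts$density[k]
  }
  mu_fine <- basis$mu1 * ff + basis$mu2 * gg
  phantom(.block_mean(ff, ss), .block_mean(gg, ss), pixel_size, basis,
          mu_ref = .block_mean(mu_fine, ss))
}

#' Four-rod quantification phantom (PTFE / LDPE / PMMA rods in water)
#'
#' Digital analog of the physical rod phantom: PTFE, LDPE and PMMA cylinders
#' with diameters 2.0, 4.0 and 5.6 mm inside a water-filled polyethylene
#' tube of 10.7 mm external diameter.  Fractions are expressed in the
#' water/PTFE basis (basis 1 = water), so water maps to (1, 0), PTFE to
#' (0, 1), and LDPE/PMMA to the non-integer signed pairs solving the 2x2
#' composition system at the working energy.
#'
#' @param n_px image side in pixels (>= 256).
#' @param pixel_size cm; default covers a 12 mm field of view.
#' @param basis decomposition basis; default water/PTFE at 20 keV.
#' @param hard_edges,supersample see [make_forbild_like()].
#' @return A [phantom()] with `mu_ref` rendered from material assignments.
#' @export
make_rod_phantom <- function(n_px = 512L, pixel_size = 1.2 / n_px,
                             basis = make_basis("water", "PTFE", 20),
                             hard_edges = FALSE, supersample = 4L) {
  if (n_px < 256L) stop("n_px must be >= 256", call. = FALSE)
  energy <- basis$energy
  rods <- data.frame(
    material = c("PTFE", "LDPE", "PMMA"),
    x = c(0.02, -0.29, 0.20), y = c(-0.37, 0.02, 0.05),
    r = c(0.10, 0.20, 0.28))               # diameters 2.0 / 4.0 / 5.6 mm
  r_out <- 1.07 / 2; r_in <- 0.50          # tube wall
  ss <- if (hard_edges) 1L else as.integer(supersample)
  xs <- .fine_coords(n_px, pixel_size, ss)
  nf <- length(xs)
  X <- matrix(xs, nf, nf); Y <- matrix(xs, nf, nf, byrow = TRUE)
  R2 <- X^2 + Y^2
  # region labels: 0 air, 1 tube wall, 2 water, 3.. rods
  lab <- matrix(0L, nf, nf)
  lab[R2 <= r_out^2] <- 1L
  lab[R2 <= r_in^2] <- 2L
  for (k in seq_len(nrow(rods)))
    lab[(X - rods$x[k])^2 + (Y - rods$y[k])^2 <= rods$r[k]^2] <- 2L + k

  frac_for <- function(name) {
    m <- material_lookup(name, energy)
    s <- .solve_basis(basis, m$mu, m$delta * basis$delta_scale)
    c(f = s$f, g = s$g, mu = m$mu)
  }
  tab <- rbind(air = c(f = 0, g = 0, mu = 0),
               wall = frac_for("polyethylene"),
               water = frac_for("water"),
               t(vapply(rods$material, frac_for, numeric(3))))
  idx <- lab + 1L
  ff <- matrix(tab[idx, "f"], nf, nf)
  gg <- matrix(tab[idx, "g"], nf, nf)
  mu_fine <- matrix(tab[idx, "mu"], nf, nf)
  phantom(.block_mean(ff, ss), .block_mean(gg, ss), pixel_size, basis,
          mu_ref = .block_mean(mu_fine, ss))
}

#' Uniform disk phantom
#'
#' Single centered disk of one basis material; handy for closed-form chord
#' tests and channel-separation checks.
#'
#' @param n_px image side; `radius` cm; `value` fraction value;
#'   `channel` which map holds the disk (`"f"` or `"g"`);
#'   `pixel_size` cm; `basis` a [basis_pair()]; `hard_edges`, `supersample`
#'   as in [make_forbild_like()].
#' @param radius,value,channel,pixel_size,basis,hard_edges,supersample see
#'   above.
#' @return A [phantom()].
#' @export
make_disk_phantom <- function(n_px = 128L, radius = 0.3, value = 1,
                              channel = c("f", "g"),
                              pixel_size = 1.024 / n_px,
                              basis = make_basis("bone", "water", 20),
                              hard_edges = FALSE, supersample = 4L) {
  channel <- match.arg(channel)
  ss <- if (hard_edges) 1L else as.integer(supersample)
  xs <- .fine_coords(n_px, pixel_size, ss)
  nf <- length(xs)
  X <- matrix(xs, nf, nf); Y <- matrix(xs, nf, nf, byrow = TRUE)
  d <- .block_mean(ifelse(X^2 + Y^2 <= radius^2, value, 0), ss)
  z <- matrix(0, n_px, n_px)
  if (channel == "f") phantom(d, z, pixel_size, basis)
  else phantom(z, d, pixel_size, basis)
}
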