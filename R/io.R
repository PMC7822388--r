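# On-disk formats: multi-page 32-bit float TIFF for the array payloads plus
# a YAML sidecar (<file>.yaml) for geometry / basis / options metadata.
# TIFF samples live in [0, 1], so each page is affinely normalized on write
# and the per-page (min, max) pair is stored in the sidecar; arrays
# round-trip at float32 precision relative to their range, metadata exactly.

.sidecar <- function(path) paste0(path, ".yaml")

# metadata must survive the round trip at full double precision
.write_yaml17 <- function(x, file) yaml::write_yaml(x, file, precision = 17L)

# normalize pages into [0,1]; returns the per-page ranges for the sidecar.
# Non-finite pixels (e.g. masked sentinels) are stored as the page minimum.
.write_pages <- function(pages, path) {
  ranges <- lapply(pages, function(p) {
    r <- suppressWarnings(range(p, finite = TRUE))
    if (!all(is.finite(r))) r <- c(0, 1)
    r
  })
  norm <- mapply(function(p, r) {
    p[!is.finite(p)] <- r[1]
    if (r[2] > r[1]) (p - r[1]) / (r[2] - r[1]) else p * 0
  }, pages, ranges, SIMPLIFY = FALSE)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  ranges
}

.read_pages <- function(path, n_expected, what, ranges) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < n_expected)
    stop("expected ", n_expected, " pages (", what, ") in ", path,
         ", found ", length(pages), call. = FALSE)
  if (length(ranges) < n_expected)
    stop("sidecar of ", path, " is missing page ranges", call. = FALSE)
  lapply(seq_len(n_expected), function(k) {
    p <- pages[[k]]
    if (length(dim(p)) > 2) p <- p[, , 1]
    r <- unlist(ranges[[k]])
    matrix(as.numeric(p) * (r[2] - r[1]) + r[1], nrow(p), ncol(p))
  })
}

.read_meta <- function(path) {
  sc <- .sidecar(path)
  if (!file.exists(sc))
    stop("missing YAML sidecar: ", sc, call. = FALSE)
  yaml::read_yaml(sc)
}

.basis_meta <- function(basis) {
  list(mu = c(basis$mu1, basis$mu2),
       delta_raw = c(basis$delta1_raw, basis$delta2_raw),
       delta_scale = basis$delta_scale, names = as.list(basis$names),
       energy = basis$energy)
}

.basis_from_meta <- function(m) {
  basis_pair(unlist(m$mu), unlist(m$delta_raw),
             names = unlist(m$names), energy = m$energy,
             delta_scale = m$delta_scale)
}

.geometry_meta <- function(g) {
  list(n_views = g$n_views, n_det = g$n_det, det_pitch = g$det_pitch,
       image_side = g$image_side, pixel_size = g$pixel_size,
       angles = as.list(g$angles))
}

.geometry_from_meta <- function(m) {
  scan_geometry(m$n_views, m$n_det, m$det_pitch, m$image_side,
                m$pixel_size, angles = unlist(m$angles))
}

#' Write / read a phantom (multi-page TIFF + YAML sidecar)
#'
#' Page 1 holds the basis-1 fraction map, page 2 the basis-2 map (32-bit
#' float); pixel size and basis metadata go to `<path>.yaml`.
#'
#' @param ph a [phantom()].
#' @param path TIFF file path.
#' @return `write_phantom` the path, invisibly; `read_phantom` a
#'   [phantom()].
#' @export
write_phantom <- function(ph, path) {
  rg <- .write_pages(list(ph$f, ph$g), path)
  .write_yaml17(list(object = "phantom", pixel_size = ph$pixel_size,
                        basis = .basis_meta(ph$basis), ranges = rg),
                   .sidecar(path))
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  meta <- .read_meta(path)
  if (!identical(meta$object, "phantom"))
    stop("sidecar does not describe a phantom: ", .sidecar(path),
         call. = FALSE)
  pages <- .read_pages(path, 2L, "f, g", meta$ranges)
  phantom(pages[[1]], pages[[2]], meta$pixel_size,
          .basis_from_meta(meta$basis))
}

#' Write / read a sinogram pair (multi-page TIFF + YAML sidecar)
#'
#' Page 1 is the absorption sinogram `M`, page 2 the differential-phase
#' sinogram `theta`; scan geometry, basis and photon count go to the
#' sidecar.
#'
#' @param pair a [sinogram_pair()].
#' @param path TIFF file path.
#' @return `write_sinogram_pair` the path, invisibly;
#'   `read_sinogram_pair` a [sinogram_pair()].
#' @export
write_sinogram_pair <- function(pair, path) {
  rg <- .write_pages(list(pair$M$values, pair$theta$values), path)
  .write_yaml17(list(object = "sinogram_pair",
                        geometry = .geometry_meta(pair$M$geometry),
                        basis = .basis_meta(pair$basis),
                        photon_count = pair$photon_count,
                        kinds = list("absorption", "differential_phase"),
                        ranges = rg),
                   .sidecar(path))
  invisible(path)
}

#' @rdname write_sinogram_pair
#' @export
read_sinogram_pair <- function(path) {
  meta <- .read_meta(path)
  if (!identical(meta$object, "sinogram_pair"))
    stop("sidecar does not describe a sinogram_pair: ", .sidecar(path),
         call. = FALSE)
  pages <- .read_pages(path, 2L, "M, theta", meta$ranges)
  g <- .geometry_from_meta(meta$geometry)
  pc <- meta$photon_count
  sinogram_pair(sinogram(pages[[1]], "absorption", g),
                sinogram(pages[[2]], "differential_phase", g),
                .basis_from_meta(meta$basis),
                photon_count = if (is.null(pc)) NA_real_ else pc)
}

#' Write / read a decomposition result (multi-page TIFF + YAML sidecar)
#'
#' Pages 1-2 hold the fraction maps; the convergence record, iteration
#' count, solver options and basis go to the sidecar.
#'
#' @param result a [decomposition_result()].
#' @param path TIFF file path.
#' @return `write_decomposition` the path, invisibly;
#'   `read_decomposition` a [decomposition_result()].
#' @export
write_decomposition <- function(result, path) {
  rg <- .write_pages(list(result$f_star, result$g_star), path)
  conv <- if (is.null(result$convergence)) NULL else
    lapply(as.list(result$convergence), as.vector)
  opts <- result$options_used
  .write_yaml17(list(object = "decomposition_result",
                        method_tag = result$method_tag,
                        iterations_run = result$iterations_run,
                        pixel_size = result$pixel_size,
                        basis = if (is.null(result$basis)) NULL else
                          .basis_meta(result$basis),
                        options = if (is.null(opts)) NULL else
                          unclass(opts),
                        convergence = conv, ranges = rg), .sidecar(path))
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  meta <- .read_meta(path)
  if (!identical(meta$object, "decomposition_result"))
    stop("sidecar does not describe a decomposition_result: ",
         .sidecar(path), call. = FALSE)
  pages <- .read_pages(path, 2L, "f_star, g_star", meta$ranges)
  conv <- if (is.null(meta$convergence)) NULL else
    as.data.frame(meta$convergence)
  opts <- if (is.null(meta$options)) NULL else
    structure(meta$options, class = "solver_options")
  decomposition_result(pages[[1]], pages[[2]], convergence = conv,
                       iterations_run = meta$iterations_run,
                       options_used = opts,
                       method_tag = meta$method_tag,
                       basis = if (is.null(meta$basis)) NULL else
                         .basis_from_meta(meta$basis),
                       pixel_size = meta$pixel_size)
}
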