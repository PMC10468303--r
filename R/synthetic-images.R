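#' Specify a wild-type ommatidial lattice
#'
#' Describes the undisturbed hexagonal array of bright ommatidium-like dots
#' that the synthetic image generator renders: in a healthy compound eye the
#' ommatidia are uniform in size and each sits a fixed distance from its six
#' nearest neighbours. Rows are offset by half the spacing and separated by
#' `spacing * sqrt(3) / 2`, so every centre-to-centre nearest-neighbour
#' distance equals `spacing`.
#'
#' @param n_rows,n_cols Lattice dimensions (counts).
#' @param spacing Centre-to-centre distance between adjacent dots, pixels.
#' @param dot_radius Dot radius, pixels (>= 1). Fusion-regime geometries with
#'   `spacing <= 2 * dot_radius` are allowed.
#' @param image_size Image height and width in pixels; defaults to the
#'   smallest frame that holds the lattice with a one-spacing margin.
#' @param background_level,dot_level Background and dot intensities in `[0, 1]`.
#' @return An object of class `lattice_spec`.
#' @export
#' @examples
#' spec <- lattice_spec(5, 5, spacing = 16, dot_radius = 5)
lattice_spec <- function(n_rows = 11L, n_cols = 11L, spacing = 16,
                         dot_radius = 5, image_size = NULL,
                         background_level = 0.1, dot_level = 0.9) {
  stopifnot(is_count(n_rows), is_count(n_cols), spacing > 0, dot_radius >= 1,
            is_prob(background_level), is_prob(dot_level))
  extent_r <- (n_rows - 1) * spacing * sqrt(3) / 2
  extent_c <- (n_cols - 1) * spacing + spacing / 2
  if (is.null(image_size)) {
    image_size <- c(ceiling(extent_r + 2 * spacing), ceiling(extent_c + 2 * spacing))
  }
  stopifnot(length(image_size) == 2L, all(image_size >= 1))
  # all dots (including the anti-aliased rim) must fit inside the frame
  if (extent_r + 2 * (dot_radius + 1) > image_size[1] ||
      extent_c + 2 * (dot_radius + 1) > image_size[2]) {
    stop("lattice does not fit inside image bounds", call. = FALSE)
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing = spacing, dot_radius = dot_radius,
                 image_size = as.integer(image_size),
                 background_level = background_level, dot_level = dot_level),
            class = "lattice_spec")
}

#' Specify a degeneration regime for synthetic eye images
#'
#' Parameterises the three degeneration modes seen in rough-eye micrographs:
#' fusion of adjacent ommatidia (a bright bridge merges two dots into one
#' blob), pitting (a dark notch carved out of a dot, reducing its bright area
#' and its minimal radius), and spatial jitter of the lattice positions.
#'
#' @param fusion_rate Probability that an adjacent dot pair is fused.
#' @param pit_rate Probability that a dot is pitted.
#' @param jitter_sd SD (pixels) of the isotropic Gaussian centroid jitter.
#' @param noise_sd Optional additive Gaussian pixel noise SD (default 0; the
#'   acquisition noise of real micrographs is not modelled beyond this).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `degeneration_spec`.
#' @export
degeneration_spec <- function(fusion_rate = 0, pit_rate = 0, jitter_sd = 0,
                              noise_sd = 0, seed = 1L) {
  stopifnot(is_prob(fusion_rate), is_prob(pit_rate), jitter_sd >= 0, noise_sd >= 0)
  structure(list(fusion_rate = fusion_rate, pit_rate = pit_rate,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "degeneration_spec")
}

# Hexagonal lattice centroids, 1-based (row, col) pixel-centre coordinates.
lattice_centroids <- function(spec) {
  row_step <- spec$spacing * sqrt(3) / 2
  extent_r <- (spec$n_rows - 1) * row_step
  extent_c <- (spec$n_cols - 1) * spec$spacing + spec$spacing / 2
  off_r <- (spec$image_size[1] - extent_r) / 2
  off_c <- (spec$image_size[2] - extent_c) / 2
  i <- rep(seq_len(spec$n_rows) - 1L, each = spec$n_cols)
  j <- rep(seq_len(spec$n_cols) - 1L, times = spec$n_rows)
  cbind(row = off_r + i * row_step,
        col = off_c + j * spec$spacing + (i %% 2) * spec$spacing / 2)
}

# Anti-aliased coverage of a disk: 1 inside, 0 outside, linear ramp across
# the one-pixel rim.  Accumulated with pmax so overlapping disks union.
add_disk_coverage <- function(cov, center, radius) {
  h <- nrow(cov); w <- ncol(cov)
  r0 <- max(1L, floor(center[1] - radius - 1)); r1 <- min(h, ceiling(center[1] + radius + 1))
  c0 <- max(1L, floor(center[2] - radius - 1)); c1 <- min(w, ceiling(center[2] + radius + 1))
  if (r0 > r1 || c0 > c1) return(cov)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - center[1])^2, (cc - center[2])^2, `+`))
  cov[rr, cc] <- pmax(cov[rr, cc], pmin(pmax(radius + 0.5 - d, 0), 1))
  cov
}

# Capsule (thick segment) coverage between two centres, used for fusion bridges.
add_capsule_coverage <- function(cov, p, q, half_width) {
  h <- nrow(cov); w <- ncol(cov)
  r0 <- max(1L, floor(min(p[1], q[1]) - half_width - 1))
  r1 <- min(h, ceiling(max(p[1], q[1]) + half_width + 1))
  c0 <- max(1L, floor(min(p[2], q[2]) - half_width - 1))
  c1 <- min(w, ceiling(max(p[2], q[2]) + half_width + 1))
  if (r0 > r1 || c0 > c1) return(cov)
  rr <- r0:r1; cc <- c0:c1
  gr <- matrix(rep(rr, length(cc)), nrow = length(rr))
  gc <- matrix(rep(cc, each = length(rr)), nrow = length(rr))
  v <- q - p
  len2 <- sum(v^2)
  t <- if (len2 == 0) 0 else pmin(pmax(((gr - p[1]) * v[1] + (gc - p[2]) * v[2]) / len2, 0), 1)
  d <- sqrt((gr - (p[1] + t * v[1]))^2 + (gc - (p[2] + t * v[2]))^2)
  cov[rr, cc] <- pmax(cov[rr, cc], pmin(pmax(half_width + 0.5 - d, 0), 1))
  cov
}

#' Generate a synthetic degenerating eye image with ground truth
#'
#' Renders anti-aliased bright dots on a hexagonal lattice into a float
#' image in `[0, 1]`, then applies the degeneration operators: jitter
#' perturbs each centroid by `N(0, jitter_sd^2)` (clipped to keep the dot in
#' frame, with a per-dot `clipped` flag in the ground truth), fusion draws a
#' bright bridge between selected adjacent dots so the pair becomes one
#' connected blob, and pitting subtracts a smaller dark disk at a random
#' interior offset, strictly reducing the dot's bright area and its minimal
#' radius. Identical specs and seed give bit-identical output.
#'
#' @param lattice A [lattice_spec()].
#' @param degeneration A [degeneration_spec()].
#' @return A list of class `synthetic_eye` with elements `image` (numeric
#'   matrix in `[0, 1]`) and `truth`, a `eye_ground_truth` list holding
#'   `true_centroids` (post-jitter, (row, col)), `true_count`, `fused_pairs`
#'   (two-column index matrix), `pitted_indices`, and `clipped`.
#' @export
#' @examples
#' eye <- generate_eye_image(lattice_spec(5, 5), degeneration_spec(seed = 7))
#' eye$truth$true_count
generate_eye_image <- function(lattice, degeneration = degeneration_spec()) {
  stopifnot(inherits(lattice, "lattice_spec"), inherits(degeneration, "degeneration_spec"))
  base <- lattice_centroids(lattice)
  n <- nrow(base)
  r <- lattice$dot_radius
  h <- lattice$image_size[1]; w <- lattice$image_size[2]

  # adjacency from the undisturbed lattice (the biology: fusion joins
  # neighbouring ommatidia, independent of the jitter applied afterwards)
  dd <- as.matrix(stats::dist(base))
  adj <- which(upper.tri(dd) & dd <= lattice$spacing * 1.05, arr.ind = TRUE)

  res <- with_seed(degeneration$seed, {
    cent <- base
    clipped <- logical(n)
    if (degeneration$jitter_sd > 0) {
      cent <- cent + matrix(stats::rnorm(2 * n, 0, degeneration$jitter_sd), ncol = 2)
      lo <- r + 1.5
      clip_r <- pmin(pmax(cent[, 1], lo), h - lo + 1)
      clip_c <- pmin(pmax(cent[, 2], lo), w - lo + 1)
      clipped <- clip_r != cent[, 1] | clip_c != cent[, 2]
      if (any(clipped)) warning("jittered dots clipped to image bounds")
      cent <- cbind(row = clip_r, col = clip_c)
    }
    fuse <- if (nrow(adj) > 0 && degeneration$fusion_rate > 0) {
      adj[stats::runif(nrow(adj)) < degeneration$fusion_rate, , drop = FALSE]
    } else matrix(integer(0), ncol = 2)
    pitted <- which(stats::runif(n) < degeneration$pit_rate)
    pit_geom <- if (length(pitted) > 0) {
      cbind(offset = stats::runif(length(pitted), 0.3, 0.7) * r,
            angle = stats::runif(length(pitted), 0, 2 * pi))
    } else matrix(numeric(0), ncol = 2)
    noise <- if (degeneration$noise_sd > 0) {
      matrix(stats::rnorm(h * w, 0, degeneration$noise_sd), h, w)
    } else NULL
    list(cent = cent, clipped = clipped, fuse = fuse, pitted = pitted,
         pit_geom = pit_geom, noise = noise)
  })

  cov <- matrix(0, h, w)
  for (k in seq_len(n)) cov <- add_disk_coverage(cov, res$cent[k, ], r)
  if (nrow(res$fuse) > 0) {
    for (k in seq_len(nrow(res$fuse))) {
      cov <- add_capsule_coverage(cov, res$cent[res$fuse[k, 1], ],
                                  res$cent[res$fuse[k, 2], ], 0.6 * r)
    }
  }
  if (length(res$pitted) > 0) {
    pit_cov <- matrix(0, h, w)
    for (k in seq_along(res$pitted)) {
      ctr <- res$cent[res$pitted[k], ] +
        res$pit_geom[k, "offset"] * c(cos(res$pit_geom[k, "angle"]),
                                      sin(res$pit_geom[k, "angle"]))
      pit_cov <- add_disk_coverage(pit_cov, ctr, 0.5 * r)
    }
    cov <- pmax(cov - pit_cov, 0)
  }
  img <- lattice$background_level +
    (lattice$dot_level - lattice$background_level) * cov
  if (!is.null(res$noise)) img <- pmin(pmax(img + res$noise, 0), 1)

  truth <- structure(list(true_centroids = res$cent, true_count = n,
                          fused_pairs = res$fuse, pitted_indices = res$pitted,
                          clipped = res$clipped, lattice = lattice,
                          degeneration = degeneration),
                     class = "eye_ground_truth")
  structure(list(image = img, truth = truth), class = "synthetic_eye")
}

#' Write a synthetic eye image and its ground-truth sidecar
#'
#' Writes the image as grayscale PNG or TIFF and the ground truth as a JSON
#' sidecar (`<image>.truth.json`) alongside it.
#'
#' @param eye A `synthetic_eye` from [generate_eye_image()].
#' @param path Output image path; the extension picks the format.
#' @return `path`, invisibly.
#' @export
write_synthetic_eye <- function(eye, path) {
  stopifnot(inherits(eye, "synthetic_eye"))
  # EBImage stores images [x = col, y = row]; transpose so that
  # read_eye_image() round-trips to the same (row, col) matrix
  EBImage::writeImage(t(eye$image), path)
  truth <- eye$truth
  sidecar <- list(true_centroids = unname(truth$true_centroids),
                  true_count = truth$true_count,
                  fused_pairs = unname(truth$fused_pairs),
                  pitted_indices = truth$pitted_indices,
                  clipped = truth$clipped,
                  seed = truth$degeneration$seed)
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
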