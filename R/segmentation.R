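# -- connected components ----------------------------------------------------

#' Label connected components of a binary mask
#'
#' 8-connected (default) or 4-connected labelling. Edges between
#' foreground pixels are built by vectorised shifts and components come
#' from the union of those adjacencies.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape: 0 for background, 1..k
#'   component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  M <- matrix(0L, nrow(mask), ncol(mask))
  M[idx] <- seq_along(idx)
  h <- nrow(mask); w <- ncol(mask)
  pair_up <- function(a, b) {
    sel <- a > 0L & b > 0L
    cbind(a[sel], b[sel])
  }
  edges <- rbind(
    if (w > 1) pair_up(M[, -w, drop = FALSE], M[, -1, drop = FALSE]),
    if (h > 1) pair_up(M[-h, , drop = FALSE], M[-1, , drop = FALSE]))
  if (connectivity == 8 && h > 1 && w > 1) {
    edges <- rbind(edges,
                   pair_up(M[-h, -w, drop = FALSE], M[-1, -1, drop = FALSE]),
                   pair_up(M[-h, -1, drop = FALSE], M[-1, -w, drop = FALSE]))
  }
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = length(idx),
                          directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Segment individual ommatidia within an ROI
#'
#' Thresholds the (preprocessed, masked) image with Otsu's rule computed
#' over the pixels inside the ROI, labels 8-connected foreground clusters,
#' and discards clusters smaller than `min_cluster_size`. Clusters touching
#' the ROI boundary are retained by default (`exclude_boundary = TRUE`
#' drops any cluster with a pixel whose 8-neighbourhood leaves the
#' ellipse).
#'
#' @param img Numeric matrix (preprocessed image, already ROI-masked or
#'   not; if `roi` is supplied the mask is applied here).
#' @param roi Optional `roi_ellipse`; `NULL` segments the whole frame.
#' @param config List of options: `min_cluster_size` (default 5),
#'   `connectivity` (8), `exclude_boundary` (FALSE).
#' @return List of clusters, each a two-column integer matrix of (row, col)
#'   pixel positions. Empty list (with a warning) when nothing is found.
#' @export
segment_ommatidia <- function(img, roi = NULL, config = list()) {
  stopifnot(is.matrix(img))
  min_size <- config$min_cluster_size %||% 5L
  conn <- config$connectivity %||% 8
  inside <- if (is.null(roi)) {
    matrix(TRUE, nrow(img), ncol(img))
  } else {
    rows <- matrix(rep(seq_len(nrow(img)), ncol(img)), nrow = nrow(img))
    cols <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow = nrow(img))
    matrix(roi_contains(roi, rows, cols), nrow(img), ncol(img))
  }
  vals <- img[inside]
  if (length(vals) == 0 || diff(range(vals)) == 0) {
    warning("no ommatidia found: ROI is empty or flat")
    return(list())
  }
  # Otsu threshold over ROI pixels only (EBImage's otsu is histogram based,
  # so a 1 x n matrix of the ROI values gives the same rule)
  thr <- EBImage::otsu(matrix(vals, nrow = 1), range = c(0, 1))
  mask <- img > thr & inside
  if (!any(mask)) {
    warning("no ommatidia found above threshold")
    return(list())
  }
  lab <- label_components(mask, connectivity = conn)
  k <- max(lab)
  clusters <- lapply(seq_len(k), function(i) which(lab == i, arr.ind = TRUE))
  sizes <- vapply(clusters, nrow, integer(1))
  clusters <- clusters[sizes >= min_size]
  if (isTRUE(config$exclude_boundary) && !is.null(roi)) {
    keep <- vapply(clusters, function(cl) {
      nb <- rbind(cl + rep(c(-1L, -1L), each = nrow(cl)),
                  cl + rep(c(-1L, 0L), each = nrow(cl)),
                  cl + rep(c(-1L, 1L), each = nrow(cl)),
                  cl + rep(c(0L, -1L), each = nrow(cl)),
                  cl + rep(c(0L, 1L), each = nrow(cl)),
                  cl + rep(c(1L, -1L), each = nrow(cl)),
                  cl + rep(c(1L, 0L), each = nrow(cl)),
                  cl + rep(c(1L, 1L), each = nrow(cl)))
      all(roi_contains(roi, nb))
    }, logical(1))
    clusters <- clusters[keep]
  }
  if (length(clusters) == 0) warning("no ommatidia passed the size filter")
  lapply(clusters, function(cl) {
    colnames(cl) <- c("row", "col")
    cl
  })
}

# -- per-ommatidium geometry -------------------------------------------------

# Moore-neighbour contour tracing; returns the closed boundary chain length
# with unit steps weighted 1 and diagonal steps weighted sqrt(2).
chain_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  start <- which(pad, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  # clockwise Moore neighbourhood starting west (rows grow downward)
  dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  step_w <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  p <- start
  bdir <- 1L                       # backtrack direction: west of start
  first_move <- NA_integer_
  perim <- 0
  max_iter <- 8L * sum(pad) + 8L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- ((bdir - 1L + k - 1L) %% 8L) + 1L   # clockwise from backtrack
      q <- p + dirs[d, ]
      if (pad[q[1], q[2]]) {
        if (iter == 1L) first_move <- d
        perim <- perim + step_w[d]
        # new backtrack: the neighbour checked just before the hit
        prev <- ((d - 2L) %% 8L) + 1L
        bprev <- p + dirs[prev, ]
        p <- q
        # direction from new p back to bprev
        rel <- bprev - p
        bdir <- which(dirs[, 1] == rel[1] & dirs[, 2] == rel[2])
        found <- TRUE
        break
      }
    }
    if (!found) return(0)          # isolated pixel
    if (all(p == start) && iter > 1L) break
    if (all(p == start) && iter == 1L) break   # two-pixel blob oscillation guard
  }
  perim
}

#' Geometric features of one segmented ommatidium
#'
#' Computes the feature vector for a pixel cluster: centroid (mean pixel
#' coordinate), area (pixel count), perimeter (Moore boundary chain with
#' `sqrt(2)` weighting of diagonal steps), radius statistics (Euclidean
#' distances from the centroid to every boundary pixel, summarised as
#' mean / min / max / sample SD), and eccentricity from the second central
#' moments: `sqrt(1 - lambda2 / lambda1)`, with each pixel treated as a
#' unit square (a `1/12` diagonal moment term) so that degenerate clusters
#' stay strictly below 1.
#'
#' @param cluster Two-column integer matrix of (row, col) pixel positions.
#' @return An object of class `ommatidium_feature`: list with `centroid`,
#'   `area`, `perimeter`, `radius_mean`, `radius_min`, `radius_max`,
#'   `radius_sd`, `eccentricity`.
#' @export
ommatidium_features <- function(cluster) {
  cluster <- matrix(as.integer(cluster), ncol = 2)
  n <- nrow(cluster)
  if (n == 0) stop("empty cluster", call. = FALSE)
  ctr <- colMeans(cluster)
  r0 <- min(cluster[, 1]); c0 <- min(cluster[, 2])
  mask <- matrix(FALSE, max(cluster[, 1]) - r0 + 1L, max(cluster[, 2]) - c0 + 1L)
  mask[cbind(cluster[, 1] - r0 + 1L, cluster[, 2] - c0 + 1L)] <- TRUE
  perim <- chain_perimeter(mask)

  # boundary pixels: any 4-neighbour outside the cluster (or outside frame)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  boundary <- which(mask & !interior, arr.ind = TRUE)
  boundary <- cbind(boundary[, 1] + r0 - 1L, boundary[, 2] + c0 - 1L)
  radii <- sqrt((boundary[, 1] - ctr[1])^2 + (boundary[, 2] - ctr[2])^2)

  # second central moments with the unit-square pixel term
  mu <- stats::cov(cluster) * (n - 1) / n
  if (n == 1) mu <- matrix(0, 2, 2)
  mu <- mu + diag(1 / 12, 2)
  ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))

  structure(list(centroid = stats::setNames(ctr, c("row", "col")),
                 area = n, perimeter = perim,
                 radius_mean = mean(radii), radius_min = min(radii),
                 radius_max = max(radii),
                 radius_sd = if (length(radii) > 1) stats::sd(radii) else 0,
                 eccentricity = ecc),
            class = "ommatidium_feature")
}

#' Nearest-neighbour distances between ommatidium centroids
#'
#' For each centroid, the Euclidean distance to its single nearest other
#' centroid. On an intact hexagonal array every value equals the lattice
#' spacing.
#'
#' @param centroids Two-column numeric matrix of (row, col) centroids
#'   (>= 2 rows).
#' @return Numeric vector, one value per centroid.
#' @export
nearest_neighbor_distances <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stop("need at least 2 centroids", call. = FALSE)
  dm <- as.matrix(stats::dist(centroids))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}

# -- image-level aggregation -------------------------------------------------

#' The 16 image-level trait metric names, in canonical order
#' @return Character vector of length 16.
#' @export
metric_names <- function() {
  c("nn_mean", "nn_sd", "ecc_mean", "ecc_sd", "area_mean", "area_sd",
    "perimeter_mean", "perimeter_sd", "radiusmean_mean", "radiusmean_sd",
    "radiussd_mean", "radiussd_sd", "radiusmin_mean", "radiusmin_sd",
    "radiusmax_mean", "radiusmax_sd")
}

#' Aggregate per-ommatidium features into the 16 image metrics
#'
#' The arithmetic mean and sample SD (n - 1) of each of the eight underlying
#' measurements (nearest-neighbour distance, eccentricity, area, perimeter,
#' radius mean, radius SD, radius min, radius max) across all ommatidia in
#' the image: 16 trait metrics in total.
#'
#' @param features List of [ommatidium_features()] results (>= 2).
#' @param nn Numeric vector of nearest-neighbour distances (defaults to
#'   computing them from the feature centroids).
#' @return One-row `data.frame` (class `image_metrics`) with the 16 metric
#'   columns of [metric_names()] plus `n_ommatidia`.
#' @export
aggregate_image_metrics <- function(features, nn = NULL) {
  stopifnot(is.list(features))
  if (length(features) < 2) {
    stop("need at least 2 ommatidia (SD metrics undefined otherwise)", call. = FALSE)
  }
  grab <- function(f) vapply(features, `[[`, numeric(1), f)
  if (is.null(nn)) {
    cent <- t(vapply(features, `[[`, numeric(2), "centroid"))
    nn <- nearest_neighbor_distances(cent)
  }
  m <- data.frame(
    nn_mean = mean(nn), nn_sd = stats::sd(nn),
    ecc_mean = mean(grab("eccentricity")), ecc_sd = stats::sd(grab("eccentricity")),
    area_mean = mean(grab("area")), area_sd = stats::sd(grab("area")),
    perimeter_mean = mean(grab("perimeter")), perimeter_sd = stats::sd(grab("perimeter")),
    radiusmean_mean = mean(grab("radius_mean")), radiusmean_sd = stats::sd(grab("radius_mean")),
    radiussd_mean = mean(grab("radius_sd")), radiussd_sd = stats::sd(grab("radius_sd")),
    radiusmin_mean = mean(grab("radius_min")), radiusmin_sd = stats::sd(grab("radius_min")),
    radiusmax_mean = mean(grab("radius_max")), radiusmax_sd = stats::sd(grab("radius_max")))
  m$n_ommatidia <- length(features)
  class(m) <- c("image_metrics", "data.frame")
  m
}

#' Quantify ommatidial degeneration in one image
#'
#' Full single-image pipeline: preprocess (luminance + white top-hat), detect
#' bright pixels, prune at the centroid-distance quantile, fit the
#' confidence-ellipse ROI, mask, segment ommatidia, extract per-ommatidium
#' geometry, and aggregate the 16 image-level trait metrics. Any stage
#' failure is re-raised with the stage name.
#'
#' @param raw Image matrix / array, or a PNG/TIFF path.
#' @param config Options: `structuring_radius` (8), `detect_method`
#'   (`"otsu"`), `detect_quantile` (0.95), `prune_q` (0.8), `conf_level`
#'   (0.95), `min_cluster_size` (5), `connectivity` (8), `exclude_boundary`
#'   (FALSE).
#' @return One-row `image_metrics` data frame (16 metrics + `n_ommatidia`),
#'   with the fitted ROI in `attr(, "roi")`.
#' @export
#' @examples
#' eye <- generate_eye_image(lattice_spec(7, 7), degeneration_spec(seed = 2))
#' quantify_image(eye$image)
quantify_image <- function(raw, config = list()) {
  cfg <- utils::modifyList(list(structuring_radius = 8, detect_method = "otsu",
                                detect_quantile = 0.95, prune_q = 0.8,
                                conf_level = 0.95, min_cluster_size = 5L,
                                connectivity = 8, exclude_boundary = FALSE),
                           config)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) stop_stage(stage, conditionMessage(e)))
  }
  img <- run("preprocess", preprocess(raw, cfg$structuring_radius))
  px <- run("detect", detect_bright_pixels(img, method = cfg$detect_method,
                                           quantile = cfg$detect_quantile))
  px <- run("prune", prune_by_centroid_distance(px, cfg$prune_q))
  roi <- run("ellipse", fit_confidence_ellipse(px, cfg$conf_level))
  masked <- run("mask", mask_to_roi(img, roi))
  clusters <- run("segment", segment_ommatidia(masked, roi, cfg))
  feats <- run("features", lapply(clusters, ommatidium_features))
  out <- run("aggregate", aggregate_image_metrics(feats))
  attr(out, "roi") <- roi
  out
}
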