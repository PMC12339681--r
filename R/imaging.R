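#' Parameters of the image-measurement stage
#'
#' Documented stand-in for a high-content analysis recipe: background is
#' removed by median subtraction, the IBA1 channel is Gaussian-smoothed
#' and Otsu-thresholded to define cell foreground, nuclei seed a watershed
#' (propagation) that splits touching cells, and objects below a minimum
#' size are discarded as debris. Boundary-touching cells are retained.
#'
#' @param smooth_sigma Gaussian smoothing SD (pixels) for the IBA1 channel.
#' @param min_size minimum object size in pixels (debris suppression).
#' @param nucleus_smooth_sigma smoothing SD for the nuclei channel.
#' @param phrodo_threshold fixed pHrodo threshold in [0, 1], or `NULL` for
#'   Otsu on the background-corrected channel.
#' @param background_correct subtract the channel median before
#'   thresholding.
#' @return list of class `imaging_params`.
#' @export
imaging_params <- function(smooth_sigma = 2, min_size = 50L,
                           nucleus_smooth_sigma = 2,
                           phrodo_threshold = NULL,
                           background_correct = TRUE) {
  p <- list(smooth_sigma = smooth_sigma, min_size = as.integer(min_size),
            nucleus_smooth_sigma = nucleus_smooth_sigma,
            phrodo_threshold = phrodo_threshold,
            background_correct = background_correct)
  class(p) <- "imaging_params"
  p
}

subtract_background <- function(channel) {
  bg <- stats::median(channel)
  out <- channel - bg
  out[out < 0] <- 0
  out
}

otsu_threshold <- function(channel) {
  m <- max(channel)
  if (m <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(channel / m), levels = 256L) * m
}

#' Segment cells from nuclei and IBA1 channels
#'
#' Nuclei-seeded segmentation: the smoothed IBA1 channel is
#' Otsu-thresholded into cell foreground, nuclei are thresholded and
#' labeled as seeds, and seeds are propagated through the foreground
#' (Voronoi watershed on the intensity landscape) so touching cells with
#' separate nuclei split into separate labels. Foreground components
#' without any nucleus seed are labeled too (a cell whose nucleus fell
#' below threshold is still a cell). Objects smaller than
#' `params$min_size` pixels are removed and labels renumbered
#' consecutively.
#'
#' @param nuclei,iba1 numeric matrices of identical dimensions,
#'   nonnegative.
#' @param params an [imaging_params()].
#' @return integer label matrix (0 = background).
#' @export
segment_cells <- function(nuclei, iba1, params = imaging_params()) {
  if (!all(dim(nuclei) == dim(iba1)))
    stop("nuclei and IBA1 channels must have identical shape",
         call. = FALSE)
  if (min(nuclei) < 0 || min(iba1) < 0)
    stop("channels must be nonnegative", call. = FALSE)
  ib <- if (params$background_correct) subtract_background(iba1) else iba1
  nu <- if (params$background_correct) subtract_background(nuclei)
        else nuclei
  sm <- as.matrix(EBImage::gblur(EBImage::Image(ib),
                                 sigma = params$smooth_sigma))
  fg <- sm > otsu_threshold(sm)
  if (!any(fg)) return(matrix(0L, nrow(iba1), ncol(iba1)))
  nsm <- as.matrix(EBImage::gblur(EBImage::Image(nu),
                                  sigma = params$nucleus_smooth_sigma))
  seeds <- EBImage::bwlabel(nsm > otsu_threshold(nsm))
  lab <- EBImage::propagate(EBImage::Image(sm), seeds = seeds, mask = fg)
  lab <- as.matrix(lab)
  ## foreground missed by propagation (no seed in the component)
  orphan <- fg & lab == 0
  if (any(orphan)) {
    extra <- as.matrix(EBImage::bwlabel(orphan))
    lab[orphan] <- max(lab) + extra[orphan]
  }
  ## drop debris and renumber
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_size)
  if (length(keep) == 0L) return(matrix(0L, nrow(iba1), ncol(iba1)))
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

## lattice-point count of the convex hull of a pixel point set.
## A pixel center is counted when it satisfies every half-plane of the
## hull (with a small tolerance so boundary pixels are included).
convex_pixel_count <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3L) return(n)
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  if (nrow(v) < 3L) return(n)
  ## orient counterclockwise (positive signed area) so the interior is
  ## on the left of every edge
  area2 <- sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                 c(v[-1, 1], v[1, 1]) * v[, 2])
  if (area2 < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  gx <- seq.int(min(xy[, 1]), max(xy[, 1]))
  gy <- seq.int(min(xy[, 2]), max(xy[, 2]))
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  ok <- rep(TRUE, length(px))
  m <- nrow(v)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]; ey <- v[j, 2] - v[i, 2]
    cr <- ex * (py - v[i, 2]) - ey * (px - v[i, 1])
    ok <- ok & (cr >= -1e-9)
    if (!any(ok)) break
  }
  sum(ok)
}

## eccentricity of the ellipse with the region's second central moments
moments_eccentricity <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

#' Shape and intensity features of segmented cells
#'
#' One row per label: pixel area, convex-hull pixel area, solidity
#' (area / convex area), eccentricity of the moments-equivalent ellipse
#' (0 for a circle, approaching 1 for a line -- the region-properties
#' convention), centroid and mean IBA1 intensity.
#'
#' @param labels integer label matrix from [segment_cells()] (or a
#'   ground-truth mask).
#' @param iba1 optional intensity matrix of the same shape.
#' @return data.frame with columns `label`, `area`, `convex_area`,
#'   `solidity`, `eccentricity`, `centroid_x`, `centroid_y`,
#'   `mean_iba1`; zero rows for an empty mask.
#' @export
shape_features <- function(labels, iba1 = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    idx <- which(labels == ids[i], arr.ind = TRUE)
    xy <- cbind(x = idx[, 2], y = idx[, 1])
    area <- nrow(xy)
    cva <- convex_pixel_count(xy)
    out[[i]] <- data.frame(
      label = ids[i],
      area = area,
      convex_area = cva,
      solidity = area / cva,
      eccentricity = moments_eccentricity(xy),
      centroid_x = mean(xy[, "x"]),
      centroid_y = mean(xy[, "y"]),
      mean_iba1 = if (is.null(iba1)) NA_real_
                  else mean(iba1[labels == ids[i]]))
  }
  if (length(out) == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      convex_area = integer(0), solidity = numeric(0),
                      eccentricity = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), mean_iba1 = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Engulfed-synaptosome signal area of a field
#'
#' Counts pHrodo pixels above threshold that fall inside a segmented cell.
#' pHrodo fluoresces only in acidic phagolysosomes, so in-cell signal
#' indicates engulfed material; masking by the cell labels enforces the
#' same premise on synthetic images, where out-of-cell puncta contribute
#' nothing.
#'
#' @param phrodo numeric matrix (pHrodo channel).
#' @param labels integer cell label matrix, same shape.
#' @param params an [imaging_params()] (threshold settings).
#' @return pixel count (integer).
#' @export
synaptosome_area <- function(phrodo, labels, params = imaging_params()) {
  if (!all(dim(phrodo) == dim(labels)))
    stop("pHrodo channel and cell mask must have identical shape",
         call. = FALSE)
  ph <- if (params$background_correct) subtract_background(phrodo)
        else phrodo
  thr <- if (is.null(params$phrodo_threshold)) otsu_threshold(ph)
         else params$phrodo_threshold
  sum(ph > thr & labels > 0)
}

#' Measure one microscopy field
#'
#' Composes [segment_cells()], [shape_features()] and
#' [synaptosome_area()] into the per-field measurement row used by the
#' screen pipeline (cell count, synaptosome signal area, per-cell shape
#' summaries). Fields without any segmented cell are flagged `empty`;
#' over-segmentation is flagged later, plate-wise, by [overseg_filter()].
#'
#' @param channels list with matrices `nuclei`, `iba1`, `phrodo` (e.g.
#'   from [render_field()]'s image slices).
#' @param params an [imaging_params()].
#' @param plate,well,field_index identifiers carried into the output.
#' @return list with `summary` (one-row data.frame: plate, well,
#'   field_index, cell_count, synaptosome_area, mean_solidity,
#'   mean_eccentricity, mean_iba1, qc_flag) and `cells` (per-cell
#'   [shape_features()] table).
#' @export
measure_field <- function(channels, params = imaging_params(),
                          plate = "P01", well = "A01", field_index = 1L) {
  labels <- segment_cells(channels$nuclei, channels$iba1, params)
  cells <- shape_features(labels, channels$iba1)
  area <- synaptosome_area(channels$phrodo, labels, params)
  n <- nrow(cells)
  summary <- data.frame(
    plate = plate, well = well, field_index = field_index,
    cell_count = n,
    synaptosome_area = area,
    mean_solidity = if (n) mean(cells$solidity) else NA_real_,
    mean_eccentricity = if (n) mean(cells$eccentricity) else NA_real_,
    mean_iba1 = if (n) mean(cells$mean_iba1) else NA_real_,
    qc_flag = if (n == 0L) "empty" else "none",
    stringsAsFactors = FALSE)
  if (n > 0L) {
    cells$plate <- plate; cells$well <- well
    cells$field_index <- field_index
  }
  list(summary = summary, cells = cells)
}
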