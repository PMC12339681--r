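#' Specification of a synthetic microscopy field
#'
#' Describes a 3-channel field (nuclei, IBA1, pHrodo) to be painted by
#' [render_field()]: elliptical cells with known position, axes,
#' orientation and IBA1 intensity, plus pHrodo puncta placed inside or
#' outside cells, Gaussian noise and a constant background.
#'
#' @param width,height image size in pixels.
#' @param cells data.frame with columns `x`, `y` (centroid, pixels), `a`,
#'   `b` (major/minor semi-axes, pixels), `theta` (orientation, radians),
#'   `iba1` (intensity in (0, 1]); zero rows give a blank field.
#' @param puncta_inside,puncta_outside numbers of pHrodo puncta placed
#'   inside cells / clear of all cells.
#' @param puncta_radius punctum disk radius in pixels.
#' @param puncta_intensity pHrodo intensity of a punctum.
#' @param nucleus_frac nucleus disk radius as a fraction of the minor
#'   semi-axis.
#' @param background constant background level per channel.
#' @param noise_sd additive Gaussian noise SD.
#' @param overlap_cap maximum tolerated fraction of cell pixels claimed by
#'   more than one cell; above it [render_field()] errors (the assay
#'   assumes resolvable cells).
#' @param seed integer seed for puncta placement and noise.
#' @return validated list of class `field_render_spec`.
#' @export
field_render_spec <- function(width = 512L, height = 512L,
                              cells = data.frame(),
                              puncta_inside = 0L, puncta_outside = 0L,
                              puncta_radius = 3,
                              puncta_intensity = 0.8,
                              nucleus_frac = 0.35,
                              background = 0.05,
                              noise_sd = 0.01,
                              overlap_cap = 0.05,
                              seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               cells = cells, puncta_inside = as.integer(puncta_inside),
               puncta_outside = as.integer(puncta_outside),
               puncta_radius = puncta_radius,
               puncta_intensity = puncta_intensity,
               nucleus_frac = nucleus_frac,
               background = background, noise_sd = noise_sd,
               overlap_cap = overlap_cap, seed = as.integer(seed))
  if (spec$width < 8L || spec$height < 8L)
    stop("invalid field spec: image too small", call. = FALSE)
  if (nrow(cells) > 0L) {
    need <- c("x", "y", "a", "b", "iba1")
    if (!all(need %in% names(cells)))
      stop("invalid field spec: cells need columns x, y, a, b, iba1",
           call. = FALSE)
    if (is.null(cells$theta)) spec$cells$theta <- 0
    if (any(cells$a <= 0 | cells$b <= 0))
      stop("invalid field spec: cell axes must be > 0", call. = FALSE)
    if (any(cells$iba1 <= 0 | cells$iba1 > 1))
      stop("invalid field spec: iba1 intensities must lie in (0, 1]",
           call. = FALSE)
    if (any(cells$x < 1 | cells$x > width | cells$y < 1 | cells$y > height))
      stop("invalid field spec: cell centroids must lie within the image",
           call. = FALSE)
  }
  class(spec) <- "field_render_spec"
  spec
}

## pixel mask of an ellipse on an h x w grid (rows = y, cols = x)
ellipse_mask <- function(h, w, x0, y0, a, b, theta) {
  xr <- seq.int(max(1L, floor(x0 - a - 1)), min(w, ceiling(x0 + a + 1)))
  yr <- seq.int(max(1L, floor(y0 - a - 1)), min(h, ceiling(y0 + a + 1)))
  dx <- outer(yr * 0, xr - x0, "+")
  dy <- outer(yr - y0, xr * 0, "+")
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  list(rows = yr, cols = xr, inside = inside)
}

paint <- function(mat, piece, value, max = FALSE) {
  sub <- mat[piece$rows, piece$cols, drop = FALSE]
  if (max) sub[piece$inside] <- pmax(sub[piece$inside], value)
  else sub[piece$inside] <- value
  mat[piece$rows, piece$cols] <- sub
  mat
}

#' Render a synthetic 3-channel microscopy field
#'
#' Paints the cells and puncta of a [field_render_spec()] into a
#' nuclei / IBA1 / pHrodo image stack and returns the exact ground-truth
#' label masks. Puncta requested "inside" are centered on a cell pixel;
#' puncta requested "outside" keep their whole disk clear of every cell.
#'
#' @param spec a [field_render_spec()].
#' @return list with `image` (height x width x 3 array in [0, 1], channels
#'   nuclei, iba1, phrodo), `cell_mask` (integer label matrix),
#'   `puncta_mask` (integer label matrix) and `puncta` (data.frame: x, y,
#'   inside, area_px).
#' @export
render_field <- function(spec) {
  if (!inherits(spec, "field_render_spec"))
    stop("spec must be a field_render_spec", call. = FALSE)
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  cell_mask <- matrix(0L, h, w)
  nuclei <- matrix(0, h, w)
  iba1 <- matrix(0, h, w)
  n_cells <- nrow(spec$cells)
  overlap_px <- 0L
  painted_px <- 0L
  if (n_cells > 0L) {
    for (i in seq_len(n_cells)) {
      cl <- spec$cells[i, ]
      piece <- ellipse_mask(h, w, cl$x, cl$y, cl$a, cl$b, cl$theta)
      prev <- cell_mask[piece$rows, piece$cols, drop = FALSE]
      overlap_px <- overlap_px + sum(prev[piece$inside] > 0L)
      painted_px <- painted_px + sum(piece$inside)
      cell_mask <- paint(cell_mask, piece, i)
      iba1 <- paint(iba1, piece, cl$iba1, max = TRUE)
      nuc <- ellipse_mask(h, w, cl$x, cl$y,
                          max(2, spec$nucleus_frac * cl$b),
                          max(2, spec$nucleus_frac * cl$b), 0)
      nuclei <- paint(nuclei, nuc, 0.9, max = TRUE)
    }
    if (painted_px > 0 && overlap_px / painted_px > spec$overlap_cap)
      stop("cell overlap fraction ",
           signif(overlap_px / painted_px, 3), " exceeds cap ",
           spec$overlap_cap, call. = FALSE)
  }

  phrodo <- matrix(0, h, w)
  puncta_mask <- matrix(0L, h, w)
  puncta <- list()
  place_punctum <- function(k, inside) {
    r <- spec$puncta_radius
    if (inside) {
      px <- which(cell_mask > 0L)
      if (length(px) == 0L)
        stop("cannot place puncta inside cells: no cell pixels",
             call. = FALSE)
      at <- px[sample.int(length(px), 1L)]
    } else {
      ## keep the whole disk clear of cells
      for (try in 1:200) {
        x <- sample.int(w, 1L); y <- sample.int(h, 1L)
        rr <- max(1L, y - ceiling(r) - 1L):min(h, y + ceiling(r) + 1L)
        cc <- max(1L, x - ceiling(r) - 1L):min(w, x + ceiling(r) + 1L)
        if (all(cell_mask[rr, cc] == 0L)) break
        if (try == 200)
          stop("cannot place puncta outside cells", call. = FALSE)
      }
      at <- (x - 1L) * h + y
    }
    y0 <- (at - 1L) %% h + 1L
    x0 <- (at - 1L) %/% h + 1L
    piece <- ellipse_mask(h, w, x0, y0, r, r, 0)
    phrodo <<- paint(phrodo, piece, spec$puncta_intensity, max = TRUE)
    prev <- puncta_mask[piece$rows, piece$cols, drop = FALSE]
    newpx <- sum(piece$inside & prev == 0L)
    sub <- prev
    sub[piece$inside & prev == 0L] <- k
    puncta_mask[piece$rows, piece$cols] <<- sub
    data.frame(x = x0, y = y0, inside = inside, area_px = sum(piece$inside))
  }
  k <- 0L
  for (i in seq_len(spec$puncta_inside)) {
    k <- k + 1L
    puncta[[k]] <- place_punctum(k, TRUE)
  }
  for (i in seq_len(spec$puncta_outside)) {
    k <- k + 1L
    puncta[[k]] <- place_punctum(k, FALSE)
  }

  img <- array(spec$background, dim = c(h, w, 3L))
  img[, , 1] <- img[, , 1] + nuclei
  img[, , 2] <- img[, , 2] + iba1
  img[, , 3] <- img[, , 3] + phrodo
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img,
       cell_mask = cell_mask,
       puncta_mask = puncta_mask,
       puncta = if (k > 0L)
         do.call(rbind, c(puncta, list(make.row.names = FALSE)))
       else data.frame(x = numeric(0), y = numeric(0),
                       inside = logical(0), area_px = integer(0)))
}
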