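# Shared small fixtures, built in code at test time.

small_screen_cfg <- function(seed = 1L, ...) {
  screen_sim_config(n_compounds = 40L, n_replicates_per_compound = 3L,
                    fields_per_well = 6L, seed = seed, ...)
}

# a rendered field with disjoint disks and internal puncta
disk_field <- function(n = 5L, radius = 25, seed = 1L, puncta = 10L) {
  pos <- data.frame(x = c(60, 160, 260, 360, 440)[seq_len(n)],
                    y = c(60, 160, 260, 360, 120)[seq_len(n)])
  field_render_spec(cells = data.frame(x = pos$x, y = pos$y,
                                       a = radius, b = radius,
                                       theta = 0, iba1 = 0.8),
                    puncta_inside = puncta, noise_sd = 0.01, seed = seed)
}

# independent convex-hull pixel-count oracle (chull + pracma::inpolygon)
hull_pixel_oracle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2], idx[, 1])
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(nrow(unique(xy)))
  g <- expand.grid(x = seq(min(xy[, 1]), max(xy[, 1])),
                   y = seq(min(xy[, 2]), max(xy[, 2])))
  sum(pracma::inpolygon(g$x, g$y, xy[h, 1], xy[h, 2], boundary = TRUE))
}
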