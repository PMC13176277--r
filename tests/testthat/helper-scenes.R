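# Small-scale scene helpers shared across test files.

tiny_params <- function(count = 5, mode = "disjoint", scale = 0.15,
                        debris = 0, seed = 1, ...) {
  scene_params(count = count, overlap_mode = mode, debris_rate = debris,
               scale = scale, seed = seed, ...)
}

tiny_edge <- function(scale = 0.15, ...) edge_params(scale = scale, ...)

# Principal-axis extent of an instance's pixel mask (major-axis length).
mask_major_axis <- function(lin, H) {
  r <- ((lin - 1) %% H) + 1
  cc <- ((lin - 1) %/% H) + 1
  xy <- cbind(cc, r)
  v <- eigen(stats::cov(xy), symmetric = TRUE)$vectors[, 1]
  proj <- xy %*% v
  max(proj) - min(proj)
}
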