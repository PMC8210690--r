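# Shared phantom renders, cached per test run (rendering is cheap but many
# test files reuse the same scenes).

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, ...) {
  if (!exists(key, .phantom_cache)) {
    assign(key, render_phantom(phantom_spec(...)), .phantom_cache)
  }
  get(key, .phantom_cache)
}

noiseless_phantom <- function() cached_phantom("noiseless", noise_sigma = 0)
noisy_phantom <- function() cached_phantom("noisy", noise_sigma = 0.05)
decoy_phantom <- function() cached_phantom("decoy", noise_sigma = 0,
                                           decoy = TRUE)

# voxelization-error budget of a voxel region: (surface voxel count) x
# (voxel volume), the natural absolute error of comparing a voxelized
# volume against its continuous counterpart
surface_voxel_volume <- function(region, voxvol) {
  d <- dim(region)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- region
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  sum(region & !interior) * voxvol
}

# independent ImageJ .roi polyline writer used as the cross-format oracle
# for the binary ROI reader (big-endian, per the published format layout)
write_imagej_polyline <- function(vertices, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, nchars = 4, eos = NULL)
  wshort <- function(v) writeBin(as.integer(v), con, size = 2,
                                 endian = "big")
  wshort(227)                      # version
  writeBin(as.raw(c(5, 0)), con)   # type 5 = polyline, pad
  left <- min(vertices[, 1]); top <- min(vertices[, 2])
  wshort(top); wshort(left)
  wshort(max(vertices[, 2])); wshort(max(vertices[, 1]))
  wshort(nrow(vertices))           # n coordinates
  writeBin(raw(64 - 18), con)      # rest of the 64-byte header
  wshort(vertices[, 1] - left)     # x offsets
  wshort(vertices[, 2] - top)      # y offsets
  invisible(path)
}
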