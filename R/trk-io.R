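# TrackVis .trk version-2 I/O. Coordinates are stored in the format's
# native "voxel-mm" space (continuous voxel index times voxel size, origin
# at the corner of voxel (0,0,0)); the reference volume supplies voxel
# size, dimensions and the voxel-to-world transform recorded in the
# header.

#' Write streamlines to a TrackVis .trk (version 2) file
#'
#' @param set a nonempty [StreamlineSet-class].
#' @param reference [ImageVolume-class] defining voxel size, dimensions
#'   and the voxel-to-world header transform.
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readTrk()] for the inverse; round-tripping reproduces
#'   coordinates to within float32 precision (<= 1e-4 mm here).
#' @export
writeTrk <- function(set, reference, path) {
  stopifnot(is(set, "StreamlineSet"))
  if (!length(set@tracks)) stop("streamline set is empty")
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  sp <- voxelSpacing(reference)
  org <- imgOrigin(reference)
  d <- dim(reference)
  writeBin(c(charToRaw("TRACK"), raw(1)), con)     # id_string, padded
  writeBin(as.integer(d), con, size = 2)                 # dim
  writeBin(as.numeric(sp), con, size = 4)                # voxel_size
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4)        # origin (unused)
  writeBin(0L, con, size = 2)                            # n_scalars
  writeBin(raw(10 * 20), con)                            # scalar_name
  writeBin(0L, con, size = 2)                            # n_properties
  writeBin(raw(10 * 20), con)                            # property_name
  # vox_to_ras: world = diag(spacing) %*% (vox - 0.5 shift) + origin;
  # trk voxel-mm points are vox * spacing, so the affine maps voxel-mm
  # through spacing-normalised indices.
  aff <- rbind(cbind(diag(sp), org - sp / 2), c(0, 0, 0, 1))
  writeBin(as.numeric(t(aff)), con, size = 4)            # row-major 4x4
  writeBin(raw(444), con)                                # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)             # voxel_order
  writeBin(raw(4), con)                                  # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4) # image orient.
  writeBin(raw(2), con)                                  # pad1
  writeBin(raw(6), con)                                  # invert/swap flags
  writeBin(length(set@tracks), con, size = 4)            # n_count
  writeBin(2L, con, size = 4)                            # version
  writeBin(1000L, con, size = 4)                         # hdr_size
  for (p in set@tracks) {
    writeBin(nrow(p), con, size = 4)
    # world mm -> voxel-mm: continuous voxel index + 0.5, times spacing
    v <- sweep(sweep(p, 2, org, "-"), 2, sp, "/") + 0.5
    vm <- sweep(v, 2, sp, "*")
    writeBin(as.numeric(t(vm)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file written by [writeTrk()]
#'
#' @param path .trk file path.
#' @return list with `tracks` (list of n x 3 world-coordinate matrices),
#'   `dim`, `voxelSize` and `nTracks` from the header.
#' @export
readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, raw(), n = 6)[1:5])
  if (id != "TRACK") stop("not a TrackVis .trk file")
  d <- readBin(con, integer(), n = 3, size = 2)
  sp <- readBin(con, numeric(), n = 3, size = 4)
  invisible(readBin(con, numeric(), n = 3, size = 4))
  nScalars <- readBin(con, integer(), n = 1, size = 2)
  invisible(readBin(con, raw(), n = 200))
  nProps <- readBin(con, integer(), n = 1, size = 2)
  invisible(readBin(con, raw(), n = 200))
  aff <- matrix(readBin(con, numeric(), n = 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, raw(), n = 444 + 4 + 4 + 24 + 2 + 6))
  nCount <- readBin(con, integer(), n = 1, size = 4)
  version <- readBin(con, integer(), n = 1, size = 4)
  invisible(readBin(con, integer(), n = 1, size = 4))
  org <- aff[1:3, 4] + sp / 2
  tracks <- vector("list", nCount)
  for (i in seq_len(nCount)) {
    np <- readBin(con, integer(), n = 1, size = 4)
    vals <- readBin(con, numeric(),
                    n = np * (3 + nScalars), size = 4)
    vm <- matrix(vals, ncol = 3 + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (nProps > 0) invisible(readBin(con, numeric(), n = nProps, size = 4))
    v <- sweep(vm, 2, sp, "/") - 0.5
    tracks[[i]] <- sweep(sweep(v, 2, sp, "*"), 2, org, "+")
  }
  list(tracks = tracks, dim = d, voxelSize = sp, nTracks = nCount,
       version = version)
}
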