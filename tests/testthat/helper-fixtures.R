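# Shared test fixtures, all generated in code at test time.

# closed-form overlap for a pure translation s of a box with edges d
shift_overlap <- function(s, d) prod(pmax(0, 1 - abs(s) / d))

# seeded random rigid parameter vector: shifts up to `max_shift` mm per axis,
# rotations up to `max_rot` rad per axis
random_params <- function(max_shift = 3, max_rot = 0.3) {
  c(runif(3, -max_shift, max_shift), runif(3, -max_rot, max_rot))
}

# printed ground-truth grid of expected percent overlaps for the six simulated
# shifts (columns) and eight simulated isotropic voxel sizes (rows); values as
# printed, truncated at the fourth decimal place
printed_shift_table <- function() {
  shifts <- c(0.5, 1, 1.5, 2, 2.5, 3)
  sizes <- c(4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5)
  vals <- rbind(
    c(87.5,    75,      62.5,    50,      37.5,    25),
    c(85.7142, 71.4285, 57.1428, 42.8571, 28.5714, 14.2857),
    c(83.3333, 66.6666, 50,      33.3333, 16.6666, 0),
    c(80,      60,      40,      20,      0,       0),
    c(75,      50,      25,      0,       0,       0),
    c(66.6666, 33.3333, 0,       0,       0,       0),
    c(50,      0,       0,       0,       0,       0),
    c(0,       0,       0,       0,       0,       0)
  )
  dimnames(vals) <- list(sizes, shifts)
  vals
}

# published calibration lookup: STS (mm) vs STS_VVO (%) at slope 43.2422,
# rounded at the second decimal
published_lookup <- function() {
  data.frame(
    sts = seq(0, 1.5, by = 0.05),
    sts_vvo = c(100, 97.84, 95.68, 93.51, 91.35, 89.19, 87.03, 84.87, 82.70,
                80.54, 78.38, 76.22, 74.05, 71.89, 69.73, 67.57, 65.41, 63.24,
                61.08, 58.92, 56.76, 54.60, 52.43, 50.27, 48.11, 45.95, 43.79,
                41.62, 39.46, 37.30, 35.14)
  )
}

# truncate at the 4th decimal as the ground-truth table prints; the epsilon
# guards exact decimal values against float round-off just below a boundary
trunc4 <- function(x) floor(x * 1e4 + 1e-6) / 1e4

# minimal single-volume NIfTI-1 file written byte by byte, so header fields
# (including negative pixdim signs) can be set freely
write_minimal_nifti <- function(path, pixdim = c(3, 3, 3), dim3 = c(2L, 2L, 2L)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                          # sizeof_hdr
  writeBin(raw(36), con)                                 # unused legacy fields
  writeBin(c(3L, dim3, 1L, 1L, 1L, 1L), con, size = 2)   # dim[0..7]
  writeBin(raw(14), con)                                 # intent_p*, intent_code
  writeBin(c(16L, 32L), con, size = 2)                   # datatype float32, bitpix
  writeBin(0L, con, size = 2)                            # slice_start
  writeBin(c(0, pixdim, 1, 1, 1, 1), con, size = 4)      # pixdim[0..7]
  writeBin(352, con, size = 4)                           # vox_offset
  writeBin(c(1, 0), con, size = 4)                       # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                            # slice_end
  writeBin(raw(2), con)                                  # slice_code, xyzt_units
  writeBin(c(0, 0, 0), con, size = 4)                    # cal_max/min, slice_dur
  writeBin(0, con, size = 4)                             # toffset
  writeBin(c(0L, 0L), con, size = 4)                     # glmax, glmin
  writeBin(raw(80 + 24), con)                            # descrip, aux_file
  writeBin(c(0L, 0L), con, size = 2)                     # qform, sform codes
  writeBin(numeric(18), con, size = 4)                   # quatern/qoffset/srow
  writeBin(raw(16), con)                                 # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)          # magic
  writeBin(raw(4), con)                                  # extender
  writeBin(numeric(prod(dim3)), con, size = 4)           # voxel data
  invisible(path)
}
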