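# Container and table I/O.
#
# BMStack container: a single binary file holding one group per slow-axis
# position. Layout (all little-endian):
#   bytes 0-7   magic "PFOCESTK"
#   bytes 8-15  uint stored as double: JSON header length L in bytes
#   bytes 16-(16+L-1) UTF-8 JSON header: list of groups, each with
#     dims (n_t, n_z, n_x), dtype ("complex64"|"complex128") and the
#     bm_stack metadata fields
#   then, per group in order, the field array as interleaved
#     (Re, Im) float32 or float64 pairs in R column-major order.
# Bead tables: plain CSV with a fixed, documented column order, SI units.

.bmstack_magic <- "PFOCESTK"
.bmstack_meta <- c("frame_rate", "f_mod", "drive_phase", "pixel_z",
                   "pixel_x", "slow_position", "oct_wavelength",
                   "medium_index")

#' Write BM-mode stacks to the binary container format
#'
#' @param stacks A [bm_stack()] or list of them.
#' @param path Output file path.
#' @param dtype `"complex64"` (default; float32 pairs) or `"complex128"`.
#'   Downcasting to complex64 warns when the stored field would deviate by
#'   more than 1e-6 of the maximum magnitude.
#' @return `path`, invisibly.
#' @export
write_bmstack <- function(stacks, path, dtype = c("complex64",
                                                  "complex128")) {
  dtype <- match.arg(dtype)
  if (inherits(stacks, "bm_stack")) stacks <- list(stacks)
  stopifnot(all(vapply(stacks, inherits, logical(1), "bm_stack")))
  header <- lapply(stacks, function(s) {
    meta <- s[.bmstack_meta]
    c(list(dims = dim(s$field), dtype = dtype,
           noise_level = if (is.null(s$noise_level)) NA else
             s$noise_level),
      meta)
  })
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                            null = "null")
  hraw <- charToRaw(as.character(hjson))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.bmstack_magic), con)
  writeBin(as.numeric(length(hraw)), con, size = 8, endian = "little")
  writeBin(hraw, con)
  for (s in stacks) {
    v <- as.vector(s$field)
    inter <- as.numeric(rbind(Re(v), Im(v)))
    if (dtype == "complex64") {
      mx <- max(Mod(v))
      f32 <- writeBin(inter, raw(), size = 4, endian = "little")
      back <- readBin(f32, numeric(), n = length(inter), size = 4,
                      endian = "little")
      if (mx > 0 && max(abs(back - inter)) > 1e-6 * mx) {
        warning("complex64 downcast deviates by more than 1e-6 of the ",
                "maximum magnitude")
      }
      writeBin(f32, con)
    } else {
      writeBin(inter, con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' Read BM-mode stacks from the binary container format
#'
#' @param path Container file written by [write_bmstack()].
#' @return A list of [bm_stack()]s.
#' @export
read_bmstack <- function(path) {
  stopifnot(file.exists(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 8))
  if (!identical(magic, .bmstack_magic)) {
    stop("not a BMStack container (bad magic): ", path)
  }
  hlen <- readBin(con, numeric(), 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), hlen)),
                               simplifyVector = FALSE)
  lapply(header, function(h) {
    missing <- setdiff(c("dims", "dtype", .bmstack_meta), names(h))
    if (length(missing)) {
      stop("BMStack schema violation, missing attribute(s): ",
           paste(missing, collapse = ", "))
    }
    dims <- unlist(h$dims)
    n <- prod(dims)
    size <- if (h$dtype == "complex64") 4L else 8L
    inter <- readBin(con, numeric(), 2 * n, size = size,
                     endian = "little")
    field <- array(complex(real = inter[c(TRUE, FALSE)],
                           imaginary = inter[c(FALSE, TRUE)]), dims)
    bm_stack(field, frame_rate = h$frame_rate, f_mod = h$f_mod,
             drive_phase = h$drive_phase, pixel_z = h$pixel_z,
             pixel_x = h$pixel_x, slow_position = h$slow_position,
             oct_wavelength = h$oct_wavelength,
             medium_index = h$medium_index,
             noise_level = if (is.null(h$noise_level) ||
                               is.na(h$noise_level)) NULL else
               h$noise_level)
  })
}

.bead_table_cols <- c("id", "xc", "yc", "zc", "a_mech", "phi_mech",
                      "force", "g_prime", "g_double_prime", "loss_ratio",
                      "n_voxels", "qc")

#' Write a bead-record table as CSV
#'
#' Columns in fixed order: `id`, `xc`, `yc`, `zc` (m), `a_mech` (m),
#' `phi_mech` (rad), `force` (N), `g_prime` (Pa), `g_double_prime` (Pa),
#' `loss_ratio`, `n_voxels`, `qc`. Numeric values are written with 17
#' significant digits so that a round trip is stable to better than 1e-12
#' relative.
#'
#' @param records A `bead_record` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bead_table <- function(records, path) {
  missing <- setdiff(.bead_table_cols, names(records))
  if (length(missing)) {
    stop("bead table missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- records[, .bead_table_cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = which(
    names(df) == "qc"))
  invisible(path)
}

#' Read a bead-record table written by [write_bead_table()]
#'
#' Malformed rows raise an error naming the line; the loss-ratio column is
#' re-verified against `g_double_prime / g_prime` on read.
#'
#' @param path CSV path.
#' @return A `bead_record` data.frame.
#' @export
read_bead_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  ncol_expected <- length(.bead_table_cols)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(qc = "character"))
  if (!identical(names(raw), .bead_table_cols)) {
    stop("bead table header mismatch: expected ",
         paste(.bead_table_cols, collapse = ","))
  }
  nf <- vapply(seq_along(lines)[-1], function(i) {
    length(scan(text = lines[i], what = "character", sep = ",",
                quiet = TRUE))
  }, numeric(1))
  bad <- which(nf != ncol_expected)
  if (length(bad)) {
    stop("malformed bead-table row at line ", bad[1] + 1, " of ", path)
  }
  num_cols <- setdiff(.bead_table_cols, c("qc"))
  for (cc in num_cols) {
    raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  }
  chk <- is.finite(raw$g_prime) & raw$g_prime != 0 &
    is.finite(raw$g_double_prime) & is.finite(raw$loss_ratio)
  if (any(chk)) {
    rel <- abs(raw$loss_ratio[chk] -
                 raw$g_double_prime[chk] / raw$g_prime[chk]) /
      pmax(abs(raw$loss_ratio[chk]), .Machine$double.eps)
    if (any(rel > 1e-9)) {
      warning("loss_ratio column inconsistent with G''/G' in ", path)
    }
  }
  class(raw) <- c("bead_record", "data.frame")
  raw
}

#' Read a run configuration file
#'
#' YAML key/value configuration holding the beam, bead, medium and
#' acquisition parameters (SI units). Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return List with `beam` ([light_sheet_beam()]), `bead`
#'   ([bead_spec()]), `medium` ([medium_spec()]), `plan`
#'   ([acquisition_plan()]), `thresholds` (free list), `seed`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  known <- c("beam", "bead", "medium", "plan", "thresholds", "paths",
             "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(fn, args) do.call(fn, args %||% list())
  list(beam = build(light_sheet_beam, cfg$beam),
       bead = build(bead_spec, cfg$bead %||% list(diameter = 1.9e-6)),
       medium = build(medium_spec, cfg$medium),
       plan = build(acquisition_plan, cfg$plan),
       thresholds = cfg$thresholds %||% list(),
       paths = cfg$paths %||% list(),
       seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a force profile as CSV
#'
#' Long-format table with columns `x` (m), `z` (m), `force` (N).
#'
#' @param fp A [force_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(fp, path) {
  stopifnot(inherits(fp, "force_profile"))
  df <- expand.grid(x = fp$grid_x, z = fp$grid_z)
  df$force <- as.vector(fp$force)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a force profile from CSV written by [write_force_csv()]
#'
#' @param path CSV path.
#' @param provenance Provenance label for the profile.
#' @return A [force_profile()].
#' @export
read_force_csv <- function(path, provenance = "measured") {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "z", "force") %in% names(df)))
  gx <- sort(unique(df$x)); gz <- sort(unique(df$z))
  f <- matrix(NA_real_, length(gx), length(gz))
  f[cbind(match(df$x, gx), match(df$z, gz))] <- df$force
  force_profile(gx, gz, f, provenance = provenance)
}
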