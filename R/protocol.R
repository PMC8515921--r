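#' Electrode layout on the domain boundary
#'
#' Describes a ring of surface electrodes, numbered 1..n counter-clockwise,
#' by their angular positions on the boundary. The default places
#' `n_electrodes` evenly over \eqn{[0, 2\pi)} starting at angle 0.
#'
#' @param n_electrodes Number of electrodes (at least 4; 16 for the standard
#'   forearm band).
#' @param angular_positions Optional numeric vector of per-electrode boundary
#'   angles in radians, strictly increasing within \eqn{[0, 2\pi)}.
#' @return An object of class `eit_layout` with fields `n_electrodes` and
#'   `angular_positions`.
#' @examples
#' electrode_layout(16)
#' @export
electrode_layout <- function(n_electrodes = 16, angular_positions = NULL) {
  if (length(n_electrodes) != 1 || !is.finite(n_electrodes) ||
      n_electrodes != round(n_electrodes) || n_electrodes < 4) {
    stop("invalid layout: need at least 4 electrodes for an adjacent protocol",
         call. = FALSE)
  }
  n_electrodes <- as.integer(n_electrodes)
  if (is.null(angular_positions)) {
    angular_positions <- 2 * pi * (seq_len(n_electrodes) - 1) / n_electrodes
  }
  if (length(angular_positions) != n_electrodes ||
      any(!is.finite(angular_positions)) ||
      any(diff(angular_positions) <= 0) ||
      angular_positions[1] < 0 || angular_positions[n_electrodes] >= 2 * pi) {
    stop("invalid layout: angular positions must be strictly increasing in [0, 2*pi)",
         call. = FALSE)
  }
  structure(list(n_electrodes = n_electrodes,
                 angular_positions = angular_positions),
            class = "eit_layout")
}

#' Build the adjacent-drive / adjacent-measurement stimulation pattern
#'
#' Enumerates the standard adjacent protocol: current is driven through each
#' neighbouring electrode pair in turn, and for every injection the voltage is
#' read from every neighbouring pair that shares no electrode with the drive
#' pair. For n electrodes this yields n injections with n - 3 measurements
#' each, i.e. a frame of n(n - 3) values (208 for the 16-electrode band).
#'
#' Ordering is fixed and documented: drive pairs ascend by their first
#' electrode (1,2), (2,3), ..., (n,1); within an injection the measurement
#' pairs follow in rotational order starting two electrodes past the drive
#' pair. Reconstruction requires only that this order match the Jacobian rows,
#' which [forward_model()] guarantees by consuming the same pattern object.
#'
#' @param layout An [electrode_layout()].
#' @return An object of class `eit_pattern`: a data frame with integer columns
#'   `drive_pos`, `drive_neg`, `meas_pos`, `meas_neg` (1-based electrode
#'   labels) and attributes `n_electrodes` and `n_per_injection`.
#' @examples
#' p <- build_pattern(electrode_layout(16))
#' frame_length(p)  # 208
#' @export
build_pattern <- function(layout) {
  if (!inherits(layout, "eit_layout")) layout <- electrode_layout(layout)
  n <- layout$n_electrodes
  wrap <- function(e) ((e - 1L) %% n) + 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    offs <- seq.int(2L, n - 2L)          # n - 3 measurement pairs
    mp <- wrap(i + offs)
    rows[[i]] <- data.frame(drive_pos = i,
                            drive_neg = wrap(i + 1L),
                            meas_pos  = mp,
                            meas_neg  = wrap(mp + 1L))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_electrodes = n, n_per_injection = n - 3L,
            class = c("eit_pattern", "data.frame"))
}

#' Number of voltage values in one frame
#'
#' @param pattern An `eit_pattern` from [build_pattern()].
#' @return Integer count of pattern entries, n(n - 3).
#' @export
frame_length <- function(pattern) {
  stopifnot(inherits(pattern, "eit_pattern"))
  nrow(pattern)
}

#' Export a stimulation/measurement pattern as a delimited table
#'
#' Writes the four electrode-label columns (drive+, drive-, meas+, meas-) as
#' CSV, documenting the frame layout for external consumers.
#'
#' @param pattern An `eit_pattern`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "eit_pattern"))
  data.table::fwrite(as.data.frame(pattern), path)
  invisible(path)
}

# internal: adjacent-pair id (1..n) of a pair given by its first electrode
.pair_id <- function(first_electrode) as.integer(first_electrode)
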