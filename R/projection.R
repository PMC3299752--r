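# Reduced-dimensionality physics: forward projection of 3D peaks into tilted
# 2D planes S_{i,j}, +/- theta pairing, plane-level overlap merging, and
# back-projection.  ppm values from different nuclei cannot be combined
# directly, so projection operates on Hz offsets at a configured field.

#' Spectrometer field configuration
#'
#' @param h_mhz proton Larmor frequency in MHz (default 600.13).
#' @return list with Larmor frequencies (MHz) for 1H, 13C, 15N; the 13C and
#'   15N values use the standard frequency ratios.
#' @export
field_config <- function(h_mhz = 600.13) {
  stopifnot(h_mhz > 0)
  list(h_mhz = h_mhz,
       c_mhz = h_mhz * 0.251449530,
       n_mhz = h_mhz * 0.101329118)
}

#' Project a (13C, 15N) coordinate onto a tilted plane
#'
#' Returns `nuC * cos(theta) + sign * nuN * sin(theta)` in Hz, where nuC and
#' nuN are the ppm values converted to Hz offsets at the configured field,
#' theta = |angle| and sign follows the +/- pair member.  90 degrees returns
#' the 15N coordinate alone (the HSQC orthogonal plane); 0 degrees the 13C
#' coordinate alone (the 1H-13C orthogonal plane).
#'
#' @param c_ppm,n_ppm carbon / nitrogen chemical shifts (vectorized).
#' @param angle_deg signed angle, |angle| <= 90.
#' @param fc a [field_config()].
#' @return combined indirect coordinate(s) in Hz.
#' @export
project_frequency <- function(c_ppm, n_ppm, angle_deg, fc = field_config()) {
  if (any(abs(angle_deg) > 90)) stop("|angle_deg| must be <= 90")
  theta <- abs(angle_deg) * pi / 180
  s <- ifelse(angle_deg < 0, -1, 1)
  c_ppm * fc$c_mhz * cos(theta) + s * n_ppm * fc$n_mhz * sin(theta)
}

#' Invert a +/- pair of projections back to (13C, 15N)
#'
#' Solves the 2 x 2 linear system from the pair members:
#' `nuC = (v+ + v-) / (2 cos theta)`, `nuN = (v+ - v-) / (2 sin theta)`.
#' Exact inverse of [project_frequency()] for matched pairs.
#'
#' @param v_plus,v_minus combined coordinates (Hz) at +theta and -theta.
#' @param angle_deg positive angle strictly between 0 and 90.
#' @param fc a [field_config()].
#' @return list with `c_ppm` and `n_ppm`.
#' @export
back_project <- function(v_plus, v_minus, angle_deg, fc = field_config()) {
  if (any(angle_deg <= 0 | angle_deg >= 90))
    stop("back-projection needs 0 < angle < 90 (system singular at 0/90)")
  theta <- angle_deg * pi / 180
  nu_c <- (v_plus + v_minus) / (2 * cos(theta))
  nu_n <- (v_plus - v_minus) / (2 * sin(theta))
  list(c_ppm = nu_c / fc$c_mhz, n_ppm = nu_n / fc$n_mhz)
}

#' Simulate the observation of one tilted plane
#'
#' Corrupts the idealized peak list with the noise model (jitter, dropout,
#' artifacts; seeded per plane), projects every surviving peak onto the
#' plane, and merges peak sets closer than `h_tol` in 1H and `resolution`
#' in the combined dimension into single peaks (summed intensity,
#' intensity-weighted centroid).  The merges are how the simulator creates
#' the spectral overlap the engine must resolve.
#'
#' @param sample_peaks idealized `true_peaks` for one experiment.
#' @param experiment experiment id.
#' @param angle_deg signed integer angle; 90 = HSQC plane, 0 = 1H-13C plane.
#' @param noise a [noise_model()]; its seed is combined with the plane
#'   identity so every plane observes independent noise.
#' @param resolution combined-dimension merge tolerance in Hz.
#' @param fc a [field_config()].
#' @param h_tol 1H merge tolerance (ppm).
#' @param noise_floor plane noise floor (intensity units).
#' @param collected_at iteration index recorded on the plane.
#' @return object of class `tilt_plane`.
#' @export
simulate_plane <- function(sample_peaks, experiment, angle_deg,
                           noise = noise_model(), resolution = 30,
                           fc = field_config(), h_tol = 0.03,
                           noise_floor = 0.05, collected_at = 0L) {
  check_experiment(experiment)
  stopifnot(resolution > 0)
  plane_seed <- (noise$seed * 373L +
                 match(experiment, EXPERIMENTS) * 1009L +
                 (angle_deg + 90L) * 13L) %% .Machine$integer.max
  nm <- noise
  nm$seed <- as.integer(plane_seed)
  obs <- corrupt_peaks(sample_peaks, nm)
  v <- if (nrow(obs)) project_frequency(obs$c_ppm, obs$n_ppm, angle_deg, fc)
       else numeric(0)
  pk <- data.frame(h_ppm = obs$h_ppm, v_hz = v,
                   intensity = obs$intensity,
                   conclusive_prob = NA_real_,
                   src_residue = obs$src_residue,
                   artifact = obs$artifact,
                   n_merged = 1L)
  pk <- merge_plane_peaks(pk, h_tol, resolution)
  if (nrow(pk)) pk$id <- sprintf("%s@%+d#%d", experiment, angle_deg,
                                 seq_len(nrow(pk)))
  else pk$id <- character(0)
  structure(list(experiment = experiment, angle_deg = as.integer(angle_deg),
                 peaks = pk, noise_floor = noise_floor,
                 resolution = resolution, fc = fc, h_tol = h_tol,
                 collected_at = as.integer(collected_at)),
            class = "tilt_plane")
}

# Single-linkage merge of peaks closer than (h_tol, resolution); merged
# peaks get the intensity-weighted centroid, summed intensity, and the
# dominant contributor's provenance.
merge_plane_peaks <- function(pk, h_tol, resolution) {
  n <- nrow(pk)
  if (n < 2L) return(pk)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(pk$h_ppm)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (pk$h_ppm[j] - pk$h_ppm[i] >= h_tol) break
      if (abs(pk$v_hz[i] - pk$v_hz[j]) < resolution) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  out <- lapply(groups, function(idx) {
    w <- pk$intensity[idx]
    dom <- idx[which.max(w)]
    data.frame(h_ppm = sum(pk$h_ppm[idx] * w) / sum(w),
               v_hz = sum(pk$v_hz[idx] * w) / sum(w),
               intensity = sum(w),
               conclusive_prob = NA_real_,
               src_residue = pk$src_residue[dom],
               artifact = all(pk$artifact[idx]),
               n_merged = sum(pk$n_merged[idx]))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$h_ppm, out$v_hz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a tilted plane to a Sparky-like 2-column list
#'
#' Header line records experiment, angle, field and resolution; the hidden
#' simulator provenance columns are never written.
#'
#' @param plane a `tilt_plane`.
#' @param path output file.
#' @export
write_plane <- function(plane, path) {
  hdr <- sprintf("# experiment=%s angle=%+d field=%.2f resolution=%.1f noise_floor=%g",
                 plane$experiment, plane$angle_deg, plane$fc$h_mhz,
                 plane$resolution, plane$noise_floor)
  pk <- plane$peaks
  lines <- c(hdr,
             sprintf("%12s %10s %12s %12s %10s",
                     "Assignment", "w1", "w2", "Intensity", "Prob"),
             sprintf("%12s %10.4f %12.2f %12.4g %10.4f",
                     pk$id, pk$h_ppm, pk$v_hz, pk$intensity,
                     ifelse(is.na(pk$conclusive_prob), 0, pk$conclusive_prob)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tilted plane written by [write_plane()]
#' @param path file path.
#' @return a `tilt_plane` (without simulator provenance).
#' @export
read_plane <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get_field <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  pk <- if (length(body)) {
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    data.frame(h_ppm = as.numeric(parts[, 2]), v_hz = as.numeric(parts[, 3]),
               intensity = as.numeric(parts[, 4]),
               conclusive_prob = as.numeric(parts[, 5]),
               src_residue = NA_integer_, artifact = NA, n_merged = NA_integer_,
               id = parts[, 1])
  } else data.frame(h_ppm = numeric(0), v_hz = numeric(0),
                    intensity = numeric(0), conclusive_prob = numeric(0),
                    src_residue = integer(0), artifact = logical(0),
                    n_merged = integer(0), id = character(0))
  structure(list(experiment = get_field("experiment"),
                 angle_deg = as.integer(as.numeric(get_field("angle"))),
                 peaks = pk,
                 noise_floor = as.numeric(get_field("noise_floor")),
                 resolution = as.numeric(get_field("resolution")),
                 fc = field_config(as.numeric(get_field("field"))),
                 h_tol = 0.03, collected_at = NA_integer_),
            class = "tilt_plane")
}
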