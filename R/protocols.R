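#' Quantify Ca2+ alternans from a whole-cell Ca2+ trace
#'
#' Locates one Ca2+ transient peak per pacing interval (windows anchored to
#' the stimulus times) and reports the alternans amplitude as the absolute
#' difference of the last two transient peaks, the standard measure on a
#' 30-s paced run. Beats whose window contains no transient (missed beats)
#' are flagged, excluded, and reported with a warning.
#'
#' @param ca_trace data.frame with columns `t` (ms) and `ca_i` (uM), e.g.
#'   the `trace` of [run_simulation()], or a numeric vector sampled at 1 ms.
#' @param pcl pacing cycle length (ms); the trace must span >= 3 beats.
#' @param threshold amplitude (uM) above which the beat pattern is called
#'   alternating (default 0.01).
#' @return list of class `alternans_result`: `peaks` (per-beat maxima, uM),
#'   `peak_times` (ms), `amplitude` (|last - second-last|, uM),
#'   `alternating` (logical), `missed_beats` (count).
#' @export
alternans_amplitude <- function(ca_trace, pcl, threshold = 0.01) {
  if (is.numeric(ca_trace) && is.null(dim(ca_trace)))
    ca_trace <- data.frame(t = seq_along(ca_trace) - 1, ca_i = ca_trace)
  t <- ca_trace$t
  ca <- ca_trace$ca_i
  if (length(t) < 3) stop("trace too short")
  t_span <- max(t) - min(t)
  if (t_span < 3 * pcl) stop("trace must span at least 3 beats")
  beat0 <- floor(min(t) / pcl)
  beatn <- floor((max(t) - 1e-9) / pcl)
  peaks <- numeric(0); ptimes <- numeric(0); missed <- 0L
  for (b in beat0:beatn) {
    sel <- which(t >= b * pcl & t < (b + 1) * pcl)
    if (length(sel) < 3) next
    seg <- ca[sel]
    k <- which.max(seg)
    # a "peak" must rise above the window's starting (diastolic) level;
    # otherwise the beat failed to produce a transient
    if (seg[k] <= seg[1] + 1e-6 && seg[k] <= min(seg) + 1e-6) {
      missed <- missed + 1L
      next
    }
    peaks <- c(peaks, seg[k])
    ptimes <- c(ptimes, t[sel[k]])
  }
  if (missed > 0)
    warning(sprintf("%d beat(s) without a detectable Ca2+ transient were excluded", missed))
  amp <- if (length(peaks) >= 2) abs(diff(utils::tail(peaks, 2))) else 0
  structure(list(peaks = peaks, peak_times = ptimes, amplitude = amp,
                 alternating = amp > threshold, missed_beats = missed,
                 threshold = threshold),
            class = "alternans_result")
}

#' @export
print.alternans_result <- function(x, ...) {
  cat(sprintf("Ca2+ alternans: amplitude %.4f uM over %d beats (%s)\n",
              x$amplitude, length(x$peaks),
              if (x$alternating) "alternating" else "not alternating"))
  invisible(x)
}

#' One-axis bifurcation curve of last-two Ca2+ transient peaks
#'
#' Runs one simulation per grid point of a single scanned axis and records
#' the final two Ca2+ transient peaks, so period-2 (alternans) regimes show
#' as split branches. Per-point seeds are derived from the point coordinate
#' (not its position in the sequence), making the scan order-independent.
#'
#' @param params parameter list.
#' @param axis name of the scanned quantity: `"pcl"`, `"alpha_mptp"`,
#'   `"alpha_mcu"`, or a clamp target (`"camkii_act"`, `"atp_cyt"`,
#'   `"ros_cyt"`).
#' @param values numeric grid for the axis.
#' @param protocol base [protocol_spec()]; the axis overrides it per point.
#' @param seed master seed; each point uses `seed + 7919 * rank(value)` by
#'   coordinate hash.
#' @param threshold alternans-flag threshold (uM).
#' @return data.frame: axis value, `peak_a` and `peak_b` (last two peaks,
#'   uM), `amplitude`, `alternating`, `p_mptp` (terminal mPTP open
#'   fraction), `failed`.
#' @export
bifurcation_curve <- function(params, axis, values, protocol = protocol_spec(),
                              seed = 1,
                              threshold = params$analysis$alternans_threshold) {
  rows <- lapply(values, function(v) {
    pr <- protocol
    if (axis == "pcl") pr$pcl <- v
    else if (axis == "alpha_mptp") pr$alpha_mptp <- v
    else if (axis == "alpha_mcu") pr$alpha_mcu <- v
    else if (axis %in% c("camkii_act", "atp_cyt", "ros_cyt"))
      pr$clamps <- c(pr$clamps, list(list(target = axis, value = v)))
    else stop("unknown scan axis: ", axis)
    pt_seed <- point_seed(seed, v)
    out <- tryCatch(run_simulation(params, pr, seed = pt_seed),
                    error = function(e) e)
    if (inherits(out, "error"))
      return(data.frame(value = v, peak_a = NA_real_, peak_b = NA_real_,
                        amplitude = NA_real_, alternating = NA,
                        p_mptp = NA_real_, failed = TRUE))
    alt <- alternans_amplitude(out$trace, pr$pcl, threshold)
    pk <- utils::tail(alt$peaks, 2)
    data.frame(value = v,
               peak_a = if (length(pk) > 1) pk[1] else NA_real_,
               peak_b = if (length(pk) > 0) pk[length(pk)] else NA_real_,
               amplitude = alt$amplitude, alternating = alt$alternating,
               p_mptp = measure_mptp_open_fraction(out$trace, window = 2000),
               failed = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- axis
  out
}

# deterministic per-point seed from the coordinate value (order-independent)
point_seed <- function(seed, value) {
  h <- sum(utf8ToInt(format(value, digits = 10)) * 131^(seq_along(
    utf8ToInt(format(value, digits = 10))) %% 5))
  (as.integer(seed) + (h %% 1000003L)) %% .Machine$integer.max
}

#' Alternans onset pacing cycle length
#'
#' The onset is the longest PCL whose alternans amplitude exceeds the
#' threshold on the scanned grid (alternans appears at fast pacing and
#' disappears above the onset PCL). Returns `NA` if no grid point
#' alternates; a non-monotone pattern returns the longest alternating PCL
#' with a warning.
#'
#' @param curve data.frame from [bifurcation_curve()] over a `pcl` axis
#'   (columns `pcl` and `amplitude`).
#' @param threshold amplitude threshold (uM, default 0.01).
#' @return onset PCL (ms) or `NA`.
#' @export
onset_pcl <- function(curve, threshold = 0.01) {
  pcl <- curve$pcl
  amp <- curve$amplitude
  ok <- !is.na(amp)
  alt <- ok & amp > threshold
  if (!any(alt)) return(NA_real_)
  onset <- max(pcl[alt])
  below <- pcl < onset
  if (any(below & !alt & ok))
    warning("non-monotone alternans pattern below the onset PCL")
  onset
}

#' Terminal mPTP open fraction
#'
#' Time- and population-averaged fraction of mitochondria in the open state
#' over the final `window` ms of a trajectory — the standard way the open
#' probability is measured at the end of each simulation.
#'
#' @param trace trace data.frame (columns `t`, `p_mptp`).
#' @param window terminal averaging window (ms, default 2000).
#' @return open fraction in \[0, 1\].
#' @export
measure_mptp_open_fraction <- function(trace, window = 2000) {
  if (nrow(trace) == 0) return(NA_real_)
  t_end <- max(trace$t)
  sel <- trace$t > t_end - window
  mean(trace$p_mptp[sel])
}

#' Cartesian parameter scan
#'
#' Runs the model over the Cartesian product of the named axis grids and
#' tabulates, per point: alternans amplitude, last two Ca2+ transient
#' peaks, terminal mPTP open fraction, and final slow-variable values.
#' Per-point seeds are coordinate-hashed, so results do not depend on the
#' iteration order and points can be recomputed independently.
#'
#' @param params parameter list.
#' @param axes named list of numeric grids; names as in
#'   [bifurcation_curve()]'s `axis`.
#' @param protocol base [protocol_spec()].
#' @param seed master seed.
#' @return data.frame with one row per grid point, the axis columns first,
#'   then `peak_a`, `peak_b`, `amplitude`, `alternating`, `p_mptp`,
#'   `camkii_act`, `atp`, `ros`, `seed`, `failed`.
#' @export
run_scan <- function(params, axes, protocol = protocol_spec(), seed = 1) {
  stopifnot(length(axes) >= 1, !is.null(names(axes)), all(nzchar(names(axes))))
  grid_pts <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid_pts)), function(r) {
    pr <- protocol
    for (ax in names(axes)) {
      v <- grid_pts[[ax]][r]
      if (ax == "pcl") pr$pcl <- v
      else if (ax == "alpha_mptp") pr$alpha_mptp <- v
      else if (ax == "alpha_mcu") pr$alpha_mcu <- v
      else if (ax %in% c("camkii_act", "atp_cyt", "ros_cyt"))
        pr$clamps <- c(pr$clamps, list(list(target = ax, value = v)))
      else stop("unknown scan axis: ", ax)
    }
    pt_seed <- point_seed(seed, sum(vapply(names(axes), function(ax)
      point_seed(0L, grid_pts[[ax]][r]), 1) %% 1000003))
    out <- tryCatch(run_simulation(params, pr, seed = pt_seed),
                    error = function(e) e)
    base <- grid_pts[r, , drop = FALSE]
    rownames(base) <- NULL
    if (inherits(out, "error"))
      return(cbind(base, peak_a = NA_real_, peak_b = NA_real_,
                   amplitude = NA_real_, alternating = NA, p_mptp = NA_real_,
                   camkii_act = NA_real_, atp = NA_real_, ros = NA_real_,
                   seed = pt_seed, failed = TRUE))
    alt <- alternans_amplitude(out$trace, pr$pcl,
                               params$analysis$alternans_threshold)
    pk <- utils::tail(alt$peaks, 2)
    tr <- out$trace
    cbind(base,
          peak_a = if (length(pk) > 1) pk[1] else NA_real_,
          peak_b = if (length(pk) > 0) pk[length(pk)] else NA_real_,
          amplitude = alt$amplitude, alternating = alt$alternating,
          p_mptp = measure_mptp_open_fraction(tr, 2000),
          camkii_act = tr$camkii_act[nrow(tr)], atp = tr$atp[nrow(tr)],
          ros = tr$ros[nrow(tr)], seed = pt_seed, failed = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a trajectory or scan table to columnar text
#'
#' Time series and scan tables are written as CSV with a header line naming
#' the units; the generating configuration is echoed alongside as
#' structured text (YAML) for provenance.
#'
#' @param x trace or scan data.frame.
#' @param path output CSV path.
#' @param params optional parameter list echoed to `<path>.config.yaml`.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, params = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  units <- c(t = "ms", V = "mV", ca_i = "uM", ca_s = "uM", ca_jsr = "uM",
             ca_nsr = "uM", ca_m = "uM", p_mptp = "fraction", dpsi = "mV",
             ros = "uM", camkii_act = "fraction", atp = "mM",
             j_up = "uM/ms", j_rel = "uM/ms", dt_small = "flag",
             f_producing = "fraction", i_sti = "uA/cm2",
             pcl = "ms", amplitude = "uM", peak_a = "uM", peak_b = "uM")
  hdr <- vapply(names(x), function(nm)
    if (nm %in% names(units)) sprintf("%s[%s]", nm, units[[nm]]) else nm, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  if (nrow(x))
    utils::write.table(x, con, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(params))
    write_config(params, paste0(path, ".config.yaml"))
  invisible(path)
}

#' Total cell Ca2+ of a snapshot (conservation audit)
#'
#' Sums free plus instantaneously buffered Ca2+ over every compartment,
#' weighted by relative volume: with buffer factor beta, total compartment
#' Ca2+ is `free / beta` per unit volume. In a closed cell (sarcolemmal and
#' mitochondrial fluxes disabled, or mitochondrial content included as
#' here) this quantity is conserved by construction of the flux scheme up
#' to Euler round-off.
#'
#' @param snapshot snapshot list from [run_simulation()].
#' @param params parameter list.
#' @return total Ca2+ in volume-weighted uM units.
#' @export
total_calcium <- function(snapshot, params) {
  cr <- params$cru; mt <- params$mito
  sum(cr$v_p / cr$beta_p * snapshot$ca_p) +
    sum(cr$v_s / cr$beta_s * snapshot$ca_s) +
    sum(cr$v_i / cr$beta_i * snapshot$ca_i) +
    sum(cr$v_nsr * snapshot$ca_nsr) +
    sum(cr$v_jsr / cr$beta_jsr * snapshot$ca_jsr) +
    sum(mt$v_m / mt$beta_m * snapshot$ca_m)
}
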