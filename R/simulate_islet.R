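#' Simulation parameters for a synthetic islet recording
#'
#' Bundles the acquisition and generative parameters of the synthetic islet
#' Ca2+ recording. Defaults mirror a typical isolated-islet field of view:
#' about 50 ROIs imaged at 0.5 Hz (2 s frame interval), a 60 s pre-stimulus
#' baseline, and slow glucose-driven oscillations (period about 1 min) shared
#' by a coupled subpopulation of cells on top of independent shot noise.
#'
#' The generative model for cell i at frame time t is
#' \deqn{F_i(t) = f0_i (1 + a_i s(t - \tau_i) 1[t \ge t_{stim}]) + b k + \epsilon_{ik}}
#' where `s` is a unit-variance periodic signal shared by all coupled cells
#' (`a_i = coupling_amplitude` when cell i is coupled, else 0), `tau_i` is a
#' per-cell constant phase shift drawn Normal(0, `phase_jitter_s`), `b` is
#' `drift_slope` (fluorescence units per frame, `k` the 0-based frame index)
#' and `epsilon` is iid Normal(0, `noise_sd^2`).
#'
#' @param n_cells number of cells (ROIs); default 50.
#' @param field_radius radius of the imaged field, arbitrary length units.
#' @param min_spacing minimum pairwise distance between ROI centroids.
#' @param n_frames number of frames; default 300 (10 min at 0.5 Hz).
#' @param frame_interval_s frame interval in seconds; default 2 (0.5 Hz).
#' @param baseline_frames frames before stimulus onset; default 30 (60 s).
#' @param coupled_fraction probability that a cell joins the coupled
#'   subpopulation (ignored when `coupled_mask` is given); default 0.4.
#' @param coupled_mask optional logical vector of length `n_cells` fixing the
#'   coupled subpopulation explicitly.
#' @param coupling_amplitude fractional-fluorescence oscillation amplitude
#'   `a` (dimensionless); default 0.10, i.e. 10% of baseline.
#' @param oscillation_period_s period of the shared signal in seconds;
#'   default 60.
#' @param waveform shape of the shared signal: `"square"` (burst train,
#'   default) or `"sine"`; both are scaled to unit variance over full cycles.
#' @param phase_jitter_s standard deviation of the per-cell constant phase
#'   shift, seconds; default 0.
#' @param noise_sd standard deviation of the additive measurement noise,
#'   fluorescence units; default 8 (about 8% of the default baseline).
#' @param drift_slope linear drift in fluorescence units per frame; default 0.
#' @param f0_mean,f0_sd mean and sd of the per-cell baseline fluorescence
#'   `f0_i`; defaults 100 and 10.
#' @param seed integer seed; the same spec and seed give bit-identical output.
#' @return An object of class `islet_sim_spec` (a validated list of the
#'   above fields).
#' @seealso [simulate_islet()], [expected_pairwise_r()]
#' @export
islet_sim_spec <- function(n_cells = 50L,
                           field_radius = 100,
                           min_spacing = 8,
                           n_frames = 300L,
                           frame_interval_s = 2,
                           baseline_frames = 30L,
                           coupled_fraction = 0.4,
                           coupled_mask = NULL,
                           coupling_amplitude = 0.10,
                           oscillation_period_s = 60,
                           waveform = c("square", "sine"),
                           phase_jitter_s = 0,
                           noise_sd = 8,
                           drift_slope = 0,
                           f0_mean = 100,
                           f0_sd = 10,
                           seed = 1L) {
  waveform <- match.arg(waveform)
  if (!is_count(n_cells, min = 2L)) stopf("`n_cells` must be an integer >= 2")
  if (!is_count(n_frames, min = 2L)) stopf("`n_frames` must be an integer >= 2")
  if (!is_count(baseline_frames, min = 1L) || baseline_frames >= n_frames) {
    stopf("`baseline_frames` must satisfy 1 <= baseline_frames < n_frames")
  }
  if (!is_number(frame_interval_s) || frame_interval_s <= 0) {
    stopf("`frame_interval_s` must be > 0")
  }
  if (!is.null(coupled_mask)) {
    if (!is.logical(coupled_mask) || length(coupled_mask) != n_cells ||
        anyNA(coupled_mask)) {
      stopf("`coupled_mask` must be a logical vector of length n_cells")
    }
  } else if (!is_number(coupled_fraction) ||
             coupled_fraction < 0 || coupled_fraction > 1) {
    stopf("`coupled_fraction` must lie in [0, 1]")
  }
  for (nm in c("coupling_amplitude", "phase_jitter_s", "noise_sd", "f0_sd")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stopf("`%s` must be a non-negative number", nm)
  }
  if (!is_number(oscillation_period_s) || oscillation_period_s <= 0) {
    stopf("`oscillation_period_s` must be > 0")
  }
  if (!is_number(drift_slope)) stopf("`drift_slope` must be a finite number")
  if (!is_number(f0_mean) || f0_mean <= 0) stopf("`f0_mean` must be > 0")
  if (!is_count(seed, min = -.Machine$integer.max)) {
    stopf("`seed` must be a single integer")
  }
  structure(
    list(n_cells = as.integer(n_cells), field_radius = field_radius,
         min_spacing = min_spacing, n_frames = as.integer(n_frames),
         frame_interval_s = frame_interval_s,
         baseline_frames = as.integer(baseline_frames),
         coupled_fraction = coupled_fraction, coupled_mask = coupled_mask,
         coupling_amplitude = coupling_amplitude,
         oscillation_period_s = oscillation_period_s, waveform = waveform,
         phase_jitter_s = phase_jitter_s, noise_sd = noise_sd,
         drift_slope = drift_slope, f0_mean = f0_mean, f0_sd = f0_sd,
         seed = as.integer(seed)),
    class = "islet_sim_spec"
  )
}

#' @export
print.islet_sim_spec <- function(x, ...) {
  cat(sprintf(
    "<islet_sim_spec> %d cells, %d frames @ %g s (%d baseline)\n",
    x$n_cells, x$n_frames, x$frame_interval_s, x$baseline_frames))
  cat(sprintf(
    "  %s wave, period %g s, amplitude %g; noise sd %g; f0 %g +/- %g; seed %d\n",
    x$waveform, x$oscillation_period_s, x$coupling_amplitude, x$noise_sd,
    x$f0_mean, x$f0_sd, x$seed))
  invisible(x)
}

# Shared unit-variance oscillation evaluated at times `tt` (seconds relative
# to stimulus onset); zero-mean over full cycles.
oscillation_signal <- function(tt, period, waveform) {
  phase <- (tt / period) %% 1
  if (waveform == "square") {
    ifelse(phase < 0.5, 1, -1)
  } else {
    sqrt(2) * sin(2 * pi * phase)
  }
}

# The deterministic per-cell signal template on the spec's frame grid:
# s(t - tau) gated to post-stimulus frames (zero during baseline).
islet_signal <- function(spec, tau = 0) {
  t_s <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_s
  t_stim <- spec$baseline_frames * spec$frame_interval_s
  s <- oscillation_signal(t_s - t_stim - tau, spec$oscillation_period_s,
                          spec$waveform)
  s * (t_s >= t_stim)
}

#' Place ROI centroids in a circular field of view
#'
#' Rejection-samples `n` points uniformly on a disc of radius `field_radius`,
#' accepting a point only if it lies at least `min_spacing` from every point
#' already placed.
#'
#' @param n number of points.
#' @param field_radius disc radius.
#' @param min_spacing minimum pairwise distance (0 disables the constraint).
#' @param seed integer seed; placement is deterministic given the seed.
#' @param max_tries rejection attempts allowed per point.
#' @return A data frame with columns `cell_id`, `x`, `y`.
#' @examples
#' xy <- generate_coordinates(50, field_radius = 100, min_spacing = 10, seed = 7)
#' min(dist(xy[, c("x", "y")]))  # >= 10
#' @export
generate_coordinates <- function(n, field_radius, min_spacing = 0, seed = 1L,
                                 max_tries = 10000L) {
  if (!is_count(n)) stopf("`n` must be a positive integer")
  if (!is_number(field_radius) || field_radius <= 0) {
    stopf("`field_radius` must be > 0")
  }
  if (!is_number(min_spacing) || min_spacing < 0) {
    stopf("`min_spacing` must be >= 0")
  }
  with_seed(seed, {
    xs <- numeric(n)
    ys <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (tries in seq_len(max_tries)) {
        r <- field_radius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        x <- r * cos(th); y <- r * sin(th)
        if (placed == 0L ||
            min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
              min_spacing^2) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stopf(paste0("could not place %d points with min_spacing %g in a disc",
                     " of radius %g; densest feasible packing tried: %d points"),
              n, min_spacing, field_radius, placed)
      }
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
    data.frame(cell_id = paste0("cell_", seq_len(n)), x = xs, y = ys,
               stringsAsFactors = FALSE)
  })
}

#' Simulate an islet Ca2+ recording with known coupling structure
#'
#' Generates per-cell fluorescence traces under the generative model described
#' in [islet_sim_spec()], ROI coordinates via [generate_coordinates()], and
#' the planted ground truth (coupled mask, true edge set, and, when the
#' closed form applies, the expected pairwise Pearson correlation of each
#' true edge).
#'
#' A single RNG stream seeded from `spec$seed` draws the coupled mask and the
#' per-cell constants (baseline `f0_i`, phase shift `tau_i`, and one noise
#' sub-seed per cell); each cell's measurement noise then comes from its own
#' deterministic sub-stream, so identical specs give bit-identical output.
#'
#' @param spec an [islet_sim_spec()].
#' @return A list of class `islet_sim` with elements `traces`
#'   ([trace_matrix()]), `coords` (data frame `cell_id,x,y`), `truth` (list
#'   with `coupled_mask`, `true_edges` data frame `cell_a,cell_b,expected_r`),
#'   and `spec`.
#' @examples
#' sim <- simulate_islet(islet_sim_spec(n_cells = 10, n_frames = 100, seed = 3))
#' sim$traces
#' sum(sim$truth$coupled_mask)
#' @export
simulate_islet <- function(spec) {
  stopifnot(inherits(spec, "islet_sim_spec"))
  sim <- with_seed(spec$seed, {
    coord_seed <- sample.int(.Machine$integer.max, 1L)
    mask <- spec$coupled_mask %||%
      (stats::runif(spec$n_cells) < spec$coupled_fraction)
    f0 <- stats::rnorm(spec$n_cells, spec$f0_mean, spec$f0_sd)
    if (any(f0 <= 0)) {
      stopf("drawn baseline f0 <= 0; reduce `f0_sd` relative to `f0_mean`")
    }
    tau <- if (spec$phase_jitter_s > 0) {
      stats::rnorm(spec$n_cells, 0, spec$phase_jitter_s)
    } else {
      numeric(spec$n_cells)
    }
    cell_seeds <- sample.int(.Machine$integer.max, spec$n_cells)
    frame_idx <- seq_len(spec$n_frames) - 1
    vals <- matrix(0, spec$n_frames, spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      a_i <- if (mask[i]) spec$coupling_amplitude else 0
      s_i <- if (a_i > 0) islet_signal(spec, tau[i]) else 0
      noise <- with_seed(cell_seeds[i],
                         stats::rnorm(spec$n_frames, 0, spec$noise_sd))
      vals[, i] <- f0[i] * (1 + a_i * s_i) +
        spec$drift_slope * frame_idx + noise
    }
    list(mask = mask, f0 = f0, vals = vals, coord_seed = coord_seed)
  })
  coords <- generate_coordinates(spec$n_cells, spec$field_radius,
                                 spec$min_spacing, seed = sim$coord_seed)
  cell_ids <- coords$cell_id
  traces <- trace_matrix(sim$vals, cell_ids = cell_ids,
                         frame_interval_s = spec$frame_interval_s)
  truth <- make_ground_truth(spec, cell_ids, sim$mask, sim$f0)
  structure(list(traces = traces, coords = coords, truth = truth, spec = spec),
            class = "islet_sim")
}

make_ground_truth <- function(spec, cell_ids, mask, f0) {
  coupled <- which(mask)
  if (length(coupled) >= 2L) {
    pairs <- t(utils::combn(coupled, 2L))
    closed_form_ok <- spec$phase_jitter_s == 0 && spec$drift_slope == 0
    er <- if (closed_form_ok) {
      v_s <- stats::var(islet_signal(spec))
      r_cell <- function(f0_i) {
        sig <- spec$coupling_amplitude^2 * f0_i^2 * v_s
        if (spec$noise_sd == 0) {
          if (sig > 0) 1 else 0
        } else {
          sig / (sig + spec$noise_sd^2)
        }
      }
      sqrt(vapply(f0[pairs[, 1L]], r_cell, 0) *
             vapply(f0[pairs[, 2L]], r_cell, 0))
    } else {
      rep(NA_real_, nrow(pairs))
    }
    true_edges <- data.frame(cell_a = cell_ids[pairs[, 1L]],
                             cell_b = cell_ids[pairs[, 2L]],
                             expected_r = er, stringsAsFactors = FALSE)
  } else {
    true_edges <- data.frame(cell_a = character(), cell_b = character(),
                             expected_r = numeric(), stringsAsFactors = FALSE)
  }
  list(coupled_mask = stats::setNames(mask, cell_ids), true_edges = true_edges)
}

#' Closed-form expected pairwise correlation of coupled cells
#'
#' For a homogeneous spec (no phase jitter, no drift, `f0_sd = 0`) the
#' population Pearson correlation between two coupled traces is
#' \deqn{R = a^2 v / (a^2 v + \sigma^2)}
#' where `a` is `coupling_amplitude`, `sigma` is `noise_sd`, and
#' `v = f0_mean^2 * var(s)` is the variance over the frame grid of the shared
#' post-stimulus signal term at the baseline fluorescence (baseline frames,
#' where the signal is zero, included). This is the simulator's calibration
#' oracle: the empirical coupled-pair correlation converges to it as the
#' recording length grows.
#'
#' @param spec an [islet_sim_spec()] with `phase_jitter_s = 0`,
#'   `drift_slope = 0` and `f0_sd = 0`.
#' @return The expected Pearson correlation, a number in `[0, 1]`.
#' @examples
#' sp <- islet_sim_spec(phase_jitter_s = 0, drift_slope = 0, f0_sd = 0)
#' expected_pairwise_r(sp)
#' @export
expected_pairwise_r <- function(spec) {
  stopifnot(inherits(spec, "islet_sim_spec"))
  if (spec$phase_jitter_s != 0 || spec$drift_slope != 0) {
    stopf(paste0("the closed form requires phase_jitter_s = 0 and ",
                 "drift_slope = 0 (shared signal identical across cells)"))
  }
  if (spec$f0_sd != 0) {
    stopf("the closed form requires f0_sd = 0 (homogeneous baseline)")
  }
  if (spec$coupling_amplitude == 0) return(0)
  v <- spec$f0_mean^2 * stats::var(islet_signal(spec))
  sig <- spec$coupling_amplitude^2 * v
  if (spec$noise_sd == 0) return(1)
  sig / (sig + spec$noise_sd^2)
}

#' Noise level achieving a target coupled-pair correlation
#'
#' Inverts the [expected_pairwise_r()] closed form: returns the `noise_sd`
#' for which a homogeneous spec's coupled pairs have expected Pearson
#' correlation `target_r`.
#'
#' @param spec an [islet_sim_spec()] with `phase_jitter_s = 0` and
#'   `drift_slope = 0`; its `noise_sd` is ignored.
#' @param target_r desired expected correlation, in (0, 1].
#' @return The noise standard deviation (fluorescence units).
#' @export
noise_sd_for_target_r <- function(spec, target_r) {
  stopifnot(inherits(spec, "islet_sim_spec"))
  if (!is_number(target_r) || target_r <= 0 || target_r > 1) {
    stopf("`target_r` must lie in (0, 1]")
  }
  if (spec$phase_jitter_s != 0 || spec$drift_slope != 0) {
    stopf("calibration requires phase_jitter_s = 0 and drift_slope = 0")
  }
  if (spec$coupling_amplitude == 0) {
    stopf("`coupling_amplitude` is 0: no noise level can reach target_r > 0")
  }
  v <- spec$f0_mean^2 * stats::var(islet_signal(spec))
  sqrt(spec$coupling_amplitude^2 * v * (1 - target_r) / target_r)
}

#' @export
print.islet_sim <- function(x, ...) {
  cat(sprintf("<islet_sim> %d cells (%d coupled), %d frames; seed %d\n",
              x$spec$n_cells, sum(x$truth$coupled_mask), x$spec$n_frames,
              x$spec$seed))
  invisible(x)
}

#' Write planted ground truth to disk
#'
#' Writes the coupled-cell mask (`cell_id, coupled`) and the true edge list
#' (`cell_a, cell_b, expected_r`) as tab-delimited text.
#'
#' @param truth the `truth` element of a [simulate_islet()] result.
#' @param mask_path,edges_path output paths.
#' @export
write_ground_truth <- function(truth, mask_path, edges_path) {
  mask_df <- data.frame(cell_id = names(truth$coupled_mask),
                        coupled = as.logical(truth$coupled_mask))
  utils::write.table(mask_df, mask_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(truth$true_edges, edges_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(mask_path, edges_path))
}
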