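#' Tracer-experiment protocol
#'
#' Bench protocol of a lumbar bolus experiment: 2 mL of tracer injected over
#' 60 s at the lumbar site (x = 0 in injection-centric coordinates), then
#' observed for 10 min at 1-min frame intervals while CSF pulsation disperses
#' the bolus. The analysis clock starts at the end of the injection.
#'
#' @param injection_volume Injected volume (mL), default 2.
#' @param injection_duration Injection duration (s), default 60.
#' @param injection_position Injection site (cm), default 0.
#' @param injection_width Axial extent of the fresh bolus (cm), default 1.
#' @param observation_duration Recording length after injection (min),
#'   default 10.
#' @param frame_interval Frame spacing (min), default 1.
#' @param roi Analysis window `c(lower, upper)` (cm) or `NULL` for the full
#'   domain.
#' @return An object of class `experiment_protocol`.
#' @export
experiment_protocol <- function(injection_volume = 2, injection_duration = 60,
                                injection_position = 0, injection_width = 1,
                                observation_duration = 10, frame_interval = 1,
                                roi = NULL) {
  if (injection_volume <= 0 || injection_duration <= 0 ||
      injection_width <= 0 || observation_duration <= 0 ||
      frame_interval <= 0)
    stop("all protocol durations, volumes and widths must be > 0")
  structure(list(injection_volume = injection_volume,
                 injection_duration = injection_duration,
                 injection_position = injection_position,
                 injection_width = injection_width,
                 observation_duration = observation_duration,
                 frame_interval = frame_interval, roi = roi),
            class = "experiment_protocol")
}

#' Optical noise specification
#'
#' Noise model mimicking uneven lighting in video-derived intensity profiles:
#' multiplicative Gaussian noise (relative s.d. `multiplicative`) plus
#' additive Gaussian noise with s.d. `additive` times the record's peak
#' noise-free intensity; noisy intensities are clipped at zero.
#'
#' @param multiplicative Relative s.d. of multiplicative noise, default 0.05.
#' @param additive Additive noise s.d. as a fraction of peak intensity,
#'   default 0.02.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(multiplicative = 0.05, additive = 0.02) {
  if (multiplicative < 0 || additive < 0) stop("noise amplitudes must be >= 0")
  structure(list(multiplicative = multiplicative, additive = additive),
            class = "noise_spec")
}

#' Intensity record container
#'
#' Time-stamped axial intensity profiles standing in for video-derived tracer
#' concentration. `intensities` is a complete times-by-positions matrix.
#'
#' @param times Frame times (min), strictly increasing.
#' @param positions Axial positions (cm), strictly increasing.
#' @param intensities Matrix (length(times) x length(positions)), >= 0.
#' @param metadata Named list (frequency_bpm, stroke_volume_ml, D_true, drift,
#'   seed, nerve_root_factor, ...); may be empty.
#' @return An object of class `intensity_record`.
#' @export
intensity_record <- function(times, positions, intensities,
                             metadata = list()) {
  times <- as.numeric(times); positions <- as.numeric(positions)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(diff(positions) <= 0)) stop("'positions' must be strictly increasing")
  if (!is.matrix(intensities) ||
      nrow(intensities) != length(times) ||
      ncol(intensities) != length(positions))
    stop("'intensities' must be a times-by-positions matrix")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(times = times, positions = positions,
                 intensities = intensities, metadata = metadata),
            class = "intensity_record")
}

#' @export
print.intensity_record <- function(x, ...) {
  cat(sprintf("<intensity_record> %d frames x %d positions, t = [%g, %g] min\n",
              length(x$times), length(x$positions),
              min(x$times), max(x$times)))
  if (!is.null(x$metadata$D_true))
    cat(sprintf("  D_true = %g cm^2/min, drift = %g cm/min, seed = %s\n",
                x$metadata$D_true, x$metadata$drift %||% 0,
                format(x$metadata$seed %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One operator-split step: first-order upwind advection (explicit, CFL-safe
# via sub-stepping), then implicit diffusion. Conservative, with closed
# (no-outflow) walls so no mass leaves the dural sac.
advect_upwind <- function(v, velocity, dt, dx) {
  if (velocity == 0 || dt <= 0) return(v)
  n <- length(v)
  n_sub <- max(1L, as.integer(ceiling(abs(velocity) * dt / (0.9 * dx))))
  cfl <- velocity * (dt / n_sub) / dx
  for (k in seq_len(n_sub)) {
    if (cfl > 0) {
      flux <- cfl * v; flux[n] <- 0         # closed cranial wall
      v <- v - flux + c(0, flux[-n])
    } else {
      flux <- (-cfl) * v; flux[1L] <- 0     # closed sacral wall
      v <- v - flux + c(flux[-1L], 0)
    }
  }
  v
}

#' Simulate a synthetic tracer experiment
#'
#' Generates an intensity record with the statistical structure of the bench
#' experiments: (phase 1) a uniform volumetric source over `injection_width`
#' centered at the injection site for `injection_duration`, evolving under
#' effective diffusion `D_true` and constant caudocranial drift; (phase 2)
#' source off, advection-diffusion continues, frames sampled every
#' `frame_interval`. Frame times are measured from the end of the injection.
#' Optical noise (multiplicative + additive Gaussian, clipped at zero) is
#' applied per frame. Fully reproducible for a given seed.
#'
#' With `drift_velocity = 0` the phase-2 evolution is produced by
#' [solve_diffusion()] itself, so a noise-free, drift-free record is
#' bit-identical to the forward model used in the moment inversion.
#'
#' @param protocol An [experiment_protocol()].
#' @param D_true True effective dispersion coefficient (cm^2/min), >= 0.
#' @param drift_velocity Constant caudocranial drift (cm/min, positive toward
#'   the cranial direction), default 0.34 (the frequency correlation evaluated
#'   at 72 bpm).
#' @param noise A [noise_spec()] or `NULL` for noise-free output.
#' @param seed Integer RNG seed (required when `noise` is active).
#' @param grid A `grid1d`; default `build_grid(-6, 59, 650)` (sacral wall 6 cm
#'   caudal of the injection site, 65 cm canal, 0.1 cm cells).
#' @param gain Optical gain converting concentration to intensity, default 1.
#' @return An `intensity_record` with metadata recording the ground truth.
#' @examples
#' rec <- simulate_tracer_experiment(experiment_protocol(), D_true = 7.4,
#'                                   drift_velocity = 0, noise = NULL,
#'                                   seed = 1)
#' @export
simulate_tracer_experiment <- function(protocol = experiment_protocol(),
                                       D_true, drift_velocity = 0.34,
                                       noise = noise_spec(), seed = NULL,
                                       grid = build_grid(), gain = 1) {
  stopifnot(inherits(protocol, "experiment_protocol"),
            inherits(grid, "grid1d"))
  if (D_true < 0) stop("'D_true' must be >= 0")
  if (!is.null(noise) && !inherits(noise, "noise_spec"))
    stop("'noise' must be a noise_spec or NULL")
  has_noise <- !is.null(noise) &&
    (noise$multiplicative > 0 || noise$additive > 0)
  if (has_noise && is.null(seed)) stop("a seed is required for noisy records")

  dx <- grid$dx
  inj_min <- protocol$injection_duration / 60   # min
  src_cells <- which(abs(grid$centers - protocol$injection_position) <=
                       protocol$injection_width / 2)
  if (length(src_cells) == 0L) stop("injection window contains no grid cells")

  # phase 1: source + drift + diffusion, operator-split sub-steps
  n1 <- max(20L, n_substeps(D_true, inj_min, dx),
            as.integer(ceiling(abs(drift_velocity) * inj_min / (0.9 * dx))))
  dt1 <- inj_min / n1
  v <- numeric(grid$n_cells)
  dC_src <- protocol$injection_volume * dt1 / inj_min /
    (length(src_cells) * dx)                     # unit source concentration
  fac1 <- if (D_true > 0) diffusion_factor(grid, D_true, dt1) else NULL
  for (k in seq_len(n1)) {
    v[src_cells] <- v[src_cells] + dC_src
    v <- advect_upwind(v, drift_velocity, dt1, dx)
    if (!is.null(fac1)) v <- as.numeric(Matrix::solve(fac1, v, system = "A"))
  }

  # phase 2: frames at 0, frame_interval, ..., observation_duration
  frame_times <- seq(0, protocol$observation_duration,
                     by = protocol$frame_interval)
  n_frames <- length(frame_times)
  conc <- matrix(0, nrow = n_frames, ncol = grid$n_cells)
  conc[1L, ] <- v
  if (drift_velocity == 0) {
    if (n_frames > 1L) {
      sol <- solve_diffusion(concentration_field(grid, 0, v), D_true,
                             frame_times[-1L])
      conc[-1L, ] <- sol$values
    }
  } else {
    for (i in seq_len(n_frames - 1L)) {
      interval <- frame_times[i + 1L] - frame_times[i]
      n2 <- max(n_substeps(D_true, interval, dx),
                as.integer(ceiling(abs(drift_velocity) * interval /
                                     (0.9 * dx))))
      dt2 <- interval / n2
      fac2 <- if (D_true > 0) diffusion_factor(grid, D_true, dt2) else NULL
      for (k in seq_len(n2)) {
        v <- advect_upwind(v, drift_velocity, dt2, dx)
        if (!is.null(fac2))
          v <- as.numeric(Matrix::solve(fac2, v, system = "A"))
      }
      conc[i + 1L, ] <- v
    }
  }

  intens <- gain * conc
  if (has_noise) {
    set.seed(seed)
    peak <- max(intens)
    mult <- matrix(stats::rnorm(length(intens), 0, noise$multiplicative),
                   nrow = n_frames)
    add <- matrix(stats::rnorm(length(intens), 0, noise$additive * peak),
                  nrow = n_frames)
    intens <- pmax(intens * (1 + mult) + add, 0)
  }

  intensity_record(frame_times, grid$centers, intens,
                   metadata = list(D_true = D_true, drift = drift_velocity,
                                   seed = seed, gain = gain,
                                   injection_volume = protocol$injection_volume,
                                   injection_width = protocol$injection_width,
                                   nerve_root_factor = 1))
}

#' Evaluate the dimensional dispersion correlation
#'
#' `log10 D = a0 + a1 f + a2 f^2 + kappa log10 Urms`, the dimensional law
#' linking effective dispersion to pulsation frequency and RMS velocity.
#'
#' @param frequency Frequency (bpm).
#' @param urms RMS velocity (cm/s).
#' @param coefficients Named list/vector with `a0`, `a1`, `a2`, `kappa`;
#'   default the published best-fit values.
#' @return Dispersion coefficient (cm^2/min).
#' @export
dimensional_law <- function(frequency, urms,
                            coefficients = dispersion_coefficients()) {
  co <- as.list(coefficients)
  10^(co$a0 + co$a1 * frequency + co$a2 * frequency^2 +
        co$kappa * log10(urms))
}

#' Published best-fit coefficients of the dimensional dispersion law
#'
#' @return Named list with `a0 = -1.2220`, `a1 = 0.0067`,
#'   `a2 = -8.2069e-5`, `kappa = 0.9830`.
#' @export
dispersion_coefficients <- function() {
  list(a0 = -1.2220, a1 = 0.0067, a2 = -8.2069e-5, kappa = 0.9830)
}

#' Generate a cohort of synthetic tracer experiments
#'
#' For every combination of pulsation frequency and stroke volume, derives the
#' CSF state, computes the true dispersion coefficient from the dimensional
#' correlation (optionally with log-normal scatter and a nerve-root
#' enhancement factor), and simulates one tracer record with a distinct
#' derived seed.
#'
#' @param frequencies Frequencies (bpm), non-empty.
#' @param stroke_volumes Stroke volumes (mL/beat), non-empty.
#' @param coefficients Dimensional-law coefficients, see [dimensional_law()].
#' @param noise A [noise_spec()] or `NULL`.
#' @param seed Master seed; run i uses `seed + i`.
#' @param scatter_sd S.d. of log10-normal scatter applied to D_true,
#'   default 0.
#' @param nerve_root_factor Multiplier on D_true representing geometry-induced
#'   mixing around nerve roots (1 = nerve roots present baseline; the
#'   published no-roots vs roots contrast corresponds to a 4.211-fold factor).
#' @param protocol,grid,constants Passed to the generator / CSF state.
#' @param drift_velocity Drift (cm/min); `NULL` (default) evaluates the
#'   frequency CCV law [ccv_coefficients()] at each frequency.
#' @return A list of entries, each with `state` (`csf_state`), `record`
#'   (`intensity_record`) and `D_true`.
#' @export
generate_cohort <- function(frequencies, stroke_volumes,
                            coefficients = dispersion_coefficients(),
                            noise = noise_spec(), seed = 1,
                            scatter_sd = 0, nerve_root_factor = 1,
                            protocol = experiment_protocol(),
                            grid = build_grid(),
                            constants = physiology_constants(),
                            drift_velocity = NULL) {
  if (length(frequencies) == 0L || length(stroke_volumes) == 0L)
    stop("'frequencies' and 'stroke_volumes' must be non-empty")
  runs <- expand.grid(frequency = frequencies, stroke_volume = stroke_volumes,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  scatter <- if (scatter_sd > 0)
    stats::rnorm(nrow(runs), 0, scatter_sd) else numeric(nrow(runs))
  lapply(seq_len(nrow(runs)), function(i) {
    st <- csf_state(runs$frequency[i], runs$stroke_volume[i], constants)
    d_true <- dimensional_law(st$frequency, st$urms, coefficients) *
      nerve_root_factor * 10^scatter[i]
    drift <- drift_velocity %||%
      (ccv_coefficients("frequency")$a * st$frequency +
         ccv_coefficients("frequency")$b)
    rec <- simulate_tracer_experiment(protocol, D_true = d_true,
                                      drift_velocity = drift, noise = noise,
                                      seed = seed + i, grid = grid)
    rec$metadata$frequency_bpm <- st$frequency
    rec$metadata$stroke_volume_ml <- st$stroke_volume
    rec$metadata$nerve_root_factor <- nerve_root_factor
    list(state = st, record = rec, D_true = d_true)
  })
}

#' Published caudocranial-velocity correlation coefficients
#'
#' Linear laws `CCV = a f + b` (frequency form, f in bpm) and
#' `CCV = a Urms + b` (velocity form, Urms in cm/s), CCV in cm/min.
#'
#' @param regressor `"frequency"` or `"urms"`.
#' @return Named list with `a` and `b`.
#' @export
ccv_coefficients <- function(regressor = c("frequency", "urms")) {
  regressor <- match.arg(regressor)
  if (regressor == "frequency") list(a = 0.0018, b = 0.2144)
  else list(a = 0.0046, b = 0.2650)
}
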