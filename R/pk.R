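#' Parameters of the distributed six-compartment PK model
#'
#' Compartments: C1 spinal CSF (spatially distributed along the neuraxis),
#' C2 spinal tissue (distributed, local exchange per axial position, no axial
#' diffusion), C3 cranial CSF, C4 cranial tissue, C5 blood plasma, C6
#' peripheral (all lumped). The spinal CSF obeys an advection-diffusion-
#' reaction equation with first-order loss `k1` and two-film mass-transfer
#' fluxes `sigma * (C_source - K * C_sink)` to spinal tissue (`sigma12`,
#' `K12`) and blood (`sigma15`, `K15`). Lumped couplings (C1<->C3 at the
#' cranial boundary cell, C3<->C4, C3<->C5, C5<->C6) use the same flux form
#' and default to zero, so by default the printed spinal-CSF equations alone
#' define the dynamics. Lumped default volumes are structural placeholders,
#' not fitted physiology.
#'
#' @param Deff Effective dispersion coefficient in spinal CSF (cm^2/min).
#' @param k1 First-order loss rate in spinal CSF (1/min), default 0.
#' @param sigma12,K12 CSF -> spinal-tissue transfer rate (1/min) and partition
#'   coefficient, defaults 0 and 1.
#' @param sigma15,K15 CSF -> blood leakage rate and partition, defaults 0, 1.
#' @param csf_area,tissue_area Cross-sectional areas (cm^2) used to convert
#'   distributed concentrations to amounts, defaults 2 and 1.
#' @param lumped_volumes Named numeric `c(c3=, c4=, c5=, c6=)` (mL).
#' @param lumped_transfer Named list of `sigma13`, `K13`, `sigma34`, `K34`,
#'   `sigma35`, `K35`, `sigma56`, `K56`; all sigmas default 0, all Ks 1.
#' @param clearance Named numeric `c(c3=, c4=, c5=, c6=)` first-order
#'   clearance rates (1/min), default 0.
#' @return An object of class `pk_parameters`.
#' @export
pk_parameters <- function(Deff, k1 = 0, sigma12 = 0, K12 = 1,
                          sigma15 = 0, K15 = 1,
                          csf_area = 2, tissue_area = 1,
                          lumped_volumes = c(c3 = 150, c4 = 1000,
                                             c5 = 5000, c6 = 40000),
                          lumped_transfer = list(),
                          clearance = c(c3 = 0, c4 = 0, c5 = 0, c6 = 0)) {
  lt_def <- list(sigma13 = 0, K13 = 1, sigma34 = 0, K34 = 1,
                 sigma35 = 0, K35 = 1, sigma56 = 0, K56 = 1)
  lt_def[names(lumped_transfer)] <- lumped_transfer
  cl_def <- c(c3 = 0, c4 = 0, c5 = 0, c6 = 0)
  cl_def[names(clearance)] <- clearance
  rates <- c(Deff = Deff, k1 = k1, sigma12 = sigma12, sigma15 = sigma15,
             unlist(lt_def[grep("sigma", names(lt_def))]), cl_def)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(lumped_volumes <= 0) || csf_area <= 0 || tissue_area <= 0)
    stop("volumes and areas must be > 0")
  structure(list(Deff = Deff, k1 = k1, sigma12 = sigma12, K12 = K12,
                 sigma15 = sigma15, K15 = K15, csf_area = csf_area,
                 tissue_area = tissue_area, lumped_volumes = lumped_volumes,
                 lumped_transfer = lt_def, clearance = cl_def),
            class = "pk_parameters")
}

#' Dose event
#'
#' An intrathecal infusion: a volumetric source of drug solution delivered at
#' a given axial position over a finite window.
#'
#' @param start_time Start (min).
#' @param duration Duration (min), > 0.
#' @param rate Volumetric infusion rate (mL/min), >= 0.
#' @param concentration Drug concentration of the infusate (amount/mL).
#' @param position Injection site (cm), default 0.
#' @param width Axial extent of the source (cm), default 1.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(start_time, duration, rate, concentration,
                       position = 0, width = 1) {
  if (duration <= 0) stop("'duration' must be > 0")
  if (rate < 0) stop("'rate' must be >= 0")
  if (concentration < 0 || width <= 0)
    stop("'concentration' must be >= 0 and 'width' > 0")
  structure(list(start_time = start_time, duration = duration, rate = rate,
                 concentration = concentration, position = position,
                 width = width), class = "dose_event")
}

#' Two-film mass-transfer flux
#'
#' `sigma * (c_source - K * c_sink)`: positive values transfer drug out of
#' the source (CSF) compartment; the flux vanishes at partition equilibrium
#' `c_source = K * c_sink`.
#'
#' @param c_source,c_sink Concentrations (amount/mL).
#' @param sigma Mass-transfer coefficient (1/min), >= 0.
#' @param K Partition (distribution) coefficient, dimensionless.
#' @return Flux as a source-compartment concentration rate (amount/(mL min)).
#' @examples
#' mass_transfer_flux(2, 1, 0.5, 1)  # 0.5
#' @export
mass_transfer_flux <- function(c_source, c_sink, sigma, K) {
  if (any(sigma < 0)) stop("'sigma' must be >= 0")
  sigma * (c_source - K * c_sink)
}

# Sparse generator matrix A of the reaction/mass-transfer ODE system on
# AMOUNTS (a1_1..a1_n, a2_1..a2_n, a3, a4, a5, a6). Columns of A sum to the
# negative of the loss rates (k1, clearances), so backward Euler conserves
# total mass exactly in closed configurations.
pk_transfer_matrix <- function(params, n, v1, v2) {
  lv <- params$lumped_volumes; lt <- params$lumped_transfer
  i1 <- seq_len(n); i2 <- n + seq_len(n)
  j3 <- 2L * n + 1L; j4 <- 2L * n + 2L; j5 <- 2L * n + 3L; j6 <- 2L * n + 4L
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(i, j, x) {
    trip$i <<- c(trip$i, i); trip$j <<- c(trip$j, j); trip$x <<- c(trip$x, x)
  }
  if (params$k1 > 0) add(i1, i1, rep(-params$k1, n))
  if (params$sigma12 > 0) {
    s <- params$sigma12; kk <- params$K12 * v1 / v2
    add(i1, i1, rep(-s, n)); add(i1, i2, rep(s * kk, n))
    add(i2, i1, rep(s, n));  add(i2, i2, rep(-s * kk, n))
  }
  if (params$sigma15 > 0) {
    s <- params$sigma15; kk <- params$K15 * v1 / lv[["c5"]]
    add(i1, i1, rep(-s, n)); add(i1, rep(j5, n), rep(s * kk, n))
    add(rep(j5, n), i1, rep(s, n)); add(j5, j5, -n * s * kk)
  }
  if (lt$sigma13 > 0) {  # cranial boundary cell <-> cranial CSF
    s <- lt$sigma13; kk <- lt$K13 * v1 / lv[["c3"]]
    add(n, n, -s); add(n, j3, s * kk)
    add(j3, n, s); add(j3, j3, -s * kk)
  }
  lump <- function(sig, K, ja, jb, va, vb) {
    if (sig > 0) {
      add(ja, ja, -sig); add(ja, jb, sig * K * va / vb)
      add(jb, ja, sig);  add(jb, jb, -sig * K * va / vb)
    }
  }
  lump(lt$sigma34, lt$K34, j3, j4, lv[["c3"]], lv[["c4"]])
  lump(lt$sigma35, lt$K35, j3, j5, lv[["c3"]], lv[["c5"]])
  lump(lt$sigma56, lt$K56, j5, j6, lv[["c5"]], lv[["c6"]])
  cl <- params$clearance
  for (k in 1:4) if (cl[k] > 0) add(2L * n + k, 2L * n + k, -cl[[k]])
  if (length(trip$i) == 0L)
    return(Matrix::sparseMatrix(i = 1L, j = 1L, x = 0,
                                dims = c(2L * n + 4L, 2L * n + 4L)))
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                       dims = c(2L * n + 4L, 2L * n + 4L))
}

# Spatially varying upwind advection (closed walls), CFL sub-stepped.
advect_field <- function(v, vel, dt, dx) {
  n <- length(v)
  umax <- max(abs(vel))
  if (umax == 0 || dt <= 0) return(v)
  n_sub <- max(1L, as.integer(ceiling(umax * dt / (0.9 * dx))))
  dts <- dt / n_sub
  uh <- (vel[-n] + vel[-1L]) / 2          # interface velocities, walls closed
  for (k in seq_len(n_sub)) {
    fl <- ifelse(uh > 0, uh * v[-n], uh * v[-1L])   # upwind interface flux
    v <- v - c(fl, 0) * dts / dx + c(0, fl) * dts / dx
  }
  v
}

#' Simulate the distributed six-compartment PK model
#'
#' Operator-split integration of the spinal-CSF advection-diffusion-reaction
#' equation coupled to the distributed tissue compartment and the lumped
#' compartments. Per split step: (i) injection-driven convection, with bulk
#' velocity `rate/2 / csf_area` directed away from the injection site on
#' either side, active only during dose events; (ii) implicit (backward-
#' Euler) diffusion with `Deff`; (iii) implicit reaction/mass-transfer update
#' of all compartments, with degraded/cleared mass accumulated in a sink.
#'
#' With reaction, transfer and convection all switched off the integrator
#' takes the identical code path as [solve_diffusion()], so the tracer-
#' matching reduction is exact.
#'
#' @param params A [pk_parameters()].
#' @param doses List of [dose_event()]s (possibly empty).
#' @param grid A `grid1d` for the spinal axis.
#' @param output_times Times (min) at which to record state, increasing,
#'   starting at or after 0.
#' @param initial Optional single-frame `concentration_field` for C1 at time
#'   0 (default: zero everywhere).
#' @param dt_split Operator-splitting step (min), default 0.5; reduced
#'   automatically to resolve dose events. Smaller values reduce splitting
#'   and backward-Euler error.
#' @return An object of class `pk_trajectory`: `times`, `c1` and `c2`
#'   (time-by-cell concentration matrices), `lumped` (time-by-4 matrix of
#'   C3..C6 concentrations), `cumulative_injected`, `cumulative_degraded`
#'   (vectors per output time), `grid`, `params`.
#' @export
simulate_pk <- function(params, doses = list(), grid = build_grid(),
                        output_times = seq(0, 10), initial = NULL,
                        dt_split = 0.5) {
  stopifnot(inherits(params, "pk_parameters"), inherits(grid, "grid1d"))
  if (inherits(doses, "dose_event")) doses <- list(doses)
  output_times <- as.numeric(output_times)
  if (any(diff(output_times) <= 0)) stop("'output_times' must be increasing")
  n <- grid$n_cells; dx <- grid$dx
  v1 <- params$csf_area * dx; v2 <- params$tissue_area * dx
  lv <- params$lumped_volumes

  c1 <- if (is.null(initial)) numeric(n) else {
    stopifnot(inherits(initial, "concentration_field"))
    as.numeric(initial$values[1L, ])
  }
  c2 <- numeric(n); lumped <- c(c3 = 0, c4 = 0, c5 = 0, c6 = 0)
  injected <- 0; degraded <- 0

  lt <- params$lumped_transfer
  coupling <- params$k1 > 0 || params$sigma12 > 0 || params$sigma15 > 0 ||
    any(unlist(lt[grep("sigma", names(lt))]) > 0) || any(params$clearance > 0)
  A <- if (coupling) pk_transfer_matrix(params, n, v1, v2) else NULL
  loss_w <- if (coupling) {
    w <- numeric(2L * n + 4L)
    w[seq_len(n)] <- params$k1
    w[2L * n + 1:4] <- params$clearance
    w
  } else NULL
  fac_cache <- new.env(parent = emptyenv())
  get_facs <- function(dt) {
    key <- format(dt, digits = 17)
    if (is.null(fac_cache[[key]])) {
      fac_cache[[key]] <- list(
        diff = if (params$Deff > 0) diffusion_factor(grid, params$Deff, dt),
        reac = if (coupling)
          Matrix::lu(Matrix::Diagonal(2L * n + 4L) - dt * A))
    }
    fac_cache[[key]]
  }

  dose_active <- function(t0, t1) {
    Filter(function(d) d$rate > 0 && d$start_time < t1 - 1e-12 &&
             d$start_time + d$duration > t0 + 1e-12, doses)
  }

  nt <- length(output_times)
  out_c1 <- matrix(0, nt, n); out_c2 <- matrix(0, nt, n)
  out_l <- matrix(0, nt, 4L, dimnames = list(NULL, c("c3", "c4", "c5", "c6")))
  out_inj <- numeric(nt); out_deg <- numeric(nt)

  record <- function(i) {
    out_c1[i, ] <<- c1; out_c2[i, ] <<- c2; out_l[i, ] <<- lumped
    out_inj[i] <<- injected; out_deg[i] <<- degraded
  }

  t_cur <- 0
  for (i in seq_len(nt)) {
    t_target <- output_times[i]
    while (t_cur < t_target - 1e-12) {
      active <- dose_active(t_cur, t_target)
      if (!coupling && length(active) == 0L) {
        # pure diffusion: identical stepping to solve_diffusion
        interval <- t_target - t_cur
        if (params$Deff > 0)
          c1 <- diffuse_interval(c1, grid, params$Deff, interval,
                                 n_substeps(params$Deff, interval, dx))
        t_cur <- t_target
        break
      }
      # split step, cut at dose boundaries
      dt <- min(dt_split, t_target - t_cur)
      for (d in doses) {
        if (d$start_time > t_cur + 1e-12)
          dt <- min(dt, d$start_time - t_cur)
        dend <- d$start_time + d$duration
        if (dend > t_cur + 1e-12) dt <- min(dt, dend - t_cur)
      }
      active <- dose_active(t_cur, t_cur + dt)
      # (i) convection + source during dose events
      for (d in active) {
        cells <- which(abs(grid$centers - d$position) <= d$width / 2)
        if (length(cells) == 0L) stop("dose window contains no grid cells")
        amt <- d$rate * d$concentration * dt
        c1[cells] <- c1[cells] + amt / (length(cells) * v1)
        injected <- injected + amt
        u <- (d$rate / 2) / params$csf_area    # cm/min, each direction
        vel <- ifelse(grid$centers >= d$position, u, -u)
        c1 <- advect_field(c1, vel, dt, dx)
      }
      facs <- get_facs(dt)
      # (ii) implicit diffusion of C1
      if (!is.null(facs$diff))
        c1 <- as.numeric(Matrix::solve(facs$diff, c1, system = "A"))
      # (iii) implicit reaction / mass transfer on amounts
      if (coupling) {
        a <- c(c1 * v1, c2 * v2, lumped * lv)
        a_new <- as.numeric(Matrix::solve(facs$reac, a))
        degraded <- degraded + dt * sum(loss_w * a_new)
        c1 <- a_new[seq_len(n)] / v1
        c2 <- a_new[n + seq_len(n)] / v2
        lumped <- a_new[2L * n + 1:4] / lv
      }
      t_cur <- t_cur + dt
    }
    record(i)
  }
  structure(list(times = output_times, c1 = out_c1, c2 = out_c2,
                 lumped = out_l, cumulative_injected = out_inj,
                 cumulative_degraded = out_deg, grid = grid, params = params),
            class = "pk_trajectory")
}

#' @export
print.pk_trajectory <- function(x, ...) {
  cat(sprintf("<pk_trajectory> %d output times on [%g, %g] min, %d cells\n",
              length(x$times), min(x$times), max(x$times), x$grid$n_cells))
  invisible(x)
}

#' Per-compartment amounts and mass-balance closure
#'
#' Amounts are concentration times volume: distributed compartments integrate
#' `C * A * dx` along the axis; lumped compartments multiply by their volume.
#' The closure residual is `injected - (sum of amounts + degraded)` at each
#' output time; it is zero (to solver precision) for any parameterization,
#' since losses are accumulated in the degraded sink.
#'
#' @param traj A `pk_trajectory`.
#' @return A data frame per output time: `time_min`, amounts `a1`..`a6`,
#'   `degraded`, `injected`, `residual`, `residual_rel` (relative to injected
#'   where nonzero).
#' @export
mass_balance_report <- function(traj) {
  stopifnot(inherits(traj, "pk_trajectory"))
  p <- traj$params; dx <- traj$grid$dx
  a1 <- rowSums(traj$c1) * p$csf_area * dx
  a2 <- rowSums(traj$c2) * p$tissue_area * dx
  al <- sweep(traj$lumped, 2L, p$lumped_volumes, "*")
  tot <- a1 + a2 + rowSums(al) + traj$cumulative_degraded
  res <- traj$cumulative_injected - tot
  data.frame(time_min = traj$times, a1 = a1, a2 = a2,
             a3 = al[, 1L], a4 = al[, 2L], a5 = al[, 3L], a6 = al[, 4L],
             degraded = traj$cumulative_degraded,
             injected = traj$cumulative_injected,
             residual = res,
             residual_rel = ifelse(traj$cumulative_injected > 0,
                                   res / traj$cumulative_injected, res))
}

#' Compare simulated and observed moment trajectories
#'
#' Computes first and left-sided second moments of the simulated spinal-CSF
#' field and of an intensity record at their overlapping times, the
#' experiment-versus-model comparison used to check that the PK model (with
#' reaction and mass transfer switched off) reproduces bench tracer data.
#'
#' @param traj A `pk_trajectory`.
#' @param record An `intensity_record`.
#' @param roi Optional analysis window (cm).
#' @return A list with `comparison` (data frame of paired moments per common
#'   time) and `rms` (named vector of RMS differences for `m1` and
#'   `m2_left`).
#' @export
moment_comparison <- function(traj, record, roi = NULL) {
  stopifnot(inherits(traj, "pk_trajectory"),
            inherits(record, "intensity_record"))
  common <- intersect(round(traj$times, 9), round(record$times, 9))
  if (length(common) == 0L) stop("no overlapping time points")
  if (is.null(roi)) roi <- range(record$positions)
  xg <- traj$grid$centers
  sel_g <- xg >= roi[1L] & xg <= roi[2L]
  xr <- record$positions
  sel_r <- xr >= roi[1L] & xr <= roi[2L]
  rows <- lapply(common, function(tt) {
    cs <- traj$c1[which(round(traj$times, 9) == tt)[1L], sel_g]
    cr <- record$intensities[which(round(record$times, 9) == tt)[1L], sel_r]
    m1s <- first_moment(xg[sel_g], cs); m1r <- first_moment(xr[sel_r], cr)
    data.frame(time_min = tt,
               m1_sim = m1s, m1_obs = m1r,
               m2_left_sim = left_second_moment(xg[sel_g], cs, m1s),
               m2_left_obs = left_second_moment(xr[sel_r], cr, m1r))
  })
  cmp <- do.call(rbind, rows)
  list(comparison = cmp,
       rms = c(m1 = sqrt(mean((cmp$m1_sim - cmp$m1_obs)^2)),
               m2_left = sqrt(mean((cmp$m2_left_sim - cmp$m2_left_obs)^2))))
}
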