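#' Simulation parameters for one synthetic infant-fNIRS recording
#'
#' Defines the signal model the generator emulates: a 34-channel,
#' two-wavelength (780/850 nm) array sampled at 10 Hz, a shared cardiac
#' oscillation inside the infant cardiac band whose cross-wavelength
#' coherence is governed by a per-channel coupling quality in
#' \code{[0, 1]}, slow drift, white detector noise, spike/step motion
#' artifacts of controllable prevalence, occasional near-zero-intensity
#' dead channels, and small evoked responses in designated task-relevant
#' channels.
#'
#' @param n_channels number of channels (default 34, 17 per hemisphere).
#' @param sampling_rate Hz (default 10).
#' @param wavelengths nm pair (default \code{c(780, 850)}).
#' @param duration recording length, seconds (default 300).
#' @param cardiac_band Hz interval the cardiac frequency is drawn from
#'   (default \code{c(1.3, 3.2)}; the draw stays in 1.5-2.4 Hz, typical
#'   of resting infants, so the small second harmonic stays below
#'   Nyquist).
#' @param coupling per-channel coupling quality: a scalar, a vector of
#'   length \code{n_channels}, or a \code{function(n)} returning \code{n}
#'   values in \code{[0, 1]}. Default draws from Beta(4, 1.5) (mostly
#'   decent, a tail of poor channels).
#' @param cardiac_amplitude cardiac modulation at perfect coupling, as a
#'   fraction of baseline intensity (default 0.02).
#' @param noise_sd white noise floor at perfect coupling, fraction of
#'   baseline (default 0.004). Poor optode contact raises the broadband
#'   noise of a channel, so the per-channel noise is
#'   \code{noise_sd * (1 + 6 * (1 - coupling))}.
#' @param motion_rate expected artifacts per minute (default 2); the
#'   scheduled count is \code{round(motion_rate * duration / 60)}, so a
#'   rate can be chosen to place an exact number of events.
#' @param motion_amplitude_range artifact amplitude interval in
#'   optical-density units (default \code{c(0.6, 1.5)}, well above the
#'   0.4 detection criterion).
#' @param wander_scale scale of the slow (0.01-0.05 Hz) baseline wander
#'   a poorly coupled optode shows. The severity is set once per channel,
#'   growing steeply as coupling degrades (\code{(1 - coupling)^1.5},
#'   default scale 0.7 of baseline, capped at 0.9), because decoupling
#'   affects the optode pair as a whole; each wavelength then wanders
#'   with its own phase and a moderately perturbed amplitude. This out-of-band
#'   component barely moves SCI/PSP but inflates the coefficient of
#'   variation -- mostly symmetrically, occasionally asymmetrically
#'   enough for the CV-difference rule to catch.
#' @param imbalance_prob probability that a channel carries a
#'   wavelength-specific slow instrumental drift (LED/detector gain
#'   wander or ambient leakage affecting one wavelength only; amplitude
#'   0.25-0.5 of baseline at 0.005-0.02 Hz; default 0.1). Such channels
#'   show a large CV difference between wavelengths while their cardiac
#'   coherence -- and the unaffected wavelength -- remain intact.
#' @param cse_probability probability that a channel is dead
#'   (near-zero intensity; default 0.05).
#' @param trc_indices task-relevant channel indices; \code{NULL} (the
#'   default) uses the bilateral set \code{c(8:10, 25:27)} clipped to the
#'   channel range (first three channels for very small arrays).
#' @param response_amplitude evoked-response amplitude as a fraction of
#'   baseline (default 0.005).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_channels = 34, sampling_rate = 10,
                       wavelengths = c(780, 850), duration = 300,
                       cardiac_band = c(1.3, 3.2),
                       coupling = function(n) stats::rbeta(n, 4, 1.5),
                       cardiac_amplitude = 0.02, noise_sd = 0.004,
                       motion_rate = 2,
                       motion_amplitude_range = c(0.6, 1.5),
                       wander_scale = 0.7,
                       imbalance_prob = 0.1,
                       cse_probability = 0.05,
                       trc_indices = NULL,
                       response_amplitude = 0.005, seed = NULL) {
  if (n_channels < 1) stop("need at least one channel")
  if (duration <= 0) stop("duration must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (cardiac_band[1] <= 0 || cardiac_band[2] >= sampling_rate / 2)
    stop("cardiac_band must lie within (0, sampling_rate/2)")
  if (is.null(trc_indices)) {
    trc_indices <- intersect(c(8:10, 25:27), seq_len(n_channels))
    if (length(trc_indices) == 0L)
      trc_indices <- seq_len(min(3L, n_channels))
  }
  if (length(trc_indices) && (min(trc_indices) < 1 ||
                              max(trc_indices) > n_channels))
    stop("trc_indices out of channel range")
  if (motion_rate < 0) stop("motion_rate must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

.resolve_coupling <- function(coupling, n) {
  c_vec <- if (is.function(coupling)) coupling(n)
           else if (length(coupling) == 1L) rep(coupling, n)
           else coupling
  if (length(c_vec) != n) stop("coupling must yield one value per channel")
  pmin(pmax(c_vec, 0), 1)
}

# gamma-family hemodynamic response, peak normalized to 1
.hrf <- function(t) {
  h <- ifelse(t > 0, (t / 5)^6 * exp(-(t - 5) * 6 / 5), 0)
  h / max(h, 1e-12)
}

#' Generate one synthetic recording with ground truth
#'
#' Each channel's intensity at wavelength \eqn{\lambda} is
#' \deqn{I_\lambda(t) = B_\lambda (1 + a(c)\, s_\lambda(t) + d(t) +
#'   r(t) + \epsilon_\lambda(t)) \cdot e^{-A(t)}}
#' where \eqn{s_1(t)} is a cardiac oscillation (sinusoid plus a small
#' second harmonic) shared across wavelengths,
#' \eqn{s_2(t) = c\, s_1(t) + (1 - c)\, h(t)} with \eqn{h} an independent
#' in-band process, so the cross-wavelength coherence is controlled by the
#' coupling quality \eqn{c}; \eqn{a(c) = a_0 (0.2 + 0.8 c)} grows with
#' coupling; \eqn{d} is slow drift (0.05 Hz, amplitude below 1\% of
#' baseline), \eqn{r} the evoked response in task-relevant channels, and
#' \eqn{A(t)} the summed optical-density excursion of the scheduled
#' motion artifacts. Dead channels get a near-zero baseline.
#'
#' @param config a [sim_config()].
#' @param metadata metadata list passed to the recording.
#' @return \code{list(recording, truth)} where \code{truth} holds the
#'   per-channel coupling, the motion event table, the dead-channel set,
#'   the cardiac frequency and any injected cohort effects.
#' @export
generate_recording <- function(config = sim_config(), metadata = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  nc <- config$n_channels
  t <- (seq_len(n) - 1) / fs

  f_lo <- max(config$cardiac_band[1], 1.5)
  f_hi <- min(config$cardiac_band[2], min(2.4, fs / 2 / 2 - 0.1))
  if (f_hi <= f_lo) { f_lo <- config$cardiac_band[1]; f_hi <- config$cardiac_band[2] }
  f_card <- stats::runif(1, f_lo, f_hi)
  phi <- stats::runif(1, 0, 2 * pi)
  g <- sin(2 * pi * f_card * t + phi) + 0.2 * sin(4 * pi * f_card * t + 2 * phi)
  g <- g / sqrt(mean((g - mean(g))^2))

  coupling <- .resolve_coupling(config$coupling, nc)
  cse <- which(stats::runif(nc) < config$cse_probability)

  # motion schedule: deterministic count, random placement
  n_ev <- round(config$motion_rate * config$duration / 60)
  events <- NULL
  A <- rep(0, n)   # array-wide dOD excursion
  if (n_ev > 0) {
    kind <- sample(c("spike", "step"), n_ev, replace = TRUE, prob = c(0.7, 0.3))
    amp <- stats::runif(n_ev, config$motion_amplitude_range[1],
                        config$motion_amplitude_range[2])
    # baseline steps (optode shifts that persist) are much smaller than
    # the transient excursion of a spike
    amp <- ifelse(kind == "step", 0.25 * amp, amp)
    dur <- ifelse(kind == "spike", stats::runif(n_ev, 0.2, 0.8), Inf)
    onset <- stats::runif(n_ev, 0, pmax(0, config$duration -
                                          ifelse(is.finite(dur), dur, 1)))
    dur <- ifelse(is.finite(dur), dur, config$duration - onset)
    events <- data.frame(onset = onset, duration = dur, kind = kind,
                         amplitude = amp)
    for (e in seq_len(n_ev)) {
      i0 <- max(1L, floor(onset[e] * fs) + 1L)
      if (kind[e] == "spike") {
        i1 <- min(n, ceiling((onset[e] + dur[e]) * fs))
        if (i1 >= i0) {
          u <- seq(0, pi, length.out = i1 - i0 + 1L)
          A[i0:i1] <- A[i0:i1] + amp[e] * sin(u)
        }
      } else {
        A[i0:n] <- A[i0:n] + amp[e]
      }
    }
  } else {
    events <- data.frame(onset = numeric(), duration = numeric(),
                         kind = character(), amplitude = numeric())
  }

  # block design for evoked responses: 10 s on / 20 s off from 20 s
  resp <- rep(0, n)
  if (length(config$trc_indices) && config$response_amplitude > 0) {
    box <- rep(0, n)
    on <- if (config$duration >= 30) seq(20, config$duration - 10, by = 30)
          else numeric()
    for (o in on) box[t >= o & t < o + 10] <- 1
    h <- .hrf(seq(0, 20, by = 1 / fs))
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
    if (max(conv) > 0) resp <- conv / max(conv) * config$response_amplitude
  }

  I <- array(0, dim = c(n, nc, 2))
  mot_factor <- exp(-A)
  for (ch in seq_len(nc)) {
    base <- stats::rlnorm(1, 0, 0.25)
    if (ch %in% cse) base <- base * 1e-4
    b <- base * c(1, 1.2)
    cc <- coupling[ch]
    a <- config$cardiac_amplitude * (0.2 + 0.8 * cc)
    hN <- bandpass_cardiac(stats::rnorm(n), fs, config$cardiac_band)
    hN <- hN / sqrt(mean((hN - mean(hN))^2))
    s2 <- cc * g + (1 - cc) * hN
    dr <- stats::runif(1, 0, 0.005) *
      sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi))
    r <- if (ch %in% config$trc_indices) resp else 0
    pol <- sample(c(-1, 1), 1)   # artifact polarity varies by channel
    jit <- stats::runif(1, 0.8, 1.2)
    mf <- mot_factor^(pol * jit)
    w_sev <- min(config$wander_scale * (1 - cc)^1.5 *
                   stats::runif(1, 0.8, 1.2), 0.9)
    imb_wl <- if (stats::runif(1) < config$imbalance_prob)
      sample(1:2, 1) else 0L
    for (wl in 1:2) {
      s <- if (wl == 1) g else s2
      rs <- if (wl == 1) -0.5 * r else r
      w_amp <- w_sev * max(0, 1 + 0.5 * stats::rnorm(1))
      wander <- w_amp * sin(2 * pi * stats::runif(1, 0.01, 0.05) * t +
                              stats::runif(1, 0, 2 * pi))
      if (wl == imb_wl) {
        wander <- wander + stats::runif(1, 0.25, 0.5) *
          sin(2 * pi * stats::runif(1, 0.005, 0.02) * t +
                stats::runif(1, 0, 2 * pi))
      }
      x <- 1 + a * s + dr + rs + wander +
        stats::rnorm(n, 0, config$noise_sd * (1 + 6 * (1 - cc)))
      I[, ch, wl] <- b[wl] * pmax(x, 0.01) * mf
    }
  }

  rec <- raw_recording(I, fs, config$wavelengths, metadata)
  truth <- list(coupling = coupling, motion_events = events,
                cse_channels = cse, cardiac_frequency = f_card,
                injected_effects = list())
  list(recording = rec, truth = truth)
}

#' Cohort design
#'
#' Crossing of age, cohort and task cells with \code{n_per_cell}
#' participants each, plus the effects injected into participant-level
#' coupling quality and motion prevalence. Effects are on the linear
#' scale of the participant coupling mean (per 1 SD of the standardized
#' covariate) and on log motion rate.
#'
#' @param ages subset of \code{c(5, 8, 12, 18, 24)} months.
#' @param cohorts subset of \code{c("Gambia", "UK")}.
#' @param tasks subset of \code{c("HaND", "SNS")}.
#' @param n_per_cell participants per age x cohort x task cell.
#' @param effects named list: \code{age_coupling}, \code{cohort_coupling}
#'   (UK relative to Gambia), \code{task_coupling} (SNS relative to HaND),
#'   \code{motion_coupling} (effect of standardized log motion rate on
#'   the coupling mean), \code{age_motion} (effect of standardized age on
#'   log motion rate). All default 0.
#' @param base_coupling cohort-level mean coupling (default 0.7).
#' @param coupling_sd between-participant SD of the coupling mean
#'   (default 0.08).
#' @param base_motion_rate events/min at covariate means (default 2).
#' @return An object of class \code{cohort_design}.
#' @export
cohort_design <- function(ages = c(5, 8, 12, 18, 24),
                          cohorts = c("Gambia", "UK"),
                          tasks = c("HaND", "SNS"),
                          n_per_cell = 3,
                          effects = list(),
                          base_coupling = 0.7, coupling_sd = 0.08,
                          base_motion_rate = 2) {
  stopifnot(all(ages %in% c(5, 8, 12, 18, 24)),
            all(cohorts %in% c("Gambia", "UK")),
            all(tasks %in% c("HaND", "SNS")),
            length(ages) >= 1, length(cohorts) >= 1, length(tasks) >= 1)
  if (n_per_cell < 1) stop("n_per_cell must be at least 1")
  defaults <- list(age_coupling = 0, cohort_coupling = 0, task_coupling = 0,
                   motion_coupling = 0, age_motion = 0)
  defaults[names(effects)] <- effects
  structure(list(ages = ages, cohorts = cohorts, tasks = tasks,
                 n_per_cell = n_per_cell, effects = defaults,
                 base_coupling = base_coupling, coupling_sd = coupling_sd,
                 base_motion_rate = base_motion_rate),
            class = "cohort_design")
}

#' Generate a synthetic cohort
#'
#' Draws per-participant coupling and motion parameters with the injected
#' age/cohort/task/motion effects, then generates one recording per
#' participant. Per-participant RNG streams are derived deterministically
#' from the master seed and the participant index, so a subset of the
#' cohort reproduces bit-identically.
#'
#' @param design a [cohort_design()].
#' @param config a [sim_config()] template (its \code{coupling} and
#'   \code{motion_rate} are overridden per participant; its \code{seed}
#'   is the master seed).
#' @return \code{list(participants, recordings)}: a participant table
#'   (id, age_months, cohort, task, motion_rate, coupling_mean, seed) and
#'   a list of \code{list(recording, truth)} in table order.
#' @export
generate_cohort <- function(design, config = sim_config()) {
  stopifnot(inherits(design, "cohort_design"), inherits(config, "sim_config"))
  master <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cells <- expand.grid(age_months = design$ages, cohort = design$cohorts,
                       task = design$tasks, stringsAsFactors = FALSE)
  tab <- cells[rep(seq_len(nrow(cells)), each = design$n_per_cell), ,
               drop = FALSE]
  np <- nrow(tab)
  tab$id <- sprintf("P%03d", seq_len(np))
  tab$seed <- vapply(seq_len(np), function(p) {
    as.integer((as.numeric(master) * 48271 + p * 1000003) %% 2147483629) + 1L
  }, integer(1))

  ef <- design$effects
  age_z <- (tab$age_months - 13.4) / 7.5          # standardized over 5..24 mo
  uk <- as.numeric(tab$cohort == "UK")
  sns <- as.numeric(tab$task == "SNS")

  recs <- vector("list", np)
  tab$motion_rate <- NA_real_
  tab$coupling_mean <- NA_real_
  for (p in seq_len(np)) {
    set.seed(tab$seed[p])
    log_rate <- log(design$base_motion_rate) + ef$age_motion * age_z[p] +
      stats::rnorm(1, 0, 0.3)
    rate <- exp(log_rate)
    motion_z <- (log_rate - log(design$base_motion_rate)) / 0.3
    cmean <- design$base_coupling +
      ef$age_coupling * age_z[p] + ef$cohort_coupling * uk[p] +
      ef$task_coupling * sns[p] + ef$motion_coupling * motion_z +
      stats::rnorm(1, 0, design$coupling_sd)
    cmean <- min(max(cmean, 0.05), 0.95)
    cfg <- config
    cfg$seed <- NULL   # stream already positioned by set.seed above
    cfg$motion_rate <- rate
    # participant effects shift the location of the cohort's channel
    # coupling distribution without destroying its shape (e.g. a
    # bimodal good/poor mixture stays bimodal)
    cfg$coupling <- local({
      template <- config$coupling
      shift <- cmean - design$base_coupling
      function(nch) {
        base <- if (is.function(template)) template(nch)
                else if (length(template) == 1L) rep(template, nch)
                else template
        pmin(pmax(base + shift, 0), 1)
      }
    })
    md <- list(id = tab$id[p], age_months = tab$age_months[p],
               cohort = tab$cohort[p], task = tab$task[p])
    out <- generate_recording(cfg, metadata = md)
    out$truth$injected_effects <- ef
    recs[[p]] <- out
    tab$motion_rate[p] <- rate
    tab$coupling_mean[p] <- cmean
  }
  rownames(tab) <- NULL
  list(participants = tab[, c("id", "age_months", "cohort", "task",
                              "motion_rate", "coupling_mean", "seed")],
       recordings = recs)
}

#' Simulate analysis rows from a known linear mixed model
#'
#' Generates a participant-by-parameter-combination outcome table directly
#' from the statistical model the full fixed-effects analysis fits, with
#' user-chosen standardized coefficients, a participant random intercept
#' and threshold-by-cohort random intercepts. This is the controlled
#' ground truth for parameter-recovery checks of the model-fitting stage,
#' bypassing the signal-level generator.
#'
#' @param n_participants number of participants.
#' @param sci_values,psp_values threshold grids defining the rows.
#' @param betas named list of standardized coefficients; recognized names:
#'   \code{sci, psp, age, pom, cse, task, cohort, sci_psp, age_sci,
#'   age_psp, sci_pom, psp_pom, age_pom}. Missing names default to 0.
#' @param sd_id participant random-intercept SD (default 0.3).
#' @param sd_group threshold-by-cohort random-intercept SD (default 0.1).
#' @param sd_resid residual SD (default 0.5).
#' @param seed RNG seed.
#' @return data.frame with columns \code{id, age_months, cohort, task,
#'   sci_thr, psp_thr, pom, cse_count, outcome}.
#' @export
simulate_analysis_rows <- function(n_participants = 20,
                                   sci_values = seq(0.1, 0.9, by = 0.2),
                                   psp_values = seq(0.01, 0.09, by = 0.02),
                                   betas = list(), sd_id = 0.3,
                                   sd_group = 0.1, sd_resid = 0.5,
                                   seed = 1) {
  set.seed(seed)
  b <- list(sci = 0, psp = 0, age = 0, pom = 0, cse = 0, task = 0,
            cohort = 0, sci_psp = 0, age_sci = 0, age_psp = 0,
            sci_pom = 0, psp_pom = 0, age_pom = 0)
  b[names(betas)] <- betas
  ages <- sample(c(5, 8, 12, 18, 24), n_participants, replace = TRUE)
  cohort <- sample(c("Gambia", "UK"), n_participants, replace = TRUE)
  task <- sample(c("HaND", "SNS"), n_participants, replace = TRUE)
  pom <- stats::runif(n_participants, 0, 40)
  cse_n <- stats::rpois(n_participants, 1.5)
  u_id <- stats::rnorm(n_participants, 0, sd_id)

  grid <- expand.grid(sci_thr = sci_values, psp_thr = psp_values)
  rows <- grid[rep(seq_len(nrow(grid)), times = n_participants), ]
  p_idx <- rep(seq_len(n_participants), each = nrow(grid))
  rows$id <- sprintf("P%03d", p_idx)
  rows$age_months <- ages[p_idx]
  rows$cohort <- cohort[p_idx]
  rows$task <- task[p_idx]
  rows$pom <- pom[p_idx]
  rows$cse_count <- cse_n[p_idx]

  z <- function(x) if (stats::sd(x) == 0) rep(0, length(x))
                   else (x - mean(x)) / stats::sd(x)
  SCI <- z(rows$sci_thr); PSP <- z(rows$psp_thr); AGE <- z(rows$age_months)
  POM <- z(rows$pom); CSE <- z(rows$cse_count)
  TASK <- as.numeric(rows$task == "SNS"); COH <- as.numeric(rows$cohort == "UK")

  g_sci <- interaction(rows$sci_thr, rows$cohort)
  g_psp <- interaction(rows$psp_thr, rows$cohort)
  u_sci <- stats::rnorm(nlevels(g_sci), 0, sd_group)
  u_psp <- stats::rnorm(nlevels(g_psp), 0, sd_group)

  rows$outcome <- b$sci * SCI + b$psp * PSP + b$age * AGE + b$pom * POM +
    b$cse * CSE + b$task * TASK + b$cohort * COH +
    b$sci_psp * SCI * PSP + b$age_sci * AGE * SCI + b$age_psp * AGE * PSP +
    b$sci_pom * SCI * POM + b$psp_pom * PSP * POM + b$age_pom * AGE * POM +
    u_id[p_idx] + u_sci[as.integer(g_sci)] + u_psp[as.integer(g_psp)] +
    stats::rnorm(nrow(rows), 0, sd_resid)
  rownames(rows) <- NULL
  rows[, c("id", "age_months", "cohort", "task", "sci_thr", "psp_thr",
           "pom", "cse_count", "outcome")]
}
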