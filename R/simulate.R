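#' Circadian intensity template
#'
#' Piecewise log-linear 24 h template for the per-mouse activation hazard
#' \eqn{\lambda(\tau)} (1/s), with named knots tied to the light transitions:
#' a pre-dawn rise starting 90 min before lights-on, a burst peaking at
#' lights-on and decaying over ~1 h, a low daytime rest level, a post-
#' lights-off ramp peaking `time_to_peak` min into the dark period, and a
#' late-night decline from 8 h after lights-off. Interpolation is linear in
#' log-intensity and 24 h periodic, so \eqn{\lambda > 0} everywhere; with the
#' defaults the night integral exceeds the day integral (nocturnal animals).
#'
#' @param time_to_peak minutes from lights-off to the nocturnal peak
#'   (default 120 — activity builds over ~2 h after darkness).
#' @param day_rest,on_burst,night_onset,night_peak,late_night hazard levels
#'   (1/s) at the named knots.
#' @param schedule a [light_schedule()] fixing where the knots sit.
#' @param knots optional explicit `data.frame(tau, lambda)` (minutes of day,
#'   1/s) overriding the template entirely, e.g. for bi-phasic night
#'   profiles.
#' @return Object of class `circadian_profile`.
#' @export
circadian_profile <- function(time_to_peak = 120, day_rest = 0.0008,
                              on_burst = 0.008, night_onset = 0.005,
                              night_peak = 0.016, late_night = 0.003,
                              schedule = light_schedule(), knots = NULL) {
  on <- schedule$on_min
  off <- schedule$off_min
  if (is.null(knots)) {
    if (time_to_peak <= 0 || time_to_peak >= 470) {
      stop("time_to_peak must be in (0, 470) min so the peak precedes the ",
           "late-night decline knot")
    }
    knots <- data.frame(
      tau = c((on - 90) %% 1440, on, (on + 60) %% 1440, (off - 10) %% 1440,
              off, (off + time_to_peak) %% 1440, (off + 480) %% 1440),
      lambda = c(day_rest, on_burst, day_rest, day_rest, night_onset,
                 night_peak, late_night))
  }
  knots <- knots[order(knots$tau), ]
  if (any(knots$lambda <= 0)) stop("lambda knots must be positive")
  if (anyDuplicated(knots$tau)) stop("duplicate knot positions")
  structure(list(knots = knots, time_to_peak = time_to_peak,
                 schedule = schedule), class = "circadian_profile")
}

#' Evaluate a circadian profile
#'
#' @param profile a [circadian_profile()].
#' @param tod_min minutes of day (vector; wrapped mod 1440).
#' @return hazard \eqn{\lambda} (1/s) at each time.
#' @export
lambda_at <- function(profile, tod_min) {
  kn <- profile$knots
  tau <- kn$tau
  lv <- log(kn$lambda)
  nk <- length(tau)
  tau_ext <- c(tau, tau[1] + 1440)
  lv_ext <- c(lv, lv[1])
  x <- tod_min %% 1440
  i <- findInterval(x, tau_ext)
  below <- i == 0L                      # before the first knot: wrap around
  x[below] <- x[below] + 1440
  i[below] <- nk
  t0 <- tau_ext[i]
  t1 <- tau_ext[i + 1L]
  w <- ifelse(t1 > t0, (x - t0) / (t1 - t0), 0)
  exp(lv_ext[i] + w * (lv_ext[i + 1L] - lv_ext[i]))
}

#' Multiplicative event response kernel
#'
#' Gain curve \eqn{g(u) \ge 0} applied to the circadian hazard after an
#' intervention at \eqn{u = 0} (minutes). Two shapes: `"exp"` — a short
#' linear rise to `peak_gain` followed by exponential decay with time
#' constant `decay` minutes; `"rect"` — constant `peak_gain` for `duration`
#' minutes (used for controlled response-duration recovery experiments). An
#' optional carry-over term `1 + carry_gain * exp(-u / (carry_days * 1440))`
#' multiplies on top, emulating the male-type response that fades over
#' several days. `g -> 1` far from the event; before the event `g = 1`.
#'
#' @param type event type the kernel responds to.
#' @param peak_gain peak multiplicative gain (>= 1 for excitatory events).
#' @param rise,decay rise time and decay constant (minutes; `"exp"` shape).
#' @param shape `"exp"` or `"rect"`.
#' @param duration plateau length (minutes; `"rect"` shape).
#' @param carry_gain,carry_days carry-over amplitude and decay (days).
#' @return Object of class `event_kernel`.
#' @export
event_kernel <- function(type = "cage_change", peak_gain = 3, rise = 10,
                         decay = 120, shape = c("exp", "rect"),
                         duration = 60, carry_gain = 0, carry_days = 1.5) {
  shape <- match.arg(shape)
  stopifnot(peak_gain >= 0, decay > 0, duration > 0, carry_gain >= 0)
  structure(list(type = type, peak_gain = peak_gain, rise = rise,
                 decay = decay, shape = shape, duration = duration,
                 carry_gain = carry_gain, carry_days = carry_days),
            class = "event_kernel")
}

#' @rdname event_kernel
#' @param kern an `event_kernel`.
#' @param u_min minutes since the event (vector; negative = before).
#' @export
kernel_gain <- function(kern, u_min) {
  g <- rep(1, length(u_min))
  pos <- u_min >= 0
  if (!any(pos)) return(g)
  u <- u_min[pos]
  gi <- if (kern$shape == "rect") {
    ifelse(u < kern$duration, kern$peak_gain, 1)
  } else {
    a <- kern$peak_gain - 1
    r <- pmin(1, u / max(kern$rise, 1e-9))
    1 + a * r * exp(-pmax(u - kern$rise, 0) / kern$decay)
  }
  if (kern$carry_gain > 0) {
    gi <- gi * (1 + kern$carry_gain * exp(-u / (kern$carry_days * 1440)))
  }
  g[pos] <- gi
  g
}

#' Cage simulation scenario
#'
#' Bundles everything the generative model needs: the circadian hazard
#' template, the group size (default 5 mice/cage), the cage floor geometry
#' (~500 cm^2 with the 4 x 3 electrode grid underneath), the two-state
#' movement model parameters, the capacitive coupling model, electrode noise,
#' and the husbandry calendar with its response kernels.
#'
#' The movement model is a two-state semi-Markov random walk: a resting mouse
#' becomes active with hazard \eqn{\lambda(t) \prod g(t)}; an active mouse
#' takes reflected Gaussian steps (`step_sd` cm per 250 ms tick) and reverts
#' to rest with constant hazard `mu_rest`. Electrode readings are baseline
#' plus each mouse's coupling attenuated by an isotropic Gaussian proximity
#' kernel of scale `kernel_scale` cm, plus Gaussian sensor noise.
#'
#' @param name scenario label.
#' @param profile a [circadian_profile()].
#' @param n_mice mice per cage (default 5).
#' @param floor `c(width, depth)` of the cage floor in cm (default 20 x 25,
#'   ~500 cm^2; 3 electrode columns across the width, 4 rows front to rear).
#' @param kernel_scale proximity kernel scale (cm); about 40% of the
#'   electrode pitch, keeping the response local enough that a mouse over one
#'   row barely registers on the next.
#' @param coupling_mean,coupling_cv per-mouse coupling amplitude (capacitance
#'   units) log-normal mean and coefficient of variation.
#' @param sigma_mean,sigma_cv per-electrode noise SD log-normal parameters.
#' @param baseline_mean,baseline_sd electrode baseline level.
#' @param step_sd active random-walk step SD (cm / tick).
#' @param mu_rest active-to-rest hazard (1/s; default 1/30 — 30 s mean bout).
#' @param lambda_scale overall multiplier on the circadian hazard.
#' @param calendar_spec named list of event schedules, each
#'   `list(every_days, offset_days, time)` relative to `start`.
#' @param kernels named list of [event_kernel()]s keyed by event type; events
#'   without a kernel only label the calendar (no effect on activity).
#' @param start scenario start instant (default a Thursday midnight so the
#'   first cage-change day is cycle day 0).
#' @param schedule a [light_schedule()].
#' @param bounds optional `c(xmin, xmax, ymin, ymax)` confining the mice to a
#'   sub-region of the floor (used in spatial-fidelity experiments).
#' @return Object of class `cage_scenario`.
#' @export
cage_scenario <- function(name = "baseline", profile = circadian_profile(),
                          n_mice = 5L, floor = c(20, 25),
                          kernel_scale = 2.5, coupling_mean = 2.2,
                          coupling_cv = 0.15, sigma_mean = 0.05,
                          sigma_cv = 0.15, baseline_mean = 15,
                          baseline_sd = 1, step_sd = 2, mu_rest = 1 / 30,
                          lambda_scale = 1,
                          calendar_spec = list(
                            cage_change = list(every_days = 7, offset_days = 0,
                                               time = "10:00"),
                            weighing = list(every_days = 7, offset_days = 4,
                                            time = "10:00")),
                          kernels = list(
                            cage_change = event_kernel("cage_change",
                                                       peak_gain = 3,
                                                       decay = 120),
                            weighing = event_kernel("weighing", peak_gain = 2,
                                                    decay = 60)),
                          start = as.POSIXct("2023-01-05 00:00:00",
                                             tz = "UTC"),
                          schedule = light_schedule(), bounds = NULL) {
  if (any(floor <= 0)) stop("invalid floor geometry")
  grid <- electrode_layout()$grid
  elec <- cbind(x = (grid$col - 0.5) * floor[1] / 3,
                y = (grid$row - 0.5) * floor[2] / 4)
  structure(list(name = name, profile = profile, n_mice = as.integer(n_mice),
                 floor = floor, elec = elec, kernel_scale = kernel_scale,
                 coupling_mean = coupling_mean, coupling_cv = coupling_cv,
                 sigma_mean = sigma_mean, sigma_cv = sigma_cv,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 step_sd = step_sd, mu_rest = mu_rest,
                 lambda_scale = lambda_scale, calendar_spec = calendar_spec,
                 kernels = kernels, extra_events = NULL, start = start,
                 schedule = schedule, bounds = bounds),
            class = "cage_scenario")
}

#' @export
print.cage_scenario <- function(x, ...) {
  cat("<cage_scenario> ", x$name, ": ", x$n_mice, " mice, floor ",
      x$floor[1], "x", x$floor[2], " cm, lights-off time-to-peak ",
      x$profile$time_to_peak, " min\n", sep = "")
  invisible(x)
}

#' Named preset scenarios
#'
#' Qualitative mimics of the site and sex profiles reported for this kind of
#' system (real recordings are not deposited, so presets reproduce
#' phenomenology, not fitted parameters):
#' \describe{
#'   \item{baseline}{default female-like cage, weekly cage-change (Thursday)
#'     and weighing (Monday), nocturnal peak 2 h after lights-off.}
#'   \item{CNR-like}{fast lights-off ramp (peak ~90 min) and higher overall
#'     gain.}
#'   \item{KI-like}{slow protracted ramp, nocturnal peak 440 min after
#'     lights-off.}
#'   \item{JAX-like}{bi-phasic dark period: early peak, dip, second peak
#'     near 400 min.}
#'   \item{male-KI-like}{KI-like ramp plus a cage-change carry-over lasting
#'     days and lower overall activity.}
#'   \item{biweekly}{cage-change every 14 days.}
#'   \item{no-intervention}{weekly calendar retained for labelling, but no
#'     kernels: interventions have no effect on activity.}
#' }
#' @return named list of [cage_scenario()] objects.
#' @export
preset_scenarios <- function() {
  sched <- light_schedule()
  off <- sched$off_min
  jax_knots <- data.frame(
    tau = c((sched$on_min - 90) %% 1440, sched$on_min,
            (sched$on_min + 60) %% 1440, (off - 10) %% 1440, off,
            (off + 60) %% 1440, (off + 180) %% 1440,
            (off + 400) %% 1440, (off + 480) %% 1440),
    lambda = c(0.0008, 0.008, 0.0008, 0.0008, 0.005, 0.014, 0.006, 0.015,
               0.003))
  # KI-type night: protracted rise to ~440 min, then a marked but gradual
  # decline (the steep-fall/slow-rise asymmetry would otherwise bias the
  # moving-average peak estimate well ahead of the true peak)
  ki_knots <- data.frame(
    tau = c((sched$on_min - 90) %% 1440, sched$on_min,
            (sched$on_min + 60) %% 1440, (off - 10) %% 1440, off,
            (off + 380) %% 1440, (off + 440) %% 1440, (off + 480) %% 1440,
            (off + 560) %% 1440),
    lambda = c(0.0008, 0.008, 0.0008, 0.0008, 0.005, 0.009, 0.016, 0.008,
               0.003))
  ki_profile <- circadian_profile(time_to_peak = 120, knots = ki_knots)
  ki_profile$time_to_peak <- 440
  male_kernels <- list(
    cage_change = event_kernel("cage_change", peak_gain = 3, decay = 120,
                               carry_gain = 1.2, carry_days = 1.5),
    weighing = event_kernel("weighing", peak_gain = 2, decay = 60))
  list(
    baseline = cage_scenario("baseline"),
    `CNR-like` = cage_scenario("CNR-like",
      profile = circadian_profile(time_to_peak = 90),
      lambda_scale = 1.4),
    `KI-like` = cage_scenario("KI-like", profile = ki_profile),
    `JAX-like` = cage_scenario("JAX-like",
      profile = circadian_profile(time_to_peak = 60, knots = jax_knots)),
    `male-KI-like` = cage_scenario("male-KI-like", profile = ki_profile,
      lambda_scale = 0.8, kernels = male_kernels),
    biweekly = cage_scenario("biweekly",
      calendar_spec = list(cage_change = list(every_days = 14,
                                              offset_days = 0,
                                              time = "10:00"))),
    `no-intervention` = cage_scenario("no-intervention", kernels = list()))
}

#' Add or override intervention events on a scenario
#'
#' Composes a calendar (explicit events) and/or response kernels onto a
#' scenario. Gains of overlapping events compose multiplicatively; two
#' identical (type, time) events are composed but trigger a warning.
#'
#' @param scenario a [cage_scenario()].
#' @param calendar an [intervention_calendar()], a `data.frame(type, time)`,
#'   or `NULL`. Explicit events replace the generated `calendar_spec`.
#' @param kernels named list of [event_kernel()]s to merge (by type).
#' @return the modified scenario.
#' @export
inject_events <- function(scenario, calendar = NULL, kernels = NULL) {
  stopifnot(inherits(scenario, "cage_scenario"))
  if (!is.null(calendar)) {
    ev <- if (inherits(calendar, "intervention_calendar")) calendar$events
          else intervention_calendar(calendar)$events
    if (anyDuplicated(ev[c("type", "time")])) {
      warning("overlapping identical events: gains will be composed")
    }
    scenario$extra_events <- ev
    scenario$calendar_spec <- list()
  }
  if (!is.null(kernels)) {
    for (nm in names(kernels)) scenario$kernels[[nm]] <- kernels[[nm]]
  }
  scenario
}

# realized event table over [start, start + n_days)
#' @noRd
expand_events <- function(scenario, n_days) {
  start <- scenario$start
  stop_t <- start + n_days * 86400
  ev <- list()
  for (type in names(scenario$calendar_spec)) {
    sp <- scenario$calendar_spec[[type]]
    t0 <- as.POSIXct(as.character(utc_date(start)), tz = "UTC") +
      sp$offset_days * 86400 + clock_to_minutes(sp$time) * 60
    if (t0 >= stop_t) next
    times <- seq(from = t0, to = stop_t, by = sp$every_days * 86400)
    times <- times[times >= start & times < stop_t]
    if (length(times)) ev[[type]] <- data.frame(type = type, time = times)
  }
  out <- do.call(rbind, c(ev, list(scenario$extra_events)))
  if (is.null(out) || !nrow(out)) {
    return(data.frame(type = character(0),
                      time = as.POSIXct(character(0), tz = "UTC")))
  }
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  out
}

# per-minute hazard lambda(t) * prod g(t) over [start, start + n_min)
#' @noRd
minute_intensity <- function(scenario, start, n_min, events) {
  t <- as.numeric(start) + (seq_len(n_min) - 1) * 60
  lam <- lambda_at(scenario$profile, (t %% 86400) / 60) * scenario$lambda_scale
  gain <- rep(1, n_min)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      kern <- scenario$kernels[[events$type[i]]]
      if (is.null(kern)) next
      u <- (t - as.numeric(events$time[i])) / 60
      gain <- gain * kernel_gain(kern, u)
    }
  }
  list(lambda = lam, gain = gain, hazard = lam * gain)
}

# scenario-level random draws; consumes RNG once per cage
#' @noRd
sim_setup <- function(scenario) {
  ns <- scenario$n_mice
  b <- scenario$bounds %||% c(0, scenario$floor[1], 0, scenario$floor[2])
  list(
    baseline = rnorm(12, scenario$baseline_mean, scenario$baseline_sd),
    sigma = rlnorm(12, log(scenario$sigma_mean), scenario$sigma_cv),
    coupling = if (ns) rlnorm(ns, log(scenario$coupling_mean),
                              scenario$coupling_cv) else numeric(0),
    x = if (ns) runif(ns, b[1], b[2]) else numeric(0),
    y = if (ns) runif(ns, b[3], b[4]) else numeric(0),
    active = rep(FALSE, ns),
    bounds = b)
}

# run one contiguous chunk; returns values matrix and updated state.
# RNG arrays are drawn vectorized here (noise first, then transition
# uniforms, then step normals) so the stream is a fixed function of the
# chunk sequence.
#' @noRd
sim_run_chunk <- function(scenario, state, start, n_min, events) {
  inten <- minute_intensity(scenario, start, n_min, events)
  p_act <- rep(-expm1(-inten$hazard * 0.25), each = 240)
  nt <- n_min * 240L
  nm <- scenario$n_mice
  p_rest <- -expm1(-scenario$mu_rest * 0.25)
  noise <- matrix(rnorm(nt * 12L), nt, 12L)
  trans <- if (nm) matrix(runif(nt * nm), nt, nm) else matrix(0, nt, 0L)
  res <- sim_chunk_cpp(p_act, nm, state$x, state$y,
                       state$active, p_rest, scenario$step_sd,
                       state$bounds[1], state$bounds[2], state$bounds[3],
                       state$bounds[4], scenario$elec, scenario$kernel_scale,
                       state$coupling, state$baseline, state$sigma,
                       noise, trans)
  state$x <- res$x
  state$y <- res$y
  state$active <- res$active
  list(values = res$values,
       n_active_min = colMeans(matrix(res$n_active, nrow = 240)),
       hazard_min = inten$hazard, state = state)
}

#' Simulate raw capacitance signals for one cage
#'
#' Generates a [signal_table()] under the two-state random-walk model (see
#' [cage_scenario()]) together with the ground truth needed to score any
#' recovery analysis. Identical seeds give identical outputs; with
#' `n_mice = 0` the signal is pure baseline plus Gaussian electrode noise,
#' so the downstream event rate follows the analytic Gaussian-difference
#' tail for a known threshold.
#'
#' @param scenario a [cage_scenario()].
#' @param duration duration in seconds (>= 60).
#' @param seed integer seed (`set.seed` is called when non-NULL; simulation
#'   is reproducibility-mandatory, so pass one).
#' @param n_mice override of the scenario group size.
#' @param start override of the scenario start instant.
#' @return list with `signal` (a `signal_table`) and `truth`: per-electrode
#'   `sigma` and `baseline`, per-mouse `coupling`, the realized `events`
#'   table, per-minute hazard `hazard_min` and mean active-mouse count
#'   `n_active_min`, the profile's intended `time_to_peak`, and the seed.
#' @export
simulate_cage <- function(scenario, duration, seed = NULL,
                          n_mice = scenario$n_mice, start = scenario$start) {
  stopifnot(inherits(scenario, "cage_scenario"))
  if (duration < 60) stop("duration must be at least one minute")
  scenario$n_mice <- as.integer(n_mice)
  scenario$start <- start
  if (!is.null(seed)) set.seed(seed)
  n_min <- ceiling(duration / 60)
  events <- expand_events(scenario, n_min / 1440)
  setup <- sim_setup(scenario)
  # simulate in daily chunks so the RNG stream is identical to the chunked
  # multi-day driver (run_scenario) under the same seed
  state <- setup
  offs <- seq(0L, n_min - 1L, by = 1440L)
  vals <- vector("list", length(offs))
  hazard <- numeric(0)
  nact <- numeric(0)
  for (i in seq_along(offs)) {
    len <- min(1440L, n_min - offs[i])
    chunk <- sim_run_chunk(scenario, state, scenario$start + offs[i] * 60,
                           len, events)
    state <- chunk$state
    vals[[i]] <- chunk$values
    hazard <- c(hazard, chunk$hazard_min)
    nact <- c(nact, chunk$n_active_min)
  }
  values <- do.call(rbind, vals)
  nt <- n_min * 240
  ts <- scenario$start + (seq_len(nt) - 1) * 0.25
  sig <- signal_table(values, ts, cage_id = scenario$name)
  truth <- list(sigma = setup$sigma, baseline = setup$baseline,
                coupling = setup$coupling, events = events,
                hazard_min = hazard, n_active_min = nact,
                time_to_peak = scenario$profile$time_to_peak,
                lambda_scale = scenario$lambda_scale, seed = seed,
                mouse_final = list(x = state$x, y = state$y))
  list(signal = sig, truth = truth)
}

#' Simulate and analyze a multi-day scenario
#'
#' End-to-end driver: simulates the scenario day by day (the raw signal of a
#' single day is ~33 MB, so long runs are processed in daily chunks that are
#' exactly equivalent to one long run — pair differencing bridges chunk
#' boundaries and the RNG stream is continuous), detects activations, and
#' bins minute activity with day/night and cycle labels.
#'
#' @param scenario a [cage_scenario()].
#' @param days number of days to simulate (alternatively give `weeks`).
#' @param weeks convenience: `days = 7 * weeks`.
#' @param seed integer seed (required).
#' @param threshold `"mad"` (estimate per-electrode thresholds from the
#'   first day's mid-day quiescent window), `"sigma"` (k times the true
#'   per-sample noise SD from the simulator truth), or a numeric vector.
#' @param k threshold multiplier.
#' @param bin_width bin width in seconds.
#' @return list of class `scenario_run`: `activity` (minute `activity_ts`
#'   with labels), `truth`, `theta` (thresholds used), `calendar`,
#'   `scenario`.
#' @export
run_scenario <- function(scenario, days = NULL, weeks = NULL, seed = 1L,
                         threshold = "mad", k = 4, bin_width = 60) {
  stopifnot(inherits(scenario, "cage_scenario"))
  if (is.null(days)) days <- 7 * weeks
  if (is.null(days) || days < 1) stop("give days or weeks")
  set.seed(seed)
  events <- expand_events(scenario, days)
  calendar <- intervention_calendar(events)
  setup <- sim_setup(scenario)
  theta <- NULL
  prev_val <- NULL
  prev_ts <- NULL
  state <- setup
  bins <- vector("list", days)
  hazard <- numeric(0)
  nact <- numeric(0)
  for (d in seq_len(days)) {
    day_start <- scenario$start + (d - 1) * 86400
    chunk <- sim_run_chunk(scenario, state, day_start, 1440, events)
    state <- chunk$state
    nt <- 1440L * 240L
    ts <- day_start + (seq_len(nt) - 1) * 0.25
    if (is.null(prev_val)) {
      vals <- chunk$values
      tss <- ts
    } else {
      vals <- rbind(prev_val, chunk$values)
      tss <- c(prev_ts, ts)
    }
    sig <- signal_table(vals, tss, cage_id = scenario$name)
    if (is.null(theta)) {
      theta <- if (identical(threshold, "mad")) {
        estimate_noise_threshold(sig, k = k, schedule = scenario$schedule)
      } else if (identical(threshold, "sigma")) {
        k * setup$sigma
      } else {
        rep_len(as.numeric(threshold), 12L)
      }
    }
    acts <- detect_activations(sig, threshold = theta, assume_clean = TRUE)
    bins[[d]] <- bin_activity(acts, bin_width, scenario$schedule, calendar)
    hazard <- c(hazard, chunk$hazard_min)
    nact <- c(nact, chunk$n_active_min)
    prev_val <- chunk$values[nt, , drop = FALSE]
    prev_ts <- ts[nt]
  }
  activity <- do.call(rbind, bins)
  activity <- as_activity_ts(activity, scenario$name, bin_width)
  truth <- list(sigma = setup$sigma, baseline = setup$baseline,
                coupling = setup$coupling, events = events,
                hazard_min = hazard, n_active_min = nact,
                time_to_peak = scenario$profile$time_to_peak,
                lambda_scale = scenario$lambda_scale, seed = seed)
  structure(list(activity = activity, truth = truth, theta = theta,
                 calendar = calendar, scenario = scenario),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("<scenario_run> ", x$scenario$name, ": ", nrow(x$activity),
      " bins; ", nrow(x$truth$events), " events; seed ", x$truth$seed,
      "\n", sep = "")
  invisible(x)
}
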