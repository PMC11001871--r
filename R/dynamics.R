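#' Tumour--immune dynamics parameters
#'
#' Bundles the mechanistic constants of the cohort simulator: exponential
#' tumour repopulation, linear-quadratic (LQ) radiation cell kill applied to
#' gross volume, and a delayed, transient immune-mediated kill that is
#' amplified while anti-PD-L1 is pharmacologically active.
#'
#' The per-animal update rule (documented and fixed) is
#' \deqn{V_{t} = V_{t-1} \cdot SF(d_t) \cdot \exp(\rho - K_t)}
#' where \eqn{SF(d) = \exp(-(\alpha d + \beta d^2))} is the LQ survival
#' fraction of the dose delivered at step \eqn{t} (1 if none), and the immune
#' kill rate \eqn{K_t} equals `kappa` when some earlier pulse has opened an
#' immune window covering \eqn{t} *and* anti-PD-L1 is active at \eqn{t},
#' `kappa_bare` when a window is open without active drug, and 0 otherwise.
#' A pulse at step \eqn{p} opens the window
#' \eqn{[p + \mathrm{immune\_delay},\; p + \mathrm{immune\_delay} +
#' \mathrm{immune\_duration}]}; an administration at step \eqn{s} keeps the
#' antibody active on steps \eqn{s, \dots, s + \mathrm{drug\_window} - 1},
#' so the conventional every-other-day dosing gives continuous coverage.
#'
#' @param rho baseline exponential growth rate (per day); must be > 0.
#' @param alpha LQ linear coefficient (per Gy).
#' @param beta LQ quadratic coefficient (per Gy^2).
#' @param immune_delay days from a radiation pulse to onset of
#'   immune-mediated killing.
#' @param immune_duration days the immune effect persists once triggered.
#' @param kappa maximal immune kill rate (per day) while anti-PD-L1 is
#'   active inside an immune window.
#' @param kappa_bare immune kill rate (per day) inside a window without
#'   active anti-PD-L1 (isotype control or no drug); `0 <= kappa_bare <=
#'   kappa`.
#' @param drug_window days a single antibody administration remains
#'   pharmacologically active (>= 1).
#' @param noise_cv inter-animal coefficient of variation applied as
#'   log-normal multiplicative noise to the initial volume and to `rho`.
#'
#' @return An object of class `dynamics_params` (a validated list).
#' @export
#' @examples
#' p <- dynamics_params()
#' p$rho
dynamics_params <- function(rho = 0.25, alpha = 0.3, beta = 0.03,
                            immune_delay = 7, immune_duration = 10,
                            kappa = 0.2, kappa_bare = 0.05,
                            drug_window = 3, noise_cv = 0.15) {
  stop_if_not_scalar(rho, "rho")
  stop_if_not_scalar(alpha, "alpha", lower = 0)
  stop_if_not_scalar(beta, "beta", lower = 0)
  stop_if_not_scalar(immune_delay, "immune_delay", lower = 0)
  stop_if_not_scalar(immune_duration, "immune_duration")
  stop_if_not_scalar(kappa, "kappa", lower = 0)
  stop_if_not_scalar(kappa_bare, "kappa_bare", lower = 0)
  stop_if_not_scalar(drug_window, "drug_window", lower = 1)
  stop_if_not_scalar(noise_cv, "noise_cv", lower = 0)
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (immune_duration <= 0) stop("`immune_duration` must be > 0", call. = FALSE)
  if (kappa_bare > kappa) {
    stop("`kappa_bare` must not exceed `kappa`", call. = FALSE)
  }
  structure(
    list(rho = rho, alpha = alpha, beta = beta,
         immune_delay = immune_delay, immune_duration = immune_duration,
         kappa = kappa, kappa_bare = kappa_bare,
         drug_window = drug_window, noise_cv = noise_cv),
    class = "dynamics_params"
  )
}

#' Treatment schedule for one group
#'
#' A schedule lives on a 1-based daily grid of `n_steps` steps; step 1 is the
#' day of the first drug administration (the modelling window opens there,
#' two days before the conventional first radiation pulse at step 3).
#'
#' @param n_steps length of the modelling window in days (default 18).
#' @param radiation data frame with columns `step` and `dose_gy` (may have
#'   zero rows for unirradiated groups). Doses must be positive.
#' @param drug data frame with columns `step` and `agent`; `agent` must be
#'   `"isotype"` or `"anti_pdl1"`.
#' @param measurement_steps strictly increasing integer vector of steps at
#'   which tumour volume is recorded (at most 6, so that consecutive
#'   differences fill the model's 5 output slots); may be `NULL` for purely
#'   hypothetical schedules that are only ever fed to a trained surrogate.
#'
#' @return An object of class `treatment_schedule`.
#' @export
#' @examples
#' sched <- treatment_schedule(
#'   radiation = data.frame(step = 3, dose_gy = 20),
#'   drug = every_other_day("anti_pdl1"),
#'   measurement_steps = c(1, 4, 7, 10, 14, 18)
#' )
treatment_schedule <- function(n_steps = 18L,
                               radiation = NULL,
                               drug = NULL,
                               measurement_steps = NULL) {
  n_steps <- stop_if_not_count(n_steps, "n_steps")
  radiation <- normalize_events(radiation, c("step", "dose_gy"))
  drug <- normalize_events(drug, c("step", "agent"))

  if (nrow(radiation)) {
    check_steps(radiation$step, n_steps, "radiation")
    if (any(!is.finite(radiation$dose_gy) | radiation$dose_gy <= 0)) {
      stop("radiation doses must be positive and finite", call. = FALSE)
    }
  }
  if (nrow(drug)) {
    check_steps(drug$step, n_steps, "drug")
    bad <- !drug$agent %in% c("isotype", "anti_pdl1")
    if (any(bad)) {
      stop("drug agent must be 'isotype' or 'anti_pdl1'", call. = FALSE)
    }
  }
  if (!is.null(measurement_steps)) {
    measurement_steps <- as.integer(measurement_steps)
    check_steps(measurement_steps, n_steps, "measurement")
    if (length(measurement_steps) > 1 && any(diff(measurement_steps) <= 0)) {
      stop("measurement_steps must be strictly increasing", call. = FALSE)
    }
    if (length(measurement_steps) > 6) {
      stop("at most 6 measurement steps are supported", call. = FALSE)
    }
  }
  structure(
    list(n_steps = n_steps, radiation = radiation, drug = drug,
         measurement_steps = measurement_steps),
    class = "treatment_schedule"
  )
}

normalize_events <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                       cols))
  }
  x <- as.data.frame(x)
  if (!all(cols %in% names(x))) {
    stop(sprintf("expected columns: %s", paste(cols, collapse = ", ")),
         call. = FALSE)
  }
  x <- x[, cols, drop = FALSE]
  x$step <- as.integer(x$step)
  x[order(x$step), , drop = FALSE]
}

check_steps <- function(steps, n_steps, what) {
  if (any(!is.finite(steps) | steps < 1L | steps > n_steps)) {
    stop(sprintf("%s steps must lie in 1..%d", what, n_steps), call. = FALSE)
  }
  invisible(steps)
}

#' Every-other-day drug administrations
#'
#' Convenience constructor for the conventional dosing arm: `agent` given on
#' steps `start, start + 2, ...` up to `n_steps`.
#'
#' @param agent `"isotype"` or `"anti_pdl1"`.
#' @param n_steps window length.
#' @param start first administration step.
#' @return data frame with columns `step`, `agent`.
#' @export
every_other_day <- function(agent = c("isotype", "anti_pdl1"),
                            n_steps = 18L, start = 1L) {
  agent <- match.arg(agent)
  steps <- seq.int(start, n_steps, by = 2L)
  data.frame(step = steps, agent = agent, stringsAsFactors = FALSE)
}

#' Consecutive-day drug administrations
#'
#' Used by in-silico offset sweeps: `n_days` daily administrations starting
#' at `start`. Days falling beyond `n_steps` are dropped (clipped) and the
#' result carries attribute `clipped = TRUE` in that case.
#'
#' @inheritParams every_other_day
#' @param n_days number of consecutive administration days.
#' @return data frame with columns `step`, `agent`.
#' @export
consecutive_days <- function(agent = c("isotype", "anti_pdl1"),
                             start, n_days, n_steps = 18L) {
  agent <- match.arg(agent)
  steps <- seq.int(start, start + n_days - 1L)
  keep <- steps >= 1L & steps <= n_steps
  out <- data.frame(step = steps[keep], agent = rep(agent, sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "clipped") <- any(!keep)
  out
}

# Per-step immune kill rate implied by a schedule (length n_steps).
immune_kill_rates <- function(params, schedule) {
  n <- schedule$n_steps
  window_open <- rep(FALSE, n)
  for (p in schedule$radiation$step) {
    lo <- p + params$immune_delay
    hi <- p + params$immune_delay + params$immune_duration
    idx <- seq_len(n)
    window_open <- window_open | (idx >= lo & idx <= hi)
  }
  drug_active <- rep(FALSE, n)
  anti <- schedule$drug$step[schedule$drug$agent == "anti_pdl1"]
  for (s in anti) {
    hi <- min(n, s + params$drug_window - 1)
    drug_active[s:hi] <- TRUE
  }
  ifelse(window_open, ifelse(drug_active, params$kappa, params$kappa_bare), 0)
}

#' Simulate one animal's daily tumour-volume trajectory
#'
#' Applies the multiplicative exponential / LQ / immune-window model of
#' [dynamics_params()] day by day. The initial volume is drawn uniformly from
#' the 150--200 mm^3 randomization range and, together with the growth rate,
#' perturbed by log-normal inter-animal noise with coefficient of variation
#' `noise_cv` (mean-one, so `noise_cv = 0` is exactly noiseless).
#'
#' @param params a [dynamics_params()] object.
#' @param schedule a [treatment_schedule()].
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return numeric vector of daily volumes (mm^3), length `schedule$n_steps`;
#'   entry `t` is the volume at step `t` (step 1 holds the initial volume,
#'   after any step-1 pulse).
#' @export
#' @examples
#' s <- treatment_schedule(radiation = data.frame(step = 3, dose_gy = 20))
#' v <- simulate_animal(dynamics_params(noise_cv = 0), s, seed = 1)
simulate_animal <- function(params, schedule, seed = NULL) {
  stopifnot(inherits(params, "dynamics_params"),
            inherits(schedule, "treatment_schedule"))
  with_seed_or_current(seed, {
    n <- schedule$n_steps
    cv <- params$noise_cv
    lnoise <- function() {
      if (cv == 0) return(1)
      sdlog <- sqrt(log1p(cv^2))
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    v0 <- stats::runif(1, 150, 200) * lnoise()
    rho_a <- params$rho * lnoise()

    dose <- numeric(n)
    if (nrow(schedule$radiation)) {
      for (j in seq_len(nrow(schedule$radiation))) {
        dose[schedule$radiation$step[j]] <-
          dose[schedule$radiation$step[j]] + schedule$radiation$dose_gy[j]
      }
    }
    sf <- exp(-(params$alpha * dose + params$beta * dose^2))
    kill <- immune_kill_rates(params, schedule)

    v <- numeric(n)
    v[1] <- v0 * sf[1]
    for (t in seq_len(n)[-1]) {
      v[t] <- v[t - 1] * sf[t] * exp(rho_a - kill[t])
    }
    v
  })
}

#' Summarize a group of trajectories at the measurement steps
#'
#' @param trajectories list of equal-length volume vectors (one per animal),
#'   or a matrix with one row per animal.
#' @param measurement_steps steps at which to report mean and SD.
#' @param group_id optional identifier carried through.
#' @return A `group_summary`: list with `group_id`, `n_animals`, and
#'   `records`, a data frame of `step`, `mean_mm3`, `sd_mm3` (sample SD,
#'   n - 1 denominator).
#' @export
summarize_group <- function(trajectories, measurement_steps, group_id = NULL) {
  if (is.list(trajectories)) {
    if (!length(trajectories)) stop("no trajectories supplied", call. = FALSE)
    len <- unique(lengths(trajectories))
    if (length(len) != 1) {
      stop("trajectories must have equal length", call. = FALSE)
    }
    trajectories <- do.call(rbind, trajectories)
  }
  trajectories <- as.matrix(trajectories)
  if (nrow(trajectories) < 2) {
    stop("need at least 2 trajectories to summarize a group", call. = FALSE)
  }
  measurement_steps <- as.integer(measurement_steps)
  check_steps(measurement_steps, ncol(trajectories), "measurement")
  sub <- trajectories[, measurement_steps, drop = FALSE]
  structure(
    list(group_id = group_id %||% NA_character_,
         n_animals = nrow(trajectories),
         records = data.frame(
           step = measurement_steps,
           mean_mm3 = colMeans(sub),
           sd_mm3 = apply(sub, 2, stats::sd)
         )),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (n = %d animals)\n", x$group_id,
              x$n_animals))
  print(x$records, row.names = FALSE)
  invisible(x)
}
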