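#' Accumulated volume change (AVC) of a schedule under the surrogate
#'
#' The in-silico tumour-control endpoint: the sum of the surrogate's
#' predicted volume changes \eqn{AVC = \sum_{i=1}^{5} \Delta VC'_i}
#' (lower = better control). The schedule is encoded with the same
#' radiation-channel configuration the model was trained with.
#'
#' @param model a `pulsim_model`.
#' @param schedule a [treatment_schedule()] (measurement steps not
#'   required).
#' @return scalar AVC in mm^3; exactly `sum(predict(model, inputs))`.
#' @export
avc <- function(model, schedule) {
  stopifnot(inherits(model, "pulsim_model"))
  if (!inherits(schedule, "treatment_schedule")) {
    stop("`schedule` must be a treatment_schedule", call. = FALSE)
  }
  inputs <- encode_inputs(schedule, alpha = model$lq$alpha,
                          beta = model$lq$beta,
                          encoding = model$lq$encoding)
  sum(predict(model, inputs))
}

#' Specification of an anti-PD-L1 timing sweep
#'
#' Fixes a radiation scheme and sweeps the onset of a short consecutive-day
#' anti-PD-L1 course relative to the first pulse: offset `o` means the
#' first administration lands `o` days after the first pulse, followed by
#' `n_drug_days - 1` further daily doses. Courses running past the window
#' end are clipped to it (and flagged), since late offsets necessarily
#' collide with the 18-step horizon.
#'
#' @param radiation data frame `step`, `dose_gy` of the pulse scheme.
#' @param n_drug_days consecutive drug days (conventionally 2 or 4).
#' @param offsets integer offsets in days (default 1..14).
#' @param agent drug agent (default `"anti_pdl1"`).
#' @param n_steps window length.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(radiation, n_drug_days = 4L, offsets = 1:14,
                       agent = "anti_pdl1", n_steps = 18L) {
  radiation <- normalize_events(radiation, c("step", "dose_gy"))
  if (!nrow(radiation)) {
    stop("a sweep needs at least one radiation pulse to anchor offsets",
         call. = FALSE)
  }
  structure(list(radiation = radiation,
                 n_drug_days = stop_if_not_count(n_drug_days, "n_drug_days"),
                 offsets = as.integer(offsets),
                 agent = agent,
                 n_steps = stop_if_not_count(n_steps, "n_steps")),
            class = "sweep_spec")
}

# schedule realised by one offset of a sweep; clipping flag on the result
sweep_schedule <- function(spec, offset) {
  first_pulse <- min(spec$radiation$step)
  drug <- consecutive_days(spec$agent, start = first_pulse + offset,
                           n_days = spec$n_drug_days,
                           n_steps = spec$n_steps)
  sched <- treatment_schedule(n_steps = spec$n_steps,
                              radiation = spec$radiation, drug = drug)
  attr(sched, "clipped") <- isTRUE(attr(drug, "clipped"))
  attr(sched, "all_out") <- nrow(drug) == 0L
  sched
}

#' Sweep anti-PD-L1 onset offsets and score each by AVC
#'
#' @param model a trained `pulsim_model`.
#' @param spec a [sweep_spec()].
#' @return data frame with one row per offset: `offset`, `n_drug_days`,
#'   `avc_mm3`, `clipped` (TRUE when the drug course was truncated by the
#'   window end; an offset whose course falls entirely outside the window
#'   keeps its row with `avc_mm3 = NA`).
#' @export
sweep_offsets <- function(model, spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- lapply(spec$offsets, function(o) {
    sched <- sweep_schedule(spec, o)
    if (isTRUE(attr(sched, "all_out"))) {
      warning(sprintf(
        "offset %d pushes every drug day outside the %d-step window", o,
        spec$n_steps), call. = FALSE)
      return(data.frame(offset = o, n_drug_days = spec$n_drug_days,
                        avc_mm3 = NA_real_, clipped = TRUE))
    }
    if (isTRUE(attr(sched, "clipped"))) {
      warning(sprintf("offset %d: drug course clipped to the window", o),
              call. = FALSE)
    }
    data.frame(offset = o, n_drug_days = spec$n_drug_days,
               avc_mm3 = avc(model, sched),
               clipped = isTRUE(attr(sched, "clipped")))
  })
  do.call(rbind, rows)
}

#' Rank delivery schemes by AVC
#'
#' Scores each schedule with [avc()] and returns them best (lowest AVC)
#' first; ties keep the input order.
#'
#' @param model a trained `pulsim_model`.
#' @param schedules named list of [treatment_schedule()]s.
#' @return data frame `scheme`, `avc_mm3`, sorted ascending by AVC.
#' @export
compare_schemes <- function(model, schedules) {
  if (!length(schedules)) stop("no schedules supplied", call. = FALSE)
  nm <- names(schedules) %||% paste0("scheme_", seq_along(schedules))
  if (is.null(names(schedules))) names(schedules) <- nm
  scores <- vapply(schedules, function(s) avc(model, s), numeric(1))
  out <- data.frame(scheme = names(schedules), avc_mm3 = scores,
                    row.names = NULL)
  out[order(out$avc_mm3, seq_len(nrow(out))), , drop = FALSE]
}
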