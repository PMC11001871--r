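#' Default 26-group study design
#'
#' Builds the group grid of the murine pulsed radiotherapy + checkpoint
#' blockade experiment this package emulates: 13 radiation schemes (no
#' radiation; single pulses of 10/15/20/40 Gy; pulse pairs of 10/15 Gy at
#' 1-, 4- and 10-day spacing; a 20 Gy pair at 4- and at 10-day spacing),
#' each crossed with an isotype-control and an anti-PD-L1 arm dosed every
#' other day from step 1, giving 26 groups of 7--8 animals. The first pulse
#' lands on step 3 of the 18-step window (two days after the first drug
#' administration, i.e. day 14 post-implantation on the experimental
#' calendar).
#'
#' @param n_steps modelling window length.
#' @param first_pulse_step step of the first radiation pulse.
#' @param measurement_steps measurement days shared by all groups (6 uneven
#'   steps by default, matching the sparse measurement cadence).
#' @return A list of group specifications (class `study_config`), each with
#'   `group_id`, `n_animals` and a [treatment_schedule()].
#' @export
default_study_config <- function(n_steps = 18L, first_pulse_step = 3L,
                                 measurement_steps = c(1L, 4L, 7L, 10L, 14L, 18L)) {
  schemes <- list(
    list(doses = numeric(0), spacing = NA),
    list(doses = 20, spacing = NA),
    list(doses = 40, spacing = NA),
    list(doses = c(20, 20), spacing = 10),
    list(doses = 10, spacing = NA),
    list(doses = 15, spacing = NA),
    list(doses = c(10, 10), spacing = 1),
    list(doses = c(10, 10), spacing = 4),
    list(doses = c(10, 10), spacing = 10),
    list(doses = c(15, 15), spacing = 1),
    list(doses = c(15, 15), spacing = 4),
    list(doses = c(15, 15), spacing = 10),
    list(doses = c(20, 20), spacing = 4)
  )
  groups <- list()
  gid <- 0L
  n_animals_cycle <- c(8L, 7L)
  for (k in seq_along(schemes)) {
    sc <- schemes[[k]]
    steps <- if (!length(sc$doses)) integer(0) else {
      first_pulse_step + c(0L, rep(sc$spacing, length(sc$doses) - 1L))
    }
    rad <- if (length(sc$doses)) {
      data.frame(step = as.integer(steps), dose_gy = sc$doses)
    } else NULL
    for (agent in c("isotype", "anti_pdl1")) {
      gid <- gid + 1L
      groups[[gid]] <- list(
        group_id = sprintf("group_%02d", gid),
        n_animals = n_animals_cycle[(gid - 1L) %% 2L + 1L],
        schedule = treatment_schedule(
          n_steps = n_steps, radiation = rad,
          drug = every_other_day(agent, n_steps = n_steps),
          measurement_steps = measurement_steps
        )
      )
    }
  }
  structure(groups, class = "study_config")
}

#' Effect-recovery study design
#'
#' A compact design whose arms vary the *onset* of anti-PD-L1 relative to a
#' single radiation pulse, so that a surrogate trained on it can in
#' principle recover the simulator's immune delay from an offset sweep (the
#' conventional every-other-day arms of [default_study_config()] carry no
#' drug-timing variation at all). Arms: untreated control (isotype only),
#' radiation-only (pulse + isotype), and pulse + `n_drug_days` consecutive
#' anti-PD-L1 days starting `offset` days after the pulse, one group per
#' offset.
#'
#' @param pulse_dose_gy dose of the single pulse.
#' @param pulse_step step of the pulse.
#' @param offsets drug-onset offsets (days after the pulse), one group each.
#' @param n_drug_days consecutive anti-PD-L1 days per offset arm.
#' @param n_animals animals per group.
#' @inheritParams default_study_config
#' @return A `study_config` list.
#' @export
recovery_study_config <- function(pulse_dose_gy = 10, pulse_step = 3L,
                                  offsets = c(1L, 3L, 5L, 7L, 9L, 11L, 13L),
                                  n_drug_days = 4L, n_animals = 8L,
                                  n_steps = 18L,
                                  measurement_steps = c(1L, 4L, 7L, 10L, 14L, 18L)) {
  rad <- data.frame(step = pulse_step, dose_gy = pulse_dose_gy)
  groups <- list(
    list(group_id = "control", n_animals = n_animals,
         schedule = treatment_schedule(
           n_steps = n_steps, drug = every_other_day("isotype", n_steps),
           measurement_steps = measurement_steps)),
    list(group_id = "rt_only", n_animals = n_animals,
         schedule = treatment_schedule(
           n_steps = n_steps, radiation = rad,
           drug = every_other_day("isotype", n_steps),
           measurement_steps = measurement_steps))
  )
  for (o in offsets) {
    groups[[length(groups) + 1L]] <- list(
      group_id = sprintf("rt_anti_off%02d", o), n_animals = n_animals,
      schedule = treatment_schedule(
        n_steps = n_steps, radiation = rad,
        drug = consecutive_days("anti_pdl1", start = pulse_step + o,
                                n_days = n_drug_days, n_steps = n_steps),
        measurement_steps = measurement_steps))
  }
  structure(groups, class = "study_config")
}

#' Simulate a full synthetic study
#'
#' Simulates every group of `config` (each animal via [simulate_animal()])
#' and summarizes it at the group's measurement steps.
#'
#' @param config a `study_config`, e.g. [default_study_config()].
#' @param params a [dynamics_params()] object shared by all groups.
#' @param seed optional integer; the whole study is reproducible given the
#'   seed.
#' @return A `pulsim_study`: list with `groups` (each holding `group_id`,
#'   `n_animals`, `schedule`, `summary`), `params`, and `seed`.
#' @export
#' @examples
#' study <- generate_study(default_study_config(), seed = 1)
#' length(study$groups)  # 26
generate_study <- function(config = default_study_config(),
                           params = dynamics_params(), seed = NULL) {
  ids <- vapply(config, function(g) as.character(g$group_id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate group ids in study config: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  with_seed_or_current(seed, {
    groups <- lapply(config, function(g) {
      traj <- lapply(seq_len(g$n_animals), function(i) {
        simulate_animal(params, g$schedule)
      })
      summ <- summarize_group(traj, g$schedule$measurement_steps,
                              group_id = g$group_id)
      list(group_id = g$group_id, n_animals = g$n_animals,
           schedule = g$schedule, summary = summ)
    })
    structure(list(groups = groups, params = params, seed = seed),
              class = "pulsim_study")
  })
}

#' @export
print.pulsim_study <- function(x, ...) {
  cat(sprintf("<pulsim_study> %d groups, %d animals total\n",
              length(x$groups),
              sum(vapply(x$groups, `[[`, integer(1), "n_animals"))))
  invisible(x)
}

#' Write / read study artifacts
#'
#' `write_study()` writes the group summaries as a flat CSV
#' (`group_summaries.csv`: group_id, n_animals, step, mean_mm3, sd_mm3) and
#' the schedules as JSON (`schedules.json`); `read_study()` reads the pair
#' back into a `pulsim_study` (without dynamics parameters, which are not an
#' observable of a real study).
#'
#' @param study a `pulsim_study`.
#' @param dir directory to write into (created if needed).
#' @return `write_study()` returns the two file paths invisibly;
#'   `read_study()` returns a `pulsim_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(study$groups, function(g) {
    data.frame(group_id = g$group_id, n_animals = g$n_animals,
               step = g$summary$records$step,
               mean_mm3 = num_chr(g$summary$records$mean_mm3),
               sd_mm3 = num_chr(g$summary$records$sd_mm3))
  }))
  csv <- file.path(dir, "group_summaries.csv")
  utils::write.csv(rows, csv, row.names = FALSE, quote = FALSE)

  sched <- lapply(study$groups, function(g) {
    s <- g$schedule
    list(group_id = g$group_id, n_steps = s$n_steps,
         radiation = if (nrow(s$radiation)) s$radiation else list(),
         drug = if (nrow(s$drug)) s$drug else list(),
         measurement_steps = s$measurement_steps)
  })
  js <- file.path(dir, "schedules.json")
  jsonlite::write_json(sched, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(summaries = csv, schedules = js))
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  csv <- file.path(dir, "group_summaries.csv")
  js <- file.path(dir, "schedules.json")
  for (f in c(csv, js)) {
    if (!file.exists(f)) stop("missing study artifact: ", f, call. = FALSE)
  }
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  sched <- jsonlite::read_json(js, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
  groups <- lapply(seq_len(nrow(sched)), function(i) {
    gi <- sched$group_id[i]
    rad <- sched$radiation[[i]]
    drug <- sched$drug[[i]]
    schedule <- treatment_schedule(
      n_steps = sched$n_steps[i],
      radiation = if (length(rad)) rad else NULL,
      drug = if (length(drug)) drug else NULL,
      measurement_steps = sched$measurement_steps[[i]]
    )
    sub <- tab[tab$group_id == gi, , drop = FALSE]
    summ <- structure(
      list(group_id = gi, n_animals = sub$n_animals[1],
           records = data.frame(step = sub$step, mean_mm3 = sub$mean_mm3,
                                sd_mm3 = sub$sd_mm3)),
      class = "group_summary")
    list(group_id = gi, n_animals = sub$n_animals[1],
         schedule = schedule, summary = summ)
  })
  structure(list(groups = groups, params = NULL, seed = NULL),
            class = "pulsim_study")
}
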