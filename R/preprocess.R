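#' Linear-quadratic radiation effect
#'
#' Scalar encoding of the killing effect of a single dose under the
#' linear-quadratic model, used for the radiation input channel. The default
#' encoding is the log cell kill \eqn{\alpha d + \beta d^2}; alternatives
#' are `1 - SF(d)` (killed fraction) and the raw dose.
#'
#' @param dose dose in Gy (vectorized, must be >= 0).
#' @param alpha per Gy.
#' @param beta per Gy^2.
#' @param encoding one of `"log_kill"`, `"one_minus_sf"`, `"dose"`.
#' @return nonnegative effect value(s); 0 iff `dose == 0`.
#' @export
#' @examples
#' lq_effect(20)          # 0.3*20 + 0.03*400 = 18
lq_effect <- function(dose, alpha = 0.3, beta = 0.03,
                      encoding = c("log_kill", "one_minus_sf", "dose")) {
  encoding <- match.arg(encoding)
  stop_if_not_scalar(alpha, "alpha", lower = 0)
  stop_if_not_scalar(beta, "beta", lower = 0)
  if (any(!is.finite(dose) | dose < 0)) {
    stop("`dose` must be nonnegative and finite", call. = FALSE)
  }
  lk <- alpha * dose + beta * dose^2
  switch(encoding,
         log_kill = lk,
         one_minus_sf = 1 - exp(-lk),
         dose = dose)
}

#' Tumour volume from caliper measurements
#'
#' @param x,y,z length, width, height (same unit; nonnegative).
#' @return `x * y * z / 2`.
#' @export
#' @examples
#' tumor_volume(2, 2, 2)  # 4
tumor_volume <- function(x, y, z) {
  if (any(!is.finite(c(x, y, z))) || any(c(x, y, z) < 0)) {
    stop("tumour dimensions must be nonnegative and finite", call. = FALSE)
  }
  x * y * z / 2
}

#' Augment a group summary into synthetic per-animal volume series
#'
#' Draws `n_samples` synthetic animals from the group's per-step Gaussian
#' `Normal(mean, sd / sd_shrink)` (the SD is deliberately shrunk, default
#' by a factor of 5, to emulate a more precise measurement technique than
#' calipers). Draws are clipped below at `floor_mm3` since volumes are
#' physical.
#'
#' @param summary a `group_summary`.
#' @param n_samples synthetic animals to draw (default 50).
#' @param sd_shrink SD shrink factor (> 0, default 5).
#' @param seed optional integer for reproducibility.
#' @param floor_mm3 positive clip floor for the draws.
#' @return matrix `n_samples` x `n_measurements` of volumes (mm^3), columns
#'   named by measurement step.
#' @export
augment_group <- function(summary, n_samples = 50L, sd_shrink = 5,
                          seed = NULL, floor_mm3 = 1) {
  stopifnot(inherits(summary, "group_summary"))
  n_samples <- stop_if_not_count(n_samples, "n_samples")
  stop_if_not_scalar(sd_shrink, "sd_shrink")
  if (sd_shrink <= 0) stop("`sd_shrink` must be > 0", call. = FALSE)
  rec <- summary$records
  if (is.null(rec) || !nrow(rec)) {
    stop("group summary has no records", call. = FALSE)
  }
  with_seed_or_current(seed, {
    draws <- vapply(seq_len(nrow(rec)), function(j) {
      stats::rnorm(n_samples, mean = rec$mean_mm3[j],
                   sd = rec$sd_mm3[j] / sd_shrink)
    }, numeric(n_samples))
    draws <- matrix(pmax(draws, floor_mm3), nrow = n_samples)
    colnames(draws) <- rec$step
    draws
  })
}

#' Encode a schedule as the surrogate's two-channel input matrix
#'
#' Channel `"radiation"` carries [lq_effect()] of the delivered dose on
#' pulse steps and 0 elsewhere (the effect value is placed on the delivery
#' day only); channel `"drug"` carries the ordinal code 1 (isotype),
#' 2 (anti-PD-L1) on administration steps and 0 elsewhere.
#'
#' @param schedule a [treatment_schedule()].
#' @param alpha,beta,encoding passed to [lq_effect()].
#' @return numeric matrix `n_steps` x 2 with columns `radiation`, `drug`.
#' @export
encode_inputs <- function(schedule, alpha = 0.3, beta = 0.03,
                          encoding = "log_kill") {
  stopifnot(inherits(schedule, "treatment_schedule"))
  n <- schedule$n_steps
  m <- matrix(0, nrow = n, ncol = 2,
              dimnames = list(NULL, c("radiation", "drug")))
  rad <- schedule$radiation
  if (nrow(rad)) {
    m[rad$step, "radiation"] <- m[rad$step, "radiation"] +
      lq_effect(rad$dose_gy, alpha, beta, encoding)
  }
  drug <- schedule$drug
  if (nrow(drug)) {
    m[drug$step, "drug"] <- ifelse(drug$agent == "anti_pdl1", 2, 1)
  }
  m
}

#' Consecutive volume changes with a validity mask
#'
#' Converts volumes observed at the measurement steps into the surrogate's
#' target vector of consecutive differences
#' \eqn{\Delta VC_i = V_{i+1} - V_i}. Undefined slots (beyond the number of
#' measured intervals) are zero-filled and masked out; positive change means
#' growth, negative means shrinkage.
#'
#' @param volumes volumes at the measurement steps (length 1..6).
#' @param n_outputs target slots (default 5).
#' @return list with `targets` (numeric, length `n_outputs`) and `mask`
#'   (logical, `TRUE` where a difference is defined).
#' @export
#' @examples
#' compute_volume_changes(c(100, 150, 130))
compute_volume_changes <- function(volumes, n_outputs = 5L) {
  n_outputs <- stop_if_not_count(n_outputs, "n_outputs")
  if (!length(volumes) || length(volumes) > n_outputs + 1L) {
    stop(sprintf("need 1..%d volumes", n_outputs + 1L), call. = FALSE)
  }
  if (any(!is.finite(volumes))) stop("volumes must be finite", call. = FALSE)
  targets <- numeric(n_outputs)
  mask <- logical(n_outputs)
  m <- length(volumes)
  if (m > 1) {
    targets[seq_len(m - 1)] <- diff(volumes)
    mask[seq_len(m - 1)] <- TRUE
  }
  list(targets = targets, mask = mask)
}

#' Build the encoded training dataset from a study
#'
#' Augments each group ([augment_group()]), encodes its schedule
#' ([encode_inputs()]) and its per-sample volume changes
#' ([compute_volume_changes()]), and assembles the arrays the surrogate
#' trains on. Groups with fewer than two measurement steps cannot yield a
#' target and are skipped with a warning.
#'
#' @param study a `pulsim_study` (from [generate_study()] or
#'   [read_study()]).
#' @param n_samples augmented samples per group (default 50).
#' @param sd_shrink SD shrink factor for augmentation.
#' @param seed optional integer.
#' @param alpha,beta,encoding radiation-channel encoding, see [lq_effect()].
#' @param target_scale fixed constant dividing the mm^3 targets during
#'   training (inverted on prediction); pure loss conditioning, round-trips
#'   exactly.
#' @return A `pulsim_dataset`: list with `inputs` (N x n_steps x 2 array),
#'   `targets` (N x 5, mm^3), `mask` (N x 5 logical), `group_id`
#'   (character N), plus the encoding configuration as fields `lq` and
#'   `target_scale`.
#' @export
build_dataset <- function(study, n_samples = 50L, sd_shrink = 5,
                          seed = NULL, alpha = 0.3, beta = 0.03,
                          encoding = "log_kill", target_scale = 100) {
  stopifnot(inherits(study, "pulsim_study"))
  with_seed_or_current(seed, {
    inputs <- list(); targets <- list(); mask <- list(); gid <- character(0)
    n_steps <- NULL
    for (g in study$groups) {
      ms <- g$schedule$measurement_steps
      if (is.null(ms) || length(ms) < 2) {
        warning(sprintf("group %s has < 2 measurement steps; skipped",
                        g$group_id), call. = FALSE)
        next
      }
      n_steps <- n_steps %||% g$schedule$n_steps
      if (g$schedule$n_steps != n_steps) {
        stop("all groups must share the same window length", call. = FALSE)
      }
      x <- encode_inputs(g$schedule, alpha, beta, encoding)
      draws <- augment_group(g$summary, n_samples = n_samples,
                             sd_shrink = sd_shrink)
      for (i in seq_len(n_samples)) {
        vc <- compute_volume_changes(draws[i, ])
        inputs[[length(inputs) + 1L]] <- x
        targets[[length(targets) + 1L]] <- vc$targets
        mask[[length(mask) + 1L]] <- vc$mask
        gid <- c(gid, g$group_id)
      }
    }
    if (!length(inputs)) stop("no usable groups in study", call. = FALSE)
    N <- length(inputs)
    X <- array(0, dim = c(N, n_steps, 2),
               dimnames = list(NULL, NULL, c("radiation", "drug")))
    for (i in seq_len(N)) X[i, , ] <- inputs[[i]]
    structure(
      list(inputs = X,
           targets = do.call(rbind, targets),
           mask = do.call(rbind, mask),
           group_id = gid,
           lq = list(alpha = alpha, beta = beta, encoding = encoding),
           target_scale = target_scale,
           n_steps = n_steps),
      class = "pulsim_dataset")
  })
}

#' @export
print.pulsim_dataset <- function(x, ...) {
  cat(sprintf(
    "<pulsim_dataset> %d samples, %d groups, %d steps x 2 channels\n",
    dim(x$inputs)[1], length(unique(x$group_id)), x$n_steps))
  invisible(x)
}
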