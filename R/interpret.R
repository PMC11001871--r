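#' Extract the hidden-unit map for one input sequence
#'
#' Runs the trained surrogate over a single encoded schedule and collects
#' the recurrent state at every step, giving a `hidden_units x n_steps`
#' activation map. The hidden state `h_t` is extracted by default; the
#' memory cell state `c_t` is available via `state = "cell"` for
#' exploration.
#'
#' @param model a `pulsim_model`.
#' @param inputs an `n_steps x 2` input matrix from [encode_inputs()].
#' @param state `"hidden"` (default) or `"cell"`.
#' @param provenance optional label (group id or schedule description)
#'   carried as an attribute; it never affects the values.
#' @return A `hidden_map`: numeric matrix, rows = hidden-unit index
#'   (1-based), columns = time step.
#' @export
extract_hidden_map <- function(model, inputs,
                               state = c("hidden", "cell"),
                               provenance = NULL) {
  state <- match.arg(state)
  if (!inherits(model, "pulsim_model") || is.null(model$weights)) {
    stop("`model` must be a trained pulsim_model", call. = FALSE)
  }
  if (!is.matrix(inputs) || nrow(inputs) != model$config$n_steps ||
      ncol(inputs) != model$config$n_input_channels) {
    stop(sprintf("inputs must be a %d x %d matrix", model$config$n_steps,
                 model$config$n_input_channels), call. = FALSE)
  }
  x <- array(inputs, dim = c(1, nrow(inputs), ncol(inputs)))
  fwd <- lstm_forward(model$weights, array_to_steps(x))
  field <- if (state == "hidden") "h" else "c_state"
  m <- vapply(fwd$cache, function(cc) as.numeric(cc[[field]]),
              numeric(model$config$hidden_units))
  dimnames(m) <- list(unit = NULL, step = NULL)
  structure(m, class = c("hidden_map", "matrix"),
            provenance = provenance, state = state)
}

#' Difference of two hidden-unit maps
#'
#' Elementwise `map_a - map_b`; with the two schedules differing in a
#' single stimulus, the difference map isolates the network's response to
#' that stimulus. Because the recurrence is causal, schedules identical
#' through step `k` produce exactly-zero difference columns `1..k`.
#'
#' @param map_a,map_b `hidden_map`s (or plain matrices) of equal shape.
#' @return numeric matrix of the same shape.
#' @export
difference_map <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b))) {
    stop("hidden maps must have identical shape", call. = FALSE)
  }
  d <- unclass(map_a) - unclass(map_b)
  attr(d, "provenance") <- NULL
  attr(d, "state") <- NULL
  class(d) <- "matrix"
  d
}

#' Region specifications over a hidden-unit map
#'
#' `region_spec()` names a block of hidden-unit rows (and optionally a
#' column/step range); `default_regions()` returns the four conventional
#' regions for a 100-unit map: three associated with the radiation response
#' (units 1--5, 20--45, 85--90) and one with the anti-PD-L1 response
#' (units 65--75). Region choice is a heuristic reading aid, fully
#' configurable.
#'
#' @param name region label.
#' @param rows integer vector of hidden-unit rows (1-based).
#' @param cols optional integer vector of steps; `NULL` means all steps.
#' @return `region_spec()`: a `region_spec` list; `default_regions()`: a
#'   list of them.
#' @export
region_spec <- function(name, rows, cols = NULL) {
  structure(list(name = name, rows = as.integer(rows),
                 cols = if (is.null(cols)) NULL else as.integer(cols)),
            class = "region_spec")
}

#' @rdname region_spec
#' @export
default_regions <- function() {
  list(region_spec("radiation_a", 1:5),
       region_spec("radiation_b", 20:45),
       region_spec("radiation_c", 85:90),
       region_spec("anti_pdl1", 65:75))
}

#' Summary statistics of a difference map by region
#'
#' Within each region reports the mean activation difference and the
#' fraction of strictly positive cells (more positive values in the
#' treatment-linked regions reading as a stronger modelled treatment
#' effect).
#'
#' @param diff a matrix from [difference_map()].
#' @param regions list of [region_spec()]s.
#' @return data frame with columns `region`, `mean`, `fraction_positive`.
#' @export
region_summary <- function(diff, regions = default_regions()) {
  rows <- lapply(regions, function(r) {
    stopifnot(inherits(r, "region_spec"))
    if (any(r$rows < 1 | r$rows > nrow(diff))) {
      stop(sprintf("region '%s' rows outside 1..%d", r$name, nrow(diff)),
           call. = FALSE)
    }
    cols <- r$cols %||% seq_len(ncol(diff))
    if (any(cols < 1 | cols > ncol(diff))) {
      stop(sprintf("region '%s' cols outside 1..%d", r$name, ncol(diff)),
           call. = FALSE)
    }
    block <- diff[r$rows, cols, drop = FALSE]
    data.frame(region = r$name, mean = mean(block),
               fraction_positive = mean(block > 0))
  })
  do.call(rbind, rows)
}

#' Heatmap of a hidden-unit (difference) map
#'
#' @param x a `hidden_map` or difference matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot.hidden_map <- function(x, ...) {
  m <- unclass(x)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  xlab = "time step", ylab = "hidden unit",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' Write a hidden map or difference map as CSV
#'
#' @param map matrix (units x steps).
#' @param path output file.
#' @export
write_map_csv <- function(map, path) {
  m <- unclass(map)
  df <- data.frame(unit = seq_len(nrow(m)),
                   apply(m, 2, num_chr))
  names(df) <- c("unit", paste0("step_", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
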