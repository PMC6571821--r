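#' Specification of one of the five PLS modelling strategies
#'
#' The five models combine a bilinear or trilinear predictor structure with a
#' group, time-response, or combined dummy response:
#'
#' * model 1 — bilinear X (samples x variables), Y = group code per sample;
#' * model 2 — bilinear X, Y = time-response label per sample;
#' * model 3 — bilinear X, Y = group code x time-response label per sample;
#' * model 4 — trilinear X (units x variables x time), Y = group code per unit;
#' * model 5 — trilinear X, two-way Y = outer product of unit group codes and
#'   per-time response labels (units x time matrix).
#'
#' @param model_id integer 1-5.
#' @param n_latent positive integer, or `"auto"` to select by cross-validated
#'   RMSECV with the 2 percent rule (see [choose_n_latent()]).
#' @param response_magnitude numeric label for the response class (> 1;
#'   default 10).
#' @return An object of class `model_spec` with fields `model_id`, `x_shape`
#'   (`"bilinear"` or `"trilinear"`), `y_variant`, `n_latent`,
#'   `response_magnitude`.
#' @export
model_spec <- function(model_id, n_latent = "auto", response_magnitude = 10) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stop("`model_id` must be in 1..5", call. = FALSE)
  if (!(identical(n_latent, "auto") ||
        (is.numeric(n_latent) && length(n_latent) == 1L && n_latent >= 1)))
    stop("`n_latent` must be a positive integer or \"auto\"", call. = FALSE)
  if (!is.numeric(response_magnitude) || response_magnitude <= 1)
    stop("`response_magnitude` must be > 1", call. = FALSE)
  x_shape <- if (model_id <= 3L) "bilinear" else "trilinear"
  y_variant <- switch(model_id, "group", "time_response", "group_x_time",
                      "trilinear_group", "trilinear_two_way")
  structure(list(model_id = model_id, x_shape = x_shape, y_variant = y_variant,
                 n_latent = n_latent, response_magnitude = response_magnitude),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model %d: %s X, dummy Y = %s, n_latent = %s\n", x$model_id,
              x$x_shape, x$y_variant, paste(x$n_latent, collapse = "")))
  invisible(x)
}

#' Time-response dummy design
#'
#' Samples collected while the target metabolites are elevated (typically the
#' middle of the time series) form the "response class" and are labelled with
#' `response_magnitude`; samples from the remaining (first/last) time points
#' form the "no-response class" labelled `no_response_magnitude`. By default
#' the response window is all interior time points; for incomplete profiles
#' (short sampling periods where levels do not return to baseline) supply the
#' responding time points explicitly, e.g. all but the first.
#'
#' @param response_times numeric vector of responding time points, or `NULL`
#'   to use all interior points of the data's time grid.
#' @param response_magnitude numeric label for the response class (default 10).
#' @param no_response_magnitude numeric label for the no-response class
#'   (default 1; must differ from `response_magnitude`).
#' @param group_codes length-2 numeric codes for (control, intervention);
#'   default `c(-1, 1)`. Under this coding the combined group x time response
#'   (model 3) assigns control samples the negated time profile, so variables
#'   responding identically in both groups cancel out of the X-Y covariance
#'   and only treatment-specific responses drive the model. `c(0, 1)` (which
#'   instead zeroes the control samples) is also accepted.
#' @return An object of class `response_design`.
#' @export
response_design <- function(response_times = NULL, response_magnitude = 10,
                            no_response_magnitude = 1, group_codes = c(-1, 1)) {
  if (response_magnitude == no_response_magnitude)
    stop("degenerate design: response and no-response magnitudes must differ",
         call. = FALSE)
  if (length(group_codes) != 2L || group_codes[1L] == group_codes[2L])
    stop("`group_codes` must be two distinct values", call. = FALSE)
  structure(list(response_times = response_times,
                 response_magnitude = response_magnitude,
                 no_response_magnitude = no_response_magnitude,
                 group_codes = group_codes),
            class = "response_design")
}

# Fill in the default response window (interior points) given a time grid.
resolve_design <- function(design, time_grid) {
  stopifnot(inherits(design, "response_design"))
  time_grid <- sort(unique(time_grid))
  if (is.null(design$response_times)) {
    if (length(time_grid) < 3L)
      stop("design error: need >= 3 time points for a default response window",
           call. = FALSE)
    design$response_times <- time_grid[-c(1L, length(time_grid))]
  }
  if (!all(design$response_times %in% time_grid))
    stop("design error: response_times not all on the data's time grid",
         call. = FALSE)
  if (length(design$response_times) == 0L ||
      length(design$response_times) >= length(time_grid))
    stop("design error: response_times must be a non-empty strict subset of the time grid",
         call. = FALSE)
  design
}

#' Time-response labels for a vector of sampling times
#'
#' @param times numeric vector of sampling times.
#' @param design a [response_design()] with `response_times` set (use
#'   [response_design()] with explicit times, or let [make_dummy_y()] resolve
#'   the default interior window).
#' @return Numeric vector of labels (`response_magnitude` at responding times,
#'   `no_response_magnitude` elsewhere).
#' @export
time_response_labels <- function(times, design) {
  stopifnot(inherits(design, "response_design"))
  if (is.null(design$response_times))
    stop("design error: response_times not set; resolve the design first",
         call. = FALSE)
  ifelse(times %in% design$response_times,
         design$response_magnitude, design$no_response_magnitude)
}

group_codes_for <- function(group, design) {
  design$group_codes[as.integer(group)]
}

#' Construct the dummy response for one of the five models
#'
#' @param data a [long_table()] (models 1-3) or `data_cube` (models 4-5).
#' @param spec a [model_spec()].
#' @param design a [response_design()]; an unset response window defaults to
#'   the interior time points of `data`'s grid.
#' @return Models 1-3: numeric vector of length ST (per sample). Model 4:
#'   numeric vector of length S' (per unit). Model 5: S' x T numeric matrix.
#' @export
make_dummy_y <- function(data, spec, design = response_design()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$x_shape == "bilinear") {
    if (!inherits(data, "long_table"))
      stop("shape error: models 1-3 need a long_table", call. = FALSE)
    s <- data$samples
    design <- resolve_design(design, s$time)
    g <- group_codes_for(s$group, design)
    switch(spec$y_variant,
           group = g,
           time_response = time_response_labels(s$time, design),
           group_x_time = g * time_response_labels(s$time, design))
  } else {
    if (inherits(data, "long_table")) data <- to_cube(data)
    if (!inherits(data, "data_cube"))
      stop("shape error: models 4-5 need a data_cube", call. = FALSE)
    design <- resolve_design(design, data$times)
    g <- group_codes_for(data$group, design)
    switch(spec$y_variant,
           trilinear_group = g,
           trilinear_two_way = outer(g, time_response_labels(data$times, design)))
  }
}
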