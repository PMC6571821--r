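#' Long-format feature table for intervention time-series data
#'
#' A `long_table` holds one row per sample (subject x time occasion) and one
#' column per measured variable (metabolite feature), together with the design
#' metadata needed to reshape the data into a three-way array: subject,
#' treatment group, sampling time, and experimental unit. The unit is the
#' subject-by-condition occasion; in a crossover design the same subject
#' contributes one unit per condition, so a 6-subject / 2-condition crossover
#' yields 12 units.
#'
#' The design must be complete: every unit is observed at the same ordered set
#' of time points, exactly once per time point, and the group label is constant
#' within a unit.
#'
#' @param X numeric matrix of feature intensities, rows = samples, columns =
#'   variables.
#' @param subject vector of subject identifiers (length `nrow(X)`).
#' @param group vector of group labels; coerced to a two-level factor. If the
#'   labels are `"control"`/`"intervention"` the control level is placed
#'   first; otherwise levels are sorted and the first is treated as the
#'   reference (code 0) group.
#' @param time numeric vector of sampling times (same unit for all rows,
#'   e.g. hours).
#' @param unit optional vector of experimental-unit identifiers. Defaults to
#'   `subject` (parallel-group design); supply `subject x condition` labels
#'   for crossover designs.
#' @param variable_ids character vector of variable names (defaults to
#'   `colnames(X)` or `V1..VJ`).
#' @return An object of class `long_table` with elements `X`, `samples`
#'   (data.frame with `subject`, `group`, `time`, `unit`) and `variable_ids`.
#' @seealso [to_cube()], [read_long_csv()], [filter_features()]
#' @export
long_table <- function(X, subject, group, time, unit = NULL,
                       variable_ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("feature matrix `X` must be numeric", call. = FALSE)
  n <- nrow(X)
  if (length(subject) != n || length(group) != n || length(time) != n)
    stop("metadata vectors must match nrow(X)", call. = FALSE)
  if (is.null(unit)) unit <- subject
  if (length(unit) != n) stop("`unit` must match nrow(X)", call. = FALSE)
  time <- as.numeric(time)
  if (anyNA(time)) stop("`time` must be numeric and non-missing", call. = FALSE)
  group <- as_group_factor(group)
  if (is.null(variable_ids)) {
    variable_ids <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  }
  if (length(variable_ids) != ncol(X))
    stop("`variable_ids` must have one entry per column of X", call. = FALSE)
  colnames(X) <- variable_ids
  tbl <- structure(
    list(X = X,
         samples = data.frame(subject = as.character(subject),
                              group = group,
                              time = time,
                              unit = as.character(unit),
                              stringsAsFactors = FALSE),
         variable_ids = as.character(variable_ids)),
    class = "long_table")
  validate_long_table(tbl)
  tbl
}

as_group_factor <- function(group) {
  if (is.factor(group)) {
    lev <- levels(droplevels(group))
  } else {
    lev <- sort(unique(as.character(group)))
  }
  if (all(c("control", "intervention") %in% lev))
    lev <- c("control", "intervention", setdiff(lev, c("control", "intervention")))
  factor(as.character(group), levels = lev)
}

validate_long_table <- function(tbl) {
  s <- tbl$samples
  key <- paste(s$unit, s$time, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("design error: duplicate sample for unit '%s' at time %g",
                 s$unit[i], s$time[i]), call. = FALSE)
  }
  times <- sort(unique(s$time))
  by_unit <- split(s$time, s$unit)
  for (u in names(by_unit)) {
    if (!identical(sort(by_unit[[u]]), times))
      stop(sprintf(paste0("design error: unit '%s' does not cover the full ",
                          "time grid {%s}"), u, paste(times, collapse = ", ")),
           call. = FALSE)
  }
  gr <- vapply(split(as.character(s$group), s$unit),
               function(g) length(unique(g)), integer(1L))
  if (any(gr != 1L))
    stop(sprintf("design error: group label varies within unit '%s'",
                 names(gr)[gr != 1L][1L]), call. = FALSE)
  invisible(tbl)
}

#' @export
print.long_table <- function(x, ...) {
  s <- x$samples
  cat(sprintf("long_table: %d samples x %d variables\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  units: %d  time points: %s\n", length(unique(s$unit)),
              paste(sort(unique(s$time)), collapse = ", ")))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (%d units)", levels(s$group),
                            tabulate(s$group[!duplicated(s$unit)],
                                     nbins = nlevels(s$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Dimensions of a long table
#'
#' @param tbl a [long_table()].
#' @return Named list with `n_units`, `n_times`, `n_variables`, `n_samples`.
#' @export
table_dims <- function(tbl) {
  stopifnot(inherits(tbl, "long_table"))
  list(n_units = length(unique(tbl$samples$unit)),
       n_times = length(unique(tbl$samples$time)),
       n_variables = ncol(tbl$X),
       n_samples = nrow(tbl$X))
}

#' Read a long-format feature CSV
#'
#' Reads a feature table exported from peak-picking software: one header row,
#' metadata columns for subject, group and time (names configurable through
#' `schema`), all remaining columns numeric feature intensities.
#'
#' @param path path to a CSV file.
#' @param schema named list mapping the roles `subject`, `group`, `time` and
#'   (optionally) `unit` to column names in the file.
#' @return A [long_table()].
#' @export
read_long_csv <- function(path,
                          schema = list(subject = "subject", group = "group",
                                        time = "time", unit = "unit")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject", "group", "time")
  for (role in need) {
    cn <- schema[[role]]
    if (is.null(cn) || !cn %in% names(df))
      stop(sprintf("schema error: no '%s' column ('%s') in %s",
                   role, schema[[role]] %||% "?", path), call. = FALSE)
  }
  unit_col <- schema[["unit"]]
  meta_cols <- c(schema$subject, schema$group, schema$time,
                 if (!is.null(unit_col) && unit_col %in% names(df)) unit_col)
  Xdf <- df[setdiff(names(df), meta_cols)]
  if (!all(vapply(Xdf, is.numeric, logical(1L))))
    stop("schema error: non-numeric feature columns present", call. = FALSE)
  X <- as.matrix(Xdf)
  unit <- if (!is.null(unit_col) && unit_col %in% names(df)) df[[unit_col]] else NULL
  tbl <- long_table(X, subject = df[[schema$subject]], group = df[[schema$group]],
                    time = df[[schema$time]], unit = unit)
  cst <- which(apply(tbl$X, 2L, function(v) length(unique(v)) == 1L))
  if (length(cst))
    message(sprintf("note: %d all-constant variable(s) retained: %s",
                    length(cst),
                    paste(utils::head(tbl$variable_ids[cst], 5L), collapse = ", ")))
  tbl
}

#' Write a long table to CSV
#'
#' @param tbl a [long_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(tbl, path) {
  stopifnot(inherits(tbl, "long_table"))
  df <- cbind(tbl$samples[c("subject", "group", "time", "unit")],
              as.data.frame(tbl$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Reshape a long table into a three-way data cube
#'
#' Stacks the per-sample rows into a units x variables x time array so that
#' trilinear (N-PLS) models can exploit the within-subject correlation between
#' time points. Units are ordered by sorted identifier and times ascending,
#' so the cube is invariant to the row order of the input.
#'
#' @param tbl a complete-design [long_table()].
#' @return An object of class `data_cube`: list with `X3` (S' x J x T array),
#'   `unit_ids`, `variable_ids`, `times`, `group` (length-S' factor) and
#'   `subjects`.
#' @export
to_cube <- function(tbl) {
  stopifnot(inherits(tbl, "long_table"))
  validate_long_table(tbl)
  s <- tbl$samples
  unit_ids <- sort(unique(s$unit))
  times <- sort(unique(s$time))
  Sn <- length(unit_ids); Tn <- length(times); J <- ncol(tbl$X)
  X3 <- array(NA_real_, dim = c(Sn, J, Tn),
              dimnames = list(unit_ids, tbl$variable_ids, times))
  si <- match(s$unit, unit_ids)
  ti <- match(s$time, times)
  for (r in seq_len(nrow(tbl$X))) X3[si[r], , ti[r]] <- tbl$X[r, ]
  first <- !duplicated(s$unit)
  ord <- match(unit_ids, s$unit[first])
  structure(list(X3 = X3,
                 unit_ids = unit_ids,
                 variable_ids = tbl$variable_ids,
                 times = times,
                 group = s$group[first][ord],
                 subjects = s$subject[first][ord]),
            class = "data_cube")
}

#' @export
print.data_cube <- function(x, ...) {
  d <- dim(x$X3)
  cat(sprintf("data_cube: %d units x %d variables x %d time points\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Flatten a data cube back into a long table
#'
#' Inverse of [to_cube()] up to row order (rows come back sorted by unit,
#' then time).
#'
#' @param cube a `data_cube`.
#' @return A [long_table()].
#' @export
from_cube <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  d <- dim(cube$X3)
  Sn <- d[1L]; J <- d[2L]; Tn <- d[3L]
  X <- matrix(NA_real_, Sn * Tn, J)
  subject <- character(Sn * Tn); unit <- character(Sn * Tn)
  group <- character(Sn * Tn); time <- numeric(Sn * Tn)
  r <- 0L
  for (si in seq_len(Sn)) for (ti in seq_len(Tn)) {
    r <- r + 1L
    X[r, ] <- cube$X3[si, , ti]
    subject[r] <- cube$subjects[si]
    unit[r] <- cube$unit_ids[si]
    group[r] <- as.character(cube$group[si])
    time[r] <- cube$times[ti]
  }
  long_table(X, subject = subject, group = group, time = time, unit = unit,
             variable_ids = cube$variable_ids)
}

#' Feature-reduction filters for real LC-MS tables
#'
#' Removes unreliable variables before modelling: variables not detected in at
#' least `detection_floor` of the samples of every subgroup (group x time
#' cell), variables whose coefficient of variation in pooled quality-control
#' samples exceeds `cv_max`, and any pre-supplied exclusion list (e.g. features
#' at extreme retention times). Detection means a strictly positive,
#' non-missing intensity.
#'
#' @param tbl a [long_table()].
#' @param qc optional matrix of QC-sample intensities (rows = QC injections,
#'   columns matching `tbl`'s variables).
#' @param detection_floor minimum detected fraction per subgroup (default 0.7).
#' @param cv_max maximum QC coefficient of variation sd/mean (default 0.7).
#' @param exclude optional character vector of variable ids to drop outright.
#' @return List with `table` (filtered [long_table()]) and `removed`
#'   (data.frame of variable id / reason).
#' @export
filter_features <- function(tbl, qc = NULL, detection_floor = 0.7,
                            cv_max = 0.7, exclude = NULL) {
  stopifnot(inherits(tbl, "long_table"))
  J <- ncol(tbl$X)
  if (!is.null(qc)) {
    qc <- as.matrix(qc)
    if (ncol(qc) != J)
      stop("dimension error: `qc` must have one column per variable", call. = FALSE)
  }
  reason <- rep(NA_character_, J)
  sub <- interaction(tbl$samples$group, tbl$samples$time, drop = TRUE)
  det <- matrix(1, nlevels(sub), J)
  for (k in seq_len(nlevels(sub))) {
    rows <- sub == levels(sub)[k]
    Xi <- tbl$X[rows, , drop = FALSE]
    det[k, ] <- colMeans(!is.na(Xi) & Xi > 0)
  }
  low <- apply(det, 2L, min) < detection_floor
  reason[low] <- "low_detection"
  if (!is.null(qc)) {
    cv <- apply(qc, 2L, function(v) stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
    bad_cv <- is.na(reason) & (is.na(cv) | cv > cv_max)
    reason[bad_cv] <- "qc_cv"
  }
  if (!is.null(exclude)) {
    reason[is.na(reason) & tbl$variable_ids %in% exclude] <- "excluded"
  }
  keep <- is.na(reason)
  removed <- data.frame(variable_id = tbl$variable_ids[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- tbl
  out$X <- tbl$X[, keep, drop = FALSE]
  out$variable_ids <- tbl$variable_ids[keep]
  list(table = out, removed = removed)
}
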