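#' Per-trial weights equalizing subjects with unequal trial counts
#'
#' Repeated-trials cohorts pool all trials of all subjects into one row set,
#' so subjects who recorded more trials would dominate any statistic computed
#' across rows. Each trial of a subject with `q_S` recorded trials receives
#' the factor `tau = 1/q_S`; normalizing the factors to unit sum gives the
#' row weights used by the weighted correlation matrix. Every subject then
#' carries identical total weight `1/(number of subjects)` regardless of how
#' many trials it contributed.
#'
#' @param subject character or factor vector, one entry per trial row, giving
#'   the subject that recorded the trial.
#' @return An object of class `trial_weights`: a list with components
#'   `tau` (per-trial factor `1/q_S`) and `w` (normalized weights summing
#'   to 1), both aligned to the input rows.
#' @examples
#' w <- compute_trial_weights(c("A", "A", "B"))
#' w$tau  # 0.5 0.5 1.0
#' w$w    # 0.25 0.25 0.50
#' @export
compute_trial_weights <- function(subject) {
  subject <- as.character(subject)
  if (length(subject) == 0L) {
    stop("cannot compute trial weights for an empty trial list")
  }
  q <- table(subject)
  tau <- 1 / as.numeric(q[subject])
  w <- tau / sum(tau)
  structure(list(tau = tau, w = w), class = "trial_weights")
}

#' Resample a raw time series onto a uniform phase grid
#'
#' Time-normalizes one trial's raw recording to a fixed number of phase
#' points spanning the recorded interval (for landing-phase waveforms, 0%
#' at initial foot strike through 100% at peak knee flexion). Interpolation
#' is piecewise linear: monotone, shape preserving, endpoints reproduced
#' exactly.
#'
#' @param time numeric vector of strictly increasing sample times.
#' @param value numeric vector of samples, same length as `time`.
#' @param p_out number of output phase points (default 101, i.e. 0%..100%
#'   in 1% steps).
#' @return Numeric vector of length `p_out`.
#' @export
time_normalize <- function(time, value, p_out = 101L) {
  if (length(time) != length(value)) {
    stop("time and value must have the same length")
  }
  if (length(time) < 2L) {
    stop("time normalization needs at least 2 samples")
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing")
  }
  if (anyNA(time) || anyNA(value)) {
    stop("time normalization does not accept missing values")
  }
  grid <- seq(time[1L], time[length(time)], length.out = p_out)
  out <- stats::approx(time, value, xout = grid, method = "linear",
                       ties = "ordered")$y
  # guard against floating-point drift at the grid ends
  out[1L] <- value[1L]
  out[p_out] <- value[length(value)]
  out
}

#' Assemble a two-group waveform cohort from per-variable trial matrices
#'
#' The central container of the pipeline: one `n x p` matrix per
#' biomechanical variable (rows = pooled trials of both groups, columns =
#' phase samples), a shared trial metadata table, and the trial weights.
#' All variables must agree on `n` and on row order; every trial of a
#' subject must carry the same group label.
#'
#' @param variables named list of numeric matrices, all `n x p`, rows
#'   aligned across variables.
#' @param trial_meta data.frame with columns `subject`, `group`, `trial`
#'   (one row per trial, aligned to matrix rows). `group` must take exactly
#'   the two values given by `case_label` / `control_label` (a single-group
#'   cohort is rejected).
#' @param case_label,control_label the group labels; `case_label` is the
#'   clinical group (e.g. ACL-reconstructed) reported first in comparisons.
#' @return Object of class `waveform_cohort`: list with `variables`,
#'   `trial_meta` (group recoded to a factor with levels case, control),
#'   `weights` (see [compute_trial_weights()]), `n`, `n_case`, `n_control`,
#'   `p`.
#' @export
waveform_cohort <- function(variables, trial_meta,
                            case_label = "case", control_label = "control") {
  if (!is.list(variables) || length(variables) == 0L ||
      is.null(names(variables)) || any(!nzchar(names(variables)))) {
    stop("variables must be a non-empty named list of matrices")
  }
  need <- c("subject", "group", "trial")
  if (!all(need %in% names(trial_meta))) {
    stop("trial_meta needs columns subject, group, trial")
  }
  n <- nrow(trial_meta)
  p <- ncol(variables[[1L]])
  for (nm in names(variables)) {
    X <- variables[[nm]]
    if (!is.matrix(X) || !is.numeric(X)) {
      stop("variable '", nm, "' is not a numeric matrix")
    }
    if (nrow(X) != n || ncol(X) != p) {
      stop("variable '", nm, "' has dimensions ", nrow(X), "x", ncol(X),
           " but the cohort requires ", n, "x", p)
    }
    if (anyNA(X)) stop("variable '", nm, "' contains missing values")
  }
  grp <- as.character(trial_meta$group)
  if (!all(grp %in% c(case_label, control_label))) {
    stop("group labels must all be '", case_label, "' or '",
         control_label, "'")
  }
  sub <- as.character(trial_meta$subject)
  mixed <- tapply(grp, sub, function(g) length(unique(g)) > 1L)
  if (any(mixed)) {
    stop("subject(s) ", paste(names(mixed)[mixed], collapse = ", "),
         " appear in both groups")
  }
  group <- factor(ifelse(grp == case_label, "case", "control"),
                  levels = c("case", "control"))
  if (any(tabulate(group, 2L) == 0L)) {
    stop("cohort must contain trials from both groups")
  }
  meta <- data.frame(subject = sub,
                     group = group,
                     trial = as.character(trial_meta$trial),
                     stringsAsFactors = FALSE)
  structure(list(variables = variables,
                 trial_meta = meta,
                 weights = compute_trial_weights(sub),
                 n = n,
                 n_case = sum(group == "case"),
                 n_control = sum(group == "control"),
                 p = p),
            class = "waveform_cohort")
}

#' @export
print.waveform_cohort <- function(x, ...) {
  cat("waveform_cohort:", x$n, "trials (", x$n_case, "case /", x$n_control,
      "control ),", length(unique(x$trial_meta$subject)), "subjects,",
      length(x$variables), "variables x", x$p, "phase points\n")
  invisible(x)
}

#' Read a long-format waveform cohort from delimited text
#'
#' Expects one row per (subject, trial, variable, phase sample) with a
#' numeric value column. Column names are remapped through `schema`, so any
#' header can be accommodated. If the file carries raw time instead of a
#' phase percentage, name the column in `schema$time` and every
#' (trial, variable) series is time-normalized to `p` points; with
#' `schema$phase` the file must already contain a complete uniform grid of
#' `p` phase values per trial and variable.
#'
#' @param path CSV file path.
#' @param schema named list mapping the roles `subject`, `group`, `trial`,
#'   `variable`, `value` and one of `phase` / `time` to column names in the
#'   file.
#' @param p number of phase points per trial (101 by default).
#' @param case_label,control_label values of the group column identifying
#'   the case (e.g. ACL-reconstructed) and control trials.
#' @return A [waveform_cohort()].
#' @export
load_cohort <- function(path,
                        schema = list(subject = "subject", group = "group",
                                      trial = "trial", variable = "variable",
                                      phase = "phase_pct", value = "value"),
                        p = 101L,
                        case_label = "case", control_label = "control") {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  roles <- c("subject", "group", "trial", "variable", "value")
  axis <- if (!is.null(schema$phase)) "phase" else "time"
  if (is.null(schema[[axis]])) {
    stop("schema must name a 'phase' or 'time' column")
  }
  cols <- unlist(schema[c(roles, axis)])
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols)) {
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  val <- dat[[schema$value]]
  if (!is.numeric(val)) {
    suppressWarnings(val <- as.numeric(val))
    if (anyNA(val)) stop("non-numeric entries in value column '",
                         schema$value, "'")
  }
  ax <- dat[[schema[[axis]]]]
  if (!is.numeric(ax)) {
    suppressWarnings(ax <- as.numeric(ax))
    if (anyNA(ax)) stop("non-numeric entries in column '", schema[[axis]], "'")
  }
  key <- data.frame(subject = as.character(dat[[schema$subject]]),
                    group = as.character(dat[[schema$group]]),
                    trial = as.character(dat[[schema$trial]]),
                    variable = as.character(dat[[schema$variable]]),
                    axis = ax, value = val,
                    stringsAsFactors = FALSE)
  key <- key[order(key$subject, key$trial, key$variable, key$axis), ]
  trial_key <- paste(key$subject, key$trial, sep = "\r")
  trials <- unique(trial_key)
  vars <- sort(unique(key$variable))

  split_tv <- split(key, list(factor(trial_key, levels = trials),
                              factor(key$variable, levels = vars)),
                    sep = "\r")
  variables <- vector("list", length(vars))
  names(variables) <- vars
  for (v in vars) {
    rows <- matrix(NA_real_, nrow = length(trials), ncol = p)
    for (i in seq_along(trials)) {
      piece <- split_tv[[paste(trials[i], v, sep = "\r")]]
      if (is.null(piece) || nrow(piece) == 0L) {
        stop("trial '", trials[i], "' has no samples for variable '", v, "'")
      }
      if (axis == "phase") {
        if (nrow(piece) != p) {
          stop("trial '", sub("\r", "/", trials[i]), "' variable '", v,
               "' has ", nrow(piece), " phase samples; expected ", p)
        }
        rows[i, ] <- piece$value[order(piece$axis)]
      } else {
        rows[i, ] <- time_normalize(piece$axis, piece$value, p_out = p)
      }
    }
    variables[[v]] <- rows
  }
  first_rows <- match(trials, trial_key)
  trial_meta <- data.frame(subject = key$subject[first_rows],
                           group = key$group[first_rows],
                           trial = key$trial[first_rows],
                           stringsAsFactors = FALSE)
  waveform_cohort(variables, trial_meta,
                  case_label = case_label, control_label = control_label)
}

#' Write a cohort as long-format CSV
#'
#' Inverse of [load_cohort()]: columns `subject, group, trial, variable,
#' phase_pct, value`, phase running 0..100 over the `p` samples.
#'
#' @param cohort a [waveform_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "waveform_cohort"))
  p <- cohort$p
  phase <- seq(0, 100, length.out = p)
  meta <- cohort$trial_meta
  pieces <- lapply(names(cohort$variables), function(v) {
    X <- cohort$variables[[v]]
    data.frame(subject = rep(meta$subject, each = p),
               group = rep(as.character(meta$group), each = p),
               trial = rep(meta$trial, each = p),
               variable = v,
               phase_pct = rep(phase, times = nrow(X)),
               value = as.vector(t(X)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
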