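#' Linguistic-label sequence of a gene
#'
#' Discretizes a series through the model's fuzzy partition of one
#' variable: the label at each time point is the index (in ascending
#' order of center, so higher labels mean higher expression) of the fuzzy
#' set with maximal membership for the value, ties breaking to the lower
#' index.  Memberships are computed directly from the values
#' (recurrence-free), so labels are a property of the data and the
#' partition, not of network history.
#'
#' @param model a trained [enfrn_model()].
#' @param series numeric vector of expression values over time.
#' @param variable an input index, an input gene name, or \code{"output"}.
#' @return Integer vector of labels (1 = lowest-expression set).
#' @export
label_sequence <- function(model, series, variable = "output") {
  if (identical(variable, "output") ||
      identical(variable, model$output_name)) {
    centers <- model$out_center
    widths <- model$out_width
  } else {
    v <- if (is.character(variable)) match(variable, model$input_names)
         else as.integer(variable)
    if (is.na(v) || v < 1 || v > length(model$input_names))
      stop("unknown variable: ", variable)
    idx <- which(model$set_var == v)
    centers <- model$set_center[idx]
    widths <- model$set_width[idx]
  }
  if (length(centers) == 0) stop("variable has no fuzzy sets")
  ord <- order(centers)
  centers <- centers[ord]
  widths <- widths[ord]
  m <- outer(series, seq_along(centers),
             function(s, j) gaussian_membership(s, centers[j], widths[j]))
  max.col(m, ties.method = "first")
}

#' Simultaneous input-change indicator
#'
#' For a transition t (between time points t and t+1), returns 1 iff
#' every regulator's label changed across that transition.  With several
#' regulators a change must be simultaneous in all of them, since the
#' rule layer joins the inputs by a fuzzy AND.
#'
#' @param labels_in list of integer label sequences, one per regulator.
#' @param t transition index, 1 <= t <= T-1.
#' @return 0 or 1.
#' @export
input_change_indicator <- function(labels_in, t) {
  if (!is.list(labels_in)) labels_in <- list(labels_in)
  len <- length(labels_in[[1]])
  if (t < 1 || t > len - 1) stop("transition index out of range")
  as.integer(all(vapply(labels_in, function(l) l[t + 1] != l[t], logical(1))))
}

#' Lag-1 regulation score
#'
#' Scores how consistently the target's expression label moves after the
#' regulators' labels change, under a first-order Markov assumption: an
#' input-label change across transition t is paired with the output-label
#' change across the next transition t+1.  Each qualifying input change
#' contributes the coupling sign — the direction of the input change
#' times the direction of the following output change (+1 when they
#' move together, -1 when they move oppositely) — and the sum is
#' normalized by \eqn{N_{IC}}, the number of qualifying input changes
#' (those with an existing next output transition, i.e. transitions
#' 1..T-2).  The score lies in [-1, 1]; +1 means every input alteration
#' evidenced up-regulation (co-movement), -1 down-regulation
#' (anti-movement), 0 an even mix (unstable regulation).  With several
#' regulators the joint input direction is the majority direction of the
#' simultaneous changes (0, contributing nothing, when they balance).
#' With no qualifying input change the score is undefined (\code{NA}):
#' without a prior input alteration no regulation can be deduced.
#'
#' @param labels_in list of regulator label sequences (or one vector).
#' @param labels_out target label sequence of the same length (>= 3).
#' @return List with \code{rs_raw} (possibly \code{NA}) and \code{n_ic}.
#' @export
regulation_score <- function(labels_in, labels_out) {
  if (!is.list(labels_in)) labels_in <- list(labels_in)
  t_n <- length(labels_out)
  if (any(vapply(labels_in, length, integer(1)) != t_n))
    stop("label sequences have different lengths")
  if (t_n < 3) stop("at least 3 time points are required")
  changed <- rep(TRUE, t_n - 1)
  in_dir <- rep(0, t_n - 1)
  for (l in labels_in) {
    d <- diff(l)
    changed <- changed & (d != 0)
    in_dir <- in_dir + sign(d)
  }
  ic <- changed[seq_len(t_n - 2)]
  n_ic <- sum(ic)
  if (n_ic == 0) return(list(rs_raw = NA_real_, n_ic = 0L))
  out_sign <- sign(diff(labels_out))[2:(t_n - 1)]
  coupling <- sign(in_dir[seq_len(t_n - 2)]) * out_sign
  list(rs_raw = sum(coupling[ic]) / n_ic, n_ic = as.integer(n_ic))
}

#' Regulation type from a score
#'
#' Positive scores mean up-regulation (activation), negative scores
#' down-regulation (repression); zero or undefined scores give no
#' deducible regulation.
#'
#' @param rs_raw regulation score in [-1, 1], or \code{NA}.
#' @return One of \code{"up"}, \code{"down"}, \code{"none"}.
#' @export
regulation_type <- function(rs_raw) {
  if (is.na(rs_raw) || rs_raw == 0) "none"
  else if (rs_raw > 0) "up"
  else "down"
}

#' Composite confidence score
#'
#' Blends model accuracy and regulation consistency:
#' \eqn{CS = n \cdot RMSE + (1-n)(1 - |RS|)}, with weight n = 0.6 on the
#' error term by default.  Lower is better; 0 is an ideal regulator
#' (perfect prediction, perfectly consistent regulation).  The score can
#' exceed 1 when the model error does.  An undefined regulation score
#' contributes its worst value (inconsistency 1).
#'
#' @param model_error non-negative model error (RMSE on [0,1]-normalized
#'   expression).
#' @param rs_raw regulation score in [-1, 1], or \code{NA} if undefined.
#' @param n weight on the error term, in [0, 1].
#' @return Non-negative composite score.
#' @export
composite_score <- function(model_error, rs_raw, n = 0.6) {
  if (n < 0 || n > 1) stop("weight n must lie in [0, 1]")
  if (model_error < 0) stop("model_error must be non-negative")
  consistency <- if (is.na(rs_raw)) 0 else abs(rs_raw)
  n * model_error + (1 - n) * (1 - consistency)
}

#' Score the regulation a trained model implies
#'
#' Computes the full per-(regulator set, target) result: the model's
#' one-step-ahead RMSE on the series, the lag-1 regulation score over the
#' label sequences of regulators and target, the regulation type, and the
#' composite score.
#'
#' @param model a trained [enfrn_model()].
#' @param x numeric matrix (time points x regulators) of regulator
#'   expression.
#' @param y numeric vector of target expression.
#' @param n composite-score weight on the error term.
#' @return A list of class \code{regulation_result} with elements
#'   \code{regulators}, \code{target}, \code{rs_raw}, \code{n_ic},
#'   \code{rs_inconsistency}, \code{regulation_type}, \code{model_error},
#'   \code{composite_score}.
#' @export
score_regulation <- function(model, x, y, n = 0.6) {
  x <- as.matrix(x)
  err <- model_rmse(model, x, y)
  labels_in <- lapply(seq_along(model$input_names),
                      function(v) label_sequence(model, x[, v], v))
  labels_out <- label_sequence(model, y, "output")
  rs <- regulation_score(labels_in, labels_out)
  structure(list(
    regulators = model$input_names,
    target = model$output_name,
    rs_raw = rs$rs_raw,
    n_ic = rs$n_ic,
    rs_inconsistency = if (is.na(rs$rs_raw)) 1 else 1 - abs(rs$rs_raw),
    regulation_type = regulation_type(rs$rs_raw),
    model_error = err,
    composite_score = composite_score(err, rs$rs_raw, n)
  ), class = "regulation_result")
}

#' @export
print.regulation_result <- function(x, ...) {
  cat(paste(x$regulators, collapse = ","), "->", x$target,
      sprintf("[%s]  RS=%s  RMSE=%.4f  CS=%.4f\n", x$regulation_type,
              ifelse(is.na(x$rs_raw), "NA", sprintf("%.3f", x$rs_raw)),
              x$model_error, x$composite_score))
  invisible(x)
}
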