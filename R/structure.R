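#' Configuration for self-organized structure learning
#'
#' Phase 1 grows the rule base online: a streamed pattern spawns a new
#' rule (a new cluster in the input space) when it is both poorly
#' predicted and far from every existing cluster.  The defaults are
#' calibrated so that cell-cycle-like series of roughly two dozen points
#' produce structures on the order of ten rules, which the later pruning
#' phase then simplifies.
#'
#' @param error_threshold prediction-error level (on [0,1]-normalized
#'   expression) above which a pattern counts as poorly handled.
#' @param firing_threshold firing strength below which a pattern counts as
#'   far from every existing rule; in (0, 1).
#' @param overlap_delta cluster-overlap constant: a freshly created fuzzy
#'   set gets width \code{overlap_delta} times the distance to its nearest
#'   neighbour in that dimension.
#' @param similarity_threshold fuzzy sets of the same input variable whose
#'   similarity exceeds this are merged; in (0, 1).
#' @param max_rules hard cap on the number of rules created.
#' @return A list of class \code{structure_config}.
#' @export
structure_config <- function(error_threshold = 0.1, firing_threshold = 0.8,
                             overlap_delta = 0.25, similarity_threshold = 0.8,
                             max_rules = 30L) {
  stopifnot(error_threshold > 0, overlap_delta > 0,
            firing_threshold > 0, firing_threshold < 1,
            similarity_threshold > 0, similarity_threshold < 1,
            max_rules >= 1)
  structure(list(error_threshold = error_threshold,
                 firing_threshold = firing_threshold,
                 overlap_delta = overlap_delta,
                 similarity_threshold = similarity_threshold,
                 max_rules = as.integer(max_rules)),
            class = "structure_config")
}

#' Prediction error of one pattern
#'
#' Absolute difference between the network prediction and the observed
#' target value (a signed difference could not be compared against the
#' positive error threshold).
#'
#' @param y_pred predicted value.
#' @param y_obs observed value.
#' @return Non-negative error.
#' @export
prediction_error <- function(y_pred, y_obs) abs(y_pred - y_obs)

#' Rule closest to an input pattern
#'
#' Returns the rule with maximal firing strength for \code{x} (firing
#' strength is the monotone inverse of the Mahalanobis distance to the
#' rule's center, so maximal firing is minimal distance).  Ties break to
#' the lowest rule index.  Evaluated recurrence-free (zero state) unless a
#' state vector is supplied.
#'
#' @param model an [enfrn_model()] with at least one rule.
#' @param x input vector.
#' @param state optional recurrent state (defaults to zeros).
#' @return List with \code{index} and \code{strength}.
#' @export
nearest_rule <- function(model, x, state = NULL) {
  if (n_rules(model) == 0) stop("model has no rules")
  if (is.null(state)) state <- numeric(length(model$set_var))
  psi <- layer2_memberships(model, x, state)
  firing <- vapply(seq_len(n_rules(model)),
                   function(r) prod(psi[model$rule_pre[r, ]]), numeric(1))
  i <- which.max(firing)
  list(index = i, strength = firing[i])
}

#' Rule-creation criterion
#'
#' A new rule is created iff the pattern is poorly predicted (error above
#' the threshold) AND not close enough to any existing cluster to join it
#' (maximal firing below the threshold).
#'
#' @param e_k prediction error of the pattern.
#' @param max_firing firing strength of the nearest rule.
#' @param config a [structure_config()].
#' @return Logical.
#' @export
should_create_rule <- function(e_k, max_firing, config) {
  e_k > config$error_threshold && max_firing < config$firing_threshold
}

#' Similarity of two Gaussian fuzzy sets
#'
#' Jaccard-style similarity \eqn{|A \cap B| / (|A| + |B| - |A \cap B|)}
#' for bell-shaped membership functions.  The area of a Gaussian of width
#' \eqn{\sigma} is \eqn{\sigma\sqrt{\pi}}; the intersection area
#' \eqn{\int \min(\mu_A, \mu_B)} is computed in closed form by locating
#' the (at most two) crossing points of the two curves and integrating the
#' lower curve piecewise via the error function.  Symmetric; equals 1 iff
#' the sets coincide.
#'
#' @param a,b fuzzy sets as lists with elements \code{center} and
#'   \code{width}.
#' @return Similarity in [0, 1].
#' @export
fuzzy_set_similarity <- function(a, b) {
  ca <- a$center; wa <- a$width; cb <- b$center; wb <- b$width
  if (wa <= 0 || wb <= 0) stop("invalid model: non-positive width")
  if (ca == cb && wa == wb) return(1)
  # integral of exp(-((x-c)/w)^2) over (l, u)
  gint <- function(c, w, l, u) {
    erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
    w * sqrt(pi) / 2 * (erf((u - c) / w) - erf((l - c) / w))
  }
  # crossing points: ((x-ca)/wa)^2 == ((x-cb)/wb)^2 is two linear equations
  xs <- (ca * wb + cb * wa) / (wa + wb)
  if (wa != wb) xs <- c(xs, (ca * wb - cb * wa) / (wb - wa))
  xs <- sort(xs[is.finite(xs)])
  bounds <- c(-Inf, xs, Inf)
  overlap <- 0
  for (i in seq_len(length(bounds) - 1)) {
    l <- bounds[i]; u <- bounds[i + 1]
    # probe which curve is lower on this interval
    p <- if (is.infinite(l) && is.infinite(u)) (ca + cb) / 2
         else if (is.infinite(l)) u - 1
         else if (is.infinite(u)) l + 1
         else (l + u) / 2
    lower_a <- gaussian_membership(p, ca, wa) <= gaussian_membership(p, cb, wb)
    overlap <- overlap + if (lower_a) gint(ca, wa, l, u) else gint(cb, wb, l, u)
  }
  area <- sqrt(pi) * (wa + wb)
  un <- area - overlap
  if (un <= 0) 1 else min(1, overlap / un)
}

# merge set j2 into j1 within a model: mean center, max width (coverage
# never shrinks), mean feedback weight; rules re-pointed
merge_two_sets <- function(model, j1, j2) {
  model$set_center[j1] <- mean(model$set_center[c(j1, j2)])
  model$set_width[j1] <- max(model$set_width[c(j1, j2)])
  model$feedback[j1] <- mean(model$feedback[c(j1, j2)])
  model$rule_pre[model$rule_pre == j2] <- j1
  keep <- setdiff(seq_along(model$set_var), j2)
  remap <- integer(length(model$set_var))
  remap[keep] <- seq_along(keep)
  model$set_var <- model$set_var[keep]
  model$set_center <- model$set_center[keep]
  model$set_width <- model$set_width[keep]
  model$feedback <- model$feedback[keep]
  model$state <- model$state[keep]
  model$rule_pre <- matrix(remap[model$rule_pre], nrow = nrow(model$rule_pre))
  model
}

#' Merge redundant fuzzy sets
#'
#' Within each input dimension, repeatedly replaces any pair of sets whose
#' similarity exceeds the threshold by a single set (center = mean of the
#' centers, width = max of the widths) and re-points all rule
#' preconditions, until no pair exceeds the threshold.  Never changes the
#' number of rules.
#'
#' @param model an [enfrn_model()].
#' @param threshold similarity above which two sets are merged.
#' @return The updated model.
#' @export
merge_similar_sets <- function(model, threshold) {
  repeat {
    merged <- FALSE
    for (v in seq_along(model$input_names)) {
      idx <- which(model$set_var == v)
      if (length(idx) < 2) next
      for (i in seq_len(length(idx) - 1)) {
        for (j in seq(i + 1, length(idx))) {
          a <- list(center = model$set_center[idx[i]],
                    width = model$set_width[idx[i]])
          b <- list(center = model$set_center[idx[j]],
                    width = model$set_width[idx[j]])
          if (fuzzy_set_similarity(a, b) > threshold) {
            model <- merge_two_sets(model, idx[i], idx[j])
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  model
}

#' Assign (or create) the output cluster for a new rule
#'
#' The creation of an input-space cluster does not force a new output
#' cluster: if the target value is well covered by an existing output
#' node, the new rule is routed to that node.  A new output node (center =
#' y) is created when none exists, or when the pattern's error exceeds the
#' error threshold and y's membership in every existing output set falls
#' below the firing threshold; its width is \code{overlap_delta} times the
#' distance to the nearest output center (the first node uses the span of
#' the output variable).
#'
#' @param model an [enfrn_model()].
#' @param y target value of the pattern.
#' @param e_k prediction error of the pattern.
#' @param config a [structure_config()].
#' @param output_span observed span of the output variable (used only for
#'   the first node's width).
#' @return List with the updated \code{model} and the output-node
#'   \code{index} the new rule should use.
#' @export
assign_output_cluster <- function(model, y, e_k, config, output_span = 1) {
  n_out <- length(model$out_center)
  if (n_out == 0) {
    model$out_center <- y
    model$out_width <- max(config$overlap_delta * output_span, SIGMA_MIN)
    return(list(model = model, index = 1L))
  }
  memb <- gaussian_membership(y, model$out_center, model$out_width)
  nearest <- which.min(abs(y - model$out_center))
  if (e_k > config$error_threshold && max(memb) < config$firing_threshold) {
    d <- abs(y - model$out_center[nearest])
    model$out_center <- c(model$out_center, y)
    model$out_width <- c(model$out_width,
                         max(config$overlap_delta * d, SIGMA_MIN))
    list(model = model, index = n_out + 1L)
  } else {
    list(model = model, index = as.integer(nearest))
  }
}

#' Create a rule (input cluster) for a pattern
#'
#' Adds one fuzzy set per input dimension, centered at the pattern with
#' width \code{overlap_delta} times the distance to the nearest existing
#' center in that dimension (the very first set of a variable uses the
#' variable's observed span), a zero-initialized feedback weight per new
#' set, and a rule whose consequent is chosen by
#' [assign_output_cluster()].  Redundant sets are then merged per
#' [merge_similar_sets()].  Refuses (with a message) once \code{max_rules}
#' is reached.
#'
#' @param model an [enfrn_model()] (possibly empty of rules).
#' @param x input pattern.
#' @param y target value.
#' @param e_k prediction error of the pattern (drives output-cluster
#'   creation); use \code{Inf} when bootstrapping an empty model.
#' @param config a [structure_config()].
#' @param input_spans observed span of each input variable.
#' @param output_span observed span of the output variable.
#' @return The updated model.
#' @export
create_rule <- function(model, x, y, e_k, config,
                        input_spans = rep(1, length(x)), output_span = 1) {
  if (n_rules(model) >= config$max_rules) {
    message("rule cap (", config$max_rules, ") reached; pattern skipped")
    return(model)
  }
  k <- length(model$input_names)
  stopifnot(length(x) == k)
  new_idx <- integer(k)
  for (v in seq_len(k)) {
    existing <- which(model$set_var == v)
    w <- if (length(existing) == 0) {
      config$overlap_delta * input_spans[v]
    } else {
      config$overlap_delta * min(abs(x[v] - model$set_center[existing]))
    }
    model$set_var <- c(model$set_var, v)
    model$set_center <- c(model$set_center, x[v])
    model$set_width <- c(model$set_width, max(w, SIGMA_MIN))
    model$feedback <- c(model$feedback, 0)
    model$state <- c(model$state, 0)
    new_idx[v] <- length(model$set_var)
  }
  out <- assign_output_cluster(model, y, e_k, config, output_span)
  model <- out$model
  model$rule_pre <- rbind(model$rule_pre, new_idx)
  rownames(model$rule_pre) <- NULL
  model$rule_out <- c(model$rule_out, out$index)
  merge_similar_sets(model, config$similarity_threshold)
}

# empty model shell used to bootstrap phase 1
empty_model <- function(input_names, output_name) {
  structure(list(
    input_names = as.character(input_names),
    output_name = as.character(output_name),
    set_var = integer(0), set_center = numeric(0), set_width = numeric(0),
    feedback = numeric(0),
    rule_pre = matrix(integer(0), nrow = 0, ncol = length(input_names)),
    rule_out = integer(0), out_center = numeric(0), out_width = numeric(0),
    normalization = NULL, state = numeric(0)
  ), class = "enfrn_model")
}

# recompute the recurrent state after a structural change by replaying the
# series from scratch (series are short, so this is cheap and exact)
replay_state <- function(model, x_rows) {
  state <- numeric(length(model$set_var))
  for (q in seq_len(nrow(x_rows)))
    state <- layer2_memberships(model, x_rows[q, ], state)
  state
}

#' Phase 1: self-organized construction of the initial network
#'
#' Streams the lag-1 training patterns \eqn{(x(t), y(t+1))},
#' \eqn{t = 1..T-1}, once through the network, carrying the recurrent
#' state across patterns.  Each pattern is first predicted with the
#' current structure; if the prediction error exceeds the error threshold
#' and the pattern is far from every existing rule, a new rule (and
#' possibly a new output cluster) is created and redundant fuzzy sets are
#' merged.  Deterministic given the data and configuration; the rule count
#' is data-dependent.
#'
#' @param x numeric matrix (time points x regulators) of input expression,
#'   normalized to [0, 1].
#' @param y numeric vector of target expression over the same time points.
#' @param config a [structure_config()].
#' @param input_names,output_name gene identifiers (defaults derived from
#'   \code{x} column names).
#' @return An [enfrn_model()] with at least one rule; attribute
#'   \code{mean_error} holds the mean streaming prediction error and
#'   \code{degenerate} flags zero-variance input/output series.
#' @export
build_initial_structure <- function(x, y, config = structure_config(),
                                    input_names = NULL,
                                    output_name = "target") {
  x <- as.matrix(x)
  t_n <- nrow(x)
  if (t_n < 2) stop("at least 2 time points are required")
  if (length(y) != t_n) stop("input and output series lengths differ")
  if (is.null(input_names))
    input_names <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  spans <- apply(x, 2, function(v) diff(range(v)))
  yspan <- diff(range(y))
  degenerate <- any(spans == 0) || yspan == 0
  if (degenerate)
    warning("zero-variance input or output series; model may be degenerate")
  spans[spans == 0] <- 1
  if (yspan == 0) yspan <- 1

  model <- empty_model(input_names, output_name)
  state <- numeric(0)
  errs <- numeric(0)
  for (p in seq_len(t_n - 1)) {
    xp <- x[p, ]
    yp <- y[p + 1]
    mutated <- FALSE
    if (n_rules(model) == 0) {
      model <- create_rule(model, xp, yp, Inf, config, spans, yspan)
      mutated <- TRUE
    } else {
      psi <- layer2_memberships(model, xp, state)
      firing <- vapply(seq_len(n_rules(model)),
                       function(r) prod(psi[model$rule_pre[r, ]]),
                       numeric(1))
      act <- vapply(seq_along(model$out_center),
                    function(o) sum(firing[model$rule_out == o]),
                    numeric(1))
      den <- sum(model$out_width * act)
      y_pred <- if (den < DENOM_FLOOR)
        model$out_center[model$rule_out[which.max(firing)]]
      else
        sum(model$out_width * model$out_center * act) / den
      e_k <- prediction_error(y_pred, yp)
      errs <- c(errs, e_k)
      if (should_create_rule(e_k, max(firing), config) &&
          n_rules(model) < config$max_rules) {
        model <- create_rule(model, xp, yp, e_k, config, spans, yspan)
        mutated <- TRUE
      }
    }
    state <- if (mutated) replay_state(model, x[seq_len(p), , drop = FALSE])
             else layer2_memberships(model, xp, state)
  }
  model$state <- numeric(length(model$set_var))
  validate_enfrn_model(model)
  attr(model, "mean_error") <- if (length(errs)) mean(errs) else 0
  attr(model, "degenerate") <- degenerate
  model
}
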