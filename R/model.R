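#' Construct a recurrent neuro-fuzzy network model
#'
#' An ENFRN is a five-layer recurrent fuzzy network mapping the expression
#' of one or more regulator genes at time \eqn{t} to the predicted
#' expression of a target gene at time \eqn{t+1}.  Layer 1 passes the
#' inputs through; layer 2 holds one Gaussian fuzzy set (a linguistic
#' label such as "lowly expressed") per input partition, each with a
#' recurrent self-link that feeds the node's previous output back into its
#' input; layer 3 holds fuzzy IF-THEN rules combining one set per input
#' variable with a product AND; layer 4 sums rule firing strengths per
#' output fuzzy set; layer 5 defuzzifies with a width-weighted average of
#' the output-set centers.
#'
#' The model is stored flat: fuzzy sets of all input variables are
#' concatenated, with \code{set_var} recording which variable each set
#' partitions.  Rule preconditions index into this global set list.
#'
#' @param input_names character vector of regulator gene identifiers.
#' @param output_name target gene identifier.
#' @param set_var integer vector, the input variable (1-based) each fuzzy
#'   set belongs to.
#' @param set_center,set_width numeric vectors of Gaussian centers and
#'   widths, one per fuzzy set; widths are floored at \code{1e-3}.
#' @param feedback numeric vector of recurrent link weights, one per set.
#' @param rule_pre integer matrix (rules x input variables) of global
#'   fuzzy-set indices; every rule must reference exactly one set of every
#'   input variable.
#' @param rule_out integer vector, the consequent output node of each rule.
#' @param out_center,out_width numeric vectors describing the output fuzzy
#'   sets (one per output node).
#' @param normalization optional per-gene (min, max) metadata carried along
#'   so predictions can be mapped back to the original expression scale.
#' @return An object of class \code{enfrn_model} with zeroed recurrent
#'   state.
#' @seealso [forward_sequence()], [build_initial_structure()]
#' @export
enfrn_model <- function(input_names, output_name, set_var, set_center,
                        set_width, feedback, rule_pre, rule_out,
                        out_center, out_width, normalization = NULL) {
  rule_pre <- matrix(as.integer(rule_pre), nrow = NROW(rule_pre))
  model <- structure(list(
    input_names = as.character(input_names),
    output_name = as.character(output_name),
    set_var = as.integer(set_var),
    set_center = as.numeric(set_center),
    set_width = pmax(as.numeric(set_width), SIGMA_MIN),
    feedback = as.numeric(feedback),
    rule_pre = rule_pre,
    rule_out = as.integer(rule_out),
    out_center = as.numeric(out_center),
    out_width = pmax(as.numeric(out_width), SIGMA_MIN),
    normalization = normalization,
    state = numeric(length(set_var))
  ), class = "enfrn_model")
  validate_enfrn_model(model)
  model
}

validate_enfrn_model <- function(model) {
  k <- length(model$input_names)
  s <- length(model$set_var)
  if (length(model$set_center) != s || length(model$set_width) != s ||
      length(model$feedback) != s || length(model$state) != s)
    stop("invalid model: fuzzy-set vectors have unequal lengths")
  if (any(model$set_width <= 0) || any(model$out_width <= 0))
    stop("invalid model: non-positive fuzzy-set width")
  if (s > 0 && (any(model$set_var < 1) || any(model$set_var > k)))
    stop("invalid model: set_var outside 1..n_inputs")
  r <- nrow(model$rule_pre)
  if (r > 0) {
    if (ncol(model$rule_pre) != k)
      stop("invalid model: rules must cover every input variable")
    if (any(model$rule_pre < 1) || any(model$rule_pre > s))
      stop("invalid model: rule precondition references a missing set")
    for (v in seq_len(k)) {
      if (any(model$set_var[model$rule_pre[, v]] != v))
        stop("invalid model: precondition set in column ", v,
             " belongs to another variable")
    }
    if (length(model$rule_out) != r)
      stop("invalid model: rule_out length mismatch")
    o <- length(model$out_center)
    if (any(model$rule_out < 1) || any(model$rule_out > o))
      stop("invalid model: rule consequent references a missing output node")
    if (!all(seq_len(o) %in% model$rule_out))
      stop("invalid model: orphan output node (not the consequent of any rule)")
  }
  invisible(model)
}

n_rules <- function(model) nrow(model$rule_pre)

#' Gaussian membership degree
#'
#' Degree to which an expression value belongs to a fuzzy set, using the
#' Gaussian form \eqn{\exp(-(x - c)^2 / \sigma^2)}.  Equals 1 exactly at
#' the center and lies in (0, 1) elsewhere.
#'
#' @param value numeric value(s) to evaluate.
#' @param center fuzzy-set center.
#' @param width fuzzy-set width (standard-deviation-like spread, > 0).
#' @return Membership degree(s) in (0, 1].
#' @export
gaussian_membership <- function(value, center, width) {
  if (any(width <= 0)) stop("invalid model: non-positive width")
  exp(-((value - center) / width)^2)
}

#' Recurrence-adjusted input of a layer-2 node
#'
#' Each linguistic node acts as a memory unit: its input at time t is the
#' raw expression value plus the node's previous membership output scaled
#' by the feedback link weight, \eqn{\phi(t) = x(t) + \beta\,\psi(t-1)}.
#' With zero state (t = 0) the input passes through unchanged.
#'
#' @param x raw input value.
#' @param prev_membership the node's membership output at the previous step
#'   (0 at the first step).
#' @param beta feedback link weight.
#' @return The adjusted input value.
#' @export
recurrent_layer2_input <- function(x, prev_membership, beta) {
  x + beta * prev_membership
}

#' Firing strength of one rule
#'
#' Product fuzzy-AND of the rule's precondition memberships, equivalent to
#' \eqn{\exp(-\lVert D(\phi - c)\rVert^2)} with \eqn{D = diag(1/\sigma)}
#' over the precondition dimensions.
#'
#' @param model an [enfrn_model()].
#' @param rule_index which rule to evaluate.
#' @param layer2 numeric vector of membership degrees, one per fuzzy set of
#'   the model (global indexing).
#' @return Firing strength in (0, 1].
#' @export
rule_firing <- function(model, rule_index, layer2) {
  pre <- model$rule_pre[rule_index, ]
  if (any(pre > length(layer2)))
    stop("invalid model: rule precondition references a missing set")
  prod(layer2[pre])
}

# layer-2 memberships for one input vector given a recurrent state
layer2_memberships <- function(model, x, state) {
  phi <- x[model$set_var] + model$feedback * state
  gaussian_membership(phi, model$set_center, model$set_width)
}

#' One recurrent forward step
#'
#' Evaluates the network on a single input vector, using and then updating
#' the recurrent state stored in the model.  The prediction is the
#' width-weighted average of output centers,
#' \eqn{y = \sum_j w_j c_j a_j / \sum_j w_j a_j}, where \eqn{a_j} sums the
#' firing strengths of rules routed to output node \eqn{j}.  When the
#' denominator underflows below \code{1e-12} the prediction falls back to
#' the consequent center of the maximally firing rule (with a warning).
#'
#' @param model an [enfrn_model()] with at least one rule.
#' @param x numeric vector of input expression values (one per regulator).
#' @return A list with elements \code{prediction} (numeric scalar) and
#'   \code{model} (the model with updated recurrent state).
#' @export
forward_step <- function(model, x) {
  if (n_rules(model) == 0) stop("model has no rules")
  if (length(x) != length(model$input_names))
    stop("input length does not match the number of input variables")
  y <- enfrn_forward_cpp(matrix(x, nrow = 1), model$set_var - 1L,
                         model$set_center, model$set_width, model$feedback,
                         model$rule_pre - 1L, model$rule_out - 1L,
                         model$out_center, model$out_width, model$state,
                         DENOM_FLOOR)
  if (attr(y, "n_floored") > 0)
    warning("defuzzification denominator underflow; ",
            "falling back to the nearest rule's consequent center")
  model$state <- attr(y, "state")
  list(prediction = as.numeric(y)[1], model = model)
}

#' Recurrent forward pass over a time series
#'
#' Resets the recurrent state, then iterates the forward step over the
#' rows of \code{x}, carrying the layer-2 memory across steps.  The
#' prediction at step t therefore depends only on inputs at steps <= t.
#'
#' @param model an [enfrn_model()] with at least one rule.
#' @param x numeric matrix (time points x input variables) of regulator
#'   expression values.
#' @return Numeric vector of predictions, one per row of \code{x}.
#' @export
forward_sequence <- function(model, x) {
  if (n_rules(model) == 0) stop("model has no rules")
  x <- as.matrix(x)
  if (nrow(x) == 0) return(numeric(0))
  if (ncol(x) != length(model$input_names))
    stop("input matrix has ", ncol(x), " columns; model expects ",
         length(model$input_names))
  y <- enfrn_forward_cpp(x, model$set_var - 1L, model$set_center,
                         model$set_width, model$feedback,
                         model$rule_pre - 1L, model$rule_out - 1L,
                         model$out_center, model$out_width,
                         numeric(length(model$set_var)), DENOM_FLOOR)
  if (attr(y, "n_floored") > 0)
    warning("defuzzification denominator underflow at ",
            attr(y, "n_floored"), " step(s); nearest-rule fallback used")
  attributes(y) <- NULL
  y
}

#' Reset the recurrent state of a model
#'
#' Zeros the layer-2 memory so the next forward step is evaluated as if at
#' the first time point.  Idempotent.
#'
#' @param model an [enfrn_model()].
#' @return The model with zeroed state.
#' @export
reset_state <- function(model) {
  model$state <- numeric(length(model$set_var))
  model
}

# one-step-ahead predictions and error of a model on a (series, target)
# pair under the lag-1 convention: x(t) predicts y(t+1)
model_predictions <- function(model, x, y) {
  x <- as.matrix(x)
  t_n <- nrow(x)
  list(pred = forward_sequence(model, x[-t_n, , drop = FALSE]),
       obs = y[-1])
}

model_rmse <- function(model, x, y) {
  p <- model_predictions(model, x, y)
  rmse(p$pred, p$obs)
}

model_mse <- function(model, x, y) {
  p <- model_predictions(model, x, y)
  mean((p$pred - p$obs)^2)
}

#' @export
print.enfrn_model <- function(x, ...) {
  cat("ENFRN model: ", paste(x$input_names, collapse = ", "),
      " -> ", x$output_name, "\n", sep = "")
  cat("  fuzzy sets per input: ",
      paste(tabulate(x$set_var, nbins = length(x$input_names)),
            collapse = ", "), "\n", sep = "")
  cat("  rules: ", n_rules(x), "   output nodes: ",
      length(x$out_center), "\n", sep = "")
  invisible(x)
}

#' Serialize a model to JSON
#'
#' Writes a versioned JSON document holding every parameter of the network
#' (fuzzy sets, feedback weights, rules, output nodes, gene names and
#' normalization metadata) at full double precision, so a written model
#' reads back bit-for-bit identical.
#'
#' @param model an [enfrn_model()].
#' @param path file to write.
#' @export
write_enfrn_model <- function(model, path) {
  obj <- list(
    format = "enfrn-model",
    version = 1L,
    input_names = model$input_names,
    output_name = model$output_name,
    set_var = model$set_var,
    set_center = model$set_center,
    set_width = model$set_width,
    feedback = model$feedback,
    rule_pre = apply(model$rule_pre, 1, function(r) r, simplify = FALSE),
    rule_out = model$rule_out,
    out_center = model$out_center,
    out_width = model$out_width,
    normalization = model$normalization
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a model serialized by [write_enfrn_model()]
#'
#' @param path JSON file written by [write_enfrn_model()].
#' @return An [enfrn_model()].
#' @export
read_enfrn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "enfrn-model"))
    stop("not an ENFRN model file: ", path)
  rule_pre <- if (length(obj$rule_out) == 0) {
    matrix(integer(0), nrow = 0, ncol = length(obj$input_names))
  } else if (is.list(obj$rule_pre)) {
    do.call(rbind, obj$rule_pre)
  } else if (is.matrix(obj$rule_pre)) {
    obj$rule_pre
  } else {
    matrix(obj$rule_pre, nrow = length(obj$rule_out), byrow = TRUE)
  }
  enfrn_model(obj$input_names, obj$output_name, obj$set_var,
              obj$set_center, obj$set_width, obj$feedback,
              rule_pre, obj$rule_out, obj$out_center, obj$out_width,
              normalization = obj$normalization)
}
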