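#' Particle swarm configuration
#'
#' Shared settings for the continuous PSO (phase-3 parameter fine-tuning)
#' and the binary PSO (phase-2 rule pruning).  The cognitive/social
#' constants and inertia default to the standard constriction-equivalent
#' values c1 = c2 = 1.494, W = 0.729; velocities are clipped to
#' \code{[-v_max, v_max]}.
#'
#' @param n_particles swarm size (>= 2).
#' @param n_iterations iteration budget.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param inertia inertia weight applied to the previous velocity.
#' @param v_max velocity clip.
#' @param seed integer seed making the run deterministic.
#' @param early_stop_tol stop when the global best improves by less than
#'   this for \code{patience} consecutive iterations.
#' @param patience iterations of stagnation tolerated before stopping.
#' @return A list of class \code{swarm_config}.
#' @export
swarm_config <- function(n_particles = 30L, n_iterations = 300L,
                         c1 = 1.494, c2 = 1.494, inertia = 0.729,
                         v_max = 4, seed = 1L, early_stop_tol = 1e-6,
                         patience = 25L) {
  stopifnot(n_particles >= 2, n_iterations >= 0, c1 > 0, c2 > 0,
            v_max > 0, early_stop_tol >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 c1 = c1, c2 = c2, inertia = inertia, v_max = v_max,
                 seed = as.integer(seed), early_stop_tol = early_stop_tol,
                 patience = as.integer(patience)),
            class = "swarm_config")
}

# defaults used for the two training phases
default_bpso_config <- function(seed = 1L)
  swarm_config(n_particles = 20L, n_iterations = 100L, seed = seed)

default_pso_config <- function(seed = 1L)
  swarm_config(n_particles = 30L, n_iterations = 300L, seed = seed)

#' PSO velocity update
#'
#' \eqn{v' = W v + c_1 n_1 (B_i - X) + c_2 n_2 (B^G - X)} componentwise,
#' with \eqn{n_1, n_2} uniform on (0,1) drawn fresh per component, clipped
#' to \code{[-v_max, v_max]}.  Uses the current RNG stream; seed the
#' stream before calling for reproducibility.
#'
#' @param particle list with \code{position}, \code{velocity},
#'   \code{best_position}.
#' @param global_best best position found by the swarm.
#' @param config a [swarm_config()].
#' @return New velocity vector.
#' @export
pso_velocity_update <- function(particle, global_best, config) {
  d <- length(particle$position)
  v <- config$inertia * particle$velocity +
    config$c1 * stats::runif(d) * (particle$best_position - particle$position) +
    config$c2 * stats::runif(d) * (global_best - particle$position)
  pmin(pmax(v, -config$v_max), config$v_max)
}

#' PSO position update
#'
#' \eqn{X' = X + v'}: the updated velocity moves the particle.
#'
#' @param particle list with \code{position} and (already updated)
#'   \code{velocity}.
#' @return New position vector.
#' @export
pso_position_update <- function(particle) {
  particle$position + particle$velocity
}

#' One binary-PSO step
#'
#' The velocity update is identical in form and constants to the
#' continuous rule; the new binary position sets each bit to 1 with
#' probability \eqn{sig(v') = 1/(1+e^{-v'})}, comparing a fresh uniform
#' draw per component against the sigmoid of the clipped velocity.
#'
#' @inheritParams pso_velocity_update
#' @return List with the new binary \code{position} and \code{velocity}.
#' @export
bpso_step <- function(particle, global_best, config) {
  v <- pso_velocity_update(particle, global_best, config)
  pos <- as.numeric(stats::runif(length(v)) < stats::plogis(v))
  list(position = pos, velocity = v)
}

# core swarm loop (continuous or binary), not seeded: callers wrap it in
# with_seed() together with their initialization draws
pso_core <- function(fitness, init, config, binary = FALSE, clamp = NULL) {
  n <- nrow(init)
  d <- ncol(init)
  pos <- init
  vel <- matrix(0, n, d)
  fit <- apply(pos, 1, fitness)
  best_pos <- pos
  best_fit <- fit
  g <- which.min(best_fit)
  gbest <- best_pos[g, ]
  gfit <- best_fit[g]
  history <- numeric(config$n_iterations)
  stall <- 0L
  it <- 0L
  while (it < config$n_iterations) {
    it <- it + 1L
    prev <- gfit
    for (i in seq_len(n)) {
      p <- list(position = pos[i, ], velocity = vel[i, ],
                best_position = best_pos[i, ])
      if (binary) {
        st <- bpso_step(p, gbest, config)
        vel[i, ] <- st$velocity
        pos[i, ] <- st$position
      } else {
        vel[i, ] <- pso_velocity_update(p, gbest, config)
        pos[i, ] <- pos[i, ] + vel[i, ]
        if (!is.null(clamp)) pos[i, ] <- clamp(pos[i, ])
      }
      f <- fitness(pos[i, ])
      if (f < best_fit[i]) {
        best_fit[i] <- f
        best_pos[i, ] <- pos[i, ]
        if (f < gfit) {
          gfit <- f
          gbest <- pos[i, ]
        }
      }
    }
    history[it] <- gfit
    stall <- if (prev - gfit < config$early_stop_tol) stall + 1L else 0L
    if (stall >= config$patience) break
  }
  list(position = gbest, fitness = gfit, history = history[seq_len(it)])
}

#' Minimize a function with global-best PSO
#'
#' Standard global-best particle swarm over real vectors, deterministic
#' given \code{config$seed}.  The global-best fitness is non-increasing
#' across iterations by construction.
#'
#' @param fitness function mapping a position vector to a scalar to
#'   minimize.
#' @param init numeric matrix of initial positions (particles x
#'   dimensions).
#' @param config a [swarm_config()].
#' @param clamp optional function applied to a position after each update
#'   (e.g. to keep widths positive).
#' @return List with \code{position}, \code{fitness} and the per-iteration
#'   global-best \code{history}.
#' @export
pso_optimize <- function(fitness, init, config, clamp = NULL) {
  with_seed(config$seed, pso_core(fitness, init, config, clamp = clamp))
}

# ---- parameter encoding (phase 3) ------------------------------------

#' Flatten a model's tunable parameters
#'
#' Concatenates, in order: input-set centers, input-set widths, output
#' centers, output widths, feedback weights.  [decode_parameters()]
#' inverts the encoding exactly, clipping decoded widths at the 1e-3
#' floor so decoded models are always valid.
#'
#' @param model an [enfrn_model()].
#' @return Numeric parameter vector.
#' @export
encode_parameters <- function(model) {
  c(model$set_center, model$set_width, model$out_center, model$out_width,
    model$feedback)
}

#' @rdname encode_parameters
#' @param theta parameter vector of the length produced by
#'   [encode_parameters()] on this model's shape.
#' @export
decode_parameters <- function(model, theta) {
  s <- length(model$set_var)
  o <- length(model$out_center)
  if (length(theta) != 3 * s + 2 * o)
    stop("parameter vector length ", length(theta),
         " does not match the model shape (expected ", 3 * s + 2 * o, ")")
  model$set_center <- theta[seq_len(s)]
  model$set_width <- pmax(theta[s + seq_len(s)], SIGMA_MIN)
  model$out_center <- theta[2 * s + seq_len(o)]
  model$out_width <- pmax(theta[2 * s + o + seq_len(o)], SIGMA_MIN)
  model$feedback <- theta[2 * s + 2 * o + seq_len(s)]
  model
}

# index of the width components within the encoding (for clamping)
width_index <- function(model) {
  s <- length(model$set_var)
  o <- length(model$out_center)
  c(s + seq_len(s), 2 * s + o + seq_len(o))
}

# ---- phase 2: structure simplification -------------------------------

# sub-model keeping the masked-in rules; output nodes no longer referenced
# are dropped, and (optionally) input fuzzy sets no longer referenced too
apply_rule_mask <- function(model, mask, trim_sets = FALSE) {
  keep <- which(mask > 0.5)
  model$rule_pre <- model$rule_pre[keep, , drop = FALSE]
  model$rule_out <- model$rule_out[keep]
  used_out <- sort(unique(model$rule_out))
  remap <- integer(length(model$out_center))
  remap[used_out] <- seq_along(used_out)
  model$out_center <- model$out_center[used_out]
  model$out_width <- model$out_width[used_out]
  model$rule_out <- remap[model$rule_out]
  if (trim_sets && nrow(model$rule_pre) > 0) {
    used <- sort(unique(as.vector(model$rule_pre)))
    smap <- integer(length(model$set_var))
    smap[used] <- seq_along(used)
    model$set_var <- model$set_var[used]
    model$set_center <- model$set_center[used]
    model$set_width <- model$set_width[used]
    model$feedback <- model$feedback[used]
    model$state <- numeric(length(used))
    model$rule_pre <- matrix(smap[model$rule_pre],
                             nrow = nrow(model$rule_pre))
  }
  model
}

#' Pruning fitness of a rule mask
#'
#' \eqn{MSE / (M - N + 1)} where MSE is the one-step-ahead mean square
#' error of the sub-model keeping the masked-in rules, M the initial rule
#' count and N the number of surviving rules: smaller with fewer rules and
#' lower error.  The all-zero mask gets \code{Inf} so it is never
#' selected.
#'
#' @param model the phase-1 model (defines M).
#' @param mask binary vector over the model's rules.
#' @param x,y training series (time points x regulators; target vector).
#' @return Non-negative fitness (lower is better).
#' @export
structure_fitness <- function(model, mask, x, y) {
  n_kept <- sum(mask > 0.5)
  if (n_kept == 0) return(Inf)
  m <- n_rules(model)
  sub <- apply_rule_mask(model, mask)
  # candidate sub-models may be degenerate (all rules far from the data);
  # the defuzzification fallback handles them, so its warning is muted here
  suppressWarnings(model_mse(sub, x, y)) / (m - n_kept + 1)
}

#' Phase 2: prune rules with binary PSO
#'
#' Searches the space of rule masks with BPSO, minimizing
#' [structure_fitness()]; redundant rules (and output nodes left without
#' any rule) are deleted.  Particle 1 starts at the all-ones mask so the
#' unpruned model is always a candidate, hence the result is never worse
#' than the input under the fitness.  Deterministic given
#' \code{config$seed}.
#'
#' @param model the phase-1 model.
#' @param x,y training series.
#' @param config a [swarm_config()] (defaults to 20 particles, 100
#'   iterations).
#' @return The pruned model; attributes \code{mask}, \code{fitness} and
#'   \code{history} record the search.
#' @export
simplify_structure <- function(model, x, y, config = default_bpso_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 3) {
    warning("series too short to prune (< 3 points); model returned unchanged")
    return(model)
  }
  m <- n_rules(model)
  fitness <- function(mask) structure_fitness(model, mask, x, y)
  res <- with_seed(config$seed, {
    init <- rbind(rep(1, m),
                  matrix(as.numeric(stats::runif((config$n_particles - 1) * m)
                                    < 0.5),
                         config$n_particles - 1, m))
    pso_core(fitness, init, config, binary = TRUE)
  })
  # only rules and their orphaned output nodes are deleted; the input
  # fuzzy sets (the linguistic partition of each regulator) survive the
  # pruning, keeping label sequences at full resolution for scoring
  out <- apply_rule_mask(model, res$position)
  validate_enfrn_model(out)
  attr(out, "mask") <- res$position
  attr(out, "fitness") <- res$fitness
  attr(out, "history") <- res$history
  out
}

# ---- phase 3: parameter fine-tuning ----------------------------------

#' Fitness of a candidate parameter vector
#'
#' Root-mean-square one-step-ahead prediction error of the model decoded
#' from \code{theta} on the training series.
#'
#' @param model model defining the parameter shape.
#' @param theta parameter vector (see [encode_parameters()]).
#' @param x,y training series.
#' @return Non-negative RMSE.
#' @export
parameter_fitness <- function(model, theta, x, y) {
  suppressWarnings(model_rmse(decode_parameters(model, theta), x, y))
}

#' Phase 3: fine-tune parameters with PSO
#'
#' Optimizes all fuzzy-set centers and widths (input and output) and the
#' recurrent feedback weights.  The swarm starts at the model's own
#' encoding (particle 1) plus Gaussian jitter (sd 0.05 in normalized
#' units), so the trained RMSE never exceeds the initial RMSE.  Widths are
#' clipped at the 1e-3 floor after every move.  Deterministic given
#' \code{config$seed}.
#'
#' @param model the (simplified) model to tune.
#' @param x,y training series.
#' @param config a [swarm_config()] (defaults to 30 particles, 300
#'   iterations).
#' @return The tuned model; attributes \code{fitness} (final RMSE) and
#'   \code{history} record the search.
#' @export
train_parameters <- function(model, x, y, config = default_pso_config()) {
  if (config$n_iterations == 0) return(model)
  x <- as.matrix(x)
  theta0 <- encode_parameters(model)
  d <- length(theta0)
  widx <- width_index(model)
  clamp <- function(theta) {
    theta[widx] <- pmax(theta[widx], SIGMA_MIN)
    theta
  }
  fitness <- function(theta) parameter_fitness(model, theta, x, y)
  res <- with_seed(config$seed, {
    init <- matrix(rep(theta0, each = config$n_particles),
                   config$n_particles, d)
    jit <- matrix(stats::rnorm((config$n_particles - 1) * d, sd = 0.05),
                  config$n_particles - 1, d)
    init[-1, ] <- init[-1, , drop = FALSE] + jit
    init <- t(apply(init, 1, clamp))
    pso_core(fitness, init, config, clamp = clamp)
  })
  out <- decode_parameters(model, res$position)
  attr(out, "fitness") <- res$fitness
  attr(out, "history") <- res$history
  out
}
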