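# Independent oracles, deliberately written as naive explicit loops so they
# share no code path with the package implementation.

# layer-by-layer recurrent forward pass, one arithmetic step at a time
naive_forward_sequence <- function(model, x) {
  x <- as.matrix(x)
  n_set <- length(model$set_var)
  n_rule <- nrow(model$rule_pre)
  n_out <- length(model$out_center)
  prev <- rep(0, n_set)
  out <- numeric(nrow(x))
  for (t in seq_len(nrow(x))) {
    psi <- numeric(n_set)
    for (s in seq_len(n_set)) {
      xin <- x[t, model$set_var[s]]
      phi <- xin + model$feedback[s] * prev[s]
      psi[s] <- exp(-((phi - model$set_center[s])^2) / model$set_width[s]^2)
    }
    firing <- numeric(n_rule)
    for (r in seq_len(n_rule)) {
      f <- 1
      for (v in seq_len(ncol(model$rule_pre))) f <- f * psi[model$rule_pre[r, v]]
      firing[r] <- f
    }
    act <- numeric(n_out)
    for (r in seq_len(n_rule)) {
      o <- model$rule_out[r]
      act[o] <- act[o] + firing[r]
    }
    num <- 0; den <- 0
    for (o in seq_len(n_out)) {
      num <- num + model$out_width[o] * model$out_center[o] * act[o]
      den <- den + model$out_width[o] * act[o]
    }
    if (den < 1e-12) {
      best <- 1
      for (r in seq_len(n_rule)) if (firing[r] > firing[best]) best <- r
      out[t] <- model$out_center[model$rule_out[best]]
    } else {
      out[t] <- num / den
    }
    prev <- psi
  }
  out
}

# literal walk over transitions implementing the lag-1 coupling score
brute_regulation_score <- function(labels_in, labels_out) {
  if (!is.list(labels_in)) labels_in <- list(labels_in)
  tt <- length(labels_out)
  n_ic <- 0
  total <- 0
  for (t in seq_len(tt - 2)) {
    all_changed <- TRUE
    dir_sum <- 0
    for (l in labels_in) {
      if (l[t + 1] == l[t]) all_changed <- FALSE
      dir_sum <- dir_sum + sign(l[t + 1] - l[t])
    }
    if (!all_changed) next
    n_ic <- n_ic + 1
    total <- total + sign(dir_sum) * sign(labels_out[t + 2] - labels_out[t + 1])
  }
  if (n_ic == 0) list(rs_raw = NA_real_, n_ic = 0L)
  else list(rs_raw = total / n_ic, n_ic = as.integer(n_ic))
}

# random valid model with k inputs, a few sets per input, random rules
random_test_model <- function(seed, k = 2, max_sets = 3, max_rules = 5,
                              feedback_range = c(-0.8, 0.8)) {
  set.seed(seed)
  n_sets_per <- sample(seq_len(max_sets), k, replace = TRUE)
  set_var <- rep(seq_len(k), n_sets_per)
  n_set <- length(set_var)
  n_rule <- sample(seq_len(max_rules), 1)
  n_out <- sample(seq_len(n_rule), 1)
  rule_pre <- sapply(seq_len(k), function(v) {
    idx <- which(set_var == v)
    idx[sample.int(length(idx), n_rule, replace = TRUE)]
  })
  rule_pre <- matrix(rule_pre, nrow = n_rule)
  rule_out <- c(seq_len(n_out), sample.int(n_out, n_rule - n_out,
                                           replace = TRUE))
  enfrn_model(
    input_names = paste0("g", seq_len(k)), output_name = "target",
    set_var = set_var,
    set_center = runif(n_set),
    set_width = runif(n_set, 0.05, 0.5),
    feedback = runif(n_set, feedback_range[1], feedback_range[2]),
    rule_pre = rule_pre, rule_out = rule_out,
    out_center = runif(n_out),
    out_width = runif(n_out, 0.05, 0.5))
}

# single (regulator, target) synthetic series pair on [0,1]
make_pair_data <- function(seed, t_points = 24, noise_sd = 0.05,
                           sign = -1) {
  topo <- structure(list(
    genes = c("REG", "TGT"),
    edges = data.frame(regulator = "REG", target = "TGT", sign = sign,
                       strength = 0.9, stringsAsFactors = FALSE),
    max_in_degree = 1L), class = "synthetic_topology")
  sim <- simulate_expression(topo, simulation_config(t_points = t_points,
                                                     noise_sd = noise_sd,
                                                     seed = seed))
  list(x = t(sim$dataset$values["REG", , drop = FALSE]),
       y = as.numeric(sim$dataset$values["TGT", ]),
       sign = sign)
}

# small swarm settings for fast pipeline-level tests
fast_config <- function(seed = 1L) {
  pipeline_config(
    n_candidates = 3L, n_best_subsets = 2L,
    bpso = swarm_config(n_particles = 8L, n_iterations = 25L, seed = seed),
    pso = swarm_config(n_particles = 10L, n_iterations = 40L, seed = seed),
    seed = seed)
}
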