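test_that("velocity update: converged particles stay, attraction points the
           right way, and the mean matches the expected drift", {
  cfg <- swarm_config(seed = 1)
  p <- list(position = c(1, 2), velocity = c(0, 0),
            best_position = c(1, 2))
  expect_equal(pso_velocity_update(p, c(1, 2), cfg), c(0, 0))
  # zero inertia and (numerically) zero social term: v points toward B_i
  cfg2 <- swarm_config(inertia = 0)
  cfg2$c2 <- 0
  p2 <- list(position = c(0, 5), velocity = c(0.3, -0.2),
             best_position = c(2, 1))
  set.seed(2)
  for (i in 1:20) {
    v <- pso_velocity_update(p2, c(0, 5), cfg2)
    expect_true(v[1] >= 0 && v[2] <= 0)
  }
  # E[v'] = W v + c1/2 (B-X) + c2/2 (G-X) over many draws
  cfg3 <- swarm_config(c1 = 1.4, c2 = 1.4, inertia = 0.7, v_max = 100)
  p3 <- list(position = 0, velocity = 0.5, best_position = 1)
  g <- 2
  set.seed(3)
  n <- 1e5
  draws <- replicate(n, pso_velocity_update(p3, g, cfg3))
  expected <- 0.7 * 0.5 + 1.4 / 2 * (1 - 0) + 1.4 / 2 * (2 - 0)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("position update is the additive move X + v", {
  expect_equal(pso_position_update(list(position = c(1, 1),
                                        velocity = c(0, 0))), c(1, 1))
  expect_equal(pso_position_update(list(position = c(0, 0),
                                        velocity = c(1, 1))), c(1, 1))
  half <- pso_position_update(list(position = 0, velocity = 0.5))
  expect_equal(pso_position_update(list(position = half, velocity = 0.5)),
               pso_position_update(list(position = 0, velocity = 1)))
})

test_that("binary step samples bits through the sigmoid of the clipped
           velocity", {
  cfg <- swarm_config(v_max = 4)
  # V = 0: P(bit) = 0.5
  p0 <- list(position = 0, velocity = 0, best_position = 0)
  cfg0 <- swarm_config(inertia = 1)
  cfg0$c1 <- 1e-300; cfg0$c2 <- 1e-300
  set.seed(4)
  n <- 1e5
  bits <- replicate(n, bpso_step(p0, 0, cfg0)$position)
  expect_lt(abs(mean(bits) - 0.5), 3 * sqrt(0.25 / n))
  # huge pull clips at v_max: P(bit) = sigmoid(4)
  pfar <- list(position = 0, velocity = 4, best_position = 1e6)
  cfgf <- swarm_config(inertia = 1, v_max = 4)
  set.seed(5)
  bits <- replicate(n, bpso_step(pfar, 1e6, cfgf)$position)
  pr <- plogis(4)
  expect_lt(abs(mean(bits) - pr), 3 * sqrt(pr * (1 - pr) / n))
  # bit probabilities always within [sig(-4), sig(4)]
  set.seed(6)
  for (i in 1:50) {
    p <- list(position = round(runif(3)), velocity = runif(3, -10, 10),
              best_position = round(runif(3)))
    st <- bpso_step(p, round(runif(3)), cfg)
    expect_true(all(st$velocity >= -4 & st$velocity <= 4))
    expect_true(all(st$position %in% c(0, 1)))
  }
})

test_that("parameter encoding round-trips a model exactly and clips
           collapsed widths on decode", {
  m <- random_test_model(21, k = 2)
  theta <- encode_parameters(m)
  m2 <- decode_parameters(m, theta)
  expect_identical(m2$set_center, m$set_center)
  expect_identical(m2$set_width, m$set_width)
  expect_identical(m2$out_center, m$out_center)
  expect_identical(m2$out_width, m$out_width)
  expect_identical(m2$feedback, m$feedback)
  theta[length(m$set_var) + 1] <- 1e-9    # first width component
  expect_equal(decode_parameters(m, theta)$set_width[1], 1e-3)
  expect_error(decode_parameters(m, theta[-1]), "length")
})

test_that("structure fitness rewards smaller rule sets at equal error", {
  d <- make_pair_data(2)
  m <- build_initial_structure(d$x, d$y)
  mm <- nrow(m$rule_pre)
  full <- rep(1, mm)
  expect_equal(structure_fitness(m, full, d$x, d$y),
               enfrn:::model_mse(m, d$x, d$y))
  expect_equal(structure_fitness(m, rep(0, mm), d$x, d$y), Inf)
  # plant a rule that never fires (its set sits far outside the data):
  # dropping it leaves the MSE bit-identical but the fitness strictly lower
  m2 <- m
  m2$set_var <- c(m2$set_var, 1L)
  m2$set_center <- c(m2$set_center, 50)
  m2$set_width <- c(m2$set_width, 1e-3)
  m2$feedback <- c(m2$feedback, 0)
  m2$state <- c(m2$state, 0)
  m2$rule_pre <- rbind(m2$rule_pre, length(m2$set_var))
  m2$rule_out <- c(m2$rule_out, m2$rule_out[1])
  mask_all <- rep(1, mm + 1)
  mask_drop <- c(rep(1, mm), 0)
  f_all <- structure_fitness(m2, mask_all, d$x, d$y)
  f_drop <- structure_fitness(m2, mask_drop, d$x, d$y)
  expect_lt(f_drop, f_all)
  sub <- enfrn:::apply_rule_mask(m2, mask_drop)
  expect_identical(enfrn:::model_mse(sub, d$x, d$y),
                   enfrn:::model_mse(m2, d$x, d$y))
})

test_that("BPSO pruning finds the exhaustive optimum and never does worse
           than the unpruned model", {
  d <- make_pair_data(3, t_points = 12)
  m <- build_initial_structure(
    d$x, d$y, structure_config(error_threshold = 0.05))
  mm <- nrow(m$rule_pre)
  expect_lte(mm, 12)
  cfg <- swarm_config(n_particles = 20, n_iterations = 100, seed = 9)
  pruned <- simplify_structure(m, d$x, d$y, cfg)
  f_best <- attr(pruned, "fitness")
  expect_lte(f_best, structure_fitness(m, rep(1, mm), d$x, d$y))
  # exhaustive minimum over all non-empty masks
  masks <- expand.grid(rep(list(c(0, 1)), mm))
  fits <- apply(masks, 1, function(mk) structure_fitness(m, mk, d$x, d$y))
  expect_equal(f_best, min(fits), tolerance = 1e-12)
  expect_lte(nrow(pruned$rule_pre), mm)
  expect_silent(enfrn:::validate_enfrn_model(pruned))
})

test_that("swarm global best is monotone over iterations and bit-identical
           under the same seed", {
  d <- make_pair_data(5, t_points = 16)
  m <- build_initial_structure(d$x, d$y)
  cfg <- swarm_config(n_particles = 10, n_iterations = 30, seed = 77)
  p1 <- simplify_structure(m, d$x, d$y, cfg)
  p2 <- simplify_structure(m, d$x, d$y, cfg)
  expect_identical(attr(p1, "mask"), attr(p2, "mask"))
  expect_identical(attr(p1, "history"), attr(p2, "history"))
  expect_true(all(diff(attr(p1, "history")) <= 0))
  t1 <- train_parameters(p1, d$x, d$y,
                         swarm_config(n_particles = 10, n_iterations = 30,
                                      seed = 78))
  t2 <- train_parameters(p1, d$x, d$y,
                         swarm_config(n_particles = 10, n_iterations = 30,
                                      seed = 78))
  expect_identical(encode_parameters(t1), encode_parameters(t2))
  expect_true(all(diff(attr(t1, "history")) <= 0))
})

test_that("the two fitness paths agree: parameter RMSE is the square root
           of the full-mask structure MSE", {
  d <- make_pair_data(6)
  m <- build_initial_structure(d$x, d$y)
  theta <- encode_parameters(m)
  expect_equal(parameter_fitness(m, theta, d$x, d$y),
               sqrt(structure_fitness(m, rep(1, nrow(m$rule_pre)),
                                      d$x, d$y)))
  expect_equal(parameter_fitness(m, theta, d$x, d$y),
               enfrn:::model_rmse(m, d$x, d$y))
})

test_that("parameter training is elitist: never worse, and a zero-iteration
           budget returns the model unchanged", {
  d <- make_pair_data(8)
  m <- build_initial_structure(d$x, d$y)
  expect_identical(
    train_parameters(m, d$x, d$y, swarm_config(n_iterations = 0)), m)
  before <- enfrn:::model_rmse(m, d$x, d$y)
  trained <- train_parameters(m, d$x, d$y,
                              swarm_config(n_particles = 15,
                                           n_iterations = 60, seed = 5))
  expect_lte(enfrn:::model_rmse(trained, d$x, d$y), before)
  expect_true(all(trained$set_width >= 1e-3))
  expect_true(all(trained$out_width >= 1e-3))
})

test_that("PSO minimizes the 5-D sphere function", {
  sphere <- function(v) sum(v^2)
  cfg <- swarm_config(n_particles = 20, n_iterations = 200, seed = 31,
                      patience = 1000L)
  set.seed(310)
  init <- matrix(runif(20 * 5, -5, 5), 20)
  res <- pso_optimize(sphere, init, cfg)
  expect_lt(res$fitness, 1e-3)
  expect_true(all(diff(res$history) <= 0))
})

test_that("short series skip pruning with a warning", {
  d <- make_pair_data(9)
  m <- build_initial_structure(d$x, d$y)
  expect_warning(out <- simplify_structure(m, d$x[1:2, , drop = FALSE],
                                           d$y[1:2]),
                 "too short")
  expect_identical(out, m)
})
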