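test_that("prediction error is the symmetric absolute difference", {
  expect_equal(prediction_error(0.4, 0.4), 0)
  expect_equal(prediction_error(0.9, 0.4), 0.5)
  expect_equal(prediction_error(0.1, 0.8), prediction_error(0.8, 0.1))
})

test_that("nearest_rule returns the max-firing rule (brute-force check)", {
  m1 <- random_test_model(1, k = 1, max_rules = 1)
  expect_equal(nearest_rule(m1, 0.99)$index, 1)
  # pattern exactly on a rule's centers fires at 1
  m <- random_test_model(5, k = 2, max_rules = 5,
                         feedback_range = c(0, 0))
  r <- nrow(m$rule_pre)
  x_on <- vapply(seq_len(2), function(v)
    m$set_center[m$rule_pre[r, v]], numeric(1))
  nr <- nearest_rule(m, x_on)
  expect_equal(nr$strength, 1.0)
  expect_equal(m$rule_pre[nr$index, ], m$rule_pre[r, ])
  for (seed in 1:20) {
    m <- random_test_model(seed + 100, k = 2, max_rules = 5)
    set.seed(seed)
    x <- runif(2)
    psi <- enfrn:::layer2_memberships(m, x, numeric(length(m$set_var)))
    brute <- vapply(seq_len(nrow(m$rule_pre)), function(r)
      prod(psi[m$rule_pre[r, ]]), numeric(1))
    expect_equal(nearest_rule(m, x)$index, which.max(brute))
  }
})

test_that("a rule is created only when the pattern is both badly predicted
           and far from all clusters", {
  cfg <- structure_config(error_threshold = 0.1, firing_threshold = 0.8)
  expect_false(should_create_rule(0, 0.1, cfg))
  expect_false(should_create_rule(100, 1.0, cfg))
  expect_true(should_create_rule(0.2, 0.5, cfg))
})

test_that("create_rule bootstraps and sets widths from nearest-center
           distances", {
  cfg <- structure_config(overlap_delta = 0.25,
                          similarity_threshold = 0.8)
  m <- enfrn:::empty_model("a", "y")
  m <- create_rule(m, 0.2, 0.3, Inf, cfg, input_spans = 1, output_span = 1)
  expect_equal(nrow(m$rule_pre), 1)
  expect_equal(length(m$set_var), 1)
  expect_equal(length(m$out_center), 1)
  expect_equal(m$set_center, 0.2)
  expect_equal(m$set_width, 0.25)          # delta * span
  expect_equal(m$out_center, 0.3)
  m <- create_rule(m, 0.8, 0.9, 1, cfg, input_spans = 1, output_span = 1)
  expect_equal(nrow(m$rule_pre), 2)
  expect_equal(m$set_center[2], 0.8)
  expect_equal(m$set_width[2], 0.25 * abs(0.8 - 0.2))
  # degenerate delta -> floor applies
  cfg0 <- structure_config(overlap_delta = 1e-9)
  m0 <- enfrn:::empty_model("a", "y")
  m0 <- create_rule(m0, 0.5, 0.5, Inf, cfg0, input_spans = 1,
                    output_span = 1)
  expect_equal(m0$set_width, 1e-3)
})

test_that("fuzzy-set similarity is a proper overlap measure", {
  s <- function(c1, w1, c2, w2)
    fuzzy_set_similarity(list(center = c1, width = w1),
                         list(center = c2, width = w2))
  expect_equal(s(0.3, 0.1, 0.3, 0.1), 1.0)
  expect_lt(s(0.0, 0.05, 1.0, 0.05), 1e-6)
  # symmetry
  expect_equal(s(0.2, 0.1, 0.5, 0.3), s(0.5, 0.3, 0.2, 0.1))
  # quadrature oracle on random pairs
  set.seed(42)
  for (i in 1:25) {
    c1 <- runif(1); c2 <- runif(1)
    w1 <- runif(1, 0.02, 0.5); w2 <- runif(1, 0.02, 0.5)
    grid <- seq(-3, 4, length.out = 20001)
    mu1 <- exp(-((grid - c1) / w1)^2)
    mu2 <- exp(-((grid - c2) / w2)^2)
    h <- grid[2] - grid[1]
    ov <- sum(pmin(mu1, mu2)) * h
    un <- sum(pmax(mu1, mu2)) * h
    expect_equal(s(c1, w1, c2, w2), ov / un, tolerance = 0.05)
  }
})

test_that("merging removes redundant sets and re-points rules", {
  # two identical sets in one dimension
  m <- enfrn_model("a", "y", set_var = c(1, 1), set_center = c(0.4, 0.4),
                   set_width = c(0.2, 0.2), feedback = c(0.1, 0.3),
                   rule_pre = rbind(1, 2), rule_out = c(1, 1),
                   out_center = 0.5, out_width = 0.3)
  m2 <- merge_similar_sets(m, 0.8)
  expect_equal(length(m2$set_var), 1)
  expect_equal(nrow(m2$rule_pre), 2)
  expect_true(all(m2$rule_pre == 1))
  expect_equal(m2$feedback, 0.2)
  # fixed point: dissimilar sets unchanged
  m3 <- enfrn_model("a", "y", set_var = c(1, 1), set_center = c(0.1, 0.9),
                    set_width = c(0.05, 0.05), feedback = c(0, 0),
                    rule_pre = rbind(1, 2), rule_out = c(1, 1),
                    out_center = 0.5, out_width = 0.3)
  expect_identical(merge_similar_sets(m3, 0.8)$set_center, m3$set_center)
  # chain a~b~c terminates with no pair above threshold
  m4 <- enfrn_model("a", "y", set_var = c(1, 1, 1),
                    set_center = c(0.40, 0.42, 0.44),
                    set_width = c(0.2, 0.2, 0.2), feedback = c(0, 0, 0),
                    rule_pre = rbind(1, 2, 3), rule_out = c(1, 1, 1),
                    out_center = 0.5, out_width = 0.3)
  m5 <- merge_similar_sets(m4, 0.8)
  expect_lte(length(m5$set_var), 2)
  expect_equal(nrow(m5$rule_pre), 3)
  if (length(m5$set_var) == 2) {
    sim <- fuzzy_set_similarity(
      list(center = m5$set_center[1], width = m5$set_width[1]),
      list(center = m5$set_center[2], width = m5$set_width[2]))
    expect_lte(sim, 0.8)
  }
  expect_silent(enfrn:::validate_enfrn_model(m5))
})

test_that("output clusters are reused when the target is covered and
           created when it is far and badly predicted", {
  cfg <- structure_config(error_threshold = 0.1, firing_threshold = 0.8,
                          overlap_delta = 0.25)
  m <- enfrn:::empty_model("a", "y")
  out <- assign_output_cluster(m, 0.3, Inf, cfg, output_span = 1)
  expect_equal(out$index, 1L)
  expect_equal(out$model$out_center, 0.3)
  m <- out$model
  # y exactly on an existing center: reused
  out2 <- assign_output_cluster(m, 0.3, 5, cfg)
  expect_equal(out2$index, 1L)
  expect_equal(length(out2$model$out_center), 1)
  # far y with large error: new node
  out3 <- assign_output_cluster(m, 0.95, 5, cfg)
  expect_equal(out3$index, 2L)
  expect_equal(out3$model$out_center[2], 0.95)
  # far y but small error: reused
  out4 <- assign_output_cluster(m, 0.95, 0.01, cfg)
  expect_equal(out4$index, 1L)
})

test_that("a 2-point series yields exactly one rule", {
  m <- build_initial_structure(matrix(c(0.2, 0.8), ncol = 1), c(0.1, 0.9))
  expect_equal(nrow(m$rule_pre), 1)
  expect_equal(length(m$out_center), 1)
})

test_that("structures on ~24-point cell-cycle-like series hold 5-20 rules", {
  counts <- integer(0)
  for (s in 1:5) {
    d <- make_pair_data(s, t_points = 24, noise_sd = 0.05,
                        sign = c(-1, 1)[s %% 2 + 1])
    m <- build_initial_structure(d$x, d$y)
    counts <- c(counts, nrow(m$rule_pre))
    expect_silent(enfrn:::validate_enfrn_model(m))
  }
  expect_true(all(counts >= 5 & counts <= 20))
})

test_that("rule count never exceeds the cap and structural integrity holds
           across a fuzz of build runs", {
  for (s in 1:8) {
    set.seed(s)
    x <- matrix(runif(20 * 2), 20)
    y <- runif(20)
    cfg <- structure_config(error_threshold = runif(1, 0.02, 0.3),
                            firing_threshold = runif(1, 0.3, 0.95),
                            overlap_delta = runif(1, 0.1, 0.6),
                            max_rules = 10L)
    m <- build_initial_structure(x, y, cfg)
    expect_lte(nrow(m$rule_pre), 10)
    expect_silent(enfrn:::validate_enfrn_model(m))
  }
})

test_that("looser error thresholds never create more rules, and training
           error does not rise with more rules", {
  d <- make_pair_data(4, t_points = 24, noise_sd = 0.02)
  thresholds <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  runs <- lapply(thresholds, function(et)
    build_initial_structure(d$x, d$y,
                            structure_config(error_threshold = et)))
  rules <- vapply(runs, function(m) nrow(m$rule_pre), numeric(1))
  errs <- vapply(runs, function(m) attr(m, "mean_error"), numeric(1))
  expect_true(all(diff(rules) <= 0))
  # more rules (lower threshold) never hurts the streamed error
  expect_true(all(diff(errs[order(rules)]) <= 1e-12))
})

test_that("constant series are flagged as degenerate but still build", {
  expect_warning(
    m <- build_initial_structure(matrix(rep(0.5, 10), ncol = 1),
                                 seq(0, 1, length.out = 10)),
    "zero-variance")
  expect_gte(nrow(m$rule_pre), 1)
})
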