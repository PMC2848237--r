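# numerical floors used throughout; widths may never collapse below
# SIGMA_MIN and the defuzzification denominator below DENOM_FLOOR
SIGMA_MIN <- 1e-3
DENOM_FLOOR <- 1e-12

# evaluate `code` with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-(target, stage) sub-seed so per-target results do not
# depend on the order genes are iterated in
gene_hash <- function(name) {
  v <- utf8ToInt(name)
  sum(v * seq_along(v)) %% 100003
}

derive_seed <- function(seed, target, stage) {
  ((seed %% 1000000) * 1009 + gene_hash(target) * 17 + stage) %% 2147483646 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))
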