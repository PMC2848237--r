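#' Random signed regulatory topology
#'
#' Draws a directed, signed gene network: no self-edges, in-degree capped
#' at \code{max_in_degree}, and at least one unregulated "driver" gene
#' whose expression is exogenous (cell-cycle-like).  Edge strengths are
#' drawn uniformly on (0.4, 1): regulation weaker than that leaves no
#' detectable lag-1 footprint in short noisy series, so such edges would
#' be unidentifiable by construction.
#'
#' @param n_genes number of genes.
#' @param n_edges number of regulatory edges; must not exceed
#'   \code{(n_genes - 1) * max_in_degree} (one gene stays a driver).
#' @param max_in_degree maximum regulators per target.
#' @param seed integer seed.
#' @return A list of class \code{synthetic_topology} with \code{genes} and
#'   an \code{edges} data frame (regulator, target, sign, strength).
#' @export
generate_topology <- function(n_genes, n_edges, max_in_degree = 2L,
                              seed = 1L) {
  if (n_genes < 2) stop("need at least 2 genes")
  if (n_edges > (n_genes - 1) * max_in_degree)
    stop("infeasible: ", n_edges, " edges cannot satisfy the in-degree cap ",
         "while keeping a driver gene")
  genes <- sprintf("G%02d", seq_len(n_genes))
  with_seed(seed, {
    driver <- sample(genes, 1)
    indeg <- stats::setNames(integer(n_genes), genes)
    edges <- list()
    existing <- character(0)
    while (length(edges) < n_edges) {
      open <- names(indeg)[indeg < max_in_degree & names(indeg) != driver]
      tgt <- if (length(open) == 1) open else sample(open, 1)
      reg <- sample(setdiff(genes, tgt), 1)
      key <- paste(reg, tgt)
      if (key %in% existing) next
      existing <- c(existing, key)
      indeg[tgt] <- indeg[tgt] + 1L
      edges[[length(edges) + 1]] <- data.frame(
        regulator = reg, target = tgt,
        sign = sample(c(1L, -1L), 1),
        strength = stats::runif(1, 0.4, 1),
        stringsAsFactors = FALSE)
    }
    edges <- if (length(edges)) do.call(rbind, edges)
             else data.frame(regulator = character(0), target = character(0),
                             sign = integer(0), strength = numeric(0))
    structure(list(genes = genes, edges = edges,
                   max_in_degree = as.integer(max_in_degree)),
              class = "synthetic_topology")
  })
}

#' Simulation settings for synthetic expression data
#'
#' @param t_points number of time points (>= 8); the defaults mirror
#'   short cell-cycle course lengths of about two dozen samples.
#' @param noise_sd standard deviation of Gaussian measurement noise added
#'   to every value (< 0.5 on the (0,1) expression scale).
#' @param period period of the cyclic driver genes, in sampling steps
#'   (cell-cycle-like oscillation).
#' @param missing_rate fraction of cells masked as missing, in [0, 1).
#' @param seed integer seed.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(t_points = 24L, noise_sd = 0.05, period = 8,
                              missing_rate = 0, seed = 1L) {
  stopifnot(t_points >= 8, noise_sd >= 0, noise_sd < 0.5, period > 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(t_points = as.integer(t_points), noise_sd = noise_sd,
                 period = period, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate time-course expression from a topology
#'
#' Driver genes (in-degree 0) follow sinusoids of the configured period
#' with random phases, emulating cell-cycle periodicity so that
#' linguistic labels alternate and true edges accumulate input changes.
#' Regulated genes follow first-order lag dynamics,
#' \deqn{x_g(t+1) = squash(\sum_{e} sign_e \cdot strength_e \cdot
#'   (x_{reg(e)}(t) - 1/2)),}
#' where \eqn{squash(u) = 1/(1 + e^{-8u})} maps to (0, 1) (inputs are
#' centered so activation and repression use the response range
#' symmetrically).  Gaussian measurement noise is then added to every
#' gene, values are clipped to (0, 1), and cells are masked at
#' \code{missing_rate}.
#'
#' @param topology a [generate_topology()] result.
#' @param config a [simulation_config()].
#' @return List with \code{expr} (raw genes x time matrix, \code{NA} where
#'   masked), \code{dataset} (the preprocessed [expression_dataset]) and
#'   \code{truth} (the edge data frame).
#' @export
simulate_expression <- function(topology, config = simulation_config()) {
  genes <- topology$genes
  t_n <- config$t_points
  edges <- topology$edges
  regulated <- unique(edges$target)
  drivers <- setdiff(genes, regulated)
  with_seed(config$seed, {
    expr <- matrix(NA_real_, length(genes), t_n,
                   dimnames = list(genes, paste0("t", seq_len(t_n))))
    phase <- stats::runif(length(genes), 0, 2 * pi)
    names(phase) <- genes
    for (g in drivers)
      expr[g, ] <- 0.5 + 0.45 * sin(2 * pi * seq_len(t_n) / config$period +
                                      phase[g])
    squash <- function(u) stats::plogis(8 * u)
    for (g in regulated) expr[g, 1] <- 0.5
    for (t in seq_len(t_n - 1)) {
      for (g in regulated) {
        e <- edges[edges$target == g, ]
        u <- sum(e$sign * e$strength * (expr[e$regulator, t] - 0.5))
        expr[g, t + 1] <- squash(u)
      }
    }
    if (config$noise_sd > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), sd = config$noise_sd),
                            nrow(expr))
      expr <- pmin(pmax(expr, 1e-3), 1 - 1e-3)
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(expr)) < config$missing_rate,
                     nrow(expr))
      expr[mask] <- NA_real_
    }
    list(expr = expr,
         dataset = preprocess_expression(expr, colnames(expr)),
         truth = edges)
  })
}

#' Compare inferred edges with the ground truth
#'
#' Directed-edge precision and recall, plus sign accuracy over the
#' correctly recovered edges.  With no inferred edges precision is
#' reported as 1 (no false positives) and flagged via the
#' \code{no_inferred} attribute; with no recovered edges sign accuracy is
#' \code{NA}.
#'
#' @param truth data frame with columns \code{regulator}, \code{target},
#'   \code{sign} (+1/-1).
#' @param inferred data frame with columns \code{regulator},
#'   \code{target}, \code{type} ("+"/"-").
#' @return List with \code{precision}, \code{recall}, \code{sign_accuracy},
#'   \code{n_true}, \code{n_inferred}, \code{n_recovered}.
#' @export
evaluate_recovery <- function(truth, inferred) {
  tkey <- paste(truth$regulator, truth$target)
  ikey <- paste(inferred$regulator, inferred$target)
  hit <- ikey %in% tkey
  n_rec <- sum(hit)
  recall <- if (length(tkey) == 0) NA_real_ else n_rec / length(tkey)
  precision <- if (length(ikey) == 0) 1 else n_rec / length(ikey)
  sign_acc <- NA_real_
  if (n_rec > 0) {
    isign <- ifelse(inferred$type[hit] == "+", 1L, -1L)
    tsign <- truth$sign[match(ikey[hit], tkey)]
    sign_acc <- mean(isign == tsign)
  }
  res <- list(precision = precision, recall = recall,
              sign_accuracy = sign_acc, n_true = length(tkey),
              n_inferred = length(ikey), n_recovered = n_rec)
  attr(res, "no_inferred") <- length(ikey) == 0
  res
}

#' Simulate statistically independent genes (null data)
#'
#' Every gene is an exogenous oscillator with its own period (drawn
#' uniformly on [6, 16] sampling steps) and phase, plus measurement
#' noise, so no gene carries lag-1 information about any other.  Used for
#' false-positive (null) benchmarking.
#'
#' @param n_genes number of genes.
#' @param config a [simulation_config()] (period is ignored; each gene
#'   draws its own).
#' @return List with \code{expr}, \code{dataset} and an empty
#'   \code{truth}.
#' @export
simulate_independent <- function(n_genes, config = simulation_config()) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  t_n <- config$t_points
  with_seed(config$seed, {
    expr <- matrix(NA_real_, n_genes, t_n,
                   dimnames = list(genes, paste0("t", seq_len(t_n))))
    for (i in seq_len(n_genes)) {
      per <- stats::runif(1, 6, 16)
      ph <- stats::runif(1, 0, 2 * pi)
      expr[i, ] <- 0.5 + 0.45 * sin(2 * pi * seq_len(t_n) / per + ph)
    }
    if (config$noise_sd > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), sd = config$noise_sd),
                            nrow(expr))
      expr <- pmin(pmax(expr, 1e-3), 1 - 1e-3)
    }
    list(expr = expr,
         dataset = preprocess_expression(expr, colnames(expr)),
         truth = data.frame(regulator = character(0), target = character(0),
                            sign = integer(0), strength = numeric(0)))
  })
}

#' Write an expression matrix as tab-delimited text
#'
#' First column \code{gene}, one column per time point; missing cells are
#' left empty.  The dialect matches [load_expression()].
#'
#' @param expr genes x time numeric matrix with dimnames.
#' @param path file to write.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
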