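#' Preprocessed expression dataset
#'
#' Container for a genes x time matrix of expression values normalized
#' per gene to [0, 1], with the (min, max) used for each gene kept so
#' predictions can be mapped back to the original scale, and the original
#' missingness pattern retained.
#'
#' @param values genes x time numeric matrix (rownames = gene ids).
#' @param times time-point labels.
#' @param normalization data frame (gene, min, max) used for scaling.
#' @param missing logical matrix of originally missing cells.
#' @param degenerate character vector of zero-variance genes (mapped to a
#'   constant 0.5).
#' @return An object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(values, times = colnames(values),
                               normalization = NULL, missing = NULL,
                               degenerate = character(0)) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene row names")
  if (anyNA(values)) stop("dataset still contains missing values")
  if (any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("dataset values must lie in [0, 1]")
  structure(list(values = values, times = times,
                 normalization = normalization,
                 missing = missing %||%
                   matrix(FALSE, nrow(values), ncol(values)),
                 degenerate = degenerate),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression dataset: ", nrow(x$values), " genes x ",
      ncol(x$values), " time points\n", sep = "")
  if (length(x$degenerate))
    cat("  zero-variance genes: ", paste(x$degenerate, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# interpolate missing cells over time, drop genes with too many missing,
# and min-max normalize each gene to [0, 1]
preprocess_expression <- function(values, times = colnames(values),
                                  max_missing = 0.3) {
  values <- as.matrix(values)
  miss <- is.na(values)
  frac <- rowMeans(miss)
  if (any(frac > max_missing)) {
    dropped <- rownames(values)[frac > max_missing]
    warning("dropping gene(s) with >", round(100 * max_missing),
            "% missing values: ", paste(dropped, collapse = ", "))
    keep <- frac <= max_missing
    values <- values[keep, , drop = FALSE]
    miss <- miss[keep, , drop = FALSE]
  }
  tt <- seq_len(ncol(values))
  for (i in which(rowSums(miss) > 0)) {
    ok <- !miss[i, ]
    values[i, !ok] <- stats::approx(tt[ok], values[i, ok], xout = tt[!ok],
                                    rule = 2)$y
  }
  lo <- apply(values, 1, min)
  hi <- apply(values, 1, max)
  degenerate <- rownames(values)[hi == lo]
  if (length(degenerate))
    warning("zero-variance gene(s) mapped to constant 0.5: ",
            paste(degenerate, collapse = ", "))
  span <- ifelse(hi > lo, hi - lo, 1)
  norm <- (values - lo) / span
  norm[hi == lo, ] <- 0.5
  expression_dataset(norm, times,
                     normalization = data.frame(gene = rownames(values),
                                                min = lo, max = hi,
                                                stringsAsFactors = FALSE),
                     missing = miss, degenerate = degenerate)
}

#' Load a tab-delimited expression matrix
#'
#' Reads a Spellman-style matrix: tab-delimited text, a header row of
#' time-point labels, first column the gene identifier, remaining columns
#' numeric (empty cells are missing).  Missing values are linearly
#' interpolated over time (boundary cells take the nearest observed
#' value); genes with more than 30% missing cells are dropped with a
#' warning; every gene is then min-max normalized to [0, 1].
#'
#' @param path file to read.
#' @param gene_subset optional character vector restricting the rows kept.
#' @return An [expression_dataset()].
#' @export
load_expression <- function(path, gene_subset = NULL) {
  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse expression file '", path,
                             "': ", conditionMessage(e)))
  if (ncol(raw) < 4) stop("fewer than 3 time points in '", path, "'")
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  values <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in '",
                                path, "'")
  rownames(values) <- ids
  if (!is.null(gene_subset)) {
    absent <- setdiff(gene_subset, ids)
    if (length(absent))
      warning("gene(s) not present in '", path, "': ",
              paste(absent, collapse = ", "))
    values <- values[intersect(gene_subset, ids), , drop = FALSE]
  }
  preprocess_expression(values, colnames(values))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the three-stage reconstruction: the maximum
#' number of candidate regulators per target (\code{n_candidates},
#' capped at 12 because stage 2 enumerates all \eqn{2^{N_k}} subsets),
#' the number of subsets promoted to full training
#' (\code{n_best_subsets}), the number of final configurations
#' (\code{n_final}), the composite-score weight and the edge-selection
#' threshold, plus the phase-1/2/3 sub-configurations.
#'
#' @param n_candidates candidate regulators kept per target (stage 1).
#' @param n_best_subsets subsets promoted from stage 2 to stage 3.
#' @param n_final configurations kept after stage 3.
#' @param cs_weight weight on the error term of the composite score.
#' @param cs_threshold composite score above which an edge is discarded.
#' @param structure a [structure_config()].
#' @param bpso,pso [swarm_config()]s for phases 2 and 3 (their seeds are
#'   re-derived per target and stage from \code{seed}).
#' @param seed master seed for the whole reconstruction.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_candidates = 5L, n_best_subsets = 5L,
                            n_final = 1L, cs_weight = 0.6,
                            cs_threshold = 0.6,
                            structure = structure_config(),
                            bpso = default_bpso_config(),
                            pso = default_pso_config(),
                            seed = 1L) {
  stopifnot(n_candidates >= 1, n_candidates <= 12,
            n_final >= 1, n_final <= n_best_subsets,
            cs_weight >= 0, cs_weight <= 1, cs_threshold > 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 n_best_subsets = as.integer(n_best_subsets),
                 n_final = as.integer(n_final),
                 cs_weight = cs_weight, cs_threshold = cs_threshold,
                 structure = structure, bpso = bpso, pso = pso,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Recognized top-level keys: \code{pipeline}, \code{structure},
#' \code{bpso}, \code{pso}; any omitted field keeps its default.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  pl <- cfg$pipeline %||% list()
  if (!is.null(seed)) pl$seed <- seed
  args <- pl[intersect(names(pl), c("n_candidates", "n_best_subsets",
                                    "n_final", "cs_weight", "cs_threshold",
                                    "seed"))]
  args$structure <- do.call(structure_config, cfg$structure %||% list())
  args$bpso <- do.call(swarm_config,
                       utils::modifyList(list(n_particles = 20L,
                                              n_iterations = 100L),
                                         cfg$bpso %||% list()))
  args$pso <- do.call(swarm_config, cfg$pso %||% list())
  do.call(pipeline_config, args)
}

# series of a gene set as (time x genes) input matrix plus target vector
gene_series <- function(data, genes) {
  t(data$values[genes, , drop = FALSE])
}

# phase-1 model + regulation scoring for one (regulator set, target)
phase1_score <- function(data, regulators, target, config) {
  x <- gene_series(data, regulators)
  y <- as.numeric(data$values[target, ])
  model <- build_initial_structure(x, y, config$structure,
                                   input_names = regulators,
                                   output_name = target)
  list(model = model, result = score_regulation(model, x, y,
                                                n = config$cs_weight))
}

#' Stage 1: rank single-gene candidate regulators
#'
#' Every other gene is tested individually as the sole regulator of the
#' target using only the computationally cheap phase-1 structure
#' learning, and the \code{n_candidates} genes with the lowest composite
#' score are kept (ties break by gene name).  Deterministic.
#'
#' @param data an [expression_dataset()].
#' @param target target gene identifier.
#' @param config a [pipeline_config()].
#' @return List with \code{candidates} (character vector) and
#'   \code{results} (per-gene data frame over all tested genes).
#' @export
stage1_rank_candidates <- function(data, target, config = pipeline_config()) {
  genes <- setdiff(rownames(data$values), target)
  if (length(genes) < 1) stop("need at least one candidate regulator")
  rows <- lapply(genes, function(g) {
    r <- phase1_score(data, g, target, config)$result
    data.frame(gene = g, rs_raw = r$rs_raw, type = r$regulation_type,
               rmse = r$model_error, cs = r$composite_score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$cs, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  list(candidates = utils::head(res$gene, config$n_candidates),
       results = res)
}

#' Stage 2: select regulator subsets by network error
#'
#' Enumerates all \eqn{2^{N_k} - 1} non-empty subsets of the stage-1
#' candidates, fits a phase-1-only network per subset, and keeps the
#' \code{n_best_subsets} with the lowest one-step-ahead RMSE (ties break
#' toward smaller subsets, then lexicographically).
#'
#' @param data an [expression_dataset()].
#' @param target target gene identifier.
#' @param candidates character vector from [stage1_rank_candidates()].
#' @param config a [pipeline_config()].
#' @return List with \code{subsets} (list of character vectors) and
#'   \code{results} (data frame with one row per subset evaluated).
#' @export
stage2_select_subsets <- function(data, target, candidates,
                                  config = pipeline_config()) {
  k <- length(candidates)
  if (k < 1) stop("no candidates supplied")
  masks <- seq_len(2^k - 1)
  rows <- lapply(masks, function(m) {
    members <- candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    x <- gene_series(data, members)
    y <- as.numeric(data$values[target, ])
    model <- build_initial_structure(x, y, config$structure,
                                     input_names = members,
                                     output_name = target)
    data.frame(subset = paste(members, collapse = ","),
               size = length(members), rmse = model_rmse(model, x, y),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ord <- order(res$rmse, res$size, res$subset)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  subsets <- lapply(utils::head(res$subset, config$n_best_subsets),
                    function(s) strsplit(s, ",", fixed = TRUE)[[1]])
  list(subsets = subsets, results = res)
}

#' Stage 3: train the selected subsets and pick the best configuration
#'
#' Each promoted subset is taken through the full training cycle:
#' phase-1 structure learning, phase-2 BPSO rule pruning and phase-3 PSO
#' parameter fine-tuning.  The composite score is then recomputed with
#' the trained model's RMSE and regulation score — on the held-out test
#' series when one is supplied (the trained model is frozen and only
#' evaluated), otherwise on the training series — and the \code{n_final}
#' lowest-scoring configurations are returned.
#'
#' @param data training [expression_dataset()].
#' @param target target gene identifier.
#' @param subsets list of regulator subsets from
#'   [stage2_select_subsets()].
#' @param config a [pipeline_config()].
#' @param test_data optional [expression_dataset()] used for scoring.
#' @return List with \code{best} (list of per-configuration lists holding
#'   \code{regulators}, \code{model}, \code{result}) and \code{results}
#'   (data frame over all trained subsets).
#' @export
stage3_finalize <- function(data, target, subsets,
                            config = pipeline_config(), test_data = NULL) {
  score_data <- test_data %||% data
  trained <- lapply(seq_along(subsets), function(i) {
    members <- subsets[[i]]
    x <- gene_series(data, members)
    y <- as.numeric(data$values[target, ])
    model <- build_initial_structure(x, y, config$structure,
                                     input_names = members,
                                     output_name = target)
    bcfg <- config$bpso
    bcfg$seed <- derive_seed(config$seed, target, 20L + i)
    model <- simplify_structure(model, x, y, bcfg)
    pcfg <- config$pso
    pcfg$seed <- derive_seed(config$seed, target, 30L + i)
    model <- train_parameters(model, x, y, pcfg)
    xs <- gene_series(score_data, members)
    ys <- as.numeric(score_data$values[target, ])
    res <- score_regulation(model, xs, ys, n = config$cs_weight)
    list(regulators = members, model = model, result = res)
  })
  cs <- vapply(trained, function(t) t$result$composite_score, numeric(1))
  res <- data.frame(
    subset = vapply(trained, function(t) paste(t$regulators, collapse = ","),
                    character(1)),
    rs_raw = vapply(trained, function(t) t$result$rs_raw, numeric(1)),
    type = vapply(trained, function(t) t$result$regulation_type,
                  character(1)),
    rmse = vapply(trained, function(t) t$result$model_error, numeric(1)),
    cs = cs, stringsAsFactors = FALSE)
  ord <- order(cs, seq_along(cs))
  list(best = trained[utils::head(ord, config$n_final)],
       results = res[ord, , drop = FALSE])
}

#' Reconstruct a gene regulatory network
#'
#' Runs the three-stage regulator search with every gene as target and
#' assembles the signed network.  For each winning configuration one edge
#' is emitted per member regulator; its sign comes from that regulator's
#' single-input regulation score (stage 1) and its confidence from the
#' configuration's composite score.  Edges whose composite score exceeds
#' \code{cs_threshold}, or whose type is \code{"none"}, are dropped.
#' Identical data, configuration and seed give an identical edge list.
#'
#' @param data training [expression_dataset()] (>= 3 genes).
#' @param config a [pipeline_config()].
#' @param test_data optional held-out [expression_dataset()]: trained
#'   models are frozen and scored on it, mirroring a train/test protocol
#'   across experimental conditions.
#' @param verbose print per-target progress.
#' @return Data frame of edges (regulator, target, type, rs_raw,
#'   composite_score), sorted by (target, composite_score).
#' @export
reconstruct_network <- function(data, config = pipeline_config(),
                                test_data = NULL, verbose = FALSE) {
  genes <- rownames(data$values)
  if (length(genes) < 3) stop("need at least 3 genes")
  edges <- list()
  for (target in genes) {
    t0 <- Sys.time()
    s1 <- stage1_rank_candidates(data, target, config)
    s2 <- stage2_select_subsets(data, target, s1$candidates, config)
    s3 <- stage3_finalize(data, target, s2$subsets, config, test_data)
    for (conf in s3$best) {
      cs <- conf$result$composite_score
      if (cs > config$cs_threshold) next
      for (reg in conf$regulators) {
        single <- s1$results[s1$results$gene == reg, ]
        type <- single$type[1]
        if (type == "none") next
        edges[[length(edges) + 1]] <- data.frame(
          regulator = reg, target = target,
          type = if (type == "up") "+" else "-",
          rs_raw = single$rs_raw[1], composite_score = cs,
          stringsAsFactors = FALSE)
      }
    }
    if (verbose)
      message(sprintf("[%s] done in %.1fs (%d edge rows so far)", target,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      length(edges)))
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(regulator = character(0), target = character(0),
                         type = character(0), rs_raw = numeric(0),
                         composite_score = numeric(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$target, out$composite_score, out$regulator), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network edge list
#'
#' \code{tsv}: columns regulator, target, type, rs_raw, composite_score
#' with numbers at 6 significant digits.  \code{sif}: simple interaction
#' format with relation tokens \code{activates} / \code{represses}.
#' Rows are written in the stable (target, composite_score) order.
#'
#' @param edges edge data frame from [reconstruct_network()].
#' @param path file to write.
#' @param format \code{"tsv"} or \code{"sif"}.
#' @export
write_network <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- edges[order(edges$target, edges$composite_score,
                       edges$regulator), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("regulator\ttarget\ttype\trs_raw\tcomposite_score", con)
    if (nrow(edges))
      writeLines(sprintf("%s\t%s\t%s\t%.6g\t%.6g", edges$regulator,
                         edges$target, edges$type, edges$rs_raw,
                         edges$composite_score), con)
  } else {
    if (nrow(edges))
      writeLines(sprintf("%s\t%s\t%s", edges$regulator,
                         ifelse(edges$type == "+", "activates", "represses"),
                         edges$target), con)
  }
  invisible(path)
}

#' Read a TSV edge list written by [write_network()]
#'
#' @param path file to read.
#' @return Edge data frame.
#' @export
read_network <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "numeric"))
}
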