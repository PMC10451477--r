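#' Training-MSE fitness of a candidate subset
#'
#' Wrapper fitness used by both metaheuristic selectors: the configured base
#' learner (softmax discriminant by default) is trained on the subset and
#' the training mean squared error between the predicted-class target value
#' and the true-class target value is returned (`MSE = mean((O - T)^2)`
#' with targets 0.85 / 0.65). Perfect training classification gives 0; the
#' worst possible value is `(T_Adeno - T_Meso)^2 = 0.04`, which is also
#' returned as a penalty when the subset leaves only one class available
#' for training (possible when selecting subject columns).
#'
#' @param subset integer indices of the candidate columns (or rows).
#' @param features a [spectral_feature_set()] or plain feature x subject
#'   matrix.
#' @param labels per-subject labels; taken from `features` when omitted.
#' @param targets a `target_map` (defaults 0.85 / 0.65).
#' @param axis `"columns"` selects subject columns (the default, matching
#'   the per-class reduction of the feature matrix to 30 and 6 subjects);
#'   `"rows"` selects feature rows.
#' @param learner base learner name for [train_classifier()]
#'   (default `"sdc"`).
#' @param learner_params extra arguments for the learner; for the default
#'   softmax discriminant the epoch cap defaults to 200, plenty for a
#'   wrapper fitness.
#' @return Non-negative training MSE.
#' @export
fitness_mse <- function(subset, features, labels = NULL,
                        targets = .default_targets(),
                        axis = c("columns", "rows"), learner = "sdc",
                        learner_params = list()) {
  if (learner == "sdc" && is.null(learner_params$epochs)) {
    learner_params$epochs <- 200L
  }
  axis <- match.arg(axis)
  values <- if (inherits(features, "SpectralFeatures")) features$values else as.matrix(features)
  if (is.null(labels) && inherits(features, "SpectralFeatures")) {
    labels <- features$labels
  }
  if (is.null(labels)) stop("labels are required")
  labels <- .as_binary_factor(labels)
  if (length(subset) < 1L) stop("subset must be non-empty")
  limit <- if (axis == "columns") ncol(values) else nrow(values)
  if (any(subset < 1L | subset > limit)) {
    stop("subset references indices outside the candidate range")
  }
  if (axis == "columns") {
    design <- t(values[, subset, drop = FALSE])
    yy <- labels[subset]
  } else {
    design <- t(values[subset, , drop = FALSE])
    yy <- labels
  }
  if (length(unique(yy[!is.na(yy)])) < 2L) {
    return((targets$t_adeno - targets$t_meso)^2)
  }
  design <- scale_unit(design)
  model <- train_classifier(learner, design, yy, learner_params)
  pred <- classifier_predict(model, design)
  observed <- .label_targets(pred, targets)
  mse(observed, .label_targets(.as_binary_factor(yy), targets))
}

#' Particle swarm configuration
#'
#' Constriction-style defaults: inertia 0.72, cognitive and social weights
#' 1.49, swarm of 30, 100 iterations.
#'
#' @param subset_size number of candidates to select.
#' @param swarm_size particles (>= 2).
#' @param iterations velocity/position updates after the random
#'   initialisation (0 evaluates the initial swarm only).
#' @param inertia,c1,c2 velocity update weights (all > 0).
#' @param seed RNG seed; runs are pure functions of the configuration.
#' @return A `pso_config` list.
#' @export
pso_config <- function(subset_size, swarm_size = 30L, iterations = 100L,
                       inertia = 0.72, c1 = 1.49, c2 = 1.49, seed = 1L) {
  cfg <- list(subset_size = as.integer(subset_size),
              swarm_size = as.integer(swarm_size),
              iterations = as.integer(iterations),
              inertia = inertia, c1 = c1, c2 = c2, seed = as.integer(seed))
  if (cfg$swarm_size < 2L) stop("invalid config: swarm_size must be >= 2")
  if (cfg$subset_size < 1L) stop("invalid config: subset_size must be >= 1")
  if (cfg$inertia <= 0 || cfg$c1 <= 0 || cfg$c2 <= 0) {
    stop("invalid config: inertia, c1, c2 must be positive")
  }
  class(cfg) <- "pso_config"
  cfg
}

#' Harmony search configuration
#'
#' Literature defaults: memory 20, 200 improvisations, memory-consideration
#' rate 0.9, pitch-adjustment rate 0.3.
#'
#' @param subset_size number of candidates to select.
#' @param memory_size harmony memory size (>= 2).
#' @param iterations improvisations after initialisation.
#' @param hmcr memory-consideration probability in (0, 1].
#' @param par pitch-adjustment probability in [0, 1).
#' @param seed RNG seed.
#' @return An `hs_config` list.
#' @export
hs_config <- function(subset_size, memory_size = 20L, iterations = 200L,
                      hmcr = 0.9, par = 0.3, seed = 1L) {
  cfg <- list(subset_size = as.integer(subset_size),
              memory_size = as.integer(memory_size),
              iterations = as.integer(iterations),
              hmcr = hmcr, par = par, seed = as.integer(seed))
  if (cfg$memory_size < 2L) stop("invalid config: memory_size must be >= 2")
  if (cfg$subset_size < 1L) stop("invalid config: subset_size must be >= 1")
  class(cfg) <- "hs_config"
  cfg
}

# memoized fitness evaluation keyed on the sorted subset
.make_fitness_cache <- function(fitness) {
  cache <- new.env(parent = emptyenv())
  function(subset) {
    key <- paste(sort(subset), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness(sort(subset))
    cache[[key]] <- val
    val
  }
}

.selection_result <- function(method, indices, best_fitness, trace, config) {
  structure(list(method = method,
                 selected_indices = sort(as.integer(indices)),
                 best_fitness = best_fitness,
                 fitness_trace = trace, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: %d indices, best fitness %.6g after %d evaluations\n",
              toupper(x$method), length(x$selected_indices), x$best_fitness,
              length(x$fitness_trace)))
  invisible(x)
}

# keep exactly k bits set, preferring the highest flip probabilities;
# ties broken by lowest index (order() is stable)
.repair_bits <- function(bits, prob, k) {
  ord <- order(-prob, seq_along(prob))
  set_now <- which(bits > 0)
  if (length(set_now) > k) {
    keep <- set_now[order(-prob[set_now], set_now)][seq_len(k)]
    bits[] <- 0
    bits[keep] <- 1
  } else if (length(set_now) < k) {
    unset <- ord[!(ord %in% set_now)]
    bits[unset[seq_len(k - length(set_now))]] <- 1
  }
  bits
}

#' Particle swarm wrapper selection
#'
#' Binary PSO over candidate indices: one bit per candidate, velocities
#' updated with inertia plus cognitive/social attraction, squashed through
#' a logistic to per-bit set probabilities, sampled, and repaired to
#' exactly `subset_size` set bits (highest probability wins, lowest index
#' on ties). Returns the best subset ever evaluated; the best-so-far trace
#' is non-increasing by construction.
#'
#' @param features a [spectral_feature_set()] or feature x subject matrix.
#' @param labels per-subject labels (taken from `features` when omitted).
#' @param config a [pso_config()].
#' @param fitness fitness function of a sorted index vector; defaults to
#'   [fitness_mse()] on `features` along `axis`.
#' @param axis candidate axis, `"columns"` (default) or `"rows"`.
#' @param ... passed to [fitness_mse()] when the default fitness is used.
#' @return A `selection_result`.
#' @export
pso_select <- function(features, labels = NULL, config, fitness = NULL,
                       axis = c("columns", "rows"), ...) {
  axis <- match.arg(axis)
  values <- if (inherits(features, "SpectralFeatures")) features$values else as.matrix(features)
  n <- if (axis == "columns") ncol(values) else nrow(values)
  k <- config$subset_size
  if (k > n) stop("invalid config: subset_size exceeds the number of candidates")
  if (is.null(fitness)) {
    fitness <- function(subset) {
      fitness_mse(subset, features, labels, axis = axis, ...)
    }
  }
  eval_fit <- .make_fitness_cache(fitness)

  set.seed(config$seed)
  S <- config$swarm_size
  pos <- matrix(0, nrow = S, ncol = n)
  vel <- matrix(stats::runif(S * n, -1, 1), nrow = S)
  for (s in seq_len(S)) pos[s, sample.int(n, k)] <- 1
  fit <- apply(pos, 1L, function(bits) eval_fit(which(bits > 0)))
  pbest <- pos
  pbest_fit <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]
  gbest_fit <- fit[g]
  trace <- gbest_fit

  for (it in seq_len(max(config$iterations, 0L))) {
    for (s in seq_len(S)) {
      r1 <- stats::runif(n)
      r2 <- stats::runif(n)
      vel[s, ] <- config$inertia * vel[s, ] +
        config$c1 * r1 * (pbest[s, ] - pos[s, ]) +
        config$c2 * r2 * (gbest - pos[s, ])
      prob <- 1 / (1 + exp(-vel[s, ]))
      bits <- as.numeric(stats::runif(n) < prob)
      pos[s, ] <- .repair_bits(bits, prob, k)
      fs <- eval_fit(which(pos[s, ] > 0))
      if (fs < pbest_fit[s]) {
        pbest[s, ] <- pos[s, ]
        pbest_fit[s] <- fs
      }
      if (fs < gbest_fit) {
        gbest <- pos[s, ]
        gbest_fit <- fs
      }
    }
    trace <- c(trace, gbest_fit)
  }
  .selection_result("pso", which(gbest > 0), gbest_fit, trace, config)
}

#' Harmony search wrapper selection
#'
#' Each improvisation builds a new subset slot by slot: with probability
#' `hmcr` the slot is taken from a random harmony in memory (and pitch
#' adjusted to a neighbouring index with probability `par`), otherwise it
#' is drawn uniformly from the candidates. Duplicate slots are redrawn by
#' the same rule (falling back to unused values already in memory). The
#' worst memory entry is replaced whenever the improvisation improves on
#' it.
#'
#' @inheritParams pso_select
#' @param config an [hs_config()].
#' @return A `selection_result`.
#' @export
hs_select <- function(features, labels = NULL, config, fitness = NULL,
                      axis = c("columns", "rows"), ...) {
  axis <- match.arg(axis)
  values <- if (inherits(features, "SpectralFeatures")) features$values else as.matrix(features)
  n <- if (axis == "columns") ncol(values) else nrow(values)
  k <- config$subset_size
  if (k > n) stop("invalid config: subset_size exceeds the number of candidates")
  if (is.null(fitness)) {
    fitness <- function(subset) {
      fitness_mse(subset, features, labels, axis = axis, ...)
    }
  }
  eval_fit <- .make_fitness_cache(fitness)

  set.seed(config$seed)
  M <- config$memory_size
  memory <- t(vapply(seq_len(M), function(i) sort(sample.int(n, k)),
                     integer(k)))
  memory <- matrix(memory, nrow = M)
  mem_fit <- apply(memory, 1L, function(s) eval_fit(s))
  trace <- min(mem_fit)

  draw_slot <- function(d) {
    if (stats::runif(1) < config$hmcr) {
      v <- memory[sample.int(M, 1L), d]
      if (stats::runif(1) < config$par) {
        v <- v + sample(c(-1L, 1L), 1L)
        v <- min(max(v, 1L), n)
      }
      v
    } else {
      sample.int(n, 1L)
    }
  }

  for (it in seq_len(max(config$iterations, 0L))) {
    new <- integer(k)
    for (d in seq_len(k)) {
      v <- draw_slot(d)
      attempts <- 0L
      while (v %in% new[seq_len(d - 1L)] && attempts < 50L) {
        v <- draw_slot(d)
        attempts <- attempts + 1L
      }
      if (v %in% new[seq_len(d - 1L)]) {
        pool <- setdiff(as.integer(memory), new[seq_len(d - 1L)])
        if (length(pool) == 0L) pool <- setdiff(seq_len(n), new[seq_len(d - 1L)])
        v <- pool[sample.int(length(pool), 1L)]
      }
      new[d] <- v
    }
    new <- sort(new)
    f_new <- eval_fit(new)
    worst <- which.max(mem_fit)
    if (f_new < mem_fit[worst]) {
      memory[worst, ] <- new
      mem_fit[worst] <- f_new
    }
    trace <- c(trace, min(mem_fit))
  }
  best <- which.min(mem_fit)
  .selection_result("hs", memory[best, ], mem_fit[best], trace, config)
}

#' Friedman rank test across methods evaluated on common blocks
#'
#' Values are ranked within each block (average ranks on ties); the
#' statistic is `12 / (n k (k+1)) * sum(R_i^2) - 3 n (k+1)` with `R_i` the
#' rank sums over the `n` blocks for each of the `k` methods, compared to a
#' chi-square distribution with `k - 1` degrees of freedom. Identical
#' methods in every block give a statistic of exactly 0; the statistic
#' depends on the values only through their within-block ranks, so it is
#' invariant under any strictly monotone transform.
#'
#' @param performance numeric matrix, blocks in rows, methods in columns.
#' @return A `friedman_result`: `statistic`, `p_value`, `rank_sums`,
#'   `n_blocks`, `n_methods`.
#' @export
friedman_test <- function(performance) {
  performance <- as.matrix(performance)
  k <- ncol(performance)
  n <- nrow(performance)
  if (k < 2L) stop("invalid argument: need at least 2 methods")
  if (n < 2L) stop("invalid argument: need at least 2 blocks")
  ranks <- t(apply(performance, 1L, rank))
  R <- colSums(ranks)
  statistic <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  statistic <- max(statistic, 0)
  structure(list(statistic = statistic,
                 p_value = stats::pchisq(statistic, df = k - 1,
                                         lower.tail = FALSE),
                 rank_sums = R, n_blocks = n, n_methods = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi2_r = %.4f on %d df, p = %.5f (%d blocks, %d methods)\n",
              x$statistic, x$n_methods - 1L, x$p_value, x$n_blocks,
              x$n_methods))
  invisible(x)
}
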