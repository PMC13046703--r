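#' Particle swarm optimizer configuration
#'
#' Swarm hyperparameters: inertia weight decaying linearly from
#' `inertia_start` (0.9) to `inertia_end` (0.4) across iterations, both
#' acceleration constants 1.5, and uniform random factors in \[0, 1\].
#' Swarm size and iteration budget default to 30 particles and 50
#' iterations.
#'
#' @param swarm_size Number of particles.
#' @param max_iters Number of update iterations after the initial
#'   evaluation.
#' @param inertia_start,inertia_end Linear inertia schedule endpoints
#'   (`inertia_start >= inertia_end`).
#' @param accel_cognitive,accel_social Acceleration constants (> 0).
#' @param fitness_tolerance Optional early-stop threshold: the run ends as
#'   soon as the global best fitness reaches it (`NULL` = run to
#'   `max_iters`).
#' @param seed Integer seed.
#' @return A list of class `"pso_config"`.
#' @export
pso_config <- function(swarm_size = 30, max_iters = 50,
                       inertia_start = 0.9, inertia_end = 0.4,
                       accel_cognitive = 1.5, accel_social = 1.5,
                       fitness_tolerance = NULL, seed = 1) {
  if (swarm_size < 1 || max_iters < 1) {
    stop("'swarm_size' and 'max_iters' must be positive", call. = FALSE)
  }
  if (inertia_start < inertia_end) {
    stop("'inertia_start' must be >= 'inertia_end'", call. = FALSE)
  }
  if (accel_cognitive <= 0 || accel_social <= 0) {
    stop("acceleration constants must be > 0", call. = FALSE)
  }
  structure(list(swarm_size = swarm_size, max_iters = max_iters,
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 accel_cognitive = accel_cognitive,
                 accel_social = accel_social,
                 fitness_tolerance = fitness_tolerance, seed = seed),
            class = "pso_config")
}

#' Inertia weight at an iteration
#'
#' Linear decay `w(t) = w0 - (w0 - w1) * t / (max_iters - 1)` for
#' `0 <= t < max_iters`, so the first iteration uses `inertia_start` and
#' the last uses `inertia_end`.
#'
#' @param t Zero-based iteration index.
#' @param config A [pso_config()].
#' @return The inertia weight.
#' @export
#' @examples
#' inertia_at(0, pso_config(max_iters = 50))    # 0.9
#' inertia_at(49, pso_config(max_iters = 50))   # 0.4
inertia_at <- function(t, config) {
  if (t < 0 || t >= config$max_iters) {
    stop("'t' must satisfy 0 <= t < max_iters", call. = FALSE)
  }
  if (config$max_iters == 1) return(config$inertia_start)
  config$inertia_start - (config$inertia_start - config$inertia_end) *
    t / (config$max_iters - 1)
}

#' Define a box search space with an optional simplex group
#'
#' @param name Dimension names.
#' @param lower,upper Per-dimension bounds (`lower < upper`).
#' @param integer Logical; integer-valued dimensions are rounded after
#'   every move.
#' @param simplex_group Optional character triple of dimension names
#'   constrained to sum to 1 (each bounded within \[0, 1\]).
#' @return A list of class `"search_space"` with a `dims` data.frame.
#' @export
search_space <- function(name = character(), lower = numeric(),
                         upper = numeric(), integer = FALSE,
                         simplex_group = NULL) {
  integer <- rep_len(integer, length(name))
  dims <- data.frame(name = name, lower = lower, upper = upper,
                     integer = integer, stringsAsFactors = FALSE)
  if (any(dims$lower >= dims$upper)) {
    stop("each dimension needs lower < upper", call. = FALSE)
  }
  if (!is.null(simplex_group)) {
    if (!all(simplex_group %in% dims$name)) {
      stop("'simplex_group' names must be search dimensions", call. = FALSE)
    }
    sg <- dims[dims$name %in% simplex_group, ]
    if (any(sg$lower < 0) || any(sg$upper > 1)) {
      stop("simplex dimensions must have bounds within [0, 1]", call. = FALSE)
    }
  }
  structure(list(dims = dims, simplex_group = simplex_group),
            class = "search_space")
}

#' Named search-space presets for the tuned model variants
#'
#' The seven tuned model variants each ship a preset search space:
#' `svm-linear` (no tunables), `svm-poly` (`c1` in \[1/80, 1/40\], `c2` in
#' \[0.1, 3\], `c3` in \[2, 4\]), `svm-gaussian` (`sigma2` in \[10, 50\]),
#' `svm-sigmoid` (`a` in \[1/100, 1\], `c` in \[-5, 5\]), `svm-hybrid`
#' (the polynomial and Gaussian parameters plus mixture weights `m`, `n`,
#' `q` on the simplex), `bpnn` (hidden layers 1-5, neurons 2-40, learning
#' rate 0.001-0.1) and `rf` (trees 50-200, minimum leaf size 2-10).
#'
#' @param preset One of the seven preset names.
#' @return A [search_space()].
#' @export
model_search_space <- function(preset = c("svm-linear", "svm-poly",
                                          "svm-gaussian", "svm-sigmoid",
                                          "svm-hybrid", "bpnn", "rf")) {
  preset <- match.arg(preset)
  switch(preset,
    "svm-linear" = search_space(),
    "svm-poly" = search_space(c("c1", "c2", "c3"),
                              c(1 / 80, 0.1, 2), c(1 / 40, 3, 4)),
    "svm-gaussian" = search_space("sigma2", 10, 50),
    "svm-sigmoid" = search_space(c("a", "c"), c(1 / 100, -5), c(1, 5)),
    "svm-hybrid" = search_space(
      c("c1", "c2", "c3", "sigma2", "m", "n", "q"),
      c(1 / 80, 0.1, 2, 10, 0, 0, 0),
      c(1 / 40, 3, 4, 50, 1, 1, 1),
      simplex_group = c("m", "n", "q")),
    "bpnn" = search_space(
      c("hidden_layers", "neurons_per_layer", "learning_rate"),
      c(1, 2, 0.001), c(5, 40, 0.1),
      integer = c(TRUE, TRUE, FALSE)),
    "rf" = search_space(c("n_trees", "min_samples_leaf"),
                        c(50, 2), c(200, 10), integer = TRUE))
}

# Evaluate a fitness function without disturbing the swarm's RNG stream
# (model training may reset the seed internally).
.with_rng_shield <- function(f, x) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  state <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", state, envir = globalenv()))
  f(x)
}

.project_position <- function(x, space) {
  dims <- space$dims
  x <- pmin(pmax(x, dims$lower), dims$upper)
  if (any(dims$integer)) x[dims$integer] <- round(x[dims$integer])
  if (!is.null(space$simplex_group)) {
    ix <- match(space$simplex_group, dims$name)
    s <- sum(x[ix])
    if (s < 1e-6) {
      x[ix] <- stats::runif(length(ix))
      s <- sum(x[ix])
    }
    x[ix] <- x[ix] / s
  }
  x
}

#' One particle swarm update step
#'
#' Applies the canonical velocity and position update to a swarm state:
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, `x <- x + v`, with
#' velocities clamped to half the box width, positions clamped to bounds,
#' integer dimensions rounded and the simplex group renormalized to sum 1.
#' Personal and global bests are then refreshed (fitness is maximized), so
#' the global best fitness never decreases. Uses the current RNG stream;
#' seed upstream for reproducibility.
#'
#' @param state Swarm state as produced by [pso_optimize()] internals: a
#'   list with `positions`, `velocities`, `pbest_pos`, `pbest_fit`,
#'   `gbest_pos`, `gbest_fit`, `iter`.
#' @param fitness_fn Function mapping a named position vector to a scalar
#'   fitness (higher is better).
#' @param config A [pso_config()].
#' @param space A [search_space()].
#' @return The updated state, with `iter` advanced.
#' @export
pso_step <- function(state, fitness_fn, config, space) {
  dims <- space$dims
  d <- nrow(dims)
  np <- nrow(state$positions)
  w <- inertia_at(min(state$iter, config$max_iters - 1), config)
  vmax <- (dims$upper - dims$lower) / 2
  r1 <- matrix(stats::runif(np * d), np, d)
  r2 <- matrix(stats::runif(np * d), np, d)
  v <- w * state$velocities +
    config$accel_cognitive * r1 * (state$pbest_pos - state$positions) +
    config$accel_social * r2 *
      (matrix(state$gbest_pos, np, d, byrow = TRUE) - state$positions)
  v <- pmin(pmax(v, matrix(-vmax, np, d, byrow = TRUE)),
            matrix(vmax, np, d, byrow = TRUE))
  x <- state$positions + v
  for (i in seq_len(np)) x[i, ] <- .project_position(x[i, ], space)
  fits <- vapply(seq_len(np), function(i) {
    xi <- stats::setNames(x[i, ], dims$name)
    .with_rng_shield(fitness_fn, xi)
  }, 0)
  improved <- fits > state$pbest_fit
  state$pbest_pos[improved, ] <- x[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fits[improved]
  if (max(state$pbest_fit) > state$gbest_fit) {
    b <- which.max(state$pbest_fit)
    state$gbest_fit <- state$pbest_fit[b]
    state$gbest_pos <- state$pbest_pos[b, ]
  }
  state$positions <- x
  state$velocities <- v
  state$iter <- state$iter + 1
  state
}

#' Particle swarm optimization over a box/simplex search space
#'
#' Maximizes `fitness_fn` over the search space with a linearly decaying
#' inertia weight. Particles are initialized uniformly in the bounds
#' (simplex groups normalized), evaluated, then updated for
#' `config$max_iters` iterations or until `fitness_tolerance` is reached.
#' Reproducible under `config$seed`.
#'
#' An empty search space (the linear-kernel preset) is legal: the fitness
#' is evaluated once at the empty position.
#'
#' @param fitness_fn Function of a named position vector returning a scalar
#'   fitness (higher is better).
#' @param space A [search_space()].
#' @param config A [pso_config()].
#' @return List with `best_position` (named), `best_fitness`, `trace` (a
#'   data.frame of the per-iteration global best fitness; iteration 0 is
#'   the initial evaluation) and `evaluations`.
#' @export
#' @examples
#' sp <- search_space(c("x", "y"), c(-5, -5), c(5, 5))
#' res <- pso_optimize(function(p) -sum(p^2), sp,
#'                     pso_config(swarm_size = 10, max_iters = 20, seed = 1))
#' res$best_fitness
pso_optimize <- function(fitness_fn, space, config = pso_config()) {
  dims <- space$dims
  d <- nrow(dims)
  set.seed(as.integer(config$seed))
  if (d == 0) {
    fit <- .with_rng_shield(fitness_fn, stats::setNames(numeric(0),
                                                        character(0)))
    return(list(best_position = stats::setNames(numeric(0), character(0)),
                best_fitness = fit,
                trace = data.frame(iteration = 0, gbest_fitness = fit),
                evaluations = 1L))
  }
  np <- config$swarm_size
  x <- matrix(stats::runif(np * d, min = rep(dims$lower, each = np),
                           max = rep(dims$upper, each = np)), np, d)
  for (i in seq_len(np)) x[i, ] <- .project_position(x[i, ], space)
  fits <- vapply(seq_len(np), function(i) {
    .with_rng_shield(fitness_fn, stats::setNames(x[i, ], dims$name))
  }, 0)
  b <- which.max(fits)
  state <- list(positions = x, velocities = matrix(0, np, d),
                pbest_pos = x, pbest_fit = fits,
                gbest_pos = x[b, ], gbest_fit = fits[b], iter = 0L)
  trace <- data.frame(iteration = 0L, gbest_fitness = state$gbest_fit)
  evals <- np
  tol <- config$fitness_tolerance
  while (state$iter < config$max_iters &&
         (is.null(tol) || state$gbest_fit < tol)) {
    state <- pso_step(state, fitness_fn, config, space)
    evals <- evals + np
    trace <- rbind(trace, data.frame(iteration = state$iter,
                                     gbest_fitness = state$gbest_fit))
  }
  list(best_position = stats::setNames(state$gbest_pos, dims$name),
       best_fitness = state$gbest_fit, trace = trace,
       evaluations = evals)
}

#' Build an origin classifier from a preset and a search-space position
#'
#' Maps a named position vector from [model_search_space()] onto the
#' corresponding training call: kernel parameters for the SVM variants,
#' architecture and learning rate for the BPNN, forest size and leaf size
#' for the RF.
#'
#' @param preset Model preset name.
#' @param position Named numeric vector over the preset's dimensions (may
#'   be empty for `svm-linear`).
#' @param table Training chem table.
#' @param C SVM soft-margin cost.
#' @param group_by Label column.
#' @param seed Seed for the stochastic learners (BPNN, RF).
#' @param ... Extra arguments passed to the underlying trainer.
#' @return A fitted origin classifier.
#' @export
build_origin_classifier <- function(preset, position, table, C = 1,
                                    group_by = "region", seed = 1, ...) {
  pv <- function(nm) unname(position[[nm]])
  switch(preset,
    "svm-linear" = train_svm(table, kernel_spec("linear"), C = C,
                             group_by = group_by, ...),
    "svm-poly" = train_svm(table,
      kernel_spec("polynomial", c1 = pv("c1"), c2 = pv("c2"), c3 = pv("c3")),
      C = C, group_by = group_by, ...),
    "svm-gaussian" = train_svm(table,
      kernel_spec("gaussian", sigma2 = pv("sigma2")), C = C,
      group_by = group_by, ...),
    "svm-sigmoid" = train_svm(table,
      kernel_spec("sigmoid", a = pv("a"), c = pv("c")), C = C,
      group_by = group_by, ...),
    "svm-hybrid" = train_svm(table,
      kernel_spec("hybrid", c1 = pv("c1"), c2 = pv("c2"), c3 = pv("c3"),
                  sigma2 = pv("sigma2"), m = pv("m"), n = pv("n"),
                  q = pv("q")), C = C, group_by = group_by, ...),
    "bpnn" = train_bpnn(table, hidden_layers = pv("hidden_layers"),
                        neurons_per_layer = pv("neurons_per_layer"),
                        learning_rate = pv("learning_rate"),
                        group_by = group_by, seed = seed, ...),
    "rf" = train_rf(table, n_trees = pv("n_trees"),
                    min_samples_leaf = pv("min_samples_leaf"),
                    group_by = group_by, seed = seed),
    stop("unknown preset '", preset, "'", call. = FALSE))
}

#' Cross-validated accuracy fitness for swarm tuning
#'
#' Returns the fitness function used to tune a model preset: for a
#' candidate position it trains the model on each of `k` stratified folds'
#' complements and returns the mean validation-fold accuracy. The folds are
#' drawn once when the fitness is created and reused for every candidate,
#' so fitness values are comparable across the swarm.
#'
#' @param table Training-split chem table (the held-out test split must not
#'   be passed here).
#' @param preset Model preset name (see [model_search_space()]).
#' @param k Number of folds.
#' @param seed Seed for fold construction and the stochastic learners.
#' @param C SVM soft-margin cost.
#' @param group_by Label column.
#' @param ... Extra arguments forwarded to the trainer.
#' @return A function mapping a named position to mean CV accuracy in
#'   \[0, 1\].
#' @export
cv_fitness <- function(table, preset, k = 5, seed = 1, C = 1,
                       group_by = "region", ...) {
  table <- as_chem_table(table)
  labels <- table[[group_by]]
  folds <- stratified_kfold(labels, k = k, seed = seed)
  extra <- list(...)
  function(position) {
    accs <- vapply(folds, function(fold) {
      train_tbl <- table[-fold, , drop = FALSE]
      test_tbl <- table[fold, , drop = FALSE]
      model <- do.call(build_origin_classifier,
                       c(list(preset = preset, position = position,
                              table = train_tbl, C = C,
                              group_by = group_by, seed = seed), extra))
      mean(as.character(predict(model, test_tbl)) ==
             as.character(test_tbl[[group_by]]))
    }, 0)
    mean(accs)
  }
}

#' Tune a model preset with particle swarm optimization
#'
#' Convenience wrapper: builds the preset's search space and CV fitness and
#' runs [pso_optimize()].
#'
#' @inheritParams cv_fitness
#' @param config A [pso_config()].
#' @return List with `preset`, `best_position`, `best_fitness` (mean CV
#'   accuracy) and the optimization `trace`.
#' @export
pso_tune <- function(table, preset, config = pso_config(), k = 5,
                     C = 1, group_by = "region", ...) {
  space <- model_search_space(preset)
  fn <- cv_fitness(table, preset, k = k, seed = config$seed, C = C,
                   group_by = group_by, ...)
  res <- pso_optimize(fn, space, config)
  list(preset = preset, best_position = res$best_position,
       best_fitness = res$best_fitness, trace = res$trace)
}
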