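# Binary particle swarm optimisation over d x 3 selection masks.
#
# Two variants share the real-valued velocity update
#   v <- omega * v + alpha * r1 * (pbest - x) + beta * r2 * (gbest - x)
# and differ in how a real velocity becomes a bit update:
#   traditional: r1, r2 ~ U[0,1]; each bit is resampled as
#                x <- 1 if u < sigmoid(v) else 0, u ~ U[0,1];
#   improved:    r1, r2 are uniform draws from {0, 1}; v is quantised by the
#                sign function to {-1, 0, 1}; x <- clamp01(x + v).
# Fitness is the mean per-image summed-channel Frobenius reconstruction
# error of the masked expansion plus a sparsity charge lambda per set bit.
#
# One iteration = evaluate every particle's position, update pbest/gbest on
# strict improvement, then (except after the final evaluation) move. A run
# of T iterations therefore performs exactly swarm_size * T evaluations.
#
# Random draws, in order, per particle and step: r1 (d x 3, column-major),
# r2 (d x 3), and for the traditional variant a further u (d x 3) for the
# bit resampling. Initialisation draws, per particle: position (d x 3
# uniform bits), then velocity (d x 3 uniform over {-1,0,1}, unless
# velocity_init = "zero").

#' Configuration for a BPSO run
#'
#' Defaults are the settings the method was developed with: swarm of 50
#' particles, 100 iterations, inertia 1.5, cognitive weight 2, social
#' weight 1, sparsity penalty 0.001.
#'
#' @param swarm_size number of particles (>= 2).
#' @param iterations number of iterations `T` (>= 1); the run performs
#'   exactly `swarm_size * T` fitness evaluations.
#' @param inertia,cognitive,social the weights `omega`, `alpha`, `beta`
#'   of the velocity update (all > 0).
#' @param sparsity penalty `lambda` (>= 0) charged per selected component.
#' @param variant `"improved"` (sign-quantised velocities, additive clamped
#'   position update) or `"traditional"` (sigmoid transfer, probabilistic
#'   bit resampling).
#' @param seed integer seed; the run is a pure function of it.
#' @param velocity_init `"random_pm1"` (uniform over -1/0/1) or `"zero"`.
#' @param fitness_subset optional integer: evaluate fitness on only the
#'   first `fitness_subset` stack images (speed knob for large stacks).
#' @return a list of class `bpso_config`.
#' @export
bpso_config <- function(swarm_size = 50L, iterations = 100L,
                        inertia = 1.5, cognitive = 2, social = 1,
                        sparsity = 0.001,
                        variant = c("improved", "traditional"),
                        seed = 1L,
                        velocity_init = c("random_pm1", "zero"),
                        fitness_subset = NULL) {
  variant <- match.arg(variant)
  velocity_init <- match.arg(velocity_init)
  stopifnot(swarm_size >= 2, iterations >= 1,
            inertia > 0, cognitive > 0, social > 0, sparsity >= 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 sparsity = sparsity, variant = variant,
                 seed = as.integer(seed), velocity_init = velocity_init,
                 fitness_subset = fitness_subset),
            class = "bpso_config")
}

#' Initialise a swarm of particles
#'
#' Positions are i.i.d. uniform bits; velocities i.i.d. uniform over
#' `{-1, 0, 1}` (or all zero under `velocity_init = "zero"`); each pbest
#' starts at the initial position with `NA` fitness (the first iteration of
#' a run evaluates it). Draws come from the current RNG state; [run_bpso()]
#' seeds it from the config.
#'
#' @param config a [bpso_config()].
#' @param d number of components (mask rows).
#' @return list of `swarm_size` particles, each a list with `position`,
#'   `velocity` (`d x 3` matrices), `pbest`, `pbest_fitness`.
#' @export
init_swarm <- function(config, d) {
  stopifnot(inherits(config, "bpso_config"), d >= 1)
  lapply(seq_len(config$swarm_size), function(i) {
    pos <- matrix(as.numeric(stats::runif(d * 3L) < 0.5), d, 3L)
    vel <- if (config$velocity_init == "zero") {
      matrix(0, d, 3L)
    } else {
      matrix(floor(stats::runif(d * 3L) * 3) - 1, d, 3L)
    }
    list(position = pos, velocity = vel, pbest = pos, pbest_fitness = NA_real_)
  })
}

#' Sigmoid transfer function
#'
#' Maps a real velocity to the probability that a bit is set:
#' `S(v) = 1 / (1 + exp(-v))`.
#'
#' @param v numeric (vectorised).
#' @return values in (0, 1).
#' @export
sigmoid_transfer <- function(v) 1 / (1 + exp(-v))

#' Sign quantisation of a velocity
#'
#' Clips a real velocity to `{-1, 0, 1}` by its sign, the discrete jump
#' rule of the improved variant.
#'
#' @param v numeric (vectorised).
#' @return -1, 0 or 1 per element.
#' @export
sign_clip <- function(v) sign(v)

eval_swarm <- function(particles, fitness_fn, gbest, gbest_fitness) {
  for (i in seq_along(particles)) {
    f <- fitness_fn(particles[[i]]$position)
    if (!is.finite(f)) {
      stop("non-finite fitness for particle ", i, call. = FALSE)
    }
    if (is.na(particles[[i]]$pbest_fitness) || f < particles[[i]]$pbest_fitness) {
      particles[[i]]$pbest <- particles[[i]]$position
      particles[[i]]$pbest_fitness <- f
    }
    if (is.null(gbest) || f < gbest_fitness) {
      gbest <- particles[[i]]$position
      gbest_fitness <- f
    }
  }
  list(particles = particles, gbest = gbest, gbest_fitness = gbest_fitness,
       evaluations = length(particles))
}

move_swarm <- function(particles, gbest, config) {
  d3 <- length(particles[[1]]$position)
  dims <- dim(particles[[1]]$position)
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    if (config$variant == "traditional") {
      r1 <- matrix(stats::runif(d3), dims[1], dims[2])
      r2 <- matrix(stats::runif(d3), dims[1], dims[2])
      v <- config$inertia * p$velocity +
        config$cognitive * r1 * (p$pbest - p$position) +
        config$social * r2 * (gbest - p$position)
      u <- matrix(stats::runif(d3), dims[1], dims[2])
      x <- ifelse(u < sigmoid_transfer(v), 1, 0)
    } else {
      r1 <- matrix(floor(stats::runif(d3) * 2), dims[1], dims[2])
      r2 <- matrix(floor(stats::runif(d3) * 2), dims[1], dims[2])
      v <- sign_clip(config$inertia * p$velocity +
                       config$cognitive * r1 * (p$pbest - p$position) +
                       config$social * r2 * (gbest - p$position))
      x <- clamp01(p$position + v)
    }
    particles[[i]]$velocity <- v
    particles[[i]]$position <- x
  }
  particles
}

#' One BPSO step: move, evaluate, update bests
#'
#' Moves every particle under the chosen transfer rule, evaluates the new
#' positions, and updates pbest/gbest on strict improvement. Exposed mainly
#' for inspection and testing; [run_bpso()]/[bpso_optimize()] drive the
#' full loop. Consumes the current RNG stream.
#'
#' @param particles list of particles from [init_swarm()].
#' @param gbest current global best mask (`d x 3`).
#' @param gbest_fitness its fitness.
#' @param fitness_fn function(mask) -> finite numeric.
#' @param config a [bpso_config()]; `config$variant` selects the rule.
#' @return list with updated `particles`, `gbest`, `gbest_fitness`,
#'   `evaluations` (= number of particles).
#' @export
bpso_step <- function(particles, gbest, gbest_fitness, fitness_fn, config) {
  particles <- move_swarm(particles, gbest, config)
  eval_swarm(particles, fitness_fn, gbest, gbest_fitness)
}

#' @rdname bpso_step
#' @export
bpso_step_traditional <- function(particles, gbest, gbest_fitness, fitness_fn,
                                  config) {
  config$variant <- "traditional"
  bpso_step(particles, gbest, gbest_fitness, fitness_fn, config)
}

#' @rdname bpso_step
#' @export
bpso_step_improved <- function(particles, gbest, gbest_fitness, fitness_fn,
                               config) {
  config$variant <- "improved"
  bpso_step(particles, gbest, gbest_fitness, fitness_fn, config)
}

#' Selection fitness of a mask (explicit reconstruction route)
#'
#' `fitness(S) = mean_i sum_c || O_i^c - Ohat_i^c(S) ||_F + lambda * k`,
#' where `k` is the total number of set bits across all three channels.
#' This route reconstructs every image explicitly; [make_fitness_fn()]
#' provides the algebraically identical cached evaluation used inside the
#' optimiser.
#'
#' @param mask `d x 3` binary matrix.
#' @param stack an [image_stack()].
#' @param basis the stack's `projection_basis`.
#' @param lambda sparsity penalty per set bit.
#' @return numeric fitness value.
#' @export
mask_fitness <- function(mask, stack, basis, lambda = 0.001) {
  mask <- check_mask(mask, basis_dim(basis))
  errs <- vapply(stack, function(img) {
    pr <- project_image(img, basis)
    frobenius_error(img, reconstruct_image(pr, basis, mask))$total
  }, numeric(1))
  mean(errs) + lambda * sum(mask)
}

#' Build a fast fitness function over a stack
#'
#' With a full orthonormal basis the reconstruction residual of a mask is
#' carried entirely by the unselected coefficient columns:
#' `||O^c - Ohat^c||_F = sqrt(sum_{j unselected} ||Y_j^c||^2)`. The column
#' energies `||Y_j^c||^2` are precomputed per image, so each evaluation
#' costs O(d) per channel instead of a matrix reconstruction.
#'
#' @param stack an [image_stack()].
#' @param basis the stack's `projection_basis`.
#' @param lambda sparsity penalty.
#' @param subset optional: use only the first `subset` images.
#' @return `function(mask) -> numeric`, equal to [mask_fitness()] to
#'   rounding error.
#' @export
make_fitness_fn <- function(stack, basis, lambda = 0.001, subset = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  idx <- seq_len(if (is.null(subset)) length(stack) else
                   min(subset, length(stack)))
  d <- basis_dim(basis)
  # energy[[ch]] is d x n: squared l2 norms of coefficient columns
  energy <- lapply(1:3, function(ch) {
    vapply(idx, function(i) {
      y <- project_image(stack[[i]], basis)[[ch]]
      colSums(y^2)
    }, numeric(d))
  })
  total <- lapply(energy, colSums)  # per channel: length-n total energies
  n <- length(idx)
  function(mask) {
    mask <- check_mask(mask, d)
    err <- 0
    for (ch in 1:3) {
      sel <- crossprod(mask[, ch], energy[[ch]])  # 1 x n selected energy
      err <- err + sum(sqrt(pmax(total[[ch]] - sel[1, ], 0)))
    }
    err / n + lambda * sum(mask)
  }
}

#' Run BPSO over an arbitrary fitness function
#'
#' The generic driver: seeds a private RNG stream from the config,
#' initialises the swarm, and performs `iterations` evaluate-update-move
#' cycles (`swarm_size * iterations` evaluations in total). The best-so-far
#' trace is non-increasing by construction.
#'
#' @param fitness_fn function(mask `d x 3`) -> finite numeric to minimise.
#' @param d number of components.
#' @param config a [bpso_config()].
#' @return object of class `bpso_result`: list with `gbest` (mask),
#'   `gbest_fitness`, `trace` (length `iterations`), `evaluations`,
#'   `variant`, `seed`.
#' @export
bpso_optimize <- function(fitness_fn, d, config = bpso_config()) {
  stopifnot(inherits(config, "bpso_config"))
  with_seed(config$seed, {
    particles <- init_swarm(config, d)
    gbest <- NULL
    gbest_fitness <- Inf
    trace <- numeric(config$iterations)
    evals <- 0L
    for (t in seq_len(config$iterations)) {
      if (t > 1L) particles <- move_swarm(particles, gbest, config)
      st <- eval_swarm(particles, fitness_fn, gbest, gbest_fitness)
      particles <- st$particles
      gbest <- st$gbest
      gbest_fitness <- st$gbest_fitness
      evals <- evals + st$evaluations
      trace[t] <- gbest_fitness
    }
    structure(list(gbest = gbest, gbest_fitness = gbest_fitness,
                   trace = trace, evaluations = evals,
                   variant = config$variant, seed = config$seed),
              class = "bpso_result")
  })
}

#' Run BPSO feature selection on an image stack
#'
#' Convenience wrapper over [bpso_optimize()] with the cached
#' reconstruction-error fitness of [make_fitness_fn()].
#'
#' @param stack an [image_stack()].
#' @param basis the stack's `projection_basis`.
#' @param config a [bpso_config()]; `sparsity` and `fitness_subset` are
#'   taken from it.
#' @return a `bpso_result`.
#' @export
run_bpso <- function(stack, basis, config = bpso_config()) {
  fn <- make_fitness_fn(stack, basis, config$sparsity, config$fitness_subset)
  bpso_optimize(fn, basis_dim(basis), config)
}

#' @export
print.bpso_result <- function(x, ...) {
  cat(sprintf("bpso_result (%s): best fitness %s after %d evaluations, %d/%d bits set\n",
              x$variant, fmt_num(x$gbest_fitness), x$evaluations,
              sum(x$gbest), length(x$gbest)))
  invisible(x)
}

#' Enumerate all tri-channel masks of dimension d
#'
#' Exhaustive testbed helper: lists all `2^(3d)` binary `d x 3` masks.
#' Feasible only for very small `d` (d <= 5 or so).
#'
#' @param d number of components.
#' @return list of `d x 3` binary matrices, in binary counting order.
#' @export
enumerate_masks <- function(d) {
  stopifnot(d >= 1, 3 * d <= 24)
  nbits <- 3L * d
  lapply(0:(2^nbits - 1), function(k) {
    bits <- as.numeric(bitwAnd(bitwShiftR(k, 0:(nbits - 1L)), 1L))
    matrix(bits, d, 3L)
  })
}

#' Exhaustive minimisation over all masks
#'
#' Ground-truth oracle for small problems: evaluates every mask of
#' [enumerate_masks()] and returns the best (ties broken by enumeration
#' order, i.e. lowest binary code).
#'
#' @param fitness_fn function(mask) -> numeric.
#' @param d number of components.
#' @return list with `mask`, `fitness`, `cardinality`.
#' @export
exhaustive_search <- function(fitness_fn, d) {
  masks <- enumerate_masks(d)
  vals <- vapply(masks, fitness_fn, numeric(1))
  i <- which.min(vals)
  list(mask = masks[[i]], fitness = vals[i], cardinality = sum(masks[[i]]))
}
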