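# Swarm optimisation over selection masks: initialisation, transfer
# functions, single-step oracles, fitness, and full-run contracts.

test_that("swarm initialisation is seeded, shaped and unbiased", {
  cfg <- bpso_config(swarm_size = 5, iterations = 10, seed = 3)
  s1 <- withr::with_seed(3, init_swarm(cfg, 7))
  s2 <- withr::with_seed(3, init_swarm(cfg, 7))
  expect_identical(s1, s2)
  expect_length(s1, 5)
  for (p in s1) {
    expect_equal(dim(p$position), c(7L, 3L))
    expect_true(all(p$position %in% c(0, 1)))
    expect_true(all(p$velocity %in% c(-1, 0, 1)))
    expect_identical(p$pbest, p$position)
    expect_true(is.na(p$pbest_fitness))
  }

  zcfg <- bpso_config(swarm_size = 2, iterations = 1, velocity_init = "zero")
  z <- withr::with_seed(1, init_swarm(zcfg, 4))
  expect_true(all(z[[1]]$velocity == 0))

  # bit frequency over many seeded initialisations at d = 2
  cfg2 <- bpso_config(swarm_size = 2, iterations = 1)
  bits <- withr::with_seed(99, {
    unlist(lapply(1:10000, function(i) {
      lapply(init_swarm(cfg2, 2), `[[`, "position")
    }))
  })
  expect_gt(mean(bits), 0.49)
  expect_lt(mean(bits), 0.51)
})

test_that("transfer functions match their closed forms", {
  expect_equal(sigmoid_transfer(0), 0.5)
  v <- c(-3, -0.7, 0.2, 5)
  expect_equal(sigmoid_transfer(-v), 1 - sigmoid_transfer(v), tolerance = 1e-14)
  # e^-4 from the power series, independently of exp()
  e4 <- sum((-4)^(0:40) / factorial(0:40))
  expect_equal(sigmoid_transfer(4), 1 / (1 + e4), tolerance = 1e-12)

  expect_identical(sign_clip(-3), -1)
  expect_identical(sign_clip(0), 0)
  expect_identical(sign_clip(2.7), 1)
  expect_equal(sign_clip(c(-0.1, 0, 1e9)), c(-1, 0, 1))
})

test_that("at full consensus the traditional update resamples bits fairly", {
  # x = pbest = gbest and v = 0 force v' = 0, so each bit is Bernoulli(0.5)
  d <- 50
  pos <- matrix(1, d, 3)
  particles <- replicate(4, list(position = pos, velocity = matrix(0, d, 3),
                                 pbest = pos, pbest_fitness = 1), simplify = FALSE)
  cfg <- bpso_config(swarm_size = 4, iterations = 1, variant = "traditional")
  bits <- withr::with_seed(17, {
    st <- bpso_step_traditional(particles, pos, 1, function(m) sum(m) + 1, cfg)
    unlist(lapply(st$particles, `[[`, "position"))
  })
  expect_true(all(bits %in% c(0, 1)))
  expect_gt(mean(bits), 0.44)
  expect_lt(mean(bits), 0.56)
})

test_that("one traditional step matches a hand simulation of the draws", {
  d <- 1
  mk <- function(x, v, pb) list(position = matrix(x, d, 3),
                                velocity = matrix(v, d, 3),
                                pbest = matrix(pb, d, 3), pbest_fitness = NA)
  particles <- list(mk(c(1, 0, 1), c(0, 0, 0), c(1, 1, 0)),
                    mk(c(0, 1, 0), c(1, -1, 0), c(0, 1, 1)))
  gbest <- matrix(c(1, 1, 1), d, 3)
  fn <- function(m) sum(m) + 0.5
  cfg <- bpso_config(swarm_size = 2, iterations = 1, variant = "traditional")

  st <- withr::with_seed(23, bpso_step_traditional(particles, gbest, 3.5, fn, cfg))

  # replay the identical draw order: per particle r1 (3), r2 (3), u (3)
  sim <- withr::with_seed(23, {
    lapply(particles, function(p) {
      r1 <- matrix(runif(3), 1, 3)
      r2 <- matrix(runif(3), 1, 3)
      v <- 1.5 * p$velocity + 2 * r1 * (p$pbest - p$position) +
        1 * r2 * (gbest - p$position)
      u <- matrix(runif(3), 1, 3)
      list(v = v, x = ifelse(u < 1 / (1 + exp(-v)), 1, 0))
    })
  })
  for (i in 1:2) {
    expect_equal(st$particles[[i]]$velocity, sim[[i]]$v)
    expect_equal(st$particles[[i]]$position, sim[[i]]$x)
    # evaluation happened: pbest fitness now set
    expect_equal(st$particles[[i]]$pbest_fitness, fn(sim[[i]]$x))
  }
  expect_equal(st$evaluations, 2L)
})

test_that("one improved step matches a hand simulation of the draws", {
  d <- 1
  mk <- function(x, v, pb) list(position = matrix(x, d, 3),
                                velocity = matrix(v, d, 3),
                                pbest = matrix(pb, d, 3), pbest_fitness = NA)
  particles <- list(mk(c(1, 0, 0), c(-1, 0, 1), c(1, 1, 0)),
                    mk(c(0, 1, 1), c(0, 1, -1), c(1, 1, 1)))
  gbest <- matrix(c(0, 1, 1), d, 3)
  fn <- function(m) 3 - sum(m)
  cfg <- bpso_config(swarm_size = 2, iterations = 1, variant = "improved")

  st <- withr::with_seed(29, bpso_step_improved(particles, gbest, 2, fn, cfg))

  sim <- withr::with_seed(29, {
    lapply(particles, function(p) {
      r1 <- matrix(floor(runif(3) * 2), 1, 3)
      r2 <- matrix(floor(runif(3) * 2), 1, 3)
      v <- sign(1.5 * p$velocity + 2 * r1 * (p$pbest - p$position) +
                  1 * r2 * (gbest - p$position))
      x <- p$position + v
      x[x < 0] <- 0
      x[x > 1] <- 1
      list(v = v, x = x)
    })
  })
  for (i in 1:2) {
    expect_equal(st$particles[[i]]$velocity, sim[[i]]$v)
    expect_equal(st$particles[[i]]$position, sim[[i]]$x)
    expect_true(all(st$particles[[i]]$velocity %in% c(-1, 0, 1)))
    expect_true(all(st$particles[[i]]$position %in% c(0, 1)))
  }
})

test_that("improved position update clamps at the binary boundaries", {
  d <- 2
  pos <- matrix(1, d, 3)
  particles <- list(list(position = pos, velocity = matrix(1, d, 3),
                         pbest = pos, pbest_fitness = 1),
                    list(position = pos * 0, velocity = matrix(-1, d, 3),
                         pbest = pos * 0, pbest_fitness = 1))
  cfg <- bpso_config(swarm_size = 2, iterations = 1, variant = "improved")
  st <- withr::with_seed(5, bpso_step_improved(particles, pos, 1,
                                               function(m) sum(m), cfg))
  # particle 1: x = 1 with v = +1 stays 1; particle 2: x = 0 pulled by pbest 0
  expect_true(all(st$particles[[1]]$position == 1))
  expect_true(all(st$particles[[2]]$position %in% c(0, 1)))
})

test_that("mask fitness matches hand values and the cached route", {
  stk <- random_stack(4, 5, 3, seed = 71)
  b <- projection_basis(stk)
  lam <- 0.001

  # all-zeros mask: mean total Frobenius norm of the raw images
  zero_mask <- matrix(0, 3, 3)
  norms <- sapply(stk, function(im) sum(sapply(1:3, function(ch)
    sqrt(sum(im[, , ch]^2)))))
  expect_equal(mask_fitness(zero_mask, stk, b, lam), mean(norms),
               tolerance = 1e-10)

  # all-ones mask with the full basis: only the sparsity charge remains
  ones_mask <- matrix(1, 3, 3)
  expect_equal(mask_fitness(ones_mask, stk, b, lam), lam * 9, tolerance = 1e-7)

  # arbitrary masks: explicit per-image loop oracle vs both routes
  fn <- make_fitness_fn(stk, b, lam)
  set.seed(73)
  for (rep in 1:5) {
    m <- matrix(rbinom(9, 1, 0.5), 3, 3)
    loop <- mean(sapply(stk, function(im) {
      tot <- 0
      for (ch in 1:3) {
        y <- im[, , ch] %*% b[[ch]]$vectors
        sel <- which(m[, ch] == 1)
        rec <- if (length(sel)) y[, sel, drop = FALSE] %*%
          t(b[[ch]]$vectors[, sel, drop = FALSE]) else matrix(0, 5, 3)
        tot <- tot + sqrt(sum((im[, , ch] - rec)^2))
      }
      tot
    })) + lam * sum(m)
    expect_equal(mask_fitness(m, stk, b, lam), loop, tolerance = 1e-10)
    # the cached route agrees to ~sqrt(machine eps): near-complete masks
    # leave a residual that is a square root of a cancelled difference
    expect_equal(fn(m), loop, tolerance = 1e-6)
  }

  # subset evaluation restricts to the leading images
  fn2 <- make_fitness_fn(stk, b, lam, subset = 2)
  sub <- image_stack(stk[1:2])
  m <- matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3)
  expect_equal(fn2(m), mask_fitness(m, sub, projection_basis(stk), lam),
               tolerance = 1e-10)
})

test_that("full runs are reproducible with exact evaluation accounting", {
  tp <- toy_problem_d4()
  cfg <- bpso_config(swarm_size = 8, iterations = 15, seed = 42)
  r1 <- bpso_optimize(tp$fitness, 4, cfg)
  r2 <- bpso_optimize(tp$fitness, 4, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$evaluations, 8L * 15L)
  expect_length(r1$trace, 15)
  expect_true(all(diff(r1$trace) <= 0))
  expect_equal(r1$gbest_fitness, r1$trace[15])
  expect_equal(r1$gbest_fitness, tp$fitness(r1$gbest))
  expect_true(all(r1$gbest %in% c(0, 1)))

  rt <- bpso_optimize(tp$fitness, 4,
                      bpso_config(swarm_size = 8, iterations = 15, seed = 42,
                                  variant = "traditional"))
  expect_equal(rt$evaluations, 8L * 15L)
  expect_true(all(diff(rt$trace) <= 0))

  expect_error(bpso_optimize(function(m) NaN, 4, cfg), "non-finite")
})

test_that("swarm invariants hold across a driven run", {
  tp <- toy_problem_d4()
  cfg <- bpso_config(swarm_size = 6, iterations = 1, seed = 9)
  withr::with_seed(9, {
    particles <- init_swarm(cfg, 4)
    # seed gbest from the evaluated initial swarm before stepping
    f0 <- vapply(particles, function(p) tp$fitness(p$position), numeric(1))
    st <- list(particles = particles,
               gbest = particles[[which.min(f0)]]$position,
               gbest_fitness = min(f0))
    for (t in 1:30) {
      st <- bpso_step(st$particles, st$gbest, st$gbest_fitness, tp$fitness, cfg)
      for (p in st$particles) {
        expect_true(all(p$position %in% c(0, 1)))
        expect_true(all(p$velocity %in% c(-1, 0, 1)))
        expect_equal(p$pbest_fitness, tp$fitness(p$pbest))
      }
    }
  })
})

test_that("with no sparsity penalty the swarm converges to full selection", {
  stk <- random_stack(6, 5, 3, seed = 101)
  b <- projection_basis(stk)
  fn0 <- make_fitness_fn(stk, b, 0)
  hits <- sum(vapply(1:10, function(s) {
    r <- bpso_optimize(fn0, 3, bpso_config(swarm_size = 20, iterations = 50,
                                           seed = s, sparsity = 0,
                                           velocity_init = "zero"))
    all(r$gbest == 1)
  }, logical(1)))
  # the unpenalised optimum is the all-ones mask; the discrete-jump swarm
  # reaches it in the clear majority of seeds at this size
  expect_gt(hits, 5)
})

test_that("exhaustive-optimal cardinality is non-increasing in lambda", {
  stk <- random_stack(5, 5, 3, seed = 81)
  b <- projection_basis(stk)
  cards <- sapply(c(0, 0.001, 0.01, 0.1, 1), function(lam) {
    exhaustive_search(make_fitness_fn(stk, b, lam), 3)$cardinality
  })
  expect_true(all(diff(cards) <= 0))
})

test_that("mask enumeration covers the space exactly once", {
  masks <- enumerate_masks(2)
  expect_length(masks, 64)
  codes <- vapply(masks, function(m) paste(m, collapse = ""), character(1))
  expect_equal(anyDuplicated(codes), 0L)
  expect_true(all(vapply(masks, function(m) all(dim(m) == c(2, 3)), logical(1))))
})
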