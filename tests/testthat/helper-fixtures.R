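# Fixtures are built in code at test time; no binary data on disk.

# seeded stack of uniform-random images (the standard small toy)
random_stack <- function(n, h, w, seed = 1) {
  withr::with_seed(seed, {
    image_stack(replicate(n, array(stats::runif(h * w * 3), c(h, w, 3)),
                          simplify = FALSE))
  })
}

# a projection basis whose axes are the canonical unit vectors
identity_basis <- function(w) {
  chans <- lapply(1:3, function(i) list(vectors = diag(w), values = rep(1, w)))
  names(chans) <- c("R", "G", "B")
  structure(chans, class = "projection_basis", d = w)
}

# feature_projection with the same H x d coefficient matrix in each channel
uniform_projection <- function(y) {
  pr <- list(R = y, G = y, B = y)
  class(pr) <- "feature_projection"
  pr
}

# the d = 4 exhaustive testbed: seeded random stack, default sparsity
toy_problem_d4 <- function(lambda = 0.001) {
  stk <- random_stack(6, 5, 4, seed = 101)
  basis <- projection_basis(stk)
  list(stack = stk, basis = basis,
       fitness = make_fitness_fn(stk, basis, lambda))
}

# naive double-loop covariance, the independent oracle for channel_covariance
naive_covariance <- function(stack, ch) {
  n <- length(stack)
  w <- dim(stack[[1]])[2]
  m <- Reduce(`+`, lapply(stack, function(im) im[, , ch])) / n
  s <- matrix(0, w, w)
  for (i in seq_len(n)) {
    d <- stack[[i]][, , ch] - m
    for (a in seq_len(w)) for (b in seq_len(w)) {
      s[a, b] <- s[a, b] + sum(d[, a] * d[, b])
    }
  }
  s / n
}
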