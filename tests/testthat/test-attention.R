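# Independent scalar re-implementations (oracles) of the attention formulas,
# kept deliberately naive, against which the package's vectorised paths are
# checked.

oracle_channel_attention <- function(s, d_list, prm) {
  C <- length(d_list)
  e <- numeric(C)
  r <- numeric(C)
  for (c in seq_len(C)) {
    acc <- as.vector(prm$b_rc)
    for (j in seq_along(s)) acc <- acc + prm$W_rg[j] * s[j] + prm$W_rc[j] * d_list[[c]][j]
    r[c] <- 1 / (1 + exp(-acc))
    ec <- as.vector(prm$b_ec)
    for (j in seq_along(s)) {
      ec <- ec + prm$W_ec[j] * ((1 - r[c]) * s[j] + r[c] * d_list[[c]][j])
    }
    e[c] <- ec
  }
  z <- exp(e - max(e))
  alpha <- z / sum(z)
  agg <- numeric(length(s))
  for (c in seq_len(C)) agg <- agg + alpha[c] * d_list[[c]]
  list(alpha = alpha, fused = c(s, agg), rate = r)
}

oracle_time_scores <- function(h_seq, t, prm) {
  T_len <- length(h_seq)
  e <- numeric(T_len)
  for (i in seq_len(T_len)) {
    r <- 1 / (1 + exp(-(sum(prm$W_rt * h_seq[[t]]) + sum(prm$W_ri * h_seq[[i]]) +
                          as.vector(prm$b_rt))))
    e[i] <- sum(prm$W_et * ((1 - r) * h_seq[[t]] + r * h_seq[[i]])) + as.vector(prm$b_et)
  }
  z <- exp(e - max(e))
  z / sum(z)
}

oracle_gru_step <- function(x, h, prm) {
  z <- 1 / (1 + exp(-(prm$z$W %*% x + prm$z$U %*% h + prm$z$b)))
  r <- 1 / (1 + exp(-(prm$r$W %*% x + prm$r$U %*% h + prm$r$b)))
  n <- tanh(prm$n$W %*% x + r * (prm$n$U %*% h) + prm$n$b)
  as.vector((1 - z) * n + z * h)
}

test_that("the fusional rate is a sigmoid gate with the expected closed forms", {
  p <- 4L
  zero <- list(W_rg = matrix(0, p, 1L), W_rc = matrix(0, p, 1L), b_rc = matrix(0),
               W_ec = matrix(0, p, 1L), b_ec = matrix(0))
  expect_equal(fusional_rate(rnorm(p), rnorm(p), zero), 0.5)
  # unit weights along separate axes: r = sigmoid(1 + 1)
  prm <- zero
  prm$W_rg[1L] <- 1; prm$W_rc[2L] <- 1
  s <- c(1, 0, 0, 0); d <- c(0, 1, 0, 0)
  expect_equal(fusional_rate(s, d, prm), plogis(2), tolerance = 1e-9)
  expect_equal(plogis(2), 0.880797, tolerance = 1e-6)
  # strictly increasing in the bias
  r1 <- fusional_rate(s, d, prm)
  prm$b_rc <- matrix(0.3)
  expect_gt(fusional_rate(s, d, prm), r1)
  expect_error(fusional_rate(rnorm(3L), rnorm(4L), zero), "dimension")
})

test_that("attention energy blends the two views convexly", {
  p <- 5L
  withr::with_seed(8L, {
    prm <- channel_attention_params(p)
    s <- rnorm(p); d <- rnorm(p)
  })
  e0 <- attention_energy(s, d, 0, prm)
  e1 <- attention_energy(s, d, 1, prm)
  expect_equal(e0, sum(prm$W_ec * s) + as.vector(prm$b_ec), tolerance = 1e-12)
  expect_equal(e1, sum(prm$W_ec * d) + as.vector(prm$b_ec), tolerance = 1e-12)
  # equal views make the energy independent of the rate
  es <- vapply(c(0, 0.3, 0.7, 1), function(r) attention_energy(s, s, r, prm), numeric(1L))
  expect_lt(diff(range(es)), 1e-12)
  expect_error(attention_energy(s, d, 1.2, prm), "\\[0, 1\\]")
})

test_that("channel scores form a shift-invariant softmax simplex", {
  expect_equal(channel_scores(rep(0.7, 14L)), rep(1 / 14, 14L), tolerance = 1e-12)
  expect_equal(channel_scores(c(0, log(2))), c(1 / 3, 2 / 3), tolerance = 1e-12)
  e <- rnorm(6L)
  expect_equal(channel_scores(e), channel_scores(e + 123.4), tolerance = 1e-12)
  expect_error(channel_scores(c(1, NaN)), "non-finite")
  # numerically stable at energies of magnitude 1e4
  big <- channel_scores(c(1e4, -1e4, 0))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1, tolerance = 1e-12)
})

test_that("channel fusion concatenates the global view with the weighted aggregate", {
  p <- 3L
  s <- rnorm(p)
  d <- list(rnorm(p), rnorm(p), rnorm(p), rnorm(p))
  onehot <- c(0, 0, 1, 0)
  expect_equal(channel_fuse(s, d, onehot), c(s, d[[3L]]), tolerance = 1e-12)
  expect_length(channel_fuse(s, d, rep(0.25, 4L)), 2L * p)
  same <- list(d[[1L]], d[[1L]], d[[1L]], d[[1L]])
  expect_equal(channel_fuse(s, same, c(0.1, 0.2, 0.3, 0.4)), c(s, d[[1L]]),
               tolerance = 1e-12)
  expect_error(channel_fuse(s, d, c(0.5, 0.5, 0.5, 0.5)), "simplex")
})

test_that("the vectorised channel attention equals the scalar oracle at C = 3, p = 4", {
  withr::with_seed(13L, {
    prm <- channel_attention_params(4L)
    s <- rnorm(4L)
    d_list <- lapply(1:3, function(i) rnorm(4L))
  })
  ca <- sleepatt:::channel_attention_forward(
    sleepatt:::as_mat(s), do.call(rbind, d_list), prm)
  orc <- oracle_channel_attention(s, d_list, prm)
  expect_equal(as.vector(sleepatt:::nd_value(ca$alpha)), orc$alpha, tolerance = 1e-10)
  expect_equal(as.vector(sleepatt:::nd_value(ca$fused)), orc$fused, tolerance = 1e-10)
  expect_equal(as.vector(sleepatt:::nd_value(ca$rate)), orc$rate, tolerance = 1e-10)
  # and the public per-channel operations compose to the same result
  r3 <- fusional_rate(s, d_list[[3L]], prm)
  e3 <- attention_energy(s, d_list[[3L]], r3, prm)
  e_all <- vapply(1:3, function(c) {
    attention_energy(s, d_list[[c]], fusional_rate(s, d_list[[c]], prm), prm)
  }, numeric(1L))
  expect_equal(channel_scores(e_all), orc$alpha, tolerance = 1e-10)
  expect_equal(channel_fuse(s, d_list, channel_scores(e_all)), orc$fused,
               tolerance = 1e-10)
})

test_that("the bidirectional GRU matches a hand-rolled per-step oracle", {
  q <- 2L
  withr::with_seed(5L, {
    prm <- bgru_params(3L, q)
    x_seq <- lapply(1:3, function(i) rnorm(3L))
  })
  h <- bgru_forward(x_seq, prm)
  expect_length(h, 3L)
  expect_length(h[[1L]], 2L * q)

  # oracle: run both layers and directions step by step
  run_dir <- function(xs, prm_dir, reverse) {
    idx <- if (reverse) rev(seq_along(xs)) else seq_along(xs)
    hh <- rep(0, q)
    out <- vector("list", length(xs))
    for (t in idx) {
      hh <- oracle_gru_step(xs[[t]], hh, prm_dir)
      out[[t]] <- hh
    }
    out
  }
  l1f <- run_dir(x_seq, prm$layer1$fwd, FALSE)
  l1b <- run_dir(x_seq, prm$layer1$bwd, TRUE)
  l1 <- Map(c, l1f, l1b)
  l2f <- run_dir(l1, prm$layer2$fwd, FALSE)
  l2b <- run_dir(l1, prm$layer2$bwd, TRUE)
  oracle_h <- Map(c, l2f, l2b)
  for (t in 1:3) expect_equal(h[[t]], oracle_h[[t]], tolerance = 1e-12)

  # reversing the input turns the forward pass into the backward computation
  # at mirrored indices (single-direction property)
  fwd_rev <- run_dir(rev(x_seq), prm$layer1$fwd, FALSE)
  bwd_on_orig <- run_dir(x_seq, prm$layer1$fwd, TRUE)
  for (t in 1:3) expect_equal(fwd_rev[[t]], bwd_on_orig[[4L - t]], tolerance = 1e-12)

  expect_length(bgru_forward(x_seq[1L], prm), 1L)
  expect_error(bgru_forward(list(), prm), "empty")
})

test_that("time scores match brute force and have the degenerate closed forms", {
  q <- 3L
  withr::with_seed(17L, {
    prm <- time_attention_params(q)
    h_seq <- lapply(1:4, function(i) rnorm(2L * q))
  })
  for (t in 1:4) {
    expect_equal(time_scores(h_seq, t, prm), oracle_time_scores(h_seq, t, prm),
                 tolerance = 1e-12)
  }
  expect_equal(time_scores(h_seq[1L], 1L, prm), 1)
  same <- rep(h_seq[1L], 4L)
  expect_equal(time_scores(same, 2L, prm), rep(0.25, 4L), tolerance = 1e-12)
  expect_error(time_scores(h_seq, 5L, prm), "out of range")

  # vectorised tape path equals the public per-pair implementation
  H <- do.call(rbind, h_seq)
  ta <- sleepatt:::time_attention_forward(H, prm)
  for (t in 1:4) {
    expect_equal(as.vector(sleepatt:::nd_value(ta[[t]]$beta)),
                 time_scores(h_seq, t, prm), tolerance = 1e-10)
    expect_equal(as.vector(sleepatt:::nd_value(ta[[t]]$context)),
                 time_context(h_seq, time_scores(h_seq, t, prm)), tolerance = 1e-10)
  }
})

test_that("the aggregate context selects and averages; the literal form degenerates", {
  h_seq <- lapply(1:5, function(i) rnorm(6L))
  onehot <- c(0, 0, 0, 1, 0)
  expect_equal(time_context(h_seq, onehot), h_seq[[4L]], tolerance = 1e-12)
  expect_equal(time_context(h_seq, rep(0.2, 5L)),
               Reduce(`+`, h_seq) / 5, tolerance = 1e-12)
  # weighting the query state instead collapses to the query state for ANY
  # normalised beta: the degeneracy that motivates the aggregate form
  for (i in 1:5) {
    beta <- channel_scores(rnorm(5L))
    expect_equal(time_context(h_seq, beta, t = 2L, form = "literal"), h_seq[[2L]],
                 tolerance = 1e-12)
  }
  expect_error(time_context(h_seq, c(0.5, 0.5, 0.5, 0, 0)), "simplex")
})

test_that("attention weights stay on the simplex over many random draws", {
  worst <- 0
  for (i in 1:100) {
    withr::with_seed(3000L + i, {
      p <- sample(2:6, 1L)
      C <- sample(2:8, 1L)
      prm <- channel_attention_params(p)
      s <- rnorm(p, sd = 3)
      D <- matrix(rnorm(C * p, sd = 3), C, p)
      q <- sample(2:4, 1L)
      tprm <- time_attention_params(q)
      T_len <- sample(2:6, 1L)
      h_seq <- lapply(seq_len(T_len), function(t) rnorm(2L * q, sd = 3))
    })
    ca <- sleepatt:::channel_attention_forward(sleepatt:::as_mat(s), D, prm)
    alpha <- as.vector(sleepatt:::nd_value(ca$alpha))
    expect_true(all(alpha >= 0))
    worst <- max(worst, abs(sum(alpha) - 1))
    beta <- time_scores(h_seq, 1L, tprm)
    expect_true(all(beta >= 0))
    worst <- max(worst, abs(sum(beta) - 1))
  }
  expect_lt(worst, 1e-6)
})
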