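test_that("the full-scale configuration reproduces the published geometry", {
  spec <- default_encoder_spec()
  # stage 1 runs four parallel kernels 8/16/32/64
  expect_length(spec$stages_1d[[1L]]$branches, 4L)
  expect_identical(vapply(spec$stages_1d[[1L]]$branches, `[[`, integer(1L), "kernel"),
                   c(8L, 16L, 32L, 64L))
  withr::with_seed(1L, {
    enc <- build_encoder(c(rep(3840L, 8L), 1920L, 3840L, rep(1920L, 4L)),
                         montage_size = 14L, p = 128L, spec = spec)
  })
  expect_length(enc$params$channel, 14L)
  # stage-1 branches all emit length 1920 at L = 3840 (equal-length paddings)
  expect_true(all(vapply(enc$arch$channel[[1L]]$stages[[1L]]$conv_idx, nrow,
                         integer(1L)) == 1920L))
  # the final 2-D pool collapses the 14-row channel axis
  expect_identical(attr(enc$arch$global$stages[[3L]]$pool_idx, "out_hw")[1L], 1L)

  rec <- full_scale_record()
  es <- preprocess_record(rec)
  ep <- es$epochs[[1L]]
  d1 <- encode_channel(ep$channels[[1L]], enc, 1L)
  expect_length(d1, 128L)
  s <- encode_global(ep$matrix, enc)
  expect_length(s, 128L)
  expect_true(all(is.finite(c(d1, s))))
  # purity: repeated calls agree exactly
  expect_identical(encode_channel(ep$channels[[1L]], enc, 1L), d1)
})

test_that("the frequency-domain input length passes stage validation", {
  withr::with_seed(2L, {
    enc <- build_encoder(rep(1950L, 3L), montage_size = 3L, p = 16L,
                         spec = default_encoder_spec())
  })
  expect_length(encode_channel(rnorm(1950L), enc, 2L), 16L)
})

test_that("build-time validation rejects impossible stage pipelines", {
  expect_error(build_encoder(4L, montage_size = 1L, p = 8L,
                             spec = default_encoder_spec()),
               "reached 0")
  # unequal branch lengths are a configuration error
  bad <- toy_encoder_spec()
  bad$stages_1d[[1L]]$branches[[2L]]$padding <- 0L
  expect_error(build_encoder(960L, montage_size = 1L, p = 8L, spec = bad),
               "unequal")
})

test_that("builds are seed-deterministic and emit C + 1 independent encoders", {
  a <- withr::with_seed(9L, build_encoder(240L, 2L, p = 8L, spec = toy_encoder_spec()))
  b <- withr::with_seed(9L, build_encoder(240L, 2L, p = 8L, spec = toy_encoder_spec()))
  expect_identical(a$params, b$params)
  expect_length(a$params$channel, 2L)
  expect_false(identical(a$params$channel[[1L]], a$params$channel[[2L]]))
})

test_that("perturbing one channel's input changes only its own channel view", {
  seqs <- tiny_sequences()
  # seed chosen so the perturbed channel has live (non-saturated) ReLU units
  model <- tiny_model(seed = 5L)
  ep <- seqs[[1L]]$epochs[[1L]]
  mv1 <- encode_epoch(ep, model$encoder)
  ep2 <- ep
  ep2$channels[[1L]] <- ep2$channels[[1L]] + rnorm(length(ep2$channels[[1L]]))
  mv2 <- encode_epoch(ep2, model$encoder)
  expect_false(identical(mv1$d[[1L]], mv2$d[[1L]]))
  expect_identical(mv1$d[[2L]], mv2$d[[2L]])
  expect_length(mv1$d, 2L)
  expect_length(mv1$s, model$dims$p)
})

test_that("encoded features stay finite over repeated random draws", {
  model <- tiny_model()
  lens <- model$encoder$arch$input_lens
  for (i in 1:20) {
    withr::with_seed(1000L + i, {
      ep <- list(channels = lapply(lens, function(n) rnorm(n)),
                 matrix = matrix(rnorm(2L * max(lens)), 2L, max(lens)),
                 label = "WAKE", t_index = 1L)
    })
    mv <- encode_epoch(ep, model$encoder)
    expect_true(all(is.finite(unlist(mv$d))) && all(is.finite(mv$s)))
  }
})

test_that("scaling a nonnegative input by k >= 1 never shrinks max-pooled activations", {
  # constrained toy instance: nonnegative conv weights, zero biases, ReLU
  spec <- toy_encoder_spec()
  withr::with_seed(3L, {
    enc <- build_encoder(240L, 1L, p = 4L, spec = spec)
  })
  flat_enc <- enc$params$channel[[1L]]
  for (s in seq_along(flat_enc$stages)) {
    for (b in seq_along(flat_enc$stages[[s]])) {
      flat_enc$stages[[s]][[b]]$W <- abs(flat_enc$stages[[s]][[b]]$W)
    }
  }
  enc$params$channel[[1L]] <- flat_enc
  x <- abs(rnorm(240L))
  pre_act <- function(x) {
    sleepatt:::nd_value(sleepatt:::conv_stack_forward(
      sleepatt:::as_mat(x), flat_enc$stages, enc$arch$channel[[1L]]))
  }
  a1 <- pre_act(x)
  a2 <- pre_act(2 * x)
  expect_true(all(a2 >= a1 - 1e-12))
})
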