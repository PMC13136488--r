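tiny_config <- function(c_n = 1L) {
  model_config(m = 3L, c_n = c_n, hidden = 4L, n_layers = 2L, latent = 3L)
}

test_that("reparameterisation matches its closed form", {
  mu <- matrix(1:6 / 2, 2, 3); lv <- matrix(0, 2, 3)
  expect_equal(reparameterise(mu, lv, 0), mu)
  nu <- matrix(rnorm(6), 2, 3)
  expect_equal(reparameterise(mu, lv, nu), mu + nu)
  # logvar = 2 ln 3 gives noise standard deviation 3
  set.seed(2)
  n <- matrix(rnorm(1e5), ncol = 1)
  z <- reparameterise(matrix(0, 1e5, 1), matrix(2 * log(3), 1e5, 1), n)
  expect_equal(sd(z), 3, tolerance = 0.02)
})

test_that("forward pass dimensions follow the concatenation contract", {
  cfg <- model_config(m = 6L, c_n = 1L)
  p <- cvae_init(cfg, seed = 1)
  # encoder input width m + c_n, decoder input width H + c_n, output m
  expect_equal(dim(p$enc1_W), c(7L, 32L))
  expect_equal(dim(p$dec1_W), c(33L, 32L))
  expect_equal(dim(p$out_W), c(32L, 6L))
  cfg2 <- model_config(m = 6L, c_n = 2L)
  p2 <- cvae_init(cfg2, seed = 1)
  expect_equal(dim(p2$dec1_W), c(34L, 32L))

  X <- matrix(runif(12 * 6), 12); C <- matrix(runif(12), 12)
  fw1 <- cvae_forward(p, X, C, 0, cfg)
  fw2 <- cvae_forward(p, X, C, 0, cfg)
  expect_identical(fw1$y, fw2$y)   # pure function
  expect_equal(dim(fw1$y), c(12L, 6L))
  expect_equal(dim(fw1$mu), c(12L, 32L))
})

test_that("loss components satisfy their analytic anchors", {
  # per-dimension KL at the standard normal is zero; mu = 1, logvar = 0
  # gives 1/2 per dimension; nonnegative everywhere
  expect_equal(kl_term(matrix(0, 2, 3), matrix(0, 2, 3)),
               matrix(0, 2, 3))
  expect_equal(kl_term(1, 0), 0.5)
  set.seed(3)
  mu <- matrix(rnorm(100, sd = 3), 10); lv <- matrix(rnorm(100, sd = 2), 10)
  expect_true(all(kl_term(mu, lv) >= 0))

  # perfect reconstruction has zero mse: feed x through an identity-like
  # check by constructing the loss from a forward pass with y replaced
  cfg <- tiny_config()
  p <- cvae_init(cfg, seed = 2)
  X <- matrix(runif(15), 5, 3); C <- matrix(runif(5), 5, 1)
  fw <- cvae_forward(p, X, C, 0, cfg)
  fw$y <- fw$X
  ls <- cvae_loss(fw, train_config(seed = 1))
  expect_equal(ls$mse, 0)

  # contrastive component vanishes when all label similarities equal the
  # threshold
  C1 <- matrix(sqrt(0.9), 4, 1)
  fwc <- cvae_forward(p, matrix(runif(12), 4, 3), C1, 0, cfg)
  tc <- train_config(seed = 1, contrastive = TRUE,
                     contrastive_threshold = 0.9)
  expect_equal(cvae_loss(fwc, tc)$contrastive, 0, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  tc <- train_config(seed = 1, kl_weight = 1e-2, contrastive = TRUE,
                     contrastive_weight = 0.1)
  set.seed(10)
  p <- cvae_init(cfg, seed = 10)
  X <- matrix(runif(5 * 3), 5); C <- matrix(runif(5), 5)
  eps <- matrix(rnorm(5 * 3), 5, 3)
  fw <- cvae_forward(p, X, C, eps, cfg)
  g <- rnacircgen:::cvae_grad(p, fw, tc, cfg)
  total <- function(par) {
    cvae_loss(cvae_forward(par, X, C, eps, cfg), tc)$total
  }
  h <- 1e-5
  for (nm in names(p)) {
    idx <- seq_len(min(6L, length(p[[nm]])))
    for (k in idx) {
      pp <- p; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- p; pm[[nm]][k] <- pm[[nm]][k] - h
      fd <- (total(pp) - total(pm)) / (2 * h)
      expect_equal(g[[nm]][k], fd, tolerance = 1e-4,
                   label = paste("grad", nm, k))
    }
  }
})

test_that("learning-rate schedule warms up linearly then decays to zero", {
  expect_equal(lr_schedule(0), 0)
  expect_equal(lr_schedule(10), 5e-4)
  expect_equal(lr_schedule(20), 1e-3)
  expect_equal(lr_schedule(2000), 0, tolerance = 1e-18)
  expect_true(all(diff(lr_schedule(20:2000)) <= 0))
})

test_that("training is deterministic and reduces the loss", {
  ds <- demo_dataset()
  tc <- train_config(seed = 5, max_epochs = 30L, val_acc_stop = 2,
                     batch_size = 128L)
  m1 <- train_cvae(ds, tconf = tc)
  m2 <- train_cvae(ds, tconf = tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
  # warmup: learning rate ramps towards the peak over the first 20 epochs
  expect_equal(m1$history$lr[20], 1e-3)
  expect_lt(m1$history$lr[1], 1e-4)
})

test_that("a trained model reconstructs held-out circuits accurately", {
  mod <- demo_model()
  ds <- demo_dataset()
  expect_gt(mod$best_val_acc, 0.9)
  expect_gt(reconstruction_r2(mod, ds), 0.95)
  # generation is reproducible, prompt-tagged, and inverse-normalised
  gen1 <- cvae_generate(mod, c(0.2, 0.8), n_per_prompt = 25, seed = 3,
                        feature_state = ds$feature_state)
  gen2 <- cvae_generate(mod, c(0.2, 0.8), n_per_prompt = 25, seed = 3,
                        feature_state = ds$feature_state)
  expect_identical(gen1, gen2)
  expect_equal(nrow(gen1), 50L)
  expect_setequal(unique(gen1$prompt1), c(0.2, 0.8))
  expect_true(all(c("k11", "k33") %in% names(gen1)))
  # prompts outside [0, 1] are accepted (extrapolation)
  genx <- cvae_generate(mod, seq(-0.2, 1.2, length.out = 10),
                        n_per_prompt = 2, seed = 1)
  expect_equal(nrow(genx), 20L)
  expect_error(cvae_generate(structure(list(trained = FALSE),
                                       class = "cvae_model"), 0.5),
               "not trained")
})
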