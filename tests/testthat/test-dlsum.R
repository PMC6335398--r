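sim_one_pop_bank <- function(n, mu, size = 10000, L = 2e4, chunk = 2e4) {
  reg <- tibble::tibble(region = 1L, L_r = L, L_c = L, recomb_rate = 1e-8)
  lapply(seq_len(n), function(i) {
    simulate_joint_sfs(one_pop_spec(size), regions = reg,
                       samples = c(POP = 4L), mu = mu, chunk_length = chunk)
  })
}

fake_net <- function(W1, b1, W2, b2, W3, b3, head = "linear",
                     labels = NULL) {
  structure(list(weights = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                                W3 = W3, b3 = b3),
                 mu = rep(0, nrow(W1)), sd = rep(1, nrow(W1)),
                 hidden = c(ncol(W1), ncol(W2)), head = head,
                 layout = list(pops = "RAW", n_hap = nrow(W1)),
                 labels = labels, targets = paste0("t", seq_len(ncol(W3))),
                 target_center = rep(0, ncol(W3)),
                 target_scale = rep(1, ncol(W3)),
                 normalize = "raw", log = tibble::tibble(), metric = NULL),
            class = "summary_net")
}

test_that("noise injection satisfies its cellwise identities and the loop oracle", {
  set.seed(3)
  s <- simulate_joint_sfs(one_pop_spec(), regions = tiny_regions(1e4),
                          samples = c(POP = 4L), mu = 1.61e-8)
  r <- simulate_joint_sfs(one_pop_spec(), regions = tiny_regions(1e4),
                          samples = c(POP = 4L), mu = 1.61e-8)
  expect_equal(inject_noise(s, r, 0)$counts, s$counts)
  expect_equal(inject_noise(s, r, 1)$counts, r$counts)
  expect_equal(inject_noise(s, r, 0.5)$counts, (s$counts + r$counts) / 2)

  # scalar loop oracle on random vectors
  a <- runif(12); b <- runif(12); alpha <- 0.37
  got <- inject_noise(a, b, alpha)
  want <- numeric(12)
  for (j in 1:12) want[j] <- (1 - alpha) * a[j] + alpha * b[j]
  expect_equal(got, want)

  expect_error(inject_noise(a, b[1:5], 0.1), "mismatch")
  expect_error(inject_noise(s, r, 1.5), "alpha")
  sp2 <- simulate_joint_sfs(one_pop_spec(), regions = tiny_regions(1e4),
                            samples = c(POP = 2L), mu = 1.61e-8)
  expect_error(inject_noise(s, sp2, 0.1), "layout")
})

test_that("a single-label training set is rejected", {
  set.seed(4)
  bank <- build_training_set(sim_one_pop_bank(6, 1.61e-8), labels = rep("A", 6))
  expect_error(train_classifier_net(bank), "two model labels")
})

test_that("two models separated by a fourfold mutation rate are classified almost perfectly", {
  set.seed(8)
  n <- 1000
  # ten independent loci per record keep genealogical variance well below the
  # fourfold rate contrast
  bank <- build_training_set(
    c(sim_one_pop_bank(n, 1.61e-8, L = 2e5),
      sim_one_pop_bank(n, 4 * 1.61e-8, L = 2e5)),
    labels = rep(c("slow", "fast"), each = n)
  )
  # the two models differ in total mutation input, so raw counts carry the
  # signal that the proportion normalization is designed to remove
  net <- train_classifier_net(bank, hyper = list(epochs = 30, normalize = "raw"))
  expect_gt(net$metric[["heldout_accuracy"]], 0.95)

  # softmax outputs sum to one
  probs <- summarize_sfs(net, bank$x[1:50, ])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
})

test_that("an all-zero classifier returns the uniform distribution over models", {
  p <- 6
  net <- fake_net(matrix(0, p, 4), rep(0, 4), matrix(0, 4, 3), rep(0, 3),
                  matrix(0, 3, 3), rep(0, 3), head = "softmax",
                  labels = c("A", "B", "C"))
  out <- summarize_sfs(net, runif(p))
  expect_equal(unname(out), rep(1 / 3, 3))
})

test_that("the forward pass equals an independently coded matrix-multiply oracle", {
  set.seed(12)
  p <- 7
  net <- fake_net(matrix(rnorm(p * 5), p, 5), rnorm(5),
                  matrix(rnorm(5 * 4), 5, 4), rnorm(4),
                  matrix(rnorm(4 * 2), 4, 2), rnorm(2))
  x <- rnorm(p)
  got <- summarize_sfs(net, x)
  expect_equal(unname(got), oracle_forward(net, matrix(x, 1)))

  # purity: the summary depends only on weights and input
  expect_identical(summarize_sfs(net, x), summarize_sfs(net, x))
})

test_that("training with alpha_max zero is bit-identical to classical training", {
  set.seed(21)
  bank <- build_training_set(
    c(sim_one_pop_bank(60, 1.61e-8), sim_one_pop_bank(60, 6e-8)),
    labels = rep(c("a", "b"), each = 60)
  )
  ref <- sfs_vector(simulate_joint_sfs(one_pop_spec(), regions = tiny_regions(2e4),
                                       samples = c(POP = 4L), mu = 1.61e-8))
  hyper <- list(epochs = 5)
  set.seed(99)
  n1 <- train_classifier_net(bank, noise = noise_spec(ref, alpha_max = 0),
                             hyper = hyper)
  set.seed(99)
  n2 <- train_classifier_net(bank, noise = NULL, hyper = hyper)
  expect_identical(n1$weights, n2$weights)
})

test_that("regression rejects constant targets and recovers a strongly identified parameter", {
  set.seed(31)
  bank <- build_training_set(sim_one_pop_bank(20, 1.61e-8),
                             params = tibble::tibble(n_pop = rep(5000, 20)))
  expect_error(train_regressor_net(bank, targets = "n_pop"), "zero variance")
  expect_error(train_regressor_net(bank, targets = "nope"), "unknown target")

  # population size of a single deme is strongly identified by its SFS
  set.seed(32)
  n <- 2000
  sizes <- exp(runif(n, log(2e3), log(5e4)))
  reg <- tiny_regions(2e5)
  sims <- lapply(sizes, function(s) {
    simulate_joint_sfs(one_pop_spec(s), regions = reg, samples = c(POP = 4L),
                       mu = 1.61e-8)
  })
  bank2 <- build_training_set(sims, params = tibble::tibble(n_pop = sizes))
  # raw counts: with a single population the size signal is the total
  # mutation input, which the proportion normalization deliberately removes
  net <- train_regressor_net(bank2, targets = "n_pop",
                             hyper = list(epochs = 80, normalize = "raw"))
  expect_gt(net$metric[["heldout_cor_n_pop"]], 0.9)
})

test_that("ghost-population sizes are far less learnable than sampled-population sizes", {
  set.seed(44)
  m <- build_model("H")
  draws <- sample_parameters(m, 400)
  reg <- region_table(0.001)
  pops <- c("AFR", "ASN", "PAP", "NEAN", "DENI")
  sims <- lapply(seq_len(400), function(i) {
    marginalize_sfs(simulate_joint_sfs(m, draws[i, ], regions = reg), pops)
  })
  bank <- build_training_set(sims, params = draws)
  net <- train_regressor_net(bank, targets = c("n_afr", "n_xe"),
                             hyper = list(epochs = 60))
  expect_gt(net$metric[["heldout_cor_n_afr"]],
            net$metric[["heldout_cor_n_xe"]] + 0.2)
})

test_that("network serialization restores a bit-identical forward pass", {
  set.seed(61)
  bank <- build_training_set(
    c(sim_one_pop_bank(40, 1.61e-8), sim_one_pop_bank(40, 6e-8)),
    labels = rep(c("a", "b"), each = 40)
  )
  net <- train_classifier_net(bank, hyper = list(epochs = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_net(net, path)
  net2 <- read_net(path)
  x <- bank$x[3, ]
  expect_identical(summarize_sfs(net, x), summarize_sfs(net2, x))

  lg <- glance(net)
  expect_s3_class(lg, "tbl_df")
  expect_equal(lg$head, "softmax")
  expect_s3_class(tidy(net), "tbl_df")
})
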