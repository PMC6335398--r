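make_quad_table <- function(w, x, y, z, block = NULL, n_hap = 2) {
  n <- length(w)
  allele_count_table(tibble::tibble(
    block = block %||% rep(1L, n),
    d_W = as.integer(w * n_hap), n_W = rep(n_hap, n),
    d_X = as.integer(x * n_hap), n_X = rep(n_hap, n),
    d_Y = as.integer(y * n_hap), n_Y = rep(n_hap, n),
    d_Z = as.integer(z * n_hap), n_Z = rep(n_hap, n)
  ))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("f4 site terms follow the defining product and vanish for identical columns", {
  # single ABBA-type site: (0 - 1)(1 - 0) = -1
  tab <- make_quad_table(0, 1, 1, 0)
  res <- f4(tab, c("W", "X", "Y", "Z"))
  expect_equal(attr(res, "f4"), -1)

  # W = X at every site -> f4 = 0
  set.seed(1)
  w <- sample(0:2, 30, replace = TRUE) / 2
  y <- sample(0:2, 30, replace = TRUE) / 2
  z <- sample(0:2, 30, replace = TRUE) / 2
  tab2 <- make_quad_table(w, w, y, z)
  expect_equal(attr(f4(tab2, c("W", "X", "Y", "Z")), "f4"), 0)

  # 20-site random table equals the brute-force site loop
  tab3 <- random_count_table(20, c("W", "X", "Y", "Z"), n_blocks = 3, seed = 5)
  got <- f4(tab3, c("W", "X", "Y", "Z"))
  oracle <- oracle_quad_stats(tab3, c("W", "X", "Y", "Z"))
  expect_equal(sum(got$num), oracle$num)
  expect_equal(attr(got, "f4"), oracle$num / oracle$n)
})

test_that("Patterson's D matches brute force, hits its boundary and respects symmetry", {
  # only ABBA-type sites -> D = -1
  tab <- make_quad_table(rep(0, 6), rep(1, 6), rep(1, 6), rep(0, 6),
                         block = rep(1:3, each = 2))
  expect_equal(patterson_d(tab, c("W", "X", "Y", "Z"))$D, -1)

  # balanced ABBA and BABA -> D = 0
  tab0 <- make_quad_table(c(1, 0), c(0, 1), c(1, 1), c(0, 0), block = c(1, 2))
  expect_equal(patterson_d(tab0, c("W", "X", "Y", "Z"))$D, 0)

  # 50-site fixture with equal-size blocks: D and SE equal brute force plus
  # the textbook delete-one jackknife
  set.seed(9)
  tab50 <- random_count_table(50, c("W", "X", "Y", "Z"), n_blocks = 5)
  tab50$block <- rep(1:5, each = 10)  # equal weights
  got <- patterson_d(tab50, c("W", "X", "Y", "Z"))
  oracle <- oracle_quad_stats(tab50, c("W", "X", "Y", "Z"))
  expect_equal(got$D, oracle$num / oracle$den)
  bn <- bd <- numeric(5)
  for (b in 1:5) {
    sub <- tab50[tab50$block == b, ]
    o <- oracle_quad_stats(sub, c("W", "X", "Y", "Z"))
    bn[b] <- o$num; bd[b] <- o$den
  }
  jk <- oracle_unweighted_jackknife(bn, bd)
  expect_equal(got$SE, jk$se, tolerance = 1e-12)

  # antisymmetry: swapping W and X negates D exactly
  rev <- patterson_d(tab50, c("X", "W", "Y", "Z"))
  expect_equal(rev$D, -got$D)
  expect_equal(rev$SE, got$SE)

  # no informative sites -> explicit error, not NaN
  flat <- make_quad_table(rep(1, 4), rep(1, 4), rep(0, 4), rep(0, 4),
                          block = c(1, 1, 2, 2))
  expect_error(patterson_d(flat, c("W", "X", "Y", "Z")), "denominator|informative")
})

test_that("the weighted block jackknife nails its closed-form special cases", {
  # identical blocks -> zero variance
  jk <- weighted_block_jackknife(matrix(c(2, 2, 2, 4, 4, 4), 3),
                                 c(5, 5, 5), statistic = function(s) s[1] / s[2])
  expect_equal(jk$estimate, 0.5)
  expect_equal(jk$se, 0)

  # equal weights reduce to the textbook delete-one jackknife
  set.seed(2)
  bn <- rnorm(8, 10); bd <- rnorm(8, 20)
  jk2 <- weighted_block_jackknife(cbind(bn, bd), rep(7, 8),
                                  statistic = function(s) s[1] / s[2])
  oracle <- oracle_unweighted_jackknife(bn, bd)
  expect_equal(jk2$estimate, oracle$estimate)
  expect_equal(jk2$se, oracle$se, tolerance = 1e-12)

  # two unequal blocks, every quantity written out by hand
  bn <- c(1, 3); bd <- c(2, 4); wts <- c(10, 30)
  theta <- 4 / 6
  tm1 <- 3 / 4   # delete block 1
  tm2 <- 1 / 2   # delete block 2
  n <- 40; h <- n / wts
  theta_dot <- 2 * theta - ((1 - 10 / 40) * tm1 + (1 - 30 / 40) * tm2)
  tau <- h * theta - (h - 1) * c(tm1, tm2)
  var_hand <- mean((tau - theta_dot)^2 / (h - 1))
  jk3 <- weighted_block_jackknife(cbind(bn, bd), wts,
                                  statistic = function(s) s[1] / s[2])
  expect_equal(jk3$estimate, theta)
  expect_equal(jk3$se, sqrt(var_hand))

  expect_error(weighted_block_jackknife(matrix(1, 1, 1), 1), "2 blocks")
})

test_that("jackknife standard errors shrink like one over the square root of the block count", {
  set.seed(33)
  gs <- c(10, 40, 160, 640)
  mean_se <- vapply(gs, function(g) {
    mean(replicate(30, {
      sums <- rnorm(g, mean = 5)  # one iid site per block, equal weights
      weighted_block_jackknife(cbind(sums, rep(1, g)), rep(1, g),
                               statistic = function(s) s[1] / s[2])$se
    }))
  }, numeric(1))
  slope <- -coef(lm(log(mean_se) ~ log(gs)))[2]
  expect_gt(slope, 0.4)
  expect_lt(slope, 0.6)
})

test_that("the f4 ratio is exactly 1 for identical quadruples", {
  tab <- random_count_table(60, c("W", "X", "Y", "Z"), n_blocks = 4, seed = 13)
  r <- suppressWarnings(
    f4_ratio(tab, c("W", "X", "Y", "Z"), c("W", "X", "Y", "Z"))
  )
  expect_equal(r$ratio, 1)
  expect_equal(r$SE, 0)
})

# admixture scenario for ratio recovery: X receives a pulse of fraction alpha
# from NEI, the sister of the second archaic sample NE2; the canonical ratio
# f4(Anc, NE1; X, AFR) / f4(Anc, NE1; NE2, AFR) then estimates alpha
admixture_spec <- function(alpha) {
  demes <- c("AFR", "X", "NE1", "NE2", "NEI")
  ev <- tibble::tibble(
    time = c(1500, 1600, 2000, 4000, 10000),
    type = "mass_move",
    a = c("X", "NEI", "X", "NE2", "NE1"),
    b = c("NEI", "NE2", "AFR", "NE1", "AFR"),
    p = c(alpha, 1, 1, 1, 1)
  )
  if (alpha == 0) ev <- ev[-1, ]
  simulator_spec(demes, stats::setNames(rep(10000, 5), demes), events = ev)
}

test_that("the f4 ratio recovers a known admixture fraction", {
  for (alpha in c(0, 0.05, 0.2)) {
    set.seed(1000 + round(alpha * 100))
    L <- 5e6; chunk <- 2.5e4
    sim <- simulate_sites(admixture_spec(alpha),
                          regions = tibble::tibble(region = 1L, L_r = L, L_c = L,
                                                   recomb_rate = 1e-8),
                          samples = c(AFR = 2L, X = 2L, NE1 = 2L, NE2 = 2L),
                          chunk_length = chunk, mu = 1.61e-8)
    counts <- allele_count_table(tibble::tibble(
      block = assign_blocks(sim$sites$pos, L, n_blocks = L / chunk),
      d_AFR = rowSums(sim$sites[, c("AFR.1", "AFR.2")]), n_AFR = 2L,
      d_X = rowSums(sim$sites[, c("X.1", "X.2")]), n_X = 2L,
      d_NE1 = rowSums(sim$sites[, c("NE1.1", "NE1.2")]), n_NE1 = 2L,
      d_NE2 = rowSums(sim$sites[, c("NE2.1", "NE2.2")]), n_NE2 = 2L
    ))
    r <- f4_ratio(counts, c("Ancestral", "NE1", "X", "AFR"),
                  c("Ancestral", "NE1", "NE2", "AFR"))
    expect_lt(abs(r$ratio - alpha), 2 * r$SE + 1e-9)
  }
})

test_that("a true outgroup yields null D in nearly all replicate simulations", {
  demes <- c("W", "X", "Y")
  ev <- tibble::tibble(time = c(1000, 4000), type = "mass_move",
                       a = c("X", "Y"), b = c("W", "W"), p = 1)
  sp <- simulator_spec(demes, c(W = 10000, X = 10000, Y = 10000), events = ev)
  set.seed(55)
  L <- 1e6; chunk <- 5e4
  zs <- replicate(100, {
    sim <- simulate_sites(sp, regions = tibble::tibble(region = 1L, L_r = L,
                                                       L_c = L, recomb_rate = 1e-8),
                          samples = c(W = 2L, X = 2L, Y = 2L),
                          chunk_length = chunk, mu = 1.61e-8)
    counts <- allele_count_table(tibble::tibble(
      block = assign_blocks(sim$sites$pos, L, n_blocks = L / chunk),
      d_W = rowSums(sim$sites[, c("W.1", "W.2")]), n_W = 2L,
      d_X = rowSums(sim$sites[, c("X.1", "X.2")]), n_X = 2L,
      d_Y = rowSums(sim$sites[, c("Y.1", "Y.2")]), n_Y = 2L
    ))
    patterson_d(counts, c("W", "X", "Y", "Ancestral"))$Z_score
  })
  expect_gte(mean(abs(zs) < 3), 0.95)
})

test_that("missing data drops sites listwise per quadruple", {
  tab <- make_quad_table(c(0, 1, 0), c(1, 0, 1), c(1, 1, 1), c(0, 0, 0),
                         block = c(1, 1, 2))
  tab$d_Y[2] <- NA_integer_
  res <- f4(tab, c("W", "X", "Y", "Z"))
  expect_equal(sum(res$n_sites), 2)
})
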