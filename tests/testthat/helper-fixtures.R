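# Shared fixtures and independent oracles, built in code at test time.

# brute-force site-by-site D / f4 oracle (independent of the package's
# grouped implementation)
oracle_quad_stats <- function(counts, quad) {
  freq <- function(label) {
    if (identical(label, "Ancestral")) return(rep(0, nrow(counts)))
    counts[[paste0("d_", label)]] / counts[[paste0("n_", label)]]
  }
  w <- freq(quad[1]); x <- freq(quad[2]); y <- freq(quad[3]); z <- freq(quad[4])
  keep <- !(is.na(w) | is.na(x) | is.na(y) | is.na(z))
  num <- den <- 0
  for (i in which(keep)) {
    num <- num + (w[i] - x[i]) * (y[i] - z[i])
    den <- den + (w[i] + x[i] - 2 * w[i] * x[i]) * (y[i] + z[i] - 2 * y[i] * z[i])
  }
  list(num = num, den = den, n = sum(keep))
}

# textbook unweighted delete-one jackknife of a ratio statistic
oracle_unweighted_jackknife <- function(block_num, block_den) {
  g <- length(block_num)
  theta <- sum(block_num) / sum(block_den)
  theta_minus <- vapply(seq_len(g), function(j) {
    sum(block_num[-j]) / sum(block_den[-j])
  }, numeric(1))
  pseudo <- g * theta - (g - 1) * theta_minus
  list(estimate = theta, se = sqrt(stats::var(pseudo) / g))
}

# hand-rolled dense forward pass used as the matrix-multiply oracle
oracle_forward <- function(net, x) {
  relu <- function(v) pmax(v, 0)
  a1 <- relu(as.vector(x %*% net$weights$W1) + net$weights$b1)
  a2 <- relu(as.vector(a1 %*% net$weights$W2) + net$weights$b2)
  as.vector(a2 %*% net$weights$W3) + net$weights$b3
}

# small constant-size single-population scenario
one_pop_spec <- function(n = 10000) {
  simulator_spec("POP", c(POP = n))
}

tiny_regions <- function(L = 1e5, n = 1) {
  tibble::tibble(region = seq_len(n), L_r = L, L_c = L, recomb_rate = 1e-8)
}

# random allele-count table over given populations
random_count_table <- function(n_sites, pops, n_blocks = 5, n_hap = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- list(block = sample.int(n_blocks, n_sites, replace = TRUE))
  for (p in pops) {
    cols[[paste0("d_", p)]] <- sample(0:n_hap, n_sites, replace = TRUE)
    cols[[paste0("n_", p)]] <- rep(n_hap, n_sites)
  }
  allele_count_table(tibble::as_tibble(cols))
}
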