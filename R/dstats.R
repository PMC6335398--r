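#' Per-site, per-population derived-allele count table
#'
#' The input of the D/F4 machinery: one row per polarized site with, for each
#' population `P`, a derived count column `d_P` and a total-allele-count
#' column `n_P`, plus a `block` column assigning the site to a contiguous
#' genome block for the jackknife.
#'
#' @param sites a data frame with columns `block`, `d_<POP>` and `n_<POP>`.
#' @return the validated table (class `allele_count_table`).
#' @export
allele_count_table <- function(sites) {
  stopifnot(is.data.frame(sites), "block" %in% names(sites))
  pops <- sub("^d_", "", grep("^d_", names(sites), value = TRUE))
  if (!length(pops)) stop("no d_<POP> columns found")
  for (p in pops) {
    d <- sites[[paste0("d_", p)]]; n <- sites[[paste0("n_", p)]]
    if (is.null(n)) stop("missing total column n_", p)
    ok <- is.na(d) | is.na(n) | (d >= 0 & d <= n)
    if (!all(ok)) stop("derived counts outside [0, total] for ", p)
  }
  if (any(is.na(sites$block))) stop("every site needs a block id")
  out <- tibble::as_tibble(sites)
  attr(out, "pops") <- pops
  class(out) <- c("allele_count_table", class(out))
  out
}

# derived-allele frequency of a (possibly pooled) population label;
# "Ancestral" is the constant-0 outgroup column
quad_freq <- function(counts, label) {
  if (identical(label, "Ancestral")) return(rep(0, nrow(counts)))
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  d <- rep(0, nrow(counts)); n <- rep(0, nrow(counts)); miss <- rep(FALSE, nrow(counts))
  for (p in parts) {
    dp <- counts[[paste0("d_", p)]]; np <- counts[[paste0("n_", p)]]
    if (is.null(dp)) stop("population not in table: ", p)
    miss <- miss | is.na(dp) | is.na(np) | np == 0
    d <- d + ifelse(is.na(dp), 0, dp); n <- n + ifelse(is.na(np), 0, np)
  }
  out <- d / n
  out[miss] <- NA_real_
  out
}

quad_terms <- function(counts, quad) {
  stopifnot(length(quad) == 4)
  w <- quad_freq(counts, quad[1]); x <- quad_freq(counts, quad[2])
  y <- quad_freq(counts, quad[3]); z <- quad_freq(counts, quad[4])
  keep <- !(is.na(w) | is.na(x) | is.na(y) | is.na(z))
  list(
    block = counts$block[keep],
    num = ((w - x) * (y - z))[keep],
    den = ((w + x - 2 * w * x) * (y + z - 2 * y * z))[keep]
  )
}

#' Per-block f4 sums for a population quadruple
#'
#' The f4 statistic is the mean over sites of `(w - x)(y - z)` on
#' derived-allele frequencies of the quadruple (W, X; Y, Z). Sites with
#' missing data in any of the four populations are dropped listwise. Per-block
#' sums and site counts are returned so the block jackknife can be applied;
#' the total f4 is their weighted mean.
#'
#' @param counts an [allele_count_table()].
#' @param quad character vector (W, X, Y, Z); `"Ancestral"` denotes the
#'   constant-0 outgroup, and `"A+B"` pools two populations.
#' @return tibble with columns `block`, `num` (sum of site terms), `n_sites`;
#'   attribute `f4` holds the genome-wide estimate.
#' @export
f4 <- function(counts, quad) {
  tm <- quad_terms(counts, quad)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(block = tm$block, num = tm$num), .data$block),
    num = sum(.data$num), n_sites = dplyr::n(), .groups = "drop"
  )
  attr(out, "f4") <- if (sum(out$n_sites) > 0) sum(out$num) / sum(out$n_sites) else NA_real_
  attr(out, "quad") <- quad
  out
}

#' Weighted delete-one-block jackknife
#'
#' Busing-style weighted jackknife over contiguous genome blocks: the
#' statistic is recomputed with each block deleted and the variance combines
#' the pseudovalues with block-size weights. With equal weights this reduces
#' to the textbook unweighted delete-one jackknife.
#'
#' @param block_stats per-block component sums: a numeric vector or a matrix
#'   with one row per block.
#' @param block_weights per-block site counts (positive).
#' @param statistic function mapping the column sums of `block_stats` to the
#'   scalar estimate; the default treats a vector of per-block sums as a
#'   weighted mean (`sum(stats) / sum(weights)`).
#' @return list with `estimate`, `se`, `n_blocks`.
#' @export
weighted_block_jackknife <- function(block_stats, block_weights, statistic = NULL) {
  if (is.vector(block_stats)) block_stats <- matrix(block_stats, ncol = 1)
  g <- nrow(block_stats)
  if (g < 2) stop("jackknife needs at least 2 blocks")
  stopifnot(length(block_weights) == g, all(block_weights > 0))
  if (is.null(statistic)) {
    # weighted mean of per-site values: per-block sums over per-block weights
    block_stats <- cbind(block_stats, block_weights)
    statistic <- function(s) s[1] / s[2]
  }
  totals <- colSums(block_stats)
  theta_hat <- unname(statistic(totals))
  theta_minus <- unname(vapply(seq_len(g), function(j) {
    statistic(totals - block_stats[j, ])
  }, numeric(1)))
  ok <- is.finite(theta_minus)
  if (!any(ok)) stop("all delete-one-block estimates are undefined")
  if (!all(ok)) {
    warning(sum(!ok), " delete-one-block estimate(s) undefined; ",
            "excluded from the jackknife variance")
    theta_minus <- theta_minus[ok]
    block_weights <- block_weights[ok]
    g <- sum(ok)
  }
  n <- sum(block_weights)
  h <- n / block_weights
  theta_dot <- g * theta_hat - sum((1 - block_weights / n) * theta_minus)
  tau <- h * theta_hat - (h - 1) * theta_minus
  var_j <- mean((tau - theta_dot)^2 / (h - 1))
  list(estimate = theta_hat, se = sqrt(max(var_j, 0)), n_blocks = g)
}

#' Patterson's D statistic with block-jackknife standard error
#'
#' `D = sum (w - x)(y - z) / sum (w + x - 2wx)(y + z - 2yz)` over sites, on
#' derived-allele frequencies of (W, X; Y, Z). The sign convention makes
#' `D(AFR, ASN, NEAN, Ancestral)` negative when ASN shares excess derived
#' alleles with the Neanderthal. The standard error comes from the weighted
#' block jackknife over the `block` column.
#'
#' @inheritParams f4
#' @return a one-row tibble (class `dstat_result`) with columns `W`, `X`,
#'   `Y`, `Z`, `D`, `SE`, `Z_score`, `n_blocks`, `n_sites`.
#' @export
patterson_d <- function(counts, quad) {
  tm <- quad_terms(counts, quad)
  if (!length(tm$num)) stop("no informative sites for this quadruple")
  bl <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(block = tm$block, num = tm$num, den = tm$den),
                    .data$block),
    num = sum(.data$num), den = sum(.data$den), n_sites = dplyr::n(),
    .groups = "drop"
  )
  if (sum(bl$den) == 0) stop("zero denominator: no informative sites")
  jk <- weighted_block_jackknife(
    as.matrix(bl[, c("num", "den")]), bl$n_sites,
    statistic = function(s) s[1] / s[2]
  )
  out <- tibble::tibble(
    W = quad[1], X = quad[2], Y = quad[3], Z = quad[4],
    D = jk$estimate, SE = jk$se,
    Z_score = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
    n_blocks = jk$n_blocks, n_sites = sum(bl$n_sites)
  )
  class(out) <- c("dstat_result", class(out))
  out
}

#' F4-ratio estimate of an admixture proportion
#'
#' Ratio of two f4 statistics, e.g.
#' `f4(Outgroup, Y; W, X) / f4(Outgroup, Y; W, Xref)`, with the standard
#' error obtained by jackknifing the whole ratio block by block.
#'
#' @inheritParams f4
#' @param num_quad quadruple of the numerator f4.
#' @param den_quad quadruple of the denominator f4.
#' @param tol denominators smaller than this (in absolute value) raise an
#'   error instead of returning an unstable ratio.
#' @return a one-row tibble (class `f4_ratio_result`) with `ratio`, `SE`,
#'   `n_blocks` and the two quadruples.
#' @export
f4_ratio <- function(counts, num_quad, den_quad, tol = 1e-12) {
  fn <- f4(counts, num_quad)
  fd <- f4(counts, den_quad)
  bl <- dplyr::full_join(
    dplyr::rename(fn, num = "num", n_num = "n_sites"),
    dplyr::rename(fd, den = "num", n_den = "n_sites"),
    by = "block"
  )
  bl[is.na(bl)] <- 0
  stat <- function(s) (s[1] / s[2]) / (s[3] / s[4])
  totals <- colSums(as.matrix(bl[, c("num", "n_num", "den", "n_den")]))
  if (abs(totals[3] / totals[4]) < tol) {
    stop("denominator f4 indistinguishable from 0")
  }
  jk <- weighted_block_jackknife(
    as.matrix(bl[, c("num", "n_num", "den", "n_den")]),
    pmax(bl$n_num + bl$n_den, 1),
    statistic = stat
  )
  out <- tibble::tibble(
    ratio = jk$estimate, SE = jk$se, n_blocks = jk$n_blocks,
    num_quad = paste(num_quad, collapse = ","),
    den_quad = paste(den_quad, collapse = ",")
  )
  class(out) <- c("f4_ratio_result", class(out))
  out
}

#' D statistic computed directly from a joint SFS
#'
#' Equivalent to [patterson_d()] without block structure: every SFS cell
#' contributes its count times the site term at the cell's derived-allele
#' frequencies. Pooled labels (`"PAP+AUS"`) sum the component axes;
#' `"Ancestral"` is frequency 0.
#'
#' @param sfs a `joint_sfs`.
#' @param quad quadruple of population labels.
#' @return the D estimate (scalar).
#' @export
d_from_sfs <- function(sfs, quad) {
  labels <- setdiff(unique(unlist(strsplit(quad, "+", fixed = TRUE))), "Ancestral")
  marg <- marginalize_sfs(sfs, labels)
  grid <- do.call(expand.grid, lapply(dim(marg$counts), function(k) 0:(k - 1)))
  names(grid) <- marg$pops
  cnt <- as.vector(marg$counts)
  freq_of <- function(label) {
    if (identical(label, "Ancestral")) return(rep(0, nrow(grid)))
    parts <- strsplit(label, "+", fixed = TRUE)[[1]]
    idx <- match(parts, marg$pops)
    rowSums(grid[, idx, drop = FALSE]) / sum(marg$n_hap[idx])
  }
  w <- freq_of(quad[1]); x <- freq_of(quad[2])
  y <- freq_of(quad[3]); z <- freq_of(quad[4])
  num <- sum(cnt * (w - x) * (y - z))
  den <- sum(cnt * (w + x - 2 * w * x) * (y + z - 2 * y * z))
  if (den == 0) stop("zero denominator: no informative sites")
  num / den
}

# the five observed quadruples used for simulation-based introgression fitting
FIT_QUADS <- list(
  c("EUR", "AFR", "NEAN", "Ancestral"),
  c("ASN", "AFR", "NEAN", "Ancestral"),
  c("PAP+AUS", "AFR", "DENI", "Ancestral"),
  c("ASN", "EUR", "NEAN", "Ancestral"),
  c("ASN", "EUR", "DENI", "Ancestral")
)

#' Fit introgression fractions to observed D statistics by simulation
#'
#' Minimizes the squared distance between a vector of observed D statistics
#' (the five canonical quadruples contrasting Neanderthal/Denisova sharing in
#' Europeans, Asians and Oceanians against Africans) and their means over
#' coalescent simulations in which only the chosen introgression fraction(s)
#' vary. One free fraction uses bounded scalar minimization
#' ([stats::optimize()]); two use bounded quasi-Newton ([stats::optim()],
#' `"L-BFGS-B"`).
#'
#' @param observed numeric vector of observed D values, one per entry of
#'   `quads` (a `dstat_result` tibble is also accepted).
#' @param free name(s) of the fraction parameter(s) to fit (1 or 2 of them).
#' @param model the demographic model simulated; defaults to the backbone
#'   model "A".
#' @param fixed_params parameter vector holding every non-fitted parameter
#'   (default: the published point estimates completed with defaults).
#' @param quads list of quadruples matching `observed`.
#' @param n_reps simulation replicates per objective evaluation.
#' @param regions region set per replicate.
#' @param lower,upper optimization bounds for each free fraction.
#' @param seed integer; each objective evaluation reseeds with `seed` so the
#'   objective is deterministic (common random numbers across evaluations).
#' @return list with `estimate` (named), `objective`, `convergence`,
#'   `trace` (tibble of evaluated points).
#' @export
fit_introgression <- function(observed, free = "f_nean_ooa",
                              model = build_model("A"),
                              fixed_params = NULL,
                              quads = FIT_QUADS,
                              n_reps = 50,
                              regions = region_table(0.002),
                              lower = 0, upper = 0.2, seed = 1) {
  if (is.data.frame(observed)) observed <- observed$D
  stopifnot(length(observed) == length(quads), length(free) %in% c(1, 2))
  if (is.null(fixed_params)) fixed_params <- published_point_estimates(model$label)
  trace <- list()
  quad_pops <- setdiff(unique(unlist(strsplit(unlist(quads), "+", fixed = TRUE))),
                       "Ancestral")
  samples <- stats::setNames(rep(2L, length(quad_pops)), quad_pops)
  objective <- function(frac) {
    p <- fixed_params
    p[free] <- as.list(frac)
    set.seed(seed)
    sims <- vapply(seq_len(n_reps), function(i) {
      s <- simulate_joint_sfs(model, p, regions = regions, samples = samples)
      vapply(quads, function(q) d_from_sfs(s, q), numeric(1))
    }, numeric(length(quads)))
    d_mean <- if (length(quads) == 1) mean(sims) else rowMeans(sims)
    obj <- sum((observed - d_mean)^2)
    trace[[length(trace) + 1]] <<- dplyr::bind_cols(
      tibble::as_tibble(as.list(stats::setNames(frac, free))),
      tibble::tibble(objective = obj)
    )
    obj
  }
  if (length(free) == 1) {
    fit <- stats::optimize(objective, lower = lower, upper = upper, tol = 1e-3)
    est <- stats::setNames(fit$minimum, free)
    res <- list(estimate = est, objective = fit$objective, convergence = 0L)
  } else {
    fit <- stats::optim(rep(mean(c(lower, upper)), 2), objective,
                        method = "L-BFGS-B",
                        lower = rep_len(lower, 2), upper = rep_len(upper, 2))
    if (fit$convergence != 0) {
      warning("optimizer did not converge: ", fit$message)
    }
    res <- list(estimate = stats::setNames(fit$par, free),
                objective = fit$value, convergence = fit$convergence)
  }
  res$trace <- dplyr::bind_rows(trace)
  res
}
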