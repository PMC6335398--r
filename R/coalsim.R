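#' Genomic region table
#'
#' Defines the simulated genomic regions: each region has a total length
#' `L_r`, a callable length `L_c` after masking, and a recombination rate.
#' The full-scale default is 9,643 regions totalling 651 Mb; `scale` shrinks
#' the region count (and hence the total length) proportionally so that
#' desk-scale runs complete in minutes.
#'
#' @param scale fraction of the full-scale region set (default 1).
#' @param n_regions number of regions at `scale = 1`.
#' @param total_length total sequence length in bp at `scale = 1`.
#' @param callable_fraction L_c / L_r per region (scalar or vector).
#' @param recomb_rate per-bp per-generation recombination rate.
#' @return a tibble with columns `region`, `L_r`, `L_c`, `recomb_rate`.
#' @export
region_table <- function(scale = 1, n_regions = 9643, total_length = 651e6,
                         callable_fraction = 0.8, recomb_rate = 1.0e-8) {
  n <- max(1L, as.integer(round(n_regions * scale)))
  L_r <- round(total_length / n_regions)
  tibble::tibble(
    region = seq_len(n),
    L_r = rep(L_r, n),
    L_c = round(L_r * rep_len(callable_fraction, n)),
    recomb_rate = rep_len(recomb_rate, n)
  )
}

#' Mutation-rate specification
#'
#' Per-simulation mutation rates are drawn from a normal distribution
#' (default mean 1.61e-8, sd 0.13e-8 per bp per generation), truncated at 0.
#'
#' @param mean mean rate per bp per generation.
#' @param sd standard deviation.
#' @return an object of class `mutation_rate_spec`.
#' @export
mutation_rate_spec <- function(mean = 1.61e-8, sd = 0.13e-8) {
  if (mean <= 0 || sd < 0) stop("mutation-rate mean must be > 0 and sd >= 0")
  structure(list(mean = mean, sd = sd), class = "mutation_rate_spec")
}

#' Draw per-simulation mutation rates
#'
#' One normal draw per simulation, shared across that simulation's regions
#' before per-region scaling; negative draws are rejected (truncation at 0).
#'
#' @param spec a [mutation_rate_spec()].
#' @param n number of draws.
#' @return numeric vector of rates.
#' @export
sample_genome_mu <- function(spec, n = 1) {
  out <- stats::rnorm(n, spec$mean, spec$sd)
  while (any(bad <- out < 0)) out[bad] <- stats::rnorm(sum(bad), spec$mean, spec$sd)
  out
}

#' Scale the mutation rate of one region by its callable fraction
#'
#' `mu_r = mu * L_c / L_r`, exactly: the region is simulated at full length
#' with a rate reduced by the fraction of masked sequence.
#'
#' @param mu per-simulation rate.
#' @param region one row of [region_table()] (or any list with `L_r`, `L_c`).
#' @return scaled rate(s).
#' @export
region_mutation_rate <- function(mu, region) {
  if (any(region$L_r == 0)) stop("region total length L_r must be positive")
  if (any(region$L_c < 0 | region$L_c > region$L_r)) {
    stop("callable length must satisfy 0 <= L_c <= L_r")
  }
  mu * region$L_c / region$L_r
}

#' Build a simulator spec directly (custom scenarios)
#'
#' Lower-level constructor used for simple control scenarios (single
#' populations, admixture toys) that are not one of the eight named models.
#' Events use the same codes as [to_simulator_spec()] output: `mass_move`
#' (lineages of deme `a` move to `b` with probability `p`), `set_size`
#' (diploid size of `a` becomes `p`) and `set_mig` (backward rate from `a`
#' to `b` becomes `p`).
#'
#' @param demes character vector of deme names.
#' @param sizes0 named diploid sizes at time 0.
#' @param events tibble with columns `time`, `type`, `a`, `b`, `p`.
#' @param mig0 optional backward migration matrix (defaults to zero).
#' @param sampled which demes carry samples (defaults to all).
#' @param sampling_times named sampling ages in generations (default 0).
#' @return a `simulator_spec`.
#' @export
simulator_spec <- function(demes, sizes0, events = NULL, mig0 = NULL,
                           sampled = demes, sampling_times = NULL) {
  if (is.null(mig0)) {
    mig0 <- matrix(0, length(demes), length(demes), dimnames = list(demes, demes))
  }
  if (is.null(events)) {
    events <- tibble::tibble(time = numeric(), type = character(),
                             a = character(), b = character(), p = numeric())
  }
  events <- events[order(events$time), , drop = FALSE]
  st <- stats::setNames(rep(0, length(demes)), demes)
  if (!is.null(sampling_times)) st[names(sampling_times)] <- sampling_times
  structure(list(demes = demes, sampled = sampled,
                 sizes0 = sizes0[demes], mig0 = mig0, events = events,
                 sampling_times = st),
            class = "simulator_spec")
}

# split regions into independent non-recombining segments; the SFS is
# insensitive to recombination in expectation, so independent segments stand
# in for recombining sequence (segment length set by `chunk_length`)
region_chunks <- function(regions, mu_r, chunk_length) {
  k <- pmax(1L, as.integer(ceiling(regions$L_r / chunk_length)))
  lens <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    full <- rep(chunk_length, k[i] - 1)
    c(full, regions$L_r[i] - sum(full))
  }))
  rates <- rep(mu_r, times = k) * lens
  list(len = lens, rate = rates, region = rep(regions$region, times = k))
}

run_engine <- function(spec, samples, chunk_rate, chunk_len, want_sites = FALSE) {
  demes <- spec$demes
  pops <- names(samples)
  unknown <- setdiff(pops, demes)
  if (length(unknown)) stop("sampled population(s) not in spec: ",
                            paste(unknown, collapse = ", "))
  leaf_pop <- rep(seq_along(pops) - 1L, times = samples)
  leaf_deme <- match(pops, demes)[leaf_pop + 1L] - 1L
  leaf_time <- spec$sampling_times[pops][leaf_pop + 1L]
  ev <- spec$events
  type_code <- c(mass_move = 0L, set_size = 1L, set_mig = 2L)
  res <- coalsim_engine(
    n_demes = length(demes),
    leaf_deme = as.integer(leaf_deme),
    leaf_time = as.numeric(leaf_time),
    leaf_pop = as.integer(leaf_pop),
    n_pops = length(pops),
    sizes0 = as.numeric(spec$sizes0),
    mig0 = spec$mig0,
    ev_time = as.numeric(ev$time),
    ev_type = type_code[ev$type],
    ev_a = match(ev$a, demes) - 1L,
    ev_b = ifelse(is.na(ev$b), 0L, match(ev$b, demes) - 1L),
    ev_p = as.numeric(ev$p),
    chunk_rate = as.numeric(chunk_rate),
    chunk_len = as.numeric(chunk_len),
    want_sites = want_sites
  )
  res
}

#' Simulate a joint SFS under a demographic model
#'
#' Runs the structured coalescent over the region set, drops mutations at the
#' per-region scaled rate, and accumulates the multidimensional joint SFS of
#' one diploid (two haploid genomes) per sampled population by default.
#'
#' @param model a `demographic_model`, or a `simulator_spec` for custom
#'   scenarios.
#' @param params one parameter draw (ignored when `model` is already a spec).
#' @param regions a [region_table()].
#' @param mu_spec a [mutation_rate_spec()].
#' @param samples named vector of haploid sample sizes per population
#'   (default: two per sampled population).
#' @param chunk_length length of the independently evolving segments (bp).
#' @param mu optional fixed per-simulation mutation rate (overrides
#'   `mu_spec`).
#' @param mu_per_region draw a fresh rate for every region instead of one
#'   shared per-simulation draw.
#' @return a `joint_sfs`; the attribute `n_sites` carries the simulator's
#'   count of polarized segregating sites.
#' @export
simulate_joint_sfs <- function(model, params = NULL, regions = region_table(0.001),
                               mu_spec = mutation_rate_spec(), samples = NULL,
                               chunk_length = 5e4, mu = NULL,
                               mu_per_region = FALSE) {
  if (!nrow(regions)) stop("empty region list")
  spec <- if (inherits(model, "simulator_spec")) model else to_simulator_spec(model, params)
  if (is.null(samples)) {
    samples <- stats::setNames(rep(2L, length(spec$sampled)), spec$sampled)
  }
  if (is.null(mu)) {
    mu <- if (mu_per_region) sample_genome_mu(mu_spec, nrow(regions))
          else sample_genome_mu(mu_spec, 1)
  }
  mu_r <- region_mutation_rate(mu, regions)
  ch <- region_chunks(regions, mu_r, chunk_length)
  res <- run_engine(spec, samples, ch$rate, ch$len, want_sites = FALSE)
  counts <- array(res$sfs, dim = samples + 1L)
  out <- joint_sfs(counts, names(samples))
  attr(out, "n_sites") <- res$n_sites
  attr(out, "mu") <- mu
  out
}

#' Simulate individual polymorphic sites (genotype-level output)
#'
#' Same engine as [simulate_joint_sfs()] but retains every mutation as a row:
#' the region it fell in, a position within the region, and the 0/1 derived
#' state of every haploid genome. Used to build toy cohorts and per-site
#' D-statistic input.
#'
#' @inheritParams simulate_joint_sfs
#' @return a list with `sites` (tibble: `region`, `pos`, one 0/1 column per
#'   haploid genome named `<POP>.<i>`), `samples`, and `n_sites`.
#' @export
simulate_sites <- function(model, params = NULL, regions = region_table(0.001),
                           mu_spec = mutation_rate_spec(), samples = NULL,
                           chunk_length = 5e4, mu = NULL) {
  if (!nrow(regions)) stop("empty region list")
  spec <- if (inherits(model, "simulator_spec")) model else to_simulator_spec(model, params)
  if (is.null(samples)) {
    samples <- stats::setNames(rep(2L, length(spec$sampled)), spec$sampled)
  }
  if (is.null(mu)) mu <- sample_genome_mu(mu_spec, 1)
  mu_r <- region_mutation_rate(mu, regions)
  ch <- region_chunks(regions, mu_r, chunk_length)
  res <- run_engine(spec, samples, ch$rate, ch$len, want_sites = TRUE)
  hap_names <- unlist(lapply(names(samples), function(p) {
    paste0(p, ".", seq_len(samples[[p]]))
  }))
  geno <- res$geno
  colnames(geno) <- hap_names
  # chunk index -> owning region and offset within the region
  chunk_region <- ch$region
  chunk_start <- unlist(lapply(split(ch$len, chunk_region), function(l) {
    cumsum(c(0, l[-length(l)]))
  }), use.names = FALSE)
  sites <- tibble::tibble(
    region = chunk_region[res$chunk],
    pos = chunk_start[res$chunk] + res$pos,
    tibble::as_tibble(geno)
  )
  sites <- sites[order(sites$region, sites$pos), , drop = FALSE]
  list(sites = sites, samples = samples, n_sites = res$n_sites)
}
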