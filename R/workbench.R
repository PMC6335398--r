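MODERN_POPS <- c("AFR", "EUR", "ASN", "AND", "IND", "PAP", "AUS")

#' Assign positions to equal-span physical genome blocks
#'
#' @param pos 1-based positions on the pseudo-chromosome.
#' @param total_length chromosome length in bp.
#' @param n_blocks number of equal-span blocks (default 555).
#' @return integer block ids in `1..n_blocks`.
#' @export
assign_blocks <- function(pos, total_length, n_blocks = 555) {
  span <- total_length / n_blocks
  pmin(pmax(as.integer(ceiling(pos / span)), 1L), as.integer(n_blocks))
}

#' Generate a synthetic genotype cohort with known ground truth
#'
#' Simulates two diploid individuals per modern population and one per
#' archaic population under a chosen model, and writes a VCF (phased
#' genotypes, `AA` ancestral-allele INFO tag), a BED block map for the
#' jackknife, and a ground-truth sidecar (YAML). VCF positions are 1-based;
#' the BED is 0-based half-open. The REF allele is the ancestral or the
#' derived allele with equal probability, so polarization is exercised.
#'
#' @param label model letter A..H.
#' @param params a parameter draw, or `"published-means"` for the built-in
#'   point estimates.
#' @param scale fraction of the full-scale region set.
#' @param seed integer seed (all randomness, including the simulation).
#' @param dir output directory (created if needed).
#' @param n_blocks number of jackknife blocks.
#' @param mu optional fixed mutation rate (default: drawn from
#'   [mutation_rate_spec()]).
#' @return (invisibly) list with `vcf`, `bed`, `truth` file paths, the
#'   simulated `sites` tibble, `samples`, and `total_length`.
#' @export
generate_toy_cohort <- function(label, params = "published-means", scale = 0.001,
                                seed = 1, dir = tempfile("cohort"),
                                n_blocks = 555, mu = NULL, chunk_length = 5e4) {
  set.seed(seed)
  model <- build_model(label)
  if (identical(params, "published-means")) params <- published_point_estimates(label)
  samples <- stats::setNames(ifelse(SAMPLED_POPS %in% MODERN_POPS, 4L, 2L),
                             SAMPLED_POPS)
  regions <- region_table(scale)
  sim <- simulate_sites(model, params, regions = regions, samples = samples,
                        mu = mu, chunk_length = chunk_length)
  region_offset <- c(0, cumsum(regions$L_r))[seq_len(nrow(regions))]
  total_length <- sum(regions$L_r)
  sites <- sim$sites
  sites$gpos <- region_offset[sites$region] + sites$pos
  sites <- sites[order(sites$gpos), , drop = FALSE]
  sites <- sites[!duplicated(sites$gpos), , drop = FALSE]

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "cohort.vcf")
  bed_path <- file.path(dir, "blocks.bed")
  truth_path <- file.path(dir, "truth.yaml")

  hap_cols <- setdiff(names(sites), c("region", "pos", "gpos"))
  dip_names <- unlist(lapply(SAMPLED_POPS, function(p) {
    paste0(p, "_", seq_len(samples[[p]] / 2))
  }))

  n_sites <- nrow(sites)
  ref_is_anc <- stats::runif(n_sites) < 0.5
  ref <- ifelse(ref_is_anc, "A", "T")
  alt <- ifelse(ref_is_anc, "T", "A")
  aa <- rep("A", n_sites)  # ancestral allele is always "A" by construction

  geno <- as.matrix(sites[, hap_cols])
  gt_cols <- if (n_sites == 0) {
    matrix(character(0), 0, length(dip_names))
  } else {
    matrix(vapply(seq_along(dip_names), function(j) {
      h1 <- geno[, 2 * j - 1]; h2 <- geno[, 2 * j]  # derived = 1
      a1 <- ifelse(ref_is_anc, h1, 1 - h1)
      a2 <- ifelse(ref_is_anc, h2, 1 - h2)
      paste0(a1, "|", a2)
    }, character(n_sites)), nrow = n_sites)
  }

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=1,length=", total_length, ">"),
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dip_names), collapse = "\t")
  )
  body <- if (n_sites) {
    paste(
      "1", sites$gpos, ".", ref, alt, ".", "PASS", paste0("AA=", aa), "GT",
      apply(gt_cols, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  } else character()
  writeLines(c(header, body), vcf_path)

  span <- total_length / n_blocks
  starts <- floor(span * (seq_len(n_blocks) - 1))
  ends <- floor(span * seq_len(n_blocks))
  writeLines(paste("1", starts, ends, seq_len(n_blocks), sep = "\t"), bed_path)

  yaml::write_yaml(list(model = label, seed = seed, scale = scale,
                        total_length = total_length,
                        params = as.list(as_param_vec(params))), truth_path)
  invisible(list(vcf = vcf_path, bed = bed_path, truth = truth_path,
                 sites = sites, samples = samples, total_length = total_length))
}

#' Read a VCF into a per-site allele-count table
#'
#' Polarizes each biallelic site with the `AA` INFO tag (or a supplied
#' ancestral-allele table): when the ancestral allele equals ALT the derived
#' allele is REF, flipping the counts. Sites whose ancestral allele matches
#' neither REF nor ALT, or with no called genotype in any population, are
#' dropped and counted in the attached log.
#'
#' @param vcf path to a VCF file.
#' @param blocks a BED path (0-based half-open), a tibble with `start`,
#'   `end`, or an integer number of equal-span blocks.
#' @param ancestral optional tibble with `pos`, `aa` overriding the AA tag.
#' @return an [allele_count_table()]; attributes `sample_counts` (per-diploid
#'   derived counts), `sample_pop`, and `log` (a tibble of site counters).
#' @export
read_vcf_counts <- function(vcf, blocks = 555, ancestral = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  n_read <- nrow(v@fix)
  if (n_read == 0) {
    stop("VCF contains no variant records")
  }
  pos <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]; alt <- v@fix[, "ALT"]
  aa <- vcfR::extract.info(v, "AA")
  if (!is.null(ancestral)) aa <- ancestral$aa[match(pos, ancestral$pos)]

  gt <- vcfR::extract.gt(v, "GT")
  samples_names <- colnames(gt)
  sample_pop <- sub("_[0-9]+$", "", samples_names)

  alt_count <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & g != "./." & g != ".|."
    a <- gsub("[|/]", "", g[ok])
    out[ok] <- vapply(strsplit(a, ""), function(x) sum(x == "1"), integer(1))
    out
  }
  ac <- apply(gt, 2, alt_count)
  if (is.null(dim(ac))) ac <- matrix(ac, nrow = 1, dimnames = list(NULL, samples_names))

  polarized <- !is.na(aa) & (aa == ref | aa == alt)
  flip <- !is.na(aa) & aa == alt
  derived <- ac
  derived[flip, ] <- 2L - ac[flip, , drop = FALSE]
  called <- !is.na(ac)
  any_called <- rowSums(called) > 0
  keep <- polarized & any_called

  log <- tibble::tibble(
    sites_read = n_read,
    dropped_unpolarized = sum(!polarized),
    dropped_all_missing = sum(polarized & !any_called),
    sites_kept = sum(keep)
  )

  derived <- derived[keep, , drop = FALSE]
  called <- called[keep, , drop = FALSE]
  pos <- pos[keep]

  if (is.character(blocks) && length(blocks) == 1) {
    bed <- utils::read.table(blocks, sep = "\t",
                             col.names = c("chrom", "start", "end", "id"))
    block <- bed$id[findInterval(pos - 1L, bed$start)]
  } else if (is.data.frame(blocks)) {
    block <- findInterval(pos - 1L, blocks$start)
  } else {
    block <- assign_blocks(pos, max(pos, 1L), n_blocks = blocks)
  }

  pops <- unique(sample_pop)
  cols <- list(block = block)
  for (p in pops) {
    idx <- which(sample_pop == p)
    d <- rowSums(derived[, idx, drop = FALSE], na.rm = TRUE)
    n <- 2L * rowSums(called[, idx, drop = FALSE])
    d[n == 0] <- NA_integer_
    cols[[paste0("d_", p)]] <- d
    cols[[paste0("n_", p)]] <- n
  }
  out <- allele_count_table(tibble::as_tibble(cols))
  attr(out, "sample_counts") <- derived
  attr(out, "sample_pop") <- sample_pop
  attr(out, "sample_names") <- samples_names
  attr(out, "pos") <- pos
  attr(out, "log") <- log
  out
}

#' Joint SFS from a per-site allele-count table
#'
#' Tabulates the combinations of per-population derived counts (sites with
#' missing data in any population are dropped).
#'
#' @param counts an [allele_count_table()].
#' @param pops populations to include (default: all, in table order).
#' @param n_hap named haploid sample size per population (default: the
#'   maximum observed total).
#' @return a `joint_sfs`.
#' @export
counts_to_sfs <- function(counts, pops = NULL, n_hap = NULL) {
  if (is.null(pops)) pops <- attr(counts, "pops")
  if (is.null(n_hap)) {
    n_hap <- vapply(pops, function(p) max(counts[[paste0("n_", p)]], na.rm = TRUE),
                    numeric(1))
  }
  d <- sapply(pops, function(p) counts[[paste0("d_", p)]])
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  keep <- rowSums(is.na(d)) == 0
  d <- d[keep, , drop = FALSE]
  arr <- array(0, dim = n_hap + 1)
  if (nrow(d)) {
    idx <- as.matrix(d) + 1L
    cell <- as.vector((idx - 1) %*% cumprod(c(1, n_hap[-length(n_hap)] + 1))) + 1
    tab <- table(cell)
    arr[as.integer(names(tab))] <- as.integer(tab)
  }
  joint_sfs(arr, pops)
}

#' Split the observed cohort in half and compute a per-half joint SFS
#'
#' Mirrors the observed-data split of the method: modern populations carry two
#' diploids, so one diploid per population feeds the noise-injection half
#' (`"noise"`) and the other the ABC target half (`"target"`); the single
#' archaic individuals are shared by both halves. Each half yields an SFS
#' with one diploid per population, the same axis layout as the simulations.
#'
#' @param counts a [read_vcf_counts()] result (per-sample counts required).
#' @param half `"noise"` (first diploid of each modern population) or
#'   `"target"` (second diploid).
#' @return a `joint_sfs` over the populations in `counts`.
#' @export
compute_observed_sfs <- function(counts, half = c("noise", "target")) {
  half <- match.arg(half)
  sc <- attr(counts, "sample_counts")
  sp <- attr(counts, "sample_pop")
  if (is.null(sc)) stop("per-sample counts are required (read the VCF with read_vcf_counts)")
  pops <- unique(sp)
  pick <- integer(0)
  for (p in pops) {
    idx <- which(sp == p)
    if (length(idx) >= 2) {
      pick <- c(pick, if (half == "noise") idx[1] else idx[2])
    } else if (p %in% c("NEAN", "DENI")) {
      pick <- c(pick, idx)  # archaic: shared by both halves
    } else {
      stop("modern population ", p, " has a single diploid; halves need two")
    }
  }
  d <- sc[, pick, drop = FALSE]
  keep <- rowSums(is.na(d)) == 0
  d <- d[keep, , drop = FALSE]
  n_hap <- stats::setNames(rep(2, length(pops)), pops)
  arr <- array(0, dim = n_hap + 1)
  if (nrow(d)) {
    idx <- d + 1
    cell <- as.vector(idx %*% cumprod(c(1, rep(3, length(pops) - 1)))) -
      sum(cumprod(c(1, rep(3, length(pops) - 1)))) + 1
    tab <- table(cell)
    arr[as.integer(names(tab))] <- as.integer(tab)
  }
  out <- joint_sfs(arr, pops)
  attr(out, "half") <- half
  attr(out, "members") <- attr(counts, "sample_names")[pick]
  out
}

#' Simulate a bank of model-labelled joint SFS
#'
#' Draws parameters from each model's prior and simulates one joint SFS per
#' draw; the flattened spectra, labels and draws feed network training and
#' the ABC reference table.
#'
#' @param labels model letters to include.
#' @param n_per_model simulations per model.
#' @param scale region-set scale per simulation.
#' @param pops optional population subset (spectra are marginalized to it).
#' @param chunk_length segment length for the simulator.
#' @param models optional pre-built models (named by label).
#' @return a `training_set` whose `params` tibble carries a `model` column.
#' @export
simulate_model_bank <- function(labels, n_per_model, scale = 0.001, pops = NULL,
                                chunk_length = 5e4, models = NULL) {
  regions <- region_table(scale)
  mu_spec <- mutation_rate_spec()
  recs <- list(); labs <- character(0); pars <- list()
  for (lab in labels) {
    model <- if (!is.null(models)) models[[lab]] else build_model(lab)
    draws <- sample_parameters(model, n_per_model)
    for (i in seq_len(n_per_model)) {
      s <- simulate_joint_sfs(model, draws[i, ], regions = regions,
                              mu_spec = mu_spec, chunk_length = chunk_length)
      if (!is.null(pops)) s <- marginalize_sfs(s, pops)
      recs[[length(recs) + 1]] <- s
    }
    labs <- c(labs, rep(lab, n_per_model))
    draws$model <- lab
    pars[[lab]] <- draws
  }
  build_training_set(recs, labels = labs, params = dplyr::bind_rows(pars))
}

new_manifest <- function(config) {
  # version-2 serialization sidesteps ALTREP state, so the hash is a pure
  # function of the configuration's content
  config_hash <- rlang::hash(serialize(config, NULL, version = 2))
  structure(list(config_hash = config_hash, stages = tibble::tibble(
    stage = character(), seed = integer(), n_records = integer()
  )), class = "run_manifest")
}

add_stage <- function(manifest, stage, seed, n_records) {
  manifest$stages <- dplyr::bind_rows(
    manifest$stages,
    tibble::tibble(stage = stage, seed = as.integer(seed),
                   n_records = as.integer(n_records))
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (config hash ", x$config_hash, ")\n", sep = "")
  print(x$stages)
  invisible(x)
}

resolve_observed <- function(config) {
  obs <- config$observed
  if (!is.null(obs$noise) && !is.null(obs$target)) return(obs)
  if (!is.null(obs$vcf)) {
    counts <- read_vcf_counts(obs$vcf, blocks = obs$blocks %||% 555)
    return(list(noise = compute_observed_sfs(counts, "noise"),
                target = compute_observed_sfs(counts, "target")))
  }
  stop("config$observed must give either joint_sfs halves (noise/target) or a vcf path")
}

#' End-to-end ABC model-choice pipeline
#'
#' Orchestrates: prior simulation for every candidate model, classifier-net
#' training with SFS-like noise injected from the observed noise half,
#' compression of simulations and the observed target half into learned
#' summaries, ABC rejection, and the multinomial-logistic model posterior.
#'
#' @param config list with entries: `models` (labels), `n_sims_per_model`,
#'   `scale`, `observed` (list with `noise`/`target` `joint_sfs`, or `vcf`
#'   plus optional `blocks`), `alpha_max` (default 0.2), `accept_rate`
#'   (default 0.01), `pops` (optional subset), `hyper` (net options),
#'   `seed`.
#' @return list with `posterior` (a `model_posterior`), `net`, `accepted`,
#'   `bank`, `manifest`.
#' @export
run_model_choice_pipeline <- function(config) {
  stopifnot(!is.null(config$models), !is.null(config$seed))
  manifest <- new_manifest(config)
  set.seed(config$seed)
  obs <- resolve_observed(config)
  if (!is.null(config$pops)) {
    obs <- lapply(obs, marginalize_sfs, pops = config$pops)
  }
  bank <- simulate_model_bank(config$models, config$n_sims_per_model,
                              scale = config$scale %||% 0.001,
                              pops = config$pops)
  manifest <- add_stage(manifest, "simulate", config$seed, nrow(bank$x))
  net <- train_classifier_net(bank, noise = noise_spec(obs$noise,
                                                       config$alpha_max %||% 0.2),
                              hyper = config$hyper %||% list())
  manifest <- add_stage(manifest, "train", config$seed, nrow(bank$x))
  ss <- summarize_sfs(net, bank$x)
  obs_ss <- summarize_sfs(net, obs$target)
  n_accept <- max(2L, round((config$accept_rate %||% 0.01) * nrow(ss)))
  acc <- rejection_sample(obs_ss, ss, abc_config(nrow(ss), n_accept))
  manifest <- add_stage(manifest, "rejection", config$seed, n_accept)
  post <- mnlogistic_model_posterior(acc, bank$labels[acc$indices], obs_ss)
  manifest <- add_stage(manifest, "posterior", config$seed, nrow(post))
  list(posterior = post, net = net, accepted = acc, bank = bank,
       manifest = manifest)
}

#' End-to-end ABC parameter-estimation pipeline
#'
#' As [run_model_choice_pipeline()] but for a single model: a regressor net
#' is trained on the prior simulations, and the accepted draws are adjusted
#' by local-linear regression at the observed summary.
#'
#' @param config as in [run_model_choice_pipeline()], plus `model` (single
#'   label) and `targets` (parameter names; default all time/fraction
#'   parameters).
#' @return list with `summary` (posterior mean and credible intervals),
#'   `posterior` (a `parameter_posterior`), `net`, `accepted`, `manifest`.
#' @export
run_estimation_pipeline <- function(config) {
  stopifnot(!is.null(config$model), !is.null(config$seed))
  manifest <- new_manifest(config)
  set.seed(config$seed)
  obs <- resolve_observed(config)
  if (!is.null(config$pops)) obs <- lapply(obs, marginalize_sfs, pops = config$pops)
  model <- build_model(config$model)
  targets <- config$targets %||%
    grep("^(t_|f_)", model$priors$name[model$priors$family != "fixed"], value = TRUE)
  bank <- simulate_model_bank(config$model, config$n_sims_per_model,
                              scale = config$scale %||% 0.001,
                              pops = config$pops)
  manifest <- add_stage(manifest, "simulate", config$seed, nrow(bank$x))
  net <- train_regressor_net(bank, noise = noise_spec(obs$noise,
                                                      config$alpha_max %||% 0.2),
                             targets = targets, hyper = config$hyper %||% list())
  manifest <- add_stage(manifest, "train", config$seed, nrow(bank$x))
  ss <- summarize_sfs(net, bank$x)
  obs_ss <- summarize_sfs(net, obs$target)
  if (is.null(dim(ss))) ss <- matrix(ss, ncol = 1)
  n_accept <- max(2L, round((config$accept_rate %||% 0.01) * nrow(ss)))
  acc <- rejection_sample(obs_ss, ss, abc_config(nrow(ss), n_accept))
  manifest <- add_stage(manifest, "rejection", config$seed, n_accept)
  post <- loclinear_adjust(acc, bank$params[acc$indices, targets, drop = FALSE],
                           obs_ss)
  manifest <- add_stage(manifest, "loclinear", config$seed, n_accept)
  list(summary = posterior_summary(post), posterior = post, net = net,
       accepted = acc, bank = bank, manifest = manifest)
}

#' Scaled confusion-matrix study of ABC-DL model choice
#'
#' Simulates a labelled reference bank from every candidate model, trains the
#' classifier net (excluding the pseudo-observed records), simulates fresh
#' pseudo-observed datasets from each model, and runs the full
#' rejection + multinomial-logistic posterior for each, tabulating hard
#' assignments.
#'
#' @param labels candidate model letters.
#' @param n_train_per_model reference simulations per model.
#' @param n_pseudo_per_model pseudo-observed datasets per model.
#' @param scale region-set scale.
#' @param accept_rate fraction of the reference bank retained per
#'   pseudo-observed dataset.
#' @param alpha_max noise-injection bound; the reference spectrum is the mean
#'   of one point-estimate simulation per model (a neutral stand-in for the
#'   observed noise half in a pure simulation study).
#' @param pops optional population subset.
#' @param hyper net options.
#' @param seed integer seed.
#' @return an `abc_confusion` (see [cross_validation_confusion()]), plus the
#'   trained `net` and `manifest` as attributes.
#' @export
run_confusion_study <- function(labels = LETTERS[1:8], n_train_per_model = 250,
                                n_pseudo_per_model = 10, scale = 0.002,
                                accept_rate = 0.05, alpha_max = 0.2,
                                pops = NULL, hyper = list(), seed = 1) {
  config <- as.list(environment())
  manifest <- new_manifest(config)
  set.seed(seed)
  bank <- simulate_model_bank(labels, n_train_per_model, scale = scale, pops = pops)
  manifest <- add_stage(manifest, "simulate_bank", seed, nrow(bank$x))
  ref_list <- lapply(labels, function(lab) {
    s <- simulate_joint_sfs(build_model(lab), published_point_estimates(lab),
                            regions = region_table(scale))
    if (!is.null(pops)) s <- marginalize_sfs(s, pops)
    sfs_vector(s)
  })
  ref <- Reduce(`+`, ref_list) / length(ref_list)
  net <- train_classifier_net(bank, noise = noise_spec(ref, alpha_max),
                              hyper = hyper)
  manifest <- add_stage(manifest, "train", seed, nrow(bank$x))
  pseudo <- simulate_model_bank(labels, n_pseudo_per_model, scale = scale,
                                pops = pops)
  manifest <- add_stage(manifest, "simulate_pseudo", seed, nrow(pseudo$x))
  sims_ss <- summarize_sfs(net, bank$x)
  pseudo_ss <- summarize_sfs(net, pseudo$x)
  n_accept <- max(2L, round(accept_rate * nrow(sims_ss)))
  out <- cross_validation_confusion(sims_ss, bank$labels, pseudo_ss,
                                    pseudo$labels, n_accept = n_accept)
  manifest <- add_stage(manifest, "confusion", seed, nrow(pseudo$x))
  attr(out, "net") <- net
  attr(out, "manifest") <- manifest
  out
}
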