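test_that("a cohort with no variants still writes a valid VCF with its header", {
  co <- generate_toy_cohort("A", scale = 0.0002, seed = 3, mu = 0,
                            dir = withr::local_tempdir())
  lines <- readLines(co$vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  expect_true(any(grepl("^#CHROM\tPOS", lines)))
  expect_false(any(!grepl("^#", lines)))  # no body rows
})

test_that("cohort generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- generate_toy_cohort("A", scale = 0.0003, seed = 21, dir = d1, n_blocks = 20)
  co2 <- generate_toy_cohort("A", scale = 0.0003, seed = 21, dir = d2, n_blocks = 20)
  expect_identical(readLines(co1$vcf), readLines(co2$vcf))
  expect_identical(readLines(co1$bed), readLines(co2$bed))
})

test_that("polarization flips counts when the ancestral allele is ALT and logs drops", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000>",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "AFR_1", "AFR_2", sep = "\t"),
    "1\t100\t.\tA\tT\t.\tPASS\tAA=A\tGT\t0|1\t1|1",  # derived = ALT count = 3
    "1\t200\t.\tA\tT\t.\tPASS\tAA=T\tGT\t0|1\t0|0",  # flip: derived = REF count = 3
    "1\t300\t.\tA\tT\t.\tPASS\tAA=C\tGT\t0|1\t0|1",  # unpolarizable -> dropped
    "1\t400\t.\tA\tT\t.\tPASS\tAA=A\tGT\t./.\t./."   # all missing -> dropped
  ), vcf)
  counts <- read_vcf_counts(vcf, blocks = 2)
  log <- attr(counts, "log")
  expect_equal(log$sites_read, 4)
  expect_equal(log$dropped_unpolarized, 1)
  expect_equal(log$dropped_all_missing, 1)
  expect_equal(log$sites_kept, 2)
  expect_equal(counts$d_AFR, c(3, 3))
  expect_equal(counts$n_AFR, c(4, 4))
})

test_that("the VCF round trip conserves the joint SFS exactly", {
  co <- generate_toy_cohort("A", scale = 0.0005, seed = 31, n_blocks = 10,
                            dir = withr::local_tempdir())
  counts <- read_vcf_counts(co$vcf, blocks = co$bed)
  got <- counts_to_sfs(counts)

  # oracle: tabulate per-population derived counts from the in-memory sites
  hap <- setdiff(names(co$sites), c("region", "pos", "gpos"))
  pop_of <- sub("\\.[0-9]+$", "", hap)
  pops <- attr(counts, "pops")
  d <- sapply(pops, function(p) {
    rowSums(co$sites[, hap[pop_of == p], drop = FALSE])
  })
  n_hap <- got$n_hap
  arr <- array(0, dim = n_hap + 1)
  stride <- cumprod(c(1, n_hap[-length(n_hap)] + 1))
  for (i in seq_len(nrow(d))) {
    cell <- sum(d[i, ] * stride) + 1
    arr[cell] <- arr[cell] + 1
  }
  expect_equal(as.vector(got$counts), as.vector(arr))
  # every polarized site with full calls lands in exactly one cell
  expect_equal(sum(got$counts), attr(counts, "log")$sites_kept)
})

test_that("observed halves are disjoint on moderns, share archaics and lose no sites", {
  co <- generate_toy_cohort("H", scale = 0.0005, seed = 41, n_blocks = 10,
                            dir = withr::local_tempdir())
  counts <- read_vcf_counts(co$vcf, blocks = co$bed)
  h1 <- compute_observed_sfs(counts, "noise")
  h2 <- compute_observed_sfs(counts, "target")
  m1 <- attr(h1, "members"); m2 <- attr(h2, "members")
  modern1 <- setdiff(m1, c("NEAN_1", "DENI_1"))
  modern2 <- setdiff(m2, c("NEAN_1", "DENI_1"))
  expect_length(intersect(modern1, modern2), 0)
  expect_true(all(c("NEAN_1", "DENI_1") %in% intersect(m1, m2)))
  # axis layout identical to simulations: one diploid per population
  expect_equal(unname(h1$n_hap), rep(2L, 9))
  # no loss: each half keeps every polarized site with full calls
  kept <- attr(counts, "log")$sites_kept
  expect_gte(sum(h1$counts), kept * 0.99)
  expect_gte(sum(h1$counts) + sum(h2$counts), max(sum(h1$counts), sum(h2$counts)))

  # a modern population with a single diploid cannot be split
  sc <- attr(counts, "sample_counts")
  counts_bad <- counts
  keep_cols <- attr(counts, "sample_pop") != "AFR" |
    attr(counts, "sample_names") == "AFR_1"
  attr(counts_bad, "sample_counts") <- sc[, keep_cols, drop = FALSE]
  attr(counts_bad, "sample_pop") <- attr(counts, "sample_pop")[keep_cols]
  attr(counts_bad, "sample_names") <- attr(counts, "sample_names")[keep_cols]
  expect_error(compute_observed_sfs(counts_bad, "noise"), "single diploid")
})

test_that("a Neanderthal pulse leaves a significant directional D signal in a toy cohort", {
  p <- published_point_estimates("A")
  p$f_nean_ooa <- 0.02
  # 5 kb segments keep the genealogical granularity close to the human
  # recombination scale, so the jackknife has enough independent units
  co <- generate_toy_cohort("A", params = p, scale = 0.12, seed = 51,
                            n_blocks = 555, chunk_length = 5e3,
                            dir = withr::local_tempdir())
  counts <- read_vcf_counts(co$vcf, blocks = co$bed)
  d <- patterson_d(counts, c("AFR", "EUR", "NEAN", "Ancestral"))
  expect_lt(d$D, 0)
  expect_gt(abs(d$Z_score), 3)
})

test_that("the model-choice pipeline runs end to end, sums to one and repeats exactly", {
  co <- generate_toy_cohort("A", scale = 0.001, seed = 61, n_blocks = 10,
                            dir = withr::local_tempdir())
  counts <- read_vcf_counts(co$vcf, blocks = co$bed)
  config <- list(
    models = c("A", "H"), n_sims_per_model = 100, scale = 0.001,
    observed = list(noise = compute_observed_sfs(counts, "noise"),
                    target = compute_observed_sfs(counts, "target")),
    pops = c("AFR", "EUR", "ASN", "PAP", "NEAN", "DENI"),
    accept_rate = 0.25, hyper = list(epochs = 10), seed = 71
  )
  run1 <- run_model_choice_pipeline(config)
  expect_equal(sum(run1$posterior$posterior), 1, tolerance = 1e-9)
  expect_s3_class(run1$manifest$stages, "tbl_df")
  expect_equal(nrow(run1$manifest$stages), 4)

  run2 <- run_model_choice_pipeline(config)
  expect_identical(run1$posterior$posterior, run2$posterior$posterior)
  expect_identical(run1$accepted$indices, run2$accepted$indices)
  expect_identical(run1$manifest$config_hash, run2$manifest$config_hash)
})

test_that("the estimation pipeline returns credible intervals on the adjusted posterior", {
  co <- generate_toy_cohort("A", scale = 0.001, seed = 81, n_blocks = 10,
                            dir = withr::local_tempdir())
  counts <- read_vcf_counts(co$vcf, blocks = co$bed)
  config <- list(
    model = "A", n_sims_per_model = 150, scale = 0.001,
    observed = list(noise = compute_observed_sfs(counts, "noise"),
                    target = compute_observed_sfs(counts, "target")),
    pops = c("AFR", "EUR", "ASN", "NEAN", "DENI"),
    targets = c("t_eurasia_afr", "f_nean_ooa"),
    accept_rate = 0.3, hyper = list(epochs = 10), seed = 91
  )
  run <- run_estimation_pipeline(config)
  expect_setequal(run$summary$parameter, c("t_eurasia_afr", "f_nean_ooa"))
  expect_true(all(run$summary$ci_lower <= run$summary$mean))
  expect_true(all(run$summary$mean <= run$summary$ci_upper))
  expect_true(all(run$posterior$samples$f_nean_ooa >= 0 &
                    run$posterior$samples$f_nean_ooa <= 1))
})

test_that("pseudo-observed data from the admixed-ghost model is preferred over the backbone", {
  wins <- 0L
  for (rep in 1:10) {
    set.seed(7000 + rep)
    co <- generate_toy_cohort("H", params = sample_parameters(build_model("H"), 1),
                              scale = 0.004, seed = 7000 + rep, n_blocks = 10,
                              dir = withr::local_tempdir())
    counts <- read_vcf_counts(co$vcf, blocks = co$bed)
    config <- list(
      models = c("A", "H"), n_sims_per_model = 300, scale = 0.004,
      observed = list(noise = compute_observed_sfs(counts, "noise"),
                      target = compute_observed_sfs(counts, "target")),
      pops = c("AFR", "EUR", "ASN", "PAP", "AUS", "NEAN", "DENI"),
      accept_rate = 0.25, hyper = list(epochs = 20), seed = 7000 + rep
    )
    run <- run_model_choice_pipeline(config)
    pH <- run$posterior$posterior[run$posterior$model == "H"]
    if (length(pH) && pH > 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
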