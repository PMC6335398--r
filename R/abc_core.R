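#' ABC configuration
#'
#' The rejection step retains the `n_accept` simulations closest to the
#' observed summaries out of `n_sims` (defaults mirror the 1,000 / 100,000
#' error threshold), under Euclidean distance on per-coordinate standardized
#' summaries.
#'
#' @param n_sims total number of simulations the distances are computed over.
#' @param n_accept number of retained simulations.
#' @param distance distance id (only `"euclidean"` is implemented).
#' @return an object of class `abc_config`.
#' @export
abc_config <- function(n_sims = 1e5, n_accept = 1000, distance = "euclidean") {
  if (n_accept <= 0 || n_accept > n_sims) stop("need 0 < n_accept <= n_sims")
  structure(list(n_sims = n_sims, n_accept = n_accept, distance = distance),
            class = "abc_config")
}

#' ABC rejection step
#'
#' Standardizes every summary coordinate by its median absolute deviation
#' across the simulations (robust to heavy tails; falls back to the standard
#' deviation, then to 1, when degenerate), computes Euclidean distances to the
#' observed summary, and retains exactly `n_accept` simulations by distance
#' rank, breaking ties at the acceptance boundary by simulation index.
#'
#' @param observed_ss numeric vector of observed summary statistics.
#' @param sims matrix of simulated summaries (one row per simulation).
#' @param cfg an [abc_config()]; its `n_accept` is used (and `n_sims` must
#'   not exceed the rows of `sims`).
#' @return an object of class `accepted_set`: `indices`, `distances`
#'   (nondecreasing), `ss` (retained summaries), `scale`.
#' @export
rejection_sample <- function(observed_ss, sims, cfg = abc_config(nrow(sims), 1000)) {
  sims <- as.matrix(sims)
  if (cfg$n_accept > nrow(sims)) stop("n_accept exceeds the number of simulations")
  if (length(observed_ss) != ncol(sims)) stop("summary dimension mismatch")
  scale <- apply(sims, 2, stats::mad)
  fallback <- apply(sims, 2, stats::sd)
  scale[scale == 0] <- fallback[scale == 0]
  scale[scale == 0 | !is.finite(scale)] <- 1
  z <- sweep(sims, 2, scale, "/")
  zo <- observed_ss / scale
  d <- sqrt(rowSums(sweep(z, 2, zo, "-")^2))
  ord <- order(d, seq_along(d))
  keep <- ord[seq_len(cfg$n_accept)]
  structure(list(indices = keep, distances = d[keep],
                 ss = sims[keep, , drop = FALSE], scale = scale,
                 observed_ss = observed_ss),
            class = "accepted_set")
}

#' Multinomial-logistic model posterior
#'
#' Fits a multinomial logistic regression of the model label on the summary
#' statistics over the accepted set and evaluates it at the observed summary.
#' Degenerate fits (single label, rank deficiency, non-convergence) fall back
#' to the rejection frequencies with a warning.
#'
#' @param accepted an [rejection_sample()] result.
#' @param labels model labels of the retained simulations (factor/character,
#'   aligned with `accepted$indices`).
#' @param observed_ss observed summary vector (defaults to the one stored in
#'   `accepted`).
#' @return a tibble (class `model_posterior`) with columns `model`,
#'   `posterior`, plus attribute `method` (`"mnlogistic"` or
#'   `"rejection-frequency"`).
#' @export
mnlogistic_model_posterior <- function(accepted, labels,
                                       observed_ss = accepted$observed_ss) {
  labels <- factor(labels)
  stopifnot(length(labels) == length(accepted$indices))
  lev <- levels(droplevels(labels))
  freq <- function() {
    tab <- table(droplevels(labels)) / length(labels)
    out <- tibble::tibble(model = names(tab), posterior = as.numeric(tab))
    attr(out, "method") <- "rejection-frequency"
    class(out) <- c("model_posterior", class(out))
    out
  }
  if (length(lev) < 2) {
    out <- tibble::tibble(model = lev, posterior = 1)
    attr(out, "method") <- "single-label"
    class(out) <- c("model_posterior", class(out))
    return(out)
  }
  df <- data.frame(label = droplevels(labels), accepted$ss)
  newd <- as.data.frame(matrix(observed_ss, nrow = 1))
  names(newd) <- names(df)[-1]
  fit <- tryCatch(
    nnet::multinom(label ~ ., data = df, trace = FALSE, maxit = 500,
                   MaxNWts = 5000),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) {
    warning("multinomial-logistic fit failed; falling back to rejection frequencies")
    return(freq())
  }
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr))) {
    pr <- if (length(pr) == 1) c(1 - pr, pr) else pr  # two-class predict
    names(pr) <- lev
  }
  pr <- pmax(as.numeric(pr), 0)
  pr <- pr / sum(pr)
  out <- tibble::tibble(model = lev, posterior = pr)
  attr(out, "method") <- "mnlogistic"
  class(out) <- c("model_posterior", class(out))
  out
}

#' Bayes factors between models
#' @param posterior a `model_posterior`.
#' @return tibble of pairwise posterior-probability ratios `p_a / p_b`.
#' @export
bayes_factors <- function(posterior) {
  tidyr::expand_grid(a = posterior$model, b = posterior$model) |>
    dplyr::filter(.data$a != .data$b) |>
    dplyr::mutate(
      bayes_factor = posterior$posterior[match(.data$a, posterior$model)] /
        posterior$posterior[match(.data$b, posterior$model)]
    )
}

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Local-linear regression adjustment of accepted parameters
#'
#' Beaumont-style adjustment: Epanechnikov kernel weights on the acceptance
#' distances, a per-parameter weighted linear regression of the parameter on
#' the summaries over the accepted set, and the adjustment
#' `theta* = theta - b' (ss - observed_ss)`. Bounded parameters are adjusted
#' on a transformed scale (logit for proportions, log for positive scale
#' parameters) and back-transformed. Rank-deficient designs fall back to the
#' unadjusted rejection posterior with a warning.
#'
#' @param accepted an [rejection_sample()] result.
#' @param params tibble of parameter draws aligned with `accepted$indices`.
#' @param observed_ss observed summary vector.
#' @param transform named character vector over parameters: `"logit"`,
#'   `"log"`, or `"identity"` (default). Fractions (`f_*` names) default to
#'   logit and sizes/rates (`n_*`, `m_*`) to log when `transform` is `NULL`.
#' @return an object of class `parameter_posterior`: adjusted `samples`
#'   (tibble), `weights`, and the raw accepted draws.
#' @export
loclinear_adjust <- function(accepted, params, observed_ss = accepted$observed_ss,
                             transform = NULL) {
  stopifnot(nrow(params) == length(accepted$indices))
  if (is.null(transform)) {
    transform <- vapply(names(params), function(nm) {
      if (grepl("^f_", nm)) "logit"
      else if (grepl("^(n_|m_)", nm)) "log" else "identity"
    }, character(1))
  }
  dmax <- max(accepted$distances)
  wts <- if (dmax == 0) rep(1, length(accepted$distances)) else {
    1 - (accepted$distances / (dmax * (1 + 1e-12)))^2  # Epanechnikov on [0, dmax]
  }
  wts[wts < 0] <- 0
  X <- sweep(accepted$ss, 2, accepted$scale, "/")
  xo <- observed_ss / accepted$scale
  centered <- sweep(X, 2, xo, "-")
  if (all(centered == 0)) {
    # every accepted summary equals the observed one: the regression offset is
    # identically zero and the draws pass through unchanged
    return(structure(list(samples = tibble::as_tibble(params),
                          weights = rep(1, nrow(params)),
                          raw = tibble::as_tibble(params)),
                     class = "parameter_posterior"))
  }
  design <- cbind(1, centered)
  adj <- params
  for (nm in names(params)) {
    y <- params[[nm]]
    tr <- transform[[nm]] %||% "identity"
    yt <- switch(tr,
      logit = logit(pmin(pmax(y, 1e-9), 1 - 1e-9)),
      log = log(pmax(y, 1e-300)),
      identity = y
    )
    fit <- stats::lm.wfit(design, yt, wts)
    if (any(is.na(fit$coefficients[-1]))) {
      warning("rank-deficient local-linear design for '", nm,
              "'; returning unadjusted draws")
      next
    }
    b <- fit$coefficients[-1]
    yt_adj <- yt - as.vector(centered %*% b)
    adj[[nm]] <- switch(tr, logit = inv_logit(yt_adj), log = exp(yt_adj),
                        identity = yt_adj)
  }
  structure(list(samples = tibble::as_tibble(adj), weights = wts,
                 raw = tibble::as_tibble(params)),
            class = "parameter_posterior")
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Posterior mean and 95% credible interval per parameter
#'
#' @param post a [loclinear_adjust()] result (or any list with `samples` and
#'   `weights`).
#' @param level credible level (default 0.95).
#' @return tibble with columns `parameter`, `mean`, `ci_lower`, `ci_upper`.
#' @export
posterior_summary <- function(post, level = 0.95) {
  w <- post$weights
  if (all(w == 0)) stop("all posterior weights are zero")
  a <- (1 - level) / 2
  dplyr::bind_rows(lapply(names(post$samples), function(nm) {
    x <- post$samples[[nm]]
    q <- weighted_quantile(x, w, c(a, 1 - a))
    tibble::tibble(parameter = nm, mean = sum(w * x) / sum(w),
                   ci_lower = q[1], ci_upper = q[2])
  }))
}

#' Cross-validation confusion matrix for ABC model choice
#'
#' Runs the model-choice step on pseudo-observed summaries with known
#' generating models and tabulates hard max-posterior assignments:
#' `confusion[i, j] = P(assigned = j | true = i)`, a row-stochastic matrix.
#' The mean posterior probability of the true model per row is retained
#' alongside.
#'
#' @param sims_ss matrix of simulated summaries (the reference table).
#' @param sim_labels model labels of `sims_ss` rows.
#' @param pseudo_ss matrix of pseudo-observed summaries.
#' @param pseudo_labels true generating model of each pseudo-observed row.
#' @param n_accept retained simulations per pseudo-observed dataset.
#' @param posterior_fun function `(accepted, labels, observed)` returning a
#'   `model_posterior`; defaults to [mnlogistic_model_posterior()]. Tests can
#'   inject an oracle here.
#' @return an object of class `abc_confusion`: `confusion` (row-stochastic
#'   matrix), `mean_true_posterior` (per true model), `assignments` tibble.
#' @export
cross_validation_confusion <- function(sims_ss, sim_labels, pseudo_ss,
                                       pseudo_labels, n_accept = 1000,
                                       posterior_fun = mnlogistic_model_posterior) {
  if (!nrow(pseudo_ss)) stop("no pseudo-observed datasets")
  sim_labels <- factor(sim_labels)
  lev <- levels(sim_labels)
  pseudo_labels <- factor(pseudo_labels, levels = lev)
  rows <- lapply(seq_len(nrow(pseudo_ss)), function(i) {
    acc <- rejection_sample(pseudo_ss[i, ], sims_ss,
                            abc_config(nrow(sims_ss), n_accept))
    post <- posterior_fun(acc, sim_labels[acc$indices], pseudo_ss[i, ])
    p <- stats::setNames(rep(0, length(lev)), lev)
    p[post$model] <- post$posterior
    dplyr::bind_cols(
      tibble::tibble(true = as.character(pseudo_labels[i]),
                     assigned = lev[which.max(p)],
                     true_posterior = unname(p[as.character(pseudo_labels[i])])),
      tibble::as_tibble(as.list(p))
    )
  })
  assignments <- dplyr::bind_rows(rows)
  conf <- matrix(0, length(lev), length(lev), dimnames = list(true = lev, assigned = lev))
  for (i in seq_len(nrow(assignments))) {
    conf[assignments$true[i], assignments$assigned[i]] <-
      conf[assignments$true[i], assignments$assigned[i]] + 1
  }
  conf <- conf / pmax(rowSums(conf), 1)
  mtp <- vapply(lev, function(l) {
    mean(assignments$true_posterior[assignments$true == l])
  }, numeric(1))
  structure(list(confusion = conf, mean_true_posterior = mtp,
                 assignments = assignments),
            class = "abc_confusion")
}

#' @export
print.abc_confusion <- function(x, ...) {
  cat("ABC model-choice confusion matrix (hard assignment):\n")
  print(round(x$confusion, 3))
  cat("Mean posterior of the true model per row:\n")
  print(round(x$mean_true_posterior, 3))
  invisible(x)
}
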