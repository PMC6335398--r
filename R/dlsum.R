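#' Assemble a training set of simulated joint SFS
#'
#' Flattens a list of simulated spectra (all sharing one axis layout) into the
#' matrix fed to the network, with per-record model labels (classification)
#' and/or parameter draws (regression).
#'
#' @param sfs_list list of `joint_sfs` objects with identical layout.
#' @param labels optional factor/character of model labels, one per record.
#' @param params optional tibble of parameter draws, one row per record.
#' @return an object of class `training_set`.
#' @export
build_training_set <- function(sfs_list, labels = NULL, params = NULL) {
  stopifnot(length(sfs_list) >= 1)
  layout <- list(pops = sfs_list[[1]]$pops, n_hap = sfs_list[[1]]$n_hap)
  same <- vapply(sfs_list, function(s) {
    identical(s$pops, layout$pops) && identical(unname(s$n_hap), unname(layout$n_hap))
  }, logical(1))
  if (!all(same)) stop("all SFS in a training set must share the axis layout")
  x <- t(vapply(sfs_list, sfs_vector, numeric(length(sfs_vector(sfs_list[[1]])))))
  if (!is.null(labels)) {
    labels <- factor(labels)
    stopifnot(length(labels) == nrow(x))
  }
  if (!is.null(params)) stopifnot(nrow(params) == nrow(x))
  structure(list(x = x, labels = labels, params = params, layout = layout),
            class = "training_set")
}

#' SFS-like noise specification
#'
#' During training, each record is mixed cellwise with a reference spectrum
#' (typically the held-out half of the observed data):
#' `(1 - alpha) * sim + alpha * ref`, with a fresh
#' `alpha ~ U(0, alpha_max)` per record per epoch. This injects observed
#' data-like structure instead of white noise, whose independence assumption
#' the correlated SFS cells violate.
#'
#' @param ref a `joint_sfs` (or raw summary vector) used as the reference.
#' @param alpha_max upper bound of the mixing coefficient (default 0.2).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(ref, alpha_max = 0.2) {
  if (alpha_max < 0 || alpha_max > 1) stop("alpha_max must lie in [0, 1]")
  structure(list(ref = ref, alpha_max = alpha_max), class = "noise_spec")
}

#' Mix a simulated SFS with a reference SFS
#'
#' Cellwise `(1 - alpha) * sim + alpha * ref`, applied on raw counts before
#' any input normalization. `alpha = 0` returns the simulation unchanged and
#' `alpha = 1` the reference.
#'
#' @param sim_sfs,ref_sfs `joint_sfs` objects with identical layout (numeric
#'   vectors of equal length are also accepted).
#' @param alpha mixing coefficient in \code{[0, 1]}.
#' @return same type as `sim_sfs`, with real-valued cells.
#' @export
inject_noise <- function(sim_sfs, ref_sfs, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (inherits(sim_sfs, "joint_sfs")) {
    if (!inherits(ref_sfs, "joint_sfs") ||
        !identical(sim_sfs$pops, ref_sfs$pops) ||
        !identical(dim(sim_sfs$counts), dim(ref_sfs$counts))) {
      stop("simulated and reference SFS layouts differ")
    }
    out <- sim_sfs
    out$counts <- (1 - alpha) * sim_sfs$counts + alpha * ref_sfs$counts
    return(out)
  }
  if (length(sim_sfs) != length(ref_sfs)) stop("layout mismatch")
  (1 - alpha) * sim_sfs + alpha * ref_sfs
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(w, X) {
  a1 <- relu(sweep(X %*% w$W1, 2, w$b1, "+"))
  a2 <- relu(sweep(a1 %*% w$W2, 2, w$b2, "+"))
  z3 <- sweep(a2 %*% w$W3, 2, w$b3, "+")
  list(a1 = a1, a2 = a2, z3 = z3)
}

mlp_init <- function(sizes) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  list(W1 = he(sizes[1], sizes[2]), b1 = rep(0, sizes[2]),
       W2 = he(sizes[2], sizes[3]), b2 = rep(0, sizes[3]),
       W3 = he(sizes[3], sizes[4]), b3 = rep(0, sizes[4]))
}

default_hidden <- function(p) {
  # geometric compression of the input, capped so the 3^9-cell SFS still
  # yields a desk-scale network
  c(min(64L, max(4L, ceiling(p / 3))), min(24L, max(2L, ceiling(p / 9))))
}

default_hyper <- function(hyper) {
  utils::modifyList(list(hidden = NULL, epochs = 60, batch = 64, lr = 1e-3,
                         patience = 8, val_frac = 0.2, normalize = "proportion_z"),
                    hyper %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared trainer for both heads; head = "softmax" or "linear"
train_mlp <- function(X_prop, row_tot, Y, head, class_weights, noise, hyper) {
  n <- nrow(X_prop); p <- ncol(X_prop)
  hidden <- hyper$hidden %||% default_hidden(p)
  stopifnot(length(hidden) == 2)

  # per-cell z-scoring against training statistics (in "raw" mode the counts
  # skip the division by their total but are still standardized)
  mu <- colMeans(X_prop)
  sd <- apply(X_prop, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1

  ref_prop <- NULL; ref_tot <- NULL; alpha_max <- 0
  if (!is.null(noise)) {
    rv <- if (inherits(noise$ref, "joint_sfs")) sfs_vector(noise$ref) else noise$ref
    if (length(rv) != p) stop("reference SFS layout differs from training layout")
    ref_tot <- sum(rv)
    ref_prop <- if (hyper$normalize == "raw" || ref_tot == 0) rv else rv / ref_tot
    alpha_max <- noise$alpha_max
  }

  n_val <- max(1L, floor(n * hyper$val_frac))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)

  sizes <- c(p, hidden, ncol(Y))
  w <- mlp_init(sizes)
  adam <- lapply(w, function(x) list(m = x * 0, v = x * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  standardize <- function(M) sweep(sweep(M, 2, mu, "-"), 2, sd, "/")

  batch_input <- function(idx, with_noise) {
    M <- X_prop[idx, , drop = FALSE]
    if (with_noise && alpha_max > 0) {
      a <- stats::runif(length(idx), 0, alpha_max)
      if (hyper$normalize == "raw") {
        M <- (1 - a) * M + outer(a, ref_prop * 1)  # raw counts mixed directly
      } else {
        # counts are mixed on the raw scale, then re-normalized:
        # ((1-a) T_s s + a T_r r) / ((1-a) T_s + a T_r), with s, r proportions
        ts <- row_tot[idx]
        num <- (1 - a) * ts * M + outer(a * ref_tot, ref_prop)
        M <- num / ((1 - a) * ts + a * ref_tot)
      }
    }
    standardize(M)
  }

  loss_of <- function(out, Yb, wt) {
    if (head == "softmax") {
      pmat <- softmax_rows(out)
      -mean(wt * log(pmat[cbind(seq_len(nrow(Yb)), max.col(Yb))] + 1e-12))
    } else {
      mean((out - Yb)^2)
    }
  }

  Xval <- batch_input(val_idx, with_noise = FALSE)
  Yval <- Y[val_idx, , drop = FALSE]
  wval <- class_weights[val_idx]

  best <- list(loss = Inf, w = w, epoch = 0L)
  log_rows <- list()

  for (epoch in seq_len(hyper$epochs)) {
    perm <- sample(tr_idx)
    tr_loss <- 0; nb <- 0
    for (start in seq(1, length(perm), by = hyper$batch)) {
      idx <- perm[start:min(start + hyper$batch - 1, length(perm))]
      Xb <- batch_input(idx, with_noise = TRUE)
      Yb <- Y[idx, , drop = FALSE]
      wt <- class_weights[idx]
      fw <- mlp_forward(w, Xb)
      m <- nrow(Xb)
      if (head == "softmax") {
        pmat <- softmax_rows(fw$z3)
        d3 <- (pmat - Yb) * (wt / m)
      } else {
        d3 <- 2 * (fw$z3 - Yb) / (m * ncol(Yb))
      }
      g <- list(
        W3 = crossprod(fw$a2, d3), b3 = colSums(d3),
        W2 = NULL, b2 = NULL, W1 = NULL, b1 = NULL
      )
      d2 <- (d3 %*% t(w$W3)) * (fw$a2 > 0)
      g$W2 <- crossprod(fw$a1, d2); g$b2 <- colSums(d2)
      d1 <- (d2 %*% t(w$W2)) * (fw$a1 > 0)
      g$W1 <- crossprod(Xb, d1); g$b1 <- colSums(d1)

      step <- step + 1
      for (nm in names(w)) {
        adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * g[[nm]]
        adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * g[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - b1^step)
        vhat <- adam[[nm]]$v / (1 - b2^step)
        w[[nm]] <- w[[nm]] - hyper$lr * mhat / (sqrt(vhat) + eps)
      }
      tr_loss <- tr_loss + loss_of(fw$z3, Yb, wt); nb <- nb + 1
    }
    val_out <- mlp_forward(w, Xval)$z3
    val_loss <- loss_of(val_out, Yval, wval)
    if (!is.finite(val_loss)) stop("non-finite loss at epoch ", epoch)
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                        train_loss = tr_loss / nb,
                                        val_loss = val_loss)
    if (val_loss < best$loss - 1e-9) best <- list(loss = val_loss, w = w, epoch = epoch)
    if (epoch - best$epoch >= hyper$patience) break
  }

  list(w = best$w, mu = mu, sd = sd, hidden = hidden,
       val_idx = val_idx, log = dplyr::bind_rows(log_rows),
       normalize = hyper$normalize)
}

finish_net <- function(fit, head, layout, labels = NULL, targets = NULL,
                       target_center = NULL, target_scale = NULL, metric = NULL) {
  structure(list(weights = fit$w, mu = fit$mu, sd = fit$sd,
                 hidden = fit$hidden, head = head, layout = layout,
                 labels = labels, targets = targets,
                 target_center = target_center, target_scale = target_scale,
                 normalize = fit$normalize,
                 log = fit$log, metric = metric),
            class = "summary_net")
}

prepare_inputs <- function(train, normalize) {
  X <- train$x
  tot <- rowSums(X)
  if (normalize == "raw") return(list(X = X, tot = tot))
  tot[tot == 0] <- 1
  list(X = X / tot, tot = rowSums(train$x))
}

#' Train the classifier network (model-choice summary statistics)
#'
#' Fits a four-layer feedforward network (input, two hidden layers, softmax
#' output over model labels) on simulated joint SFS, with SFS-like noise
#' injection and early stopping on an internal held-out split. The per-model
#' softmax scores are the learned summary statistics used downstream by the
#' ABC step. Class imbalance is handled by inverse-frequency loss weights.
#'
#' @param train a [build_training_set()] result with `labels`.
#' @param noise a [noise_spec()] or `NULL` for classical training.
#' @param hyper list of training options: `hidden` (two integers), `epochs`,
#'   `batch`, `lr`, `patience`, `val_frac`, `normalize` (`"proportion_z"` to
#'   divide by the included-cell total and z-score, `"raw"` for raw counts).
#' @return a `summary_net` with softmax head; `glance()` reports the held-out
#'   accuracy, `tidy()` the per-epoch training log.
#' @export
train_classifier_net <- function(train, noise = NULL, hyper = list()) {
  if (is.null(train$labels) || nlevels(train$labels) < 2) {
    stop("classification needs at least two model labels")
  }
  hyper <- default_hyper(hyper)
  lev <- levels(train$labels)
  Y <- vapply(lev, function(l) as.numeric(train$labels == l),
              numeric(length(train$labels)))
  freq <- table(train$labels)[train$labels]
  cw <- as.numeric(length(train$labels) / (nlevels(train$labels) * freq))
  inp <- prepare_inputs(train, hyper$normalize)
  fit <- train_mlp(inp$X, inp$tot, Y, "softmax", cw, noise, hyper)
  val_out <- mlp_forward(fit$w, sweep(sweep(inp$X[fit$val_idx, , drop = FALSE],
                                            2, fit$mu, "-"), 2, fit$sd, "/"))$z3
  acc <- mean(lev[max.col(val_out)] == train$labels[fit$val_idx])
  finish_net(fit, "softmax", train$layout, labels = lev,
             metric = c(heldout_accuracy = acc))
}

#' Train the regressor network (parameter-estimation summary statistics)
#'
#' Same architecture as [train_classifier_net()] but with a linear output
#' head, one unit per target parameter; targets are z-scored internally
#' against the prior sample and predictions are returned in original units.
#'
#' @inheritParams train_classifier_net
#' @param targets character vector of parameter names from `train$params`.
#' @param target_transform named character vector (`"log"` or `"identity"`)
#'   per target; by default size and migration-rate parameters (`n_*`, `m_*`)
#'   are learned on the log scale, matching their log-uniform priors, and
#'   back-transformed on prediction.
#' @return a `summary_net` with linear head; `glance()` reports the held-out
#'   Pearson correlation per target (on the learning scale).
#' @export
train_regressor_net <- function(train, noise = NULL, targets, hyper = list(),
                                target_transform = NULL) {
  if (is.null(train$params)) stop("training set carries no parameter draws")
  missing <- setdiff(targets, names(train$params))
  if (length(missing)) stop("unknown target(s): ", paste(missing, collapse = ", "))
  hyper <- default_hyper(hyper)
  if (is.null(target_transform)) {
    target_transform <- stats::setNames(
      ifelse(grepl("^(n_|m_)", targets), "log", "identity"), targets)
  }
  Yraw <- as.matrix(train$params[, targets, drop = FALSE])
  for (j in seq_along(targets)) {
    if (identical(target_transform[[targets[j]]], "log")) {
      Yraw[, j] <- log(pmax(Yraw[, j], 1e-300))
    }
  }
  ctr <- colMeans(Yraw); scl <- apply(Yraw, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant target (zero variance): ",
         paste(targets[scl == 0], collapse = ", "))
  }
  Y <- sweep(sweep(Yraw, 2, ctr, "-"), 2, scl, "/")
  inp <- prepare_inputs(train, hyper$normalize)
  fit <- train_mlp(inp$X, inp$tot, Y, "linear", rep(1, nrow(Y)), noise, hyper)
  val_out <- mlp_forward(fit$w, sweep(sweep(inp$X[fit$val_idx, , drop = FALSE],
                                            2, fit$mu, "-"), 2, fit$sd, "/"))$z3
  cors <- vapply(seq_along(targets), function(j) {
    stats::cor(val_out[, j], Y[fit$val_idx, j])
  }, numeric(1))
  net <- finish_net(fit, "linear", train$layout, targets = targets,
                    target_center = ctr, target_scale = scl,
                    metric = stats::setNames(cors, paste0("heldout_cor_", targets)))
  net$target_transform <- target_transform
  net
}

#' Compress an SFS into its learned summary statistics
#'
#' Deterministic forward pass of a trained network: the classifier head
#' returns per-model softmax scores, the regressor head per-parameter
#' predictions in original units. A matrix input (one SFS vector per row)
#' returns a matrix of summaries.
#'
#' @param net a `summary_net`.
#' @param sfs a `joint_sfs` with the training layout, a raw summary vector,
#'   or a matrix of raw summary vectors.
#' @return named numeric vector, or a matrix for matrix input.
#' @export
summarize_sfs <- function(net, sfs) {
  if (inherits(sfs, "joint_sfs")) {
    if (!identical(sfs$pops, net$layout$pops) ||
        !identical(unname(sfs$n_hap), unname(net$layout$n_hap))) {
      stop("SFS layout differs from the network's training layout")
    }
    X <- matrix(sfs_vector(sfs), nrow = 1)
  } else if (is.matrix(sfs)) X <- sfs else X <- matrix(sfs, nrow = 1)
  if (ncol(X) != nrow(net$weights$W1)) stop("input length differs from training layout")
  if (net$normalize != "raw") {
    tot <- rowSums(X); tot[tot == 0] <- 1
    X <- X / tot
  }
  X <- sweep(sweep(X, 2, net$mu, "-"), 2, net$sd, "/")
  out <- mlp_forward(net$weights, X)$z3
  if (net$head == "softmax") {
    out <- softmax_rows(out)
    colnames(out) <- net$labels
  } else {
    out <- sweep(sweep(out, 2, net$target_scale, "*"), 2, net$target_center, "+")
    if (!is.null(net$target_transform)) {
      for (j in seq_along(net$targets)) {
        if (identical(net$target_transform[[net$targets[j]]], "log")) {
          out[, j] <- exp(out[, j])
        }
      }
    }
    colnames(out) <- net$targets
  }
  if (nrow(out) == 1) out[1, ] else out
}

#' @export
print.summary_net <- function(x, ...) {
  cat("Four-layer feedforward summary network (", x$head, " head)\n", sep = "")
  cat("Layers:", nrow(x$weights$W1), "->", x$hidden[1], "->", x$hidden[2],
      "->", ncol(x$weights$W3), "\n")
  if (!is.null(x$metric)) {
    cat("Held-out:", paste(names(x$metric), round(x$metric, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore a trained network as JSON
#'
#' Self-describing text serialization (version tag, layer sizes, weights,
#' normalization constants); `read_net(write_net(net, path))` restores a net
#' whose forward pass is bit-identical.
#'
#' @param net a `summary_net`.
#' @param path file path.
#' @return `write_net` returns `path` invisibly; `read_net` a `summary_net`.
#' @export
write_net <- function(net, path) {
  doc <- list(format = "abcdl-summary-net", version = 1L,
              head = net$head, hidden = net$hidden,
              normalize = net$normalize,
              layout = net$layout, labels = net$labels, targets = net$targets,
              target_center = net$target_center, target_scale = net$target_scale,
              target_transform = as.list(net$target_transform),
              mu = net$mu, sd = net$sd, metric = as.list(net$metric),
              weights = lapply(net$weights, function(x) {
                if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
                else list(dim = length(x), data = as.vector(x))
              }))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_net
#' @export
read_net <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "abcdl-summary-net")) stop("not a summary-net file")
  weights <- lapply(doc$weights, function(el) {
    if (length(el$dim) == 2) matrix(el$data, el$dim[1], el$dim[2]) else el$data
  })
  structure(list(weights = weights, mu = doc$mu, sd = doc$sd,
                 hidden = doc$hidden, head = doc$head,
                 layout = list(pops = doc$layout$pops, n_hap = doc$layout$n_hap),
                 labels = doc$labels, targets = doc$targets,
                 target_center = unlist(doc$target_center),
                 target_scale = unlist(doc$target_scale),
                 target_transform = unlist(doc$target_transform),
                 normalize = doc$normalize,
                 log = tibble::as_tibble(doc$log %||% NULL),
                 metric = unlist(doc$metric)),
            class = "summary_net")
}
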