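# Training workflows: stratified splitting, online coordinate augmentation,
# direct training, k-fold ensembling, transfer learning, and metrics.

#' Training configuration
#'
#' @param lr Adam learning rate after warm-up.
#' @param warmup linear warm-up steps (learning rate ramps 0 -> `lr`).
#' @param epochs passes over the training set.
#' @param batch_size complexes per optimization step.
#' @param dropout dropout rate between readout dense layers (training only).
#' @param augment_radius online augmentation: each atom is displaced uniformly
#'   within a sphere of this radius (Angstrom) every time an example is drawn;
#'   augmentation is off at inference. Default 0.1.
#' @param seed master seed; fanned out to init/shuffle/augment streams.
#' @param mode `"full"` or `"ligand_only"`.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param keep_shift for transfer learning: keep the base model's shift
#'   instead of re-initializing to the local label mean.
#' @return a `training_config` list.
#' @export
training_config <- function(lr = 3e-3, warmup = 100, epochs = 150,
                            batch_size = 64, dropout = 0,
                            augment_radius = 0.1, seed = 1,
                            mode = c("full", "ligand_only"),
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                            keep_shift = FALSE) {
  mode <- match.arg(mode)
  stopifnot(lr > 0, warmup >= 0, epochs >= 0, batch_size >= 1,
            dropout >= 0, dropout < 1, augment_radius >= 0)
  structure(list(lr = lr, warmup = as.integer(warmup),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 augment_radius = augment_radius, seed = as.integer(seed),
                 mode = mode, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, keep_shift = isTRUE(keep_shift)),
            class = "training_config")
}

#' Stratified train/test split on activity
#'
#' Labels are binned into activity quantiles (default 5 bins); within each bin
#' a seeded sample goes to the training set. Per-bin counts use floor plus
#' largest-remainder correction so the total train size is exactly
#' `round(train_frac * n)`. With fewer labels than bins the split falls back
#' to a plain seeded split with a warning.
#'
#' @param labels numeric pK labels (>= 5).
#' @param train_frac training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @param bins number of activity quantile bins.
#' @return list with integer vectors `train` and `test` (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1, bins = 5) {
  n <- length(labels)
  stopifnot(train_frac > 0, train_frac < 1)
  if (n < 5) stop("need at least 5 labels to split")
  n_train <- round(train_frac * n)
  with_local_seed(derive_seed(seed, "split"), {
    if (n < bins) {
      warning("fewer labels than bins; falling back to a plain seeded split")
      train <- sort(sample(n, n_train))
      return(list(train = train, test = setdiff(seq_len(n), train)))
    }
    breaks <- unique(stats::quantile(labels, probs = seq(0, 1, length.out = bins + 1)))
    bin <- if (length(breaks) < 3) {
      rep(1L, n) # (near-)constant labels: a single bin
    } else {
      cut(labels, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    }
    groups <- split(seq_len(n), bin)
    sizes <- lengths(groups)
    exact <- train_frac * sizes
    take <- floor(exact)
    short <- n_train - sum(take)
    if (short > 0) {
      ord <- order(exact - take, decreasing = TRUE)
      room <- which(take[ord] < sizes[ord])
      take[ord[utils::head(room, short)]] <-
        take[ord[utils::head(room, short)]] + 1L
    } else if (short < 0) {
      ord <- order(exact - take)
      nz <- which(take[ord] > 0)
      take[ord[utils::head(nz, -short)]] <-
        take[ord[utils::head(nz, -short)]] - 1L
    }
    train <- sort(unlist(lapply(seq_along(groups), function(g) {
      ix <- groups[[g]]
      if (take[g] == 0) return(integer())
      ix[sample(length(ix), take[g])]
    }), use.names = FALSE))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Perturb coordinates uniformly within a sphere
#'
#' Each atom is displaced independently by a vector drawn uniformly from the
#' solid ball of the given radius (so the mean displacement norm is 3r/4).
#' Draws come from the current RNG stream. `radius = 0` returns the input
#' unchanged.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param radius augmentation sphere radius, Angstrom (>= 0).
#' @return perturbed coordinate matrix.
#' @export
augment_coordinates <- function(coords, radius) {
  stopifnot(radius >= 0)
  if (radius == 0 || nrow(coords) == 0) return(coords)
  coords + runif_ball(nrow(coords), radius)
}

# Shared optimization loop. Returns updated params, optimizer state, and the
# per-step training loss history. Deterministic given config$seed.
run_training <- function(params, dataset, config, mcfg) {
  labels <- vapply(dataset, function(x) x$label, numeric(1))
  if (anyNA(labels)) stop("all training complexes must be labeled")
  state <- adam_init(params)
  losses <- numeric(0)
  nd <- length(dataset)
  # without augmentation a full-dataset batch never changes: build it once
  full_batch <- if (config$augment_radius == 0 && config$batch_size >= nd) {
    build_batch(dataset, mcfg, config$mode)
  } else {
    NULL
  }
  with_local_seed(derive_seed(config$seed, "trainloop"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample(nd)
      starts <- seq(1, nd, by = config$batch_size)
      for (s in starts) {
        idx <- if (!is.null(full_batch)) seq_len(nd)
               else perm[s:min(s + config$batch_size - 1, nd)]
        coords_list <- NULL
        if (config$augment_radius > 0) {
          coords_list <- lapply(dataset[idx], function(x) {
            augment_coordinates(x$coords, config$augment_radius)
          })
        }
        batch <- if (!is.null(full_batch)) {
          full_batch
        } else {
          build_batch(dataset[idx], mcfg, config$mode, coords_list)
        }
        fwd <- forward_batch(params, batch, mcfg, training = TRUE,
                             dropout = config$dropout, keep_cache = TRUE)
        err <- fwd$total - labels[idx]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", ep, "; batch ids: ",
               paste(batch$ids, collapse = ", "))
        }
        losses <- c(losses, loss)
        dtotal <- 2 * err / length(idx)
        grads <- backward_batch(params, batch, mcfg, fwd, dtotal)
        upd <- adam_step(params, grads, state, lr = config$lr,
                         warmup = config$warmup, beta1 = config$beta1,
                         beta2 = config$beta2, eps = config$adam_eps)
        params <- upd$params
        state <- upd$state
      }
    }
  })
  list(params = params, optimizer = state, loss_history = losses)
}

#' Train a model from random initialization
#'
#' Minimizes mean squared error on pK labels with Adam under linear warm-up.
#' The shift parameter is initialized to the training-label mean; online
#' coordinate augmentation is applied each time an example is drawn.
#'
#' @param dataset list of labeled [atomic_complex()] (>= 2).
#' @param config a [training_config()].
#' @param mcfg a [model_config()].
#' @return an `eq_checkpoint` (with in-memory optimizer state and loss
#'   history).
#' @export
train_direct <- function(dataset, config = training_config(),
                         mcfg = model_config()) {
  if (length(dataset) == 0) stop("empty dataset")
  if (length(dataset) < 2) stop("need at least 2 labeled complexes")
  labels <- vapply(dataset, function(x) x$label, numeric(1))
  if (anyNA(labels)) stop("all training complexes must be labeled")
  params <- init_params(mcfg, derive_seed(config$seed, "init"))
  params[["shift"]] <- mean(labels)
  res <- run_training(params, dataset, config, mcfg)
  new_checkpoint(res$params, mcfg, label_mean = mean(labels),
                 seed = config$seed, mode = config$mode,
                 loss_history = res$loss_history, optimizer = res$optimizer)
}

#' Train a k-fold cross-validation ensemble
#'
#' Seeded k-fold partition; one model per fold trained on the other k-1
#' folds. Ensemble predictions are the arithmetic mean of member predictions
#' (their spread is reported alongside).
#'
#' @param dataset list of labeled complexes (size >= k).
#' @param k number of folds (default 5).
#' @param config a [training_config()].
#' @param mcfg a [model_config()].
#' @return an `eq_ensemble`.
#' @export
train_kfold_ensemble <- function(dataset, k = 5, config = training_config(),
                                 mcfg = model_config()) {
  stopifnot(k >= 2)
  n <- length(dataset)
  if (k > n) stop("k exceeds dataset size")
  folds <- with_local_seed(derive_seed(config$seed, "folds"), {
    split(sample(n), rep_len(seq_len(k), n))
  })
  members <- lapply(seq_len(k), function(f) {
    cf <- config
    cf$seed <- derive_seed(config$seed, paste0("fold-", f))
    ck <- train_direct(dataset[-folds[[f]]], cf, mcfg)
    ck$fold <- f
    ck
  })
  structure(list(members = members, folds = folds, k = k),
            class = "eq_ensemble")
}

#' @export
print.eq_ensemble <- function(x, ...) {
  cat(sprintf("<eq_ensemble: %d members (k = %d)>\n", length(x$members), x$k))
  invisible(x)
}

#' Transfer-learn a pretrained model onto a local dataset
#'
#' All parameters are initialized from the base checkpoint; nothing is
#' frozen. Optimizer momenta are freshly zeroed and the warm-up schedule
#' re-applied, so large early gradients cannot wreck the pretrained weights.
#' By default the shift parameter is re-initialized to the local training
#' label mean (set `config$keep_shift = TRUE` to retain the global shift).
#'
#' @param base a pretrained `eq_checkpoint`.
#' @param dataset local labeled complexes (non-empty).
#' @param config a [training_config()].
#' @return an `eq_checkpoint`.
#' @export
transfer_learn <- function(base, dataset, config = training_config()) {
  stopifnot(inherits(base, "eq_checkpoint"))
  if (length(dataset) == 0) stop("empty local dataset")
  mcfg <- base$cfg
  if (config_hash(mcfg) != base$config_hash) {
    stop("checkpoint architecture mismatch (config hash ", base$config_hash,
         " vs ", config_hash(mcfg), ")")
  }
  labels <- vapply(dataset, function(x) x$label, numeric(1))
  if (anyNA(labels)) stop("all training complexes must be labeled")
  params <- base$params
  if (!config$keep_shift) params[["shift"]] <- mean(labels)
  res <- run_training(params, dataset, config, mcfg)
  new_checkpoint(res$params, mcfg, label_mean = mean(labels),
                 seed = config$seed, mode = config$mode,
                 loss_history = res$loss_history, optimizer = res$optimizer)
}

#' Regression metrics on a labeled dataset
#'
#' @param model an `eq_checkpoint` or `eq_ensemble`.
#' @param dataset labeled complexes.
#' @param mode prediction mode; defaults to the model's training mode.
#' @return an `eq_metrics` list: `rmse`, `mue`, `r2` (squared Pearson
#'   correlation), `n`. Zero-variance predictions or labels give `r2 = 0`
#'   with a warning.
#' @export
evaluate <- function(model, dataset, mode = NULL) {
  if (length(dataset) == 0) stop("empty evaluation dataset")
  labels <- vapply(dataset, function(x) x$label, numeric(1))
  if (anyNA(labels)) stop("all evaluation complexes must be labeled")
  preds <- predict_dataset(model, dataset, mode = mode)$pred
  compute_metrics(preds, labels)
}

#' Metrics from prediction and label vectors
#' @param preds predicted pK values.
#' @param labels experimental pK values.
#' @return an `eq_metrics` list.
#' @export
compute_metrics <- function(preds, labels) {
  stopifnot(length(preds) == length(labels), length(preds) > 0)
  err <- preds - labels
  r2 <- if (stats::sd(labels) == 0 || stats::sd(preds) == 0) {
    warning("zero variance in predictions or labels; reporting r2 = 0")
    0
  } else {
    stats::cor(preds, labels)^2
  }
  structure(list(rmse = sqrt(mean(err^2)), mue = mean(abs(err)),
                 r2 = r2, n = length(preds)),
            class = "eq_metrics")
}

#' @export
print.eq_metrics <- function(x, ...) {
  cat(sprintf("<metrics (n = %d): RMSE %.4f, MUE %.4f, r2 %.4f>\n",
              x$n, x$rmse, x$mue, x$r2))
  invisible(x)
}
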