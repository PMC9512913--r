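#' Hyperparameters for the multi-headed MLP
#'
#' The six tuned hyperparameters (hidden width, learning rate, momentum, L2
#' coefficient, dropout probability, max-norm bound) plus batch size, epoch
#' cap and initialization seed. Training runs mini-batch gradient descent
#' with momentum for up to `max_epochs` epochs (default cap 100) and keeps
#' the epoch with the lowest validation MSE.
#'
#' @param hidden_width Width of the shared trunk layer and of each head's
#'   hidden layer.
#' @param learning_rate Step size for gradient descent.
#' @param momentum Classical momentum coefficient.
#' @param l2 L2 regularization coefficient (penalty `l2 * sum(w^2)`,
#'   weights only).
#' @param dropout Dropout probability on the hidden layers, in [0, 1).
#' @param max_norm Maximum L2 norm allowed for the incoming weight vector of
#'   any hidden or output unit; weights are rescaled after every update.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap (default 100).
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Object of class `mlp_hyperparams`.
#' @export
mlp_hyperparams <- function(hidden_width = 32L, learning_rate = 0.02,
                            momentum = 0.9, l2 = 1e-4, dropout = 0.1,
                            max_norm = 3, batch_size = 64L,
                            max_epochs = 100L, seed = 1L) {
  stopifnot(hidden_width >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            l2 >= 0, dropout >= 0, dropout < 1, max_norm > 0,
            batch_size >= 1, max_epochs >= 1)
  structure(list(hidden_width = as.integer(hidden_width),
                 learning_rate = learning_rate, momentum = momentum,
                 l2 = l2, dropout = dropout, max_norm = max_norm,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "mlp_hyperparams")
}

#' Per-arm loss weights
#'
#' The factual squared error of a patient allocated to arm t is weighted by
#' n_s / (m * n_t), where n_s is the training-split size, m the number of
#' arms and n_t the arm's size. This compensates for allocation imbalance:
#' the size-weighted mean of the weights is exactly 1.
#'
#' @param allocations Arm id per training patient.
#' @param arms Arm registry (character vector); defaults to the arms present.
#' @return Named numeric vector of per-arm weights.
#' @export
loss_weights <- function(allocations, arms = NULL) {
  if (is.null(arms)) arms <- unique(allocations)
  bad <- setdiff(unique(allocations), arms)
  if (length(bad) > 0L) {
    stop("allocation outside arm registry: ", paste(bad, collapse = ", "))
  }
  n_s <- length(allocations)
  m <- length(arms)
  n_t <- table(factor(allocations, levels = arms))
  if (any(n_t == 0)) {
    stop("arm with no allocated patients: ",
         paste(arms[n_t == 0], collapse = ", "))
  }
  stats::setNames(n_s / (m * as.numeric(n_t)), arms)
}

#' Weighted factual loss
#'
#' Mean over patients of `weight(t_i) * (mu_hat_{t_i}(x_i) - y_i)^2`: only
#' the output head corresponding to each patient's allocated arm (the head
#' with available ground truth) contributes.
#'
#' @param predictions Matrix of potential-outcome predictions, one column
#'   per arm (column names = arm ids).
#' @param targets Observed outcomes (EDSS slopes).
#' @param allocations Arm id per patient.
#' @param weights Named per-arm weights from [loss_weights()].
#' @return Scalar loss.
#' @export
weighted_factual_loss <- function(predictions, targets, allocations, weights) {
  cols <- match(allocations, colnames(predictions))
  if (anyNA(cols)) {
    stop("allocation outside arm registry: ",
         paste(unique(allocations[is.na(cols)]), collapse = ", "))
  }
  mu <- predictions[cbind(seq_along(targets), cols)]
  mean(weights[allocations] * (mu - targets)^2)
}

# He-style uniform fan-in initialization, seeded by the caller's RNG state
.init_mat <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a multi-headed MLP
#'
#' One shared ReLU trunk layer feeding one treatment-specific ReLU hidden
#' layer plus a scalar output per arm. Weights use uniform He-style fan-in
#' initialization from the supplied seed.
#'
#' @param n_features Input dimensionality.
#' @param arms Character vector of arm ids (one head each).
#' @param hidden_width Layer width.
#' @param seed Integer seed.
#' @return Object of class `mlp_model`.
#' @export
mlp_init <- function(n_features, arms, hidden_width, seed = 1L) {
  set.seed(seed)
  W <- as.integer(hidden_width)
  heads <- stats::setNames(lapply(arms, function(a) {
    list(W2 = .init_mat(W, W), b2 = rep(0, W),
         w3 = drop(.init_mat(W, 1L)), b3 = 0)
  }), arms)
  structure(list(W1 = .init_mat(n_features, W), b1 = rep(0, W),
                 heads = heads, arms = arms, hidden_width = W,
                 frozen_trunk = FALSE),
            class = "mlp_model")
}

#' Predict potential outcomes with an MLP
#'
#' @param object An `mlp_model`.
#' @param newdata Feature matrix (patients x features).
#' @param ... Unused.
#' @return Matrix of predicted slopes, one column per arm.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  H1 <- pmax(newdata %*% object$W1 +
               matrix(object$b1, nrow(newdata), object$hidden_width,
                      byrow = TRUE), 0)
  mu <- vapply(object$arms, function(a) {
    h <- object$heads[[a]]
    H2 <- pmax(H1 %*% h$W2 +
                 matrix(h$b2, nrow(H1), object$hidden_width, byrow = TRUE), 0)
    drop(H2 %*% h$w3) + h$b3
  }, numeric(nrow(newdata)))
  mu <- matrix(mu, nrow = nrow(newdata),
               dimnames = list(rownames(newdata), object$arms))
  mu
}

# rescale columns (incoming weight vectors) whose norm exceeds max_norm
.clip_cols <- function(W, max_norm) {
  nrm <- sqrt(colSums(W^2))
  sc <- pmin(1, max_norm / pmax(nrm, 1e-12))
  sweep(W, 2, sc, "*")
}

.clip_vec <- function(w, max_norm) {
  nrm <- sqrt(sum(w^2))
  if (nrm > max_norm) w * (max_norm / nrm) else w
}

# per-epoch stratified batches: shuffle within each arm, interleave
# proportionally by fractional position, then chunk; last short batch kept
.stratified_batches <- function(alloc, batch_size) {
  pos <- numeric(length(alloc))
  for (a in unique(alloc)) {
    idx <- which(alloc == a)
    idx <- idx[sample.int(length(idx))]
    pos[idx] <- (seq_along(idx) - 0.5) / length(idx)
  }
  ord <- order(pos)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

# one momentum-SGD step on a mini-batch; returns updated model and velocities
.sgd_step <- function(model, vel, X, y, alloc, wts, hp) {
  B <- nrow(X)
  W <- model$hidden_width
  p <- hp$dropout
  A1 <- X %*% model$W1 + matrix(model$b1, B, W, byrow = TRUE)
  H1 <- pmax(A1, 0)
  if (p > 0) {
    M1 <- matrix((stats::runif(B * W) >= p) / (1 - p), B, W)
    H1d <- H1 * M1
  } else {
    M1 <- NULL
    H1d <- H1
  }
  dH1d <- matrix(0, B, W)
  lam <- hp$l2
  for (a in unique(alloc)) {
    idx <- which(alloc == a)
    h <- model$heads[[a]]
    Ha <- H1d[idx, , drop = FALSE]
    A2 <- Ha %*% h$W2 + matrix(h$b2, length(idx), W, byrow = TRUE)
    H2 <- pmax(A2, 0)
    if (p > 0) {
      M2 <- matrix((stats::runif(length(idx) * W) >= p) / (1 - p),
                   length(idx), W)
      H2d <- H2 * M2
    } else {
      H2d <- H2
    }
    mu <- drop(H2d %*% h$w3) + h$b3
    g <- (2 * wts[[a]] / B) * (mu - y[idx])
    gw3 <- drop(crossprod(H2d, g)) + 2 * lam * h$w3
    gb3 <- sum(g)
    dH2d <- g %*% t(h$w3)
    dA2 <- dH2d * (A2 > 0)
    if (p > 0) dA2 <- dA2 * M2
    gW2 <- crossprod(Ha, dA2) + 2 * lam * h$W2
    gb2 <- colSums(dA2)
    dH1d[idx, ] <- dH1d[idx, , drop = FALSE] + dA2 %*% t(h$W2)
    v <- vel$heads[[a]]
    v$W2 <- hp$momentum * v$W2 - hp$learning_rate * gW2
    v$b2 <- hp$momentum * v$b2 - hp$learning_rate * gb2
    v$w3 <- hp$momentum * v$w3 - hp$learning_rate * gw3
    v$b3 <- hp$momentum * v$b3 - hp$learning_rate * gb3
    h$W2 <- .clip_cols(h$W2 + v$W2, hp$max_norm)
    h$b2 <- h$b2 + v$b2
    h$w3 <- .clip_vec(h$w3 + v$w3, hp$max_norm)
    h$b3 <- h$b3 + v$b3
    model$heads[[a]] <- h
    vel$heads[[a]] <- v
  }
  if (!model$frozen_trunk) {
    dA1 <- dH1d * (A1 > 0)
    if (p > 0) dA1 <- dA1 * M1
    gW1 <- crossprod(X, dA1) + 2 * lam * model$W1
    gb1 <- colSums(dA1)
    vel$W1 <- hp$momentum * vel$W1 - hp$learning_rate * gW1
    vel$b1 <- hp$momentum * vel$b1 - hp$learning_rate * gb1
    model$W1 <- .clip_cols(model$W1 + vel$W1, hp$max_norm)
    model$b1 <- model$b1 + vel$b1
  }
  list(model = model, vel = vel)
}

.factual_mse <- function(model, X, y, alloc) {
  mu <- predict(model, X)
  mean((mu[cbind(seq_along(y), match(alloc, colnames(mu)))] - y)^2)
}

#' Train one early-stopped MLP on a train/validation split
#'
#' Mini-batch gradient descent with momentum on the weighted factual loss
#' plus L2 penalty, with dropout on the hidden layers, a max-norm constraint
#' re-applied after every update, and per-epoch mini-batches stratified to
#' preserve the arm proportions. Training runs up to `hp$max_epochs` epochs
#' and the returned model is the parameter snapshot from the epoch with the
#' lowest validation factual MSE.
#'
#' @param X_train,y_train,alloc_train Training features, slope targets and
#'   arm allocations.
#' @param X_val,y_val,alloc_val Validation split (disjoint from training).
#' @param hp An [mlp_hyperparams()] object.
#' @param arms Arm registry (character); defaults to the arms in training.
#' @param seed Seed for initialization and shuffling; defaults to `hp$seed`.
#' @param init_trunk Optional `mlp_model` whose trunk parameters initialize
#'   (and, with `frozen_trunk = TRUE`, are kept fixed in) the new model;
#'   heads are always freshly initialized.
#' @param frozen_trunk If `TRUE` the trunk receives no updates.
#' @return List with `model` (the early-stopped `mlp_model`), `best_epoch`
#'   and `history` (data frame of per-epoch train/validation MSE).
#' @export
train_fold <- function(X_train, y_train, alloc_train, X_val, y_val, alloc_val,
                       hp, arms = NULL, seed = hp$seed,
                       init_trunk = NULL, frozen_trunk = FALSE) {
  if (nrow(X_train) == 0L || nrow(X_val) == 0L) stop("empty split")
  if (is.null(arms)) arms <- unique(alloc_train)
  model <- mlp_init(ncol(X_train), arms, hp$hidden_width, seed)
  if (!is.null(init_trunk)) {
    if (init_trunk$hidden_width != hp$hidden_width) {
      stop("init_trunk width does not match hp$hidden_width")
    }
    model$W1 <- init_trunk$W1
    model$b1 <- init_trunk$b1
  }
  model$frozen_trunk <- isTRUE(frozen_trunk)
  wts <- loss_weights(alloc_train, arms)
  W <- model$hidden_width
  vel <- list(W1 = model$W1 * 0, b1 = model$b1 * 0,
              heads = lapply(model$heads, function(h) {
                list(W2 = h$W2 * 0, b2 = h$b2 * 0, w3 = h$w3 * 0, b3 = 0)
              }))
  best <- list(mse = Inf, model = model, epoch = 0L)
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  for (epoch in seq_len(hp$max_epochs)) {
    batches <- .stratified_batches(alloc_train, hp$batch_size)
    for (b in batches) {
      step <- .sgd_step(model, vel, X_train[b, , drop = FALSE], y_train[b],
                        alloc_train[b], wts, hp)
      model <- step$model
      vel <- step$vel
    }
    train_mse <- .factual_mse(model, X_train, y_train, alloc_train)
    val_mse <- .factual_mse(model, X_val, y_val, alloc_val)
    if (!is.finite(train_mse) || !is.finite(val_mse)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    history <- rbind(history, data.frame(epoch = epoch, train_mse = train_mse,
                                         val_mse = val_mse))
    if (val_mse < best$mse) {
      best <- list(mse = val_mse, model = model, epoch = epoch)
    }
  }
  list(model = best$model, best_epoch = best$epoch, history = history)
}

#' Cross-validated early-stopping ensemble with crogged metrics
#'
#' Splits the data into k folds stratified by arm, trains one early-stopped
#' MLP per fold ([train_fold()]), and pools all out-of-fold predictions to
#' compute single "crogged" (cross-validation aggregated) validation
#' metrics: the factual MSE and, when CDP24 labels are supplied, the
#' AD_wabc of the out-of-fold CATE ranking. The k members form an ensemble
#' whose prediction is the arithmetic mean of the members' predictions.
#'
#' @param X,y,alloc Features, slope targets, arm allocations.
#' @param hp An [mlp_hyperparams()].
#' @param k Number of folds (default 4).
#' @param seed Seed for fold assignment; member j trains with `seed + j`.
#' @param arms Arm registry; defaults to the arms present.
#' @param surv Optional data frame with `time` and `event` columns (CDP24
#'   labels, aligned with rows of `X`) enabling the crogged AD_wabc.
#' @param treatment_arm,control_arm Arms differenced for the CATE ranking
#'   when `surv` is supplied.
#' @param grid,horizon AD(c) threshold grid and RMST horizon.
#' @param init Optional `mlp_model` or list of models supplying trunk
#'   initializations per member.
#' @param frozen_trunk If `TRUE`, trunks stay fixed at their initialization.
#' @return Object of class `mlp_ensemble`: `members`, `arms`, `folds`,
#'   `oof` (out-of-fold prediction matrix), `fold_mses`, `crogged_mse`,
#'   `crogged_ad_wabc` (or `NA`), `hp`.
#' @export
cross_validated_ensemble <- function(X, y, alloc, hp, k = 4L, seed = 1L,
                                     arms = NULL, surv = NULL,
                                     treatment_arm = NULL, control_arm = NULL,
                                     grid = seq(0, 0.85, by = 0.05),
                                     horizon = 2, init = NULL,
                                     frozen_trunk = FALSE) {
  if (k < 2L) stop("k must be at least 2")
  if (is.null(arms)) arms <- unique(alloc)
  set.seed(seed)
  folds <- integer(length(alloc))
  for (a in arms) {
    idx <- which(alloc == a)
    if (length(idx) < k) {
      stop("stratification error: arm '", a, "' has fewer patients than folds")
    }
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  if (inherits(init, "mlp_model")) init <- list(init)
  members <- vector("list", k)
  oof <- matrix(NA_real_, nrow(X), length(arms),
                dimnames = list(rownames(X), arms))
  fold_mses <- numeric(k)
  for (j in seq_len(k)) {
    tr <- folds != j
    va <- folds == j
    tf <- train_fold(X[tr, , drop = FALSE], y[tr], alloc[tr],
                     X[va, , drop = FALSE], y[va], alloc[va],
                     hp, arms = arms, seed = seed + j,
                     init_trunk = if (!is.null(init)) {
                       init[[(j - 1L) %% length(init) + 1L]]
                     },
                     frozen_trunk = frozen_trunk)
    members[[j]] <- tf$model
    mu_va <- predict(tf$model, X[va, , drop = FALSE])
    oof[va, ] <- mu_va
    fold_mses[j] <- mean((mu_va[cbind(seq_len(sum(va)),
                                      match(alloc[va], arms))] - y[va])^2)
  }
  crogged_mse <- mean((oof[cbind(seq_along(y), match(alloc, arms))] - y)^2)
  crogged_ad <- NA_real_
  if (!is.null(surv)) {
    if (is.null(treatment_arm) || is.null(control_arm)) {
      stop("treatment_arm and control_arm are required with surv labels")
    }
    cate <- -(oof[, treatment_arm] - oof[, control_arm])
    sel <- alloc %in% c(treatment_arm, control_arm)
    curve <- ad_curve(cate[sel], surv$time[sel], surv$event[sel],
                      alloc[sel] == treatment_arm, grid = grid,
                      horizon = horizon)
    crogged_ad <- ad_wabc(curve)
  }
  structure(list(members = members, arms = arms, folds = folds, oof = oof,
                 fold_mses = fold_mses, crogged_mse = crogged_mse,
                 crogged_ad_wabc = crogged_ad, hp = hp),
            class = "mlp_ensemble")
}

#' Predict potential outcomes with an ensemble
#'
#' The ensemble prediction is the arithmetic mean of its members'
#' predictions.
#'
#' @param object An `mlp_ensemble`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Matrix of predicted slopes, one column per arm.
#' @export
predict.mlp_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, predict, newdata = newdata)
  Reduce(`+`, preds) / length(preds)
}

#' CATE estimate from a fitted model or ensemble
#'
#' Computes `-(mu_hat_treatment(x) - mu_hat_control(x))`: the potential
#' outcomes are EDSS slopes (worsening rates), and the sign flip makes
#' positive values mean predicted benefit (slower worsening on treatment).
#'
#' @param model An `mlp_model` or `mlp_ensemble`.
#' @param X Feature matrix.
#' @param treatment_arm,control_arm Registered arm ids to difference.
#' @return Numeric vector of CATE estimates, one per row of `X`.
#' @export
predict_cate <- function(model, X, treatment_arm, control_arm) {
  mu <- predict(model, X)
  for (a in c(treatment_arm, control_arm)) {
    if (!a %in% colnames(mu)) stop("unregistered arm: ", a)
  }
  -(mu[, treatment_arm] - mu[, control_arm])
}

#' One-SD model selection rule
#'
#' Given per-candidate crogged MSEs, per-fold MSE vectors and crogged
#' AD_wabc values, selects the candidate with the highest AD_wabc among
#' those whose crogged MSE is within one standard deviation (computed from
#' the best candidate's per-fold MSEs) of the minimum crogged MSE.
#'
#' @param crogged_mse Numeric vector of crogged MSEs.
#' @param fold_mses List of per-fold MSE vectors, one per candidate.
#' @param crogged_ad Numeric vector of crogged AD_wabc values.
#' @return List with `selected` (index) and `eligible` (logical vector).
#' @export
select_one_sd <- function(crogged_mse, fold_mses, crogged_ad) {
  best <- which.min(crogged_mse)
  thr <- crogged_mse[best] + stats::sd(fold_mses[[best]])
  eligible <- crogged_mse <= thr
  ad <- ifelse(eligible, crogged_ad, -Inf)
  ad[is.na(ad)] <- -Inf
  selected <- which.max(ad)
  list(selected = selected, eligible = eligible)
}

#' Random hyperparameter search with crogged selection
#'
#' Draws `n_candidates` hyperparameter configurations (log-uniform for the
#' learning rate and L2 coefficient, uniform for momentum, dropout and
#' max-norm, uniform over the width set), evaluates each with
#' [cross_validated_ensemble()] on identical folds, and applies the one-SD
#' rule ([select_one_sd()]): the winner has the highest crogged AD_wabc
#' among candidates whose crogged MSE is within one SD (of the best
#' candidate's per-fold MSEs) of the minimum.
#'
#' @param X,y,alloc Training data.
#' @param surv CDP24 labels (`time`, `event`) for the AD_wabc metric.
#' @param treatment_arm,control_arm Arms differenced for the ranking metric.
#' @param search_space List of ranges: `hidden_width` (set),
#'   `learning_rate`, `l2` (log-uniform bounds), `momentum`, `dropout`,
#'   `max_norm` (uniform bounds).
#' @param n_candidates Number of configurations to draw.
#' @param seed Seed for the draw and for every CV split.
#' @param k Folds per evaluation.
#' @param batch_size,max_epochs Fixed (untuned) training settings.
#' @return Object of class `mlp_search`: `candidates` (data frame with
#'   per-candidate hyperparameters and crogged metrics), `selected` (row
#'   index), `ensemble` (the selected candidate's fitted ensemble).
#' @export
random_search_select <- function(X, y, alloc, surv, treatment_arm, control_arm,
                                 search_space = list(
                                   hidden_width = c(16L, 32L, 64L, 128L),
                                   learning_rate = c(1e-4, 1e-1),
                                   momentum = c(0.5, 0.99),
                                   l2 = c(1e-6, 1e-2),
                                   max_norm = c(1, 5),
                                   dropout = c(0, 0.5)),
                                 n_candidates = 20L, seed = 1L, k = 4L,
                                 batch_size = 64L, max_epochs = 100L) {
  if (n_candidates < 1L) stop("n_candidates must be at least 1")
  set.seed(seed)
  logu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  hps <- lapply(seq_len(n_candidates), function(i) {
    mlp_hyperparams(
      hidden_width = sample(search_space$hidden_width, 1L),
      learning_rate = logu(search_space$learning_rate[1],
                           search_space$learning_rate[2]),
      momentum = stats::runif(1, search_space$momentum[1],
                              search_space$momentum[2]),
      l2 = logu(search_space$l2[1], search_space$l2[2]),
      dropout = stats::runif(1, search_space$dropout[1],
                             search_space$dropout[2]),
      max_norm = stats::runif(1, search_space$max_norm[1],
                              search_space$max_norm[2]),
      batch_size = batch_size, max_epochs = max_epochs, seed = seed)
  })
  ensembles <- lapply(hps, function(hp) {
    cross_validated_ensemble(X, y, alloc, hp, k = k, seed = seed, surv = surv,
                             treatment_arm = treatment_arm,
                             control_arm = control_arm)
  })
  mse <- vapply(ensembles, `[[`, numeric(1), "crogged_mse")
  ad <- vapply(ensembles, `[[`, numeric(1), "crogged_ad_wabc")
  fold_mses <- lapply(ensembles, `[[`, "fold_mses")
  sel <- select_one_sd(mse, fold_mses, ad)
  candidates <- data.frame(
    hidden_width = vapply(hps, `[[`, integer(1), "hidden_width"),
    learning_rate = vapply(hps, `[[`, numeric(1), "learning_rate"),
    momentum = vapply(hps, `[[`, numeric(1), "momentum"),
    l2 = vapply(hps, `[[`, numeric(1), "l2"),
    dropout = vapply(hps, `[[`, numeric(1), "dropout"),
    max_norm = vapply(hps, `[[`, numeric(1), "max_norm"),
    crogged_mse = mse,
    fold_sd = vapply(fold_mses, stats::sd, numeric(1)),
    crogged_ad_wabc = ad,
    eligible = sel$eligible)
  structure(list(candidates = candidates, selected = sel$selected,
                 ensemble = ensembles[[sel$selected]]),
            class = "mlp_search")
}

#' Pretrain on a multi-arm dataset, then freeze the trunk and fine-tune
#'
#' Two-phase transfer scheme: phase 1 trains a multi-headed ensemble (one
#' head per arm, e.g. five for a pooled relapsing-remitting dataset) on the
#' pretraining data; phase 2 copies each member's trunk, freezes its
#' parameters, attaches freshly initialized heads for the fine-tuning arms
#' (e.g. treatment and placebo of a primary-progressive dataset), and
#' trains only the head parameters.
#'
#' @param X_pre,y_pre,alloc_pre Pretraining data (multi-arm).
#' @param X_fine,y_fine,alloc_fine Fine-tuning data.
#' @param hp_pre,hp_fine Hyperparameters for each phase; the hidden widths
#'   must match so the trunk is transferable.
#' @param k Folds per phase.
#' @param seed Base seed.
#' @param surv_fine Optional CDP24 labels for the fine-tuning data (enables
#'   the crogged AD_wabc of the fine-tuned ensemble).
#' @param treatment_arm,control_arm Fine-tuning arms for the CATE.
#' @return List of class `transfer_model` with `pretrained` and `finetuned`
#'   `mlp_ensemble`s.
#' @export
pretrain_and_finetune <- function(X_pre, y_pre, alloc_pre,
                                  X_fine, y_fine, alloc_fine,
                                  hp_pre, hp_fine, k = 4L, seed = 1L,
                                  surv_fine = NULL,
                                  treatment_arm = NULL, control_arm = NULL) {
  if (hp_pre$hidden_width != hp_fine$hidden_width) {
    stop("pretraining and fine-tuning hidden widths must match")
  }
  pretrained <- cross_validated_ensemble(X_pre, y_pre, alloc_pre, hp_pre,
                                         k = k, seed = seed)
  finetuned <- cross_validated_ensemble(X_fine, y_fine, alloc_fine, hp_fine,
                                        k = k, seed = seed + 1000L,
                                        surv = surv_fine,
                                        treatment_arm = treatment_arm,
                                        control_arm = control_arm,
                                        init = pretrained$members,
                                        frozen_trunk = TRUE)
  structure(list(pretrained = pretrained, finetuned = finetuned),
            class = "transfer_model")
}
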