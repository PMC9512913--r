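# small deterministic training problem shared across blocks
make_problem <- function(n = 160, seed = 3, arms = c("anti_cd20", "placebo"),
                         p = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("P%03d", seq_len(n)), NULL))
  alloc <- sample(arms, n, replace = TRUE, prob = rep(1, length(arms)))
  beta <- seq(0.1, by = 0.05, length.out = p)
  y <- drop(X %*% beta) - 0.3 * (alloc == arms[1]) * X[, 1] + rnorm(n, 0, 0.1)
  list(X = X, y = y, alloc = alloc, arms = arms)
}

test_that("loss weights compensate allocation imbalance and conserve mass", {
  # equal arm sizes: all weights 1, loss is the plain factual MSE
  w <- loss_weights(rep(c("a", "b"), each = 5))
  expect_equal(unname(w), c(1, 1))
  # arm sizes (2, 1): weights n_s/(m*n_t) = 3/4 and 3/2
  alloc <- c("a", "a", "b")
  w2 <- loss_weights(alloc)
  expect_equal(unname(w2), c(3 / 4, 3 / 2))
  # size-weighted mean of the weights is exactly 1
  expect_identical(mean(w2[alloc]), 1)
  expect_error(loss_weights(c("a", "z"), arms = "a"), "z")
})

test_that("weighted factual loss uses only the allocated head", {
  pred <- matrix(c(1, 2, 3, 9, 9, 9), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  # squared errors all 1 on the factual head, arm sizes (2, 1)
  pred[3, "b"] <- 3
  targets <- c(0, 1, 2)
  alloc <- c("a", "a", "b")
  w <- loss_weights(alloc)
  expect_equal(weighted_factual_loss(pred, targets, alloc, w),
               (0.75 * 1 + 0.75 * 1 + 1.5 * 1) / 3)
  # perfect predictions: loss 0
  pred2 <- pred
  pred2[cbind(1:3, c(1, 1, 2))] <- targets
  expect_equal(weighted_factual_loss(pred2, targets, alloc, w), 0)
  expect_error(weighted_factual_loss(pred, targets, c("a", "a", "z"), w), "z")
})

test_that("training is deterministic, bounded by max-norm and <= 100 epochs", {
  pr <- make_problem()
  hp <- mlp_hyperparams(hidden_width = 8, max_epochs = 12, max_norm = 1.5,
                        batch_size = 32)
  idx <- seq_len(120)
  run <- function() {
    train_fold(pr$X[idx, ], pr$y[idx], pr$alloc[idx],
               pr$X[-idx, ], pr$y[-idx], pr$alloc[-idx], hp, seed = 11)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(predict(f1$model, pr$X), predict(f2$model, pr$X))
  expect_identical(f1$history, f2$history)
  expect_lte(nrow(f1$history), 100L)
  # every incoming weight vector respects the max-norm constraint
  m <- f1$model
  expect_true(all(sqrt(colSums(m$W1^2)) <= hp$max_norm + 1e-9))
  for (h in m$heads) {
    expect_true(all(sqrt(colSums(h$W2^2)) <= hp$max_norm + 1e-9))
    expect_lte(sqrt(sum(h$w3^2)), hp$max_norm + 1e-9)
  }
  # the snapshot is the argmin of the validation curve
  expect_equal(f1$best_epoch, which.min(f1$history$val_mse))
})

test_that("CATE predictions are antisymmetric and sign-flipped differences", {
  pr <- make_problem()
  model <- mlp_init(ncol(pr$X), pr$arms, 8, seed = 2)
  cate <- predict_cate(model, pr$X, "anti_cd20", "placebo")
  swap <- predict_cate(model, pr$X, "placebo", "anti_cd20")
  expect_identical(cate, -swap)
  expect_error(predict_cate(model, pr$X, "anti_cd20", "nope"), "unregistered")
  # identical head parameters: CATE exactly zero
  model$heads[["placebo"]] <- model$heads[["anti_cd20"]]
  expect_true(all(predict_cate(model, pr$X, "anti_cd20", "placebo") == 0))
  # constant-output surgery: mu_1 = 0.1, mu_0 = 0.3 -> CATE +0.2 (benefit)
  const <- mlp_init(ncol(pr$X), pr$arms, 4, seed = 1)
  for (a in pr$arms) {
    const$heads[[a]]$w3 <- rep(0, 4)
    const$heads[[a]]$b3 <- c(anti_cd20 = 0.1, placebo = 0.3)[[a]]
  }
  expect_equal(unname(predict_cate(const, pr$X, "anti_cd20", "placebo")),
               rep(0.2, nrow(pr$X)), tolerance = 1e-12)
})

test_that("crogged MSE pools out-of-fold predictions and the ensemble averages members", {
  pr <- make_problem(n = 200)
  hp <- mlp_hyperparams(hidden_width = 8, max_epochs = 8, batch_size = 32)
  ens <- cross_validated_ensemble(pr$X, pr$y, pr$alloc, hp, k = 4, seed = 5)
  # manual pooling oracle over the concatenated out-of-fold pairs
  mu_f <- ens$oof[cbind(seq_along(pr$y), match(pr$alloc, ens$arms))]
  expect_equal(ens$crogged_mse, mean((mu_f - pr$y)^2), tolerance = 1e-12)
  # oof rows come from the member whose fold held the patient out
  j <- 2L
  va <- ens$folds == j
  expect_equal(ens$oof[va, ], predict(ens$members[[j]], pr$X[va, , drop = FALSE]))
  # ensemble prediction is the arithmetic mean of member predictions
  probe <- pr$X[1:3, , drop = FALSE]
  manual <- Reduce(`+`, lapply(ens$members, predict, newdata = probe)) / 4
  expect_equal(predict(ens, probe), manual, tolerance = 1e-12)
  # an arm with fewer patients than folds cannot be stratified
  expect_error(
    cross_validated_ensemble(pr$X[1:9, ], pr$y[1:9],
                             c(rep("a", 7), "b", "b"), hp, k = 4, seed = 1),
    "stratification")
})

test_that("the one-SD rule trades MSE for ranking quality as specified", {
  # A: MSE 1.0 with fold SD 0.2, AD_wabc 0.01; B: MSE 1.1, AD_wabc 0.05
  fold_a <- c(0.8, 1.0, 1.2)  # sd = 0.2
  expect_equal(sd(fold_a), 0.2)
  sel <- select_one_sd(c(1.0, 1.1), list(fold_a, c(1.0, 1.1, 1.2)),
                       c(0.01, 0.05))
  expect_equal(sel$selected, 2L)  # B eligible: 1.1 <= 1.0 + 0.2
  sel2 <- select_one_sd(c(1.0, 1.5), list(fold_a, c(1.4, 1.5, 1.6)),
                        c(0.01, 0.05))
  expect_equal(sel2$selected, 1L)  # B ineligible: 1.5 > 1.2
  expect_false(sel2$eligible[2])
})

test_that("a single random-search candidate is always selected", {
  pr <- make_problem(n = 120)
  surv <- data.frame(time = rexp(120, 0.4) + 0.1,
                     event = rbinom(120, 1, 0.5))
  res <- random_search_select(pr$X, pr$y, pr$alloc, surv,
                              treatment_arm = "anti_cd20",
                              control_arm = "placebo",
                              n_candidates = 1L, seed = 9, k = 3L,
                              batch_size = 32L, max_epochs = 4L)
  expect_equal(res$selected, 1L)
  expect_equal(nrow(res$candidates), 1L)
  expect_s3_class(res$ensemble, "mlp_ensemble")
  expect_error(
    random_search_select(pr$X, pr$y, pr$alloc, surv, "anti_cd20", "placebo",
                         n_candidates = 0L),
    "at least 1")
})

test_that("fine-tuning freezes the trunk and retrains fresh heads", {
  arms5 <- c("ocrelizumab", "ifnb_sc", "laquinimod", "ifnb_im", "placebo")
  pre <- make_problem(n = 150, seed = 8, arms = arms5)
  fine <- make_problem(n = 120, seed = 9)
  hp <- mlp_hyperparams(hidden_width = 8, max_epochs = 5, batch_size = 32)
  tm <- pretrain_and_finetune(pre$X, pre$y, pre$alloc,
                              fine$X, fine$y, fine$alloc,
                              hp, hp, k = 3L, seed = 4)
  expect_equal(length(tm$pretrained$members[[1]]$heads), 5L)
  expect_equal(length(tm$finetuned$members[[1]]$heads), 2L)
  for (j in 1:3) {
    # trunk parameters bit-identical before and after fine-tuning
    expect_identical(tm$finetuned$members[[j]]$W1, tm$pretrained$members[[j]]$W1)
    expect_identical(tm$finetuned$members[[j]]$b1, tm$pretrained$members[[j]]$b1)
    # head parameters moved away from their fresh initialization
    init <- mlp_init(ncol(fine$X), fine$arms, 8,
                     seed = 4 + 1000L + j)
    expect_false(identical(tm$finetuned$members[[j]]$heads[[1]]$W2,
                           init$heads[[1]]$W2))
  }
})
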