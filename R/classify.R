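# Monte Carlo cross-validation classification: per-type undersampling to
# balanced classes, stratified 75:25 split, train-only PCA retaining 95%
# variance, nested 4-fold selection over five classifier families with fixed
# hyperparameter grids, test-set metrics, and label-permutation significance.

#' Deterministic child seed derivation
#'
#' Every source of randomness in the pipeline draws its own child seed from a
#' master seed through this map, so runs are reproducible and independent
#' stages are decoupled.
#'
#' @param master Master seed (integer).
#' @param index Stage/iteration index (integer >= 1).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  as.integer(((as.numeric(master) %% m) * 48271 + as.numeric(index)) %% m + 1)
}

#' Per-type undersampling quota
#'
#' Balanced-class quotas: by default each minority-class (+cognition) type
#' contributes 40 samples and each majority-class (-cognition) type 60, so
#' both classes total 120 (240 samples overall for a 3+/2- type structure).
#'
#' @param manifest A `voc_manifest`.
#' @param per_plus Samples per +cognition type (default 40).
#' @param per_minus Samples per -cognition type (default 60).
#' @return Named integer vector of per-type counts.
#' @export
default_quota <- function(manifest, per_plus = 40, per_minus = 60) {
  cls <- tapply(manifest$class_label, manifest$voc_type, function(z) z[1])
  q <- ifelse(cls == "+cognition", per_plus, per_minus)
  tot_plus <- sum(q[cls == "+cognition"]); tot_minus <- sum(q[cls == "-cognition"])
  if (tot_plus != tot_minus)
    stop("quota imbalance: +cognition total ", tot_plus,
         " vs -cognition total ", tot_minus)
  storage.mode(q) <- "integer"
  q
}

#' Undersample a manifest to per-type quotas
#'
#' @param manifest A `voc_manifest`.
#' @param quota Named per-type counts, e.g. from [default_quota()].
#' @param seed Integer seed.
#' @return Character vector of selected sample ids.
#' @export
undersample <- function(manifest, quota, seed) {
  set.seed(as.integer(seed))
  ids <- character(0)
  for (ty in names(quota)) {
    pool <- manifest$id[manifest$voc_type == ty]
    if (length(pool) < quota[[ty]])
      stop("type '", ty, "' has ", length(pool),
           " samples, fewer than its quota ", quota[[ty]])
    ids <- c(ids, sample(pool, quota[[ty]]))
  }
  ids
}

#' Stratified train/test split
#'
#' Splits per vocalization type so per-type proportions are preserved
#' (nearest-integer allocation, corrected to hit the overall ratio exactly
#' when per-type rounding drifts).
#'
#' @param manifest A `voc_manifest` (provides type lookup).
#' @param ids Sample ids from [undersample()].
#' @param ratio Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint).
#' @export
stratified_split <- function(manifest, ids, ratio = 0.75, seed) {
  set.seed(as.integer(seed))
  ty <- manifest$voc_type[match(ids, manifest$id)]
  types <- unique(ty)
  n_target <- round(ratio * length(ids))
  n_tr <- round(ratio * table(ty)[types])
  drift <- n_target - sum(n_tr)
  if (drift != 0) {
    frac <- (ratio * table(ty)[types]) - floor(ratio * table(ty)[types])
    ord <- order(frac, decreasing = drift > 0)
    for (i in seq_len(abs(drift)))
      n_tr[ord[i]] <- n_tr[ord[i]] + sign(drift)
  }
  train <- character(0)
  for (i in seq_along(types)) {
    pool <- ids[ty == types[i]]
    train <- c(train, sample(pool, n_tr[i]))
  }
  list(train = train, test = setdiff(ids, train))
}

# --- PCA ----------------------------------------------------------------------

#' Fit a leakage-safe PCA on training rows
#'
#' Standardizes (center, optionally unit SD) and retains the minimal number
#' of components whose cumulative explained variance reaches
#' `variance_target`. Zero-variance dimensions are dropped before fitting.
#'
#' @param x Training feature matrix (rows = samples).
#' @param variance_target Cumulative explained-variance threshold (default 0.95).
#' @param scale Unit-SD standardization before PCA (default `TRUE`).
#' @return A `pca_model`: `center`, `scale`, `keep` (retained input dims),
#'   `loadings` (dims x k), `variance_fraction`, `k`.
#' @export
fit_pca <- function(x, variance_target = 0.95, scale = TRUE) {
  stopifnot(nrow(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  keep <- which(sds > 1e-12)
  xk <- x[, keep, drop = FALSE]
  ctr <- colMeans(xk)
  scl <- if (scale) sds[keep] else rep(1, length(keep))
  xs <- sweep(sweep(xk, 2, ctr), 2, scl, "/")
  n <- nrow(xs)
  if (ncol(xs) > n) {
    # wide data: eigendecompose the n x n Gram matrix instead of a full SVD
    eg <- eigen(tcrossprod(xs), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    vf <- ev / sum(ev)
    k <- which(cumsum(vf) >= variance_target)[1]
    d <- sqrt(ev[seq_len(k)])
    loadings <- crossprod(xs, eg$vectors[, seq_len(k), drop = FALSE])
    loadings <- sweep(loadings, 2, pmax(d, 1e-300), "/")
  } else {
    sv <- svd(xs, nu = 0)
    ev <- sv$d^2
    vf <- ev / sum(ev)
    k <- which(cumsum(vf) >= variance_target)[1]
    loadings <- sv$v[, seq_len(k), drop = FALSE]
  }
  structure(
    list(center = ctr, scale = scl, keep = keep,
         loadings = loadings,
         variance_fraction = vf[seq_len(k)], k = k,
         n_dropped = ncol(x) - length(keep)),
    class = "pca_model")
}

#' Project a feature matrix onto a fitted PCA model
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param x Feature matrix with the same dimensions the model was fitted on.
#' @return Score matrix (rows x k).
#' @export
project <- function(model, x) {
  if (ncol(x) != length(model$keep) + model$n_dropped)
    stop("dimension mismatch: model fitted on ",
         length(model$keep) + model$n_dropped, " dims, got ", ncol(x))
  xs <- sweep(sweep(x[, model$keep, drop = FALSE], 2, model$center),
              2, model$scale, "/")
  xs %*% model$loadings
}

# --- classifiers --------------------------------------------------------------

#' The classifier array with its hyperparameter grids
#'
#' Enumeration order (used for deterministic tie-breaks): lasso, decision
#' tree, SVM, ridge, naive Bayes; within each, grid order as listed. Lasso
#' and ridge are L1-/L2-penalized logistic regressions with penalty strengths
#' \{0.1, 1, 10, 100\}; the decision-tree minimum leaf size takes 10
#' log-spaced integers in \[1, 67\] (deduplicated after rounding); the SVM
#' crosses C in \{0.01, 0.1, 1, 10\} with linear and RBF kernels; naive Bayes
#' comes in normal and kernel-density variants.
#'
#' @return A list of spec entries `(kind, hyper)` in enumeration order.
#' @export
classifier_specs <- function() {
  lam <- c(0.1, 1, 10, 100)
  leaves <- unique(round(exp(seq(log(1), log(67), length.out = 10))))
  costs <- c(0.01, 0.1, 1, 10)
  specs <- list()
  add <- function(kind, hyper) specs[[length(specs) + 1]] <<- list(kind = kind, hyper = hyper)
  for (l in lam) add("lasso", list(lambda = l))
  for (m in leaves) add("dt", list(min_leaf = m))
  for (k in c("linear", "rbf")) for (C in costs) add("svm", list(C = C, kernel = k))
  for (l in lam) add("ridge", list(lambda = l))
  for (v in c("normal", "kernel")) add("nbc", list(variant = v))
  specs
}

# y is integer 0/1 (1 = +cognition) throughout the fit/predict internals

fit_predict <- function(kind, hyper, xtr, ytr, xte) {
  switch(kind,
    lasso = glmnet_predict(xtr, ytr, xte, alpha = 1, lambda = hyper$lambda),
    ridge = glmnet_predict(xtr, ytr, xte, alpha = 0, lambda = hyper$lambda),
    dt = {
      # matrix-column data frame keeps formula/model.frame overhead flat in
      # the predictor count
      df <- data.frame(y = factor(ytr, levels = 0:1)); df$x <- xtr
      fit <- rpart::rpart(y ~ x, df, method = "class",
                          control = rpart::rpart.control(
                            minbucket = hyper$min_leaf,
                            minsplit = max(2, 3 * hyper$min_leaf),
                            cp = 0, xval = 0,
                            maxcompete = 0, maxsurrogate = 0,
                            usesurrogate = 0))
      dfe <- data.frame(row.names = seq_len(nrow(xte))); dfe$x <- xte
      pr <- stats::predict(fit, dfe)[, "1"]
      list(score = pr, label = as.integer(pr > 0.5))
    },
    svm = svm_predict(xtr, ytr, xte, hyper),
    nbc = if (hyper$variant == "normal") nb_normal_predict(xtr, ytr, xte)
          else nb_kernel_predict(xtr, ytr, xte),
    stop("unknown classifier kind: ", kind))
}

glmnet_predict <- function(xtr, ytr, xte, alpha, lambda) {
  pr <- glmnet_path_scores(xtr, ytr, xte, alpha, lambda)[, 1]
  list(score = pr, label = as.integer(pr > 0.5))
}

# response-scale scores for every lambda in one path fit (columns = lambdas)
glmnet_path_scores <- function(xtr, ytr, xte, alpha, lambdas) {
  path <- sort(unique(c(lambdas, max(lambdas) * 2)), decreasing = TRUE)
  fit <- glmnet::glmnet(xtr, factor(ytr, levels = 0:1), family = "binomial",
                        alpha = alpha, lambda = path)
  stats::predict(fit, xte, s = lambdas, type = "response", exact = TRUE,
                 x = xtr, y = factor(ytr, levels = 0:1))
}

svm_predict <- function(xtr, ytr, xte, hyper) {
  # standardize once ourselves; with unit variances the bandwidth scale
  # heuristic 1/(d * Var) becomes 1/d
  ctr <- colMeans(xtr)
  sds <- pmax(apply(xtr, 2, stats::sd), 1e-12)
  xs <- sweep(sweep(xtr, 2, ctr), 2, sds, "/")
  vs <- sweep(sweep(xte, 2, ctr), 2, sds, "/")
  kern <- if (hyper$kernel == "rbf") "radial" else "linear"
  gam <- 1 / ncol(xtr)
  # SMO termination tolerance relaxed to 0.01: inner-CV accuracy is stable
  # to it and non-separable label-permuted fits converge much faster
  fit <- e1071::svm(xs, factor(ytr, levels = 0:1), kernel = kern,
                    cost = hyper$C, gamma = gam, scale = FALSE,
                    tolerance = 0.01, fitted = FALSE)
  dv <- svm_decision_values(fit, vs)
  # orient the decision value so larger = +cognition (class "1")
  pos_first <- fit$levels[fit$labels[1]] == "1"
  score <- if (pos_first) dv else -dv
  list(score = score, label = as.integer(score > 0))
}

# decision values straight from the libsvm model object (skips predict.svm's
# model-frame machinery); fit must have been trained with scale = FALSE
svm_decision_values <- function(fit, x) {
  K <- if (fit$kernel == 0) {
    x %*% t(fit$SV)
  } else {
    d2 <- outer(rowSums(x^2), rowSums(fit$SV^2), "+") - 2 * x %*% t(fit$SV)
    exp(-fit$gamma * pmax(d2, 0))
  }
  as.numeric(K %*% fit$coefs) - fit$rho
}

nb_normal_predict <- function(xtr, ytr, xte) {
  loglik <- function(cls) {
    xi <- xtr[ytr == cls, , drop = FALSE]
    mu <- colMeans(xi)
    sg <- pmax(apply(xi, 2, stats::sd), 1e-9)
    z <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    -0.5 * rowSums(z^2) - sum(log(sg)) + log(mean(ytr == cls))
  }
  l0 <- loglik(0); l1 <- loglik(1)
  m <- pmax(l0, l1)
  p1 <- exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
  list(score = p1, label = as.integer(p1 > 0.5))
}

nb_kernel_predict <- function(xtr, ytr, xte) {
  loglik <- function(cls) {
    xi <- xtr[ytr == cls, , drop = FALSE]
    # Silverman rule-of-thumb bandwidth per dimension (SD form)
    sds <- sqrt(pmax(colMeans(xi^2) - colMeans(xi)^2, 0) * nrow(xi) / (nrow(xi) - 1))
    bw <- pmax(0.9 * sds * nrow(xi)^(-0.2), 1e-9)
    ll <- numeric(nrow(xte))
    for (j in seq_len(ncol(xte))) {
      z <- outer(xte[, j], xi[, j], "-") / bw[j]
      dens <- rowMeans(exp(-0.5 * z * z)) / (bw[j] * sqrt(2 * pi))
      ll <- ll + log(pmax(dens, 1e-300))
    }
    ll + log(mean(ytr == cls))
  }
  l0 <- loglik(0); l1 <- loglik(1)
  m <- pmax(l0, l1)
  p1 <- exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
  list(score = p1, label = as.integer(p1 > 0.5))
}

# --- metrics ------------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half: equals the
#' probability that a random positive outscores a random negative. Degenerate
#' score sets (all equal) give 0.5.
#'
#' @param scores Continuous classifier scores (larger = more positive).
#' @param labels Binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- nested selection and evaluation ------------------------------------------

stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Inner 4-fold classifier and hyperparameter selection
#'
#' Stratified k-fold cross-validation on the training scores only; every
#' (classifier, hyperparameter) combination is trained on k-1 folds and
#' validated on the held-out fold, rotating. The combination with the highest
#' mean validation accuracy wins; exact ties go to the earliest combination
#' in [classifier_specs()] enumeration order.
#'
#' @param x Training score matrix.
#' @param y Training labels (integer 0/1).
#' @param folds Number of inner folds (default 4).
#' @param specs Classifier array (default [classifier_specs()]).
#' @param seed Integer seed (fold assignment).
#' @return List `(kind, hyper, cv_accuracy)`.
#' @export
inner_select <- function(x, y, folds = 4, specs = classifier_specs(), seed) {
  fold <- stratified_folds(y, folds, seed)
  if (any(tapply(y, fold, function(z) length(unique(z))) < 2))
    stop("an inner fold is missing a class")
  kinds <- vapply(specs, `[[`, character(1), "kind")
  acc <- matrix(NA_real_, length(specs), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xva <- x[!tr, , drop = FALSE]; yva <- y[!tr]
    # lasso/ridge: one path fit per fold covers the whole lambda grid
    for (kd in c("lasso", "ridge")) {
      pos <- which(kinds == kd)
      if (!length(pos)) next
      lams <- vapply(specs[pos], function(s) s$hyper$lambda, numeric(1))
      sc <- glmnet_path_scores(xtr, ytr, xva, alpha = if (kd == "lasso") 1 else 0,
                               lambdas = lams)
      acc[pos, f] <- colMeans((sc > 0.5) == (yva == 1))
    }
    for (s in which(!(kinds %in% c("lasso", "ridge")))) {
      p <- fit_predict(specs[[s]]$kind, specs[[s]]$hyper, xtr, ytr, xva)
      acc[s, f] <- mean(p$label == yva)
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc) # first maximum = enumeration-order tie-break
  list(kind = specs[[best]]$kind, hyper = specs[[best]]$hyper,
       cv_accuracy = mean_acc[best])
}

#' Fit the selected model on all training rows and evaluate on the test set
#'
#' @param kind,hyper Winning classifier from [inner_select()].
#' @param xtr,ytr Training scores and labels.
#' @param xte,yte Test scores and labels.
#' @param test_types Optional vocalization types of test rows, for per-type
#'   confusion counts.
#' @return An `iteration_result`: selected model, `auc`, `acc`, `sensitivity`,
#'   `specificity`, and per-type confusion counts.
#' @export
train_and_evaluate <- function(kind, hyper, xtr, ytr, xte, yte,
                               test_types = NULL) {
  p <- fit_predict(kind, hyper, xtr, ytr, xte)
  tp <- sum(p$label == 1 & yte == 1); fn <- sum(p$label == 0 & yte == 1)
  tn <- sum(p$label == 0 & yte == 0); fp <- sum(p$label == 1 & yte == 0)
  conf <- NULL
  if (!is.null(test_types)) {
    conf <- table(voc_type = test_types,
                  predicted = factor(p$label, levels = 0:1,
                                     labels = c("-cognition", "+cognition")))
  }
  structure(
    list(kind = kind, hyper = hyper,
         auc = auc_score(p$score, yte),
         acc = (tp + tn) / length(yte),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         confusion = conf),
    class = "iteration_result")
}

# Stage 1 of an MCCV iteration: undersample, split, fit PCA on training rows,
# project. None of this depends on the class labels (the split is stratified
# by vocalization type), so one prepared iteration serves both the observed
# run and every label permutation of its subset.
prepare_iteration <- function(block, manifest, quota, iter_seed,
                              variance_target, scale, ratio = 0.75) {
  ids <- undersample(manifest, quota, seed = child_seed(iter_seed, 1))
  lab <- ifelse(manifest$class_label[match(ids, manifest$id)] == "+cognition", 1L, 0L)
  ty <- manifest$voc_type[match(ids, manifest$id)]
  sp <- stratified_split(manifest, ids, ratio, seed = child_seed(iter_seed, 2))
  itr <- match(sp$train, ids); ite <- match(sp$test, ids)
  pca <- fit_pca(block$matrix[sp$train, , drop = FALSE], variance_target, scale)
  list(ids = ids, lab = lab, types = ty, itr = itr, ite = ite,
       str = project(pca, block$matrix[sp$train, , drop = FALSE]),
       ste = project(pca, block$matrix[sp$test, , drop = FALSE]),
       pca_k = pca$k, iter_seed = iter_seed)
}

# Stage 2: nested selection + test evaluation, optionally on permuted labels
evaluate_iteration <- function(prep, specs, permute_seed = NULL) {
  lab <- prep$lab
  inner_seed <- child_seed(prep$iter_seed, 3)
  if (!is.null(permute_seed)) {
    set.seed(as.integer(permute_seed))
    lab <- lab[sample.int(length(lab))]
    inner_seed <- child_seed(permute_seed, 3)
  }
  sel <- inner_select(prep$str, lab[prep$itr], specs = specs, seed = inner_seed)
  res <- train_and_evaluate(sel$kind, sel$hyper,
                            prep$str, lab[prep$itr],
                            prep$ste, lab[prep$ite],
                            test_types = prep$types[prep$ite])
  res$cv_accuracy <- sel$cv_accuracy
  res$pca_k <- prep$pca_k
  res
}

mccv_iteration <- function(block, manifest, quota, iter_seed, specs,
                           variance_target, scale, ratio = 0.75,
                           permute_seed = NULL) {
  prep <- prepare_iteration(block, manifest, quota, iter_seed,
                            variance_target, scale, ratio)
  evaluate_iteration(prep, specs, permute_seed)
}

#' Run Monte Carlo cross-validation
#'
#' Each iteration draws its own undersampled, class-balanced subset, splits
#' 75:25 stratified by type, fits PCA on the training rows only, selects a
#' classifier by inner 4-fold CV, and evaluates on the held-out test rows.
#' Child seeds for every stage derive deterministically from `seed`.
#'
#' @param block A `feature_block` from [assemble_features()].
#' @param manifest The matching `voc_manifest`.
#' @param n_iter Number of MCCV iterations (the reference analysis uses 100).
#' @param seed Master seed.
#' @param quota Per-type undersampling quota (default [default_quota()]).
#' @param specs Classifier array (default [classifier_specs()]).
#' @param variance_target PCA cumulative-variance threshold.
#' @param scale Standardize features before PCA.
#' @return An `mccv_result`: per-iteration results, aggregate mean and median
#'   metrics, and a per-type classification-percentage matrix (rows sum
#'   to 100).
#' @export
run_mccv <- function(block, manifest, n_iter = 100, seed = 1,
                     quota = default_quota(manifest),
                     specs = classifier_specs(),
                     variance_target = 0.95, scale = TRUE) {
  stopifnot(inherits(block, "feature_block"))
  iters <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    iters[[i]] <- tryCatch(
      mccv_iteration(block, manifest, quota, child_seed(seed, i),
                     specs, variance_target, scale),
      error = function(e) stop("MCCV iteration ", i, ": ", conditionMessage(e)))
  }
  metrics <- c("auc", "acc", "sensitivity", "specificity")
  agg <- sapply(metrics, function(m) {
    v <- vapply(iters, `[[`, numeric(1), m)
    c(mean = mean(v), median = stats::median(v))
  })
  conf <- Reduce(`+`, lapply(iters, function(r) unclass(r$confusion)))
  pct <- 100 * conf / rowSums(conf)
  structure(
    list(iterations = iters, mean = agg["mean", ], median = agg["median", ],
         confusion_counts = conf, confusion_percent = pct,
         feature_class = block$feature_class, n_iter = n_iter, seed = seed),
    class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("<mccv_result '%s'> %d iterations\n", x$feature_class, x$n_iter))
  cat(sprintf("  mean   AUC %.4f  ACC %.4f  sens %.4f  spec %.4f\n",
              x$mean["auc"], x$mean["acc"], x$mean["sensitivity"],
              x$mean["specificity"]))
  cat(sprintf("  median AUC %.4f  ACC %.4f  sens %.4f  spec %.4f\n",
              x$median["auc"], x$median["acc"], x$median["sensitivity"],
              x$median["specificity"]))
  invisible(x)
}

#' Label-permutation significance test
#'
#' Re-runs the full pipeline (split, PCA, nested selection, evaluation) on
#' each MCCV subset with class labels permuted before splitting; the p-value
#' is the fraction of permuted AUCs at or above the observed mean AUC
#' (add-one smoothed by default so p is never exactly zero).
#'
#' @param block,manifest As in [run_mccv()].
#' @param n_perm_per_iter Permutations per MCCV subset (the reference analysis
#'   uses 1000; scaled runs use fewer).
#' @param n_iter MCCV subsets (reference: 100).
#' @param seed Master seed; must match the observed run for the subsets to
#'   coincide.
#' @param observed An `mccv_result` for identical settings, or `NULL` to
#'   compute it.
#' @param add_one Add-one smoothing of the p-value (default `TRUE`).
#' @param ... Passed to [run_mccv()] / the iteration pipeline.
#' @return A `permutation_result`: `observed_auc`, `null_auc`, `p_value`.
#' @export
permutation_test <- function(block, manifest, n_perm_per_iter = 50,
                             n_iter = 20, seed = 1, observed = NULL,
                             add_one = TRUE,
                             quota = default_quota(manifest),
                             specs = classifier_specs(),
                             variance_target = 0.95, scale = TRUE) {
  if (n_perm_per_iter < 1) stop("n_perm_per_iter must be >= 1")
  if (is.null(observed))
    observed <- run_mccv(block, manifest, n_iter, seed, quota, specs,
                         variance_target, scale)
  obs_auc <- unname(observed$mean["auc"])
  null_auc <- numeric(0)
  for (i in seq_len(n_iter)) {
    iter_seed <- child_seed(seed, i)
    # the subset, split and PCA are label-independent, so they are prepared
    # once per MCCV subset and shared by its permutations
    prep <- prepare_iteration(block, manifest, quota, iter_seed,
                              variance_target, scale)
    for (j in seq_len(n_perm_per_iter)) {
      r <- evaluate_iteration(prep, specs,
                              permute_seed = child_seed(iter_seed, 1000 + j))
      null_auc <- c(null_auc, r$auc)
    }
  }
  n_ge <- sum(null_auc >= obs_auc)
  p <- if (add_one) (n_ge + 1) / (length(null_auc) + 1) else n_ge / length(null_auc)
  structure(list(observed_auc = obs_auc, null_auc = null_auc, p_value = p,
                 n_perm = length(null_auc)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed mean AUC %.4f, %d permutations, p = %.4g\n",
              x$observed_auc, x$n_perm, x$p_value))
  invisible(x)
}
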