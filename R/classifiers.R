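# The four classifier families of the evaluation protocol, implemented
# in-package (no Weka/LibSVM-equivalent backend is assumed):
#   mlp  - single hidden layer of H sigmoid units, one-hot sigmoid outputs,
#          squared-error loss, full-batch gradient descent with learning rate
#          L and momentum M for N epochs, weights initialized U(-0.5, 0.5)
#          from seed S; inputs rescaled to [-1, 1] from train ranges.
#   svm  - C-SVC with RBF kernel exp(-G * |u - v|^2), solved by SMO;
#          one-vs-one voting for multi-class; inputs rescaled to [0, 1].
#   knn  - k nearest neighbors, euclidean or manhattan distance, majority
#          vote with nearest-neighbor tie-break.
#   mnlr - multinomial logistic regression with ridge penalty R, fitted by
#          BFGS on the penalized negative log-likelihood.

#' Classifier configuration
#'
#' @param family one of `"mlp"`, `"svm"`, `"knn"`, `"mnlr"`.
#' @param ... family parameters: MLP `L` (learning rate), `M` (momentum),
#'   `H` (hidden units), `N` (epochs), `S` (seed); SVM `C` (cost), `G`
#'   (gamma), `kernel` (`"rbf"`); KNN `k`, `distance`; MNLR `R` (ridge).
#' @return a `classifier_config`.
#' @export
classifier_config <- function(family = c("mlp", "svm", "knn", "mnlr"), ...) {
  family <- match.arg(family)
  p <- list(...)
  defaults <- switch(family,
    mlp = list(L = 0.2045, M = 0.1909, H = 59L, N = 5000L, S = 0L),
    svm = list(C = 1000, G = 0.1, kernel = "rbf"),
    knn = list(k = 1L, distance = "euclidean"),
    mnlr = list(R = 1e-8))
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown))
    stop("unknown ", family, " parameters: ", paste(unknown, collapse = ", "))
  defaults[names(p)] <- p
  structure(c(list(family = family), defaults), class = "classifier_config")
}

#' Shipped classifier presets
#'
#' Returns the verbatim per-experiment configurations of the published
#' protocol (learning rates, epochs, costs, gammas, distances) from the
#' packaged presets file, e.g. `classifier_preset("exp1_face", "svm")`.
#'
#' @param experiment preset name (`exp1_face`, `exp1_eyes`, `exp1_mouth`,
#'   `exp2_test1_eyes`, ..., `exp3_test2_mouth`).
#' @param family classifier family; omit for the list of all four.
#' @return a `classifier_config`, or a named list of four.
#' @export
classifier_preset <- function(experiment, family = NULL) {
  path <- system.file("extdata", "classifier_presets.json",
                      package = "facesym", mustWork = TRUE)
  all <- jsonlite::fromJSON(path)
  all[["_comment"]] <- NULL
  if (!experiment %in% names(all))
    stop("unknown preset '", experiment, "'; available: ",
         paste(names(all), collapse = ", "))
  build <- function(cfg) {
    fam <- cfg$family
    cfg$family <- NULL
    do.call(classifier_config, c(list(family = fam), cfg))
  }
  if (is.null(family)) lapply(all[[experiment]], build)
  else build(all[[experiment]][[match.arg(family,
                                          c("mlp", "svm", "knn", "mnlr"))]])
}

# ---- backends -------------------------------------------------------------

rescale_cols <- function(x, lo, hi, to = c(0, 1)) {
  rng <- hi - lo
  rng[rng == 0] <- 1
  sweep(sweep(x, 2L, lo), 2L, rng, "/") * (to[2L] - to[1L]) + to[1L]
}

fit_mlp <- function(x, y, cfg) {
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  xs <- rescale_cols(x, lo, hi, to = c(-1, 1))
  classes <- levels(y)
  tgt <- outer(as.integer(y), seq_along(classes), "==") * 1
  n <- nrow(xs); p <- ncol(xs); h <- as.integer(cfg$H); k <- length(classes)
  w1 <- v1 <- matrix(0, p + 1L, h)
  w2 <- v2 <- matrix(0, h + 1L, k)
  with_seed(as.integer(cfg$S) + 1203L, {
    w1[] <- stats::runif((p + 1L) * h, -0.5, 0.5)
    w2[] <- stats::runif((h + 1L) * k, -0.5, 0.5)
  })
  sig <- function(z) 1 / (1 + exp(-z))
  x1 <- cbind(xs, 1)
  for (epoch in seq_len(as.integer(cfg$N))) {
    a1 <- sig(x1 %*% w1)
    a1b <- cbind(a1, 1)
    out <- sig(a1b %*% w2)
    d2 <- (out - tgt) * out * (1 - out) / n
    d1 <- (d2 %*% t(w2[seq_len(h), , drop = FALSE])) * a1 * (1 - a1)
    g2 <- crossprod(a1b, d2)
    g1 <- crossprod(x1, d1)
    v2 <- cfg$M * v2 - cfg$L * g2
    v1 <- cfg$M * v1 - cfg$L * g1
    w2 <- w2 + v2
    w1 <- w1 + v1
  }
  list(w1 = w1, w2 = w2, lo = lo, hi = hi, classes = classes, sig = sig)
}

predict_mlp <- function(model, x) {
  xs <- rescale_cols(x, model$lo, model$hi, to = c(-1, 1))
  a1 <- model$sig(cbind(xs, 1) %*% model$w1)
  out <- model$sig(cbind(a1, 1) %*% model$w2)
  model$classes[max.col(out, ties.method = "first")]
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# simplified SMO for binary C-SVC on a precomputed kernel; labels in {-1, +1}
smo_fit <- function(K, y, C, tol = 1e-3, max_passes = 10L, max_iter = 5000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  passes <- 0L; iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    f <- fcache()
    E <- f - y
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * y) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        Ejs <- as.numeric(K %*% (alpha * y)) + b - y
        j <- which.max(abs(Ejs - Ei) + ifelse(seq_len(n) == i, -Inf, 0))
        Ej <- Ejs[j]
        ai <- alpha[i]; aj <- alpha[j]
        if (y[i] != y[j]) {
          Lb <- max(0, aj - ai); Hb <- min(C, C + aj - ai)
        } else {
          Lb <- max(0, ai + aj - C); Hb <- min(C, ai + aj)
        }
        if (Lb >= Hb) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj_new <- aj - y[j] * (Ei - Ej) / eta
        aj_new <- min(Hb, max(Lb, aj_new))
        if (abs(aj_new - aj) < 1e-7) next
        ai_new <- ai + y[i] * y[j] * (aj - aj_new)
        b1 <- b - Ei - y[i] * (ai_new - ai) * K[i, i] -
          y[j] * (aj_new - aj) * K[i, j]
        b2 <- b - Ej - y[i] * (ai_new - ai) * K[i, j] -
          y[j] * (aj_new - aj) * K[j, j]
        alpha[i] <- ai_new; alpha[j] <- aj_new
        b <- if (ai_new > 0 && ai_new < C) b1
             else if (aj_new > 0 && aj_new < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
      iter <- iter + 1L
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

fit_svm <- function(x, y, cfg) {
  if (!identical(cfg$kernel, "rbf"))
    stop("only the RBF kernel is supported")
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  xs <- rescale_cols(x, lo, hi, to = c(0, 1))
  classes <- levels(y)
  K <- rbf_kernel(xs, xs, cfg$G)
  pairs <- utils::combn(seq_along(classes), 2L, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- which(as.integer(y) %in% pr)
    yy <- ifelse(as.integer(y)[idx] == pr[1L], -1, 1)
    fit <- smo_fit(K[idx, idx, drop = FALSE], yy, cfg$C)
    list(idx = idx, y = yy, alpha = fit$alpha, b = fit$b, pair = pr)
  })
  list(xs = xs, lo = lo, hi = hi, classes = classes, models = models,
       gamma = cfg$G)
}

predict_svm <- function(model, x) {
  xs <- rescale_cols(x, model$lo, model$hi, to = c(0, 1))
  votes <- matrix(0L, nrow(xs), length(model$classes))
  for (m in model$models) {
    Kt <- rbf_kernel(xs, model$xs[m$idx, , drop = FALSE], model$gamma)
    dec <- as.numeric(Kt %*% (m$alpha * m$y)) + m$b
    win <- ifelse(dec >= 0, m$pair[2L], m$pair[1L])
    votes[cbind(seq_len(nrow(xs)), win)] <- votes[cbind(seq_len(nrow(xs)),
                                                        win)] + 1L
  }
  model$classes[max.col(votes, ties.method = "first")]
}

knn_predict <- function(train_x, train_y, test_x, k, distance) {
  k <- as.integer(k)
  dmat <- switch(distance,
    euclidean = {
      d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
        2 * tcrossprod(test_x, train_x)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      out <- matrix(0, nrow(test_x), nrow(train_x))
      for (j in seq_len(ncol(test_x)))
        out <- out + abs(outer(test_x[, j], train_x[, j], "-"))
      out
    },
    stop("unknown distance '", distance, "'"))
  classes <- levels(train_y)
  apply(dmat, 1L, function(d) {
    nb <- order(d)[seq_len(k)]
    tab <- table(train_y[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else as.character(train_y[nb[1L]])
  })
}

fit_mnlr <- function(x, y, cfg) {
  classes <- levels(y)
  k <- length(classes); p <- ncol(x)
  if (k < 2L) stop("mnlr needs at least two classes")
  X <- cbind(1, x)
  yi <- as.integer(y)
  nll <- function(beta) {
    B <- matrix(beta, p + 1L, k - 1L)
    eta <- cbind(X %*% B, 0)
    logz <- apply(eta, 1L, function(r) max(r) + log(sum(exp(r - max(r)))))
    -sum(eta[cbind(seq_len(nrow(X)), yi)] - logz) +
      cfg$R * sum(B[-1L, ]^2)
  }
  grad <- function(beta) {
    B <- matrix(beta, p + 1L, k - 1L)
    eta <- cbind(X %*% B, 0)
    pm <- exp(eta - apply(eta, 1L, max))
    pm <- pm / rowSums(pm)
    Y <- outer(yi, seq_len(k - 1L), "==") * 1
    G <- crossprod(X, pm[, seq_len(k - 1L), drop = FALSE] - Y)
    G[-1L, ] <- G[-1L, ] + 2 * cfg$R * B[-1L, ]
    as.numeric(G)
  }
  fit <- stats::optim(numeric((p + 1L) * (k - 1L)), nll, grad,
                      method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  list(B = matrix(fit$par, p + 1L, k - 1L), classes = classes)
}

predict_mnlr <- function(model, x) {
  eta <- cbind(cbind(1, x) %*% model$B, 0)
  model$classes[max.col(eta, ties.method = "first")]
}

# ---- dispatch -------------------------------------------------------------

#' Train on one dataset and predict another
#'
#' @param cfg a [classifier_config()] (or preset from
#'   [classifier_preset()]).
#' @param train,test `labeled_dataset`s sharing feature dimensionality and
#'   label set.
#' @return character vector of predicted labels, one per test sample.
#' @export
train_predict <- function(cfg, train, test) {
  stopifnot(inherits(cfg, "classifier_config"),
            inherits(train, "labeled_dataset"),
            inherits(test, "labeled_dataset"))
  if (ncol(train$features) != ncol(test$features))
    stop("train and test feature dimensionality differ")
  x <- train$features; y <- droplevels(train$labels); xt <- test$features
  switch(cfg$family,
         mlp = predict_mlp(fit_mlp(x, y, cfg), xt),
         svm = predict_svm(fit_svm(x, y, cfg), xt),
         knn = knn_predict(x, y, xt, cfg$k, cfg$distance),
         mnlr = predict_mnlr(fit_mnlr(x, y, cfg), xt))
}

# stratified fold assignment: within each class, shuffled then dealt
# round-robin so per-fold class proportions deviate by at most one sample
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop("class '", cls, "' has fewer than k = ", k, " members")
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' The protocol of the evaluation: per repeat, a fresh stratified partition
#' into `k` folds (seeded `seed + repeat`); every sample is tested exactly
#' once per repeat; the confusion counts of the `k` folds are accumulated and
#' summarized, then metrics are averaged across repeats (mean and sd across
#' repeats and, separately, across all k x repeats folds).
#'
#' @param ds a `labeled_dataset`.
#' @param cfg a [classifier_config()].
#' @param k number of folds (default 5).
#' @param repeats number of repetitions (default 10).
#' @param seed base seed for the fold shuffles.
#' @param group_by_subject keep all samples (and augmented siblings) of one
#'   subject in the same fold. Default `FALSE`, mirroring the image-wise
#'   protocol of the published evaluation — note that with multiple images
#'   per subject this leaks subject identity between train and test folds.
#' @return a `metrics_report`: list with `mean`, `sd`, `per_repeat`,
#'   `per_fold` (data frames), `fold_sd`, `confusion` (summed counts) and
#'   call details.
#' @export
repeated_kfold <- function(ds, cfg, k = 5L, repeats = 10L, seed = 1L,
                           group_by_subject = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"), k >= 2L, repeats >= 1L)
  labels <- droplevels(ds$labels)
  lev <- levels(labels)
  per_repeat <- vector("list", repeats)
  per_fold <- list()
  total_cm <- matrix(0, length(lev), length(lev),
                     dimnames = list(truth = lev, pred = lev))
  for (r in seq_len(repeats)) {
    fold <- with_seed(seed + r, {
      if (group_by_subject) {
        subj <- unique(ds$subject_id)
        subj_lab <- factor(
          vapply(subj, function(s)
            as.character(labels[match(s, ds$subject_id)]), character(1L)),
          levels = lev)
        sf <- stratified_folds(subj_lab, k)
        sf[match(ds$subject_id, subj)]
      } else stratified_folds(labels, k)
    })
    cm_r <- matrix(0, length(lev), length(lev),
                   dimnames = list(truth = lev, pred = lev))
    for (f in seq_len(k)) {
      test_i <- which(fold == f)
      train_i <- which(fold != f)
      pred <- train_predict(cfg, subset_dataset(ds, train_i),
                            subset_dataset(ds, test_i))
      cm_f <- confusion_matrix(labels[test_i], pred, levels = lev)
      cm_r <- cm_r + unclass(cm_f)
      per_fold[[length(per_fold) + 1L]] <-
        c(repeat_ = r, fold = f,
          compute_metrics(structure(unclass(cm_f),
                                    class = "confusion_matrix")))
    }
    total_cm <- total_cm + cm_r
    per_repeat[[r]] <- compute_metrics(structure(cm_r,
                                                 class = "confusion_matrix"))
  }
  rep_df <- as.data.frame(do.call(rbind, per_repeat))
  fold_df <- as.data.frame(do.call(rbind, per_fold))
  structure(list(
    mean = colMeans(rep_df),
    sd = apply(rep_df, 2L, stats::sd),
    fold_sd = apply(fold_df[, -(1:2)], 2L, stats::sd),
    per_repeat = rep_df, per_fold = fold_df,
    confusion = structure(total_cm, class = "confusion_matrix"),
    k = k, repeats = repeats, seed = seed, family = cfg$family),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d-fold CV x %d repeats\n",
              x$family, x$k, x$repeats))
  s <- rbind(mean = x$mean, `sd (repeats)` = x$sd)
  print(round(s, 4))
  invisible(x)
}
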