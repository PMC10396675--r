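# The classical-classifier bank: decision trees (exhaustive Gini CART),
# k-nearest-neighbour variants, kernel SVMs (dual QP via quadprog),
# regularized linear discriminants, and the bagged / random-subspace /
# RUS-boosted ensembles built on them.  Presets mirror the published
# defaults of the usual interactive classifier-comparison tool; all
# learners are written in-package because no tree/SVM/KNN package is
# available as a dependency.

# ---------------------------------------------------------------------------
# CART (binary, Gini, best-first growth capped by max_splits)

fit_cart <- function(X, y, w = NULL, max_splits = 20L) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1 / n, n)
  node_idx <- list(seq_len(n))
  feature <- 0L; threshold <- 0; left <- 0L; right <- 0L
  prob1 <- sum(w[y == 1L]) / sum(w)
  cand <- list()
  add_cand <- function(node) {
    ix <- node_idx[[node]]
    if (length(ix) < 2) return(NULL)
    s <- cpp_best_split(X[ix, , drop = FALSE], y[ix], w[ix])
    if (s$feature == 0L) return(NULL)
    list(node = node, split = s)
  }
  c1 <- add_cand(1L)
  if (!is.null(c1)) cand[[1]] <- c1
  splits_done <- 0L
  while (splits_done < max_splits && length(cand) > 0) {
    gains <- vapply(cand, function(cd) cd$split$gain, numeric(1))
    pick <- which.max(gains)
    cd <- cand[[pick]]
    cand[[pick]] <- NULL
    node <- cd$node
    ix <- node_idx[[node]]
    go_left <- X[ix, cd$split$feature] <= cd$split$threshold
    if (!any(go_left) || all(go_left)) next
    lid <- length(node_idx) + 1L; rid <- lid + 1L
    node_idx[[lid]] <- ix[go_left]; node_idx[[rid]] <- ix[!go_left]
    feature[node] <- cd$split$feature; threshold[node] <- cd$split$threshold
    left[node] <- lid; right[node] <- rid
    for (nid in c(lid, rid)) {
      feature[nid] <- 0L; threshold[nid] <- 0; left[nid] <- 0L; right[nid] <- 0L
      jw <- w[node_idx[[nid]]]
      prob1[nid] <- sum(jw[y[node_idx[[nid]]] == 1L]) / sum(jw)
      nc <- add_cand(nid)
      if (!is.null(nc)) cand[[length(cand) + 1L]] <- nc
    }
    splits_done <- splits_done + 1L
  }
  list(feature = feature, threshold = threshold, left = left, right = right,
       prob1 = prob1)
}

predict_cart <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (tree$left[node] > 0L) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    }
    out[i] <- tree$prob1[node]
  }
  as.integer(out > 0.5)
}

# ---------------------------------------------------------------------------
# KNN variants

fit_knn <- function(X, y, k, metric = "euclidean", weighted = FALSE) {
  list(X = X, y = y, k = min(k, nrow(X)), metric = metric, weighted = weighted)
}

knn_dist <- function(model, Xt) {
  A <- model$X
  switch(model$metric,
    euclidean = {
      d2 <- outer(rowSums(Xt^2), rowSums(A^2), "+") - 2 * Xt %*% t(A)
      sqrt(pmax(d2, 0))
    },
    cosine = {
      nr <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
      1 - nr(Xt) %*% t(nr(A))
    },
    minkowski3 = {
      D <- matrix(0, nrow(Xt), nrow(A))
      for (i in seq_len(nrow(Xt)))
        D[i, ] <- (colSums(abs(t(A) - Xt[i, ])^3))^(1 / 3)
      D
    },
    stopf("unknown KNN metric '%s'", model$metric))
}

predict_knn <- function(model, Xt) {
  D <- knn_dist(model, Xt)
  out <- integer(nrow(Xt))
  for (i in seq_len(nrow(Xt))) {
    ord <- order(D[i, ])[seq_len(model$k)]
    wts <- if (model$weighted) 1 / (D[i, ord]^2 + 1e-12) else rep(1, model$k)
    s1 <- sum(wts[model$y[ord] == 1L]); s0 <- sum(wts) - s1
    out[i] <- as.integer(s1 > s0)  # tie -> negative (benign) class
  }
  out
}

# ---------------------------------------------------------------------------
# Kernel SVM (C-classification, dual solved with quadprog)

svm_kernel <- function(A, B, kern) {
  switch(kern$type,
    # automatic kernel scale 1/P keeps dot products of standardized
    # features O(1) regardless of dimensionality
    poly = (1 + (A %*% t(B)) / ncol(A))^kern$degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      exp(-pmax(d2, 0) / kern$sigma^2)
    },
    stopf("unknown SVM kernel '%s'", kern$type))
}

fit_svm <- function(X, y01, kern, C = 1, standardize = TRUE) {
  n <- nrow(X)
  std <- if (standardize) standardize_fit(X) else NULL
  Xs <- if (is.null(std)) X else std$apply(X)
  if (kern$type == "rbf" && is.function(kern$sigma_fn))
    kern$sigma <- kern$sigma_fn(ncol(X))
  y <- ifelse(y01 == 1L, 1, -1)
  K <- svm_kernel(Xs, Xs, kern)
  Q <- (y %o% y) * K
  ridge <- 1e-8 * max(1, mean(diag(Q)))
  sol <- NULL
  for (tries in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = Q + diag(ridge, n), dvec = rep(1, n),
                         Amat = cbind(y, diag(n), -diag(n)),
                         bvec = c(0, rep(0, n), rep(-C, n)), meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stopf("SVM dual QP failed to solve")
  alpha <- pmax(sol$solution, 0)
  sv <- alpha > 1e-8
  f0 <- as.vector(K %*% (alpha * y))
  free <- sv & alpha < C - 1e-6
  b <- if (any(free)) mean(y[free] - f0[free]) else mean(y[sv] - f0[sv])
  list(std = std, kern = kern, alpha = alpha[sv], y = y[sv],
       Xsv = Xs[sv, , drop = FALSE], b = b)
}

predict_svm <- function(model, Xt) {
  Xs <- if (is.null(model$std)) Xt else model$std$apply(Xt)
  f <- as.vector(svm_kernel(Xs, model$Xsv, model$kern) %*%
                   (model$alpha * model$y)) + model$b
  as.integer(f > 0)
}

# ---------------------------------------------------------------------------
# Regularized linear discriminant (used standalone in subspace ensembles)

fit_lda2 <- function(X, y01, reg = 1e-4) {
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  if (n1 == 0 || n0 == 0)
    return(list(majority = as.integer(n1 >= n0)))
  mu0 <- colMeans(X[y01 == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y01 == 1L, , drop = FALSE])
  Xc <- X
  Xc[y01 == 0L, ] <- sweep(X[y01 == 0L, , drop = FALSE], 2, mu0)
  Xc[y01 == 1L, ] <- sweep(X[y01 == 1L, , drop = FALSE], 2, mu1)
  S <- crossprod(Xc) / max(1, nrow(X) - 2)
  lam <- reg * max(mean(diag(S)), 1e-8)
  wv <- NULL
  for (tries in 1:6) {
    wv <- tryCatch(solve(S + diag(lam, ncol(X)), mu1 - mu0),
                   error = function(e) NULL)
    if (!is.null(wv)) break
    lam <- lam * 100
  }
  if (is.null(wv)) return(list(majority = as.integer(n1 >= n0)))
  thr <- sum(wv * (mu0 + mu1)) / 2 - log(n1 / n0)
  list(w = wv, thr = thr)
}

predict_lda2 <- function(model, Xt) {
  if (!is.null(model$majority)) return(rep(model$majority, nrow(Xt)))
  as.integer(as.vector(Xt %*% model$w) > model$thr)
}

# ---------------------------------------------------------------------------
# Ensembles

fit_bagged <- function(X, y, n_trees = 30L, seed = 1L) {
  trees <- vector("list", n_trees)
  with_local_seed(derive_seed(seed, 11L), {
    for (t in seq_len(n_trees)) {
      ix <- sample(nrow(X), replace = TRUE)
      trees[[t]] <- fit_cart(X[ix, , drop = FALSE], y[ix],
                             max_splits = nrow(X) - 1L)
    }
  })
  list(trees = trees)
}

fit_subspace <- function(X, y, base = c("discriminant", "knn"),
                         n_learners = 30L, seed = 1L) {
  base <- match.arg(base)
  p <- ncol(X)
  dim_sub <- ceiling(p / 2)
  learners <- vector("list", n_learners)
  with_local_seed(derive_seed(seed, 13L), {
    for (t in seq_len(n_learners)) {
      fs <- sort(sample(p, dim_sub))
      m <- if (base == "discriminant")
        fit_lda2(X[, fs, drop = FALSE], y)
      else fit_knn(X[, fs, drop = FALSE], y, k = 1L)
      learners[[t]] <- list(features = fs, model = m)
    }
  })
  list(base = base, learners = learners)
}

fit_rusboost <- function(X, y, n_rounds = 30L, max_splits = 20L,
                         learn_rate = 0.1, seed = 1L) {
  n <- nrow(X)
  d <- rep(1 / n, n)
  rounds <- list()
  minority <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  n_min <- sum(y == minority)
  with_local_seed(derive_seed(seed, 17L), {
    for (t in seq_len(n_rounds)) {
      maj_ix <- which(y != minority); min_ix <- which(y == minority)
      take <- if (length(maj_ix) > n_min) {
        pr <- d[maj_ix] / sum(d[maj_ix])
        sample(maj_ix, n_min, prob = pr)
      } else maj_ix
      ix <- c(min_ix, take)
      tree <- fit_cart(X[ix, , drop = FALSE], y[ix], w = d[ix] / sum(d[ix]),
                       max_splits = max_splits)
      pred <- predict_cart(tree, X)
      miss <- pred != y
      eps <- sum(d[miss])
      eps <- min(max(eps, 1e-10), 1 - 1e-10)
      alpha <- learn_rate * 0.5 * log((1 - eps) / eps)
      if (alpha <= 0) alpha <- 1e-6
      rounds[[t]] <- list(tree = tree, alpha = alpha)
      d <- d * exp(alpha * ifelse(miss, 1, -1))
      d <- d / sum(d)
    }
  })
  list(rounds = rounds)
}

vote01 <- function(votes, weights = NULL) {
  # votes: matrix n x m of 0/1 predictions
  if (is.null(weights)) weights <- rep(1, ncol(votes))
  s1 <- as.vector(votes %*% weights)
  s0 <- sum(weights) - s1
  as.integer(s1 > s0)
}

# ---------------------------------------------------------------------------
# Presets and the public classifier interface

#' Classifier presets
#'
#' The full preset table for the classifier bank.  Tree presets differ in
#' the maximum number of splits (100/20/4); KNN presets in k and metric
#' (fine/medium/coarse k = 1/10/100 Euclidean, cubic k = 10 Minkowski-3,
#' cosine k = 10 cosine, weighted k = 10 squared-inverse-distance);
#' SVM presets in kernel (polynomial degree 1/2/3 and Gaussian with kernel
#' scale sqrt(P)/4, sqrt(P), 4*sqrt(P) for P features, box constraint 1);
#' ensembles use 30 learners (bagged deep trees, random half-dimension
#' subspaces for discriminant/1-NN, and boosted 20-split trees with random
#' under-sampling at learning rate 0.1).
#'
#' @return Named list of preset descriptions.
#' @export
classifier_presets <- function() {
  list(
    bagged_ensemble = list(kind = "bagged", n_trees = 30L),
    subspace_discriminant = list(kind = "subspace", base = "discriminant",
                                 n_learners = 30L),
    subspace_knn = list(kind = "subspace", base = "knn", n_learners = 30L),
    rusboost = list(kind = "rusboost", n_rounds = 30L, max_splits = 20L,
                    learn_rate = 0.1),
    fine_tree = list(kind = "tree", max_splits = 100L),
    medium_tree = list(kind = "tree", max_splits = 20L),
    coarse_tree = list(kind = "tree", max_splits = 4L),
    linear_svm = list(kind = "svm", kern = list(type = "poly", degree = 1)),
    quadratic_svm = list(kind = "svm", kern = list(type = "poly", degree = 2)),
    cubic_svm = list(kind = "svm", kern = list(type = "poly", degree = 3)),
    fine_gaussian_svm = list(kind = "svm",
      kern = list(type = "rbf", sigma_fn = function(p) sqrt(p) / 4)),
    medium_gaussian_svm = list(kind = "svm",
      kern = list(type = "rbf", sigma_fn = function(p) sqrt(p))),
    coarse_gaussian_svm = list(kind = "svm",
      kern = list(type = "rbf", sigma_fn = function(p) 4 * sqrt(p))),
    fine_knn = list(kind = "knn", k = 1L, metric = "euclidean"),
    medium_knn = list(kind = "knn", k = 10L, metric = "euclidean"),
    coarse_knn = list(kind = "knn", k = 100L, metric = "euclidean"),
    cubic_knn = list(kind = "knn", k = 10L, metric = "minkowski3"),
    cosine_knn = list(kind = "knn", k = 10L, metric = "cosine"),
    weighted_knn = list(kind = "knn", k = 10L, metric = "euclidean",
                        weighted = TRUE)
  )
}

#' Default classifier bank
#'
#' The 17 methods benchmarked by default: four ensembles, three trees, five
#' SVMs (three polynomial, fine and medium Gaussian) and five KNN variants.
#'
#' @export
default_classifier_bank <- function() {
  c("bagged_ensemble", "subspace_discriminant", "subspace_knn", "rusboost",
    "fine_tree", "medium_tree", "coarse_tree",
    "linear_svm", "quadratic_svm", "cubic_svm",
    "fine_gaussian_svm", "medium_gaussian_svm",
    "fine_knn", "medium_knn", "cubic_knn", "cosine_knn", "weighted_knn")
}

#' Build an untrained classifier from a preset name
#'
#' @param name a preset name (see [classifier_presets()]).
#' @param seed integer seed for any stochastic learner.
#' @return Object of class `focalseg_classifier`.
#' @export
build_classifier <- function(name, seed = 1L) {
  presets <- classifier_presets()
  if (!name %in% names(presets))
    stopf("unknown classifier '%s'; valid names: %s", name,
          paste(names(presets), collapse = ", "))
  structure(list(name = name, preset = presets[[name]],
                 seed = as.integer(seed)),
            class = "focalseg_classifier")
}

#' @export
print.focalseg_classifier <- function(x, ...) {
  cat("<focalseg_classifier>", x$name, "\n")
  invisible(x)
}

# y01: integer 0/1 with 1 = positive (malignant)
fit_classifier <- function(clf, X, y01) {
  p <- clf$preset
  model <- switch(p$kind,
    tree = fit_cart(X, y01, max_splits = p$max_splits),
    knn = fit_knn(X, y01, k = p$k, metric = p$metric,
                  weighted = isTRUE(p$weighted)),
    svm = fit_svm(X, y01, kern = p$kern),
    bagged = fit_bagged(X, y01, n_trees = p$n_trees, seed = clf$seed),
    subspace = fit_subspace(X, y01, base = p$base,
                            n_learners = p$n_learners, seed = clf$seed),
    rusboost = fit_rusboost(X, y01, n_rounds = p$n_rounds,
                            max_splits = p$max_splits,
                            learn_rate = p$learn_rate, seed = clf$seed),
    stopf("unhandled classifier kind '%s'", p$kind))
  list(clf = clf, model = model)
}

predict_classifier <- function(fitted, Xt) {
  p <- fitted$clf$preset
  m <- fitted$model
  switch(p$kind,
    tree = predict_cart(m, Xt),
    knn = predict_knn(m, Xt),
    svm = predict_svm(m, Xt),
    bagged = {
      votes <- vapply(m$trees, function(tr) predict_cart(tr, Xt),
                      integer(nrow(Xt)))
      vote01(matrix(votes, nrow = nrow(Xt)))
    },
    subspace = {
      votes <- vapply(m$learners, function(l) {
        Xs <- Xt[, l$features, drop = FALSE]
        if (m$base == "discriminant") predict_lda2(l$model, Xs)
        else predict_knn(l$model, Xs)
      }, integer(nrow(Xt)))
      vote01(matrix(votes, nrow = nrow(Xt)))
    },
    rusboost = {
      votes <- vapply(m$rounds, function(r) predict_cart(r$tree, Xt),
                      integer(nrow(Xt)))
      wts <- vapply(m$rounds, `[[`, numeric(1), "alpha")
      vote01(matrix(votes, nrow = nrow(Xt)), wts)
    })
}
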