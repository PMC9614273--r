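# Classifier training behind a pluggable fitted-predictor contract: every
# model standardizes features on training statistics, tunes its
# hyperparameter over a small grid by inner stratified CV maximizing AUC,
# and exposes continuous positive-class scores for new samples via
# predict(). Ridge uses glmnet; the linear SVC, KNN, decision tree and MLP
# are compact deterministic implementations (the surrounding analysis treats
# classifier internals as exchangeable).

#' Names of the available classifiers
#' @return character vector.
#' @export
classifier_names <- function() c("ridge", "svc", "knn", "tree", "mlp")

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, st) {
  sweep(sweep(as.matrix(X), 2, st$mu), 2, st$sd, `/`)
}

# Stratified inner folds that tolerate very small minority classes: use 3
# folds when every fold can hold >= 2 minority members, else 2, else signal
# that tuning is impossible (caller falls back to the middle grid value).
inner_fold_count <- function(y) {
  n_min <- min(table(factor(y, levels = c(0, 1))))
  if (n_min >= 6) 3L else if (n_min >= 4) 2L else 0L
}

tune_by_inner_cv <- function(Xs, y, grid, fit_score_fun, seed) {
  folds <- inner_fold_count(y)
  if (folds == 0L || length(grid) == 1L) {
    return(grid[[ceiling(length(grid) / 2)]])
  }
  splits <- make_cv_splits(y, folds = folds, repetitions = 1,
                           seed = derive_seed(seed, "inner"))
  mean_auc <- vapply(grid, function(par) {
    aucs <- vapply(splits, function(sp) {
      sc <- tryCatch(
        fit_score_fun(Xs[sp$train, , drop = FALSE], y[sp$train],
                      Xs[sp$test, , drop = FALSE], par),
        error = function(e) rep(0, length(sp$test)))
      if (length(unique(y[sp$test])) < 2) return(NA_real_)
      auc(sc, y[sp$test])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  grid[[which.max(mean_auc)]]  # first max: deterministic tie-break
}

# --- individual learners (on standardized matrices) -----------------------

# glmnet needs >= 2 columns; pad single-feature models with a zero column
ridge_pad <- function(Xs) {
  if (ncol(Xs) == 1L) cbind(Xs, `.pad` = 0) else Xs
}

fit_ridge <- function(Xs, y, lambda) {
  # glmnet warns on folds with < 8 events; small-event cohorts are the
  # normal operating regime here, so the advisory is muted
  suppressWarnings(
    glmnet::glmnet(ridge_pad(Xs), y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE)
  )
}

# Linear SVC, squared-hinge loss, L2 penalty, solved by BFGS (smooth
# objective). cost scales the data term.
fit_svc <- function(Xs, y, cost) {
  yy <- ifelse(y == 1, 1, -1)
  p <- ncol(Xs)
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- 1 - yy * (Xs %*% w + b)
    0.5 * sum(w^2) + cost * mean(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- pmax(1 - yy * as.vector(Xs %*% w + b), 0)
    gw <- w - 2 * cost * colMeans((m * yy) * Xs)
    gb <- -2 * cost * mean(m * yy)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(w = fit$par[1:p], b = fit$par[p + 1])
}

score_svc <- function(fit, Xs) as.vector(Xs %*% fit$w + fit$b)

# KNN positive-class vote fraction; Euclidean distance on standardized
# features, distance ties resolved by index order.
score_knn <- function(Xtr, ytr, Xnew, k) {
  d2 <- outer(rowSums(Xnew^2), rowSums(Xtr^2), `+`) - 2 * Xnew %*% t(Xtr)
  apply(d2, 1, function(dd) {
    nn <- order(dd)[seq_len(min(k, length(dd)))]
    mean(ytr[nn])
  })
}

# Depth-limited CART with Gini impurity; leaf score = positive fraction.
fit_tree <- function(Xs, y, max_depth, min_split = 10) {
  build <- function(rows, depth) {
    node <- list(score = mean(y[rows]), leaf = TRUE)
    if (depth >= max_depth || length(rows) < min_split ||
        length(unique(y[rows])) == 1L) {
      return(node)
    }
    best <- NULL
    parent_gini <- {
      p <- mean(y[rows]); 2 * p * (1 - p)
    }
    for (j in seq_len(ncol(Xs))) {
      v <- Xs[rows, j]
      cand <- unique(stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1),
                                     type = 7))
      for (thr in cand) {
        left <- v <= thr
        nl <- sum(left); nr <- length(rows) - nl
        if (nl < 2 || nr < 2) next
        pl <- mean(y[rows][left]); pr <- mean(y[rows][!left])
        g <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / length(rows)
        gain <- parent_gini - g
        if (is.null(best) || gain > best$gain + 1e-12) {
          best <- list(gain = gain, j = j, thr = thr)
        }
      }
    }
    if (is.null(best) || best$gain <= 1e-10) return(node)
    rows_l <- rows[Xs[rows, best$j] <= best$thr]
    rows_r <- rows[Xs[rows, best$j] > best$thr]
    list(leaf = FALSE, j = best$j, thr = best$thr,
         left = build(rows_l, depth + 1), right = build(rows_r, depth + 1),
         score = mean(y[rows]))
  }
  build(seq_along(y), 0)
}

score_tree <- function(node, Xs) {
  apply(Xs, 1, function(x) {
    nd <- node
    while (!nd$leaf) nd <- if (x[nd$j] <= nd$thr) nd$left else nd$right
    nd$score
  })
}

# One-hidden-layer MLP (tanh units, logistic output), weight decay, BFGS.
fit_mlp <- function(Xs, y, hidden, decay = 1e-2, seed = 1) {
  p <- ncol(Xs); h <- hidden
  n_par <- p * h + h + h + 1
  unpack <- function(th) {
    W1 <- matrix(th[1:(p * h)], p, h)
    b1 <- th[(p * h + 1):(p * h + h)]
    w2 <- th[(p * h + h + 1):(p * h + 2 * h)]
    b2 <- th[n_par]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  fwd <- function(pars, X) {
    H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, `+`))
    as.vector(H %*% pars$w2 + pars$b2)
  }
  obj <- function(th) {
    pars <- unpack(th)
    eta <- fwd(pars, Xs)
    pr <- stats::plogis(eta)
    eps <- 1e-12
    -mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps)) +
      decay * (sum(pars$W1^2) + sum(pars$w2^2))
  }
  grad <- function(th) {
    pars <- unpack(th)
    H <- tanh(sweep(Xs %*% pars$W1, 2, pars$b1, `+`))
    eta <- as.vector(H %*% pars$w2 + pars$b2)
    d <- (stats::plogis(eta) - y) / length(y)
    dH <- (d %o% pars$w2) * (1 - H^2)
    c(as.vector(t(Xs) %*% dH + 2 * decay * pars$W1),
      colSums(dH),
      as.vector(t(H) %*% d + 2 * decay * pars$w2),
      sum(d))
  }
  th0 <- with_seed(derive_seed(seed, "mlp_init"),
                   stats::rnorm(n_par, 0, 0.5))
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-8))
  unpack(fit$par)
}

score_mlp <- function(pars, Xs) {
  H <- tanh(sweep(Xs %*% pars$W1, 2, pars$b1, `+`))
  as.vector(H %*% pars$w2 + pars$b2)
}

#' Train a classifier with inner-CV hyperparameter tuning
#'
#' Features are standardized on the training statistics; the classifier's
#' hyperparameter is chosen by inner stratified CV maximizing AUC over a
#' small grid (ridge: lambda over 5 log-spaced values; SVC: cost over 5
#' log-spaced values; KNN: k in 3/5/7/9; tree: depth 2/3/4; MLP: 2/4/8
#' hidden units). The returned object answers `predict(fit, newX)` with
#' continuous positive-class scores.
#'
#' @param name one of `"ridge"`, `"svc"`, `"knn"`, `"tree"`, `"mlp"`.
#' @param X training patients-by-features matrix (>= 1 feature).
#' @param y binary outcome, both classes present.
#' @param seed integer seed (inner folds, MLP init).
#' @return object of class `rr_model`.
#' @export
train_classifier <- function(name, X, y, seed = 1) {
  if (!name %in% classifier_names()) stop("unknown classifier: ", name)
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("need at least one feature")
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  fit <- switch(
    name,
    ridge = {
      grid <- as.list(10^seq(-3, 1, length.out = 5))
      lam <- tune_by_inner_cv(Xs, y, grid, function(Xtr, ytr, Xte, par) {
        m <- fit_ridge(Xtr, ytr, par)
        as.vector(stats::predict(m, ridge_pad(Xte)))
      }, seed)
      list(par = lam, model = fit_ridge(Xs, y, lam))
    },
    svc = {
      grid <- as.list(10^seq(-2, 2, length.out = 5))
      cost <- tune_by_inner_cv(Xs, y, grid, function(Xtr, ytr, Xte, par) {
        score_svc(fit_svc(Xtr, ytr, par), Xte)
      }, seed)
      list(par = cost, model = fit_svc(Xs, y, cost))
    },
    knn = {
      grid <- as.list(c(3, 5, 7, 9))
      k <- tune_by_inner_cv(Xs, y, grid, function(Xtr, ytr, Xte, par) {
        score_knn(Xtr, ytr, Xte, par)
      }, seed)
      list(par = k, model = list(Xtr = Xs, ytr = y))
    },
    tree = {
      grid <- as.list(c(2, 3, 4))
      dep <- tune_by_inner_cv(Xs, y, grid, function(Xtr, ytr, Xte, par) {
        score_tree(fit_tree(Xtr, ytr, par), Xte)
      }, seed)
      list(par = dep, model = fit_tree(Xs, y, dep))
    },
    mlp = {
      grid <- as.list(c(2, 4, 8))
      hid <- tune_by_inner_cv(Xs, y, grid, function(Xtr, ytr, Xte, par) {
        score_mlp(fit_mlp(Xtr, ytr, par, seed = seed), Xte)
      }, seed)
      list(par = hid, model = fit_mlp(Xs, y, hid, seed = seed))
    }
  )
  structure(list(name = name, standardize = st, par = fit$par,
                 model = fit$model, features = colnames(X)),
            class = "rr_model")
}

#' @export
predict.rr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  Xs <- standardize_apply(X, object$standardize)
  switch(object$name,
         ridge = as.vector(stats::predict(object$model, ridge_pad(Xs))),
         svc = score_svc(object$model, Xs),
         knn = score_knn(object$model$Xtr, object$model$ytr, Xs, object$par),
         tree = score_tree(object$model, Xs),
         mlp = score_mlp(object$model, Xs))
}

#' @export
print.rr_model <- function(x, ...) {
  cat(sprintf("<rr_model> %s (tuned parameter: %s), %d features\n",
              x$name, format(x$par), length(x$features)))
  invisible(x)
}
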