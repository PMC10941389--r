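#' Stratified 50/50 train/test split
#'
#' Splits samples into train and test sets within each breed-by-class
#' stratum, allocating ceiling(n/2) vs floor(n/2) per cell with a seeded
#' coin flip deciding which side receives the odd unit (a singleton
#' stratum therefore lands on one side at random).
#'
#' @param data Tibble with one row per sample.
#' @param class Name of the class column. Default `"class"`.
#' @param breed Name of the breed column, or `NULL` to stratify on class
#'   only. Default `"breed"`.
#' @param fraction Training fraction. Default 0.5.
#' @param seed Optional seed.
#' @return `data` with an added `split` column (`"train"`/`"test"`).
#' @export
stratified_split <- function(data, class = "class", breed = "breed",
                             fraction = 0.5, seed = NULL) {
  assert_cols(data, c(class, breed), "data")
  if (!is.null(seed)) set.seed(seed)
  cls <- data[[class]]
  if (is.factor(cls)) {
    empty <- setdiff(levels(cls), as.character(unique(cls)))
    if (length(empty) > 0) {
      abort(sprintf("empty stratum(s) for class level(s): %s",
                    paste(empty, collapse = ", ")))
    }
  }
  strat <- interaction(cls,
                       if (is.null(breed)) rep(1, nrow(data))
                       else data[[breed]], drop = TRUE)
  split <- character(nrow(data))
  for (lev in unique(as.character(strat))) {
    idx <- which(strat == lev)
    n <- length(idx)
    n_train <- if (runif(1) < 0.5) ceiling(fraction * n) else {
      floor(fraction * n)
    }
    train_idx <- sample(idx, n_train)
    split[train_idx] <- "train"
    split[setdiff(idx, train_idx)] <- "test"
  }
  dplyr::mutate(data, split = split)
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis: the class labels are
#' one-hot encoded and a PLS2 model is fitted on column-centred-and-scaled
#' features. Each component's weight vector is the leading singular vector
#' of the current X'Y cross-product (the NIPALS fixed point), with X and Y
#' deflated by the component scores. Class scores for new data come from
#' the indicator regression coefficients; the predicted label is the
#' argmax score.
#'
#' @param x Numeric feature matrix, samples x features (e.g. CLR values).
#' @param y Factor (or coercible) of class labels with >= 2 levels.
#' @param ncomp Number of latent components.
#' @return Object of class `resilink_plsda` with weights `W` (unit norm),
#'   loadings `P`, scores `T`, Y-loadings `Q`, per-component explained
#'   Y-variance `ssy`, preprocessing parameters and retained `features`.
#' @export
fit_plsda <- function(x, y, ncomp = 2) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("`y` must contain at least 2 classes")
  if (nrow(x) != length(y)) abort("`x` rows must match `y`")
  sds <- apply(x, 2, sd)
  drop_cols <- sds == 0 | is.na(sds)
  if (any(drop_cols)) {
    warn(sprintf("dropping %d zero-variance feature(s)", sum(drop_cols)))
    x <- x[, !drop_cols, drop = FALSE]
  }
  p <- ncol(x)
  n <- nrow(x)
  ncomp <- min(ncomp, p, n - 1)
  x_center <- colMeans(x)
  x_scale <- apply(x, 2, sd)
  xs <- scale(x, center = x_center, scale = x_scale)
  ymat <- model.matrix(~ y - 1)
  colnames(ymat) <- levels(y)
  y_means <- colMeans(ymat)
  f_mat <- scale(ymat, center = y_means, scale = FALSE)

  w_all <- matrix(0, p, ncomp)
  p_all <- matrix(0, p, ncomp)
  q_all <- matrix(0, ncol(ymat), ncomp)
  t_all <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  e_mat <- xs
  a <- 0L
  for (comp in seq_len(ncomp)) {
    m <- crossprod(e_mat, f_mat)
    sv <- svd(m, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) break
    w <- sv$u[, 1]
    t_vec <- e_mat %*% w
    tt <- sum(t_vec^2)
    if (tt < 1e-12) break
    p_vec <- crossprod(e_mat, t_vec) / tt
    q_vec <- crossprod(f_mat, t_vec) / tt
    e_mat <- e_mat - t_vec %*% t(p_vec)
    f_mat <- f_mat - t_vec %*% t(q_vec)
    a <- comp
    w_all[, a] <- w
    p_all[, a] <- p_vec
    q_all[, a] <- q_vec
    t_all[, a] <- t_vec
    ssy[a] <- sum(q_vec^2) * tt
  }
  if (a == 0) abort("no informative component could be extracted")
  w_all <- w_all[, seq_len(a), drop = FALSE]
  p_all <- p_all[, seq_len(a), drop = FALSE]
  q_all <- q_all[, seq_len(a), drop = FALSE]
  t_all <- t_all[, seq_len(a), drop = FALSE]
  ssy <- ssy[seq_len(a)]
  # regression coefficients on the scaled-X scale
  r_mat <- w_all %*% solve(crossprod(p_all, w_all))
  beta <- r_mat %*% t(q_all)
  structure(
    list(ncomp = a, W = w_all, P = p_all, Q = q_all, T = t_all,
         ssy = ssy, beta = beta, x_center = x_center, x_scale = x_scale,
         y_means = y_means, levels = levels(y),
         features = colnames(x) %||% as.character(seq_len(p))),
    class = "resilink_plsda")
}

#' Predict from a PLS-DA model
#'
#' @param object A `resilink_plsda` model.
#' @param newdata Feature matrix with (at least) the model's features.
#' @param type `"score"` for per-class indicator scores, `"class"` for
#'   argmax labels, `"components"` for latent scores.
#' @param ... Unused.
#' @return Matrix of scores, factor of labels, or matrix of component
#'   scores.
#' @export
predict.resilink_plsda <- function(object, newdata,
                                   type = c("score", "class",
                                            "components"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing) > 0) abort("newdata lacks model features")
    newdata <- newdata[, object$features, drop = FALSE]
  }
  xs <- scale(newdata, center = object$x_center, scale = object$x_scale)
  if (type == "components") {
    r_mat <- object$W %*% solve(crossprod(object$P, object$W))
    return(xs %*% r_mat)
  }
  scores <- xs %*% object$beta
  scores <- sweep(scores, 2, object$y_means, "+")
  colnames(scores) <- object$levels
  if (type == "score") return(scores)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}} with
#' unit-norm weight vectors and \eqn{SSY_a} the Y-variance explained by
#' component a, so that the mean squared VIP equals 1.
#'
#' @param model A `resilink_plsda` model.
#' @return Named numeric vector of VIP scores per retained feature.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "resilink_plsda"))
  p <- nrow(model$W)
  wnorm2 <- colSums(model$W^2)
  contrib <- sweep(model$W^2, 2, wnorm2, "/")
  v <- sqrt(p * as.vector(contrib %*% model$ssy) / sum(model$ssy))
  names(v) <- model$features
  v
}

#' Area under the ROC curve by the rank (Mann-Whitney) identity
#'
#' @param pos,neg Scores of positive and negative samples.
#' @return AUC in `[0, 1]`, with half credit for ties.
#' @export
auc_scores <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# ROC curve coordinates from scores.
roc_coordinates <- function(pos, neg) {
  lab <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  sc <- c(pos, neg)
  ord <- order(sc, decreasing = TRUE)
  lab <- lab[ord]
  tibble::tibble(
    tpr = c(0, cumsum(lab) / sum(lab)),
    fpr = c(0, cumsum(1 - lab) / sum(1 - lab)))
}

# Stratified k-fold assignment guaranteeing every class in every fold
# when class counts allow (round-robin over shuffled members per class).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  offset <- 0L
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# Mean cross-validated macro AUC of a candidate feature set / ncomp.
cv_macro_auc <- function(x, y, ncomp, folds, repeats) {
  aucs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      fit <- suppressWarnings(fit_plsda(x[tr, , drop = FALSE], y[tr],
                                        ncomp = ncomp))
      sc <- predict(fit, x[!tr, , drop = FALSE], type = "score")
      yv <- y[!tr]
      per_class <- vapply(fit$levels, function(lev) {
        auc_scores(sc[yv == lev, lev], sc[yv != lev, lev])
      }, numeric(1))
      aucs <- c(aucs, mean(per_class, na.rm = TRUE))
    }
  }
  mean(aucs)
}

#' Choose the number of PLS-DA components by cross-validated AUC
#'
#' Repeated stratified k-fold cross-validation; for each candidate number
#' of components the mean held-out macro AUC is recorded and the argmax is
#' returned, with ties resolved toward fewer components.
#'
#' @param x Feature matrix.
#' @param y Class factor.
#' @param max_comp Largest candidate. Default 5.
#' @param folds,repeats CV layout. Defaults 4 and 50.
#' @param seed Optional seed.
#' @return List with `best` (chosen number) and `auc` (tibble
#'   `ncomp, cv_auc`).
#' @export
select_components <- function(x, y, max_comp = 5, folds = 4, repeats = 50,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- droplevels(as.factor(y))
  max_comp <- max(1, min(max_comp, ncol(x), nrow(x) - 2))
  res <- tibble::tibble(
    ncomp = seq_len(max_comp),
    cv_auc = vapply(seq_len(max_comp), function(a) {
      cv_macro_auc(as.matrix(x), y, a, folds, repeats)
    }, numeric(1)))
  best <- res$ncomp[which.max(res$cv_auc)]
  # which.max already keeps the first (fewest components) among exact ties
  list(best = best, auc = res)
}

#' Recursive VIP-based feature elimination
#'
#' Starting from the full feature set, repeatedly drops the
#' `floor(0.2 p)` (at least 1) features with the lowest VIP, refits, and
#' records the cross-validated macro AUC. Iteration stops at the first
#' failure to improve or when fewer than `min_features` remain; the
#' feature set of the best recorded iteration is returned together with a
#' model refitted on it.
#'
#' @param x Feature matrix.
#' @param y Class factor.
#' @param ncomp Number of components (fixed across iterations).
#' @param folds,repeats CV layout for the per-iteration AUC. Defaults 4
#'   and 10.
#' @param drop_frac Fraction of features dropped per iteration. Default
#'   0.2.
#' @param min_features Stop below this many features. Default 5.
#' @param seed Optional seed.
#' @return List with `model` (refit on the selected features),
#'   `features`, and `trajectory` (tibble `iteration, n_features,
#'   cv_auc`).
#' @export
recursive_vip_elimination <- function(x, y, ncomp, folds = 4, repeats = 10,
                                      drop_frac = 0.2, min_features = 5,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  current <- colnames(x)
  traj <- list()
  sets <- list()
  it <- 0L
  best_auc <- -Inf
  repeat {
    it <- it + 1L
    xs <- x[, current, drop = FALSE]
    auc <- cv_macro_auc(xs, y, min(ncomp, ncol(xs)), folds, repeats)
    traj[[it]] <- tibble::tibble(iteration = it,
                                 n_features = length(current),
                                 cv_auc = auc)
    sets[[it]] <- current
    improved <- auc > best_auc
    if (improved) best_auc <- auc
    if (!improved || length(current) < min_features) break
    n_drop <- max(1L, floor(drop_frac * length(current)))
    if (length(current) - n_drop < 2) break
    fit <- suppressWarnings(
      fit_plsda(xs, y, ncomp = min(ncomp, ncol(xs))))
    vip <- vip_scores(fit)
    vip_all <- setNames(rep(0, length(current)), current)
    vip_all[names(vip)] <- vip
    drop_feats <- names(sort(vip_all))[seq_len(n_drop)]
    current <- setdiff(current, drop_feats)
  }
  trajectory <- purrr::list_rbind(traj)
  best_it <- which.max(trajectory$cv_auc)
  features <- sets[[best_it]]
  model <- suppressWarnings(
    fit_plsda(x[, features, drop = FALSE], y,
              ncomp = min(ncomp, length(features))))
  list(model = model, features = features, trajectory = trajectory)
}

#' Evaluate a PLS-DA model on held-out data
#'
#' Per-class one-vs-rest AUC and ROC curves from the class scores, overall
#' AUC as their unweighted macro mean, the confusion matrix of argmax
#' labels, per-class incidence, and a one-sided Mann-Whitney (Wilcoxon)
#' p-value testing that scores of class members exceed those of
#' non-members.
#'
#' @param model A `resilink_plsda` model.
#' @param x_test,y_test Held-out features and labels.
#' @return Object of class `plsda_evaluation`: list with `per_class`
#'   (tibble `class, auc, incidence, p_value, n_pos, n_neg`),
#'   `overall_auc`, `confusion` (true x predicted matrix) and `roc`
#'   (long tibble of ROC coordinates).
#' @export
evaluate_plsda <- function(model, x_test, y_test) {
  stopifnot(inherits(model, "resilink_plsda"))
  y_test <- factor(as.character(y_test), levels = model$levels)
  scores <- predict(model, x_test, type = "score")
  pred <- predict(model, x_test, type = "class")
  per_class <- purrr::list_rbind(purrr::map(model$levels, function(lev) {
    pos <- scores[which(y_test == lev), lev]
    neg <- scores[which(y_test != lev), lev]
    if (length(pos) == 0) {
      warn(sprintf("class '%s' absent from the test set", lev))
      return(tibble::tibble(class = lev, auc = NA_real_,
                            incidence = 0, p_value = NA_real_,
                            n_pos = 0L, n_neg = length(neg)))
    }
    pv <- if (length(neg) == 0) NA_real_ else {
      suppressWarnings(
        wilcox.test(pos, neg, alternative = "greater")$p.value)
    }
    tibble::tibble(class = lev, auc = auc_scores(pos, neg),
                   incidence = length(pos) / length(y_test),
                   p_value = pv, n_pos = length(pos),
                   n_neg = length(neg))
  }))
  roc <- purrr::list_rbind(purrr::map(model$levels, function(lev) {
    pos <- scores[which(y_test == lev), lev]
    neg <- scores[which(y_test != lev), lev]
    if (length(pos) == 0 || length(neg) == 0) return(NULL)
    dplyr::mutate(roc_coordinates(pos, neg), class = lev)
  }))
  confusion <- table(true = y_test, predicted = pred)
  structure(
    list(per_class = per_class,
         overall_auc = mean(per_class$auc, na.rm = TRUE),
         confusion = confusion, roc = roc),
    class = "plsda_evaluation")
}

#' @export
print.resilink_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d component(s), %d feature(s), classes: %s\n",
              x$ncomp, length(x$features), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
print.plsda_evaluation <- function(x, ...) {
  cat(sprintf("PLS-DA evaluation (overall AUC %.3f)\n", x$overall_auc))
  print(x$per_class)
  invisible(x)
}
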