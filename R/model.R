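#' Family-grouped k-fold partition
#'
#' Assigns hairpins to cross-validation folds so that every member of a
#' miRNA family lands in the same fold, preventing homology leakage between
#' training and test sets ("non-redundant" cross-validation). Families are
#' packed greedily, largest first, into the currently smallest fold; ties
#' among equal-sized families are broken in a seeded random order, so the
#' partition is deterministic given the seed.
#'
#' @param ids character vector of hairpin ids (one entry per dataset item;
#'   repeated ids allowed).
#' @param families named character vector `hairpin_id -> family` (e.g. from
#'   [read_family_map()]); ids absent from it form singleton families.
#'   `NULL` makes every id its own family.
#' @param k number of folds (default 5); requires at least `k` families.
#' @param seed integer seed.
#' @return Integer vector of fold indices in `1..k`, aligned with `ids`.
#' @export
grouped_kfold <- function(ids, families = NULL, k = 5, seed = 1) {
  stopifnot(k >= 2)
  fam <- if (is.null(families)) stats::setNames(ids, ids) else {
    out <- families[ids]
    missing <- is.na(out)
    out[missing] <- ids[missing]   # singleton families
    out
  }
  sizes <- table(fam)
  if (length(sizes) < k) {
    stop(sprintf("need at least k = %d families, got %d", k, length(sizes)),
         call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(names(sizes)))
  ord <- shuffled[order(-as.integer(sizes[shuffled]))]
  load <- integer(k)
  fold_of_family <- stats::setNames(integer(length(ord)), ord)
  for (f in ord) {
    dest <- which.min(load)           # ties -> lowest index
    fold_of_family[f] <- dest
    load[dest] <- load[dest] + sizes[[f]]
  }
  unname(fold_of_family[fam])
}

#' The RBF hyperparameter grid of the method
#'
#' Kernel width `g` in {0.001, 0.01, 0.1}, error cost `c` in 1..10, and
#' positive-class cost factor `j` in 1..10 (realised as a class-weight
#' multiplier on the positive class), 300 configurations in all.
#'
#' @param g,cost,j candidate values for each hyperparameter.
#' @return Data frame with columns `g`, `c`, `j`, one row per configuration.
#' @export
dicer_grid <- function(g = c(0.001, 0.01, 0.1), cost = 1:10, j = 1:10) {
  grid <- expand.grid(g = g, c = cost, j = j, KEEP.OUT.ATTRS = FALSE)
  grid[order(grid$g, grid$c, grid$j), , drop = FALSE]
}

rbf_kernel <- function(gamma, a, b) {
  # K[i, j] = exp(-gamma * ||a_i - b_j||^2)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Raw decision scores of an e1071-style RBF machine (SVs, coefs, rho),
# before sign orientation. Matches libsvm's decision function.
raw_svm_scores <- function(sv, coefs, rho, gamma, x) {
  drop(crossprod(rbf_kernel(gamma, sv, x), coefs)) - rho
}

fit_rbf_svm <- function(x, y01, g, c, j) {
  # y01: factor with levels c("pos", "neg")
  e1071::svm(x = x, y = y01, type = "C-classification", kernel = "radial",
             gamma = g, cost = c, scale = FALSE,
             class.weights = c(pos = j, neg = 1))
}

# Oriented scores (> 0 = positive-like): flip raw scores if positives
# score lower than negatives on the training data.
svm_component <- function(fit, x, y01, g) {
  sv <- fit$SV
  coefs <- as.numeric(fit$coefs)
  rho <- as.numeric(fit$rho)
  raw_train <- raw_svm_scores(sv, coefs, rho, g, x)
  flip <- if (mean(raw_train[y01 == "pos"]) >= mean(raw_train[y01 == "neg"])) 1 else -1
  list(sv = sv, coefs = coefs, rho = rho, gamma = g, flip = flip)
}

score_component <- function(comp, x) {
  comp$flip * raw_svm_scores(comp$sv, comp$coefs, comp$rho, comp$gamma, x)
}

cv_scores_for_config <- function(x, y01, folds, g, c, j) {
  scores <- rep(NA_real_, nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2L) {
      stop("a training fold contains a single class; use more families or fewer folds",
           call. = FALSE)
    }
    fit <- fit_rbf_svm(x[tr, , drop = FALSE], y01[tr], g, c, j)
    comp <- svm_component(fit, x[tr, , drop = FALSE], y01[tr], g)
    scores[!tr] <- score_component(comp, x[!tr, , drop = FALSE])
  }
  scores
}

#' Fit the Dicer cleavage-site classifier
#'
#' Trains an RBF-kernel support vector machine on encoded pattern windows,
#' tuning `(g, c, j)` over a grid by family-grouped k-fold cross-validation.
#' For every configuration the CV decision scores are pooled over folds and
#' thresholded to a confusion matrix; the configuration with the highest CV
#' accuracy is selected (ties: higher MCC, then smaller `c`, then smaller
#' `j`, then smaller `g`) and refit on the full data. `j` multiplies the
#' error cost of the positive class, as in classic SVM tools.
#'
#' @param x numeric feature matrix (rows = windows), e.g. from
#'   [encode_windows()].
#' @param y labels, one per row; values compared against `positive`.
#' @param ids hairpin id per row (defaults to rownames of `x`); used for
#'   family grouping.
#' @param families named vector `hairpin_id -> family`, or `NULL` for
#'   singleton families.
#' @param grid data frame of configurations from [dicer_grid()].
#' @param k number of CV folds.
#' @param seed integer seed (fold assignment).
#' @param threshold decision-score cutoff; scores above it are called
#'   cleavage. Default 0; raise it to trade sensitivity for specificity.
#' @param positive the positive label value (default `"cleavage"`).
#' @param scheme,width optional tags recording how `x` was encoded; checked
#'   by [scan_hairpin()].
#' @param use_structure_rows tag for composition schemes (see
#'   [encode_window()]).
#' @return Object of class `"dicer_svm"` with elements `config` (best g, c,
#'   j), `cv_table` (per-configuration Sn/Sp/Ac/MCC), `cv_metrics`,
#'   `cv_scores`/`cv_labels` (pooled CV scores of the selected
#'   configuration), `auc`, the fitted machine (`sv`, `coefs`, `rho`,
#'   `gamma`, `flip`), and `provenance`.
#' @seealso [predict.dicer_svm()], [scan_hairpin()], [write_dicer_model()]
#' @export
dicer_svm <- function(x, y, ids = rownames(x), families = NULL,
                      grid = dicer_grid(), k = 5, seed = 1, threshold = 0,
                      positive = "cleavage", scheme = NULL, width = NULL,
                      use_structure_rows = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix contains NA/NaN/Inf values", call. = FALSE)
  }
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  stopifnot(length(ids) == nrow(x))
  y01 <- factor(ifelse(y == positive, "pos", "neg"), levels = c("pos", "neg"))
  if (length(unique(y01)) < 2L) {
    stop("both classes must be present in y", call. = FALSE)
  }
  stopifnot(all(c("g", "c", "j") %in% names(grid)), nrow(grid) >= 1L)

  folds <- grouped_kfold(ids, families, k = k, seed = seed)
  cv_table <- grid
  cv_table$sn <- cv_table$sp <- cv_table$ac <- cv_table$mcc <- NA_real_
  for (r in seq_len(nrow(grid))) {
    sc <- cv_scores_for_config(x, y01, folds, grid$g[r], grid$c[r], grid$j[r])
    pred <- ifelse(sc > threshold, "pos", "neg")
    m <- compute_metrics(confusion_counts(y01, pred, positive = "pos"))
    cv_table$sn[r] <- m$sn; cv_table$sp[r] <- m$sp
    cv_table$ac[r] <- m$ac; cv_table$mcc[r] <- m$mcc
  }
  ord <- order(-cv_table$ac, -ifelse(is.na(cv_table$mcc), -Inf, cv_table$mcc),
               cv_table$c, cv_table$j, cv_table$g)
  best <- ord[1]
  config <- list(g = grid$g[best], c = grid$c[best], j = grid$j[best],
                 threshold = threshold)

  cv_scores <- cv_scores_for_config(x, y01, folds, config$g, config$c, config$j)
  cv_pred <- ifelse(cv_scores > threshold, "pos", "neg")
  cv_metrics <- compute_metrics(confusion_counts(y01, cv_pred, positive = "pos"))
  auc <- roc_auc(cv_scores, y01, positive = "pos")

  fit <- fit_rbf_svm(x, y01, config$g, config$c, config$j)
  comp <- svm_component(fit, x, y01, config$g)

  obj <- structure(list(
    config = config,
    scheme = scheme, width = width, use_structure_rows = use_structure_rows,
    positive = positive, threshold = threshold,
    sv = comp$sv, coefs = comp$coefs, rho = comp$rho, gamma = comp$gamma,
    flip = comp$flip, n_sv = nrow(comp$sv),
    cv_table = cv_table[order(-cv_table$ac), , drop = FALSE],
    cv_metrics = cv_metrics, auc = auc,
    cv_scores = cv_scores, cv_labels = as.character(y01),
    folds = folds,
    provenance = list(seed = seed, k = k, n = nrow(x), d = ncol(x),
                      n_pos = sum(y01 == "pos"), n_neg = sum(y01 == "neg"),
                      x_checksum = signif(sum(x) + sum(x^2), 12),
                      version = as.character(utils::packageVersion("dicerscan")))
  ), class = "dicer_svm")
  obj
}

#' Predict decision scores or labels for encoded windows
#'
#' @param object a [dicer_svm()] fit (or a model loaded with
#'   [read_dicer_model()]).
#' @param newdata feature matrix encoded under the model's scheme, or a
#'   list of `pattern_window`s (encoded automatically when the model carries
#'   a `scheme` tag).
#' @param type `"score"` for decision scores (higher = more cleavage-like)
#'   or `"label"` for thresholded labels.
#' @param threshold cutoff for `type = "label"`; defaults to the model's.
#' @param ... unused.
#' @return Numeric scores or character labels.
#' @export
predict.dicer_svm <- function(object, newdata, type = c("score", "label"),
                              threshold = object$threshold, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, TRUE, "pattern_window"))) {
    if (is.null(object$scheme)) {
      stop("model has no scheme tag; encode the windows explicitly", call. = FALSE)
    }
    newdata <- encode_windows(newdata, object$scheme,
                              use_structure_rows = object$use_structure_rows)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$sv)) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 ncol(object$sv), ncol(newdata)), call. = FALSE)
  }
  scores <- score_component(object, newdata)
  if (type == "score") scores
  else ifelse(scores > threshold, object$positive, paste0("non", object$positive))
}

#' @export
print.dicer_svm <- function(x, ...) {
  cat("Dicer cleavage-site SVM (RBF kernel)\n")
  cat(sprintf("  scheme: %s%s  width: %s\n",
              if (is.null(x$scheme)) "?" else x$scheme,
              if (isTRUE(x$use_structure_rows)) " (+structure rows)" else "",
              if (is.null(x$width)) "?" else x$width))
  cat(sprintf("  config: g = %g, c = %g, j = %g  (threshold %g, %d SVs)\n",
              x$config$g, x$config$c, x$config$j, x$threshold, x$n_sv))
  cat(sprintf("  grouped %d-fold CV: Sn %.2f%%  Sp %.2f%%  Ac %.2f%%  MCC %.3f  AUC %.3f\n",
              x$provenance$k, x$cv_metrics$sn, x$cv_metrics$sp,
              x$cv_metrics$ac, x$cv_metrics$mcc, x$auc))
  invisible(x)
}

#' @export
summary.dicer_svm <- function(object, n_configs = 5, ...) {
  print(object)
  cat(sprintf("  data: %d windows (%d cleavage / %d non), %d features, seed %s\n",
              object$provenance$n, object$provenance$n_pos,
              object$provenance$n_neg, object$provenance$d,
              object$provenance$seed))
  cat(sprintf("  grid: %d configurations; top %d by CV accuracy:\n",
              nrow(object$cv_table), min(n_configs, nrow(object$cv_table))))
  top <- utils::head(object$cv_table, n_configs)
  print(`rownames<-`(round(as.data.frame(top), 3), NULL))
  invisible(object)
}

#' Plot the cross-validated ROC curve of a fitted model
#'
#' Empirical ROC from the pooled CV decision scores of the selected
#' configuration, with the AUC in the legend.
#'
#' @param x a [dicer_svm()] fit.
#' @param ... passed to [plot()].
#' @export
plot.dicer_svm <- function(x, ...) {
  ord <- order(x$cv_scores, decreasing = TRUE)
  lab <- x$cv_labels[ord] == "pos"
  tpr <- c(0, cumsum(lab) / sum(lab))
  fpr <- c(0, cumsum(!lab) / sum(!lab))
  plot(fpr, tpr, type = "l", xlab = "1 - specificity (FPR)",
       ylab = "sensitivity (TPR)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Persist a fitted model as a versioned plain-text archive
#'
#' JSON holding the configuration, support vectors, dual coefficients,
#' scheme tag and provenance; [read_dicer_model()] restores a `"dicer_svm"`
#' object whose predictions are identical to the original's.
#'
#' @param model a [dicer_svm()] fit.
#' @param path output file (JSON).
#' @export
write_dicer_model <- function(model, path) {
  stopifnot(inherits(model, "dicer_svm"))
  payload <- list(
    format = "dicerscan-model", format_version = 1L,
    scheme = model$scheme, width = model$width,
    use_structure_rows = model$use_structure_rows,
    positive = model$positive, threshold = model$threshold,
    config = model$config,
    gamma = model$gamma, flip = model$flip, rho = model$rho,
    coefs = model$coefs, sv = model$sv,
    cv_metrics = model$cv_metrics[c("sn", "sp", "ac", "mcc")],
    auc = model$auc,
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dicer_model
#' @export
read_dicer_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dicerscan-model")) {
    stop("not a dicerscan model archive: ", path, call. = FALSE)
  }
  structure(list(
    config = as.list(p$config),
    scheme = p$scheme, width = p$width,
    use_structure_rows = isTRUE(p$use_structure_rows),
    positive = p$positive, threshold = p$threshold,
    sv = as.matrix(p$sv), coefs = as.numeric(p$coefs),
    rho = as.numeric(p$rho), gamma = as.numeric(p$gamma),
    flip = as.numeric(p$flip), n_sv = nrow(as.matrix(p$sv)),
    cv_table = NULL, cv_metrics = as.list(p$cv_metrics), auc = p$auc,
    cv_scores = NULL, cv_labels = NULL, folds = NULL,
    provenance = as.list(p$provenance)
  ), class = "dicer_svm")
}
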