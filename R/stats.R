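# Group statistics and binary wooden-breast classification.
#
# Group comparisons use one-way ANOVA with Tukey HSD post hoc letters and
# Spearman rank correlation against the ordinal severity score (0/1/2).
# Classification is binary (normal vs wooden breast = moderate + severe) on
# a single 1-D feature, evaluated by repeated stratified k-fold
# cross-validation with four metrics: overall accuracy, balanced accuracy,
# F1 and the Matthews correlation coefficient.

.severity_levels <- c("normal", "moderate", "severe")

# Ordinal severity score 0/1/2 from a label vector (accepts names or 0/1/2).
severity_score <- function(label) {
  if (is.numeric(label)) {
    if (!all(label %in% 0:2)) stop_invalid("numeric labels must be 0, 1 or 2")
    return(as.integer(label))
  }
  m <- match(as.character(label), .severity_levels)
  if (anyNA(m)) stop_invalid("labels must be normal/moderate/severe or 0/1/2")
  m - 1L
}

# Compact letter display from a matrix of pairwise p-values, insert-absorb
# algorithm. Groups ordered by decreasing mean get earlier letters
# (a = highest mean).
.tukey_letters <- function(pmat, means, alpha = 0.05) {
  groups <- names(means)
  sets <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i >= j) next
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      gi <- groups[i]; gj <- groups[j]
      for (k in rev(seq_along(sets))) {
        if (gi %in% sets[[k]] && gj %in% sets[[k]]) {
          sets <- c(sets[-k], list(setdiff(sets[[k]], gi)),
                    list(setdiff(sets[[k]], gj)))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(sets))
      for (k in seq_along(sets)) {
        for (l in seq_along(sets)) {
          if (k != l && keep[l] &&
              all(sets[[k]] %in% sets[[l]]) &&
              length(sets[[k]]) < length(sets[[l]])) {
            keep[k] <- FALSE
          }
        }
      }
      sets <- unique(sets[keep])
    }
  }
  sets <- sets[order(-vapply(sets, function(s) max(means[s]), numeric(1)))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Group statistics of a feature table
#'
#' For every feature column: group means and SDs per severity class, one-way
#' ANOVA F and p, Tukey HSD pairwise tests rendered as compact letters
#' (alpha = 0.05, `a` marks the highest-mean group), and the Spearman rank
#' correlation of the feature with the ordinal severity score 0/1/2.
#'
#' @param table a feature table data frame with a `label` column; every
#'   other numeric column is analyzed.
#' @param alpha significance level for the letter display.
#' @return an object of class `group_stats`: `summary` (data frame with
#'   feature, F, p, rho, rho_p), `means`, `sds`, `letters` (feature x group).
#' @export
group_statistics <- function(table, alpha = 0.05) {
  if (!is.data.frame(table) || !"label" %in% names(table)) {
    stop_invalid("`table` must be a data frame with a `label` column")
  }
  grp <- factor(.severity_levels[severity_score(table$label) + 1L],
                levels = .severity_levels)
  grp <- droplevels(grp)
  if (nlevels(grp) < 2L) stop_invalid("need at least 2 groups")
  if (any(table(grp) < 2L)) stop_invalid("need >= 2 samples per group")
  score <- severity_score(table$label)
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  feats <- setdiff(feats, c("label"))
  if (!length(feats)) stop_invalid("no numeric feature columns")
  means <- sds <- matrix(NA_real_, length(feats), nlevels(grp),
                         dimnames = list(feats, levels(grp)))
  lets <- matrix("", length(feats), nlevels(grp),
                 dimnames = list(feats, levels(grp)))
  summ <- data.frame(feature = feats, F = NA_real_, p = NA_real_,
                     rho = NA_real_, rho_p = NA_real_)
  for (i in seq_along(feats)) {
    v <- table[[feats[i]]]
    means[i, ] <- tapply(v, grp, mean)
    sds[i, ] <- tapply(v, grp, stats::sd)
    fit <- stats::aov(v ~ grp)
    an <- summary(fit)[[1]]
    summ$F[i] <- an[["F value"]][1]
    summ$p[i] <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$grp
    pmat <- matrix(NA_real_, nlevels(grp), nlevels(grp),
                   dimnames = list(levels(grp), levels(grp)))
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1]]
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[r, "p adj"]
    }
    gm <- means[i, ]
    lt <- .tukey_letters(pmat[levels(grp), levels(grp)],
                         stats::setNames(gm, levels(grp)), alpha)
    lets[i, ] <- lt[levels(grp)]
    ct <- suppressWarnings(stats::cor.test(v, score, method = "spearman",
                                           exact = FALSE))
    summ$rho[i] <- unname(ct$estimate)
    summ$rho_p[i] <- ct$p.value
  }
  structure(list(summary = summ, means = means, sds = sds, letters = lets,
                 alpha = alpha),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, digits = 3, ...) {
  cat("Group statistics (ANOVA + Tukey letters, Spearman vs severity)\n")
  df <- x$summary
  for (g in colnames(x$means)) {
    df[[g]] <- sprintf("%.3g +/- %.2g %s", x$means[, g], x$sds[, g],
                       x$letters[, g])
  }
  print(df, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Classification metrics for binary predictions
#'
#' Overall accuracy, balanced accuracy, F1 and Matthews correlation
#' coefficient from true/predicted binary labels, with the wooden-breast
#' class as positive. `MCC` (and `F1`) are defined as 0 when their
#' denominator vanishes.
#'
#' @param y_true,y_pred vectors of equal length with two classes.
#' @param positive the positive-class label (default `"wbc"`).
#' @return named numeric vector `c(OACC, BACC, F1, MCC)`.
#' @export
binary_metrics <- function(y_true, y_pred, positive = "wbc") {
  if (length(y_true) != length(y_pred)) {
    stop_invalid("`y_true` and `y_pred` must have equal length")
  }
  yt <- as.character(y_true) == positive
  yp <- as.character(y_pred) == positive
  tp <- sum(yt & yp); tn <- sum(!yt & !yp)
  fp <- sum(!yt & yp); fn <- sum(yt & !yp)
  n <- length(yt)
  oacc <- (tp + tn) / n
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  bacc <- (tpr + tnr) / 2
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  c(OACC = oacc, BACC = bacc, F1 = f1, MCC = mcc)
}

#' Fit a 1-D binary classifier and predict
#'
#' The five evaluated decision rules on a single feature: linear and
#' quadratic discriminant analysis (Gaussian class-conditionals with pooled
#' / per-class variance), a depth-limited decision tree, a radial-kernel
#' support vector machine (C = 1, feature standardized) and k-nearest
#' neighbors (k = 5). Hyperparameters are overridable through `params`.
#'
#' @param model_name one of `"LDA"`, `"QDA"`, `"DT"`, `"SVM"`, `"KNN"`.
#' @param train_x,train_y numeric training feature and binary labels.
#' @param test_x numeric test feature values.
#' @param params named list of hyperparameter overrides: `cost` and `gamma`
#'   (SVM), `k` (KNN), `maxdepth`, `minsplit` and `cp` (DT).
#' @return factor of predicted labels with the training levels.
#' @export
fit_predict_1d <- function(model_name, train_x, train_y, test_x,
                           params = list()) {
  if (!is.character(model_name) || length(model_name) != 1L ||
      !model_name %in% c("LDA", "QDA", "DT", "SVM", "KNN")) {
    stop_invalid("`model_name` must be one of LDA, QDA, DT, SVM, KNN")
  }
  y <- factor(train_y)
  if (nlevels(y) < 2L) stop_degen_fit("training set contains a single class")
  if (length(train_x) != length(y)) {
    stop_invalid("`train_x` and `train_y` must have equal length")
  }
  xm <- matrix(as.numeric(train_x), ncol = 1, dimnames = list(NULL, "x"))
  tm <- matrix(as.numeric(test_x), ncol = 1, dimnames = list(NULL, "x"))
  pred <- switch(model_name,
    LDA = {
      fit <- MASS::lda(xm, grouping = y)
      stats::predict(fit, tm)$class
    },
    QDA = {
      fit <- tryCatch(MASS::qda(xm, grouping = y),
                      error = function(e) stop_degen_fit(conditionMessage(e)))
      stats::predict(fit, tm)$class
    },
    DT = {
      ctl <- rpart::rpart.control(
        maxdepth = params$maxdepth %||% 3,
        minsplit = params$minsplit %||% 5,
        cp = params$cp %||% 0.01)
      df <- data.frame(y = y, x = as.numeric(train_x))
      fit <- rpart::rpart(y ~ x, data = df, method = "class", control = ctl)
      stats::predict(fit, data.frame(x = as.numeric(test_x)), type = "class")
    },
    SVM = {
      fit <- e1071::svm(xm, y, kernel = "radial",
                        cost = params$cost %||% 1,
                        gamma = params$gamma %||% 1,
                        scale = TRUE)
      stats::predict(fit, tm)
    },
    KNN = {
      k <- min(params$k %||% 5, length(train_x))
      class::knn(xm, tm, cl = y, k = k)
    })
  factor(as.character(pred), levels = levels(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into `folds` folds.
.stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation of a 1-D classifier
#'
#' Runs `repeats` independent stratified `folds`-fold splits. Within each
#' repeat, test-fold predictions are pooled and scored once; the four
#' metrics are then averaged over repeats (set `average = "fold"` to score
#' each fold separately and average over all folds instead).
#'
#' @param x numeric 1-D feature.
#' @param y binary labels.
#' @param model_name classifier name, see [fit_predict_1d()].
#' @param repeats,folds number of repeats and folds.
#' @param seed integer seed making the fold draws reproducible.
#' @param average `"repeat"` (default) or `"fold"`.
#' @param positive positive-class label for [binary_metrics()].
#' @param params hyperparameter overrides for [fit_predict_1d()].
#' @return named numeric `c(OACC, BACC, F1, MCC)` with attribute
#'   `"per_repeat"` carrying the repeat-level (or fold-level) metric matrix.
#' @export
repeated_cv <- function(x, y, model_name, repeats = 10, folds = 5, seed = 1,
                        average = c("repeat", "fold"), positive = "wbc",
                        params = list()) {
  average <- match.arg(average)
  y <- factor(y)
  if (nlevels(y) != 2L) stop_invalid("`y` must contain exactly two classes")
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length")
  if (length(x) < folds) stop_invalid("need at least `folds` samples")
  if (min(table(y)) < 2L) stop_degen_fit("each class needs >= 2 samples")
  per <- NULL
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- .stratified_folds(y, folds)
      # re-stratify (never silently proceed) if a training split lost a class
      tries <- 0L
      while (any(vapply(seq_len(folds), function(k)
        nlevels(droplevels(y[fold_of != k])) < 2L, logical(1)))) {
        fold_of <- .stratified_folds(y, folds)
        tries <- tries + 1L
        if (tries > 100L) stop_degen_fit("cannot stratify: class too small")
      }
      if (average == "repeat") {
        pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
        for (k in seq_len(folds)) {
          te <- fold_of == k
          if (!any(te)) next
          pred[te] <- fit_predict_1d(model_name, x[!te], y[!te], x[te], params)
        }
        per <- rbind(per, binary_metrics(y, pred, positive))
      } else {
        for (k in seq_len(folds)) {
          te <- fold_of == k
          if (!any(te)) next
          pr <- fit_predict_1d(model_name, x[!te], y[!te], x[te], params)
          per <- rbind(per, binary_metrics(y[te], pr, positive))
        }
      }
    }
  })
  out <- colMeans(per)
  attr(out, "per_repeat") <- per
  out
}
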