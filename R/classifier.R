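# Mutual information between two discrete vectors (natural log).
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

# Equal-frequency discretisation into at most `bins` levels.
discretize_ef <- function(x, bins = 8) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR: features are discretised into equal-frequency bins, the
#' first pick maximises mutual information with the label, and each later
#' pick maximises `MI(f; y) - mean(MI(f; already selected))`. Deterministic
#' given the discretisation; ties break towards the lower column index.
#'
#' @param X Numeric matrix or data frame of features (columns).
#' @param y Binary labels (0/1), one per row.
#' @param n_keep Number of features to rank.
#' @param bins Discretisation bins (default 8).
#' @return Integer vector of column indices in selection order.
#' @export
mrmr_select <- function(X, y, n_keep, bins = 8) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) abort("mRMR needs both classes present.")
  if (n_keep > ncol(X)) abort("n_keep exceeds the number of features.")
  D <- apply(X, 2, discretize_ef, bins = bins)
  rel <- apply(D, 2, discrete_mi, b = y)
  selected <- integer(0)
  candidates <- seq_len(ncol(X))
  red <- matrix(NA_real_, ncol(X), ncol(X))
  for (step in seq_len(n_keep)) {
    score <- if (step == 1) {
      rel[candidates]
    } else {
      vapply(candidates, function(j) {
        for (s in selected) {
          if (is.na(red[j, s])) {
            red[j, s] <<- discrete_mi(D[, j], D[, s])
          }
        }
        rel[j] - mean(red[j, selected])
      }, numeric(1))
    }
    pick <- candidates[which.max(score)]
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
  }
  selected
}

#' Train the ocular-artifact segment classifier
#'
#' Extracts the full feature set from labelled segments, z-scores each
#' feature with the training mean/sd, ranks features by mRMR, and fits an
#' RBF-kernel support vector machine on the selected subset. Label 1 marks
#' ocular-contaminated segments (the positive class, to be denoised) and 0
#' clean segments (left untouched).
#'
#' @param corpus Tibble with a `samples` list-column and a `label` column
#'   (0/1), e.g. from [gen_corpus()], plus `fs` (column or argument).
#' @param n_keep Features kept by mRMR (default 10).
#' @param fs Sampling rate if the corpus carries none.
#' @param cost SVM cost parameter (default 1).
#' @param features Optional precomputed feature tibble (one row per
#'   segment), bypassing extraction.
#' @return Object of class `artifact_classifier`.
#' @export
train_classifier <- function(corpus, n_keep = 10, fs = NULL, cost = 1,
                             features = NULL) {
  y <- corpus$label
  if (length(unique(y)) < 2) abort("Training needs both classes present.")
  if (min(table(y)) < 10) abort("Need at least 10 segments per class.")
  if (is.null(fs)) fs <- if ("fs" %in% names(corpus)) corpus$fs[1] else 200
  feats <- if (is.null(features)) extract_features(corpus, fs = fs) else features
  X <- as.matrix(feats)
  if (n_keep > ncol(X)) abort("n_keep exceeds the number of features.")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  sel <- mrmr_select(Xs, y, n_keep)
  fit <- e1071::svm(Xs[, sel, drop = FALSE], factor(y, levels = c(0, 1)),
                    kernel = "radial", cost = cost, scale = FALSE)
  # keep only what the RBF decision function needs, so the model survives
  # a plain-text round trip
  structure(list(SV = unname(as.matrix(fit$SV)),
                 coefs = as.vector(fit$coefs), rho = fit$rho,
                 gamma = fit$gamma,
                 positive_level = levels(fit$fitted)[fit$labels[1]],
                 levels = levels(fit$fitted),
                 selected = sel,
                 feature_names = colnames(X), mu = mu, sd = sdev,
                 fs = fs, n_keep = n_keep),
            class = "artifact_classifier")
}

# RBF-SVM decision values: sum_i coefs_i exp(-gamma ||sv_i - x||^2) - rho.
# Positive decision values map to `positive_level`.
svm_decision <- function(clf, X) {
  d2 <- outer(rowSums(clf$SV^2), rowSums(X^2), "+") -
    2 * clf$SV %*% t(X)
  as.vector(crossprod(exp(-clf$gamma * d2), clf$coefs)) - clf$rho
}

#' @export
print.artifact_classifier <- function(x, ...) {
  cat(sprintf("<artifact_classifier> RBF SVM (%d support vectors) on %d mRMR-selected of %d features\n",
              nrow(x$SV), length(x$selected), length(x$feature_names)))
  cat("  selected:", paste(x$feature_names[x$selected], collapse = ", "), "\n")
  invisible(x)
}

#' Label segments as clean (0) or ocular-contaminated (1)
#'
#' @param clf An [train_classifier()] model.
#' @param segments Tibble with a `samples` list-column (and optional `fs`),
#'   or a bare list of numeric vectors.
#' @param fs Sampling rate if `segments` carries none; defaults to the
#'   training rate.
#' @return The input tibble with a `label` column of 0/1 predictions (a
#'   new tibble is built for list input). Empty input gives zero rows.
#' @export
classify_segments <- function(clf, segments, fs = NULL) {
  if (!inherits(clf, "artifact_classifier")) {
    abort("classify_segments() needs a trained artifact_classifier.")
  }
  if (is.data.frame(segments)) {
    tbl <- segments
  } else {
    tbl <- tibble(samples = segments)
  }
  if (nrow(tbl) == 0) {
    tbl$label <- integer(0)
    return(tbl)
  }
  if (is.null(fs)) fs <- if ("fs" %in% names(tbl)) tbl$fs[1] else clf$fs
  feats <- extract_features(tbl, fs = fs)
  X <- as.matrix(feats)[, clf$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, clf$mu), 2, clf$sd, "/")
  dv <- svm_decision(clf, Xs[, clf$selected, drop = FALSE])
  lab <- ifelse(dv > 0, clf$positive_level,
                setdiff(clf$levels, clf$positive_level))
  tbl$label <- as.integer(lab)
  tbl
}

#' Save / load a trained classifier as JSON
#'
#' The SVM state (support vectors, coefficients, kernel parameters) and
#' the standardisation/selection metadata are stored in a single
#' schema-versioned JSON file, so a trained model survives a plain-text
#' round trip.
#'
#' @param clf An `artifact_classifier`.
#' @param path Destination file.
#' @return `path` invisibly (`save_classifier`); the restored
#'   `artifact_classifier` (`load_classifier`).
#' @export
save_classifier <- function(clf, path) {
  obj <- list(
    schema = 1L,
    feature_names = clf$feature_names,
    selected = clf$selected,
    mu = unname(clf$mu), sd = unname(clf$sd),
    fs = clf$fs, n_keep = clf$n_keep,
    svm = list(SV = as.vector(clf$SV), sv_dim = dim(clf$SV),
               coefs = clf$coefs, rho = clf$rho, gamma = clf$gamma,
               positive_level = clf$positive_level, levels = clf$levels)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != 1) {
    abort("Unrecognised classifier file schema.")
  }
  structure(list(SV = matrix(obj$svm$SV, obj$svm$sv_dim[1], obj$svm$sv_dim[2]),
                 coefs = obj$svm$coefs, rho = obj$svm$rho,
                 gamma = obj$svm$gamma,
                 positive_level = obj$svm$positive_level,
                 levels = obj$svm$levels,
                 selected = obj$selected,
                 feature_names = obj$feature_names,
                 mu = stats::setNames(obj$mu, obj$feature_names),
                 sd = stats::setNames(obj$sd, obj$feature_names),
                 fs = obj$fs, n_keep = obj$n_keep),
            class = "artifact_classifier")
}
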