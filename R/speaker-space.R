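#' Remove collinear acoustic features by Pearson correlation
#'
#' Greedy collinearity filter: while any retained pair of features has
#' \code{|r| >= r_max}, the pair with the largest \code{|r|} is located and
#' the member with the larger mean absolute correlation to all other
#' retained features is dropped (ties drop the feature later in the
#' canonical table order). This reproduces the usual exclusion of derived
#' features (range/max-type measures) before discriminant analysis.
#'
#' @param tbl Feature table: data frame with one row per sentence containing
#'   the columns of \code{\link{feature_names}} (additional columns are
#'   ignored).
#' @param r_max Absolute Pearson correlation threshold in (0, 1].
#' @param features Candidate feature columns (default: all canonical
#'   features present in \code{tbl}).
#' @return Character vector of retained feature names, in canonical order,
#'   with attribute \code{"dropped"}.
#' @export
collinearity_filter <- function(tbl, r_max = 0.8,
                                features = intersect(feature_names(), names(tbl))) {
  if (!is.numeric(r_max) || length(r_max) != 1 || r_max <= 0 || r_max > 1) {
    stop("r_max must lie in (0, 1]", call. = FALSE)
  }
  x <- tbl[, features, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete-case rows", call. = FALSE)
  keep <- features[vapply(x, function(col) stats::sd(col) > 0, logical(1))]
  dropped <- setdiff(features, keep)
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < r_max) break
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    mean_abs <- rowMeans(r)[idx]
    drop <- if (abs(diff(mean_abs)) > 1e-12) {
      pair[which.max(mean_abs)]
    } else {
      # tie: drop the feature later in canonical order
      pair[which.max(match(pair, features))]
    }
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  out <- keep[order(match(keep, features))]
  attr(out, "dropped") <- dropped
  out
}

#' Linear discriminant analysis of speaker identity
#'
#' Canonical discriminant analysis with speakers as groups: solves the
#' generalized eigenproblem of between-group versus pooled within-group
#' covariance. Discriminant vectors are scaled to unit pooled within-group
#' variance (\code{a' W a = 1}) and ordered by decreasing between/within
#' variance ratio. Loadings are standardized coefficients — each coefficient
#' multiplied by the within-group SD of its feature — the scale on which a
#' \code{|loading| > 1.3} marker-selection rule operates.
#'
#' @param tbl Feature table with a \code{speaker_id} column and one row per
#'   sentence. Rows with missing values on \code{features} are dropped
#'   (listwise) with a message.
#' @param features Feature columns to use.
#' @param ridge Ridge added to the within-group covariance (as a fraction of
#'   its mean diagonal) only if it is singular; escalated with a message.
#' @return Object of class \code{"speaker_lda"}: list with
#'   \code{features}, \code{group_means}, \code{within_cov},
#'   \code{discriminants} (columns = functions), \code{eigenvalues},
#'   \code{loadings} (features x functions), \code{selection_threshold},
#'   \code{selected_markers}, and the training projections.
#' @export
fit_lda <- function(tbl, features, ridge = 1e-8) {
  stopifnot("speaker_id" %in% names(tbl), length(features) >= 1)
  cols <- c("speaker_id", features)
  cc <- stats::complete.cases(tbl[, features, drop = FALSE])
  if (!all(cc)) {
    message(sprintf("dropping %d incomplete rows (listwise deletion)", sum(!cc)))
  }
  d <- tbl[cc, cols, drop = FALSE]
  g <- factor(d$speaker_id)
  if (nlevels(g) < 2) stop("need at least 2 speakers", call. = FALSE)
  if (any(table(g) < 2)) stop("need >= 2 sentences per speaker", call. = FALSE)
  X <- as.matrix(d[, features, drop = FALSE])
  storage.mode(X) <- "double"
  N <- nrow(X)
  G <- nlevels(g)
  p <- length(features)

  means <- apply(X, 2, function(col) tapply(col, g, mean))
  means <- matrix(means, nrow = G, dimnames = list(levels(g), features))
  Xc <- X - means[as.integer(g), , drop = FALSE]
  W <- crossprod(Xc) / (N - G)
  n_g <- as.numeric(table(g))
  mbar <- colSums(means * n_g) / N
  Mc <- sweep(means, 2, mbar) * sqrt(n_g)
  B <- crossprod(Mc) / (G - 1)

  L <- tryCatch(chol(W), error = function(e) NULL)
  lam <- ridge
  while (is.null(L)) {
    if (lam > 1) stop("within-group covariance singular even after ridge", call. = FALSE)
    message(sprintf("within-group covariance singular; ridge = %g applied", lam))
    L <- tryCatch(chol(W + diag(lam * mean(diag(W)), p)), error = function(e) NULL)
    if (is.null(L)) lam <- lam * 100
  }
  # whiten: M = L'^-1 B L^-1 is symmetric with the same eigenvalues as W^-1 B
  Linv <- backsolve(L, diag(p))
  M <- t(Linv) %*% B %*% Linv
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  nf <- min(G - 1, p)
  A <- Linv %*% eg$vectors[, seq_len(nf), drop = FALSE]  # a' W a = 1
  # sign convention: largest-|coefficient| entry positive
  for (k in seq_len(nf)) {
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) A[, k] <- -A[, k]
  }
  dimnames(A) <- list(features, paste0("LD", seq_len(nf)))
  loadings <- A * sqrt(diag(W))

  scores <- X %*% A
  mean_scores <- means %*% A
  out <- list(
    features = features,
    group_means = means,
    within_cov = W,
    between_cov = B,
    discriminants = A,
    eigenvalues = eg$values[seq_len(nf)],
    loadings = loadings,
    selection_threshold = 1.3,
    n_obs = N,
    groups = levels(g),
    scores = scores,
    mean_scores = mean_scores,
    labels = as.character(d$speaker_id)
  )
  out$selected_markers <- select_markers(out, quiet = TRUE)
  class(out) <- "speaker_lda"
  out
}

#' @export
print.speaker_lda <- function(x, ...) {
  cat(sprintf(
    "<speaker_lda: %d speakers, %d features, %d discriminant functions>\n",
    length(x$groups), length(x$features), ncol(x$discriminants)
  ))
  cat("selected markers (|loading| >", x$selection_threshold, "):",
      if (length(x$selected_markers)) paste(x$selected_markers, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Project feature rows into discriminant space
#'
#' @param m A \code{\link{fit_lda}} model.
#' @param tbl Data frame containing the model's feature columns.
#' @return Matrix of discriminant scores (rows x functions).
#' @export
lda_project <- function(m, tbl) {
  X <- as.matrix(tbl[, m$features, drop = FALSE])
  storage.mode(X) <- "double"
  X %*% m$discriminants
}

classify_nearest <- function(m, tbl) {
  sc <- lda_project(m, tbl)
  d2 <- vapply(seq_along(m$groups), function(gi) {
    rowSums(sweep(sc, 2, m$mean_scores[gi, ])^2)
  }, numeric(nrow(sc)))
  d2 <- matrix(d2, nrow = nrow(sc))
  m$groups[max.col(-d2, ties.method = "first")]
}

#' Classification success of the speaker LDA
#'
#' Percentage of sentences assigned to their true speaker by the
#' nearest-group-mean rule in discriminant space (equal priors). The default
#' leave-one-out mode refits the discriminant analysis without the held-out
#' sentence before classifying it; resubstitution classifies the training
#' rows directly.
#'
#' @param m A \code{\link{fit_lda}} model.
#' @param tbl The feature table the model was built from.
#' @param mode \code{"loo"} (leave-one-out, default) or
#'   \code{"resubstitution"}.
#' @return Percentage in \code{[0, 100]}.
#' @export
classification_success <- function(m, tbl, mode = c("loo", "resubstitution")) {
  mode <- match.arg(mode)
  cc <- stats::complete.cases(tbl[, m$features, drop = FALSE])
  d <- tbl[cc, , drop = FALSE]
  truth <- as.character(d$speaker_id)
  if (mode == "resubstitution") {
    pred <- classify_nearest(m, d)
  } else {
    pred <- character(nrow(d))
    for (i in seq_len(nrow(d))) {
      mi <- suppressMessages(fit_lda(d[-i, , drop = FALSE], m$features))
      pred[i] <- classify_nearest(mi, d[i, , drop = FALSE])
    }
  }
  100 * mean(pred == truth)
}

#' Select identity markers from discriminant loadings
#'
#' Features whose absolute standardized loading exceeds the selection
#' threshold on at least one discriminant function, ordered by maximum
#' absolute loading (descending).
#'
#' @param m A \code{\link{fit_lda}} model (or any list with a
#'   \code{loadings} matrix).
#' @param threshold Absolute-loading threshold (default 1.3).
#' @param quiet Suppress the empty-selection warning.
#' @return Character vector of selected feature names (possibly empty, with
#'   a warning).
#' @export
select_markers <- function(m, threshold = m$selection_threshold %||% 1.3,
                           quiet = FALSE) {
  lo <- apply(abs(m$loadings), 1, max)
  sel <- names(lo)[lo > threshold]
  if (!length(sel)) {
    if (!quiet) warning("no feature has |loading| above the threshold")
    return(character(0))
  }
  sel[order(lo[sel], decreasing = TRUE)]
}

#' Acoustic distance between two speakers on selected markers
#'
#' The distance on each marker is the absolute value of the difference
#' between the two speakers' values on that acoustic parameter. Distances
#' are symmetric, nonnegative and translation-invariant; z-scoring across a
#' trial table is applied afterwards by \code{\link{zscore_distances}}.
#'
#' @param owner,control Named numeric vectors (or one-row data frames) of
#'   feature values.
#' @param markers Marker names to use.
#' @return Named numeric vector of raw distances (feature units).
#' @export
acoustic_distance <- function(owner, control, markers) {
  o <- unlist(owner)[markers]
  c_ <- unlist(control)[markers]
  if (any(is.na(o)) || any(is.na(c_))) {
    stop("missing marker value; trial must be flagged", call. = FALSE)
  }
  abs(o - c_)
}

#' Z-score distance columns across a trial table
#'
#' @param trials Data frame with raw distance columns named
#'   \code{dist_<marker>}.
#' @param markers Marker names whose distance columns to standardize.
#' @return \code{trials} with added \code{zdist_<marker>} columns (mean 0,
#'   SD 1 over non-missing rows).
#' @export
zscore_distances <- function(trials, markers) {
  for (mk in markers) {
    raw <- trials[[paste0("dist_", mk)]]
    if (is.null(raw)) stop(sprintf("missing column dist_%s", mk), call. = FALSE)
    trials[[paste0("zdist_", mk)]] <- as.numeric(scale(raw))
  }
  trials
}
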