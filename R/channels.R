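#' Lasso screening of channels against a pre/post-stimulus indicator
#'
#' Regresses a 0/1 stimulus indicator on the channel matrix with an l1
#' penalty, \eqn{\hat\beta = \arg\min_\beta n^{-1}\|Y - X\beta\|^2 +
#' \lambda\|\beta\|_1}; channels with nonzero coefficients are "selected" as
#' carrying the pre/post difference. Columns of X and Y are centered and
#' standardized first, and coefficients are reported on that standardized
#' scale. The solver is the coordinate-descent path of \pkg{glmnet} (whose
#' objective uses \eqn{(2n)^{-1}} on the quadratic term, so its penalty is
#' `lambda / 2`); it returns exact zeros, and "selected" means exactly
#' nonzero.
#'
#' @param X Numeric matrix, observations x channels.
#' @param Y 0/1 indicator, one value per row of X (both classes present).
#' @param lambda Nonnegative penalty on the scale above, or `"cv"` (default)
#'   for K-fold cross-validation with the minimum-CV-error rule. `lambda =
#'   0` with p < n returns the least-squares solution.
#' @param nfolds Folds for cross-validation (default 10).
#' @param seed Optional seed for the fold assignment.
#' @param logistic Use the lasso-penalized logistic loss instead of squared
#'   error (off by default; the squared-error form is the primary).
#' @return Object of class `channel_selection`: list with `coefficients`
#'   (length p, standardized scale), `selected` (integer index set),
#'   `lambda_used`, `labels`.
#' @export
lasso_select <- function(X, Y, lambda = "cv", nfolds = 10, seed = NULL,
                         logistic = FALSE) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  if (nrow(X) != length(Y)) {
    stop("`X` and `Y` must have matching lengths.", call. = FALSE)
  }
  if (length(unique(Y)) < 2L) {
    stop("`Y` must contain both classes (0 and 1).", call. = FALSE)
  }
  p <- ncol(X)
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("ch", seq_len(p))

  sds <- apply(X, 2L, sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant channel(s) dropped from selection: ",
            paste(labels[constant], collapse = ", "), call. = FALSE)
  }
  keep <- which(!constant)
  Xs <- scale(X[, keep, drop = FALSE])
  Ys <- as.numeric(scale(Y))

  beta <- numeric(length(keep))
  yy <- if (logistic) Y else Ys
  fam <- if (logistic) "binomial" else "gaussian"
  use_intercept <- logistic
  if (identical(lambda, "cv")) {
    if (!is.null(seed)) set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(Xs)))
    cv <- glmnet::cv.glmnet(Xs, yy, foldid = foldid, family = fam,
                            standardize = FALSE, intercept = use_intercept)
    lambda_used <- 2 * cv$lambda.min
    beta <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  } else {
    check_scalar(lambda, "lambda", lower = 0)
    lambda_used <- lambda
    if (lambda == 0 && !logistic && length(keep) < nrow(Xs)) {
      beta <- as.numeric(stats::lm.fit(Xs, Ys)$coefficients)
      beta[is.na(beta)] <- 0
    } else {
      fit <- glmnet::glmnet(Xs, yy, family = fam, standardize = FALSE,
                            intercept = use_intercept)
      beta <- as.numeric(predict(fit, s = lambda / 2,
                                 type = "coefficients", exact = TRUE,
                                 x = Xs, y = yy, family = fam,
                                 standardize = FALSE,
                                 intercept = use_intercept))[-1L]
    }
  }

  coefficients <- numeric(p)
  coefficients[keep] <- beta
  names(coefficients) <- labels
  structure(
    list(coefficients = coefficients,
         selected = which(coefficients != 0),
         lambda_used = lambda_used, labels = labels),
    class = "channel_selection"
  )
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection>", length(x$selected), "of",
      length(x$coefficients), "channels selected (lambda =",
      signif(x$lambda_used, 4), ")\n")
  if (length(x$selected)) {
    cat("  ", paste(x$labels[x$selected], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate channel-selection frequencies across fits
#'
#' Counts, for each channel, how many of the supplied per-individual lasso
#' fits selected it — the bar heights of a selection-frequency chart.
#'
#' @param selections List of [lasso_select()] results sharing a common p.
#' @param labels Optional channel names (default: taken from the first
#'   selection).
#' @return A tibble of class `channel_frequency` with columns `channel`,
#'   `label`, `count`, sorted by decreasing count.
#' @export
selection_frequency <- function(selections, labels = NULL) {
  stopifnot(length(selections) >= 1L)
  p <- length(selections[[1L]]$coefficients)
  counts <- integer(p)
  for (sel in selections) {
    stopifnot(inherits(sel, "channel_selection"))
    if (length(sel$coefficients) != p) {
      stop("All selections must share the same number of channels.",
           call. = FALSE)
    }
    counts[sel$selected] <- counts[sel$selected] + 1L
  }
  if (is.null(labels)) labels <- selections[[1L]]$labels
  out <- tibble::tibble(channel = seq_len(p), label = labels,
                        count = counts)
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$channel)
  class(out) <- c("channel_frequency", class(out))
  out
}

#' Degree centrality of a significant-change network
#'
#' Degree = number of incident edges per channel; the `top_k` ranking is by
#' degree descending with ties broken by label order, so reports are
#' deterministic.
#'
#' @param edges A data frame with integer columns `i` and `j` (e.g. the
#'   `edges` of an [mpde_test()] result or the output of
#'   [significant_network()]), or a two-column matrix of index pairs.
#' @param p Number of channels.
#' @param labels Optional channel names.
#' @param k Number of top channels to report (default 5).
#' @return Object of class `centrality_report`: list with `degrees` (tibble
#'   `channel`, `label`, `degree`) and `top_k` (character vector).
#' @export
degree_centrality <- function(edges, p, labels = NULL, k = 5) {
  if (is.matrix(edges)) {
    edges <- tibble::tibble(i = edges[, 1L], j = edges[, 2L])
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(p))
  stopifnot(length(labels) == p)
  deg <- integer(p)
  if (nrow(edges) > 0) {
    idx <- c(edges$i, edges$j)
    if (any(idx < 1 | idx > p)) {
      stop("Edge index out of range 1..", p, ".", call. = FALSE)
    }
    tab <- table(factor(idx, levels = seq_len(p)))
    deg <- as.integer(tab)
  }
  degrees <- tibble::tibble(channel = seq_len(p), label = labels,
                            degree = deg)
  ord <- order(-degrees$degree, degrees$label)
  top_k <- degrees$label[ord][seq_len(min(k, p))]
  structure(list(degrees = degrees, top_k = top_k, n_edges = nrow(edges)),
            class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("<centrality_report>", x$n_edges, "edges; top channels:",
      paste(x$top_k, collapse = ", "), "\n")
  invisible(x)
}
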