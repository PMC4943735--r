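# Distinguishability of labeled pattern classes: leave-one-out success of
# a linear maximum-margin classifier (libsvm via e1071, C = 1), a
# label-permutation significance test, the pairwise (Table-style) driver
# with optional Holm correction, and the unknown-group assignment
# procedure.

#' Bundle signatures and class labels for classification
#'
#' @param matrix n x T numeric matrix of visual signatures (rows =
#'   images).
#' @param labels Character vector of class names, length n.
#' @param ids Optional image identifiers (default: matrix row names or
#'   generated).
#' @param mode `"color"` or `"grayscale"` (metadata only).
#' @return An object of class `signature_dataset`.
#' @export
signature_dataset <- function(matrix, labels, ids = NULL,
                              mode = c("color", "grayscale")) {
  mode <- match.arg(mode)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_validation("matrix must be a numeric matrix")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop_validation("signatures must contain no missing or non-finite values")
  labels <- as.character(labels)
  if (length(labels) != nrow(matrix))
    stop_validation("labels must have one entry per matrix row")
  if (is.null(ids)) ids <- rownames(matrix)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(nrow(matrix)))
  structure(
    list(matrix = matrix, labels = labels, ids = ids, mode = mode),
    class = "signature_dataset")
}

#' Linear maximum-margin classifier configuration
#'
#' The classifier is a linear soft-margin SVM (hinge loss) solved by
#' libsvm with regularization constant `C` and dual tolerance
#' `tolerance`. Features are standardized (zero mean, unit variance)
#' on each training fold before fitting — libsvm's recommended
#' preprocessing, which makes the analysis invariant to the overall
#' scale of the signature values. A test point whose decision value is
#' exactly 0 is assigned to the lexicographically first class name,
#' making predictions deterministic.
#'
#' @param C Regularization constant (> 0; default 1).
#' @param tolerance Solver termination tolerance (default 1e-6).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(C = 1, tolerance = 1e-6) {
  if (!is_scalar_number(C) || C <= 0) stop_validation("C must be > 0")
  if (!is_scalar_number(tolerance) || tolerance <= 0)
    stop_validation("tolerance must be > 0")
  structure(list(C = C, tolerance = tolerance), class = "classifier_config")
}

check_two_class <- function(labels, min_per_class = 2L) {
  tab <- table(labels)
  if (length(tab) < 2L)
    stop_validation("need exactly 2 classes; got a single class: ", names(tab))
  if (length(tab) > 2L)
    stop_validation("need exactly 2 classes; got ", length(tab),
                    " (use pairwise_distinguishability for multi-class tables)")
  if (any(tab < min_per_class))
    stop_validation("every class needs >= ", min_per_class, " members; counts: ",
                    paste(names(tab), tab, sep = "=", collapse = ", "))
  invisible(tab)
}

# Train the linear SVM and return a closure predicting new rows with the
# deterministic tie rule (decision value exactly 0 -> lexicographically
# first class name).
train_linear <- function(X, labels, cfg) {
  lev <- sort(unique(labels))
  # features are standardized on the training fold (libsvm's recommended
  # preprocessing); constant columns trigger a harmless scaling warning
  fit <- suppressWarnings(
    e1071::svm(X, factor(labels, levels = lev), kernel = "linear",
               cost = cfg$C, tolerance = cfg$tolerance, scale = TRUE))
  # decision values are signed toward the first label seen by libsvm
  pos <- strsplit(colnames(fit$decision.values), "/", fixed = TRUE)[[1]][1]
  neg <- setdiff(lev, pos)
  list(
    n_support = sum(fit$nSV),
    predict = function(newX) {
      dv <- attr(stats::predict(fit, newX, decision.values = TRUE),
                 "decision.values")[, 1]
      out <- ifelse(dv > 0, pos, neg)
      out[dv == 0] <- lev[1]
      out
    })
}

loo_predictions <- function(X, labels, cfg) {
  vapply(seq_len(nrow(X)), function(i) {
    model <- train_linear(X[-i, , drop = FALSE], labels[-i], cfg)
    model$predict(X[i, , drop = FALSE])
  }, character(1))
}

#' Leave-one-out classification success rate
#'
#' For each sample in turn, trains the linear classifier on the remaining
#' n - 1 samples and predicts the held-out one; the success rate is the
#' fraction of correct predictions. High rates indicate visually
#' distinguishable classes; rates near chance indicate classes the
#' signature cannot separate.
#'
#' @param data A two-class [signature_dataset()] with >= 2 members per
#'   class and n >= 4.
#' @param cfg A [classifier_config()].
#' @return An object of class `loo_result`: `success_rate` (exactly
#'   #correct / n), `predicted` (per-sample labels, input order), `n`,
#'   and `n_support` (support-vector count of a fit on the full data,
#'   logged for comparability).
#' @export
loo_success_rate <- function(data, cfg = classifier_config()) {
  if (!inherits(data, "signature_dataset"))
    stop_validation("data must be a signature_dataset")
  check_two_class(data$labels)
  if (nrow(data$matrix) < 4L)
    stop_validation("need n >= 4 for a two-class leave-one-out analysis")
  pred <- loo_predictions(data$matrix, data$labels, cfg)
  structure(
    list(success_rate = sum(pred == data$labels) / length(pred),
         predicted = pred, n = length(pred),
         n_support = train_linear(data$matrix, data$labels, cfg)$n_support),
    class = "loo_result")
}

#' Permutation test for a leave-one-out success rate
#'
#' Estimates the null distribution of the LOO success rate under the
#' hypothesis that labels and visual appearance are not linked: in each
#' randomization the labels are permuted uniformly among all samples and
#' the entire leave-one-out loop is recomputed. The P-value uses the
#' add-one estimator `p = (1 + #\{null >= observed\}) / (n_permutations
#' + 1)`, which is never zero and is bounded below by
#' `1 / (n_permutations + 1)`.
#'
#' @inheritParams loo_success_rate
#' @param n_permutations Number of label permutations (>= 99; the
#'   full-scale analysis uses 10000).
#' @param seed Integer seed; the same seed reproduces the identical null
#'   distribution.
#' @return An object of class `permutation_result`: `observed_rate`,
#'   `null_rates` (length `n_permutations`), `p_value`,
#'   `n_permutations`, `seed`, `n`.
#' @export
permutation_p_value <- function(data, cfg = classifier_config(),
                                n_permutations = 999L, seed = 1L) {
  if (!inherits(data, "signature_dataset"))
    stop_validation("data must be a signature_dataset")
  check_two_class(data$labels)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 99L)
    stop_validation("n_permutations must be >= 99 (P-value resolution too coarse)")
  obs <- loo_success_rate(data, cfg)
  null_rates <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    perm <- sample(data$labels)
    pred <- loo_predictions(data$matrix, perm, cfg)
    sum(pred == perm) / length(perm)
  }, numeric(1)))
  p <- (1 + sum(null_rates >= obs$success_rate)) / (n_permutations + 1)
  structure(
    list(observed_rate = obs$success_rate, null_rates = null_rates,
         p_value = p, n_permutations = n_permutations, seed = seed,
         n = obs$n, predicted = obs$predicted),
    class = "permutation_result")
}

#' Pairwise distinguishability table
#'
#' Runs [permutation_p_value()] for every requested unordered pair of
#' classes in a multi-class dataset, producing one row per pair — the
#' structure of a pairwise classification table with per-pair success
#' rates and permutation P-values, optionally flagged by Holm's
#' sequential (step-down Bonferroni) multiple-testing procedure.
#'
#' @param data A [signature_dataset()] with k >= 2 classes.
#' @param cfg A [classifier_config()].
#' @param n_permutations,seed Passed to [permutation_p_value()]; each
#'   pair uses a sub-seed derived deterministically from `seed`.
#' @param pairs Optional restriction: list of length-2 character vectors
#'   or a data.frame/matrix with two columns of class names (default: all
#'   unordered pairs).
#' @param holm_alpha Family-wise error level for the Holm flags (default
#'   0.05).
#' @return A data.frame with columns `class1`, `class2`, `n1`, `n2`,
#'   `success_rate`, `p_value`, `n_permutations`, `holm_significant`.
#' @export
pairwise_distinguishability <- function(data, cfg = classifier_config(),
                                        n_permutations = 999L, seed = 1L,
                                        pairs = NULL, holm_alpha = 0.05) {
  if (!inherits(data, "signature_dataset"))
    stop_validation("data must be a signature_dataset")
  classes <- sort(unique(data$labels))
  if (length(classes) < 2L) stop_validation("need at least 2 classes")
  if (is.null(pairs)) {
    cmb <- utils::combn(classes, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    if (is.matrix(pairs) || is.data.frame(pairs))
      pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(unlist(pairs[i, 1:2])))
    bad <- unique(unlist(pairs))[!unique(unlist(pairs)) %in% classes]
    if (length(bad))
      stop_validation("requested pair mentions unknown class(es): ",
                      paste(bad, collapse = ", "))
  }
  rows <- lapply(seq_along(pairs), function(j) {
    pr <- sort(pairs[[j]])
    keep <- data$labels %in% pr
    sub <- signature_dataset(data$matrix[keep, , drop = FALSE],
                             data$labels[keep], data$ids[keep], data$mode)
    res <- permutation_p_value(sub, cfg, n_permutations, derive_seed(seed, j))
    data.frame(class1 = pr[1], class2 = pr[2],
               n1 = sum(sub$labels == pr[1]), n2 = sum(sub$labels == pr[2]),
               success_rate = res$observed_rate, p_value = res$p_value,
               n_permutations = n_permutations)
  })
  out <- do.call(rbind, rows)
  out$holm_significant <- holm_flags(out$p_value, holm_alpha)
  out
}

#' Holm (sequential Bonferroni) significance flags
#'
#' @param p Vector of P-values.
#' @param alpha Family-wise error level.
#' @return Logical vector: whether each test survives Holm's step-down
#'   procedure at level `alpha` (equivalent to `p.adjust(p, "holm") <=
#'   alpha`).
#' @export
holm_flags <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Assign unknown samples to one of two trained classes
#'
#' Trains the linear classifier once on the full two-class training set,
#' assigns every unknown to one of the training classes, and reports the
#' fraction assigned to each. In addition, the unknown group as a whole is
#' tested for separability from each training class: the unknowns are
#' labeled as one class, the training class's samples as the other, and
#' [permutation_p_value()] is run on that two-class dataset. A large
#' group-separability P-value means the unknowns are statistically
#' indistinguishable from that class.
#'
#' @param train A two-class [signature_dataset()].
#' @param unknowns m x T matrix of signatures with the same T and mode as
#'   `train`.
#' @param cfg A [classifier_config()].
#' @param n_permutations,seed For the group-separability tests.
#' @return An object of class `unknown_assignment`: `assigned`
#'   (per-unknown predicted class), `fractions` (named, sums to 1),
#'   `group_separability` (named list of `permutation_result`, one per
#'   training class).
#' @export
assign_unknowns <- function(train, unknowns, cfg = classifier_config(),
                            n_permutations = 999L, seed = 1L) {
  if (!inherits(train, "signature_dataset"))
    stop_validation("train must be a signature_dataset")
  check_two_class(train$labels)
  if (!is.matrix(unknowns) || ncol(unknowns) != ncol(train$matrix))
    stop_validation("unknowns must be a matrix with the same number of columns (",
                    ncol(train$matrix), ") as the training signatures")
  if (nrow(unknowns) < 2L) stop_validation("need at least 2 unknown samples")
  classes <- sort(unique(train$labels))
  model <- train_linear(train$matrix, train$labels, cfg)
  assigned <- model$predict(unknowns)
  fractions <- vapply(classes, function(cl) mean(assigned == cl), numeric(1))
  sep <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    keep <- train$labels == cl
    X <- rbind(train$matrix[keep, , drop = FALSE], unknowns)
    lab <- c(rep(cl, sum(keep)), rep("unknown_group", nrow(unknowns)))
    ds <- signature_dataset(X, lab, mode = train$mode)
    permutation_p_value(ds, cfg, n_permutations, derive_seed(seed, ci))
  })
  names(sep) <- classes
  structure(
    list(assigned = assigned, fractions = fractions,
         group_separability = sep),
    class = "unknown_assignment")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("leave-one-out: success rate", signif(x$success_rate, 4),
      "on n =", x$n, "(support vectors:", x$n_support, ")\n")
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("LOO success rate", signif(x$observed_rate, 4), "on n =", x$n,
      "; permutation P =", signif(x$p_value, 4),
      "(", x$n_permutations, "permutations, seed", x$seed, ")\n")
  invisible(x)
}

#' @export
print.unknown_assignment <- function(x, ...) {
  cat("unknown assignment:",
      paste(sprintf("%s: %.1f%%", names(x$fractions), 100 * x$fractions),
            collapse = ", "), "\n")
  for (cl in names(x$group_separability))
    cat("  separability of unknown group vs", cl, ": P =",
        signif(x$group_separability[[cl]]$p_value, 4), "\n")
  invisible(x)
}
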