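#' Parameters for conditional inference tree growth
#'
#' @param alpha significance level for the Bonferroni-adjusted variable
#'   selection test (default 0.05); a node is split only when the best
#'   covariate's adjusted p-value reaches it.
#' @param min_node_to_split smallest node size still considered for
#'   splitting (default 4, sized for ~21-sample cohorts).
#' @param min_leaf minimum samples per child (default 2).
#' @param max_depth depth cap (`Inf` = unlimited).
#' @param exact_permutation_n below this node size the association p-value
#'   comes from full permutation enumeration instead of the normal
#'   approximation (default 8).
#' @return A validated `rbdge_ctree_params` list.
#' @export
ctree_params <- function(alpha = 0.05, min_node_to_split = 4, min_leaf = 2,
                         max_depth = Inf, exact_permutation_n = 8) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_leaf < 1) stop("min_leaf must be at least 1")
  structure(list(alpha = alpha, min_node_to_split = min_node_to_split,
                 min_leaf = min_leaf, max_depth = max_depth,
                 exact_permutation_n = exact_permutation_n),
            class = "rbdge_ctree_params")
}

#' Permutation association test between a covariate and a binary response
#'
#' The linear statistic is `T = sum(x_i y_i)` with conditional moments
#' `E[T] = sum(x) sum(y) / n` and
#' `V[T] = sum((x - xbar)^2) sum((y - ybar)^2) / (n - 1)` under random
#' permutation of the response. The two-sided p-value uses the normal
#' approximation of `z = (T - E) / sqrt(V)` for nodes of size
#' `exact_permutation_n` or more, and full enumeration of the distinct
#' permutations of `y` below it. A degenerate covariate or response
#' (V = 0) gives p = 1.
#'
#' @param x numeric covariate.
#' @param y binary (0/1) response.
#' @param exact_permutation_n see [ctree_params()].
#' @return A list: `T`, `E`, `V`, `z`, `p`.
#' @export
assoc_test <- function(x, y, exact_permutation_n = 8) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  T_obs <- sum(x * y)
  E <- sum(x) * sum(y) / n
  V <- sum((x - mean(x))^2) * sum((y - mean(y))^2) / (n - 1)
  if (V <= 0) {
    return(list(T = T_obs, E = E, V = 0, z = 0, p = 1))
  }
  z <- (T_obs - E) / sqrt(V)
  if (n < exact_permutation_n) {
    # enumerate distinct permutations of y: choose positions of the ones
    ones <- sum(y)
    pos_sets <- utils::combn(n, ones)
    T_all <- vapply(seq_len(ncol(pos_sets)), function(j) {
      sum(x[pos_sets[, j]])
    }, numeric(1))
    obs_dev <- abs(T_obs - E)
    p <- mean(abs(T_all - E) >= obs_dev - 1e-12)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(T = T_obs, E = E, V = V, z = z, p = p)
}

#' Bonferroni variable selection at a node
#'
#' Runs [assoc_test()] for every covariate, multiplies the p-values by the
#' number of covariates (capped at 1), and returns the best covariate if
#' its adjusted p reaches `alpha` — otherwise no split. Ties go to the
#' first covariate in input order.
#'
#' @param X numeric matrix, covariates in columns.
#' @param y binary 0/1 response.
#' @param params [ctree_params()].
#' @return A list: `variable` (column name or `NA`), `p_adj`, and the
#'   per-covariate adjusted p-values.
#' @export
select_variable <- function(X, y, params = ctree_params()) {
  m <- ncol(X)
  if (m < 1) stop("need at least one covariate")
  p_raw <- vapply(seq_len(m), function(j) {
    assoc_test(X[, j], y, params$exact_permutation_n)$p
  }, numeric(1))
  p_adj <- pmin(p_raw * m, 1)
  names(p_adj) <- colnames(X)
  best <- which.min(p_adj)          # first index on ties
  if (p_adj[best] <= params$alpha) {
    list(variable = colnames(X)[best], index = best,
         p_adj = unname(p_adj[best]), all_p_adj = p_adj)
  } else {
    list(variable = NA_character_, index = NA_integer_,
         p_adj = unname(p_adj[best]), all_p_adj = p_adj)
  }
}

#' Best binary split of a selected covariate
#'
#' Over every midpoint between adjacent distinct values that leaves at
#' least `min_leaf` samples on each side, choose the threshold maximizing
#' the absolute standardized two-sample statistic (the left-side indicator
#' plays the covariate role in [assoc_test()]'s moments); ties take the
#' smaller threshold.
#'
#' @param x numeric covariate (already selected).
#' @param y binary 0/1 response.
#' @param params [ctree_params()].
#' @return Threshold, or `NA` when no admissible split exists.
#' @export
best_split <- function(x, y, params = ctree_params()) {
  u <- sort(unique(x))
  if (length(u) < 2) return(NA_real_)
  thr <- (u[-1] + u[-length(u)]) / 2
  admissible <- vapply(thr, function(t) {
    sum(x <= t) >= params$min_leaf && sum(x > t) >= params$min_leaf
  }, logical(1))
  thr <- thr[admissible]
  if (length(thr) == 0) return(NA_real_)
  zs <- vapply(thr, function(t) {
    ind <- as.numeric(x <= t)
    at <- assoc_test(ind, y, exact_permutation_n = 0)  # |z| only
    abs(at$z)
  }, numeric(1))
  thr[which.max(zs)]                 # which.max takes the first (smallest)
}

#' Grow a conditional inference tree
#'
#' Recursive partitioning for a binary response: at each node the split
#' covariate is chosen by the Bonferroni-adjusted permutation association
#' test and the node is split at the best threshold; growth stops when no
#' covariate reaches `alpha`, the node is pure or too small, or the depth
#' cap is hit.
#'
#' @param X numeric matrix or data frame, covariates in columns.
#' @param y binary response (factor, logical or 0/1).
#' @param params [ctree_params()].
#' @return A `rbdge_ctree`: nested nodes (`split` with `variable`,
#'   `threshold`, `p_adj`, `left`, `right`; or `leaf` with `counts`,
#'   `majority`), plus the class levels and training prevalence.
#' @export
grow_ctree <- function(X, y, params = ctree_params()) {
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  yf <- factor(y)
  if (nlevels(yf) > 2) stop("binary response required")
  levels_y <- levels(yf)
  y01 <- as.numeric(yf == levels_y[length(levels_y)])
  root_major <- levels_y[which.max(tabulate(yf, nlevels(yf)))]

  leaf <- function(idx) {
    counts <- table(factor(yf[idx], levels = levels_y))
    maj_n <- max(counts)
    maj <- names(counts)[counts == maj_n]
    list(type = "leaf", n = length(idx),
         counts = stats::setNames(as.integer(counts), levels_y),
         majority = if (length(maj) == 1) maj else NA_character_)
  }
  build <- function(idx, depth) {
    pure <- length(unique(y01[idx])) == 1
    if (pure || length(idx) < params$min_node_to_split ||
        depth >= params$max_depth) {
      return(leaf(idx))
    }
    sel <- select_variable(X[idx, , drop = FALSE], y01[idx], params)
    if (is.na(sel$index)) return(leaf(idx))
    thr <- best_split(X[idx, sel$index], y01[idx], params)
    if (is.na(thr)) return(leaf(idx))
    left <- idx[X[idx, sel$index] <= thr]
    right <- idx[X[idx, sel$index] > thr]
    list(type = "split", variable = sel$variable, threshold = thr,
         p_adj = sel$p_adj, n = length(idx),
         left = build(left, depth + 1), right = build(right, depth + 1))
  }
  structure(list(root = build(seq_along(y01), 0), levels = levels_y,
                 train_majority = root_major, params = params),
            class = "rbdge_ctree")
}

tree_depth <- function(node) {
  if (node$type == "leaf") 0 else {
    1 + max(tree_depth(node$left), tree_depth(node$right))
  }
}

#' @export
print.rbdge_ctree <- function(x, ...) {
  cat("Conditional inference tree: depth", tree_depth(x$root),
      "| classes:", paste(x$levels, collapse = "/"), "\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "leaf n=", node$n, " (",
          paste(names(node$counts), node$counts, sep = ":", collapse = ", "),
          ")\n", sep = "")
    } else {
      cat(pad, node$variable, " <= ", signif(node$threshold, 4),
          "  [p_adj=", signif(node$p_adj, 3), "]\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$root, 1)
  invisible(x)
}

#' Predict classes from a conditional inference tree
#'
#' Samples at exactly a split threshold route left (the `<=` convention).
#' A tied leaf falls back to the parent's majority, then to the training
#' prevalence, then to the lexicographically first class.
#'
#' @param object a [grow_ctree()] tree.
#' @param newdata matrix or data frame containing the covariates the tree
#'   uses.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.rbdge_ctree <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata))
  route <- function(node, i, parent_majority) {
    if (node$type == "leaf") {
      if (!is.na(node$majority)) return(node$majority)
      if (!is.na(parent_majority)) return(parent_majority)
      if (!is.na(object$train_majority)) return(object$train_majority)
      return(sort(object$levels)[1])
    }
    if (!node$variable %in% colnames(X)) {
      stop("covariate missing from newdata: ", node$variable)
    }
    counts <- node_counts(node)
    maj_n <- max(counts)
    maj <- names(counts)[counts == maj_n]
    here_majority <- if (length(maj) == 1) maj else parent_majority
    if (X[i, node$variable] <= node$threshold) {
      route(node$left, i, here_majority)
    } else {
      route(node$right, i, here_majority)
    }
  }
  vapply(seq_len(nrow(X)), function(i) route(object$root, i, NA_character_),
         "")
}

node_counts <- function(node) {
  if (node$type == "leaf") return(node$counts)
  lc <- node_counts(node$left)
  rc <- node_counts(node$right)
  lc + rc[names(lc)]
}

#' Leave-one-out cross-validation of a conditional inference tree
#'
#' Grows `n` trees, each with one sample held out, and scores the held-out
#' predictions. Fully deterministic: the trees use asymptotic or exact
#' permutation p-values, never Monte-Carlo.
#'
#' @param X covariate matrix or data frame.
#' @param y binary response.
#' @param params [ctree_params()].
#' @return A list: `predictions`, `truth`, `accuracy`, `confusion`.
#' @export
loocv_ctree <- function(X, y, params = ctree_params()) {
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 3) stop("leave-one-out cross-validation needs n >= 3")
  yf <- as.character(factor(y))
  preds <- vapply(seq_len(n), function(i) {
    fit <- grow_ctree(X[-i, , drop = FALSE], yf[-i], params)
    predict(fit, X[i, , drop = FALSE])
  }, "")
  lev <- sort(unique(yf))
  list(predictions = preds, truth = yf,
       accuracy = mean(preds == yf),
       confusion = table(truth = factor(yf, lev),
                         predicted = factor(preds, lev)))
}
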