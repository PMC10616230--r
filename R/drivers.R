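## Attribution of growth-VPD sensitivity (t-values) to site predictors with
## a bagged CART regression forest. The forest is implemented in-package
## because the interpretation statistics required here — unscaled OOB
## permutation importance, per-variable average minimal depth, and
## root-node occurrence counts — need access to the full split structure of
## every tree. Species enters one-hot; its indicator columns are treated as
## one variable for every statistic (minimal depth = min over indicators,
## importance permutes the block jointly).

#' Assemble the sensitivity table for driver attribution
#'
#' One row per significant site-species VPD relationship: the t-value as
#' response plus the seven predictors (elevation, MAT, MAP, long-term summer
#' SMI, species, mean tree age, mean basal area).
#'
#' @param fits List of `growth_model_fit` (convergent and not).
#' @param site_summaries Data frame from [site_summary()] (`site_id`,
#'   `species`, `mean_age`, `mean_ba`).
#' @param climatologies Data frame with `site_id`, `elevation`, `mat`,
#'   `map`, `mean_summer_smi`.
#' @param alpha_level Significance threshold (default 0.05).
#' @param covariates Which VPD covariates to pool (default both).
#' @return Data frame `site_id, species, which_covariate, t_value,
#'   elevation, mat, map, summer_smi, mean_age, mean_ba`. Rows with a
#'   missing predictor are dropped with a message.
#' @export
assemble_sensitivity_table <- function(fits, site_summaries, climatologies,
                                       alpha_level = 0.05,
                                       covariates = c("vpd_t", "vpd_t1")) {
  rows <- list()
  for (fit in fits) {
    if (!isTRUE(fit$converged)) next
    cl <- classify_response(fit, alpha_level)
    for (cov in covariates) {
      term <- if (cov == "vpd_t") "beta1" else "beta2"
      klass <- if (cov == "vpd_t") cl$class_vpd_t else cl$class_vpd_t1
      if (!klass %in% c("negative", "positive")) next
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = fit$site_id, species = fit$species, which_covariate = cov,
        t_value = unname(fit$t[term]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(site_id = character(), species = character(),
                      which_covariate = character(), t_value = numeric()))
  d <- do.call(rbind, rows)
  d <- merge(d, site_summaries[, c("site_id", "species", "mean_age", "mean_ba")],
             by = c("site_id", "species"), all.x = TRUE)
  d <- merge(d, climatologies, by = "site_id", all.x = TRUE)
  pred <- c("elevation", "mat", "map", "summer_smi", "mean_age", "mean_ba")
  miss <- !stats::complete.cases(d[, intersect(pred, names(d))])
  if (any(miss)) {
    message(sum(miss), " significant rows dropped: missing predictors")
    d <- d[!miss, , drop = FALSE]
  }
  d
}

## ---- CART regression tree ------------------------------------------------

## Grow one regression tree on rows (x, y). Returns parallel node vectors.
grow_tree <- function(X, y, mtry, min_node, max_nodes = 4096L) {
  n <- length(y)
  p <- ncol(X)
  var <- integer(max_nodes); split <- numeric(max_nodes)
  left <- integer(max_nodes); right <- integer(max_nodes)
  pred <- numeric(max_nodes); depth <- integer(max_nodes)
  n_nodes <- 1L
  stack <- list(list(id = 1L, idx = seq_len(n), depth = 0L))
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- nd$idx
    yi <- y[idx]
    pred[nd$id] <- mean(yi)
    depth[nd$id] <- nd$depth
    m <- length(idx)
    if (m <= min_node || stats::var(yi) == 0 || n_nodes + 2L > max_nodes) {
      var[nd$id] <- 0L
      next
    }
    cand <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- list(score = Inf)
    sse_tot <- sum(yi^2) - m * mean(yi)^2
    for (v in cand) {
      xv <- X[idx, v]
      o <- order(xv)
      xs <- xv[o]; ys <- yi[o]
      cs <- cumsum(ys)
      csq <- cumsum(ys^2)
      i <- seq_len(m - 1L)
      valid <- xs[i] < xs[i + 1L]
      if (!any(valid)) next
      nl <- i
      sse_l <- csq[i] - cs[i]^2 / nl
      sse_r <- (csq[m] - csq[i]) - (cs[m] - cs[i])^2 / (m - nl)
      score <- sse_l + sse_r
      score[!valid] <- Inf
      b <- which.min(score)
      if (score[b] < best$score) {
        best <- list(score = score[b], v = v,
                     cut = (xs[b] + xs[b + 1L]) / 2, o = o, nl = b)
      }
    }
    if (!is.finite(best$score) || best$score >= sse_tot - 1e-12 * max(sse_tot, 1)) {
      # no variance reduction available
      if (!is.finite(best$score)) { var[nd$id] <- 0L; next }
    }
    lid <- n_nodes + 1L; rid <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    var[nd$id] <- best$v
    split[nd$id] <- best$cut
    left[nd$id] <- lid; right[nd$id] <- rid
    go_left <- X[idx, best$v] <= best$cut
    stack[[length(stack) + 1L]] <- list(id = lid, idx = idx[go_left],
                                        depth = nd$depth + 1L)
    stack[[length(stack) + 1L]] <- list(id = rid, idx = idx[!go_left],
                                        depth = nd$depth + 1L)
  }
  keep <- seq_len(n_nodes)
  list(var = var[keep], split = split[keep], left = left[keep],
       right = right[keep], pred = pred[keep], depth = depth[keep])
}

## Vectorised routing of rows through one tree.
predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    v <- tree$var[node]
    active <- v > 0L
    if (!any(active)) break
    ia <- which(active)
    xv <- X[cbind(ia, v[ia])]
    goleft <- xv <= tree$split[node[ia]]
    node[ia] <- ifelse(goleft, tree$left[node[ia]], tree$right[node[ia]])
  }
  tree$pred[node]
}

#' Fit a bagged regression forest
#'
#' 500 (by default) CART regression trees, each grown on a bootstrap sample
#' with `mtry` candidate predictors per split; out-of-bag indices are
#' retained for permutation importance. The species factor is one-hot
#' encoded but aggregated as a single variable in all reports.
#'
#' @param table Sensitivity table from [assemble_sensitivity_table()], or
#'   any data frame containing `response_col` and the predictors.
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed.
#' @param mtry Predictors tried per split (default `ceiling(p / 3)` over the
#'   aggregated variables).
#' @param min_node Minimum node size eligible for splitting (default 5).
#' @param response_col Response column (default `"t_value"`).
#' @param predictors Predictor columns (default the seven standard ones
#'   present in `table`).
#' @return An `rf_model` list with the trees, encoded matrix, variable
#'   grouping, and OOB indices.
#' @export
fit_forest <- function(table, n_trees = 500, seed = 1L, mtry = NULL,
                       min_node = 5, response_col = "t_value",
                       predictors = NULL) {
  y <- table[[response_col]]
  if (is.null(y)) stop_config("response column '%s' missing", response_col)
  if (length(y) < 2 || is.na(stats::var(y)) || stats::var(y) == 0)
    stop_config("constant or empty response")
  predictors <- predictors %||%
    intersect(c("elevation", "mat", "map", "summer_smi", "species",
                "mean_age", "mean_ba"), names(table))
  n <- nrow(table)
  if (n < 30) warning("fewer than 30 rows: forest estimates will be noisy",
                      call. = FALSE)
  cols <- list(); groups <- character(); levels_map <- list()
  for (v in predictors) {
    x <- table[[v]]
    if (is.numeric(x)) {
      cols[[length(cols) + 1L]] <- x
      groups <- c(groups, v)
    } else {
      lev <- sort(unique(as.character(x)))
      levels_map[[v]] <- lev
      for (l in lev) {
        cols[[length(cols) + 1L]] <- as.numeric(as.character(x) == l)
        groups <- c(groups, v)
      }
    }
  }
  X <- do.call(cbind, cols)
  mtry <- mtry %||% ceiling(length(predictors) / 3)
  mtry_cols <- min(ncol(X), max(mtry, 1L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob[[b]] <- setdiff(seq_len(n), unique(boot))
    trees[[b]] <- grow_tree(X[boot, , drop = FALSE], y[boot], mtry_cols,
                            min_node)
    trees[[b]]$boot <- boot
  }
  structure(list(trees = trees, oob = oob, X = X, y = y, groups = groups,
                 predictors = predictors, levels_map = levels_map,
                 n_trees = n_trees, mtry = mtry_cols,
                 min_node = min_node, seed = seed),
            class = "rf_model")
}

#' Predict from a bagged forest
#' @param object An `rf_model`.
#' @param newdata Data frame with the predictor columns, or an encoded
#'   matrix matching the training encoding; defaults to the training data.
#' @param ... Unused.
#' @return Numeric predictions (mean over trees).
#' @export
predict.rf_model <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else encode_rf(object, newdata)
  preds <- matrix(0, nrow(X), object$n_trees)
  for (b in seq_len(object$n_trees))
    preds[, b] <- predict_tree(object$trees[[b]], X)
  rowMeans(preds)
}

encode_rf <- function(forest, newdata) {
  if (is.matrix(newdata)) return(newdata)
  cols <- list(); ci <- 1L
  for (v in forest$predictors) {
    if (is.null(forest$levels_map[[v]])) {
      cols[[ci]] <- newdata[[v]]; ci <- ci + 1L
    } else {
      x <- as.character(newdata[[v]])
      for (l in forest$levels_map[[v]]) {
        cols[[ci]] <- as.numeric(x == l); ci <- ci + 1L
      }
    }
  }
  do.call(cbind, cols)
}

#' Unscaled OOB permutation importance
#'
#' For each variable and tree, the variable's column block is permuted over
#' the tree's out-of-bag rows and the increase in OOB mean squared error is
#' recorded; importances are averaged over trees without scaling.
#'
#' @param forest An `rf_model`.
#' @param seed Seed for the permutations (default forest seed + 1).
#' @return Data frame `variable`, `mse_increase`, sorted decreasing.
#' @export
permutation_importance <- function(forest, seed = NULL) {
  stopifnot(inherits(forest, "rf_model"))
  seed <- seed %||% (forest$seed + 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vars <- unique(forest$groups)
  imp <- stats::setNames(numeric(length(vars)), vars)
  n_used <- stats::setNames(numeric(length(vars)), vars)
  for (b in seq_len(forest$n_trees)) {
    ob <- forest$oob[[b]]
    if (length(ob) < 2) next
    tree <- forest$trees[[b]]
    Xo <- forest$X[ob, , drop = FALSE]
    yo <- forest$y[ob]
    base_mse <- mean((yo - predict_tree(tree, Xo))^2)
    for (v in vars) {
      cols_v <- which(forest$groups == v)
      Xp <- Xo
      perm <- sample.int(length(ob))
      Xp[, cols_v] <- Xo[perm, cols_v, drop = FALSE]
      mse_p <- mean((yo - predict_tree(tree, Xp))^2)
      imp[v] <- imp[v] + (mse_p - base_mse)
      n_used[v] <- n_used[v] + 1
    }
  }
  res <- data.frame(variable = vars,
                    mse_increase = unname(imp / pmax(n_used, 1)))
  res[order(-res$mse_increase), ]
}

#' Average minimal depth and root-node occurrence per variable
#'
#' Minimal depth of a variable in a tree is the depth of the shallowest
#' node splitting on it (root = 0); variables absent from a tree are
#' assigned that tree's depth plus one. Root-node occurrences count which
#' variable splits the root, and sum to the number of trees.
#'
#' @param forest An `rf_model`.
#' @return Data frame `variable`, `avg_min_depth`, `root_node_count`, sorted
#'   by increasing depth.
#' @export
minimal_depth_stats <- function(forest) {
  stopifnot(inherits(forest, "rf_model"))
  vars <- unique(forest$groups)
  depth_sum <- stats::setNames(numeric(length(vars)), vars)
  root_count <- stats::setNames(integer(length(vars)), vars)
  for (b in seq_len(forest$n_trees)) {
    tree <- forest$trees[[b]]
    internal <- tree$var > 0L
    tree_depth <- max(tree$depth)
    split_groups <- forest$groups[tree$var[internal]]
    dvec <- tree$depth[internal]
    for (v in vars) {
      dv <- dvec[split_groups == v]
      depth_sum[v] <- depth_sum[v] +
        if (length(dv)) min(dv) else tree_depth + 1
    }
    root_var <- forest$groups[tree$var[1]]
    root_count[root_var] <- root_count[root_var] + 1L
  }
  res <- data.frame(variable = vars,
                    avg_min_depth = unname(depth_sum / forest$n_trees),
                    root_node_count = unname(root_count))
  res[order(res$avg_min_depth), ]
}

#' Importance report (tri-metric)
#'
#' Combines permutation importance with minimal-depth statistics into one
#' table with the three dominance metrics per variable.
#'
#' @param forest An `rf_model`.
#' @return Data frame `variable`, `avg_min_depth`, `mse_increase`,
#'   `root_node_count`.
#' @export
importance_report <- function(forest) {
  md <- minimal_depth_stats(forest)
  pi <- permutation_importance(forest)
  merge(md, pi, by = "variable")[, c("variable", "avg_min_depth",
                                     "mse_increase", "root_node_count")]
}

#' Partial dependence of the forest on one variable
#'
#' `PD(v) = mean_i f(x_i with variable forced to v)`. For the categorical
#' species variable, one value per level is returned. The output carries
#' the variable's sample quantiles (central 95 percent coverage band) so
#' extrapolated grid points can be flagged.
#'
#' @param forest An `rf_model`.
#' @param variable Variable name.
#' @param grid Grid of values (default: 25 points over the observed range
#'   for numeric variables; all levels for species).
#' @return Data frame `value`, `pd`, `extrapolated`; attribute `coverage95`
#'   holds the central 95 percent band of the variable.
#' @export
partial_dependence <- function(forest, variable, grid = NULL) {
  stopifnot(inherits(forest, "rf_model"))
  cols_v <- which(forest$groups == variable)
  if (length(cols_v) == 0) stop_config("unknown variable '%s'", variable)
  n <- nrow(forest$X)
  if (length(cols_v) > 1) {  # categorical block
    pd <- numeric(length(cols_v))
    for (j in seq_along(cols_v)) {
      Xg <- forest$X
      Xg[, cols_v] <- 0
      Xg[, cols_v[j]] <- 1
      pd[j] <- mean(predict.rf_model(forest, Xg))
    }
    lev <- forest$levels_map[[variable]] %||% paste0(variable, seq_along(cols_v))
    return(data.frame(value = lev, pd = pd, extrapolated = FALSE))
  }
  xobs <- forest$X[, cols_v]
  rng <- range(xobs)
  grid <- grid %||% seq(rng[1], rng[2], length.out = 25)
  cov95 <- stats::quantile(xobs, c(0.025, 0.975), names = FALSE)
  extrap <- grid < rng[1] | grid > rng[2]
  if (any(extrap)) warning("grid extends outside the observed range",
                           call. = FALSE)
  pd <- vapply(grid, function(v) {
    Xg <- forest$X
    Xg[, cols_v] <- v
    mean(predict.rf_model(forest, Xg))
  }, numeric(1))
  out <- data.frame(value = grid, pd = pd, extrapolated = extrap)
  attr(out, "coverage95") <- cov95
  out
}
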