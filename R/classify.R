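#' Decision-tree training configuration
#'
#' Hyperparameters of the CART learner: Gini impurity, no depth cap beyond
#' the implementation limit, minimum leaf size 5, no cost-complexity
#' pruning. All values are adjustable.
#'
#' @param minbucket Minimum number of windows in a leaf (default 5).
#' @param cp Complexity parameter; 0 disables pruning (default 0).
#' @param maxdepth Maximum tree depth (default 30, the CART limit).
#' @param seed Integer RNG seed recorded with the model.
#' @return A list of class `herdsense_tree_config`.
#' @export
tree_config <- function(minbucket = 5, cp = 0, maxdepth = 30, seed = 1L) {
  structure(
    list(
      minbucket = minbucket, cp = cp, maxdepth = maxdepth,
      seed = as.integer(seed)
    ),
    class = "herdsense_tree_config"
  )
}

# Internal constructor for a tree model over a node table.
# nodes: tibble with columns id, var (NA for leaves), threshold, left,
# right, label (leaf prediction), n, and per-class counts as a list column.
new_tree <- function(nodes, class_set, features, levels, config = tree_config()) {
  structure(
    list(
      nodes = nodes, class_set = class_set, features = features,
      levels = levels, config = config
    ),
    class = "herdsense_tree"
  )
}

# Convert a fitted rpart object into the canonical node table. Continuous
# splits are canonicalized so that `value <= threshold` always routes to
# the left child.
rpart_to_nodes <- function(fit) {
  frame <- fit$frame
  ids <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  ylevels <- attr(fit, "ylevels")
  counts <- frame$yval2[, 1 + seq_along(ylevels), drop = FALSE]
  var <- ifelse(is_leaf, NA_character_, as.character(frame$var))
  threshold <- rep(NA_real_, nrow(frame))
  left <- rep(NA_integer_, nrow(frame))
  right <- rep(NA_integer_, nrow(frame))
  if (any(!is_leaf)) {
    nsub <- frame$ncompete + frame$nsurrogate + 1L
    pos <- cumsum(c(1L, head(nsub[!is_leaf], -1)))
    thr <- fit$splits[pos, "index"]
    ncat <- fit$splits[pos, "ncat"]
    threshold[!is_leaf] <- thr
    l <- 2L * ids[!is_leaf]
    r <- l + 1L
    swap <- ncat > 0 # rpart sends `x < thr` right when ncat = +1
    left[!is_leaf] <- ifelse(swap, r, l)
    right[!is_leaf] <- ifelse(swap, l, r)
  }
  tibble(
    id = ids,
    var = var,
    threshold = threshold,
    left = left,
    right = right,
    label = ylevels[frame$yval],
    n = as.integer(frame$n),
    counts = lapply(seq_len(nrow(frame)), function(i) {
      stats::setNames(as.integer(counts[i, ]), ylevels)
    })
  )
}

#' Train a decision tree for one class set
#'
#' Fits a CART classification tree (Gini impurity, via \pkg{rpart}) on the
#' window feature table and converts it to a plain node table that the
#' package owns: prediction walks the table with the convention that
#' `value <= threshold` goes to the left child, and models serialize
#' losslessly to JSON ([write_tree()]).
#'
#' @param features Data frame of feature columns (no missing values).
#' @param labels Character vector of class-set group labels, aligned to
#'   `features` rows; at least two distinct labels.
#' @param class_set One of `"S1"`..`"S5"` (recorded in the model).
#' @param feature_subset Optional character vector of feature names to use
#'   (default: all feature columns present).
#' @param config A [tree_config()].
#' @return An object of class `herdsense_tree`.
#' @examples
#' feats <- tibble::tibble(vebda = c(rnorm(20, 1), rnorm(20, 2)))
#' fit <- train_tree(feats, rep(c("a", "b"), each = 20), "S1")
#' @export
train_tree <- function(features, labels, class_set,
                       feature_subset = NULL, config = tree_config()) {
  stopifnot(is.data.frame(features))
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) abort("labels must align with feature rows.")
  if (length(unique(labels)) < 2) {
    abort(sprintf("cannot train `%s`: training set has a single class.", class_set))
  }
  fn <- feature_subset %||% intersect(names(features), feature_names())
  missing_f <- setdiff(fn, names(features))
  if (length(missing_f) > 0) {
    abort(sprintf("feature(s) missing from table: %s", paste(missing_f, collapse = ", ")))
  }
  dat <- features[fn]
  if (anyNA(dat)) abort("features must be complete (no missing values).")
  dat$.label <- factor(labels)
  set.seed(config$seed)
  fit <- rpart::rpart(
    .label ~ ., data = dat, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      minsplit = 2L * config$minbucket, minbucket = config$minbucket,
      cp = config$cp, maxdepth = config$maxdepth, xval = 0L
    )
  )
  new_tree(rpart_to_nodes(fit), class_set, fn, levels(dat$.label), config)
}

#' Predict group labels with a trained tree
#'
#' Deterministically routes each feature vector from the root: values
#' `<= threshold` go left, larger values go right.
#'
#' @param object A `herdsense_tree`.
#' @param newdata Data frame containing (at least) the model's features.
#' @param ... Unused.
#' @return Character vector of group labels, one per row of `newdata`.
#' @export
predict.herdsense_tree <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f) > 0) {
    abort(sprintf("missing feature(s): %s", paste(missing_f, collapse = ", ")))
  }
  nodes <- object$nodes
  row_of <- match(seq_len(max(nodes$id)), nodes$id)
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    r <- row_of[1L]
    repeat {
      if (is.na(nodes$var[r])) {
        out[i] <- nodes$label[r]
        break
      }
      v <- newdata[[nodes$var[r]]][i]
      nxt <- if (v <= nodes$threshold[r]) nodes$left[r] else nodes$right[r]
      r <- row_of[nxt]
    }
  }
  out
}

#' @export
print.herdsense_tree <- function(x, ...) {
  cat(sprintf(
    "<herdsense_tree> class set %s: %d nodes (%d leaves), %d features\n",
    x$class_set, nrow(x$nodes), sum(is.na(x$nodes$var)), length(x$features)
  ))
  invisible(x)
}

#' Serialize / deserialize a tree model as JSON
#'
#' The JSON document carries the node table, class set, feature list,
#' class levels and training configuration; predictions after a round trip
#' are identical.
#'
#' @param tree A `herdsense_tree`.
#' @param path JSON file path.
#' @return `write_tree()` returns `path` invisibly; `read_tree()` returns
#'   the `herdsense_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "herdsense_tree"))
  doc <- list(
    class_set = tree$class_set,
    features = tree$features,
    levels = tree$levels,
    config = unclass(tree$config),
    nodes = tree$nodes |> mutate(counts = purrr::map(.data$counts, as.list))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- purrr::map(doc$nodes, function(nd) {
    tibble(
      id = as.integer(nd$id),
      var = if (is.null(nd$var)) NA_character_ else nd$var,
      threshold = if (is.null(nd$threshold)) NA_real_ else as.numeric(nd$threshold),
      left = if (is.null(nd$left)) NA_integer_ else as.integer(nd$left),
      right = if (is.null(nd$right)) NA_integer_ else as.integer(nd$right),
      label = nd$label,
      n = as.integer(nd$n),
      counts = list(unlist(nd$counts))
    )
  }) |> list_rbind()
  new_tree(
    nodes,
    class_set = doc$class_set,
    features = unlist(doc$features),
    levels = unlist(doc$levels),
    config = do.call(tree_config, doc$config)
  )
}

#' Train the five-classifier bank
#'
#' Trains one decision tree per class set S1--S5 on the labeled feature
#' table and stores the combiner weights (all 1 by default).
#'
#' @param features Data frame with the feature columns.
#' @param labels Data frame with label columns `s1`..`s5` aligned to
#'   `features` rows (e.g. from [window_labels()]).
#' @param feature_subset Optional retained feature names (e.g.
#'   `reduce_features(...)$selected`).
#' @param weights Numeric length-5 combiner weights, all >= 0 with at least
#'   one positive.
#' @param config A [tree_config()].
#' @return An object of class `herdsense_bank`: list with `models`
#'   (named `S1`..`S5`), `weights`, `feature_subset`.
#' @export
train_classifier_bank <- function(features, labels, feature_subset = NULL,
                                  weights = rep(1, 5), config = tree_config()) {
  stopifnot(is.data.frame(labels), all(paste0("s", 1:5) %in% names(labels)))
  check_weights(weights)
  models <- lapply(1:5, function(i) {
    train_tree(features, labels[[paste0("s", i)]], paste0("S", i),
      feature_subset = feature_subset, config = config
    )
  })
  names(models) <- paste0("S", 1:5)
  structure(
    list(
      models = models, weights = as.numeric(weights),
      feature_subset = models[[1]]$features
    ),
    class = "herdsense_bank"
  )
}

check_weights <- function(weights) {
  if (length(weights) != 5L || any(weights < 0) || all(weights == 0)) {
    abort("`weights` must be 5 non-negative values with at least one positive.")
  }
  invisible(weights)
}

#' @export
print.herdsense_bank <- function(x, ...) {
  cat(sprintf(
    "<herdsense_bank> 5 decision trees on %d features; weights (%s)\n",
    length(x$feature_subset), paste(format(x$weights), collapse = ", ")
  ))
  invisible(x)
}

#' Per-window predictions of the five classifiers
#'
#' @param bank A `herdsense_bank`.
#' @param features Feature table; a `window` column, if present, is carried
#'   through.
#' @return Tibble with columns `window` (if available) and `s1`..`s5`
#'   (group labels).
#' @export
predict_bank <- function(bank, features) {
  stopifnot(inherits(bank, "herdsense_bank"))
  out <- tibble(.rows = nrow(features))
  if ("window" %in% names(features)) out$window <- features$window
  for (i in 1:5) {
    out[[paste0("s", i)]] <- predict(bank$models[[paste0("S", i)]], features)
  }
  out
}

#' Combine the five classifier outputs into the weighted estimate S6
#'
#' For each behavior class k in 1..8, the overall weight `W_k` is the sum
#' of the weights of the classifiers whose output group contains k (a group
#' label contains the codes of its digits; an S5 pair `(a,b)` contains
#' classes a and b, so `(8,8)` contains only 8). The combined estimate `s6`
#' is the class with maximal `W_k`; ties are broken in favor of the S1
#' prediction when it is among the tied classes, else the lowest class
#' index.
#'
#' @param estimates Tibble with label columns `s1`..`s5` (from
#'   [predict_bank()]); a `window` column is carried through.
#' @param weights Numeric length-5 combiner weights.
#' @return `estimates` with added columns `w1`..`w8` (overall class
#'   weights) and `s6` (integer combined estimate).
#' @examples
#' est <- tibble::tibble(s1 = "3", s2 = "34", s3 = "13", s4 = "1234", s5 = "33")
#' combine_estimates(est)
#' @export
combine_estimates <- function(estimates, weights = rep(1, 5)) {
  stopifnot(is.data.frame(estimates), all(paste0("s", 1:5) %in% names(estimates)))
  check_weights(weights)
  n <- nrow(estimates)
  W <- matrix(0, nrow = n, ncol = 8)
  for (i in 1:5) {
    labs <- estimates[[paste0("s", i)]]
    for (lab in unique(labs)) {
      rows <- which(labs == lab)
      W[rows, group_members(lab)] <- W[rows, group_members(lab)] + weights[i]
    }
  }
  s1_code <- suppressWarnings(as.integer(estimates$s1))
  s6 <- integer(n)
  for (r in seq_len(n)) {
    cand <- which(W[r, ] == max(W[r, ]))
    s6[r] <- if (!is.na(s1_code[r]) && s1_code[r] %in% cand) s1_code[r] else min(cand)
  }
  out <- estimates
  colnames(W) <- paste0("w", 1:8)
  out <- bind_cols(out, as_tibble(W))
  out$s6 <- s6
  out
}

#' Write / read a classifier bank
#'
#' One JSON model file per classifier (`S1.json` .. `S5.json`) plus a
#' `manifest.json` carrying the weights and the feature subset.
#'
#' @param bank A `herdsense_bank`.
#' @param dir Directory (created if needed).
#' @return `write_bank()` returns `dir` invisibly; `read_bank()` returns
#'   the `herdsense_bank`.
#' @export
write_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "herdsense_bank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(bank$models)) {
    write_tree(bank$models[[id]], file.path(dir, paste0(id, ".json")))
  }
  jsonlite::write_json(
    list(
      weights = bank$weights, feature_subset = bank$feature_subset,
      models = paste0(names(bank$models), ".json")
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_bank
#' @export
read_bank <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  models <- lapply(manifest$models, function(f) read_tree(file.path(dir, f)))
  names(models) <- sub("\\.json$", "", manifest$models)
  structure(
    list(
      models = models, weights = as.numeric(manifest$weights),
      feature_subset = as.character(manifest$feature_subset)
    ),
    class = "herdsense_bank"
  )
}
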