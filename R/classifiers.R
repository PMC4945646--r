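#' Classifier cascade specification
#'
#' A cascade is written as meta-wrappers applied left-to-right to a base
#' learner, e.g. `"MCC+AB+RF"` is a one-against-all multiclass wrapper
#' around AdaBoost.M1 around a random forest. Supported tokens:
#'
#' * `MCC` - one-against-all multiclass meta-classifier;
#' * `BAG` - bagging, 10 bootstrap replicates, probability-averaged;
#' * `AB`  - AdaBoost.M1, 10 iterations, weighted resampling;
#' * `ASC` - attribute-selected classifier: wrapper feature selection
#'   (see [wrapper_select()]) is run on the dataset before the remaining
#'   cascade is trained;
#' * bases: `RF` (random forest, 100 trees, unlimited depth, all features
#'   eligible at every split), `SVM`, `MLP`, `LOGISTIC`, `NB` (naive
#'   Bayes), `CART` (decision tree), `KNN` (nearest neighbour, linear
#'   search), `ZERO_RULE`, `ONE_RULE`.
#'
#' @param cascade Cascade string.
#' @param trees Random-forest size (default 100).
#' @param ab_iterations AdaBoost.M1 iterations (default 10).
#' @param bags Bagging replicates (default 10).
#' @param seed Seed used to derive all stochastic fits.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(cascade = "RF", trees = 100, ab_iterations = 10,
                            bags = 10, seed = 1L) {
  tokens <- strsplit(cascade, "+", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  asc <- "ASC" %in% tokens
  tokens <- setdiff(tokens, "ASC")
  bases <- c("RF", "SVM", "MLP", "LOGISTIC", "NB", "CART", "KNN",
             "ZERO_RULE", "ONE_RULE")
  metas <- c("MCC", "BAG", "AB")
  assert_that(length(tokens) >= 1 && tokens[length(tokens)] %in% bases,
              "cascade must end with a base learner")
  assert_that(all(tokens[-length(tokens)] %in% metas),
              "unknown meta-classifier token")
  structure(list(cascade = cascade, tokens = tokens, asc = asc,
                 trees = trees, ab_iterations = ab_iterations, bags = bags,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---------------------------------------------------------------------------
# Base learners. Every fitter returns list(predict = function(x) probs)
# where probs is an n x nlevels matrix with colnames = class levels.

# Reindex a probability matrix onto the full class-level set: a resampled
# training set can miss a class entirely, in which case its column is 0.
align_probs <- function(p, levels) {
  out <- matrix(0, nrow(p), length(levels), dimnames = list(NULL, levels))
  common <- intersect(colnames(p), levels)
  out[, common] <- p[, common, drop = FALSE]
  out
}

one_hot <- function(pred, levels) {
  p <- matrix(0, length(pred), length(levels),
              dimnames = list(NULL, levels))
  p[cbind(seq_along(pred), match(as.character(pred), levels))] <- 1
  p
}

fit_base <- function(base, x, y, spec, seed) {
  levels <- levels(y)
  switch(
    base,
    RF = {
      fit <- ranger::ranger(x = x, y = y, num.trees = spec$trees,
                            mtry = ncol(x), min.node.size = 1,
                            probability = TRUE, seed = seed,
                            num.threads = 1)
      list(predict = function(newx) {
        p <- stats::predict(fit, data = newx, num.threads = 1)$predictions
        align_probs(p, levels)
      })
    },
    SVM = {
      fit <- e1071::svm(x = x, y = y)
      list(predict = function(newx) {
        one_hot(stats::predict(fit, newx), levels)
      })
    },
    MLP = {
      h <- max(3L, round((ncol(x) + length(levels)) / 2))
      fit <- with_local_seed(seed,
        nnet::nnet(x = as.matrix(x), y = nnet::class.ind(y), size = h,
                   softmax = TRUE, decay = 5e-4, maxit = 300,
                   MaxNWts = 100000, trace = FALSE))
      list(predict = function(newx) {
        p <- stats::predict(fit, as.matrix(newx))
        align_probs(p, levels)
      })
    },
    LOGISTIC = {
      df <- data.frame(x, .label = y, check.names = TRUE)
      fit <- nnet::multinom(.label ~ ., data = df, trace = FALSE,
                            MaxNWts = 100000)
      list(predict = function(newx) {
        ndf <- data.frame(newx, check.names = TRUE)
        p <- stats::predict(fit, ndf, type = "probs")
        if (is.null(dim(p))) { # binary: vector of P(second level)
          p <- cbind(1 - p, p)
          colnames(p) <- fit$lev
        }
        align_probs(p, levels)
      })
    },
    NB = {
      fit <- e1071::naiveBayes(x = x, y = y)
      list(predict = function(newx) {
        p <- stats::predict(fit, newx, type = "raw")
        align_probs(p, levels)
      })
    },
    CART = {
      df <- data.frame(x, .label = y, check.names = TRUE)
      fit <- rpart::rpart(.label ~ ., data = df, method = "class")
      list(predict = function(newx) {
        ndf <- data.frame(newx, check.names = TRUE)
        p <- stats::predict(fit, ndf, type = "prob")
        align_probs(p, levels)
      })
    },
    KNN = {
      train_x <- as.matrix(x)
      train_y <- y
      list(predict = function(newx) {
        pred <- class::knn(train_x, as.matrix(newx), train_y, k = 1)
        one_hot(pred, levels)
      })
    },
    ZERO_RULE = {
      counts <- table(y)
      major <- names(counts)[which.max(counts)] # ties: alphabetical first
      list(predict = function(newx) {
        one_hot(rep(major, nrow(newx)), levels)
      })
    },
    ONE_RULE = fit_one_rule(x, y, levels),
    stop("unknown base learner: ", base)
  )
}

# One Rule: a single feature discretized into quantile bins, each bin
# predicting its training-majority class; the feature with the highest
# training accuracy wins.
fit_one_rule <- function(x, y, levels, n_bins = 6) {
  best <- NULL
  best_acc <- -1
  for (f in names(x)) {
    v <- x[[f]]
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                 na.rm = TRUE))
    if (length(br) < 2) next
    br[1] <- -Inf
    br[length(br)] <- Inf
    bins <- cut(v, br)
    rule <- tapply(y, bins, function(g) {
      names(sort(table(g), decreasing = TRUE))[1]
    })
    rule[is.na(rule)] <- names(sort(table(y), decreasing = TRUE))[1]
    acc <- mean(rule[bins] == y, na.rm = TRUE)
    if (acc > best_acc) {
      best_acc <- acc
      best <- list(feature = f, breaks = br, rule = rule)
    }
  }
  if (is.null(best)) {
    major <- names(sort(table(y), decreasing = TRUE))[1]
    return(list(predict = function(newx) one_hot(rep(major, nrow(newx)),
                                                 levels)))
  }
  list(predict = function(newx) {
    bins <- cut(newx[[best$feature]], best$breaks)
    pred <- best$rule[bins]
    pred[is.na(pred)] <- best$rule[1]
    one_hot(unname(pred), levels)
  })
}

# ---------------------------------------------------------------------------
# Meta-learners

fit_bagging <- function(fit_inner, x, y, bags, seed) {
  seeds <- derive_seeds(seed, bags)
  models <- lapply(seq_len(bags), function(b) {
    idx <- with_local_seed(seeds[b],
                           sample.int(nrow(x), nrow(x), replace = TRUE))
    if (length(unique(y[idx])) < 2) idx <- seq_len(nrow(x))
    fit_inner(x[idx, , drop = FALSE], droplevels_keep(y[idx], y), seeds[b])
  })
  list(predict = function(newx) {
    ps <- lapply(models, function(m) m$predict(newx))
    Reduce(`+`, ps) / length(ps)
  })
}

droplevels_keep <- function(y, template) factor(y, levels = levels(template))

# AdaBoost.M1 with weighted resampling: each round the base learner is
# trained on a weight-proportional bootstrap of the data; instance weights
# are multiplied by beta = e/(1-e) when classified correctly and the votes
# are combined with weight log(1/beta).
fit_adaboost <- function(fit_inner, x, y, iterations, seed) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  seeds <- derive_seeds(seed, iterations)
  models <- list()
  alphas <- numeric()
  for (m in seq_len(iterations)) {
    idx <- with_local_seed(seeds[m],
                           sample.int(n, n, replace = TRUE, prob = w))
    if (length(unique(y[idx])) < 2) idx <- seq_len(n)
    fit <- fit_inner(x[idx, , drop = FALSE], droplevels_keep(y[idx], y),
                     seeds[m])
    pred_p <- fit$predict(x)
    pred <- colnames(pred_p)[max.col(pred_p, ties.method = "first")]
    err <- sum(w[pred != as.character(y)])
    if (err >= 0.5) {
      if (length(models) == 0) {
        models <- list(fit)
        alphas <- 1
      }
      break
    }
    if (err == 0) {
      models[[length(models) + 1L]] <- fit
      alphas <- c(alphas, 10) # effectively decisive vote
      break
    }
    beta <- err / (1 - err)
    alpha <- log(1 / beta)
    models[[length(models) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w[pred == as.character(y)] <- w[pred == as.character(y)] * beta
    w <- w / sum(w)
  }
  levels <- levels(y)
  list(predict = function(newx) {
    votes <- matrix(0, nrow(newx), length(levels),
                    dimnames = list(NULL, levels))
    for (m in seq_along(models)) {
      p <- models[[m]]$predict(newx)
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      votes[cbind(seq_len(nrow(newx)), match(pred, levels))] <-
        votes[cbind(seq_len(nrow(newx)), match(pred, levels))] + alphas[m]
    }
    votes / pmax(rowSums(votes), 1e-12)
  })
}

# One-against-all multiclass wrapper: one binary model per class, predict
# by the largest positive-class confidence.
fit_mcc <- function(fit_inner, x, y, seed) {
  levels <- levels(y)
  seeds <- derive_seeds(seed, length(levels))
  models <- lapply(seq_along(levels), function(i) {
    yb <- factor(ifelse(y == levels[i], "yes", "other"),
                 levels = c("other", "yes"))
    fit_inner(x, yb, seeds[i])
  })
  list(predict = function(newx) {
    conf <- vapply(models, function(m) m$predict(newx)[, "yes"],
                   numeric(nrow(newx)))
    conf <- matrix(conf, nrow = nrow(newx))
    colnames(conf) <- levels
    conf / pmax(rowSums(conf), 1e-12)
  })
}

#' Fit a classifier cascade
#'
#' @param spec A [classifier_spec()]. (For `ASC` cascades run
#'   [wrapper_select()] first and fit on the reduced table; the `ASC` token
#'   itself does not alter the fit.)
#' @param table A prepared `feature_table` (balanced, standardized) with
#'   labelled instances.
#' @return A `cascade_model` with a `$predict_class(table)` method.
#' @export
fit_cascade <- function(spec, table) {
  x <- as.data.frame(table[, feature_columns(table)])
  y <- factor(table$label)
  model <- build_cascade(spec$tokens, x, y, spec, spec$seed)
  structure(list(model = model, levels = levels(y),
                 features = feature_columns(table), spec = spec),
            class = "cascade_model")
}

build_cascade <- function(tokens, x, y, spec, seed) {
  head_tok <- tokens[1]
  if (length(tokens) == 1) {
    return(fit_base(head_tok, x, y, spec, seed))
  }
  rest <- tokens[-1]
  inner <- function(xx, yy, s) build_cascade(rest, xx, yy, spec, s)
  switch(head_tok,
         MCC = fit_mcc(inner, x, y, seed),
         BAG = fit_bagging(inner, x, y, spec$bags, seed),
         AB = fit_adaboost(inner, x, y, spec$ab_iterations, seed),
         stop("unknown meta token: ", head_tok))
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %s on %d features, classes: %s\n",
              x$spec$cascade, length(x$features),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict classes with a fitted cascade
#'
#' @param object A `cascade_model`.
#' @param table Instances with the model's feature columns.
#' @return Character vector of predicted classes.
#' @export
predict_classes <- function(object, table) {
  x <- as.data.frame(table[, object$features])
  p <- object$model$predict(x)
  colnames(p)[max.col(p, ties.method = "first")]
}
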