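#' Stratified cross-validation of a cascade
#'
#' Evaluates a classifier cascade by k-fold stratified cross-validation and
#' reports per-class accuracies (class recall aggregated over folds, in %)
#' and their macro average. By default the table is expected to be prepared
#' already (SMOTE-balanced and standardized before CV, the order the staged
#' protocol uses); `balance = "fold"` instead balances and standardizes
#' inside each training fold, a leak-free alternative used when testing for
#' absence of class information.
#'
#' For an `ASC` cascade the wrapper attribute search is run once on the
#' supplied table (matching the protocol's table-level preparation order)
#' and the remaining cascade is cross-validated on the reduced table.
#'
#' @param table A `feature_table` with labelled instances.
#' @param spec A [classifier_spec()] (or cascade string).
#' @param k Number of folds (default 10).
#' @param seed Seed for folds and fits.
#' @param balance `"none"` (table already prepared) or `"fold"`.
#' @param smote_k SMOTE neighbour count for `balance = "fold"`.
#' @param group Optional grouping vector (e.g. `table$subject`): all
#'   instances of a group are assigned to the same fold. Instance-level
#'   folds (the default, as the staged protocol uses) let a subject appear
#'   on both sides of a split; group-level folds remove that dependence and
#'   are the appropriate design when testing for the absence of class
#'   information.
#' @return A `cv_result`: list with `per_class` tibble (`class`,
#'   `accuracy`), `average`, `confusion` matrix (true x predicted),
#'   `folds`, `cascade`, `variant`, `selected` (for ASC).
#' @export
cross_validate <- function(table, spec = classifier_spec("RF"), k = 10,
                           seed = 1L, balance = c("none", "fold"),
                           smote_k = 5, group = NULL) {
  balance <- match.arg(balance)
  if (is.character(spec)) spec <- classifier_spec(spec, seed = seed)
  selected <- NULL
  if (spec$asc) {
    selected <- wrapper_select(table, base_spec = strip_asc(spec),
                               seed = seed)
    table <- table[, c("subject", "ad", "label", selected)]
    class(table) <- unique(c("feature_table", class(table)))
  }
  labels <- factor(table$label)
  counts <- table(labels)
  assert_that(all(counts >= 2), "every class needs at least 2 instances")
  if (is.null(group)) {
    folds <- stratified_folds(as.character(labels), k = k, seed = seed)
  } else {
    assert_that(length(group) == nrow(table),
                "`group` must have one entry per instance")
    g <- unique(group)
    gf <- with_local_seed(seed, {
      stats::setNames(rep_len(sample(k), length(g)), sample(g))
    })
    folds <- unname(gf[group])
  }
  lev <- levels(labels)
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  predicted <- rep(NA_character_, nrow(table))
  fold_seeds <- derive_seeds(seed + 1L, k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    if (length(test_idx) == 0) next
    train <- table[-test_idx, , drop = FALSE]
    test <- table[test_idx, , drop = FALSE]
    if (balance == "fold") {
      train <- smote_balance(train, k = smote_k, seed = fold_seeds[f])
      train <- standardize_features(train)
      test <- apply_standardization(test, train)
    }
    fspec <- spec
    fspec$seed <- fold_seeds[f]
    model <- fit_cascade(fspec, train)
    pred <- predict_classes(model, test)
    predicted[test_idx] <- pred
    for (i in seq_along(test_idx)) {
      confusion[as.character(labels[test_idx[i]]), pred[i]] <-
        confusion[as.character(labels[test_idx[i]]), pred[i]] + 1L
    }
  }
  predictions <- tibble::tibble(
    subject = table$subject %||% NA_character_,
    ad = table$ad %||% NA_character_,
    true = as.character(labels), predicted = predicted, fold = folds)
  per_class <- tibble::tibble(
    class = lev,
    accuracy = 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  )
  structure(
    list(per_class = per_class, average = mean(per_class$accuracy),
         confusion = confusion, folds = folds, predictions = predictions,
         cascade = spec$cascade, selected = selected,
         variant = attr(table, "variant")),
    class = "cv_result"
  )
}

strip_asc <- function(spec) {
  classifier_spec(paste(spec$tokens, collapse = "+"), trees = spec$trees,
                  ab_iterations = spec$ab_iterations, bags = spec$bags,
                  seed = spec$seed)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s%s: average %.2f%%\n", x$cascade,
              if (is.null(x$variant)) "" else paste0(" on ", x$variant),
              x$average))
  print(x$per_class)
  invisible(x)
}

# Internal CV score (macro accuracy) used by the wrapper search.
cv_score <- function(x, y, spec, folds) {
  lev <- levels(y)
  correct <- stats::setNames(numeric(length(lev)), lev)
  total <- stats::setNames(numeric(length(lev)), lev)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- build_cascade(spec$tokens, x[tr, , drop = FALSE],
                           droplevels_keep(y[tr], y), spec,
                           spec$seed + f)
    p <- model$predict(x[!tr, , drop = FALSE])
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    truth <- as.character(y[!tr])
    for (l in lev) {
      total[l] <- total[l] + sum(truth == l)
      correct[l] <- correct[l] + sum(truth == l & pred == l)
    }
  }
  mean(correct / pmax(total, 1))
}

#' Wrapper attribute selection
#'
#' Greedy forward search scored by internal stratified cross-validation of
#' the base classifier itself (the wrapper principle: the deployed learner
#' judges every candidate subset). Starting from the empty set, the feature
#' whose addition maximizes the internal CV macro accuracy is added until no
#' addition improves the score.
#'
#' @param table A `feature_table` with labelled instances.
#' @param base_spec The classifier evaluating subsets (default RF).
#' @param seed Seed (internal folds and fits are derived from it).
#' @param nfolds Internal folds (default 5).
#' @param max_features Optional cap on the subset size.
#' @return Character vector of selected feature names (in selection order).
#' @export
wrapper_select <- function(table, base_spec = classifier_spec("RF"),
                           seed = 1L, nfolds = 5, max_features = Inf) {
  if (is.character(base_spec)) {
    base_spec <- classifier_spec(base_spec, seed = seed)
  }
  feats <- feature_columns(table)
  if (length(feats) < 2) {
    return(feats) # nothing to search over
  }
  x <- as.data.frame(table[, feats])
  y <- factor(table$label)
  folds <- stratified_folds(as.character(y), k = nfolds, seed = seed)
  selected <- character()
  best_score <- -Inf
  while (length(selected) < min(length(feats), max_features)) {
    remaining <- setdiff(feats, selected)
    scores <- vapply(remaining, function(f) {
      cv_score(x[, c(selected, f), drop = FALSE], y, base_spec, folds)
    }, numeric(1))
    top <- which.max(scores)
    if (scores[top] <= best_score + 1e-12) break
    best_score <- scores[top]
    selected <- c(selected, remaining[top])
  }
  selected
}

#' Run the three-round classification protocol
#'
#' Round 1 cross-validates each available dataset variant with the base
#' cascade set; variants whose best macro accuracy reaches the threshold
#' (default 75%) become "winners". Round 2 evaluates the stated
#' combinations of winners (GSR+HRV, plus GSR+HRV+EEG_IND /
#' GSR+HRV+EEG_ALL when those EEG variants won). Round 3 re-evaluates GSR
#' and the round-2 combinations restricted to wrapper-selected attributes,
#' with the extended cascade set including the AdaBoost cascades. The best
#' round-3 cell becomes the final model, which is then applied to the
#' unlabeled holdout ad.
#'
#' Every variant is prepared once: holdout split off, SMOTE balancing of
#' the labelled instances, then standardization (the order of the staged
#' protocol; see the methods vignette for the leakage discussion).
#'
#' @param cohort_features Named list of feature tibbles
#'   ([extract_cohort_features()] / [simulate_study()]).
#' @param seed Master seed.
#' @param cascades_round1 Cascade strings for rounds 1-2.
#' @param cascades_round3 Cascade strings for round 3.
#' @param threshold Winner threshold in percent (default 75).
#' @param k CV folds (default 10).
#' @param variants Optional subset of variant names to consider in round 1
#'   (defaults to every variant whose families are available).
#' @return A `protocol_report`.
#' @export
run_protocol <- function(cohort_features, seed = 1L,
                         cascades_round1 = c("RF", "MCC+BAG+RF", "ASC+RF"),
                         cascades_round3 = c("RF", "MCC+BAG+RF", "ASC+RF",
                                             "AB+RF", "MCC+AB+RF"),
                         threshold = 75, k = 10, variants = NULL) {
  defs <- variant_definitions()
  singles <- c("EEG_ALL", "EEG_GFP-ZSCORE", "EEG_PSD", "EEG_IND", "RSP",
               "HRV", "GSR")
  avail <- names(defs)[vapply(defs, function(f) {
    all(f %in% names(cohort_features))
  }, logical(1))]
  r1_variants <- intersect(variants %||% singles, avail)
  prepared <- list()
  prepare <- function(variant) {
    if (!is.null(prepared[[variant]])) return(prepared[[variant]])
    tab <- assemble_variant(variant, cohort_features)
    parts <- split_holdout(tab)
    bal <- smote_balance(parts$labeled, seed = seed)
    std <- standardize_features(bal)
    p <- list(table = std, holdout = parts$holdout)
    prepared[[variant]] <<- p
    p
  }

  eval_cell <- function(table, cascade, cell_seed) {
    cv <- cross_validate(table, classifier_spec(cascade, seed = cell_seed),
                         k = k, seed = cell_seed)
    tibble::tibble(cascade = cascade,
                   positive = cv$per_class$accuracy[
                     cv$per_class$class == "positive"],
                   neutral = cv$per_class$accuracy[
                     cv$per_class$class == "neutral"],
                   negative = cv$per_class$accuracy[
                     cv$per_class$class == "negative"],
                   average = cv$average,
                   selected = list(cv$selected))
  }

  run_round <- function(variant_names, cascades, tables = NULL,
                        selections = NULL, round_seed = seed) {
    rows <- list()
    for (v in variant_names) {
      tab <- if (is.null(tables)) prepare(v)$table else tables[[v]]
      for (cas in cascades) {
        cell <- eval_cell(tab, cas, round_seed)
        cell$variant <- v
        if (!is.null(selections) && !is.null(selections[[v]])) {
          cell$selected <- list(selections[[v]])
        }
        rows[[length(rows) + 1L]] <- cell
      }
    }
    out <- dplyr::bind_rows(rows)
    dplyr::relocate(out, "variant")
  }

  round1 <- run_round(r1_variants, cascades_round1)
  best1 <- round1 |>
    dplyr::group_by(.data$variant) |>
    dplyr::slice_max(.data$average, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  winners <- best1$variant[best1$average >= threshold]

  combos <- character()
  if (all(c("GSR", "HRV") %in% winners)) {
    combos <- "GSR+HRV"
    if ("EEG_ALL" %in% winners && "GSR+HRV+EEG_ALL" %in% avail) {
      combos <- c(combos, "GSR+HRV+EEG_ALL")
    }
    if ("EEG_IND" %in% winners && "GSR+HRV+EEG_IND" %in% avail) {
      combos <- c(combos, "GSR+HRV+EEG_IND")
    }
  }
  round2 <- if (length(combos) > 0) {
    run_round(combos, cascades_round1, round_seed = seed + 100L)
  } else {
    NULL
  }

  r3_variants <- intersect(c("GSR", setdiff(combos, "GSR+HRV+EEG_ALL")),
                           c(r1_variants, combos))
  sel_seeds <- derive_seeds(seed + 200L, max(length(r3_variants), 1))
  selections <- list()
  r3_tables <- list()
  for (i in seq_along(r3_variants)) {
    v <- r3_variants[i]
    tab <- prepare(v)$table
    sel <- wrapper_select(tab, seed = sel_seeds[i])
    selections[[v]] <- sel
    red <- tab[, c("subject", "ad", "label", sel)]
    attr(red, "variant") <- paste0(v, "_SEL")
    attr(red, "center") <- attr(tab, "center")[sel]
    attr(red, "scale") <- attr(tab, "scale")[sel]
    class(red) <- unique(c("feature_table", class(red)))
    r3_tables[[v]] <- red
  }
  round3 <- if (length(r3_variants) > 0) {
    run_round(r3_variants, cascades_round3, tables = r3_tables,
              selections = selections, round_seed = seed + 300L)
  } else {
    NULL
  }

  # final model: best round-3 cell (fall back to round 2, then round 1)
  pool <- round3 %||% round2 %||% round1
  final_row <- pool[which.max(pool$average), ]
  fv <- final_row$variant
  final_table <- r3_tables[[fv]] %||% prepare(fv)$table
  final_spec <- classifier_spec(final_row$cascade, seed = seed + 400L)
  if (final_spec$asc) final_spec <- strip_asc(final_spec)
  final_model <- fit_cascade(final_spec, final_table)

  holdout_raw <- prepare(fv)$holdout
  holdout_pred <- NULL
  if (nrow(holdout_raw) > 0) {
    hold <- apply_standardization(holdout_raw, prepare(fv)$table)
    holdout_pred <- predict_holdout(final_model, hold)
  }

  structure(
    list(round1 = round1, winners = winners, round2 = round2,
         round3 = round3, selections = selections,
         final = list(variant = fv, cascade = final_row$cascade,
                      average = final_row$average,
                      selected = selections[[fv]],
                      model = final_model),
         holdout = holdout_pred, seed = seed),
    class = "protocol_report"
  )
}

#' Predict the held-out ad
#'
#' Applies a trained cascade to the unlabeled instances and aggregates a
#' cohort-level majority vote (ties broken alphabetically).
#'
#' @param model A `cascade_model`.
#' @param holdout_table Standardized unlabeled instances.
#' @return List with `instances` tibble (`subject`, `ad`, `predicted`),
#'   `shares` (named vote fractions over the model's classes, summing to
#'   1), and `majority`.
#' @export
predict_holdout <- function(model, holdout_table) {
  pred <- predict_classes(model, holdout_table)
  shares <- table(factor(pred, levels = model$levels)) / length(pred)
  shares <- stats::setNames(as.numeric(shares), model$levels)
  top <- max(shares)
  majority <- sort(names(shares)[shares == top])[1]
  list(
    instances = tibble::tibble(subject = holdout_table$subject,
                               ad = holdout_table$ad, predicted = pred),
    shares = shares,
    majority = majority
  )
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("<protocol_report>\n")
  cat("Round 1 (individual datasets):\n")
  print(x$round1)
  cat("Winners (>= threshold):", paste(x$winners, collapse = ", "), "\n")
  if (!is.null(x$round2)) {
    cat("Round 2 (combinations):\n")
    print(x$round2)
  }
  if (!is.null(x$round3)) {
    cat("Round 3 (selected attributes):\n")
    print(x$round3)
  }
  cat(sprintf("Final: %s with %s (%.2f%%)\n", x$final$variant,
              x$final$cascade, x$final$average))
  if (!is.null(x$holdout)) {
    cat("Holdout majority vote:", x$holdout$majority, "\n")
  }
  invisible(x)
}
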