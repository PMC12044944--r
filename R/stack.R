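#' Compute descriptor blocks for several families
#'
#' @param smiles Standardized SMILES vector.
#' @param families Character vector of registry families (default all five).
#' @return Named list of descriptor matrices, one per family.
#' @export
featurize_blocks <- function(smiles, families = descriptor_families()$family) {
  setNames(lapply(families, function(f) compute_descriptor_block(smiles, f)),
           families)
}

base_key <- function(algorithm, family, subset) {
  paste(algorithm, family, subset, sep = ".")
}

#' Train the full stacked ensemble
#'
#' End-to-end training: the majority class is partitioned into `k` disjoint
#' balanced subsets; one base classifier is tuned (10-fold CV grid search
#' maximizing MCC) and fitted per (algorithm, descriptor block, subset)
#' triple; the probabilistic feature vector (PFV) is assembled from
#' cross-validated out-of-fold scores (inside a base model's own subset) and
#' fitted-model scores (elsewhere); features are ranked by random-forest
#' mean decrease in Gini impurity and a feature subset is selected by
#' cross-validated MCC of an SVM meta-classifier; the final SVM
#' meta-classifier is fitted on the selected columns.
#'
#' @param blocks Named list of aligned feature matrices (one per descriptor
#'   family), or a character vector of standardized SMILES (blocks are then
#'   computed for `families`).
#' @param y Binary labels aligned with rows (`"active"`/`"inactive"`,
#'   factor, logical or 0/1; positive class = active/1).
#' @param algorithms Base-learner names from [base_learners()].
#' @param k Number of balanced subsets, or `"auto"` (imbalance ratio,
#'   rounded).
#' @param tune Grid-search base hyperparameters (`FALSE` uses each grid's
#'   first row, for fast scaled-down runs).
#' @param grids Optional named list (algorithm -> data frame) overriding the
#'   default hyperparameter grids of [base_learners()].
#' @param select Run MDGI ranking + feature-subset selection (`FALSE` keeps
#'   the full PFV).
#' @param grid_m Candidate numbers of top-ranked features (default
#'   10, 20, ..., 150 truncated to the PFV width).
#' @param folds Cross-validation folds throughout (default 10).
#' @param threshold Decision threshold on the meta probability (default
#'   0.5).
#' @param families Descriptor families used when `blocks` is a SMILES
#'   vector.
#' @param seed Integer seed governing all randomness.
#' @return A `stack_model` bundling subsets, base models, the training PFV,
#'   the selection result, and the meta-classifier.
#' @export
train_stack <- function(blocks, y, algorithms = names(base_learners()),
                        k = "auto", tune = TRUE, select = TRUE,
                        grid_m = NULL, folds = 10, threshold = 0.5,
                        families = descriptor_families()$family,
                        grids = NULL, seed = 1) {
  featurizer <- NULL
  if (is.character(blocks)) {
    smiles <- blocks
    featurizer <- function(s) featurize_blocks(s, families)
    blocks <- featurizer(smiles)
  }
  assert_that(is.list(blocks) && !is.null(names(blocks)),
              "`blocks` must be a named list of matrices or a SMILES vector",
              class = "stackscreen_input_error")
  n <- nrow(blocks[[1]])
  assert_that(all(vapply(blocks, nrow, 1L) == n),
              "all blocks must have the same number of rows",
              class = "stackscreen_input_error")
  y01 <- as_binary(y, "active")
  assert_that(length(y01) == n, "labels must align with block rows",
              class = "stackscreen_input_error")

  maj_class <- as.integer(names(which.max(table(y01))))
  maj_idx <- which(y01 == maj_class)
  min_idx <- which(y01 != maj_class)
  subsets <- make_balanced_subsets(maj_idx, min_idx, k = k,
                                   seed = derive_seed(seed, "subsets"))

  base <- list()
  for (alg in algorithms) {
    for (fam in names(blocks)) {
      for (s in subsets) {
        rows <- c(s$majority_ids, s$minority_ids)
        xs <- blocks[[fam]][rows, , drop = FALSE]
        ys <- y01[rows]
        kseed <- derive_seed(seed, alg, fam, s$index)
        grid <- grids[[alg]] %||% as.data.frame(get_learner(alg)$grid(ncol(xs)))
        if (!tune) grid <- utils::head(grid, 1)
        model <- tune_base_classifier(xs, ys, alg, grid = grid,
                                      folds = folds, seed = kseed)
        oof <- oof_probability(xs, ys, alg, model$params,
                               folds = min(folds, nrow(xs)),
                               seed = kseed)
        base[[base_key(alg, fam, s$index)]] <- list(
          algorithm = alg, family = fam, subset_index = s$index,
          rows = rows, model = model, oof = oof)
      }
    }
  }

  pfv <- build_pfv(blocks, base, subsets = subsets, mode = "train")
  selection <- NULL
  if (isTRUE(select)) {
    ranking <- rank_pfs_mdgi(pfv, y01, seed = derive_seed(seed, "mdgi"))
    selection <- select_feature_subset(ranking, pfv, y01, grid = grid_m,
                                       folds = folds,
                                       seed = derive_seed(seed, "select"))
  }
  meta <- fit_meta(pfv, y01, selection = selection, threshold = threshold,
                   seed = derive_seed(seed, "meta"))
  structure(
    list(subsets = subsets, base = base, train_pfv = pfv,
         selection = selection, meta = meta,
         algorithms = algorithms, families = names(blocks),
         featurizer = featurizer, threshold = threshold,
         folds = folds, seed = seed),
    class = "stack_model")
}

#' Assemble the probabilistic feature vector matrix
#'
#' One column per (algorithm, descriptor family, subset) base model, in
#' algorithm-major order, holding that model's probability score for every
#' compound. In `"train"` mode, compounds belonging to a base model's own
#' balanced subset receive their cross-validated out-of-fold score and all
#' other compounds the fitted-model score; in `"apply"` mode every compound
#' receives the fitted-model score. Width is always
#' `algorithms x families x subsets`.
#'
#' @param blocks Named list of descriptor matrices.
#' @param base Named list of base-model entries from [train_stack()].
#' @param subsets `balanced_subsets` (required for `"train"` mode).
#' @param mode `"train"` or `"apply"`.
#' @return Numeric matrix, entries in `[0, 1]`, columns named
#'   `<algorithm>.<family>.<subset>`.
#' @export
build_pfv <- function(blocks, base, subsets = NULL,
                      mode = c("train", "apply")) {
  mode <- match.arg(mode)
  algorithms <- unique(vapply(base, function(b) b$algorithm, ""))
  fams <- unique(vapply(base, function(b) b$family, ""))
  subset_ids <- sort(unique(vapply(base, function(b) b$subset_index, 1L)))
  n <- nrow(blocks[[1]])
  keys <- character(0)
  for (alg in algorithms) for (fam in fams) for (si in subset_ids) {
    keys <- c(keys, base_key(alg, fam, si))
  }
  missing <- setdiff(keys, names(base))
  assert_that(length(missing) == 0,
              sprintf("incomplete base-model matrix; missing: %s",
                      paste(utils::head(missing, 5), collapse = ", ")),
              class = "stackscreen_incomplete_matrix")
  pfv <- matrix(NA_real_, nrow = n, ncol = length(keys),
                dimnames = list(NULL, keys))
  for (key in keys) {
    b <- base[[key]]
    assert_that(b$family %in% names(blocks),
                sprintf("block '%s' not supplied", b$family),
                class = "stackscreen_incomplete_matrix")
    scores <- predict(b$model, blocks[[b$family]])
    if (mode == "train") {
      scores[b$rows] <- b$oof
    }
    pfv[, key] <- scores
  }
  assert_that(!anyNA(pfv) && all(pfv >= 0 & pfv <= 1),
              "PFV entries must be probabilities in [0, 1]",
              class = "stackscreen_invariant_violation")
  pfv
}

#' Rank probabilistic features by mean decrease in Gini impurity
#'
#' Fits random forests on the PFV and ranks columns by their mean decrease
#' in Gini impurity (MDGI), averaged over several forest seeds to damp
#' seed sensitivity.
#'
#' @param pfv PFV matrix from [build_pfv()].
#' @param y Binary labels aligned with rows.
#' @param seed Integer seed.
#' @param n_seeds Forests averaged (default 5).
#' @param ntree Trees per forest (default 500).
#' @return Tibble (`column`, `score`) sorted by decreasing score.
#' @export
rank_pfs_mdgi <- function(pfv, y, seed = 1, n_seeds = 5, ntree = 500) {
  pfv <- as.matrix(pfv)
  y01 <- as_binary(y, "active")
  assert_that(any(apply(pfv, 2, function(col) length(unique(col)) > 1)),
              "all PFV columns are constant: degenerate input",
              class = "stackscreen_degenerate_input")
  scores <- rowMeans(vapply(seq_len(n_seeds), function(i) {
    rf <- with_seed(derive_seed(seed, "rf", i), randomForest::randomForest(
      pfv, factor(y01, levels = c(0, 1)), ntree = ntree))
    randomForest::importance(rf, type = 2)[, 1]
  }, numeric(ncol(pfv))))
  tibble(column = colnames(pfv), score = unname(scores)) |>
    arrange(desc(.data$score))
}

#' Select the best feature subset by cross-validated MCC
#'
#' For each candidate size `m`, an SVM meta-classifier is evaluated by
#' stratified cross-validation on the top-`m` MDGI-ranked columns; the `m`
#' maximizing the pooled out-of-fold MCC is chosen (smallest `m` on ties).
#'
#' @param ranking Tibble from [rank_pfs_mdgi()].
#' @param pfv Training PFV matrix.
#' @param y Binary labels.
#' @param grid Candidate sizes; default `10, 20, ..., 150` truncated to the
#'   PFV width (with a warning when truncation occurs).
#' @param folds CV folds (default 10).
#' @param seed Integer seed (independent of base-model folds).
#' @return A `selection_result`: `ranking`, `grid`, `cv_mcc` (tibble `m`,
#'   `mcc`), `chosen_m`, `chosen_columns`.
#' @export
select_feature_subset <- function(ranking, pfv, y, grid = NULL, folds = 10,
                                  seed = 1) {
  pfv <- as.matrix(pfv)
  y01 <- as_binary(y, "active")
  width <- ncol(pfv)
  if (is.null(grid)) {
    grid <- seq(10, 150, by = 10)
    if (any(grid > width)) grid <- grid[grid <= width]
    if (length(grid) == 0) grid <- width
  } else {
    assert_that(length(grid) > 0, "empty candidate grid",
                class = "stackscreen_config_error")
    if (any(grid > width)) {
      warn("candidate sizes exceeding the PFV width were dropped")
      grid <- grid[grid <= width]
      assert_that(length(grid) > 0, "no feasible candidate sizes",
                  class = "stackscreen_config_error")
    }
  }
  grid <- sort(unique(as.integer(grid)))
  mcc <- vapply(grid, function(m) {
    cols <- ranking$column[seq_len(m)]
    cv <- cross_validate(
      pfv[, cols, drop = FALSE], y01,
      fit = function(xt, yt) fit_meta_svm(xt, yt, derive_seed(seed, "m", m)),
      predict_prob = predict_meta_svm,
      folds = folds, seed = derive_seed(seed, "selfolds"))
    cv$pooled$mcc
  }, numeric(1))
  chosen_m <- grid[which.max(mcc)]  # which.max takes the first = smallest m
  structure(
    list(ranking = ranking, grid = grid,
         cv_mcc = tibble(m = grid, mcc = mcc),
         chosen_m = chosen_m,
         chosen_columns = ranking$column[seq_len(chosen_m)]),
    class = "selection_result")
}

fit_meta_svm <- function(x, y01, seed) {
  with_seed(seed, suppressWarnings(e1071::svm(
    x, factor(y01, levels = c(0, 1)), kernel = "radial",
    probability = TRUE)))
}

predict_meta_svm <- function(model, x) {
  pr <- suppressWarnings(predict(model, x, probability = TRUE))
  unname(attr(pr, "probabilities")[, "1"])
}

#' Fit the SVM meta-classifier
#'
#' Trains the radial-kernel SVM meta-classifier (with Platt-style
#' probability outputs) on the selected PFV columns, or on the full PFV
#' when no selection is supplied.
#'
#' @param pfv Training PFV matrix.
#' @param y Binary labels.
#' @param selection Optional `selection_result` computed on the same PFV.
#' @param threshold Decision threshold (in (0, 1), default 0.5).
#' @param seed Integer seed.
#' @return A `meta_model`: `fit`, `columns`, `threshold`.
#' @export
fit_meta <- function(pfv, y, selection = NULL, threshold = 0.5, seed = 1) {
  pfv <- as.matrix(pfv)
  assert_that(threshold > 0 && threshold < 1,
              "threshold must lie in (0, 1)",
              class = "stackscreen_config_error")
  y01 <- as_binary(y, "active")
  columns <- colnames(pfv)
  if (!is.null(selection)) {
    assert_that(all(selection$chosen_columns %in% colnames(pfv)),
                "selection columns not present in PFV: integrity error",
                class = "stackscreen_integrity_error")
    columns <- selection$chosen_columns
  }
  fit <- fit_meta_svm(pfv[, columns, drop = FALSE], y01, seed)
  structure(list(fit = fit, columns = columns, threshold = threshold),
            class = "meta_model")
}

#' Predict with a stacked model
#'
#' Runs the full pipeline on new compounds: featurization (for SMILES
#' input), apply-mode PFV from all base models, column selection, and the
#' meta-classifier probability. Unparsable SMILES yield `NA` rows and the
#' batch continues.
#'
#' @param object A `stack_model`.
#' @param newdata Character vector of SMILES (requires the model to have
#'   been trained from SMILES) or a named list of descriptor matrices.
#' @param ... Unused.
#' @return Tibble with `probability` and `label`
#'   (`"active"`/`"inactive"`), plus `smiles` and `parse_error` for SMILES
#'   input.
#' @export
predict.stack_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    assert_that(!is.null(object$featurizer),
                "model was trained on precomputed blocks; supply matrices",
                class = "stackscreen_input_error")
    std <- standardize_structure(newdata, on_error = "na")
    ok <- !is.na(std)
    out <- tibble(smiles = newdata, probability = NA_real_,
                  label = NA_character_, parse_error = !ok)
    if (any(ok)) {
      blocks <- object$featurizer(std[ok])
      res <- predict_stack_blocks(object, blocks)
      out$probability[ok] <- res$probability
      out$label[ok] <- res$label
    }
    return(out)
  }
  predict_stack_blocks(object, newdata)
}

predict_stack_blocks <- function(object, blocks) {
  pfv <- build_pfv(blocks, object$base, mode = "apply")
  prob <- predict_meta_svm(object$meta$fit,
                           pfv[, object$meta$columns, drop = FALSE])
  tibble(probability = prob,
         label = ifelse(prob >= object$meta$threshold, "active", "inactive"))
}

#' Rank a compound library by predicted activity
#'
#' Scores every library compound with the stacked model and returns the
#' `top_n` highest-probability compounds (ties keep input order; unparsable
#' SMILES rank last with `NA` probability).
#'
#' @param object A `stack_model`.
#' @param smiles Library SMILES vector.
#' @param top_n Number of top-ranked rows to return (default 30); a value
#'   larger than the library returns the full ranking with a warning.
#' @return Tibble (`rank`, `position`, `smiles`, `probability`, `label`).
#' @export
screen_library <- function(object, smiles, top_n = 30) {
  pred <- predict(object, smiles)
  ranked <- pred |>
    mutate(position = row_number()) |>
    arrange(desc(.data$probability), .data$position) |>
    mutate(rank = row_number())
  if (top_n > nrow(ranked)) {
    warn("top_n exceeds library size; returning the full ranking")
    top_n <- nrow(ranked)
  }
  ranked[seq_len(top_n), c("rank", "position", "smiles", "probability",
                           "label")]
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf(
    "Stacked ensemble: %d base models (%d algorithms x %d blocks x %d subsets)\n",
    length(x$base), length(x$algorithms), length(x$families),
    length(x$subsets)))
  if (!is.null(x$selection)) {
    cat(sprintf("Meta-classifier: SVM on %d of %d PFV columns (CV MCC %.3f)\n",
                x$selection$chosen_m, ncol(x$train_pfv),
                max(x$selection$cv_mcc$mcc)))
  } else {
    cat(sprintf("Meta-classifier: SVM on the full %d-column PFV\n",
                ncol(x$train_pfv)))
  }
  invisible(x)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection: chose m = %d from {%s} (CV MCC %.3f)\n",
              x$chosen_m, paste(x$grid, collapse = ", "),
              max(x$cv_mcc$mcc)))
  invisible(x)
}
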