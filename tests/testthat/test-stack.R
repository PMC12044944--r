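# Small synthetic feature configurations keep these tests fast; the
# full-scale structural constants live in the acceptance suite.

make_split_data <- function(seed, n_pos = 200, n_neg = 40, p = 40,
                            informative = 8, effect = 0.55) {
  fd <- generate_feature_dataset(n_pos, n_neg, p, informative, effect,
                                 seed = seed)
  idx <- with(fd, {
    pos <- which(y == "active"); neg <- which(y == "inactive")
    test <- c(pos[seq_len(round(0.25 * length(pos)))],
              neg[seq_len(round(0.25 * length(neg)))])
    list(train = setdiff(seq_along(y), test), test = test)
  })
  list(fd = fd, train = idx$train, test = idx$test)
}

test_that("base classifiers tune by CV MCC and emit probabilities", {
  fd <- generate_feature_dataset(60, 60, 10, 6, 0.7, seed = 14)
  # linearly separable-ish toy: RF reaches near-perfect CV MCC
  m <- tune_base_classifier(fd$x, fd$y, "RF", folds = 5, seed = 1)
  expect_s3_class(m, "base_model")
  expect_gt(m$cv_mcc, 0.5)
  p <- predict(m, fd$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[fd$y == "active"]), mean(p[fd$y == "inactive"]))
  expect_error(tune_base_classifier(fd$x, fd$y, "RF", grid = data.frame()),
               class = "stackscreen_config_error")
  expect_error(tune_base_classifier(fd$x, fd$y, "nope"),
               class = "stackscreen_config_error")
})

test_that("every learner in the registry fits and predicts in range", {
  fd <- generate_feature_dataset(40, 40, 12, 6, 0.6, seed = 9)
  for (alg in names(base_learners())) {
    grid <- utils::head(as.data.frame(base_learners()[[alg]]$grid(ncol(fd$x))), 1)
    if (alg == "XGB") grid$nrounds <- 40
    if (alg == "RF") grid$ntree <- 100
    m <- tune_base_classifier(fd$x, fd$y, alg, grid = grid, folds = 5,
                              seed = 3)
    p <- predict(m, fd$x)
    expect_length(p, 80)
    expect_true(all(p >= 0 & p <= 1), label = paste(alg, "probability range"))
  }
})

test_that("out-of-fold probabilities are reproducible and informative", {
  fd <- generate_feature_dataset(50, 50, 15, 8, 0.6, seed = 4)
  oof <- oof_probability(fd$x, fd$y, "RF", list(mtry = 3, ntree = 150),
                         folds = 10, seed = 5)
  oof2 <- oof_probability(fd$x, fd$y, "RF", list(mtry = 3, ntree = 150),
                          folds = 10, seed = 5)
  expect_identical(oof, oof2)
  expect_true(all(oof >= 0 & oof <= 1))
  expect_gt(mean(oof[fd$y == "active"]), mean(oof[fd$y == "inactive"]))
  expect_error(oof_probability(fd$x[1:9, ], fd$y[1:9], "RF",
                               list(mtry = 3), folds = 10),
               class = "stackscreen_fold_error")
})

test_that("PFV width is algorithms x blocks x subsets for any configuration", {
  set.seed(60)
  for (i in 1:3) {
    a <- sample(1:3, 1); d <- sample(1:3, 1); k <- sample(1:4, 1)
    n_min <- 12; n_maj <- n_min * k
    fd <- generate_feature_dataset(n_maj, n_min, 10 * d, 4, 0.5,
                                   seed = 100 + i)
    blocks <- setNames(lapply(seq_len(d), function(j)
      fd$x[, ((j - 1) * 10 + 1):(j * 10), drop = FALSE]),
      paste0("blk", seq_len(d)))
    m <- train_stack(blocks, fd$y,
                     algorithms = c("KNN", "RF", "XGB")[seq_len(a)],
                     k = k, tune = FALSE, select = FALSE, folds = 3,
                     seed = 7)
    expect_equal(ncol(m$train_pfv), a * d * k)
    expect_true(all(m$train_pfv >= 0 & m$train_pfv <= 1))
    expect_false(anyNA(m$train_pfv))
    # column keys enumerate the full cartesian product
    expect_equal(length(unique(colnames(m$train_pfv))), a * d * k)
  }
})

test_that("build_pfv flags missing base models by key", {
  fd <- generate_feature_dataset(24, 12, 10, 4, 0.5, seed = 2)
  blocks <- list(blk1 = fd$x)
  m <- train_stack(blocks, fd$y, algorithms = c("KNN", "RF"), k = 2,
                   tune = FALSE, select = FALSE, folds = 3, seed = 1)
  base <- m$base
  broken <- base[-1]
  expect_error(build_pfv(blocks, broken, mode = "apply"),
               regexp = names(base)[1],
               class = "stackscreen_incomplete_matrix")
})

test_that("MDGI ranking surfaces a perfectly predictive column", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80
    y <- rep(c(1, 0), each = n / 2)
    pfv <- matrix(runif(n * 12), n, 12,
                  dimnames = list(NULL, paste0("c", 1:12)))
    pfv[, 7] <- y * 0.45 + 0.25 + runif(n, 0, 0.05)  # clean signal column
    rk <- rank_pfs_mdgi(pfv, y, seed = seed, n_seeds = 3, ntree = 200)
    if (rk$column[1] == "c7") hits <- hits + 1L
  }
  expect_gte(hits, 9)
  expect_error(rank_pfs_mdgi(matrix(0.5, 10, 3), rep(c(0, 1), 5)),
               class = "stackscreen_degenerate_input")
})

test_that("duplicated informative columns share the importance mass", {
  set.seed(42)
  n <- 100
  y <- rep(c(1, 0), each = n / 2)
  base_col <- y * 0.4 + 0.3 + runif(n, 0, 0.05)
  noise <- matrix(runif(n * 8), n, 8)
  single <- cbind(noise, sig = base_col)
  colnames(single) <- c(paste0("n", 1:8), "sig")
  dup <- cbind(noise, sig1 = base_col, sig2 = base_col)
  colnames(dup) <- c(paste0("n", 1:8), "sig1", "sig2")
  rk_s <- rank_pfs_mdgi(single, y, seed = 1, n_seeds = 5, ntree = 300)
  rk_d <- rank_pfs_mdgi(dup, y, seed = 1, n_seeds = 5, ntree = 300)
  expect_setequal(rk_d$column[1:2], c("sig1", "sig2"))
  combined <- sum(rk_d$score[rk_d$column %in% c("sig1", "sig2")])
  single_mass <- rk_s$score[rk_s$column == "sig"]
  expect_equal(combined, single_mass, tolerance = 0.35)
})

test_that("feature-subset selection maximizes CV MCC, ties to smallest m", {
  fd <- generate_feature_dataset(60, 60, 20, 10, 0.6, seed = 8)
  rk <- rank_pfs_mdgi(fd$x, fd$y, seed = 1, n_seeds = 2, ntree = 150)
  sel <- select_feature_subset(rk, fd$x, fd$y, grid = c(5, 10, 20),
                               folds = 5, seed = 2)
  expect_true(sel$chosen_m %in% c(5, 10, 20))
  expect_equal(sel$cv_mcc$mcc[sel$cv_mcc$m == sel$chosen_m],
               max(sel$cv_mcc$mcc))
  expect_length(sel$chosen_columns, sel$chosen_m)
  sel1 <- select_feature_subset(rk, fd$x, fd$y, grid = 10, folds = 5)
  expect_equal(sel1$chosen_m, 10L)
  expect_warning(
    selw <- select_feature_subset(rk, fd$x, fd$y, grid = c(10, 50), folds = 5),
    regexp = "width")
  expect_equal(selw$grid, 10L)
  expect_error(select_feature_subset(rk, fd$x, fd$y, grid = integer(0)),
               class = "stackscreen_config_error")
})

test_that("tie-breaking picks the smallest m when CV MCC is equal", {
  # a PFV with one perfect column: every m achieves MCC 1, so m = 5 wins
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  pfv <- matrix(runif(n * 20), n, 20,
                dimnames = list(NULL, paste0("c", 1:20)))
  pfv[, 1] <- ifelse(y == 1, 0.95, 0.05)
  rk <- rank_pfs_mdgi(pfv, y, seed = 3, n_seeds = 2, ntree = 100)
  sel <- select_feature_subset(rk, pfv, y, grid = c(5, 10), folds = 5,
                               seed = 4)
  if (abs(diff(sel$cv_mcc$mcc)) < 1e-12) expect_equal(sel$chosen_m, 5L)
  expect_lte(sel$cv_mcc$mcc[1], 1)
})

test_that("meta-classifier integrity and end-to-end prediction", {
  d <- make_split_data(19)
  blocks_tr <- list(b1 = d$fd$x[d$train, 1:20], b2 = d$fd$x[d$train, 21:40])
  m <- train_stack(blocks_tr, d$fd$y[d$train], algorithms = c("KNN", "RF"),
                   k = "auto", tune = FALSE, select = TRUE,
                   grid_m = c(5, 10), folds = 5, seed = 3)
  expect_s3_class(m, "stack_model")
  # meta predicts with exactly the chosen columns
  expect_length(m$meta$columns, m$selection$chosen_m)
  blocks_te <- list(b1 = d$fd$x[d$test, 1:20], b2 = d$fd$x[d$test, 21:40])
  pred <- predict(m, blocks_te)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  rep <- classification_report(d$fd$y[d$test] == "active", pred$probability)
  expect_gt(rep$auc, 0.5)
  # integrity: selection from a different PFV is rejected
  other <- m$selection
  other$chosen_columns <- c("ghost.col.1")
  expect_error(fit_meta(m$train_pfv, d$fd$y[d$train], other),
               class = "stackscreen_integrity_error")
  # determinism of refit
  m2 <- train_stack(blocks_tr, d$fd$y[d$train], algorithms = c("KNN", "RF"),
                    k = "auto", tune = FALSE, select = TRUE,
                    grid_m = c(5, 10), folds = 5, seed = 3)
  expect_identical(predict(m2, blocks_te)$probability, pred$probability)
})

test_that("screening ranks by probability with stable tie order", {
  ds <- generate_smiles_dataset(synthetic_spec(n_active = 40, n_inactive = 20,
                                               label_noise = 0, seed = 17))
  m <- train_stack(ds$canonical_smiles, ds$label, algorithms = "RF",
                   k = "auto", tune = FALSE, select = FALSE, folds = 5,
                   families = "MACCS", seed = 5)
  lib <- c(ds$canonical_smiles[1:6], ds$canonical_smiles[1])
  scr <- screen_library(m, lib, top_n = 7)
  expect_equal(nrow(scr), 7)
  expect_true(all(diff(scr$probability) <= 0))
  # duplicate compound scores identically and ranks adjacently
  dup_rows <- scr[scr$smiles == lib[1], ]
  expect_equal(length(unique(dup_rows$probability)), 1)
  expect_equal(diff(sort(dup_rows$rank)), 1)
  expect_warning(full <- screen_library(m, lib[1:3], top_n = 10))
  expect_equal(nrow(full), 3)
  # full-library screen is a permutation of the inputs
  all_scr <- screen_library(m, lib, top_n = 7)
  expect_setequal(all_scr$position, 1:7)
})

test_that("predictions survive unparsable SMILES and repeat batches", {
  ds <- generate_smiles_dataset(synthetic_spec(n_active = 30, n_inactive = 15,
                                               label_noise = 0, seed = 27))
  m <- train_stack(ds$canonical_smiles, ds$label, algorithms = "KNN",
                   k = "auto", tune = FALSE, select = FALSE, folds = 5,
                   families = "MACCS", seed = 2)
  batch <- c(ds$canonical_smiles[1], "xxxx", ds$canonical_smiles[1])
  pred <- predict(m, batch)
  expect_true(pred$parse_error[2])
  expect_true(is.na(pred$probability[2]))
  expect_equal(pred$probability[1], pred$probability[3])
  expect_true(all(stats::na.omit(pred$probability) >= 0 &
                    stats::na.omit(pred$probability) <= 1))
})
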