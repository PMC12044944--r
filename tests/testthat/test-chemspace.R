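test_that("rule flags use strict inequalities exactly", {
  p <- tibble::tibble(
    mw = c(300, 500, 480), alogp = c(2, 2, 5), hba = c(4, 4, 4),
    hbd = c(1, 1, 1), tpsa = c(100, 100, 139.9), nrotb = c(3, 3, 10))
  f <- rule_flags(p)
  expect_true(f$ro5_pass[1])
  expect_false(f$ro5_pass[2])   # mw == 500 fails the strict rule
  expect_false(f$ro5_pass[3])   # alogp == 5 fails
  expect_true(f$veber_pass[1])
  expect_false(f$veber_pass[3]) # nrotb == 10 fails
})

test_that("Mann-Whitney U: symmetry identity and exact enumeration", {
  a <- c(1, 2); b <- c(3, 4)
  mw <- mann_whitney(a, b)
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 2 / 6)  # {0,4} of the 6 equally likely U values
  expect_equal(mann_whitney(b, a)$u, 4)
  # U_A + U_B = nA * nB
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    expect_equal(mann_whitney(x, y)$u + mann_whitney(y, x)$u,
                 length(x) * length(y))
  }
  ident <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ident$u, 4.5)  # nA*nB/2 under identical multisets
  expect_error(mann_whitney(numeric(0), 1),
               class = "stackscreen_input_error")
})

test_that("exact enumeration agrees with wilcox.test and the approximation", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)   # tie-free: wilcox exact is valid oracle
    mw <- mann_whitney(x, y)
    wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mw$u, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)
  }
  # approximation close to enumeration at the regime boundary
  x <- rnorm(8, 0.8); y <- rnorm(12)
  exact <- mann_whitney(x, y)
  expect_equal(exact$method, "exact enumeration")
  approx <- mann_whitney(c(x, 1e-9), y)  # 9 obs switches to approximation
  expect_equal(approx$method, "normal approximation")
  expect_lt(abs(exact$p_value - approx$p_value), 0.05)
})

test_that("scaffold uniqueness is a set difference, duplicate-invariant", {
  train <- c("Cc1ccccc1", "CCc1ccccc1", "c1ccc2ccccc2c1")
  expect_equal(scaffold_uniqueness(train, c("c1ccccc1", "Cc1ccccc1")), 0)
  expect_equal(scaffold_uniqueness(train, c("C1CCCCC1", "c1ccncc1")), 1)
  test4 <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccoc1")
  expect_equal(scaffold_uniqueness(train, test4), 0.75)
  expect_equal(scaffold_uniqueness(train, rep(test4, 3)),
               scaffold_uniqueness(rep(train, 2), test4))
  expect_error(scaffold_uniqueness(train, character(0)),
               class = "stackscreen_input_error")
})

test_that("tanimoto audit matches the brute-force pair loop", {
  train <- c("Cc1ccccc1", "CCO", "c1ccc2ccccc2c1")
  test <- c("CCc1ccccc1", "CCCO")
  aud <- tanimoto_audit(train, test)
  expect_equal(dim(aud$matrix), c(3, 2))
  fps_tr <- ecfp4(train); fps_te <- ecfp4(test)
  for (i in 1:3) for (j in 1:2) {
    expect_equal(aud$matrix[i, j], tanimoto(fps_tr[i, ], fps_te[j, ]))
  }
  expect_equal(aud$below_threshold_fraction, mean(aud$matrix < 0.5))
  expect_true(aud$mean >= 0 && aud$mean <= 1)
  # identical sets put 1.0 on the diagonal
  self <- tanimoto_audit(train, train)
  expect_equal(diag(self$matrix), rep(1, 3))
})

test_that("chemspace report composes property stats, rules and audits", {
  ds <- generate_smiles_dataset(synthetic_spec(n_active = 30, n_inactive = 15,
                                               label_noise = 0, seed = 6))
  sp <- split_train_test(ds, 0.75, seed = 1)
  rep <- chem_space_report(ds, split = sp)
  expect_setequal(rep$properties$property,
                  c("mw", "alogp", "hba", "hbd", "tpsa", "nrotb"))
  expect_true(all(rep$properties$p_value > 0 & rep$properties$p_value <= 1))
  expect_true(all(rep$rules$ro5_pass_fraction >= 0 &
                    rep$rules$ro5_pass_fraction <= 1))
  expect_true(rep$scaffold_unique_fraction >= 0 &&
                rep$scaffold_unique_fraction <= 1)
  expect_equal(rep$tanimoto_below_half_fraction +
                 mean(tanimoto_audit(sp$train$canonical_smiles,
                                     sp$test$canonical_smiles)$matrix >= 0.5),
               1)
})
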