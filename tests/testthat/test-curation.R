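test_that("pIC50 conversion matches the molar log scale and is decreasing", {
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(1), 9)
  expect_equal(to_pic50(50), 7.3010, tolerance = 1e-4)
  v <- sort(runif(20, 0.1, 1e5))
  expect_true(all(diff(to_pic50(v)) < 0))
  expect_error(to_pic50(-1), class = "stackscreen_domain_error")
  expect_error(to_pic50(0), class = "stackscreen_domain_error")
})

test_that("activity labelling respects both cutoffs and rejects inversion", {
  expect_equal(label_activity(c(7, 4, 5.5), 6, 5),
               c("active", "inactive", "intermediate"))
  expect_equal(label_activity(6, 6, 5), "active")  # boundary is active
  expect_error(label_activity(5, 4, 6), class = "stackscreen_config_error")
})

test_that("parsing retains '=' rows only and audits every drop", {
  path <- write_toy_activity_csv()
  rec <- parse_activity_table(path)
  audit <- attr(rec, "audit")
  # 8 rows: 3 non-'=' relations, 1 missing value, 1 unparsable SMILES
  expect_equal(nrow(rec) + nrow(audit), 8)
  expect_equal(sum(audit$reason == "relation"), 3)
  expect_equal(sum(audit$reason == "missing value"), 1)
  expect_equal(sum(audit$reason == "unparsable smiles"), 1)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$relation == "="))
  expect_false(is.unsorted(match(rec$compound_id, paste0("CHEMBL", 1:8))))
})

test_that("parsing converts units and reports missing columns by name", {
  rows <- data.frame(
    `Molecule ChEMBL ID` = c("A", "B"), Smiles = c("CCO", "CCN"),
    `Standard Relation` = "=", `Standard Value` = c(1, 1000),
    `Standard Units` = c("uM", "nM"), check.names = FALSE)
  rec <- parse_activity_table(write_toy_activity_csv(rows = rows))
  expect_equal(rec$standard_value, c(1000, 1000))
  expect_equal(rec$pic50, c(6, 6))

  bad <- rows[, setdiff(names(rows), "Smiles")]
  expect_error(parse_activity_table(write_toy_activity_csv(rows = bad)),
               regexp = "Smiles", class = "stackscreen_config_error")
  empty <- rows[0, ]
  expect_error(parse_activity_table(write_toy_activity_csv(rows = empty)),
               class = "stackscreen_empty_input")
})

test_that("curation merges duplicate structures at the median pIC50", {
  rec <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    smiles = c("C1=CC=CC=C1O", "Oc1ccccc1", "c1ccccc1O", "CCO"),
    pic50 = c(6.9, 7.0, 7.3, 4.0))
  ds <- curate_dataset(rec)
  expect_equal(nrow(ds), 2)
  merged <- ds[ds$label == "active", ]
  expect_equal(merged$pic50, 7.0)  # median of the three phenol records
  expect_equal(attr(ds, "n_active"), 1)
  expect_equal(attr(ds, "n_inactive"), 1)
})

test_that("intermediates are excluded from counts and curation is idempotent", {
  rec <- tibble::tibble(
    compound_id = letters[1:10],
    smiles = c("CCO", "CCN", "CCC", "CCCC", "CCCCC", "c1ccccc1",
               "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1"),
    pic50 = c(7, 8, 6.5, 9, 4, 4.5, 5.5, 5.2, 7.7, 3.9))
  ds <- curate_dataset(rec)
  expect_equal(attr(ds, "n_active") + attr(ds, "n_inactive"), 8)
  ds2 <- curate_dataset(ds)
  expect_equal(as.data.frame(ds2[order(ds2$compound_id), ]),
               as.data.frame(ds[order(ds$compound_id), ]))
  all_mid <- tibble::tibble(compound_id = "x", smiles = "CCO", pic50 = 5.5)
  expect_error(curate_dataset(all_mid), class = "stackscreen_empty_dataset")
})

test_that("stratified split conserves classes and is seed-deterministic", {
  ds <- tibble::tibble(
    compound_id = paste0("c", 1:120),
    canonical_smiles = paste0("C", 1:120),
    pic50 = c(rep(7, 100), rep(4, 20)),
    label = c(rep("active", 100), rep("inactive", 20)))
  sp <- split_train_test(ds, 0.75, seed = 42)
  expect_equal(sum(sp$train$label == "active"), 75)
  expect_equal(sum(sp$train$label == "inactive"), 15)
  expect_equal(nrow(sp$test), 30)
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)
  expect_setequal(c(sp$train$compound_id, sp$test$compound_id),
                  ds$compound_id)
  sp2 <- split_train_test(ds, 0.75, seed = 42)
  expect_identical(sp$train$compound_id, sp2$train$compound_id)

  small <- ds[c(1:7, 101:103), ]
  sp3 <- split_train_test(small, 0.75, seed = 1)
  expect_true(sum(sp3$train$label == "active") %in% 5:6)
  expect_true(sum(sp3$train$label == "inactive") %in% 2:3)
  expect_equal(nrow(sp3$train) + nrow(sp3$test), 10)

  one_class <- ds[1:5, ]
  expect_error(split_train_test(one_class),
               class = "stackscreen_stratification_error")
})

test_that("split conservation holds across seeds", {
  ds <- tibble::tibble(
    compound_id = paste0("c", 1:40),
    canonical_smiles = paste0("C", 1:40),
    pic50 = c(rep(7, 30), rep(4, 10)),
    label = c(rep("active", 30), rep("inactive", 10)))
  for (seed in 1:10) {
    sp <- split_train_test(ds, 0.75, seed = seed)
    expect_setequal(c(sp$train$compound_id, sp$test$compound_id),
                    ds$compound_id)
    expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)
  }
})
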