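#' Lipinski and Veber rule flags
#'
#' Applies the oral-bioavailability heuristics with strict inequalities:
#' Rule of Five passes when AlogP < 5, MW < 500 Da, HBD < 5 and HBA < 10;
#' the Veber rule passes when nRotB < 10 and TPSA < 140 A^2. Boundary
#' values (e.g. MW exactly 500) fail.
#'
#' @param physchem Tibble from [compute_physchem()] (columns `mw`, `alogp`,
#'   `hba`, `hbd`, `tpsa`, `nrotb`).
#' @return The input with logical columns `ro5_pass` and `veber_pass`
#'   appended.
#' @export
rule_flags <- function(physchem) {
  physchem |>
    mutate(
      ro5_pass = .data$alogp < 5 & .data$mw < 500 & .data$hbd < 5 &
        .data$hba < 10,
      veber_pass = .data$nrotb < 10 & .data$tpsa < 140
    )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank tie handling. For
#' `min(nA, nB) <= 8` the p-value comes from full enumeration of all
#' group-label arrangements (exact even under ties); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples.
#' @return A list with `u` (U statistic of group `a`), `p_value`
#'   (two-sided), and `method`.
#' @export
mann_whitney <- function(a, b) {
  assert_that(length(a) > 0 && length(b) > 0, "both groups must be non-empty",
              class = "stackscreen_input_error")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (min(n_a, n_b) <= 8 && choose(n_a + n_b, n_a) <= 5e5) {
    combos <- combn(n_a + n_b, n_a)
    u_null <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
    mu <- n_a * n_b / 2
    p <- mean(abs(u_null - mu) >= abs(u_a - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n_a + n_b) * (n_a + n_b - 1))
    sigma <- sqrt(n_a * n_b / 12 * ((n_a + n_b + 1) - tie_term))
    z <- (abs(u_a - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(u = u_a, p_value = p, method = method)
}

#' Scaffold uniqueness of a test set relative to a training set
#'
#' Fraction of distinct Bemis-Murcko scaffold keys in the test set that do
#' not occur among the training-set scaffold keys. Duplicate molecules
#' within either split do not change the result.
#'
#' @param train_smiles,test_smiles Standardized SMILES vectors.
#' @return Fraction in `[0, 1]`.
#' @export
scaffold_uniqueness <- function(train_smiles, test_smiles) {
  assert_that(length(test_smiles) > 0, "empty test set",
              class = "stackscreen_input_error")
  assert_that(length(train_smiles) > 0, "empty training set",
              class = "stackscreen_input_error")
  train_keys <- unique(murcko_scaffold(train_smiles)$scaffold)
  test_keys <- unique(murcko_scaffold(test_smiles)$scaffold)
  mean(!test_keys %in% train_keys)
}

#' Tanimoto similarity audit between two compound sets
#'
#' Scores every train x test pair with the Tanimoto coefficient on
#' ECFP4-style fingerprints and summarizes the similarity landscape.
#'
#' @param train_smiles,test_smiles Standardized SMILES vectors.
#' @param threshold Dissimilarity cutoff for the reported fraction
#'   (default 0.5).
#' @param n_bits Fingerprint width (default 2048).
#' @return A list: `mean` similarity over all pairs, `below_threshold_fraction`
#'   (pairs with similarity < `threshold`), and the train x test `matrix`.
#' @export
tanimoto_audit <- function(train_smiles, test_smiles, threshold = 0.5,
                           n_bits = 2048) {
  assert_that(length(train_smiles) > 0 && length(test_smiles) > 0,
              "both compound sets must be non-empty",
              class = "stackscreen_input_error")
  fp_a <- ecfp4(train_smiles, n_bits) > 0
  fp_b <- ecfp4(test_smiles, n_bits) > 0
  inter <- fp_a %*% t(fp_b)
  pop_a <- rowSums(fp_a)
  pop_b <- rowSums(fp_b)
  uni <- outer(pop_a, pop_b, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  list(mean = mean(sim),
       below_threshold_fraction = mean(sim < threshold),
       matrix = sim)
}

#' Chemical-space diagnostics report
#'
#' Class-wise physicochemical summaries with Mann-Whitney comparisons,
#' Ro5/Veber pass fractions per class, and (when a train/test split is
#' given) the scaffold-uniqueness fraction and Tanimoto audit between the
#' partitions.
#'
#' @param data Curated tibble with `canonical_smiles` and `label` columns.
#' @param split Optional list with `train`/`test` curated tibbles (from
#'   [split_train_test()]).
#' @param tanimoto_threshold Dissimilarity cutoff for the audit.
#' @return A list of class `chemspace_report`: `properties` (per-property,
#'   per-class median/IQR/range plus `u` and `p_value`), `rules`
#'   (per-class Ro5/Veber pass fractions), and optionally
#'   `scaffold_unique_fraction`, `tanimoto_mean`,
#'   `tanimoto_below_half_fraction`.
#' @export
chem_space_report <- function(data, split = NULL, tanimoto_threshold = 0.5) {
  labelled <- data[data$label %in% c("active", "inactive"), ]
  props <- rule_flags(compute_physchem(labelled$canonical_smiles))
  props$label <- labelled$label
  prop_names <- c("mw", "alogp", "hba", "hbd", "tpsa", "nrotb")
  properties <- purrr::map_dfr(prop_names, function(p) {
    va <- props[[p]][props$label == "active"]
    vi <- props[[p]][props$label == "inactive"]
    mw <- mann_whitney(va, vi)
    tibble(property = p,
           median_active = median(va), iqr_active = stats::IQR(va),
           min_active = min(va), max_active = max(va),
           median_inactive = median(vi), iqr_inactive = stats::IQR(vi),
           min_inactive = min(vi), max_inactive = max(vi),
           u = mw$u, p_value = mw$p_value)
  })
  rules <- props |>
    group_by(.data$label) |>
    summarise(ro5_pass_fraction = mean(.data$ro5_pass),
              veber_pass_fraction = mean(.data$veber_pass),
              .groups = "drop")
  out <- list(properties = properties, rules = rules, physchem = props)
  if (!is.null(split)) {
    out$scaffold_unique_fraction <- scaffold_uniqueness(
      split$train$canonical_smiles, split$test$canonical_smiles)
    aud <- tanimoto_audit(split$train$canonical_smiles,
                          split$test$canonical_smiles,
                          threshold = tanimoto_threshold)
    out$tanimoto_mean <- aud$mean
    out$tanimoto_below_half_fraction <- aud$below_threshold_fraction
  }
  structure(out, class = "chemspace_report")
}

#' @export
print.chemspace_report <- function(x, ...) {
  cat("Chemical-space report\n")
  print(x$properties[, c("property", "median_active", "median_inactive",
                         "u", "p_value")])
  print(x$rules)
  if (!is.null(x$scaffold_unique_fraction)) {
    cat(sprintf("Scaffold uniqueness (test vs train): %.1f%%\n",
                100 * x$scaffold_unique_fraction))
    cat(sprintf("Tanimoto: mean %.3f, %.1f%% of pairs < 0.5\n",
                x$tanimoto_mean, 100 * x$tanimoto_below_half_fraction))
  }
  invisible(x)
}
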