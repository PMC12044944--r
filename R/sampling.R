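#' Disjoint balanced training subsets by majority-class under-sampling
#'
#' Partitions the majority class into `k` disjoint, near-equal slices (after
#' one seeded shuffle) and pairs every slice with the full minority class.
#' Each subset is therefore approximately balanced while the union of slices
#' covers the whole majority class, so no majority example is discarded.
#'
#' With `k = "auto"` the number of subsets is the imbalance ratio rounded to
#' the nearest integer (minimum 1): e.g. 790 majority vs 159 minority gives
#' `round(4.97) = 5` subsets. Slice sizes differ by at most one compound
#' (790 over 5 slices gives 158 each).
#'
#' @param majority_ids Identifiers of the majority class (actives in the
#'   typical imbalanced bioactivity setting).
#' @param minority_ids Identifiers of the minority class, shared by every
#'   subset.
#' @param k Number of subsets, or `"auto"`.
#' @param seed Integer seed for the single shuffle.
#' @return A list of class `balanced_subsets`; each element has `index`,
#'   `majority_ids`, `minority_ids`, `seed`.
#' @examples
#' bs <- make_balanced_subsets(paste0("a", 1:10), paste0("i", 1:2), k = "auto")
#' length(bs)
#' @export
make_balanced_subsets <- function(majority_ids, minority_ids, k = "auto",
                                  seed = 1) {
  n_maj <- length(majority_ids)
  n_min <- length(minority_ids)
  assert_that(n_min >= 1, "minority class is empty",
              class = "stackscreen_empty_class")
  assert_that(n_maj >= n_min,
              "majority class must be at least as large as the minority class",
              class = "stackscreen_input_error")
  assert_that(!anyDuplicated(majority_ids) && !anyDuplicated(minority_ids),
              "ids must be unique within each class",
              class = "stackscreen_input_error")
  if (identical(k, "auto")) k <- max(1L, as.integer(round(n_maj / n_min)))
  k <- as.integer(k)
  assert_that(k >= 1 && k <= n_maj,
              sprintf("k = %d infeasible for %d majority compounds", k, n_maj),
              class = "stackscreen_infeasible")
  shuffled <- with_seed(seed, sample(majority_ids))
  slice_of <- sort(rep_len(seq_len(k), n_maj))
  subsets <- purrr::map(seq_len(k), function(i) {
    list(index = i,
         majority_ids = shuffled[slice_of == i],
         minority_ids = minority_ids,
         seed = seed)
  })
  structure(subsets, class = "balanced_subsets",
            n_majority = n_maj, n_minority = n_min, seed = seed)
}

#' Audit report for balanced subsets
#'
#' Checks disjointness and coverage of the majority-class slices and reports
#' slice sizes.
#'
#' @param subsets A `balanced_subsets` object (or equivalent list).
#' @param majority_ids Optional full majority id set; defaults to the union
#'   of the slices, in which case `unused` is 0 by construction.
#' @return A list with `sizes` (tibble: subset, n_majority, n_minority,
#'   balance_ratio), `disjoint` (flag), `unused` (majority ids in no slice).
#'   Overlapping slices raise an invariant-violation error.
#' @export
subset_coverage_report <- function(subsets, majority_ids = NULL) {
  assert_that(length(subsets) >= 1, "no subsets supplied",
              class = "stackscreen_input_error")
  slices <- purrr::map(subsets, "majority_ids")
  all_ids <- unlist(slices, use.names = FALSE)
  disjoint <- !anyDuplicated(all_ids)
  assert_that(disjoint, "majority slices overlap: invariant violation",
              class = "stackscreen_invariant_violation")
  unused <- if (is.null(majority_ids)) 0L else sum(!majority_ids %in% all_ids)
  sizes <- tibble(
    subset = purrr::map_int(subsets, function(s) as.integer(s$index)),
    n_majority = purrr::map_int(slices, length),
    n_minority = purrr::map_int(subsets, function(s) length(s$minority_ids))
  )
  sizes$balance_ratio <- sizes$n_majority / sizes$n_minority
  list(sizes = sizes, disjoint = disjoint, unused = unused)
}

#' @export
print.balanced_subsets <- function(x, ...) {
  rep <- subset_coverage_report(x)
  cat(sprintf(
    "%d balanced subsets: majority %d -> slices of %s, minority %d shared\n",
    length(x), attr(x, "n_majority"),
    paste(unique(range(rep$sizes$n_majority)), collapse = "-"),
    attr(x, "n_minority")))
  invisible(x)
}
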