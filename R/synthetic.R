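#' Specification for a synthetic bioactivity dataset
#'
#' Describes the statistical structure the generator emulates: a
#' majority-active / minority-inactive label imbalance (default mirrors the
#' curated 1314/275 study composition, roughly 5:1), activity driven by
#' planted substructure "pharmacophore" markers carried by actives with
#' probability `marker_effect`, label noise, and a fragment grammar drawn
#' from a fixed scaffold pool so that train/test splits contain novel
#' scaffolds.
#'
#' @param n_active,n_inactive Class sizes before label noise.
#' @param marker_smarts SMARTS patterns of the planted activity markers
#'   (defaults: thiol, nitrile, primary aliphatic amine).
#' @param marker_effect Probability that an active carries at least one
#'   marker substituent; inactives carry one with probability
#'   `1 - marker_effect`.
#' @param label_noise Probability that a compound's label (and matching
#'   pIC50) is flipped after structures are assigned.
#' @param scaffold_pool_size Number of ring scaffolds drawn from the shipped
#'   pool (max the pool size).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 1314, n_inactive = 275,
                           marker_smarts = c("[SX2H]", "[CX2]#[NX1]",
                                             "[NX3;H2][CX4]"),
                           marker_effect = 0.9, label_noise = 0.05,
                           scaffold_pool_size = 30, seed = 1) {
  assert_that(n_active >= 1 && n_inactive >= 1, "class counts must be >= 1",
              class = "stackscreen_spec_error")
  assert_that(marker_effect >= 0 && marker_effect <= 1 &&
                label_noise >= 0 && label_noise <= 1,
              "probabilities must lie in [0, 1]",
              class = "stackscreen_spec_error")
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 marker_smarts = marker_smarts,
                 marker_effect = marker_effect,
                 label_noise = label_noise,
                 scaffold_pool_size = as.integer(scaffold_pool_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Fixed fragment grammar. Scaffold templates carry one substitution site
# "{R}"; substituents are chains of simple units ending in a terminal or a
# marker fragment (thiol / nitrile / primary aliphatic amine motifs).
scaffold_pool <- function() {
  c("c1ccc({R})cc1",                     # benzene
    "c1ccc2cc({R})ccc2c1",               # naphthalene
    "c1cc({R})ccn1",                     # pyridine
    "c1cc({R})cnc1",                     # pyridine (meta N)
    "c1cc({R})sc1",                      # thiophene
    "c1cc({R})oc1",                      # furan
    "c1cc({R})[nH]c1",                   # pyrrole
    "c1ccc(-c2ccc({R})cc2)cc1",          # biphenyl
    "C1CCC({R})CC1",                     # cyclohexane
    "C1CCC({R})C1",                      # cyclopentane
    "C1CC({R})C1",                       # cyclobutane
    "C1CCCCC({R})C1",                    # cycloheptane
    "C1CCC({R})OC1",                     # tetrahydropyran
    "C1CC({R})CO1",                      # tetrahydrofuran
    "C1CCN(CC1){R}",                     # piperidine (N-subst.)
    "C1CN(CCO1){R}",                     # morpholine (N-subst.)
    "c1ccc2c(c1)cccc2{R}",               # naphthalene (1-subst.)
    "c1ccc2c(c1)oc({R})c2",              # benzofuran
    "c1ccc2c(c1)sc({R})c2",              # benzothiophene
    "c1ccc2c(c1)[nH]c({R})c2",           # indole
    "c1ccc2c(c1)ncc({R})c2",             # quinoline-like
    "c1cnc({R})cn1",                     # pyrazine
    "c1cc({R})cc(C)c1",                  # m-tolyl
    "c1cc(F)cc({R})c1",                  # fluorophenyl
    "c1cc(Cl)ccc1{R}",                   # chlorophenyl
    "C1=CC({R})CC1",                     # cyclopentene
    "c1ccc(C({R})=O)cc1",                # phenyl ketone core
    "c1ccc(O{R})cc1",                    # phenol ether core
    "c1ccc(C{R})cc1",                    # benzyl core
    "C1CCC2(CC1)CCCC2{R}")               # spiro[4.5]decane
}

# Ring-bearing units keep the Bemis-Murcko framework space large: a ring
# inside a substituent survives side-chain pruning, so train/test splits
# contain genuinely novel frameworks.
chain_units <- function() {
  c("C", "CC", "OC", "c1ccc(cc1)", "C1CCC(CC1)")
}

terminal_pool <- function() {
  c("C", "O", "OC", "Cl", "F", "C(F)(F)F", "C(=O)OC", "C(=O)N(C)C",
    "S(C)(=O)=O", "OCC", "c1ccccc1", "c1ccncc1")
}

marker_pool <- function() c("CS", "CCS", "C#N", "CC#N", "CN", "CCN")

random_substituent <- function(marker) {
  n_chain <- sample(0:2, 1)
  chain <- if (n_chain > 0) {
    paste(sample(chain_units(), n_chain, replace = TRUE), collapse = "")
  } else ""
  tail_frag <- if (marker) sample(marker_pool(), 1) else sample(terminal_pool(), 1)
  paste0(chain, tail_frag)
}

#' Generate a synthetic curated SMILES dataset
#'
#' Assembles molecules from the shipped fragment grammar (scaffold pool x
#' substituent chains), plants marker substructures in actives at rate
#' `marker_effect` (and in inactives at `1 - marker_effect`), flips labels at
#' `label_noise`, assigns pIC50 values consistent with the final label, and
#' returns a deduplicated curated dataset. Deterministic under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `curated_tbl` tibble (compound_id, canonical_smiles, pic50,
#'   label) with `n_active` / `n_inactive` attributes.
#' @export
generate_smiles_dataset <- function(spec = synthetic_spec()) {
  assert_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec",
              class = "stackscreen_spec_error")
  with_seed(spec$seed, {
    pool <- scaffold_pool()
    pool <- pool[seq_len(min(spec$scaffold_pool_size, length(pool)))]
    n_total <- spec$n_active + spec$n_inactive
    want_active <- c(rep(TRUE, spec$n_active), rep(FALSE, spec$n_inactive))
    seen <- character(0)
    smiles <- character(n_total)
    max_tries <- 60L * n_total
    tries <- 0L
    for (i in seq_len(n_total)) {
      repeat {
        tries <- tries + 1L
        assert_that(tries <= max_tries,
                    "fragment grammar exhausted before reaching requested counts",
                    class = "stackscreen_spec_error")
        p_marker <- if (want_active[i]) spec$marker_effect else 1 - spec$marker_effect
        marker <- runif(1) < p_marker
        smi <- sub("{R}", random_substituent(marker), sample(pool, 1), fixed = TRUE)
        can <- tryCatch(standardize_structure(smi), error = function(e) NA_character_)
        if (!is.na(can) && !can %in% seen) {
          seen <- c(seen, can)
          smiles[i] <- can
          break
        }
      }
    }
    label <- ifelse(want_active, "active", "inactive")
    flip <- runif(n_total) < spec$label_noise
    label[flip] <- ifelse(label[flip] == "active", "inactive", "active")
    pic50 <- ifelse(label == "active", runif(n_total, 6.2, 9.0),
                    runif(n_total, 3.5, 4.8))
    ds <- tibble(
      compound_id = sprintf("SYN-%05d", seq_len(n_total)),
      canonical_smiles = smiles,
      pic50 = round(pic50, 3),
      label = label
    )
    new_curated_dataset(ds, audit = tibble(reason = "synthetic", n = n_total))
  })
}

#' Generate a synthetic binary feature dataset
#'
#' Binary feature matrix with `n_informative` columns whose bit-presence
#' probability differs between classes by `effect_delta`; all other columns
#' are exchangeable noise at the base rate. Rows are positives first, then
#' negatives. The informative column positions are randomized and recorded.
#'
#' @param n_pos,n_neg Class sizes.
#' @param n_features Total number of binary features.
#' @param n_informative Number of class-linked features.
#' @param effect_delta Shift in presence probability for positives
#'   (`base_rate + effect_delta` must stay in `[0, 1]`).
#' @param seed Integer seed.
#' @param base_rate Presence probability in the negative class (default 0.2).
#' @return A list: `x` (0/1 matrix with column names `f1..`), `y` (factor
#'   inactive/active with positives labelled `"active"`), `informative`
#'   (column indices carrying signal).
#' @export
generate_feature_dataset <- function(n_pos, n_neg, n_features,
                                     n_informative, effect_delta, seed = 1,
                                     base_rate = 0.2) {
  assert_that(n_informative <= n_features,
              "n_informative must not exceed n_features",
              class = "stackscreen_spec_error")
  p_pos <- base_rate + effect_delta
  assert_that(p_pos >= 0 && p_pos <= 1 && base_rate >= 0 && base_rate <= 1,
              "effect_delta pushes presence probability outside [0, 1]",
              class = "stackscreen_spec_error")
  with_seed(seed, {
    informative <- sort(sample(n_features, n_informative))
    n <- n_pos + n_neg
    x <- matrix(rbinom(n * n_features, 1, base_rate), nrow = n)
    if (n_informative > 0 && n_pos > 0) {
      x[seq_len(n_pos), informative] <-
        rbinom(n_pos * n_informative, 1, p_pos)
    }
    colnames(x) <- paste0("f", seq_len(n_features))
    rownames(x) <- sprintf("S%05d", seq_len(n))
    y <- factor(c(rep("active", n_pos), rep("inactive", n_neg)),
                levels = c("inactive", "active"))
    list(x = x, y = y, informative = informative)
  })
}
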