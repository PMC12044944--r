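# Shared fixtures, all generated in code.

# A small ChEMBL-style activity CSV written to a temp file.
write_toy_activity_csv <- function(path = tempfile(fileext = ".csv"),
                                   rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      `Molecule ChEMBL ID` = paste0("CHEMBL", 1:8),
      Smiles = c("CCO", "c1ccccc1", "CCN", "CCCC", "CC(=O)O",
                 "c1ccccc1O", "CCO", "not_a_smiles"),
      `Standard Relation` = c("=", "<", "=", ">", "/", "=", "=", "="),
      `Standard Value` = c(1000, 50, NA, 10, 20, 50, 2000, 10),
      `Standard Units` = "nM",
      `Assay Type` = "B",
      check.names = FALSE
    )
  }
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Small labelled SMILES sets with known scaffold structure.
toy_smiles <- function() {
  c(toluene = "Cc1ccccc1", ethylbenzene = "CCc1ccccc1",
    hexane = "CCCCCC", naphthalene = "c1ccc2ccccc2c1",
    phenol = "Oc1ccccc1", pyridine = "c1ccncc1")
}

# Brute-force metric oracle, written independently of compute_metrics().
oracle_metrics <- function(tp, tn, fp, fn) {
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(sn = sn, sp = sp, acc = acc, bacc = (sn + sp) / 2, mcc = mcc)
}

# All-pairs AUC oracle: wins + half-ties over positive x negative pairs.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Quick SMARTS match count used to audit generated structures.
count_smarts <- function(smiles, pattern) {
  vapply(smiles, function(s) {
    res <- ChemmineOB::forEachMol("SMI", s, function(m)
      ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE))
    as.numeric(res[[1]])
  }, numeric(1), USE.NAMES = FALSE)
}
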