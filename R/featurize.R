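# Chemistry backend: OpenBabel via ChemmineOB/ChemmineR. SMARTS pattern
# files for the MACCS and FP4 families are read from the OpenBabel data
# directory discovered at load time.

the <- new.env(parent = emptyenv())

ob_data_dir <- function() {
  if (!is.null(the$ob_dir)) return(the$ob_dir)
  candidates <- character(0)
  env <- Sys.getenv("BABEL_DATADIR", "")
  if (nzchar(env)) candidates <- c(candidates, env)
  ob <- Sys.which("obabel")
  if (nzchar(ob)) {
    prefix <- dirname(dirname(ob))
    share <- file.path(prefix, "share", "openbabel")
    if (dir.exists(share)) {
      candidates <- c(candidates, share, list.dirs(share, recursive = FALSE))
    }
  }
  for (d in candidates) {
    if (file.exists(file.path(d, "SMARTS_InteLigand.txt"))) {
      the$ob_dir <- d
      return(d)
    }
  }
  abort("OpenBabel data directory (SMARTS_InteLigand.txt) not found",
        class = "stackscreen_config_error")
}

read_smarts_file <- function(file) {
  lines <- readLines(file.path(ob_data_dir(), file), warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  name <- trimws(sub(":.*$", "", lines))
  smarts <- trimws(sub("^[^:]+:", "", lines))
  # strip trailing comments present in the MACCS key file
  smarts <- trimws(sub("\\s+[0-9]+\\s*(#.*)?$", "", smarts))
  tibble(name = name, smarts = smarts)
}

fp4_patterns <- function() {
  if (is.null(the$fp4)) the$fp4 <- read_smarts_file("SMARTS_InteLigand.txt")
  the$fp4
}

#' Standardize SMILES structures
#'
#' Canonicalizes each structure with OpenBabel after keeping only the
#' largest organic fragment (salt/solvate stripping). The operation is
#' idempotent: standardizing an already-standard SMILES returns it
#' unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @param on_error `"abort"` (default) to raise a parse error naming the
#'   offending string, `"na"` to return `NA` for unparsable entries.
#' @return Character vector of canonical SMILES.
#' @examples
#' \donttest{standardize_structure("CCO.[Na+].[Cl-]")}
#' @export
standardize_structure <- function(smiles, on_error = c("abort", "na")) {
  on_error <- match.arg(on_error)
  out <- vapply(as.character(smiles), function(smi) {
    if (is.na(smi) || !nzchar(trimws(smi))) return(NA_character_)
    can <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smi)),
      error = function(e) "")
    can <- trimws(strsplit(can, "\t|\n")[[1]][1])
    if (is.na(can) || !nzchar(can)) return(NA_character_)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) > 1) {
      # carbon-containing fragments ("C" not part of "Cl"; aromatic "c")
      organic <- grepl("c|C(?!l)", frags, perl = TRUE)
      if (any(organic)) frags <- frags[organic]
      best <- frags[which.max(nchar(gsub("[^A-Za-z]", "", frags)))]
      can2 <- tryCatch(
        suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", best)),
        error = function(e) "")
      can <- trimws(strsplit(can2, "\t|\n")[[1]][1])
      if (is.na(can) || !nzchar(can)) return(NA_character_)
    }
    can
  }, character(1), USE.NAMES = FALSE)
  if (on_error == "abort" && anyNA(out)) {
    bad <- as.character(smiles)[is.na(out)]
    abort(sprintf("unparsable SMILES: %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "stackscreen_parse_error")
  }
  out
}

# Run f(molRef) once per molecule over a SMILES vector, in input order.
for_each_smiles <- function(smiles, f) {
  res <- ChemmineOB::forEachMol("SMI", paste(smiles, collapse = "\n"), f)
  assert_that(length(res) == length(smiles),
              "OpenBabel dropped molecules while parsing",
              class = "stackscreen_parse_error")
  res
}

ob_fingerprint_matrix <- function(smiles, fp_name) {
  rows <- for_each_smiles(smiles, function(m)
    ChemmineOB::fingerprint_OB(list(m), fp_name))
  do.call(rbind, lapply(rows, as.numeric))
}

fold_bits <- function(mat, n_bits) {
  idx <- ((seq_len(ncol(mat)) - 1) %% n_bits) + 1
  out <- matrix(0, nrow(mat), n_bits)
  for (j in seq_len(ncol(mat))) {
    out[, idx[j]] <- pmax(out[, idx[j]], mat[, j])
  }
  out
}

# Atom-pair block: 12 element classes x topological distances 1..10.
ap_element_classes <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "X")
}

smiles_to_graph <- function(smi) {
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", smi)
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdfstr, "\n", fixed = TRUE)[[1]]))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  edges <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  list(elements = elements, edges = edges,
       bond_order = if (nrow(edges) > 0) as.integer(bb[, 3]) else integer(0))
}

atom_pair_row <- function(smi, max_dist = 10) {
  g <- smiles_to_graph(smi)
  classes <- ap_element_classes()
  cls <- match(g$elements, classes)
  cls[is.na(cls)] <- length(classes)  # "X": anything outside the named set
  n_cls <- length(classes)
  n_pairs <- n_cls * (n_cls + 1) / 2
  row <- numeric(n_pairs * max_dist)
  n_atoms <- length(cls)
  if (n_atoms >= 2 && nrow(g$edges) > 0) {
    gr <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, n_atoms - igraph::vcount(gr)))
    dmat <- igraph::distances(gr)
    for (i in seq_len(n_atoms - 1)) {
      for (j in seq((i + 1), n_atoms)) {
        d <- dmat[i, j]
        if (is.finite(d) && d >= 1 && d <= max_dist) {
          a <- min(cls[i], cls[j]); b <- max(cls[i], cls[j])
          pair_idx <- (a - 1) * n_cls - (a - 1) * a / 2 + b
          row[(d - 1) * n_pairs + pair_idx] <- 1
        }
      }
    }
  }
  row
}

#' Descriptor family registry
#'
#' The five SMILES-based fingerprint families with their fixed dimensions
#' and value kinds. `AP2DC` encodes presence of element-class pairs at
#' topological distances 1-10 (78 unordered pairs of 12 classes x 10
#' distances = 780 bits); `CDKExt` is a 1024-bit hashed path/ring
#' fingerprint; `FP4C` counts matches of 307 functional-group SMARTS
#' patterns; `MACCS` is the 166 structural keys; `Pubchem` is an 881-bit
#' substructure block (circular-fingerprint bits folded to width 881).
#'
#' @return Tibble with columns `family`, `dim`, `value_kind`.
#' @export
descriptor_families <- function() {
  tibble(
    family = c("AP2DC", "CDKExt", "FP4C", "MACCS", "Pubchem"),
    dim = c(780L, 1024L, 307L, 166L, 881L),
    value_kind = c("binary", "binary", "count", "binary", "binary")
  )
}

#' Compute one descriptor block
#'
#' Returns the n x d feature matrix of the requested fingerprint family for
#' a vector of standardized SMILES. Row order matches input order; the
#' width always equals the registry dimension; binary families contain only
#' 0/1 and `FP4C` contains non-negative SMARTS match counts.
#'
#' @param smiles Standardized SMILES (see [standardize_structure()]).
#' @param family One of `"AP2DC"`, `"CDKExt"`, `"FP4C"`, `"MACCS"`,
#'   `"Pubchem"`.
#' @return Numeric matrix with column names `<family>_<index>` and
#'   attributes `family` and `value_kind`; class `descriptor_block`.
#' @export
compute_descriptor_block <- function(smiles, family) {
  reg <- descriptor_families()
  assert_that(family %in% reg$family,
              sprintf("unknown family '%s'; valid: %s", family,
                      paste(reg$family, collapse = ", ")),
              class = "stackscreen_config_error")
  d <- reg$dim[reg$family == family]
  smiles <- as.character(smiles)
  mat <- switch(
    family,
    MACCS = ob_fingerprint_matrix(smiles, "MACCS")[, seq_len(d), drop = FALSE],
    CDKExt = ob_fingerprint_matrix(smiles, "FP2")[, seq_len(d), drop = FALSE],
    Pubchem = fold_bits(ob_fingerprint_matrix(smiles, "ECFP4"), d),
    FP4C = {
      pats <- fp4_patterns()$smarts
      rows <- for_each_smiles(smiles, function(m) {
        vapply(pats, function(p)
          ChemmineOB::smartsSearch_OB(list(m), p, uniqueMatches = TRUE),
          numeric(1), USE.NAMES = FALSE)
      })
      do.call(rbind, rows)
    },
    AP2DC = do.call(rbind, lapply(smiles, atom_pair_row))
  )
  assert_that(ncol(mat) == d, "descriptor width does not match registry",
              class = "stackscreen_invariant_violation")
  colnames(mat) <- paste0(family, "_", seq_len(d))
  rownames(mat) <- NULL
  structure(mat, family = family,
            value_kind = reg$value_kind[reg$family == family],
            class = c("descriptor_block", class(mat)))
}

#' Physicochemical property profile
#'
#' Computes the six oral-bioavailability properties used in chemical-space
#' analysis: molecular weight (Da), calculated logP, hydrogen-bond acceptor
#' and donor counts, topological polar surface area (A^2), and rotatable
#' bond count.
#'
#' @param smiles Standardized SMILES vector.
#' @return Tibble with columns `smiles`, `mw`, `alogp`, `hba`, `hbd`,
#'   `tpsa`, `nrotb`; unparsable entries yield an `error` flag row of `NA`s
#'   and the batch continues.
#' @export
compute_physchem <- function(smiles) {
  rotor_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
  rows <- lapply(as.character(smiles), function(smi) {
    tryCatch({
      res <- for_each_smiles(smi, function(m) {
        p <- ChemmineOB::prop_OB(list(m))
        nrot <- ChemmineOB::smartsSearch_OB(list(m), rotor_smarts,
                                            uniqueMatches = TRUE)
        tibble(mw = p$MW, alogp = p$logP, hba = p$HBA1, hbd = p$HBD,
               tpsa = p$TPSA, nrotb = as.numeric(nrot))
      })
      res[[1]]
    }, error = function(e) tibble(mw = NA_real_, alogp = NA_real_,
                                  hba = NA_real_, hbd = NA_real_,
                                  tpsa = NA_real_, nrotb = NA_real_))
  })
  bind_cols(tibble(smiles = as.character(smiles)), bind_rows(rows))
}

#' Circular (ECFP4-style) fingerprint
#'
#' Radius-2 extended-connectivity fingerprint folded to `n_bits`.
#'
#' @param smiles Standardized SMILES vector.
#' @param n_bits Folded width (default 2048).
#' @return 0/1 matrix with one row per molecule.
#' @export
ecfp4 <- function(smiles, n_bits = 2048) {
  mat <- ob_fingerprint_matrix(as.character(smiles), "ECFP4")
  if (ncol(mat) > n_bits) mat <- fold_bits(mat, n_bits)
  mat
}

#' Tanimoto similarity between bit vectors
#'
#' `|a AND b| / |a OR b|` for binary fingerprints; two empty vectors give 0
#' with a warning.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  assert_that(length(a) == length(b), "fingerprints differ in length",
              class = "stackscreen_input_error")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) {
    warn("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / u
}

#' Bemis-Murcko scaffold key
#'
#' Extracts the ring-systems-plus-linkers framework of each molecule by
#' iteratively pruning terminal side-chain atoms (the 2-core of the
#' heavy-atom graph) and canonicalizing the retained substructure.
#' Ring-free molecules map to a single acyclic sentinel key.
#'
#' @param smiles Standardized SMILES vector.
#' @return Tibble with `smiles`, `scaffold` (canonical scaffold SMILES, or
#'   `"<acyclic>"` for ring-free molecules), `is_acyclic`.
#' @export
murcko_scaffold <- function(smiles) {
  rows <- lapply(as.character(smiles), function(smi) {
    g <- smiles_to_graph(smi)
    n <- length(g$elements)
    keep <- rep(TRUE, n)
    edges <- g$edges
    repeat {
      deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n) * keep
      leaves <- which(keep & deg <= 1)
      if (length(leaves) == 0) break
      keep[leaves] <- FALSE
      if (nrow(edges) > 0) {
        edges <- edges[keep[edges[, 1]] & keep[edges[, 2]], , drop = FALSE]
      }
    }
    if (!any(keep)) {
      return(tibble(smiles = smi, scaffold = "<acyclic>", is_acyclic = TRUE))
    }
    scaffold <- scaffold_to_smiles(smi, keep)
    tibble(smiles = smi, scaffold = scaffold, is_acyclic = FALSE)
  })
  bind_rows(rows)
}

# Rebuild an SDF holding only the retained atoms and convert it to
# canonical SMILES. Bond orders are preserved; aromatic perception is
# re-done by the toolkit on conversion.
scaffold_to_smiles <- function(smi, keep) {
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", smi)
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdfstr, "\n", fixed = TRUE)[[1]]))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  old_idx <- which(keep)
  new_idx <- match(seq_len(nrow(ab)), old_idx)
  elements <- gsub("_.*$", "", rownames(ab))[old_idx]
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    b <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
    b[keep[b[, 1]] & keep[b[, 2]], , drop = FALSE]
  }
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    ab[old_idx, 1], ab[old_idx, 2], 0, elements)
  bond_lines <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", new_idx[bonds[, 1]],
            new_idx[bonds[, 2]], bonds[, 3])
  } else character(0)
  sdf_txt <- c("scaffold", "  stackscreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       length(old_idx), nrow(bonds)),
               atom_lines, bond_lines, "M  END", "$$$$")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SDF", "CAN", paste(sdf_txt, collapse = "\n"))),
    error = function(e) "")
  out <- trimws(strsplit(out, "\t|\n")[[1]][1])
  if (is.na(out) || !nzchar(out)) {
    abort(sprintf("scaffold extraction failed for %s", smi),
          class = "stackscreen_parse_error")
  }
  # canonical key: re-standardize so identical frameworks compare equal
  standardize_structure(out)
}
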