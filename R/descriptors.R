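# Structure-derived descriptors: topological diameter, a 25-slot drug-like
# panel, and an additive polarizability proxy.
#
# Conventions (all deterministic; see the methods vignette for the full table):
#   H-acceptors       N + O atom count (Lipinski-style)
#   H-donors          N/O with at least one attached H (OpenBabel HBD)
#   TSA               additive van-der-Waals surface approximation (A^2)
#   PSA               topological polar surface area (Ertl fragment scheme,
#                     via OpenBabel)
#   RPSA              PSA / TSA, clipped to [0, 1]
#   cLogP             Wildman-Crippen atom-contribution logP (OpenBabel)
#   cLogS             ESOL-style estimated log solubility
#   drug-likeness     composite desirability score in [0, 1]
#   rotatable bonds   non-ring single bonds between two non-terminal heavy atoms
#   ring closures     cyclomatic number (bonds - atoms + components)
#   small rings       distinct simple rings of size 3-7 (unique atom sets)
#   stereo centers    stereo-specified bracket atoms ('@') in the input SMILES
#   symmetric atoms   atoms in non-singleton graph-automorphism colour classes
#                     (colour refinement on the H-depleted graph)

DRUG_LIKE_NAMES <- c(
  "HAcceptors", "HDonors", "TSA", "RPSA", "PSA", "DrugLikeness", "MW",
  "cLogP", "cLogS", "ElectronegAtoms", "StereoCenters", "RotBonds",
  "RingClosures", "SmallRings", "AromaticRings", "AromaticAtoms", "Sp3Atoms",
  "SymmetricAtoms", "Amides", "Amines", "AromaticN", "BasicN", "AcidicO",
  "NonHAtoms", "NonCHAtoms")

DESCRIPTOR_NAMES <- c("QPpolrz", "TD", DRUG_LIKE_NAMES)

# Bondi van-der-Waals radii (Angstrom) for the additive surface approximation.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
               Br = 1.85, I = 1.98, P = 1.80, S = 1.80, B = 1.92, Si = 2.10)

.fd_cache <- new.env(parent = emptyenv())

#' Polarizability increment table
#'
#' Element-level additive polarizability increments (cubic Angstrom),
#' calibrated to Miller-style atomic additivity values and shipped as plain
#' data with the package.
#'
#' @return data frame with columns `element` and `alpha`.
#' @export
polarizability_increments <- function() {
  if (is.null(.fd_cache$pol_inc)) {
    path <- system.file("extdata", "polarizability_increments.csv",
                        package = "fdtox", mustWork = TRUE)
    .fd_cache$pol_inc <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .fd_cache$pol_inc
}

as_fd_mols <- function(x) {
  if (inherits(x, "fd_mols")) x else parse_molecules(x)
}

# "C9H12N2O+" -> c(C = 9, H = 12, N = 2, O = 1)
parse_formula <- function(formula) {
  body <- gsub("[+-]+[0-9]*$", "", formula)
  parts <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(sub("^[A-Za-z]+", "", parts))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' Topological diameter
#'
#' The maximum over atom pairs of the shortest-path length (in bonds) on the
#' hydrogen-depleted graph of the largest connected component. A single heavy
#' atom has diameter 0.
#'
#' @param x a character vector of SMILES or an `fd_mols` object.
#' @return integer vector of diameters.
#' @examples
#' topological_diameter(c("C", "c1ccccc1", "CCCCCC"))  # 0 3 5
#' @export
topological_diameter <- function(x) {
  mols <- as_fd_mols(x)
  vapply(mols$graphs, function(g) {
    n <- igraph::vcount(g)
    fd_assert(n >= 1L, "domain", "empty molecule has no topological diameter")
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, keep)
    as.integer(max(igraph::distances(sub)))
  }, integer(1))
}

#' Additive polarizability proxy
#'
#' Element-level additive estimate of the polarizability volume (cubic
#' Angstrom), used only when a supplied `QPpolrz` column is absent. Strictly
#' additive over disconnected fragments. This is the package's own labelled
#' stand-in; it is never silently mixed with supplied polarizability values.
#'
#' @param x a character vector of SMILES or an `fd_mols` object.
#' @return numeric vector (cubic Angstrom).
#' @examples
#' polarizability_proxy("C")            # methane: 1 C + 4 H increments
#' @export
polarizability_proxy <- function(x) {
  mols <- as_fd_mols(x)
  inc <- polarizability_increments()
  alpha <- stats::setNames(inc$alpha, inc$element)
  vapply(mols$props$formula, function(f) {
    counts <- parse_formula(f)
    missing <- setdiff(names(counts), names(alpha))
    if (length(missing) > 0)
      fd_stop("descriptor",
              "element(s) missing from polarizability increment table: %s",
              paste(missing, collapse = ", "))
    sum(counts * alpha[names(counts)])
  }, numeric(1), USE.NAMES = FALSE)
}

# Colour refinement (1-WL) symmetry classes on the H-depleted graph.
symmetry_classes <- function(g, elements) {
  n <- length(elements)
  if (n == 1L) return(1L)
  adj <- igraph::as_adj_list(g)
  colour <- paste0(elements, "/", igraph::degree(g))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(colour[i], paste(sort(colour[adj[[i]]]), collapse = ","),
            sep = "|")
    }, character(1))
    new_colour <- as.character(match(sig, unique(sig)))
    if (length(unique(new_colour)) == length(unique(colour))) break
    colour <- new_colour
  }
  as.integer(match(colour, unique(colour)))
}

# Count distinct simple rings of sizes 3..7 via SMARTS ring-closure patterns
# with unique-atom-set deduplication.
ring_counts <- function(smiles) {
  sizes <- 3:7
  counts <- matrix(0L, nrow = length(smiles), ncol = length(sizes))
  for (k in seq_along(sizes)) {
    pat <- paste0("*1", strrep("*", sizes[k] - 1L), "1")
    counts[, k] <- smarts_count(smiles, pat)
  }
  rowSums(counts)
}

aromatic_ring_counts <- function(smiles) {
  total <- integer(length(smiles))
  for (size in 5:7) {
    pat <- paste0("a1", strrep("a", size - 1L), "1")
    total <- total + smarts_count(smiles, pat)
  }
  total
}

#' Compute the 25 drug-like descriptors
#'
#' @param x a character vector of SMILES or an `fd_mols` object.
#' @return data frame with one row per molecule and the 25 drug-like slots
#'   (see package conventions above).
#' @examples
#' compute_drug_like("c1ccccc1")[, c("AromaticRings", "AromaticAtoms")]
#' @export
compute_drug_like <- function(x) {
  mols <- as_fd_mols(x)
  smi <- mols$smiles
  n <- length(smi)
  p <- mols$props

  heavy <- vapply(mols$elements, length, integer(1))
  non_ch <- vapply(mols$elements, function(e) sum(e != "C"), integer(1))
  n_h <- vapply(p$formula, function(f) {
    cts <- parse_formula(f); if ("H" %in% names(cts)) cts[["H"]] else 0L
  }, numeric(1), USE.NAMES = FALSE)

  # graph-derived quantities
  rot <- integer(n); closures <- integer(n); tsa <- numeric(n)
  symm <- integer(n)
  for (i in seq_len(n)) {
    g <- mols$graphs[[i]]
    bd <- mols$bonds[[i]]
    deg <- igraph::degree(g)
    comp <- igraph::components(g)$no
    closures[i] <- nrow(bd) - heavy[i] + comp
    if (nrow(bd) > 0L) {
      bridge_ids <- igraph::bridges(g)
      is_bridge <- seq_len(nrow(bd)) %in% as.integer(bridge_ids)
      rot[i] <- sum(bd$order == 1L & is_bridge &
                      deg[bd$from] >= 2L & deg[bd$to] >= 2L)
    }
    r <- VDW_RADII[mols$elements[[i]]]
    r[is.na(r)] <- 1.7
    area <- 4 * pi * r^2
    tsa[i] <- sum(area * pmax(0.2, 1 - 0.23 * pmin(deg, 3))) +
      n_h[i] * 0.40 * 4 * pi * VDW_RADII[["H"]]^2
    cls <- symmetry_classes(g, mols$elements[[i]])
    symm[i] <- sum(table(cls)[as.character(cls)] > 1L)
  }

  stereo <- vapply(smi, function(s) {
    tk <- smiles_tokens(s)
    sum(startsWith(tk, "[") & grepl("@", tk, fixed = TRUE))
  }, integer(1), USE.NAMES = FALSE)

  arom_atoms <- smarts_count(smi, "[a]")
  out <- data.frame(
    HAcceptors = smarts_count(smi, "[#7,#8]"),
    HDonors = as.integer(p$HBD),
    TSA = tsa,
    RPSA = NA_real_,
    PSA = p$TPSA,
    DrugLikeness = NA_real_,
    MW = p$MW,
    cLogP = p$logP,
    cLogS = NA_real_,
    ElectronegAtoms = smarts_count(smi, "[#7,#8,#9,#17,#35,#53]"),
    StereoCenters = stereo,
    RotBonds = rot,
    RingClosures = closures,
    SmallRings = ring_counts(smi),
    AromaticRings = aromatic_ring_counts(smi),
    AromaticAtoms = arom_atoms,
    Sp3Atoms = smarts_count(smi, "[CX4]"),
    SymmetricAtoms = symm,
    Amides = smarts_count(smi, "[CX3](=[OX1])[NX3]"),
    Amines = smarts_count(smi, "[N;X3;!a;!$([N][C]=[O]);!$([N]=*)]"),
    AromaticN = smarts_count(smi, "[n]"),
    BasicN = smarts_count(
      smi, "[$([N;X3;!a;!$([N][C]=[O]);!$([N]=*);!$([N][a])]),$([NX4+])]"),
    AcidicO = smarts_count(
      smi, "[$([OX2H][CX3]=[OX1]),$([OX2H][#15,#16]=[OX1])]"),
    NonHAtoms = heavy,
    NonCHAtoms = non_ch)

  out$RPSA <- pmin(1, pmax(0, out$PSA / pmax(out$TSA, 1e-8)))
  out$cLogS <- 0.16 - 0.63 * out$cLogP - 0.0062 * out$MW +
    0.066 * out$RotBonds - 0.74 * (out$AromaticAtoms / pmax(heavy, 1))
  pen <- cbind(pmin(1, abs(out$cLogP - 2.5) / 5),
               pmin(1, abs(out$MW - 400) / 400),
               pmin(1, abs(out$PSA - 60) / 120),
               pmin(1, out$RotBonds / 15))
  out$DrugLikeness <- 1 - rowMeans(pen)
  rownames(out) <- mols$ids
  out
}

#' Assemble the full descriptor table
#'
#' Builds the 27-column predictor table (`QPpolrz`, `TD`, and the 25 drug-like
#' descriptors; the DCW optimal descriptor is fitted later and attached as the
#' 28th). When `supplied` contains a descriptor column, the supplied values
#' take precedence and the per-column provenance records `"supplied"`;
#' otherwise the value is computed from structure and recorded as
#' `"computed"`. In particular a supplied `QPpolrz` (e.g. a QikProp value) is
#' used verbatim, and only in its absence is the additive
#' \code{\link{polarizability_proxy}} substituted.
#'
#' @param x a character vector of SMILES or an `fd_mols` object.
#' @param supplied optional data frame of pre-computed descriptor columns,
#'   rows aligned with `x`.
#' @return data frame with 27 descriptor columns and a `"provenance"`
#'   attribute (named character vector, `"supplied"` or `"computed"`).
#' @export
descriptor_table <- function(x, supplied = NULL) {
  mols <- as_fd_mols(x)
  out <- cbind(
    data.frame(QPpolrz = polarizability_proxy(mols),
               TD = topological_diameter(mols)),
    compute_drug_like(mols))
  provenance <- stats::setNames(rep("computed", ncol(out)), names(out))
  if (!is.null(supplied)) {
    fd_assert(nrow(supplied) == length(mols), "dimension",
              "'supplied' has %d rows for %d molecules",
              nrow(supplied), length(mols))
    for (col in intersect(names(supplied), names(out))) {
      out[[col]] <- supplied[[col]]
      provenance[[col]] <- "supplied"
    }
  }
  rownames(out) <- mols$ids
  attr(out, "provenance") <- provenance
  out
}
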