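#' Parse SMILES into an internal molecule set
#'
#' Thin wrapper around OpenBabel (via \pkg{ChemmineR}/\pkg{ChemmineOB}) that
#' parses a character vector of SMILES once and exposes everything downstream
#' code needs: elements, the hydrogen-depleted molecular graph, canonical
#' SMILES, and molecule-level properties (MW, logP, TPSA, H-bond donors).
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound identifiers (defaults to `FD1`, `FD2`, ...).
#' @return An object of class `fd_mols`: a list with elements `ids`, `smiles`,
#'   `canonical`, `props` (data frame), `elements` (list of element vectors),
#'   `bonds` (list of data frames with columns `from`, `to`, `order`) and
#'   `graphs` (list of \pkg{igraph} graphs).
#' @examples
#' m <- parse_molecules(c("CCO", "c1ccccc1"))
#' m$props$MW
#' @export
parse_molecules <- function(smiles, ids = NULL) {
  fd_assert(is.character(smiles) && length(smiles) > 0, "parse",
            "no SMILES supplied")
  fd_assert(!anyNA(smiles) && all(nzchar(smiles)), "parse",
            "empty or missing SMILES at position(s): %s",
            paste(which(is.na(smiles) | !nzchar(smiles)), collapse = ", "))
  if (is.null(ids)) ids <- paste0("FD", seq_along(smiles))
  fd_assert(!anyDuplicated(ids), "parse", "duplicate compound ids")

  # Heavy-atom graphs via OpenBabel's MOL2 writer. The conversion runs through
  # the obabel executable: the in-process conversion entry point stalls on
  # fused cage polycycles, while the command-line driver over the same library
  # is fast and stable, and one batch call per parse covers everything.
  mol2 <- obabel_convert(smiles, ids)
  parsed <- read_mol2_blocks(mol2)
  fd_assert(length(parsed) == length(smiles), "parse",
            "OpenBabel failed to parse %d of %d SMILES",
            length(smiles) - length(parsed), length(smiles))

  elements <- vector("list", length(smiles))
  bonds <- vector("list", length(smiles))
  graphs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    el <- parsed[[i]]$elements
    if (length(el) == 0L)
      fd_stop("parse", "SMILES '%s' (id %s) parsed to an empty molecule",
              smiles[i], ids[i])
    bd <- parsed[[i]]$bonds
    g <- igraph::make_empty_graph(n = length(el), directed = FALSE)
    if (nrow(bd) > 0L)
      g <- igraph::add_edges(g, rbind(bd$from, bd$to))
    elements[[i]] <- el
    bonds[[i]] <- bd
    graphs[[i]] <- g
  }

  props <- mol_props(smiles)
  structure(list(ids = ids, smiles = smiles,
                 canonical = props$cansmi, props = props,
                 elements = elements, bonds = bonds, graphs = graphs),
            class = "fd_mols")
}

#' @export
print.fd_mols <- function(x, ...) {
  cat("fd_mols: ", length(x$smiles), " molecule(s)\n", sep = "")
  print(utils::head(data.frame(id = x$ids, smiles = x$smiles,
                               formula = x$props$formula, MW = x$props$MW)))
  invisible(x)
}

#' @export
length.fd_mols <- function(x) length(x$smiles)

# Batch SMILES -> MOL2 text via the obabel command-line tool.
obabel_convert <- function(smiles, ids) {
  exe <- Sys.which("obabel")
  fd_assert(nzchar(exe), "parse",
            "the 'obabel' executable is required but was not found on PATH")
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(infile, outfile)))
  writeLines(paste(smiles, ids), infile)
  status <- suppressWarnings(system2(
    exe, c("-ismi", shQuote(infile), "-omol2", "-O", shQuote(outfile)),
    stdout = FALSE, stderr = FALSE))
  fd_assert(identical(status, 0L) && file.exists(outfile), "parse",
            "obabel failed to convert the SMILES batch (exit status %s)",
            status)
  paste(readLines(outfile), collapse = "\n")
}

# Minimal TRIPOS MOL2 reader: elements (from the atom-type field, hydrogens
# excluded) and bonds with order codes (1, 2, 3; "ar" -> 4, "am" -> 1),
# renumbered over heavy atoms only.
read_mol2_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  lapply(seq_along(starts), function(k) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    blk <- lines[from:to]
    a0 <- which(blk == "@<TRIPOS>ATOM")
    b0 <- which(blk == "@<TRIPOS>BOND")
    counts <- scan(text = blk[3], quiet = TRUE)
    n_atoms <- counts[1]; n_bonds <- if (length(counts) > 1) counts[2] else 0
    el <- character(0); keep <- integer(0)
    if (n_atoms > 0) {
      fields <- strsplit(trimws(blk[a0 + seq_len(n_atoms)]), "[ \t]+")
      type <- vapply(fields, `[[`, character(1), 6L)
      el_all <- sub("\\..*$", "", type)
      keep <- which(el_all != "H")
      el <- el_all[keep]
    }
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
    if (length(b0) == 1L && n_bonds > 0) {
      bf <- strsplit(trimws(blk[b0 + seq_len(n_bonds)]), "[ \t]+")
      u <- vapply(bf, function(x) as.integer(x[2]), integer(1))
      v <- vapply(bf, function(x) as.integer(x[3]), integer(1))
      ty <- vapply(bf, `[[`, character(1), 4L)
      ord <- ifelse(ty == "ar", 4L, ifelse(ty == "am", 1L,
                    suppressWarnings(as.integer(ty))))
      ord[is.na(ord)] <- 1L
      remap <- match(seq_len(n_atoms), keep)
      ok <- !is.na(remap[u]) & !is.na(remap[v])
      bonds <- data.frame(from = remap[u][ok], to = remap[v][ok],
                          order = ord[ok])
    }
    list(elements = el, bonds = bonds)
  })
}

# One pass of OpenBabel's property calculator over a SMILES batch.
mol_props <- function(smiles) {
  res <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                function(mol) ChemmineOB::prop_OB(list(mol)))
  fd_assert(length(res) == length(smiles), "parse",
            "property calculation returned %d records for %d molecules",
            length(res), length(smiles))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  for (col in c("MW", "logP", "TPSA", "HBA1", "HBD", "MR"))
    out[[col]] <- as.numeric(out[[col]])
  out
}

#' Count unique SMARTS matches
#'
#' Matches a SMARTS pattern against each molecule and returns the number of
#' symmetry-deduplicated (unique atom-set) matches.
#'
#' @param smiles character vector of SMILES, or an `fd_mols` object.
#' @param smarts a single SMARTS pattern.
#' @return integer vector of match counts, one per molecule.
#' @examples
#' smarts_count(c("CCO", "c1ccccc1"), "[OX2H]")
#' @export
smarts_count <- function(smiles, smarts) {
  if (inherits(smiles, "fd_mols")) smiles <- smiles$smiles
  fd_assert(is.character(smarts) && length(smarts) == 1L, "parameter",
            "'smarts' must be a single pattern")
  n <- unlist(ChemmineOB::forEachMol(
    "SMILES", paste(smiles, collapse = "\n"),
    function(mol) ChemmineOB::smartsSearch_OB(list(mol), smarts,
                                              uniqueMatches = TRUE)))
  fd_assert(length(n) == length(smiles), "parse",
            "SMARTS matching returned %d results for %d molecules",
            length(n), length(smiles))
  as.integer(n)
}

#' Canonicalize SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of OpenBabel canonical SMILES.
#' @examples
#' canonical_smiles("OCC") == canonical_smiles("CCO")
#' @export
canonical_smiles <- function(smiles) {
  fd_assert(is.character(smiles) && all(nzchar(smiles)), "parse",
            "empty SMILES cannot be canonicalized")
  mol_props(smiles)$cansmi
}
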