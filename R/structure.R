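#' Trimeric structure container
#'
#' Atom table for a three-chain channel structure: one row per atom with
#' chain id, residue number, residue name, atom name and coordinates in
#' Angstrom. Residue numbers follow the same reference numbering as the
#' sequence scan so candidates map directly onto chains.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param require_trimer If `TRUE` (default) insist on exactly three chains.
#' @return Object of class `trimer_structure`.
#' @export
trimer_structure <- function(atoms, require_trimer = TRUE) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns chain, resno, resid, elety, x, y, z",
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  chains <- unique(atoms$chain)
  if (require_trimer && length(chains) != 3L) {
    stop(sprintf("expected 3 chains, found %d", length(chains)), call. = FALSE)
  }
  for (ch in chains) {
    resno <- atoms$resno[atoms$chain == ch & atoms$elety == "CA"]
    if (anyDuplicated(resno)) {
      stop(sprintf("duplicate residue numbers in chain %s", ch), call. = FALSE)
    }
  }
  structure(list(atoms = atoms[need]), class = "trimer_structure")
}

#' @export
print.trimer_structure <- function(x, ...) {
  cat(sprintf("trimer_structure: %d atoms, chains %s\n",
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Read a structure from PDB
#'
#' First model only; alternate locations restricted to blank or 'A';
#' insertion codes are rejected because they break the 1:1 residue-number
#' mapping the pipeline relies on.
#'
#' @param path Path to a PDB file.
#' @param require_trimer Insist on exactly 3 chains (default `TRUE`).
#' @return A [trimer_structure()].
#' @export
read_structure_pdb <- function(path, require_trimer = TRUE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ins <- at$insert
  if (any(!is.na(ins) & ins != "")) {
    stop("PDB contains insertion codes; renumber the structure first",
         call. = FALSE)
  }
  trimer_structure(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    require_trimer = require_trimer
  )
}

#' @rdname read_structure_pdb
#' @param structure A [trimer_structure()].
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = at$resid, chain = at$chain,
    elety = at$elety, o = rep(1, nrow(at)), b = rep(0, nrow(at))
  )
  invisible(path)
}

# atoms under the given mode: CA only, or all heavy atoms
select_mode <- function(atoms, atom_mode = c("CA", "heavy")) {
  atom_mode <- match.arg(atom_mode)
  if (atom_mode == "CA") {
    atoms[atoms$elety == "CA", , drop = FALSE]
  } else {
    atoms[!grepl("^H", atoms$elety), , drop = FALSE]
  }
}

#' Minimum distance from one residue to any other chain
#'
#' Minimum Euclidean distance from the selected atoms of the residue to any
#' selected atom in a different chain, together with the identity of the
#' closest partner chain. Under C3 symmetry the two neighbouring chains are
#' equivalent; the nearer one is reported.
#'
#' @param structure A [trimer_structure()].
#' @param chain Chain id of the query residue.
#' @param resno Residue number of the query residue.
#' @param atom_mode `"CA"` (default) or `"heavy"`. Calpha mode is the default
#'   because side-chain placement in low-identity homology models is
#'   unreliable.
#' @return List with `distance` (Angstrom) and `partner` (chain id).
#' @export
min_interchain_distance <- function(structure, chain, resno,
                                    atom_mode = c("CA", "heavy")) {
  atom_mode <- match.arg(atom_mode)
  at <- select_mode(structure$atoms, atom_mode)
  mine <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  if (nrow(mine) == 0L) {
    stop(sprintf("residue %d not present in chain %s (mode %s)",
                 resno, chain, atom_mode), call. = FALSE)
  }
  others <- at[at$chain != chain, , drop = FALSE]
  if (nrow(others) == 0L) {
    stop("structure has no other chain to measure against", call. = FALSE)
  }
  a <- as.matrix(mine[, c("x", "y", "z")])
  b <- as.matrix(others[, c("x", "y", "z")])
  # all-pairs squared distances, small enough to do densely
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  idx <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[idx]), partner = others$chain[idx[2]])
}

#' Flag candidate residues at subunit interfaces
#'
#' Each candidate residue number is looked up in the query chain and flagged
#' as interfacial if its minimum interchain distance is at most `cutoff`.
#' Candidates missing from the structure (e.g. unmodeled loops) are recorded
#' as `"unresolved"` rather than raising an error, so a partial model still
#' yields a report.
#'
#' @param structure A [trimer_structure()].
#' @param candidates Integer vector of residue numbers (reference numbering).
#' @param cutoff Distance cutoff in Angstrom; defaults to 8 in CA mode and 5
#'   in heavy mode.
#' @param atom_mode `"CA"` or `"heavy"`.
#' @param chain Chain to assess (default `"A"`; chains are equivalent under
#'   C3 symmetry).
#' @return Data frame of class `pocket_report` with columns `ref_number`,
#'   `chain`, `status` (`resolved`/`unresolved`), `min_distance`,
#'   `partner_chain`, `interfacial`.
#' @export
detect_interface_residues <- function(structure, candidates, cutoff = NULL,
                                      atom_mode = c("CA", "heavy"),
                                      chain = "A") {
  atom_mode <- match.arg(atom_mode)
  if (is.null(cutoff)) cutoff <- if (atom_mode == "CA") 8 else 5
  assert_scalar(cutoff, "cutoff")
  at <- select_mode(structure$atoms, atom_mode)
  present <- unique(at$resno[at$chain == chain])
  rows <- lapply(sort(unique(as.integer(candidates))), function(rn) {
    if (!rn %in% present) {
      return(data.frame(ref_number = rn, chain = chain, status = "unresolved",
                        min_distance = NA_real_, partner_chain = NA_character_,
                        interfacial = FALSE, stringsAsFactors = FALSE))
    }
    d <- min_interchain_distance(structure, chain, rn, atom_mode)
    data.frame(ref_number = rn, chain = chain, status = "resolved",
               min_distance = d$distance, partner_chain = d$partner,
               interfacial = d$distance <= cutoff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cutoff") <- cutoff
  attr(out, "atom_mode") <- atom_mode
  class(out) <- c("pocket_report", "data.frame")
  out
}

#' Cluster interfacial residues into pockets
#'
#' Single-linkage clustering of the flagged residues' Calpha positions in the
#' query chain: residues within `linkage_cutoff` of each other (directly or
#' through intermediates) form one pocket. Deterministic; singletons allowed.
#'
#' @param report A `pocket_report` from [detect_interface_residues()].
#' @param structure The same [trimer_structure()].
#' @param linkage_cutoff Angstrom (default 12).
#' @param chain Chain whose Calpha coordinates anchor the clustering.
#' @return List of pockets, each a list with `residues` (integer vector) and
#'   `diameter` (max pairwise Calpha distance, 0 for singletons).
#' @export
cluster_pockets <- function(report, structure, linkage_cutoff = 12, chain = "A") {
  flagged <- report$ref_number[report$interfacial %in% TRUE]
  if (length(flagged) == 0L) return(list())
  at <- structure$atoms
  ca <- at[at$chain == chain & at$elety == "CA" & at$resno %in% flagged, , drop = FALSE]
  ca <- ca[match(flagged, ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  if (length(flagged) == 1L) {
    return(list(list(residues = flagged, diameter = 0)))
  }
  d <- stats::dist(xyz)
  grp <- stats::cutree(stats::hclust(d, method = "single"), h = linkage_cutoff)
  dm <- as.matrix(d)
  lapply(unname(split(seq_along(flagged), grp)), function(idx) {
    list(residues = sort(flagged[idx]),
         diameter = if (length(idx) > 1L) max(dm[idx, idx]) else 0)
  })
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure A [trimer_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return Transformed [trimer_structure()].
#' @export
apply_rigid_transform <- function(structure, rotation = diag(3),
                                  translation = c(0, 0, 0)) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
  at$x <- xyz[, 1] + translation[1]
  at$y <- xyz[, 2] + translation[2]
  at$z <- xyz[, 3] + translation[3]
  trimer_structure(at, require_trimer = length(unique(at$chain)) == 3L)
}
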