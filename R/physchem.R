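#' Physicochemical amino-acid classes
#'
#' The six-class scheme used throughout the package, both by the synthetic
#' alignment generator (to plant class-conserved columns) and by the
#' clade-contrast scan (to score class-level conservation). Histidine is
#' grouped with the positives, cysteine with the aliphatics, and glycine and
#' proline are isolated as a "special" class because their backbone behaviour
#' matches neither the aliphatics nor the polars.
#'
#' Classes:
#' * aliphatic: A V L I M C
#' * aromatic:  F W Y
#' * positive:  K R H
#' * negative:  D E
#' * polar:     S T N Q
#' * special:   G P
#'
#' Gaps (`-`) and the ambiguity character `X` belong to no class.
#'
#' @return Named list of character vectors partitioning the 20 standard
#'   residues.
#' @examples
#' physchem_scheme()
#' physchem_class(c("F", "Y", "K", "G", "X", "-"))
#' @export
physchem_scheme <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M", "C"),
    aromatic  = c("F", "W", "Y"),
    positive  = c("K", "R", "H"),
    negative  = c("D", "E"),
    polar     = c("S", "T", "N", "Q"),
    special   = c("G", "P")
  )
}

#' @rdname physchem_scheme
#' @param residues Character vector of one-letter residue codes.
#' @param scheme A class scheme as returned by [physchem_scheme()].
#' @return For `physchem_class`, a character vector of class labels
#'   (`NA` for gaps, `X`, or anything outside the scheme).
#' @export
physchem_class <- function(residues, scheme = physchem_scheme()) {
  lut <- stats::setNames(
    rep(names(scheme), lengths(scheme)),
    unlist(scheme, use.names = FALSE)
  )
  unname(lut[residues])
}

#' The 20 standard amino acids
#' @return Character vector of one-letter codes.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# validate that a scheme partitions the 20 standard residues
validate_scheme <- function(scheme) {
  res <- sort(unlist(scheme, use.names = FALSE))
  if (!identical(res, amino_acids())) {
    stop("physicochemical scheme must partition the 20 standard residues",
         call. = FALSE)
  }
  invisible(scheme)
}
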