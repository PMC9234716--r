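#' Clade-labeled multiple sequence alignment
#'
#' Container pairing a gapped amino-acid alignment with a foreground /
#' background / excluded partition of its rows. The foreground is the clade of
#' interest (e.g. verified peptide-gated channels); the background is every
#' other member of the superfamily in the alignment; excluded rows are carried
#' along but ignored by the scan.
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (one-letter residue codes, `-` for gaps), or an `AAStringSet`.
#' @param labels Named character vector mapping every sequence id to one of
#'   `"foreground"`, `"background"`, `"excluded"`.
#' @return An object of class `clade_alignment` with elements `seqs` and
#'   `labels`.
#' @examples
#' aln <- clade_alignment(
#'   c(f1 = "MKRF", f2 = "MKRF", b1 = "MQLF", b2 = "MQIF"),
#'   c(f1 = "foreground", f2 = "foreground",
#'     b1 = "background", b2 = "background")
#' )
#' aln
#' @export
clade_alignment <- function(seqs, labels) {
  if (!is.character(seqs)) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must carry unique, nonempty names", call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows must all have the same length", call. = FALSE)
  }
  labels <- labels[names(seqs)]
  if (anyNA(labels)) {
    stop("every sequence must be labeled foreground/background/excluded",
         call. = FALSE)
  }
  ok <- labels %in% c("foreground", "background", "excluded")
  if (!all(ok)) {
    stop("labels must be 'foreground', 'background' or 'excluded'", call. = FALSE)
  }
  if (sum(labels == "foreground") < 2L || sum(labels == "background") < 2L) {
    stop("need at least 2 foreground and 2 background sequences", call. = FALSE)
  }
  structure(list(seqs = seqs, labels = stats::setNames(unname(labels), names(seqs))),
            class = "clade_alignment")
}

#' @export
print.clade_alignment <- function(x, ...) {
  tab <- table(factor(x$labels, c("foreground", "background", "excluded")))
  cat(sprintf(
    "clade_alignment: %d sequences x %d columns (%d foreground, %d background, %d excluded)\n",
    length(x$seqs), nchar(x$seqs[[1]]), tab[[1]], tab[[2]], tab[[3]]
  ))
  invisible(x)
}

#' Read and write gapped FASTA alignments
#'
#' Thin wrappers over Biostrings that return/accept plain named character
#' vectors, the representation used throughout the package.
#'
#' @param path File path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read and write clade membership tables
#'
#' Two-column tab-separated files: sequence id and label
#' (`foreground`/`background`/`excluded`), no header comment lines.
#'
#' @param path File path.
#' @return Named character vector of labels.
#' @export
read_clades <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("clade file needs columns 'id' and 'label'", call. = FALSE)
  }
  stats::setNames(df$label, df$id)
}

#' @rdname read_clades
#' @param labels Named character vector of labels.
#' @export
write_clades <- function(labels, path) {
  utils::write.table(
    data.frame(id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Derive clade labels from a newick tree
#'
#' All leaves under the named internal node become the foreground; every
#' other leaf becomes background.
#'
#' @param tree An `ape::phylo` object or path to a newick file.
#' @param foreground_node Label of the internal node defining the foreground
#'   clade.
#' @return Named character vector of labels suitable for [clade_alignment()].
#' @export
clades_from_tree <- function(tree, foreground_node) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.null(tree$node.label)) {
    stop("tree carries no internal node labels", call. = FALSE)
  }
  hit <- which(tree$node.label == foreground_node)
  if (length(hit) != 1L) {
    stop(sprintf("internal node '%s' not found exactly once", foreground_node),
         call. = FALSE)
  }
  node <- length(tree$tip.label) + hit
  fg <- ape::extract.clade(tree, node)$tip.label
  labels <- stats::setNames(rep("background", length(tree$tip.label)), tree$tip.label)
  labels[fg] <- "foreground"
  labels
}
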