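#' Classify alignment columns
#'
#' Counts invariant, variable-but-parsimony-uninformative, and
#' parsimony-informative columns of a multiple sequence alignment.  Gaps and
#' ambiguity codes are ignored when tallying states; a column with at most one
#' observed state (including all-missing columns) is invariant; a column is
#' parsimony informative when at least two states are each carried by at least
#' two sequences; any other variable column is uninformative.
#'
#' @param alignment a character matrix (rows = sequences), a list/vector of
#'   equal-length sequence strings, or an \code{ape} \code{DNAbin} object.
#' @return a list with \code{n_invariant}, \code{n_variable_uninformative},
#'   \code{n_parsimony_informative}; the three sum to the alignment length.
#' @export
classify_sites <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  res <- apply(m, 2, classify_column)
  counts <- table(factor(res, levels = c("inv", "var", "pi")))
  list(n_invariant = unname(counts["inv"]),
       n_variable_uninformative = unname(counts["var"]),
       n_parsimony_informative = unname(counts["pi"]))
}

classify_column <- function(col) {
  col <- toupper(col)
  col <- col[col %in% c("A", "C", "G", "T")]
  if (length(col) == 0) return("inv")
  tab <- table(col)
  if (length(tab) <= 1) return("inv")
  if (sum(tab >= 2) >= 2) return("pi")
  "var"
}

as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    m <- as.character(alignment)
    if (!is.matrix(m)) m <- do.call(rbind, m)
    return(toupper(m))
  }
  if (is.matrix(alignment)) return(alignment)
  if (is.list(alignment)) alignment <- unlist(alignment)
  if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1)
      stopf("ragged alignment: sequence lengths differ (%s)",
            paste(unique(lens), collapse = ", "))
    return(do.call(rbind, strsplit(alignment, "")))
  }
  stopf("unsupported alignment representation")
}

#' Number of quartets among n taxa
#'
#' @param n_taxa number of taxa (>= 4).
#' @return \code{choose(n_taxa, 4)}.
#' @export
count_quartets <- function(n_taxa) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa != round(n_taxa))
    stopf("n_taxa must be a single integer")
  if (n_taxa < 4) stopf("quartets require at least 4 taxa")
  choose(n_taxa, 4)
}
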