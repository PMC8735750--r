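#' Flag outlier SNPs by ordination locus scores
#'
#' Applies the standard-deviation loading rule used in genotype-environment
#' association screens: on each constrained ordination axis, a SNP whose
#' locus score lies more than \code{sd_mult} sample standard deviations from
#' the mean loading of that axis is flagged; the result is the union over
#' axes with per-axis provenance.  The rule is invariant to affine rescaling
#' of any axis.  A zero-variance axis contributes no outliers (with a
#' message).
#'
#' @param loadings numeric matrix of locus scores (SNPs x axes), ideally with
#'   row and column names; a data.frame with an optional \code{snp_id} column
#'   is also accepted.
#' @param sd_mult positive multiplier (default 2.5).
#' @return a data.frame with columns \code{snp_id}, \code{axis},
#'   \code{score}, \code{z} (signed score in SD units), one row per
#'   (outlier, triggering axis).
#' @export
loading_outliers <- function(loadings, sd_mult = 2.5) {
  if (!is.numeric(sd_mult) || length(sd_mult) != 1 || sd_mult <= 0)
    stopf("sd_mult must be a single positive number")
  if (is.data.frame(loadings)) {
    if ("snp_id" %in% names(loadings)) {
      rn <- loadings$snp_id
      loadings <- as.matrix(loadings[setdiff(names(loadings), "snp_id")])
      rownames(loadings) <- rn
    } else loadings <- as.matrix(loadings)
  }
  if (!is.matrix(loadings) || !is.numeric(loadings) || ncol(loadings) < 1)
    stopf("loadings must be a numeric SNP x axis matrix with >= 1 axis")
  if (any(!is.finite(loadings))) stopf("loadings must be finite")
  if (is.null(rownames(loadings)))
    rownames(loadings) <- paste0("snp", seq_len(nrow(loadings)))
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("axis", seq_len(ncol(loadings)))
  out <- list()
  for (a in seq_len(ncol(loadings))) {
    x <- loadings[, a]
    s <- stats::sd(x)                    # sample SD, n-1 denominator
    if (!is.finite(s) || s == 0) {
      message("axis '", colnames(loadings)[a], "' has zero variance; skipped")
      next
    }
    z <- (x - mean(x)) / s
    hit <- abs(z) > sd_mult
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        snp_id = rownames(loadings)[hit], axis = colnames(loadings)[a],
        score = unname(x[hit]), z = unname(z[hit]))
  }
  if (!length(out))
    return(data.frame(snp_id = character(), axis = character(),
                      score = numeric(), z = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign each candidate SNP its strongest environmental predictor
#'
#' Maps every candidate SNP to the environmental variable with which it has
#' the largest absolute Pearson correlation; ties are broken in favour of the
#' first-listed variable (with a message).
#'
#' @param candidates character vector of candidate SNP ids (must all be rows
#'   of \code{corr}).
#' @param corr numeric matrix of SNP x environment correlations with row and
#'   column names.
#' @return a data.frame with columns \code{snp_id}, \code{predictor},
#'   \code{r}; one row per candidate.
#' @export
assign_predictor <- function(candidates, corr) {
  corr <- as.matrix(corr)
  if (is.null(rownames(corr)) || is.null(colnames(corr)))
    stopf("corr must have SNP row names and environment column names")
  miss <- setdiff(candidates, rownames(corr))
  if (length(miss)) stopf("candidate(s) missing from the correlation matrix: %s",
                          paste(miss, collapse = ", "))
  rows <- lapply(candidates, function(id) {
    r <- corr[id, ]
    a <- abs(r)
    best <- which(a == max(a))
    if (length(best) > 1)
      message("tie for SNP '", id, "': keeping first-listed variable '",
              colnames(corr)[best[1]], "'")
    best <- best[1]
    data.frame(snp_id = id, predictor = colnames(corr)[best],
               r = unname(r[best]))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
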