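#' Three-dimensional joint site frequency spectrum
#'
#' Container for a 3D joint SFS over ordered populations.  \code{counts} has
#' shape \code{(n1+1, n2+1, n3+1)} where \code{n_d} is the haploid sample size
#' of axis \code{d}; cell \code{[i+1, j+1, k+1]} holds the (expected) number of
#' sites with derived-allele counts \code{(i, j, k)}.  Masked cells carry no
#' likelihood mass; the fixed cells \code{(0,0,0)} and \code{(n1,n2,n3)} are
#' always masked, and folding masks the major-allele half of the array.
#'
#' @param counts non-negative numeric array (vectors are treated as a
#'   one-population spectrum).
#' @param folded logical, is this a minor-allele (folded) spectrum?
#' @param mask optional logical array of the same shape (\code{TRUE} =
#'   excluded); the always-masked cells are added automatically.
#' @param pop_order character vector of population labels, one per axis.
#' @return an object of class \code{"jsfs3"}.
#' @export
jsfs3 <- function(counts, folded = FALSE, mask = NULL,
                  pop_order = c("DST", "STH", "PLN")) {
  counts <- as.array(counts)
  if (length(dim(counts)) == 1L) dim(counts) <- c(dim(counts), 1L, 1L)
  if (length(dim(counts)) == 2L) dim(counts) <- c(dim(counts), 1L)
  if (length(dim(counts)) != 3L) stopf("counts must be a (vector or) 3D array")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  n <- dim(counts) - 1L
  if (is.null(mask)) mask <- array(FALSE, dim(counts))
  mask <- as.array(mask)
  if (length(dim(mask)) < 3L) dim(mask) <- dim(counts)
  if (!all(dim(mask) == dim(counts))) stopf("mask shape must match counts")
  mask[1, 1, 1] <- TRUE
  mask[n[1] + 1L, n[2] + 1L, n[3] + 1L] <- TRUE
  if (folded) {
    tot <- cell_totals(dim(counts))
    up <- tot > sum(n) / 2
    if (any(counts[up] > 0))
      stopf("spectrum declared folded but carries mass in the major-allele half")
    mask[up] <- TRUE
  }
  counts[mask] <- 0
  if (length(pop_order) != 3L) pop_order <- c(pop_order, paste0(".unused", seq_len(3 - length(pop_order))))
  structure(list(counts = counts, folded = folded, mask = mask,
                 pop_order = pop_order, n_haploid = n),
            class = "jsfs3")
}

# array of i+j+k (0-based derived totals), same shape as the spectrum
cell_totals <- function(dims) {
  i <- slice.index(array(0, dims), 1) - 1L
  j <- slice.index(array(0, dims), 2) - 1L
  k <- slice.index(array(0, dims), 3) - 1L
  i + j + k
}

#' @export
print.jsfs3 <- function(x, ...) {
  cat(sprintf("%s 3D JSFS, n = (%s), pops (%s); total mass %.6g over %d unmasked cells\n",
              if (x$folded) "Folded" else "Unfolded",
              paste(x$n_haploid, collapse = ", "),
              paste(x$pop_order, collapse = ", "),
              sum(x$counts[!x$mask]), sum(!x$mask)))
  invisible(x)
}

#' Total countable mass of a spectrum
#' @param jsfs a \code{\link{jsfs3}}.
#' @return sum of counts over unmasked cells.
#' @export
jsfs_mass <- function(jsfs) sum(jsfs$counts[!jsfs$mask])

#' Normalise a spectrum to unit mass over unmasked cells
#' @param jsfs a \code{\link{jsfs3}}.
#' @return the normalised \code{jsfs3}.
#' @export
normalize_jsfs <- function(jsfs) {
  m <- jsfs_mass(jsfs)
  if (m <= 0) stopf("cannot normalise a spectrum with zero mass")
  jsfs$counts <- jsfs$counts / m
  jsfs
}

#' Fold a joint SFS onto minor-allele counts
#'
#' Cell \code{(i,j,k)} with derived total above \code{n_tot/2} has its mass
#' added to its mirror \code{(n1-i, n2-j, n3-k)}, then is zeroed and masked.
#' Tie cells (total exactly \code{n_tot/2}) are combined with their mirror and
#' the sum assigned to the lexicographically smaller index tuple, the mirror
#' being masked -- a documented convention, since text-file dialects differ.
#'
#' @param jsfs an unfolded \code{\link{jsfs3}}.
#' @return the folded \code{jsfs3}; total countable mass is conserved.
#' @export
fold_jsfs <- function(jsfs) {
  stopifnot(inherits(jsfs, "jsfs3"))
  if (jsfs$folded) stopf("spectrum is already folded")
  n <- jsfs$n_haploid
  ntot <- sum(n)
  cnt <- jsfs$counts
  msk <- jsfs$mask
  dims <- dim(cnt)
  for (i in 0:n[1]) for (j in 0:n[2]) for (k in 0:n[3]) {
    tot <- i + j + k
    if (tot * 2 < ntot) next
    mi <- c(n[1] - i, n[2] - j, n[3] - k)
    self_mirror <- all(mi == c(i, j, k))
    cell <- cbind(i, j, k) + 1L
    mirror <- rbind(mi) + 1L
    if (tot * 2 > ntot) {
      cnt[mirror] <- cnt[mirror] + cnt[cell]
      cnt[cell] <- 0
      msk[cell] <- TRUE
    } else if (!self_mirror) {
      # tie: combined mass to the lexicographically smaller tuple
      smaller <- if (lex_less(c(i, j, k), mi)) cell else mirror
      larger <- if (lex_less(c(i, j, k), mi)) mirror else cell
      if (!msk[larger]) {
        cnt[smaller] <- cnt[smaller] + cnt[larger]
        cnt[larger] <- 0
        msk[larger] <- TRUE
      }
    }
  }
  out <- jsfs3(cnt, folded = TRUE, mask = msk, pop_order = jsfs$pop_order)
  out
}

lex_less <- function(a, b) {
  for (d in seq_along(a)) {
    if (a[d] < b[d]) return(TRUE)
    if (a[d] > b[d]) return(FALSE)
  }
  FALSE
}

#' Hypergeometric down-projection of an unfolded spectrum
#'
#' Standard projection to smaller sample sizes, applied independently per
#' axis: a site with \code{i} derived among \code{n} haploids contributes
#' hypergeometric weights over \code{j} derived among \code{m} resampled
#' haploids.  Mass moved into the newly fixed cells is masked away; otherwise
#' the total expected mass is conserved.
#'
#' @param jsfs an unfolded \code{\link{jsfs3}}.
#' @param target integer vector \code{(m1, m2, m3)} with \code{m_d <= n_d}.
#' @return the projected \code{jsfs3}.
#' @export
project_jsfs <- function(jsfs, target) {
  stopifnot(inherits(jsfs, "jsfs3"))
  if (jsfs$folded) stopf("project an unfolded spectrum, then fold")
  n <- jsfs$n_haploid
  target <- as.integer(target)
  if (length(target) != 3L) stopf("target must have three sizes")
  if (any(target > n)) stopf("cannot project up: target exceeds current sizes")
  if (any(target < 0)) stopf("target sizes must be non-negative")
  if (all(target == n)) return(jsfs)
  arr <- jsfs$counts
  for (d in 1:3) {
    A <- proj_matrix(n[d], target[d])     # (n_d+1) x (m_d+1)
    arr <- tensor_axis(arr, A, d)
  }
  jsfs3(arr, folded = FALSE, pop_order = jsfs$pop_order)
}

proj_matrix <- function(n, m) {
  outer(0:n, 0:m, function(i, j) stats::dhyper(j, i, n - i, m))
}

# multiply axis d of a 3D array by t(A): out[..j..] = sum_i arr[..i..] A[i, j]
tensor_axis <- function(arr, A, d) {
  perm <- c(d, setdiff(1:3, d))
  a <- aperm(arr, perm)
  dm <- dim(a)
  a <- matrix(a, nrow = dm[1])
  out <- crossprod(A, a)                  # (m+1) x rest
  dim(out) <- c(ncol(A), dm[2], dm[3])
  aperm(out, order(perm))
}

#' Build a joint SFS from a genotype table
#'
#' The genotype table is a data.frame with columns \code{locus}, \code{pos}
#' and one column per individual holding derived-allele dosages (0..ploidy,
#' \code{NA} for missing).  Dosages are counted against the declared ancestral
#' allele (for VCF input the REF allele; folding removes the dependence).
#' Missing data are handled by hypergeometric projection to \code{project_to}
#' (or to the full sizes): a site whose observed haploid count in any
#' population falls below the target is dropped with a message.
#'
#' @param genotypes genotype table (see Details) or a \code{\link{locus_set}}.
#' @param pop_map named character vector mapping individual -> population.
#' @param fold fold the spectrum before returning?
#' @param one_per_locus retain only the first biallelic SNP of each locus (in
#'   position order) to minimise linkage disequilibrium?
#' @param project_to optional target haploid sizes \code{(m1, m2, m3)}.
#' @param ploidy haploid dose carried by one individual column (1 = haploid
#'   samples, 2 = diploid genotypes coded 0/1/2).
#' @param pop_order optional population order for the axes; defaults to first
#'   appearance in \code{pop_map}.
#' @return a \code{\link{jsfs3}} whose total mass is the number of retained
#'   segregating sites (after the projection policy).
#' @export
build_jsfs <- function(genotypes, pop_map, fold = FALSE, one_per_locus = FALSE,
                       project_to = NULL, ploidy = 1, pop_order = NULL) {
  if (inherits(genotypes, "locus_set")) {
    if (missing(pop_map)) pop_map <- genotypes$sample_labels
    genotypes <- locus_genotypes(genotypes)
  }
  ind <- setdiff(colnames(genotypes), c("locus", "pos", "anc"))
  if (!length(ind)) stopf("genotype table has no individual columns")
  miss <- setdiff(ind, names(pop_map))
  if (length(miss)) stopf("individual(s) missing from pop_map: %s",
                          paste(miss, collapse = ", "))
  pops <- pop_map[ind]
  if (is.null(pop_order)) pop_order <- unique(unname(pops))
  if (length(pop_order) > 3L) stopf("at most three populations are supported")
  if (!all(pops %in% pop_order)) stopf("pop_order must cover all populations")

  if (one_per_locus && nrow(genotypes)) {
    o <- order(genotypes$locus, genotypes$pos)
    genotypes <- genotypes[o, , drop = FALSE]
    genotypes <- genotypes[!duplicated(genotypes$locus), , drop = FALSE]
  }

  G <- as.matrix(genotypes[, ind, drop = FALSE])
  storage.mode(G) <- "double"
  if (any(G < 0 | G > ploidy, na.rm = TRUE))
    stopf("dosages must lie in 0..ploidy")
  pop_idx <- match(pops, pop_order)
  n_hap <- vapply(seq_along(pop_order), function(d) ploidy * sum(pop_idx == d), 0)
  n_hap <- c(n_hap, rep(0, 3 - length(n_hap)))[1:3]
  target <- if (is.null(project_to)) n_hap else {
    t0 <- as.integer(project_to)
    if (length(t0) != 3L) t0 <- c(t0, rep(0L, 3 - length(t0)))[1:3]
    if (any(t0 > n_hap)) stopf("project_to exceeds available haploid sizes")
    t0
  }
  pop_order3 <- c(pop_order, paste0(".unused", seq_len(3 - length(pop_order))))[1:3]

  arr <- array(0, target + 1L)
  if (nrow(G)) {
    memb <- vapply(seq_along(pop_order), function(d) as.numeric(pop_idx == d),
                   numeric(length(ind)))
    has_na <- rowSums(is.na(G)) > 0
    # complete sites, no projection needed
    Gc <- G[!has_na, , drop = FALSE]
    if (nrow(Gc)) {
      der <- Gc %*% memb
      der <- cbind(der, matrix(0, nrow(der), 3 - ncol(der)))
      if (is.null(project_to)) {
        idx <- der[, 1] + (target[1] + 1) * (der[, 2] + (target[2] + 1) * der[, 3]) + 1
        tab <- tabulate(idx, nbins = length(arr))
        arr <- arr + array(tab, dim(arr))
      } else {
        for (s in seq_len(nrow(der)))
          arr <- arr + site_projection(der[s, ], n_hap, target)
      }
    }
    # incomplete sites: project from observed haploids
    dropped <- 0L
    for (s in which(has_na)) {
      g <- G[s, ]
      ok <- !is.na(g)
      obs <- vapply(1:3, function(d)
        if (d > length(pop_order)) 0 else ploidy * sum(ok & pop_idx == d), 0)
      if (any(obs < target & c(seq_along(target) <= length(pop_order)))) {
        dropped <- dropped + 1L
        next
      }
      der <- vapply(1:3, function(d)
        if (d > length(pop_order)) 0 else sum(g[ok & pop_idx == d]), 0)
      arr <- arr + site_projection(der, obs, target)
    }
    if (dropped > 0)
      message(dropped, " site(s) dropped: unprojectable at the target sizes")
  }
  out <- jsfs3(arr, folded = FALSE, pop_order = pop_order3)
  if (fold) out <- fold_jsfs(out)
  out
}

# expected cell weights for one site: derived counts `der` among observed
# haploids `obs`, projected to `target` per axis
site_projection <- function(der, obs, target) {
  w <- lapply(1:3, function(d)
    stats::dhyper(0:target[d], der[d], obs[d] - der[d], target[d]))
  outer(outer(w[[1]], w[[2]]), w[[3]])
}

#' Stack a locus set into a genotype table
#'
#' @param loci a \code{\link{locus_set}} simulated with the genotype
#'   representation.
#' @return a data.frame with columns \code{locus}, \code{pos} and one 0/1
#'   column per haploid sample.
#' @export
locus_genotypes <- function(loci) {
  stopifnot(inherits(loci, "locus_set"))
  if (is.null(loci$genotypes))
    stopf("locus set carries no genotypes (distance representation)")
  rows <- lapply(seq_len(loci$n_loci), function(l) {
    g <- loci$genotypes[[l]]
    if (nrow(g) == 0) return(NULL)
    data.frame(locus = sprintf("L%05d", l), pos = as.integer(loci$positions[[l]]),
               g, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus = character(), pos = integer())
  rownames(out) <- NULL
  out
}

#' Write / read the SFS text dialect
#'
#' Serialises a \code{\link{jsfs3}} in the dadi/moments flavoured text format:
#' a header line \code{"<d1> <d2> <d3> <folded|unfolded> \"pop1\" ..."}, a line
#' of flattened counts (C order: last axis fastest), and a line of 0/1 mask
#' flags.  \code{read_sfs(write_sfs(x))} reproduces \code{x}; malformed files
#' raise errors naming the offending line.
#'
#' @param jsfs a \code{\link{jsfs3}}.
#' @param path file path.
#' @return \code{read_sfs} returns a \code{\link{jsfs3}};
#'   \code{write_sfs} returns \code{path} invisibly.
#' @export
write_sfs <- function(jsfs, path) {
  stopifnot(inherits(jsfs, "jsfs3"))
  d <- dim(jsfs$counts)
  header <- paste(c(d, if (jsfs$folded) "folded" else "unfolded",
                    sprintf('"%s"', jsfs$pop_order)), collapse = " ")
  flat <- function(a) as.vector(aperm(a, c(3, 2, 1)))
  lines <- c(header,
             paste(formatC(flat(jsfs$counts), format = "g", digits = 17), collapse = " "),
             paste(as.integer(flat(jsfs$mask)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stopf("SFS file truncated: expected 3 lines, found %d", length(lines))
  hdr <- scan(text = lines[1], what = "", quiet = TRUE)
  if (length(hdr) < 4) stopf("line 1: malformed header")
  d <- suppressWarnings(as.integer(hdr[1:3]))
  if (anyNA(d) || any(d < 1)) stopf("line 1: dimensions must be positive integers")
  foldtag <- hdr[4]
  if (!foldtag %in% c("folded", "unfolded"))
    stopf("line 1: expected 'folded' or 'unfolded', got '%s'", foldtag)
  pops <- if (length(hdr) >= 7) hdr[5:7] else c("pop1", "pop2", "pop3")
  ncell <- prod(d)
  vals <- suppressWarnings(as.numeric(scan(text = lines[2], what = "", quiet = TRUE)))
  if (length(vals) != ncell || anyNA(vals))
    stopf("line 2: expected %d numeric counts, found %d", ncell, length(vals))
  mk <- suppressWarnings(as.integer(scan(text = lines[3], what = "", quiet = TRUE)))
  if (length(mk) != ncell || anyNA(mk) || any(!mk %in% 0:1))
    stopf("line 3: expected %d 0/1 mask flags, found %d", ncell, length(mk))
  unflat <- function(v) aperm(array(v, dim = rev(d)), c(3, 2, 1))
  jsfs3(unflat(vals), folded = foldtag == "folded",
        mask = unflat(as.logical(mk)), pop_order = pops)
}
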