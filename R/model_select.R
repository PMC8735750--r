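#' Akaike ranking table
#'
#' Computes \eqn{\Delta AIC = AIC - \min AIC}, relative likelihood
#' \eqn{\exp(-\Delta AIC / 2)} and Akaike weights
#' \eqn{wAIC = relL / \sum relL} for a set of fitted models, sorted by
#' ascending AIC.
#'
#' @param entries either a named numeric vector of AICs, a data.frame with
#'   columns \code{name} (or \code{Model}) and \code{AIC}, or a list of
#'   \code{fit_result} objects.
#' @return a data.frame of class \code{"akaike_table"} with columns
#'   \code{Model}, \code{AIC}, \code{dAIC}, \code{relL}, \code{wAIC}.
#' @export
akaike_table <- function(entries) {
  if (is.list(entries) && length(entries) && inherits(entries[[1]], "fit_result")) {
    aic <- vapply(entries, function(f) f$AIC, 0)
    names(aic) <- vapply(entries, function(f) f$model_name, "")
    entries <- aic
  }
  if (is.data.frame(entries)) {
    nm <- if ("Model" %in% names(entries)) entries$Model else entries$name
    aic <- stats::setNames(entries$AIC, nm)
  } else aic <- entries
  if (length(aic) < 1) stopf("need at least one model entry")
  if (is.null(names(aic)) || any(!nzchar(names(aic))))
    stopf("entries must be named by model")
  if (any(!is.finite(aic))) stopf("AIC values must be finite")
  d <- aic - min(aic)
  relL <- exp(-d / 2)
  w <- relL / sum(relL)
  out <- data.frame(Model = names(aic), AIC = unname(aic), dAIC = unname(d),
                    relL = unname(relL), wAIC = unname(w))
  out <- out[order(out$AIC, out$Model), ]
  rownames(out) <- NULL
  class(out) <- c("akaike_table", "data.frame")
  out
}

#' Akaike-weight confidence set
#'
#' The smallest prefix of the weight-sorted models whose cumulative Akaike
#' weight reaches \code{level}.
#'
#' @param table an \code{\link{akaike_table}}.
#' @param level confidence level in (0, 1].
#' @return character vector of model names in the set.
#' @export
confidence_set <- function(table, level = 0.95) {
  stopifnot(inherits(table, "akaike_table"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1)
    stopf("level must lie in (0, 1]")
  o <- order(-table$wAIC)
  cum <- cumsum(table$wAIC[o])
  n_keep <- which(cum >= level - 1e-12)[1]
  if (is.na(n_keep)) n_keep <- nrow(table)
  table$Model[o][seq_len(n_keep)]
}

#' Bootstrap joint spectra by resampling loci
#'
#' Nonparametric bootstrap with the locus as the resampling unit: each
#' replicate draws loci with replacement up to the original locus count and
#' rebuilds the spectrum.  With one retained SNP per locus this coincides
#' with multinomially resampling the observed SNPs
#' (\code{\link{bootstrap_jsfs}}).
#'
#' @param genotypes genotype table (or a \code{\link{locus_set}}).
#' @param pop_map named individual -> population vector.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param ... passed to \code{\link{build_jsfs}} (e.g. \code{fold},
#'   \code{one_per_locus}, \code{project_to}).
#' @return a list of \code{B} \code{\link{jsfs3}} objects.
#' @export
bootstrap_spectra <- function(genotypes, pop_map, B, seed = 1, ...) {
  if (inherits(genotypes, "locus_set")) {
    if (missing(pop_map)) pop_map <- genotypes$sample_labels
    genotypes <- locus_genotypes(genotypes)
  }
  if (B < 1) stopf("B must be >= 1")
  loci <- unique(genotypes$locus)
  if (length(loci) < 2) stopf("bootstrap needs at least 2 loci")
  with_seed(seed, lapply(seq_len(B), function(b) {
    take <- sample(loci, length(loci), replace = TRUE)
    rows <- lapply(seq_along(take), function(i) {
      g <- genotypes[genotypes$locus == take[i], , drop = FALSE]
      g$locus <- sprintf("B%05d", i)     # keep resampled copies distinct
      g
    })
    build_jsfs(do.call(rbind, rows), pop_map, ...)
  }))
}

#' Multinomial bootstrap of an observed spectrum
#'
#' Resamples the observed SNPs with replacement (the locus-level bootstrap in
#' the one-SNP-per-locus regime): each replicate is a multinomial draw of the
#' observed total mass from the observed cell frequencies.
#'
#' @param obs observed \code{\link{jsfs3}} with integer-like counts.
#' @param B number of replicates.
#' @param seed RNG seed.
#' @return a list of \code{B} \code{\link{jsfs3}} objects.
#' @export
bootstrap_jsfs <- function(obs, B, seed = 1) {
  stopifnot(inherits(obs, "jsfs3"))
  if (B < 1) stopf("B must be >= 1")
  keep <- !obs$mask
  n <- round(sum(obs$counts[keep]))
  pr <- obs$counts[keep] / sum(obs$counts[keep])
  with_seed(seed, lapply(seq_len(B), function(b) {
    cnt <- obs$counts
    cnt[keep] <- as.numeric(stats::rmultinom(1, n, pr))
    jsfs3(cnt, folded = obs$folded, mask = obs$mask, pop_order = obs$pop_order)
  }))
}

#' Godambe-adjusted likelihood-ratio test between nested model fits
#'
#' For composite (non-independent) likelihoods the usual LRT statistic
#' \eqn{D = 2(\ell_{full} - \ell_{nested})} is miscalibrated; following the
#' Godambe-information approach, \eqn{D} is rescaled by
#' \eqn{df / tr(J H^{-1})} where \eqn{H} is the observed information and
#' \eqn{J} the bootstrap variance of the score, both taken with respect to
#' the parameters fixed by the nesting and evaluated at the nested optimum
#' embedded in the full model.  Because the fixed migration rates sit on the
#' boundary of the parameter space, the default null is the 50:50 mixture
#' \eqn{\chi^2_0 : \chi^2_{df}}; a non-positive adjusted statistic yields
#' \eqn{p = 1}.
#'
#' @param fit_full,fit_nested \code{fit_result} objects for the full and
#'   nested models (the nested model's free parameters must be a subset of
#'   the full model's).
#' @param boot list of bootstrap spectra (from \code{\link{bootstrap_spectra}}
#'   or \code{\link{bootstrap_jsfs}}).
#' @param nested_map named list/vector giving the full-model parameters fixed
#'   by the nesting and their fixed values (e.g. \code{c(mDS = 0)}).
#' @param obs the observed \code{\link{jsfs3}} both models were fitted to.
#' @param eps finite-difference step for scores/Hessians, in the natural
#'   units of the fixed parameters (absolute, one-sided at a zero boundary).
#' @param boundary use the 50:50 boundary mixture null (default) instead of a
#'   plain \eqn{\chi^2_{df}}?
#' @return an object of class \code{"lrt_result"} with \code{D},
#'   \code{D_adj}, \code{df}, \code{p_value}, \code{n_boot},
#'   \code{adjustment}.
#' @export
lrt_godambe <- function(fit_full, fit_nested, boot, nested_map, obs,
                        eps = 0.01, boundary = TRUE) {
  stopifnot(inherits(fit_full, "fit_result"), inherits(fit_nested, "fit_result"))
  fixed <- names(nested_map)
  pn_full <- model_params(fit_full$model_name)
  pn_nested <- model_params(fit_nested$model_name)
  if (!all(fixed %in% pn_full))
    stopf("nested_map names must be full-model parameters")
  if (!setequal(setdiff(pn_full, fixed), pn_nested))
    stopf("models are not nested via nested_map: free full-model parameters %s vs nested %s",
          paste(setdiff(pn_full, fixed), collapse = ","),
          paste(pn_nested, collapse = ","))
  df <- length(fixed)
  D <- 2 * (fit_full$lnL - fit_nested$lnL)

  # nested optimum embedded in the full parameter space
  p0 <- stats::setNames(numeric(length(pn_full)), pn_full)
  p0[pn_nested] <- fit_nested$params[pn_nested]
  p0[fixed] <- unlist(nested_map)

  spectrum_at <- function(p) {
    expected_sfs(fit_full$model_name, p, obs$n_haploid, fold = obs$folded,
                 n_reps = fit_full$n_reps, seed = fit_full$crn_seed)
  }
  ll <- function(spec, data) multinomial_loglik(data, spec)

  # spectra needed for forward-difference scores and Hessian in the fixed
  # directions (shared across bootstrap replicates: the data enter only
  # through the inner product of counts with log-probabilities)
  base <- spectrum_at(p0)
  shift1 <- shift2 <- vector("list", df)
  for (a in seq_len(df)) {
    p1 <- p0; p1[fixed[a]] <- p1[fixed[a]] + eps
    shift1[[a]] <- spectrum_at(p1)
    p2 <- p0; p2[fixed[a]] <- p2[fixed[a]] + 2 * eps
    shift2[[a]] <- spectrum_at(p2)
  }
  cross <- NULL
  if (df > 1) {
    cross <- matrix(list(), df, df)
    for (a in seq_len(df - 1)) for (b in (a + 1):df) {
      p12 <- p0
      p12[fixed[a]] <- p12[fixed[a]] + eps
      p12[fixed[b]] <- p12[fixed[b]] + eps
      cross[[a, b]] <- spectrum_at(p12)
    }
  }
  hess_of <- function(data) {
    l0 <- ll(base, data)
    l1 <- vapply(shift1, ll, 0, data = data)
    l2 <- vapply(shift2, ll, 0, data = data)
    H <- matrix(0, df, df)
    for (a in seq_len(df)) H[a, a] <- (l2[a] - 2 * l1[a] + l0) / eps^2
    if (df > 1) for (a in seq_len(df - 1)) for (b in (a + 1):df) {
      lab <- ll(cross[[a, b]], data)
      H[a, b] <- H[b, a] <- (lab - l1[a] - l1[b] + l0) / eps^2
    }
    H
  }
  score_of <- function(data) {
    l0 <- ll(base, data)
    vapply(seq_len(df), function(a) (ll(shift1[[a]], data) - l0) / eps, 0)
  }

  H <- -hess_of(obs)                                   # observed information
  U <- do.call(rbind, lapply(boot, score_of))          # n_boot x df
  J <- stats::cov(U) * (nrow(U) - 1) / nrow(U)
  if (df == 1) J <- matrix(J, 1, 1)
  tr <- sum(diag(J %*% solve(H)))
  adjustment <- df / tr
  D_adj <- adjustment * D

  # a non-positive raw statistic carries no evidence for the full model, and
  # a non-positive adjusted statistic is treated the same way
  p_value <- if (!is.finite(D_adj) || D_adj <= 0 || D <= 0) 1 else {
    tail <- stats::pchisq(D_adj, df = df, lower.tail = FALSE)
    if (boundary) 0.5 * tail else tail
  }
  structure(list(D = D, D_adj = D_adj, df = df, p_value = p_value,
                 n_boot = length(boot), adjustment = adjustment),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Godambe-adjusted LRT: D = %.3f, D_adj = %.3f (df = %d), p = %.4g [%d bootstraps]\n",
              x$D, x$D_adj, x$df, x$p_value, x$n_boot))
  invisible(x)
}
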