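#' Expected joint SFS of a registered model
#'
#' Normalised expected spectrum of a registered demographic model at concrete
#' parameter values, computed by the genealogy branch-length Monte Carlo
#' engine (\code{\link{branch_spectrum}}).  Fixing \code{(seed, n_reps)} makes
#' the map from parameters to spectrum deterministic (common random numbers),
#' which is what the staged optimiser relies on.
#'
#' @param model model name (see \code{\link{list_models}}).
#' @param params named or ordered parameter vector.
#' @param sizes haploid sample sizes \code{(n1, n2, n3)} for (DST, STH, PLN).
#' @param fold return the folded spectrum?
#' @param n_reps genealogy replicates per evaluation.
#' @param seed RNG seed for the common-random-number stream.
#' @return a normalised \code{\link{jsfs3}}.
#' @export
expected_sfs <- function(model, params, sizes, fold = TRUE,
                         n_reps = 2000, seed = 1) {
  dem <- model_demography(model, params)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 1)) stopf("sizes must be three positive counts")
  cfg <- pop_config(n_samples = c(DST = sizes[1], STH = sizes[2], PLN = sizes[3]),
                    n_loci = 1, locus_len = 1, mut_scale = 1, seed = seed)
  sp <- branch_spectrum(dem, cfg, n_reps = n_reps)
  if (fold) sp <- normalize_jsfs(fold_jsfs(sp))
  sp
}

#' Multinomial composite log-likelihood of an observed spectrum
#'
#' \eqn{\ell = \sum_c n_c \log p_c} over unmasked cells, with expected
#' probabilities floored at \code{1e-300} so observed mass on an empty model
#' cell yields a large negative but finite value.  The parameter-independent
#' multinomial coefficient is omitted (it cancels from all model
#' comparisons).
#'
#' @param obs observed \code{\link{jsfs3}} (counts).
#' @param expected normalised model \code{\link{jsfs3}} of the same shape,
#'   folding state and population order.
#' @return the composite log-likelihood (a scalar).
#' @export
multinomial_loglik <- function(obs, expected) {
  stopifnot(inherits(obs, "jsfs3"), inherits(expected, "jsfs3"))
  if (!all(dim(obs$counts) == dim(expected$counts)))
    stopf("spectrum shapes differ")
  if (isTRUE(obs$folded) != isTRUE(expected$folded))
    stopf("folding states differ")
  keep <- !(obs$mask | expected$mask)
  p <- pmax(expected$counts[keep], 1e-300)
  sum(obs$counts[keep] * log(p))
}

default_schedule <- function() {
  list(replicates = c(10L, 20L, 30L, 40L),
       maxiter = c(3L, 5L, 10L, 15L),
       fold = c(3, 2, 2, 1))
}

#' Fit a demographic model to an observed joint SFS
#'
#' Staged stochastic optimisation of the multinomial composite likelihood:
#' consecutive rounds of multiple replicate searches, each replicate a
#' Nelder-Mead simplex in log-parameter space started from the incumbent best
#' perturbed by up to a factor \code{2^fold}, with the per-replicate iteration
#' cap and the perturbation fold shrinking over rounds (defaults: replicates
#' 10/20/30/40, maxiter 3/5/10/15, fold 3/2/2/1).  All parameters are searched
#' within \code{[lower, upper]} in relative units.  Model evaluations use
#' common random numbers, so the fit is deterministic given \code{seed}.
#'
#' @param obs observed \code{\link{jsfs3}}; model spectra are evaluated with
#'   the same folding state.
#' @param model model name.
#' @param seed integer seed controlling both the search perturbations and the
#'   common-random-number likelihood surface.
#' @param n_reps genealogy replicates per likelihood evaluation; a scalar or
#'   one value per round (the last value is also used for the reported fit).
#' @param schedule list with \code{replicates}, \code{maxiter}, \code{fold}.
#' @param start optional named start vector (defaults to all ones).
#' @param lower,upper box bounds for all parameters.
#' @param polish refine the staged best by a compass (pattern) search before
#'   reporting?  The common-random-number surface carries Monte-Carlo
#'   roughness at small parameter scales that stalls simplex moves near
#'   convergence; a coordinate/scale pattern search with shrinking step sizes
#'   (\code{polish_steps}, in log units) at higher precision
#'   (\code{polish_reps} genealogy replicates) is robust to it.  The move set
#'   includes the all-parameter scaling direction, the softest mode of
#'   normalised-spectrum fits.
#' @param polish_steps decreasing log-space step sizes for the pattern search.
#' @param polish_reps genealogy replicates used during polishing and for the
#'   reported log-likelihood (default: eight times the final-round
#'   \code{n_reps}).
#' @param polish_cycles number of pattern-search passes; passes after the
#'   first are preceded by a short Nelder-Mead run, which travels diagonal
#'   valleys the coordinate moves cannot, while the next pattern pass
#'   escapes the simplex's noise-induced stalls.
#' @return an object of class \code{"fit_result"}: fitted \code{params},
#'   \code{lnL}, \code{k}, \code{AIC = 2k - 2 lnL}, \code{theta_hat} (the
#'   observed total mass, i.e. the multinomial scale), \code{schedule_log}.
#' @export
fit_model <- function(obs, model, seed, n_reps = 2000,
                      schedule = default_schedule(), start = NULL,
                      lower = 1e-3, upper = 1e3, polish = TRUE,
                      polish_steps = c(0.3, 0.15, 0.08, 0.04),
                      polish_reps = NULL, polish_cycles = 1) {
  stopifnot(inherits(obs, "jsfs3"))
  pn <- model_params(model)
  k <- length(pn)
  sizes <- obs$n_haploid
  crn_seed <- (as.double(seed) + 99991) %% 2147483647
  llo <- log(lower); lup <- log(upper)

  make_nll <- function(nr) {
    function(logp) {
      viol <- sum(pmax(0, logp - lup)^2) + sum(pmax(0, llo - logp)^2)
      if (viol > 0) return(1e12 * (1 + viol))
      sp <- tryCatch(
        expected_sfs(model, stats::setNames(exp(logp), pn), sizes,
                     fold = obs$folded, n_reps = nr, seed = crn_seed),
        error = function(e) NULL)
      if (is.null(sp)) return(1e12)
      -multinomial_loglik(obs, sp)
    }
  }

  n_rounds <- length(schedule$replicates)
  nr_round <- rep(n_reps, length.out = n_rounds)
  best_p <- if (is.null(start)) stats::setNames(rep(1, k), pn) else {
    s <- start[pn]
    if (anyNA(s)) stopf("start must provide all parameters of %s", model)
    pmin(pmax(s, lower), upper)
  }
  set.seed(seed)
  best_val <- Inf
  schedule_log <- numeric(0)
  n_ok <- 0L
  for (r in seq_len(n_rounds)) {
    nll <- make_nll(nr_round[r])
    best_val <- nll(log(best_p))
    for (j in seq_len(schedule$replicates[r])) {
      p0 <- best_p * 2^stats::runif(k, -schedule$fold[r], schedule$fold[r])
      p0 <- pmin(pmax(p0, lower), upper)
      o <- tryCatch(
        stats::optim(log(p0), nll, method = "Nelder-Mead",
                     control = list(maxit = schedule$maxiter[r])),
        error = function(e) NULL)
      if (is.null(o)) next
      n_ok <- n_ok + 1L
      if (o$value < best_val) {
        best_val <- o$value
        best_p <- stats::setNames(exp(o$par), pn)
      }
    }
    schedule_log <- c(schedule_log, best_val)
  }
  if (n_ok == 0L) {
    cond <- simpleError("optimization failed in every replicate")
    cond$partial <- list(params = best_p, value = best_val)
    stop(cond)
  }
  final_reps <- nr_round[n_rounds]
  if (polish) {
    final_reps <- polish_reps %||% (8L * nr_round[n_rounds])
    nll_p <- make_nll(final_reps)
    dirs <- rbind(diag(k), -diag(k), rep(1, k), rep(-1, k))
    run_compass <- function(x) {
      fx <- nll_p(x)
      for (cycle in seq_len(max(1, polish_cycles))) {
        if (cycle > 1) {
          o <- tryCatch(stats::optim(x, nll_p, method = "Nelder-Mead",
                                     control = list(maxit = 100)),
                        error = function(e) NULL)
          if (!is.null(o) && o$value < fx) { x <- o$par; fx <- o$value }
        }
        for (h in polish_steps) {
          for (sweep in 1:25) {
            improved <- FALSE
            for (d in seq_len(nrow(dirs))) {
              xx <- x + h * dirs[d, ]
              fxx <- nll_p(xx)
              if (fxx < fx - 1e-9) { x <- xx; fx <- fxx; improved <- TRUE }
            }
            if (!improved) break
          }
        }
      }
      list(x = x, f = fx)
    }
    # polish from the staged best and (if distinct) from the original start:
    # the rough surface has far-apart local basins, and the staged phase can
    # commit to a poor one
    start_p <- if (is.null(start)) stats::setNames(rep(1, k), pn) else
      pmin(pmax(start[pn], lower), upper)
    cands <- list(log(best_p))
    if (max(abs(log(start_p) - log(best_p))) > 1e-8)
      cands <- c(cands, list(log(unname(start_p) * 1)))
    res <- lapply(cands, run_compass)
    bi <- which.min(vapply(res, function(r) r$f, 0))
    best_p <- stats::setNames(exp(res[[bi]]$x), pn)
    best_val <- res[[bi]]$f
  }
  lnL <- -make_nll(final_reps)(log(best_p))
  structure(list(model_name = model, params = best_p, lnL = lnL, k = k,
                 AIC = 2 * k - 2 * lnL, theta_hat = jsfs_mass(obs),
                 seed = seed, n_reps = final_reps,
                 crn_seed = crn_seed, folded = obs$folded,
                 sizes = sizes, schedule_log = schedule_log),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of %s: lnL = %.3f, k = %d, AIC = %.2f\n",
              x$model_name, x$lnL, x$k, x$AIC))
  print(signif(x$params, 4))
  invisible(x)
}

#' Composite log-likelihood of a model at given parameters
#'
#' Convenience wrapper evaluating \code{\link{multinomial_loglik}} at the
#' expected spectrum of a registered model.
#'
#' @inheritParams fit_model
#' @param params named parameter vector.
#' @return scalar log-likelihood.
#' @export
model_loglik <- function(obs, model, params, n_reps = 2000, seed = 1) {
  sp <- expected_sfs(model, params, obs$n_haploid, fold = obs$folded,
                     n_reps = n_reps, seed = seed)
  multinomial_loglik(obs, sp)
}
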