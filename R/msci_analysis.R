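#' Per-locus pairwise divergence summary
#'
#' Raw proportion distances (differences per site, no multiple-hit
#' correction, consistent with infinite-sites simulation) between all sample
#' pairs at every locus, with between-side minima and means.  The global
#' between-side minimum over all loci and all pairs is the operational version
#' of the smallest cross-population sequence divergence, which under the
#' coalescent bounds the relevant divergence/introgression time from above
#' (divided by two).
#'
#' @param loci a \code{\link{locus_set}} (either representation).
#' @param side1,side2 optional character vectors of population labels defining
#'   the two (possibly pooled) sides; when omitted only the full distance
#'   matrices and within-population means are computed.
#' @return an object of class \code{"divergence_summary"}: \code{d_matrix}
#'   (per-locus distance matrices), \code{d_mean_within} (named per
#'   population), and when sides are given \code{d_min_between},
#'   \code{d_mean_between} and the per-locus cross minima.
#' @export
divergence_summary <- function(loci, side1 = NULL, side2 = NULL) {
  stopifnot(inherits(loci, "locus_set"))
  if (loci$n_loci < 1) stopf("need at least one locus")
  dm <- pairwise_distances(loci)
  labels <- loci$sample_labels
  pops <- unique(unname(labels))
  within <- vapply(pops, function(p) {
    idx <- which(labels == p)
    if (length(idx) < 2) return(NA_real_)
    mean(vapply(dm, function(D) mean(D[idx, idx][upper.tri(D[idx, idx])]), 0))
  }, 0)
  out <- list(d_matrix = dm, sample_labels = labels,
              d_mean_within = within[!is.na(within)])
  if (!is.null(side1) || !is.null(side2)) {
    i1 <- which(labels %in% side1)
    i2 <- which(labels %in% side2)
    if (!length(i1) || !length(i2)) stopf("each side needs at least one sample")
    per_min <- vapply(dm, function(D) min(D[i1, i2]), 0)
    per_mean <- vapply(dm, function(D) mean(D[i1, i2]), 0)
    out$side1 <- side1; out$side2 <- side2
    out$per_locus_min <- per_min
    out$per_locus_mean <- per_mean
    out$d_min_between <- min(per_min)
    out$d_mean_between <- mean(per_mean)
  }
  class(out) <- "divergence_summary"
  out
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Divergence summary over %d loci\n", length(x$d_matrix)))
  if (!is.null(x$d_min_between))
    cat(sprintf("  %s vs %s: d_min = %.3g, d_mean = %.3g\n",
                paste(x$side1, collapse = "+"), paste(x$side2, collapse = "+"),
                x$d_min_between, x$d_mean_between))
  if (length(x$d_mean_within))
    cat("  within:", paste(sprintf("%s=%.3g", names(x$d_mean_within),
                                   x$d_mean_within), collapse = " "), "\n")
  invisible(x)
}

# per-locus distance matrices for either representation
pairwise_distances <- function(loci) {
  if (!is.null(loci$distances)) return(loci$distances)
  if (is.null(loci$genotypes))
    stopf("locus set carries neither genotypes nor distances")
  L <- loci$locus_len
  lapply(loci$genotypes, function(g) {
    if (nrow(g) == 0) {
      n <- ncol(g)
      D <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
      return(D)
    }
    cnt <- colSums(g)
    XtX <- crossprod(g)
    D <- (outer(cnt, cnt, "+") - 2 * XtX) / L
    diag(D) <- 0
    D
  })
}

#' Remove samples from a locus set
#'
#' @param loci a \code{\link{locus_set}}.
#' @param drop character vector of sample names to remove.
#' @return the reduced \code{locus_set} (same underlying data).
#' @export
drop_samples <- function(loci, drop) {
  stopifnot(inherits(loci, "locus_set"))
  keep <- setdiff(names(loci$sample_labels), drop)
  if (!length(keep)) stopf("cannot drop all samples")
  if (!is.null(loci$genotypes))
    loci$genotypes <- lapply(loci$genotypes, function(g) g[, keep, drop = FALSE])
  if (!is.null(loci$distances))
    loci$distances <- lapply(loci$distances, function(D) D[keep, keep, drop = FALSE])
  if (!is.null(loci$coal_times))
    loci$coal_times <- lapply(loci$coal_times, function(D) D[keep, keep, drop = FALSE])
  loci$sample_labels <- loci$sample_labels[keep]
  loci
}

#' Moment estimators of MSC parameters from divergence summaries
#'
#' Ignoring gene flow, between-population per-locus distances behave like a
#' shifted exponential: \eqn{d = 2\tau + e} with \eqn{e} the (mutation-scaled)
#' extra coalescent time in the ancestor, of mean \eqn{\theta_{anc}}.  The
#' location/scale estimators are \eqn{\hat\tau = d_{min}/2} and
#' \eqn{\hat\theta_{anc} = \overline{d} - d_{min}}; within-population
#' diversity estimates each \eqn{\hat\theta_{pop}}.  The inner node uses the
#' (STH, PLN) pair and the root uses DST against the pooled STH+PLN sample,
#' on the fixed topology ((STH, PLN), DST).
#'
#' @param loci a \code{\link{locus_set}} (or a precomputed full
#'   \code{\link{divergence_summary}} of one).
#' @return a list of estimates: \code{tau_root}, \code{tau_inner},
#'   \code{theta_pop} (named per population), \code{theta_anc} (inner node)
#'   and \code{theta_anc_root}.
#' @export
msc_moment_fit <- function(loci) {
  if (inherits(loci, "locus_set")) {
    if (loci$n_loci < 2) stopf("moment estimation needs at least 2 loci")
    summ <- divergence_summary(loci)
  } else if (inherits(loci, "divergence_summary")) summ <- loci
  else stopf("expected a locus_set or divergence_summary")
  if (length(summ$d_matrix) < 2) stopf("moment estimation needs at least 2 loci")
  labels <- summ$sample_labels

  cross <- function(side1, side2) {
    i1 <- which(labels %in% side1); i2 <- which(labels %in% side2)
    if (!length(i1) || !length(i2)) stopf("missing samples for %s vs %s",
                                          paste(side1, collapse = "+"),
                                          paste(side2, collapse = "+"))
    mins <- vapply(summ$d_matrix, function(D) min(D[i1, i2]), 0)
    means <- vapply(summ$d_matrix, function(D) mean(D[i1, i2]), 0)
    c(dmin = min(mins), dmean = mean(means))
  }
  inner <- cross("STH", "PLN")
  root <- cross("DST", c("STH", "PLN"))
  list(tau_root = unname(root["dmin"]) / 2,
       tau_inner = unname(inner["dmin"]) / 2,
       theta_pop = summ$d_mean_within,
       theta_anc = unname(inner["dmean"] - inner["dmin"]),
       theta_anc_root = unname(root["dmean"] - root["dmin"]))
}

#' Ignored-gene-flow bias experiment
#'
#' Simulates multilocus data under the introgression (MSci) model and
#' estimates divergence times and population sizes with the no-gene-flow
#' moment estimators (\code{\link{msc_moment_fit}}), recording signed errors
#' per replicate.  A control arm with all introgression probabilities set to
#' zero is always run alongside the treatment arm.  The expected outcome when
#' gene flow is present but ignored is that divergence times are
#' underestimated and ancestral population sizes overestimated.
#'
#' @param msci_params treatment-arm \code{\link{msci_params}}; at least one
#'   \eqn{\phi} must be positive.
#' @param config a \code{\link{pop_config}}; replicate seeds are derived from
#'   \code{seed}.
#' @param n_replicates number of replicates per arm (>= 5).
#' @param seed integer seed.
#' @return an object of class \code{"bias_report"}: a per-replicate
#'   data.frame of estimates and truths plus one-sided sign-test p-values for
#'   the two directional claims in the treatment arm.
#' @export
bias_experiment <- function(msci_params, config, n_replicates = 20, seed = 1) {
  stopifnot(inherits(msci_params, "msci_params"), inherits(config, "pop_config"))
  if (n_replicates < 5) stopf("need at least 5 replicates")
  phis <- c(msci_params$phi_A, msci_params$phi_B, msci_params$phi_C, msci_params$phi_D)
  if (all(phis == 0)) stopf("treatment arm requires at least one positive phi")
  control <- msci_params
  control$phi_A <- control$phi_B <- control$phi_C <- control$phi_D <- 0

  truth <- list(tau_root = msci_params$tau_S, tau_inner = msci_params$tau_T,
                theta_anc = unname(msci_params$theta["T"]),
                theta_pop = msci_params$theta[c("DST", "STH", "PLN")])

  run_arm <- function(params, arm) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      cfg <- config
      cfg$seed <- as.integer((as.double(seed) + 10007 * r +
                                1e6 * (arm == "treatment")) %% 2147483647)
      est <- msc_moment_fit(simulate_msci(params, cfg, representation = "distances"))
      data.frame(arm = arm, replicate = r,
                 tau_root_hat = unname(est$tau_root),
                 tau_inner_hat = unname(est$tau_inner),
                 theta_anc_hat = est$theta_anc,
                 theta_DST_hat = unname(est$theta_pop["DST"]),
                 theta_STH_hat = unname(est$theta_pop["STH"]),
                 theta_PLN_hat = unname(est$theta_pop["PLN"]))
    }))
  }
  res <- rbind(run_arm(msci_params, "treatment"), run_arm(control, "control"))
  tr <- res[res$arm == "treatment", ]
  n_tau_under <- sum(tr$tau_inner_hat < truth$tau_inner)
  n_theta_over <- sum(tr$theta_anc_hat > truth$theta_anc)
  p_tau <- stats::binom.test(n_tau_under, n_replicates, 0.5, alternative = "greater")$p.value
  p_theta <- stats::binom.test(n_theta_over, n_replicates, 0.5, alternative = "greater")$p.value
  structure(list(replicates = res, truth = truth, n_replicates = n_replicates,
                 seed = seed,
                 n_tau_inner_under = n_tau_under, n_theta_anc_over = n_theta_over,
                 p_tau_inner_under = p_tau, p_theta_anc_over = p_theta),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("Ignored-gene-flow bias experiment (%d replicates per arm)\n",
              x$n_replicates))
  cat(sprintf("  treatment: tau_inner underestimated in %d/%d (sign test p = %.3g)\n",
              x$n_tau_inner_under, x$n_replicates, x$p_tau_inner_under))
  cat(sprintf("  treatment: theta_anc overestimated in %d/%d (sign test p = %.3g)\n",
              x$n_theta_anc_over, x$n_replicates, x$p_theta_anc_over))
  invisible(x)
}

#' Sensitivity of divergence estimates to one recently admixed sample
#'
#' Simulates data including one recent hybrid individual
#' (\code{\link{hybrid_spec}}) and compares the minimum cross-population
#' divergence and the moment estimates computed on the same data with and
#' without the hybrid.  Because divergence-time estimators are driven by the
#' minimum rather than the average divergence, the hybrid's donor-derived
#' loci (with within-population-scale distances) drag the estimates down.
#'
#' @param msci_params an \code{\link{msci_params}} object.
#' @param config a \code{\link{pop_config}}.
#' @param hybrid a \code{\link{hybrid_spec}}.
#' @param n_replicates paired replicates to run.
#' @param seed integer seed.
#' @return a data.frame with per-replicate paired statistics:
#'   \code{d_min_with}/\code{d_min_without} (host vs donor populations),
#'   \code{tau_root_with}/\code{without} and \code{tau_inner_with}/
#'   \code{without}.
#' @export
hybrid_sensitivity <- function(msci_params, config, hybrid,
                               n_replicates = 20, seed = 1) {
  stopifnot(inherits(hybrid, "hybrid_spec"))
  donor <- setdiff(hybrid$parent_pops, hybrid$host_pop)[1]
  if (is.na(donor)) donor <- hybrid$parent_pops[1]
  do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer((as.double(seed) + 20011 * r) %% 2147483647)
    with_h <- simulate_msci(msci_params, cfg, hybrid = hybrid,
                            representation = "distances")
    without_h <- drop_samples(with_h, paste0(hybrid$host_pop, "_hyb"))
    s_w <- divergence_summary(with_h, hybrid$host_pop, donor)
    s_o <- divergence_summary(without_h, hybrid$host_pop, donor)
    e_w <- msc_moment_fit(with_h)
    e_o <- msc_moment_fit(without_h)
    data.frame(replicate = r,
               d_min_with = s_w$d_min_between, d_min_without = s_o$d_min_between,
               tau_root_with = unname(e_w$tau_root),
               tau_root_without = unname(e_o$tau_root),
               tau_inner_with = unname(e_w$tau_inner),
               tau_inner_without = unname(e_o$tau_inner))
  }))
}

# Calibration ---------------------------------------------------------------

#' Calibration configuration
#'
#' Defaults: substitution rate 0.0008 substitutions/site/My (a slow squamate
#' genome-wide rate), generation time 2 years, and an external calibration
#' divergence of 20 My for deriving empirical rates.
#'
#' @param mu_per_My substitutions per site per million years.
#' @param gen_time_yr generation time in years.
#' @param calib_T_My external calibration divergence time in My.
#' @return an object of class \code{"calibration_config"}.
#' @export
calibration_config <- function(mu_per_My = 0.0008, gen_time_yr = 2,
                               calib_T_My = 20) {
  if (mu_per_My <= 0 || gen_time_yr <= 0 || calib_T_My <= 0)
    stopf("all calibration constants must be positive")
  structure(list(mu_per_My = mu_per_My, gen_time_yr = gen_time_yr,
                 calib_T_My = calib_T_My), class = "calibration_config")
}

#' Convert a mutation-scaled node age to millions of years
#'
#' \eqn{T_{My} = \tau / \mu_{My}} where \eqn{\tau} is in expected
#' substitutions per site.
#'
#' @param tau node age(s) in expected substitutions per site (>= 0).
#' @param cal a \code{\link{calibration_config}}.
#' @return time(s) in My.
#' @export
calibrate_time <- function(tau, cal = calibration_config()) {
  if (any(tau < 0)) stopf("tau must be non-negative")
  tau / cal$mu_per_My
}

#' Convert a mutation-scaled population size to an effective size
#'
#' \eqn{N_e = \theta / (4 \mu g)} with \eqn{\mu} per site per year and
#' \eqn{g} the generation time in years (\eqn{\theta = 4 N \mu} per site).
#'
#' @param theta population-size parameter(s), expected substitutions per site.
#' @param cal a \code{\link{calibration_config}}.
#' @return effective population size(s), in individuals.
#' @export
calibrate_Ne <- function(theta, cal = calibration_config()) {
  if (any(theta < 0)) stopf("theta must be non-negative")
  theta / (4 * cal$mu_per_My * 1e-6 * cal$gen_time_yr)
}

#' Empirical substitution rate from a calibrated divergence
#'
#' \eqn{\mu = \tau / T}: dividing a mutation-scaled root age by an externally
#' calibrated divergence time yields the implied substitution rate.  Inverse
#' of \code{\link{calibrate_time}}.
#'
#' @param tau_root root age in expected substitutions per site (> 0).
#' @param T_My calibration divergence time in My (> 0).
#' @return substitutions per site per My.
#' @export
empirical_rate <- function(tau_root, T_My) {
  if (any(tau_root <= 0) || any(T_My <= 0)) stopf("tau_root and T_My must be positive")
  tau_root / T_My
}
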