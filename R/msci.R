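#' Parameters of the three-population introgression (MSci) model
#'
#' The model places two bidirectional-introgression (BDI) events on the rooted
#' species tree ((STH, PLN), DST) with outgroup OG: one between the STH-side
#' and PLN-side branches at time \code{tau_CD} (nodes C and D), and one between
#' the DST branch and the STH-side branch at time \code{tau_AB} (nodes A and
#' B).  Branch segments, identified by their daughter node, are:
#' STH (0..tau_CD), PLN (0..tau_CD), C (tau_CD..tau_AB), D (tau_CD..tau_T),
#' DST (0..tau_AB), A (tau_AB..tau_S), B (tau_AB..tau_T), T (tau_T..tau_S),
#' S (tau_S..tau_R), R (above the root), OG (0..tau_R).
#'
#' Tracing a lineage backward in time, at node A (a DST lineage) it crosses to
#' branch B with probability \code{phi_A} and continues into branch A
#' otherwise; at node B (a lineage arriving up branch C) it crosses to branch A
#' with probability \code{phi_B}; at node C (an STH lineage) it crosses to
#' branch D with probability \code{phi_C}; at node D (a PLN lineage) it crosses
#' to branch C with probability \code{phi_D}.
#'
#' All \eqn{\tau} (node ages) and \eqn{\theta = 4N\mu} are in expected
#' substitutions per site (raw per-site values, not multiplied by 1,000).
#'
#' @param theta named numeric vector of population-size parameters for the 11
#'   branches \code{OG, DST, STH, PLN, R, S, T, A, B, C, D}.
#' @param tau_R,tau_S,tau_T,tau_AB,tau_CD node ages, requiring
#'   \code{0 < tau_CD < tau_AB < tau_T <= tau_S < tau_R}.
#' @param phi_A,phi_B,phi_C,phi_D introgression probabilities in \code{[0,1]}.
#' @return an object of class \code{"msci_params"}.
#' @seealso \code{\link{msci_params_peak1}}, \code{\link{label_swap}},
#'   \code{\link{simulate_msci}}
#' @export
msci_params <- function(theta, tau_R, tau_S, tau_T, tau_AB, tau_CD,
                        phi_A = 0, phi_B = 0, phi_C = 0, phi_D = 0) {
  branches <- c("OG", "DST", "STH", "PLN", "R", "S", "T", "A", "B", "C", "D")
  if (length(theta) == 1L) theta <- stats::setNames(rep(theta, 11L), branches)
  if (is.null(names(theta)) || !setequal(names(theta), branches))
    stopf("theta must be named with the 11 branches: %s", paste(branches, collapse = ", "))
  theta <- theta[branches]
  if (any(!is.finite(theta)) || any(theta <= 0)) stopf("all theta must be positive")
  taus <- c(tau_R = tau_R, tau_S = tau_S, tau_T = tau_T, tau_AB = tau_AB, tau_CD = tau_CD)
  if (any(!is.finite(taus))) stopf("all tau must be finite")
  if (!(0 < tau_CD && tau_CD < tau_AB && tau_AB < tau_T && tau_T <= tau_S && tau_S < tau_R))
    stopf("node ages must satisfy 0 < tau_CD < tau_AB < tau_T <= tau_S < tau_R")
  phis <- c(phi_A = phi_A, phi_B = phi_B, phi_C = phi_C, phi_D = phi_D)
  if (any(!is.finite(phis)) || any(phis < 0) || any(phis > 1))
    stopf("introgression probabilities must lie in [0, 1]")
  structure(c(list(theta = theta), as.list(taus), as.list(phis)),
            class = "msci_params")
}

#' @export
print.msci_params <- function(x, ...) {
  cat("MSci parameters (per-site units)\n")
  cat(sprintf("  tau: R=%.3g S=%.3g T=%.3g AB=%.3g CD=%.3g\n",
              x$tau_R, x$tau_S, x$tau_T, x$tau_AB, x$tau_CD))
  cat(sprintf("  phi: A=%.3f B=%.3f C=%.3f D=%.3f\n",
              x$phi_A, x$phi_B, x$phi_C, x$phi_D))
  cat("  theta:", paste(sprintf("%s=%.3g", names(x$theta), x$theta), collapse = " "), "\n")
  invisible(x)
}

#' Posterior-mean MSci parameter set (Peak 1, nonadmixed)
#'
#' The published Peak-1 posterior means for the nonadmixed data set, converted
#' from the x1,000 reporting scale back to raw per-site units.  Useful as a
#' realistic default parameter vector for simulation experiments.
#'
#' @return an \code{\link{msci_params}} object.
#' @export
msci_params_peak1 <- function() {
  msci_params(
    theta = c(OG = 1.22, DST = 1.34, STH = 3.52, PLN = 0.93, R = 23.1,
              S = 2.69, T = 1.89, A = 2.55, B = 2.95, C = 4.27, D = 6.96) / 1000,
    tau_R = 9.75e-3, tau_S = 6.14e-3, tau_T = 3.86e-3,
    tau_AB = 1.42e-3, tau_CD = 0.17e-3,
    phi_A = 0.868, phi_B = 0.090, phi_C = 0.065, phi_D = 0.935)
}

#' Label-swap transformation of a BDI event
#'
#' Within-model unidentifiability of bidirectional introgression: swapping the
#' labels of the two introgression nodes of a BDI pair maps
#' \eqn{\phi_X \to 1-\phi_X}, \eqn{\phi_Y \to 1-\phi_Y} and exchanges
#' \eqn{\theta_X \leftrightarrow \theta_Y}, leaving all other parameters
#' unchanged.  Applying the swap twice returns the original parameters.
#'
#' @param params an \code{\link{msci_params}} object.
#' @param node_pair which BDI event to swap: \code{"AB"} or \code{"CD"}.
#' @return the transformed \code{msci_params}.
#' @export
label_swap <- function(params, node_pair = c("AB", "CD")) {
  stopifnot(inherits(params, "msci_params"))
  node_pair <- match.arg(node_pair)
  th <- params$theta
  if (node_pair == "AB") {
    th[c("A", "B")] <- th[c("B", "A")]
    msci_params(th, params$tau_R, params$tau_S, params$tau_T, params$tau_AB,
                params$tau_CD, 1 - params$phi_A, 1 - params$phi_B,
                params$phi_C, params$phi_D)
  } else {
    th[c("C", "D")] <- th[c("D", "C")]
    msci_params(th, params$tau_R, params$tau_S, params$tau_T, params$tau_AB,
                params$tau_CD, params$phi_A, params$phi_B,
                1 - params$phi_C, 1 - params$phi_D)
  }
}

#' Build the engine demography for an MSci parameter set
#'
#' Populations are the branch segments of the introgression network; sizes are
#' \eqn{\theta/2} (so the pairwise coalescence rate is \eqn{2/\theta}), time is
#' measured in expected substitutions per site, and the BDI events are
#' instantaneous backward pulses at their node ages.  With all \eqn{\phi = 0}
#' the events reduce to the plain multispecies-coalescent species tree.
#'
#' @param params an \code{\link{msci_params}} object.
#' @param drop_phi if \code{TRUE}, build the no-introgression (MSC) reduction:
#'   identical segments and sizes but no introgression pulses.
#' @return a \code{\link{demography}} in mutation-scaled units.
#' @export
msci_demography <- function(params, drop_phi = FALSE) {
  stopifnot(inherits(params, "msci_params"))
  th <- params$theta
  pops <- names(th)
  ev <- list()
  add <- function(time, code, i = NA, j = NA, x = NA)
    ev[[length(ev) + 1L]] <<- data.frame(time = time, code = code, i = i, j = j, x = x)
  p <- function(phi) if (drop_phi) 0 else phi
  # C <-> D BDI at tau_CD
  if (p(params$phi_C) > 0) add(params$tau_CD, "pulse", "STH", "D", p(params$phi_C))
  add(params$tau_CD, "join", "STH", "C")
  if (p(params$phi_D) > 0) add(params$tau_CD, "pulse", "PLN", "C", p(params$phi_D))
  add(params$tau_CD, "join", "PLN", "D")
  # A <-> B BDI at tau_AB
  if (p(params$phi_A) > 0) add(params$tau_AB, "pulse", "DST", "B", p(params$phi_A))
  add(params$tau_AB, "join", "DST", "A")
  if (p(params$phi_B) > 0) add(params$tau_AB, "pulse", "C", "A", p(params$phi_B))
  add(params$tau_AB, "join", "C", "B")
  # speciation nodes
  add(params$tau_T, "join", "B", "T")
  add(params$tau_T, "join", "D", "T")
  add(params$tau_S, "join", "A", "S")
  add(params$tau_S, "join", "T", "S")
  add(params$tau_R, "join", "S", "R")
  add(params$tau_R, "join", "OG", "R")
  demography(pop_names = pops, sizes = unname(th) / 2,
             events = do.call(rbind, ev),
             sample_pops = c("DST", "STH", "PLN", "OG"), mu = 1)
}
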