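# shared fixtures, all generated in code

# printed AIC columns of the published ranking table (inputs to the Akaike
# arithmetic; upper panel = nonadmixed, lower = admixed)
aic_nonadmixed <- c(
  refugia_adj_2 = 514.28, refugia_asymmig_adjacent = 517.90,
  refugia_barrier = 518.48, split_nomig = 519.38, refugia_adj_1 = 529.54,
  refugia_adj_3 = 553.04, split_asymmig_adjacent = 559.26,
  split_sym_mig_all = 600.70, split_symmig_adjacent = 624.66,
  refugia_symmig_all = 629.98)

aic_admixed <- c(
  refugia_barrier = 738.38, refugia_adj_2 = 750.78, refugia_adj_1 = 778.82,
  refugia_adj_3 = 779.32, split_asymmig_adjacent = 799.04,
  split_nomig = 840.36, split_sym_mig_all = 870.88,
  refugia_asymmig_adjacent = 884.50, split_symmig_adjacent = 992.34,
  refugia_symmig_all = 1226.80)

# published table cells (dAIC, relL, wAIC at printed precision) keyed by model
table1_nonadmixed <- data.frame(
  Model = names(aic_nonadmixed),
  dAIC = c(0.00, 3.62, 4.20, 5.10, 15.26, 38.76, 44.98, 86.42, 110.38, 115.70),
  relL = c(1.00, 0.16, 0.12, 0.08, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
  wAIC = c(0.73, 0.12, 0.09, 0.06, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00))

table1_admixed <- data.frame(
  Model = names(aic_admixed),
  dAIC = c(0.00, 12.40, 40.44, 40.94, 60.66, 101.98, 132.50, 146.12, 253.96, 488.42),
  relL = c(1.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
  wAIC = c(1.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00))

# a small random unfolded spectrum with deterministic contents
random_jsfs <- function(n = c(4, 4, 4), seed = 1, pop_order = c("DST", "STH", "PLN")) {
  set.seed(seed)
  arr <- array(rpois(prod(n + 1), 5), n + 1)
  jsfs3(arr, folded = FALSE, pop_order = pop_order)
}

# split-with-ancestor two-population demography used in closed-form checks
two_pop_split <- function(T_split = 0.5, nu_anc = 2) {
  demography(c("A", "B", "ANC"), sizes = c(1, 1, nu_anc),
             events = data.frame(time = T_split, code = "join",
                                 i = c("A", "B"), j = "ANC", x = NA),
             mu = NA)
}

# default experiment parameter set: published node ages, one common theta on
# every branch so the no-gene-flow arm is an exact shifted exponential
msci_params_experiment <- function(theta = 0.002, phi_A = 0, phi_B = 0,
                                   phi_C = 0, phi_D = 0) {
  msci_params(theta = theta,
              tau_R = 9.75e-3, tau_S = 6.14e-3, tau_T = 3.86e-3,
              tau_AB = 1.42e-3, tau_CD = 0.17e-3,
              phi_A = phi_A, phi_B = phi_B, phi_C = phi_C, phi_D = phi_D)
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(max(abs(est - truth) / abs(truth)), tol)
}
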