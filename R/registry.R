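# Declarative registry of the ten three-population demographic models.
#
# Shared skeleton (forward in time): an ancestral population of relative size
# 1 (the reference, theta_ref = 4 N_ref mu) first splits into DST and the
# STH+PLN ancestor (relative size nu23), and after a further interval the
# latter splits into STH and PLN (sizes nu2, nu3; DST has size nu1).  The
# topology is fixed: ((STH, PLN), DST).  Durations (T*) are in units of
# 2 N_ref generations; migration entries are 2 N_ref m (expected migration
# events per lineage per 2 N_ref generations), with "adjacent" meaning the
# DST<->STH and STH<->PLN pairs only.
#
# Family semantics (the two headline models follow the source prose; the
# other eight are reconstructed from their names following the usual
# diffusion/moments community conventions, and are deliberately kept in this
# single declarative table so their structure can be amended without touching
# the engine):
#   split_*    migration (if any) is active from the moment each split occurs;
#   refugia_*  divergence happens in isolation and migration only starts with
#              a later secondary-contact phase:
#     refugia_adj_1  contact already during the two-population epoch (after
#                    the first split) and continuing after the second split,
#                    preceded by an isolation phase;
#     refugia_adj_2  isolation during the two-population epoch, contact
#                    (adjacent pairs) throughout the three-population epoch;
#     refugia_adj_3  isolation after both splits, contact only in a terminal
#                    sub-epoch;
#     refugia_barrier  refugia_adj_2 with no gene flow to/from DST (the
#                    riverine-barrier hypothesis): STH<->PLN contact only;
#     refugia_asymmig_adjacent  refugia_adj_2 with asymmetric adjacent rates;
#     refugia_symmig_all        refugia_adj_2 with symmetric contact between
#                    all three pairs.

model_registry <- list(
  split_nomig = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2"),
    description = "two splits, never any gene flow"),
  split_symmig_adjacent = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2", "mDS", "mSP"),
    description = "symmetric adjacent migration active from each split"),
  split_asymmig_adjacent = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2",
               "mDS12", "mDS21", "mSP23", "mSP32"),
    description = "asymmetric adjacent migration active from each split"),
  split_sym_mig_all = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2", "mDS", "mSP", "mDP"),
    description = "symmetric migration between all pairs from each split"),
  refugia_adj_1 = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1a", "T1b", "T2", "mDS", "mSP"),
    description = "isolation, then secondary contact starting before the second split"),
  refugia_adj_2 = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2", "mDS", "mSP"),
    description = "isolation between the splits, adjacent contact after the second split"),
  refugia_adj_3 = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2a", "T2b", "mDS", "mSP"),
    description = "isolation after both splits, adjacent contact only recently"),
  refugia_barrier = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2", "mSP"),
    description = "as refugia_adj_2 but gene flow only between STH and PLN"),
  refugia_asymmig_adjacent = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2",
               "m12", "m21", "m23", "m32"),
    description = "as refugia_adj_2 with asymmetric adjacent contact"),
  refugia_symmig_all = list(
    params = c("nu1", "nu2", "nu3", "nu23", "T1", "T2", "mDS", "mSP", "mDP"),
    description = "as refugia_adj_2 with symmetric contact between all pairs"))

#' List the registered demographic models
#'
#' @return a data.frame with one row per model: \code{name}, \code{k} (number
#'   of free parameters), \code{params} (comma-separated) and a short
#'   description.
#' @export
list_models <- function() {
  data.frame(
    name = names(model_registry),
    k = vapply(model_registry, function(m) length(m$params), 0L),
    params = vapply(model_registry, function(m) paste(m$params, collapse = ","), ""),
    description = vapply(model_registry, function(m) m$description, ""),
    row.names = NULL)
}

#' Parameter names of a registered model
#' @param name model name (see \code{\link{list_models}}).
#' @return character vector of free-parameter names.
#' @export
model_params <- function(name) {
  m <- model_registry[[name]]
  if (is.null(m)) stopf("unknown model '%s'", name)
  m$params
}

#' Instantiate a registered model as an engine demography
#'
#' Builds the backward-in-time event list for one of the ten registered
#' three-population models at concrete parameter values.  Populations are
#' DST, STH, PLN plus the internal ANC23 and ROOT demes; times are in
#' 2 N_ref generations, sizes relative to N_ref, migration entries
#' \eqn{2 N_{ref} m}.
#'
#' @param name model name.
#' @param params named (or ordered) numeric vector matching
#'   \code{\link{model_params}}.
#' @return a \code{\link{demography}} tagged with the model name (its
#'   \code{mu} is left to the simulation configuration's \code{mut_scale}).
#' @export
model_demography <- function(name, params) {
  pn <- model_params(name)
  if (is.null(names(params))) {
    if (length(params) != length(pn)) stopf("expected %d parameters for %s",
                                            length(pn), name)
    names(params) <- pn
  }
  if (!all(pn %in% names(params))) stopf("missing parameter(s): %s",
                                         paste(setdiff(pn, names(params)), collapse = ", "))
  p <- as.list(params[pn])
  if (any(!vapply(p, is.finite, TRUE))) stopf("parameters must be finite")
  sizes <- unlist(p[c("nu1", "nu2", "nu3", "nu23")])
  if (any(sizes <= 0)) stopf("population sizes must be positive")
  durs <- unlist(p[grep("^T", pn, value = TRUE)])
  if (any(durs <= 0)) stopf("epoch durations must be positive")
  migs <- unlist(p[grep("^m", pn, value = TRUE)])
  if (length(migs) && any(migs < 0)) stopf("migration rates must be non-negative")

  pops <- c("DST", "STH", "PLN", "ANC23", "ROOT")
  ev <- list()
  add <- function(time, code, i = NA, j = NA, x = NA)
    ev[[length(ev) + 1L]] <<- data.frame(time = time, code = code, i = i, j = j, x = x)
  mig0 <- matrix(0, 5, 5, dimnames = list(pops, pops))
  set_sym <- function(M, a, b, r) { M[a, b] <- r; M[b, a] <- r; M }

  # epoch boundaries, backward from the present
  t_split2 <- switch(name,
    refugia_adj_1 = p$T2,
    refugia_adj_3 = p$T2a + p$T2b,
    p$T2)
  t_split1 <- t_split2 + switch(name,
    refugia_adj_1 = p$T1a + p$T1b,
    p$T1)

  # recent-epoch migration
  if (name == "split_symmig_adjacent" || name == "refugia_adj_1" ||
      name == "refugia_adj_2") {
    mig0 <- set_sym(mig0, "DST", "STH", p$mDS)
    mig0 <- set_sym(mig0, "STH", "PLN", p$mSP)
  } else if (name == "split_asymmig_adjacent") {
    mig0["DST", "STH"] <- p$mDS12; mig0["STH", "DST"] <- p$mDS21
    mig0["STH", "PLN"] <- p$mSP23; mig0["PLN", "STH"] <- p$mSP32
  } else if (name == "split_sym_mig_all" || name == "refugia_symmig_all") {
    mig0 <- set_sym(mig0, "DST", "STH", p$mDS)
    mig0 <- set_sym(mig0, "STH", "PLN", p$mSP)
    mig0 <- set_sym(mig0, "DST", "PLN", p$mDP)
  } else if (name == "refugia_barrier") {
    mig0 <- set_sym(mig0, "STH", "PLN", p$mSP)
  } else if (name == "refugia_asymmig_adjacent") {
    mig0["DST", "STH"] <- p$m12; mig0["STH", "DST"] <- p$m21
    mig0["STH", "PLN"] <- p$m23; mig0["PLN", "STH"] <- p$m32
  }
  if (name == "refugia_adj_3") {
    # contact only in the terminal sub-epoch: migration on at present, off
    # (backward) at T2b
    mig0 <- set_sym(mig0, "DST", "STH", p$mDS)
    mig0 <- set_sym(mig0, "STH", "PLN", p$mSP)
    add(p$T2b, "mig_clear")
  }

  # second split (backward: STH and PLN merge into ANC23)
  add(t_split2, "mig_clear")
  add(t_split2, "join", "STH", "ANC23")
  add(t_split2, "join", "PLN", "ANC23")
  # two-population epoch migration (DST <-> ANC23)
  if (name == "split_symmig_adjacent" || name == "split_sym_mig_all") {
    add(t_split2, "mig", "DST", "ANC23", p$mDS)
    add(t_split2, "mig", "ANC23", "DST", p$mDS)
  } else if (name == "split_asymmig_adjacent") {
    add(t_split2, "mig", "DST", "ANC23", p$mDS12)
    add(t_split2, "mig", "ANC23", "DST", p$mDS21)
  } else if (name == "refugia_adj_1") {
    # contact in the later (more recent, backward-first) part of the epoch
    add(t_split2, "mig", "DST", "ANC23", p$mDS)
    add(t_split2, "mig", "ANC23", "DST", p$mDS)
    add(t_split2 + p$T1b, "mig_clear")
  }
  # first split
  add(t_split1, "mig_clear")
  add(t_split1, "join", "DST", "ROOT")
  add(t_split1, "join", "ANC23", "ROOT")

  dem <- demography(pop_names = pops,
                    sizes = c(p$nu1, p$nu2, p$nu3, p$nu23, 1),
                    migration = mig0,
                    events = do.call(rbind, ev),
                    sample_pops = c("DST", "STH", "PLN"),
                    mu = NA)
  attr(dem, "model_name") <- name
  attr(dem, "params") <- params[pn]
  dem
}
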