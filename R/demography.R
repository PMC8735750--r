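#' Generic structured-coalescent demography
#'
#' Low-level container consumed by the simulation engine.  A demography is a
#' set of populations with sizes (pairwise coalescence rate \code{1/size}), a
#' backward migration-rate matrix, and a time-ordered list of events.  Units
#' are whatever the caller chooses, as long as they are consistent: the
#' registry models (\code{\link{model_demography}}) use N_ref-relative units
#' (sizes \eqn{\nu}, times in 2N_ref generations, migration \eqn{2 N_{ref} m});
#' the introgression models (\code{\link{msci_demography}}) use mutation-scaled
#' units (sizes \eqn{\theta/2}, times in expected substitutions per site).
#'
#' @param pop_names character vector naming the populations (tracked and
#'   ancestral); its length fixes the number of demes.
#' @param sizes numeric vector of initial population sizes, one per deme.
#' @param migration square backward migration matrix (rate at which one lineage
#'   in row-deme moves to column-deme); defaults to no migration.
#' @param events data.frame with columns \code{time}, \code{code}, \code{i},
#'   \code{j}, \code{x}; codes are \code{"size"}, \code{"join"},
#'   \code{"pulse"}, \code{"mig"}, \code{"mig_clear"} (or integers 0--4).
#'   \code{i}/\code{j} are population names or indices.
#' @param sample_pops names of the demes in which samples can be placed at
#'   time 0 (defaults to all demes).
#' @param mu expected substitutions per site per unit time (mutation scale used
#'   when sequences/distances are generated).
#' @return an object of class \code{"demography"}.
#' @export
demography <- function(pop_names, sizes, migration = NULL, events = NULL,
                       sample_pops = pop_names, mu = 1) {
  np <- length(pop_names)
  if (length(sizes) != np) stopf("need one size per population")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stopf("population sizes must be positive and finite")
  if (is.null(migration)) migration <- matrix(0, np, np)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == np)) stopf("migration matrix must be %d x %d", np, np)
  if (any(migration < 0)) stopf("migration rates must be non-negative")
  diag(migration) <- 0

  ev <- matrix(numeric(0), ncol = 5,
               dimnames = list(NULL, c("time", "code", "i", "j", "x")))
  if (!is.null(events) && nrow(events) > 0) {
    codes <- c(size = 0, join = 1, pulse = 2, mig = 3, mig_clear = 4)
    code <- if (is.numeric(events$code)) events$code else unname(codes[as.character(events$code)])
    if (anyNA(code)) stopf("unknown event code")
    idx <- function(v) {
      if (is.numeric(v)) return(as.integer(v) - 1L)
      m <- match(as.character(v), pop_names)
      m[is.na(as.character(v))] <- 1L   # placeholder for codes that ignore i/j
      if (anyNA(m)) stopf("event references unknown population")
      m - 1L
    }
    if (any(!is.finite(events$time)) || any(events$time < 0))
      stopf("event times must be non-negative and finite")
    ev <- cbind(time = events$time, code = code,
                i = idx(events$i), j = idx(events$j),
                x = ifelse(is.na(events$x), 0, events$x))
    ev <- ev[order(ev[, "time"], seq_len(nrow(ev))), , drop = FALSE]
    bad <- ev[, "code"] == 0 & ev[, "x"] <= 0
    if (any(bad)) stopf("size events must set a positive size")
    bad <- ev[, "code"] == 2 & (ev[, "x"] < 0 | ev[, "x"] > 1)
    if (any(bad)) stopf("pulse probabilities must lie in [0, 1]")
    bad <- ev[, "code"] == 3 & ev[, "x"] < 0
    if (any(bad)) stopf("migration rates must be non-negative")
  }
  structure(list(pop_names = pop_names, sizes = as.numeric(sizes),
                 migration = migration, events = ev,
                 sample_pops = sample_pops, mu = mu),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("Structured-coalescent demography\n")
  cat("  populations:", paste(x$pop_names, collapse = ", "), "\n")
  cat("  events:", nrow(x$events), " mutation scale mu =", x$mu, "\n")
  invisible(x)
}

# Engine-call helpers -------------------------------------------------------

# sample_pop: 0-based deme index per sample, from a named count vector
sample_vector <- function(dem, n_samples) {
  pops <- names(n_samples)
  bad <- setdiff(pops, dem$pop_names)
  if (length(bad)) stopf("unknown population(s): %s", paste(bad, collapse = ", "))
  idx <- rep.int(match(pops, dem$pop_names) - 1L, n_samples)
  labels <- rep.int(pops, n_samples)
  list(idx = as.integer(idx), labels = labels,
       names = make_sample_names(labels))
}

make_sample_names <- function(labels) {
  paste0(labels, "_", stats::ave(seq_along(labels), labels, FUN = seq_along))
}
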