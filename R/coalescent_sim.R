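#' Simulation configuration
#'
#' Holds the sampling design and reproducibility settings shared by the
#' simulators.  Defaults mirror the study design this package emulates: three
#' focal populations (DST = desert, STH = southern, PLN = plains) plus a
#' single outgroup individual, and 500 independent loci.
#'
#' @param n_samples named integer vector of haploid sample counts per
#'   population; populations with 0 samples are allowed (e.g. to drop the
#'   outgroup).
#' @param n_loci number of independent loci.
#' @param locus_len sites per locus; under the infinite-sites model it only
#'   sets the per-site scale of distances and the mutation target size.
#' @param mut_scale per-site mutation parameter \eqn{\theta_{ref} = 4 N_{ref}
#'   \mu} used to convert N_ref-scaled coalescent time to expected
#'   substitutions (ignored by mutation-scaled demographies, which carry their
#'   own scale).
#' @param seed integer master seed; per-locus substreams are derived from it by
#'   a fixed counter scheme so any locus is reproducible in isolation.
#' @return an object of class \code{"pop_config"}.
#' @export
pop_config <- function(n_samples = c(DST = 4, STH = 4, PLN = 4, OG = 1),
                       n_loci = 500, locus_len = 100,
                       mut_scale = 0.002, seed = 1) {
  if (is.null(names(n_samples)) || any(!nzchar(names(n_samples))))
    stopf("n_samples must be a named vector")
  if (any(n_samples < 0) || all(n_samples < 1))
    stopf("need at least one sampled haploid (and no negative counts)")
  if (n_loci < 1) stopf("n_loci must be >= 1")
  if (locus_len < 1) stopf("locus_len must be >= 1")
  if (mut_scale <= 0) stopf("mut_scale must be positive")
  structure(list(n_samples = n_samples[n_samples > 0], n_loci = as.integer(n_loci),
                 locus_len = as.integer(locus_len), mut_scale = mut_scale,
                 seed = as.integer(seed)),
            class = "pop_config")
}

#' Recent-hybrid specification
#'
#' Describes one extra individual appended to the sample: at each locus its
#' lineage starts in \code{parent_pops[1]} with probability \code{mixing_prob}
#' and in \code{parent_pops[2]} otherwise (parental assignment at sampling
#' time, i.e. a very recent hybrid), but the individual is labelled as a
#' member of \code{host_pop} in all downstream analyses.
#'
#' @param host_pop population label the hybrid is assigned to.
#' @param parent_pops two distinct source populations.
#' @param mixing_prob probability a locus descends from the first parent.
#' @return an object of class \code{"hybrid_spec"}.
#' @export
hybrid_spec <- function(host_pop, parent_pops, mixing_prob = 0.5) {
  if (length(parent_pops) != 2L || parent_pops[1] == parent_pops[2])
    stopf("parent_pops must be two distinct populations")
  if (mixing_prob < 0 || mixing_prob > 1) stopf("mixing_prob must lie in [0, 1]")
  structure(list(host_pop = host_pop, parent_pops = parent_pops,
                 mixing_prob = mixing_prob), class = "hybrid_spec")
}

# shared simulation driver ---------------------------------------------------
sim_locus_set <- function(dem, config, representation, hybrid = NULL,
                          truth = NULL) {
  stopifnot(inherits(dem, "demography"), inherits(config, "pop_config"))
  representation <- match.arg(representation, c("genotypes", "distances"))
  sv <- sample_vector(dem, config$n_samples)
  labels <- sv$labels
  base_idx <- sv$idx
  hyb_name <- NULL
  if (!is.null(hybrid)) {
    stopifnot(inherits(hybrid, "hybrid_spec"))
    bad <- setdiff(c(hybrid$host_pop, hybrid$parent_pops), dem$pop_names)
    if (length(bad)) stopf("hybrid references unknown population(s): %s",
                           paste(bad, collapse = ", "))
    hyb_name <- paste0(hybrid$host_pop, "_hyb")
    labels <- c(labels, hybrid$host_pop)
  }
  sample_labels <- stats::setNames(labels, c(sv$names, hyb_name))

  mu <- if (is.na(dem$mu)) config$mut_scale / 2 else dem$mu
  np <- length(dem$pop_names)
  n_loci <- config$n_loci
  genotypes <- positions <- site_bases <- distances <- coal_times <- NULL
  if (representation == "genotypes") {
    genotypes <- positions <- site_bases <- vector("list", n_loci)
  } else {
    distances <- coal_times <- vector("list", n_loci)
  }
  parents_idx <- match(hybrid$parent_pops, dem$pop_names) - 1L

  for (l in seq_len(n_loci)) {
    with_seed(locus_seed(config$seed, l), {
      sp <- base_idx
      if (!is.null(hybrid)) {
        start <- if (stats::runif(1) < hybrid$mixing_prob) parents_idx[1] else parents_idx[2]
        sp <- c(sp, start)
      }
      if (representation == "genotypes") {
        res <- sim_locus_cpp(sp, np, dem$sizes, dem$migration, dem$events,
                             mu, config$locus_len)
        g <- res$genotypes
        colnames(g) <- names(sample_labels)
        genotypes[[l]] <- g
        positions[[l]] <- res$positions
        ns <- nrow(g)
        anc <- sample(c("A", "C", "G", "T"), ns, replace = TRUE)
        der <- vapply(anc, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        site_bases[[l]] <- list(anc = anc, der = unname(der))
      } else {
        res <- sim_distances_cpp(sp, np, dem$sizes, dem$migration, dem$events,
                                 mu, config$locus_len)
        dimnames(res$d) <- dimnames(res$t) <- list(names(sample_labels), names(sample_labels))
        distances[[l]] <- res$d
        coal_times[[l]] <- res$t
      }
    })
  }
  structure(list(genotypes = genotypes, positions = positions,
                 site_bases = site_bases, distances = distances,
                 coal_times = coal_times, sample_labels = sample_labels,
                 pop_names = dem$pop_names, n_loci = n_loci,
                 locus_len = config$locus_len, representation = representation,
                 truth = truth, seed = config$seed),
            class = "locus_set")
}

#' Simulate multilocus data under a multispecies-coalescent demography
#'
#' Draws an independent genealogy per locus under the structured coalescent
#' with the demography's epochs and migration, then places infinite-sites
#' mutations on branches as a Poisson process.  With
#' \code{representation = "genotypes"} each locus carries a 0/1 haploid
#' genotype matrix (sites x samples) plus site positions; with
#' \code{"distances"} only the per-locus pairwise raw-proportion distance
#' matrices (and pairwise coalescence times) are kept, which scales to very
#' long loci.
#'
#' @param demography a \code{\link{demography}}, e.g. from
#'   \code{\link{model_demography}} or \code{\link{msci_demography}}.
#' @param config a \code{\link{pop_config}}; its \code{n_samples} names must be
#'   populations of the demography.
#' @param representation \code{"genotypes"} or \code{"distances"}.
#' @return an object of class \code{"locus_set"}.
#' @export
simulate_msc <- function(demography, config, representation = "genotypes") {
  truth <- list(kind = "msc", model = attr(demography, "model_name"),
                params = attr(demography, "params"),
                config = unclass(config))
  sim_locus_set(demography, config, representation, truth = truth)
}

#' Simulate multilocus data under the MSci introgression model
#'
#' Backward-in-time lineage tracing with instantaneous bidirectional
#' introgression pulses (see \code{\link{msci_params}}).  With all
#' \eqn{\phi = 0} the output distribution is identical to
#' \code{\link{simulate_msc}} on the underlying species tree; at matched seeds
#' the outputs are bit-identical.  If \code{hybrid} is given, one extra
#' individual is appended whose per-locus lineage starts in one of the two
#' parental populations (see \code{\link{hybrid_spec}}).
#'
#' @param params an \code{\link{msci_params}} object.
#' @param config a \code{\link{pop_config}}.
#' @param hybrid optional \code{\link{hybrid_spec}}.
#' @param representation \code{"genotypes"} or \code{"distances"}.
#' @return an object of class \code{"locus_set"}.
#' @export
simulate_msci <- function(params, config, hybrid = NULL,
                          representation = "genotypes") {
  dem <- msci_demography(params)
  truth <- list(kind = "msci", params = unclass(params),
                hybrid = if (!is.null(hybrid)) unclass(hybrid),
                config = unclass(config))
  sim_locus_set(dem, config, representation, hybrid = hybrid, truth = truth)
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d loci x %d samples (%s representation)\n",
              x$n_loci, length(x$sample_labels), x$representation))
  cat("  populations:", paste(unique(x$sample_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Expected joint SFS from genealogy branch lengths
#'
#' Monte-Carlo expectation of the unfolded joint site frequency spectrum: for
#' each of \code{n_reps} simulated genealogies, the length of every branch is
#' credited to the spectrum cell indexed by the number of tips it subtends in
#' each population (a Rao-Blackwellised estimate of the expected SFS, since
#' mutation placement is integrated out).  The result is normalised to sum to
#' one over unmasked cells; the fixed cells are masked.  Deterministic given
#' \code{config$seed}.
#'
#' @param demography a \code{\link{demography}}.
#' @param config a \code{\link{pop_config}}; spectrum axes are the sampled
#'   populations listed in \code{axes} (at most 3).
#' @param n_reps number of genealogy replicates (>= 1).
#' @param axes character vector of population names forming the spectrum axes;
#'   sampled populations not listed (e.g. an outgroup) influence genealogies
#'   but not the spectrum.
#' @return a \code{\link{jsfs3}} with the normalised expected spectrum.
#' @export
branch_spectrum <- function(demography, config, n_reps,
                            axes = intersect(c("DST", "STH", "PLN"),
                                             names(config$n_samples))) {
  stopifnot(inherits(demography, "demography"), inherits(config, "pop_config"))
  if (n_reps < 1) stopf("n_reps must be >= 1")
  if (length(axes) < 1 || length(axes) > 3)
    stopf("between 1 and 3 spectrum axes are required")
  if (!all(axes %in% names(config$n_samples)))
    stopf("axes must be sampled populations")
  sv <- sample_vector(demography, config$n_samples)
  axis_of <- match(sv$labels, axes) - 1L      # NA -> ignored
  axis_of[is.na(axis_of)] <- -1L
  n_ax <- c(as.integer(config$n_samples[axes]), 0L, 0L)[1:3]
  arr <- with_seed(config$seed,
    branch_spectrum_cpp(sv$idx, length(demography$pop_names), demography$sizes,
                        demography$migration, demography$events,
                        as.integer(axis_of), n_ax, as.integer(n_reps)))
  dim(arr) <- n_ax + 1L
  pop_order <- c(axes, rep(NA_character_, 3 - length(axes)))[1:3]
  pop_order[is.na(pop_order)] <- paste0(".unused", which(is.na(pop_order)))
  spec <- jsfs3(arr, folded = FALSE, pop_order = pop_order)
  normalize_jsfs(spec)
}
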