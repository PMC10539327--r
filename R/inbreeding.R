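#' Observed heterozygosity of a cohort
#'
#' Proportion of individual-locus genotypes carrying both alleles.  Under
#' X-linkage only females (two X copies) contribute.
#'
#' @param cohort A cohort.
#' @return Proportion in \[0, 1\].
#' @export
heterozygosity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  het <- cohort$maternal != cohort$paternal
  mean(het, na.rm = TRUE)
}

# breed a sibship guaranteed to contain both sexes (resampled when a small
# random-sex brood comes out single-sex)
breed_mixed_sibship <- function(mother, father, size) {
  for (i in 1:1000) {
    sib <- breed_cohort(mother, father, n_offspring = size,
                        sex_assignment = "random")
    if (any(sib$male) && any(!sib$male)) return(sib)
  }
  stop("failed to produce a mixed-sex sibship")   # practically unreachable
}

#' Simulate one line through extreme inbreeding
#'
#' The line experiences 11 generations of inbreeding: a founding male-female
#' pair drawn from the stock (allele frequency \code{A}) followed by
#' \code{n_sib_generations} single brother-sister pair matings, with the last
#' of these producing a brood of \code{n_final_parents} siblings, which are
#' then mass mated (the final inbreeding generation) to produce the
#' \code{assay_cohort} offspring required for a 1-opportunity dispersal
#' assay.  A 200-individual stock cohort is assayed the same way before
#' inbreeding (generation 0) for comparison.  No line extinction is modelled.
#'
#' @param arch A [genetic_architecture()].
#' @param sibship_size Offspring per sib mating (enough to guarantee both
#'   sexes with high probability).
#' @param n_sib_generations Number of single-pair sib-mating generations.
#' @param n_final_parents Siblings mass-mated in the final generation.
#' @param assay_cohort Size of the assayed cohorts.
#' @param line_id Line identifier.
#' @param seed Optional seed.
#' @return A list of class \code{"inbred_line"}: disperser counts before and
#'   after inbreeding, the mean dispersal-allele frequency of the terminal
#'   cohort, its per-locus fixation states (\code{"fixed_dispersal"},
#'   \code{"fixed_non_dispersal"} or \code{"segregating"}), and the
#'   generation-by-generation allele-frequency trajectory.
#' @export
run_inbred_line <- function(arch, sibship_size = 10L, n_sib_generations = 10L,
                            n_final_parents = 30L, assay_cohort = 200L,
                            line_id = "I1", seed = NULL) {
  stopifnot_architecture(arch)
  if (!is.null(seed)) set.seed(seed)

  gen0 <- run_dispersal_assay(
    found_cohort(arch, n = assay_cohort, line_id = line_id, generation = 0L),
    k = 1L)

  pair <- found_cohort(arch, n = 2L, sex_ratio = 0.5, line_id = line_id,
                       generation = 0L)
  mother <- pair[!pair$male]
  father <- pair[pair$male]
  freq <- numeric(n_sib_generations + 2L)
  freq[1L] <- allele_freq(pair)
  parents <- NULL
  for (g in seq_len(n_sib_generations)) {
    last <- g == n_sib_generations
    sib <- breed_mixed_sibship(mother, father,
                               if (last) n_final_parents else sibship_size)
    freq[g + 1L] <- allele_freq(sib)
    if (last) {
      parents <- sib   # the final brood of siblings is mass mated below
    } else {
      fem <- which(!sib$male)
      mal <- which(sib$male)
      mother <- sib[if (length(fem) > 1L) sample(fem, 1L) else fem]
      father <- sib[if (length(mal) > 1L) sample(mal, 1L) else mal]
    }
  }
  terminal <- breed_cohort(parents[!parents$male], parents[parents$male],
                           n_offspring = assay_cohort,
                           sex_assignment = "balanced")
  freq[n_sib_generations + 2L] <- allele_freq(terminal)
  assay <- run_dispersal_assay(terminal, k = 1L)

  pl <- allele_freq_by_locus(terminal)
  fixation <- ifelse(pl == 1, "fixed_dispersal",
                     ifelse(pl == 0, "fixed_non_dispersal", "segregating"))
  structure(
    list(line_id = line_id,
         generation0_dispersers = n_dispersers(gen0),
         terminal_dispersers = n_dispersers(assay),
         mean_allele_freq = mean(pl),
         fixation = fixation,
         allele_freq_trajectory = freq),
    class = "inbred_line")
}

#' Simulate a set of inbred lines for one or more architectures
#'
#' Runs [run_inbred_line()] on independent RNG substreams for
#' \code{n_lines} replicate lines per architecture, assembling the terminal
#' distributions used for multimodality testing.
#'
#' @param arch A [genetic_architecture()] or a list of them.
#' @param n_lines Replicate lines per architecture (250 in the study design).
#' @param seed Top-level seed.
#' @param ... Passed to [run_inbred_line()].
#' @return A data frame of class \code{"inbreeding_experiment"}: one row per
#'   line with architecture descriptors, generation-0 and terminal disperser
#'   counts and mean allele frequency.  Per-locus fixation states are in
#'   attribute \code{"fixation"} (lines by loci character matrices, one per
#'   architecture), allele-frequency trajectories in attribute
#'   \code{"trajectories"}.
#' @export
run_inbreeding_experiment <- function(arch, n_lines = 250L, seed = 1L, ...) {
  if (is_architecture(arch)) arch <- list(arch)
  stopifnot(all(vapply(arch, is_architecture, TRUE)))
  out <- vector("list", length(arch))
  fixations <- vector("list", length(arch))
  trajectories <- vector("list", length(arch))
  for (a in seq_along(arch)) {
    ar <- arch[[a]]
    fix <- matrix(NA_character_, n_lines, ar$n_loci)
    traj <- NULL
    g0 <- term <- integer(n_lines)
    mfreq <- numeric(n_lines)
    for (i in seq_len(n_lines)) {
      ln <- run_inbred_line(ar, line_id = sprintf("I%d", i),
                            seed = derive_seed(seed, 7000L + a, i), ...)
      g0[i] <- ln$generation0_dispersers
      term[i] <- ln$terminal_dispersers
      mfreq[i] <- ln$mean_allele_freq
      fix[i, ] <- ln$fixation
      if (is.null(traj))
        traj <- matrix(NA_real_, n_lines, length(ln$allele_freq_trajectory))
      traj[i, ] <- ln$allele_freq_trajectory
    }
    out[[a]] <- data.frame(
      n_loci = ar$n_loci, sex_linked = ar$sex_linked, d = ar$d, h = ar$h,
      A = ar$A, line = seq_len(n_lines), generation0_dispersers = g0,
      terminal_dispersers = term, mean_allele_freq = mfreq,
      stringsAsFactors = FALSE)
    fixations[[a]] <- fix
    trajectories[[a]] <- traj
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fixation") <- fixations
  attr(res, "trajectories") <- trajectories
  attr(res, "seed") <- seed
  class(res) <- c("inbreeding_experiment", "data.frame")
  res
}

#' @export
print.inbreeding_experiment <- function(x, ...) {
  archs <- unique(x[, c("n_loci", "sex_linked", "d", "h", "A")])
  cat(sprintf("Inbreeding experiment: %d lines across %d architecture(s)\n",
              nrow(x), nrow(archs)))
  for (i in seq_len(nrow(archs))) {
    sel <- x$n_loci == archs$n_loci[i] & x$A == archs$A[i] &
      x$d == archs$d[i] & x$h == archs$h[i]
    cat(sprintf(
      "  %d-locus (d = %g, h = %g, A = %g): terminal dispersers %d-%d (median %d)\n",
      archs$n_loci[i], archs$d[i], archs$h[i], archs$A[i],
      min(x$terminal_dispersers[sel]), max(x$terminal_dispersers[sel]),
      round(stats::median(x$terminal_dispersers[sel]))))
  }
  invisible(x)
}

#' Histograms of disperser counts before and after inbreeding
#'
#' @param x An \code{"inbreeding_experiment"}.
#' @param ... Unused.
#' @return Invisibly \code{x}.
#' @export
plot.inbreeding_experiment <- function(x, ...) {
  archs <- unique(x[, c("n_loci", "A")])
  op <- graphics::par(mfrow = c(nrow(archs), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(archs))) {
    sel <- x$n_loci == archs$n_loci[i] & x$A == archs$A[i]
    brk <- seq(0, max(x$generation0_dispersers, x$terminal_dispersers) + 10, 10)
    graphics::hist(x$generation0_dispersers[sel], breaks = brk,
                   col = "steelblue", border = NA,
                   main = sprintf("%d-locus, A = %g: generation 0",
                                  archs$n_loci[i], archs$A[i]),
                   xlab = "dispersers per line")
    graphics::hist(x$terminal_dispersers[sel], breaks = brk,
                   col = "firebrick", border = NA,
                   main = "after 11 generations", xlab = "dispersers per line")
  }
  invisible(x)
}

#' Subsample inbred lines
#'
#' Uniform sampling without replacement down to \code{m} lines per
#' architecture, matching a smaller experimental design (64 surviving lines).
#' \code{m = 0} is permitted and returns an empty table (with a message).
#'
#' @param experiment An \code{"inbreeding_experiment"}.
#' @param m Lines to retain per architecture.
#' @param seed Optional seed.
#' @return The subsampled \code{"inbreeding_experiment"} (without fixation or
#'   trajectory attributes).
#' @export
subsample_lines <- function(experiment, m = 64L, seed = NULL) {
  stopifnot(inherits(experiment, "inbreeding_experiment") ||
              is.data.frame(experiment))
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m)
  if (is.na(m) || m < 0L) stop("'m' must be a non-negative integer")
  if (m == 0L) message("subsampling to zero lines: returning an empty table")
  key <- interaction(experiment$n_loci, experiment$sex_linked, experiment$d,
                     experiment$h, experiment$A, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(experiment)), key), function(idx) {
    if (m > length(idx))
      stop(sprintf("cannot subsample %d of %d lines", m, length(idx)))
    if (m == length(idx)) idx else sort(sample(idx, m))
  }), use.names = FALSE)
  out <- experiment[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fixation") <- NULL
  attr(out, "trajectories") <- NULL
  class(out) <- c("inbreeding_experiment", "data.frame")
  out
}
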