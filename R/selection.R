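#' Build the parameter grid for a scenario scan
#'
#' The scan covers 100 combinations per architecture: dominance
#' \code{d} in \{0, 0.25, 0.5, 0.75, 1\}, heritability \code{h} in
#' \{0.2, 0.4, 0.6, 0.8, 1\} and founding dispersal-allele frequency \code{A}
#' in \{0.2, 0.4, 0.6, 0.8\}.  Frequencies of 0 and 1 and a heritability of 0
#' are excluded because no response to selection is possible there.
#'
#' @param n_loci Vector of locus numbers; one 100-row block per entry.
#' @param sex_linked Logical; X-linked single-locus grid (requires
#'   \code{n_loci = 1}).
#' @param d,h,A Optional overrides of the lattice values.
#' @return Data frame with columns \code{n_loci}, \code{sex_linked},
#'   \code{d}, \code{h}, \code{A}.
#' @examples
#' nrow(build_parameter_grid(1))               # 100
#' nrow(build_parameter_grid(c(1, 3, 5, 10)))  # 400
#' @export
build_parameter_grid <- function(n_loci = c(1L, 3L, 5L, 10L),
                                 sex_linked = FALSE,
                                 d = c(0, 0.25, 0.5, 0.75, 1),
                                 h = c(0.2, 0.4, 0.6, 0.8, 1),
                                 A = c(0.2, 0.4, 0.6, 0.8)) {
  if (sex_linked && !identical(as.integer(n_loci), 1L))
    stop("the X-linked grid is only defined for n_loci = 1")
  if (any(h == 0) || any(A %in% c(0, 1)))
    stop("scenarios with h = 0 or A in {0, 1} are excluded: evolution is not possible")
  grids <- lapply(as.integer(n_loci), function(L) {
    g <- expand.grid(d = d, h = h, A = A, KEEP.OUT.ATTRS = FALSE)
    data.frame(n_loci = L, sex_linked = sex_linked, g)
  })
  out <- do.call(rbind, grids)
  rownames(out) <- NULL
  out
}

#' Select parents after a 3-opportunity assay
#'
#' High-regime qualifiers dispersed on all \code{k} opportunities; low-regime
#' qualifiers never dispersed.  If more than \code{n_par} individuals qualify,
#' \code{n_par} are sampled uniformly without replacement; otherwise all
#' qualifiers are taken.  If the qualifying set lacks a sex entirely, the
#' individual of the missing sex whose phenotype is closest to the selection
#' criterion is added (ties broken at random), so a line can never go extinct
#' for want of one sex.
#'
#' @param assay A \code{"dispersal_assay"} from a \code{k}-opportunity assay.
#' @param regime \code{"high"} or \code{"low"}.
#' @param n_par Number of parents aimed for (30 in the experimental design).
#' @return List with cohorts \code{mothers} (females) and \code{fathers}
#'   (males).
#' @export
select_parents <- function(assay, regime = c("high", "low"), n_par = 30L) {
  stopifnot(inherits(assay, "dispersal_assay"))
  regime <- match.arg(regime)
  target <- if (regime == "high") assay$k else 0L
  qual <- which(assay$counts == target)
  if (length(qual) > n_par) qual <- sample(qual, n_par)
  for (want_male in c(FALSE, TRUE)) {
    if (!any(assay$male[qual] == want_male)) {
      pool <- which(assay$male == want_male)
      dist <- abs(assay$counts[pool] - target)
      best <- pool[dist == min(dist)]
      add <- if (length(best) > 1L) sample(best, 1L) else best
      qual <- c(qual, add)
    }
  }
  coh <- assay$cohort
  list(mothers = coh[qual[!assay$male[qual]]],
       fathers = coh[qual[assay$male[qual]]])
}

# Lean inner loop shared by run_selection_replicate() and
# run_parameter_scan(): no data-frame construction, minimal dispatch.
# Returns per-generation summary vectors and (optionally) the parents
# selected from the final assay.
selection_core <- function(arch, regime, n_generations, cohort_size, n_par,
                           assay_k, line_id, keep_parents = FALSE) {
  coh <- found_cohort(arch, n = cohort_size, line_id = line_id,
                      generation = 1L)
  ngen <- n_generations + 1L
  mean_d <- freq <- m_mean <- f_mean <- numeric(ngen)
  parents <- NULL
  for (g in seq_len(ngen)) {
    assay <- run_dispersal_assay(coh, k = assay_k)
    mean_d[g] <- mean(assay$counts)
    freq[g] <- allele_freq(coh)
    m_mean[g] <- mean(assay$counts[assay$male])
    f_mean[g] <- mean(assay$counts[!assay$male])
    parents <- select_parents(assay, regime, n_par = n_par)
    if (g <= n_generations) {
      coh <- breed_cohort(parents$mothers, parents$fathers,
                          n_offspring = cohort_size, line_id = line_id)
    }
  }
  list(mean_dispersals = mean_d, allele_freq = freq, male_mean = m_mean,
       female_mean = f_mean,
       final_parents = if (keep_parents) parents else NULL)
}

#' Simulate one selection line
#'
#' Founds a cohort of \code{cohort_size} individuals at the architecture's
#' founding allele frequency, assays it (generation 1, the stock behaviour),
#' then runs \code{n_generations} cycles of truncation selection: qualifiers
#' are selected from the 3-opportunity assay, up to \code{n_par} parents are
#' mass mated, and the next cohort of \code{cohort_size} offspring is
#' assayed.
#'
#' @param arch A [genetic_architecture()].
#' @param regime \code{"high"} or \code{"low"}.
#' @param n_generations Number of selection cycles after the founding assay.
#' @param cohort_size Assayed cohort size per generation.
#' @param n_par Parents selected per generation.
#' @param assay_k Opportunities per assay.
#' @param line_id Line identifier.
#' @param seed Optional seed applied before founding (otherwise the current
#'   RNG state is used).
#' @param keep_parents If \code{TRUE}, the parents selected from the final
#'   assay are attached as attribute \code{"final_parents"} (used to breed
#'   crosses).
#' @return A data frame of class \code{"line_trajectory"} with one row per
#'   tracked generation (1 to \code{n_generations + 1}): mean dispersals,
#'   dispersal-allele frequency and per-sex mean dispersals.
#' @export
run_selection_replicate <- function(arch, regime = c("high", "low"),
                                    n_generations = 4L, cohort_size = 200L,
                                    n_par = 30L, assay_k = 3L,
                                    line_id = NULL, seed = NULL,
                                    keep_parents = FALSE) {
  stopifnot_architecture(arch)
  regime <- match.arg(regime)
  if (n_par > cohort_size) stop("'n_par' cannot exceed 'cohort_size'")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(line_id)) line_id <- paste0(toupper(substr(regime, 1, 1)), "1")
  core <- selection_core(arch, regime, n_generations, cohort_size, n_par,
                         assay_k, line_id, keep_parents = keep_parents)
  out <- data.frame(
    line_id = line_id, regime = regime,
    generation = seq_len(n_generations + 1L),
    mean_dispersals = core$mean_dispersals, allele_freq = core$allele_freq,
    male_mean = core$male_mean, female_mean = core$female_mean,
    stringsAsFactors = FALSE)
  class(out) <- c("line_trajectory", "data.frame")
  if (keep_parents) attr(out, "final_parents") <- core$final_parents
  out
}

#' Run the simulated selection experiment over a scenario grid
#'
#' For every row of \code{grid} and every repeat, one high and one low
#' selection line are simulated independently (each repeat mirrors one
#' high/low line pair of the experimental design).  Each (scenario, repeat,
#' regime) triple runs on its own deterministically derived RNG substream, so
#' any replicate can be regenerated in isolation from the top-level seed.
#'
#' @param grid Data frame from [build_parameter_grid()] (columns
#'   \code{n_loci}, \code{sex_linked}, \code{d}, \code{h}, \code{A}).
#' @param n_repeats Independent high/low line pairs per scenario.
#' @param seed Top-level seed.
#' @param baseline Baseline dispersal probability passed to every
#'   architecture.
#' @param n_generations,cohort_size,n_par,assay_k Demographic constants of
#'   the selection design.
#' @param verbose Print scenario progress.
#' @return A data frame of class \code{"dispersal_scan"}: one row per line
#'   and generation, carrying the scenario parameters, with the call's
#'   settings in attributes.
#' @seealso [score_scan()] to score the result against the experimental
#'   selection-response model.
#' @export
run_parameter_scan <- function(grid, n_repeats = 50L, seed = 1L,
                               baseline = 0.5, n_generations = 4L,
                               cohort_size = 200L, n_par = 30L, assay_k = 3L,
                               verbose = FALSE) {
  stopifnot(is.data.frame(grid),
            all(c("n_loci", "sex_linked", "d", "h", "A") %in% names(grid)))
  n_repeats <- as.integer(n_repeats)
  ngen <- n_generations + 1L
  per_line <- ngen
  per_scenario <- 2L * n_repeats * per_line
  N <- nrow(grid) * per_scenario
  scenario <- replicate_id <- n_loci_c <- integer(N)
  sexl <- logical(N)
  d_c <- h_c <- A_c <- gen_c <- mean_c <- freq_c <- mm_c <- fm_c <- numeric(N)
  regime_c <- character(N)

  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    arch <- genetic_architecture(sc$n_loci, sc$sex_linked, sc$d, sc$h, sc$A,
                                 baseline = baseline)
    off <- (i - 1L) * per_scenario
    for (r in seq_len(n_repeats)) {
      for (code in 1:2) {
        regime <- c("high", "low")[code]
        set.seed(derive_seed(seed, i, r, code))
        core <- selection_core(arch, regime, n_generations, cohort_size,
                               n_par, assay_k,
                               line_id = sprintf("%s%d",
                                                 c("H", "L")[code], r))
        idx <- off + seq_len(per_line)
        off <- off + per_line
        scenario[idx] <- i
        replicate_id[idx] <- r
        n_loci_c[idx] <- sc$n_loci
        sexl[idx] <- sc$sex_linked
        d_c[idx] <- sc$d; h_c[idx] <- sc$h; A_c[idx] <- sc$A
        regime_c[idx] <- regime
        gen_c[idx] <- seq_len(per_line)
        mean_c[idx] <- core$mean_dispersals
        freq_c[idx] <- core$allele_freq
        mm_c[idx] <- core$male_mean
        fm_c[idx] <- core$female_mean
      }
    }
    if (verbose && i %% 25L == 0L)
      message(sprintf("scanned %d / %d scenarios", i, nrow(grid)))
  }
  out <- data.frame(
    scenario = scenario, n_loci = n_loci_c, sex_linked = sexl, d = d_c,
    h = h_c, A = A_c, replicate = replicate_id, regime = regime_c,
    generation = gen_c, mean_dispersals = mean_c, allele_freq = freq_c,
    male_mean = mm_c, female_mean = fm_c, stringsAsFactors = FALSE)
  attr(out, "n_repeats") <- n_repeats
  attr(out, "seed") <- seed
  attr(out, "settings") <- list(baseline = baseline,
                                n_generations = n_generations,
                                cohort_size = cohort_size, n_par = n_par,
                                assay_k = assay_k)
  class(out) <- c("dispersal_scan", "data.frame")
  out
}

#' Summarise a parameter scan by scoring it against the experimental model
#'
#' Convenience wrapper: \code{summary(scan)} is [score_scan()] with the
#' shipped selection reference model.
#'
#' @param object A \code{"dispersal_scan"}.
#' @param model A [reference_model()] of kind \code{"selection"}.
#' @param ... Passed to [score_scan()].
#' @return A \code{"scan_scores"} table.
#' @export
summary.dispersal_scan <- function(object,
                                   model = reference_model("selection"),
                                   ...) {
  score_scan(object, model, ...)
}

#' @export
print.dispersal_scan <- function(x, ...) {
  ns <- length(unique(x$scenario))
  cat(sprintf(
    "Parameter scan: %d scenarios x %d repeats (high/low pairs), %d rows\n",
    ns, attr(x, "n_repeats"), nrow(x)))
  cat(sprintf("  architectures: %s\n",
              paste(sort(unique(paste0(x$n_loci, "-locus",
                                       ifelse(x$sex_linked, " X-linked", "")))),
                    collapse = ", ")))
  invisible(x)
}
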