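#' Breed the offspring cohort of one reciprocal cross
#'
#' Mates the selected parents of a high line and a low line according to the
#' cross type.  Cross types are coded sire line first: \code{"HmLf"} crosses
#' high-line males to low-line females, \code{"LmHf"} the reciprocal, and
#' \code{"HmHf"} / \code{"LmLf"} are the within-regime crosses.  The offspring
#' cohort is mass-bred by polygamous random union with a deterministic 1:1
#' sex ratio.
#'
#' @param high_parents,low_parents Lists with cohorts \code{mothers} and
#'   \code{fathers}, as returned by [select_parents()] from the final
#'   generation of a selection line.
#' @param cross_type One of \code{"HmHf"}, \code{"HmLf"}, \code{"LmHf"},
#'   \code{"LmLf"}.
#' @param n_offspring Offspring cohort size (200: 100 per sex).
#' @return A cohort of offspring.
#' @export
simulate_cross_cohort <- function(high_parents, low_parents,
                                  cross_type = c("HmHf", "HmLf", "LmHf",
                                                 "LmLf"),
                                  n_offspring = 200L) {
  cross_type <- match.arg(cross_type)
  sire_pool <- if (substr(cross_type, 1, 2) == "Hm") high_parents else low_parents
  dam_pool <- if (substr(cross_type, 3, 4) == "Hf") high_parents else low_parents
  breed_cohort(dam_pool$mothers, sire_pool$fathers,
               n_offspring = n_offspring, sex_assignment = "balanced",
               line_id = cross_type)
}

#' Simulate the reciprocal-cross experiment
#'
#' For each replicate, one high and one low selection line are simulated
#' under the given single-locus scenario (defaults: the best-fitting scenario
#' \code{h = 0.6}, \code{d = 0.5}, \code{A = 0.8}); the parents selected from
#' their final assay are then mated in all four cross types, and each
#' offspring cohort of 200 (100 per sex) goes through a 1-opportunity
#' dispersal assay.  Disperser counts are recorded per sex.
#'
#' @param n_replicates Number of simulated line pairs.
#' @param sex_linked Logical; X-linked or autosomal architecture.
#' @param d,h,A Scenario parameters of the architecture.
#' @param baseline Baseline dispersal probability.
#' @param seed Top-level seed (each replicate derives its own substream).
#' @param n_generations,cohort_size,n_par Selection-phase constants.
#' @param n_offspring Offspring per cross assay.
#' @return A data frame of class \code{"cross_experiment"} with one row per
#'   replicate, cross type and sex: \code{dispersers} out of
#'   \code{cohort_size/2}.
#' @seealso [fit_cross_model()] for the fixed-effect analysis mirroring the
#'   experimental model.
#' @export
run_cross_experiment <- function(n_replicates = 50L, sex_linked = FALSE,
                                 d = 0.5, h = 0.6, A = 0.8, baseline = 0.5,
                                 seed = 1L, n_generations = 4L,
                                 cohort_size = 200L, n_par = 30L,
                                 n_offspring = 200L) {
  arch <- genetic_architecture(1L, sex_linked, d, h, A, baseline = baseline)
  types <- c("HmHf", "HmLf", "LmHf", "LmLf")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, 901L, r, 1L))
    high <- run_selection_replicate(arch, "high",
                                    n_generations = n_generations,
                                    cohort_size = cohort_size, n_par = n_par,
                                    line_id = sprintf("H%d", r),
                                    keep_parents = TRUE)
    set.seed(derive_seed(seed, 901L, r, 2L))
    low <- run_selection_replicate(arch, "low",
                                   n_generations = n_generations,
                                   cohort_size = cohort_size, n_par = n_par,
                                   line_id = sprintf("L%d", r),
                                   keep_parents = TRUE)
    hp <- attr(high, "final_parents")
    lp <- attr(low, "final_parents")
    set.seed(derive_seed(seed, 902L, r))
    block <- vector("list", length(types))
    for (tt in seq_along(types)) {
      off <- simulate_cross_cohort(hp, lp, types[tt],
                                   n_offspring = n_offspring)
      assay <- run_dispersal_assay(off, k = 1L)
      bys <- dispersers_by_sex(assay)
      block[[tt]] <- data.frame(
        sex_linked = sex_linked, replicate = r, cross_type = types[tt],
        sex = c("female", "male"),
        dispersers = c(bys[["female"]], bys[["male"]]),
        cohort_size = c(sum(!assay$male), sum(assay$male)),
        stringsAsFactors = FALSE)
    }
    rows[[r]] <- do.call(rbind, block)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scenario") <- list(sex_linked = sex_linked, d = d, h = h, A = A,
                                baseline = baseline)
  attr(out, "seed") <- seed
  class(out) <- c("cross_experiment", "data.frame")
  out
}

#' @export
print.cross_experiment <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Simulated reciprocal crosses (%s architecture; d = %g, h = %g, A = %g)\n",
    if (sc$sex_linked) "X-linked" else "autosomal", sc$d, sc$h, sc$A))
  cat(sprintf("  %d replicates x 4 cross types x 2 sexes = %d rows\n",
              max(x$replicate), nrow(x)))
  cm <- aggregate(dispersers ~ cross_type + sex, data = x, FUN = mean)
  wide <- stats::reshape(cm, idvar = "cross_type", timevar = "sex",
                         direction = "wide")
  names(wide) <- sub("dispersers.", "", names(wide), fixed = TRUE)
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}
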