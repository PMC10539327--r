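#' Run a simulated dispersal assay
#'
#' Each individual receives \code{k} independent opportunities to disperse;
#' each opportunity succeeds with the individual's per-opportunity dispersal
#' probability, so the recorded count is Binomial(\code{k}, \code{p}).  An
#' individual dispersing at least once is a "disperser".
#'
#' @param cohort A non-empty cohort.
#' @param k Opportunities per individual (1 or 3 in the experimental designs).
#' @return An object of class \code{"dispersal_assay"}: the per-individual
#'   counts with the assayed cohort and its provenance.
#' @examples
#' coh <- found_cohort(genetic_architecture(h = 1, A = 1), n = 20)
#' res <- run_dispersal_assay(coh, k = 3)
#' mean_dispersals(res)  # 3: every opportunity taken
#' @export
run_dispersal_assay <- function(cohort, k = 3L) {
  stopifnot(inherits(cohort, "cohort"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  n <- length(cohort$male)
  if (n == 0L) stop("cannot assay an empty cohort")
  p <- dispersal_probability(cohort)
  counts <- rbinom(n, k, p)
  structure(
    list(counts = counts, k = k, male = cohort$male, cohort = cohort,
         line_id = cohort$line_id, generation = cohort$generation),
    class = "dispersal_assay"
  )
}

#' @export
print.dispersal_assay <- function(x, ...) {
  cat(sprintf("Dispersal assay (k = %d) on line '%s', generation %d\n",
              x$k, x$line_id, x$generation))
  cat(sprintf("  %d individuals, %d dispersers, mean dispersals %.3f\n",
              length(x$counts), n_dispersers(x), mean_dispersals(x)))
  bys <- dispersers_by_sex(x)
  cat(sprintf("  dispersers: %d male, %d female\n", bys[["male"]],
              bys[["female"]]))
  invisible(x)
}

#' Mean dispersals per individual
#' @param assay A dispersal assay result.
#' @return Total dispersals divided by cohort size (0 to \code{k}).
#' @export
mean_dispersals <- function(assay) {
  stopifnot(inherits(assay, "dispersal_assay"))
  mean(assay$counts)
}

#' Number of dispersers (individuals with at least one dispersal)
#' @param assay A dispersal assay result.
#' @return Integer count.
#' @export
n_dispersers <- function(assay) {
  stopifnot(inherits(assay, "dispersal_assay"))
  sum(assay$counts >= 1L)
}

#' Disperser counts split by sex
#' @param assay A dispersal assay result.
#' @return Named integer vector with elements \code{male} and \code{female}.
#' @export
dispersers_by_sex <- function(assay) {
  stopifnot(inherits(assay, "dispersal_assay"))
  disp <- assay$counts >= 1L
  c(male = sum(disp & assay$male), female = sum(disp & !assay$male))
}

#' Sex bias in dispersal tendency
#'
#' Mean dispersals per male minus mean dispersals per female.  Positive values
#' indicate male-biased dispersal.
#'
#' @param assay A dispersal assay result containing both sexes.
#' @return Numeric difference on the 0 to \code{k} scale.
#' @export
sex_bias <- function(assay) {
  stopifnot(inherits(assay, "dispersal_assay"))
  if (!any(assay$male) || all(assay$male))
    stop("sex bias requires both sexes in the assayed cohort")
  mean(assay$counts[assay$male]) - mean(assay$counts[!assay$male])
}

#' Tabulate assay outcomes
#'
#' @param x A dispersal assay result.
#' @param ... Unused.
#' @return Data frame with one row per individual: line, generation, sex,
#'   dispersal count and \code{k}.
#' @export
as.data.frame.dispersal_assay <- function(x, ...) {
  data.frame(line_id = x$line_id, generation = x$generation,
             sex = ifelse(x$male, "male", "female"),
             dispersal_count = x$counts, k = x$k, stringsAsFactors = FALSE)
}
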