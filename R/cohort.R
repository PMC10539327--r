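#' Found a cohort from the stock population
#'
#' Creates a cohort of individuals whose allele copies are drawn independently
#' as dispersal alleles with probability \code{A} (the architecture's founding
#' frequency).  Sexes are assigned as a deterministic split at
#' \code{sex_ratio} (proportion male), with any fractional remainder resolved
#' by a fair coin; male/female positions are randomised.
#'
#' Individuals are stored column-wise as two allele matrices (maternally and
#' paternally inherited copies).  Under X-linkage males are hemizygous: their
#' paternally inherited copy is the non-contributing Y, stored as \code{NA}.
#'
#' @param arch A [genetic_architecture()].
#' @param n Cohort size.
#' @param sex_ratio Proportion of males, in \[0, 1\].
#' @param line_id Opaque line identifier carried through to summaries.
#' @param generation Generation index (\code{>= 0}).
#' @return An object of class \code{"cohort"}.
#' @examples
#' coh <- found_cohort(genetic_architecture(A = 1), n = 10)
#' allele_freq(coh)  # exactly 1
#' @export
found_cohort <- function(arch, n = 200L, sex_ratio = 0.5, line_id = "L1",
                         generation = 0L) {
  stopifnot_architecture(arch)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop("'sex_ratio' must be in [0, 1]")
  male <- balanced_sexes(n, sex_ratio)
  L <- arch$n_loci
  maternal <- matrix(as.integer(runif(n * L) < arch$A), n, L)
  paternal <- matrix(as.integer(runif(n * L) < arch$A), n, L)
  if (arch$sex_linked) paternal[male, ] <- NA_integer_
  new_cohort(maternal, paternal, male, arch, generation, line_id)
}

# deterministic split with randomised remainder and positions
balanced_sexes <- function(n, sex_ratio = 0.5) {
  n_m <- floor(n * sex_ratio)
  if (runif(1) < n * sex_ratio - n_m) n_m <- n_m + 1L
  male <- logical(n)
  if (n_m > 0L) male[sample.int(n, n_m)] <- TRUE
  male
}

new_cohort <- function(maternal, paternal, male, arch, generation, line_id) {
  structure(
    list(maternal = maternal, paternal = paternal, male = male,
         architecture = arch, generation = as.integer(generation),
         line_id = line_id),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s' (generation %d): %d individuals (%d M / %d F), %s\n",
              x$line_id, x$generation, length(x$male), sum(x$male),
              sum(!x$male),
              sprintf("%d %s locus/loci", x$architecture$n_loci,
                      if (x$architecture$sex_linked) "X-linked" else "autosomal")))
  cat(sprintf("  dispersal-allele frequency: %.3f\n", allele_freq(x)))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$male)

#' Subset a cohort
#'
#' @param x A cohort.
#' @param i Index vector of individuals.
#' @param ... Unused.
#' @return A cohort containing the selected individuals.
#' @export
`[.cohort` <- function(x, i, ...) {
  new_cohort(x$maternal[i, , drop = FALSE], x$paternal[i, , drop = FALSE],
             x$male[i], x$architecture, x$generation, x$line_id)
}

#' Dispersal-allele frequency of a cohort
#'
#' The frequency of the dispersal allele among trait-contributing allele
#' copies, averaged over loci.  Under X-linkage males contribute one copy per
#' locus and females two.
#'
#' @param cohort A cohort.
#' @return Frequency in \[0, 1\].
#' @export
allele_freq <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  tot <- sum(cohort$maternal) + sum(cohort$paternal, na.rm = TRUE)
  copies <- sum(!is.na(cohort$maternal)) + sum(!is.na(cohort$paternal))
  tot / copies
}

# per-locus frequency vector (used by inbreeding fixation summaries)
allele_freq_by_locus <- function(cohort) {
  tot <- colSums(cohort$maternal) + colSums(cohort$paternal, na.rm = TRUE)
  copies <- colSums(!is.na(cohort$maternal)) + colSums(!is.na(cohort$paternal))
  tot / copies
}

#' Genotypic score of each individual
#'
#' Per locus the score is 0 (no dispersal allele), \code{d} (heterozygote) or
#' 1 (dispersal homozygote); hemizygous X-linked males score 0 or 1 from their
#' single allele.  The individual's score is the mean over loci.
#'
#' @param cohort A cohort.
#' @return Numeric vector in \[0, 1\], one score per individual.
#' @export
genotypic_score <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  arch <- cohort$architecture
  g <- cohort$maternal + cohort$paternal            # 0, 1, 2 (NA for X males)
  s <- (g == 1L) * arch$d + (g == 2L)
  if (arch$sex_linked && any(cohort$male)) {
    s[cohort$male, ] <- cohort$maternal[cohort$male, , drop = FALSE]
  }
  rowMeans(s)
}

#' Per-opportunity dispersal probability of each individual
#'
#' Applies the genotype-to-phenotype map \eqn{p = h s + (1 - h) b} where
#' \eqn{s} is the genotypic score, \eqn{h} the heritability weight and
#' \eqn{b} the baseline dispersal probability.
#'
#' @param cohort A cohort.
#' @return Numeric vector of probabilities.
#' @export
dispersal_probability <- function(cohort) {
  arch <- cohort$architecture
  arch$h * genotypic_score(cohort) + (1 - arch$h) * arch$baseline
}

#' Draw one gamete per individual
#'
#' For autosomal loci (and for X-linked females) one of the two allele copies
#' is chosen uniformly and independently at each locus (free assortment, no
#' linkage).  An X-linked male's gamete is his single X-borne allele; whether
#' an offspring receives it or the Y is decided by the offspring's sex at
#' breeding time.
#'
#' @param cohort A cohort.
#' @return Integer matrix (individuals by loci) of transmitted alleles.
#' @export
make_gametes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n <- length(cohort$male)
  L <- cohort$architecture$n_loci
  g <- cohort$maternal
  if (cohort$architecture$sex_linked) {
    f <- !cohort$male
    if (any(f)) {
      swap <- matrix(runif(sum(f) * L) < 0.5, sum(f), L)
      gf <- g[f, , drop = FALSE]
      pf <- cohort$paternal[f, , drop = FALSE]
      gf[swap] <- pf[swap]
      g[f, ] <- gf
    }
  } else {
    swap <- matrix(runif(n * L) < 0.5, n, L)
    g[swap] <- cohort$paternal[swap]
  }
  g
}

#' Breed a new cohort from parental pools
#'
#' Each offspring is produced by a uniformly chosen mother and a uniformly
#' chosen father (polygamous random union, drawn independently per offspring),
#' receiving one gamete from each.  Under X-linkage daughters receive the
#' father's X and sons his Y (so sons' X comes from the mother only).
#'
#' @param mothers Cohort of female parents (at least one individual, all
#'   female).
#' @param fathers Cohort of male parents (at least one individual, all male).
#' @param n_offspring Number of offspring.
#' @param sex_assignment \code{"balanced"} for a deterministic 1:1 split
#'   (assay cohorts) or \code{"random"} for independent fair-coin sexes
#'   (small sibships).
#' @param line_id Line identifier for the offspring cohort; defaults to the
#'   mothers' line.
#' @return A cohort with \code{generation} incremented from the mothers'.
#' @export
breed_cohort <- function(mothers, fathers, n_offspring = 200L,
                         sex_assignment = c("balanced", "random"),
                         line_id = NULL) {
  stopifnot(inherits(mothers, "cohort"), inherits(fathers, "cohort"))
  sex_assignment <- match.arg(sex_assignment)
  if (length(mothers$male) == 0L || any(mothers$male))
    stop("'mothers' must be a non-empty all-female cohort")
  if (length(fathers$male) == 0L || any(!fathers$male))
    stop("'fathers' must be a non-empty all-male cohort")
  arch <- mothers$architecture
  n <- as.integer(n_offspring)
  if (is.na(n) || n < 1L) stop("'n_offspring' must be a positive integer")
  L <- arch$n_loci

  mi <- sample.int(length(mothers$male), n, replace = TRUE)
  fi <- sample.int(length(fathers$male), n, replace = TRUE)
  male <- if (sex_assignment == "balanced") balanced_sexes(n) else runif(n) < 0.5

  # maternal gametes
  gm <- mothers$maternal[mi, , drop = FALSE]
  pm <- mothers$paternal[mi, , drop = FALSE]
  swap <- matrix(runif(n * L) < 0.5, n, L)
  gm[swap] <- pm[swap]

  if (arch$sex_linked) {
    gp <- fathers$maternal[fi, , drop = FALSE]   # the father's X
    gp[male, ] <- NA_integer_                    # sons receive the Y
  } else {
    gp <- fathers$maternal[fi, , drop = FALSE]
    pp <- fathers$paternal[fi, , drop = FALSE]
    swap <- matrix(runif(n * L) < 0.5, n, L)
    gp[swap] <- pp[swap]
  }
  new_cohort(gm, gp, male, arch,
             generation = mothers$generation + 1L,
             line_id = if (is.null(line_id)) mothers$line_id else line_id)
}

#' Tabulate a cohort as a data frame
#'
#' One row per individual with line, generation, sex and per-locus genotype
#' codes (number of dispersal alleles; \code{NA}-free hemizygous males report
#' their single allele).
#'
#' @param x A cohort.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.cohort <- function(x, ...) {
  g <- x$maternal + ifelse(is.na(x$paternal), 0L, x$paternal)
  colnames(g) <- paste0("locus", seq_len(ncol(g)))
  data.frame(line_id = x$line_id, generation = x$generation,
             sex = ifelse(x$male, "male", "female"), g,
             stringsAsFactors = FALSE)
}
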