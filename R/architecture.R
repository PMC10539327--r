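#' Define a genetic architecture for the dispersal trait
#'
#' A genetic architecture describes how dispersal probability is determined:
#' the number of additive, unlinked, biallelic loci, whether the single-locus
#' case is X-linked, the dominance of the dispersal allele, the heritability
#' weighting of genotype against a fixed baseline, and the founding frequency
#' of the dispersal allele in the stock population.
#'
#' At each locus the genotypic score is 0 for non-dispersal homozygotes,
#' \code{d} for heterozygotes and 1 for dispersal homozygotes; an individual's
#' score is the mean across loci.  Under X-linkage males are hemizygous: they
#' carry a single X-borne allele (score 0 or 1) and a Y that does not
#' contribute to the phenotype.  The per-opportunity dispersal probability is
#' \deqn{p = h s + (1 - h) b,} so that at \code{h = 0} behaviour is genotype
#' independent (probability \code{b}) and at \code{h = 1} it is fully
#' genetically determined.
#'
#' @param n_loci Number of loci (1, 3, 5 or 10 in the study design; any
#'   positive integer is accepted).
#' @param sex_linked Logical; X-linked inheritance.  Only valid with
#'   \code{n_loci = 1}.
#' @param d Dominance of the dispersal allele, in \[0, 1\].
#' @param h Heritability weight, in \[0, 1\].
#' @param A Founding dispersal-allele frequency, in \[0, 1\] (applied to every
#'   locus).
#' @param baseline Dispersal probability at \code{h = 0}; defaults to 0.5.
#' @return An object of class \code{"genetic_architecture"}.
#' @examples
#' arch <- genetic_architecture(n_loci = 3, d = 0.5, h = 0.6, A = 0.8)
#' arch
#' @export
genetic_architecture <- function(n_loci = 1L, sex_linked = FALSE, d = 0.5,
                                 h = 0.6, A = 0.8, baseline = 0.5) {
  n_loci <- as.integer(n_loci)
  if (length(n_loci) != 1L || is.na(n_loci) || n_loci < 1L)
    stop("'n_loci' must be a single positive integer")
  if (!is.logical(sex_linked) || length(sex_linked) != 1L || is.na(sex_linked))
    stop("'sex_linked' must be TRUE or FALSE")
  if (sex_linked && n_loci != 1L)
    stop("X-linked architectures are only defined for a single locus")
  for (nm in c("d", "h", "A", "baseline")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < 0 || val > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", nm))
  }
  structure(
    list(n_loci = n_loci, sex_linked = sex_linked, d = as.numeric(d),
         h = as.numeric(h), A = as.numeric(A), baseline = as.numeric(baseline)),
    class = "genetic_architecture"
  )
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(
    "Genetic architecture: %d %s locus/loci (d = %g, h = %g, A = %g, baseline = %g)\n",
    x$n_loci, if (x$sex_linked) "X-linked" else "autosomal",
    x$d, x$h, x$A, x$baseline))
  invisible(x)
}

is_architecture <- function(x) inherits(x, "genetic_architecture")

stopifnot_architecture <- function(x) {
  if (!is_architecture(x)) stop("expected a 'genetic_architecture' object")
  invisible(x)
}
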