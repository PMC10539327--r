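#' Load a printed reference coefficient set
#'
#' The evaluation layer scores simulations against the fixed-effect
#' coefficients of the models fitted to the experimental data, consumed as
#' printed values (they are data, not re-estimated).  Two sets ship with the
#' package as editable plain-text tables:
#' \describe{
#'   \item{\code{"selection"}}{the selection-response model: mean dispersals
#'     per individual (0--3) modelled on an orthogonal second-order polynomial
#'     of generation, selection regime (reference \code{"high"}), their
#'     interactions, and a two-level block effect.}
#'   \item{\code{"crosses"}}{the reciprocal-cross model: per-sex dispersers
#'     out of 100 modelled on cross type (reference \code{"HmLf"}: high-line
#'     sire by low-line dam), sex (reference female) and their interaction.}
#' }
#'
#' @param which \code{"selection"} or \code{"crosses"}.
#' @param file Optional path to a custom coefficient table (tab separated,
#'   columns \code{term} and \code{estimate}) replacing the shipped one.
#' @return An object of class \code{"reference_model"}.
#' @examples
#' reference_model("selection")
#' @export
reference_model <- function(which = c("selection", "crosses"), file = NULL) {
  which <- match.arg(which)
  if (is.null(file)) {
    file <- system.file("extdata",
                        paste0(which, "_model_coefficients.tsv"),
                        package = "dispersim")
  }
  if (!nzchar(file) || !file.exists(file))
    stop(sprintf("reference coefficient file not found: '%s'", file))
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("term", "estimate") %in% names(tab)))
    stop("coefficient file needs columns 'term' and 'estimate'")
  if (anyDuplicated(tab$term))
    stop("duplicated terms in coefficient file: ",
         paste(tab$term[duplicated(tab$term)], collapse = ", "))
  coefs <- setNames(tab$estimate, tab$term)
  required <- switch(which,
    selection = c("intercept", "generation_linear", "generation_quadratic",
                  "regime_low", "block", "generation_linear:regime_low",
                  "generation_quadratic:regime_low"),
    crosses = c("intercept", "cross_HmHf", "cross_LmHf", "cross_LmLf",
                "sex_male", "cross_HmHf:sex_male", "cross_LmHf:sex_male",
                "cross_LmLf:sex_male"))
  missing <- setdiff(required, names(coefs))
  if (length(missing))
    stop("coefficient file is missing terms: ", paste(missing, collapse = ", "))
  structure(list(kind = which, coefficients = coefs, file = file),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("Reference model '%s' (%d printed coefficients)\n", x$kind,
              length(x$coefficients)))
  print(round(x$coefficients, 3))
  invisible(x)
}

# Orthogonal polynomial basis over generations 1..5.
#
# The printed coefficients come from a model fitted with an orthogonal
# second-order polynomial of generation.  R's poly() normalises the basis
# columns to unit length over the *model rows*, not over the five generation
# values, so the column value at generation g is contrast_g / sqrt(R * ss)
# where R is the number of lines observed per generation in the fitted data
# set (32: 16 high + 16 low) and ss the contrast sum of squares.  The
# "contrast" basis (unit norm over the five generation values) and a raw
# power basis are provided as alternatives.
generation_basis <- function(generation, basis = c("design", "contrast", "raw"),
                             design_replicates = 32L) {
  basis <- match.arg(basis)
  g <- as.numeric(generation)
  if (any(g < 1 | g > 5 | g != round(g)))
    stop("'generation' must be integers between 1 and 5")
  if (basis == "raw") return(cbind(linear = g, quadratic = g^2))
  scale <- if (basis == "design") as.numeric(design_replicates) else 1
  cbind(linear = (g - 3) / sqrt(10 * scale),
        quadratic = ((g - 3)^2 - 2) / sqrt(14 * scale))
}

#' Predicted selection response from the printed experimental model
#'
#' Evaluates the linear predictor of the experimental selection-response
#' model at given generations and regimes, on the mean-dispersals 0--3 scale.
#' Generation enters through an orthogonal second-order polynomial; the block
#' effect (0/1 coding) is averaged over its two levels by default because
#' simulated lines have no block structure.
#'
#' @param model A [reference_model()] of kind \code{"selection"}.
#' @param generation Integer vector with values in 1..5 (1 is the stock
#'   population before selection).
#' @param regime Character vector, \code{"high"} or \code{"low"}, recycled
#'   against \code{generation}.
#' @param block \code{"average"} (default), 0 or 1.
#' @param basis Polynomial coding: \code{"design"} (unit-norm over the
#'   fitted model's rows; the default, matching how the printed coefficients
#'   were estimated), \code{"contrast"} (unit-norm over the five generation
#'   values) or \code{"raw"} (raw powers).
#' @param design_replicates Lines per generation in the experimental data set
#'   behind the printed coefficients (32).
#' @return Numeric vector of predicted mean dispersals.
#' @examples
#' m <- reference_model("selection")
#' predict_selection_response(m, 1:5, "high")
#' predict_selection_response(m, 1:5, "low")
#' @export
predict_selection_response <- function(model, generation, regime,
                                       block = "average",
                                       basis = "design",
                                       design_replicates = 32L) {
  stopifnot(inherits(model, "reference_model"))
  if (model$kind != "selection")
    stop("need a reference model of kind 'selection'")
  n <- max(length(generation), length(regime))
  generation <- rep_len(generation, n)
  regime <- rep_len(regime, n)
  if (!all(regime %in% c("high", "low")))
    stop("'regime' must be 'high' or 'low'")
  P <- generation_basis(generation, basis, design_replicates)
  co <- model$coefficients
  low <- as.numeric(regime == "low")
  blk <- if (identical(block, "average")) 0.5 else {
    if (!block %in% c(0, 1)) stop("'block' must be \"average\", 0 or 1")
    as.numeric(block)
  }
  unname(co[["intercept"]] +
    co[["generation_linear"]] * P[, "linear"] +
    co[["generation_quadratic"]] * P[, "quadratic"] +
    co[["regime_low"]] * low +
    co[["generation_linear:regime_low"]] * P[, "linear"] * low +
    co[["generation_quadratic:regime_low"]] * P[, "quadratic"] * low +
    co[["block"]] * blk)
}

#' Predicted cell means from the printed cross model
#'
#' Evaluates the experimental cross model (intercept + cross type + sex +
#' interaction) on the per-sex dispersers-out-of-100 scale.  Cross types are
#' coded sire-line first: \code{"HmLf"} means a high-line male crossed to a
#' low-line female.  Reference categories are cross \code{"HmLf"} and sex
#' \code{"female"}.
#'
#' @param model A [reference_model()] of kind \code{"crosses"}.
#' @param cross_type Character vector in \code{c("HmHf", "HmLf", "LmHf",
#'   "LmLf")}.
#' @param sex Character vector, \code{"female"} or \code{"male"}, recycled.
#' @return Numeric vector of predicted disperser counts per 100.
#' @examples
#' m <- reference_model("crosses")
#' predict_cross_means(m, "HmLf", "female")  # the printed intercept
#' @export
predict_cross_means <- function(model, cross_type, sex) {
  stopifnot(inherits(model, "reference_model"))
  if (model$kind != "crosses")
    stop("need a reference model of kind 'crosses'")
  n <- max(length(cross_type), length(sex))
  cross_type <- rep_len(cross_type, n)
  sex <- rep_len(sex, n)
  if (!all(cross_type %in% c("HmHf", "HmLf", "LmHf", "LmLf")))
    stop("unknown cross type")
  if (!all(sex %in% c("female", "male"))) stop("unknown sex")
  co <- model$coefficients
  male <- as.numeric(sex == "male")
  out <- rep(co[["intercept"]], n) + co[["sex_male"]] * male
  for (ct in c("HmHf", "LmHf", "LmLf")) {
    is_ct <- as.numeric(cross_type == ct)
    out <- out + co[[paste0("cross_", ct)]] * is_ct +
      co[[paste0("cross_", ct, ":sex_male")]] * is_ct * male
  }
  unname(out)
}

#' Coefficient of determination of fixed predictions
#'
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2} for predictions
#' generated outside the data (no refitting), so values may be negative when
#' the predictions fit worse than the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors (length at least
#'   2); \code{observed} must not be constant.
#' @return A single numeric value, at most 1.
#' @examples
#' compute_r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
compute_r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2L) stop("need at least two observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("'observed' is constant: R-squared is undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Score a parameter scan against the experimental selection model
#'
#' For every scenario the observed values are all line-by-generation mean
#' dispersals (repeats of both regimes across the five tracked generations)
#' and the predictions come from [predict_selection_response()] matched on
#' regime and generation.  One pooled R-squared is reported per scenario
#' (both regimes in a single vector), together with per-regime R-squared and
#' the per-regime sex-bias surface (male minus female mean dispersals,
#' averaged over replicates and generations).
#'
#' @param scan A \code{"dispersal_scan"} from [run_parameter_scan()].
#' @param model A [reference_model()] of kind \code{"selection"}; loaded
#'   automatically if omitted.
#' @param ... Passed on to [predict_selection_response()] (e.g. \code{basis}).
#' @return A data frame of class \code{"scan_scores"}, one row per scenario.
#' @export
score_scan <- function(scan, model = reference_model("selection"), ...) {
  stopifnot(inherits(scan, "dispersal_scan") || is.data.frame(scan))
  need <- c("scenario", "n_loci", "sex_linked", "d", "h", "A", "regime",
            "generation", "mean_dispersals", "male_mean", "female_mean")
  stopifnot(all(need %in% names(scan)))
  pred <- predict_selection_response(model, scan$generation, scan$regime, ...)
  obs <- scan$mean_dispersals
  bias <- scan$male_mean - scan$female_mean
  ids <- unique(scan$scenario)
  out <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    sel <- scan$scenario == ids[q]
    hi <- sel & scan$regime == "high"
    lo <- sel & scan$regime == "low"
    out[[q]] <- data.frame(
      scenario = ids[q],
      n_loci = scan$n_loci[sel][1L], sex_linked = scan$sex_linked[sel][1L],
      d = scan$d[sel][1L], h = scan$h[sel][1L], A = scan$A[sel][1L],
      r_squared = compute_r_squared(obs[sel], pred[sel]),
      r_squared_high = compute_r_squared(obs[hi], pred[hi]),
      r_squared_low = compute_r_squared(obs[lo], pred[lo]),
      sex_bias_high = mean(bias[hi]), sex_bias_low = mean(bias[lo]),
      n_points = sum(sel))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("scan_scores", "data.frame")
  res
}

#' @export
print.scan_scores <- function(x, digits = 3, ...) {
  need <- c("n_loci", "sex_linked", "d", "h", "A", "r_squared")
  if (!all(need %in% names(x))) return(NextMethod())
  cat(sprintf("Scenario fit scores: %d scenarios\n", nrow(x)))
  cat(sprintf("  R-squared range: %.3f to %.3f; %d scenario(s) at R2 >= 0.80\n",
              min(x$r_squared), max(x$r_squared), sum(x$r_squared >= 0.80)))
  best <- x[which.max(x$r_squared), ]
  cat(sprintf("  best fit: %d-locus%s d = %g, h = %g, A = %g (R2 = %.3f)\n",
              best$n_loci, if (best$sex_linked) " X-linked" else "",
              best$d, best$h, best$A, best$r_squared))
  invisible(x)
}

#' Heatmaps of scenario fit across parameter space
#'
#' Draws one dominance-by-heritability panel per founding allele frequency
#' for a single architecture, colouring cells by pooled R-squared (or any
#' other column).
#'
#' @param x A \code{"scan_scores"} table.
#' @param n_loci,sex_linked Architecture to display.
#' @param value Column to map to colour.
#' @param ... Unused.
#' @return Invisibly, the displayed subset.
#' @export
plot.scan_scores <- function(x, n_loci = 1L, sex_linked = FALSE,
                             value = "r_squared", ...) {
  sub <- x[x$n_loci == n_loci & x$sex_linked == sex_linked, ]
  if (!nrow(sub)) stop("no scenarios for that architecture in the table")
  As <- sort(unique(sub$A))
  op <- graphics::par(mfrow = c(1, length(As)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  ds <- sort(unique(sub$d)); hs <- sort(unique(sub$h))
  pal <- grDevices::hcl.colors(25, "viridis")
  for (a in As) {
    z <- matrix(NA_real_, length(ds), length(hs))
    cell <- sub[sub$A == a, ]
    z[cbind(match(cell$d, ds), match(cell$h, hs))] <- cell[[value]]
    graphics::image(ds, hs, pmax(z, 0), zlim = c(0, 1), col = pal,
                    xlab = "dominance d", ylab = "heritability h",
                    main = sprintf("A = %g", a))
  }
  invisible(sub)
}
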