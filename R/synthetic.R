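#' Generate a pseudo-experimental selection data set
#'
#' Builds a line-by-generation table with the statistical structure the
#' selection analysis assumes: predicted mean dispersals from the printed
#' experimental model, plus Normal line-level intercepts (between-line
#' variation) and Normal residuals, truncated to the 0--3 response scale.
#' With both standard deviations at zero the table equals the model
#' predictions exactly, which makes noiseless round-trip tests possible.
#' A binomial alternative draws each line-generation mean as the mean of
#' \code{cohort_size} individuals with three opportunities each.
#'
#' @param model A [reference_model()] of kind \code{"selection"}.
#' @param n_lines Lines per regime (16 in the experimental design).
#' @param sigma_line Standard deviation of line intercepts (the printed
#'   random-effect SD is 0.05).
#' @param sigma_res Residual standard deviation.
#' @param seed Optional seed.
#' @param family \code{"gaussian"} (additive noise) or \code{"binomial"}
#'   (counts of dispersals among \code{3 * cohort_size} Bernoulli trials).
#' @param cohort_size Individuals per line and generation for the binomial
#'   family.
#' @param ... Passed to [predict_selection_response()] (e.g. \code{basis}).
#' @return Data frame with columns \code{line_id}, \code{regime},
#'   \code{block}, \code{generation}, \code{mean_dispersals}; the number of
#'   truncated values is recorded in attribute \code{"n_truncated"}.
#' @export
generate_selection_data <- function(model = reference_model("selection"),
                                    n_lines = 16L, sigma_line = 0.05,
                                    sigma_res = 0.2, seed = NULL,
                                    family = c("gaussian", "binomial"),
                                    cohort_size = 200L, ...) {
  family <- match.arg(family)
  if (sigma_line < 0 || sigma_res < 0) stop("standard deviations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  regimes <- rep(c("high", "low"), each = n_lines)
  line_ids <- paste0(ifelse(regimes == "high", "H", "L"),
                     rep(seq_len(n_lines), 2L))
  block <- rep(as.integer(seq_len(n_lines) > n_lines / 2), 2L)
  line_eff <- rnorm(length(line_ids), 0, sigma_line)
  rows <- expand.grid(idx = seq_along(line_ids), generation = 1:5,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- predict_selection_response(model, rows$generation,
                                   regimes[rows$idx],
                                   block = "average", ...) -
    0.5 * model$coefficients[["block"]] +
    block[rows$idx] * model$coefficients[["block"]]
  mu <- mu + line_eff[rows$idx]
  if (family == "gaussian") {
    y <- mu + rnorm(nrow(rows), 0, sigma_res)
  } else {
    p <- pmin(pmax(mu / 3, 0), 1)
    y <- rbinom(nrow(rows), 3L * cohort_size, p) / cohort_size
  }
  n_trunc <- sum(y < 0 | y > 3)
  y <- pmin(pmax(y, 0), 3)
  out <- data.frame(line_id = line_ids[rows$idx], regime = regimes[rows$idx],
                    block = block[rows$idx], generation = rows$generation,
                    mean_dispersals = y, stringsAsFactors = FALSE)
  out <- out[order(out$line_id, out$generation), ]
  rownames(out) <- NULL
  attr(out, "n_truncated") <- n_trunc
  if (n_trunc > 0) message(n_trunc, " value(s) truncated to the 0-3 scale")
  attr(out, "params") <- list(n_lines = n_lines, sigma_line = sigma_line,
                              sigma_res = sigma_res, family = family)
  out
}

#' Generate a pseudo-experimental cross data set
#'
#' Cell means from the printed cross model plus Normal line-pair intercepts
#' and residual noise, truncated to the 0--100 per-sex disperser scale (or a
#' binomial alternative drawing dispersers directly out of 100).
#'
#' @param model A [reference_model()] of kind \code{"crosses"}.
#' @param n_pairs Line pairs (16 in the experimental design).
#' @param sigma_pair SD of pair intercepts (the printed random-effect SD is
#'   10.78).
#' @param sigma_res Residual SD (5 is about the binomial sampling noise of
#'   counts near 50 out of 100).
#' @param seed Optional seed.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @return Data frame with columns \code{pair}, \code{cross_type},
#'   \code{sex}, \code{dispersers}; truncation count in attribute
#'   \code{"n_truncated"}.
#' @export
generate_cross_data <- function(model = reference_model("crosses"),
                                n_pairs = 16L, sigma_pair = 10.78,
                                sigma_res = 5, seed = NULL,
                                family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (sigma_pair < 0 || sigma_res < 0) stop("standard deviations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(pair = seq_len(n_pairs),
                      cross_type = c("HmLf", "HmHf", "LmHf", "LmLf"),
                      sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pair_eff <- rnorm(n_pairs, 0, sigma_pair)
  mu <- predict_cross_means(model, rows$cross_type, rows$sex) +
    pair_eff[rows$pair]
  if (family == "gaussian") {
    y <- mu + rnorm(nrow(rows), 0, sigma_res)
  } else {
    y <- rbinom(nrow(rows), 100L, pmin(pmax(mu / 100, 0), 1))
  }
  n_trunc <- sum(y < 0 | y > 100)
  y <- pmin(pmax(y, 0), 100)
  out <- data.frame(rows, dispersers = y, stringsAsFactors = FALSE)
  out <- out[order(out$pair, out$cross_type, out$sex), ]
  rownames(out) <- NULL
  attr(out, "n_truncated") <- n_trunc
  if (n_trunc > 0) message(n_trunc, " value(s) truncated to the 0-100 scale")
  attr(out, "params") <- list(n_pairs = n_pairs, sigma_pair = sigma_pair,
                              sigma_res = sigma_res, family = family)
  out
}

#' Refit the selection-response fixed-effect structure
#'
#' Ordinary least squares of line-by-generation mean dispersals on the same
#' fixed-effect structure as the experimental selection model (orthogonal
#' second-order generation polynomial, regime, block where present, and the
#' generation-by-regime interactions).  Used for round-trip recovery checks
#' on synthetic data and as the least-squares ceiling for transfer R-squared
#' comparisons.
#'
#' @param data Data frame with columns \code{generation}, \code{regime},
#'   \code{mean_dispersals} and optionally \code{block}.
#' @param basis,design_replicates Polynomial coding, as in
#'   [predict_selection_response()].
#' @return An \code{lm} fit whose coefficients are named like the reference
#'   coefficient table.
#' @export
fit_selection_model <- function(data, basis = "design",
                                design_replicates = 32L) {
  stopifnot(all(c("generation", "regime", "mean_dispersals") %in% names(data)))
  P <- generation_basis(data$generation, basis, design_replicates)
  df <- data.frame(
    y = data$mean_dispersals,
    generation_linear = P[, "linear"],
    generation_quadratic = P[, "quadratic"],
    regime_low = as.numeric(data$regime == "low"))
  fml <- "y ~ generation_linear + generation_quadratic + regime_low +
            generation_linear:regime_low + generation_quadratic:regime_low"
  if ("block" %in% names(data) && length(unique(data$block)) > 1L) {
    df$block <- as.numeric(data$block)
    fml <- paste(fml, "+ block")
  }
  fit <- lm(stats::as.formula(fml), data = df)
  nm <- names(coef(fit))
  nm[nm == "(Intercept)"] <- "intercept"
  names(fit$coefficients) <- nm
  fit
}
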