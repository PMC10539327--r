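#' Fixed-effect linear model for cross assay tables
#'
#' Fits the analysis model used for simulated cross data: ordinary least
#' squares of per-sex disperser counts on cross type (reference
#' \code{"HmLf"}), sex (reference female), and optionally their interaction.
#' This mirrors the experimental mixed model with the line random effect
#' dropped, which is how the simulated data were analysed (the random effect
#' explains no variance there).  Two-sided t-test p-values are reported per
#' coefficient.
#'
#' @param table Data frame with columns \code{cross_type}, \code{sex} and
#'   \code{dispersers} (e.g. a \code{"cross_experiment"} or a synthetic cross
#'   table).
#' @param formula_kind \code{"interaction"} (cross type, sex and their
#'   interaction) or \code{"main_effects"} (cross type and sex only).
#' @param covariates Optional names of additional columns entered as fixed
#'   effects.
#' @return An object of class \code{"cross_model"}: a coefficient table with
#'   estimates, standard errors, t statistics and p-values, plus the
#'   underlying \code{lm} fit.
#' @examples
#' tab <- expand.grid(cross_type = c("HmLf", "HmHf"), sex = c("female", "male"),
#'                    rep = 1:3)
#' tab$dispersers <- c(50, 80, 50, 80, 51, 79, 49, 81, 50, 80, 50, 80)
#' fit_cross_model(tab, "main_effects")
#' @export
fit_cross_model <- function(table,
                            formula_kind = c("interaction", "main_effects"),
                            covariates = NULL) {
  formula_kind <- match.arg(formula_kind)
  stopifnot(is.data.frame(table),
            all(c("cross_type", "sex", "dispersers") %in% names(table)))
  dat <- as.data.frame(table)
  lev <- intersect(c("HmLf", "HmHf", "LmHf", "LmLf"),
                   unique(as.character(dat$cross_type)))
  dat$cross_type <- factor(as.character(dat$cross_type), levels = lev)
  dat$sex <- factor(as.character(dat$sex), levels = c("female", "male"))
  rhs <- if (formula_kind == "interaction") "cross_type * sex"
         else "cross_type + sex"
  if (!is.null(covariates))
    rhs <- paste(c(rhs, covariates), collapse = " + ")
  fml <- stats::as.formula(paste("dispersers ~", rhs))
  fit <- lm(fml, data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("singular design: aliased terms ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  tab_out <- data.frame(term = rownames(sm$coefficients),
                        estimate = sm$coefficients[, 1],
                        se = sm$coefficients[, 2],
                        t = sm$coefficients[, 3],
                        p = sm$coefficients[, 4],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab_out, formula_kind = formula_kind,
                 sigma = sm$sigma, fit = fit),
            class = "cross_model")
}

#' @export
print.cross_model <- function(x, digits = 3, ...) {
  cat(sprintf("Cross assay linear model (%s)\n", x$formula_kind))
  out <- x$coefficients
  out$estimate <- round(out$estimate, digits)
  out$se <- round(out$se, digits)
  out$t <- round(out$t, 2)
  out$p <- signif(out$p, 2)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cross_model <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Transfer fit of the printed cross model to a simulated cross table
#'
#' Applies [predict_cross_means()] cell predictions to the rows of a cross
#' table and returns the resulting R-squared, measuring how well the
#' experimental model's coefficients describe the simulated outcomes.
#'
#' @param table A cross table (columns \code{cross_type}, \code{sex},
#'   \code{dispersers}).
#' @param model A [reference_model()] of kind \code{"crosses"}.
#' @return A single R-squared value (possibly negative).
#' @export
cross_transfer_r_squared <- function(table,
                                     model = reference_model("crosses")) {
  pred <- predict_cross_means(model, as.character(table$cross_type),
                              as.character(table$sex))
  compute_r_squared(table$dispersers, pred)
}
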