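# -- mixed model per trait ---------------------------------------------------

#' Fit the per-trait line mixed model by REML
#'
#' Fits `value ~ group + batch + (1 | line)` by restricted maximum
#' likelihood (lme4): image group and experimental batch are fixed effects,
#' line is random. Factors with a single observed level are dropped from
#' the fixed part, so the same call covers the reduced model without group
#' and batch. Negative variance estimates are truncated at zero by the
#' boundary REML fit. The conditional modes of the line effects are the
#' per-line BLUPs used downstream.
#'
#' @param data `data.frame` with columns `line`, `value` and optionally
#'   `group` and `batch`; at least 2 lines, replicated within line.
#' @param include_fixed Logical: include group/batch fixed effects where the
#'   columns exist and have >= 2 levels (default `TRUE`). `FALSE` forces the
#'   reduced model `value ~ (1 | line)`.
#' @return An object of class `line_model`: list with `fit` (the `lmerMod`),
#'   `varcomp` (class `variance_components`: `var_line`, `var_residual`,
#'   `var_total`, `mu_hat`, `fixed_effects`), `blups` (`data.frame`: `line`,
#'   `blup`, `se`) and `nobs`.
#' @export
#' @examples
#' ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 20, seed = 1))
#' fm <- fit_line_model(ph)
#' fm
fit_line_model <- function(data, include_fixed = TRUE) {
  stopifnot(is.data.frame(data), all(c("line", "value") %in% names(data)))
  if (length(unique(data$line)) < 2) {
    stop("need at least 2 lines to separate line and residual variance", call. = FALSE)
  }
  if (anyNA(data$value)) stop("missing trait values are not allowed", call. = FALSE)
  terms <- character(0)
  if (include_fixed) {
    for (f in c("group", "batch")) {
      if (f %in% names(data) && length(unique(data[[f]])) >= 2) terms <- c(terms, f)
    }
  }
  rhs <- paste(c("1", terms, "(1 | line)"), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code < 0) {
    stop("REML fit did not converge: ", paste(unlist(conv$messages), collapse = "; "),
         call. = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_line <- vc$vcov[vc$grp == "line"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit, condVar = TRUE)$line
  pv <- attr(re, "postVar")
  blups <- data.frame(line = rownames(re), blup = re[, 1],
                      se = sqrt(pv[1, 1, ]), stringsAsFactors = FALSE,
                      row.names = NULL)
  varcomp <- structure(list(var_line = var_line, var_residual = var_res,
                            var_total = var_line + var_res,
                            mu_hat = unname(fe["(Intercept)"]),
                            fixed_effects = fe),
                       class = "variance_components")
  structure(list(fit = fit, varcomp = varcomp, blups = blups,
                 formula = form, nobs = nrow(data)),
            class = "line_model")
}

#' @export
print.line_model <- function(x, ...) {
  cat("Line mixed model (REML):", deparse(x$formula), "\n")
  cat(sprintf("  %d observations, %d lines\n", x$nobs, nrow(x$blups)))
  cat(sprintf("  var_line = %.4g, var_residual = %.4g (H2 point = %.3f)\n",
              x$varcomp$var_line, x$varcomp$var_residual,
              x$varcomp$var_line / x$varcomp$var_total))
  invisible(x)
}

#' @export
summary.line_model <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  print(object$varcomp$fixed_effects)
  cat("\nBLUP summary:\n")
  print(summary(object$blups$blup))
  invisible(object)
}

#' @export
coef.line_model <- function(object, ...) object$varcomp$fixed_effects

#' Extract per-line BLUPs from a fitted line model
#' @param x A `line_model`.
#' @return Named numeric vector of line BLUPs.
#' @export
blups <- function(x) {
  stopifnot(inherits(x, "line_model"))
  stats::setNames(x$blups$blup, x$blups$line)
}

# -- heritability ------------------------------------------------------------

#' Broad-sense heritability with a parametric-bootstrap CI
#'
#' Point estimate `H2 = var_line / (var_line + var_residual)` from the REML
#' variance components; group and batch are fixed effects and contribute no
#' variance. The confidence interval is a percentile interval over
#' parametric-bootstrap refits (data simulated from the fitted model,
#' as in lme4's `bootMer`).
#'
#' @param x A `line_model` from [fit_line_model()].
#' @param n_boot Number of bootstrap refits (0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @return An object of class `heritability_estimate`: `h2`, `ci_low`,
#'   `ci_high`, `n_boot`, and the bootstrap draws in `boot`.
#' @export
heritability <- function(x, n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(x, "line_model"))
  vt <- x$varcomp$var_total
  if (vt <= 0) stop("total variance is zero: heritability undefined", call. = FALSE)
  h2 <- x$varcomp$var_line / vt
  ci <- c(NA_real_, NA_real_)
  draws <- numeric(0)
  if (n_boot > 0) {
    h2_fun <- function(m) {
      v <- as.data.frame(lme4::VarCorr(m))$vcov
      v[1] / sum(v)
    }
    bt <- suppressMessages(suppressWarnings(
      lme4::bootMer(x$fit, h2_fun, nsim = n_boot, seed = as.integer(seed),
                    type = "parametric", use.u = FALSE)))
    draws <- as.numeric(bt$t)
    alpha <- (1 - level) / 2
    ci <- stats::quantile(draws, c(alpha, 1 - alpha), na.rm = TRUE,
                          type = 7, names = FALSE)
  }
  structure(list(h2 = h2, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), boot = draws),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H2 = %.3f", x$h2))
  if (x$n_boot > 0) {
    cat(sprintf(" [%.3f, %.3f] (%d parametric bootstrap draws)",
                x$ci_low, x$ci_high, x$n_boot))
  }
  cat("\n")
  invisible(x)
}

# -- human-score validation --------------------------------------------------

#' Spearman correlation between machine and human degeneration scores
#'
#' Validates machine-generated line BLUPs against blinded human scoring
#' (0 = wild type to 4 = severely affected): Spearman rank correlation with
#' average ranks for ties and the analytic two-sided large-sample P value.
#'
#' @param blups_machine Named numeric vector (names = line ids).
#' @param blups_human Named numeric vector on the human scale.
#' @return List with `rho`, `p`, `n` (matched lines).
#' @export
correlate_with_human_scores <- function(blups_machine, blups_human) {
  stopifnot(!is.null(names(blups_machine)), !is.null(names(blups_human)))
  common <- intersect(names(blups_machine), names(blups_human))
  if (length(common) < 3) stop("need at least 3 matched lines", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(blups_machine[common],
                                         blups_human[common],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common))
}

# -- trait selection ---------------------------------------------------------

central_trait_names <- function() {
  c("nn_mean", "ecc_mean", "area_mean", "radiusmean_mean", "perimeter_mean")
}

dispersion_trait_names <- function() {
  c("nn_sd", "area_sd", "radiusmean_sd", "perimeter_sd", "radiusmin_sd",
    "radiusmax_mean", "radiusmax_sd", "radiussd_mean", "radiussd_sd")
}

#' Select heritable, human-validated traits and classify them
#'
#' Retains traits with broad-sense heritability above `h2_threshold`
#' (strictly greater than 0.05 by default) AND a significant human-score
#' correlation (two-sided P below `p_threshold`). Retained traits are
#' labelled by the fixed central / dispersion taxonomy (5 central: nn,
#' eccentricity, area, radius-mean and perimeter means; 9 dispersion: the
#' SD metrics plus radius-max mean); retained traits outside the taxonomy
#' are flagged for review rather than silently classified.
#'
#' @param traits `data.frame` with columns `trait`, `h2`, `rho`, `p` for all
#'   16 metrics.
#' @param h2_threshold,p_threshold Selection gates (defaults 0.05 and 0.05).
#' @return An object of class `trait_taxonomy`: `central`, `dispersion`,
#'   `excluded`, `unclassified` (character vectors) plus the annotated
#'   input table in `$table`.
#' @export
select_traits <- function(traits, h2_threshold = 0.05, p_threshold = 0.05) {
  stopifnot(is.data.frame(traits),
            all(c("trait", "h2", "rho", "p") %in% names(traits)))
  missing_traits <- setdiff(metric_names(), traits$trait)
  if (length(missing_traits) > 0) {
    stop("all 16 metrics must be present; missing: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  retained <- traits$h2 > h2_threshold & traits$p < p_threshold
  keep <- traits$trait[retained]
  central <- intersect(central_trait_names(), keep)
  dispersion <- intersect(dispersion_trait_names(), keep)
  unclassified <- setdiff(keep, c(central_trait_names(), dispersion_trait_names()))
  tab <- traits
  tab$retained <- retained
  tab$class <- ifelse(tab$trait %in% central, "central",
                      ifelse(tab$trait %in% dispersion, "dispersion",
                             ifelse(retained, "unclassified", "excluded")))
  tab$class[!retained] <- "excluded"
  structure(list(central = central, dispersion = dispersion,
                 excluded = traits$trait[!retained],
                 unclassified = unclassified, table = tab),
            class = "trait_taxonomy")
}

#' @export
print.trait_taxonomy <- function(x, ...) {
  cat(sprintf("trait taxonomy: %d central, %d dispersion, %d excluded",
              length(x$central), length(x$dispersion), length(x$excluded)))
  if (length(x$unclassified) > 0) {
    cat(sprintf(", %d retained but outside the taxonomy (%s)",
                length(x$unclassified), paste(x$unclassified, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# -- transgene interaction ---------------------------------------------------

#' Fixed-effect interaction model for two transgenes
#'
#' Quantifies the individual additive effects of two transgenes (e.g. the
#' amyloid and tau constructs) and their non-additive interaction with the
#' two-way fixed-effect linear model `value ~ ab42 * tau`, coefficients
#' reported relative to the control cell (both transgenes absent).
#'
#' @param data `data.frame` with columns `ab42`, `tau` (each 0/1) and
#'   `value`; all four genotype cells must be represented.
#' @return An object of class `interaction_fit`: `beta_ab42`, `beta_tau`,
#'   `beta_interaction`, `p_interaction`, and the underlying `lm` in `fit`.
#' @export
fit_transgene_interaction <- function(data) {
  stopifnot(is.data.frame(data), all(c("ab42", "tau", "value") %in% names(data)))
  a <- as.integer(as.character(factor(data$ab42)))
  t <- as.integer(as.character(factor(data$tau)))
  stopifnot(all(a %in% 0:1), all(t %in% 0:1))
  cells <- table(a, t)
  if (any(dim(cells) != c(2, 2)) || any(cells == 0)) {
    stop("all four genotype cells must be represented", call. = FALSE)
  }
  fit <- stats::lm(value ~ a * t, data = data.frame(a = a, t = t, value = data$value))
  cf <- summary(fit)$coefficients
  structure(list(beta_ab42 = cf["a", "Estimate"],
                 beta_tau = cf["t", "Estimate"],
                 beta_interaction = cf["a:t", "Estimate"],
                 p_interaction = cf["a:t", "Pr(>|t|)"],
                 fit = fit),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("transgene interaction: beta_ab42 = %.3g, beta_tau = %.3g, interaction = %.3g (p = %.3g)\n",
              x$beta_ab42, x$beta_tau, x$beta_interaction, x$p_interaction))
  invisible(x)
}
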