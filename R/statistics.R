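# Statistical pipeline for the empirical peak-strain model: z-normalisation
# of peak strains across the cohort, bivariate Pearson screening of candidate
# sagittal-plane predictors, Box-Cox transformation of the (positive) peak
# strain, an ordinary-least-squares multivariate fit with sequential (type-I)
# variance contributions, and an evaluator for the published empirical
# equation
#   ln(peak ACL strain, %) = 9.09 + 0.0701 knee - 0.2661 ankle
#                            - 0.1362 hip - 0.1649 trunk
# (angles in degrees: maximum knee flexion, and ankle/hip/trunk flexion at
# peak ground reaction force).  Strain in the equation is in percent: with
# angles of tens of degrees the constant 9.09 is only consistent with
# strains of a few percent on the natural-log scale.

#' z-normalise a vector
#'
#' Subtract the mean and divide by the sample (n-1) standard deviation.
#' @param values numeric, length >= 2, non-constant
#' @return numeric with mean 0 and sd 1
#' @export
znormalize <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("znormalize: zero standard deviation (constant input)")
  (values - mean(values)) / s
}

#' Bivariate Pearson screening of predictors against a response
#'
#' Two-sided p-values from the t distribution with n-2 degrees of freedom.
#' Constant predictors are flagged (r = NA) rather than dropped.
#' @param table data.frame; one column is the response, the rest predictors
#' @param response response column name (default "peak_strain")
#' @param predictors predictor column names (default: all numeric columns
#'   except the response)
#' @return data.frame: predictor, pearson_r, p_value, flag
#' @export
bivariate_screen <- function(table, response = "peak_strain",
                             predictors = NULL) {
  stopifnot(response %in% names(table))
  y <- table[[response]]
  n <- length(y)
  if (n < 3) stop("bivariate_screen: need n >= 3")
  if (is.null(predictors)) {
    num <- vapply(table, is.numeric, logical(1))
    predictors <- setdiff(names(table)[num], response)
  }
  out <- do.call(rbind, lapply(predictors, function(p) {
    x <- table[[p]]
    if (stats::sd(x) == 0)
      return(data.frame(predictor = p, pearson_r = NA_real_,
                        p_value = NA_real_, flag = "constant",
                        stringsAsFactors = FALSE))
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    data.frame(predictor = p, pearson_r = r, p_value = pv, flag = "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Box-Cox transformation by profile maximum likelihood
#'
#' Lambda maximises the profile log-likelihood of the power family over a
#' grid on [-2, 2] (step 0.01); lambda = 0 is the natural log.  The
#' transform is \code{(y^lambda - 1)/lambda} (or \code{log(y)}).
#' @param values positive numeric vector
#' @param lambda_grid grid searched (default seq(-2, 2, by = 0.01))
#' @return list(lambda, transformed, loglik = profile log-likelihood at
#'   lambda)
#' @export
boxcox_transform <- function(values, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(values <= 0)) stop("boxcox_transform: values must be positive")
  n <- length(values)
  logy <- log(values)
  ll <- vapply(lambda_grid, function(l) {
    z <- if (abs(l) < 1e-12) logy else (values^l - 1) / l
    -n / 2 * log(max(1e-300, mean((z - mean(z))^2))) + (l - 1) * sum(logy)
  }, numeric(1))
  lambda <- lambda_grid[which.max(ll)]
  z <- if (abs(lambda) < 1e-12) logy else (values^lambda - 1) / lambda
  list(lambda = lambda, transformed = z, loglik = max(ll))
}

#' Fit the empirical peak-strain regression
#'
#' Ordinary least squares of the (optionally Box-Cox transformed) response on
#' the named predictors, with per-term p-values, R-squared and sequential
#' (type-I) variance contributions in the order the predictors are given;
#' contributions plus error always total 100.
#'
#' @param table data.frame (e.g. cohort summary with a peak-strain column)
#' @param predictors character vector of predictor column names
#' @param response response column name (default "peak_strain")
#' @param transform "boxcox" (estimate lambda on the positive response),
#'   "log" (natural log, the published form), or "identity"
#' @return a \code{strain_model}: list(coefficients, boxcox_lambda,
#'   r_squared, p_values, contribution_pct (named, incl. "error"), fit (lm),
#'   transform)
#' @export
fit_empirical_model <- function(table, predictors,
                                response = "peak_strain",
                                transform = c("boxcox", "log", "identity")) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(table), all(predictors %in% names(table)))
  n <- nrow(table)
  if (n <= length(predictors) + 1)
    stop("fit_empirical_model: need n > number of predictors + 1")
  X <- as.matrix(table[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, scale(X, scale = FALSE)))
  if (qrX$rank < ncol(X) + 1) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1
    stop("fit_empirical_model: rank-deficient design; collinear column(s): ",
         paste(predictors[drop_idx], collapse = ", "))
  }
  y <- table[[response]]
  lambda <- NA_real_
  yt <- switch(transform,
               boxcox = { b <- boxcox_transform(y); lambda <- b$lambda; b$transformed },
               log = { if (any(y <= 0)) stop("log transform needs positive response"); lambda <- 0; log(y) },
               identity = y)
  dat <- data.frame(.y = yt, table[, predictors, drop = FALSE])
  fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  an <- stats::anova(fit)            # sequential (type-I) sums of squares
  ss <- an[["Sum Sq"]]
  total <- sum(ss)
  contrib <- 100 * ss / total
  names(contrib) <- rownames(an)
  names(contrib)[length(contrib)] <- "error"
  structure(list(
    coefficients = stats::coef(fit),
    boxcox_lambda = lambda,
    r_squared = sm$r.squared,
    p_values = sm$coefficients[, "Pr(>|t|)"],
    contribution_pct = contrib,
    transform = transform,
    fit = fit
  ), class = "strain_model")
}

#' The published empirical peak-strain model
#'
#' Full-precision coefficients of the reported regression (response:
#' ln of peak ACL strain in percent), its R-squared and the reported
#' per-term variance contributions.
#' @return a \code{strain_model}-like list
#' @export
published_strain_model <- function() {
  structure(list(
    coefficients = c(`(Intercept)` = 9.09,
                     max_knee_flexion = 0.0701,
                     ankle_flexion_at_maxGRF = -0.2661,
                     hip_flexion_at_maxGRF = -0.1362,
                     trunk_flexion_at_maxGRF = -0.1649),
    boxcox_lambda = 0,
    r_squared = 0.9004,
    contribution_pct = c(trunk_flexion_at_maxGRF = 43.43,
                         max_knee_flexion = 31.55,
                         ankle_flexion_at_maxGRF = 8.44,
                         hip_flexion_at_maxGRF = 6.62,
                         error = 9.96),
    transform = "log"
  ), class = "strain_model")
}

#' Predict peak ACL strain from sagittal landing descriptors
#'
#' Evaluates \code{exp} of the linear predictor of a log-scale strain model
#' (default: the published equation).  Angles in degrees; the returned strain
#' is in percent.  Warns outside the documented envelope (all angles within
#' [-30, 120] deg) where the empirical fit is extrapolating.
#'
#' @param trunk,hip,ankle flexion angles at peak ground reaction force, deg
#' @param knee maximum knee flexion, deg
#' @param model a log-scale \code{strain_model} with coefficients named
#'   (Intercept), max_knee_flexion, ankle_flexion_at_maxGRF,
#'   hip_flexion_at_maxGRF, trunk_flexion_at_maxGRF
#' @return predicted peak ACL strain, percent
#' @export
predict_peak_strain <- function(trunk, hip, knee, ankle,
                                model = published_strain_model()) {
  angs <- c(trunk = trunk, hip = hip, knee = knee, ankle = ankle)
  if (any(angs < -30 | angs > 120))
    warning("predict_peak_strain: angle(s) outside the documented envelope ",
            "[-30, 120] deg; extrapolating")
  b <- model$coefficients
  lp <- b[["(Intercept)"]] + b[["max_knee_flexion"]] * knee +
    b[["ankle_flexion_at_maxGRF"]] * ankle +
    b[["hip_flexion_at_maxGRF"]] * hip +
    b[["trunk_flexion_at_maxGRF"]] * trunk
  unname(exp(lp))
}
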