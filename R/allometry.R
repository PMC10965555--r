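# Allometric scaling of luminal diameter with body mass, and classification
# of vessels as normal / dilated / aneurysmal.

#' Fit the allometric diameter-mass power law
#'
#' Luminal aortic diameter scales with body mass as `di = alpha * BM^beta`.
#' A log transformation linearizes the law; ordinary least squares of
#' `ln(di)` on `ln(BM)` gives `beta` (slope) and `alpha = exp(intercept)`.
#' The residual standard deviation on the log scale (`n - 2` denominator)
#' calibrates the interval used for dilatation classification. The model is
#' conventionally fit on healthy wild-type vessels only, then applied to all
#' genotypes.
#'
#' @param body_mass_g Body masses (g), positive.
#' @param di_um Luminal diameters (um, typically model-predicted systolic),
#'   positive, same length.
#' @param interval_level Two-sided coverage of the classification interval
#'   (default 0.95; only the upper tail flags dilatation).
#' @return Object of class `allometric_model`: `alpha` (um g^-beta), `beta`,
#'   `n`, `s_log`, `interval_level`, plus the log-scale regression internals
#'   (`mean_logbm`, `sxx`) needed for leverage.
#' @examples
#' bm <- seq(15, 35, length.out = 56)
#' fit_allometric(bm, 671.7862 * bm^0.2816)
#' @export
fit_allometric <- function(body_mass_g, di_um, interval_level = 0.95) {
  if (length(body_mass_g) != length(di_um))
    stop("fit_allometric: input lengths differ")
  if (length(body_mass_g) < 3)
    stop("fit_allometric: need at least 3 observations")
  if (any(body_mass_g <= 0) || any(di_um <= 0))
    stop("fit_allometric: body mass and diameter must be positive")
  x <- log(body_mass_g); y <- log(di_um)
  fit <- lm(y ~ x)
  n <- length(x)
  s_log <- sqrt(sum(fit$residuals^2) / (n - 2))
  structure(list(alpha = exp(unname(coef(fit)[1])), beta = unname(coef(fit)[2]),
                 n = n, s_log = s_log, interval_level = interval_level,
                 mean_logbm = mean(x), sxx = sum((x - mean(x))^2)),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf(
    "Allometric model: di = %.6g * BM^%.4g um (n = %d, s_log = %.4g, level = %g)\n",
    x$alpha, x$beta, x$n, x$s_log, x$interval_level))
  invisible(x)
}

#' Expected diameter under an allometric model
#'
#' @param object An [fit_allometric()] model.
#' @param body_mass_g Body masses (g).
#' @param ... Unused.
#' @return Expected luminal diameter `alpha * BM^beta` (um).
#' @export
predict.allometric_model <- function(object, body_mass_g, ...) {
  object$alpha * body_mass_g^object$beta
}

#' Classify vessels against normal allometric scaling
#'
#' A vessel is *dilated* when its log-diameter exceeds the upper bound of the
#' interval for normal scaling at its body mass, and *aneurysmal* when the
#' normalized diameter (measured / expected) exceeds 1.5, the clinical
#' aneurysm convention. The default interval is the prediction interval for a
#' new individual, `z * s_log * sqrt(1 + 1/n + leverage)` on the log scale —
#' classification targets individual vessels, not the mean response; the
#' narrower mean-response (confidence) interval is available via `interval`.
#' Only the upper bound flags dilatation; vessels below the lower bound are
#' flagged `small` separately, not dilated.
#'
#' @param model An [fit_allometric()] model.
#' @param body_mass_g,di_um Body masses (g) and measured luminal diameters
#'   (um), vectorised.
#' @param interval `"prediction"` (default) or `"confidence"`.
#' @return Data frame with columns `normalized_diameter`, `status` (factor
#'   `normal < dilated < aneurysmal`), and logical `small`.
#' @export
classify_vessel <- function(model, body_mass_g, di_um,
                            interval = c("prediction", "confidence")) {
  stopifnot(inherits(model, "allometric_model"))
  interval <- match.arg(interval)
  x <- log(body_mass_g)
  mu <- log(model$alpha) + model$beta * x
  lev <- 1 / model$n + (x - model$mean_logbm)^2 / model$sxx
  half <- qnorm(1 - (1 - model$interval_level) / 2) * model$s_log *
    sqrt(if (interval == "prediction") 1 + lev else lev)
  nd <- di_um / exp(mu)
  dilated <- log(di_um) > mu + half
  status <- factor(ifelse(nd > 1.5, "aneurysmal",
                          ifelse(dilated, "dilated", "normal")),
                   levels = c("normal", "dilated", "aneurysmal"), ordered = TRUE)
  data.frame(normalized_diameter = nd, status = status,
             small = log(di_um) < mu - half)
}

#' Serialize an allometric model to JSON
#'
#' @param model An [fit_allometric()] model.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_allometric_json <- function(model, path) {
  stopifnot(inherits(model, "allometric_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
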