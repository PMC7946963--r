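#' Fraction of labeled ligand bound under ligand depletion
#'
#' The exact one-site solution for a labeled ligand at total
#' concentration `Lt` titrated with protein at total `Pt`:
#' \deqn{FB = \frac{(K_d + L_t + P_t) - \sqrt{(K_d + L_t + P_t)^2 - 4 L_t P_t}}{2 L_t}}
#' This reduces to the hyperbola `Pt / (Pt + Kd)` when `Lt << Kd`
#' (no depletion).
#'
#' @param Kd Dissociation constant (uM), >= 0.
#' @param Lt Total labeled-ligand concentration (uM), > 0.
#' @param Pt Total protein concentration(s) (uM), >= 0. Vectorized.
#' @return Fraction bound in \[0, 1\].
#' @examples
#' fraction_bound(50, 0.25, 50)     # half saturation near Pt = Kd
#' fraction_bound(0, 1, c(0.5, 2))  # stoichiometric limit min(Pt/Lt, 1)
#' @export
fraction_bound <- function(Kd, Lt, Pt) {
  stopifnot(Kd >= 0, all(Pt >= 0))
  if (Lt <= 0) abort("`Lt` must be > 0.")
  s <- Kd + Lt + Pt
  disc <- pmax(s^2 - 4 * Lt * Pt, 0)
  fb <- (s - sqrt(disc)) / (2 * Lt)
  pmin(pmax(fb, 0), 1)
}

#' Simulate a fluorescence-polarization titration
#'
#' Signal = `A_free + (A_bound - A_free) * FB(Kd, Lt, Pt)` plus
#' homoscedastic Gaussian noise, replicated and seeded.
#'
#' @param Kd True dissociation constant (uM).
#' @param Pt Protein concentration series (uM), strictly increasing.
#' @param Lt Labeled-peptide total concentration (uM); 0.25 uM is the
#'   usual FITC-peptide working concentration.
#' @param A_free,A_bound Asymptotic polarization signals (arbitrary units).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param replicates Number of replicate curves.
#' @param seed RNG seed (reproducible curves).
#' @return A `titration_curve`: tibble with `Pt_uM`, `replicate`,
#'   `signal`; the generating truth is attached as `attr(x, "truth")`.
#' @export
simulate_titration <- function(Kd, Pt, Lt = 0.25, A_free = 50, A_bound = 250,
                               noise_sd = 2, replicates = 3L, seed = 1L) {
  stopifnot(all(diff(Pt) > 0), all(Pt >= 0), noise_sd >= 0, replicates >= 1)
  fb <- fraction_bound(Kd, Lt, Pt)
  mu <- A_free + (A_bound - A_free) * fb
  curves <- with_preserved_seed(seed, {
    map(seq_len(replicates), function(r) {
      tibble(Pt_uM = Pt, replicate = r,
             signal = mu + rnorm(length(Pt), 0, noise_sd))
    })
  })
  out <- bind_rows(curves)
  attr(out, "truth") <- list(Kd = Kd, Lt = Lt, A_free = A_free,
                             A_bound = A_bound, noise_sd = noise_sd,
                             seed = seed)
  class(out) <- c("titration_curve", class(out))
  out
}

# local seed without touching the global RNG stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit the one-site binding model to an FP titration
#'
#' Nonlinear least squares over `Kd`, `A_free`, `A_bound`. The default
#' `"depletion"` model uses the exact quadratic [fraction_bound()]; the
#' `"hyperbola"` model uses `Pt / (Pt + Kd)`. Initialization is
#' deterministic: `A_free`/`A_bound` from the signals at the lowest and
#' highest `Pt`, `Kd` from the `Pt` at half-maximal signal (linear
#' interpolation).
#'
#' @param curve A `titration_curve` or data frame with `Pt_uM`, `signal`
#'   (and optionally `replicate`); at least 4 distinct `Pt` values.
#' @param model `"depletion"` or `"hyperbola"`.
#' @param Lt Labeled-ligand concentration for the depletion model; taken
#'   from the curve's truth attribute when present.
#' @return A `binding_fit`: `Kd`, `Kd_se`, `A_free`, `A_bound`, `model`,
#'   `rss`, `converged`, plus the underlying `nls` object. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_one_site <- function(curve, model = c("depletion", "hyperbola"), Lt = NULL) {
  model <- match.arg(model)
  dat <- as_tibble(curve)
  stopifnot(all(c("Pt_uM", "signal") %in% names(dat)))
  if (length(unique(dat$Pt_uM)) < 4) {
    abort("Need >= 4 distinct Pt values to fit three parameters.")
  }
  truth <- attr(curve, "truth")
  Lt <- Lt %||% truth$Lt %||% 0.25

  means <- summarise(group_by(dat, .data$Pt_uM),
                     signal = mean(.data$signal), .groups = "drop")
  a0 <- means$signal[which.min(means$Pt_uM)]
  a1 <- means$signal[which.max(means$Pt_uM)]
  half <- (a0 + a1) / 2
  kd0 <- tryCatch(
    approx(means$signal, means$Pt_uM, xout = half, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(means$Pt_uM)

  form <- if (model == "depletion") {
    signal ~ A_free + (A_bound - A_free) * fraction_bound(Kd, Lt, Pt_uM)
  } else {
    signal ~ A_free + (A_bound - A_free) * Pt_uM / (Pt_uM + Kd)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat,
                      start = list(Kd = kd0, A_free = a0, A_bound = a1),
                      lower = c(Kd = 1e-9, A_free = -Inf, A_bound = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(Kd = NA_real_, Kd_se = NA_real_, A_free = NA_real_,
                A_bound = NA_real_, model = model, Lt = Lt, rss = NA_real_,
                converged = FALSE, diagnostics = conditionMessage(fit),
                fit = NULL, data = dat)
    class(out) <- "binding_fit"
    return(out)
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  out <- list(
    Kd = unname(est["Kd"]), Kd_se = unname(se["Kd"]),
    A_free = unname(est["A_free"]), A_bound = unname(est["A_bound"]),
    model = model, Lt = Lt,
    rss = sum(stats::residuals(fit)^2),
    converged = isTRUE(fit$convInfo$isConv),
    diagnostics = fit$convInfo$stopMessage %||% "",
    fit = fit, data = dat
  )
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> one-site", x$model, "model\n")
  if (x$converged) {
    cat(sprintf("  Kd = %.4g +/- %.3g uM  (A_free %.4g, A_bound %.4g; rss %.4g)\n",
                x$Kd, x$Kd_se, x$A_free, x$A_bound, x$rss))
  } else {
    cat("  NOT converged:", x$diagnostics, "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("Kd", "A_free", "A_bound"),
    estimate = c(x$Kd, x$A_free, x$A_bound),
    std.error = c(x$Kd_se,
                  tryCatch(summary(x$fit)$coefficients[c("A_free", "A_bound"),
                                                       "Std. Error"],
                           error = function(e) c(NA_real_, NA_real_)))
  )
}

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(Kd = x$Kd, Kd_se = x$Kd_se, model = x$model, Lt = x$Lt,
         rss = x$rss, converged = x$converged,
         nobs = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(Pt_uM = exp(seq(log(max(min(dat$Pt_uM), 1e-3)),
                                 log(max(dat$Pt_uM)), length.out = 200)))
  grid$signal <- if (object$model == "depletion") {
    object$A_free + (object$A_bound - object$A_free) *
      fraction_bound(object$Kd, object$Lt, grid$Pt_uM)
  } else {
    object$A_free + (object$A_bound - object$A_free) *
      grid$Pt_uM / (grid$Pt_uM + object$Kd)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$Pt_uM, y = .data$signal)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[protein] (uM)", y = "polarization (a.u.)",
                  title = sprintf("One-site %s fit: Kd = %.3g uM",
                                  object$model, object$Kd)) +
    ggplot2::theme_minimal()
}

#' Fold change between two fitted affinities
#'
#' `Kd_B / Kd_A` with first-order error propagation:
#' `se = ratio * sqrt((seA/KdA)^2 + (seB/KdB)^2)`.
#'
#' @param fitA,fitB Converged `binding_fit` objects; the ratio is
#'   `fitB$Kd / fitA$Kd` (so a tighter `fitA` gives a fold > 1).
#' @return Tibble with `ratio` and `ratio_se`.
#' @export
fold_change <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "binding_fit"), inherits(fitB, "binding_fit"))
  if (!isTRUE(fitA$converged) || !isTRUE(fitB$converged)) {
    abort("Both fits must have converged to compute a fold change.")
  }
  ratio <- fitB$Kd / fitA$Kd
  rel <- sqrt((fitA$Kd_se / fitA$Kd)^2 + (fitB$Kd_se / fitB$Kd)^2)
  tibble(ratio = ratio, ratio_se = abs(ratio) * rel)
}
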