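#' Morrison tight-binding fractional activity
#'
#' Fractional residual enzyme activity v/v0 under tight-binding inhibition,
#' where free-inhibitor depletion is not negligible:
#' \deqn{v/v_0 = 1 - \frac{(E + I + K_i^{app}) -
#'   \sqrt{(E + I + K_i^{app})^2 - 4 E I}}{2E}}
#' All concentrations share one unit (nM here). The expression is clamped to
#' [0, 1] to guard floating-point underflow at extreme I.
#'
#' @param E enzyme concentration (nM), > 0.
#' @param I inhibitor concentration(s) (nM), >= 0; vectorized.
#' @param kiApp apparent inhibition constant (nM), > 0.
#' @return Fractional activity in [0, 1], same length as \code{I}.
#' @examples
#' morrisonFraction(3, c(0, 1, 10, 100), kiApp = 1.6)
#' @export
morrisonFraction <- function(E, I, kiApp) {
    stopifnot(E > 0, kiApp > 0, all(I >= 0))
    s <- E + I + kiApp
    disc <- s^2 - 4 * E * I
    frac <- 1 - (s - sqrt(pmax(disc, 0))) / (2 * E)
    pmin(pmax(frac, 0), 1)
}

#' Correct an apparent Ki for substrate competition
#'
#' Classical competitive correction \eqn{K_i = K_i^{app} / (1 + S/K_m)}.
#'
#' @param kiApp apparent inhibition constant (nM).
#' @param S substrate concentration (uM).
#' @param Km substrate Michaelis constant (uM), > 0.
#' @return Ki in nM.
#' @examples
#' kiFromKiApp(10, S = 100, Km = 100)   # 5
#' @export
kiFromKiApp <- function(kiApp, S, Km) {
    if (Km <= 0) stop("Km must be > 0", call. = FALSE)
    kiApp / (1 + S / Km)
}

#' Construct an inhibition assay
#'
#' @param inhibitorNM inhibitor concentrations (nM).
#' @param rate observed rates, parallel to \code{inhibitorNM}.
#' @param v0 uninhibited rate.
#' @param enzymeNM active-site-titrated enzyme concentration (nM).
#' @param substrateUM substrate concentration (uM).
#' @param kmUM substrate Km (uM).
#' @param replicates replicate count.
#' @return An [InhibitionAssay-class].
#' @export
InhibitionAssay <- function(inhibitorNM, rate, v0, enzymeNM, substrateUM,
                            kmUM, replicates = 1L) {
    new("InhibitionAssay", enzymeNM = enzymeNM, substrateUM = substrateUM,
        kmUM = kmUM, inhibitorNM = as.numeric(inhibitorNM),
        rate = as.numeric(rate), v0 = v0,
        replicates = as.integer(replicates))
}

setMethod("show", "InhibitionAssay", function(object) {
    cat(sprintf(paste0("InhibitionAssay: E = %g nM, S = %g uM, Km = %g uM, ",
                       "%d inhibitor concentrations (%g-%g nM)\n"),
                object@enzymeNM, object@substrateUM, object@kmUM,
                length(object@inhibitorNM), min(object@inhibitorNM),
                max(object@inhibitorNM)))
})

#' @rdname accessors
#' @export
setMethod("ki", "KineticFit", function(x) x@ki)

#' @rdname accessors
#' @export
setMethod("kiSE", "KineticFit", function(x) x@kiSE)

#' @rdname accessors
#' @export
setMethod("kiApp", "KineticFit", function(x) x@kiApp)

#' @rdname accessors
#' @export
setMethod("converged", "KineticFit", function(x) x@converged)

setMethod("show", "KineticFit", function(object) {
    if (object@converged)
        cat(sprintf("KineticFit: Ki = %.4g +/- %.2g nM (Ki_app = %.4g nM)\n",
                    object@ki, object@kiSE, object@kiApp))
    else cat("KineticFit: did not converge\n")
})

#' Fit a tight-binding inhibition constant
#'
#' Nonlinear least squares of fractional activity v/v0 against the Morrison
#' model with Ki_app as the only free parameter (the enzyme concentration is
#' fixed from active-site titration). The fit is parameterized in
#' log(Ki_app) so positivity is structural; the standard error is transported
#' back by the delta method. Ki is then obtained by the competitive
#' correction [kiFromKiApp()].
#'
#' Residuals are unweighted by default. The initial guess is the inhibitor
#' concentration at half-maximal observed inhibition.
#'
#' @param assay an [InhibitionAssay-class] with at least 5 distinct
#'   inhibitor concentrations.
#' @param weights optional per-point weights for weighted least squares.
#' @return A [KineticFit-class].
#' @examples
#' a <- simulateInhibitionAssay(ki = 1.6, E = 0.5, S = 100, Km = 100,
#'                              I = c(0.25, 0.5, 1, 2, 4, 8, 16), cv = 0,
#'                              seed = 1)
#' fitKi(a)
#' @export
fitKi <- function(assay, weights = NULL) {
    stopifnot(is(assay, "InhibitionAssay"))
    I <- assay@inhibitorNM
    y <- assay@rate / assay@v0
    if (all(assay@rate == 0)) stop("all rates are zero", call. = FALSE)
    if (length(unique(I)) < 5)
        stop("need >= 5 distinct inhibitor concentrations", call. = FALSE)
    E <- assay@enzymeNM
    # start at the concentration nearest half-maximal inhibition
    half <- which.min(abs(y - (max(y) + min(y)) / 2))
    start <- max(I[half], E * 1e-3, 1e-6)
    df <- data.frame(I = I, y = y)
    fit <- tryCatch(
        stats::nls(y ~ morrisonFraction(E, I, exp(lk)), data = df,
                   start = list(lk = log(start)), weights = weights,
                   control = stats::nls.control(maxiter = 500,
                                                tol = 1e-8,
                                                minFactor = 1e-12,
                                                scaleOffset = 1)),
        error = function(e) NULL)
    if (is.null(fit))
        return(new("KineticFit", ki = NA_real_, kiSE = NA_real_,
                   kiApp = NA_real_, kiAppSE = NA_real_,
                   residuals = rep(NA_real_, length(y)), converged = FALSE))
    lk <- stats::coef(fit)[["lk"]]
    lkSE <- summary(fit)$coefficients["lk", "Std. Error"]
    kiAppHat <- exp(lk)
    kiAppSE <- kiAppHat * lkSE            # delta method
    corr <- 1 + assay@substrateUM / assay@kmUM
    new("KineticFit", ki = kiAppHat / corr, kiSE = kiAppSE / corr,
        kiApp = kiAppHat, kiAppSE = kiAppSE,
        residuals = as.numeric(stats::residuals(fit)), converged = TRUE)
}

#' Residual activity as a percentage
#'
#' Rates normalized to the uninhibited rate, expressed in percent.
#'
#' @param rates observed rates.
#' @param v0 uninhibited rate, > 0.
#' @return \code{100 * rates / v0}.
#' @examples
#' residualActivity(c(0.5, 0.25, 0), 0.5)
#' @export
residualActivity <- function(rates, v0) {
    if (v0 <= 0) stop("v0 must be > 0", call. = FALSE)
    100 * rates / v0
}
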