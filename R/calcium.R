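## Ca2+ dissociation constants from chromophoric-chelator competition
## curves and from NMR titrations.
##
## Competition model: free Ca2+ partitions between the chromophoric
## chelator (known Kd, 1.6 uM for 5,5'-Br2BAPTA under the working buffer)
## and the protein site(s). The normalized absorbance signal equals the
## fraction of chelator in its Ca-free state, Kq/(f + Kq), with f the free
## Ca2+ solving the total-calcium mass balance.

#' Construct a CompetitionTitration
#'
#' @param points data.frame with columns \code{ca_total} (M, strictly
#'   increasing) and \code{signal} (normalized, 1 at zero calcium).
#' @param chelatorTotal,proteinTotal,chelatorKd concentrations and chelator
#'   Kd in molar.
#' @return A \linkS4class{CompetitionTitration}.
#' @export
CompetitionTitration <- function(points, chelatorTotal, proteinTotal,
                                 chelatorKd = 1.6e-6) {
    new("CompetitionTitration", points = points,
        chelatorTotal = chelatorTotal, proteinTotal = proteinTotal,
        chelatorKd = chelatorKd)
}

#' Construct an NMRTitrationCurve
#'
#' @param points data.frame with columns \code{ca_total}, \code{observed}.
#' @param proteinTotal protein concentration (M).
#' @return An \linkS4class{NMRTitrationCurve}.
#' @export
NMRTitrationCurve <- function(points, proteinTotal) {
    new("NMRTitrationCurve", points = points, proteinTotal = proteinTotal)
}

#' Solve the free-calcium mass balance
#'
#' Finds the unique root f in [0, caTotal] of
#' caTotal = f + sum_i total_i * f / (f + kd_i), i.e. total calcium equals
#' free calcium plus calcium bound to each saturable site.
#'
#' @param caTotal total calcium (M).
#' @param siteTotals,siteKds site concentrations and dissociation constants
#'   (M), equal length.
#' @return free calcium (M), relative accuracy better than 1e-12.
#' @export
solveFreeCa <- function(caTotal, siteTotals = numeric(), siteKds = numeric()) {
    stopifnot(length(siteTotals) == length(siteKds),
              all(siteTotals >= 0), all(siteKds > 0), caTotal >= 0)
    if (caTotal == 0 || length(siteTotals) == 0L) return(caTotal)
    g <- function(f) f + sum(siteTotals * f / (f + siteKds)) - caTotal
    lo <- 0; hi <- caTotal
    if (g(hi) < -1e-15 * caTotal)
        stop("internal error: mass balance root not bracketed")
    root <- stats::uniroot(g, c(lo, hi), tol = 1e-14 * caTotal)$root
    ## Newton polish to full relative precision
    for (i in 1:3) {
        gp <- 1 + sum(siteTotals * siteKds / (root + siteKds)^2)
        step <- g(root) / gp
        root <- min(max(root - step, 0), caTotal)
    }
    root
}

#' Forward competition-curve model
#'
#' Normalized chelator signal at a given total calcium: the fraction of
#' chelator in the Ca-free state after free calcium equilibrates over the
#' chelator and the protein sites.
#'
#' @param caTotal total calcium (M); vectorized.
#' @param t a \linkS4class{CompetitionTitration} (its points are ignored;
#'   only the chelator/protein metadata are used).
#' @param proteinKds protein site dissociation constants (M); each site is
#'   present at the protein total concentration.
#' @return normalized signal in [0, 1]; 1 at zero calcium.
#' @export
competitionSignal <- function(caTotal, t, proteinKds) {
    stopifnot(is(t, "CompetitionTitration"), all(proteinKds > 0))
    totals <- c(t@chelatorTotal, rep(t@proteinTotal, length(proteinKds)))
    kds <- c(t@chelatorKd, proteinKds)
    vapply(caTotal, function(ca) {
        f <- solveFreeCa(ca, totals, kds)
        t@chelatorKd / (f + t@chelatorKd)
    }, numeric(1L))
}

## Shared nls.lm driver: residual function of log10(kd) vector; multiple
## log-spaced starts; returns the best fit with curvature-based SEs.
.lmMultiStart <- function(residFun, starts, nPoints) {
    best <- NULL
    for (s0 in starts) {
        fit <- tryCatch(
            minpack.lm::nls.lm(par = s0, fn = residFun,
                control = minpack.lm::nls.lm.control(
                    maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
            error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best)) return(NULL)
    p <- length(best$par)
    dof <- max(nPoints - p, 1L)
    sigma2 <- best$deviance / dof
    covm <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
    se <- if (is.null(covm)) rep(NA_real_, p) else sqrt(pmax(diag(covm), 0))
    list(par = best$par, se = se, sse = best$deviance,
         converged = best$info %in% 1:4)
}

#' Fit a competition titration to a 1- or 2-site model
#'
#' Least-squares fit of the forward competition model. The two-site model
#' uses two independent sites with separate Kds, each at the protein total
#' concentration. Optimization runs from five log-spaced Kd starts
#' (shallow SSE surfaces near the chelator Kd make a single start
#' unreliable); standard errors come from the local curvature. A fit is
#' flagged ill-determined when a Kd standard error exceeds its estimate or
#' the Kd lands beyond the highest total calcium titrated (pure
#' extrapolation), as happens for sites far outside the chelation working
#' range of roughly 1-20 uM.
#'
#' @param t a \linkS4class{CompetitionTitration} with at least 8 points.
#' @param nSites 1 or 2.
#' @param start optional numeric Kd start values (M).
#' @return A \linkS4class{BindingFit}.
#' @examples
#' t <- simulateCompetition(4e-6, noise = 0, seed = 1)
#' kdValues(fitCompetition(t, 1))
#' @export
fitCompetition <- function(t, nSites = 1L, start = NULL) {
    stopifnot(is(t, "CompetitionTitration"), nSites %in% c(1L, 2L))
    pts <- t@points
    if (nrow(pts) < 8L) stop("at least 8 titration points are required")
    residFun <- function(logkd)
        pts$signal - competitionSignal(pts$ca_total, t, 10^logkd)
    if (is.null(start)) {
        grid <- log10(c(5e-7, 2e-6, 8e-6, 3e-5, 1e-4))
        starts <- if (nSites == 1L) as.list(grid)
                  else lapply(seq_along(grid), function(i)
                      c(grid[max(i - 1L, 1L)], grid[min(i + 1L,
                                                        length(grid))]))
    } else starts <- list(log10(start))
    best <- .lmMultiStart(residFun, starts, nrow(pts))
    if (is.null(best))
        return(new("BindingFit", nSites = as.integer(nSites),
                   kd = rep(1, nSites), kdSe = rep(Inf, nSites),
                   amplitude = NA_real_, sse = Inf,
                   nPoints = nrow(pts), nPar = as.integer(nSites),
                   converged = FALSE, illDetermined = TRUE))
    ord <- order(best$par)
    kd <- 10^best$par[ord]
    kdSe <- log(10) * kd * best$se[ord]
    new("BindingFit", nSites = as.integer(nSites), kd = kd, kdSe = kdSe,
        amplitude = NA_real_, sse = best$sse, nPoints = nrow(pts),
        nPar = as.integer(nSites), converged = best$converged,
        illDetermined = any(!is.finite(kdSe)) || any(kdSe > kd) ||
            any(kd > max(pts$ca_total)))
}

#' F-test selection between nested binding models
#'
#' F = ((sse1 - sse2)/(p2 - p1)) / (sse2/(n - p2)); the richer model is
#' selected when its improvement is significant at \code{alpha}.
#'
#' @param fit1,fit2 \linkS4class{BindingFit} objects on the same data, with
#'   fit1 nested in fit2.
#' @param alpha significance level.
#' @return list(selected = 1 or 2, F, p).
#' @export
fTestSelect <- function(fit1, fit2, alpha = 0.05) {
    stopifnot(is(fit1, "BindingFit"), is(fit2, "BindingFit"))
    if (fit1@nPoints != fit2@nPoints)
        stop("fits must be on the same data (n differs)")
    if (fit2@nPar <= fit1@nPar) stop("fit1 must be nested in fit2")
    n <- fit1@nPoints
    p1 <- fit1@nPar; p2 <- fit2@nPar
    if (fit2@sse == 0)
        return(list(selected = 2L, F = Inf, p = 0))
    Fval <- ((fit1@sse - fit2@sse) / (p2 - p1)) / (fit2@sse / (n - p2))
    Fval <- max(Fval, 0)
    p <- stats::pf(Fval, p2 - p1, n - p2, lower.tail = FALSE)
    list(selected = if (p < alpha) 2L else 1L, F = Fval, p = p)
}

## Bound fraction of a single site with ligand depletion: the bound
## complex is the physical root of B^2 - (P + L + Kd) B + P L = 0.
.boundFraction <- function(L, P, kd) {
    s <- P + L + kd
    B <- (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / 2
    B / P
}

#' Fit a single-site NMR titration
#'
#' Fast-exchange observable proportional to the bound fraction, with ligand
#' depletion: the bound complex is the quadratic-root solution of the
#' binding equilibrium at each total calcium. Fits amplitude and Kd.
#'
#' @param c an \linkS4class{NMRTitrationCurve}.
#' @return A \linkS4class{BindingFit} with \code{nSites = 1} and the fitted
#'   amplitude. Curves with no curvature in the sampled range are flagged
#'   ill-determined.
#' @examples
#' c <- simulateNMRTitration(170e-6, noise = 0, seed = 1)
#' kdValues(fitNMRTitration(c))
#' @export
fitNMRTitration <- function(c) {
    stopifnot(is(c, "NMRTitrationCurve"))
    pts <- c@points
    P <- c@proteinTotal
    boundFrac <- function(L, kd) .boundFraction(L, P, kd)
    if (diff(range(pts$observed)) == 0)
        return(new("BindingFit", nSites = 1L, kd = 1, kdSe = Inf,
                   amplitude = 0, sse = 0, nPoints = nrow(pts), nPar = 2L,
                   converged = TRUE, illDetermined = TRUE))
    amp0 <- max(abs(pts$observed))
    residFun <- function(par)
        pts$observed - par[1L] * boundFrac(pts$ca_total, 10^par[2L])
    kdGrid <- log10(c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1))
    starts <- lapply(kdGrid, function(k) c(amp0, k))
    best <- .lmMultiStart(residFun, starts, nrow(pts))
    if (is.null(best))
        return(new("BindingFit", nSites = 1L, kd = 1, kdSe = Inf,
                   amplitude = NA_real_, sse = Inf, nPoints = nrow(pts),
                   nPar = 2L, converged = FALSE, illDetermined = TRUE))
    kd <- 10^best$par[2L]
    kdSe <- log(10) * kd * best$se[2L]
    new("BindingFit", nSites = 1L, kd = kd, kdSe = kdSe,
        amplitude = best$par[1L], sse = best$sse, nPoints = nrow(pts),
        nPar = 2L, converged = best$converged,
        illDetermined = !is.finite(kdSe) || kdSe > kd)
}

#' Fractional site occupancy at a given free calcium
#'
#' @param kd site dissociation constant (M).
#' @param freeCa free calcium concentration (M).
#' @return list(kd, freeCa, fractionBound) with
#'   fractionBound = freeCa/(freeCa + kd).
#' @examples
#' occupancy(170e-6, 1.4e-3)$fractionBound  # ~0.89 at extracellular Ca2+
#' @export
occupancy <- function(kd, freeCa) {
    stopifnot(kd > 0, freeCa >= 0)
    list(kd = kd, freeCa = freeCa, fractionBound = freeCa / (freeCa + kd))
}
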