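## {1H}-15N heteronuclear NOE ratios with Monte Carlo uncertainties.
##
## The NOE ratio i_sat/i_ref reports fast (ps-ns) backbone dynamics:
## rigid residues in a tumbling domain sit near the rigid-limit plateau
## while mobile termini and loops show reduced or negative ratios.
## Uncertainties are estimated by resampling both peak heights with
## independent Gaussian noise at the baseline-noise level.

#' Compute heteronuclear NOE ratios with Monte Carlo errors
#'
#' @param pairs data.frame with columns \code{residue}, \code{i_sat},
#'   \code{i_ref}, \code{noise} (baseline noise, same units as the peak
#'   heights; must be positive).
#' @param nMc number of Monte Carlo resamples (>= 2).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return data.frame(residue, ratio, sigma, unreliable): \code{sigma} is
#'   the standard deviation of the resampled ratios; \code{unreliable}
#'   flags residues whose reference height is within 3x noise of zero.
#' @examples
#' p <- data.frame(residue = 1:2, i_sat = c(0.78, 0.3),
#'                 i_ref = c(1, 1), noise = 0.02)
#' computeHetNOE(p, nMc = 500, seed = 1)
#' @export
computeHetNOE <- function(pairs, nMc = 500L, seed = 1L) {
    need <- c("residue", "i_sat", "i_ref", "noise")
    stopifnot(all(need %in% names(pairs)), nMc >= 2L,
              all(pairs$noise > 0), all(pairs$i_ref != 0))
    withLocalSeed(seed, {
        n <- nrow(pairs)
        ratio <- pairs$i_sat / pairs$i_ref
        sigma <- numeric(n)
        for (i in seq_len(n)) {
            sat <- pairs$i_sat[i] + stats::rnorm(nMc, 0, pairs$noise[i])
            ref <- pairs$i_ref[i] + stats::rnorm(nMc, 0, pairs$noise[i])
            sigma[i] <- stats::sd(sat / ref)
        }
        data.frame(residue = pairs$residue, ratio = ratio, sigma = sigma,
                   unreliable = abs(pairs$i_ref) < 3 * pairs$noise)
    })
}

#' Flag fast-timescale flexible residues and linkers
#'
#' A residue is called flexible when even the upper end of its NOE ratio
#' (ratio + sigma) falls below the threshold. A linker is fast-flexible
#' when any of its residues is flexible; linkers with no measured residues
#' get the verdict "no data".
#'
#' @param results data.frame from \code{\link{computeHetNOE}}.
#' @param threshold NOE ratio cutoff in (0, 1); default 0.65, which
#'   separates a rigid-domain plateau near 0.78 from mobile residues.
#' @param linkers optional named list of integer(2) residue ranges.
#' @return list with \code{residues} (the results data.frame plus a
#'   \code{flexible} column) and \code{linkers}
#'   (data.frame(linker, verdict)).
#' @export
flagFlexible <- function(results, threshold = 0.65, linkers = list()) {
    stopifnot(threshold > 0, threshold < 1)
    results$flexible <- (results$ratio + results$sigma) < threshold
    linkerVerdicts <- data.frame(linker = character(), verdict = character(),
                                 stringsAsFactors = FALSE)
    if (length(linkers) > 0L) {
        nm <- names(linkers)
        if (is.null(nm)) nm <- paste0("linker", seq_along(linkers))
        verdict <- vapply(linkers, function(rng) {
            inside <- results$residue >= rng[1L] & results$residue <= rng[2L]
            if (!any(inside)) return("no data")
            if (any(results$flexible[inside])) "fast-flexible" else "rigid"
        }, character(1L))
        linkerVerdicts <- data.frame(linker = nm, verdict = verdict,
                                     stringsAsFactors = FALSE)
    }
    list(residues = results, linkers = linkerVerdicts)
}
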