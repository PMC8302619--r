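#' Normalize a FRAP curve to its pre-bleach level
#'
#' The pre-bleach level \code{F_pre} is the mean of the pre-bleach frames
#' (at least 3 required) of a background-corrected bleach-ROI intensity
#' trace; the whole curve is divided by it, so the pre-bleach plateau is 1.
#'
#' @param record data.frame with \code{t_s} and \code{F} columns.
#' @param bleachFrame 1-based index of the first post-bleach sample
#'   (taken from \code{attr(record, "bleachFrame")} if missing).
#' @return The record with \code{F} normalized, plus attributes
#'   \code{fPre} (the raw pre-bleach mean) and \code{bleachFrame}.
#' @export
normalizeFrap <- function(record, bleachFrame = attr(record, "bleachFrame")) {
    if (is.null(bleachFrame)) {
        stop("bleachFrame must be supplied")
    }
    if (bleachFrame < 4L) {
        stop("need at least 3 pre-bleach frames")
    }
    fPre <- mean(record$F[seq_len(bleachFrame - 1L)])
    if (fPre <= 0) {
        stop("non-positive pre-bleach level")
    }
    record$F <- record$F / fPre
    attr(record, "fPre") <- fPre
    attr(record, "bleachFrame") <- bleachFrame
    record
}

#' Mobile fraction from a normalized FRAP curve
#'
#' Fits the single-exponential recovery
#' \deqn{F(t) = F_{post} + (F_{plateau} - F_{post})(1 - e^{-t/\tau})}
#' to the post-bleach record and returns
#' \deqn{M_f = (F_{plateau} - F_{post}) / (F_{pre} - F_{post}),}
#' clamped to [0, 1]. \code{F_post} is the first post-bleach sample; if the
#' nonlinear fit fails, the plateau falls back to the mean of the final
#' \code{plateauWindow} fraction of post-bleach frames. The estimate is
#' invariant to rescaling the raw curve by any positive constant.
#'
#' @param record normalized record from \code{\link{normalizeFrap}}.
#' @param bleachFrame 1-based index of the first post-bleach sample.
#' @param plateauWindow fraction of the post-bleach record used by the
#'   fallback plateau estimate (default 0.2).
#' @return list(Mf, fPre, fPost, fPlateau, tauS).
#' @export
mobileFraction <- function(record, bleachFrame = attr(record, "bleachFrame"),
                           plateauWindow = 0.2) {
    if (is.null(bleachFrame)) {
        stop("bleachFrame must be supplied")
    }
    post <- record[bleachFrame:nrow(record), ]
    fPre <- 1 # normalized
    fPost <- post$F[1L]
    if (fPre - fPost <= .Machine$double.eps^0.5) {
        stop("no bleach depth: F_pre equals F_post")
    }
    t <- post$t_s - post$t_s[1L]
    nTail <- max(2L, ceiling(plateauWindow * nrow(post)))
    tailMean <- mean(post$F[(nrow(post) - nTail + 1L):nrow(post)])
    fit <- tryCatch(
        minpack.lm::nlsLM(
            F ~ fPost + (plateau - fPost) * (1 - exp(-t / tau)),
            data = data.frame(F = post$F, t = t),
            start = list(plateau = tailMean, tau = max(t[2L], 1)),
            lower = c(plateau = fPost, tau = 1e-6),
            upper = c(plateau = Inf, tau = Inf),
            control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
    )
    if (is.null(fit)) {
        fPlateau <- tailMean
        tauS <- NA_real_
    } else {
        co <- stats::coef(fit)
        fPlateau <- co[["plateau"]]
        tauS <- co[["tau"]]
    }
    mf <- (fPlateau - fPost) / (fPre - fPost)
    list(
        Mf = min(max(mf, 0), 1), fPre = fPre, fPost = fPost,
        fPlateau = fPlateau, tauS = tauS
    )
}
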