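# Shared fixtures and small oracles, built in code at test time.

# a filled disc mask
discMask <- function(radiusPx, pad = 5L, pixelSize = 100) {
    n <- 2L * (radiusPx + pad) + 1L
    c0 <- radiusPx + pad + 1L
    d2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")
    CellMask(d2 <= radiusPx^2, pixelSize = pixelSize)
}

# one noiseless Gaussian spot at a continuous 0-based position
gaussFrame <- function(dims, y0, x0, A = 100, sigma = 1.5, pedestal = 0) {
    renderSpots(dims, y0, x0, A, sigma) + pedestal
}

# match estimated points to truth within a tolerance; recall/precision
matchPoints <- function(truth, est, tolNm) {
    if (nrow(est) == 0L) {
        return(list(recall = 0, precision = NA_real_, matchedErr = numeric(0)))
    }
    d <- sqrt(
        outer(truth[, 1L], est[, 1L], "-")^2 +
            outer(truth[, 2L], est[, 2L], "-")^2
    )
    mn <- apply(d, 1L, min)
    list(
        recall = mean(mn < tolNm),
        precision = mean(apply(d, 2L, min) < tolNm),
        matchedErr = mn[mn < tolNm]
    )
}

# plain-loop nearest-neighbour oracle (intentionally a different code path
# from the chunked-matrix implementation)
nnOracle <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
        sqrt(min((b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2))
    }, numeric(1))
}

# exhaustive max-cardinality / min-total-distance matching for small frames
oracleMatch <- function(P, Q, gate) {
    np <- nrow(P)
    nq <- nrow(Q)
    d <- sqrt(outer(P[, 1L], Q[, 1L], "-")^2 +
        outer(P[, 2L], Q[, 2L], "-")^2)
    bestCard <- -1L
    bestCost <- Inf
    rec <- function(i, used, card, cost) {
        if (i > np) {
            if (card > bestCard ||
                (card == bestCard && cost < bestCost - 1e-12)) {
                bestCard <<- card
                bestCost <<- cost
            }
            return(invisible())
        }
        rec(i + 1L, used, card, cost)
        for (j in seq_len(nq)) {
            if (!used[j] && d[i, j] <= gate) {
                rec(i + 1L, replace(used, j, TRUE), card + 1L, cost + d[i, j])
            }
        }
    }
    rec(1L, rep(FALSE, nq), 0L, 0)
    list(card = bestCard, cost = bestCost)
}
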