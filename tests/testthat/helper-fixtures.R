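# shared fixtures and independent oracles, built in code at test time

# fine-step explicit (midpoint) integration of the precursor-product
# system; independent of the package's adaptive solver
eulerOracle <- function(kPL, kPB, aP, aL, aB, input, tEnd, dt = 1e-3) {
  n <- floor(tEnd / dt)
  P <- L <- B <- numeric(n + 1)
  tt <- (0:n) * dt
  step <- function(y, u1, u2) {
    d1 <- c(u1 - aP * y[1], kPL * y[1] - aL * y[2],
            kPB * y[1] - aB * y[3])
    ym <- y + dt / 2 * d1
    d2 <- c(u2 - aP * ym[1], kPL * ym[1] - aL * ym[2],
            kPB * ym[1] - aB * ym[3])
    y + dt * d2
  }
  y <- c(0, 0, 0)
  for (i in seq_len(n)) {
    y <- step(y, input(tt[i]), input(tt[i] + dt / 2))
    P[i + 1] <- y[1]; L[i + 1] <- y[2]; B[i + 1] <- y[3]
  }
  list(t = tt, P = P, L = L, B = B)
}

# half-maximum crossing width (Hz) of the real absorption peak nearest
# `centerHz`, with linear interpolation between bins
measureFwhm <- function(spectrum, centerHz = 0, phase = 0) {
  re <- Re(exp(-1i * phase) * spectrum@values)
  hz <- spectrum@hz
  re <- re - stats::median(re[abs(hz - centerHz) > 500])  # baseline
  near <- which(abs(hz - centerHz) < 200)
  ipk <- near[which.max(re[near])]
  half <- re[ipk] / 2
  cross <- function(dir) {
    i <- ipk
    while (re[i + dir] > half) i <- i + dir
    # linear interpolation between i and i + dir
    f <- (re[i] - half) / (re[i] - re[i + dir])
    hz[i] + f * (hz[i + dir] - hz[i])
  }
  cross(1L) - cross(-1L)
}

# uniform-map MetaboliteMapSet with constant pyr/lac/bic values
uniformMaps <- function(pyr, lac, bic, n = 8) {
  pk <- defaultPeaks()
  maps <- array(0, dim = c(n, n, 3),
                dimnames = list(NULL, NULL, pk$name))
  maps[, , "pyr"] <- pyr; maps[, , "lac"] <- lac; maps[, , "bic"] <- bic
  new("MetaboliteMapSet", maps = maps, peaks = pk, factor = 1L,
      resMm = 1, datasetPhase = c(pyr = 0, lac = 0, bic = 0),
      nClamped = c(pyr = 0, lac = 0, bic = 0),
      nLowSignal = c(pyr = 0, lac = 0, bic = 0),
      provenance = list())
}

# hand product-limit estimator: independent of survival::survfit
handKm <- function(times, events) {
  ord <- order(times, -events)  # deaths before censorings at ties
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    atRisk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# hand log-rank O-E / variance accumulation for two groups
handLogrank <- function(tA, eA, tB, eB) {
  times <- sort(unique(c(tA[eA == 1], tB[eB == 1])))
  O <- E <- V <- 0
  for (tt in times) {
    nA <- sum(tA >= tt); nB <- sum(tB >= tt); N <- nA + nB
    d <- sum(tA == tt & eA == 1) + sum(tB == tt & eB == 1)
    oA <- sum(tA == tt & eA == 1)
    O <- O + oA
    E <- E + d * nA / N
    if (N > 1) V <- V + d * (nA / N) * (nB / N) * (N - d) / (N - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# exact signed-rank two-sided p by brute-force enumeration of all sign
# assignments (independent of the package's DP convolution)
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  pLo <- mean(vs <= v); pHi <- mean(vs >= v)
  min(1, 2 * min(pLo, pHi))
}

# brute-force Clopper-Pearson bound by scanning binomial tail sums
gridClopperPearson <- function(k, n, conf = 0.95, step = 1e-6) {
  a <- (1 - conf) / 2
  ps <- seq(step, 1 - step, by = step)
  lower <- if (k == 0) 0 else {
    # largest p with P(X >= k) <= a  ->  lower bound
    tail <- stats::pbinom(k - 1, n, ps, lower.tail = FALSE)
    ps[max(which(tail <= a))]
  }
  upper <- if (k == n) 1 else {
    tail <- stats::pbinom(k, n, ps)
    ps[min(which(tail <= a))]
  }
  c(lower = lower, upper = upper)
}
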