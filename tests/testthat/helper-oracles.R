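# Independent oracle implementations and small fixture builders, kept
# deliberately separate from the package's code paths.

# Lin's concordance correlation coefficient, moment form
# 2*s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2) with population moments over
# the vector (Lin's original estimator, as in epi.ccc).
linCCCOracle <- function(x, y) {
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2); sy2 <- mean((y - mean(y))^2)
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Exhaustive concordant-pair AUC: P(responder ranks on the responsive side
# of a non-responder), ties half credit. `respLow`: responders are expected
# to have LOWER scores.
aucPairOracle <- function(scores, response, respLow = TRUE) {
  rs <- scores[response == 1]
  ns <- scores[response == 0]
  tot <- 0
  for (a in rs) for (b in ns) {
    win <- if (respLow) a < b else a > b
    tot <- tot + if (win) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(rs) * length(ns))
}

# Log-rank chi-square from first principles: at each distinct event time,
# the observed minus hypergeometric-expected events in group 1, with the
# hypergeometric variance increment.
logrankOracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in times) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Random symmetric unit-diagonal matrix pair sharing feature order; only
# column g matters to the CCEC, so embed the given vectors there.
embedCorrPair <- function(u, v, g = 1) {
  n <- length(u) + 1
  mk <- function(vec) {
    M <- matrix(runif(n * n, -1, 1), n, n)
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    diag(M) <- 1
    M[-g, g] <- vec; M[g, -g] <- vec
    M
  }
  list(U = mk(u), V = mk(v))
}

assayMat <- function(se) SummarizedExperiment::assay(se)

# Small labelled expression matrix from a numeric vector/matrix.
toyExpr <- function(values, nFeatures, nSamples,
                    features = sprintf("g%d", seq_len(nFeatures)),
                    samples = sprintf("s%d", seq_len(nSamples))) {
  matrix(values, nFeatures, nSamples, dimnames = list(features, samples))
}

binaryOutcome <- function(ids, response) {
  out <- data.frame(sample_id = ids, response = response,
                    stringsAsFactors = FALSE)
  attr(out, "outcome_kind") <- "binary_response"
  out
}

survivalOutcome <- function(ids, time, event) {
  out <- data.frame(sample_id = ids, time = time, event = event,
                    stringsAsFactors = FALSE)
  attr(out, "outcome_kind") <- "survival"
  out
}

# Small, fast simulated study used by several test files.
smallSim <- function(seed = 3, ...) {
  simulateStudy(simConfig(nFeatures = 150, nSensitivity = 20,
                          nConcordant = 12, nPdx = 12, nPatientsRef = 60,
                          nPatientsVal = 80, moduleSize = 20, seed = seed,
                          ...))
}
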