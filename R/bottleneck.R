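## Heterozygosity-excess bottleneck testing: coalescent equilibrium
## distribution of gene diversity under the TPM conditional on the observed
## allele count, Wilcoxon signed-rank combination across loci, and the
## allele-frequency mode-shift (L-shape) check.

tpmGeomQ <- function(multistepVariance) {
  (-1 + sqrt(1 + 4 * multistepVariance)) / (2 * multistepVariance)
}

#' Equilibrium heterozygosity distribution given an observed allele count
#'
#' Simulates coalescent samples of `nCopies` gene copies under the two-phase
#' mutation model, calibrates the scaled mutation rate theta by bisection so
#' the mean simulated allele count matches `kObs`, then retains only
#' replicates whose allele count equals `kObs` exactly (the conditional
#' distribution used by heterozygosity-excess tests). Returns the mean, SD
#' and samples of unbiased gene diversity among accepted replicates.
#'
#' @param nCopies gene copies in the observed sample.
#' @param kObs observed number of distinct alleles (2 <= kObs <= nCopies).
#' @param pMultistep TPM multistep probability (default 0.10).
#' @param multistepVariance variance of the multistep size distribution.
#' @param nSims accepted replicates required (>= 100).
#' @param seed optional RNG seed.
#' @param nCal replicates per theta evaluation during calibration.
#' @return List with `mean`, `sd`, `median`, `samples`, `theta`.
#' @export
equilibriumHet <- function(nCopies, kObs, pMultistep = 0.10,
                           multistepVariance = 12, nSims = 1000L,
                           seed = NULL, nCal = 300L) {
  if (kObs < 2 || kObs > nCopies) stop("need 2 <= kObs <= nCopies")
  if (nSims < 100L) stop("nSims must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  q <- tpmGeomQ(multistepVariance)
  meanK <- function(theta) {
    mean(cpp_tpm_coalescent(nCopies, theta, pMultistep, q, nCal)$k)
  }
  lo <- 0.005
  hi <- 1
  while (meanK(hi) < kObs && hi < 4096) hi <- hi * 2
  for (it in seq_len(14L)) {
    mid <- sqrt(lo * hi)
    if (meanK(mid) < kObs) lo <- mid else hi <- mid
  }
  theta <- sqrt(lo * hi)
  acc <- numeric(0)
  attempts <- 0L
  batch <- max(500L, nSims)
  while (length(acc) < nSims) {
    sims <- cpp_tpm_coalescent(nCopies, theta, pMultistep, q, batch)
    acc <- c(acc, sims$H[sims$k == kObs])
    attempts <- attempts + batch
    if (attempts >= 1000L * nSims && length(acc) < attempts / 1000) {
      stop(
        "acceptance rate below 0.1% at kObs = ", kObs,
        "; review TPM parameters"
      )
    }
  }
  acc <- acc[seq_len(nSims)]
  list(
    mean = mean(acc), sd = sd(acc), median = stats::median(acc),
    samples = acc, theta = theta
  )
}

#' Wilcoxon signed-rank test for heterozygosity excess or deficit
#'
#' Pairs each locus's observed gene diversity with its simulated equilibrium
#' mean and tests the signed differences. Exact by full enumeration of the
#' signed-rank distribution (handles midranks) for up to 20 informative
#' loci; normal approximation with continuity correction above that.
#'
#' @param observedH numeric vector of per-locus observed gene diversity.
#' @param equilibriumMeans matched vector of simulated equilibrium means.
#' @param tail `"excess"` (observed above equilibrium), `"deficit"`, or
#'   `"two.sided"`.
#' @return p-value in `(0, 1]`.
#' @examples
#' wilcoxonHetTest(rep(0.8, 5), rep(0.5, 5), "excess") # 1/32
#' @export
wilcoxonHetTest <- function(observedH, equilibriumMeans,
                            tail = c("excess", "deficit", "two.sided")) {
  tail <- match.arg(tail)
  d <- observedH - equilibriumMeans
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  L <- length(d)
  if (L <= 20L) {
    r2 <- as.integer(round(2 * r)) # doubled ranks are integers (midranks)
    dist <- c(1, rep(0, sum(r2)))
    for (rk in r2) {
      shifted <- c(rep(0, rk), dist[seq_len(length(dist) - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^L
    w2 <- round(2 * wPlus)
    pGe <- sum(dist[seq(w2 + 1L, length(dist))]) # P(W+ >= w)
    pLe <- sum(dist[seq_len(w2 + 1L)]) # P(W+ <= w)
  } else {
    mu <- sum(r) / 2
    sdw <- sqrt(sum(r^2) / 4)
    pGe <- pnorm((wPlus - mu - 0.5) / sdw, lower.tail = FALSE)
    pLe <- pnorm((wPlus - mu + 0.5) / sdw)
  }
  p <- switch(tail,
    excess = pGe,
    deficit = pLe,
    two.sided = min(1, 2 * min(pGe, pLe))
  )
  min(max(p, .Machine$double.xmin), 1)
}

#' Allele-frequency mode-shift check
#'
#' Pools allele frequencies across loci into ten classes of width 0.1. At
#' mutation-drift equilibrium the histogram is L-shaped: the rarest class
#' `(0, 0.1]` is the strict mode. A mode shift (the classic qualitative
#' bottleneck signature) is declared when it is not.
#'
#' @param freqs numeric vector of allele frequencies pooled across loci
#'   (each in `(0, 1]`).
#' @return List with `modeShift` (logical) and `histogram` (named counts of
#'   the ten classes).
#' @export
modeShift <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  breaks <- seq(0, 1, by = 0.1)
  h <- table(cut(freqs, breaks, include.lowest = FALSE))
  lShaped <- length(freqs) > 0 && h[1L] > max(h[-1L])
  list(modeShift = !lShaped, histogram = h)
}

#' Bottleneck test per cluster
#'
#' For every cluster: per-locus observed gene diversity is compared with the
#' simulated TPM equilibrium distribution conditional on the locus's allele
#' count ([equilibriumHet()]); the standardized differences DH and all
#' three Wilcoxon tails are reported, along with the mode-shift verdict.
#' Monomorphic loci are uninformative and skipped.
#'
#' The conditional distribution of H given an allele count is left-skewed,
#' so centering the paired differences on its mean makes the one-tailed
#' excess test anticonservative; the default pairs each observed H with the
#' conditional median instead, which holds the test at or below nominal
#' size (the mean and SD still enter through DH).
#'
#' @param panel a [GenotypePanel-class].
#' @param by grouping level, `"cluster"` or `"site"`.
#' @param pMultistep,multistepVariance TPM parameters.
#' @param nSims accepted equilibrium replicates per locus.
#' @param center pair observed H against the conditional `"median"`
#'   (default) or `"mean"`.
#' @param seed optional RNG seed.
#' @return A list of class `BottleneckResult`: per cluster a list with
#'   `perLocus` (data.frame: locus, nCopies, kObs, Hobs, Heq, HeqSd, DH),
#'   `p` (named vector: excess, deficit, two.sided), `modeShift`,
#'   `histogram`.
#' @export
bottleneckTest <- function(panel, by = c("cluster", "site"),
                           pMultistep = 0.10, multistepVariance = 12,
                           nSims = 500L, center = c("median", "mean"),
                           seed = NULL) {
  by <- match.arg(by)
  center <- match.arg(center)
  if (!is.null(seed)) set.seed(seed)
  ft <- alleleCounts(panel, by = by)
  cache <- new.env(parent = emptyenv())
  out <- lapply(ft$groups, function(grp) {
    rows <- list()
    freqs <- numeric(0)
    for (loc in ft$loci) {
      cnt <- ft$counts[[grp]][[loc]]
      n <- sum(cnt)
      k <- length(cnt)
      if (n > 0) freqs <- c(freqs, as.numeric(cnt) / n)
      if (k < 2L || n < 4L) next
      key <- paste(n, k, sep = "_")
      eq <- if (exists(key, cache)) get(key, cache) else {
        e <- equilibriumHet(n, k, pMultistep, multistepVariance, nSims)
        assign(key, e, cache)
        e
      }
      hobs <- expectedHet(cnt)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, nCopies = n, kObs = k, Hobs = hobs,
        Heq = eq$mean, HeqSd = eq$sd, HeqMed = eq$median,
        DH = if (eq$sd > 0) (hobs - eq$mean) / eq$sd else NA_real_
      )
    }
    perLocus <- do.call(rbind, rows)
    if (is.null(perLocus) || nrow(perLocus) < 4L) {
      stop("cluster '", grp, "' has fewer than 4 polymorphic loci")
    }
    ms <- modeShift(freqs)
    ref <- if (center == "median") perLocus$HeqMed else perLocus$Heq
    list(
      perLocus = perLocus,
      p = c(
        excess = wilcoxonHetTest(perLocus$Hobs, ref, "excess"),
        deficit = wilcoxonHetTest(perLocus$Hobs, ref, "deficit"),
        two.sided = wilcoxonHetTest(perLocus$Hobs, ref, "two.sided")
      ),
      modeShift = ms$modeShift, histogram = ms$histogram
    )
  })
  names(out) <- ft$groups
  class(out) <- "BottleneckResult"
  out
}

#' @export
print.BottleneckResult <- function(x, ...) {
  cat("Bottleneck tests (", length(x), " cluster(s))\n", sep = "")
  for (g in names(x)) {
    cat(sprintf(
      "  %-6s excess p = %.4f  deficit p = %.4f  mode shift: %s\n",
      g, x[[g]]$p["excess"], x[[g]]$p["deficit"],
      if (x[[g]]$modeShift) "YES" else "no"
    ))
  }
  invisible(x)
}
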