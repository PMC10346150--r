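#' EM haplotype-frequency estimation for two unphased biallelic loci
#'
#' Estimates the four two-locus haplotype frequencies from a pair of
#' dosage columns. Only the double-heterozygote class is phase-ambiguous;
#' starting at linkage equilibrium, EM reassigns it between the cis and
#' trans configurations until the log-likelihood is stationary
#' (delta < 1e-10) or 1000 iterations. The log-likelihood is verified to
#' be non-decreasing at every step.
#'
#' @param g1,g2 integer dosage vectors (0/1/2, `NA` allowed); at least 10
#'   pairwise-complete samples are required.
#' @return `list(freqs, em_iterations, converged, loglik)`; `freqs` is a
#'   named numeric(4) in the order (minor-minor, minor-major,
#'   major-minor, major-major), summing to 1.
#' @export
emHaplotypeFreqs <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 10)
    stop("need at least 10 pairwise-complete samples, got ", sum(ok))
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[g1[i] + 1, g2[i] + 1] <-
      cnt[g1[i] + 1, g2[i] + 1] + 1
  # haplotype counts fixed by unambiguous genotype classes
  # indices: f11 minor-minor, f10 minor-major, f01 major-minor, f00 maj-maj
  base11 <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  base10 <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  base01 <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]
  base00 <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  ndh <- cnt[2, 2]                      # double heterozygotes
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  f <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  f <- pmax(f, 1e-12); f <- f / sum(f)
  ll <- function(f) {
    probs <- matrix(0, 3, 3)
    probs[1, 1] <- f[4]^2
    probs[1, 2] <- 2 * f[4] * f[3]
    probs[1, 3] <- f[3]^2
    probs[2, 1] <- 2 * f[2] * f[4]
    probs[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
    probs[2, 3] <- 2 * f[1] * f[3]
    probs[3, 1] <- f[2]^2
    probs[3, 2] <- 2 * f[1] * f[2]
    probs[3, 3] <- f[1]^2
    sum(cnt[cnt > 0] * log(probs[cnt > 0]))
  }
  prev <- ll(f)
  iter <- 0
  converged <- FALSE
  while (iter < 1000) {
    iter <- iter + 1
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    c11 <- base11 + w * ndh
    c10 <- base10 + (1 - w) * ndh
    c01 <- base01 + (1 - w) * ndh
    c00 <- base00 + w * ndh
    f <- c(c11, c10, c01, c00) / (2 * n)
    cur <- ll(f)
    if (cur < prev - 1e-8)
      stop("EM log-likelihood decreased (", prev, " -> ", cur, ")")
    if (abs(cur - prev) < 1e-10) { converged <- TRUE; prev <- cur; break }
    prev <- cur
  }
  names(f) <- c("mm", "mM", "Mm", "MM")
  list(freqs = f, em_iterations = iter, converged = converged,
       loglik = prev)
}

#' Normalized linkage disequilibrium |D'|
#'
#' With haplotype frequencies (pAB, pAb, paB, pab): D = pAB - pA*pB and
#' D' = D / Dmax, where Dmax = min(pA*pb, pa*pB) for D > 0 and
#' min(pA*pB, pa*pb) for D < 0. Returns |D'|; 0 when either locus is
#' monomorphic (D' is undefined there).
#'
#' @param freqs numeric(4) haplotype frequencies in the order
#'   (AB, Ab, aB, ab), summing to 1.
#' @return |D'| in `[0, 1]`.
#' @examples
#' dPrime(c(0.5, 0, 0, 0.5))          # 1: complete LD
#' dPrime(c(0.4, 0.1, 0.2, 0.3))      # 0.5
#' @export
dPrime <- function(freqs) {
  stopifnot(length(freqs) == 4, all(freqs >= -1e-9),
            abs(sum(freqs) - 1) < 1e-6)
  pA <- freqs[1] + freqs[2]
  pB <- freqs[1] + freqs[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(0)
  D <- freqs[1] - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (Dmax <= 0) return(0)
  unname(min(abs(D) / Dmax, 1))
}

#' Greedy LD pruning of candidate variants
#'
#' Candidates are visited in ascending scan p-value (the strongest
#' association first); a candidate is dropped when its |D'| with any
#' already-retained candidate is at or above the threshold. Variants in
#' strong LD carry redundant information, so one of each such pair is
#' excluded and mutually independent candidates are kept. After pruning,
#' all pairwise |D'| among retained variants are verified to lie below
#' the threshold.
#'
#' @param candidates character vector of variant ids (subset of the
#'   cohort's variants).
#' @param x a [CohortExperiment].
#' @param p named numeric vector of scan p-values for the candidates
#'   (names = variant ids); defaults to the candidate order given.
#' @param threshold |D'| at or above which a pair is considered redundant
#'   (default 0.2).
#' @return `list(retained = <ids>, log = <data.frame of drops with their
#'   retained partner and |D'|>, pairs = <all computed pairs>)`.
#' @export
ldPrune <- function(candidates, x, p = NULL, threshold = 0.2) {
  d <- dosages(x)
  missing_ids <- setdiff(candidates, colnames(d))
  if (length(missing_ids))
    stop("candidates absent from cohort: ",
         paste(missing_ids, collapse = ", "))
  if (is.null(p)) p <- setNames(seq_along(candidates), candidates)
  ord <- candidates[order(p[candidates])]
  retained <- character(0)
  drops <- list()
  pairs <- list()
  for (id in ord) {
    partner <- NA_character_; dp_hit <- NA_real_
    for (r in retained) {
      em <- emHaplotypeFreqs(d[, id], d[, r])
      dp <- dPrime(em$freqs)
      pairs[[length(pairs) + 1]] <- data.frame(
        id1 = id, id2 = r, d_prime = dp,
        em_iterations = em$em_iterations, converged = em$converged,
        stringsAsFactors = FALSE)
      if (dp >= threshold) { partner <- r; dp_hit <- dp; break }
    }
    if (is.na(partner)) retained <- c(retained, id)
    else drops[[length(drops) + 1]] <-
        data.frame(dropped = id, partner = partner, d_prime = dp_hit,
                   stringsAsFactors = FALSE)
  }
  log <- if (length(drops)) do.call(rbind, drops) else
    data.frame(dropped = character(0), partner = character(0),
               d_prime = numeric(0))
  # post-hoc invariant: retained set is pairwise below threshold
  if (length(retained) > 1) {
    cmb <- combn(retained, 2)
    for (i in seq_len(ncol(cmb))) {
      dp <- dPrime(emHaplotypeFreqs(d[, cmb[1, i]], d[, cmb[2, i]])$freqs)
      if (dp >= threshold)
        stop("internal error: retained pair ", cmb[1, i], "/", cmb[2, i],
             " has |D'| = ", dp)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id1 = character(0), id2 = character(0),
               d_prime = numeric(0), em_iterations = integer(0),
               converged = logical(0))
  list(retained = retained, log = log, pairs = pairs)
}
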