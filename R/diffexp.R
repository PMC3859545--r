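#' Median-of-ratios size factors
#'
#' s_j = median over genes of counts_ij / (geometric mean of gene i across
#' samples), computed on genes with nonzero counts in every sample. Equal
#' columns give all-1 factors.
#'
#' @param counts `count_matrix` or plain matrix (genes x samples).
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- .counts_of(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep))
    stop("no gene has nonzero counts in all samples; ",
         "a pseudo-reference fallback is not implemented")
  lg <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lg)  # log geometric mean
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  setNames(sf, colnames(m))
}

#' Estimate per-gene dispersions and the mean-dispersion curve
#'
#' Method-of-moments estimate on size-normalized counts z_ij = k_ij / s_j:
#' alpha_i = max(0, (v_i - mu_i * mean(1/s)) / mu_i^2) with v_i the pooled
#' within-group variance (the mean(1/s) term is the shot-noise contribution
#' of the normalization; it is 1 at unit size factors). Only groups with at
#' least two replicates contribute to the variance: a single-replicate
#' group (e.g. the lone polyA+ sample in a protocol contrast) carries no
#' replication information, and folding it in would count the group
#' difference under test as noise. A hyperbolic mean-dispersion curve
#' alpha(mu) = a0 + a1/mu is then fitted by least squares through the
#' positive raw estimates, and each gene's final dispersion is the maximum
#' of its raw estimate and the curve value at its mean (the "hockey-stick"
#' rule that guards against underestimated noise).
#'
#' @param counts `count_matrix` or plain matrix.
#' @param sf Size factors from [size_factors()].
#' @param groups Optional per-sample group labels for within-group pooling.
#' @return A list of class `dispersion_estimate` with mu, alpha_raw,
#'   alpha_fit, alpha_final, bcv (sqrt of final dispersion) and curve
#'   coefficients a0, a1.
#' @export
estimate_dispersions <- function(counts, sf, groups = NULL) {
  m <- .counts_of(counts)
  if (ncol(m) < 2) stop("at least 2 samples required")
  sf <- sf[colnames(m)]
  z <- sweep(m, 2, sf, "/")
  if (is.null(groups)) groups <- rep("all", ncol(m))
  groups <- as.character(groups)
  # groups with replicates carry the variance information
  G <- names(which(table(groups) >= 2))
  if (!length(G)) stop("fewer than 2 usable samples for dispersion estimation")
  used <- groups %in% G
  mu <- rowMeans(z[, used, drop = FALSE])
  ss <- rowSums(matrix(vapply(G, function(g) {
    zg <- z[, groups == g, drop = FALSE]
    rowSums((zg - rowMeans(zg))^2)
  }, numeric(nrow(z))), nrow = nrow(z)))
  df <- sum(used) - length(G)
  v <- ss / df
  xi <- mean(1 / sf[used])
  alpha_raw <- ifelse(mu > 0, pmax(0, (v - xi * mu) / mu^2), 0)
  use <- alpha_raw > 0 & mu > 0
  if (sum(use) >= 2) {
    cf <- coef(lm(alpha_raw[use] ~ I(1 / mu[use])))
    a0 <- unname(cf[1]); a1 <- unname(cf[2])
  } else {
    a0 <- mean(alpha_raw); a1 <- 0
  }
  alpha_fit <- pmax(0, a0 + ifelse(mu > 0, a1 / mu, 0))
  alpha_final <- pmax(alpha_raw, alpha_fit)
  structure(list(mu = mu, alpha_raw = alpha_raw, alpha_fit = alpha_fit,
                 alpha_final = alpha_final, bcv = sqrt(alpha_final),
                 a0 = a0, a1 = a1, pooled = length(G) == 1),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf(
    "<dispersion_estimate> %d genes; curve alpha(mu) = %.4g + %.4g/mu; median BCV %.3f\n",
    length(x$mu), x$a0, x$a1, median(x$bcv, na.rm = TRUE)))
  invisible(x)
}

#' Fold change with the 0-handling conventions of the DE tables
#'
#' FC = b/a with 0/x = 0, x/0 = Inf and 0/0 = NaN.
#'
#' @param a,b Group mean expressions (baseMeanA, baseMeanB).
#' @return Fold change(s).
#' @export
fold_change <- function(a, b) {
  ifelse(a == 0 & b == 0, NaN, ifelse(a == 0, Inf, b / a))
}

# two-sided exact-style conditioned NB test for one gene: given group sums
# kA, kB, compare all partitions of kA + kB between the two group-sum NB
# distributions, summing the probability of partitions no more likely than
# the observed one. The enumeration window holds all but < 1e-6 of the
# conditional mass.
.nb_exact_p <- function(kA, kB, muA, muB, varA, varB) {
  S <- kA + kB
  if (S == 0) return(1)
  dA <- function(k) {
    if (varA > muA * (1 + 1e-8)) {
      stats::dnbinom(k, mu = muA, size = muA^2 / (varA - muA))
    } else stats::dpois(k, muA)
  }
  dB <- function(k) {
    if (varB > muB * (1 + 1e-8)) {
      stats::dnbinom(k, mu = muB, size = muB^2 / (varB - muB))
    } else stats::dpois(k, muB)
  }
  qlo <- function(mu, var) {
    if (var > mu * (1 + 1e-8)) stats::qnbinom(1e-7, mu = mu, size = mu^2 / (var - mu))
    else stats::qpois(1e-7, mu)
  }
  qhi <- function(mu, var) {
    if (var > mu * (1 + 1e-8)) stats::qnbinom(1 - 1e-7, mu = mu, size = mu^2 / (var - mu))
    else stats::qpois(1 - 1e-7, mu)
  }
  a_lo <- max(0, min(qlo(muA, varA), S - qhi(muB, varB)))
  a_hi <- min(S, max(qhi(muA, varA), S - qlo(muB, varB)))
  a_lo <- min(a_lo, kA); a_hi <- max(a_hi, kA)
  ks <- a_lo:a_hi
  p <- dA(ks) * dB(S - ks)
  denom <- sum(p)
  if (denom <= 0) return(1)
  p_obs <- dA(kA) * dB(kB)
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]) / denom)
}

#' Negative-binomial test for differential expression
#'
#' For each gene, the size-normalized group means give baseMeanA/B, FC and
#' log2FC; the p-value comes from a two-sided exact-style test conditioning
#' on the total of the two group sums: under the pooled-mean null each
#' group's sum is NB with mean q0 * sum(s_j in group) and variance
#' mean + alpha * q0^2 * sum(s_j^2 in group) (alpha = the gene's final
#' fitted dispersion), and the p-value adds up the probabilities of all
#' partitions of the observed total no more likely than the observed one.
#' The test uses the fitted mean-dispersion curve value for each gene (the
#' classic formulation; per-gene raw estimates are far too noisy at 2-3
#' replicates and enter only through the curve fit), while the
#' `dispersion_estimate`'s final values keep the conservative max(raw,
#' fitted) rule for reporting. Genes with zero counts in both groups get
#' p = 1 and NaN fold change and are flagged in the `zero_total` column.
#'
#' @param counts `count_matrix` or plain matrix.
#' @param sf Size factors.
#' @param disp A `dispersion_estimate`.
#' @param condition Per-sample two-level labels (character or factor); the
#'   first level is group A, the second group B.
#' @param locus Optional named per-gene locus strings for the output table.
#' @return data.frame with gene_id, locus, baseMean, baseMeanA, baseMeanB,
#'   FC, log2FC, pval, padj, zero_total, sorted as input.
#' @export
nb_test <- function(counts, sf, disp, condition, locus = NULL) {
  m <- .counts_of(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly 2 levels")
  iA <- which(condition == levels(condition)[1])
  iB <- which(condition == levels(condition)[2])
  if (!length(iA) || !length(iB)) stop("both groups must be non-empty")
  sf <- sf[colnames(m)]
  z <- sweep(m, 2, sf, "/")
  baseMean <- rowMeans(z)
  baseMeanA <- rowMeans(z[, iA, drop = FALSE])
  baseMeanB <- rowMeans(z[, iB, drop = FALSE])
  sA <- sum(sf[iA]); sB <- sum(sf[iB])
  s2A <- sum(sf[iA]^2); s2B <- sum(sf[iB]^2)
  alpha <- if (!is.null(disp$alpha_fit)) disp$alpha_fit else disp$alpha_final
  pval <- vapply(seq_len(nrow(m)), function(i) {
    kA <- sum(m[i, iA]); kB <- sum(m[i, iB])
    if (kA + kB == 0) return(1)
    q0 <- (kA + kB) / (sA + sB)
    muA <- q0 * sA; muB <- q0 * sB
    varA <- muA + alpha[i] * q0^2 * s2A
    varB <- muB + alpha[i] * q0^2 * s2B
    .nb_exact_p(kA, kB, muA, muB, varA, varB)
  }, numeric(1))
  fc <- fold_change(baseMeanA, baseMeanB)
  zero <- baseMeanA == 0 & baseMeanB == 0
  out <- data.frame(
    gene_id = rownames(m),
    locus = if (is.null(locus)) NA_character_ else locus[rownames(m)],
    baseMean = baseMean, baseMeanA = baseMeanA, baseMeanB = baseMeanB,
    FC = fc, log2FC = log2(fc), pval = pval,
    padj = bh_adjust(pval), zero_total = zero,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvals p-values in [0, 1] (finite).
#' @return Adjusted p-values, each >= its input p-value.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Filter a DE table at an FDR threshold
#'
#' @param results data.frame from [nb_test()].
#' @param fdr FDR threshold (e.g. 0.10).
#' @return Rows with padj <= fdr, sorted by padj ascending.
#' @export
de_genes <- function(results, fdr = 0.10) {
  out <- results[!is.na(results$padj) & results$padj <= fdr, , drop = FALSE]
  out[order(out$padj), , drop = FALSE]
}

#' Mean expression vs biological coefficient of variation
#'
#' BCV = sqrt(final dispersion); mean expression is reported as counts per
#' million of size-normalized counts.
#'
#' @param disp A `dispersion_estimate`.
#' @param counts `count_matrix` or plain matrix.
#' @param sf Size factors.
#' @return data.frame with gene_id, cpm, bcv.
#' @export
bcv_summary <- function(disp, counts, sf) {
  m <- .counts_of(counts)
  z <- sweep(m, 2, sf[colnames(m)], "/")
  cpm <- rowMeans(sweep(z, 2, colSums(z), "/") * 1e6)
  data.frame(gene_id = rownames(m), cpm = cpm, bcv = disp$bcv,
             row.names = NULL, stringsAsFactors = FALSE)
}
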