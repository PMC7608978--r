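# Two-stage Simple Sum colocalization test.
#
# Stage 1 screens the region for any secondary-trait signal: S1 = sum of the
# 1-df chi-square evidence T_j, whose null distribution under LD matrix R is
# the quadratic form sum_i lambda_i * chisq_1 with lambda_i the eigenvalues
# of R. Stage 2 weights T by centered GWAS evidence c_j = -log10 p_j - mean
# and standardizes against a null covariance calibrated by the region-wide
# noncentrality estimate.

#' Transform p-values to 1-df chi-square evidence
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of upper-tail chi-square(1 df) quantiles.
#' @examples
#' pvalues_to_chisq(c(1, 0.05))
#' @export
pvalues_to_chisq <- function(p) {
  if (length(p) == 0L || anyNA(p) || any(p <= 0 | p > 1)) {
    ss_stop("p-values must lie in (0, 1]", "sscoloc_domain_error")
  }
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Tail probability of a weighted sum of chi-squares
#'
#' Computes Pr(sum_i lambda_i X_i > s) for independent 1-df chi-squares X_i
#' by Imhof-type numerical inversion of the characteristic function, with
#' closed forms for the one-eigenvalue and equal-eigenvalue cases. The result
#' is clipped to (1e-300, 1].
#'
#' @param s Observed value of the quadratic form.
#' @param lambdas Nonnegative eigenvalue weights, at least one positive.
#' @return The upper-tail probability.
#' @examples
#' quadform_tail_prob(qchisq(0.95, 2), c(1, 1))
#' @export
quadform_tail_prob <- function(s, lambdas) {
  if (length(lambdas) == 0L || anyNA(lambdas) || any(lambdas < 0)) {
    ss_stop("eigenvalues must be nonnegative", "sscoloc_domain_error")
  }
  lambdas <- lambdas[lambdas > 1e-12]
  if (length(lambdas) == 0L) {
    ss_stop("all eigenvalues are (numerically) zero", "sscoloc_degenerate_error")
  }
  if (!is.finite(s)) ss_stop("observed statistic must be finite", "sscoloc_domain_error")
  if (s <= 0) return(1)
  k <- length(lambdas)
  if (k == 1L || max(lambdas) - min(lambdas) < 1e-12 * max(lambdas)) {
    p <- stats::pchisq(s / mean(lambdas), df = k, lower.tail = FALSE)
    return(min(max(p, 1e-300), 1))
  }
  integrand <- function(u) {
    vapply(u, function(ui) {
      if (ui == 0) return((sum(lambdas) - s) / 2)
      lu <- lambdas * ui
      theta <- 0.5 * sum(atan(lu)) - 0.5 * s * ui
      log_rho <- 0.25 * sum(log1p(lu^2))
      sin(theta) * exp(-log_rho) / ui
    }, numeric(1))
  }
  res <- tryCatch(
    stats::integrate(integrand, 0, Inf, subdivisions = 2000L,
                     rel.tol = 1e-10, abs.tol = 1e-9, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) {
    # two-moment (Satterthwaite) fallback: a * chisq_nu matching mean/variance
    a <- sum(lambdas^2) / sum(lambdas)
    nu <- sum(lambdas)^2 / sum(lambdas^2)
    p <- stats::pchisq(s / a, df = nu, lower.tail = FALSE)
  } else {
    p <- 0.5 + res$value / pi
  }
  min(max(p, 1e-300), 1)
}

#' Stage-1 region-wide signal test
#'
#' Tests whether the secondary dataset shows any association in the region:
#' the sum of the chi-square evidence is referred to its LD-implied null,
#' the quadratic form weighted by the eigenvalues of R (eigenvalues below
#' 1e-10 dropped).
#'
#' @param T Vector of 1-df chi-square statistics.
#' @param R An `ld_matrix` (or bare correlation matrix) aligned to `T`.
#' @return The stage-1 p-value.
#' @export
stage1_test <- function(T, R) {
  r <- if (inherits(R, "ld_matrix")) R$r else as.matrix(R)
  if (nrow(r) != length(T)) {
    ss_stop("LD matrix dimension does not match statistic vector", "sscoloc_alignment_error")
  }
  lam <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam >= 1e-10]
  quadform_tail_prob(sum(T), lam)
}

#' Estimate the common noncentrality of a region
#'
#' Regions passing stage 1 contain secondary-trait signal; the stage-2 null
#' is calibrated by attributing a common noncentrality delta-hat =
#' max(mean(T) - 1, 0) to every SNP.
#'
#' @param T Vector of 1-df chi-square statistics.
#' @return The noncentrality estimate (nonnegative scalar).
#' @export
estimate_noncentrality <- function(T) {
  max(mean(T) - 1, 0)
}

#' GWAS evidence weights for the Simple Sum statistic
#'
#' @param p_gwas GWAS p-values in (0, 1].
#' @return List with `g` (-log10 p) and centered weights `c` (sum zero).
#' @export
ss_weights <- function(p_gwas) {
  if (anyNA(p_gwas) || any(p_gwas <= 0 | p_gwas > 1)) {
    ss_stop("GWAS p-values must lie in (0, 1]", "sscoloc_domain_error")
  }
  g <- -log10(p_gwas)
  list(g = g, c = g - mean(g))
}

#' Stage-2 Simple Sum colocalization test
#'
#' Standardizes the GWAS-weighted sum of secondary chi-square evidence
#' against its null covariance Sigma_jk = 2 r_jk^2 + 4 delta r_jk (signed r
#' when available; with unsigned input the cross terms are upper-bounded).
#' The alternative is one-sided: colocalization predicts positive
#' association between GWAS evidence and secondary evidence.
#'
#' @param T Chi-square evidence vector.
#' @param weights Output of [ss_weights()], aligned to `T`.
#' @param R `ld_matrix` (or bare matrix) aligned to `T`.
#' @param delta Noncentrality estimate from [estimate_noncentrality()].
#' @return List with `ok`; when `ok`, `z` (the standardized statistic) and
#'   `p` (upper-tail normal probability); otherwise a `reason` string.
#' @export
ss_stage2_test <- function(T, weights, R, delta) {
  r <- if (inherits(R, "ld_matrix")) R$r else as.matrix(R)
  cc <- weights$c
  if (nrow(r) != length(T) || length(cc) != length(T)) {
    ss_stop("T, weights and R must be aligned", "sscoloc_alignment_error")
  }
  if (all(abs(cc) < 1e-12)) {
    return(list(ok = FALSE, reason = "constant GWAS p-values (degenerate weights)"))
  }
  Sigma <- 2 * r * r + 4 * delta * r
  q <- as.numeric(crossprod(cc, Sigma %*% cc))
  if (!is.finite(q) || q <= 0) {
    return(list(ok = FALSE, reason = "non-positive null variance"))
  }
  z <- sum(cc * T) / sqrt(q)
  if (!is.finite(z)) {
    return(list(ok = FALSE, reason = "non-finite statistic"))
  }
  list(ok = TRUE, z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

# sentinel codes, as printed by the heatmap/table outputs
SENTINEL_NO_DATA <- -1L
SENTINEL_NOT_SIGNIFICANT <- -2L
SENTINEL_FAILED <- -3L

sentinel_reason <- function(sentinel) {
  switch(as.character(sentinel),
         "-1" = "No eQTL data",
         "-2" = "No significant eQTLs",
         "-3" = "SS test failed",
         "")
}

ss_result <- function(status, sentinel = NA_integer_, stage1_p = NA_real_,
                      ss_z = NA_real_, ss_p = NA_real_, n_snps = 0L,
                      m = 1L, alpha = 0.05, label = NULL, reason = "") {
  neglog <- if (status == "OK") -log10(max(ss_p, 1e-300)) else NA_real_
  structure(list(status = status, sentinel = sentinel, stage1_p = stage1_p,
                 ss_z = ss_z, ss_p = ss_p, neglog10_ss_p = neglog,
                 n_snps = n_snps, m = m, alpha = alpha, label = label,
                 reason = if (nzchar(reason)) reason else sentinel_reason(sentinel)),
            class = "ss_result")
}

#' Run the two-stage Simple Sum test for one secondary dataset
#'
#' Harmonizes the primary and secondary datasets with the LD matrix inside
#' the Simple Sum region and runs the Bonferroni-gated two-stage test.
#' Failure modes are encoded as sentinel statuses rather than errors:
#' \describe{
#'   \item{-1 (NO_DATA)}{no secondary records (or no harmonizable variants)
#'     in the region}
#'   \item{-2 (NOT_SIGNIFICANT)}{stage-1 p exceeds alpha / m}
#'   \item{-3 (FAILED)}{fewer than `min_snps` harmonized SNPs, or a
#'     numerical failure in stage 2}
#' }
#'
#' @param primary GWAS `sumstat_dataset`.
#' @param secondary Secondary (e.g. eQTL) `sumstat_dataset`.
#' @param ld An `ld_matrix` covering the region.
#' @param ss_region The `region` the test is computed on.
#' @param alpha Nominal level for the stage-1 gate (default 0.05).
#' @param m Bonferroni denominator: number of secondary datasets in the run.
#' @param min_snps Minimum harmonized SNPs required for stage 2 (default 5).
#' @param label Optional label stored on the result.
#' @return An `ss_result`.
#' @export
run_simple_sum <- function(primary, secondary, ld, ss_region,
                           alpha = 0.05, m = 1L, min_snps = 5L, label = NULL) {
  sec <- subset_region(secondary, ss_region)
  if (nrow(sec) == 0L) {
    return(ss_result("NO_DATA", SENTINEL_NO_DATA, m = m, alpha = alpha, label = label))
  }
  prim <- subset_region(primary, ss_region)
  if (nrow(prim) == 0L) {
    return(ss_result("NO_DATA", SENTINEL_NO_DATA, m = m, alpha = alpha, label = label))
  }
  h <- tryCatch(harmonize_datasets(prim, sec, ld),
                sscoloc_no_overlap_error = function(e) NULL)
  if (is.null(h)) {
    return(ss_result("NO_DATA", SENTINEL_NO_DATA, m = m, alpha = alpha, label = label))
  }
  n <- length(h$primary_idx)
  r_sub <- ld$r[h$ld_idx, h$ld_idx, drop = FALSE]
  T <- pvalues_to_chisq(sec$p[h$secondary_idx])
  stage1_p <- tryCatch(stage1_test(T, r_sub), sscoloc_error = function(e) NA_real_)
  if (is.na(stage1_p)) {
    return(ss_result("FAILED", SENTINEL_FAILED, n_snps = n, m = m, alpha = alpha,
                     label = label, reason = "stage-1 computation failed"))
  }
  if (stage1_p > alpha / m) {
    return(ss_result("NOT_SIGNIFICANT", SENTINEL_NOT_SIGNIFICANT,
                     stage1_p = stage1_p, n_snps = n, m = m, alpha = alpha,
                     label = label))
  }
  if (n < min_snps) {
    return(ss_result("FAILED", SENTINEL_FAILED, stage1_p = stage1_p, n_snps = n,
                     m = m, alpha = alpha, label = label,
                     reason = "insufficient number of SNPs"))
  }
  w <- ss_weights(prim$p[h$primary_idx])
  delta <- estimate_noncentrality(T)
  st2 <- ss_stage2_test(T, w, r_sub, delta)
  if (!st2$ok) {
    return(ss_result("FAILED", SENTINEL_FAILED, stage1_p = stage1_p, n_snps = n,
                     m = m, alpha = alpha, label = label, reason = st2$reason))
  }
  ss_result("OK", NA_integer_, stage1_p = stage1_p, ss_z = st2$z,
            ss_p = max(st2$p, 1e-300), n_snps = n, m = m, alpha = alpha,
            label = label)
}

#' @export
print.ss_result <- function(x, ...) {
  cat("Simple Sum colocalization test",
      if (!is.null(x$label)) sprintf(" [%s]", x$label) else "", "\n", sep = "")
  cat(sprintf("  status: %s", x$status))
  if (!is.na(x$sentinel)) cat(sprintf(" (sentinel %d: %s)", x$sentinel, x$reason))
  cat("\n")
  if (!is.na(x$stage1_p)) {
    cat(sprintf("  stage-1 p = %.3g (gate alpha/m = %.3g/%d = %.3g)\n",
                x$stage1_p, x$alpha, x$m, x$alpha / x$m))
  }
  if (x$status == "OK") {
    cat(sprintf("  SS z = %.3f, p = %.3g, -log10 p = %.3f, n = %d SNPs\n",
                x$ss_z, x$ss_p, x$neglog10_ss_p, x$n_snps))
  } else if (x$n_snps > 0) {
    cat(sprintf("  n = %d SNPs\n", x$n_snps))
  }
  invisible(x)
}
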