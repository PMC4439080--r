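#' Tajima constants for sample size n
#'
#' The harmonic-number constants a1, a2 and the derived b1, b2, c1, c2,
#' e1, e2 entering Watterson's theta and the normalisation of Tajima's D:
#' a1 = sum(1/i), a2 = sum(1/i^2) over i = 1..n-1; b1 = (n+1)/(3(n-1));
#' b2 = 2(n^2+n+3)/(9n(n-1)); c1 = b1 - 1/a1;
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2; e1 = c1/a1; e2 = c2/(a1^2 + a2).
#'
#' @param n Number of sequences (>= 2; e1/e2 meaningful for n >= 4).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

retained_columns <- function(aln) {
  # complete-deletion retention: drop columns with any gap or N, matching
  # the "excluding indels" convention of the summary-statistics table
  keep <- !apply(aln$matrix == "-" | aln$matrix == "N", 2, any)
  aln$matrix[, keep, drop = FALSE]
}

#' Number of segregating sites
#'
#' Counts alignment columns with at least two distinct symbols after
#' excluding every column carrying a gap or N in any sequence (indels and
#' missing data are excluded, as in the standard summary-statistics
#' convention).
#'
#' @param aln An `aligned_seqs` object with >= 2 sequences.
#' @return Integer S.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "aligned_seqs"))
  if (length(aln$ids) < 2L) stop("need at least 2 sequences")
  m <- retained_columns(aln)
  if (ncol(m) == 0L) return(0L)
  sum(apply(m, 2, function(col) length(unique(col)) > 1L))
}

#' Average number of pairwise differences (K)
#'
#' Mean Hamming distance over all n(n-1)/2 sequence pairs on the retained
#' (complete-deletion) columns.  Nucleotide diversity per site is pi = K/L
#' with L the number of retained columns.
#'
#' @param aln An `aligned_seqs` object with >= 2 sequences.
#' @return Numeric K.
#' @export
pairwise_K <- function(aln) {
  stopifnot(inherits(aln, "aligned_seqs"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  m <- retained_columns(aln)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

#' Haplotype (gene) diversity
#'
#' Hd = n/(n-1) * (1 - sum p_i^2) with p_i the haplotype frequencies.
#'
#' @param table A `haplotype_table`, or an integer vector of haplotype
#'   counts.
#' @param n Total sample count; defaults to the sum of counts.
#' @return Hd in [0, 1].
#' @export
haplotype_diversity <- function(table, n = NULL) {
  counts <- if (inherits(table, "haplotype_table")) table$haplotypes$count
            else as.numeric(table)
  if (is.null(n)) n <- sum(counts)
  if (n < 2) stop("need n >= 2")
  if (sum(counts) != n) stop("counts do not sum to n")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Watterson's theta per sequence
#'
#' theta_W = S / a1 with a1 = sum_{i=1}^{n-1} 1/i.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @return theta per sequence (divide by L for the per-site value).
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("need n >= 2")
  stopifnot(S >= 0)
  S / tajima_constants(n)$a1
}

#' Tajima's D
#'
#' D = (K - S/a1) / sqrt(e1 S + e2 S (S - 1)), the standardized difference
#' between the pairwise-difference and segregating-sites estimators of
#' theta.  Negative values indicate an excess of rare variants, as after a
#' population expansion.
#'
#' @param n Number of sequences (>= 4).
#' @param S Segregating sites (>= 1; D undefined at S = 0).
#' @param K Mean pairwise differences.
#' @return Numeric D (NA with a warning when S = 0).
#' @export
tajimas_D <- function(n, S, K) {
  stopifnot(n >= 4)
  if (S == 0) {
    warning("Tajima's D undefined for S = 0")
    return(NA_real_)
  }
  tc <- tajima_constants(n)
  (K - S / tc$a1) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
}

#' Two-sided significance of Tajima's D (beta approximation)
#'
#' Under neutrality D is approximately distributed as a scaled beta on the
#' interval [Dmin, Dmax] with mean 0 and variance 1, where
#' Dmin = (2/n - 1/a1)/sqrt(e2) and Dmax = ((n+1)/(2n) - 1/a1)/sqrt(e2)
#' (the extremes attained by all-singleton and maximally balanced
#' configurations).  The two-sided p is twice the smaller tail.
#'
#' @param D Observed Tajima's D.
#' @param n Number of sequences (>= 4).
#' @param alpha Significance level (default 0.05).
#' @return List with `p_value`, `significant`, `Dmin`, `Dmax`.
#' @export
tajima_significance <- function(D, n, alpha = 0.05) {
  stopifnot(n >= 4)
  if (is.na(D)) return(list(p_value = NA_real_, significant = FALSE,
                            Dmin = NA_real_, Dmax = NA_real_))
  tc <- tajima_constants(n)
  a <- (2 / n - 1 / tc$a1) / sqrt(tc$e2)
  b <- ((n + 1) / (2 * n) - 1 / tc$a1) / sqrt(tc$e2)
  ## beta with mean 0, variance 1 on [a, b]:
  ## f(D) prop. to (b - D)^(alpha0-1) (D - a)^(beta0-1)
  alpha0 <- -(1 + a * b) * b / (b - a)
  beta0 <- (1 + a * b) * a / (b - a)
  x <- min(max((D - a) / (b - a), 0), 1)
  lo <- stats::pbeta(x, beta0, alpha0)
  p <- 2 * min(lo, 1 - lo)
  list(p_value = p, significant = p < alpha, Dmin = a, Dmax = b)
}

#' Heterochrony correction of nucleotide diversity
#'
#' Sequences sampled at different ages accumulate extra differences along
#' the time gap between sampling events, inflating pi relative to a
#' single-time sample.  With mean pairwise age difference
#' Dt = 2/(n(n-1)) sum_{i<j} |t_i - t_j| (years) and a per-site mutation
#' rate r (per year), the expected inflation is c = r * Dt per site, giving
#' the corrected value pi_hmu = pi - c and a relative bias
#' (pi - pi_hmu)/pi_hmu * 100 (%).
#'
#' The rate is supplied as percent per million years (e.g. 43 or 53).  By
#' default it is interpreted per site per calendar year
#' (`per = "site_year"`).  Alternatives: `"fragment_year"` divides by `L`
#' so the quoted rate refers to the whole fragment; `"site_generation"`
#' treats the quoted rate as per generation and converts ages to
#' generations via `generation_length`.
#'
#' @param pi Nucleotide diversity per site.
#' @param ages Numeric vector of sample ages (years BP), one per sequence.
#' @param rate_pct_per_myr Mutation rate in percent per million years.
#' @param generation_length Generation length in years (used only under the
#'   per-generation interpretation; 5 and 7 are conventional bounds for
#'   cattle).
#' @param L Number of analyzed sites (used under the per-fragment
#'   interpretation).
#' @param per Rate interpretation; see Details.
#' @return List with `pi_hmu`, `bias_pct`, `delta_t` (mean pairwise age
#'   difference, years) and `inflation` (the subtracted per-site term).
#' @export
heterochrony_correction <- function(pi, ages, rate_pct_per_myr,
                                    generation_length = 7, L = NULL,
                                    per = c("site_year", "fragment_year",
                                            "site_generation")) {
  per <- match.arg(per)
  stopifnot(pi >= 0, all(ages >= 0), rate_pct_per_myr > 0,
            generation_length > 0)
  n <- length(ages)
  if (n < 2) stop("need ages for at least 2 samples")
  dt <- mean(stats::dist(matrix(ages, ncol = 1), method = "manhattan"))
  r_per_year <- rate_pct_per_myr / 100 / 1e6
  c_site <- switch(per,
    site_year = r_per_year * dt,
    fragment_year = {
      if (is.null(L)) stop("L required for the per-fragment interpretation")
      r_per_year * dt / L
    },
    site_generation = r_per_year * (dt / generation_length))
  pi_hmu <- pi - c_site
  if (pi_hmu < 0) {
    warning("corrected diversity negative; clamped to 0")
    pi_hmu <- 0
  }
  bias <- if (pi_hmu > 0) (pi - pi_hmu) / pi_hmu * 100
          else if (pi == 0) 0 else Inf
  list(pi_hmu = pi_hmu, bias_pct = bias, delta_t = dt, inflation = c_site)
}

#' Full diversity summary for one cohort
#'
#' Computes the per-cohort summary row: N, S, h, Hd, K, theta_W (per
#' sequence), Tajima's D with its beta-approximation p, pi = K/L, and (when
#' ages are supplied) the heterochrony-corrected pi_hmu and bias.
#'
#' @param aln An `aligned_seqs` object for the cohort.
#' @param ages Optional numeric vector of ages (years BP) matching
#'   `aln$ids`.
#' @param rate_pct_per_myr,generation_length,per Passed to
#'   [heterochrony_correction()].
#' @return An object of class `diversity_estimates` (a one-row data.frame).
#' @export
diversity_estimates <- function(aln, ages = NULL, rate_pct_per_myr = 43,
                                generation_length = 7, per = "site_year") {
  n <- length(aln$ids)
  S <- segregating_sites(aln)
  K <- pairwise_K(aln)
  ht <- collapse_haplotypes(aln)
  L <- ncol(retained_columns(aln))
  Hd <- haplotype_diversity(ht, n)
  theta <- watterson_theta(S, n)
  D <- if (n >= 4 && S >= 1) tajimas_D(n, S, K) else NA_real_
  sig <- if (!is.na(D)) tajima_significance(D, n)
         else list(p_value = NA_real_, significant = FALSE)
  pi <- K / L
  out <- data.frame(N = n, S = S, h = nrow(ht$haplotypes), Hd = Hd, K = K,
                    theta_s = theta, D = D, D_p = sig$p_value,
                    D_significant = sig$significant, pi = pi,
                    L = L, pi_hmu = NA_real_, bias_pct = NA_real_)
  if (!is.null(ages)) {
    stopifnot(length(ages) == n)
    hc <- heterochrony_correction(pi, ages, rate_pct_per_myr,
                                  generation_length, L = L, per = per)
    out$pi_hmu <- hc$pi_hmu
    out$bias_pct <- hc$bias_pct
  }
  class(out) <- c("diversity_estimates", "data.frame")
  out
}

#' @export
print.diversity_estimates <- function(x, digits = 4, ...) {
  cat("Cohort diversity estimates:\n")
  y <- as.data.frame(x)
  y$D <- ifelse(!is.na(y$D) & y$D_significant, paste0(round(y$D, 3), "*"),
                as.character(round(y$D, 3)))
  print(format(y[c("N", "S", "h", "Hd", "K", "theta_s", "D", "pi",
                   "pi_hmu", "bias_pct")], digits = digits),
        row.names = FALSE)
  invisible(x)
}

#' Write a per-cohort diversity table to TSV
#' @param rows A data.frame made by rbinding `diversity_estimates` rows.
#' @param path Output path.
#' @export
write_diversity_table <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
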