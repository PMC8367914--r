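#' Two-tailed paired t test on per-participant differences
#'
#' @param diff Numeric vector of per-participant condition differences
#'   (n >= 2, non-degenerate).
#' @return A list with `t`, `df` (= n - 1), `p` (two-tailed), `n`.
#' @export
paired_t <- function(diff) {
  n <- length(diff)
  if (n < 2) stop("need at least two participants", call. = FALSE)
  if (stats::sd(diff) == 0) {
    stop("zero variance of differences: t statistic undefined",
         call. = FALSE)
  }
  res <- stats::t.test(diff, alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, n = n)
}

#' Exact small-sample bias-correction factor J(a)
#'
#' `J(a) = Gamma(a/2) / (sqrt(a/2) * Gamma((a-1)/2))`, evaluated via
#' log-gamma. This is the exact correction, not the common
#' `1 - 3/(4a - 1)` approximation. `J` increases monotonically toward 1.
#'
#' @param a Degrees of freedom (here `n - 1`).
#' @return The correction factor, in (0, 1).
#' @export
j_correction <- function(a) {
  if (any(a <= 1)) stop("J(a) requires a > 1", call. = FALSE)
  exp(lgamma(a / 2) - lgamma((a - 1) / 2)) / sqrt(a / 2)
}

#' Hedge's g for paired differences
#'
#' `g = J(n - 1) * mean(diff) / sd(diff)` with the exact gamma-ratio
#' correction [j_correction()]. Signed: positive when the mean difference
#' is positive. Algebraically, `|g| = J(n - 1) * |t| / sqrt(n)`.
#'
#' @inheritParams paired_t
#' @return Signed effect size g.
#' @export
hedges_g <- function(diff) {
  n <- length(diff)
  if (n < 2) stop("need at least two participants", call. = FALSE)
  s <- stats::sd(diff)
  if (s == 0) stop("zero variance of differences: g undefined",
                   call. = FALSE)
  j_correction(n - 1) * mean(diff) / s
}

#' @rdname hedges_g
#' @param t Paired t statistic.
#' @param n Number of participants.
#' @return `hedges_g_from_t()` converts a printed paired t statistic to g
#'   via the identity `g = J(n - 1) * t / sqrt(n)`.
#' @export
hedges_g_from_t <- function(t, n) {
  j_correction(n - 1) * t / sqrt(n)
}

#' Bias-corrected and accelerated bootstrap interval for Hedge's g
#'
#' Participant-level resampling with the BCa correction: the bias term
#' `z0` comes from the fraction of bootstrap replicates below the point
#' estimate, the acceleration from the jackknife skewness. Degenerate
#' resamples (zero variance) are skipped and counted.
#'
#' @param diff Per-participant differences (n >= 8 recommended).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param conf Confidence level (default 0.95).
#' @return A list with `lo`, `hi`, `g` (point estimate), `n_boot`,
#'   `n_skipped`.
#' @export
bootstrap_ci_g <- function(diff, n_boot = 10000, seed = NULL, conf = 0.95) {
  n <- length(diff)
  g_hat <- hedges_g(diff) # errors on degenerate input
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  reps <- apply(idx, 1, function(i) {
    d <- diff[i]
    if (stats::sd(d) == 0) return(NA_real_)
    hedges_g(d)
  })
  skipped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  if (length(reps) < 100) {
    stop("too few non-degenerate bootstrap replicates", call. = FALSE)
  }
  z0 <- stats::qnorm(mean(reps < g_hat))
  jack <- vapply(seq_len(n), function(i) hedges_g(diff[-i]), numeric(1))
  dj <- mean(jack) - jack
  denom <- 6 * sum(dj^2)^1.5
  acc <- if (denom == 0) 0 else sum(dj^3) / denom
  alpha <- (1 - conf) / 2
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
  qs <- stats::quantile(reps, probs = c(a1, a2), names = FALSE, type = 6)
  list(lo = qs[1], hi = qs[2], g = g_hat, n_boot = n_boot,
       n_skipped = skipped)
}

#' AIC-based log Bayes factors across candidate measures
#'
#' Compares candidate measures (e.g. scanpath length over different
#' windows) of the same participants. Each candidate's participant-by-
#' condition values are z-scored across all its values, paired differences
#' are formed, and the AIC of a two-parameter Gaussian model (MLE mean and
#' variance) of those standardized differences is computed; every
#' candidate thus has the same parameter count, making the AIC-based log
#' Bayes factor `LBF = (AIC - AIC_ref) / 2` equal to the BIC-based one.
#' Smaller LBF is better; the reference scores exactly 0.
#'
#' @param candidates Named list of tibbles, each with columns
#'   `participant`, `condition`, and the value column; all candidates must
#'   share the same participant set.
#' @param reference Name of the reference candidate.
#' @param value Name of the value column (default `"value"`).
#' @return A tibble `candidate`, `aic`, `lbf` with `lbf` 0 at the
#'   reference.
#' @export
aic_lbf <- function(candidates, reference, value = "value") {
  stopifnot(is.list(candidates), !is.null(names(candidates)),
            reference %in% names(candidates))
  part_sets <- lapply(candidates, function(m) sort(unique(m$participant)))
  if (length(unique(part_sets)) != 1) {
    stop("all candidates must share the same participant set",
         call. = FALSE)
  }
  aic <- vapply(candidates, function(m) {
    v <- m[[value]]
    z <- (v - mean(v)) / stats::sd(v)
    m$z <- z
    d <- paired_differences(m, value = "z")
    mu <- mean(d)
    s2 <- mean((d - mu)^2) # MLE variance
    ll <- sum(stats::dnorm(d, mu, sqrt(s2), log = TRUE))
    2 * 2 - 2 * ll
  }, numeric(1))
  lbf <- unname(aic - aic[[reference]]) / 2
  tibble::tibble(candidate = names(candidates), aic = unname(aic),
                 lbf = lbf)
}

#' Sign-based classification accuracy of a conditioning measure
#'
#' A participant is classified correctly when their CS+ minus CS-
#' difference shares the sign of the group mean difference. Differences of
#' exactly zero count against accuracy (conservative tie rule).
#'
#' @inheritParams paired_t
#' @return Proportion in `[0, 1]`.
#' @export
classification_accuracy <- function(diff) {
  m <- mean(diff)
  if (m == 0) stop("group mean difference is zero: sign undefined",
                   call. = FALSE)
  mean(sign(diff) == sign(m) & diff != 0)
}

#' Consecutive-pair split-half reliability
#'
#' Splits each participant's trials, per condition, into pairs of
#' consecutive trials (assuming the latent CS-US association is similar
#' within a pair, even while learning drifts across the session). One
#' trial of each pair is randomly allocated to set 1 and the other to set
#' 2; trial-set means are formed, the CS+ minus CS- difference is computed
#' per set and participant, and the two sets' differences are correlated
#' across participants. The procedure is repeated `n_rep` times and the
#' mean correlation returned. An odd trailing trial in a condition is
#' dropped.
#'
#' Note the interpretation limits: if all participants learn identically
#' (no true between-participant variance), the expected correlation is
#' zero no matter how small the measurement noise.
#'
#' @param trialwise Tibble with columns `participant`, `condition`,
#'   `trial_id` (ordering within condition), and a value column; only the
#'   analyzed conditions are used.
#' @param n_rep Number of random allocations (default 5000).
#' @param seed Integer seed.
#' @param value Name of the value column (default `"length_deg"`).
#' @return A list with `mean_r`, `n_rep`, and the vector `r` of
#'   per-repetition correlations.
#' @export
split_half_reliability <- function(trialwise, n_rep = 5000, seed = NULL,
                                   value = "length_deg") {
  tw <- trialwise[trialwise$condition %in% analyzed_conditions(), ,
                  drop = FALSE]
  participants <- unique(tw$participant)
  if (length(participants) < 3) {
    stop("need at least three participants for a split-half correlation",
         call. = FALSE)
  }
  # pre-index pairs of consecutive same-condition trials per participant
  pairs <- list()
  for (p in participants) {
    for (cond in analyzed_conditions()) {
      rows <- which(tw$participant == p & tw$condition == cond)
      rows <- rows[order(tw$trial_id[rows])]
      npair <- floor(length(rows) / 2)
      if (npair < 1) {
        stop("participant ", p, " has fewer than two '", cond, "' trials",
             call. = FALSE)
      }
      pairs[[paste(p, cond)]] <- list(
        p = p, cond = cond,
        first = rows[seq(1, 2 * npair, by = 2)],
        second = rows[seq(2, 2 * npair, by = 2)])
    }
  }
  vals <- tw[[value]]
  info_p <- vapply(pairs, function(pr) as.character(pr$p), character(1))
  info_cond <- vapply(pairs, function(pr) pr$cond, character(1))
  plus_idx <- vapply(as.character(participants), function(p)
    which(info_p == p & info_cond == "CSplus_USminus"), integer(1))
  minus_idx <- vapply(as.character(participants), function(p)
    which(info_p == p & info_cond == "CSminus"), integer(1))
  if (!is.null(seed)) set.seed(seed)
  rs <- vapply(seq_len(n_rep), function(rep) {
    m <- t(vapply(pairs, function(pr) {
      flip <- stats::runif(length(pr$first)) < 0.5
      set1 <- ifelse(flip, pr$first, pr$second)
      set2 <- ifelse(flip, pr$second, pr$first)
      c(mean(vals[set1]), mean(vals[set2]))
    }, numeric(2)))
    d1 <- m[plus_idx, 1] - m[minus_idx, 1]
    d2 <- m[plus_idx, 2] - m[minus_idx, 2]
    stats::cor(d1, d2)
  }, numeric(1))
  list(mean_r = mean(rs), n_rep = n_rep, r = rs)
}

#' Correlations between conditioning measures
#'
#' Pearson correlations, across participants, of the per-participant
#' CS+ minus CS- differences of several measures.
#'
#' @param diffs Named list of equal-length per-participant difference
#'   vectors (aligned participants).
#' @return Correlation matrix.
#' @export
measure_correlations <- function(diffs) {
  stats::cor(do.call(cbind, diffs))
}

#' Full contrast summary for one measure
#'
#' Bundles the statistics reported per measure: paired t, two-tailed p,
#' exact-J Hedge's g, BCa bootstrap CI, sign-based classification
#' accuracy, and effect direction.
#'
#' @inheritParams bootstrap_ci_g
#' @return A one-row tibble `n`, `t`, `df`, `p`, `g`, `ci_lo`, `ci_hi`,
#'   `accuracy`, `direction`.
#' @export
contrast_summary <- function(diff, n_boot = 2000, seed = NULL) {
  tt <- paired_t(diff)
  ci <- bootstrap_ci_g(diff, n_boot = n_boot, seed = seed)
  tibble::tibble(
    n = tt$n, t = tt$t, df = tt$df, p = tt$p, g = ci$g,
    ci_lo = ci$lo, ci_hi = ci$hi,
    accuracy = classification_accuracy(diff),
    direction = sign(mean(diff)))
}
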