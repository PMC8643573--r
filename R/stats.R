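# Group-level statistics: one-way ANOVA with Tukey post hoc on feature
# tables, bootstrap within-group significance maps, and permutation
# between-group difference maps.

#' One-way ANOVA with gated Tukey post hoc
#'
#' Classical between/within sum-of-squares decomposition (via
#' \code{stats::aov}) across the groups of a named list of value vectors.
#' Tukey HSD adjusted p-values are computed only when the omnibus p is at
#' or below \code{alpha}, mirroring the gated post-hoc protocol.
#'
#' @param valuesByGroup named list, one numeric vector per group (>= 2
#'   groups of >= 2 values each).
#' @param alpha gate for the post hoc (default 0.05).
#' @return list of class \code{AnovaResult}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{group_means}, \code{tukey}
#'   (data.frame groupA, groupB, mean_diff, adjusted_p; empty when not
#'   gated).
#' @export
anovaOneway <- function(valuesByGroup, alpha = 0.05) {
  if (length(valuesByGroup) < 2) stop("need >= 2 groups")
  if (any(vapply(valuesByGroup, length, 1L) < 2))
    stop("every group needs >= 2 values")
  df <- data.frame(
    value = unlist(valuesByGroup, use.names = FALSE),
    group = factor(rep(names(valuesByGroup),
                       vapply(valuesByGroup, length, 1L))))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  Fval <- tab["group", "F value"]
  p <- tab["group", "Pr(>F)"]
  if (is.na(Fval)) { Fval <- 0; p <- 1 }     # zero residual variance
  tukey <- data.frame(groupA = character(), groupB = character(),
                      mean_diff = numeric(), adjusted_p = numeric())
  if (!is.na(p) && p <= alpha) {
    th <- stats::TukeyHSD(fit)$group
    pair <- strsplit(rownames(th), "-", fixed = TRUE)
    tukey <- data.frame(
      groupA = vapply(pair, `[`, "", 1), groupB = vapply(pair, `[`, "", 2),
      mean_diff = th[, "diff"], adjusted_p = th[, "p adj"],
      row.names = NULL)
  }
  out <- list(F = Fval, df_between = tab["group", "Df"],
              df_within = tab["Residuals", "Df"], p = p,
              group_means = vapply(valuesByGroup, mean, 0),
              tukey = tukey)
  class(out) <- "AnovaResult"
  out
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("Group means:\n")
  print(round(x$group_means, 4))
  if (nrow(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

bootErd <- function(Xmat, counts, n, basMask, nf) {
  P <- matrix((Xmat %*% counts) / n, nrow = nf)
  B <- rowSums(P * basMask) / rowSums(basMask)
  100 * (P - B) / B
}

#' Bootstrap significance mask of a group ERD map
#'
#' Resamples trials with replacement \code{nBoot} times, recomputing the
#' group ERD map (trial-average then baseline-normalize) for each
#' resample, and marks a time-frequency pixel significant when the
#' two-sided bootstrap confidence interval at level \code{alpha} excludes
#' zero. The default interval is BCa (bias-corrected and accelerated, with
#' an analytic leave-one-out jackknife for the acceleration), which
#' corrects the small-sample skew of power averages that makes the plain
#' percentile interval run anti-conservative; \code{ciType = "percentile"}
#' selects the uncorrected construction. When the trial maps carry an
#' edge-validity mask, pixels inside the per-frequency edge margin are
#' never marked significant: power there is attenuated by the epoch
#' boundary, not by the brain. Deterministic under a fixed seed.
#'
#' @param maps list of \linkS4class{TFRMap}s or array freqs x times x
#'   trials (>= 10 trials).
#' @param times time axis (taken from the first map when a list).
#' @param baselineWindow baseline interval (s).
#' @param alpha significance level (default 0.05).
#' @param nBoot bootstrap replicates (>= 200; default 1000).
#' @param seed integer seed.
#' @param ciType "bca" (default) or "percentile".
#' @return an \linkS4class{ERDMap} with the observed map and the boolean
#'   \code{significanceMask}.
#' @export
bootstrapSignificance <- function(maps, times = NULL,
                                  baselineWindow = c(-4, -2), alpha = 0.05,
                                  nBoot = 1000, seed = 1,
                                  ciType = c("bca", "percentile")) {
  ciType <- match.arg(ciType)
  if (!is.array(maps) && is.null(times)) times <- tfrTimes(maps[[1]])
  arr <- powerArray(maps)
  nf <- dim(arr)[1]; nt <- dim(arr)[2]; n <- dim(arr)[3]
  if (n < 10) stop("need >= 10 trials for the bootstrap")
  if (nBoot < 200) stop("nBoot must be >= 200")
  edgeValid <- if (is.array(maps)) NULL else maps[[1]]@edgeValid
  basMask <- baselineMask(times, baselineWindow, edgeValid, freqsN = nf)
  freqs <- if (is.array(maps)) seq_len(nf) else tfrFreqs(maps[[1]])
  channel <- if (is.array(maps)) "" else maps[[1]]@channel

  npx <- nf * nt
  Xmat <- matrix(arr, npx, n)
  obs <- erdFromMean(matrix(rowMeans(Xmat), nf, nt), basMask)
  set.seed(seed)
  boots <- matrix(0, npx, nBoot)
  for (b in seq_len(nBoot)) {
    counts <- tabulate(sample.int(n, n, replace = TRUE), n)
    boots[, b] <- bootErd(Xmat, counts, n, basMask, nf)
  }
  if (ciType == "percentile") {
    a1 <- rep(alpha / 2, npx); a2 <- rep(1 - alpha / 2, npx)
  } else {
    obsv <- as.numeric(obs)
    z0 <- stats::qnorm(pmin(pmax(rowMeans(boots < obsv), 1 / (2 * nBoot)),
                            1 - 1 / (2 * nBoot)))
    jack <- matrix(0, npx, n)
    ones <- rep(1, n)
    for (i in seq_len(n)) {
      cnt <- ones; cnt[i] <- 0
      jack[, i] <- bootErd(Xmat, cnt, n - 1, basMask, nf)
    }
    d <- rowMeans(jack) - jack
    acc <- rowSums(d^3) / (6 * pmax(rowSums(d^2), 1e-300)^1.5)
    zl <- stats::qnorm(alpha / 2); zu <- stats::qnorm(1 - alpha / 2)
    a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
    a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
  }
  lo <- hi <- numeric(npx)
  for (px in seq_len(npx)) {
    q <- stats::quantile(boots[px, ], c(a1[px], a2[px]), names = FALSE)
    lo[px] <- q[1]; hi[px] <- q[2]
  }
  mask <- matrix(lo > 0 | hi < 0, nf, nt)
  if (!is.null(edgeValid)) mask <- mask & edgeValid
  new("ERDMap", channel = channel, freqs = as.numeric(freqs),
      times = times, erd = obs,
      baselineWindow = as.numeric(baselineWindow),
      significanceMask = mask, nTrials = n)
}

#' Permutation test on a between-group ERD difference map
#'
#' Observed difference of the two group ERD maps (A minus B), with a
#' pointwise null built by shuffling trial-to-group labels \code{nPerm}
#' times. Two-sided p per pixel = (1 + #(|perm diff| >= |observed|)) /
#' (nPerm + 1); the mask marks p <= alpha. No correction beyond the
#' pointwise level is applied by default; \code{maxStat = TRUE} switches to
#' a max-statistic familywise threshold.
#'
#' @param mapsA,mapsB lists of \linkS4class{TFRMap}s or arrays freqs x
#'   times x trials (>= 10 trials each).
#' @param times time axis (from the first A map when lists).
#' @param baselineWindow baseline interval (s).
#' @param alpha significance level.
#' @param nPerm permutations (>= 500; default 1000).
#' @param seed integer seed.
#' @param maxStat use the max-|diff| null for familywise control.
#' @return list of class \code{DiffMap}: \code{difference} (matrix),
#'   \code{p} (matrix), \code{mask}, \code{freqs}, \code{times},
#'   \code{erdA}, \code{erdB}.
#' @export
permutationDifference <- function(mapsA, mapsB, times = NULL,
                                  baselineWindow = c(-4, -2), alpha = 0.05,
                                  nPerm = 1000, seed = 1, maxStat = FALSE) {
  if (!is.array(mapsA) && is.null(times)) times <- tfrTimes(mapsA[[1]])
  arrA <- powerArray(mapsA); arrB <- powerArray(mapsB)
  nA <- dim(arrA)[3]; nB <- dim(arrB)[3]
  if (nA < 10 || nB < 10) stop("need >= 10 trials per group")
  if (nPerm < 500) stop("nPerm must be >= 500")
  nf <- dim(arrA)[1]; nt <- dim(arrA)[2]
  edgeValid <- if (is.array(mapsA)) NULL else mapsA[[1]]@edgeValid
  basMask <- baselineMask(times, baselineWindow, edgeValid, freqsN = nf)
  freqs <- if (is.array(mapsA)) seq_len(nf) else tfrFreqs(mapsA[[1]])

  Xall <- cbind(matrix(arrA, nf * nt, nA), matrix(arrB, nf * nt, nB))
  n <- nA + nB
  erdOf <- function(sel) {
    a <- bootErd(Xall, as.numeric(sel), nA, basMask, nf)
    b <- bootErd(Xall, as.numeric(!sel), nB, basMask, nf)
    a - b
  }
  labels <- c(rep(TRUE, nA), rep(FALSE, nB))
  obs <- erdOf(labels)
  set.seed(seed)
  exceed <- matrix(0, nf, nt)
  maxNull <- numeric(nPerm)
  for (k in seq_len(nPerm)) {
    perm <- sample(labels)
    d <- erdOf(perm)
    exceed <- exceed + (abs(d) >= abs(obs))
    maxNull[k] <- max(abs(d))
  }
  p <- (1 + exceed) / (nPerm + 1)
  mask <- if (maxStat) {
    abs(obs) >= stats::quantile(maxNull, 1 - alpha, names = FALSE)
  } else p <= alpha
  if (!is.null(edgeValid)) mask <- mask & edgeValid
  out <- list(difference = obs, p = p, mask = mask,
              freqs = as.numeric(freqs), times = times,
              erdA = bootErd(Xall, as.numeric(labels), nA, basMask, nf),
              erdB = bootErd(Xall, as.numeric(!labels), nB, basMask, nf),
              alpha = alpha, nPerm = nPerm)
  class(out) <- "DiffMap"
  out
}

#' @export
print.DiffMap <- function(x, ...) {
  cat(sprintf("DiffMap: %d freqs x %d times, %.1f%% significant (alpha %g, %d perms)\n",
              nrow(x$difference), ncol(x$difference),
              100 * mean(x$mask), x$alpha, x$nPerm))
  invisible(x)
}

#' Group summary table of MRCP features
#'
#' Per group and feature: n, mean, SD, plus the omnibus ANOVA p-value and
#' Tukey-significant pair markers. The unit of analysis is the single
#' non-outlier trial pooled across subjects (set \code{bySubject = TRUE}
#' to aggregate to subject means first).
#'
#' @param features data.frame from [mrcpFeatures()] (stacked across
#'   subjects), with a \code{group} column.
#' @param featureCols feature columns to summarize.
#' @param alpha post-hoc gate.
#' @param bySubject aggregate trials to subject means before testing.
#' @return list with \code{summary} (data.frame) and \code{anova} (named
#'   list of \code{AnovaResult}).
#' @export
featureGroupTable <- function(features,
                              featureCols = c("peak_negativity_uv",
                                              "peak_time_ms", "ns1_uv_per_s",
                                              "ns2_uv_per_s",
                                              "rebound_uv_per_s",
                                              "emg_peak_uv",
                                              "emg_peak_time_ms",
                                              "latency_mrcp_emg_ms"),
                              alpha = 0.05, bySubject = FALSE) {
  dat <- features[!features$outlier, , drop = FALSE]
  rows <- list(); tests <- list()
  for (fc in featureCols) {
    if (!fc %in% names(dat)) next
    d <- dat[is.finite(dat[[fc]]), c("subject_id", "group", fc)]
    if (bySubject)
      d <- stats::aggregate(d[[fc]],
                            by = list(subject_id = d$subject_id,
                                      group = d$group),
                            FUN = mean) |>
        stats::setNames(c("subject_id", "group", fc))
    vals <- split(d[[fc]], d$group)
    vals <- vals[vapply(vals, length, 1L) > 0]
    res <- if (length(vals) >= 2 && all(vapply(vals, length, 1L) >= 2))
      anovaOneway(vals, alpha = alpha) else NULL
    tests[[fc]] <- res
    for (g in names(vals)) {
      marker <- ""
      if (!is.null(res) && nrow(res$tukey)) {
        sig <- res$tukey[res$tukey$adjusted_p <= alpha, , drop = FALSE]
        inPair <- sig$groupA == g | sig$groupB == g
        if (any(inPair)) marker <- "*"
      }
      rows[[length(rows) + 1]] <- data.frame(
        feature = fc, group = g, n = length(vals[[g]]),
        mean = mean(vals[[g]]),
        sd = if (length(vals[[g]]) > 1) stats::sd(vals[[g]]) else 0,
        anova_p = if (is.null(res)) NA_real_ else res$p,
        tukey_sig = marker)
    }
  }
  list(summary = do.call(rbind, rows), anova = tests)
}
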