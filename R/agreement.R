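.mtKey <- function(df)
  paste(df$participant_id, df$artery, ifelse(is.na(df$side), "", df$side),
        sep = "\r")

# pair manual and auto tables on (participant, artery, side); error when a
# key exists in one table but has no row at all in the other (distinct from
# a row recorded as missing)
.pairTables <- function(manual, auto) {
  manual <- measurementTable(manual)
  auto <- measurementTable(auto)
  km <- .mtKey(manual)
  ka <- .mtKey(auto)
  if (anyDuplicated(km) || anyDuplicated(ka))
    stop("tables must have one row per (participant, artery, side)")
  if (!setequal(km, ka))
    stop("tables do not share the same (participant, artery, side) keys; ",
         "absent rows are not the same as missing measurements")
  i <- match(km, ka)
  data.frame(participant_id = manual$participant_id, artery = manual$artery,
             side = manual$side, manual = manual$diameter_mm,
             auto = auto$diameter_mm[i], stringsAsFactors = FALSE)
}

#' Detection confusion counts per artery
#'
#' For every shared (participant, artery, side) key: both measurements
#' present is a true positive, both missing a true negative, manual-only a
#' false negative and auto-only a false positive. The four counts always
#' partition the shared keys.
#'
#' @param manual,auto measurement tables sharing the same keys.
#' @return data.frame with one row per artery plus a pooled \code{"all"}
#'   row: \code{artery}, \code{tp}, \code{tn}, \code{fn}, \code{fp},
#'   \code{n}.
#' @export
classifyDetection <- function(manual, auto) {
  p <- .pairTables(manual, auto)
  cls <- ifelse(!is.na(p$manual) & !is.na(p$auto), "tp",
         ifelse(is.na(p$manual) & is.na(p$auto), "tn",
         ifelse(!is.na(p$manual), "fn", "fp")))
  one <- function(sub, name) {
    data.frame(artery = name,
               tp = sum(sub == "tp"), tn = sum(sub == "tn"),
               fn = sum(sub == "fn"), fp = sum(sub == "fp"),
               n = length(sub), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(unique(p$artery), function(a)
    one(cls[p$artery == a], a)), list(one(cls, "all"))))
  rownames(out) <- NULL
  out
}

#' Detection rates from confusion counts
#'
#' @param counts data.frame from \code{\link{classifyDetection}} (or any
#'   rows with tp/tn/fn/fp columns).
#' @return data.frame with \code{pct_tp_tn}, \code{pct_fn}, \code{pct_fp}
#'   (percentages summing to 100 per row).
#' @export
detectionRates <- function(counts) {
  n <- counts$tp + counts$tn + counts$fn + counts$fp
  if (any(n == 0)) stop("detection rates undefined for zero records")
  data.frame(artery = counts$artery,
             pct_tp_tn = 100 * (counts$tp + counts$tn) / n,
             pct_fn = 100 * counts$fn / n,
             pct_fp = 100 * counts$fp / n,
             stringsAsFactors = FALSE)
}

#' ROC points for artery presence detection
#'
#' Manual presence is the reference; the automated estimated diameter serves
#' as the presence score (missing scored 0). Thresholds sweep the observed
#' scores; a record is called present when its score >= threshold. The
#' returned curve starts at (0, 0) and ends at (1, 1) and is monotone
#' non-decreasing in both coordinates.
#'
#' @param manual,auto measurement tables sharing the same keys.
#' @return data.frame with columns \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
rocPoints <- function(manual, auto) {
  p <- .pairTables(manual, auto)
  ref <- !is.na(p$manual)
  score <- ifelse(is.na(p$auto), 0, p$auto)
  npos <- sum(ref)
  nneg <- sum(!ref)
  if (npos == 0 || nneg == 0)
    stop("reference must contain both present and missing records")
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  out <- do.call(rbind, lapply(thr, function(t) {
    call <- score >= t
    data.frame(threshold = t,
               fpr = sum(call & !ref) / nneg,
               tpr = sum(call & ref) / npos)
  }))
  rownames(out) <- NULL
  out
}

#' Area under an ROC curve (trapezoidal)
#' @param roc data.frame from \code{\link{rocPoints}}.
#' @return numeric(1) area.
#' @export
rocAuc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Paired differences (auto - manual) over true-positive records
#'
#' @param manual,auto measurement tables sharing the same keys.
#' @return data.frame of tp records with columns \code{participant_id},
#'   \code{artery}, \code{side}, \code{manual}, \code{auto}, \code{diff}
#'   (auto - manual, so overestimation is positive).
#' @export
diffTable <- function(manual, auto) {
  p <- .pairTables(manual, auto)
  p <- p[!is.na(p$manual) & !is.na(p$auto), , drop = FALSE]
  p$diff <- p$auto - p$manual
  rownames(p) <- NULL
  p
}

#' Percentage of differences within a threshold
#'
#' @param diffs numeric vector of paired differences (mm).
#' @param thr_mm positive threshold (mm).
#' @return 100 * #\{|d| <= thr\} / n, or \code{NA} when \code{diffs} is empty.
#' @export
withinThreshold <- function(diffs, thr_mm) {
  stopifnot(thr_mm > 0)
  diffs <- diffs[!is.na(diffs)]
  if (!length(diffs)) return(NA_real_)
  100 * sum(abs(diffs) <= thr_mm) / length(diffs)
}

# exact null distribution of the signed-rank statistic W+ for given ranks
# (average ranks allowed): P(W+ <= w) with each rank included w.p. 1/2;
# equals brute-force enumeration over all 2^n sign patterns
.signrankCdf <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))  # average ranks are half-integers
  probs <- c(1)                        # distribution over 2*W+, support 0..sum
  for (r in r2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) / 2 + shifted / 2
  }
  sum(probs[seq_len(min(length(probs), floor(2 * w + 1e-9) + 1))])
}

#' Wilcoxon signed-rank test of paired differences against a margin
#'
#' Tests whether paired absolute differences lie within a tolerance margin:
#' the signed-rank statistic is computed on \code{|d| - margin} (values
#' exactly equal to the margin are dropped). With
#' \code{direction = "less"} the alternative is that the differences are
#' within the margin (median |d| < margin) and the p-value is
#' P(W+ <= w_obs) under the null; \code{"greater"} tests the opposite
#' one-sided alternative. The null distribution is exact (full enumeration,
#' tie-aware, via a generating-function recursion) for n <= 25 and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param diffs paired differences (mm).
#' @param margin_mm tolerance margin (mm), e.g. 0.5 or 1.
#' @param direction \code{"less"} (default) or \code{"greater"}.
#' @return one-sided p-value.
#' @export
wilcoxonVsMargin <- function(diffs, margin_mm, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  x <- abs(diffs[!is.na(diffs)]) - margin_mm
  x <- x[x != 0]
  n <- length(x)
  if (n < 5) stop("need at least 5 non-tied differences, got ", n)
  r <- rank(abs(x))
  wpos <- sum(r[x > 0])
  if (n <= 25) {
    p_le <- .signrankCdf(r, wpos)
    p_ge <- 1 - .signrankCdf(r, wpos - 0.5)  # P(W+ >= w)
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48)
    p_le <- stats::pnorm((wpos + 0.5 - mu) / sg)
    p_ge <- stats::pnorm((wpos - 0.5 - mu) / sg, lower.tail = FALSE)
  }
  if (direction == "less") p_le else p_ge
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param pvals raw p-values.
#' @param m family size (>= length(pvals)).
#' @return adjusted p-values, min(1, p * m).
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= length(pvals))
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}

#' Spearman rank correlation with p-value
#'
#' Rank correlation using average ranks for ties. The p-value comes from an
#' exact permutation enumeration for n <= 10 and the t-approximation
#' otherwise (two-sided). Zero variance in either vector yields missing
#' results.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
spearmanCor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (n <= 10) {
    cpp_spearman_exact_p(rx, ry)
  } else {
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    if (!is.finite(tv)) 0 else 2 * stats::pt(-abs(tv), n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' OLS regression summary of manual on automated measurements
#'
#' Ordinary least squares with the manual measurement on the y-axis and the
#' automated estimate on the x-axis.
#'
#' @param manual_vals,auto_vals paired numeric vectors.
#' @return list with \code{slope}, \code{intercept}, \code{r2}, \code{rmse},
#'   \code{n}.
#' @export
linregSummary <- function(manual_vals, auto_vals) {
  ok <- !is.na(manual_vals) & !is.na(auto_vals)
  y <- manual_vals[ok]
  x <- auto_vals[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("zero variance in automated values")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
       rmse = sqrt(mean(res^2)),
       n = length(x))
}

#' Shapiro-Wilk normality test
#'
#' Royston's algorithm (as implemented in base R), valid for 3 <= n <= 5000;
#' constant input is an error (zero variance).
#'
#' @param diffs numeric sample.
#' @return list with \code{W} and \code{p}.
#' @export
shapiroWilk <- function(diffs) {
  x <- diffs[!is.na(diffs)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("zero variance sample")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Full method-agreement report
#'
#' Assembles, per artery and per resolution: detection counts, paired
#' difference summaries (mean, sd), percentages within the tolerance
#' margins, one-sided Wilcoxon signed-rank margin tests (raw and
#' Bonferroni-adjusted over the declared family), Spearman correlation,
#' OLS regression summary (manual on y, auto on x) and the Shapiro-Wilk
#' normality check of the differences.
#'
#' @param manual reference measurement table.
#' @param auto_by_resolution named list of automated measurement tables,
#'   one per voxel size.
#' @param margins tolerance margins in mm (default 0.5 and 1).
#' @param bonferroni_m family size for the Bonferroni adjustment; default
#'   #arteries x #resolutions x #margins.
#' @return data.frame, one row per artery x resolution, with attribute
#'   \code{"bonferroni_m"}.
#' @export
buildReport <- function(manual, auto_by_resolution, margins = c(0.5, 1),
                        bonferroni_m = NULL) {
  stopifnot(length(auto_by_resolution) >= 1)
  manual <- measurementTable(manual)
  arteries <- unique(manual$artery)
  if (is.null(bonferroni_m))
    bonferroni_m <- length(arteries) * length(auto_by_resolution) *
      length(margins)
  rows <- list()
  for (resname in names(auto_by_resolution)) {
    auto <- measurementTable(auto_by_resolution[[resname]])
    for (a in arteries) {
      msub <- manual[manual$artery == a, , drop = FALSE]
      asub <- auto[auto$artery == a, , drop = FALSE]
      dt <- diffTable(msub, asub)
      d <- dt$diff
      safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
      sp <- if (nrow(dt) >= 3) tryCatch(spearmanCor(dt$manual, dt$auto),
                                        error = function(e)
                                          list(rho = NA, p = NA))
            else list(rho = NA_real_, p = NA_real_)
      lr <- tryCatch(linregSummary(dt$manual, dt$auto),
                     error = function(e)
                       list(slope = NA, intercept = NA, r2 = NA, rmse = NA))
      row <- data.frame(
        artery = a, resolution = resname, n_pairs = length(d),
        mean_diff_mm = if (length(d)) mean(d) else NA_real_,
        sd_diff_mm = if (length(d) > 1) stats::sd(d) else NA_real_,
        pct_within_0.5 = withinThreshold(d, 0.5),
        pct_within_1.0 = withinThreshold(d, 1.0),
        wilcoxon_p_0.5 = safe(wilcoxonVsMargin(d, margins[1])),
        wilcoxon_p_1.0 = if (length(margins) > 1)
          safe(wilcoxonVsMargin(d, margins[2])) else NA_real_,
        bonferroni_m = bonferroni_m,
        spearman_rho = sp$rho, spearman_p = sp$p,
        slope = lr$slope, intercept = lr$intercept, r2 = lr$r2,
        rmse = lr$rmse,
        shapiro_p = safe(shapiroWilk(d)$p),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$wilcoxon_p_0.5_adj <- bonferroni(out$wilcoxon_p_0.5, m = bonferroni_m)
  out$wilcoxon_p_1.0_adj <- bonferroni(out$wilcoxon_p_1.0, m = bonferroni_m)
  rownames(out) <- NULL
  attr(out, "bonferroni_m") <- bonferroni_m
  out
}
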