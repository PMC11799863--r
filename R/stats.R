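#' Median and interquartile range
#'
#' @param values Non-empty numeric vector.
#' @param convention `"linear"` (type-7 interpolated quantiles, default) or
#'   `"hinges"` (Tukey hinges); the two agree when `n %% 4 == 1`.
#' @return A [quartile_spec()] with attribute `convention`.
#' @export
median_iqr <- function(values, convention = c("linear", "hinges")) {
  convention <- match.arg(convention)
  if (length(values) == 0) stop("empty input")
  if (convention == "linear") {
    q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  } else {
    f <- fivenum(values)
    q <- f[2:4]
  }
  out <- quartile_spec(q[2], q[1], q[3])
  attr(out, "convention") <- convention
  out
}

#' Exact (enumerated) Mann-Whitney U test
#'
#' Computes U from rank sums (midranks under ties).  When there are no
#' ties and `choose(na + nb, na)` does not exceed `enum_limit`, the
#' two-sided p-value is obtained by full enumeration of all group
#' labelings of the pooled sample; otherwise the normal approximation with
#' tie correction and continuity correction is used.  The two-sided p is
#' `min(1, 2 min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b Non-empty numeric vectors.
#' @param enum_limit Enumeration budget on `choose(na + nb, na)`.
#' @return List `U` (statistic of the first sample), `p` (two-sided),
#'   `exact` (logical: enumeration used), `n_a`, `n_b`.
#' @export
mannwhitney_exact <- function(a, b, enum_limit = 4e5) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && choose(na + nb, na) <= enum_limit) {
    combs <- combn(na + nb, na)
    # ranks are a permutation of 1..(na+nb): U for each labeling
    Us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    list(U = U, p = p, exact = TRUE, n_a = na, n_b = nb)
  } else {
    mu <- na * nb / 2
    tie_counts <- table(pooled)
    n <- na + nb
    correction <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - correction))
    z <- (abs(U - mu) - 0.5) / sigma
    if (z < 0) z <- 0
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    list(U = U, p = p, exact = FALSE, n_a = na, n_b = nb)
  }
}

#' Levene / Brown-Forsythe test for equality of spread
#'
#' Classic Levene statistic: one-way ANOVA F on absolute deviations from
#' the group center (mean by default; `center = "median"` gives the
#' Brown-Forsythe variant).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return List `W` (the F statistic), `p`, `center`.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(a) >= 2, length(b) >= 2)
  ctr <- if (center == "mean") mean else median
  za <- abs(a - ctr(a))
  zb <- abs(b - ctr(b))
  z <- c(za, zb)
  zbar <- mean(z)
  means <- c(mean(za), mean(zb))
  n <- c(length(za), length(zb))
  N <- sum(n)
  between <- sum(n * (means - zbar)^2) / (2 - 1)
  within_ss <- sum((za - means[1])^2) + sum((zb - means[2])^2)
  if (within_ss == 0) {
    if (between == 0) return(list(W = 0, p = 1, center = center))
    stop("Levene statistic undefined: zero within-group deviation spread")
  }
  W <- between / (within_ss / (N - 2))
  list(W = W, p = pf(W, 1, N - 2, lower.tail = FALSE), center = center)
}

#' Full group comparison table
#'
#' Reproduces the study's statistical layer on a set of accuracy records:
#' for each outcome (angular deviation, entry distance) a pooled row plus
#' one row per ligament, each with group medians/IQRs, the exact (or
#' approximated) Mann-Whitney two-sided p, and the Levene p.
#'
#' @param records Data frame as produced by [evaluate_knee()] /
#'   [simulate_study()]: columns `group` (`"freehand"`/`"psi"`),
#'   `ligament`, `angular_deviation_deg`, `entry_distance_mm`.
#' @param quartile_convention Passed to [median_iqr()].
#' @param levene_center Passed to [levene_test()].
#' @param min_n Minimum per-group size for a stratum row; smaller strata
#'   are omitted with a warning.
#' @return Data frame of class `group_comparison_table`, one row per
#'   (outcome, stratum).
#' @export
compare_study <- function(records, quartile_convention = "linear",
                          levene_center = "mean", min_n = 2L) {
  stopifnot(all(c("group", "ligament", "angular_deviation_deg",
                  "entry_distance_mm") %in% names(records)))
  if (!all(c("freehand", "psi") %in% records$group))
    stop("both groups must be present")
  outcomes <- c(angular = "angular_deviation_deg",
                entry = "entry_distance_mm")
  strata <- c("pooled", LIGAMENTS)
  rows <- list()
  for (oc in names(outcomes)) {
    col <- outcomes[[oc]]
    for (st in strata) {
      sub <- if (st == "pooled") records else
        records[records$ligament == st, , drop = FALSE]
      x_ctrl <- sub[[col]][sub$group == "freehand"]
      x_psi <- sub[[col]][sub$group == "psi"]
      if (length(x_ctrl) < min_n || length(x_psi) < min_n) {
        warning("stratum '", st, "' (", oc, ") omitted: fewer than ",
                min_n, " observations per group")
        next
      }
      mi_c <- median_iqr(x_ctrl, quartile_convention)
      mi_p <- median_iqr(x_psi, quartile_convention)
      mw <- mannwhitney_exact(x_ctrl, x_psi)
      lv <- tryCatch(levene_test(x_ctrl, x_psi, levene_center),
                     error = function(e) {
                       warning("stratum '", st, "' (", oc, "): ",
                               conditionMessage(e))
                       list(p = NA_real_)
                     })
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, stratum = st,
        n_control = length(x_ctrl), n_psi = length(x_psi),
        median_control = mi_c$median, q1_control = mi_c$q1,
        q3_control = mi_c$q3,
        median_psi = mi_p$median, q1_psi = mi_p$q1, q3_psi = mi_p$q3,
        p_mannwhitney = mw$p, mw_exact = mw$exact, U = mw$U,
        p_levene = lv$p, levene_center = levene_center,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison_table", class(out))
  out
}

#' @export
print.group_comparison_table <- function(x, ...) {
  cat("Group comparison (control = freehand vs PSI)\n")
  fmt <- function(m, q1, q3) sprintf("%5.1f [%.1f-%.1f]", m, q1, q3)
  hdr <- sprintf("%-8s %-7s %-18s %-18s %8s %8s", "outcome", "stratum",
                 "control med [IQR]", "PSI med [IQR]", "p(MW)", "p(Lev)")
  cat(hdr, "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-8s %-7s %-18s %-18s %8.3g %8.3g\n",
                x$outcome[i], x$stratum[i],
                fmt(x$median_control[i], x$q1_control[i], x$q3_control[i]),
                fmt(x$median_psi[i], x$q1_psi[i], x$q3_psi[i]),
                x$p_mannwhitney[i], x$p_levene[i]))
  }
  invisible(x)
}
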