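# Longitudinal cohort analysis: visit pairing, tercile stratification at
# fixed strain/pressure cutoffs, annualized change rates, nonparametric
# group comparisons (Kruskal-Wallis with Dunn post hoc, Mann-Whitney,
# Fisher exact, Spearman), and median [IQR] / "k (pct)" table summaries.
#
# Strain units: per-visit strain is carried as eps_pp in percent per mmHg
# (the reporting unit); the tercile cutoffs are expressed in strain-fraction
# per mmHg (0.0251 and 0.038), i.e. 2.51 and 3.8 %/mmHg — divide eps_pp by
# 100 before calling assign_tercile(), or use the `scale` argument of
# pair_visits()/cohort_report() which does it for you.

#' Annualized rate of change between two visits
#'
#' @param v_index,v_followup measurement at the index and follow-up visit.
#' @param interval_years time between the visits (> 0), in years.
#' @return (v_followup - v_index) / interval_years, per year.
#' @export
annualized_rate <- function(v_index, v_followup, interval_years) {
  if (any(interval_years <= 0))
    stop_ws("interval_years must be positive", "invalid_interval")
  (v_followup - v_index) / interval_years
}

#' Tercile configuration
#'
#' Fixed strain cutoffs, in strain-fraction per mmHg, separating the low,
#' intermediate and high strain groups. The defaults 0.0251 and 0.038 are
#' the externally established cutoffs (equivalently 2.51 and 3.8 %/mmHg).
#'
#' @param c1,c2 cutoffs with 0 < c1 < c2.
#' @export
tercile_config <- function(c1 = 0.0251, c2 = 0.038) {
  if (!(c1 > 0 && c2 > c1)) stop_ws("need 0 < c1 < c2", "invalid_config")
  structure(list(c1 = c1, c2 = c2), class = "tercile_config")
}

#' Assign a strain tercile label
#'
#' `v < c1` is low; `c1 <= v <= c2` is intermediate (closed interval: values
#' exactly at a cutoff are intermediate); `v > c2` is high.
#'
#' @param eps_pp_fraction_per_mmHg index-visit strain in strain-fraction per
#'   mmHg (i.e. the %/mmHg value divided by 100); vectorized.
#' @param cfg a [tercile_config()].
#' @return factor with levels low/intermediate/high.
#' @export
assign_tercile <- function(eps_pp_fraction_per_mmHg, cfg = tercile_config()) {
  v <- eps_pp_fraction_per_mmHg
  if (any(!is.finite(v)) || any(v < 0))
    stop_ws("strain values must be finite and >= 0", "domain_error")
  lab <- ifelse(v < cfg$c1, "low", ifelse(v <= cfg$c2, "intermediate", "high"))
  factor(lab, levels = c("low", "intermediate", "high"))
}

#' Frequency cell "k (pct)"
#'
#' @param k,n counts with 0 <= k <= n, n > 0.
#' @return string, percentage rounded half-away-from-zero to 1 decimal.
#' @export
#' @examples
#' summarize_binary(26, 31)  # "26 (83.9)"
summarize_binary <- function(k, n) {
  if (n <= 0) stop_ws("denominator must be positive", "undefined_denominator")
  if (k < 0 || k > n) stop_ws("need 0 <= k <= n", "invalid_input")
  sprintf("%d (%.1f)", as.integer(k), round_half_away(100 * k / n, 1))
}

#' Continuous cell "median [Q1, Q3]"
#'
#' Quartiles use linear interpolation of order statistics (the type-7
#' convention); formatting rounds half-away-from-zero.
#'
#' @param values non-empty numeric vector.
#' @param digits decimals in the formatted string.
#' @return string.
#' @export
#' @examples
#' summarize_continuous(1:5, 0)  # "3 [2, 4]"
summarize_continuous <- function(values, digits = 1) {
  if (!length(values) || any(!is.finite(values)))
    stop_ws("values must be non-empty and finite", "invalid_input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  fmt <- function(x) formatC(round_half_away(x, digits), format = "f", digits = digits)
  sprintf("%s [%s, %s]", fmt(q[2]), fmt(q[1]), fmt(q[3]))
}

#' Kruskal-Wallis test with Dunn's pairwise post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H. The p-value is exact — computed by full
#' enumeration of the permutation distribution of H over all group-label
#' assignments — when the pooled sample is small enough to enumerate
#' (total n <= 9); otherwise the usual chi-square approximation
#' (df = k - 1) is used. When the omnibus p is below `alpha`, Dunn's
#' rank-based pairwise z tests are computed, reporting both unadjusted and
#' Holm-adjusted p-values (the headline is the unadjusted column; the
#' adjusted one is provided alongside).
#'
#' @param groups list of >= 2 numeric vectors, each non-empty.
#' @param alpha significance gate for running the post hoc tests.
#' @param exact_n_max largest pooled sample size for which the exact
#'   permutation p-value is computed.
#' @return list with `H`, `p`, `df`, `p_method` ("exact" or "chi-square"),
#'   and (when computed) `pairwise`: a data.frame with columns group1,
#'   group2, z, p_unadjusted, p_holm.
#' @export
kruskal_wallis_dunn <- function(groups, alpha = 0.05, exact_n_max = 9L) {
  if (any(lengths(groups) == 0)) stop_ws("every group needs observations", "invalid_input")
  if (length(groups) < 2 || sum(lengths(groups)) < 3)
    stop_ws("need >= 2 groups and >= 3 total observations", "invalid_input")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- stats::kruskal.test(x, g)
  out <- list(H = unname(kw$statistic), p = kw$p.value,
              df = unname(kw$parameter), p_method = "chi-square")
  if (length(x) <= exact_n_max) {
    out$p <- kw_exact_p(x, lengths(groups), out$H)
    out$p_method <- "exact"
  }
  if (is.finite(out$p) && out$p < alpha && length(groups) >= 2) {
    rk <- rank(x)
    N <- length(x)
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    rbar <- tapply(rk, g, mean)
    n <- lengths(groups)
    cmb <- utils::combn(seq_along(groups), 2)
    pw <- apply(cmb, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
      z <- unname((rbar[i] - rbar[j]) / se)
      c(z = z, p = 2 * stats::pnorm(-abs(z)))
    })
    nm <- names(groups) %||% as.character(seq_along(groups))
    out$pairwise <- data.frame(
      group1 = nm[cmb[1, ]], group2 = nm[cmb[2, ]],
      z = pw["z", ], p_unadjusted = pw["p", ],
      p_holm = stats::p.adjust(pw["p", ], method = "holm")
    )
  }
  out
}

# Exact permutation p of the tie-corrected Kruskal-Wallis H: enumerate all
# distinct assignments of the pooled values to groups of the given sizes.
kw_exact_p <- function(x, sizes, H_obs) {
  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H_of <- function(assign_list) {
    s <- vapply(assign_list, function(ix) sum(rk[ix]), numeric(1))
    H <- 12 / (N * (N + 1)) * sum(s^2 / sizes) - 3 * (N + 1)
    if (corr > 0) H / corr else 0
  }
  count <- 0L; total <- 0L
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes) - 1) {
      total <<- total + 1L
      if (H_of(c(acc, list(remaining))) >= H_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    k <- length(acc) + 1L
    for (pick in utils::combn(length(remaining), sizes[k], simplify = FALSE)) {
      recurse(remaining[-pick], c(acc, list(remaining[pick])))
    }
    invisible()
  }
  recurse(seq_len(N), list())
  count / total
}

#' Mann-Whitney U test
#'
#' Two-sided; the exact permutation distribution is used when the smaller
#' sample has at most 8 observations and there are no ties, otherwise the
#' normal approximation with tie correction (and continuity correction).
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U` (for the first sample) and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_ws("samples must be non-empty", "invalid_input")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(rbind(c(1, 20), c(0, 10)))  # 1
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop_ws("need a 2 x 2 table of non-negative integers", "invalid_input")
  stats::fisher.test(tab)$p.value
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged); the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_ws("need equal-length samples, n >= 3", "invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ws("correlation undefined for constant input", "undefined_correlation")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Shapiro-Wilk normality gate
#'
#' Annotates whether a variable looks normally distributed; the pipeline's
#' tests are nonparametric regardless, this only drives report annotation.
#' Constant samples are reported as non-normal with p = 0 (the test statistic
#' is undefined there).
#'
#' @param values numeric, 3 <= n <= 5000.
#' @param alpha significance level.
#' @return list with `p` and `normal` (logical).
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 5000) stop_ws("Shapiro-Wilk requires 3 <= n <= 5000", "invalid_input")
  if (stats::sd(values) == 0) return(list(p = 0, normal = FALSE))
  sw <- stats::shapiro.test(values)
  list(p = sw$p.value, normal = sw$p.value >= alpha)
}

#' Pair index and follow-up visits and derive longitudinal measures
#'
#' For each patient the earliest visit is the index and the latest the
#' follow-up (patients with fewer than two visits are dropped). Intervals
#' are days / 365.25. Terciles are assigned from the index strain; the
#' change direction is "increase" for positive net strain change and
#' "decrease" otherwise (exact zero counts as decrease by convention).
#'
#' @param visits data.frame with columns `patient_id`, `visit_date`
#'   (Date or ISO-8601 string), `diameter_cm`, `eps_pp` (%/mmHg); optional
#'   outcome columns are carried through from the index visit.
#' @param cfg a [tercile_config()] (cutoffs in strain-fraction per mmHg).
#' @param scale factor converting `eps_pp` to the cutoff unit; the default
#'   1/100 converts %/mmHg to strain-fraction per mmHg.
#' @return data.frame, one row per paired patient: index/follow-up values,
#'   `interval_years`, `net_strain_change` (%/mmHg), `strain_rate`
#'   (%/mmHg/year), `growth_rate` (cm/year), `tercile`, `direction`.
#' @export
pair_visits <- function(visits, cfg = tercile_config(), scale = 1 / 100) {
  need <- c("patient_id", "visit_date", "diameter_cm", "eps_pp")
  if (!all(need %in% names(visits)))
    stop_ws(paste("visits table needs columns:", paste(need, collapse = ", ")),
            "invalid_input")
  visits$visit_date <- as.Date(visits$visit_date)
  rows <- lapply(split(visits, visits$patient_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$visit_date), , drop = FALSE]
    idx <- d[1, , drop = FALSE]
    fup <- d[nrow(d), , drop = FALSE]
    iv <- as.numeric(fup$visit_date - idx$visit_date) / 365.25
    if (iv <= 0) stop_ws(sprintf("patient %s: non-positive follow-up interval",
                                 idx$patient_id), "invalid_interval")
    net <- fup$eps_pp - idx$eps_pp
    extra <- idx[setdiff(names(idx), need)]
    cbind(data.frame(
      patient_id = idx$patient_id,
      index_date = idx$visit_date, followup_date = fup$visit_date,
      index_diameter_cm = idx$diameter_cm, followup_diameter_cm = fup$diameter_cm,
      index_eps_pp = idx$eps_pp, followup_eps_pp = fup$eps_pp,
      interval_years = iv,
      net_strain_change = net,
      strain_rate = annualized_rate(idx$eps_pp, fup$eps_pp, iv),
      growth_rate = annualized_rate(idx$diameter_cm, fup$diameter_cm, iv),
      tercile = assign_tercile(idx$eps_pp * scale, cfg),
      direction = factor(if (net > 0) "increase" else "decrease",
                         levels = c("increase", "decrease"))
    ), extra, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Markdown outcome table stratified by strain-change direction
#'
#' Builds the "Decrease (n = ...) | Increase (n = ...) | p" layout used for
#' clinical outcome tables: continuous variables as `median [Q1, Q3]` with a
#' Mann-Whitney p, binary outcomes as `k (pct)` with a Fisher exact p.
#'
#' @param paired output of [pair_visits()].
#' @param continuous named character vector: display label -> column name.
#' @param binary named character vector: display label -> 0/1 column name.
#' @param digits decimals for continuous cells.
#' @return character vector of Markdown lines.
#' @export
direction_outcomes_markdown <- function(paired,
                                        continuous = c(`Growth (cm/year)` = "growth_rate"),
                                        binary = NULL, digits = 2) {
  dec <- paired[paired$direction == "decrease", , drop = FALSE]
  inc <- paired[paired$direction == "increase", , drop = FALSE]
  lines <- c(
    sprintf("| Variable | Decrease (n = %d) | Increase (n = %d) | p-value |",
            nrow(dec), nrow(inc)),
    "|---|---|---|---|")
  fmtp <- function(p) if (is.na(p)) "N.A." else
    if (p < 0.01) "<0.01" else sub("0\\.", "0.", sprintf("%.2g", p))
  for (lab in names(continuous)) {
    v <- continuous[[lab]]
    p <- if (nrow(dec) && nrow(inc)) mann_whitney(dec[[v]], inc[[v]])$p else NA
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", lab,
                              summarize_continuous(dec[[v]], digits),
                              summarize_continuous(inc[[v]], digits), fmtp(p)))
  }
  for (lab in names(binary)) {
    v <- binary[[lab]]
    kd <- sum(dec[[v]] > 0); ki <- sum(inc[[v]] > 0)
    p <- if (nrow(dec) && nrow(inc))
      fisher_exact_2x2(rbind(c(kd, nrow(dec) - kd), c(ki, nrow(inc) - ki))) else NA
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", lab,
                              summarize_binary(kd, nrow(dec)),
                              summarize_binary(ki, nrow(inc)), fmtp(p)))
  }
  lines
}

#' Cohort report: tercile comparisons and direction-stratified outcomes
#'
#' Runs the longitudinal analysis on a paired-visit table: per-tercile
#' summaries and Kruskal-Wallis (+ Dunn when significant) comparisons of net
#' strain change, strain rate and growth rate; Spearman correlation of
#' strain rate with index strain; and Mann-Whitney / Fisher comparisons
#' between patients with increasing vs decreasing strain.
#'
#' @param paired output of [pair_visits()].
#' @param alpha significance level.
#' @return list with `tercile_n`, `tercile_tests`, `tercile_summaries`,
#'   `spearman_rate_vs_index`, `direction_tests`, `direction_summaries`.
#' @export
cohort_report <- function(paired, alpha = 0.05) {
  stopifnot(is.data.frame(paired), nrow(paired) >= 3)
  by_terc <- split(paired, paired$tercile, drop = FALSE)
  vars <- c("net_strain_change", "strain_rate", "growth_rate")
  nonempty <- Filter(function(d) nrow(d) > 0, by_terc)
  tests <- lapply(vars, function(v) {
    if (length(nonempty) >= 2)
      kruskal_wallis_dunn(lapply(nonempty, `[[`, v), alpha = alpha)
    else NULL
  })
  names(tests) <- vars
  summaries <- lapply(by_terc, function(d) {
    if (!nrow(d)) return(NULL)
    vapply(vars, function(v) summarize_continuous(d[[v]], 2), character(1))
  })
  sp <- spearman_rank(paired$strain_rate, paired$index_eps_pp)
  by_dir <- split(paired, paired$direction)
  dir_tests <- list()
  dir_sum <- NULL
  if (all(vapply(by_dir, nrow, integer(1)) > 0)) {
    dir_tests$growth_rate <- mann_whitney(by_dir$increase$growth_rate,
                                          by_dir$decrease$growth_rate)
    for (oc in intersect(c("rupture"), names(paired))) {
      tab <- rbind(
        c(sum(by_dir$decrease[[oc]] > 0), sum(by_dir$decrease[[oc]] == 0)),
        c(sum(by_dir$increase[[oc]] > 0), sum(by_dir$increase[[oc]] == 0))
      )
      dir_tests[[oc]] <- list(p = fisher_exact_2x2(tab), table = tab)
    }
    dir_sum <- lapply(by_dir, function(d)
      c(n = nrow(d), growth_rate = summarize_continuous(d$growth_rate, 2)))
  }
  list(
    tercile_n = vapply(by_terc, nrow, integer(1)),
    tercile_tests = tests,
    tercile_summaries = summaries,
    spearman_rate_vs_index = sp,
    direction_tests = dir_tests,
    direction_summaries = dir_sum
  )
}
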