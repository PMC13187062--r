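#' Studentized range distribution function
#'
#' CDF of the studentized range: the range of `k` independent standard
#' normal values divided by an independent estimate of the standard
#' deviation on `df` degrees of freedom. This is the reference distribution
#' of the Games-Howell test statistic q = t * sqrt(2). Evaluation is by
#' numerical integration of the range distribution against the chi
#' density (via [stats::ptukey()]); tests verify agreement with a
#' Monte-Carlo simulation oracle and with the k = 2 closed form
#' F(q; 2, df) = 2 T_df(q / sqrt(2)) - 1.
#'
#' @param q Quantile(s), >= 0 (values below 0 have probability 0).
#' @param k Number of groups in the family (>= 2).
#' @param df Degrees of freedom (> 0).
#' @return F(q; k, df), vectorized over `q`; monotone increasing in `q`.
#' @examples
#' studentized_range_cdf(3.5, 3, 10)
#' # k = 2 reduction to the t distribution:
#' studentized_range_cdf(2, 2, 10) - (2 * pt(2 / sqrt(2), 10) - 1)
#' @export
studentized_range_cdf <- function(q, k, df) {
  if (!is_count(k) || k < 2) {
    abort_stage("studentized_range_cdf", "k must be a count >= 2")
  }
  if (!is_scalar_number(df) || df <= 0) {
    abort_stage("studentized_range_cdf", "df must be > 0")
  }
  if (anyNA(q)) {
    abort_stage("studentized_range_cdf", "q contains missing values")
  }
  out <- numeric(length(q))
  pos <- q > 0
  out[pos] <- stats::ptukey(q[pos], nmeans = k, df = df)
  out
}

#' Group summary for statistical comparison
#'
#' @param group_id Identifier.
#' @param mean,sd Summary statistics (sd > 0).
#' @param n Number of measurements (>= 2 for use in testing).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(group_id, mean, sd, n) {
  if (!is_count(n) || n < 2) {
    abort_stage("group_summary", "n must be a count >= 2")
  }
  if (!is_scalar_number(sd) || sd <= 0) {
    abort_stage("group_summary", "sd must be > 0")
  }
  structure(list(group_id = group_id, mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Games-Howell pairwise comparison from summary statistics
#'
#' Post-hoc pairwise test for unequal variances and unequal group sizes:
#' \deqn{t = |m_a - m_b| / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with Welch-Satterthwaite degrees of freedom
#' \deqn{df = (s_a^2/n_a + s_b^2/n_b)^2 /
#'   [(s_a^2/n_a)^2/(n_a-1) + (s_b^2/n_b)^2/(n_b-1)]}
#' and p-value \eqn{1 - F(t \sqrt{2}; k, df)} where F is the studentized
#' range CDF with family size `k_groups`. With `k_groups = 2` this reduces
#' exactly to the two-sided Welch t-test.
#'
#' @param a,b `group_summary` objects (see [group_summary()]).
#' @param k_groups Family size for the studentized range (>= 2). The family
#'   size for a table of many simultaneous comparisons is a design choice;
#'   the packaged analysis defaults to the number of groups compared per
#'   metric (see [build_comparison_table()]).
#' @param alpha Significance level (default 0.05); significance is the
#'   strict inequality p < alpha.
#' @return Object of class `games_howell`: list with `pair`, `t_stat`,
#'   `df`, `q_stat`, `k_groups`, `p_value`, `alpha`, `significant`.
#'   Symmetric under swapping `a` and `b`.
#' @examples
#' a <- group_summary("frag", 13743.9, 2766.0, 3)
#' b <- group_summary("ref", 224893.3, 27974.9 * sqrt(18), 18)
#' games_howell_pair(a, b, k_groups = 48)$p_value
#' @export
games_howell_pair <- function(a, b, k_groups = 2, alpha = 0.05) {
  if (!inherits(a, "group_summary") || !inherits(b, "group_summary")) {
    abort_stage("games_howell_pair", "a and b must be group_summary objects")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_stage("games_howell_pair", "alpha must be in (0, 1)")
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  pooled <- va + vb
  if (pooled <= 0) {
    abort_stage("games_howell_pair", "zero pooled variance")
  }
  t_stat <- abs(a$mean - b$mean) / sqrt(pooled)
  df <- pooled^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  q_stat <- t_stat * sqrt(2)
  p <- 1 - studentized_range_cdf(q_stat, k = k_groups, df = df)
  p <- min(max(p, 0), 1)
  structure(
    list(pair = c(a$group_id, b$group_id),
         t_stat = t_stat, df = df, q_stat = q_stat,
         k_groups = as.integer(k_groups), p_value = p,
         alpha = alpha, significant = p < alpha),
    class = "games_howell"
  )
}

#' @export
print.games_howell <- function(x, ...) {
  cat(sprintf("Games-Howell: %s vs %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  t = %.3f, df = %.2f, q = %.3f (k = %d)\n",
              x$t_stat, x$df, x$q_stat, x$k_groups))
  cat(sprintf("  p = %s%s\n", format_pvalue(x$p_value),
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha) else ""))
  invisible(x)
}

format_pvalue <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}

#' Games-Howell comparison table for fragments vs reference specimens
#'
#' Builds the full grid of pairwise comparisons: each fragment x each
#' reference specimen x each metric (On.Ar, H.Ar), under one shrinkage
#' scenario. `no_shrinkage` uses the fragments' lower-bound summaries
#' (burning at 500-600 degrees C); `shrinkage_700` uses the upper-bound
#' summaries (areas divided by the shrinkage factor). Reference SDs are
#' obtained from the reported dispersions via [dispersion_to_sd()].
#' Reference rows lacking a metric (or with n < 2) get an `NA` cell.
#'
#' @param fragments List of `interval_summary` objects from
#'   [apply_shrinkage_bounds()].
#' @param references Filtered `reference_db` (see
#'   [filter_statistical_set()]).
#' @param scenario `"no_shrinkage"` or `"shrinkage_700"`.
#' @param alpha Significance level (default 0.05).
#' @param k_groups Family size for the studentized range. Default 48 =
#'   3 fragments + 45 reference specimens compared per metric; headline
#'   conclusions are robust to choices in \[10, 60\].
#' @return Data frame of class `comparison_table` with columns `scenario`,
#'   `fragment`, `reference_specimen`, `taxon`, `metric`, `t`, `df`, `q`,
#'   `k`, `p`, `significant`.
#' @export
build_comparison_table <- function(fragments, references,
                                   scenario = c("no_shrinkage", "shrinkage_700"),
                                   alpha = 0.05, k_groups = 48) {
  scenario <- match.arg(scenario)
  empty <- data.frame(
    scenario = character(0), fragment = character(0),
    reference_specimen = character(0), taxon = character(0),
    metric = character(0), t = numeric(0), df = numeric(0), q = numeric(0),
    k = integer(0), p = numeric(0), significant = logical(0),
    stringsAsFactors = FALSE
  )
  if (length(fragments) == 0 || nrow(references) == 0) {
    class(empty) <- c("comparison_table", "data.frame")
    return(empty)
  }
  rows <- list()
  for (frag in fragments) {
    s <- if (scenario == "no_shrinkage") frag$lower else frag$upper
    for (i in seq_len(nrow(references))) {
      refrow <- references[i, ]
      for (metric in c("OnAr", "HAr")) {
        suffix <- if (metric == "OnAr") "onar" else "har"
        ref_n <- refrow[[paste0("n_", suffix)]]
        ref_mean <- refrow[[paste0("mean_", suffix)]]
        ref_disp <- refrow[[paste0("disp_", suffix)]]
        ref_kind <- refrow[[paste0("disp_kind_", suffix)]]
        frag_mean <- if (metric == "OnAr") s$mean_onar else s$mean_har
        frag_sd <- if (metric == "OnAr") s$sd_onar else s$sd_har

        cell <- data.frame(
          scenario = scenario, fragment = frag$specimen_id,
          reference_specimen = refrow$specimen_id, taxon = refrow$taxon,
          metric = metric, t = NA_real_, df = NA_real_, q = NA_real_,
          k = as.integer(k_groups), p = NA_real_, significant = NA,
          stringsAsFactors = FALSE
        )
        usable <- !is.na(ref_mean) && !is.na(ref_disp) && !is.na(ref_n) &&
          ref_n >= 2 && !is.na(frag_sd) && s$n_on >= 2
        if (usable) {
          ref_sd <- dispersion_to_sd(ref_mean, ref_disp, ref_kind, ref_n)
          gh <- games_howell_pair(
            group_summary(frag$specimen_id, frag_mean, frag_sd, s$n_on),
            group_summary(refrow$specimen_id, ref_mean, ref_sd, ref_n),
            k_groups = k_groups, alpha = alpha
          )
          cell$t <- gh$t_stat; cell$df <- gh$df; cell$q <- gh$q_stat
          cell$p <- gh$p_value; cell$significant <- gh$significant
        }
        rows[[length(rows) + 1]] <- cell
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Per-taxon significance pattern
#'
#' Summarizes a comparison table as "x of y specimens" per taxon: a
#' reference specimen counts as distinguished when at least one of its
#' cells (either metric) is significant. With
#' `require_all_fragments = TRUE` the specimen must be distinguished from
#' every fragment in the table; with the default `FALSE`, from at least
#' one.
#'
#' @param table A `comparison_table`.
#' @param require_all_fragments Logical (see above).
#' @return Data frame with columns `taxon`, `n_specimens`,
#'   `n_distinguished`.
#' @export
significance_pattern <- function(table, require_all_fragments = FALSE) {
  if (nrow(table) == 0) {
    return(data.frame(taxon = character(0), n_specimens = integer(0),
                      n_distinguished = integer(0), stringsAsFactors = FALSE))
  }
  fragments <- unique(table$fragment)
  per_spec <- lapply(split(table, table$reference_specimen), function(d) {
    sig_by_frag <- vapply(fragments, function(f) {
      any(d$significant[d$fragment == f], na.rm = TRUE)
    }, logical(1))
    data.frame(taxon = d$taxon[1],
               distinguished = if (require_all_fragments) all(sig_by_frag)
                               else any(sig_by_frag),
               stringsAsFactors = FALSE)
  })
  per_spec <- do.call(rbind, per_spec)
  agg <- lapply(split(per_spec, per_spec$taxon), function(d) {
    data.frame(taxon = d$taxon[1], n_specimens = nrow(d),
               n_distinguished = sum(d$distinguished),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
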