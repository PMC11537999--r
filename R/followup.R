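#' Fold change from qPCR cycle thresholds (delta-delta-Ct)
#'
#' \deqn{\Delta Ct = Ct_{target} - Ct_{housekeeping}} per group,
#' \deqn{\Delta\Delta Ct = \Delta Ct_{treated} - \Delta Ct_{control}},
#' \deqn{Fold = 2^{-\Delta\Delta Ct}.}
#' Adding a constant to all four Ct values leaves the fold unchanged, as
#' any plate-wide threshold shift should.
#'
#' @param ct_target_treated,ct_house_treated target and housekeeping Ct in
#'   the treated group.
#' @param ct_target_control,ct_house_control the same in the control group.
#' @return Fold change relative to control (vectorized).
#' @examples
#' ddct_fold(24, 18, 25, 18) # 2
#' @export
ddct_fold <- function(ct_target_treated, ct_house_treated,
                      ct_target_control, ct_house_control) {
  stopifnot(all(is.finite(c(ct_target_treated, ct_house_treated,
                            ct_target_control, ct_house_control))))
  ddct <- (ct_target_treated - ct_house_treated) -
    (ct_target_control - ct_house_control)
  2^(-ddct)
}

#' Per-replicate fold changes from a long qPCR table
#'
#' Computes a fold change for every replicate of every treatment group
#' relative to the mean control-group delta-Ct, normalizing the target gene
#' to the housekeeping gene within each replicate.  Computing the fold per
#' replicate and summarizing afterwards (rather than propagating errors on
#' mean Ct) matches the usual mean-of-triplicates +/- SD presentation and
#' feeds directly into [dunnett_anova()].
#'
#' @param data data frame `group`, `gene`, `replicate`, `ct` (a
#'   `sample_id` column, if present, is ignored for the arithmetic).
#' @param control label of the control group (e.g. `"DMSO"`).
#' @param housekeeping housekeeping gene label (e.g. `"GAPDH"`).
#' @param target target gene label; default = the single non-housekeeping
#'   gene present.
#' @return Data frame `group`, `replicate`, `delta_ct`, `delta_delta_ct`,
#'   `fold`.
#' @export
qpcr_fold_change <- function(data, control = "DMSO",
                             housekeeping = "GAPDH", target = NULL) {
  req <- c("group", "gene", "replicate", "ct")
  stopifnot(all(req %in% names(data)))
  genes <- unique(data$gene)
  if (is.null(target)) {
    target <- setdiff(genes, housekeeping)
    if (length(target) != 1L)
      stop("specify `target`: found genes ", paste(genes, collapse = ", "))
  }
  if (!control %in% data$group) stop("control group not present: ", control)

  tgt <- data[data$gene == target, c("group", "replicate", "ct")]
  hk <- data[data$gene == housekeeping, c("group", "replicate", "ct")]
  m <- merge(tgt, hk, by = c("group", "replicate"),
             suffixes = c("_target", "_house"))
  m$delta_ct <- m$ct_target - m$ct_house
  ref <- mean(m$delta_ct[m$group == control])
  m$delta_delta_ct <- m$delta_ct - ref
  m$fold <- 2^(-m$delta_delta_ct)
  out <- m[order(m$group != control, m$group, m$replicate),
           c("group", "replicate", "delta_ct", "delta_delta_ct", "fold")]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits the one-way ANOVA and compares every treatment group against the
#' shared control with Dunnett's procedure: the two-sided adjusted p-value
#' of comparison i is \eqn{1 - P(\max_j |T_j| \le |t_i|)} under the
#' multivariate t distribution of the comparison statistics, with the
#' equal-correlation structure
#' \eqn{\rho_{ij} = \sqrt{n_i n_j / ((n_i + n_0)(n_j + n_0))}} implied by
#' the shared control (0.5 for balanced designs).  The distribution is
#' evaluated with `mvtnorm` under a locally fixed RNG so results are
#' reproducible to quadrature accuracy.  With a single comparison the
#' adjusted p equals the ordinary two-sample pooled-t p.
#'
#' Stars follow the usual convention: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.
#'
#' @param values numeric response (e.g. qPCR fold changes).
#' @param groups group label per value.
#' @param control label of the control group.
#' @return List with `f_statistic`, `f_p_value`, `df_residual`, and
#'   `comparisons`: data frame `group`, `estimate`, `t`, `p_adj`, `stars`.
#' @examples
#' dunnett_anova(c(1, 1.1, 0.9, 0.2, 0.25, 0.22),
#'               rep(c("DMSO", "drug"), each = 3), control = "DMSO")
#' @export
dunnett_anova <- function(values, groups, control) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), control %in% groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two replicates")

  fit <- stats::aov(values ~ factor(groups))
  an <- summary(fit)[[1]]
  s2 <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  if (s2 <= .Machine$double.eps * mean(values^2))
    stop("zero within-group variance: Dunnett's test degenerate")

  trt <- setdiff(names(tab), control)
  n0 <- tab[[control]]
  mu0 <- mean(values[groups == control])
  ni <- as.numeric(tab[trt])
  est <- vapply(trt, function(g) mean(values[groups == g]) - mu0, 0)
  tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))

  lam <- sqrt(ni / (ni + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  p_adj <- vapply(abs(tstat), function(q) {
    1 - dunnett_prob(q, R, df)
  }, 0)
  p_adj <- pmin(pmax(p_adj, 0), 1)

  stars <- ifelse(p_adj < 0.001, "***",
                  ifelse(p_adj < 0.01, "**",
                         ifelse(p_adj < 0.05, "*", "")))
  list(f_statistic = an[1, "F value"], f_p_value = an[1, "Pr(>F)"],
       df_residual = df,
       comparisons = data.frame(group = trt, estimate = unname(est),
                                t = unname(tstat), p_adj = unname(p_adj),
                                stars = stars, stringsAsFactors = FALSE,
                                row.names = NULL))
}

# P(max_j |T_j| <= q) under the multivariate t with correlation R and df;
# RNG is pinned locally so the quasi-Monte-Carlo quadrature is reproducible
dunnett_prob <- function(q, R, df) {
  k <- nrow(R)
  withr_seed(20240501L, {
    as.numeric(mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                             df = as.integer(df), corr = R,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                            maxpts = 100000)))
  })
}

#' Two-sided Dunnett critical value
#'
#' The quantile q with \eqn{P(\max_j |T_j| \le q) = 1 - \alpha} for k
#' balanced comparisons against a shared control (correlation 0.5) and the
#' given residual degrees of freedom — the entry a printed Dunnett table
#' lists.
#'
#' @param k number of treatment groups compared to the control.
#' @param df residual degrees of freedom.
#' @param alpha two-sided significance level.
#' @return The critical value.
#' @examples
#' dunnett_critical(1, 8)  # reduces to qt(0.975, 8)
#' @export
dunnett_critical <- function(k, df, alpha = 0.05) {
  R <- matrix(0.5, k, k); diag(R) <- 1
  stats::uniroot(function(q) dunnett_prob(q, R, df) - (1 - alpha),
                 interval = c(0.5, 15), tol = 1e-6)$root
}

#' Pharmacological IC50-shift analysis
#'
#' A true receptor antagonist co-treated with increasing agonist
#' concentrations shifts its inhibition curve to the right (less potent
#' apparent IC50).  Each co-treatment condition's series is fitted
#' independently with [fit_hill()]; the maximum fold shift is the ratio of
#' the largest to the smallest fitted IC50 across conditions, and the
#' compound is flagged target-dependent when that shift strictly exceeds
#' `fold_threshold`.  Any unconverged condition fit makes the result
#' indeterminate rather than silently passing.
#'
#' @param responses long data frame `cotreatment`, `concentration_um`,
#'   `percent_activity` for one compound (extra columns ignored).
#' @param compound_id optional label.
#' @param fold_threshold shift (strict) required to call dependence.
#' @param ... passed to [fit_hill()].
#' @return Object of class `shift_result`: list with `compound_id`,
#'   `fits` (table: `cotreatment`, `ic50_um`, `efficacy`, `converged`),
#'   `max_fold_shift`, `pxr_dependent`, `indeterminate`.
#' @export
shift_analysis <- function(responses, compound_id = NA_character_,
                           fold_threshold = 2, ...) {
  req <- c("cotreatment", "concentration_um", "percent_activity")
  stopifnot(all(req %in% names(responses)))
  conds <- split(responses, responses$cotreatment)
  if (length(conds) < 2L)
    stop("need at least two co-treatment conditions")
  fits <- lapply(conds, function(p)
    fit_hill(p$concentration_um, p$percent_activity, ...))
  tab <- data.frame(
    cotreatment = names(conds),
    ic50_um = vapply(fits, function(f) f$k, 0),
    efficacy = vapply(fits, function(f) f$efficacy, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  indeterminate <- !all(tab$converged)
  shift <- if (indeterminate) NA_real_ else
    max(tab$ic50_um) / min(tab$ic50_um)
  structure(list(compound_id = compound_id, fits = tab,
                 max_fold_shift = shift,
                 pxr_dependent = !indeterminate && shift > fold_threshold,
                 indeterminate = indeterminate),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat("IC50-shift analysis",
      if (!is.na(x$compound_id)) paste0("(", x$compound_id, ")"), "\n")
  print(x$fits, row.names = FALSE)
  if (x$indeterminate) {
    cat("  indeterminate: at least one condition did not converge\n")
  } else {
    cat(sprintf("  max fold shift %.3g -> %starget-dependent\n",
                x$max_fold_shift, if (x$pxr_dependent) "" else "NOT "))
  }
  invisible(x)
}
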