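#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Thin validated wrapper around
#' [stats::p.adjust()]: adjusted values are monotone in the p-value ranks,
#' capped at 1, and returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Newton solve of trigamma(y) = x, vectorized (method of moments helper)
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-8) break
  }
  y
}

# Empirical-Bayes squeeze of per-feature sample variances toward a pooled
# prior. The scaled inverse-chi-square prior (df_prior, var_prior) is
# estimated by method of moments on log sample variances; prior_df can be
# forced (0 = no shrinkage, Inf = full shrinkage to the pooled variance).
squeeze_variances <- function(s2, df, prior_df = NULL) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) {
    return(list(df_prior = 0, var_prior = 0, s2_post = s2))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  if (is.null(prior_df)) {
    evar <- var(e) - trigamma(df / 2)
    if (length(e) < 2 || !is.finite(evar) || evar <= 0) {
      df_prior <- Inf
    } else {
      df_prior <- 2 * trigamma_inverse(evar)
    }
  } else {
    df_prior <- prior_df
  }
  if (is.infinite(df_prior)) {
    # with no evidence of variance heterogeneity the pooled variance is the
    # maximum-likelihood scale estimate
    var_prior <- mean(s2[ok])
    s2_post <- rep(var_prior, length(s2))
  } else if (df_prior == 0) {
    var_prior <- exp(mean(e))
    s2_post <- s2
  } else {
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  list(df_prior = df_prior, var_prior = var_prior, s2_post = s2_post)
}

#' Paired empirical-Bayes moderated t-test, tumor versus normal
#'
#' For every feature, computes within-patient paired differences (tumor
#' minus normal, on the log2 scale when `log_transform = TRUE`), their mean
#' (`log2fc`), and a moderated t-statistic in which the per-feature variance
#' of the differences is shrunk toward a pooled prior variance. The prior
#' (its degrees of freedom and scale) is estimated by method of moments from
#' the observed distribution of sample variances; two-sided p-values use a t
#' distribution with residual-plus-prior degrees of freedom. With
#' `prior_df = 0` the statistic is the ordinary paired t; with
#' `prior_df = Inf` every feature is tested against the pooled variance.
#'
#' Samples without a tumor/normal partner (matched by `patient_id`) are
#' dropped. Features that are constant across all paired differences are
#' reported with `t = 0`, `p = 1`.
#'
#' @param x Wide omics tibble (`feature_id` + sample columns).
#' @param sample_meta Sample metadata (`sample_id`, `patient_id`, `tissue`).
#' @param log_transform Test on `log2(value + pseudocount)` (use `FALSE`
#'   for data already on an additive scale).
#' @param pseudocount Added before the log2 transform; use 0 for strictly
#'   positive data such as methylation beta values, where the fold change
#'   is then a ratio of betas.
#' @param prior_df Force the prior degrees of freedom (`NULL` = estimate).
#' @return A `omx_differential` tibble: `feature_id`, `log2fc`, `t`,
#'   `p_raw`, `p_adj` (BH), `status` (all `"ns"` until
#'   [classify_differential()] is applied), with the fitted prior recorded
#'   in attributes (see [glance.omx_differential()]).
#' @export
paired_moderated_test <- function(x, sample_meta, log_transform = TRUE,
                                  pseudocount = 1, prior_df = NULL) {
  m <- omx_as_matrix(x)
  meta <- validate_sample_meta(sample_meta)
  meta <- meta[meta$sample_id %in% colnames(m), ]
  tum <- meta[meta$tissue == "tumor", ]
  nor <- meta[meta$tissue == "normal", ]
  paired <- intersect(tum$patient_id, nor$patient_id)
  if (length(paired) < 2) {
    abort("paired differential analysis needs at least 2 tumor/normal pairs")
  }
  t_ids <- tum$sample_id[match(paired, tum$patient_id)]
  n_ids <- nor$sample_id[match(paired, nor$patient_id)]
  v <- m[, c(t_ids, n_ids), drop = FALSE]
  if (log_transform) {
    if (any(v + pseudocount <= 0)) {
      abort("values must be positive after adding the pseudocount before log2")
    }
    v <- log2(v + pseudocount)
  }
  d <- v[, t_ids, drop = FALSE] - v[, n_ids, drop = FALSE]
  n <- ncol(d)
  df <- n - 1
  mean_d <- rowMeans(d)
  s2 <- rowSums((d - mean_d)^2) / df
  pr <- squeeze_variances(s2, df, prior_df)
  se <- sqrt(pr$s2_post / n)
  t_mod <- mean_d / se
  degenerate <- se == 0
  if (any(degenerate & mean_d != 0)) {
    abort("zero-variance feature with a non-zero effect and zero prior variance: statistic undefined")
  }
  t_mod[degenerate] <- 0
  df_total <- df + pr$df_prior
  p_raw <- 2 * pt(-abs(t_mod), df = df_total)
  p_raw[degenerate] <- 1
  out <- tibble(feature_id = rownames(m), log2fc = unname(mean_d),
                t = unname(t_mod), p_raw = unname(p_raw),
                p_adj = bh_adjust(unname(p_raw)), status = "ns")
  new_omx_differential(out, n_pairs = n, df_residual = df,
                       df_prior = pr$df_prior, var_prior = pr$var_prior,
                       log_transform = log_transform)
}

new_omx_differential <- function(tbl, ...) {
  structure(tbl, class = c("omx_differential", class(tbl)), fit = list(...))
}

#' Classify features as up, down or not significant
#'
#' A feature is `up` when its fold change is at least `fc_min` (i.e.
#' `log2fc >= log2(fc_min)`, boundary included) and its BH-adjusted p-value
#' is strictly below `p_max`; `down` symmetrically; `ns` otherwise.
#'
#' @param table A differential table from [paired_moderated_test()].
#' @param fc_min Minimum fold change (natural scale), default 2.
#' @param p_max Adjusted-p threshold (strict), default 0.01.
#' @return The table with `status` set.
#' @export
classify_differential <- function(table, fc_min = 2, p_max = 0.01) {
  assert_columns(table, c("feature_id", "log2fc", "p_adj"), "differential table")
  if (fc_min < 1) abort("fc_min must be >= 1")
  lfc <- log2(fc_min)
  table$status <- dplyr::case_when(
    table$log2fc >= lfc & table$p_adj < p_max ~ "up",
    table$log2fc <= -lfc & table$p_adj < p_max ~ "down",
    TRUE ~ "ns")
  table
}

#' Average methylation probe values into gene-level values
#'
#' Each gene's value in a sample is the arithmetic mean of its mapped
#' probe (site) values in that sample; genes with no mapped site are
#' absent from the result.
#'
#' @param site_matrix Wide omics tibble of per-site values.
#' @param site_map Tibble with columns `site_id`, `gene_id`.
#' @return A gene-level wide omics tibble.
#' @export
aggregate_probes_to_genes <- function(site_matrix, site_map) {
  m <- omx_as_matrix(site_matrix)
  assert_columns(site_map, c("site_id", "gene_id"), "site-to-gene map")
  if (nrow(site_map) == 0) {
    warn("empty site-to-gene mapping: returning an empty gene-level matrix")
    return(tibble(feature_id = character(0)))
  }
  missing <- setdiff(site_map$site_id, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("site-to-gene map references %d site(s) absent from the matrix (e.g. %s)",
                  length(missing), missing[1]))
  }
  sub <- m[site_map$site_id, , drop = FALSE]
  sums <- rowsum(sub, group = site_map$gene_id)
  counts <- as.vector(table(site_map$gene_id)[rownames(sums)])
  omx_from_matrix(sums / counts)
}
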