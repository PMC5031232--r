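#' Effective sample size of a two-arm mean-difference trial
#'
#' For a mean difference between two arms with a common within-arm variance
#' \eqn{\sigma^2}, the variance of the effect estimate is
#' \eqn{\sigma^2 (1/N_T + 1/N_C)}, so the trial carries the same information
#' as a one-sample study of effective size
#' \eqn{n = (1/N_T + 1/N_C)^{-1}}. For a balanced trial of total size
#' \eqn{N} this is \eqn{N/4}.
#'
#' @param n_treat Treatment-arm sample size (>= 1).
#' @param n_control Control-arm sample size (>= 1).
#' @return The effective sample size, a positive real number.
#' @examples
#' effective_sample_size(122, 122) # N/4 = 61 for N = 244
#' @export
effective_sample_size <- function(n_treat, n_control) {
  if (any(n_treat < 1) || any(n_control < 1)) {
    stop("arm sizes must be >= 1", call. = FALSE)
  }
  1 / (1 / n_treat + 1 / n_control)
}

#' Construct a study summary
#'
#' Holds the per-trial quantities every other computation consumes: the
#' mean-difference effect estimate, the effective sample size, the pooled
#' within-study variance estimate and its degrees of freedom. Either
#' `n_eff` or both arm sizes must be given; when both are present they
#' must agree.
#'
#' @param effect Effect estimate (mean difference, outcome units). May be
#'   `NA` when only the weight of the study is needed.
#' @param n_eff Effective sample size (> 0); computed from the arm sizes
#'   when omitted.
#' @param s2 Pooled within-study variance estimate (> 0).
#' @param df Degrees of freedom of `s2` (integer >= 1).
#' @param n_treat,n_control Optional arm sizes (> 0).
#' @return An object of class `"study_summary"`.
#' @export
study_summary <- function(effect, n_eff = NULL, s2, df,
                          n_treat = NULL, n_control = NULL) {
  has_arms <- !is.null(n_treat) && !is.null(n_control)
  if (is.null(n_eff)) {
    if (!has_arms) stop("supply n_eff or both arm sizes", call. = FALSE)
    n_eff <- effective_sample_size(n_treat, n_control)
  } else if (has_arms) {
    if (abs(n_eff - effective_sample_size(n_treat, n_control)) >
        1e-6 * n_eff) {
      stop("n_eff disagrees with the arm sizes", call. = FALSE)
    }
  }
  if (n_eff <= 0) stop("n_eff must be > 0", call. = FALSE)
  if (s2 <= 0) stop("s2 must be > 0", call. = FALSE)
  df <- as.integer(round(df))
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  structure(
    list(effect = effect, n_eff = n_eff, s2 = s2, df = df,
         arm_sizes = if (has_arms) c(n_treat, n_control) else NULL),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("study summary: effect = %s, n_eff = %.4g, s2 = %.4g, df = %d\n",
              format(x$effect), x$n_eff, x$s2, x$df))
  invisible(x)
}

#' Read a table of study summaries
#'
#' Reads a delimited text table with header columns `study_id`, `effect`,
#' `s2`, `df` and exactly one of the pair `n_treat`/`n_control` or `n_eff`
#' per row (both allowed when consistent).
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @return A list of [study_summary()] objects, named by `study_id`.
#' @export
read_study_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("study_id", "effect", "s2", "df")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_arm_cols <- all(c("n_treat", "n_control") %in% names(tab))
  has_neff_col <- "n_eff" %in% names(tab)
  if (!has_arm_cols && !has_neff_col) {
    stop("need n_eff or the n_treat/n_control pair", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    arms_ok <- has_arm_cols && !is.na(row$n_treat) && !is.na(row$n_control)
    neff_ok <- has_neff_col && !is.na(row$n_eff)
    if (!arms_ok && !neff_ok) {
      stop(sprintf("row %d: need n_eff or both arm sizes", i), call. = FALSE)
    }
    study_summary(
      effect = row$effect,
      n_eff = if (neff_ok) row$n_eff else NULL,
      s2 = row$s2, df = row$df,
      n_treat = if (arms_ok) row$n_treat else NULL,
      n_control = if (arms_ok) row$n_control else NULL
    )
  })
  names(out) <- tab$study_id
  out
}

#' Fixed-effect inverse-variance pooling
#'
#' Combines study effect estimates with unnormalised inverse-variance
#' weights \eqn{w_j = n_j / s_j^2}, giving the cumulative estimate
#' \eqn{\hat\theta_{(i)} = \sum_j w_j \hat\theta_j / W_i} with
#' \eqn{W_i = \sum_j w_j} and variance \eqn{1/W_i}. A study with zero
#' weight (zero effective size) is dropped.
#'
#' @param studies A list of [study_summary()] objects, or a data frame with
#'   columns `effect`, `n_eff`, `s2`.
#' @return An object of class `"cumulative_meta"` with elements
#'   `combined_effect`, `weights`, `total_weight`, `variance`,
#'   `normalized_weights`.
#' @export
combine_fixed <- function(studies) {
  if (is.data.frame(studies)) {
    if (!all(c("effect", "n_eff", "s2") %in% names(studies))) {
      stop("data frame needs columns effect, n_eff, s2", call. = FALSE)
    }
    if (!nrow(studies)) stop("empty study list", call. = FALSE)
    if (any(studies$n_eff < 0)) stop("n_eff must be >= 0", call. = FALSE)
    effect <- studies$effect
    n_eff <- studies$n_eff
    s2 <- studies$s2
  } else {
    if (!length(studies)) stop("empty study list", call. = FALSE)
    effect <- vapply(studies, function(s) as.numeric(s$effect), numeric(1))
    n_eff <- vapply(studies, `[[`, numeric(1), "n_eff")
    s2 <- vapply(studies, `[[`, numeric(1), "s2")
  }
  if (any(s2 <= 0)) stop("all variances must be > 0", call. = FALSE)
  w <- n_eff / s2
  keep <- w > 0
  w <- w[keep]
  effect <- effect[keep]
  if (!length(w)) stop("no studies with positive weight", call. = FALSE)
  W <- sum(w)
  structure(
    list(combined_effect = sum(w * effect) / W,
         weights = w,
         total_weight = W,
         variance = 1 / W,
         normalized_weights = w / W),
    class = "cumulative_meta"
  )
}

#' @export
print.cumulative_meta <- function(x, ...) {
  cat(sprintf(
    "fixed-effect pooled estimate: %.4f (variance %.4f, %d studies)\n",
    x$combined_effect, x$variance, length(x$weights)))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}
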