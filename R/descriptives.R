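#' Prevalence of a binary outcome by group
#'
#' Per level of `by`: group size, outcome count, and percentage, plus an
#' overall row. Factor levels without observations are dropped with a
#' message.
#'
#' @param data data frame.
#' @param by grouping column name (a covariate or the region id).
#' @param outcome binary outcome column name.
#' @return data frame `group`, `n`, `n_anaemic`, `percent`; the final row is
#'   `Overall`.
#' @export
prevalence_by <- function(data, by, outcome = "anaemic") {
  if (!by %in% names(data)) stop("grouping column '", by, "' not in data")
  y <- data[[outcome]]
  g <- as.character(data[[by]])
  if (is.factor(data[[by]])) {
    empty <- setdiff(levels(data[[by]]), unique(g))
    if (length(empty) > 0L) {
      message("prevalence_by: dropping empty group(s): ",
              paste(empty, collapse = ", "))
    }
  }
  tot <- tapply(y, g, length)
  cnt <- tapply(y, g, sum)
  out <- data.frame(group = names(tot), n = as.integer(tot),
                    n_anaemic = as.integer(cnt),
                    percent = 100 * as.numeric(cnt) / as.numeric(tot),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(group = "Overall", n = length(y),
                               n_anaemic = sum(y),
                               percent = 100 * mean(y),
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Chi-square screen of categorical covariates
#'
#' Pearson chi-square test of independence between the binary outcome and
#' each categorical covariate, without continuity correction (large-sample
#' setting). A covariate is retained iff `p <= alpha` (20% by default — a
#' deliberately permissive screen). The full p-value table is always
#' returned; covariates with a single observed level are excluded with a
#' message. The screen is advisory: model configuration may override
#' inclusion.
#'
#' @param data data frame.
#' @param covariates character vector of categorical covariate names.
#' @param alpha retention threshold in (0, 1).
#' @param outcome binary outcome column name.
#' @return data frame `covariate`, `statistic`, `df`, `p_value`, `retained`.
#' @export
chi2_screen <- function(data, covariates, alpha = 0.20, outcome = "anaemic") {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  y <- data[[outcome]]
  rows <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    ok <- !is.na(x) & !is.na(y)
    tab <- table(x[ok], y[ok])
    if (nrow(tab) < 2L) {
      message("chi2_screen: '", nm, "' has a single observed level; excluded")
      return(data.frame(covariate = nm, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        retained = FALSE, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(covariate = nm, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = unname(ct$p.value),
               retained = unname(ct$p.value) <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
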