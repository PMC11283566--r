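#' Bray-Curtis similarity of each sample to a baseline set
#'
#' For each non-baseline sample, similarity is the mean (or median) over
#' baseline samples of `1 - d`, paired with the sample's day covariate —
#' the input of baseline-recovery regressions over a drought time course.
#'
#' @param dm distance matrix (dissimilarities in \[0,1\]).
#' @param metadata metadata with `sample_id` and `day`.
#' @param baseline_ids sample ids forming the baseline (e.g. the pre-drought
#'   samples of one treatment arm).
#' @param stat `"mean"` (default) or `"median"` aggregation over baseline
#'   samples.
#' @return data.frame: `sample_id`, `day`, `similarity`.
#' @export
similarity_to_baseline <- function(dm, metadata, baseline_ids,
                                   stat = c("mean", "median")) {
  stat <- match.arg(stat)
  dm <- as_dist_matrix(dm)
  baseline_ids <- intersect(baseline_ids, rownames(dm))
  if (length(baseline_ids) == 0) stop("baseline set is empty")
  others <- setdiff(rownames(dm), baseline_ids)
  md <- align_metadata(metadata, others)
  sim <- apply(1 - dm[others, baseline_ids, drop = FALSE], 1,
               if (stat == "mean") mean else median)
  data.frame(sample_id = others, day = md$day, similarity = unname(sim),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit of y on x
#'
#' Thin wrapper around [stats::lm()] returning the slope, intercept, R^2,
#' and the slope t-test p-value — the quantities read off the temporal
#' baseline-similarity and DNA-yield trend models (slope = rate of change,
#' intercept = magnitude).
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return list: `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least three complete observations")
  if (length(unique(x)) < 2) stop("x is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients[2, 4],
       n = length(x))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p on `K - 1` degrees of
#' freedom (wraps [stats::kruskal.test()]). All values tied gives `H = 0`,
#' `p = 1`.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Type-III ANOVA with sum-to-zero contrasts
#'
#' Fits a fixed-effects linear model under `contr.sum` contrasts (required
#' for type-III tests to be meaningful in unbalanced designs) and returns
#' per-term partial F tests via [car::Anova()].
#'
#' @param response numeric response vector.
#' @param data data.frame of factors.
#' @param formula_rhs right-hand side, e.g. `"planted * drought"`.
#' @return data.frame: `term`, `sum_of_squares`, `df`, `f_value`, `p_value`.
#' @export
anova_type3 <- function(response, data, formula_rhs) {
  df <- data.frame(.y = response, data, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", formula_rhs))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased coefficients: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  a <- car::Anova(fit, type = 3)
  keep <- !(rownames(a) %in% c("(Intercept)", "Residuals"))
  data.frame(term = rownames(a)[keep],
             sum_of_squares = a$`Sum Sq`[keep],
             df = a$Df[keep],
             f_value = a$`F value`[keep],
             p_value = a$`Pr(>F)`[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality statistic
#'
#' Royston's approximation via [stats::shapiro.test()], with the
#' conventional screening flag `normal = W > cutoff`.
#'
#' @param values numeric, `3 <= n <= 5000`.
#' @param cutoff W threshold (default 0.9).
#' @return list: `w`, `p_value`, `normal`.
#' @export
shapiro_w <- function(values, cutoff = 0.9) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  st <- shapiro.test(values)
  list(w = unname(st$statistic), p_value = st$p.value,
       normal = unname(st$statistic) > cutoff)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values with monotonicity enforcement (wraps
#' [stats::p.adjust()]).
#'
#' @param p_values numeric in \[0,1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
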