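#' Shapiro-Wilk normality test
#'
#' Thin wrapper with explicit input contracts: 3 <= n <= 5000 and a
#' non-degenerate sample (a constant sample has no defined W and errors).
#'
#' @param values numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (max(values) == min(values))
    stop("constant sample: W is undefined")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

## insert-and-absorb compact letter display from a pairwise significance
## matrix; deterministic in the group order supplied
cld_letters <- function(sig, means, labels) {
  k <- length(labels)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # letters assigned from the set containing the highest mean downwards;
  # ties broken by label order (the order of `labels`)
  ord <- order(vapply(sets, function(s) -max(means[s]), numeric(1)),
               vapply(sets, function(s) min(s), numeric(1)))
  sets <- sets[ord]
  lets <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  lets
}

#' One-way ANOVA with Fisher's protected LSD letters
#'
#' Omnibus one-way ANOVA; pairwise comparisons by Fisher's least significant
#' difference on the pooled mean-square error are performed only when the
#' omnibus F is significant at `alpha` (the protection rule), otherwise all
#' groups share one letter. Groups sharing a letter are not significantly
#' different.
#'
#' @param values numeric observations.
#' @param groups group labels (factor or character), >= 2 groups with >= 2
#'   observations each.
#' @param alpha significance level (default 0.05).
#' @return A `comparison_result`: list with `F`, `p`, `df`, per-group `table`
#'   (n, mean, sd, letters), the pairwise p matrix and `alpha`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("every group needs >= 2 observations")
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, sd)
  # textbook sums of squares
  grand <- mean(values)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- N - k
  mse <- ss_within / df2
  if (mse == 0) {
    Fstat <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
  } else {
    Fstat <- (ss_between / df1) / mse
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tstat <- (means[i] - means[j]) /
      sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    pw[i, j] <- pw[j, i] <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
  }
  sig <- if (is.finite(p) && p < alpha) pw < alpha
         else matrix(FALSE, k, k)
  sig[is.na(sig)] <- FALSE
  lets <- cld_letters(sig, as.numeric(means), levels(groups))
  structure(list(
    F = unname(Fstat), p = unname(p), df = c(df1, df2), mse = mse,
    table = data.frame(group = levels(groups), n = as.integer(ns),
                       mean = as.numeric(means), sd = as.numeric(sds),
                       letters = lets, stringsAsFactors = FALSE),
    pairwise_p = pw, alpha = alpha), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g (alpha = %g)\n",
              x$df[1], x$df[2], x$F, x$p, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations over complete pairs, two-sided p-values from
#' the t transform `t = r sqrt((n-2)/(1-r^2))`, and a significance flag at
#' `alpha`. Zero-variance variables give NA with a warning.
#'
#' @param tab numeric matrix or data frame, samples in rows, variables in
#'   columns.
#' @param alpha significance level for the flag matrix.
#' @return List with `r`, `p`, `sig`, `n`.
#' @export
pearson_matrix <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab)) stop("'tab' must be numeric")
  k <- ncol(tab)
  vnames <- colnames(tab)
  if (is.null(vnames)) vnames <- paste0("V", seq_len(k))
  sdev <- apply(tab, 2, sd, na.rm = TRUE)
  if (any(sdev == 0, na.rm = TRUE))
    warning("zero-variance variable(s): ",
            paste(vnames[which(sdev == 0)], collapse = ", "),
            "; correlations set to NA")
  r <- matrix(NA_real_, k, k, dimnames = list(vnames, vnames))
  p <- nmat <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(tab[, c(i, j)])
    n <- sum(ok)
    nmat[i, j] <- n
    if (i == j) { r[i, j] <- 1; next }
    if (n < 3 || sdev[i] == 0 || sdev[j] == 0) next
    rij <- cor(tab[ok, i], tab[ok, j])
    r[i, j] <- rij
    if (abs(rij) < 1) {
      tstat <- rij * sqrt((n - 2) / (1 - rij^2))
      p[i, j] <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    } else p[i, j] <- 0
  }
  list(r = r, p = p, sig = p < alpha, n = nmat)
}

#' Univariate least-squares regression with a confidence band
#'
#' Ordinary least squares of `y` on `x` with the two-sided slope test and the
#' pointwise confidence band for the mean response (narrowest at the mean of
#' x, the leverage property).
#'
#' @param x predictor, n >= 3, non-constant.
#' @param y response.
#' @param level band confidence level (default 0.95).
#' @param n_grid number of band evaluation points across the x range.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope), and
#'   `band` (data frame: x, fit, lwr, upr).
#' @export
univariate_regression <- function(x, y, level = 0.95, n_grid = 50) {
  if (length(x) < 3) stop("need n >= 3")
  if (max(x) == min(x)) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  grid <- data.frame(x = seq(min(x), max(x), length.out = n_grid))
  ci <- predict(fit, newdata = grid, interval = "confidence", level = level)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       band = data.frame(x = grid$x, fit = ci[, "fit"], lwr = ci[, "lwr"],
                         upr = ci[, "upr"]),
       fit = fit)
}
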