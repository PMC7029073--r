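# Group comparisons of pattern descriptors: two-factor MANOVA (Wilks'
# lambda), two-factor ANOVAs with interaction, Tukey-Kramer HSD and paired
# t-tests of target vs background.
#
# Designs are species (2 levels) x sex (2 levels) and typically
# unbalanced, so sums of squares are Type III with sum-to-zero contrasts:
# each term is adjusted for all others including the interaction, matching
# the conventions of mainstream commercial ANOVA software.

check_factor_frame <- function(frame, responses) {
  for (v in c("species", "sex"))
    if (!v %in% names(frame)) stopf("frame must contain a '%s' column", v)
  miss <- setdiff(responses, names(frame))
  if (length(miss)) stopf("missing response column(s): %s",
                          paste(miss, collapse = ", "))
  frame$species <- factor(frame$species)
  frame$sex <- factor(frame$sex)
  tab <- table(frame$species, frame$sex)
  if (any(tab == 0)) stopf("design error: empty species x sex cell")
  for (r in responses) {
    if (anyNA(frame[[r]]) || !is.numeric(frame[[r]]))
      stopf("response '%s' must be numeric without missing values", r)
  }
  frame
}

type3_lm <- function(frame, responses) {
  fml <- stats::as.formula(paste(
    if (length(responses) > 1)
      paste0("cbind(", paste(responses, collapse = ", "), ")")
    else responses,
    "~ species * sex"))
  lm(fml, data = frame,
     contrasts = list(species = "contr.sum", sex = "contr.sum"))
}

TERMS <- c("species", "sex", "species:sex")

#' Two-factor ANOVA with interaction (Type III)
#'
#' Fits `response ~ species * sex` with sum-to-zero contrasts and Type III
#' sums of squares, appropriate for unbalanced cohorts. With equal cell
#' sizes this reduces exactly to the classical balanced decomposition.
#'
#' @param frame data.frame with `species`, `sex` (2 levels each, all four
#'   cells nonempty, >= 2 observations per cell) and the response column.
#' @param response name of the response column.
#' @return an object of class `cq_anova`: data.frame with one row per term
#'   (`species`, `sex`, `species:sex`, `Residuals`) and columns `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(frame, response) {
  frame <- check_factor_frame(frame, response)
  if (any(table(frame$species, frame$sex) < 2))
    stopf("design error: need >= 2 observations per cell")
  y <- frame[[response]]
  if (var(y) == 0) {
    res <- data.frame(term = c(TERMS, "Residuals"),
                      df = c(1, 1, 1, nrow(frame) - 4),
                      sum_sq = 0, mean_sq = 0,
                      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA))
    return(structure(res, response = response,
                     class = c("cq_anova", "data.frame")))
  }
  frame$.y <- y
  mod <- type3_lm(frame, ".y")
  a3 <- car::Anova(mod, type = 3)
  keep <- rownames(a3) %in% c(TERMS, "Residuals")
  a3 <- a3[keep, ]
  res <- data.frame(term = rownames(a3),
                    df = a3$Df, sum_sq = a3$`Sum Sq`,
                    mean_sq = a3$`Sum Sq` / a3$Df,
                    F = a3$`F value`, p = a3$`Pr(>F)`)
  rownames(res) <- NULL
  structure(res, response = response, class = c("cq_anova", "data.frame"))
}

# Rao's F approximation to Wilks' lambda for p responses, q hypothesis df,
# v error df.
rao_f <- function(lambda, p, q, v) {
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * (v - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  Fv <- (1 - lam_s) / lam_s * df2 / df1
  list(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Two-factor MANOVA with Wilks' lambda
#'
#' Multivariate test of the species, sex and interaction terms on a set of
#' responses (typically the three log10 pattern descriptors). Uses Type III
#' hypothesis SSP matrices; for each term, Wilks'
#' `lambda = det(E) / det(E + H)` with Rao's F approximation.
#'
#' @param frame data.frame as in [two_way_anova()].
#' @param responses character vector of response column names.
#' @return an object of class `cq_manova`: data.frame with one row per term
#'   and columns `wilks_lambda`, `F_approx`, `df1`, `df2`, `p`.
#' @export
manova_wilks <- function(frame, responses) {
  frame <- check_factor_frame(frame, responses)
  p <- length(responses)
  if (p == 1) {
    # algebraic reduction: lambda = SSE / (SSE + SSH), F is the
    # univariate Type III F
    a <- two_way_anova(frame, responses)
    sse <- a$sum_sq[a$term == "Residuals"]
    vdf <- a$df[a$term == "Residuals"]
    rows <- lapply(TERMS, function(tm) {
      ssh <- a$sum_sq[a$term == tm]
      data.frame(term = tm, wilks_lambda = sse / (sse + ssh),
                 F_approx = a$F[a$term == tm], df1 = a$df[a$term == tm],
                 df2 = vdf, p = a$p[a$term == tm])
    })
    return(structure(do.call(rbind, rows), responses = responses,
                     class = c("cq_manova", "data.frame")))
  }
  mod <- type3_lm(frame, responses)
  mv <- tryCatch(car::Anova(mod, type = 3, test.statistic = "Wilks"),
                 error = function(e) stopf(
                   "multicollinearity error: %s", conditionMessage(e)))
  E <- mv$SSPE
  v <- mv$error.df
  if (v < p + 1) stopf("design error: need at least p + 1 error df")
  detE <- det(E)
  if (!is.finite(detE) || detE <= max(1e-12 * prod(diag(E)), 0))
    stopf("multicollinearity error: singular error SSP (collinear responses)")
  rows <- lapply(TERMS, function(tm) {
    H <- mv$SSP[[tm]]
    q <- mv$df[[tm]]
    lambda <- detE / det(E + H)
    rf <- rao_f(lambda, p, q, v)
    data.frame(term = tm, wilks_lambda = lambda, F_approx = rf$F,
               df1 = rf$df1, df2 = rf$df2, p = rf$p)
  })
  structure(do.call(rbind, rows), responses = responses,
            class = c("cq_manova", "data.frame"))
}

#' Tukey-Kramer honest significant differences
#'
#' Pairwise comparisons of the species-by-sex cell means using the
#' studentized range distribution, with the error stratum of the full
#' two-factor model with interaction (identical to the one-way cell-means
#' model). Unequal cell sizes use the Tukey-Kramer standard error. A
#' compact letter display is derived from the significance graph: groups
#' sharing a letter are not significantly different.
#'
#' @param values numeric response vector.
#' @param groups factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 observations each.
#' @param alpha familywise error rate.
#' @return an object of class `cq_tukey`: list with `comparisons`
#'   (data.frame: `contrast`, `difference`, `se`, `q`, `p_adj`, `lwr`,
#'   `upr`) and `letters` (named character vector).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("design error: need >= 2 groups")
  if (any(table(groups) < 2))
    stopf("design error: need >= 2 observations per group")
  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  mse <- sum(fit$residuals^2) / fit$df.residual
  ns <- table(groups)
  cons <- strsplit(rownames(tk), "-", fixed = TRUE)
  se <- vapply(cons, function(pr)
    sqrt(mse / 2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]])), numeric(1))
  comparisons <- data.frame(
    contrast = rownames(tk),
    difference = tk[, "diff"], se = se,
    q = abs(tk[, "diff"]) / se,
    p_adj = tk[, "p adj"], lwr = tk[, "lwr"], upr = tk[, "upr"])
  rownames(comparisons) <- NULL
  letters_out <- letter_display(levels(groups), cons,
                                comparisons$p_adj < alpha,
                                tapply(values, groups, mean))
  structure(list(comparisons = comparisons, letters = letters_out,
                 alpha = alpha),
            class = "cq_tukey")
}

# Compact letter display: order groups by mean, find maximal runs of
# mutually non-significant groups, assign one letter per run.
letter_display <- function(lev, pairs, sig, means) {
  k <- length(lev)
  sig_mat <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    sig_mat[a, b] <- sig_mat[b, a] <- sig[i]
  }
  ord <- names(sort(means))
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig_mat[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1
    runs[[length(runs) + 1L]] <- ord[i:j]
  }
  # drop runs contained in an earlier/larger run
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    if (i != j && keep[j] && all(runs[[i]] %in% runs[[j]]) &&
        length(runs[[i]]) < length(runs[[j]])) keep[i] <- FALSE
  }
  runs <- unique(runs[keep])
  out <- setNames(rep("", k), lev)
  for (i in seq_along(runs))
    out[runs[[i]]] <- paste0(out[runs[[i]]], letters[i])
  out
}

#' Paired t-test of target vs background values
#'
#' Two-sided paired t-test, e.g. of a log10 pattern descriptor measured on
#' each animal and on its own background patch.
#'
#' @param target_values,background_values equal-length numeric vectors
#'   (paired by individual, n >= 2).
#' @return an object of class `cq_paired_t`: list with `mean_target`,
#'   `mean_background`, `se_target`, `se_background`, `t`, `df`, `p`, `n`.
#' @export
paired_t <- function(target_values, background_values) {
  n <- length(target_values)
  if (length(background_values) != n)
    stopf("paired vectors must have equal length")
  if (n < 2) stopf("need at least 2 pairs")
  d <- target_values - background_values
  if (var(d) <= 0)
    stopf("degenerate error: zero variance of paired differences")
  ht <- t.test(target_values, background_values, paired = TRUE)
  structure(list(
    mean_target = mean(target_values),
    mean_background = mean(background_values),
    se_target = sd(target_values) / sqrt(n),
    se_background = sd(background_values) / sqrt(n),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, n = n), class = "cq_paired_t")
}
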