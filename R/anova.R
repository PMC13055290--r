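#' Treatment contrasts by one-way and two-way ANOVA with Tukey HSD
#'
#' One-way ANOVA across all treatment levels plus, where both factors are
#' supplied and form crossed cells, a two-way ANOVA on N rate x Fe amendment
#' (crossed subset only; uncrossed treatments such as a lone 100%N control
#' are kept in the one-way analysis and dropped from the two-way). Pairwise
#' Tukey HSD comparisons are flagged with the conventional star codes
#' (*, **, *** at 0.05 / 0.01 / 0.001).
#'
#' @param values plot-level data frame; one row per plot.
#' @param response name of the numeric response column.
#' @param treatment name of the treatment factor column (one-way analysis).
#' @param n_rate,fe optional column names for the two crossed factors.
#' @param alpha significance level for Tukey flags.
#' @return An object of class `treatment_anova`: list with `oneway` (F, df, p),
#'   `tukey` (tibble of pairwise contrasts), and `twoway` (tibble of main and
#'   interaction effects, or NULL). Has `tidy()` and `glance()` methods.
#' @export
compare_treatments <- function(values, response, treatment = "treatment",
                               n_rate = NULL, fe = NULL, alpha = 0.05) {
  if (!response %in% names(values)) abort(paste0("no column `", response, "`"))
  if (!treatment %in% names(values)) abort(paste0("no column `", treatment, "`"))
  y <- values[[response]]
  g <- factor(values[[treatment]])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(sizes) < 2) abort("need at least 2 treatment groups")
  if (length(small)) {
    abort(paste0("groups with fewer than 2 replicates: ", paste(small, collapse = ", ")))
  }
  fit1 <- aov(y ~ g)
  a1 <- summary(fit1)[[1]]
  oneway <- tibble::tibble(
    term = "treatment",
    df = a1[1, "Df"], f_statistic = a1[1, "F value"], p_value = a1[1, "Pr(>F)"]
  )
  tk <- TukeyHSD(fit1, conf.level = 1 - alpha)$g
  tukey <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    signif = stars(tk[, "p adj"])
  )
  twoway <- NULL
  if (!is.null(n_rate) && !is.null(fe)) {
    fN <- factor(values[[n_rate]])
    fF <- factor(values[[fe]])
    cells <- table(fN, fF)
    crossed_n <- rownames(cells)[apply(cells >= 2, 1, all)]
    keep <- fN %in% crossed_n
    if (length(crossed_n) >= 2 && nlevels(droplevels(fF[keep])) >= 2) {
      d2 <- data.frame(y = y[keep], N = droplevels(fN[keep]), Fe = droplevels(fF[keep]))
      a2 <- summary(aov(y ~ N * Fe, data = d2))[[1]]
      terms <- trimws(rownames(a2))
      ok <- terms != "Residuals"
      twoway <- tibble::tibble(
        term = c("N_rate", "Fe", "N_rate:Fe")[seq_len(sum(ok))],
        df = a2[ok, "Df"], f_statistic = a2[ok, "F value"], p_value = a2[ok, "Pr(>F)"]
      )
    }
  }
  structure(list(oneway = oneway, tukey = tukey, twoway = twoway,
                 response = response, alpha = alpha),
            class = "treatment_anova")
}

stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "N.S.")
}

#' @export
print.treatment_anova <- function(x, ...) {
  cat("Treatment ANOVA on `", x$response, "`\n", sep = "")
  cat("One-way: F =", signif(x$oneway$f_statistic, 4),
      " p =", signif(x$oneway$p_value, 4), "\n")
  if (!is.null(x$twoway)) {
    cat("Two-way (crossed subset):\n")
    print(as.data.frame(x$twoway), row.names = FALSE)
  }
  cat("Tukey HSD contrasts:\n")
  print(as.data.frame(x$tukey), row.names = FALSE)
  invisible(x)
}

#' @rdname compare_treatments
#' @param x a `treatment_anova` object.
#' @param ... unused.
#' @method tidy treatment_anova
#' @export
tidy.treatment_anova <- function(x, ...) x$tukey

#' @rdname compare_treatments
#' @method glance treatment_anova
#' @export
glance.treatment_anova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$oneway, analysis = "one-way"),
    if (!is.null(x$twoway)) dplyr::mutate(x$twoway, analysis = "two-way")
  )
}
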