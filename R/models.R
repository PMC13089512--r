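# Linear mixed models with the Condition x Session x StimulusType factorial
# structure and the nine Bonferroni-corrected planned comparisons following a
# significant Condition x Session interaction. Estimation is delegated to
# lme4/lmerTest (Satterthwaite denominator degrees of freedom); the bespoke
# content is the contrast scheme, its adjustment, and the reporting hierarchy.

#' Fit the factorial mixed model and run the planned-contrast scheme
#'
#' Fits `outcome ~ condition * session * stimulus_type` with a random
#' intercept per participant and, for reactivity outcomes measured per
#' stimulus, a crossed random intercept per stimulus ID. F-tests use
#' Satterthwaite degrees of freedom. The nine planned comparisons are the
#' within-condition session pairs (T0 vs T1, T0 vs T2, T1 vs T2 in each
#' condition) and the between-condition comparison at each session, averaged
#' over stimulus type; their p-values are Bonferroni-multiplied by 9 (capped
#' at 1). Contrasts are computed unconditionally but the reporting hierarchy
#' is recorded: the Condition x Session interaction is interpretable only in
#' the absence of a significant three-way interaction, and the contrasts only
#' when the two-way interaction is significant.
#'
#' If the full random structure yields a singular fit, the model is refitted
#' without the stimulus intercept and the fallback is logged.
#'
#' @param data Long tibble with columns `condition` (CTR/FRG), `session`
#'   (T0/T1/T2), `stimulus_type` (negative/neutral), `subject`, optionally
#'   `stimulus_id`, and the outcome.
#' @param outcome Name of the outcome column (string).
#' @param stimulus_random Include a stimulus-ID random intercept? Default:
#'   yes when a `stimulus_id` column is present.
#' @param alpha Significance level for the hierarchy flags (default 0.05).
#' @return An object of class `lmm_contrasts`: the fitted model, `anova`
#'   (F-table tibble), `contrasts` (9-row tibble with `p_adj`),
#'   `interaction_p`, `three_way_p`, `hierarchy` notes, `singular_fallback`.
#' @export
fit_and_contrast <- function(data, outcome, stimulus_random = NULL,
                             alpha = 0.05) {
  abort_if(!outcome %in% names(data), paste0("no column '", outcome, "' in data"))
  need <- c("condition", "session", "stimulus_type", "subject")
  abort_if(!all(need %in% names(data)),
           paste("data needs columns:", paste(need, collapse = ", ")))
  for (v in need) data[[v]] <- factor(data[[v]])
  abort_if(any(vapply(data[need[1:3]], nlevels, integer(1)) < 2),
           "each fixed factor needs at least two levels")
  if (is.null(stimulus_random)) stimulus_random <- "stimulus_id" %in% names(data)

  rand <- "(1 | subject)"
  if (stimulus_random) {
    abort_if(!"stimulus_id" %in% names(data),
             "stimulus_random = TRUE requires a stimulus_id column")
    data$stimulus_id <- factor(data$stimulus_id)
    rand <- paste(rand, "+ (1 | stimulus_id)")
  }
  form <- stats::as.formula(paste(
    outcome, "~ condition * session * stimulus_type +", rand))
  fit <- lmerTest::lmer(form, data = data)
  singular_fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4) && stimulus_random) {
    singular_fallback <- TRUE
    form <- stats::as.formula(paste(
      outcome, "~ condition * session * stimulus_type + (1 | subject)"))
    fit <- lmerTest::lmer(form, data = data)
  }

  an <- as.data.frame(anova(fit))  # lmerTest: Satterthwaite, type III
  an_tbl <- tibble::tibble(
    term = rownames(an), sum_sq = an$`Sum Sq`, df1 = an$NumDF, df2 = an$DenDF,
    f = an$`F value`, p = an$`Pr(>F)`
  )
  p_of <- function(term) {
    i <- match(term, an_tbl$term)
    if (is.na(i)) NA_real_ else an_tbl$p[i]
  }
  interaction_p <- p_of("condition:session")
  three_way_p <- p_of("condition:session:stimulus_type")

  # cell-mean rows of the fixed-effect design, averaged over stimulus type
  full_grid <- tidyr::expand_grid(
    condition = factor(levels(data$condition), levels(data$condition)),
    session = factor(levels(data$session), levels(data$session)),
    stimulus_type = factor(levels(data$stimulus_type),
                           levels(data$stimulus_type))
  )
  X <- stats::model.matrix(lme4::nobars(form)[-2], full_grid)
  cell <- interaction(full_grid$condition, full_grid$session, sep = ":")
  G <- rowsum(X, cell) / as.vector(table(cell))
  gvec <- function(cn, sn) G[paste(cn, sn, sep = ":"), ]

  conds <- levels(data$condition)
  sess <- levels(data$session)
  meth <- list()
  for (cn in conds) {
    for (pair in utils::combn(sess, 2, simplify = FALSE)) {
      meth[[sprintf("%s: %s - %s", cn, pair[1], pair[2])]] <-
        gvec(cn, pair[1]) - gvec(cn, pair[2])
    }
  }
  for (sn in sess) {
    meth[[sprintf("%s: %s - %s", sn, conds[1], conds[2])]] <-
      gvec(conds[1], sn) - gvec(conds[2], sn)
  }
  n_ct <- length(meth)
  contrasts <- purrr::imap(meth, function(L, nm) {
    ct <- lmerTest::contest1D(fit, L, ddf = "Satterthwaite")
    tibble::tibble(contrast = nm, estimate = ct$Estimate,
                   se = ct$`Std. Error`, df = ct$df, t = ct$`t value`,
                   p = ct$`Pr(>|t|)`)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(p_adj = pmin(1, .data$p * n_ct))

  hierarchy <- c(
    if (!is.na(three_way_p) && three_way_p < alpha)
      "three-way interaction significant: interpret Condition x Session with caution",
    if (!is.na(interaction_p) && interaction_p >= alpha)
      "Condition x Session interaction not significant: planned contrasts are exploratory"
  )

  structure(list(fit = fit, anova = an_tbl, contrasts = contrasts,
                 outcome = outcome, interaction_p = interaction_p,
                 three_way_p = three_way_p, alpha = alpha,
                 hierarchy = hierarchy %||% character(0),
                 singular_fallback = singular_fallback,
                 df_method = "Satterthwaite"),
            class = "lmm_contrasts")
}

#' @export
print.lmm_contrasts <- function(x, ...) {
  cat(sprintf("<lmm_contrasts> outcome: %s (df: %s%s)\n", x$outcome,
              x$df_method,
              if (x$singular_fallback) "; stimulus intercept dropped (singular)" else ""))
  cat("\nF-tests:\n"); print(as.data.frame(x$anova), digits = 4)
  cat("\nPlanned contrasts (Bonferroni x", nrow(x$contrasts), "):\n")
  print(as.data.frame(x$contrasts), digits = 4)
  for (h in x$hierarchy) cat("note:", h, "\n")
  invisible(x)
}

#' @export
#' @rdname fit_and_contrast
#' @param x An `lmm_contrasts` object.
#' @param ... Unused.
tidy.lmm_contrasts <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                 std.error = co[, "Std. Error"], df = co[, "df"],
                 statistic = co[, "t value"], p.value = co[, "Pr(>|t|)"])
}

#' @export
#' @rdname fit_and_contrast
glance.lmm_contrasts <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    n_obs = stats::nobs(x$fit),
    aic = stats::AIC(x$fit),
    logLik = as.numeric(stats::logLik(x$fit)),
    interaction_p = x$interaction_p,
    three_way_p = x$three_way_p,
    singular_fallback = x$singular_fallback
  )
}
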