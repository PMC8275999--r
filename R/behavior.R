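# Behavioral self-bias scoring and psychometric prediction of mediation
# subgroup membership.

#' Self-bias score of a trial table
#'
#' Proportion of all trials on which either a positive item was endorsed
#' (valence +1, response +1) or a negative item was rejected (valence -1,
#' response -1). Neutral trials never enter the numerator but stay in the
#' denominator, so a balanced 25/25/25 design bounds the score at
#' 50/75 = 0.67.
#'
#' @param trial_table Data frame with `valence` (-1/0/+1) and `response`
#'   (-1/+1) columns.
#' @return The score (proportion in [0, 2/3] for balanced designs).
#' @export
self_bias_score <- function(trial_table) {
  if (!nrow(trial_table)) stop("empty trial table")
  v <- trial_table$valence
  r <- trial_table$response
  if (anyNA(r)) stop("trial table has missing responses")
  (sum(v == 1 & r == 1) + sum(v == -1 & r == -1)) / nrow(trial_table)
}

#' Input-output correlation (Fisher z)
#'
#' Pearson correlation between trial-wise stimulus valence and the binary
#' endorsement response, Fisher z-transformed (atanh). Positive values
#' indicate positive self-bias.
#'
#' @param X Valence codes (-1/0/+1).
#' @param Y Response codes (-1/+1).
#' @return List `r` (raw Pearson correlation) and `z` (atanh(r)).
#' @export
ioc <- function(X, Y) {
  if (length(X) != length(Y)) stop("X and Y must have equal length")
  if (stats::sd(X) == 0 || stats::sd(Y) == 0)
    stop("degenerate input: constant valence or response vector")
  r <- stats::cor(X, Y)
  list(r = r, z = atanh(r))
}

#' Predict subgroup membership from psychometric features
#'
#' Binary logistic regression of a subgroup indicator on candidate
#' predictors. The default mode is forward stepwise selection: at each step
#' the candidate with the smallest likelihood-ratio p-value enters if that
#' p-value is below `entry_p`; selection stops otherwise. `mode = "full"`
#' fits all candidates at once; `mode = "fixed"` fits exactly `predictors`.
#' Reported per retained predictor: coefficient B (log-odds), odds ratio
#' exp(B), and Wald p. Classification accuracy uses a 0.5 probability cut.
#' Complete separation (divergent coefficients) is flagged as
#' non-converged.
#'
#' @param features Data frame of numeric candidate predictors.
#' @param labels Binary outcome (0/1, logical, or two-level factor).
#' @param mode `"stepwise"` (default), `"full"`, or `"fixed"`.
#' @param entry_p Likelihood-ratio entry threshold for stepwise mode.
#' @param predictors Predictor names for `mode = "fixed"`.
#' @return Object of class `group_logit`: `table` (data frame `predictor`,
#'   `B`, `odds_ratio`, `p`), `percent_correct`, `converged`, `model`
#'   (the final `glm`), `n`.
#' @export
predict_group_membership <- function(features, labels,
                                     mode = c("stepwise", "full", "fixed"),
                                     entry_p = 0.05, predictors = NULL) {
  mode <- match.arg(mode)
  features <- as.data.frame(features)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (anyNA(y)) stop("labels contain missing values")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  n <- length(y)
  if (nrow(features) != n) stop("features and labels disagree in length")
  dat <- cbind(.y = y, features)

  fit_formula <- function(vars) {
    f <- if (length(vars)) stats::reformulate(vars, ".y") else .y ~ 1
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  }

  selected <- switch(mode,
    fixed = {
      if (is.null(predictors)) stop("mode = 'fixed' requires predictors")
      predictors
    },
    full = names(features),
    stepwise = {
      sel <- character(0)
      cand <- names(features)
      current <- fit_formula(sel)
      repeat {
        if (!length(cand) || length(sel) + 2 > n) break
        pvals <- vapply(cand, function(v) {
          trial <- fit_formula(c(sel, v))
          an <- stats::anova(current, trial, test = "Chisq")
          p <- an$`Pr(>Chi)`[2]
          if (is.na(p)) 1 else p
        }, numeric(1))
        best <- which.min(pvals)
        if (pvals[best] >= entry_p) break
        sel <- c(sel, cand[best])
        cand <- cand[-best]
        current <- fit_formula(sel)
      }
      sel
    })

  model <- fit_formula(selected)
  converged <- model$converged &&
    !any(abs(stats::coef(model)[-1]) > 15, na.rm = TRUE) &&
    !any(model$fitted.values > 1 - 1e-8 | model$fitted.values < 1e-8)
  sm <- summary(model)$coefficients
  if (length(selected)) {
    rows <- match(selected, rownames(sm))
    tab <- data.frame(predictor = selected,
                      B = sm[rows, "Estimate"],
                      odds_ratio = exp(sm[rows, "Estimate"]),
                      p = sm[rows, "Pr(>|z|)"])
  } else {
    tab <- data.frame(predictor = character(0), B = numeric(0),
                      odds_ratio = numeric(0), p = numeric(0))
  }
  rownames(tab) <- NULL
  pc <- 100 * mean((model$fitted.values > 0.5) == (y == 1))
  structure(list(table = tab, percent_correct = pc, converged = converged,
                 model = model, n = n, mode = mode),
            class = "group_logit")
}

#' @export
print.group_logit <- function(x, digits = 3, ...) {
  cat("Subgroup membership logistic regression (", x$mode, ", n = ", x$n,
      ")\n", sep = "")
  if (nrow(x$table)) print(round_df <- transform(x$table,
                                                 B = round(B, digits),
                                                 odds_ratio = round(odds_ratio, digits),
                                                 p = round(p, 4)))
  else cat("  no predictor entered the model\n")
  cat("  correctly classified: ", round(x$percent_correct, 1), "%",
      if (!x$converged) "  [non-converged / separation]", "\n", sep = "")
  invisible(x)
}
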