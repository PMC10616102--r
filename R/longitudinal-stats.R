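# Statistical stages: within/between-person age decomposition, adversity
# factor extraction by PCA, and longitudinal linear mixed models.

#' Decompose age into cross-sectional and longitudinal components
#'
#' For participant i at visit j: cross-sectional age is the participant's
#' mean age minus the sample mean of participant means; longitudinal age is
#' the visit age minus the participant's own mean age.  The decomposition is
#' exact: `age_ij = sample_mean + cross_sectional_i + longitudinal_ij`.
#'
#' @param data Long-format data frame, one row per subject-visit.
#' @param age_col,subject_col Column names.
#' @return `data` with added columns `cross_sectional_age` and
#'   `longitudinal_age`, plus attribute `sample_mean_age`.
#' @export
#' @examples
#' d <- data.frame(subject_id = c("a", "a", "b"), age = c(14, 15.5, 22))
#' decompose_age(d)
decompose_age <- function(data, age_col = "age", subject_col = "subject_id") {
  if (!age_col %in% names(data) || !subject_col %in% names(data)) {
    stop("data must contain columns '", age_col, "' and '", subject_col, "'")
  }
  ages <- data[[age_col]]
  if (anyNA(ages)) {
    bad <- unique(data[[subject_col]][is.na(ages)])
    warning("dropping subject(s) with missing ages: ",
            paste(bad, collapse = ", "))
    data <- data[!data[[subject_col]] %in% bad, , drop = FALSE]
    ages <- data[[age_col]]
  }
  if (any(ages <= 0)) stop("ages must be positive")
  subj <- as.character(data[[subject_col]])
  subj_mean <- tapply(ages, subj, mean)
  sample_mean <- mean(subj_mean)
  data$cross_sectional_age <- as.numeric(subj_mean[subj] - sample_mean)
  data$longitudinal_age <- ages - as.numeric(subj_mean[subj])
  attr(data, "sample_mean_age") <- sample_mean
  data
}

#' Family-adversity factor by principal component analysis
#'
#' Standardizes each questionnaire subscale to mean 0 / sd 1, extracts the
#' first principal component, and orients it so that higher scores denote
#' greater self-reported family adversity: the mean loading on the
#' adversity-coded subscales (all columns not listed in `positive_cols`) is
#' made positive.
#'
#' @param subscales Data frame or matrix of subscale totals (rows =
#'   subjects, >= 3; columns = subscales, >= 2; no constant column).
#' @param positive_cols Names of subscales coding positive family
#'   experiences (expected to load opposite to the adversity pole).
#' @return List of class `adversity_factor`: standardized `scores` (mean 0),
#'   `loadings`, `explained` variance share of the first component, and
#'   `center`/`scale` used.
#' @export
adversity_factor <- function(subscales, positive_cols = character(0)) {
  x <- as.matrix(subscales)
  if (ncol(x) < 2L) stop("need at least 2 subscales")
  if (nrow(x) < 3L) stop("need at least 3 subjects")
  if (anyNA(x)) stop("subscale table contains missing values")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant subscale column(s): ",
         paste(colnames(x)[sds < 1e-12], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1L]
  scores <- pc$x[, 1L]
  adversity_cols <- setdiff(colnames(x), positive_cols)
  if (length(adversity_cols) == 0L) {
    stop("at least one adversity-coded subscale is required")
  }
  if (mean(load1[adversity_cols]) < 0) {
    load1 <- -load1
    scores <- -scores
  }
  structure(
    list(scores = as.numeric(scores), loadings = load1,
         explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
         center = pc$center, scale = pc$scale),
    class = "adversity_factor"
  )
}

#' @export
#' @method print adversity_factor
print.adversity_factor <- function(x, ...) {
  cat("<adversity_factor> first component explains",
      sprintf("%.1f%%", 100 * x$explained), "of variance\n loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Longitudinal linear mixed model
#'
#' Fits `outcome ~ fixed terms + interactions + (1 | subject)` by REML with
#' Satterthwaite approximate degrees of freedom (via lmerTest).  Continuous
#' predictors are centred on zero and categorical predictors effect-coded
#' (sum contrasts) before fitting.  Covers the study designs: trust outcomes
#' on longitudinal x cross-sectional age plus sex (optionally trial number),
#' the same plus adversity and its two-way interactions, and friendship
#' scores on baseline trust x longitudinal age x adversity plus sex.
#'
#' @param data Long-format data frame.
#' @param outcome Outcome column name.
#' @param fixed Character vector of fixed-effect column names.
#' @param interactions List of character vectors, each an interaction term
#'   (e.g. `list(c("longitudinal_age", "cross_sectional_age"))`).
#' @param random Random-effects formula fragment; default
#'   `"(1 | subject_id)"` (random intercepts); random slopes can be
#'   requested, e.g. `"(1 + longitudinal_age | subject_id)"`.
#' @param center Centre continuous predictors (default TRUE).
#' @param quadratic_age Add a squared cross-sectional age term (off by
#'   default).
#' @param reml Fit by REML (default) or ML.
#' @return Object of class `model_output`: `fixed` (data frame with
#'   estimate, se, df, t, p per fixed effect), `ranef_variances`, `formula`,
#'   and the underlying `fit`.
#' @export
fit_longitudinal_model <- function(data, outcome, fixed,
                                   interactions = list(),
                                   random = "(1 | subject_id)",
                                   center = TRUE, quadratic_age = FALSE,
                                   reml = TRUE) {
  need <- unique(c(outcome, fixed, unlist(interactions)))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(data)
  preds <- unique(c(fixed, unlist(interactions)))
  for (nm in preds) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
    if (is.factor(df[[nm]])) {
      stats::contrasts(df[[nm]]) <- stats::contr.sum(nlevels(df[[nm]]))
    } else if (center) {
      df[[nm]] <- df[[nm]] - mean(df[[nm]], na.rm = TRUE)
    }
  }
  if (quadratic_age) {
    if (!"cross_sectional_age" %in% names(df)) {
      stop("quadratic_age requires a cross_sectional_age column")
    }
    df$cross_sectional_age_sq <- df$cross_sectional_age^2
    fixed <- c(fixed, "cross_sectional_age_sq")
  }
  terms_ <- c(fixed, vapply(interactions, paste, character(1), collapse = ":"))
  fml <- stats::as.formula(paste(outcome, "~", paste(terms_, collapse = " + "),
                                 "+", random))
  # detect singular fixed-effect designs up front and name the culprits
  fe_fml <- stats::as.formula(paste(outcome, "~",
                                    paste(terms_, collapse = " + ")))
  mm <- stats::model.matrix(fe_fml, df)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lmerTest::lmer(fml, data = df, REML = reml)
  sm <- summary(fit)$coefficients
  fixed_tab <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    df = sm[, "df"],
    t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(fixed = fixed_tab, ranef_variances = vc, formula = fml, fit = fit),
    class = "model_output"
  )
}

#' @export
#' @method print model_output
print.model_output <- function(x, ...) {
  cat("<model_output>", deparse(x$formula), "\n")
  tab <- x$fixed
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$df <- round(tab$df, 1)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
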