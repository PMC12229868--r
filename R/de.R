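#' Fit the hierarchical differential-abundance model
#'
#' Fits one linear mixed model across all proteins at once: NPX is modelled
#' by protein, group and their interaction as fixed effects, adjusted for
#' age, sex and BMI, with a random per-person intercept that absorbs
#' person-level technical and biological offsets shared across the panel.
#' Age and BMI are mean-centered before fitting so the group contrast is
#' evaluated at average covariates. Below-LOD (missing) cells are simply
#' dropped from the likelihood.
#'
#' Two pooling modes are offered because "protein-specific group effect" can
#' be parameterized either way: `fixed_interaction` (default) estimates each
#' protein x group interaction as a fixed effect; `shrunken_interaction`
#' instead models the protein-specific group effect as a random slope over
#' proteins, partially pooling the contrasts toward the panel-average group
#' effect.
#'
#' @param data long tibble with columns `person_id`, `assay_id`, `npx`
#'   (one value per person x protein; `NA` allowed).
#' @param samples sample metadata (person_id, group, age, sex, bmi).
#' @param pooling_mode `"fixed_interaction"` or `"shrunken_interaction"`.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param heteroscedastic when `TRUE` (fixed_interaction only), allows a
#'   separate residual variance per protein via a variance-function GLS fit;
#'   default `FALSE` uses a single shared residual variance.
#' @return an object of class `npx_de_fit`; use [extract_group_contrasts()]
#'   or `tidy()` for per-protein fold changes, `glance()` for variance
#'   components.
#' @export
fit_hierarchical_model <- function(data, samples,
                                   pooling_mode = c("fixed_interaction",
                                                    "shrunken_interaction"),
                                   estimation = c("REML", "ML"),
                                   heteroscedastic = FALSE) {
  pooling_mode <- match.arg(pooling_mode)
  estimation <- match.arg(estimation)
  df <- data |>
    dplyr::select("person_id", "assay_id", "npx") |>
    dplyr::left_join(samples, by = "person_id") |>
    dplyr::filter(!is.na(.data$npx))
  if (!all(c("control", "OA") %in% df$group)) {
    stop("both groups (control, OA) must be present")
  }
  if (length(unique(df$person_id)) < 4) stop("need >= 2 persons per group")

  one_group <- df |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$group), .groups = "drop") |>
    dplyr::filter(.data$k < 2)
  if (nrow(one_group)) {
    stop("protein(s) observed in only one group (singular design): ",
         paste(one_group$assay_id, collapse = ", "))
  }

  df <- df |>
    dplyr::mutate(
      protein = factor(.data$assay_id, levels = sort(unique(.data$assay_id))),
      group = factor(.data$group, levels = c("control", "OA")),
      case = as.numeric(.data$group == "OA"),
      sex = factor(.data$sex),
      age_c = .data$age - mean(.data$age),
      bmi_c = .data$bmi - mean(.data$bmi),
      person_id = factor(.data$person_id)
    )
  covar_terms <- c("age_c", if (nlevels(df$sex) > 1) "sex", "bmi_c")
  covar_rhs <- paste(covar_terms, collapse = " + ")

  reml <- estimation == "REML"
  if (pooling_mode == "fixed_interaction" && heteroscedastic) {
    model <- nlme::lme(
      stats::as.formula(paste("npx ~ protein * group +", covar_rhs)),
      random = ~ 1 | person_id,
      weights = nlme::varIdent(form = ~ 1 | protein),
      data = df, method = estimation,
      control = nlme::lmeControl(opt = "optim")
    )
    engine <- "nlme"; converged <- TRUE
  } else if (pooling_mode == "fixed_interaction") {
    model <- lme4::lmer(
      stats::as.formula(paste("npx ~ protein * group +", covar_rhs,
                              "+ (1 | person_id)")),
      data = df, REML = reml,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    )
    engine <- "lme4"
    converged <- length(model@optinfo$conv$lme4$messages) == 0
  } else {
    model <- lme4::lmer(
      stats::as.formula(paste("npx ~ protein + case +", covar_rhs,
                              "+ (1 | person_id) + (0 + case | protein)")),
      data = df, REML = reml,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    )
    engine <- "lme4"
    converged <- length(model@optinfo$conv$lme4$messages) == 0
  }

  structure(list(
    model = model,
    engine = engine,
    pooling_mode = pooling_mode,
    heteroscedastic = heteroscedastic,
    estimation = estimation,
    proteins = levels(df$protein),
    reference_protein = levels(df$protein)[1],
    converged = converged,
    n_obs = nrow(df),
    n_persons = nlevels(df$person_id)
  ), class = "npx_de_fit")
}

de_fixef <- function(fit) {
  if (fit$engine == "nlme") nlme::fixef(fit$model) else lme4::fixef(fit$model)
}

de_vcov <- function(fit) as.matrix(stats::vcov(fit$model))

#' Per-protein group contrasts with fold-change confidence intervals
#'
#' Extracts, for every protein, the estimated case-minus-control difference
#' on the log2 scale (`delta_log2` = group main effect + that protein's
#' interaction term; the reference protein carries the main effect alone),
#' its Wald 95% confidence interval with normal critical values, and the
#' corresponding fold change `2^delta_log2` with CI obtained by
#' exponentiation. `direction` is `up`/`down` when the CI excludes 0 and
#' `inconclusive` otherwise. No multiplicity correction is applied.
#'
#' @param fit an `npx_de_fit` from [fit_hierarchical_model()].
#' @param conf_level confidence level, default 0.95.
#' @return tibble: protein, delta_log2, se, ci_low, ci_high, fold_change,
#'   fc_ci_low, fc_ci_high, direction.
#' @export
extract_group_contrasts <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "npx_de_fit"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  proteins <- fit$proteins
  beta <- de_fixef(fit)
  if (fit$pooling_mode == "fixed_interaction") {
    V <- de_vcov(fit)
    gname <- "groupOA"
    delta <- se <- setNames(numeric(length(proteins)), proteins)
    for (pr in proteins) {
      iname <- paste0("protein", pr, ":groupOA")
      if (pr == fit$reference_protein || !(iname %in% names(beta))) {
        delta[pr] <- beta[[gname]]
        se[pr] <- sqrt(V[gname, gname])
      } else {
        delta[pr] <- beta[[gname]] + beta[[iname]]
        se[pr] <- sqrt(V[gname, gname] + V[iname, iname] +
                         2 * V[gname, iname])
      }
    }
  } else {
    V <- de_vcov(fit)
    re <- lme4::ranef(fit$model, condVar = TRUE)$protein
    u <- setNames(re[, "case"], rownames(re))
    pv <- attr(re, "postVar")
    cvar <- setNames(as.numeric(pv[1, 1, ]), rownames(re))
    delta <- beta[["case"]] + u[proteins]
    # approximate: fixed-effect variance plus BLUP conditional variance
    se <- sqrt(V["case", "case"] + cvar[proteins])
    names(delta) <- names(se) <- proteins
  }
  res <- tibble::tibble(
    protein = proteins,
    delta_log2 = unname(delta),
    se = unname(se),
    ci_low = unname(delta - z * se),
    ci_high = unname(delta + z * se)
  ) |>
    dplyr::mutate(
      fold_change = 2^.data$delta_log2,
      fc_ci_low = 2^.data$ci_low,
      fc_ci_high = 2^.data$ci_high,
      direction = dplyr::case_when(
        .data$ci_low > 0 ~ "up",
        .data$ci_high < 0 ~ "down",
        TRUE ~ "inconclusive"
      )
    )
  res
}

#' @exportS3Method generics::tidy
tidy.npx_de_fit <- function(x, conf_level = 0.95, ...) {
  extract_group_contrasts(x, conf_level = conf_level)
}

#' @exportS3Method generics::glance
glance.npx_de_fit <- function(x, ...) {
  if (x$engine == "lme4") {
    vc <- as.data.frame(lme4::VarCorr(x$model))
    person_sd <- vc$sdcor[vc$grp == "person_id"][1]
    resid_sd <- vc$sdcor[vc$grp == "Residual"][1]
  } else {
    person_sd <- as.numeric(nlme::VarCorr(x$model)["(Intercept)", "StdDev"])
    resid_sd <- x$model$sigma
  }
  tibble::tibble(
    pooling_mode = x$pooling_mode,
    estimation = x$estimation,
    person_sd = person_sd,
    residual_sd = resid_sd,
    n_obs = x$n_obs,
    n_persons = x$n_persons,
    n_proteins = length(x$proteins),
    converged = x$converged
  )
}

#' @export
print.npx_de_fit <- function(x, ...) {
  cat("Hierarchical NPX differential-abundance fit\n")
  cat("  proteins:", length(x$proteins), " persons:", x$n_persons,
      " observations:", x$n_obs, "\n")
  cat("  pooling:", x$pooling_mode, " estimation:", x$estimation,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Classify differential-abundance results
#'
#' Splits per-protein contrasts into `up` (CI excludes 0, positive shift),
#' `down` (CI excludes 0, negative shift) and the `high_magnitude` subset of
#' those whose fold change magnitude `max(FC, 1/FC)` reaches the threshold.
#'
#' @param results tibble from [extract_group_contrasts()].
#' @param fc_magnitude fold-change magnitude threshold, default 1.5.
#' @return list of character vectors `up`, `down`, `high_magnitude`.
#' @export
classify_de <- function(results, fc_magnitude = 1.5) {
  up <- results$protein[results$direction == "up"]
  down <- results$protein[results$direction == "down"]
  mag <- pmax(results$fold_change, 1 / results$fold_change)
  high <- results$protein[results$direction != "inconclusive" &
                            mag >= fc_magnitude]
  list(up = up, down = down, high_magnitude = high)
}
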