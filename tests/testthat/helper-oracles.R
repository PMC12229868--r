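# Independent normal-equations oracle for the 4-coefficient pairwise
# interaction model y = b0 + b1 x + b2 g + b3 x g (g = 1 for case).
# Deliberately naive: dense design matrix, solve(X'X) X'y, textbook SEs.
ols_pair_oracle <- function(x, y, case, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; g <- as.numeric(case[ok])
  X <- cbind(1, x, g, x * g)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(y)
  sigma2 <- sum(resid^2) / (n - 4)
  V <- sigma2 * solve(XtX)
  tcrit <- qt(1 - (1 - conf_level) / 2, n - 4)
  slope_control <- beta[2]
  slope_case <- beta[2] + beta[4]
  slope_diff <- beta[4]
  se_control <- sqrt(V[2, 2])
  se_case <- sqrt(V[2, 2] + V[4, 4] + 2 * V[2, 4])
  se_diff <- sqrt(V[4, 4])
  list(
    slope_control = slope_control, se_control = se_control,
    control_ci = slope_control + c(-1, 1) * tcrit * se_control,
    slope_case = slope_case, se_case = se_case,
    case_ci = slope_case + c(-1, 1) * tcrit * se_case,
    slope_diff = slope_diff, se_diff = se_diff,
    diff_ci = slope_diff + c(-1, 1) * tcrit * se_diff,
    n_used = n
  )
}

# Exhaustive hypergeometric upper tail by enumerating every possible draw of
# size n_draw from a small background: P(X >= q_obs).
hyper_tail_enumeration <- function(background, pathway_members, query_size, q_obs) {
  draws <- utils::combn(length(background), query_size)
  in_path <- background %in% pathway_members
  hits <- colSums(matrix(in_path[draws], nrow = query_size))
  mean(hits >= q_obs)
}

# Minimal two-group dataset for the hierarchical model: one panel, single
# dilution, no censoring artifacts.
make_de_config <- function(n_control = 12, n_case = 12, deltas, person_sd = 0.5,
                           residual_sd = 1, seed = 1,
                           covariate_effects = c(age = 0.01, sex = 0.25,
                                                 bmi = 0.02)) {
  p <- length(deltas)
  ids <- sprintf("P%03d", seq_len(p))
  simulation_config(
    n_control = n_control, n_case = n_case,
    panels = c(A = p),
    dilution_factors = list(A = 1),
    log2_effects = setNames(deltas, ids),
    covariate_effects = covariate_effects,
    person_sd = person_sd, residual_sd = residual_sd,
    network_proteins = character(0),
    lod_quantile = 0, uloq_quantile = 1,
    dilution_noise_sd = 0,
    bad_assay_ids = character(0), low_assay_ids = character(0),
    seed = seed
  )
}

simulate_de_data <- function(...) {
  sim <- simulate_npx_dataset(make_de_config(...))
  list(data = sim$npx, samples = sim$samples, truth = sim$truth)
}

# fake pair-model row for exercising the selection rules directly
make_pair_row <- function(outcome, predictor, slope_control, slope_case,
                          se_control = 0.05, se_case = 0.05,
                          se_diff = sqrt(se_control^2 + se_case^2),
                          df = 20, estimable = TRUE) {
  tcrit <- qt(0.975, df)
  slope_diff <- slope_case - slope_control
  tibble::tibble(
    outcome = outcome, predictor = predictor,
    slope_control = slope_control, se_control = se_control,
    slope_case = slope_case, se_case = se_case,
    slope_diff = slope_diff, se_diff = se_diff,
    n_used = df + 4L, df = as.integer(df), estimable = estimable,
    control_ci_low = slope_control - tcrit * se_control,
    control_ci_high = slope_control + tcrit * se_control,
    case_ci_low = slope_case - tcrit * se_case,
    case_ci_high = slope_case + tcrit * se_case,
    diff_ci_low = slope_diff - tcrit * se_diff,
    diff_ci_high = slope_diff + tcrit * se_diff
  )
}

# planted differential co-expression data: 8 disjoint pairs where only the
# control group carries a slope (+-1.5, residual sd 0.5 around it); in the
# case group the same proteins are independent unit-variance noise. Values
# are generated directly on the analysis scale and fed to all_pairs as-is.
simulate_planted_pairs <- function(n_per_group = 12, n_pairs = 8,
                                   n_noise = 0, slope = 1.5,
                                   residual_sd = 0.5) {
  n <- 2 * n_per_group
  case <- rep(c(FALSE, TRUE), each = n_per_group)
  p <- 2 * n_pairs + n_noise
  mat <- matrix(rnorm(n * p), n, p)
  colnames(mat) <- sprintf("Q%02d", seq_len(p))
  signs <- rep(c(1, -1), length.out = n_pairs)
  planted <- character(0)
  for (k in seq_len(n_pairs)) {
    xi <- 2 * k - 1; yi <- 2 * k
    mat[!case, yi] <- signs[k] * slope * mat[!case, xi] +
      rnorm(n_per_group, sd = residual_sd)
    mat[case, yi] <- rnorm(n_per_group, sd = 1)
    planted <- c(planted, paste(colnames(mat)[xi], colnames(mat)[yi], sep = "|"))
  }
  list(mat = mat, group = ifelse(case, "OA", "control"), planted = planted)
}

edge_keys <- function(edges) {
  unique(paste(edges$protein_a, edges$protein_b, sep = "|"))
}
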