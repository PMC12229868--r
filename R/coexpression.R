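# Sufficient statistics for all pairwise interaction regressions within one
# group, on pairwise-complete rows. For predictor i and outcome j:
#   n[i,j]   complete rows, Sx[i,j] sum of var i over those rows,
#   Sxy[i,j] cross product,  Sxx[i,j] sum of squares of var i.
pair_group_stats <- function(Z) {
  M <- !is.na(Z)
  Z0 <- Z
  Z0[!M] <- 0
  storage.mode(M) <- "double"
  list(
    n = crossprod(M),
    Sx = crossprod(Z0, M),
    Sxy = crossprod(Z0),
    Sxx = crossprod(Z0^2, M)
  )
}

# centered second moments: Cxx = predictor variance*n, Cxy = cross, both per
# ordered pair (i = predictor, j = outcome)
pair_centered <- function(st) {
  Cxy <- st$Sxy - st$Sx * t(st$Sx) / st$n
  Cxx <- st$Sxx - st$Sx^2 / st$n
  Cxy[st$n == 0] <- NA
  Cxx[st$n == 0] <- NA
  list(Cxy = Cxy, Cxx = Cxx, n = st$n)
}

coerce_case <- function(group) {
  group <- as.character(group)
  labs <- sort(unique(group))
  if (length(labs) < 2) stop("two groups are required (found ",
                             paste(labs, collapse = ", "), ")")
  if (length(labs) > 2) stop("more than two group labels: ",
                             paste(labs, collapse = ", "))
  ref <- if ("control" %in% labs) "control" else labs[1]
  group != ref
}

# exact OLS for y ~ x * group (4 coefficients, shared residual variance)
# from per-group centered moments; vectorized over all ordered pairs
pair_models_from_stats <- function(cc, co, conf_level = 0.95) {
  n_used <- cc$n + co$n
  df <- n_used - 4
  cxx_c <- ifelse(!is.na(cc$Cxx) & cc$Cxx > 1e-12, cc$Cxx, NA)
  cxx_o <- ifelse(!is.na(co$Cxx) & co$Cxx > 1e-12, co$Cxx, NA)
  b_c <- cc$Cxy / cxx_c
  b_o <- co$Cxy / cxx_o
  rss <- (t(cc$Cxx) - cc$Cxy^2 / cxx_c) + (t(co$Cxx) - co$Cxy^2 / cxx_o)
  rss <- pmax(rss, 0) # guard tiny negatives from cancellation (e.g. y == x)
  sigma2 <- rss / ifelse(df >= 1, df, NA)
  se_c <- sqrt(sigma2 / cxx_c)
  se_o <- sqrt(sigma2 / cxx_o)
  se_d <- sqrt(sigma2 * (1 / cxx_c + 1 / cxx_o))
  estimable <- cc$n >= 4 & co$n >= 4 & df >= 1 &
    !is.na(cc$Cxx) & !is.na(co$Cxx) &
    cc$Cxx > 1e-12 & co$Cxx > 1e-12
  list(b_c = b_c, b_o = b_o, b_d = b_o - b_c,
       se_c = se_c, se_o = se_o, se_d = se_d,
       df = df, n_used = n_used, estimable = estimable)
}

assemble_pairs <- function(pm, idx_pred, idx_out, names_vec, conf_level = 0.95) {
  ii <- cbind(idx_pred, idx_out)
  df <- pm$df[ii]
  tcrit <- ifelse(df >= 1, qt(1 - (1 - conf_level) / 2, pmax(df, 1)), NA)
  grab <- function(M) M[ii]
  out <- tibble::tibble(
    outcome = names_vec[idx_out],
    predictor = names_vec[idx_pred],
    slope_control = grab(pm$b_c),
    se_control = grab(pm$se_c),
    slope_case = grab(pm$b_o),
    se_case = grab(pm$se_o),
    slope_diff = grab(pm$b_d),
    se_diff = grab(pm$se_d),
    n_used = as.integer(grab(pm$n_used)),
    df = as.integer(df),
    estimable = grab(pm$estimable)
  ) |>
    dplyr::mutate(
      control_ci_low = .data$slope_control - tcrit * .data$se_control,
      control_ci_high = .data$slope_control + tcrit * .data$se_control,
      case_ci_low = .data$slope_case - tcrit * .data$se_case,
      case_ci_high = .data$slope_case + tcrit * .data$se_case,
      diff_ci_low = .data$slope_diff - tcrit * .data$se_diff,
      diff_ci_high = .data$slope_diff + tcrit * .data$se_diff
    )
  na_cols <- c("slope_control", "se_control", "slope_case", "se_case",
               "slope_diff", "se_diff", "control_ci_low", "control_ci_high",
               "case_ci_low", "case_ci_high", "diff_ci_low", "diff_ci_high")
  out[!out$estimable, na_cols] <- NA_real_
  dplyr::arrange(out, .data$outcome, .data$predictor)
}

#' Fit one pairwise differential co-expression model
#'
#' Ordinary least squares for `y ~ x + group + x:group`: the control-group
#' slope, the case (OA) group slope, and their difference (the interaction
#' coefficient), each with a t-based confidence interval on `n_used - 4`
#' degrees of freedom and a residual variance shared across groups. Rows
#' with a missing value in either protein are dropped (pairwise complete).
#' Rank-deficient pairs (a group with constant predictor, or fewer than 4
#' complete rows per group) are flagged `estimable = FALSE` rather than
#' erroring, so they can be excluded from downstream selection.
#'
#' @param x predictor protein values (typically standardized log2 NPX).
#' @param y outcome protein values.
#' @param group group labels (two levels; `control` is the reference when
#'   present).
#' @param conf_level confidence level for all intervals.
#' @param outcome,predictor names recorded in the result.
#' @return one-row tibble in the same layout as [all_pairs()].
#' @export
fit_pair <- function(x, y, group, conf_level = 0.95,
                     outcome = "y", predictor = "x") {
  case <- coerce_case(group)
  Z <- cbind(x, y)
  colnames(Z) <- c(predictor, outcome)
  cc <- pair_centered(pair_group_stats(Z[!case, , drop = FALSE]))
  co <- pair_centered(pair_group_stats(Z[case, , drop = FALSE]))
  pm <- pair_models_from_stats(cc, co, conf_level)
  assemble_pairs(pm, idx_pred = 1L, idx_out = 2L,
                 names_vec = colnames(Z), conf_level = conf_level)
}

#' All-pairs differential co-expression
#'
#' Fits the pairwise interaction regression of [fit_pair()] for every
#' ordered pair of proteins (both directions of each unordered pair, since
#' OLS slopes are not symmetric), returning `p * (p - 1)` models in
#' deterministic lexicographic order (outcome, then predictor). Implemented
#' with closed-form per-group sufficient statistics, so the full panel
#' (tens of thousands of pairs) runs in seconds.
#'
#' @param mat samples x proteins matrix, typically [standardize()]d pooled
#'   across groups; missing cells handled pairwise-complete.
#' @param group per-sample group labels (two levels required).
#' @param conf_level confidence level for the slope intervals.
#' @return tibble with one row per ordered pair: outcome, predictor,
#'   slope_control, slope_case, slope_diff, their SEs and CIs, n_used, df,
#'   estimable.
#' @export
all_pairs <- function(mat, group, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 proteins")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  case <- coerce_case(group)
  if (length(case) != nrow(mat)) stop("group length must match rows of mat")
  ord <- order(colnames(mat))
  mat <- mat[, ord, drop = FALSE]
  cc <- pair_centered(pair_group_stats(mat[!case, , drop = FALSE]))
  co <- pair_centered(pair_group_stats(mat[case, , drop = FALSE]))
  pm <- pair_models_from_stats(cc, co, conf_level)
  p <- ncol(mat)
  idx <- which(matrix(TRUE, p, p) & !diag(p), arr.ind = TRUE)
  assemble_pairs(pm, idx_pred = idx[, 1], idx_out = idx[, 2],
                 names_vec = colnames(mat), conf_level = conf_level)
}

ci_excludes_zero <- function(lo, hi) !is.na(lo) & !is.na(hi) & (lo > 0 | hi < 0)

# one row per unordered pair: the direction with the larger |slope_diff|
dedup_unordered <- function(pairs) {
  pairs |>
    dplyr::mutate(
      pair_key = paste(pmin(.data$outcome, .data$predictor),
                       pmax(.data$outcome, .data$predictor), sep = "|")
    ) |>
    dplyr::group_by(.data$pair_key) |>
    dplyr::arrange(dplyr::desc(abs(.data$slope_diff)), .data$outcome,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Select proteins for co-expression enrichment analyses
#'
#' A pair qualifies when its co-expression slopes differ between the groups
#' by at least `min_abs_diff` (default 1, in standardized log2 units) and
#' the confidence interval of the slope difference excludes 0. The proteins
#' of qualifying pairs are pooled and split into two sets by which group
#' shows the larger absolute slope — the input lists for the two
#' co-expression enrichment analyses (control-dominant and OA-dominant).
#'
#' @param pairs tibble from [all_pairs()].
#' @param min_abs_diff minimum absolute slope difference.
#' @return list: `control` and `case` protein character vectors, plus
#'   `pairs`, the qualifying deduplicated pair rows.
#' @export
select_enrichment_proteins <- function(pairs, min_abs_diff = 1) {
  qual <- dedup_unordered(pairs) |>
    dplyr::filter(.data$estimable,
                  abs(.data$slope_diff) >= min_abs_diff,
                  ci_excludes_zero(.data$diff_ci_low, .data$diff_ci_high)) |>
    dplyr::mutate(dominant = ifelse(abs(.data$slope_case) >
                                      abs(.data$slope_control),
                                    "case", "control"))
  list(
    control = sort(unique(unlist(qual[qual$dominant == "control",
                                      c("outcome", "predictor")]))),
    case = sort(unique(unlist(qual[qual$dominant == "case",
                                   c("outcome", "predictor")]))),
    pairs = qual
  )
}

#' Edge selection rule for differential co-expression networks
#'
#' @param min_abs_slope minimum absolute within-group slope for an edge.
#' @param min_abs_diff minimum absolute between-group slope difference.
#' @param require_diff_ci require the slope-difference CI to exclude 0.
#' @param require_slope_ci require the qualifying group's slope CI to
#'   exclude 0.
#' @return an `edge_rule` list.
#' @export
edge_rule <- function(min_abs_slope = 1, min_abs_diff = 1,
                      require_diff_ci = TRUE, require_slope_ci = TRUE) {
  stopifnot(min_abs_slope > 0, min_abs_diff > 0)
  structure(list(min_abs_slope = min_abs_slope, min_abs_diff = min_abs_diff,
                 require_diff_ci = require_diff_ci,
                 require_slope_ci = require_slope_ci),
            class = "edge_rule")
}

#' Select signed edges for the group co-expression networks
#'
#' An unordered pair enters the networks when the slopes differ between the
#' groups (|difference| at least `min_abs_diff` with CI excluding 0) *and*
#' a group's own slope is strong (|slope| at least `min_abs_slope` with its
#' CI excluding 0) — that group receives the edge, signed by its slope. A
#' pair can yield an edge in both group networks. When both directions of a
#' pair qualify, the direction with the larger |slope difference| is kept.
#'
#' @param pairs tibble from [all_pairs()].
#' @param rule an [edge_rule()].
#' @return tibble: protein_a, protein_b (alphabetical), group (`control` or
#'   `OA`), slope, sign (`positive`/`negative`).
#' @export
select_network_edges <- function(pairs, rule = edge_rule()) {
  dd <- dedup_unordered(pairs) |>
    dplyr::filter(.data$estimable) |>
    dplyr::mutate(
      diff_ok = abs(.data$slope_diff) >= rule$min_abs_diff &
        (!rule$require_diff_ci |
           ci_excludes_zero(.data$diff_ci_low, .data$diff_ci_high)),
      control_ok = .data$diff_ok &
        abs(.data$slope_control) >= rule$min_abs_slope &
        (!rule$require_slope_ci |
           ci_excludes_zero(.data$control_ci_low, .data$control_ci_high)),
      case_ok = .data$diff_ok &
        abs(.data$slope_case) >= rule$min_abs_slope &
        (!rule$require_slope_ci |
           ci_excludes_zero(.data$case_ci_low, .data$case_ci_high))
    )
  edge_tbl <- function(sub, grp, slope_col) {
    tibble::tibble(
      protein_a = pmin(sub$outcome, sub$predictor),
      protein_b = pmax(sub$outcome, sub$predictor),
      group = grp,
      slope = sub[[slope_col]],
      sign = c("negative", "positive")[(sub[[slope_col]] >= 0) + 1L]
    )
  }
  dplyr::bind_rows(
    edge_tbl(dd[dd$control_ok, ], "control", "slope_control"),
    edge_tbl(dd[dd$case_ok, ], "OA", "slope_case")
  ) |>
    dplyr::arrange(.data$group, .data$protein_a, .data$protein_b)
}
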