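#' @importFrom rlang .data
#' @importFrom stats median sd quantile rnorm runif rbinom setNames phyper
#'   prcomp qnorm qt pt var optim
#' @importFrom utils head
NULL

# Named substreams off one base seed: adding proteins or stages must not
# perturb unrelated draws, so each stage seeds its own stream by name.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 40009L
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Standardize a samples-by-proteins matrix
#'
#' Centers each protein (column) to mean 0 and scales to sample standard
#' deviation 1, pooling both groups, using non-missing cells only. Missing
#' cells stay missing. Standardization makes co-expression slopes comparable
#' across protein pairs.
#'
#' @param mat numeric matrix, samples in rows, proteins in columns.
#' @return matrix of the same shape with columns standardized.
#' @export
standardize <- function(mat) {
  mat <- as.matrix(mat)
  n_ok <- colSums(!is.na(mat))
  if (any(n_ok < 2)) {
    stop("proteins with fewer than 2 non-missing values: ",
         paste(colnames(mat)[n_ok < 2], collapse = ", "))
  }
  sds <- apply(mat, 2, sd, na.rm = TRUE)
  if (any(sds == 0)) {
    stop("zero-variance protein(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  mus <- colMeans(mat, na.rm = TRUE)
  sweep(sweep(mat, 2, mus, "-"), 2, sds, "/")
}

# Pairwise-complete covariance with denominator n (within-group means),
# followed by eigenvalue clipping so the result is usable as a Gaussian
# graphical model input even when missingness breaks positive definiteness.
pairwise_covariance <- function(mat, psd_repair = TRUE, eig_floor = 1e-8) {
  Z <- as.matrix(mat)
  M <- !is.na(Z)
  Z0 <- Z
  Z0[!M] <- 0
  storage.mode(M) <- "double"
  n <- crossprod(M)
  Sxy <- crossprod(Z0)
  Sx <- crossprod(Z0, M) # [i,j] = sum of var i over rows where both present
  C <- (Sxy - Sx * t(Sx) / n) / n
  C[n == 0] <- 0
  C <- (C + t(C)) / 2
  if (psd_repair) {
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) < eig_floor) {
      C <- e$vectors %*% (pmax(e$values, eig_floor) * t(e$vectors))
      C <- (C + t(C)) / 2
      dimnames(C) <- dimnames(Sxy)
    }
  }
  C
}

#' Pivot a long NPX table to a samples-by-proteins matrix
#'
#' @param npx long NPX table with one row per sample and assay (dilution
#'   already selected).
#' @param value column holding the measurement, default `"npx"`.
#' @return numeric matrix with sample ids as rownames, assay ids as colnames.
#' @export
npx_wide <- function(npx, value = "npx") {
  wide <- npx |>
    dplyr::select("sample_id", "assay_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "assay_id", values_from = dplyr::all_of(value)) |>
    dplyr::arrange(.data$sample_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, order(colnames(m)), drop = FALSE]
}

format_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

#' Format a fold change with its confidence interval
#'
#' Renders a differential-abundance row the way panel-proteomics results are
#' usually quoted, e.g. `"0.03 [0.02, 0.05]"`.
#'
#' @param fold_change,fc_ci_low,fc_ci_high fold change and CI bounds (ratio
#'   scale).
#' @param digits digits after the decimal point.
#' @return character vector.
#' @export
format_fc <- function(fold_change, fc_ci_low, fc_ci_high, digits = 2) {
  paste0(format_num(fold_change, digits), " [", format_num(fc_ci_low, digits),
         ", ", format_num(fc_ci_high, digits), "]")
}
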