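#' ADMM configuration for the joint graphical lasso
#'
#' @param rho ADMM penalty parameter (> 0), or `NULL` (default) to set it
#'   to the mean group sample size at run time — the likelihood term scales
#'   with `n_k`, so matching rho to it keeps the primal and dual updates on
#'   comparable scales and speeds convergence markedly.
#' @param tol_primal,tol_dual convergence tolerances on the primal
#'   (`||Theta - Z||_F`) and dual (`rho * ||Z - Z_prev||_F`) residuals.
#' @param max_iter iteration cap; hitting it returns `converged = FALSE`.
#' @param edge_tol absolute threshold below which a precision entry is
#'   treated as zero when building adjacency matrices.
#' @return a `jgl_config` list.
#' @export
jgl_config <- function(rho = NULL, tol_primal = 1e-8, tol_dual = 1e-8,
                       max_iter = 5000, edge_tol = 1e-5) {
  stopifnot(is.null(rho) || rho > 0, tol_primal > 0, tol_dual > 0,
            max_iter >= 1, edge_tol >= 0)
  structure(list(rho = rho, tol_primal = tol_primal, tol_dual = tol_dual,
                 max_iter = max_iter, edge_tol = edge_tol),
            class = "jgl_config")
}

# eigen-step: argmin_Theta  n (tr(S Theta) - logdet Theta) + rho/2 ||Theta - A||^2
jgl_theta_update <- function(S, A, n, rho) {
  B <- (A + t(A)) / 2 - (n / rho) * S
  e <- eigen(B, symmetric = TRUE)
  d <- (e$values + sqrt(e$values^2 + 4 * n / rho)) / 2
  Th <- e$vectors %*% (d * t(e$vectors))
  (Th + t(Th)) / 2
}

soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# fused soft-threshold for two groups: fuse toward each other by t2,
# then (off-diagonals only) shrink both by t1
jgl_z_update <- function(A_list, lambda1, lambda2, rho) {
  p <- nrow(A_list[[1]])
  offd <- !diag(p)
  if (length(A_list) == 1) {
    Z <- A_list[[1]]
    Z[offd] <- soft(Z[offd], lambda1 / rho)
    return(list(Z))
  }
  a1 <- A_list[[1]]; a2 <- A_list[[2]]
  t2 <- lambda2 / rho
  gap <- a1 - a2
  fuse <- abs(gap) <= 2 * t2
  m <- (a1 + a2) / 2
  z1 <- ifelse(fuse, m, a1 - sign(gap) * t2)
  z2 <- ifelse(fuse, m, a2 + sign(gap) * t2)
  z1[offd] <- soft(z1[offd], lambda1 / rho)
  z2[offd] <- soft(z2[offd], lambda1 / rho)
  list((z1 + t(z1)) / 2, (z2 + t(z2)) / 2)
}

jgl_objective <- function(Theta_list, S_list, n_list, lambda1, lambda2) {
  p <- nrow(Theta_list[[1]])
  offd <- !diag(p)
  val <- 0
  for (k in seq_along(Theta_list)) {
    Th <- Theta_list[[k]]
    ld <- determinant(Th, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    val <- val + n_list[[k]] * (sum(S_list[[k]] * Th) - as.numeric(ld$modulus))
    val <- val + lambda1 * sum(abs(Th[offd]))
  }
  if (length(Theta_list) == 2) {
    val <- val + lambda2 * sum(abs(Theta_list[[1]] - Theta_list[[2]]))
  }
  val
}

#' Fused joint graphical lasso via ADMM
#'
#' Estimates one sparse precision matrix per group from the group sample
#' covariances, minimizing
#' \deqn{\sum_k n_k (\mathrm{tr}(S_k \Theta_k) - \log\det \Theta_k)
#'   + \lambda_1 \sum_k \sum_{i \ne j} |\Theta_{k,ij}|
#'   + \lambda_2 \sum_{i,j} |\Theta_{1,ij} - \Theta_{2,ij}|}
#' by alternating an eigen-decomposition primal step with a fused-lasso
#' proximal step. \eqn{\lambda_1} controls network density (sparsity,
#' off-diagonals only); \eqn{\lambda_2} controls between-group similarity
#' (as \eqn{\lambda_2 \to \infty} the two precision matrices coincide). The
#' diagonal is never sparsity-penalized. A zero off-diagonal precision entry
#' means conditional independence of the two proteins given the rest.
#'
#' @param S_list list of 1 or 2 symmetric positive semi-definite sample
#'   covariance matrices of equal dimension (denominator `n`, within-group
#'   means; see [group_covariances()]).
#' @param n_list per-group sample sizes.
#' @param lambda1 sparsity penalty (>= 0).
#' @param lambda2 fusion penalty (>= 0; ignored for a single group).
#' @param config a [jgl_config()].
#' @return object of class `npx_jgl`: `theta` (list of precision matrices),
#'   `adjacency` (list of logical matrices, `|Theta| > edge_tol`, empty
#'   diagonal), `iterations`, `converged`, `primal_residual`,
#'   `dual_residual`, `objective` (per-iteration trace), plus the inputs.
#' @export
joint_graphical_lasso <- function(S_list, n_list, lambda1 = 0, lambda2 = 0,
                                  config = jgl_config()) {
  if (!is.list(S_list)) S_list <- list(S_list)
  K <- length(S_list)
  stopifnot(K %in% c(1, 2), length(n_list) == K, lambda1 >= 0, lambda2 >= 0)
  p <- nrow(S_list[[1]])
  for (k in seq_len(K)) {
    if (!isSymmetric(unname(S_list[[k]]), tol = 1e-7)) {
      stop("covariance matrix ", k, " is not symmetric")
    }
    if (nrow(S_list[[k]]) != p) stop("covariance matrices differ in dimension")
    S_list[[k]] <- (S_list[[k]] + t(S_list[[k]])) / 2
  }
  rho <- config$rho
  if (is.null(rho)) rho <- mean(unlist(n_list))
  Theta <- Z <- lapply(S_list, function(S) diag(1 / pmax(diag(S), 1e-4)))
  U <- lapply(S_list, function(S) matrix(0, p, p))
  objective <- numeric(0)
  converged <- FALSE
  r_norm <- s_norm <- NA_real_
  scale_tol <- max(p, 1)

  for (it in seq_len(config$max_iter)) {
    for (k in seq_len(K)) {
      Theta[[k]] <- jgl_theta_update(S_list[[k]], Z[[k]] - U[[k]],
                                     n_list[[k]], rho)
    }
    Z_old <- Z
    A_list <- lapply(seq_len(K), function(k) Theta[[k]] + U[[k]])
    Z <- jgl_z_update(A_list, lambda1, lambda2, rho)
    for (k in seq_len(K)) U[[k]] <- U[[k]] + Theta[[k]] - Z[[k]]

    objective <- c(objective,
                   jgl_objective(Theta, S_list, n_list, lambda1, lambda2))
    r_norm <- sqrt(sum(vapply(seq_len(K), function(k) {
      sum((Theta[[k]] - Z[[k]])^2)
    }, 0)))
    s_norm <- rho * sqrt(sum(vapply(seq_len(K), function(k) {
      sum((Z[[k]] - Z_old[[k]])^2)
    }, 0)))
    if (r_norm < config$tol_primal * scale_tol &&
        s_norm < config$tol_dual * scale_tol) {
      converged <- TRUE
      break
    }
  }

  # report the thresholded iterate (exact zeros) but keep PD via Theta
  theta_out <- lapply(seq_len(K), function(k) {
    Th <- Z[[k]]
    ev <- eigen((Th + t(Th)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) Th <- Theta[[k]]
    dimnames(Th) <- dimnames(S_list[[k]])
    Th
  })
  adjacency <- lapply(theta_out, function(Th) {
    A <- abs(Th) > config$edge_tol
    diag(A) <- FALSE
    A
  })
  structure(list(
    theta = theta_out,
    adjacency = adjacency,
    iterations = length(objective),
    converged = converged,
    primal_residual = r_norm,
    dual_residual = s_norm,
    objective = objective,
    lambda1 = lambda1, lambda2 = lambda2,
    S_list = S_list, n_list = n_list,
    edge_tol = config$edge_tol
  ), class = "npx_jgl")
}

#' @export
print.npx_jgl <- function(x, ...) {
  edges <- vapply(x$adjacency, function(A) sum(A[upper.tri(A)]), 0)
  cat("Fused joint graphical lasso fit\n")
  cat("  groups:", length(x$theta), " p:", nrow(x$theta[[1]]),
      " lambda1:", x$lambda1, " lambda2:", x$lambda2, "\n")
  cat("  edges per group:", paste(edges, collapse = ", "),
      " iterations:", x$iterations, " converged:", x$converged, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.npx_jgl <- function(x, ...) {
  groups <- if (length(x$theta) == 2) c("control", "OA") else "group1"
  purrr::map2_dfr(x$theta, groups, function(Th, g) {
    A <- abs(Th) > x$edge_tol
    diag(A) <- FALSE
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    nm <- colnames(Th)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(Th)))
    tibble::tibble(
      group = g,
      protein_a = nm[idx[, 1]],
      protein_b = nm[idx[, 2]],
      precision = Th[idx]
    )
  })
}

#' @exportS3Method generics::glance
glance.npx_jgl <- function(x, ...) {
  edges <- vapply(x$adjacency, function(A) sum(A[upper.tri(A)]), 0)
  tibble::tibble(
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    iterations = x$iterations, converged = x$converged,
    primal_residual = x$primal_residual, dual_residual = x$dual_residual,
    edges_control = edges[1],
    edges_case = if (length(edges) > 1) edges[2] else NA_real_
  )
}

#' Per-group sample covariances for graphical-model estimation
#'
#' Within-group means, denominator `n_k`, pairwise-complete cells, followed
#' by an eigenvalue-clipping repair to the nearest positive semi-definite
#' matrix (floor 1e-8) so the graphical lasso input is well defined even
#' with missing cells.
#'
#' @param mat samples x proteins matrix (standardized upstream).
#' @param group per-sample group labels.
#' @return list with `S_list` (control first), `n_list`.
#' @export
group_covariances <- function(mat, group) {
  case <- coerce_case(group)
  list(
    S_list = list(pairwise_covariance(mat[!case, , drop = FALSE]),
                  pairwise_covariance(mat[case, , drop = FALSE])),
    n_list = list(sum(!case), sum(case))
  )
}

#' Tuning-parameter selection for the joint graphical lasso
#'
#' Fits the solver on a grid of (lambda1, lambda2), scoring each fit with
#' AIC and BIC defined per group as `n_k tr(S_k Theta_k) - n_k logdet
#' Theta_k + penalty * E_k`, where `E_k` counts nonzero upper-triangle
#' off-diagonal precision entries and the penalty is 2 (AIC) or `log(n_k)`
#' (BIC); group scores are summed. Three models of increasing complexity
#' are marked: the BIC optimum, the AIC optimum, and a denser alternative —
#' the best-AIC grid point with strictly more total edges than the AIC
#' optimum (the densest grid point if none is denser).
#'
#' @param S_list,n_list as for [joint_graphical_lasso()].
#' @param lambda1_grid,lambda2_grid non-empty penalty grids.
#' @param config a [jgl_config()].
#' @return a `ModelSelectionTable` tibble: lambda1, lambda2, aic, bic,
#'   per-group and shared edge counts, converged, selected label.
#' @export
model_selection <- function(S_list, n_list, lambda1_grid, lambda2_grid,
                            config = jgl_config()) {
  stopifnot(length(lambda1_grid) >= 1, length(lambda2_grid) >= 1)
  grid <- expand.grid(lambda1 = sort(lambda1_grid),
                      lambda2 = sort(lambda2_grid))
  rows <- purrr::pmap_dfr(grid, function(lambda1, lambda2) {
    fit <- joint_graphical_lasso(S_list, n_list, lambda1, lambda2, config)
    aic <- bic <- 0
    edges <- integer(length(fit$theta))
    for (k in seq_along(fit$theta)) {
      Th <- fit$theta[[k]]
      E_k <- sum(abs(Th[upper.tri(Th)]) > config$edge_tol)
      ll <- n_list[[k]] * (sum(fit$S_list[[k]] * Th) -
                             as.numeric(determinant(Th)$modulus))
      aic <- aic + ll + 2 * E_k
      bic <- bic + ll + log(n_list[[k]]) * E_k
      edges[k] <- E_k
    }
    shared <- if (length(fit$adjacency) == 2) {
      A <- fit$adjacency[[1]] & fit$adjacency[[2]]
      sum(A[upper.tri(A)])
    } else NA_integer_
    tibble::tibble(
      lambda1 = lambda1, lambda2 = lambda2, aic = aic, bic = bic,
      edges_control = edges[1],
      edges_case = if (length(edges) > 1) edges[2] else NA_integer_,
      shared_edges = shared,
      total_edges = sum(edges),
      converged = fit$converged
    )
  })
  rows$selected <- ""
  ok <- which(rows$converged)
  if (length(ok)) {
    i_aic <- ok[which.min(rows$aic[ok])]
    i_bic <- ok[which.min(rows$bic[ok])]
    denser <- ok[rows$total_edges[ok] > rows$total_edges[i_aic]]
    i_dense <- if (length(denser)) denser[which.min(rows$aic[denser])] else {
      ok[which.max(rows$total_edges[ok])]
    }
    rows$selected[i_bic] <- paste0(rows$selected[i_bic], "bic;")
    rows$selected[i_aic] <- paste0(rows$selected[i_aic], "aic;")
    rows$selected[i_dense] <- paste0(rows$selected[i_dense], "denser;")
  }
  rows
}

#' Group-distinct clusters from a joint graphical lasso fit
#'
#' Takes the edges present in one group's adjacency but absent in the
#' other's, and reports the connected components of each group-distinct
#' edge set, sorted by decreasing size — the "clusters more prominent" in
#' one condition.
#'
#' @param fit an `npx_jgl` with two groups.
#' @return list with `control` and `case`: each a list of character vectors
#'   of member proteins.
#' @export
differential_clusters <- function(fit) {
  stopifnot(inherits(fit, "npx_jgl"), length(fit$adjacency) == 2)
  nm <- colnames(fit$theta[[1]])
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(fit$theta[[1]])))
  comp <- function(A_only) {
    idx <- which(A_only & upper.tri(A_only), arr.ind = TRUE)
    if (!nrow(idx)) return(list())
    g <- igraph::graph_from_edgelist(
      cbind(nm[idx[, 1]], nm[idx[, 2]]), directed = FALSE)
    cl <- igraph::components(g)
    comps <- split(names(cl$membership), cl$membership)
    comps <- lapply(unname(comps), sort)
    comps[order(-vapply(comps, length, 0L))]
  }
  A1 <- fit$adjacency[[1]]; A2 <- fit$adjacency[[2]]
  list(control = comp(A1 & !A2), case = comp(A2 & !A1))
}
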