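random_pd <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p + diag(p) * 0.5
  dimnames(S) <- list(sprintf("P%d", 1:p), sprintf("P%d", 1:p))
  S
}

test_that("unpenalized solution is the inverse covariance", {
  S <- random_pd(5, seed = 2)
  fit <- joint_graphical_lasso(list(S), list(40), 0, 0)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta[[1]] - solve(S))), 1e-6)

  S2 <- random_pd(5, seed = 3)
  fit2 <- joint_graphical_lasso(list(S, S2), list(40, 30), 0, 0)
  expect_lt(max(abs(fit2$theta[[1]] - solve(S))), 1e-6)
  expect_lt(max(abs(fit2$theta[[2]] - solve(S2))), 1e-6)
})

test_that("zero fusion penalty decouples into single-group fits", {
  S1 <- random_pd(6, seed = 4)
  S2 <- random_pd(6, seed = 5)
  joint <- joint_graphical_lasso(list(S1, S2), list(50, 35), lambda1 = 8,
                                 lambda2 = 0)
  alone1 <- joint_graphical_lasso(list(S1), list(50), lambda1 = 8)
  alone2 <- joint_graphical_lasso(list(S2), list(35), lambda1 = 8)
  expect_lt(sqrt(sum((joint$theta[[1]] - alone1$theta[[1]])^2)), 1e-6)
  expect_lt(sqrt(sum((joint$theta[[2]] - alone2$theta[[1]])^2)), 1e-6)
})

test_that("two-variable solution matches the soft-threshold closed form", {
  # With p = 2 and no diagonal penalty, the estimated covariance W satisfies
  # W12 = sign(s12) * max(|s12| - lambda1/n, 0), W_ii = s_ii.
  n <- 50
  for (s12 in c(-0.6, -0.3, 0.1, 0.4, 0.7)) {
    for (lam in c(0, 0.1 * n, 0.3 * n, 0.8 * n)) {
      S <- matrix(c(1, s12, s12, 1), 2)
      fit <- joint_graphical_lasso(list(S), list(n), lambda1 = lam)
      W <- solve(fit$theta[[1]])
      expect_equal(W[1, 2], sign(s12) * max(abs(s12) - lam / n, 0),
                   tolerance = 1e-5)
      expect_equal(diag(W), c(1, 1), tolerance = 1e-5)

      # independent check: direct minimization of the penalized objective
      obj <- function(par) {
        Th <- matrix(c(par[1], par[3], par[3], par[2]), 2)
        det <- par[1] * par[2] - par[3]^2
        if (det <= 0 || par[1] <= 0) return(1e10)
        n * (sum(S * Th) - log(det)) + 2 * lam * abs(par[3])
      }
      direct <- optim(c(1, 1, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
      Th_direct <- matrix(c(direct$par[1], direct$par[3], direct$par[3],
                            direct$par[2]), 2)
      expect_lt(max(abs(fit$theta[[1]] - Th_direct)), 5e-3)
    }
  }
})

test_that("a huge sparsity penalty empties both adjacencies", {
  fit <- joint_graphical_lasso(list(random_pd(6, 7), random_pd(6, 8)),
                               list(40, 40), lambda1 = 1e6, lambda2 = 0)
  expect_false(any(fit$adjacency[[1]]))
  expect_false(any(fit$adjacency[[2]]))
  ev <- eigen(fit$theta[[1]], symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("a huge fusion penalty forces identical precision matrices", {
  fit <- joint_graphical_lasso(list(random_pd(5, 9), random_pd(5, 10)),
                               list(40, 40), lambda1 = 1, lambda2 = 1e4)
  expect_lt(max(abs(fit$theta[[1]] - fit$theta[[2]])), 1e-4)
})

test_that("the objective is non-increasing across iterations", {
  for (seed in c(11, 12)) {
    fit <- joint_graphical_lasso(list(random_pd(8, seed), random_pd(8, seed + 50)),
                                 list(30, 25), lambda1 = 5, lambda2 = 1)
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
})

test_that("the solution is invariant to relabeling the proteins", {
  S1 <- random_pd(6, 13); S2 <- random_pd(6, 14)
  fit <- joint_graphical_lasso(list(S1, S2), list(30, 30), 4, 1)
  perm <- c(3, 1, 6, 2, 5, 4)
  fitp <- joint_graphical_lasso(list(S1[perm, perm], S2[perm, perm]),
                                list(30, 30), 4, 1)
  expect_lt(max(abs(fitp$theta[[1]] - fit$theta[[1]][perm, perm])), 1e-6)
})

test_that("input validation rejects malformed covariance input", {
  S <- random_pd(4, 15)
  bad <- S; bad[1, 2] <- bad[1, 2] + 1
  expect_error(joint_graphical_lasso(list(bad), list(10)), "not symmetric")
  expect_error(joint_graphical_lasso(list(S, random_pd(5, 16)), list(10, 10)),
               "dimension")
  tiny <- joint_graphical_lasso(list(S), list(10),
                                config = jgl_config(max_iter = 2))
  expect_false(tiny$converged)
})

test_that("model selection scores a grid and marks three models", {
  Zc <- MASS::mvrnorm(60, rep(0, 8), solve(planted_precision(8, cbind(1:7, 2:8), 0.4)))
  Zo <- MASS::mvrnorm(60, rep(0, 8), diag(8))
  S_list <- list(stats::cov(Zc), stats::cov(Zo))
  tab <- model_selection(S_list, list(60, 60), c(1, 5, 20), c(0.5, 2))
  expect_equal(nrow(tab), 6)
  expect_equal(sum(grepl("aic;", tab$selected)), 1)
  expect_equal(sum(grepl("bic;", tab$selected)), 1)
  expect_equal(sum(grepl("denser;", tab$selected)), 1)
  i_aic <- which(grepl("aic;", tab$selected))
  i_dense <- which(grepl("denser;", tab$selected))
  expect_gte(tab$total_edges[i_dense], tab$total_edges[i_aic])

  single <- model_selection(S_list, list(60, 60), 5, 1)
  expect_equal(nrow(single), 1)
  expect_true(grepl("aic;", single$selected) && grepl("bic;", single$selected))
})

test_that("group-distinct clusters are connected components", {
  nm <- letters[1:5]
  A1 <- matrix(FALSE, 5, 5, dimnames = list(nm, nm))
  A2 <- A1
  # control-only chain a-b-c and isolated pair d-e shared by both groups
  A1["a", "b"] <- A1["b", "a"] <- TRUE
  A1["b", "c"] <- A1["c", "b"] <- TRUE
  A1["d", "e"] <- A1["e", "d"] <- TRUE
  A2["d", "e"] <- A2["e", "d"] <- TRUE
  fake <- structure(list(
    theta = list(matrix(0, 5, 5, dimnames = list(nm, nm)),
                 matrix(0, 5, 5, dimnames = list(nm, nm))),
    adjacency = list(A1, A2), edge_tol = 1e-5
  ), class = "npx_jgl")
  cl <- differential_clusters(fake)
  expect_equal(cl$control, list(c("a", "b", "c")))
  expect_equal(cl$case, list())

  same <- fake
  same$adjacency <- list(A1, A1)
  cl2 <- differential_clusters(same)
  expect_equal(cl2$control, list())
  expect_equal(cl2$case, list())
})

test_that("BIC-selected models recover planted structure", {
  set.seed(17)
  p <- 20
  shared <- cbind(1:10, 2:11)
  ctrl_only <- cbind(12:16, 13:17)
  case_only <- cbind(c(12, 14, 16, 18, 19), c(18, 19, 20, 20, 12))
  Pc <- planted_precision(p, rbind(shared, ctrl_only), 0.35)
  Po <- planted_precision(p, rbind(shared, case_only), 0.35)
  truth_edges <- function(P) {
    idx <- which(abs(P) > 1e-10 & upper.tri(P), arr.ind = TRUE)
    paste(idx[, 1], idx[, 2])
  }
  cfg <- jgl_config(tol_primal = 1e-7, tol_dual = 1e-7, max_iter = 4000)
  stats <- t(sapply(1:50, function(i) {
    Zc <- MASS::mvrnorm(100, rep(0, p), solve(Pc))
    Zo <- MASS::mvrnorm(100, rep(0, p), solve(Po))
    S_list <- list(stats::cov(Zc), stats::cov(Zo))
    # coarse x3-spaced ladder from clearly under- to clearly over-penalized
    tab <- model_selection(S_list, list(100, 100),
                           lambda1_grid = c(10, 30, 90),
                           lambda2_grid = c(1, 5), cfg)
    pick <- tab[grepl("bic;", tab$selected), ][1, ]
    fit <- joint_graphical_lasso(S_list, list(100, 100), pick$lambda1,
                                 pick$lambda2, cfg)
    found <- lapply(fit$adjacency, function(A) {
      idx <- which(A & upper.tri(A), arr.ind = TRUE)
      paste(idx[, 1], idx[, 2])
    })
    truth <- list(truth_edges(Pc), truth_edges(Po))
    tp <- sum(found[[1]] %in% truth[[1]]) + sum(found[[2]] %in% truth[[2]])
    fp <- sum(!found[[1]] %in% truth[[1]]) + sum(!found[[2]] %in% truth[[2]])
    c(recall = tp / (length(truth[[1]]) + length(truth[[2]])),
      fdp = if (tp + fp > 0) fp / (tp + fp) else 0)
  }))
  expect_gte(median(stats[, "recall"]), 0.7)
  expect_lte(median(stats[, "fdp"]), 0.3)
})
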