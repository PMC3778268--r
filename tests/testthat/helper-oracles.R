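# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# --- connected components: iterative minimum-label propagation ------------
# Each candidate voxel starts with its own label (its linear index); labels
# repeatedly take the minimum over in-mask neighbours until a fixed point.
# Distinct surviving labels are the components.
oracle_components <- function(candidate, connectivity = 26) {
  dims <- dim(candidate)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[manh <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3), ]
  shift3 <- function(a, dx, dy, dz, fill) {
    out <- array(fill, dim = dims)
    src_x <- seq_len(dims[1]) - dx; src_y <- seq_len(dims[2]) - dy
    src_z <- seq_len(dims[3]) - dz
    ok_x <- src_x >= 1 & src_x <= dims[1]
    ok_y <- src_y >= 1 & src_y <= dims[2]
    ok_z <- src_z >= 1 & src_z <= dims[3]
    out[ok_x, ok_y, ok_z] <- a[src_x[ok_x], src_y[ok_y], src_z[ok_z]]
    out
  }
  lab <- array(Inf, dim = dims)
  lab[candidate] <- which(candidate)
  repeat {
    m <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- shift3(lab, offs$dx[r], offs$dy[r], offs$dz[r], Inf)
      m <- pmin(m, sh)
    }
    m[!candidate] <- Inf
    if (identical(m, lab)) break
    lab <- m
  }
  lab[!is.finite(lab)] <- 0
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, dim = dims)
  if (length(u)) out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# Second independent component oracle for larger volumes: connected
# components of the voxel adjacency graph via igraph.
oracle_components_igraph <- function(candidate, connectivity = 26) {
  dims <- dim(candidate)
  n <- prod(dims)
  idx <- which(candidate)
  if (!length(idx)) return(array(0L, dims))
  pos <- arrayInd(idx, dims)
  key <- rep(NA_integer_, n)
  key[idx] <- seq_along(idx)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[order(offs$dz, offs$dy, offs$dx), ]
  offs <- offs[(offs$dx + 10 * offs$dy + 100 * offs$dz) > 0, ]  # half-shell
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[manh <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3), ]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(pos[, 1] + offs$dx[r], pos[, 2] + offs$dy[r],
                pos[, 3] + offs$dz[r])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
      dims[1] * dims[2] * (nb[ok, 3] - 1)
    tgt <- key[nb_lin]
    src <- which(ok)[!is.na(tgt)]
    edges <- c(edges, rbind(src, tgt[!is.na(tgt)]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- array(0L, dims)
  out[idx] <- comp
  out
}

# Oracle version of binarize_lesion: threshold, label with the propagation
# oracle, drop small components.
oracle_binarize <- function(grid, threshold = 0.3, min_cluster = 100,
                            connectivity = 26) {
  cand <- grid > threshold
  if (!any(cand)) return(array(FALSE, dim = dim(grid)))
  lab <- oracle_components(cand, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster)
  array(lab %in% keep, dim = dim(grid))
}

# --- dense closed-form GP oracle ------------------------------------------
# Naive R evaluation of the RQ-ARD kernel and the textbook predictive
# equations using solve() on the full covariance. No Cholesky, no caching.
oracle_rq <- function(x1, x2, sf2, alpha, ell) {
  r2 <- sum(((x1 - x2) / ell)^2)
  sf2 * (1 + r2 / (2 * alpha))^(-alpha)
}

oracle_gp_predict <- function(X, y, Xstar, sf2, sn2, alpha, ell) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- oracle_rq(X[i, ], X[j, ], sf2, alpha, ell)
  Ky <- K + diag(sn2, n)
  Kinv <- solve(Ky)
  t(apply(Xstar, 1, function(xs) {
    ks <- vapply(seq_len(n),
                 function(i) oracle_rq(X[i, ], xs, sf2, alpha, ell),
                 numeric(1))
    c(mean = sum(ks * (Kinv %*% y)),
      var = sf2 - drop(t(ks) %*% Kinv %*% ks) + sn2)
  }))
}

oracle_gp_logml <- function(X, y, sf2, sn2, alpha, ell) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- oracle_rq(X[i, ], X[j, ], sf2, alpha, ell)
  Ky <- K + diag(sn2, n)
  drop(-0.5 * t(y) %*% solve(Ky, y) - 0.5 * determinant(Ky)$modulus -
         n / 2 * log(2 * pi))
}

# --- AUC: brute-force pairwise concordance --------------------------------
oracle_auc <- function(score, impaired) {
  pos <- score[impaired]   # impaired expected to score LOW
  neg <- score[!impaired]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p < q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# --- Wilcoxon signed rank: exact enumeration for small n ------------------
# Distribution of W+ over all 2^n sign assignments given the observed
# absolute-difference ranks.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  list(w = w_obs,
       p_exact = mean(abs(w_all - n * (n + 1) / 4) >=
                        abs(w_obs - n * (n + 1) / 4)))
}

# --- OLS closed form -------------------------------------------------------
oracle_ols_r2 <- function(actual, predicted) {
  n <- length(actual)
  r <- sum((actual - mean(actual)) * (predicted - mean(predicted))) /
    sqrt(sum((actual - mean(actual))^2) * sum((predicted - mean(predicted))^2))
  r2 <- r^2
  list(r2 = r2, f = (n - 2) * r2 / (1 - r2))
}

# --- small fixture builders ------------------------------------------------
cuboid_image <- function(dims = c(20, 20, 20), from = c(3, 3, 3),
                         to = c(7, 7, 7), value = 0.5,
                         affine = diag(c(2, 2, 2, 1))) {
  g <- array(0, dims)
  g[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- value
  abnormality_image(g, affine)
}

# tiny cohort for fast end-to-end tests
small_cohort <- function(n = 60, seed = 1, ...) {
  simulate_cohort(sim_config(n_patients = n, grid = c(32, 36, 32),
                             n_regions = 12, n_informative = 2,
                             informative_weights = c(35, 30),
                             seed = seed, ...))
}
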