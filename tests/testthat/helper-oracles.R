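# Independent oracles used to cross-check the package implementation.
# Each is a deliberately naive reimplementation (enumeration or direct
# likelihood maximisation), kept separate from the code path it checks.

# Exact signed-rank test by full enumeration of the 2^n sign assignments.
enum_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_ge <- mean(vs >= V)
  p_le <- mean(vs <= V)
  list(V = V, p = min(1, 2 * min(p_ge, p_le)))
}

# Exact rank-sum test by enumeration of all C(nx+ny, nx) group labelings.
enum_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(nx + ny, nx)
  ws <- apply(combos, 2L, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  p_ge <- mean(ws >= W)
  p_le <- mean(ws <= W)
  list(W = W, p = min(1, 2 * min(p_ge, p_le)))
}

# NB log-likelihood with log link and log-area offset.
nb_loglik <- function(par, counts, areas, sandy) {
  eta <- par[1L] + if (length(par) > 2L) par[2L] * sandy else 0
  mu <- exp(eta + log(areas))
  theta <- exp(par[length(par)])
  sum(dnbinom(counts, mu = mu, size = theta, log = TRUE))
}

# NB residual deviance given theta (y log y term is 0 at y = 0).
nb_deviance <- function(counts, mu, theta) {
  t1 <- ifelse(counts > 0, counts * log(counts / mu), 0)
  t2 <- (counts + theta) * log((counts + theta) / (mu + theta))
  2 * sum(t1 - t2)
}

# Joint ML refit of count ~ terrain + offset(log(area)) by direct
# optimisation, plus the percent deviance explained computed with the
# fitted theta (null model refit as intercept-only at the same theta).
nb_joint_ml <- function(counts, areas, terrain) {
  sandy <- as.numeric(terrain == "sandy_type")
  start <- c(log(sum(counts) / sum(areas)), 0, log(1))
  opt <- optim(start, nb_loglik, counts = counts, areas = areas,
               sandy = sandy, method = "BFGS",
               control = list(fnscale = -1, reltol = 1e-15, maxit = 2000))
  b0 <- opt$par[1L]; b1 <- opt$par[2L]; theta <- exp(opt$par[3L])
  mu_full <- exp(b0 + b1 * sandy + log(areas))
  dev_res <- nb_deviance(counts, mu_full, theta)
  # intercept-only ML at fixed theta (1-D, high precision)
  f0 <- function(b) {
    mu <- exp(b + log(areas))
    sum(dnbinom(counts, mu = mu, size = theta, log = TRUE))
  }
  b_null <- optimize(f0, interval = c(b0 - 10, b0 + 10), maximum = TRUE,
                     tol = 1e-12)$maximum
  dev_null <- nb_deviance(counts, exp(b_null + log(areas)), theta)
  list(intercept = b0, sandy = b1, theta = theta,
       residual_deviance = dev_res, null_deviance = dev_null,
       deviance_explained = 100 * (1 - dev_res / dev_null))
}

# Standard synthetic fixture: balanced polygons of one grid-cell size at
# the generating coefficients of the pooled count model.
make_nb_fixture <- function(n = 2000L, beta0 = -0.434, beta_sandy = 0.305,
                            theta = 8.979, area = 19.68^2, seed = 1L) {
  set.seed(seed)
  terrain <- rep(c("rocky_type", "sandy_type"), each = n / 2L)
  mu <- exp(beta0 + beta_sandy * (terrain == "sandy_type")) * area
  counts <- rnbinom(n, mu = mu, size = theta)
  data.frame(count = counts, area = area, terrain = terrain,
             stringsAsFactors = FALSE)
}
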