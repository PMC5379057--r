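# Independent oracle for the linear mass-balance system: assembles the
# balance matrix directly from the path list and solves the constant-rate
# system in closed form with a matrix exponential (Matrix::expm), with no
# use of the package's ODE machinery.

oracle_system <- function(config, rates = NULL, eliminations = NULL) {
  ids <- config$modules$id
  V <- stats::setNames(config$modules$volume_ml, ids)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  p <- config$paths
  for (i in seq_len(nrow(p))) {
    s <- p$src[i]; d <- p$dst[i]; q <- p$rate_ml_h[i]
    A[d, s] <- A[d, s] + q / V[d]
    A[s, s] <- A[s, s] - q / V[s]
  }
  acc <- config$acceptor_id
  inflow_acc <- sum(p$rate_ml_h[p$dst == acc])
  A[acc, acc] <- A[acc, acc] - inflow_acc / V[acc]
  b <- stats::setNames(numeric(n), ids)
  if (!is.null(rates)) b[names(rates)] <- rates / V[names(rates)]
  if (!is.null(eliminations)) {
    for (id in names(eliminations)) {
      A[id, id] <- A[id, id] - eliminations[[id]]
    }
  }
  list(A = A, b = b, ids = ids, V = V)
}

# Closed-form solution of dC/dt = A C + b via the augmented matrix
# exponential: d/dt [C; 1] = [[A, b], [0, 0]] [C; 1].
oracle_solution <- function(config, rates, times, init = NULL,
                            eliminations = NULL) {
  sys <- oracle_system(config, rates, eliminations)
  n <- length(sys$ids)
  M <- rbind(cbind(sys$A, sys$b), 0)
  y0 <- c(if (is.null(init)) numeric(n) else init[sys$ids], 1)
  out <- t(vapply(times, function(t) {
    as.numeric(Matrix::expm(M * t) %*% y0)[seq_len(n)]
  }, numeric(n)))
  colnames(out) <- sys$ids
  out
}

# Random flow-balanced 5-module chain (donor, three tissues, acceptor),
# optionally with a balanced recirculation loop t3 -> t1.
random_chain_config <- function(with_recirc = FALSE) {
  v <- stats::runif(5, 0.1, 1)
  q <- stats::runif(1, 0.02, 0.2)
  qr <- if (with_recirc) stats::runif(1, 0, 0.5) else 0
  modules <- rbind(
    mfp_module("donor", "donor", v[1]),
    mfp_module("t1", "tissue", v[2]),
    mfp_module("t2", "tissue", v[3]),
    mfp_module("t3", "tissue", v[4]),
    mfp_module("acceptor", "acceptor", v[5]))
  paths <- rbind(
    mfp_path("donor", "t1", q),
    mfp_path("t1", "t2", q + qr),
    mfp_path("t2", "t3", q + qr),
    mfp_path("t3", "acceptor", q))
  if (with_recirc) {
    paths <- rbind(paths, mfp_path("t3", "t1", qr, kind = "recirculation"))
  }
  platform_config("random-chain", modules, paths)
}

# Daily integer-day noiseless acceptor series for a Solo run of a profile.
solo_daily_series <- function(profile, analyte,
                              t_grid = seq(0, 28 * 24, by = 1)) {
  solo <- make_platform("solo")
  spec <- cycle_secretion_spec(profile, "tissue", analyte)
  traj <- simulate_platform(solo, spec, t_grid)
  sample_assay(traj, "acceptor", analyte, noise_cv = 0)
}
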