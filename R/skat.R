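#' Intercept-only binary null model for score tests
#'
#' The standard null model of the binary-trait kernel association
#' framework with no covariates: the fitted mean is the cohort-B
#' fraction, residuals are `y - mu`, and the working variance is
#' `mu * (1 - mu)` for every sample.
#'
#' @param y binary phenotype vector (0 = cohort A, 1 = cohort B).
#' @return list of class `skat_null_model`: `y`, `mu`, `resid`, `v`,
#'   `n`.
#' @export
skat_null_model <- function(y) {
  stopifnot(all(y %in% c(0, 1)))
  mu <- mean(y)
  if (mu <= 0 || mu >= 1) abort("phenotype must contain both cohorts")
  structure(list(y = y, mu = mu, resid = y - mu, v = mu * (1 - mu),
                 n = length(y)),
            class = "skat_null_model")
}

#' Beta-density MAF weights
#'
#' The default rare-variant weighting: `w_j = dbeta(MAF_j, 1, 25)`,
#' upweighting rarer variants.
#'
#' @param maf minor allele frequencies in (0, 1).
#' @param a1,a2 Beta shape parameters.
#' @return positive weights.
#' @export
beta_maf_weights <- function(maf, a1 = 1, a2 = 25) {
  stopifnot(all(maf > 0 & maf < 1))
  dbeta(maf, a1, a2)
}

# Mean-impute missing dosages per variant (score tests only; the
# collapsed-count tests use observed alleles directly).
impute_dosage <- function(G) {
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- mean(G[!miss, j])
  }
  G
}

# Eigenvalues of a PSD matrix, dropping numerically-zero ones.
psd_eigenvalues <- function(K) {
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  pos <- lambda[lambda > 0]
  if (length(pos) == 0) return(numeric())
  lambda[lambda >= mean(pos) * 1e-10]
}

#' Tail probability of a weighted sum of chi-squared(1) variables
#'
#' Computes `P(sum(lambda_i * chisq_1) > q)`.  The default is the
#' Liu-Tang-Zhang four-moment match to a noncentral chi-squared, which
#' is exact for equal eigenvalues; `method = "imhof"` numerically
#' inverts the characteristic function (Imhof's integral) instead.
#' Results are clamped to `(1e-300, 1]`.
#'
#' @param q observed statistic.
#' @param lambda eigenvalues (not all non-positive).
#' @param method `"liu"` (moment match, default) or `"imhof"` (numerical
#'   inversion).
#' @return upper-tail probability.
#' @export
quadform_pvalue <- function(q, lambda, method = c("liu", "imhof")) {
  method <- arg_match(method)
  lambda <- lambda[is.finite(lambda)]
  if (length(lambda) == 0 || all(lambda <= 0)) abort("eigenvalues must not all be <= 0")
  if (q <= 0) return(1)
  p <- if (method == "liu") liu_pvalue(q, lambda) else imhof_pvalue(q, lambda)
  min(max(p, 1e-300), 1)
}

liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- c2^3 / c3^2
  }
  t_star <- (q - c1) / sqrt(2 * c2)
  x <- t_star * sqrt(2 * (df + 2 * delta)) + df + delta
  pchisq(x, df = df, ncp = delta, lower.tail = FALSE)
}

# Vectorised Liu tail for a fixed eigenvalue set (params from
# liu_params); used to rank SKAT-O statistics across many assignments.
liu_tail_vec <- function(q, lp) {
  x <- (q - lp$mu_q) / lp$sigma_q * sqrt(2 * (lp$df + 2 * lp$delta)) +
    lp$df + lp$delta
  if (lp$delta == 0) {
    pchisq(x, df = lp$df, lower.tail = FALSE)
  } else {
    pchisq(x, df = lp$df, ncp = lp$delta, lower.tail = FALSE)
  }
}

# Liu parameters reused by SKAT-O for per-rho null quantiles.
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- c2^3 / c3^2
  }
  list(mu_q = c1, sigma_q = sqrt(2 * c2), df = df, delta = delta)
}

imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  # The integrand oscillates with asymptotic half-period 2*pi/q under a
  # polynomially decaying envelope: integrate chunk by chunk and stop
  # once consecutive partial sums (whose average accelerates the
  # alternating tail) agree.
  h <- 2 * pi / max(q, 0.5 * sum(lambda))
  total <- 0
  prev_total <- Inf
  for (k in 0:5000) {
    piece <- integrate(integrand, lower = k * h, upper = (k + 1) * h,
                       subdivisions = 200L, rel.tol = 1e-8,
                       abs.tol = 1e-12, stop.on.error = FALSE)$value
    new_total <- total + piece
    if (k > 2 && abs(new_total - prev_total) < 1e-8 &&
        abs(piece) < 1e-8) {
      total <- new_total
      break
    }
    prev_total <- total
    total <- new_total
  }
  min(max(0.5 + total / pi, 0), 1)
}

the_assignment_cache <- new.env(parent = emptyenv())

# All distinct case/control assignments with k cases among n samples,
# as an n x choose(n, k) 0/1 matrix (cached).
case_assignments <- function(n, k) {
  key <- paste(n, k, sep = "_")
  hit <- the_assignment_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- utils::combn(n, k)
  y_all <- matrix(0, n, ncol(idx))
  y_all[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = k))] <- 1
  the_assignment_cache[[key]] <- y_all
  y_all
}

exact_feasible <- function(null, limit = 20000) {
  choose(null$n, sum(null$y)) <= limit
}

# Resolve the exact-null switch. With "auto" (default) the exact
# conditional null is used whenever full enumeration of case
# assignments is feasible; the asymptotic quadratic-form null is used
# otherwise and under "never".
use_exact_null <- function(exact, null) {
  switch(exact,
    auto = exact_feasible(null),
    never = FALSE,
    always = {
      if (!exact_feasible(null)) {
        abort("exact enumeration infeasible for this design; use exact = 'auto' or 'never'")
      }
      TRUE
    }
  )
}

# Weighted, variance-scaled, column-centred genotype matrix Z1 such
# that under the null Var(t(Z) %*% r) = t(Z1) %*% Z1.
skat_z1 <- function(G, null, w) {
  Z <- sweep(G, 2, w, "*")
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  Zc * sqrt(null$v)
}

#' Weighted burden score test
#'
#' Collapses the weighted dosages into a single score
#' `Q_B = (sum_j w_j t(g_j) r)^2`.  In small two-cohort designs
#' (`exact = "auto"` and full enumeration feasible) the p-value is the
#' exact conditional tail probability of `Q_B` over every case/control
#' assignment with the observed case count; otherwise `Q_B / Var(Q_B)`
#' is referred to a 1-df chi-squared (the single-eigenvalue case of the
#' quadratic-form null).
#'
#' @param G dosage matrix (samples x variants; missing entries are
#'   mean-imputed).
#' @param null a [skat_null_model()].
#' @param w per-variant weights (see [beta_maf_weights()]).
#' @param exact `"auto"` (exact conditional null when enumeration of
#'   case assignments is feasible, the default), `"never"`
#'   (asymptotic), or `"always"` (error if infeasible).
#' @return p-value.
#' @export
burden_test <- function(G, null, w = NULL,
                        exact = c("auto", "never", "always")) {
  exact <- arg_match(exact)
  G <- impute_dosage(as.matrix(G))
  if (is.null(w)) w <- default_weights(G)
  stopifnot(ncol(G) == length(w), nrow(G) == null$n)
  cvec <- as.vector(G %*% w)
  q_b <- sum(cvec * null$resid)^2
  if (sum((cvec - mean(cvec))^2) * null$v <= 0) {
    warn("zero-variance collapsed genotype; p = 1")
    return(1)
  }
  if (use_exact_null(exact, null)) {
    y_all <- case_assignments(null$n, sum(null$y))
    q_all <- as.vector(crossprod(cvec, y_all - null$mu))^2
    return(mean(q_all >= q_b * (1 - 1e-12)))
  }
  lambda1 <- null$v * sum((cvec - mean(cvec))^2)
  pchisq(q_b / lambda1, df = 1, lower.tail = FALSE)
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score test `Q = t(r) G W^2 t(G) r`.  In small
#' two-cohort designs (`exact = "auto"` and enumeration feasible) the
#' p-value is the exact conditional tail probability of `Q` over every
#' case/control assignment with the observed case count; otherwise the
#' null is the weighted chi-squared mixture with eigenvalues of the
#' projected weighted kernel and the tail probability comes from
#' [quadform_pvalue()].
#'
#' @inheritParams burden_test
#' @param method asymptotic tail method passed to [quadform_pvalue()].
#' @return p-value.
#' @export
skat_test <- function(G, null, w = NULL, method = c("liu", "imhof"),
                      exact = c("auto", "never", "always")) {
  method <- arg_match(method)
  exact <- arg_match(exact)
  G <- impute_dosage(as.matrix(G))
  if (is.null(w)) w <- default_weights(G)
  stopifnot(ncol(G) == length(w), nrow(G) == null$n)
  Z <- sweep(G, 2, w, "*")
  q <- sum(as.vector(crossprod(Z, null$resid))^2)
  Z1 <- skat_z1(G, null, w)
  lambda <- psd_eigenvalues(crossprod(Z1))
  if (length(lambda) == 0) return(1)
  if (use_exact_null(exact, null)) {
    y_all <- case_assignments(null$n, sum(null$y))
    q_all <- colSums(crossprod(Z, y_all - null$mu)^2)
    return(mean(q_all >= q * (1 - 1e-12)))
  }
  quadform_pvalue(q, lambda, method = method)
}

default_weights <- function(G) {
  maf <- colMeans(G) / 2
  maf <- pmin(pmax(maf, 1e-4), 1 - 1e-4)
  beta_maf_weights(maf)
}

#' Optimal unified kernel association test (SKAT-O)
#'
#' Evaluates `Q_rho = (1 - rho) * Q_SKAT + rho * Q_Burden` over a grid
#' of rho values, computes each rho's quadratic-form p-value, and
#' combines the minimum p-value over the grid.  In small two-cohort
#' designs (`exact = "auto"` and enumeration feasible) the minimum-p
#' statistic is referred to its exact conditional null over every case
#' assignment; otherwise the combined p-value comes from the standard
#' one-dimensional integration over the shared common factor of the
#' correlated statistics.  At `rho = 0` the test reduces to SKAT, at
#' `rho = 1` to the burden test.
#'
#' @inheritParams skat_test
#' @param rho_grid grid of rho values in `[0, 1]`.
#' @return p-value.
#' @export
skato_test <- function(G, null, w = NULL,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                       method = c("liu", "imhof"),
                       exact = c("auto", "never", "always")) {
  method <- arg_match(method)
  exact <- arg_match(exact)
  G <- impute_dosage(as.matrix(G))
  if (is.null(w)) w <- default_weights(G)
  stopifnot(ncol(G) == length(w), nrow(G) == null$n,
            all(rho_grid >= 0 & rho_grid <= 1))
  rho_grid <- sort(unique(rho_grid))
  m <- ncol(G)
  if (length(rho_grid) == 1) {
    if (rho_grid == 0) return(skat_test(G, null, w, method = method, exact = exact))
    if (rho_grid == 1) return(burden_test(G, null, w, exact = exact))
  }
  if (m == 1) return(skat_test(G, null, w, method = method, exact = exact))

  Z <- sweep(G, 2, w, "*")
  s <- as.vector(crossprod(Z, null$resid))
  q_skat <- sum(s^2)
  q_burden <- sum(s)^2
  q_rho <- (1 - rho_grid) * q_skat + rho_grid * q_burden

  Z1 <- skat_z1(G, null, w)
  K <- crossprod(Z1)

  # per-rho eigenvalues and p-values
  rho_eff <- ifelse(rho_grid >= 1, 0.999, rho_grid)  # keep R_rho full rank
  lambdas <- vector("list", length(rho_grid))
  p_each <- numeric(length(rho_grid))
  for (i in seq_along(rho_grid)) {
    r_mat <- matrix(rho_eff[i], m, m)
    diag(r_mat) <- 1
    cr <- chol(r_mat)
    lambdas[[i]] <- psd_eigenvalues(cr %*% K %*% t(cr))
    p_each[i] <- if (rho_grid[i] == 1 && !use_exact_null(exact, null)) {
      burden_test(G, null, w, exact = "never")
    } else {
      quadform_pvalue(q_rho[i], lambdas[[i]], method = method)
    }
  }
  t_min <- min(p_each)
  if (!is.finite(t_min)) return(1)

  if (use_exact_null(exact, null)) {
    # Exact conditional null of the minimum-p statistic: the per-rho
    # Liu tail is a fixed monotone map of Q_rho, applied identically to
    # the observed data and to every case assignment.
    lps <- lapply(lambdas, liu_params)
    t_obs <- min(vapply(seq_along(rho_grid), function(i) {
      liu_tail_vec(q_rho[i], lps[[i]])
    }, numeric(1)))
    y_all <- case_assignments(null$n, sum(null$y))
    s_all <- crossprod(Z, y_all - null$mu)
    qs_all <- colSums(s_all^2)
    qb_all <- colSums(s_all)^2
    t_all <- rep(Inf, ncol(y_all))
    for (i in seq_along(rho_grid)) {
      q_all <- (1 - rho_grid[i]) * qs_all + rho_grid[i] * qb_all
      t_all <- pmin(t_all, liu_tail_vec(q_all, lps[[i]]))
    }
    return(mean(t_all <= t_obs * (1 + 1e-12)))
  }

  # Null decomposition along the common burden direction (Lee et al.).
  z_mean <- rowMeans(Z1)
  zm2 <- sum(z_mean^2)
  if (zm2 <= 0) return(min(1, t_min * length(rho_grid)))
  cof1 <- as.vector(crossprod(z_mean, Z1)) / zm2
  z_item1 <- outer(z_mean, cof1)
  z_item2 <- Z1 - z_item1
  w22 <- crossprod(z_item2)
  lambda0 <- psd_eigenvalues(w22)
  if (length(lambda0) == 0) return(min(1, t_min * length(rho_grid)))
  mu_q <- sum(lambda0)
  var_zeta <- 4 * sum(crossprod(z_item1) * w22)
  var_q <- 2 * sum(lambda0^2) + var_zeta
  tau <- zm2 * (rho_grid * m^2 + (1 - rho_grid) * sum(cof1^2))

  # per-rho null quantiles at the minimum p (Liu-type inversion)
  q_min <- vapply(seq_along(rho_grid), function(i) {
    lp <- liu_params(lambdas[[i]])
    x <- qchisq(t_min, df = lp$df, ncp = lp$delta, lower.tail = FALSE)
    (x - (lp$df + lp$delta)) / sqrt(2 * (lp$df + 2 * lp$delta)) * lp$sigma_q +
      lp$mu_q
  }, numeric(1))

  sd_ratio <- sqrt(max(var_q - var_zeta, 0)) / sqrt(var_q)
  integrand <- function(x) {
    vapply(x, function(xi) {
      bound <- min((q_min - tau * xi) / (1 - rho_eff))
      surv <- if (bound > sum(lambda0) * 1e4) {
        0
      } else if (bound <= 0) {
        1
      } else {
        b_std <- (bound - mu_q) * sd_ratio + mu_q
        if (b_std <= 0) 1 else quadform_pvalue(b_std, lambda0, method = method)
      }
      (1 - surv) * dchisq(xi, df = 1)
    }, numeric(1))
  }
  int <- tryCatch(
    integrate(integrand, lower = 0, upper = 40,
              subdivisions = 2000L, rel.tol = 1e-8, abs.tol = 1e-12)$value,
    error = function(e) NA_real_
  )
  p <- 1 - int
  if (!is.finite(p) || p <= 0) p <- t_min * length(rho_grid)
  min(p, 1)
}
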