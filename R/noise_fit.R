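#' Extract the noise profile of a real high/low-resolution pair
#'
#' The high-resolution image is downsampled by area averaging to create a
#' "noiseless" low-resolution image, which is subtracted from the true
#' low-resolution acquisition. The resulting signed residual array
#' characterizes the acquisition noise; its value distribution is what the
#' crappifier fit targets.
#'
#' @param hr High-resolution [image_stack()].
#' @param lr_true True low-resolution [image_stack()] (same field of view).
#' @param scale Integer factor relating the two; `downsample(hr, scale)` must
#'   match `lr_true`'s spatial shape.
#' @return An object of class `noise_profile` holding `values` (array with the
#'   low-resolution spatial shape, unclipped).
#' @export
compute_noise_profile <- function(hr, lr_true, scale) {
  lr_clean <- downsample(hr, scale)
  if (!identical(dim(lr_clean$data), dim(lr_true$data))) {
    stop("downsampled HR shape (", paste(dim(lr_clean$data), collapse = "x"),
         ") does not match true LR shape (",
         paste(dim(lr_true$data), collapse = "x"), ")")
  }
  structure(list(values = lr_true$data - lr_clean$data),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat("<noise_profile> ", paste(dim(x$values), collapse = " x "),
      ", sd = ", signif(stats::sd(as.numeric(x$values)), 4), "\n", sep = "")
  invisible(x)
}

#' Distance between two noise profiles
#'
#' First-order Wasserstein (earth mover's) distance between the empirical
#' value distributions of two profiles, computed exactly from the sorted
#' samples. The profiles need not have the same shape — only their value
#' distributions are compared. Zero iff the distributions are identical;
#' symmetric; satisfies the triangle inequality.
#'
#' @param profile_a,profile_b `noise_profile` objects (or bare numeric
#'   arrays).
#' @return Nonnegative scalar distance, in intensity units.
#' @export
profile_distance <- function(profile_a, profile_b) {
  a <- if (inherits(profile_a, "noise_profile")) profile_a$values else profile_a
  b <- if (inherits(profile_b, "noise_profile")) profile_b$values else profile_b
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("profiles must be nonempty")
  wasserstein1(a, b)
}

# Exact W1 between empirical distributions, any sample sizes.
wasserstein1 <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == nb) {
    return(mean(abs(sort(a) - sort(b))))
  }
  za <- sort(a); zb <- sort(b)
  z <- sort(c(za, zb))
  left <- z[-length(z)]
  dz <- diff(z)
  Fa <- findInterval(left, za) / na
  Fb <- findInterval(left, zb) / nb
  sum(abs(Fa - Fb) * dz)
}

#' Fit crappifier parameters to real pairs by Bayesian optimization
#'
#' Searches the crappifier parameter space for the setting whose semi-synthetic
#' low-resolution images have noise profiles distributionally closest (mean
#' 1-Wasserstein over pairs) to the measured ones. The objective surface is
#' explored with a Gaussian-process surrogate (Matérn-5/2 kernel, expected-
#' improvement acquisition, Latin-hypercube initial design). Each candidate is
#' evaluated with one shared internal noise seed so the objective is
#' quasi-deterministic, as GP optimization assumes.
#'
#' @param pairs List of `list(hr =, lr_true =)` [image_stack()] pairs.
#' @param family Noise family, as in [crappifier()].
#' @param bounds Named list of `c(low, high)` search ranges over crappifier
#'   parameters (`intensity`, `gain`, `poisson_intensity`).
#' @param n_calls Total objective evaluations (>= 10; the first
#'   `n_initial` are the space-filling design).
#' @param rng_seed Integer seed controlling the design, the acquisition
#'   randomness, and the shared noise seed.
#' @param n_initial Size of the initial design (default 10).
#' @param max_profile_values Residuals are subsampled to at most this many
#'   values per evaluation; the Wasserstein estimate is stable well below the
#'   default 1e5.
#' @param base Optional base [crappifier()] supplying the non-searched
#'   parameters (e.g. a fixed `gain` while fitting `intensity`).
#' @return An object of class `crappifier_fit` with `family`, `fitted_params`
#'   (named list), `objective`, `n_evaluations`, `trace` (a tibble of evaluated
#'   parameters, objective values and the running best), and `crappifier` (a
#'   ready-to-use [crappifier()] at the fitted parameters).
#' @export
fit_crappifier <- function(pairs, family, bounds, n_calls = 40L,
                           rng_seed = 0L, n_initial = 10L,
                           max_profile_values = 1e5, base = NULL) {
  if (length(pairs) == 0L) stop("`pairs` must be nonempty")
  if (length(bounds) == 0L) stop("`bounds` must be nonempty")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1] > b[2]) {
      stop("bounds for '", nm, "' must be c(low, high) with low <= high")
    }
  }
  n_calls <- as.integer(n_calls)
  if (n_calls < 10L) stop("n_calls must be >= 10")
  if (n_calls < n_initial) stop("n_calls must be >= the initial design size (",
                                n_initial, ")")
  if (is.null(base)) base <- crappifier(family)
  base$family <- family

  # scale inferred from each pair's shapes
  prep <- lapply(pairs, function(p) {
    sp_hr <- spatial_dim(p$hr); sp_lr <- spatial_dim(p$lr_true)
    sc <- sp_hr[1] %/% sp_lr[1]
    if (any(sp_hr != sp_lr * sc)) {
      stop("pair shapes ", sp_hr[1], "x", sp_hr[2], " and ",
           sp_lr[1], "x", sp_lr[2], " are not related by an integer scale")
    }
    lr_clean <- downsample(p$hr, sc)
    list(lr_clean = lr_clean,
         true_profile = as.numeric(p$lr_true$data - lr_clean$data))
  })

  noise_seed <- derive_seed(rng_seed, 104729L)
  subsample <- function(v, seed_off) {
    if (length(v) <= max_profile_values) return(v)
    with_seed_local(derive_seed(noise_seed, seed_off),
                    v[sample.int(length(v), max_profile_values)])
  }
  truth <- lapply(seq_along(prep), function(i) subsample(prep[[i]]$true_profile, i))

  pnames <- names(bounds)
  lo <- vapply(bounds, `[`, 0, 1)
  hi <- vapply(bounds, `[`, 0, 2)

  objective <- function(theta) {  # theta in original units, named
    cand <- base
    for (nm in pnames) cand[[nm]] <- theta[[nm]]
    ds <- vapply(seq_along(prep), function(i) {
      synth <- apply_noise(prep[[i]]$lr_clean, cand,
                           intensity = cand$intensity,
                           rng_seed = derive_seed(noise_seed, i))
      prof <- as.numeric(synth$data - prep[[i]]$lr_clean$data)
      wasserstein1(subsample(prof, i), truth[[i]])
    }, 0)
    mean(ds)
  }

  d <- length(pnames)
  X <- matrix(0, 0, d)  # unit-cube coordinates
  y <- numeric(0)
  to_unit <- function(th) (th - lo) / ifelse(hi > lo, hi - lo, 1)
  from_unit <- function(u) as.list(stats::setNames(lo + u * (hi - lo), pnames))

  design <- with_seed_local(rng_seed, lhs::randomLHS(n_initial, d))
  for (i in seq_len(n_initial)) {
    u <- design[i, ]
    X <- rbind(X, u)
    y <- c(y, objective(from_unit(u)))
  }

  for (it in seq_len(n_calls - n_initial)) {
    u_next <- with_seed_local(derive_seed(rng_seed, it), {
      propose_ei(X, y, d)
    })
    X <- rbind(X, u_next)
    y <- c(y, objective(from_unit(u_next)))
  }

  best <- which.min(y)
  fitted <- from_unit(X[best, ])
  trace <- tibble::tibble(
    eval = seq_along(y),
    objective = y,
    best_so_far = cummin(y)
  )
  for (j in seq_len(d)) trace[[pnames[j]]] <- lo[j] + X[, j] * (hi[j] - lo[j])

  cr <- base
  for (nm in pnames) cr[[nm]] <- fitted[[nm]]
  structure(list(family = family, fitted_params = fitted,
                 objective = y[best], n_evaluations = length(y),
                 trace = trace, crappifier = cr, bounds = bounds),
            class = "crappifier_fit")
}

# --- Gaussian-process surrogate ---------------------------------------------

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

pairdist <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  M <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(M, 0))
}

gp_fit <- function(X, y) {
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  ys <- (y - mu) / sdy
  D <- pairdist(X, X)
  nll <- function(par) {
    ell <- exp(par[1]); sn2 <- exp(par[2])
    K <- matern52(D, ell) + diag(sn2 + 1e-8, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(ch)))
  }
  opt <- stats::optim(c(log(0.3), log(1e-2)), nll, method = "Nelder-Mead",
                      control = list(maxit = 80))
  ell <- exp(opt$par[1]); sn2 <- exp(opt$par[2])
  K <- matern52(D, ell) + diag(sn2 + 1e-8, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(X = X, ch = ch, alpha = alpha, ell = ell, mu = mu, sdy = sdy)
}

gp_predict <- function(fit, Xnew) {
  Ks <- matern52(pairdist(Xnew, fit$X), fit$ell)
  m <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$ch), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = m * fit$sdy + fit$mu, sd = sqrt(s2) * fit$sdy)
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * stats::pnorm(z) + sd * stats::dnorm(z)
}

# Propose the next unit-cube point by maximizing EI over a random candidate
# cloud plus jittered copies of the incumbent.
propose_ei <- function(X, y, d, n_cand = 512L) {
  fit <- gp_fit(X, y)
  best_x <- X[which.min(y), , drop = FALSE]
  cand <- matrix(stats::runif(n_cand * d), n_cand, d)
  local <- matrix(pmin(pmax(rep(best_x, each = 64L) +
                              stats::rnorm(64L * d, 0, 0.05), 0), 1), 64L, d)
  cand <- rbind(cand, local)
  pr <- gp_predict(fit, cand)
  ei <- expected_improvement(pr$mean, pr$sd, min(y))
  cand[which.max(ei), ]
}

#' @export
print.crappifier_fit <- function(x, ...) {
  cat("<crappifier_fit> family=", x$family, "\n", sep = "")
  for (nm in names(x$fitted_params)) {
    cat("  ", nm, " = ", signif(x$fitted_params[[nm]], 5), "\n", sep = "")
  }
  cat("  objective (mean W1) = ", signif(x$objective, 5),
      " over ", x$n_evaluations, " evaluations\n", sep = "")
  invisible(x)
}

#' Tidy the evaluation trace of a crappifier fit
#' @param x A `crappifier_fit`.
#' @param ... Unused.
#' @return The trace as a tibble (one row per objective evaluation).
#' @export
tidy.crappifier_fit <- function(x, ...) x$trace

#' One-row summary of a crappifier fit
#' @param x A `crappifier_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the fitted parameters and final objective.
#' @export
glance.crappifier_fit <- function(x, ...) {
  tibble::tibble(family = x$family, objective = x$objective,
                 n_evaluations = x$n_evaluations,
                 !!!x$fitted_params)
}

# generics so tidy()/glance() work without broom on the search path
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")
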