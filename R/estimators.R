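# Free-energy estimators: thermodynamic integration (trapezoid), Bennett
# acceptance ratio, and multistate BAR, with overlap diagnostics, replicate
# uncertainties, and forward/reverse convergence scans.  All energies kT.

#' Thermodynamic integration by the trapezoid rule
#'
#' `sum over intervals of 0.5 (lambda_{i+1} - lambda_i)
#' (<dU/dl>_i + <dU/dl>_{i+1})`.
#'
#' @param lambdas strictly increasing lambda values (>= 2).
#' @param mean_dudl per-state mean dU/dlambda, kT.
#' @return Total Delta G, kT, with attribute `"intervals"` (per-interval
#'   contributions).
#' @export
ti_trapezoid <- function(lambdas, mean_dudl) {
  stopifnot(length(lambdas) >= 2, length(mean_dudl) == length(lambdas))
  if (any(diff(lambdas) <= 0)) stop("lambdas must be strictly increasing")
  dl <- diff(lambdas)
  intervals <- 0.5 * dl * (head(mean_dudl, -1) + tail(mean_dudl, -1))
  structure(sum(intervals), intervals = intervals)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bennett acceptance ratio for one state pair
#'
#' Self-consistent solution of the Bennett implicit equation with the
#' Fermi-function weights:
#' `sum_F f(M + w_F - dG) = sum_R f(-M + w_R + dG)`, `f(x) = 1/(1+e^x)`,
#' `M = log(n_F / n_R)`, solved to `|residual| < tol`.
#'
#' @param w_forward `DeltaU_{i->j}` evaluated on samples from state i, kT.
#' @param w_reverse `DeltaU_{j->i}` evaluated on samples from state j, kT.
#' @param tol convergence tolerance on the implicit-equation residual.
#' @return Delta G (i -> j), kT.  If the two work distributions share no
#'   overlap the best available estimate is returned with a warning and
#'   attribute `"converged" = FALSE`.
#' @export
bar_pair <- function(w_forward, w_reverse, tol = 1e-10) {
  stopifnot(length(w_forward) > 0, length(w_reverse) > 0)
  M <- log(length(w_forward) / length(w_reverse))
  # log-sum formulation of the residual; increasing in dG
  g <- function(dG) {
    .logsumexp(plogis(-(M + w_forward - dG), log.p = TRUE)) -
      .logsumexp(plogis(-(-M + w_reverse + dG), log.p = TRUE))
  }
  lo <- min(mean(w_forward), -mean(w_reverse)) - 10
  hi <- max(mean(w_forward), -mean(w_reverse)) + 10
  sol <- tryCatch(
    uniroot(g, c(lo, hi), extendInt = "upX", tol = min(tol, 1e-12),
            maxiter = 2000),
    error = function(e) NULL
  )
  if (is.null(sol)) {
    warning("BAR: no solution bracketed; phase-space overlap may be zero")
    est <- optimize(function(d) abs(g(d)), c(lo - 40, hi + 40))$minimum
    return(structure(est, converged = FALSE))
  }
  structure(sol$root, converged = abs(g(sol$root)) < 1e-8)
}

#' Multistate Bennett acceptance ratio
#'
#' Solves the MBAR self-consistency equations for the reduced free energies
#' of all K states simultaneously (self-consistent iteration, a BFGS pass on
#' the convex MBAR objective if needed, then polish), with state 1 pinned at
#' zero.  Also returns the phase-space overlap matrix (row-stochastic).
#'
#' @param u_kn either a [sample_set] or an N x K matrix of the
#'   lambda-dependent (scaled) energy of every sample at every state, kT;
#'   configuration-independent offsets cancel.
#' @param counts samples per state (length K, summing to N); taken from the
#'   sample set when one is given.
#' @param tol self-consistency tolerance, kT.
#' @param max_iter iteration cap.
#' @return List of class `mbar_fit`: `delta_g` (free energy of each state
#'   relative to state 1), `overlap`, `converged`, `iterations`.
#' @export
mbar <- function(u_kn, counts = NULL, tol = 1e-10, max_iter = 10000) {
  if (inherits(u_kn, "sample_set")) {
    counts <- u_kn$n
    u_kn <- do.call(rbind, u_kn$u_scaled)
  }
  u_kn <- as.matrix(u_kn)
  K <- ncol(u_kn)
  stopifnot(!is.null(counts), length(counts) == K, sum(counts) == nrow(u_kn),
            all(counts > 0))
  N <- nrow(u_kn)
  logN <- log(counts)
  f <- numeric(K)

  sc_update <- function(f) {
    # log denom_n = logsumexp_k (log N_k + f_k - u_nk)
    a <- sweep(-u_kn, 2, logN + f, "+")
    amax <- apply(a, 1, max)
    logden <- amax + log(rowSums(exp(a - amax)))
    fn <- vapply(seq_len(K), function(k) {
      b <- -u_kn[, k] - logden
      -.logsumexp(b)
    }, numeric(1))
    fn - fn[1]
  }
  iter <- 0L
  repeat {
    fn <- sc_update(f)
    delta <- max(abs(fn - f))
    f <- fn
    iter <- iter + 1L
    if (delta < tol || iter >= 60) break
  }
  if (delta >= tol) {
    # convex MBAR objective; minimum is the self-consistent solution
    obj <- function(fr) {
      fv <- c(0, fr)
      a <- sweep(-u_kn, 2, logN + fv, "+")
      amax <- apply(a, 1, max)
      sum(amax + log(rowSums(exp(a - amax)))) / N - sum(counts * fv) / N
    }
    grad <- function(fr) {
      fv <- c(0, fr)
      a <- sweep(-u_kn, 2, logN + fv, "+")
      amax <- apply(a, 1, max)
      w <- exp(a - amax) / rowSums(exp(a - amax))  # N x K, rows sum 1
      (colSums(w) - counts)[-1] / N
    }
    op <- optim(f[-1], obj, grad, method = "BFGS",
                control = list(maxit = max_iter, reltol = 1e-14))
    f <- c(0, op$par)
    repeat {
      fn <- sc_update(f)
      delta <- max(abs(fn - f))
      f <- fn
      iter <- iter + 1L
      if (delta < tol || iter >= max_iter) break
    }
  }
  if (delta >= tol)
    stop(sprintf("MBAR did not converge in %d iterations (residual %.3g kT)",
                 iter, delta))
  # weights and overlap: W_nk = exp(f_k - u_nk)/denom_n, sum_n W_nk = 1
  a <- sweep(-u_kn, 2, logN + f, "+")
  amax <- apply(a, 1, max)
  logden <- amax + log(rowSums(exp(a - amax)))
  logW <- sweep(-u_kn, 2, f, "+") - logden
  W <- exp(logW)
  overlap <- t(W) %*% sweep(W, 2, counts, "*")  # rows sum to 1
  structure(list(delta_g = f - f[1], overlap = overlap,
                 converged = TRUE, iterations = iter),
            class = "mbar_fit")
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat("<mbar_fit> ", length(x$delta_g), " states, Delta G(1 -> K) = ",
      format(x$delta_g[length(x$delta_g)]), " kT (",
      x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Standard deviation across trajectory replicates
#'
#' The package-wide uncertainty convention: +-1 sample standard deviation of
#' per-replicate estimates.
#' @param estimates per-trajectory Delta G estimates.
#' @return The standard deviation, or `NA` (with a message) for a single
#'   replicate.
#' @export
replicate_uncertainty <- function(estimates) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 2) {
    message("replicate uncertainty not available from a single replicate")
    return(NA_real_)
  }
  sd(estimates)
}

# estimate one method on a subset of frames (selector: function(k) -> logical)
.estimate_subset <- function(samples, method, keep = NULL) {
  K <- length(samples$lambdas)
  sel <- lapply(seq_len(K), function(k) {
    if (is.null(keep)) rep(TRUE, samples$n[k]) else keep(k)
  })
  if (any(vapply(sel, sum, integer(1)) == 0)) return(NA_real_)
  if (method == "ti") {
    means <- vapply(seq_len(K),
                    function(k) mean(samples$dudl[[k]][sel[[k]]]), numeric(1))
    return(as.numeric(ti_trapezoid(samples$lambdas, means)))
  }
  if (method == "bar") {
    total <- 0
    for (k in seq_len(K - 1)) {
      wf <- samples$u_scaled[[k]][sel[[k]], k + 1] -
        samples$u_scaled[[k]][sel[[k]], k]
      wr <- samples$u_scaled[[k + 1]][sel[[k + 1]], k] -
        samples$u_scaled[[k + 1]][sel[[k + 1]], k + 1]
      total <- total + as.numeric(bar_pair(wf, wr))
    }
    return(total)
  }
  u <- do.call(rbind, lapply(seq_len(K),
                             function(k) samples$u_scaled[[k]][sel[[k]], ,
                                                               drop = FALSE]))
  counts <- vapply(sel, sum, integer(1))
  fit <- mbar(u, counts)
  fit$delta_g[K]
}

#' Estimate the stage free energy with TI, BAR, and MBAR
#'
#' @param samples a [sample_set].
#' @param methods any of `"ti"`, `"bar"`, `"mbar"`.
#' @return An object of class `free_energy`: per-method total Delta G (kT),
#'   per-interval Delta G between adjacent states, replicate std (+-1 sd over
#'   per-trajectory estimates), and the MBAR overlap matrix.
#' @export
estimate_stage <- function(samples, methods = c("ti", "bar", "mbar")) {
  stopifnot(inherits(samples, "sample_set"))
  methods <- match.arg(methods, several.ok = TRUE)
  K <- length(samples$lambdas)
  res <- list()
  overlap <- NULL
  for (m in methods) {
    total <- .estimate_subset(samples, m)
    intervals <- switch(m,
      ti = {
        means <- vapply(seq_len(K), function(k) mean(samples$dudl[[k]]),
                        numeric(1))
        attr(ti_trapezoid(samples$lambdas, means), "intervals")
      },
      bar = vapply(seq_len(K - 1), function(k) {
        wf <- samples$u_scaled[[k]][, k + 1] - samples$u_scaled[[k]][, k]
        wr <- samples$u_scaled[[k + 1]][, k] - samples$u_scaled[[k + 1]][, k + 1]
        as.numeric(bar_pair(wf, wr))
      }, numeric(1)),
      mbar = {
        fit <- mbar(samples)
        overlap <- fit$overlap
        diff(fit$delta_g)
      }
    )
    trajs <- sort(unique(unlist(samples$traj_id)))
    per_traj <- if (length(trajs) >= 2) {
      vapply(trajs, function(t) {
        .estimate_subset(samples, m, keep = function(k) samples$traj_id[[k]] == t)
      }, numeric(1))
    } else NA_real_
    res[[m]] <- list(total = total, intervals = intervals,
                     per_trajectory = per_traj,
                     std = replicate_uncertainty(per_traj))
  }
  structure(list(methods = res, lambdas = samples$lambdas,
                 stage = samples$stage, overlap = overlap,
                 n = samples$n),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat("<free_energy> stage ", x$stage, " (", length(x$lambdas),
      " states)\n", sep = "")
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    cat(sprintf("  %-5s Delta G = %8.4f kT  (+-%s, %s replicates)\n",
                toupper(m), r$total,
                if (is.na(r$std)) "NA" else sprintf("%.4f", r$std),
                if (all(is.na(r$per_trajectory))) "1"
                else length(r$per_trajectory)))
  }
  if (!is.null(x$overlap)) {
    nn <- min(x$overlap[cbind(1:(nrow(x$overlap) - 1), 2:nrow(x$overlap))])
    cat(sprintf("  min nearest-neighbour overlap: %.3f\n", nn))
  }
  invisible(x)
}

#' @export
summary.free_energy <- function(object, ...) {
  d <- do.call(rbind, lapply(names(object$methods), function(m) {
    r <- object$methods[[m]]
    data.frame(stage = object$stage, method = m, delta_g = r$total,
               std = r$std)
  }))
  rownames(d) <- NULL
  d
}

#' Forward/reverse convergence scan
#'
#' Recomputes the stage Delta G on the first (`forward`) and last
#' (`reverse`) fraction of every trajectory's frames.  The estimate is
#' `converged` when both curves stay inside the final (100%) estimate
#' +- `band` for all fractions at or past the midpoint.
#'
#' @param samples a [sample_set].
#' @param fractions data fractions to evaluate.
#' @param method `"ti"`, `"bar"`, or `"mbar"`.
#' @param band tolerance band, kT (0.1 by convention).
#' @return An object of class `convergence_scan` with `fractions`,
#'   `forward`, `reverse`, `final`, `band`, `converged`.
#' @export
convergence_scan <- function(samples, fractions = seq(0.1, 1, by = 0.1),
                             method = "ti", band = 0.1) {
  stopifnot(inherits(samples, "sample_set"), all(fractions > 0),
            all(fractions <= 1))
  fractions <- sort(fractions)
  take <- function(direction, f) {
    function(k) {
      id <- samples$traj_id[[k]]
      keep <- rep(FALSE, length(id))
      for (t in unique(id)) {
        w <- which(id == t)
        m <- max(1L, floor(f * length(w)))
        keep[if (direction == "forward") w[seq_len(m)]
             else w[(length(w) - m + 1):length(w)]] <- TRUE
      }
      keep
    }
  }
  fw <- vapply(fractions, function(f)
    .estimate_subset(samples, method, take("forward", f)), numeric(1))
  rv <- vapply(fractions, function(f)
    .estimate_subset(samples, method, take("reverse", f)), numeric(1))
  final <- fw[length(fw)]
  mid <- fractions >= 0.5
  converged <- all(abs(fw[mid] - final) <= band, na.rm = TRUE) &&
    all(abs(rv[mid] - final) <= band, na.rm = TRUE)
  structure(list(fractions = fractions, forward = fw, reverse = rv,
                 final = final, band = band, method = method,
                 converged = converged),
            class = "convergence_scan")
}

#' @export
print.convergence_scan <- function(x, ...) {
  cat("<convergence_scan> ", x$method, ": final = ", sprintf("%.4f", x$final),
      " kT; ", if (x$converged) "converged" else "NOT converged",
      " (band +-", x$band, " kT)\n", sep = "")
  invisible(x)
}

#' @export
plot.convergence_scan <- function(x, ...) {
  rng <- range(c(x$forward, x$reverse, x$final + c(-1, 1) * x$band),
               na.rm = TRUE)
  plot(x$fractions, x$forward, type = "b", pch = 16, ylim = rng,
       xlab = "fraction of samples", ylab = "Delta G (kT)", ...)
  graphics::lines(x$fractions, x$reverse, type = "b", pch = 1, lty = 2)
  graphics::rect(0, x$final - x$band, 1, x$final + x$band,
                 col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::legend("topright", c("forward", "reverse"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
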