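#' Per-generation event frequencies
#'
#' The result of deconvolving a dye-dilution histogram: percentages
#' `X[1..D+1]` of events per generation (`X[1]` = undivided peak), the
#' number of observed divisions `D = length(X) - 1`, per-generation log10
#' boundary intervals, and fit diagnostics.
#'
#' @param X non-negative frequencies (any scale; normalized to percent).
#' @param means,sd,boundaries,loglik,n_events,converged fit diagnostics
#'   (optional when constructing by hand).
#' @return object of class `generation_frequencies`.
#' @export
generation_frequencies <- function(X, means = NULL, sd = NA_real_,
                                   boundaries = NULL, loglik = NA_real_,
                                   n_events = NA_integer_, converged = NA) {
  X <- as.numeric(X)
  if (length(X) < 1 || any(X < 0) || sum(X) <= 0)
    stop("X must be non-negative with positive sum", call. = FALSE)
  X <- 100 * X / sum(X)
  structure(list(X = X, D = length(X) - 1L, means = means, sd = sd,
                 boundaries = boundaries, loglik = loglik,
                 n_events = n_events, converged = converged),
            class = "generation_frequencies")
}

#' @export
print.generation_frequencies <- function(x, ...) {
  cat(sprintf("<generation_frequencies> D = %d divisions\n", x$D))
  print(round(stats::setNames(x$X, paste0("Gen", seq_along(x$X))), 2))
  if (!is.null(x$means))
    cat("means:", paste(round(x$means, 3), collapse = " "),
        " shared sd:", signif(x$sd, 3), "\n")
  invisible(x)
}

# Strongest mode of a kernel density estimate: the tallest peak is the most
# reliably detected landmark; the mean lattice is anchored on it and
# extended in both directions.
kde_strongest_mode <- function(x) {
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Deconvolve a fluorescence distribution into generations
#'
#' Fits a constrained one-dimensional Gaussian mixture to a log10-scaled
#' dye channel: component means lie on a lattice
#' `mu_g = mu_1 - (g-1) * delta` with `delta` initialized at
#' `log10(dilution_factor)` (each division halves the label for factor 2)
#' and optionally refined within +/-10%; the component sd is shared.
#' Mixture weights, times 100, are the per-generation frequencies
#' `X[1..D+1]`; trailing components with weight below `min_weight` are
#' dropped and `D` reduced accordingly, so `D` is derived from the data,
#' never asserted.
#'
#' Near-discrete data (at most `max_generations` distinct values, e.g. a
#' noiseless simulation) bypass EM and are counted exactly on the lattice.
#' Large samples are binned into a fine histogram (`n_bins` weighted
#' observations) before EM; with bin width far below the component sd the
#' approximation is negligible and fitting cost is independent of n.
#'
#' @param table an [event_table()] (or numeric vector of log10 values).
#' @param channel channel to deconvolve (default `"CellTrace"`).
#' @param max_generations ceiling on the number of components.
#' @param dilution_factor per-division dilution (default 2).
#' @param refine_delta refine the lattice step within +/-10%?
#' @param min_weight components beyond the last peak with weight below this
#'   fraction are dropped (default 0.005 = 0.5%).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param n_bins histogram resolution for large samples.
#' @param min_events refuse to fit fewer events than this.
#' @return a [generation_frequencies()].
#' @export
fit_generations <- function(table, channel = "CellTrace",
                            max_generations = 12, dilution_factor = 2,
                            refine_delta = TRUE, min_weight = 0.005,
                            max_iter = 500, tol = 1e-8, n_bins = 2048,
                            min_events = 200) {
  if (inherits(table, "event_table")) {
    if (!channel %in% channels(table))
      stop("unknown channel '", channel, "'", call. = FALSE)
    tr <- transform_state(table)[[channel]]
    if (!is.na(tr) && tr == "linear")
      warning("channel '", channel, "' is on a linear scale; ",
              "deconvolution expects log10", call. = FALSE)
    x <- table[[channel]]
  } else {
    x <- as.numeric(table)
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < min_events)
    stop("need at least ", min_events, " events, got ", n, call. = FALSE)
  delta0 <- log10(dilution_factor)

  # exact path for (near-)noiseless data: count events on the lattice
  ux <- sort(unique(round(x, 9)), decreasing = TRUE)
  if (length(ux) <= max_generations) {
    mu1 <- ux[1]
    gen <- pmin(round((mu1 - round(x, 9)) / delta0) + 1L, max_generations)
    K <- max(gen)
    w <- tabulate(gen, K) / n
    means <- mu1 - (seq_len(K) - 1) * delta0
    return(finish_fit(w, means, 0, delta0, sum(log(w[gen])), n, TRUE,
                      min_weight))
  }

  # bin large samples into a weighted histogram
  if (n > 5000) {
    br <- seq(min(x), max(x), length.out = n_bins + 1)
    mids <- (br[-1] + br[-length(br)]) / 2
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
    keep <- cnt > 0
    xs <- mids[keep]; wt <- cnt[keep]
  } else {
    xs <- x; wt <- rep(1, n)
  }

  # Anchor on the strongest density mode (always reliable), then extend the
  # mean lattice upward to cover the brightest events: in heavily divided
  # cultures the undivided peak can hold well under 1% of events and is
  # invisible to mode detection, but its events still sit k full dilution
  # steps above the anchor.  Spurious leading components (pure Gaussian tail
  # of the top real peak) collect negligible weight and are dropped after
  # fitting.
  m_star <- kde_strongest_mode(x)
  k_up <- max(0L, as.integer(floor((max(x) - m_star) / delta0 + 0.5)))
  mu1 <- m_star + k_up * delta0
  K <- min(max_generations,
           max(1L, 1L + as.integer(floor((mu1 - min(x)) / delta0 + 0.5))))
  delta <- delta0
  means <- mu1 - (seq_len(K) - 1) * delta
  # crude init: assign to nearest mean
  nearest <- apply(abs(outer(xs, means, "-")), 1, which.min)
  w <- pmax(vapply(seq_len(K), function(g) sum(wt[nearest == g]), 0), 0.5) /
    sum(wt)
  w <- w / sum(w)
  sigma <- max(stats::sd(xs - means[nearest]), 0.01)
  sigma_min <- 1e-4
  z <- seq_len(K) - 1

  loglik <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step (log-space for stability)
    lp <- outer(xs, means, function(a, b) stats::dnorm(a, b, sigma,
                                                       log = TRUE))
    lp <- sweep(lp, 2, log(pmax(w, 1e-300)), "+")
    m <- apply(lp, 1, max)
    pr <- exp(lp - m)
    rs <- rowSums(pr)
    r <- pr / rs
    new_ll <- sum(wt * (m + log(rs)))
    # M-step
    rw <- r * wt
    Ng <- colSums(rw)
    w <- Ng / sum(Ng)
    S <- sum(Ng); Sz <- sum(Ng * z); Szz <- sum(Ng * z^2)
    Sx <- sum(rw * xs); Sxz <- sum(sweep(rw, 2, z, "*") * xs)
    denom <- Szz - Sz^2 / S
    if (denom > 1e-12) {
      beta1 <- (Sxz - Sx * Sz / S) / denom
      new_delta <- -beta1
      if (refine_delta)
        delta <- min(max(new_delta, 0.9 * delta0), 1.1 * delta0)
      mu1 <- (Sx + delta * Sz) / S
    } else {
      mu1 <- Sx / S
    }
    means <- mu1 - z * delta
    resid2 <- sweep(outer(xs, means, "-")^2 * r, 1, wt, "*")
    sigma <- max(sqrt(sum(resid2) / S), sigma_min)
    if (is.finite(loglik) && abs(new_ll - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- new_ll; converged <- TRUE; break
    }
    loglik <- new_ll
  }
  if (!converged)
    stop(sprintf(paste0("EM did not converge in %d iterations ",
                        "(loglik %.4f, sd %.4g, K %d)"),
                 max_iter, loglik, sigma, K), call. = FALSE)
  finish_fit(w, means, sigma, delta, loglik, n, converged, min_weight)
}

# Drop negligible leading components (spurious lattice extensions above the
# true undivided peak) and trailing sub-threshold components, build
# boundaries, assemble the result.  The leading cutoff is far below any
# real generation's event share, so genuine small undivided peaks survive.
finish_fit <- function(w, means, sigma, delta, loglik, n, converged,
                       min_weight, leading_min = 5e-4) {
  first <- min(c(which(w >= leading_min), length(w)))
  w <- w[first:length(w)]
  means <- means[first:length(means)]
  keep_upto <- max(c(1L, which(w >= min_weight)))
  w <- w[seq_len(keep_upto)]
  means <- means[seq_len(keep_upto)]
  K <- keep_upto
  cuts <- if (K > 1) (means[-K] + means[-1]) / 2 else numeric(0)
  boundaries <- cbind(lower = c(cuts, -Inf), upper = c(Inf, cuts))
  rownames(boundaries) <- paste0("Gen", seq_len(K))
  generation_frequencies(w / sum(w), means = means, sd = sigma,
                         boundaries = boundaries, loglik = loglik,
                         n_events = n, converged = converged)
}

#' Label events with their maximum-posterior generation
#'
#' Adds a `generation` column: the component with the highest posterior
#' probability under the fitted mixture; exact posterior ties go to the
#' lower (brighter, less-divided) generation.
#'
#' @param table an [event_table()].
#' @param fit a [generation_frequencies()] from [fit_generations()] on the
#'   same channel.
#' @param channel channel name.
#' @return the `event_table` with a `generation` column.
#' @export
assign_events <- function(table, fit, channel = "CellTrace") {
  stopifnot(inherits(fit, "generation_frequencies"))
  if (is.null(fit$means))
    stop("fit carries no component means; refit with fit_generations()",
         call. = FALSE)
  x <- table[[channel]]
  sigma <- max(fit$sd, 1e-6)
  lp <- outer(x, fit$means, function(a, b) stats::dnorm(a, b, sigma,
                                                        log = TRUE))
  lp <- sweep(lp, 2, log(pmax(fit$X / 100, 1e-300)), "+")
  # ties go to the first column = lower generation
  table$generation <- max.col(lp, ties.method = "first")
  table
}

#' Bin generations into reporting groups
#'
#' Standard reporting bins: `Gen1` (undivided), `Gen2_5` (one to four
#' divisions) and `Gen6plus` (at least five divisions).  The bins always
#' partition 100%.
#'
#' @param x a [generation_frequencies()] or numeric frequency vector.
#' @return named numeric: Gen1, Gen2_5, Gen6plus (percent).
#' @export
bin_generations <- function(x) {
  X <- if (inherits(x, "generation_frequencies")) x$X else {
    x <- as.numeric(x)
    100 * x / sum(x)
  }
  idx <- seq_along(X)
  c(Gen1 = sum(X[idx == 1]),
    Gen2_5 = sum(X[idx >= 2 & idx <= 5]),
    Gen6plus = sum(X[idx >= 6]))
}
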