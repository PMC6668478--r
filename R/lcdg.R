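#' Empirical gray-level density
#'
#' Normalized histogram of a quantized volume over `0..Q-1`, optionally
#' restricted to a voxel mask (e.g. the stripped brain).
#'
#' @param volume a [volume3d()].
#' @param Q number of gray levels.
#' @param mask optional logical array selecting the voxels to count.
#' @return numeric length-`Q` vector, non-negative, summing to 1.
#' @export
empirical_density <- function(volume, Q = volume$Q, mask = NULL) {
  v <- if (is.null(mask)) as.vector(volume$data) else volume$data[mask]
  h <- tabulate(as.integer(v) + 1L, nbins = Q)
  h / sum(h)
}

#' Discrete Gaussian bin mass
#'
#' Probability mass of gray level `q` under a Gaussian integrated over the
#' unit bin: `psi(q) = Phi(q+0.5) - Phi(q-0.5)` with the boundary bins
#' absorbing the tails (`psi(0) = Phi(0.5)`,
#' `psi(Q-1) = 1 - Phi(Q-1.5)`), so the masses sum to exactly 1.
#'
#' @param q integer gray level(s) in `0..Q-1`.
#' @param mu,sigma2 mean and variance (gray levels); `sigma2 > 0`.
#' @param Q number of gray levels.
#' @return Probability mass at each `q`.
#' @export
discrete_gaussian <- function(q, mu, sigma2, Q = 256L) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  s <- sqrt(sigma2)
  upper <- ifelse(q >= Q - 1, Inf, q + 0.5)
  lower <- ifelse(q <= 0, -Inf, q - 0.5)
  pnorm(upper, mu, s) - pnorm(lower, mu, s)
}

# full length-Q mass vector for one component
dg_vector <- function(mu, sigma2, Q) discrete_gaussian(0:(Q - 1), mu, sigma2, Q)

# signed mixture density over 0..Q-1 from a component table
lcdg_density <- function(comps, Q) {
  p <- numeric(Q)
  for (i in seq_len(nrow(comps)))
    p <- p + comps$sign[i] * comps$weight[i] *
      dg_vector(comps$mean[i], comps$var[i], Q)
  p
}

lcdg_loglik <- function(h, comps, Q) {
  p <- pmax(lcdg_density(comps, Q), 1e-12)
  sum(h * log(p))
}

# ---------------------------------------------------------------------------
# plain EM for a k-component (all-positive) mixture of discrete Gaussians on
# a histogram; returns a component data frame
dg_em <- function(h, k, Q, mu0 = NULL, max_iter = 300, tol = 1e-9,
                  min_var = 0.05) {
  q <- 0:(Q - 1)
  if (is.null(mu0)) mu0 <- quantile(rep(q, round(h * 1e5)),
                                    probs = (seq_len(k) - 0.5) / k,
                                    names = FALSE)
  mu <- as.numeric(mu0)
  s2 <- rep(max(stats::weighted.mean((q - sum(q * h))^2, h) / k, 4), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    psi <- vapply(seq_len(k), function(i) dg_vector(mu[i], s2[i], Q),
                  numeric(Q))
    px <- psi %*% w
    px <- pmax(px, 1e-300)
    ll <- sum(h * log(px))
    gamma <- sweep(psi, 2, w, `*`) / as.vector(px) # Q x k responsibilities
    Nk <- colSums(h * gamma)
    Nk <- pmax(Nk, 1e-12)
    mu <- colSums(h * gamma * q) / Nk
    s2 <- pmax(colSums(h * gamma * (outer(q, mu, `-`))^2) / Nk, min_var)
    w <- Nk / sum(Nk)
    if (abs(ll - ll_old) < tol * max(1, abs(ll))) break
    ll_old <- ll
  }
  data.frame(weight = w, mean = mu, var = s2)
}

# model the scaled residual deviation with up to `cap` components, choosing
# the count by residual-error reduction
fit_residual_part <- function(r, Q, cap = 4) {
  tot <- sum(r)
  if (tot < 1e-4) return(NULL)
  rn <- r / tot
  best <- NULL
  best_err <- Inf
  for (k in seq_len(cap)) {
    fit <- tryCatch(dg_em(rn, k, Q), error = function(e) NULL)
    if (is.null(fit)) next
    approx <- numeric(Q)
    for (i in seq_len(k))
      approx <- approx + fit$weight[i] * dg_vector(fit$mean[i], fit$var[i], Q)
    err <- sum((rn - approx)^2)
    if (err < best_err * 0.95) {
      best_err <- err
      best <- fit
    } else break
  }
  if (is.null(best)) return(NULL)
  best$weight <- best$weight * tot
  best
}

#' Fit a linear combination of discrete Gaussians
#'
#' Three stages: (i) two dominant positive components (bright vessels and
#' darker non-vessel tissue) by standard EM; (ii) the deviation between the
#' empirical density and the dominant mixture is modeled by alternating-sign
#' subordinate components (positive part and negative part fitted
#' separately, up to `max_subordinate` each, count chosen by residual-error
#' reduction); (iii) all parameters refined by a modified EM on signed
#' responsibilities, with weights kept non-negative, the signed-weight
#' constraint (sum of positive weights minus sum of negative weights = 1)
#' re-imposed after every update, and step damping that rejects any update
#' decreasing the log-quasi-likelihood — making the recorded likelihood
#' trace monotone non-decreasing.
#'
#' The component with the largest mean among the dominant pair anchors the
#' vessel class (time-of-flight bright-blood convention); each subordinate
#' component joins the class of its nearer dominant mean. Class priors are
#' the total signed weight allocated to each class.
#'
#' @param hist normalized gray-level histogram (length `Q`, sums to 1).
#' @param Q number of gray levels.
#' @param max_subordinate cap on subordinate components of each sign.
#' @param tol relative log-quasi-likelihood convergence tolerance.
#' @param max_iter refinement iteration cap; non-convergence is flagged in
#'   the returned model, never silent.
#' @return An object of class `lcdg_model`: `components` data frame
#'   (`weight, mean, var, sign, dominant, class`), class priors `prior_v`,
#'   `prior_o`, the `loglik_trace`, and a `converged` flag.
#' @export
fit_lcdg <- function(hist, Q = length(hist), max_subordinate = 4,
                     tol = 1e-6, max_iter = 500) {
  stopifnot(abs(sum(hist) - 1) < 1e-8, all(hist >= 0))
  q <- 0:(Q - 1)
  # (i) dominant pair, split initialized at the Otsu threshold
  t0 <- otsu_threshold(hist)
  mu0 <- c(sum(q[q <= t0] * hist[q <= t0]) / max(sum(hist[q <= t0]), 1e-12),
           sum(q[q > t0] * hist[q > t0]) / max(sum(hist[q > t0]), 1e-12))
  if (!all(is.finite(mu0))) mu0 <- quantile(rep(q, round(hist * 1e5)),
                                            c(0.25, 0.75), names = FALSE)
  dom <- dg_em(hist, 2, Q, mu0 = mu0)
  # (ii) subordinate components from the signed residual
  p_dom <- numeric(Q)
  for (i in 1:2)
    p_dom <- p_dom + dom$weight[i] * dg_vector(dom$mean[i], dom$var[i], Q)
  resid <- hist - p_dom
  sub_p <- fit_residual_part(pmax(resid, 0), Q, max_subordinate)
  sub_n <- fit_residual_part(pmax(-resid, 0), Q, max_subordinate)
  comps <- data.frame(weight = dom$weight, mean = dom$mean, var = dom$var,
                      sign = 1, dominant = TRUE)
  if (!is.null(sub_p))
    comps <- rbind(comps, cbind(sub_p, sign = 1, dominant = FALSE))
  if (!is.null(sub_n))
    comps <- rbind(comps, cbind(sub_n, sign = -1, dominant = FALSE))
  comps <- normalize_weights(comps)
  # (iii) modified EM refinement with damping
  trace <- lcdg_loglik(hist, comps, Q)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prop <- lcdg_em_step(hist, comps, Q)
    ll_old <- trace[length(trace)]
    lam <- 1
    repeat {
      cand <- blend_comps(comps, prop, lam)
      cand <- normalize_weights(cand)
      ll_new <- lcdg_loglik(hist, cand, Q)
      if (ll_new >= ll_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-4) {
        cand <- comps
        ll_new <- ll_old
        break
      }
    }
    comps <- cand
    trace <- c(trace, max(ll_new, ll_old))
    if (abs(ll_new - ll_old) < tol * max(1, abs(ll_old))) {
      converged <- TRUE
      break
    }
  }
  # class allocation: largest dominant mean -> vessel
  dom_means <- comps$mean[comps$dominant]
  vessel_anchor <- max(dom_means)
  other_anchor <- min(dom_means)
  comps$class <- ifelse(abs(comps$mean - vessel_anchor) <=
                          abs(comps$mean - other_anchor), "vessel", "other")
  prior_v <- sum(comps$sign[comps$class == "vessel"] *
                   comps$weight[comps$class == "vessel"])
  prior_v <- min(max(prior_v, 1e-6), 1 - 1e-6)
  structure(list(Q = Q, components = comps, prior_v = prior_v,
                 prior_o = 1 - prior_v, loglik_trace = trace,
                 converged = converged),
            class = "lcdg_model")
}

# enforce w >= 0 and sum(w_p) - sum(w_n) = 1 by rescaling positive weights
normalize_weights <- function(comps) {
  comps$weight <- pmax(comps$weight, 1e-8)
  wp <- sum(comps$weight[comps$sign > 0])
  wn <- sum(comps$weight[comps$sign < 0])
  comps$weight[comps$sign > 0] <- comps$weight[comps$sign > 0] * (1 + wn) / wp
  comps
}

blend_comps <- function(old, new, lam) {
  out <- old
  out$weight <- (1 - lam) * old$weight + lam * new$weight
  out$mean <- (1 - lam) * old$mean + lam * new$mean
  out$var <- pmax((1 - lam) * old$var + lam * new$var, 0.05)
  out
}

# one modified-EM proposal: responsibilities are proportions of the
# *unsigned* mixture (sum_j w_j psi_j with all signs dropped), which sum to
# one at every gray level and keep the weight updates bounded even where
# positive and negative components nearly cancel
lcdg_em_step <- function(h, comps, Q) {
  q <- 0:(Q - 1)
  k <- nrow(comps)
  psi <- vapply(seq_len(k), function(i)
    dg_vector(comps$mean[i], comps$var[i], Q), numeric(Q))
  punsigned <- pmax(psi %*% comps$weight, 1e-300)
  out <- comps
  for (i in seq_len(k)) {
    g <- comps$weight[i] * psi[, i] / punsigned
    Ni <- sum(h * g)
    if (Ni < 1e-12) next
    out$weight[i] <- Ni
    out$mean[i] <- sum(h * g * q) / Ni
    out$var[i] <- max(sum(h * g * (q - out$mean[i])^2) / Ni, 0.05)
  }
  out
}

#' @export
print.lcdg_model <- function(x, ...) {
  cat(sprintf("<lcdg_model> Q=%d, %d component(s), P(vessel)=%.4f%s\n",
              x$Q, nrow(x$components), x$prior_v,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$components, digits = 4)
  invisible(x)
}

#' Evaluate the fitted signed mixture
#'
#' @param model an `lcdg_model`.
#' @return length-`Q` signed density (may dip below zero locally before the
#'   class-conditional clipping).
#' @export
lcdg_predict <- function(model) lcdg_density(model$components, model$Q)

# class-conditional density: signed sum of the class's components, clipped
# at zero and renormalized (negative-weight mixtures can dip below zero)
class_conditional <- function(model, cls) {
  sel <- model$components$class == cls
  p <- lcdg_density(model$components[sel, , drop = FALSE], model$Q)
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) return(rep(0, model$Q))
  p / s
}

#' Gray-level decision rule of the fitted model
#'
#' Applies the Bayesian rule `P(v) p(q|v) >= P(O) p(q|O)` and closes the
#' vessel set upward (bright-blood convention): the decision is `q >= q*`
#' with `q*` the lowest gray level at or above the non-vessel dominant mean
#' where the rule favors the vessel class. This keeps the decision monotone
#' in intensity and immune to spurious wins at gray levels where both
#' clipped class densities vanish.
#'
#' @param model an `lcdg_model`.
#' @return logical length-`Q` vector: `TRUE` where the level is vessel.
#' @export
lcdg_decision <- function(model) {
  out <- rep(FALSE, model$Q)
  if (model$prior_v <= 0) return(out)
  pv <- class_conditional(model, "vessel")
  po <- class_conditional(model, "other")
  raw <- model$prior_v * pv >= model$prior_o * po & pv > 0
  # q* = lowest level from which the vessel class wins contiguously up to
  # its own dominant mode (isolated wins inside the inter-mode valley,
  # where the clipped non-vessel density vanishes, are not a boundary)
  vi <- round(max(model$components$mean[model$components$dominant])) + 1L
  vi <- min(max(vi, 1L), model$Q)
  if (raw[vi]) {
    qstar <- vi
    while (qstar > 1 && raw[qstar - 1]) qstar <- qstar - 1
  } else {
    above <- which(raw & seq_along(raw) > vi)
    if (length(above) == 0) return(out)
    qstar <- min(above)
  }
  out[qstar:model$Q] <- TRUE
  out
}

#' Initial Bayesian vessel classification
#'
#' Labels a voxel vessel iff `P(v) p(q|v) >= P(O) p(q|O)` for its gray level
#' `q`, using the class-conditional densities assembled from the model's
#' vessel/other components. Voxels outside `mask` are background.
#'
#' @param volume a [volume3d()].
#' @param model an `lcdg_model`.
#' @param mask optional logical array restricting classification (e.g. the
#'   stripped brain).
#' @return A [vessel_mask()].
#' @export
classify_initial <- function(volume, model, mask = NULL) {
  lut <- lcdg_decision(model)
  m <- array(lut[as.integer(volume$data) + 1L], dim(volume$data))
  if (!is.null(mask)) m <- m & mask
  vessel_mask(m, spacing = volume$spacing)
}

#' Serialize / load an LCDG model as structured text
#'
#' @param model an `lcdg_model`.
#' @param path file path (JSON).
#' @export
write_lcdg <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for model serialization")
  obj <- list(Q = model$Q, components = model$components,
              prior_v = model$prior_v, prior_o = model$prior_o,
              converged = model$converged)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_lcdg
#' @export
read_lcdg <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for model serialization")
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  structure(list(Q = obj$Q, components = as.data.frame(obj$components),
                 prior_v = obj$prior_v, prior_o = obj$prior_o,
                 loglik_trace = numeric(0), converged = obj$converged),
            class = "lcdg_model")
}
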