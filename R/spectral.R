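# Heavy-tailed self-regularization audit: eigenvalue spectra of layer weight
# matrices, power-law tail-exponent fits, and the 2-6 "well-trained" band.
#
# The tail exponent alpha of a layer's weight-correlation eigenvalue spectral
# density diagnoses training quality without any data: 2 <= alpha <= 6 marks
# a well-trained layer, alpha > 6 overfitting, alpha < 2 underfitting.

#' Eigenvalue spectral density of a weight array
#'
#' Convolution kernels `(k, k, cin, cout)` are reshaped to
#' `(cout, k^2 * cin)`; 2-D arrays are taken as `(fan_in, fan_out)` and
#' transposed.  Returns the eigenvalues of the fan-in-normalized Gram matrix
#' `W W' / fan_in`, sorted decreasing.
#'
#' @param weights a 2-D or 4-D numeric array.
#' @return numeric vector of nonnegative eigenvalues.
#' @export
layer_esd <- function(weights) {
  d <- dim(weights)
  if (is.null(d) || length(d) < 2)
    stop("layer_esd needs a 2-D or 4-D weight array", call. = FALSE)
  X <- if (length(d) == 2) t(weights)
       else matrix(aperm(array(weights, c(prod(d[-length(d)]), d[length(d)])),
                         c(2, 1)), d[length(d)], prod(d[-length(d)]))
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("weight array too small for a spectrum", call. = FALSE)
  g <- tcrossprod(X) / ncol(X)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  sort(pmax(ev, 0), decreasing = TRUE)
}

#' Sample from a continuous power law (for calibration tests)
#'
#' Density `p(x) ~ x^(-alpha)` for `x >= xmin`.
#'
#' @param n sample count. @param alpha tail exponent (> 1). @param xmin
#'   lower cutoff.
#' @return numeric vector.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1) {
  stopifnot(alpha > 1, xmin > 0)
  xmin * (1 - stats::runif(n))^(-1 / (alpha - 1))
}

#' Continuous maximum-likelihood power-law tail fit
#'
#' For each candidate cutoff the tail exponent is the continuous MLE
#' `alpha = 1 + n / sum(log(x / xmin))`; the cutoff minimizing the
#' Kolmogorov-Smirnov distance between the tail's empirical distribution and
#' the fitted power law is selected.
#'
#' @param eigs positive values (at least 10).
#' @param max_candidates cap on distinct cutoffs scanned (quantile-spaced).
#' @return list(alpha, xmin, ks, n_tail) of class `powerlaw_fit`.
#' @export
fit_power_law <- function(eigs, max_candidates = 100L) {
  x <- sort(eigs[is.finite(eigs) & eigs > 0])
  if (length(x) < 10)
    stop("need at least 10 positive values to fit a tail", call. = FALSE)
  cand <- unique(x[x < x[length(x)]])
  if (length(cand) > max_candidates)
    cand <- unique(stats::quantile(cand, probs = seq(0, 1,
                                                     length.out = max_candidates),
                                   names = FALSE, type = 1))
  best <- NULL
  for (xm in cand) {
    tail <- x[x >= xm]
    nt <- length(tail)
    if (nt < 10) next
    s <- sum(log(tail / xm))
    if (s <= 0) next
    alpha <- 1 + nt / s
    ecdf_t <- seq_len(nt) / nt
    cdf_t <- 1 - (xm / tail)^(alpha - 1)
    ks <- max(abs(ecdf_t - cdf_t), abs(ecdf_t - 1 / nt - cdf_t))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = xm, ks = ks, n_tail = nt)
  }
  if (is.null(best))
    stop("no admissible cutoff found for the tail fit", call. = FALSE)
  structure(best, class = "powerlaw_fit")
}

#' Band label for a tail exponent
#'
#' @param alpha tail exponent(s).
#' @return `"underfit"` (< 2), `"well-trained"` (2-6) or `"overfit"` (> 6).
#' @export
alpha_band <- function(alpha) {
  ifelse(alpha < 2, "underfit",
         ifelse(alpha > 6, "overfit", "well-trained"))
}

default_component <- function(path, family) {
  top <- sub("\\..*$", "", path)
  if (identical(family, "s2agscunet")) {
    switch(top, encoder = "Encoder", neck = "Neck", decoder = "Decoder",
           "Other")
  } else {
    if (grepl("^enc|^bott", top)) "Encoder"
    else if (grepl("^up|^dec|^head", top)) "Decoder"
    else "Other"
  }
}

#' Spectral audit of a model's weight matrices
#'
#' Fits a power-law tail exponent to the eigenvalue spectral density of
#' every eligible weight array (2-D or flattened convolution kernel with at
#' least 10 eigenvalues; vector-shaped parameters are skipped), then
#' aggregates mean exponents per component and labels them with the 2/6
#' band thresholds.
#'
#' @param model a `panseg_model` or `panseg_encoder`.
#' @param grouping either `"component"` (encoder/neck/decoder by parameter
#'   path), `"single"` (one component), or a function `path -> label`.
#' @param min_eigs smallest usable spectrum; smaller layers are flagged and
#'   excluded from aggregates.
#' @return object of class `alpha_report`: list with `layers` and
#'   `components` data.frames.
#' @export
audit_model <- function(model, grouping = "component", min_eigs = 10L) {
  fp <- flatten_params(if (inherits(model, "panseg_encoder")) model$params
                       else model$params)
  family <- if (inherits(model, "panseg_encoder")) "encoder"
            else model$spec$family
  grp <- if (is.function(grouping)) grouping
         else if (identical(grouping, "single")) function(p) "model"
         else function(p) default_component(p, family)
  rows <- NULL
  for (nm in names(fp)) {
    a <- fp[[nm]]
    d <- dim(a)
    if (is.null(d) || length(d) < 2) next          # vectors skipped
    if (min(d[length(d)], prod(d[-length(d)])) < 2) next
    ev <- layer_esd(a)
    if (length(ev) < min_eigs || sum(ev > 0) < min_eigs) {
      rows <- rbind(rows, data.frame(
        layer = nm, component = grp(nm), alpha = NA, xmin = NA, ks = NA,
        n_eigs = length(ev), flagged = TRUE))
      next
    }
    ft <- fit_power_law(ev)
    rows <- rbind(rows, data.frame(
      layer = nm, component = grp(nm), alpha = ft$alpha, xmin = ft$xmin,
      ks = ft$ks, n_eigs = length(ev), flagged = FALSE))
  }
  if (is.null(rows)) stop("model has no eligible layers", call. = FALSE)
  comp <- NULL
  for (cn in unique(rows$component)) {
    sub <- rows[rows$component == cn & !rows$flagged, ]
    if (nrow(sub) == 0) next
    ma <- mean(sub$alpha)
    comp <- rbind(comp, data.frame(component = cn, mean_alpha = ma,
                                   n_layers = nrow(sub),
                                   band = alpha_band(ma)))
  }
  structure(list(layers = rows, components = comp),
            class = "alpha_report")
}

#' @export
print.alpha_report <- function(x, ...) {
  cat("spectral audit (well-trained band: 2 <= alpha <= 6)\n")
  print(x$components, row.names = FALSE)
  n_fl <- sum(x$layers$flagged)
  cat(sprintf("%d layers fit, %d flagged (too few eigenvalues)\n",
              sum(!x$layers$flagged), n_fl))
  invisible(x)
}

#' @export
#' @importFrom graphics abline barplot legend par
plot.alpha_report <- function(x, ...) {
  ok <- x$layers[!x$layers$flagged, ]
  bp <- barplot(ok$alpha, names.arg = seq_len(nrow(ok)),
                col = ifelse(ok$alpha < 2, "steelblue",
                             ifelse(ok$alpha > 6, "firebrick", "seagreen")),
                xlab = "layer", ylab = "alpha",
                main = "power-law tail exponents", ...)
  abline(h = c(2, 6), lty = 2)
  invisible(bp)
}
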