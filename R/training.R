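# Cross-entropy fine-tuning and temperature-scaled knowledge distillation.

#' Distillation / training configuration
#'
#' @param alpha weight of the hard-label cross-entropy term in `[0, 1]`; the
#'   softened KL term gets `1 - alpha`.
#' @param temperature softmax temperature `T > 0`; the KL term is scaled by
#'   `T^2` so its gradient magnitude is preserved as `T` grows.
#' @param epochs training epochs.
#' @param batch_size mini-batch size (16 unless scaled down for fixtures).
#' @param lr Adam learning rate.
#' @param seed seed controlling initialization-independent training
#'   randomness (shuffling).
#' @return object of class `distill_config`.
#' @export
distill_config <- function(alpha = 0.5, temperature = 2, epochs = 5,
                           batch_size = 16L, lr = 1e-3, seed = 0L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(list(alpha = alpha, temperature = temperature,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed)),
            class = "distill_config")
}

check_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must take values in {0, 1}", call. = FALSE)
}

# Row-wise log-softmax pieces; m is (pixels, classes).
logsoftmax_rows <- function(m) {
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  z <- m - mx
  z - log(rowSums(exp(z)))
}

#' Pixelwise cross-entropy loss
#'
#' Mean over all pixels of the negative log softmax probability of the true
#' class.  (The summed form is the pixel count times this value.)
#'
#' @param logits array `(H, W, classes, N)`.
#' @param labels integer array `(H, W, N)` with values in `{0, 1}`.
#' @return object of class `loss_value` with fields `total`, `ce_term`,
#'   `kl_term` (0 here).
#' @export
ce_loss <- function(logits, labels) {
  ce_loss_grad(logits, labels, want_grad = FALSE)$loss
}

ce_loss_grad <- function(logits, labels, want_grad = TRUE) {
  d <- dim(logits)
  stopifnot(length(labels) == d[1] * d[2] * d[4])
  check_labels(labels)
  m <- chan_mat(logits)
  lp <- logsoftmax_rows(m)
  ii <- cbind(seq_len(nrow(m)), as.integer(labels) + 1L)
  total <- -mean(lp[ii])
  loss <- structure(list(total = total, ce_term = total, kl_term = 0),
                    class = "loss_value")
  if (!want_grad) return(list(loss = loss))
  p <- exp(lp)
  p[ii] <- p[ii] - 1
  glogits <- mat_chan(p / nrow(m), d)
  list(loss = loss, glogits = glogits)
}

#' Knowledge-distillation loss
#'
#' `alpha * CE(y, student) + (1 - alpha) * T^2 * KL(teacher || student)`,
#' with both distributions softened by the temperature `T` and the KL taken
#' with the teacher as reference, mean over pixels.  Teacher logits are
#' treated as constants.
#'
#' @param student_logits,teacher_logits arrays `(H, W, classes, N)`.
#' @param labels integer array `(H, W, N)` in `{0, 1}`.
#' @param cfg a [distill_config()].
#' @return `loss_value` with `total`, `ce_term`, `kl_term` (the raw KL
#'   mean, before the `(1-alpha) T^2` weight).
#' @export
kd_loss <- function(student_logits, teacher_logits, labels, cfg) {
  kd_loss_grad(student_logits, teacher_logits, labels, cfg,
               want_grad = FALSE)$loss
}

kd_loss_grad <- function(student_logits, teacher_logits, labels, cfg,
                         want_grad = TRUE) {
  stopifnot(inherits(cfg, "distill_config"))
  if (!identical(dim(student_logits), dim(teacher_logits)))
    stop("student and teacher output grids disagree", call. = FALSE)
  d <- dim(student_logits)
  ce <- ce_loss_grad(student_logits, labels, want_grad = want_grad)
  Tt <- cfg$temperature
  ms <- chan_mat(student_logits) / Tt
  mt <- chan_mat(teacher_logits) / Tt
  lps <- logsoftmax_rows(ms)
  lpt <- logsoftmax_rows(mt)
  pt <- exp(lpt)
  kl <- mean(rowSums(pt * (lpt - lps)))
  total <- cfg$alpha * ce$loss$total + (1 - cfg$alpha) * Tt^2 * kl
  loss <- structure(list(total = total, ce_term = ce$loss$total,
                         kl_term = kl),
                    class = "loss_value")
  if (!want_grad) return(list(loss = loss))
  npix <- nrow(ms)
  gkl <- (exp(lps) - pt) * (Tt / npix)        # T^2 weight times 1/T chain rule
  glogits <- cfg$alpha * ce$glogits +
    (1 - cfg$alpha) * mat_chan(gkl, d)
  list(loss = loss, glogits = glogits)
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("loss %.6f (ce %.6f, kl %.6f)\n", x$total, x$ce_term,
              x$kl_term))
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(fp)) {
    if (is_frozen(fp[[nm]])) next
    g <- fg[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]]
    v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    fp[[nm]] <- fp[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = unflatten_into(params, fp), state = state)
}

# ---- training loops --------------------------------------------------------

as_dataset <- function(dataset) {
  stopifnot(is.list(dataset), !is.null(dataset$images), !is.null(dataset$masks))
  n <- dim(dataset$images)[4]
  if (n < 1) stop("dataset is empty", call. = FALSE)
  stopifnot(dim(dataset$masks)[3] == n)
  dataset
}

fit_loop <- function(model, dataset, cfg, teacher = NULL) {
  dataset <- as_dataset(dataset)
  n <- dim(dataset$images)[4]
  state <- adam_init()
  log <- NULL
  tlogits <- NULL
  if (!is.null(teacher)) {
    # teacher is fixed throughout: run it once in eval mode over the data
    tlogits <- predict_logits_chunked(teacher, dataset$images,
                                      chunk = cfg$batch_size)
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 10000L + epoch, sample.int(n))
    tot <- 0; ce_sum <- 0; kl_sum <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
      xb <- dataset$images[, , , idx, drop = FALSE]
      yb <- dataset$masks[, , idx, drop = FALSE]
      ctx <- list(buffers = model$buffers, training = TRUE)
      fw <- net_forward(model, xb, ctx)
      if (is.null(teacher)) {
        lg <- ce_loss_grad(fw$out, yb)
      } else {
        tb <- tlogits[, , , idx, drop = FALSE]
        lg <- kd_loss_grad(fw$out, tb, yb, cfg)
      }
      if (!is.finite(lg$loss$total))
        stop("training aborted: non-finite loss at epoch ", epoch,
             " (exploding optimization or bad inputs)", call. = FALSE)
      bk <- net_backward(model, fw$cache, lg$glogits)
      st <- adam_step(model$params, bk$grads, state, lr = cfg$lr)
      model$params <- st$params
      state <- st$state
      tot <- tot + lg$loss$total
      ce_sum <- ce_sum + lg$loss$ce_term
      kl_sum <- kl_sum + lg$loss$kl_term
      nb <- nb + 1L
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = tot / nb,
                                 ce_term = ce_sum / nb,
                                 kl_term = kl_sum / nb))
  }
  list(model = model, log = log)
}

#' Train a model with pixelwise cross-entropy
#'
#' Adam optimizer (lr 0.001 by default, per the reference training setup),
#' mini-batches of 16, fully seeded; frozen parameters are never updated.
#'
#' @param model a `panseg_model`.
#' @param dataset list with `images` `(H, W, 3, N)` and `masks` `(H, W, N)`.
#' @param cfg a [distill_config()] (`alpha`/`temperature` ignored here).
#' @return list with the trained `model` and the per-epoch `log`
#'   (epoch, loss, ce_term, kl_term).
#' @export
train <- function(model, dataset, cfg = distill_config()) {
  fit_loop(model, dataset, cfg, teacher = NULL)
}

#' Distill a teacher into a student model
#'
#' The teacher runs in inference mode throughout (its weights and statistics
#' are never touched); the student is optimized on [kd_loss()].  `ce_term`
#' and `kl_term` are logged separately per epoch.
#'
#' @param teacher a trained `panseg_model` (e.g. the adapter-tuned network).
#' @param student the student `panseg_model` (e.g. the 1/8-width UNet).
#' @param dataset list with `images` and `masks`.
#' @param cfg a [distill_config()].
#' @return list with the trained student `model` and the per-epoch `log`.
#' @export
distill <- function(teacher, student, dataset, cfg = distill_config()) {
  dataset <- as_dataset(dataset)
  tprobe <- model_logits(teacher,
                         dataset$images[, , , 1, drop = FALSE])
  d <- dim(dataset$images)
  if (!identical(dim(tprobe)[1:2], d[1:2]))
    stop("teacher and student output grids disagree", call. = FALSE)
  fit_loop(student, dataset, cfg, teacher = teacher)
}

# Eval-mode logits over a large batch, in chunks.
predict_logits_chunked <- function(model, images, chunk = 16L) {
  n <- dim(images)[4]
  out <- NULL
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(n, b0 + chunk - 1L)
    z <- model_logits(model, images[, , , idx, drop = FALSE])
    if (is.null(out)) out <- array(0, c(dim(z)[1:3], n))
    out[, , , idx] <- z
  }
  out
}
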