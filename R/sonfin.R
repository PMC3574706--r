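#' Self-constructing neural fuzzy inference network (SoNFIN)
#'
#' A five-layer Takagi-Sugeno-Kang fuzzy network. Each rule j holds one
#' Gaussian fuzzy set per input i (center `m[j, i]`, width `sigma[j, i]`);
#' its firing strength is the product of the per-input membership degrees
#' `exp(-(x_i - m_ji)^2 / sigma_ji^2)`; each output k is the firing-strength-
#' weighted average of the rules' linear consequents
#' `w0_jk + sum_i w_ijk x_i`. Rules are created online during training
#' whenever no existing rule fires above a threshold H.
#'
#' Firing strengths are computed in log space and normalized by
#' log-sum-exp: with hundreds of inputs, the raw product of memberships
#' underflows double precision routinely while the normalized strengths
#' remain well defined.
#'
#' @param n_inputs Input dimension (200 for two-lead beat segments).
#' @param n_outputs Number of output nodes = number of classes (default 4).
#' @param class_labels Labels attached to the output nodes, in coding order.
#' @return An empty `sonfin` model (0 rules): a list with `n_inputs`,
#'   `n_outputs`, `class_labels`, `centers` / `widths` (0 x n matrices), and
#'   `weights` (array `(n_inputs + 1) x 0 x n_outputs`).
#' @export
sonfin <- function(n_inputs, n_outputs = 4L,
                   class_labels = c("N", "V", "L", "R")[seq_len(n_outputs)]) {
  stopifnot(n_inputs >= 1, n_outputs >= 1,
            length(class_labels) == n_outputs)
  structure(
    list(n_inputs = as.integer(n_inputs), n_outputs = as.integer(n_outputs),
         class_labels = class_labels,
         centers = matrix(numeric(0), 0, n_inputs),
         widths = matrix(numeric(0), 0, n_inputs),
         weights = array(0, dim = c(n_inputs + 1L, 0L, n_outputs)),
         trained = FALSE),
    class = "sonfin")
}

n_rules <- function(model) nrow(model$centers)

#' @export
print.sonfin <- function(x, ...) {
  cat(sprintf("<sonfin> %d inputs, %d outputs (%s), %d rule(s)%s\n",
              x$n_inputs, x$n_outputs, paste(x$class_labels, collapse = "/"),
              n_rules(x), if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

#' Gaussian membership degree
#'
#' `exp(-(value - m)^2 / sigma^2)` — degree to which `value` belongs to the
#' fuzzy set with center `m` and width `sigma`.
#'
#' @param value Input value(s).
#' @param m Center.
#' @param sigma Width, strictly positive.
#' @return Membership degree(s) in `(0, 1]`.
#' @export
membership <- function(value, m, sigma) {
  if (any(sigma <= 0)) stop("membership: sigma must be > 0")
  exp(-(value - m)^2 / sigma^2)
}

# log firing strengths: log u3_j = -sum_i (x_i - m_ji)^2 / sigma_ji^2
log_firing <- function(model, x) {
  if (length(x) != model$n_inputs)
    stop("input has length ", length(x), ", model expects ", model$n_inputs)
  if (!n_rules(model)) return(numeric(0))
  d <- sweep(model$centers, 2, x)            # m_ji - x_i
  -rowSums((d / model$widths)^2)
}

#' Rule firing strengths
#'
#' Product over inputs of the Gaussian membership degrees (Layer 3).
#'
#' @param model A `sonfin` model.
#' @param x Input vector of length `n_inputs`.
#' @return Numeric vector, one strength in `(0, 1]` per rule.
#' @export
firing_strengths <- function(model, x) exp(log_firing(model, x))

# normalized strengths via log-sum-exp (softmax over log firings)
normalized_firing <- function(logu) {
  m <- max(logu)
  e <- exp(logu - m)
  e / sum(e)
}

# per-rule consequent values: p x K matrix, z[j, k] = w0_jk + sum_i w_ijk x_i
consequent_values <- function(model, x) {
  p <- n_rules(model); K <- model$n_outputs
  z <- matrix(0, p, K)
  xx <- c(1, x)
  for (k in seq_len(K))
    z[, k] <- drop(crossprod(model$weights[, , k, drop = FALSE][, , 1], xx))
  z
}

#' SoNFIN forward pass
#'
#' Defuzzified output: for each output node k,
#' `o_k = sum_j u3_j (w0_jk + sum_i w_ijk x_i) / sum_j u3_j` — a convex
#' combination of the rules' consequent values.
#'
#' @param model A `sonfin` with at least one rule.
#' @param x Input vector.
#' @return Named numeric vector of length `n_outputs`.
#' @export
sonfin_forward <- function(model, x) {
  if (!n_rules(model)) stop("sonfin_forward: model has no rules")
  phi <- normalized_firing(log_firing(model, x))
  z <- consequent_values(model, x)
  stats::setNames(drop(crossprod(z, phi)), model$class_labels)
}

#' Online rule generation (structure learning)
#'
#' If the model is empty, or the maximum firing strength over all rules at
#' `x` is below the threshold `H`, a new rule is appended with centers at
#' `x`, all widths `sigma0`, and zero consequent weights (which leaves the
#' input-output map unchanged at creation except through normalization).
#'
#' @param model A `sonfin`.
#' @param x Input vector.
#' @param H Rule-generation threshold in (0, 1); larger H generates more
#'   rules (default 0.1).
#' @param sigma0 Initial Gaussian width (default 0.6).
#' @return A list with `model` (possibly grown) and `added` (logical).
#' @export
maybe_add_rule <- function(model, x, H = 0.1, sigma0 = 0.6) {
  stopifnot(H > 0, H < 1, sigma0 > 0)
  add <- !n_rules(model) || max(log_firing(model, x)) < log(H)
  if (add) {
    model$centers <- rbind(model$centers, x)
    model$widths <- rbind(model$widths, rep(sigma0, model$n_inputs))
    rownames(model$centers) <- rownames(model$widths) <- NULL
    old <- model$weights
    p <- dim(old)[2] + 1L
    w <- array(0, dim = c(model$n_inputs + 1L, p, model$n_outputs))
    if (p > 1L) w[, seq_len(p - 1L), ] <- old
    model$weights <- w
  }
  list(model = model, added = add)
}

#' Recursive least-squares state for the consequent parameters
#'
#' The consequent layer is linear in its parameters: stacking each rule's
#' `(w0_jk, w_1jk, ..., w_njk)` scaled by the rule's normalized firing
#' strength gives a regressor shared by all output nodes, so one covariance
#' matrix serves every output.
#'
#' @param model A `sonfin` (used for dimensions).
#' @param p0 Initial covariance scale (default `1e4`).
#' @param lambda Forgetting factor in (0, 1] (default 1).
#' @return A list of class `rls_state` with `P` (covariance), `lambda`, `p0`.
#' @export
rls_state <- function(model, p0 = 1e4, lambda = 1) {
  d <- n_rules(model) * (model$n_inputs + 1L)
  structure(list(P = diag(p0, d), lambda = lambda, p0 = p0),
            class = "rls_state")
}

# regressor: normalized firing strengths (x) [1, x]; column-major matches
# as.vector(weights[, , k])
rls_regressor <- function(model, x, phi) {
  as.vector(outer(c(1, x), phi))
}

#' RLS update of the consequent weights
#'
#' One recursive least-squares step on the linear-in-parameters output, for
#' all output nodes at once (they share the regressor). If the covariance
#' loses positive definiteness numerically it is reset to `p0 * I` (logged
#' via a warning).
#'
#' @param model A non-empty `sonfin`.
#' @param rls An `rls_state` matching the model's current rule count (it is
#'   grown automatically after rule creation).
#' @param x Input vector.
#' @param d Target vector of length `n_outputs`.
#' @return A list with updated `model` and `rls`.
#' @export
update_consequent_rls <- function(model, rls, x, d) {
  if (!n_rules(model)) stop("update_consequent_rls: model has no rules")
  rls <- grow_rls(rls, model)
  phi <- normalized_firing(log_firing(model, x))
  r <- rls_regressor(model, x, phi)
  if (all(r == 0)) return(list(model = model, rls = rls))
  Pr <- rls$P %*% r
  denom <- rls$lambda + drop(crossprod(r, Pr))
  gain <- Pr / denom
  rls$P <- (rls$P - gain %*% crossprod(r, rls$P)) / rls$lambda
  rls$P <- (rls$P + t(rls$P)) / 2
  if (!all(is.finite(rls$P)) || any(diag(rls$P) <= 0)) {
    warning("RLS covariance lost positive definiteness; reset to p0 * I")
    rls$P <- diag(rls$p0, length(r))
  }
  z <- consequent_values(model, x)
  o <- drop(crossprod(z, phi))
  p <- n_rules(model)
  for (k in seq_len(model$n_outputs)) {
    theta <- as.vector(model$weights[, , k])
    theta <- theta + gain * (d[k] - o[k])
    model$weights[, , k] <- matrix(theta, model$n_inputs + 1L, p)
  }
  list(model = model, rls = rls)
}

grow_rls <- function(rls, model) {
  d_need <- n_rules(model) * (model$n_inputs + 1L)
  d_have <- nrow(rls$P)
  if (d_have == d_need) return(rls)
  if (d_have > d_need) stop("rls state larger than model")
  P <- diag(rls$p0, d_need)
  if (d_have) P[seq_len(d_have), seq_len(d_have)] <- rls$P
  rls$P <- P
  rls
}

#' Gradient-descent update of the consequent weights
#'
#' Alternative to RLS: one step of gradient descent on the squared error
#' `V = sum_k (d_k - o_k)^2` with respect to the consequent weights.
#'
#' @inheritParams update_consequent_rls
#' @param lr Learning rate (default 0.01).
#' @return Updated `sonfin`.
#' @export
update_consequent_gd <- function(model, x, d, lr = 0.01) {
  if (!n_rules(model)) stop("update_consequent_gd: model has no rules")
  phi <- normalized_firing(log_firing(model, x))
  z <- consequent_values(model, x)
  o <- drop(crossprod(z, phi))
  xx <- c(1, x)
  # dV/dw_jk = -2 (d_k - o_k) phi_j [1, x]
  for (k in seq_len(model$n_outputs)) {
    err <- d[k] - o[k]
    model$weights[, , k] <- model$weights[, , k] +
      lr * 2 * err * outer(xx, phi)
  }
  model
}

#' Gradient-descent update of the fuzzy-set parameters
#'
#' One step on the squared error `V = sum_k (d_k - o_k)^2` with respect to
#' every Gaussian center and width, with derivatives taken through the
#' normalized defuzzifier. Widths are clipped below at `1e-3` to stay
#' positive.
#'
#' @inheritParams update_consequent_rls
#' @param lr Learning rate (default 0.05).
#' @return Updated `sonfin`.
#' @export
update_fuzzy_gd <- function(model, x, d, lr = 0.05) {
  if (!n_rules(model)) stop("update_fuzzy_gd: model has no rules")
  g <- fuzzy_gradients(model, x, d)
  model$centers <- model$centers - lr * g$dm
  model$widths <- pmax(model$widths - lr * g$dsigma, 1e-3)
  model
}

# dV/dm_ji and dV/dsigma_ji via: dV/dlogu3_j = sum_k -2 (d_k - o_k)
# phi_j (z_jk - o_k); dlogu3_j/dm_ji = 2 (x_i - m_ji)/sigma^2;
# dlogu3_j/dsigma_ji = 2 (x_i - m_ji)^2 / sigma^3
fuzzy_gradients <- function(model, x, d) {
  phi <- normalized_firing(log_firing(model, x))
  z <- consequent_values(model, x)
  o <- drop(crossprod(z, phi))
  g_log <- drop((z - matrix(o, n_rules(model), model$n_outputs,
                            byrow = TRUE)) %*% (-2 * (d - o))) * phi
  dx <- -sweep(model$centers, 2, x)          # x_i - m_ji
  dm <- g_log * (2 * dx / model$widths^2)
  dsigma <- g_log * (2 * dx^2 / model$widths^3)
  list(dm = dm, dsigma = dsigma)
}

# squared-error objective of one sample
sonfin_error <- function(model, x, d) sum((d - sonfin_forward(model, x))^2)

#' Training configuration
#'
#' @param H Rule-generation threshold (default 0.1).
#' @param sigma0 Initial fuzzy-set width (default 0.6).
#' @param iterations Training epochs (default 1000; sweeps over the dataset).
#' @param lr_consequent Consequent learning rate for `consequent_mode =
#'   "gradient"` (default 0.01).
#' @param lr_fuzzy Fuzzy-set (antecedent) learning rate (default 0.05).
#' @param consequent_mode `"rls"` (recursive least squares, default) or
#'   `"gradient"`.
#' @param structure_epochs Epochs during which structure learning (rule
#'   creation) is active (default 1: rules are created on the first pass and
#'   the structure is then frozen, keeping rule count bounded and the run
#'   reproducible).
#' @param shuffle Shuffle sample order each epoch (default FALSE).
#' @param seed Integer seed (used when `shuffle = TRUE`).
#' @return A list of class `sonfin_config`.
#' @export
sonfin_config <- function(H = 0.1, sigma0 = 0.6, iterations = 1000L,
                          lr_consequent = 0.01, lr_fuzzy = 0.05,
                          consequent_mode = c("rls", "gradient"),
                          structure_epochs = 1L, shuffle = FALSE,
                          seed = 1L) {
  consequent_mode <- match.arg(consequent_mode)
  stopifnot(H > 0, H < 1, sigma0 > 0, iterations >= 1)
  structure(list(H = as.numeric(H), sigma0 = as.numeric(sigma0),
                 iterations = as.integer(iterations),
                 lr_consequent = as.numeric(lr_consequent),
                 lr_fuzzy = as.numeric(lr_fuzzy),
                 consequent_mode = consequent_mode,
                 structure_epochs = as.integer(structure_epochs),
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "sonfin_config")
}

#' Desired-output coding for a class label
#'
#' Class k of K is coded as a K-vector of -1 with +1 at position k.
#'
#' @param label Integer class index (1-based) or label matching
#'   `class_labels`.
#' @param class_labels Character vector of class labels.
#' @return Numeric target vector.
#' @export
target_coding <- function(label, class_labels = c("N", "V", "L", "R")) {
  k <- if (is.character(label)) match(label, class_labels) else as.integer(label)
  if (is.na(k) || k < 1 || k > length(class_labels))
    stop("unknown class label: ", label)
  d <- rep(-1, length(class_labels))
  d[k] <- 1
  d
}

#' Train a SoNFIN
#'
#' Structure and parameter learning run concurrently over the data: for each
#' sample, first the structure step ([maybe_add_rule()], active during the
#' first `structure_epochs` epochs), then the parameter step — consequent
#' weights by RLS (or gradient descent), fuzzy-set centers/widths by gradient
#' descent. Returns the trained model with a per-epoch total squared-error
#' trace.
#'
#' @param features Numeric matrix, one sample per row.
#' @param labels Class labels: integers `1..K` or characters matching
#'   `class_labels`.
#' @param config A [sonfin_config()].
#' @param class_labels Output-node labels (default `c("N","V","L","R")`).
#' @param model Optional existing `sonfin` to continue training.
#' @return A trained `sonfin`; attribute `"error_trace"` holds the per-epoch
#'   sum of `sum_k (d_k - o_k)^2`, and `"rule_trace"` the rule count per
#'   epoch.
#' @export
sonfin_train <- function(features, labels, config = sonfin_config(),
                         class_labels = c("N", "V", "L", "R"),
                         model = NULL) {
  features <- as.matrix(features)
  if (!nrow(features)) stop("sonfin_train: empty dataset")
  if (nrow(features) != length(labels))
    stop("sonfin_train: features and labels disagree in length")
  K <- length(class_labels)
  targets <- t(vapply(labels, target_coding, numeric(K),
                      class_labels = class_labels))
  if (is.null(model))
    model <- sonfin(ncol(features), K, class_labels)
  rls <- rls_state(model)
  set.seed(config$seed)
  err_trace <- numeric(config$iterations)
  rule_trace <- integer(config$iterations)
  order0 <- seq_len(nrow(features))
  for (epoch in seq_len(config$iterations)) {
    ord <- if (config$shuffle) sample(order0) else order0
    e_sum <- 0
    for (s in ord) {
      x <- features[s, ]; d <- targets[s, ]
      if (epoch <= config$structure_epochs) {
        st <- maybe_add_rule(model, x, config$H, config$sigma0)
        model <- st$model
      }
      e_sum <- e_sum + sonfin_error(model, x, d)
      if (config$consequent_mode == "rls") {
        up <- update_consequent_rls(model, rls, x, d)
        model <- up$model; rls <- up$rls
      } else {
        model <- update_consequent_gd(model, x, d, config$lr_consequent)
      }
      model <- update_fuzzy_gd(model, x, d, config$lr_fuzzy)
    }
    err_trace[epoch] <- e_sum
    rule_trace[epoch] <- n_rules(model)
  }
  model$trained <- TRUE
  attr(model, "error_trace") <- err_trace
  attr(model, "rule_trace") <- rule_trace
  model
}

#' Predict SoNFIN outputs for a feature matrix
#'
#' @param object A trained `sonfin`.
#' @param newdata Numeric matrix, one sample per row.
#' @param ... Unused.
#' @return Numeric matrix (`nrow(newdata)` x `n_outputs`) of raw outputs,
#'   columns named by `class_labels`.
#' @export
predict.sonfin <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- t(apply(newdata, 1, function(x) sonfin_forward(object, x)))
  if (nrow(newdata) == 1L) out <- matrix(out, 1L,
                                         dimnames = list(NULL, object$class_labels))
  colnames(out) <- object$class_labels
  out
}

#' Serialize / restore a SoNFIN model
#'
#' @param model A `sonfin`.
#' @param path JSON file path.
#' @return `write_sonfin` invisibly returns `path`; `read_sonfin` the model.
#' @export
write_sonfin <- function(model, path) {
  stopifnot(inherits(model, "sonfin"))
  obj <- list(type = "sonfin", n_inputs = model$n_inputs,
              n_outputs = model$n_outputs,
              class_labels = model$class_labels,
              centers = model$centers, widths = model$widths,
              weights = stats::setNames(
                lapply(seq_len(model$n_outputs), function(k)
                  model$weights[, , k, drop = FALSE][, , 1]),
                paste0("output", seq_len(model$n_outputs))),
              trained = isTRUE(model$trained))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sonfin
#' @export
read_sonfin <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "sonfin")) stop("not a serialized sonfin: ", path)
  m <- sonfin(obj$n_inputs, obj$n_outputs, obj$class_labels)
  m$centers <- matrix(as.numeric(obj$centers), ncol = obj$n_inputs)
  m$widths <- matrix(as.numeric(obj$widths), ncol = obj$n_inputs)
  p <- nrow(m$centers)
  w <- array(0, dim = c(obj$n_inputs + 1L, p, obj$n_outputs))
  for (k in seq_len(obj$n_outputs))
    w[, , k] <- matrix(as.numeric(obj$weights[[k]]), obj$n_inputs + 1L, p)
  m$weights <- w
  m$trained <- isTRUE(obj$trained)
  m
}
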