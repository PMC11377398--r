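# Annotation-guided sparse network: a variant layer sparsely connected to a
# gene layer (one weight per topology row), the gene layer fully connected
# to a single logistic output. Gene node g computes
#   h_g = act( sum_{v in g} w_v x_v + b_g )
# and the output is sigmoid( sum_g u_g h_g + c ). With the default linear
# gene activation the gene nodes are parallel regressions of their variants
# and the output layer is a logistic regression on the gene values.
# Trained by mini-batch Adam on mean binary cross-entropy.

#' Build an untrained sparse gene network
#'
#' Allocates parameters for the sparse architecture defined by a topology
#' table: one weight per variant (its edge into its gene node), one bias
#' and one output weight per gene, and one output bias — i.e.
#' `n_variants + 2 * n_genes + 1` trainable scalars in total. Weights are
#' initialised from a small-variance normal distribution, biases at zero.
#'
#' @param topology Tibble from [make_topology()] / [build_topology()].
#' @param gene_activation Activation of the gene layer: `"linear"`
#'   (default; gene nodes act as parallel regressions) or `"tanh"`.
#' @param init_sd Standard deviation of the weight initialisation.
#' @param missing_fill How `NA` genotypes are resolved at the input:
#'   `"zero"` (reference genotype; the default, defensible under a >= 90%
#'   call-rate floor) or `"mean"` (per-variant mean imputation).
#' @param seed Integer seed for the initialisation.
#' @return A `gennet` object.
#' @export
#' @examples
#' net <- build_gennet(make_topology(5, 2), seed = 1)
#' n_params(net)
build_gennet <- function(topology, gene_activation = c("linear", "tanh"),
                         init_sd = 0.05, missing_fill = c("zero", "mean"),
                         seed = 1L) {
  validate_topology(topology)
  gene_activation <- match.arg(gene_activation)
  missing_fill <- match.arg(missing_fill)
  V <- nrow(topology)
  genes <- topology$gene[!duplicated(topology$gene_node)]
  G <- length(genes)
  par <- withr::with_seed(as.integer(seed), list(
    w = stats::setNames(rnorm(V, 0, init_sd), topology$variant),
    b = stats::setNames(numeric(G), genes),
    u = stats::setNames(rnorm(G, 0, init_sd), genes),
    c = 0
  ))
  structure(list(
    par = par,
    topology = topology,
    gene_index = topology$gene_node + 1L,
    variant_ids = topology$variant,
    gene_ids = genes,
    activation = gene_activation,
    missing_fill = missing_fill,
    trained = FALSE,
    history = NULL
  ), class = "gennet")
}

#' Number of trainable parameters
#'
#' `n_variants + 2 * n_genes + 1` for a gene network or a topology table.
#'
#' @param x A `gennet` or a topology tibble.
#' @return Integer count.
#' @export
n_params <- function(x) {
  tp <- if (inherits(x, "gennet")) x$topology else x
  nrow(tp) + 2L * length(unique(tp$gene_node)) + 1L
}

#' @export
print.gennet <- function(x, ...) {
  cat(sprintf("<gennet> %d variants -> %d genes -> 1 (%s gene layer), %d parameters\n",
              length(x$par$w), length(x$par$u), x$activation, n_params(x)))
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d epochs, final loss %.4f%s\n", nrow(h),
                h$loss[nrow(h)],
                if (!all(is.na(h$val_loss)))
                  sprintf(" (val %.4f)", h$val_loss[nrow(h)]) else ""))
  } else cat("  untrained\n")
  invisible(x)
}

# Resolve missing genotypes per the network's fill rule.
fill_missing <- function(x, missing_fill) {
  if (!anyNA(x)) return(x)
  if (missing_fill == "zero") {
    x[is.na(x)] <- 0
  } else {
    mu <- colMeans(x, na.rm = TRUE)
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- mu[na_idx[, 2]]
  }
  x
}

# Forward pass. Returns scores, optionally the gene-layer values.
gennet_forward <- function(object, x, hidden = FALSE) {
  if (ncol(x) != length(object$par$w)) {
    abort(sprintf("input has %d variants but the network expects %d.",
                  ncol(x), length(object$par$w)))
  }
  x <- fill_missing(x, object$missing_fill)
  V <- length(object$par$w); G <- length(object$par$u)
  W <- matrix(0, V, G)
  W[cbind(seq_len(V), object$gene_index)] <- object$par$w
  pre <- x %*% W + rep(object$par$b, each = nrow(x))
  h <- if (object$activation == "tanh") tanh(pre) else pre
  z <- drop(h %*% object$par$u) + object$par$c
  p <- sigmoid(z)
  if (hidden) list(scores = p, hidden = h, pre = pre) else p
}

# Analytic gradient of mean binary cross-entropy (+ optional L1 on variant
# weights) with respect to all parameters, on a (mini-)batch.
gennet_grad <- function(object, x, y, l1 = 0) {
  n <- nrow(x)
  fw <- gennet_forward(object, x, hidden = TRUE)
  dz <- (fw$scores - y) / n
  du <- drop(crossprod(fw$hidden, dz))
  dc <- sum(dz)
  dh <- tcrossprod(dz, object$par$u)
  dpre <- if (object$activation == "tanh") dh * (1 - fw$hidden^2) else dh
  x_filled <- fill_missing(x, object$missing_fill)
  dW <- crossprod(x_filled, dpre)
  dw <- dW[cbind(seq_along(object$par$w), object$gene_index)]
  if (l1 > 0) dw <- dw + l1 * sign(object$par$w)
  list(w = dw, b = colSums(dpre), u = du, c = dc)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a sparse gene network
#'
#' Minimises mean binary cross-entropy by mini-batch Adam. Batch order is
#' reshuffled every epoch under the run seed, so a given seed yields a
#' bit-identical loss history and final weights. When validation data are
#' supplied, training stops early once the validation loss has not improved
#' for `patience` epochs and the best-validation weights are restored;
#' without validation data the network trains for exactly `max_epochs`
#' epochs (the hard cap used for full-cohort outlier scoring).
#'
#' @param x Samples x variants matrix of additive codes (`NA` allowed; see
#'   `missing_fill` in [build_gennet()]).
#' @param y 0/1 labels (1 = case), one per sample; both classes required.
#' @param topology Topology tibble (ignored when `object` is given).
#' @param object Optional pre-built [build_gennet()] network to train.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Epoch cap.
#' @param validation Optional `list(x = , y = )` held-out set for early
#'   stopping.
#' @param patience Early-stopping patience, in epochs.
#' @param l1 Optional L1 penalty on the variant weights (0 = off).
#' @param seed Run seed (initialisation + batch shuffling).
#' @param ... Passed to [build_gennet()] (`gene_activation`, `init_sd`,
#'   `missing_fill`).
#' @return A trained `gennet`; `$history` is a tibble with per-epoch
#'   `epoch`, `loss` (mean over batches) and `val_loss`.
#' @export
train_gennet <- function(x, y, topology = NULL, object = NULL,
                         batch_size = 64, learning_rate = 1e-3,
                         max_epochs = 200, validation = NULL, patience = 20,
                         l1 = 0, seed = 1L, ...) {
  y <- assert_binary_labels(y, "y")
  if (is.null(object)) {
    if (is.null(topology)) abort("supply `topology` or a built `object`.")
    object <- build_gennet(topology, seed = seed, ...)
  }
  if (nrow(x) != length(y)) abort("`x` and `y` disagree on sample count.")
  stopifnot(batch_size >= 1, max_epochs >= 1)
  x <- fill_missing(x, object$missing_fill)
  if (!is.null(validation)) {
    vx <- fill_missing(validation$x, object$missing_fill)
    vy <- validation$y
  }

  V <- length(object$par$w); G <- length(object$par$u)
  iw <- seq_len(V); ib <- V + seq_len(G); iu <- V + G + seq_len(G)
  ic <- V + 2L * G + 1L
  sel <- cbind(seq_len(V), object$gene_index)
  tanh_act <- object$activation == "tanh"

  withr::with_seed(as.integer(seed), {
    theta <- c(object$par$w, object$par$b, object$par$u, object$par$c)
    m <- numeric(length(theta)); v2 <- numeric(length(theta)); step <- 0L
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    n <- nrow(x)
    history <- vector("list", max_epochs)
    best_val <- Inf; best_theta <- theta; wait <- 0L; stopped <- max_epochs

    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]; yb <- y[idx]; nb <- length(idx)
        W <- matrix(0, V, G); W[sel] <- theta[iw]
        pre <- xb %*% W + rep(theta[ib], each = nb)
        h <- if (tanh_act) tanh(pre) else pre
        z <- drop(h %*% theta[iu]) + theta[ic]
        p <- sigmoid(z)
        epoch_loss <- epoch_loss + bce_loss(p, yb) * nb
        dz <- (p - yb) / nb
        du <- drop(crossprod(h, dz)); dc <- sum(dz)
        dh <- tcrossprod(dz, theta[iu])
        dpre <- if (tanh_act) dh * (1 - h^2) else dh
        dW <- crossprod(xb, dpre)
        dw <- dW[sel]
        if (l1 > 0) dw <- dw + l1 * sign(theta[iw])
        grad <- c(dw, colSums(dpre), du, dc)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * grad
        v2 <- b2 * v2 + (1 - b2) * grad * grad
        theta <- theta - learning_rate *
          (m / (1 - b1^step)) / (sqrt(v2 / (1 - b2^step)) + adam_eps)
      }
      val_loss <- NA_real_
      if (!is.null(validation)) {
        object$par <- list(w = theta[iw], b = theta[ib],
                           u = theta[iu], c = theta[ic])
        val_loss <- bce_loss(gennet_forward(object, vx), vy)
        if (val_loss < best_val) {
          best_val <- val_loss; best_theta <- theta; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) {
            history[[epoch]] <- c(epoch, epoch_loss / n, val_loss)
            stopped <- epoch
            break
          }
        }
      }
      history[[epoch]] <- c(epoch, epoch_loss / n, val_loss)
      stopped <- epoch
    }
    if (!is.null(validation)) theta <- best_theta
    object$par <- list(
      w = stats::setNames(theta[iw], object$variant_ids),
      b = stats::setNames(theta[ib], object$gene_ids),
      u = stats::setNames(theta[iu], object$gene_ids),
      c = theta[ic]
    )
  })
  hm <- do.call(rbind, history[seq_len(stopped)])
  object$history <- tibble(epoch = as.integer(hm[, 1]), loss = hm[, 2],
                           val_loss = hm[, 3])
  object$trained <- TRUE
  object
}

#' Predict case scores from a gene network
#'
#' @param object A `gennet`.
#' @param newdata Samples x variants matrix in topology variant order.
#' @param type `"response"` for scores in (0, 1), `"hidden"` for the
#'   gene-layer values (samples x genes).
#' @param ... Unused.
#' @return Numeric score vector, or a matrix for `type = "hidden"`.
#' @export
predict.gennet <- function(object, newdata, type = c("response", "hidden"),
                           ...) {
  type <- match.arg(type)
  fw <- gennet_forward(object, newdata, hidden = type == "hidden")
  if (type == "hidden") fw$hidden else fw
}

#' Ensemble gene importances
#'
#' Averages the gene-layer output weights (the coefficients of the final
#' logistic regression) across an ensemble of trained networks and ranks
#' genes by the result. Because the sign of a gene's weight is not
#' identifiable across independently initialised runs, `magnitude = TRUE`
#' ranks genes by the mean absolute weight instead.
#'
#' @param models A trained `gennet` or a list of them sharing one topology.
#' @param magnitude Rank by `|mean weight|` contributions (mean of absolute
#'   weights) instead of signed means?
#' @return Tibble with columns `gene`, `mean_weight`, `rank`, sorted by
#'   descending importance; ties broken alphabetically by gene id.
#' @export
gene_importances <- function(models, magnitude = FALSE) {
  if (inherits(models, "gennet")) models <- list(models)
  if (length(models) == 0) abort("empty model ensemble.")
  genes <- models[[1]]$gene_ids
  same <- vapply(models, function(mod) identical(mod$gene_ids, genes),
                 logical(1))
  if (!all(same)) abort("all ensemble members must share one topology.")
  U <- vapply(models, function(mod) mod$par$u, numeric(length(genes)))
  U <- matrix(U, nrow = length(genes))
  if (magnitude) U <- abs(U)
  mw <- rowMeans(U)
  out <- tibble(gene = genes, mean_weight = mw) |>
    arrange(desc(.data$mean_weight), .data$gene) |>
    mutate(rank = row_number())
  out
}
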