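#' @export
print.gladet <- function(x, ...) {
  cfg <- x$config
  cat("Contrastive graph-autoencoder anomaly detector\n")
  cat(sprintf("  trained on %d normal graphs ('%s', feature dim %d, features: %s)\n",
              x$data_info$n_train, x$data_info$name, x$data_info$feature_dim,
              x$data_info$feature_source))
  cat(sprintf("  encoder dims %s, projection %d, activation %s\n",
              paste(c(x$data_info$feature_dim, cfg$hidden_dims), collapse = "-"),
              cfg$proj_dim, cfg$activation))
  cat(sprintf("  %d epochs, batch %d, lr %g, eta %g, tau %g%s\n",
              cfg$epochs, cfg$batch_size, cfg$learning_rate, cfg$eta, cfg$tau,
              if (length(cfg$ablate)) paste0(", ablated: ",
                                             paste(cfg$ablate, collapse = "+")) else ""))
  n <- nrow(x$history)
  cat(sprintf("  final losses: L1 %.4f  L2 %.4f  L3 %.4f  total %.4f\n",
              x$history$L1[n], x$history$L2[n], x$history$L3[n],
              x$history$L_total[n]))
  invisible(x)
}

#' @export
summary.gladet <- function(object, ...) {
  h <- object$history
  npar <- length(flatten_params(object$params))
  out <- list(n_params = npar, epochs = nrow(h),
              first_total = h$L_total[1], final_total = h$L_total[nrow(h)],
              history_tail = utils::tail(h, 5), config = object$config)
  class(out) <- "summary.gladet"
  out
}

#' @export
print.summary.gladet <- function(x, ...) {
  cat(sprintf("gladet model: %d parameters, %d epochs\n", x$n_params, x$epochs))
  cat(sprintf("total loss: %.4f (epoch 1) -> %.4f (final)\n",
              x$first_total, x$final_total))
  cat("last epochs:\n")
  print(x$history_tail, row.names = FALSE)
  invisible(x)
}

#' Extract the learned weight matrices
#' @param object A fitted [gladet()] model.
#' @param ... Unused.
#' @return Named list of weight matrices and bias vectors.
#' @export
coef.gladet <- function(object, ...) {
  p <- object$params
  c(stats::setNames(p$W_enc, paste0("encoder_layer", seq_along(p$W_enc))),
    stats::setNames(p$W_dec, paste0("decoder_layer", seq_along(p$W_dec))),
    list(projection_W1 = p$Wp1, projection_b1 = p$bp1,
         projection_W2 = p$Wp2, projection_b2 = p$bp2))
}

#' Plot the training loss trajectory
#' @param x A fitted [gladet()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gladet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$L1, h$L2, h$L3, h$L_total), type = "l",
                    lty = 1, col = c("grey40", "steelblue", "darkorange", "black"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("L1 (reconstruction)", "L2 (contrastive)",
                                 "L3 (representation error)", "total"),
                   lty = 1, col = c("grey40", "steelblue", "darkorange", "black"),
                   bty = "n")
  invisible(x)
}

#' Save a fitted model to a checkpoint file
#'
#' Writes a versioned container with all weight arrays, the resolved
#' configuration and the training seed; [read_gladet()] restores it
#' bit-faithfully.
#'
#' @param object A fitted [gladet()] model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gladet <- function(object, path) {
  stopifnot(inherits(object, "gladet"))
  saveRDS(list(format = "gladet-checkpoint", version = 1L, model = object),
          path)
  invisible(path)
}

#' Load a fitted model from a checkpoint file
#' @param path Checkpoint written by [write_gladet()].
#' @return The restored `gladet` model.
#' @export
read_gladet <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "gladet-checkpoint"))
    stop("not a gladet checkpoint: ", path)
  x$model
}
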