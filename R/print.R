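# Compact print methods.

#' @export
print.remap_fit <- function(x, ...) {
  cat(sprintf("<remap_fit> objective: %s\n", x$objective))
  cat(sprintf("  architecture: %d -> %s, %d steps per fixation\n",
              x$net_config$input_dim,
              paste(x$net_config$hidden_sizes, collapse = " -> "),
              x$net_config$steps_per_fixation))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  epochs: %d  train loss: %.5g  held-out loss: %.5g\n",
                last$epoch, last$train_loss, last$heldout_loss))
  } else {
    cat("  untrained (initialized weights only)\n")
  }
  invisible(x)
}

#' @export
print.decoder_fit <- function(x, ...) {
  cat(sprintf("<decoder_fit> held-out R^2: x = %.3f, y = %.3f (n = %d rows)\n",
              x$r2["x"], x$r2["y"], x$n))
  cat(sprintf("  ridge penalties: %s; top unit beta: %.3g\n",
              paste(signif(x$lambda, 3), collapse = ", "),
              max(x$unit_beta)))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison> mean a = %.5g, mean b = %.5g, Welch t = %.3g, p = %.3g (n = %d)\n",
    x$mean_a, x$mean_b, x$t, x$p, x$n))
  invisible(x)
}

#' @export
print.loss_table <- function(x, ...) {
  cat(sprintf("<loss_table> %d conditions x %d fixations\n",
              length(x$losses), length(x$losses[[1]])))
  print(sort(vapply(x$losses, mean, 0)))
  invisible(x)
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> k = %d units\n", x$k))
  cat(sprintf("  mean onset loss: intact %.5g, targeted %.5g, random %.5g\n",
              mean(x$intact), mean(x$targeted), mean(x$random)))
  cat(sprintf("  targeted vs random: t = %.3g, p = %.3g\n",
              x$targeted_vs_random$t, x$targeted_vs_random$p))
  cat(sprintf("  activity: targeted %.4g vs population %.4g\n",
              x$targeted_activity, x$population_activity))
  invisible(x)
}

#' @export
print.spatial_memory_table <- function(x, ...) {
  cat("<spatial_memory_table> mean z-scored loss (distance x lag)\n")
  print(round(x$mean_z, 4))
  invisible(x)
}

#' @export
print.cluster_report <- function(x, ...) {
  if (x$degenerate) {
    cat("<cluster_report> degenerate: identical profiles, k = 1\n")
  } else {
    cat(sprintf("<cluster_report> k = %d (silhouette %.3f)\n",
                x$k, max(x$silhouette)))
    print(table(cluster = x$assignments))
  }
  invisible(x)
}
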